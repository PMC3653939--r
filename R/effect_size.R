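#' Per-seed recruitment effect size for a single quadrat
#'
#' The realized-limitation effect size: the number of new recruits per seed
#' added, `(treatment_count - control_count) / seeds_added`. Values usually
#' lie in [0, 1] (1 = complete seed limitation, 0 = complete establishment
#' limitation) but can fall outside that range — by chance, or through
#' overcompensating density dependence — and are returned unclipped.
#'
#' @param treatment_count Seedling count in the treatment quadrat (>= 0).
#' @param control_count Seedling count (or mean count) in matched control
#'   quadrats (>= 0).
#' @param seeds_added Seeds sown into the treatment quadrat (>= 1).
#' @return Numeric effect size(s); vectorised over all arguments.
#' @export
#' @examples
#' quadrat_effect_size(10, 2, 50) # 0.16
quadrat_effect_size <- function(treatment_count, control_count, seeds_added) {
  if (any(seeds_added == 0)) {
    stop("effect size is undefined when seeds_added = 0 (control level)",
         call. = FALSE)
  }
  if (any(seeds_added < 1)) {
    stop("seeds_added must be >= 1", call. = FALSE)
  }
  (treatment_count - control_count) / seeds_added
}

#' Plot-level effect sizes at one census
#'
#' Aggregates quadrat counts into a single plot-level effect size per
#' species x augmentation-level combination: the control reference is the
#' mean count over that plot x species' control quadrats (augmentation 0) at
#' the census, and quadrat effect sizes are averaged over treatment quadrats
#' sharing plot, species and level. Strata with no control quadrat are
#' skipped with a warning listing them. Out-of-range values are flagged
#' (`flag` column: `"ok"`, `"negative"` or `"gt1"`), never clipped.
#'
#' @param records Quadrat-record table (see [simulate_experiment()] for the
#'   schema).
#' @param census_month The census to evaluate.
#' @return A data.frame with columns `plot_id`, `species_code`,
#'   `aug_multiple`, `census_month`, `E`, `n_quadrats`, `flag`.
#' @export
plot_effect_sizes <- function(records, census_month) {
  stopifnot(is.data.frame(records))
  x <- records[records$census_month == census_month, , drop = FALSE]
  if (nrow(x) == 0) {
    return(data.frame(plot_id = character(), species_code = character(),
                      aug_multiple = numeric(), census_month = numeric(),
                      E = numeric(), n_quadrats = integer(),
                      flag = character(), stringsAsFactors = FALSE))
  }
  ctrl <- x[x$aug_multiple == 0, , drop = FALSE]
  trt <- x[x$aug_multiple > 0, , drop = FALSE]
  ctrl_key <- paste(ctrl$plot_id, ctrl$species_code)
  ctrl_mean <- tapply(ctrl$seedling_count, ctrl_key, mean)

  trt_key <- paste(trt$plot_id, trt$species_code)
  has_ctrl <- trt_key %in% names(ctrl_mean)
  if (any(!has_ctrl)) {
    missing <- sort(unique(trt_key[!has_ctrl]))
    warning("skipping strata with no control quadrat at month ",
            census_month, ": ", paste(missing, collapse = "; "),
            call. = FALSE)
    trt <- trt[has_ctrl, , drop = FALSE]
    trt_key <- trt_key[has_ctrl]
  }
  if (nrow(trt) == 0) {
    return(data.frame(plot_id = character(), species_code = character(),
                      aug_multiple = numeric(), census_month = numeric(),
                      E = numeric(), n_quadrats = integer(),
                      flag = character(), stringsAsFactors = FALSE))
  }
  e_quadrat <- quadrat_effect_size(trt$seedling_count,
                                   as.numeric(ctrl_mean[trt_key]),
                                   trt$seeds_added)
  grp <- interaction(trt$plot_id, trt$species_code, trt$aug_multiple,
                     drop = TRUE, lex.order = TRUE)
  agg <- data.frame(
    plot_id = tapply(trt$plot_id, grp, `[`, 1),
    species_code = tapply(trt$species_code, grp, `[`, 1),
    aug_multiple = as.numeric(tapply(trt$aug_multiple, grp, `[`, 1)),
    census_month = census_month,
    E = as.numeric(tapply(e_quadrat, grp, mean)),
    n_quadrats = as.integer(tapply(e_quadrat, grp, length)),
    stringsAsFactors = FALSE
  )
  agg$flag <- ifelse(agg$E < 0, "negative", ifelse(agg$E > 1, "gt1", "ok"))
  agg <- agg[order(agg$plot_id, agg$species_code, agg$aug_multiple), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Plot-level effect sizes across all censuses
#'
#' Applies [plot_effect_sizes()] at every census present in the data and
#' stacks the results, sorted by census month.
#'
#' @inheritParams plot_effect_sizes
#' @return A data.frame with the [plot_effect_sizes()] columns over all
#'   censuses.
#' @export
effect_size_time_series <- function(records) {
  stopifnot(is.data.frame(records))
  months <- sort(unique(records$census_month))
  out <- do.call(rbind, lapply(months, function(m) plot_effect_sizes(records, m)))
  if (is.null(out)) {
    out <- plot_effect_sizes(records[0, , drop = FALSE], NA_real_)
  }
  rownames(out) <- NULL
  out
}
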