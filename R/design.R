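#' Default focal-species profiles
#'
#' Five tropical tree species profiles used as generator defaults: mean annual
#' ambient seed rain (seeds m^-2 yr^-1) and mean conspecific adult density
#' (stems ha^-1, stems > 10 cm dbh). The between-plot SD of conspecific
#' density is not part of the published species table; the default of half the
#' mean is a generator convention.
#'
#' @return A data.frame with columns `code`, `ambient_seed_rain`,
#'   `conspecific_density_mean`, `conspecific_density_sd`.
#' @export
#' @examples
#' species_profiles()
species_profiles <- function() {
  data.frame(
    code = c("ENUT", "PLAU", "SKAM", "MARB", "MMAB"),
    ambient_seed_rain = c(0.10, 0.20, 0.26, 0.53, 0.58),
    conspecific_density_mean = c(1.17, 2.37, 0.57, 3.96, 1.67),
    conspecific_density_sd = c(1.17, 2.37, 0.57, 3.96, 1.67) / 2,
    stringsAsFactors = FALSE
  )
}

#' Define a seed-addition experiment design
#'
#' Describes the layout of a multi-species sowing experiment: plots each
#' holding several stations, each station holding one quadrat per species x
#' augmentation-level combination. Defaults reproduce a 21-plot, 3-station
#' design with 0.5 x 0.5 m quadrats, augmentation multiples
#' {0, 25, 50, 100, 200, 500, 2000} of species-specific ambient seed rain, and
#' censuses every 3 months from month 3 to month 24.
#'
#' @param n_plots Number of vegetation plots (>= 1).
#' @param stations_per_plot Sowing stations per plot (>= 1).
#' @param quadrat_area Quadrat area in m^2 (> 0).
#' @param aug_multiples Strictly increasing augmentation multiples of ambient
#'   seed rain; must contain 0 (the control level).
#' @param census_months Strictly increasing census times in months after
#'   sowing; first census >= 3.
#' @param species Species profile table as returned by [species_profiles()].
#' @param ambient_window_years Years of ambient seed rain accruing to every
#'   quadrat (controls plus treatments); ambient seeds per quadrat are
#'   `ambient_seed_rain * quadrat_area * ambient_window_years`.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_plots = 21,
                              stations_per_plot = 3,
                              quadrat_area = 0.25,
                              aug_multiples = c(0, 25, 50, 100, 200, 500, 2000),
                              census_months = seq(3, 24, by = 3),
                              species = species_profiles(),
                              ambient_window_years = 1) {
  if (n_plots < 1 || stations_per_plot < 1) {
    stop("n_plots and stations_per_plot must be >= 1", call. = FALSE)
  }
  if (quadrat_area <= 0) stop("quadrat_area must be > 0", call. = FALSE)
  if (!is.data.frame(species) || nrow(species) == 0) {
    stop("species must be a non-empty data.frame of species profiles", call. = FALSE)
  }
  need <- c("code", "ambient_seed_rain", "conspecific_density_mean",
            "conspecific_density_sd")
  miss <- setdiff(need, names(species))
  if (length(miss)) {
    stop("species table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(species$ambient_seed_rain <= 0)) {
    stop("ambient_seed_rain must be > 0 for every species", call. = FALSE)
  }
  if (any(species$conspecific_density_mean < 0) ||
      any(species$conspecific_density_sd < 0)) {
    stop("conspecific densities must be >= 0", call. = FALSE)
  }
  if (any(diff(aug_multiples) <= 0) || any(aug_multiples < 0)) {
    stop("aug_multiples must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (!0 %in% aug_multiples) {
    stop("aug_multiples must contain 0 (the control level)", call. = FALSE)
  }
  if (length(census_months) < 1 || any(diff(census_months) <= 0) ||
      census_months[1] < 3) {
    stop("census_months must be strictly increasing with first census >= 3",
         call. = FALSE)
  }
  if (ambient_window_years < 0) {
    stop("ambient_window_years must be >= 0", call. = FALSE)
  }
  structure(
    list(
      n_plots = as.integer(n_plots),
      stations_per_plot = as.integer(stations_per_plot),
      quadrat_area = quadrat_area,
      aug_multiples = as.numeric(aug_multiples),
      census_months = as.numeric(census_months),
      species = species,
      ambient_window_years = ambient_window_years
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Seed-addition experiment design\n")
  cat(sprintf("  %d plots x %d stations = %d stations\n", x$n_plots,
              x$stations_per_plot, x$n_plots * x$stations_per_plot))
  cat(sprintf("  %d species x %d augmentation levels (%s) per station\n",
              nrow(x$species), length(x$aug_multiples),
              paste(x$aug_multiples, collapse = ", ")))
  cat(sprintf("  quadrat area %.2f m^2; censuses at months %s\n",
              x$quadrat_area, paste(x$census_months, collapse = ", ")))
  invisible(x)
}

#' Seeds sown for an augmentation level
#'
#' Converts an augmentation multiple of ambient seed rain into a whole number
#' of seeds per quadrat: `round(aug_multiple * ambient_seed_rain *
#' quadrat_area)`, floored to 1 when the treatment is non-zero but the product
#' falls below one seed (one seed is always sown for a non-control treatment),
#' and 0 at the control level.
#'
#' @param aug_multiple Augmentation multiple (>= 0); vectorised.
#' @param ambient_seed_rain Ambient seed rain, seeds m^-2 yr^-1 (>= 0).
#' @param quadrat_area Quadrat area, m^2 (>= 0).
#' @return Integer vector of seeds to sow per quadrat.
#' @export
#' @examples
#' seeds_for_level(25, 0.10, 0.25)   # 0.625 seeds -> 1 (floor-to-one rule)
#' seeds_for_level(2000, 0.58, 0.25) # 290
seeds_for_level <- function(aug_multiple, ambient_seed_rain, quadrat_area) {
  if (any(aug_multiple < 0) || any(ambient_seed_rain < 0) ||
      any(quadrat_area < 0)) {
    stop("seeds_for_level: all inputs must be >= 0", call. = FALSE)
  }
  product <- aug_multiple * ambient_seed_rain * quadrat_area
  n <- as.integer(round(product))
  n[aug_multiple > 0 & product < 1] <- 1L
  n[aug_multiple == 0] <- 0L
  n
}

#' Expand a design into its quadrat layout
#'
#' Enumerates every quadrat of the experiment: each station receives one
#' quadrat per species x augmentation level (the 0 level being that species'
#' control quadrat), with seeds sown per [seeds_for_level()].
#'
#' @param design An [experiment_design()].
#' @return A data.frame with one row per quadrat: `plot_id`, `station_id`,
#'   `quadrat_id`, `species_code`, `aug_multiple`, `seeds_added`,
#'   `ambient_seed_rain`.
#' @export
build_design <- function(design) {
  if (!inherits(design, "experiment_design")) {
    stop("design must be an experiment_design object", call. = FALSE)
  }
  sp <- design$species
  per_station <- expand.grid(
    species_code = sp$code,
    aug_multiple = design$aug_multiples,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  per_station <- per_station[order(per_station$species_code,
                                   per_station$aug_multiple), , drop = FALSE]
  stations <- expand.grid(
    station = seq_len(design$stations_per_plot),
    plot = seq_len(design$n_plots),
    KEEP.OUT.ATTRS = FALSE
  )
  n_q <- nrow(per_station)
  out <- per_station[rep(seq_len(n_q), times = nrow(stations)), , drop = FALSE]
  out$plot_id <- sprintf("P%02d", rep(stations$plot, each = n_q))
  out$station_id <- paste0(out$plot_id,
                           sprintf("-S%d", rep(stations$station, each = n_q)))
  out$quadrat_id <- paste0(out$station_id, sprintf("-Q%02d", seq_len(n_q)))
  out$ambient_seed_rain <-
    sp$ambient_seed_rain[match(out$species_code, sp$code)]
  out$seeds_added <- seeds_for_level(out$aug_multiple, out$ambient_seed_rain,
                                     design$quadrat_area)
  rownames(out) <- NULL
  out[, c("plot_id", "station_id", "quadrat_id", "species_code",
          "aug_multiple", "seeds_added", "ambient_seed_rain")]
}
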