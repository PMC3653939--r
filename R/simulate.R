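#' Ground-truth parameters for the experiment generator
#'
#' The generator draws first-census seedling counts from a negative-binomial
#' (NB2) distribution whose mean follows a Beverton-Holt recruitment curve
#' with a multiplicative log-normal plot effect, and thins counts between
#' censuses by density-dependent binomial survival.
#'
#' Defaults are set to the middle of the parameter ranges typical of
#' community-level tropical seedling recruitment: per-seed recruitment
#' `P0 = 0.01`, saturation density `Rmax = 1.125` seedlings per 0.25 m^2
#' quadrat (4.5 m^-2), overdispersion `k = 1.5` (small k = strongly
#' overdispersed), plot effect SD 0.5 on the log scale, and a 3-monthly
#' survival of about 0.87 at low density (logit intercept 1.9) declining with
#' crowding (0.02 logits per standing seedling).
#'
#' @param P0 Per-seed recruitment probability under density-independent
#'   mortality only, in (0, 1].
#' @param Rmax Seedling saturation density, seedlings per quadrat (> 0).
#' @param k NB2 overdispersion parameter (> 0); variance = mu + mu^2/k.
#' @param sigma_plot SD of the plot-level log-scale random effect (>= 0).
#' @param surv_intercept Log-odds of surviving one inter-census interval at
#'   zero seedling density.
#' @param surv_density_slope Decrement of the survival log-odds per standing
#'   seedling in the quadrat (>= 0); 0 gives purely density-independent
#'   mortality.
#' @return An object of class `true_params`.
#' @export
true_params <- function(P0 = 0.01, Rmax = 1.125, k = 1.5, sigma_plot = 0.5,
                        surv_intercept = 1.9, surv_density_slope = 0.02) {
  if (P0 <= 0 || P0 > 1) stop("P0 must be in (0, 1]", call. = FALSE)
  if (Rmax <= 0) stop("Rmax must be > 0", call. = FALSE)
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  if (sigma_plot < 0) stop("sigma_plot must be >= 0", call. = FALSE)
  if (!is.finite(surv_intercept)) stop("surv_intercept must be finite", call. = FALSE)
  if (surv_density_slope < 0) stop("surv_density_slope must be >= 0", call. = FALSE)
  structure(
    list(P0 = P0, Rmax = Rmax, k = k, sigma_plot = sigma_plot,
         surv_intercept = surv_intercept,
         surv_density_slope = surv_density_slope),
    class = "true_params"
  )
}

#' @export
print.true_params <- function(x, ...) {
  cat("Generator truth: P0 =", x$P0, " Rmax =", x$Rmax, "/quadrat  k =", x$k,
      "\n  sigma_plot =", x$sigma_plot, " survival logit =", x$surv_intercept,
      "-", x$surv_density_slope, "x count\n")
  invisible(x)
}

#' Simulate a complete seed-addition experiment
#'
#' Generates a per-quadrat x census table of seedling counts from known
#' ground truth. Per quadrat, total seed input is
#' `S = seeds_added + ambient_seed_rain * quadrat_area * ambient_window_years`.
#' The count at the first census is drawn NB2 with mean
#' `exp(u_plot) * P0 * S / (1 + P0 * S / Rmax)` and overdispersion `k`, where
#' `u_plot ~ Normal(0, sigma_plot^2)` is shared by all quadrats of a plot.
#' Each later census applies binomial thinning with survival probability
#' `plogis(surv_intercept - surv_density_slope * count)`, so counts are
#' non-increasing over time (pure post-emergence mortality). Conspecific
#' adult density is drawn once per plot x species from a Normal truncated at
#' zero.
#'
#' @param design An [experiment_design()].
#' @param truth A [true_params()] object.
#' @param rng_seed Integer seed; identical seeds give identical tables.
#' @return A data.frame of quadrat records with columns `plot_id`,
#'   `station_id`, `quadrat_id`, `species_code`, `aug_multiple`,
#'   `seeds_added`, `ambient_seed_rain`, `conspecific_density`,
#'   `census_month`, `seedling_count`.
#' @export
#' @examples
#' d <- experiment_design(n_plots = 2, stations_per_plot = 1)
#' x <- simulate_experiment(d, true_params(), rng_seed = 1)
#' head(x)
simulate_experiment <- function(design, truth, rng_seed) {
  if (!inherits(design, "experiment_design")) {
    stop("design must be an experiment_design object", call. = FALSE)
  }
  if (!inherits(truth, "true_params")) {
    stop("truth must be a true_params object", call. = FALSE)
  }
  layout <- build_design(design)
  with_seed(rng_seed, {
    plots <- sprintf("P%02d", seq_len(design$n_plots))
    u_plot <- stats::rnorm(design$n_plots, 0, truth$sigma_plot)
    names(u_plot) <- plots

    # one conspecific adult density per plot x species, truncated at 0
    sp <- design$species
    dens <- expand.grid(plot_id = plots, species_code = sp$code,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    i <- match(dens$species_code, sp$code)
    dens$conspecific_density <- pmax(
      0, stats::rnorm(nrow(dens), sp$conspecific_density_mean[i],
                      sp$conspecific_density_sd[i])
    )

    key <- paste(layout$plot_id, layout$species_code)
    layout$conspecific_density <-
      dens$conspecific_density[match(key, paste(dens$plot_id, dens$species_code))]

    S <- layout$seeds_added + layout$ambient_seed_rain * design$quadrat_area *
      design$ambient_window_years
    mu <- exp(u_plot[layout$plot_id]) * bh_mean(S, truth$P0, truth$Rmax)
    n_q <- nrow(layout)
    counts <- matrix(0L, n_q, length(design$census_months))
    counts[, 1] <- stats::rnbinom(n_q, size = truth$k, mu = mu)
    if (length(design$census_months) > 1) {
      for (j in 2:length(design$census_months)) {
        prev <- counts[, j - 1]
        p_surv <- stats::plogis(truth$surv_intercept -
                                  truth$surv_density_slope * prev)
        counts[, j] <- stats::rbinom(n_q, size = prev, prob = p_surv)
      }
    }

    out <- layout[rep(seq_len(n_q), times = length(design$census_months)), ,
                  drop = FALSE]
    out$census_month <- rep(design$census_months, each = n_q)
    out$seedling_count <- as.integer(counts)
    rownames(out) <- NULL
    out[, c("plot_id", "station_id", "quadrat_id", "species_code",
            "aug_multiple", "seeds_added", "ambient_seed_rain",
            "conspecific_density", "census_month", "seedling_count")]
  })
}
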