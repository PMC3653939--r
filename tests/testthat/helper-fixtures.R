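# Shared fixtures, built in code.

# single-species design at full field scale (21 plots x 3 stations, 7 levels)
recovery_design <- function() {
  experiment_design(species = species_profiles()[5, , drop = FALSE])
}

# small deterministic quadrat table for likelihood oracles:
# 3 plots x 4 quadrats, one census
tiny_records <- function(counts = c(0, 2, 1, 3, 1, 0, 4, 2, 0, 1, 2, 5)) {
  data.frame(
    plot_id = rep(c("A", "B", "C"), each = 4),
    station_id = "s1",
    quadrat_id = paste0("q", seq_len(12)),
    species_code = "SPX",
    aug_multiple = rep(c(25, 50, 100, 200), 3),
    seeds_added = rep(c(5L, 10L, 20L, 40L), 3),
    ambient_seed_rain = 0.4,
    conspecific_density = 1,
    census_month = 3,
    seedling_count = as.integer(counts),
    stringsAsFactors = FALSE
  )
}

# hand-rolled records with explicit counts for effect-size arithmetic
effect_records <- function(trt_counts, ctrl_counts, seeds = 20L,
                           aug = 100, month = 3) {
  n_t <- length(trt_counts); n_c <- length(ctrl_counts)
  data.frame(
    plot_id = "P01",
    station_id = "P01-S1",
    quadrat_id = paste0("q", seq_len(n_t + n_c)),
    species_code = "SPX",
    aug_multiple = c(rep(aug, n_t), rep(0, n_c)),
    seeds_added = c(rep(seeds, n_t), rep(0L, n_c)),
    ambient_seed_rain = 0.5,
    conspecific_density = 1,
    census_month = month,
    seedling_count = as.integer(c(trt_counts, ctrl_counts)),
    stringsAsFactors = FALSE
  )
}

# dense-grid (trapezoid) oracle for the marginal likelihood of one census
dense_grid_loglik <- function(records, params, model = "DD",
                              n_grid = 20001, span = 8,
                              quadrat_area = 0.25) {
  S <- records$seeds_added + records$ambient_seed_rain * quadrat_area
  m <- switch(model,
    DD = bh_mean(S, params$P0, params$Rmax),
    DI = params$P0 * S,
    SEED_ONLY = S,
    NO_DI = S / (1 + S / params$Rmax)
  )
  total <- 0
  u <- seq(-span * params$sigma_plot, span * params$sigma_plot,
           length.out = n_grid)
  for (pl in unique(records$plot_id)) {
    i <- records$plot_id == pl
    ll_u <- colSums(matrix(
      stats::dnbinom(rep(records$seedling_count[i], length(u)),
                     size = params$k,
                     mu = as.vector(outer(m[i], exp(u))), log = TRUE),
      nrow = sum(i)
    ))
    g <- ll_u + stats::dnorm(u, 0, params$sigma_plot, log = TRUE)
    total <- total + log(pracma::trapz(u, exp(g)))
  }
  total
}

# data simulated directly from the binomial-logit hierarchical model
# (21 plots, 5 species, 6 augmentation levels) with known truth
logit_model_data <- function(seed, beta_aug = 0, sd_species = 0.5,
                             sd_plot = 0.5, intercept = -2) {
  set.seed(seed)
  g <- expand.grid(plot_id = sprintf("P%02d", 1:21),
                   species_code = paste0("S", 1:5),
                   aug_multiple = c(25, 50, 100, 200, 500, 2000),
                   stringsAsFactors = FALSE)
  g$quadrat_id <- paste0("q", seq_len(nrow(g)))
  g$station_id <- g$plot_id
  g$seeds_added <- pmax(1L, as.integer(round(g$aug_multiple * 0.3 * 0.25)))
  g$ambient_seed_rain <- 0.3
  g$census_month <- 3
  g$conspecific_density <- 1
  csp <- stats::rnorm(5, 0, sd_species); names(csp) <- paste0("S", 1:5)
  cpl <- stats::rnorm(21, 0, sd_plot); names(cpl) <- sprintf("P%02d", 1:21)
  z <- as.numeric(scale(log10(g$aug_multiple)))
  eta <- intercept + beta_aug * z + csp[g$species_code] + cpl[g$plot_id]
  g$seedling_count <- stats::rbinom(nrow(g), g$seeds_added,
                                    stats::plogis(eta))
  ctrl <- g[g$aug_multiple == 25, , drop = FALSE]
  ctrl$aug_multiple <- 0; ctrl$seeds_added <- 0L; ctrl$seedling_count <- 0L
  ctrl$quadrat_id <- paste0("c", seq_len(nrow(ctrl)))
  rbind(g, ctrl)
}
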