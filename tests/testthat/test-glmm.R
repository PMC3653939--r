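test_that("model specification enforces response-link pairing", {
  expect_error(glmm_spec("per_seed", link = "log"), "requires link")
  expect_error(glmm_spec("count", link = "logit"), "requires link")
  s <- glmm_spec("per_seed")
  expect_equal(s$link, "logit")
  # the observation-level deviate that makes the count model
  # lognormal-Poisson is always present
  s <- glmm_spec("count", random_effects = c("plot", "species"))
  expect_true("quadrat" %in% s$random_effects)
})

test_that("Gelman-Rubin PSRF behaves at its anchor cases", {
  set.seed(1)
  ch <- rnorm(1000)
  expect_lte(gelman_rubin(list(ch, ch)), 1) # identical chains
  # chains from the same stationary normal are near 1
  chains <- replicate(4, rnorm(5000), simplify = FALSE)
  expect_lt(abs(gelman_rubin(chains) - 1), 0.05)
  # wildly separated chains: construct the pooled-variance PSRF by hand
  a <- rnorm(5000, 0, 1); b <- rnorm(5000, 10, 1)
  psrf <- gelman_rubin(list(a, b))
  expect_gt(psrf, 1.1)
  mns <- c(mean(a[1:2500]), mean(a[2501:5000]),
           mean(b[1:2500]), mean(b[2501:5000]))
  W <- mean(c(var(a[1:2500]), var(a[2501:5000]),
              var(b[1:2500]), var(b[2501:5000])))
  hand <- sqrt((2499 / 2500) + var(mns) / W)
  expect_equal(psrf, hand, tolerance = 1e-10)
  expect_warning(flat <- gelman_rubin(list(rep(1, 100), rep(1, 100))),
                 "zero")
  expect_lte(flat, 1)
  expect_error(gelman_rubin(list(rnorm(100))), ">= 2")
  expect_error(gelman_rubin(list(rnorm(5), rnorm(5))), "length")
})

test_that("PSRF agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  set.seed(4)
  chains <- replicate(3, as.numeric(arima.sim(list(ar = 0.4), 4000)),
                      simplify = FALSE)
  ours <- gelman_rubin(chains)
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                           autoburnin = FALSE)$psrf[1]
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("binomial GLMM summaries are well-formed and reproducible", {
  x <- logit_model_data(301, beta_aug = 0.3)
  spec <- glmm_spec("per_seed", fixed_effects = "aug_level",
                    random_effects = c("plot", "species"))
  s <- suppressWarnings(fit_effect_glmm(x, 3, spec, chains = 2,
                                        burn_in = 300, draws = 300,
                                        rng_seed = 2))
  expect_true(all(s$ci_2_5 <= s$mean & s$mean <= s$ci_97_5))
  expect_setequal(s$parameter,
                  c("intercept", "aug_level", "sd_plot", "sd_species"))
  dr <- attr(s, "draws")
  expect_equal(nrow(dr), 600)
  expect_equal(sort(unique(dr$chain)), 1:2)
  s2 <- suppressWarnings(fit_effect_glmm(x, 3, spec, chains = 2,
                                         burn_in = 300, draws = 300,
                                         rng_seed = 2))
  expect_identical(attr(s, "draws"), attr(s2, "draws"))
  expect_error(fit_effect_glmm(x, 3, spec, chains = 1, burn_in = 100,
                               draws = 100, rng_seed = 1), "chains")
})

test_that("a positive augmentation effect is detected, a null one is not", {
  spec <- glmm_spec("per_seed", fixed_effects = "aug_level",
                    random_effects = c("plot", "species"))
  x <- logit_model_data(310, beta_aug = 0.5)
  s <- suppressWarnings(fit_effect_glmm(x, 3, spec, chains = 3,
                                        burn_in = 600, draws = 600,
                                        rng_seed = 3))
  row <- s[s$parameter == "aug_level", ]
  expect_gt(row$ci_2_5, 0)
  # flat data: slope CI contains 0
  x0 <- logit_model_data(311, beta_aug = 0, sd_species = 0.2, sd_plot = 0.2)
  s0 <- suppressWarnings(fit_effect_glmm(x0, 3, spec, chains = 3,
                                         burn_in = 600, draws = 600,
                                         rng_seed = 4))
  row0 <- s0[s0$parameter == "aug_level", ]
  expect_true(row0$ci_2_5 <= 0 && 0 <= row0$ci_97_5)
})

test_that("all-zero successes warn but still return summaries", {
  x <- logit_model_data(320, intercept = -30)
  expect_true(all(x$seedling_count == 0))
  spec <- glmm_spec("per_seed", fixed_effects = "aug_level",
                    random_effects = c("plot", "species"))
  w <- capture_warnings(
    s <- fit_effect_glmm(x, 3, spec, chains = 2, burn_in = 200,
                         draws = 200, rng_seed = 5)
  )
  expect_true(any(grepl("zero", w)))
  expect_equal(nrow(s), 4)
})

test_that("the count GLMM recovers a plot-effect SD of known size", {
  # Poisson counts with log-normal quadrat noise and a plot effect
  make_counts <- function(seed, sd_plot = 0.8) {
    set.seed(seed)
    g <- expand.grid(plot_id = sprintf("P%02d", 1:21),
                     quadrat = 1:10, stringsAsFactors = FALSE)
    g$quadrat_id <- paste0("q", seq_len(nrow(g)))
    g$station_id <- g$plot_id
    g$species_code <- "S1"
    g$aug_multiple <- rep(c(25, 50, 100, 200, 500), length.out = nrow(g))
    g$seeds_added <- as.integer(round(g$aug_multiple * 0.1))
    g$ambient_seed_rain <- 0.4
    g$conspecific_density <- 1
    g$census_month <- 3
    u <- rnorm(21, 0, sd_plot); names(u) <- sprintf("P%02d", 1:21)
    eta <- 0.5 + u[g$plot_id] + rnorm(nrow(g), 0, 0.3)
    g$seedling_count <- rpois(nrow(g), exp(eta))
    g
  }
  spec <- glmm_spec("count", fixed_effects = "aug_level",
                    random_effects = c("quadrat", "plot"))
  est <- vapply(1:5, function(r) {
    x <- make_counts(400 + r)
    s <- suppressWarnings(fit_count_glmm(x, 3, spec, chains = 2,
                                         burn_in = 500, draws = 500,
                                         rng_seed = r))
    s$mean[s$parameter == "sd_plot"]
  }, numeric(1))
  expect_lt(abs(median(est) - 0.8) / 0.8, 0.5)
})
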