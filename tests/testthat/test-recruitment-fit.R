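test_that("bh_mean follows the saturating recruitment curve", {
  expect_equal(bh_mean(1000, 0.01, 5), 10 / 3)
  expect_equal(bh_mean(0, 0.5, 2), 0)
  expect_equal(bh_mean(1e9, 0.01, 5), 5, tolerance = 1e-5)
  expect_equal(bh_mean(100, 0.02, Inf), 2) # density-independent line
  expect_error(bh_mean(-1, 0.1, 5), ">= 0")
})

test_that("bh_mean is increasing, concave, bounded, with decreasing per-seed mean", {
  set.seed(3)
  for (i in 1:20) {
    P0 <- runif(1, 0.001, 0.9)
    Rmax <- exp(runif(1, log(0.5), log(50)))
    S <- sort(runif(200, 0.01, 5000))
    m <- bh_mean(S, P0, Rmax)
    expect_true(all(diff(m) > 0))
    expect_true(all(diff(diff(m) / diff(S)) < 1e-9)) # slope non-increasing
    expect_true(all(m <= pmin(P0 * S, Rmax) + 1e-12))
    expect_true(all(diff(m / S) < 0))
  }
})

test_that("nb_log_pmf is the NB2 mass with Poisson limit and unit normalisation", {
  expect_equal(nb_log_pmf(0, 1, 1), log(0.5))
  expect_equal(nb_log_pmf(2, 2, 1e6), dpois(2, 2, log = TRUE),
               tolerance = 1e-5)
  expect_equal(sum(exp(nb_log_pmf(0:2000, 3, 0.7))), 1, tolerance = 1e-10)
  expect_identical(nb_log_pmf(3, 0, 2), -Inf)
  expect_identical(nb_log_pmf(0, 0, 2), 0)
  expect_error(nb_log_pmf(-1, 1, 1), "non-negative")
})

test_that("marginal likelihood reduces exactly to the fixed-effects case at sigma = 0", {
  rec <- tiny_records()
  p <- bh_params(0.05, 3, k = 1.2, sigma_plot = 0)
  S <- rec$seeds_added + rec$ambient_seed_rain * 0.25
  direct <- sum(nb_log_pmf(rec$seedling_count, bh_mean(S, 0.05, 3), 1.2))
  expect_equal(marginal_loglik(rec, p, "DD"), direct, tolerance = 1e-12)
})

test_that("adaptive quadrature matches a dense-grid integral and is node-stable", {
  rec <- tiny_records()
  p <- bh_params(0.05, 3, k = 1.2, sigma_plot = 0.7)
  agq <- marginal_loglik(rec, p, "DD", n_nodes = 20)
  oracle <- dense_grid_loglik(rec, p, "DD")
  expect_equal(agq, oracle, tolerance = 1e-6)
  agq40 <- marginal_loglik(rec, p, "DD", n_nodes = 40)
  expect_lt(abs(agq40 - agq), 1e-6)
  expect_error(marginal_loglik(rec, p, "DD", n_nodes = 3), "n_nodes")
})

test_that("likelihood is invariant to quadrat order and plot relabelling", {
  rec <- tiny_records()
  p <- bh_params(0.03, 2, k = 0.8, sigma_plot = 0.4)
  base <- marginal_loglik(rec, p, "DD")
  set.seed(5)
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(marginal_loglik(shuf, p, "DD"), base, tolerance = 1e-12)
  relab <- rec
  relab$plot_id <- c(A = "Z9", B = "M2", C = "A1")[relab$plot_id]
  expect_equal(marginal_loglik(relab, p, "DD"), base, tolerance = 1e-12)
})

test_that("fit_model recovers the generator and flags degenerate inputs", {
  d <- recovery_design()
  tr <- true_params(sigma_plot = 0.3)
  x <- simulate_experiment(d, tr, rng_seed = 42)
  f <- fit_model(x, 3, "DD", options = list(n_starts = 3))
  expect_s3_class(f, "recruit_fit")
  expect_true(f$converged)
  # fitted optimum at least as good as the truth's likelihood
  truth_ll <- marginal_loglik(x[x$census_month == 3, ],
                              bh_params(tr$P0, tr$Rmax, tr$k, tr$sigma_plot),
                              "DD", n_nodes = 12)
  expect_gte(f$loglik, truth_ll - 1e-6)
  expect_lt(abs(f$estimates$P0 - tr$P0) / tr$P0, 0.8)
  expect_equal(f$aic, 2 * 4 - 2 * f$loglik)
  expect_true(all(f$ci$ci_2_5 <= f$ci$estimate & f$ci$estimate <= f$ci$ci_97_5))
  # DD needs at least two distinct seed inputs
  one_level <- x[x$aug_multiple == 100 & x$census_month == 3, ]
  expect_error(fit_model(one_level, 3, "DD"), "distinct seed-input")
  # all-zero counts pin P0 at the boundary with a warning
  zeros <- x[x$census_month == 3, ]
  zeros$seedling_count <- 0L
  expect_warning(fz <- fit_model(zeros, 3, "DD",
                                 options = list(n_starts = 2)), "zero")
  expect_true(fz$boundary)
  expect_lt(fz$estimates$P0, 1e-5)
})

test_that("free-parameter counts follow the nested-model definitions", {
  d <- experiment_design(n_plots = 4, stations_per_plot = 1,
                         species = species_profiles()[5, , drop = FALSE])
  x <- simulate_experiment(d, true_params(), rng_seed = 8)
  opts <- list(n_starts = 2, n_nodes = 8)
  expect_equal(fit_model(x, 3, "DD", opts)$n_free_params, 4)
  expect_equal(fit_model(x, 3, "DI", opts)$n_free_params, 3)
  expect_equal(fit_model(x, 3, "NO_DI", opts)$n_free_params, 3)
  f <- fit_model(x, 3, "SEED_ONLY", opts)
  expect_equal(f$n_free_params, 2)
  expect_equal(f$estimates$P0, 1)
  expect_true(is.infinite(f$estimates$Rmax))
})

test_that("model comparison ranks by AIC with the 4-unit distinction rule", {
  mkfit <- function(model, loglik, n_free) {
    structure(list(model = model, loglik = loglik, n_free_params = n_free,
                   aic = 2 * n_free - 2 * loglik, n_obs = 100),
              class = "recruit_fit")
  }
  cmp <- compare_models(list(mkfit("DD", -100, 4), mkfit("DI", -105, 3)))
  expect_equal(cmp$aic, c(208, 216))
  expect_equal(cmp$model[cmp$selected], "DD")
  expect_true(cmp$distinguished[1])
  # equal AICs: tie flagged, deterministic enum order
  cmp <- compare_models(list(mkfit("DI", -104, 3), mkfit("DD", -103, 4)))
  expect_equal(cmp$aic, c(214, 214))
  expect_equal(cmp$model, c("DD", "DI"))
  expect_true(all(cmp$tied))
  expect_false(cmp$distinguished[1])
  # single fit: selected but not distinguished
  cmp <- compare_models(mkfit("DD", -100, 4))
  expect_true(cmp$selected)
  expect_false(cmp$distinguished)
  # mismatched observations are refused
  f2 <- mkfit("DI", -105, 3); f2$n_obs <- 99
  expect_error(compare_models(list(mkfit("DD", -100, 4), f2)), "identical")
})
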