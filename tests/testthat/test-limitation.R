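test_that("limitation decomposition matches hand arithmetic", {
  l <- limitation_at(100, bh_params(P0 = 0.01, Rmax = 5))
  R <- 5 / 6
  expect_equal(l$L_S, 5 - R)          # 4.1667
  expect_equal(l$L_DI, 100 / 21 - R)  # 3.9286
  expect_equal(l$L_DD, 1 - R)         # 0.1667
  expect_equal(l$L_E, 100 - R)        # 99.1667
})

test_that("limitation edge cases: no seeds, no density-independent loss, no saturation", {
  p <- bh_params(P0 = 0.3, Rmax = 4)
  l0 <- limitation_at(0, p)
  expect_equal(l0$L_S, 4)
  expect_equal(c(l0$L_DI, l0$L_DD, l0$L_E), c(0, 0, 0))
  l1 <- limitation_at(c(1, 10, 500), bh_params(P0 = 1, Rmax = 4))
  expect_equal(l1$L_DI, rep(0, 3))
  expect_error(limitation_at(10, bh_params(P0 = 0.5, Rmax = Inf)),
               "undefined")
})

test_that("crossover closed forms hold and degenerate cleanly", {
  expect_equal(as.numeric(crossover_seed_establishment(bh_params(0.01, 4.5))),
               4.5)
  # in ambient multiples: 4.5 seeds/quadrat over 0.9 ambient = 5 multiples
  cv <- limitation_curve(bh_params(0.01, 4.5), ambient = 0.9)
  expect_equal(attr(cv, "crossover_seed_establishment")$multiples, 5)
  expect_equal(as.numeric(crossover_dd_di(bh_params(0.01, 4))), 396)
  expect_equal(as.numeric(crossover_dd_di(bh_params(0.5, 10))), 10)
  x <- crossover_dd_di(bh_params(1, 5))
  expect_equal(as.numeric(x), 0)
  expect_match(attr(x, "note"), "P0 = 1")
})

test_that("numeric root-finding agrees with the crossover algebra", {
  set.seed(11)
  for (i in 1:50) {
    p <- bh_params(P0 = runif(1, 0.001, 0.9),
                   Rmax = exp(runif(1, log(0.2), log(100))))
    # independent in-test root of L_E - L_S and L_DD - L_DI
    r1 <- uniroot(function(S) {
      l <- limitation_at(S, p); l$L_E - l$L_S
    }, c(1e-6, 1e7), tol = 1e-12)$root
    expect_equal(r1, as.numeric(crossover_seed_establishment(p)),
                 tolerance = 1e-6)
    r2 <- uniroot(function(S) {
      l <- limitation_at(S, p); l$L_DD - l$L_DI
    }, c(1e-8, 1e9), tol = 1e-12)$root
    expect_equal(r2, as.numeric(crossover_dd_di(p)), tolerance = 1e-6)
  }
})

test_that("limitation curve is monotone, ordered and rescaling-invariant", {
  p <- bh_params(P0 = 0.01, Rmax = 4.5)
  cv <- limitation_curve(p, ambient = 0.145)
  expect_equal(nrow(cv), 200)
  expect_true(all(diff(cv$L_S) < 0))
  expect_true(all(diff(cv$L_E) > 0))
  expect_true(all(cv$L_S >= 0 & cv$L_DI >= -1e-12 & cv$L_DD >= -1e-12 &
                    cv$L_E >= 0))
  expect_true(all(cv$L_DI + cv$L_DD <= cv$L_E + 1e-9))
  expect_true(all(pmax(cv$L_DI, cv$L_DD) <= cv$L_E + 1e-12))
  # at the grid point S = Rmax, seed and establishment limitation meet
  at <- limitation_at(p$Rmax, p)
  expect_equal(at$L_S, at$L_E)
  # ambient-multiple conversion is exact division, invariant to joint rescale
  cv2 <- limitation_curve(p, ambient = 0.29, grid = cv$S * 2)
  expect_equal(cv2$ambient_multiple, cv$ambient_multiple)
  expect_warning(limitation_curve(p, ambient = 0), "conversion omitted")
})

test_that("temporal trend computes Pearson r with its t test", {
  tr <- temporal_trend(c(10, 8, 6, 4, 2, 0), c(3, 6, 9, 12, 15, 18), "L_S")
  expect_equal(tr$pearson_r, -1)
  expect_lt(tr$p_value, 1e-6)
  expect_equal(tr$df, 4L)
  # t = r sqrt(df / (1 - r^2)) identity on a noisy series
  set.seed(2)
  v <- rnorm(8) + seq(0, 2, length.out = 8)
  tr <- temporal_trend(v, seq(3, 24, by = 3))
  expect_equal(tr$t_stat,
               tr$pearson_r * sqrt(tr$df / (1 - tr$pearson_r^2)))
  expect_warning(tz <- temporal_trend(rep(1, 5), 1:5), "zero-variance")
  expect_equal(tz$flag, "undefined_r")
  expect_error(temporal_trend(1:2, 1:2), ">= 3")
})

test_that("white-noise series trigger the 5% level at about the nominal rate", {
  set.seed(17)
  months <- seq(3, 24, by = 3) # 8 censuses, df = 6
  crit <- qt(0.975, 6)
  hits <- mean(replicate(1000, {
    tr <- temporal_trend(rnorm(8), months)
    abs(tr$t_stat) > crit
  }))
  expect_gt(hits, 0.03)
  expect_lt(hits, 0.08)
})

test_that("effect-size time slope pools species slopes", {
  base <- expand.grid(species_code = c("A", "B", "C"),
                      census_month = seq(3, 24, by = 3),
                      stringsAsFactors = FALSE)
  base$plot_id <- "P01"
  # constant E: slope exactly 0
  base$E <- 0.2
  expect_equal(effect_time_slope(base)$slope, 0)
  # exact common decline of 0.01/month
  base$E <- 0.5 - 0.01 * base$census_month +
    c(A = 0, B = 0.05, C = -0.05)[base$species_code]
  es <- effect_time_slope(base)
  expect_equal(es$slope, -0.01)
  expect_equal(es$method, "pooled")
  # single species falls back to plain OLS
  one <- base[base$species_code == "A", ]
  one$E <- one$E + rnorm(nrow(one), 0, 1e-3)
  es1 <- effect_time_slope(one)
  expect_equal(es1$method, "ols_fallback")
  expect_equal(es1$slope, -0.01, tolerance = 0.01)
})

test_that("a generator-built decline in E is recovered in sign", {
  # heavy density-independent thinning makes E fall over censuses
  sp <- species_profiles()[4:5, ]
  d <- experiment_design(n_plots = 8, stations_per_plot = 2, species = sp)
  tr <- true_params(P0 = 0.05, k = 5, sigma_plot = 0.2,
                    surv_intercept = 0.5, surv_density_slope = 0)
  hits <- 0
  for (r in 1:10) {
    x <- simulate_experiment(d, tr, rng_seed = 500 + r)
    es <- effect_time_slope(effect_size_time_series(x))
    hits <- hits + (es$slope < 0)
  }
  expect_gte(hits, 9)
})
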