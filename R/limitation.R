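#' Fundamental limitation decomposition at a seed input
#'
#' Decomposes the shortfall of recruitment below its fundamental optimum at
#' seed input `S`, given fitted Beverton-Holt parameters. Each component is
#' the recruitment gained by removing one limiting process while leaving the
#' others in place, relative to ambient recruitment `R = bh_mean(S)`:
#'
#' * seed limitation `L_S = Rmax - R` (limitless seed supply and no
#'   post-dispersal loss would yield `Rmax`);
#' * density-independent limitation `L_DI = S / (1 + S / Rmax) - R`
#'   (set `P0 = 1`);
#' * density-dependent limitation `L_DD = P0 * S - R` (let `Rmax -> Inf`);
#' * establishment limitation `L_E = S - R` (remove both losses: every
#'   dispersed seed recruits).
#'
#' @param S Seed input per quadrat (>= 0); vectorised.
#' @param params A [bh_params()] with finite `Rmax` (the decomposition needs
#'   a saturating fit).
#' @return A data.frame with columns `S`, `L_S`, `L_DI`, `L_DD`, `L_E`.
#' @export
#' @examples
#' limitation_at(100, bh_params(P0 = 0.01, Rmax = 5))
limitation_at <- function(S, params) {
  stopifnot(inherits(params, "bh_params"))
  if (is.infinite(params$Rmax)) {
    stop("limitation decomposition is undefined for Rmax = Inf ",
         "(no saturation to remove)", call. = FALSE)
  }
  if (any(S < 0)) stop("S must be >= 0", call. = FALSE)
  R <- bh_mean(S, params$P0, params$Rmax)
  data.frame(
    S = S,
    L_S = params$Rmax - R,
    L_DI = S / (1 + S / params$Rmax) - R,
    L_DD = params$P0 * S - R,
    L_E = S - R
  )
}

# numeric root of f on (lo, hi), used to confirm the closed forms
numeric_crossover <- function(f, lo, hi) {
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root
}

#' Seed input where establishment limitation overtakes seed limitation
#'
#' The crossover of `L_E(S)` and `L_S(S)`. Since `L_E - L_S = S - Rmax`, the
#' crossover is exactly `S* = Rmax`; a bracketing root-finder confirms the
#' closed form (attribute `"numeric_root"`).
#'
#' @param params A [bh_params()] with finite `Rmax`.
#' @return Crossover seed input per quadrat.
#' @export
crossover_seed_establishment <- function(params) {
  stopifnot(inherits(params, "bh_params"))
  if (is.infinite(params$Rmax)) {
    stop("crossover undefined for Rmax = Inf", call. = FALSE)
  }
  s_star <- params$Rmax
  f <- function(S) {
    l <- limitation_at(S, params)
    l$L_E - l$L_S
  }
  num <- numeric_crossover(f, s_star * 1e-6, s_star * 1e6)
  structure(s_star, numeric_root = num)
}

#' Seed input where density-dependent loss overtakes density-independent loss
#'
#' The crossover of `L_DD(S)` and `L_DI(S)`, closed form
#' `S* = Rmax * (1 - P0) / P0`, confirmed numerically (attribute
#' `"numeric_root"`). At `P0 = 1` density-independent loss is absent and the
#' crossover degenerates to 0 (attribute `"note"`).
#'
#' @param params A [bh_params()] with finite `Rmax`.
#' @return Crossover seed input per quadrat.
#' @export
crossover_dd_di <- function(params) {
  stopifnot(inherits(params, "bh_params"))
  if (is.infinite(params$Rmax)) {
    stop("crossover undefined for Rmax = Inf", call. = FALSE)
  }
  if (params$P0 == 1) {
    return(structure(0, note = "P0 = 1: no density-independent loss to overtake"))
  }
  s_star <- params$Rmax * (1 - params$P0) / params$P0
  f <- function(S) {
    l <- limitation_at(S, params)
    l$L_DD - l$L_DI
  }
  num <- numeric_crossover(f, s_star * 1e-6, s_star * 1e6)
  structure(s_star, numeric_root = num)
}

#' Limitation curves over a seed-input grid
#'
#' Evaluates the four limitation components over a grid of seed inputs and
#' attaches both crossover points, in seeds per quadrat and (when an ambient
#' seed input is supplied) in multiples of ambient seed density. The default
#' grid is log-spaced over 0.01-2000 ambient multiples (200 points).
#'
#' @param params A [bh_params()] with finite `Rmax`.
#' @param ambient Ambient seed input per quadrat (> 0 for the
#'   ambient-multiple conversion); defaults to `params$S_amb`.
#' @param grid Optional explicit grid of seed inputs per quadrat (positive,
#'   increasing).
#' @param grid_max_multiple,n_grid Default-grid extent in ambient multiples
#'   and number of (log-spaced) points.
#' @return A `limitation_curve` data.frame with columns `S`,
#'   `ambient_multiple` (if available), `L_S`, `L_DI`, `L_DD`, `L_E`;
#'   attributes `crossover_seed_establishment`, `crossover_dd_di` (each in
#'   seeds and multiples) and `params`.
#' @export
limitation_curve <- function(params, ambient = params$S_amb, grid = NULL,
                             grid_max_multiple = 2000, n_grid = 200) {
  stopifnot(inherits(params, "bh_params"))
  has_amb <- is.numeric(ambient) && length(ambient) == 1 && ambient > 0
  if (!has_amb) {
    warning("ambient seed input <= 0: ambient-multiple conversion omitted",
            call. = FALSE)
  }
  if (is.null(grid)) {
    base <- if (has_amb) ambient else 1
    grid <- base * exp(seq(log(0.01), log(grid_max_multiple),
                           length.out = n_grid))
  }
  if (any(grid <= 0) || any(diff(grid) <= 0)) {
    stop("grid must be positive and strictly increasing", call. = FALSE)
  }
  out <- limitation_at(grid, params)
  if (has_amb) out$ambient_multiple <- out$S / ambient
  cse <- crossover_seed_establishment(params)
  cdd <- crossover_dd_di(params)
  attr(out, "crossover_seed_establishment") <- list(
    seeds = as.numeric(cse),
    multiples = if (has_amb) as.numeric(cse) / ambient else NA_real_
  )
  attr(out, "crossover_dd_di") <- list(
    seeds = as.numeric(cdd),
    multiples = if (has_amb) as.numeric(cdd) / ambient else NA_real_
  )
  attr(out, "params") <- params
  class(out) <- c("limitation_curve", "data.frame")
  out
}

#' @export
print.limitation_curve <- function(x, ...) {
  cse <- attr(x, "crossover_seed_establishment")
  cdd <- attr(x, "crossover_dd_di")
  cat(sprintf("Limitation curve over %d seed inputs [%.3g, %.3g] seeds/quadrat\n",
              nrow(x), min(x$S), max(x$S)))
  cat(sprintf("  L_E overtakes L_S at S = %.4g seeds/quadrat (%.4g x ambient)\n",
              cse$seeds, cse$multiples))
  cat(sprintf("  L_DD overtakes L_DI at S = %.4g seeds/quadrat (%.4g x ambient)\n",
              cdd$seeds, cdd$multiples))
  invisible(x)
}

#' Pearson trend of a per-census quantity
#'
#' Correlates a per-census scalar (a limitation component, an effect size,
#' a fitted parameter) against census month, with the usual two-sided t test
#' on `n - 2` degrees of freedom.
#'
#' @param values Per-census values (length >= 3).
#' @param census_months Matching census months.
#' @param quantity Label for the tested quantity.
#' @return A list of class `trend_result`: `quantity`, `census_months`,
#'   `values`, `pearson_r`, `t_stat`, `df`, `p_value`, `flag` (`"ok"` or
#'   `"undefined_r"` for zero-variance series).
#' @export
temporal_trend <- function(values, census_months, quantity = "value") {
  if (length(values) != length(census_months)) {
    stop("values and census_months must have equal length", call. = FALSE)
  }
  if (length(values) < 3) stop("need >= 3 censuses", call. = FALSE)
  out <- list(quantity = quantity, census_months = census_months,
              values = values, df = length(values) - 2L)
  if (stats::sd(values) == 0 || stats::sd(census_months) == 0) {
    warning("zero-variance series: correlation undefined", call. = FALSE)
    out$pearson_r <- NA_real_; out$t_stat <- NA_real_
    out$p_value <- NA_real_; out$flag <- "undefined_r"
  } else {
    ct <- stats::cor.test(census_months, values, method = "pearson")
    out$pearson_r <- unname(ct$estimate)
    out$t_stat <- unname(ct$statistic)
    out$p_value <- ct$p.value
    out$flag <- "ok"
  }
  class(out) <- "trend_result"
  out
}

#' @export
print.trend_result <- function(x, ...) {
  if (identical(x$flag, "undefined_r")) {
    cat(sprintf("Trend of %s: undefined (zero-variance series)\n", x$quantity))
  } else {
    cat(sprintf("Trend of %s: r = %.3f, t = %.3f, df = %d, p = %.3g\n",
                x$quantity, x$pearson_r, x$t_stat, x$df, x$p_value))
  }
  invisible(x)
}

#' Pooled time slope of effect sizes across species
#'
#' Estimates the common rate of change of the per-seed effect size E with
#' census month, allowing each species its own intercept: an ordinary
#' least-squares slope is fitted per species and the slopes are pooled with
#' inverse-variance (precision) weights. Exactly collinear per-species data
#' (zero residual variance) get unbounded precision; such slopes are then
#' averaged unweighted and the t statistic is infinite unless the pooled
#' slope is 0.
#'
#' @param effects Effect-size table from [effect_size_time_series()].
#' @return A list: `slope`, `se`, `t_stat`, `df`, `n_species`, `method`
#'   (`"pooled"` or `"ols_fallback"` when only one species is present).
#' @export
effect_time_slope <- function(effects) {
  stopifnot(is.data.frame(effects))
  if (length(unique(effects$census_month)) < 2) {
    stop("need >= 2 censuses to estimate a time slope", call. = FALSE)
  }
  split_sp <- split(effects, effects$species_code)
  if (length(split_sp) < 2) {
    fit <- stats::lm(E ~ census_month, data = effects)
    s <- suppressWarnings(summary(fit))$coefficients["census_month", ]
    return(list(slope = unname(s["Estimate"]), se = unname(s["Std. Error"]),
                t_stat = unname(s["t value"]),
                df = fit$df.residual, n_species = length(split_sp),
                method = "ols_fallback"))
  }
  sl <- t(vapply(split_sp, function(d) {
    fit <- stats::lm(E ~ census_month, data = d)
    cf <- suppressWarnings(summary(fit))$coefficients
    c(b = cf["census_month", "Estimate"],
      se = cf["census_month", "Std. Error"],
      df = fit$df.residual)
  }, numeric(3)))
  exact <- sl[, "se"] < 1e-10
  if (any(exact)) {
    slope <- mean(sl[exact, "b"])
    se <- 0
    t_stat <- if (slope == 0) 0 else sign(slope) * Inf
  } else {
    w <- 1 / sl[, "se"]^2
    slope <- sum(w * sl[, "b"]) / sum(w)
    se <- sqrt(1 / sum(w))
    t_stat <- slope / se
  }
  list(slope = slope, se = se, t_stat = t_stat,
       df = as.integer(sum(sl[, "df"])), n_species = nrow(sl),
       method = "pooled")
}
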