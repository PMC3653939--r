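#' Specify a hierarchical model for realized limitation
#'
#' Two model families are supported: `response = "per_seed"` models the
#' per-seed recruitment of treatment quadrats with binomial error and a
#' logit link (trials = seeds sown, successes = recruits above the plot
#' control mean); `response = "count"` models seedling counts with a
#' lognormal-Poisson (Poisson with an observation-level normal deviate on
#' the log mean) and a log link. Fixed effects may include the seed
#' augmentation level and conspecific adult density; random effects may
#' include quadrat, plot, species and the crossed species-by-plot
#' interaction.
#'
#' @param response `"per_seed"` or `"count"`.
#' @param fixed_effects Subset of `c("aug_level", "conspecific_density")`.
#' @param random_effects Subset of
#'   `c("quadrat", "plot", "species", "species_x_plot")`. For the count
#'   response the quadrat (observation-level) deviate is what makes the
#'   error lognormal-Poisson and is added automatically if omitted.
#' @param link Link function; must match the response (`"logit"` for
#'   per_seed, `"log"` for count). Defaults accordingly.
#' @return An object of class `glmm_spec`.
#' @export
glmm_spec <- function(response = c("per_seed", "count"),
                      fixed_effects = c("aug_level", "conspecific_density"),
                      random_effects = c("quadrat", "plot", "species",
                                         "species_x_plot"),
                      link = NULL) {
  response <- match.arg(response)
  fixed_effects <- match.arg(fixed_effects,
                             c("aug_level", "conspecific_density"),
                             several.ok = TRUE)
  random_effects <- match.arg(random_effects,
                              c("quadrat", "plot", "species",
                                "species_x_plot"),
                              several.ok = TRUE)
  expected <- if (response == "per_seed") "logit" else "log"
  if (is.null(link)) link <- expected
  if (link != expected) {
    stop("response '", response, "' requires link '", expected, "'",
         call. = FALSE)
  }
  if (response == "count" && !"quadrat" %in% random_effects) {
    random_effects <- c("quadrat", random_effects)
  }
  structure(list(response = response, fixed_effects = fixed_effects,
                 random_effects = random_effects, link = link),
            class = "glmm_spec")
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# ---- MCMC engine: adaptive random-walk Metropolis within Gibbs ----------

# family: "binomial" (y successes of `trials`) or "poisson".
# Returns list(draws = matrix [chains*draws x p], chain = integer vector,
# par_names).
glmm_mcmc <- function(y, trials, X, re_idx, family, chains, burn_in, draws,
                      rng_seed, prior_on = "sd", sd_max = 100,
                      beta_prior_var = 100) {
  if (chains < 2) {
    stop("chains must be >= 2 (convergence diagnostics undefined otherwise)",
         call. = FALSE)
  }
  n <- length(y)
  p <- ncol(X)
  blocks <- names(re_idx)
  m_b <- vapply(re_idx, max, integer(1))

  loglik_vec <- if (family == "binomial") {
    function(eta) y * eta - trials * log1pexp(eta)
  } else {
    function(eta) y * eta - exp(eta)
  }
  # log prior for an SD given its deviates; uniform on sd or on precision
  log_sd_prior <- function(sd) {
    if (sd <= 0 || sd > sd_max) return(-Inf)
    if (prior_on == "sd") 0 else -3 * log(sd) # tau ~ U: p(sd) propto sd^-3
  }

  par_names <- c(colnames(X), paste0("sd_", blocks))
  all_draws <- vector("list", chains)

  for (ch in seq_len(chains)) {
    ch_draws <- with_seed(rng_seed + ch * 1000L, {
      beta <- stats::rnorm(p, 0, 0.1)
      d <- lapply(m_b, function(m) numeric(m))
      sd_b <- stats::setNames(rep(0.5 + 0.2 * ch, length(blocks)), blocks)
      eta <- as.vector(X %*% beta)
      for (b in blocks) eta <- eta + d[[b]][re_idx[[b]]]
      ll <- loglik_vec(eta)

      sc_beta <- rep(0.5, p)
      sc_d <- stats::setNames(rep(0.5, length(blocks)), blocks)
      sc_sd <- stats::setNames(rep(0.4, length(blocks)), blocks)
      acc_beta <- numeric(p); acc_d <- sc_d * 0; acc_sd <- sc_sd * 0
      batch <- 50L; since <- 0L

      out <- matrix(NA_real_, draws, length(par_names))
      total <- burn_in + draws
      for (it in seq_len(total)) {
        # fixed effects, one at a time
        for (j in seq_len(p)) {
          delta <- stats::rnorm(1, 0, sc_beta[j])
          eta_new <- eta + delta * X[, j]
          ll_new <- loglik_vec(eta_new)
          bj <- beta[j] + delta
          lr <- sum(ll_new - ll) +
            (beta[j]^2 - bj^2) / (2 * beta_prior_var)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            beta[j] <- bj; eta <- eta_new; ll <- ll_new
            acc_beta[j] <- acc_beta[j] + 1
          }
        }
        # random-effect deviates: vectorised elementwise Metropolis
        for (b in blocks) {
          idx <- re_idx[[b]]
          prop <- stats::rnorm(m_b[[b]], 0, sc_d[[b]])
          eta_new <- eta + prop[idx]
          ll_new <- loglik_vec(eta_new)
          dll <- rowsum(ll_new - ll, idx, reorder = TRUE)[, 1]
          dnew <- d[[b]] + prop
          dpr <- (d[[b]]^2 - dnew^2) / (2 * sd_b[[b]]^2)
          acc <- log(stats::runif(m_b[[b]])) < dll + dpr
          if (any(acc)) {
            d[[b]][acc] <- dnew[acc]
            keep <- acc[idx]
            eta[keep] <- eta_new[keep]
            ll[keep] <- ll_new[keep]
          }
          acc_d[[b]] <- acc_d[[b]] + mean(acc)
        }
        # recentring (Gibbs): shift each block's mean into the intercept.
        # eta is invariant, so the conditional of the shift is Gaussian.
        for (b in blocks) {
          m <- m_b[[b]]
          prec <- 1 / beta_prior_var + m / sd_b[[b]]^2
          mu_d <- (-beta[1] / beta_prior_var +
                     sum(d[[b]]) / sd_b[[b]]^2) / prec
          delta <- stats::rnorm(1, mu_d, 1 / sqrt(prec))
          beta[1] <- beta[1] + delta
          d[[b]] <- d[[b]] - delta
        }
        # random-effect SDs: random walk on the log scale
        for (b in blocks) {
          cur <- sd_b[[b]]
          new <- cur * exp(stats::rnorm(1, 0, sc_sd[[b]]))
          lp_cur <- sum(stats::dnorm(d[[b]], 0, cur, log = TRUE)) +
            log_sd_prior(cur)
          lp_new <- sum(stats::dnorm(d[[b]], 0, new, log = TRUE)) +
            log_sd_prior(new)
          lr <- lp_new - lp_cur + log(new) - log(cur) # log-scale Jacobian
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            sd_b[[b]] <- new
            acc_sd[[b]] <- acc_sd[[b]] + 1
          }
        }
        since <- since + 1L
        if (it <= burn_in && since == batch) {
          adj <- function(sc, acc, target) {
            sc * exp(pmin(pmax((acc / batch - target), -0.5), 0.5))
          }
          sc_beta <- pmax(adj(sc_beta, acc_beta, 0.44), 1e-3)
          sc_d <- pmax(adj(sc_d, acc_d, 0.44), 1e-3)
          sc_sd <- pmax(adj(sc_sd, acc_sd, 0.44), 1e-3)
          acc_beta[] <- 0; acc_d[] <- 0; acc_sd[] <- 0; since <- 0L
        }
        if (it > burn_in) {
          out[it - burn_in, ] <- c(beta, unname(sd_b))
        }
      }
      out
    })
    all_draws[[ch]] <- ch_draws
  }
  list(draws = do.call(rbind, all_draws),
       chain = rep(seq_len(chains), each = draws),
       par_names = par_names, chains = chains, n_draws = draws)
}

# split-chain summaries for every parameter
summarise_posterior <- function(mc) {
  draws <- mc$draws
  out <- data.frame(parameter = mc$par_names,
                    mean = colMeans(draws),
                    ci_2_5 = apply(draws, 2, stats::quantile, 0.025),
                    ci_97_5 = apply(draws, 2, stats::quantile, 0.975),
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(mc$par_names)) {
    per_chain <- split(draws[, j], mc$chain)
    out$rhat[j] <- suppressWarnings(gelman_rubin(per_chain))
    out$ess[j] <- ess_chains(per_chain)
  }
  rownames(out) <- NULL
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain PSRF: each chain is halved, the within-sequence variance `W`
#' and between-sequence variance `B` are combined into the pooled variance
#' estimate, and the statistic is `sqrt(((n-1)/n * W + B/n) / W)`. Values
#' near 1 indicate the chains have mixed; values above about 1.1 indicate
#' non-convergence.
#'
#' @param chains List of >= 2 equal-length numeric draw sequences
#'   (length >= 10).
#' @return The PSRF (a scalar). Degenerate zero-variance chains return a
#'   value <= 1 with a warning.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) {
    stop("need >= 2 chains", call. = FALSE)
  }
  len <- lengths(chains)
  if (length(unique(len)) != 1 || len[1] < 10) {
    stop("chains must have equal length >= 10", call. = FALSE)
  }
  half <- floor(len[1] / 2)
  seqs <- unlist(lapply(chains, function(x) {
    list(x[seq_len(half)], x[half + seq_len(half)])
  }), recursive = FALSE)
  mns <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(mns)
  if (W == 0) {
    warning("zero within-chain variance: PSRF degenerate", call. = FALSE)
    return(1)
  }
  sqrt((half - 1) / half + B_over_n / W)
}

# effective sample size via Geyer-style truncated autocorrelation sum
ess_chains <- function(chains) {
  n <- length(chains[[1]])
  m <- length(chains)
  if (all(vapply(chains, stats::var, numeric(1)) == 0)) return(m * n)
  max_lag <- min(n - 1, 200)
  rho <- rowMeans(vapply(chains, function(x) {
    if (stats::var(x) == 0) rep(0, max_lag + 1)
    else as.vector(stats::acf(x, lag.max = max_lag, plot = FALSE,
                              demean = TRUE)$acf)
  }, numeric(max_lag + 1)))
  s <- 0
  t <- 2
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(1, m * n / (1 + 2 * s))
}

# ---- data construction -------------------------------------------------

# Successes/trials for the binomial per-seed model: y = count minus the
# rounded plot x species control mean (floored at 0, capped at trials).
binomial_data <- function(records, census_month) {
  x <- records[records$census_month == census_month, , drop = FALSE]
  if (nrow(x) == 0) stop("no records at census month ", census_month,
                         call. = FALSE)
  ctrl <- x[x$aug_multiple == 0, , drop = FALSE]
  trt <- x[x$aug_multiple > 0, , drop = FALSE]
  cm <- tapply(ctrl$seedling_count, paste(ctrl$plot_id, ctrl$species_code),
               mean)
  key <- paste(trt$plot_id, trt$species_code)
  ctrl_mean <- as.numeric(cm[key])
  ctrl_mean[is.na(ctrl_mean)] <- 0
  trt$trials <- trt$seeds_added
  trt$successes <- pmin(trt$trials,
                        pmax(0, trt$seedling_count - round(ctrl_mean)))
  trt$control_mean <- ctrl_mean
  trt
}

glmm_design <- function(x, spec) {
  cols <- list()
  if ("aug_level" %in% spec$fixed_effects) {
    cols$aug_level <- as.numeric(scale(log10(pmax(x$aug_multiple, 1e-3))))
  }
  if ("conspecific_density" %in% spec$fixed_effects) {
    v <- x$conspecific_density
    cols$conspecific_density <-
      if (stats::sd(v) > 0) as.numeric(scale(v)) else v * 0
  }
  X <- cbind(intercept = rep(1, nrow(x)))
  for (nm in names(cols)) X <- cbind(X, cols[[nm]])
  colnames(X) <- c("intercept", names(cols))
  re_idx <- list()
  for (b in spec$random_effects) {
    f <- switch(b,
      quadrat = x$quadrat_id,
      plot = x$plot_id,
      species = x$species_code,
      species_x_plot = paste(x$species_code, x$plot_id)
    )
    idx <- as.integer(factor(f))
    # degenerate blocks with a single level carry no information
    if (max(idx) >= 2) re_idx[[b]] <- idx
  }
  list(X = X, re_idx = re_idx)
}

#' Fit the binomial-logit GLMM for per-seed recruitment
#'
#' Hierarchical Bayesian fit (adaptive random-walk Metropolis within Gibbs)
#' of per-seed recruitment at one census: successes are each treatment
#' quadrat's seedling count in excess of its plot x species control mean,
#' out of `seeds_added` trials, with a logit link. Priors: Normal(0, 100)
#' on fixed effects; Uniform(0, 100) on random-effect SDs (set
#' `prior_on = "precision"` for a uniform prior on the precisions instead).
#'
#' @param records Quadrat-record table.
#' @param census_month Census to fit.
#' @param spec A [glmm_spec()] with `response = "per_seed"`.
#' @param chains Number of chains (>= 2).
#' @param burn_in,draws Iterations discarded / retained per chain.
#' @param rng_seed Integer seed; chain c uses `rng_seed + 1000 * c`.
#' @param prior_on `"sd"` (default) or `"precision"`.
#' @return A data.frame of posterior summaries (`parameter`, `mean`,
#'   `ci_2_5`, `ci_97_5`, `rhat`, `ess`) with the retained draws attached as
#'   attribute `"draws"` (one column per parameter plus `chain`). Any
#'   `rhat > 1.1` triggers a non-convergence warning, not an error.
#' @export
fit_effect_glmm <- function(records, census_month, spec = glmm_spec("per_seed"),
                            chains = 3, burn_in = 50000, draws = 25000,
                            rng_seed = 1, prior_on = c("sd", "precision")) {
  prior_on <- match.arg(prior_on)
  if (!inherits(spec, "glmm_spec") || spec$response != "per_seed") {
    stop("spec must be a glmm_spec with response 'per_seed'", call. = FALSE)
  }
  x <- binomial_data(records, census_month)
  if (all(x$successes == 0)) {
    warning("all successes are zero: posterior lies at the boundary",
            call. = FALSE)
  }
  des <- glmm_design(x, spec)
  mc <- glmm_mcmc(x$successes, x$trials, des$X, des$re_idx, "binomial",
                  chains, burn_in, draws, rng_seed, prior_on)
  finish_glmm(mc)
}

#' Fit the lognormal-Poisson GLMM for seedling counts
#'
#' As [fit_effect_glmm()] but for the absolute seedling count of every
#' quadrat at one census: Poisson likelihood with a log link and an
#' observation-level (quadrat) normal deviate on the log mean — the
#' lognormal-Poisson formulation of overdispersion — plus the requested
#' crossed random effects.
#'
#' @inheritParams fit_effect_glmm
#' @param spec A [glmm_spec()] with `response = "count"`.
#' @return As [fit_effect_glmm()].
#' @export
fit_count_glmm <- function(records, census_month, spec = glmm_spec("count"),
                           chains = 3, burn_in = 50000, draws = 25000,
                           rng_seed = 1, prior_on = c("sd", "precision")) {
  prior_on <- match.arg(prior_on)
  if (!inherits(spec, "glmm_spec") || spec$response != "count") {
    stop("spec must be a glmm_spec with response 'count'", call. = FALSE)
  }
  x <- records[records$census_month == census_month, , drop = FALSE]
  if (nrow(x) == 0) stop("no records at census month ", census_month,
                         call. = FALSE)
  des <- glmm_design(x, spec)
  mc <- glmm_mcmc(x$seedling_count, NULL, des$X, des$re_idx, "poisson",
                  chains, burn_in, draws, rng_seed, prior_on)
  finish_glmm(mc)
}

finish_glmm <- function(mc) {
  out <- summarise_posterior(mc)
  bad <- out$rhat > 1.1
  if (any(bad, na.rm = TRUE)) {
    warning("non-convergence flagged (rhat > 1.1) for: ",
            paste(out$parameter[which(bad)], collapse = ", "), call. = FALSE)
  }
  dr <- as.data.frame(mc$draws)
  names(dr) <- mc$par_names
  dr$chain <- mc$chain
  attr(out, "draws") <- dr
  out
}

#' Write retained MCMC draws to CSV
#'
#' @param summary A result of [fit_effect_glmm()] or [fit_count_glmm()].
#' @param path Output CSV path (one column per parameter plus `chain`).
#' @return `path`, invisibly.
#' @export
write_draws <- function(summary, path) {
  dr <- attr(summary, "draws")
  if (is.null(dr)) stop("no draws attached to this summary", call. = FALSE)
  utils::write.csv(dr, path, row.names = FALSE)
  invisible(path)
}
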