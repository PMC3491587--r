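# Run code with a private RNG stream: set.seed(seed) for the duration and
# restore the caller's .Random.seed afterwards, so package internals never
# perturb user-level reproducibility.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' BCa bootstrap confidence intervals for the seasonal conductance fit
#'
#' Resamples the included conductance observations with replacement in
#' subsamples of size `round(frac * n)`, refits the log-log power law to
#' each, and returns bias-corrected accelerated (BCa) 95 % intervals for
#' alpha and beta. The acceleration constant comes from a jackknife over the
#' included observations. A resample with fewer than two distinct tau values
#' cannot be fit and is redrawn (hard cap: `10 * n_boot` attempts in total).
#'
#' If the bias-correction z-value is unbounded (every resample falls on one
#' side of the point estimate, as with noiseless data), the method falls
#' back to plain percentile intervals with a warning.
#'
#' @param obs Flux observations (see [fit_seasonal_model()]).
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param frac Resample size as a fraction of n (default 0.8); resampling is
#'   with replacement.
#' @param seed Integer seed; the whole bootstrap consumes one RNG stream
#'   (resample indices drawn in loop order), so results are reproducible.
#' @param conf Confidence level (default 0.95).
#' @return List with `alpha_ci`, `beta_ci` (length-2 numeric), `n_boot`,
#'   `frac`, `seed`, `method` ("BCa" or "percentile"), and the bootstrap
#'   replicate matrix `replicates` (columns alpha, beta).
#' @export
bootstrap_ci <- function(obs, n_boot = 100, frac = 0.8, seed = 1L,
                         conf = 0.95) {
  if (n_boot < 2) stop("`n_boot` must be >= 2", call. = FALSE)
  if (frac <= 0 || frac > 1) stop("`frac` must be in (0, 1]", call. = FALSE)
  d <- included_obs(obs)
  n <- nrow(d)
  if (n < 3) stop("need >= 3 included observations", call. = FALSE)
  m <- max(3L, as.integer(round(frac * n)))
  lt <- log(d$tau_days)
  lg <- log(d$G)
  hat <- .ols2(lt, lg)
  theta_hat <- c(alpha = exp(hat[1]), beta = hat[2])

  reps <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("alpha", "beta")))
  with_seed(seed, {
    attempts <- 0L
    b <- 1L
    while (b <= n_boot) {
      attempts <- attempts + 1L
      if (attempts > 10L * n_boot)
        stop("too many degenerate resamples (single tau value); ",
             "data may be nearly degenerate", call. = FALSE)
      idx <- sample.int(n, m, replace = TRUE)
      if (length(unique(lt[idx])) < 2) next
      co <- .ols2(lt[idx], lg[idx])
      reps[b, ] <- c(exp(co[1]), co[2])
      b <- b + 1L
    }
  })

  # jackknife over the included observations for the acceleration constant
  jack <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    co <- .ols2(lt[-i], lg[-i])
    jack[i, ] <- c(exp(co[1]), co[2])
  }

  ci <- lapply(1:2, function(j)
    bca_interval(reps[, j], theta_hat[j], jack[, j], conf = conf))
  method <- if (any(vapply(ci, attr, logical(1), which = "fallback")))
    "percentile" else "BCa"
  list(alpha_ci = as.numeric(ci[[1]]), beta_ci = as.numeric(ci[[2]]),
       n_boot = n_boot, frac = frac, seed = seed, conf = conf,
       method = method, replicates = reps)
}

# One-parameter BCa interval. Falls back to percentile quantiles (with a
# warning) when the bias-correction or acceleration terms are undefined --
# e.g. all replicates identical, or all on one side of the point estimate.
bca_interval <- function(theta_boot, theta_hat, theta_jack, conf = 0.95) {
  a_lo <- (1 - conf) / 2
  a_hi <- 1 - a_lo
  fallback <- function() {
    out <- stats::quantile(theta_boot, c(a_lo, a_hi), names = FALSE)
    attr(out, "fallback") <- TRUE
    out
  }
  prop <- mean(theta_boot < theta_hat)
  z0 <- stats::qnorm(prop)
  if (!is.finite(z0)) {
    warning("BCa bias correction unbounded (all resamples on one side of ",
            "the estimate); using percentile interval", call. = FALSE)
    return(fallback())
  }
  theta_jack <- theta_jack[is.finite(theta_jack)]   # leave-one-out may degenerate
  if (length(theta_jack) < 2) return(fallback())
  dif <- mean(theta_jack) - theta_jack
  denom <- sum(dif^2)^1.5
  accel <- if (denom > 0) sum(dif^3) / (6 * denom) else 0
  z <- stats::qnorm(c(a_lo, a_hi))
  adj <- stats::pnorm(z0 + (z0 + z) / (1 - accel * (z0 + z)))
  if (any(!is.finite(adj))) {
    warning("BCa adjusted levels undefined; using percentile interval",
            call. = FALSE)
    return(fallback())
  }
  out <- stats::quantile(theta_boot, adj, names = FALSE)
  attr(out, "fallback") <- FALSE
  out
}

#' Fit the seasonal model and attach bootstrap intervals
#'
#' Convenience wrapper: [fit_seasonal_model()] followed by [bootstrap_ci()],
#' with the intervals stored on the returned model.
#'
#' @inheritParams bootstrap_ci
#' @return A `"kt_conductance_model"` with `alpha_ci`, `beta_ci` and a
#'   `bootstrap` element (the [bootstrap_ci()] result minus replicates).
#' @export
fit_seasonal_model_ci <- function(obs, n_boot = 100, frac = 0.8, seed = 1L,
                                  conf = 0.95) {
  model <- fit_seasonal_model(obs)
  bs <- bootstrap_ci(obs, n_boot = n_boot, frac = frac, seed = seed,
                     conf = conf)
  model$alpha_ci <- bs$alpha_ci
  model$beta_ci <- bs$beta_ci
  model$bootstrap <- bs[c("n_boot", "frac", "seed", "conf", "method")]
  model
}
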