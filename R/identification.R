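#' Screen windspeed and radiation for influence on inferred conductance
#'
#' The transpiration model E = G * dPw assumes skin conductance dominates
#' (no boundary-layer term, so no windspeed dependence) and that fruit
#' temperature tracks air temperature (no radiative-heating term). This
#' screen tests both assumptions: within each measurement period (campaign
#' day), inferred G is regressed on windspeed W and, separately, on solar
#' radiation R, and the two-sided P-value of each slope is reported. With
#' six campaign days this is the classic 12-regression screen; slopes all
#' non-significant means the unextended model is accepted.
#'
#' A period whose driver has zero variance (e.g. all-night data with R = 0
#' throughout) cannot support a slope; that regression is skipped and
#' flagged rather than fabricated.
#'
#' @param obs Flux observations from [build_conductance_dataset()] carrying
#'   `G`, `tau_days`, `W_ms`, `R_kJ_m2` and `included`.
#' @param threshold Significance threshold for a slope P-value
#'   (default 0.05).
#' @param campaign_days Optional numeric vector of campaign-day labels;
#'   each observation is assigned to the nearest. Default: the distinct
#'   values of `floor(tau_days)`.
#' @return Object of class `"kt_identification"`: list with `results` (one
#'   row per period x driver: `period`, `driver`, `slope`, `slope_p`, `n`,
#'   `skipped`), `min_p`, `max_p`, `any_significant`, `threshold`,
#'   `conclusion`.
#' @export
identify_drivers <- function(obs, threshold = 0.05, campaign_days = NULL) {
  check_columns(obs, c("G", "tau_days", "W_ms", "R_kJ_m2"), "obs")
  d <- included_obs(obs)
  if (nrow(d) == 0) stop("no included observations", call. = FALSE)
  if (is.null(campaign_days)) campaign_days <- sort(unique(floor(d$tau_days)))
  d$period <- vapply(d$tau_days, function(t)
    campaign_days[which.min(abs(campaign_days - t))], numeric(1))

  rows <- list()
  for (p in campaign_days) {
    dp <- d[d$period == p, , drop = FALSE]
    for (driver in c("W", "R")) {
      x <- if (driver == "W") dp$W_ms else dp$R_kJ_m2
      ok <- is.finite(x) & is.finite(dp$G)
      x <- x[ok]; g <- dp$G[ok]
      if (length(g) < 3 || stats::var(x) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          period = p, driver = driver, slope = NA_real_, slope_p = NA_real_,
          n = length(g), skipped = TRUE)
        next
      }
      fit <- summary(stats::lm(g ~ x))$coefficients
      pval <- fit["x", "Pr(>|t|)"]
      # zero residual variance (e.g. constant G) leaves the t-test undefined
      rows[[length(rows) + 1L]] <- data.frame(
        period = p, driver = driver,
        slope = fit["x", "Estimate"],
        slope_p = if (is.finite(pval)) pval else NA_real_,
        n = length(g), skipped = !is.finite(pval))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  pv <- results$slope_p[!results$skipped]
  if (length(pv) == 0) stop("every identification regression was degenerate",
                            call. = FALSE)
  any_sig <- min(pv) < threshold
  out <- list(
    results = results,
    min_p = min(pv), max_p = max(pv),
    any_significant = any_sig, threshold = threshold,
    conclusion = if (any_sig)
      "at least one driver slope is significant: consider extending the model"
    else
      "no significant driver effect: E = G * dPw accepted unextended"
  )
  class(out) <- "kt_identification"
  out
}

#' @export
print.kt_identification <- function(x, ...) {
  cat("Model-identification screen: G vs windspeed (W) and radiation (R)\n")
  print(x$results, row.names = FALSE)
  cat(sprintf("slope P-values in [%.3g, %.3g]; threshold %.3g\n",
              x$min_p, x$max_p, x$threshold))
  cat(x$conclusion, "\n")
  invisible(x)
}
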