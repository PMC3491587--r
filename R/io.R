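# Delimited-text dialect used everywhere: comma separator, period decimal
# mark, UTF-8, header row, timestamps as ISO-8601 local civil time
# ("YYYY-MM-DD HH:MM:SS" or with a "T" separator). Doubles are written with
# 17 significant digits so write -> read round trips are bit-exact.

kt_write_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct"))
      out[[nm]] <- format(out[[nm]], "%Y-%m-%d %H:%M:%S")
    else if (is.double(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

kt_read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if ("timestamp" %in% names(df)) df$timestamp <- parse_timestamp(df$timestamp)
  df
}

parse_timestamp <- function(x) {
  x <- gsub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out) && !anyNA(x)) {
    bad <- which(is.na(out))
    stop("unparseable timestamp(s), e.g. row ", bad[1], ": '", x[bad[1]], "'",
         call. = FALSE)
  }
  out
}

#' Read and validate a weather file
#'
#' Expects columns `timestamp`, `T_C`, `RH_pct` and optionally `W_ms`,
#' `R_kJ_m2`. Validates ranges (RH in \[0, 102\] with overshoot clamping,
#' W and R non-negative) and strictly increasing timestamps, addressing
#' errors by row.
#'
#' @param path CSV file path.
#' @return Validated weather data frame.
#' @export
read_weather <- function(path) {
  df <- kt_read_csv(path)
  check_columns(df, c("timestamp", "T_C", "RH_pct"), basename(path))
  if (any(diff(as.numeric(df$timestamp)) <= 0)) {
    bad <- which(diff(as.numeric(df$timestamp)) <= 0)[1] + 1L
    stop(basename(path), ": timestamps not strictly increasing at row ", bad,
         call. = FALSE)
  }
  df$RH_pct <- clamp_rh(df$RH_pct)
  for (nm in intersect(c("W_ms", "R_kJ_m2"), names(df))) {
    if (any(df[[nm]] < 0, na.rm = TRUE)) {
      bad <- which(df[[nm]] < 0)[1]
      stop(basename(path), ": negative ", nm, " at row ", bad, call. = FALSE)
    }
  }
  df
}

#' Read and validate a fruit weighing file
#'
#' Expects columns `fruit_id`, `timestamp`, `tau_days`, `weight_g`,
#' `length_cm`, `width_cm`; weights and dimensions must be positive.
#'
#' @param path CSV file path.
#' @return Validated weighings data frame.
#' @export
read_weighings <- function(path) {
  df <- kt_read_csv(path)
  check_columns(df, c("fruit_id", "timestamp", "tau_days", "weight_g",
                      "length_cm", "width_cm"), basename(path))
  for (nm in c("weight_g", "length_cm", "width_cm")) {
    if (any(df[[nm]] <= 0, na.rm = TRUE)) {
      bad <- which(df[[nm]] <= 0)[1]
      stop(basename(path), ": non-positive ", nm, " at row ", bad,
           call. = FALSE)
    }
  }
  df
}

#' Write / read a flux-observation table
#'
#' The on-disk column set follows the conductance-dataset contract:
#' `fruit_id`, `timestamp`, `tau_days`, `E_mmol_cm2_h`, `delta_pw`, `G`,
#' `included`, `reason`, plus the paired weather means (`T_C`, `RH_pct`,
#' `W_ms`, `R_kJ_m2`) needed by the identification screen.
#'
#' @param obs Flux observations from [build_conductance_dataset()].
#' @param path CSV file path.
#' @return `path` (write) or the observation data frame (read).
#' @export
write_flux_obs <- function(obs, path) {
  out <- as.data.frame(obs)
  names(out)[names(out) == "E"] <- "E_mmol_cm2_h"
  kt_write_csv(out, path)
}

#' @rdname write_flux_obs
#' @export
read_flux_obs <- function(path) {
  df <- kt_read_csv(path)
  check_columns(df, c("fruit_id", "timestamp", "tau_days", "E_mmol_cm2_h",
                      "delta_pw", "G", "included", "reason"), basename(path))
  names(df)[names(df) == "E_mmol_cm2_h"] <- "E"
  df$included <- as.logical(df$included)
  class(df) <- c("kt_flux_obs", "data.frame")
  df
}

#' Write / read a fitted conductance model as flat key-value text
#'
#' @param model A `"kt_conductance_model"`.
#' @param path Output text file.
#' @return `path` (write) or the model object (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "kt_conductance_model"))
  kv <- c(alpha = model$alpha, beta = model$beta,
          alpha_lo = model$alpha_ci[1] %||% NA, alpha_hi = model$alpha_ci[2] %||% NA,
          beta_lo = model$beta_ci[1] %||% NA, beta_hi = model$beta_ci[2] %||% NA,
          adj_r2 = model$adj_r2, n_obs = model$n_obs,
          tau_min = model$tau_range[1], tau_max = model$tau_range[2],
          n_boot = model$bootstrap$n_boot %||% NA,
          frac = model$bootstrap$frac %||% NA,
          seed = model$bootstrap$seed %||% NA)
  writeLines(sprintf("%s %.17g", names(kv), as.numeric(kv)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- strsplit(trimws(readLines(path)), "\\s+")
  kv <- stats::setNames(vapply(lines, function(x) as.numeric(x[2]), numeric(1)),
                        vapply(lines, `[`, character(1), 1))
  model <- list(
    alpha = kv[["alpha"]], beta = kv[["beta"]],
    alpha_ci = if (!is.na(kv["alpha_lo"])) unname(kv[c("alpha_lo", "alpha_hi")]),
    beta_ci = if (!is.na(kv["beta_lo"])) unname(kv[c("beta_lo", "beta_hi")]),
    adj_r2 = kv[["adj_r2"]], n_obs = as.integer(kv[["n_obs"]]),
    tau_range = unname(kv[c("tau_min", "tau_max")]),
    bootstrap = if (!is.na(kv["n_boot"]))
      list(n_boot = as.integer(kv[["n_boot"]]), frac = kv[["frac"]],
           seed = as.integer(kv[["seed"]]))
  )
  class(model) <- "kt_conductance_model"
  model
}
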