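#' Dissociation rate from event durations
#'
#' k_off = 1 / mean(tau_off), the standard conversion of mean event duration
#' to a dissociation rate. A nonparametric bootstrap supplies the confidence
#' interval.
#'
#' @param events Tibble with a `tau_off` column (or a numeric vector).
#' @param conf Confidence level for the bootstrap CI (0 to disable).
#' @param n_boot Bootstrap resamples.
#' @return A list of class `koff_estimate`: `k_off` (1/s), `ci`, `n`.
#' @export
koff <- function(events, conf = 0.95, n_boot = 1000) {
  tau <- if (is.data.frame(events)) events$tau_off else as.numeric(events)
  if (!length(tau)) stop("empty event set")
  est <- 1 / mean(tau)
  ci <- c(NA_real_, NA_real_)
  if (conf > 0 && length(tau) > 1) {
    bs <- vapply(seq_len(n_boot), function(b) {
      1 / mean(sample(tau, replace = TRUE))
    }, 0)
    ci <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
  }
  structure(list(k_off = est, ci = ci, n = length(tau), conf = conf),
            class = "koff_estimate")
}

#' @exportS3Method base::print
print.koff_estimate <- function(x, ...) {
  cat(sprintf("k_off = %.4g /s (n = %d, %g%% CI %.4g-%.4g)\n",
              x$k_off, x$n, 100 * x$conf, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Exponential and double-exponential dwell-time fits
#'
#' Maximum-likelihood fits of event-duration distributions. `fit_exponential`
#' fits a single rate; `fit_double_exponential` fits a two-component mixture
#' w k1 e^{-k1 t} + (1-w) k2 e^{-k2 t} by direct likelihood maximization with
#' random multistarts. An optional left-censoring threshold restricts the fit
#' to durations above `censor` with the likelihood renormalized by the
#' truncated survival function (used to exclude events shorter than the
#' recording filter would resolve).
#'
#' @param durations Numeric vector of dwell times (s), or a tibble with
#'   `tau_off`.
#' @param censor Left-truncation threshold (s), or `NULL`.
#' @return An object of class `exp_fit` / `dexp_fit` with rate estimates,
#'   standard errors, and the maximized log-likelihood.
#' @export
fit_exponential <- function(durations, censor = NULL) {
  tau <- if (is.data.frame(durations)) durations$tau_off else as.numeric(durations)
  if (!is.null(censor)) tau <- tau[tau > censor] - censor  # memoryless shift
  n <- length(tau)
  if (n < 10) stop("need at least 10 durations")
  rate <- 1 / mean(tau)
  se <- rate / sqrt(n)
  ll <- sum(stats::dexp(tau, rate, log = TRUE))
  structure(list(rate = rate, se = se, loglik = ll, n = n, censor = censor),
            class = "exp_fit")
}

#' @rdname fit_exponential
#' @param n_starts Number of random multistarts.
#' @param seed Seed for the multistarts.
#' @export
fit_double_exponential <- function(durations, censor = NULL, n_starts = 10,
                                   seed = 1) {
  tau_all <- if (is.data.frame(durations)) durations$tau_off else as.numeric(durations)
  cen <- if (is.null(censor)) 0 else censor
  tau <- tau_all[tau_all > cen]
  n <- length(tau)
  if (n < 10) stop("need at least 10 durations")
  nll <- function(par) {
    w <- stats::plogis(par[1]); k1 <- exp(par[2]); k2 <- exp(par[3])
    dens <- w * k1 * exp(-k1 * tau) + (1 - w) * k2 * exp(-k2 * tau)
    surv <- w * exp(-k1 * cen) + (1 - w) * exp(-k2 * cen)
    -sum(log(pmax(dens, 1e-300))) + n * log(max(surv, 1e-300))
  }
  rate0 <- 1 / mean(tau - cen)
  set.seed(seed)
  best <- NULL
  converged <- FALSE
  for (s in seq_len(n_starts)) {
    par0 <- c(stats::rnorm(1), log(rate0) + stats::rnorm(1, 0, 1.5),
              log(rate0) + stats::rnorm(1, 0, 1.5))
    opt <- tryCatch(
      stats::optim(par0, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
      converged <- opt$convergence == 0
    }
  }
  if (is.null(best)) stop("double-exponential fit failed for all starts")
  w <- stats::plogis(best$par[1])
  k1 <- exp(best$par[2]); k2 <- exp(best$par[3])
  # order components: k1 = slow (small), k2 = fast
  if (k1 > k2) { tmp <- k1; k1 <- k2; k2 <- tmp; w <- 1 - w }
  structure(list(weight_slow = w, rate_slow = k1, rate_fast = k2,
                 loglik = -best$value, n = n, censor = censor,
                 converged = converged),
            class = "dexp_fit")
}

#' @exportS3Method base::print
print.exp_fit <- function(x, ...) {
  cat(sprintf("exponential fit: rate %.4g /s (se %.2g, n %d, logLik %.1f)\n",
              x$rate, x$se, x$n, x$loglik))
  invisible(x)
}

#' @exportS3Method base::print
print.dexp_fit <- function(x, ...) {
  cat(sprintf(
    "double-exponential fit: rates %.4g and %.4g /s (weight %.2f on slow), n %d, logLik %.1f%s\n",
    x$rate_slow, x$rate_fast, x$weight_slow, x$n, x$loglik,
    if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = "rate", estimate = x$rate, std.error = x$se)
}

#' @export
tidy.dexp_fit <- function(x, ...) {
  tibble::tibble(term = c("weight_slow", "rate_slow", "rate_fast"),
                 estimate = c(x$weight_slow, x$rate_slow, x$rate_fast),
                 std.error = NA_real_)
}

#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, censor = x$censor %||% 0)
}

#' @export
glance.dexp_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, censor = x$censor %||% 0,
                 converged = x$converged)
}

#' Voltage dependence of the dissociation rate
#'
#' Least-squares fit of log10(k_off) against voltage across groups of events
#' recorded at different voltages. A positive slope magnitude indicates
#' force-accelerated dissociation (Bell behaviour).
#'
#' @param events Tibble with columns `tau_off` and `voltage` (mV).
#' @return A list of class `koff_voltage_fit` with the `lm` fit, slope,
#'   intercept and per-voltage rates.
#' @export
koff_vs_voltage <- function(events) {
  stopifnot(all(c("tau_off", "voltage") %in% names(events)))
  groups <- dplyr::summarise(dplyr::group_by(events, .data$voltage),
                             k_off = 1 / mean(.data$tau_off),
                             n = dplyr::n(), .groups = "drop")
  if (nrow(groups) < 2) stop("need at least two voltage groups")
  fit <- stats::lm(log10(k_off) ~ voltage, data = groups)
  structure(list(fit = fit, groups = groups,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "koff_voltage_fit")
}

#' @exportS3Method base::print
print.koff_voltage_fit <- function(x, ...) {
  cat(sprintf("koff_vs_voltage: slope %.4g log10(/s)/mV over %d voltages\n",
              x$slope, nrow(x$groups)))
  invisible(x)
}

#' @export
tidy.koff_voltage_fit <- function(x, ...) {
  out <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(out), estimate = out[, 1],
                 std.error = out[, 2])
}

#' Event scatter table and dwell-time histogram
#'
#' `scatter_table` exports the (tau_off, A/I0) event cloud; `event_histogram`
#' bins durations, by default logarithmically (event durations span submicro-
#' second failed attempts to seconds-long bound events).
#'
#' @param events Event tibble with `tau_off`, `amplitude`, `outcome`, `bound`.
#' @return `scatter_table`: a tibble with one row per event. `event_histogram`:
#'   a tibble of bins with counts.
#' @export
scatter_table <- function(events) {
  cols <- intersect(c("tau_off", "amplitude", "outcome", "bound"),
                    names(events))
  tibble::as_tibble(events[, cols, drop = FALSE])
}

#' @rdname scatter_table
#' @param bins Number of bins.
#' @param log_scale Logarithmic bin edges (default TRUE).
#' @export
event_histogram <- function(events, bins = 30, log_scale = TRUE) {
  tau <- events$tau_off
  if (!length(tau)) {
    return(tibble::tibble(lower = numeric(0), upper = numeric(0),
                          count = integer(0)))
  }
  rng <- range(tau)
  if (log_scale) {
    edges <- exp(seq(log(rng[1] * 0.999), log(rng[2] * 1.001),
                     length.out = bins + 1))
  } else {
    edges <- seq(rng[1] * 0.999, rng[2] * 1.001, length.out = bins + 1)
  }
  idx <- findInterval(tau, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > bins] <- bins
  cnt <- tabulate(idx, nbins = bins)
  tibble::tibble(lower = edges[-length(edges)], upper = edges[-1], count = cnt)
}
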