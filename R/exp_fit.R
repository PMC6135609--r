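#' Fit a single exponential to one trace
#'
#' Least-squares fit of `offset + amplitude * exp(-kobs * t)` to a trace,
#' the standard per-trace analysis of stopped-flow data.  `kobs` is kept
#' positive by optimising its logarithm; initialisation is deterministic,
#' from the time at which the signal has covered half its amplitude
#' (`kobs0 = log(2) / t_half`).  A trace with no resolvable amplitude —
#' e.g. the probe release experiment at 5 nM oligomer competitor, where
#' no exchange is observable — is reported with `converged = FALSE` and
#' `kobs = 0` rather than an error.
#'
#' @param trace an [new_trace()] object, or a numeric vector of times if
#'   `values` is given separately.
#' @param values anisotropy values when `trace` is a plain time vector.
#' @return An object of class `exp_fit` with elements `kobs` (1/s),
#'   `amplitude` (signed, anisotropy units), `offset`, `fitted`,
#'   `residuals`, `rmse`, `converged`, `diagnostic`.
#' @export
fit_single_exponential <- function(trace, values = NULL) {
  if (inherits(trace, "sf_trace")) {
    x <- trace$times; y <- trace$values
  } else {
    x <- as.numeric(trace); y <- as.numeric(values)
  }
  n <- length(x)
  if (n < 10L) stop("need at least 10 points to fit an exponential")

  flat_fit <- function(msg) {
    structure(list(kobs = 0, amplitude = 0, offset = mean(y),
                   fitted = rep(mean(y), n), residuals = y - mean(y),
                   rmse = sqrt(mean((y - mean(y))^2)),
                   converged = FALSE, diagnostic = msg),
              class = "exp_fit")
  }
  if (sd(y) < .Machine$double.eps * 10) return(flat_fit("constant trace"))

  # smooth head/tail estimates for initialisation and flatness screening
  k <- max(5L, n %/% 20L)
  offset0 <- mean(tail(y, k))
  amp0 <- mean(head(y, k)) - offset0
  noise0 <- sd(diff(y)) / sqrt(2)
  if (abs(amp0) < 3 * noise0 / sqrt(k)) {
    return(flat_fit("no resolvable amplitude above the noise"))
  }

  crossed <- which(abs(y - offset0) <= abs(amp0) / 2)
  t_half <- if (length(crossed)) x[crossed[1]] else x[n %/% 2L]
  kobs0 <- log(2) / max(t_half, x[1])

  res_fn <- function(par) {
    y - (par[3] + par[2] * exp(-exp(par[1]) * x))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(log(kobs0), amp0, offset0), fn = res_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(flat_fit("least-squares iteration failed"))

  par <- fit$par
  fitted <- par[3] + par[2] * exp(-exp(par[1]) * x)
  resid <- y - fitted
  structure(list(kobs = exp(par[1]), amplitude = par[2], offset = par[3],
                 fitted = fitted, residuals = resid,
                 rmse = sqrt(mean(resid^2)),
                 converged = fit$info %in% 1:4, diagnostic = fit$message),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "Single-exponential fit: kobs = %.4g 1/s, amplitude = %.4g, rmse = %.3g%s\n",
    x$kobs, x$amplitude, x$rmse,
    if (x$converged) "" else paste0("  [not converged: ", x$diagnostic, "]")))
  invisible(x)
}

#' Single-exponential fits for every trace of a series
#'
#' @param series a [trace_series()].
#' @return A data frame with one row per trace: the varied concentration
#'   (`conc`, nM — protein for association series, competitor sites for
#'   dissociation series), `kobs`, `amplitude`, `rmse`, `converged`, and
#'   the fit objects in the `fit` list-column.
#' @export
series_exp_fits <- function(series) {
  stopifnot(inherits(series, "trace_series"))
  fits <- lapply(series$traces, fit_single_exponential)
  out <- data.frame(
    conc = vapply(series$traces, varied_concentration, numeric(1),
                  kind = series$kind),
    kobs = vapply(fits, `[[`, numeric(1), "kobs"),
    amplitude = vapply(fits, `[[`, numeric(1), "amplitude"),
    rmse = vapply(fits, `[[`, numeric(1), "rmse"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  out$fit <- fits
  out
}

#' Linear replot of observed rates against concentration
#'
#' Ordinary least squares through `(concentration, kobs)` pairs.  Under
#' pseudo-first-order association conditions the slope estimates the
#' second-order association rate constant and the intercept the
#' first-order dissociation rate constant; for a competitor-independent
#' dissociation mechanism the slope is statistically zero.
#'
#' @param concs concentrations, nM; or a data frame from
#'   [series_exp_fits()] (columns `conc`, `kobs`).
#' @param kobs observed rates, 1/s (when `concs` is a plain vector).
#' @return An object of class `linear_replot`: `slope` (1/(nM s)),
#'   `intercept` (1/s), `slope_se`, `intercept_se`, `r_squared`, `n`.
#' @export
replot_kobs <- function(concs, kobs = NULL) {
  if (is.data.frame(concs)) {
    kobs <- concs$kobs; concs <- concs$conc
  }
  if (length(concs) < 3L) stop("a replot needs at least 3 concentrations")
  fit <- lm(kobs ~ concs)
  # noiseless series fit perfectly; the summary is still well defined
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(list(slope = co["concs", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 slope_se = co["concs", "Std. Error"],
                 intercept_se = co["(Intercept)", "Std. Error"],
                 r_squared = sm$r.squared, n = length(concs)),
            class = "linear_replot")
}

#' @export
print.linear_replot <- function(x, ...) {
  cat(sprintf(
    "kobs replot (n = %d): slope = %.4g +/- %.2g 1/(nM s), intercept = %.4g +/- %.2g 1/s, R^2 = %.4f\n",
    x$n, x$slope, x$slope_se, x$intercept, x$intercept_se, x$r_squared))
  invisible(x)
}
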