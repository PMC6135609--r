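#' Default free parameters of a scheme fit
#'
#' Association fits free the binding-step constants `(k1, k_m1)`;
#' simple-competition fits free the release rate `k_m1` (the binding
#' constant `k1` comes from the association experiment); ternary fits
#' free the four second-DNA constants `(k2, k_m2, k3, k_m3)` with the
#' binding steps fixed at association-derived values.
#'
#' @param scheme one of [schemes()].
#' @return Character vector of parameter names.
#' @export
default_free_params <- function(scheme) {
  switch(match_scheme(scheme),
         association = c("k1", "k_m1"),
         simple_competition = "k_m1",
         ternary = c("k2", "k_m2", "k3", "k_m3"))
}

# model anisotropy for one trace under a full parameter set
predict_trace_values <- function(trace, scheme, params, cal,
                                 k1_prime = NULL, rtol = 1e-8,
                                 atol = 1e-8) {
  m <- trace$meta
  if (identical(m$kind, "association")) {
    init <- species_state(P = m$totalP, Dstar = m$totalDstar)
    total <- m$totalDstar
  } else {
    init <- pre_equilibrate(m$preP, m$preDstar, params$k1, params$k_m1)
    init["D"] <- m$D_sites
    total <- m$preDstar
  }
  traj <- simulate_trajectory(scheme, params, init, trace$times,
                              k1_prime = k1_prime, rtol = rtol, atol = atol)
  state_to_anisotropy(traj, cal, total)
}

#' Predicted anisotropy curves for a whole series
#'
#' @param series a [trace_series()].
#' @param scheme one of [schemes()].
#' @param params a full [rate_params()].
#' @param k1_prime optional competitor-capture constant.
#' @return List of numeric vectors, one per trace.
#' @export
predict_series <- function(series, scheme, params, k1_prime = NULL) {
  params <- as_rate_params(params)
  lapply(series$traces, predict_trace_values, scheme = scheme,
         params = params, cal = series$calibration, k1_prime = k1_prime)
}

# deterministic data-driven starting point for the free parameters
heuristic_start <- function(series, scheme, fixed) {
  ef <- tryCatch(series_exp_fits(series), error = function(e) NULL)
  ok <- !is.null(ef) && any(ef$converged & ef$kobs > 0)
  kobs <- if (ok) ef$kobs[ef$converged & ef$kobs > 0] else 1
  conc <- if (ok) ef$conc[ef$converged & ef$kobs > 0] else 1
  start <- switch(scheme,
    association = {
      k1 <- if (ok && length(kobs) >= 3) {
        max(replot_kobs(conc, kobs)$slope, 1e-4)
      } else max(kobs) / max(conc, 1)
      c(k1 = k1, k_m1 = max(min(kobs) / 10, 0.5))
    },
    simple_competition = c(k_m1 = median(kobs)),
    ternary = {
      k3 <- 1.2 * max(kobs)
      k_m2 <- 10 * k3
      i0 <- which.min(conc)
      k2 <- max(kobs[i0] * (k_m2 + k3) / (k3 * max(conc[i0], 1)), 1e-6)
      c(k2 = k2, k_m2 = k_m2, k3 = k3, k_m3 = k2 / 3)
    })
  start
}

#' Global fit of a kinetic scheme to a concentration series
#'
#' Fits a scheme to all traces of a series simultaneously by minimising
#' the unweighted sum of squared anisotropy residuals, the multi-trace
#' analogue of the classical global analysis of stopped-flow data.  Rate
#' constants are optimised in log space (they span five orders of
#' magnitude, and positivity comes for free); the optimiser is
#' Levenberg-Marquardt.  Because the four-constant ternary surface has
#' local optima when the competitor excess is small, the fit is started
#' from a deterministic data-driven initial guess plus `n_starts - 1`
#' seeded Latin-hypercube points spanning two decades around it, and the
#' best optimum is reported together with the full multistart log.
#' Parameter standard errors come from the Jacobian at the optimum.
#'
#' @param series a [trace_series()].
#' @param scheme scheme to fit, one of [schemes()].
#' @param free names of the rate constants to optimise (default
#'   [default_free_params()]).
#' @param fixed named values for the constants held fixed (a
#'   [rate_params()], named vector or list).  Dissociation fits need
#'   `k1` and `k_m1` here unless they are free.
#' @param n_starts number of multistart points (default 16).
#' @param seed integer seed for the Latin-hypercube draw.
#' @param k1_prime optional competitor-capture constant
#'   (simple-competition scheme; defaults to the current `k1`).
#' @param rtol,atol integrator tolerances used inside the fit.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @param .start optional named vector of starting values for the free
#'   parameters; when supplied, a single start is run from it (used by
#'   profiling and bootstrap refits).
#' @return An object of class `global_fit_result`: `params` (full
#'   [rate_params()] at the optimum), `free`, `param_se` (NA for fixed
#'   constants), `chi2`, `n_data`, `n_free`, `per_trace_residuals`,
#'   `per_trace_rmse`, `fitted`, `multistart_log`, `converged`, `seed`,
#'   `scheme`.
#' @export
global_fit <- function(series, scheme, free = NULL, fixed = NULL,
                       n_starts = 16, seed = 1L, k1_prime = NULL,
                       rtol = 1e-8, atol = 1e-8, max_iter = 60,
                       .start = NULL) {
  stopifnot(inherits(series, "trace_series"))
  scheme <- match_scheme(scheme)
  if (is.null(free)) free <- default_free_params(scheme)
  free <- unique(free)

  full0 <- unclass(rate_params())
  if (!is.null(fixed)) {
    fixed <- unclass(as_rate_params(fixed))
    full0[names(fixed)[!is.na(unlist(fixed))]] <-
      fixed[!is.na(unlist(fixed))]
  }

  obs <- lapply(series$traces, `[[`, "values")
  n_data <- sum(lengths(obs))
  n_free <- length(free)
  cal <- series$calibration

  make_params <- function(theta) {
    full <- full0
    full[free] <- pmin(pmax(exp(theta), 1e-10), 1e8)
    as_rate_params(full)
  }
  residual_fn <- function(theta) {
    params <- make_params(theta)
    pred <- tryCatch(
      predict_series(series, scheme, params, k1_prime = k1_prime),
      error = function(e) NULL)
    if (is.null(pred)) return(rep(1e4, n_data) + sum(theta^2))
    unlist(pred) - unlist(obs)
  }

  # starting points
  if (!is.null(.start)) {
    starts <- matrix(log(.start[free]), nrow = 1,
                     dimnames = list(NULL, free))
  } else {
    centre <- heuristic_start(series, scheme, full0)
    centre <- centre[intersect(names(centre), free)]
    missing_free <- setdiff(free, names(centre))
    if (length(missing_free)) {
      centre <- c(centre, setNames(rep(1, length(missing_free)),
                                   missing_free))
    }
    centre <- log(centre[free])
    starts <- matrix(rep(centre, each = 1), nrow = 1)
    if (n_starts > 1) {
      set.seed(as.integer(seed))
      u <- lhs::randomLHS(n_starts - 1L, n_free)
      spread <- sweep((u - 0.5) * 2 * (2 * log(10)), 2, centre, `+`)
      starts <- rbind(starts, spread)
    }
    colnames(starts) <- free
  }

  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = residual_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-13,
                           ptol = 1e-13, epsfcn = 1e-8)),
      error = function(e) NULL)
    runs[[i]] <- if (is.null(fit)) {
      list(ok = FALSE, chi2 = Inf, par = starts[i, ], info = -1L)
    } else {
      list(ok = fit$info %in% 1:4, chi2 = fit$deviance, par = fit$par,
           info = fit$info)
    }
  }
  chi2s <- vapply(runs, `[[`, numeric(1), "chi2")
  # ties (within 1e-10) resolve to the lowest start index: which.min
  # already returns the first minimum
  best_i <- which.min(ifelse(is.finite(chi2s), chi2s, Inf))
  best <- runs[[best_i]]
  if (!is.finite(best$chi2)) {
    return(structure(list(
      params = make_params(starts[1, ]), free = free,
      param_se = setNames(rep(NA_real_, 6), names(full0)),
      chi2 = Inf, n_data = n_data, n_free = n_free,
      per_trace_residuals = NULL, per_trace_rmse = NULL, fitted = NULL,
      multistart_log = data.frame(start = seq_along(runs), chi2 = chi2s,
                                  converged = FALSE),
      converged = FALSE, seed = seed, scheme = scheme, kind = series$kind),
      class = "global_fit_result"))
  }

  theta <- best$par
  params <- make_params(theta)
  pred <- predict_series(series, scheme, params, k1_prime = k1_prime)
  per_res <- Map(function(p, o) o - p, pred, obs)
  chi2 <- sum(unlist(per_res)^2)

  # standard errors: sigma^2 (J'J)^-1 in log space, delta-method back
  se <- setNames(rep(NA_real_, 6), names(full0))
  if (n_data > n_free && chi2 > 0) {
    J <- numeric_jacobian(residual_fn, theta)
    sigma2 <- chi2 / (n_data - n_free)
    covth <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(covth)) {
      se_theta <- sqrt(pmax(diag(covth), 0))
      se[free] <- unlist(params)[free] * se_theta
    }
  }

  structure(list(
    params = params, free = free, param_se = se, chi2 = chi2,
    n_data = n_data, n_free = n_free,
    per_trace_residuals = per_res,
    per_trace_rmse = vapply(per_res, function(r) sqrt(mean(r^2)),
                            numeric(1)),
    fitted = pred,
    multistart_log = data.frame(
      start = seq_along(runs), chi2 = chi2s,
      converged = vapply(runs, `[[`, logical(1), "ok")),
    converged = best$ok, seed = seed, scheme = scheme,
    kind = series$kind),
    class = "global_fit_result")
}

numeric_jacobian <- function(fn, theta, eps = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    th <- theta
    th[j] <- th[j] + eps
    J[, j] <- (fn(th) - f0) / eps
  }
  J
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat(sprintf("Global %s fit: chi2 = %.6g over %d points, %d free parameter(s)%s\n",
              x$scheme, x$chi2, x$n_data, x$n_free,
              if (x$converged) "" else "  [NOT converged]"))
  v <- unlist(x$params)
  for (nm in names(v)) {
    if (is.na(v[[nm]])) next
    tag <- if (nm %in% x$free) {
      sprintf("fitted, se %.3g", x$param_se[[nm]])
    } else "fixed"
    cat(sprintf("  %-5s %10.4g  (%s)\n", nm, v[[nm]], tag))
  }
  invisible(x)
}

#' Profile-likelihood bound on one rate constant
#'
#' Scans a rate constant away from its point estimate, re-optimising all
#' other free constants at each value, until the profiled objective rises
#' by `delta_chi2` above its minimum (default 3.84, the 95% chi-square
#' threshold for one parameter).  The objective is measured on the
#' statistical scale: the raw sum of squared residuals divided by the
#' residual variance estimate at the optimum, `chi2_min / (n - p)`, so
#' the threshold is `delta_chi2` regardless of the (unknown) noise level.
#' The crossing value is the profile bound.  This is how a weakly identified constant is bounded:
#' on a 25 ms association window essentially no dissociation occurs, so
#' `k_m1` has a finite upper bound near 10 1/s but little lower
#' resolution.  A constant with no influence on the observable never
#' raises the objective and is reported as unbounded within the scan
#' range.
#'
#' @param series a [trace_series()].
#' @param scheme scheme to fit.
#' @param param_name rate constant to profile.
#' @param delta_chi2 objective increase defining the bound (default 3.84;
#'   0 returns the point estimate).
#' @param bound_type `"upper"` or `"lower"`.
#' @param fit optional pre-computed [global_fit()] result to profile
#'   around (must have been fitted with the same arguments).
#' @param max_decades scan range in decades away from the estimate.
#' @param ... passed to [global_fit()] (e.g. `free`, `fixed`, `seed`).
#' @return An object of class `profile_bound`: `parameter`, `bound_type`,
#'   `bound` (`Inf`/0 with `status = "unbounded within range"` when no
#'   crossing occurs), `chi2_threshold`, `estimate`, `chi2_min`.
#' @export
profile_upper_bound <- function(series, scheme, param_name,
                                delta_chi2 = 3.84,
                                bound_type = c("upper", "lower"),
                                fit = NULL, max_decades = 4, ...) {
  bound_type <- match.arg(bound_type)
  scheme <- match_scheme(scheme)
  dots <- list(...)
  if (is.null(fit)) {
    fit <- do.call(global_fit, c(list(series = series, scheme = scheme),
                                 dots))
  }
  if (!fit$converged) stop("base global fit did not converge")
  chi2_min <- fit$chi2
  # raw-RSS increment equivalent to delta_chi2 on the statistical scale
  sigma2_hat <- chi2_min / max(fit$n_data - fit$n_free, 1)
  delta_rss <- delta_chi2 * sigma2_hat
  est <- unlist(fit$params)[[param_name]]
  if (is.na(est)) est <- 1  # constant absent from the scheme: probe anyway

  mk_bound <- function(bound, status) {
    structure(list(parameter = param_name, bound_type = bound_type,
                   bound = bound, chi2_threshold = delta_chi2,
                   estimate = est, chi2_min = chi2_min, status = status),
              class = "profile_bound")
  }
  if (delta_chi2 == 0) return(mk_bound(est, "point estimate"))

  other_free <- setdiff(fit$free, param_name)
  start_other <- unlist(fit$params)[other_free]
  refit_chi2 <- function(val) {
    fx <- unclass(fit$params)
    fx[[param_name]] <- val
    fx <- fx[!vapply(fx, is.na, logical(1))]
    if (!length(other_free)) {
      pr <- predict_series(series, scheme, as_rate_params(fx),
                           k1_prime = dots$k1_prime)
      return(sum((unlist(pr) -
                  unlist(lapply(series$traces, `[[`, "values")))^2))
    }
    rf <- do.call(global_fit,
                  c(list(series = series, scheme = scheme,
                         free = other_free, fixed = fx,
                         .start = start_other), dots[setdiff(names(dots),
                           c("free", "fixed", "n_starts"))]))
    rf$chi2
  }

  dir_factor <- if (bound_type == "upper") sqrt(10) else 1 / sqrt(10)
  lo <- est; chi_lo <- chi2_min
  val <- est
  crossed <- FALSE
  for (j in seq_len(ceiling(max_decades * 2))) {
    val <- val * dir_factor
    chi <- refit_chi2(val)
    if (chi >= chi2_min + delta_rss) { crossed <- TRUE; break }
    lo <- val; chi_lo <- chi
  }
  if (!crossed) {
    return(mk_bound(if (bound_type == "upper") Inf else 0,
                    "unbounded within range"))
  }
  hi <- val
  for (j in 1:20) {
    mid <- sqrt(lo * hi)
    chi <- refit_chi2(mid)
    if (chi >= chi2_min + delta_rss) hi <- mid else lo <- mid
    if (abs(log(hi / lo)) < 1e-3) break
  }
  mk_bound(sqrt(lo * hi), "crossed")
}

#' @export
print.profile_bound <- function(x, ...) {
  cat(sprintf("Profile %s bound on %s: %.4g (estimate %.4g, delta-chi2 %.3g, %s)\n",
              x$bound_type, x$parameter, x$bound, x$estimate,
              x$chi2_threshold, x$status))
  invisible(x)
}

#' Residual-resampling bootstrap for a global fit
#'
#' Resamples the per-trace residuals of the best fit (with replacement,
#' within each trace), adds them back to the fitted curves, refits from
#' the point estimate, and reports percentile intervals for each free
#' rate constant.  Complements the Jacobian standard errors; the
#' experimental papers instead report the spread across independent
#' repeat experiments.
#'
#' @param series a [trace_series()].
#' @param scheme scheme to fit.
#' @param n_boot number of bootstrap replicates (>= 10).
#' @param seed integer seed; results are reproducible.
#' @param fit optional pre-computed [global_fit()] result.
#' @param level interval coverage (default 0.95).
#' @param ... passed to [global_fit()].
#' @return A data frame with one row per free parameter: `estimate`,
#'   `lower`, `upper`, `level`.
#' @export
bootstrap_uncertainty <- function(series, scheme, n_boot = 100, seed = 1L,
                                  fit = NULL, level = 0.95, ...) {
  if (n_boot < 10) stop("n_boot must be >= 10")
  scheme <- match_scheme(scheme)
  dots <- list(...)
  if (is.null(fit)) {
    fit <- do.call(global_fit, c(list(series = series, scheme = scheme),
                                 dots))
  }
  if (!fit$converged) stop("base global fit did not converge")
  est <- unlist(fit$params)[fit$free]
  fixed_part <- unclass(fit$params)
  fixed_part[fit$free] <- NA_real_
  fixed_part <- fixed_part[!vapply(fixed_part, is.na, logical(1))]

  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, n_boot, length(est),
                  dimnames = list(NULL, fit$free))
  for (b in seq_len(n_boot)) {
    boot_traces <- lapply(seq_along(series$traces), function(i) {
      tr <- series$traces[[i]]
      r <- fit$per_trace_residuals[[i]]
      new_trace(tr$times,
                fit$fitted[[i]] + sample(r, length(r), replace = TRUE),
                tr$meta)
    })
    boot_series <- trace_series(boot_traces, series$scheme, series$kind,
                                series$calibration, series$instrument)
    bf <- tryCatch(
      do.call(global_fit,
              c(list(series = boot_series, scheme = scheme,
                     free = fit$free, fixed = fixed_part, .start = est),
                dots[setdiff(names(dots),
                             c("free", "fixed", "n_starts"))])),
      error = function(e) NULL)
    if (!is.null(bf) && is.finite(bf$chi2)) {
      draws[b, ] <- unlist(bf$params)[fit$free]
    }
  }
  alpha <- (1 - level) / 2
  data.frame(parameter = fit$free, estimate = unname(est),
             lower = apply(draws, 2, quantile, alpha, na.rm = TRUE),
             upper = apply(draws, 2, quantile, 1 - alpha, na.rm = TRUE),
             level = level, row.names = NULL)
}
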