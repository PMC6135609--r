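#' Integrate a kinetic scheme over a time grid
#'
#' Numerically integrates the mass-action ODE system of a scheme from an
#' initial state, using the stiff-capable `lsoda` integrator of
#' \pkg{deSolve} with a compiled right-hand side.  Effective first-order
#' rates in the experiments span roughly 0.013 to >1000 1/s, so a stiff
#' solver is required.
#'
#' @param scheme one of [schemes()].
#' @param params a [rate_params()].
#' @param init initial [species_state()].
#' @param times strictly increasing sampling times, s, all `>= 0`.  If the
#'   first time is positive, integration still starts at the moment of
#'   mixing (`t = 0`).
#' @param k1_prime optional competitor-capture rate constant for the
#'   simple-competition scheme.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @return A data frame with column `time` and one column per species
#'   (nM), one row per requested time.
#' @export
simulate_trajectory <- function(scheme, params, init, times,
                                k1_prime = NULL, rtol = 1e-8, atol = 1e-8) {
  p8 <- scheme_rate_vector(scheme, params, k1_prime)
  y0 <- unlist(init)[.species]
  if (any(is.na(y0)) || any(y0 < 0)) {
    stop("initial state must contain the six species, all >= 0")
  }
  times <- as.numeric(times)
  if (length(times) < 1L || any(times < 0) ||
      (length(times) > 1L && any(diff(times) <= 0))) {
    stop("times must be non-negative and strictly increasing")
  }
  prepend <- times[1] > 0
  tt <- if (prepend) c(0, times) else times

  out <- tryCatch(
    deSolve::ode(y = setNames(as.numeric(y0), .species), times = tt,
                 func = "pk_derivs", parms = p8, dllname = "parpkin",
                 initfunc = "pk_initmod", method = "lsoda",
                 rtol = rtol, atol = atol, maxsteps = 50000),
    warning = function(w) {
      stop("integration failed for scheme '", scheme, "' (rates: ",
           paste(signif(p8, 3), collapse = ", "), "): ",
           conditionMessage(w), call. = FALSE)
    },
    error = function(e) {
      stop("integration failed for scheme '", scheme, "' (rates: ",
           paste(signif(p8, 3), collapse = ", "), "): ",
           conditionMessage(e), call. = FALSE)
    })
  if (nrow(out) != length(tt)) {
    stop("integration stopped early for scheme '", scheme,
         "' at t = ", out[nrow(out), 1], " s")
  }
  traj <- as.data.frame(out)
  if (prepend) traj <- traj[-1L, , drop = FALSE]
  # integrator round-off may leave concentrations a hair below zero
  neg <- traj[.species] < 0
  if (any(neg)) {
    worst <- min(as.matrix(traj[.species]))
    if (worst < -1e-5) {
      stop("integration produced significantly negative concentrations (",
           signif(worst, 3), " nM) for scheme '", scheme, "'")
    }
    traj[.species][neg] <- 0
  }
  rownames(traj) <- NULL
  traj
}

#' Convert a species trajectory to a fluorescence anisotropy signal
#'
#' The anisotropy readout reports the fraction of labeled DNA whose
#' rotation is slowed by bound protein.  Both the probe-bound binary
#' complex and the ternary complex carry the high-anisotropy signal, so
#' \deqn{r(t) = r_{free} + (r_{bound} - r_{free}) \,
#'       \frac{PD^*(t) + T(t)}{[D^*]_{tot}}.}
#' The calibration (`r_free` from protein-free controls, `r_bound` from
#' the saturated plateau) is how raw anisotropy is converted to
#' concentration in the analysis of real experiments.
#'
#' @param traj a trajectory from [simulate_trajectory()] (or anything with
#'   `PDstar` and `T` components).
#' @param cal an [anisotropy_calibration()].
#' @param totalDstar total labeled DNA, nM (> 0).
#' @return Numeric vector of anisotropy values, one per row of `traj`.
#' @export
state_to_anisotropy <- function(traj, cal, totalDstar) {
  if (!is.numeric(totalDstar) || totalDstar <= 0) {
    stop("totalDstar must be > 0 to define the bound fraction")
  }
  bound <- (unlist2d(traj, "PDstar") + unlist2d(traj, "T")) / totalDstar
  cal$r_free + (cal$r_bound - cal$r_free) * bound
}

# column extraction that works for data frames, matrices and plain states
unlist2d <- function(x, name) {
  if (is.data.frame(x) || is.matrix(x)) as.numeric(x[, name]) else
    as.numeric(unlist(x)[name])
}
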