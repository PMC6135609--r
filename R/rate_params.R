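#' Rate constants for the PARP1-DNA binding schemes
#'
#' Container for the six mass-action rate constants shared by the three
#' kinetic schemes:
#' \describe{
#'   \item{k1}{bimolecular association of free protein with free DNA
#'     (labeled or competitor), 1/(nM s).}
#'   \item{k_m1}{unimolecular dissociation of the binary protein-DNA
#'     complex, 1/s.}
#'   \item{k2}{bimolecular association of competitor DNA with the
#'     probe-bound binary complex, forming the ternary complex, 1/(nM s).}
#'   \item{k_m2}{release of the competitor DNA from the ternary complex,
#'     regenerating the probe-bound binary complex, 1/s.}
#'   \item{k3}{release of the pre-bound (labeled) DNA from the ternary
#'     complex, leaving protein bound to competitor only, 1/s.}
#'   \item{k_m3}{re-formation of the ternary complex from the
#'     competitor-bound binary complex plus free labeled DNA, 1/(nM s).}
#' }
#' The second-DNA steps are deliberately asymmetric (`k2 != k_m3`,
#' `k_m2 != k3` is allowed and expected): the incoming DNA binds a
#' different, weaker site than the pre-bound one.
#'
#' Constants not needed by a given scheme may be left `NA`; supplied values
#' must be finite and non-negative.
#'
#' @param k1,k_m1,k2,k_m2,k3,k_m3 rate constants as described above.
#' @return An object of class `rate_params` (a named list of six numerics).
#' @examples
#' wt <- rate_params(k1 = 3.1, k_m1 = 5, k2 = 0.043, k_m2 = 102,
#'                   k3 = 9.7, k_m3 = 0.013)
#' kd_from_rates(wt$k_m2, wt$k2)  # equilibrium constant of the second site
#' @export
rate_params <- function(k1 = NA_real_, k_m1 = NA_real_, k2 = NA_real_,
                        k_m2 = NA_real_, k3 = NA_real_, k_m3 = NA_real_) {
  p <- c(k1 = as.numeric(k1)[1], k_m1 = as.numeric(k_m1)[1],
         k2 = as.numeric(k2)[1], k_m2 = as.numeric(k_m2)[1],
         k3 = as.numeric(k3)[1], k_m3 = as.numeric(k_m3)[1])
  bad <- !is.na(p) & (!is.finite(p) | p < 0)
  if (any(bad)) {
    stop("rate constants must be finite and >= 0; offending: ",
         paste(names(p)[bad], collapse = ", "))
  }
  structure(as.list(p), class = "rate_params")
}

#' Coerce a named list or vector to rate_params
#' @param x named list or numeric vector with a subset of
#'   `k1, k_m1, k2, k_m2, k3, k_m3`.
#' @return A `rate_params` object.
#' @export
as_rate_params <- function(x) {
  if (inherits(x, "rate_params")) return(x)
  x <- as.list(x)
  known <- c("k1", "k_m1", "k2", "k_m2", "k3", "k_m3")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown rate constant name(s): ", paste(unknown, collapse = ", "),
         "; valid names are ", paste(known, collapse = ", "))
  }
  do.call(rate_params, x)
}

#' @export
print.rate_params <- function(x, ...) {
  v <- unlist(x)
  units <- c("1/(nM s)", "1/s", "1/(nM s)", "1/s", "1/s", "1/(nM s)")
  cat("Rate constants (nM, s units):\n")
  for (i in seq_along(v)) {
    cat(sprintf("  %-5s %10.4g  %s\n", names(v)[i], v[i], units[i]))
  }
  invisible(x)
}

#' Update a subset of rate constants
#' @param params a `rate_params` object.
#' @param ... named replacement values, e.g. `k_m1 = 10`.
#' @return A new `rate_params` object.
#' @export
update_rate_params <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 1L && is.null(names(repl)) && is.list(repl[[1]])) {
    repl <- repl[[1]]
  }
  as_rate_params(modifyList(unclass(as_rate_params(params)), repl))
}

#' Equilibrium dissociation constant from rate constants
#'
#' `K_D = k_off / k_on`.  For the first binding site this is `k_m1 / k1`
#' (< 3 nM for wild-type, ~5 nM for the W589A mutant); for the second,
#' ternary-forming site it is `k_m2 / k2`, in the micromolar range, which
#' is why the ternary complex is essentially undetectable in equilibrium
#' titrations at nanomolar protein.
#'
#' @param k_off unimolecular off-rate, 1/s (>= 0).
#' @param k_on bimolecular on-rate, 1/(nM s) (> 0).
#' @return `K_D` in nM.
#' @export
kd_from_rates <- function(k_off, k_on) {
  stopifnot(is.numeric(k_off), is.numeric(k_on))
  if (any(k_on <= 0)) stop("k_on must be > 0 to define a K_D")
  if (any(k_off < 0)) stop("k_off must be >= 0")
  k_off / k_on
}

#' Re-express a per-site rate constant under a different site count
#'
#' A bimolecular rate constant for a long competitor (e.g. a 4.5 kb
#' plasmid) is only defined per binding site, and its fitted value scales
#' inversely with the assumed number of sites per particle.  A constant
#' fitted assuming `sites_assumed` sites is converted to the value it
#' would take under `sites_target` sites.  For the plasmid the plausible
#' range is 5 sites (the minimum able to strip a 25 nM pre-bound probe at
#' 5 nM particles) to ~450 (one protein per 10 bp), so a fitted per-site
#' constant maps to a bounded interval rather than a point.
#'
#' @param k_per_site per-site bimolecular rate constant, 1/(nM s).
#' @param sites_assumed site count under which `k_per_site` was fitted
#'   (integer >= 1).
#' @param sites_target site count to re-express under (integer >= 1).
#' @return The rescaled per-site rate constant, 1/(nM s).
#' @examples
#' per_site_rescale(0.041, 450, 5)  # 3.69
#' @export
per_site_rescale <- function(k_per_site, sites_assumed, sites_target) {
  if (any(sites_assumed < 1) || any(sites_target < 1)) {
    stop("site counts must be >= 1")
  }
  k_per_site * sites_assumed / sites_target
}

#' Steady-state approximation to the exchange rate in the ternary scheme
#'
#' Closed-form observed rate of probe release when the ternary pathway
#' dominates and rebinding of released probe is negligible (large excess
#' of competitor sites):
#' \deqn{k_{obs}(D) = \frac{k_3 k_2 D}{k_2 D + k_{-2} + k_3}}
#' obtained by treating the ternary complex as a steady-state intermediate
#' between the probe-bound binary complex and release.  It increases
#' monotonically with the competitor site concentration `D` and saturates
#' at `k3`.  Used as an independent oracle for full ODE simulations; the
#' full model, not this approximation, is what gets fitted.
#'
#' @param params `rate_params` with `k2`, `k_m2`, `k3` set.
#' @param D_sites competitor concentration in binding-site units, nM
#'   (vectorised, >= 0).
#' @return Approximate observed exchange rate(s), 1/s.
#' @export
approx_kobs_ternary <- function(params, D_sites) {
  params <- as_rate_params(params)
  if (any(is.na(c(params$k2, params$k_m2, params$k3)))) {
    stop("approx_kobs_ternary needs k2, k_m2 and k3")
  }
  if (any(D_sites < 0)) stop("D_sites must be >= 0")
  with(params, k3 * k2 * D_sites / (k2 * D_sites + k_m2 + k3))
}
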