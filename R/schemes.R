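#' The three kinetic schemes
#'
#' @description
#' Three reaction networks describe the stopped-flow experiments:
#' \describe{
#'   \item{`"association"`}{a single reversible binding step
#'     `P + Dstar <-> PDstar` with `(k1, k_m1)` — the association
#'     experiment, where protein is mixed with free labeled DNA.}
#'   \item{`"simple_competition"`}{competitor-independent release: the probe
#'     complex dissociates at `k_m1` and the freed protein is captured
#'     irreversibly by excess unlabeled DNA (`P + D -> PD` at `k1'`,
#'     equal to `k1` by default — same chemistry, unlabeled molecule).
#'     Valid as a trap for `k1'[DNA] >> k_m1`; the mechanism followed by
#'     the WGR-deficient proteins.}
#'   \item{`"ternary"`}{DNA-dependent release through a ternary complex:
#'     the competitor binds the probe-bound protein first
#'     (`PDstar + D <-> T`, `(k2, k_m2)`), then the pre-bound probe is
#'     released (`T <-> PD + Dstar`, release `k3`, re-formation `k_m3`).
#'     The scheme also carries both first-site binding steps
#'     (`P + Dstar <-> PDstar`, `P + D <-> PD`, each `(k1, k_m1)`) so that
#'     free protein present after pre-equilibration is accounted for.
#'     The direction convention: `k3` releases the labeled DNA from the
#'     ternary complex; `k_m3` re-forms it from `PD + Dstar`.}
#' }
#'
#' The state carries six species (all nM): `P` free protein, `Dstar` free
#' labeled DNA, `D` free competitor DNA (in binding-site units), `PDstar`
#' and `PD` the two binary complexes, and `T` the ternary complex
#' `Dstar.P.D`.  A doubly-labeled ternary complex (`Dstar.P.Dstar`) is not
#' represented: at the experimental stoichiometry (25 nM probe, 37 nM
#' protein) free labeled DNA is negligible.  Each DNA oligomer counts as
#' one binding equivalent (not two): anisotropy detects only the first
#' binding event.
#'
#' @name schemes
#' @return `schemes()` returns the character vector of valid scheme
#'   identifiers.
#' @export
schemes <- function() c("association", "simple_competition", "ternary")

#' @rdname schemes
#' @param scheme a scheme identifier (partial matching is not performed).
#' @export
match_scheme <- function(scheme) {
  if (length(scheme) != 1L || !is.character(scheme) ||
      !(scheme %in% schemes())) {
    stop("unknown scheme ", deparse(scheme), "; valid schemes are: ",
         paste(schemes(), collapse = ", "))
  }
  scheme
}

.species <- c("P", "Dstar", "D", "PDstar", "PD", "T")

#' Species concentration state
#'
#' Named non-negative concentration vector over the six chemical species
#' (nM): free protein `P`, free labeled DNA `Dstar`, free competitor DNA
#' `D` (site units), binary complexes `PDstar` and `PD`, ternary complex
#' `T`.
#'
#' @param P,Dstar,D,PDstar,PD,T concentrations in nM (>= 0).
#' @return Named numeric vector of class `species_state`.
#' @export
species_state <- function(P = 0, Dstar = 0, D = 0, PDstar = 0, PD = 0,
                          T = 0) {
  s <- c(P = P, Dstar = Dstar, D = D, PDstar = PDstar, PD = PD, T = T)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("species concentrations must be finite and >= 0")
  }
  structure(s, class = "species_state")
}

#' Conserved totals of a state
#'
#' Mass balance of the network: total protein `P + PDstar + PD + T`, total
#' labeled DNA `Dstar + PDstar + T`, and total competitor sites
#' `D + PD + T`.  Every trajectory of every scheme conserves all three.
#'
#' @param state a `species_state` (or named vector/one-row data frame with
#'   the six species).
#' @return Named numeric vector `totalP`, `totalDstar`, `totalD` (nM).
#' @export
conserved_totals <- function(state) {
  s <- unlist(state)[.species]
  c(totalP = unname(s["P"] + s["PDstar"] + s["PD"] + s["T"]),
    totalDstar = unname(s["Dstar"] + s["PDstar"] + s["T"]),
    totalD = unname(s["D"] + s["PD"] + s["T"]))
}

#' Reaction network of a scheme
#'
#' Lists the elementary steps of a scheme with their rate-constant labels,
#' one row per step.  Reversible steps carry both a forward and a reverse
#' label; the irreversible competitor trap of the simple-competition
#' scheme has `k_reverse = NA`.
#'
#' @param scheme one of [schemes()].
#' @return A data frame with columns `reactants`, `products`, `k_forward`,
#'   `k_reverse`, `reversible`.
#' @examples
#' reaction_network("ternary")
#' @export
reaction_network <- function(scheme) {
  scheme <- match_scheme(scheme)
  bind_probe <- data.frame(reactants = "P + Dstar", products = "PDstar",
                           k_forward = "k1", k_reverse = "k_m1",
                           reversible = TRUE)
  switch(scheme,
    association = bind_probe,
    simple_competition = rbind(
      bind_probe,
      data.frame(reactants = "P + D", products = "PD",
                 k_forward = "k1'", k_reverse = NA_character_,
                 reversible = FALSE)),
    ternary = rbind(
      bind_probe,
      data.frame(reactants = "P + D", products = "PD",
                 k_forward = "k1", k_reverse = "k_m1", reversible = TRUE),
      data.frame(reactants = "PDstar + D", products = "T",
                 k_forward = "k2", k_reverse = "k_m2", reversible = TRUE),
      data.frame(reactants = "PD + Dstar", products = "T",
                 k_forward = "k_m3", k_reverse = "k3", reversible = TRUE)))
}

# Map (scheme, rate_params) onto the generic 8-parameter network used by
# both the R and the compiled right-hand side:
# (k1, km1, k1p, km1p, k2, km2, k3, km3).  k1_prime overrides the
# competitor-capture constant of the simple-competition scheme (defaults
# to k1).
scheme_rate_vector <- function(scheme, params, k1_prime = NULL) {
  scheme <- match_scheme(scheme)
  params <- as_rate_params(params)
  need <- switch(scheme,
                 association = c("k1", "k_m1"),
                 simple_competition = c("k1", "k_m1"),
                 ternary = c("k1", "k_m1", "k2", "k_m2", "k3", "k_m3"))
  miss <- need[vapply(need, function(nm) is.na(params[[nm]]), logical(1))]
  if (length(miss)) {
    stop("scheme '", scheme, "' needs rate constants: ",
         paste(miss, collapse = ", "))
  }
  k1p <- if (is.null(k1_prime)) params$k1 else as.numeric(k1_prime)
  switch(scheme,
    association = c(params$k1, params$k_m1, 0, 0, 0, 0, 0, 0),
    simple_competition = c(params$k1, params$k_m1, k1p, 0, 0, 0, 0, 0),
    ternary = c(params$k1, params$k_m1, params$k1, params$k_m1,
                params$k2, params$k_m2, params$k3, params$k_m3))
}

#' Time derivative of the species state
#'
#' Signed sum of the mass-action fluxes of a scheme at a given state.
#' By construction the derivative of each conserved total is exactly zero.
#'
#' @param scheme one of [schemes()].
#' @param params a [rate_params()] with the constants the scheme needs.
#' @param state a [species_state()] (negative concentrations are rejected).
#' @param k1_prime optional competitor-capture rate constant for the
#'   simple-competition scheme (defaults to `k1`).
#' @return Named numeric vector of derivatives, nM/s per species.
#' @export
ode_rhs <- function(scheme, params, state, k1_prime = NULL) {
  p <- scheme_rate_vector(scheme, params, k1_prime)
  s <- unlist(state)[.species]
  if (any(is.na(s)) || any(s < 0)) {
    stop("state must contain the six species with non-negative values")
  }
  v1 <- p[1] * s["P"] * s["Dstar"] - p[2] * s["PDstar"]
  v2 <- p[3] * s["P"] * s["D"] - p[4] * s["PD"]
  v3 <- p[5] * s["PDstar"] * s["D"] - p[6] * s["T"]
  v4 <- p[8] * s["PD"] * s["Dstar"] - p[7] * s["T"]
  setNames(c(-v1 - v2, -v1 - v4, -v2 - v3, v1 - v3, v2 - v4, v3 + v4),
           .species)
}

#' Binding equilibrium of protein and labeled DNA before mixing
#'
#' The dissociation experiments start from a pre-formed complex of protein
#' and labeled DNA (37 and 25 nM in the reference design).  This computes
#' the exact single-site binding equilibrium with `K_D = k_m1 / k1`: the
#' physical (smaller) root of
#' `PDstar^2 - (P0 + D0 + K_D) PDstar + P0 D0 = 0`,
#' with free protein and free probe by difference and all other species
#' zero.
#'
#' @param totalP,totalDstar total protein and labeled DNA, nM (>= 0).
#' @param k1 association rate constant, 1/(nM s) (> 0).
#' @param k_m1 dissociation rate constant, 1/s (>= 0; 0 gives the
#'   stoichiometric limit).
#' @return A [species_state()] at equilibrium.
#' @examples
#' pre_equilibrate(37, 25, 3.1, 6.2)  # K_D = 2 nM -> ~22 nM complex
#' @export
pre_equilibrate <- function(totalP, totalDstar, k1, k_m1) {
  stopifnot(totalP >= 0, totalDstar >= 0, k_m1 >= 0)
  if (k1 <= 0) stop("k1 must be > 0: no binding equilibrium is defined")
  kd <- k_m1 / k1
  a <- totalP + totalDstar + kd
  disc <- a^2 - 4 * totalP * totalDstar
  pd <- (a - sqrt(max(disc, 0))) / 2
  pd <- min(pd, totalP, totalDstar)  # guard rounding at the boundary
  species_state(P = max(totalP - pd, 0), Dstar = max(totalDstar - pd, 0),
                PDstar = pd)
}
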