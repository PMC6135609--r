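#' Kinetic parameter presets for PARP1 constructs
#'
#' Generating truths for the synthetic experiments: the aggregated
#' stopped-flow rate constants of wild-type PARP1, the four DNA-binding
#' domain deletions, the W589A point mutant, and wild-type challenged
#' with intact plasmid competitor.  Each preset carries the mean rate
#' constants, the reported spread across independent experiments (`sd`),
#' the dissociation mechanism the construct follows, and the competitor
#' site count.  The association experiments only bound the probe
#' off-rate from above (`k_m1 < 10` 1/s); presets that follow the ternary
#' mechanism use 0.5 1/s as the generating value, an order of magnitude
#' below that bound, because the dissociation experiments themselves show
#' that unassisted release is negligible on the observation timescale
#' (observed rates fall towards zero as competitor is withdrawn, and a
#' 5 nM oligomer competitor triggers no observable release).  For the
#' plasmid preset
#' the per-site `k2` is stored under the 450-sites assumption; use
#' [per_site_rescale()] to re-express it (0.041-3.7 1/(nM s) across the
#' 5-450 site range).
#'
#' @param name preset name; omit for the vector of available names.
#' @return `parp_presets()`: character vector of preset names.
#'   `preset(name)`: a list with `name`, `params` ([rate_params()]),
#'   `sd` (named numeric), `dissociation_scheme`, `competitor_sites`,
#'   `k_m1_upper_bound` (where only a bound is known).
#' @examples
#' preset("WT")$params
#' @export
parp_presets <- function() names(.presets())

#' @rdname parp_presets
#' @export
preset <- function(name) {
  tab <- .presets()
  if (length(name) != 1L || !name %in% names(tab)) {
    stop("unknown preset ", deparse(name), "; available presets: ",
         paste(names(tab), collapse = ", "))
  }
  c(list(name = name), tab[[name]])
}

.presets <- function() list(
  WT = list(
    params = rate_params(k1 = 3.1, k_m1 = 0.5, k2 = 0.043, k_m2 = 102,
                         k3 = 9.7, k_m3 = 0.013),
    sd = c(k1 = 0.2, k2 = 0.019, k_m2 = 22, k3 = 0.8, k_m3 = 0.002),
    dissociation_scheme = "ternary", competitor_sites = 1L,
    k_m1_upper_bound = 10),
  dZn1 = list(
    params = rate_params(k1 = 3.7, k_m1 = 0.5, k2 = 0.018, k_m2 = 97,
                         k3 = 21, k_m3 = 0.027),
    sd = c(k1 = 0.4, k2 = 0.012, k_m2 = 19, k3 = 5, k_m3 = 0.009),
    dissociation_scheme = "ternary", competitor_sites = 1L,
    k_m1_upper_bound = 10),
  dZn2 = list(
    params = rate_params(k1 = 4.0, k_m1 = 0.5, k2 = 0.073, k_m2 = 145,
                         k3 = 15, k_m3 = 0.023),
    sd = c(k1 = 1.3, k2 = 0.015, k_m2 = 66, k3 = 4, k_m3 = 0.007),
    dissociation_scheme = "ternary", competitor_sites = 1L,
    k_m1_upper_bound = 10),
  dZn3 = list(
    params = rate_params(k1 = 5.5, k_m1 = 0.5, k2 = 0.034, k_m2 = 76,
                         k3 = 19, k_m3 = 0.050),
    sd = c(k1 = 0.3, k2 = 0.013, k_m2 = 66, k3 = 7, k_m3 = 0.016),
    dissociation_scheme = "ternary", competitor_sites = 1L,
    k_m1_upper_bound = 10),
  dWGR = list(
    params = rate_params(k1 = 2.4, k_m1 = 18.7),
    sd = c(k1 = 1.1, k_m1 = 2.7),
    dissociation_scheme = "simple_competition", competitor_sites = 1L),
  W589A = list(
    params = rate_params(k1 = 4.2, k_m1 = 20.2),
    sd = c(k1 = 0.5, k_m1 = 2.4),
    dissociation_scheme = "simple_competition", competitor_sites = 1L),
  WT_plasmid = list(
    params = rate_params(k1 = 3.1, k_m1 = 0.5, k2 = 0.041, k_m2 = 161,
                         k3 = 9, k_m3 = 0.032),
    sd = c(k_m2 = 8, k3 = 3, k_m3 = 0.006),
    dissociation_scheme = "ternary", competitor_sites = 450L,
    k_m1_upper_bound = 10, k2_per_site_range = c(0.041, 3.7)))

#' Reference concentration designs
#'
#' The concentration layouts of the stopped-flow experiments, after
#' mixing.  Association: 30 nM labeled probe against 60-250 nM protein
#' over a 25 ms window.  Dissociation: 37 nM protein pre-bound to 25 nM
#' probe, challenged with competitor over 1-5 s — six 18-mer
#' concentrations spanning 50 nM-4 uM for ternary-mechanism constructs,
#' three 0.4-4 uM concentrations for the WGR-deficient constructs (whose
#' release rate is competitor-independent), and 0.7-5.8 nM particles for
#' the intact 4.5 kb plasmid.
#'
#' @param preset_name a preset name (see [parp_presets()]); the
#'   dissociation layout depends on the construct and competitor.
#' @return A list with the design concentrations (nM) and window (s).
#' @export
association_design <- function(preset_name = "WT") {
  list(P_concs = c(60, 80, 106, 141, 188, 250), Dstar_total = 30,
       t_end = 0.025)
}

#' @rdname association_design
#' @export
dissociation_design <- function(preset_name = "WT") {
  ps <- preset(preset_name)
  if (ps$competitor_sites > 1L) {
    list(competitor_molar = c(0.7, 2.0, 5.8),
         sites_per_particle = ps$competitor_sites,
         preP = 37, preDstar = 25, t_end = 5)
  } else if (ps$dissociation_scheme == "simple_competition") {
    list(competitor_molar = c(400, 1300, 4000), sites_per_particle = 1L,
         preP = 37, preDstar = 25, t_end = 1)
  } else {
    list(competitor_molar = c(50, 120, 288, 693, 1665, 4000),
         sites_per_particle = 1L, preP = 37, preDstar = 25, t_end = 5)
  }
}

#' Simulate a full preset design
#'
#' Convenience wrapper: generates the association or dissociation series
#' of a preset at its published truth, with the reference design.
#'
#' @param preset_name a preset name.
#' @param design `"association"` or `"dissociation"`.
#' @param seed integer noise seed.
#' @param n_points,noise_sd optional overrides of the instrument
#'   defaults.
#' @param competitor_molar optional override of the competitor
#'   concentrations (nM particles).
#' @param inhibitor optional inhibitor name recorded in metadata (never
#'   alters parameters: catalytic-site inhibitors do not change DNA
#'   release kinetics).
#' @return A [trace_series()].
#' @export
simulate_preset <- function(preset_name,
                            design = c("dissociation", "association"),
                            seed = 1L, n_points = NULL, noise_sd = NULL,
                            competitor_molar = NULL, inhibitor = NULL) {
  design <- match.arg(design)
  ps <- preset(preset_name)
  if (design == "association") {
    d <- association_design(preset_name)
    inst <- instrument_spec(t_end = d$t_end, seed = seed)
    if (!is.null(n_points)) inst$n_points <- as.integer(n_points)
    if (!is.null(noise_sd)) inst$noise_sd <- noise_sd
    generate_association_series(ps$params, d$P_concs, d$Dstar_total,
                                instrument = inst, inhibitor = inhibitor)
  } else {
    d <- dissociation_design(preset_name)
    if (!is.null(competitor_molar)) d$competitor_molar <- competitor_molar
    inst <- instrument_spec(t_end = d$t_end, seed = seed)
    if (!is.null(n_points)) inst$n_points <- as.integer(n_points)
    if (!is.null(noise_sd)) inst$noise_sd <- noise_sd
    comps <- lapply(d$competitor_molar, competitor_spec,
                    sites_per_particle = d$sites_per_particle)
    generate_dissociation_series(ps$params, comps,
                                 scheme = ps$dissociation_scheme,
                                 preP = d$preP, preDstar = d$preDstar,
                                 instrument = inst, inhibitor = inhibitor)
  }
}
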