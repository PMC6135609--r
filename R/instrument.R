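#' Anisotropy calibration
#'
#' Baseline and plateau anisotropy used to convert between bound-probe
#' fraction and signal.  In the laboratory these come from control shots:
#' the free-probe baseline from reactions without protein, the bound
#' plateau from saturating conditions.  Defaults (0.05 free, 0.25 bound)
#' are representative fluorescein-labeled 18-mer values; their absolute
#' magnitude is immaterial because fitting uses the same calibrated
#' conversion as simulation.
#'
#' @param r_free anisotropy of free labeled DNA.
#' @param r_bound anisotropy of protein-bound labeled DNA
#'   (`r_bound > r_free`; both within the physical range \[0, 0.4\]).
#' @return An object of class `anisotropy_calibration`.
#' @export
anisotropy_calibration <- function(r_free = 0.05, r_bound = 0.25) {
  if (!(r_free >= 0 && r_bound <= 0.4 && r_bound > r_free)) {
    stop("need 0 <= r_free < r_bound <= 0.4")
  }
  structure(list(r_free = r_free, r_bound = r_bound),
            class = "anisotropy_calibration")
}

#' Stopped-flow instrument and acquisition settings
#'
#' Describes one acquisition: the mixing dead time during which no signal
#' can be recorded (default 1.5 ms, typical for this instrument class),
#' logarithmic sampling ("log mode") with `n_points` samples between the
#' dead time and `t_end`, the number of shots averaged per trace (10-12
#' in the experiments; default 11), and the per-shot noise level.  The
#' noise actually added to an averaged trace has standard deviation
#' `noise_sd / sqrt(shots_averaged)`; the default `noise_sd` puts the
#' averaged-trace residual scatter at about 2% of the full anisotropy
#' span.
#'
#' @param t_end end of the acquisition window, s (25 ms for association
#'   experiments, 1-5 s for dissociation).
#' @param dead_time mixing dead time, s (>= 0).
#' @param n_points samples per trace (>= 10).
#' @param shots_averaged shots averaged per trace (>= 1).
#' @param noise_sd per-shot Gaussian noise standard deviation, anisotropy
#'   units (>= 0).
#' @param seed integer seed for the noise stream; each trace in a series
#'   uses `xor(seed, trace index)` so traces are independent but the whole
#'   series is reproducible.
#' @param log_spaced logical; `FALSE` gives a linear grid (useful in
#'   tests).
#' @return An object of class `instrument_spec`.
#' @export
instrument_spec <- function(t_end, dead_time = 0.0015, n_points = 500,
                            shots_averaged = 11, noise_sd = 0.0133,
                            seed = 1L, log_spaced = TRUE) {
  stopifnot(dead_time >= 0, n_points >= 10, t_end > dead_time,
            shots_averaged >= 1, noise_sd >= 0)
  structure(list(t_end = t_end, dead_time = dead_time,
                 n_points = as.integer(n_points),
                 shots_averaged = as.integer(shots_averaged),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 log_spaced = isTRUE(log_spaced)),
            class = "instrument_spec")
}

#' Sampling grid of an instrument spec
#' @param instrument an [instrument_spec()].
#' @return Strictly increasing times from `dead_time` to `t_end`, s.
#' @export
sampling_times <- function(instrument) {
  with(instrument, {
    t0 <- if (dead_time > 0) dead_time else t_end / (n_points * 100)
    if (log_spaced) exp(seq(log(t0), log(t_end), length.out = n_points))
    else seq(t0, t_end, length.out = n_points)
  })
}
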