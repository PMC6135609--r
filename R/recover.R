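#' Parameter-recovery experiment for a preset
#'
#' The headline validation: simulate a preset's concentration design at
#' its published rate constants, fit the appropriate scheme globally, and
#' tabulate how well the constants are recovered across independently
#' seeded replicates.  Association designs are fitted with the
#' association scheme (free `k1`, `k_m1`); dissociation designs with the
#' construct's mechanism — the four second-DNA constants for ternary
#' constructs (binding steps fixed at their generating values, as in the
#' original analysis where they came from the association experiments),
#' or the release rate `k_m1` for simple-competition constructs.
#'
#' @param preset_name a preset name (see [parp_presets()]).
#' @param design `"dissociation"` (default) or `"association"`.
#' @param n_replicates number of independently seeded synthetic series
#'   (default 10).
#' @param seed base integer seed; replicate `r` uses `seed + 7919 * r`.
#' @param n_starts multistarts per fit (default 8).
#' @param n_points points per trace (default 250).
#' @param ... passed to [global_fit()].
#' @return An object of class `recovery_summary`: `replicates` (one row
#'   per replicate per free parameter) and `summary` (per parameter:
#'   truth, median and median absolute relative error of the recovered
#'   values, the published spread `sd`, and the fraction of replicates
#'   within it).
#' @export
recover_params <- function(preset_name,
                           design = c("dissociation", "association"),
                           n_replicates = 10, seed = 1L, n_starts = 8,
                           n_points = 250, ...) {
  design <- match.arg(design)
  ps <- preset(preset_name)
  truth <- unlist(ps$params)

  if (design == "association") {
    scheme <- "association"
    free <- c("k1", "k_m1")
    fixed <- NULL
  } else {
    scheme <- ps$dissociation_scheme
    free <- default_free_params(scheme)
    fixed <- unclass(ps$params)
    fixed[free] <- NA_real_
    fixed <- fixed[!vapply(fixed, is.na, logical(1))]
  }

  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s_r <- as.integer(seed) + 7919L * r
    series <- simulate_preset(preset_name, design, seed = s_r,
                              n_points = n_points)
    fit <- global_fit(series, scheme, free = free, fixed = fixed,
                      n_starts = n_starts, seed = s_r, ...)
    got <- unlist(fit$params)[free]
    rows[[r]] <- data.frame(replicate = r, seed = s_r, parameter = free,
                            truth = unname(truth[free]),
                            estimate = unname(got),
                            converged = fit$converged, chi2 = fit$chi2)
  }
  reps <- do.call(rbind, rows)
  reps$rel_error <- (reps$estimate - reps$truth) / reps$truth

  sd_pub <- ps$sd
  summ <- do.call(rbind, lapply(free, function(nm) {
    sub <- reps[reps$parameter == nm, ]
    s <- if (nm %in% names(sd_pub)) sd_pub[[nm]] else NA_real_
    data.frame(parameter = nm, truth = sub$truth[1],
               median = median(sub$estimate),
               bias = median(sub$estimate) - sub$truth[1],
               median_abs_rel_error = median(abs(sub$rel_error)),
               published_sd = s,
               frac_within_sd = if (is.na(s)) NA_real_ else
                 mean(abs(sub$estimate - sub$truth) <= s))
  }))
  structure(list(preset = preset_name, design = design,
                 replicates = reps, summary = summ,
                 n_replicates = n_replicates, seed = seed),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Parameter recovery, preset %s (%s design, %d replicates):\n",
              x$preset, x$design, x$n_replicates))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
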