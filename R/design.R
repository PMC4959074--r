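# Study design for the synthetic generator.

#' Synthetic study design
#'
#' Describes the acquisition layout and noise model of a synthetic
#' direct-infusion (DIMS) or LC FT-ICR study.  Defaults mirror a three-group
#' mosquito cell-line experiment: 7 control / 6 wMel / 6 wMelPop biological
#' samples, technical triplicates, 12 overlapping SIM windows spanning
#' m/z 120-1200, pooled QC acquisitions and solvent blanks.
#'
#' @param n_control,n_wmel,n_wmelpop Biological sample counts per group.
#' @param tech_reps Technical replicates per sample (3 for DIMS, 1 for LC).
#' @param n_windows Number of SIM windows (DIMS).
#' @param mz_range Acquired m/z span.
#' @param window_overlap Overlap between adjacent SIM windows (Da); windows
#'   are equal width and tile `mz_range`.
#' @param n_qc Number of pooled-QC acquisitions (each with `tech_reps`
#'   replicates).
#' @param n_blank Number of solvent-blank acquisitions.
#' @param cv_biological Biological coefficient of variation (log-normal).
#' @param cv_technical Technical (per replicate) coefficient of variation.
#' @param cv_window Per-SIM-window multiplicative gain CV (DIMS).
#' @param ppm_sd Mass-error standard deviation in ppm.
#' @param detection_limit Intensity below which a peak is censored (absent);
#'   set to 0 to disable censoring.
#' @param rt_sd LC retention-time jitter SD in seconds (LC mode).
#' @param seed Random seed driving the whole study.
#' @param mode `"DIMS"` or `"LC"`.
#' @return A `study_design` list; window boundaries are in `$windows`.
#' @examples
#' d <- study_design(seed = 7)
#' d$windows[1:2, ]
#' @export
study_design <- function(n_control = 7, n_wmel = 6, n_wmelpop = 6,
                         tech_reps = if (mode == "DIMS") 3 else 1,
                         n_windows = 12, mz_range = c(120, 1200),
                         window_overlap = 10, n_qc = 4, n_blank = 3,
                         cv_biological = 0.25, cv_technical = 0.10,
                         cv_window = 0.10, ppm_sd = 0.5,
                         detection_limit = 2.5e4, rt_sd = 2,
                         seed = 1, mode = c("DIMS", "LC")) {
  mode <- match.arg(mode)
  stopifnot(cv_biological >= 0, cv_technical >= 0, cv_window >= 0,
            ppm_sd >= 0, detection_limit >= 0, n_windows >= 1,
            tech_reps >= 1, mz_range[2] > mz_range[1])
  windows <- sim_windows(n_windows, mz_range, window_overlap)
  structure(list(
    group_sizes = c(control = n_control, wMel = n_wmel, wMelPop = n_wmelpop),
    tech_reps = tech_reps, n_windows = n_windows, mz_range = mz_range,
    window_overlap = window_overlap, windows = windows, n_qc = n_qc,
    n_blank = n_blank, cv_biological = cv_biological,
    cv_technical = cv_technical, cv_window = cv_window, ppm_sd = ppm_sd,
    detection_limit = detection_limit, rt_sd = rt_sd, seed = seed,
    mode = mode
  ), class = "study_design")
}

#' SIM window boundaries
#'
#' Equal-width windows tiling an m/z range with a fixed positive overlap
#' between adjacent windows.
#'
#' @param n_windows Number of windows.
#' @param mz_range Range to tile.
#' @param overlap Overlap in Da (must leave no gaps).
#' @return Data frame with `window`, `start`, `end`.
#' @export
sim_windows <- function(n_windows, mz_range = c(120, 1200), overlap = 10) {
  if (n_windows == 1) {
    return(data.frame(window = 1L, start = mz_range[1], end = mz_range[2]))
  }
  if (overlap <= 0) stop("adjacent SIM windows must overlap (overlap > 0)")
  span <- diff(mz_range)
  width <- (span + (n_windows - 1) * overlap) / n_windows
  if (width <= overlap) stop("window tiling leaves gaps: overlap too large")
  start <- mz_range[1] + (seq_len(n_windows) - 1) * (width - overlap)
  data.frame(window = seq_len(n_windows), start = start, end = start + width)
}

#' A noise-free variant of a design
#'
#' All CVs, the mass-error SD and the detection limit are set to zero; used
#' for exactness checks.
#'
#' @param design A `study_design`.
#' @return The modified design.
#' @export
noise_free <- function(design) {
  design$cv_biological <- 0
  design$cv_technical <- 0
  design$cv_window <- 0
  design$ppm_sd <- 0
  design$detection_limit <- 0
  design$rt_sd <- 0
  design
}

#' @export
print.study_design <- function(x, ...) {
  cat("Synthetic", x$mode, "study design\n")
  cat("  samples:", paste(names(x$group_sizes), x$group_sizes,
                          sep = "=", collapse = ", "),
      "| QC:", x$n_qc, "| blanks:", x$n_blank, "\n")
  cat("  technical replicates:", x$tech_reps,
      "| SIM windows:", x$n_windows,
      sprintf("(m/z %g-%g, overlap %g Da)\n", x$mz_range[1], x$mz_range[2],
              x$window_overlap))
  cat(sprintf("  noise: bio CV %g, tech CV %g, window CV %g, mass error %g ppm\n",
              x$cv_biological, x$cv_technical, x$cv_window, x$ppm_sd))
  cat(sprintf("  detection limit %g | seed %d\n", x$detection_limit,
              as.integer(x$seed)))
  invisible(x)
}
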