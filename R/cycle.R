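#' Exposure position of a probe target in the nascent RNA
#'
#' The target becomes available for hybridization once the polymerase active
#' site passes the target 3' end plus the nascent-RNA footprint of the
#' polymerase.
#'
#' @param target_end Target 3'-end position in the transcript, nt.
#' @param footprint Protected nascent-RNA length, nt (default 14).
#' @return Exposure position, nt.
#' @examples
#' exposure_position(46)    # 60
#' exposure_position(199)   # 213
#' @export
exposure_position <- function(target_end, footprint = 14L) {
  stopifnot(target_end > 0, footprint >= 0)
  target_end + footprint
}

#' Time to elongate between two template positions
#'
#' @param from_pos,to_pos Template positions, nt (`to_pos >= from_pos`).
#' @param rate Elongation rate, nt/s (> 0).
#' @return Elongation time, s.
#' @examples
#' elongation_time(13, 60, 300)   # ~0.16 s
#' @export
elongation_time <- function(from_pos, to_pos, rate) {
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  stopifnot(to_pos >= from_pos)
  (to_pos - from_pos) / rate
}

#' Mean hybridization time at a probe concentration
#'
#' `T_hybridization = 1 / (k_on * conc)`; the inverse of [on_rate()].
#'
#' @param k_on On-rate, /M/s (> 0).
#' @param conc Probe concentration, M (> 0).
#' @return Mean waiting time, s.
#' @examples
#' hybridization_time(6e6, 500e-9)  # ~0.33 s
#' @export
hybridization_time <- function(k_on, conc) {
  if (!is.finite(k_on) || k_on <= 0) stop("k_on must be > 0")
  if (!is.finite(conc) || conc <= 0) stop("conc must be > 0")
  1 / (k_on * conc)
}

#' Net abortive-cycling time from the probe binding delay
#'
#' `T_abortive = delta_T_on - (T_elongation + T_hybridization)`: the probe
#' binding delay minus the elongation time to the exposure position and the
#' mean hybridization wait (promoter opening being negligible). A negative
#' result is returned as-is with a model-inconsistency warning, so
#' propagated uncertainty stays visible.
#'
#' @param delta_t_on Probe binding delay, s.
#' @param t_elong Elongation time to the exposure position, s.
#' @param t_hyb Mean hybridization time, s.
#' @return Net abortive time, s.
#' @examples
#' abortive_time(0.7, 0.16, 0.33)  # ~0.2 s
#' @export
abortive_time <- function(delta_t_on, t_elong, t_hyb) {
  stopifnot(is.finite(delta_t_on), is.finite(t_elong), is.finite(t_hyb))
  out <- delta_t_on - (t_elong + t_hyb)
  if (out < 0)
    warning("negative abortive time (", signif(out, 3),
            " s): delay components exceed the measured delta_T_on")
  out
}

#' Regress peak dwell time on transcribed template length
#'
#' Ordinary least squares of the peak (productive) dwell time against
#' template length. The slope is the time per transcribed nucleotide, its
#' reciprocal the elongation rate, and the intercept the net time the
#' polymerase spends on the template without elongating (`T_stationary`).
#'
#' @param lengths Template lengths, nt (>= 2 distinct values).
#' @param dwells Peak dwell times, s.
#' @return Object of class `length_series_fit`: list with `slope` (s/nt),
#'   `intercept` (s), `rate` (nt/s), `ci` (95% t-based intervals for slope
#'   and intercept), `fit` (the `lm` object).
#' @examples
#' fit_dwell_vs_length(c(295, 633, 910), c(1.7, 2.7, 3.7))
#' @export
fit_dwell_vs_length <- function(lengths, dwells) {
  stopifnot(length(lengths) == length(dwells))
  if (length(lengths) < 2L)
    stop("need at least two (length, dwell) points")
  if (length(unique(lengths)) < 2L)
    stop("need at least two distinct template lengths")
  fit <- lm(dwell ~ len, data = data.frame(len = lengths, dwell = dwells))
  cf <- coef(fit)
  ci <- if (length(lengths) > 2L) stats::confint(fit)
        else matrix(NA_real_, 2L, 2L,
                    dimnames = list(names(cf), c("2.5 %", "97.5 %")))
  structure(list(slope = cf[["len"]], intercept = cf[["(Intercept)"]],
                 rate = 1 / cf[["len"]], ci = ci, fit = fit),
            class = "length_series_fit")
}

#' @export
print.length_series_fit <- function(x, ...) {
  cat(sprintf(paste0("<length_series_fit> slope = %.3g s/nt ",
                     "(rate %.0f nt/s), T_stationary = %.2f s\n"),
              x$slope, x$rate, x$intercept))
  invisible(x)
}

#' Assemble the transcription-cycle kinetic summary
#'
#' Combines the measured quantities into the full cycle decomposition:
#' `k_off = 1/T0` (non-productive promoter complexes), `T_abortive =
#' delta_T_on - (T_elongation + T_hybridization)` with `k_escape =
#' 1/T_abortive`, the end dwell `T_end = T_stationary - T_abortive`, and the
#' promoter-search upper bound `T_search = one frame` at the fast
#' acquisition rate. Negative derived times are kept (with warning flags)
#' rather than clamped.
#'
#' @param T0 Mean non-productive dwell, s.
#' @param delta_t_on Probe binding delay, s.
#' @param geometry List with `escape_position`, `target_window`, `footprint`
#'   (e.g. a [sim_params()] object).
#' @param rate Elongation rate, nt/s.
#' @param k_on Probe on-rate, /M/s.
#' @param conc Probe concentration, M.
#' @param t_stationary Intercept of the dwell-vs-length regression, s.
#' @param efficiency Real-time detection efficiency, fraction.
#' @param retention Post-run-off probe retention, fraction.
#' @param frame_interval Fast-acquisition frame interval, s (default 0.08).
#' @param delta_t_off Probe dissociation delay, s (default 0).
#' @return Object of class `kinetic_summary` (list of named quantities, all
#'   in s / per-s / nt-per-s; `warnings` collects inconsistency flags).
#' @export
summarize_cycle <- function(T0, delta_t_on, geometry, rate, k_on, conc,
                            t_stationary, efficiency = NA_real_,
                            retention = NA_real_, frame_interval = 0.08,
                            delta_t_off = 0) {
  expo <- exposure_position(geometry$target_window[2L], geometry$footprint)
  t_elong <- elongation_time(geometry$escape_position, expo, rate)
  t_hyb <- hybridization_time(k_on, conc)
  warnings <- character(0)
  t_abortive <- withCallingHandlers(
    abortive_time(delta_t_on, t_elong, t_hyb),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  t_end <- t_stationary - t_abortive
  if (t_end < 0)
    warnings <- c(warnings, "negative end dwell: T_abortive > T_stationary")
  structure(list(
    T_search_bound = frame_interval,
    T0 = T0, k_off = 1 / T0,
    delta_t_on = delta_t_on, delta_t_off = delta_t_off,
    t_elongation = t_elong, t_hybridization = t_hyb,
    T_abortive = t_abortive,
    k_escape = if (t_abortive > 0) 1 / t_abortive else NA_real_,
    elongation_rate = rate,
    T_stationary = t_stationary,
    T_end = t_end,
    exposure_position = expo,
    detection_efficiency = efficiency,
    retention_fraction = retention,
    warnings = warnings
  ), class = "kinetic_summary")
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat("<kinetic_summary> transcription-cycle decomposition\n")
  cat(sprintf("  T_search upper bound : %.3g s\n", x$T_search_bound))
  cat(sprintf("  T_0 / k_off          : %.3g s / %.3g /s\n", x$T0, x$k_off))
  cat(sprintf("  delta_T_on           : %.3g s\n", x$delta_t_on))
  cat(sprintf("  T_elongation (to +%d): %.3g s\n",
              x$exposure_position, x$t_elongation))
  cat(sprintf("  T_hybridization      : %.3g s\n", x$t_hybridization))
  cat(sprintf("  T_abortive / k_escape: %.3g s / %.3g /s\n",
              x$T_abortive, x$k_escape))
  cat(sprintf("  elongation rate      : %.3g nt/s\n", x$elongation_rate))
  cat(sprintf("  T_stationary / T_end : %.3g s / %.3g s\n",
              x$T_stationary, x$T_end))
  if (is.finite(x$detection_efficiency))
    cat(sprintf("  detection efficiency : %.1f%%\n",
                100 * x$detection_efficiency))
  if (is.finite(x$retention_fraction))
    cat(sprintf("  probe retention      : %.1f%%\n",
                100 * x$retention_fraction))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write a kinetic summary as JSON
#'
#' @param summary A [summarize_cycle()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kinetic_summary <- function(summary, path) {
  stopifnot(inherits(summary, "kinetic_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
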