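#' Simulation parameters for the single-molecule transcription assay
#'
#' Generative kinetic, optical and noise parameters for the forward simulator.
#' Kinetic defaults follow the measured summary of the T7 RNAP cycle:
#' non-productive promoter complexes dissociate after an exponential dwell
#' (`T0_mean`, 0.14 s with NTPs / ~0.3 s without), productive cycles escape
#' the promoter at `k_escape` (5 /s, active site at about +13 at escape),
#' elongate by per-nucleotide exponential steps at `v_elong` (300 nt/s) to the
#' template end, idle there for an exponential end dwell (0.5 s) and then run
#' off. The probe target (default window +28..+46) becomes available for
#' hybridization once the active site passes the target 3' end plus the ~14-nt
#' nascent-RNA footprint of the polymerase; probe arrival is exponential at
#' `k_on_probe * probe_conc`, suppressed for the `dark_fraction` of probes
#' carrying a non-emitting fluorophore, and the probe is retained on the DNA
#' after run-off with probability `p_retain` for an extra exponential dwell.
#'
#' Optical defaults: symmetric Gaussian PSF of `psf_sigma` pixels at 200
#' nm/pixel, RNAP fluorescence attenuated as the polymerase climbs the
#' tethered template out of the evanescent field (`rise_per_bp` nm of height
#' per transcribed bp, decay length `evanescent_decay` nm), frame integration
#' at `frame_rate` (2.5 Hz conventional / 12.5 Hz fast acquisition), additive
#' Gaussian camera noise, exponential photobleaching lifetimes long enough
#' not to truncate events.
#'
#' @param k_on_probe Probe on-rate, /M/s (default 6e6).
#' @param probe_conc Probe concentration, M (default 500e-9).
#' @param rnap_arrival_rate RNAP arrival rate per locus, /s (default 0.02).
#' @param p_productive Fraction of arrivals that are productive cycles
#'   (default 0.5).
#' @param T0_mean Mean non-productive dwell, s (default 0.14).
#' @param k_escape Promoter-escape rate, /s (default 5).
#' @param escape_position Active-site position at escape, nt (default 13).
#' @param v_elong Mean elongation rate, nt/s (default 300).
#' @param template_length Transcribed template length, nt (default 295).
#' @param target_window `(start, end)` of the probe target in the transcript,
#'   nt (default `c(28, 46)`).
#' @param footprint Nascent-RNA nucleotides occluded by the polymerase,
#'   nt (default 14).
#' @param end_dwell_mean Mean dwell at the template end before run-off, s
#'   (default 0.5).
#' @param dark_fraction Fraction of probes with a dark fluorophore
#'   (default 0.19).
#' @param p_retain Probability the probe stays on the DNA after run-off
#'   (default 0.28).
#' @param retain_dwell_mean Mean extra probe dwell after run-off, s
#'   (default 5).
#' @param photobleach_lifetimes Named pair `c(rnap=, probe=)` of mean
#'   photobleaching lifetimes, s (default 500 each).
#' @param frame_rate Acquisition rate, Hz (default 2.5).
#' @param psf_sigma PSF standard deviation, px (default 1.0).
#' @param pixel_size Pixel size, nm (default 200).
#' @param evanescent_decay Evanescent-field decay length, nm (default 100).
#' @param rise_per_bp Height gained per transcribed bp, nm (default 0.34).
#' @param amplitude Named pair of per-channel fluorophore amplitudes
#'   (default 1 each, camera units).
#' @param background Constant image background (default 0).
#' @param noise_sd Additive Gaussian noise sd, camera units (default 0.05).
#' @param field_size `(height, width)` of the imaged field, px
#'   (default `c(32, 32)`).
#' @param min_separation Minimum distance between loci, px (default 4,
#'   about 4 PSF sigmas: the locus-mapping step only keeps diffraction-
#'   resolvable molecules).
#' @param n_loci Number of surface-tethered template loci (default 25).
#' @param duration Acquisition duration, s (default 300).
#' @param pause_rate Optional long-pause rate per transcribed nt, /nt
#'   (default 0 = off).
#' @param pause_mean Mean long-pause duration, s (default 1).
#' @param seed Optional integer seed.
#' @return Object of class `sim_params` (a validated list).
#' @export
sim_params <- function(k_on_probe = 6e6,
                       probe_conc = 500e-9,
                       rnap_arrival_rate = 0.02,
                       p_productive = 0.5,
                       T0_mean = 0.14,
                       k_escape = 5,
                       escape_position = 13L,
                       v_elong = 300,
                       template_length = 295L,
                       target_window = c(28L, 46L),
                       footprint = 14L,
                       end_dwell_mean = 0.5,
                       dark_fraction = 0.19,
                       p_retain = 0.28,
                       retain_dwell_mean = 5,
                       photobleach_lifetimes = c(rnap = 500, probe = 500),
                       frame_rate = 2.5,
                       psf_sigma = 1.0,
                       pixel_size = 200,
                       evanescent_decay = 100,
                       rise_per_bp = 0.34,
                       amplitude = c(rnap = 1, probe = 1),
                       background = 0,
                       noise_sd = 0.05,
                       field_size = c(32L, 32L),
                       min_separation = 4,
                       n_loci = 25L,
                       duration = 300,
                       pause_rate = 0,
                       pause_mean = 1,
                       seed = NULL) {
  p <- list(k_on_probe = k_on_probe, probe_conc = probe_conc,
            rnap_arrival_rate = rnap_arrival_rate,
            p_productive = p_productive, T0_mean = T0_mean,
            k_escape = k_escape,
            escape_position = as.integer(escape_position),
            v_elong = v_elong,
            template_length = as.integer(template_length),
            target_window = as.integer(target_window),
            footprint = as.integer(footprint),
            end_dwell_mean = end_dwell_mean,
            dark_fraction = dark_fraction, p_retain = p_retain,
            retain_dwell_mean = retain_dwell_mean,
            photobleach_lifetimes = photobleach_lifetimes,
            frame_rate = frame_rate, psf_sigma = psf_sigma,
            pixel_size = pixel_size, evanescent_decay = evanescent_decay,
            rise_per_bp = rise_per_bp, amplitude = amplitude,
            background = background, noise_sd = noise_sd,
            field_size = as.integer(field_size),
            min_separation = min_separation,
            n_loci = as.integer(n_loci), duration = duration,
            pause_rate = pause_rate, pause_mean = pause_mean, seed = seed)

  rates <- c(k_on_probe = p$k_on_probe, probe_conc = p$probe_conc,
             T0_mean = p$T0_mean, k_escape = p$k_escape,
             v_elong = p$v_elong, frame_rate = p$frame_rate)
  if (any(rates <= 0))
    stop("rates and times must be > 0: ",
         paste(names(rates)[rates <= 0], collapse = ", "))
  fracs <- c(p_productive = p$p_productive, dark_fraction = p$dark_fraction,
             p_retain = p$p_retain)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  stopifnot(p$rnap_arrival_rate >= 0, p$end_dwell_mean >= 0,
            p$noise_sd >= 0, p$duration > 0, p$n_loci >= 1L,
            length(p$target_window) == 2L,
            p$target_window[1L] <= p$target_window[2L],
            p$footprint >= 0L, p$pause_rate >= 0)
  if (p$target_window[2L] + p$footprint > p$template_length)
    stop("target_window end + footprint must not exceed template_length")
  if (p$escape_position >= p$target_window[2L] + p$footprint)
    stop("escape_position must lie before the exposure position ",
         "(target end + footprint)")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_params> template %d nt, target +%d..+%d (+%d exposure), ",
    "k_escape %.3g /s, v %.3g nt/s, k_on %.2g /M/s at %.3g nM, ",
    "%d loci x %.0f s at %.3g Hz\n"),
    x$template_length, x$target_window[1L], x$target_window[2L],
    exposure_position(x$target_window[2L], x$footprint),
    x$k_escape, x$v_elong, x$k_on_probe, x$probe_conc * 1e9,
    x$n_loci, x$duration, x$frame_rate))
  invisible(x)
}
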