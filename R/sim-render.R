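# Add to `row` (per-frame intensities) the exact frame-averaged contribution
# of intensity amp * exp(-c * (pos0 + slope*(t - t0))) over [a, b].
# c = rise_per_bp / evanescent_decay per nt; slope in nt/s. c*slope == 0
# reduces to a constant-intensity interval.
add_interval_ <- function(row, a, b, dt, amp, c = 0, pos0 = 0, slope = 0,
                          t0 = a) {
  n <- length(row)
  if (b <= a || a >= n * dt || b <= 0) return(row)
  a <- max(a, 0); b <- min(b, n * dt)
  k1 <- floor(a / dt) + 1L
  k2 <- min(ceiling(b / dt), n)
  if (k2 < k1) return(row)
  ks <- k1:k2
  u <- pmax(a, (ks - 1) * dt)
  v <- pmin(b, ks * dt)
  cs <- c * slope
  contrib <- if (cs == 0) {
    amp * exp(-c * pos0) * (v - u) / dt
  } else {
    amp * exp(-c * (pos0 - slope * t0)) *
      (exp(-cs * u) - exp(-cs * v)) / (cs * dt)
  }
  row[ks] <- row[ks] + contrib
  row
}

#' Render per-locus fluorescence traces from ground-truth events
#'
#' Converts the event schedule into two-channel intensity time series at the
#' camera frame interval. Per-frame intensity is the fluorophore occupancy
#' integrated over the frame (a 0.08 s event in a 0.4 s frame contributes 20%
#' amplitude). The RNAP channel is attenuated by
#' `exp(-(position_nt * rise_per_bp) / evanescent_decay)` as the polymerase
#' elongates away from the surface (position 0 at the promoter, then linear
#' from `escape_position` to the template end between escape and arrival at
#' the end); the probe channel has constant amplitude from arrival to
#' release. Each fluorophore photobleaches after an exponential lifetime
#' counted from its first appearance. Optional additive Gaussian noise.
#'
#' @param field A [simulate_field()] result.
#' @param noise_sd Camera noise sd (default `params$noise_sd`); use 0 for
#'   ideal traces, e.g. as input to [render_movie()].
#' @param seed Seed for bleaching and noise draws; defaults to
#'   `params$seed + 1000003` when the field has a seed, so the full pipeline
#'   is reproducible.
#' @return Object of class `trace_set`: numeric array
#'   `[n_loci, n_frames, channel]` with channels `"rnap"` and `"probe"`,
#'   with attributes `frame_rate`, `times` (frame-center timestamps, s) and
#'   `loci`.
#' @export
render_traces <- function(field, noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(field, "sim_field"))
  p <- field$params
  noise_sd <- noise_sd %||% p$noise_sd
  if (is.null(seed) && !is.null(p$seed)) seed <- p$seed + 1000003
  n_frames <- floor(p$duration * p$frame_rate)
  dt <- 1 / p$frame_rate
  ev <- field$events
  cc <- p$rise_per_bp / p$evanescent_decay  # attenuation per transcribed nt

  with_seed(seed, {
    tr <- array(0, dim = c(nrow(field$loci), n_frames, 2L),
                dimnames = list(NULL, NULL, c("rnap", "probe")))
    for (i in seq_len(nrow(ev))) {
      li <- match(ev$locus_id[i], field$loci$locus_id)
      bleach_r <- rexp(1L, 1 / p$photobleach_lifetimes[["rnap"]])
      amp_r <- p$amplitude[["rnap"]]
      t0 <- ev$t_bind[i]
      end_r <- min(ev$t_runoff[i], t0 + bleach_r)
      row <- tr[li, , "rnap"]
      if (ev$kind[i] == "nonproductive") {
        row <- add_interval_(row, t0, end_r, dt, amp_r)
      } else {
        esc <- ev$t_escape[i]; tend <- ev$t_end_reached[i]
        slope <- if (tend > esc)
          (p$template_length - p$escape_position) / (tend - esc) else 0
        row <- add_interval_(row, t0, min(esc, end_r), dt, amp_r)
        if (end_r > esc)
          row <- add_interval_(row, esc, min(tend, end_r), dt, amp_r,
                               c = cc, pos0 = p$escape_position,
                               slope = slope, t0 = esc)
        if (end_r > tend)
          row <- add_interval_(row, tend, end_r, dt, amp_r,
                               c = cc, pos0 = p$template_length)
      }
      tr[li, , "rnap"] <- row

      if (isTRUE(ev$detected[i])) {
        bleach_p <- rexp(1L, 1 / p$photobleach_lifetimes[["probe"]])
        a <- ev$t_probe_arrival[i]
        b <- min(ev$t_probe_release[i], a + bleach_p)
        tr[li, , "probe"] <-
          add_interval_(tr[li, , "probe"], a, b, dt, p$amplitude[["probe"]])
      }
    }
    if (noise_sd > 0)
      tr <- tr + array(rnorm(length(tr), sd = noise_sd), dim = dim(tr))
    structure(tr, class = "trace_set", frame_rate = p$frame_rate,
              times = (seq_len(n_frames) - 0.5) * dt, loci = field$loci)
  })
}

#' Render a two-channel image stack from traces
#'
#' Each emitting locus contributes a symmetric 2D Gaussian PSF (sd
#' `psf_sigma` px, normalized to unit sum so flux is conserved: the total
#' injected signal per frame equals the sum of the trace values), plus a
#' constant background and additive Gaussian camera noise.
#'
#' @param field A [simulate_field()] result.
#' @param traces A [render_traces()] result; render with `noise_sd = 0` so
#'   noise is added once, at the camera. Defaults to doing exactly that.
#' @param noise_sd Camera noise sd (default `params$noise_sd`).
#' @param background Constant offset (default `params$background`).
#' @param seed Seed for the noise; defaults to `params$seed + 2000003` when
#'   the field has a seed.
#' @return Object of class `image_stack`: list with `rnap` and `probe`
#'   arrays `[height, width, n_frames]`, plus `loci`, `frame_rate`,
#'   `background`.
#' @export
render_movie <- function(field, traces = render_traces(field, noise_sd = 0),
                         noise_sd = NULL, background = NULL, seed = NULL) {
  stopifnot(inherits(field, "sim_field"), inherits(traces, "trace_set"))
  p <- field$params
  noise_sd <- noise_sd %||% p$noise_sd
  background <- background %||% p$background
  if (is.null(seed) && !is.null(p$seed)) seed <- p$seed + 2000003
  H <- p$field_size[1L]; W <- p$field_size[2L]
  n_frames <- dim(traces)[2L]

  # pixel-center coordinates: pixel (row r, col c) is centered at x=c, y=r
  psf <- vapply(seq_len(nrow(field$loci)), function(l) {
    gx <- exp(-((seq_len(W) - field$loci$x[l])^2) / (2 * p$psf_sigma^2))
    gy <- exp(-((seq_len(H) - field$loci$y[l])^2) / (2 * p$psf_sigma^2))
    m <- outer(gy, gx)
    as.vector(m / sum(m))
  }, numeric(H * W))

  with_seed(seed, {
    out <- list()
    for (ch in c("rnap", "probe")) {
      mat <- psf %*% matrix(unclass(traces)[, , ch],
                            nrow = dim(traces)[1L]) + background
      if (noise_sd > 0)
        mat <- mat + matrix(rnorm(length(mat), sd = noise_sd), nrow = H * W)
      out[[ch]] <- array(mat, dim = c(H, W, n_frames))
    }
    structure(list(rnap = out$rnap, probe = out$probe, loci = field$loci,
                   frame_rate = p$frame_rate, background = background),
              class = "image_stack")
  })
}

#' Write an image stack to multi-page TIFF (one file per channel)
#'
#' Requires the suggested `tiff` package.
#'
#' @param stack An [render_movie()] result.
#' @param prefix Output path prefix; files `<prefix>_rnap.tif` and
#'   `<prefix>_probe.tif` are written as 32-bit float TIFF with intensities
#'   clamped to the writer's \[0, 1\] range (single-fluorophore amplitudes
#'   are 1 by default, so only noise excursions are clipped).
#' @return The two file paths, invisibly.
#' @export
write_stack_tiff <- function(stack, prefix) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF stacks")
  paths <- character(0)
  for (ch in c("rnap", "probe")) {
    a <- pmin(pmax(stack[[ch]], 0), 1)
    pages <- lapply(seq_len(dim(a)[3L]), function(f) a[, , f])
    path <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
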