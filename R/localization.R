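# Separable Gaussian smoothing with edge renormalization. `frame` is a
# matrix [rows = y, cols = x].
smooth_gaussian_ <- function(frame, sigma = 1) {
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
      wt[ok] <- wt[ok] + k[j]
    }
    out / wt
  }
  t(conv1(t(conv1(frame))))
}

#' Detect candidate spots in a single frame
#'
#' Local maxima of a lightly smoothed image exceeding
#' `median + min_snr * robust sd` (MAD-based), with non-maximum suppression
#' within one PSF radius so each diffraction-limited spot yields one peak.
#'
#' @param frame Numeric matrix (rows = y, cols = x; pixel centers at integer
#'   coordinates).
#' @param min_snr Detection threshold in robust noise sds (default 5).
#' @param psf_sigma Expected PSF sd in px; sets the smoothing kernel and the
#'   suppression radius (default 1).
#' @return Data frame `x`, `y` (integer pixel coordinates), `value`
#'   (smoothed intensity); zero rows when nothing exceeds the threshold.
#' @export
detect_spots <- function(frame, min_snr = 5, psf_sigma = 1) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  sm <- smooth_gaussian_(frame, sigma = psf_sigma / sqrt(2))
  noise <- mad(sm)
  thr <- median(sm) + min_snr * noise
  if (noise == 0) thr <- median(sm) + .Machine$double.eps

  H <- nrow(sm); W <- ncol(sm)
  if (H < 3L || W < 3L) return(data.frame(x = integer(0), y = integer(0),
                                          value = numeric(0)))
  core <- sm[2:(H - 1), 2:(W - 1)]
  ismax <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismax <- ismax & core >= sm[2:(H - 1) + dy, 2:(W - 1) + dx]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(x = integer(0), y = integer(0),
                                    value = numeric(0)))
  peaks <- data.frame(x = idx[, 2L] + 1L, y = idx[, 1L] + 1L,
                      value = core[idx])
  peaks <- peaks[order(-peaks$value), , drop = FALSE]

  # greedy non-maximum suppression within one PSF radius
  rad2 <- max(1, psf_sigma)^2
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      j <- (i + 1L):nrow(peaks)
      d2 <- (peaks$x[j] - peaks$x[i])^2 + (peaks$y[j] - peaks$y[i])^2
      keep[j][d2 <= rad2] <- FALSE
    }
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a symmetric 2D Gaussian to a square ROI
#'
#' Nonlinear least squares of `offset + A * exp(-((x-x0)^2+(y-y0)^2) /
#' (2 sigma^2))` to the pixel values of a (typically 5x5) patch, giving a
#' subpixel spot center.
#'
#' @param roi Square numeric matrix with odd side length.
#' @param sigma_init Initial PSF sd, px (default 1).
#' @return List: `x`, `y` (center in ROI coordinates, 1..side), `dx`, `dy`
#'   (offset from the ROI center pixel), `amplitude`, `offset`, `sigma`,
#'   `rss`, `accepted` (FALSE for non-convergence or amplitude <= 0).
#' @export
fit_gaussian_2d <- function(roi, sigma_init = 1) {
  stopifnot(is.matrix(roi), nrow(roi) == ncol(roi), nrow(roi) %% 2L == 1L,
            all(is.finite(roi)))
  side <- nrow(roi)
  ctr <- (side + 1) / 2
  # as.vector(roi) is column-major: row (= y) varies fastest
  d <- data.frame(x = rep(seq_len(side), each = side),
                  y = rep(seq_len(side), times = side),
                  z = as.vector(roi))
  off0 <- min(d$z)
  a0 <- max(d$z) - off0
  rej <- list(x = NA_real_, y = NA_real_, dx = NA_real_, dy = NA_real_,
              amplitude = NA_real_, offset = NA_real_, sigma = NA_real_,
              rss = NA_real_, accepted = FALSE)
  if (a0 <= 0) return(rej)
  w <- pmax(d$z - off0, 0)
  x0 <- sum(w * d$x) / sum(w)
  y0 <- sum(w * d$y) / sum(w)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ off + A * exp(-((x - mx)^2 + (y - my)^2) / (2 * s^2)),
      data = d,
      start = list(off = off0, A = a0, mx = x0, my = y0, s = sigma_init),
      lower = c(-Inf, 0, 1 - 1, 1 - 1, 0.3),
      upper = c(Inf, Inf, side + 1, side + 1, side),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(rej)
  cf <- coef(fit)
  if (cf[["A"]] <= 0 || !is.finite(cf[["A"]])) return(rej)
  list(x = cf[["mx"]], y = cf[["my"]],
       dx = cf[["mx"]] - ctr, dy = cf[["my"]] - ctr,
       amplitude = cf[["A"]], offset = cf[["off"]], sigma = cf[["s"]],
       rss = sum(residuals(fit)^2), accepted = TRUE)
}

#' Detect and subpixel-localize spots in a frame
#'
#' [detect_spots()] followed by a 5x5 [fit_gaussian_2d()] around each peak;
#' peaks too close to the frame edge for a full ROI are skipped.
#'
#' @inheritParams detect_spots
#' @param roi_halfwidth Half-width of the fit ROI (default 2, i.e. 5x5).
#' @return Data frame `x`, `y` (subpixel), `amplitude`, `offset`, `sigma`,
#'   `rss`; only accepted fits are returned.
#' @export
locate_spots <- function(frame, min_snr = 5, psf_sigma = 1,
                         roi_halfwidth = 2L) {
  peaks <- detect_spots(frame, min_snr = min_snr, psf_sigma = psf_sigma)
  hw <- as.integer(roi_halfwidth)
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    px <- peaks$x[i]; py <- peaks$y[i]
    if (px - hw < 1L || px + hw > ncol(frame) ||
        py - hw < 1L || py + hw > nrow(frame)) return(NULL)
    roi <- frame[(py - hw):(py + hw), (px - hw):(px + hw)]
    f <- fit_gaussian_2d(roi, sigma_init = psf_sigma)
    if (!f$accepted) return(NULL)
    data.frame(x = px + f$dx, y = py + f$dy, amplitude = f$amplitude,
               offset = f$offset, sigma = f$sigma, rss = f$rss)
  })
  res <- res[!vapply(res, is.null, logical(1L))]
  if (!length(res))
    return(data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      offset = numeric(0), sigma = numeric(0),
                      rss = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Localize spots in every frame of a stack channel
#'
#' @param stack_channel 3D array `[height, width, frames]` (one channel of an
#'   [render_movie()] stack).
#' @param ... Passed to [locate_spots()].
#' @return Data frame with a `frame` column plus the [locate_spots()]
#'   columns.
#' @export
localize_stack <- function(stack_channel, ...) {
  stopifnot(length(dim(stack_channel)) == 3L)
  res <- lapply(seq_len(dim(stack_channel)[3L]), function(f) {
    s <- locate_spots(stack_channel[, , f], ...)
    if (nrow(s)) cbind(frame = f, s) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1L))]
  if (!length(res))
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      amplitude = numeric(0), offset = numeric(0),
                      sigma = numeric(0), rss = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cluster localizations into molecule positions ("blobs")
#'
#' Bins localizations into 1-px bins; occupied bins joined by 8-connectivity
#' form clusters, and each blob position is the centroid of its member
#' localizations.
#'
#' @param localizations Data frame with `x`, `y` (subpixel), optionally
#'   `frame`.
#' @return Data frame `blob`, `x`, `y` (centroids), `n` (member count),
#'   `n_frames` (distinct frames present, when `frame` is available).
#' @export
cluster_blobs <- function(localizations) {
  stopifnot(is.data.frame(localizations), nrow(localizations) >= 1L,
            all(c("x", "y") %in% names(localizations)))
  bx <- round(localizations$x)
  by <- round(localizations$y)
  key <- paste(bx, by)
  bins <- unique(data.frame(bx = bx, by = by, key = key,
                            stringsAsFactors = FALSE))
  lab <- rep(NA_integer_, nrow(bins))
  nb_off <- expand.grid(dx = -1:1, dy = -1:1)
  nxt <- 0L
  for (i in seq_len(nrow(bins))) {
    if (!is.na(lab[i])) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      nb_keys <- paste(bins$bx[cur] + nb_off$dx, bins$by[cur] + nb_off$dy)
      hits <- match(nb_keys, bins$key)
      hits <- hits[!is.na(hits)]
      new <- hits[is.na(lab[hits])]
      lab[new] <- nxt
      queue <- c(queue, new)
    }
  }
  blob_of_loc <- lab[match(key, bins$key)]
  out <- do.call(rbind, lapply(seq_len(nxt), function(b) {
    sel <- blob_of_loc == b
    data.frame(blob = b,
               x = mean(localizations$x[sel]),
               y = mean(localizations$y[sel]),
               n = sum(sel),
               n_frames = if ("frame" %in% names(localizations))
                 length(unique(localizations$frame[sel])) else NA_integer_)
  }))
  rownames(out) <- NULL
  out
}

#' Extract a background-subtracted intensity trace at a locus
#'
#' Per frame, the mean of an inner `roi_size x roi_size` region of interest
#' centered on the locus, minus the mean of the one-pixel perimeter ring
#' around it.
#'
#' @param stack_channel 3D array `[height, width, frames]`.
#' @param x,y Locus position, px (rounded to the nearest pixel center).
#' @param roi_size Inner ROI side, 3 or 5 (default 5).
#' @return Numeric vector of per-frame background-subtracted intensities.
#' @export
extract_trace <- function(stack_channel, x, y, roi_size = 5L) {
  stopifnot(length(dim(stack_channel)) == 3L, roi_size %in% c(3L, 5L))
  hw <- (as.integer(roi_size) - 1L) %/% 2L
  cx <- round(x); cy <- round(y)
  H <- dim(stack_channel)[1L]; W <- dim(stack_channel)[2L]
  if (cx - hw - 1L < 1L || cx + hw + 1L > W ||
      cy - hw - 1L < 1L || cy + hw + 1L > H)
    stop("locus too close to the frame edge for a ", roi_size,
         "x", roi_size, " ROI with perimeter ring")
  rows_o <- (cy - hw - 1L):(cy + hw + 1L)
  cols_o <- (cx - hw - 1L):(cx + hw + 1L)
  outer_box <- stack_channel[rows_o, cols_o, , drop = FALSE]
  inner_idx_r <- 2:(length(rows_o) - 1L)
  inner <- outer_box[inner_idx_r, inner_idx_r, , drop = FALSE]
  n_out <- length(rows_o)^2
  n_in <- roi_size^2
  inner_mean <- apply(inner, 3L, mean)
  ring_mean <- (apply(outer_box, 3L, sum) - apply(inner, 3L, sum)) /
    (n_out - n_in)
  inner_mean - ring_mean
}
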