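#' Nearest-neighbor co-localization offsets between two blob sets
#'
#' For every reference blob the closest query blob (Euclidean distance) is
#' found and the deviations `dx = query_x - ref_x`, `dy = query_y - ref_y`
#' recorded; the offsets are binned into a 2D histogram (the co-localization
#' plot), whose central peak at (0, 0) indicates true molecular coincidence.
#'
#' @param reference,query Data frames with `x`, `y` columns (e.g.
#'   [cluster_blobs()] output); assignment is one-directional,
#'   reference -> query.
#' @param bin_width Histogram bin width, px (default 0.2).
#' @param range Histogram half-range, px (default 4).
#' @return Object of class `coloc_plot`: list with `offsets` (data frame
#'   `ref`, `dx`, `dy`, `dist`), `hist` (`x_mids`, `y_mids`, `counts`
#'   matrix), `bin_width`.
#' @export
colocalization_offsets <- function(reference, query, bin_width = 0.2,
                                   range = 4) {
  stopifnot(is.data.frame(reference), nrow(reference) >= 1L)
  if (!is.data.frame(query) || nrow(query) < 1L)
    stop("query blob set is empty")
  d2 <- outer(reference$x, query$x, "-")^2 + outer(reference$y, query$y, "-")^2
  nn <- max.col(-d2, ties.method = "first")
  dx <- query$x[nn] - reference$x
  dy <- query$y[nn] - reference$y
  offsets <- data.frame(ref = seq_len(nrow(reference)), dx = dx, dy = dy,
                        dist = sqrt(d2[cbind(seq_along(nn), nn)]))
  edges <- seq(-range, range, by = bin_width)
  mids <- head(edges, -1L) + bin_width / 2
  ix <- findInterval(dx, edges, rightmost.closed = TRUE)
  iy <- findInterval(dy, edges, rightmost.closed = TRUE)
  counts <- matrix(0L, nrow = length(mids), ncol = length(mids))
  ok <- ix >= 1L & ix <= length(mids) & iy >= 1L & iy <= length(mids)
  for (i in which(ok)) counts[iy[i], ix[i]] <- counts[iy[i], ix[i]] + 1L
  structure(list(offsets = offsets,
                 hist = list(x_mids = mids, y_mids = mids, counts = counts),
                 bin_width = bin_width),
            class = "coloc_plot")
}

#' Select active reference loci from a co-localization plot
#'
#' Fits a symmetric 2D Gaussian to the co-localization histogram to estimate
#' the width sigma of the central (0, 0) peak, then selects references whose
#' offset magnitude is at most `radius_sd * sigma` (about 40 nm at the
#' default 2 sd and 200 nm/px scale).
#'
#' @param coloc A [colocalization_offsets()] result.
#' @param radius_sd Selection radius in peak sds (default 2).
#' @return List: `active` (integer indices into the reference set), `sigma`
#'   (px), `radius` (px), `fit` (the histogram Gaussian fit).
#' @export
select_active <- function(coloc, radius_sd = 2) {
  stopifnot(inherits(coloc, "coloc_plot"), radius_sd >= 0)
  counts <- coloc$hist$counts
  peak <- max(counts)
  bg <- median(counts)
  if (peak <= 3 * max(bg, 1))
    stop("no discernible central peak in the co-localization plot; ",
         "compare against a randomized control to verify specificity")
  # fit on a square window around the peak bin
  pk <- which(counts == peak, arr.ind = TRUE)[1L, ]
  hw <- min(7L, nrow(counts) %/% 2L)
  rows <- max(1L, pk[1L] - hw):min(nrow(counts), pk[1L] + hw)
  cols <- max(1L, pk[2L] - hw):min(ncol(counts), pk[2L] + hw)
  side <- min(length(rows), length(cols))
  if (side %% 2L == 0L) side <- side - 1L
  rows <- rows[seq_len(side)]; cols <- cols[seq_len(side)]
  f <- fit_gaussian_2d(counts[rows, cols] * 1.0, sigma_init = 1)
  if (!f$accepted)
    stop("central-peak fit failed; compare against a randomized control")
  sigma_px <- f$sigma * coloc$bin_width
  radius <- radius_sd * sigma_px
  r <- sqrt(coloc$offsets$dx^2 + coloc$offsets$dy^2)
  list(active = coloc$offsets$ref[r <= radius],
       sigma = sigma_px, radius = radius, fit = f)
}

#' Active-locus call from per-frame co-localization flags
#'
#' A locus is "active" if it co-localized with a spot in at least
#' `min_frames` cumulative (not necessarily consecutive) frames.
#'
#' @param flags Logical vector, one flag per frame.
#' @param min_frames Cumulative-frame threshold (default 5).
#' @return Logical scalar.
#' @export
active_by_frames <- function(flags, min_frames = 5L) {
  stopifnot(is.logical(flags))
  sum(flags, na.rm = TRUE) >= min_frames
}
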