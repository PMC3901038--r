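#' Call binding events from an intensity trace
#'
#' Threshold event calling with hysteresis: an event starts when the
#' intensity exceeds `baseline + enter_k * sigma` and ends when it falls
#' below `baseline + exit_k * sigma` (`enter_k > exit_k`). Baseline and
#' noise sigma are estimated robustly (median / MAD) in two passes: a first
#' pass over the whole trace, then a re-estimate excluding frames more than
#' 3 sigma above baseline, so bright bound intervals do not inflate the
#' noise estimate. The trace is assumed to be mostly unbound. Events
#' touching the first or last frame
#' are flagged censored. After an event is triggered its onset is refined by
#' extending backward over contiguous preceding frames already above the
#' exit level (the entry threshold is deliberately conservative, so the
#' trigger can lag the true onset by a frame or two). `T_on` is the start
#' time of the first event frame and `T_off` the end time of the last, so a
#' clean synthetic step is recovered exactly.
#'
#' @param trace Numeric intensity vector (one value per frame).
#' @param frame_interval Frame duration, s.
#' @param enter_k,exit_k Entry/exit thresholds in noise sds (defaults 4, 2).
#' @param min_frames Minimum event length in frames (default 1).
#' @return Data frame `t_on`, `t_off`, `dwell` (s), `first_frame`,
#'   `last_frame`, `censored`; zero rows for an all-baseline trace.
#' @export
call_events <- function(trace, frame_interval, enter_k = 4, exit_k = 2,
                        min_frames = 1L) {
  if (!all(is.finite(trace)))
    stop("trace contains non-finite values")
  stopifnot(length(trace) >= 10L, frame_interval > 0, enter_k > exit_k)
  base <- median(trace)
  sigma <- mad(trace)
  quiet <- trace <= base + 3 * sigma
  if (sum(quiet) >= 10L) {
    base <- median(trace[quiet])
    sigma <- mad(trace[quiet])
  }
  if (sigma == 0) sigma <- .Machine$double.eps
  hi <- base + enter_k * sigma
  lo <- base + exit_k * sigma

  n <- length(trace)
  inside <- logical(n)
  state <- FALSE
  for (i in seq_len(n)) {
    state <- if (state) trace[i] >= lo else trace[i] > hi
    inside[i] <- state
  }
  if (!any(inside))
    return(data.frame(t_on = numeric(0), t_off = numeric(0),
                      dwell = numeric(0), first_frame = integer(0),
                      last_frame = integer(0), censored = logical(0)))
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_frames
  first <- starts[sel]; last <- ends[sel]
  # refine onsets: the 4-sigma trigger is conservative, so extend each event
  # backward over contiguous preceding frames already above the exit level
  prev_last <- c(0L, head(last, -1L))
  for (j in seq_along(first)) {
    while (first[j] - 1L > prev_last[j] && trace[first[j] - 1L] >= lo)
      first[j] <- first[j] - 1L
  }
  data.frame(t_on = (first - 1L) * frame_interval,
             t_off = last * frame_interval,
             dwell = (last - first + 1L) * frame_interval,
             first_frame = first, last_frame = last,
             censored = first == 1L | last == n)
}

#' Bin dwell times with the cube-root rule
#'
#' Builds a probability histogram with `N_bins = round((2 N)^(1/3))` bins,
#' the first and last bin centers placed at the minimum and maximum observed
#' dwell. The first bin can be discarded (recommended for hybridization
#' waiting times, where the buffer-exchange lag distorts the shortest waits);
#' probabilities always sum to 1 before the discard.
#'
#' @param dwells Numeric vector of dwell/waiting times (>= 2 distinct
#'   values).
#' @param discard_first Flag the first bin to be ignored by fits
#'   (default FALSE).
#' @return Object of class `dwell_histogram`: list with `mids`,
#'   `probabilities`, `counts`, `n_events`, `n_bins`, `bin_width`,
#'   `first_bin_discarded`.
#' @export
dwell_histogram <- function(dwells, discard_first = FALSE) {
  dwells <- dwells[is.finite(dwells)]
  n <- length(dwells)
  if (n < 2L || length(unique(dwells)) < 2L)
    stop("need at least two distinct dwell values to bin")
  n_bins <- max(2L, as.integer(round((2 * n)^(1 / 3))))
  lo <- min(dwells); hi <- max(dwells)
  width <- (hi - lo) / (n_bins - 1L)
  mids <- lo + (seq_len(n_bins) - 1L) * width
  edges <- c(mids - width / 2, hi + width / 2)
  ix <- findInterval(dwells, edges, rightmost.closed = TRUE)
  ix[ix < 1L] <- 1L; ix[ix > n_bins] <- n_bins
  counts <- tabulate(ix, nbins = n_bins)
  structure(list(mids = mids, edges = edges, probabilities = counts / n,
                 counts = counts, n_events = n, n_bins = n_bins,
                 bin_width = width,
                 first_bin_discarded = isTRUE(discard_first)),
            class = "dwell_histogram")
}

#' @export
print.dwell_histogram <- function(x, ...) {
  cat(sprintf("<dwell_histogram> %d events in %d bins (width %.3g s)%s\n",
              x$n_events, x$n_bins, x$bin_width,
              if (x$first_bin_discarded) ", first bin discarded" else ""))
  invisible(x)
}

# Bin centers, edges and probabilities used for fitting, honoring the
# first-bin discard. Models are fit as bin-integrated probabilities (CDF
# differences over the bin edges, lower edge clamped at 0) rather than
# densities at bin centers: the first bin is centered on the minimum
# observed dwell, so half its span holds no data and a center-density fit
# is biased for fast components.
fit_bins_ <- function(hist) {
  keep <- if (hist$first_bin_discarded) seq_along(hist$mids)[-1L]
          else seq_along(hist$mids)
  data.frame(t = hist$mids[keep],
             lo = pmax(hist$edges[keep], 0),
             hi = hist$edges[keep + 1L],
             p = hist$probabilities[keep])
}

ci95_ <- function(fit, df) {
  se <- sqrt(diag(vcov(fit)))
  est <- coef(fit)
  q <- qt(0.975, df)
  cbind(lower = est - q * se, upper = est + q * se)
}

#' Fit a single exponential to a dwell histogram
#'
#' Nonlinear least squares of an exponential decay with characteristic time
#' `T` to the bin probabilities (each bin modeled as the integral
#' `A * (exp(-lo/T) - exp(-hi/T))` over its edges, with a free amplitude),
#' returning `T` with its 95% confidence interval and the goodness of fit.
#'
#' @param hist A [dwell_histogram()].
#' @return Object of class `fit_result`: `model = "exponential"`,
#'   `T` (s), `A`, `ci` (95%), `r_squared`, `fit` (the `nls` object).
#' @export
fit_single_exponential <- function(hist) {
  stopifnot(inherits(hist, "dwell_histogram"))
  d <- fit_bins_(hist)
  if (nrow(d) < 3L)
    stop("need at least 3 usable bins to fit an exponential")
  T0 <- max(sum(d$t * d$p) / sum(d$p), hist$bin_width / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ A * (exp(-lo / T) - exp(-hi / T)), data = d,
                      start = list(A = 1, T = T0),
                      lower = c(0, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("exponential fit did not converge; residual bin probabilities: ",
           paste(signif(d$p, 3), collapse = ", ")))
  rss <- sum(residuals(fit)^2)
  tss <- sum((d$p - mean(d$p))^2)
  structure(list(model = "exponential",
                 T = coef(fit)[["T"]], A = coef(fit)[["A"]],
                 ci = ci95_(fit, nrow(d) - 2L),
                 r_squared = 1 - rss / tss,
                 fit = fit),
            class = "fit_result")
}

#' Fit an exponential + Gaussian mixture to dwell times
#'
#' Models the dwell distribution of a mixed population: short-lived
#' non-productive events (exponential, mean `T0`) plus a bell-shaped
#' productive population (Gaussian, mean `T1` = the "peak dwell time", sd
#' `sigma`), fit to the cube-root-binned histogram. The model density
#' `p(t) = w * exp(-t/T0)/T0 + (1-w) * N(t; T1, sigma)` is integrated over
#' each bin's edges when predicting the bin probabilities. Initialization
#' splits the sample into two groups by k-means.
#'
#' @param dwells Numeric vector (n >= 50).
#' @param discard_first Passed to [dwell_histogram()] (default FALSE; the
#'   first-bin discard convention applies to hybridization waits, not RNAP
#'   dwell fits).
#' @return Object of class `fit_result`: `model = "exp_gauss"`, `T0`, `T1`,
#'   `sigma`, `w` (exponential weight), `ci`, `r_squared`, `degenerate`
#'   (TRUE when the fit collapses to one component), `fit`.
#' @export
fit_exp_gauss_mixture <- function(dwells, discard_first = FALSE) {
  dwells <- dwells[is.finite(dwells)]
  if (length(dwells) < 50L)
    stop("need at least 50 events for the mixture fit")
  hist <- dwell_histogram(dwells, discard_first = discard_first)
  d <- fit_bins_(hist)
  width <- hist$bin_width

  km <- kmeans(dwells, centers = range(dwells))
  lo_cl <- which.min(km$centers)
  T0_init <- max(mean(dwells[km$cluster == lo_cl]), width / 4)
  hi <- dwells[km$cluster != lo_cl]
  T1_init <- mean(hi)
  s_init <- max(sd(hi), width / 4)
  w_init <- min(max(mean(km$cluster == lo_cl), 0.05), 0.95)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      p ~ w * (exp(-lo / T0) - exp(-hi / T0)) +
          (1 - w) * (pnorm(hi, T1, s) - pnorm(lo, T1, s)),
      data = d,
      start = list(w = w_init, T0 = T0_init, T1 = T1_init, s = s_init),
      lower = c(0, 1e-9, 1e-9, 1e-9),
      upper = c(1, Inf, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # mixture collapsed: fit each single-component model and keep the better
    exp_fit <- tryCatch(
      minpack.lm::nlsLM(p ~ exp(-lo / T0) - exp(-hi / T0), data = d,
                        start = list(T0 = T0_init), lower = 1e-9),
      error = function(e) NULL)
    gauss_fit <- tryCatch(
      minpack.lm::nlsLM(p ~ pnorm(hi, T1, s) - pnorm(lo, T1, s), data = d,
                        start = list(T1 = T1_init, s = s_init),
                        lower = c(1e-9, 1e-9)),
      error = function(e) NULL)
    rss_of <- function(f) if (is.null(f)) Inf else sum(residuals(f)^2)
    use_exp <- rss_of(exp_fit) <= rss_of(gauss_fit)
    fit <- if (use_exp) exp_fit else gauss_fit
    if (is.null(fit))
      stop("exponential+Gaussian mixture fit did not converge")
    cf <- coef(fit)
    rss <- sum(residuals(fit)^2)
    tss <- sum((d$p - mean(d$p))^2)
    return(structure(list(
      model = "exp_gauss",
      T0 = if (use_exp) cf[["T0"]] else NA_real_,
      T1 = if (use_exp) NA_real_ else cf[["T1"]],
      sigma = if (use_exp) NA_real_ else cf[["s"]],
      w = if (use_exp) 1 else 0,
      ci = ci95_(fit, nrow(d) - length(cf)),
      r_squared = 1 - rss / tss,
      degenerate = TRUE, fit = fit), class = "fit_result"))
  }
  cf <- coef(fit)
  degenerate <- cf[["w"]] <= 1e-3 || cf[["w"]] >= 1 - 1e-3 ||
    cf[["s"]] < width / 100
  rss <- sum(residuals(fit)^2)
  tss <- sum((d$p - mean(d$p))^2)
  structure(list(model = "exp_gauss",
                 T0 = cf[["T0"]], T1 = cf[["T1"]], sigma = cf[["s"]],
                 w = cf[["w"]],
                 ci = ci95_(fit, nrow(d) - 4L),
                 r_squared = 1 - rss / tss,
                 degenerate = degenerate,
                 fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$model == "exponential") {
    cat(sprintf("<fit_result> exponential: T = %.4g s (R^2 = %.3f)\n",
                x$T, x$r_squared))
  } else {
    cat(sprintf(paste0("<fit_result> exp+gauss: T0 = %.4g s, T1 = %.4g s, ",
                       "sigma = %.4g s, w = %.3f (R^2 = %.3f)%s\n"),
                x$T0, x$T1, x$sigma, x$w, x$r_squared,
                if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  }
  invisible(x)
}

#' Convert a mean waiting time to an on-rate
#'
#' `k_on = 1 / (T_wait * conc)`.
#'
#' @param T_wait Mean waiting time, s (> 0).
#' @param conc Probe concentration, M (> 0).
#' @return On-rate in /M/s.
#' @examples
#' on_rate(1 / 3, 500e-9)  # 6e6
#' @export
on_rate <- function(T_wait, conc) {
  if (!is.finite(T_wait) || T_wait <= 0) stop("T_wait must be > 0")
  if (!is.finite(conc) || conc <= 0) stop("conc must be > 0")
  1 / (T_wait * conc)
}
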