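# Vectorized core of the transcription-cycle simulator. Draws n events with
# the given binding times and kinds ("productive"/"nonproductive") under the
# current RNG state. Times are absolute (seconds from acquisition start).
simulate_cycles_ <- function(params, n, t_bind, kind) {
  p <- params
  na_n <- rep(NA_real_, n)
  out <- data.frame(kind = kind, t_bind = t_bind,
                    t_escape = na_n, t_exposure = na_n,
                    t_end_reached = na_n, t_runoff = na_n,
                    probe_dark = rep(NA, n), t_probe_arrival = na_n,
                    detected = rep(FALSE, n), retained = rep(NA, n),
                    t_probe_release = na_n,
                    stringsAsFactors = FALSE)

  np <- kind == "nonproductive"
  if (any(np))
    out$t_runoff[np] <- t_bind[np] + rexp(sum(np), rate = 1 / p$T0_mean)

  pr <- which(kind == "productive")
  if (length(pr)) {
    m <- length(pr)
    expo_pos <- p$target_window[2L] + p$footprint
    seg1 <- expo_pos - p$escape_position          # escape -> exposure, nt
    seg2 <- p$template_length - expo_pos          # exposure -> template end

    t_escape <- t_bind[pr] + rexp(m, rate = p$k_escape)
    gamma_steps <- function(len) {
      if (len == 0L) return(numeric(m))
      tt <- if (is.infinite(p$v_elong)) numeric(m)
            else rgamma(m, shape = len, rate = p$v_elong)
      if (p$pause_rate > 0) {
        npause <- rpois(m, p$pause_rate * len)
        tt <- tt + vapply(npause, function(k)
          if (k) sum(rexp(k, 1 / p$pause_mean)) else 0, numeric(1L))
      }
      tt
    }
    t_exposure <- t_escape + gamma_steps(seg1)
    t_end <- t_exposure + gamma_steps(seg2)
    end_dwell <- if (p$end_dwell_mean > 0)
      rexp(m, rate = 1 / p$end_dwell_mean) else numeric(m)
    t_runoff <- t_end + end_dwell

    dark <- rbinom(m, 1L, p$dark_fraction) == 1L
    wait <- rexp(m, rate = p$k_on_probe * p$probe_conc)
    t_arr <- ifelse(dark, NA_real_, t_exposure + wait)
    detected <- !dark & t_arr <= t_runoff
    retained <- ifelse(detected, rbinom(m, 1L, p$p_retain) == 1L, NA)
    t_rel <- rep(NA_real_, m)
    t_rel[detected & !is.na(retained) & !retained] <-
      t_runoff[detected & !is.na(retained) & !retained]
    ret <- detected & !is.na(retained) & retained
    if (any(ret))
      t_rel[ret] <- t_runoff[ret] + rexp(sum(ret), 1 / p$retain_dwell_mean)

    out$t_escape[pr] <- t_escape
    out$t_exposure[pr] <- t_exposure
    out$t_end_reached[pr] <- t_end
    out$t_runoff[pr] <- t_runoff
    out$probe_dark[pr] <- dark
    out$t_probe_arrival[pr] <- t_arr
    out$detected[pr] <- detected
    out$retained[pr] <- retained
    out$t_probe_release[pr] <- t_rel
  }
  out$dwell <- out$t_runoff - out$t_bind
  out
}

#' Simulate a single transcription-cycle event
#'
#' Draws the full ground-truth event anatomy: exponential escape delay from
#' promoter binding, per-nucleotide exponential elongation steps (so segment
#' times are Gamma distributed, giving the bell-shaped, right-skewed
#' productive dwell population), an exponential end dwell before run-off,
#' exponential probe arrival after the target is exposed (position = target
#' 3' end + polymerase footprint), a dark-fluorophore Bernoulli draw, and
#' Bernoulli-plus-exponential post-run-off probe retention. Non-productive
#' events are a single exponential dwell with no transcript.
#'
#' The probe waiting time is always drawn when the fluorophore is not dark;
#' the `detected` column records whether the arrival beat run-off, so
#' censoring of slow hybridization by run-off is explicit rather than folded
#' into the arrival time.
#'
#' @param params A [sim_params()] object.
#' @param t_bind Absolute binding time, s (default 0).
#' @param kind `"random"` (Bernoulli `p_productive`), `"productive"` or
#'   `"nonproductive"`.
#' @param seed Optional seed.
#' @return One-row data frame: `kind`, `t_bind`, `t_escape`, `t_exposure`,
#'   `t_end_reached`, `t_runoff`, `probe_dark`, `t_probe_arrival`,
#'   `detected`, `retained`, `t_probe_release`, `dwell`.
#' @export
simulate_transcription_cycle <- function(params, t_bind = 0,
                                         kind = c("random", "productive",
                                                  "nonproductive"),
                                         seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "random")
      kind <- if (runif(1L) < params$p_productive) "productive"
              else "nonproductive"
    simulate_cycles_(params, 1L, t_bind, kind)
  })
}

#' Simulate a field of template loci
#'
#' Places `n_loci` loci at random subpixel positions (kept 4 px inside the
#' field edge so 5x5 ROIs with a perimeter ring fit), generates RNAP arrivals
#' per locus as a Poisson process at `rnap_arrival_rate`, marks each arrival
#' productive with probability `p_productive`, and draws the full event
#' anatomy for each. Arrivals landing while the locus is still occupied by
#' the previous polymerase are dropped (a locus binds one polymerase at a
#' time); at default rates this discards ~2% of arrivals.
#'
#' @param params A [sim_params()] object; `params$seed` (if set) makes the
#'   field reproducible.
#' @return Object of class `sim_field`: list with `events` (ground-truth
#'   event table with `locus_id` and an `event` id), `loci` (data frame
#'   `locus_id`, `x`, `y` in pixel units), `n_dropped` (arrivals discarded as
#'   overlapping) and `params`.
#' @export
simulate_field <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    margin <- 4
    H <- p$field_size[1L]; W <- p$field_size[2L]
    if (H <= 2 * margin || W <= 2 * margin)
      stop("field_size too small for the ", margin, "-px locus margin")
    # rejection-sample locus positions so all pairs are resolvable
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < p$n_loci) {
      if ((tries <- tries + 1L) > 200L * p$n_loci)
        stop("could not place ", p$n_loci, " loci at min_separation = ",
             p$min_separation, " px in a ", H, "x", W, " field")
      x <- runif(1L, margin + 1, W - margin)
      y <- runif(1L, margin + 1, H - margin)
      if (!length(xs) ||
          min((xs - x)^2 + (ys - y)^2) >= p$min_separation^2) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    loci <- data.frame(locus_id = seq_len(p$n_loci), x = xs, y = ys)

    n_arr <- rpois(p$n_loci, p$rnap_arrival_rate * p$duration)
    locus_id <- rep(loci$locus_id, n_arr)
    t_bind <- unlist(lapply(n_arr, function(k) sort(runif(k, 0, p$duration))),
                     use.names = FALSE)
    if (!length(t_bind)) {
      ev <- cbind(locus_id = integer(0),
                  simulate_cycles_(p, 0L, numeric(0), character(0)))
      return(structure(list(events = ev, loci = loci, n_dropped = 0L,
                            params = p), class = "sim_field"))
    }
    kind <- ifelse(runif(length(t_bind)) < p$p_productive,
                   "productive", "nonproductive")
    ev <- simulate_cycles_(p, length(t_bind), t_bind, kind)
    ev <- cbind(locus_id = locus_id, ev)

    # drop arrivals during occupancy (rows are sorted by locus, then time)
    keep <- logical(nrow(ev))
    last_dep <- -Inf; last_locus <- -1L
    for (i in seq_len(nrow(ev))) {
      if (ev$locus_id[i] != last_locus) { last_dep <- -Inf
                                          last_locus <- ev$locus_id[i] }
      if (ev$t_bind[i] >= last_dep) {
        keep[i] <- TRUE
        last_dep <- max(ev$t_runoff[i], ev$t_probe_release[i], na.rm = TRUE)
      }
    }
    events <- ev[keep, , drop = FALSE]
    events$event <- seq_len(nrow(events))
    rownames(events) <- NULL
    structure(list(events = events, loci = loci,
                   n_dropped = sum(!keep), params = p),
              class = "sim_field")
  })
}

#' @export
print.sim_field <- function(x, ...) {
  cat(sprintf("<sim_field> %d loci, %d events (%d productive), %.0f s\n",
              nrow(x$loci), nrow(x$events),
              sum(x$events$kind == "productive"), x$params$duration))
  invisible(x)
}

#' Simulate a probe-target hybridization assay
#'
#' One exponential waiting time per surface-immobilized target at rate
#' `k_on * conc`; waits exceeding the acquisition are right-censored at
#' `duration`.
#'
#' @param k_on Probe on-rate, /M/s.
#' @param conc Probe concentration, M.
#' @param n_targets Number of target molecules.
#' @param duration Acquisition duration, s.
#' @param seed Optional seed.
#' @return Data frame `target`, `t_wait` (s, censored waits set to
#'   `duration`), `censored`.
#' @examples
#' a <- simulate_hybridization_assay(6e6, 500e-9, 1000, 30, seed = 1)
#' mean(a$t_wait[!a$censored])  # ~ 1 / (6e6 * 500e-9) = 0.33 s
#' @export
simulate_hybridization_assay <- function(k_on, conc, n_targets, duration,
                                         seed = NULL) {
  stopifnot(k_on > 0, conc > 0, n_targets >= 1, duration > 0)
  with_seed(seed, {
    w <- rexp(n_targets, rate = k_on * conc)
    data.frame(target = seq_len(n_targets),
               t_wait = pmin(w, duration),
               censored = w > duration)
  })
}
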