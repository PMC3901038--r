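# Hand-build a sim_field with a prescribed event table, for exact
# rendering checks.
manual_field <- function(params, events, loci = NULL) {
  if (is.null(loci))
    loci <- data.frame(locus_id = unique(events$locus_id), x = 10, y = 10)
  defaults <- data.frame(kind = "nonproductive", t_bind = 0,
                         t_escape = NA_real_, t_exposure = NA_real_,
                         t_end_reached = NA_real_, t_runoff = 1,
                         probe_dark = NA, t_probe_arrival = NA_real_,
                         detected = FALSE, retained = NA,
                         t_probe_release = NA_real_, stringsAsFactors = FALSE)
  for (col in names(defaults))
    if (!col %in% names(events)) events[[col]] <- defaults[[col]]
  events$dwell <- events$t_runoff - events$t_bind
  structure(list(events = events, loci = loci, n_dropped = 0L,
                 params = params), class = "sim_field")
}

test_that("ground-truth events satisfy their ordering invariants", {
  p <- sim_params(n_loci = 100L, duration = 600, rnap_arrival_rate = 0.2,
                  field_size = c(128L, 128L),
                  seed = 42)
  f <- simulate_field(p)
  ev <- f$events
  expect_gt(nrow(ev), 5000)
  pr <- ev[ev$kind == "productive", ]
  expect_true(all(pr$t_bind <= pr$t_escape))
  expect_true(all(pr$t_escape <= pr$t_exposure))
  expect_true(all(pr$t_exposure <= pr$t_end_reached))
  expect_true(all(pr$t_end_reached <= pr$t_runoff))
  arr <- pr$t_probe_arrival
  expect_true(all(arr[!is.na(arr)] >= pr$t_exposure[!is.na(arr)]))
  rel <- pr$t_probe_release
  expect_true(all(rel[!is.na(rel)] >= pr$t_runoff[!is.na(rel)]))
  np <- ev[ev$kind == "nonproductive", ]
  expect_true(all(np$t_runoff > np$t_bind))
  expect_true(all(is.na(np$t_probe_arrival)))
  # dark probes never yield an arrival time
  expect_true(all(is.na(pr$t_probe_arrival[pr$probe_dark])))
})

test_that("event counts per locus follow the arrival rate", {
  p <- sim_params(n_loci = 400L, duration = 500, rnap_arrival_rate = 0.02,
                  field_size = c(256L, 256L),
                  seed = 7)
  f <- simulate_field(p)
  expected <- p$rnap_arrival_rate * p$duration * p$n_loci
  # within Poisson error plus the ~2% busy-locus drop
  expect_lt(abs(nrow(f$events) + f$n_dropped - expected) / expected, 0.05)
  expect_lt(f$n_dropped / nrow(f$events), 0.06)

  p0 <- sim_params(n_loci = 10L, duration = 50, rnap_arrival_rate = 0,
                   seed = 1)
  expect_identical(nrow(simulate_field(p0)$events), 0L)
})

test_that("simulation is reproducible for a fixed seed", {
  p <- sim_params(n_loci = 20L, duration = 100, seed = 99)
  f1 <- simulate_field(p); f2 <- simulate_field(p)
  expect_identical(f1$events, f2$events)
  expect_identical(render_traces(f1), render_traces(f2))
})

test_that("mean productive dwell matches the kinetic model for all templates", {
  for (L in c(295L, 633L, 910L)) {
    p <- sim_params(template_length = L, p_productive = 1, field_size = c(128L, 128L),
                    rnap_arrival_rate = 0.05, n_loci = 60L, duration = 700,
                    seed = L)
    f <- simulate_field(p)
    d <- f$events$dwell[f$events$kind == "productive"]
    expect_gt(length(d), 1000)
    analytic <- 1 / p$k_escape + (L - p$escape_position) / p$v_elong +
      p$end_dwell_mean
    expect_lt(abs(mean(d) - analytic), 2 * sd(d) / sqrt(length(d)))
  }
})

test_that("productive dwell collapses to the escape exponential in the limit", {
  p <- sim_params(v_elong = Inf, end_dwell_mean = 0, p_productive = 1, field_size = c(128L, 128L),
                  rnap_arrival_rate = 0.05, n_loci = 50L, duration = 500,
                  seed = 3)
  f <- simulate_field(p)
  d <- f$events$dwell[f$events$kind == "productive"]
  expect_gt(length(d), 800)
  ks <- stats::ks.test(d, "pexp", rate = p$k_escape)
  expect_gt(ks$p.value, 0.01)
})

test_that("probe arrival delay after exposure is exponential at k_on*conc", {
  p <- sim_params(p_productive = 1, rnap_arrival_rate = 0.1, n_loci = 260L, field_size = c(256L, 256L),
                  duration = 600, seed = 12)
  f <- simulate_field(p)
  pr <- f$events[f$events$kind == "productive" & !f$events$probe_dark, ]
  delays <- pr$t_probe_arrival - pr$t_exposure
  expect_gt(length(delays), 8000)
  ks <- stats::ks.test(delays, "pexp", rate = p$k_on_probe * p$probe_conc)
  expect_gt(ks$p.value, 0.01)
})

test_that("visible-probe fraction at run-off approaches 1 - dark_fraction", {
  # long template: the exposure-to-runoff window (~3.3 s) makes hybridization
  # censoring negligible, isolating the dark-fluorophore loss
  p <- sim_params(template_length = 910L, p_productive = 1, field_size = c(128L, 128L),
                  rnap_arrival_rate = 0.05, n_loci = 80L, duration = 600,
                  seed = 5)
  f <- simulate_field(p)
  pr <- f$events[f$events$kind == "productive", ]
  frac <- mean(pr$detected)
  tol <- 3 * sqrt(0.19 * 0.81 / nrow(pr))
  expect_lt(abs(frac - (1 - p$dark_fraction)), tol + 0.01)

  p_dark <- sim_params(dark_fraction = 1, p_productive = 1,
                       rnap_arrival_rate = 0.05, n_loci = 20L,
                       duration = 200, seed = 6)
  f_dark <- simulate_field(p_dark)
  expect_true(all(is.na(f_dark$events$t_probe_arrival)))
  expect_false(any(f_dark$events$detected))
})

test_that("hybridization assay waits are exponential with censoring", {
  a <- simulate_hybridization_assay(6e6, 500e-9, 20000, 30, seed = 8)
  expect_equal(mean(a$t_wait[!a$censored]), 1 / (6e6 * 500e-9),
               tolerance = 0.03)
  # population mean approaches ~0.33 s at the reference rate and conc
  expect_equal(mean(a$t_wait), 0.333, tolerance = 0.02)
  short <- simulate_hybridization_assay(1, 1, 50, 1e-6, seed = 9)
  expect_true(all(short$censored))
  expect_true(all(short$t_wait == 1e-6))
})

test_that("noiseless traces are exact frame-integrated occupancy", {
  p <- sim_params(noise_sd = 0, frame_rate = 2.5, duration = 40,
                  n_loci = 1L, rise_per_bp = 0)
  # clean step: frames 11..20 occupied exactly
  f <- manual_field(p, data.frame(locus_id = 1L, kind = "nonproductive",
                                  t_bind = 4, t_runoff = 8))
  tr <- render_traces(f, seed = 1)
  expect_equal(unname(tr[1, , "rnap"]),
               c(rep(0, 10), rep(1, 10), rep(0, 80)))

  # sub-frame event: 0.08 s in a 0.4 s frame -> 20% amplitude in one frame
  f2 <- manual_field(p, data.frame(locus_id = 1L, kind = "nonproductive",
                                   t_bind = 4.1, t_runoff = 4.18))
  tr2 <- render_traces(f2, seed = 1)
  expect_equal(sum(tr2[1, , "rnap"] > 0), 1L)
  expect_equal(max(tr2[1, , "rnap"]), 0.08 / 0.4, tolerance = 1e-9)

  # probe channel: constant amplitude from arrival to release
  f3 <- manual_field(p, data.frame(locus_id = 1L, kind = "productive",
                                   t_bind = 4, t_escape = 4.2,
                                   t_exposure = 4.4, t_end_reached = 5,
                                   t_runoff = 8, probe_dark = FALSE,
                                   t_probe_arrival = 4.8, detected = TRUE,
                                   retained = FALSE, t_probe_release = 8))
  tr3 <- render_traces(f3, seed = 1)
  expect_equal(unname(tr3[1, , "probe"]),
               c(rep(0, 12), rep(1, 8), rep(0, 80)))
})

test_that("evanescent-field decay attenuates the RNAP signal with position", {
  p <- sim_params(template_length = 910L, noise_sd = 0, duration = 40,
                  n_loci = 1L)
  f <- manual_field(p, data.frame(locus_id = 1L, kind = "productive",
                                  t_bind = 4, t_escape = 4.2,
                                  t_exposure = 6, t_end_reached = 7.2,
                                  t_runoff = 7.6))
  tr <- render_traces(f, seed = 1)
  occ <- which(tr[1, , "rnap"] > 0.02)
  expect_lt(tr[1, max(occ), "rnap"], tr[1, min(occ), "rnap"])
  # frame 19 spans [7.2, 7.6] s: polymerase sits at the template end, so the
  # attenuation is exp(-910 * 0.34 / 100)
  expect_equal(unname(tr[1, 19, "rnap"]), exp(-910 * 0.34 / 100),
               tolerance = 1e-6)
})

test_that("movies conserve flux and peak at the locus pixel", {
  p <- sim_params(n_loci = 3L, duration = 20, noise_sd = 0, background = 0,
                  seed = 31, rnap_arrival_rate = 0.2)
  f <- simulate_field(p)
  tr <- render_traces(f, noise_sd = 0)
  mv <- render_movie(f, tr, noise_sd = 0)
  for (fr in c(5L, 20L, 40L)) {
    expect_equal(sum(mv$rnap[, , fr]), sum(tr[, fr, "rnap"]),
                 tolerance = 1e-6)
  }
  # single bright locus: argmax at its pixel
  busiest <- which.max(rowSums(tr[, , "rnap"]))
  fr <- which.max(tr[busiest, , "rnap"])
  img <- mv$rnap[, , fr]
  pk <- which(img == max(img), arr.ind = TRUE)[1L, ]
  expect_lt(abs(pk[["col"]] - f$loci$x[busiest]), 1)
  expect_lt(abs(pk[["row"]] - f$loci$y[busiest]), 1)
})

test_that("parameter validation catches inconsistent geometry", {
  expect_error(sim_params(target_window = c(28, 290), template_length = 295),
               "footprint")
  expect_error(sim_params(escape_position = 70), "exposure")
  expect_error(sim_params(dark_fraction = 1.2), "fractions")
  expect_error(sim_params(k_escape = -1), "rates")
})
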