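test_that("simulated events are deterministic by seed", {
  a <- simulate_event(seed = 5)
  b <- simulate_event(seed = 5)
  expect_identical(a$segment$samples, b$segment$samples)
  expect_identical(a$truth, b$truth)
  c <- simulate_event(seed = 6)
  expect_false(identical(a$segment$samples, c$segment$samples))
})

test_that("friction component energy is confined to the configured band", {
  # FFT band-energy oracle on the noise-free components
  cfg <- sim_event_config(noise_rms = 1e-9)
  for (seed in c(2, 9, 31)) {
    ev <- simulate_event(cfg, seed = seed)
    tr <- ev$truth
    fs <- ev$segment$fs
    i1 <- round(tr$ph1_onset * fs) + 1L
    i2 <- round(tr$ph1_offset * fs)
    fric <- ev$segment$samples[i1:i2]
    X <- fft(fric)
    f <- (0:(length(fric) - 1)) * fs / length(fric)
    f <- pmin(f, fs - f)
    inband <- sum(Mod(X[f >= 1800 & f <= 7000])^2) / sum(Mod(X)^2)
    expect_gte(inband, 0.90)
  }
})

test_that("component energies are exact by construction", {
  for (seed in c(3, 17)) {
    ev <- simulate_event(seed = seed)
    expect_equal(ev$truth$E3, 160, tolerance = 1e-3)
    expect_equal(ev$truth$E2, 8, tolerance = 1e-3)
    # friction energy = rms^2 * n_samples
    n_f <- round(ev$truth$friction_duration_ms / 1000 * 16000)
    expect_equal(ev$truth$E1, 0.05^2 * n_f, tolerance = 1e-6)
  }
})

test_that("ground-truth onsets are ordered and the layout fits the window", {
  for (seed in 1:10) {
    tr <- simulate_event(seed = seed)$truth
    expect_lt(tr$ph1_onset, tr$ph2_onset)
    expect_lt(tr$ph2_onset, tr$ph3_onset)
    expect_lt(tr$ph3_onset, tr$attack_peak)
    expect_gte(tr$ph1_onset, 0)
    expect_lt(tr$end_of_event, 0.4)
  }
})

test_that("impossible phase layouts are configuration errors", {
  expect_error(sim_event_config(latency_ms = 200), "layout")
  expect_error(sim_event_config(puncture_dur_ms = 5, latency_ms = 3.5),
               "overlaps")
  expect_error(sim_event_config(click_weight_fast = 1.2), "click_weight_fast")
  expect_error(sim_event_config(friction_band = c(1800, 9000)), "friction_band")
  expect_error(sim_event_config(noise_rms = 0), "noise_rms")
})

test_that("closed-form recovery times match the bi-exponential defaults", {
  t_rec <- click_recovery_time(c(0.90, 0.95, 0.98))
  # within 15% of the reported 13/20/35 ms medians
  expect_equal(t_rec[1], 13, tolerance = 0.15)
  expect_equal(t_rec[2], 20, tolerance = 0.15)
  expect_equal(t_rec[3], 35, tolerance = 0.15)
  expect_true(all(diff(t_rec) > 0))
})

test_that("insertions without a cavity event stay near the noise floor", {
  out <- simulate_insertion(sim_event_config(), seed = 42,
                            reached_cavity = FALSE, duration_s = 6)
  expect_null(out$annotation)
  expect_false(out$truth$reached_cavity)
  x <- out$recording$samples
  fs <- out$recording$fs
  env <- veressva:::.st_rms(x, fs, 32L, 8L)
  # mask out transient neighbourhoods
  keep <- rep(TRUE, length(env$times))
  for (tc in out$truth$transient_times) {
    keep[abs(env$times - tc) < 0.05] <- FALSE
  }
  expect_lte(max(env$rms[keep]), 10 * 0.005)
})

test_that("the embedded click dominates every tissue transient", {
  for (seed in c(8, 21)) {
    out <- simulate_insertion(sim_event_config(), seed = seed,
                              reached_cavity = TRUE, duration_s = 8)
    x <- out$recording$samples
    fs <- out$recording$fs
    pk <- round(out$truth$attack_peak * fs)
    click_peak <- max(abs(x[(pk - 80):(pk + 80)]))
    for (tc in out$truth$transient_times) {
      i <- round(tc * fs)
      trans_peak <- max(abs(x[(i - 40):(i + 240)]))
      expect_gte(click_peak, 3 * trans_peak)
    }
  }
})

test_that("requested duration fixes the sample count", {
  out <- simulate_insertion(sim_event_config(), seed = 1, duration_s = 5)
  expect_length(out$recording$samples, 80000)
})

test_that("cohort layout reproduces the per-subject counts exactly", {
  spec <- porcine_cohort_spec()
  lay <- cohort_layout(spec, seed = 11)
  expect_equal(nrow(lay), 193)
  expect_equal(sum(lay$reached_cavity), 154)
  expect_equal(sum(lay$ph2_present), 141)
  by_subj <- tapply(lay$reached_cavity, lay$subject_id, sum)
  expect_equal(as.integer(by_subj[spec$subject_id]), spec$cavity)
  # deterministic by seed
  expect_identical(lay, cohort_layout(spec, seed = 11))
  expect_false(identical(lay$reached_cavity,
                         cohort_layout(spec, seed = 12)$reached_cavity))
})

test_that("inconsistent cohort specifications are rejected", {
  bad <- data.frame(subject_id = "s", insertions = 3L, cavity = 5L,
                    ph2_suppressed = 0L)
  expect_error(cohort_layout(bad, 1), "exceed")
  bad2 <- data.frame(subject_id = "s", insertions = 5L, cavity = 3L,
                     ph2_suppressed = 4L)
  expect_error(cohort_layout(bad2, 1), "exceed")
  empty <- data.frame(subject_id = character(0), insertions = integer(0),
                      cavity = integer(0), ph2_suppressed = integer(0))
  expect_equal(nrow(cohort_layout(empty, 1)), 0)
})

test_that("simulated cohorts carry consistent annotations and truths", {
  spec <- data.frame(subject_id = c("s1", "s2"),
                     insertions = c(3L, 2L), cavity = c(2L, 1L),
                     ph2_suppressed = c(1L, 0L))
  co <- simulate_cohort(spec, seed = 7, duration_range = c(3, 4))
  expect_length(co$recordings, 5)
  expect_equal(nrow(co$annotations), 3)
  expect_equal(sum(vapply(co$truths, function(t) isTRUE(t$reached_cavity),
                          logical(1))), 3)
  # annotations point at the true burst (or click) onset inside the recording
  for (i in seq_len(nrow(co$annotations))) {
    j <- match(co$annotations$recording_id[i],
               vapply(co$recordings, function(r) r$recording_id, character(1)))
    tr <- co$truths[[j]]
    expected <- if (tr$ph2_present) tr$ph2_onset else tr$ph3_onset
    expect_equal(co$annotations$t_puncture_s[i], expected)
  }
  # same seed -> identical annotation table
  co2 <- simulate_cohort(spec, seed = 7, duration_range = c(3, 4))
  expect_identical(co$annotations, co2$annotations)
})
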