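test_that("extract_segment returns a centred 400 ms window", {
  rec <- recording(rnorm(10 * 16000, 0, 0.01), fs = 16000)
  seg <- extract_segment(rec, 1.0)
  expect_length(seg$samples, 6400)
  expect_equal(seg$t0, 0.8)
  expect_equal(seg$t0 + length(seg$samples) / seg$fs, 1.2)
  expect_identical(seg$samples, extract_segment(rec, 1.0)$samples)
  # annotations too close to an edge are boundary errors, no padding
  expect_error(extract_segment(rec, 0.1), "edge")
  expect_error(extract_segment(rec, 9.95), "edge")
  expect_error(extract_segment(rec, 20), "outside")
})

test_that("CWT localizes tones in frequency against the brute-force oracle", {
  fs <- 16000
  t <- (0:1599) / fs
  x <- sin(2 * pi * 1000 * t)
  sc <- compute_cwt(x, fs = fs)
  avg <- rowMeans(sc$magnitude[, 400:1200])
  f_hat <- sc$frequencies[which.max(avg)]
  expect_lt(abs(f_hat - 1000) / 1000, 0.05)

  # oracle comparison at interior points
  for (f in c(500, 1000, 3000)) {
    i <- which.min(abs(sc$frequencies - f))
    for (ti in c(600, 800, 1000)) {
      o <- cwt_oracle_mag(x, fs, sc$frequencies[i], ti)
      expect_equal(sc$magnitude[i, ti], o, tolerance = 1e-6 + 0.02 * o)
    }
  }
})

test_that("CWT of an impulse peaks at the impulse time at every frequency", {
  x <- numeric(3200); x[1600] <- 1
  sc <- compute_cwt(x, fs = 16000)
  peak_t <- sc$times[apply(sc$magnitude, 1, which.max)]
  expect_true(all(abs(peak_t - 1599 / 16000) <= 0.002))
  expect_true(all(sc$magnitude >= 0))
  expect_true(all(sc$frequencies > 0 & sc$frequencies <= 8000))
})

test_that("CWT separates two simultaneous tones", {
  fs <- 16000
  t <- (0:6399) / fs
  x <- sin(2 * pi * 1000 * t) + sin(2 * pi * 5000 * t)
  sc <- compute_cwt(x, fs = fs)
  avg <- rowMeans(sc$magnitude[, 1000:5400])
  # local maxima of the time-averaged spectrum
  locmax <- which(diff(sign(diff(avg))) == -2) + 1
  peaks <- sc$frequencies[locmax[order(avg[locmax], decreasing = TRUE)][1:2]]
  expect_lt(min(abs(peaks - 1000)) / 1000, 0.05)
  expect_lt(min(abs(peaks - 5000)) / 5000, 0.05)
})

test_that("CWT is deterministic and finite on unit-energy input", {
  set.seed(9)
  x <- rnorm(1600); x <- x / sqrt(sum(x^2))
  a <- compute_cwt(x, fs = 16000)
  b <- compute_cwt(x, fs = 16000)
  expect_identical(a$magnitude, b$magnitude)
  expect_true(all(is.finite(a$magnitude)))
})

test_that("pure background noise yields no excitations", {
  set.seed(110)
  rec <- recording(rnorm(8 * 16000, 0, 0.005))
  exc <- detect_excitations(preprocess(rec))
  expect_equal(nrow(exc), 0)
})

test_that("a cavity insertion yields exactly one cavity candidate near the true peak", {
  for (seed in c(5001, 5002, 5003)) {
    out <- simulate_insertion(sim_event_config(), seed = seed,
                              reached_cavity = TRUE)
    exc <- detect_excitations(preprocess(out$recording))
    cand <- exc[exc$is_cavity_candidate, ]
    expect_equal(nrow(cand), 1)
    expect_lt(abs(cand$event_time - out$truth$attack_peak), 0.010)
  }
})

test_that("insertions that do not reach the cavity yield no cavity candidate", {
  for (seed in c(6001, 6002, 6003)) {
    out <- simulate_insertion(sim_event_config(), seed = seed,
                              reached_cavity = FALSE)
    exc <- detect_excitations(preprocess(out$recording))
    expect_equal(sum(exc$is_cavity_candidate), 0)
  }
})

test_that("phase onsets are recovered within 2 ms on default events", {
  for (seed in c(301, 302, 303, 304)) {
    ev <- simulate_event(seed = seed)
    pb <- segment_phases(ev$segment)
    ph <- pb$phases
    expect_true(ph$present[1])
    expect_true(ph$present[2])
    expect_lt(abs(ph$onset[1] - ev$truth$ph1_onset), 0.002)
    expect_lt(abs(ph$onset[2] - ev$truth$ph2_onset), 0.002)
    expect_lt(abs(ph$onset[3] - ev$truth$ph3_onset), 0.002)
    expect_lt(abs(pb$attack_peak_time - ev$truth$attack_peak), 0.002)
  }
})

test_that("suppressed bursts are reported absent while Ph1 and Ph3 remain", {
  for (seed in c(311, 312)) {
    ev <- simulate_event(sim_event_config(ph2_present = FALSE), seed = seed)
    pb <- segment_phases(ev$segment)
    expect_false(pb$phases$present[2])
    expect_true(pb$phases$present[1])
    expect_true(pb$phases$present[3])
    expect_lt(abs(pb$phases$onset[3] - ev$truth$ph3_onset), 0.002)
  }
})

test_that("phase bounds satisfy the ordering invariants on random events", {
  set.seed(120)
  for (k in 1:50) {
    cfg <- sim_event_config(ph2_present = runif(1) > 0.1)
    ev <- simulate_event(cfg, seed = 7000 + k)
    pb <- segment_phases(ev$segment)
    ph <- pb$phases
    on <- ph$onset; off <- ph$offset; pres <- ph$present
    expect_true(all(on[pres] <= off[pres]))
    if (pres[1] && pres[2]) expect_lte(off[1], on[2])
    if (pres[2]) expect_lte(on[2], on[3])
    expect_lte(on[3], pb$attack_peak_time)
    expect_equal(off[4], on[5])  # Ph4 -> Ph5 boundary
    expect_equal(off[5], on[6])  # Ph5 -> Ph6 boundary
    expect_true(pres[3])
  }
})

test_that("segments without an excitation raise a not-an-event error", {
  set.seed(121)
  seg <- structure(list(samples = rnorm(6400, 0, 0.005), fs = 16000,
                        t0 = 0, annotation_time = 0.2,
                        recording_id = "noise"),
                   class = "va_segment")
  expect_error(segment_phases(seg), class = "veressva_not_event")
  zero <- structure(list(samples = numeric(6400), fs = 16000, t0 = 0,
                         annotation_time = 0.2, recording_id = "zero"),
                    class = "va_segment")
  expect_error(segment_phases(zero), class = "veressva_not_event")
})

test_that("onset estimation is unbiased within 1 ms on noise-free events", {
  errs <- sapply(1:20, function(i) {
    ev <- simulate_event(sim_event_config(noise_rms = 1e-6), seed = 400 + i)
    pb <- segment_phases(ev$segment)
    c(ph1 = (pb$phases$onset[1] - ev$truth$ph1_onset) * 1000,
      ph2 = if (pb$phases$present[2]) {
        (pb$phases$onset[2] - ev$truth$ph2_onset) * 1000
      } else NA_real_,
      ph3 = (pb$phases$onset[3] - ev$truth$ph3_onset) * 1000)
  })
  bias <- rowMeans(errs, na.rm = TRUE)
  expect_true(all(abs(bias) <= 1))
})
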