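# Hand-built phase bounds for direct energy checks.
make_bounds <- function(onsets, offsets, present, peak) {
  structure(list(
    phases = data.frame(phase = c("ph1", "ph2", "ph3", "ph4", "ph5", "ph6"),
                        onset = onsets, offset = offsets, present = present,
                        stringsAsFactors = FALSE),
    attack_peak_time = peak, noise_median = 0, noise_mad = 0,
    fs = 16000, n = 6400), class = "va_phase_bounds")
}

test_that("phase_energy sums squared samples over the phase interval", {
  fs <- 16000
  b <- make_bounds(onsets = c(0, 0.05, 0.1, 0.11, 0.12, 0.13),
                   offsets = c(0.01, 0.06, 0.11, 0.12, 0.13, 0.14),
                   present = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
                   peak = 0.11)
  zero <- numeric(6400)
  expect_equal(phase_energy(zero, b, "ph1", fs = fs), 0)

  single <- numeric(6400); single[10] <- 1  # t ~ 0.56 ms, inside ph1
  expect_equal(phase_energy(single, b, "ph1", fs = fs), 1)

  const <- numeric(6400)
  const[801:960] <- 0.5  # 160 samples of 0.5 inside ph2 [0.05, 0.06)
  expect_equal(phase_energy(const, b, "ph2", fs = fs), 40)
})

test_that("energy of an absent phase is an undefined-metric signal", {
  b <- make_bounds(onsets = c(NA, NA, 0.1, 0.11, 0.12, 0.13),
                   offsets = c(NA, NA, 0.11, 0.12, 0.13, 0.14),
                   present = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
                   peak = 0.11)
  expect_error(phase_energy(numeric(6400), b, "ph2", fs = 16000),
               class = "veressva_undefined_metric")
})

test_that("recovery_time matches the single-exponential closed form", {
  fs <- 16000
  tau <- 5  # ms, energy decay constant
  t_ms <- (0:6399) / fs * 1000
  x <- exp(-t_ms / (2 * tau))  # amplitude decay -> energy decays as exp(-t/tau)
  expect_equal(recovery_time(x, 0, 0.90, fs = fs), tau * log(10),
               tolerance = 0.02)
  expect_equal(recovery_time(x, 0, 0.95, fs = fs), tau * log(20),
               tolerance = 0.02)
})

test_that("recovery time is nondecreasing in the threshold fraction", {
  set.seed(130)
  for (k in 1:10) {
    x <- rnorm(2000) * exp(-(1:2000) / runif(1, 50, 500))
    r <- vapply(c(0.90, 0.95, 0.98), function(f) {
      recovery_time(x, 0, f, fs = 16000)
    }, numeric(1))
    expect_true(all(diff(r) >= 0))
  }
  expect_error(recovery_time(numeric(100), 0, 0.9, fs = 16000),
               class = "veressva_undefined_metric")
})

test_that("event metrics reproduce the generator's energy ratios", {
  ev <- simulate_event(seed = 501)
  pb <- segment_phases(ev$segment)
  m <- compute_event_metrics(ev$segment, pb)
  expect_equal(m$fold_3_to_2, 20, tolerance = 0.15)
  expect_equal(m$ratio_pct_2, 5, tolerance = 0.15)
  expect_gte(m$E1, 0)
  expect_true(m$recovery90_ms <= m$recovery95_ms &&
              m$recovery95_ms <= m$recovery98_ms)
  expect_gte(m$total_event_ms, m$friction_duration_ms)
  # phase energies are bounded by the total segment energy
  tot <- sum(ev$segment$samples^2)
  expect_lte(m$E1 + m$E2 + m$E3, tot)
})

test_that("metrics of burst-suppressed events leave latency undefined", {
  ev <- simulate_event(sim_event_config(ph2_present = FALSE), seed = 502)
  pb <- segment_phases(ev$segment)
  m <- compute_event_metrics(ev$segment, pb)
  expect_true(is.na(m$latency_ms))
  expect_true(is.na(m$E2))
  expect_false(m$ph2_present)
  expect_true(is.finite(m$E3))
})

test_that("box statistics follow the linear-interpolation convention", {
  b <- box_stats(c(1, 2, 3, 4, 100))
  expect_equal(b$median, 3)
  expect_equal(b$q1, 2)
  expect_equal(b$q3, 4)
  expect_equal(b$outliers, 100)
  expect_equal(b$whisker_high, 4)

  single <- box_stats(5)
  expect_equal(single$median, 5)
  expect_length(single$outliers, 0)

  set.seed(131)
  for (k in 1:20) {
    v <- rnorm(sample(5:60, 1))
    b <- box_stats(v)
    expect_equal(b$q1, quartile_oracle(v, 0.25))
    expect_equal(b$median, quartile_oracle(v, 0.5))
    expect_equal(b$q3, quartile_oracle(v, 0.75))
    iqr <- b$q3 - b$q1
    expect_true(all(b$outliers < b$q1 - 1.5 * iqr |
                    b$outliers > b$q3 + 1.5 * iqr))
    expect_gte(b$whisker_low, b$q1 - 1.5 * iqr)
    expect_lte(b$whisker_high, b$q3 + 1.5 * iqr)
  }
})

test_that("cohort summaries reproduce the reference cohort count table", {
  spec <- porcine_cohort_spec()
  lay <- cohort_layout(spec, seed = 3)
  # ground-truth presence flags stand in for a perfect analysis pass
  events <- data.frame(subject_id = lay$subject_id,
                       reached_cavity = lay$reached_cavity,
                       excitation_detected = lay$reached_cavity,
                       ph1_present = lay$reached_cavity,
                       ph2_present = lay$ph2_present,
                       ph3_present = lay$reached_cavity)
  s <- summarize_cohort(events)
  tot <- s$counts[s$counts$subject_id == "Total", ]
  expect_equal(unname(unlist(tot[-1])), c(193, 154, 154, 154, 141, 154))
  c1 <- s$counts[s$counts$subject_id == "Cadaver01", ]
  expect_equal(c1$insertions, 13)
  expect_equal(c1$cavity_reached, 10)
  expect_error(summarize_cohort(events[0, ]), "empty cohort")
})

test_that("cohort metric statistics exclude undefined values", {
  events <- data.frame(subject_id = "s", reached_cavity = TRUE,
                       excitation_detected = TRUE, ph1_present = TRUE,
                       ph2_present = c(TRUE, TRUE, FALSE),
                       ph3_present = TRUE,
                       latency_ms = c(3, 4, NA))
  s <- summarize_cohort(events)
  lat <- s$stats[s$stats$metric == "latency_ms", ]
  expect_equal(lat$n, 2)
  expect_equal(lat$median, 3.5)
})
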