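test_that("the averaging window is validated against the protocol", {
  rec <- simulate_patch(wt_params(), noise = clean_noise(), seed = 1)
  expect_error(extract_instantaneous(rec, c(0.1, 0.4)),
               class = "ivperm_invalid_window")  # inside dead time
  expect_error(extract_instantaneous(rec, c(0.5, 50)),
               class = "ivperm_invalid_window")  # beyond the segment
  expect_error(extract_instantaneous(rec, c(2, 1)),
               class = "ivperm_invalid_window")
  expect_s3_class(extract_instantaneous(rec, c(0.5, 2)), "instantaneous_iv")
})

test_that("extractor noise shrinks as the standard error of the mean", {
  # 30 samples at 20 kHz in a 1.5 ms window: sd(extract) ~ sd/sqrt(30)
  nm <- noise_model(gaussian_sd_pA = 5, leak_conductance_pA_per_mV = 0,
                    rundown_tau_sweeps = Inf, patch_amplitude_cv = 0,
                    offset_range_mV = 0)
  vals <- vapply(1:120, function(s) {
    rec <- simulate_patch(wt_params(), protocol = minimal_protocol(),
                          noise = nm, seed = s)
    extract_instantaneous(rec)$i_test_pA[3]
  }, numeric(1))
  expect_equal(sd(vals), 5 / sqrt(30), tolerance = 0.25)
})

test_that("correction steps enforce their order and single application", {
  rec <- simulate_patch(wt_params(), noise = clean_noise(tau = 5), seed = 1)
  bg <- simulate_background(noise = clean_noise(), seed = 2)
  iv <- extract_instantaneous(rec)
  expect_error(correct_rundown(iv), class = "ivperm_state_error")
  expect_error(normalize_iv(iv), class = "ivperm_state_error")
  sub <- subtract_background(iv, extract_instantaneous(bg))
  expect_error(subtract_background(sub, extract_instantaneous(bg)),
               class = "ivperm_state_error")
  corr <- correct_rundown(sub)
  expect_error(correct_rundown(corr), class = "ivperm_state_error")
  expect_s3_class(normalize_iv(corr), "iv_curve")
})

test_that("rundown correction restores first-sweep amplitudes exactly", {
  p <- calibrate_amplitude(barrier_params(sigma_beta = 0.3))
  rec <- simulate_patch(p, noise = clean_noise(tau = 5), seed = 1)
  bg <- simulate_background(noise = clean_noise(), seed = 2)
  corr <- extract_instantaneous(rec) |>
    subtract_background(extract_instantaneous(bg)) |>
    correct_rundown()
  expect_equal(corr$i_test_pA,
               barrier_current(corr$voltage_mV, ion_spec(), p),
               tolerance = 1e-10)
})

test_that("uncorrected rundown masquerades as inward rectification", {
  # sweeps run in ascending voltage order, so later (positive) sweeps have
  # lost more current; without the pre-pulse correction a linear ground
  # truth looks inward-rectifying
  rec <- simulate_patch(wt_params(), noise = clean_noise(tau = 5), seed = 1)
  bg <- simulate_background(noise = clean_noise(), seed = 2)
  sub <- subtract_background(extract_instantaneous(rec),
                             extract_instantaneous(bg))
  ri_raw <- abs(sub$i_test_pA[sub$voltage_mV == 100]) /
    abs(sub$i_test_pA[sub$voltage_mV == -100])
  expect_lt(ri_raw, 0.75)
  corrected <- normalize_iv(correct_rundown(sub))
  expect_equal(rectification_index(corrected), 1, tolerance = 1e-10)
})

test_that("rundown correction fails safely when the reference is dead", {
  # first sweep's pre-pulse carries no current (e.g. the patch activated
  # late): the rundown reference is unusable
  rec <- simulate_patch(wt_params(), noise = clean_noise(), seed = 1)
  pp <- rec$protocol$prepulse_duration_ms
  kill <- rec$sweeps$sweep_index == 0 & rec$sweeps$time_ms < pp
  rec$sweeps$current_pA[kill] <- 0
  bg <- simulate_background(noise = clean_noise(), seed = 2)
  sub <- subtract_background(extract_instantaneous(rec),
                             extract_instantaneous(bg))
  expect_error(correct_rundown(sub),
               class = "ivperm_uncorrectable_rundown")
})

test_that("full preprocessing reproduces the generating curve on clean data", {
  p <- calibrate_amplitude(barrier_params(sigma_beta = 0.1, sigma_h = 0.5))
  nm <- clean_noise(leak = 0.05, leak_offset = 2, tau = 5)
  rec <- simulate_patch(p, noise = nm, seed = 1)
  bg <- simulate_background(noise = nm, seed = 2)
  got <- preprocess_patch(rec, bg)
  ref <- barrier_iv(got$voltage_mV, ion_spec(), p, normalize = TRUE)
  expect_lt(max(abs(got$current - ref$current)), 1e-10)
  expect_equal(got$current[got$voltage_mV == 120], 1)
})

test_that("offset QC measures injected offsets and applies the 2 mV rule", {
  nm <- clean_noise(leak = 0.05, leak_offset = 1)
  for (case in list(list(off = 0, pass = TRUE),
                    list(off = 2.5, pass = FALSE),
                    list(off = -1, pass = TRUE))) {
    rec <- simulate_patch(wt_params(), noise = nm,
                          voltage_offset_mV = case$off, seed = 1)
    bg <- simulate_background(noise = nm, voltage_offset_mV = case$off,
                              seed = 2)
    qc <- qc_patch(rec, bg)
    expect_equal(qc$voltage_offset_mV, case$off, tolerance = 0.05)
    expect_identical(qc$offset_pass, case$pass)
  }
  # flat (all-positive) curve: offset indeterminate
  flat <- simulate_background(noise = clean_noise(leak = 0,
                                                  leak_offset = 5),
                              seed = 3)
  qc <- qc_patch(flat)
  expect_true(is.na(qc$voltage_offset_mV))
  expect_false(qc$offset_pass)
  expect_match(qc$exclusion_reasons, "offset_indeterminate")
})

test_that("aggregation averages, propagates s.e.m. and checks the grid", {
  v <- seq(-100, 120, 20)
  mk <- function(scale) {
    cv <- barrier_iv(v, ion_spec(), barrier_params(), normalize = TRUE)
    cv$current <- cv$current * scale + (1 - scale)  # keep 1 at +120
    iv_curve(v, cv$current, normalization = "normalized_to_plus120mV")
  }
  single <- aggregate_patches(list(mk(1)))
  expect_equal(single$sem, rep(0, length(v)))
  trio <- aggregate_patches(list(mk(0.9), mk(1), mk(1.1)))
  expect_equal(trio$current, mk(1)$current, tolerance = 1e-12)
  expect_equal(unique(trio$n_patches), 3L)
  other <- barrier_iv(seq(-120, 120, 20), ion_spec(), barrier_params(),
                      normalize = TRUE)
  expect_error(aggregate_patches(list(mk(1), other)),
               class = "ivperm_alignment_error")
  raw <- barrier_iv(v, ion_spec(), barrier_params())
  expect_error(aggregate_patches(list(raw)), class = "ivperm_state_error")
})

test_that("s.e.m. shrinks as one over the square root of patch count", {
  nm <- noise_model(gaussian_sd_pA = 10, leak_conductance_pA_per_mV = 0.05,
                    rundown_tau_sweeps = 20, patch_amplitude_cv = 0,
                    offset_range_mV = 0)
  # pool the s.e.m. estimate over 8 replicate sets per size to beat the
  # chi-distribution noise of individual standard deviations
  pooled_sem <- function(n) {
    v2 <- vapply(1:8, function(set) {
      ds <- simulate_dataset(list(WT = wt_params()), n_patches = n,
                             protocol = minimal_protocol(), noise = nm,
                             seed = 40 * n + set)
      curves <- purrr::map(names(ds$recordings), function(id) {
        preprocess_patch(ds$recordings[[id]], ds$backgrounds[[id]])
      })
      agg <- aggregate_patches(curves)
      mean(agg$sem[agg$voltage_mV != 120]^2)
    }, numeric(1))
    sqrt(mean(v2))
  }
  sems <- vapply(c(4, 8, 16), pooled_sem, numeric(1))
  expect_equal(sems[1] / sems[2], sqrt(2), tolerance = 0.2)
  expect_equal(sems[2] / sems[3], sqrt(2), tolerance = 0.2)
})

test_that("background subtraction and extraction commute on plateau data", {
  nm <- clean_noise(leak = 0.08, leak_offset = 3, tau = 5)
  rec <- simulate_patch(wt_params(), noise = nm, seed = 1)
  bg <- simulate_background(noise = nm, seed = 2)
  # route 1: extract then subtract
  r1 <- subtract_background(extract_instantaneous(rec),
                            extract_instantaneous(bg))
  # route 2: subtract traces sample-wise, then extract
  rec2 <- rec
  rec2$sweeps$current_pA <- rec$sweeps$current_pA - bg$sweeps$current_pA
  r2 <- extract_instantaneous(rec2)
  expect_equal(r1$i_test_pA, r2$i_test_pA, tolerance = 1e-12)
  expect_equal(r1$i_prepulse_pA, r2$i_prepulse_pA, tolerance = 1e-12)
})
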