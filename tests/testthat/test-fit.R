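test_that("noise-free curves are fit back to their generating parameters", {
  v <- seq(-100, 120, 20)
  for (truth in list(c(1, 1), c(0.1, 1), c(0.3, 4), c(10, 0.5))) {
    p <- barrier_params(truth[1], truth[2])
    curve <- barrier_iv(v, ion_spec(), p, normalize = TRUE)
    fit <- fit_barrier_model(curve, ion_spec())
    expect_true(fit$converged)
    expect_equal(fit$params_hat$sigma_beta, truth[1], tolerance = 1e-4)
    expect_equal(fit$params_hat$sigma_h, truth[2], tolerance = 1e-3)
    expect_lt(fit$residual_norm, 1e-6)
  }
  # the flat (all-barriers-equal) optimum is recovered essentially exactly
  flat <- fit_barrier_model(barrier_iv(v, ion_spec(), barrier_params(1, 1),
                                       normalize = TRUE), ion_spec())
  expect_equal(flat$params_hat$sigma_beta, 1, tolerance = 1e-6)
  expect_equal(flat$params_hat$sigma_h, 1, tolerance = 1e-6)
})

test_that("fits are deterministic and internally consistent", {
  curve <- barrier_iv(seq(-100, 120, 20), ion_spec(),
                      barrier_params(0.2, 2), normalize = TRUE)
  f1 <- fit_barrier_model(curve, ion_spec())
  f2 <- fit_barrier_model(curve, ion_spec())
  expect_identical(f1$log_sigma, f2$log_sigma)
  expect_identical(f1$residual_norm, f2$residual_norm)
  # stored energy profile is exactly the profile of the estimate
  expect_identical(f1$energy_profile,
                   energy_profile(f1$params_hat, f1$thermo))
  # and the stored RI is the model RI of the estimate
  expect_equal(f1$rectification_index,
               rectification_index(f1$params_hat, ion_spec()),
               tolerance = 1e-12)
})

test_that("fit preconditions are enforced", {
  raw <- barrier_iv(seq(-100, 120, 20), ion_spec(), barrier_params())
  expect_error(fit_barrier_model(raw, ion_spec()),
               class = "ivperm_precondition_error")
  few <- iv_curve(c(20, 60, 120), c(0.2, 0.5, 1),
                  normalization = "normalized_to_plus120mV")
  expect_error(fit_barrier_model(few, ion_spec()),
               class = "ivperm_precondition_error")
})

test_that("tidy and glance expose the fit in broom style", {
  ds <- simulate_dataset(list(WT = wt_params()), n_patches = 6,
                         noise = study_noise(), seed = 21)
  pre <- preprocess_dataset(ds)
  fit <- fit_barrier_model(pre$aggregated$WT, ion_spec())
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "delta_ea_kJmol", "conf_low",
                     "conf_high"))
  expect_identical(td$term, c("sigma_beta", "sigma_h"))
  expect_true(all(td$conf_low < td$estimate & td$estimate < td$conf_high))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  # WT ground truth: both sigmas near 1, RI near 1
  expect_lt(max(abs(log(td$estimate))), 0.2)
  expect_equal(gl$rectification_index, 1, tolerance = 0.1)
})

test_that("log-sigma error shrinks as recording noise decreases", {
  p <- calibrate_amplitude(barrier_params(sigma_beta = 0.3))
  mse <- vapply(c(25, 10, 2.5), function(sd) {
    errs <- vapply(1:20, function(r) {
      nm <- noise_model(gaussian_sd_pA = sd,
                        leak_conductance_pA_per_mV = 0.05,
                        rundown_tau_sweeps = 20, patch_amplitude_cv = 0,
                        offset_range_mV = 0)
      rec <- simulate_patch(p, noise = nm, seed = 600 + r)
      bg <- simulate_background(noise = nm, seed = 9600 + r)
      fit <- fit_barrier_model(preprocess_patch(rec, bg), ion_spec())
      (fit$log_sigma[["log_sigma_beta"]] - log(0.3))^2
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mse) < 0))
})

test_that("well-posed rectifying data do not collapse to the bounds", {
  curve <- barrier_iv(seq(-100, 120, 20), ion_spec(),
                      barrier_params(0.1, 1), normalize = TRUE)
  fit <- fit_barrier_model(curve, ion_spec())
  est <- exp(fit$log_sigma)
  expect_true(all(est > 1e-3 * 1.0001 & est < 1e3 * 0.9999))
  # pinning either parameter to a bound fits decidedly worse
  v <- curve$voltage_mV
  pinned <- barrier_iv(v, ion_spec(), barrier_params(1e-3, 1),
                       normalize = TRUE)
  sse_pinned <- sum((curve$current - pinned$current)^2)
  expect_gt(sse_pinned, 100 * fit$residual_norm^2 + 1e-6)
})

test_that("sensitivity refits run at alternative barrier counts", {
  curve <- barrier_iv(seq(-100, 120, 20), ion_spec(),
                      barrier_params(0.2, 1), normalize = TRUE)
  sens <- fit_sensitivity(curve, ion_spec(), n_set = c(3, 4))
  expect_identical(sens$n_barriers, c(3, 4))
  expect_lt(sens$residual_norm[1], 1e-6)  # generated with n = 3
})

test_that("slope conductance matches lines exactly and models locally", {
  line <- iv_curve(seq(-120, 120, 20), 0.35 * seq(-120, 120, 20) + 4)
  expect_equal(slope_conductance(line), 0.35, tolerance = 1e-12)
  p <- wt_params()
  fine <- barrier_iv(seq(-120, -80, 2), ion_spec(), p)
  g <- slope_conductance(fine, at_mV = -100, window_mV = 20)
  dI <- (barrier_current(-99.995, ion_spec(), p) -
           barrier_current(-100.005, ion_spec(), p)) / 0.01
  expect_equal(g, dI, tolerance = 0.01)
  one <- iv_curve(-100, 5)
  expect_error(slope_conductance(one),
               class = "ivperm_insufficient_points")
})

test_that("conductance grows linearly with concentration in the model", {
  p <- wt_params()
  concs <- c(150, 75, 37.5, 15)
  curves <- purrr::map(concs, function(ci) {
    barrier_iv(seq(-120, -80, 5), ion_spec(-1, ci, 150), p)
  })
  names(curves) <- concs
  cc <- concentration_conductance(curves)
  expect_equal(cc$table$conc_mM, sort(concs))
  # no saturation in the model: G rises affinely with concentration, so a
  # straight line fits essentially perfectly and any fitted half-maximal
  # concentration lies far beyond the tested range
  expect_true(all(diff(cc$table$conductance_pA_per_mV) > 0))
  lin <- lm(conductance_pA_per_mV ~ conc_mM, data = cc$table)
  expect_lt(max(abs(stats::residuals(lin))),
            1e-6 * max(cc$table$conductance_pA_per_mV))
  if (!is.null(cc$hyperbola)) {
    expect_gt(abs(cc$hyperbola$k_half_mM), max(cc$table$conc_mM))
  }
  dup <- concentration_conductance(curves[c(1, 1)])
  expect_equal(dup$table$conductance_pA_per_mV[1],
               dup$table$conductance_pA_per_mV[2])
  expect_error(concentration_conductance(list()),
               class = "ivperm_invalid_argument")
})
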