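test_that("equal-barrier model collapses to the sinh closed form", {
  th <- thermo(295)
  ion <- ion_spec(-1, 150, 150)
  for (n in 2:6) {
    p <- barrier_params(1, 1, amplitude = 1, n_barriers = n)
    v <- c(-100, -60, 60, 100)
    got <- barrier_current(v, ion, p, th)
    u <- ion$valence * th$faraday * (v / 1000) /
      (th$gas_constant * th$temperature_K)
    ref <- 2 * ion$valence * th$faraday * 150 * sinh(u / (2 * n))
    expect_lt(max(abs(got - ref) / abs(ref)), 1e-12)
    vv <- seq(-120, 120, 2.5)
    got2 <- barrier_current(vv, ion, p, th)
    u2 <- ion$valence * th$faraday * (vv / 1000) /
      (th$gas_constant * th$temperature_K)
    ref2 <- 2 * ion$valence * th$faraday * 150 * sinh(u2 / (2 * n))
    rel <- abs(got2 - ref2) / pmax(abs(ref2), 1e-300)
    expect_lt(max(rel[vv != 0]), 1e-10)
  }
})

test_that("current vanishes at equilibrium for random parameter draws", {
  withr::with_seed(42, {
    for (k in 1:100) {
      n <- sample(2:6, 1)
      p <- barrier_params(10^runif(1, -2, 2), 10^runif(1, -2, 2),
                          n_barriers = n)
      ci <- 150 * 10^runif(1, -1, 1)
      ion <- ion_spec(-1, ci, 150)
      vn <- nernst_potential(ion)
      i_scale <- abs(barrier_current(120, ion, p))
      expect_lt(abs(barrier_current(vn, ion, p)), 1e-12 * i_scale)
      # equal concentrations: zero current at 0 mV exactly
      ion0 <- ion_spec(-1, ci, ci)
      expect_identical(barrier_current(0, ion0, p), 0)
    }
  })
})

test_that("symmetric profile is antisymmetric in voltage, so RI = 1", {
  ion <- ion_spec()
  p <- barrier_params(1, 1, n_barriers = 3)
  v <- seq(5, 120, 5)
  expect_equal(barrier_current(-v, ion, p), -barrier_current(v, ion, p),
               tolerance = 1e-12)
  expect_equal(rectification_index(p, ion), 1, tolerance = 1e-12)
})

test_that("current is linear in amplitude and in joint concentration scale", {
  p1 <- barrier_params(0.3, 2, amplitude = 1)
  p3 <- barrier_params(0.3, 2, amplitude = 3)
  v <- seq(-120, 120, 20)
  expect_equal(barrier_current(v, ion_spec(), p3),
               3 * barrier_current(v, ion_spec(), p1), tolerance = 1e-14)
  expect_equal(barrier_current(v, ion_spec(-1, 300, 450), p1),
               3 * barrier_current(v, ion_spec(-1, 100, 150), p1),
               tolerance = 1e-14)
})

test_that("lowering a relative rate strictly suppresses the current", {
  v <- setdiff(seq(-120, 120, 10), 0)
  ion <- ion_spec()
  base <- abs(barrier_current(v, ion, barrier_params(1, 1)))
  expect_true(all(abs(barrier_current(v, ion, barrier_params(0.1, 1))) <
                    base))
  expect_true(all(abs(barrier_current(v, ion, barrier_params(1, 0.1))) <
                    base))
})

test_that("the removable singularity at 0 mV is handled continuously", {
  p <- barrier_params(0.2, 5, n_barriers = 4)
  ion <- ion_spec(-1, 30, 150)
  eps <- 10^seq(-1, -6)
  gaps <- abs(barrier_current(eps, ion, p) - barrier_current(-eps, ion, p))
  expect_true(all(diff(gaps) < 0))
  # the analytic-limit branch agrees with direct evaluation nearby: the
  # even part of I at +/-1e-6 mV (which removes the genuine linear term)
  # must coincide with the limit-branch value at 0
  i0 <- barrier_current(0, ion, p)
  i_eps <- barrier_current(c(-1e-6, 1e-6), ion, p)
  expect_lt(abs(mean(i_eps) - i0) / abs(i0), 1e-8)
})

test_that("energy profile implements dEa = -RT ln sigma and round-trips", {
  ep <- energy_profile(barrier_params(sigma_beta = 0.1), thermo(295))
  expect_equal(ep$delta_ea_in_minus_out_kJmol, 5.65, tolerance = 0.01 / 5.65)
  ep2 <- energy_profile(barrier_params(sigma_h = 10), thermo(295))
  expect_equal(ep2$delta_ea_mid_minus_out_kJmol, -5.65,
               tolerance = 0.01 / 5.65)
  expect_equal(energy_profile(barrier_params())$delta_ea_in_minus_out_kJmol,
               0)
  # sigma < 1 <=> positive offset
  expect_gt(ep$delta_ea_in_minus_out_kJmol, 0)
  expect_lt(ep2$delta_ea_mid_minus_out_kJmol, 0)
  p <- barrier_params(0.037, 12.5, amplitude = 2, n_barriers = 4)
  back <- params_from_energy_profile(energy_profile(p), amplitude = 2)
  expect_equal(back$sigma_beta, p$sigma_beta, tolerance = 1e-12)
  expect_equal(back$sigma_h, p$sigma_h, tolerance = 1e-12)
  expect_identical(back$n_barriers, p$n_barriers)
})

test_that("Nernst potential matches the textbook values and symmetry", {
  expect_equal(nernst_potential(ion_spec(-1, 150, 150)), 0)
  e10 <- nernst_potential(ion_spec(-1, 15, 150), thermo(295))
  expect_equal(e10, -58.5, tolerance = 0.2 / 58.5)
  expect_equal(nernst_potential(ion_spec(-1, 150, 15), thermo(295)), -e10)
  expect_error(nernst_potential(ion_spec(-1, 0, 150)),
               class = "ivperm_undefined_potential")
})

test_that("rectification index reads model and data consistently", {
  # a straight line through the origin has RI exactly 1
  line <- iv_curve(seq(-120, 120, 20), 0.5 * seq(-120, 120, 20))
  expect_equal(rectification_index(line), 1)
  p <- barrier_params(sigma_beta = 0.1)
  ri_model <- rectification_index(p, ion_spec())
  expect_gt(ri_model, 1)
  curve <- barrier_iv(seq(-120, 120, 20), ion_spec(), p)
  expect_equal(rectification_index(curve), ri_model, tolerance = 1e-12)
  expect_equal(ri_model,
               abs(barrier_current(100, ion_spec(), p)) /
                 abs(barrier_current(-100, ion_spec(), p)))
})

test_that("normalized model curves have value 1 at +120 mV", {
  cv <- barrier_iv(seq(-100, 120, 20), ion_spec(), barrier_params(),
                   normalize = TRUE)
  expect_equal(cv$current[cv$voltage_mV == 120], 1)
  expect_true(is_normalized(cv))
  # single point at the Nernst potential is zero current
  ion10 <- ion_spec(-1, 15, 150)
  one <- barrier_iv(nernst_potential(ion10), ion10, barrier_params(0.2, 3))
  scale <- abs(barrier_current(120, ion10, barrier_params(0.2, 3)))
  expect_lt(abs(one$current), 1e-12 * scale)
})

test_that("invalid model inputs are rejected", {
  expect_error(barrier_params(sigma_beta = -1),
               class = "ivperm_invalid_argument")
  expect_error(barrier_params(n_barriers = 1),
               class = "ivperm_invalid_argument")
  expect_error(ion_spec(valence = 0), class = "ivperm_invalid_argument")
  expect_error(ion_spec(conc_in = 0, conc_out = 0),
               class = "ivperm_invalid_argument")
  expect_error(barrier_current(NaN, ion_spec(), barrier_params()),
               class = "ivperm_invalid_argument")
  expect_error(barrier_iv(c(0, 0, 120), ion_spec(), barrier_params()),
               class = "ivperm_invalid_argument")
  expect_error(thermo(-1), class = "ivperm_invalid_argument")
})
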