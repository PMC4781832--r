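test_that("master curve hits its calibration anchors and is strictly decreasing", {
  expect_equal(master_curve(0, dev), 2.0e7)
  expect_equal(master_curve(dev$t_inc, dev), 1.0e7)
  # midpoint of the fast-growth segment, evaluated by hand: 10^5.5
  expect_equal(master_curve(140e-9, dev), 10^5.5, tolerance = 1e-12)
  expect_equal(master_curve(200e-9, dev), 1.0e4)
  expect_equal(master_curve(250e-9, dev), 1.0e4)
  ts <- seq(0, dev$t_c, length.out = 200)
  expect_true(all(diff(master_curve(ts, dev)) < 0))
  expect_error(master_curve(-1e-9, dev), "non-negative")
})

test_that("state_from_resistance inverts the master curve", {
  expect_equal(state_from_resistance(2.0e7, dev), 0)
  expect_equal(state_from_resistance(1.0e4, dev), dev$t_c)
  expect_equal(state_from_resistance(1.0e7, dev), dev$t_inc)
  set.seed(11)
  R <- 10^runif(100, log10(dev$R_set_full), log10(dev$R_reset_full))
  expect_equal(master_curve(state_from_resistance(R, dev), dev), R,
               tolerance = 1e-9)
  expect_error(state_from_resistance(5e3, dev), "window")
  expect_error(state_from_resistance(3e7, dev), "window")
})

test_that("set pulses crystallize cumulatively and only inside the voltage window", {
  C0 <- pcm_state(state_from_resistance(1.0e7, dev), dev)
  one <- apply_set_pulse(C0, 1.05, 40e-9, dev)
  expect_equal(master_curve(one$t_eff, dev), 1.0e6, tolerance = 1e-9)
  five <- Reduce(function(s, i) apply_set_pulse(s, 1.05, 40e-9, dev),
                 1:5, init = C0)
  expect_equal(master_curve(five$t_eff, dev), 1.0e4)
  # conductance increase of ~1e3 after 5 spikes from the amorphized state
  expect_equal(1.0e7 / master_curve(five$t_eff, dev), 1e3)
  # read bias and over-melting amplitudes do not crystallize
  expect_equal(apply_set_pulse(C0, -0.030, 10e-3, dev)$t_eff, C0$t_eff)
  expect_equal(apply_set_pulse(C0, 0.5, 40e-9, dev)$t_eff, C0$t_eff)
  expect_equal(apply_set_pulse(C0, 1.3, 40e-9, dev)$t_eff, C0$t_eff)
})

test_that("n set pulses equal one pulse of n-fold width", {
  set.seed(21)
  for (i in 1:100) {
    R0 <- 10^runif(1, 4, log10(2e7))
    t_P <- runif(1, 5e-9, 60e-9)
    n <- sample(2:6, 1)
    s <- pcm_state(state_from_resistance(R0, dev), dev)
    many <- Reduce(function(st, k) apply_set_pulse(st, 1.05, t_P, dev),
                   seq_len(n), init = s)
    once <- apply_set_pulse(s, 1.05, n * t_P, dev)
    expect_equal(master_curve(many$t_eff, dev),
                 master_curve(once$t_eff, dev), tolerance = 1e-9)
  }
})

test_that("reset is abrupt, history-independent and idempotent", {
  set.seed(31)
  R <- sapply(1:100, function(i) {
    s <- pcm_state(runif(1, 0, dev$t_c), dev)
    master_curve(apply_reset_pulse(s, 1.75, 40e-9, dev)$t_eff, dev)
  })
  expect_true(all(R == 2.0e7))
  # below the melting voltage the state is untouched
  full_set <- pcm_state(dev$t_c, dev)
  expect_equal(apply_reset_pulse(full_set, 1.0, 40e-9, dev)$t_eff, dev$t_c)
  # pulse width is irrelevant above V_m (quench-limited)
  a <- apply_reset_pulse(full_set, 1.5, 40e-9, dev)
  b <- apply_reset_pulse(full_set, 1.5, 500e-9, dev)
  expect_identical(a$t_eff, b$t_eff)
  # applying the full reset twice gives the same resistance both times
  s <- pcm_state(state_from_resistance(5e5, dev), dev)
  r1 <- apply_reset_pulse(s, 1.75, 40e-9, dev)
  r2 <- apply_reset_pulse(r1, 1.75, 40e-9, dev)
  expect_equal(master_curve(r1$t_eff, dev), master_curve(r2$t_eff, dev))
})

test_that("reset characteristic is log-linear in voltage with clamping", {
  expect_equal(reset_characteristic(1.75, dev), 2.0e7)
  expect_equal(reset_characteristic(2.0, dev), 2.0e7)
  # midpoint between V_m and V_reset_full, evaluated by hand
  expect_equal(reset_characteristic(1.475, dev),
               10^((log10(1e4) + log10(2e7)) / 2), tolerance = 1e-12)
  Vs <- seq(1.25, 1.75, by = 0.05)
  expect_true(all(diff(reset_characteristic(Vs, dev)) > 0))
  expect_error(reset_characteristic(1.0, dev), "V_m")
})

test_that("all reachable resistances stay inside the device window", {
  set.seed(41)
  s <- pcm_state(runif(1, 0, dev$t_c), dev)
  for (i in 1:300) {
    if (runif(1) < 0.5) {
      s <- apply_set_pulse(s, runif(1, 0.9, 1.19), runif(1, 1e-9, 100e-9), dev)
    } else {
      s <- apply_reset_pulse(s, runif(1, 1.21, 2.0), 40e-9, dev)
    }
    R <- master_curve(s$t_eff, dev)
    expect_true(R >= dev$R_set_full && R <= dev$R_reset_full)
  }
})
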