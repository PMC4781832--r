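test_that("communication energy follows the array-normalized formula", {
  # learned pattern frame: 76 potentiated synapses of a 784x1 array
  E <- communication_energy(rep(1e4, 76))
  expect_equal(E, 10e-3 * 76 * 0.030^2 / 1.24e4 / 784, tolerance = 1e-12)
  expect_equal(E * 1e12, 70.4, tolerance = 1e-2)
  # noise frame on a depressed background sits below 100 fJ
  E3 <- communication_energy(rep(2e7, 51))
  expect_lt(E3, 1e-13)
  expect_equal(E3, 2.926945e-14, tolerance = 1e-6)
  expect_identical(communication_energy(numeric(0)), 0)
})

test_that("fire energy is per-event, resistance-at-start, linear in width", {
  ev <- list(V = 1.05, R_start = 1.0e4)
  E <- fire_energy(ev)
  expect_equal(attr(E, "per_event"), 1.05^2 * 40e-9 / 1.24e4,
               tolerance = 1e-12)
  expect_equal(as.numeric(E), attr(E, "per_event") / 784)
  E2 <- fire_energy(ev, t_P = 80e-9)
  expect_equal(as.numeric(E2), 2 * as.numeric(E))
  expect_identical(as.numeric(fire_energy(NULL)), 0)
})

test_that("capacitance design rule reproduces the worked example", {
  C <- capacitance_estimate()
  expect_equal(C, 3.136e-6, tolerance = 1e-9)
  # inverse proportionality to the threshold
  expect_equal(capacitance_estimate(V_th = 1.0), C / 2)
  # a 1e-3 read duty cycle brings it to the nF range
  expect_equal(capacitance_estimate(duty_cycle = 1e-3), C * 1e-3)
  expect_lt(capacitance_estimate(duty_cycle = 1e-3), 5e-9)
})

test_that("pulsed-read duty cycle cuts power by t_spike over T_spike", {
  expect_equal(duty_cycle_factor(pulsed_read_config(1e-6, 1e-3)), 1e-3)
  expect_equal(duty_cycle_factor(pulsed_read_config(1e-3, 1e-3)), 1)
  expect_equal(duty_cycle_factor(pulsed_read_config(0.5e-6, 1e-3)), 0.5e-3)
})

test_that("recognition reports count fires by epoch kind with conservation", {
  trace <- data.frame(
    kind = c("pattern", "pattern", "noise", "noise", "noise"),
    label = c("1", "1", "noise", "noise", "noise"),
    out_fired = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  rep <- recognition_report(trace)
  expect_equal(rep$P_learn, 0.5)
  expect_equal(rep$P_err, 1 / 3)
  expect_equal(rep$n_p_f + rep$n_p_0, rep$n_p)
  expect_equal(rep$n_n_f + rep$n_n_0, rep$n_n)
  expect_equal(rep$n_p + rep$n_n, rep$n)
  # perfect recognition
  perfect <- data.frame(kind = c("pattern", "noise"), label = c("1", "noise"),
                        out_fired = c(TRUE, FALSE))
  p <- recognition_report(perfect)
  expect_equal(p$P_learn, 1)
  expect_equal(p$P_err, 0)
  # a class with no epochs is flagged, not silently zero
  expect_warning(
    r0 <- recognition_report(data.frame(kind = "pattern", label = "1",
                                        out_fired = TRUE)),
    "P_err undefined")
  expect_true(is.na(r0$P_err))
})

test_that("energy histogram groups epochs by the three levels", {
  E <- c(8e-11, 7e-11, 5e-12, 3e-12, 5e-14, 0)
  h <- energy_histogram(E)
  expect_equal(as.vector(h[c("I", "II", "III")]), c(2, 2, 2))
  expect_equal(sum(h), length(E))
  h0 <- energy_histogram(rep(0, 5))
  expect_equal(as.vector(h0["III"]), 5)
})

test_that("cortical-density power stays under a kilowatt per square centimeter", {
  P <- power_density(communication_energy(rep(1e4, 76)))
  expect_equal(P, 704, tolerance = 1e-3) # W/cm^2
  expect_lt(P / 1000, 1) # below 1 kW/cm^2
})
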