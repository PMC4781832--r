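test_that("network construction is deterministic and respects init modes", {
  cfg <- network_config(N = 784, M = 1, seed = 123)
  a <- build_network(cfg)
  b <- build_network(cfg)
  expect_identical(a, b)
  expect_equal(dim(a$W1), c(784, 1))
  R <- master_curve(a$W1, dev)
  expect_true(all(R >= dev$R_set_full & R <= dev$R_reset_full))
  rst <- build_network(cfg, init = "full_reset")
  expect_true(all(master_curve(rst$W1, dev) == 2.0e7))
  expect_true(all(build_network(cfg, init = "full_set")$W1 == dev$t_c))
  expect_error(network_config(N = 0, M = 1), "N")
})

test_that("a fire potentiates this epoch's active synapses", {
  st <- tiny_net(N = 4, M = 1, n_cross = 2)
  st$W1[, 1] <- state_from_resistance(c(1e4, 1e4, 5e5, 5e5), dev)
  r <- step_epoch(st, active = c(1, 2))
  expect_equal(r$record$n_fired_hidden, 1)
  expect_equal(r$record$n_set, 2)
  # active synapses got a set pulse; inactive ones untouched
  expect_equal(master_curve(r$state$W1[3, 1], dev), 5e5)
  expect_equal(master_curve(r$state$W1[4, 1], dev), 5e5)
  expect_identical(r$state$V1, 0)
  expect_true(r$state$pend1)
})

test_that("depression strikes freshly active PREs one epoch after a fire", {
  st <- tiny_net(N = 4, M = 1, n_cross = 2)
  # the uncorrelated follow-up input drives a weaker synapse, so the
  # neuron cannot re-cross before the stale reset sub-pulse lands
  st$W1[3:4, 1] <- state_from_resistance(5e5, dev)
  r1 <- step_epoch(st, active = c(1, 2)) # fires
  expect_true(r1$state$pend1)
  r2 <- step_epoch(r1$state, active = c(2, 3)) # PRE 3 fresh, PRE 2 spared
  expect_equal(r2$record$n_fired_hidden, 0)
  W <- r2$state$W1[, 1]
  expect_equal(master_curve(W[3], dev), 2.0e7) # depressed
  expect_equal(master_curve(W[2], dev), 1.0e4) # in its after-pulse: spared
  expect_equal(master_curve(W[1], dev), 1.0e4) # gate off: untouched
  expect_equal(r2$record$n_reset, 1)
})

test_that("re-firing on the same input retriggers and supersedes depression", {
  st <- tiny_net(N = 4, M = 1, n_cross = 2)
  r1 <- step_epoch(st, active = c(1, 2))
  r2 <- step_epoch(r1$state, active = c(1, 2))
  expect_equal(r2$record$n_fired_hidden, 1)
  expect_equal(r2$record$n_reset, 0)
  expect_true(all(master_curve(r2$state$W1[1:2, 1], dev) == 1.0e4))
})

test_that("no fire means no plasticity beyond pending depression", {
  st <- tiny_net(N = 4, M = 1, n_cross = 3)
  r <- step_epoch(st, active = 1) # one synapse cannot cross
  expect_equal(r$record$n_fired_hidden, 0)
  expect_equal(r$record$n_set + r$record$n_reset, 0)
  expect_identical(master_curve(r$state$W1, dev), master_curve(st$W1, dev))
  r2 <- step_epoch(r$state, active = integer(0)) # silent epoch
  expect_equal(r2$record$n_active, 0)
  expect_equal(r2$record$E_syn_c, 0)
})

test_that("membrane potential carries over and leaks between epochs", {
  st <- tiny_net(N = 4, M = 1, n_cross = 3, tau_leak = Inf)
  r1 <- step_epoch(st, active = 1)
  v1 <- r1$state$V1
  expect_gt(v1, 0)
  r2 <- step_epoch(r1$state, active = 1)
  expect_equal(r2$state$V1, 2 * v1, tolerance = 1e-12)
  leaky <- tiny_net(N = 4, M = 1, n_cross = 3, tau_leak = 0.1)
  l1 <- step_epoch(leaky, active = 1)
  l2 <- step_epoch(l1$state, active = integer(0))
  expect_equal(l2$state$V1, l1$state$V1 * exp(-prot$t_ck / 0.1))
})

test_that("inhibition is applied in fire order and can veto later siblings", {
  st <- tiny_net(N = 4, M = 2, n_cross = 2.3, inhibition_on = TRUE)
  # both columns identical: both would cross; neuron 1 fires first and
  # discharges neuron 2 by 20%, pushing it back below threshold
  r <- step_epoch(st, active = c(1, 2))
  expect_equal(r$record$n_fired_hidden, 1)
  expect_identical(r$state$V1[1], 0)
  expect_gt(r$state$V1[2], 0)
  # without inhibition both fire
  st2 <- tiny_net(N = 4, M = 2, n_cross = 2.3, inhibition_on = FALSE)
  expect_equal(step_epoch(st2, active = c(1, 2))$record$n_fired_hidden, 2)
})

test_that("second-layer fires gate the third layer within the same epoch", {
  st <- tiny_net(N = 4, M = 2, n_cross = 2, layers = 3)
  # output capacitance sized like the hidden one: 2 firing hidden neurons
  # with full-set output synapses cross in one epoch
  r <- step_epoch(st, active = c(1, 2))
  expect_equal(r$record$n_fired_hidden, 2)
  expect_true(r$record$out_fired)
  # output synapses of the firing hidden neurons were potentiated
  expect_true(all(r$state$W2 == dev$t_c))
})

test_that("schedules run reproducibly for the stated number of epochs", {
  pat <- make_fixture_digits()[["1"]]
  sched <- make_schedule(list(pat), 0.5, 51 / 784)
  cfg <- network_config(N = 784, M = 1, seed = 5)
  set.seed(5)
  out1 <- run_epochs(build_network(cfg), sched, 50)
  set.seed(5)
  out2 <- run_epochs(build_network(cfg), sched, 50)
  expect_identical(out1, out2)
  expect_equal(nrow(out1$trace), 50)
  # 7 s at the 10 ms clock is 700 epochs
  expect_equal(7 / prot$t_ck, 700)
  # all-silent schedule leaves the weights untouched
  silent <- make_schedule(list(), numeric(0), 0)
  st <- build_network(cfg)
  out3 <- run_epochs(st, silent, 10)
  expect_identical(out3$state$W1, st$W1)
})

test_that("weight maps reshape conductances onto the retina", {
  cfg <- network_config(N = 784, M = 1, seed = 3)
  st <- build_network(cfg, init = "full_reset")
  wm <- weight_map(st, 1)
  expect_equal(dim(wm), c(28, 28))
  expect_true(all(wm == 1 / 2.0e7))
})
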