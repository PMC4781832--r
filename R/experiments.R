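#' STDP characterization map over initial states and delays
#'
#' For each initial resistance state, delay and spike count: prepare the
#' device on the master curve, apply the given number of identical STDP
#' events, and record the conductance change `R_0 / R`. Reproduces the
#' characterization of the three reference states (A close to full set at
#' 15 kohm, B intermediate at 500 kohm, C close to full reset at 10 Mohm)
#' with 1, 3 and 5 repeated spikes for the amorphized state.
#'
#' @param states Named numeric vector of initial resistances, ohms.
#' @param delta_t Grid of PRE/POST delays, seconds.
#' @param spike_counts Named list giving the spike counts applied per
#'   state.
#' @param device A [device_params()] object.
#' @param protocol A [protocol_params()] object.
#' @return A data frame with columns `state`, `R0`, `delta_t`, `n_spikes`,
#'   `R`, `ratio` (= `R0 / R`).
#' @export
run_stdp_map <- function(states = c(A = 1.5e4, B = 5.0e5, C = 1.0e7),
                         delta_t = seq(-25e-3, 25e-3, by = 1e-3),
                         spike_counts = list(A = 1, B = 1, C = c(1, 3, 5)),
                         device = device_params(),
                         protocol = protocol_params()) {
  rows <- list()
  for (s in names(states)) {
    for (n in spike_counts[[s]]) {
      for (dt in delta_t) {
        syn <- synapse_1t1r(
          pcm_state(state_from_resistance(states[[s]], device), device),
          device_params = device)
        ev <- stdp_event(t_pre = 0, t_post = dt)
        for (i in seq_len(n)) syn <- apply_stdp(syn, ev, protocol)
        R <- pcm_resistance(syn$device, device)
        rows[[length(rows) + 1L]] <-
          data.frame(state = s, R0 = states[[s]], delta_t = dt,
                     n_spikes = n, R = R, ratio = states[[s]] / R)
      }
    }
  }
  do.call(rbind, rows)
}

#' Random-delay spiking experiment
#'
#' Applies a sequence of STDP events with delays drawn uniformly from
#' `range` to a single synapse, recording the resistance before and after
#' every event. From the full-reset state the resistance stays near full
#' reset most of the time, with occasional potentiation runs requiring
#' several consecutive positive-delay spikes.
#'
#' @param epochs Number of spike events.
#' @param range Delay range (seconds, pair) for the uniform draw.
#' @param initial_R Initial device resistance, ohms.
#' @param seed RNG seed.
#' @param device A [device_params()] object.
#' @param protocol A [protocol_params()] object.
#' @return A data frame with columns `epoch`, `delta_t`, `R_before`, `R`,
#'   `ratio` (= `R_before / R`).
#' @export
run_random_delay <- function(epochs = 1000, range = c(-10e-3, 10e-3),
                             initial_R = 2.0e7, seed = 1,
                             device = device_params(),
                             protocol = protocol_params()) {
  set.seed(seed)
  syn <- synapse_1t1r(pcm_state(state_from_resistance(initial_R, device),
                                device),
                      device_params = device)
  dts <- stats::runif(epochs, range[1], range[2])
  R_before <- R_after <- numeric(epochs)
  for (e in seq_len(epochs)) {
    R_before[e] <- pcm_resistance(syn$device, device)
    syn <- apply_stdp(syn, stdp_event(0, dts[e]), protocol)
    R_after[e] <- pcm_resistance(syn$device, device)
  }
  data.frame(epoch = seq_len(epochs), delta_t = dts,
             R_before = R_before, R = R_after,
             ratio = R_before / R_after)
}

.duration_to_epochs <- function(duration, protocol) {
  n <- duration / protocol$t_ck
  stopifnot(abs(n - round(n)) < 1e-9)
  as.integer(round(n))
}

#' Single-pattern unsupervised learning
#'
#' The 784-PRE retina with a single POST neuron. One digit pattern and
#' white 1/0 noise are presented with probability 50% each; noise drives
#' the depression of background synapses while pattern-coincident fires
#' potentiate the pattern synapses. The trace monitors the mean pattern
#' and background conductances each epoch.
#'
#' @param duration Simulated time, seconds.
#' @param noise_density Fraction of PREs active per noise epoch.
#' @param pattern A [retina_pattern()]; default the "1" fixture.
#' @param pattern_prob Probability of a pattern epoch.
#' @param seed RNG seed (controls both the weight initialization and the
#'   epoch draws).
#' @param config A [network_config()]; `N` and `M` must be 784 and 1.
#' @return A list with `trace` (including `G_pattern_1`, `G_background_1`
#'   columns), `state`, `pattern`, and `report` (a
#'   [recognition_report()]).
#' @export
run_single_pattern <- function(duration = 7, noise_density = 51 / 784,
                               pattern = make_fixture_digits()[["1"]],
                               pattern_prob = 0.5, seed = 1,
                               config = network_config(N = 784, M = 1)) {
  config$seed <- seed
  state <- build_network(config, init = "random")
  sched <- make_schedule(list(pattern), pattern_prob, noise_density)
  idx <- pattern_active(pattern)
  monitor <- list(pattern = idx, background = setdiff(seq_len(config$N), idx))
  out <- run_epochs(state, sched,
                    .duration_to_epochs(duration, config$protocol),
                    monitor = monitor)
  out$pattern <- pattern
  out$report <- recognition_report(out$trace)
  out
}

#' Sequential learning: forget one pattern, learn another
#'
#' Presents the first pattern (with noise) for the first half of the run,
#' then switches to the second pattern. Synapses exclusive to the old
#' pattern are depressed, synapses exclusive to the new one potentiated,
#' while synapses in both or in neither keep their class. The monitor
#' tracks the four pixel classes separately.
#'
#' @param durations Two simulated times (seconds): first and second
#'   pattern phase.
#' @param patterns List of two [retina_pattern()]s.
#' @param noise_density Fraction of PREs active per noise epoch.
#' @param seed RNG seed.
#' @param config A [network_config()].
#' @return A list with `trace` (monitored classes `only1`, `only2`,
#'   `both`, `background`), `state`, and `patterns`.
#' @export
run_sequential <- function(durations = c(7, 7),
                           patterns = make_fixture_digits()[c("1", "2")],
                           noise_density = 51 / 784, seed = 1,
                           config = network_config(N = 784, M = 1)) {
  stopifnot(length(durations) == 2, length(patterns) == 2)
  config$seed <- seed
  state <- build_network(config, init = "random")
  i1 <- pattern_active(patterns[[1]])
  i2 <- pattern_active(patterns[[2]])
  monitor <- list(only1 = setdiff(i1, i2), only2 = setdiff(i2, i1),
                  both = intersect(i1, i2),
                  background = setdiff(seq_len(config$N), union(i1, i2)))
  out1 <- run_epochs(state, make_schedule(patterns[1], 0.5, noise_density),
                     .duration_to_epochs(durations[1], config$protocol),
                     monitor = monitor)
  out2 <- run_epochs(out1$state,
                     make_schedule(patterns[2], 0.5, noise_density),
                     .duration_to_epochs(durations[2], config$protocol),
                     monitor = monitor)
  out2$trace$epoch <- out2$trace$epoch + nrow(out1$trace)
  list(trace = rbind(out1$trace, out2$trace), state = out2$state,
       patterns = patterns)
}

#' Parallel learning of multiple patterns with lateral inhibition
#'
#' Several POST neurons compete through fixed-weight inhibitory synapses
#' (partial discharge of all siblings on every fire) while several
#' patterns are presented at a low rate amid frequent sparse noise. Each
#' POST eventually specializes on some pattern; duplicates are possible
#' at the default 20% inhibition strength.
#'
#' @param duration Simulated time, seconds.
#' @param patterns List of [retina_pattern()]s.
#' @param pattern_prob Presentation probability of each pattern.
#' @param noise_density Fraction of PREs active per noise epoch.
#' @param M Number of competing POST neurons.
#' @param discharge_fraction Inhibitory discharge fraction.
#' @param seed RNG seed.
#' @return A list with `trace` (per-pattern and background mean
#'   conductances per POST), `state`, and `patterns`.
#' @export
run_parallel <- function(duration = 300,
                         patterns = make_fixture_digits(),
                         pattern_prob = 0.05,
                         noise_density = 4 / 784,
                         M = 3, discharge_fraction = 0.2, seed = 1) {
  config <- network_config(N = 784, M = M,
                           inhibition = inhibition_config(discharge_fraction),
                           inhibition_on = TRUE, seed = seed)
  state <- build_network(config, init = "random")
  sched <- make_schedule(patterns, rep(pattern_prob, length(patterns)),
                         noise_density)
  idx <- lapply(patterns, pattern_active)
  monitor <- c(stats::setNames(idx, paste0("p", seq_along(idx))),
               list(background = setdiff(seq_len(config$N),
                                         unique(unlist(idx)))))
  out <- run_epochs(state, sched,
                    .duration_to_epochs(duration, config$protocol),
                    monitor = monitor)
  out$patterns <- patterns
  out
}

#' Repeated recognition runs of a 2- or 3-layer network
#'
#' Runs `runs` independent simulations (fresh random weights and input
#' draws each) of pattern-plus-noise presentation and computes the
#' recognition probability `P_learn` and error probability `P_err` of the
#' output neuron in each.
#'
#' @param M Second-layer size for a 3-layer network, or `NULL` for the
#'   2-layer baseline (784 PREs, one POST).
#' @param runs Number of independent simulations.
#' @param duration Simulated time per run, seconds.
#' @param noise_density Fraction of PREs active per noise epoch.
#' @param pattern A [retina_pattern()].
#' @param seed Master seed; per-run seeds are derived from it.
#' @return A data frame with one row per run: `P_learn`, `P_err` and the
#'   underlying counts.
#' @export
run_recognition <- function(M = NULL, runs = 100, duration = 2,
                            noise_density = 51 / 784,
                            pattern = make_fixture_digits()[["1"]],
                            seed = 1) {
  set.seed(seed)
  run_seeds <- sample.int(2147483646L, runs)
  sched <- make_schedule(list(pattern), 0.5, noise_density)
  res <- vector("list", runs)
  for (r in seq_len(runs)) {
    config <- if (is.null(M)) {
      network_config(N = 784, M = 1, layers = 2, seed = run_seeds[r])
    } else {
      network_config(N = 784, M = M, layers = 3, seed = run_seeds[r])
    }
    state <- build_network(config, init = "random")
    out <- run_epochs(state, sched,
                      .duration_to_epochs(duration, config$protocol))
    rep <- recognition_report(out$trace)
    res[[r]] <- data.frame(run = r, seed = run_seeds[r],
                           n_p = rep$n_p, n_n = rep$n_n,
                           n_p_f = rep$n_p_f, n_n_f = rep$n_n_f,
                           P_learn = rep$P_learn, P_err = rep$P_err)
  }
  do.call(rbind, res)
}

#' Recognition sweep over the second-layer size
#'
#' Repeats the recognition experiment for each second-layer size (with
#' the 2-layer 784-to-1 network as optional baseline) and averages
#' `P_learn` and `P_err` over the runs.
#'
#' @param M_values Second-layer sizes to sweep.
#' @param runs Independent simulations per size.
#' @param duration Simulated time per run, seconds.
#' @param noise_density Fraction of PREs active per noise epoch.
#' @param seed Master seed.
#' @param include_baseline Prepend the 2-layer baseline row (`M = NA`)?
#' @return A list with `summary` (one row per network) and `runs` (the
#'   raw per-run table with an `M` column; `NA` = 2-layer baseline).
#' @export
run_multilayer_sweep <- function(M_values = c(4, 16, 64, 128, 256),
                                 runs = 100, duration = 2,
                                 noise_density = 51 / 784, seed = 1,
                                 include_baseline = TRUE) {
  configs <- c(if (include_baseline) list(NULL), as.list(M_values))
  raw <- list()
  for (i in seq_along(configs)) {
    M <- configs[[i]]
    # common random numbers across the sweep: every network size sees the
    # same per-run seeds, so the M comparison is not blurred by
    # between-condition sampling noise
    tab <- run_recognition(M = M, runs = runs, duration = duration,
                           noise_density = noise_density, seed = seed)
    tab$M <- if (is.null(M)) NA_integer_ else M
    raw[[i]] <- tab
  }
  raw <- do.call(rbind, raw)
  summary <- do.call(rbind, lapply(split(raw, raw$M, drop = FALSE), function(d)
    data.frame(M = d$M[1], runs = nrow(d),
               P_learn = mean(d$P_learn), P_err = mean(d$P_err))))
  summary <- summary[order(is.na(summary$M), summary$M, decreasing = FALSE), ]
  baseline <- raw[is.na(raw$M), , drop = FALSE]
  if (nrow(baseline) > 0) {
    summary <- rbind(data.frame(M = NA_integer_, runs = nrow(baseline),
                                P_learn = mean(baseline$P_learn),
                                P_err = mean(baseline$P_err)),
                     summary[!is.na(summary$M), ])
  }
  rownames(summary) <- NULL
  list(summary = summary, runs = raw)
}

#' Recognition sweep over the input noise density
#'
#' Repeats the recognition experiment for each noise density. Rising
#' noise speeds background depression but increasingly forgets the
#' pattern and triggers spurious fires, so `P_learn` falls and `P_err`
#' rises with density.
#'
#' @param densities Noise densities (fractions of PREs active per noise
#'   epoch).
#' @param M Second-layer size (`NULL` = 2-layer baseline).
#' @param runs Independent simulations per density.
#' @param duration Simulated time per run, seconds.
#' @param seed Master seed.
#' @return A list with `summary` (one row per density) and `runs` (raw
#'   per-run table with a `noise_density` column).
#' @export
run_noise_sweep <- function(densities = c(0.04, 0.055, 0.065, 0.08, 0.10),
                            M = NULL, runs = 100, duration = 2, seed = 1) {
  raw <- list()
  for (i in seq_along(densities)) {
    # common random numbers across densities (see run_multilayer_sweep)
    tab <- run_recognition(M = M, runs = runs, duration = duration,
                           noise_density = densities[i], seed = seed)
    tab$noise_density <- densities[i]
    raw[[i]] <- tab
  }
  raw <- do.call(rbind, raw)
  summary <- do.call(rbind, lapply(split(raw, raw$noise_density), function(d)
    data.frame(noise_density = d$noise_density[1], runs = nrow(d),
               P_learn = mean(d$P_learn), P_err = mean(d$P_err))))
  rownames(summary) <- NULL
  list(summary = summary[order(summary$noise_density), ], runs = raw)
}
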