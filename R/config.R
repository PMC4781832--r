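#' Read a simulation configuration file
#'
#' YAML configuration with optional sections `device`, `synapse`,
#' `protocol`, `neuron`, `network`, `inhibition` and `schedule`, each a
#' flat key/value map in SI units whose keys mirror the corresponding
#' constructor arguments ([device_params()], [synapse_params()],
#' [protocol_params()], [network_config()], [inhibition_config()]).
#' Missing keys fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with a `network` ([network_config()]) element and, if a
#'   `schedule` section is present, a `schedule` element (list of
#'   [make_schedule()] arguments resolved against the fixture digits).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  take <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) fn() else do.call(fn, args)
  }
  device <- take("device", device_params)
  synapse <- take("synapse", synapse_params)
  protocol <- take("protocol", protocol_params)
  inhib <- take("inhibition", inhibition_config)
  net_args <- raw[["network"]]
  if (is.null(net_args)) net_args <- list()
  neuron <- raw[["neuron"]]
  if (!is.null(neuron)) {
    for (k in intersect(names(neuron), c("V_th", "C_hidden", "C_out",
                                         "tau_leak")))
      net_args[[k]] <- neuron[[k]]
  }
  if (is.character(net_args$tau_leak))
    net_args$tau_leak <- as.numeric(net_args$tau_leak)
  net_args$device <- device
  net_args$synapse <- synapse
  net_args$protocol <- protocol
  net_args$inhibition <- inhib
  out <- list(network = do.call(network_config, net_args))
  if (!is.null(raw$schedule)) {
    s <- raw$schedule
    digits <- make_fixture_digits()
    pats <- lapply(as.character(s$patterns %||% character(0)),
                   function(d) digits[[d]])
    out$schedule <- make_schedule(
      pats,
      as.numeric(s$pattern_probs %||% rep(0, length(pats))),
      s$noise_density %||% (51 / 784),
      s$mode %||% "bernoulli")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the default configuration to a YAML file
#'
#' Emits a file with every section fully populated from the package
#' defaults, as a template for custom runs.
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path) {
  d <- unclass(device_params())
  s <- unclass(synapse_params())
  p <- unclass(protocol_params())
  cfg <- list(
    device = d,
    synapse = s,
    protocol = p,
    neuron = list(V_th = 0.5, tau_leak = 0.15),
    network = list(N = 784L, M = 1L, layers = 2L, inhibition_on = FALSE),
    inhibition = list(discharge_fraction = 0.2),
    schedule = list(patterns = list("1"), pattern_probs = list(0.5),
                    noise_density = 51 / 784, mode = "bernoulli"))
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}
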