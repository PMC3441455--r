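#' Simulation and analysis run configuration
#'
#' Collects every tunable of a simulation/analysis run: the reduced
#' temperature ladder, step counts, periodic box edge, receptor restraint
#' coefficient, state thresholds, clustering cutoff, histogram bin widths
#' and the random seed. Values default to the package's standard study
#' conditions (150 Angstrom box; bound/unbound thresholds 5/25 Angstrom with
#' a 20-contact bound requirement; 1 Angstrom / 1 contact / 0.05 bin widths).
#'
#' @param temperatures Strictly increasing reduced temperatures.
#' @param n_steps Monte Carlo steps per run.
#' @param box_length Periodic cube edge, Angstrom.
#' @param k_restraint Receptor restraint coefficient, energy * Angstrom^-2.
#' @param delta_bound,nc_bound,delta_unbound State thresholds: bound iff
#'   `delta <= delta_bound` and `nc >= nc_bound`; unbound iff
#'   `delta >= delta_unbound`; intermediate otherwise.
#' @param cluster_cutoff Complete-linkage cutoff, Angstrom.
#' @param bin_width_delta,bin_width_nc,bin_width_helix Histogram bin widths.
#' @param save_interval Steps between saved frames.
#' @param seed Integer random seed.
#' @return Object of class `bs_run_config` (a validated named list).
#' @export
run_config <- function(temperatures = c(1.0),
                       n_steps = 100000L,
                       box_length = 150,
                       k_restraint = 2,
                       delta_bound = 5,
                       nc_bound = 20,
                       delta_unbound = 25,
                       cluster_cutoff = 8,
                       bin_width_delta = 1,
                       bin_width_nc = 1,
                       bin_width_helix = 0.05,
                       save_interval = 1000L,
                       seed = 1L) {
  cfg <- structure(list(
    temperatures = as.numeric(temperatures),
    n_steps = as.integer(n_steps),
    box_length = as.numeric(box_length),
    k_restraint = as.numeric(k_restraint),
    delta_bound = as.numeric(delta_bound),
    nc_bound = as.numeric(nc_bound),
    delta_unbound = as.numeric(delta_unbound),
    cluster_cutoff = as.numeric(cluster_cutoff),
    bin_width_delta = as.numeric(bin_width_delta),
    bin_width_nc = as.numeric(bin_width_nc),
    bin_width_helix = as.numeric(bin_width_helix),
    save_interval = as.integer(save_interval),
    seed = as.integer(seed)), class = "bs_run_config")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  with(cfg, {
    if (!length(temperatures) || any(diff(temperatures) <= 0))
      stop("temperatures must be non-empty and strictly increasing")
    if (any(temperatures <= 0)) stop("temperatures must be positive")
    if (n_steps <= 0) stop("n_steps must be positive")
    if (box_length <= 0) stop("box_length must be positive")
    if (!(delta_bound < delta_unbound))
      stop("delta_bound must be smaller than delta_unbound")
    if (any(c(bin_width_delta, bin_width_nc, bin_width_helix) <= 0))
      stop("histogram bin widths must be positive")
    if (save_interval <= 0) stop("save_interval must be positive")
  })
  cfg
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `bs_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param cfg A `bs_run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
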