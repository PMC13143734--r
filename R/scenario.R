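# Scripted scenario fixtures and YAML configuration I/O.

scenario_registry <- function() c("adam-apple")

#' Load a named scenario fixture
#'
#' `"adam-apple"` encodes the deviant-forager narrative: Adam and Eve
#' (band A) meet Charles and Pete (band B) at a shared campsite. Adam is
#' scripted: he shares once while paired with Pete, forages, then conceals
#' a harvest at tick 10. Pete, a two-level watcher, scores Adam's actions
#' under the cultural versus egocentric model; the conceal observation
#' (detection is certain in this scenario) collapses P(cultural), Pete
#' declares, and the sanction confiscates Adam's inventory, banishes him
#' and raises every observer's effective alpha.
#'
#' @param name Scenario name; unknown names raise an error listing the
#'   available scenarios.
#' @return A simulation config for [run_simulation()] (sections `world`,
#'   `agents`, `experiment` including the scripted action and pairing
#'   overrides).
#' @export
load_scenario <- function(name) {
  if (!name %in% scenario_registry()) {
    stop("unknown scenario '", name, "'; available: ",
         paste(scenario_registry(), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".yaml"),
                      package = "transcend")
  if (!nzchar(path)) {
    stop("scenario file missing from installation", call. = FALSE)
  }
  read_config_yaml(path)
}

#' Read a simulation config from YAML
#'
#' Sections `world`, `agents`, `experiment`; scripted overrides
#' (`experiment$action_script`, `experiment$pairing_script`) are lists of
#' records converted to data frames. The world section is validated
#' immediately via [world_config()].
#'
#' @param path YAML file path.
#' @return Config list for [run_simulation()].
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$world) || is.null(y$agents)) {
    stop("config validation: sections 'world' and 'agents' are required",
         call. = FALSE)
  }
  cfg <- do.call(world_config, y$world)   # validates field ranges
  ex <- y$experiment %||% list()
  to_df <- function(recs) {
    if (is.null(recs)) return(NULL)
    do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
  }
  ex$action_script <- to_df(ex$action_script)
  ex$pairing_script <- to_df(ex$pairing_script)
  list(world = cfg, agents = y$agents, experiment = ex)
}

#' Write a simulation config to YAML
#'
#' @param config Config list (as accepted by [run_simulation()]).
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_config_yaml <- function(config, path) {
  w <- config$world
  if (inherits(w, "world_config")) w <- unclass(w)
  ex <- config$experiment %||% list()
  from_df <- function(df) {
    if (is.null(df)) return(NULL)
    lapply(seq_len(nrow(df)), function(r) as.list(df[r, ]))
  }
  ex$action_script <- from_df(ex$action_script)
  ex$pairing_script <- from_df(ex$pairing_script)
  yaml::write_yaml(list(world = w, agents = config$agents,
                        experiment = ex), path)
  invisible(path)
}
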