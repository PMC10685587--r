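# Run configuration: YAML key-value files with documented defaults.

.config_defaults <- function() {
  list(
    v_w = 30.0,          # molecular volume of liquid water, A^3
    seed = 0L,           # master random seed
    tol = 1e-8,          # generic numerical tolerance
    n_points = 513L,     # default synthesis grid size
    out_dir = ".",       # default artifact directory
    log_level = "info"
  )
}

#' Build a run configuration
#'
#' @param ... overrides of the documented defaults (`v_w`, `seed`, `tol`,
#'   `n_points`, `out_dir`, `log_level`)
#' @return an object of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    lam_log("warning", "config", "ignoring unknown configuration key(s): %s",
            paste(unknown, collapse = ", "))
    over <- over[setdiff(names(over), unknown)]
  }
  cfg <- modifyList(cfg, over)
  check_number(cfg$v_w, "v_w", 0, strict_lower = TRUE)
  if (!is.numeric(cfg$seed) || cfg$seed < 0 || cfg$seed != round(cfg$seed)) {
    lam_abort("seed must be a non-negative integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  check_number(cfg$tol, "tol", 0, strict_lower = TRUE)
  structure(cfg, class = "run_config")
}

#' Load a YAML run configuration
#'
#' Missing keys take the documented defaults, unknown keys produce a logged
#' warning, and the effective configuration is logged in full.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults
#' @return a `run_config`
#' @export
load_config <- function(path = NULL) {
  over <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      lam_abort("config file '%s' does not exist", path, class = "lamellar_io_error")
    }
    over <- tryCatch(yaml::read_yaml(path), error = function(e) {
      lam_abort("cannot parse config '%s': %s", path, conditionMessage(e),
                class = "lamellar_format_error")
    })
    if (is.null(over)) over <- list()
  }
  cfg <- do.call(run_config, over)
  lam_log("info", "config", "effective configuration: %s",
          paste(sprintf("%s=%s", names(cfg), unlist(lapply(cfg, format))),
                collapse = ", "))
  cfg
}
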