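#' Load and resolve a run configuration
#'
#' Run configurations are flat YAML files with up to four blocks --
#' `model`, `tissue`, `integration`, `scenario` -- each holding only the
#' keys below; unknown keys are rejected by name. Model parameters may also
#' be given at the top level as shorthand (e.g. a file containing just
#' `b: 0.01`). An empty file resolves to the reference parameterization and
#' the development scenario defaults.
#'
#' Recognized keys:
#' \itemize{
#'   \item `model`: `a, b, c, q, r, s, n, eta_x, eta_y`
#'   \item `tissue`: `topology` (`hex_lattice`/`triangle3`), `width`,
#'     `height`, `density`, `boundary`, `mask` (CSV path)
#'   \item `integration`: `dt`, `t_end`, `seed`, `noise_on`,
#'     `record_every`, `t_pre`
#'   \item `scenario`: `name` (`development`, `conversion_stab`,
#'     `conversion_both`, `inhibition_only`, `recovery`, `density_sweep`,
#'     `shape_sweep`), `replicates`, `t_rec`, `densities`, `b_values`,
#'     `y_threshold`, `z_threshold`, `schedule` (list of
#'     `time`/`parameter`/`value` entries)
#' }
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A `run_config` list with fully resolved `model` (a
#'   [model_params()] object), `tissue`, `integration` and `scenario`
#'   blocks.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    # keep the literal keys "n"/"y" (YAML 1.1 would read them as booleans)
    y <- yaml::read_yaml(path, handlers = list(
      "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE,
      "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE))
    if (is.null(y)) list() else y
  }
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  param_keys <- c("a", "b", "c", "q", "r", "s", "n", "eta_x", "eta_y")
  blocks <- c("model", "tissue", "integration", "scenario")
  unknown <- setdiff(names(raw), c(blocks, param_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  model_in <- c(raw$model, raw[intersect(names(raw), param_keys)])
  check_keys(model_in, param_keys, "model")
  model <- do.call(model_params, model_in)

  tissue_def <- list(topology = "hex_lattice", width = 30L, height = 30L,
                     density = 1, boundary = "periodic", mask = NULL)
  tissue <- merge_block(raw$tissue, tissue_def, "tissue")
  if (!tissue$topology %in% c("hex_lattice", "triangle3"))
    stop("tissue$topology must be 'hex_lattice' or 'triangle3'",
         call. = FALSE)

  integ_def <- list(dt = 0.02, t_end = 100, seed = 1L, noise_on = TRUE,
                    record_every = 50L, t_pre = 0)
  integration <- merge_block(raw$integration, integ_def, "integration")

  scen_def <- list(name = "development", replicates = 20L, t_rec = NULL,
                   densities = c(0.25, 0.5, 0.75),
                   b_values = c(1, 0.1, 0.01),
                   y_threshold = 0.5, z_threshold = 0.5, schedule = NULL)
  scenario <- merge_block(raw$scenario, scen_def, "scenario")
  scen_names <- c("development", "conversion_stab", "conversion_both",
                  "inhibition_only", "recovery", "density_sweep",
                  "shape_sweep")
  if (!scenario$name %in% scen_names)
    stop("unknown scenario name '", scenario$name, "'; must be one of: ",
         paste(scen_names, collapse = ", "), call. = FALSE)

  structure(list(model = model, tissue = tissue,
                 integration = integration, scenario = scenario),
            class = "run_config")
}

check_keys <- function(given, allowed, block) {
  bad <- setdiff(names(given), allowed)
  if (length(bad))
    stop("unknown key(s) in '", block, "' block: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(given)
}

merge_block <- function(given, defaults, block) {
  if (is.null(given)) return(defaults)
  check_keys(given, names(defaults), block)
  modifyList(defaults, given, keep.null = TRUE)
}

#' Write a fully-resolved configuration next to run outputs
#'
#' Every run emits a resolved copy of its configuration (all defaults made
#' explicit) so outputs are reproducible from the file alone.
#'
#' @param config A `run_config` from [load_config()].
#' @param path Output path (YAML).
#' @export
write_config <- function(config, path) {
  out <- list(model = unclass(config$model), tissue = config$tissue,
              integration = config$integration,
              scenario = config$scenario)
  drop_null <- function(x)
    if (is.list(x)) lapply(Filter(Negate(is.null), x), drop_null) else x
  yaml::write_yaml(drop_null(out), path)
  invisible(path)
}
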