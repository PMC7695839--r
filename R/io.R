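#' Parse a run configuration from YAML
#'
#' Reads a structured plain-text configuration (community parameters plus
#' optional module blocks for wavenumber grids, phase axes and simulation
#' settings), validates every field through the [community_params()]
#' invariants, and fills documented defaults. Invariant violations name the
#' offending field and the violated constraint.
#'
#' @param path Path to a YAML file, or a named list with the same structure.
#' @return An object of class `run_config`: list with `params`
#'   ([community_params()]), `seed`, `q_grid` (NULL for the default grid),
#'   `sim` (arguments for [sim_config()]), `phase` (axis specs), `out_dir`,
#'   and `raw` (the resolved input).
#' @examples
#' cfg <- parse_config(list(params = list(N = 100, C = 0.2, c = 0.5), seed = 7))
#' cfg$params$N
#' @export
parse_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    # keep YAML-1.1 boolean-like scalars (N, n, y, ...) verbatim so that they
    # survive as keys; boolean values are coerced where they are consumed
    yaml::read_yaml(path, handlers = list(
      "bool#yes" = function(x) if (x %in% c("true", "True", "TRUE")) TRUE else x,
      "bool#no" = function(x) if (x %in% c("false", "False", "FALSE")) FALSE else x))
  } else if (is.list(path)) path
  else stop("parse_config: `path` must be a file path or a list")
  if (is.null(raw$params)) stop("parse_config: missing `params` block")
  # manifests carry the derived fields too; they are recomputed on re-parse
  raw$params <- raw$params[setdiff(names(raw$params),
                                   c("N_v", "gamma_u", "gamma_v"))]
  known <- names(formals(community_params))
  unknown <- setdiff(names(raw$params), known)
  if (length(unknown)) {
    stop("parse_config: unknown params field(s): ",
         paste(unknown, collapse = ", "))
  }
  params <- do.call(community_params, raw$params)
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  q_grid <- if (!is.null(raw$q_grid)) {
    qg <- raw$q_grid
    if (!is.null(qg$q_max) || !is.null(qg$n)) {
      default_q_grid(params,
                     n = if (is.null(qg$n)) 60L else as.integer(qg$n),
                     q_max = qg$q_max)
    } else as.numeric(unlist(qg))
  } else NULL
  raw$seed <- seed
  structure(list(params = params, seed = seed, q_grid = q_grid,
                 sim = raw$sim, phase = raw$phase,
                 out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
                 raw = raw),
            class = "run_config")
}

#' Write a run manifest
#'
#' Records the fully resolved configuration, the seed and the package version
#' alongside a run's outputs, so that any output can be regenerated from its
#' manifest: re-parsing the manifest with [parse_config()] reproduces an
#' identical `run_config`.
#'
#' @param config A [parse_config()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  resolved <- config$raw
  resolved$params <- unclass(config$params)
  resolved$package_version <- as.character(utils::packageVersion("ecostab"))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(resolved, path)
  invisible(path)
}

#' Tabular writers for analysis results
#'
#' CSV writers (with headers) for the package's result types; all outputs are
#' round-trippable with [readr::read_csv()].
#'
#' @param x A result object (`bulk_boundary`, `outlier_set`,
#'   `dispersion_relation`, `phase_diagram`, `spectrum_result`, or a plain
#'   data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  tbl <- if (inherits(x, "bulk_boundary")) {
    dplyr::mutate(x$curve, q = x$q, .before = 1)
  } else if (inherits(x, "outlier_set")) {
    tibble::tibble(q = x$q, re = Re(x$values$omega), im = Im(x$values$omega),
                   admissible = x$values$admissible,
                   near_edge = x$values$near_edge)
  } else if (inherits(x, "spectrum_result")) {
    tidy(x)
  } else if (inherits(x, "phase_diagram")) {
    x$cells
  } else if (is.data.frame(x)) {
    x
  } else stop("write_result_csv: unsupported type ", paste(class(x), collapse = "/"))
  readr::write_csv(tbl, path)
  invisible(path)
}
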