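#' Load a model configuration from a YAML file
#'
#' The file may name a \code{preset} (\code{fig2}..\code{fig5}) and/or give
#' scalar fields; explicit fields override the preset. Recognised keys:
#' \code{preset}, \code{k_fast}, \code{u_fast}, \code{k_slow}, \code{u_slow},
#' \code{alpha}, \code{beta}, \code{sigma}, \code{threshold},
#' \code{max_steps}, \code{init} (length-2), \code{seed}, \code{n_trials},
#' and an optional \code{sweep} block (\code{parameter}, \code{values},
#' \code{n_per_value}). Unspecified fields take the documented defaults
#' (sigma 0.01, threshold 30, max_steps 50000, init (0, 0)). Unknown keys
#' are an error, not a warning.
#'
#' @param path Path to a YAML file.
#' @return A list with \code{model} (a [perspective_model()]), \code{seed},
#'   \code{n_trials}, and \code{sweep} (\code{NULL} or the sweep block).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("config parse failure in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("preset", .param_paths, "threshold", "max_steps", "init",
             "seed", "n_trials", "sweep")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  base <- if (!is.null(cfg$preset)) coef(preset(cfg$preset)) else NULL
  get <- function(key, default) {
    if (!is.null(cfg[[key]])) cfg[[key]]
    else if (!is.null(base) && key %in% names(base)) unname(base[[key]])
    else default
  }
  model <- withCallingHandlers(
    perspective_model(
      k_fast = get("k_fast", 0), u_fast = get("u_fast", 0.2),
      k_slow = get("k_slow", 0), u_slow = get("u_slow", 0.2),
      alpha = get("alpha", 0), beta = get("beta", 0),
      sigma = get("sigma", .defaults$sigma),
      threshold = get("threshold", .defaults$threshold),
      max_steps = get("max_steps", .defaults$max_steps),
      init = get("init", .defaults$init)),
    error = function(e) e)
  if (!is.null(cfg$preset) && is.null(cfg$k_fast) && is.null(cfg$u_fast))
    model$preset <- cfg$preset

  sweep <- cfg$sweep
  if (!is.null(sweep)) {
    if (is.null(sweep$parameter) || is.null(sweep$values))
      stop("sweep block needs `parameter` and `values`", call. = FALSE)
    if (!sweep$parameter %in% .param_paths)
      stop("unknown sweep parameter: ", sweep$parameter, call. = FALSE)
  }
  list(model = model,
       seed = as.integer(get("seed", 1L)),
       n_trials = as.integer(get("n_trials", 500L)),
       sweep = sweep)
}

#' Run manifest: the full resolved configuration of a run
#'
#' Every output file written by the package embeds this manifest as
#' commented header lines, so each file is traceable to the exact
#' configuration and seed that produced it. The manifest holds every
#' numeric parameter affecting the output; the wall-clock timestamp is
#' logged to standard error rather than written into files, so that
#' re-running a configuration reproduces output files bitwise.
#'
#' @param model A [perspective_model()].
#' @param seed Seed(s) used.
#' @param ... Further scalar fields to record (e.g. \code{n_trials}).
#' @return Named list of manifest fields.
#' @export
run_manifest <- function(model, seed = NULL, ...) {
  model <- as_perspective_model(model)
  c(list(artifact = "perspectr",
         version = as.character(utils::packageVersion("perspectr"))),
    as.list(coef(model)),
    list(max_steps = model$max_steps,
         init_fast = model$init[[1L]], init_slow = model$init[[2L]],
         preset = if (is.null(model$preset)) NA else model$preset,
         seed = if (is.null(seed)) NA else seed),
    list(...))
}

manifest_header <- function(manifest) {
  vapply(names(manifest), function(k)
    sprintf("# %s: %s", k, format(manifest[[k]], digits = 15)), "")
}

write_table_with_manifest <- function(df, path, manifest) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write '", path, "': ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(manifest_header(manifest), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write batch results as tidy CSV with a manifest header
#'
#' One data row per trial (trial index, per-trial seed, outcome, winner,
#' steps, final accumulators), preceded by \code{#}-commented manifest
#' lines. Round-trips through [read_results()].
#'
#' @param batch A \code{perspective_batch}.
#' @param path Destination file.
#' @param trajectories Also write the long-format trajectory table (only
#'   possible if the batch kept states)? If \code{TRUE}, written to
#'   \code{path} with suffix \code{"_trajectories"} before the extension.
#' @return The path, invisibly.
#' @export
write_results <- function(batch, path, trajectories = FALSE) {
  stopifnot(inherits(batch, "perspective_batch"))
  mf <- run_manifest(batch$model, seed = batch$seed,
                     n_trials = batch$n_trials)
  write_table_with_manifest(as.data.frame(batch), path, mf)
  if (trajectories) {
    tp <- sub("(\\.[^.]*)?$", "_trajectories\\1", path)
    write_table_with_manifest(trajectories(batch), tp, mf)
  }
  invisible(path)
}

#' Read back a results or field table written by this package
#'
#' @param path File written by [write_results()], [write_field()] or
#'   [write_sweep()].
#' @return The data frame (manifest lines are attached as attribute
#'   \code{"manifest"}, a character vector).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  attr(df, "manifest") <- hdr
  df
}

#' Write a vector field as long-format CSV with a manifest header
#'
#' @param field A \code{vector_field_grid} (see [vector_field()]).
#' @param path Destination file.
#' @param model The model that produced the field (for the manifest).
#' @return The path, invisibly.
#' @export
write_field <- function(field, path, model) {
  stopifnot(inherits(field, "vector_field_grid"))
  mf <- run_manifest(model, resolution = length(field$x),
                     x_min = min(field$x), x_max = max(field$x))
  write_table_with_manifest(as.data.frame(field), path, mf)
}

#' Write a sweep result as tidy CSV with a manifest header
#'
#' @param sweep A \code{sweep_result} (see [sweep_parameter()]).
#' @param path Destination file.
#' @param model The base model of the sweep.
#' @return The path, invisibly.
#' @export
write_sweep <- function(sweep, path, model) {
  stopifnot(inherits(sweep, "sweep_result"))
  mf <- run_manifest(model, seed = attr(sweep, "seed"),
                     swept_parameter = attr(sweep, "parameter"))
  write_table_with_manifest(as.data.frame(sweep), path, mf)
}
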