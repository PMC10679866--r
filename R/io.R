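config_scalar_keys <- function() {
  c("Konc", "Konm", "Koffc", "Koffm", "Kc", "Km", "n", "delta",
    "dpsi_m0", "dpsi_pm", "tht_ext", "tmrm_ext",
    "tht_permeability_plasma", "tht_permeability_mito",
    "tmrm_permeability_plasma", "tmrm_permeability_mito",
    "temperature", "solver_rtol", "solver_atol")
}

#' Load and validate a model/experiment configuration
#'
#' Reads a flat YAML document holding model parameters (field names as in
#' [model_parameters()], plus `tht_permeability_plasma` etc. for the dye
#' permeabilities and `temperature`), solver settings (`solver_rtol`,
#' `solver_atol`) and an `events` list of maps with keys `t`, `type`
#' (`set_reservoir`/`scale_kon`/`fccp`) and the event's own fields.
#' Missing keys take package defaults; unknown keys are rejected with
#' their names; all values are range-checked.
#'
#' @param path Path to a YAML file. An empty file yields the full default
#'   configuration.
#'
#' @return List with elements `params` ([model_parameters()]), `solver`
#'   (list `rtol`, `atol`), `events` ([event_schedule()]), and `raw`
#'   (canonical key-value form).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  known <- c(config_scalar_keys(), "events")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  bad <- names(cfg)[vapply(cfg, function(v)
    !is.list(v) && !(is.numeric(v) && length(v) == 1L && is.finite(v)),
    logical(1))]
  bad <- setdiff(bad, "events")
  if (length(bad))
    stop("non-numeric value for key(s): ", paste(bad, collapse = ", "))
  get_or <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  def <- model_parameters()
  params <- model_parameters(
    Konc = get_or("Konc", def$Konc), Konm = get_or("Konm", def$Konm),
    Koffc = get_or("Koffc", def$Koffc), Koffm = get_or("Koffm", def$Koffm),
    Kc = get_or("Kc", def$Kc), Km = get_or("Km", def$Km),
    n = get_or("n", def$n), delta = get_or("delta", def$delta),
    dpsi_m0 = get_or("dpsi_m0", def$dpsi_m0),
    dpsi_pm = get_or("dpsi_pm", def$dpsi_pm),
    tht_ext = get_or("tht_ext", def$tht_ext),
    tmrm_ext = get_or("tmrm_ext", def$tmrm_ext),
    tht = dye_spec("ThT", 1L,
      permeability_plasma = get_or("tht_permeability_plasma",
                                   def$tht$permeability_plasma),
      permeability_mito = get_or("tht_permeability_mito",
                                 def$tht$permeability_mito),
      photoactive = TRUE),
    tmrm = dye_spec("TMRM", 1L,
      permeability_plasma = get_or("tmrm_permeability_plasma",
                                   def$tmrm$permeability_plasma),
      permeability_mito = get_or("tmrm_permeability_mito",
                                 def$tmrm$permeability_mito),
      photoactive = FALSE),
    constants = physical_constants(
      temperature = get_or("temperature",
                           def$constants$temperature)))
  solver <- list(rtol = get_or("solver_rtol", 1e-8),
                 atol = get_or("solver_atol", 1e-12))
  events <- do.call(event_schedule, lapply(cfg$events, parse_event))
  list(params = params, solver = solver, events = events,
       raw = canonical_config(params, solver, events))
}

parse_event <- function(e) {
  if (is.null(e$t) || is.null(e$type)) stop("event needs keys 't' and 'type'")
  switch(as.character(e$type),
    set_reservoir = ev_set_reservoir(e$t, e$dye, e$value),
    scale_kon = ev_scale_kon(e$t, e$value),
    fccp = ev_fccp(e$t,
                   target = if (is.null(e$target)) -10 else e$target,
                   tau = if (is.null(e$tau)) 60 else e$tau),
    stop("unknown event type: ", e$type))
}

canonical_config <- function(params, solver, events) {
  ev <- lapply(unclass(events), function(e) {
    e <- unclass(e)
    names(e)[names(e) == "time"] <- "t"
    names(e)[names(e) == "factor"] <- "value"
    e
  })
  list(Konc = params$Konc, Konm = params$Konm,
       Koffc = params$Koffc, Koffm = params$Koffm,
       Kc = params$Kc, Km = params$Km, n = params$n, delta = params$delta,
       dpsi_m0 = params$dpsi_m0, dpsi_pm = params$dpsi_pm,
       tht_ext = params$tht_ext, tmrm_ext = params$tmrm_ext,
       tht_permeability_plasma = params$tht$permeability_plasma,
       tht_permeability_mito = params$tht$permeability_mito,
       tmrm_permeability_plasma = params$tmrm$permeability_plasma,
       tmrm_permeability_mito = params$tmrm$permeability_mito,
       temperature = params$constants$temperature,
       solver_rtol = solver$rtol, solver_atol = solver$atol,
       events = ev)
}

#' @rdname load_config
#' @param config A list as returned by `load_config()`.
#' @param path Output YAML path.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

fmt12 <- function(x) signif(x, 12)

#' Write a trajectory to CSV with a JSON sidecar
#'
#' The CSV has columns `time_s`, the six state variables and `dpsi_m_mV`
#' (12 significant digits); the sidecar `<path>.json` records the resolved
#' parameters, schedule, solver settings and package version, enough to
#' re-run the simulation.
#'
#' @param traj A `dye_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "dye_trajectory"))
  df <- as.data.frame(lapply(as.data.frame(traj), fmt12))
  utils::write.csv(df, path, row.names = FALSE)
  p <- attr(traj, "parameters")
  sched <- attr(traj, "schedule")
  solver <- attr(traj, "solver")
  meta <- list(
    package = "thtmito",
    version = as.character(utils::packageVersion("thtmito")),
    parameters = canonical_config(p, list(rtol = solver$rtol,
                                          atol = solver$atol), sched))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read/write trace sets as long-format CSV
#'
#' Columns: `cell_id`, `condition`, `channel`, `time_s`, `value`.
#'
#' @param ts A `trace_set`.
#' @param path CSV path.
#' @return `read_trace_csv` returns a `trace_set`; `write_trace_csv`
#'   returns `path` invisibly.
#' @export
write_trace_csv <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  df <- as.data.frame(ts)
  df$time_s <- fmt12(df$time_s)
  df$value <- fmt12(df$value)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  as_trace_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read/write multi-frame two-channel image stacks as TIFF
#'
#' Stacks are stored as 16-bit multi-page TIFF in TCYX page order (frame
#' major, channel minor); label masks as a single 16-bit page. Values are
#' scaled by 1/65535 on write and restored on read.
#'
#' @param stack Array `[frame, channel, y, x]` with values in
#'   `[0, 65535]`.
#' @param path TIFF path.
#' @param n_channels Channel count used to refold pages on read.
#' @return `read_stack_tiff` returns the array; writers return `path`
#'   invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 4L)
  pages <- list()
  for (fr in seq_len(dim(stack)[1L]))
    for (ci in seq_len(dim(stack)[2L]))
      pages[[length(pages) + 1L]] <- stack[fr, ci, , ] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, n_channels = 2L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  n_pages <- length(pages)
  if (n_pages %% n_channels != 0L)
    stop("page count is not a multiple of the channel count")
  n_frames <- n_pages %/% n_channels
  dims <- dim(pages[[1L]])
  stack <- array(0, c(n_frames, n_channels, dims[1L], dims[2L]))
  k <- 0L
  for (fr in seq_len(n_frames))
    for (ci in seq_len(n_channels)) {
      k <- k + 1L
      stack[fr, ci, , ] <- pages[[k]] * 65535
    }
  stack
}

#' @rdname write_stack_tiff
#' @param masks Integer label matrix (labels < 65536).
#' @export
write_mask_tiff <- function(masks, path) {
  stopifnot(is.matrix(masks), max(masks) < 65536)
  tiff::writeTIFF(masks / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a run manifest
#'
#' Records the command, resolved configuration, seed, package version,
#' timestamp and MD5 checksums of the produced files — enough to re-run a
#' deterministic command bit-identically (or a seeded one
#' distribution-identically).
#'
#' @param command Character label of the command that ran.
#' @param config Arbitrary (JSON-serializable) resolved configuration.
#' @param seed Integer seed used (or `NULL`).
#' @param outputs Character vector of produced file paths.
#' @param path Manifest JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, config, seed, outputs, path) {
  man <- list(command = command,
              package = "thtmito",
              version = as.character(utils::packageVersion("thtmito")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed,
              config = config,
              outputs = lapply(outputs, function(f)
                list(file = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}
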