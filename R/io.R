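#' Write a simulated session to plain-text files
#'
#' Writes `tracking.csv` (t_s, x_cm, direction), `spikes.csv`
#' (cell_id, t_s), `theta.csv` (t_s, phase_deg, lfp) and `truth.json`
#' (all generator parameters including the seed) into a directory.
#'
#' @param session a `theta_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session_csv <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(
    dplyr::transmute(session$tracking, t_s = .data$t, x_cm = .data$x,
                     direction = .data$direction),
    file.path(dir, "tracking.csv"))
  readr::write_csv(
    dplyr::transmute(session$spikes, cell_id = .data$cell, t_s = .data$t),
    file.path(dir, "spikes.csv"))
  readr::write_csv(
    dplyr::transmute(session$theta$samples, t_s = .data$t,
                     phase_deg = .data$phase, lfp = .data$lfp),
    file.path(dir, "theta.csv"))
  truth <- session$truth
  truth$params <- unclass(truth$params)
  truth$spiking <- unclass(truth$spiking)
  truth$track <- unclass(session$track)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a session written by [write_session_csv()]
#'
#' @param dir directory containing the session files.
#' @return a `theta_session` (the theta series' cycles are re-derived
#'   from the phase samples).
#' @export
read_session_csv <- function(dir) {
  tr <- readr::read_csv(file.path(dir, "tracking.csv"),
                        show_col_types = FALSE)
  sp <- readr::read_csv(file.path(dir, "spikes.csv"),
                        show_col_types = FALSE)
  th <- readr::read_csv(file.path(dir, "theta.csv"),
                        show_col_types = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  fs <- 1 / median(diff(th$t_s))
  cycles <- segment_cycles(th$t_s, th$phase_deg)
  track <- do.call(track_config, truth$track[
    c("length", "spatial_bin", "n_runs_per_direction", "pause_range",
      "tracking_fs")])
  structure(list(
    tracking = tibble::tibble(t = tr$t_s, x = tr$x_cm,
                              direction = tr$direction),
    theta = structure(list(
      samples = tibble::tibble(t = th$t_s, phase = th$phase_deg,
                               lfp = th$lfp),
      cycles = cycles, fs = fs), class = "theta_series"),
    spikes = tibble::tibble(cell = sp$cell_id, t = sp$t_s),
    truth = truth, track = track), class = "theta_session")
}

#' Write the main analysis tables of a session
#'
#' Writes `fields.csv`, `fields_by_speed.csv`, `precession.csv`,
#' `cycles.csv` and (when decoding was run) `trajectories.csv` and
#' `averaged_trajectories.csv`.
#'
#' @param analysis a `theta_analysis`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_analysis_csv <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(analysis$fields, file.path(dir, "fields.csv"))
  if (!is.null(analysis$sizes_by_speed)) {
    readr::write_csv(analysis$sizes_by_speed,
                     file.path(dir, "fields_by_speed.csv"))
  }
  if (!is.null(analysis$slopes_by_speed)) {
    readr::write_csv(analysis$slopes_by_speed,
                     file.path(dir, "precession.csv"))
  }
  readr::write_csv(analysis$cycles, file.path(dir, "cycles.csv"))
  if (!is.null(analysis$trajectories)) {
    readr::write_csv(analysis$trajectories,
                     file.path(dir, "trajectories.csv"))
  }
  if (!is.null(analysis$avg_trajectories)) {
    readr::write_csv(analysis$avg_trajectories,
                     file.path(dir, "averaged_trajectories.csv"))
  }
  invisible(dir)
}
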