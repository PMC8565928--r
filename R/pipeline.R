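#' Run the full analysis pipeline on a session
#'
#' Starting from the raw session (tracking, LFP, spike times), this
#' extracts theta phase and significant cycles from the LFP, computes
#' speed, acceleration, run epochs and characteristic-speed profiles,
#' detects place fields per cell and direction, optimizes the
#' session-wide phase offset, fits phase precession slopes (all-speed,
#' pooled by speed bin, and optionally single passes), measures field
#' sizes per speed bin, and (optionally) decodes theta trajectories per
#' cycle.
#'
#' @param session a `theta_session` (see [generate_session()]).
#' @param decode run the Bayesian theta-trajectory decoding?
#' @param single_pass fit single-pass precession slopes?
#' @param optimize_offset optimize the session phase offset (otherwise
#'   0)?
#' @param cfg a [decoding_config()].
#' @param mask_seed seed for the significance-surrogate permutation.
#' @return object of class `theta_analysis`: list with `behavior`
#'   (annotated tracking), `profile`, `cycles`, `phase_offset`,
#'   `fields`, `clouds`, `slopes_by_speed`, `sizes_by_speed`,
#'   `single_pass`, `trajectories`, `avg_trajectories`, `spikes`
#'   (annotated), `track`.
#' @export
analyze_session <- function(session, decode = FALSE, single_pass = FALSE,
                            optimize_offset = TRUE,
                            cfg = decoding_config(), mask_seed = 1L) {
  track <- session$track
  L <- track$length
  fs <- track$tracking_fs
  th <- session$theta$samples
  theta_fs <- session$theta$fs

  filt <- bandpass_theta(th$lfp, theta_fs)
  phase <- theta_phase(filt)
  mask <- significant_theta_mask(th$lfp, theta_fs, seed = mask_seed)
  cycles <- segment_cycles(th$t, phase, mask)

  beh <- annotate_behavior(session$tracking[, c("t", "x")], L, fs)
  beh <- annotate_sample_significance(beh, cycles)
  profile <- dplyr::bind_rows(
    characteristic_speed(beh, L, "right"),
    characteristic_speed(beh, L, "left"))

  spk <- annotate_spikes(session$spikes, beh, th$t, phase, cycles)

  fields <- detect_all_fields(spk, beh, L, fs)

  phase_offset <- 0
  if (optimize_offset && nrow(fields) > 0) {
    complete <- fields[!fields$incomplete, ]
    clouds0 <- purrr::pmap(
      list(complete$cell, complete$direction, complete$start, complete$end),
      function(cell, direction, start, end)
        build_cloud(spk, cell, direction, start, end))
    eligible <- purrr::keep(clouds0, ~ nrow(.x) >= 12)
    if (length(eligible) > 0) {
      phase_offset <- optimize_session_phase_offset(eligible)
    }
  }
  if (phase_offset != 0) {
    cycles <- segment_cycles(th$t, phase, mask, offset = phase_offset)
    beh <- annotate_sample_significance(beh, cycles)
    spk <- annotate_spikes(session$spikes, beh, th$t, phase, cycles)
  }

  res <- precession_and_sizes(spk, beh, fields, L, fs,
                              phase_offset = phase_offset,
                              single_pass = single_pass)
  fields <- res$fields

  trajectories <- NULL; avg_traj <- NULL
  if (decode && nrow(fields) > 0) {
    maps <- direction_rate_maps(spk, beh, L, fs,
                                cells = sort(unique(session$spikes$cell)))
    dec_spikes <- spk[spk$significant & !is.na(spk$run_id),
                      c("cell", "t")]
    trajectories <- decode_session_cycles(dec_spikes, cycles, beh,
                                          maps$rates, maps$bin_centers, cfg)
    if (!is.null(trajectories) && nrow(trajectories) > 0) {
      avg_traj <- average_posteriors_by_speed(trajectories, cfg)
      trajectories$pm <- NULL
    }
  }

  structure(list(behavior = beh, profile = profile, cycles = cycles,
                 phase_offset = phase_offset, fields = fields,
                 clouds = res$clouds, slopes_by_speed = res$slopes,
                 sizes_by_speed = res$sizes, single_pass = res$single_pass,
                 trajectories = trajectories, avg_trajectories = avg_traj,
                 spikes = spk, track = track),
            class = "theta_analysis")
}

#' Annotate spikes with position, speed, phase and cycle membership
#'
#' @param spikes tibble `cell`, `t`.
#' @param behavior annotated tracking (see [annotate_behavior()]).
#' @param theta_t,theta_phase theta sample times and phases.
#' @param cycles cycle table (see [segment_cycles()]).
#' @return spike tibble with `x`, `v`, `direction`, `run_id`, `phase`,
#'   `cycle`, `significant`.
#' @export
annotate_spikes <- function(spikes, behavior, theta_t, theta_phase, cycles) {
  s <- spikes
  s$x <- interp1(behavior$t, behavior$x, s$t)
  s$v <- abs(interp1(behavior$t, behavior$v, s$t))
  idx <- pmin(pmax(round(interp1(behavior$t, seq_len(nrow(behavior)), s$t)),
                   1L), nrow(behavior))
  s$direction <- behavior$direction[idx]
  s$run_id <- behavior$run_id[idx]
  pidx <- pmin(pmax(round(interp1(theta_t, seq_along(theta_t), s$t)), 1L),
               length(theta_t))
  s$phase <- theta_phase[pidx]
  ci <- findInterval(s$t, cycles$start_t)
  inside <- ci >= 1 & ci <= nrow(cycles) & s$t < cycles$end_t[pmax(ci, 1L)]
  s$cycle <- ifelse(inside, cycles$cycle[pmax(ci, 1L)], NA_integer_)
  s$significant <- !is.na(s$cycle) &
    cycles$significant[pmax(ci, 1L)] & inside
  s
}

# mark tracking samples that fall inside a significant theta cycle
annotate_sample_significance <- function(beh, cycles) {
  ci <- findInterval(beh$t, cycles$start_t)
  inside <- ci >= 1 & ci <= nrow(cycles) & beh$t < cycles$end_t[pmax(ci, 1L)]
  beh$sig_sample <- inside & cycles$significant[pmax(ci, 1L)]
  beh
}

# all-speed fields for every cell x direction
detect_all_fields <- function(spk, beh, L, fs) {
  cells <- sort(unique(spk$cell))
  out <- list()
  for (d in c("right", "left")) {
    occ_x <- beh$x[!is.na(beh$run_id) & beh$direction == d & beh$sig_sample]
    if (length(occ_x) == 0) next
    for (cl in cells) {
      sx <- spk$x[spk$cell == cl & spk$direction == d & spk$significant]
      rm_ <- compute_rate_map(sx, occ_x, fs, L)
      f <- detect_fields(rm_, sx)
      if (nrow(f) == 0) next
      f$cell <- cl
      f$direction <- d
      # skew is reported in the travel frame (positive = long lead-in
      # tail), so the track-frame moment flips sign for leftward fields
      f$skew <- vapply(seq_len(nrow(f)), function(i) {
        if (f$incomplete[i]) NA_real_
        else (if (d == "left") -1 else 1) *
          field_skew(rm_, f$start[i], f$end[i])
      }, numeric(1))
      out[[length(out) + 1L]] <- f
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(cell = integer(), direction = character(),
                          peak_x = numeric(), peak_rate = numeric(),
                          start = numeric(), end = numeric(),
                          start_detected = logical(),
                          end_detected = logical(),
                          incomplete = logical(), size = numeric(),
                          n_spikes = integer(), skew = numeric()))
  }
  dplyr::bind_rows(out) |>
    dplyr::relocate("cell", "direction")
}

# per-field precession fits, per-speed sizes and slopes
precession_and_sizes <- function(spk, beh, fields, L, fs, phase_offset = 0,
                                 single_pass = FALSE,
                                 fit_precession = TRUE) {
  if (nrow(fields) == 0) {
    return(list(fields = fields, clouds = list(), slopes = NULL,
                sizes = NULL, single_pass = NULL))
  }
  sb <- speed_bins()
  profile_v <- dplyr::bind_rows(
    characteristic_speed(beh, L, "right"),
    characteristic_speed(beh, L, "left"))
  fields$field_id <- seq_len(nrow(fields))
  fields$vbar <- NA_real_; fields$abar <- NA_real_
  fields$slope_norm <- NA_real_; fields$slope_deg_per_cm <- NA_real_
  fields$fit_error <- NA_real_
  clouds <- vector("list", nrow(fields))
  slopes <- list(); sizes <- list(); passes <- list()
  for (d in c("right", "left")) {
    sel_d <- which(fields$direction == d)
    if (length(sel_d) == 0) next
    base <- !is.na(beh$run_id) & beh$direction == d & beh$sig_sample
    occ_all <- beh$x[base]
    occ_by_bin <- lapply(seq_len(nrow(sb)), function(i)
      beh$x[base & abs(beh$v) >= sb$lo[i] & abs(beh$v) < sb$hi[i]])
    p_d <- profile_v[profile_v$direction == d, ]
    for (i in sel_d) {
      fld <- fields[i, ]
      sel_bins <- p_d$bin_center >= fld$start & p_d$bin_center <= fld$end
      fields$vbar[i] <- mean(p_d$vbar[sel_bins], na.rm = TRUE)
      fields$abar[i] <- mean(p_d$abar[sel_bins], na.rm = TRUE)
      spx_bin <- lapply(seq_len(nrow(sb)), function(b)
        spk$x[spk$cell == fld$cell & spk$direction == d & spk$significant &
                spk$v >= sb$lo[b] & spk$v < sb$hi[b]])
      sz <- sizes_by_speed(fld, spx_bin, occ_by_bin, fs, L)
      sz$field_id <- fld$field_id
      sizes[[length(sizes) + 1L]] <- sz
      if (fld$incomplete || !fit_precession) next
      cl <- build_cloud(spk, fld$cell, d, fld$start, fld$end,
                        phase_offset = phase_offset)
      clouds[[i]] <- cl
      if (nrow(cl) >= 12) {
        f <- fit_odr_wrapped(cl)
        fields$slope_norm[i] <- f$slope_norm
        fields$slope_deg_per_cm[i] <-
          slope_to_physical(f, fld$end - fld$start)
        fields$fit_error[i] <- f$error
        bins_ok <- sz$bin[!is.na(sz$sampling_index) &
                            sz$sampling_index >= 0.4]
        ps <- pooled_slopes_by_speed(cl, fld$end - fld$start,
                                     bins_ok = bins_ok)
        if (nrow(ps) > 0) {
          ps$field_id <- fld$field_id
          slopes[[length(slopes) + 1L]] <- ps
        }
        if (single_pass) {
          sp_fit <- single_pass_slopes(cl, beh, fld$start, fld$end)
          if (nrow(sp_fit) > 0) {
            sp_fit$field_id <- fld$field_id
            passes[[length(passes) + 1L]] <- sp_fit
          }
        }
      }
    }
  }
  list(fields = fields, clouds = clouds,
       slopes = if (length(slopes)) dplyr::bind_rows(slopes) else NULL,
       sizes = if (length(sizes)) dplyr::bind_rows(sizes) else NULL,
       single_pass = if (length(passes)) dplyr::bind_rows(passes) else NULL)
}

# direction-specific rate matrices for decoding
direction_rate_maps <- function(spk, beh, L, fs, cells, bin = 4) {
  edges <- seq(0, L, by = bin)
  centers <- edges[-length(edges)] + bin / 2
  rates <- list()
  for (d in c("right", "left")) {
    occ_x <- beh$x[!is.na(beh$run_id) & beh$direction == d & beh$sig_sample]
    M <- matrix(0, nrow = length(centers), ncol = length(cells))
    for (j in seq_along(cells)) {
      sx <- spk$x[spk$cell == cells[j] & spk$direction == d & spk$significant]
      M[, j] <- compute_rate_map(sx, occ_x, fs, L, bin = bin)$rate
    }
    rates[[d]] <- M
  }
  list(rates = rates, bin_centers = centers)
}
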