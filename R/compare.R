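#' Field-by-speed-bin table
#'
#' Joins per-speed-bin field sizes and phase precession slopes into one
#' tidy table with per-field covariates (characteristic speed and
#' acceleration over the field, distance from the field peak to the
#' nearest track end).
#'
#' @param analysis a `theta_analysis` (see [analyze_session()]).
#' @return tibble with `field_id`, `cell`, `direction`, `bin`, `center`,
#'   `size`, `slope_deg_per_cm`, `vbar`, `abar`, `dist_to_end`.
#' @export
field_speed_table <- function(analysis) {
  fields <- analysis$fields
  if (is.null(fields) || nrow(fields) == 0) return(tibble::tibble())
  L <- analysis$track$length
  meta <- fields |>
    dplyr::mutate(dist_to_end = pmin(.data$peak_x, L - .data$peak_x)) |>
    dplyr::select("field_id", "cell", "direction", "vbar", "abar",
                  "dist_to_end")
  sz <- analysis$sizes_by_speed
  sl <- analysis$slopes_by_speed
  base <- if (!is.null(sz)) {
    dplyr::select(sz, "field_id", "bin", "center", "size")
  } else tibble::tibble(field_id = integer(), bin = integer(),
                        center = numeric(), size = numeric())
  if (!is.null(sl)) {
    base <- dplyr::full_join(
      base, dplyr::select(sl, "field_id", "bin", "center",
                          "slope_deg_per_cm"),
      by = c("field_id", "bin", "center"))
  } else {
    base$slope_deg_per_cm <- NA_real_
  }
  dplyr::left_join(base, meta, by = "field_id") |>
    dplyr::arrange(.data$field_id, .data$bin)
}

#' Within-field regressions of a metric on speed bin
#'
#' Ordinary least-squares slope of the metric against speed-bin center
#' for each field with data in at least two bins, followed by a
#' two-sided Wilcoxon signed-rank test of the per-field slopes against
#' zero. This is the single-field analysis that distinguishes
#' instantaneous-speed effects from the across-field (pooled) ones.
#'
#' @param table output of [field_speed_table()].
#' @param metric "size" or "slope_deg_per_cm".
#' @param min_fields minimum number of fields, default 5.
#' @return list of class `within_field_test`: `slopes` tibble, `p`,
#'   `statistic`, `median_slope`, `n_fields`.
#' @export
within_field_regressions <- function(table, metric = "size",
                                     min_fields = 5) {
  tb <- table[!is.na(table[[metric]]), ]
  slopes <- tb |>
    dplyr::group_by(.data$field_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(slope = unname(
      stats::coef(stats::lm(.data[[metric]] ~ center,
                            data = dplyr::pick(dplyr::everything())))[2]),
      n_bins = dplyr::n(), .groups = "drop") |>
    dplyr::filter(!is.na(.data$slope))
  abort_if(nrow(slopes) < min_fields,
           paste0("need at least ", min_fields, " fields with >= 2 bins"))
  wt <- suppressWarnings(stats::wilcox.test(slopes$slope, mu = 0))
  structure(list(slopes = slopes, p = wt$p.value,
                 statistic = unname(wt$statistic),
                 median_slope = median(slopes$slope),
                 n_fields = nrow(slopes)),
            class = "within_field_test")
}

#' Pooled association between a metric and running speed
#'
#' Kendall rank correlation (with tie handling) of a metric pooled
#' across fields or cycles against speed.
#'
#' @param x speeds (bin centers or cycle speeds).
#' @param y metric values.
#' @param min_points minimum number of complete pairs, default 10.
#' @return tibble with `tau`, `p`, `n`.
#' @export
pooled_association <- function(x, y, min_points = 10) {
  ok <- !is.na(x) & !is.na(y)
  abort_if(sum(ok) < min_points,
           paste0("need at least ", min_points, " points"))
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "kendall"))
  tibble::tibble(tau = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Moving average over a sliding speed window
#'
#' @param x,y data points.
#' @param window window width (same units as `x`), e.g. 10 or 15 cm/s.
#' @param xout query points; defaults to a grid over the range of `x`.
#' @return tibble with `x`, `y` (window mean), `n`.
#' @export
moving_average <- function(x, y, window, xout = NULL) {
  abort_if(window <= 0, "window must be positive")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  xout <- xout %||% seq(min(x), max(x), length.out = 50)
  res <- vapply(xout, function(q) {
    sel <- abs(x - q) <= window / 2
    c(mean(y[sel]), sum(sel))
  }, numeric(2))
  tibble::tibble(x = xout, y = res[1, ], n = as.integer(res[2, ]))
}

#' Grand average of per-session curves
#'
#' Unweighted mean across curves evaluated on a common grid, so every
#' session (animal) contributes equally regardless of how many data
#' points it has.
#'
#' @param curves list of tibbles with columns `x`, `y` on the same grid.
#' @return tibble with `x`, `y`.
#' @export
grand_average <- function(curves) {
  x <- curves[[1]]$x
  ys <- vapply(curves, function(cv) cv$y, numeric(length(x)))
  tibble::tibble(x = x, y = rowMeans(as.matrix(ys), na.rm = TRUE))
}

#' Estimate the look-ahead time from precession slopes
#'
#' Least-squares fit through the origin of the inverse phase precession
#' slope relationship `360/|m| = vbar * tau_theta` over fields, giving
#' the look-ahead time in seconds.
#'
#' @param vbar characteristic speeds at the fields (cm/s).
#' @param slope_deg_per_cm fitted precession slopes (deg/cm, negative).
#' @param min_fields minimum number of fields, default 10.
#' @return object of class `tau_theta_fit`: `tau_theta` (s), `n`, `r2`,
#'   and the fitted points.
#' @export
fit_tau_theta <- function(vbar, slope_deg_per_cm, min_fields = 10) {
  ok <- !is.na(vbar) & !is.na(slope_deg_per_cm) & slope_deg_per_cm != 0
  abort_if(sum(ok) < min_fields,
           paste0("need at least ", min_fields, " fields"))
  v <- vbar[ok]
  y <- 360 / abs(slope_deg_per_cm[ok])
  tau <- sum(v * y) / sum(v^2)
  resid <- y - tau * v
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  structure(list(tau_theta = tau, n = sum(ok), r2 = r2,
                 points = tibble::tibble(vbar = v, inv_slope = y)),
            class = "tau_theta_fit")
}

#' Variance partitioning between characteristic speed and border distance
#'
#' Fits the full linear model `response ~ vbar + dist_to_end` and the
#' two reduced models; reports the full R^2, each predictor's unique
#' R^2 (full minus reduced), and likelihood-ratio p-values on 1 df.
#'
#' @param response numeric response (field size or inverse slope).
#' @param vbar,dist_to_end predictors.
#' @param min_fields minimum complete cases, default 20.
#' @return list of class `variance_partition` with `r2_full`,
#'   `unique_r2` (named), `lrt_p` (named), `n`.
#' @export
variance_partition <- function(response, vbar, dist_to_end,
                               min_fields = 20) {
  ok <- stats::complete.cases(response, vbar, dist_to_end)
  abort_if(sum(ok) < min_fields,
           paste0("need at least ", min_fields, " fields"))
  d <- data.frame(y = response[ok], v = vbar[ok], b = dist_to_end[ok])
  full <- stats::lm(y ~ v + b, data = d)
  no_v <- stats::lm(y ~ b, data = d)
  no_b <- stats::lm(y ~ v, data = d)
  r2 <- function(m) summary(m)$r.squared
  lrt <- function(reduced) {
    stat <- 2 * (as.numeric(stats::logLik(full)) -
                   as.numeric(stats::logLik(reduced)))
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(
    r2_full = r2(full),
    unique_r2 = c(vbar = r2(full) - r2(no_v),
                  dist_to_end = r2(full) - r2(no_b)),
    lrt_p = c(vbar = lrt(no_v), dist_to_end = lrt(no_b)),
    n = nrow(d)), class = "variance_partition")
}

#' Association between place-field skew and mean acceleration
#'
#' The behavior-dependent sweep predicts that fields skew according to
#' whether the characteristic speed rises or falls through the field,
#' i.e. with the mean acceleration there.
#'
#' @param fields field table with `skew` and `abar` columns.
#' @param min_fields minimum complete fields, default 10.
#' @return tibble with `tau`, `p`, `n`.
#' @export
skew_vs_acceleration <- function(fields, min_fields = 10) {
  ok <- !is.na(fields$skew) & !is.na(fields$abar)
  abort_if(sum(ok) < min_fields,
           paste0("need at least ", min_fields, " complete fields"))
  pooled_association(fields$abar[ok], fields$skew[ok],
                     min_points = min_fields)
}

sign_call <- function(tau, p, tau_flat = 0.1, alpha = 0.05) {
  if (is.na(tau) || is.na(p)) return("flat")
  if (abs(tau) < tau_flat || p > alpha) return("flat")
  if (tau > 0) "increase" else "decrease"
}

within_call <- function(wf, alpha = 0.05) {
  if (is.na(wf$p) || is.na(wf$median_slope) || wf$p > alpha ||
        wf$median_slope == 0) return("flat")
  if (wf$median_slope > 0) "increase" else "decrease"
}

#' Three-scheme model comparison harness
#'
#' Simulates a batch of sessions under each sweep scheme with the
#' published generative parameters (spatial `d_theta` = 30 cm, temporal
#' `tau_theta` = 0.55 s, behavior-dependent `tau_theta` = 0.57 s), runs
#' the full analysis pipeline on each session, and summarizes five
#' speed-effect metrics per scheme: pooled theta-trajectory length,
#' pooled field size and pooled precession slope against instantaneous
#' speed, and the within-field size and slope changes. Each metric is
#' called "increase", "flat" or "decrease"; the behavior-dependent sweep
#' is the only scheme expected to combine pooled increases with flat
#' within-field effects. Mean squared deviations of the per-speed-bin
#' pooled means are computed against a reference table (by default the
#' behavior-scheme run, standing in for experimental data).
#'
#' @param schemes character vector of schemes to simulate.
#' @param n_sessions sessions per scheme, default 3.
#' @param n_cells cells per session, default 20.
#' @param track a [track_config()].
#' @param seed base RNG seed; session s of scheme k uses
#'   `seed + 100 * k + s`.
#' @param decode decode theta trajectories (needed for the pooled-L
#'   metric)?
#' @param reference optional reference table (tibble `metric`, `center`,
#'   `value`) for the mean squared deviations.
#' @param params named list overriding the per-scheme sweep parameters.
#' @return object of class `comparison_summary`: `signs` tibble
#'   (scheme, metric, call, tau, p), `msd` tibble, `pooled` per-bin
#'   means, `tables` (the underlying per-scheme data).
#' @export
run_model_comparison <- function(schemes = c("spatial", "temporal",
                                             "behavior"),
                                 n_sessions = 3, n_cells = 20,
                                 track = track_config(), seed = 1,
                                 decode = TRUE, reference = NULL,
                                 params = NULL) {
  params <- params %||% list(
    spatial = sweep_params("spatial", d_theta = 30),
    temporal = sweep_params("temporal", tau_theta = 0.55),
    behavior = sweep_params("behavior", tau_theta = 0.57))
  sb <- speed_bins()
  signs <- list(); pooled_rows <- list(); tables <- list()
  for (k in seq_along(schemes)) {
    sch <- schemes[k]
    tabs <- list(); trajs <- list()
    for (s in seq_len(n_sessions)) {
      sess <- generate_session(track, params[[sch]], n_cells = n_cells,
                               seed = seed + 100 * k + s)
      an <- analyze_session(sess, decode = decode)
      tabs[[s]] <- field_speed_table(an)
      if (decode && !is.null(an$trajectories)) {
        trajs[[s]] <- an$trajectories[an$trajectories$ok, ]
      }
    }
    tab <- dplyr::bind_rows(tabs)
    traj <- if (length(trajs)) dplyr::bind_rows(trajs) else NULL
    tables[[sch]] <- list(fields = tab, trajectories = traj)
    if (!is.null(traj)) {
      # the 70 cm decoding window cannot cover a sweep beyond the track
      # ends, which artificially shortens trajectories at the (slow)
      # corner regions; speed-effect metrics use interior cycles
      traj <- traj[traj$x0 > 35 & traj$x0 < track$length - 35, ]
    }
    # steep wrapped precession clouds identify the slope magnitude but
    # not reliably its sign (an ascending line fits a full-span wrapped
    # stripe almost as well); the speed-effect metrics therefore use
    # the folded slope -|m|, whose "increase" still means shallower
    # precession at higher speed
    tab$slope_fold <- -abs(tab$slope_deg_per_cm)

    size_clean <- filter_outliers_by(tab, "size", k = 3)
    slope_clean <- filter_outliers_by(tab, "slope_fold", k = 3)
    pa_size <- pooled_association(size_clean$center, size_clean$size)
    pa_slope <- pooled_association(slope_clean$center,
                                   slope_clean$slope_fold)
    wf_size <- within_field_regressions(tab, "size")
    wf_slope <- within_field_regressions(tab, "slope_fold")
    pa_L <- if (!is.null(traj) && sum(!is.na(traj$length)) >= 10) {
      pooled_association(traj$v_mid, traj$length)
    } else tibble::tibble(tau = NA_real_, p = NA_real_, n = 0L)

    signs[[sch]] <- tibble::tibble(
      scheme = sch,
      metric = c("pooled_L", "pooled_size", "pooled_slope",
                 "within_size", "within_slope"),
      call = c(sign_call(pa_L$tau, pa_L$p),
               sign_call(pa_size$tau, pa_size$p),
               sign_call(pa_slope$tau, pa_slope$p),
               within_call(wf_size), within_call(wf_slope)),
      tau = c(pa_L$tau, pa_size$tau, pa_slope$tau,
              wf_size$median_slope, wf_slope$median_slope),
      p = c(pa_L$p, pa_size$p, pa_slope$p, wf_size$p, wf_slope$p))

    pooled_rows[[sch]] <- dplyr::bind_rows(
      per_bin_means(size_clean$center, size_clean$size, "pooled_size",
                    sch),
      per_bin_means(slope_clean$center, slope_clean$slope_fold,
                    "pooled_slope", sch),
      if (!is.null(traj)) {
        ab <- assign_speed_bins(traj$v_mid)
        per_bin_means(ab$center, traj$length[ab$index], "pooled_L", sch)
      })
  }
  pooled <- dplyr::bind_rows(pooled_rows)
  reference <- reference %||% {
    ref_scheme <- if ("behavior" %in% schemes) "behavior" else schemes[1]
    pooled[pooled$scheme == ref_scheme, c("metric", "center", "value")]
  }
  msd <- pooled |>
    dplyr::inner_join(reference, by = c("metric", "center"),
                      suffix = c("", "_ref")) |>
    dplyr::group_by(.data$scheme, .data$metric) |>
    dplyr::summarise(msd = mean((.data$value - .data$value_ref)^2,
                                na.rm = TRUE), .groups = "drop")
  structure(list(signs = dplyr::bind_rows(signs), msd = msd,
                 pooled = pooled, tables = tables, seed = seed),
            class = "comparison_summary")
}

filter_outliers_by <- function(tab, metric, k = 3) {
  v <- tab[[metric]]
  kept <- remove_outliers(v, k)
  tab[!is.na(v) & v %in% kept, ]
}

per_bin_means <- function(center, value, metric, scheme) {
  ok <- !is.na(center) & !is.na(value)
  if (!any(ok)) return(NULL)
  tibble::tibble(center = center[ok], value = value[ok]) |>
    dplyr::group_by(.data$center) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(metric = metric, scheme = scheme)
}

#' Pairwise relations among trajectory length, field size and inverse
#' slope
#'
#' Bins theta-trajectory lengths, field sizes and inverse precession
#' slopes by track position, joins them with the characteristic speed,
#' and fits all pairwise linear relations; under the behavior-dependent
#' sweep all three are linear in the characteristic speed and hence in
#' one another.
#'
#' @param analysis a `theta_analysis` with decoding run.
#' @param bin position bin width (cm), default 20.
#' @return tibble with `xvar`, `yvar`, `slope`, `intercept`, `r`, `n`.
#' @export
triad_relations <- function(analysis, bin = 20) {
  L <- analysis$track$length
  edges <- seq(0, L, by = bin)
  mids <- edges[-length(edges)] + bin / 2
  bin_of <- function(x) pmin(pmax(findInterval(x, edges,
                                               rightmost.closed = TRUE),
                                  1L), length(mids))
  f <- analysis$fields
  traj <- analysis$trajectories
  abort_if(is.null(traj), "triad relations need decoded trajectories")
  fld <- tibble::tibble(pos = bin_of(f$peak_x), size = f$size,
                        inv_slope = 360 / abs(f$slope_deg_per_cm)) |>
    dplyr::group_by(.data$pos) |>
    dplyr::summarise(size = mean(.data$size, na.rm = TRUE),
                     inv_slope = mean(.data$inv_slope, na.rm = TRUE),
                     .groups = "drop")
  tr <- tibble::tibble(pos = bin_of(traj$x0), L_traj = traj$length) |>
    dplyr::group_by(.data$pos) |>
    dplyr::summarise(L_traj = mean(.data$L_traj, na.rm = TRUE),
                     .groups = "drop")
  prof <- analysis$profile |>
    dplyr::mutate(pos = bin_of(.data$bin_center)) |>
    dplyr::group_by(.data$pos) |>
    dplyr::summarise(vbar = mean(.data$vbar, na.rm = TRUE),
                     .groups = "drop")
  d <- Reduce(function(a, b) dplyr::full_join(a, b, by = "pos"),
              list(fld, tr, prof))
  vars <- c("vbar", "L_traj", "size", "inv_slope")
  out <- list()
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (i >= j) next
    ok <- stats::complete.cases(d[[vars[i]]], d[[vars[j]]])
    if (sum(ok) < 3) next
    m <- stats::lm(d[[vars[j]]][ok] ~ d[[vars[i]]][ok])
    out[[length(out) + 1L]] <- tibble::tibble(
      xvar = vars[i], yvar = vars[j],
      slope = unname(stats::coef(m)[2]),
      intercept = unname(stats::coef(m)[1]),
      r = stats::cor(d[[vars[i]]][ok], d[[vars[j]]][ok]),
      n = sum(ok))
  }
  dplyr::bind_rows(out)
}
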