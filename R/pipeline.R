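#' Spherical-mean series from raw DWI blocks
#'
#' For each acquisition block: restrict to the strong shell, attenuate
#' the Rician bias per volume, then average over directions. The result
#' stacks one spherical-mean map per protocol row into a 4D array.
#'
#' @param blocks List of [dwi_block()], aligned with the protocol rows.
#' @param target_b Shell to keep, s/mm^2 (default 6000).
#' @param sigma Rician noise level for [rician_correct()]; 0 disables.
#' @param shell_tol Shell tolerance, s/mm^2.
#' @return 4D array (x, y, z, block) of corrected spherical means.
#' @export
prepare_spherical_means <- function(blocks, target_b = 6000, sigma = 0,
                                    shell_tol = 100) {
  maps <- lapply(blocks, function(bl) {
    sh <- extract_shell(bl, target_b, shell_tol)
    if (sigma > 0) sh$volume <- rician_correct(sh$volume, sigma)
    spherical_mean(sh)
  })
  arr <- array(0, dim = c(dim(maps[[1]]), length(maps)))
  for (p in seq_along(maps)) arr[, , , p] <- maps[[p]]
  arr
}

#' Voxelwise relaxation fitting
#'
#' Fits the joint or T2-only relaxation model in every masked voxel of a
#' spherical-mean series and returns one tidy row per voxel. Degenerate
#' voxels (all-zero signal, bound-limited parameters) are flagged, not
#' dropped, so the map stays total.
#'
#' @param means 4D array (x, y, z, block) of spherical means, e.g. from
#'   [prepare_spherical_means()].
#' @param protocol Protocol tibble aligned with the 4th dimension.
#' @param mask Optional 3D mask (nonzero = fit); default fits voxels with
#'   any positive signal.
#' @param model `"t1t2"` or `"t2"`.
#' @return A tibble with `i, j, k, K, T2a, T1a, rss, degenerate,
#'   at_bound`.
#' @export
fit_map <- function(means, protocol, mask = NULL,
                    model = c("t1t2", "t2")) {
  model <- match.arg(model)
  stopifnot(length(dim(means)) == 4, dim(means)[4] == nrow(protocol))
  if (is.null(mask)) {
    mask <- apply(means, c(1, 2, 3), function(v) any(v > 0))
  }
  if (!identical(dim(mask)[1:3], dim(means)[1:3])) {
    abort("mask and data are on different voxel grids.")
  }
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("Empty mask: no voxels to fit.")
  rows <- vector("list", nrow(idx))
  for (v in seq_len(nrow(idx))) {
    m <- means[idx[v, 1], idx[v, 2], idx[v, 3], ]
    fit <- if (model == "t1t2") fit_t1t2(m, protocol)
           else fit_t2(m, protocol$TE)
    rows[[v]] <- tibble(
      i = idx[v, 1], j = idx[v, 2], k = idx[v, 3],
      K = fit$K, T2a = fit$T2a, T1a = fit$T1a, rss = fit$rss,
      degenerate = "degenerate" %in% fit$flags,
      at_bound = any(fit$at_bound)
    )
  }
  dplyr::bind_rows(rows)
}

#' Rebuild a 3D parameter map from voxelwise fits
#'
#' @param fits Tibble from [fit_map()].
#' @param grid_dim Integer vector of length 3.
#' @param var Column to place into the volume (default `"T2a"`).
#' @param fill Background value (default `NA`).
#' @return 3D array.
#' @export
map_from_fits <- function(fits, grid_dim, var = "T2a", fill = NA_real_) {
  out <- array(fill, grid_dim)
  out[cbind(fits$i, fits$j, fits$k)] <- fits[[var]]
  out
}

#' ROI-mean relaxation times
#'
#' Aggregates a voxelwise fit table over ROI masks. By default the
#' arithmetic mean of voxel relaxation times is taken per ROI (and the
#' inverse of that mean later enters calibration); set
#' `aggregate = "rate"` to average rates 1/T instead.
#'
#' @param fits Tibble from [fit_map()].
#' @param rois Named list of 3D masks.
#' @param var `"T2a"` or `"T1a"`.
#' @param aggregate `"time"` (mean of times, default) or `"rate"`.
#' @return Tibble with `roi`, `mean_T` (ms), `n_voxels`.
#' @export
roi_mean_times <- function(fits, rois, var = "T2a",
                           aggregate = c("time", "rate")) {
  aggregate <- match.arg(aggregate)
  purrr::map_dfr(names(rois), function(nm) {
    m <- rois[[nm]]
    inroi <- m[cbind(fits$i, fits$j, fits$k)] != 0
    vals <- fits[[var]][inroi & !fits$degenerate]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) abort(sprintf("ROI '%s' has no usable voxels.", nm))
    mt <- if (aggregate == "time") mean(vals) else 1 / mean(1 / vals)
    tibble(roi = nm, mean_T = mt, n_voxels = length(vals))
  })
}

#' Calibrate on reference ROIs and predict radii in the rest
#'
#' The workflow behind radius prediction: the surface-relaxation model is
#' calibrated on ROIs with histological effective radii, then inverted to
#' predict the effective radius of every other ROI from its mean
#' intra-axonal relaxation time. If reference radii are available for the
#' predicted ROIs, the predicted-vs-reference regression is reported too.
#'
#' @param roi_times Tibble from [roi_mean_times()] (`roi`, `mean_T`).
#' @param histology Tibble with `roi` and `r_eff_um` columns; rows
#'   matching `calib_rois` drive the calibration, remaining matches serve
#'   as reference for comparison.
#' @param calib_rois Character vector naming the calibration ROIs.
#' @param channel `"T2"` or `"T1"`.
#' @return A list with `calibration` ([calibrate()] result), `predicted`
#'   (tibble: roi, mean_T, r_pred_um, r_ref_um) and `comparison`
#'   ([ols_with_test()] row or `NULL`).
#' @export
run_calibrate_predict <- function(roi_times, histology, calib_rois,
                                  channel = c("T2", "T1")) {
  channel <- match.arg(channel)
  cal_dat <- roi_times |>
    dplyr::inner_join(histology, by = "roi") |>
    dplyr::filter(.data$roi %in% calib_rois)
  if (nrow(cal_dat) < 2) abort("Fewer than 2 calibration ROIs available.")
  calib <- calibrate(cal_dat, r_eff = r_eff_um, mean_Ta = mean_T,
                     channel = channel)

  pred <- roi_times |>
    dplyr::filter(!.data$roi %in% calib_rois) |>
    dplyr::mutate(r_pred_um = radius_from_relaxation(.data$mean_T,
                                                     calib$params)) |>
    dplyr::left_join(dplyr::select(histology, "roi",
                                   r_ref_um = "r_eff_um"),
                     by = "roi")

  comparison <- NULL
  refd <- dplyr::filter(pred, is.finite(.data$r_ref_um) &
                          is.finite(.data$r_pred_um))
  if (nrow(refd) >= 3) {
    comparison <- ols_with_test(refd, r_ref_um, r_pred_um)
  }
  list(calibration = calib, predicted = pred, comparison = comparison)
}

#' Full map-fitting run
#'
#' Orchestrates shell extraction, Rician correction, spherical means and
#' voxelwise fitting; optionally writes the parameter maps as NIfTI and
#' the voxel table as CSV.
#'
#' @param blocks List of [dwi_block()] aligned with `protocol`.
#' @param protocol Protocol tibble.
#' @param mask Optional 3D mask.
#' @param model `"t1t2"` or `"t2"`.
#' @param sigma Rician noise level (0 disables correction).
#' @param out_dir Optional output directory for NIfTI maps + CSV.
#' @return The voxelwise fit tibble (invisibly carries attribute
#'   `"grid_dim"`).
#' @export
run_fit <- function(blocks, protocol, mask = NULL,
                    model = c("t1t2", "t2"), sigma = 0, out_dir = NULL) {
  model <- match.arg(model)
  means <- prepare_spherical_means(blocks, sigma = sigma)
  fits <- fit_map(means, protocol, mask = mask, model = model)
  grid_dim <- dim(means)[1:3]
  attr(fits, "grid_dim") <- grid_dim
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vars <- c("K", "T2a", if (model == "t1t2") "T1a", "rss")
    for (v in vars) {
      write_volume(map_from_fits(fits, grid_dim, v),
                   file.path(out_dir, paste0(v, ".nii")))
    }
    readr::write_csv(fits, file.path(out_dir, "voxel_fits.csv"))
  }
  invisible(fits)
}

#' Plot predicted radii against reference values
#'
#' @param predicted Tibble with `r_ref_um` and `r_pred_um` columns (e.g.
#'   `run_calibrate_predict()$predicted`).
#' @return A ggplot.
#' @export
plot_radius_prediction <- function(predicted) {
  d <- dplyr::filter(predicted, is.finite(.data$r_ref_um))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_ref_um, y = .data$r_pred_um)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Reference effective radius (um)",
                  y = "Predicted effective radius (um)") +
    ggplot2::theme_minimal()
}
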