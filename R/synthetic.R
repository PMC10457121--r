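#' Sample axon radii from a distribution family
#'
#' Generates per-axon radii (um) for simulation experiments. The default
#' gamma family (shape 3, scale 0.2 um; mean 0.6 um) mimics the
#' right-skewed radius distributions measured in the corpus callosum.
#' All randomness flows through the mandatory `seed`, so draws are
#' reproducible.
#'
#' @param n Number of axons; positive.
#' @param family `"gamma"`, `"lognormal"` or `"discrete"`.
#' @param seed Integer RNG seed (mandatory).
#' @param shape,scale Gamma parameters.
#' @param meanlog,sdlog Lognormal parameters.
#' @param radii,weights Atoms and probabilities for the discrete family;
#'   weights must sum to 1.
#' @return Numeric vector of `n` positive radii, um.
#' @examples
#' sample_radii(5, "discrete", seed = 1, radii = c(0.5, 1), weights = c(.2, .8))
#' @export
sample_radii <- function(n, family = c("gamma", "lognormal", "discrete"),
                         seed, shape = 3, scale = 0.2,
                         meanlog = log(0.6), sdlog = 0.4,
                         radii = NULL, weights = NULL) {
  family <- match.arg(family)
  if (missing(seed)) abort("A seed is required for reproducible sampling.")
  if (n <= 0) abort("n must be positive.")
  out <- withr::with_seed(seed, switch(family,
    gamma = {
      if (shape <= 0 || scale <= 0) abort("Invalid gamma parameters.")
      rgamma(n, shape = shape, scale = scale)
    },
    lognormal = rlnorm(n, meanlog = meanlog, sdlog = sdlog),
    discrete = {
      if (is.null(radii) || is.null(weights) ||
          length(radii) != length(weights)) {
        abort("Discrete family needs matching radii and weights.")
      }
      if (abs(sum(weights) - 1) > 1e-8) abort("Weights must sum to 1.")
      if (any(radii <= 0)) abort("All atoms must be positive radii.")
      sample(radii, n, replace = TRUE, prob = weights)
    }
  ))
  # the gamma/lognormal tail at zero is physically impossible; clip softly
  pmax(out, 1e-6)
}

# spin-count weights: each axon contributes in proportion to its
# cross-sectional area, w_i = r_i^2 / sum(r^2)
spin_weights <- function(radii) {
  if (length(radii) == 0) abort("Radii must be nonempty.")
  if (any(radii <= 0)) abort("All radii must be positive.")
  radii^2 / sum(radii^2)
}

#' Signal mixtures over an axon-radius distribution
#'
#' Forward-simulates the spherical-mean signal of a voxel containing many
#' axons. Each axon of radius `r_i` relaxes mono-exponentially at the
#' surface-model rate `1/Tc + 2 rho/r_i` and contributes spins in
#' proportion to its cross-sectional area, giving weights
#' `w_i = r_i^2 / sum(r^2)`:
#' \deqn{\bar M(TE) = K \sum_i w_i \exp(-TE\,(1/T_c + 2\rho/r_i)).}
#' `mixture_signal_t1()` forms the analogous r^2-weighted mixture of
#' magnitude inversion-recovery factors
#' `|1 - 2 exp(-TI/T1_i) + exp(-TR/T1_i)|`, and
#' `mixture_signal_t1t2()` multiplies both factors per axon for joint
#' (TE, TI) protocols.
#'
#' @param radii Per-axon radii, um.
#' @param params [surface_params()] for the matching channel.
#' @param K Signal scale.
#' @param TEs Echo times, ms.
#' @return Numeric vector of mixture signals (one per TE or per protocol
#'   block) with attributes `radii`, `K` and the generating parameters.
#' @examples
#' p <- surface_params("T2", Tc = 126.97, rho = 0.00116)
#' mixture_signal_t2(c(0.5, 1), p, K = 1, TEs = c(73, 93, 118, 150))
#' @export
mixture_signal_t2 <- function(radii, params, K, TEs) {
  stopifnot(inherits(params, "surface_params"))
  if (params$channel != "T2") abort("params must be the T2 channel.")
  w <- spin_weights(radii)
  rates <- rate_from_radius(radii, params)
  vals <- K * vapply(TEs, function(te) sum(w * exp(-te * rates)), numeric(1))
  structure(vals, radii = radii, K = K, params = params)
}

#' @rdname mixture_signal_t2
#' @param protocol Protocol tibble carrying TI and TR per block.
#' @param include_tr Include the `exp(-TR/T1)` recovery term (default
#'   `TRUE`; with very long TR it is negligible).
#' @export
mixture_signal_t1 <- function(radii, params, K, protocol,
                              include_tr = TRUE) {
  stopifnot(inherits(params, "surface_params"))
  if (params$channel != "T1") abort("params must be the T1 channel.")
  validate_protocol(protocol, require_ti = TRUE)
  w <- spin_weights(radii)
  t1s <- 1 / rate_from_radius(radii, params)
  vals <- vapply(seq_len(nrow(protocol)), function(p) {
    tr_term <- if (include_tr) exp(-protocol$TR[p] / t1s) else 0
    sum(w * abs(1 - 2 * exp(-protocol$TI[p] / t1s) + tr_term))
  }, numeric(1))
  structure(K * vals, radii = radii, K = K, params = params)
}

#' @rdname mixture_signal_t2
#' @param params_t2,params_t1 Channel-specific [surface_params()].
#' @export
mixture_signal_t1t2 <- function(radii, params_t2, params_t1, K, protocol,
                                include_tr = TRUE) {
  stopifnot(inherits(params_t2, "surface_params"),
            inherits(params_t1, "surface_params"))
  if (params_t2$channel != "T2" || params_t1$channel != "T1") {
    abort("params_t2/params_t1 must be the T2 and T1 channels.")
  }
  validate_protocol(protocol, require_ti = TRUE)
  w <- spin_weights(radii)
  r2 <- rate_from_radius(radii, params_t2)
  t1s <- 1 / rate_from_radius(radii, params_t1)
  vals <- vapply(seq_len(nrow(protocol)), function(p) {
    tr_term <- if (include_tr) exp(-protocol$TR[p] / t1s) else 0
    ir <- abs(1 - 2 * exp(-protocol$TI[p] / t1s) + tr_term)
    sum(w * exp(-protocol$TE[p] * r2) * ir)
  }, numeric(1))
  structure(K * vals, radii = radii, K = K)
}

#' Add Rician noise to magnitude signals
#'
#' Replaces each value `v` by `sqrt((v + g1)^2 + g2^2)` with independent
#' zero-mean Gaussians of standard deviation `sigma`, the magnitude noise
#' model of MRI. `sigma = 0` is the identity.
#'
#' @param values Numeric vector or array of noiseless magnitudes.
#' @param sigma Noise standard deviation; nonnegative.
#' @param seed Integer RNG seed (mandatory).
#' @return Noisy values, same shape.
#' @export
add_rician_noise <- function(values, sigma, seed) {
  if (sigma < 0) abort("sigma must be nonnegative.")
  if (missing(seed)) abort("A seed is required for reproducible noise.")
  if (sigma == 0) return(values)
  withr::with_seed(seed, {
    g1 <- rnorm(length(values), 0, sigma)
    g2 <- rnorm(length(values), 0, sigma)
    out <- sqrt((as.numeric(values) + g1)^2 + g2^2)
    attributes(out) <- attributes(values)
    out
  })
}

#' Build a synthetic DWI phantom with known ground truth
#'
#' Lays axon-radius populations into rectangular ROIs on a small voxel
#' grid and simulates every acquisition block of the protocol: each voxel
#' of an ROI carries the (direction-independent) mixture signal of that
#' ROI's radius sample, replicated over `n_directions` gradient
#' directions at b = 6000 s/mm^2, plus Rician noise. The phantom is the
#' end-to-end test bed: its ground-truth table records the realized
#' effective radius and generating relaxation times per ROI.
#'
#' @param rois Named list of 3D logical arrays (one mask per ROI, all on
#'   the same grid, non-overlapping).
#' @param radius_specs Named list (same names) of argument lists for
#'   [sample_radii()], excluding `seed`.
#' @param params_t2 [surface_params()] for the T2 channel.
#' @param params_t1 Optional T1-channel parameters; required when the
#'   protocol carries inversion times.
#' @param protocol Protocol tibble.
#' @param K Signal scale (default 500).
#' @param sigma Rician noise standard deviation (0 = noiseless).
#' @param seed Integer RNG seed (mandatory); per-ROI and per-block seeds
#'   are derived from it.
#' @param n_directions Gradient directions per block (default 48, the
#'   direction count of the targeted acquisitions).
#' @param out_dir Optional directory; when given, NIfTI volumes,
#'   bval/bvec files, the protocol YAML and the ground-truth CSV are
#'   written there.
#' @return A list with `blocks` (list of [dwi_block()], one per protocol
#'   row), `truth` (tibble: roi, n_axons, r_eff_um, T2a_ms, T1a_ms),
#'   `rois`, `protocol` and (if written) `paths`.
#' @export
make_phantom_dwi <- function(rois, radius_specs, params_t2,
                             params_t1 = NULL, protocol, K = 500,
                             sigma = 0, seed, n_directions = 48,
                             out_dir = NULL) {
  if (missing(seed)) abort("A seed is required.")
  stopifnot(length(rois) >= 1, identical(sort(names(rois)),
                                         sort(names(radius_specs))))
  grid_dim <- dim(rois[[1]])
  overlap <- Reduce(`+`, lapply(rois, function(m) m != 0))
  if (any(overlap > 1)) abort("ROI regions overlap.")
  joint <- !all(is.na(protocol$TI))
  if (joint && is.null(params_t1)) {
    abort("Protocol carries TI: params_t1 is required.")
  }

  truth <- vector("list", length(rois))
  signals <- matrix(0, nrow = length(rois), ncol = nrow(protocol))
  radii_list <- list()
  for (i in seq_along(rois)) {
    nm <- names(rois)[i]
    spec <- radius_specs[[nm]]
    spec$seed <- seed + i
    radii <- do.call(sample_radii, spec)
    radii_list[[nm]] <- radii
    signals[i, ] <- if (joint) {
      mixture_signal_t1t2(radii, params_t2, params_t1, K, protocol)
    } else {
      mixture_signal_t2(radii, params_t2, K, protocol$TE)
    }
    truth[[i]] <- tibble(
      roi = nm, n_axons = length(radii),
      r_eff_um = effective_radius(radii),
      T2a_ms = 1 / rate_from_radius(effective_radius(radii), params_t2),
      T1a_ms = if (joint) {
        1 / rate_from_radius(effective_radius(radii), params_t1)
      } else NA_real_
    )
  }
  truth <- dplyr::bind_rows(truth)

  bvecs <- unit_directions(n_directions)
  blocks <- vector("list", nrow(protocol))
  for (p in seq_len(nrow(protocol))) {
    vol <- array(0, dim = c(grid_dim, n_directions))
    for (i in seq_along(rois)) {
      idx <- which(rois[[i]] != 0)
      for (d in seq_len(n_directions)) {
        plane <- vol[, , , d]
        plane[idx] <- signals[i, p]
        vol[, , , d] <- plane
      }
    }
    if (sigma > 0) {
      vol <- add_rician_noise(vol, sigma, seed = seed + 1000L + p)
    }
    blocks[[p]] <- dwi_block(vol, bvals = rep(protocol$b[p], n_directions),
                             bvecs = bvecs, acquisition = protocol[p, ])
  }

  out <- list(blocks = blocks, truth = truth, rois = rois,
              protocol = protocol, radii = radii_list, K = K, sigma = sigma)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    for (p in seq_along(blocks)) {
      stem <- file.path(out_dir, sprintf("block%02d", p))
      write_volume(blocks[[p]]$volume, paste0(stem, ".nii"))
      writeLines(paste(blocks[[p]]$bvals, collapse = " "),
                 paste0(stem, ".bval"))
      writeLines(apply(blocks[[p]]$bvecs, 1, paste, collapse = " "),
                 paste0(stem, ".bvec"))
      paths <- c(paths, paste0(stem, ".nii"))
    }
    write_protocol(protocol, file.path(out_dir, "protocol.yaml"))
    readr::write_csv(truth, file.path(out_dir, "ground_truth.csv"))
    out$paths <- paths
  }
  out
}

# deterministic, roughly uniform unit directions (golden spiral)
unit_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  rbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Rectangular ROI masks on a small grid
#'
#' Convenience generator for phantom layouts: splits the grid into
#' non-overlapping axis-aligned boxes, one per ROI.
#'
#' @param grid_dim Integer vector of length 3.
#' @param n_rois Number of ROIs.
#' @return Named list of logical 3D arrays (`roi1`, `roi2`, ...).
#' @export
phantom_rois <- function(grid_dim = c(16, 16, 4), n_rois = 4) {
  per_row <- ceiling(sqrt(n_rois))
  xs <- floor(seq(1, grid_dim[1] + 1, length.out = per_row + 1))
  ys <- floor(seq(1, grid_dim[2] + 1, length.out = per_row + 1))
  rois <- list()
  k <- 0
  for (iy in seq_len(per_row)) {
    for (ix in seq_len(per_row)) {
      if (k >= n_rois) break
      k <- k + 1
      m <- array(FALSE, grid_dim)
      m[xs[ix]:(xs[ix + 1] - 1), ys[iy]:(ys[iy + 1] - 1), ] <- TRUE
      rois[[paste0("roi", k)]] <- m
    }
  }
  rois
}
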