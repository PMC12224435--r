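# File I/O (NIfTI volumes, FSL gradient tables, JSON run configs) and
# the synthetic fixture generator that stands behind all training and
# test datasets.

#' Generate a labeled synthetic voxel dataset
#'
#' Draws voxel parameters from the prior for each requested fiber
#' count, simulates HCP-style signals, optionally adds Gaussian noise,
#' and renders the 32 x 32 x 3 ODF maps. The returned provenance
#' (prior, seed, noise) is sufficient to regenerate the dataset
#' bit-identically.
#'
#' @param prior a [prior_spec()].
#' @param scheme a [acquisition_scheme()].
#' @param counts named integer vector: voxels per fiber count, e.g.
#'   `c("1" = 100, "2" = 100, "3" = 100)`.
#' @param noise_sigma Gaussian noise standard deviation (0 for
#'   noiseless).
#' @param seed integer seed.
#' @param render if FALSE, skip ODF-map rendering (signals only).
#' @return object of class `voxel_dataset`: signals (nvox x nmeas),
#'   maps (nvox x 3072 or NULL), labels, params (list of
#'   [voxel_params()]), alpha (list of per-class matrices), provenance.
#' @export
make_fixture <- function(prior = prior_spec(), scheme = hcp_scheme(),
                         counts = c("1" = 10, "2" = 10, "3" = 10),
                         noise_sigma = prior$sigma, seed = 1L,
                         render = TRUE) {
  if (any(counts < 1)) stop("counts must be >= 1")
  if (is.null(names(counts))) names(counts) <- seq_along(counts)
  set.seed(seed)
  params <- list(); labels <- integer(0)
  for (nf in names(counts)) {
    vps <- sample_prior(prior, as.integer(nf), counts[[nf]])
    params <- c(params, vps)
    labels <- c(labels, rep(as.integer(nf), counts[[nf]]))
  }
  nmeas <- nrow(scheme$directions)
  signals <- t(vapply(params, function(vp)
    simulate_signal(vp, scheme)$values, numeric(nmeas)))
  if (noise_sigma > 0)
    signals <- signals + matrix(rnorm(length(signals), 0, noise_sigma),
                                nrow(signals))
  maps <- if (render) render_maps_batch(signals, scheme) else NULL
  alpha <- lapply(split(seq_along(labels), labels), function(ii)
    do.call(rbind, lapply(params[ii], params_to_alpha)))
  structure(list(signals = signals, maps = maps, labels = labels,
                 params = params, alpha = alpha,
                 provenance = list(prior = prior, seed = seed,
                                   noise_sigma = noise_sigma,
                                   counts = counts)),
            class = "voxel_dataset")
}

#' Well-separated prior for classifier sanity protocols
#'
#' A restricted prior in which the three classes are unambiguous:
#' high fast-component FA for every fiber and wide crossing angles.
#' Used for scaled-down classifier checks where near-ceiling accuracy
#' is expected.
#'
#' @param min_fa FA floor applied to every fiber (including n = 1).
#' @param min_angle_2,min_angle_3 pairwise crossing-angle floors,
#'   degrees, for the two- and three-fiber classes.
#' @return a [prior_spec()] with `shared_lambda = TRUE`: one
#'   eigenvalue draw per voxel, so every ODF lobe is equally strong
#'   (classic crossing-phantom design).
#' @export
well_separated_prior <- function(min_fa = 0.35, min_angle_2 = 60,
                                 min_angle_3 = 60) {
  prior_spec(min_fa = min_fa, min_fa_n1 = min_fa,
             min_angle_deg = c("2" = min_angle_2, "3" = min_angle_3),
             shared_lambda = TRUE, sigma = 0)
}

#' Load a 4D diffusion volume with its gradient table
#'
#' Reads a NIfTI volume, normalizes every voxel by its mean b = 0
#' signal, and returns per-voxel signals for the diffusion-weighted
#' volumes together with the scheme restricted to those volumes.
#'
#' @param nifti_path 4D NIfTI path.
#' @param bval_path,bvec_path FSL-style gradient table paths.
#' @param mask_path optional 3D NIfTI brain mask (non-zero = keep).
#' @return list: signals (nvox x n_dwi), scheme (diffusion-weighted
#'   volumes only), coords (nvox x 3 voxel indices), dim (volume
#'   dimensions), ref (the RNifti image, for header reuse).
#' @export
load_dmri <- function(nifti_path, bval_path, bvec_path,
                      mask_path = NULL) {
  img <- RNifti::readNifti(nifti_path)
  dm <- dim(img)
  if (length(dm) != 4) stop("expected a 4D NIfTI volume")
  scheme_all <- read_bvals_bvecs(bval_path, bvec_path)
  if (nrow(scheme_all$directions) != dm[4])
    stop("gradient table and volume count mismatch")
  if (!any(scheme_all$b0)) stop("no b=0 volumes found")
  mask <- if (is.null(mask_path)) array(TRUE, dm[1:3])
  else RNifti::readNifti(mask_path) != 0
  if (!all(dim(mask) == dm[1:3])) stop("mask geometry mismatch")
  vox <- which(mask, arr.ind = TRUE)
  mat <- matrix(img, prod(dm[1:3]), dm[4])
  flat <- (vox[, 3] - 1) * dm[1] * dm[2] + (vox[, 2] - 1) * dm[1] +
    vox[, 1]
  sig <- mat[flat, , drop = FALSE]
  b0_mean <- rowMeans(sig[, scheme_all$b0, drop = FALSE])
  b0_mean[b0_mean <= 0] <- NA_real_
  dwi <- !scheme_all$b0
  signals <- sig[, dwi, drop = FALSE] / b0_mean
  scheme <- acquisition_scheme(scheme_all$directions[dwi, ,
                                                     drop = FALSE],
                               scheme_all$bvalues[dwi])
  list(signals = signals, scheme = scheme, coords = vox, dim = dm[1:3],
       ref = img)
}

#' Write per-voxel scalar maps as NIfTI volumes
#'
#' @param values named list of per-voxel numeric vectors (aligned with
#'   `coords`).
#' @param coords nvox x 3 matrix of voxel indices.
#' @param dim 3D volume dimensions.
#' @param out_dir output directory.
#' @param ref optional RNifti image whose header geometry is copied.
#' @return named character vector of written paths. Voxels outside
#'   the mask are written as NaN.
#' @export
save_maps <- function(values, coords, dim, out_dir, ref = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  flat <- (coords[, 3] - 1) * dim[1] * dim[2] +
    (coords[, 2] - 1) * dim[1] + coords[, 1]
  paths <- character(0)
  for (nm in names(values)) {
    v <- values[[nm]]
    if (length(v) != nrow(coords)) stop("value/coords mismatch: ", nm)
    vol <- array(NaN, dim)
    vol[flat] <- v
    p <- file.path(out_dir, paste0(nm, ".nii.gz"))
    img <- if (is.null(ref)) RNifti::asNifti(vol)
    else RNifti::asNifti(vol, reference = ref)
    RNifti::writeNifti(img, p)
    paths[nm] <- p
  }
  paths
}

#' Save / load a run configuration (JSON round trip)
#'
#' @param cfg a named list of plain values (seeds, sizes, prior
#'   fields, mode).
#' @param path JSON path.
#' @return `save_run_config` returns the path; `load_run_config` the
#'   restored list.
#' @export
save_run_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' End-to-end voxel-wise pipeline
#'
#' Classifier routes each voxel to the posterior network matching its
#' predicted fiber count; the dominant mixture component provides the
#' point estimate and per-parameter uncertainty, from which derived
#' measures are propagated on request.
#'
#' @param signals nvox x nmeas matrix of normalized signals.
#' @param scheme the shared [acquisition_scheme()].
#' @param classifier a trained `fiber_classifier`.
#' @param posteriors named list of trained `posterior_net`s, names
#'   "1", "2", "3".
#' @param prior a [prior_spec()].
#' @param measures character vector of measures to propagate (subset
#'   of FA, MD, MSD, RTOP) or NULL.
#' @param rule dominant-component selection rule.
#' @return list with per-voxel `label`, `alpha` (list), `sd` (list),
#'   `nmse` (model fit quality vs the input signal) and optionally
#'   `measures` (data.frame).
#' @export
fit_voxels <- function(signals, scheme, classifier, posteriors,
                       prior = prior_spec(), measures = NULL,
                       rule = "delta") {
  maps <- render_maps_batch(signals, scheme)
  labels <- predict_fiber_count(classifier, maps)$label
  nvox <- nrow(signals)
  alpha <- vector("list", nvox)
  sds <- vector("list", nvox)
  fit_nmse <- numeric(nvox)
  meas_rows <- list()
  for (nf in sort(unique(labels))) {
    key <- as.character(nf)
    if (is.null(posteriors[[key]]))
      stop("no posterior network for n = ", key)
    sel <- which(labels == nf)
    posts <- posterior_predict(posteriors[[key]],
                               maps[sel, , drop = FALSE])
    for (j in seq_along(sel)) {
      v <- sel[j]
      est <- select_dominant_component(posts[[j]], rule = rule,
                                       prior = prior)
      alpha[[v]] <- est$alpha_hat
      sds[[v]] <- est$sd
      rec <- .signal_from_alpha(.canonical_alpha(est$alpha_hat),
                                prior$w, scheme)
      fit_nmse[v] <- nmse(rec, signals[v, ])
      if (!is.null(measures)) {
        for (mm in measures) {
          pm <- posterior_measure(est, mm, fiber = 1L, w = prior$w)
          meas_rows[[length(meas_rows) + 1L]] <-
            data.frame(voxel = v, measure = mm, mean = pm$mean,
                       std = pm$std)
        }
      }
    }
  }
  out <- list(label = labels, alpha = alpha, sd = sds,
              nmse = fit_nmse)
  if (!is.null(measures)) out$measures <- do.call(rbind, meas_rows)
  out
}
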