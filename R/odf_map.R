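# 2D ODF maps: the 32 x 32 x 3 image representation (rows = theta in
# [0, pi], cols = phi in [0, 2 pi), one channel per b-shell) used as
# the input of both the fiber-count classifier and the posterior
# networks. Image batches are stored as flat matrices in the engine
# layout: column index = h + H (w - 1) + H W (c - 1), 1-based.

.dmripost_cache <- new.env(parent = emptyenv())

.map_grid <- function(size = 32L) {
  key <- paste0("grid", size)
  g <- .dmripost_cache[[key]]
  if (is.null(g)) {
    th <- (seq_len(size) - 0.5) / size * pi
    ph <- (seq_len(size) - 0.5) / size * 2 * pi
    g <- list(theta = rep(th, times = size),
              phi = rep(ph, each = size), size = size)
    .dmripost_cache[[key]] <- g
  }
  g
}

.map_basis <- function(L, size = 32L) {
  key <- paste0("mapbasis", L, "_", size)
  B <- .dmripost_cache[[key]]
  if (is.null(B)) {
    g <- .map_grid(size)
    B <- sh_basis(L, g$theta, g$phi)
    .dmripost_cache[[key]] <- B
  }
  B
}

# per-shell projection matrix: signal samples -> ODF SH coefficients
.shell_projector <- function(scheme, shell, L, lambda) {
  key <- paste0("proj_", shell, "_", L, "_", lambda, "_",
                nrow(scheme$directions),
                "_", format(sum(scheme$directions), digits = 12))
  M <- .dmripost_cache[[key]]
  if (is.null(M)) {
    sel <- which(scheme$shell_ids == shell)
    dirs <- scheme$directions[sel, , drop = FALSE]
    th <- acos(pmin(1, pmax(-1, dirs[, 3])))
    ph <- atan2(dirs[, 2], dirs[, 1])
    B <- sh_basis(L, th, ph)
    idx <- .sh_index(L)
    reg <- (idx$l * (idx$l + 1))^2
    M <- solve(crossprod(B) + lambda * diag(reg, ncol(B)), t(B))
    M <- frt_eigenvalue(idx$l) * M      # fold in the Funk-Radon scaling
    attr(M, "sel") <- sel
    .dmripost_cache[[key]] <- M
  }
  M
}

#' Render the 32 x 32 x 3 ODF map of one voxel
#'
#' Fits even-degree spherical harmonics per b-shell, applies the
#' Funk-Radon transform (analytic q-ball ODF) and evaluates each
#' shell's ODF on a uniform grid in (theta, phi); rows map to theta in
#' \[0, pi\], columns to phi in \[0, 2 pi). Channels are min-max
#' normalized to \[0, 1\] independently; a constant (isotropic) channel
#' maps to all zeros.
#'
#' @param signal a `dmri_signal` covering all three shells.
#' @param L maximum SH degree (default 8).
#' @param lambda Laplace-Beltrami regularization weight.
#' @param size grid size per axis (default 32).
#' @return an `odf_map`: a size x size x 3 array.
#' @export
render_map <- function(signal, L = 8, lambda = 6e-3, size = 32L) {
  stopifnot(inherits(signal, "dmri_signal"))
  flat <- render_maps_batch(matrix(signal$values, nrow = 1),
                            signal$scheme, L = L, lambda = lambda,
                            size = size)
  structure(array(flat[1, ], dim = c(size, size, 3)), class = "odf_map")
}

#' Render ODF maps for a batch of voxels
#'
#' Vectorized version of [render_map()]: all per-voxel fits and grid
#' evaluations are carried out as dense matrix products.
#'
#' @param signals nvox x nmeas matrix of signal values, columns aligned
#'   with the scheme.
#' @param scheme the shared [acquisition_scheme()]; must have 3 shells.
#' @param L,lambda,size see [render_map()].
#' @return nvox x (size*size*3) matrix in engine layout (theta index
#'   fastest, then phi, then shell channel).
#' @export
render_maps_batch <- function(signals, scheme, L = 8, lambda = 6e-3,
                              size = 32L) {
  if (length(scheme$shells) != 3L)
    stop("expected a 3-shell scheme")
  B <- .map_basis(L, size)
  npx <- size * size
  out <- matrix(0, nrow(signals), 3L * npx)
  for (ch in 1:3) {
    M <- .shell_projector(scheme, ch, L, lambda)
    sel <- attr(M, "sel")
    coeffs <- signals[, sel, drop = FALSE] %*% t(M)   # nvox x R
    vals <- coeffs %*% t(B)                           # nvox x npx
    lo <- apply(vals, 1, min)
    hi <- apply(vals, 1, max)
    rng <- hi - lo
    rng[rng < 1e-12] <- Inf            # constant channel -> zeros
    out[, (ch - 1L) * npx + seq_len(npx)] <- (vals - lo) / rng
  }
  out
}

# dense quasi-uniform sphere tessellation with neighbor lists, cached
.peak_grid <- function(n = 3000L, k = 8L) {
  key <- paste0("peakgrid", n, "_", k)
  g <- .dmripost_cache[[key]]
  if (is.null(g)) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    phi <- pi * (1 + sqrt(5)) * i
    st <- sqrt(pmax(0, 1 - z^2))
    pts <- cbind(st * cos(phi), st * sin(phi), z)
    gram <- tcrossprod(pts)
    nb <- t(apply(-gram, 1, function(r) order(r)[2:(k + 1)]))
    g <- list(pts = pts,
              theta = acos(pmin(1, pmax(-1, pts[, 3]))),
              phi = atan2(pts[, 2], pts[, 1]) %% (2 * pi),
              nb = nb)
    .dmripost_cache[[key]] <- g
  }
  g
}

#' Extract ODF peaks by hill climbing
#'
#' Candidate maxima are located on a dense quasi-uniform sphere
#' tessellation (local maxima over nearest neighbors), refined by
#' Nelder-Mead ascent on the SH expansion, folded antipodally into the
#' hemisphere, merged within the separation radius and thresholded
#' relative to the global maximum.
#'
#' @param odf an `sh_coeffs` object in the ODF domain.
#' @param min_separation merge radius in degrees (default 15).
#' @param relative_threshold discard peaks below this fraction of the
#'   global maximum (default 0.3).
#' @return object of class `peak_set`: list(directions, amplitudes,
#'   theta_phi), sorted by descending amplitude.
#' @export
find_peaks <- function(odf, min_separation = 15,
                       relative_threshold = 0.3) {
  stopifnot(inherits(odf, "sh_coeffs"))
  if (relative_threshold <= 0 || relative_threshold > 1)
    stop("relative_threshold must be in (0, 1]")
  if (min_separation <= 0) stop("min_separation must be positive")
  g <- .peak_grid()
  vals <- drop(sh_basis(odf$L, g$theta, g$phi) %*% odf$coeffs)
  vmax <- max(vals)
  rng <- vmax - min(vals)
  if (rng < 1e-10 * max(1, abs(vmax)))
    return(structure(list(directions = matrix(0, 0, 3),
                          amplitudes = numeric(0),
                          theta_phi = matrix(0, 0, 2)),
                     class = "peak_set"))
  is_max <- vapply(seq_along(vals), function(i)
    vals[i] >= max(vals[g$nb[i, ]]), logical(1))
  cand <- which(is_max & vals >= relative_threshold * vmax)
  if (!length(cand))
    return(structure(list(directions = matrix(0, 0, 3),
                          amplitudes = numeric(0),
                          theta_phi = matrix(0, 0, 2)),
                     class = "peak_set"))
  refine <- function(i) {
    o <- optim(c(g$theta[i], g$phi[i]),
               function(x) -sh_eval(odf, x[1], x[2]),
               method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 200))
    c(o$par, -o$value)
  }
  ref <- t(vapply(cand, refine, numeric(3)))
  dirs <- sph_to_cart(ref[, 1], ref[, 2])
  dirs <- matrix(dirs, ncol = 3)
  amps <- ref[, 3]
  ord <- order(amps, decreasing = TRUE)
  dirs <- dirs[ord, , drop = FALSE]
  amps <- amps[ord]
  keep <- integer(0)
  for (i in seq_along(amps)) {
    if (!length(keep)) { keep <- i; next }
    sep <- vapply(keep, function(j)
      crossing_angle(dirs[i, ], dirs[j, ]), numeric(1))
    if (all(sep > min_separation)) keep <- c(keep, i)
  }
  dirs <- dirs[keep, , drop = FALSE]
  amps <- amps[keep]
  amps <- amps[amps >= relative_threshold * max(amps)]
  dirs <- dirs[seq_along(amps), , drop = FALSE]
  tp <- t(apply(dirs, 1, cart_to_sph))       # antipodal fold
  tp <- matrix(tp, ncol = 2)
  dirs <- matrix(sph_to_cart(tp[, 1], tp[, 2]), ncol = 3)
  structure(list(directions = matrix(dirs, ncol = 3),
                 amplitudes = amps,
                 theta_phi = matrix(tp, ncol = 2)),
            class = "peak_set")
}
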