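# Closed-form microstructure measures of the biexponential multi-tensor
# model and unscented-transform propagation of posterior uncertainty.

#' Fractional anisotropy of a cylindrically symmetric (fast) tensor
#'
#' FA = sqrt((lam1 - lam2)^2 / (lam1^2 + 2 lam2^2)), the standard
#' three-eigenvalue FA specialized to eigenvalues (lam1, lam2, lam2).
#' Vectorized.
#'
#' @param lam1,lam2 eigenvalues, um^2/ms, lam1 >= lam2 > 0.
#' @return FA in \[0, 1\].
#' @export
fa_fast <- function(lam1, lam2) {
  if (any(lam1 <= 0) || any(lam2 <= 0))
    stop("eigenvalues must be positive")
  sqrt((lam1 - lam2)^2 / (lam1^2 + 2 * lam2^2))
}

#' Generalized fractional anisotropy of a signal
#'
#' GFA = std(S) / rms(S). By default the population standard deviation
#' (divide by N) is used, so that GFA^2 = 1 - mean(S)^2 / rms(S)^2
#' holds exactly and GFA is bounded by 1.
#'
#' @param values signal samples (conventionally the b = 1000 s/mm^2
#'   shell).
#' @param type `"population"` (default) or `"sample"` standard
#'   deviation convention.
#' @return GFA in \[0, 1\] (population convention).
#' @export
gfa <- function(values, type = c("population", "sample")) {
  type <- match.arg(type)
  if (length(values) < 2) stop("need at least 2 samples")
  rms <- sqrt(mean(values^2))
  if (rms == 0) stop("all-zero signal")
  s <- if (type == "population")
    sqrt(mean((values - mean(values))^2)) else sd(values)
  s / rms
}

#' GFA of a simulated voxel on one shell
#'
#' @param signal a `dmri_signal`.
#' @param shell shell index (default 1, i.e. b = 1000 s/mm^2).
#' @param ... passed to [gfa()].
#' @return scalar GFA.
#' @export
signal_gfa <- function(signal, shell = 1L, ...) {
  gfa(signal$values[signal$scheme$shell_ids == shell], ...)
}

# coerce a voxel_params (or list(lam = n x 4 matrix, w = vector)) to
# the eigenvalue set used by MSD/RTOP
.as_eigen <- function(ev) {
  if (inherits(ev, "voxel_params")) {
    lam <- t(vapply(ev$fibers, function(f)
      c(f$lam1, f$lam2, f$lam3, f$lam4), numeric(4)))
    w <- vapply(ev$fibers, function(f) f$w, numeric(1))
    return(list(lam = lam, w = w, n = ev$n))
  }
  lam <- matrix(ev$lam, ncol = 4)
  w <- rep(ev$w, length.out = nrow(lam))
  list(lam = lam, w = w, n = nrow(lam))
}

#' Mean squared displacement
#'
#' MSD = (1/n) pi^2 sum_i \[ w_i (lam1_i + 2 lam2_i) +
#' (1 - w_i)(lam3_i + 2 lam4_i) \]: the compartment-weighted tensor
#' trace averaged over fibers, with the diffusion-time convention
#' absorbed into the pi^2 prefactor. Linear (degree 1 homogeneous) in
#' the eigenvalues.
#'
#' @param ev a [voxel_params()] or list(lam = n x 4 matrix, w).
#' @return MSD in um^2 (model convention).
#' @export
msd <- function(ev) {
  e <- .as_eigen(ev)
  if (any(e$lam <= 0)) stop("eigenvalues must be positive")
  tr_fast <- e$lam[, 1] + 2 * e$lam[, 2]
  tr_slow <- e$lam[, 3] + 2 * e$lam[, 4]
  pi^2 / e$n * sum(e$w * tr_fast + (1 - e$w) * tr_slow)
}

#' Return-to-origin probability
#'
#' RTOP = (2/n) pi^(3/2) sum_i \[ w_i / (lam2_i sqrt(lam1_i)) +
#' (1 - w_i) / (lam4_i sqrt(lam3_i)) \]: the compartment-weighted
#' inverse square-root determinant of the cylindrical tensors
#' (det = lam1 lam2^2), homogeneous of degree -3/2 and strictly
#' decreasing in every eigenvalue.
#'
#' @param ev a [voxel_params()] or list(lam = n x 4 matrix, w).
#' @return RTOP in model units.
#' @export
rtop <- function(ev) {
  e <- .as_eigen(ev)
  if (any(e$lam <= 0)) stop("eigenvalues must be positive")
  fast <- e$w / (e$lam[, 2] * sqrt(e$lam[, 1]))
  slow <- (1 - e$w) / (e$lam[, 4] * sqrt(e$lam[, 3]))
  2 * pi^1.5 / e$n * sum(fast + slow)
}

#' Mean diffusivity of the fast cylindrical tensor
#'
#' MD = (lam1 + 2 lam2) / 3. Vectorized.
#'
#' @param lam1,lam2 eigenvalues, um^2/ms.
#' @return MD in um^2/ms.
#' @export
mean_diffusivity <- function(lam1, lam2) {
  if (any(lam1 <= 0) || any(lam2 <= 0))
    stop("eigenvalues must be positive")
  (lam1 + 2 * lam2) / 3
}

#' Unscented-transform configuration
#'
#' Symmetric sigma-point set with 2d + 1 points and spread parameter
#' kappa (default 3 - d, the classical heuristic matching the fourth
#' moment of a Gaussian in low dimension). Weights sum to 1 by
#' construction.
#'
#' @param kappa spread parameter; NULL selects 3 - d at call time.
#' @param lower optional lower bounds; sigma points below a bound are
#'   reflected into the feasible region and flagged.
#' @return object of class `ut_config`.
#' @export
ut_config <- function(kappa = NULL, lower = NULL) {
  structure(list(kappa = kappa, lower = lower), class = "ut_config")
}

#' Propagate a Gaussian through a nonlinear function (unscented
#' transform)
#'
#' Standard symmetric sigma-point transform: points mu and
#' mu +/- sqrt(d + kappa) times the columns of a square root of Sigma,
#' with weights kappa/(d + kappa) and 1/(2(d + kappa)). Exact for
#' affine functions.
#'
#' @param mean mean vector.
#' @param cov SPD covariance matrix (or all-zero for a point mass).
#' @param f function of one vector argument returning a scalar or
#'   vector.
#' @param cfg a [ut_config()].
#' @return list(mean, var, n_reflected); `var` is the full covariance
#'   when f returns a vector.
#' @export
unscented_propagate <- function(mean, cov, f, cfg = ut_config()) {
  d <- length(mean)
  cov <- as.matrix(cov)
  kappa <- if (is.null(cfg$kappa)) 3 - d else cfg$kappa
  if (d + kappa <= 0) stop("need d + kappa > 0")
  if (all(cov == 0)) {
    y <- f(mean)
    return(list(mean = y, var = if (length(y) == 1) 0
                else matrix(0, length(y), length(y)),
                n_reflected = 0L))
  }
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values)))
    stop("covariance must be positive semi-definite")
  A <- ev$vectors %*% diag(sqrt(pmax(0, ev$values)), d)
  pts <- matrix(rep(mean, 2 * d + 1), ncol = d, byrow = TRUE)
  sc <- sqrt(d + kappa)
  for (i in seq_len(d)) {
    pts[1 + i, ] <- mean + sc * A[, i]
    pts[1 + d + i, ] <- mean - sc * A[, i]
  }
  n_reflected <- 0L
  if (!is.null(cfg$lower)) {
    lower <- rep(cfg$lower, length.out = d)
    for (j in seq_len(nrow(pts))) {
      bad <- pts[j, ] < lower
      if (any(bad)) {
        pts[j, bad] <- 2 * lower[bad] - pts[j, bad]
        n_reflected <- n_reflected + 1L
      }
    }
  }
  wts <- c(kappa / (d + kappa), rep(1 / (2 * (d + kappa)), 2 * d))
  ys <- lapply(seq_len(nrow(pts)), function(j) f(pts[j, ]))
  y0 <- ys[[1]]
  Y <- do.call(rbind, lapply(ys, as.numeric))
  mu_y <- colSums(wts * Y)
  if (length(y0) == 1) {
    var_y <- sum(wts * (Y[, 1] - mu_y)^2)
  } else {
    Dev <- sweep(Y, 2, mu_y)
    var_y <- t(Dev) %*% (wts * Dev)
  }
  list(mean = if (length(y0) == 1) mu_y[1] else mu_y,
       var = var_y, n_reflected = n_reflected)
}

#' Inverse-variance weighted mean
#'
#' sum(v_i / s2_i) / sum(1 / s2_i): data points contribute inversely
#' to their variance.
#'
#' @param values numeric vector.
#' @param variances positive variances, aligned with `values`.
#' @return scalar weighted mean.
#' @export
variance_weighted_mean <- function(values, variances) {
  if (length(values) != length(variances))
    stop("length mismatch")
  if (any(variances <= 0)) stop("variances must be positive")
  sum(values / variances) / sum(1 / variances)
}

#' Posterior mean and uncertainty of a derived measure
#'
#' Propagates the dominant-component posterior of the eigenvalue
#' sub-vector through the measure's closed form with the unscented
#' transform. Angles do not enter FA/MD/MSD/RTOP and are marginalized
#' out by sub-setting the mean and covariance.
#'
#' @param est a `parameter_estimate` from
#'   [select_dominant_component()].
#' @param measure one of "FA", "MD", "MSD", "RTOP".
#' @param fiber fiber index for the per-fiber measures FA and MD.
#' @param w fast-compartment fraction assumed by MSD/RTOP.
#' @return object of class `measure_estimate`: list(name, mean, std).
#' @export
posterior_measure <- function(est, measure = c("FA", "MD", "MSD",
                                               "RTOP"),
                              fiber = 1L, w = 0.7) {
  measure <- match.arg(measure)
  stopifnot(inherits(est, "parameter_estimate"))
  n <- length(est$alpha_hat) / 6
  lam_idx <- as.vector(vapply(seq_len(n), function(i)
    (i - 1) * 6 + 3:6, numeric(4)))
  if (measure %in% c("FA", "MD")) {
    idx <- (fiber - 1) * 6 + 3:4
    f <- if (measure == "FA")
      function(x) fa_fast(max(x[1], x[2]), min(x[1], x[2]))
    else function(x) mean_diffusivity(x[1], x[2])
  } else {
    idx <- lam_idx
    f <- function(x) {
      lam <- matrix(x, ncol = 4, byrow = TRUE)
      lam <- t(apply(lam, 1, function(r)
        c(sort(r[1:2], decreasing = TRUE),
          sort(r[3:4], decreasing = TRUE))))
      ev <- list(lam = lam, w = w)
      if (measure == "MSD") msd(ev) else rtop(ev)
    }
  }
  mu <- est$alpha_hat[idx]
  Sig <- est$cov[idx, idx, drop = FALSE]
  r <- unscented_propagate(mu, Sig, f,
                           ut_config(lower = rep(1e-3, length(idx))))
  structure(list(name = measure, mean = r$mean,
                 std = sqrt(max(0, r$var)),
                 n_reflected = r$n_reflected),
            class = "measure_estimate")
}
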