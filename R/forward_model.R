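#' Single-fiber biexponential compartment parameters
#'
#' Each fiber is modeled as two cylindrically symmetric Gaussian
#' compartments (fast and slow) sharing their eigenvectors. The
#' principal axis is m(theta, phi) = (sin t cos p, sin t sin p, cos t);
#' because fiber orientations are axes (antipodally symmetric), theta
#' and phi are both restricted to \[0, pi\].
#'
#' @param theta polar angle, rad, in \[0, pi\].
#' @param phi azimuth, rad, in \[0, pi\].
#' @param lam1,lam2 fast-compartment eigenvalues, um^2/ms, lam1 >= lam2 > 0;
#'   lam1 lies along the fiber axis.
#' @param lam3,lam4 slow-compartment eigenvalues, um^2/ms, lam3 >= lam4 > 0.
#' @param w fast-compartment signal fraction in (0, 1).
#' @return an object of class `fiber_params`.
#' @export
fiber_params <- function(theta, phi, lam1, lam2, lam3, lam4, w = 0.7) {
  if (!is.finite(theta) || !is.finite(phi))
    stop("angles must be finite")
  if (lam2 <= 0 || lam4 <= 0 || lam1 < lam2 || lam3 < lam4)
    stop("invalid eigenvalues: need lam1 >= lam2 > 0, lam3 >= lam4 > 0")
  if (w <= 0 || w >= 1) stop("w must be in (0, 1)")
  structure(list(theta = theta, phi = phi, lam1 = lam1, lam2 = lam2,
                 lam3 = lam3, lam4 = lam4, w = w),
            class = "fiber_params")
}

#' Voxel parameters: 1 to 3 crossing fibers
#'
#' The full parameter vector of an n-fiber voxel is
#' alpha = (theta_i, phi_i, lam1_i, lam2_i, lam3_i, lam4_i) for
#' i = 1..n, dimension 6n.
#'
#' @param fibers list of [fiber_params()] objects (1 to 3).
#' @return an object of class `voxel_params` with fields `fibers`, `n`.
#' @export
voxel_params <- function(fibers) {
  if (inherits(fibers, "fiber_params")) fibers <- list(fibers)
  n <- length(fibers)
  if (n < 1 || n > 3) stop("1 to 3 fibers supported")
  if (!all(vapply(fibers, inherits, TRUE, "fiber_params")))
    stop("fibers must be fiber_params objects")
  structure(list(fibers = fibers, n = n), class = "voxel_params")
}

#' Spherical to Cartesian unit vector
#' @param theta,phi spherical angles, rad.
#' @return unit 3-vector (or matrix when inputs are vectors).
#' @export
sph_to_cart <- function(theta, phi) {
  out <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  if (nrow(out) == 1L) drop(out) else out
}

#' Cartesian unit vector to spherical angles in the right hemisphere
#'
#' Folds the axis antipodally so that theta, phi lie in \[0, pi\].
#' @param v unit 3-vector.
#' @return c(theta, phi).
#' @export
cart_to_sph <- function(v) {
  v <- v / sqrt(sum(v^2))
  # fold into y >= 0 (phi in [0, pi]); at y == 0 require x >= 0
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0) ||
      (v[1] == 0 && v[2] == 0 && v[3] < 0)) v <- -v
  theta <- acos(pmin(1, pmax(-1, v[3])))
  phi <- atan2(v[2], v[1])
  if (phi < 0) phi <- phi + pi        # guard rounding at the seam
  c(theta = theta, phi = phi)
}

# deterministic orthonormal completion {p, v} of a unit axis m;
# reference axis z with x fallback near the pole. The simulated signal
# is independent of this choice because lam2 (lam4) weights p and v
# equally.
orthonormal_completion <- function(m) {
  ref <- if (abs(m[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p <- ref - sum(ref * m) * m
  p <- p / sqrt(sum(p^2))
  v <- c(m[2] * p[3] - m[3] * p[2],
         m[3] * p[1] - m[1] * p[3],
         m[1] * p[2] - m[2] * p[1])
  cbind(p = p, v = v)
}

#' Fast and slow diffusion tensors of a fiber
#'
#' Builds the cylindrically symmetric tensor pair
#' D = lam1 m m' + lam2 (p p' + v v') and
#' Dbar = lam3 m m' + lam4 (p p' + v v'), where (m, p, v) is any
#' orthonormal frame with m the fiber axis. Using
#' p p' + v v' = I - m m', the result is independent of the completion.
#'
#' @param f a [fiber_params()] object.
#' @return list with symmetric positive definite 3x3 matrices `D`
#'   (fast) and `Dbar` (slow), um^2/ms.
#' @export
tensor_from_fiber <- function(f) {
  stopifnot(inherits(f, "fiber_params"))
  m <- sph_to_cart(f$theta, f$phi)
  P <- diag(3) - tcrossprod(m)        # p p' + v v'
  M <- tcrossprod(m)
  list(D = f$lam1 * M + f$lam2 * P,
       Dbar = f$lam3 * M + f$lam4 * P)
}

# per-fiber attenuation for all directions of a scheme:
# w exp(-b u'Du * 1e-3) + (1-w) exp(-b u'Dbar u * 1e-3)
# (b in s/mm^2, eigenvalues in um^2/ms, so b*lambda*1e-3 is
# dimensionless)
.fiber_attenuation <- function(f, scheme) {
  ten <- tensor_from_fiber(f)
  U <- scheme$directions
  qf <- rowSums((U %*% ten$D) * U)
  qs <- rowSums((U %*% ten$Dbar) * U)
  b <- scheme$bvalues * 1e-3
  f$w * exp(-b * qf) + (1 - f$w) * exp(-b * qs)
}

#' Simulate the noiseless biexponential multi-tensor signal
#'
#' S(b, u) = (1/n) sum_i \[ w_i exp(-b u' D_i u) +
#' (1 - w_i) exp(-b u' Dbar_i u) \]. The 1/n factor normalizes the
#' attenuation so that S(0, u) = 1 for every fiber count. Per-fiber
#' contributions are summed in a canonical (sorted) order so that the
#' output is bit-identical under any permutation of the fibers.
#'
#' @param vp a [voxel_params()] object.
#' @param scheme a [acquisition_scheme()] object.
#' @return an object of class `dmri_signal`: list(values, scheme).
#' @export
simulate_signal <- function(vp, scheme) {
  stopifnot(inherits(vp, "voxel_params"), inherits(scheme, "dmri_scheme"))
  contribs <- vapply(vp$fibers, .fiber_attenuation,
                     numeric(nrow(scheme$directions)), scheme = scheme)
  contribs <- matrix(contribs, ncol = vp$n)
  values <- .order_free_rowsum(contribs) / vp$n
  structure(list(values = values, scheme = scheme),
            class = "dmri_signal")
}

# sum the columns of a (ndir x n) matrix, n <= 3, in ascending value
# order per row so the result does not depend on column order
.order_free_rowsum <- function(m) {
  n <- ncol(m)
  if (n == 1L) return(m[, 1])
  if (n == 2L) return(pmin(m[, 1], m[, 2]) + pmax(m[, 1], m[, 2]))
  a <- pmin(m[, 1], m[, 2]); b <- pmax(m[, 1], m[, 2])
  lo <- pmin(a, m[, 3]); m1 <- pmax(a, m[, 3])
  mid <- pmin(b, m1); hi <- pmax(b, m1)
  (lo + mid) + hi
}

#' Add zero-mean Gaussian measurement noise to a signal
#'
#' Gaussian noise is an adequate approximation of the Rician magnitude
#' noise for SNR above about 3; sigma = 0.04 corresponds to an average
#' white-matter SNR of roughly 3 for the normalized signal.
#'
#' @param s a `dmri_signal`.
#' @param sigma noise standard deviation (signal units); must be >= 0.
#' @param seed optional integer seed for reproducibility.
#' @return a `dmri_signal` with perturbed values.
#' @export
add_noise <- function(s, sigma, seed = NULL) {
  stopifnot(inherits(s, "dmri_signal"))
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(s)
  if (!is.null(seed)) set.seed(seed)
  s$values <- s$values + rnorm(length(s$values), 0, sigma)
  s
}

#' Uniform prior specification over voxel parameters
#'
#' Defaults follow the plausible white-matter ranges used for training:
#' fast eigenvalues uniform in \[1, 3\] um^2/ms, slow eigenvalues in
#' \[0.1, 0.6\] um^2/ms, fast fraction fixed at 0.7, measurement noise
#' sigma = 0.04. Multi-fiber voxels additionally require fast-component
#' FA > 0.2 for every fiber, and minimum pairwise crossing angles of
#' 10 degrees (n = 2) and 45 degrees (n = 3).
#'
#' @param theta_range,phi_range angle ranges, rad.
#' @param fast_range,slow_range eigenvalue ranges, um^2/ms.
#' @param w fixed fast-compartment fraction.
#' @param min_fa minimum fast-component FA per fiber when n >= 2.
#' @param min_fa_n1 FA floor for single-fiber voxels (default 0: the
#'   single-fiber tensor may be fully isotropic).
#' @param min_angle_deg named-by-n minimum pairwise crossing angle,
#'   degrees: c(`2` = 10, `3` = 45).
#' @param shared_lambda if TRUE, all fibers of a voxel share one
#'   eigenvalue draw (a classic crossing-phantom design in which every
#'   ODF lobe is equally strong); default FALSE draws eigenvalues
#'   independently per fiber.
#' @param sigma noise standard deviation of the acquisition.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(theta_range = c(0, pi), phi_range = c(0, pi),
                       fast_range = c(1, 3), slow_range = c(0.1, 0.6),
                       w = 0.7, min_fa = 0.2, min_fa_n1 = 0,
                       min_angle_deg = c("2" = 10, "3" = 45),
                       shared_lambda = FALSE,
                       sigma = 0.04) {
  structure(list(theta_range = theta_range, phi_range = phi_range,
                 fast_range = fast_range, slow_range = slow_range,
                 w = w, min_fa = min_fa, min_fa_n1 = min_fa_n1,
                 min_angle_deg = min_angle_deg,
                 shared_lambda = isTRUE(shared_lambda),
                 sigma = sigma),
            class = "prior_spec")
}

#' Crossing angle between two fiber axes
#'
#' Antipodally folded: acos(|<m1, m2>|), in \[0, 90\] degrees.
#' @param m1,m2 unit 3-vectors.
#' @return angle in degrees.
#' @export
crossing_angle <- function(m1, m2) {
  acos(pmin(1, abs(sum(m1 * m2)))) * 180 / pi
}

#' Sample voxel parameters from the uniform prior
#'
#' Draws are uniform on the constrained support. Constraints
#' (eigenvalue ordering, the FA floor for multi-fiber voxels, minimum
#' pairwise crossing angles) are enforced by rejection, which keeps the
#' distribution exactly uniform on the accepted set.
#'
#' @param spec a [prior_spec()].
#' @param n_fibers fiber count, 1 to 3.
#' @param count number of voxels to draw.
#' @param seed optional integer seed.
#' @return list of [voxel_params()] of length `count`.
#' @export
sample_prior <- function(spec, n_fibers, count, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"))
  if (!n_fibers %in% 1:3) stop("n_fibers must be 1, 2 or 3")
  if (count < 1) stop("count must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", count)
  got <- 0L
  tried <- 0L
  min_angle <- if (n_fibers >= 2)
    spec$min_angle_deg[[as.character(n_fibers)]] else 0
  while (got < count) {
    chunk <- max(64L, 2L * (count - got))
    cand <- .draw_prior_chunk(spec, n_fibers, chunk, min_angle)
    tried <- tried + chunk
    take <- min(length(cand), count - got)
    if (take > 0) {
      out[(got + 1L):(got + take)] <- cand[seq_len(take)]
      got <- got + take
    }
    if (tried > 1000 && got / tried < 0.001)
      stop("prior constraints reject > 99.9% of draws; ",
           "configuration infeasible")
  }
  out
}

# draw a chunk of candidates and keep those satisfying the joint
# constraints; eigenvalue ordering is itself handled by rejection
.draw_prior_chunk <- function(spec, n_fibers, chunk, min_angle) {
  total <- chunk * n_fibers
  draw_pair <- function(rng, m) {
    a <- runif(m, rng[1], rng[2])
    b <- runif(m, rng[1], rng[2])
    ok <- a >= b
    while (!all(ok)) {
      k <- which(!ok)
      a[k] <- runif(length(k), rng[1], rng[2])
      b[k] <- runif(length(k), rng[1], rng[2])
      ok[k] <- a[k] >= b[k]
    }
    cbind(a, b)
  }
  th <- runif(total, spec$theta_range[1], spec$theta_range[2])
  ph <- runif(total, spec$phi_range[1], spec$phi_range[2])
  fast <- draw_pair(spec$fast_range, total)
  slow <- draw_pair(spec$slow_range, total)
  if (isTRUE(spec$shared_lambda) && n_fibers > 1) {
    # one eigenvalue draw per voxel, replicated across its fibers
    rep_rows <- rep(seq(1, total, by = n_fibers), each = n_fibers)
    fast <- fast[rep_rows, , drop = FALSE]
    slow <- slow[rep_rows, , drop = FALSE]
  }
  fa_floor <- if (n_fibers >= 2) spec$min_fa
  else if (!is.null(spec$min_fa_n1)) spec$min_fa_n1 else 0
  keep_fiber <- if (fa_floor > 0)
    fa_fast(fast[, 1], fast[, 2]) > fa_floor else rep(TRUE, total)
  idx <- matrix(seq_len(total), nrow = n_fibers)
  res <- list()
  for (j in seq_len(chunk)) {
    ii <- idx[, j]
    if (!all(keep_fiber[ii])) next
    if (n_fibers >= 2) {
      dirs <- sph_to_cart(th[ii], ph[ii])
      dirs <- matrix(dirs, ncol = 3)
      angs <- utils::combn(n_fibers, 2, function(p)
        crossing_angle(dirs[p[1], ], dirs[p[2], ]))
      if (any(angs < min_angle)) next
    }
    fl <- lapply(seq_len(n_fibers), function(k)
      fiber_params(th[ii[k]], ph[ii[k]], fast[ii[k], 1], fast[ii[k], 2],
                   slow[ii[k], 1], slow[ii[k], 2], spec$w))
    res[[length(res) + 1L]] <- voxel_params(fl)
  }
  res
}

#' Flatten voxel parameters to the vector alpha
#' @param vp a [voxel_params()].
#' @return numeric vector of length 6n, fiber blocks
#'   (theta, phi, lam1, lam2, lam3, lam4).
#' @export
params_to_alpha <- function(vp) {
  unlist(lapply(vp$fibers, function(f)
    c(f$theta, f$phi, f$lam1, f$lam2, f$lam3, f$lam4)),
    use.names = FALSE)
}

#' Rebuild voxel parameters from an alpha vector
#' @param alpha numeric vector of length 6n.
#' @param w fast fraction applied to every fiber.
#' @param validate if FALSE, out-of-range values are accepted (useful
#'   for evaluating estimates that violate constraints).
#' @return a [voxel_params()] object (or plain list when
#'   `validate = FALSE`).
#' @export
alpha_to_params <- function(alpha, w = 0.7, validate = TRUE) {
  if (length(alpha) %% 6 != 0) stop("alpha length must be 6n")
  n <- length(alpha) / 6
  fibers <- lapply(seq_len(n), function(i) {
    x <- alpha[(6 * (i - 1) + 1):(6 * i)]
    if (validate) {
      fiber_params(x[1], x[2], x[3], x[4], x[5], x[6], w)
    } else {
      structure(list(theta = x[1], phi = x[2], lam1 = x[3], lam2 = x[4],
                     lam3 = x[5], lam4 = x[6], w = w),
                class = "fiber_params")
    }
  })
  structure(list(fibers = fibers, n = n), class = "voxel_params")
}

#' Count fiber orderings producing the identical signal
#'
#' The forward model averages over fibers, so any permutation of the
#' fiber blocks of alpha yields the same signal; an n-fiber posterior
#' therefore has at least n! exchange-symmetric modes. The count is
#' verified directly by simulating every permutation and comparing
#' signals.
#'
#' @param n fiber count, 1 to 3.
#' @param scheme scheme used for verification (default [hcp_scheme()]).
#' @param seed seed for the generic test voxel.
#' @return integer: the number of equivalent orderings (n!).
#' @export
count_equivalent_permutations <- function(n, scheme = hcp_scheme(),
                                          seed = 7L) {
  if (!n %in% 1:3) stop("n must be 1, 2 or 3")
  vp <- sample_prior(prior_spec(), n, 1, seed = seed)[[1]]
  ref <- simulate_signal(vp, scheme)$values
  perms <- .permutations(n)
  hits <- vapply(perms, function(p) {
    s <- simulate_signal(voxel_params(vp$fibers[p]), scheme)$values
    identical(s, ref)
  }, logical(1))
  sum(hits)
}

# all permutations of 1..n for small n
.permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .permutations(n - 1L)
  out <- list()
  for (p in sub)
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}
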