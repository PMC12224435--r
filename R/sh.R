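# Real symmetric spherical-harmonic basis (even degrees only) and the
# analytic q-ball ODF via the Funk-Radon transform.

#' Number of even-degree real SH basis functions up to order L
#'
#' @param L maximum harmonic degree; must be even and >= 0.
#' @return (L+1)(L+2)/2, the count of (l, m) pairs with l even, l <= L.
#' @export
sh_basis_size <- function(L) {
  if (length(L) != 1 || L < 0 || L %% 2 != 0)
    stop("L must be a non-negative even integer")
  as.integer((L + 1) * (L + 2) / 2)
}

# degrees/orders of each basis column, m = -l..l within each even l
.sh_index <- function(L) {
  l <- unlist(lapply(seq(0, L, by = 2), function(li) rep(li, 2 * li + 1)))
  m <- unlist(lapply(seq(0, L, by = 2), function(li) seq(-li, li)))
  list(l = l, m = m)
}

#' Evaluate the real symmetric SH basis
#'
#' Real basis built from associated Legendre functions: for order m = 0
#' the zonal harmonic, for m > 0 the sqrt(2)-scaled cosine harmonic and
#' for m < 0 the sine harmonic. Only even degrees are included, so the
#' basis spans exactly the antipodally symmetric functions.
#'
#' @param L maximum even degree.
#' @param theta,phi spherical coordinates of evaluation points, rad.
#' @return matrix, length(theta) x sh_basis_size(L).
#' @export
sh_basis <- function(L, theta, phi) {
  stopifnot(length(theta) == length(phi))
  npt <- length(theta)
  R <- sh_basis_size(L)
  B <- matrix(0, npt, R)
  ct <- cos(theta)
  col <- 1L
  for (l in seq(0, L, by = 2)) {
    P <- pracma::legendre(l, ct)          # (l+1) x npt, m = 0..l rows
    if (l == 0) P <- matrix(P, nrow = 1)
    for (m in seq(-l, l)) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      pv <- P[am + 1, ]
      B[, col] <- if (m == 0) nrm * pv
      else if (m > 0) sqrt(2) * nrm * pv * cos(m * phi)
      else sqrt(2) * nrm * pv * sin(am * phi)
      col <- col + 1L
    }
  }
  B
}

#' Least-squares SH fit of a single-shell signal
#'
#' Fits even-degree real SH coefficients to per-direction samples with
#' Laplace-Beltrami regularization (penalty (l(l+1))^2 per
#' coefficient). With `lambda = 0` and enough well-spread directions
#' the fit interpolates band-limited inputs exactly.
#'
#' @param values signal samples on the shell.
#' @param directions unit vectors, one row per sample.
#' @param L maximum even degree; requires
#'   `length(values) >= sh_basis_size(L)`.
#' @param lambda Laplace-Beltrami regularization weight (default 6e-3).
#' @return object of class `sh_coeffs`: list(coeffs, L).
#' @export
fit_sh <- function(values, directions, L = 8, lambda = 6e-3) {
  R <- sh_basis_size(L)
  if (length(values) < R)
    stop("under-determined SH fit: ", length(values),
         " samples for ", R, " coefficients")
  th <- acos(pmin(1, pmax(-1, directions[, 3])))
  ph <- atan2(directions[, 2], directions[, 1])
  B <- sh_basis(L, th, ph)
  idx <- .sh_index(L)
  reg <- (idx$l * (idx$l + 1))^2
  coeffs <- solve(crossprod(B) + lambda * diag(reg, R),
                  crossprod(B, values))
  structure(list(coeffs = drop(coeffs), L = L), class = "sh_coeffs")
}

#' Funk-Radon eigenvalue of degree l
#'
#' The Funk-Radon transform is diagonal in the SH basis with eigenvalue
#' 2 pi P_l(0) on degree l, where P_l(0) = (-1)^(l/2) (l-1)!!/l!! for
#' even l.
#'
#' @param l even degree (vectorized).
#' @return numeric eigenvalues.
#' @export
frt_eigenvalue <- function(l) {
  vapply(l, function(li) {
    if (li %% 2 != 0) stop("degree must be even")
    if (li == 0) return(2 * pi)
    k <- seq(2, li, by = 2)
    2 * pi * (-1)^(li / 2) * prod((k - 1) / k)
  }, numeric(1))
}

#' Analytic q-ball ODF from signal SH coefficients
#'
#' Applies the Funk-Radon transform in the SH domain: each coefficient
#' of degree l is scaled by 2 pi P_l(0). The resulting expansion
#' evaluates the (unnormalized) diffusion ODF anywhere on the sphere
#' and is antipodally symmetric by construction.
#'
#' @param c an `sh_coeffs` object (signal domain).
#' @return an `sh_coeffs` object in the ODF domain.
#' @export
compute_odf <- function(c) {
  stopifnot(inherits(c, "sh_coeffs"))
  idx <- .sh_index(c$L)
  c$coeffs <- c$coeffs * frt_eigenvalue(idx$l)
  c$domain <- "odf"
  c
}

#' Evaluate an SH expansion at points on the sphere
#'
#' @param c an `sh_coeffs` object.
#' @param theta,phi evaluation angles, rad.
#' @return numeric vector of values.
#' @export
sh_eval <- function(c, theta, phi) {
  drop(sh_basis(c$L, theta, phi) %*% c$coeffs)
}
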