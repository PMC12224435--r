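#' Diffusion acquisition scheme
#'
#' An acquisition scheme is the measurement operator of the diffusion
#' experiment: one unit gradient direction and one b-value per measured
#' volume. Directions sharing (up to a tolerance) the same non-zero
#' b-value form a shell.
#'
#' @param directions numeric matrix, one row per measurement, 3 columns;
#'   each non-b0 row must have unit Euclidean norm (tolerance 1e-9).
#' @param bvalues numeric vector of b-values in s/mm^2, one per row of
#'   `directions`; zeros mark b=0 measurements.
#' @param b0_threshold b-values at or below this are treated as b=0.
#'
#' @return An object of class `dmri_scheme` with elements `directions`,
#'   `bvalues`, `shell_ids` (0 for b=0), `shells` (sorted unique
#'   non-zero nominal b-values) and `b0` (logical mask).
#' @export
acquisition_scheme <- function(directions, bvalues, b0_threshold = 50) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L)
    stop("directions must have 3 columns")
  bvalues <- as.numeric(bvalues)
  if (nrow(directions) != length(bvalues))
    stop("directions and bvalues length mismatch")
  if (any(bvalues < 0)) stop("bvalues must be non-negative")
  b0 <- bvalues <= b0_threshold
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm[!b0] - 1) > 1e-9))
    stop("non-b0 directions must be unit vectors")
  # group non-b0 b-values into shells, merging within 100 s/mm^2
  # (real multi-shell tables jitter around the nominal values)
  ub <- sort(unique(bvalues[!b0]))
  shells <- numeric(0)
  if (length(ub)) {
    grp <- cumsum(c(1, diff(ub) > 100))
    shells <- as.numeric(tapply(ub, grp, mean))
  }
  shell_ids <- integer(length(bvalues))
  if (length(shells)) {
    nearest <- vapply(bvalues, function(b)
      which.min(abs(shells - b)), integer(1))
    shell_ids[!b0] <- nearest[!b0]
  }
  structure(list(directions = directions, bvalues = bvalues,
                 shell_ids = shell_ids, shells = shells, b0 = b0),
            class = "dmri_scheme")
}

#' @export
print.dmri_scheme <- function(x, ...) {
  cat("dmri acquisition scheme:", nrow(x$directions), "measurements,",
      sum(x$b0), "b=0,", length(x$shells), "shells (b =",
      paste(x$shells, collapse = ", "), "s/mm^2)\n")
  invisible(x)
}

#' Evenly spread hemisphere directions (golden-spiral construction)
#'
#' Deterministic quasi-uniform points on the upper hemisphere, folded so
#' they serve as gradient directions for antipodally symmetric signals.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors with non-negative z.
#' @export
hemisphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  # golden-spiral covering of the upper hemisphere
  z <- i / n                      # cos(theta) in (0, 1)
  phi <- pi * (1 + sqrt(5)) * i
  st <- sqrt(pmax(0, 1 - z^2))
  cbind(st * cos(phi), st * sin(phi), z)
}

#' HCP-style multi-shell acquisition scheme
#'
#' The synthetic protocol used throughout the package: `n_dirs` gradient
#' directions repeated on each shell (default b = 1000, 2000,
#' 3000 s/mm^2), emulating a Human Connectome Project style multi-shell
#' acquisition, plus an optional number of b=0 volumes.
#'
#' @param n_dirs directions per shell.
#' @param bvalues shell b-values, s/mm^2.
#' @param n_b0 number of leading b=0 volumes.
#' @return a [acquisition_scheme()] object.
#' @export
hcp_scheme <- function(n_dirs = 90, bvalues = c(1000, 2000, 3000),
                       n_b0 = 0) {
  dirs <- hemisphere_directions(n_dirs)
  directions <- do.call(rbind, c(
    if (n_b0 > 0) list(matrix(0, n_b0, 3)),
    rep(list(dirs), length(bvalues))))
  bv <- c(rep(0, n_b0), rep(bvalues, each = n_dirs))
  acquisition_scheme(directions, bv)
}

#' Read an FSL-style gradient table
#'
#' @param bval_path path to the whitespace-separated 1 x N b-value file.
#' @param bvec_path path to the 3 x N unit-direction file.
#' @return a [acquisition_scheme()] object.
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  if (nrow(bvecs) != 3L)
    stop("bvec file must have 3 rows")
  if (ncol(bvecs) != length(bvals))
    stop("bval/bvec column counts differ")
  dirs <- t(bvecs)
  nrm <- sqrt(rowSums(dirs^2))
  ok <- nrm > 0
  dirs[ok, ] <- dirs[ok, , drop = FALSE] / nrm[ok]
  acquisition_scheme(dirs, bvals)
}

#' Write an FSL-style gradient table
#'
#' @param scheme a [acquisition_scheme()] object.
#' @param bval_path,bvec_path output paths.
#' @return invisibly, the scheme.
#' @export
write_bvals_bvecs <- function(scheme, bval_path, bvec_path) {
  cat(paste(scheme$bvalues, collapse = " "), "\n", file = bval_path)
  write.table(format(t(scheme$directions), digits = 10),
              bvec_path, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(scheme)
}
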