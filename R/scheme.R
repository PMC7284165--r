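#' Generate a diffusion gradient scheme
#'
#' Builds a single-shell HARDI acquisition scheme: `n_b0` non-weighted
#' volumes followed by `n_dirs` unit gradient directions at b-value `b`.
#' Directions are spread quasi-uniformly over the sphere by iterative
#' electrostatic repulsion of antipodal point pairs (fixed iteration count,
#' so the scheme is deterministic for a given seed). The default matches
#' the acquisition emulated by the package: 60 directions at b = 1000
#' s/mm^2 with 6 b = 0 images.
#'
#' @param n_dirs Number of diffusion-weighted directions.
#' @param b b-value in s/mm^2 for the weighted volumes.
#' @param n_b0 Number of b = 0 volumes.
#' @param seed RNG seed for the initial point set.
#' @return Object of class `gradient_scheme`: `bvals` (length
#'   `n_b0 + n_dirs`), `bvecs` (`(n_b0 + n_dirs) x 3`, zero rows for b0),
#'   and the component counts.
#' @export
make_scheme <- function(n_dirs = 60, b = 1000, n_b0 = 6, seed = 0) {
  if (n_dirs < 6) abort("need at least 6 diffusion directions for a tensor fit")
  set.seed(seed_derive(seed, "scheme"))
  x <- matrix(rnorm(3 * n_dirs), n_dirs, 3)
  x <- x / sqrt(rowSums(x^2))
  ## electrostatic repulsion on axes: each point repels both x_j and -x_j
  n_iter <- 400L
  for (it in seq_len(n_iter)) {
    step <- 0.05 * (1 - it / (n_iter + 1))
    f <- matrix(0, n_dirs, 3)
    for (i in seq_len(n_dirs)) {
      d1 <- sweep(-x, 2, x[i, ], `+`)          # x_i - x_j
      d2 <- sweep(x, 2, x[i, ], `+`)           # x_i + x_j
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
      r1[i] <- Inf
      f[i, ] <- colSums(d1 / r1^3) + colSums(d2 / r2^3)
    }
    fn <- sqrt(rowSums(f^2))
    x <- x + step * f / pmax(max(fn), 1e-12)
    x <- x / sqrt(rowSums(x^2))
  }
  bvals <- c(rep(0, n_b0), rep(b, n_dirs))
  bvecs <- rbind(matrix(0, n_b0, 3), x)
  structure(
    list(bvals = bvals, bvecs = bvecs, n_dirs = n_dirs, n_b0 = n_b0, b = b),
    class = "gradient_scheme"
  )
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d directions at b = %g s/mm^2 + %d b0; min pairwise angle %.1f deg\n",
              x$n_dirs, x$b, x$n_b0, min_pairwise_angle(x)))
  invisible(x)
}

#' Minimum pairwise angle of a scheme's directions
#'
#' Smallest angular separation (degrees, axial: antipodes identified)
#' between any two diffusion directions; a uniformity diagnostic.
#'
#' @param scheme A `gradient_scheme`.
#' @return Angle in degrees.
#' @export
min_pairwise_angle <- function(scheme) {
  g <- scheme$bvecs[scheme$bvals > 0, , drop = FALSE]
  ct <- abs(tcrossprod(g))
  diag(ct) <- -Inf
  acos(pmin(pmax(max(ct), -1), 1)) * 180 / pi
}

## Tensor-fit design matrix: rows b * (gx^2, gy^2, gz^2, 2gxgy, 2gxgz, 2gygz)
## for the b > 0 volumes of a scheme.
design_matrix <- function(scheme) {
  sel <- scheme$bvals > 0
  g <- scheme$bvecs[sel, , drop = FALSE]
  b <- scheme$bvals[sel]
  b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
            2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

#' Write / read FSL-style gradient tables
#'
#' `write_bvals_bvecs()` writes the scheme as space-separated `bvals`
#' (1 x N) and `bvecs` (3 x N) text files in the FSL dialect;
#' `read_bvals_bvecs()` reads them back into a `gradient_scheme`.
#' Values are written with 17 significant digits so the round trip is
#' exact.
#'
#' @param scheme A `gradient_scheme`.
#' @param prefix Path prefix; files `<prefix>.bval` and `<prefix>.bvec`.
#' @return `write_bvals_bvecs()` the prefix, invisibly;
#'   `read_bvals_bvecs()` a `gradient_scheme`.
#' @export
write_bvals_bvecs <- function(scheme, prefix) {
  writeLines(paste(sprintf("%.17g", scheme$bvals), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(t(scheme$bvecs), 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname write_bvals_bvecs
#' @export
read_bvals_bvecs <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bv <- as.matrix(read.table(paste0(prefix, ".bvec")))
  if (nrow(bv) != 3) abort("bvec file must be 3 x N (FSL dialect)")
  bvecs <- t(bv)
  dimnames(bvecs) <- NULL
  sel <- bvals > 0
  structure(
    list(bvals = bvals, bvecs = bvecs, n_dirs = sum(sel), n_b0 = sum(!sel),
         b = if (any(sel)) max(bvals) else 0),
    class = "gradient_scheme"
  )
}
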