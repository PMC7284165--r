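## Real even-order spherical harmonic basis. The ADC profile of tissue is
## antipodally symmetric, so only even degrees appear; degree <= 2 spans
## exactly the quadratic forms g -> g' D g on the sphere, which makes the
## SH fit and the tensor fit mutually consistent oracles on noise-free
## tensor data.

## Basis matrix: one row per direction, columns (l, m) for l = 0, 2, ...,
## order and m = -l..l. Real convention: sqrt(2) * N * P_l^|m| * sin(|m|
## phi) for m < 0, N * P_l^0 for m = 0, sqrt(2) * N * P_l^m * cos(m phi)
## for m > 0, with N the orthonormalisation constant. (The fixed
## Condon-Shortley phase of pracma's Legendre routines is immaterial: fit
## and evaluation use the same basis.)
sh_basis <- function(dirs, order) {
  if (order %% 2 != 0 || order < 0 || order > 8) {
    abort("SH order must be even and between 0 and 8")
  }
  dirs <- matrix(dirs, ncol = 3)
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs / nrm
  ct <- pmin(pmax(dirs[, 3], -1), 1)      # cos(theta), polar from +z
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  cols <- list()
  labs <- character(0)
  for (l in seq(0, order, by = 2)) {
    P <- pracma::legendre(l, ct)          # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in -l:l) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - am) / factorial(l + am))
      base <- N * P[am + 1, ]
      y <- if (m < 0) {
        sqrt(2) * base * sin(am * phi)
      } else if (m == 0) {
        base
      } else {
        sqrt(2) * base * cos(m * phi)
      }
      cols[[length(cols) + 1]] <- y
      labs <- c(labs, sprintf("l%d m%+d", l, m))
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- labs
  out
}

n_sh_coef <- function(order) (order + 1) * (order + 2) / 2

#' Fit a spherical harmonic ADC profile
#'
#' Least-squares fit of a real even-order spherical harmonic basis (orders
#' 0, 2, ..., `order`; 15 coefficients at the default order 4) to
#' per-direction ADC samples, interpolating the apparent diffusion
#' coefficient profile continuously over the sphere. With order >= 2 and
#' noise-free tensor input the fitted profile equals the quadratic form
#' `g -> g' D g` exactly.
#'
#' @param adc ADC samples: a vector (one voxel) or voxels-by-directions
#'   matrix, in mm^2/s, one column per diffusion direction of `scheme`.
#' @param scheme The `gradient_scheme` that produced the samples.
#' @param order Even SH order, at most 8; the direction count must be at
#'   least the coefficient count (15 at order 4).
#' @return Object of class `adc_profile`: coefficient matrix (voxels x
#'   coefficients), the order, per-column degrees, and the condition number
#'   of the basis.
#' @export
fit_sh <- function(adc, scheme, order = 4) {
  if (order %% 2 != 0 || order < 0 || order > 8) {
    abort("SH order must be even and between 0 and 8")
  }
  if (is.null(dim(adc))) adc <- matrix(adc, nrow = 1)
  sel <- scheme$bvals > 0
  dirs <- scheme$bvecs[sel, , drop = FALSE]
  if (ncol(adc) != nrow(dirs)) {
    abort("ADC samples must have one column per diffusion direction")
  }
  k <- n_sh_coef(order)
  if (nrow(dirs) < k) {
    abort(sprintf("underdetermined SH system: %d directions < %d coefficients", nrow(dirs), k))
  }
  B <- sh_basis(dirs, order)
  BtB <- crossprod(B)
  coef <- adc %*% B %*% solve(BtB)
  colnames(coef) <- colnames(B)
  degrees <- as.integer(sub("^l(\\d+) .*", "\\1", colnames(B)))
  structure(
    list(coef = coef, order = order, degrees = degrees, cond = kappa(B, exact = TRUE)),
    class = "adc_profile"
  )
}

#' @export
print.adc_profile <- function(x, ...) {
  cat(sprintf("<adc_profile> order %d (%d coefficients) over %d voxel(s); basis condition %.2f\n",
              x$order, ncol(x$coef), nrow(x$coef), x$cond))
  invisible(x)
}

#' Evaluate an ADC profile along an axis
#'
#' Evaluates the spherical harmonic expansion at a direction. The pipeline
#' uses the dorso-ventral axis `(0, 1, 0)` and the left-right axis
#' `(1, 0, 0)` in image coordinates; by construction the profile is
#' antipodally symmetric, so `axis` and `-axis` agree.
#'
#' @param profile An `adc_profile`.
#' @param axis Length-3 direction vector (normalised internally).
#' @return Numeric vector of ADC values (mm^2/s), one per voxel.
#' @export
evaluate_axis <- function(profile, axis) {
  B <- sh_basis(matrix(axis, 1, 3), profile$order)
  as.vector(profile$coef %*% t(B))
}

#' Axis diffusivity maps from a DWI stack
#'
#' Composes the per-voxel pipeline: ADC samples from signal attenuation
#' (b0-mean reference), spherical harmonic profile fit, and evaluation
#' along the dorso-ventral and left-right axes, yielding `dvD`, `lrD` and
#' the `dvlr_ratio = dvD / lrD` maps. The ratio is masked where
#' `lrD < 1e-6` mm^2/s; the validity mask propagates to all outputs.
#'
#' @param stack A `dwi_stack`.
#' @param mask Logical voxel mask (default: Otsu on the mean b0, as in
#'   [fit_tensor()]); `TRUE` fits everywhere.
#' @param order Even SH order (default 4, the standard HARDI choice for 60
#'   directions).
#' @return Object of class `axis_diffusivities`: matrices `dv`, `lr`,
#'   `ratio` on the grid plus the mask. An all-masked input yields all-NA
#'   maps without error.
#' @export
axis_maps <- function(stack, mask = NULL, order = 4) {
  b0sel <- stack$scheme$bvals == 0
  S0v <- rowMeans(stack$signals[, b0sel, drop = FALSE])
  if (is.null(mask)) {
    mask <- S0v > otsu_threshold(S0v)
  } else if (isTRUE(mask)) {
    mask <- rep(TRUE, nrow(stack$signals))
  } else {
    mask <- as.vector(mask)
  }
  mask <- mask & S0v > 0
  nvox <- nrow(stack$signals)
  dv <- lr <- ratio <- rep(NA_real_, nvox)
  if (any(mask)) {
    S <- stack$signals[mask, !b0sel, drop = FALSE]
    adc <- -log(pmin(pmax(S / S0v[mask], 1e-6), 1)) / stack$scheme$b
    prof <- fit_sh(adc, stack$scheme, order)
    dv[mask] <- evaluate_axis(prof, c(0, 1, 0))
    lr[mask] <- evaluate_axis(prof, c(1, 0, 0))
    ratio <- ifelse(lr >= 1e-6, dv / lr, NA_real_)
  }
  gs <- stack$grid_shape
  shape <- function(v) if (is.null(gs)) v else matrix(v, gs[1], gs[2])
  structure(
    list(dv = shape(dv), lr = shape(lr), ratio = shape(ratio),
         mask = shape(as.numeric(mask)) > 0, grid_shape = gs,
         voxel_size = stack$voxel_size, order = order),
    class = "axis_diffusivities"
  )
}

#' @export
print.axis_diffusivities <- function(x, ...) {
  cat(sprintf("<axis_diffusivities> dvD/lrD/ratio (SH order %d) over %d voxels (%d valid)\n",
              x$order, length(x$dv), sum(x$mask)))
  invisible(x)
}
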