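#' Pointwise apparent diffusion coefficient from signal attenuation
#'
#' `ADC = -ln(S / S0) / b`, with the signal ratio clamped to
#' `(1e-6, 1]` before the logarithm as a noise-floor guard: ratios above 1
#' (noise pushing the weighted signal above the reference) give ADC = 0 and
#' are flagged rather than erroring.
#'
#' @param S Diffusion-weighted signal(s), any numeric shape.
#' @param S0 Non-weighted reference signal(s), must be > 0.
#' @param b b-value in s/mm^2, must be > 0.
#' @return Numeric ADC in mm^2/s, same shape as `S`, with a logical
#'   attribute `"clamped"` marking entries clipped at either bound.
#' @export
adc_from_signal <- function(S, S0, b) {
  if (any(S0 <= 0)) abort("S0 must be > 0")
  if (b <= 0) abort("b must be > 0")
  ratio <- S / S0
  clamped <- ratio > 1 | ratio <= 1e-6
  ratio <- pmin(pmax(ratio, 1e-6), 1)
  adc <- -log(ratio) / b
  attr(adc, "clamped") <- clamped
  adc
}

## Otsu's threshold on a numeric vector (256-bin histogram): maximises
## between-class variance. Used to split tissue from background on mean b0.
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  h <- graphics::hist(x, breaks = 256, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Fit diffusion tensors voxel-wise
#'
#' Weighted least squares on log-signals: per voxel solve `B d = y` with
#' `y_i = ln(S0 / S_i)`, design rows `b_i (gx^2, gy^2, gz^2, 2gxgy, 2gxgz,
#' 2gygz)` and weights `S_i^2` (the standard one-pass WLS for
#' log-transformed magnitude data; on noise-free input it reduces to the
#' exact inversion). The b = 0 volumes are averaged into the per-voxel
#' reference `S0`. Tensors with negative eigenvalues are clamped to
#' positive semidefinite, with the number of clamped voxels recorded.
#'
#' @param stack A `dwi_stack`.
#' @param mask Logical vector/matrix of voxels to fit. Default: Otsu
#'   threshold on the mean b0 image (tissue vs background). Use
#'   `mask = TRUE` to fit everywhere.
#' @return A `tensor_field` with per-voxel 6-entry tensors (NA outside the
#'   mask), the mask, and attribute `n_clamped`.
#' @export
fit_tensor <- function(stack, mask = NULL) {
  scheme <- stack$scheme
  B <- design_matrix(scheme)
  if (qr(B)$rank < 6) {
    abort("gradient scheme is rank-deficient: need >= 6 non-collinear directions")
  }
  b0sel <- scheme$bvals == 0
  if (!any(b0sel)) abort("scheme has no b = 0 volume")
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
  D <- matrix(NA_real_, nvox, 6)
  colnames(D) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  n_clamped <- 0L
  if (any(mask)) {
    S <- stack$signals[mask, !b0sel, drop = FALSE]
    ratio <- pmin(pmax(S / S0v[mask], 1e-6), 1)
    y <- -log(ratio)
    w <- S^2
    fit <- cpp_wls_fit(y, w, B)
    cl <- cpp_clamp_psd(fit)
    D[mask, ] <- cl$D
    n_clamped <- cl$n_clamped
  }
  structure(
    list(D = D, grid_shape = stack$grid_shape, voxel_size = stack$voxel_size,
         mask = mask, n_clamped = n_clamped),
    class = "tensor_field"
  )
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %d voxels (%d in mask), %d eigenvalue-clamped\n",
              nrow(x$D), sum(x$mask), x$n_clamped %||% 0L))
  invisible(x)
}

#' Scalar maps from a tensor field
#'
#' Eigendecomposes every tensor (eigenvalues `l1 >= l2 >= l3`) and derives
#' mean diffusivity `MD = (l1 + l2 + l3) / 3`, fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((l - MD)^2)) / sqrt(sum(l^2))`, and the
#' primary in-plane diffusion orientation `theta = atan2(e1y, e1x) mod 180`
#' degrees from the left-right axis. `theta` is NA where the leading
#' eigenvalue is degenerate (within `1e-12`) or the principal eigenvector
#' has no in-plane component.
#'
#' @param tensors A `tensor_field`.
#' @return Object of class `scalar_maps`: matrices `fa`, `md`, `theta` on
#'   the grid, eigenvalues, and the validity mask.
#' @export
tensor_metrics <- function(tensors) {
  nvox <- nrow(tensors$D)
  md <- fa <- theta <- rep(NA_real_, nvox)
  l <- matrix(NA_real_, nvox, 3)
  ok <- tensors$mask & stats::complete.cases(tensors$D)
  if (any(ok)) {
    m <- cpp_tensor_metrics(tensors$D[ok, , drop = FALSE], 1e-12)
    md[ok] <- m[, 1]; fa[ok] <- m[, 2]; theta[ok] <- m[, 3]
    l[ok, ] <- m[, 4:6]
  }
  gs <- tensors$grid_shape
  shape <- function(v) if (is.null(gs)) v else matrix(v, gs[1], gs[2])
  structure(
    list(fa = shape(fa), md = shape(md), theta = shape(theta),
         eigenvalues = l, mask = shape(as.numeric(ok)) > 0,
         grid_shape = gs, voxel_size = tensors$voxel_size),
    class = "scalar_maps"
  )
}

#' @export
print.scalar_maps <- function(x, ...) {
  cat(sprintf("<scalar_maps> FA/MD/theta over %d voxels (%d valid)\n",
              length(x$fa), sum(x$mask)))
  invisible(x)
}

#' @export
as_tibble.scalar_maps <- function(x, ...) {
  tibble(
    voxel = seq_along(x$fa),
    fa = as.vector(x$fa),
    md = as.vector(x$md),
    theta = as.vector(x$theta),
    valid = as.vector(x$mask)
  )
}
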