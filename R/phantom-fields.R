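## von Mises sampler (Best & Fisher rejection scheme); kappa = 0 falls back
## to the uniform circle. Used on doubled angles for axial orientations.
rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-12) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      th <- mu + sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      out[(got + 1):(got + k)] <- th
      got <- got + k
    }
  }
  out %% (2 * pi)
}

#' Generate the per-voxel axial orientation field
#'
#' Draws one axial orientation per tissue voxel from the region's axial von
#' Mises distribution, via the standard angle-doubling construction for
#' apolar (180-degree periodic) structures: `phi ~ vonMises(2 mu, kappa)`,
#' orientation `= (phi / 2) mod 180`. `kappa = 0` yields uniform axial
#' orientations (used for regions that lose orientation coherence, e.g.
#' ipsilateral CA1 after pyramidal cell loss). Background voxels are `NA`.
#'
#' @param roiset `roi_set` from [generate_geometry()].
#' @param spec The matching [phantom_spec()].
#' @param seed RNG seed; defaults to a stream derived from `spec$seed`.
#' @return Matrix of orientations in degrees `[0, 180)`, `NA` outside tissue.
#' @export
generate_orientation_field <- function(roiset, spec, seed = NULL) {
  if (!identical(dim(roiset$labels), as.integer(spec$grid_shape))) {
    abort("roiset and spec disagree on grid shape")
  }
  eff <- effective_params(spec)
  set.seed(seed %||% seed_derive(spec$seed, "orientation"))
  theta <- matrix(NA_real_, nrow(roiset$labels), ncol(roiset$labels))
  for (i in seq_len(nrow(eff))) {
    sel <- roiset$labels == roiset$roi_names[[eff$roi[i]]]
    n <- sum(sel)
    phi <- rvonmises(n, 2 * eff$mu[i] * pi / 180, eff$kappa[i])
    theta[sel] <- (phi * 180 / pi / 2) %% 180
  }
  theta
}

#' Generate the cell-density proxy map
#'
#' Per-voxel cell-density proxy (arbitrary units, emulating background-
#' subtracted DAPI intensity): region baseline scaled by the condition's
#' density-loss effect and severity, with slice-level jitter and voxel
#' noise. Background density is 0. The same effective densities drive the
#' diffusivity coupling in [build_tensor_field()], so that density loss is
#' mirrored by increased diffusivity / reduced anisotropy.
#'
#' @inheritParams generate_orientation_field
#' @return Object of class `density_map`: list with the voxel `map`, tidy
#'   per-region means (`roi_means`), and the measured GCL width in mm.
#' @export
generate_density <- function(roiset, spec, seed = NULL) {
  eff <- effective_params(spec)
  set.seed(seed %||% seed_derive(spec$seed, "density"))
  dm <- matrix(0, nrow(roiset$labels), ncol(roiset$labels))
  for (i in seq_len(nrow(eff))) {
    sel <- roiset$labels == roiset$roi_names[[eff$roi[i]]]
    dm[sel] <- pmax(eff$density[i] + rnorm(sum(sel), 0, spec$voxel_density_sd), 0)
  }
  roi_means <- tibble(
    roi = eff$roi,
    density = vapply(eff$roi, function(rn) mean(dm[roi_mask(roiset, rn)]), numeric(1))
  )
  structure(
    list(map = dm, roi_means = roi_means, gcl_width = measure_gcl_width(roiset)),
    class = "density_map"
  )
}

#' Build the per-voxel diffusion tensor field
#'
#' Constructs, for every voxel, the symmetric positive definite tensor
#' `D = lambda_perp I + (lambda_par - lambda_perp) u u^T` with the principal
#' axis `u = (cos theta, sin theta, 0)` in-plane at the voxel's orientation.
#' Background voxels receive an isotropic saline-like tensor (trace/3 =
#' 2.0e-3 mm^2/s by default). If a density map is supplied and the spec's
#' coupling slope is non-zero, the perpendicular diffusivity follows the
#' local density, `lambda_perp(voxel) = a_MD - b_MD * density(voxel)`
#' (times the slice's diffusivity jitter), so that cell loss raises
#' diffusivity and lowers anisotropy; otherwise regions use their nominal
#' `lambda_perp`.
#'
#' @inheritParams generate_orientation_field
#' @param orientations Orientation matrix from [generate_orientation_field()].
#' @param density Optional `density_map` (or matrix) enabling the coupling.
#' @return Object of class `tensor_field`: voxels-by-6 matrix of unique
#'   tensor entries (`Dxx, Dyy, Dzz, Dxy, Dxz, Dyz`; column-major voxel
#'   order) plus grid metadata.
#' @export
build_tensor_field <- function(roiset, orientations, spec, density = NULL) {
  if (!all(dim(orientations) == dim(roiset$labels))) {
    abort("orientation field and label map must share the grid")
  }
  eff <- effective_params(spec)
  nvox <- length(roiset$labels)
  lam_par <- rep(spec$background_diffusivity, nvox)
  lam_perp <- rep(spec$background_diffusivity, nvox)
  dmap <- if (inherits(density, "density_map")) density$map else density
  b <- spec$coupling$b_MD %||% 0
  a <- spec$coupling$a_MD %||% 0
  for (i in seq_len(nrow(eff))) {
    sel <- which(roiset$labels == roiset$roi_names[[eff$roi[i]]])
    lam_par[sel] <- eff$lambda_par[i]
    lam_perp[sel] <- if (!is.null(dmap) && b != 0) {
      (a - b * dmap[sel]) * eff$jit_perp[i]
    } else {
      eff$lambda_perp[i]
    }
  }
  if (any(!is.finite(lam_perp)) || any(lam_perp <= 0) || any(lam_perp > lam_par + 1e-15)) {
    abort("density coupling produced non-physical diffusivities (lambda_perp outside (0, lambda_par])")
  }
  th <- orientations * pi / 180
  ux <- cos(th); uy <- sin(th)
  ux[is.na(ux)] <- 0; uy[is.na(uy)] <- 0 # background: isotropic, axis irrelevant
  dl <- lam_par - lam_perp
  D <- cbind(
    xx = lam_perp + dl * as.vector(ux)^2,
    yy = lam_perp + dl * as.vector(uy)^2,
    zz = lam_perp,
    xy = dl * as.vector(ux) * as.vector(uy),
    xz = 0,
    yz = 0
  )
  structure(
    list(D = D, grid_shape = spec$grid_shape, voxel_size = spec$voxel_size,
         mask = rep(TRUE, nvox)),
    class = "tensor_field"
  )
}

#' Build a complete phantom slice
#'
#' Runs the full generative chain for one [phantom_spec()]: geometry,
#' orientation field, density map and tensor field, plus the relative b0
#' signal map (tissue 1, background `background_s0_factor`). The effective
#' per-region parameters actually used for this slice (after condition
#' effects, severity scaling and slice jitter) are attached for reference.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `hippo_phantom` with elements `spec`, `roi`,
#'   `orientations`, `density`, `tensors`, `s0_map`, `effective`.
#' @export
build_phantom <- function(spec) {
  roi <- generate_geometry(spec)
  orient <- generate_orientation_field(roi, spec)
  dens <- generate_density(roi, spec)
  tens <- build_tensor_field(roi, orient, spec, density = dens)
  s0 <- matrix(1, nrow(roi$labels), ncol(roi$labels))
  s0[roi$labels == 0L] <- spec$background_s0_factor
  structure(
    list(spec = spec, roi = roi, orientations = orient, density = dens,
         tensors = tens, s0_map = s0, effective = effective_params(spec)),
    class = "hippo_phantom"
  )
}

#' @export
print.hippo_phantom <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  GCL width %.3f mm; mean tissue density %.2f\n",
              x$density$gcl_width, mean(x$density$map[x$roi$labels > 0])))
  invisible(x)
}
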