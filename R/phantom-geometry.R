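## Stylized parametric hippocampus: concentric curved bands (CA1 continuing
## into CA3, stratum radiatum interior to CA1) around a V-shaped granule
## cell layer with the hilar wedge between its blades. The real regions are
## segmented manually on histology; any geometry preserving region adjacency
## and orientation structure supports the downstream statistics, so the
## layout is an arc-and-wedge stand-in, not an atlas.

dist_to_segment <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  t <- pmin(pmax(((px - a[1]) * abx + (py - a[2]) * aby) / len2, 0), 1)
  sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2)
}

in_triangle <- function(px, py, A, B, C) {
  s1 <- (B[1] - A[1]) * (py - A[2]) - (B[2] - A[2]) * (px - A[1])
  s2 <- (C[1] - B[1]) * (py - B[2]) - (C[2] - B[2]) * (px - B[1])
  s3 <- (A[1] - C[1]) * (py - C[2]) - (A[2] - C[2]) * (px - C[1])
  (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
}

#' Generate the region label map of a phantom slice
#'
#' Deterministically renders the stylized hippocampal geometry of a
#' [phantom_spec()]: an outer C-shaped CA1 pyramidal band continuing into a
#' CA3 band, the CA1 stratum radiatum interior to CA1, a V-shaped dentate
#' gyrus granule cell layer (GCL) and the hilar wedge enclosed by its
#' blades. Band widths scale with grid size; the GCL band width is
#' multiplied by the spec's `gcl_dispersion` factor (granule cell
#' dispersion widens it in epileptic slices).
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `roi_set`: integer label matrix (`0` =
#'   background plus the five named regions), with the region name table,
#'   voxel size and the analytic GCL centerline length (voxels) attached.
#' @export
generate_geometry <- function(spec) {
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  rmin <- min(nr, nc)
  cx <- 0.52 * nc; cy <- 0.48 * nr
  r_out <- 0.42 * rmin
  w <- max(3, round(0.045 * rmin))

  xy <- expand.grid(y = seq_len(nr) - 1, x = seq_len(nc) - 1) # 0-based centers
  x <- xy$x; y <- xy$y
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  phi <- atan2(y - cy, x - cx) * 180 / pi

  ca1 <- r <= r_out & r > r_out - w & phi >= -90 & phi <= 45
  ca3 <- r <= r_out & r > r_out - w & phi > 45 & phi <= 170
  sr  <- r <= r_out - w & r > r_out - 2 * w & phi >= -90 & phi <= 45

  deg <- pi / 180
  p0 <- c(cx, cy) + 0.06 * rmin * c(cos(120 * deg), sin(120 * deg))
  p1 <- c(cx, cy) + 0.26 * rmin * c(cos(70 * deg), sin(70 * deg))
  p2 <- c(cx, cy) + 0.26 * rmin * c(cos(178 * deg), sin(178 * deg))
  w_gcl <- max(3, 0.03 * rmin) * spec$gcl_dispersion
  d_gcl <- pmin(dist_to_segment(x, y, p0, p1), dist_to_segment(x, y, p0, p2))
  dg <- d_gcl <= w_gcl / 2
  hil <- in_triangle(x, y, p0, p1, p2) & !dg

  labels <- integer(nr * nc)
  assign_roi <- function(labels, sel, lab) {
    labels[sel & labels == 0L] <- lab
    labels
  }
  labels <- assign_roi(labels, dg, ROI_LABELS[["DG"]])
  labels <- assign_roi(labels, hil, ROI_LABELS[["hilus"]])
  labels <- assign_roi(labels, sr, ROI_LABELS[["srCA1"]])
  labels <- assign_roi(labels, ca1, ROI_LABELS[["CA1"]])
  labels <- assign_roi(labels, ca3, ROI_LABELS[["CA3"]])
  labels <- matrix(labels, nr, nc)

  counts <- vapply(ROI_LABELS, function(l) sum(labels == l), integer(1))
  if (any(counts == 0L)) {
    abort(sprintf(
      "grid %d x %d too small: region(s) %s empty; enlarge the grid (>= 64 x 64 recommended)",
      nr, nc, paste(names(counts)[counts == 0], collapse = ", ")
    ))
  }

  structure(
    list(
      labels = labels,
      roi_names = ROI_LABELS,
      voxel_size = spec$voxel_size,
      grid_shape = spec$grid_shape,
      gcl_centerline_vox = sqrt(sum((p1 - p0)^2)) + sqrt(sum((p2 - p0)^2)),
      gcl_nominal_width_vox = w_gcl
    ),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  counts <- vapply(x$roi_names, function(l) sum(x$labels == l), integer(1))
  cat(sprintf("<roi_set> %d x %d voxels @ %.3g mm\n", nrow(x$labels), ncol(x$labels), x$voxel_size))
  print(counts)
  invisible(x)
}

## Logical mask of one region on the grid.
roi_mask <- function(roiset, roi) {
  roiset$labels == roiset$roi_names[[roi]]
}

#' Measure the granule cell layer width
#'
#' Mean width of the dentate gyrus GCL band, a morphological marker of
#' epileptogenicity (granule cell dispersion widens the layer). Computed as
#' band area divided by centerline length,
#' `width = (area * voxel^2) / (centerline * voxel)`.
#' When the label map was produced by [generate_geometry()], the analytic
#' centerline length of the V-shaped band is used; for external label maps
#' the centerline length is approximated by the band's extent along its
#' principal axis (exact for straight bands).
#'
#' @param roiset An `roi_set`.
#' @return Width in mm.
#' @export
measure_gcl_width <- function(roiset) {
  dg <- roi_mask(roiset, "DG")
  area_vox <- sum(dg)
  if (area_vox == 0) abort("no DG voxels in label map")
  len <- roiset$gcl_centerline_vox
  if (is.null(len)) {
    idx <- which(dg, arr.ind = TRUE)
    ctr <- scale(idx, scale = FALSE)
    pc1 <- svd(ctr, nu = 0, nv = 1)$v[, 1]
    proj <- ctr %*% pc1
    len <- diff(range(proj)) + 1
  }
  (area_vox * roiset$voxel_size^2) / (len * roiset$voxel_size)
}
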