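#' Default per-region tissue parameters
#'
#' Baseline (control-condition) microstructural parameters for the five
#' hippocampal regions of the digital phantom. Orientations follow the
#' layered dendritic/axonal architecture of the subfields: dorso-ventral
#' (90 degrees) pyramidal and granule cell dendrites in CA1 and the dentate
#' gyrus, oblique (45 degrees) CA3 dendrites, and left-right (0 degrees)
#' mossy fibers in the hilus and Schaffer collaterals in the CA1 stratum
#' radiatum. Diffusivities are on the fixed-tissue scale (mean diffusivity
#' of the order of 0.5e-3 mm^2/s).
#'
#' @details Each element holds:
#' * `mu`: mean axial orientation, degrees in `[0, 180)` from the
#'   left-right (+x) image axis;
#' * `kappa`: von Mises concentration applied on doubled angles
#'   (0 = uniform axial orientations);
#' * `lambda_par`, `lambda_perp`: parallel/perpendicular diffusivities,
#'   mm^2/s;
#' * `baseline_density`: cell-density proxy in `[0, 1]` (arbitrary units).
#'
#' The within-region concentrations are calibration choices, not measured
#' values; the vignette discusses how they were fixed.
#'
#' @return Named list of per-region parameter lists.
#' @export
default_tissue_params <- function() {
  list(
    CA1   = list(mu = 90, kappa = 20, lambda_par = 0.9e-3, lambda_perp = 0.300e-3, baseline_density = 0.80),
    CA3   = list(mu = 45, kappa = 20, lambda_par = 0.9e-3, lambda_perp = 0.325e-3, baseline_density = 0.75),
    DG    = list(mu = 90, kappa = 30, lambda_par = 1.0e-3, lambda_perp = 0.225e-3, baseline_density = 0.95),
    hilus = list(mu = 0,  kappa = 10, lambda_par = 0.8e-3, lambda_perp = 0.425e-3, baseline_density = 0.55),
    srCA1 = list(mu = 0,  kappa = 15, lambda_par = 0.9e-3, lambda_perp = 0.400e-3, baseline_density = 0.60)
  )
}

#' Default condition effects
#'
#' Per-region pathology effects applied to epileptic phantoms, scaled by the
#' slice's severity scalar. They encode hippocampal sclerosis as seen in the
#' intrahippocampal kainate model: loss of CA1/CA3 pyramidal cells (density
#' loss, loss of orientation coherence), granule cell layer changes in the
#' dentate gyrus (density loss with increased diffusivities), and mossy
#' fiber sprouting in the hilus (increased parallel diffusivity, hence
#' anisotropy). Contralateral slices show only partial CA1 involvement.
#'
#' @details Fields per region: `dens_loss` (fraction of baseline density
#' lost at severity 1), `lambda_gain` (relative increase of `lambda_par` at
#' severity 1), `kappa` (absolute override of the orientation concentration,
#' `NULL` = keep baseline). Magnitudes are configuration defaults chosen to
#' mirror the direction/significance pattern of the epileptic hippocampus;
#' they are not measured effect sizes.
#'
#' @return Nested list: condition -> region -> effect fields.
#' @export
default_condition_effects <- function() {
  list(
    control = list(),
    ipsilateral = list(
      CA1   = list(dens_loss = 0.65, kappa = 0),
      CA3   = list(dens_loss = 0.55, kappa = 0),
      DG    = list(dens_loss = 0.35, lambda_gain = 0.35),
      hilus = list(dens_loss = 0.25, lambda_gain = 0.60),
      srCA1 = list(dens_loss = 0.30)
    ),
    contralateral = list(
      CA1 = list(dens_loss = 0.65, kappa = 6)
    )
  )
}

#' Specify a synthetic hippocampal-slice phantom
#'
#' A `phantom_spec` is the complete parametric description of one synthetic
#' 2D hippocampal section: grid geometry, experimental condition, per-region
#' tissue parameters, density-diffusivity coupling, pathology severity and
#' the random seed. Identical specs (including seed) generate bit-identical
#' phantoms.
#'
#' @param condition One of `"control"`, `"ipsilateral"`, `"contralateral"`.
#' @param grid_shape Integer vector `c(rows, cols)`; rows index the
#'   dorso-ventral axis, columns the left-right axis. Both dims must be
#'   at least 32 (64+ recommended so all five regions fit).
#' @param voxel_size In-plane voxel size in mm (default 0.04, i.e. 40 um).
#' @param severity Pathology severity scalar in `[0, 1]`. Default 0 for
#'   control, 0.75 for ipsilateral and 0.3 for contralateral slices; cohort
#'   generation draws it per animal (uniform on `[0.5, 1]` ipsilaterally).
#' @param seed Integer RNG seed for all stochastic stages of this slice.
#' @param tissue Per-region tissue parameters, see [default_tissue_params()].
#' @param effects Condition effects, see [default_condition_effects()].
#' @param coupling List with intercept `a_MD` (mm^2/s) and slope `b_MD`
#'   (mm^2/s per density unit) tying the perpendicular diffusivity to the
#'   local cell-density proxy, `lambda_perp(voxel) = a_MD - b_MD *
#'   density(voxel)`. Higher density means lower diffusivity and higher
#'   anisotropy in layered regions; `b_MD = 0` decouples them (regions then
#'   use their nominal `lambda_perp`). The default region baselines satisfy
#'   `lambda_perp = a_MD - b_MD * baseline_density`, so control slices sit
#'   at their nominal diffusivities either way.
#' @param jitter_sd Slice-level multiplicative jitter (sd, relative) applied
#'   to region densities and diffusivities, emulating slice-to-slice
#'   biological variability.
#' @param voxel_density_sd Additive within-region voxel noise on the density
#'   map (arbitrary units).
#' @param gcl_dispersion Width multiplier of the granule cell layer band
#'   (granule cell dispersion). Default derived from condition and severity:
#'   `1 + severity` ipsilaterally, `1 + 0.25 * severity` contralaterally.
#' @param background_diffusivity Isotropic diffusivity of the saline
#'   background, mm^2/s.
#' @param background_s0_factor Relative b0 signal of the background (proton
#'   density / T2 surrogate) used so that b0-based masking is well posed.
#'
#' @return Object of class `phantom_spec`.
#' @seealso [build_phantom()], [generate_geometry()]
#' @export
phantom_spec <- function(condition = c("control", "ipsilateral", "contralateral"),
                         grid_shape = c(102L, 128L),
                         voxel_size = 0.04,
                         severity = NULL,
                         seed = 1L,
                         tissue = default_tissue_params(),
                         effects = default_condition_effects(),
                         coupling = list(a_MD = 0.7e-3, b_MD = 0.5e-3),
                         jitter_sd = 0.04,
                         voxel_density_sd = 0.03,
                         gcl_dispersion = NULL,
                         background_diffusivity = 2.0e-3,
                         background_s0_factor = 0.6) {
  condition <- match.arg(condition)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape < 32)) {
    abort("`grid_shape` must be two integers, both >= 32.")
  }
  if (!is.numeric(voxel_size) || voxel_size <= 0) {
    abort("`voxel_size` must be > 0.")
  }
  if (is.null(severity)) {
    severity <- switch(condition, control = 0, ipsilateral = 0.75, contralateral = 0.3)
  }
  if (severity < 0 || severity > 1) abort("`severity` must lie in [0, 1].")
  if (!setequal(names(tissue), ROI_NAMES)) {
    abort("`tissue` must provide parameters for exactly the five regions.")
  }
  for (roi in ROI_NAMES) {
    tp <- tissue[[roi]]
    if (tp$lambda_par < tp$lambda_perp || tp$lambda_perp <= 0) {
      abort(sprintf("region %s: need lambda_par >= lambda_perp > 0", roi))
    }
    if (tp$kappa < 0) abort(sprintf("region %s: kappa must be >= 0", roi))
    md <- (tp$lambda_par + 2 * tp$lambda_perp) / 3
    if (md < 0.1e-3 || md > 2.0e-3) {
      abort(sprintf("region %s: trace/3 = %.3g outside the fixed-tissue range [0.1, 2.0]e-3 mm^2/s", roi, md))
    }
    ## coupling must keep diffusivities physical over the density range
    b <- coupling$b_MD %||% 0
    if (b != 0) {
      a <- coupling$a_MD %||% abort("coupling needs `a_MD` when `b_MD` != 0")
      lp_max <- a                                  # density -> 0
      lp_min <- a - b * (tp$baseline_density + 0.35) # density overshoot
      if (lp_min <= 0 || lp_max > tp$lambda_par) {
        abort(sprintf("region %s: density coupling drives lambda_perp outside (0, lambda_par]", roi))
      }
    }
  }
  if (is.null(gcl_dispersion)) {
    gcl_dispersion <- switch(condition,
      control = 1,
      ipsilateral = 1 + 1.0 * severity,
      contralateral = 1 + 0.25 * severity
    )
  }
  structure(
    list(
      condition = condition,
      grid_shape = grid_shape,
      voxel_size = voxel_size,
      severity = severity,
      seed = as.integer(seed),
      tissue = tissue,
      effects = effects,
      coupling = coupling,
      jitter_sd = jitter_sd,
      voxel_density_sd = voxel_density_sd,
      gcl_dispersion = gcl_dispersion,
      background_diffusivity = background_diffusivity,
      background_s0_factor = background_s0_factor
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s slice, %d x %d voxels @ %.3g mm, severity %.2f, seed %d\n",
    x$condition, x$grid_shape[1], x$grid_shape[2], x$voxel_size, x$severity, x$seed
  ))
  invisible(x)
}

## Slice-level effective parameters: condition effects scaled by severity,
## plus seeded multiplicative jitter. Deterministic in (spec, seed).
effective_params <- function(spec) {
  eff <- spec$effects[[spec$condition]] %||% list()
  set.seed(seed_derive(spec$seed, "jitter"))
  rows <- lapply(ROI_NAMES, function(roi) {
    tp <- spec$tissue[[roi]]
    ef <- eff[[roi]] %||% list()
    loss <- (ef$dens_loss %||% 0) * spec$severity
    gain <- (ef$lambda_gain %||% 0) * spec$severity
    jit <- rnorm(3, 1, c(spec$jitter_sd, spec$jitter_sd / 1.5, spec$jitter_sd / 1.5))
    tibble(
      roi = roi,
      mu = tp$mu,
      kappa = if (is.null(ef$kappa)) tp$kappa else ef$kappa,
      lambda_par = tp$lambda_par * (1 + gain) * jit[2],
      lambda_perp = tp$lambda_perp * jit[3],
      jit_perp = jit[3],
      density = tp$baseline_density * (1 - loss) * max(jit[1], 0),
      baseline_density = tp$baseline_density
    )
  })
  dplyr::bind_rows(rows)
}
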