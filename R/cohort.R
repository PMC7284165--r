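#' Configure a cohort experiment
#'
#' A `run_config` fixes everything needed to simulate and analyse one full
#' study: cohort sizes per condition (default 6 control / 9 ipsilateral /
#' 6 contralateral slices), phantom overrides, acquisition scheme, noise
#' level, spherical harmonic order, significance level and the master seed.
#' The master seed deterministically derives every per-slice and per-stage
#' seed, so a config reproduces its cohort bit-identically.
#'
#' @param n_control,n_ipsilateral,n_contralateral Slices per condition.
#' @param grid_shape,voxel_size Phantom grid (rows x cols) and voxel size
#'   in mm.
#' @param snr Simulated signal-to-noise ratio against the tissue b0 level
#'   (the emulated acquisitions ranged over roughly 11-22; default 15).
#'   `Inf` disables noise.
#' @param S0 Reference b0 signal level.
#' @param n_dirs,b,n_b0 Gradient scheme: direction count, b-value (s/mm^2),
#'   number of b = 0 volumes.
#' @param sh_order Even SH order for the ADC profile fit.
#' @param alpha Significance threshold for all tests.
#' @param seed Master seed (integer).
#' @param contra_severity_factor Contralateral severity as a fraction of the
#'   same animal's ipsilateral severity.
#' @param n_orient_per_roi Per-slice cap on orientation samples entering
#'   the group V-tests.
#' @param coupling,tissue,effects Passed to [phantom_spec()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_control = 6, n_ipsilateral = 9, n_contralateral = 6,
                       grid_shape = c(102L, 128L), voxel_size = 0.04,
                       snr = 15, S0 = 1000,
                       n_dirs = 60, b = 1000, n_b0 = 6,
                       sh_order = 4, alpha = 0.05, seed = 1L,
                       contra_severity_factor = 0.4,
                       n_orient_per_roi = 200,
                       coupling = list(a_MD = 0.7e-3, b_MD = 0.5e-3),
                       tissue = default_tissue_params(),
                       effects = default_condition_effects()) {
  if (n_contralateral > n_ipsilateral) {
    abort("contralateral slices pair with ipsilateral animals: need n_contralateral <= n_ipsilateral")
  }
  structure(
    list(
      n_control = n_control, n_ipsilateral = n_ipsilateral,
      n_contralateral = n_contralateral,
      grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
      snr = snr, S0 = S0, n_dirs = n_dirs, b = b, n_b0 = n_b0,
      sh_order = sh_order, alpha = alpha, seed = as.integer(seed),
      contra_severity_factor = contra_severity_factor,
      n_orient_per_roi = n_orient_per_roi,
      coupling = coupling, tissue = tissue, effects = effects
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> cohort %d/%d/%d (control/ipsi/contra), grid %d x %d, SNR %s, SH order %d, seed %d\n",
    x$n_control, x$n_ipsilateral, x$n_contralateral,
    x$grid_shape[1], x$grid_shape[2], format(x$snr), x$sh_order, x$seed
  ))
  invisible(x)
}

#' Write / read a run configuration as YAML
#'
#' The round trip is lossless for all scalar and list fields.
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config()` the path invisibly; `read_run_config()` a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[setdiff(names(x), character(0))])
}

#' Cohort manifest
#'
#' One row per slice: identifier, animal, condition, per-slice seed and
#' severity. Ipsilateral severities are drawn uniformly on `[0.5, 1]` per
#' epileptic animal; a contralateral slice from the same animal receives
#' `contra_severity_factor` times that severity (pathology spreads only
#' partially to the non-injected side). Controls have severity 0.
#'
#' @param config A [run_config()].
#' @return Tibble with columns `slice_id`, `animal`, `group`, `seed`,
#'   `severity`.
#' @export
cohort_manifest <- function(config) {
  set.seed(seed_derive(config$seed, "severity"))
  sev_ipsi <- runif(config$n_ipsilateral, 0.5, 1)
  rows <- list()
  add <- function(id, animal, group, sev) {
    tibble(slice_id = id, animal = animal, group = group,
           seed = seed_derive(config$seed, id), severity = sev)
  }
  for (i in seq_len(config$n_control)) {
    rows[[length(rows) + 1]] <- add(sprintf("ctrl%02d", i), sprintf("ctrl_an%02d", i), "control", 0)
  }
  for (i in seq_len(config$n_ipsilateral)) {
    rows[[length(rows) + 1]] <- add(sprintf("ipsi%02d", i), sprintf("epi_an%02d", i), "ipsilateral", sev_ipsi[i])
  }
  for (i in seq_len(config$n_contralateral)) {
    rows[[length(rows) + 1]] <- add(sprintf("contra%02d", i), sprintf("epi_an%02d", i), "contralateral",
                                    config$contra_severity_factor * sev_ipsi[i])
  }
  dplyr::bind_rows(rows)
}

## Full single-slice pipeline: phantom -> signal -> noise -> tensor fit ->
## scalar maps -> SH axis maps -> per-region summaries. Returns the tidy
## pieces that feed the cohort-level statistics.
process_slice <- function(slice, scheme, config) {
  spec <- phantom_spec(
    condition = slice$group, grid_shape = config$grid_shape,
    voxel_size = config$voxel_size, severity = slice$severity,
    seed = slice$seed, coupling = config$coupling,
    tissue = config$tissue, effects = config$effects
  )
  ph <- build_phantom(spec)
  stack <- simulate_signal(ph$tensors, scheme, S0 = config$S0, s0_map = ph$s0_map)
  if (is.finite(config$snr)) {
    stack <- add_rician_noise(stack, config$snr, seed = seed_derive(slice$seed, "noise"))
  }
  tf <- fit_tensor(stack)
  sm <- tensor_metrics(tf)
  ax <- axis_maps(stack, mask = tf$mask, order = config$sh_order)

  labels <- ph$roi$labels
  valid <- sm$mask
  roi_stats <- lapply(ROI_NAMES, function(rn) {
    sel <- labels == ROI_LABELS[[rn]] & valid
    tibble(
      roi = rn,
      FA = mean(sm$fa[sel]), MD = mean(sm$md[sel]),
      dvD = mean(ax$dv[sel]), lrD = mean(ax$lr[sel]),
      dvlr_ratio = mean(ax$ratio[sel], na.rm = TRUE)
    )
  })
  roi_stats <- dplyr::bind_rows(roi_stats)

  set.seed(seed_derive(slice$seed, "orient_sub"))
  orients <- lapply(ROI_NAMES, function(rn) {
    th <- sm$theta[labels == ROI_LABELS[[rn]] & valid]
    th <- th[is.finite(th)]
    if (length(th) > config$n_orient_per_roi) {
      th <- th[sample.int(length(th), config$n_orient_per_roi)]
    }
    tibble(roi = rn, theta = th)
  })
  orients <- dplyr::bind_rows(orients)

  dens <- ph$density$roi_means
  list(
    roi_stats = roi_stats,
    orientations = orients,
    density_CA1 = dens$density[dens$roi == "CA1"],
    density_CA3 = dens$density[dens$roi == "CA3"],
    density_GCL = dens$density[dens$roi == "DG"],
    gcl_width = ph$density$gcl_width,
    phantom = ph, stack = stack, maps = sm, axis = ax
  )
}

#' Run a full cohort experiment
#'
#' End-to-end pipeline over a seeded cohort: per slice, generate the
#' phantom, simulate the HARDI acquisition, add Rician noise, fit tensors
#' and the spherical harmonic ADC profile, and extract per-region slice
#' means; then run the statistical workflow over the cohort: axial V-tests
#' of the fitted orientations per group and region against the hypothesized
#' directions, one-way ANOVA with Tukey contrasts across groups (per region
#' and parameter) and across regions (control slices), paired ipsilateral/
#' contralateral t-tests (animals contributing both sides), and Pearson
#' correlations between diffusion parameters and the phantom's histology
#' proxies, pooled and within the ipsilateral subset.
#'
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, per-slice NIfTI
#'   stacks, gradient tables, label/density/FA/MD/orientation maps, the ROI
#'   table, manifest, config and statistics report are written there.
#' @param keep_slices Keep per-slice image objects in the result (memory
#'   heavy; default `FALSE`).
#' @return Object of class `hippo_cohort`: `manifest`, `roi_table` (tidy
#'   rows slice x region x parameter with histology columns), pooled
#'   `orientations`, the `report` ([build_report()]), and the `config`.
#' @export
run_cohort <- function(config = run_config(), output_dir = NULL, keep_slices = FALSE) {
  manifest <- cohort_manifest(config)
  scheme <- make_scheme(config$n_dirs, config$b, config$n_b0,
                        seed = seed_derive(config$seed, "scheme"))
  notes <- character(0)
  small <- manifest |>
    dplyr::count(.data$group) |>
    dplyr::filter(.data$n < 3)
  if (nrow(small)) {
    notes <- c(notes, sprintf("underpowered group(s): %s",
                              paste(small$group, small$n, collapse = ", ")))
    warning("cohort has underpowered groups (< 3 slices); tests flagged in report notes")
  }

  slice_out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    slice_out[[i]] <- process_slice(manifest[i, ], scheme, config)
  }

  roi_table <- purrr::map2_dfr(slice_out, seq_len(nrow(manifest)), function(so, i) {
    so$roi_stats |>
      tidyr::pivot_longer(cols = c("FA", "MD", "dvD", "lrD", "dvlr_ratio"),
                          names_to = "parameter", values_to = "value") |>
      dplyr::mutate(
        slice_id = manifest$slice_id[i], animal = manifest$animal[i],
        group = manifest$group[i], severity = manifest$severity[i],
        density_CA1 = so$density_CA1, density_CA3 = so$density_CA3,
        density_GCL = so$density_GCL, gcl_width = so$gcl_width,
        .before = 1
      )
  })

  orientations <- purrr::map2_dfr(slice_out, seq_len(nrow(manifest)), function(so, i) {
    dplyr::mutate(so$orientations, slice_id = manifest$slice_id[i],
                  group = manifest$group[i], .before = 1)
  })

  ## --- statistics ---
  alpha <- config$alpha
  vtests <- purrr::map_dfr(unique(orientations$group), function(g) {
    purrr::map_dfr(ROI_NAMES, function(rn) {
      th <- orientations$theta[orientations$group == g & orientations$roi == rn]
      dplyr::mutate(vtest(th, roi_orientation_hypotheses[[rn]], alpha = alpha),
                    group = g, roi = rn, .before = 1)
    })
  })

  params <- c("FA", "MD", "dvD", "lrD", "dvlr_ratio")
  anovas <- NULL
  if (dplyr::n_distinct(manifest$group) >= 2 && !nrow(small)) {
    anovas <- purrr::map_dfr(ROI_NAMES, function(rn) {
      purrr::map_dfr(params, function(p) {
        anova_tukey(roi_table, p, across = "group", roi = rn, alpha = alpha)
      })
    })
    anovas <- dplyr::bind_rows(
      anovas,
      purrr::map_dfr(params, function(p) {
        anova_tukey(roi_table, p, across = "roi", group = "control", alpha = alpha)
      })
    )
  }

  paired <- NULL
  paired_animals <- intersect(manifest$animal[manifest$group == "ipsilateral"],
                              manifest$animal[manifest$group == "contralateral"])
  if (length(paired_animals) >= 3) {
    paired <- purrr::map_dfr(ROI_NAMES, function(rn) {
      purrr::map_dfr(params, function(p) paired_test(roi_table, p, rn, alpha = alpha))
    })
  }

  corr_specs <- list(
    c("MD", "density_CA1", "CA1"), c("FA", "density_CA1", "CA1"),
    c("FA", "density_CA3", "CA3"), c("MD", "density_GCL", "DG"),
    c("FA", "gcl_width", "CA1")
  )
  correlations <- purrr::map_dfr(corr_specs, function(cs) {
    dplyr::bind_rows(
      correlate(roi_table, cs[1], cs[2], cs[3], subset = "all", alpha = alpha),
      correlate(roi_table, cs[1], cs[2], cs[3], subset = "ipsilateral", alpha = alpha)
    )
  })

  report <- build_report(roi_table, vtests = vtests, anovas = anovas,
                         paired = paired, correlations = correlations,
                         alpha = alpha, notes = notes)

  out <- structure(
    list(manifest = manifest, roi_table = roi_table, orientations = orientations,
         report = report, config = config, scheme = scheme,
         slices = if (keep_slices) slice_out else NULL),
    class = "hippo_cohort"
  )

  if (!is.null(output_dir)) {
    write_cohort_artifacts(out, slice_out, output_dir)
  }
  out
}

## Writes the on-disk form of a cohort: NIfTI stacks + gradient tables +
## maps per slice, the tidy tables as CSV, config as YAML, report as
## CSV/JSON, and a manifest recording seeds and the config hash.
write_cohort_artifacts <- function(cohort, slice_out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort$manifest
  for (i in seq_len(nrow(manifest))) {
    so <- slice_out[[i]]
    pre <- file.path(dir, manifest$slice_id[i])
    write_dwi_stack(so$stack, pre)
    write_map(so$phantom$roi, paste0(pre, "_labels.nii.gz"))
    vs <- so$phantom$roi$voxel_size
    write_map(so$phantom$density$map, paste0(pre, "_density.nii.gz"), vs)
    write_map(so$maps$fa, paste0(pre, "_FA.nii.gz"), vs)
    write_map(so$maps$md, paste0(pre, "_MD.nii.gz"), vs)
    write_map(so$maps$theta, paste0(pre, "_theta.nii.gz"), vs)
    write_map(so$axis$ratio, paste0(pre, "_dvlr_ratio.nii.gz"), vs)
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$roi_table, file.path(dir, "roi_table.csv"), row.names = FALSE)
  write_run_config(cohort$config, file.path(dir, "config.yaml"))
  write_report(cohort$report, file.path(dir, "report"))
  invisible(dir)
}

#' Read an ROI table written by [run_cohort()]
#'
#' @param path CSV path.
#' @return Tibble in the ROI-table schema.
#' @export
read_roi_table <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' @export
print.hippo_cohort <- function(x, ...) {
  print(x$config)
  print(x$report)
  invisible(x)
}

#' Quantify user-supplied DWI data
#'
#' Applies the quantification stack (tensor fit, scalar maps, spherical
#' harmonic axis diffusivities, per-region means) to an externally acquired
#' dataset: a NIfTI DWI stack with FSL-style bval/bvec files and a region
#' label map using the package's coding. No group statistics are computed —
#' one slice carries no cohort structure.
#'
#' @param dwi_prefix Path prefix of `<prefix>.nii.gz` + `.bval`/`.bvec`.
#' @param roi_path NIfTI label map path.
#' @param sh_order Even SH order for the profile fit.
#' @param mask Optional voxel mask; default Otsu on mean b0.
#' @return List with `maps` (`scalar_maps`), `axis`
#'   (`axis_diffusivities`), and the tidy `roi_table` of per-region means.
#' @export
fit_external <- function(dwi_prefix, roi_path, sh_order = 4, mask = NULL) {
  stack <- read_dwi_stack(dwi_prefix)
  roiset <- read_roiset(roi_path)
  if (!identical(as.integer(roiset$grid_shape), as.integer(stack$grid_shape))) {
    abort("DWI stack and label map disagree on grid shape")
  }
  tf <- fit_tensor(stack, mask = mask)
  sm <- tensor_metrics(tf)
  ax <- axis_maps(stack, mask = tf$mask, order = sh_order)
  labels <- roiset$labels
  valid <- sm$mask
  roi_table <- purrr::map_dfr(ROI_NAMES, function(rn) {
    sel <- labels == ROI_LABELS[[rn]] & valid
    tibble(
      roi = rn, n_voxels = sum(sel),
      FA = mean(sm$fa[sel]), MD = mean(sm$md[sel]),
      dvD = mean(ax$dv[sel]), lrD = mean(ax$lr[sel]),
      dvlr_ratio = mean(ax$ratio[sel], na.rm = TRUE),
      theta_axial_mean = axial_mean(sm$theta[sel][is.finite(sm$theta[sel])])
    )
  })
  list(maps = sm, axis = ax, roi_table = roi_table)
}
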