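# Shared fixtures. Everything is generated in code; the expensive cohort
# Monte-Carlo batches are computed once per session and cached.

ROIS <- c("CA1", "CA3", "DG", "hilus", "srCA1")
LAB <- c(CA1 = 1L, CA3 = 2L, DG = 3L, hilus = 4L, srCA1 = 5L)

# Small grid used by unit tests (full default grid reserved for the
# end-to-end checks).
small_spec <- function(condition = "control", seed = 1L, ...) {
  phantom_spec(condition, grid_shape = c(72L, 90L), seed = seed, ...)
}

roi_sel <- function(ph, roi, extra = TRUE) {
  ph$roi$labels == LAB[[roi]] & extra
}

# A hand-built straight-band label map (DG only), for width measurement.
straight_band_roiset <- function(width_vox = 5, n = 60, voxel_size = 0.04) {
  labels <- matrix(0L, 20, n)
  labels[10:(10 + width_vox - 1), ] <- LAB[["DG"]]
  structure(
    list(labels = labels, roi_names = LAB, voxel_size = voxel_size,
         grid_shape = dim(labels)),
    class = "roi_set"
  )
}

# Arbitrary symmetric positive definite test tensor on the tissue scale.
random_spd_tensor <- function() {
  A <- matrix(rnorm(9, sd = 1), 3, 3)
  D <- crossprod(A) + diag(3) * 0.1
  D <- D / sum(diag(D)) * 3 * 0.5e-3 # trace/3 = 0.5e-3
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

tensor_field_from_rows <- function(D6, voxel_size = 0.04) {
  structure(
    list(D = D6, grid_shape = NULL, voxel_size = voxel_size,
         mask = rep(TRUE, nrow(D6))),
    class = "tensor_field"
  )
}

quad_form <- function(D6, g) {
  D <- matrix(c(D6[1], D6[4], D6[5],
                D6[4], D6[2], D6[6],
                D6[5], D6[6], D6[3]), 3, 3)
  as.numeric(t(g) %*% D %*% g)
}

# ---- cached Monte-Carlo cohort batches (used by the end-to-end tests) ----
.fixture_env <- new.env(parent = emptyenv())

# Default-condition cohorts (6/9/6 at SNR 15), one per seed.
cohort_batch <- function(n = 50) {
  key <- paste0("cohorts_", n)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- lapply(seq_len(n), function(i) {
      ch <- run_cohort(run_config(seed = 5000L + i))
      list(report = ch$report, roi_table = ch$roi_table)
    })
  }
  .fixture_env[[key]]
}

# Ipsilateral-only cohorts with the density-diffusivity coupling switched
# off: the null for the intra-group correlation calibration.
null_corr_batch <- function(n = 100) {
  key <- paste0("null_", n)
  if (is.null(.fixture_env[[key]])) {
    cfg0 <- function(seed) {
      run_config(n_control = 0, n_ipsilateral = 9, n_contralateral = 0,
                 coupling = list(a_MD = 0.7e-3, b_MD = 0), seed = seed)
    }
    .fixture_env[[key]] <- vapply(seq_len(n), function(i) {
      ch <- suppressWarnings(run_cohort(cfg0(7000L + i)))
      row <- subset(ch$report$correlations,
                    parameter == "FA" & histology == "density_CA1" &
                      roi == "CA1" & subset == "ipsilateral")
      row$p_value[1]
    }, numeric(1))
  }
  .fixture_env[[key]]
}

tukey_row <- function(report, param, roi_, contrast_) {
  subset(report$anovas, test == "tukey" & across == "group" &
           parameter == param & roi == roi_ & contrast == contrast_)
}
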