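#' V-test for non-uniformity of axial orientations
#'
#' Tests angle samples for non-uniformity against a hypothesized mean
#' direction `mu0`. For axial data (orientations defined modulo 180
#' degrees, the default here) angles are doubled first, `phi_i = 2
#' theta_i`, `phi0 = 2 mu0` — without doubling the test is ill-posed for
#' apolar structures such as dendrites and axons. The statistic is
#' `V = sum(cos(phi_i - phi0))`, standardised as `u = V * sqrt(2 / n)`,
#' with a one-sided p-value from the standard normal upper tail (the usual
#' large-sample approximation, adequate for n >= 5).
#'
#' @param angles Angles in degrees; values outside `[0, 180)` are
#'   normalised, not rejected.
#' @param mu0 Hypothesized mean direction, degrees.
#' @param axial Double the angles (default `TRUE`). Set `FALSE` for truly
#'   circular (360-degree periodic) data.
#' @param alpha Significance level for the flag.
#' @return One-row tibble: `test`, `n`, `mu0`, `statistic` (u), `V`,
#'   `p_value`, `significant`.
#' @export
vtest <- function(angles, mu0, axial = TRUE, alpha = 0.05) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n == 0) abort("empty angle vector")
  if (n < 5) abort("V-test needs at least 5 angles (normal approximation)")
  mult <- if (axial) 2 else 1
  phi <- mult * (angles %% (360 / mult)) * pi / 180
  phi0 <- mult * mu0 * pi / 180
  V <- sum(cos(phi - phi0))
  u <- V * sqrt(2 / n)
  p <- pnorm(u, lower.tail = FALSE)
  tibble(
    test = "vtest", n = n, mu0 = mu0, statistic = u, V = V,
    p_value = p, significant = p < alpha
  )
}

#' One-way ANOVA with Tukey HSD post hoc contrasts
#'
#' Compares per-slice region means of one diffusion parameter across the
#' levels of `across` (`"group"`: control / ipsilateral / contralateral,
#' optionally within one region; `"roi"`: across regions, optionally within
#' one group). Returns the ANOVA F-test plus all pairwise Tukey honest
#' significant difference contrasts (studentized-range adjusted p-values).
#'
#' @param table An ROI table (see [run_cohort()]): tidy rows with columns
#'   `slice_id`, `group`, `roi`, `parameter`, `value`.
#' @param parameter Which parameter to test (`"FA"`, `"MD"`, `"dvD"`,
#'   `"lrD"`, `"dvlr_ratio"`).
#' @param across `"group"` or `"roi"`.
#' @param roi,group Optional filter fixing the other factor.
#' @param alpha Significance level.
#' @return Tibble with one ANOVA row (`test = "anova"`, `statistic` = F)
#'   and one row per Tukey contrast (`test = "tukey"`, `contrast` such as
#'   `"ipsilateral-control"`, `estimate` = level-mean difference).
#' @export
anova_tukey <- function(table, parameter, across = c("group", "roi"),
                        roi = NULL, group = NULL, alpha = 0.05) {
  across <- match.arg(across)
  df <- dplyr::filter(table, .data$parameter == !!parameter)
  if (!is.null(roi)) df <- dplyr::filter(df, .data$roi == !!roi)
  if (!is.null(group)) df <- dplyr::filter(df, .data$group == !!group)
  df <- dplyr::filter(df, is.finite(.data$value))
  fac <- factor(df[[across]])
  if (nlevels(fac) < 2) abort("ANOVA needs at least 2 factor levels")
  if (any(table(fac) < 2)) abort("ANOVA needs at least 2 observations per level")
  fit <- aov(df$value ~ fac)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$fac
  out_anova <- tibble(
    test = "anova", parameter = parameter, across = across,
    roi = roi %||% NA_character_, group = group %||% NA_character_,
    contrast = NA_character_, estimate = NA_real_,
    statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1],
    significant = an$`Pr(>F)`[1] < alpha
  )
  out_tukey <- tibble(
    test = "tukey", parameter = parameter, across = across,
    roi = roi %||% NA_character_, group = group %||% NA_character_,
    contrast = rownames(tk), estimate = unname(tk[, "diff"]),
    statistic = NA_real_, p_value = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"] < alpha)
  )
  dplyr::bind_rows(out_anova, out_tukey)
}

#' Paired t-test between ipsilateral and contralateral slices
#'
#' Two-sided paired t-test of one parameter in one region between two
#' groups, pairing observations that share `pair_by` (default the animal:
#' ipsilateral and contralateral sections of the same brain). Degenerate
#' pairs with zero within-pair variance are flagged (`note`) instead of
#' erroring: identical pairs report p = 1, a constant non-zero shift
#' reports p = NA.
#'
#' @inheritParams anova_tukey
#' @param roi Region to test.
#' @param groups Length-2 character, the two paired groups.
#' @param pair_by Column identifying pairs.
#' @return One-row tibble with `statistic` (t), `p_value`, `n_pairs`,
#'   `estimate` (mean paired difference, first group minus second),
#'   `significant`, `note`.
#' @export
paired_test <- function(table, parameter, roi,
                        groups = c("ipsilateral", "contralateral"),
                        pair_by = "animal", alpha = 0.05) {
  df <- dplyr::filter(table, .data$parameter == !!parameter, .data$roi == !!roi,
                      .data$group %in% groups)
  wide <- df |>
    dplyr::select(dplyr::all_of(pair_by), "group", "value") |>
    tidyr::pivot_wider(names_from = "group", values_from = "value") |>
    tidyr::drop_na()
  x <- wide[[groups[1]]]; y <- wide[[groups[2]]]
  n <- length(x)
  if (n < 2) abort("paired test needs at least 2 complete pairs")
  d <- x - y
  if (sd(d) < 1e-12) {
    degenerate_p <- if (abs(mean(d)) < 1e-12) 1 else NA_real_
    return(tibble(
      test = "paired_t", parameter = parameter, roi = roi, n_pairs = n,
      estimate = mean(d), statistic = if (is.na(degenerate_p)) Inf * sign(mean(d)) else 0,
      p_value = degenerate_p,
      significant = if (is.na(degenerate_p)) NA else FALSE,
      note = "zero within-pair variance"
    ))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble(
    test = "paired_t", parameter = parameter, roi = roi, n_pairs = n,
    estimate = unname(tt$estimate), statistic = unname(tt$statistic),
    p_value = tt$p.value, significant = tt$p.value < alpha,
    note = NA_character_
  )
}

#' Pearson correlation between a diffusion and a histology measure
#'
#' Correlates per-slice region means of a diffusion parameter with a
#' histology-proxy column (`density_CA1`, `density_CA3`, `density_GCL`,
#' `gcl_width`), either pooled across all slices or within the ipsilateral
#' subset only (intra-group correlations are the stronger evidence that
#' diffusion metrics track pathology severity rather than group
#' membership).
#'
#' @inheritParams paired_test
#' @param dwi_param Diffusion parameter name.
#' @param histology_param Histology column name.
#' @param subset `"all"` or `"ipsilateral"`.
#' @return One-row tibble with `estimate` (r), `statistic` (t), `p_value`,
#'   `n`, `significant`.
#' @export
correlate <- function(table, dwi_param, histology_param, roi,
                      subset = c("all", "ipsilateral"), alpha = 0.05) {
  subset <- match.arg(subset)
  df <- dplyr::filter(table, .data$parameter == !!dwi_param, .data$roi == !!roi)
  if (subset == "ipsilateral") df <- dplyr::filter(df, .data$group == "ipsilateral")
  x <- df$value
  y <- df[[histology_param]]
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3) { # too few slices for an inference; report, don't error
    return(tibble(
      test = "pearson", parameter = dwi_param, histology = histology_param,
      roi = roi, subset = subset, n = sum(keep),
      estimate = NA_real_, statistic = NA_real_, p_value = NA_real_,
      significant = NA
    ))
  }
  ct <- cor.test(x[keep], y[keep], method = "pearson")
  tibble(
    test = "pearson", parameter = dwi_param, histology = histology_param,
    roi = roi, subset = subset, n = sum(keep),
    estimate = unname(ct$estimate), statistic = unname(ct$statistic),
    p_value = ct$p.value, significant = ct$p.value < alpha
  )
}

#' Assemble a statistics report
#'
#' Bundles the test tables of a cohort analysis with per-region/per-group
#' parameter summaries (means and standard deviations, the error bars of
#' the group-comparison figures) into a single machine-readable object.
#' No multiple-testing correction is applied by default (each test is read
#' at its own `alpha`); `bonferroni = TRUE` adds a column of
#' Bonferroni-adjusted p-values within each test family.
#'
#' @param roi_table ROI table (see [run_cohort()]).
#' @param vtests,anovas,paired,correlations Tidy result tibbles.
#' @param alpha Significance level recorded with the report.
#' @param bonferroni Add family-wise adjusted p-values.
#' @param notes Character vector of analysis notes (e.g. underpowered
#'   groups).
#' @return Object of class `stats_report`.
#' @export
build_report <- function(roi_table, vtests = NULL, anovas = NULL,
                         paired = NULL, correlations = NULL,
                         alpha = 0.05, bonferroni = FALSE, notes = character(0)) {
  summaries <- roi_table |>
    dplyr::group_by(.data$group, .data$roi, .data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE), .groups = "drop"
    )
  adjust <- function(df) {
    if (!is.null(df) && bonferroni && nrow(df)) {
      df$p_adjusted <- stats::p.adjust(df$p_value, "bonferroni")
    }
    df
  }
  structure(
    list(
      summaries = summaries,
      vtests = adjust(vtests), anovas = adjust(anovas),
      paired = adjust(paired), correlations = adjust(correlations),
      alpha = alpha, notes = notes
    ),
    class = "stats_report"
  )
}

#' @export
print.stats_report <- function(x, ...) {
  nn <- function(df) if (is.null(df)) 0L else nrow(df)
  cat(sprintf(
    "<stats_report> alpha = %g; %d V-tests, %d ANOVA/Tukey rows, %d paired tests, %d correlations\n",
    x$alpha, nn(x$vtests), nn(x$anovas), nn(x$paired), nn(x$correlations)
  ))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Write a statistics report to disk
#'
#' Emits each result table as CSV plus a single JSON file with the whole
#' report (summaries, tests, alpha, notes).
#'
#' @param report A `stats_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("summaries", "vtests", "anovas", "paired", "correlations")
  for (tb in tabs) {
    if (!is.null(report[[tb]])) {
      write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")), row.names = FALSE)
    }
  }
  jsonlite::write_json(
    report[c(tabs, "alpha", "notes")],
    file.path(dir, "stats_report.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}
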