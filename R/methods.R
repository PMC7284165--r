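#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cohort analysis
#'
#' Returns the cohort's results as a single tidy tibble.
#'
#' @param x A `hippo_cohort` from [run_cohort()].
#' @param what `"tests"` (all statistical results, stacked with a `family`
#'   column), `"roi"` (the slice-by-region parameter table) or
#'   `"summaries"` (per group/region/parameter mean and SD).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hippo_cohort <- function(x, what = c("tests", "roi", "summaries"), ...) {
  what <- match.arg(what)
  if (what == "roi") return(x$roi_table)
  if (what == "summaries") return(x$report$summaries)
  rep <- x$report
  fam <- function(df, family) {
    if (is.null(df)) return(NULL)
    dplyr::mutate(df, family = family, .before = 1)
  }
  dplyr::bind_rows(
    fam(rep$vtests, "vtest"),
    fam(rep$anovas, "anova_tukey"),
    fam(rep$paired, "paired_t"),
    fam(rep$correlations, "pearson")
  )
}

#' Glance at a cohort analysis
#'
#' @param x A `hippo_cohort`.
#' @param ... Unused.
#' @return One-row tibble: cohort sizes, SNR, alpha, master seed and the
#'   number of significant results per test family.
#' @export
glance.hippo_cohort <- function(x, ...) {
  rep <- x$report
  nsig <- function(df) if (is.null(df)) NA_integer_ else sum(df$significant, na.rm = TRUE)
  tibble(
    n_control = x$config$n_control,
    n_ipsilateral = x$config$n_ipsilateral,
    n_contralateral = x$config$n_contralateral,
    snr = x$config$snr,
    alpha = rep$alpha,
    seed = x$config$seed,
    n_sig_vtests = nsig(rep$vtests),
    n_sig_anova = nsig(rep$anovas),
    n_sig_paired = nsig(rep$paired),
    n_sig_correlations = nsig(rep$correlations)
  )
}
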