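test_that("V-test matches its closed form on aligned axial data", {
  res <- vtest(rep(37, 8), 37)
  expect_equal(res$statistic, 4) # u = sqrt(2 n) for perfect alignment
  expect_equal(res$p_value, pnorm(4, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(res$significant)
  expect_error(vtest(numeric(0), 0), "empty")
  expect_error(vtest(c(1, 2, 3), 0), "at least 5")
})

test_that("axial doubling makes the V-test invariant to 180-degree relabeling", {
  withr::with_seed(21, {
    th <- runif(40, 0, 180)
    base <- vtest(th, 90)
    flip <- th
    idx <- sample(40, 17)
    flip[idx] <- flip[idx] + 180
    res <- vtest(flip, 90)
    expect_equal(res$statistic, base$statistic, tolerance = 1e-12)
    expect_equal(res$p_value, base$p_value, tolerance = 1e-12)
    # without doubling the same relabeling changes the statistic
    circ_base <- vtest(th, 90, axial = FALSE)
    circ_flip <- vtest((th + c(180, rep(0, 39))) %% 360, 90, axial = FALSE)
    expect_false(isTRUE(all.equal(circ_base$statistic, circ_flip$statistic)))
  })
})

test_that("V-test type-I error is near nominal under uniform orientations", {
  withr::with_seed(22, {
    p <- vapply(1:200, function(i) vtest(runif(500, 0, 180), 90)$p_value, numeric(1))
    expect_gt(mean(p < 0.05), 0.01)
    expect_lt(mean(p < 0.05), 0.11)
  })
})

toy_table <- function(values, groups, rois = "CA1", parameter = "FA") {
  tibble::tibble(
    slice_id = sprintf("s%02d", seq_along(values)),
    animal = sprintf("a%02d", seq_along(values)),
    group = groups, roi = rois, parameter = parameter, value = values
  )
}

test_that("ANOVA + Tukey agree with a hand-rolled studentized-range oracle", {
  withr::with_seed(23, {
    vals <- c(rnorm(4, 10), rnorm(4, 12), rnorm(4, 11.2))
    grp <- rep(c("control", "ipsilateral", "contralateral"), each = 4)
    res <- anova_tukey(toy_table(vals, grp), "FA", across = "group", roi = "CA1")
    tukey <- res[res$test == "tukey", ]

    # oracle: pooled MSE + ptukey on each pairwise mean difference
    means <- tapply(vals, grp, mean)
    ni <- tapply(vals, grp, length)
    mse <- sum((vals - ave(vals, grp))^2) / (12 - 3)
    for (k in seq_len(nrow(tukey))) {
      ab <- strsplit(tukey$contrast[k], "-")[[1]]
      diff <- means[[ab[1]]] - means[[ab[2]]]
      se <- sqrt(mse / 2 * (1 / ni[[ab[1]]] + 1 / ni[[ab[2]]]))
      p_or <- stats::ptukey(abs(diff) / se, nmeans = 3, df = 9, lower.tail = FALSE)
      expect_equal(tukey$estimate[k], unname(diff), tolerance = 1e-10)
      expect_equal(tukey$p_value[k], p_or, tolerance = 1e-10)
    }
  })
})

test_that("two-group ANOVA F equals the squared t statistic", {
  withr::with_seed(24, {
    vals <- c(rnorm(6, 0.5, 0.05), rnorm(9, 0.4, 0.05))
    grp <- rep(c("control", "ipsilateral"), c(6, 9))
    res <- anova_tukey(toy_table(vals, grp), "FA", across = "group", roi = "CA1")
    f <- res$statistic[res$test == "anova"]
    t2 <- t.test(vals ~ grp, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-10)
  })
})

test_that("ANOVA rejects malformed designs and holds its nominal size", {
  tab1 <- toy_table(rnorm(4), rep("control", 4))
  expect_error(anova_tukey(tab1, "FA", across = "group", roi = "CA1"), "levels")
  tab2 <- toy_table(rnorm(3), c("control", "control", "ipsilateral"))
  expect_error(anova_tukey(tab2, "FA", across = "group", roi = "CA1"), "observations")
  withr::with_seed(25, {
    rej <- vapply(1:300, function(i) {
      tab <- toy_table(rnorm(18), rep(c("a", "b", "c"), each = 6))
      anova_tukey(tab, "FA", across = "group", roi = "CA1")$significant[1]
    }, logical(1))
    expect_gt(mean(rej), 0.015)
    expect_lt(mean(rej), 0.10)
  })
})

test_that("paired tests flag degenerate pairs and detect shifts", {
  mk_paired <- function(ipsi, contra) {
    n <- length(ipsi)
    tibble::tibble(
      slice_id = c(sprintf("i%d", 1:n), sprintf("c%d", 1:n)),
      animal = rep(sprintf("a%d", 1:n), 2),
      group = rep(c("ipsilateral", "contralateral"), each = n),
      roi = "CA1", parameter = "FA", value = c(ipsi, contra)
    )
  }
  x <- c(0.3, 0.35, 0.4, 0.32, 0.38)
  ident <- paired_test(mk_paired(x, x), "FA", "CA1")
  expect_equal(ident$p_value, 1)
  expect_equal(ident$note, "zero within-pair variance")
  shift <- paired_test(mk_paired(x + 0.1, x), "FA", "CA1")
  expect_true(is.na(shift$p_value))
  expect_equal(shift$note, "zero within-pair variance")
  withr::with_seed(26, {
    jit <- paired_test(mk_paired(x + 0.1 + rnorm(5, 0, 0.005), x), "FA", "CA1")
    expect_lt(jit$p_value, 0.05)
    expect_gt(jit$estimate, 0)
  })
})

test_that("Pearson correlations are exact on linear data and calibrated under the null", {
  tab <- toy_table(1:6 * 0.1, rep("ipsilateral", 6))
  tab$density_CA1 <- 2 * tab$value
  res <- correlate(tab, "FA", "density_CA1", "CA1", subset = "ipsilateral")
  expect_equal(res$estimate, 1, tolerance = 1e-12)
  withr::with_seed(27, {
    p <- vapply(1:1000, function(i) {
      tab <- toy_table(rnorm(21), rep("ipsilateral", 21))
      tab$density_CA1 <- rnorm(21)
      correlate(tab, "FA", "density_CA1", "CA1")$p_value
    }, numeric(1))
    expect_gt(mean(p < 0.05), 0.03)
    expect_lt(mean(p < 0.05), 0.07)
  })
})

test_that("reports aggregate summaries and serialize to CSV + JSON", {
  withr::with_seed(28, {
    vals <- rnorm(15, 0.5, 0.05)
    tab <- toy_table(vals, rep(c("control", "ipsilateral", "contralateral"), each = 5))
    tab$density_CA1 <- rnorm(15)
    rep_ <- build_report(
      tab,
      vtests = vtest(runif(30, 0, 180), 90),
      anovas = anova_tukey(tab, "FA", across = "group", roi = "CA1"),
      correlations = correlate(tab, "FA", "density_CA1", "CA1")
    )
    s <- rep_$summaries[rep_$summaries$group == "control", ]
    expect_equal(s$mean, mean(vals[1:5]))
    expect_equal(s$sd, sd(vals[1:5]))
    d <- withr::local_tempdir()
    write_report(rep_, d)
    expect_true(file.exists(file.path(d, "summaries.csv")))
    expect_true(file.exists(file.path(d, "stats_report.json")))
    js <- jsonlite::read_json(file.path(d, "stats_report.json"))
    expect_equal(js$alpha, 0.05)
  })
})
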