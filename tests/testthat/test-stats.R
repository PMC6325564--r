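test_that("Kruskal-Wallis omnibus matches a hand rank computation", {
  vals <- c(2.1, 3.4, 1.2, 4.8, 5.5, 6.1, 7.0, 4.9, 9.2, 8.1, 10.3, 11.7)
  grp <- rep(c("a", "b", "c"), each = 4L)
  cr <- compare_groups(vals, grp)
  # independent computation straight from the rank-sum definition (no ties)
  r <- rank(vals); N <- length(vals)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, grp, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  expect_lt(abs(cr$omnibus$H - H), 1e-10)
  expect_identical(cr$omnibus$df, 2L)
  expect_true(all(cr$pairwise$p_adj >= cr$pairwise$p - 1e-15))
})

test_that("identical groups give H = 0 and p = 1", {
  cr <- compare_groups(rep(5, 12L), rep(c("a", "b", "c"), each = 4L))
  expect_identical(cr$omnibus$H, 0)
  expect_identical(cr$omnibus$p, 1)
})

test_that("the dunnett name maps to Dunn with Sidak adjustment, with a warning", {
  vals <- rnorm(30); grp <- rep(c("a", "b", "c"), 10L)
  expect_warning(cr <- compare_groups(vals, grp, procedure = "dunnett"),
                 "Dunn")
  expect_match(cr$procedure, "dunn_sidak")
})

test_that("a 3-SD-shifted group is detected in nearly all replicates", {
  hits <- 0L
  set.seed(11L)
  for (r in 1:200) {
    vals <- c(rnorm(25L), rnorm(25L), rnorm(25L, mean = 3))
    grp <- rep(c("a", "b", "c"), each = 25L)
    cr <- compare_groups(vals, grp)
    sig <- cr$pairwise$significant[cr$pairwise$group1 == "c" | cr$pairwise$group2 == "c"]
    if (all(sig)) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.99)
})

test_that("percent change is exact arithmetic with display rounding isolated", {
  expect_equal(percent_change(0.16, 0.26), 62.5, tolerance = 1e-12)
  expect_identical(display_round(percent_change(0.16, 0.26)), 63)
  expect_identical(display_round(percent_change(0.17, 0.28)), 65)
  expect_identical(display_round(percent_change(2.5, 1.7)), -32)
  expect_identical(display_round(percent_change(0.36, 0.66)), 83)
  expect_identical(display_round(percent_change(0.42, 0.52)), 24)
  expect_identical(percent_change(0.7, 0.7), 0)
  expect_error(percent_change(0, 1), class = "wormswim_invalid_params")
})

test_that("Holm-Sidak adjustment is monotone and never below raw p", {
  set.seed(5L)
  for (r in 1:20) {
    p <- runif(25L)
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
  # small hand case: step-down Sidak on sorted p
  p <- c(0.01, 0.04, 0.3)
  expect_equal(holm_sidak(p),
               cummax(c(1 - 0.99^3, 1 - 0.96^2, 0.3)), tolerance = 1e-12)
})

test_that("position-wise Welch tests agree with t.test", {
  set.seed(9L)
  m1 <- matrix(rnorm(20L * 6L), 20L)
  m2 <- matrix(rnorm(15L * 6L, sd = 1.6), 15L)
  res <- profile_position_tests(m1, m2, sigma = seq(0.1, 0.6, by = 0.1))
  for (j in 1:6) {
    tt <- t.test(m1[, j], m2[, j])
    expect_equal(res$p[j], tt$p.value, tolerance = 1e-12)
    expect_equal(res$t[j], unname(tt$statistic), tolerance = 1e-12)
  }
  expect_true(all(res$p_adj >= res$p - 1e-15))
  expect_error(profile_position_tests(m1[1, , drop = FALSE], m2, seq(0.1, 0.6, 0.1)),
               class = "wormswim_invalid_params")
})

test_that("group summaries handle single-worm groups and are duplication-stable", {
  profiles <- data.frame(
    id = c("a1", "a2", "b1"), group = c("g1", "g1", "g2"),
    stage = "late", L_mm = c(0.6, 0.64, 0.7), speed_mm_s = c(0.2, 0.24, 0.3),
    frequency_hz = c(2.2, 2.4, 2.0), force_nN = c(0.5, 0.6, 0.4),
    power_pW = c(1.2, 1.4, 1.0)
  )
  gt <- summarize_groups(profiles)
  one <- gt[gt$group == "g2" & gt$metric == "L_mm", ]
  expect_identical(one$n, 1L)
  expect_true(is.na(one$sd))
  expect_identical(one$mean, 0.7)
  # exact duplication of the full set leaves the mean unchanged
  gt2 <- summarize_groups(rbind(profiles, profiles))
  expect_equal(gt2$mean, gt$mean, tolerance = 1e-14)
})

test_that("reports are deterministic and degrade gracefully without comparisons", {
  profiles <- data.frame(
    id = sprintf("w%d", 1:8), group = rep(c("g1", "g2"), each = 4L),
    stage = rep(c("L2", "late"), 4L),
    L_mm = seq(0.4, 0.68, length.out = 8L), speed_mm_s = seq(0.15, 0.29, length.out = 8L),
    frequency_hz = seq(1.9, 2.6, length.out = 8L), force_nN = seq(0.3, 0.7, length.out = 8L),
    power_pW = seq(0.5, 1.9, length.out = 8L)
  )
  gt <- summarize_groups(profiles)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  render_report(gt, list(), d1)
  render_report(gt, list(), d2)
  expect_false(file.exists(file.path(d1, "comparisons.csv")))
  expect_true(file.exists(file.path(d1, "group_table.csv")))
  f1 <- readLines(file.path(d1, "summary.txt")); f2 <- readLines(file.path(d2, "summary.txt"))
  expect_identical(f1, f2)
  cmp <- compare_groups(profiles$speed_mm_s, profiles$group)
  render_report(gt, list(speed_mm_s = cmp), d1)
  expect_true(file.exists(file.path(d1, "comparisons.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("preset cohorts reproduce the direction of developmental changes", {
  co <- make_cohort(c("N2_L2", "N2_late", "smn1_L2", "smn1_late",
                      "daf2_L2", "daf2_late"),
                    n_per_group = 8L, seed = 21L, duration = 2.5)
  res <- profile_cohort(co, chamber = list(center_mm = c(0, 0), radius_mm = 10))
  gt <- summarize_groups(res$profiles)
  m <- function(g, st, metric) gt$mean[gt$group == g & gt$stage == st & gt$metric == metric]
  expect_gt(percent_change(m("N2", "L2", "speed_mm_s"), m("N2", "late", "speed_mm_s")), 0)
  expect_gt(percent_change(m("daf2", "L2", "force_nN"), m("daf2", "late", "force_nN")), 0)
  expect_lt(percent_change(m("smn1", "L2", "frequency_hz"), m("smn1", "late", "frequency_hz")), 0)
  # cohort means recover the preset body length within a few percent
  expect_lt(abs(m("N2", "L2", "L_mm") - 0.39) / 0.39, 0.03)
})
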