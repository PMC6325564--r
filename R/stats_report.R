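# Group summaries and comparison procedures: mean +/- SD tables, percent
# changes, Kruskal-Wallis with Dunn post hoc tests, and position-wise t
# tests with Holm-Sidak correction for curvature profiles.

#' Summarize biomechanical profiles by group and stage
#'
#' @param profiles Data frame from [profile_cohort()] (columns `group`,
#'   `stage` plus metric columns).
#' @param metrics Metric columns to summarize.
#' @return Long data frame: `group`, `stage`, `metric`, `n`, `mean`, `sd`
#'   (`sd` is NA for single-worm groups).
#' @export
summarize_groups <- function(profiles,
                             metrics = c("L_mm", "speed_mm_s", "frequency_hz",
                                         "force_nN", "power_pW")) {
  key <- interaction(profiles$group, profiles$stage, drop = TRUE, sep = "|")
  out <- list()
  for (g in levels(key)) {
    sel <- profiles[key == g, , drop = FALSE]
    parts <- strsplit(g, "|", fixed = TRUE)[[1L]]
    for (m in metrics) {
      v <- sel[[m]]
      v <- v[is.finite(v)]
      out[[length(out) + 1L]] <- data.frame(
        group = parts[1L], stage = parts[2L], metric = m,
        n = length(v), mean = mean(v),
        sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Percent change between two stage means
#'
#' Signed change of the late-stage mean relative to the early-stage mean,
#' in percent: 100 * (late - early) / early. Full precision is returned;
#' use `round()` only for display.
#'
#' @param mean_early Early-stage group mean (> 0).
#' @param mean_late Late-stage group mean.
#' @return Percent change (numeric, full precision).
#' @export
percent_change <- function(mean_early, mean_late) {
  if (any(mean_early <= 0)) ws_stop("invalid_params", "percent change undefined for non-positive baseline")
  100 * (mean_late - mean_early) / mean_early
}

#' Display rounding to the nearest integer, halves away from zero
#'
#' Conventional display rounding for reported percentages (62.5 prints as
#' 63), as opposed to `round()`'s round-half-even. Stored values keep full
#' precision; this is for display only.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
display_round <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Compare a metric across groups (Kruskal-Wallis + Dunn)
#'
#' Omnibus Kruskal-Wallis test (tie-corrected) followed by Dunn's pairwise
#' rank comparisons with the configured p adjustment. `"dunnett"` is accepted
#' as a procedure name but is parametric and incompatible with rank tests;
#' it is mapped to Dunn with a Sidak adjustment, with a warning.
#'
#' @param values Numeric vector of metric values.
#' @param groups Group labels (same length).
#' @param procedure Post-hoc procedure: `"dunn"` or `"dunnett"` (mapped to
#'   Dunn).
#' @param adjust P-adjustment across the pairwise family: `"sidak"`,
#'   `"holm"`, `"bonferroni"`, `"BH"`, or `"none"`.
#' @param alpha Significance threshold recorded in the result.
#' @return A `comparison_result`: list with `omnibus` (`H`, `df`, `p`),
#'   `pairwise` data frame (`group1`, `group2`, `z`, `p`, `p_adj`,
#'   `significant`), `procedure`, `alpha`.
#' @export
compare_groups <- function(values, groups, procedure = c("dunn", "dunnett"),
                           adjust = c("sidak", "holm", "bonferroni", "BH", "none"),
                           alpha = 0.05) {
  procedure <- match.arg(procedure)
  adjust <- match.arg(adjust)
  if (procedure == "dunnett") {
    warning("'dunnett' is parametric and incompatible with Kruskal-Wallis; using Dunn's test with Sidak adjustment")
    procedure <- "dunn"
    adjust <- "sidak"
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) ws_stop("invalid_params", "need >= 2 groups")
  if (any(table(groups) < 2L)) ws_stop("invalid_params", "each group needs n >= 2")

  if (stats::var(values) == 0) {
    omnibus <- list(H = 0, df = nlevels(groups) - 1L, p = 1)
  } else {
    kt <- stats::kruskal.test(values, groups)
    omnibus <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                    p = kt$p.value)
  }

  # Dunn's z statistics on mean ranks with tie correction
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2L)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    z[j] <- if (se > 0) (mean_rank[[g1]] - mean_rank[[g2]]) / se else 0
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  m <- length(p_raw)
  p_adj <- switch(adjust,
    sidak = pmin(1, 1 - (1 - p_raw)^m),
    holm = stats::p.adjust(p_raw, "holm"),
    bonferroni = stats::p.adjust(p_raw, "bonferroni"),
    BH = stats::p.adjust(p_raw, "BH"),
    none = p_raw
  )
  pairwise <- data.frame(
    group1 = pairs[1L, ], group2 = pairs[2L, ], z = z, p = p_raw,
    p_adj = p_adj, significant = p_adj < alpha, stringsAsFactors = FALSE
  )
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 procedure = paste0("kruskal_wallis+", procedure, "_", adjust),
                 alpha = alpha), class = "comparison_result")
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak: order raw p ascending and set
#' adj_(k) = 1 - (1 - p_(k))^(m - k + 1), enforcing monotonicity by a
#' running maximum. Adjusted p values are always >= the raw ones.
#'
#' @param p Vector of raw p values.
#' @return Adjusted p values, in the original order.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Position-wise comparison of curvature profiles between two groups
#'
#' One Welch two-sample t test per body position, with Holm-Sidak
#' family-wise adjustment across positions.
#'
#' @param mat1,mat2 Matrices of normalized per-worm profiles
#'   (worms x positions) on a common sigma grid.
#' @param sigma Body-coordinate grid (length = number of positions).
#' @param alpha Significance threshold.
#' @return Data frame: `sigma`, `t`, `df`, `p`, `p_adj`, `significant`.
#' @export
profile_position_tests <- function(mat1, mat2, sigma, alpha = 0.05) {
  if (nrow(mat1) < 2L || nrow(mat2) < 2L) ws_stop("invalid_params", "each group needs n >= 2 worms")
  stopifnot(ncol(mat1) == ncol(mat2), ncol(mat1) == length(sigma))
  n1 <- nrow(mat1); n2 <- nrow(mat2)
  m1 <- colMeans(mat1); m2 <- colMeans(mat2)
  v1 <- apply(mat1, 2L, stats::var); v2 <- apply(mat2, 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate positions (zero variance in both groups, e.g. the normalized
  # head position): identical means are a clean null, differing means are not
  zero <- se2 <= 0
  if (any(zero)) {
    same <- zero & (m1 == m2)
    tstat[same] <- 0; p[same] <- 1
    p[zero & !same] <- 0
  }
  p_adj <- holm_sidak(p)
  data.frame(sigma = sigma, t = tstat, df = df, p = p, p_adj = p_adj,
             significant = p_adj < alpha)
}

#' Write a full report for a cohort comparison
#'
#' Writes `group_table.csv` (mean +/- SD per group and stage),
#' `comparisons.csv` (omnibus and pairwise results per metric),
#' `percent_changes.csv` (stage-to-stage change of each group mean), and a
#' plain-text `summary.txt`. Output is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param group_table From [summarize_groups()].
#' @param comparisons Named list of `comparison_result`s (one per metric),
#'   may be empty.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
render_report <- function(group_table, comparisons = list(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(group_table, file.path(dir, "group_table.csv"), row.names = FALSE)

  comp_rows <- list()
  for (metric in names(comparisons)) {
    cr <- comparisons[[metric]]
    pw <- cr$pairwise
    comp_rows[[length(comp_rows) + 1L]] <- data.frame(
      metric = metric, group1 = pw$group1, group2 = pw$group2,
      H = cr$omnibus$H, omnibus_p = cr$omnibus$p,
      z = pw$z, p = pw$p, p_adj = pw$p_adj, significant = pw$significant,
      stringsAsFactors = FALSE
    )
  }
  if (length(comp_rows)) {
    utils::write.csv(do.call(rbind, comp_rows),
                     file.path(dir, "comparisons.csv"), row.names = FALSE)
  }

  # stage-to-stage percent change of each group mean, per metric
  pc_rows <- list()
  stages <- unique(group_table$stage)
  if (length(stages) == 2L) {
    early <- stages[1L]; late <- stages[2L]
    for (g in unique(group_table$group)) {
      for (m in unique(group_table$metric)) {
        e <- group_table$mean[group_table$group == g & group_table$stage == early & group_table$metric == m]
        l <- group_table$mean[group_table$group == g & group_table$stage == late & group_table$metric == m]
        if (length(e) == 1L && length(l) == 1L && e > 0) {
          pc_rows[[length(pc_rows) + 1L]] <- data.frame(
            group = g, metric = m, mean_early = e, mean_late = l,
            percent_change = percent_change(e, l), stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  pc <- if (length(pc_rows)) do.call(rbind, pc_rows) else NULL
  if (!is.null(pc)) utils::write.csv(pc, file.path(dir, "percent_changes.csv"), row.names = FALSE)

  lines <- c("wormswim cohort report", "")
  for (i in seq_len(nrow(group_table))) {
    r <- group_table[i, ]
    lines <- c(lines, sprintf("%s %s %s: %.3g +/- %.3g (n = %d)",
                              r$group, r$stage, r$metric, r$mean,
                              if (is.na(r$sd)) 0 else r$sd, r$n))
  }
  if (!is.null(pc)) {
    lines <- c(lines, "", "stage-to-stage percent change of group means:")
    for (i in seq_len(nrow(pc))) {
      lines <- c(lines, sprintf("%s %s: %+d%%", pc$group[i], pc$metric[i],
                                as.integer(display_round(pc$percent_change[i]))))
    }
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
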