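#' Two-sample Student's t-test
#'
#' Pooled-variance two-sided t-test for independent samples (the classic
#' Student form); Welch's unequal-variance form behind a flag. Degenerate
#' input with zero variance in both groups returns `t = 0, p = 1` when the
#' means coincide and `|t| = Inf, p = 0` otherwise.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's correction instead of pooled variance.
#' @return List with `statistic`, `df`, and `p`.
#' @export
students_t <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (!all(is.finite(group_a)) || !all(is.finite(group_b))) {
    stop("non-finite values in input")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    df <- length(group_a) + length(group_b) - 2
    if (mean(group_a) == mean(group_b)) {
      return(list(statistic = 0, df = df, p = 1))
    }
    return(list(statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                df = df, p = 0))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with tie correction against a chi-square
#' reference. All-identical input returns `H = 0, p = 1` rather than an
#' error.
#'
#' @param groups List of numeric vectors (>= 2 groups, total n >= 3).
#' @return List with `statistic` (H), `df`, and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least 2 groups")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) stop("need at least 3 observations in total")
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, df = length(groups) - 1, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square with Yates continuity correction on by default, the
#' appropriate small-sample form for group-by-sex tables.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @param yates Apply the continuity correction.
#' @return List with `statistic`, `df`, and `p`.
#' @export
#' @examples
#' # sex distribution (males, females) in two groups
#' chi_square_2x2(rbind(c(24, 6), c(16, 11)))$p # ~0.15
chi_square_2x2 <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("`table` must be 2x2")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Score columns of a manifest that lacks an explicit declaration: every
# numeric column that is not the id, group, or a standard covariate.
default_score_cols <- function(manifest) {
  cand <- setdiff(names(manifest),
                  c("subject_id", "group", "sex", "age",
                    "other_substance_months"))
  cand[vapply(manifest[cand], is.numeric, logical(1))]
}

#' Group comparisons of efficiency and cognition for a cohort
#'
#' Runs the study's statistical toolkit: pooled-variance t-tests on global
#' efficiency and each subnetwork efficiency, Kruskal-Wallis tests on each
#' cognitive score, and BH-FDR correction applied separately within the
#' efficiency family and the cognition family.
#'
#' @param efficiency_table Data frame from [cohort_efficiency()].
#' @param manifest Cohort manifest with `subject_id`, `group`, and score
#'   columns.
#' @param score_cols Names of the cognitive score columns; defaults to the
#'   manifest's `score_cols` attribute when present, otherwise to every
#'   numeric manifest column that is not an id, group, or standard
#'   demographic/covariate column.
#' @param welch Use Welch's t instead of pooled variance.
#' @return Data frame with one row per comparison: `variable`, `family`,
#'   `test`, `statistic`, `p_raw`, `p_fdr`, and per-group mean/SD/n.
#' @export
compare_cohort <- function(efficiency_table, manifest, score_cols = NULL,
                           welch = FALSE) {
  score_cols <- score_cols %||% attr(manifest, "score_cols") %||%
    default_score_cols(manifest)
  missing_ids <- setdiff(efficiency_table$subject_id, manifest$subject_id)
  if (length(missing_ids)) {
    stop("subjects missing from manifest: ", paste(missing_ids, collapse = ", "))
  }
  dat <- merge(efficiency_table, manifest, by = "subject_id")
  groups <- sort(unique(dat$group))
  if (length(groups) != 2L) stop("expected exactly 2 groups")
  split_var <- function(v) split(dat[[v]], dat$group)[groups]

  eff_cols <- setdiff(names(efficiency_table), "subject_id")
  one_row <- function(v, family, test) {
    g <- split_var(v)
    res <- if (test == "t") {
      r <- students_t(g[[1L]], g[[2L]], welch = welch)
      list(stat = r$statistic, p = r$p)
    } else {
      r <- kruskal_wallis(g)
      list(stat = r$statistic, p = r$p)
    }
    data.frame(
      variable = v, family = family,
      test = if (test == "t") "student_t" else "kruskal_wallis",
      statistic = res$stat, p_raw = res$p,
      mean_1 = mean(g[[1L]]), sd_1 = stats::sd(g[[1L]]), n_1 = length(g[[1L]]),
      mean_2 = mean(g[[2L]]), sd_2 = stats::sd(g[[2L]]), n_2 = length(g[[2L]]),
      stringsAsFactors = FALSE
    )
  }
  eff <- do.call(rbind, lapply(eff_cols, one_row, family = "efficiency",
                               test = "t"))
  eff$p_fdr <- bh_fdr(eff$p_raw)
  out <- eff
  if (length(score_cols)) {
    cog <- do.call(rbind, lapply(score_cols, one_row, family = "cognition",
                                 test = "kw"))
    cog$p_fdr <- bh_fdr(cog$p_raw)
    out <- rbind(eff, cog)
  }
  names(out) <- sub("_1$", paste0("_", groups[1L]), names(out))
  names(out) <- sub("_2$", paste0("_", groups[2L]), names(out))
  rownames(out) <- NULL
  out
}
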