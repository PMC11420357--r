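#' Compare one feature between two arms
#'
#' Continuous features: a normality check in both arms at alpha = 0.05
#' (Shapiro-Wilk up to n = 5000, Anderson-Darling above) gates the choice
#' between the unpaired t-test and the Mann-Whitney U test. Categorical
#' features: Fisher's exact test when any expected cell count of the 2 x 2
#' table is below 5, otherwise the chi-square test (no continuity
#' correction).
#'
#' @param values_a,values_b Feature values per arm (numeric; 0/1 for
#'   binary).
#' @param type `"continuous"` or `"binary"`.
#' @param feature Feature name carried into the result.
#' @return A one-row data frame `feature`, `test` (`t`, `mann_whitney`,
#'   `chi2`, `fisher`, or `skipped`), `statistic`, `p`, `reason` (non-empty
#'   only when skipped).
#' @export
compare_two_arms <- function(values_a, values_b, type, feature = "") {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  row <- function(test, statistic, p, reason = "") {
    data.frame(feature = feature, test = test, statistic = statistic,
               p = p, reason = reason, stringsAsFactors = FALSE)
  }
  if (type == "continuous") {
    if (normal_enough(values_a) && normal_enough(values_b)) {
      tt <- stats::t.test(values_a, values_b)
      row("t", unname(tt$statistic), tt$p.value)
    } else {
      wt <- stats::wilcox.test(values_a, values_b, exact = FALSE)
      row("mann_whitney", unname(wt$statistic), wt$p.value)
    }
  } else {
    tab <- rbind(
      c(sum(values_a == 1), sum(values_a == 0)),
      c(sum(values_b == 1), sum(values_b == 0))
    )
    if (any(colSums(tab) == 0)) {
      return(row("skipped", NA_real_, NA_real_,
                 "feature constant in both arms"))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      row("fisher", NA_real_, ft$p.value)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      row("chi2", unname(ct$statistic), ct$p.value)
    }
  }
}

# normality gate at alpha = 0.05; small samples (n < 8) default to the
# rank test by returning FALSE
normal_enough <- function(x, alpha = 0.05) {
  if (length(x) < 8) return(FALSE)
  if (stats::sd(x) == 0) return(FALSE)
  p <- if (length(x) <= 5000) {
    stats::shapiro.test(x)$p.value
  } else {
    nortest::ad.test(x)$p.value
  }
  p > alpha
}

#' Pairwise phenogroup comparisons of one feature
#'
#' Tests every unordered pair of phenogroups: the two-sample
#' Kolmogorov-Smirnov test for continuous features, chi-square or Fisher's
#' exact test (expected-count rule) for categorical ones. Raw p-values are
#' reported; no multiplicity correction is applied by default, with an
#' optional Holm adjustment.
#'
#' @param values_by_group List of per-group feature value vectors (names
#'   used as group labels).
#' @param type `"continuous"` or `"binary"`.
#' @param feature Feature name.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A data frame with one row per pair: `group_a`, `group_b`,
#'   `test`, `statistic`, `p`, `reason`.
#' @export
pairwise_phenogroup_tests <- function(values_by_group, type, feature = "",
                                      adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  labs <- names(values_by_group)
  if (is.null(labs)) labs <- as.character(seq_along(values_by_group))
  pairs <- utils::combn(seq_along(values_by_group), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    a <- values_by_group[[i]][!is.na(values_by_group[[i]])]
    b <- values_by_group[[j]][!is.na(values_by_group[[j]])]
    base <- data.frame(group_a = labs[i], group_b = labs[j],
                       stringsAsFactors = FALSE)
    if (type == "continuous") {
      if (length(a) < 2 || length(b) < 2) {
        return(cbind(base, test = "skipped", statistic = NA_real_,
                     p = NA_real_, reason = "group too small for KS"))
      }
      ks <- suppressWarnings(stats::ks.test(a, b))
      cbind(base, test = "ks", statistic = unname(ks$statistic),
            p = ks$p.value, reason = "")
    } else {
      cmp <- compare_two_arms(a, b, "binary", feature)
      cbind(base, test = cmp$test, statistic = cmp$statistic, p = cmp$p,
            reason = cmp$reason)
    }
  })
  out <- do.call(rbind, rows)
  out$feature <- feature
  if (adjust == "holm") out$p_adjusted <- stats::p.adjust(out$p, "holm")
  out
}

#' Baseline-table comparison of two arms across many features
#'
#' Emits one row per feature with per-arm summaries (mean and n) and the
#' [compare_two_arms()] test result, the layout of a clinical "Table 1".
#'
#' @param features A `feature_matrix`.
#' @param arm Character/logical vector splitting patients into two arms.
#' @return Data frame, one row per feature.
#' @export
baseline_table <- function(features, arm) {
  arms <- unique(arm)
  if (length(arms) != 2) stop("arm must define exactly two groups")
  rows <- lapply(seq_len(ncol(features$values)), function(j) {
    v <- features$values[, j]
    a <- v[arm == arms[1]]
    b <- v[arm == arms[2]]
    cmp <- compare_two_arms(a, b, features$feature_meta$type[j],
                            colnames(features$values)[j])
    data.frame(
      feature = colnames(features$values)[j],
      type = features$feature_meta$type[j],
      mean_a = mean(a, na.rm = TRUE), n_a = sum(!is.na(a)),
      mean_b = mean(b, na.rm = TRUE), n_b = sum(!is.na(b)),
      test = cmp$test, statistic = cmp$statistic, p = cmp$p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "arms") <- arms
  out
}
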