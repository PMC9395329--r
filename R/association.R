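# Association scans: rank tests for categorical phenotypes, Pearson for
# numeric pairs, chi-squared/Fisher for demographics, with Bonferroni or
# Benjamini-Hochberg correction. One scan (one phenotype against all
# features) is one multiple-testing family.

new_association_record <- function(feature, phenotype, test, statistic, p,
                                   group_sizes = NA) {
  data.frame(feature = feature, phenotype = phenotype, test = test,
             statistic = statistic, p = p,
             adjusted_p = NA_real_, correction = NA_character_,
             level = NA_real_, significant = NA,
             group_sizes = paste(group_sizes, collapse = "/"),
             stringsAsFactors = FALSE)
}

#' Rank-test scan of features against a categorical phenotype
#'
#' Two groups: two-sided Mann-Whitney (exact enumeration when both groups
#' have at most `exact_max` observations and no ties; otherwise the
#' continuity-corrected normal approximation with tie correction). More
#' than two groups: Kruskal-Wallis with tie correction. Features whose
#' grouping leaves any group with fewer than 2 samples are skipped with a
#' logged reason.
#'
#' @param features a `feature_table` (or data.frame with `sample_id`).
#' @param metadata cohort metadata with `dog_id` matching
#'   `features$sample_id`.
#' @param phenotype name of the categorical metadata column.
#' @param feature_cols which feature columns to scan (default: all numeric).
#' @param exact_max exact-enumeration cutoff per group (default 8).
#' @return An `association_table` data.frame of records (unadjusted);
#'   skipped features in `attr(, "skipped")`.
#' @export
rank_test_scan <- function(features, metadata, phenotype,
                           feature_cols = NULL, exact_max = 8) {
  d <- join_features_metadata(features, metadata)
  if (is.null(feature_cols)) feature_cols <- numeric_feature_cols(features)
  g_all <- d[[phenotype]]
  records <- list()
  skipped <- character()
  for (f in feature_cols) {
    x <- d[[f]]
    ok <- !is.na(x) & !is.na(g_all)
    x <- x[ok]
    g <- factor(g_all[ok])
    g <- droplevels(g)
    sizes <- table(g)
    if (nlevels(g) < 2 || any(sizes < 2)) {
      skipped <- c(skipped, sprintf(
        "%s: group with <2 samples for %s", f, phenotype))
      next
    }
    if (length(unique(x)) < 2) {
      skipped <- c(skipped, sprintf(
        "%s: zero variance against %s", f, phenotype))
      next
    }
    if (nlevels(g) == 2) {
      xs <- split(x, g)
      exact <- all(sizes <= exact_max) && !any(duplicated(x))
      wt <- suppressWarnings(stats::wilcox.test(
        xs[[1]], xs[[2]], exact = exact, correct = TRUE))
      rec <- new_association_record(f, phenotype, "mann_whitney",
                                    unname(wt$statistic), wt$p.value, sizes)
    } else {
      kt <- stats::kruskal.test(x, g)
      rec <- new_association_record(f, phenotype, "kruskal_wallis",
                                    unname(kt$statistic), kt$p.value, sizes)
    }
    records[[f]] <- rec
  }
  as_association_table(records, skipped)
}

#' Pearson-correlation scan of features against a numeric phenotype
#'
#' Two-sided p from the t transform with n-2 degrees of freedom. Features
#' with fewer than 3 complete pairs or zero variance on either side are
#' skipped with a logged reason.
#'
#' @inheritParams rank_test_scan
#' @param phenotype name of the numeric metadata column.
#' @return An `association_table` (statistic = Pearson r).
#' @export
pearson_scan <- function(features, metadata, phenotype,
                         feature_cols = NULL) {
  d <- join_features_metadata(features, metadata)
  if (is.null(feature_cols)) feature_cols <- numeric_feature_cols(features)
  y_all <- d[[phenotype]]
  records <- list()
  skipped <- character()
  for (f in feature_cols) {
    x <- d[[f]]
    ok <- !is.na(x) & !is.na(y_all)
    x <- x[ok]
    y <- y_all[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      skipped <- c(skipped, sprintf(
        "%s: <3 pairs or zero variance against %s", f, phenotype))
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    records[[f]] <- new_association_record(
      f, phenotype, "pearson", unname(ct$estimate), ct$p.value, length(x))
  }
  as_association_table(records, skipped)
}

#' Association between two categorical demographic variables
#'
#' Builds the contingency table on complete pairs; Fisher's exact test
#' (two-sided) is used when the table is 2x2 and any expected count is
#' below 5, otherwise chi-squared without continuity correction.
#'
#' @param metadata cohort metadata.
#' @param var_a,var_b categorical column names.
#' @return A one-row `association_table` record.
#' @export
categorical_test <- function(metadata, var_a, var_b) {
  a <- factor(metadata[[var_a]])
  b <- factor(metadata[[var_b]])
  ok <- !is.na(a) & !is.na(b)
  a <- droplevels(a[ok])
  b <- droplevels(b[ok])
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("categorical_test needs at least two levels in each variable")
  }
  tab <- table(a, b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2, 2)) && any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    rec <- new_association_record(var_a, var_b, "fisher_exact",
                                  NA_real_, ft$p.value, dim(tab))
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rec <- new_association_record(var_a, var_b, "chi_squared",
                                  unname(ct$statistic), ct$p.value, dim(tab))
  }
  as_association_table(list(rec), character())
}

#' Multiple-testing correction over one scan family
#'
#' Bonferroni (`adjusted_p = min(1, m * p)`) or Benjamini-Hochberg step-up
#' with monotonicity enforcement. Default level: 0.15 under Bonferroni and
#' for correlation-style scans (the study's stated level) — family-level
#' scans may use 0.05; both overridable.
#'
#' @param records an `association_table` (one family).
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @param level significance level applied to adjusted p (default 0.15).
#' @return The records with `adjusted_p`, `correction`, `level` and
#'   `significant` filled.
#' @export
adjust_pvalues <- function(records, method = c("bonferroni", "bh_fdr"),
                           level = 0.15) {
  method <- match.arg(method)
  if (nrow(records) == 0) stop("empty record list")
  adj <- stats::p.adjust(records$p,
                         method = if (method == "bonferroni") "bonferroni"
                                  else "BH")
  records$adjusted_p <- adj
  records$correction <- method
  records$level <- level
  records$significant <- adj <= level
  records
}

join_features_metadata <- function(features, metadata) {
  stopifnot("sample_id" %in% names(features))
  key <- if ("dog_id" %in% names(metadata)) "dog_id" else "sample_id"
  i <- match(features$sample_id, metadata[[key]])
  if (anyNA(i)) stop("feature table samples missing from metadata")
  cbind(features, metadata[i, setdiff(names(metadata), names(features)),
                           drop = FALSE])
}

numeric_feature_cols <- function(features) {
  cols <- setdiff(names(features), "sample_id")
  cols[vapply(features[cols], is.numeric, TRUE)]
}

as_association_table <- function(records, skipped) {
  out <- if (length(records) == 0) {
    data.frame(feature = character(), phenotype = character(),
               test = character(), statistic = numeric(), p = numeric(),
               adjusted_p = numeric(), correction = character(),
               level = numeric(), significant = logical(),
               group_sizes = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, records)
  }
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  attr(out, "skipped") <- skipped
  out
}
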