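## Behavioural network construction and group profiling statistics.

#' Build the subject-by-subject behavioural correlation network
#'
#' Edges are Pearson correlations across the six scale T-scores for every
#' pair of subjects. Subjects whose scores do not vary across the scales are
#' excluded (their correlation is undefined); optionally, subjects whose
#' Negative Impressions score exceeds a cutoff are excluded first, since an
#' overly negative rating bias distorts the correlations.
#'
#' @param table data.frame with `subject_id`, scale score columns, and
#'   optionally `negative_impressions`.
#' @param scales Character vector of scale column names (defaults to the six
#'   standard scales present in `table`).
#' @param niCutoff Optional Negative Impressions cutoff; subjects strictly
#'   above it are excluded.
#' @return A [SubjectNetwork-class] (diagonal zeroed) with the exclusion log.
#' @export
buildSubjectNetwork <- function(table, scales = NULL, niCutoff = NULL) {
  scales <- scales %||% intersect(SCALE_NAMES, names(table))
  if (length(scales) < 2L)
    stop("need at least two scale columns to correlate")
  if (anyDuplicated(table$subject_id))
    stop("subject ids must be unique")
  scores <- as.matrix(table[, scales, drop = FALSE])
  if (anyNA(scores)) stop("missing scale scores for included subjects")
  rownames(scores) <- table$subject_id
  excluded <- data.frame(subject_id = character(), reason = character())
  if (!is.null(niCutoff) && "negative_impressions" %in% names(table)) {
    drop <- table$negative_impressions > niCutoff
    excluded <- rbind(excluded, data.frame(
      subject_id = table$subject_id[drop],
      reason = rep("negative impressions", sum(drop))))
    scores <- scores[!drop, , drop = FALSE]
  }
  zv <- apply(scores, 1L, function(r) stats::sd(r) == 0)
  excluded <- rbind(excluded, data.frame(
    subject_id = rownames(scores)[zv],
    reason = rep("zero variance", sum(zv))))
  scores <- scores[!zv, , drop = FALSE]
  if (nrow(scores) < 3L)
    stop("fewer than 3 subjects with valid (non-constant) scores")
  m <- stats::cor(t(scores))
  diag(m) <- 0
  methods::new("SubjectNetwork", matrix = m, excluded = excluded)
}

#' Nonparametric group profiling statistics
#'
#' For every unordered pair of groups and every scale, a Mann-Whitney U test
#' (exact when both groups have at most `exactMax` observations and no ties;
#' otherwise the normal approximation with continuity and tie correction),
#' Bonferroni-corrected over all scale-by-pair tests run in the call.
#' Categorical characteristics are compared with chi-square tests on the
#' group-by-level frequency table; continuous characteristics with Welch
#' t-tests Bonferroni-corrected over pair-by-variable tests.
#'
#' @param table data.frame of per-subject scores (one row per subject).
#' @param groups Character/factor of group labels aligned with `table` rows
#'   (e.g. consensus communities merged with a comparison label).
#' @param scales Scale columns to test (default: the standard six present).
#' @param categorical Optional character vector of categorical columns.
#' @param continuous Optional character vector of continuous columns.
#' @param exactMax Largest group size for which the exact U distribution is
#'   used (default 8).
#' @return list with data.frames `scaleTests` (group1, group2, scale, U,
#'   p, pBonferroni), `categoricalTests` (variable, chisq, df, p), and
#'   `continuousTests` (group1, group2, variable, t, df, p, pBonferroni).
#' @export
profileGroupStats <- function(table, groups, scales = NULL,
                              categorical = NULL, continuous = NULL,
                              exactMax = 8L) {
  scales <- scales %||% intersect(SCALE_NAMES, names(table))
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(table))
  lv <- unique(groups)
  sizes <- table(groups)
  if (sum(sizes >= 2L) < 2L) stop("need at least 2 groups with >= 2 subjects")
  pairs <- utils::combn(lv, 2L, simplify = FALSE)

  scaleRows <- list()
  for (pr in pairs) {
    n1 <- sizes[[pr[1]]]; n2 <- sizes[[pr[2]]]
    if (n1 < 2L || n2 < 2L) {
      warning(sprintf("skipping pair %s vs %s: group with < 2 subjects",
                      pr[1], pr[2]))
      next
    }
    for (sc in scales) {
      x <- table[[sc]][groups == pr[1]]
      y <- table[[sc]][groups == pr[2]]
      useExact <- n1 <= exactMax && n2 <= exactMax &&
        !anyDuplicated(c(x, y))
      wt <- suppressWarnings(stats::wilcox.test(
        x, y, exact = useExact, correct = TRUE))
      scaleRows[[length(scaleRows) + 1L]] <- data.frame(
        group1 = pr[1], group2 = pr[2], scale = sc,
        U = unname(wt$statistic), p = wt$p.value)
    }
  }
  scaleTests <- do.call(rbind, scaleRows)
  if (!is.null(scaleTests))
    scaleTests$pBonferroni <- pmin(1, scaleTests$p * nrow(scaleTests))

  catRows <- lapply(categorical, function(v) {
    ct <- suppressWarnings(stats::chisq.test(table(groups, table[[v]]),
                                             correct = FALSE))
    data.frame(variable = v, chisq = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value)
  })
  categoricalTests <- if (length(catRows)) do.call(rbind, catRows) else NULL

  contRows <- list()
  for (pr in pairs) {
    for (v in continuous) {
      x <- table[[v]][groups == pr[1]]
      y <- table[[v]][groups == pr[2]]
      if (length(x) < 2L || length(y) < 2L) next
      tt <- stats::t.test(x, y)
      contRows[[length(contRows) + 1L]] <- data.frame(
        group1 = pr[1], group2 = pr[2], variable = v,
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
    }
  }
  continuousTests <- do.call(rbind, contRows)
  if (!is.null(continuousTests))
    continuousTests$pBonferroni <- pmin(1, continuousTests$p * nrow(continuousTests))

  list(scaleTests = scaleTests, categoricalTests = categoricalTests,
       continuousTests = continuousTests)
}
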