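#' Pair scores with gold-standard labels
#'
#' Flattens a score matrix into (score, label) pairs for ranking evaluation.
#' Only defined cells are kept. The orientation contract across the package:
#' *smaller* proximity values rank as *more* predicted-positive. Gold pairs
#' referencing unscored herbs/diseases are excluded with a message.
#'
#' @param scores A `score_matrix` from [score_all_pairs()].
#' @param gold A two-column data frame (herb, disease) of known-positive
#'   pairs, or any object coercible to one.
#' @return Data frame with columns `herb`, `disease`, `score`, `label`
#'   (logical; `TRUE` = known positive).
#' @export
label_and_orient <- function(scores, gold) {
  stopifnot(inherits(scores, "score_matrix"))
  gold <- as.data.frame(gold, stringsAsFactors = FALSE)
  if (ncol(gold) < 2) stop("gold standard needs herb and disease columns",
                           call. = FALSE)
  gold <- unique(data.frame(herb = as.character(gold[[1]]),
                            disease = as.character(gold[[2]]),
                            stringsAsFactors = FALSE))
  matched <- gold$herb %in% rownames(scores) &
    gold$disease %in% colnames(scores)
  if (any(!matched)) {
    message(sprintf("label_and_orient: %d gold pair(s) reference unscored entities; excluded",
                    sum(!matched)))
    gold <- gold[matched, , drop = FALSE]
  }
  pos <- matrix(FALSE, nrow(scores), ncol(scores),
                dimnames = dimnames(scores))
  pos[cbind(gold$herb, gold$disease)] <- TRUE

  keep <- !is.na(scores)
  out <- data.frame(
    herb = rep(rownames(scores), times = ncol(scores))[as.vector(keep)],
    disease = rep(colnames(scores), each = nrow(scores))[as.vector(keep)],
    score = as.vector(scores)[as.vector(keep)],
    label = as.vector(pos)[as.vector(keep)],
    stringsAsFactors = FALSE)
  if (nrow(out) == 0) stop("no defined cells to evaluate", call. = FALSE)
  if (!any(out$label)) stop("no matched positives in the gold standard",
                            call. = FALSE)
  out
}

#' Area under the ROC curve for low-is-positive scores
#'
#' Rank-based (Mann-Whitney) formulation: the probability that a randomly
#' chosen positive has a *lower* score than a randomly chosen negative, with
#' ties counted 1/2. Equivalent to trapezoidal integration of the ROC curve.
#'
#' @param scores Numeric vector (lower = stronger predicted association).
#' @param labels Logical (or 0/1) vector; `TRUE` = positive.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- as.numeric(sum(labels))  # doubles: n_pos * n_neg can pass 2^31
  n_neg <- as.numeric(sum(!labels))
  if (n_pos == 0 || n_neg == 0) {
    stop("auroc requires both positive and negative examples", call. = FALSE)
  }
  r <- rank(scores)  # midranks for ties
  # pairs (pos, neg) with pos ranked above (higher score than) the negative
  u_above <- sum(r[labels]) - n_pos * (n_pos + 1) / 2
  1 - u_above / (n_pos * n_neg)
}

#' ROC curve points
#'
#' One point per distinct score threshold, calling positive every item with
#' `score <= threshold`; a (0, 0, -Inf) anchor is prepended. Both
#' coordinates are monotone non-decreasing.
#'
#' @inheritParams auroc
#' @return Data frame with columns `fpr`, `tpr`, `threshold` (thresholds on
#'   the original score scale, increasing).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc requires both positive and negative examples", call. = FALSE)
  }
  ord <- order(scores)
  s <- scores[ord]
  l <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)  # block ends of tied scores
  data.frame(fpr = c(0, cumsum(!l)[last] / n_neg),
             tpr = c(0, cumsum(l)[last] / n_pos),
             threshold = c(-Inf, s[last]))
}

#' Area under the precision-recall curve
#'
#' Step-wise (rectangular) integration over ranked recall increments, the
#' average-precision convention; tied scores are handled as one block. The
#' chance-level baseline is `positives / total`, reported alongside by
#' [evaluate_predictions()].
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  if (n_pos == 0) stop("auprc requires at least one positive", call. = FALSE)
  ord <- order(scores)
  s <- scores[ord]
  l <- labels[ord]
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[last]
  n_called <- last
  recall <- tp / n_pos
  precision <- tp / n_called
  sum(diff(c(0, recall)) * precision)
}

#' AUROC within each herb's row or each disease's column
#'
#' An entity is evaluated only if its defined cells contain at least one
#' positive and at least one negative; others are omitted (AUROC would be
#' ill-defined) and the omission counts are reported in a message.
#'
#' @inheritParams label_and_orient
#' @param axis `"herb"` (per row) or `"disease"` (per column).
#' @return Named numeric vector of per-entity AUROCs.
#' @export
per_entity_auroc <- function(scores, gold, axis = c("herb", "disease")) {
  axis <- match.arg(axis)
  labeled <- label_and_orient(scores, gold)
  key <- if (axis == "herb") labeled$herb else labeled$disease
  groups <- split(labeled[c("score", "label")], key)
  ok <- vapply(groups, function(g) any(g$label) && any(!g$label), logical(1))
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    message(sprintf("per_entity_auroc: omitted %d %s(s) lacking a positive or a negative",
                    n_skip, axis))
  }
  vapply(groups[ok], function(g) auroc(g$score, g$label), numeric(1))
}

#' Correlation between per-entity AUROC and gold-partner count
#'
#' Pearson product-moment correlation (with the standard two-sided
#' t-distributed p-value) between each entity's AUROC and its number of
#' gold-standard partners, to diagnose whether prediction quality merely
#' tracks annotation richness.
#'
#' @param per_entity Named numeric vector from [per_entity_auroc()].
#' @param gold Gold-standard pair data frame (herb, disease).
#' @param axis `"herb"` or `"disease"`: which column of `gold` the names of
#'   `per_entity` refer to.
#' @return List with `r` and `p`; both `NA` (with a warning) when either
#'   variable has zero variance.
#' @export
auroc_vs_count_correlation <- function(per_entity, gold,
                                       axis = c("herb", "disease")) {
  axis <- match.arg(axis)
  if (length(per_entity) < 3) {
    stop("need at least 3 entities for a correlation", call. = FALSE)
  }
  gold <- as.data.frame(gold, stringsAsFactors = FALSE)
  id_col <- if (axis == "herb") 1L else 2L
  counts <- table(as.character(gold[[id_col]]))
  n_partners <- as.numeric(counts[names(per_entity)])
  n_partners[is.na(n_partners)] <- 0
  if (stats::sd(per_entity) == 0 || stats::sd(n_partners) == 0) {
    warning("zero variance on one axis; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(as.numeric(per_entity), n_partners,
                        method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Score threshold achieving a target false-positive rate
#'
#' Returns the largest original-scale score threshold whose achieved FPR does
#' not exceed `target_fpr` (conservative: the target is never exceeded), plus
#' the recall (TPR) attained there.
#'
#' @param roc Data frame from [roc_points()].
#' @param target_fpr Target false-positive rate in (0, 1\]; default 0.05.
#' @return List with `threshold`, `fpr` (achieved), `recall`.
#' @export
threshold_at_fpr <- function(roc, target_fpr = 0.05) {
  stopifnot(is.data.frame(roc), all(c("fpr", "tpr", "threshold") %in% names(roc)))
  if (!is.numeric(target_fpr) || length(target_fpr) != 1 ||
      target_fpr <= 0 || target_fpr > 1) {
    stop("target_fpr must lie in (0, 1]", call. = FALSE)
  }
  ok <- which(roc$fpr <= target_fpr)
  at <- ok[which.max(roc$threshold[ok])]
  list(threshold = roc$threshold[at], fpr = roc$fpr[at], recall = roc$tpr[at])
}

#' Global ranking evaluation report
#'
#' Convenience wrapper producing the global metrics for one score matrix:
#' AUROC, AUPRC with its chance baseline, and the ROC curve.
#'
#' @inheritParams label_and_orient
#' @return An `eval_report` list: `measure`, `auroc`, `auprc`,
#'   `baseline_auprc` (positives/defined cells), `n_pairs`, `n_positives`,
#'   `roc` (data frame).
#' @export
evaluate_predictions <- function(scores, gold) {
  labeled <- label_and_orient(scores, gold)
  structure(list(
    measure = attr(scores, "measure"),
    auroc = auroc(labeled$score, labeled$label),
    auprc = auprc(labeled$score, labeled$label),
    baseline_auprc = mean(labeled$label),
    n_pairs = nrow(labeled),
    n_positives = sum(labeled$label),
    roc = roc_points(labeled$score, labeled$label)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: AUROC %.3f, AUPRC %.4f (baseline %.4f), %d positives / %d pairs\n",
              x$measure %||% "?", x$auroc, x$auprc, x$baseline_auprc,
              x$n_positives, x$n_pairs))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report` from [evaluate_predictions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(measure = report$measure,
              auroc = report$auroc,
              auprc = report$auprc,
              baseline_auprc = report$baseline_auprc,
              n_pairs = report$n_pairs,
              n_positives = report$n_positives,
              roc = unname(as.matrix(report$roc)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Select herbs with reliable per-herb prediction performance
#'
#' A herb qualifies when (i) its per-herb AUROC exceeds `auroc_min`, (ii) it
#' has at least `min_known` known associated diseases with defined scores,
#' and (iii) *all* of those known-disease scores fall below `wacp_threshold`
#' (typically the FPR-anchored threshold from [threshold_at_fpr()]).
#'
#' @param per_herb_auroc Named vector from
#'   `per_entity_auroc(scores, gold, "herb")`.
#' @inheritParams label_and_orient
#' @param auroc_min Minimum per-herb AUROC (exclusive); default 0.9.
#' @param min_known Minimum number of known associated diseases; default 3.
#' @param wacp_threshold Score ceiling for all known associations.
#' @return Data frame (`herb`, `auroc`, `n_known`, `max_known_score`) sorted
#'   by AUROC descending, ties by herb id.
#' @export
select_reliable_herbs <- function(per_herb_auroc, scores, gold,
                                  auroc_min = 0.9, min_known = 3L,
                                  wacp_threshold) {
  stopifnot(inherits(scores, "score_matrix"))
  if (missing(wacp_threshold) || !is.numeric(wacp_threshold)) {
    stop("wacp_threshold must be supplied (see threshold_at_fpr)",
         call. = FALSE)
  }
  labeled <- label_and_orient(scores, gold)
  known <- labeled[labeled$label, , drop = FALSE]
  rows <- lapply(names(per_herb_auroc), function(h) {
    if (per_herb_auroc[[h]] <= auroc_min) return(NULL)
    ks <- known$score[known$herb == h]
    if (length(ks) < min_known || any(ks >= wacp_threshold)) return(NULL)
    data.frame(herb = h, auroc = per_herb_auroc[[h]],
               n_known = length(ks), max_known_score = max(ks),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(herb = character(0), auroc = numeric(0),
               n_known = integer(0), max_known_score = numeric(0),
               stringsAsFactors = FALSE))))
  out[order(-out$auroc, out$herb), , drop = FALSE]
}

#' Propose novel herb-disease associations
#'
#' For each supplied herb, proposes the diseases that are (i) not among its
#' gold-standard partners, (ii) scored *below the mean score of the herb's
#' known associated diseases* (i.e. predicted at least as proximal as its
#' established indications on average), and (iii) individually well-predicted:
#' the disease's own per-disease AUROC exceeds `disease_auroc_min` (typically
#' the mean per-disease AUROC of the current run).
#'
#' @inheritParams label_and_orient
#' @param per_disease_auroc Named vector from
#'   `per_entity_auroc(scores, gold, "disease")`.
#' @param herbs Character vector of herb ids (e.g. from
#'   [select_reliable_herbs()]); each must have at least one known disease
#'   with a defined score.
#' @param disease_auroc_min Per-disease AUROC floor (exclusive).
#' @return Data frame (`herb`, `disease`, `score`, `disease_auroc`,
#'   `mean_known_score`), sorted by herb then score; never contains
#'   gold-standard pairs.
#' @export
discover_novel <- function(scores, gold, per_disease_auroc, herbs,
                           disease_auroc_min) {
  stopifnot(inherits(scores, "score_matrix"))
  labeled <- label_and_orient(scores, gold)
  rows <- lapply(herbs, function(h) {
    cells <- labeled[labeled$herb == h, , drop = FALSE]
    ks <- cells$score[cells$label]
    if (length(ks) == 0) {
      stop(sprintf("herb %s has no known disease with a defined score", h),
           call. = FALSE)
    }
    cand <- cells[!cells$label & cells$score < mean(ks), , drop = FALSE]
    da <- per_disease_auroc[cand$disease]
    cand <- cand[!is.na(da) & da > disease_auroc_min, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    data.frame(herb = h, disease = cand$disease, score = cand$score,
               disease_auroc = unname(per_disease_auroc[cand$disease]),
               mean_known_score = mean(ks), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(herb = character(0), disease = character(0),
               score = numeric(0), disease_auroc = numeric(0),
               mean_known_score = numeric(0), stringsAsFactors = FALSE))))
  out[order(out$herb, out$score), , drop = FALSE]
}

#' Two-sided Wilcoxon rank-sum comparison of two score samples
#'
#' Used to ask whether a herb's known associated diseases score systematically
#' lower than the remaining diseases. Midrank tie handling; the exact null
#' distribution is used when both samples have at most 8 observations and no
#' ties, otherwise the tie-corrected normal approximation (no continuity
#' correction).
#'
#' @param known_scores,other_scores Non-empty numeric vectors.
#' @return List with `statistic` (the Mann-Whitney U of `known_scores`) and
#'   `p` (two-sided).
#' @export
rank_sum_compare <- function(known_scores, other_scores) {
  if (length(known_scores) == 0 || length(other_scores) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(known_scores, other_scores)) > 0
  exact <- length(known_scores) <= 8 && length(other_scores) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(known_scores, other_scores,
                       alternative = "two.sided",
                       exact = exact, correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
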