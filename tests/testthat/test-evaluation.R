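make_score_matrix <- function(m, measure = "WACP") {
  structure(m, measure = measure,
            n_herb_genes_used = stats::setNames(rep(1L, nrow(m)),
                                                rownames(m)),
            n_disease_genes_used = stats::setNames(rep(1L, ncol(m)),
                                                   colnames(m)),
            class = c("score_matrix", "matrix", "array"))
}

test_that("labeling flattens defined cells and matches gold pairs", {
  set.seed(4)
  m <- matrix(round(stats::runif(20), 3), 5, 4,
              dimnames = list(paste0("h", 1:5), paste0("d", 1:4)))
  sc <- make_score_matrix(m)
  gold <- data.frame(herb = c("h1", "h3", "h5"),
                     disease = c("d2", "d1", "d4"))
  lab <- label_and_orient(sc, gold)
  expect_equal(nrow(lab), 20L)
  expect_equal(sum(lab$label), 3L)
  expect_equal(lab$score[lab$herb == "h3" & lab$disease == "d1"], m["h3", "d1"])

  # gold pair for an unscored herb is excluded with a message
  expect_message(
    lab2 <- label_and_orient(sc, rbind(gold,
                                       data.frame(herb = "hX", disease = "d1"))),
    "1 gold pair")
  expect_equal(sum(lab2$label), 3L)

  # NA cells drop out of both numerator and denominator
  m_na <- m; m_na["h2", ] <- NA
  expect_equal(nrow(label_and_orient(make_score_matrix(m_na), gold)), 16L)
  expect_error(label_and_orient(sc, data.frame(herb = "hX", disease = "dX")),
               "no matched positives")
})

test_that("AUROC equals exhaustive pair counting with ties at one half", {
  expect_equal(auroc(c(0.5, 2.0), c(TRUE, FALSE)), 1.0)  # perfect separation
  expect_equal(auroc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)  # all ties
  set.seed(5)
  scores <- sample(round(stats::runif(30), 2))  # duplicates likely
  labels <- stats::runif(30) < 0.4
  labels[1] <- TRUE; labels[2] <- FALSE
  expect_equal(auroc(scores, labels), auroc_pairs_oracle(scores, labels))
  expect_error(auroc(scores, rep(TRUE, 30)), "both positive and negative")
})

test_that("AUROC is monotone-invariant and negation flips it", {
  set.seed(8)
  scores <- stats::rnorm(40)
  labels <- stats::runif(40) < 0.3
  labels[1:2] <- c(TRUE, FALSE)
  a <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), a)  # strictly monotone transform
  expect_equal(auroc(-scores, labels), 1 - a)
})

test_that("shuffled labels give chance-level AUROC", {
  set.seed(12)
  scores <- stats::rnorm(200)
  aucs <- replicate(20, {
    labels <- sample(rep(c(TRUE, FALSE), c(40, 160)))
    auroc(scores, labels)
  })
  se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-12)
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- stats::rnorm(60)
  labels <- stats::runif(60) < 0.35
  labels[1:2] <- c(TRUE, FALSE)
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                        predictor = scores,
                                        direction = ">", quiet = TRUE)))
  expect_equal(auroc(scores, labels), ref)
})

test_that("AUPRC uses step-wise integration and sits above baseline for good rankings", {
  # perfect ranking: 2 positives scored lowest of 10
  scores <- 1:10
  labels <- c(TRUE, TRUE, rep(FALSE, 8))
  expect_equal(auprc(scores, labels), 1.0)
  set.seed(9)
  s <- stats::rnorm(40)
  l <- stats::runif(40) < 0.3
  l[1:2] <- c(TRUE, FALSE)
  expect_equal(auprc(s, l), auprc_step_oracle(s, l))
  # tied blocks handled identically to the oracle
  s_tied <- round(s, 1)
  expect_equal(auprc(s_tied, l), auprc_step_oracle(s_tied, l))
  # planted signal: positives shifted low -> AUPRC beats the baseline
  s2 <- c(stats::rnorm(10, -2), stats::rnorm(90))
  l2 <- rep(c(TRUE, FALSE), c(10, 90))
  expect_gt(auprc(s2, l2), mean(l2))
  expect_error(auprc(1:5, rep(FALSE, 5)), "positive")
})

test_that("per-entity AUROC equals the global metric on that entity's slice", {
  set.seed(21)
  m <- matrix(stats::rnorm(200), 20, 10,
              dimnames = list(sprintf("h%02d", 1:20), sprintf("d%02d", 1:10)))
  sc <- make_score_matrix(m)
  gold <- unique(data.frame(
    herb = sprintf("h%02d", sample(20, 30, replace = TRUE)),
    disease = sprintf("d%02d", sample(10, 30, replace = TRUE))))
  per_herb <- per_entity_auroc(sc, gold, "herb")
  for (h in names(per_herb)) {
    lab <- label_and_orient(sc, gold)
    lab <- lab[lab$herb == h, ]
    expect_equal(per_herb[[h]], auroc(lab$score, lab$label))
  }
  # herbs with no gold partner (or no negative) are omitted
  expect_true(all(names(per_herb) %in% unique(gold$herb)))
  gold_one <- data.frame(herb = "h01", disease = "d01")
  suppressMessages(ph <- per_entity_auroc(sc, gold_one, "herb"))
  expect_named(ph, "h01")
})

test_that("AUROC-count correlation reproduces the covariance formula", {
  expect_equal(
    auroc_vs_count_correlation(
      stats::setNames(c(0.1, 0.2, 0.3), c("a", "b", "c")),
      data.frame(herb = c("a", "b", "b", "c", "c", "c"),
                 disease = paste0("d", 1:6)),
      "herb")$r,
    1.0)
  expect_warning(
    flat <- auroc_vs_count_correlation(
      stats::setNames(rep(0.5, 4), letters[1:4]),
      data.frame(herb = letters[1:4], disease = paste0("d", 1:4)), "herb"),
    "zero variance")
  expect_true(is.na(flat$r))

  set.seed(2)
  ent <- sprintf("e%02d", 1:50)
  aurocs <- stats::setNames(stats::runif(50), ent)
  counts <- sample(1:6, 50, replace = TRUE)
  gold <- data.frame(herb = rep(ent, counts),
                     disease = paste0("d", seq_len(sum(counts))))
  got <- auroc_vs_count_correlation(aurocs, gold, "herb")
  x <- as.numeric(aurocs); y <- counts
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_direct * sqrt(48 / (1 - r_direct^2))
  expect_equal(got$r, r_direct)
  expect_equal(got$p, 2 * stats::pt(-abs(t_stat), df = 48))
})

test_that("FPR-anchored thresholds never exceed the target rate", {
  # negatives at 1..20, one positive at 0.5: threshold 1 gives FPR exactly 5%
  scores <- c(0.5, 1:20)
  labels <- c(TRUE, rep(FALSE, 20))
  roc <- roc_points(scores, labels)
  got <- threshold_at_fpr(roc, 0.05)
  expect_equal(got$threshold, 1)
  expect_equal(got$fpr, 0.05)
  expect_equal(got$recall, 1)
  expect_equal(threshold_at_fpr(roc, 1.0)$threshold, 20)
  expect_error(threshold_at_fpr(roc, 0), "\\(0, 1\\]")
  expect_error(threshold_at_fpr(roc, 1.2), "\\(0, 1\\]")

  set.seed(17)
  s <- stats::rnorm(200)
  l <- stats::runif(200) < 0.25
  l[1:2] <- c(TRUE, FALSE)
  roc2 <- roc_points(s, l)
  for (target in c(0.01, 0.05, 0.2, 0.5)) {
    got <- threshold_at_fpr(roc2, target)
    neg <- s[!l]
    achieved <- mean(neg <= got$threshold)
    expect_lte(achieved, target)
    # exhaustive scan: no larger threshold keeps FPR within target
    better <- sort(unique(s[s > got$threshold]))
    if (length(better) > 0) {
      expect_true(all(vapply(better, function(t) mean(neg <= t) > target,
                             logical(1))))
    }
    expect_equal(got$fpr, achieved)
  }
})

test_that("ROC points are monotone and anchored at the origin", {
  set.seed(6)
  s <- round(stats::rnorm(60), 1)
  l <- stats::runif(60) < 0.4
  l[1:2] <- c(TRUE, FALSE)
  roc <- roc_points(s, l)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
})

test_that("reliable-herb selection applies all three rules", {
  # engineer 15 herbs, exactly 2 satisfying auroc > 0.9, >= 3 known, all
  # known scores below threshold
  herbs <- sprintf("h%02d", 1:15)
  diseases <- sprintf("d%02d", 1:8)
  set.seed(40)
  m <- matrix(stats::runif(120, 2, 4), 15, 8,
              dimnames = list(herbs, diseases))
  gold <- data.frame(herb = rep(c("h01", "h02", "h03", "h04"), each = 3),
                     disease = rep(c("d01", "d02", "d03"), 4))
  m[cbind(gold$herb, gold$disease)] <- 0.5   # known pairs score best
  m["h03", "d02"] <- 3.5                     # violates the threshold rule
  m["h04", c("d05", "d06", "d07", "d08")] <- 0.1  # non-gold outrank knowns
  gold <- rbind(gold, data.frame(herb = "h05", disease = "d01"))
  m["h05", "d01"] <- 0.5                     # high AUROC but only 1 known
  sc <- make_score_matrix(m)
  per_herb <- per_entity_auroc(sc, gold, "herb")
  sel <- select_reliable_herbs(per_herb, sc, gold, auroc_min = 0.9,
                               min_known = 3, wacp_threshold = 1.0)
  expect_equal(sel$herb, c("h01", "h02"))
  expect_true(all(sel$auroc > 0.9))
  expect_true(all(sel$n_known >= 3))
  expect_error(select_reliable_herbs(per_herb, sc, gold), "wacp_threshold")
})

test_that("novel discovery applies both rules and equals a brute-force filter", {
  herbs <- sprintf("h%02d", 1:6)
  diseases <- sprintf("d%02d", 1:6)
  set.seed(31)
  m <- matrix(stats::runif(36, 0.5, 3), 6, 6,
              dimnames = list(herbs, diseases))
  gold <- data.frame(herb = c("h01", "h01", "h02", "h03", "h04", "h05", "h06"),
                     disease = c("d01", "d02", "d01", "d03", "d04", "d05",
                                 "d06"))
  m[cbind(gold$herb, gold$disease)] <- c(1.0, 2.0, 0.8, 0.9, 1.1, 0.7, 0.9)
  sc <- make_score_matrix(m)
  per_disease <- suppressMessages(per_entity_auroc(sc, gold, "disease"))
  dmin <- mean(per_disease)
  got <- discover_novel(sc, gold, per_disease, c("h01", "h02"), dmin)

  # independent exhaustive filter over all cells
  gold_key <- paste(gold$herb, gold$disease)
  expected <- list()
  for (h in c("h01", "h02")) {
    known_mean <- mean(m[h, gold$disease[gold$herb == h]])
    for (d in diseases) {
      if (paste(h, d) %in% gold_key) next
      if (!(d %in% names(per_disease))) next
      if (m[h, d] < known_mean && per_disease[[d]] > dmin) {
        expected[[length(expected) + 1]] <- c(h, d)
      }
    }
  }
  expect_equal(nrow(got), length(expected))
  if (length(expected) > 0) {
    exp_df <- do.call(rbind, expected)
    expect_setequal(paste(got$herb, got$disease),
                    paste(exp_df[, 1], exp_df[, 2]))
  }
  # no candidate is ever a gold pair
  expect_false(any(paste(got$herb, got$disease) %in% gold_key))
  # a disease below the AUROC floor is excluded even if proximal
  got_hi <- discover_novel(sc, gold, per_disease, c("h01", "h02"),
                           disease_auroc_min = 1)
  expect_equal(nrow(got_hi), 0L)
})

test_that("rank-sum comparison is exact for small samples", {
  same <- rank_sum_compare(c(1, 2), c(1, 2))
  expect_equal(same$p, 1.0)
  expect_equal(same$statistic, 2)  # null mean of U for n=m=2

  sep <- rank_sum_compare(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(sep$p, 2 / 70)

  # enumerate all C(8,4)=70 assignments of ranks to the first sample
  u_obs <- sep$statistic
  ranks <- utils::combn(8, 4)
  u_all <- apply(ranks, 2, function(r) sum(r) - 4 * 5 / 2)
  p_enum <- 2 * sum(u_all <= u_obs) / ncol(ranks)
  expect_equal(sep$p, p_enum)
  expect_error(rank_sum_compare(numeric(0), 1), "nonempty")
})

test_that("rank-sum normal approximation agrees with permutation resampling", {
  set.seed(41)
  known <- stats::rnorm(4, mean = -1.5)
  other <- stats::rnorm(331)
  got <- rank_sum_compare(known, other)

  pooled <- c(known, other)
  r <- rank(pooled)
  u_obs <- sum(r[1:4]) - 4 * 5 / 2
  u_null_mean <- 4 * 331 / 2
  perm <- replicate(1e5, {
    idx <- sample.int(335, 4)
    sum(r[idx]) - 4 * 5 / 2
  })
  # two-sided by symmetry of U around its null mean
  p_perm <- mean(abs(perm - u_null_mean) >= abs(u_obs - u_null_mean))
  mc_se <- sqrt(p_perm * (1 - p_perm) / 1e5)
  expect_lt(abs(got$p - p_perm), max(4 * mc_se, 0.002))
})

test_that("evaluation reports serialize completely", {
  set.seed(50)
  m <- matrix(stats::runif(30), 5, 6,
              dimnames = list(paste0("h", 1:5), paste0("d", 1:6)))
  sc <- make_score_matrix(m)
  gold <- data.frame(herb = c("h1", "h2"), disease = c("d1", "d2"))
  rep <- evaluate_predictions(sc, gold)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$baseline_auprc, 2 / 30)
  expect_equal(rep$n_pairs, 30L)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$auroc, rep$auroc)
  expect_equal(back$baseline_auprc, rep$baseline_auprc)
  expect_equal(nrow(back$roc), nrow(rep$roc))
})
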