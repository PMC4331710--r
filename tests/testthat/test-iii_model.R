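test_that("logit_score is the plain linear predictor", {
  expect_equal(logit_score(c(0, 0, 0), c(0.3, 2)), 0)
  expect_equal(plogis(logit_score(c(0, 0, 0), c(0.3, 2))), 0.5)
  expect_equal(logit_score(c(1, 0, 0), c(0, 0)), 1)
  set.seed(30)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    beta <- rnorm(k + 1)
    x <- rnorm(k)
    manual <- beta[1]
    for (j in seq_len(k)) manual <- manual + beta[j + 1] * x[j]
    expect_equal(logit_score(beta, x), manual, tolerance = 1e-12)
  }
  expect_error(logit_score(c(1, 2, 3), c(1, 2, 3)),
               class = "iii_contract_error")
})

test_that("fit_logistic handles separable data and rejects bad input", {
  set.seed(31)
  x <- matrix(c(runif(40, 0, 0.3), runif(40, 0.7, 1)), ncol = 2,
              byrow = FALSE)
  x <- rbind(x[1:20, , drop = FALSE] * 0.2, x[21:40, , drop = FALSE])
  colnames(x) <- c("E1", "ddi")
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic(x, y, ridge = 0.01)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(fit$converged)
  acc <- mean((logit_score(fit, x) > 0) == y)
  expect_equal(acc, 1.0)

  expect_error(fit_logistic(x, rep(1, 40)), class = "iii_contract_error")
  expect_error(fit_logistic(x, y[-1]), class = "iii_contract_error")
})

test_that("slopes shrink to zero under permuted labels and large ridge", {
  sim <- simulate_logistic_pairs(600, alpha0 = -1, alpha_corr = rep(1.5, 3),
                                 alpha_ddi = 0.7, seed = 32L)
  set.seed(33)
  y_perm <- sample(sim$labels)
  fit <- fit_logistic(sim$features, y_perm, ridge = 1e6)
  slopes <- fit$coefficients[-1]
  expect_true(all(abs(slopes) < 1e-3))
})

test_that("coefficients are recovered within 3 SE on model-generated data", {
  truth <- c(-3, rep(2, 5), 0.8)
  sim <- simulate_logistic_pairs(5000, alpha0 = -3, alpha_corr = rep(2, 5),
                                 alpha_ddi = 0.8, seed = 34L)
  fit <- fit_logistic(sim$features, sim$labels)
  expect_true(all(abs(fit$coefficients - truth) <= 3 * fit$se))
  # estimates tighten with n: compare mean absolute error at two sizes
  sim_small <- simulate_logistic_pairs(500, alpha0 = -3,
                                       alpha_corr = rep(2, 5),
                                       alpha_ddi = 0.8, seed = 35L)
  fit_small <- fit_logistic(sim_small$features, sim_small$labels)
  expect_lt(mean(abs(fit$coefficients - truth)),
            mean(abs(fit_small$coefficients - truth)))
})

test_that("precision_recall_curve matches brute-force confusion counting", {
  curve <- precision_recall_curve(c(3, 2, 1), c(1, 1, 0))
  at <- function(thr) curve[curve$threshold == thr, ]
  expect_equal(at(1)$precision, 1.0)   # t just below 2 == t at distinct score 1
  expect_equal(at(1)$recall, 1.0)

  all_pos <- precision_recall_curve(c(1, 2, 3), c(1, 1, 1))
  expect_true(all(is.na(all_pos$precision) | all_pos$precision == 1))

  set.seed(36)
  scores <- round(rnorm(100), 1)  # ties guaranteed
  labels <- rbinom(100, 1, 0.4)
  curve <- precision_recall_curve(scores, labels)
  expect_true(all(diff(curve$threshold) > 0))
  expect_true(all(diff(curve$recall) <= 0))
  for (i in seq_len(nrow(curve))) {
    want <- oracle_pr_at(scores, labels, curve$threshold[i])
    expect_equal(curve$precision[i], want$precision, tolerance = 1e-12)
    expect_equal(curve$recall[i], want$recall, tolerance = 1e-12)
  }
  expect_error(precision_recall_curve(scores, rep(0, 100)),
               class = "iii_contract_error")
})

test_that("threshold_for_operating_point equals a full scan of the knots", {
  set.seed(37)
  for (rep in 1:30) {
    scores <- rnorm(60)
    labels <- rbinom(60, 1, 0.5)
    if (sum(labels) == 0) labels[1] <- 1
    curve <- precision_recall_curve(scores, labels)
    target <- runif(1, 0, 1)
    ok <- !is.na(curve$precision) & curve$precision >= target
    if (!any(ok)) {
      expect_error(threshold_for_operating_point(curve, target),
                   "unattainable")
      next
    }
    # oracle: scan every knot, keep qualifying threshold with best recall
    best_thr <- NA; best_rec <- -1
    for (i in seq_len(nrow(curve))) {
      if (is.na(curve$precision[i]) || curve$precision[i] < target) next
      if (curve$recall[i] > best_rec ||
          (curve$recall[i] == best_rec && curve$threshold[i] < best_thr)) {
        best_rec <- curve$recall[i]; best_thr <- curve$threshold[i]
      }
    }
    expect_equal(threshold_for_operating_point(curve, target), best_thr)
  }
  # target 0 -> minimum threshold
  curve <- precision_recall_curve(c(1, 2, 3), c(0, 1, 1))
  expect_equal(threshold_for_operating_point(curve, 0), -Inf)
})

test_that("predict_iii applies tier rules, rescue and strict thresholds", {
  cat <- new_catalog(c("A1", "A2", "B1", "C1"), c("GA", "GA", "GB", "GC"))
  ppi <- new_ppi(c("GA", "GA"), c("GB", "GC"),
                 timestamp = as.Date("2012-01-01"))
  ddi <- new_ddi("PFX", "PFY", "high")
  d1 <- rand_expression(c("A1", "A2", "B1", "C1"), "d1", 10, seed = 40)
  cand <- candidate_pairs(ppi, cat)
  expect_equal(nrow(cand), 4)  # A1/A2 x B1, A1/A2 x C1
  fv <- build_feature_vectors(cand, list(d1), cat, ddi)
  # coefficients chosen so scores are known: score = 10 * |r_d1| - 1
  beta <- c(-1, 10, 0)
  sc <- logit_score(beta, fv)
  preds <- predict_iii(fv, beta, ppi, cat,
                       thresholds = c(high = max(sc) - 1e-9,
                                      low = stats::median(sc)))
  # exactly one high (the top pair), strict > excludes scores == threshold
  expect_equal(sum(preds$tier == "high"), 1)
  # every PPI retains at least one prediction
  for (g in unique(paste(cand$gene_a, cand$gene_b)))
    expect_true(g %in% paste(preds$gene_a, preds$gene_b))

  # a PPI whose best pair scores below the low threshold is rescued
  low_preds <- predict_iii(fv, c(-10, 0, 0), ppi, cat,
                           thresholds = c(high = 2.575, low = 1.692))
  expect_true(all(low_preds$tier == "rescued"))
  expect_equal(nrow(low_preds), 2)  # one per PPI
  expect_equal(low_preds$logit_score, rep(-10, 2))

  # candidate universe enforcement
  rogue <- build_feature_vectors(
    data.frame(isoform_a = "A1", isoform_b = "A2"), list(d1), cat, ddi)
  expect_error(predict_iii(rogue, beta, ppi, cat),
               class = "iii_contract_error")
})

test_that("predict_iii matches brute-force tier rules on random worlds", {
  for (seed in c(501L, 502L)) {
    w <- small_world(seed)
    cand <- candidate_pairs(w$ppi, w$catalog)
    fv <- build_feature_vectors(cand, w$datasets, w$catalog, w$ddi)
    set.seed(seed)
    beta <- rnorm(ncol(iiinet:::feature_matrix(fv)) + 1)
    thr <- c(high = 1.0, low = -0.5)
    preds <- predict_iii(fv, beta, w$ppi, w$catalog, thresholds = thr)
    sc <- logit_score(beta, fv)

    # oracle: apply the three rules pair by pair
    want_tier <- rep(NA_character_, nrow(cand))
    want_tier[sc > thr["low"]] <- "low"
    want_tier[sc > thr["high"]] <- "high"
    for (g in unique(paste(cand$gene_a, cand$gene_b, sep = "|"))) {
      rows <- which(paste(cand$gene_a, cand$gene_b, sep = "|") == g)
      top <- rows[order(-sc[rows], cand$isoform_a[rows],
                        cand$isoform_b[rows])][1]
      if (is.na(want_tier[top])) want_tier[top] <- "rescued"
    }
    got <- merge(cand, as.data.frame(preds)[, c("isoform_a", "isoform_b",
                                                "tier")],
                 by = c("isoform_a", "isoform_b"), all.x = TRUE)
    got <- got[order(got$isoform_a, got$isoform_b), ]
    ref <- data.frame(isoform_a = cand$isoform_a, isoform_b = cand$isoform_b,
                      tier = want_tier)
    ref <- ref[order(ref$isoform_a, ref$isoform_b), ]
    expect_identical(got$tier, ref$tier)
    # rescue guarantee & tier nesting
    expect_true(all(paste(cand$gene_a, cand$gene_b) %in%
                      paste(preds$gene_a, preds$gene_b)))
    expect_true(all(preds$logit_score[preds$tier == "high"] >
                      thr["high"]))
    expect_true(all(preds$logit_score[preds$tier == "low"] <= thr["high"] &
                      preds$logit_score[preds$tier == "low"] > thr["low"]))
    # enumeration-order invariance
    perm <- fv[sample(nrow(fv)), , drop = FALSE]
    attr(perm, "dataset_ids") <- attr(fv, "dataset_ids")
    class(perm) <- class(fv)
    preds2 <- predict_iii(perm, beta, w$ppi, w$catalog, thresholds = thr)
    expect_identical(as.data.frame(preds), as.data.frame(preds2))
  }
})

test_that("evaluate_on_test orders precision across thresholds on planted signal", {
  w <- small_world(503L)
  gold <- build_gold_standard(w$ppi, w$catalog, w$localization)
  gp <- rbind(gold$positives_train[, 1:2], gold$positives_test[, 1:2],
              gold$negatives)
  gf <- build_feature_vectors(gp, w$datasets, w$catalog, w$ddi)
  ntr <- nrow(gold$positives_train); nte <- nrow(gold$positives_test)
  idx <- c(seq_len(ntr), ntr + nte + seq_len(nrow(gold$negatives)))
  fit <- fit_logistic(gf[idx, , drop = FALSE],
                      c(rep(1, ntr), rep(0, nrow(gold$negatives))))
  ev <- evaluate_on_test(fit, gf, gold)
  op <- ev$operating_points
  expect_gte(op$precision[op$tier == "high"],
             op$precision[op$tier == "low"] - 1e-12)
  expect_gte(op$recall[op$tier == "low"], op$recall[op$tier == "high"])
  expect_s3_class(ev$curve, "iii_pr_curve")
})

test_that("null-world test precision approximates prevalence", {
  # labels independent of scores: precision at any threshold ~ prevalence
  set.seed(44)
  scores <- rnorm(4000)
  labels <- rbinom(4000, 1, 0.3)
  curve <- precision_recall_curve(scores, labels)
  mid <- curve[curve$recall > 0.2 & curve$recall < 0.8, ]
  # binomial error bound at the sparsest point in the window
  n_min <- ceiling(sum(labels) * 0.2)
  expect_true(all(abs(mid$precision - 0.3) < 4 * sqrt(0.3 * 0.7 / n_min)))
})
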