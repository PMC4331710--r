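# The 21-coefficient logistic regression (intercept + one coefficient per
# expression dataset + one for the DDI score), precision-recall machinery,
# and tiered prediction with the best-pair-per-PPI rescue rule.

#' Fit the isoform-interaction logistic regression
#'
#' Maximizes the Bernoulli log-likelihood of
#' `logit(y) = a0 + sum_k a_k E_k + a_ddi DDI`
#' by iteratively reweighted least squares, with a small ridge penalty on the
#' slope coefficients (not the intercept) for numerical stability under
#' separation. Missing correlation entries are imputed as 0 (no co-expression
#' evidence) before fitting.
#'
#' @param features an `iii_features` data frame, or a numeric matrix whose
#'   columns are the model features in order (E1..EK, ddi).
#' @param labels binary vector (1 = interacting) of length `nrow(features)`.
#' @param ridge non-negative ridge penalty on slopes; default `1e-6`.
#' @param tol convergence tolerance on the max-norm of the penalized score
#'   (gradient); default `1e-8`.
#' @param max_iter iteration cap; default 100.
#' @return Object of class `iii_logit`: list with named `coefficients`
#'   (`(Intercept)`, one per dataset, `ddi`), `se` (from the observed
#'   information), `converged`, `iterations`, `ridge`, `dataset_ids`.
#' @export
fit_logistic <- function(features, labels, ridge = 1e-6, tol = 1e-8,
                         max_iter = 100L) {
  if (inherits(features, "iii_features")) {
    ds <- attr(features, "dataset_ids")
    x <- feature_matrix(features)
  } else {
    x <- as.matrix(features)
    x[is.na(x)] <- 0
    ds <- colnames(x)[-ncol(x)]
  }
  y <- as.numeric(labels)
  if (length(y) != nrow(x))
    contract_error("fit_logistic: %d labels for %d feature rows",
                   length(y), nrow(x))
  if (!all(y %in% c(0, 1)))
    contract_error("fit_logistic: labels must be binary")
  if (length(unique(y)) < 2)
    contract_error("fit_logistic: need both classes in the labels")
  if (ridge < 0) contract_error("fit_logistic: ridge must be non-negative")

  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  pen <- c(0, rep(ridge, p - 1L))
  beta <- numeric(p)
  converged <- FALSE
  iter <- 0L
  gnorm <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    gnorm <- max(abs(grad))
    if (gnorm < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(pen, p)
    step <- solve(H, grad)
    # halve the step while it worsens the penalized log-likelihood
    ll <- function(b) {
      e <- drop(X %*% b)
      sum(y * e - log1p(exp(e))) - sum(pen * b^2) / 2
    }
    ll0 <- ll(beta)
    lambda <- 1
    while (ll(beta + lambda * step) < ll0 && lambda > 1e-8) lambda <- lambda / 2
    beta <- beta + lambda * step
  }
  if (!converged) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    gnorm <- max(abs(drop(crossprod(X, y - mu)) - pen * beta))
    if (gnorm >= tol)
      stop(sprintf(
        "fit_logistic: no convergence after %d iterations (gradient norm %.3g)",
        max_iter, gnorm))
    converged <- TRUE
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * w, X) + diag(pen, p)
  se <- sqrt(diag(solve(info)))
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  structure(list(coefficients = beta, se = se, converged = converged,
                 iterations = iter, ridge = ridge, dataset_ids = ds),
            class = "iii_logit")
}

#' @export
print.iii_logit <- function(x, ...) {
  cat(sprintf("iii_logit: %d coefficients, converged in %d iterations\n",
              length(x$coefficients), x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Linear predictor (logit score) for feature vectors
#'
#' @param fit an `iii_logit`, or a bare named coefficient vector ordered
#'   `(Intercept)`, E1..EK, ddi.
#' @param features an `iii_features` data frame or numeric matrix/vector of
#'   features in model order.
#' @return Numeric vector of logit scores; the interaction probability is
#'   `plogis(score)`.
#' @export
logit_score <- function(fit, features) {
  beta <- if (inherits(fit, "iii_logit")) fit$coefficients else fit
  if (inherits(features, "iii_features")) {
    m <- feature_matrix(features)
  } else if (is.matrix(features)) {
    m <- features
    m[is.na(m)] <- 0
  } else {
    m <- matrix(features, nrow = 1)
    m[is.na(m)] <- 0
  }
  if (ncol(m) != length(beta) - 1L)
    contract_error("logit_score: %d features for %d slope coefficients",
                   ncol(m), length(beta) - 1L)
  drop(beta[1] + m %*% beta[-1])
}

#' Precision-recall curve with strict-greater thresholding
#'
#' At every threshold `t`, the predicted positives are the items with
#' `score > t` (strict, matching the tier rules). Thresholds are `-Inf`
#' followed by every distinct score, in increasing order; at the largest score
#' no item is predicted positive and precision is undefined (`NA`).
#'
#' @param scores numeric vector.
#' @param labels binary vector; at least one positive required.
#' @return Data frame of class `iii_pr_curve` with columns `threshold`,
#'   `precision`, `recall`.
#' @export
precision_recall_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    contract_error("precision_recall_curve: length mismatch")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L)
    contract_error("precision_recall_curve: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp_cum <- cumsum(l)
  # with s sorted decreasing, the items with score > s[i] are exactly those
  # ranked before the first occurrence of s[i]
  first_of_run <- which(!duplicated(s))
  thr <- s[first_of_run]             # decreasing distinct scores
  pred <- first_of_run - 1L
  tp <- ifelse(pred > 0, tp_cum[pmax(pred, 1L)], 0L)
  precision <- ifelse(pred > 0, tp / pred, NA_real_)
  recall <- tp / n_pos
  out <- data.frame(threshold = c(-Inf, rev(thr)),
                    precision = c(n_pos / length(l), rev(precision)),
                    recall = c(1, rev(recall)))
  rownames(out) <- NULL
  class(out) <- c("iii_pr_curve", "data.frame")
  out
}

#' Threshold attaining a target precision with maximal recall
#'
#' Scans the precision-recall curve for the smallest threshold whose precision
#' meets the target; because recall is non-increasing in the threshold, the
#' smallest qualifying threshold maximizes recall subject to the precision
#' constraint.
#'
#' @param curve an `iii_pr_curve`.
#' @param target_precision required precision in `[0, 1]`.
#' @return The threshold (numeric scalar).
#' @export
threshold_for_operating_point <- function(curve, target_precision) {
  ok <- !is.na(curve$precision) & curve$precision >= target_precision
  if (!any(ok)) {
    mx <- max(curve$precision, na.rm = TRUE)
    stop(sprintf(
      "target precision %.4g unattainable; maximum achievable is %.4g",
      target_precision, mx))
  }
  min(curve$threshold[ok])
}

#' Enumerate candidate isoform pairs from gene-level PPIs
#'
#' The candidate universe of the predictor: for every distinct gene-level PPI,
#' the full cross product of the two genes' isoforms (the PPI-confirmation
#' filter applied up front). Homodimer PPIs contribute all unordered isoform
#' pairs of the gene, including isoform self-pairs.
#'
#' @param ppi an `iii_ppi` table.
#' @param catalog an `iii_catalog`.
#' @return Data frame with columns `isoform_a`, `isoform_b`, `gene_a`,
#'   `gene_b`, canonical and duplicate-free.
#' @export
candidate_pairs <- function(ppi, catalog) {
  gp <- unique(data.frame(gene_a = ppi$gene_a, gene_b = ppi$gene_b,
                          stringsAsFactors = FALSE))
  res <- vector("list", nrow(gp))
  for (i in seq_len(nrow(gp))) {
    ia <- isoforms_of_gene(catalog, gp$gene_a[i])
    ib <- isoforms_of_gene(catalog, gp$gene_b[i])
    if (length(ia) == 0 || length(ib) == 0) next
    grid <- expand.grid(a = ia, b = ib, stringsAsFactors = FALSE)
    if (gp$gene_a[i] == gp$gene_b[i])
      grid <- grid[grid$a <= grid$b, , drop = FALSE]
    cp <- canonical_pair(grid$a, grid$b)
    res[[i]] <- data.frame(isoform_a = cp$a, isoform_b = cp$b,
                           gene_a = gp$gene_a[i], gene_b = gp$gene_b[i],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(isoform_a = character(0), isoform_b = character(0),
                      gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE)
  out <- out[!duplicated(pair_key(out$isoform_a, out$isoform_b)), ,
             drop = FALSE]
  out <- out[order(out$isoform_a, out$isoform_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tiered prediction of isoform-isoform interactions
#'
#' Scores every candidate pair and assigns confidence tiers: `high` for
#' `score > thresholds["high"]`, `low` for
#' `thresholds["low"] < score <= thresholds["high"]`. Additionally, for every
#' gene-level PPI the best-scoring isoform pair is kept even when it clears
#' neither threshold (tier `rescued`; ties broken by canonical pair order), so
#' every PPI retains at least one predicted isoform-level interaction.
#'
#' @param features an `iii_features` table for the candidate pairs (as
#'   produced by [build_feature_vectors()] on [candidate_pairs()] output).
#' @param fit an `iii_logit` (or named coefficient vector).
#' @param ppi the `iii_ppi` table defining the candidate universe.
#' @param catalog the `iii_catalog`.
#' @param thresholds named numeric vector with elements `high` and `low`;
#'   defaults `c(high = 2.575, low = 1.692)`.
#' @return Data frame of class `iii_predictions`: columns `isoform_a`,
#'   `isoform_b`, `gene_a`, `gene_b`, `logit_score`, `probability`, `tier`,
#'   `ddi_score` and one correlation column per dataset. Rows are the
#'   low-confidence prediction set (high and low tiers plus rescued pairs).
#' @export
predict_iii <- function(features, fit, ppi, catalog,
                        thresholds = c(high = 2.575, low = 1.692)) {
  if (!all(c("high", "low") %in% names(thresholds)))
    contract_error("predict_iii: thresholds must name 'high' and 'low'")
  if (thresholds["high"] < thresholds["low"])
    contract_error("predict_iii: high threshold below low threshold")
  cand <- candidate_pairs(ppi, catalog)
  ckey <- pair_key(cand$isoform_a, cand$isoform_b)
  fkey <- pair_key(features$isoform_a, features$isoform_b)
  if (!all(fkey %in% ckey))
    contract_error(
      "predict_iii: feature pair %s-%s has no supporting gene-level PPI",
      features$isoform_a[!(fkey %in% ckey)][1],
      features$isoform_b[!(fkey %in% ckey)][1])
  if (!all(ckey %in% fkey))
    contract_error("predict_iii: %d candidate pair(s) lack feature vectors",
                   sum(!(ckey %in% fkey)))
  features <- features[match(ckey, fkey), , drop = FALSE]
  scores <- logit_score(fit, features)

  tier <- rep(NA_character_, length(scores))
  tier[scores > thresholds["low"]] <- "low"
  tier[scores > thresholds["high"]] <- "high"

  # rescue: per gene-level PPI, the best-scoring pair (ties by canonical
  # pair order) joins the prediction set even below the low threshold
  gkey <- pair_key(cand$gene_a, cand$gene_b)
  ord <- order(gkey, -scores, cand$isoform_a, cand$isoform_b)
  best <- ord[!duplicated(gkey[ord])]
  rescue <- best[is.na(tier[best])]
  tier[rescue] <- "rescued"

  keep <- !is.na(tier)
  ds <- attr(features, "dataset_ids")
  out <- data.frame(isoform_a = cand$isoform_a[keep],
                    isoform_b = cand$isoform_b[keep],
                    gene_a = cand$gene_a[keep], gene_b = cand$gene_b[keep],
                    logit_score = scores[keep],
                    probability = stats::plogis(scores[keep]),
                    tier = tier[keep],
                    ddi_score = features$ddi[keep],
                    stringsAsFactors = FALSE)
  for (d in ds) out[[d]] <- features[[d]][keep]
  out <- out[order(out$isoform_a, out$isoform_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dataset_ids") <- ds
  class(out) <- c("iii_predictions", "data.frame")
  out
}

#' Evaluate a fitted model on the held-out gold standard
#'
#' Scores the test positives against the negatives, returns the full
#' precision-recall curve and the operating points at the two tier thresholds.
#'
#' @param fit an `iii_logit`.
#' @param features an `iii_features` table covering all test positive and
#'   negative pairs.
#' @param gold an `iii_gold`.
#' @param thresholds named vector with `high` and `low` thresholds.
#' @return List with `curve` (an `iii_pr_curve`) and `operating_points`
#'   (data frame: tier, threshold, precision, recall).
#' @export
evaluate_on_test <- function(fit, features, gold,
                             thresholds = c(high = 2.575, low = 1.692)) {
  pos <- gold$positives_test
  neg <- gold$negatives
  if (nrow(pos) == 0 || nrow(neg) == 0)
    contract_error("evaluate_on_test: empty test positives or negatives")
  fkey <- pair_key(features$isoform_a, features$isoform_b)
  want <- c(pair_key(pos$isoform_a, pos$isoform_b),
            pair_key(neg$isoform_a, neg$isoform_b))
  if (!all(want %in% fkey))
    contract_error("evaluate_on_test: %d test pair(s) lack feature vectors",
                   sum(!(want %in% fkey)))
  idx <- match(want, fkey)
  labels <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
  scores <- logit_score(fit, features[idx, , drop = FALSE])
  curve <- precision_recall_curve(scores, labels)
  op <- lapply(c(high = "high", low = "low"), function(t) {
    thr <- thresholds[[t]]
    sel <- scores > thr
    tp <- sum(labels[sel] == 1L)
    data.frame(tier = t, threshold = thr,
               precision = if (sum(sel) > 0) tp / sum(sel) else NA_real_,
               recall = tp / sum(labels == 1L), stringsAsFactors = FALSE)
  })
  list(curve = curve, operating_points = do.call(rbind, c(op,
                                                          make.row.names = FALSE)))
}
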