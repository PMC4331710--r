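# Independent brute-force oracles. Each re-derives a quantity from first
# principles with none of the package's internal shortcuts, so that
# implementation and oracle can only agree by both being right.

# textbook Pearson formula, accumulated term by term in explicit loops
oracle_abs_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  if (sxx == 0 || syy == 0) return(NA_real_)
  min(abs(sxy / sqrt(sxx * syy)), 1)
}

# enumerate every cross pair of domains against every DDI row
oracle_ddi_score <- function(domains_a, domains_b, ddi) {
  best <- 0L
  score_of <- c(high = 3L, medium = 2L, low = 1L)
  for (da in domains_a) for (db in domains_b) {
    for (i in seq_len(nrow(ddi))) {
      match_fwd <- ddi$domain_a[i] == da && ddi$domain_b[i] == db
      match_rev <- ddi$domain_a[i] == db && ddi$domain_b[i] == da
      if (match_fwd || match_rev)
        best <- max(best, score_of[[ddi$confidence[i]]])
    }
  }
  best
}

# confusion matrix at a single threshold, counted one item at a time
oracle_pr_at <- function(scores, labels, threshold) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(scores)) {
    predicted <- scores[i] > threshold
    if (predicted && labels[i] == 1) tp <- tp + 1L
    if (predicted && labels[i] == 0) fp <- fp + 1L
    if (!predicted && labels[i] == 1) fn <- fn + 1L
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = tp / (tp + fn))
}

# density by checking all n(n-1)/2 member pairs against the edge list
oracle_density <- function(members, edges) {
  n <- length(members)
  e_in <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    hit <- (edges$isoform_a == members[i] & edges$isoform_b == members[j]) |
      (edges$isoform_a == members[j] & edges$isoform_b == members[i])
    if (any(hit)) e_in <- e_in + 1L
  }
  2 * e_in / (n * (n - 1))
}

# hypergeometric upper tail by direct pmf summation
oracle_hyper_upper <- function(k, K, n, N) {
  tot <- 0
  for (x in k:min(K, n))
    tot <- tot + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  min(tot, 1)
}

# GSN by filtering all unordered pairs of the covered isoforms
oracle_gsn <- function(covered, loc, gsp = NULL) {
  covered <- sort(covered)
  out_a <- character(0); out_b <- character(0)
  for (i in seq_along(covered)) for (j in seq_along(covered)) {
    if (i >= j) next
    m <- covered[i]; n <- covered[j]
    lm <- if (m %in% names(loc)) loc[[m]] else character(0)
    ln <- if (n %in% names(loc)) loc[[n]] else character(0)
    mem_m <- "plasma_membrane" %in% lm; nuc_m <- "nucleus" %in% lm
    mem_n <- "plasma_membrane" %in% ln; nuc_n <- "nucleus" %in% ln
    # one membrane-only, the other nucleus-only (dual-localized excluded)
    ok <- (mem_m && !nuc_m && nuc_n && !mem_n) ||
      (mem_n && !nuc_n && nuc_m && !mem_m)
    if (!ok) next
    if (!is.null(gsp) &&
        any(gsp$isoform_a == m & gsp$isoform_b == n)) next
    out_a <- c(out_a, m); out_b <- c(out_b, n)
  }
  data.frame(isoform_a = out_a, isoform_b = out_b, stringsAsFactors = FALSE)
}

pkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
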