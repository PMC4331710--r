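# Per-pair explanatory variables of the logistic model: one domain-domain
# interaction (DDI) score in {0,1,2,3} and one absolute Pearson correlation
# per expression dataset.

#' Absolute Pearson correlation
#'
#' The co-expression evidence used per RNA-seq dataset is the absolute value
#' of the sample Pearson correlation; the sign carries no meaning for
#' interaction propensity under this model.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return `|r|` in `[0, 1]`, or `NA_real_` when either vector has zero
#'   variance (correlation undefined).
#' @examples
#' abs_pearson(c(1, 2, 3), c(6, 4, 2)) # 1
#' @export
abs_pearson <- function(x, y) {
  if (length(x) != length(y))
    contract_error("abs_pearson: length mismatch (%d vs %d)",
                   length(x), length(y))
  if (length(x) < 2)
    contract_error("abs_pearson: need at least 2 observations")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sum(xc^2)
  sy <- sum(yc^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  min(abs(sum(xc * yc) / sqrt(sx * sy)), 1)
}

# Orderless lookup table: canonical domain-pair key -> best score.
ddi_score_table <- function(ddi) {
  score <- c(high = 3L, medium = 2L, low = 1L)[ddi$confidence]
  key <- pair_key(ddi$domain_a, ddi$domain_b)
  tapply(score, key, max)
}

#' Domain-domain interaction score for a pair of domain sets
#'
#' Scores every cross pair of domains against the DDI table (orderless match)
#' and returns the best hit: high-confidence interactions score 3, medium 2,
#' low 1. A pair with several matching DDIs takes the highest score; a pair
#' with no match scores 0 ("no evidence").
#'
#' @param domains_a,domains_b character vectors of domain ids (may be empty).
#' @param ddi an `iii_ddi` table, or a precomputed lookup from the internal
#'   score table (for bulk scoring).
#' @return Integer in `{0, 1, 2, 3}`.
#' @export
ddi_score <- function(domains_a, domains_b, ddi) {
  tab <- if (inherits(ddi, "iii_ddi")) ddi_score_table(ddi) else ddi
  if (length(domains_a) == 0 || length(domains_b) == 0 || length(tab) == 0)
    return(0L)
  grid <- expand.grid(a = unique(domains_a), b = unique(domains_b),
                      stringsAsFactors = FALSE)
  cp <- canonical_pair(grid$a, grid$b)
  hits <- tab[pair_key(cp$a, cp$b)]
  hits <- hits[!is.na(hits)]
  if (length(hits) == 0) 0L else as.integer(max(hits))
}

#' Assemble per-pair feature vectors
#'
#' For each isoform pair, computes the DDI score from the isoforms' domain
#' compositions and, within every expression dataset, the absolute Pearson
#' correlation over that dataset's samples. A dataset's entry is missing
#' (`NA`) when either isoform is absent from the dataset or has zero variance
#' in it; the missingness mask is preserved for reporting and imputed as 0 at
#' model time ("no co-expression evidence").
#'
#' @param pairs data frame with columns `isoform_a`, `isoform_b` (any order;
#'   canonicalized here).
#' @param datasets list of `iii_expression` objects.
#' @param catalog an `iii_catalog`; every isoform in `pairs` must be known.
#' @param ddi an `iii_ddi` table.
#' @return Data frame of class `iii_features` with columns `isoform_a`,
#'   `isoform_b`, `ddi` and one numeric column per dataset (named by
#'   `dataset_id`); attribute `dataset_ids` records the column order.
#' @export
build_feature_vectors <- function(pairs, datasets, catalog, ddi) {
  cp <- canonical_pair(pairs$isoform_a, pairs$isoform_b)
  check_isoforms_known(catalog, c(cp$a, cp$b))
  n <- length(cp$a)
  tab <- ddi_score_table(ddi)
  doms <- catalog$domains
  out <- data.frame(isoform_a = cp$a, isoform_b = cp$b,
                    stringsAsFactors = FALSE)
  out$ddi <- vapply(seq_len(n), function(i)
    ddi_score(doms[[cp$a[i]]], doms[[cp$b[i]]], tab), integer(1))
  ds_ids <- vapply(datasets, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ds_ids))
    validation_error("duplicate dataset_id among expression datasets")
  for (k in seq_along(datasets)) {
    m <- datasets[[k]]$matrix
    # centred rows + row sums of squares, then r per pair in one pass
    cm <- m - rowMeans(m)
    ss <- rowSums(cm^2)
    col <- rep(NA_real_, n)
    ia <- match(cp$a, rownames(m))
    ib <- match(cp$b, rownames(m))
    ok <- !is.na(ia) & !is.na(ib) & ss[ia] > 0 & ss[ib] > 0
    if (any(ok)) {
      num <- rowSums(cm[ia[ok], , drop = FALSE] * cm[ib[ok], , drop = FALSE])
      col[ok] <- pmin(abs(num / sqrt(ss[ia[ok]] * ss[ib[ok]])), 1)
    }
    out[[ds_ids[k]]] <- col
  }
  attr(out, "dataset_ids") <- ds_ids
  class(out) <- c("iii_features", "data.frame")
  out
}

#' Missingness mask of a feature table
#' @param features an `iii_features` data frame.
#' @return Logical matrix (pairs x datasets): `TRUE` where the correlation was
#'   unavailable.
#' @export
missing_mask <- function(features) {
  ds <- attr(features, "dataset_ids")
  m <- sapply(ds, function(d) is.na(features[[d]]))
  m <- matrix(m, nrow = nrow(features), dimnames = list(NULL, ds))
  m
}

# Numeric design columns in model order (E1..EK, ddi), NA imputed to 0.
feature_matrix <- function(features) {
  ds <- attr(features, "dataset_ids")
  m <- as.matrix(features[, c(ds, "ddi"), drop = FALSE])
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  m
}
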