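# Module functional enrichment: hypergeometric upper-tail test per
# (module, term), Benjamini-Hochberg correction within module and namespace,
# and the enrichment-rate comparison against size-matched random modules.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance that a uniform
#' draw of `n` objects from a universe of `N`, of which `K` are marked,
#' contains at least `k` marked objects.
#'
#' @param k observed overlap (module members annotated with the term).
#' @param K annotated objects in the universe.
#' @param n draw size (module size counted in the universe).
#' @param N universe size.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || k > min(K, n) || K > N || n > N)
    contract_error("hypergeom_upper_tail: inconsistent counts k=%d K=%d n=%d N=%d",
                   k, K, n, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Functional enrichment of one module
#'
#' Tests every term with at least one annotated module member; annotations are
#' restricted to the given universe (by default the network's isoforms, not
#' the full catalog, to avoid inflating significance from unobservable
#' isoforms). BH adjustment is applied within the module, separately per
#' namespace.
#'
#' @param members character vector of module member isoform ids (subset of
#'   `universe`).
#' @param annotation an `iii_annotation`.
#' @param universe character vector of isoform ids.
#' @param module_id label carried into the result.
#' @return Data frame with columns `module_id`, `term_id`, `namespace`, `k`,
#'   `K`, `n`, `N`, `p_value`, `adjusted_p`; zero rows when no term overlaps
#'   the module.
#' @export
enrich_module <- function(members, annotation, universe,
                          module_id = "module") {
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (N == 0) contract_error("enrich_module: empty universe")
  members <- intersect(unique(members), universe)
  n <- length(members)
  rows <- lapply(seq_len(nrow(annotation$terms)), function(i) {
    term <- annotation$terms$term_id[i]
    ann <- intersect(annotation$members[[term]], universe)
    k <- length(intersect(ann, members))
    if (k == 0) return(NULL)
    K <- length(ann)
    data.frame(module_id = module_id, term_id = term,
               namespace = annotation$terms$namespace[i],
               k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(module_id = character(0), term_id = character(0),
                      namespace = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0), stringsAsFactors = FALSE))
  out$adjusted_p <- NA_real_
  for (ns in unique(out$namespace)) {
    sel <- out$namespace == ns
    out$adjusted_p[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Enrichment over a module list
#' @param modules an `iii_modules` list.
#' @param annotation an `iii_annotation`.
#' @param universe isoform id universe (typically the network nodes).
#' @return Row-bound [enrich_module()] results.
#' @export
enrich_modules <- function(modules, annotation, universe) {
  res <- lapply(modules, function(m)
    enrich_module(m$members, annotation, universe, m$module_id))
  out <- do.call(rbind, res)
  if (is.null(out)) out <- enrich_module(character(0), annotation, universe)[0, ]
  rownames(out) <- NULL
  out
}

#' Fraction of modules with at least one enriched term
#'
#' The module-functionality statistic: the share of modules carrying at least
#' one term of the given namespace with BH-adjusted p below `alpha`.
#'
#' @param modules an `iii_modules` list (non-empty).
#' @param annotation an `iii_annotation`.
#' @param universe isoform id universe.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param namespace `"GO"` or `"pathway"`.
#' @return Fraction in `[0, 1]`.
#' @export
enrichment_rate <- function(modules, annotation, universe, alpha = 0.05,
                            namespace = c("GO", "pathway")) {
  namespace <- match.arg(namespace)
  if (length(modules) == 0) contract_error("enrichment_rate: no modules")
  hits <- vapply(modules, function(m) {
    res <- enrich_module(m$members, annotation, universe, m$module_id)
    any(res$namespace == namespace & res$adjusted_p < alpha)
  }, logical(1))
  mean(hits)
}
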