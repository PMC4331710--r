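# Gold-standard construction: positives from isoform-specified PPI records
# plus the single-isoform rule; negatives from plasma-membrane x nucleus
# localization among the isoforms covered by the positives; train/test split
# on record timestamps.

#' Build the gold-standard positive (GSP) set
#'
#' Positives are the union of (a) isoform pairs carried by isoform-specified
#' PPI records and (b), for every gene-level PPI whose two genes each have
#' exactly one isoform in the catalog, that unique isoform pair. Provenance
#' records which rule produced each pair; a pair produced by both is tagged
#' `isoform_specified`.
#'
#' @param ppi an `iii_ppi` record table.
#' @param catalog an `iii_catalog`.
#' @return Data frame with columns `isoform_a`, `isoform_b`, `provenance`
#'   (one of `"isoform_specified"`, `"single_isoform"`), canonical order,
#'   no duplicates.
#' @export
build_gsp <- function(ppi, catalog) {
  iso_spec <- !is.na(ppi$isoform_a)
  if (any(iso_spec)) {
    sub <- ppi[iso_spec, , drop = FALSE]
    check_isoforms_known(catalog, c(sub$isoform_a, sub$isoform_b),
                         "isoform-specified PPI records")
    bad <- catalog$gene_of[sub$isoform_a] != sub$gene_a |
      catalog$gene_of[sub$isoform_b] != sub$gene_b
    if (any(bad))
      validation_error(
        "ppi record %s-%s: isoform's catalog gene mismatches its gene column",
        sub$isoform_a[bad][1], sub$isoform_b[bad][1])
  }
  iso_count <- table(catalog$isoforms$gene_id)
  only_iso <- stats::setNames(catalog$isoforms$isoform_id,
                              catalog$isoforms$gene_id)
  only_iso <- only_iso[names(iso_count)[iso_count == 1L]]

  a <- character(0); b <- character(0); prov <- character(0)
  if (any(iso_spec)) {
    cp <- canonical_pair(ppi$isoform_a[iso_spec], ppi$isoform_b[iso_spec])
    a <- cp$a; b <- cp$b; prov <- rep("isoform_specified", length(cp$a))
  }
  gp <- unique(data.frame(gene_a = ppi$gene_a, gene_b = ppi$gene_b,
                          stringsAsFactors = FALSE))
  single <- gp$gene_a %in% names(only_iso) & gp$gene_b %in% names(only_iso)
  if (any(single)) {
    cp <- canonical_pair(only_iso[gp$gene_a[single]],
                         only_iso[gp$gene_b[single]])
    a <- c(a, cp$a); b <- c(b, cp$b)
    prov <- c(prov, rep("single_isoform", length(cp$a)))
  }
  # isoform_specified wins when a pair arises from both rules
  ord <- order(prov == "single_isoform")
  a <- a[ord]; b <- b[ord]; prov <- prov[ord]
  keep <- !duplicated(pair_key(a, b))
  out <- data.frame(isoform_a = a[keep], isoform_b = b[keep],
                    provenance = prov[keep], stringsAsFactors = FALSE)
  out <- out[order(out$isoform_a, out$isoform_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Records that would generate a given GSP pair under build_gsp: all matching
# isoform-specified records, plus gene-level records of the gene pair when
# both genes are single-isoform (so the record implies exactly this pair).
supporting_timestamps <- function(gsp, ppi, catalog) {
  iso_count <- table(catalog$isoforms$gene_id)
  gene_of <- catalog$gene_of
  cp_rec <- ifelse(is.na(ppi$isoform_a), NA_character_,
                   pair_key(ppi$isoform_a, ppi$isoform_b))
  gp_rec <- pair_key(ppi$gene_a, ppi$gene_b)
  lapply(seq_len(nrow(gsp)), function(i) {
    key <- pair_key(gsp$isoform_a[i], gsp$isoform_b[i])
    ts <- ppi$timestamp[!is.na(cp_rec) & cp_rec == key]
    ga <- gene_of[gsp$isoform_a[i]]
    gb <- gene_of[gsp$isoform_b[i]]
    gcp <- canonical_pair(ga, gb)
    if (iso_count[ga] == 1L && iso_count[gb] == 1L)
      ts <- c(ts, ppi$timestamp[is.na(cp_rec) & gp_rec == pair_key(gcp$a,
                                                                   gcp$b)])
    as.Date(ts, origin = "1970-01-01")
  })
}

#' Split the GSP into training and test sets by record timestamp
#'
#' A pair is assigned to the test set iff the earliest timestamp among its
#' supporting PPI records is strictly after the cutoff; a pair first recorded
#' on or before the cutoff is training knowledge. The boundary date itself
#' therefore goes to train ("after" is strict).
#'
#' @param gsp data frame from [build_gsp()].
#' @param ppi the `iii_ppi` table the GSP was built from.
#' @param catalog the `iii_catalog`.
#' @param cutoff a `Date`; default `2012-01-01`.
#' @return List with data frames `train` and `test` (columns as `gsp`).
#' @export
split_gsp_by_timestamp <- function(gsp, ppi, catalog,
                                   cutoff = as.Date("2012-01-01")) {
  ts <- supporting_timestamps(gsp, ppi, catalog)
  none <- lengths(ts) == 0
  if (any(none))
    contract_error("GSP pair %s-%s has no supporting PPI record",
                   gsp$isoform_a[none][1], gsp$isoform_b[none][1])
  earliest <- as.Date(vapply(ts, function(d) min(as.numeric(d)), numeric(1)),
                      origin = "1970-01-01")
  is_test <- earliest > cutoff
  list(train = gsp[!is_test, , drop = FALSE],
       test = gsp[is_test, , drop = FALSE])
}

#' Build the gold-standard negative (GSN) set
#'
#' Negatives are isoform pairs in which one isoform is assigned to the plasma
#' membrane and the other to the nucleus, drawn from the isoforms covered by
#' the GSP. Isoforms carrying both labels are excluded from both sides; other
#' compartment labels are ignored. Pairs that are themselves gold-standard
#' positives are removed.
#'
#' @param covered_isoforms isoform ids appearing in any GSP pair.
#' @param localization an `iii_localization`.
#' @param gsp optional GSP data frame whose pairs are excluded.
#' @return Data frame with canonical columns `isoform_a`, `isoform_b`.
#' @export
build_gsn <- function(covered_isoforms, localization, gsp = NULL) {
  loc <- localization[intersect(names(localization), covered_isoforms)]
  has_mem <- vapply(loc, function(v) "plasma_membrane" %in% v, logical(1))
  has_nuc <- vapply(loc, function(v) "nucleus" %in% v, logical(1))
  mem <- names(loc)[has_mem & !has_nuc]
  nuc <- names(loc)[has_nuc & !has_mem]
  if (length(mem) == 0 || length(nuc) == 0)
    return(data.frame(isoform_a = character(0), isoform_b = character(0),
                      stringsAsFactors = FALSE))
  grid <- expand.grid(m = mem, n = nuc, stringsAsFactors = FALSE)
  grid <- grid[grid$m != grid$n, , drop = FALSE]
  cp <- canonical_pair(grid$m, grid$n)
  keep <- !duplicated(pair_key(cp$a, cp$b))
  a <- cp$a[keep]; b <- cp$b[keep]
  if (!is.null(gsp) && nrow(gsp) > 0) {
    drop <- pair_key(a, b) %in% pair_key(gsp$isoform_a, gsp$isoform_b)
    a <- a[!drop]; b <- b[!drop]
  }
  out <- data.frame(isoform_a = a, isoform_b = b, stringsAsFactors = FALSE)
  out <- out[order(out$isoform_a, out$isoform_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the full gold standard
#'
#' Convenience wrapper: GSP via [build_gsp()], timestamp split via
#' [split_gsp_by_timestamp()], GSN via [build_gsn()] over the GSP-covered
#' isoforms. The full GSN serves both training and evaluation; only the
#' positives are split by timestamp.
#'
#' @param ppi an `iii_ppi` table.
#' @param catalog an `iii_catalog`.
#' @param localization an `iii_localization`.
#' @param cutoff split date, default `2012-01-01`.
#' @return Object of class `iii_gold`: list with `positives_train`,
#'   `positives_test`, `negatives` (pair data frames) and `covered_isoforms`.
#' @export
build_gold_standard <- function(ppi, catalog, localization,
                                cutoff = as.Date("2012-01-01")) {
  gsp <- build_gsp(ppi, catalog)
  split <- split_gsp_by_timestamp(gsp, ppi, catalog, cutoff)
  covered <- sort(unique(c(gsp$isoform_a, gsp$isoform_b)))
  gsn <- build_gsn(covered, localization, gsp)
  structure(list(positives_train = split$train, positives_test = split$test,
                 negatives = gsn, covered_isoforms = covered),
            class = "iii_gold")
}

#' @export
print.iii_gold <- function(x, ...) {
  cat(sprintf(paste0("iii_gold: %d train / %d test positives, %d negatives,",
                     " %d covered isoforms\n"),
              nrow(x$positives_train), nrow(x$positives_test),
              nrow(x$negatives), length(x$covered_isoforms)))
  invisible(x)
}

#' Write a gold standard to TSV
#'
#' Columns: `isoform_a`, `isoform_b`, `label` in
#' `{pos_train, pos_test, neg}`, `provenance` (blank for negatives).
#' @param gold an `iii_gold`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path) {
  part <- function(df, label, prov) {
    data.frame(isoform_a = df$isoform_a, isoform_b = df$isoform_b,
               label = rep_len(label, nrow(df)),
               provenance = rep_len(prov, nrow(df)),
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    part(gold$positives_train, "pos_train", gold$positives_train$provenance),
    part(gold$positives_test, "pos_test", gold$positives_test$provenance),
    part(gold$negatives, "neg", ""))
  write_tsv(rows, path)
}
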