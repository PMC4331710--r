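# On-disk dialects ----------------------------------------------------------
#
# All inputs are flattened, headered TSVs. The pipeline deliberately consumes
# processed snapshots rather than raw MITAB/OBO/GAF so that it is
# self-contained:
#   catalog      isoform_id  gene_id  domains(";")  [mrna_length  protein_length]
#   ppi          gene_a  gene_b  isoform_a  isoform_b  timestamp(ISO-8601 date)
#   ddi          domain_a  domain_b  confidence{high,medium,low}
#   expression   isoform_id  <sample columns...>          (one file per dataset)
#   localization isoform_id  compartments(";")
#   annotation   term_id  namespace{GO,pathway}  isoform_ids(";")

#' Controlled vocabulary of subcellular compartments
#'
#' The compartment labels accepted in localization tables. Mirrors the classes
#' of a sequence-based eukaryotic localization predictor; only
#' `plasma_membrane` and `nucleus` play a role in gold-standard-negative
#' construction.
#' @export
iii_compartments <- c(
  "plasma_membrane", "nucleus", "cytoplasm", "extracellular",
  "mitochondrion", "endoplasmic_reticulum", "golgi_apparatus",
  "lysosome", "peroxisome", "cytoskeleton", "vacuole", "chloroplast"
)

.DDI_LEVELS <- c("high", "medium", "low")

#' Read an isoform catalog
#'
#' The catalog maps every transcript isoform to its gene and lists the protein
#' domains (Pfam-style accessions) encoded by that isoform. Optional mRNA and
#' protein lengths are carried through when present.
#'
#' @param path TSV with header columns `isoform_id`, `gene_id`, `domains`
#'   (semicolon-separated, possibly empty) and optionally `mrna_length`,
#'   `protein_length`.
#' @return An object of class `iii_catalog`: a list with `isoforms` (data
#'   frame), `domains` (named list of character vectors keyed by isoform) and
#'   `gene_of` (named character vector).
#' @export
read_isoform_catalog <- function(path) {
  df <- read_tsv_strict(path, c("isoform_id", "gene_id", "domains"),
                        c("mrna_length", "protein_length"))
  new_catalog(
    isoform_id = df$isoform_id,
    gene_id = df$gene_id,
    domains = split_multi(df$domains),
    mrna_length = if ("mrna_length" %in% names(df))
      suppressWarnings(as.integer(df$mrna_length)) else NULL,
    protein_length = if ("protein_length" %in% names(df))
      suppressWarnings(as.integer(df$protein_length)) else NULL
  )
}

#' Construct an isoform catalog from vectors
#'
#' @param isoform_id,gene_id character vectors of equal length.
#' @param domains list of character vectors, one per isoform (may be empty).
#' @param mrna_length,protein_length optional positive integer vectors.
#' @return An `iii_catalog`.
#' @export
new_catalog <- function(isoform_id, gene_id, domains = NULL,
                        mrna_length = NULL, protein_length = NULL) {
  isoform_id <- as.character(isoform_id)
  gene_id <- as.character(gene_id)
  if (length(isoform_id) != length(gene_id))
    validation_error("catalog: isoform_id and gene_id differ in length")
  if (any(!nzchar(isoform_id)) || any(!nzchar(gene_id)))
    validation_error("catalog: empty isoform_id or gene_id (row %d)",
                     which(!nzchar(isoform_id) | !nzchar(gene_id))[1])
  dup <- duplicated(isoform_id)
  if (any(dup))
    validation_error("catalog: duplicate isoform_id '%s' (row %d)",
                     isoform_id[dup][1], which(dup)[1])
  if (is.null(domains)) domains <- rep(list(character(0)), length(isoform_id))
  if (length(domains) != length(isoform_id))
    validation_error("catalog: domains list length mismatch")
  domains <- lapply(domains, function(d) sort(unique(as.character(d))))
  names(domains) <- isoform_id
  isoforms <- data.frame(isoform_id = isoform_id, gene_id = gene_id,
                         stringsAsFactors = FALSE)
  if (!is.null(mrna_length)) {
    if (any(!is.na(mrna_length) & mrna_length <= 0))
      validation_error("catalog: non-positive mrna_length")
    isoforms$mrna_length <- as.integer(mrna_length)
  }
  if (!is.null(protein_length)) {
    if (any(!is.na(protein_length) & protein_length <= 0))
      validation_error("catalog: non-positive protein_length")
    isoforms$protein_length <- as.integer(protein_length)
  }
  gene_of <- stats::setNames(gene_id, isoform_id)
  structure(list(isoforms = isoforms, domains = domains, gene_of = gene_of),
            class = "iii_catalog")
}

#' @export
print.iii_catalog <- function(x, ...) {
  cat(sprintf("iii_catalog: %d isoforms across %d genes\n",
              nrow(x$isoforms), length(unique(x$isoforms$gene_id))))
  invisible(x)
}

#' Isoforms belonging to a gene
#' @param catalog an `iii_catalog`.
#' @param gene gene identifier.
#' @return Character vector of isoform ids (possibly empty).
#' @export
isoforms_of_gene <- function(catalog, gene) {
  catalog$isoforms$isoform_id[catalog$isoforms$gene_id == gene]
}

check_isoforms_known <- function(catalog, ids, what = "pair list") {
  unknown <- setdiff(ids, catalog$isoforms$isoform_id)
  if (length(unknown) > 0)
    validation_error("%s references unknown isoform(s): %s", what,
                     paste(utils::head(unknown, 5), collapse = ", "))
  invisible(TRUE)
}

#' Read a gene-level PPI table
#'
#' Records are canonicalized so that `gene_a <= gene_b` lexicographically
#' (isoform columns swapped consistently; for homodimers the isoform pair is
#' ordered instead) and exact duplicate rows are collapsed. A record is
#' isoform-specified when both isoform columns are non-blank; a row with
#' exactly one isoform filled in is rejected as malformed.
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `isoform_a`, `isoform_b`
#'   (may be blank) and `timestamp` (strict ISO-8601 date, `YYYY-MM-DD`).
#' @return A data frame of class `iii_ppi` with character columns `gene_a`,
#'   `gene_b`, `isoform_a`, `isoform_b` (`NA` when unspecified) and a `Date`
#'   column `timestamp`.
#' @export
read_ppi_table <- function(path) {
  df <- read_tsv_strict(path, c("gene_a", "gene_b", "isoform_a", "isoform_b",
                                "timestamp"))
  new_ppi(gene_a = df$gene_a, gene_b = df$gene_b,
          isoform_a = ifelse(nzchar(df$isoform_a), df$isoform_a, NA_character_),
          isoform_b = ifelse(nzchar(df$isoform_b), df$isoform_b, NA_character_),
          timestamp = parse_iso_date(df$timestamp, path))
}

parse_iso_date <- function(x, where = "ppi table") {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(d) | format(d, "%Y-%m-%d") != x
  if (any(bad))
    validation_error("%s: unparseable ISO-8601 date '%s' (row %d)",
                     where, x[bad][1], which(bad)[1])
  d
}

#' Construct a canonical PPI record table
#'
#' @param gene_a,gene_b gene identifiers.
#' @param isoform_a,isoform_b optional isoform identifiers (`NA` when the
#'   record carries no isoform specification).
#' @param timestamp `Date` vector.
#' @return An `iii_ppi` data frame in canonical order with duplicates
#'   collapsed.
#' @export
new_ppi <- function(gene_a, gene_b, isoform_a = NA_character_,
                    isoform_b = NA_character_, timestamp) {
  n <- length(gene_a)
  df <- data.frame(gene_a = as.character(gene_a),
                   gene_b = as.character(gene_b),
                   isoform_a = rep_len(as.character(isoform_a), n),
                   isoform_b = rep_len(as.character(isoform_b), n),
                   timestamp = rep_len(as.Date(timestamp), n),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$gene_a) | !nzchar(df$gene_b)))
    validation_error("ppi: empty gene identifier (row %d)",
                     which(!nzchar(df$gene_a) | !nzchar(df$gene_b))[1])
  half <- xor(is.na(df$isoform_a), is.na(df$isoform_b))
  if (any(half))
    validation_error("ppi: row %d specifies only one isoform of the pair",
                     which(half)[1])
  # canonical order on genes; homodimer rows are ordered on the isoform pair
  swap <- df$gene_a > df$gene_b |
    (df$gene_a == df$gene_b & !is.na(df$isoform_a) &
       df$isoform_a > df$isoform_b)
  tmp <- df$gene_a[swap]; df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  tmp <- df$isoform_a[swap]; df$isoform_a[swap] <- df$isoform_b[swap]
  df$isoform_b[swap] <- tmp
  key <- paste(df$gene_a, df$gene_b, df$isoform_a, df$isoform_b,
               format(df$timestamp), sep = .KEY_SEP)
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("iii_ppi", "data.frame")
  df
}

#' Read a domain-domain interaction table
#'
#' @param path TSV with columns `domain_a`, `domain_b` and `confidence`, the
#'   latter one of `high`, `medium`, `low`.
#' @return A data frame of class `iii_ddi` with canonical domain order and
#'   exact duplicates collapsed.
#' @export
read_ddi_table <- function(path) {
  df <- read_tsv_strict(path, c("domain_a", "domain_b", "confidence"))
  new_ddi(df$domain_a, df$domain_b, df$confidence)
}

#' Construct a DDI record table
#' @param domain_a,domain_b domain identifiers.
#' @param confidence one of `"high"`, `"medium"`, `"low"` per record.
#' @return An `iii_ddi` data frame.
#' @export
new_ddi <- function(domain_a, domain_b, confidence) {
  confidence <- as.character(confidence)
  bad <- !(confidence %in% .DDI_LEVELS)
  if (any(bad))
    validation_error("ddi: unknown confidence level '%s' (row %d)",
                     confidence[bad][1], which(bad)[1])
  cp <- canonical_pair(domain_a, domain_b)
  df <- data.frame(domain_a = cp$a, domain_b = cp$b, confidence = confidence,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$domain_a, df$domain_b, df$confidence,
                             sep = .KEY_SEP)), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("iii_ddi", "data.frame")
  df
}

#' Read an isoform expression matrix
#'
#' One file per RNA-seq dataset: first column `isoform_id`, remaining columns
#' numeric sample values. Correlation is undefined on fewer than two samples,
#' so such files are rejected.
#'
#' @param path TSV path.
#' @param dataset_id identifier for the dataset; defaults to the filename stem.
#' @param catalog optional `iii_catalog`; when given, rows must be catalog
#'   isoforms.
#' @return An object of class `iii_expression`: list with `dataset_id` and
#'   `matrix` (isoforms x samples, rownames = isoform ids).
#' @export
read_expression_matrix <- function(path, dataset_id = NULL, catalog = NULL) {
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  if (!file.exists(path)) io_error("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  if (!"isoform_id" %in% names(df))
    validation_error("%s: missing isoform_id column", path)
  sample_cols <- setdiff(names(df), "isoform_id")
  if (length(sample_cols) < 2)
    validation_error("%s: expression matrix needs >= 2 sample columns", path)
  m <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m))
    validation_error("%s: non-numeric or missing expression value", path)
  rownames(m) <- df$isoform_id
  new_expression(dataset_id, m, catalog = catalog)
}

#' Construct an expression dataset
#' @param dataset_id dataset identifier.
#' @param matrix numeric isoforms x samples matrix with isoform rownames.
#' @param catalog optional catalog for row validation.
#' @return An `iii_expression`.
#' @export
new_expression <- function(dataset_id, matrix, catalog = NULL) {
  if (is.null(rownames(matrix)))
    validation_error("expression %s: matrix lacks isoform rownames", dataset_id)
  if (ncol(matrix) < 2)
    validation_error("expression %s: needs >= 2 samples", dataset_id)
  dup <- duplicated(rownames(matrix))
  if (any(dup))
    validation_error("expression %s: duplicate isoform row '%s'",
                     dataset_id, rownames(matrix)[dup][1])
  if (any(matrix < 0))
    validation_error("expression %s: negative expression value", dataset_id)
  if (!is.null(catalog))
    check_isoforms_known(catalog, rownames(matrix),
                         sprintf("expression %s", dataset_id))
  structure(list(dataset_id = dataset_id, matrix = matrix),
            class = "iii_expression")
}

#' Read an isoform localization table
#'
#' @param path TSV with columns `isoform_id` and `compartments`
#'   (semicolon-separated labels from [iii_compartments]).
#' @param catalog optional catalog; keys must be catalog isoforms when given.
#' @return Named list of class `iii_localization` mapping isoform id to a
#'   character vector of compartments.
#' @export
read_localization <- function(path, catalog = NULL) {
  df <- read_tsv_strict(path, c("isoform_id", "compartments"))
  new_localization(stats::setNames(split_multi(df$compartments),
                                   df$isoform_id), catalog = catalog)
}

#' Construct a localization map
#' @param x named list: isoform id -> character vector of compartment labels.
#' @param catalog optional catalog for key validation.
#' @return An `iii_localization`.
#' @export
new_localization <- function(x, catalog = NULL) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    validation_error("localization: unnamed entries")
  if (anyDuplicated(names(x)))
    validation_error("localization: duplicate isoform_id '%s'",
                     names(x)[duplicated(names(x))][1])
  labs <- unique(unlist(x, use.names = FALSE))
  unknown <- setdiff(labs, iii_compartments)
  if (length(unknown) > 0)
    validation_error("localization: unknown compartment label '%s'",
                     unknown[1])
  if (!is.null(catalog))
    check_isoforms_known(catalog, names(x), "localization")
  x <- lapply(x, function(v) sort(unique(v)))
  structure(x, class = "iii_localization")
}

#' Isoforms localized to both plasma membrane and nucleus
#' @param localization an `iii_localization`.
#' @return Character vector of dual-localized isoform ids.
#' @export
dual_localized <- function(localization) {
  names(localization)[vapply(localization, function(v)
    all(c("plasma_membrane", "nucleus") %in% v), logical(1))]
}

#' Read a functional annotation table
#'
#' @param path TSV with columns `term_id`, `namespace` (`GO` or `pathway`) and
#'   `isoform_ids` (semicolon-separated, non-empty).
#' @param catalog optional catalog; annotated isoforms must exist when given.
#' @return An object of class `iii_annotation`: list with `terms` (data frame
#'   `term_id`, `namespace`) and `members` (named list of isoform id vectors).
#' @export
read_annotation <- function(path, catalog = NULL) {
  df <- read_tsv_strict(path, c("term_id", "namespace", "isoform_ids"))
  new_annotation(df$term_id, df$namespace, split_multi(df$isoform_ids),
                 catalog = catalog)
}

#' Construct an annotation map
#' @param term_id,namespace character vectors (namespace in `GO`/`pathway`).
#' @param members list of isoform id vectors, one per term, each non-empty.
#' @param catalog optional catalog for member validation.
#' @return An `iii_annotation`.
#' @export
new_annotation <- function(term_id, namespace, members, catalog = NULL) {
  term_id <- as.character(term_id)
  namespace <- as.character(namespace)
  bad <- !(namespace %in% c("GO", "pathway"))
  if (any(bad))
    validation_error("annotation: unknown namespace '%s'", namespace[bad][1])
  if (anyDuplicated(term_id))
    validation_error("annotation: duplicate term_id '%s'",
                     term_id[duplicated(term_id)][1])
  members <- lapply(members, function(v) sort(unique(as.character(v))))
  empty <- lengths(members) == 0
  if (any(empty))
    validation_error("annotation: term '%s' has an empty isoform set",
                     term_id[empty][1])
  if (!is.null(catalog))
    check_isoforms_known(catalog, unlist(members, use.names = FALSE),
                         "annotation")
  names(members) <- term_id
  structure(list(terms = data.frame(term_id = term_id, namespace = namespace,
                                    stringsAsFactors = FALSE),
                 members = members),
            class = "iii_annotation")
}

# Prediction and module output ----------------------------------------------

#' Write scored predictions to TSV
#'
#' One row per isoform pair with columns `isoform_a`, `isoform_b`, `gene_a`,
#' `gene_b`, `logit_score`, `tier`, `ddi_score` and one absolute-correlation
#' column per expression dataset (blank where the evidence was missing).
#' Numeric columns are written at full precision so the file round-trips
#' losslessly through [read_predictions()].
#'
#' @param predictions an `iii_predictions` data frame from [predict_iii()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  ds <- attr(predictions, "dataset_ids")
  if (nrow(predictions) == 0)
    warning("writing an empty prediction set (header-only file)")
  out <- predictions[, c("isoform_a", "isoform_b", "gene_a", "gene_b"),
                     drop = FALSE]
  out$logit_score <- format_num(predictions$logit_score)
  out$tier <- predictions$tier
  out$ddi_score <- as.integer(predictions$ddi_score)
  for (d in ds) out[[d]] <- format_num(predictions[[d]])
  write_tsv(out, path)
}

#' Read predictions written by [write_predictions()]
#' @param path TSV path.
#' @return An `iii_predictions` data frame.
#' @export
read_predictions <- function(path) {
  df <- read_tsv_strict(path, c("isoform_a", "isoform_b", "gene_a", "gene_b",
                                "logit_score", "tier", "ddi_score"))
  full <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE,
                            na.strings = NULL, quote = "",
                            stringsAsFactors = FALSE)
  ds <- setdiff(names(full), c("isoform_a", "isoform_b", "gene_a", "gene_b",
                               "logit_score", "tier", "ddi_score"))
  out <- data.frame(isoform_a = df$isoform_a, isoform_b = df$isoform_b,
                    gene_a = df$gene_a, gene_b = df$gene_b,
                    logit_score = as.numeric(df$logit_score),
                    tier = df$tier,
                    ddi_score = as.integer(df$ddi_score),
                    stringsAsFactors = FALSE)
  for (d in ds)
    out[[d]] <- suppressWarnings(as.numeric(ifelse(nzchar(full[[d]]),
                                                   full[[d]], NA)))
  attr(out, "dataset_ids") <- ds
  class(out) <- c("iii_predictions", "data.frame")
  out
}

#' Write discovered modules to TSV
#'
#' Columns: `module_id`, `members` (semicolon-joined isoform ids), `density`
#' and `top_terms` (semicolon-joined enriched term ids, blank when enrichment
#' was not run or nothing was significant).
#'
#' @param modules an `iii_modules` list from [discover_modules()].
#' @param path output path.
#' @param top_terms optional named list: module_id -> character vector of
#'   enriched term ids.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path, top_terms = NULL) {
  if (length(modules) == 0)
    warning("writing an empty module set (header-only file)")
  df <- data.frame(
    module_id = vapply(modules, `[[`, character(1), "module_id"),
    members = vapply(modules, function(m)
      paste(sort(m$members), collapse = ";"), character(1)),
    density = format_num(vapply(modules, `[[`, numeric(1), "density")),
    top_terms = vapply(modules, function(m) {
      tt <- if (!is.null(top_terms)) top_terms[[m$module_id]] else NULL
      if (is.null(tt)) "" else paste(tt, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Read modules written by [write_modules()]
#' @param path TSV path.
#' @return An `iii_modules` list; each element has `module_id`, `members`,
#'   `density` and `top_terms`.
#' @export
read_modules <- function(path) {
  df <- read_tsv_strict(path, c("module_id", "members", "density"),
                        "top_terms")
  mods <- lapply(seq_len(nrow(df)), function(i) {
    list(module_id = df$module_id[i],
         members = sort(split_multi(df$members[i])[[1]]),
         density = as.numeric(df$density[i]),
         top_terms = if ("top_terms" %in% names(df))
           split_multi(df$top_terms[i])[[1]] else character(0))
  })
  structure(mods, class = "iii_modules")
}
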