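#' @keywords internal
"_PACKAGE"

# Separator used to build pair keys. Identifiers come from TSV columns and
# therefore can never contain a tab.
.KEY_SEP <- "\t"

pair_key <- function(a, b) paste(a, b, sep = .KEY_SEP)

#' Canonicalize unordered pairs
#'
#' Orders each pair lexicographically so that `a <= b`. All pair containers in
#' the package store canonical order only; symmetry of pair-level operations
#' follows from canonicalizing at every entry point.
#'
#' @param a,b character vectors of identifiers (recycled to common length).
#' @return A list with elements `a` and `b` (reordered) and `swapped`, a
#'   logical vector marking pairs whose elements were exchanged.
#' @examples
#' canonical_pair(c("B", "A"), c("A", "B"))
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  swap <- a > b
  out_a <- ifelse(swap, b, a)
  out_b <- ifelse(swap, a, b)
  list(a = out_a, b = out_b, swapped = swap)
}

validation_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("iii_validation_error", "error")))
}

contract_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("iii_contract_error", "error")))
}

io_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("iii_io_error", "error")))
}

# Run `expr` under `set.seed(seed)` and restore the caller's RNG state, so
# seeded operations do not perturb the global stream ("no global state").
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Full-precision numeric formatting so written tables round-trip losslessly.
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

read_tsv_strict <- function(path, required, optional = character()) {
  if (!file.exists(path)) io_error("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    validation_error("%s: missing required column(s): %s", path,
                     paste(missing_cols, collapse = ", "))
  df[, intersect(c(required, optional), names(df)), drop = FALSE]
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) io_error("cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

split_multi <- function(x, sep = ";") {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, sep, fixed = TRUE)[[1]]
  })
}

join_multi <- function(x, sep = ";") {
  vapply(x, function(s) paste(sort(unique(s)), collapse = sep), character(1))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random positive is
#' scored above a random negative, with ties counted one half.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1 or logical) of the same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    contract_error("auroc: scores and labels differ in length")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    contract_error("auroc: need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
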