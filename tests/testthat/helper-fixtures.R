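# Small in-code fixtures shared across test files.

write_lines_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# two genes, three isoforms, two domains each on the interacting isoforms
tiny_catalog <- function() {
  new_catalog(
    isoform_id = c("NM_001", "NM_002", "NM_101"),
    gene_id = c("GA", "GA", "GB"),
    domains = list(c("PF00001", "PF00002"), character(0), "PF00003")
  )
}

tiny_expression <- function(dataset_id = "d1", seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(3 * 6, mean = 5)), nrow = 3,
              dimnames = list(c("NM_001", "NM_002", "NM_101"),
                              paste0("s", 1:6)))
  new_expression(dataset_id, m)
}

# a small random world fixture for property tests (smaller than the default;
# localization priors raised so the gold-standard negative set stays
# non-empty at this scale)
small_world <- function(seed, ...) {
  generate_world(synthetic_world_config(
    n_genes = 40L, n_ppis = 50L, n_datasets = 3L, samples_per_dataset = 12L,
    n_planted_modules = 2L, planted_module_size_range = c(4L, 5L),
    n_go_terms = 10L, n_pathway_terms = 5L,
    p_membrane = 0.25, p_nucleus = 0.45, seed = seed, ...))
}

# random expression matrix over a given catalog
rand_expression <- function(iso_ids, dataset_id, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(length(iso_ids) * n_samples, mean = 5)),
              nrow = length(iso_ids),
              dimnames = list(iso_ids, paste0("s", seq_len(n_samples))))
  new_expression(dataset_id, m)
}
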