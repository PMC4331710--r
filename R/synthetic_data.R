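# Synthetic input worlds with planted ground truth. The generator emits all
# six pipeline inputs (catalog, PPIs, DDIs, expression datasets, localization,
# annotation) plus the truth used to validate every stage: the set of truly
# interacting isoform pairs and the planted dense modules.
#
# Co-expression is induced by shared latent factors: every true interaction
# owns one factor on which exactly its two isoforms load, so truly
# interacting pairs are correlated while all other pairs have population
# correlation zero. Loadings carry random signs, so the generator also
# exercises the absolute-value feature definition.

#' Configuration of a synthetic world
#'
#' Defaults describe a desk-scale world: 200 genes with one to four isoforms
#' each (mean about two), 300 gene-level PPIs each backed by at least one true
#' isoform pair (extra cross pairs interact with probability 0.2), 19
#' expression datasets of 20
#' samples (mirroring many-experiment RNA-seq series), target absolute
#' correlation 0.8 for interacting pairs and 0 for background, and four
#' planted clique modules of 5-8 isoforms with coherent annotations.
#'
#' @param n_genes number of genes.
#' @param isoform_count_probs probabilities for 1..k isoforms per gene.
#' @param n_domains size of the domain pool.
#' @param domains_per_isoform range (min, max) of domains per isoform.
#' @param ddi_background_density fraction of all domain pairs given a random
#'   DDI record (noise).
#' @param ddi_confidence_mix named probabilities for high/medium/low records
#'   supporting real interactions.
#' @param ddi_background_mix confidence mix of spurious background records,
#'   skewed to low confidence as predicted-DDI noise typically is.
#' @param p_ddi_true probability a truly interacting pair receives a
#'   supporting DDI between its domains.
#' @param n_ppis number of distinct gene-level PPIs (including planted-module
#'   gene pairs).
#' @param true_iii_rate probability an extra isoform cross pair of a PPI truly
#'   interacts, beyond the one true pair every PPI is guaranteed (so the
#'   unique pair of a single-isoform x single-isoform PPI is always true,
#'   matching the single-isoform gold-standard rule).
#' @param frac_isoform_specified fraction of PPIs whose record carries an
#'   isoform specification (a true pair of that PPI).
#' @param n_datasets,samples_per_dataset expression panel shape
#'   (`samples_per_dataset >= 10`, echoing many-experiment series).
#' @param corr_strength_true,corr_strength_false target `|r|` for interacting
#'   vs unrelated pairs.
#' @param dataset_presence probability an isoform is quantified in a dataset.
#' @param p_membrane,p_nucleus independent localization priors; isoforms with
#'   neither label are cytoplasmic.
#' @param n_go_terms,n_pathway_terms annotation table sizes (planted-module
#'   terms included).
#' @param annotation_coherence fraction of a planted module annotated by its
#'   dedicated term.
#' @param n_planted_modules,planted_module_size_range planted clique modules
#'   (disjoint gene sets; all member pairs are true interactions).
#' @param timestamp_range character vector of two ISO dates bounding record
#'   timestamps.
#' @param seed mandatory integer seed.
#' @return A validated list of class `iii_world_config`.
#' @export
synthetic_world_config <- function(
    n_genes = 200L,
    isoform_count_probs = c(0.35, 0.35, 0.2, 0.1),
    n_domains = 80L,
    domains_per_isoform = c(1L, 3L),
    ddi_background_density = 0.01,
    ddi_confidence_mix = c(high = 0.3, medium = 0.4, low = 0.3),
    ddi_background_mix = c(high = 0.1, medium = 0.3, low = 0.6),
    p_ddi_true = 0.6,
    n_ppis = 300L,
    true_iii_rate = 0.2,
    frac_isoform_specified = 0.25,
    n_datasets = 19L,
    samples_per_dataset = 20L,
    corr_strength_true = 0.8,
    corr_strength_false = 0,
    dataset_presence = 0.95,
    p_membrane = 0.1,
    p_nucleus = 0.4,
    n_go_terms = 40L,
    n_pathway_terms = 15L,
    annotation_coherence = 0.9,
    n_planted_modules = 4L,
    planted_module_size_range = c(5L, 8L),
    timestamp_range = c("2008-01-01", "2013-06-30"),
    seed) {
  if (missing(seed) || is.null(seed)) stop("synthetic world: seed is mandatory")
  cfg <- as.list(environment())
  probs <- c(cfg$true_iii_rate, cfg$frac_isoform_specified,
             cfg$dataset_presence, cfg$p_membrane, cfg$p_nucleus,
             cfg$annotation_coherence, cfg$corr_strength_true,
             cfg$corr_strength_false, cfg$ddi_background_density,
             cfg$p_ddi_true)
  if (any(probs < 0 | probs > 1))
    stop("synthetic world: probabilities must lie in [0, 1]")
  if (cfg$samples_per_dataset < 2)
    stop("synthetic world: samples_per_dataset must be >= 2")
  if (cfg$n_genes < 1 || cfg$n_domains < 1)
    stop("synthetic world: counts must be positive")
  if (cfg$n_planted_modules > 0 &&
      cfg$n_planted_modules * max(cfg$planted_module_size_range) > cfg$n_genes)
    stop("synthetic world: planted modules exceed the gene pool")
  structure(cfg, class = "iii_world_config")
}

#' Generate a synthetic world
#'
#' Fully deterministic given `config$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param config an `iii_world_config`.
#' @return Object of class `iii_world`: list with the six pipeline inputs
#'   (`catalog`, `ppi`, `ddi`, `datasets`, `localization`, `annotation`),
#'   ground `truth` (`true_iii` pair data frame, `planted_modules` member
#'   sets) and the `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "iii_world_config"))
  with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_iso <- sample(seq_along(cfg$isoform_count_probs), cfg$n_genes,
                  replace = TRUE, prob = cfg$isoform_count_probs)
  gene_of_iso <- rep(genes, n_iso)
  iso_ids <- paste0(gene_of_iso, ".",
                    unlist(lapply(n_iso, seq_len), use.names = FALSE))
  domain_pool <- sprintf("PF%05d", seq_len(cfg$n_domains))
  n_dom <- sample(seq(cfg$domains_per_isoform[1], cfg$domains_per_isoform[2]),
                  length(iso_ids), replace = TRUE)
  domains <- lapply(n_dom, function(k) sample(domain_pool, k))
  catalog <- new_catalog(iso_ids, gene_of_iso, domains,
                         mrna_length = sample(500:12000, length(iso_ids),
                                              replace = TRUE),
                         protein_length = sample(80:3000, length(iso_ids),
                                                 replace = TRUE))
  iso_of_gene <- split(iso_ids, gene_of_iso)

  # planted clique modules on disjoint gene sets; one member isoform per gene
  planted <- list()
  used_genes <- character(0)
  if (cfg$n_planted_modules > 0) {
    sizes <- sample(seq(cfg$planted_module_size_range[1],
                        cfg$planted_module_size_range[2]),
                    cfg$n_planted_modules, replace = TRUE)
    for (s in sizes) {
      gs <- sample(setdiff(genes, used_genes), s)
      used_genes <- c(used_genes, gs)
      members <- vapply(gs, function(g) {
        pool <- iso_of_gene[[g]]
        if (length(pool) == 1L) pool else sample(pool, 1)
      }, character(1))
      planted[[length(planted) + 1L]] <- sort(unname(members))
    }
  }
  planted_gene_pairs <- do.call(rbind, lapply(planted, function(m) {
    gs <- sort(unique(catalog$gene_of[m]))
    idx <- utils::combn(length(gs), 2)
    data.frame(gene_a = gs[idx[1, ]], gene_b = gs[idx[2, ]],
               stringsAsFactors = FALSE)
  }))

  # gene-level PPIs: planted-module pairs first, random distinct-gene pairs
  # fill up to n_ppis
  gp <- planted_gene_pairs
  if (is.null(gp)) gp <- data.frame(gene_a = character(0),
                                    gene_b = character(0),
                                    stringsAsFactors = FALSE)
  have <- pair_key(gp$gene_a, gp$gene_b)
  while (nrow(gp) < cfg$n_ppis) {
    need <- cfg$n_ppis - nrow(gp)
    a <- sample(genes, 2 * need, replace = TRUE)
    b <- sample(genes, 2 * need, replace = TRUE)
    ok <- a != b
    cp <- canonical_pair(a[ok], b[ok])
    new <- !duplicated(pair_key(cp$a, cp$b)) &
      !(pair_key(cp$a, cp$b) %in% have)
    add <- utils::head(which(new), need)
    gp <- rbind(gp, data.frame(gene_a = cp$a[add], gene_b = cp$b[add],
                               stringsAsFactors = FALSE))
    have <- c(have, pair_key(cp$a[add], cp$b[add]))
  }

  # ground-truth interacting isoform pairs. Every gene-level PPI is given at
  # least one underlying true isoform pair (the premise behind the rescue
  # rule: a PPI is mediated by at least one isoform pair); additional cross
  # pairs interact with probability true_iii_rate. Planted-clique pairs are
  # true by construction.
  true_a <- character(0); true_b <- character(0)
  planted_key <- character(0)
  for (m in planted) {
    idx <- utils::combn(length(m), 2)
    true_a <- c(true_a, m[idx[1, ]])
    true_b <- c(true_b, m[idx[2, ]])
  }
  if (length(true_a) > 0) {
    cp0 <- canonical_pair(true_a, true_b)
    planted_key <- pair_key(cp0$a, cp0$b)
  }
  for (i in seq_len(nrow(gp))) {
    ia <- iso_of_gene[[gp$gene_a[i]]]
    ib <- iso_of_gene[[gp$gene_b[i]]]
    grid <- expand.grid(a = ia, b = ib, stringsAsFactors = FALSE)
    gcp <- canonical_pair(grid$a, grid$b)
    pick <- stats::runif(nrow(grid)) < cfg$true_iii_rate
    has_true <- any(pick) || any(pair_key(gcp$a, gcp$b) %in% planted_key)
    if (!has_true)
      pick[if (nrow(grid) == 1L) 1L else sample(nrow(grid), 1)] <- TRUE
    true_a <- c(true_a, grid$a[pick])
    true_b <- c(true_b, grid$b[pick])
  }
  tcp <- canonical_pair(true_a, true_b)
  keep <- !duplicated(pair_key(tcp$a, tcp$b))
  true_iii <- data.frame(isoform_a = tcp$a[keep], isoform_b = tcp$b[keep],
                         stringsAsFactors = FALSE)
  true_iii <- true_iii[order(true_iii$isoform_a, true_iii$isoform_b), ,
                       drop = FALSE]
  rownames(true_iii) <- NULL
  true_key <- pair_key(true_iii$isoform_a, true_iii$isoform_b)

  # DDI table: supporting records for true pairs + background noise
  conf_levels <- names(cfg$ddi_confidence_mix)
  da <- character(0); db <- character(0); dc <- character(0)
  supported <- stats::runif(nrow(true_iii)) < cfg$p_ddi_true
  for (i in which(supported)) {
    d1 <- catalog$domains[[true_iii$isoform_a[i]]]
    d2 <- catalog$domains[[true_iii$isoform_b[i]]]
    if (length(d1) == 0 || length(d2) == 0) next
    da <- c(da, if (length(d1) == 1L) d1 else sample(d1, 1))
    db <- c(db, if (length(d2) == 1L) d2 else sample(d2, 1))
    dc <- c(dc, sample(conf_levels, 1, prob = cfg$ddi_confidence_mix))
  }
  n_bg <- round(cfg$ddi_background_density *
                  choose(cfg$n_domains, 2))
  if (n_bg > 0) {
    ba <- sample(domain_pool, n_bg, replace = TRUE)
    bb <- sample(domain_pool, n_bg, replace = TRUE)
    ok <- ba != bb
    da <- c(da, ba[ok]); db <- c(db, bb[ok])
    dc <- c(dc, sample(names(cfg$ddi_background_mix), sum(ok), replace = TRUE,
                       prob = cfg$ddi_background_mix))
  }
  ddi <- new_ddi(da, db, dc)

  # expression: latent factors shared along an edge clique cover of the true
  # interaction graph -- one factor per planted clique module, one per
  # remaining true edge. Pairs sharing no structure have population
  # correlation exactly 0 (plus the optional global background factor); a
  # pair sharing a structure attains |r| = sqrt(q_i q_j) with per-isoform
  # budget q = min(rho, 0.95 / #structures): the target rho when each isoform
  # belongs to a single structure, and the closest feasible attenuation for
  # hubs, whose unit variance must be split across their interactions.
  # Loadings carry random signs so only |r| is informative.
  structures <- planted
  covered <- unlist(lapply(planted, function(m) {
    idx <- utils::combn(length(m), 2)
    pair_key(m[idx[1, ]], m[idx[2, ]])
  }))
  loose <- which(!(true_key %in% covered))
  structures <- c(structures, lapply(loose, function(e)
    c(true_iii$isoform_a[e], true_iii$isoform_b[e])))
  n_struct_of <- table(factor(unlist(structures), levels = iso_ids))
  q <- pmin(cfg$corr_strength_true, 0.95 / pmax(as.numeric(n_struct_of), 1))
  names(q) <- iso_ids
  load_bg <- sqrt(cfg$corr_strength_false)
  sign_iso <- stats::setNames(sample(c(-1, 1), length(iso_ids),
                                     replace = TRUE), iso_ids)
  A <- matrix(0, nrow = length(iso_ids), ncol = max(length(structures), 1),
              dimnames = list(iso_ids, NULL))
  for (s in seq_along(structures)) for (i in structures[[s]])
    A[i, s] <- sign_iso[[i]] * sqrt(q[[i]])
  resid_sd <- sqrt(pmax(1 - rowSums(A^2) - load_bg^2, 0))
  datasets <- vector("list", cfg$n_datasets)
  for (d in seq_len(cfg$n_datasets)) {
    ns <- cfg$samples_per_dataset
    present <- stats::runif(length(iso_ids)) < cfg$dataset_presence
    if (sum(present) < 2)
      present[seq_len(min(2L, length(present)))] <- TRUE
    fac <- matrix(stats::rnorm(ncol(A) * ns), nrow = ncol(A))
    gfac <- stats::rnorm(ns)
    x <- A %*% fac +
      load_bg * sign_iso * matrix(gfac, length(iso_ids), ns, byrow = TRUE) +
      resid_sd * matrix(stats::rnorm(length(iso_ids) * ns),
                        nrow = length(iso_ids))
    m <- pmax(8 + x, 0)   # sd 1 around mean 8: non-negative in practice
    rownames(m) <- iso_ids
    colnames(m) <- paste0("s", seq_len(ns))
    datasets[[d]] <- new_expression(sprintf("d%d", d),
                                    m[present, , drop = FALSE])
  }

  # PPI records: uniform timestamps; a fraction carry an isoform
  # specification drawn from the PPI's true pairs
  t0 <- as.Date(cfg$timestamp_range[1])
  t1 <- as.Date(cfg$timestamp_range[2])
  stamps <- t0 + sample.int(as.integer(t1 - t0) + 1L, nrow(gp),
                            replace = TRUE) - 1L
  iso_a <- rep(NA_character_, nrow(gp))
  iso_b <- rep(NA_character_, nrow(gp))
  specify <- stats::runif(nrow(gp)) < cfg$frac_isoform_specified
  for (i in which(specify)) {
    ia <- iso_of_gene[[gp$gene_a[i]]]
    ib <- iso_of_gene[[gp$gene_b[i]]]
    grid <- expand.grid(a = ia, b = ib, stringsAsFactors = FALSE)
    cp <- canonical_pair(grid$a, grid$b)
    is_true <- pair_key(cp$a, cp$b) %in% true_key
    if (!any(is_true)) next
    j <- which(is_true)[if (sum(is_true) == 1L) 1L
                        else sample(sum(is_true), 1)]
    iso_a[i] <- grid$a[j]
    iso_b[i] <- grid$b[j]
  }
  ppi <- new_ppi(gp$gene_a, gp$gene_b, iso_a, iso_b, stamps)

  # localization: independent membrane/nucleus priors, cytoplasm otherwise
  loc <- lapply(seq_along(iso_ids), function(i) {
    labs <- character(0)
    if (stats::runif(1) < cfg$p_membrane) labs <- c(labs, "plasma_membrane")
    if (stats::runif(1) < cfg$p_nucleus) labs <- c(labs, "nucleus")
    if (length(labs) == 0) labs <- "cytoplasm"
    labs
  })
  localization <- new_localization(stats::setNames(loc, iso_ids), catalog)

  # annotation: one coherent GO term per planted module (+ pathway term for
  # every other module), then gene-level background terms propagated to all
  # of a gene's isoforms
  term_id <- character(0); term_ns <- character(0); term_members <- list()
  for (i in seq_along(planted)) {
    m <- planted[[i]]
    core <- sample(m, max(2L, round(cfg$annotation_coherence * length(m))))
    extra <- sample(setdiff(iso_ids, m), 2)
    term_id <- c(term_id, sprintf("GO:MOD%03d", i))
    term_ns <- c(term_ns, "GO")
    term_members <- c(term_members, list(c(core, extra)))
    if (i %% 2 == 1L) {
      term_id <- c(term_id, sprintf("path:MOD%03d", i))
      term_ns <- c(term_ns, "pathway")
      term_members <- c(term_members, list(c(core, extra)))
    }
  }
  n_bg_go <- max(cfg$n_go_terms - sum(term_ns == "GO"), 0L)
  n_bg_pw <- max(cfg$n_pathway_terms - sum(term_ns == "pathway"), 0L)
  for (i in seq_len(n_bg_go + n_bg_pw)) {
    gs <- sample(genes, min(length(genes), sample(3:10, 1)))
    term_members <- c(term_members,
                      list(unlist(iso_of_gene[gs], use.names = FALSE)))
    if (i <= n_bg_go) {
      term_id <- c(term_id, sprintf("GO:%07d", i))
      term_ns <- c(term_ns, "GO")
    } else {
      term_id <- c(term_id, sprintf("path:hsa%05d", i - n_bg_go))
      term_ns <- c(term_ns, "pathway")
    }
  }
  annotation <- new_annotation(term_id, term_ns, term_members, catalog)

  structure(list(catalog = catalog, ppi = ppi, ddi = ddi,
                 datasets = datasets, localization = localization,
                 annotation = annotation,
                 truth = list(true_iii = true_iii, planted_modules = planted),
                 config = cfg),
            class = "iii_world")
}

#' @export
print.iii_world <- function(x, ...) {
  cat(sprintf(paste0("iii_world: %d isoforms / %d genes, %d PPI records, ",
                     "%d true interactions, %d planted modules, %d datasets\n"),
              nrow(x$catalog$isoforms),
              length(unique(x$catalog$isoforms$gene_id)),
              nrow(x$ppi), nrow(x$truth$true_iii),
              length(x$truth$planted_modules), length(x$datasets)))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits every pipeline input in its TSV dialect: `catalog.tsv`, `ppi.tsv`,
#' `ddi.tsv`, `localization.tsv`, `annotation.tsv` and one
#' `expression/<dataset_id>.tsv` per dataset. Reading the files back
#' reproduces the world's public parts (ground truth is not written).
#'
#' @param world an `iii_world`.
#' @param directory output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
world_to_files <- function(world, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(directory, "expression"), showWarnings = FALSE)
  paths <- c(catalog = file.path(directory, "catalog.tsv"),
             ppi = file.path(directory, "ppi.tsv"),
             ddi = file.path(directory, "ddi.tsv"),
             localization = file.path(directory, "localization.tsv"),
             annotation = file.path(directory, "annotation.tsv"))
  iso <- world$catalog$isoforms
  write_tsv(data.frame(
    isoform_id = iso$isoform_id, gene_id = iso$gene_id,
    domains = join_multi(world$catalog$domains[iso$isoform_id]),
    mrna_length = iso$mrna_length, protein_length = iso$protein_length,
    stringsAsFactors = FALSE), paths["catalog"])
  ppi <- world$ppi
  write_tsv(data.frame(
    gene_a = ppi$gene_a, gene_b = ppi$gene_b,
    isoform_a = ifelse(is.na(ppi$isoform_a), "", ppi$isoform_a),
    isoform_b = ifelse(is.na(ppi$isoform_b), "", ppi$isoform_b),
    timestamp = format(ppi$timestamp, "%Y-%m-%d"),
    stringsAsFactors = FALSE), paths["ppi"])
  write_tsv(as.data.frame(unclass(world$ddi), stringsAsFactors = FALSE),
            paths["ddi"])
  write_tsv(data.frame(isoform_id = names(world$localization),
                       compartments = join_multi(world$localization),
                       stringsAsFactors = FALSE), paths["localization"])
  write_tsv(data.frame(term_id = world$annotation$terms$term_id,
                       namespace = world$annotation$terms$namespace,
                       isoform_ids = join_multi(world$annotation$members),
                       stringsAsFactors = FALSE), paths["annotation"])
  for (d in world$datasets) {
    p <- file.path(directory, "expression", paste0(d$dataset_id, ".tsv"))
    df <- data.frame(isoform_id = rownames(d$matrix), stringsAsFactors = FALSE)
    for (j in seq_len(ncol(d$matrix)))
      df[[colnames(d$matrix)[j]]] <- format_num(d$matrix[, j])
    write_tsv(df, p)
    paths[d$dataset_id] <- p
  }
  invisible(paths)
}

#' Read a world directory back into memory
#' @param directory a directory written by [world_to_files()].
#' @return List with the six pipeline inputs (no ground truth).
#' @export
read_world_files <- function(directory) {
  catalog <- read_isoform_catalog(file.path(directory, "catalog.tsv"))
  expr_dir <- file.path(directory, "expression")
  files <- sort(list.files(expr_dir, pattern = "\\.tsv$", full.names = TRUE))
  datasets <- lapply(files, read_expression_matrix, catalog = catalog)
  list(catalog = catalog,
       ppi = read_ppi_table(file.path(directory, "ppi.tsv")),
       ddi = read_ddi_table(file.path(directory, "ddi.tsv")),
       datasets = datasets,
       localization = read_localization(file.path(directory,
                                                  "localization.tsv"),
                                        catalog),
       annotation = read_annotation(file.path(directory, "annotation.tsv"),
                                    catalog))
}

#' Simulate feature/label pairs from the logistic model family
#'
#' Draws feature vectors (uniform correlations, categorical DDI scores) and
#' labels from the exact generating model
#' `logit(p) = a0 + sum a_k E_k + a_ddi DDI`; used to validate coefficient
#' recovery of the fitting routine.
#'
#' @param n number of pairs.
#' @param alpha0 intercept.
#' @param alpha_corr numeric vector of dataset coefficients (length K).
#' @param alpha_ddi DDI coefficient.
#' @param seed integer seed.
#' @return List with `features` (n x (K+1) matrix, columns E1..EK, ddi),
#'   `labels` and the generating `coefficients` (named, model order).
#' @export
simulate_logistic_pairs <- function(n, alpha0 = -3, alpha_corr = rep(2, 5),
                                    alpha_ddi = 0.8, seed) {
  with_seed(seed, {
    K <- length(alpha_corr)
    E <- matrix(stats::runif(n * K), nrow = n,
                dimnames = list(NULL, paste0("E", seq_len(K))))
    ddi <- sample(0:3, n, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
    X <- cbind(E, ddi = ddi)
    eta <- alpha0 + drop(X %*% c(alpha_corr, alpha_ddi))
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    list(features = X, labels = y,
         coefficients = stats::setNames(c(alpha0, alpha_corr, alpha_ddi),
                                        c("(Intercept)", colnames(E), "ddi")))
  })
}
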