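test_that("catalog reader handles minimal, empty-domain and invalid inputs", {
  p <- write_lines_tsv(c("isoform_id\tgene_id\tdomains",
                         "I1\tG1\tPF1;PF2",
                         "I2\tG1\t"))
  cat <- read_isoform_catalog(p)
  expect_equal(nrow(cat$isoforms), 2)
  expect_equal(length(unique(cat$isoforms$gene_id)), 1)
  expect_equal(cat$domains[["I1"]], c("PF1", "PF2"))
  expect_equal(cat$domains[["I2"]], character(0))

  dup <- write_lines_tsv(c("isoform_id\tgene_id\tdomains",
                           "NM_138578\tBCL2L1\tPF1",
                           "NM_138578\tBCL2L1\tPF2"))
  expect_error(read_isoform_catalog(dup), "NM_138578",
               class = "iii_validation_error")
  expect_error(read_isoform_catalog(tempfile()), class = "iii_io_error")
})

test_that("ppi reader canonicalizes, collapses duplicates, rejects bad dates", {
  p <- write_lines_tsv(c("gene_a\tgene_b\tisoform_a\tisoform_b\ttimestamp",
                         "A\tB\t\t\t2011-05-01",
                         "B\tA\t\t\t2011-05-01",
                         "B\tA\tIB1\tIA1\t2012-06-01"))
  ppi <- read_ppi_table(p)
  expect_equal(nrow(ppi), 2) # swapped duplicate collapsed
  expect_true(all(ppi$gene_a <= ppi$gene_b))
  # isoforms swapped consistently with their genes
  row <- ppi[!is.na(ppi$isoform_a), ]
  expect_equal(row$gene_a, "A")
  expect_equal(row$isoform_a, "IA1")
  expect_true(is.na(ppi$isoform_a[1]))

  bad <- write_lines_tsv(c("gene_a\tgene_b\tisoform_a\tisoform_b\ttimestamp",
                           "A\tB\t\t\t2013-13-40"))
  expect_error(read_ppi_table(bad), "2013-13-40",
               class = "iii_validation_error")
  half <- write_lines_tsv(c("gene_a\tgene_b\tisoform_a\tisoform_b\ttimestamp",
                            "A\tB\tIA1\t\t2013-01-01"))
  expect_error(read_ppi_table(half), class = "iii_validation_error")
})

test_that("ppi canonicalization is idempotent", {
  set.seed(5)
  genes <- sprintf("G%02d", 1:12)
  ppi <- new_ppi(sample(genes, 30, TRUE), sample(genes, 30, TRUE),
                 timestamp = as.Date("2010-01-01") + sample(0:1500, 30))
  again <- new_ppi(ppi$gene_a, ppi$gene_b, ppi$isoform_a, ppi$isoform_b,
                   ppi$timestamp)
  expect_identical(as.data.frame(ppi), as.data.frame(again))
})

test_that("ddi / expression / localization readers validate their dialects", {
  d <- write_lines_tsv(c("domain_a\tdomain_b\tconfidence",
                         "PF00001\tPF00002\thigh"))
  ddi <- read_ddi_table(d)
  expect_s3_class(ddi, "iii_ddi")
  expect_equal(ddi$confidence, "high")
  bad <- write_lines_tsv(c("domain_a\tdomain_b\tconfidence",
                           "PF1\tPF2\tcertain"))
  expect_error(read_ddi_table(bad), "certain",
               class = "iii_validation_error")

  one_col <- write_lines_tsv(c("isoform_id\ts1", "I1\t3.5"))
  expect_error(read_expression_matrix(one_col), ">= 2 sample",
               class = "iii_validation_error")
  ok <- write_lines_tsv(c("isoform_id\ts1\ts2", "I1\t3.5\t4", "I2\t1\t0"))
  expr <- read_expression_matrix(ok, dataset_id = "dX")
  expect_equal(dim(expr$matrix), c(2L, 2L))
  neg <- write_lines_tsv(c("isoform_id\ts1\ts2", "I1\t-1\t4"))
  expect_error(read_expression_matrix(neg), class = "iii_validation_error")

  l <- write_lines_tsv(c("isoform_id\tcompartments",
                         "I1\tplasma_membrane;nucleus",
                         "I2\tcytoplasm"))
  loc <- read_localization(l)
  expect_equal(dual_localized(loc), "I1")
  badl <- write_lines_tsv(c("isoform_id\tcompartments", "I1\tmoon"))
  expect_error(read_localization(badl), "moon",
               class = "iii_validation_error")
})

test_that("annotation reader validates namespace and non-empty sets", {
  a <- write_lines_tsv(c("term_id\tnamespace\tisoform_ids",
                         "GO:1\tGO\tI1;I2",
                         "hsa01\tpathway\tI2"))
  ann <- read_annotation(a)
  expect_equal(ann$members[["GO:1"]], c("I1", "I2"))
  empty <- write_lines_tsv(c("term_id\tnamespace\tisoform_ids",
                             "GO:1\tGO\t"))
  expect_error(read_annotation(empty), class = "iii_validation_error")
  badns <- write_lines_tsv(c("term_id\tnamespace\tisoform_ids",
                             "X\tontology\tI1"))
  expect_error(read_annotation(badns), class = "iii_validation_error")
})

test_that("prediction and module writers round-trip losslessly", {
  preds <- data.frame(
    isoform_a = c("I1", "I2"), isoform_b = c("I3", "I4"),
    gene_a = c("G1", "G2"), gene_b = c("G3", "G4"),
    logit_score = c(2.7182818284590451, -0.1),
    probability = plogis(c(2.7182818284590451, -0.1)),
    tier = c("high", "rescued"), ddi_score = c(3L, 0L),
    d1 = c(0.123456789012345678, NA), d2 = c(1.0, 0.5),
    stringsAsFactors = FALSE)
  attr(preds, "dataset_ids") <- c("d1", "d2")
  class(preds) <- c("iii_predictions", "data.frame")
  path <- tempfile(fileext = ".tsv")
  write_predictions(preds, path)
  back <- read_predictions(path)
  expect_identical(back$logit_score, preds$logit_score)
  expect_identical(back$d1, preds$d1)
  expect_identical(back$tier, preds$tier)
  expect_identical(attr(back, "dataset_ids"), c("d1", "d2"))
  # one data row per prediction, one column per dataset
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(sum(hdr %in% c("d1", "d2")), 2)

  empty <- preds[0, ]
  attr(empty, "dataset_ids") <- c("d1", "d2")
  class(empty) <- c("iii_predictions", "data.frame")
  expect_warning(write_predictions(empty, tempfile(fileext = ".tsv")),
                 "empty")

  mods <- structure(list(
    list(module_id = "M0001", members = c("I1", "I2", "I3"), density = 1),
    list(module_id = "M0002", members = c("I2", "I4", "I5", "I6"),
         density = 5 / 6)), class = "iii_modules")
  mpath <- tempfile(fileext = ".tsv")
  write_modules(mods, mpath, top_terms = list(M0001 = c("GO:1", "GO:2")))
  mback <- read_modules(mpath)
  expect_equal(mback[[1]]$members, c("I1", "I2", "I3"))
  expect_identical(mback[[2]]$density, 5 / 6)
  expect_equal(mback[[1]]$top_terms, c("GO:1", "GO:2"))
  expect_equal(mback[[2]]$top_terms, character(0))
})

test_that("world files round-trip through the readers", {
  w <- small_world(301L)
  d <- withr::local_tempdir()
  world_to_files(w, d)
  back <- read_world_files(d)
  expect_identical(back$catalog$isoforms$isoform_id,
                   w$catalog$isoforms$isoform_id)
  expect_identical(back$catalog$domains, w$catalog$domains)
  expect_identical(as.data.frame(back$ppi), as.data.frame(w$ppi))
  expect_identical(as.data.frame(back$ddi), as.data.frame(w$ddi))
  expect_identical(unclass(back$localization), unclass(w$localization))
  expect_identical(back$annotation$members, w$annotation$members)
  expect_equal(length(back$datasets), length(w$datasets))
  for (k in seq_along(w$datasets))
    expect_identical(back$datasets[[k]]$matrix, w$datasets[[k]]$matrix)
  # row counts match world cardinalities
  expect_equal(length(readLines(file.path(d, "ppi.tsv"))) - 1L, nrow(w$ppi))
  expect_equal(length(readLines(file.path(d, "catalog.tsv"))) - 1L,
               nrow(w$catalog$isoforms))
})
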