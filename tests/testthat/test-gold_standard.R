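make_cat <- function() {
  new_catalog(c("A1", "B1", "C1", "C2", "D1"),
              c("GA", "GB", "GC", "GC", "GD"))
}

test_that("build_gsp applies the isoform-specified and single-isoform rules", {
  cat <- make_cat()
  ppi <- new_ppi(gene_a = c("GA", "GA", "GC"),
                 gene_b = c("GB", "GC", "GD"),
                 isoform_a = c(NA, "A1", NA),
                 isoform_b = c(NA, "C2", NA),
                 timestamp = as.Date(c("2011-05-01", "2012-06-01",
                                       "2010-01-01")))
  gsp <- build_gsp(ppi, cat)
  # (GA,GB): both single-isoform -> A1-B1; (GA,GC): isoform-specified A1-C2;
  # (GC,GD): GC has 2 isoforms -> contributes nothing
  expect_equal(nrow(gsp), 2)
  expect_setequal(pkey(gsp$isoform_a, gsp$isoform_b),
                  c(pkey("A1", "B1"), pkey("A1", "C2")))
  expect_equal(gsp$provenance[gsp$isoform_a == "A1" & gsp$isoform_b == "C2"],
               "isoform_specified")
  expect_equal(gsp$provenance[pkey(gsp$isoform_a, gsp$isoform_b) ==
                                pkey("A1", "B1")], "single_isoform")

  bad <- new_ppi("GA", "GC", "B1", "C1", as.Date("2012-01-01"))
  expect_error(build_gsp(bad, cat), "mismatch",
               class = "iii_validation_error")
})

test_that("gsp union matches brute-force rule application on random worlds", {
  set.seed(20)
  for (rep in 1:30) {
    n_genes <- 8
    genes <- sprintf("g%d", 1:n_genes)
    n_iso <- sample(1:3, n_genes, TRUE)
    cat <- new_catalog(unlist(mapply(function(g, k) paste0(g, "_", 1:k),
                                     genes, n_iso, SIMPLIFY = FALSE)),
                       rep(genes, n_iso))
    # random gene pairs, some isoform-specified with matching isoforms
    ga <- sample(genes, 10, TRUE); gb <- sample(genes, 10, TRUE)
    ia <- rep(NA_character_, 10); ib <- rep(NA_character_, 10)
    for (i in 1:10) {
      if (runif(1) < 0.4) {
        ia[i] <- sample(isoforms_of_gene(cat, ga[i]), 1)
        ib[i] <- sample(isoforms_of_gene(cat, gb[i]), 1)
      }
    }
    ppi <- new_ppi(ga, gb, ia, ib,
                   as.Date("2011-01-01") + sample(0:900, 10, TRUE))
    gsp <- build_gsp(ppi, cat)

    # oracle: enumerate expected pairs rule by rule
    want <- character(0)
    for (i in seq_len(nrow(ppi)))
      if (!is.na(ppi$isoform_a[i]))
        want <- c(want, pkey(ppi$isoform_a[i], ppi$isoform_b[i]))
    for (i in seq_len(nrow(ppi))) {
      isoa <- isoforms_of_gene(cat, ppi$gene_a[i])
      isob <- isoforms_of_gene(cat, ppi$gene_b[i])
      if (length(isoa) == 1 && length(isob) == 1)
        want <- c(want, pkey(isoa, isob))
    }
    expect_setequal(pkey(gsp$isoform_a, gsp$isoform_b), unique(want))
  }
})

test_that("timestamp split is strict-after with earliest-record precedence", {
  cat <- make_cat()
  mk <- function(dates) {
    ppi <- new_ppi(rep("GA", length(dates)), rep("GB", length(dates)),
                   timestamp = as.Date(dates))
    gsp <- build_gsp(ppi, cat)
    split_gsp_by_timestamp(gsp, ppi, cat)
  }
  s <- mk("2012-06-01")
  expect_equal(nrow(s$test), 1); expect_equal(nrow(s$train), 0)
  s <- mk("2012-01-01")          # boundary: "after" is strict -> train
  expect_equal(nrow(s$train), 1); expect_equal(nrow(s$test), 0)
  s <- mk(c("2011-12-31", "2013-01-01"))  # earliest governs -> train
  expect_equal(nrow(s$train), 1)
  s <- mk(c("2013-01-01", "2011-12-31"))  # order-independent
  expect_equal(nrow(s$train), 1)
})

test_that("split is invariant to record shuffling", {
  w <- small_world(401L)
  gsp <- build_gsp(w$ppi, w$catalog)
  ref <- split_gsp_by_timestamp(gsp, w$ppi, w$catalog)
  set.seed(4)
  for (i in 1:5) {
    perm <- w$ppi[sample(nrow(w$ppi)), , drop = FALSE]
    class(perm) <- class(w$ppi)
    s <- split_gsp_by_timestamp(gsp, perm, w$catalog)
    expect_identical(s$train$isoform_a, ref$train$isoform_a)
    expect_identical(s$test$isoform_a, ref$test$isoform_a)
  }
})

test_that("build_gsn crosses membrane-only with nucleus-only isoforms", {
  covered <- c("M1", "M2", "N1", "N2", "N3", "X1")
  loc <- new_localization(list(
    M1 = "plasma_membrane", M2 = "plasma_membrane",
    N1 = "nucleus", N2 = "nucleus", N3 = "nucleus",
    X1 = c("plasma_membrane", "nucleus")))
  gsn <- build_gsn(covered, loc)
  expect_equal(nrow(gsn), 6)  # 2 x 3 cross product
  expect_false(any(gsn$isoform_a == "X1" | gsn$isoform_b == "X1"))
})

test_that("build_gsn equals exhaustive pair filtering on random localizations", {
  set.seed(21)
  for (rep in 1:25) {
    iso <- sprintf("i%02d", 1:30)
    loc_list <- lapply(iso, function(i) {
      labs <- c(if (runif(1) < 0.3) "plasma_membrane",
                if (runif(1) < 0.4) "nucleus",
                if (runif(1) < 0.3) "cytoplasm")
      if (is.null(labs)) "cytoplasm" else labs
    })
    names(loc_list) <- iso
    loc <- new_localization(loc_list)
    covered <- sample(iso, 20)
    gsp <- data.frame(isoform_a = pmin(sample(covered, 5), sample(covered, 5)),
                      isoform_b = pmax(sample(covered, 5), sample(covered, 5)))
    gsn <- build_gsn(covered, loc, gsp)
    want <- oracle_gsn(covered, loc_list, gsp)
    expect_setequal(pkey(gsn$isoform_a, gsn$isoform_b),
                    pkey(want$isoform_a, want$isoform_b))
    # bipartite: every pair joins a membrane-only to a nucleus-only isoform
    for (i in seq_len(nrow(gsn))) {
      la <- loc[[gsn$isoform_a[i]]]; lb <- loc[[gsn$isoform_b[i]]]
      expect_true(xor("plasma_membrane" %in% la, "plasma_membrane" %in% lb))
      expect_true(xor("nucleus" %in% la, "nucleus" %in% lb))
    }
  }
})

test_that("gold standard has no GSP/GSN leakage and respects invariants", {
  for (seed in c(402L, 403L, 404L)) {
    w <- small_world(seed)
    gold <- build_gold_standard(w$ppi, w$catalog, w$localization)
    pos <- rbind(gold$positives_train[, 1:2], gold$positives_test[, 1:2])
    expect_length(intersect(pkey(pos$isoform_a, pos$isoform_b),
                            pkey(gold$negatives$isoform_a,
                                 gold$negatives$isoform_b)), 0)
    expect_length(intersect(pkey(gold$positives_train$isoform_a,
                                 gold$positives_train$isoform_b),
                            pkey(gold$positives_test$isoform_a,
                                 gold$positives_test$isoform_b)), 0)
    expect_true(all(c(gold$negatives$isoform_a, gold$negatives$isoform_b)
                    %in% gold$covered_isoforms))
  }
})

test_that("adding isoforms to a gene shrinks its single-isoform contribution", {
  cat1 <- new_catalog(c("A1", "B1"), c("GA", "GB"))
  cat2 <- new_catalog(c("A1", "A2", "B1"), c("GA", "GA", "GB"))
  ppi <- new_ppi("GA", "GB", timestamp = as.Date("2011-01-01"))
  expect_equal(nrow(build_gsp(ppi, cat1)), 1)
  expect_equal(nrow(build_gsp(ppi, cat2)), 0)
})
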