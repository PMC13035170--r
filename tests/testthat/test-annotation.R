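# Over-representation analysis and ortholog agreement.

makeTerms <- function(sets) {
  data.frame(term_id = names(sets),
             term_name = paste("term", names(sets)),
             genes = I(unname(sets)), stringsAsFactors = FALSE)
}

test_that("hypergeometric p-values equal the exhaustive enumeration oracle (background <= 60)", {
  set.seed(41)
  for (i in 1:40) {
    N <- sample(10:60, 1)
    background <- sprintf("g%03d", seq_len(N))
    m <- sample(2:(N - 2), 1)
    k <- sample(2:(N - 2), 1)
    term <- sample(background, m)
    query <- sample(background, k)
    x <- length(intersect(query, term))
    res <- enrich(query, makeTerms(list(T1 = term)), background)
    expect_equal(res$p_value, hyperTailOracle(x, m, N, k),
                 tolerance = 1e-12)
    expect_equal(res$overlap, x)
  }
})

test_that("degenerate containment: query equal to the whole background gives p = 1", {
  bg <- sprintf("g%d", 1:20)
  term <- bg[1:8]
  res <- enrich(bg, makeTerms(list(T1 = term)), bg)
  expect_equal(res$p_value, 1)
  # strict subset query containing the whole term: p < 1
  res2 <- enrich(bg[1:10], makeTerms(list(T1 = term)), bg)
  expect_lt(res2$p_value, 1)
})

test_that("BH adjustment is the step-up correction, results sorted, bins assigned", {
  set.seed(42)
  bg <- sprintf("g%03d", 1:300)
  sets <- c(list(HIT = sample(bg[1:40], 30)),
            lapply(1:8, function(i) sample(bg, 25)))
  names(sets) <- c("HIT", paste0("R", 1:8))
  query <- bg[1:40]
  res <- enrich(query, makeTerms(sets), bg)
  expect_equal(res$fdr, stats::p.adjust(res$p_value, "BH"),
               tolerance = 1e-12)
  expect_true(!is.unsorted(res$fdr))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  expect_equal(res$fdr_bin,
               ifelse(res$fdr < 1e-4, "<1e-4",
                      ifelse(res$fdr < 1e-3, "<0.001",
                             ifelse(res$fdr < 1e-2, "<0.01", "ns"))))
  expect_equal(res$term_id[1], "HIT")
})

test_that("enrichment input contracts: empty query, foreign genes, zero-overlap terms", {
  bg <- sprintf("g%d", 1:50)
  terms <- makeTerms(list(A = bg[1:10], B = c("zz1", "zz2")))
  expect_error(enrich(character(), terms, bg), "empty")
  expect_error(enrich(c(bg[1:5], "alien"), terms, bg), "alien")
  expect_message(res <- enrich(bg[1:5], terms, bg), "no background overlap")
  expect_equal(nrow(res), 1)  # term B skipped, not dropped silently as NA
})

test_that("GMT files round-trip term ids, names and gene sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO:0008380\tRNA splicing\tg1\tg2\tg3\tg2",
               "GO:0003723\tRNA binding\tg2\tg4"), path)
  terms <- readGMT(path)
  expect_equal(terms$term_id, c("GO:0008380", "GO:0003723"))
  expect_equal(terms$term_name[1], "RNA splicing")
  expect_setequal(terms$genes[[1]], c("g1", "g2", "g3"))  # dup collapsed
  writeLines(c("GO:1\tx\tg1", "GO:1\ty\tg2"), path)
  expect_error(readGMT(path), "duplicate term id")
  writeLines("GO:1\tonlytwo", path)
  expect_error(readGMT(path), "fewer than 3")
})

toyOrthologs <- function() {
  genes <- sprintf("wbg%d", 1:9)
  mappedA <- c(rep(TRUE, 7), FALSE, FALSE)   # UniProt-like source maps 7
  mappedB <- c(rep(TRUE, 5), rep(FALSE, 4))  # OrthoList2-like source maps 5
  rbind(
    data.frame(worm_gene = genes, source = "A",
               human_ortholog = ifelse(mappedA, toupper(genes), NA)),
    data.frame(worm_gene = genes, source = "B",
               human_ortholog = ifelse(mappedB, toupper(genes), NA)))
}

test_that("two-source ortholog agreement reproduces the 7/5/2-of-9 accounting", {
  rec <- toyOrthologs()
  out <- orthologAgreement(rec)
  expect_equal(out$nGenes, 9)
  expect_equal(unname(out$perSource[c("A", "B")]), c(7L, 5L))
  expect_equal(out$both, 5)
  expect_equal(out$neither, 2)
  expect_equal(out$atLeastOne, 7)
  expect_equal(round(out$pctAtLeastOne), 78)  # 7/9 = 77.8%
  # row order invariance
  out2 <- orthologAgreement(rec[sample(nrow(rec)), ])
  expect_equal(out2$pctAtLeastOne, out$pctAtLeastOne)
  expect_equal(out2$both, out$both)
})

test_that("ortholog edge cases: all unmapped, identical sources, malformed input", {
  genes <- sprintf("wbg%d", 1:4)
  none <- rbind(
    data.frame(worm_gene = genes, source = "A", human_ortholog = NA),
    data.frame(worm_gene = genes, source = "B", human_ortholog = NA))
  expect_equal(orthologAgreement(none)$pctAtLeastOne, 0)
  same <- rbind(
    data.frame(worm_gene = genes, source = "A", human_ortholog = toupper(genes)),
    data.frame(worm_gene = genes, source = "B", human_ortholog = toupper(genes)))
  outSame <- orthologAgreement(same)
  expect_equal(outSame$both, unname(outSame$perSource[["A"]]))

  dup <- rbind(none, none[1, ])
  expect_error(orthologAgreement(dup), "duplicate")
  partial <- none[-1, ]  # wbg1 present only in source B
  expect_error(orthologAgreement(partial), "missing from source")
})

test_that("ortholog CSV reader labels sources and encodes absence as NA", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("worm_gene,human_ortholog", "ogt-1,OGT", "unc-13,",
               "pdi-2,P4HB"), path)
  tab <- readOrthologTable(path, "UniProt")
  expect_equal(tab$source, rep("UniProt", 3))
  expect_true(is.na(tab$human_ortholog[2]))
  writeLines("gene,ortholog", path)
  expect_error(readOrthologTable(path, "x"), "worm_gene")
})
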