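de_row <- function(tx, gene, fc, p, q) {
  tibble::tibble(transcript_id = tx, gene_symbol = gene,
                 log2_fold_change = fc, p_value = p, q_value = q)
}

test_that("DE filter applies strict FDR and linear fold-change cutoffs", {
  recs <- dplyr::bind_rows(
    de_row("t1", "G1", 1.5, 0.001, 0.01),  # kept
    de_row("t2", "G2", 0.9, 0.001, 0.01),  # |FC| < 2
    de_row("t3", "G3", 3.0, 0.01, 0.05),   # q not < 0.05 (strict)
    de_row("t4", "G4", -1.0, 0.001, 0.01)  # kept: FC exactly 2, boundary in
  )
  kept <- filter_de(recs)
  expect_setequal(kept$transcript_id, c("t1", "t4"))
  # subset of input and idempotent
  expect_true(all(kept$transcript_id %in% recs$transcript_id))
  expect_identical(filter_de(kept), kept)
})

test_that("symbol collapse keeps the lowest-p transcript deterministically", {
  recs <- dplyr::bind_rows(
    de_row("t1", "GENE1", 2, 0.01, 0.02),
    de_row("t2", "GENE1", 3, 0.001, 0.005),
    de_row("t3", "GENE2", 1.5, 0.04, 0.08),
    de_row("t5", "GENE3", 1, 0.02, 0.05),
    de_row("t4", "GENE3", -1, 0.02, 0.05) # tie: lexicographically smaller id
  )
  out <- collapse_by_symbol(recs)
  expect_equal(out$transcript_id[out$gene_symbol == "GENE1"], "t2")
  expect_equal(out$transcript_id[out$gene_symbol == "GENE2"], "t3")
  expect_equal(out$transcript_id[out$gene_symbol == "GENE3"], "t4")
  expect_identical(collapse_by_symbol(out)$transcript_id, out$transcript_id)

  noname <- dplyr::bind_rows(recs, de_row("t9", "", 2, 0.001, 0.001))
  expect_warning(out2 <- collapse_by_symbol(noname), "skipped")
  expect_equal(attr(out2, "skipped")$transcript_id, "t9")
})

test_that("symbol collapse equals a brute-force per-symbol minimum scan", {
  set.seed(31)
  n <- 200
  recs <- de_row(sprintf("tx%03d", sample(n)),
                 sample(sprintf("G%02d", 1:40), n, TRUE),
                 rnorm(n), runif(n), runif(n))
  out <- collapse_by_symbol(recs)
  for (g in unique(recs$gene_symbol)) {
    sub <- recs[recs$gene_symbol == g, ]
    best <- sub[sub$p_value == min(sub$p_value), ]
    best <- best[order(best$transcript_id)[1], ]
    expect_identical(out$transcript_id[out$gene_symbol == g],
                     best$transcript_id)
  }
  expect_lte(nrow(out), nrow(recs))
})

test_that("signed rank scores are the signed negative log q, sorted", {
  recs <- dplyr::bind_rows(
    de_row("t1", "UP", 2, 0.001, 0.01),
    de_row("t2", "DOWN", -2, 0.001, 0.01),
    de_row("t3", "NULL", 5, 0.9, 1)
  )
  sc <- signed_rank_scores(recs)
  expect_equal(sc$rank_score[sc$gene_symbol == "UP"], 2)
  expect_equal(sc$rank_score[sc$gene_symbol == "DOWN"], -2)
  expect_equal(sc$rank_score[sc$gene_symbol == "NULL"], 0)
  expect_equal(sc$gene_symbol[1], "UP") # descending order

  # antisymmetry under a global fold-change sign flip
  flipped <- dplyr::mutate(recs, log2_fold_change = -log2_fold_change)
  sc2 <- signed_rank_scores(flipped)
  expect_equal(
    sc2$rank_score[match(sc$gene_symbol, sc2$gene_symbol)],
    -sc$rank_score
  )

  # zero q floored to half the smallest nonzero q: finite scores
  zero <- dplyr::bind_rows(recs, de_row("t4", "TOP", 3, 0, 0))
  sc3 <- signed_rank_scores(zero)
  expect_true(all(is.finite(sc3$rank_score)))
  expect_equal(sc3$rank_score[sc3$gene_symbol == "TOP"], -log10(0.005))
})

test_that("the .rnk export round-trips losslessly", {
  set.seed(41)
  recs <- de_row(sprintf("t%d", 1:50), sprintf("G%02d", 1:50),
                 rnorm(50), runif(50, 0, 0.1), runif(50, 0.001, 0.2))
  sc <- signed_rank_scores(recs)
  path <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(sc, path)
  back <- read_rnk(path)
  expect_equal(back$gene_symbol, sc$gene_symbol)
  expect_equal(back$rank_score, sc$rank_score)
  # no header line
  expect_equal(length(readLines(path)), nrow(sc))
})

test_that("cross-condition correlation behaves on constructed tables", {
  sim <- simulate_de_tables(n_genes = 300, n_transcripts = 360,
                            frac_significant = 0.3, seed = 5)
  tab <- sim$tables$a
  expect_equal(shared_de_correlation(tab, tab)$r, 1)
  neg <- dplyr::mutate(tab, log2_fold_change = -log2_fold_change)
  expect_equal(shared_de_correlation(tab, neg)$r, -1)
  expect_error(
    shared_de_correlation(tab, dplyr::mutate(tab, q_value = 0.99)),
    class = "spherotax_insufficient_overlap"
  )
})

test_that("paired synthetic tables reproduce the planted fold-change correlation", {
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_de_tables(frac_significant = 0.2, paired = TRUE,
                              cross_correlation = 0.9, seed = s)
    r <- shared_de_correlation(sim$tables$a, sim$tables$b)$r
    if (abs(r - 0.9) <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("DE tables read from disk with Sleuth-style column aliases", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("target_id\text_gene\tb\tpval\tqval",
               "tx1\tG1\t1.5\t0.001\t0.01",
               "tx2\tG2\t-2.5\t0.2\t0.6"), path)
  tab <- read_de_table(path)
  expect_equal(names(tab),
               c("transcript_id", "gene_symbol", "log2_fold_change",
                 "p_value", "q_value"))
  expect_equal(tab$log2_fold_change, c(1.5, -2.5))
})
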