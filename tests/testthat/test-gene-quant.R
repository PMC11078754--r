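test_that("unique-only counting reproduces union-mode ambiguous-discard semantics case by case", {
  mf <- micro_gene_fixture()
  genes <- read_gene_models(mf$gtf)
  frags <- load_fragment_mappings(mf$sam)
  expect_equal(nrow(frags$fragments), mf$n_proper_fragments)

  h <- count_unique_only(frags, genes)
  expect_identical(setNames(h$H, h$gene_id), mf$expected_H)
})

test_that("fractional counting distributes multimappers and applies the ambiguity rule", {
  mf <- micro_gene_fixture()
  genes <- read_gene_models(mf$gtf)
  frags <- load_fragment_mappings(mf$sam)

  cc <- count_multimapper_aware(frags, genes)
  expect_equal(setNames(cc$C, cc$gene_id), mf$expected_C)

  # the same 12 cases through the naive per-fragment loop
  oc <- oracle_gene_counts(pairs_as_df(frags, 50L),
                           data.frame(gene_id = S4Vectors::mcols(genes$exons)$gene_id,
                                      chrom = as.character(seqnames(genes$exons)),
                                      start = start(genes$exons),
                                      end = end(genes$exons)))
  expect_equal(setNames(cc$C, cc$gene_id)[names(oc$C)], oc$C, tolerance = 1e-12)
  h <- count_unique_only(frags, genes)
  expect_equal(as.numeric(setNames(h$H, h$gene_id)[names(oc$H)]),
               as.numeric(oc$H))
})

test_that("overlapping_genes returns the union-mode set over both mates", {
  mf <- micro_gene_fixture()
  genes <- read_gene_models(mf$gtf)
  blocks_a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1101, 1301), width = 50))
  expect_equal(overlapping_genes(blocks_a, genes), "geneA")
  blocks_ab <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1101, 3101), width = 50))
  expect_equal(overlapping_genes(blocks_ab, genes), c("geneA", "geneB"))
  blocks_none <- GenomicRanges::GRanges("chr1", IRanges::IRanges(14001, width = 50))
  expect_equal(overlapping_genes(blocks_none, genes), character(0))
})

test_that("per-fragment mass is in [0,1] and column sums obey H <= C <= fragments", {
  for (fx in list(fx_pe500(), fx_paralog())) {
    genes <- fx_gene_models(fx)
    frags <- load_fragment_mappings(fx$sam[["all"]])
    sets <- fragment_gene_sets(frags, genes)
    mass <- sets[, .(m = sum((n_genes == 1L) / n_mappings)), by = fragment_id]
    expect_true(all(mass$m >= -1e-12 & mass$m <= 1 + 1e-12))
    tab <- gene_count_table(frags, genes, seed = 1L)
    expect_lte(sum(tab$H), sum(tab$C) + 1e-9)
    expect_lte(sum(tab$C), nrow(frags$fragments) + 1e-9)
    # monotonicity on every gene
    expect_true(all(tab$C >= tab$H - 1e-12))
  }
})

test_that("C >= H holds on adversarial nested-gene cases", {
  mf <- micro_gene_fixture()
  genes <- read_gene_models(mf$gtf)
  frags <- load_fragment_mappings(mf$sam)
  tab <- gene_count_table(frags, genes, seed = 3L)
  expect_true(all(tab$C >= tab$H - 1e-12))
  # nested geneE collects nothing: every read overlapping it is ambiguous
  expect_equal(tab[tab$gene_id == "geneE"]$C, 0)
})

test_that("random-selection counts match fractional counts in expectation", {
  mf <- micro_gene_fixture()
  genes <- read_gene_models(mf$gtf)
  frags <- load_fragment_mappings(mf$sam)
  sets <- fragment_gene_sets(frags, genes)
  n_runs <- 2000L
  acc <- matrix(0, nrow = nrow(genes$genes), ncol = n_runs)
  for (s in seq_len(n_runs))
    acc[, s] <- count_random_strategy(frags, genes, seed = s, .sets = sets)$R
  mean_R <- rowMeans(acc)
  cc <- count_multimapper_aware(frags, genes, .sets = sets)$C
  # per-gene binomial SE of the mean over runs
  se <- sqrt(apply(acc, 1, var) / n_runs)
  expect_true(all(abs(mean_R - cc) <= 4 * pmax(se, 1e-3)))
  # the ambiguity rule still applies after selection: geneE never counts
  expect_equal(max(acc[which(genes$genes$gene_id == "geneE"), ]), 0)
})

test_that("expression values and under-quantification flags follow the strict ratio rule", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(sprintf('chr1\tt\tgene\t%d\t%d\t.\t+\t.\tgene_id "g%d"; gene_type "protein_coding";\nchr1\tt\texon\t%d\t%d\t.\t+\t.\tgene_id "g%d"; transcript_id "g%d.1";',
                     c(1, 2001, 4001, 6001), c(1000, 3000, 5000, 7000),
                     1:4, c(1, 2001, 4001, 6001), c(1000, 3000, 5000, 7000),
                     1:4, 1:4), gtf)
  genes <- read_gene_models(gtf)
  counts <- data.table::data.table(
    gene_id = c("g1", "g2", "g3", "g4"),
    H = c(10L, 10L, 0L, 0L),
    C = c(25, 20, 7, 0))
  out <- expression_and_flags(counts, genes, factor = 2)
  expect_equal(out$under_quantified, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$expressed, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$expr_C, counts$C / 1000)
  expect_equal(out$C_rounded, c(25L, 20L, 7L, 0L))
  expect_error(expression_and_flags(
    data.table::data.table(gene_id = "g1", H = -1L, C = 0), genes),
    "negative")
})

test_that("fractional counts round half-up at export", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c('chr1\tt\tgene\t1\t1000\t.\t+\t.\tgene_id "g1"; gene_type "protein_coding";',
               'chr1\tt\texon\t1\t1000\t.\t+\t.\tgene_id "g1"; transcript_id "g1.1";'),
             gtf)
  genes <- read_gene_models(gtf)
  out <- expression_and_flags(
    data.table::data.table(gene_id = "g1", H = 0L, C = 2.5), genes)
  expect_identical(out$C_rounded, 3L)
})

test_that("top-N selection ranks protein-coding genes with a deterministic tie-break", {
  gtf <- tempfile(fileext = ".gtf")
  ids <- c("gA", "gB", "gC", "gD")
  writeLines(unlist(lapply(seq_along(ids), function(i) {
    s <- (i - 1) * 2000 + 1
    c(sprintf('chr1\tt\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_type "%s";',
              s, s + 999, ids[i],
              ifelse(i == 4, "lncRNA", "protein_coding")),
      sprintf('chr1\tt\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s.1";',
              s, s + 999, ids[i], ids[i]))
  })), gtf)
  genes <- read_gene_models(gtf)
  tab <- expression_and_flags(data.table::data.table(
    gene_id = ids, H = c(5L, 2L, 9L, 100L), C = c(5, 2, 9, 100)), genes)
  top2 <- top_n_protein_coding(tab, 2, "expr_C")
  expect_equal(top2$gene_id, c("gC", "gA"))   # lncRNA gD excluded
  # tie at rank n: lexicographically smaller id wins
  tab2 <- expression_and_flags(data.table::data.table(
    gene_id = ids, H = c(5L, 5L, 9L, 1L), C = c(5, 5, 9, 1)), genes)
  top2b <- top_n_protein_coding(tab2, 2, "expr_C")
  expect_equal(top2b$gene_id, c("gC", "gA"))
  expect_warning(top_n_protein_coding(tab, 4, "expr_C"), "returning all")
})

test_that("H- and C-based rankings differ exactly by the designed paralog family", {
  fx <- fx_paralog()
  genes <- fx_gene_models(fx)
  frags <- load_fragment_mappings(fx$sam[["all"]])
  tab <- gene_count_table(frags, genes, seed = 2L)
  n_pc <- nrow(tab)
  # paralogs have expr_H = 0, so the full-table H ranking warns about
  # fewer positive-expression genes than requested
  expect_warning(th <- top_n_protein_coding(tab, n_pc, "expr_H")$gene_id,
                 "returning all")
  tc <- top_n_protein_coding(tab, n_pc, "expr_C")$gene_id
  # paralogs sink to the bottom of the H ranking (H ~ 0) but not of C's
  rank_h <- match(grep("^PARA", th, value = TRUE), th)
  rank_c <- match(grep("^PARA", tc, value = TRUE), tc)
  expect_true(mean(rank_h) > mean(rank_c))
  flagged <- tab[tab$under_quantified]$gene_id
  expect_setequal(flagged, grep("^PARA", tab$gene_id, value = TRUE))
})
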