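test_that("overlap length sums block intersections and ignores other chromosomes", {
  copy <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 400))
  b1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  expect_equal(overlap_length(b1, copy), 50L)
  # split blocks: [1,50]+[251,300] vs [41,260] -> 10 + 10
  b2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 251), c(50, 300)))
  copy2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(41, 260))
  expect_equal(overlap_length(b2, copy2), 20L)
  b3 <- GenomicRanges::GRanges("chr2", IRanges::IRanges(151, 200))
  expect_equal(overlap_length(b3, copy), 0L)
})

test_that("group coverage implements the fractional overlap-weighted formula", {
  groups <- make_te_groups(data.frame(
    chrom = "chr1", start = c(1001, 2001, 5001), end = c(1300, 2300, 5300),
    name = c("AluYa5", "AluYa5", "L1HS")))

  # unimapper fully inside one copy -> contributes exactly 1
  rm1 <- make_read_mappings(data.frame(
    read_id = "u1", chrom = "chr1", pos = 1101L, read_length = 100L))
  cov1 <- te_group_coverage(rm1, groups)
  expect_equal(cov1[cov1$group == "AluYa5" & cov1$class == "all"]$coverage, 1.0)

  # |M_r| = 2, both mappings fully inside copies of the same group -> 1.0
  rm2 <- make_read_mappings(data.frame(
    read_id = "m1", chrom = "chr1", pos = c(1101L, 2101L), read_length = 100L))
  cov2 <- te_group_coverage(rm2, groups)
  expect_equal(cov2[cov2$group == "AluYa5" & cov2$class == "all"]$coverage, 1.0)
  expect_equal(cov2[cov2$group == "AluYa5" & cov2$class == "multimapper"]$coverage, 1.0)

  # |M_r| = 2, L_r = 100: one mapping overlaps a copy by 60 bp, the other
  # nothing -> (1/2) * (60/100) = 0.30
  rm3 <- make_read_mappings(data.frame(
    read_id = "m2", chrom = "chr1", pos = c(1241L, 9001L), read_length = 100L))
  cov3 <- te_group_coverage(rm3, groups)
  expect_equal(cov3[cov3$group == "AluYa5" & cov3$class == "all"]$coverage, 0.30)
  # untouched group still gets a zero row
  expect_equal(cov3[cov3$group == "L1HS" & cov3$class == "all"]$coverage, 0)
})

test_that("stratified coverage satisfies class additivity and per-read conservation", {
  fx <- fx_young()
  reads <- load_read_mappings(fx$sam[["all"]])
  groups <- fx_te_groups(fx)
  cov <- te_group_coverage(reads, groups)
  wide <- data.table::dcast(cov, group ~ class, value.var = "coverage")
  expect_equal(wide$all, wide$unimapper + wide$multimapper,
               tolerance = 1e-9)

  # per-read contribution <= 1 on non-overlapping annotation, and == 1 for
  # reads fully inside copies (every read in this fixture is)
  m <- mappings_as_df(reads)
  copies_df <- data.frame(chrom = as.character(seqnames(groups$copies)),
                          start = start(groups$copies),
                          end = end(groups$copies),
                          name = groups$copies$name)
  per_read <- oracle_te_coverage_per_read(m, copies_df)
  expect_true(all(per_read <= 1 + 1e-9))
  expect_equal(sum(cov[cov$class == "all"]$coverage), sum(per_read),
               tolerance = 1e-9)
})

test_that("unique-only coverage equals integer read counts when reads sit inside single copies", {
  groups <- make_te_groups(data.frame(
    chrom = "chr1", start = c(1001, 3001), end = c(1500, 3500),
    name = c("A", "B")))
  rm <- make_read_mappings(data.frame(
    read_id = sprintf("u%d", 1:5), chrom = "chr1",
    pos = c(1101L, 1201L, 1301L, 3101L, 3201L), read_length = 100L))
  cov <- te_group_coverage(rm, groups)
  expect_identical(cov[cov$class == "unimapper" & cov$group == "A"]$coverage, 3)
  expect_identical(cov[cov$class == "unimapper" & cov$group == "B"]$coverage, 2)
})

test_that("streaming coverage equals the naive triple-loop oracle", {
  groups <- fx_te_groups(fx_young())
  reads <- load_read_mappings(fx_young()$sam[["all"]])
  # subsample 600 reads for the naive oracle
  keep_ids <- head(reads$reads$read_id, 600)
  sub <- reads
  sub$reads <- reads$reads[reads$reads$read_id %in% keep_ids]
  sub$mappings <- reads$mappings[reads$mappings$read_id %in% keep_ids]
  sub$blocks <- reads$blocks[S4Vectors::mcols(reads$blocks)$mapping_id %in%
                               sub$mappings$mapping_id]
  cov <- te_group_coverage(sub, groups)
  copies_df <- data.frame(chrom = as.character(seqnames(groups$copies)),
                          start = start(groups$copies),
                          end = end(groups$copies),
                          name = groups$copies$name)
  oc <- oracle_te_coverage(mappings_as_df(sub), copies_df)
  got <- setNames(cov[cov$class == "all"]$coverage,
                  cov[cov$class == "all"]$group)
  expect_equal(got[names(oc)], oc, tolerance = 1e-9)
})

test_that("multimapper fraction per group counts touching reads", {
  groups <- make_te_groups(data.frame(
    chrom = "chr1", start = c(1001, 5001), end = c(1500, 5500),
    name = c("A", "Empty")))
  df <- rbind(
    data.frame(read_id = sprintf("u%d", 1:3), chrom = "chr1",
               pos = 1101L, read_length = 100L),
    do.call(rbind, lapply(1:7, function(i) data.frame(
      read_id = sprintf("m%d", i), chrom = "chr1",
      pos = c(1201L, 9001L), read_length = 100L))))
  rm <- make_read_mappings(df)
  mm <- multimapper_fraction_per_group(rm, groups)
  expect_equal(mm$per_group[mm$per_group$group == "A"]$multimapper_fraction, 0.7)
  # untouched group excluded from the share denominator
  expect_equal(mm$n_groups_touched, 1L)
  expect_equal(mm$n_groups_total, 2L)
  expect_equal(mm$share_above, 1.0)
})

test_that("clade aggregation sums assigned groups and drops unassigned ones", {
  groups <- make_te_groups(data.frame(
    chrom = "chr1", start = c(1001, 3001, 5001), end = c(1500, 3500, 5500),
    name = c("A", "B", "NoClade")))
  tab <- data.table::data.table(name = c("A", "B"),
                                clades = list("Homo", "Homo"))
  groups <- assign_clades(groups, tab, c("Homo", "Eutheria"))
  rm <- make_read_mappings(data.frame(
    read_id = sprintf("r%d", 1:3), chrom = "chr1",
    pos = c(1101L, 3101L, 5101L), read_length = 100L))
  cov <- te_group_coverage(rm, groups)
  # fixed coverages 2.0 and 3.0 for the two Homo groups
  cov[cov$group == "A" & cov$class == "all", coverage := 2.0]
  cov[cov$group == "B" & cov$class == "all", coverage := 3.0]
  cl <- aggregate_by_clade(cov, groups)
  expect_equal(cl[cl$clade == "Homo" & cl$class == "all"]$coverage, 5.0)
  # the unassigned group appears in no clade row; no empty-clade rows
  expect_false(any(is.na(cl$clade)))
  expect_setequal(unique(cl$clade), "Homo")
  expect_equal(cl[cl$class == "all"]$n_groups, 2L)
})
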