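# Fixtures are generated programmatically and cached for the test session.
# Seeds here are fixed so every run sees the same designed genomes.

.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx_cache))
    assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

fx_young <- function() fx_get("young", function() {
  make_fixture("young_vs_old_te", file.path(tempdir(), "fx_young"),
               seed = 101L, n_reads = 4000L)
})

fx_paralog <- function() fx_get("paralog", function() {
  make_fixture("paralog_genes", file.path(tempdir(), "fx_paralog"),
               seed = 202L, n_reads = 1250L)
})

fx_trim <- function() fx_get("trim", function() {
  make_fixture("trim_series", file.path(tempdir(), "fx_trim"),
               seed = 303L, n_reads = 3000L)
})

# small paired fixtures for oracle and Monte-Carlo checks
.fx_paralog_n <- function(n, seed) {
  dir <- file.path(tempdir(), sprintf("fx_pe%d", n))
  make_fixture("paralog_genes", dir, seed = seed, n_reads = n)
}
fx_pe500 <- function() fx_get("pe500", function() .fx_paralog_n(500L, 404L))
fx_pe200 <- function() fx_get("pe200", function() .fx_paralog_n(200L, 505L))

# mixed single-end fixture with exactly-matching multimappers (identical
# young copies), used for streaming-vs-oracle equivalence at 10,000 reads
fx_oracle10k <- function() fx_get("oracle10k", function() {
  dir <- file.path(tempdir(), "fx_oracle10k")
  spec <- synthetic_spec(
    background_length = 4000,
    repeat_families = data.frame(
      name = c("IdentZ", "OldZ"),
      consensus_length = 300L, n_copies = 10L,
      divergence = c(0, 0.15),
      clade = c("Homo", "Eutheria")),
    read_length = 100L, n_reads = 10000L, seed = 606L)
  genome <- build_genome(spec, dir)
  sim_r <- simulate_reads(genome, "from_repeats", n_reads = 6000L,
                          seed = 607L, out_prefix = file.path(dir, "rep"),
                          id_prefix = "rR")
  sim_u <- simulate_reads(genome, "uniform", n_reads = 4000L,
                          seed = 608L, out_prefix = file.path(dir, "bg"),
                          id_prefix = "rU")
  fq <- file.path(dir, "reads.fastq")
  file.create(fq)
  file.append(fq, c(sim_r$fastq, sim_u$fastq))
  sam <- file.path(dir, "aligned.sam")
  exhaustive_align(fq, genome, sam, max_mismatches = 0L)
  list(genome = genome, truth = rbind(sim_r$truth, sim_u$truth),
       sam = c(all = sam), fastq = fq, max_mismatches = 0L)
})

# te_groups for a fixture directory (with clades assigned)
fx_te_groups <- function(fx) {
  copies <- read_repeat_annotation(fx$genome$paths$repeats_bed, "bed6")
  groups <- merge_te_groups(copies)
  assign_clades(groups,
                read_clade_table(fx$genome$paths$clades_tsv),
                read_clade_ordering(fx$genome$paths$clade_ordering))
}

fx_gene_models <- function(fx) read_gene_models(fx$genome$paths$genes_gtf)

# ---- hand-built micro fixtures ------------------------------------------

sam_header_lines <- function(seqs) {
  c("@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), unname(seqs)))
}

sam_rec <- function(qname, flag, rname, pos, cigar, rnext = "*", pnext = 0,
                    tlen = 0, mapq = 255) {
  paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, "*", "*",
        sep = "\t")
}

# paired proper fragment: two mates of `rl` M at p1 (forward) / p2 (reverse)
pe_pair <- function(qname, p1, p2, rl = 50, secondary = FALSE,
                    proper = TRUE, rname = "chr1") {
  base1 <- 1 + 64 + ifelse(proper, 2, 0) + 32
  base2 <- 1 + 128 + ifelse(proper, 2, 0) + 16
  if (secondary) { base1 <- base1 + 256; base2 <- base2 + 256 }
  tlen <- p2 + rl - p1
  c(sam_rec(qname, base1, rname, p1, paste0(rl, "M"), "=", p2, tlen),
    sam_rec(qname, base2, rname, p2, paste0(rl, "M"), "=", p1, -tlen))
}

# 12-case micro fixture exercising union-mode "--nonunique none" semantics
micro_gene_fixture <- function() fx_get("micro_gene", function() {
  dir <- file.path(tempdir(), "micro_gene")
  dir.create(dir, showWarnings = FALSE)
  gtf <- file.path(dir, "genes.gtf")
  gene_line <- function(id, s, e) {
    c(sprintf('chr1\ttest\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_type "protein_coding";', s, e, id),
      sprintf('chr1\ttest\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s.1";', s, e, id, id))
  }
  exon_line <- function(id, s, e)
    sprintf('chr1\ttest\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s.1";', s, e, id, id)
  writeLines(c(
    gene_line("geneA", 1001, 2000),
    gene_line("geneB", 3001, 4000),
    gene_line("geneD", 5001, 8000),
    gene_line("geneE", 6001, 6500),   # nested inside geneD
    gene_line("geneF", 9001, 10000),
    sprintf('chr1\ttest\tgene\t%d\t%d\t.\t+\t.\tgene_id "geneG"; gene_type "protein_coding";', 11001, 13000),
    exon_line("geneG", 11001, 11500),
    exon_line("geneG", 12501, 13000)
  ), gtf)

  sam <- file.path(dir, "frags.sam")
  writeLines(c(
    sam_header_lines(c(chr1 = 20000L)),
    pe_pair("f01", 1101, 1301),                         # unique in A
    pe_pair("f02", 1101, 3101),                         # ambiguous A+B
    pe_pair("f03", 14001, 14201),                       # intergenic
    pe_pair("f04", 11601, 12301),                       # intron of G only
    pe_pair("f05", 1201, 1401),                         # multimapper, both in A
    pe_pair("f05", 1501, 1701, secondary = TRUE),
    pe_pair("f06", 1201, 1401),                         # multi: A then B
    pe_pair("f06", 3201, 3401, secondary = TRUE),
    pe_pair("f07", 1801, 1901),                         # multi: A then D+E ambig
    pe_pair("f07", 6101, 6301, secondary = TRUE),
    pe_pair("f08", 6101, 6301),                         # unique but nested D+E
    pe_pair("f09", 1101, 1301, proper = FALSE),         # not a proper pair
    pe_pair("f10", 5101, 5301),                         # unique in D (outside E)
    pe_pair("f11", 9101, 9301),                         # multi x3, all in F
    pe_pair("f11", 9201, 9401, secondary = TRUE),
    pe_pair("f11", 9401, 9601, secondary = TRUE),
    pe_pair("f12", 11301, 11601)                        # mate1 exonic G, mate2 intronic
  ), sam)
  expected_H <- c(geneA = 1L, geneB = 0L, geneD = 1L, geneE = 0L,
                  geneF = 0L, geneG = 1L)
  expected_C <- c(geneA = 3, geneB = 0.5, geneD = 1, geneE = 0,
                  geneF = 1, geneG = 1)
  list(gtf = gtf, sam = sam, expected_H = expected_H,
       expected_C = expected_C, n_proper_fragments = 11L)
})

# single-end micro SAM for reference filtering / multiplicity grouping
micro_chip_sam <- function() fx_get("micro_chip", function() {
  path <- file.path(tempdir(), "micro_chip.sam")
  writeLines(c(
    sam_header_lines(c(chr1 = 20000L, chr2 = 20000L, chr5 = 20000L,
                       chrM = 16000L, scaffold_1 = 5000L)),
    sam_rec("r1", 0, "chr1", 101, "50M"),
    sam_rec("r2", 0, "chr1", 501, "50M"),
    sam_rec("r2", 256, "chrM", 201, "50M"),
    sam_rec("r3", 0, "chr1", 901, "50M"),
    sam_rec("r3", 256, "chr2", 901, "50M"),
    sam_rec("r3", 272, "chr5", 901, "50M"),
    sam_rec("r4", 0, "scaffold_1", 301, "50M")
  ), path)
  path
})

# build a read_mappings object directly (single-block "<L>M" mappings)
make_read_mappings <- function(df) {
  # df: read_id, chrom, pos, read_length (one row per mapping)
  dt <- data.table::as.data.table(df)
  dt[, mapping_id := seq_len(.N)]
  dt[, n_mappings := .N, by = read_id]
  dt[, strand := "+"]
  dt[, cigar := paste0(read_length, "M")]
  blocks <- GenomicRanges::GRanges(
    dt$chrom, IRanges::IRanges(dt$pos, dt$pos + dt$read_length - 1L))
  S4Vectors::mcols(blocks)$mapping_id <- dt$mapping_id
  structure(list(
    reads = dt[, .(read_length = read_length[1], n_mappings = .N),
               by = read_id],
    mappings = dt[, .(mapping_id, read_id, chrom, strand, pos, cigar,
                      read_length, n_mappings)],
    blocks = blocks,
    seqinfo = NULL, n_loaded = nrow(dt)
  ), class = "read_mappings")
}

# te_groups object from a plain data.frame (chrom, start, end, name)
make_te_groups <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr)$name <- df$name
  S4Vectors::mcols(gr)$repeat_class <- NA_character_
  S4Vectors::mcols(gr)$repeat_family <- NA_character_
  merge_te_groups(gr)
}
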