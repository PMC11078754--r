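# Exhaustive substring aligner.
#
# Reports EVERY genomic position (both strands) where a read matches with
# at most `max_mismatches` substitutions — no indels, no heuristics — so
# the counting modules see the complete multimapper structure. Matching is
# delegated to Biostrings (PDict/matchPDict for exact search, matchPattern
# for mismatch-tolerant search); by construction the result equals a
# brute-force scan over all positions.

# all hits of `reads` against `genome` (DNAStringSet); returns
# data.table(read = index into reads, chrom, pos, strand)
.find_hits <- function(reads, genome, max_mismatches) {
  out <- list()
  rc <- Biostrings::reverseComplement(reads)
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    for (strand_i in c("+", "-")) {
      set <- if (strand_i == "+") reads else rc
      if (max_mismatches == 0L) {
        for (w in unique(width(set))) {
          idx <- which(width(set) == w)
          pd <- Biostrings::PDict(set[idx])
          mi <- Biostrings::matchPDict(pd, subject)
          st <- Biostrings::startIndex(mi)
          n_hits <- lengths(st)
          if (sum(n_hits) == 0) next
          out[[length(out) + 1L]] <- data.table(
            read = rep(idx, n_hits), chrom = chrom,
            pos = unlist(st), strand = strand_i)
        }
      } else {
        hits <- lapply(seq_along(set), function(i) {
          Biostrings::start(Biostrings::matchPattern(
            set[[i]], subject, max.mismatch = max_mismatches,
            with.indels = FALSE))
        })
        n_hits <- lengths(hits)
        if (sum(n_hits) == 0) next
        out[[length(out) + 1L]] <- data.table(
          read = rep(seq_along(set), n_hits), chrom = chrom,
          pos = unlist(hits), strand = strand_i)
      }
    }
  }
  if (!length(out)) {
    return(data.table(read = integer(), chrom = character(),
                      pos = integer(), strand = character()))
  }
  unique(rbindlist(out))
}

.sam_header <- function(genome, extra = character()) {
  c("@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), width(genome)),
    "@PG\tID:ambiquant\tPN:ambiquant",
    extra)
}

#' Exhaustively align reads against a genome
#'
#' Every position on either strand where the read matches with at most
#' `max_mismatches` substitutions is reported as one alignment record; all
#' hits share the same mapping quality, the leftmost hit (by chromosome,
#' position, strand; `+` before `-`) is flagged primary and the rest
#' secondary, and `NH` carries the hit count. In paired mode, hits of the
#' two mates are combined into proper pairs (opposite strands, plus-strand
#' mate leftmost, insert within `insert_range`); each such pairing is one
#' fragment mapping, and fragments with no proper pairing are emitted
#' unmapped. Unmappable single-end reads are emitted unmapped.
#'
#' @param fastq FASTQ path, or a length-2 vector of mate FASTQs for paired
#'   mode.
#' @param genome_fasta Genome FASTA path (or a `synthetic_genome`).
#' @param out_sam Output SAM path.
#' @param max_mismatches Maximum substitutions per read (per mate in paired
#'   mode).
#' @param insert_range Length-2 numeric: allowed insert (outer distance)
#'   range for proper pairs; default `c(2 * read length, 1000)` spans the
#'   simulator's fragment distribution.
#' @return Invisibly, a list: `sam`, `n_reads`, `n_mapped`, `n_records`.
#' @export
exhaustive_align <- function(fastq, genome_fasta, out_sam,
                             max_mismatches = 0L, insert_range = NULL) {
  stopifnot(max_mismatches >= 0L)
  genome <- if (inherits(genome_fasta, "synthetic_genome"))
    genome_fasta$genome else Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  paired <- length(fastq) == 2L
  if (paired) .align_paired(fastq, genome, out_sam, max_mismatches,
                            insert_range)
  else .align_single(fastq, genome, out_sam, max_mismatches)
}

.align_single <- function(fastq, genome, out_sam, max_mismatches) {
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  ids <- sub("\\s.*$", "", names(reads))
  hits <- .find_hits(reads, genome, max_mismatches)
  rl <- width(reads)

  lines <- character(0)
  if (nrow(hits)) {
    setorder(hits, read, chrom, pos, strand)
    hits[, rank := seq_len(.N), by = read]
    hits[, nh := .N, by = read]
    seq_fwd <- as.character(reads)[hits$read]
    seq_out <- ifelse(hits$strand == "-", .revcomp(seq_fwd), seq_fwd)
    flag <- ifelse(hits$strand == "-", 16L, 0L) +
      ifelse(hits$rank > 1L, 256L, 0L)
    w <- rl[hits$read]
    lines <- paste(ids[hits$read], flag, hits$chrom, hits$pos, 255L,
                   paste0(w, "M"), "*", 0L, 0L, seq_out, strrep("I", w),
                   paste0("NH:i:", hits$nh), sep = "\t")
  }
  unmapped_idx <- setdiff(seq_along(reads), unique(hits$read))
  if (length(unmapped_idx)) {
    lines <- c(lines, paste(ids[unmapped_idx], 4L, "*", 0L, 0L, "*", "*",
                            0L, 0L, as.character(reads)[unmapped_idx],
                            strrep("I", rl[unmapped_idx]),
                            "NH:i:0", sep = "\t"))
  }
  writeLines(c(.sam_header(genome), lines), out_sam)
  invisible(list(sam = out_sam, n_reads = length(reads),
                 n_mapped = length(unique(hits$read)),
                 n_records = nrow(hits)))
}

.align_paired <- function(fastq, genome, out_sam, max_mismatches,
                          insert_range) {
  r1 <- Biostrings::readDNAStringSet(fastq[1], format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq[2], format = "fastq")
  ids1 <- sub("\\s.*$", "", names(r1))
  ids2 <- sub("\\s.*$", "", names(r2))
  if (!identical(ids1, ids2))
    stop("mate FASTQ files are not ID-synchronised")
  if (is.null(insert_range))
    insert_range <- c(2L * max(width(r1)), 1000L)

  h1 <- .find_hits(r1, genome, max_mismatches)
  h2 <- .find_hits(r2, genome, max_mismatches)
  h1[, end := pos + width(r1)[read] - 1L]
  h2[, end := pos + width(r2)[read] - 1L]

  # proper combos: opposite strands, same chrom, plus-strand mate leftmost
  p1 <- merge(h1[strand == "+"], h2[strand == "-"],
              by = c("read", "chrom"), allow.cartesian = TRUE,
              suffixes = c("_1", "_2"))
  p2 <- merge(h1[strand == "-"], h2[strand == "+"],
              by = c("read", "chrom"), allow.cartesian = TRUE,
              suffixes = c("_1", "_2"))
  p1 <- p1[pos_2 >= pos_1 & end_2 - pos_1 + 1L >= insert_range[1] &
             end_2 - pos_1 + 1L <= insert_range[2]]
  p2 <- p2[pos_1 >= pos_2 & end_1 - pos_2 + 1L >= insert_range[1] &
             end_1 - pos_2 + 1L <= insert_range[2]]
  pairs <- rbind(p1, p2)

  lines <- character(0)
  mapped_reads <- integer(0)
  if (nrow(pairs)) {
    setorder(pairs, read, chrom, pos_1, pos_2, strand_1)
    pairs[, rank := seq_len(.N), by = read]
    pairs[, nh := .N, by = read]
    mapped_reads <- unique(pairs$read)

    w1 <- width(r1)[pairs$read]; w2 <- width(r2)[pairs$read]
    tlen <- ifelse(pairs$strand_1 == "+",
                   pairs$end_2 - pairs$pos_1 + 1L,
                   -(pairs$end_1 - pairs$pos_2 + 1L))
    sec <- ifelse(pairs$rank > 1L, 256L, 0L)
    f1 <- 1L + 2L + 64L + sec +
      ifelse(pairs$strand_1 == "-", 16L, 0L) +
      ifelse(pairs$strand_2 == "-", 32L, 0L)
    f2 <- 1L + 2L + 128L + sec +
      ifelse(pairs$strand_2 == "-", 16L, 0L) +
      ifelse(pairs$strand_1 == "-", 32L, 0L)
    s1 <- as.character(r1)[pairs$read]
    s1 <- ifelse(pairs$strand_1 == "-", .revcomp(s1), s1)
    s2 <- as.character(r2)[pairs$read]
    s2 <- ifelse(pairs$strand_2 == "-", .revcomp(s2), s2)
    nm <- ids1[pairs$read]
    nh_tag <- paste0("NH:i:", pairs$nh)
    l1 <- paste(nm, f1, pairs$chrom, pairs$pos_1, 255L, paste0(w1, "M"),
                "=", pairs$pos_2, tlen, s1, strrep("I", w1), nh_tag,
                sep = "\t")
    l2 <- paste(nm, f2, pairs$chrom, pairs$pos_2, 255L, paste0(w2, "M"),
                "=", pairs$pos_1, -tlen, s2, strrep("I", w2), nh_tag,
                sep = "\t")
    lines <- as.vector(rbind(l1, l2))
  }
  unmapped_idx <- setdiff(seq_along(r1), mapped_reads)
  if (length(unmapped_idx)) {
    u1 <- paste(ids1[unmapped_idx], 77L, "*", 0L, 0L, "*", "*", 0L, 0L,
                as.character(r1)[unmapped_idx],
                strrep("I", width(r1)[unmapped_idx]), "NH:i:0", sep = "\t")
    u2 <- paste(ids1[unmapped_idx], 141L, "*", 0L, 0L, "*", "*", 0L, 0L,
                as.character(r2)[unmapped_idx],
                strrep("I", width(r2)[unmapped_idx]), "NH:i:0", sep = "\t")
    lines <- c(lines, as.vector(rbind(u1, u2)))
  }
  writeLines(c(.sam_header(genome), lines), out_sam)
  invisible(list(sam = out_sam, n_reads = length(r1),
                 n_mapped = length(mapped_reads),
                 n_records = 2L * nrow(pairs)))
}

#' Build a complete, seeded test fixture
#'
#' Generates genome, reads, alignments and truth for one of three designed
#' scenarios:
#' \describe{
#'   \item{`young_vs_old_te`}{Two 20-copy, 300-bp repeat families: a young
#'     one at 0.5\% divergence (clade Homo) and an old one at 15\%
#'     divergence (clade Eutheria). 100-bp single-end reads drawn from the
#'     copies, aligned with 3 mismatches allowed (about twice the expected
#'     young-family pairwise difference per 100-bp window, far below the
#'     old family's ~30). Reads from the young family multimap across
#'     copies; reads from the old family map uniquely.}
#'   \item{`paralog_genes`}{One 4-paralog gene family at 0.5\% divergence
#'     plus 20 single-copy genes (two 400-bp exons, 150-bp intron each).
#'     Paired 100-bp fragments (250 +/- 30 bp) drawn from exons, aligned
#'     with 3 mismatches per mate. Family fragments multimap across the
#'     paralogs, so each paralog is under-quantified by the unique-only
#'     strategy; single-copy genes are counted identically by all
#'     strategies.}
#'   \item{`trim_series`}{One 20-copy young family (0.5\% divergence) plus
#'     unique background; 100-bp single-end reads (60\% from the repeats,
#'     40\% uniform), trimmed at the 3' end to 25/50/75 bp and each length
#'     aligned exactly (0 mismatches). Shorter reads match more copies, so
#'     the multimapper fraction falls as read length grows.}
#' }
#'
#' @param preset One of `"young_vs_old_te"`, `"paralog_genes"`,
#'   `"trim_series"`.
#' @param dir Output directory.
#' @param seed Integer seed driving genome, reads and alignment.
#' @param n_reads Number of reads/fragments; defaults: 4000, 1250, 3000.
#' @return A list: `genome` (`synthetic_genome`), `truth`, `sam` (named
#'   character vector of SAM paths; one per read length for
#'   `trim_series`), `fastq`, `max_mismatches`.
#' @export
make_fixture <- function(preset = c("young_vs_old_te", "paralog_genes",
                                    "trim_series"),
                         dir, seed = 1L, n_reads = NULL) {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  switch(preset,
    young_vs_old_te = .fixture_young_vs_old(dir, seed,
                                            n_reads %||% 4000L),
    paralog_genes = .fixture_paralog_genes(dir, seed, n_reads %||% 1250L),
    trim_series = .fixture_trim_series(dir, seed, n_reads %||% 3000L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_young_vs_old <- function(dir, seed, n_reads) {
  spec <- synthetic_spec(
    background_length = 3000,
    repeat_families = data.frame(
      name = c("YoungA", "OldB"),
      consensus_length = 300L, n_copies = 20L,
      divergence = c(0.005, 0.15),
      clade = c("Homo", "Eutheria")),
    read_length = 100L, n_reads = n_reads, seed = seed)
  genome <- build_genome(spec, dir)
  sim <- simulate_reads(genome, mode = "from_repeats",
                        out_prefix = file.path(dir, "reads"),
                        seed = seed + 1L)
  sam <- file.path(dir, "aligned.sam")
  exhaustive_align(sim$fastq, genome, sam, max_mismatches = 3L)
  list(genome = genome, truth = sim$truth, sam = c(all = sam),
       fastq = sim$fastq, max_mismatches = 3L)
}

.fixture_paralog_genes <- function(dir, seed, n_reads) {
  spec <- synthetic_spec(
    background_length = 2000,
    gene_families = data.frame(
      name = c("PARA", sprintf("UNIQ%02d", 1:20)),
      n_paralogs = c(4L, rep(1L, 20)),
      n_exons = 2L, exon_length = 400L, intron_length = 150L,
      divergence = c(0.005, rep(0, 20))),
    read_length = 100L, paired = TRUE,
    fragment_mean = 250, fragment_sd = 30,
    n_reads = n_reads, seed = seed)
  genome <- build_genome(spec, dir)
  sim <- simulate_reads(genome, mode = "from_genes",
                        out_prefix = file.path(dir, "frags"),
                        seed = seed + 1L)
  sam <- file.path(dir, "aligned.sam")
  exhaustive_align(sim$fastq, genome, sam, max_mismatches = 3L,
                   insert_range = c(150, 420))
  list(genome = genome, truth = sim$truth, sam = c(all = sam),
       fastq = sim$fastq, max_mismatches = 3L)
}

.fixture_trim_series <- function(dir, seed, n_reads) {
  spec <- synthetic_spec(
    background_length = 6000,
    repeat_families = data.frame(
      name = "YoungA", consensus_length = 300L, n_copies = 20L,
      divergence = 0.005, clade = "Homo"),
    read_length = 100L, n_reads = n_reads, seed = seed)
  genome <- build_genome(spec, dir)
  n_rep <- round(0.6 * n_reads)
  sim_r <- simulate_reads(genome, mode = "from_repeats", n_reads = n_rep,
                          out_prefix = file.path(dir, "reads_rep"),
                          seed = seed + 1L, id_prefix = "rR")
  sim_u <- simulate_reads(genome, mode = "uniform",
                          n_reads = n_reads - n_rep,
                          out_prefix = file.path(dir, "reads_bg"),
                          seed = seed + 2L, id_prefix = "rU")
  fq100 <- file.path(dir, "reads100.fastq")
  file.create(fq100)
  file.append(fq100, c(sim_r$fastq, sim_u$fastq))
  truth <- rbind(sim_r$truth, sim_u$truth)

  lengths_bp <- c(25L, 50L, 75L, 100L)
  sams <- setNames(file.path(dir, sprintf("aligned_%d.sam", lengths_bp)),
                   lengths_bp)
  fqs <- setNames(file.path(dir, sprintf("reads%d.fastq", lengths_bp)),
                  lengths_bp)
  fqs[["100"]] <- fq100
  for (L in c(25L, 50L, 75L))
    trim_fastq_3prime(fq100, fqs[[as.character(L)]], L)
  for (L in lengths_bp)
    exhaustive_align(fqs[[as.character(L)]], genome,
                     sams[[as.character(L)]], max_mismatches = 0L)
  list(genome = genome, truth = truth, sam = sams, fastq = fqs,
       max_mismatches = 0L)
}
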