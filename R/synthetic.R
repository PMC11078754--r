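# Synthetic genomes, simulated reads, and an exhaustive stand-in aligner.
#
# The generator builds a single-chromosome toy genome from unique random
# background plus repeat families (consensus copied n times with i.i.d.
# per-site substitutions at the family's divergence) and gene families
# (paralogs built the same way, with exon/intron structure). Divergence is
# substitution-only — no indels — so the exhaustive aligner can report the
# complete, unambiguous set of equal-best hits and every simulated read's
# true origin is recorded exactly.

.DNA <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.DNA, n, replace = TRUE), collapse = "")

# i.i.d. substitutions at rate `divergence`; returns the mutated string and
# the number of substituted sites
.mutate_seq <- function(seq, divergence) {
  if (divergence <= 0) return(list(seq = seq, n_subs = 0L))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < divergence)
  if (length(hit)) {
    idx <- match(chars[hit], .DNA)
    chars[hit] <- .DNA[((idx - 1L + sample(1:3, length(hit), replace = TRUE)) %% 4L) + 1L]
  }
  list(seq = paste(chars, collapse = ""), n_subs = length(hit))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Specify a synthetic genome and library
#'
#' @param background_length Bases of trailing unique random sequence, in
#'   addition to the unique spacers placed between elements.
#' @param repeat_families `data.frame` with columns `name`,
#'   `consensus_length`, `n_copies`, `divergence` (per-site substitution
#'   probability, in `[0, 0.5)`), `clade`.
#' @param gene_families `data.frame` with columns `name`, `n_paralogs`,
#'   `n_exons`, `exon_length`, `intron_length`, `divergence` (families with
#'   `n_paralogs = 1` are single-copy genes with independent sequence).
#' @param read_length Read length in bases.
#' @param paired Simulate proper read pairs rather than single-end reads.
#' @param fragment_mean,fragment_sd Fragment-length distribution (truncated
#'   normal) for paired libraries.
#' @param n_reads Number of reads (or fragments when paired).
#' @param error_rate Per-base sequencing error rate (default 0 so mapping
#'   multiplicity is a pure function of genome structure).
#' @param seed Integer seed; the whole bundle is deterministic given the
#'   spec and seed.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(background_length = 3000,
                           repeat_families = NULL,
                           gene_families = NULL,
                           read_length = 100L,
                           paired = FALSE,
                           fragment_mean = 250,
                           fragment_sd = 30,
                           n_reads = 1000L,
                           error_rate = 0,
                           seed = 1L) {
  if (!is.null(repeat_families)) {
    repeat_families <- as.data.table(repeat_families)
    stopifnot(all(c("name", "consensus_length", "n_copies", "divergence",
                    "clade") %in% names(repeat_families)),
              all(repeat_families$divergence >= 0),
              all(repeat_families$divergence < 0.5),
              all(repeat_families$consensus_length > 0),
              all(repeat_families$n_copies >= 1))
  }
  if (!is.null(gene_families)) {
    gene_families <- as.data.table(gene_families)
    stopifnot(all(c("name", "n_paralogs", "n_exons", "exon_length",
                    "intron_length", "divergence") %in% names(gene_families)),
              all(gene_families$divergence >= 0),
              all(gene_families$divergence < 0.5),
              all(gene_families$exon_length > 0))
  }
  stopifnot(background_length >= 0, read_length >= 1, n_reads >= 1,
            error_rate >= 0, error_rate < 1)
  structure(list(
    background_length = as.integer(background_length),
    repeat_families = repeat_families,
    gene_families = gene_families,
    read_length = as.integer(read_length),
    paired = isTRUE(paired),
    fragment_mean = fragment_mean,
    fragment_sd = fragment_sd,
    n_reads = as.integer(n_reads),
    error_rate = error_rate,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Build a synthetic genome bundle on disk
#'
#' Assembles the chromosome (`chr1`) by placing every repeat copy and gene
#' paralog sequentially, separated by unique spacers of twice the read
#' length (so no read can bridge two elements), and appending
#' `background_length` bases of unique background. Writes FASTA (+ `.fai`),
#' BED6 repeat annotation, GENCODE-like GTF gene models, a clade TSV, a
#' clade ordering file, a truth layout TSV, and a YAML echo of the spec.
#' Byte-identical output for identical spec + seed.
#'
#' @param spec A `synthetic_spec`.
#' @param dir Output directory (created if needed).
#' @return An object of class `synthetic_genome`: list with the genome
#'   `DNAStringSet`, `repeats` (`GRanges` with `name`, `clade`, `n_subs`),
#'   `genes` (`data.table` of paralog spans), `exons` (`GRanges` with
#'   `gene_id`), `consensus` (named list of family consensus sequences),
#'   `layout` (`data.table` truth), `paths` (named list of files), `spec`.
#' @export
build_genome <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$seed, .build_genome_impl(spec, dir))
}

.build_genome_impl <- function(spec, dir) {
  spacer <- 2L * spec$read_length
  segs <- character()
  cursor <- 0L  # bases emitted so far
  layout <- list()
  consensus <- list()

  emit <- function(s) {
    segs[[length(segs) + 1L]] <<- s
    cursor <<- cursor + nchar(s)
  }

  emit(.random_dna(spacer))
  # repeat copies
  if (!is.null(spec$repeat_families)) {
    for (i in seq_len(nrow(spec$repeat_families))) {
      fam <- spec$repeat_families[i]
      cons <- .random_dna(fam$consensus_length)
      consensus[[fam$name]] <- cons
      for (j in seq_len(fam$n_copies)) {
        mut <- .mutate_seq(cons, fam$divergence)
        layout[[length(layout) + 1L]] <- data.table(
          type = "repeat", name = sprintf("%s_copy%02d", fam$name, j),
          family = fam$name, chrom = "chr1",
          start = cursor + 1L, end = cursor + nchar(mut$seq),
          n_subs = mut$n_subs, clade = fam$clade)
        emit(mut$seq)
        emit(.random_dna(spacer))
      }
    }
  }
  # gene paralogs: exons and introns are contiguous within the gene span
  genes <- list(); exons <- list()
  if (!is.null(spec$gene_families)) {
    for (i in seq_len(nrow(spec$gene_families))) {
      fam <- spec$gene_families[i]
      region_len <- fam$n_exons * fam$exon_length +
        (fam$n_exons - 1L) * fam$intron_length
      cons <- .random_dna(region_len)
      consensus[[fam$name]] <- cons
      for (j in seq_len(fam$n_paralogs)) {
        mut <- if (fam$n_paralogs > 1L) .mutate_seq(cons, fam$divergence)
               else list(seq = cons, n_subs = 0L)
        gid <- if (fam$n_paralogs > 1L)
          sprintf("%s_p%02d", fam$name, j) else fam$name
        gstart <- cursor + 1L
        layout[[length(layout) + 1L]] <- data.table(
          type = "gene", name = gid, family = fam$name, chrom = "chr1",
          start = gstart, end = cursor + region_len,
          n_subs = mut$n_subs, clade = NA_character_)
        genes[[length(genes) + 1L]] <- data.table(
          gene_id = gid, family = fam$name, chrom = "chr1",
          start = gstart, end = cursor + region_len)
        for (e in seq_len(fam$n_exons)) {
          es <- gstart + (e - 1L) * (fam$exon_length + fam$intron_length)
          exons[[length(exons) + 1L]] <- data.table(
            gene_id = gid, chrom = "chr1", start = es,
            end = es + fam$exon_length - 1L)
        }
        emit(mut$seq)
        emit(.random_dna(spacer))
      }
    }
  }
  emit(.random_dna(spec$background_length))

  chrom_seq <- paste(segs, collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(chrom_seq, "chr1"))
  layout <- rbindlist(layout)
  rep_layout <- layout[type == "repeat"]
  repeats <- GRanges(rep(
                       "chr1", nrow(rep_layout)),
                     IRanges(rep_layout$start, rep_layout$end),
                     strand = rep("+", nrow(rep_layout)),
                     name = rep_layout$family,
                     clade = rep_layout$clade, n_subs = rep_layout$n_subs,
                     seqlengths = c(chr1 = nchar(chrom_seq)))
  genes_dt <- if (length(genes)) rbindlist(genes) else
    data.table(gene_id = character(), family = character(),
               chrom = character(), start = integer(), end = integer())
  exons_dt <- if (length(exons)) rbindlist(exons) else
    data.table(gene_id = character(), chrom = character(),
               start = integer(), end = integer())
  exons_gr <- GRanges(exons_dt$chrom,
                      IRanges(exons_dt$start, exons_dt$end),
                      strand = rep("+", nrow(exons_dt)),
                      gene_id = exons_dt$gene_id)

  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    repeats_bed = file.path(dir, "repeats.bed"),
    genes_gtf = file.path(dir, "genes.gtf"),
    clades_tsv = file.path(dir, "clades.tsv"),
    clade_ordering = file.path(dir, "clade_ordering.txt"),
    layout_tsv = file.path(dir, "layout.tsv"),
    spec_yaml = file.path(dir, "spec.yaml")
  )
  Biostrings::writeXStringSet(genome, paths$fasta)
  Rsamtools::indexFa(paths$fasta)
  if (length(repeats)) {
    bed <- repeats
    mcols(bed) <- S4Vectors::DataFrame(name = repeats$name, score = 0L)
    rtracklayer::export(bed, paths$repeats_bed, format = "BED")
  } else {
    file.create(paths$repeats_bed)
  }
  .write_gtf(genes_dt, exons_dt, paths$genes_gtf)
  clades <- if (!is.null(spec$repeat_families))
    spec$repeat_families[, .(name, clades = clade)] else
    data.table(name = character(), clades = character())
  fwrite(clades, paths$clades_tsv, sep = "\t", quote = FALSE)
  file.copy(system.file("extdata", "clade_ordering_human.txt",
                        package = "ambiquant"),
            paths$clade_ordering, overwrite = TRUE)
  fwrite(layout, paths$layout_tsv, sep = "\t", na = ".", quote = FALSE)
  yaml::write_yaml(.spec_as_list(spec), paths$spec_yaml)

  structure(list(genome = genome, repeats = repeats, genes = genes_dt,
                 exons = exons_gr, consensus = consensus, layout = layout,
                 paths = paths, spec = spec),
            class = "synthetic_genome")
}

.spec_as_list <- function(spec) {
  out <- unclass(spec)
  for (nm in c("repeat_families", "gene_families"))
    if (!is.null(out[[nm]])) out[[nm]] <- as.data.frame(out[[nm]])
  out
}

# minimal GENCODE-dialect GTF writer (gene + exon features, gene_id/gene_type)
.write_gtf <- function(genes_dt, exons_dt, path) {
  lines <- character()
  if (nrow(genes_dt)) {
    attr_g <- sprintf('gene_id "%s"; gene_type "protein_coding"; gene_name "%s";',
                      genes_dt$gene_id, genes_dt$gene_id)
    g <- paste(genes_dt$chrom, "ambiquant", "gene", genes_dt$start,
               genes_dt$end, ".", "+", ".", attr_g, sep = "\t")
    attr_e <- sprintf('gene_id "%s"; transcript_id "%s.1"; gene_type "protein_coding";',
                      exons_dt$gene_id, exons_dt$gene_id)
    e <- paste(exons_dt$chrom, "ambiquant", "exon", exons_dt$start,
               exons_dt$end, ".", "+", ".", attr_e, sep = "\t")
    ord <- order(c(genes_dt$start, exons_dt$start),
                 c(rep(0L, nrow(genes_dt)), rep(1L, nrow(exons_dt))))
    lines <- c(g, e)[ord]
  }
  writeLines(c("##description: synthetic gene models", lines), path)
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome: chr1 of ", sum(nchar(x$genome)), " bp, ",
      length(x$repeats), " repeat copies, ", nrow(x$genes), " genes\n",
      sep = "")
  invisible(x)
}

#' Simulate reads or fragments with recorded truth
#'
#' Draws error-free reads (or proper fragments, when the spec is paired)
#' from the synthetic genome and writes FASTQ plus a truth TSV recording
#' each read's exact origin. Reads are drawn from both strands.
#'
#' @param genome A `synthetic_genome`.
#' @param mode `"uniform"` (anywhere on the chromosome), `"from_repeats"`
#'   (uniform over repeat copies, read/fragment fully inside the copy) or
#'   `"from_genes"` (uniform over gene paralogs, then over exons;
#'   read/fragment fully inside one exon — splice-free simulation).
#' @param n_reads Number of reads/fragments (default from the spec).
#' @param seed Integer seed (default: the spec's seed).
#' @param out_prefix Path prefix; writes `<prefix>.fastq` (single-end) or
#'   `<prefix>_1.fastq`/`<prefix>_2.fastq` (paired) and `<prefix>.truth.tsv`.
#' @param id_prefix Read-ID prefix (default `"r"`).
#' @return Invisibly, a list with `fastq` (character vector of paths),
#'   `truth` (`data.table`: `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `source_type`, `source_name`), `truth_tsv`.
#' @export
simulate_reads <- function(genome, mode = c("uniform", "from_repeats",
                                            "from_genes"),
                           n_reads = NULL, seed = NULL, out_prefix,
                           id_prefix = "r") {
  stopifnot(inherits(genome, "synthetic_genome"))
  mode <- match.arg(mode)
  spec <- genome$spec
  if (is.null(n_reads)) n_reads <- spec$n_reads
  if (is.null(seed)) seed <- spec$seed
  withr::with_seed(seed,
    .simulate_reads_impl(genome, mode, n_reads, out_prefix, id_prefix))
}

.simulate_reads_impl <- function(genome, mode, n_reads, out_prefix,
                                 id_prefix) {
  spec <- genome$spec
  rl <- spec$read_length
  chrom_seq <- as.character(genome$genome[["chr1"]])
  glen <- nchar(chrom_seq)
  if (rl > glen) stop("read_length exceeds genome length")

  # candidate source regions per mode
  if (mode == "uniform") {
    regions <- data.table(start = 1L, end = glen,
                          source_type = "background",
                          source_name = "background")
  } else if (mode == "from_repeats") {
    if (length(genome$repeats) == 0) stop("genome has no repeat copies")
    regions <- data.table(start = start(genome$repeats),
                          end = end(genome$repeats),
                          source_type = "repeat",
                          source_name = genome$repeats$name)
  } else {
    if (length(genome$exons) == 0) stop("genome has no genes")
    regions <- data.table(start = start(genome$exons),
                          end = end(genome$exons),
                          source_type = "gene",
                          source_name = mcols(genome$exons)$gene_id)
  }

  span_needed <- if (spec$paired) rl else rl  # fragment span checked per draw
  regions <- regions[end - start + 1L >= span_needed]
  if (nrow(regions) == 0) stop("no source region can hold a read of length ", rl)

  ids <- sprintf("%s%06d", id_prefix, seq_len(n_reads))
  reg_idx <- sample.int(nrow(regions), n_reads, replace = TRUE)
  src_strand <- sample(c("+", "-"), n_reads, replace = TRUE)

  apply_errors <- function(s) {
    if (spec$error_rate <= 0) return(s)
    vapply(s, function(x) .mutate_seq(x, spec$error_rate)$seq, character(1),
           USE.NAMES = FALSE)
  }

  if (!spec$paired) {
    rstart <- regions$start[reg_idx] +
      floor(runif(n_reads) *
              (regions$end[reg_idx] - regions$start[reg_idx] - rl + 2L))
    rend <- rstart + rl - 1L
    seqs <- substring(chrom_seq, rstart, rend)
    minus <- src_strand == "-"
    seqs[minus] <- .revcomp(seqs[minus])
    seqs <- apply_errors(seqs)
    fq <- paste0(out_prefix, ".fastq")
    .write_fastq(ids, seqs, fq)
    truth <- data.table(read_id = ids, chrom = "chr1", start = as.integer(rstart),
                        end = as.integer(rend), strand = src_strand,
                        source_type = regions$source_type[reg_idx],
                        source_name = regions$source_name[reg_idx])
    fastq_paths <- fq
  } else {
    avail <- regions$end[reg_idx] - regions$start[reg_idx] + 1L
    flen <- as.integer(pmax(rl, pmin(avail,
      round(rnorm(n_reads, spec$fragment_mean, spec$fragment_sd)))))
    fstart <- regions$start[reg_idx] +
      floor(runif(n_reads) * (avail - flen + 1L))
    fend <- fstart + flen - 1L
    frag <- substring(chrom_seq, fstart, fend)
    r1 <- substr(frag, 1L, rl)
    r2 <- .revcomp(substring(frag, flen - rl + 1L))
    minus <- src_strand == "-"
    # a minus-strand fragment swaps the mate roles: mate1 reads the reverse
    # strand from the fragment's right end, mate2 the forward left end
    tmp <- r1[minus]; r1[minus] <- r2[minus]; r2[minus] <- tmp
    r1 <- apply_errors(r1); r2 <- apply_errors(r2)
    fq1 <- paste0(out_prefix, "_1.fastq"); fq2 <- paste0(out_prefix, "_2.fastq")
    .write_fastq(ids, r1, fq1); .write_fastq(ids, r2, fq2)
    truth <- data.table(read_id = ids, chrom = "chr1",
                        start = as.integer(fstart), end = as.integer(fend),
                        strand = src_strand,
                        source_type = regions$source_type[reg_idx],
                        source_name = regions$source_name[reg_idx])
    fastq_paths <- c(fq1, fq2)
  }
  truth_tsv <- paste0(out_prefix, ".truth.tsv")
  fwrite(truth, truth_tsv, sep = "\t", quote = FALSE)
  invisible(list(fastq = fastq_paths, truth = truth, truth_tsv = truth_tsv))
}

.write_fastq <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
}
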