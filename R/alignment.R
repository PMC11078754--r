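# SAM ingestion and read-level operations.
#
# SAM files are converted to BAM in a temporary directory via Rsamtools and
# read back through GenomicAlignments, so CIGAR arithmetic and flag handling
# follow the reference implementation of the SAM spec. All records of a read
# are held in memory at once (files here are desk-scale).

#' Default reference filter for ChIP-seq style analyses
#'
#' Keeps primary chromosomes (`chr1`..`chr22`, `chrX`, `chrY`) and drops
#' non-chromosomal scaffolds and the mitochondrial chromosome (`chrM`),
#' matching UCSC naming for GRCh38/GRCm38.
#' @export
CHIP_REFERENCE_PATTERN <- "^chr([0-9]+|X|Y)$"

.sam_to_gal <- function(path, what = c("qname", "flag", "mapq", "mrnm", "mpos"),
                        tags = "NH") {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "@"))
    stop("SAM file lacks a header: ", path)
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = what, tag = tags,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
}

.gal_to_dt <- function(gal) {
  data.table(
    read_id = as.character(mcols(gal)$qname),
    flag = mcols(gal)$flag,
    chrom = as.character(seqnames(gal)),
    strand = as.character(strand(gal)),
    pos = start(gal),
    end = end(gal),
    cigar = GenomicAlignments::cigar(gal),
    read_length = GenomicAlignments::qwidth(gal),
    mapq = mcols(gal)$mapq,
    mpos = if ("mpos" %in% names(mcols(gal))) mcols(gal)$mpos else NA_integer_,
    nh = if ("NH" %in% names(mcols(gal))) mcols(gal)$NH else NA_integer_
  )
}

#' Load single-end read mappings from a SAM file
#'
#' Groups all reported alignment records (primary and secondary) by read
#' name, applies the reference filter, and classifies each read as a
#' unimapper (exactly one surviving mapping) or multimapper (more than one).
#' The reference filter is applied before multiplicity is computed, so a
#' read whose only secondary hit lies on an excluded scaffold becomes a
#' unimapper. Multiplicity is the count of retained records, not the NH tag;
#' when NH is present, disagreements (expected whenever the filter removed
#' records) are reported as a message.
#'
#' @param path SAM file containing all reported hits per read.
#' @param keep_pattern Regular expression; records on reference sequences
#'   not matching it are dropped before anything else. `NULL` (default)
#'   keeps every reference; use [CHIP_REFERENCE_PATTERN] for the
#'   ChIP-seq-style primary-chromosome filter.
#' @param min_mapq Optional minimum mapping quality; default `NULL` applies
#'   no threshold (the fractional strategies are defined on the full
#'   mapping set).
#' @return An object of class `read_mappings`: list with
#'   \describe{
#'     \item{reads}{`data.table`: `read_id`, `read_length`, `n_mappings`.}
#'     \item{mappings}{`data.table`: `mapping_id`, `read_id`, `chrom`,
#'       `strand`, `pos`, `cigar`, `read_length`, `n_mappings`.}
#'     \item{blocks}{`GRanges` of reference-consuming aligned blocks
#'       (junction `N` gaps excluded, deletions internal), metadata column
#'       `mapping_id`.}
#'     \item{seqinfo}{`Seqinfo` of the alignment.}
#'   }
#' @export
load_read_mappings <- function(path, keep_pattern = NULL, min_mapq = NULL) {
  gal <- .sam_to_gal(path)
  dt <- .gal_to_dt(gal)
  n_loaded <- nrow(dt)
  keep <- rep(TRUE, n_loaded)
  if (!is.null(keep_pattern)) keep <- keep & grepl(keep_pattern, dt$chrom)
  if (!is.null(min_mapq)) keep <- keep & !is.na(dt$mapq) & dt$mapq >= min_mapq
  gal <- gal[keep]
  dt <- dt[keep]

  dup <- duplicated(dt[, .(read_id, chrom, strand, pos, cigar)])
  if (any(dup)) {
    warning(sum(dup), " duplicate identical (read, position) record(s) collapsed")
    gal <- gal[!dup]
    dt <- dt[!dup]
  }
  if (nrow(dt) == 0) {
    return(structure(list(
      reads = data.table(read_id = character(), read_length = integer(),
                         n_mappings = integer()),
      mappings = data.table(mapping_id = integer(), read_id = character(),
                            chrom = character(), strand = character(),
                            pos = integer(), cigar = character(),
                            read_length = integer(), n_mappings = integer()),
      blocks = GRanges(mapping_id = integer()),
      seqinfo = GenomeInfoDb::seqinfo(gal),
      n_loaded = n_loaded
    ), class = "read_mappings"))
  }
  dt[, mapping_id := seq_len(.N)]
  dt[, n_mappings := .N, by = read_id]
  if (!all(is.na(dt$nh))) {
    bad <- dt[!is.na(nh) & nh != n_mappings, unique(read_id)]
    if (length(bad))
      message("NH tag disagrees with retained multiplicity for ",
              length(bad), " read(s) (expected when records were filtered)")
  }
  reads <- dt[, .(read_length = read_length[1], n_mappings = .N),
              by = read_id]
  blk <- unlist(GenomicAlignments::grglist(gal, drop.D.ranges = FALSE))
  mcols(blk)$mapping_id <- rep(dt$mapping_id,
                               lengths(GenomicAlignments::grglist(gal)))
  structure(list(
    reads = reads[],
    mappings = dt[, .(mapping_id, read_id, chrom, strand, pos, cigar,
                      read_length, n_mappings)],
    blocks = blk,
    seqinfo = GenomeInfoDb::seqinfo(gal),
    n_loaded = n_loaded
  ), class = "read_mappings")
}

#' @export
print.read_mappings <- function(x, ...) {
  n_multi <- sum(x$reads$n_mappings > 1)
  cat("read_mappings: ", nrow(x$reads), " reads (",
      nrow(x$reads) - n_multi, " unimappers, ", n_multi,
      " multimappers), ", nrow(x$mappings), " mappings\n", sep = "")
  invisible(x)
}

#' Load paired-end fragment mappings from a SAM file
#'
#' Only records flagged as mapped in a proper pair are considered. Mate
#' records are joined into pairs by position/mate-position concordance on
#' the same chromosome; each joined pair is one element of the fragment's
#' mapping set M_f. A fragment is a multimapper when it has more than one
#' proper pairing, i.e. when at least one read of the pair mapped more than
#' once. Proper-pair-flagged records whose mate cannot be found are dropped
#' with a warning.
#'
#' @param path Paired-end SAM with proper-pair flags set.
#' @return An object of class `fragment_mappings`: list with
#'   \describe{
#'     \item{fragments}{`data.table`: `fragment_id`, `n_mappings`.}
#'     \item{pairs}{`data.table`: one row per fragment mapping (`pair_id`,
#'       `fragment_id`, `chrom`, `pos1`, `cigar1`, `pos2`, `cigar2`,
#'       `n_mappings`).}
#'     \item{blocks}{`GRanges` of aligned blocks of both mates, metadata
#'       column `pair_id`.}
#'     \item{seqinfo}{`Seqinfo`.}
#'   }
#' @export
load_fragment_mappings <- function(path) {
  gal <- .sam_to_gal(path)
  dt <- .gal_to_dt(gal)
  n_loaded <- nrow(dt)
  proper <- bitwAnd(dt$flag, 0x1L) > 0 & bitwAnd(dt$flag, 0x2L) > 0
  gal <- gal[proper]
  dt <- dt[proper]
  dt[, rec := .I]
  is1 <- bitwAnd(dt$flag, 0x40L) > 0
  is2 <- bitwAnd(dt$flag, 0x80L) > 0
  m1 <- unique(dt[is1], by = c("read_id", "chrom", "pos", "mpos", "strand"))
  m2 <- unique(dt[is2], by = c("read_id", "chrom", "pos", "mpos", "strand"))
  pairs <- merge(
    m1[, .(read_id, chrom, pos, mpos, cigar, rec)],
    m2[, .(read_id, chrom, pos = mpos, mpos = pos, cigar2 = cigar,
           pos2_real = pos, rec2 = rec)],
    by = c("read_id", "chrom", "pos", "mpos"))
  n_orphan <- nrow(m1) + nrow(m2) - 2L * nrow(pairs)
  if (n_orphan > 0)
    warning(n_orphan, " proper-pair-flagged record(s) without a joinable ",
            "mate dropped")
  if (nrow(pairs) == 0) {
    return(structure(list(
      fragments = data.table(fragment_id = character(), n_mappings = integer()),
      pairs = data.table(pair_id = integer(), fragment_id = character(),
                         chrom = character(), pos1 = integer(),
                         cigar1 = character(), pos2 = integer(),
                         cigar2 = character(), n_mappings = integer()),
      blocks = GRanges(pair_id = integer()),
      seqinfo = GenomeInfoDb::seqinfo(gal),
      n_loaded = n_loaded
    ), class = "fragment_mappings"))
  }
  setorder(pairs, read_id, chrom, pos)
  pairs[, pair_id := seq_len(.N)]
  pairs[, n_mappings := .N, by = read_id]

  grl <- GenomicAlignments::grglist(gal, drop.D.ranges = FALSE)
  blk1 <- unlist(grl[pairs$rec])
  blk2 <- unlist(grl[pairs$rec2])
  mcols(blk1)$pair_id <- rep(pairs$pair_id, lengths(grl[pairs$rec]))
  mcols(blk2)$pair_id <- rep(pairs$pair_id, lengths(grl[pairs$rec2]))
  blk <- c(blk1, blk2)
  structure(list(
    fragments = pairs[, .(n_mappings = .N), by = read_id][
      , .(fragment_id = read_id, n_mappings)],
    pairs = pairs[, .(pair_id, fragment_id = read_id, chrom, pos1 = pos,
                      cigar1 = cigar, pos2 = pos2_real, cigar2,
                      n_mappings)],
    blocks = blk,
    seqinfo = GenomeInfoDb::seqinfo(gal),
    n_loaded = n_loaded
  ), class = "fragment_mappings")
}

#' @export
print.fragment_mappings <- function(x, ...) {
  n_multi <- sum(x$fragments$n_mappings > 1)
  cat("fragment_mappings: ", nrow(x$fragments), " fragments (",
      nrow(x$fragments) - n_multi, " unimappers, ", n_multi,
      " multimappers), ", nrow(x$pairs), " pairings\n", sep = "")
  invisible(x)
}

#' Reference-consuming blocks of a CIGAR string
#'
#' Returns the maximal reference intervals consumed by an alignment:
#' `M`/`=`/`X` consume reference, deletions (`D`) are internal to a block,
#' junction gaps (`N`) split blocks, and `S`/`I`/`H` consume no reference.
#'
#' @param cigar Character vector of CIGAR strings.
#' @param pos Integer vector of 1-based leftmost mapped positions.
#' @return An `IRangesList`, one element per input alignment.
#' @export
reference_blocks <- function(cigar, pos) {
  GenomicAlignments::extractAlignmentRangesOnReference(
    cigar, pos = pos, drop.D.ranges = FALSE)
}

#' Randomly select one mapping per multimapper
#'
#' Replaces each read's (or fragment's) mapping set with a single mapping
#' drawn uniformly at random; unimappers pass through unchanged. The draw is
#' deterministic for a fixed seed and input order.
#'
#' @param x A `read_mappings` or `fragment_mappings` object.
#' @param seed Integer seed.
#' @return An object of the same class with every multiplicity equal to 1.
#' @export
random_select <- function(x, seed) UseMethod("random_select")

.uniform_pick <- function(n, seed) {
  withr::with_seed(seed, {
    u <- runif(length(n))
    pmin(n, floor(u * n) + 1L)
  })
}

#' @export
random_select.read_mappings <- function(x, seed) {
  m <- data.table::copy(x$mappings)
  setorder(m, read_id, mapping_id)
  first <- m[, .(i0 = .I[1], n = .N), by = read_id]
  pick_rows <- first$i0 + .uniform_pick(first$n, seed) - 1L
  sel <- m[sort(pick_rows)]
  sel[, n_mappings := 1L]
  keep_blocks <- x$blocks[mcols(x$blocks)$mapping_id %in% sel$mapping_id]
  reads <- data.table::copy(x$reads)[, n_mappings := 1L]
  structure(list(reads = reads[], mappings = sel[], blocks = keep_blocks,
                 seqinfo = x$seqinfo, n_loaded = x$n_loaded),
            class = "read_mappings")
}

#' @export
random_select.fragment_mappings <- function(x, seed) {
  p <- data.table::copy(x$pairs)
  setorder(p, fragment_id, pair_id)
  first <- p[, .(i0 = .I[1], n = .N), by = fragment_id]
  pick_rows <- first$i0 + .uniform_pick(first$n, seed) - 1L
  sel <- p[sort(pick_rows)]
  sel[, n_mappings := 1L]
  keep_blocks <- x$blocks[mcols(x$blocks)$pair_id %in% sel$pair_id]
  frags <- data.table::copy(x$fragments)[, n_mappings := 1L]
  structure(list(fragments = frags[], pairs = sel[], blocks = keep_blocks,
                 seqinfo = x$seqinfo, n_loaded = x$n_loaded),
            class = "fragment_mappings")
}

#' Trim reads at the 3' end to a fixed length
#'
#' Truncates every read's sequence and quality string to
#' `min(length, target_length)` bases, keeping the 5' end; read IDs (and
#' hence pairing between files of a pair) are preserved. Used to simulate
#' shorter sequencing libraries from longer ones.
#'
#' @param input FASTQ path, or a length-2 vector for a read pair.
#' @param output Output path(s), same length as `input`.
#' @param target_length Target read length in bases (>= 1).
#' @return Invisibly, `output`.
#' @export
trim_fastq_3prime <- function(input, output, target_length) {
  stopifnot(length(input) == length(output), target_length >= 1)
  for (i in seq_along(input)) {
    # the FASTQ reader silently reconciles mismatched quality strings, so
    # validate the 4-line records before parsing
    lines <- readLines(input[i])
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ (not a multiple of 4 lines): ", input[i])
    bad <- which(nchar(lines[seq(2L, length(lines), by = 4L)]) !=
                   nchar(lines[seq(4L, length(lines), by = 4L)]))
    if (length(bad))
      stop("sequence/quality length mismatch in ", input[i],
           " at record '", lines[(bad[1] - 1L) * 4L + 1L], "'")
    reads <- Biostrings::readDNAStringSet(input[i], format = "fastq",
                                          with.qualities = TRUE)
    quals <- mcols(reads)$qualities
    w <- pmin(width(reads), as.integer(target_length))
    out <- Biostrings::subseq(reads, start = 1L, width = w)
    mcols(out)$qualities <- Biostrings::subseq(quals, start = 1L, width = w)
    Biostrings::writeXStringSet(out, output[i], format = "fastq",
                                qualities = mcols(out)$qualities)
  }
  invisible(output)
}
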