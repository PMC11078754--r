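#' Read a repeat annotation into a GRanges of repeat copies
#'
#' Parses RepeatMasker-style repeat annotations, either a UCSC rmsk table
#' export (TSV with `genoName`/`genoStart`/`genoEnd`/`strand`/`repName`/
#' `repClass`/`repFamily` columns, 0-based starts) or BED6 (0-based starts,
#' `name` column holding the repeat name). Coordinates are converted to the
#' 1-based closed convention of [GenomicRanges::GRanges] on ingest, so a BED
#' record `chr1 100 394` becomes `chr1:101-394` (length 294 either way).
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed6"` or `"rmsk"`.
#' @return A `GRanges`, sorted by (chrom, start, end), with metadata columns
#'   `name`, `repeat_class` and `repeat_family` (the latter two `NA` for BED
#'   input lacking them).
#' @export
read_repeat_annotation <- function(path, dialect = c("bed6", "rmsk")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("repeat annotation file not found: ", path)
  if (dialect == "bed6") {
    gr <- tryCatch(
      rtracklayer::import(path, format = "BED"),
      error = function(e) stop("failed to parse BED repeat annotation '",
                               path, "': ", conditionMessage(e))
    )
    if (length(gr) > 0 && (is.null(gr$name) || anyNA(gr$name)))
      stop("BED repeat annotation must carry a name column (repName)")
    mcols(gr) <- S4Vectors::DataFrame(
      name = if (length(gr)) gr$name else character(),
      repeat_class = NA_character_,
      repeat_family = NA_character_
    )
  } else {
    tab <- data.table::fread(path, sep = "\t", header = TRUE,
                             colClasses = list(character = "genoName"))
    needed <- c("genoName", "genoStart", "genoEnd", "repName")
    missing_cols <- setdiff(needed, names(tab))
    if (length(missing_cols))
      stop("rmsk table '", path, "' lacks required column(s): ",
           paste(missing_cols, collapse = ", "))
    bad <- which(!is.finite(tab$genoStart) | !is.finite(tab$genoEnd) |
                   tab$genoEnd <= tab$genoStart)
    if (length(bad))
      stop("malformed rmsk record at data line ", bad[1],
           ": genoEnd must exceed genoStart")
    gr <- GRanges(
      seqnames = tab$genoName,
      ranges = IRanges(start = tab$genoStart + 1L, end = tab$genoEnd),
      strand = if ("strand" %in% names(tab))
        ifelse(tab$strand %in% c("+", "-"), tab$strand, "*") else "*"
    )
    mcols(gr) <- S4Vectors::DataFrame(
      name = as.character(tab$repName),
      repeat_class = if ("repClass" %in% names(tab))
        as.character(tab$repClass) else NA_character_,
      repeat_family = if ("repFamily" %in% names(tab))
        as.character(tab$repFamily) else NA_character_
    )
  }
  if (length(gr) && any(gr$name == ""))
    stop("repeat records with empty name are not allowed")
  sort(gr, ignore.strand = TRUE)
}

#' Merge same-name repeat copies into TE groups
#'
#' All repeat copies sharing one name form a TE group. Within a group and
#' chromosome, copies that overlap or are immediately adjacent (zero gap; a
#' 1-bp gap is kept apart) are merged into a single copy spanning their
#' union. Copies with different names are never merged, even when they
#' overlap. Strand is ignored.
#'
#' @param copies A `GRanges` of repeat copies as returned by
#'   [read_repeat_annotation()] (metadata column `name` required).
#' @param classes Optional character vector of `repeat_class` values to keep
#'   before merging (e.g. `c("LINE","SINE","LTR","DNA")`); default keeps all
#'   records.
#' @return An object of class `te_groups`: a list with
#'   \describe{
#'     \item{copies}{`GRanges` of post-merge copies, metadata column `name`.}
#'     \item{groups}{`data.table` with one row per group: `name`,
#'       `n_copies`, `total_bp`, `repeat_class`, `repeat_family`.}
#'   }
#' @export
merge_te_groups <- function(copies, classes = NULL) {
  stopifnot(is(copies, "GRanges"))
  if (!is.null(classes) && length(copies))
    copies <- copies[!is.na(copies$repeat_class) &
                       copies$repeat_class %in% classes]
  if (length(copies) == 0) {
    return(structure(list(
      copies = GRanges(name = character()),
      groups = data.table(name = character(), n_copies = integer(),
                          total_bp = integer(),
                          repeat_class = character(),
                          repeat_family = character())
    ), class = "te_groups"))
  }
  strand(copies) <- "*"
  by_name <- split(copies, copies$name)
  # min.gapwidth = 1: zero-gap neighbours merge, >= 1 bp gaps do not
  merged <- reduce(by_name, min.gapwidth = 1L)
  flat <- unlist(merged, use.names = TRUE)
  flat$name <- names(flat)
  names(flat) <- NULL
  flat <- sort(flat, ignore.strand = TRUE)

  meta <- as.data.table(mcols(copies))[
    , .(repeat_class = repeat_class[1], repeat_family = repeat_family[1]),
    by = name]
  groups <- data.table(
    name = names(merged),
    n_copies = lengths(merged),
    total_bp = vapply(merged, function(x) sum(width(x)), integer(1))
  )
  groups <- meta[groups, on = "name"]
  data.table::setcolorder(groups,
    c("name", "n_copies", "total_bp", "repeat_class", "repeat_family"))
  setorder(groups, name)
  structure(list(copies = flat, groups = groups[]), class = "te_groups")
}

#' @export
print.te_groups <- function(x, ...) {
  cat("te_groups: ", nrow(x$groups), " groups, ",
      length(x$copies), " merged copies, ",
      sum(x$groups$total_bp), " bp total\n", sep = "")
  invisible(x)
}

#' Read a clade table and clade ordering
#'
#' The clade table maps repeat names to the set of taxonomic clades in which
#' the family is presumed to have been active (Dfam-style "Clades" column,
#' comma-separated). The ordering ranks clade labels from youngest to
#' oldest; a default human-lineage ordering ships with the package
#' (`system.file("extdata", "clade_ordering_human.txt", package =
#' "ambiquant")`).
#'
#' @param path TSV with columns `name` and `clades` (comma-separated labels).
#' @return `data.table` with columns `name`, `clades` (list column).
#' @export
read_clade_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  if (!all(c("name", "clades") %in% names(tab)))
    stop("clade table must have columns 'name' and 'clades'")
  tab[, clades := lapply(strsplit(clades, ",", fixed = TRUE), trimws)]
  tab[]
}

#' @rdname read_clade_table
#' @param ordering_path One clade label per line, youngest first.
#' @return `read_clade_ordering`: character vector, youngest first.
#' @export
read_clade_ordering <- function(ordering_path) {
  x <- trimws(readLines(ordering_path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (anyDuplicated(x)) stop("clade ordering contains duplicate labels")
  x
}

#' Assign an age clade to each TE group
#'
#' A family listed in several clades is assigned the youngest one according
#' to the supplied ordering (e.g. L1HS listed under Homo and Hominoidea is
#' assigned Homo). Families absent from the clade table get `NA` and are
#' excluded from clade-level aggregation downstream.
#'
#' @param groups A `te_groups` object from [merge_te_groups()].
#' @param clade_table `data.table` from [read_clade_table()].
#' @param ordering Character vector of clade labels, youngest first.
#' @return The `te_groups` object with a `clade` column added to `$groups`.
#' @export
assign_clades <- function(groups, clade_table, ordering) {
  stopifnot(inherits(groups, "te_groups"))
  all_labels <- unique(unlist(clade_table$clades))
  unknown <- setdiff(all_labels, ordering)
  if (length(unknown))
    stop("clade label(s) missing from ordering: ",
         paste(unknown, collapse = ", "))
  youngest <- vapply(clade_table$clades, function(cl) {
    cl[which.min(match(cl, ordering))]
  }, character(1))
  lut <- setNames(youngest, clade_table$name)
  groups$groups[, clade := unname(lut[name])]
  groups
}

#' Read gene models from a GTF file
#'
#' Builds one gene model per `gene_id` from GENCODE-dialect GTF. The gene
#' length L_g is the genomic span (end - start, as the gene's start and end
#' coordinates define it), not the exon sum; the exon intervals form the
#' overlap universe used for read assignment (union of exons, HTSeq-count
#' union mode). When exons carry a `gene_id` with no `gene` feature, the
#' span is synthesised from the exon extremes with a warning.
#'
#' @param path GTF file with `gene` and `exon` features carrying `gene_id`
#'   (and `gene_type` when available).
#' @return An object of class `gene_models`: list with
#'   \describe{
#'     \item{genes}{`data.table`: `gene_id`, `chrom`, `start`, `end`,
#'       `strand`, `length`, `biotype`.}
#'     \item{exons}{`GRanges` with metadata column `gene_id`.}
#'   }
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "GTF")
  if (is.null(gff$type)) stop("GTF lacks feature types: ", path)
  exons <- gff[gff$type == "exon"]
  gene_feats <- gff[gff$type == "gene"]
  if (length(exons) == 0 && length(gene_feats) == 0)
    stop("GTF contains neither gene nor exon features: ", path)
  if (length(exons) && (is.null(exons$gene_id) || anyNA(exons$gene_id)))
    stop("exon features without gene_id in ", path)

  biotype_of <- function(gr) {
    if (!is.null(gr$gene_type)) as.character(gr$gene_type)
    else if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype)
    else rep(NA_character_, length(gr))
  }
  genes <- data.table(
    gene_id = as.character(gene_feats$gene_id),
    chrom = as.character(seqnames(gene_feats)),
    start = start(gene_feats), end = end(gene_feats),
    strand = as.character(strand(gene_feats)),
    biotype = biotype_of(gene_feats)
  )
  orphan <- setdiff(unique(exons$gene_id), genes$gene_id)
  if (length(orphan)) {
    warning(length(orphan), " gene_id(s) have exons but no gene feature; ",
            "span synthesised from exon extremes")
    oe <- exons[exons$gene_id %in% orphan]
    odt <- data.table(
      gene_id = as.character(oe$gene_id),
      chrom = as.character(seqnames(oe)),
      start = start(oe), end = end(oe),
      strand = as.character(strand(oe)),
      biotype = biotype_of(oe)
    )[, .(chrom = chrom[1], start = min(start), end = max(end),
          strand = strand[1], biotype = biotype[1]), by = gene_id]
    genes <- rbind(genes, odt, use.names = TRUE)
  }
  genes[, length := end - start + 1L]
  setorder(genes, gene_id)
  exons <- exons[, "gene_id"]
  mcols(exons)$gene_id <- as.character(exons$gene_id)
  structure(list(genes = genes[], exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", nrow(x$genes), " genes, ",
      length(x$exons), " exons\n", sep = "")
  invisible(x)
}

#' Write merged TE groups to BED6 and a group summary TSV
#'
#' @param groups A `te_groups` object (optionally with clades assigned).
#' @param bed_path Output BED6 path (one record per merged copy; the score
#'   field is 0 and the strand `.`).
#' @param summary_path Output TSV path (`name`, `n_copies`, `total_bp`,
#'   `clade`); pass `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_te_groups <- function(groups, bed_path, summary_path = NULL) {
  stopifnot(inherits(groups, "te_groups"))
  gr <- groups$copies
  gr$score <- 0L
  rtracklayer::export(gr, bed_path, format = "BED")
  if (!is.null(summary_path)) {
    out <- data.table::copy(groups$groups)
    if (!"clade" %in% names(out)) out[, clade := NA_character_]
    fwrite(out[, .(name, n_copies, total_bp, clade)], summary_path,
           sep = "\t", na = ".", quote = FALSE)
  }
  invisible(c(bed_path, summary_path))
}
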