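# Fractional TE-group coverage.
#
# Each mapping r_i of read r contributes, for every TE copy k it overlaps,
# (1/|M_r|) * (l / L_r) to the copy's group, where l is the number of
# aligned nucleotides of r_i overlapping k and L_r the read length. Summing
# over all copies of a group and all reads gives the group coverage C_K.
# Overlap uses the aligned reference blocks (junction gaps excluded); L_r is
# the read length in bases including soft-clipped bases, so a fully aligned
# clipped read contributes less than 1.

#' Overlap length between a mapping and an interval
#'
#' Sum over aligned blocks of the intersection length with the target
#' interval; 0 when disjoint or on a different chromosome.
#'
#' @param blocks `GRanges` of aligned blocks of one mapping.
#' @param target A length-1 `GRanges` (e.g. one TE copy).
#' @return Integer number of overlapping bases.
#' @export
overlap_length <- function(blocks, target) {
  stopifnot(length(target) == 1L)
  # disjoint sequence levels simply mean no overlap
  hits <- suppressWarnings(findOverlaps(blocks, target, ignore.strand = TRUE))
  if (length(hits) == 0) return(0L)
  sum(width(pintersect(blocks[queryHits(hits)], target[subjectHits(hits)],
                       ignore.strand = TRUE)))
}

.te_contributions <- function(reads, groups) {
  stopifnot(inherits(reads, "read_mappings"), inherits(groups, "te_groups"))
  copies <- groups$copies
  hits <- findOverlaps(reads$blocks, copies, ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(data.table(group = character(), read_id = character(),
                      is_multi = logical(), contrib = numeric()))
  }
  ov <- width(pintersect(reads$blocks[queryHits(hits)],
                         copies[subjectHits(hits)], ignore.strand = TRUE))
  dt <- data.table(
    mapping_id = mcols(reads$blocks)$mapping_id[queryHits(hits)],
    group = copies$name[subjectHits(hits)],
    w = ov
  )
  m <- reads$mappings[, .(mapping_id, read_id, read_length, n_mappings)]
  dt <- m[dt, on = "mapping_id"]
  if (any(dt$read_length == 0)) stop("read of length 0 encountered")
  dt[, .(read_id = read_id, group = group,
         is_multi = n_mappings > 1L,
         contrib = w / (n_mappings * read_length))]
}

#' Fractional read coverage per TE group (C_K)
#'
#' Computes, for every TE group, the fractional overlap-weighted read
#' coverage, stratified by read class: unimappers (exactly one mapping),
#' multimappers (more than one), and all reads. Groups touched by no read
#' get coverage 0. By construction
#' `coverage(all) = coverage(unimapper) + coverage(multimapper)`.
#'
#' @param reads A `read_mappings` object (filters already applied).
#' @param groups A `te_groups` object (post-merge).
#' @return A `data.table` with one row per group x class
#'   (`class` in `"unimapper"`, `"multimapper"`, `"all"`): columns `group`,
#'   `class`, `coverage`, `n_reads_touching` (reads with >= 1 mapping
#'   overlapping >= 1 copy by >= 1 base, for that class), and
#'   `multimapper_read_fraction` (share of all touching reads that are
#'   multimappers; identical across the three rows of a group, `NA` for
#'   untouched groups).
#' @export
te_group_coverage <- function(reads, groups) {
  dt <- .te_contributions(reads, groups)
  per_read <- unique(dt[, .(read_id, group, is_multi)])
  touch <- per_read[, .(
    n_reads_touching = .N,
    n_multi = sum(is_multi)
  ), by = group]

  strat <- dt[, .(coverage = sum(contrib),
                  n_reads_touching = length(unique(read_id))),
              by = .(group, class = ifelse(is_multi, "multimapper", "unimapper"))]
  allr <- dt[, .(coverage = sum(contrib),
                 n_reads_touching = length(unique(read_id)),
                 class = "all"), by = group]
  full <- data.table::CJ(group = groups$groups$name,
                         class = c("unimapper", "multimapper", "all"))
  out <- rbind(strat, allr[, .(group, class, coverage, n_reads_touching)])
  out <- out[full, on = c("group", "class")]
  out[is.na(coverage), `:=`(coverage = 0, n_reads_touching = 0L)]
  out <- touch[, .(group, multimapper_read_fraction = n_multi / n_reads_touching)][
    out, on = "group"]
  data.table::setcolorder(out, c("group", "class", "coverage",
                                 "n_reads_touching",
                                 "multimapper_read_fraction"))
  setorder(out, group, class)
  out[]
}

#' Multimapper read fraction per TE group
#'
#' A read "maps to" a group when at least one of its mappings overlaps at
#' least one copy by at least one base. For every touched group the
#' function reports the fraction of such reads that are multimappers, and
#' the share of touched groups whose fraction reaches a threshold. Groups
#' touched by no read have an undefined fraction and are excluded from the
#' share's denominator; the total group count is reported alongside.
#'
#' @inheritParams te_group_coverage
#' @param threshold Fraction threshold (default 0.70).
#' @return A list: `per_group` (`data.table`: `group`, `n_reads`,
#'   `multimapper_fraction`), `share_above` (share of touched groups with
#'   fraction >= threshold), `n_groups_touched`, `n_groups_total`.
#' @export
multimapper_fraction_per_group <- function(reads, groups, threshold = 0.70) {
  dt <- .te_contributions(reads, groups)
  per_read <- unique(dt[, .(read_id, group, is_multi)])
  per_group <- per_read[, .(n_reads = .N,
                            multimapper_fraction = mean(is_multi)),
                        by = group]
  setorder(per_group, group)
  list(
    per_group = per_group[],
    share_above = if (nrow(per_group)) {
      mean(per_group$multimapper_fraction >= threshold)
    } else NA_real_,
    n_groups_touched = nrow(per_group),
    n_groups_total = nrow(groups$groups)
  )
}

#' Aggregate TE group coverage by clade
#'
#' Sums coverage per clade and read class, and reports the number of TE
#' copies and groups per clade. Groups without an assigned clade are
#' excluded.
#'
#' @param cov Coverage table from [te_group_coverage()].
#' @param groups A `te_groups` object with clades assigned
#'   ([assign_clades()]).
#' @param ordering Optional clade ordering (youngest first) used to order
#'   the rows.
#' @return `data.table`: `clade`, `class`, `coverage`, `n_te_copies`,
#'   `n_groups`.
#' @export
aggregate_by_clade <- function(cov, groups, ordering = NULL) {
  stopifnot(inherits(groups, "te_groups"))
  g <- groups$groups
  if (!"clade" %in% names(g))
    stop("groups carry no clade assignments; call assign_clades() first")
  ann <- g[!is.na(clade), .(group = name, clade, n_copies)]
  dt <- ann[cov, on = "group", nomatch = NULL]
  out <- dt[, .(coverage = sum(coverage)), by = .(clade, class)]
  meta <- ann[, .(n_te_copies = sum(n_copies), n_groups = .N), by = clade]
  out <- meta[out, on = "clade"]
  data.table::setcolorder(out, c("clade", "class", "coverage",
                                 "n_te_copies", "n_groups"))
  if (!is.null(ordering)) {
    out[, clade := factor(clade, levels = ordering)]
    setorder(out, clade, class)
    out[, clade := as.character(clade)]
  } else {
    setorder(out, clade, class)
  }
  out[]
}

#' Write a coverage table (and optional clade summary) to TSV
#'
#' @param cov Coverage table from [te_group_coverage()].
#' @param path Output TSV path.
#' @param clade_cov Optional clade table from [aggregate_by_clade()].
#' @param clade_path Output path for the clade table.
#' @return Invisibly, the paths written.
#' @export
write_coverage_table <- function(cov, path, clade_cov = NULL,
                                 clade_path = NULL) {
  fwrite(cov, path, sep = "\t", na = ".", quote = FALSE)
  if (!is.null(clade_cov)) {
    stopifnot(!is.null(clade_path))
    fwrite(clade_cov, clade_path, sep = "\t", na = ".", quote = FALSE)
  }
  invisible(c(path, clade_path))
}
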