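# Gene expression quantification under three strategies.
#
# All three share union-mode overlap semantics: for each fragment mapping
# f_i, the gene set S(f_i) contains every gene with >= 1 exon overlapped by
# >= 1 aligned base of either mate. A mapping counts to a gene only when
# |S| = 1; |S| = 0 (no feature) and |S| >= 2 (ambiguous) count nowhere —
# the default HTSeq-count behaviour ("--nonunique none").
#
#   H_g  unique-only: fragments with |M_f| = 1 whose single mapping has
#        S = {g} add 1 (multimappers are discarded entirely).
#   C_g  multimapper-aware: every mapping with S = {g} adds 1/|M_f|.
#   R_g  random-selection: one mapping kept per fragment, drawn uniformly,
#        then the unique-only rule applied to it.

#' Gene sets overlapped by each fragment mapping
#'
#' Computes, for every fragment mapping (proper pairing of mates), the set
#' of genes whose exons it overlaps, in union mode over the two mates.
#' Overlap is unstranded.
#'
#' @param fragments A `fragment_mappings` object.
#' @param genes A `gene_models` object.
#' @return A `data.table` with one row per fragment mapping: `pair_id`,
#'   `fragment_id`, `n_mappings`, `n_genes` (|S|), `gene_id` (the single
#'   gene when |S| = 1, otherwise `NA`).
#' @export
fragment_gene_sets <- function(fragments, genes) {
  stopifnot(inherits(fragments, "fragment_mappings"),
            inherits(genes, "gene_models"))
  hits <- findOverlaps(fragments$blocks, genes$exons, ignore.strand = TRUE)
  ov <- unique(data.table(
    pair_id = mcols(fragments$blocks)$pair_id[queryHits(hits)],
    gene_id = mcols(genes$exons)$gene_id[subjectHits(hits)]
  ))
  sets <- ov[, .(n_genes = .N,
                 gene_id = if (.N == 1L) gene_id else NA_character_),
             by = pair_id]
  out <- fragments$pairs[, .(pair_id, fragment_id, n_mappings)]
  out <- sets[out, on = "pair_id"]
  out[is.na(n_genes), n_genes := 0L]
  data.table::setcolorder(out, c("pair_id", "fragment_id", "n_mappings",
                                 "n_genes", "gene_id"))
  setorder(out, pair_id)
  out[]
}

#' Gene set of a single mapping pair (set S)
#'
#' Convenience wrapper returning the union-mode gene set of one fragment
#' mapping, given the aligned blocks of its two mates.
#'
#' @param blocks `GRanges` of the aligned blocks of both mates.
#' @param genes A `gene_models` object.
#' @return Character vector of gene ids (possibly empty).
#' @export
overlapping_genes <- function(blocks, genes) {
  hits <- findOverlaps(blocks, genes$exons, ignore.strand = TRUE)
  sort(unique(mcols(genes$exons)$gene_id[subjectHits(hits)]))
}

.count_template <- function(genes) {
  data.table(gene_id = genes$genes$gene_id, n = 0)
}

#' Unique-only gene counts (H)
#'
#' @param fragments A `fragment_mappings` object.
#' @param genes A `gene_models` object.
#' @param .sets Precomputed [fragment_gene_sets()] table (internal reuse).
#' @return `data.table`: `gene_id`, `H` (integer), one row per gene.
#' @export
count_unique_only <- function(fragments, genes, .sets = NULL) {
  sets <- if (is.null(.sets)) fragment_gene_sets(fragments, genes) else .sets
  cnt <- sets[n_mappings == 1L & n_genes == 1L, .(H = .N), by = gene_id]
  out <- cnt[genes$genes[, .(gene_id)], on = "gene_id"]
  out[is.na(H), H := 0L]
  setorder(out, gene_id)
  out[]
}

#' Fractional multimapper-aware gene counts (C)
#'
#' @inheritParams count_unique_only
#' @return `data.table`: `gene_id`, `C` (double), one row per gene.
#' @export
count_multimapper_aware <- function(fragments, genes, .sets = NULL) {
  sets <- if (is.null(.sets)) fragment_gene_sets(fragments, genes) else .sets
  cnt <- sets[n_genes == 1L, .(C = sum(1 / n_mappings)), by = gene_id]
  out <- cnt[genes$genes[, .(gene_id)], on = "gene_id"]
  out[is.na(C), C := 0]
  setorder(out, gene_id)
  out[]
}

#' Random-selection gene counts (R)
#'
#' One mapping is kept per fragment, drawn uniformly at random
#' (see [random_select()]), and the unique-only assignment rule is applied
#' to it; the ambiguity rule still discards chosen mappings with |S| != 1.
#' Over many seeds the counts converge to C gene by gene.
#'
#' @inheritParams count_unique_only
#' @param seed Integer seed for the per-fragment draw.
#' @return `data.table`: `gene_id`, `R` (integer), one row per gene.
#' @export
count_random_strategy <- function(fragments, genes, seed, .sets = NULL) {
  sets <- if (is.null(.sets)) fragment_gene_sets(fragments, genes) else .sets
  sets <- sets[order(pair_id)]
  first <- sets[, .(i0 = .I[1], n = n_mappings[1]), by = fragment_id]
  pick <- first$i0 + .uniform_pick(first$n, seed) - 1L
  chosen <- sets[pick]
  cnt <- chosen[n_genes == 1L, .(R = .N), by = gene_id]
  out <- cnt[genes$genes[, .(gene_id)], on = "gene_id"]
  out[is.na(R), R := 0L]
  setorder(out, gene_id)
  out[]
}

#' Expression values and under-quantification flags
#'
#' Adds span-based expression values (`expr_H = H/L`, `expr_C = C/L`), the
#' expressed flag (`C > 0`), and the under-quantification flag: a gene is
#' under-quantified by the unique-only strategy when the expression-value
#' ratio `(C/L)/(H/L) = C/H` strictly exceeds `factor`. A gene with
#' `H = 0` and `C > 0` has an infinite ratio and is flagged; `H = 0, C = 0`
#' is not flagged.
#'
#' @param counts `data.table` with columns `gene_id`, `H`, `C` (and
#'   optionally `R`).
#' @param genes A `gene_models` object (provides `L` and `biotype`).
#' @param factor Ratio threshold, default 2.
#' @return `data.table`: `gene_id`, `biotype`, `L`, `H`, `C`, `C_rounded`
#'   (nearest integer, half-up, for downstream count-based tools), `R` (if
#'   supplied), `expr_H`, `expr_C`, `expressed`, `under_quantified`.
#' @export
expression_and_flags <- function(counts, genes, factor = 2) {
  stopifnot(all(c("gene_id", "H", "C") %in% names(counts)))
  if (any(counts$H < 0) || any(counts$C < 0))
    stop("negative counts encountered")
  out <- genes$genes[, .(gene_id, biotype, L = length)][counts, on = "gene_id"]
  if (any(is.na(out$L))) stop("counts contain gene_id(s) absent from models")
  out[, `:=`(
    C_rounded = as.integer(floor(C + 0.5)),
    expr_H = H / L,
    expr_C = C / L,
    expressed = C > 0,
    under_quantified = (H > 0 & C / H > factor) | (H == 0 & C > 0)
  )]
  cols <- c("gene_id", "biotype", "L", "H", "C", "C_rounded",
            if ("R" %in% names(out)) "R", "expr_H", "expr_C",
            "expressed", "under_quantified")
  setorder(out, gene_id)
  out[, ..cols]
}

#' Full gene count table under all three strategies
#'
#' Runs the unique-only, fractional and random-selection strategies on one
#' set of fragment mappings and assembles the joint per-gene table.
#'
#' @param fragments A `fragment_mappings` object.
#' @param genes A `gene_models` object.
#' @param seed Seed for the random-selection strategy.
#' @param factor Under-quantification ratio threshold, default 2.
#' @return See [expression_and_flags()].
#' @export
gene_count_table <- function(fragments, genes, seed = 1L, factor = 2) {
  sets <- fragment_gene_sets(fragments, genes)
  h <- count_unique_only(fragments, genes, .sets = sets)
  cc <- count_multimapper_aware(fragments, genes, .sets = sets)
  rr <- count_random_strategy(fragments, genes, seed, .sets = sets)
  counts <- h[cc, on = "gene_id"][rr, on = "gene_id"]
  expression_and_flags(counts, genes, factor = factor)
}

#' Top-N protein-coding genes by expression value
#'
#' Filters to protein-coding genes, ranks by the chosen expression value
#' (descending) with a deterministic tie-break on `gene_id` (ascending),
#' and returns the first `n`. When fewer than `n` protein-coding genes have
#' positive expression a warning is issued and all are returned.
#'
#' @param table Gene count table from [gene_count_table()] /
#'   [expression_and_flags()].
#' @param n Number of genes (e.g. 50, 100 or 200).
#' @param which `"expr_C"` (default) or `"expr_H"`.
#' @return `data.table` of the selected rows, ranked.
#' @export
top_n_protein_coding <- function(table, n, which = c("expr_C", "expr_H")) {
  which <- match.arg(which)
  pc <- table[biotype == "protein_coding"]
  setorderv(pc, c(which, "gene_id"), order = c(-1L, 1L))
  if (sum(pc[[which]] > 0) < n)
    warning("only ", sum(pc[[which]] > 0),
            " protein-coding genes with positive ", which,
            "; returning all available")
  head(pc, n)
}

#' Write a gene count table to TSV
#'
#' @param table Gene count table.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_gene_count_table <- function(table, path) {
  fwrite(table, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}
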