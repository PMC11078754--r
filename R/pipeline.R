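# Config-driven pipeline runs and strategy comparison reports.
#
# Every run writes its resolved configuration (YAML) next to its outputs,
# and logs per-stage record counts, so any result can be reproduced
# byte-for-byte from the echoed config. Outputs are plain TSV with a fixed
# header line; undefined values are written as ".".

.log_msg <- function(quiet, ...) if (!quiet) message(...)

#' Run the TE coverage pipeline
#'
#' Loads repeats, merges same-name copies into groups, optionally assigns
#' clades, loads single-end read mappings (with the reference filter),
#' computes the stratified fractional coverage table, and writes TSVs.
#'
#' @param sam SAM file with all reported hits per read.
#' @param repeats Repeat annotation path.
#' @param dialect `"bed6"` or `"rmsk"`.
#' @param out_dir Output directory.
#' @param clades,clade_ordering Optional clade TSV and ordering paths;
#'   when both are given a clade-level summary is also written.
#' @param keep_pattern Reference filter regex (see [load_read_mappings()]);
#'   default `NULL` keeps all references.
#' @param classes Optional repeat classes filter for [merge_te_groups()].
#' @param threshold Multimapper-fraction threshold, default 0.70.
#' @param quiet Suppress log messages.
#' @return Invisibly, a list: `coverage`, `clade_coverage` (or `NULL`),
#'   `multimapper`, `paths`.
#' @export
run_te_coverage <- function(sam, repeats, dialect = "bed6", out_dir,
                            clades = NULL, clade_ordering = NULL,
                            keep_pattern = NULL, classes = NULL,
                            threshold = 0.70, quiet = FALSE) {
  for (p in c(sam, repeats, clades, clade_ordering))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  copies <- read_repeat_annotation(repeats, dialect)
  groups <- merge_te_groups(copies, classes = classes)
  .log_msg(quiet, "annotation: ", length(copies), " copies -> ",
           nrow(groups$groups), " groups (", length(groups$copies),
           " merged copies)")
  if (!is.null(clades)) {
    ordering <- read_clade_ordering(clade_ordering)
    groups <- assign_clades(groups, read_clade_table(clades), ordering)
  }
  reads <- load_read_mappings(sam, keep_pattern = keep_pattern)
  n_multi <- sum(reads$reads$n_mappings > 1)
  .log_msg(quiet, "alignment: ", reads$n_loaded, " records loaded; ",
           nrow(reads$reads), " reads kept (", nrow(reads$reads) - n_multi,
           " uni + ", n_multi, " multi)")

  cov <- te_group_coverage(reads, groups)
  mm <- multimapper_fraction_per_group(reads, groups, threshold = threshold)
  clade_cov <- NULL
  paths <- list(coverage = file.path(out_dir, "coverage.tsv"),
                config = file.path(out_dir, "run_config.yaml"))
  if (!is.null(clades)) {
    clade_cov <- aggregate_by_clade(cov, groups, ordering = ordering)
    paths$clade_coverage <- file.path(out_dir, "clade_coverage.tsv")
    write_coverage_table(cov, paths$coverage, clade_cov,
                         paths$clade_coverage)
  } else {
    write_coverage_table(cov, paths$coverage)
  }
  yaml::write_yaml(list(
    stage = "te-coverage", sam = sam, repeats = repeats, dialect = dialect,
    clades = clades, clade_ordering = clade_ordering,
    keep_pattern = keep_pattern, classes = classes, threshold = threshold,
    counts = list(records_loaded = reads$n_loaded,
                  reads_kept = nrow(reads$reads),
                  unimappers = nrow(reads$reads) - n_multi,
                  multimappers = n_multi)
  ), paths$config)
  invisible(list(coverage = cov, clade_coverage = clade_cov,
                 multimapper = mm, paths = paths))
}

#' Run the gene quantification pipeline
#'
#' Loads gene models and proper-paired fragment mappings, computes the
#' unique-only (H), fractional (C) and random-selection (R) counts,
#' expression values and under-quantification flags, plus top-N
#' protein-coding lists for both expression measures, and writes TSVs.
#'
#' @param sam Paired-end SAM with proper-pair flags.
#' @param gtf Gene models GTF.
#' @param out_dir Output directory.
#' @param seed Seed for the random-selection strategy.
#' @param factor Under-quantification ratio threshold, default 2.
#' @param top_n Integer vector of top-N list sizes, default
#'   `c(50, 100, 200)`.
#' @param quiet Suppress log messages.
#' @return Invisibly, a list: `table`, `top_n`, `paths`.
#' @export
run_gene_quant <- function(sam, gtf, out_dir, seed = 1L, factor = 2,
                           top_n = c(50L, 100L, 200L), quiet = FALSE) {
  for (p in c(sam, gtf)) if (!file.exists(p)) stop("input not found: ", p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- read_gene_models(gtf)
  frags <- load_fragment_mappings(sam)
  n_multi <- sum(frags$fragments$n_mappings > 1)
  .log_msg(quiet, "alignment: ", frags$n_loaded, " records loaded; ",
           nrow(frags$fragments), " fragments kept (",
           nrow(frags$fragments) - n_multi, " uni + ", n_multi, " multi)")
  tab <- gene_count_table(frags, genes, seed = seed, factor = factor)
  .log_msg(quiet, "counts: ", sum(tab$expressed), " expressed genes, ",
           sum(tab$under_quantified), " under-quantified")

  tops <- rbindlist(lapply(top_n, function(n) {
    n_eff <- min(n, sum(tab$biotype == "protein_coding"))
    rbind(
      top_n_protein_coding(tab, n_eff, "expr_C")[
        , .(gene_id, rank = seq_len(.N), n = n, which = "expr_C")],
      top_n_protein_coding(tab, n_eff, "expr_H")[
        , .(gene_id, rank = seq_len(.N), n = n, which = "expr_H")])
  }))
  paths <- list(counts = file.path(out_dir, "gene_counts.tsv"),
                top_n = file.path(out_dir, "top_genes.tsv"),
                config = file.path(out_dir, "run_config.yaml"))
  write_gene_count_table(tab, paths$counts)
  fwrite(tops, paths$top_n, sep = "\t", quote = FALSE)
  yaml::write_yaml(list(
    stage = "gene-count", sam = sam, gtf = gtf, seed = seed,
    factor = factor, top_n = as.integer(top_n),
    counts = list(records_loaded = frags$n_loaded,
                  fragments_kept = nrow(frags$fragments),
                  unimappers = nrow(frags$fragments) - n_multi,
                  multimappers = n_multi,
                  expressed = sum(tab$expressed),
                  under_quantified = sum(tab$under_quantified))
  ), paths$config)
  invisible(list(table = tab, top_n = tops, paths = paths))
}

#' Compare gene quantification strategies
#'
#' Produces a per-gene side-by-side report for two count columns of a gene
#' count table, the share of expressed genes under-quantified by the
#' baseline, and top-N symmetric differences between the rankings.
#'
#' @param table Gene count table from [gene_count_table()] (columns `H`,
#'   `C`, flags).
#' @param top_n Integer vector of list sizes, default `c(50, 100, 200)`.
#' @param out_tsv Optional path to write the per-gene report.
#' @return A list: `per_gene` (`data.table`), `share_under_quantified`
#'   (among expressed genes), `n_under_quantified`, `top_n_diff`
#'   (`data.table`: `n`, `n_only_H`, `n_only_C`, `symmetric_difference`).
#' @export
compare_strategies_report <- function(table, top_n = c(50L, 100L, 200L),
                                      out_tsv = NULL) {
  stopifnot(all(c("gene_id", "H", "C", "expressed",
                  "under_quantified") %in% names(table)))
  per_gene <- table[, .(gene_id, biotype, L, H, C, ratio = C / H,
                        expressed, under_quantified)]
  n_expr <- sum(table$expressed)
  share <- if (n_expr) sum(table$under_quantified) / n_expr else NA_real_
  top_diff <- rbindlist(lapply(top_n, function(n) {
    n_eff <- min(n, sum(table$biotype == "protein_coding"))
    th <- top_n_protein_coding(table, n_eff, "expr_H")$gene_id
    tc <- top_n_protein_coding(table, n_eff, "expr_C")$gene_id
    data.table(n = n, n_only_H = length(setdiff(th, tc)),
               n_only_C = length(setdiff(tc, th)),
               symmetric_difference = length(setdiff(th, tc)) +
                 length(setdiff(tc, th)))
  }))
  if (!is.null(out_tsv))
    fwrite(per_gene, out_tsv, sep = "\t", na = ".", quote = FALSE)
  list(per_gene = per_gene, share_under_quantified = share,
       n_under_quantified = sum(table$under_quantified),
       top_n_diff = top_diff)
}

#' Run a full pipeline from a config file or list
#'
#' The config is a YAML file (or an equivalent named list) with a `stage`
#' key (`"te-coverage"` or `"gene-count"`) plus the arguments of
#' [run_te_coverage()] / [run_gene_quant()]. The resolved config is echoed
#' next to the outputs, making runs reproducible.
#'
#' @param config Path to a YAML config, or a named list.
#' @return Invisibly, the stage's result list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stage <- config$stage %||% stop("config lacks a 'stage' key")
  config$stage <- NULL
  fn <- switch(stage,
               "te-coverage" = run_te_coverage,
               "gene-count" = run_gene_quant,
               stop("unknown stage: ", stage))
  do.call(fn, config)
}
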