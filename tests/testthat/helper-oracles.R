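# Independent reference implementations used as oracles. These deliberately
# use plain loops and base-R interval arithmetic, not the package's overlap
# machinery.

# Naive evaluation of the fractional TE-group coverage: for every read, for
# every mapping, for every copy, add (1/|M_r|) * (overlap / L_r).
# mappings: data.frame with read_id, chrom, start, end, read_length
#           (one row per mapping; single aligned block each)
# copies:   data.frame with chrom, start, end, name (1-based closed)
oracle_te_coverage <- function(mappings, copies) {
  # enumerate every (read, mapping, copy) term, then sum per group with
  # R's extended-precision sum() so accumulation order does not matter
  cap <- 4L * nrow(mappings)
  term_grp <- character(cap); term_val <- numeric(cap); n_terms <- 0L
  rows_by_read <- split(seq_len(nrow(mappings)), mappings$read_id)
  for (rows in rows_by_read) {
    M <- length(rows)
    for (i in rows) {
      same_chrom <- copies$chrom == mappings$chrom[i]
      l <- pmax(0L, pmin(copies$end, mappings$end[i]) -
                      pmax(copies$start, mappings$start[i]) + 1L)
      l[!same_chrom] <- 0L
      for (k in which(l > 0L)) {
        n_terms <- n_terms + 1L
        if (n_terms > length(term_val)) {  # grow
          term_grp <- c(term_grp, character(length(term_grp)))
          term_val <- c(term_val, numeric(length(term_val)))
        }
        term_grp[n_terms] <- copies$name[k]
        term_val[n_terms] <- (1 / M) * (l[k] / mappings$read_length[i])
      }
    }
  }
  cov <- setNames(rep(0, length(unique(copies$name))),
                  sort(unique(copies$name)))
  if (n_terms > 0L) {
    sums <- tapply(term_val[seq_len(n_terms)], term_grp[seq_len(n_terms)], sum)
    cov[names(sums)] <- as.numeric(sums)
  }
  cov
}

# Total contribution of each read summed over all groups, by the same
# naive per-read evaluation (for the conservation bound).
oracle_te_coverage_per_read <- function(mappings, copies) {
  rows_by_read <- split(seq_len(nrow(mappings)), mappings$read_id)
  vapply(rows_by_read, function(rows) {
    M <- length(rows)
    total <- 0
    for (i in rows) {
      same_chrom <- copies$chrom == mappings$chrom[i]
      l <- pmax(0L, pmin(copies$end, mappings$end[i]) -
                      pmax(copies$start, mappings$start[i]) + 1L)
      l[!same_chrom] <- 0L
      total <- total + sum(l) / (M * mappings$read_length[i])
    }
    total
  }, numeric(1))
}

# Naive evaluation of the gene counting strategies: per fragment, per
# mapping, compute the union-mode gene set S over the two mates and apply
# the |S| = 1 rule.
# pairs: data.frame with fragment_id, chrom, s1, e1, s2, e2
# exons: data.frame with gene_id, chrom, start, end
oracle_gene_counts <- function(pairs, exons) {
  gene_ids <- sort(unique(exons$gene_id))
  exon_list <- lapply(gene_ids, function(g)
    exons[exons$gene_id == g, , drop = FALSE])
  names(exon_list) <- gene_ids
  H <- setNames(rep(0L, length(gene_ids)), gene_ids)
  C <- setNames(rep(0, length(gene_ids)), gene_ids)
  rows_by_frag <- split(seq_len(nrow(pairs)), pairs$fragment_id)
  for (rows in rows_by_frag) {
    M <- length(rows)
    for (i in rows) {
      S <- character(0)
      for (g in gene_ids) {
        ex <- exon_list[[g]]
        samec <- ex$chrom == pairs$chrom[i]
        ov <- any(samec & ex$start <= pairs$e1[i] & ex$end >= pairs$s1[i]) ||
              any(samec & ex$start <= pairs$e2[i] & ex$end >= pairs$s2[i])
        if (ov) S <- c(S, g)
      }
      if (length(S) == 1L) {
        C[[S]] <- C[[S]] + 1 / M
        if (M == 1L) H[[S]] <- H[[S]] + 1L
      }
    }
  }
  list(H = H, C = C)
}

# Brute-force all-position scan: returns every start (1-based) on the given
# strand of `genome_str` where `read` matches with <= max_mm substitutions.
oracle_scan_positions <- function(read, genome_str, max_mm) {
  g <- utf8ToInt(genome_str)
  r <- utf8ToInt(read)
  L <- length(r)
  n <- length(g) - L + 1L
  if (n < 1L) return(integer(0))
  mm <- integer(n)
  for (j in seq_len(L)) mm <- mm + (g[j:(j + n - 1L)] != r[j])
  which(mm <= max_mm)
}

revcomp_str <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# all hits of a read on both strands, as a data.frame(pos, strand)
oracle_align_read <- function(read, genome_str, max_mm) {
  fwd <- oracle_scan_positions(read, genome_str, max_mm)
  rev <- oracle_scan_positions(revcomp_str(read), genome_str, max_mm)
  out <- rbind(
    if (length(fwd)) data.frame(pos = fwd, strand = "+"),
    if (length(rev)) data.frame(pos = rev, strand = "-"))
  if (is.null(out)) data.frame(pos = integer(0), strand = character(0))
  else out[order(out$pos, out$strand), , drop = FALSE]
}

# mapping table (single-block alignments) of a read_mappings object, in the
# shape oracle_te_coverage expects
mappings_as_df <- function(reads) {
  m <- as.data.frame(reads$mappings)
  m$start <- m$pos
  m$end <- m$pos + m$read_length - 1L
  m[, c("read_id", "chrom", "start", "end", "read_length")]
}

# pair table of a fragment_mappings object (pure "<L>M" mates)
pairs_as_df <- function(frags, read_length) {
  p <- as.data.frame(frags$pairs)
  data.frame(fragment_id = p$fragment_id, chrom = p$chrom,
             s1 = p$pos1, e1 = p$pos1 + read_length - 1L,
             s2 = p$pos2, e2 = p$pos2 + read_length - 1L)
}
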