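---
title: "Multimapper-aware quantification: models, parameters and design choices"
author: "ambiquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimapper-aware quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A short sequencing read drawn from a recently expanded transposable element
(TE) family, or from one member of a young paralogous gene family, often
aligns equally well to many genomic loci. Standard pipelines either keep
only the primary alignment or discard such *multimappers* altogether. Both
choices are systematically biased: coverage over young TE families is
underestimated relative to old, diverged families (whose copies have
accumulated enough substitutions to make reads unique), and members of
repetitive gene families receive far fewer unique-counting reads than they
actually produced.

ambiquant quantifies both effects and implements the fractional counting
strategies that correct them, together with a synthetic-data module that
generates genomes where the *true* origin of every read is known, so each
claim the package makes is verifiable end to end at desk scale.

## Models

### Fractional TE group coverage

A *TE group* is the set $K$ of all annotated repeat copies sharing one
repeat name, after merging same-name annotations that overlap or are
immediately adjacent. For a library $Q$, each read $r$ of length $L_r$ with
mapping set $M_r$ contributes to the coverage of group $K$:

$$C_K \;=\; \sum_{k\in K}\;\sum_{r\in Q}\;\sum_{r_i\in M_r}
  \frac{I_k(r_i)}{|M_r|}\cdot\frac{l_{k,r_i}}{L_r},$$

where $I_k(r_i)$ indicates whether mapping $r_i$ overlaps copy $k$ and
$l_{k,r_i}$ is the number of aligned nucleotides of $r_i$ inside $k$. A
read that maps once ($|M_r| = 1$) is a *unimapper*; more than once, a
*multimapper*. The statistic is reported stratified by that class, and by
construction the "all" stratum is the sum of the two. A read fully inside
annotated copies contributes exactly 1 in total; partial overlaps and
multimapping spread that mass fractionally.

Two details are deliberate:

* $l$ is computed over the aligned reference blocks of the mapping
  (junction `N` gaps excluded, deletions kept internal), because "aligned
  nucleotides overlapping the copy" is most faithfully the reference bases
  the read actually covers.
* $L_r$ is the full read length including soft-clipped bases, so a clipped
  read contributes less than 1 even when all its aligned bases fall inside
  a copy. The ratio is a property of the read, not of the alignment.

### Gene counting under three strategies

For paired-end RNA-seq, the counting unit is the *fragment* (proper read
pair); a fragment is a multimapper when at least one mate maps more than
once, so $M_f$ is the set of its proper pairings. Every strategy shares
union-mode overlap semantics: the gene set $S(f_i)$ of a fragment mapping
contains every gene with at least one exon overlapped by at least one
aligned base of either mate, and a mapping counts only when $|S| = 1$ —
mappings overlapping no gene or more than one gene count nowhere. This is
the default (`--nonunique none`) behaviour of HTSeq-count, reimplemented
here so the baseline and the corrections share one overlap engine.

* **Unique-only baseline** $H_g$: only fragments with $|M_f| = 1$ count;
  the single mapping with $S = \{g\}$ adds 1 to $g$.
* **Fractional (multimapper-aware)** $C_g = \sum_f \sum_{f_i \in M_f}
  I_g(f_i)/|M_f|$, where $I_g(f_i) = 1$ only when $S(f_i) = \{g\}$.
* **Random selection** $R_g$: one mapping is drawn uniformly per fragment,
  then the unique-only rule is applied to it. Gene by gene,
  $\mathbb{E}[R_g] = C_g$, which the test suite verifies by Monte Carlo.

Because a unimapper contributes identically to $H$ and $C$, and
multimapper mass is non-negative, $C_g \ge H_g$ always. Expression values
divide by the gene's genomic span $L_g$ (end minus start — not the exon
sum), a gene is *expressed* when $C_g > 0$, and it is *under-quantified*
by the baseline when the expression ratio $(C_g/L_g)/(H_g/L_g) = C_g/H_g$
strictly exceeds a factor (default 2).

The case $H_g = 0$ with $C_g > 0$ is not covered by the ratio formula; the
package treats it as an infinite ratio and flags the gene, since the
baseline assigned nothing to a gene the multimapper-aware strategy found
expressed. $H_g = C_g = 0$ is never flagged. This convention is an explicit
package choice and is documented here rather than hidden in code.

### Clade (age) assignment

Each repeat family can be annotated with the set of taxonomic clades in
which it was presumably active. When several clades are listed, the group
is assigned the *youngest* one according to a user-supplied ranking; a
default human-lineage ranking (Homo < Homininae < Hominoidea < Catarrhini
< Simiiformes < Primates < Euarchontoglires < Eutheria < Theria < Mammalia
< Amniota < Tetrapoda) ships as a config file. "Youngest" is a
lineage-dependent notion, which is why the ranking is data, not code.
Families with no clade entry are excluded from clade-level aggregation.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `factor` (under-quantification) | 2 | strict ratio threshold on $C/H$ |
| `threshold` (multimapper fraction) | 0.70 | per-group share of touching reads that are multimappers |
| `keep_pattern` | `NULL` (keep all) | reference filter; `CHIP_REFERENCE_PATTERN` keeps `chr1..22, X, Y` and drops scaffolds and `chrM`, applied *before* multiplicity is computed |
| `min_mapq` | off | mapping-quality cutoff; off because the fractional strategies are defined on the full mapping set |
| `top_n` | 50/100/200 | sizes of the ranked protein-coding lists |
| `max_mismatches` (aligner) | 0 | substitutions tolerated per read (per mate) |
| `insert_range` (aligner, paired) | `c(2·read length, 1000)` | allowed outer distance for proper pairs |

Multiplicity is always the count of retained alignment records, not the
`NH` tag: upstream filters change the effective mapping set, so `NH` is
only cross-checked and disagreements reported.

## The synthetic-data module

The generator emulates exactly the structure that produces multimapper
bias, and nothing else:

* **young repeat families** — many near-identical copies (per-site
  divergence about 0–1%) of a random consensus;
* **old families** — the same construction at 10–20% divergence, so nearly
  every read carries copy-specific substitutions and maps uniquely;
* **paralogous gene families** — paralogs copied from one consensus gene
  region (exons and introns) at low divergence, plus independent
  single-copy genes;
* **unique background** and spacers of twice the read length between
  placed elements, so no read or fragment can bridge two elements.

Divergence is substitution-only — no indels. That choice keeps the
stand-in aligner exact (pure Hamming matching) and the truth records
unambiguous; it deliberately sacrifices indel realism. Reads are drawn
error-free by default (an error-rate knob exists for robustness tests)
from both strands, either uniformly, from repeat copies, or from within
single exons (no splicing-aware simulation). Paired fragments use a
truncated normal length distribution (default 250 ± 30 bp, bounded below
by the read length and above by the source region).

The exhaustive aligner reports *every* position on either strand where the
read matches with at most `max_mismatches` substitutions, all hits with
equal mapping quality, the leftmost flagged primary, and `NH` set to the
hit count. Exact search uses `Biostrings::PDict`/`matchPDict`;
mismatch-tolerant search uses `matchPattern`. The suite asserts equality
with a brute-force all-position scan, so the aligner's completeness is a
tested property, not an assumption.

What passing tests on these genomes does *not* show: behaviour under
indels, sequencing errors interacting with mapper heuristics, soft
clipping, nested or fragmented TE annotations, spliced alignments, or any
mapper-specific secondary-hit capping. The package consumes whatever
mapping set the SAM contains and documents that as its contract.

### Designed fixtures

* `young_vs_old_te` — two 20-copy, 300-bp families at divergence 0.005
  (clade Homo) and 0.15 (clade Eutheria); 100-bp single-end reads drawn
  from copies; aligned with 3 mismatches. Three mismatches is roughly
  twice the expected pairwise difference between young copies within a
  100-bp window (2 × 100 × 0.005 = 1), and far below the old family's
  (≈ 30), so young-family reads multimap across copies while old-family
  reads map uniquely. Expected outcome (verified by the tests): the
  unimapper share of the young family's coverage is below 0.1 and the old
  family's above 0.9.
* `paralog_genes` — one 4-paralog family at 0.5% divergence plus 20
  single-copy genes, each two 400-bp exons with a 150-bp intron; paired
  100-bp fragments (250 ± 30 bp) from exons, aligned with 3 mismatches and
  insert window 150–420. Nearly every family fragment multimaps over all
  four paralogs, so each paralog receives $C \approx n/4$ with $H \approx
  0$ and is flagged under-quantified, while single-copy genes satisfy
  $C = H$ exactly.
* `trim_series` — one 20-copy young family plus background; 3000 100-bp
  reads (60% from repeats, 40% uniform), trimmed at the 3' end to
  25/50/75 bp and each length aligned exactly. The probability that a
  length-$L$ window of a young copy is substitution-free is about
  $0.995^L$, so the multimapper fraction falls strictly with read length.

## Numerical and coordinate choices

* Internally, all intervals live in `GRanges`/`IRanges` (1-based, closed),
  the native convention of the Bioconductor interval stack that performs
  all overlap arithmetic. BED and rmsk 0-based starts are converted on
  ingest; GTF is already 1-based. Lengths and merge semantics are
  unaffected by the convention.
* "Immediately adjacent" means a zero-length gap (`end + 1 == start` in
  closed coordinates); a 1-bp gap is never merged. Strand is ignored for
  merging and all overlap tests.
* Fractional counts accumulate in double precision with extended-precision
  summation (both `data.table` grouped sums and base `sum()` use long
  doubles); the suite checks agreement with naive re-computation to
  1e-9 absolute on libraries of 10,000 reads.
* Rounding of $C_g$ for downstream count-based tools is half-up
  (`floor(C + 0.5)`) and happens only at export; the raw fractional value
  is always kept alongside.
* Top-N ranking breaks ties deterministically by gene id (ascending), so
  repeated runs produce identical lists.
* Random selection draws one uniform variate per read/fragment under a
  user-supplied seed (`withr::with_seed`, leaving the session RNG state
  untouched); identical seed and input order give identical selections.
* Degenerate inputs: empty annotations or libraries give empty (not
  failing) tables; reads of length 0 are an error; groups touched by no
  read are excluded from threshold-share denominators (a fraction of an
  empty set is undefined) but still appear with coverage 0.

## Problem sizes in the test suite

The suite and the acceptance script run entirely on generated data, sized
to exercise the statistics without waste: 10,000 single-end reads for the
streaming-vs-naive equivalence, 4,000 reads for the young-vs-old contrast,
1,250/500/200 fragments for gene counting (the 200-fragment library drives
10,000 seeded random-selection runs), 3,000 reads for the trim series, and
40-read subsamples per genome for the brute-force aligner comparison.
These sizes are the package's own choices and are stated here so the
designed statistical margins (e.g. 4 standard errors for the expectation
identity, α = 0.001 for the proportion test) can be judged against them.

## Known limitations

* Gene overlap is unstranded by default; stranded protocols are supported
  via an option but the synthetic module does not simulate them.
* Paired-end TE coverage is out of scope ($C_K$ is defined on single-end
  reads); mates can be fed as independent reads explicitly.
* No duplicate-read removal, adapter trimming, or quality filtering —
  those are upstream stages whose output the package consumes.
* The under-quantification flag for $H = 0$, $C > 0$ genes is a package
  convention (see above), and the "maps to a group" relation for the
  multimapper-fraction statistic is any-overlap of at least one base —
  both are interpretations that other implementations might make
  differently.
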