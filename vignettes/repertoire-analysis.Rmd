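---
title: "Methods: clonotyping, repertoire features and hypermutation profiling"
author: "repscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonotyping, repertoire features and hypermutation profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repscope)
```

This vignette documents the statistical definitions, modelling choices and
numerical conventions implemented in repscope. It is the reference for what
each number the package prints actually means.

## The clone as the unit of analysis

Rep-seq reads aligned to the IGH locus are grouped into **clones**: records
sharing the same V gene, the same J gene, the same C gene (by default), and
an identical CDR3 nucleotide sequence. Grouping is at the *gene* level —
allele suffixes (`*01`) are stripped before comparison — because allele
calls are unstable across aligners while gene calls are not. The C gene can
be dropped from the key (`use_c_gene = FALSE`) to merge clones that switched
isotype; both definitions are in circulation, and the C-inclusive one is
the default because isotype-stratified hypermutation analysis requires it.

A clone's read count is the sum of its supporting records' duplicate
counts. Its representative CDR3 amino-acid sequence and junction fields are
taken from the highest-count supporting record (ties broken by record id),
which makes clustering deterministic and permutation-invariant. Output
order is descending read count, then clone key.

The CDR3 convention throughout is junction-inclusive: the sequence runs
from the conserved second Cys codon (immediately after FR3) through the
conserved Trp codon of FR4, so printed CDR3s look like `CARGYGMDVW`.

## Repertoire features

Two weighting schemes coexist deliberately:

* **Clone-count based** — gene usage and CDR3 length distributions report
  the *fraction of clones* with a given gene or length. A hugely expanded
  clone counts once; these features describe the recombination repertoire.
* **Read-weighted** — the diversity statistics (Shannon `-Σ p_i ln p_i` in
  nats, Simpson `Σ p_i²`, D50, top-100 fraction) use clone frequencies
  `p_i = reads_i / total reads`; these describe the expansion structure.

D50 ranks clones by abundance and reports `100·m/R`, where `m` is the
smallest number of top clones whose cumulative frequency reaches 0.5 and
`R` the clone count. The boundary is `≥ 0.5` (not `>`), so a clone holding
exactly half the reads gives `m = 1`. Shannon satisfies `H ≤ ln R` and
Simpson `≥ 1/R`, with equality exactly for an even repertoire; both bounds
are asserted in the test-suite.

### Junction diversity

Clones with V, D and J assignments and complete junction fields contribute
deletion-length tallies at four sites (V3′, D5′, D3′, J5′) and insertion
lengths at the two junctions (V–D, D–J). Insertions and deletions are
treated as **mutually exclusive observations of the same junction**: a
clone with a positive insertion at a junction contributes length 0 to that
junction's deletion tallies, and a clone with a positive deletion
contributes 0 to that junction's insertion tally. The rule is applied per
junction by default — an insertion at V–D says nothing about D–J — because
the two junctions are formed by independent trimming events; a
clone-global variant (`exclusivity = "global"`) is available for
compatibility with tools that zero all deletions whenever any insertion is
present. Whichever variant is chosen, no clone can feed both the insertion
and a deletion tally of one junction, and the test-suite asserts this over
10⁵ simulated clones.

## Somatic hypermutation profiling

Mutation analysis is restricted to FR1–FR3 of the V segment (the junction
itself is not a mutation substrate — it differs from germline by
construction) and is computed **per isotype**, since class-switched and
naive compartments have very different mutation loads.

The clone is the unit of observation: for one clone, the frequency at
position `p` is the fraction of its non-redundant supporting reads carrying
a mutation event there, summed over the at most three possible substitution
events (a read carries exactly one base at `p`, so the value is in [0, 1]).
Clone-level frequencies are then averaged with **equal weight per clone** —
a 10,000-read clone and a 2-read clone contribute equally — so expanded
clones do not dominate the mutation landscape. Duplicate counts are
intentionally ignored inside this module.

Positions are keyed per (V gene, position); no cross-gene alignment is
imposed, because any such alignment (IMGT numbering or otherwise) would
add an external convention the rest of the package does not need. Region
rates are the arithmetic mean of the position frequencies over each
region's (gene, position) cells, pooled across genes; this makes the
region rate exactly the mean of the positional matrix restricted to the
region, an identity the tests check to 1e-12. The transition matrix entry
(b → c) is the mean, over positions with germline base b, of the
clone-averaged b→c event frequency, so each row sums to that base's mean
mutation frequency (a conservation law, also asserted).

### Locus classes and motifs

Each FR1–FR3 position inside a complete codon is classified by enumerating
its three alternative bases against the standard genetic code: all
synonymous → *silent*, none synonymous → *replacement*, mixed →
*composite*. A substitution creating a stop codon counts as
non-synonymous: a stop is never a silent outcome. The 64 codons × 3
positions = 192 cases are verified against an independent brute-force
enumeration in the tests.

Hotspot motifs WRCY/RGYW (tagging the mutable C and G) and WA/TW (tagging
the A and T), and coldspot motifs SYC/GRS (tagging the C and G), are found
by IUPAC scan (W = A/T, R = A/G, Y = C/T, S = C/G) with overlapping matches
all recorded; a position may carry several tags. Note that some motif
instances are easy to miss by eye — `GGG` is itself a valid GRS coldspot
(R = G, S = G). Motif rates are reported per locus class × motif tag cell
with `all` marginals.

## Group comparison and public clones

A reference group is selected from a repertoire catalog by exact-match
metadata filtering (tissue, health condition, isotype, read length, primer
locations, ...); unspecified criteria match everything. Feature
comparisons report, per category (gene, length, junction site), the
reference group's five-number summary using linear-interpolation quantiles
(R's default type 7 — deterministic and the common spreadsheet convention)
plus each experimental sample's value, unclipped. Categories absent from a
sample take value 0, which is the correct reading for distributional
features (an unobserved gene has usage 0).

Public-clone detection counts a sharing key **once per sample** regardless
of clone count. The default key is the CDR3 amino-acid sequence — the
level at which convergent responses across individuals are usually
reported — with CDR3 nucleotide and V/J + CDR3nt keys available for
stricter definitions. Keys carried by at least `min_share` (default 2)
samples, at least one of them experimental, are reported as *intragroup*
(experimental carriers only) or *intergroup* (carriers in both groups),
sorted by total carrier count. The implementation is validated against a
brute-force membership-matrix oracle on simulated 20-sample groups.

## Annotation, enrichment and query

Clone annotation is exact, case-sensitive, full-string CDR3 amino-acid
identity against the antibody database; all matching records are listed
and their disease tags unioned. Database ingestion enforces the standard
20-letter alphabet and unique ids but deliberately does not require a
C...W junction pattern, since curated light-chain and F-ending junctions
exist.

Disease enrichment uses a hypergeometric upper tail `P(X ≥ k)`
(`k = 0` → p = 1), i.e. the over-representation convention that includes
the observed count. The counting contract is clone-level: the universe `N`
is the database records carrying at least one disease tag (configurable to
the full database), `K` the records tagged with the disease, `n` the
annotated clones with at least one tag, `k` the annotated clones tagged
with the disease, each clone counted once per disease (so Σk may exceed
`n` for multi-tag clones). Diseases with `k ≥ 1` form the
Benjamini–Hochberg family within one sample; the full table is returned
with a significance flag at adjusted p < 0.05. In the degenerate case
`k > K` (several distinct clones matching one record) the observation lies
outside the hypergeometric support and p = 0 is reported. One caution on
the BH step-up: it is *not* an idempotent map (re-adjusting an adjusted
vector changes it — `[.01,.02,.04] → [.03,.03,.04] → [.04,.04,.04]`); only
its internal monotone-enforcement step is.

Sequence query in amino-acid mode is exact full-string equality; in
nucleotide mode a hit needs local-alignment identity ≥ 0.90 — identity
defined as matching columns over alignment columns, gap columns included —
*and* alignment coverage of at least 90% of the query. The coverage
condition pins down the denominator ambiguity in a bare "90% identity"
criterion: without it, a local alignment could trim mismatching ends and
report inflated identity on a fragment. Candidate subjects are prefiltered
by a shared k-mer (pigeonhole bound: ≤ d mismatches over a length-L query
guarantee an exact run of ⌊(L−d)/(d+1)⌋), then aligned with
Biostrings::pairwiseAlignment (match +1, mismatch −1, gap open 2,
extension 1).

## The simulator and what passing tests show

`simulate_repertoire()` draws, per clone: V/D/J segments from usage
vectors (uniform by default); trimming lengths at V3/D5/D3/J5 and
N-insertion lengths at VD/DJ from truncated geometric distributions
(one-parameter, non-negative, mode at zero — the qualitative shape of real
junction statistics without claiming a fitted model); random insertion
bases; an isotype from a six-category vector; a clone abundance
proportional to `rank^-a` (Zipf), normalised to a total read target
(default 20 reads/clone) and floored at one read; and per-read i.i.d.
point mutations over the V segment with the base rate (default 0.02/base,
an IGHG-like load) multiplied at hotspot positions (×3 default) and
divided at coldspot positions (×0.3), capped at probability 1. Planted
public clones are synthesised from a fixed reverse-codon table and
injected into exactly the requested samples. Defaults were chosen once as
field-plausible study conditions and are not tuned to test outcomes.

Everything is deterministic given the seed; per-sample seeds in grouped
simulations derive from the master seed. The ground-truth object carries
every generative variable (genes, trims, insertion sequences, abundances,
per-read mutation strings), is JSON-serialisable, and suffices to
recompute every downstream feature — the tests assert feature equality
between the emitted TSV route and the truth route.

The simulator deliberately omits: lineage structure within clones
(mutations are i.i.d. per read, which is sufficient for the clone-as-unit
estimator but cannot test phylogenetic methods), sequencing error,
selection and affinity maturation dynamics, biologically calibrated gene
usage priors, and cross-position mutation correlation beyond single-site
motif multipliers. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not biological realism of any
particular dataset.

Problem sizes used by the test-suite were chosen to make sampling error
negligible relative to the asserted tolerances: 10,000 clones for
parameter-recovery checks (3 standard errors), 20 seeds for the
hotspot-ratio sign check, 20 samples × 1,000 clones for the public-clone
oracle, and 10⁵ clones for the junction-exclusivity sweep.

## Degenerate inputs and numerical conventions

* All internal coordinates are 0-based half-open; AIRR's 1-based closed
  columns are converted at the boundary, and the MiXCR refPoints layout is
  documented in `?parse_refpoints`.
* Frequency vectors are validated to sum to 1 within 1e-9;
  `0·ln 0 := 0` in the Shannon index.
* Empty inputs warn and return empty structures (empty record table,
  isotype with no clones, repertoire with no D calls); genuinely
  inconsistent inputs (negative derived deletions, mutation positions
  beyond the germline, duplicate database ids) are errors.
* Ties are always broken lexicographically (gene hits with equal scores,
  clones with equal counts), so every output is reproducible
  byte-for-byte; the pipeline writes no timestamps into its tables.
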