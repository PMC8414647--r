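# repscope

Offline analysis of antibody heavy-chain (IGH) repertoire sequencing
(Rep-seq) data in R. The package takes aligned clone/read tables (AIRR
Rearrangement TSV, a MiXCR clone-export subset, or its own native TSV
dialect) plus a germline V/D/J/C reference, and provides the analysis layer
a repertoire study needs once alignment is done:

* **Clonotyping** — records sharing the same V gene, J gene, optionally C
  gene, and CDR3 nucleotide sequence are clustered into clones; isotypes
  (IGHM/IGHD/IGHG/IGHA/IGHE/NA) are assigned from the best C-gene hit.
* **Repertoire features** — V/D/J gene usage (clone-count based), CDR3
  length distributions (nt and aa), junction diversity (deletion lengths at
  V3/D5/D3/J5 and non-templated insertion lengths at VD/DJ, with insertions
  and deletions treated as mutually exclusive events per junction), and
  clonal diversity:
  - Shannon index `H = -Σ p_i ln p_i` (nats),
  - Simpson index `Σ p_i²`,
  - D50 — the percentage of distinct clones whose cumulative reads reach
    50% of the repertoire,
  - top-100 clone fraction,
  computed on read-weighted clone frequencies.
* **Somatic hypermutation profiling** — per-isotype position-weighted
  mutation frequencies over FR1–FR3 with the clone as the unit of
  observation; silent / replacement / composite locus classification from
  the genetic code; canonical hotspot (WRCY/RGYW, WA/TW) and coldspot
  (SYC/GRS) motif rates; and the 4×4 germline→observed base transition
  matrix.
* **Group comparison** — metadata-based reference selection, per-category
  five-number summaries of a reference group against experimental samples,
  and public (convergent) clone detection: keys shared by ≥ `min_share`
  samples are classed *intragroup* (experimental samples only) or
  *intergroup* (spanning experimental and reference groups).
* **Annotation and enrichment** — clones are annotated by exact CDR3
  amino-acid identity against an antibody database; disease
  over-representation is tested with a hypergeometric upper tail
  `P(X ≥ k)` and Benjamini–Hochberg FDR correction.
* **Sequence query** — exact amino-acid and near-exact (identity ≥ 90%)
  nucleotide search over CDR3s or variable regions.
* **Simulation** — a seeded V(D)J recombination simulator (gene usage,
  truncated-geometric trimming and N-insertion, motif-biased point
  mutation, power-law clonal expansion, planted public clones) that emits
  native TSV plus a ground-truth object, so every stage above is testable
  without external data.

## Worked example

Simulate a repertoire with known ground truth, cluster it, and extract
features:

```r
library(repscope)
params <- simulation_params(n_clones = 2000, seed = 42)
sim <- simulate_repertoire(params, sample_id = "demo")
sim$repertoire
#> <repertoire> demo: 1993 clone(s), 40808 read(s)

round(diversity_indices(sim$repertoire), 4)
#>      shannon      simpson          d50 top_fraction
#>       3.1497       0.1752       0.1004       0.9210

round(gene_usage(sim$repertoire, "V"), 3)
#>  IGHV1-8 IGHV3-23 IGHV4-59
#>    0.337    0.347    0.316

prof <- repertoire_shm_profile(sim$repertoire, params$germline, "IGHG")
prof
#> <shm_profile> isotype IGHG, 978 clone(s)
#>   region rates: FR1=0.02407, CDR1=0.03662, FR2=0.01657, CDR2=0.04377, FR3=0.03011
round(hotspot_to_untagged_ratio(prof, params$germline), 2)
#> [1] 2.91
```

Reading: 2,000 simulated clones collapse to 1,993 clonotypes (a handful of
junctions coincide). The power-law clonal expansion (exponent 1.5) gives a
strongly skewed repertoire — the top 100 clones carry 92% of reads and only
0.1% of clones are needed to reach half the reads (D50). The three V genes
are used near-uniformly by default. Hypermutation is concentrated in the CDR
loops (CDR1/CDR2 rates above the frameworks) and runs ~2.9× hotter at
hotspot-motif positions than at untagged positions, matching the simulated
3× hotspot multiplier.

A full pipeline (features, hypermutation, group comparison, public clones,
annotation, enrichment) runs from a YAML config; a bundled fixture
demonstrates the layout:

```r
cfg <- validate_config(system.file("extdata", "fixture_config.yaml",
                                   package = "repscope"))
cfg$outdir <- "repscope_out"
run_pipeline(cfg)   # writes TSV tables + manifest.json
```

The same pipeline is scriptable from a shell via the thin CLI wrapper in
`inst/scripts/repscope.R` (subcommands `analyze`, `compare`, `annotate`,
`simulate`, `query`).

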