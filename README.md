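# dualsplice

Annotation and differential analysis of alternative splicing from RNA-seq
data with **two complementary callers**, at desk scale.

Most exon-centric splicing tools are *mapping-first*: reads are aligned to
the reference genome and junction reads are interpreted against a
transcript annotation. The alternative is *assembly-first*: reads are
assembled into a De Bruijn graph, transcript variations surface as
*bubbles* (pairs of internally vertex-disjoint paths sharing their end
k-mers), and only the assembled variant sequences are aligned to the
genome, with the annotation used as evidence rather than as a filter. The
two designs miss different events — the mapping-first caller cannot call
unannotated exons or combinations and silently drops multi-mapping reads
from recent paralogs; the assembly-first caller misses lowly expressed
isoforms, prunes relatively weak junctions inside highly expressed genes,
and skips the highly branching graph regions created by repeat families
(e.g. exonised Alu elements). `dualsplice` implements both, runs the same
differential test on each, and mechanises the comparison, so each caller's
blind spots are measured rather than assumed.

For users: bioinformaticians who want a transparent, fully testable
re-implementation of this dual strategy on small genomes or simulations —
for teaching, method comparison, or as a reference implementation of the
individual components (bubble enumeration, exon projection, junction
filters, PSI testing).

## The core model

Per skipping event, inclusion (variant 1) and exclusion (variant 2)
junction counts in a 2-condition, replicated design follow a negative
binomial GLM on the expected intensity λ:

    log λ_ijk = μ + α_i + β_j + (αβ)_ij

with isoform effect α, condition effect β, and isoform×condition
interaction (αβ). H0: (αβ)_ij = 0 (no differential usage) is tested by a
1-df likelihood-ratio test; p-values are Benjamini–Hochberg adjusted. The
effect size is the Percent Spliced In,

    PSI = counts_variant1 / (counts_variant1 + counts_variant2),

computed per replicate (masked below 10 counts), averaged per condition;
ΔPSI = PSI_1 − PSI_2. A call is significant at FDR 5% with |ΔPSI| ≥ 0.1.
The NB dispersion is pooled across events from the within-cell replication
(see the methods vignette for why a per-event estimator fails at two
replicates).

## Worked example

Simulate a 4-gene genome with one skipping event per gene, run both
pipelines end to end and compare them:

```r
library(dualsplice)
cfg <- sim_config(seed = 42, n_genes = 4, n_events = 4, coverage = 40)
out <- run_pipeline("all", outdir = "readme_out", config = cfg)

out$assembly$events[, .(event_id, type, gene_id, skip_start, skip_end,
                        incl_c1r1, excl_c1r1)]
#>    event_id          type gene_id skip_start skip_end incl_c1r1 excl_c1r1
#> 1:   asm001 exon-skipping  gene01       1011     1124      17.0        18
#> 2:   asm002 exon-skipping  gene02       3870     3984       4.5        16
#> 3:   asm003 exon-skipping  gene03       6139     6288       7.0        26
#> 4:   asm004 exon-skipping  gene04       8892     9027      24.5         5

out$diff_b
#> Differential splicing: 4 event(s); 1 significant (padj <= 0.05,
#> |DeltaPSI| >= 0.1); 0 untestable
#>    event_id     p_value       padj      psi1      psi2    delta_psi significant
#> 1:   map001 0.727962892 0.93775911 0.4864469 0.5245957 -0.038148801       FALSE
#> 2:   map002 0.618354675 0.93775911 0.3399779 0.2934169  0.046560924       FALSE
#> 3:   map003 0.937759113 0.93775911 0.3031746 0.3090909 -0.005916306       FALSE
#> 4:   map004 0.004408934 0.01763574 0.7870491 0.4816785  0.305370622        TRUE
```

Each assembly event is one classified bubble: `skip_start`/`skip_end` are
the skipped-exon coordinates from the spliced alignment of the two bubble
paths, and `incl_`/`excl_` columns are junction-read counts per sample
(inclusion = mean of the two inclusion junctions). The differential table
shows one event whose inclusion rate shifts by ΔPSI ≈ 0.31 between
conditions — the one simulated regulated event at this seed — significant
after BH adjustment; the others are planted nulls. `readme_out/summary.json`
records the cross-pipeline comparison: here all 4 events are found by both
callers (`post_common_fraction: 1`) and their ΔPSI estimates correlate at
0.998.

The engineered failure modes are reproduced with
`sim_config(scenarios = c("novel_exon", "paralog", "repeat_exon",
"low_minor", "complex_event"))`: the novel exon and the paralog pair are
then reported only by the assembly path (the latter as an exact repeat),
the repeat-derived annotated exon and the weak-minor events only by the
mapping path, and `compare_pipelines()` labels each with its category.

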