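# utrintrons

Detection, classification and splicing statistics of 3′ UTR introns (3UIs).

## The problem

Introns downstream of a stop codon are classically expected to trigger
nonsense-mediated decay (NMD): an exon junction complex deposited more than
~55 nt past the termination codon recruits the decay machinery. Yet
transcript catalogues and cancer transcriptome assemblies contain thousands
of isoforms with spliced 3′ UTRs, and they split into two very different
groups:

* **e3UI** — *exclusively UTR* introns, whose splice sites are used by no
  coding region of any isoform (bona-fide 3′ UTR splicing);
* **co3UI** — *CDS-overlapping* introns, which share a splice donor or
  acceptor with a coding intron of another isoform and are usually in the
  UTR only because of an early premature termination codon.

`utrintrons` implements the annotation-comparison algorithm that makes this
separation: each query transcript is matched to every high-confidence
reference whose start codon falls in a query exon and whose intron chain the
query reproduces exactly across the reference CDS span; query introns
downstream of the matched stop codon are reported as 3UIs, classed
e3UI/co3UI against a genome-wide coding-boundary index, flagged novel
against all annotated junctions, and annotated with their spliced distance
to the stop codon for comparison with the 55-nt rule. Around that core the
package provides the merge-stage assembly filters, sequence features
(GC, GT–AG canonicality, DRACH motif counts), expression filters
(TPM > 1, transcript/gene fraction > 0.25, broadly-expressed calls with
junction coverage), percent-spliced-out (PSO = 1 − PSI) summaries with a
per-gene Spearman screen (Benjamini–Hochberg adjusted, Fisher-z comparison
of conditions), and a fully seeded synthetic fixture generator with planted
ground truth.

It is a tidyverse-native package: functions take data frames (or tibbles
with list-columns for transcript models) and return tibbles, results have
`tidy()`/`glance()`/`autoplot()` methods, and everything chains with the
pipe.

## Worked example

Generate a synthetic dataset with planted truth, run the full annotation
workflow, and screen for expression–PSO correlations:

```r
library(utrintrons)

fx <- make_fixture(fixture_spec(n_genes = 12, seed = 1), outdir = "demo")
res <- annotate_utr_introns("demo/reference.gtf", "demo/assembly.gtf",
                            genome_fasta = "demo/genome.fa",
                            tpm_tsv = "demo/tpm.tsv")
dplyr::select(res$records, transcript_id, klass, novel, distance_to_stop,
              donor2, acceptor2, canonical)
#> # A tibble: 9 × 7
#>   transcript_id klass novel distance_to_stop donor2 acceptor2 canonical
#>   <chr>         <chr> <lgl>            <int> <chr>  <chr>     <lgl>
#> 1 TX_GENE001    e3UI  FALSE              300 GT     AG        TRUE
#> 2 TX_GENE002    e3UI  TRUE               135 GT     AG        TRUE
#> 3 TX_GENE003    co3UI FALSE               80 GT     AG        TRUE
#> 4 TX_GENE005    e3UI  FALSE              200 GT     AG        TRUE
#> 5 TX_GENE008    co3UI FALSE              200 GT     AG        TRUE
#> 6 TX_GENE009    co3UI FALSE               80 GT     AG        TRUE
#> 7 TX_GENE010    e3UI  FALSE              135 GT     AG        TRUE
#> 8 TX_GENE011    e3UI  FALSE               35 GT     AG        TRUE
#> 9 TX_GENE012    e3UI  FALSE               80 GT     AG        TRUE
```

Each row is one detected 3UI: its class, whether its junction is annotated,
and its spliced distance from the matched stop codon (e.g. 35 nt is below
the 55-nt NMD threshold, 135 nt above it — `nmd_expectation()` makes that
call explicit). All planted splice sites are canonical GT–AG here, as the
generator promises.

The statistics layer recovers a planted regulator whose expression tracks
mean e3UI PSO at Spearman −0.34 in normal samples but not in cancer:

```r
pso  <- pso_from_psi(fx$psi)
summ <- sample_average_pso(pso, fx$event_classes, fx$sample_sheet)
expr <- normalize_counts(make_correlated_quant(fx)$counts)
cors <- correlate_genes(expr, summ)
dplyr::filter(cors, gene_id == "REGULATOR", klass == "e3UI")[,
  c("rho_normal", "rho_cancer", "z_diff", "p_diff")]
#>   rho_normal rho_cancer    z_diff      p_diff
#> 1 -0.5353846  0.2276923 -2.750866 0.005943791
```

The negative normal-condition correlation, its loss in cancer, and the
significant Fisher-z difference are exactly the planted pattern (25 samples
per condition, so individual estimates are noisy; at n = 100 the recovered
rho is within a few hundredths of the target).

A command-line wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript inst/cli/utrintrons simulate --outdir fx --seed 7 --n-genes 50
Rscript inst/cli/utrintrons annotate --reference fx/reference.gtf \
    --assembly fx/assembly.gtf --genome fx/genome.fa --tpm fx/tpm.tsv \
    --outdir out
```

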