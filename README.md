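# memorytc

Transcriptional memory analysis of heat-shock time-course RNA-seq.

## The problem

When *Saccharomyces cerevisiae* is heat-shocked a second time after a
recovery period, the transcriptional response differs from the naive one —
mostly it is *dampened*: heat-induced genes rise less, heat-repressed genes
fall less. Dissecting this "transcriptional memory", and how it depends on
a mutant background, calls for a factorial design — strain (wild type vs
mutant) × exposure history (memory vs no-memory) × time (0, 15, 20 min of
shock) with biological replicates — and a per-gene model that separates the
time trend from its modulation by each factor.

`memorytc` is for researchers analyzing such designs (and for validating
the analysis itself): it covers the path from a count matrix to per-gene
effect labels, plus a negative binomial simulator with known ground truth
so every step is testable.

## The model and the classifier

Per gene, log2 expression is regressed on a quadratic time polynomial and
its interactions with the 0/1-coded factors M (memory) and S (strain):

    y = b0 + bM·M + bS·S + bMS·MS
        + bT·t + bTM·tM + bTS·tS + bTMS·tMS
        + bT2·t² + bT2M·t²M + bT2S·t²S + bT2MS·t²MS + e

After a gene-level time-trend filter (F-test of all time terms,
Benjamini–Hochberg across genes) and hierarchy-respecting backward stepwise
elimination (a term is only removable when no retained higher-order term
marginalizes it), each significant factor is labeled by comparing the
modulated slope with the reference slope bT:

| condition                                | label    |
|------------------------------------------|----------|
| sign(bT + bTM) opposite to sign(bT)      | reversed |
| abs(bT + bTM) > abs(bT)                    | enhanced |
| abs(bT + bTM) < abs(bT)                    | dampened |
| not significant / equal magnitude        | no_change |

(the same rule with bTS for strain; the interaction compares the net slope
of the doubly exposed cell against the additive expectation). Around this
core: TMM normalization and CPM filtering, PCA QC, empirical
noise-distribution differential expression with five-level fold-change
categories and transition tables, UpSet-style overlap counts, proportion
tests of gene subsets, Fisher/BH gene-set over-representation, and
2^−ΔΔCt qPCR quantification with paired t-tests.

## Worked example

```r
library(memorytc)

cfg <- run_config(sim = sim_config(n_genes = 2000), seed = 1)
run <- run_pipeline(cfg)
run
#> Transcriptional-memory pipeline run (seed 1)
#>   genes: input 2000 -> filtered 1990 -> time-significant 994
#>   memory effects: dampened=318, enhanced=153, no_change=373, reversed=150
#>   truth recovery: memory=0.867, strain=0.930, interaction=0.928
```

Reading the output: of 2,000 simulated genes, 1,990 pass the CPM ≥ 1
low-count filter and 994 show a time trend at FDR 0.05 (half the simulated
transcriptome is flat by design). Among time-significant genes the memory
condition most often *dampens* the response (318 dampened vs 153 enhanced),
matching the generator's truth table, and the per-factor labels agree with
the known truth for 87–93% of genes. `glance(run)` returns the same
numbers as a one-row tibble, `tidy(run$fits)` the per-gene coefficient
table, and `autoplot(run$pca)` / `autoplot(run$classes)` /
`autoplot(run$transitions)` the standard displays. Real data enter through
`run_config(counts_path = ..., design_path = ...)` or the individual
functions (`filter_low_counts()`, `normalize_counts()`,
`fit_timecourse()`, `classify_genes()`, ...).

## Vignette

`vignettes/transcriptional-memory.Rmd` documents the model and its
assumptions, the significance-gating design, what the simulator does and
does not emulate, and known limitations (in particular the ~0.97
linear–quadratic collinearity of a 3-point time course and what it means
for heavily dampened genes).
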