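# p53decode

Tools for analysing how a transcription factor's temporal pattern —
oscillatory versus continuously rising p53 — is decoded into the dynamics
of its target mRNAs and proteins, for systems biologists working with
paired time-course transcriptomics and proteomics (two conditions, two
replicates, hourly sampling over 0–9 h plus a late 24 h point).

## The model

Target-gene kinetics are a discrete-time production–degradation system
with a translational delay, evaluated on an hourly grid:

```
mRNA(t) = (1 − kd^mRNA) · mRNA(t−1) + kp^mRNA · p53(t−1)
prot(t) = (1 − kd^prot) · prot(t−1) + kp^prot · mRNA(t − t_del)
```

Initial conditions are pre-stimulus steady states, so each trajectory is
proportional to its production rate: production sets scale, degradation
and delay set shape. Fitting maximises the squared Pearson correlation
between simulated and observed trajectories (grid search over `kd` and
`t_del`, production recovered by least-squares scaling), and parameters
fitted under the oscillatory regime are frozen to predict the rising
regime — agreement means the input dynamics alone explain the
between-regime difference, failure flags regulation beyond simple
kinetics.

Around the kinetic core the package implements the full analysis:
fold-change / BH-FDR / replicate-correlation differential-expression
filters; fuzzy c-means clustering (fuzzifier 1.3) of z-scored traces;
a 4 × 6 dynamical category table (letters a–k) pairing mRNA and protein
response classes with decoding-mechanism annotation; simulators for
activation thresholds and coherent/incoherent feed-forward loops
(persistence detection and exclusive induction); and the
between-condition area statistics `diff` (3–9 h) and `diff_early`
(0–3 h). A mechanism-labelled synthetic-cohort generator emulates the
study design so everything is testable offline.

## Worked example

```r
library(p53decode)

p53_osc  <- gen_p53(p53_waveform_spec("oscillatory"), 0:24)
p53_rise <- gen_p53(p53_waveform_spec("rising"), 0:24)

gene <- simulate_gene(
  mechanism_spec("simple", kinetic_params(kd_mrna = 0.85, kd_prot = 0.85,
                                          tdel = 0.5)),
  p53_osc, p53_rise, noise_model(0))
grid <- default_grid()
mrna_osc <- sapply(grid, function(t)
  mean(gene$data$level[gene$data$modality == "mRNA" &
                       gene$data$condition == "oscillatory" &
                       gene$data$time == t]))

fit_mrna(p53_osc$times, p53_osc$levels, grid, mrna_osc)
#> <fit_result> kp=1 kd=0.85 tdel=- r2=1.0000

res <- run_pipeline(pipeline_config(n_genes = 60, seed = 1))
str(res$manifest)
#> $ n_induced_mrna_osc : int 55
#> $ n_induced_mrna_rise: int 60
#> $ n_induced_prot_osc : int 35
#> $ n_induced_prot_rise: int 46
#> $ frac_exclusive_mrna: num 0.0833
#> $ frac_exclusive_prot: num 0.412
table(res$categories$letter)
#>  a  b  d  g  h  j  k
#> 15 15  8  3  5  5  9
```

The fit recovers the generating degradation fraction exactly on noiseless
data (`kd = 0.85`, `r² = 1`). On the mixed cohort, the rising regime
induces more species than the oscillatory one at both the mRNA and
protein level, a subset of species is induced under exactly one regime
(the exclusivity fractions), and each gene lands in a dynamical category:
`a` (oscillatory mRNA and protein, fast turnover), `b` (oscillatory mRNA,
stable protein), `d`/`j` (rising-exclusive protein via post-transcriptional
/ transcriptional coherent feed-forward loops), `h` (oscillatory-exclusive
protein via an incoherent loop), `g` (medium activation threshold), and
`k` (no protein induction).

See the vignette (`vignettes/decoding-p53-dynamics.Rmd`) for the models,
their assumptions, and every tunable parameter.

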