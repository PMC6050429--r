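# gpersig

Mass-action modeling of GPER/EGFR signaling and the tamoxifen response in
breast cancer cells, with the downstream RNA-seq expression statistics of a
treated-versus-untreated comparison.

## What this is for

Tamoxifen is best known as an estrogen-receptor antagonist, but it is also
an agonist of GPR30/GPER, a G-protein-coupled estrogen receptor expressed
in MCF-7 cells. Through GPER it can fire growth-factor signaling from the
outside in: Gβγ release activates PLC/PKC and Src, Src matures MMPs that
shed membrane HB-EGF, the released EGF transactivates EGFR, and the
combined input drives the Ras/Raf/MEK/ERK cascade alongside PI3K/Akt and
JAK/STAT. Sustained ERK hyperactivity feeds p53-dependent intrinsic
apoptosis — a mechanism by which a "growth" pathway kills the cell.

`gpersig` provides, as a tested R pipeline:

* core mass-action machinery — species/reaction/rule types, net flux
  `v = kf·∏[reactants] − kr·∏[products]`, stoichiometry matrix `N`, the ODE
  right-hand side `ẋ = N·v(x)`, exact integer conserved-moiety analysis,
  and model validation;
* a packaged **synthetic transcription** of the full
  GPR30/EGFR/PI3K/MAPK/STAT network (128 species, 143 reactions,
  213 parameters, 1 rule) assembled from a documented reaction-table TSV,
  plus seven self-contained pathway motifs for property testing;
* stiff ODE simulation (`deSolve`), treated-vs-untreated observable
  comparison (peak, time-to-peak, AUC, terminal value), normalized local
  sensitivity analysis `S = (∂y/∂p)(p/y)` with ranking, and multi-start
  rate-constant fitting in log space;
* SBML Level 3 export / Level 2+3 import with numeric verification that
  every kinetic law is pure mass action;
* the expression-statistics tail of the analysis: Phred quality, read
  filtering (adapter, >20% N, >50% of bases below Q20), RPKM,
  Benjamini–Hochberg adjustment, DEG calling at q < 0.01, and upper-tail
  hypergeometric gene-set enrichment;
* seeded synthetic-data generators (random mass-action networks, noisy
  time courses, negative-binomial count tables with planted DEGs, gene
  sets with one planted enriched term) so every stage is testable with
  known ground truth.

## Worked example

```r
library(gpersig)

m_u <- build_full_model("untreated")   # tamoxifen input clamped at 0
m_t <- build_full_model("treated")     # tamoxifen input clamped at 1 uM
print(m_t)
#> <sig_model> gper_signaling_treated (treated)
#>   128 species, 143 reactions, 213 parameters, 1 rule(s)

cmp <- compare_conditions(m_u, m_t, full_model_observables(m_t)$ppERK)
print(cmp)
#> <sig_comparison> ppERK
#>   untreated: peak 0.004434 uM @ 3600 s, AUC 10.78 uM*s
#>   treated:   peak 0.105 uM @ 282 s, AUC 341.5 uM*s
#>   peak ratio 23.7, AUC ratio 31.7, treated_exceeds_untreated = TRUE

rank_sensitivities(m_t, full_model_observables(m_t), "Tam_dose")
#>    observable max_abs_S  mean_abs_S rank
#> 1       ppERK 1.8910650 0.041146131    1
#> 2       ppMEK 1.8306667 0.017787577    2
#> 3 Raf1_active 0.9562446 0.009641634    3
#> 4 PI3K_active 0.8719455 0.126927057    4
```

Reading the numbers: with the tamoxifen input on, total doubly
phosphorylated ERK peaks at 0.105 µM about five minutes after stimulation
and stays elevated (AUC 32× the untreated hour), whereas the untreated
model only accumulates a weak basal signal from its small EGF bolus. The
sensitivity table ranks the four headline observables by the maximum over
time of the normalized coefficient with respect to the tamoxifen dose:
ppERK responds the most — each tier of the dual-phosphorylation cascade
amplifies the relative response, so the most downstream readout is the most
dose-sensitive.

The expression tail works the same way on tabular data:

```r
syn <- synthetic_counts(n_genes = 1000, n_samples_per_group = 10,
                        n_up = 50, effect_log2fc = 3, seed = 1)
degs <- call_degs(syn$stats, q_threshold = 0.01)
table(degs$direction)

pe  <- planted_enrichment(seed = 1)
head(hypergeom_enrichment(pe$gene_list, pe$gene_sets, pe$background), 3)
```

Models move in and out of SBML with `write_sbml()` / `read_sbml()`, and
trajectories export to TSV with `trajectory_to_table()`.

## A caveat on the packaged network

The packaged reaction and species tables are labelled `*_synthetic.tsv`
deliberately: they are a reconstruction of the network from its pathway
biology, with rate constants chosen by this package (see the methods
vignette, `vignettes/gper-signaling-methods.Rmd`). Structure counts are
exact; dynamics reproduce the qualitative treated-versus-untreated and
sensitivity-ranking results, not quantitative measurements.
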