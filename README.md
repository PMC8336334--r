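# tmesig

Immune and stromal tumor-microenvironment (TME) signatures and scores from
bulk gene expression.

Bulk tumor profiles mix malignant, immune and stromal cells, and the balance
of the latter two carries prognosis: immune infiltration is typically
protective, a fibrotic/stromal phenotype typically adverse. `tmesig` is for
computational oncologists who want to (a) **train** cohort-derived immune and
stromal gene signatures that are explicitly tied to overall survival, and
(b) **score** any cohort — their own, or one profiled on a different
platform — against such signatures, classifying samples into four TME
subtypes (HH, HL, LH, LL).

## The method

**Training** (expression matrix + survival data + immune/stromal marker
sets):

1. Gene-wise z-score then min–max normalization of the expression matrix
   `V` (genes × samples).
2. Non-negative matrix factorization `V ≈ W H` (multiplicative updates,
   KL divergence). Each `H` row is a per-sample latent-program activity;
   the *immune* program is the factor whose activity is protective in a
   univariate Cox model (HR < 1, p < 0.05) and whose top-weighted genes are
   most enriched for immune markers; the *stromal* program analogously with
   HR > 1 and stromal markers.
3. Joint gene selection with an ℓ2,1-regularized two-task regression of the
   two activities on all genes,

   minimize over W:  Σ_t ‖W_tᵀX − Y_t‖²_F + ρ₁‖W‖₂,₁ + ρ_L2‖W‖²_F

   solved by accelerated proximal gradient (FISTA); the ℓ2,1 penalty zeroes
   whole gene rows jointly across the two tasks.
4. Refinement: rank-2 consensus clustering of samples on the selected
   genes, moderated differential expression (limma) across the split, BH
   adjustment, and a sign split — significant genes with positive logFC
   (immune-high reference cluster) form the immune signature, negative
   logFC the stromal signature.

**Scoring** (expression matrix + a signature pair): per-sample ssGSEA
enrichment scores for each signature (rank-based, hence platform-robust),
min–max normalized across the cohort, then a median split on each score
giving the HH/HL/LH/LL subtype (first letter immune, second stromal).
Kaplan–Meier, log-rank, Cox, concordance-index and marker-ratio utilities
(e.g. the T-cell exhaustion ratio (PD-1+CTLA4+LAG3+TIM-3)/(CD28+CD40LG))
support the downstream analyses. A seeded synthetic-data generator with
planted immune/stromal modules makes every stage testable offline.

## Worked example

```r
library(tmesig)

sim  <- simulate_tme(sim_params(seed = 1))          # 2000 genes x 200 samples
refs <- make_reference_sets(sim$truth, rownames(sim$expression),
                            contamination = 0.2, seed = 1)
tr <- run_train(sim$expression, sim$clinical,
                immune_refs = refs["IMMUNE_REF"],
                stromal_refs = refs["STROMAL_REF"],
                k = 8, seed = 1, nmf_tol = 1e-5)
tr$signatures
#> TME signature pair: 60 immune genes, 41 stromal genes

sc <- run_score(sim$expression, tr$signatures)
head(sc$scores, 3)
#>   sample_id immune_raw stromal_raw immune_norm stromal_norm
#> 1      s001        479         926       0.467        0.937
#> 2      s002        881         734       0.878        0.763
#> 3      s003        414         353       0.401        0.419
table(sc$subtypes$subtype)
#> HH HL LH LL
#> 22 78 78 22

cx <- cox_univariate(setNames(sc$scores$immune_norm, sc$scores$sample_id),
                     sim$clinical)
#> immune score Cox HR = 0.074 (p = 3.98e-17)
```

The trained immune signature recovers the 60 planted immune-module genes
exactly here (the stromal signature picks up 40/41 planted genes plus one
bystander), the normalized scores track the latent activities at Spearman
ρ ≈ 0.98, and the immune score is strongly protective — the direction the
method is built to find. `signature_to_gmt()` + `write_gmt()` export
signatures for reuse; `run_score()` accepts any two-set GMT, so a published
signature pair can be applied without retraining.

A thin CLI covers the same flow:

```sh
Rscript inst/cli/tmesig.R simulate --seed 1 --out sim/
Rscript inst/cli/tmesig.R train --in sim/expr.tsv --clinical sim/clin.tsv \
    --immune-refs sim/refs.gmt --stromal-refs sim/refs.gmt --k 8 --out tr/
Rscript inst/cli/tmesig.R score --in sim/expr.tsv \
    --signatures tr/signatures.gmt --out sc/
```

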