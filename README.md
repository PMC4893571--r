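# rvmlpq

Sequence-based prediction of protein–protein interactions (PPIs) with a
sparse Bayesian classifier over local-phase texture features of
evolutionary profiles.

High-throughput PPI screens (yeast two-hybrid, co-immunoprecipitation)
are costly and noisy, which makes computational prediction from sequence
alone attractive. This package implements one such predictor end to end,
for computational biologists who want a transparent, fully inspectable
reference implementation rather than a black box:

1. **PSSM** — each protein is represented as an L×20 Position Specific
   Scoring Matrix, either read from PSI-BLAST ASCII output
   (`read_psiblast_pssm()`) or built internally from the sequence with
   the Dayhoff PAM250 mutation matrix:
   X<sub>ij</sub> = Σ<sub>k</sub> p(i,k) · q(j,k), where p(i,k) is the
   frequency of amino acid k at position i and q is the substitution
   table.
2. **LPQ** — the PSSM is treated as a grayscale image and summarized by
   Local Phase Quantization: a short-term Fourier transform over a
   sliding M×M window at four low frequencies u₁=(a,0), u₂=(0,a),
   u₃=(a,a), u₄=(a,−a); the signs of the eight real/imaginary parts are
   packed into an 8-bit code per pixel, f(x) = Σ<sub>j</sub> q<sub>j</sub>(x)·2ʲ,
   and histogrammed into a fixed 256-bin feature vector. The phase signs
   are invariant to centrally symmetric blur, which makes the descriptor
   robust to smooth distortions of the profile.
3. **PCA** — per-protein 256-vectors are reduced by SVD-based principal
   component analysis (`fit_pca()`), fitted on training proteins only.
4. **RVM** — pairs are classified by a from-scratch Relevance Vector
   Machine (`rvm_fit()`): Gaussian-kernel design matrix
   Φ = [1, K(xᵢ,xⱼ)], Gaussian likelihood on the 0/1 labels, independent
   Gaussian priors with precisions αᵢ optimized by the evidence
   fixed-point updates γᵢ = 1 − αᵢΣᵢᵢ, αᵢ ← γᵢ/μᵢ²,
   σ² ← ‖t − Φμ‖²/(N − Σγᵢ). Most αᵢ diverge and their basis functions
   are pruned; the surviving training pairs are the relevance vectors.
5. **Evaluation** — shuffled k-fold cross-validation (`run_cv()`)
   reporting accuracy, sensitivity, specificity, precision and Matthews
   correlation per fold (mean ± sd) plus a pooled ROC/AUC, and an SVM
   baseline (`run_svm_baseline()`, RBF, cost 0.7, gamma 0.6) on
   identical folds.

A seeded synthetic-data module (`synthetic_spec()`, `gen_pair_dataset()`,
`write_fixture_bundle()`) generates sequences, PSSM-like matrices and
balanced pair lists in which interacting pairs share a rank-one motif —
so the whole pipeline can be exercised and benchmarked offline, without
databases or PSI-BLAST runs.

## Worked example

```r
library(rvmlpq)

spec  <- synthetic_spec(n_pairs = 200, seed = 42)   # strong motif signal
ds    <- gen_pair_dataset(spec)
feats <- featurize_pssms(ds$pssms)                  # 400 x 256 LPQ matrix
cv    <- run_cv(ds$pairs, feats, pipeline_config(pca_k = 100, seed = 42))
print(cv)
#> 5-fold cross-validation, classifier = rvm, 200 pairs
#>   ac   1.0000 +/- 0.0000
#>   sn   1.0000 +/- 0.0000
#>   sp   1.0000 +/- 0.0000
#>   pe   1.0000 +/- 0.0000
#>   mcc  1.0000 +/- 0.0000
#>   pooled AUC 1.0000
```

The interaction motif here is strong (about five times the background
score spread), so the classifier recovers it perfectly; weaker settings
of `motif_strength` degrade accuracy smoothly toward the 0.5 of
`motif_strength = 0`. A fitted RVM is sparse:

```r
blobs <- cbind(rnorm(100) + rep(c(0, 3), each = 50), rnorm(100))
m <- rvm_fit(blobs, rep(c(0, 1), each = 50))
print(m)
#> Relevance vector machine (regression-on-labels form)
#>   training points: 100  relevance vectors: 19  bias: retained
#>   kernel: gaussian width=0.6 (bandwidth)  sigma2=0.02452
#>   iterations: 448 (converged)
```

## Command line

`exec/rvmlpq` wraps the same functions for shell use:

```sh
rvmlpq simulate         --out bundle --n-pairs 200 --seed 1
rvmlpq extract-features --fasta bundle/proteins.fasta --pssm-dir bundle/pssm --out feats.tsv
rvmlpq evaluate         --pairs bundle/pairs.tsv --features feats.tsv --out report.json --roc roc.csv
rvmlpq train            --pairs bundle/pairs.tsv --features feats.tsv --out model.rds
rvmlpq predict          --model model.rds --pairs bundle/pairs.tsv --features feats.tsv --out scores.tsv
```

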