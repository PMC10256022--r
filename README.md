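# ivas3 — scalable joint blind source separation by shared subspace separation

Joint blind source separation (JBSS) recovers latent sources from `K`
related datasets — in the motivating application, multi-subject
resting-state fMRI, where each subject's scan is a linear mixture
`X[k] = A[k] S[k]` of the same `N` underlying brain networks. Sources of the
same index across datasets form a *source component vector* (SCV). An SCV is
**shared** when it is effectively one common source repeated across all
datasets, so its `K x K` covariance has a single dominant eigenvalue;
non-shared SCVs have full-rank covariances. The two regimes favor different
estimators, and real data contain both.

This package implements a three-stage pipeline for that mixed regime:

1. **SUMCORR initialization.** The multiset-CCA SUMCORR solution — the
   top-`N` principal eigenvectors of the `NK x NK` stacked-data covariance,
   split into per-dataset blocks — is analytic, deterministic, and accurate
   on shared SCVs.
2. **IVA-G** (independent vector analysis with a multivariate Gaussian SCV
   prior) refines it by minimizing

   C(W) = NK·log(2πe)/2 + ½ Σₙ log det Σ̂\_yₙ − Σₖ log |det W[k]|,

   where Σ̂\_yₙ is the covariance of the n-th estimated SCV. Each estimated
   SCV is then classified by the **spectral gap ratio**
   σₙ = (λₙ₁ − λₙ₂)/λₙ₁ of its covariance: σₙ > Δ (default 0.86) ⇒ shared.
3. **Per-subspace IVA.** IVA-G runs again, separately, on the shared and
   non-shared source stacks (identity-initialized), shrinking the problem
   dimension and refining each subspace under the model that fits it. The
   stage demixings compose into one exact linear map from whitened data to
   final sources.

Also included: a simulator with the exact latent structure above (rank-one
shared covariances `μ·11' + (1−μ)·I`, random full-rank `QQ'` non-shared
covariances, multivariate generalized Gaussian sources with shape β = 0.5),
and the evaluation metrics joint-ISI (joint intersymbol interference against
known mixing), normalized mutual information between estimated sources, and
one-sample t-maps with Benjamini–Hochberg FDR control.

## Worked example

Half-shared scenario at `N = 10` sources, `K = 10` datasets,
`T = 20NK = 2000` samples:

```r
library(ivas3)

cfg <- sim_config(n_sources = 10, n_datasets = 10, n_shared = 5, seed = 42)
sim <- generate_ground_truth(cfg)
ws  <- whiten_stack(sim$data, order = 10)

res <- run_iva_s3(ws, settings = ivag_settings(max_iter = 64, tol = 1e-5))
res
#> IVA-S3 result: N = 10 SCVs, K = 10 datasets
#>   partition at Delta = 0.86: 5 shared / 5 non-shared
#>   stage-1 sweeps: 64; stage-3 sweeps: 64 (shared), 64 (non-shared)

round(sort(res$sigma, decreasing = TRUE), 3)
#>  [1] 0.973 0.956 0.942 0.920 0.891 0.386 0.288 0.239 0.209 0.155

G <- mix_demix_products(res$total_demixing, sim$truth, ws)
joint_isi(G)
#> 0.0178
```

The five planted shared SCVs (correlation levels 0.80 down to 0.50) produce
gap ratios 0.89–0.97, cleanly above Δ = 0.86; the five full-rank SCVs sit
below 0.39, so the partition recovers the planted split exactly. Joint-ISI
is 0 for perfect separation (up to scale and permutation) and 1 in the worst
case; 0.018 here beats both single-method baselines on the same data —
SUMCORR alone scores 0.105 (it cannot model the full-rank half) and
randomly initialized IVA-G scores 0.062 (it overparameterizes the shared
half).

A command-line front end covering `simulate`, `run`, and `evaluate` (text
matrices or masked 4-D NIfTI input) is installed at `inst/cli/ivas3`; see
the script header for flags.

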