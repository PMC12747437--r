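# lear — localization-error reduction for chromatin tracing

Chromatin tracing (multiplexed DNA-FISH) localizes tens to thousands of
identifiable genomic loci in single cells, producing "traces" of 3D
coordinates per chromosome copy. Localization errors of 25–100 nm blur
these coordinates — frustratingly close to the distance scale of
enhancer–promoter contacts — inflating pairwise distances and strongly
suppressing measured contact frequencies, especially multi-way ones.
`lear` implements a post-processing correction that needs no extra
experiments, together with the machinery around it: localization-error
estimation from repeat-imaged loci, off-target filtering, simulation-based
validation, and pairwise / multi-way contact analysis.

## The method

For one imaging dimension, the observed coordinates of locus ℓ across N
traces are `O^ℓ = T^ℓ + ε^ℓ` — truth plus independent localization error.
For any pair of loci (α, β) the displacement variance decomposes as

    Var(O^α − O^β) = Var(T^α − O^β) + Var(ε^α)

so, given an estimate of `Var(ε^α)`, the error-free **goal variance**
`μ_{α,β} ≈ Var(T^α − O^β)` is computable from the data. With many loci,
every partner β contributes one constraint on locus α. Corrections
`C^α` are chosen so that the adjusted coordinates `A^α = O^α + C^α`
maximize the likelihood

    l[A^α] ∝ ∏_β  N( Var(A^α − O^β) | μ_{α,β}, σ_{α,β} )

where `σ_{α,β}` is the CLT sampling uncertainty of the variance. The
maximization is a greedy stochastic descent over per-trace corrections
(annealed Gaussian proposals, accepted only when the likelihood improves),
run independently per locus and dimension, which makes it embarrassingly
parallel and bit-reproducible under a fixed seed.

When no error estimate is available, `estimate_error_from_repeats()`
recovers per-round error STDs from repeat-imaged loci (two imagings of one
locus share a true position), and `worst_case_error_bound()` bounds the
error from half the smallest neighbor displacement variance.

## Worked example

Simulate a 100-locus chain at 1 kb-like compaction (30 nm per-axis
neighbor STD), blur it with 50 nm localization error, and correct:

```r
library(lear)
spec  <- simulation_spec(L = 100, N = 500, step_sd = 30, seed = 1)
gt    <- generate_polymer_traces(spec)
noisy <- add_localization_error(gt, sigma = 50, seed = 2)
em    <- error_model(matrix(50, nrow = 100, ncol = 3))
fit   <- run_lear(noisy$observed, em, optimizer_config(seed = 3))
fit
#> lear_result: 500 traces x 100 loci, 3 dimension(s)
#>   dim 1: 100 loci corrected, mean RMS correction 40.7 nm, goal coverage (3 sd) 1.000
#>   dim 2: 100 loci corrected, mean RMS correction 40.9 nm, goal coverage (3 sd) 1.000
#>   dim 3: 100 loci corrected, mean RMS correction 41.0 nm, goal coverage (3 sd) 1.000

rel <- relative_error_per_locus(fit$adjusted, noisy$observed, gt$truth)
mean(rel)
#> 0.697   # 30.3% of the localization error removed

tm <- contact_frequency(gt$truth, 150)
contact_map_frobenius(contact_frequency(noisy$observed, 150), tm)
#> 9.81    # raw map vs truth
contact_map_frobenius(contact_frequency(fit$adjusted, 150), tm)
#> 1.21    # corrected map vs truth
```

The corrections carry ~41 nm RMS against a 50 nm injected error, every
achieved displacement variance sits within 3 uncertainties of its goal,
and the contact map moves about 8× closer to the truth. Larger errors
and tighter locus spacing yield larger gains; at 25 nm error the same
setup improves by ~13%.

On experimental data, start from `read_traces()` (FOF-CT-style CSV or a
simple TSV), clean with `filter_off_target()` /
`filter_by_detection()`, estimate the error from repeat-imaged loci, and
proceed the same way. Multi-way contacts and their independence baseline
come from `multiway_contact_frequency()` and
`expected_independent_multiway()`.

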