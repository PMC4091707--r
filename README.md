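# tfscape

Fitness-landscape inference for transcription factor (TF) binding sites.

## The problem

A TF binds a genomic site of length *L* with free energy
*E*(σ) = Σᵢ ε[i, σᵢ] given by an additive energy matrix, and occupies it
with the Fermi-Dirac probability *p*(*E*) = 1/(1 + e^{β(E−μ)}).  If
organismal fitness depends on the site only through this occupancy,

  *F*(*E*) = f₀ + (1 − f₀) · p(*E*),

then a haploid population that is monomorphic at the locus and has reached
mutation–selection–drift steady state shows the site with probability

  *P*(σ) ∝ π₀(σ) · *F*(σ)^ν,

where π₀ is the neutral (mutation-only) sequence distribution and ν a
scaling effective population size.  Reading this backwards: the observed
distribution of a TF's genomic sites, together with the neutral energy
spectrum *Q*₀(*E*), determines the fitness landscape over binding energy —
nonparametrically via ln *F* ∝ (1/ν)[ln *P*obs − ln *Q*₀], and
parametrically by maximum-likelihood fits of the Fermi-Dirac family, its
constrained "non-lethal" variant (f₀ = 0.99), and the one-parameter
exponential (non-epistatic) limit, compared by AICc/Akaike weights.

The package is for quantitative molecular evolution and regulatory
genomics work: it implements the energy-matrix machinery (PSAM conversion,
unit-SD rescaling, collection alignment), the dinucleotide Markov neutral
model and its exact transfer-matrix projection to *Q*₀, the grid-search
fits with their degeneracy diagnostics (γ = ν(1−f₀) ridges, μ
degeneracies, Hessians, subsample refits), a compiled Wright-Fisher
forward simulator for validating the monomorphism/steady-state
assumptions, permutation and Spearman screens for site-specific
selection, and a fully seeded synthetic-data generator so the entire
pipeline runs without external data.

## Worked example

```r
library(tfscape)

# a complete synthetic study: matrix, background, sites from the exact
# steady state, gene table, ortholog pairs, and the truth record
fx <- make_fixture(fixture_config(L = 8, regime = "threshold",
                                  n_sites = 2000, seed = 2))
fx$truth$params
#> Fermi-Dirac params: f0=0.99 beta=1 mu=2.8766 nu=2000 (gamma=20)

fit <- fit_gridsearch(fx$sites$energies, fx$spectrum, "CFD")
fit
#> CFD fit: lnL=9318.8931 AICc=-18631.7742 (k=3, n=2000)
#> Fermi-Dirac params: f0=0.99 beta=1 mu=2.84 nu=1995.26 (gamma=19.9526)
#> regime: threshold
```

The generating landscape (γ = 20, μ = 2.88 kcal/mol, β = 1) is recovered
to 0.2% in γ and 0.04 kcal/mol in μ, and the sites are correctly labelled
as straddling the bound/unbound threshold.  (`lnL` omits the constant
π₀ site terms, which cancel in all model comparisons, so its sign is not
meaningful.)

The analysis workflow lives in `analysis/01_fixture.R` …
`04_site_selection.R`: numbered drivers that generate the standing
synthetic study, run landscape inference and model selection, validate
the evolutionary assumptions by Wright-Fisher simulation, and run the
site-specific-selection battery, writing their tables under `results/`.

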