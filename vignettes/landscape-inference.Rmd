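---
title: "Inferring fitness landscapes for TF binding sites from their genomic energy distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring fitness landscapes for TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A transcription factor (TF) binds a genomic site of length $L$ with a free
energy that, in the additive (mean-field) approximation, is a sum of
per-position contributions from an energy matrix $\epsilon_{i\alpha}$
(kcal/mol): $E(\sigma) = \sum_i \epsilon_{i,\sigma_i}$.  The probability
that the site is occupied is the Fermi-Dirac function
$p(E) = 1/(1 + e^{\beta(E-\mu)})$, with inverse temperature $\beta$ and
chemical potential $\mu$ (a proxy for free TF concentration).

The package's central hypothesis is that organismal fitness depends on the
site only through this occupancy, interpolating between a fitness of 1 for
an always-bound site and $f_0$ for a never-bound one:

$$F(E) \;=\; f_0 + (1 - f_0)\, p(E).$$

$\beta$, $\mu$ and $f_0$ are treated as *effective* parameters: deviations
from their physical counterparts encode selection pressures beyond the raw
energetics of binding (e.g. an effectively sharper-than-thermal threshold).

A haploid population that is monomorphic at the locus — mutations are rare
enough ($\mu_{rate} N L$ small) that each either fixes or dies before the
next arrives — and has reached mutation–selection–drift steady state
occupies genotypes with probability

$$P(\sigma) \;=\; \frac{1}{Z}\,\pi_0(\sigma)\, F(\sigma)^{\nu},$$

where $\pi_0$ is the neutral sequence distribution and $\nu$ is a scaling
effective population size ($\nu = 2N - 2$ for the Wright-Fisher model).
Projected into energy space this becomes
$P(E) \propto Q_0(E)\,F(E)^\nu$, where $Q_0$ is the neutral energy
spectrum.  Inverting the relation,
$\ln F(E) = \tfrac{1}{\nu}\left[\ln P_{obs}(E) - \ln Q_0(E)\right]$ up to
an overall scale and shift, which is the nonparametric estimate produced
by `invert_landscape()`.

Three parametric families are fitted by `fit_gridsearch()`:

* **UFD** — unconstrained Fermi-Dirac, $k = 4$ parameters
  $(f_0, \beta, \mu, \nu)$;
* **CFD** — the "non-lethal" constrained fit with $f_0 = 0.99$, $k = 3$;
* **EXP** — a pure exponential $F^\nu = e^{-\mathrm{rate}\,E}$, $k = 1$,
  the non-epistatic limit underlying log-odds weight matrices.

Models are compared by finite-sample AICc,
$2k - 2\ln L + 2k(k+1)/(n-k-1)$, and Akaike weights.

## Parameter degeneracies

The steady state does not always identify all four UFD parameters:

* With $f_0 \to 1$, $F^\nu \approx e^{\nu(1-f_0)p}$ up to a constant, so
  only $\gamma = \nu(1-f_0)$ is identified (the likelihood is flat along
  $\ln\nu + \ln(1-f_0) = const$).
* When all site energies sit far above $\mu$ (the exponential tail), only
  the combination $\gamma\,e^{\beta\mu}$ is identified: $\mu$ can be moved
  down indefinitely with a compensating $\nu$.  The mirror-image
  degeneracy holds on the high-occupancy plateau ($E \ll \mu$), with
  $\gamma\,e^{-\beta\mu}$.

Fits are therefore labelled by regime — `exponential_tail`, `threshold`,
`plateau` — according to where the central 80% of $\beta(E-\mu)$ falls
relative to $\pm 2$ (thresholds configurable; the cutoff is ours, anchored
to the qualitative three-way classification of published fits), and carry
degeneracy flags read off the fitted position: $f_0$ on the top grid point
($0.999$), and $\hat\mu$ below or above all site energies.  The
diagnostics (`fit_diagnostics()`) expose the same structure numerically: a
finite-difference Hessian in $(\ln\nu, \ln\beta, \ln(1-f_0), \mu)$, where
the $\gamma$ ridge appears as a near-zero eigenvalue along
$(1, 0, -1, 0)/\sqrt2$, plus half-subsample refits on a doubled-spacing
mesh.

Because the ridge direction couples $\mu$ and $\nu$ continuously, discrete
profile likelihoods along $\mu$ on the tail are jagged unless the
compensating $\nu$ is optimized continuously; `optimize_nu()` exists for
exactly this purpose and is what the degeneracy checks use.

## Selection strength and its $\beta$-dependence

The local selection coefficient per unit energy is
$|s^*| = |d\ln F/dE| = \beta(1-f_0)\,p(1-p)/F$.  Its partial derivative
with respect to $\beta$ at fixed $(E-\mu, f_0)$ changes sign along curves
of constant $x = \beta(E-\mu)$.  For $f_0 = 0$ there is a single boundary
at $x = -(1 + W(e^{-1})) \approx -1.2785$ ($W$ the principal Lambert-W
branch); for $0 < f_0 < 1$ two numeric branches bracket the sign change.
`regime_boundaries()` locates these by sign-scan plus root-finding on the
analytic stationarity function, and the Lambert-W closed form is used as
an independent cross-check in the tests.

## The neutral model and discretization

$\pi_0$ is a first-order Markov chain estimated from mono- and
dinucleotide frequencies of intergenic sequence (`fit_background()`).  We
use row-normalized dinucleotide transitions with the mononucleotide vector
as the initial distribution, so $\pi_0$ sums to exactly one over sequence
space; the mono marginal and the dinucleotide row marginal differ only by
record-edge effects.

$Q_0$ is computed by a transfer-matrix dynamic program over (last base,
discretized energy) states.  Every per-position energy increment is
rounded to the bin grid (default width 0.02 kcal/mol, integer multiples of
the width), so the DP is *exact* for the grid-aligned matrix: mass is
conserved to machine precision, and all binned quantities (steady state,
likelihood normalization) agree with exhaustive $4^L$ enumeration to
$10^{-8}$ or better.  `log_likelihood()` snaps site energies to the same
grid; `snap_matrix()` aligns a matrix to it (worst-case energy shift
$L \cdot \mathrm{width}/2 = 0.08$ kcal/mol at $L = 8$, negligible against
the unit-SD energy scale).  The synthetic generator snaps its matrices at
creation so the whole pipeline is self-consistent.  The default width
keeps the DP to a few hundred bins over the few-kcal/mol support of a
unit-SD matrix.

## Grid-search maximum likelihood

The likelihood surface is ridged, so fitting is an exhaustive mesh scan
rather than gradient ascent.  Default mesh: $\beta \in 10^{[-1,1]}$ and
$\nu \in 10^{[0,6]}$ at 0.1 dex; $\mu$ from 5 kcal/mol below to 5 above
the spectrum support in steps of 0.1; $f_0$ on the two-branch grid
$\{e^{-x}\} \cup \{1 - e^{-x}\}$, $x = 0.2(0.2)10$, truncated at 0.999 —
resolving both the near-lethal ($f_0 = e^{-10} = 4.5\times10^{-5}$) and
near-neutral ends on a log scale, which matches the printed precision
pattern of published fit tables.  Ties are broken toward smaller $\nu$,
then smaller $\beta$, then larger $\mu$, making fits deterministic.  The
scan is compiled (Rcpp); a full UFD scan takes minutes, so repeated refits
(subsampling, simulation sweeps) use the doubled-spacing convention
(`mesh_coarsen()`), and the packaged Wright-Fisher study additionally
coarsens only $\nu$ to 0.2 dex while keeping the $\mu$ resolution that the
threshold regime needs.

## What the synthetic generator emulates

`make_fixture()` produces every input the analysis needs: a random
unit-SD energy matrix (uniform entries rescaled by the analytic background
SD), an AT-rich intergenic record from the Markov chain (mono
$A = T = 0.31$, $C = G = 0.19$, a mild same-base dinucleotide excess —
illustrative, not estimated from any genome), sites sampled *exactly* from
$\pi_0 F^\nu$ by $4^L$ enumeration (alias sampling; a seeded single-site
Metropolis sampler with burn-in $200L$ and thinning $20L$ proposals covers
$L > 10$ and is cross-checked against the exact sampler), a gene table
with essentiality, growth, expression and dN/dS columns that are
independent of energy unless an effect is planted, and ortholog pairs at a
set per-base divergence.  Default study conditions: $L = 8$, $n = 500$
sites, the "non-lethal" landscape $f_0 = 0.99$, $\beta = 1$, $\nu = 2000$
($\gamma = 20$), with $\mu$ placed two SD below the neutral mean
(threshold regime), below the support with $\gamma = 120$ (tail), or
three SD above the neutral bulk (plateau).

What passing on these fixtures does *not* show: real promoters have
overlapping sites, multiple TFs, position-dependent background
composition, and energy matrices with correlated (non-additive) entries;
none of these are emulated, so agreement here validates the machinery,
not the biology.

## Wright-Fisher validation

`wf_simulate()` runs the forward model exactly as the steady-state theory
assumes away: $N$ haploids, fitness-weighted multinomial resampling, then
per-base mutation to one of the three other bases.  The population is
stored as unique-genotype counts, which makes the monomorphic regime
essentially free and lets $10^5$-generation ensembles run in seconds.
The observed distribution is built from one random sequence per replicate
(an unbiased draw from the ensemble), binned on 100 equal-width bins over
the matrix's energy range; distance to the predicted $\pi_0 F^{2N-2}$
state is the total variation distance.  Note that this one-per-replicate
sampling puts a floor of roughly $0.4\sqrt{K_{eff}/R}$ under the TVD at
$R$ replicates, so the neutral-agreement checks use thousands of
replicates.

Two empirical facts shaped the validation scales (both measured with this
package, both stated here as the package's own choices):

* Populations initialized *at* the predicted steady state stay there, but
  the approach from a random start is substitution-limited: at
  $\mu_{rate} = 10^{-5}$, $N = 1000$, $L = 10$ the mean energy needs
  several $10^5$ generations to settle, an order of magnitude beyond the
  neutral $1/(L\mu_{rate})$ estimate, because the final downhill steps
  wait on rare beneficial substitutions.  The validation study therefore
  runs $6\times10^5$ generations for its converged condition, and the
  relaxation-time test checks the $\propto 1/\mu_{rate}$ *scaling* (ratio
  within a factor of 3) rather than the absolute neutral constant.
* At $n = 500$ sites per fit (the resampling unit of the recovery study),
  the threshold-regime fit scatters over the $(\gamma, \beta, \mu)$ ridge
  — seed-to-seed $\hat\gamma$ varies by a factor of ~2 even on the full
  mesh — while at $n = 2000$ the same fit recovers $\gamma$ to a few
  percent and $\mu$ to under 0.1 kcal/mol.  Quantitative round-trip
  assertions (25% on $\gamma$, 0.3 kcal/mol on $\mu$, the
  degeneracy-flag/regime consistency) are therefore made at $n = 2000$;
  at $n = 500$ only ensemble-level statements (mean within 1 SD) are
  made, which is also how the recovery study reports its sweep.

The recovery study (`wf_validation_study()`) refits 200 samples of 500
sequences per condition and shows the three expected behaviors: accurate
$\gamma$ below the monomorphism bound $1/(NL\ln N)$; $\hat\nu$ and
$\hat\beta$ biased low once the population is polymorphic; and $\hat\mu$
biased high before steady state.  The pre-steady bias direction depends
on which side of the steady state the populations approach from, so the
condition pins the start: populations launched from the consensus
(strongest) site and stopped at a fifth of the equilibration time have
lifted off the energy floor but not yet filled the high-energy side of
the steady state; their distribution looks like a neutral spectrum
truncated from above, which the fit explains with an occupancy threshold
placed too high (and a too-soft $\hat\beta$) — the plateau-side ridge.

## Site-specific selection tests

`site_specific_battery()` asks whether binding energy correlates with
anything it should not under a universal landscape: essentiality of the
regulated gene (permutation test on group means and variances, labels
shuffled preserving group sizes, two-sided add-one p-values), knockout
growth rate (the minimum over available conditions), expression, dN/dS,
and TSS distance (Spearman, ties mid-ranked), with sites assigned to
genes by a strand-aware 700-bp upstream window on the site midpoint.
Cross-TF summaries are unweighted mean p-values, and raw p-values are
reported alongside Benjamini-Hochberg-adjusted columns (the adjustment is
an extension beyond the raw-p convention).  Permutations default to
10,000; the add-one estimator keeps $p \ge 1/(n_{perm}+1)$.

## Numerical choices and limitations

* All steady-state and likelihood arithmetic is in the log domain with
  log-sum-exp normalizations; occupancy uses the stable logistic branches.
* Inversion error bars use the binomial delta-method SE
  $\sqrt{(1-\hat f)/(\hat f N)}/\nu$ on the per-bin fraction — a
  documented substitute convention, since only the binomial character of
  the bin counts is assumed.
* $f_0$ estimates on the mesh ends are reported as degeneracy flags, not
  point estimates.
* AICc requires $n > k + 1$; below that the fit reports `NA` and model
  comparison is refused.
* The package fits *site-level* landscapes; promoter-level fitness
  (several sites jointly buffering each other) and fitness penalties for
  over-binding are out of scope, as are dinucleotide energy models and
  PSAM inference from raw binding data.
* Where a site collection mixes sites under genuinely different
  selection, the fitted parameters describe the mixture-averaged
  landscape only.

## Problem sizes used by the shipped analyses

The analysis scripts and tests run: $L = 8$ fixtures at $n = 500$–$2000$
sites; $4^L$ enumeration oracles at $L \le 6$; inversion at $n = 10^4$;
Wright-Fisher at $N = 1000$, $L = 10$, 250–500 replicates with up to
$6\times10^5$ generations; permutation calibration over 2000 null
datasets at 999 permutations each.
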