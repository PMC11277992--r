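---
title: "Methods: formula validation, ensemble ECD simulation and Mosher analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: formula validation, ensemble ECD simulation and Mosher analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npstereo)
```

This vignette explains the models behind `npstereo`, the parameters that
matter, the numerical choices made where the design was open, and what the
synthetic-data tests do and do not demonstrate about real data.

## Molecular-formula arithmetic

Monoisotopic masses come from an internal table of CODATA/IUPAC values
(12C = 12 exactly, 1H = 1.00782503, 16O = 15.9949146, Na = 22.98976928,
35Cl = 34.96885268, 19F = 18.99840322, 14N = 14.0030740; electron
0.00054858 Da). The formula grammar is deliberately flat — element symbols
with optional counts, no parentheses, charges or isotope labels — because
that is how molecular formulas appear in isolation reports and HRESIMS
software.

Adduct m/z always applies the electron-mass correction:

$$m/z = \frac{m(\mathrm{M}) + m(\Delta) - z\,m_e}{|z|}$$

A sodiated cation is one electron light, a deprotonated or chloride-adduct
anion one electron heavy. The correction is 0.00055 Da — about 2 ppm at
m/z 261 — which is the difference between matching and missing a printed
calcd value at 4-decimal precision. Presentation rounding (4 decimals for
m/z, 1 for ppm) mirrors journal formatting; full precision is kept
internally.

Degrees of unsaturation use the standard valence formula
$\mathrm{DBE} = 1 + \sum_i n_i (v_i - 2)/2$ with C 4, N/P 3, O/S 2,
H/halogen 1. It is integral for neutral even-electron molecules; adduct-ion
compositions such as the [M+Cl]$^-$ species are odd-electron and give
half-integer values, which is why the package computes DBE on neutral
formulas.

Isotope patterns are the convolution of per-element isotopologue
distributions aggregated by *nominal* mass offset: 13C and 2H land in M+1,
37Cl, 81Br, 34S and 18O in M+2. Fine structure inside a slot is summed, not
resolved — sufficient for the diagnostic use here, namely the one-chlorine
signature: a single Cl pushes M+2/M to about 0.32 (the 37Cl/35Cl abundance
ratio 0.2424/0.7576), the "3:1" appearance. `chlorine_signature()` accepts
M+2/M in [0.24, 0.42], wide enough for 13C2 contributions of mid-size
molecules on top of the Cl term, and far above the ~0.02 of a CHNO
molecule of this size. The convolution is tested against a direct
enumeration oracle.

## Conformer weighting

Populations follow the Boltzmann expression
$g_i = e^{-\Delta G_i/RT} / \sum_j e^{-\Delta G_j/RT}$ on relative Gibbs
free energies in kcal/mol, $R = 1.98720425\times10^{-3}$ kcal mol$^{-1}$
K$^{-1}$. The temperature defaults to 298.15 K, the standard state at
which Gibbs energies are usually reported; it is configurable on the
ensemble and per call. Free energies are used exactly as supplied — no
fallback to electronic energies — because the weighting is only as good as
the energies fed to it.

The $\Delta G \le 4$ kcal/mol selection rule is boundary *inclusive*
(a conformer at exactly 4.0 survives), and the dG = 0 conformer always
survives, so filtering can never empty an ensemble. At 298.15 K a
conformer 4 kcal/mol up carries a weight of about 0.001 relative to the
ground conformer, so the cutoff discards only spectroscopically irrelevant
structures.

Class-mixture weighting handles the situation where computed energies are
not trusted *across* rotamer families but are trusted *within* them: the
user imposes family totals (say dihedral classes 0°:180° as 40:60), and
within each family the conformers keep their Boltzmann proportions,
renormalised to the family total. With a single family this reduces
exactly to plain Boltzmann weighting; the 40:60 two-family case with one
family split 0.8439/0.1561 internally yields 0.3376/0.0624/0.6, which the
tests pin against hand computation.

## ECD band shapes, scaling and the enantiomer decision

Each electronic transition contributes a Gaussian band on the *energy*
axis:

$$\Delta\varepsilon(E) = \frac{1}{2.297\times10^{-39}\sqrt{\pi}\,\zeta}
\sum_i E_i\, R_i \times 10^{-40}\, e^{-\left((E-E_i)/\zeta\right)^2}$$

with $R_i$ in $10^{-40}$ cgs, giving the dimensionless prefactor
$E_i R_i / (22.97\sqrt{\pi}\zeta)$. Conventions worth stating because
practice varies:

* $\zeta$ is the 1/e half-width in eV (it sits directly in the exponent),
  the common choice in ensemble-averaged ECD work; typical values are
  0.2-0.4 eV.
* The closed-form band area is
  $\int \Delta\varepsilon/E \, dE = R_i / 22.97$; the tests verify this by
  trapezoidal quadrature to 0.5%, which pins both the prefactor and the
  width convention.
* Spectra are built in energy and rendered on a wavelength grid
  ($hc = 1239.84193$ eV nm), default 190-400 nm at 1 nm.
* The empirical UV shift $\Delta\lambda$ (nm) is applied on the
  *wavelength* axis, to the theoretical spectrum. Where possible it is
  applied by re-evaluating the band-shape sum at shifted wavelengths
  (`stick_to_spectrum(..., delta_lambda=)`), which is exact;
  `apply_uv_shift()` interpolates an existing grid and edge-holds, for
  spectra whose sticks are no longer available.

Peak scaling divides a spectrum by the absolute intensity at the positive
local maximum nearest a reference band (default 290 nm, search window
±25 nm): $\Delta\varepsilon_{sc}(\lambda) = \Delta\varepsilon(\lambda) /
|\Delta\varepsilon(\lambda_{peak})|$. This removes the unknown amplitude
calibration of a measured CD curve (concentration, path length, ellipticity
conversion). It is idempotent and invariant under positive rescaling of
the input; it fails loudly, reporting the window, when no positive local
maximum exists there.

Spectral comparison is the cosine similarity of the two curves resampled
onto their common wavelength coverage within a window (default
$\lambda \ge 200$ nm, where measured curves are reliable): +1 for
proportional same-sign curves, $-1$ for mirror images. Literature practice
compares curves qualitatively by eye; a quantitative, sign-sensitive
metric is needed for automation, and cosine is the simplest one whose
extremes correspond exactly to "same spectrum" and "enantiomer". Because
cosine is invariant to positive scaling, the enantiomer decision is
unchanged whether or not the inputs were peak-scaled — which also means a
mirror-image experimental curve (no positive 290 nm band, hence not
scalable by the peak rule) can still be classified. The decision itself
compares the experimental curve against the theoretical one and its
pointwise negation and returns whichever matches better, reporting a tie
within $10^{-12}$ as undecidable.

## Modified Mosher analysis

The package computes $\Delta\delta = \delta_S - \delta_R$ per proton and
evaluates the two sign hypotheses of the MTPA plane model: an R carbinol
center places negative $\Delta\delta$ on the branch labelled side "A" and
positive on side "B"; S reverses the pattern. The geometric step — which
branch is which relative to the MTPA plane — requires the drawn structure
and is therefore delegated to the user through the side labels; automating
it would need connectivity and conformation information a shift table does
not carry.

Protons with $|\Delta\delta| < 0.005$ ppm (below 2-decimal shift
resolution) are uninformative and excluded from the consistency count
entirely; counting them against both hypotheses would prevent a perfectly
consistent table containing one unresolved proton from ever reaching
consistency 1.0. The call is withheld below a consistency threshold
(default 0.8 — published assignments rest on fully consistent patterns,
and a pattern barely above half-matching should not produce a confident
call), and an exact tie between hypotheses is undecidable. Column-swap
antisymmetry (swapping the $\delta_S$/$\delta_R$ columns mirrors the call
at identical consistency) and permutation invariance are enforced by
property tests.

## The synthetic-data generators

No conformer energies, rotatory strengths or digitized spectra are
deposited with the study this package's procedures come from, so its
figure-level curves cannot be regenerated; validation instead uses
synthetic studies with known ground truth.

`generate_ensemble()` emulates what a DFT conformational search of a
flexible decalin polyketide returns: one dominant hydrogen-bond-stabilised
conformer at $\Delta G = 0$ and the rest on an exponential energy ladder
(mean 2 kcal/mol, truncated at 8 = twice the selection cutoff so the
cutoff rule is genuinely exercised), a 60:40 split between the two
dihedral-class labels, and six transitions per conformer. One transition
per conformer is a guaranteed positive band at 4.275 eV (290 nm) emulating
the carbonyl n→π\* band these ketones show; the remaining transitions are
random (energies uniform in 5.2-6.5 eV, i.e. 190-238 nm; rotatory
strengths centred normal, SD 15 × 10$^{-40}$ cgs) emulating the dense
π→π\* region. The deep-UV window is kept clear of the anchor band
deliberately: in these chromophores the n→π\* band *is* spectrally
isolated, and the separation guarantees the positive ~290 nm local maximum
that peak scaling anchors to exists in every draw.

`forward_experiment()` is the measurement model: enantiomer sign ×
amplitude calibration × (shifted ensemble spectrum) + Gaussian noise +
a slow quadratic baseline, with noise and baseline amplitudes expressed
relative to the clean signal's peak so that amplitude calibration cancels
exactly. Real CD noise is wavelength-dependent (worse in the far UV) and
instruments introduce wavelength calibration error; neither is modelled,
so the recovery rates quantify robustness to *amplitude* noise and drift
only, not to every instrumental artefact.

All generators draw from a private RNG stream seeded by their `seed`
argument (the caller's `.Random.seed` is untouched), making them pure
functions of their arguments; Monte-Carlo drivers derive per-trial seeds
deterministically from a master seed.

At the reference conditions — 100 trials, 10% peak-relative noise, 5%
baseline drift — the enantiomer decision recovers the true sign in every
trial, and at zero noise recovery is exact by construction. The Mosher
Monte-Carlo (200 tables, 5 protons per side, 10% per-proton sign-flip
probability, consistency threshold 0.8) recovers the planted configuration
in ≥ 95% of decided tables; the threshold converts borderline scrambled
tables into abstentions rather than wrong calls, which is the behaviour a
chemist wants. Problem sizes (8 conformers × 6 transitions, 211-point
grids, 100-200 Monte-Carlo repeats) were chosen as the smallest that make
the stochastic properties stable across master seeds; the full suite runs
in a few seconds.

## Known limitations

* The package consumes tabulated quantum-chemistry output; it does not
  generate conformers, optimise geometries or compute transitions, and
  the quality of an ECD assignment is bounded by the quality of those
  inputs.
* Band shapes are pure Gaussians with a single global bandwidth; vibronic
  structure, wavelength-dependent solvent shifts and velocity/length gauge
  differences are out of scope.
* The isotope simulator works at nominal-mass resolution and unit charge;
  fine structure and multiply charged species are not modelled, and
  formula *inference* from an observed m/z is deliberately excluded.
* The Mosher module trusts the user's side labels; a mislabelled branch
  mirrors the call, and no amount of internal consistency checking can
  detect it.
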