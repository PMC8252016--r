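---
title: "Multiplet models behind Kbeta XES and 1s3p RXES oxidation-state analysis"
author: "rxesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplet models behind Kbeta XES and 1s3p RXES oxidation-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxesim)
```

## The problem

The Kbeta mainline of a first-row transition metal — 3p to 1s emission after
1s ionization — is split by 3p–3d exchange into the Kbeta~1,3~ main peak and
the Kbeta′ satellite. In principle the splitting counts unpaired d electrons;
in practice covalent dilution of metal 3d character shrinks the effective
exchange integrals so much that a ferric d^5^ site and a ferrous d^6^ site can
show nearly identical mainlines. Resonant 1s3p emission (RXES/RIXS) breaks
this degeneracy: exciting into the 1s→3d pre-edge produces a
1s^1^3d^n+1^ intermediate and a 3p^5^3d^n+1^ final state, and for high-spin
d^n^, n ≥ 5, only the spin-down (β) 1s→3d excitation is allowed, so the
resonant spectrum contains only the maximum-multiplicity final-state terms.
The resulting multiplet structure differs qualitatively between d-counts even
when the non-resonant spectra do not, which is what makes the experiment an
oxidation-state probe. `rxesim` implements the full chain from term algebra
to simulated spectra to the difference-spectrum analysis, so every
qualitative claim can be recomputed from first principles on a desk.

## Electronic-structure model

The model space is the minimal one that carries the physics: the 1s, 3p and
3d shells (18 spin-orbitals). All determinants of a shell configuration form
the basis; the largest space used (3p^5^3d^6^-type with a d^5^ ground state)
has 1512 determinants, so dense diagonalization is always feasible and no
iterative machinery is used.

The Hamiltonian of one configuration is

* **Coulomb repulsion** parameterized by Slater–Condon radial integrals:
  F^0^~dd~, F^2^~dd~, F^4^~dd~ for the d shell and F^2^~pd~, G^1^~pd~,
  G^3^~pd~ for the 3p–3d interaction, combined with closed-form Gaunt
  angular factors in the complex spherical-harmonic basis. Matrix elements
  between determinants follow the Slater–Condon rules (implemented in C++;
  the only hot loop in the package). Direct 1s–3p/1s–3d monopoles and 1s
  exchange integrals are constant or negligible within a configuration and
  are absorbed into a scalar configuration energy offset — all spectral
  structure comes from the 3d–3d and 3p–3d multipole and exchange terms.
* **Spin–orbit coupling** ζ~3p~ l·s and ζ~3d~ l·s, one-electron operators
  per open shell. Defaults in the presets are conventional atomic magnitudes
  for Fe (ζ~3p~ ≈ 0.9–1.0 eV, ζ~3d~ ≈ 0.05 eV).
* **Cubic ligand field** as the one-parameter e/t~2~ splitting of the 3d
  shell (barycenter preserved; T~d~ puts e below t~2~, O~h~ the inverse),
  applied after transforming from complex to real cubic harmonics. No
  lower-symmetry distortions are modeled, matching the one-knob treatment
  that the analysis requires.

Covalency is treated entirely through multiplicative reduction of the 3p–3d
Slater–Condon parameters (the `scaling` slot); an independent factor for the
d–d parameters exists but defaults to 1. F^0^ is never scaled — it is a pure
shift.

In the spherical, zero-spin-orbit limit the package labels every degeneracy
group with a Russell–Saunders term. Because the Slater parameterization
produces accidental degeneracies (for d^7^ the ^2^P and ^2^H terms coincide
exactly), S² and L² are diagonalized simultaneously inside each energy
cluster before labeling; the resulting group multiset equals the pen-and-paper
term enumeration exactly, which the tests assert.

## Spectra

**Non-resonant Kbeta XES** uses the sudden approximation: both α and β 1s
ionization channels statistically populate the 1s-hole eigenstates (giving,
for a d^6^ ground state, the ^4^D and ^6^D manifolds with 2:3 weight), then
each 3p→1s emission stick is weighted by the squared many-body amplitude of
the spin-conserving one-electron operator, summed incoherently over the three
3p orbital components (an isotropic orientation average). Only the
ground-state degeneracy group is populated — no thermal excitation.

**1s3p RXES** evaluates the Kramers–Heisenberg double sum: for each final
state, the coherent sum over intermediate states of emission × absorption
amplitudes divided by E~g~ + Ω − E~n~ + iΓ~i~/2, squared and averaged over
the ground degeneracy and the orbital components of both transition
operators, then multiplied by an energy-conservation Lorentzian of width
Γ~f~ in (Ω − ω) − (E~f~ − E~g~). A Gaussian instrumental convolution is
applied last, along the emission axis only. Interference between
intermediate states is kept by default (`coherent = FALSE` exists as a
diagnostic). The implementation prunes states with exactly zero route
amplitude and is verified in the tests against an independent brute-force
triple loop at random grid points to 10^−10^ relative.

Constant-incident-energy cuts, HERFD traces (fixed emission energy), and the
total 1s→3d absorption profile are derived views of the plane. Each cut
carries its final-state transition strengths as stick provenance, so
analyses can separate true transition intensity from lifetime tails.
Rising-edge excitation is not modeled with explicit continuum states: by the
observation that edge-excited RXES collapses onto the non-resonant spectrum,
the `rising_edge` mode of `rxesEmissionCut()` delegates to the XES path.

### Line widths

Defaults are Γ~i~ = 1.25 eV (Fe K-level lifetime width), Γ~f~ = 1.6 eV
(Fe M~2,3~ lifetime width), and a 0.7 eV FWHM Gaussian. The 3p core-hole
width deserves a note: 3p holes in 3d metals decay by super-Coster-Kronig
channels and are intrinsically broad (~1.5–2 eV; the natural Kbeta~1,3~
linewidth of ~3–4 eV is the sum of the K and M~2,3~ widths). With this
physical value the simulated ferric pre-edge cut shows a single Kbeta~1,3~
maximum with a weak low-energy shoulder ~2.7 eV below, while the ferrous cut
keeps a resolved ~2 eV doublet — exactly the observed contrast. A narrower
final-state width (0.5 eV) turns the ferric shoulder into a resolved second
maximum. One exception is documented below for the covalency scan.

### Energy calibration

A semi-empirical multiplet model produces relative energies only. Two rigid
offsets place the axes on the experimental scale: an absorption origin for
incident energies and an emission origin. They carry no physics: the tests
assert that all splittings and intensity ratios are invariant under both to
10^−12^. The presets compute their offsets automatically so that the
pre-edge resonance and the Kbeta~1,3~ maximum land at typical Fe values
(~7112–7113 and ~7059–7061 eV).

## Analysis operations

* `normalizeSpectrum()` — unit area (trapezoidal, over a window) or unit
  maximum. Area mode is the default for difference spectra because it makes
  mixture subtraction exactly linear.
* `differenceSpectrum()` — resamples operands onto their intersection grid
  (linear interpolation, no extrapolation), normalizes both, subtracts the
  ferric reference.
* `findSpectralPeaks()` — interior local maxima filtered by prominence
  (default 2% of the spectrum maximum, ties toward lower energy); shoulders
  are concave regions of a 5-point Savitzky–Golay second derivative that
  contain no maximum.
* `exchangeSplitting()` — the Kbeta~1,3~–Kbeta′ separation. The default
  "peak" method mirrors how the splitting is read off a measured spectrum:
  strongest maximum in a window 8–20 eV below the mainline, with a
  barycenter fallback flagged as unresolved. At full atomic parameters the
  satellite complex is rich and partly outside any fixed window, so a
  second method, "cluster", measures the separation of the
  intensity-weighted two-group partition of the stick spectrum — the direct
  α/β exchange separation of the final-state manifolds. The cluster metric
  is the one that grows strictly with the unpaired d-count (d^2^→d^5^),
  which the acceptance suite asserts.
* `kbetaPrimeSuppression()` — the "intensity only on the Kbeta~1,3~
  channel" observable: the Kbeta′-window fraction of the resonant cut over
  the same fraction of the non-resonant spectrum. It is measured on the
  transition-strength sticks by default because at the physical Γ~f~ the
  Lorentzian tail of the mainline alone floors the broadened-window ratio
  near 10%; the stick ratio expresses the spin-selection theorem itself
  (presets: ~1%, versus ~300% for d-counts below 5 where no selection rule
  operates).
* `covalencyScan()` — re-simulates the pre-edge cut while scaling the
  3p–3d parameters from 100% down to 40%. The scan's purpose is to track
  multiplet term positions, so the acceptance battery renders it at a 0.5 eV
  final-state width — a display choice for peak tracking, not a lifetime
  claim; at the physical 1.6 eV width the ferrous doublet merges below
  ~50% scaling while the underlying term splitting (the quantity of
  interest) remains well-defined.

## Synthetic data

The presets stand in for the measured systems: ferrous/ferric tetrachloride
sites carry the 60%/45% 3p–3d reductions used in the study's fits, and
sulfide-like sites a stronger 50%/40% reduction as a covalency stand-in.
Every radial integral is a standard atomic Hartree–Fock magnitude for Fe and
is recorded in the preset metadata as an assumption — the source study does
not print its parameter values. Mixtures (mixed-valent dimers, cubanes,
MoFe-protein-like 4:3 ferrous:ferric) are incoherent weighted sums of
area-normalized single-site spectra, all cut at the ferrous pre-edge
resonance (the measurement protocol for mixed-valence samples); inter-site
coupling such as the double exchange of delocalized mixed-valence pairs is
deliberately outside the model. Pseudo-measurements add a rigid calibration
shift and seeded Poisson (peak-count) or Gaussian noise, bit-for-bit
reproducible from the seed (default 20210323).

What passing tests on these synthetic data do **not** show: that the preset
parameters are quantitatively right for any real compound, that absolute
energies are predicted (they are calibrated), or that mixture spectra of
real clusters are simple site sums. They do show that the term-coupling
logic, the spin-selection rule, the covalency robustness, and the
difference-spectrum protocol behave as the physics dictates.

## Numerical choices

* Degeneracy clustering tolerance 10^−6^ eV; S/L expectation rounding
  tolerance 10^−3^.
* Dense Hermitian diagonalization (LAPACK `zheev` through `eigen()`), basis
  dimension ≤ 1512.
* Stick rendering integrates the Lorentzian CDF per grid cell and
  renormalizes over the window so each stick contributes exactly its weight
  to the in-grid area; zero widths reduce to nearest-node binning. The
  Gaussian kernel is discrete, truncated at 6σ and renormalized.
* Amplitude pruning threshold 10^−12^ relative — removes exact zeros only.
* Weighted 2-means for the cluster splitting is seeded deterministically at
  the energy extremes.
* The test and acceptance problem sizes are the full chains of the physical
  systems (up to the 1512-determinant d^5^ XES final state); nothing is
  subsampled.

## Known limitations

* LS-coupled atomic + cubic-field model only: no charge-transfer
  configurations (3d^n+1^L̲), no hybridization hopping, no polarization or
  angular anisotropy (the transition operators are isotropic averages), no
  Boltzmann population of excited ground levels.
* d^1^/d^2^ pre-edge cuts at Fe-scale parameters do not resolve the
  characteristic second Kbeta~1,3~ maximum: their configuration-interaction
  gap (~1–1.7 eV) lies below the Fe core-hole width. The grouping rule for
  those d-counts is carried by the term algebra
  (`predictSpectralClass()`); resolving it in a simulated spectrum would
  require early-transition-metal parameters and widths, which are outside
  the preset set.
* Calibration offsets are inputs, not predictions; only splittings and
  intensity ratios are meaningful outputs.
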