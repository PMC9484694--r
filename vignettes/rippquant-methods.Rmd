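---
title: "Methods: quantifying peptide modification from LC-MS and MS/MS data"
author: "rippquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying peptide modification from LC-MS and MS/MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rippquant)
```

This vignette is the package's own account of its models and the choices
behind them. `rippquant` quantifies post-translational modification of RiPP
precursor peptides from centroided LC-MS data and annotates their MS/MS
spectra. The pipeline has five parts: mass bookkeeping, charge-ladder
deconvolution, fraction-modified quantification, b/y-ion annotation, and a
ground-truth synthetic-data generator used to validate all of the above.

## Mass bookkeeping

Peptide masses are sums of standard residue (water-subtracted) masses plus
one water; the table ships with the package (`residue_masses`) on both the
average scale (used for all intact-mass work, where isotopes are
unresolved) and the monoisotopic scale (used for fragment ions, where they
are). The residue values are the standard ones, stated to 5 decimals; no
external mass table is consulted at run time. `MassScale` is explicit at
every call so the two regimes cannot be mixed silently.

Ions are protonated species: `mz_for_charge()` computes
$(M + z \cdot 1.00728)/z$ with the physical proton mass. The one deliberate
exception is charge-ladder deconvolution (below), whose printed procedure
uses a bare 1 Da proton; we keep that form by default there, with a
`physical_proton` flag for users who prefer the physical constant.

**Modification states.** A modification registry (name, average and
monoisotopic delta, maximum count, optional residue targets) defines the
expected species in an extract. `enumerate_states()` always includes the
unmodified and fully modified states; intermediate occupancies are included
only for modifications whose individual shift is at least 15 Da in
magnitude (default `partial_threshold`), because a unit-resolution
instrument cannot separate the per-occupancy species of a ±2 Da thioether
on a 10+ kDa fusion, whereas an 18 Da dehydration ladder is resolvable.
A state is labelled `modified` only when *every* registered modification is
at full count; any other state with at least one applied delta is
`partial`.

## Charge-ladder deconvolution

An electrosprayed species of mass $M$ appears as $[M+zH]^{z+}$ at several
consecutive charges. Given five consecutive peaks $m_1 < \dots < m_5$
(descending charge), each adjacent pair determines the charge of its
lower-$m/z$ member:

$$z_i = \frac{m_{i+1} - 1}{m_{i+1} - m_i}.$$

Each pairwise estimate is converted to an estimate of the lowest charge
$z_5$ by subtracting the peak's proton offset relative to $m_5$; the four
estimates are averaged *before* rounding (the order is irrelevant for the
mean, but this is the documented choice), and rounded half-away-from-zero
(ties are not expected from real data; the rule makes the behaviour
deterministic). Charges are then fixed as $z_i = z_5 + (5 - i)$ and each
peak inverted to an uncharged mass $M_i = z_i m_i - z_i$.

The reported uncertainty is the larger of the sample standard deviation of
the five $M_i$ and the instrument resolution floor $\sigma z_1$, with
$\sigma = 0.3$ (QQQ, from FWHM 0.7 via $\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$)
or $\sigma = 0.026$ (QTOF; the stored constant is 0.026 even though
FWHM/2.3548 rounds to 0.0255 — we keep the conventional stored value).
Because the inversion subtracts $z \times 1$ rather than $z \times 1.00728$,
a noiseless ladder generated with physical protons reconstructs to
$M + \bar z \times 0.00728$; the offset (a tenth of a dalton at $\bar z = 12$)
is far below the resolution floor of the instruments this procedure serves,
which is why the printed form is kept as the default.

Selecting *which* five peaks form the ladder is the analyst's job;
`pick_ladder()` offers an intensity-based helper but is explicitly a
convenience beyond the core procedure.

## Fraction-modified quantification

For each expected modification state:

1. **EIC per charge.** Every charge whose $[M+zH]^{z+}$ lies inside the
   instrument scan window (500–2000 m/z for the QQQ profile, 100–3200 for
   QTOF) gets an extracted ion chromatogram: per-scan summed intensity
   within ±2/z Da (QQQ) or ±1/z Da (QTOF) of the predicted m/z. Scans with
   no matching peaks contribute zero, so every EIC lives on the same time
   grid.
2. **ECC.** Charge-state EICs are summed pointwise into the extracted
   compound chromatogram. The identity ECC = Σ EIC is exact by
   construction and asserted in the tests.
3. **Peak fit.** The ECC is fitted with a density-scaled skew-normal,
   $f(t) = b + A \cdot \tfrac{2}{\omega}\phi(x)\Phi(\alpha x)$,
   $x = (t - \xi)/\omega$ — parameters peak area $A$ (intensity·min,
   baseline excluded), retention time $\xi$ (min), width $\omega$ (min),
   skew $\alpha$, baseline $b$. Fitting is bounded Levenberg–Marquardt
   (`minpack.lm::nlsLM`) with deterministic initialisation: location and
   height from the maximum point, width from the half-maximum span, zero
   skew, minimum intensity as baseline. Bounds: $A \ge 0$, $\xi$ inside the
   trace, $\omega$ between half a scan interval and the trace span,
   $\alpha \in [-10, 10]$, $b \in [0, \max y]$. A flat, empty or
   non-converging trace yields `converged = FALSE` and zero area.
4. **Validity screen.** A fitted peak is trusted only if: more than eight
   charge states show signal at the fitted retention time ±0.2 min (read
   literally as ≥ 9; the threshold is configurable via `peak_criteria()`
   because the intended boundary is ambiguous), at least four of them
   consecutive; the ECC has no secondary peak above 80% of the tallest
   peak and at most two above 40%; fitted skew lies in [0, 1.5]; fitted
   width is ≤ 0.25 min. Secondary peaks are counted among local maxima of
   the raw ECC after a 3-point moving mean, ignoring maxima below 5% of
   the global maximum, and excluding the candidate peak itself (otherwise
   the 80% rule could never pass). "Presence" of a charge means any
   strictly positive EIC intensity in the window — after the ingest
   intensity floor (1000 by default, matching vendor centroid exports)
   this is a meaningful test; the floor is configurable.
5. **Fraction modified.** Invalid or absent states contribute zero area.
   The fraction is the summed area of states labelled `modified` divided by
   the total valid area; `modified_labels = c("partial", "modified")`
   widens the numerator for chemistries where partially occupied species
   count as product (e.g. summing mono- and di-phosphorylated peptide).
   When no state yields a valid peak the result is flagged undetected
   (`NA` fraction) rather than zero.

Width is interpreted as the skew-normal scale parameter in minutes, and
the reported area is the fitted skew-normal mass excluding baseline; both
are documented interpretive choices. Peak counting is done on the
(smoothed) measured ECC rather than on the fitted curve. States are fitted
independently; co-eluting states are not jointly deconvolved.

## MS/MS annotation

Preprocessing mirrors intensity-heterogeneous centroid MS/MS data: (i)
intensities are capped at `ceiling_multiplier` × mean intensity, so a
dominant precursor or immonium ion does not define the dynamic range; (ii)
the m/z range is cut into `n_slices` equal windows and peaks strictly below
`snr_threshold` × the mean intensity of their slice and its *existing*
neighbours (no wraparound at the edges) are removed.

Hypothetical ions are built from a `peptide_structure()`: a sequence,
residue-localised monoisotopic deltas, and crosslink spans. Fragment
formulas — documented because there is no single convention to inherit —
are: $b_k$ = sum of the first $k$ residue masses (plus their deltas);
$y_k$ = sum of the last $k$ residue masses (plus deltas) plus water; the
parent is the full residue sum plus all deltas plus water. Hence
$b_k + y_{L-k} = \text{parent}$ exactly, which the tests assert against an
independent residue-by-residue oracle. Each ion is emitted at charges 1–3
as $[M+zH]^{z+}$ with the physical proton mass.

Two interpretations are flagged explicitly. First, deltas are
*residue-localised*: a fragment carries exactly the deltas of the residues
it retains. Intact-mass work only needs the total shift, but fragments are
only informative if the shift is placed. Second, backbone cleavage sites
strictly inside a crosslink span (a lanthionine ring, a lactone macrocycle)
are suppressed rather than emitted as ring-opened masses — consistent with
fragmentation being observed between, not within, macrocyclic repeats.
Spans may nest but not partially overlap.

Matching assigns each ion the nearest surviving peak within the m/z
tolerance; a peak may support several ions (fragments genuinely co-incide
in m/z), and exact ties break towards the smaller m/z. Coverage is the
fraction of non-suppressed cleavage sites supported by at least one
matched b or y ion.

## The synthetic-data generator

`simulate_run()` emulates the statistical structure of a centroided MS1
screen of tagged peptide fusions: scans every 0.3 s (QQQ) or 0.25 s (QTOF)
across a 1–6 min window; each species contributes one centroid per visible
charge state at the average-mass $[M+zH]^{z+}$, with intensity =
abundance × discretised-Gaussian charge-envelope weight × skew-normal
elution density. Envelope weights are normalised over the visible charges
(weights below 0.1% of the envelope maximum are truncated), so a species'
integrated signal equals its abundance and abundance ratios are the ground
truth fractions. Background is Poisson in count per scan (default 5),
uniform in m/z, exponential in intensity (default mean 2000, sitting just
above a typical vendor-export floor of 1000). Default elution (width
0.08 min, skew 1) gives the mild tailing of a sharp reversed-phase peptide
peak; default abundances around 10⁷ match the intensity scale of a
QQQ screen. All randomness flows from the mandatory seed.

`simulate_msms()` injects a random subset of a structure's hypothetical
ions (probability `efficiency`) with log-normal intensities, plus many
low-intensity background peaks (default 500 at mean 100 versus fragment
intensities around 10⁵). The count asymmetry is deliberate: centroided
MS/MS spectra are dominated in *peak count* by chemical and electronic
background, which is the regime the sliced background filter assumes — in
a spectrum whose slices are mostly signal, a mean-based threshold would
remove signal.

What the generator does **not** emulate: isotope fine structure (a single
centroid per charge state, which is what a unit-resolution centroid stream
supports; an isotope-resolved mode would be needed for QTOF realism),
chemical noise with structure in m/z or time, chromatographic drift,
detector saturation, and in-source fragmentation. Passing the recovery
suites therefore shows the *algorithms* are correct and well-conditioned
under realistic intensity ratios — not that the pipeline is robust to every
artefact of real instrument data.

Synthetic mzXML written by `write_mzxml()` uses 64-bit network-order
uncompressed peak data and round-trips through `read_mzxml()` exactly.

## Numerical choices and degenerate inputs

- Retention times are normalised to minutes at ingest; both analysis
  filters (1–6 min, 500–2500 m/z) are closed intervals.
- The ingest intensity floor (default 1000) is applied per peak.
- Equal adjacent ladder m/z values and inferred charges below 1 are
  rejected as non-physical.
- Empty signal tables propagate as empty/zero chromatograms; states whose
  every charge falls outside the scan window are treated as absent (zero
  area) during quantification rather than aborting the extract.
- The skew-normal fit is deterministic (no random restarts); `nlsLM`
  failure is caught and reported as non-convergence.

## Validation scale

The test suite validates parameter recovery at sizes chosen to exercise
the methods while keeping the default run fast: fraction-modified recovery
on a 16.7 kDa two-state system across fractions {0.1, 0.25, 0.5, 0.75,
0.9} × 4 seeds (|f̂ − f| ≤ 0.05 in every replicate), deconvolution
round-trips over 2–50 kDa × z₅ ∈ {1, 5, 10, 20} with and without ±0.1 m/z
peak noise, and MS/MS annotation of 20 seeded simulated spectra (≥ 95% of
injected ions recovered at 0.05 m/z tolerance).

## Known limitations

- Average-mass EIC centring ignores the offset between average and
  most-abundant-isotopologue m/z; at unit resolution and ±2/z windows this
  is negligible, at QTOF resolution it is the main reason the ±1/z window
  is kept generous.
- Co-eluting modification states are quantified from independent fits; a
  partially overlapping interference that survives the validity screen
  biases areas.
- The ladder-based deconvolution assumes the five peaks belong to one
  species; mixed ladders give large sample standard deviations rather than
  an explicit mixture diagnosis.
- Ring-opened fragments of macrocycles are not generated; true spectra of
  cyclic peptides may contain matchable ions the annotator will not
  predict.
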