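---
title: "Methods: models, parameters, and design choices in ribobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in ribobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribobind)
```

ribobind implements three analysis stages used to characterize the RNA
binding of an RRM-domain protein — RIP-Seq enrichment calling, microscale
thermophoresis (MST) binding-curve analysis, and docked-pose ensemble
surface mapping — together with synthetic-data generators that emulate each
input class. This vignette documents the underlying models, the tunable
parameters and their defaults, the numerical choices, and what the
generators do and do not establish.

## 1. RIP-Seq enrichment calling

### Model

Expression is quantified as FPKM (fragments per kilobase of transcript per
million mapped fragments):

$$\mathrm{FPKM} = \frac{c \times 10^9}{\ell \cdot N}$$

with $c$ the fragment count, $\ell$ the transcript length in nt (sum of
exon widths) and $N$ the library's total mapped fragments. A transcript is
a *positive hit* in a replicate when its FPKM in the RIP (pull-down) sample
strictly exceeds its FPKM in the paired non-specific-antibody control. The
*stringent* class requires a fold change above 2 in at least two
replicates, where

$$\mathrm{FC}_r = \frac{\mathrm{FPKM}_{\mathrm{RIP},r} + p}
                       {\mathrm{FPKM}_{\mathrm{ctrl},r} + p}.$$

### Parameters

* **Pseudocount** `pseudocount = 0.1` FPKM. Transcripts entirely absent
  from the negative control (control FPKM 0) are observed in this kind of
  data and need a finite fold change for ranking; 0.1 FPKM is at the
  detection floor of a typical library, so it barely perturbs expressed
  transcripts while capping the fold change of control-absent ones at
  `(FPKM+0.1)/0.1`.
* **Minimum-expression floor** `min_fpkm = 0` (off). The positive-call rule
  is deliberately the bare FPKM comparison; a floor is available for users
  who want to suppress noise-level calls, but it is off by default because
  the calling rule as defined involves no floor. This was a genuinely open
  choice; we resolved it in favor of the literal rule and exposed the floor
  as an option.
* **Intron threshold** `min_intronic_reads = 1`: the co- versus
  post-transcriptional classification is "any intron-overlapping read at
  all" versus "none", matching the qualitative criterion of no reads in
  intronic segments. A read counts as intronic when it overlaps an intron
  by at least one base.
* **Coordinates** are 0-based half-open internally; GTF input (1-based
  inclusive) is converted on read. Single-exon transcripts have no introns
  and are reported post-transcriptional (with a `single_exon` annotation)
  whenever exonic reads exist.

No replicate-aware statistical test (negative-binomial GLM etc.) is
applied: the calling rule is a deterministic per-replicate FPKM comparison,
because that is the rule being implemented, not an approximation of one.

### qPCR quantification

Fold enrichment is $2^{-\Delta\Delta C_t}$ between the specific and control
IPs after input normalization. The input $C_t$ is adjusted by
$\log_2(1/f)$ cycles for an input fraction $f$ (3.32 cycles for 10%
input); the adjustment cancels in the fold enrichment, which reduces to
$2^{C_t^{\mathrm{ctrl}} - C_t^{\mathrm{spec}}}$ — asserted numerically in
the tests. Percent input is
$100 \times 2^{(C_t^{\mathrm{input}} - \log_2(1/f)) - C_t^{\mathrm{spec}}}$.

## 2. MST binding-curve analysis

### Trace model

The instrument records fluorescence before the IR laser switches on (cold
window, 5 s), during the MST-on window (30 s), and after laser-off (5 s).
Traces are normalized to the cold-window mean. The three phases are
described qualitatively in the MST literature but have no published
functional form; we model the normalized trace as piecewise exponentials —
the simplest forms reproducing the described phenomenology:

* **T-jump**: fast exponential with $\tau = 0.3$ s after laser-on;
* **thermophoresis**: slow exponential with $\tau = 8$ s;
* **back diffusion**: after laser-off, exponential recovery toward the
  baseline with a time constant that grows with fraction bound
  ($\tau$ from 2 s free to 6 s bound), since complexes are larger and
  diffuse back more slowly.

The T-jump and thermophoresis amplitudes are linear in the fraction bound.
The amplitude values (T-jump 3% free to 8% bound; thermophoresis 2% to 7%)
were chosen once as typical few-percent MST signal changes, large enough
that the 5-sigma no-binding screen (below) does not swallow genuine binding
at the 1% noise level used in the recovery property tests. The
back-diffusion readout is *not* exactly linear in fraction bound (both the
amplitude and the recovery rate depend on it), so Kd values fitted from
back diffusion are approximations; the tests hold that readout to
monotonicity and ordering, not to exact round-trips.

### Readouts

* `tjump`: normalized value interpolated at **1.25 s** after laser-on (the
  published evaluation point).
* `thermophoresis`: mean over the **final 1 s** of the MST-on window.
* `backdiffusion`: value **2.5 s** after laser-off. The vendor software's
  exact thermophoresis/back-diffusion windows are not published; these two
  are declared package defaults (an early-recovery time maximizes size
  sensitivity), not reproductions.

### Isotherm and fit

The binding isotherm is 1:1 mass action with ligand depletion:

$$\mathrm{FB}(L) = \frac{(T + L + K_d) - \sqrt{(T + L + K_d)^2 - 4TL}}{2T},$$

evaluated in the numerically stable form $2L/(T+L+K_d+\sqrt{\cdot})$, with
$T$ the labeled-RNA concentration (default 5 nM) and $L$ the titrated
protein. $T \to 0$ reduces to $L/(L+K_d)$. The readout is fitted as
$y(L) = f_{\mathrm{free}} + (f_{\mathrm{bound}} - f_{\mathrm{free}})\,
\mathrm{FB}(L, T, K_d)$ by least squares: $K_d$ on a log10 scale bounded to
$[10^{-12}, 10^{-2}]$ M, initialized from an 81-point log-grid scan;
plateaus initialized from the three lowest-/highest-concentration readouts;
L-BFGS-B followed by a Nelder-Mead polish at `reltol = 1e-15` so noiseless
synthetic series round-trip $K_d$ to better than $10^{-6}$ relative.

### Flags

* `no_binding`: the binding signal *realized over the measured range*,
  $|f_{\mathrm{bound}} - f_{\mathrm{free}}| \cdot
  (\max \mathrm{FB} - \min \mathrm{FB})$, is below 5x the residual SD. The
  realized amplitude is used rather than the plateau difference because the
  plateau difference extrapolates arbitrarily when $K_d$ runs into the box
  bound on flat data.
* `irregular` (Kd reported as n.d.): aggregation-like instability at high
  concentration, detected by (i) per-trace roughness — median absolute
  second difference over the MST-on segment — with the top-quartile
  concentrations exceeding 5x the bottom-quartile median, or (ii) isotherm
  residuals at top concentrations exceeding 3x the global residual SD. The
  residual screen carries an SD floor of 1e-6 so that numerically perfect
  (noiseless) fits are not flagged on their rounding error. An irregular
  series yields n.d. for the size-sensitive thermophoresis readout while
  the early T-jump remains evaluable.

### Dilution-series defaults

16 points, 2-fold serial dilution from 40 µM, labeled RNA 5 nM, Gaussian
noise SD 0.002 on the normalized scale (consistent with 300-500 raw
counts), per-capillary raw level drawn from 300-500 counts. In aggregation
mode the generator corrupts the top-quartile concentrations from 10 s into
the MST-on window with 20x-noise flicker plus 3-8% transient spikes —
aggregates forming as the spot heats — which trips the roughness screen
while leaving the 1.25 s T-jump clean.

## 3. Docked-pose filtering and contact mapping

Two geometric filters, both strict-inequality at their thresholds:

* **Terminal proximity** (default 5 Å): drop a pose when any receptor atom
  is within 5 Å of any atom of a terminal (first/last per chain)
  nucleotide — binding at an artificial free end of a trimmed RNA core is
  non-physiological. Multi-chain RNAs contribute terminals per chain; a
  single-nucleotide chain is all-terminal. Poses not contacting the
  receptor at all pass this filter (they are simply non-contributing
  downstream).
* **Reference clash** (default 2.5 Å): drop a pose when any RNA heavy atom
  is within 2.5 Å of a partner-subunit heavy atom of the reference
  assembly. The source criterion is qualitative ("clearly clashed"); 2.5 Å
  is below the minimum non-bonded heavy-atom approach distance, so only
  unambiguous overlap trips it. This threshold is a declared package
  default, configurable. With no reference complex the filter is a no-op.

The filters commute (each pose is tested independently against both), and
the filter report attributes drops as terminal-only, clash-only, or both,
because the attribution of doubly-violating poses is otherwise ambiguous.

A receptor residue is *in contact* with a retained pose when any of its
atoms lies strictly within 5 Å of any RNA atom; the contact-frequency map
is the per-residue fraction of retained poses in contact. Frequencies can
be painted into the B-factor column of a PDB copy for surface
visualization.

Hydrogens are excluded from every distance rule (docking outputs and
crystal structures are heavy-atom). `min_distance()` is exact; the
spatial-grid acceleration (cell hashing with expanding-shell search and the
$(k-1)h$ lower bound) is verified identical to all-pairs brute force, and
small problems use the vectorized all-pairs path directly. Receptor
superposition across poses is assumed done upstream (docking programs emit
poses in the receptor frame).

## 4. Synthetic data: what it emulates, and what a green test establishes

* **RIP counts**: negative-binomial counts (variance $\mu + \phi\mu^2$,
  $\phi = 0.05$, typical of cell-line replicates) with log-normal baseline
  means (`meanlog = log(50)`, `sdlog = 1.2`), 500 transcripts, 3
  replicates, 10% planted binders at $2^2$-fold enrichment, library size
  $10^6$. Planted binders split evenly into co-transcriptional (intronic
  reads at rate 0.15) and post-transcriptional (no intronic reads); read
  intervals are clipped to their exon/intron so the planted class is
  unambiguous. The generator does not emulate positional read biases, GC
  effects, multimapping, or between-replicate library composition shifts —
  a green sensitivity/FPR test establishes that the calling logic recovers
  a planted signal of the stated size under clean overdispersed counts,
  not performance on real libraries.
* **MST series**: generated from the same trace model the fit assumes, so
  noiseless round-trips are exact by construction; this validates the
  estimator, not the trace model itself. Aggregation mode plants the
  instability the irregularity screen is designed to catch.
* **Pose ensembles**: the receptor is a ~100-residue Fibonacci-sphere
  shell (every residue surface-exposed), the partner subunit a second
  shell 40 Å away, the RNA a 2-atom-per-nucleotide helix trace — geometry
  stands in for structure because only inter-atomic distances matter to
  the stage under test. Planted violations are placed with margins (clean
  poses keep terminals ≥ 5.5 Å from the receptor and all atoms ≥ 3.5 Å
  from the partner; violations at 4.0 Å / < 2.0 Å), so filter recovery is
  exact rather than threshold-straddling. Hotspot bias reweights where
  clean poses dock, giving a recoverable enrichment of contact frequency.

All generators take an explicit seed, are deterministic given it, and
restore the caller's RNG state.

## 5. Numerical choices and degenerate inputs

* Fold changes with zero-control transcripts are finite via the
  pseudocount; FPKM of a zero count is exactly 0 regardless of length.
* `fraction_bound` uses the cancellation-free quadratic root; $T = 0$
  switches to the hyperbolic limit. Agreement with the non-depleting
  hyperbola when $T \le K_d/100$ is within 0.005 on the fraction-bound
  scale (the *relative* deviation approaches $T/K_d$ at low saturation).
* Venn cells are exact subset counts (disjoint, summing to
  positives-in-any); ties at thresholds resolve by the strict inequalities
  stated above.
* An ensemble whose poses are all filtered out returns an empty map with
  `n_retained = 0` and a warning rather than an error.
* PDB coordinates round-trip to the format's 0.001 Å precision; altlocs
  resolve to highest occupancy; waters/ions are dropped on read.

## 6. Known limitations

* The MST trace model is phenomenological; fitted `f_free`/`f_bound` have
  no photophysical interpretation beyond plateau readout values.
* Back-diffusion Kd values are biased by the linear-in-FB approximation
  (of order 10-30% in our simulations), mirroring the weaker agreement of
  that readout in practice.
* The T-jump readout is a single interpolated sample and therefore noisy;
  at 1% per-sample noise its single-fit Kd error can reach tens of
  percent in the weak-binder regime, which is why recovery criteria are
  stated on 20-seed medians.
* The enrichment caller implements the deterministic FPKM-comparison rule;
  it is not a differential-expression method and provides no error control
  beyond the planted-truth characterization above.
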