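---
title: "Mapping protein interfaces from differential HDX-MS and generalising them into degenerate motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein interfaces from differential HDX-MS and generalising them into degenerate motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxmotif)
library(dplyr)
```

## The measurement and its model

Hydrogen-deuterium exchange mass spectrometry observes the mass gain of
proteolytic peptides after a protein has been incubated in deuterated
buffer. Backbone amide hydrogens exchange with solvent deuterium at rates
set by hydrogen bonding and solvent accessibility, so a partner protein
bound to a surface slows exchange locally; comparing an apo state with a
complex state localises the interface at peptide resolution.

The package works entirely at the level the instrument software exports:
replicate deuterium uptakes (Da) per peptide, state and exposure time.
Three conventions anchor everything downstream.

* **Exchangeable amides.** A peptide of length $L$ can carry at most
  $N = L - 1 - \#\{\text{prolines at positions } 2..L\}$ deuterons: the
  N-terminal residue's label is lost during quench and digestion, and
  proline has no amide hydrogen. Vendor pipelines differ on whether the
  second residue should also be discounted (its amide exchanges too fast to
  retain label); `max_exchangeable_amides(, exclude_first = 2)` exposes
  that alternative, but the default follows the single-exclusion
  convention.
* **Uncertainty.** Replicate summaries use the sample standard deviation
  ($n-1$ denominator) divided by $\sqrt{n}$. A single replicate yields an
  *undefined* SEM (`NA`), never zero: treating one observation as
  noise-free would manufacture significance.
* **Significance.** For each peptide and time,
  $\Delta = \bar D_\text{complex} - \bar D_\text{apo}$ is compared with the
  summed-SEM envelope. Protection requires $\Delta < -(\mathrm{SEM}_a +
  \mathrm{SEM}_c)$ with a *strict* inequality: envelopes that merely touch
  are not significant. Significance is evaluated on the dalton scale by
  default; the relative scale (per maximum uptake) is also computed and can
  be selected, but the envelope test is scale-equivariant for a single
  peptide, so the choice matters only when policies aggregate across
  peptides of different lengths.

Uptake tables plotted as "relative uptake" in the literature rarely state
the normaliser; this package always reports both $\Delta$ (Da) and
$\Delta_{rel}$ (fraction of maximum uptake) so either reading is available.

## Calling protection in time

Interface protection has a kinetic signature: the uptake deficit grows with
exposure time as slower-exchanging amides accumulate label in the apo state
but not in the complex. The default calling policy therefore requires
significant protection at **two or more exposure times including the
longest**. A stricter optional policy (`require_nondecreasing`) additionally
demands $|\Delta|$ non-decreasing in time within one envelope of slack; it
is off by default because a single noisy early timepoint should not veto an
otherwise clean call.

## From protected peptides to residues

Two reductions are provided, answering different questions.

**Minimal protected segments** (`minimal_protected_segments()`) answer
"what is the smallest region that can carry the protection shared by a
group of overlapping peptides?". Peptide spans are intervals and intervals
have the Helly property: a set of spans has a common residue exactly when
they pairwise overlap. Every *maximal clique* of mutually overlapping
protected spans therefore has a non-empty intersection, and the function
returns one segment per clique via an endpoint sweep (a clique closes
whenever a span start is immediately followed by a span end in coordinate
order). This is deterministic, $O(n\log n)$, and provably identical to
brute-force enumeration of all maximal subsets with non-empty intersection
— the test suite checks that equivalence exhaustively on random span sets.
An earlier design considered splitting overlap components by greedily
dropping peptides until the intersection becomes non-empty; that produces a
*partition* and disagrees with the subset-enumeration definition whenever
maximal groups overlap, so the clique formulation was adopted instead.

**Protected regions** (`protected_regions()`) answer "which residues are
protected?". Span intersections systematically under-cover a binding site
once the peptide map is dense, because a peptide that clips the site's edge
by a single amide is genuinely and strongly protected, and its span end
truncates the intersection. The region caller therefore works at the
resolution the map actually supports: residues amide-covered by the same
set of analysed peptides are indistinguishable and form a *block*. Each
analysed peptide contributes a protection budget $\max(0, -\Delta)$ at its
longest exposure; blocks are assigned protection mass greedily, deepest
block (most protected peptides) first, never exceeding any covering
peptide's remaining budget. Unprotected peptides carry near-zero budgets
and so exonerate their blocks quantitatively; edge-clip flank blocks
inherit only the clipping peptide's small residual. Blocks whose assigned
per-residue protection exceeds a threshold — by default the mean envelope
at the longest exposure, i.e. the measurement uncertainty scale — are
called, uninformative gaps (prolines, peptide N-termini) flanked by called
blocks are bridged, and maximal runs become regions. In simulations this
recovers a planted seven-residue site with Jaccard $\ge 0.5$ in $\ge 90\%$
of runs where raw span intersections manage roughly half that.

Coverage and redundancy are summarised per protein as the fraction of
residues covered by at least one distinct peptide span and the mean span
depth over covered residues; redundancy is necessarily $\ge 1$ wherever
coverage is positive. The per-covered-residue mean-depth definition is used
because vendor reports do not document their internal formula.

## Degenerate motifs and the chance null

The motif grammar supports exactly what short-linear-motif queries need:
single residues, bracketed ambiguity sets, and the `X` wildcard, joined by
`-`. Exclusion sets and repetition counts are rejected loudly rather than
silently ignored. Parsed motifs render to a canonical text form (bracket
contents alphabetised), so induced and hand-written patterns compare
equal when they denote the same position sets.

Scanning tests every window, counts overlapping matches, and treats the
ambiguity codes B/Z/X/U/O/J as matching *no* position — the conservative
choice, since a window containing an ambiguous residue cannot be certified
as a match. The headline statistic of a proteome scan is the number of
distinct carrier proteins.

The chance expectation uses a position-independent null: windows are
imagined drawn i.i.d. from the proteome's residue composition, giving a
per-window match probability $p=\prod_j \sum_{a\in A_j} f(a)$ and
expectation $E = W\,p$ over the proteome's $W$ windows (computed per
protein; no concatenation artefacts). Window overlap dependence is ignored;
in the intended regime $E \ll 1$ the approximation error is far below the
Monte Carlo standard error, and `empirical_expected_matches()` — which
simulates whole proteomes and scans them — quantifies it directly. The two
estimators agree within three standard errors across the motif and
composition grid in the test suite. Non-standard residues are excluded from
both the numerator and denominator of the composition and tallied
separately.

Motif induction generalises aligned, equal-length instances column-wise:
residues reaching a minimum column frequency (default 0.1) form the allowed
set, and columns whose set would exceed `max_set_size` (default 4) become
wildcards — degenerate positions carry little discriminating power and a
large bracket set overfits the instance sample. With the threshold at or
below $1/n$ the induced motif provably matches all $n$ inputs.

## Conservation of the motif window

Ortholog sets are curated before logo building: entries shorter than 70% of
the reference's ungapped length, or with more than 20% gaps inside the
analysis window, are removed (the reference never is). The two defaults
quantify the usual manual curation of "substantially smaller" and "large
gaps"; both are parameters and both are echoed in the removal log.

Column profiles exclude gaps from the counts (gaps are absence of evidence,
not a 21st residue) and report information content
$IC = \log_2 20 - H - e(n)$ bits with the small-sample correction
$e(n) = 19/(2\ln 2\, n)$ applied by default, matching standard logo
practice; IC is clamped at zero and all-gap columns are flagged rather than
given a value. Consensus calls emit the modal residue, uppercase when its
frequency reaches the plurality threshold (default 0.5), lowercase
otherwise; ties break alphabetically — an arbitrary but deterministic rule.

## The forward simulator

`simulate_uptake()` is a deliberately simple, fully parameterised forward
model of the experiment, not a physical digital twin:

| parameter | default | units | rationale |
|---|---|---|---|
| exposure times | 0.5, 2, 5, 10 | min | standard bench design for a binding experiment |
| replicates | 4 | — | typical technical replication |
| intrinsic rates | lognormal, meanlog 0, sdlog 1.2 | min⁻¹ | spreads half-lives across the observed time window |
| protection factor | 100 | fold | strong interface protection |
| deuterium fraction | 135/165 ≈ 0.818 | — | 30 µl protein into 135 µl deuterated buffer |
| back-exchange | 0.7 | fraction retained | conventional figure for quench + LC losses |
| noise | 0.1 | Da SD | typical replicate scatter |
| peptide map | length 12 ± 2, step 6 | residues | full coverage at redundancy ≈ 2, the geometry in which a short site is contained in ~2 overlapping peptides |
| planted region | 61–67 of a 120-mer | residues | a seven-residue epitope away from the termini |

Noiseless uptake is $D(t) = \beta\,\varphi \sum_i (1 - e^{-k_i t})$ over the
peptide's exchangeable amides; the complex state divides $k_i$ by the
protection factor inside the planted region; replicates add Gaussian noise
truncated at zero (homoscedastic — the simplest model consistent with
replicate SEM envelopes). The lognormal rate model is a stand-in for
sequence-specific intrinsic rate tables; a `rates` hook accepts
user-supplied per-amide rates when realism matters. The simulator does
**not** model EX1/bimodal kinetics, isotope envelopes, pH or temperature
corrections, or correlated replicate error — so passing recovery tests
demonstrates that the analysis logic is sound under the stated noise model,
not that it is robust to every pathology of real data.

Synthetic proteomes draw i.i.d. residues from a Firmicute-like composition
(`bsubtilis_like_composition`, a calibration constant, not measured data)
with lognormal lengths (mean 285), and plant motif instances at
non-overlapping positions recorded in a manifest; real compositional
structure (repeats, low-complexity regions, domain biases) is absent, which
makes the chance null *exact* for these proteomes and slightly optimistic
for real ones. All generators are bit-reproducible for a fixed seed.

## Numerical and engineering choices

* Coordinates are 1-based inclusive throughout (mass-spec convention).
* Ties at the envelope boundary are not significant; consensus ties break
  alphabetically; the endpoint sweep orders a start before an end at the
  same coordinate (two spans meeting at one residue do overlap).
* Identification-quality filters (intensity ≥ 1000, products per amino acid
  ≥ 0.3, length ≤ 25 inclusive, |ppm| ≤ 6, replicates ≥ 4) apply only when
  the corresponding column is present — exported tables often lack them
  because the thresholds were already applied upstream — and the rejection
  log names the first failing rule per record.
* All randomness flows through explicit `seed` arguments via a temporary
  RNG state, so library calls never perturb a user's session RNG.
* Problem sizes in the test suite (120-residue analyte, 100 recovery
  seeds, 1000-sequence scanner oracle, 500 segment-oracle span sets,
  a 4284-entry synthetic proteome) were chosen to exercise every code path
  at the scale of the motivating experiment while keeping the default
  check fast on a laptop.

## Known limitations

Back-exchange correction from fully-deuterated controls is out of scope
(uptake is analysed as exported); no mixed-effects or hybrid significance
models beyond the envelope rule are offered; PSSM/profile scoring and
multiple-testing control across many patterns are not implemented; ortholog
alignments must be built upstream, and no phylogenetic weighting is applied
to logo columns, so dense clades inflate apparent conservation.
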