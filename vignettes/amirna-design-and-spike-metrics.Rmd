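---
title: "Designing artificial miRNAs and quantifying extracellular spike trains with amirephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing artificial miRNAs and quantifying extracellular spike trains with amirephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amirephys)
```

# Scope

`amirephys` implements two computational workflows that are usually stitched
together ad hoc when an RNA-interference knockdown study is taken from bench
design to in vivo electrophysiological readout:

1. **amiRNA design** — choosing a 21-nt silencing guide against a target
   transcript (here, tau/*MAPT* as the motivating case), screening it for
   off-target potential, generating a scrambled control, and embedding it in
   the miR-155 expression scaffold.
2. **Spike-train metrics** — turning raw extracellular voltage traces into
   sorted units with firing rate, inter-spike intervals, autocorrelogram and
   a burstiness index, plus a waveform-width classification into putative
   pyramidal cells and interneurons.

Both workflows ship with seeded synthetic-data generators that produce
ground-truth inputs, so every stage can be validated end to end without any
external database or recording.

# The design model

## Candidate scanning

A duplex candidate is a 23-nt window on the target whose sequence satisfies
the positional consensus `N2[CG]N8[AUT]N8[AUT]N2`: window position 3 (1-based)
is C or G, positions 12 and 21 are A or T/U. T and U are treated as
equivalent throughout; internally all comparisons canonicalize RNA to DNA.
Two further filters act on the 21-nt sense strand inside the window:

* **GC content** must lie in the inclusive band 45–50%. For a 21-mer this is
  only satisfiable by exactly 10 G+C (47.62%), which is why compliant scans
  report a single GC value. The band bounds are configurable
  (`filter_config()`), and whether GC is computed on the 21-nt sense or the
  full 23-nt window is a switch (`gc_on`), because "the sequence" is genuinely
  ambiguous between the two readings; the sense strand is the default as it
  is the molecule whose silencing behaviour the rule protects.
* **Homopolymer runs** of four or more identical bases are rejected
  (`max_run = 3`).

Where the 21-nt duplex sits inside the 23-nt window is a convention, not a
derivable fact: the reference designs do not expose their flanking bases. The
default is `sense_offset = 1` (window positions 2–22, centred), exposed as
configuration. Every filter is independently toggleable so that guides that
violate one rule — the shipped TauMiRNA166 guide has antisense GC of 42.86%,
below the band — can still be carried through the rest of the pipeline by
direct specification.

Internally all coordinates are 0-based half-open; 1-based positions appear
only in reports and in the deletion-position convention below.

## Terminal thermodynamic asymmetry

RISC preferentially loads the strand whose 5' end is the *less* stable duplex
end. The package scores this with nearest-neighbor stack free energies:

$$E_s = \sum_{i=1}^{w} \Delta G^\circ_{37}(s_i s_{i+1}), \qquad
  E_{as} = \sum_{i=1}^{w} \Delta G^\circ_{37}(a_i a_{i+1}), \qquad
  \Delta = E_{as} - E_s$$

where `s` is the sense strand read from its 5' end, `a` the antisense strand
read from its 5' end, and `w` the terminal window in base-pair steps. A
candidate is accepted when `Eas < Es` (the antisense 5' end is the more
stable duplex end, i.e. the *antisense* strand's own 5' terminus is the
easier end to fray from the sense side) and `Δ` lies in the inclusive band
`[-5, -3]`.

Three choices here were open and are therefore configuration, with these
defaults and rationale:

* **Parameter set**: the Xia et al. (1998) RNA Watson–Crick ΔG°37 stack
  table, shipped as a plain-text file (`inst/extdata/nn_stacks_dg37.tsv`)
  and identified in its header. It is the standard published set for RNA
  duplexes at 37 °C.
* **Window**: `w = 5` base-pair steps. Asymmetry windows of 4–5 bp are the
  norm in the siRNA design literature.
* **Units**: kcal/mol, the table's units. The acceptance band is applied to
  whatever `Δ` the configured table and window produce — it is honoured as a
  filter contract, not asserted as a physical claim, because the original
  rule states no units or window.

`Δ` is interpreted as `Eas − Es`; with the acceptance requirement `Eas < Es`
this makes accepted values negative, consistent with a band of `[-5, -3]`.
Dangling-end and terminal-AU corrections are deliberately omitted: the score
is a stack-only sum, which is sufficient for *ranking* end stabilities and
keeps the quantity exactly reproducible from the shipped table.

## Off-target screening

The screen measures, for each candidate guide, the longest contiguous exact
match between any non-excluded transcriptome record and either orientation:
the target-site sequence `revcomp(guide)` ("guide_match", where the guide
could pair) and the guide itself ("sense_match", passenger-strand risk).
Candidates with a match **greater than 17 nt** are discarded (17 itself is
kept); scrambled controls must match **strictly less than 15 nt**.

A gapped, scored aligner (BLAST) is deliberately replaced by exact longest
contiguous match: that is the quantity the thresholds are phrased in, it
needs no external databases, and it is conservative in the sense of being
reproducible and assumption-free. Mismatches and gaps are not modelled. The
implementation searches descending substring lengths with fixed-string
matching against the concatenated transcriptome; its correctness is defined
by (and tested against) a brute-force all-substrings oracle.

Scrambled controls are seeded random permutations of the guide — the base
multiset, and hence GC content, is preserved exactly — accepted only when
their longest transcriptome match is below 15 nt. The generator additionally
rejects permutations with homopolymer runs over 3 nt; that rule is not part
of the original control recipe, but it prevents degenerate controls, and it
can be switched off (`enforce_run = FALSE`).

## Scaffold embedding

The expression construct is

```
[ 5' arm (73 nt) | antisense 21 nt | loop (19 nt) | sense 19 nt | 3' arm (90 nt) ]
```

with the sense strand carrying a deletion of positions 10 and 11 (1-based on
the 21-nt sense), producing the central bulge that biases RISC toward the
guide strand. The arm and loop sequences are defined *operationally* as the
longest common prefix/suffix and the invariant interior segment of the three
reference constructs shipped in `inst/extdata/reference_constructs.fa`; they
are treated as opaque verbatim flanks (whether they include vector cloning
adapters is not resolved, and does not matter for assembly). `build_construct()`
reproduces all three reference constructs byte-identically, which is the
package's primary correctness surface on the design side.

**Deletion inference.** Recovering the deleted positions from a parsed
construct is ambiguous when the full-length sense strand contains repeats:
for the reference constructs, two to four adjacent pairs reproduce the
reference 19-mer (e.g. pairs starting at 9, 10, 11 and 12 for TauMiRNA724).
`infer_deletion()` therefore returns *all* consistent pairs in an attribute
and selects as canonical the pair whose midpoint is closest to the centre of
the 21-mer, ties toward the 5' end. A lexicographically-smallest tie-break
was considered and rejected: it would report pair {9,10} for the tau
constructs even though the design convention is a *central* deletion, and the
centre-proximal rule recovers {10,11} for all three reference constructs.

# The spike-train model

The processing chain is the standard threshold-sorting workflow:

1. **Band-pass** 300–6000 Hz, zero-phase (Butterworth of order 3 run forward
   and backward via `signal::filtfilt`), which also removes DC. Only the band
   itself is prescribed by the method; order and realization are documented
   configuration.
2. **Detection** at 5 standard deviations from the mean. The original rule
   says "above the mean" without fixing the sign convention; extracellular
   somatic spikes are negative-going, so the default thresholds negative
   deflections (`mean − 5·SD`), and an absolute-deviation mode (`polarity =
   "abs"`) covers the literal reading. Events are aligned to the extremum of
   each threshold crossing and a 1-ms refractory separation is enforced
   greedily in time order.
3. **Clustering** by k-means on the leading three principal components of
   the spike-waveform matrix, seeded and deterministic. Aggregating clusters
   by pairwise interface energy is *not* implemented (it is a separately
   published method); externally curated labels can be supplied to
   `sort_units()` instead.
4. **Classification** by trough-to-peak duration of the mean waveform:
   strictly greater than 440 μs is a putative pyramidal neuron (pPYR),
   otherwise a putative interneuron (pIN). Extrema are refined to sub-sample
   precision by parabolic interpolation (three-point vertex fit), and the
   duration is reported to 0.1 μs — finer precision has no physical meaning
   at 20 kHz. Flat or monotone waveforms are flagged undefined rather than
   classified.
5. **Rasters** at 1 ms: binary per bin (coincident spikes collapse to one).
   Firing rate is spike count over duration; ISIs are successive differences.
6. **Autocorrelogram** over lags 1–50 ms computed from the raster,
   `c(l) = Σ_t r[t]·r[t+l]`. The lag-0 bin is excluded: it counts only
   self-pairs, carries no information, and would pin the half-mass lag at
   zero for sparse trains. This is the one deliberate departure from the
   literal "0 to +50 ms" phrasing.
7. **Burstiness index** `BI = (50 − Δt)/50`, where `Δt` is the smallest lag
   at which the cumulative autocorrelogram reaches half its 50-ms total.
   `Δt` is taken on the raster's native 1-ms grid without interpolation, and
   "reaches" means `≥` (ties break toward smaller `Δt`, i.e. toward higher
   BI). A lag-uniform autocorrelogram gives BI = 0.5 exactly; all mass at
   lag 1 gives the maximum attainable 0.98; an empty autocorrelogram is
   flagged undefined (`NA`), never reported as 0. Because BI is a ratio of
   lag positions it is invariant to any normalization of the
   autocorrelogram, so raw counts are used.

# What the generators emulate — and what they do not

`make_transcriptome()` produces i.i.d.-base transcripts (GC fraction
configurable, 0.5 by default) with planted exact matches of controlled
length; flanking bases are forced to differ from the site so the planted
match cannot extend. It emulates exactly the quantity the off-target screen
measures. It does **not** emulate real transcriptome composition — splice
isoforms, UTR structure, repeat families — so passing screens here say the
*algorithm* is correct, not that a guide is clinically clean; screening
against real transcriptome FASTA files is supported but not required.

`make_target_gene()` plants rule-compliant 23-nt windows (rejection-sampled)
in random background, then repairs, one base at a time and never inside a
planted window, any background window that passes all filters by chance
(about 2% of uniform random windows do). Plants must be at least 23 nt
apart, and sampled plants whose ±1-shifted frames would pass using planted
bases alone are resampled, since no background mutation could break those.
This makes "the scan recovers exactly the planted windows" a property the
generator can guarantee and the tests can assert.

`make_recording()` sums, over units, parametric biphasic templates placed at
continuous (non-grid-aligned) spike times from Poisson or bursty generators,
plus white Gaussian noise. The template is a negative **quadratic** lobe
followed by a positive one with vertices exactly `ttp_us` apart. Parabolic
lobes — rather than half-sine — are a deliberate numerical choice: parabolic
sub-sample refinement is then *exact* for the sampled extrema, so a planted
440 vs 441 μs distinction survives 20-kHz sampling (half-sine lobes leave an
interpolation bias of a fraction of a microsecond, enough to blur a 1-μs
boundary). Only the trough-to-peak duration and amplitude matter to the
downstream metrics, so the lobe shape is otherwise inconsequential. The
generator does **not** emulate 1/f neural background, electrode drift, or
tetrode geometry; recall/precision results on it are upper bounds on
real-data performance.

All generators are pure functions of an explicit per-plan seed; no global
RNG state leaks (the caller's RNG state is saved and restored).

# Numerical choices and degenerate inputs

* Inclusive bounds everywhere a band is stated (GC 45–50%, Δ in [−5, −3],
  off-target "kept iff ≤ 17").
* `detect_spikes()` on a zero-variance trace warns and returns no events;
  `burstiness()` of an empty autocorrelogram is `NA` with an `NA` `delta_t`
  attribute; `trough_to_peak()` of flat/monotone waveforms is `NA`.
* `cluster_waveforms()` with fewer distinct waveforms than `k` returns an
  arbitrary deterministic split (any split of identical points is equally
  valid; merging is out of scope).
* Scramble search, compliant-window sampling and the target-gene repair loop
  are capped and fail loudly with diagnostics rather than looping forever.
* Parabolic refinement offsets are clamped to half a sample; refinement at a
  boundary sample falls back to sample resolution.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path while completing in a couple of minutes: 2-kb
targets with 5 planted windows, transcriptomes of 6–10 records totalling up
to 50 kb, 200 randomized oracle-equivalence instances, 500-duplex
thermodynamic pools, 60-s two-unit recordings at 20 kHz (SNR 8–10), and
600-s spike trains for burstiness calibration across 20 seeds.

# Known limitations

* Off-target screening is exact-match only; near-matches with mismatches or
  G:U wobble, and seed-region (positions 2–8) miRNA-like effects, are out of
  scope.
* The thermodynamic score is a stack-only terminal sum; it is not a full
  hybridization ΔG, a melting temperature, or a target-accessibility model.
* Which strand the positional consensus describes is not recoverable from
  the reference designs, and those designs do not all satisfy the stated GC
  band; the scanner therefore never asserts consensus compliance of shipped
  guides, and filters remain toggleable.
* Spike sorting is single-channel k-means; no interface-energy merging, no
  drift correction, no overlapping-spike resolution. Statistical comparison
  of firing properties between groups is routine downstream work and is not
  part of the package.
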