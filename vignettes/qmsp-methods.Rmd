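---
title: "Methods: methylation-specific PCR design and quantification with mspkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-specific PCR design and quantification with mspkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspkit)
```

## The problem

Dying cells shed DNA into the bloodstream. Because CpG methylation is laid
down tissue-specifically, a locus that is unmethylated only in one cell type
— here, the insulin gene in pancreatic beta cells, methylated everywhere
else — turns circulating cell-free DNA into a cell-death biomarker: finding
*unmethylated* insulin-gene DNA in blood means beta cells died. The
measurement chain is (i) bisulfite conversion, which rewrites unmethylated
cytosine as thymine while 5-methylcytosine survives as cytosine, so the
methylation state becomes an ordinary sequence difference; (ii)
methylation-specific PCR (MSP), whose primers end on converted CpG
positions and therefore extend only on one methylation state; and (iii)
relative quantification of the MSP signal against a bisulfite-specific PCR
(BSP) that amplifies all converted template regardless of state.

`mspkit` implements this chain in silico: a coordinate model and
methylation-aware bisulfite conversion; primer classification, GC-clamp
design and in-silico PCR; clone-level methylation mapping with per-CpG
exact tests; and the full qMSP analysis calculus with reproducibility
statistics. Seeded generators supply every input class, so the whole
pipeline is testable without any external data.

## Coordinates and conversion

Positions are TSS-relative with no position zero: +1 is the first
transcribed base, −1 the base immediately upstream. Internally everything
is a 0-based fragment-local offset; the two scales round-trip exactly. The
modelled locus is the 842 bp insulin-gene interval from −480 to +362 with
nine CpG sites (−414, −182, −171 in the promoter, +14 in exon 1, +121 in
intron 1, +190, +310, +337, +340 in exon 2).

Conversion acts per strand: every C outside CpG context becomes T; a
CpG-context C follows its site's state in the `methylation_profile`
(uniform all-methylated and all-unmethylated profiles mirror the
enzymatically methylated and mock-treated templates). The bottom strand is
converted as the reverse complement under the symmetric rule, because the
two strands of converted DNA are no longer complementary and a reverse
primer must be evaluated on the strand it actually anneals to. One profile
applies to both strands; hemimethylation is out of scope, as is non-CpG
(CHH/CHG) methylation. Only fully specified A/C/G/T sequences are
accepted — the templates modelled here are cloned, fully known sequences.

## Primer model

A primer is an untemplated 5' GC clamp plus a template-complementary core.
Binding-site search scans both orientations exhaustively. Three numerical
choices matter:

* **3' discrimination window = 2 bases.** Polymerase extension is taken to
  fail if any mismatch falls in the last two 3' bases. The discrimination
  mechanism of MSP is exactly such a terminal mismatch (primer T over a
  protected methylated C).
* **Maximum internal mismatches = 2.** Published primer sets are not
  perfectly mutually consistent — among the packaged oligos, one reverse
  primer contains a guanine whose complement would require a non-CpG C on
  a converted strand, so it necessarily carries one internal mismatch —
  and annealing tolerates a small number of internal mismatches at these
  temperatures. Both values are arguments everywhere they matter.
* **5' overhang tolerance (5 nt).** A core may overhang a template end on
  its 5' side; overhanging bases are untemplated, exactly like clamps, and
  are excluded from mismatch counting but included in product length. This
  is physically correct for amplicon-end priming and is needed because one
  packaged primer's footprint extends one base past the fragment end.

Classification aligns the core against all four converted references
(top/bottom × all-methylated/all-unmethylated) and the unconverted
fragment: extendable on one state only → MSP; on both → BSP; strictly
better on the unconverted sequence → non-bisulfite. A pair combining one
MSP and one BSP primer is reported `mixed` with a warning: it interrogates
a single CpG and has only moderate methylation specificity.

Melting temperatures use the nearest-neighbor model with the SantaLucia
(1998) unified parameter table, terminal initiation penalties, and the
entropic salt correction 0.368·(N−1)·ln[Na⁺], at 50 mM monovalent cations
and 500 nM oligo (the assay's reaction concentrations). No installed
package provides oligonucleotide nearest-neighbor Tm, so the parameter
table is implemented here; symmetry Tm(x) = Tm(reverse complement of x)
holds by construction of the table.

`design_clamp()` reconstructs the clamping procedure whose published
outcome is known (the redesigned primer pair with clamps `GCAGG` and
`CCTGCCAAACACTTCCC`) but whose selection rule is not: it grows a GC-rich
(default GC fraction 0.8) untemplated 5' addition of minimal length until
the target Tm — and, optionally, agreement with a partner within 2 °C — is
reached, never touching the core. It is a principled reconstruction, not
the original algorithm.

## Clone methylation mapping

Bisulfite-sequenced clones are single molecules; mapping is exact-position
(amplicon sequencing of plasmid inserts), with indel-containing reads
rejected rather than aligned. At each CpG C the read base calls the state
(C = methylated, T = unmethylated, anything else missing); the conversion
rate is the fraction of covered non-CpG cytosines read as T, and clones
below 0.95 — the conventional bisulfite QC bar — are flagged and
excluded from frequencies.
Per-site group comparison is the two-sided Fisher exact test by summation
of all tables with point probability not exceeding the observed one
(`stats::fisher.test`; the test suite checks it against an independent
hypergeometric enumeration), with no multiple-testing correction, matching
standard per-CpG mapping practice. Degenerate tables (a zero margin)
report p = 1 and are flagged.

The packaged clone matrix is reconstructed from the published per-site
counts (17 beta-cell clones vs 23 pooled non-beta clones); per-clone joint
patterns are not published, so unmethylated calls are assigned to the
lowest-numbered clones. Site frequencies and per-site exact tests depend
only on the marginals, which is all the reconstruction preserves. The
insulinoma cell line (9 clones) can be carried as a third group; the
default comparison is beta versus pooled other tissues.

## The quantification calculus

With Cq the quantification cycle and A the per-cycle amplification factor
(A = 10^(−1/slope) from a dilution-series standard curve, efficiency% =
(A−1)·100):

* **ΔΔCq**: ΔCq = Cq(MSP) − Cq(BSP) per specimen; ΔΔCq = ΔCq(sample) −
  ΔCq(reference); ratio = 2^(−ΔΔCq). Assumes both efficiencies are 100%.
* **RER** (Relative Expression Ratio): A_MSP^(Cq_MSP,ref − Cq_MSP,sample) /
  A_BSP^(Cq_BSP,ref − Cq_BSP,sample) — the efficiency-corrected form,
  reducing exactly to ΔΔCq when both A = 2.
* **DI** (Demethylation Index): 2^(Cq_BSP − Cq_MSP), reference-free.

The original descriptions of these indices leave their sign conventions
ambiguous, so the orientations are fixed by a consistency argument and
stated here openly:
the fully unmethylated plasmid reference must map to ratio 1 under ΔΔCq
and RER (blood samples then fall below 1, as the published per-day
averages of 0.45–0.77 do), and DI must rise when more unmethylated
template lowers Cq(MSP) (published values sit near 1 and rise after
beta-cell destruction). Technical replicates are averaged on the Cq scale
before any ratio is formed — the standard convention. Replicate statistics use the sample SD (n−1) throughout;
%CV = 100·SD/mean. No-amplification wells are Cq = NA and are excluded;
any template-free control with Cq < 40 should fail the run. The t-test is
the two-tailed unpaired pooled-variance (Student) form, matching the
default of the graphing software the field uses; Welch is a flag.

## The simulators

Generators are pure functions of (specification, seed).

* **Fragment.** Construction happens on the converted unmethylated top
  strand: declared CpG positions are written as T·G, primer footprints are
  stamped in (conflicting single bases and bases that would demand a
  non-CpG C on a converted strand remain as mismatches, which must stay
  out of any 3' window and within the binding tolerance), the remainder is
  filled from A/G/T, and the strand is "unconverted" by restoring CpG
  cytosines and sprinkling decoy non-CpG cytosines where no CpG can arise.
  The default specification reproduces the published band pattern: MSP
  pairs amplify only the unmethylated conversion, BSP pairs amplify both
  at equal length. It is a synthetic stand-in — classification behaviour
  is guaranteed, printed product sizes are not.
* **Cq.** Effective template for MSP is `unmethylated + λ·methylated` with
  leakage λ = 10⁻⁵, the simplest model consistent with the observed
  analytical specificity (a million methylated copies look like ten
  unmethylated ones); BSP sees the total. Cq = intercept − log_A(N) +
  Gaussian noise (SD 0.3 cycles), censored at the no-detect ceiling of 40.
  Defaults A_MSP = 1.9334 and A_BSP = 1.9147 are the published measured
  efficiencies; the intercept 38.7 places 10⁶ copies near Cq 18 as on the
  published curve.
* **Dilution series.** Eleven 3-fold steps from 10⁶ down to 17 copies,
  12 replicates — the published design.
* **Time course.** Days 0, 1, 2, 5, 6, 7, 14, 35; the default
  unmethylated-fraction trajectory follows the published per-day RER means
  (0.459 at baseline, peaking ~0.65 around days 2–7, returning by day 14);
  8 animals per day with between-animal SD 0.10 (matching the published
  per-day SD scale), 3 technical replicates, and total amplifiable copies
  held constant across days — total-DNA dynamics after beta-cell injury
  are not well characterised, so the simplest assumption is made and
  stated rather than hidden. The plasmid reference
  is drawn once per simulated run, which faithfully reproduces the
  day-to-day reference-shift sensitivity that distinguishes the three
  calculation methods.
* **Clones.** Per-site Bernoulli methylation, top-strand conversion, and
  conversion failures injected at non-CpG cytosines at a configurable
  rate.

What the simulators do *not* model: bisulfite degradation and
fragmentation of cell-free DNA, single-molecule PCR stochasticity beyond
Gaussian Cq noise, sequencing error in clone reads, and any real genomic
sequence context. Passing tests therefore demonstrate the correctness of
the calculus and the discrimination logic on clean templates, not
performance on real blood.

## Statistical design of the test suite

Problem sizes were chosen once: 200 clones for probability recovery
(binomial 4·SE bands), 12 replicates × 11 levels for efficiency recovery
(within ±5 efficiency points at noise SD 0.3, the published SD scale), and
8 animals/day for the time course. One point deserves honesty: at n = 8
and α = 0.05, a time course with the unmethylated fraction doubled on days
2–7 gives the textbook ~14% family-wise chance of a false positive among
the flat days, so "significant on exactly the elevated days" is not a
reliable property of a single cohort — the acceptance test therefore takes
a majority vote across five independently seeded cohorts (null-day error
~0.1% per day), while a module-level test keeps a single fixed-seed
cohort as a plain regression witness.

## Known limitations

* The fragment is synthetic; analyses that depend on the true genomic
  sequence (printed product sizes of 304/580/804/548/505/316 bp,
  validation against the real locus) are out of scope.
* One published reverse primer is listed among the qMSP set but its
  sequence places its 3' terminus on a CpG; the toolkit classifies from
  sequence and reports what it finds rather than assuming the label.
* Recomputed values are reported even where the published table cells are
  internally inconsistent at the last printed digit (the standard-curve
  CV column's low end recomputes to 7.5 where the accompanying text says
  8.5; some inter-assay summary cells appear truncated rather than
  rounded).
* The two-way ANOVA comparison of method variability is not reimplemented;
  the CVs it compares are.
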