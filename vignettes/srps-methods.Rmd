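---
title: "Mapping selective RNA processing and stabilization from paired dRNA-Seq libraries"
author: "SRPSseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping selective RNA processing and stabilization from paired dRNA-Seq libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SRPSseq)
```

## The biological question

Bacterial operons are transcribed as single polycistronic mRNAs, yet the
genes on one operon often accumulate to very different transcript
levels. One mechanism producing such non-equimolar output is *selective
RNA processing and stabilization* (SRPS): an endonuclease cleaves the
primary transcript at defined *processed sites* (PSs), and the resulting
segments then decay at different rates, with segments whose 3' end is
shielded by a stem-loop surviving longest. The hallmark is an operon
whose per-gene abundance profile is "Complex" — neither monotonically
decreasing (natural polarity) nor flat — with intergenic processed sites
(iPSs) at the abundance breakpoints and stable hairpins just upstream of
those sites.

SRPSseq implements the computational side of an SRPS screen from paired
dRNA-Seq libraries:

* **Hyb** — an rRNA-subtracted library containing all transcripts;
* **Exo** — a library treated with a 5'-monophosphate-dependent
  exonuclease, which digests processed 5' ends (monophosphorylated) but
  spares true transcription starts (triphosphorylated).

A genuine transcriptional start site (TS) therefore shows a read-start
peak in both libraries, whereas a processed site shows a peak in Hyb
that is depleted in Exo.

## End-site calling model

Per condition, each library/replicate contributes a stranded per-base
read 5'-start track. Calling proceeds in the five classical steps:

1. **Start windows** (`detectStartWindows`): maximal runs of nonzero
   positions within `mergeGap` (5 bases) of each other, kept when the
   summed starts reach `minStarts` (15) and the window's start density
   is at least `bgFold` (3x) the median per-base density in a
   ±250-base flank. The anchor is the maximal-count position, ties
   broken 5'-most.
2. **End sites**: Hyb windows with replicate-consistent anchors
   (±2 bases), plus replicate-consistent Exo-only windows as TS
   candidates.
3. **Counting**: start counts are re-read from the raw tracks over each
   site's window, so Exo signal below the window threshold still
   contributes.
4. **Discrimination**: with the library-size-normalized enrichment
   ratio rho = (Exo starts / Exo library size) / (Hyb starts / Hyb
   library size), the verdict is **TS** when rho ≥ 2 in both
   replicates, or when the replicate-pooled rho is ≥ 1 and an Exo
   window was independently detected in both Exo replicates; **PS**
   when rho ≤ 0.5 in both replicates; otherwise ambiguous. A site with
   zero Hyb starts is a TS candidate with rho = +Inf.
5. **Merging and categorization** (`mergeConditions`, `categorizeTs`,
   `categorizePs`): anchors agreeing within ±2 bases across conditions
   are one site; the merged set is the union over conditions, with
   per-condition and all-condition-intersection counts reported. TSs
   are gTS (≤ `utrMax` = 500 bases upstream of a same-strand gene
   start, outside CDS), iTS (inside a same-strand CDS) or nTS
   (orphan). PSs are cPS (inside CDS), uPS (between an operon's TS and
   its first gene) or iPS (between two member genes).

The window and threshold values above are configurable defaults chosen
so that verdicts are stable under the simulator's overdispersed noise;
they are deliberately conservative (both replicates must pass).
Two clarifications the calling rule needs to be implementable: the
"rho ≥ 1 with an independent Exo window" clause uses the
replicate-pooled ratio (halving its sampling variance at the 5'-flank
of genuine TSs), and a merged site's verdict is the majority across
supporting conditions, a TS/PS tie collapsing to ambiguous.

## Abundance and operon polarity

Transcript abundance (TA) is the coverage-weighted gene count
normalized by trimmed mean of M values (TMM). `tmmFactors` implements
the published TMM procedure with its standard constants — reference
library by upper-quartile closest to the mean, two-sided 30% trim on
log-ratios M, 5% trim on average log-abundance A, delta-method
precision weights — and rescales factors to geometric mean 1. Genes
with zero counts in the library or the reference are excluded; when
fewer than 10 finite genes enter the trim the factor falls back to the
untrimmed weighted mean with a warning. The test suite checks the
factors against an independent reference implementation (edgeR) to
1e-6. Polarity comparisons are within-operon and within-library, so no
length or GC correction is applied.

Operons are assembled from coverage contiguity: adjacent same-strand
genes join when their intergenic gap holds at least `covFloor` (20%) of
the flanking genes' mean coverage over at least `contFrac` (90%) of its
length, or when ≥ `minPairs` (3) read pairs bridge them — but never
when a same-strand TS (a promoter for the downstream gene) lies in the
gap. External DOOR-style predictions only break borderline ties (a pair
failing the coverage rule joins when predicted together and the gap
still reaches half the required contiguity).

Each consecutive gene pair (X upstream of Y) is a **Down** step when
log2(TA_X/TA_Y) > 0.5, **Up** when < −0.5, and **Flat** on the closed
interval [−0.5, 0.5]. An operon is labelled by its common step class,
and **Complex** when classes mix — the strictest reading of
"progressive" polarity; boundary ratios of exactly ±0.5 are Flat. Any
member TA below `taFloor` (1 normalized unit) makes the operon
unknown. Per-condition labels are merged by majority, ties going to
Complex.

## Enrichment

`hypergeomUpper` computes P(X ≥ m) for m marked items in a class of M,
with n of N marked overall, as a log-space sum of log-binomials —
stable for tail probabilities far below double underflow when computed
naively. PS-category-by-pattern enrichment supports two backgrounds:
N = PS-harbouring, pattern-classified polycistronic operons (the
literal definition), and N = all pattern-classified polycistronic
operons (which percentage-based summaries imply). Both are computed and
reported; they answer slightly different questions, and the choice
matters when PSs are rare. Raw p-values at 0.05 are the significance
criterion; Benjamini–Hochberg q-values are emitted alongside for the
reader but do not drive the flags. COG enrichment excludes genes
without a COG assignment from both foreground and background, and a
multi-letter assignment counts the gene in each letter.

## RNA folding and stem-loop analysis

PS flanks are exactly 100 nt: 49 upstream, the PS base, 50 downstream,
in coding-strand orientation. Controls are non-PS intergenic regions
within PS-harbouring operons, 100 nt centred on the region midpoint
(extended into the flanking genes when short, truncated when long).

Two folding backends are provided, because minimum-free-energy values
are not bit-reproducible across folding programs and versions:

* `external` delegates to ViennaRNA's `RNAfold` when installed (full
  MFE structure);
* `builtin` is a self-contained single-hairpin nearest-neighbour model:
  dynamic programming over all closing pairs with bundled stacking
  energies and hairpin/bulge/internal-loop penalties (approximate 37 °C
  parameters), no multiloops, interior loops capped at 6 unpaired
  bases per side. It is **not** numerically identical to Mfold or
  RNAfold, but shares the sign convention and ranks hairpins
  equivalently for the filters used here; the test suite checks that
  the two backends agree on the presence of qualifying hairpins for
  planted stems.

The default backend (`auto`) is `external` when `RNAfold` is on the
PATH, else `builtin`.

`scanStemLoops` enumerates candidate hairpins whose full extent lies
within ±100 bases of each iPS and retains those with dG < −5 kcal/mol
and a helix carrying at most 5 unpaired stem positions distributed over
at most 3 interruptions. The published filter phrase "no more than five
mispairs within three places" is ambiguous; this package reads it as
≤ 5 non-paired stem positions (mismatches plus bulged bases) across
≤ 3 interruptions of the helix, counted walking the helix outside-in.
The lowest-dG survivor is returned, ties resolved to the hairpin
closest to the iPS. A hairpin 5' of the iPS on the coding strand is the
3' stem-loop of the upstream gene — the protective configuration — and
carries that gene as `protected_gene`. A run of ≥ 4 U residues
beginning within 5 bases downstream of the hairpin marks a
rho-independent-terminator-like element.

`protectionCorrelation` reports the signed Pearson correlation between
the protected/downstream TA ratio and stem-loop dG (protective
stem-loops give a negative value: more stable hairpin, higher relative
abundance of the protected segment). The correlation is Pearson on the
raw ratio; literature values of such correlations are sometimes quoted
as unsigned magnitudes, so the sign is always reported explicitly here.
`compareDgGroups` reports both the Welch and the pooled-variance
two-sample tests, since "Student's t-test" in common usage can mean
either.

## The synthetic-data generator

`simulateGenome`/`simulateTracks` plant a complete SRPS landscape with
known truth, so every downstream stage has a self-contained test
surface:

* a low-GC (37%) random genome with `nOperons` stranded operons, gene
  lengths 300–900 nt, intra-operon gaps 60–160 nt, and exactly one
  genuine TS 20–700 bases upstream of each operon's first gene
  (matching the scale of long regulatory 5'-UTRs such as the 643-base
  cellulosome-operon leader);
* a polarity-pattern mix for polycistronic operons defaulting to
  Down 0.25 / Flat 0.16 / Up 0.28 / Complex 0.31, mirroring published
  genome-wide tallies (188/116/210/213);
* Complex operons realise SRPS: an interior protected gene whose
  downstream junction carries an iPS, with a designed hairpin embedded
  verbatim 5' of the iPS and the protected gene's intended abundance
  exceeding both neighbours by a factor growing as the planted dG
  drops (uniform on `stemloopDgRange`, default −25 to −8 kcal/mol);
  uPSs and cPSs are planted at rate-scaled probabilities in 5'-UTRs
  and CDSs;
* tracks: expected starts `depthPerSite` (200) at planted sites in
  both libraries for TSs, `exoRetention` × Hyb for PSs in Exo;
  negative-binomial noise (dispersion 0.1); geometric downstream smear
  (mean 3 bases) approximating the sawtooth-like peak shape of real
  5'-end data; uniform background totalling 1% of the summed per-site
  depth (interpreted as a total, since a per-base rate of that size
  would fuse all windows); two replicates per library per condition,
  and per-site condition support (75% of sites in all three
  conditions, the rest in two);
* coverage: per-gene levels proportional to the intended TA profile,
  with intra-operon gaps carrying 60% of the flanking mean (nascent
  read-through) so contiguity assembly can work.

The exonuclease retention default of 0.05 is a free model parameter:
the true digestion efficiency of the commercial enzyme is not public.
Results are insensitive to it anywhere below ~0.2, where PS ratios fall
safely under the 0.5 verdict threshold.

What the simulator does **not** emulate: sequence-dependent cleavage
motifs, RNase binding preferences, rRNA contamination, transcription–
translation coupling, condition-dependent polarity changes, or genome-
scale operon counts. Passing tests therefore certify the statistical
machinery and the recovery of planted signal under idealized noise —
not performance on real libraries, where window thresholds may need
retuning.

## Numerical choices and degenerate inputs

* End-site anchors match within ±2 bases (replicates and conditions).
* A zero median flank density always passes the enrichment filter
  (background unmeasurable); window-anchor ties break 5'-most.
* `hypergeomUpper(m = 0)` is exactly 1; domain violations error.
* TMM: an all-zero library errors; identical libraries give factors 1.
* Folding: sequences with no stabilizing structure report dG = 0 and
  an all-dot structure; T is read as U; stem-loop scan caps hairpin
  extent at 80 nt (`maxSpan`) for speed — wider than any planted stem.
* Degenerate protection correlation (constant ratio or dG) is reported
  as r = 0 with a `degenerate` flag rather than NA, so downstream
  tabulation never fails.
* All stage randomness derives from the single master seed
  (`simConfig(seed = )`); a fixed configuration is bitwise
  reproducible.

## Problem sizes in the test suite

The packaged checks run at desk scale: 12-operon, 60-kb genomes for
recovery (10 seeds, pooled sensitivity and precision ≥ 0.95), a
40-operon genome for the end-to-end enrichment demonstration, 100
seeded simulations for the sign of the dG–ratio correlation, an
exhaustive hypergeometric sweep to N = 25 against exact enumeration,
and 20-gene matrices for the TMM oracle comparison. Genome-scale
figures reported in the SRPS literature (hundreds of TSs/PSs, ~1,800
operons) require the original sequencing data and are outside what the
simulator is meant to reproduce.

## Worked example

```{r example, eval = FALSE}
cfg <- simConfig(seed = 3)
res <- runPipeline(cfg, backend = "builtin")
res$endSites
res$report$psCategories
head(res$enrichment$psOperons, 3)
res$protection$r
```

See the README for the printed output of this exact run.

## Known limitations

* The builtin folding model is hairpin-restricted: flank dG values are
  upper bounds on the full-structure MFE (multi-stem structures fold
  lower). Group comparisons remain valid because both groups are
  folded identically; absolute dG values are backend-dependent.
* Operon assembly encodes coverage contiguity and TS splitting only —
  manual curation steps used in genome-scale operon maps cannot be
  encoded.
* Pattern classification treats replicate-mean TA as exact; no
  uncertainty propagates into the Down/Flat/Up calls beyond the
  `taFloor` guard.
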