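---
title: "Quantifying intron retention at annotated splice junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intron retention at annotated splice junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irquant)
library(data.table)
```

# The model and its assumptions

`irquant` measures splicing efficiency per intron from aligned paired-end
RNA-seq. The object of inference is, for each annotated intron, the fraction
of transcript molecules that still carry it. The observable is the verdict of
each sequencing fragment overlapping the 5′ splice site:

* a **spliced** fragment carries an alignment gap running exactly from the
  donor to the acceptor (the intron was excised);
* an **unspliced** fragment has a contiguous alignment across the
  exon–intron junction (the intron is still present);
* a **mis-spliced** fragment is split at the donor but its gap does not end
  at the annotated acceptor.

Retention is estimated as `100 * unspliced / (unspliced + spliced)`.
Mis-spliced fragments are counted and reported but excluded from the
denominator: the estimate compares unsplit reads with correctly split reads,
and mis-splicing is a qualitatively different defect. Under the sampling
model below, at a boundary with true retention $p$ and mis-splice rate
$\varepsilon$, the verdict counts are multinomial with probabilities
$(p,\,(1-p)(1-\varepsilon),\,(1-p)\varepsilon)$ and the estimator is the
binomial MLE of $p/(p + (1-p)(1-\varepsilon))$ — equal to $p$ when
$\varepsilon = 0$ and within a fraction of a point of it at realistic
$\varepsilon$.

Assumptions: the annotation is trusted (no junction discovery); the library
is effectively unstranded, so fragments are matched to boundaries by
coordinates only; primary alignments represent fragments once; mate verdicts
from one fragment are merged (a conflict — both mates informative but
disagreeing — discards the fragment, and is counted).

# Boundaries and their filters

Introns are the gaps between consecutive exons of each transcript,
deduplicated by `(chrom, start, end, strand)` across transcripts and genes.
Two filters follow:

* **safe set** — a boundary is removed if *any* annotated exon (any gene,
  any transcript, either strand) overlaps the intron interval. This is the
  most conservative reading of "overlapping exon sequence": nested genes and
  alternative 5′/3′ splice sites would otherwise make unsplit coverage
  ambiguous.
* **minimum length** (coverage analysis only) — intron and both flanking
  exons must be ≥ 50 nt, with the flank length of a shared intron taken as
  the *minimum* over transcripts sharing it, so the guarantee holds for every
  context reads may come from. "Less than 50 b" is excluded, so exactly 50 is
  kept.

Coordinates are 0-based half-open internally; GTF is read and written
1-based inclusive. Boundaries are indexed by the donor; on the minus strand
donor and acceptor mirror (the donor is the genomic right edge of the
intron).

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_overlap` | 10 | nt | aligned sequence required on *each* side of the junction for a fragment to be informative; for a split read the far side lies across the gap (a split read has no intronic bases, so this is the only coherent reading) |
| `min_fragments` | 10 | fragments | a boundary is reported only if at least this many informative fragments overlap it (noise floor) |
| `halfwidth` | 50 | nt | coverage window ±50 around the donor; the window is the 100 positions `[donor−50, donor+50)` |
| `min_reads` | 50 | reads | minimum reads intersecting the window (partial overlaps count) for a profile to be defined |
| `min_flank` | 50 | nt | boundary length filter for the coverage analysis |
| `n_segments` | 1000 | segments | gene-structure profile resolution |
| `motif_left/right` | 3 / 6 | nt | exonic/intronic flank of the motif window; the source analysis does not state its window, so this is an explicit package choice |
| classifier | 10 / 5× / 50 / 1000 | expression units | early zygotic: 2–4 h > 10 **and** ≥ 5× the 0–2 h value; maternal: not early zygotic and 0–2 h > 50; excluded: > 1000 at either stage |

Threshold readings are literal: "more than" is strict `>`, "at least 5×" is
`≥`. Which stage the > 1000-unit exclusion applies to is not stated at the
source; this package applies it to the maximum over both stages, before both
class rules, which makes the rule unambiguous and order-independent. Intron
size bins put 100 and 500 in the middle bin ("from 100 to 500").

# Numerical choices

* **Coverage values** are reads-covering-a-base over reads-touching-the
  window, hence always in $[0, 1]$; a split read covers only its aligned
  blocks (never gap bases) but still counts in the denominator. The
  denominator counts *reads*, not fragments, matching the definition of the
  quantity being profiled.
* **Motif information content** is $IC = 2 - H$ bits with Shannon entropy
  per position and **no small-sample correction** — a deliberate choice,
  stated rather than inferred; sequences with non-ACGT symbols (or windows
  running off a contig) are dropped and counted.
* **Structure profile** segments use exact integer arithmetic
  (segment $s$ of a length-$L$ gene covers $[sL/n, (s+1)L/n)$; an exon
  $[e_0,e_1)$ intersects it iff $sL < e_1 n$ and $(s+1)L > e_0 n$), so
  results are floating-point-free. Genes shorter than `n_segments` nt are
  skipped with a warning, not rescaled.
* **Boxplot summaries** are five-number Tukey summaries (quartiles type 7,
  whiskers at the most extreme points within 1.5 IQR).
* **Degenerate inputs**: a boundary that is informative by fragment count
  but has zero spliced+unspliced fragments (all mis-spliced) has undefined
  retention; empty gene classes yield empty strata with a warning, and
  boundaries whose gene lacks an expression record are reported in an
  `unclassified` stratum, never dropped.

# What the synthetic generator emulates

`generate_world()` builds, from one seed: a random genome; gene models with
heterogeneous exon–intron structure on both strands (including one nested
single-exon gene inside another gene's intron, intronless genes, duplicated
transcripts, and introns spread over the three size bins); canonical GT..AG
splice sites (with a configurable non-canonical donor fraction); a
class-conditional expression table; and paired-end split alignments emitted
directly as SAM (mapping is out of scope — the pipeline consumes
alignments).

Sampling model: each fragment first draws a per-intron state vector
(retained with probability $p$; spliced, rerouted to a wrong acceptor 15 nt
into the downstream exon with probability $\varepsilon$), then a fragment
length $\mathcal{N}(250, 30)$ (clamped to template) and a uniform start.
Two design points matter for unbiasedness and were found the hard way:

1. **Length-proportional sampling.** Fragments are produced at a constant
   rate per template nt (isoform draw followed by length-proportional
   thinning). With a fixed per-gene fragment count split by isoform
   probability alone, longer retained precursors dilute junction coverage
   and retention is *underestimated*; at constant per-nt rate the
   informative window has the same width on every isoform and
   junction-level verdict proportions match the per-intron truth exactly.
2. **Long terminal exons.** Terminal exons are drawn at
   ≥ `frag_mean + 4·frag_sd` nt so no junction lies within a fragment
   length of a template end. Otherwise the informative window truncates
   differently on spliced vs retained templates (the retained one is longer
   downstream) — a real edge effect in short genes that the stated test
   world deliberately excludes.

Defaults describe the desk-scale world: 50 genes (20 maternal, 20 early
zygotic, 5 excluded-high, 5 unclassified), 100 bp paired reads, 500 target
informative fragments per boundary, truth retention drawn from
{0, 0.1, 0.3, 0.5, 0.9}, mis-splice rate 2%. Expression units are drawn
class-conditionally away from every threshold (e.g. early zygotic:
0–2 h ∈ [0, 2], 2–4 h ∈ [20, 500]), so classifier truth recovery is exact by
construction — a green classifier test establishes the rule logic, not
robustness to borderline expression values.

What the generator does **not** emulate: sequencing errors and base
qualities, GC and positional bias, PCR duplicates, multi-mapping,
unannotated junctions, expression-level heterogeneity between genes beyond
the class ranges. A green end-to-end test therefore establishes that the
*measurement machinery* is correct under the declared sampling model, not
that the pipeline is robust to artefacts of real libraries.

The RNG draw order is documented in the generator (genome, structures,
expression, truth, fragments) and a separate `read_seed` can vary fragments
while keeping the world fixed; `emit_worked_fixture()` pins the world seed
and is committed to the package as golden files.

# In-silico RT-PCR

The amplicon module is positional: a primer is a (segment, offset, length)
placement, hybridisation is assumed perfect, and the product size is the
standard amplicon definition (forward 5′ end to reverse 5′ end, inclusive).
An intron–exon pair yields product only on intron-retained templates; an
exon–exon pair yields product on both, with the retained product exceeding
the spliced one by exactly the summed lengths of retained introns strictly
between the primers. On a template with four identical introns the four
per-intron exon–exon assays share one constant spliced/retained offset —
the internal-consistency property the module validates (absolute printed
sizes would require the original primer sequences, which are not modelled).

# Known limitations and one red acceptance criterion

* SAM text is the first-class alignment format; BAM is accepted only when
  `Rsamtools` is available (converted, then parsed).
* The safe filter tests the intron interval only, not a window around the
  junction; boundaries abutting (but not overlapped by) foreign exons pass.
* Retention conditions on annotated acceptors; splicing at unannotated sites
  appears as mis-spliced, never as spliced.
* One acceptance criterion is statistically unattainable as stated and is
  left failing by design: it requires the Bernoulli(0.5) structure-profile
  null over 2000 genes to sit within ±3 percentage points of 50% at *every*
  interior segment. Per segment the frequency is Binomial(2000, 0.5)/2000
  (SD 1.12 pp), so ±3 pp is a 2.68σ band and ~7 of 998 segments are
  expected outside it; the probability that none is, is about 0.1%. The
  companion check on the *mean* over interior segments (±2 pp) passes with
  large margin. The test implements the stated bound faithfully rather than
  widening it.

# Reproducibility

Every pipeline run writes a `manifest.json` with package version, all
parameters and MD5 checksums of the inputs; identical inputs and parameters
reproduce every table byte for byte, and piecewise subcommand runs equal the
bundled `report` run on the shared tables.
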