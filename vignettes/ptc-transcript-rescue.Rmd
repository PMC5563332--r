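---
title: "Quantifying PTC transcripts and rescue isoforms from long-read amplicons"
author: "ptcrescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PTC transcripts and rescue isoforms from long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptcrescue)
```

# The problem

Premature termination codon (PTC) mutations — nonsense substitutions,
frameshift indels and canonical splice-site mutations — are expected to
trigger nonsense-mediated mRNA decay (NMD) and haploinsufficiency. In
practice the picture is messier: PTC-bearing transcripts escape decay to
varying degrees, and alternative splicing around the mutated region can
restore the reading frame (in-frame skipping of the mutated exon, cryptic
donor/acceptor usage) or disrupt it further (out-of-frame skipping, intron
retention). Targeted long-read amplicon cDNA sequencing reads are long
enough to phase a mutation with the splice junctions around it, so each
read supports an *implied transcript* that can be classified:

* **WT** — wild-type allele, no premature stop;
* **PTC** — a premature stop attributable to the mutation;
* **RESCUE** — the mutant (or excised) allele with the frame restored and
  no premature stop;
* **OTHER** — everything uninformative or not attributable (unassigned
  allele, event-induced stops on the wild-type allele, unresolvable
  junctions).

The summary statistic is the **PTC expression fraction**
`n_PTC / (n_PTC + n_WT)`: 0 means complete degradation of PTC transcripts,
0.5 equal expression of the PTC and WT alleles. The **rescue fraction** is
reported as `n_rescue / (n_PTC + n_WT + n_rescue)`; because the raw counts
are always emitted, any other denominator convention can be recomputed.

# The model, piece by piece

## Gene model and PTC scan

A single-transcript gene model (exons, strand, CDS span) on a reference
sequence is the coordinate backbone. All internal coordinates are 0-based
half-open; 1-based conventions exist only at I/O boundaries (HGVS, SAM,
BED12). A transcript is *mature* after applying a set of splice events
(exon skips, cryptic-site boundary shifts, retained introns) and at most
one exonic variant edit; events are applied first, and a variant whose
site was excised is flagged rather than applied.

`scan_for_ptc()` translates from the CDS start in codon steps with the
standard nuclear code (stops TAA/TAG/TGA only). A stop strictly upstream
of the canonical terminal codon is premature; a stop exactly at the
canonical position is the normal terminus; running off the 3' end is
flagged `nonstop`, and a stop landing downstream of the canonical
position (possible after a frameshift near the 3' end) is flagged
`readthrough` and not counted as a PTC. No 50-nt NMD rule is applied:
the pipeline *measures* decay via read counts, it does not predict it.

## Mutation taxonomy from coding HGVS

The parser covers the forms that occur in PTC mutation tables —
substitutions with optional intronic offsets (both ASCII hyphen and the
typographic minus that print tables use), deletions, duplications and
insertions. Classification is purely grammatical where the grammar
decides: offsets +1/+2 are canonical donor mutations, −1/−2 canonical
acceptor mutations, larger offsets splice-region; exonic indels are
frameshift or in-frame by span modulo 3. An exonic substitution is
`undetermined` until either a protein label (`*`/`fs`) or the reference
sequence resolves it. Inputs are assumed HGVS 3'-normalized; the parser
does not re-normalize (that would require the genuine transcript
sequence).

The deleterious-missense filter keeps records with MAF < 0.01% (as a
fraction, 1e-4), depth ≥ 20, allele-balance ratio strictly below 3, and
CADD strictly above 20 — the depth rule inclusive, the others strict,
matching the wording conventions such filters are quoted with. A
heterozygote with a zero allele count is excluded and flagged.

## Read classification

Alignments arrive as SAM/BAM with splice gaps encoded as CIGAR `N`
(deletions of ≥ `gap_threshold` = 30 nt are promoted to junctions;
canonical introns in the fixtures are ≥ 60 nt, so the two are not
confusable). Per read:

1. **Junction chain → events.** Junctions matching a canonical junction
   within `tolerance` (default 3 nt, the typical splice-site wobble of
   noisy long-read spliced alignments) are canonical. Donor-of-exon
   *k−1* to acceptor-of-exon *k+1* is an exon skip. A junction with one
   canonical end and the other displaced is a cryptic donor/acceptor
   with a signed exon-length delta — *including* displacements into the
   intron, since splicing at a displaced intronic point is cryptic-site
   usage; `intron_retention` is reserved for contiguous alignment
   crossing an exon–intron boundary (by ≥ `tolerance`). A donor-side
   partial retention and a downstream cryptic donor describe the same
   molecule and build identical implied transcripts, so this labeling
   choice cannot change a read's class. Junctions matching nothing make
   the read `OTHER`. Note the flip side of the wobble tolerance: a
   cryptic shift with |delta| ≤ tolerance is absorbed as canonical;
   resolving a 2-nt cryptic donor requires `tolerance` < 2.
2. **Allele call.** Substitutions: the aligned base at the variant
   position (via reference-space projection of the read), gated on ≥ 70%
   agreement of the ±12 nt flanking window with the reference.
   Indels: the net inserted-minus-deleted length in the window, assigned
   to whichever of 0 or the variant's length change is nearer; ties are
   `UNASSIGNED`. Canonical-splice variants have no exonic marker; their
   allele is inferred from the junction outcome at the mutated site and
   flagged as junction-inferred (with the caveat, shared with the
   original experimental design, that a rescue-type event on the
   wild-type allele at that site is not distinguishable without a phased
   marker). Reads whose events excised the variant site are `REMOVED`.
3. **Implied transcript → class.** The mature transcript for (allele,
   events) is scanned for a premature stop, and the class follows the
   definitions above. A read carrying the PTC allele *and* an unrelated
   deleterious event counts as PTC (the premature stop attributable to
   the variant takes precedence). `UNASSIGNED` reads never enter any
   fraction denominator — this avoids an error-rate-dependent bias —
   and their count is reported.

Event frequencies are allele-agnostic: each event's frequency is
computed over the reads whose alignment spans the event's full genomic
extent, which reproduces observations like "skipping of exon 30 in 30%
of all reads, unrelated to a PTC".

## The synthetic read generator

The generator emulates the study conditions, not the platform physics.
Per transcript: the allele is mutant with probability `1 − w`
(`w = wt_allele_share`, default 0.5 — balanced allelic amplification);
a mutant transcript takes rescue isoform *k* with probability `r_k`,
otherwise the PTC isoform, which survives decay with probability
`1 − e` (`e = nmd_efficiency`); wild-type transcripts always survive
(optionally taking rescue-type isoforms at a separate rate, default 0,
to model PTC-unrelated alternative splicing). Surviving transcripts are
sampled to `n_reads`, so the expected PTC expression fraction is

```
E[f] = (1 − R)(1 − e) m / ((1 − R)(1 − e) m + w),   m = 1 − w, R = Σ r_k
```

which is recorded in the simulation metadata. Errors are per-base
substitutions/insertions/deletions at 5%/3%/5% by default — an
order-of-magnitude match to early nanopore chemistry; NMD is a single
per-transcript survival Bernoulli, not a mechanistic 50-nt-rule model,
because the pipeline needs known fractions, not decay predictions. The
emitted SAM encodes each read's *generative* alignment (exon blocks as
`M`, introns as `N`, simulated and variant indels as `I`/`D`), so the
pipeline is testable without an external spliced aligner; externally
aligned FASTQ can be supplied instead. What this does **not** emulate —
homopolymer-structured errors, PCR chimeras, unbalanced amplification,
truncated or degraded molecules beyond the optional uniform end-trimming
— bounds what passing tests show about real data: they validate the
classification logic, not robustness to every artifact of a real run.

A practical consequence of single-read allele calling at these error
rates is an irreducible false-mutant floor: a substitution error at the
variant site mimics the mutant base in ~`p_sub/3` ≈ 1.7% of wild-type
reads, so a locus with *no* surviving PTC transcripts measures ~1–2%
rather than exactly 0 (the indel-length caller has a wider window and a
floor near 3%). This floor, not sampling noise, dominates the
complete-decay pole; consensus-based calling would remove it but is out
of scope at the read level.

## Cohort statistics

Carrier-level (dominant) 2×2 tables per stratum are the association
unit. The Mantel–Haenszel summary odds ratio is
`Σ(a_i d_i / n_i) / Σ(b_i c_i / n_i)` with the Robins–Breslow–Greenland
variance for the 95% interval and the 1-df chi-square with
hypergeometric moments, without continuity correction (the convention of
the standard genetics toolchains). Strata with an empty margin are
dropped with a warning rather than erroring — small national strata with
a handful of individuals are the motivating case. Single-stratum input
reduces exactly to the crude odds ratio (Woolf interval;
Haldane–Anscombe +0.5 when a cell is zero, flagged).

Hardy–Weinberg is the exact conditional test by full enumeration of
heterozygote counts given the allele counts. Pairwise LD accepts phased
haplotype counts or unphased genotype tables; the double-heterozygote
phase is resolved by EM (convergence 1e-10, ≤ 1000 iterations), and
`D`, `r²` and `D′` follow the standard definitions. The effective number
of tests uses the Li–Ji spectral decomposition
(`m_eff = Σ [I(λ ≥ 1) + (λ − ⌊λ⌋)]` on the absolute correlation
matrix) — chosen over the Nyholt variant, which the original analyses do
not disambiguate — and the study-wide threshold is `α / m_eff`.

# Numerical choices and degenerate inputs

* Junction tolerance 3 nt, gap threshold 30 nt, allele window 12 nt,
  window agreement 0.7 — all surfaced as arguments.
* Display rounding is half-up to two decimals (`3.015 → 3.02`); all
  internal computation is full precision.
* Toy loci are built from non-stop codons with a planted `ATG`/`TAA`, so
  the canonical frame is stop-free by construction; introns carry
  `GT…AG`. References with `N` inside the CDS are rejected at model
  build. Degenerate cases error loudly: empty read sets, all-degraded
  transcript pools, zero WT+PTC denominators, CDS shorter than one codon
  after edits, conflicting event pairs.
* Simulations in the test suite are sized to the question: 5000 reads
  for pole estimates, 2000 for recovery at the published fractions
  (binomial standard error ≈ 1.1 pp, comfortably inside the 3 pp band),
  100 replicates for interval coverage.

# Known limitations

* One transcript per gene model; no UTR-intron structures or recoding.
* Allele calling is per read; no consensus polishing, so estimated
  fractions carry the miscall floor described above.
* Canonical-splice variants rely on junction-outcome inference; rescue
  events on the wild-type allele at the mutated site are attributed to
  the mutant allele, as in the underlying experimental design.
* Acceptor-side partial retentions are labeled as cryptic acceptors (see
  above); the label differs from a retention call some tools would
  produce, the implied molecule does not.
* The cohort simulator draws carriers independently with equal
  frequencies across strata; it exercises the estimators, not
  population structure.
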