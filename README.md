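# ptcrescue

Transcript-aware analysis of **premature termination codon (PTC)
mutations** — nonsense substitutions, frameshift indels and canonical
splice-site mutations — for researchers studying nonsense-mediated mRNA
decay (NMD) escape and reading-frame rescue with targeted long-read
amplicon cDNA sequencing, and for case-control cohorts of carriers of
such mutations.

The package provides four connected layers:

1. **Mutation taxonomy from coding HGVS.** A parser and grammar
   classifier for `c.` nomenclature (substitutions with intronic
   offsets, deletions, duplications, insertions) that sorts mutations
   into frameshift / nonsense / canonical splice / splice-region /
   in-frame classes, computes affected codons
   (`codon = ⌊(pos − 1)/3⌋ + 1`), and applies a deleterious-missense
   filter (MAF < 0.01%, depth ≥ 20×, allele balance < 3-fold,
   CADD > 20).

2. **Read-level isoform quantification.** Spliced long-read alignments
   (SAM, `N`-gap CIGARs) of a mutation-spanning amplicon are decomposed
   into splice events (exon skips, cryptic donors/acceptors, intron
   retentions), the mutant/wild-type allele is called per read despite
   high random error, and each read's implied transcript is translated
   to classify it **WT / PTC / RESCUE / OTHER**. The headline statistic
   is the PTC expression fraction

   `f = n_PTC / (n_PTC + n_WT)`

   (0 = complete decay of PTC transcripts, 0.5 = equal expression of
   both alleles), plus a rescue fraction and allele-agnostic event
   frequencies.

3. **Cohort statistics.** Carrier frequencies, crude and
   Cochran–Mantel–Haenszel stratified odds ratios
   (`OR_MH = Σ(a_i d_i/n_i) / Σ(b_i c_i/n_i)`, Robins–Breslow–Greenland
   interval, χ² without continuity correction), exact Hardy–Weinberg
   tests, pairwise LD (`r²`, `D′`, EM phasing) and the Li–Ji
   spectral-decomposition multiple-testing threshold.

4. **A synthetic-data generator** producing toy loci, planted mutations
   of every class, amplicon reads drawn from an explicit two-allele
   NMD/rescue generative model with nanopore-like errors (plus truth
   labels and generative SAM alignments), and stratified cohorts — so
   the whole pipeline is testable end to end without external data.

## Worked example

Simulate an amplicon for a planted 7-nt frameshift deletion
(`c.368_374delCTGTCAC`) with 35% NMD efficiency and an 8% in-frame
exon-skip rescue isoform, then quantify:

```r
library(ptcrescue)

loc <- make_toy_locus(seed = 1)                      # 5-exon toy locus
pv  <- plant_variant(loc$model, loc$reference, "frameshift_del", exon = 4)
cfg <- sim_config(seed = 7, n_reads = 2000, nmd_efficiency = 0.35,
                  rescue = 0.08)
sim <- simulate_amplicon_reads(loc$model, loc$reference, pv$variant,
         rescue_isoforms = list(list(splice_event("exon_skip", 4))),
         config = cfg)
sim$meta$expected_ptc_fraction
#> [1] 0.3742178

sam <- tempfile(fileext = ".sam")
write_sam(sim$sam, sam, loc$reference$name, nchar(loc$reference$sequence))
aln <- read_alignments(sam, loc$reference)
cl  <- classify_reads(aln, loc$model, loc$reference, pv$variant)
quantify(cl, aln, loc$model)
#> Transcript quantification over 2000 reads
#>   WT 1155 | PTC 750 | RESCUE 95 | OTHER 0 (unassigned allele 0)
#>   PTC expression fraction: 0.394
#>   Rescue fraction:         0.048
#>   Event frequencies (reads spanning each event):
#>     skip:4         0.048
```

The estimate (0.394 from 2000 noisy reads) recovers the generative
expectation (0.374) within sampling error; the skip frequency matches
the planted rescue proportion. Annotating the packaged mutation table
and running a stratified association:

```r
head(annotate_variant_table(ptc_table_fixture())[,
       c("id", "chgvs", "protein_label", "category")], 3)
#>    id               chgvs protein_label                  category
#> 1 v01           c.67−1G>A          <NA> splice_canonical_acceptor
#> 2 v02 c.124_130dupGTTCGCC     p.His44fs                frameshift
#> 3 v03            c.206G>A      p.Trp69*                  nonsense

coh <- simulate_cohort(list(list(label = "ES", n_pat = 400L, n_ctl = 250L),
                            list(label = "IT", n_pat = 160L, n_ctl = 300L),
                            list(label = "SE", n_pat = 160L, n_ctl = 300L)),
                       carrier_freq_pat = 0.03, carrier_freq_ctl = 0.006,
                       seed = 11)
cmh(tabulate_strata(coh))
#> OR_MH = 4.97 (95% CI 1.84-13.41), chi2 = 12.92, p = 0.000326 (3 strata)
```

A thin command-line wrapper with `simulate`, `annotate`, `quantify`,
`associate` and `report` subcommands ships at
`inst/scripts/ptcrescue.R`.

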