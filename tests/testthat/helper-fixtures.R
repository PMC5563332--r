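# Shared fixtures and independent oracles for the test suite.

# Hand-built 3-exon locus (exons 9/12/9 nt, CDS covering all 30 nt) with
# fixed sequence, used where exact strings matter.
tiny_locus <- function() {
  ex_seq <- c("ATGAAACCC", "GGGTTTAAACCC", "GGGTTTTAA")
  intr <- c("GTAAGCCCAG", "GTTTTCCCAG")
  genome <- paste0(ex_seq[1], intr[1], ex_seq[2], intr[2], ex_seq[3])
  ref <- reference_seq("tiny", genome)
  model <- build_transcript(ref, rbind(c(0, 9), c(19, 31), c(41, 50)), "+")
  list(reference = ref, model = model, exon_seq = ex_seq, genome = genome)
}

# Locus with out-of-frame exon lengths (exon 2 = 100 nt, exon 3 = 44 nt)
# for frame-disruption fixtures; intron 2 is 91 nt (out-of-frame when
# retained).
frame_locus <- function(seed = 41) {
  make_toy_locus(seed = seed, exon_lengths = c(30L, 100L, 44L, 255L, 33L),
                 intron_lengths = c(90L, 91L, 88L, 90L))
}

# Independent PTC oracle: translate from cds_start with Biostrings and
# find the first stop, instead of the codon-wise substring scan used by
# scan_for_ptc().
oracle_scan_ptc <- function(mature) {
  seq <- mature$sequence
  start <- mature$cds_start_t
  n_cod <- (nchar(seq) - start) %/% 3L
  if (n_cod < 1L) stop("degenerate")
  dna <- Biostrings::DNAString(substr(seq, start + 1L, start + 3L * n_cod))
  aa <- as.character(Biostrings::translate(dna, no.init.codon = TRUE))
  first_stop <- regexpr("*", aa, fixed = TRUE)[1L]
  canon_end <- mature$canonical_end_t
  if (is.na(canon_end)) canon_end <- start + 3L * n_cod
  canon_codon <- (canon_end - start) %/% 3L
  if (first_stop < 0L) return(list(ptc_codon = NA_integer_, status = "nonstop"))
  if (first_stop == canon_codon) {
    return(list(ptc_codon = NA_integer_, status = "canonical"))
  }
  if (first_stop > canon_codon) {
    return(list(ptc_codon = NA_integer_, status = "readthrough"))
  }
  list(ptc_codon = as.integer(first_stop), status = "ptc")
}

# Independent consequence oracle for exonic variants: string surgery on
# the CDS followed by translation, bypassing mature_sequence().
oracle_classify <- function(v, model, reference) {
  cds <- ptcrescue:::cds_sequence(model, reference)
  p <- v$cds_pos
  edited <- switch(v$kind,
    SNV = { tmp <- cds; substr(tmp, p, p) <- v$alt_allele; tmp },
    deletion = paste0(substr(cds, 1, p - 1),
                      substr(cds, p + v$span_length, nchar(cds))),
    duplication = paste0(substr(cds, 1, p + v$span_length - 1),
                         substr(cds, p, p + v$span_length - 1),
                         substr(cds, p + v$span_length, nchar(cds))),
    insertion = paste0(substr(cds, 1, p), v$alt_allele,
                       substr(cds, p + 1, nchar(cds)))
  )
  n_cod <- nchar(edited) %/% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(edited, 1, 3 * n_cod)),
    no.init.codon = TRUE))
  ref_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE))
  if (v$kind == "SNV") {
    cod <- affected_codon(p)
    obs <- substr(aa, cod, cod)
    expc <- substr(ref_aa, cod, cod)
    if (obs == "*" && expc != "*") return("nonsense")
    if (obs == expc) return("synonymous")
    return("missense")
  }
  if (v$span_length %% 3L != 0L) "frameshift" else "inframe_indel"
}

# Independent exact HWE oracle: enumerate all genotype configurations
# consistent with the allele counts, with probabilities from multinomial
# coefficients, and sum the tail of configurations no more probable than
# the observed one.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n1 <- 2L * n_aa + n_Aa
  if (n1 == 0L || n1 == 2L * n) return(1)
  hets <- seq.int(n1 %% 2L, min(n1, 2L * n - n1), by = 2L)
  weight <- vapply(hets, function(h) {
    naa <- (n1 - h) / 2
    nAA <- n - naa - h
    # ways to realize the genotype vector times phase multiplicity
    exp(lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
          h * log(2))
  }, numeric(1))
  pr <- weight / sum(weight)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Simulate, write SAM, read back, classify: the standard round trip.
sim_roundtrip <- function(model, reference, variant, mut_events = list(),
                          rescue_isoforms = list(), config, ...) {
  sim <- simulate_amplicon_reads(model, reference, variant,
                                 mut_events = mut_events,
                                 rescue_isoforms = rescue_isoforms,
                                 config = config)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$sam, sam, reference$name, nchar(reference$sequence))
  aln <- read_alignments(sam, reference)
  cl <- classify_reads(aln, model, reference, variant, ...)
  unlink(sam)
  list(sim = sim, aln = aln, cl = cl)
}
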