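# The simulator provides alignment fixtures; at zero error rate the SAM it
# emits is the exact implied alignment of each isoform.

zero_err <- function(seed, n_reads, ...) {
  sim_config(seed = seed, n_reads = n_reads, p_sub = 0, p_ins = 0,
             p_del = 0, ...)
}

test_that("junction chains reflect N gaps and canonical reads give no events", {
  loc <- make_toy_locus(seed = 21)
  m <- loc$model; ref <- loc$reference
  pv <- plant_variant(m, ref, "nonsense", exon = 3)
  rt <- sim_roundtrip(m, ref, pv$variant, config = zero_err(1, 5))
  ch <- junction_chain(rt$aln, 1L)
  expect_identical(nrow(ch), 4L)  # five exons, four junctions
  expect_identical(unname(ch[, 1L]), unname(m$exons[1:4, 2L]))
  expect_identical(unname(ch[, 2L]), unname(m$exons[2:5, 1L]))
  det <- detect_events(rt$aln, 1L, m)
  expect_identical(length(det$events), 0L)
  expect_false(det$unresolvable)

  # an unspliced read has an empty chain: single-exon locus
  loc1 <- make_toy_locus(seed = 2, exon_lengths = 90L,
                         intron_lengths = integer(0))
  pv1 <- plant_variant(loc1$model, loc1$reference, "nonsense", exon = 1)
  rt1 <- sim_roundtrip(loc1$model, loc1$reference, pv1$variant,
                       config = zero_err(1, 3))
  expect_identical(nrow(junction_chain(rt1$aln, 1L)), 0L)
})

test_that("event detection recovers skips, cryptic sites and retentions", {
  loc <- make_toy_locus(seed = 21)
  m <- loc$model; ref <- loc$reference
  pv <- plant_variant(m, ref, "frameshift_del", exon = 2)

  check_single_isoform <- function(events, expected_sig, tolerance = 3L) {
    rt <- sim_roundtrip(m, ref, pv$variant, rescue_isoforms = list(events),
                        config = zero_err(3, 40, rescue = 1,
                                          wt_allele_share = 0),
                        tolerance = tolerance)
    sigs <- unique(rt$cl$events)
    expect_identical(sigs, expected_sig)
  }
  # exact skip of one exon
  check_single_isoform(list(splice_event("exon_skip", 4)), "skip:4")
  # cryptic donor 2 nt into the exon: resolvable only when the junction
  # tolerance is below the shift
  check_single_isoform(list(splice_event("cryptic_donor", 2, delta = -2L)),
                       "crypD:2:-2", tolerance = 1L)
  # cryptic acceptor extending exon 3 upstream into the intron
  check_single_isoform(list(splice_event("cryptic_acceptor", 3, delta = 6L)),
                       "crypA:3:+6")
  # donor-side partial retention splices at a point inside the intron and
  # is reported as a downstream cryptic donor of the same length
  check_single_isoform(list(splice_event("intron_retention", 2,
                                         retained = 40L)), "crypD:2:+40")
  # complete retention: contiguous alignment across the intron
  check_single_isoform(list(splice_event("intron_retention", 2)), "ret:2:full")

  # a junction matching nothing is unresolvable and the read goes OTHER
  sam <- tempfile(fileext = ".sam")
  exon1_len <- m$exons[1, 2] - m$exons[1, 1]
  weird <- data.frame(
    qname = "odd1", flag = 0L, rname = ref$name,
    pos = m$exons[1, 1] + 1L, mapq = 60L,
    cigar = paste0(exon1_len - 10L, "M", 137L, "N", 40L, "M"),
    rnext = "*", pnext = 0L, tlen = 0L,
    seq = strrep("A", exon1_len - 10L + 40L), qual = "*")
  write_sam(weird, sam, ref$name, nchar(ref$sequence))
  aln <- read_alignments(sam, ref)
  det <- detect_events(aln, 1L, m)
  expect_true(det$unresolvable)
  cl <- classify_reads(aln, m, ref, pv$variant)
  expect_identical(cl$transcript_class, "OTHER")
  expect_identical(cl$reason, "unresolvable_junction")
  unlink(sam)
})

test_that("zero-error classification reproduces truth for every variant kind", {
  loc <- frame_locus()
  m <- loc$model; ref <- loc$reference

  run_case <- function(pv, mut_events = list(), rescue_isoforms = list(),
                       rescue = numeric(0)) {
    rt <- sim_roundtrip(m, ref, pv$variant, mut_events = mut_events,
                        rescue_isoforms = rescue_isoforms,
                        config = zero_err(17, 300, nmd_efficiency = 0.25,
                                          rescue = rescue))
    expect_identical(rt$cl$transcript_class, rt$sim$truth$expected_class)
    expect_identical(rt$cl$read_id, rt$sim$truth$read_id)
  }

  # nonsense substitution
  run_case(plant_variant(m, ref, "nonsense", exon = 4))
  # frameshift deletion with an in-frame skip rescue (exon 4 = 255 nt)
  run_case(plant_variant(m, ref, "frameshift_del", exon = 4),
           rescue_isoforms = list(list(splice_event("exon_skip", 4))),
           rescue = 0.1)
  # single-base duplication
  run_case(plant_variant(m, ref, "frameshift_dup", exon = 4))
  # splice donor death: full retention of the out-of-frame intron 2
  run_case(plant_variant(m, ref, "splice_donor", exon = 2),
           mut_events = list(splice_event("intron_retention", 2)))
  # splice acceptor death: out-of-frame skip of the 100-nt exon 2
  run_case(plant_variant(m, ref, "splice_acceptor", exon = 2),
           mut_events = list(splice_event("exon_skip", 2)))
})

test_that("allele calls tolerate nanopore-like noise", {
  loc <- make_toy_locus(seed = 31)
  m <- loc$model; ref <- loc$reference
  pv <- plant_variant(m, ref, "frameshift_del", exon = 2)  # 7-nt deletion
  rt <- sim_roundtrip(m, ref, pv$variant,
                      config = sim_config(seed = 99, n_reads = 1000L))
  calls <- vapply(seq_len(1000L), function(i)
    call_allele(rt$aln, i, pv$variant, m, ref, window = 12L), character(1))
  correct <- mean(calls == rt$sim$truth$source_allele)
  expect_gte(correct, 0.95)
})

test_that("expression fractions follow the counts and are order invariant", {
  cl <- data.frame(
    read_id = sprintf("r%03d", 1:100),
    allele = rep(c("WT", "MUT"), c(59, 41)),
    events = "",
    transcript_class = rep(c("WT", "PTC"), c(59, 41)),
    reason = "")
  q <- quantify(cl)
  expect_equal(q$ptc_expression_fraction, 0.41)
  expect_equal(q$rescue_fraction, 0)

  # permutation and duplication invariance
  q2 <- quantify(cl[sample(nrow(cl)), ])
  expect_equal(q2$ptc_expression_fraction, q$ptc_expression_fraction)
  q3 <- quantify(rbind(cl, cl))
  expect_equal(q3$ptc_expression_fraction, q$ptc_expression_fraction)

  # the poles of the statistic
  cl_pole <- cl; cl_pole$transcript_class <- "WT"
  expect_equal(quantify(cl_pole)$ptc_expression_fraction, 0)
  cl_half <- cl; cl_half$transcript_class <- rep(c("WT", "PTC"), 50)
  expect_equal(quantify(cl_half)$ptc_expression_fraction, 0.5)

  # empty denominator is an error
  cl_bad <- cl; cl_bad$transcript_class <- "OTHER"
  expect_error(quantify(cl_bad), "undefined-fraction")

  # rescue denominator includes rescue reads
  cl_r <- cl; cl_r$transcript_class <- rep(c("WT", "PTC", "RESCUE"),
                                           c(50, 30, 20))
  expect_equal(quantify(cl_r)$rescue_fraction, 0.2)
  expect_equal(quantify(cl_r)$ptc_expression_fraction, 30 / 80)
})

test_that("event frequencies count reads spanning the event extent", {
  loc <- make_toy_locus(seed = 51)
  m <- loc$model; ref <- loc$reference
  pv <- plant_variant(m, ref, "frameshift_del", exon = 2)
  # planted cryptic-donor isoform at realistic error rates
  crypt <- list(splice_event("cryptic_donor", 2, delta = -5L))
  rt <- sim_roundtrip(m, ref, pv$variant, rescue_isoforms = list(crypt),
                      config = sim_config(seed = 5, n_reads = 2000L,
                                          rescue = 0.2,
                                          wt_allele_share = 0))
  # 20% of mutant transcripts take the cryptic isoform
  f <- event_frequency(rt$aln, rt$cl, crypt[[1]], m)
  expect_lt(abs(f - 0.2), 0.02)
  rm(f)
  q <- quantify(rt$cl, rt$aln, m)
  expect_true("crypD:2" %in% names(q$event_frequencies))

  # exact arithmetic on a constructed count: 30 of 100 spanning reads
  rt2 <- sim_roundtrip(m, ref, pv$variant,
                       rescue_isoforms = list(list(splice_event("exon_skip",
                                                                3))),
                       config = zero_err(8, 100, rescue = 0.3,
                                         wt_allele_share = 0))
  n_skip <- sum(rt2$cl$events == "skip:3")
  f2 <- event_frequency(rt2$aln, rt2$cl, splice_event("exon_skip", 3), m)
  expect_equal(f2, n_skip / 100)

  expect_error(
    event_frequency(rt2$aln, rt2$cl, splice_event("exon_skip", 1), m),
    NA)  # exon 1 is spanned by full-length reads: frequency 0, no error
  expect_equal(
    event_frequency(rt2$aln, rt2$cl, splice_event("exon_skip", 1), m), 0)
})
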