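test_that("toy loci are reproducible, stop-free and strand-symmetric", {
  l1 <- make_toy_locus(seed = 9)
  l2 <- make_toy_locus(seed = 9)
  expect_identical(l1$reference$sequence, l2$reference$sequence)
  expect_identical(l1$model$exons, l2$model$exons)

  # exon architecture and the canonical frame
  expect_identical(unname(l1$model$exons[, 2] - l1$model$exons[, 1]),
                   c(30L, 168L, 45L, 255L, 33L))
  sc <- scan_for_ptc(mature_sequence(l1$model, l1$reference))
  expect_identical(sc$status, "canonical")

  # splice dinucleotides at every intron
  for (k in 1:4) {
    ig <- ptcrescue:::intron_genomic(l1$model, k)
    expect_identical(substr(l1$reference$sequence, ig[1] + 1, ig[1] + 2), "GT")
    expect_identical(substr(l1$reference$sequence, ig[2] - 1, ig[2]), "AG")
  }

  # minus-strand build yields the same mature transcript sequence
  lm <- make_toy_locus(seed = 9, strand = "-")
  expect_identical(mature_sequence(lm$model, lm$reference)$sequence,
                   mature_sequence(l1$model, l1$reference)$sequence)

  expect_error(make_toy_locus(seed = 1, exon_lengths = c(4L)),
               "config error")
  expect_error(make_toy_locus(seed = 1, exon_lengths = c(10L, 10L),
                              intron_lengths = 5L), "config error")
})

test_that("planted variants round-trip through the classifiers", {
  loc <- frame_locus()
  m <- loc$model; ref <- loc$reference

  pv <- plant_variant(m, ref, "frameshift_del", exon = 2)
  expect_identical(classify_by_grammar(pv$variant)$category, "frameshift")
  expect_identical(pv$variant$span_length, 7L)

  pv <- plant_variant(m, ref, "splice_donor", exon = 2)
  expect_identical(classify_by_grammar(pv$variant)$category,
                   "splice_canonical_donor")
  # the genomic edit hits the GT dinucleotide
  expect_identical(substr(ref$sequence, pv$genomic$pos + 1,
                          pv$genomic$pos + 1), pv$genomic$ref)
  expect_identical(pv$genomic$ref, "G")

  pv <- plant_variant(m, ref, "splice_acceptor", exon = 3)
  expect_identical(classify_by_grammar(pv$variant)$category,
                   "splice_canonical_acceptor")

  # planted nonsense lands where the sequence classifier finds the stop
  pv <- plant_variant(m, ref, "nonsense", exon = 4)
  cc <- classify_with_sequence(pv$variant, m, ref)
  expect_identical(cc$category, "nonsense")
  expect_identical(cc$ptc_codon, affected_codon(pv$variant$cds_pos))
  expect_match(pv$variant$protein_label, "\\*$")

  # in-frame deletion
  pv <- plant_variant(m, ref, "inframe_del", exon = 4)
  expect_identical(classify_with_sequence(pv$variant, m, ref)$category,
                   "inframe_indel")
})

test_that("simulations are bit-reproducible and expose expected fractions", {
  loc <- make_toy_locus(seed = 4)
  pv <- plant_variant(loc$model, loc$reference, "nonsense", exon = 3)
  cfg <- sim_config(seed = 23, n_reads = 150L, nmd_efficiency = 0.4)
  s1 <- simulate_amplicon_reads(loc$model, loc$reference, pv$variant,
                                config = cfg)
  s2 <- simulate_amplicon_reads(loc$model, loc$reference, pv$variant,
                                config = cfg)
  expect_identical(s1$sam, s2$sam)
  expect_identical(s1$truth, s2$truth)

  # written outputs are reproducible byte for byte
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_simulation(s1, d1); p2 <- write_simulation(s2, d2)
  for (k in c("fasta", "bed", "sam", "fastq", "truth")) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  unlink(c(d1, d2), recursive = TRUE)

  # expected-fraction arithmetic at the poles and in between
  e0 <- sim_config(seed = 1, n_reads = 10L, nmd_efficiency = 0)
  e1 <- sim_config(seed = 1, n_reads = 10L, nmd_efficiency = 1)
  s_e0 <- simulate_amplicon_reads(loc$model, loc$reference, pv$variant,
                                  config = e0)
  s_e1 <- simulate_amplicon_reads(loc$model, loc$reference, pv$variant,
                                  config = e1)
  expect_equal(s_e0$meta$expected_ptc_fraction, 0.5)
  expect_equal(s_e1$meta$expected_ptc_fraction, 0)
  # general formula: (1-R)(1-e)m / ((1-R)(1-e)m + w)
  cfg_g <- sim_config(seed = 1, n_reads = 10L, nmd_efficiency = 0.3,
                      rescue = 0.2, wt_allele_share = 0.6)
  s_g <- simulate_amplicon_reads(loc$model, loc$reference, pv$variant,
                                 rescue_isoforms =
                                   list(list(splice_event("exon_skip", 3))),
                                 config = cfg_g)
  num <- 0.8 * 0.7 * 0.4
  expect_equal(s_g$meta$expected_ptc_fraction, num / (num + 0.6))

  # a fully degraded pool is an error
  dead <- sim_config(seed = 1, n_reads = 10L, nmd_efficiency = 1,
                     wt_allele_share = 0)
  expect_error(simulate_amplicon_reads(loc$model, loc$reference, pv$variant,
                                       config = dead), "empty-pool")
})

test_that("estimated PTC fraction obeys the law of large numbers", {
  loc <- make_toy_locus(seed = 4)
  pv <- plant_variant(loc$model, loc$reference, "nonsense", exon = 3)
  e <- 0.4
  f_true <- (1 - e) * 0.5 / ((1 - e) * 0.5 + 0.5)
  for (n in c(200L, 2000L, 20000L)) {
    cfg <- sim_config(seed = 1234, n_reads = n, nmd_efficiency = e,
                      p_sub = 0, p_ins = 0, p_del = 0)
    rt <- sim_roundtrip(loc$model, loc$reference, pv$variant, config = cfg)
    q <- quantify(rt$cl)
    tol <- 3 * sqrt(f_true * (1 - f_true) / n)
    expect_lt(abs(q$ptc_expression_fraction - f_true), tol)
  }
})

test_that("cohort simulation is reproducible and implies the target odds", {
  strata <- list(list(label = "ES", n_pat = 300L, n_ctl = 300L),
                 list(label = "IT", n_pat = 300L, n_ctl = 300L),
                 list(label = "SE", n_pat = 300L, n_ctl = 300L))
  c1 <- simulate_cohort(strata, 0.03, 0.006, seed = 31)
  c2 <- simulate_cohort(strata, 0.03, 0.006, seed = 31)
  expect_identical(c1, c2)
  expect_identical(nrow(c1), 1800L)
  expect_equal(attr(c1, "implied_or"),
               (0.03 / 0.97) / (0.006 / 0.994), tolerance = 1e-12)

  # zero control carriers exercises the Haldane path downstream
  c0 <- simulate_cohort(strata[1], 0.05, 0, seed = 2)
  tabs <- tabulate_strata(c0)
  expect_identical(tabs[[1]]$c, 0L)
  o <- crude_or(tabs[[1]])
  expect_true(o$corrected)
})
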