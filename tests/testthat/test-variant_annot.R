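test_that("the coding-HGVS grammar parses published mutation forms", {
  v <- parse_chgvs("c.206G>A")
  expect_identical(v$kind, "SNV")
  expect_identical(v$cds_pos, 206L)
  expect_identical(v$ref_allele, "G")
  expect_identical(v$alt_allele, "A")
  expect_true(is.na(v$intron_offset))

  v <- parse_chgvs("c.1109dupT")
  expect_identical(v$kind, "duplication")
  expect_identical(v$span_length, 1L)
  expect_identical(v$cds_pos, 1109L)

  # typographic minus in the printed acceptor string
  v <- parse_chgvs("c.67−1G>A")
  expect_identical(v$cds_pos, 67L)
  expect_identical(v$intron_offset, -1L)

  # whitespace around offsets is ignored
  v <- parse_chgvs("c.5570 + 5G>C")
  expect_identical(v$intron_offset, 5L)

  v <- parse_chgvs("c.1968_1977delTGCGGCCTGC")
  expect_identical(v$span_length, 10L)
  expect_identical(v$ref_allele, "TGCGGCCTGC")

  v <- parse_chgvs("c.10_11insGCA")
  expect_identical(v$kind, "insertion")
  expect_identical(v$span_length, 3L)

  expect_error(parse_chgvs("g.206G>A"), "parse error")
  expect_error(parse_chgvs("c.10_9delAA"), "parse error")
  expect_error(parse_chgvs("c.12_14delAA"), "parse error")
  expect_error(parse_chgvs("c.frobnicate"), "parse error")

  # re-serialization round-trips to an equivalent normalized string
  tab <- read.delim(ptc_table_fixture(), fileEncoding = "UTF-8")
  for (s in tab$chgvs) {
    n1 <- format_chgvs(parse_chgvs(s))
    expect_identical(format_chgvs(parse_chgvs(n1)), n1)
  }
})

test_that("affected codons match printed protein labels", {
  expect_identical(affected_codon(c(206L, 2134L, 2194L, 4008L, 4382L, 4465L)),
                   c(69L, 712L, 732L, 1336L, 1461L, 1489L))
  expect_identical(affected_codon(c(1L, 3L, 4L)), c(1L, 1L, 2L))
  # non-decreasing and constant on codon triples
  pos <- 1:300
  cods <- affected_codon(pos)
  expect_true(all(diff(cods) >= 0L))
  expect_true(all(tapply(pos, cods, length) == 3L))
})

test_that("grammar taxonomy reproduces the published mutation classes", {
  df <- annotate_variant_table(ptc_table_fixture())
  expect_identical(nrow(df), 18L)
  tab <- table(df$category)
  expect_identical(unname(tab[["frameshift"]]), 6L)
  expect_identical(unname(tab[["nonsense"]]), 6L)
  expect_identical(unname(tab[["splice_canonical_donor"]]) +
                     unname(tab[["splice_canonical_acceptor"]]), 5L)
  expect_identical(unname(tab[["splice_region"]]), 1L)
  expect_identical(sum(df$is_ptc), 17L)
  expect_identical(df$chgvs[!df$is_ptc], "c.5570+5G>C")

  # the published in-frame deletion is not PTC-class
  v <- parse_chgvs("c.4922_4924delTCT")
  expect_identical(classify_by_grammar(v)$category, "inframe_indel")

  # nonsense calls carry the PTC codon
  cc <- classify_by_grammar(parse_chgvs("c.206G>A", "p.Trp69*"))
  expect_identical(cc$category, "nonsense")
  expect_identical(cc$ptc_codon, 69L)
})

test_that("sequence classification resolves substitutions and shifted stops", {
  # TGG codon: G>A at its second base creates TAG (nonsense); G>C creates
  # TCG (missense)
  ref <- reference_seq("w", "ATGAAACCCGGGTTTAAATGGGGTCCCTAA")
  # codon 7 = TGG at CDS pos 19-21
  m <- build_transcript(ref, rbind(c(0L, 30L)), "+")
  expect_identical(substr(ptcrescue:::cds_sequence(m, ref), 19, 21), "TGG")
  cc <- classify_with_sequence(parse_chgvs("c.20G>A"), m, ref)
  expect_identical(cc$category, "nonsense")
  expect_identical(cc$ptc_codon, 7L)
  cc <- classify_with_sequence(parse_chgvs("c.20G>C"), m, ref)
  expect_identical(cc$category, "missense")

  # out-of-CDS coordinate errors
  expect_error(classify_with_sequence(parse_chgvs("c.999G>A"), m, ref),
               "coordinate error")

  # random substitutions and indels agree with the translation oracle
  loc <- make_toy_locus(seed = 77, exon_lengths = c(30L, 120L, 45L),
                        intron_lengths = c(80L, 85L))
  cds <- ptcrescue:::cds_sequence(loc$model, loc$reference)
  set.seed(99)
  n_checked <- 0L
  for (rep in 1:120) {
    kind <- sample(c("snv", "del", "dup", "ins"), 1)
    p <- sample(4:(nchar(cds) - 10), 1)
    v <- if (kind == "snv") {
      refb <- substr(cds, p, p)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      parse_chgvs(sprintf("c.%d%s>%s", p, refb, altb))
    } else if (kind == "del") {
      L <- sample(1:6, 1)
      parse_chgvs(if (L == 1) sprintf("c.%ddel", p)
                  else sprintf("c.%d_%ddel", p, p + L - 1))
    } else if (kind == "dup") {
      L <- sample(1:4, 1)
      parse_chgvs(if (L == 1) sprintf("c.%ddup", p)
                  else sprintf("c.%d_%ddup", p, p + L - 1))
    } else {
      parse_chgvs(sprintf("c.%d_%dins%s", p, p + 1,
                          paste(sample(c("A", "C", "G", "T"),
                                       sample(1:5, 1), replace = TRUE),
                                collapse = "")))
    }
    got <- classify_with_sequence(v, loc$model, loc$reference)$category
    expect_identical(got, oracle_classify(v, loc$model, loc$reference))
    # never disagree with the grammar where the grammar decides
    g <- classify_by_grammar(v)$category
    if (g != "undetermined") expect_identical(got, g)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})

test_that("the missense filter applies each rule and flags zero counts", {
  recs <- data.frame(
    id = c("clean", "common", "shallow", "imbalanced", "benign", "homalt"),
    maf = c(0.00005, 0.002, 0.00005, 0.00005, 0.00005, 0.00005),
    depth = c(40L, 40L, 12L, 40L, 40L, 40L),
    ref_count = c(22L, 20L, 6L, 31L, 22L, 40L),
    alt_count = c(18L, 20L, 6L, 9L, 18L, 0L),
    cadd = c(25, 25, 25, 25, 12, 25)
  )
  kept <- filter_deleterious_missense(recs)
  expect_identical(kept$id, "clean")
  ex <- attr(kept, "excluded")
  expect_identical(nrow(ex), 5L)
  expect_identical(ex$reason[ex$id == "homalt"], "zero_allele_count")
  expect_identical(ex$reason[ex$id == "imbalanced"], "allele_balance")

  # CADD exactly 20 is dropped: 'above 20' is strict
  rec20 <- data.frame(id = "edge", maf = 0.00005, depth = 40L,
                      ref_count = 20L, alt_count = 15L, cadd = 20)
  expect_identical(nrow(filter_deleterious_missense(rec20)), 0L)
  # depth exactly 20 is kept: 'at least 20x' is inclusive
  rec_d <- data.frame(id = "d20", maf = 0.00005, depth = 20L,
                      ref_count = 12L, alt_count = 8L, cadd = 25)
  expect_identical(nrow(filter_deleterious_missense(rec_d)), 1L)
  # exactly threefold imbalance is dropped ('less than threefold' strict)
  rec_b <- data.frame(id = "b3", maf = 0.00005, depth = 40L,
                      ref_count = 30L, alt_count = 10L, cadd = 25)
  expect_identical(nrow(filter_deleterious_missense(rec_b)), 0L)
})
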