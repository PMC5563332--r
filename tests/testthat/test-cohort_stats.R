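test_that("carrier percentages use half-up display rounding", {
  expect_identical(carrier_stats(28, 928)$percent, 3.02)
  expect_identical(carrier_stats(6, 980)$percent, 0.61)
  expect_identical(carrier_stats(0, 100)$percent, 0)
  # half-up, not banker's: 0.125 -> 0.13
  expect_identical(carrier_stats(125, 100000)$percent, 0.13)
  expect_error(carrier_stats(1, 0), "undefined")
  expect_error(carrier_stats(5, 4), "n_total")
})

test_that("crude odds ratios use Woolf intervals and the Haldane correction", {
  t1 <- stratum_table("all", 28, 900, 6, 974)
  o <- crude_or(t1)
  expect_equal(o$or, 28 * 974 / (900 * 6), tolerance = 1e-12)
  expect_false(o$corrected)
  expect_lt(o$ci_low, o$or); expect_gt(o$ci_high, o$or)

  expect_equal(crude_or(stratum_table("u", 1, 1, 1, 1))$or, 1)

  o0 <- crude_or(stratum_table("z", 0, 50, 5, 45))
  expect_true(o0$corrected)
  expect_lt(o0$or, 1)

  expect_error(crude_or(stratum_table("m", 0, 0, 5, 45)), "undefined")
})

test_that("Mantel-Haenszel algebra holds and matches the reference test", {
  s1 <- stratum_table("A", 10, 90, 5, 95)
  s2 <- stratum_table("B", 4, 46, 2, 48)

  # single stratum == crude OR exactly
  expect_equal(cmh(list(s1))$or_mh, crude_or(s1)$or, tolerance = 1e-12)

  # hand-computed sum(ad/n) / sum(bc/n)
  num <- 10 * 95 / 200 + 4 * 48 / 100
  den <- 90 * 5 / 200 + 46 * 2 / 100
  res <- cmh(list(s1, s2))
  expect_equal(res$or_mh, num / den, tolerance = 1e-12)

  # invariance under stratum duplication and permutation
  expect_equal(cmh(list(s1, s1, s1))$or_mh, crude_or(s1)$or,
               tolerance = 1e-12)
  expect_equal(cmh(list(s2, s1))$or_mh, res$or_mh, tolerance = 1e-12)
  expect_equal(cmh(list(s2, s1))$chi2, res$chi2, tolerance = 1e-12)

  # cross-check estimate, chi-square and RBG interval against
  # stats::mantelhaen.test (no continuity correction)
  arr <- array(c(10, 90, 5, 95, 4, 46, 2, 48), dim = c(2, 2, 2))
  arr <- aperm(array(c(10, 5, 90, 95, 4, 2, 46, 48), dim = c(2, 2, 2)),
               c(2, 1, 3))
  mh <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(res$or_mh, unname(mh$estimate), tolerance = 1e-10)
  expect_equal(res$chi2, unname(mh$statistic), tolerance = 1e-10)
  expect_equal(res$p, mh$p.value, tolerance = 1e-10)
  expect_equal(c(res$ci_low, res$ci_high), as.numeric(mh$conf.int),
               tolerance = 1e-6)

  # degenerate strata are dropped with a warning
  s_deg <- stratum_table("empty", 0, 0, 3, 7)
  expect_warning(res2 <- cmh(list(s1, s2, s_deg)), "empty margin")
  expect_equal(res2$or_mh, res$or_mh, tolerance = 1e-12)
})

test_that("the exact HWE test agrees with the enumeration oracle", {
  # (1,2,1): all three heterozygote configurations are equally extreme
  expect_equal(hwe_exact(1, 2, 1), 1)
  expect_equal(hwe_exact(100, 0, 0), 1)
  # a large all-heterozygote sample fails the QC gate
  expect_lt(hwe_exact(0, 100, 0), 0.001)

  set.seed(7)
  for (rep in 1:120) {
    n <- sample(3:200, 1)
    part <- stats::rmultinom(1, n, prob = runif(3, 0.05, 1))
    p_impl <- hwe_exact(part[1], part[2], part[3])
    p_orac <- oracle_hwe(part[1], part[2], part[3])
    expect_equal(p_impl, p_orac, tolerance = 1e-9)
  }
})

test_that("LD estimates recover phased truth through the EM", {
  # perfectly coupled haplotypes
  o <- ld_pair(haplotypes = c(AB = 50, Ab = 0, aB = 0, ab = 50))
  expect_equal(o$d_prime, 1)
  expect_equal(o$r2, 1)

  # independence at equilibrium frequencies
  o2 <- ld_pair(haplotypes = c(AB = 25, Ab = 25, aB = 25, ab = 25))
  expect_equal(o2$d_prime, 0)
  expect_equal(o2$r2, 0)

  expect_error(ld_pair(haplotypes = c(100, 0, 100, 0)), "monomorphic")

  # EM on genotypes collapsed from known phased haplotypes recovers the
  # haplotype frequencies
  set.seed(13)
  for (rep in 1:20) {
    hf <- as.numeric(stats::rmultinom(1, 500, prob = c(0.4, 0.25, 0.2, 0.15)))
    if (any(hf == 0)) next
    # pair haplotypes into 250 individuals at random
    haps <- rep(1:4, hf)
    haps <- matrix(sample(haps), ncol = 2)
    a_cnt <- (haps >= 3) * 1    # haplotypes aB, ab carry allele a
    b_cnt <- (haps %% 2 == 0) * 1  # haplotypes Ab, ab carry allele b
    g <- table(factor(rowSums(a_cnt), 0:2), factor(rowSums(b_cnt), 0:2))
    fit <- ld_pair(genotypes = unclass(g))
    truth <- ld_pair(haplotypes = hf)
    expect_true(fit$converged)
    # the EM solution is a fixed point of its own update
    f <- unname(fit$haplotype_freqs)
    cis <- f[1] * f[4]; trans <- f[2] * f[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    dh <- g[2, 2]
    base <- c(2 * g[1, 1] + g[1, 2] + g[2, 1] + dh * w,
              2 * g[1, 3] + g[1, 2] + g[2, 3] + dh * (1 - w),
              2 * g[3, 1] + g[2, 1] + g[3, 2] + dh * (1 - w),
              2 * g[3, 3] + g[2, 3] + g[3, 2] + dh * w)
    expect_equal(f, unname(base / sum(base)), tolerance = 1e-8)
    # ML frequencies track the realized phased counts statistically
    expect_true(max(abs(f - unname(truth$haplotype_freqs))) < 0.05)
    # when no double heterozygotes exist, agreement is exact
    if (g[2, 2] == 0) {
      expect_equal(unname(fit$haplotype_freqs),
                   unname(truth$haplotype_freqs), tolerance = 1e-6)
    }
  }

  # unambiguous phase: no double heterozygote, exact agreement
  g0 <- matrix(c(30, 10, 0, 12, 0, 0, 0, 0, 8), 3, 3, byrow = TRUE)
  fit0 <- ld_pair(genotypes = g0)
  hf0 <- c(2 * 30 + 10 + 12, 2 * 0 + 10 + 0, 2 * 0 + 12 + 0, 2 * 8)
  truth0 <- ld_pair(haplotypes = hf0)
  expect_equal(unname(fit0$haplotype_freqs),
               unname(truth0$haplotype_freqs), tolerance = 1e-6)
  expect_equal(fit0$d_prime, truth0$d_prime, tolerance = 1e-6)
})

test_that("the effective test count follows the eigenvalue rule", {
  id22 <- diag(22)
  o <- meff_cutoff(id22)
  expect_equal(o$m_eff, 22)
  expect_equal(o$threshold, 0.05 / 22)

  r1 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(meff_cutoff(r1)$m_eff, 1)
  expect_equal(meff_cutoff(r1)$threshold, 0.05)

  r05 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  o2 <- meff_cutoff(r05)
  expect_equal(o2$m_eff, 2)          # eigenvalues 1.5 and 0.5
  expect_equal(o2$threshold, 0.025)

  # negative correlations count through the absolute value
  rneg <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_equal(meff_cutoff(rneg)$m_eff, 2)

  expect_error(meff_cutoff(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
  expect_error(meff_cutoff(matrix(c(2, 0, 0, 2), 2, 2)), "diagonal")
})
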