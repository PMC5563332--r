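## Stratified case-control association statistics for carrier tables:
## crude and Mantel-Haenszel odds ratios, exact Hardy-Weinberg tests,
## pairwise linkage disequilibrium and the spectral-decomposition
## multiple-testing threshold.

#' Carrier frequency summary
#'
#' @param n_carriers Number of carriers.
#' @param n_total Cohort size (> 0).
#' @return List with `fraction` (full precision) and `percent`
#'   (half-up rounded to 2 decimals, the display convention).
#' @export
carrier_stats <- function(n_carriers, n_total) {
  if (n_total <= 0L) stop("undefined: n_total must be positive")
  if (n_carriers < 0L || n_carriers > n_total) {
    stop("n_carriers must lie in [0, n_total]")
  }
  f <- n_carriers / n_total
  list(fraction = f, percent = round_half_up(100 * f, 2L))
}

#' A per-stratum 2x2 carrier table
#'
#' @param label Stratum label (e.g. country of origin).
#' @param a Carrier patients.
#' @param b Non-carrier patients.
#' @param c Carrier controls.
#' @param d Non-carrier controls.
#' @return Object of class `stratum_table`.
#' @export
stratum_table <- function(label, a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(v < 0) || sum(v) <= 0) {
    stop("cell counts must be non-negative with a positive total")
  }
  structure(list(label = as.character(label), a = a, b = b, c = c, d = d),
            class = "stratum_table")
}

stratum_degenerate <- function(t) {
  (t$a + t$b) == 0 || (t$c + t$d) == 0 || (t$a + t$c) == 0 ||
    (t$b + t$d) == 0
}

#' Crude odds ratio with Woolf confidence interval
#'
#' `OR = ad/bc` with a log-scale 95% interval
#' `exp(ln OR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero the Haldane-Anscombe correction (+0.5 on all cells) is applied
#' and flagged.
#'
#' @param table A [stratum_table()].
#' @return List with `or`, `ci_low`, `ci_high`, `corrected`.
#' @export
crude_or <- function(table) {
  stopifnot(inherits(table, "stratum_table"))
  if (stratum_degenerate(table)) {
    stop("undefined-OR: a zero margin leaves the odds ratio undefined")
  }
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = or * exp(-1.959963984540054 * se),
       ci_high = or * exp(1.959963984540054 * se), corrected = corrected)
}

#' Cochran-Mantel-Haenszel stratified association
#'
#' Summary odds ratio `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`;
#' the variance of its logarithm uses the Robins-Breslow-Greenland
#' estimator for the 95% interval. The chi-square statistic is
#' `(sum(a_i - E a_i))^2 / sum Var(a_i)` with hypergeometric moments and
#' no continuity correction; p from a 1-df chi-square. Strata with an
#' empty margin are dropped with a warning.
#'
#' @param strata List of [stratum_table()] objects (a single table is
#'   promoted to a list).
#' @return Object of class `cmh_result` with `or_mh`, `ci_low`,
#'   `ci_high`, `chi2`, `p`, `n_strata_used`, `dropped`.
#' @export
cmh <- function(strata) {
  if (inherits(strata, "stratum_table")) strata <- list(strata)
  stopifnot(length(strata) >= 1L,
            all(vapply(strata, inherits, logical(1), "stratum_table")))
  degen <- vapply(strata, stratum_degenerate, logical(1))
  if (any(degen)) {
    warning("dropping ", sum(degen), " stratum/strata with an empty margin: ",
            paste(vapply(strata[degen], `[[`, character(1), "label"),
                  collapse = ", "))
  }
  strata <- strata[!degen]
  if (length(strata) == 0L) stop("undefined: all strata degenerate")

  a <- vapply(strata, `[[`, numeric(1), "a")
  b <- vapply(strata, `[[`, numeric(1), "b")
  c_ <- vapply(strata, `[[`, numeric(1), "c")
  d <- vapply(strata, `[[`, numeric(1), "d")
  n <- a + b + c_ + d

  R_i <- a * d / n; S_i <- b * c_ / n
  R <- sum(R_i); S <- sum(S_i)
  or_mh <- R / S

  ## Robins-Breslow-Greenland variance of log OR_MH
  P_i <- (a + d) / n; Q_i <- (b + c_) / n
  var_ln <- sum(P_i * R_i) / (2 * R^2) +
    sum(P_i * S_i + Q_i * R_i) / (2 * R * S) +
    sum(Q_i * S_i) / (2 * S^2)
  z <- 1.959963984540054
  ci <- or_mh * exp(c(-1, 1) * z * sqrt(var_ln))

  e_a <- (a + b) * (a + c_) / n
  v_a <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  chi2 <- (sum(a - e_a))^2 / sum(v_a)
  p <- pchisq(chi2, df = 1L, lower.tail = FALSE)

  structure(list(or_mh = or_mh, ci_low = ci[1L], ci_high = ci[2L],
                 chi2 = chi2, p = p, n_strata_used = length(strata),
                 dropped = sum(degen)),
            class = "cmh_result")
}

#' @export
print.cmh_result <- function(x, ...) {
  cat(sprintf("OR_MH = %.2f (95%% CI %.2f-%.2f), chi2 = %.2f, p = %.3g (%d strata)\n",
              x$or_mh, x$ci_low, x$ci_high, x$chi2, x$p, x$n_strata_used))
  invisible(x)
}

#' Tabulate per-individual carrier records into per-stratum 2x2 tables
#'
#' @param df Data frame with columns `cohort` (`"patient"`/`"control"`),
#'   `stratum` and `carrier` (0/1).
#' @return List of [stratum_table()] objects, one per stratum.
#' @export
tabulate_strata <- function(df) {
  stopifnot(all(c("cohort", "stratum", "carrier") %in% names(df)))
  lapply(split(df, df$stratum), function(s) {
    stratum_table(s$stratum[1L],
                  a = sum(s$cohort == "patient" & s$carrier == 1),
                  b = sum(s$cohort == "patient" & s$carrier == 0),
                  c = sum(s$cohort == "control" & s$carrier == 1),
                  d = sum(s$cohort == "control" & s$carrier == 0))
  })
}

## ---------------------------------------------------------------------------
## Hardy-Weinberg exact test
## ---------------------------------------------------------------------------

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, sums the probabilities of
#' all heterozygote counts no more probable than the observed one
#' (two-sided exact test by full enumeration). Monomorphic sites return
#' p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Exact p value.
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop("empty genotype table")
  n1 <- 2L * n_aa + n_Aa  # minor-allele copies (either orientation works)
  n2 <- 2L * n - n1
  if (n1 == 0L || n2 == 0L) return(1)
  hets <- seq.int(n1 %% 2L, min(n1, n2), by = 2L)
  lp <- lfactorial(n) - lfactorial((n1 - hets) / 2) - lfactorial(hets) -
    lfactorial((n2 - hets) / 2) + hets * log(2) +
    lfactorial(n1) + lfactorial(n2) - lfactorial(2L * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

## ---------------------------------------------------------------------------
## Linkage disequilibrium
## ---------------------------------------------------------------------------

ld_from_hapfreq <- function(pAB, pAb, paB, pab) {
  pAB <- unname(pAB); pAb <- unname(pAb)
  paB <- unname(paB); pab <- unname(pab)
  pA <- pAB + pAb; pB <- pAB + paB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("undefined LD: monomorphic variant")
  }
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (d_max == 0) 0 else abs(D) / d_max
  list(D = D, r2 = r2, d_prime = d_prime,
       haplotype_freqs = c(AB = pAB, Ab = pAb, aB = paB, ab = pab))
}

#' Pairwise linkage disequilibrium
#'
#' With phased input, haplotype frequencies are the observed counts. With
#' unphased genotypes the double-heterozygote phase is resolved by EM
#' (converged when the largest frequency change drops below `tol`, at
#' most `max_iter` iterations). `D = p_AB - p_A p_B`;
#' `r2 = D^2 / (p_A p_a p_B p_b)`; `D' = |D| / D_max`.
#'
#' @param haplotypes Optional length-4 vector of phased haplotype counts
#'   `(AB, Ab, aB, ab)`.
#' @param genotypes Optional 3x3 matrix of unphased genotype counts, rows
#'   = copies of allele `a` at the first variant (0, 1, 2), columns =
#'   copies of `b` at the second.
#' @param tol EM convergence tolerance (default 1e-10).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return Object of class `ld_result`: `D`, `r2`, `d_prime`,
#'   `haplotype_freqs`, and for EM fits `iterations` and `converged`.
#' @export
ld_pair <- function(haplotypes = NULL, genotypes = NULL, tol = 1e-10,
                    max_iter = 1000L) {
  if (!is.null(haplotypes)) {
    stopifnot(length(haplotypes) == 4L, all(haplotypes >= 0),
              sum(haplotypes) > 0)
    h <- haplotypes / sum(haplotypes)
    out <- ld_from_hapfreq(h[1L], h[2L], h[3L], h[4L])
    out$iterations <- 0L
    out$converged <- TRUE
    return(structure(out, class = "ld_result"))
  }
  g <- as.matrix(genotypes)
  stopifnot(all(dim(g) == c(3L, 3L)), all(g >= 0), sum(g) > 0)
  n_hap <- 2 * sum(g)
  ## haplotype-count contributions that are phase-unambiguous; genotype
  ## (1,1) contributes either AB+ab or Ab+aB
  ## rows: copies of a (so row 1 = AA), columns: copies of b
  base_AB <- 2 * g[1, 1] + g[1, 2] + g[2, 1]
  base_Ab <- 2 * g[1, 3] + g[1, 2] + g[2, 3]
  base_aB <- 2 * g[3, 1] + g[2, 1] + g[3, 2]
  base_ab <- 2 * g[3, 3] + g[2, 3] + g[3, 2]
  dh <- g[2, 2]
  f <- rep(0.25, 4)  # AB, Ab, aB, ab
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    cis <- f[1] * f[4]; trans <- f[2] * f[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- c(base_AB + dh * w, base_Ab + dh * (1 - w),
             base_aB + dh * (1 - w), base_ab + dh * w)
    f_new <- cnt / n_hap
    if (max(abs(f_new - f)) < tol) { f <- f_new; converged <- TRUE; break }
    f <- f_new
  }
  out <- ld_from_hapfreq(f[1], f[2], f[3], f[4])
  out$iterations <- it
  out$converged <- converged
  structure(out, class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD: r2 = %.3f, D' = %.3f (D = %.4f)\n", x$r2, x$d_prime, x$D))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Effective number of tests
## ---------------------------------------------------------------------------

#' Spectral-decomposition multiple-testing threshold
#'
#' Effective number of independent tests from the eigenvalues of the
#' absolute-value correlation matrix (Li-Ji):
#' `m_eff = sum(I(lambda >= 1) + (lambda - floor(lambda)))`;
#' the study-wide threshold is `alpha / m_eff`.
#'
#' @param correlation_matrix Symmetric correlation matrix with unit
#'   diagonal.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List with `m_eff` and `threshold`.
#' @export
meff_cutoff <- function(correlation_matrix, alpha = 0.05) {
  m <- as.matrix(correlation_matrix)
  if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8)) {
    stop("structural error: correlation matrix must be symmetric")
  }
  if (any(abs(diag(m) - 1) > 1e-8)) {
    stop("structural error: diagonal must be 1")
  }
  lambda <- eigen(abs(m), symmetric = TRUE, only.values = TRUE)$values
  m_eff <- sum(as.numeric(lambda >= 1) + (lambda - floor(lambda)))
  list(m_eff = m_eff, threshold = alpha / m_eff)
}
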