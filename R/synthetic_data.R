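## Synthetic inputs: toy loci, planted mutations, amplicon cDNA reads under
## an explicit NMD/rescue generative model, and stratified cohort tables.
##
## The generator's defaults encode the study conditions the pipeline is
## validated under: equal allelic amplification (wt_allele_share 0.5),
## nanopore-like random error (5% substitution, 3% insertion, 5% deletion
## per base) and amplicon read depths in the low thousands.

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste0,
        collapse = ""),
  STOP_CODONS)

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Configure an amplicon read simulation
#'
#' @param seed Integer RNG seed; identical configurations are
#'   bit-reproducible.
#' @param n_reads Number of surviving reads to emit.
#' @param nmd_efficiency Probability `e` in `[0,1]` that a PTC-bearing
#'   transcript is degraded before sampling (0 = no decay, 1 = complete
#'   decay).
#' @param rescue Numeric vector of per-rescue-isoform proportions `r_k`
#'   among mutant-allele transcripts; must sum to at most 1.
#' @param wt_rescue Proportions of the same rescue isoforms on the
#'   wild-type allele (rescue-type splicing unrelated to a PTC);
#'   default all zero.
#' @param wt_allele_share Share `w` of the transcript pool from the
#'   wild-type allele before decay (default 0.5, balanced amplification).
#' @param p_sub,p_ins,p_del Per-base substitution / insertion / deletion
#'   error rates (defaults 0.05 / 0.03 / 0.05).
#' @param truncation Optional `list(max5 =, max3 =)` giving maximum
#'   uniform 5'/3' reference-side truncation per read; `NULL` disables.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, n_reads = 2000L, nmd_efficiency = 0,
                       rescue = numeric(0), wt_rescue = NULL,
                       wt_allele_share = 0.5,
                       p_sub = 0.05, p_ins = 0.03, p_del = 0.05,
                       truncation = NULL) {
  probs <- c(nmd_efficiency, rescue, wt_allele_share, p_sub, p_ins, p_del)
  if (any(probs < 0 | probs > 1)) stop("config error: probabilities in [0,1]")
  if (sum(rescue) > 1) stop("config error: rescue proportions sum above 1")
  if (is.null(wt_rescue)) wt_rescue <- rep(0, length(rescue))
  if (length(wt_rescue) != length(rescue) || sum(wt_rescue) > 1) {
    stop("config error: wt_rescue must match rescue and sum to at most 1")
  }
  if (n_reads < 1L) stop("config error: n_reads must be positive")
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 nmd_efficiency = nmd_efficiency, rescue = rescue,
                 wt_rescue = wt_rescue, wt_allele_share = wt_allele_share,
                 p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 truncation = truncation),
            class = "sim_config")
}

## ---------------------------------------------------------------------------
## Toy locus
## ---------------------------------------------------------------------------

#' Generate a random toy locus with a valid single-transcript model
#'
#' The coding sequence is assembled from non-stop codons (so the canonical
#' frame has no internal stop by construction) with a planted `ATG` start
#' and `TAA` terminal codon; introns carry `GT...AG` splice dinucleotides
#' in transcript orientation.
#'
#' @param seed Integer RNG seed.
#' @param exon_lengths Integer vector of exon lengths (sum divisible by 3).
#' @param intron_lengths Integer vector of intron lengths (one fewer than
#'   exons; each at least 10).
#' @param strand `"+"` or `"-"`.
#' @param flank Plain flanking sequence length on each side (default 25).
#' @param name Reference name.
#' @return List with `reference` (a [reference_seq()]) and `model`
#'   (a `transcript_model`).
#' @export
make_toy_locus <- function(seed, exon_lengths = c(30L, 168L, 45L, 255L, 33L),
                           intron_lengths = rep(90L, length(exon_lengths) - 1L),
                           strand = "+", flank = 25L, name = "toylocus") {
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  n <- length(exon_lengths)
  if (n < 1L || any(exon_lengths < 1L)) stop("config error: bad exon lengths")
  if (length(intron_lengths) != n - 1L || (n > 1L && any(intron_lengths < 10L))) {
    stop("config error: need ", n - 1L, " intron lengths of at least 10")
  }
  total_cds <- sum(exon_lengths)
  if (total_cds < 6L || total_cds %% 3L != 0L) {
    stop("config error: total CDS length must be >= 6 and divisible by 3")
  }
  with_seed(seed, {
    n_codons <- total_cds %/% 3L
    codons <- c("ATG",
                sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
                "TAA")
    cds <- paste(codons, collapse = "")
    cuts <- cumsum(exon_lengths)
    exon_seq <- substring(cds, c(1L, head(cuts, -1L) + 1L), cuts)
    intron_seq <- vapply(intron_lengths, function(L) {
      body <- paste(sample(DNA_BASES, L - 4L, replace = TRUE), collapse = "")
      paste0("GT", body, "AG")
    }, character(1))
    flank5 <- paste(sample(DNA_BASES, flank, replace = TRUE), collapse = "")
    flank3 <- paste(sample(DNA_BASES, flank, replace = TRUE), collapse = "")

    pieces <- character(2L * n - 1L)
    pieces[seq(1L, 2L * n - 1L, by = 2L)] <- exon_seq
    if (n > 1L) pieces[seq(2L, 2L * n - 2L, by = 2L)] <- intron_seq
    genome_plus <- paste0(flank5, paste(pieces, collapse = ""), flank3)

    starts <- integer(n); ends <- integer(n)
    pos <- flank
    for (i in seq_len(n)) {
      starts[i] <- pos
      ends[i] <- pos + exon_lengths[i]
      pos <- ends[i] + if (i < n) intron_lengths[i] else 0L
    }
    exons <- cbind(starts, ends)

    if (strand == "-") {
      L <- nchar(genome_plus)
      genome <- revcomp(genome_plus)
      exons <- cbind(L - ends, L - starts)[rev(seq_len(n)), , drop = FALSE]
    } else {
      genome <- genome_plus
    }
    reference <- reference_seq(name, genome)
    model <- build_transcript(reference, exons, strand)
    list(reference = reference, model = model)
  })
}

## ---------------------------------------------------------------------------
## Variant planting
## ---------------------------------------------------------------------------

## 1-based CDS positions covered by exon k (transcript order).
exon_cds_positions <- function(model, k) {
  sp <- exon_tx_span(model, k)
  lo <- max(sp[1L], model$cds_start_t)
  hi <- min(sp[2L], model$cds_end_t)
  if (lo >= hi) return(integer(0))
  seq.int(lo - model$cds_start_t + 1L, hi - model$cds_start_t)
}

#' Plant a mutation of a requested class into a toy locus
#'
#' @param model A `transcript_model`.
#' @param reference A [reference_seq()].
#' @param kind One of `"nonsense"`, `"frameshift_del"`, `"frameshift_dup"`,
#'   `"inframe_del"`, `"splice_donor"`, `"splice_acceptor"`.
#' @param exon Target exon (transcript order). For `"splice_donor"` the
#'   donor site of the intron following this exon is mutated; for
#'   `"splice_acceptor"` the acceptor site of the intron preceding it.
#' @param span Span in nt for deletions/duplications (default 7 for
#'   frameshift deletions, 1 for duplications, 3 for in-frame deletions).
#' @return List with `variant` (an `hgvs_variant`) and `genomic`
#'   (0-based genomic position, ref and alt of the DNA edit; splice-site
#'   edits are intronic).
#' @export
plant_variant <- function(model, reference,
                          kind = c("nonsense", "frameshift_del",
                                   "frameshift_dup", "inframe_del",
                                   "splice_donor", "splice_acceptor"),
                          exon = 2L, span = NULL) {
  kind <- match.arg(kind)
  cds <- cds_sequence(model, reference)
  n_codons <- nchar(cds) %/% 3L

  cds_to_genomic <- function(cds_pos) {
    transcript_to_genomic(model, model$cds_start_t + cds_pos - 1L)
  }

  if (kind == "nonsense") {
    pos_all <- exon_cds_positions(model, exon)
    cods <- unique(affected_codon(pos_all))
    cods <- cods[cods > 1L & cods < n_codons]
    for (cod in cods) {
      ## codon must lie fully inside the exon
      if (!all(((cod - 1L) * 3L + 1L):(cod * 3L) %in% pos_all)) next
      codon <- substr(cds, (cod - 1L) * 3L + 1L, cod * 3L)
      for (stp in STOP_CODONS) {
        diffs <- which(strsplit(codon, "")[[1L]] != strsplit(stp, "")[[1L]])
        if (length(diffs) == 1L) {
          p <- (cod - 1L) * 3L + diffs
          ref <- substr(codon, diffs, diffs)
          alt <- substr(stp, diffs, diffs)
          aa <- as.character(Biostrings::GENETIC_CODE[codon])
          lab <- sprintf("p.%s%d*", AA3[[aa]], cod)
          v <- parse_chgvs(sprintf("c.%d%s>%s", p, ref, alt), lab)
          return(list(variant = v,
                      genomic = list(pos = cds_to_genomic(p), ref = ref,
                                     alt = alt)))
        }
      }
    }
    stop("placement error: no nonsense-capable codon in exon ", exon)
  }

  if (kind %in% c("frameshift_del", "frameshift_dup", "inframe_del")) {
    if (is.null(span)) {
      span <- switch(kind, frameshift_del = 7L, frameshift_dup = 1L,
                     inframe_del = 3L)
    }
    span <- as.integer(span)
    if (kind == "inframe_del" && span %% 3L != 0L) {
      stop("placement error: in-frame deletion span must be divisible by 3")
    }
    if (kind != "inframe_del" && span %% 3L == 0L) {
      stop("placement error: frameshift span must not be divisible by 3")
    }
    pos_all <- exon_cds_positions(model, exon)
    ## keep clear of the start and terminal codons
    pos_ok <- pos_all[pos_all > 3L & pos_all <= nchar(cds) - 3L - span]
    if (length(pos_ok) < span) {
      stop("placement error: exon ", exon, " too short for a ", span,
           " nt edit")
    }
    p <- pos_ok[(length(pos_ok) - span) %/% 2L + 1L]  # mid-exon
    seq <- substr(cds, p, p + span - 1L)
    s <- if (grepl("del", kind)) {
      if (span == 1L) sprintf("c.%ddel%s", p, seq)
      else sprintf("c.%d_%ddel%s", p, p + span - 1L, seq)
    } else {
      if (span == 1L) sprintf("c.%ddup%s", p, seq)
      else sprintf("c.%d_%ddup%s", p, p + span - 1L, seq)
    }
    v <- parse_chgvs(s)
    return(list(variant = v,
                genomic = list(pos = cds_to_genomic(p), ref = seq,
                               alt = if (grepl("dup", kind))
                                 paste0(seq, seq) else "")))
  }

  ## canonical splice-site substitutions
  if (kind == "splice_donor") {
    if (exon >= n_exons(model)) stop("placement error: no intron after exon ",
                                     exon)
    pos_all <- exon_cds_positions(model, exon)
    anchor <- max(pos_all)               # last coding base of the exon
    ig <- intron_genomic(model, exon)
    gpos <- if (model$strand == "+") ig[1L] else ig[2L] - 1L
    v <- parse_chgvs(sprintf("c.%d+1G>T", anchor))
    return(list(variant = v,
                genomic = list(pos = gpos,
                               ref = if (model$strand == "+") "G" else "C",
                               alt = if (model$strand == "+") "T" else "A")))
  }
  ## splice_acceptor: mutate the AG immediately before `exon`
  if (exon <= 1L) stop("placement error: no intron before exon ", exon)
  pos_all <- exon_cds_positions(model, exon)
  anchor <- min(pos_all)                 # first coding base of the exon
  ig <- intron_genomic(model, exon - 1L)
  gpos <- if (model$strand == "+") ig[2L] - 1L else ig[1L]
  v <- parse_chgvs(sprintf("c.%d-1G>A", anchor))
  list(variant = v,
       genomic = list(pos = gpos,
                      ref = if (model$strand == "+") "G" else "C",
                      alt = if (model$strand == "+") "A" else "T"))
}

## ---------------------------------------------------------------------------
## Read simulation
## ---------------------------------------------------------------------------

## An isoform template: reference blocks, the edited transcript sequence,
## and where the variant's indel sits on the reference (for CIGAR D/I ops).
build_template <- function(model, reference, events, variant) {
  mt <- mature_sequence(model, reference, events = events, variant = variant)
  blocks <- mt$blocks
  del_span <- NULL; ins_after <- NULL
  if (!is.null(variant) && mt$variant_applied) {
    g0 <- transcript_to_genomic(model,
                                model$cds_start_t + variant$cds_pos - 1L)
    if (variant$kind == "deletion") {
      del_span <- c(g0, g0 + variant$span_length)
    } else if (variant$kind == "duplication") {
      ins_after <- c(g0 + variant$span_length - 1L, variant$span_length)
    } else if (variant$kind == "insertion") {
      ins_after <- c(g0, variant$span_length)
    }
  }
  list(mature = mt, blocks = blocks, del_span = del_span,
       ins_after = ins_after)
}

## Flatten a template into reference-space ops. Each element:
## list(op, len, seq) where op is M (aligned segment, seq = query bases),
## I (insertion, seq = query bases), D or N (reference only).
template_ops <- function(template) {
  blocks <- template$blocks
  seq <- template$mature$sequence
  ops <- list()
  qpos <- 0L
  push <- function(op, len, s = "") {
    if (len > 0L) ops[[length(ops) + 1L]] <<- list(op = op, len = len, seq = s)
  }
  take <- function(len) {
    s <- substr(seq, qpos + 1L, qpos + len)
    qpos <<- qpos + len
    s
  }
  ds <- template$del_span; ia <- template$ins_after
  for (i in seq_len(nrow(blocks))) {
    s <- blocks$gstart[i]; e <- blocks$gend[i]
    if (!is.null(ds) && ds[1L] >= s && ds[2L] <= e) {
      push("M", ds[1L] - s, take(ds[1L] - s))
      push("D", ds[2L] - ds[1L])
      push("M", e - ds[2L], take(e - ds[2L]))
    } else if (!is.null(ia) && ia[1L] >= s && ia[1L] < e) {
      push("M", ia[1L] + 1L - s, take(ia[1L] + 1L - s))
      push("I", ia[2L], take(ia[2L]))
      push("M", e - ia[1L] - 1L, take(e - ia[1L] - 1L))
    } else {
      push("M", e - s, take(e - s))
    }
    if (i < nrow(blocks)) push("N", blocks$gstart[i + 1L] - e)
  }
  stopifnot(qpos == nchar(seq))
  ops
}

## Trim t5/t3 reference-consuming bases from the op list ends.
trim_ops <- function(ops, t5, t3) {
  ref_len <- function(o) if (o$op %in% c("M", "D", "N")) o$len else 0L
  trim_one_side <- function(ops, t, from_left) {
    while (t > 0L && length(ops) > 1L) {
      i <- if (from_left) 1L else length(ops)
      o <- ops[[i]]
      rl <- ref_len(o)
      if (rl <= t && o$op != "M") { t <- t - rl; ops[[i]] <- NULL; next }
      if (o$op != "M") break
      cut <- min(t, o$len - 1L)
      if (cut <= 0L) break
      if (from_left) {
        o$seq <- substr(o$seq, cut + 1L, o$len)
      } else {
        o$seq <- substr(o$seq, 1L, o$len - cut)
      }
      o$len <- o$len - cut
      ops[[i]] <- o
      t <- t - cut
      if (o$len >= 1L) break
    }
    ops
  }
  ops <- trim_one_side(ops, t5, TRUE)
  trim_one_side(ops, t3, FALSE)
}

ops_ref_len <- function(ops) {
  sum(vapply(ops, function(o)
    if (o$op %in% c("M", "D", "N")) o$len else 0L, integer(1)))
}

## Apply per-base random errors to one read. Returns list(cigar, seq).
## The first and last aligned bases are protected from deletion so the
## alignment keeps M at both ends.
read_with_errors <- function(ops, p_sub, p_ins, p_del) {
  if (p_sub == 0 && p_ins == 0 && p_del == 0) {
    return(list(
      cigar = cigar_string(vapply(ops, `[[`, character(1), "op"),
                           vapply(ops, `[[`, integer(1), "len")),
      seq = paste(vapply(ops, `[[`, character(1), "seq"), collapse = "")))
  }
  cig_ops <- character(0); cig_len <- integer(0)
  seq_parts <- character(0)
  m_idx <- which(vapply(ops, function(o) o$op == "M", logical(1)))
  first_m <- m_idx[1L]; last_m <- m_idx[length(m_idx)]
  for (j in seq_along(ops)) {
    o <- ops[[j]]
    if (o$op %in% c("D", "N")) {
      cig_ops <- c(cig_ops, o$op); cig_len <- c(cig_len, o$len)
      next
    }
    if (o$op == "I") {  # variant-template insertion passed through as-is
      cig_ops <- c(cig_ops, "I"); cig_len <- c(cig_len, o$len)
      seq_parts <- c(seq_parts, o$seq)
      next
    }
    L <- o$len
    base <- strsplit(o$seq, "", fixed = TRUE)[[1L]]
    keep <- runif(L) >= p_del
    if (j == first_m) keep[1L] <- TRUE
    if (j == last_m) keep[L] <- TRUE
    sub <- runif(L) < p_sub
    if (any(sub & keep)) {
      idx <- which(sub & keep)
      shift <- sample.int(3L, length(idx), replace = TRUE)
      base[idx] <- DNA_BASES[(match(base[idx], DNA_BASES) - 1L + shift) %% 4L + 1L]
    }
    ins <- runif(L) < p_ins
    cells_op <- ifelse(keep, "M", "D")
    cells_seq <- ifelse(keep, base, "")
    if (any(ins)) {
      idx <- which(ins)
      cells_op[idx] <- paste0(cells_op[idx], "I")
      cells_seq[idx] <- paste0(cells_seq[idx],
                               sample(DNA_BASES, length(idx), replace = TRUE))
    }
    opstr <- strsplit(paste(cells_op, collapse = ""), "", fixed = TRUE)[[1L]]
    cig_ops <- c(cig_ops, opstr)
    cig_len <- c(cig_len, rep(1L, length(opstr)))
    seq_parts <- c(seq_parts, paste(cells_seq, collapse = ""))
  }
  list(cigar = cigar_string(cig_ops, cig_len),
       seq = paste(seq_parts, collapse = ""))
}

#' Simulate amplicon cDNA reads from a two-allele transcript pool
#'
#' Per transcript draw: the allele is mutant with probability
#' `1 - wt_allele_share`; mutant transcripts take rescue isoform `k` with
#' probability `rescue[k]` and otherwise the PTC isoform, which survives
#' nonsense-mediated decay with probability `1 - nmd_efficiency`;
#' wild-type transcripts always survive (and may take a rescue-type
#' isoform with probability `wt_rescue[k]`). Surviving transcripts are
#' sampled to `n_reads` and each read receives independent per-base
#' substitution/insertion/deletion errors. The emitted SAM encodes each
#' read's generative alignment (exon blocks as `M`, introns as `N`,
#' simulated indels as `I`/`D`), so no external aligner is required.
#'
#' The expected PTC expression fraction under this model,
#' `(1-R)(1-e)m / ((1-R)(1-e)m + w)` with `m = 1 - w` and `R = sum(rescue)`,
#' is recorded in the returned metadata.
#'
#' @param model A plus-strand `transcript_model`.
#' @param reference A [reference_seq()].
#' @param variant Optional `hgvs_variant` carried by the mutant allele.
#'   Canonical-splice variants carry no exonic edit; their mis-splicing
#'   must be supplied as `mut_events`.
#' @param mut_events List of [splice_event()]s constituting the mutant
#'   allele's aberrant splicing (required for splice-site variants, empty
#'   for exonic variants).
#' @param rescue_isoforms List of event lists, one per rescue isoform.
#' @param config A [sim_config()].
#' @return List with `sam` (data frame of SAM fields), `truth` (per-read
#'   truth records: `read_id`, `source_allele`, `source_isoform`,
#'   `expected_class`), `meta` (configuration echo plus expected
#'   fractions), `reference` and `model`.
#' @export
simulate_amplicon_reads <- function(model, reference, variant = NULL,
                                    mut_events = list(),
                                    rescue_isoforms = list(),
                                    config) {
  stopifnot(inherits(config, "sim_config"))
  if (model$strand != "+") {
    stop("read simulation is defined on plus-strand toy loci")
  }
  if (length(config$rescue) != length(rescue_isoforms)) {
    stop("config error: rescue proportions must match rescue_isoforms")
  }
  w <- config$wt_allele_share
  m <- 1 - w
  e <- config$nmd_efficiency
  R <- sum(config$rescue)

  expected_class_of <- function(mt, source_allele) {
    scan <- scan_for_ptc(mt)
    has_ptc <- scan$status == "ptc"
    if (source_allele == "WT") {
      if (has_ptc) "OTHER" else "WT"
    } else {
      if (has_ptc) "PTC" else "RESCUE"
    }
  }

  templates <- list()
  probs <- numeric(0)
  add_template <- function(label, allele, isoform, events, var, prob) {
    tpl <- build_template(model, reference, events, var)
    tpl$ops <- template_ops(tpl)
    tpl$allele <- allele
    tpl$isoform <- isoform
    tpl$expected_class <- expected_class_of(tpl$mature, allele)
    templates[[label]] <<- tpl
    probs[label] <<- prob
  }

  wtR <- sum(config$wt_rescue)
  add_template("WT_canonical", "WT", "canonical", list(), NULL, w * (1 - wtR))
  for (k in seq_along(rescue_isoforms)) {
    if (config$wt_rescue[k] > 0) {
      add_template(paste0("WT_rescue_", k), "WT", paste0("rescue_", k),
                   rescue_isoforms[[k]], NULL, w * config$wt_rescue[k])
    }
    add_template(paste0("MUT_rescue_", k), "MUT", paste0("rescue_", k),
                 rescue_isoforms[[k]], variant, m * config$rescue[k])
  }
  add_template("MUT_ptc", "MUT", "aberrant", mut_events, variant,
               m * (1 - R) * (1 - e))

  if (sum(probs) <= 0) {
    stop("empty-pool error: no transcript survives the generative model")
  }
  p_norm <- probs / sum(probs)
  expected_ptc_fraction <-
    if ((1 - R) * (1 - e) * m + w > 0)
      (1 - R) * (1 - e) * m / ((1 - R) * (1 - e) * m + w) else NA_real_

  with_seed(config$seed, {
    draw <- sample(seq_along(templates), config$n_reads, replace = TRUE,
                   prob = p_norm)
    qname <- sprintf("read%05d", seq_len(config$n_reads))
    cigar <- character(config$n_reads)
    seqs <- character(config$n_reads)
    pos1 <- integer(config$n_reads)
    for (i in seq_len(config$n_reads)) {
      tpl <- templates[[draw[i]]]
      ops <- tpl$ops
      off5 <- 0L
      if (!is.null(config$truncation)) {
        t5 <- sample.int(config$truncation$max5 + 1L, 1L) - 1L
        t3 <- sample.int(config$truncation$max3 + 1L, 1L) - 1L
        full_len <- ops_ref_len(ops)
        ops <- trim_ops(ops, t5, 0L)
        off5 <- full_len - ops_ref_len(ops)
        ops <- trim_ops(ops, 0L, t3)
      }
      rd <- read_with_errors(ops, config$p_sub, config$p_ins, config$p_del)
      cigar[i] <- rd$cigar
      seqs[i] <- rd$seq
      pos1[i] <- tpl$blocks$gstart[1L] + off5 + 1L
    }
    labels <- names(templates)[draw]
    truth <- data.frame(
      read_id = qname,
      source_allele = vapply(templates[draw], `[[`, character(1), "allele"),
      source_isoform = vapply(templates[draw], `[[`, character(1), "isoform"),
      expected_class = vapply(templates[draw], `[[`, character(1),
                              "expected_class"),
      template = labels,
      stringsAsFactors = FALSE
    )
    sam <- data.frame(
      qname = qname, flag = 0L, rname = reference$name, pos = pos1,
      mapq = 60L, cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
      seq = seqs, qual = vapply(seqs, function(s) strrep("I", nchar(s)),
                                character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
    meta <- list(
      config = unclass(config),
      variant = if (!is.null(variant)) format_chgvs(variant) else NA_character_,
      template_probs = as.list(p_norm),
      expected_ptc_fraction = expected_ptc_fraction,
      expected_rescue_fraction =
        if (m * R + (1 - R) * (1 - e) * m + w > 0)
          m * R / (m * R + (1 - R) * (1 - e) * m + w) else NA_real_
    )
    list(sam = sam, truth = truth, meta = meta, reference = reference,
         model = model)
  })
}

#' Write a simulation to FASTA/BED12/SAM/FASTQ/TSV/JSON files
#'
#' @param sim Result of [simulate_amplicon_reads()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of written paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  paths <- c(fasta = p(".fa"), bed = p(".bed"), sam = p(".sam"),
             fastq = p(".fastq"), truth = p("_truth.tsv"),
             meta = p("_meta.json"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(sim$reference$sequence,
                                      sim$reference$name)),
    paths[["fasta"]])
  write_transcript_bed12(sim$model, paths[["bed"]])
  write_sam(sim$sam, paths[["sam"]],
            refname = sim$reference$name,
            reflen = nchar(sim$reference$sequence))
  fq <- character(4L * nrow(sim$sam))
  fq[seq(1L, length(fq), 4L)] <- paste0("@", sim$sam$qname)
  fq[seq(2L, length(fq), 4L)] <- sim$sam$seq
  fq[seq(3L, length(fq), 4L)] <- "+"
  fq[seq(4L, length(fq), 4L)] <- sim$sam$qual
  writeLines(fq, paths[["fastq"]])
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(sim$meta, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               paths[["meta"]])
  }
  paths
}

#' Write alignment rows as a SAM file
#'
#' @param sam Data frame with the eleven mandatory SAM columns.
#' @param path Output path.
#' @param refname,reflen `@SQ` header name and length.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(sam, path, refname, reflen) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", refname, "\tLN:", reflen))
  body <- do.call(paste, c(sam[, c("qname", "flag", "rname", "pos", "mapq",
                                   "cigar", "rnext", "pnext", "tlen",
                                   "seq", "qual")],
                           sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Cohort simulation
## ---------------------------------------------------------------------------

#' Simulate a stratified carrier cohort
#'
#' Independent Bernoulli carrier draws per individual, with the same
#' carrier frequencies in every stratum (the stratified design varies the
#' stratum sizes, not the effect).
#'
#' @param strata List of `list(label =, n_pat =, n_ctl =)`.
#' @param carrier_freq_pat,carrier_freq_ctl Carrier frequencies among
#'   patients and controls.
#' @param seed Integer RNG seed.
#' @return Per-individual data frame (`id`, `cohort`, `stratum`,
#'   `carrier`), with attribute `"implied_or"` giving the odds ratio
#'   implied by the generating frequencies.
#' @export
simulate_cohort <- function(strata, carrier_freq_pat, carrier_freq_ctl,
                            seed) {
  stopifnot(carrier_freq_pat >= 0, carrier_freq_pat <= 1,
            carrier_freq_ctl >= 0, carrier_freq_ctl <= 1)
  with_seed(seed, {
    rows <- lapply(strata, function(s) {
      n <- s$n_pat + s$n_ctl
      data.frame(
        id = paste0(s$label, "_", seq_len(n)),
        cohort = rep(c("patient", "control"), c(s$n_pat, s$n_ctl)),
        stratum = s$label,
        carrier = c(rbinom(s$n_pat, 1L, carrier_freq_pat),
                    rbinom(s$n_ctl, 1L, carrier_freq_ctl)),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "implied_or") <-
      (carrier_freq_pat / (1 - carrier_freq_pat)) /
      (carrier_freq_ctl / (1 - carrier_freq_ctl))
    out
  })
}
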