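## Classification of spliced long-read amplicon alignments into wild-type,
## PTC-bearing, frame-rescued and other transcripts, and the expression
## fractions derived from the counts.

## ---------------------------------------------------------------------------
## Alignment ingestion
## ---------------------------------------------------------------------------

#' Read spliced alignments from a SAM or BAM file
#'
#' Splice gaps must be encoded as CIGAR `N`; soft clips are tolerated.
#' Secondary and supplementary alignments are dropped with a logged count,
#' as are unmapped records. SAM input is converted through
#' [Rsamtools::asBam()].
#'
#' @param path SAM or BAM file.
#' @param reference A [reference_seq()]; the file's `@SQ` must name it.
#' @param gap_threshold Deletions of at least this many nt are treated as
#'   splice junctions rather than alignment deletions (default 30).
#' @return An object of class `aligned_reads`: per-read ids, 0-based
#'   alignment starts, CIGARs, block lists (0-based half-open, split on
#'   `N` gaps and on deletions of at least `gap_threshold`),
#'   reference-space projected sequences, and indel op tables.
#' @export
read_alignments <- function(path, reference, gap_threshold = 30L) {
  stopifnot(inherits(reference, "reference_seq"))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                             indexDestination = FALSE))
  } else {
    bam <- path
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!reference$name %in% names(hdr)) {
    stop("reference mismatch: no @SQ record named '", reference$name, "'")
  }
  if (hdr[[reference$name]] != ref_length(reference)) {
    stop("reference mismatch: @SQ length ", hdr[[reference$name]],
         " differs from reference length ", ref_length(reference))
  }
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag", "seq"))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  flag <- S4Vectors::mcols(gal)$flag
  sup <- bitwAnd(flag, 0x900L) != 0L
  n_dropped <- sum(sup)
  gal <- gal[!sup]
  if (length(gal) == 0L) stop("empty read set: no primary alignments")

  cig <- GenomicAlignments::cigar(gal)
  starts0 <- GenomicAlignments::start(gal) - 1L
  qname <- S4Vectors::mcols(gal)$qname
  layered <- GenomicAlignments::sequenceLayer(S4Vectors::mcols(gal)$seq, cig,
                                              from = "query",
                                              to = "reference")
  layered <- as.character(layered)

  ## blocks: split on N; additionally split on D >= gap_threshold
  grl <- GenomicAlignments::grglist(gal, drop.D.ranges = FALSE)
  nblk <- S4Vectors::elementNROWS(grl)
  ublk <- BiocGenerics::unlist(grl, use.names = FALSE)
  all_start <- GenomicRanges::start(ublk) - 1L
  all_end <- GenomicRanges::end(ublk)
  grp <- rep.int(seq_along(gal), nblk)
  sstart <- split(all_start, grp)
  send <- split(all_end, grp)
  blocks <- lapply(seq_along(gal), function(i) {
    cbind(start = sstart[[i]], end = send[[i]])
  })
  indel_rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = starts0 + 1L, ops = c("I", "D"), with.ops = TRUE)
  n_ind <- S4Vectors::elementNROWS(indel_rng)
  u_ind <- BiocGenerics::unlist(indel_rng, use.names = TRUE)
  igrp <- factor(rep.int(seq_along(gal), n_ind), levels = seq_along(gal))
  ind_op <- split(names(u_ind), igrp)
  ind_start <- split(IRanges::start(u_ind) - 1L, igrp)
  ind_len <- split(unlist(GenomicAlignments::explodeCigarOpLengths(
    cig, ops = c("I", "D")), use.names = FALSE), igrp)
  indels <- lapply(seq_along(gal), function(i)
    list(op = ind_op[[i]], start0 = ind_start[[i]], len = ind_len[[i]]))
  ## split blocks at large deletions
  for (i in seq_along(blocks)) {
    sel <- indels[[i]]$op == "D" & indels[[i]]$len >= gap_threshold
    if (!any(sel)) next
    b <- blocks[[i]]
    for (j in which(sel)) {
      d0 <- indels[[i]]$start0[j]; d1 <- d0 + indels[[i]]$len[j]
      hit <- which(b[, 1L] < d0 & b[, 2L] > d1)
      if (length(hit) == 1L) {
        b <- rbind(b[seq_len(hit - 1L), , drop = FALSE],
                   c(b[hit, 1L], d0), c(d1, b[hit, 2L]),
                   b[-seq_len(hit), , drop = FALSE])
      }
    }
    blocks[[i]] <- b[order(b[, 1L]), , drop = FALSE]
  }

  structure(list(read_id = qname, start0 = starts0, cigar = cig,
                 blocks = blocks, layered = layered, indels = indels,
                 n_dropped_secondary = n_dropped),
            class = "aligned_reads")
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat("<aligned_reads: ", length(x$read_id), " primary alignments, ",
      x$n_dropped_secondary, " secondary/supplementary dropped>\n", sep = "")
  invisible(x)
}

n_reads_aln <- function(aln) length(aln$read_id)

read_span <- function(aln, i) {
  b <- aln$blocks[[i]]
  c(b[1L, 1L], b[nrow(b), 2L])
}

#' Junction chain of one aligned read
#'
#' One junction per inter-block gap: splice (`N`) gaps plus deletions at
#' or above the gap threshold used at ingestion. Small deletions are not
#' junctions.
#'
#' @param aln An `aligned_reads` object.
#' @param i Read index.
#' @return Two-column matrix (`donor_end`, `acceptor_start`), 0-based
#'   half-open boundary coordinates; zero rows for unspliced reads.
#' @export
junction_chain <- function(aln, i) {
  b <- aln$blocks[[i]]
  n <- nrow(b)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("donor_end", "acceptor_start"))))
  }
  cbind(donor_end = b[-n, 2L], acceptor_start = b[-1L, 1L])
}

## ---------------------------------------------------------------------------
## Event detection
## ---------------------------------------------------------------------------

## Canonical boundary tables in genomic coordinates.
canonical_boundaries <- function(model) {
  ex <- model$exons  # genomic order
  n <- nrow(ex)
  list(left = ex[, 1L], right = ex[, 2L], n = n)
}

## Map genomic-order exon index to transcript-order index.
g2t_exon <- function(model, k) {
  if (model$strand == "+") k else n_exons(model) + 1L - k
}

#' Detect splice events of one read against the canonical junction chain
#'
#' Junctions matching a canonical junction within `tolerance` are
#' canonical. A junction connecting the donor of exon `k-1` to the
#' acceptor of exon `k+1` is an exon skip. A junction with exactly one
#' canonical end and the other displaced by at least `tolerance` is a
#' cryptic donor/acceptor when displaced into the exon, and a partial
#' intron retention when displaced into the intron. A contiguous block
#' crossing an exon-intron boundary by at least `tolerance` is an intron
#' retention with the retained length. Junctions matching nothing are
#' flagged unresolvable.
#'
#' @param aln An `aligned_reads` object.
#' @param i Read index.
#' @param model A `transcript_model`.
#' @param tolerance Junction matching tolerance in nt (default 3).
#' @return List with `events` (list of [splice_event()]) and
#'   `unresolvable` (logical).
#' @export
detect_events <- function(aln, i, model, tolerance = 3L) {
  ex <- model$exons
  n <- nrow(ex)
  plus <- model$strand == "+"
  ch <- junction_chain(aln, i)
  events <- list()
  unresolvable <- FALSE
  near <- function(a, b) abs(a - b) <= tolerance

  ## genomic introns in genomic order: intron g sits between genomic exon g
  ## and g+1; its transcript-order intron index:
  intron_t_index <- function(g) if (plus) g else n - g
  ## exon transcript index for genomic exon index
  tx_exon <- function(g) g2t_exon(model, g)

  for (j in seq_len(nrow(ch))) {
    d <- ch[j, 1L]; a <- ch[j, 2L]
    ## canonical junction?
    g_can <- which(vapply(seq_len(n - 1L), function(g)
      near(d, ex[g, 2L]) && near(a, ex[g + 1L, 1L]), logical(1)))
    if (length(g_can)) next
    ## skip: right ends of exon g, left start of exon g2 with g2 > g+1
    g_d <- which(vapply(seq_len(n), function(g) near(d, ex[g, 2L]),
                        logical(1)))
    g_a <- which(vapply(seq_len(n), function(g) near(a, ex[g, 1L]),
                        logical(1)))
    if (length(g_d) == 1L && length(g_a) == 1L && g_a > g_d + 1L) {
      for (g in seq.int(g_d + 1L, g_a - 1L)) {
        events[[length(events) + 1L]] <- splice_event("exon_skip", tx_exon(g))
      }
      next
    }
    if (length(g_d) == 1L && length(g_a) == 0L) {
      ## junction leaves the canonical donor of exon g_d but lands at a
      ## displaced acceptor of the next exon: cryptic acceptor, with
      ## positive delta when the boundary moves into the intron
      ## (lengthening the exon) and negative when it moves into the exon
      g2 <- g_d + 1L
      if (g2 <= n && a > ex[g_d, 2L] && a <= ex[g2, 2L] - 1L) {
        shift <- ex[g2, 1L] - a
        type <- if (plus) "cryptic_acceptor" else "cryptic_donor"
        events[[length(events) + 1L]] <-
          splice_event(type, tx_exon(g2), delta = shift)
        next
      }
      unresolvable <- TRUE
      next
    }
    if (length(g_a) == 1L && length(g_d) == 0L) {
      ## displaced donor of the preceding exon
      g1 <- g_a - 1L
      if (g1 >= 1L && d < ex[g_a, 1L] && d >= ex[g1, 1L] + 1L) {
        shift <- d - ex[g1, 2L]
        type <- if (plus) "cryptic_donor" else "cryptic_acceptor"
        events[[length(events) + 1L]] <-
          splice_event(type, tx_exon(g1), delta = shift)
        next
      }
      unresolvable <- TRUE
      next
    }
    unresolvable <- TRUE
  }

  ## intron retention: a contiguous block crossing an exon-intron boundary
  ## by >= tolerance with no junction anchored in that intron (a spliced
  ## junction inside the intron is a cryptic site, handled above)
  b <- aln$blocks[[i]]
  for (g in seq_len(n - 1L)) {
    istart <- ex[g, 2L]; iend <- ex[g + 1L, 1L]
    if (nrow(ch) > 0L &&
        any(ch >= istart - tolerance & ch <= iend + tolerance)) next
    ov <- pmin(b[, 2L], iend) - pmax(b[, 1L], istart)
    ov_len <- max(c(0L, ov))
    if (ov_len >= tolerance) {
      events[[length(events) + 1L]] <-
        splice_event("intron_retention", intron_t_index(g),
                     retained = if (ov_len >= iend - istart) NA_integer_
                                else ov_len)
    }
  }
  list(events = events, unresolvable = unresolvable)
}

## ---------------------------------------------------------------------------
## Allele calling
## ---------------------------------------------------------------------------

## Genomic 0-based half-open span of an exonic variant's affected bases.
variant_genomic_span <- function(model, variant) {
  vt <- model$cds_start_t + variant$cds_pos - 1L
  span <- if (variant$kind %in% c("deletion", "duplication"))
    variant$span_length else 1L
  g <- transcript_to_genomic(model, seq.int(vt, vt + span - 1L))
  c(min(g), max(g) + 1L)
}

## Does the event set excise the variant site from the implied transcript?
events_remove_variant <- function(model, events, variant) {
  if (length(events) == 0L) return(FALSE)
  blocks <- tryCatch(apply_events_to_blocks(model, events),
                     error = function(e) NULL)
  if (is.null(blocks)) return(FALSE)
  vs <- variant_genomic_span(model, variant)
  covered <- vapply(seq.int(vs[1L], vs[2L] - 1L), function(g)
    any(blocks$gstart <= g & g < blocks$gend), logical(1))
  !all(covered)
}

#' Error-tolerant allele call for one read at an exonic variant
#'
#' Substitutions are called from the aligned base at the variant position,
#' gated on agreement of the flanking window with the reference;
#' insertions/deletions/duplications from the net query-minus-reference
#' length within the window around the site, assigned to whichever of 0
#' (wild-type) or the variant's length change is nearer (ties are
#' unassigned). Canonical-splice variants cannot be called from exonic
#' bases and return `UNASSIGNED`.
#'
#' @param aln An `aligned_reads` object.
#' @param i Read index.
#' @param variant An `hgvs_variant`.
#' @param model A `transcript_model`.
#' @param reference A [reference_seq()].
#' @param window Flanking window in nt (default 12).
#' @param min_agree Minimum fraction of window bases agreeing with the
#'   reference for a substitution call (default 0.7).
#' @return One of `"WT"`, `"MUT"`, `"UNASSIGNED"`.
#' @export
call_allele <- function(aln, i, variant, model, reference, window = 12L,
                        min_agree = 0.7) {
  if (!is.na(variant$intron_offset)) return("UNASSIGNED")
  vs <- variant_genomic_span(model, variant)
  span <- read_span(aln, i)
  lo <- vs[1L] - window
  hi <- vs[2L] + window
  if (span[1L] > lo || span[2L] < hi) return("UNASSIGNED")

  if (variant$kind == "SNV") {
    lay <- aln$layered[[i]]
    at <- function(g) substr(lay, g - aln$start0[i] + 1L, g - aln$start0[i] + 1L)
    obs <- at(vs[1L])
    win_pos <- setdiff(seq.int(lo, hi - 1L), vs[1L])
    win_obs <- vapply(win_pos, at, character(1))
    win_ref <- vapply(win_pos, function(g) ref_sub(reference, g, g + 1L),
                      character(1))
    informative <- win_obs %in% DNA_BASES
    if (!any(informative)) return("UNASSIGNED")
    agree <- mean(win_obs[informative] == win_ref[informative])
    if (agree < min_agree) return("UNASSIGNED")
    sense_ref <- variant$ref_allele
    sense_alt <- variant$alt_allele
    if (model$strand == "-") {
      sense_ref <- revcomp(sense_ref); sense_alt <- revcomp(sense_alt)
    }
    if (obs == sense_alt) return("MUT")
    if (obs == sense_ref) return("WT")
    return("UNASSIGNED")
  }

  ## indel variants: net inserted-minus-deleted length near the site
  ind <- aln$indels[[i]]
  net <- 0L
  if (length(ind$op)) {
    sel <- ind$start0 + pmax(ind$len * (ind$op == "D"), 1L) > lo &
           ind$start0 < hi
    if (any(sel)) {
      net <- sum(ifelse(ind$op[sel] == "I", ind$len[sel], -ind$len[sel]))
    }
  }
  delta_v <- switch(variant$kind, deletion = -variant$span_length,
                    duplication = variant$span_length,
                    insertion = variant$span_length)
  d_wt <- abs(net); d_mut <- abs(net - delta_v)
  if (d_mut < d_wt) "MUT" else if (d_wt < d_mut) "WT" else "UNASSIGNED"
}

## ---------------------------------------------------------------------------
## Read classification
## ---------------------------------------------------------------------------

## Intron index (transcript order) whose splice site the variant mutates.
variant_intron_index <- function(model, variant) {
  vt <- model$cds_start_t + variant$cds_pos - 1L
  k <- exon_index_of_tpos(model, vt)
  if (is.na(k)) return(NA_integer_)
  if (variant$intron_offset > 0L) k else k - 1L
}

## Is any event located at the variant's splice site?
event_at_intron <- function(model, events, intron) {
  for (e in events) {
    hit <- switch(e$type,
      intron_retention = e$exon == intron,
      cryptic_donor = e$exon == intron,          # donor of exon k = intron k
      cryptic_acceptor = e$exon == intron + 1L,  # acceptor of exon k+1
      exon_skip = e$exon == intron || e$exon == intron + 1L)
    if (isTRUE(hit)) return(TRUE)
  }
  FALSE
}

#' Classify every read as WT / PTC / RESCUE / OTHER
#'
#' For each read the splice events are detected, the allele is called
#' (exonic variants from aligned bases and indel lengths; canonical-splice
#' variants by the junction outcome at the mutated site, flagged
#' junction-inferred), the implied mature transcript is built and scanned
#' for a premature stop, and the transcript class follows: `WT` when the
#' wild-type allele shows no premature stop; `PTC` when a premature stop
#' is attributable to the variant; `RESCUE` when the mutant (or excised)
#' allele yields no premature stop; `OTHER` for unassigned alleles without
#' informative events, event-induced stops on the wild-type allele, and
#' unresolvable junctions.
#'
#' @param aln An `aligned_reads` object.
#' @param model A `transcript_model`.
#' @param reference A [reference_seq()].
#' @param variant An `hgvs_variant`.
#' @param tolerance Junction tolerance in nt (default 3).
#' @param window Allele-call window in nt (default 12).
#' @param min_agree Minimum window agreement for substitution calls.
#' @return Data frame with one row per read: `read_id`, `allele`,
#'   `events` (signature string), `transcript_class`, `reason`.
#' @export
classify_reads <- function(aln, model, reference, variant, tolerance = 3L,
                           window = 12L, min_agree = 0.7) {
  splice_variant <- !is.na(variant$intron_offset)
  v_intron <- if (splice_variant) variant_intron_index(model, variant)
              else NA_integer_
  cache <- new.env(parent = emptyenv())

  scan_cached <- function(events, with_variant) {
    key <- paste0(event_signature(events), "|", with_variant)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- tryCatch({
      mt <- mature_sequence(model, reference, events = events,
                            variant = if (with_variant) variant else NULL)
      sc <- scan_for_ptc(mt)
      list(status = sc$status, removed = mt$variant_removed)
    }, error = function(e) list(status = "error", removed = FALSE))
    cache[[key]] <- res
    res
  }

  n <- n_reads_aln(aln)
  allele <- character(n); class_ <- character(n)
  evsig <- character(n); reason <- character(n)

  for (i in seq_len(n)) {
    det <- detect_events(aln, i, model, tolerance = tolerance)
    ev <- det$events
    evsig[i] <- event_signature(ev)
    if (det$unresolvable) {
      allele[i] <- "UNASSIGNED"; class_[i] <- "OTHER"
      reason[i] <- "unresolvable_junction"
      next
    }

    if (splice_variant) {
      at_site <- event_at_intron(model, ev, v_intron)
      sc <- scan_cached(ev, FALSE)
      if (sc$status == "error") {
        allele[i] <- "UNASSIGNED"; class_[i] <- "OTHER"
        reason[i] <- "event_conflict"
        next
      }
      ## the read must span the mutated junction to be informative
      span <- read_span(aln, i)
      ig <- intron_genomic(model, v_intron)
      if (span[1L] > min(ig) || span[2L] < max(ig)) {
        allele[i] <- "UNASSIGNED"; class_[i] <- "OTHER"
        reason[i] <- "no_junction_coverage"
        next
      }
      if (at_site) {
        allele[i] <- "MUT"  # junction-inferred
        class_[i] <- if (sc$status == "ptc") "PTC" else "RESCUE"
        reason[i] <- "junction_inferred"
      } else {
        allele[i] <- "WT"   # junction-inferred
        if (sc$status == "ptc") {
          class_[i] <- "OTHER"; reason[i] <- "deleterious_event_on_wt"
        } else {
          class_[i] <- "WT"; reason[i] <- "junction_inferred"
        }
      }
      next
    }

    ## exonic variant
    removed <- events_remove_variant(model, ev, variant)
    if (removed) {
      al <- "REMOVED"
    } else {
      al <- call_allele(aln, i, variant, model, reference, window = window,
                       min_agree = min_agree)
    }
    allele[i] <- al
    if (al == "UNASSIGNED") {
      class_[i] <- "OTHER"; reason[i] <- "unassigned_allele"
      next
    }
    sc <- scan_cached(ev, al == "MUT")
    if (sc$status == "error") {
      class_[i] <- "OTHER"; reason[i] <- "event_conflict"
      next
    }
    has_ptc <- sc$status == "ptc"
    if (al == "WT") {
      if (has_ptc) {
        class_[i] <- "OTHER"; reason[i] <- "deleterious_event_on_wt"
      } else {
        class_[i] <- "WT"; reason[i] <- ""
      }
    } else {  # MUT or REMOVED
      if (has_ptc) {
        if (al == "MUT") {
          class_[i] <- "PTC"; reason[i] <- ""
        } else {
          class_[i] <- "OTHER"; reason[i] <- "event_ptc_without_variant"
        }
      } else {
        class_[i] <- "RESCUE"; reason[i] <- ""
      }
    }
  }

  data.frame(read_id = aln$read_id, allele = allele, events = evsig,
             transcript_class = class_, reason = reason,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Quantification
## ---------------------------------------------------------------------------

#' Summarize read classifications into expression fractions
#'
#' The PTC expression fraction is `n_ptc / (n_ptc + n_wt)`: 0 corresponds
#' to complete degradation of PTC transcripts and 0.5 to equal expression
#' of the PTC and wild-type alleles. The rescue fraction is
#' `n_rescue / (n_ptc + n_wt + n_rescue)`; raw counts are always reported
#' so other denominators can be recomputed.
#'
#' @param classifications Data frame from [classify_reads()].
#' @param aln Optional `aligned_reads` for event-frequency denominators.
#' @param model Optional `transcript_model` (required with `aln`).
#' @return Object of class `quant_result`: counts, fractions, and
#'   per-event frequencies over reads spanning each event's extent.
#' @export
quantify <- function(classifications, aln = NULL, model = NULL) {
  cl <- classifications$transcript_class
  n_wt <- sum(cl == "WT"); n_ptc <- sum(cl == "PTC")
  n_rescue <- sum(cl == "RESCUE"); n_other <- sum(cl == "OTHER")
  n_unassigned <- sum(classifications$allele == "UNASSIGNED")
  if (n_ptc + n_wt == 0L) {
    stop("undefined-fraction error: no WT or PTC reads")
  }
  ev_freq <- numeric(0)
  if (!is.null(aln)) {
    stopifnot(!is.null(model))
    all_ev <- unique(unlist(strsplit(classifications$events[
      nzchar(classifications$events)], ";", fixed = TRUE)))
    if (length(all_ev)) {
      base <- base_signature(all_ev)
      reps <- all_ev[!duplicated(base)]
      ev_freq <- vapply(reps, function(sig)
        tryCatch(event_frequency_sig(aln, classifications, sig, model),
                 error = function(e) NA_real_), numeric(1))
      names(ev_freq) <- base[!duplicated(base)]
    }
  }
  structure(list(
    n_wt = n_wt, n_ptc = n_ptc, n_rescue = n_rescue, n_other = n_other,
    n_unassigned = n_unassigned,
    n_reads = nrow(classifications),
    ptc_expression_fraction = n_ptc / (n_ptc + n_wt),
    rescue_fraction = n_rescue / (n_ptc + n_wt + n_rescue),
    event_frequencies = ev_freq
  ), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("Transcript quantification over", x$n_reads, "reads\n")
  cat(sprintf("  WT %d | PTC %d | RESCUE %d | OTHER %d (unassigned allele %d)\n",
              x$n_wt, x$n_ptc, x$n_rescue, x$n_other, x$n_unassigned))
  cat(sprintf("  PTC expression fraction: %.3f\n", x$ptc_expression_fraction))
  cat(sprintf("  Rescue fraction:         %.3f\n", x$rescue_fraction))
  if (length(x$event_frequencies)) {
    cat("  Event frequencies (reads spanning each event):\n")
    for (nm in names(x$event_frequencies)) {
      cat(sprintf("    %-14s %.3f\n", nm, x$event_frequencies[[nm]]))
    }
  }
  invisible(x)
}

## Genomic extent of an event given its signature parts.
event_extent <- function(model, ev) {
  ex <- exons_tx_order(model)
  if (ev$type == "exon_skip") {
    return(c(ex[ev$exon, 1L], ex[ev$exon, 2L]))
  }
  if (ev$type == "intron_retention") {
    ig <- intron_genomic(model, ev$exon)
    return(c(min(ig), max(ig)))
  }
  ## cryptic: the canonical boundary +- the shift
  sp <- if (ev$type == "cryptic_donor") {
    if (model$strand == "+") ex[ev$exon, 2L] else ex[ev$exon, 1L]
  } else {
    if (model$strand == "+") ex[ev$exon, 1L] else ex[ev$exon, 2L]
  }
  d <- abs(ev$delta)
  c(sp - d, sp + d)
}

parse_event_signature <- function(sig) {
  parts <- strsplit(sig, ":", fixed = TRUE)[[1L]]
  switch(parts[1L],
    skip = splice_event("exon_skip", as.integer(parts[2L])),
    crypD = splice_event("cryptic_donor", as.integer(parts[2L]),
                         delta = as.integer(parts[3L])),
    crypA = splice_event("cryptic_acceptor", as.integer(parts[2L]),
                         delta = as.integer(parts[3L])),
    ret = splice_event("intron_retention", as.integer(parts[2L]),
                       retained = if (parts[3L] == "full") NA_integer_
                                  else as.integer(parts[3L])),
    stop("bad event signature: ", sig))
}

event_frequency_sig <- function(aln, classifications, sig, model) {
  ev <- parse_event_signature(sig)
  ext <- event_extent(model, ev)
  spans <- t(vapply(seq_len(n_reads_aln(aln)), function(i) read_span(aln, i),
                    integer(2)))
  spanning <- spans[, 1L] <= ext[1L] & spans[, 2L] >= ext[2L]
  if (!any(spanning)) {
    stop("undefined-fraction error: no reads span event ", sig)
  }
  has_base <- function(s) vapply(strsplit(s, ";", fixed = TRUE), function(p)
    any(base_signature(p) == base_signature(sig)), logical(1))
  has <- has_base(classifications$events) & nzchar(classifications$events)
  sum(has & spanning) / sum(spanning)
}

## Collapse a signature to type:index (retention lengths vary read to read).
base_signature <- function(sigs) {
  vapply(sigs, function(s) {
    if (!nzchar(s)) return("")
    p <- strsplit(s, ":", fixed = TRUE)[[1L]]
    paste(p[1L], p[2L], sep = ":")
  }, character(1), USE.NAMES = FALSE)
}

#' Frequency of one splice event among reads spanning its extent
#'
#' Allele-agnostic: the denominator is every read whose alignment span
#' covers the event's full genomic extent.
#'
#' @param aln An `aligned_reads` object.
#' @param classifications Data frame from [classify_reads()].
#' @param event A [splice_event()].
#' @param model A `transcript_model`.
#' @return Fraction in `[0, 1]`.
#' @export
event_frequency <- function(aln, classifications, event, model) {
  event_frequency_sig(aln, classifications, format(event), model)
}
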