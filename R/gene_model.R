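#' @importFrom stats rbinom runif setNames pchisq qnorm
#' @importFrom utils read.delim write.table head tail
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")

## ---------------------------------------------------------------------------
## ReferenceSeq
## ---------------------------------------------------------------------------

#' Create a reference sequence
#'
#' A minimal container for a named nucleotide sequence used as the alignment
#' and annotation target for a single-transcript gene model.
#'
#' @param name Sequence (chromosome/contig) name.
#' @param sequence Uppercase nucleotide string over `A,C,G,T,N`.
#' @return An object of class `reference_seq` with fields `name` and
#'   `sequence`.
#' @export
reference_seq <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("reference sequence must be non-empty")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference sequence contains characters outside {A,C,G,T,N}")
  }
  structure(list(name = name, sequence = sequence), class = "reference_seq")
}

#' Read a reference sequence from a FASTA file
#'
#' @param path Path to a single- or multi-record FASTA file.
#' @param name Optional record name; required when the file holds more than
#'   one record.
#' @return A [reference_seq()] object.
#' @export
read_reference_fasta <- function(path, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.null(name)) {
    if (length(seqs) != 1L) {
      stop("FASTA has ", length(seqs), " records; supply `name`")
    }
    idx <- 1L
  } else {
    idx <- match(name, ids)
    if (is.na(idx)) stop("no FASTA record named '", name, "'")
  }
  reference_seq(ids[idx], as.character(seqs[[idx]]))
}

ref_length <- function(reference) nchar(reference$sequence)

## Extract reference subsequence, 0-based half-open coordinates.
ref_sub <- function(reference, start0, end0) {
  substr(reference$sequence, start0 + 1L, end0)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## ---------------------------------------------------------------------------
## TranscriptModel
## ---------------------------------------------------------------------------

#' Build a single-transcript gene model
#'
#' Computes transcript coordinates (5'->3', reverse-complement traversal on
#' the minus strand) for an exon chain and validates the coding region
#' against the reference: the CDS must begin with `ATG`, end with a stop
#' codon, have length divisible by three, and contain no `N`.
#'
#' All internal coordinates are 0-based half-open; 1-based conventions are
#' confined to I/O boundaries (HGVS, SAM, BED display).
#'
#' @param reference A [reference_seq()].
#' @param exons Two-column integer matrix of genomic exon intervals
#'   (0-based half-open), ascending and non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @param cds_genomic Length-2 integer vector: genomic interval (0-based
#'   half-open) spanned by the coding region. Its ends must fall inside
#'   exons.
#' @return An object of class `transcript_model` with fields
#'   `reference_name`, `strand`, `exons`, `cds_start_t`, `cds_end_t`.
#' @export
build_transcript <- function(reference, exons, strand = "+", cds_genomic = NULL) {
  stopifnot(inherits(reference, "reference_seq"))
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L || nrow(exons) < 1L) {
    stop("structural error: exons must be a non-empty two-column matrix")
  }
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, 1L] >= exons[, 2L])) {
    stop("structural error: empty or inverted exon interval")
  }
  if (any(exons[, 1L] < 0L) || any(exons[, 2L] > ref_length(reference))) {
    stop("structural error: exon outside reference bounds")
  }
  if (nrow(exons) > 1L) {
    o <- order(exons[, 1L])
    exons <- exons[o, , drop = FALSE]
    if (any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
      stop("structural error: overlapping exons")
    }
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")

  model <- structure(
    list(reference_name = reference$name, strand = strand, exons = exons,
         cds_start_t = NA_integer_, cds_end_t = NA_integer_),
    class = "transcript_model"
  )

  total <- sum(exons[, 2L] - exons[, 1L])
  if (is.null(cds_genomic)) {
    cds_genomic <- c(exons[1L, 1L], exons[nrow(exons), 2L])
  }
  cs <- genomic_to_transcript(model, cds_genomic[1L])
  ce <- genomic_to_transcript(model, cds_genomic[2L] - 1L)
  if (is.na(cs) || is.na(ce)) {
    stop("structural error: CDS span does not fall inside exons")
  }
  tt <- sort(unname(c(cs, ce)))
  model$cds_start_t <- tt[1L]
  model$cds_end_t <- tt[2L] + 1L
  if (model$cds_start_t < 0L || model$cds_end_t > total ||
      model$cds_start_t >= model$cds_end_t) {
    stop("structural error: invalid CDS transcript span")
  }
  if ((model$cds_end_t - model$cds_start_t) %% 3L != 0L) {
    stop("model-validation error: CDS length not divisible by 3")
  }
  cds <- cds_sequence(model, reference)
  if (grepl("N", cds, fixed = TRUE)) {
    stop("model-validation error: N base inside CDS")
  }
  if (substr(cds, 1L, 3L) != "ATG") {
    stop("model-validation error: CDS does not start with ATG")
  }
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last %in% STOP_CODONS) {
    stop("model-validation error: CDS does not end in a stop codon")
  }
  model
}

n_exons <- function(model) nrow(model$exons)

exon_lengths <- function(model) {
  w <- model$exons[, 2L] - model$exons[, 1L]
  if (model$strand == "-") rev(w) else w
}

## Exons in transcript (5'->3') order as genomic intervals.
exons_tx_order <- function(model) {
  ex <- model$exons
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

#' Map a transcript coordinate to a genomic coordinate
#'
#' @param model A `transcript_model`.
#' @param tpos 0-based transcript position.
#' @return 0-based genomic position, or `NA` if out of range.
#' @export
transcript_to_genomic <- function(model, tpos) {
  tpos <- unname(tpos)
  vapply(tpos, function(t) {
    if (is.na(t) || t < 0L) return(NA_integer_)
    ex <- exons_tx_order(model)
    off <- as.integer(t)
    for (i in seq_len(nrow(ex))) {
      w <- ex[i, 2L] - ex[i, 1L]
      if (off < w) {
        return(if (model$strand == "+") ex[i, 1L] + off else ex[i, 2L] - 1L - off)
      }
      off <- off - w
    }
    NA_integer_
  }, integer(1))
}

#' Map a genomic coordinate to a transcript coordinate
#'
#' Total function: intronic or out-of-range positions map to `NA`.
#'
#' @param model A `transcript_model`.
#' @param gpos 0-based genomic position.
#' @return 0-based transcript position or `NA`.
#' @export
genomic_to_transcript <- function(model, gpos) {
  gpos <- unname(gpos)
  vapply(gpos, function(g) {
    if (is.na(g)) return(NA_integer_)
    ex <- exons_tx_order(model)
    cum <- 0L
    for (i in seq_len(nrow(ex))) {
      if (g >= ex[i, 1L] && g < ex[i, 2L]) {
        off <- if (model$strand == "+") g - ex[i, 1L] else ex[i, 2L] - 1L - g
        return(cum + as.integer(off))
      }
      cum <- cum + (ex[i, 2L] - ex[i, 1L])
    }
    NA_integer_
  }, integer(1))
}

## Canonical mature transcript sequence (no events, no variant).
canonical_sequence <- function(model, reference) {
  ex <- model$exons
  parts <- vapply(seq_len(nrow(ex)), function(i) {
    ref_sub(reference, ex[i, 1L], ex[i, 2L])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}

cds_sequence <- function(model, reference) {
  s <- canonical_sequence(model, reference)
  substr(s, model$cds_start_t + 1L, model$cds_end_t)
}

## Index (in transcript order, 1-based) of the exon containing transcript
## position tpos; NA when out of range.
exon_index_of_tpos <- function(model, tpos) {
  if (is.na(tpos) || tpos < 0L) return(NA_integer_)
  cum <- cumsum(exon_lengths(model))
  i <- which(tpos < cum)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

## Transcript-coordinate span [start, end) of exon k (transcript order).
exon_tx_span <- function(model, k) {
  lens <- exon_lengths(model)
  start <- if (k == 1L) 0L else sum(lens[seq_len(k - 1L)])
  c(start, start + lens[k])
}

#' Read a single-transcript gene model from a BED12 file
#'
#' One BED12 line defines the transcript: `blockStarts`/`blockSizes` give
#' the exons, `thickStart`/`thickEnd` the CDS, and the strand column is
#' honored.
#'
#' @param path BED12 file path.
#' @param reference A [reference_seq()] used to validate the CDS.
#' @return A `transcript_model`.
#' @export
read_transcript_bed12 <- function(path, reference) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) != 1L) stop("BED12 must contain exactly one transcript line")
  bl <- gr$blocks[[1L]]
  chrom_start <- GenomicRanges::start(gr) - 1L  # back to 0-based
  ex <- cbind(chrom_start + IRanges::start(bl) - 1L,
              chrom_start + IRanges::end(bl))
  thick <- gr$thick
  cds <- c(IRanges::start(thick) - 1L, IRanges::end(thick))
  build_transcript(reference, ex,
                   strand = as.character(GenomicRanges::strand(gr)),
                   cds_genomic = cds)
}

#' Write a transcript model as one BED12 line
#'
#' @param model A `transcript_model`.
#' @param path Output file path.
#' @param name Feature name for column 4.
#' @return Invisibly, `path`.
#' @export
write_transcript_bed12 <- function(model, path, name = "transcript") {
  ex <- model$exons
  chrom_start <- ex[1L, 1L]
  chrom_end <- ex[nrow(ex), 2L]
  cds_g <- range(transcript_to_genomic(
    model, c(model$cds_start_t, model$cds_end_t - 1L)))
  line <- paste(
    model$reference_name, chrom_start, chrom_end, name, 0L, model$strand,
    cds_g[1L], cds_g[2L] + 1L, "0,0,0", nrow(ex),
    paste0(paste(ex[, 2L] - ex[, 1L], collapse = ","), ","),
    paste0(paste(ex[, 1L] - chrom_start, collapse = ","), ","),
    sep = "\t"
  )
  writeLines(line, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Splice events
## ---------------------------------------------------------------------------

#' Describe a deviation from the canonical junction chain
#'
#' @param type One of `"exon_skip"`, `"cryptic_donor"`, `"cryptic_acceptor"`,
#'   `"intron_retention"`.
#' @param exon 1-based exon index in transcript order (for skips and cryptic
#'   sites) or the intron index (intron k follows exon k) for retention.
#' @param delta Signed exon-length change in nt for cryptic sites
#'   (negative = boundary moved into the exon, truncating it).
#' @param retained Retained intron length in nt for `intron_retention`;
#'   `NA` means the complete intron.
#' @return An object of class `splice_event`.
#' @export
splice_event <- function(type, exon, delta = NA_integer_,
                         retained = NA_integer_) {
  type <- match.arg(type, c("exon_skip", "cryptic_donor", "cryptic_acceptor",
                            "intron_retention"))
  if (type %in% c("cryptic_donor", "cryptic_acceptor")) {
    if (is.na(delta) || delta == 0L) {
      stop("cryptic splice event requires a nonzero delta")
    }
  }
  structure(list(type = type, exon = as.integer(exon),
                 delta = as.integer(delta), retained = as.integer(retained)),
            class = "splice_event")
}

#' @export
format.splice_event <- function(x, ...) {
  switch(x$type,
    exon_skip = sprintf("skip:%d", x$exon),
    cryptic_donor = sprintf("crypD:%d:%+d", x$exon, x$delta),
    cryptic_acceptor = sprintf("crypA:%d:%+d", x$exon, x$delta),
    intron_retention = sprintf("ret:%d:%s", x$exon,
                               ifelse(is.na(x$retained), "full", x$retained))
  )
}

#' @export
print.splice_event <- function(x, ...) {
  cat("<splice_event ", format(x), ">\n", sep = "")
  invisible(x)
}

event_signature <- function(events) {
  if (length(events) == 0L) return("")
  paste(sort(vapply(events, format, character(1))), collapse = ";")
}

## Intron interval (genomic, 0-based half-open) following transcript exon k.
intron_genomic <- function(model, k) {
  ex <- exons_tx_order(model)
  if (k < 1L || k >= nrow(ex)) stop("no intron after exon ", k)
  if (model$strand == "+") c(ex[k, 2L], ex[k + 1L, 1L])
  else c(ex[k + 1L, 2L], ex[k, 1L])  # transcript-order: donor side on the left end? no
}

intron_length <- function(model, k) {
  ex <- exons_tx_order(model)
  if (model$strand == "+") ex[k + 1L, 1L] - ex[k, 2L]
  else ex[k, 1L] - ex[k + 1L, 2L]
}

## Check for pairwise-incompatible events (same boundary edited twice).
## Each event claims boundary resources ("exon:side" tokens); two events
## claiming the same token conflict.
check_event_compat <- function(events, model) {
  claims <- list()
  for (e in events) {
    tok <- switch(e$type,
      exon_skip = c(paste0(e$exon, ":5"), paste0(e$exon, ":3")),
      cryptic_donor = paste0(e$exon, ":3"),
      cryptic_acceptor = paste0(e$exon, ":5"),
      intron_retention = c(paste0(e$exon, ":3"),
                           if (is.na(e$retained) ||
                               e$retained >= intron_length(model, e$exon))
                             paste0(e$exon + 1L, ":5"))
    )
    claims <- c(claims, list(tok))
  }
  all_tok <- unlist(claims)
  if (anyDuplicated(all_tok)) {
    stop("event-conflict error: incompatible splice events (",
         paste(unique(all_tok[duplicated(all_tok)]), collapse = ", "), ")")
  }
  invisible(TRUE)
}

## Apply events to the exon chain. Returns a data.frame of blocks in
## transcript order (genomic 0-based half-open).
apply_events_to_blocks <- function(model, events) {
  check_event_compat(events, model)
  ex <- exons_tx_order(model)
  n <- nrow(ex)
  gs <- ex[, 1L]; ge <- ex[, 2L]
  keep <- rep(TRUE, n)
  plus <- model$strand == "+"
  ## boundary shifts first, then retention merges, then skips, so that a
  ## merge or removal sees already-shifted boundaries
  prio <- vapply(events, function(e) switch(e$type,
    cryptic_donor = 1L, cryptic_acceptor = 1L,
    intron_retention = 2L, exon_skip = 3L), integer(1))
  events <- events[order(prio)]
  for (e in events) {
    k <- e$exon
    if (e$type == "exon_skip") {
      if (k < 1L || k > n) stop("exon_skip index out of range")
      keep[k] <- FALSE
    } else if (e$type == "cryptic_donor") {
      ## donor = transcript-3' boundary of exon k
      if (plus) ge[k] <- ge[k] + e$delta else gs[k] <- gs[k] - e$delta
    } else if (e$type == "cryptic_acceptor") {
      ## acceptor = transcript-5' boundary of exon k
      if (plus) gs[k] <- gs[k] - e$delta else ge[k] <- ge[k] + e$delta
    } else if (e$type == "intron_retention") {
      ilen <- intron_length(model, k)
      len <- if (is.na(e$retained)) ilen else min(e$retained, ilen)
      if (len >= ilen) {
        ## complete retention: merge exons k and k+1
        if (plus) { ge[k] <- ge[k + 1L] } else { gs[k] <- gs[k + 1L] }
        keep[k + 1L] <- FALSE
      } else {
        ## partial retention from the donor side
        if (plus) ge[k] <- ge[k] + len else gs[k] <- gs[k] - len
      }
    }
  }
  blocks <- data.frame(gstart = gs[keep], gend = ge[keep])
  if (any(blocks$gend <= blocks$gstart)) {
    stop("event-conflict error: event empties or inverts an exon")
  }
  ## transcript order must remain strictly progressing
  if (nrow(blocks) > 1L) {
    if (plus) {
      if (any(diff(blocks$gstart) <= 0) ||
          any(blocks$gstart[-1L] < blocks$gend[-nrow(blocks)])) {
        stop("event-conflict error: edited blocks overlap")
      }
    } else {
      if (any(diff(blocks$gend) >= 0) ||
          any(blocks$gend[-1L] > blocks$gstart[-nrow(blocks)])) {
        stop("event-conflict error: edited blocks overlap")
      }
    }
  }
  blocks
}

## Position of genomic coordinate g in the edited transcript; NA if removed.
edited_tpos_of_genomic <- function(blocks, g, strand) {
  cum <- 0L
  for (i in seq_len(nrow(blocks))) {
    s <- blocks$gstart[i]; e <- blocks$gend[i]
    if (!is.na(g) && g >= s && g < e) {
      off <- if (strand == "+") g - s else e - 1L - g
      return(cum + off)
    }
    cum <- cum + (e - s)
  }
  NA_integer_
}

## ---------------------------------------------------------------------------
## MatureTranscript
## ---------------------------------------------------------------------------

#' Build the mature transcript implied by a splice-event set and a variant
#'
#' Events are applied first (exon removal, boundary shifts, retained-intron
#' insertion), then the variant's exonic edit is applied if its CDS position
#' survives the events; when an event deletes the variant site the result is
#' flagged `variant_removed`. Intronic variants (canonical splice or splice
#' region) carry no exonic edit; their consequence is represented by the
#' event set.
#'
#' @param model A `transcript_model`.
#' @param reference A [reference_seq()].
#' @param events List of [splice_event()] objects (mutually compatible).
#' @param variant Optional parsed coding-HGVS variant (see [parse_chgvs()]).
#' @return An object of class `mature_transcript`: fields `sequence`,
#'   `cds_start_t`, `canonical_end_t` (position just past the canonical
#'   terminal codon in the edited transcript, `NA` if removed),
#'   `variant_removed`, `variant_applied`, and `provenance`.
#' @export
mature_sequence <- function(model, reference, events = list(), variant = NULL) {
  if (inherits(events, "splice_event")) events <- list(events)
  blocks <- apply_events_to_blocks(model, events)
  parts <- vapply(seq_len(nrow(blocks)), function(i) {
    s <- ref_sub(reference, blocks$gstart[i], blocks$gend[i])
    if (model$strand == "-") revcomp(s) else s
  }, character(1))
  seq <- paste(parts, collapse = "")

  map_canonical <- function(tpos) {
    g <- transcript_to_genomic(model, tpos)
    edited_tpos_of_genomic(blocks, g, model$strand)
  }

  ## first surviving CDS base defines the translation start
  cds_start_new <- NA_integer_
  for (t in seq.int(model$cds_start_t, model$cds_end_t - 1L)) {
    p <- map_canonical(t)
    if (!is.na(p)) { cds_start_new <- p; break }
  }
  if (is.na(cds_start_new)) {
    stop("degenerate-transcript error: no CDS base survives the events")
  }
  last_cds <- map_canonical(model$cds_end_t - 1L)
  canonical_end <- if (is.na(last_cds)) NA_integer_ else last_cds + 1L

  variant_removed <- FALSE
  variant_applied <- FALSE
  if (!is.null(variant) && is.na(variant$intron_offset)) {
    vt <- model$cds_start_t + variant$cds_pos - 1L  # canonical tpos of anchor
    span <- if (variant$kind %in% c("deletion", "duplication"))
      variant$span_length else 1L
    pos_edit <- vapply(seq.int(vt, vt + span - 1L), map_canonical, integer(1))
    if (anyNA(pos_edit)) {
      variant_removed <- TRUE
    } else {
      p <- pos_edit[1L]  # 0-based position of first affected base
      shift_after <- p
      delta <- 0L
      if (variant$kind == "SNV") {
        obs <- substr(seq, p + 1L, p + 1L)
        if (nzchar(variant$ref_allele) && obs != variant$ref_allele) {
          warning("reference base ", obs, " does not match HGVS ref ",
                  variant$ref_allele, " at c.", variant$cds_pos)
        }
        substr(seq, p + 1L, p + 1L) <- variant$alt_allele
      } else if (variant$kind == "deletion") {
        seq <- paste0(substr(seq, 1L, p), substr(seq, p + span + 1L, nchar(seq)))
        delta <- -span
      } else if (variant$kind == "duplication") {
        dup <- substr(seq, p + 1L, p + span)
        seq <- paste0(substr(seq, 1L, p + span), dup,
                      substr(seq, p + span + 1L, nchar(seq)))
        shift_after <- p + span
        delta <- span
      } else if (variant$kind == "insertion") {
        seq <- paste0(substr(seq, 1L, p + 1L), variant$alt_allele,
                      substr(seq, p + 2L, nchar(seq)))
        shift_after <- p + 1L
        delta <- variant$span_length
      }
      if (delta != 0L) {
        if (!is.na(canonical_end) && canonical_end > shift_after) {
          canonical_end <- canonical_end + delta
          if (variant$kind == "deletion" &&
              canonical_end <= shift_after) canonical_end <- NA_integer_
        }
        if (cds_start_new > shift_after) cds_start_new <- cds_start_new + delta
      }
      variant_applied <- TRUE
    }
  }

  structure(
    list(sequence = seq, cds_start_t = cds_start_new,
         canonical_end_t = canonical_end,
         variant_removed = variant_removed,
         variant_applied = variant_applied,
         blocks = blocks, strand = model$strand,
         provenance = list(events = events, variant = variant)),
    class = "mature_transcript"
  )
}

#' @export
print.mature_transcript <- function(x, ...) {
  cat("<mature_transcript ", nchar(x$sequence), " nt, cds_start ",
      x$cds_start_t,
      if (x$variant_removed) ", variant removed by events" else "",
      ">\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## PTC scan
## ---------------------------------------------------------------------------

#' Locate the first premature termination codon of a mature transcript
#'
#' Translates from `cds_start_t` in steps of three and reports the codon
#' index (1-based) of the first in-frame stop strictly upstream of the
#' canonical terminal codon. A stop at the canonical terminal position is
#' not premature; translation running off the 3' end without any stop is
#' flagged `nonstop`; a stop landing downstream of the canonical terminus
#' (possible after frame shifts near the 3' end) is flagged `readthrough`.
#'
#' @param mature A `mature_transcript` from [mature_sequence()].
#' @return List with `ptc_codon` (integer or `NA`) and `status`, one of
#'   `"ptc"`, `"canonical"`, `"nonstop"`, `"readthrough"`.
#' @export
scan_for_ptc <- function(mature) {
  stopifnot(inherits(mature, "mature_transcript"))
  seq <- mature$sequence
  start <- mature$cds_start_t
  len <- nchar(seq)
  if (len - start < 3L) {
    stop("degenerate-transcript error: CDS shorter than 3 nt after edits")
  }
  canon_end <- mature$canonical_end_t
  if (is.na(canon_end)) {
    ## canonical stop removed: terminal codon = last complete codon
    canon_end <- start + ((len - start) %/% 3L) * 3L
  }
  i <- start
  while (i + 3L <= len) {
    codon <- substr(seq, i + 1L, i + 3L)
    if (codon %in% STOP_CODONS) {
      if (i == canon_end - 3L) {
        return(list(ptc_codon = NA_integer_, status = "canonical"))
      }
      if (i > canon_end - 3L) {
        return(list(ptc_codon = NA_integer_, status = "readthrough"))
      }
      return(list(ptc_codon = (i - start) %/% 3L + 1L, status = "ptc"))
    }
    i <- i + 3L
  }
  list(ptc_codon = NA_integer_, status = "nonstop")
}

## ---------------------------------------------------------------------------
## Frame arithmetic
## ---------------------------------------------------------------------------

## Signed CDS-length change contributed by one event.
event_cds_delta <- function(model, event) {
  cds <- c(model$cds_start_t, model$cds_end_t)
  if (event$type == "exon_skip") {
    sp <- exon_tx_span(model, event$exon)
    ov <- min(sp[2L], cds[2L]) - max(sp[1L], cds[1L])
    return(-max(0L, ov))
  }
  if (event$type %in% c("cryptic_donor", "cryptic_acceptor")) {
    sp <- exon_tx_span(model, event$exon)
    b <- if (event$type == "cryptic_donor") sp[2L] else sp[1L]
    if (b >= cds[1L] && b <= cds[2L]) return(event$delta) else return(0L)
  }
  if (event$type == "intron_retention") {
    sp <- exon_tx_span(model, event$exon)  # donor boundary of exon k
    len <- if (is.na(event$retained)) intron_length(model, event$exon)
           else min(event$retained, intron_length(model, event$exon))
    if (sp[2L] >= cds[1L] && sp[2L] <= cds[2L]) return(as.integer(len))
    return(0L)
  }
  0L
}

variant_cds_delta <- function(variant) {
  if (is.null(variant) || !is.na(variant$intron_offset)) return(0L)
  switch(variant$kind,
    SNV = 0L,
    deletion = -variant$span_length,
    duplication = variant$span_length,
    insertion = variant$span_length
  )
}

#' Net coding-length change of an event set plus a variant
#'
#' @param model A `transcript_model`.
#' @param events List of [splice_event()] objects.
#' @param variant Optional parsed variant.
#' @return List with `delta` (signed nt) and `in_frame`
#'   (`delta %% 3 == 0`).
#' @export
frame_delta <- function(model, events = list(), variant = NULL) {
  if (inherits(events, "splice_event")) events <- list(events)
  d <- sum(vapply(events, function(e) event_cds_delta(model, e), integer(1)),
           variant_cds_delta(variant))
  list(delta = as.integer(d), in_frame = (d %% 3L) == 0L)
}
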