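## Coding-HGVS parsing and mutation-taxonomy classification.
##
## The grammar covers the forms used for PTC-class mutations in targeted
## resequencing reports: substitutions (exonic and intronic), deletions,
## duplications and insertions, with 1-based CDS coordinates. HGVS
## 3'-normalization is assumed already applied to inputs.

MINUS_CHARS <- "[-−–]"  # ASCII hyphen, minus sign, en-dash

#' Parse a coding-HGVS mutation string
#'
#' Accepts `c.N>M` substitutions (with optional intronic offsets written
#' with either an ASCII hyphen or a typographic minus), `c.N_Mdel[SEQ]`,
#' `c.Ndel[SEQ]`, `c.N_Mdup[SEQ]`, `c.Ndup[SEQ]` and `c.N_MinsSEQ`.
#' Whitespace is ignored.
#'
#' @param s A coding-HGVS string beginning with `"c."`.
#' @param protein_label Optional protein-level label (e.g. `"p.Trp69*"`)
#'   carried along for grammar classification.
#' @return An object of class `hgvs_variant` with fields `raw`, `kind`
#'   (`SNV`, `deletion`, `duplication`, `insertion`), `cds_pos` (1-based
#'   CDS position of the first affected base, or the anchor base for
#'   intronic variants), `intron_offset` (signed integer or `NA`),
#'   `span_length`, `ref_allele`, `alt_allele`, `protein_label`.
#' @export
parse_chgvs <- function(s, protein_label = NA_character_) {
  stopifnot(is.character(s), length(s) == 1L)
  raw <- s
  s <- gsub("\\s+", "", s)
  s <- gsub(MINUS_CHARS, "-", s)
  if (!startsWith(s, "c.")) {
    stop("parse error: expected 'c.' prefix in '", raw, "'")
  }
  body <- substr(s, 3L, nchar(s))

  num <- "([0-9]+)"
  off <- "([+-][0-9]+)?"

  mk <- function(kind, cds_pos, intron_offset = NA_integer_, span = 1L,
                 ref = "", alt = "") {
    if (cds_pos < 1L) stop("parse error: cds position must be >= 1")
    structure(list(raw = raw, kind = kind, cds_pos = as.integer(cds_pos),
                   intron_offset = as.integer(intron_offset),
                   span_length = as.integer(span),
                   ref_allele = ref, alt_allele = alt,
                   protein_label = protein_label),
              class = "hgvs_variant")
  }

  ## substitution: cN[+-k]R>A
  m <- regmatches(body, regexec(paste0("^", num, off, "([ACGT])>([ACGT])$"), body))[[1L]]
  if (length(m)) {
    offv <- if (nzchar(m[3L])) as.integer(m[3L]) else NA_integer_
    return(mk("SNV", m[2L], offv, 1L, m[4L], m[5L]))
  }
  ## range del/dup: cN_M(del|dup)[SEQ]
  m <- regmatches(body, regexec(paste0("^", num, "_", num,
                                       "(del|dup)([ACGT]*)$"), body))[[1L]]
  if (length(m)) {
    p1 <- as.integer(m[2L]); p2 <- as.integer(m[3L])
    if (p2 < p1) stop("parse error: inverted range in '", raw, "'")
    span <- p2 - p1 + 1L
    seq <- m[5L]
    if (nzchar(seq) && nchar(seq) != span) {
      stop("parse error: ", m[4L], " sequence length ", nchar(seq),
           " does not match range ", span, " in '", raw, "'")
    }
    kind <- if (m[4L] == "del") "deletion" else "duplication"
    return(mk(kind, p1, NA_integer_, span, seq, ""))
  }
  ## single-base del/dup: cN(del|dup)[SEQ]
  m <- regmatches(body, regexec(paste0("^", num, "(del|dup)([ACGT]*)$"),
                                body))[[1L]]
  if (length(m)) {
    seq <- m[4L]
    if (nzchar(seq) && nchar(seq) != 1L) {
      stop("parse error: single-position ", m[3L], " with multi-base ",
           "sequence in '", raw, "'")
    }
    kind <- if (m[3L] == "del") "deletion" else "duplication"
    return(mk(kind, m[2L], NA_integer_, 1L, seq, ""))
  }
  ## insertion: cN_MinsSEQ (M must be N+1)
  m <- regmatches(body, regexec(paste0("^", num, "_", num, "ins([ACGT]+)$"),
                                body))[[1L]]
  if (length(m)) {
    p1 <- as.integer(m[2L]); p2 <- as.integer(m[3L])
    if (p2 != p1 + 1L) {
      stop("parse error: insertion flanks must be adjacent in '", raw, "'")
    }
    return(mk("insertion", p1, NA_integer_, nchar(m[4L]), "", m[4L]))
  }
  stop("parse error: unrecognized coding-HGVS token '", body, "'")
}

#' Serialize a parsed variant back to normalized coding-HGVS
#'
#' @param v An `hgvs_variant`.
#' @return A normalized coding-HGVS string (ASCII hyphen offsets).
#' @export
format_chgvs <- function(v) {
  stopifnot(inherits(v, "hgvs_variant"))
  pos <- as.character(v$cds_pos)
  if (!is.na(v$intron_offset)) {
    pos <- paste0(pos, sprintf("%+d", v$intron_offset))
  }
  switch(v$kind,
    SNV = paste0("c.", pos, v$ref_allele, ">", v$alt_allele),
    deletion = if (v$span_length == 1L)
      paste0("c.", pos, "del", v$ref_allele)
    else paste0("c.", pos, "_", v$cds_pos + v$span_length - 1L, "del",
                v$ref_allele),
    duplication = if (v$span_length == 1L)
      paste0("c.", pos, "dup", v$ref_allele)
    else paste0("c.", pos, "_", v$cds_pos + v$span_length - 1L, "dup",
                v$ref_allele),
    insertion = paste0("c.", pos, "_", v$cds_pos + 1L, "ins", v$alt_allele)
  )
}

#' @export
print.hgvs_variant <- function(x, ...) {
  cat("<hgvs_variant ", format_chgvs(x), " (", x$kind, ")>\n", sep = "")
  invisible(x)
}

#' Codon index affected by a CDS position
#'
#' @param cds_pos 1-based CDS nucleotide position(s).
#' @return 1-based codon index: `floor((cds_pos - 1)/3) + 1`.
#' @export
affected_codon <- function(cds_pos) {
  stopifnot(all(is.na(cds_pos) | cds_pos >= 1L))
  as.integer((cds_pos - 1L) %/% 3L + 1L)
}

consequence_call <- function(category, affected_codon = NA_integer_,
                             ptc_codon = NA_integer_,
                             frame_delta = NA_integer_) {
  structure(list(category = category,
                 affected_codon = as.integer(affected_codon),
                 ptc_codon = as.integer(ptc_codon),
                 frame_delta = as.integer(frame_delta)),
            class = "consequence_call")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat("<consequence_call ", x$category,
      if (!is.na(x$ptc_codon)) paste0(", PTC at codon ", x$ptc_codon) else "",
      ">\n", sep = "")
  invisible(x)
}

#' Categories counted as PTC-introducing
#' @keywords internal
PTC_CATEGORIES <- c("frameshift", "nonsense",
                    "splice_canonical_donor", "splice_canonical_acceptor")

#' Classify a parsed variant from its grammar alone
#'
#' Intronic offsets of +1/+2 are canonical donor mutations and -1/-2
#' canonical acceptor mutations; larger offsets are splice-region. Exonic
#' indels are frameshift or in-frame by span modulo 3. Exonic
#' substitutions are `undetermined` unless a protein label ending in `*`
#' (nonsense) or `fs` (frameshift) resolves them.
#'
#' @param v An `hgvs_variant`.
#' @return A `consequence_call` with fields `category`, `affected_codon`,
#'   `ptc_codon`, `frame_delta`.
#' @export
classify_by_grammar <- function(v) {
  stopifnot(inherits(v, "hgvs_variant"))
  if (!is.na(v$intron_offset)) {
    o <- v$intron_offset
    cat_ <- if (o %in% c(1L, 2L)) "splice_canonical_donor"
            else if (o %in% c(-1L, -2L)) "splice_canonical_acceptor"
            else "splice_region"
    return(consequence_call(cat_))
  }
  cod <- affected_codon(v$cds_pos)
  if (v$kind %in% c("deletion", "duplication", "insertion")) {
    delta <- variant_cds_delta(v)
    if (v$span_length %% 3L != 0L) {
      return(consequence_call("frameshift", cod, frame_delta = delta))
    }
    return(consequence_call("inframe_indel", cod, frame_delta = delta))
  }
  ## exonic SNV: decide from the protein label when one is supplied
  lab <- v$protein_label
  if (!is.na(lab) && nzchar(lab)) {
    if (grepl("(\\*|Ter)$", lab)) {
      return(consequence_call("nonsense", cod, ptc_codon = cod,
                              frame_delta = 0L))
    }
    if (grepl("fs\\*?[0-9]*$", lab)) {
      return(consequence_call("frameshift", cod))
    }
  }
  consequence_call("undetermined", cod, frame_delta = 0L)
}

#' Classify a variant against the transcript sequence
#'
#' Applies the variant to the mature transcript, translates, and resolves
#' grammar-undetermined substitutions into nonsense, missense or
#' synonymous; for indels the first premature stop of the shifted frame is
#' located. Intronic variants fall back to the grammar classification
#' (splicing outcomes are observed from reads, not predicted from
#' sequence).
#'
#' @param v An `hgvs_variant`.
#' @param model A `transcript_model`.
#' @param reference A [reference_seq()].
#' @return A `consequence_call`.
#' @export
classify_with_sequence <- function(v, model, reference) {
  g <- classify_by_grammar(v)
  if (!is.na(v$intron_offset)) return(g)
  cds_len <- model$cds_end_t - model$cds_start_t
  if (v$cds_pos > cds_len) {
    stop("coordinate error: c.", v$cds_pos, " outside the ", cds_len,
         " nt CDS")
  }
  mt <- mature_sequence(model, reference, events = list(), variant = v)
  scan <- scan_for_ptc(mt)
  cod <- affected_codon(v$cds_pos)
  if (v$kind == "SNV") {
    if (scan$status == "ptc" && scan$ptc_codon == cod) {
      return(consequence_call("nonsense", cod, ptc_codon = cod,
                              frame_delta = 0L))
    }
    ref_cds <- cds_sequence(model, reference)
    alt_cds <- substr(mt$sequence, mt$cds_start_t + 1L, nchar(mt$sequence))
    ref_codon <- substr(ref_cds, (cod - 1L) * 3L + 1L, cod * 3L)
    alt_codon <- substr(alt_cds, (cod - 1L) * 3L + 1L, cod * 3L)
    ref_aa <- as.character(Biostrings::GENETIC_CODE[ref_codon])
    alt_aa <- as.character(Biostrings::GENETIC_CODE[alt_codon])
    cat_ <- if (identical(ref_aa, alt_aa)) "synonymous" else "missense"
    return(consequence_call(cat_, cod, frame_delta = 0L))
  }
  delta <- variant_cds_delta(v)
  ptc <- if (scan$status == "ptc") scan$ptc_codon else NA_integer_
  if (v$span_length %% 3L != 0L) {
    return(consequence_call("frameshift", cod, ptc_codon = ptc,
                            frame_delta = delta))
  }
  consequence_call("inframe_indel", cod, ptc_codon = ptc,
                   frame_delta = delta)
}

## ---------------------------------------------------------------------------
## Deleterious-missense filter
## ---------------------------------------------------------------------------

#' Filter missense records for predicted deleteriousness
#'
#' Keeps rare missense records meeting all of: minor allele frequency
#' strictly below `maf_max`, read depth at least `min_depth`, allele
#' balance (max/min of ref and alt counts) strictly below
#' `max_balance_ratio`, and Phred-scaled CADD strictly above `min_cadd`.
#' A putative heterozygote with a zero allele count cannot satisfy the
#' balance rule; such records are excluded and flagged.
#'
#' @param records Data frame with columns `maf`, `depth`, `ref_count`,
#'   `alt_count`, `cadd` (an `id` column is carried through if present).
#' @param maf_max Maximum minor allele frequency (fraction; default 1e-4,
#'   i.e. 0.01 percent).
#' @param min_depth Minimum read depth (default 20).
#' @param max_balance_ratio Maximum ref/alt count ratio (default 3).
#' @param min_cadd Minimum Phred-scaled CADD score (default 20, strict).
#' @return The surviving rows, with an attribute `"excluded"` holding a
#'   data frame of dropped rows and the rule each one violated.
#' @export
filter_deleterious_missense <- function(records, maf_max = 1e-4,
                                        min_depth = 20L,
                                        max_balance_ratio = 3,
                                        min_cadd = 20) {
  stopifnot(is.data.frame(records))
  need <- c("maf", "depth", "ref_count", "alt_count", "cadd")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(records$ref_count < 0 | records$alt_count < 0)) {
    stop("negative allele counts")
  }
  if (any(records$maf < 0 | records$maf > 1)) {
    stop("maf must be a fraction in [0, 1]")
  }
  reason <- rep(NA_character_, nrow(records))
  lo <- pmin(records$ref_count, records$alt_count)
  hi <- pmax(records$ref_count, records$alt_count)
  zero_het <- lo == 0
  reason[zero_het] <- "zero_allele_count"
  bal_bad <- !zero_het & (hi / lo) >= max_balance_ratio
  reason[is.na(reason) & bal_bad] <- "allele_balance"
  reason[is.na(reason) & records$depth < min_depth] <- "depth"
  reason[is.na(reason) & records$maf >= maf_max] <- "maf"
  reason[is.na(reason) & records$cadd <= min_cadd] <- "cadd"
  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  attr(out, "excluded") <- excluded
  out
}

## ---------------------------------------------------------------------------
## Variant tables
## ---------------------------------------------------------------------------

#' Read a variant TSV and classify every row by grammar
#'
#' The TSV must have columns `id` and `chgvs`; `protein_label` is used when
#' present to resolve substitution categories. Extra columns are tolerated
#' and carried through. Row count is preserved: unparseable strings raise
#' an error naming the offending row.
#'
#' @param path TSV file path.
#' @return The input data frame with added columns `category`,
#'   `affected_codon`, `ptc_codon`, `frame_delta` and `is_ptc`.
#' @export
annotate_variant_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", "."), check.names = FALSE,
                   fileEncoding = "UTF-8")
  if (!all(c("id", "chgvs") %in% names(df))) {
    stop("variant TSV needs 'id' and 'chgvs' columns")
  }
  labs <- if ("protein_label" %in% names(df)) df$protein_label
          else rep(NA_character_, nrow(df))
  calls <- lapply(seq_len(nrow(df)), function(i) {
    v <- tryCatch(parse_chgvs(df$chgvs[i], labs[i]),
                  error = function(e) stop("row ", i, " (", df$id[i], "): ",
                                           conditionMessage(e)))
    classify_by_grammar(v)
  })
  df$category <- vapply(calls, `[[`, character(1), "category")
  df$affected_codon <- vapply(calls, `[[`, integer(1), "affected_codon")
  df$ptc_codon <- vapply(calls, `[[`, integer(1), "ptc_codon")
  df$frame_delta <- vapply(calls, `[[`, integer(1), "frame_delta")
  df$is_ptc <- df$category %in% PTC_CATEGORIES
  df
}

#' Path of the packaged PTC mutation fixture table
#'
#' Eighteen coding-HGVS strings (17 PTC-class plus one splice-region
#' variant) with protein labels and carrier counts, as observed in a
#' European early-onset Alzheimer cohort screen of ABCA7.
#'
#' @return File path of the TSV shipped under `extdata`.
#' @export
ptc_table_fixture <- function() {
  system.file("extdata", "abca7_ptc_table1.tsv", package = "ptcrescue",
              mustWork = TRUE)
}
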