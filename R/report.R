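## Pipeline orchestration: annotate / simulate / quantify / associate /
## report. These functions are the programmatic surface behind the
## command-line script shipped under inst/scripts/ptcrescue.R; every run
## writes its exact configuration next to its outputs so any report can be
## regenerated from the emitted files alone.

write_tsv <- function(df, path) {
  df[] <- lapply(df, function(x) ifelse(is.na(x), ".", as.character(x)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

emit_config <- function(config, out_prefix) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               paste0(out_prefix, "_config.json"))
  }
  invisible(NULL)
}

#' Annotate a TSV of coding-HGVS strings
#'
#' Parses and grammar-classifies every row; row count is preserved.
#'
#' @param variants_tsv Input TSV with columns `id`, `chgvs` and optional
#'   `protein_label`.
#' @param out_tsv Output TSV path (`NULL` to skip writing).
#' @return The annotated data frame, invisibly when writing.
#' @export
run_annotate <- function(variants_tsv, out_tsv = NULL) {
  df <- annotate_variant_table(variants_tsv)
  if (!is.null(out_tsv)) {
    write_tsv(df, out_tsv)
    emit_config(list(subcommand = "annotate", variants_tsv = variants_tsv),
                tools::file_path_sans_ext(out_tsv))
    return(invisible(df))
  }
  df
}

#' Simulate an amplicon experiment to files
#'
#' Builds a toy locus, plants a variant of the requested class, simulates
#' reads and writes FASTA/BED12/SAM/FASTQ/TSV outputs plus the
#' configuration echo.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (locus and reads derive distinct streams).
#' @param variant_kind Mutation class for [plant_variant()].
#' @param exon Target exon.
#' @param n_reads,nmd_efficiency,rescue,wt_allele_share,p_sub,p_ins,p_del
#'   Passed to [sim_config()].
#' @param rescue_isoforms Optional list of event lists; default plants an
#'   in-frame skip of the mutated exon when its length allows, else none.
#' @return Named vector of written paths (attribute `"sim"` holds the
#'   in-memory simulation).
#' @export
run_simulate <- function(out_dir, seed = 1L, variant_kind = "frameshift_del",
                         exon = 2L, n_reads = 2000L, nmd_efficiency = 0,
                         rescue = numeric(0), wt_allele_share = 0.5,
                         p_sub = 0.05, p_ins = 0.03, p_del = 0.05,
                         rescue_isoforms = NULL) {
  loc <- make_toy_locus(seed = seed)
  pv <- plant_variant(loc$model, loc$reference, variant_kind, exon = exon)
  if (is.null(rescue_isoforms)) {
    rescue_isoforms <- if (length(rescue) > 0)
      rep(list(list(splice_event("exon_skip", exon))), length(rescue))
    else list()
  }
  cfg <- sim_config(seed = (seed + 104729L) %% 2147483647L,
                    n_reads = n_reads,
                    nmd_efficiency = nmd_efficiency, rescue = rescue,
                    wt_allele_share = wt_allele_share,
                    p_sub = p_sub, p_ins = p_ins, p_del = p_del)
  mut_events <- list()
  if (!is.na(pv$variant$intron_offset)) {
    ## splice-site variant: default aberrant isoform retains the intron
    intr <- variant_intron_index(loc$model, pv$variant)
    mut_events <- list(splice_event("intron_retention", intr))
  }
  sim <- simulate_amplicon_reads(loc$model, loc$reference, pv$variant,
                                 mut_events = mut_events,
                                 rescue_isoforms = rescue_isoforms,
                                 config = cfg)
  paths <- write_simulation(sim, out_dir)
  emit_config(list(subcommand = "simulate", seed = seed,
                   variant = format_chgvs(pv$variant),
                   variant_kind = variant_kind, exon = exon,
                   config = unclass(cfg)),
              file.path(out_dir, "sim"))
  attr(paths, "sim") <- sim
  paths
}

#' Quantify transcript classes from a SAM file
#'
#' @param sam SAM/BAM alignments of amplicon reads.
#' @param fasta Reference FASTA.
#' @param bed BED12 single-transcript model.
#' @param chgvs The carried coding-HGVS variant.
#' @param out_prefix Output prefix; writes `<prefix>_reads.tsv` and
#'   `<prefix>_summary.tsv` (`NULL` to skip writing).
#' @param tolerance,window,min_agree,gap_threshold Classification
#'   parameters (see [classify_reads()] and [read_alignments()]).
#' @return List with `classifications` (per-read data frame), `quant`
#'   (a `quant_result`) and `summary` (one-row data frame).
#' @export
run_quantify <- function(sam, fasta, bed, chgvs, out_prefix = NULL,
                         tolerance = 3L, window = 12L, min_agree = 0.7,
                         gap_threshold = 30L) {
  reference <- read_reference_fasta(fasta)
  model <- read_transcript_bed12(bed, reference)
  variant <- parse_chgvs(chgvs)
  aln <- read_alignments(sam, reference, gap_threshold = gap_threshold)
  cl <- classify_reads(aln, model, reference, variant,
                       tolerance = tolerance, window = window,
                       min_agree = min_agree)
  q <- quantify(cl, aln, model)
  summary <- data.frame(
    variant = chgvs, n_reads = q$n_reads, n_wt = q$n_wt, n_ptc = q$n_ptc,
    n_rescue = q$n_rescue, n_other = q$n_other,
    n_unassigned = q$n_unassigned,
    n_dropped_secondary = aln$n_dropped_secondary,
    ptc_expression_fraction = q$ptc_expression_fraction,
    rescue_fraction = q$rescue_fraction,
    rescue_events = if (length(q$event_frequencies))
      paste(sprintf("%s=%.4f", names(q$event_frequencies),
                    q$event_frequencies), collapse = ";")
    else NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(out_prefix)) {
    write_tsv(cl, paste0(out_prefix, "_reads.tsv"))
    write_tsv(summary, paste0(out_prefix, "_summary.tsv"))
    emit_config(list(subcommand = "quantify", sam = sam, fasta = fasta,
                     bed = bed, chgvs = chgvs, tolerance = tolerance,
                     window = window, min_agree = min_agree,
                     gap_threshold = gap_threshold),
                out_prefix)
  }
  list(classifications = cl, quant = q, summary = summary)
}

#' Stratified carrier association from a cohort TSV
#'
#' @param cohort_tsv Per-individual TSV (`id`, `cohort`, `stratum`,
#'   `carrier`) or pre-tabulated per-stratum counts TSV (`stratum`, `a`,
#'   `b`, `c`, `d`).
#' @param out_tsv Optional output TSV.
#' @return One-row data frame with the Mantel-Haenszel summary plus
#'   carrier frequencies.
#' @export
run_associate <- function(cohort_tsv, out_tsv = NULL) {
  df <- read.delim(cohort_tsv, sep = "\t", stringsAsFactors = FALSE)
  if (all(c("stratum", "a", "b", "c", "d") %in% names(df))) {
    strata <- lapply(seq_len(nrow(df)), function(i)
      stratum_table(df$stratum[i], df$a[i], df$b[i], df$c[i], df$d[i]))
  } else {
    strata <- tabulate_strata(df)
  }
  res <- cmh(strata)
  a <- sum(vapply(strata, `[[`, numeric(1), "a"))
  b <- sum(vapply(strata, `[[`, numeric(1), "b"))
  c_ <- sum(vapply(strata, `[[`, numeric(1), "c"))
  d <- sum(vapply(strata, `[[`, numeric(1), "d"))
  out <- data.frame(
    n_patients = a + b, n_controls = c_ + d,
    patient_carriers = a, control_carriers = c_,
    patient_carrier_pct = carrier_stats(a, a + b)$percent,
    control_carrier_pct = carrier_stats(c_, c_ + d)$percent,
    or_mh = res$or_mh, ci_low = res$ci_low, ci_high = res$ci_high,
    chi2 = res$chi2, p = res$p, n_strata = res$n_strata_used,
    stringsAsFactors = FALSE
  )
  if (!is.null(out_tsv)) {
    write_tsv(out, out_tsv)
    emit_config(list(subcommand = "associate", cohort_tsv = cohort_tsv),
                tools::file_path_sans_ext(out_tsv))
  }
  out
}

#' Join annotation, quantification and association into one report
#'
#' Produces a mutation-table-style report keyed by variant id: coding and
#' protein HGVS, category, carrier counts, PTC expression fraction and
#' rescue events. Row count equals the annotation row count.
#'
#' @param annot Annotated data frame (from [run_annotate()]) or TSV path.
#' @param quant_summaries Optional data frame of quantification summaries
#'   with a `variant` column matching `chgvs`, or TSV path.
#' @param assoc Optional association data frame or TSV path (appended as
#'   columns on every row, cohort-level).
#' @param out_tsv Optional output TSV.
#' @return The joined data frame.
#' @export
run_report <- function(annot, quant_summaries = NULL, assoc = NULL,
                       out_tsv = NULL) {
  as_df <- function(x) if (is.character(x))
    read.delim(x, sep = "\t", stringsAsFactors = FALSE, na.strings = ".",
               fileEncoding = "UTF-8") else x
  annot <- as_df(annot)
  out <- annot
  if (!is.null(quant_summaries)) {
    qs <- as_df(quant_summaries)
    keep <- setdiff(names(qs), "variant")
    out <- merge(out, qs, by.x = "chgvs", by.y = "variant",
                 all.x = TRUE, sort = FALSE)
    out <- out[match(annot$id, out$id), , drop = FALSE]
  }
  if (!is.null(assoc)) {
    as_ <- as_df(assoc)
    names(as_) <- paste0("cohort_", names(as_))
    out <- cbind(out, as_[rep(1L, nrow(out)), , drop = FALSE])
  }
  rownames(out) <- NULL
  if (!is.null(out_tsv)) write_tsv(out, out_tsv)
  out
}
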