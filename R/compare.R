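## Cross-pipeline comparison: low-expression filtering, event matching on
## skipped-exon coordinates, and mechanised assignment of the discrepancy
## categories (novel exon / novel flank / novel combination / paralog;
## repeat overlap / relatively-weak junction / low minor isoform).

es_types_assembly <- c("exon-skipping", "exact-repeat")
es_types_mapping <- c("skipped-exon", "multi-exon-skipping")

event_minor_major <- function(events) {
  inc <- rowSums(as.matrix(events[, grep("^incl_", names(events)),
                                  with = FALSE]))
  exc <- rowSums(as.matrix(events[, grep("^excl_", names(events)),
                                  with = FALSE]))
  data.table(incl_total = inc, excl_total = exc,
             minor = pmin(inc, exc), total = inc + exc)
}

#' Filter out poorly expressed isoforms
#'
#' Drops events whose minor isoform is supported by fewer than `min_reads`
#' reads or by less than `min_fraction` of the reads supporting both
#' isoforms (counts summed over samples).
#'
#' @param events Event table with per-sample `incl_` / `excl_` columns.
#' @param min_reads Absolute cutoff (default 5).
#' @param min_fraction Relative cutoff (default 0.10).
#' @return The surviving events.
#' @export
filter_low_expression <- function(events, min_reads = 5, min_fraction = 0.10) {
  if (!nrow(events)) return(events)
  mm <- event_minor_major(events)
  keep <- mm$minor >= min_reads & mm$total > 0 &
    mm$minor / mm$total >= min_fraction
  events[keep]
}

#' Match exon-skipping events of the two pipelines
#'
#' Events are matched on their skipped-exon coordinates only; the flanking
#' exons are ignored because the two pipelines may legitimately choose
#' different flanks for the same skipped exon.
#'
#' @param a Assembly-first event table.
#' @param b Mapping-first event table.
#' @param tolerance Coordinate tolerance in nt (default 0).
#' @return List of class `comparison_report`: `common` (a_event_id,
#'   b_event_id and coordinates), `a_only`, `b_only` (event tables).
#' @export
match_events <- function(a, b, tolerance = 0L) {
  es <- c(es_types_assembly, es_types_mapping)
  a_es <- if (nrow(a)) a[type %in% es & !is.na(skip_start)] else a
  b_es <- if (nrow(b)) b[type %in% es & !is.na(skip_start)] else b
  if (!nrow(a_es) || !nrow(b_es)) {
    return(structure(list(common = data.table(), a_only = a_es,
                          b_only = b_es), class = "comparison_report"))
  }
  # unique skipped-exon keys per side
  pairs <- list()
  used_a <- rep(FALSE, nrow(a_es)); used_b <- rep(FALSE, nrow(b_es))
  for (i in seq_len(nrow(a_es))) {
    j <- which(!used_b & b_es$contig == a_es$contig[i] &
               abs(b_es$skip_start - a_es$skip_start[i]) <= tolerance &
               abs(b_es$skip_end - a_es$skip_end[i]) <= tolerance)
    if (length(j)) {
      j <- j[1L]
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.table(
        a_event_id = a_es$event_id[i], b_event_id = b_es$event_id[j],
        contig = a_es$contig[i], skip_start = a_es$skip_start[i],
        skip_end = a_es$skip_end[i])
    }
  }
  structure(list(
    common = if (length(pairs)) rbindlist(pairs) else data.table(),
    a_only = a_es[!used_a], b_only = b_es[!used_b]),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("event comparison: common", nrow(x$common),
      "| assembly-only", nrow(x$a_only),
      "| mapping-only", nrow(x$b_only), "\n")
  invisible(x)
}

#' Categorise an event found by exactly one pipeline
#'
#' Events missed by the mapping-first caller are explained by annotation
#' lookup (unannotated skipped exon, unannotated flanking exon, no
#' annotated transcript combining annotated exons) or flagged as paralogs
#' when the assembler reported an exact repeat. Events missed by the
#' assembly are explained by repeat overlap of the skipped exon, a minor
#' isoform under 5 reads, or a junction removed by the assembler's
#' relative-support filter (per its log); anything else is `other`.
#'
#' @param event One event row (from the side that found it).
#' @param side `"assembly_only"` or `"mapping_only"`.
#' @param model A `gene_model`.
#' @param repeats Repeat intervals (contig, start, end), may be NULL.
#' @param assembler_log List with `removed_edges` (from
#'   [filter_low_support()]); may be NULL.
#' @param genome A `genome` (needed for the removed-junction check).
#' @return Category string.
#' @export
categorize_discrepancy <- function(event, side, model, repeats = NULL,
                                   assembler_log = NULL, genome = NULL) {
  ge <- model$genomic_exons
  if (side == "assembly_only") {
    if (!is.null(event$repeat_status) &&
        isTRUE(event$repeat_status == "exact-repeat")) return("paralog")
    skip_ann <- nrow(ge[contig == event$contig & start == event$skip_start &
                        end == event$skip_end]) > 0L
    if (!skip_ann) return("novel-exon")
    up_ann <- any(vapply(ge[contig == event$contig]$alt_ends,
                         function(v) event$up_end %in% v, logical(1)))
    dn_ann <- any(vapply(ge[contig == event$contig]$alt_starts,
                         function(v) event$down_start %in% v, logical(1)))
    if (!up_ann || !dn_ann) return("novel-flank")
    if (!junction_annotated(model, event$contig, event$up_end,
                            event$down_start)) return("novel-combination")
    return("other")
  }
  # mapping_only: missed by the assembly
  if (!is.null(repeats) && nrow(repeats)) {
    ov <- repeats[contig == event$contig & start <= event$skip_end &
                  end >= event$skip_start]
    if (nrow(ov)) return("repeat-overlap")
  }
  mm <- event_minor_major(as.data.table(event))
  if (mm$minor < 5) return("low-minor-isoform")
  if (!is.null(assembler_log) && !is.null(assembler_log$removed_edges) &&
      nrow(assembler_log$removed_edges) && !is.null(genome)) {
    js <- assembler_log$removed_edges$junction_seq
    k <- nchar(js[1L]) - 1L
    ctx <- paste0(
      genome_seq(genome, event$contig, event$up_end - k + 1L, event$up_end),
      genome_seq(genome, event$contig, event$down_start,
                 event$down_start + k - 1L))
    if (any(vapply(js, function(s) grepl(s, ctx, fixed = TRUE) ||
                     grepl(revcomp(s), ctx, fixed = TRUE), logical(1))))
      return("complex-low-branch")
  }
  "other"
}

#' Compare the two pipelines end to end
#'
#' Matches the exon-skipping events of both pipelines before and after the
#' low-expression filter and categorises every event found by only one
#' pipeline (pre-filter sets, where the engineered low-expression cases are
#' still visible).
#'
#' @param events_a,events_b Assembly-first and mapping-first event tables.
#' @param model A `gene_model`.
#' @param repeats Repeat intervals or NULL.
#' @param assembler_log Assembler log list or NULL.
#' @param genome A `genome` or NULL.
#' @param min_reads,min_fraction Low-expression filter parameters.
#' @return List: `prefilter` and `postfilter` comparison reports,
#'   `categories` (event key, detected_by, category), `summary`.
#' @export
compare_pipelines <- function(events_a, events_b, model, repeats = NULL,
                              assembler_log = NULL, genome = NULL,
                              min_reads = 5, min_fraction = 0.10) {
  pre <- match_events(events_a, events_b)
  fa <- filter_low_expression(events_a, min_reads, min_fraction)
  fb <- filter_low_expression(events_b, min_reads, min_fraction)
  post <- match_events(fa, fb)
  cats <- list()
  if (nrow(pre$a_only)) for (i in seq_len(nrow(pre$a_only))) {
    ev <- pre$a_only[i]
    cats[[length(cats) + 1L]] <- data.table(
      event_id = ev$event_id, detected_by = "assembly",
      contig = ev$contig, skip_start = ev$skip_start,
      skip_end = ev$skip_end,
      category = categorize_discrepancy(ev, "assembly_only", model, repeats,
                                        assembler_log, genome))
  }
  if (nrow(pre$b_only)) for (i in seq_len(nrow(pre$b_only))) {
    ev <- pre$b_only[i]
    cats[[length(cats) + 1L]] <- data.table(
      event_id = ev$event_id, detected_by = "mapping",
      contig = ev$contig, skip_start = ev$skip_start,
      skip_end = ev$skip_end,
      category = categorize_discrepancy(ev, "mapping_only", model, repeats,
                                        assembler_log, genome))
  }
  categories <- if (length(cats)) rbindlist(cats) else
    data.table(event_id = character(), detected_by = character(),
               contig = character(), skip_start = integer(),
               skip_end = integer(), category = character())
  n_union <- nrow(post$common) + nrow(post$a_only) + nrow(post$b_only)
  summary <- list(
    pre_common = nrow(pre$common), pre_assembly_only = nrow(pre$a_only),
    pre_mapping_only = nrow(pre$b_only),
    post_common = nrow(post$common), post_assembly_only = nrow(post$a_only),
    post_mapping_only = nrow(post$b_only),
    post_common_fraction = if (n_union > 0) nrow(post$common) / n_union
    else NA_real_)
  list(prefilter = pre, postfilter = post, categories = categories,
       summary = summary)
}

#' Compare differential results of the two pipelines
#'
#' Pairs events identified by both pipelines, reports their DeltaPSI values
#' and correlation, partitions the significant calls, and flags events
#' identified by both but significant in only one.
#'
#' @param diff_a,diff_b `diff_splice` tables of the two pipelines.
#' @param matches `common` table from [match_events()] (a_event_id,
#'   b_event_id).
#' @return List: `paired` (per common event: both DeltaPSI and significance),
#'   `deltapsi_correlation`, `n_sig_both`, `n_sig_a_only`, `n_sig_b_only`,
#'   `discordant` (common events significant on one side only).
#' @export
compare_differential <- function(diff_a, diff_b, matches) {
  if (!nrow(matches)) {
    return(list(paired = data.table(), deltapsi_correlation = NA_real_,
                n_sig_both = 0L,
                n_sig_a_only = sum(diff_a$significant),
                n_sig_b_only = sum(diff_b$significant),
                discordant = data.table()))
  }
  da <- as.data.table(diff_a)[, .(a_event_id = event_id,
                                  delta_psi_a = delta_psi,
                                  sig_a = significant)]
  db <- as.data.table(diff_b)[, .(b_event_id = event_id,
                                  delta_psi_b = delta_psi,
                                  sig_b = significant)]
  paired <- db[da[as.data.table(matches), on = "a_event_id"],
               on = "b_event_id"]
  ok <- paired[!is.na(delta_psi_a) & !is.na(delta_psi_b)]
  corr <- if (nrow(ok) >= 3L) stats::cor(ok$delta_psi_a, ok$delta_psi_b)
  else NA_real_
  matched_a <- paired$a_event_id
  matched_b <- paired$b_event_id
  n_sig_a_only <- sum(diff_a$significant &
                      !(diff_a$event_id %in% matched_a[paired$sig_b %in% TRUE]))
  n_sig_b_only <- sum(diff_b$significant &
                      !(diff_b$event_id %in% matched_b[paired$sig_a %in% TRUE]))
  list(paired = paired, deltapsi_correlation = corr,
       n_sig_both = sum(paired$sig_a %in% TRUE & paired$sig_b %in% TRUE),
       n_sig_a_only = n_sig_a_only, n_sig_b_only = n_sig_b_only,
       discordant = paired[xor(sig_a %in% TRUE, sig_b %in% TRUE)])
}
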