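## Pipeline orchestration: one entry point wiring simulation, the
## assembly-first caller, the mapping-first caller, the shared differential
## layer and the comparator; used by the command-line wrapper in
## inst/scripts/dualsplice.

#' Run the assembly-first caller on reads
#'
#' Builds the De Bruijn graph from the pooled sample reads, removes
#' relatively weakly supported branches, enumerates bounded-branching
#' bubbles, quantifies their paths and annotates them against the genome.
#'
#' @param reads Named list of read vectors (one per sample).
#' @param genome A `genome`.
#' @param model A `gene_model`.
#' @param k k-mer length (odd; 15 suits toy scale, 41 realistic reads).
#' @param relative_cutoff Relative branch-support cutoff (default 0.02).
#' @param max_branches Bubble branching bound (default 5).
#' @param ir_threshold IR-vs-deletion threshold (nt).
#' @param budget Per-source enumeration budget.
#' @return List: `events`, `bubbles`, `graph_log` (removed edges),
#'   `enum_log`.
#' @export
assembly_pipeline <- function(reads, genome, model, k = 15L,
                              relative_cutoff = 0.02, max_branches = 5L,
                              ir_threshold = 50L, budget = 1e5) {
  g <- build_dbg(reads, k)
  g <- filter_low_support(g, relative_cutoff)
  bubbles <- enumerate_bubbles(g, max_branches = max_branches,
                               budget = budget)
  enum_log <- attr(bubbles, "log")
  bubbles <- quantify_bubbles(bubbles, reads, k)
  events <- annotate_bubbles(bubbles, genome, model, reads = reads, k = k,
                             ir_threshold = ir_threshold)
  list(events = events, bubbles = bubbles, graph_log = g$log,
       enum_log = enum_log)
}

#' Run a full simulated dual-pipeline analysis
#'
#' Simulates the reference and reads, runs both callers, the differential
#' layer on each, and the comparator, writing all standard outputs under
#' `outdir`. Running twice with the same seed yields byte-identical
#' outputs.
#'
#' @param subcommand One of `"simulate"`, `"assemble"`, `"mapfirst"`,
#'   `"diff"`, `"compare"`, `"all"`. Subcommands other than `"all"` stop
#'   after the corresponding stage.
#' @param outdir Output directory.
#' @param config A [sim_config()].
#' @param k,relative_cutoff,max_branches,ir_threshold Assembly parameters.
#' @param min_reads,min_fraction Low-expression filter parameters.
#' @param psi_min_count,fdr,min_delta_psi Differential parameters.
#' @return Invisibly, a list with the stage outputs that were produced.
#' @export
run_pipeline <- function(subcommand = "all", outdir, config = sim_config(),
                         k = 15L, relative_cutoff = 0.02, max_branches = 5L,
                         ir_threshold = 50L, min_reads = 5,
                         min_fraction = 0.10, psi_min_count = 10,
                         fdr = 0.05, min_delta_psi = 0.1) {
  subcommand <- match.arg(subcommand,
                          c("simulate", "assemble", "mapfirst", "diff",
                            "compare", "all"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(config)
  write_reference(ref, outdir)
  sim <- simulate_reads(ref, outdir)
  out <- list(ref = ref, sim = sim)
  if (subcommand == "simulate") return(invisible(out))

  do_assembly <- subcommand %in% c("assemble", "diff", "compare", "all")
  do_mapfirst <- subcommand %in% c("mapfirst", "diff", "compare", "all")
  if (do_assembly) {
    asm <- assembly_pipeline(sim$reads, ref$genome, ref$model, k = k,
                             relative_cutoff = relative_cutoff,
                             max_branches = max_branches,
                             ir_threshold = ir_threshold)
    write_bubbles_fasta(asm$bubbles, file.path(outdir, "bubbles.fa"))
    if (nrow(asm$events)) {
      fwrite(asm$events, file.path(outdir, "events_assembly.tsv"),
             sep = "\t")
      write_events_bed12(asm$events,
                         file.path(outdir, "events_assembly.bed"))
    }
    out$assembly <- asm
  }
  if (subcommand == "assemble") return(invisible(out))
  if (do_mapfirst) {
    fl <- mapfirst_events(sim$sam_paths, ref$model)
    if (nrow(fl$events))
      fwrite(fl$events[, !c("up_idx", "dn_idx", "sk_first", "sk_last")],
             file.path(outdir, "events_mapping.tsv"), sep = "\t")
    fwrite(fl$junctions, file.path(outdir, "junctions.tsv"), sep = "\t")
    fwrite(fl$drop_log, file.path(outdir, "drop_log.tsv"), sep = "\t")
    out$mapfirst <- fl
  }
  if (subcommand == "mapfirst") return(invisible(out))

  diff_a <- run_differential(as_count_table(out$assembly$events, sim$samples),
                             psi_min_count, fdr, min_delta_psi)
  diff_b <- run_differential(as_count_table(out$mapfirst$events, sim$samples),
                             psi_min_count, fdr, min_delta_psi)
  fwrite(diff_a, file.path(outdir, "differential_assembly.tsv"), sep = "\t")
  fwrite(diff_b, file.path(outdir, "differential_mapping.tsv"), sep = "\t")
  out$diff_a <- diff_a; out$diff_b <- diff_b
  if (subcommand == "diff") return(invisible(out))

  cp <- compare_pipelines(out$assembly$events, out$mapfirst$events,
                          ref$model, ref$repeats,
                          out$assembly$graph_log, ref$genome,
                          min_reads, min_fraction)
  cd <- compare_differential(diff_a, diff_b, cp$postfilter$common)
  fwrite(cp$categories, file.path(outdir, "discrepancy_categories.tsv"),
         sep = "\t")
  summary <- c(cp$summary,
               list(deltapsi_correlation = cd$deltapsi_correlation,
                    n_sig_both = cd$n_sig_both,
                    n_sig_assembly_only = cd$n_sig_a_only,
                    n_sig_mapping_only = cd$n_sig_b_only))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  out$comparison <- cp
  out$diff_comparison <- cd
  invisible(out)
}
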