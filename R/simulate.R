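## Deterministic RNA-seq simulator: toy genome + annotation with engineered
## scenarios (novel exon, recent paralog duplication, repeat-derived exon,
## 2-read minor isoform, relatively weak junction in a highly expressed
## context, short flanking exon, intron retention, genomic deletion),
## condition/replicate-structured spliced read pairs with planted
## per-event inclusion rates and NB count noise, and a ground-truth SAM.

#' Simulation configuration
#'
#' Defaults define the standard study conditions: 20 genes carrying 30
#' exon-skipping events, complete annotation, two conditions with two
#' replicates each, 76-nt paired reads and an expected 50 reads per
#' junction.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_genes Number of plain multi-exon genes.
#' @param n_events Number of planted exon-skipping events across them.
#' @param exon_len,intron_len Integer ranges (length-2) for exon and intron
#'   sizes in nt.
#' @param read_len Read length (nt).
#' @param insert_len Fragment length for read pairs (nt).
#' @param coverage Expected junction-read count per junction at weight 1.
#' @param replicates Replicates per condition (2 conditions).
#' @param dispersion NB dispersion of per-replicate fragment counts.
#' @param error_rate Per-base substitution error rate.
#' @param psi_range Range the condition-1 inclusion rates are drawn from.
#' @param frac_regulated Fraction of events with a planted PSI shift.
#' @param delta_psi Magnitude of the planted shift.
#' @param scenarios Character vector of engineered scenarios to enable;
#'   any of `"novel_exon"`, `"paralog"`, `"repeat_exon"`, `"low_minor"`,
#'   `"complex_event"`, `"short_flank"`, `"intron_retention"`,
#'   `"genomic_deletion"`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, n_events = 30L,
                       exon_len = c(90L, 160L), intron_len = c(150L, 350L),
                       read_len = 76L, insert_len = 180L, coverage = 50,
                       replicates = 2L, dispersion = 0.05,
                       error_rate = 0, psi_range = c(0.2, 0.65),
                       frac_regulated = 0.5, delta_psi = 0.3,
                       scenarios = character()) {
  if (exon_len[1L] < 2L) stop("infeasible config: exons shorter than 2 nt")
  stopifnot(n_genes >= 1L, read_len >= 20L, insert_len > read_len,
            all(psi_range >= 0 & psi_range <= 1))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_events = as.integer(n_events), exon_len = exon_len,
                 intron_len = intron_len, read_len = as.integer(read_len),
                 insert_len = as.integer(insert_len), coverage = coverage,
                 replicates = as.integer(replicates),
                 dispersion = dispersion, error_rate = error_rate,
                 psi_range = psi_range, frac_regulated = frac_regulated,
                 delta_psi = delta_psi, scenarios = scenarios),
            class = "sim_config")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# intron with canonical GT..AG boundaries
random_intron <- function(n) paste0("GT", random_seq(n - 4L), "AG")

mutate_seq <- function(seq, n_subs) {
  s <- strsplit(seq, "")[[1L]]
  pos <- sample(seq_along(s), n_subs)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  paste(s, collapse = "")
}

## ---------------------------------------------------------------------------
## Reference generation
## ---------------------------------------------------------------------------

#' Generate the simulated reference: genome, annotation, truth
#'
#' Builds a single-contig genome of random multi-exon genes with canonical
#' GT-AG introns, plants the configured exon-skipping events and engineered
#' scenarios, and derives the annotation (GTF-equivalent transcript exons;
#' scenario-dependent omissions such as the novel exon), the repeat
#' intervals, the expressed-isoform table used by the read simulator and the
#' per-event truth table.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_reference`: `genome` (a `genome`),
#'   `annotation` (transcript-exon data.table), `model` (the `gene_model`
#'   built from the annotation), `isoforms`, `events` (truth), `repeats`
#'   (data.table of repeat intervals) and `config`.
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  b <- new.env(parent = emptyenv())
  b$parts <- list(); b$pos <- 0L
  add_seq <- function(s) {
    start <- b$pos + 1L
    b$parts[[length(b$parts) + 1L]] <- s
    b$pos <- b$pos + nchar(s)
    start
  }
  spacer <- function() add_seq(random_seq(sample(400:800, 1L)))

  ann <- list()       # transcript exon rows
  isoforms <- list()  # expressed isoforms with weights
  events <- list()    # truth events
  repeats <- list()

  add_exons <- function(exon_seqs, intron_lens) {
    # returns data.table(start, end) of exon coordinates as appended
    n <- length(exon_seqs)
    coords <- data.table(start = integer(n), end = integer(n))
    for (i in seq_len(n)) {
      s <- add_seq(exon_seqs[[i]])
      coords[i, `:=`(start = s, end = s + nchar(exon_seqs[[i]]) - 1L)]
      if (i < n) add_seq(random_intron(intron_lens[i]))
    }
    coords
  }
  ann_tx <- function(gene, tx, coords, idx) {
    data.table(contig = "chr1", start = coords$start[idx],
               end = coords$end[idx], strand = "+",
               gene_id = gene, transcript_id = tx)
  }
  iso_row <- function(gene, iso, coords, idx, w1, w2, fixed_n = NULL,
                      fixed_u = NULL, mapq0 = FALSE, sec_offset = NA_integer_) {
    list(gene_id = gene, iso_id = iso,
         blocks = coords[idx, .(start, end)],
         w1 = w1, w2 = w2, fixed_n = fixed_n, fixed_u = fixed_u,
         mapq0 = mapq0, sec_offset = sec_offset)
  }

  ## plain genes with planted ES events ------------------------------------
  extra <- max(0L, config$n_events - config$n_genes)
  n_ev_gene <- rep(1L, config$n_genes)
  if (config$n_events < config$n_genes) {
    n_ev_gene[] <- 0L
    n_ev_gene[seq_len(config$n_events)] <- 1L
  }
  if (extra > 0L) n_ev_gene[seq_len(min(extra, config$n_genes))] <-
    n_ev_gene[seq_len(min(extra, config$n_genes))] + 1L
  ev_id <- 0L
  for (g in seq_len(config$n_genes)) {
    gene <- sprintf("gene%02d", g)
    nev <- n_ev_gene[g]
    n_ex <- if (nev >= 2L) sample(6:7, 1L) else sample(4:6, 1L)
    exon_seqs <- lapply(sample(config$exon_len[1L]:config$exon_len[2L], n_ex,
                               replace = TRUE), random_seq)
    intr <- sample(config$intron_len[1L]:config$intron_len[2L], n_ex - 1L,
                   replace = TRUE)
    spacer()
    coords <- add_exons(exon_seqs, intr)
    skippable <- if (nev == 0L) integer() else if (nev == 1L)
      sample(2:(n_ex - 1L), 1L) else c(2L, 4L)
    ann[[length(ann) + 1L]] <- ann_tx(gene, paste0(gene, ".t1"), coords,
                                      seq_len(n_ex))
    psis <- list()
    for (sk in skippable) {
      ev_id <- ev_id + 1L
      psi1 <- runif(1L, config$psi_range[1L], config$psi_range[2L])
      regulated <- runif(1L) < config$frac_regulated
      psi2 <- if (regulated) psi1 + config$delta_psi else psi1
      if (regulated && runif(1L) < 0.5) { tmp <- psi1; psi1 <- psi2; psi2 <- tmp }
      psis[[as.character(sk)]] <- c(psi1, psi2)
      ann[[length(ann) + 1L]] <- ann_tx(gene, paste0(gene, ".skip", sk),
                                        coords, setdiff(seq_len(n_ex), sk))
      events[[length(events) + 1L]] <- data.table(
        event_id = sprintf("ev%03d", ev_id), gene_id = gene,
        scenario = "plain", contig = "chr1", strand = "+",
        skip_start = coords$start[sk], skip_end = coords$end[sk],
        up_end = coords$end[sk - 1L], down_start = coords$start[sk + 1L],
        psi1 = psi1, psi2 = psi2)
    }
    # expressed isoforms: independent inclusion per skippable exon
    combos <- if (length(skippable)) {
      expand.grid(rep(list(c(TRUE, FALSE)), length(skippable)))
    } else data.frame(row.names = 1L)
    for (ci in seq_len(max(1L, nrow(combos)))) {
      inc <- if (length(skippable)) unlist(combos[ci, ]) else logical()
      w1 <- 1; w2 <- 1
      for (j in seq_along(skippable)) {
        p <- psis[[as.character(skippable[j])]]
        w1 <- w1 * if (inc[j]) p[1L] else 1 - p[1L]
        w2 <- w2 * if (inc[j]) p[2L] else 1 - p[2L]
      }
      idx <- setdiff(seq_len(n_ex), skippable[!inc])
      isoforms[[length(isoforms) + 1L]] <- iso_row(
        gene, paste0(gene, ".iso", ci), coords, idx, w1, w2)
    }
  }

  ## engineered scenarios ----------------------------------------------------
  sc <- config$scenarios
  if ("novel_exon" %in% sc) {
    gene <- "gnovel"
    e <- lapply(c(120L, 130L, 100L, 130L, 120L), random_seq) # E1 E2 N E3 E4
    spacer()
    coords <- add_exons(e, c(200L, 180L, 180L, 200L))
    ann[[length(ann) + 1L]] <- ann_tx(gene, "gnovel.t1", coords, c(1L, 2L, 4L, 5L))
    ev_id <- ev_id + 1L
    events[[length(events) + 1L]] <- data.table(
      event_id = sprintf("ev%03d", ev_id), gene_id = gene,
      scenario = "novel_exon", contig = "chr1", strand = "+",
      skip_start = coords$start[3L], skip_end = coords$end[3L],
      up_end = coords$end[2L], down_start = coords$start[4L],
      psi1 = 0.5, psi2 = 0.5)
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "gnovel.inc", coords,
                                                 1:5, 0.5, 0.5)
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "gnovel.exc", coords,
                                                 c(1L, 2L, 4L, 5L), 0.5, 0.5)
  }
  if ("paralog" %in% sc) {
    gene <- "gpar_a"
    e <- lapply(c(130L, 110L, 130L), random_seq)
    intr <- c(220L, 240L)
    spacer()
    coords <- add_exons(e, intr)
    gene_seq_start <- coords$start[1L]
    # verbatim copy of the whole locus elsewhere: a recent duplication
    gene_seq <- paste(unlist(tail(b$parts, 5L)), collapse = "")
    spacer()
    copy_start <- add_seq(gene_seq)
    ann[[length(ann) + 1L]] <- ann_tx(gene, "gpar_a.t1", coords, 1:3)
    ann[[length(ann) + 1L]] <- ann_tx(gene, "gpar_a.skip", coords, c(1L, 3L))
    offset <- copy_start - gene_seq_start
    coordsB <- copy(coords)[, `:=`(start = start + offset, end = end + offset)]
    ann[[length(ann) + 1L]] <- ann_tx("gpar_b", "gpar_b.t1", coordsB, 1:3)
    ann[[length(ann) + 1L]] <- ann_tx("gpar_b", "gpar_b.skip", coordsB, c(1L, 3L))
    ev_id <- ev_id + 1L
    events[[length(events) + 1L]] <- data.table(
      event_id = sprintf("ev%03d", ev_id), gene_id = gene,
      scenario = "paralog", contig = "chr1", strand = "+",
      skip_start = coords$start[2L], skip_end = coords$end[2L],
      up_end = coords$end[1L], down_start = coords$start[3L],
      psi1 = 0.7, psi2 = 0.7)
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "gpar_a.inc", coords,
                                                 1:3, 0.7, 0.7, mapq0 = TRUE,
                                                 sec_offset = offset)
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "gpar_a.exc", coords,
                                                 c(1L, 3L), 0.3, 0.3,
                                                 mapq0 = TRUE,
                                                 sec_offset = offset)
  }
  if ("repeat_exon" %in% sc) {
    unit <- random_seq(300L)
    gene <- "grep"
    e <- list(random_seq(130L), unit, random_seq(130L))
    spacer()
    coords <- add_exons(e, c(220L, 220L))
    ann[[length(ann) + 1L]] <- ann_tx(gene, "grep.t1", coords, 1:3)
    ann[[length(ann) + 1L]] <- ann_tx(gene, "grep.skip", coords, c(1L, 3L))
    repeats[[length(repeats) + 1L]] <- data.table(
      contig = "chr1", start = coords$start[2L], end = coords$end[2L],
      name = "repunit.0")
    ev_id <- ev_id + 1L
    events[[length(events) + 1L]] <- data.table(
      event_id = sprintf("ev%03d", ev_id), gene_id = gene,
      scenario = "repeat_exon", contig = "chr1", strand = "+",
      skip_start = coords$start[2L], skip_end = coords$end[2L],
      up_end = coords$end[1L], down_start = coords$start[3L],
      psi1 = 0.5, psi2 = 0.5)
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "grep.inc", coords,
                                                 1:3, 0.5, 0.5)
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "grep.exc", coords,
                                                 c(1L, 3L), 0.5, 0.5)
    # divergent copies, each expressed inside its own single-exon gene so
    # that the graph around the repeat is highly branching
    for (i in 1:6) {
      cgene <- paste0("grepbg", i)
      copyseq <- mutate_seq(unit, 12L)
      ex <- paste0(random_seq(50L), copyseq, random_seq(50L))
      spacer()
      cstart <- add_seq(ex)
      cc <- data.table(start = cstart, end = cstart + nchar(ex) - 1L)
      ann[[length(ann) + 1L]] <- ann_tx(cgene, paste0(cgene, ".t1"), cc, 1L)
      repeats[[length(repeats) + 1L]] <- data.table(
        contig = "chr1", start = cstart + 50L, end = cstart + 349L,
        name = paste0("repunit.", i))
      isoforms[[length(isoforms) + 1L]] <- iso_row(
        cgene, paste0(cgene, ".iso"), cc, 1L, 0.6, 0.6)
    }
  }
  if ("low_minor" %in% sc) {
    gene <- "glow"
    e <- lapply(c(130L, 110L, 130L), random_seq)
    spacer()
    coords <- add_exons(e, c(220L, 240L))
    ann[[length(ann) + 1L]] <- ann_tx(gene, "glow.t1", coords, 1:3)
    ann[[length(ann) + 1L]] <- ann_tx(gene, "glow.skip", coords, c(1L, 3L))
    ev_id <- ev_id + 1L
    events[[length(events) + 1L]] <- data.table(
      event_id = sprintf("ev%03d", ev_id), gene_id = gene,
      scenario = "low_minor", contig = "chr1", strand = "+",
      skip_start = coords$start[2L], skip_end = coords$end[2L],
      up_end = coords$end[1L], down_start = coords$start[3L],
      psi1 = NA_real_, psi2 = NA_real_)
    # inclusion at 3x the default junction coverage so the two exclusion
    # reads fall under the assembler's 2% relative-support cutoff
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "glow.inc", coords,
                                                 1:3, 3, 3)
    # exactly two exclusion fragments, both in condition 1 replicate 1,
    # placed so that read 1 spans the exclusion junction with good anchors
    # while the pair still fits the exclusion isoform
    ju <- nchar(e[[1L]])  # junction position in exclusion-isoform coordinates
    isoforms[[length(isoforms) + 1L]] <- iso_row(
      gene, "glow.exc", coords, c(1L, 3L), 0, 0,
      fixed_n = c(c1r1 = 2L), fixed_u = c(ju - 60L, ju - 53L))
  }
  if ("complex_event" %in% sc) {
    gene <- "gcomplex"
    # flanking exons long enough that the junction-read windows of both
    # mates are untruncated, so the planted counts are realised
    e <- lapply(c(200L, 100L, 200L), random_seq)
    spacer()
    coords <- add_exons(e, c(220L, 240L))
    ann[[length(ann) + 1L]] <- ann_tx(gene, "gcomplex.t1", coords, 1:3)
    ann[[length(ann) + 1L]] <- ann_tx(gene, "gcomplex.skip", coords, c(1L, 3L))
    ev_id <- ev_id + 1L
    events[[length(events) + 1L]] <- data.table(
      event_id = sprintf("ev%03d", ev_id), gene_id = gene,
      scenario = "complex_event", contig = "chr1", strand = "+",
      skip_start = coords$start[2L], skip_end = coords$end[2L],
      up_end = coords$end[1L], down_start = coords$start[3L],
      psi1 = NA_real_, psi2 = NA_real_)
    # fixed counts: ~70 inclusion-junction reads, ~12 exclusion-junction
    # reads per sample -> minor fraction ~15% (kept by the 5-read/10%
    # filter) but < 2% of the reads branching out of exon 1's 3' end once
    # the highly expressed companion gene below is pooled in
    li <- sum(nchar(unlist(e)))
    le <- nchar(e[[1L]]) + nchar(e[[3L]])
    win <- 2L * (config$read_len - 7L)
    isoforms[[length(isoforms) + 1L]] <- iso_row(
      gene, "gcomplex.inc", coords, 1:3, 0, 0,
      fixed_n = round(70 * (li - config$insert_len + 1L) / win))
    isoforms[[length(isoforms) + 1L]] <- iso_row(
      gene, "gcomplex.exc", coords, c(1L, 3L), 0, 0,
      fixed_n = round(12 * (le - config$insert_len + 1L) / win))
    # companion gene sharing the terminal 20 nt of exon 1, highly
    # expressed; the shared segment sits mid-transcript so both mates
    # cover it and its k-mer depth dominates the branching vertex
    comp <- paste0(random_seq(170L),
                   substring(e[[1L]], nchar(e[[1L]]) - 19L, nchar(e[[1L]])),
                   random_seq(170L))
    spacer()
    cstart <- add_seq(comp)
    cc <- data.table(start = cstart, end = cstart + nchar(comp) - 1L)
    ann[[length(ann) + 1L]] <- ann_tx("gcomphi", "gcomphi.t1", cc, 1L)
    isoforms[[length(isoforms) + 1L]] <- iso_row(
      "gcomphi", "gcomphi.iso", cc, 1L, 0, 0, fixed_n = 900L)
  }
  if ("short_flank" %in% sc) {
    gene <- "gshort"
    e <- lapply(c(120L, 100L, 12L, 120L), random_seq)
    spacer()
    coords <- add_exons(e, c(200L, 180L, 200L))
    ann[[length(ann) + 1L]] <- ann_tx(gene, "gshort.t1", coords, 1:4)
    ann[[length(ann) + 1L]] <- ann_tx(gene, "gshort.skip", coords, c(1L, 3L, 4L))
    ev_id <- ev_id + 1L
    events[[length(events) + 1L]] <- data.table(
      event_id = sprintf("ev%03d", ev_id), gene_id = gene,
      scenario = "short_flank", contig = "chr1", strand = "+",
      skip_start = coords$start[2L], skip_end = coords$end[2L],
      up_end = coords$end[1L], down_start = coords$start[3L],
      psi1 = 0.5, psi2 = 0.5)
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "gshort.inc", coords,
                                                 1:4, 0.5, 0.5)
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "gshort.exc", coords,
                                                 c(1L, 3L, 4L), 0.5, 0.5)
  }
  if ("intron_retention" %in% sc) {
    gene <- "gir"
    e1 <- random_seq(140L); e2 <- random_seq(140L)
    intr <- 200L
    spacer()
    coords <- add_exons(list(e1, e2), intr)
    retained <- data.table(start = coords$start[1L], end = coords$end[2L])
    ann[[length(ann) + 1L]] <- ann_tx(gene, "gir.spliced", coords, 1:2)
    ann[[length(ann) + 1L]] <- ann_tx(gene, "gir.retained", retained, 1L)
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "gir.spl", coords, 1:2,
                                                 0.7, 0.7)
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "gir.ret", retained, 1L,
                                                 0.3, 0.3)
  }
  if ("genomic_deletion" %in% sc) {
    gene <- "gdel"
    e1 <- random_seq(200L); e2 <- random_seq(140L)
    spacer()
    coords <- add_exons(list(e1, e2), 220L)
    ann[[length(ann) + 1L]] <- ann_tx(gene, "gdel.t1", coords, 1:2)
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "gdel.full", coords, 1:2,
                                                 0.5, 0.5)
    # variant lacking a 30-nt interior segment of exon 1 (not at splice
    # sites): a transcriptomic deletion relative to the genome
    delv <- data.table(
      start = c(coords$start[1L], coords$start[1L] + 130L, coords$start[2L]),
      end = c(coords$start[1L] + 99L, coords$end[1L], coords$end[2L]))
    isoforms[[length(isoforms) + 1L]] <- iso_row(gene, "gdel.del", delv, 1:3,
                                                 0.5, 0.5)
  }
  spacer()

  genome_str <- paste(unlist(b$parts), collapse = "")
  seqs <- Biostrings::DNAStringSet(genome_str)
  names(seqs) <- "chr1"
  genome <- structure(list(seqs = seqs), class = "genome")
  annotation <- rbindlist(ann)
  model <- build_gene_model(annotation, genome)
  ev <- if (length(events)) rbindlist(events) else data.table()
  rp <- if (length(repeats)) rbindlist(repeats) else
    data.table(contig = character(), start = integer(), end = integer(),
               name = character())
  structure(list(genome = genome, annotation = annotation, model = model,
                 isoforms = isoforms, events = ev, repeats = rp,
                 config = config),
            class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("sim_reference:", sum(Biostrings::width(x$genome$seqs)), "bp genome,",
      nrow(x$model$genes), "annotated gene(s),", nrow(x$events),
      "planted event(s)\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Read simulation
## ---------------------------------------------------------------------------

#' Simulate condition/replicate-structured spliced read pairs
#'
#' Per expressed isoform and sample, fragment numbers are drawn from a
#' negative binomial around the planted inclusion-rate weights times the
#' junction coverage; fragments tile the isoform uniformly. Reads are
#' emitted as proper pairs (fixed insert length). The truth SAM encodes the
#' true spliced placements with N CIGAR operations, MAPQ 50 for unique
#' placements and MAPQ 0 plus a secondary record for reads lying entirely
#' within duplicated sequence.
#'
#' @param ref A `sim_reference`.
#' @param outdir Directory to write FASTQ (one per sample), SAM (one per
#'   sample), the truth table and the sample sheet into.
#' @return List: `reads` (named list of character vectors per sample),
#'   `sam_paths` (named), `truth` (events with per-sample planted junction
#'   counts), `samples` (sample sheet data.table), `junction_tally`.
#' @export
simulate_reads <- function(ref, outdir) {
  config <- ref$config
  set.seed(config$seed + 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  samples <- as.vector(t(outer(seq_len(2L), seq_len(config$replicates),
                               function(c, r) sprintf("c%dr%d", c, r))))
  rl <- config$read_len
  ins <- config$insert_len
  win <- 2L * (rl - 7L)  # fragment starts whose mates span a junction >=4 nt

  reads_acc <- setNames(rep(list(list()), length(samples)), samples)
  sam_acc <- setNames(rep(list(list()), length(samples)), samples)
  tally <- list()

  for (iso in ref$isoforms) {
    blocks <- iso$blocks
    widths <- blocks$end - blocks$start + 1L
    L <- sum(widths)
    if (L < ins + 1L) stop("isoform shorter than insert length: ", iso$iso_id)
    iso_seq <- paste(vapply(seq_len(nrow(blocks)), function(i)
      genome_seq(ref$genome, "chr1", blocks$start[i], blocks$end[i]),
      character(1)), collapse = "")
    cum <- cumsum(widths)
    for (si in seq_along(samples)) {
      s <- samples[si]
      cond <- as.integer(substring(s, 2L, 2L))
      if (!is.null(iso$fixed_n)) {
        n <- if (!is.null(names(iso$fixed_n))) {
          if (s %in% names(iso$fixed_n)) iso$fixed_n[[s]] else 0L
        } else as.integer(iso$fixed_n)
      } else {
        w <- if (cond == 1L) iso$w1 else iso$w2
        mu <- w * config$coverage * (L - ins + 1L) / win
        n <- if (mu <= 0) 0L else
          rnbinom(1L, mu = mu, size = 1 / config$dispersion)
      }
      if (n == 0L) next
      u <- if (!is.null(iso$fixed_u)) as.integer(iso$fixed_u[seq_len(n)]) else
        sample.int(L - ins + 1L, n, replace = TRUE)
      mq <- if (isTRUE(iso$mapq0)) 0L else 50L
      batch_reads <- character(2L * n)
      batch_sam <- vector("list", n)
      batch_jx <- vector("list", n)
      for (fi in seq_len(n)) {
        qn <- paste0(iso$iso_id, ".", s, ".", fi)
        r1 <- emit_mate(ref, iso, iso_seq, blocks, cum, u[fi], rl, config)
        r2 <- emit_mate(ref, iso, iso_seq, blocks, cum, u[fi] + ins - rl, rl,
                        config)
        # FASTQ: mate 2 is sequenced from the opposite strand
        # (reverse complement applied in one batch below)
        batch_reads[2L * fi - 1L] <- r1$seq
        batch_reads[2L * fi] <- r2$seq
        lines <- c(sam_line(qn, 99L, r1, mq, r2$pos, ins),
                   sam_line(qn, 147L, r2, mq, r1$pos, -ins))
        if (isTRUE(iso$mapq0) && !is.na(iso$sec_offset)) {
          lines <- c(lines,
            sam_line(qn, 99L + 256L, shift_mate(r1, iso$sec_offset), 0L,
                     r2$pos + iso$sec_offset, ins),
            sam_line(qn, 147L + 256L, shift_mate(r2, iso$sec_offset), 0L,
                     r1$pos + iso$sec_offset, -ins))
        }
        batch_sam[[fi]] <- lines
        jx <- rbind(r1$jx, r2$jx)
        if (!is.null(jx) && nrow(jx)) batch_jx[[fi]] <- jx
      }
      even <- seq_len(n) * 2L
      batch_reads[even] <- revcomp(batch_reads[even])
      reads_acc[[s]][[length(reads_acc[[s]]) + 1L]] <- batch_reads
      sam_acc[[s]][[length(sam_acc[[s]]) + 1L]] <- unlist(batch_sam)
      jxm <- do.call(rbind, batch_jx[!vapply(batch_jx, is.null, logical(1))])
      if (!is.null(jxm) && nrow(jxm)) {
        tally[[length(tally) + 1L]] <- data.table(
          sample = s, lend = jxm[, 1L], rstart = jxm[, 2L])
      }
    }
  }
  reads <- lapply(reads_acc, function(x) unlist(x, use.names = FALSE))
  sam <- lapply(sam_acc, function(x) unlist(x, use.names = FALSE))
  jt <- if (length(tally)) {
    rbindlist(tally)[, .(count = .N), by = .(sample, lend, rstart)]
  } else data.table(sample = character(), lend = integer(),
                    rstart = integer(), count = integer())

  # truth junction counts per event and sample
  truth <- copy(ref$events)
  if (nrow(truth)) {
    for (s in samples) {
      jts <- jt[sample == s]
      cnt <- function(l, r) {
        v <- jts[lend == l & rstart == r, count]
        if (length(v)) v else 0L
      }
      truth[, paste0("incl_", s) := (cnt(up_end, skip_start) +
                                     cnt(skip_end, down_start)) / 2,
            by = event_id]
      truth[, paste0("excl_", s) := cnt(up_end, down_start), by = event_id]
    }
  }

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:chr1\tLN:",
                     sum(Biostrings::width(ref$genome$seqs))))
  sam_paths <- character()
  sheet <- list()
  for (s in samples) {
    fq <- file.path(outdir, paste0(s, ".fastq"))
    rs <- reads[[s]]
    writeLines(as.vector(rbind(paste0("@", s, ".", seq_along(rs)), rs, "+",
                               strrep("I", nchar(rs)))), fq)
    sp <- file.path(outdir, paste0(s, ".sam"))
    writeLines(c(header, sam[[s]]), sp)
    sam_paths[s] <- sp
    sheet[[length(sheet) + 1L]] <- data.table(
      sample = s, condition = as.integer(substring(s, 2L, 2L)),
      replicate = as.integer(substring(s, 4L, 4L)),
      fastq = paste0(s, ".fastq"), sam = paste0(s, ".sam"))
  }
  sheet <- rbindlist(sheet)
  fwrite(sheet, file.path(outdir, "samples.tsv"), sep = "\t")
  if (nrow(truth)) fwrite(truth, file.path(outdir, "truth.tsv"), sep = "\t")
  list(reads = reads, sam_paths = sam_paths, truth = truth, samples = sheet,
       junction_tally = jt)
}

# one mate: isoform coordinates [u, u+rl-1] -> genomic blocks, CIGAR, seq
emit_mate <- function(ref, iso, iso_seq, blocks, cum, u, rl, config) {
  s_tx <- u; e_tx <- u + rl - 1L
  bi <- findInterval(s_tx - 1L, cum) + 1L
  gb <- list()
  tpos <- s_tx
  while (tpos <= e_tx) {
    boff <- tpos - c(0L, cum)[bi] # 1-based offset into block bi
    gstart <- blocks$start[bi] + boff - 1L
    take <- min(e_tx, cum[bi]) - tpos + 1L
    gb[[length(gb) + 1L]] <- c(gstart, gstart + take - 1L)
    tpos <- tpos + take
    bi <- bi + 1L
  }
  gb <- do.call(rbind, gb)
  nb <- nrow(gb)
  w <- gb[, 2L] - gb[, 1L] + 1L
  if (nb == 1L) {
    cigar <- paste0(w, "M")
    jx <- NULL
  } else {
    gaps <- gb[-1L, 1L] - gb[-nb, 2L] - 1L
    cigar <- paste0(paste0(w[-nb], "M", gaps, "N", collapse = ""),
                    w[nb], "M")
    # count a junction only with >= 4 nt anchors on both sides
    ok <- w[-nb] >= 4L & w[-1L] >= 4L
    jx <- if (any(ok)) cbind(gb[-nb, 2L][ok], gb[-1L, 1L][ok]) else NULL
  }
  seq <- substring(iso_seq, s_tx, e_tx)
  if (config$error_rate > 0) {
    nmut <- rbinom(1L, rl, config$error_rate)
    if (nmut > 0L) seq <- mutate_seq(seq, nmut)
  }
  list(pos = gb[1L, 1L], cigar = cigar, seq = seq, jx = jx)
}

shift_mate <- function(r, offset) {
  r$pos <- r$pos + offset
  r
}

sam_line <- function(qname, flag, mate, mapq, pnext, tlen) {
  paste(qname, flag, "chr1", mate$pos, mapq, mate$cigar, "=", pnext, tlen,
        mate$seq, strrep("I", nchar(mate$seq)), sep = "\t")
}

#' Write the simulated reference to standard files
#'
#' @param ref A `sim_reference`.
#' @param outdir Output directory; writes `genome.fa`, `annotation.gtf`,
#'   `repeats.bed` (0-based half-open) and `genomic_exons.bed`.
#' @return Invisibly, a named vector of paths.
#' @export
write_reference <- function(ref, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(ref$genome$seqs, fa, width = 70L)
  gtf <- file.path(outdir, "annotation.gtf")
  a <- ref$annotation
  lines <- sprintf(
    "%s\tdualsplice_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    a$contig, a$start, a$end, a$strand, a$gene_id, a$transcript_id)
  writeLines(lines, gtf)
  bed <- file.path(outdir, "repeats.bed")
  rp <- ref$repeats
  writeLines(sprintf("%s\t%d\t%d\t%s", rp$contig, rp$start - 1L, rp$end,
                     rp$name), bed)
  geb <- file.path(outdir, "genomic_exons.bed")
  write_genomic_exons_bed(ref$model, geb)
  invisible(c(genome = fa, gtf = gtf, repeats = bed, genomic_exons = geb))
}

## ---------------------------------------------------------------------------
## Direct count-table simulation (for the differential layer)
## ---------------------------------------------------------------------------

#' Simulate a count table directly from the NB model
#'
#' Draws inclusion/exclusion junction counts for `n_events` events under
#' planted per-condition inclusion rates, bypassing read simulation. Used
#' for calibration and power checks of the differential test.
#'
#' @param n_events Number of events.
#' @param psi1,psi2 Inclusion rates (scalar or vector) per condition.
#' @param coverage Expected total junction count per replicate.
#' @param dispersion NB dispersion.
#' @param replicates Replicates per condition.
#' @param seed Integer seed.
#' @return A long-format count table (event_id, isoform, condition,
#'   replicate, count).
#' @export
simulate_count_table <- function(n_events, psi1 = 0.5, psi2 = psi1,
                                 coverage = 100, dispersion = 0.1,
                                 replicates = 2L, seed = 1L) {
  set.seed(seed)
  psi1 <- rep_len(psi1, n_events); psi2 <- rep_len(psi2, n_events)
  rows <- list()
  for (e in seq_len(n_events)) {
    for (cond in 1:2) {
      psi <- if (cond == 1L) psi1[e] else psi2[e]
      for (r in seq_len(replicates)) {
        inc <- rnbinom(1L, mu = coverage * psi, size = 1 / dispersion)
        exc <- rnbinom(1L, mu = coverage * (1 - psi), size = 1 / dispersion)
        rows[[length(rows) + 1L]] <- data.table(
          event_id = sprintf("sim%04d", e),
          isoform = c("inclusion", "exclusion"),
          condition = cond, replicate = r, count = c(inc, exc))
      }
    }
  }
  rbindlist(rows)
}
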