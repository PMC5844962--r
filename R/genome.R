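#' @import data.table
#' @importFrom methods is
NULL

#' Load a reference genome from FASTA
#'
#' Reads all contigs of a FASTA file into memory and case-normalises the
#' sequence to upper case. Only the nucleotide alphabet A/C/G/T/N is
#' accepted.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `genome`: a list with element `seqs`, a named
#'   [Biostrings::DNAStringSet] (one entry per contig).
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1L],
         " does not start a record ('>') in ", path)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate contig names in FASTA: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(seqs) <- nm
  if (any(Biostrings::width(seqs) == 0L)) stop("empty sequence in FASTA")
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  af <- Biostrings::alphabetFrequency(seqs)
  bad <- rowSums(af[, setdiff(colnames(af), c("A", "C", "G", "T", "N")),
                    drop = FALSE])
  if (any(bad > 0)) stop("non-ACGTN characters in contig(s): ",
                         paste(names(seqs)[bad > 0], collapse = ", "))
  structure(list(seqs = seqs), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$seqs), "contig(s),",
      sum(Biostrings::width(x$seqs)), "bp total\n")
  invisible(x)
}

#' Extract genomic sequence
#'
#' @param genome A `genome` object.
#' @param contig Contig name.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`; on `"-"` the reverse complement is returned.
#' @return Character scalar.
#' @export
genome_seq <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome$seqs)) stop("unknown contig: ", contig)
  s <- Biostrings::subseq(genome$seqs[[contig]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## ---------------------------------------------------------------------------
## Exon projection: transcript exons -> genomic exons
## ---------------------------------------------------------------------------

#' Project transcript exons onto genomic exons
#'
#' Collapses the transcript exons of each gene into a non-redundant set of
#' genomic exons. Transcript exons are grouped by transitive genomic overlap;
#' each group yields one genomic exon whose start is the leftmost start over
#' the group members that are not the first exon of their transcript (falling
#' back to the leftmost start overall when only first exons are present) and
#' whose end is the rightmost end over members that are not the last exon of
#' their transcript and that end before the next group (falling back to the
#' rightmost end overall). When a strict majority of the transcripts
#' containing both exons flanking an intron annotate that intron as retained
#' (a single transcript exon spanning both), the two exons and the intron are
#' emitted as one merged genomic exon flagged `is_merged_retention`.
#'
#' @param tx_exons A data.frame/data.table of transcript exons with columns
#'   `exon_id`, `transcript_id`, `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `is_first`, `is_last` (1-based inclusive coordinates).
#' @return A data.table of genomic exons with columns `gene_id`, `contig`,
#'   `start`, `end`, `strand`, `exon_index`, `source_exons` (list column),
#'   `alt_starts`, `alt_ends` (list columns of member boundaries) and
#'   `is_merged_retention`.
#' @export
project_exons <- function(tx_exons) {
  tx <- as.data.table(tx_exons)
  req <- c("transcript_id", "gene_id", "contig", "start", "end",
           "strand", "is_first", "is_last")
  miss <- setdiff(req, names(tx))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(tx) == 0L) stop("empty transcript-exon set")
  if (!"exon_id" %in% names(tx)) tx[, exon_id := paste0("te", .I)]
  out <- tx[, project_gene_exons(.SD), by = .(gene_id, contig, strand)]
  setcolorder(out, c("gene_id", "contig", "start", "end", "strand",
                     "exon_index", "source_exons", "alt_starts", "alt_ends",
                     "is_merged_retention"))
  out[]
}

# one gene's transcript exons -> its genomic exons (gene_id/contig/strand
# supplied by the grouping)
project_gene_exons <- function(tx) {
  tx <- copy(tx)[order(start, end)]
  # annotated introns of this gene (gaps between consecutive exons of a
  # transcript, transcript exons taken in coordinate order)
  introns <- tx[order(transcript_id, start),
                .(istart = head(end, -1L) + 1L, iend = tail(start, -1L) - 1L),
                by = transcript_id][iend >= istart]
  # single-linkage clustering by genomic overlap
  cummax_end <- cummax(tx$end)
  newgrp <- c(TRUE, tx$start[-1L] > head(cummax_end, -1L))
  tx[, cluster := cumsum(newgrp)]

  groups <- list()
  for (cl in unique(tx$cluster)) {
    m <- tx[cluster == cl]
    groups <- c(groups, split_retention_cluster(m, introns))
  }
  # groups is a list of lists(members=DT, merged=flag); order by start
  gstart <- vapply(groups, function(g) min(g$members$start), numeric(1))
  groups <- groups[order(gstart)]
  n <- length(groups)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    m <- groups[[i]]$members
    nxt_start <- if (i < n) min(groups[[i + 1L]]$members$start) else NA_integer_
    s_cand <- m[is_first == FALSE, start]
    s <- if (length(s_cand)) min(s_cand) else min(m$start)
    e_cand <- m[is_last == FALSE, end]
    if (!is.na(nxt_start)) e_cand <- e_cand[e_cand < nxt_start]
    e <- if (length(e_cand)) max(e_cand) else max(m$end)
    if (s > e) { s <- min(m$start); e <- max(m$end) }
    res[[i]] <- data.table(
      start = as.integer(s), end = as.integer(e),
      exon_index = i,
      source_exons = list(m$exon_id),
      alt_starts = list(sort(unique(m$start))),
      alt_ends = list(sort(unique(m$end))),
      is_merged_retention = isTRUE(groups[[i]]$merged))
  }
  rbindlist(res)
}

# Split an overlap cluster that is only held together by intron-retaining
# exons, unless retention is the majority annotation across the transcripts
# that contain both flanking exons.
split_retention_cluster <- function(m, introns) {
  if (nrow(m) == 1L) return(list(list(members = m, merged = FALSE)))
  # exons spanning a whole annotated intron are retention evidence
  spans_intron <- vapply(seq_len(nrow(m)), function(i) {
    any(introns$istart > m$start[i] & introns$iend < m$end[i])
  }, logical(1))
  core <- m[!spans_intron]
  if (nrow(core) == 0L) return(list(list(members = m, merged = TRUE)))
  # sub-cluster the non-spanning members
  core <- core[order(start, end)]
  newgrp <- c(TRUE, core$start[-1L] > head(cummax(core$end), -1L))
  core[, sub := cumsum(newgrp)]
  subs <- split(core, core$sub)
  if (length(subs) == 1L) return(list(list(members = m, merged = FALSE)))
  # decide merging between consecutive sub-clusters
  pieces <- list(list(members = subs[[1L]], merged = FALSE))
  for (j in seq_len(length(subs) - 1L)) {
    g1 <- pieces[[length(pieces)]]$members
    g2 <- subs[[j + 1L]]
    gap_lo <- max(g1$end) + 1L
    gap_hi <- min(g2$start) - 1L
    span_ex <- m[spans_intron][start < gap_lo & end > gap_hi]
    retainers <- unique(span_ex$transcript_id)
    both <- intersect(unique(g1$transcript_id), unique(g2$transcript_id))
    splicers <- setdiff(both, retainers)
    if (length(retainers) > length(splicers)) {
      merged <- rbind(g1, g2, span_ex, fill = TRUE)
      pieces[[length(pieces)]] <- list(members = merged, merged = TRUE)
    } else {
      pieces <- c(pieces, list(list(members = g2, merged = FALSE)))
    }
  }
  pieces
}

## ---------------------------------------------------------------------------
## GTF loading and the full gene model
## ---------------------------------------------------------------------------

#' Load a transcript annotation (GTF) into a gene model
#'
#' Parses exon features of an EnsEMBL-dialect GTF (attributes `gene_id` and
#' `transcript_id`), assembles transcripts, projects transcript exons into
#' genomic exons and derives the annotated splice-site and exon-exon junction
#' sets.
#'
#' @param path Path to a GTF file.
#' @param genome A `genome` object; exon contigs must exist in it.
#' @return An object of class `gene_model`: list with data.tables `exons`
#'   (transcript exons), `genomic_exons`, `junctions` (contig, lend, rstart,
#'   gene_id, n_tx), `genes` (spans) and site lookup tables.
#' @export
load_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    warning("no exon features in GTF: ", path)
    return(empty_gene_model())
  }
  ex <- data.table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id))
  if (any(is.na(ex$gene_id)) || any(is.na(ex$transcript_id)))
    stop("exon feature missing gene_id/transcript_id attribute")
  unknown <- setdiff(unique(ex$contig), names(genome$seqs))
  if (length(unknown)) stop("exon on unknown contig(s): ",
                            paste(unknown, collapse = ", "))
  build_gene_model(ex, genome)
}

empty_gene_model <- function() {
  structure(list(
    exons = data.table(), genomic_exons = data.table(),
    junctions = data.table(), genes = data.table(),
    donor_sites = data.table(), acceptor_sites = data.table()),
    class = "gene_model")
}

#' Build a gene model from a transcript-exon table
#'
#' Lower-level constructor used by [load_annotation()] and by the simulator.
#'
#' @param ex data.table with columns contig, start, end, strand, gene_id,
#'   transcript_id (one row per transcript exon).
#' @param genome A `genome` object (used only for validation, may be NULL).
#' @return A `gene_model` object.
#' @export
build_gene_model <- function(ex, genome = NULL) {
  ex <- as.data.table(ex)
  # per-transcript consistency and ranks
  bad <- ex[, .(nc = uniqueN(contig), ns = uniqueN(strand)), by = transcript_id]
  if (any(bad$nc > 1L)) stop("transcript spanning two contigs: ",
                             paste(bad[nc > 1L, transcript_id], collapse = ", "))
  if (any(bad$ns > 1L)) stop("transcript on both strands: ",
                             paste(bad[ns > 1L, transcript_id], collapse = ", "))
  setorder(ex, transcript_id, start)
  ovl <- ex[, .(ovl = .N > 1L && any(start[-1L] <= head(end, -1L))),
            by = transcript_id]
  if (any(ovl$ovl)) stop("transcript with overlapping exons: ",
                         paste(ovl[ovl == TRUE, transcript_id], collapse = ", "))
  # rank in transcript: 1 = 5'-most exon (rightmost on minus strand)
  ex[, coord_idx := seq_len(.N), by = transcript_id]
  ex[, n_ex := .N, by = transcript_id]
  ex[, rank := ifelse(strand == "-", n_ex - coord_idx + 1L, coord_idx)]
  ex[, is_first := rank == 1L]
  ex[, is_last := rank == n_ex]
  ex[, exon_id := paste0(transcript_id, ".", rank)]
  ex[, c("coord_idx", "n_ex") := NULL]

  genomic <- project_exons(ex)

  # annotated exon-exon junctions: consecutive exons in coordinate order
  jx <- ex[order(transcript_id, start),
           .(lend = head(end, -1L), rstart = tail(start, -1L),
             contig = contig[1L], strand = strand[1L], gene_id = gene_id[1L]),
           by = transcript_id]
  jx <- jx[rstart > lend + 1L]
  junctions <- if (nrow(jx)) {
    jx[, .(n_tx = uniqueN(transcript_id)),
       by = .(contig, lend, rstart, strand, gene_id)]
  } else {
    data.table(contig = character(), lend = integer(), rstart = integer(),
               strand = character(), gene_id = character(), n_tx = integer())
  }
  # splice sites: donor = exonic base adjacent to the intron on the 5' side
  # of the intron (gene-strand aware); stored on the forward axis
  donor_sites <- unique(rbind(
    jx[strand == "+", .(contig, pos = lend, strand)],
    jx[strand == "-", .(contig, pos = rstart, strand)]))
  acceptor_sites <- unique(rbind(
    jx[strand == "+", .(contig, pos = rstart, strand)],
    jx[strand == "-", .(contig, pos = lend, strand)]))

  genes <- ex[, .(start = min(start), end = max(end),
                  strand = strand[1L], contig = contig[1L],
                  n_transcripts = uniqueN(transcript_id)), by = gene_id]

  structure(list(exons = ex[], genomic_exons = genomic,
                 junctions = junctions, genes = genes,
                 donor_sites = donor_sites, acceptor_sites = acceptor_sites),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$genes), "gene(s),",
      if (nrow(x$exons)) uniqueN(x$exons$transcript_id) else 0L,
      "transcript(s),", nrow(x$genomic_exons), "genomic exon(s),",
      nrow(x$junctions), "annotated junction(s)\n")
  invisible(x)
}

#' Write projected genomic exons as BED6
#'
#' 0-based half-open intervals, name = `geneid.exonindex`.
#'
#' @param model A `gene_model`.
#' @param path Output BED path.
#' @return Invisibly, the path.
#' @export
write_genomic_exons_bed <- function(model, path) {
  ge <- model$genomic_exons
  bed <- data.table(chrom = ge$contig, chromStart = ge$start - 1L,
                    chromEnd = ge$end,
                    name = paste0(ge$gene_id, ".", ge$exon_index),
                    score = 0L, strand = ge$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# is junction (contig,lend,rstart) annotated in the model?
junction_annotated <- function(model, contig, lend, rstart) {
  jx <- model$junctions
  if (!nrow(jx)) return(logical(length(lend)))
  key <- paste(contig, lend, rstart)
  key %in% paste(jx$contig, jx$lend, jx$rstart)
}
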