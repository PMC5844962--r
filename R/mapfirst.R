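## Mapping-first caller: alignment filtering (primary, paired, MAPQ >= 10),
## CIGAR block decomposition, junction-read filters, junction annotation
## against projected exons, exon-skipping / intron-retention calling and
## junction-based quantification.

#' Read a SAM file into an alignment table
#'
#' @param path SAM file (headers required).
#' @return data.table with qname, flag, contig, pos, mapq, cigar.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM not found: ", path)
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.table(qname = b$qname, flag = b$flag,
             contig = as.character(b$rname), pos = b$pos,
             mapq = b$mapq, cigar = b$cigar)
}

#' Filter alignment records
#'
#' Keeps mapped, primary, paired records with mapping quality at least 10
#' (`samtools view -F 260 -f 1 -q 10` semantics); the MAPQ cutoff removes
#' multi-mapping reads.
#'
#' @param aln Alignment table from [read_sam()].
#' @param min_mapq Minimum mapping quality (default 10).
#' @return Filtered table.
#' @export
filter_alignments <- function(aln, min_mapq = 10L) {
  aln[bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
      bitwAnd(flag, 1L) == 1L & mapq >= min_mapq & !is.na(cigar)]
}

#' Decompose one alignment into blocks and junctions
#'
#' M/=/X advance read and genome; D advances the genome within a block; N
#' splits blocks and defines a junction; I is consumed on the read only; S
#' is recorded as soft-clip. Alignment blocks under `min_edge_block` nt at
#' the read extremities are removed (their junctions with them).
#'
#' @param pos 1-based leftmost mapping position.
#' @param cigar CIGAR string.
#' @param min_edge_block Minimum terminal block length (nt), default 4.
#' @return List: `blocks` (matrix start,end), `junctions` (data.table
#'   lend,rstart), `softclip`, `read_len`, `indels` (genomic positions of
#'   I/D operations), or NULL for an unusable CIGAR.
#' @export
extract_blocks <- function(pos, cigar, min_edge_block = 4L) {
  ops <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1L]]
  if (!length(ops)) return(NULL)
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  codes <- sub("^\\d+", "", ops)
  if (any(!codes %in% c("M", "=", "X", "I", "D", "N", "S", "H", "P")))
    return(NULL)
  g <- pos
  bstart <- pos
  blocks <- list()
  junctions <- list()
  softclip <- 0L
  read_len <- 0L
  indels <- integer()
  open <- FALSE
  for (i in seq_along(codes)) {
    op <- codes[i]; w <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (!open) { bstart <- g; open <- TRUE }
      g <- g + w; read_len <- read_len + w
    } else if (op == "D") {
      if (open) { indels <- c(indels, g); g <- g + w }
    } else if (op == "I") {
      indels <- c(indels, g); read_len <- read_len + w
    } else if (op == "N") {
      if (open) {
        blocks[[length(blocks) + 1L]] <- c(bstart, g - 1L)
        junctions[[length(junctions) + 1L]] <- c(g - 1L, g + w)
        open <- FALSE
      }
      g <- g + w
    } else if (op == "S") {
      softclip <- softclip + w; read_len <- read_len + w
    }
  }
  if (open) blocks[[length(blocks) + 1L]] <- c(bstart, g - 1L)
  bm <- do.call(rbind, blocks)
  jx <- if (length(junctions)) do.call(rbind, junctions) else
    matrix(integer(), ncol = 2L)
  # trim sub-threshold blocks at the read extremities
  repeat {
    if (is.null(bm) || nrow(bm) == 0L) break
    if (bm[1L, 2L] - bm[1L, 1L] + 1L < min_edge_block) {
      bm <- bm[-1L, , drop = FALSE]
      if (nrow(jx)) jx <- jx[-1L, , drop = FALSE]
      next
    }
    n <- nrow(bm)
    if (bm[n, 2L] - bm[n, 1L] + 1L < min_edge_block) {
      bm <- bm[-n, , drop = FALSE]
      if (nrow(jx)) jx <- jx[-nrow(jx), , drop = FALSE]
      next
    }
    break
  }
  if (is.null(bm) || nrow(bm) == 0L) return(NULL)
  list(blocks = bm,
       junctions = data.table(lend = jx[, 1L], rstart = jx[, 2L]),
       softclip = softclip, read_len = read_len, indels = indels)
}

#' Junction-read filters
#'
#' Drops a junction read when more than `max_softclip_frac` of it is
#' soft-clipped, when an indel lies within `indel_window` nt of a junction
#' (the junction position would be uncertain), or when its first or last
#' alignment block overlaps zero or several projected exons.
#'
#' @param bl Output of [extract_blocks()].
#' @param contig Contig of the record.
#' @param model A `gene_model`.
#' @param max_softclip_frac Maximum soft-clipped fraction (default 0.10).
#' @param indel_window Indel-to-junction proximity window in nt (default 5).
#' @return `list(keep=TRUE)` or `list(keep=FALSE, reason=...)`.
#' @export
filter_junction_read <- function(bl, contig, model,
                                 max_softclip_frac = 0.10,
                                 indel_window = 5L) {
  if (bl$softclip > max_softclip_frac * bl$read_len)
    return(list(keep = FALSE, reason = "softclip"))
  if (length(bl$indels) && nrow(bl$junctions)) {
    jpos <- c(bl$junctions$lend, bl$junctions$rstart)
    if (any(vapply(bl$indels, function(ip) any(abs(ip - jpos) <= indel_window),
                   logical(1))))
      return(list(keep = FALSE, reason = "indel-near-junction"))
  }
  ge <- model$genomic_exons
  ctg <- contig
  for (i in c(1L, nrow(bl$blocks))) {
    b <- bl$blocks[i, ]
    n_ov <- nrow(ge[contig == ctg & start <= b[2L] & end >= b[1L]])
    if (n_ov != 1L)
      return(list(keep = FALSE, reason = "block-exon-overlap"))
  }
  list(keep = TRUE)
}

#' Annotate junctions against the exon model
#'
#' Each junction boundary is compared to the annotated exon boundaries;
#' junctions where both sides are novel with equal (within 1 nt) shifts
#' from the nearest annotated boundaries on opposite sides are discarded as
#' mapping artifacts.
#'
#' @param jx Junction table (contig, lend, rstart, per-sample counts).
#' @param model A `gene_model`.
#' @param symmetry_tol Shift tolerance of the symmetry filter (nt).
#' @return Junction table with `status` (annotated / novel-donor /
#'   novel-acceptor / both-novel / discarded) and `annotated` flag.
#' @export
annotate_junction <- function(jx, model, symmetry_tol = 1L) {
  mj <- model$junctions
  ann_l <- if (nrow(mj)) unique(mj[, .(contig, pos = lend)]) else
    data.table(contig = character(), pos = integer())
  ann_r <- if (nrow(mj)) unique(mj[, .(contig, pos = rstart)]) else
    data.table(contig = character(), pos = integer())
  out <- copy(jx)
  nearest_shift <- function(tab, ctg, p) {
    cand <- tab[contig == ctg, pos]
    if (!length(cand)) return(NA_integer_)
    d <- p - cand
    d[which.min(abs(d))]
  }
  res <- lapply(seq_len(nrow(out)), function(i) {
    ctg <- out$contig[i]; l <- out$lend[i]; r <- out$rstart[i]
    l_ann <- nrow(ann_l[contig == ctg & pos == l]) > 0L
    r_ann <- nrow(ann_r[contig == ctg & pos == r]) > 0L
    gstrand <- junction_gene_strand(model, ctg, l, r)
    left_role <- if (!is.na(gstrand) && gstrand == "-") "acceptor" else "donor"
    if (l_ann && r_ann) return(list(status = "annotated", ann = TRUE))
    if (!l_ann && !r_ann) {
      sl <- nearest_shift(ann_l, ctg, l)
      sr <- nearest_shift(ann_r, ctg, r)
      if (!is.na(sl) && !is.na(sr) && abs(sl - sr) <= symmetry_tol)
        return(list(status = "discarded", ann = FALSE))
      return(list(status = "both-novel", ann = FALSE))
    }
    novel_side <- if (!l_ann) "left" else "right"
    role <- if (novel_side == "left") left_role else
      if (left_role == "donor") "acceptor" else "donor"
    list(status = paste0("novel-", role), ann = FALSE)
  })
  out[, status := vapply(res, `[[`, character(1), "status")]
  out[, annotated := vapply(res, `[[`, logical(1), "ann")]
  out[]
}

junction_gene_strand <- function(model, ctg, l, r) {
  if (!nrow(model$genes)) return(NA_character_)
  g <- model$genes[contig == ctg & start <= l & end >= r]
  if (nrow(g) == 1L) g$strand else if (nrow(g) > 1L &&
                                       uniqueN(g$strand) == 1L) g$strand[1L]
  else NA_character_
}

#' Detect intron retention evidence from alignment blocks
#'
#' A block continuously spanning an exon-intron boundary contributes to the
#' retention count of that intron.
#'
#' @param blocks data.table of kept alignment blocks (contig, start, end,
#'   sample).
#' @param model A `gene_model`.
#' @return data.table per intron and sample: gene_id, intron_lend (last
#'   exonic base), intron_rstart, count.
#' @export
detect_intron_retention <- function(blocks, model) {
  ge <- model$genomic_exons
  if (!nrow(ge) || !nrow(blocks)) {
    return(data.table(gene_id = character(), contig = character(),
                      intron_lend = integer(), intron_rstart = integer(),
                      sample = character(), count = integer()))
  }
  introns <- ge[order(gene_id, start),
                .(contig = contig[-.N], intron_lend = head(end, -1L),
                  intron_rstart = tail(start, -1L)), by = gene_id]
  introns <- introns[intron_rstart > intron_lend + 1L]
  out <- list()
  for (i in seq_len(nrow(introns))) {
    itr <- introns[i]
    hit <- blocks[contig == itr$contig &
                  ((start <= itr$intron_lend & end > itr$intron_lend) |
                   (start < itr$intron_rstart & end >= itr$intron_rstart))]
    if (!nrow(hit)) next
    cnt <- hit[, .(count = uniqueN(read_id)), by = sample]
    out[[length(out) + 1L]] <- data.table(
      gene_id = itr$gene_id, contig = itr$contig,
      intron_lend = itr$intron_lend, intron_rstart = itr$intron_rstart,
      sample = cnt$sample, count = cnt$count)
  }
  if (!length(out)) {
    return(data.table(gene_id = character(), contig = character(),
                      intron_lend = integer(), intron_rstart = integer(),
                      sample = character(), count = integer()))
  }
  rbindlist(out)
}

## ---------------------------------------------------------------------------
## Event calling from the junction table
## ---------------------------------------------------------------------------

# map transcripts of a gene to ordered genomic-exon indices
transcript_genomic_paths <- function(model, gene) {
  ge <- model$genomic_exons[gene_id == gene][order(start)]
  map <- data.table(exon_id = unlist(ge$source_exons),
                    gidx = rep(ge$exon_index, lengths(ge$source_exons)))
  ex <- model$exons[gene_id == gene][order(start)]
  ex <- map[ex, on = "exon_id"]
  split(ex$gidx, ex$transcript_id)
}

#' Call exon-skipping events from counted junctions
#'
#' Every covered junction whose genomic span contains at least one projected
#' exon defines candidate skipping events. If the junction is annotated, one
#' event is emitted per annotated combination of flanking exons and skipped
#' exon(s) (transcripts containing both flanks with exons in between); a
#' junction absent from the annotation is annotated with the longest covered
#' inclusion isoform. Events skipping several exons are typed
#' multi-exon-skipping.
#'
#' @param jx Annotated junction table ([annotate_junction()]; discarded
#'   junctions ignored) with per-sample count columns `n_<sample>`.
#' @param model A `gene_model`.
#' @return Event table in the shared schema with per-sample `incl_` /
#'   `excl_` columns ([quantify_event()] applied).
#' @export
call_skipped_exons <- function(jx, model) {
  samples <- sub("^n_", "", grep("^n_", names(jx), value = TRUE))
  jx_use <- jx[status != "discarded"]
  rows <- list()
  ge_all <- model$genomic_exons
  for (i in seq_len(nrow(jx_use))) {
    ctg <- jx_use$contig[i]; l <- jx_use$lend[i]; r <- jx_use$rstart[i]
    ge <- ge_all[contig == ctg]
    up <- ge[vapply(alt_ends, function(v) l %in% v, logical(1))]
    dn <- ge[vapply(alt_starts, function(v) r %in% v, logical(1))]
    cand <- merge(up[, .(gene_id, up_idx = exon_index)],
                  dn[, .(gene_id, dn_idx = exon_index)], by = "gene_id")
    for (ci in seq_len(nrow(cand))) {
      gene <- cand$gene_id[ci]
      geg <- ge[gene_id == gene]
      interior <- geg[start > l & end < r, exon_index]
      if (!length(interior)) next
      upx <- cand$up_idx[ci]; dnx <- cand$dn_idx[ci]
      paths <- transcript_genomic_paths(model, gene)
      skipped_sets <- list()
      if (junction_annotated(model, ctg, l, r)) {
        for (p in paths) {
          iu <- match(upx, p); id <- match(dnx, p)
          if (is.na(iu) || is.na(id) || id <= iu + 1L) next
          skipped_sets[[length(skipped_sets) + 1L]] <- p[(iu + 1L):(id - 1L)]
        }
        skipped_sets <- unique(skipped_sets)
        skipped_sets <- Filter(function(s) all(s %in% interior), skipped_sets)
      } else {
        # longest covered inclusion isoform: chain of covered junctions
        # through the interior exons with the most exons (ties: extent)
        skipped_sets <- longest_covered_chain(jx_use, geg, upx, dnx, interior)
      }
      for (sk in skipped_sets) {
        sk_ex <- geg[exon_index %in% sk][order(start)]
        rows[[length(rows) + 1L]] <- data.table(
          type = if (length(sk) > 1L) "multi-exon-skipping" else
            "skipped-exon",
          gene_id = gene, contig = ctg, strand = geg$strand[1L],
          skip_start = sk_ex$start[1L], skip_end = sk_ex$end[nrow(sk_ex)],
          up_end = l, down_start = r,
          up_idx = upx, dn_idx = dnx,
          sk_first = sk[1L], sk_last = sk[length(sk)])
      }
    }
  }
  if (!length(rows)) return(data.table())
  ev <- unique(rbindlist(rows))
  ev <- quantify_event(ev, jx, model, samples)
  setorder(ev, contig, up_end, skip_start)
  ev[, event_id := sprintf("map%03d", .I)]
  setcolorder(ev, c("event_id", "type", "gene_id", "contig", "strand",
                    "skip_start", "skip_end", "up_end", "down_start"))
  ev[]
}

# chains of covered inclusion junctions through the interior exons
longest_covered_chain <- function(jx, geg, upx, dnx, interior) {
  covered <- function(a_idx, b_idx) {
    ea <- geg[exon_index == a_idx]; eb <- geg[exon_index == b_idx]
    combos <- CJ(l = ea$alt_ends[[1L]], r = eb$alt_starts[[1L]])
    any(jx[combos, on = .(lend = l, rstart = r), nomatch = 0L, which = TRUE] > 0L)
  }
  nodes <- sort(interior)
  best <- NULL
  # depth-first over increasing exon chains
  explore <- function(chain, last_idx) {
    if (covered(last_idx, dnx) && length(chain)) {
      if (is.null(best) || length(chain) > length(best)) best <<- chain
    }
    for (nx in nodes[nodes > last_idx]) {
      if (covered(last_idx, nx)) explore(c(chain, nx), nx)
    }
  }
  explore(integer(), upx)
  if (is.null(best)) list() else list(best)
}

#' Quantify events by junction reads
#'
#' The exclusion count is the exclusion-junction read count; the inclusion
#' count is the mean of the two inclusion-junction counts, each being the
#' sum over all annotated alternative donors/acceptors of that junction.
#' Only junction reads are counted.
#'
#' @param ev Event table with `up_idx`, `dn_idx`, `sk_first`, `sk_last`.
#' @param jx Junction table with per-sample counts `n_<sample>`.
#' @param model A `gene_model`.
#' @param samples Sample names.
#' @return `ev` with `incl_<sample>` and `excl_<sample>` columns.
#' @export
quantify_event <- function(ev, jx, model, samples) {
  ge_all <- model$genomic_exons
  jsum <- function(ctg, lends, rstarts, s) {
    combos <- CJ(l = lends, r = rstarts)
    hit <- jx[contig == ctg][combos, on = .(lend = l, rstart = r),
                             nomatch = 0L]
    if (!nrow(hit)) 0 else sum(hit[[paste0("n_", s)]])
  }
  ev <- copy(ev)
  for (i in seq_len(nrow(ev))) {
    geg <- ge_all[gene_id == ev$gene_id[i]]
    up <- geg[exon_index == ev$up_idx[i]]
    dn <- geg[exon_index == ev$dn_idx[i]]
    skf <- geg[exon_index == ev$sk_first[i]]
    skl <- geg[exon_index == ev$sk_last[i]]
    for (s in samples) {
      i1 <- jsum(ev$contig[i], up$alt_ends[[1L]], skf$alt_starts[[1L]], s)
      i2 <- jsum(ev$contig[i], skl$alt_ends[[1L]], dn$alt_starts[[1L]], s)
      xx <- jsum(ev$contig[i], up$alt_ends[[1L]], dn$alt_starts[[1L]], s)
      ev[i, paste0("incl_", s) := (i1 + i2) / 2]
      ev[i, paste0("excl_", s) := xx]
    }
  }
  ev[]
}

## ---------------------------------------------------------------------------
## Orchestration
## ---------------------------------------------------------------------------

#' Run the mapping-first caller on per-sample SAM files
#'
#' @param sam_paths Named character vector of SAM paths (names = samples).
#' @param model A `gene_model`.
#' @param min_mapq Minimum mapping quality.
#' @param max_softclip_frac,indel_window,min_edge_block Junction-read filter
#'   parameters.
#' @return List: `events` (ES events, shared schema), `ir` (intron-retention
#'   evidence), `junctions` (annotated junction table with per-sample
#'   counts), `drop_log` (per-sample drop reasons).
#' @export
mapfirst_events <- function(sam_paths, model, min_mapq = 10L,
                           max_softclip_frac = 0.10, indel_window = 5L,
                           min_edge_block = 4L) {
  samples <- names(sam_paths)
  tallies <- list()
  drop_log <- list()
  all_blocks <- list()
  for (s in samples) {
    aln <- filter_alignments(read_sam(sam_paths[[s]]), min_mapq)
    for (i in seq_len(nrow(aln))) {
      bl <- extract_blocks(aln$pos[i], aln$cigar[i], min_edge_block)
      if (is.null(bl)) {
        drop_log[[length(drop_log) + 1L]] <- data.table(
          sample = s, qname = aln$qname[i], reason = "bad-cigar")
        next
      }
      if (nrow(bl$junctions)) {
        fl <- filter_junction_read(bl, aln$contig[i], model,
                                   max_softclip_frac, indel_window)
        if (!fl$keep) {
          drop_log[[length(drop_log) + 1L]] <- data.table(
            sample = s, qname = aln$qname[i], reason = fl$reason)
          next
        }
        tallies[[length(tallies) + 1L]] <- data.table(
          sample = s, contig = aln$contig[i],
          lend = bl$junctions$lend, rstart = bl$junctions$rstart)
      }
      all_blocks[[length(all_blocks) + 1L]] <- data.table(
        read_id = paste0(s, ":", aln$qname[i], ":", aln$flag[i]),
        sample = s, contig = aln$contig[i],
        start = bl$blocks[, 1L], end = bl$blocks[, 2L])
    }
  }
  jt <- if (length(tallies)) {
    rbindlist(tallies)[, .(count = .N), by = .(sample, contig, lend, rstart)]
  } else data.table(sample = character(), contig = character(),
                    lend = integer(), rstart = integer(), count = integer())
  jx <- if (nrow(jt)) {
    dcast(jt, contig + lend + rstart ~ sample, value.var = "count",
          fill = 0L)
  } else data.table(contig = character(), lend = integer(),
                    rstart = integer())
  for (s in samples) {
    if (!s %in% names(jx)) jx[, (s) := 0L]
    setnames(jx, s, paste0("n_", s))
  }
  jx <- annotate_junction(jx, model)
  events <- call_skipped_exons(jx, model)
  blocks <- if (length(all_blocks)) rbindlist(all_blocks) else
    data.table(read_id = character(), sample = character(),
               contig = character(), start = integer(), end = integer())
  ir <- detect_intron_retention(blocks, model)
  list(events = events, ir = ir, junctions = jx,
       drop_log = if (length(drop_log)) rbindlist(drop_log) else
         data.table(sample = character(), qname = character(),
                    reason = character()))
}
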