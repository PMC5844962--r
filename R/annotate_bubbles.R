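## Annotation of assembled bubbles against the reference genome:
## exact seed-and-extend spliced alignment of each bubble path, block-count
## classification into AS event types, splice-site status against the
## annotation, and exact/inexact repeat separation.

# longest exact common prefix of s[spos..] and contig[gpos..]
match_run <- function(s, spos, cseq, gpos) {
  n <- nchar(s); m <- nchar(cseq)
  len <- 0L
  chunk <- 64L
  while (spos + len <= n && gpos + len <= m) {
    a <- substring(s, spos + len, min(n, spos + len + chunk - 1L))
    b <- substring(cseq, gpos + len, min(m, gpos + len + nchar(a) - 1L))
    if (nchar(b) < nchar(a)) a <- substring(a, 1L, nchar(b))
    if (!nzchar(a)) break
    if (a == b) { len <- len + nchar(a); next }
    # binary-free scan of the differing chunk
    ac <- strsplit(a, "")[[1L]]; bc <- strsplit(b, "")[[1L]]
    same <- which(ac != bc)[1L] - 1L
    if (is.na(same)) same <- length(ac)
    return(len + same)
  }
  len
}

# greedy spliced extension of path s (from its first base) anchored at
# genomic position pos; returns a block matrix or NULL
extend_right <- function(s, cseq, pos, min_intron = 30L,
                         max_gap_search = 5e5L, initial_gap_ok = FALSE) {
  n <- nchar(s)
  # candidate genomic starts for the block beginning at path position spos,
  # at least min_intron beyond g_from; shorter seeds allow crossing exons
  # shorter than the default seek seed
  seek <- function(spos, g_from) {
    from <- g_from + min_intron
    to <- min(nchar(cseq), g_from + max_gap_search)
    if (from > to) return(integer())
    win <- substring(cseq, from, to)
    hits <- integer()
    for (sl in unique(pmin(c(20L, 12L, 8L), n - spos + 1L))) {
      seed <- substring(s, spos, spos + sl - 1L)
      m <- gregexpr(seed, win, fixed = TRUE)[[1L]]
      if (m[1L] > 0L) hits <- c(hits, from + as.integer(m) - 1L)
    }
    hits <- sort(unique(hits))
    if (!length(hits)) return(integer())
    # prefer acceptor-like targets (AG immediately upstream), nearest first
    ag <- substring(cseq, pmax(1L, hits - 2L), pmax(1L, hits - 1L)) == "AG"
    hits <- c(hits[ag], hits[!ag])
    hits[seq_len(min(10L, length(hits)))]
  }
  extend_from <- function(spos, g) {
    run <- match_run(s, spos, cseq, g)
    if (run < 1L) return(NULL)
    if (spos + run > n) return(list(c(g, g + run - 1L)))
    # the block end is ambiguous when the intron starts like the next
    # exon: try donor-like ends (GT right after the block) first
    runs <- unique(pmax(1L, c(run, run - 1L, run - 2L)))
    gt <- substring(cseq, g + runs, g + runs + 1L) == "GT"
    runs <- c(runs[gt], runs[!gt])
    for (ru in runs) {
      for (h in seek(spos + ru, g + ru)) {
        rest <- extend_from(spos + ru, h)
        if (!is.null(rest)) return(c(list(c(g, g + ru - 1L)), rest))
      }
    }
    NULL
  }
  blocks <- if (initial_gap_ok && match_run(s, 1L, cseq, pos) < 1L) {
    res <- NULL
    for (h in seek(1L, pos)) {
      res <- extend_from(1L, h)
      if (!is.null(res)) break
    }
    res
  } else {
    extend_from(1L, pos)
  }
  if (is.null(blocks)) return(NULL)
  do.call(rbind, blocks)
}

# anchored bidirectional spliced extension: path position `anchor` matches
# genomic position `gpos`; the part left of the anchor is aligned on the
# reversed strings
extend_spliced <- function(s, cseq, anchor, gpos, cseq_rev,
                           min_intron = 30L) {
  n <- nchar(s); m <- nchar(cseq)
  right <- extend_right(substring(s, anchor, n), cseq, gpos, min_intron)
  if (is.null(right)) return(NULL)
  gb <- right
  if (anchor > 1L) {
    s_rev <- reverse_str(substring(s, 1L, anchor - 1L))
    left_rev <- extend_right(s_rev, cseq_rev, m - (gpos - 1L) + 1L,
                             min_intron, initial_gap_ok = TRUE)
    if (is.null(left_rev)) return(NULL)
    left <- cbind(m - left_rev[, 2L] + 1L, m - left_rev[, 1L] + 1L)
    left <- left[rev(seq_len(nrow(left))), , drop = FALSE]
    # the block adjoining the anchor is contiguous with the first right
    # block: merge them
    if (left[nrow(left), 2L] == gb[1L, 1L] - 1L) {
      gb[1L, 1L] <- left[nrow(left), 1L]
      left <- left[-nrow(left), , drop = FALSE]
    }
    if (nrow(left)) gb <- rbind(left, gb)
  }
  gb <- wobble_junctions(s, cseq, gb)
  gb
}

reverse_str <- function(x) {
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

# shift junctions within the alignment-ambiguity window (either direction)
# to prefer canonical GT..AG introns
wobble_junctions <- function(s, cseq, gb) {
  if (nrow(gb) > 1L) {
    for (i in seq_len(nrow(gb) - 1L)) {
      spos_ends <- cumsum(gb[, 2L] - gb[, 1L] + 1L)
      e <- gb[i, 2L]; s2 <- gb[i + 1L, 1L]
      if (substring(cseq, e + 1L, e + 2L) == "GT" &&
          substring(cseq, s2 - 2L, s2 - 1L) == "AG") next
      pe <- spos_ends[i]
      wmax <- 10L
      cand <- as.integer(outer(seq_len(wmax), c(-1L, 1L)))[
        order(rep(seq_len(wmax), 2L))]
      for (d in cand) {
        if (d < 0L) {  # move junction left: block i shrinks
          if (-d > gb[i, 2L] - gb[i, 1L]) next
          # the moved path bases must match the other side of the junction
          if (substring(s, pe + d + 1L, pe) !=
              substring(cseq, s2 + d, s2 - 1L)) next
        } else {       # move junction right: block i grows
          if (d > gb[i + 1L, 2L] - gb[i + 1L, 1L]) next
          if (substring(s, pe + 1L, pe + d) !=
              substring(cseq, e + 1L, e + d)) next
        }
        if (substring(cseq, e + d + 1L, e + d + 2L) == "GT" &&
            substring(cseq, s2 + d - 2L, s2 + d - 1L) == "AG") {
          gb[i, 2L] <- e + d; gb[i + 1L, 1L] <- s2 + d
          break
        }
      }
    }
  }
  gb
}

#' Align a bubble path to the genome (toy spliced aligner)
#'
#' Exact-match seed-and-extend spliced alignment: maximal exact blocks
#' separated by gaps of at least `min_intron` nt; junction boundaries are
#' shifted within the ambiguity window to prefer canonical GT-AG introns.
#' All equally best loci (complete alignments with the minimal number of
#' blocks) are returned, on both strands.
#'
#' @param seq Path sequence.
#' @param genome A `genome` object.
#' @param min_intron Minimum gap length treated as an intron (nt).
#' @return data.table with one row per alignment: `contig`, `strand`,
#'   `nblocks`, `blocks` (list column of two-column matrices),
#'   `multi` (TRUE when several equally best loci exist); zero rows when
#'   the path does not align.
#' @export
align_path <- function(seq, genome, min_intron = 30L) {
  res <- list()
  seed_len <- 15L
  for (contig in names(genome$seqs)) {
    cseq <- as.character(genome$seqs[[contig]])
    cseq_rev <- reverse_str(cseq)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else revcomp(seq)
      n <- nchar(s)
      found <- FALSE
      for (sl in c(seed_len, 12L, 10L)) {
        if (sl > n) next
        last_off <- max(1L, n - sl + 1L)
        step <- if (sl == seed_len) 16L else 4L
        offsets <- unique(c(seq(1L, last_off, by = step), last_off))
        for (off in offsets) {
          seed <- substring(s, off, off + sl - 1L)
          hits <- Biostrings::start(Biostrings::matchPattern(
            seed, Biostrings::DNAString(cseq)))
          for (h in hits) {
            gb <- extend_spliced(s, cseq, off, h, cseq_rev, min_intron)
            if (is.null(gb)) next
            if (sum(gb[, 2L] - gb[, 1L] + 1L) != n) next
            found <- TRUE
            res[[length(res) + 1L]] <- data.table(
              contig = contig, strand = strand, nblocks = nrow(gb),
              start = gb[1L, 1L], blocks = list(gb))
          }
          if (found) break
        }
        if (found) break
      }
    }
  }
  if (!length(res)) {
    return(data.table(contig = character(), strand = character(),
                      nblocks = integer(), start = integer(),
                      blocks = list(), multi = logical()))
  }
  al <- rbindlist(res)
  al <- al[nblocks == min(nblocks)]
  al <- unique(al, by = c("contig", "strand", "start"))
  setorder(al, contig, start, strand)
  al[, multi := .N > 1L]
  al[]
}

# strip alignment blocks shared by both paths from both ends
strip_common_blocks <- function(ub, lb) {
  nu <- nrow(ub); nl <- nrow(lb)
  p <- 0L
  while (p < min(nu, nl) && all(ub[p + 1L, ] == lb[p + 1L, ])) p <- p + 1L
  s <- 0L
  while (s < min(nu, nl) - p &&
         all(ub[nu - s, ] == lb[nl - s, ])) s <- s + 1L
  list(p = p, s = s, urem = nu - p - s, lrem = nl - p - s)
}

#' Classify a bubble from the block patterns of its two path alignments
#'
#' The block-count signature determines the event type: a path pair with the
#' same outer boundaries where the longer path has one extra internal block
#' is an exon skipping; one block against two blocks separates genomic
#' deletions from intron retentions by the gap length against
#' `ir_threshold`; two against one is a genomic insertion; equal block
#' counts differing at a single inner boundary are alternative donor or
#' acceptor sites, oriented by gene strand. When a flanking exon is shorter
#' than k the block count rises on both paths but the block-count
#' difference, which the classification relies on, is unchanged.
#'
#' @param upper,lower Single alignments (one row of [align_path()] output).
#' @param model A `gene_model` for gene assignment and strand.
#' @param ir_threshold Gap length (nt) below which a one-vs-two-block bubble
#'   is a genomic deletion and above which an intron retention; default 50.
#' @return One-row data.table: `type`, `gene_id`, `contig`, `strand`,
#'   `skip_start`, `skip_end`, `up_end`, `down_start`, `reason`.
#' @export
classify_bubble <- function(upper, lower, model, ir_threshold = 50L) {
  out <- data.table(type = "unclassified", gene_id = NA_character_,
                    contig = NA_character_, strand = NA_character_,
                    skip_start = NA_integer_, skip_end = NA_integer_,
                    up_end = NA_integer_, down_start = NA_integer_,
                    reason = NA_character_)
  if (upper$contig != lower$contig) {
    out[, reason := "paths align to different contigs"]
    return(out)
  }
  ub <- upper$blocks[[1L]]; lb <- lower$blocks[[1L]]
  ctg <- upper$contig
  outer_lo <- min(ub[1L, 1L], lb[1L, 1L])
  outer_hi <- max(ub[nrow(ub), 2L], lb[nrow(lb), 2L])
  genes <- overlapping_genes(model, ctg, outer_lo, outer_hi)
  gid <- if (length(genes)) paste(genes, collapse = ",") else NA_character_
  gstrand <- gene_strand(model, genes)
  out[, `:=`(contig = ctg, gene_id = gid, strand = gstrand)]

  same_outer <- ub[1L, 1L] == lb[1L, 1L] &&
    ub[nrow(ub), 2L] == lb[nrow(lb), 2L]
  if (nrow(ub) == 1L && nrow(lb) == 2L && same_outer) {
    gap <- lb[2L, 1L] - lb[1L, 2L] - 1L
    out[, `:=`(type = if (gap < ir_threshold) "genomic-deletion"
               else "intron-retention",
               up_end = lb[1L, 2L], down_start = lb[2L, 1L],
               skip_start = lb[1L, 2L] + 1L, skip_end = lb[2L, 1L] - 1L)]
    return(out)
  }
  if (nrow(ub) == 2L && nrow(lb) == 1L && same_outer) {
    out[, `:=`(type = "genomic-insertion",
               up_end = ub[1L, 2L], down_start = ub[2L, 1L])]
    return(out)
  }
  st <- strip_common_blocks(ub, lb)
  if (st$lrem == 0L && st$urem >= 1L && st$p >= 1L && st$s >= 1L) {
    sk <- ub[(st$p + 1L):(st$p + st$urem), , drop = FALSE]
    out[, `:=`(type = "exon-skipping",
               skip_start = sk[1L, 1L], skip_end = sk[nrow(sk), 2L],
               up_end = ub[st$p, 2L],
               down_start = ub[st$p + st$urem + 1L, 1L])]
    return(out)
  }
  if (st$urem == 1L && st$lrem == 1L && (st$p >= 1L || st$s >= 1L)) {
    bu <- ub[st$p + 1L, ]; bl <- lb[st$p + 1L, ]
    if (bu[2L] == bl[2L] && bu[1L] != bl[1L]) {
      # variable inner boundary on the right (3') side of the junction
      tp <- if (is.na(gstrand)) "alt-boundary-unoriented"
      else if (gstrand == "+") "alt-acceptor" else "alt-donor"
      out[, `:=`(type = tp, up_end = ub[st$p, 2L],
                 down_start = max(bu[1L], bl[1L]),
                 skip_start = min(bu[1L], bl[1L]),
                 skip_end = max(bu[1L], bl[1L]) - 1L)]
      return(out)
    }
    if (bu[1L] == bl[1L] && bu[2L] != bl[2L]) {
      tp <- if (is.na(gstrand)) "alt-boundary-unoriented"
      else if (gstrand == "+") "alt-donor" else "alt-acceptor"
      out[, `:=`(type = tp, up_end = min(bu[2L], bl[2L]),
                 down_start = ub[st$p + 2L, 1L],
                 skip_start = min(bu[2L], bl[2L]) + 1L,
                 skip_end = max(bu[2L], bl[2L]))]
      return(out)
    }
  }
  out[, reason := "block pattern not recognised"]
  out
}

overlapping_genes <- function(model, ctg, lo, hi) {
  ge <- model$genomic_exons
  if (!nrow(ge)) return(character())
  sort(unique(ge[contig == ctg & start <= hi & end >= lo, gene_id]))
}

gene_strand <- function(model, genes) {
  if (!length(genes) || !nrow(model$genes)) return(NA_character_)
  st <- unique(model$genes[gene_id %in% genes, strand])
  if (length(st) == 1L) st else NA_character_
}

#' Flag the splice sites of a classified event as annotated or novel
#'
#' Each donor/acceptor of the event's junctions is looked up in the
#' annotated site sets; novel sites are reported with the genomic
#' dinucleotides at the intron boundaries (strand-aware: GT-AG for a
#' canonical intron).
#'
#' @param event One-row classified event (needs `contig`, `strand`, `type`,
#'   `up_end`, `down_start`, `skip_start`, `skip_end`).
#' @param model A `gene_model`.
#' @param genome A `genome`.
#' @return The event with columns `n_novel_sites` and `site_detail` added.
#' @export
flag_splice_sites <- function(event, model, genome) {
  jx <- event_junctions(event)
  details <- character()
  n_novel <- 0L
  for (i in seq_len(nrow(jx))) {
    ss <- junction_site_status(model, genome, event$contig, jx$lend[i],
                               jx$rstart[i], event$strand)
    n_novel <- n_novel + ss$n_novel
    details <- c(details, ss$detail)
  }
  ev <- copy(event)
  ev[, `:=`(n_novel_sites = n_novel,
            site_detail = paste(details, collapse = ";"))]
  ev[]
}

# the junctions implied by an event's type and coordinates
event_junctions <- function(event) {
  if (event$type %in% c("exon-skipping", "multi-exon-skipping")) {
    data.table(lend = c(event$up_end, event$skip_end, event$up_end),
               rstart = c(event$skip_start, event$down_start,
                          event$down_start))
  } else if (event$type == "intron-retention") {
    data.table(lend = event$up_end, rstart = event$down_start)
  } else if (!is.na(event$up_end) && !is.na(event$down_start)) {
    data.table(lend = event$up_end, rstart = event$down_start)
  } else data.table(lend = integer(), rstart = integer())
}

junction_site_status <- function(model, genome, contig, lend, rstart, strand) {
  if (is.na(strand)) strand <- "+"
  left_pos <- lend; right_pos <- rstart
  left_role <- if (strand == "+") "donor" else "acceptor"
  right_role <- if (strand == "+") "acceptor" else "donor"
  left_ann <- site_annotated(model, contig, left_pos,
                             if (left_role == "donor") "donor" else "acceptor")
  right_ann <- site_annotated(model, contig, right_pos,
                              if (right_role == "donor") "donor" else "acceptor")
  fmt <- function(role, pos, ann) {
    if (ann) sprintf("%s:%d:annotated", role, pos) else {
      dn <- site_dinucleotide(genome, contig, lend, rstart, role, strand)
      sprintf("%s:%d:novel:%s", role, pos, dn)
    }
  }
  n_novel <- sum(!left_ann, !right_ann)
  detail <- paste(fmt(left_role, left_pos, left_ann),
                  fmt(right_role, right_pos, right_ann), sep = ",")
  list(n_novel = n_novel, detail = detail)
}

site_annotated <- function(model, ctg, position, role) {
  tab <- if (role == "donor") model$donor_sites else model$acceptor_sites
  if (!nrow(tab)) return(FALSE)
  nrow(tab[contig == ctg & pos == position]) > 0L
}

# dinucleotide at the intron boundary nearest the given site role
site_dinucleotide <- function(genome, contig, lend, rstart, role, strand) {
  left_dn <- genome_seq(genome, contig, lend + 1L, lend + 2L)
  right_dn <- genome_seq(genome, contig, rstart - 2L, rstart - 1L)
  if (strand == "+") {
    if (role == "donor") left_dn else right_dn
  } else {
    if (role == "donor") revcomp(right_dn) else revcomp(left_dn)
  }
}

#' Separate repeat-induced multi-mapping bubbles
#'
#' When bubble paths align to several loci: if both paths map to both
#' locations the bubble is an exact repeat (putative alternative splicing
#' within a recent gene duplication); if each path maps to its own location
#' it is an inexact repeat.
#'
#' @param upper_alns,lower_alns [align_path()] outputs for the two paths.
#' @return `"exact-repeat"`, `"inexact-repeat"` or `"none"`.
#' @export
classify_repeat <- function(upper_alns, lower_alns) {
  lu <- unique(paste(upper_alns$contig, upper_alns$start))
  ll <- unique(paste(lower_alns$contig, lower_alns$start))
  if (length(lu) >= 2L && length(ll) >= 2L && setequal(lu, ll))
    return("exact-repeat")
  if (length(lu) == 1L && length(ll) == 1L && lu != ll)
    return("inexact-repeat")
  "none"
}

#' Merge bubbles that differ only by linked polymorphism
#'
#' Bubbles identical in type and junction coordinates but differing only by
#' substitutions within their aligned blocks are combinations of genomic and
#' transcriptomic variants of one splicing event; they are merged and their
#' per-sample path counts summed.
#'
#' @param events Classified event table.
#' @return Deduplicated event table.
#' @export
deduplicate_polymorphism <- function(events) {
  if (!nrow(events)) return(events)
  key_cols <- c("type", "contig", "up_end", "skip_start", "skip_end",
                "down_start")
  cnt_cols <- grep("^(incl|excl)_", names(events), value = TRUE)
  ev <- copy(events)
  ev[, .dup_key := do.call(paste, .SD), .SDcols = key_cols]
  merged <- ev[, .SD[1L], by = .dup_key,
               .SDcols = setdiff(names(ev), c(cnt_cols, ".dup_key"))]
  if (length(cnt_cols)) {
    sums <- ev[, lapply(.SD, sum), by = .dup_key, .SDcols = cnt_cols]
    merged <- merged[sums, on = ".dup_key"]
  }
  merged[, .dup_key := NULL]
  merged[]
}

## ---------------------------------------------------------------------------
## Bubble -> event orchestration
## ---------------------------------------------------------------------------

#' Annotate quantified bubbles into classified splicing events
#'
#' Aligns both paths of every bubble, separates repeat cases, classifies
#' the block patterns, flags splice sites and removes polymorphism
#' redundancy. When `reads` are supplied, events are quantified by junction
#' reads only (the convention shared with the mapping-first caller): the
#' inclusion count is the mean of the reads spanning the two
#' inclusion-specific junctions of the upper path, the exclusion count the
#' reads spanning the exclusion junction of the lower path, each with at
#' least 4 nt on both sides. Without `reads`, the bubble path-support
#' counts are used.
#'
#' @param bubbles Quantified bubble table ([quantify_bubbles()]).
#' @param genome A `genome`.
#' @param model A `gene_model`.
#' @param reads Named list of read vectors per sample (optional).
#' @param k k-mer length used for the assembly (needed with `reads`).
#' @param ir_threshold IR-vs-deletion gap threshold (nt).
#' @param min_intron Minimum intron length for the spliced aligner (nt).
#' @return data.table of events (shared schema with the mapping-first
#'   caller) with `attr(,"log")` carrying unmapped-path counts.
#' @export
annotate_bubbles <- function(bubbles, genome, model, reads = NULL, k = NULL,
                             ir_threshold = 50L, min_intron = 30L) {
  samples <- setdiff(sub("^upper_", "",
                         grep("^upper_", names(bubbles), value = TRUE)),
                     "seq")
  idx <- NULL
  if (!is.null(reads)) {
    if (is.null(k)) stop("k must be given with reads")
    rd <- toupper(unlist(reads, use.names = FALSE))
    smp <- rep(names(reads), lengths(reads))
    keep <- nchar(rd) >= k
    rd <- rd[keep]; smp <- smp[keep]
    occ <- kmer_occurrences(rd, k)
    occ[, canon := canonical_kmers(kmer)]
    setkey(occ, canon)
    samples <- names(reads)
    idx <- list(rd = rd, smp = smp, occ = occ)
  }
  rows <- list()
  unmapped <- 0L
  for (i in seq_len(nrow(bubbles))) {
    ua <- align_path(bubbles$upper_seq[i], genome, min_intron)
    la <- align_path(bubbles$lower_seq[i], genome, min_intron)
    if (!nrow(ua) || !nrow(la)) { unmapped <- unmapped + 1L; next }
    rep_status <- classify_repeat(ua, la)
    # classify at the first common locus (alignments are coordinate-sorted)
    ev <- classify_bubble(ua[1L], la[1L], model, ir_threshold)
    ev[, `:=`(bubble_id = bubbles$bubble_id[i],
              branch_count = bubbles$branch_count[i],
              repeat_status = rep_status,
              repeat_loci = if (rep_status == "exact-repeat")
                paste(unique(paste0(ua$contig, ":", ua$start)),
                      collapse = ",") else NA_character_)]
    if (rep_status == "exact-repeat") ev[, type := "exact-repeat"]
    ev <- flag_splice_sites(ev, model, genome)
    cnts <- if (!is.null(idx)) {
      bubble_junction_counts(bubbles$upper_seq[i], bubbles$lower_seq[i],
                             ua$blocks[[1L]], la$blocks[[1L]],
                             idx, samples, k)
    } else NULL
    for (s in samples) {
      if (!is.null(cnts)) {
        ev[, paste0("incl_", s) := cnts$incl[[s]]]
        ev[, paste0("excl_", s) := cnts$excl[[s]]]
      } else {
        ev[, paste0("incl_", s) := bubbles[[paste0("upper_", s)]][i]]
        ev[, paste0("excl_", s) := bubbles[[paste0("lower_", s)]][i]]
      }
    }
    rows[[length(rows) + 1L]] <- ev
  }
  if (!length(rows)) {
    out <- data.table()
    setattr(out, "log", list(unmapped_paths = unmapped))
    return(out)
  }
  events <- rbindlist(rows, fill = TRUE)
  events <- deduplicate_polymorphism(events)
  setorder(events, contig, up_end, skip_start, na.last = TRUE)
  events[, event_id := sprintf("asm%03d", .I)]
  setcolorder(events, c("event_id", "type", "gene_id", "contig", "strand",
                        "skip_start", "skip_end", "up_end", "down_start"))
  setattr(events, "log", list(unmapped_paths = unmapped))
  events[]
}

# junction-read quantification of one bubble: reads (with >= 4 nt anchors)
# spanning the junctions specific to each path
bubble_junction_counts <- function(up, lo, ub, lb, idx, samples, k,
                                   min_anchor = 4L) {
  jx_of <- function(bl) {
    if (nrow(bl) < 2L) return(data.table(lend = integer(),
                                         rstart = integer(), jpos = integer()))
    w <- bl[, 2L] - bl[, 1L] + 1L
    data.table(lend = bl[-nrow(bl), 2L], rstart = bl[-1L, 1L],
               jpos = cumsum(w)[-length(w)])
  }
  ju <- jx_of(ub); jl <- jx_of(lb)
  keyu <- paste(ju$lend, ju$rstart); keyl <- paste(jl$lend, jl$rstart)
  # junctions specific to each path carry the event signal
  ju_spec <- ju[!keyu %in% keyl]
  jl_spec <- jl[!keyl %in% keyu]
  # a path with a single block (retention/insertion): use the positions of
  # the other path's specific junction boundaries projected onto it
  if (!nrow(ju_spec) && nrow(ub) == 1L && nrow(jl_spec)) {
    ju_spec <- data.table(lend = NA_integer_, rstart = NA_integer_,
                          jpos = c(jl_spec$lend - ub[1L, 1L] + 1L,
                                   jl_spec$rstart - ub[1L, 1L]))
  }
  if (!nrow(jl_spec) && nrow(lb) == 1L && nrow(ju_spec)) {
    jl_spec <- data.table(lend = NA_integer_, rstart = NA_integer_,
                          jpos = c(ju_spec$lend - lb[1L, 1L] + 1L,
                                   ju_spec$rstart - lb[1L, 1L]))
  }
  count_side <- function(pathseq, otherseq, jpos_vec) {
    out <- setNames(rep(0, length(samples)), samples)
    if (!length(jpos_vec)) return(as.list(out))
    pk <- unique(canonical_kmers(all_kmers(pathseq, k)))
    ok <- unique(canonical_kmers(all_kmers(otherseq, k)))
    spec <- setdiff(pk, ok)
    if (!length(spec)) return(as.list(out))
    hits <- idx$occ[J(spec), nomatch = 0L]
    cand <- unique(hits$read)
    if (!length(cand)) return(as.list(out))
    per_j <- matrix(0, nrow = length(jpos_vec), ncol = length(samples),
                    dimnames = list(NULL, samples))
    for (r in cand) {
      sp <- read_path_span(idx$rd[r], pathseq, k)
      if (is.null(sp)) next
      cover <- sp[1L] <= jpos_vec - min_anchor + 1L &
        sp[2L] >= jpos_vec + min_anchor
      if (any(cover)) per_j[cover, idx$smp[r]] <-
          per_j[cover, idx$smp[r]] + 1
    }
    as.list(colMeans(per_j))
  }
  list(incl = count_side(up, lo, ju_spec$jpos),
       excl = count_side(lo, up, jl_spec$jpos))
}

#' Write exon-skipping events as BED12 for genome-browser inspection
#'
#' One record per skipping event: a minimal three-block representation
#' anchoring the last base of the upstream flank, the skipped exon and the
#' first base of the downstream flank (0-based half-open).
#'
#' @param events Event table (assembly or mapping schema).
#' @param path Output BED12 path.
#' @return Invisibly, the path.
#' @export
write_events_bed12 <- function(events, path) {
  es <- events[type %in% c("exon-skipping", "skipped-exon",
                           "multi-exon-skipping") & !is.na(skip_start)]
  lines <- character(nrow(es))
  for (i in seq_len(nrow(es))) {
    cs <- es$up_end[i] - 1L
    ce <- es$down_start[i]
    sizes <- c(1L, es$skip_end[i] - es$skip_start[i] + 1L, 1L)
    starts <- c(0L, es$skip_start[i] - 1L - cs, ce - 1L - cs)
    lines[i] <- paste(es$contig[i], cs, ce, es$event_id[i], 0L,
                      es$strand[i], cs, ce, "0,0,0", 3L,
                      paste(sizes, collapse = ","),
                      paste(starts, collapse = ","), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
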