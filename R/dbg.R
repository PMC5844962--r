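## Assembly-first core: De Bruijn graph, relative-support filtering,
## bounded-branching bubble enumeration, per-path read support.

# all k-mer occurrences of a set of reads; returns data.table(read, pos, kmer)
kmer_occurrences <- function(reads, k) {
  L <- nchar(reads)
  res <- vector("list", 0L)
  for (l in sort(unique(L[L >= k]))) {
    idx <- which(L == l)
    npos <- l - k + 1L
    starts <- rep(seq_len(npos), times = length(idx))
    res[[length(res) + 1L]] <- data.table(
      read = rep(idx, each = npos),
      pos = starts,
      kmer = substring(rep(reads[idx], each = npos), starts, starts + k - 1L))
  }
  if (!length(res)) return(data.table(read = integer(), pos = integer(),
                                      kmer = character()))
  rbindlist(res)
}

# canonical form: lexicographic min of a k-mer and its reverse complement
canonical_kmers <- function(kmers) {
  u <- unique(kmers)
  rc <- revcomp(u)
  canon <- ifelse(u <= rc, u, rc)
  canon[match(kmers, u)]
}

#' Build a De Bruijn graph from reads
#'
#' Nodes are canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement); node counts conserve the total number of k-mer
#' occurrences in the reads and are kept per sample. Edges connect k-mers
#' overlapping by k-1 nt and are stored in both orientations, with the count
#' of the underlying (k+1)-mer (orientation-symmetric), so that unstranded
#' read sets assemble into one double-stranded graph.
#'
#' @param reads Character vector of reads, or a named list of character
#'   vectors (one per sample).
#' @param k Odd k-mer length, at least 5.
#' @return An object of class `dbg`.
#' @export
build_dbg <- function(reads, k) {
  if (k < 5L || k %% 2L == 0L) stop("k must be odd and >= 5")
  if (!is.list(reads)) reads <- list(sample1 = reads)
  if (is.null(names(reads))) names(reads) <- paste0("sample", seq_along(reads))
  samples <- names(reads)
  rd <- unlist(reads, use.names = FALSE)
  smp <- rep(samples, lengths(reads))
  rd <- toupper(rd)
  ok <- nchar(rd) >= k
  if (!any(ok)) stop("all reads shorter than k")
  rd <- rd[ok]; smp <- smp[ok]

  occ <- kmer_occurrences(rd, k)
  occ[, canon := canonical_kmers(kmer)]
  occ[, sample := smp[read]]
  nodes <- occ[, .(count = .N), by = .(kmer = canon)]
  setorder(nodes, kmer)
  sc <- occ[, .N, by = .(canon, sample)]
  sample_counts <- matrix(0L, nrow = nrow(nodes), ncol = length(samples),
                          dimnames = list(nodes$kmer, samples))
  sample_counts[cbind(match(sc$canon, nodes$kmer), match(sc$sample, samples))] <- sc$N

  # edges from canonical (k+1)-mer counts, emitted in both orientations
  eocc <- kmer_occurrences(rd, k + 1L)
  if (nrow(eocc)) {
    eocc[, canon := canonical_kmers(kmer)]
    ec <- eocc[, .(count = .N), by = .(canon)]
    fwd <- ec[, .(from = substring(canon, 1L, k),
                  to = substring(canon, 2L, k + 1L), count)]
    rcs <- revcomp(ec$canon)
    rev <- data.table(from = substring(rcs, 1L, k),
                      to = substring(rcs, 2L, k + 1L), count = ec$count)
    edges <- unique(rbind(fwd, rev))
  } else {
    edges <- data.table(from = character(), to = character(), count = integer())
  }
  setorder(edges, from, to)
  structure(list(k = k, nodes = nodes, sample_counts = sample_counts,
                 edges = edges, samples = samples, log = list()),
            class = "dbg")
}

#' @export
print.dbg <- function(x, ...) {
  cat("De Bruijn graph: k =", x$k, "|", nrow(x$nodes), "canonical k-mers |",
      nrow(x$edges), "oriented edges |", length(x$samples), "sample(s)\n")
  invisible(x)
}

#' Remove relatively weakly supported branches
#'
#' At every branching vertex, outgoing (and incoming) edges whose count is
#' below `relative_cutoff` times the total count of the sibling edges at that
#' vertex are removed; these are the relatively weakly supported junctions
#' that local assemblers interpret as sequencing errors or spurious junctions
#' in highly expressed genes. Removal is orientation-symmetric. Nodes that
#' lose all their edges are pruned. The removed edges are recorded in the
#' graph log (`$log$removed_edges`), including the spelled (k+1)-mer of each
#' removed junction.
#'
#' @param graph A `dbg`.
#' @param relative_cutoff Fraction in (0, 1); default 0.02.
#' @return The filtered `dbg`.
#' @export
filter_low_support <- function(graph, relative_cutoff = 0.02) {
  stopifnot(relative_cutoff > 0, relative_cutoff < 1)
  ed <- copy(graph$edges)
  if (!nrow(ed)) return(graph)
  k <- graph$k
  ed[, out_frac := count / sum(count), by = from]
  ed[, in_frac := count / sum(count), by = to]
  ed[, drop := out_frac < relative_cutoff | in_frac < relative_cutoff]
  # orientation symmetry: if an edge goes, its reverse complement goes too
  key <- paste0(ed$from, substring(ed$to, k, k))
  rckey <- revcomp(key)
  ed[, drop := drop | rckey %in% key[drop]]
  removed <- ed[drop == TRUE, .(from, to, count)]
  removed[, junction_seq := paste0(from, substring(to, k, k))]
  kept <- ed[drop == FALSE, .(from, to, count)]

  had_edge <- unique(canonical_kmers(c(ed$from, ed$to)))
  has_edge <- unique(canonical_kmers(c(kept$from, kept$to)))
  orphan <- setdiff(had_edge, has_edge)
  nodes <- graph$nodes[!kmer %in% orphan]
  sc <- graph$sample_counts[nodes$kmer, , drop = FALSE]

  out <- graph
  out$nodes <- nodes
  out$sample_counts <- sc
  out$edges <- kept
  out$log$removed_edges <- removed
  out$log$relative_cutoff <- relative_cutoff
  out
}

## ---------------------------------------------------------------------------
## Bubble enumeration on the unitig-compressed oriented graph
## ---------------------------------------------------------------------------

# compress the oriented graph into maximal non-branching segments
compress_graph <- function(edges) {
  verts <- sort(unique(c(edges$from, edges$to)))
  nv <- length(verts)
  fi <- match(edges$from, verts); ti <- match(edges$to, verts)
  outdeg <- tabulate(fi, nv); indeg <- tabulate(ti, nv)
  ord <- order(fi)
  out_to <- ti[ord]
  out_start <- c(0L, cumsum(tabulate(fi, nv)))  # adjacency slices
  out_nb <- function(v) if (outdeg[v] == 0L) integer() else
    out_to[(out_start[v] + 1L):(out_start[v] + outdeg[v])]
  ordi <- order(ti)
  in_from <- fi[ordi]
  in_start <- c(0L, cumsum(tabulate(ti, nv)))
  in_nb <- function(v) if (indeg[v] == 0L) integer() else
    in_from[(in_start[v] + 1L):(in_start[v] + indeg[v])]

  is_head <- vapply(seq_len(nv), function(v) {
    indeg[v] != 1L || outdeg[in_nb(v)[1L]] != 1L
  }, logical(1))
  seg_of <- integer(nv)
  segs <- list()
  for (h in which(is_head)) {
    if (seg_of[h] != 0L) next
    mem <- h
    cur <- h
    repeat {
      if (outdeg[cur] != 1L) break
      nxt <- out_nb(cur)[1L]
      if (is_head[nxt] || seg_of[nxt] != 0L || nxt == h) break
      mem <- c(mem, nxt); cur <- nxt
    }
    segs[[length(segs) + 1L]] <- mem
    seg_of[mem] <- length(segs)
  }
  # isolated cycles of pure chain vertices (cannot host bubble endpoints)
  for (v in which(seg_of == 0L)) {
    if (seg_of[v] != 0L) next
    mem <- v; cur <- v
    repeat {
      nxt <- out_nb(cur)[1L]
      if (nxt == v || seg_of[nxt] != 0L) break
      mem <- c(mem, nxt); cur <- nxt
    }
    segs[[length(segs) + 1L]] <- mem
    seg_of[mem] <- length(segs)
  }
  ns <- length(segs)
  k <- nchar(verts[1L])
  seg_head <- vapply(segs, `[`, integer(1), 1L)
  seg_tail <- vapply(segs, function(m) m[length(m)], integer(1))
  seg_n <- lengths(segs)
  seg_spell <- vapply(seq_len(ns), function(i) {
    m <- segs[[i]]
    if (length(m) == 1L) verts[m] else
      paste0(verts[m[1L]], paste(substring(verts[m[-1L]], k, k), collapse = ""))
  }, character(1))
  branchy <- outdeg >= 2L | indeg >= 2L
  seg_branch <- lapply(segs, function(m) m[branchy[m]])
  # segment adjacency: tail out-neighbours are always heads
  seg_out <- lapply(seq_len(ns), function(i) seg_of[out_nb(seg_tail[i])])
  list(verts = verts, outdeg = outdeg, indeg = indeg, segs = segs,
       seg_of = seg_of, seg_head = seg_head, seg_tail = seg_tail,
       seg_n = seg_n, seg_spell = seg_spell, seg_branch = seg_branch,
       seg_out = seg_out, k = k)
}

#' Enumerate bubbles in a De Bruijn graph
#'
#' A bubble is a pair of internally vertex-disjoint paths sharing their first
#' and last k-mers; it is the assembly-level signature of a variation in
#' transcript content. Enumeration walks the unitig-compressed oriented graph
#' from every branching vertex. Bubbles whose paths traverse more than
#' `max_branches` branching vertices are skipped and counted in the log:
#' these highly branching regions (typically repeats) are the cases a local
#' assembler deliberately leaves alone because their exhaustive enumeration
#' is combinatorial. A per-source budget of partial path extensions bounds
#' the search; a source that exhausts it is abandoned with a warning.
#'
#' @param graph A (filtered) `dbg`.
#' @param max_branches Maximum number of distinct branching vertices
#'   (in- or out-degree at least 2) on the two paths of a reported bubble.
#' @param min_path_length Minimum spelled length (nt) of the shorter path.
#'   The spelled path includes both shared end k-mers, and junction
#'   ambiguity (continuations sharing their first or last bases) shortens
#'   it below 2k; the default k+1 admits every pure-junction path.
#' @param max_path_length Maximum spelled length (nt) of the longer path.
#' @param budget Maximum partial-path extensions per source vertex.
#' @return data.table with columns `bubble_id`, `upper_seq`, `lower_seq`,
#'   `branch_count`, `entry_kmer`, `exit_kmer`; enumeration statistics in
#'   `attr(, "log")` (`skipped_high_branch`, `aborted_sources`).
#' @export
enumerate_bubbles <- function(graph, max_branches = 5L,
                              min_path_length = graph$k + 1L,
                              max_path_length = 1000L + 2L * graph$k - 2L,
                              budget = 1e5) {
  empty <- data.table(bubble_id = integer(), upper_seq = character(),
                      lower_seq = character(), branch_count = integer(),
                      entry_kmer = character(), exit_kmer = character())
  if (!nrow(graph$edges)) {
    setattr(empty, "log", list(skipped_high_branch = 0L, aborted_sources = 0L))
    return(empty)
  }
  cg <- compress_graph(graph$edges)
  k <- graph$k
  sources <- which(cg$outdeg[cg$seg_tail] >= 2L)
  skipped <- 0L
  aborted <- 0L
  found <- list()

  for (s in sources) {
    entry_v <- cg$seg_tail[s]
    entry_branch <- if (cg$outdeg[entry_v] >= 2L || cg$indeg[entry_v] >= 2L)
      entry_v else integer()
    # paths[[target]] = list of list(mids, branches, len)
    paths <- new.env(parent = emptyenv())
    expansions <- 0L
    overbudget <- FALSE
    # frame: (segment, mids, branches, L_end)
    stack <- list(list(seg = s, mids = integer(), branches = entry_branch,
                       L_end = k))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (g in cg$seg_out[[fr$seg]]) {
        expansions <- expansions + 1L
        if (expansions > budget) { overbudget <- TRUE; break }
        if (g %in% fr$mids) next
        record_only <- g == s
        # a path may END at the source segment's head (a distinct vertex
        # when the segment has length > 1) but cannot pass through it
        if (record_only && cg$seg_n[s] == 1L) next
        # record the path ending at g (exit = head of g)
        plen <- fr$L_end + 1L
        if (plen > max_path_length) next
        hb <- cg$seg_head[g]
        pbr <- fr$branches
        if (cg$outdeg[hb] >= 2L || cg$indeg[hb] >= 2L) pbr <- union(pbr, hb)
        key <- as.character(g)
        rec <- list(mids = fr$mids, branches = pbr, len = plen)
        prev <- if (exists(key, envir = paths, inherits = FALSE))
          get(key, envir = paths) else list()
        assign(key, c(prev, list(rec)), envir = paths)
        if (record_only) next
        # extend through g
        ebr <- union(fr$branches, cg$seg_branch[[g]])
        if (length(ebr) > max_branches) { skipped <- skipped + 1L; next }
        L2 <- fr$L_end + cg$seg_n[g]
        if (L2 + 1L > max_path_length) next
        stack[[length(stack) + 1L]] <- list(seg = g, mids = c(fr$mids, g),
                                            branches = ebr, L_end = L2)
      }
      if (overbudget) break
    }
    if (overbudget) {
      aborted <- aborted + 1L
      warning("bubble enumeration budget exceeded at source k-mer ",
              cg$verts[entry_v], "; component abandoned", call. = FALSE)
      next
    }
    # pair paths per target
    for (key in ls(paths)) {
      pl <- paths[[key]]
      if (length(pl) < 2L) next
      t <- as.integer(key)
      for (i in seq_len(length(pl) - 1L)) for (j in (i + 1L):length(pl)) {
        a <- pl[[i]]; b <- pl[[j]]
        if (length(a$mids) == length(b$mids) && all(a$mids == b$mids)) next
        if (length(intersect(a$mids, b$mids))) next
        bc <- length(union(a$branches, b$branches))
        if (bc > max_branches) { skipped <- skipped + 1L; next }
        lo <- min(a$len, b$len); hi <- max(a$len, b$len)
        if (lo < min_path_length || hi > max_path_length) next
        sa <- spell_path(cg, s, a$mids, t)
        sb <- spell_path(cg, s, b$mids, t)
        found[[length(found) + 1L]] <- list(
          seq1 = sa, seq2 = sb, branch_count = bc,
          entry = cg$verts[cg$seg_tail[s]], exit = cg$verts[cg$seg_head[t]])
      }
    }
  }
  if (!length(found)) {
    setattr(empty, "log", list(skipped_high_branch = skipped,
                               aborted_sources = aborted))
    return(empty)
  }
  bt <- rbindlist(lapply(found, function(b) {
    ul <- orient_pair(b$seq1, b$seq2)
    data.table(upper_seq = ul[1L], lower_seq = ul[2L],
               branch_count = b$branch_count,
               entry_kmer = b$entry, exit_kmer = b$exit)
  }))
  # canonical dedup across the two strands
  fwd_key <- paste(bt$upper_seq, bt$lower_seq)
  rc_up <- revcomp(bt$upper_seq); rc_lo <- revcomp(bt$lower_seq)
  rc_key <- vapply(seq_len(nrow(bt)), function(i) {
    ul <- orient_pair(rc_up[i], rc_lo[i]); paste(ul[1L], ul[2L])
  }, character(1))
  bt[, ckey := pmin(fwd_key, rc_key)]
  bt[, is_canon_orient := fwd_key <= rc_key]
  bt <- bt[order(ckey, -is_canon_orient)]
  bt <- bt[!duplicated(ckey)]
  # report every bubble in its canonical orientation for determinism
  flip <- !bt$is_canon_orient
  if (any(flip)) {
    new_up <- revcomp(bt$upper_seq[flip]); new_lo <- revcomp(bt$lower_seq[flip])
    en <- revcomp(bt$exit_kmer[flip]); ex <- revcomp(bt$entry_kmer[flip])
    for (ii in seq_along(which(flip))) {
      i <- which(flip)[ii]
      ul <- orient_pair(new_up[ii], new_lo[ii])
      bt[i, `:=`(upper_seq = ul[1L], lower_seq = ul[2L],
                 entry_kmer = en[ii], exit_kmer = ex[ii])]
    }
  }
  bt[, c("ckey", "is_canon_orient") := NULL]
  bt[, bubble_id := .I]
  setcolorder(bt, c("bubble_id", "upper_seq", "lower_seq", "branch_count",
                    "entry_kmer", "exit_kmer"))
  setattr(bt, "log", list(skipped_high_branch = skipped,
                          aborted_sources = aborted))
  bt[]
}

# upper = longer sequence; lexicographic order decides ties
orient_pair <- function(s1, s2) {
  if (nchar(s1) > nchar(s2)) c(s1, s2)
  else if (nchar(s2) > nchar(s1)) c(s2, s1)
  else if (s1 >= s2) c(s1, s2) else c(s2, s1)
}

# spelled sequence of the trimmed path entry-kmer .. mids .. exit-kmer
spell_path <- function(cg, s, mids, t) {
  k <- cg$k
  parts <- cg$verts[cg$seg_tail[s]]
  for (g in mids) {
    sp <- cg$seg_spell[g]
    parts <- c(parts, substring(sp, k, nchar(sp)))
  }
  exitk <- cg$verts[cg$seg_head[t]]
  paste0(paste(parts, collapse = ""), substring(exitk, k, k))
}

## ---------------------------------------------------------------------------
## Per-path read support
## ---------------------------------------------------------------------------

#' Quantify bubble paths with per-sample read support
#'
#' A read supports a path when it matches the path sequence over their
#' overlap and that overlap covers at least one path-specific k-mer (a k-mer
#' present in this path and absent from the other, canonical comparison).
#' Reads matching only the shared flanks are counted for neither path.
#'
#' @param bubbles data.table from [enumerate_bubbles()].
#' @param reads Named list of character vectors (one per sample).
#' @param k k-mer length used for the assembly.
#' @return `bubbles` with added integer columns `upper_<sample>` and
#'   `lower_<sample>`.
#' @export
quantify_bubbles <- function(bubbles, reads, k) {
  if (!is.list(reads)) reads <- list(sample1 = reads)
  if (is.null(names(reads))) names(reads) <- paste0("sample", seq_along(reads))
  samples <- names(reads)
  bubbles <- copy(bubbles)
  for (s in samples) {
    bubbles[, paste0("upper_", s) := 0L]
    bubbles[, paste0("lower_", s) := 0L]
  }
  if (!nrow(bubbles)) return(bubbles[])
  rd <- unlist(reads, use.names = FALSE)
  if (any(nchar(rd) < k)) {
    keep <- nchar(rd) >= k
    smp_all <- rep(samples, lengths(reads))[keep]
    rd <- rd[keep]
  } else smp_all <- rep(samples, lengths(reads))
  if (!length(rd)) return(bubbles[])
  occ <- kmer_occurrences(rd, k)
  occ[, canon := canonical_kmers(kmer)]
  setkey(occ, canon)
  for (i in seq_len(nrow(bubbles))) {
    up <- bubbles$upper_seq[i]; lo <- bubbles$lower_seq[i]
    kup <- unique(canonical_kmers(all_kmers(up, k)))
    klo <- unique(canonical_kmers(all_kmers(lo, k)))
    for (side in c("upper", "lower")) {
      pseq <- if (side == "upper") up else lo
      spec <- if (side == "upper") setdiff(kup, klo) else setdiff(klo, kup)
      if (!length(spec)) next
      hits <- occ[J(spec), nomatch = 0L]
      if (!nrow(hits)) next
      cand <- unique(hits$read)
      supp <- cand[vapply(cand, function(r)
        read_matches_path(rd[r], pseq, k), logical(1))]
      if (!length(supp)) next
      tab <- table(factor(smp_all[supp], levels = samples))
      for (s in samples) {
        col <- paste0(side, "_", s)
        bubbles[i, (col) := as.integer(tab[[s]])]
      }
    }
  }
  bubbles[]
}

all_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) stop("path shorter than k")
  substring(seq, seq_len(n - k + 1L), k:n)
}

# exact-overlap check: the interval of the path matched by the read (either
# orientation) at a shared k-mer anchor, or NULL when inconsistent
read_path_span <- function(read, path, k) {
  for (r in c(read, revcomp(read))) {
    rk <- all_kmers(r, k)
    pk <- all_kmers(path, k)
    m <- match(rk, pk)
    anchors <- which(!is.na(m))
    if (!length(anchors)) next
    q <- anchors[1L]; p <- m[q]
    off <- p - q
    a <- max(1L, 1L - off); b <- min(nchar(r), nchar(path) - off)
    if (a > b) next
    if (substring(r, a, b) == substring(path, a + off, b + off))
      return(c(a + off, b + off))
  }
  NULL
}

read_matches_path <- function(read, path, k) {
  !is.null(read_path_span(read, path, k))
}

#' Write bubbles as paired FASTA
#'
#' Two records per bubble; identifiers encode bubble number, path rank and
#' per-sample read counts.
#'
#' @param bubbles Quantified bubble table.
#' @param path Output FASTA path.
#' @param samples Sample names (defaults to those found in the columns).
#' @return Invisibly, the path.
#' @export
write_bubbles_fasta <- function(bubbles, path, samples = NULL) {
  if (is.null(samples)) {
    samples <- setdiff(sub("^upper_", "",
                           grep("^upper_", names(bubbles), value = TRUE)),
                       "seq")
  }
  lines <- character(0)
  for (i in seq_len(nrow(bubbles))) {
    for (side in c("upper", "lower")) {
      cnts <- vapply(samples, function(s)
        as.integer(bubbles[[paste0(side, "_", s)]][i]), integer(1))
      id <- paste0("bcc_", bubbles$bubble_id[i], "|path",
                   if (side == "upper") 1L else 2L, "|",
                   paste(paste0(samples, "=", cnts), collapse = ";"))
      lines <- c(lines, paste0(">", id),
                 bubbles[[paste0(side, "_seq")]][i])
    }
  }
  writeLines(lines, path)
  invisible(path)
}
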