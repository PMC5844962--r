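# shared fixtures and independent oracles

base4 <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(base4, n, replace = TRUE), collapse = "")

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# tile a sequence with overlapping reads
tile_reads <- function(s, width = 30L, step = 5L) {
  n <- nchar(s)
  st <- seq(1L, max(1L, n - width + 1L), by = step)
  substring(s, st, pmin(n, st + width - 1L))
}

# brute-force bubble oracle: igraph all_simple_paths over the oriented
# k-mer graph, pairwise internal-disjointness, canonical-strand dedup
brute_force_bubbles <- function(graph) {
  ed <- graph$edges
  if (!nrow(ed)) return(character())
  k <- graph$k
  ig <- igraph::graph_from_data_frame(ed[, c("from", "to")], directed = TRUE)
  vs <- igraph::V(ig)$name
  spell <- function(p) paste0(p[1L], paste(substring(p[-1L], k, k),
                                           collapse = ""))
  orient <- function(a, b) {
    if (nchar(a) > nchar(b)) c(a, b)
    else if (nchar(b) > nchar(a)) c(b, a)
    else if (a >= b) c(a, b) else c(b, a)
  }
  keys <- character()
  for (s in vs) for (t in vs) {
    if (s == t) next
    paths <- igraph::all_simple_paths(ig, from = s, to = t, mode = "out")
    if (length(paths) < 2L) next
    pn <- lapply(paths, names)
    for (i in seq_len(length(pn) - 1L)) for (j in (i + 1L):length(pn)) {
      a <- pn[[i]]; b <- pn[[j]]
      if (length(intersect(a[-c(1L, length(a))], b[-c(1L, length(b))]))) next
      ul <- orient(spell(a), spell(b))
      fwd <- paste(ul[1L], ul[2L])
      rcul <- orient(rc(ul[1L]), rc(ul[2L]))
      keys <- c(keys, min(fwd, paste(rcul[1L], rcul[2L])))
    }
  }
  sort(unique(keys))
}

# step-up BH from its definition, independent of stats::p.adjust
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    v <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- v
    prev <- v
  }
  adj
}

# Poisson LRT (G-test) oracle for a 2x2 single-replicate table
g_test_p <- function(y11, y12, y21, y22) {
  y <- c(y11, y12, y21, y22)
  rs <- c(y11 + y12, y21 + y22)
  cs <- c(y11 + y21, y12 + y22)
  e <- outer(rs, cs) / sum(y)
  lrt <- 2 * sum(ifelse(y > 0, y * log(y / as.vector(t(e))), 0))
  pchisq(lrt, df = 1L, lower.tail = FALSE)
}

# a small explicit two-transcript locus with known coordinates, for the
# annotation-side unit tests; returns genome, model and handy sequences
make_toy_locus <- function(seed = 101L) {
  set.seed(seed)
  e1 <- rand_seq(100L); e2 <- rand_seq(90L); e3 <- rand_seq(110L)
  i1 <- paste0("GT", rand_seq(196L), "AG")
  i2 <- paste0("GT", rand_seq(246L), "AG")
  lead <- rand_seq(200L); trail <- rand_seq(200L)
  gseq <- paste0(lead, e1, i1, e2, i2, e3, trail)
  s1 <- 201L; en1 <- s1 + 99L            # e1: 201-300
  s2 <- en1 + 201L; en2 <- s2 + 89L      # e2: 501-590
  s3 <- en2 + 251L; en3 <- s3 + 109L     # e3: 841-950
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", gseq), fa)
  genome <- load_genome(fa)
  ex <- data.table::data.table(
    contig = "chr1",
    start = c(s1, s2, s3, s1, s3),
    end = c(en1, en2, en3, en1, en3),
    strand = "+",
    gene_id = "toy",
    transcript_id = c("toy.t1", "toy.t1", "toy.t1", "toy.skip", "toy.skip"))
  model <- build_gene_model(ex, genome)
  list(genome = genome, model = model,
       e1 = e1, e2 = e2, e3 = e3,
       coords = data.table::data.table(start = c(s1, s2, s3),
                                       end = c(en1, en2, en3)),
       incl_seq = paste0(e1, e2, e3), excl_seq = paste0(e1, e3))
}

# write SAM lines with a header for the mapping-first tests
write_test_sam <- function(lines, ln = 100000L) {
  f <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:chr1\tLN:", ln), lines), f)
  f
}

sam_rec <- function(qname, flag, pos, mapq, cigar, seqlen = NULL) {
  sq <- if (is.null(seqlen)) "*" else strrep("A", seqlen)
  qual <- if (is.null(seqlen)) "*" else strrep("I", seqlen)
  paste(qname, flag, "chr1", pos, mapq, cigar, "=", pos, 0, sq, qual,
        sep = "\t")
}
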