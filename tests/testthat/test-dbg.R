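test_that("graph construction uses canonical k-mers and conserves counts", {
  # the read contains the reverse-complement pair CGTAC/GTACG, which
  # collapses to one canonical node under the double-stranded convention
  g <- build_dbg(c("ACGTACG", "ACGTACG"), 5L)
  expect_equal(g$nodes$kmer, c("ACGTA", "CGTAC"))
  expect_equal(g$nodes$count, c(2L, 4L))
  expect_equal(sum(g$nodes$count), 2L * 3L)  # total k-mer occurrences

  # single read of length k: one node, no edge
  g1 <- build_dbg("ACGTAGA", 7L)
  expect_equal(nrow(g1$nodes), 1L)
  expect_equal(nrow(g1$edges), 0L)

  expect_error(build_dbg(c("ACG", "TTA"), 5L), "shorter than k")
  expect_error(build_dbg("ACGTACGT", 4L), "odd")
})

test_that("count conservation holds on random read sets", {
  set.seed(1)
  for (i in 1:10) {
    reads <- replicate(sample(3:8, 1), rand_seq(sample(20:40, 1)))
    k <- sample(c(5L, 7L, 9L), 1)
    g <- build_dbg(reads, k)
    expect_equal(sum(g$nodes$count),
                 sum(pmax(0L, nchar(reads) - k + 1L)))
  }
})

test_that("per-sample k-mer counts are kept", {
  g <- build_dbg(list(a = c("ACGTTGCAA"), b = c("ACGTTGCAA", "ACGTTGCAA")), 5L)
  expect_equal(colnames(g$sample_counts), c("a", "b"))
  expect_true(all(g$sample_counts[, "b"] == 2L * g$sample_counts[, "a"]))
})

test_that("relative-support filtering removes weak branches only", {
  set.seed(7)
  P <- rand_seq(30); S <- rand_seq(30)
  a <- paste0(P, "A", S); c_ <- paste0(P, "C", S)
  # 2945 vs 55 at the branching vertex (the weak junction is < 2%)
  reads <- c(rep(a, 100), rep(c_, 2))
  g <- build_dbg(reads, 15L)
  gf <- filter_low_support(g, 0.02)
  expect_true(nrow(gf$log$removed_edges) > 0L)
  expect_lt(nrow(gf$edges), nrow(g$edges))
  # bubble destroyed by the filter
  expect_equal(nrow(enumerate_bubbles(gf)), 0L)
  expect_equal(nrow(enumerate_bubbles(g)), 1L)

  # symmetric 50/50 branch survives
  reads2 <- c(rep(a, 50), rep(c_, 50))
  g2 <- build_dbg(reads2, 15L)
  g2f <- filter_low_support(g2, 0.02)
  expect_equal(nrow(g2f$edges), nrow(g2$edges))

  # linear graph unchanged
  g3 <- build_dbg(tile_reads(rand_seq(100)), 15L)
  expect_equal(nrow(filter_low_support(g3, 0.02)$edges), nrow(g3$edges))
})

test_that("raising the cutoff never increases surviving edges", {
  set.seed(12)
  reads <- unlist(lapply(1:4, function(i) {
    P <- rand_seq(25); S <- rand_seq(25)
    c(rep(paste0(P, rand_seq(10), S), sample(2:20, 1)),
      rep(paste0(P, S), sample(2:20, 1)))
  }))
  g <- build_dbg(reads, 15L)
  sizes <- sapply(c(0.01, 0.05, 0.2, 0.45),
                  function(co) nrow(filter_low_support(g, co)$edges))
  expect_true(all(diff(sizes) <= 0))
})

test_that("a simple insert bubble is enumerated with its exact sequences", {
  set.seed(5)
  P <- rand_seq(40); X <- rand_seq(30); S <- rand_seq(40)
  k <- 15L
  reads <- c(tile_reads(paste0(P, X, S)), tile_reads(paste0(P, S)))
  g <- build_dbg(reads, k)
  bb <- enumerate_bubbles(g)
  expect_equal(nrow(bb), 1L)
  # upper spells the insert plus the shared entry/exit k-mers
  expect_equal(nchar(bb$upper_seq), nchar(X) + 2L * k)
  expect_true(grepl(X, bb$upper_seq, fixed = TRUE) ||
                grepl(rc(X), bb$upper_seq, fixed = TRUE))
  expect_gte(nchar(bb$upper_seq), nchar(bb$lower_seq))

  # linear sequence: no bubble
  g2 <- build_dbg(tile_reads(rand_seq(120)), k)
  expect_equal(nrow(enumerate_bubbles(g2)), 0L)
})

test_that("enumeration equals the brute-force oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(42)
  tested <- 0L
  for (rep in 1:110) {
    reads <- replicate(sample(3:5, 1),
                       paste(sample(c("A", "C", "G"), sample(10:16, 1),
                                    replace = TRUE), collapse = ""))
    g <- tryCatch(build_dbg(reads, 5L), error = function(e) NULL)
    if (is.null(g) || nrow(g$nodes) > 50L) next
    tested <- tested + 1L
    mine <- enumerate_bubbles(g, max_branches = 1e9, min_path_length = 0L,
                              max_path_length = 1e9, budget = 1e7)
    mk <- if (nrow(mine)) sort(paste(mine$upper_seq, mine$lower_seq))
    else character()
    expect_identical(mk, brute_force_bubbles(g))
  }
  expect_gte(tested, 80L)
})

test_that("highly branching bubbles are skipped under the branch bound", {
  set.seed(33)
  k <- 15L
  P <- rand_seq(30); S <- rand_seq(30)
  # the inclusion path passes through 5 internal branch points (each with
  # a decoy out-edge), plus the entry and exit vertices: 7 branching
  # vertices in total
  mids <- replicate(6, rand_seq(20))
  incl <- paste0(P, paste(mids, collapse = ""), S)
  excl <- paste0(P, S)
  reads <- c(tile_reads(incl, step = 3), tile_reads(excl, step = 3))
  for (i in 1:5) {
    joint_end <- sum(nchar(mids[seq_len(i)])) + nchar(P)
    decoy <- paste0(substring(incl, joint_end - k + 1L, joint_end),
                    rand_seq(20))
    reads <- c(reads, tile_reads(decoy, step = 3))
  }
  g <- build_dbg(reads, k)
  b5 <- enumerate_bubbles(g, max_branches = 5L)
  b7 <- enumerate_bubbles(g, max_branches = 7L)
  main5 <- b5[grepl(substring(S, 1, k), upper_seq, fixed = TRUE) |
                grepl(rc(substring(S, 1, k)), upper_seq, fixed = TRUE)]
  main7 <- b7[nchar(upper_seq) >= nchar(incl) - 2L * k]
  expect_equal(nrow(main7), 1L)
  expect_equal(main7$branch_count, 7L)
  expect_equal(nrow(main5[nchar(upper_seq) >= nchar(incl) - 2L * k]), 0L)
  expect_gt(attr(b5, "log")$skipped_high_branch, 0L)
  # raising the bound never loses bubbles
  expect_gte(nrow(b7), nrow(b5))
})

test_that("path support requires a path-specific k-mer match", {
  set.seed(8)
  P <- rand_seq(40); X <- rand_seq(30); S <- rand_seq(40)
  k <- 15L
  incl <- paste0(P, X, S); excl <- paste0(P, S)
  g <- build_dbg(c(tile_reads(incl), tile_reads(excl)), k)
  bb <- enumerate_bubbles(g)
  up_reads <- tile_reads(incl, width = 40, step = 3)  # 12 reads
  lo_reads <- tile_reads(excl, width = 40, step = 11) # 4 reads
  q <- quantify_bubbles(bb, list(s1 = up_reads, s2 = lo_reads), k)
  # every upper-tiling read overlaps X or a junction (path-specific);
  # flank-only reads must not be counted for either path
  expect_gt(q$upper_s1, 0L)
  expect_equal(q$upper_s2, 0L)
  expect_gt(q$lower_s2, 0L)
  # sample without reads: zero, not missing
  q2 <- quantify_bubbles(bb, list(s1 = up_reads, s2 = character()), k)
  expect_equal(q2$lower_s2, 0L)
  # a read matching only the shared flank counts for neither path
  flank_read <- substring(P, 5, 38)
  q3 <- quantify_bubbles(bb, list(s1 = flank_read), k)
  expect_equal(q3$upper_s1 + q3$lower_s1, 0L)
})
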