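toy <- make_toy_locus()

test_that("paths align into the expected spliced blocks", {
  k <- 15L
  # inclusion-like path: parts of all three exons -> 3 blocks
  p3 <- paste0(substring(toy$e1, 81, 100), toy$e2,
               substring(toy$e3, 1, 20))
  a3 <- align_path(p3, toy$genome)
  expect_equal(nrow(a3), 1L)
  expect_equal(a3$nblocks, 3L)
  bl <- a3$blocks[[1]]
  expect_equal(bl[1, ], c(281L, 300L))
  expect_equal(bl[2, ], c(501L, 590L))
  expect_equal(bl[3, ], c(841L, 860L))
  # exclusion-like path -> 2 blocks
  p2 <- paste0(substring(toy$e1, 81, 100), substring(toy$e3, 1, 20))
  a2 <- align_path(p2, toy$genome)
  expect_equal(a2$nblocks, 2L)
  # unmappable path -> zero rows, not an error
  expect_equal(nrow(align_path(strrep("ACGT", 10), toy$genome)), 0L)
})

test_that("duplicated loci give all equally best alignments", {
  set.seed(77)
  locus <- rand_seq(120)
  gseq <- paste0(rand_seq(150), locus, rand_seq(300), locus, rand_seq(150))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", gseq), fa)
  g <- load_genome(fa)
  al <- align_path(substring(locus, 10, 90), g)
  expect_equal(nrow(al), 2L)
  expect_true(all(al$multi))
})

test_that("block signatures classify event types per the block-count rules", {
  mk <- function(m) data.table::data.table(contig = "chr1", strand = "+",
                                           nblocks = nrow(m), start = m[1, 1],
                                           blocks = list(m), multi = FALSE)
  m <- toy$model
  # (3,2) same outer boundaries -> exon skipping of the middle block
  up <- mk(rbind(c(281L, 300L), c(501L, 590L), c(841L, 860L)))
  lo <- mk(rbind(c(281L, 300L), c(841L, 860L)))
  ev <- classify_bubble(up[1], lo[1], m)
  expect_equal(ev$type, "exon-skipping")
  expect_equal(c(ev$skip_start, ev$skip_end), c(501L, 590L))
  expect_equal(c(ev$up_end, ev$down_start), c(300L, 841L))
  expect_equal(ev$gene_id, "toy")

  # (1,2): gap below/above the threshold separates deletion from IR
  up1 <- mk(rbind(c(101L, 700L)))
  lo_del <- mk(rbind(c(101L, 400L), c(431L, 700L)))   # gap 30 < 50
  lo_ir <- mk(rbind(c(101L, 400L), c(701L - 1L + 0L, 700L)))
  expect_equal(classify_bubble(up1[1], lo_del[1], m)$type, "genomic-deletion")
  lo_ir <- mk(rbind(c(101L, 400L), c(701L, 1000L)))
  up_ir <- mk(rbind(c(101L, 1000L)))
  expect_equal(classify_bubble(up_ir[1], lo_ir[1], m)$type,
               "intron-retention")
  # boundary: gap threshold-1 vs threshold flips the call
  gap49 <- mk(rbind(c(101L, 400L), c(450L, 700L)))   # gap 49
  gap50 <- mk(rbind(c(101L, 400L), c(451L, 700L)))   # gap 50
  up49 <- mk(rbind(c(101L, 700L)))
  expect_equal(classify_bubble(up49[1], gap49[1], m)$type, "genomic-deletion")
  expect_equal(classify_bubble(up49[1], gap50[1], m)$type, "intron-retention")

  # (2,1): genomic insertion
  up_ins <- mk(rbind(c(101L, 400L), c(401L, 700L)))
  lo_ins <- mk(rbind(c(101L, 700L)))
  expect_equal(classify_bubble(up_ins[1], lo_ins[1], m)$type,
               "genomic-insertion")

  # short flanking exon: block counts rise on both paths but the
  # difference stays 1 -> still exon skipping
  up_sf <- mk(rbind(c(101L, 200L), c(301L, 400L), c(441L, 460L),
                    c(501L, 600L)))
  lo_sf <- mk(rbind(c(101L, 200L), c(441L, 460L), c(501L, 600L)))
  ev_sf <- classify_bubble(up_sf[1], lo_sf[1], m)
  expect_equal(ev_sf$type, "exon-skipping")
  expect_equal(c(ev_sf$skip_start, ev_sf$skip_end), c(301L, 400L))

  # (2,2) sharing the left junction side: alternative acceptor on +
  up_aa <- mk(rbind(c(101L, 200L), c(301L, 400L)))
  lo_aa <- mk(rbind(c(101L, 200L), c(331L, 400L)))
  expect_equal(classify_bubble(up_aa[1], lo_aa[1], m)$type, "alt-acceptor")
  # sharing the right side: alternative donor on +
  up_ad <- mk(rbind(c(101L, 230L), c(301L, 400L)))
  lo_ad <- mk(rbind(c(101L, 200L), c(301L, 400L)))
  expect_equal(classify_bubble(up_ad[1], lo_ad[1], m)$type, "alt-donor")
})

test_that("alt-site orientation follows gene strand", {
  ex <- data.table::data.table(
    contig = "chr1", start = c(101L, 301L), end = c(200L, 400L),
    strand = "-", gene_id = "mg", transcript_id = "mg.t1")
  mm <- build_gene_model(ex)
  mk <- function(m) data.table::data.table(contig = "chr1", strand = "+",
                                           nblocks = nrow(m), start = m[1, 1],
                                           blocks = list(m), multi = FALSE)
  up_aa <- mk(rbind(c(101L, 200L), c(301L, 400L)))
  lo_aa <- mk(rbind(c(101L, 200L), c(331L, 400L)))
  # on the minus strand the variable right-side boundary is the donor
  expect_equal(classify_bubble(up_aa[1], lo_aa[1], mm)$type, "alt-donor")
})

test_that("splice sites are flagged against the annotation with dinucleotides", {
  m <- toy$model
  ev <- data.table::data.table(
    type = "exon-skipping", gene_id = "toy", contig = "chr1", strand = "+",
    skip_start = 501L, skip_end = 590L, up_end = 300L, down_start = 841L)
  fl <- flag_splice_sites(ev, m, toy$genome)
  expect_equal(fl$n_novel_sites, 0L)
  expect_true(grepl("annotated", fl$site_detail))
  # a shifted (novel) junction: dinucleotides reported from the genome
  ev2 <- data.table::data.table(
    type = "intron-retention", gene_id = "toy", contig = "chr1",
    strand = "+", skip_start = NA_integer_, skip_end = NA_integer_,
    up_end = 310L, down_start = 841L)
  fl2 <- flag_splice_sites(ev2, m, toy$genome)
  expect_equal(fl2$n_novel_sites, 1L)
  dn <- sub(".*donor:310:novel:([ACGT]{2}).*", "\\1", fl2$site_detail)
  expect_equal(dn, genome_seq(toy$genome, "chr1", 311L, 312L))
})

test_that("novel-site dinucleotides equal the genome at intron boundaries", {
  # cross-check property on the simulated reference: annotated junctions
  # flagged novel against an empty model must report GT/AG
  cfg <- sim_config(seed = 21L, n_genes = 2L, n_events = 2L)
  ref <- generate_reference(cfg)
  empty <- build_gene_model(data.table::data.table(
    contig = "chr1", start = 1L, end = 10L, strand = "+",
    gene_id = "x", transcript_id = "x.1"))
  jx <- ref$model$junctions
  for (i in seq_len(min(5L, nrow(jx)))) {
    ev <- data.table::data.table(
      type = "intron-retention", gene_id = NA_character_, contig = "chr1",
      strand = "+", skip_start = NA_integer_, skip_end = NA_integer_,
      up_end = jx$lend[i], down_start = jx$rstart[i])
    fl <- flag_splice_sites(ev, empty, ref$genome)
    expect_equal(fl$n_novel_sites, 2L)
    expect_true(grepl("novel:GT", fl$site_detail))
    expect_true(grepl("novel:AG", fl$site_detail))
  }
})

test_that("repeat status distinguishes exact and inexact repeats", {
  two <- data.table::data.table(contig = "chr1", strand = "+", nblocks = 1L,
                                start = c(100L, 900L),
                                blocks = list(cbind(100L, 150L),
                                              cbind(900L, 950L)),
                                multi = TRUE)
  one_a <- two[1]; one_b <- two[2]
  expect_equal(classify_repeat(two, two), "exact-repeat")
  expect_equal(classify_repeat(one_a, one_b), "inexact-repeat")
  expect_equal(classify_repeat(one_a, one_a), "none")
  # symmetric under swapping locus labels
  swapped <- two[2:1]
  expect_equal(classify_repeat(swapped, two), "exact-repeat")
})

test_that("polymorphism redundancy is merged with summed counts", {
  ev <- data.table::data.table(
    event_id = c("a", "b", "c"),
    type = "exon-skipping", contig = "chr1",
    up_end = c(300L, 300L, 300L), skip_start = c(501L, 501L, 601L),
    skip_end = c(590L, 590L, 690L), down_start = c(841L, 841L, 841L),
    incl_s1 = c(10, 5, 7), excl_s1 = c(2, 3, 1))
  dd <- deduplicate_polymorphism(ev)
  expect_equal(nrow(dd), 2L)
  merged <- dd[skip_start == 501L]
  expect_equal(merged$incl_s1, 15)
  expect_equal(merged$excl_s1, 5)
  expect_equal(nrow(deduplicate_polymorphism(ev[0])), 0L)
})
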