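toy_map <- make_toy_locus(seed = 202L)

test_that("alignment filtering applies flag and MAPQ semantics", {
  sam <- write_test_sam(c(
    sam_rec("r1", 99L, 100L, 50L, "76M", 76L),          # keep
    sam_rec("r2", 99L + 256L, 100L, 50L, "76M", 76L),   # secondary
    sam_rec("r3", 99L, 100L, 3L, "76M", 76L),           # low MAPQ
    sam_rec("r4", 4L, 100L, 0L, "*", NULL),             # unmapped
    sam_rec("r5", 0L, 100L, 50L, "76M", 76L)))          # unpaired
  aln <- read_sam(sam)
  expect_equal(nrow(aln), 5L)
  kept <- filter_alignments(aln)
  expect_equal(kept$qname, "r1")
})

test_that("CIGAR walking produces blocks, junctions and trims short ends", {
  # 38M100N38M from 101: blocks 101-138 and 239-276, junction (138, 239)
  bl <- extract_blocks(101L, "38M100N38M")
  expect_equal(bl$blocks, rbind(c(101L, 138L), c(239L, 276L)))
  expect_equal(unlist(bl$junctions), c(lend = 138L, rstart = 239L))
  # plain match: one block, no junction
  bl2 <- extract_blocks(101L, "76M")
  expect_equal(nrow(bl2$blocks), 1L)
  expect_equal(nrow(bl2$junctions), 0L)
  # 2M100N74M: 2-nt end block removed, read no longer a junction read
  bl3 <- extract_blocks(101L, "2M100N74M")
  expect_equal(nrow(bl3$blocks), 1L)
  expect_equal(nrow(bl3$junctions), 0L)
  expect_equal(bl3$blocks[1, ], c(203L, 276L))
  # deletions stay within a block; insertions consume the read only
  bl4 <- extract_blocks(101L, "30M2D44M")
  expect_equal(nrow(bl4$blocks), 1L)
  expect_equal(bl4$blocks[1, 2L], 101L + 30L + 2L + 44L - 1L)
  expect_equal(length(bl4$indels), 1L)
  bl5 <- extract_blocks(101L, "30M2I44M")
  expect_equal(bl5$blocks[1, 2L], 101L + 30L + 44L - 1L)
  # unknown operation: NULL with no crash
  expect_null(extract_blocks(101L, "10Q66M"))
})

test_that("junction-read filters drop softclip, indel-near-junction and bad blocks", {
  m <- toy_map$model
  # 10S30M100N36M on a 76-nt read: 10/76 > 10% -> softclip
  bl <- extract_blocks(271L, "10S30M100N36M")
  res <- filter_junction_read(bl, "chr1", m)
  expect_false(res$keep)
  expect_equal(res$reason, "softclip")
  # deletion 4 nt from the junction -> indel-near-junction
  bl2 <- extract_blocks(265L, "30M2D4M100N40M")
  res2 <- filter_junction_read(bl2, "chr1", m)
  expect_false(res2$keep)
  expect_equal(res2$reason, "indel-near-junction")
  # clean junction read with both end blocks in single annotated exons
  bl3 <- extract_blocks(281L, "20M200N40M")  # e1 end + e2 start of the toy
  res3 <- filter_junction_read(bl3, "chr1", m)
  expect_true(res3$keep)
  # first block outside any exon -> dropped
  bl4 <- extract_blocks(150L, "20M131N40M")
  res4 <- filter_junction_read(bl4, "chr1", m)
  expect_false(res4$keep)
  expect_equal(res4$reason, "block-exon-overlap")
})

test_that("junction annotation flags sides and discards symmetric shifts", {
  m <- toy_map$model  # junctions: (300,501), (590,841), (300,841)
  jx <- data.table::data.table(
    contig = "chr1",
    lend = c(300L, 293L, 300L, 280L),
    rstart = c(501L, 494L, 586L, 560L),
    n_s1 = c(10L, 5L, 4L, 3L))
  out <- annotate_junction(jx, m)
  expect_equal(out$status[1], "annotated")
  # shifted by -7 on both sides: mapping artifact
  expect_equal(out$status[2], "discarded")
  # novel acceptor 85 nt off with an annotated donor
  expect_equal(out$status[3], "novel-acceptor")
  # both sides novel with different shifts: kept as both-novel
  expect_equal(out$status[4], "both-novel")
})

test_that("intron retention evidence comes from boundary-spanning blocks", {
  m <- toy_map$model
  blocks <- data.table::data.table(
    read_id = c("a", "b", "c"), sample = "s1", contig = "chr1",
    start = c(281L, 520L, 281L), end = c(330L, 560L, 900L))
  ir <- detect_intron_retention(blocks, m)
  # read a spans the exon1-intron1 boundary; read c spans both introns
  expect_equal(sort(unique(ir$intron_lend)), c(300L, 590L))
  expect_equal(ir[intron_lend == 300L, count], 2L)
  expect_equal(ir[intron_lend == 590L, count], 1L)
})

test_that("skipped exons are called from annotated junctions with quantification", {
  m <- toy_map$model
  jx <- data.table::data.table(
    contig = "chr1",
    lend = c(300L, 590L, 300L),
    rstart = c(501L, 841L, 841L),
    n_s1 = c(10L, 20L, 7L))
  jx <- annotate_junction(jx, m)
  ev <- call_skipped_exons(jx, m)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "skipped-exon")
  expect_equal(c(ev$skip_start, ev$skip_end), c(501L, 590L))
  # inclusion = mean of the two inclusion junctions; exclusion = its count
  expect_equal(ev$incl_s1, 15)
  expect_equal(ev$excl_s1, 7)
  # missing junction counts as zero
  jx0 <- data.table::data.table(contig = "chr1", lend = 300L, rstart = 841L,
                                n_s1 = 4L)
  jx0 <- annotate_junction(jx0, m)
  ev0 <- call_skipped_exons(jx0, m)
  expect_equal(ev0$incl_s1, 0)
  expect_equal(ev0$excl_s1, 4)
})

test_that("unannotated exclusion junctions use the longest covered inclusion isoform", {
  # gene with exons 1..4; transcripts: full and (1,2,4); the junction
  # 1->4 is NOT annotated; covered inclusion junctions allow the chains
  # 1-2-4 and 1-2-3-4: the longest covered chain wins
  ex <- data.table::data.table(
    contig = "chr1",
    start = c(101L, 301L, 501L, 701L, 101L, 301L),
    end = c(200L, 400L, 600L, 800L, 200L, 400L),
    strand = "+", gene_id = "g",
    transcript_id = c(rep("t1", 4), rep("t2", 2)))
  ex2 <- rbind(ex[1:4], ex[5:6],
               data.table::data.table(contig = "chr1", start = 701L,
                                      end = 800L, strand = "+",
                                      gene_id = "g", transcript_id = "t2"))
  m <- build_gene_model(ex2)
  jx <- data.table::data.table(
    contig = "chr1",
    lend = c(200L, 400L, 600L, 400L, 200L),
    rstart = c(301L, 501L, 701L, 701L, 701L),
    n_s1 = c(10L, 10L, 10L, 5L, 3L))
  jx <- annotate_junction(jx, m)
  ev <- call_skipped_exons(jx, m)
  # the junction 200->701 is unannotated: chain 1-2-3-4 (skip {2,3}) is
  # covered and longer than 1-2-4 (skip {2})
  un <- ev[up_end == 200L & down_start == 701L]
  expect_equal(nrow(un), 1L)
  expect_equal(un$type, "multi-exon-skipping")
  expect_equal(c(un$skip_start, un$skip_end), c(301L, 600L))
})

test_that("annotated junctions emit one event per annotated combination", {
  # transcripts (4,5,6,7), (4,6,7) and (4,7): the exclusion junction 4->7
  # yields the skipping of {5,6} and of {6} (and of {5} via (4,5,7))
  mkx <- function(tid, idx) data.table::data.table(
    contig = "chr1", start = c(101L, 301L, 501L, 701L)[idx],
    end = c(200L, 400L, 600L, 800L)[idx], strand = "+", gene_id = "g",
    transcript_id = tid)
  ex <- rbind(mkx("t_full", 1:4), mkx("t_46", c(1L, 3L, 4L)),
              mkx("t_47", c(1L, 4L)), mkx("t_45", c(1L, 2L, 4L)))
  m <- build_gene_model(ex)
  jx <- data.table::data.table(
    contig = "chr1",
    lend = c(200L, 200L, 400L, 600L, 200L, 400L),
    rstart = c(701L, 501L, 701L, 701L, 301L, 501L),
    n_s1 = c(8L, 6L, 4L, 9L, 12L, 11L))
  jx <- annotate_junction(jx, m)
  ev <- call_skipped_exons(jx, m)
  e47 <- ev[up_end == 200L & down_start == 701L]
  sets <- sort(paste(e47$skip_start, e47$skip_end))
  expect_true(paste(301L, 600L) %in% sets)  # skip {2,3}
  expect_true(paste(501L, 600L) %in% sets)  # skip {3} flanked by 1 and 4
  expect_true(paste(301L, 400L) %in% sets)  # skip {2} flanked by 1 and 4
})

test_that("the mapping-first caller recovers simulated events from SAM", {
  cfg <- sim_config(seed = 14L, n_genes = 3L, n_events = 3L, coverage = 30)
  ref <- generate_reference(cfg)
  out <- tempfile()
  sim <- simulate_reads(ref, out)
  fl <- mapfirst_events(sim$sam_paths, ref$model)
  expect_equal(nrow(fl$events), 3L)
  expect_equal(
    fl$events[order(skip_start), .(skip_start, skip_end)],
    sim$truth[order(skip_start), .(skip_start, skip_end)])
  for (s in sim$samples$sample) {
    expect_equal(fl$events[order(skip_start)][[paste0("incl_", s)]],
                 sim$truth[order(skip_start)][[paste0("incl_", s)]])
    expect_equal(fl$events[order(skip_start)][[paste0("excl_", s)]],
                 as.numeric(sim$truth[order(skip_start)][[paste0("excl_", s)]]))
  }
  # every dropped junction read carries exactly one reason
  expect_true(all(fl$drop_log$reason %in%
                    c("bad-cigar", "softclip", "indel-near-junction",
                      "block-exon-overlap")))
})
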