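mk_events <- function(skips, incl, excl, type = "skipped-exon",
                      prefix = "e") {
  data.table::data.table(
    event_id = paste0(prefix, seq_along(skips)),
    type = type, gene_id = "g", contig = "chr1", strand = "+",
    skip_start = skips, skip_end = skips + 99L,
    up_end = skips - 201L, down_start = skips + 300L,
    incl_s1 = incl, excl_s1 = excl)
}

test_that("low-expression filtering applies both cutoffs", {
  ev <- mk_events(c(1000L, 3000L, 5000L), incl = c(100, 100, 100),
                  excl = c(4, 8, 50))
  out <- filter_low_expression(ev)
  # minor 4 < 5 reads; minor 8 is 8/108 < 10%; minor 50 kept
  expect_equal(out$event_id, "e3")
  # monotone: raising either threshold never enlarges the surviving set
  base <- nrow(filter_low_expression(ev, 5, 0.10))
  expect_lte(nrow(filter_low_expression(ev, 10, 0.10)), base)
  expect_lte(nrow(filter_low_expression(ev, 5, 0.30)), base)
})

test_that("event matching uses skipped-exon coordinates, not flanks", {
  a <- mk_events(c(1000L, 3000L), incl = c(20, 20), excl = c(10, 10),
                 type = "exon-skipping", prefix = "a")
  b <- mk_events(c(1000L, 7000L), incl = c(20, 20), excl = c(10, 10),
                 prefix = "b")
  b[1, `:=`(up_end = 500L, down_start = 1400L)]  # different flanks
  rep <- match_events(a, b)
  expect_equal(nrow(rep$common), 1L)
  expect_equal(rep$common$skip_start, 1000L)
  expect_equal(rep$a_only$event_id, "a2")
  expect_equal(rep$b_only$event_id, "b2")
  # symmetry: swapping sides swaps the only-sets
  rep2 <- match_events(b, a)
  expect_equal(nrow(rep2$common), 1L)
  expect_equal(rep2$a_only$event_id, "b2")
  expect_equal(rep2$b_only$event_id, "a2")
  # empty side
  rep3 <- match_events(a[0], b)
  expect_equal(nrow(rep3$common), 0L)
  expect_equal(nrow(rep3$b_only), 2L)
})

test_that("discrepancy categories follow annotation and repeat evidence", {
  toy <- make_toy_locus(seed = 303L)
  m <- toy$model  # exons: 201-300, 501-590, 841-950
  asm_ev <- function(skip_s, skip_e, up, dn, rep_status = "none") {
    data.table::data.table(
      event_id = "x", type = "exon-skipping", gene_id = "toy",
      contig = "chr1", strand = "+", skip_start = skip_s, skip_end = skip_e,
      up_end = up, down_start = dn, repeat_status = rep_status,
      incl_s1 = 50, excl_s1 = 30)
  }
  # skipped exon absent from the annotation
  expect_equal(categorize_discrepancy(
    asm_ev(651L, 750L, 590L, 841L), "assembly_only", m), "novel-exon")
  # skipped exon annotated, flank boundary not annotated
  expect_equal(categorize_discrepancy(
    asm_ev(501L, 590L, 320L, 841L), "assembly_only", m), "novel-flank")
  # exact-repeat flag wins: paralog
  expect_equal(categorize_discrepancy(
    asm_ev(501L, 590L, 300L, 841L, rep_status = "exact-repeat"),
    "assembly_only", m), "paralog")
  # both exons annotated, junction annotated -> other
  expect_equal(categorize_discrepancy(
    asm_ev(501L, 590L, 300L, 841L), "assembly_only", m), "other")

  # mapping-only: repeat overlap of the skipped exon
  reps <- data.table::data.table(contig = "chr1", start = 480L, end = 610L,
                                 name = "alu1")
  mev <- asm_ev(501L, 590L, 300L, 841L)
  expect_equal(categorize_discrepancy(mev, "mapping_only", m, reps),
               "repeat-overlap")
  # low minor isoform before the complex check
  mev2 <- data.table::copy(mev)[, `:=`(incl_s1 = 100, excl_s1 = 2)]
  expect_equal(categorize_discrepancy(mev2, "mapping_only", m),
               "low-minor-isoform")
  # removed-junction evidence from the assembler log
  k <- 15L
  ctx <- paste0(genome_seq(toy$genome, "chr1", 300L - k + 1L, 300L),
                genome_seq(toy$genome, "chr1", 841L, 841L + k - 1L))
  log <- list(removed_edges = data.table::data.table(
    junction_seq = substring(ctx, 8L, 8L + k)))
  expect_equal(categorize_discrepancy(mev, "mapping_only", m, NULL, log,
                                      toy$genome), "complex-low-branch")
  expect_equal(categorize_discrepancy(mev, "mapping_only", m), "other")
})

test_that("novel-combination requires annotated exons without a joining transcript", {
  # exons 1..3 annotated but only via transcripts (1,2) and (2,3): the
  # junction 1->3 is not annotated
  ex <- data.table::data.table(
    contig = "chr1", start = c(101L, 301L, 101L + 0L, 501L),
    end = c(200L, 400L, 200L, 600L), strand = "+", gene_id = "g",
    transcript_id = c("t1", "t1", "t2", "t2"))
  ex[3, `:=`(start = 301L, end = 400L)]
  m <- build_gene_model(ex)
  ev <- data.table::data.table(
    event_id = "x", type = "exon-skipping", gene_id = "g", contig = "chr1",
    strand = "+", skip_start = 301L, skip_end = 400L, up_end = 200L,
    down_start = 501L, repeat_status = "none", incl_s1 = 40, excl_s1 = 20)
  expect_equal(categorize_discrepancy(ev, "assembly_only", m),
               "novel-combination")
})

test_that("differential comparison pairs events and flags discordance", {
  da <- data.table::data.table(
    event_id = c("a1", "a2", "a3"), p_value = c(0.001, 0.2, 0.001),
    padj = c(0.003, 0.3, 0.003), psi1 = c(0.8, 0.5, 0.7),
    psi2 = c(0.5, 0.5, 0.4), delta_psi = c(0.3, 0, 0.3),
    significant = c(TRUE, FALSE, TRUE))
  db <- data.table::data.table(
    event_id = c("b1", "b2"), p_value = c(0.002, 0.2),
    padj = c(0.004, 0.3), psi1 = c(0.82, 0.5), psi2 = c(0.5, 0.5),
    delta_psi = c(0.32, 0.01), significant = c(TRUE, FALSE))
  matches <- data.table::data.table(a_event_id = c("a1", "a2"),
                                    b_event_id = c("b1", "b2"))
  cd <- compare_differential(da, db, matches)
  expect_equal(cd$n_sig_both, 1L)
  expect_equal(cd$n_sig_a_only, 1L)  # a3 unmatched but significant
  expect_equal(nrow(cd$discordant), 0L)
  # make b1 non-significant: a1/b1 becomes discordant
  db2 <- data.table::copy(db)[1, significant := FALSE]
  cd2 <- compare_differential(da, db2, matches)
  expect_equal(nrow(cd2$discordant), 1L)
  expect_equal(cd2$discordant$a_event_id, "a1")
  # empty significant sets: empty report
  cd3 <- compare_differential(da[significant == FALSE],
                              db2[significant == FALSE], matches[0])
  expect_equal(cd3$n_sig_both, 0L)
  expect_equal(nrow(cd3$paired), 0L)
})
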