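test_that("contigs anchor with correct interval, orientation and identity", {
  g <- fx_genome()
  s <- g$record$seq
  exact <- substr(s, 101, 500)  # reference[100, 500) 0-based
  anc <- anchor_contigs(c(exact, revcomp(exact)), g)
  expect_equal(anc$start, c(100L, 100L))
  expect_equal(anc$end, c(500L, 500L))
  expect_identical(anc$strand, c("+", "-"))
  expect_equal(anc$identity, c(1, 1))
  expect_identical(anc$seq[2L], exact)  # oriented to reference forward

  set.seed(61)
  junk <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  anc2 <- anchor_contigs(junk, g)
  expect_true(is.na(anc2$start))

  # origin-spanning contig
  wrap <- paste0(substr(s, nchar(s) - 199, nchar(s)), substr(s, 1, 200))
  anc3 <- anchor_contigs(wrap, g)
  expect_identical(anc3$start, nchar(s) - 200L)
  expect_identical(anc3$end - anc3$start, 400L)
})

test_that("agreeing overlaps merge; disagreeing ones are logged as conflicts", {
  g <- fx_genome()
  s <- g$record$seq
  a <- substr(s, 1001, 2000)
  b <- substr(s, 1951, 2950)  # 50 bp agreement
  pre <- merge_and_close(anchor_contigs(c(a, b), g), NULL, g, reads = NULL)
  expect_identical(nrow(pre$placements), 1L)
  expect_identical(nchar(pre$placements$seq), nchar(a) + nchar(b) - 50L)

  b2 <- b
  substr(b2, 10L, 25L) <- strrep("A", 16)  # corrupt the overlap
  if (substr(b, 10, 25) == strrep("A", 16)) skip("degenerate fixture")
  pre2 <- merge_and_close(anchor_contigs(c(a, b2), g), NULL, g, reads = NULL)
  expect_identical(nrow(pre2$placements), 2L)
  expect_gt(nrow(pre2$conflicts), 0L)
})

test_that("gap recruit windows span the gap plus 300 bp on both sides", {
  g <- fx_genome()
  gaps <- data.frame(start = 5000L, end = 5200L)
  fl <- mitobait:::gap_flanks(g$record, gaps, 300L)
  expect_identical(nchar(fl), 200L + 2L * 300L)
  expect_identical(fl, substr(g$record$seq, 5000L - 300L + 1L, 5200L + 300L))
  # wrap-aware at the origin
  gw <- data.frame(start = -50L, end = 100L)
  flw <- mitobait:::gap_flanks(g$record, gw, 300L)
  L <- seq_length(g)
  expect_identical(flw, paste0(substr(g$record$seq, L - 349L, L),
                               substr(g$record$seq, 1L, 400L)))
})

test_that("local reassembly closes a covered gap completely", {
  mx <- small_mixture()
  # withhold contigs overlapping one region to force a gap, then let the
  # reads close it
  anc <- anchor_contigs(mx$contigs, mx$ref)
  anc <- anc[!is.na(anc$start), , drop = FALSE]
  keep <- !(anc$start < 6000 & anc$end > 4000)
  pre <- merge_and_close(anc[keep, , drop = FALSE], NULL, mx$ref,
                         reads = mx$trimmed)
  sc <- finalize_scaffold(pre, mx$ref)
  expect_gt(sc$completeness, 99.9)
  expect_identical(sum(strsplit(sc$seq, "")[[1L]] == "N"), 0L)
})

test_that("completeness arithmetic and N-fill follow the reference frame", {
  set.seed(67)
  ref <- seq_record("r", paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                               collapse = ""), circular = FALSE)
  rg <- annotated_genome(ref, list())
  # one contig covering reference[0, 619)
  anc <- anchor_contigs(substr(ref$seq, 1, 619), rg)
  pre <- merge_and_close(anc, NULL, rg, reads = NULL)
  sc <- finalize_scaffold(pre, rg)
  expect_equal(sc$completeness, 61.9)
  expect_identical(nchar(sc$seq), 1000L)
  expect_identical(nrow(sc$gaps), 1L)
  expect_identical(sc$gaps$fill_length, 381L)
  expect_identical(substr(sc$seq, 620, 1000), strrep("N", 381))
  # non-N bases are exactly the contig bases, never reference-altered
  expect_identical(substr(sc$seq, 1, 619), substr(ref$seq, 1, 619))

  empty <- finalize_scaffold(
    merge_and_close(anchor_contigs(character(0), rg), NULL, rg, reads = NULL), rg)
  expect_equal(empty$completeness, 0)
  full <- finalize_scaffold(
    merge_and_close(anchor_contigs(ref$seq, rg), NULL, rg, reads = NULL), rg)
  expect_equal(full$completeness, 100)
  expect_false(grepl("N", full$seq, fixed = TRUE))
})

test_that("back-mapping reports per-library coverage and flags mixed sites", {
  mx <- small_mixture()
  sc <- structure(list(id = "sc", seq = mx$prey$record$seq, circular = TRUE),
                  class = "scaffold_result")
  qc <- backmap_qc(list(sc), list(enriched = mx$trimmed))
  expect_identical(nrow(qc), 1L)
  expect_identical(qc$library, "enriched")
  expect_lt(abs(qc$mean_coverage - 50) / 50, 0.1)
  # a 50/50 two-haplotype pile-up flags the divergent sites
  hapB <- derive_haplotype(mx$prey, 0.003, seed = 99L, id = "hapB")
  trB <- truth_set(list(hapB), 50, seed = 100L)
  simB <- simulate_library(trB)
  both <- read_set(c(mx$sim$reads$id, simB$reads$id),
                   c(mx$sim$reads$seq1, simB$reads$seq1),
                   c(mx$sim$reads$seq2, simB$reads$seq2),
                   read_length = 250L, insert_range = c(400L, 800L))
  qc2 <- backmap_qc(list(sc), list(mixed = both))
  expect_gt(qc2$flagged_sites, 0L)
})
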