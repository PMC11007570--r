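test_that("sliding-window trimming removes low-quality tails", {
  good <- strrep("A", 90)
  tail_bad <- strrep("C", 10)
  q <- paste0(strrep("I", 90), strrep("#", 10))  # I = Q40, # = Q2
  rs <- read_set("p1", paste0(good, tail_bad), paste0(good, tail_bad), q, q)
  out <- preprocess_reads(rs, quality_cutoff = 15, min_length = 10L)
  expect_identical(out$seq1, good)
  expect_identical(nchar(out$qual1), 90L)
  # correct = FALSE leaves sequences otherwise untouched
  clean <- read_set("p2", good, good)
  expect_identical(preprocess_reads(clean, min_length = 10L)$seq1, good)
})

test_that("adapter suffixes are clipped at exact matches of 10+ bp", {
  insert <- paste(rep(c("A", "C", "G", "T"), 20), collapse = "")
  ad <- mitobait:::DEFAULT_ADAPTERS[1L]
  read <- paste0(insert, substr(ad, 1, 14))
  rs <- read_set("p1", read, read)
  out <- preprocess_reads(rs, min_length = 10L)
  expect_identical(out$seq1, insert)
})

test_that("short pairs are dropped whole, with their mates", {
  rs <- read_set(c("a", "b"),
                 c(strrep("A", 100), strrep("A", 100)),
                 c(strrep("C", 100), strrep("C", 30)))
  out <- preprocess_reads(rs, min_length = 50L)
  expect_identical(out$id, "a")
})

test_that("the k-mer spectrum corrector repairs an isolated substitution", {
  set.seed(21)
  tpl <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  reads <- tile_reads(tpl, 100L, 3L)  # ~30x error-free coverage
  mutated <- reads[50L]
  substr(mutated, 40L, 40L) <- setdiff(c("A", "C", "G", "T"),
                                       substr(mutated, 40L, 40L))[1L]
  n <- length(reads)
  rs <- read_set(sprintf("p%d", 1:n), c(reads[-50L], mutated), rev(reads))
  out <- preprocess_reads(rs, correct = TRUE, min_length = 10L)
  expect_identical(out$seq1[n], reads[50L])      # repaired
  expect_identical(out$seq1[1:(n - 1L)], reads[-50L])  # untouched
})

test_that("baiting recruits panel-derived reads and rejects random ones", {
  g <- fx_genome()
  s <- g$record$seq
  verbatim <- substr(s, 1001, 1250)
  junk <- strrep("A", 250)
  rs <- read_set(c("hit", "pair_rescue"),
                 c(verbatim, junk),
                 c(junk, revcomp(substr(s, 5001, 5250))))
  out <- bait_reads(rs, list(g))
  expect_setequal(out$id, c("hit", "pair_rescue"))  # mate rescue included

  set.seed(31)
  gc_frac <- mean(strsplit(s, "")[[1L]] %in% c("G", "C"))
  nrand <- 1e5
  mat <- matrix(sample(c("G", "C", "A", "T"), nrand * 25,
                       prob = c(gc_frac / 2, gc_frac / 2,
                                (1 - gc_frac) / 2, (1 - gc_frac) / 2),
                       replace = TRUE), nrow = nrand)
  rand <- apply(mat, 1L, paste, collapse = "")
  rand <- vapply(seq_len(nrand / 10), function(i)
    paste(rand[(10 * i - 9):(10 * i)], collapse = ""), "")  # 250 nt each
  rrs <- read_set(sprintf("r%d", seq_along(rand)), rand, rand)
  expect_identical(n_pairs(bait_reads(rrs, list(g), min_shared_kmers = 2L)), 0L)
})

test_that("baiting reports recall and precision against a truth table", {
  mx <- small_mixture()
  metrics <- attr(mx$baited, "metrics")
  expect_gte(metrics[["recall"]], 0.95)
  expect_gte(metrics[["precision"]], 0.99)
})

test_that("error-free tiled reads assemble to the exact target", {
  set.seed(41)
  target <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  reads <- tile_reads(target, 100L, 10L)
  rs <- read_set(sprintf("p%d", seq_along(reads)), reads, rev(reads))
  ctg <- assemble_and_extend(rs, min_kmer_count = 1L)
  expect_identical(nrow(ctg), 1L)
  expect_identical(canonical_seq(ctg$seq[1L]), canonical_seq(target))
  # and matches the brute-force overlap-layout-consensus oracle
  oracle <- olc_oracle(reads)
  expect_identical(length(oracle), 1L)
  expect_identical(canonical_seq(oracle), canonical_seq(target))
})

test_that("a seed with no overlapping reads survives extension unchanged", {
  set.seed(43)
  seed_seq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  lone <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
  rs <- read_set("p1", seed_seq, lone)
  ctg <- assemble_and_extend(rs, iterations = 10L, min_kmer_count = 1L)
  expect_true(canonical_seq(seed_seq) %in% canonical_seq(ctg$seq))
})

test_that("assembly is deterministic and extension monotone", {
  mx <- small_mixture()
  again <- assemble_and_extend(preprocess_reads(mx$baited, quality_cutoff = 0,
                                                correct = TRUE))
  expect_identical(mx$contigs$seq, again$seq)
  few <- assemble_and_extend(mx$baited, iterations = 1L)
  more <- assemble_and_extend(mx$baited, iterations = 4L)
  expect_identical(nrow(few), nrow(more))
  expect_true(all(more$length >= few$length))
})

test_that("two haplotypes at 5% divergence assemble without chimeric columns", {
  base <- build_panel_genome(seed = 55L, id = "b55")
  hapA <- derive_haplotype(base, 0.025, seed = 56L, id = "hapA")
  hapB <- derive_haplotype(base, 0.025, seed = 57L, id = "hapB")
  tr <- truth_set(list(hapA, hapB), c(100, 100), error_rate = 0, seed = 58L)
  sim <- simulate_library(tr)
  ctg <- assemble_and_extend(sim$reads)
  expect_gt(nrow(ctg), 0L)
  ev <- evaluate_recovery(setNames(ctg$seq, ctg$id),
                          list(hapA = hapA, hapB = hapB))
  expect_true(all(ev$chimeric_columns == 0L))
  expect_true(all(ev$identity_nonN > 99.9))
})
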