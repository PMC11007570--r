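test_that("generated genomes carry the full placozoan-style architecture", {
  g <- fx_genome()
  nm <- vapply(g$features, `[[`, "", "name")
  expect_true(all(c("COX1", "COX2", "COX3", "COB", "ATP6", "NAD1", "NAD2",
                    "NAD3", "NAD4", "NAD5", "NAD6", "NAD4L") %in% nm))
  expect_true(seq_length(g) >= 32000 && seq_length(g) <= 44000)
  expect_true(g$record$circular)
  cox1 <- g$features[[match("COX1", nm)]]
  expect_identical(nrow(cox1$exons), 8L)
  exlen <- mitobait:::exon_lengths(cox1$exons, seq_length(g))
  expect_true(any(exlen >= 9 & exlen <= 20))  # the micro exon
  expect_identical(nrow(g$features[[match("NAD5", nm)]]$exons), 2L)
  s16 <- g$features[nm %in% c("16S_a", "16S_b")]
  expect_identical(length(s16), 2L)
  expect_identical(sum(vapply(s16, function(f) nrow(f$exons), 0L)), 4L)
  # every coding feature is a clean table-4 ORF
  for (f in g$features) {
    if (f$kind %in% c("CDS", "ORF"))
      expect_no_error(translate_cds(extract_feature(g, f), 4L))
  }
  # features do not overlap
  spans <- t(vapply(g$features, function(f)
    c(min(f$exons[, 1L]), max(f$exons[, 2L])), c(0L, 0L)))
  ord <- order(spans[, 1L])
  expect_true(all(spans[ord, 1L][-1L] >= spans[ord, 2L][-nrow(spans)]))
})

test_that("genome generation is deterministic in the seed", {
  expect_identical(build_panel_genome(seed = 123L), build_panel_genome(seed = 123L))
  expect_false(identical(build_panel_genome(seed = 123L)$record$seq,
                         build_panel_genome(seed = 124L)$record$seq))
})

test_that("derived haplotypes hit the requested divergence and stay ORF-clean", {
  g <- fx_genome()
  same <- derive_haplotype(g, 0, seed = 1L)
  expect_identical(same$record$seq, g$record$seq)
  L <- seq_length(g)
  for (d in c(0.02, 0.1)) {
    h <- derive_haplotype(g, d, seed = 5L)
    realized <- attr(h, "divergence")
    tol <- 3 * sqrt(d * (1 - d) / L)
    expect_lt(abs(realized - d), tol + 0.1 * d)  # stop-repair pulls down slightly
    for (f in h$features)
      if (f$kind %in% c("CDS", "ORF"))
        expect_no_error(translate_cds(extract_feature(h, f), 4L))
  }
})

test_that("structural rearrangements update sequence and annotation together", {
  g <- fx_genome()
  inv <- derive_haplotype(g, 0, rearrangement = list(
    type = "inversion", from = "tRNA-Thr", to = "tRNA-Lys"), seed = 2L)
  expect_identical(seq_length(inv), seq_length(g))
  thr <- Filter(function(f) f$name == "tRNA-Thr", inv$features)[[1L]]
  expect_identical(thr$strand, "-")
  expect_identical(extract_feature(inv, "tRNA-Thr"), extract_feature(g, "tRNA-Thr"))
  tl <- derive_haplotype(g, 0, rearrangement = list(
    type = "translocation", feature = "POLB", after = "tRNA-Lys"), seed = 2L)
  expect_identical(seq_length(tl), seq_length(g))
  expect_identical(extract_feature(tl, "POLB"), extract_feature(g, "POLB"))
  for (f in tl$features)
    if (f$kind %in% c("CDS", "ORF"))
      expect_no_error(translate_cds(extract_feature(tl, f), 4L))
})

test_that("library simulation respects the stated library parameters", {
  g <- fx_genome()
  L <- seq_length(g)
  tr <- truth_set(list(g), 50, host = NULL, read_length = 250L,
                  insert_range = c(400L, 800L), error_rate = 0, seed = 9L)
  sim <- simulate_library(tr)
  expect_identical(n_pairs(sim$reads), as.integer(round(50 * L / 500)))
  expect_true(all(nchar(sim$reads$seq1) == 250L))
  expect_true(all(nchar(sim$reads$seq2) == 250L))
  expect_true(all(sim$origins$insert >= 400L & sim$origins$insert <= 800L))
  # error-free reads map perfectly and coverage lands within 10%
  qc <- backmap_qc(setNames(g$record$seq, "truth"), list(lib = sim$reads),
                   min_identity = 0.99)
  expect_lt(abs(qc$mean_coverage - 50) / 50, 0.1)
  expect_identical(qc$pairs, n_pairs(sim$reads))
})

test_that("two simulations with one seed give identical FASTQ bytes", {
  g <- fx_genome()
  tr <- truth_set(list(g), 2, seed = 77L)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_library(tr, outdir = d1)
  simulate_library(tr, outdir = d2)
  for (f in c("reads_1.fastq.gz", "reads_2.fastq.gz")) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2)
  }
})

test_that("infeasible architecture specs are rejected", {
  spec <- architecture_spec(genome_length_range = c(15000, 15000))
  expect_error(build_panel_genome(spec, seed = 1L), "infeasible")
})
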