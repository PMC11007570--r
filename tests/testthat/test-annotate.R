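test_that("transferring a genome's own annotations is the identity", {
  g <- fx_genome()
  tr <- transfer_annotations(g$record, g)
  expect_equal(tr$identity, 1)
  expect_identical(length(tr$genome$features), length(g$features))
  for (i in seq_along(g$features)) {
    expect_equal(unname(tr$genome$features[[i]]$exons),
                 unname(g$features[[i]]$exons))
    expect_identical(tr$genome$features[[i]]$strand, g$features[[i]]$strand)
  }
  expect_true(all(tr$report$status == "transferred"))
})

test_that("an insertion shifts downstream features through the projection", {
  g <- fx_genome()
  # insert 3 nt into an intergenic stretch between the first two features
  starts <- sort(vapply(g$features, function(f) min(f$exons[, 1L]), 0L))
  ends <- sort(vapply(g$features, function(f) max(f$exons[, 2L]), 0L))
  pos <- starts[2L] - 5L  # inside the gap before the second feature
  stopifnot(pos > ends[1L])
  mut <- seq_record("ins3", paste0(substr(g$record$seq, 1L, pos), "GGG",
                                   substr(g$record$seq, pos + 1L,
                                          seq_length(g))), circular = TRUE)
  tr <- transfer_annotations(mut, g)
  for (f0 in g$features) {
    f1 <- Filter(function(f) f$name == f0$name, tr$genome$features)[[1L]]
    shift <- ifelse(f0$exons >= pos, 3L, 0L)
    expect_equal(unname(f1$exons), unname(f0$exons + shift),
                 info = f0$name)
  }
  # structure is preserved: COX1 keeps its 8 exons
  cox1 <- Filter(function(f) f$name == "COX1", tr$genome$features)[[1L]]
  expect_identical(nrow(cox1$exons), 8L)
})

test_that("transfer onto a diverged haplotype keeps CDS readable", {
  g <- fx_genome()
  h <- derive_haplotype(g, 0.05, seed = 13L, id = "h5")
  tr <- transfer_annotations(h$record, g)
  val <- validate_orfs(tr$genome)
  expect_true(all(val$pass))
  expect_error(transfer_annotations(
    seq_record("junk", paste(rep("ACGT", 8000), collapse = "")), g),
    "refusing transfer")
})

test_that("ORF validation distinguishes failures from gap truncation", {
  g <- fx_genome()
  expect_true(all(validate_orfs(g)$pass))
  nm <- vapply(g$features, `[[`, "", "name")
  cob <- g$features[[match("COB", nm)]]
  # frame shift by 1 nt creates internal stops
  shifted <- feature("COB", "CDS",
                     cbind(cob$exons[, 1L] + 1L, cob$exons[, 2L] + 1L),
                     cob$strand, 4L)
  gs <- annotated_genome(g$record, list(shifted))
  vs <- validate_orfs(gs)
  expect_false(vs$pass)
  expect_identical(vs$status, "internal_stop")
  expect_false(is.na(vs$stop_codon))
  # N-truncated CDS is incomplete, not failed
  s <- g$record$seq
  tail_start <- cob$exons[nrow(cob$exons), 2L] - 30L
  substr(s, tail_start + 1L, tail_start + 60L) <- strrep("N", 60L)
  gn <- annotated_genome(seq_record("gn", s, TRUE), list(cob))
  vn <- validate_orfs(gn)
  expect_true(vn$pass)
  expect_identical(vn$status, "incomplete_gap")
})

test_that("planted rearrangements are each detected exactly once", {
  g <- fx_genome()
  inv <- derive_haplotype(g, 0, rearrangement = list(
    type = "inversion", from = "tRNA-Thr", to = "tRNA-Lys"), seed = 3L)
  calls <- detect_rearrangements(g, inv)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$kind, "inversion")
  expect_setequal(strsplit(calls$features, ",")[[1L]],
                  c("tRNA-Thr", "tRNA-Lys"))

  tl <- derive_haplotype(g, 0, rearrangement = list(
    type = "translocation", feature = "POLB", after = "tRNA-Lys"), seed = 3L)
  calls2 <- detect_rearrangements(g, tl)
  expect_identical(nrow(calls2), 1L)
  expect_identical(calls2$kind, "translocation")
  expect_identical(calls2$features, "POLB")
  expect_identical(calls2$span_a, "NAD1..NAD4L")

  expect_identical(nrow(detect_rearrangements(g, g)), 0L)
})

test_that("rearrangement detection is symmetric and divergence-tolerant", {
  g <- fx_genome()
  for (re in list(list(type = "inversion", from = "tRNA-Thr", to = "tRNA-Lys"),
                  list(type = "translocation", feature = "POLB",
                       after = "tRNA-Lys"))) {
    h <- derive_haplotype(g, 0.05, rearrangement = re, seed = 17L)
    ab <- detect_rearrangements(g, h)
    ba <- detect_rearrangements(h, g)
    expect_identical(nrow(ab), 1L)
    expect_identical(nrow(ab), nrow(ba))
    expect_identical(ab$kind, ba$kind)
  }
})

test_that("rearrangements survive a transfer round-trip", {
  # derive a haplotype with an inversion, transfer annotations from the
  # un-rearranged reference: the detector must still see exactly one event
  g <- fx_genome()
  h <- derive_haplotype(g, 0.03, rearrangement = list(
    type = "inversion", from = "tRNA-Thr", to = "tRNA-Lys"), seed = 19L)
  calls <- detect_rearrangements(g, h)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$kind, "inversion")
})
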