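test_that("translation under genetic code 4 follows the table", {
  expect_identical(translate_cds("ATGTGATTTTAA", 4L), "MWF")
  err <- tryCatch(translate_cds("ATGTGATTTTAA", 1L), error = identity)
  expect_s3_class(err, "mitobait_internal_stop")
  expect_identical(err$codon, 2L)
  expect_error(translate_cds("ATGTT", 4L), "multiple of 3")
  expect_identical(translate_cds("ATGAANTAA", 4L), "MX")  # N codon
})

test_that("translation agrees with an independent codon-table oracle", {
  set.seed(11)
  code4 <- Biostrings::getGeneticCode("4")
  for (i in 1:200) {
    n <- 3L * sample(2:60, 1L)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(s), genetic.code = code4, no.init.codon = TRUE))
    aa <- strsplit(ref, "")[[1L]]
    internal <- which(aa[-length(aa)] == "*")
    if (length(internal)) {
      expect_error(translate_cds(s, 4L), class = "mitobait_internal_stop")
    } else {
      want <- if (aa[length(aa)] == "*") substr(ref, 1L, nchar(ref) - 1L) else ref
      expect_identical(translate_cds(s, 4L), want)
    }
  }
})

test_that("feature extraction honours wrap, order and strand", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  g <- annotated_genome(seq_record("g", s, circular = TRUE), list())
  wrap <- feature("w", "rRNA", matrix(c(90L, 10L), 1L), "+")
  expect_identical(extract_feature(g, wrap),
                   paste0(substr(s, 91, 100), substr(s, 1, 10)))
  two <- feature("t", "rRNA", rbind(c(0L, 6L), c(50L, 56L)), "+")
  expect_identical(extract_feature(g, two),
                   paste0(substr(s, 1, 6), substr(s, 51, 56)))
  minus <- feature("m", "rRNA", matrix(c(0L, 6L), 1L), "-")
  expect_identical(extract_feature(g, minus), revcomp(substr(s, 1, 6)))
  lin <- annotated_genome(seq_record("l", substr(s, 1, 50)), list())
  expect_error(extract_feature(lin, wrap), "linear")
})

test_that("extraction is inverse-consistent with the genome layout", {
  g <- fx_genome()
  s <- g$record$seq
  for (f in g$features) {
    ext <- extract_feature(g, f)
    expect_identical(nchar(ext), as.integer(feature_length(f, nchar(s))))
    # re-splice: the forward-strand image of the transcript must equal the
    # concatenated genome segments
    fwd <- if (f$strand == "-") revcomp(ext) else ext
    pieces <- vapply(seq_len(nrow(f$exons)), function(i)
      substr(s, f$exons[i, 1L] + 1L, f$exons[i, 2L]), "")
    expect_identical(fwd, paste(pieces, collapse = ""))
  }
})

test_that("sequence records validate their alphabet and emptiness", {
  expect_error(seq_record("x", ""), "non-empty")
  expect_error(seq_record("x", "ACGU"), "outside")
  expect_identical(seq_record("x", "acgtn")$seq, "ACGTN")
  expect_error(annotated_genome(
    seq_record("x", "ACGT"),
    list(feature("a", "tRNA", matrix(c(0L, 2L), 1L)),
         feature("a", "tRNA", matrix(c(2L, 4L), 1L)))), "duplicate")
})

test_that("FASTA and paired FASTQ round-trip, gzip included", {
  set.seed(5)
  n <- 20L
  seqs <- setNames(vapply(1:n, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), sample(40:200, 1L), TRUE),
          collapse = ""), ""), sprintf("rec%02d", 1:n))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  back <- read_fasta(fa)
  expect_identical(unname(back[names(seqs)]), unname(seqs))

  rs <- read_set(sprintf("p%03d", 1:n),
                 vapply(1:n, function(i) paste(sample(c("A", "C", "G", "T"),
                                                      120, TRUE), collapse = ""), ""),
                 vapply(1:n, function(i) paste(sample(c("A", "C", "G", "T"),
                                                      120, TRUE), collapse = ""), ""))
  for (ext in c(".fastq", ".fastq.gz")) {
    f1 <- tempfile(fileext = ext); f2 <- tempfile(fileext = ext)
    write_fastq_pairs(rs, f1, f2)
    back <- read_fastq_pairs(f1, f2)
    expect_identical(back$id, rs$id)
    expect_identical(back$seq1, rs$seq1)
    expect_identical(back$seq2, rs$seq2)
    expect_identical(back$qual2, rs$qual2)
  }

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIII"), bad)  # 8 nt, 7 quals
  expect_error(mitobait:::parse_fastq(bad), "length mismatch")
  ok1 <- tempfile(fileext = ".fastq"); ok2 <- tempfile(fileext = ".fastq")
  writeLines(c("@r1/1", "ACGT", "+", "IIII"), ok1)
  writeLines(c("@r2/2", "ACGT", "+", "IIII"), ok2)
  expect_error(read_fastq_pairs(ok1, ok2), "desynchronized")
})

test_that("feature tables and GFF3 export genomes faithfully", {
  g <- fx_genome()
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  write_fasta(list(g), fa)
  write_feature_table(list(g), tsv)
  back <- read_genomes(fa, tsv)[[g$record$id]]
  expect_identical(back$record$seq, g$record$seq)
  expect_identical(length(back$features), length(g$features))
  f0 <- g$features[[5L]]
  fb <- Filter(function(f) f$name == f0$name, back$features)[[1L]]
  expect_equal(unname(fb$exons), unname(f0$exons))
  expect_identical(fb$strand, f0$strand)

  gff <- tempfile(fileext = ".gff3")
  write_gff3(g, gff)
  lines <- readLines(gff)
  expect_match(lines[1L], "gff-version 3")
  body <- read.delim(text = lines[-(1:2)], header = FALSE)
  expect_true(all(body$V4 >= 1 & body$V5 <= seq_length(g)))
  expect_true(all(body$V4 <= body$V5))
})
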