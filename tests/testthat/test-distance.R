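test_that("p-distance with pairwise deletion follows the definition", {
  d <- pdistance_matrix(gene_alignment(c(a = "MKV", b = "MKL"), "aa"))
  expect_equal(d$d["a", "b"], 1 / 3)
  d2 <- pdistance_matrix(gene_alignment(c(a = "MK-", b = "MKL"), "aa"))
  expect_equal(d2$d["a", "b"], 0)
  expect_identical(d2$sites["a", "b"], 2L)
  # X and N count as missing under pairwise deletion
  d3 <- pdistance_matrix(gene_alignment(c(a = "MKX", b = "MKL"), "aa"))
  expect_identical(d3$sites["a", "b"], 2L)
  d4 <- pdistance_matrix(gene_alignment(c(a = "ACGN", b = "ACTT"), "nt"))
  expect_equal(d4$d["a", "b"], 1 / 3)
  # zero usable sites -> undefined
  d5 <- pdistance_matrix(gene_alignment(c(a = "--A", b = "CC-"), "nt"))
  expect_true(is.na(d5$d["a", "b"]))
})

test_that("p-distance equals a brute-force site loop on fuzzed alignments", {
  set.seed(71)
  brute <- function(x, y, alphabet) {
    miss <- mitobait:::missing_chars(alphabet)
    mm <- 0L; n <- 0L
    for (i in seq_along(x)) {
      if (x[i] %in% miss || y[i] %in% miss) next
      n <- n + 1L
      if (x[i] != y[i]) mm <- mm + 1L
    }
    if (n == 0L) NA_real_ else mm / n
  }
  for (rep in 1:40) {
    alphabet <- sample(c("nt", "aa"), 1L)
    chars <- if (alphabet == "nt") c("A", "C", "G", "T", "N", "-")
             else c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]], "X", "-")
    ntax <- sample(2:8, 1L); ncol <- sample(5:60, 1L)
    rows <- setNames(vapply(seq_len(ntax), function(i)
      paste(sample(chars, ncol, TRUE, prob = c(rep(1, length(chars) - 2L), 1, 1)),
            collapse = ""), ""), paste0("t", seq_len(ntax)))
    dm <- pdistance_matrix(gene_alignment(rows, alphabet))
    m <- strsplit(rows, "")
    for (i in 1:(ntax - 1L)) for (j in (i + 1L):ntax) {
      expect_identical(dm$d[i, j], brute(m[[i]], m[[j]], alphabet))
    }
    expect_true(all(diag(dm$d) == 0))
    expect_identical(dm$d, t(dm$d))
  }
})

test_that("percent identity matches its definition and the p-distance link", {
  expect_equal(percent_identity("ACGT", "ACGT"), 100)
  a <- paste(rep("A", 100), collapse = "")
  b <- paste0(strrep("A", 99), "C")
  expect_equal(percent_identity(a, b), 99)
  set.seed(73)
  x <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  y <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  dm <- pdistance_matrix(gene_alignment(c(x = x, y = y), "nt"))
  expect_equal(percent_identity(x, y), 100 * (1 - dm$d["x", "y"]))
  expect_error(percent_identity("---", "A--"), "zero comparable")
})

test_that("codon-aware matrices keep the 3:1 width relation", {
  g1 <- fx_genome()
  g2 <- g1
  g2$record$id <- "copy"
  mats <- build_matrices(list(one = g1, copy = g2))
  expect_identical(nchar(mats$CDS_nt$rows[[1L]]), 3L * nchar(mats$CDS_aa$rows[[1L]]))
  expect_false(any(grepl("-", mats$CDS_aa$rows, fixed = TRUE)))
  expect_equal(percent_identity(mats$CDS_aa$rows[[1L]], mats$CDS_aa$rows[[2L]]), 100)
  # concatenated width equals the sum of the per-gene partitions
  p <- mats$CDS_aa$partitions
  expect_identical(nchar(mats$CDS_aa$rows[[1L]]), p$end[nrow(p)])
  expect_identical(p$start[1L], 1L)
  expect_true(all(p$start[-1L] == p$end[-nrow(p)] + 1L))
  # per-gene widths also triple
  for (gene in names(mats$genes))
    expect_identical(nchar(mats$genes_nt[[gene]]$rows[[1L]]),
                     3L * nchar(mats$genes[[gene]]$rows[[1L]]))
})

test_that("missing genes become flagged all-gap blocks", {
  g1 <- fx_genome()
  feats <- Filter(function(f) f$name != "NAD3", g1$features)
  g2 <- annotated_genome(seq_record("del", g1$record$seq, TRUE), feats)
  mats <- build_matrices(list(full = g1, del = g2))
  miss <- attr(mats, "missing")
  expect_identical(miss$taxon, "del")
  expect_identical(miss$gene, "NAD3")
  nad3 <- mats$genes[["NAD3"]]
  expect_true(grepl("^-+$", nad3$rows[["del"]]))
})

test_that("group means and the single-group rule follow the scheme", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "C"] <- d["C", "A"] <- 0.4
  d["B", "C"] <- d["C", "B"] <- 0.2
  d["A", "B"] <- d["B", "A"] <- 0.1
  expect_equal(mitobait:::between_child_mean(d, c("A", "B", "C"),
                                             c("g1", "g1", "g2")), 0.3)
  expect_true(is.na(mitobait:::between_child_mean(d, c("A", "B", "C"),
                                                  c("g1", "g1", "g1"))))
})

test_that("rank partitions enforce nesting", {
  df <- data.frame(taxon = c("a", "b"), class = c("U", "U"),
                   order = c("o1", "o1"), family = c("f1", "f2"),
                   genus = c("g1", "g1"),  # one genus in two families
                   species = c("s1", "s2"), clade = c("c1", "c1"),
                   haplotype = c("H1", "H2"))
  expect_error(rank_partition(df), "nesting violated")
  df$genus <- c("g1", "g2")
  expect_s3_class(rank_partition(df), "rank_partition")
})

test_that("grand-mean distances decrease toward lower ranks on a clock-like panel", {
  cp <- clock_panel()
  tab <- rank_mean_distances(cp$per_gene, cp$partition)
  gm <- tab[tab$gene == "GRAND_MEAN" & tab$scope == "all", ]
  vals <- setNames(gm$mean_distance, gm$rank)
  expect_true(vals["order"] > vals["family"])
  expect_true(vals["family"] > vals["genus"])
  expect_true(vals["genus"] > vals["species"])
  expect_true(vals["species"] > vals["haplotype"])
  # the within-class summary exists and sits below the between-class signal
  expect_true(any(grepl("^within_", tab$scope)))
})

test_that("the diagnostic scan finds exactly the planted marker", {
  cp <- clock_panel()
  expect_identical(diagnostic_marker_scan(cp$per_gene[names(cp$matrices$genes)],
                                          cp$partition, "genus"), "NAD3")
  # a constant gene is not diagnostic (between-group distance zero)
  const <- cp$per_gene[["NAD3"]]
  const$d[] <- 0
  expect_identical(diagnostic_marker_scan(list(flat = const), cp$partition,
                                          "genus"), character(0))
})

test_that("neighbor joining recovers additive topologies and round-trips", {
  taxa <- c("A", "B", "C", "D")
  # additive matrix for ((A,B),(C,D)) with internal branch 0.02
  d <- matrix(c(0, .02, .13, .14,
                .02, 0, .13, .14,
                .13, .13, 0, .03,
                .14, .14, .03, 0), 4, 4, dimnames = list(taxa, taxa))
  dm <- structure(list(d = d, sites = d * 0 + 100L, label = "toy"),
                  class = "distance_matrix")
  res <- nj_tree_and_export(dm, "D")
  expect_true(ape::is.monophyletic(res$tree, c("A", "B")))
  back <- ape::read.tree(text = res$newick)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(res$tree))[1L], 0)
  expect_equal(sort(back$edge.length), sort(res$tree$edge.length))
  expect_true(all(res$tree$edge.length >= 0))
  expect_error(nj_tree_and_export(dm, "Z"), "outgroup absent")
})

test_that("alignment exports carry taxa, widths and partitions", {
  cp <- clock_panel()
  aln <- cp$matrices$CDS_aa
  phy <- tempfile(fileext = ".phy"); nex <- tempfile(fileext = ".nex")
  write_phylip(aln, phy)
  l1 <- readLines(phy)
  expect_identical(strsplit(l1[1L], " ")[[1L]],
                   c("7", as.character(nchar(aln$rows[[1L]]))))
  write_nexus(aln, nex)
  nx <- readLines(nex)
  expect_identical(nx[1L], "#NEXUS")
  expect_identical(sum(grepl("^CHARSET", nx)), nrow(aln$partitions))
})
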