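# Shared fixtures, memoized so expensive builds run once per session.

.fx_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx_cache))
    assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

fx_genome <- function(seed = 7L) {
  fixture(paste0("genome", seed), function() build_panel_genome(seed = seed))
}

# brute-force overlap-layout-consensus oracle for error-free toy read sets:
# greedily merges the pair of sequences with the longest exact overlap
# (considering both orientations) until no overlap >= min_overlap remains.
# Overlaps are cached in a matrix; after each merge only the new row and
# column are recomputed.
olc_oracle <- function(reads, min_overlap = 50L) {
  seqs <- unique(reads)
  # overlaps between error-free reads (and chains of them) never exceed
  # the read length, so the search is bounded there
  ov_cap <- max(nchar(reads))
  # longest suffix of a equal to a prefix of b (vectorized over lengths)
  overlap_len <- function(a, b) {
    max_ov <- min(nchar(a), nchar(b), ov_cap)
    if (max_ov < min_overlap) return(0L)
    ovs <- seq(max_ov, min_overlap)
    hit <- which(substring(a, nchar(a) - ovs + 1L, nchar(a)) ==
                   substring(b, 1L, ovs))
    if (length(hit)) ovs[hit[1L]] else 0L
  }
  rc_str <- function(s) {
    vapply(s, function(x)
      paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]),
            collapse = ""), "", USE.NAMES = FALSE)
  }
  rcs <- rc_str(seqs)
  # drop sequences contained in another (either orientation)
  n <- length(seqs)
  contained <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && !contained[j] &&
          (grepl(seqs[i], seqs[j], fixed = TRUE) ||
           grepl(rcs[i], seqs[j], fixed = TRUE))) {
        contained[i] <- TRUE
        break
      }
    }
  }
  seqs <- seqs[!contained]
  rcs <- rcs[!contained]
  n <- length(seqs)
  if (n <= 1L) return(seqs)
  pair_ov <- function(i, j) {
    ov1 <- overlap_len(seqs[i], seqs[j])
    ov2 <- overlap_len(seqs[i], rcs[j])
    if (ov1 >= ov2) c(ov1, 0L) else c(ov2, 1L)
  }
  OV <- matrix(0L, n, n)
  FLIP <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    po <- pair_ov(i, j)
    OV[i, j] <- po[1L]; FLIP[i, j] <- po[2L]
  }
  active <- rep(TRUE, n)
  repeat {
    OVa <- OV
    OVa[!active, ] <- 0L; OVa[, !active] <- 0L
    m <- max(OVa)
    if (m < min_overlap) break
    ij <- which(OVa == m, arr.ind = TRUE)[1L, ]
    i <- ij[1L]; j <- ij[2L]
    b <- if (FLIP[i, j]) rcs[j] else seqs[j]
    merged <- paste0(seqs[i], substr(b, m + 1L, nchar(b)))
    active[c(i, j)] <- FALSE
    seqs <- c(seqs, merged)
    rcs <- c(rcs, rc_str(merged))
    active <- c(active, TRUE)
    OV <- rbind(cbind(OV, 0L), 0L)
    FLIP <- rbind(cbind(FLIP, 0L), 0L)
    nn <- length(seqs)
    for (t in which(active)) {
      if (t == nn) next
      po <- pair_ov(nn, t)
      OV[nn, t] <- po[1L]; FLIP[nn, t] <- po[2L]
      po <- pair_ov(t, nn)
      OV[t, nn] <- po[1L]; FLIP[t, nn] <- po[2L]
    }
  }
  seqs[active]
}

# canonical orientation of a sequence: the lexicographically smaller of the
# sequence and its reverse complement (the assembler's output convention)
canonical_seq <- function(s) {
  r <- revcomp(s)
  ifelse(s <= r, s, r)
}

# error-free reads tiling a template every `step` bases
tile_reads <- function(template, read_len = 100L, step = 10L) {
  starts <- seq(1L, nchar(template) - read_len + 1L, by = step)
  substring(template, starts, starts + read_len - 1L)
}

# a clock-like seven-taxon panel with nested divergence levels and NAD3
# planted as the unique genus/clade-diagnostic gene; deterministic
clock_panel <- function() {
  fixture("clock_panel", function() {
    base <- build_panel_genome(seed = 97L, id = "ancestor")
    mk <- function(from, d, seed, id) derive_haplotype(from, d, seed = seed, id = id)
    t7 <- mk(base, 0.24, 71L, "t7")        # second class
    u <- mk(base, 0.02, 72L, "u")          # class-U ancestor
    t6 <- mk(u, 0.20, 73L, "t6")           # second order
    o1 <- mk(u, 0.02, 74L, "o1")
    t5 <- mk(o1, 0.12, 75L, "t5")          # second family
    f1 <- mk(o1, 0.01, 76L, "f1")
    t4 <- mk(f1, 0.08, 77L, "t4")          # second genus
    g1 <- mk(f1, 0.01, 78L, "g1")
    t3 <- mk(g1, 0.04, 79L, "t3")          # second species
    s1 <- mk(g1, 0.005, 80L, "s1")
    t1 <- mk(s1, 0.01, 81L, "t1")          # two haplotypes of species s1
    t2 <- mk(s1, 0.01, 82L, "t2")
    genomes <- list(t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5,
                    t6 = t6, t7 = t7)
    # plant NAD3: identical within each genus group, distinct between
    # groups (a fixed codon receives a group-specific non-stop codon)
    groups <- list(c("t1", "t2", "t3"), "t4", "t5", "t6", "t7")
    donor <- extract_feature(base, "NAD3")
    variant_codons <- c("GCT", "TGT", "GAA", "GGT", "CAT")  # A C E G H
    for (gi in seq_along(groups)) {
      nad3 <- paste0(substr(donor, 1L, 30L), variant_codons[gi],
                     substr(donor, 34L, nchar(donor)))
      for (tx in groups[[gi]]) {
        g <- genomes[[tx]]
        f <- Filter(function(x) x$name == "NAD3", g$features)[[1L]]
        s <- f$exons[1L, 1L]; e <- f$exons[1L, 2L]
        body <- if (f$strand == "+") nad3 else revcomp(nad3)
        seqs <- paste0(substr(g$record$seq, 1L, s), body,
                       substr(g$record$seq, e + 1L, nchar(g$record$seq)))
        genomes[[tx]] <- annotated_genome(
          seq_record(g$record$id, seqs, TRUE), g$features)
      }
    }
    part <- rank_partition(data.frame(
      taxon = paste0("t", 1:7),
      class = c("U", "U", "U", "U", "U", "U", "V"),
      order = c("o1", "o1", "o1", "o1", "o1", "o2", "o7"),
      family = c("f1", "f1", "f1", "f1", "f2", "f6", "f7"),
      genus = c("g1", "g1", "g1", "g2", "g5", "g6", "g7"),
      species = c("s1", "s1", "s2", "s4", "s5", "s6", "s7"),
      clade = c("c1", "c1", "c1", "c2", "c5", "c6", "c7"),
      haplotype = c("H1", "H2", "H3", "H4", "H5", "H6", "H7")))
    mats <- build_matrices(genomes)
    per_gene <- lapply(mats$genes, pdistance_matrix)
    per_gene$concat <- pdistance_matrix(mats$CDS_aa)
    list(genomes = genomes, partition = part, matrices = mats,
         per_gene = per_gene)
  })
}

# small predator-gut mixture shared by scaffolding-level tests
small_mixture <- function() {
  fixture("small_mixture", function() {
    base <- build_panel_genome(seed = 42L, id = "base")
    ref <- derive_haplotype(base, 0.08, seed = 43L, id = "refA")
    prey <- derive_haplotype(ref, 0.05, seed = 44L, id = "preyA")
    host <- simulate_host(2e5, 10L, seed = 45L)
    truth <- truth_set(list(prey), 50, host, 10, seed = 46L)
    sim <- simulate_library(truth)
    trimmed <- preprocess_reads(sim$reads)
    baited <- bait_reads(trimmed, list(ref), truth = sim$origins)
    corrected <- preprocess_reads(baited, quality_cutoff = 0, correct = TRUE)
    contigs <- assemble_and_extend(corrected)
    list(base = base, ref = ref, prey = prey, truth = truth, sim = sim,
         trimmed = trimmed, baited = baited, contigs = contigs)
  })
}
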