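## Synthetic predator-gut community generator: host background plus prey
## mitogenomes with a placozoan-style architecture (12 CDS, split cox1 with
## a micro exon, two-exon nad5, a two-part 16S split over four exons, tRNAs,
## optional accessory ORFs), and a paired-end library simulator with
## recorded ground truth.

MITO_CDS <- c("COX1", "COX2", "COX3", "COB", "ATP6",
              "NAD1", "NAD2", "NAD3", "NAD4", "NAD4L", "NAD5", "NAD6")

MITO_TRNAS <- c("tRNA-Phe", "tRNA-Val", "tRNA-Leu1", "tRNA-Ile", "tRNA-Gln",
                "tRNA-Met", "tRNA-Trp", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys",
                "tRNA-Tyr", "tRNA-Ser1", "tRNA-Asp", "tRNA-Gly", "tRNA-Arg",
                "tRNA-His", "tRNA-Ser2", "tRNA-Leu2", "tRNA-Thr", "tRNA-Lys",
                "tRNA-Glu", "tRNA-Pro")

# typical spliced lengths (bp); CDS lengths include the terminal stop and
# are divisible by 3
CDS_LENGTHS <- c(COX1 = 1536, COX2 = 690, COX3 = 780, COB = 1140, ATP6 = 696,
                 NAD1 = 930, NAD2 = 1020, NAD3 = 351, NAD4 = 1380,
                 NAD4L = 294, NAD5 = 1734, NAD6 = 501)
ORF_LENGTHS <- c(POLB = 1050, LAG = 801, `RVT-IM` = 1200)
RRNA_LENGTHS <- c(`12S` = 1000, `16S_a` = 1400, `16S_b` = 1400)
TRNA_LENGTH <- 72L

#' Architecture specification for synthetic prey mitogenomes
#'
#' Defaults emulate the placozoan mitochondrial architecture: 12
#' protein-coding genes, an eight-exon COX1 including one micro exon,
#' a two-exon NAD5, a 16S ribosomal RNA split into two parts of two exons
#' each, a standard mitochondrial tRNA set, and optional accessory ORFs
#' (a type-B DNA polymerase by default, mirroring its restricted taxonomic
#' distribution).
#'
#' @param genome_length_range Total genome length interval in bp.
#' @param cds_names The protein-coding genes.
#' @param cox1_exons Number of COX1 exons (one of them a micro exon of
#'   9-20 bp).
#' @param nad5_exons Number of NAD5 exons.
#' @param r16s_parts Number of 16S parts (each split into 2 exons).
#' @param trna_names tRNA gene names.
#' @param optional_orfs Subset of `c("POLB", "LAG", "RVT-IM")`.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(genome_length_range = c(32000, 44000),
                              cds_names = MITO_CDS,
                              cox1_exons = 8L,
                              nad5_exons = 2L,
                              r16s_parts = 2L,
                              trna_names = MITO_TRNAS,
                              optional_orfs = "POLB") {
  stopifnot(length(genome_length_range) == 2L,
            genome_length_range[1] <= genome_length_range[2],
            cox1_exons >= 1L, nad5_exons >= 1L, r16s_parts >= 1L)
  if (length(optional_orfs) && !all(optional_orfs %in% names(ORF_LENGTHS)))
    stop("optional_orfs must be a subset of ", paste(names(ORF_LENGTHS), collapse = ", "))
  structure(list(genome_length_range = as.integer(genome_length_range),
                 cds_names = cds_names, cox1_exons = as.integer(cox1_exons),
                 nad5_exons = as.integer(nad5_exons),
                 r16s_parts = as.integer(r16s_parts),
                 trna_names = trna_names, optional_orfs = optional_orfs),
            class = "architecture_spec")
}

# random in-frame CDS: ATG start, stop-free body under table 4, TAA end
random_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  code4 <- Biostrings::getGeneticCode("4")
  ok <- names(code4)[code4 != "*"]
  body <- sample(ok, len / 3L - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

# split a total length into n parts, each >= min_part
random_partition <- function(total, n, min_part = 1L) {
  if (n == 1L) return(total)
  w <- rexp(n) + 0.05
  raw <- floor(w / sum(w) * (total - n * min_part))
  parts <- raw + min_part
  parts[1L] <- parts[1L] + (total - sum(parts))
  parts
}

#' Build one synthetic prey mitogenome
#'
#' Generates a circular genome with a fixed, known gene order and the split
#' exon structure of the architecture spec. Every CDS translates without
#' internal stops under genetic code 4. Deterministic for a given seed.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed.
#' @param id Genome id.
#' @return An `annotated_genome`.
#' @export
build_panel_genome <- function(spec = architecture_spec(), seed = 1L,
                               id = sprintf("synth%d", seed)) {
  with_seed(seed, {
    L <- sample(seq(spec$genome_length_range[1], spec$genome_length_range[2]), 1L)
    # gene order around the circle (name, kind); fixed across seeds
    order <- list(
      c("12S", "rRNA"), c("tRNA-Phe", "tRNA"), c("16S_a", "rRNA"),
      c("tRNA-Val", "tRNA"), c("16S_b", "rRNA"), c("tRNA-Leu1", "tRNA"),
      c("NAD1", "CDS"))
    if ("POLB" %in% spec$optional_orfs) order <- c(order, list(c("POLB", "ORF")))
    order <- c(order, list(
      c("NAD4L", "CDS"), c("tRNA-Ile", "tRNA"), c("tRNA-Gln", "tRNA"),
      c("NAD2", "CDS"), c("tRNA-Trp", "tRNA"), c("tRNA-Met", "tRNA"),
      c("COX1", "CDS"), c("tRNA-Asp", "tRNA"), c("COX2", "CDS"),
      c("tRNA-Gly", "tRNA"), c("NAD3", "CDS"), c("tRNA-Ala", "tRNA"),
      c("tRNA-Asn", "tRNA"), c("NAD4", "CDS"), c("tRNA-His", "tRNA"),
      c("NAD5", "CDS"), c("tRNA-Ser1", "tRNA"), c("tRNA-Cys", "tRNA"),
      c("COB", "CDS"), c("tRNA-Thr", "tRNA"), c("tRNA-Lys", "tRNA"),
      c("ATP6", "CDS"), c("tRNA-Ser2", "tRNA"), c("tRNA-Tyr", "tRNA"),
      c("COX3", "CDS"), c("tRNA-Glu", "tRNA"), c("NAD6", "CDS"),
      c("tRNA-Arg", "tRNA"), c("tRNA-Leu2", "tRNA"), c("tRNA-Pro", "tRNA")))
    if ("LAG" %in% spec$optional_orfs) order <- c(order, list(c("LAG", "ORF")))
    if ("RVT-IM" %in% spec$optional_orfs) order <- c(order, list(c("RVT-IM", "ORF")))
    keep <- vapply(order, function(o)
      o[2] != "CDS" || o[1] %in% spec$cds_names, TRUE)
    keep <- keep & vapply(order, function(o)
      o[2] != "tRNA" || o[1] %in% spec$trna_names, TRUE)
    order <- order[keep]

    # spliced sequence and exon-count plan per feature
    minus <- c("NAD6", "tRNA-Gln", "tRNA-Cys", "tRNA-Tyr", "tRNA-Pro")
    plan <- lapply(order, function(o) {
      name <- o[1]; kind <- o[2]
      len <- switch(kind,
                    CDS = CDS_LENGTHS[[name]],
                    ORF = ORF_LENGTHS[[name]],
                    rRNA = RRNA_LENGTHS[[name]],
                    tRNA = TRNA_LENGTH)
      nex <- 1L
      exlens <- len
      if (name == "COX1" && spec$cox1_exons > 1L) {
        nex <- spec$cox1_exons
        micro <- sample(9:18, 1L)
        rest <- random_partition(len - micro, nex - 1L, 60L)
        # micro exon sits internally (third slot)
        exlens <- append(rest, micro, after = min(2L, length(rest)))
      } else if (name == "NAD5" && spec$nad5_exons > 1L) {
        nex <- spec$nad5_exons
        exlens <- random_partition(len, nex, 200L)
      } else if (kind == "rRNA" && grepl("^16S", name)) {
        nex <- 2L
        exlens <- random_partition(len, 2L, 300L)
      }
      seq <- if (kind %in% c("CDS", "ORF")) random_cds(len) else random_dna(len)
      list(name = name, kind = kind, strand = if (name %in% minus) "-" else "+",
           exlens = exlens, seq = seq)
    })
    total_exonic <- sum(vapply(plan, function(p) sum(p$exlens), 0))
    n_slots <- length(plan) + sum(vapply(plan, function(p) length(p$exlens) - 1L, 0L))
    spacer_total <- L - total_exonic
    if (spacer_total < n_slots)
      stop("architecture spec infeasible: features exceed genome length")
    spacers <- random_partition(spacer_total, n_slots, 1L)

    # lay features around the circle
    chars <- character(0)
    feats <- list()
    pos <- 0L
    slot <- 1L
    for (p in plan) {
      # leading spacer
      chars <- c(chars, random_dna(spacers[slot])); pos <- pos + spacers[slot]
      slot <- slot + 1L
      sseq <- p$seq
      if (p$strand == "-") sseq <- revcomp(sseq)
      # exon pieces in ascending genome order; for minus-strand features
      # the genome-order exon lengths are the transcription lengths reversed
      npieces <- length(p$exlens)
      glens <- if (p$strand == "-") rev(p$exlens) else p$exlens
      offs <- cumsum(c(0L, glens))
      ex <- matrix(NA_integer_, npieces, 2L)
      for (i in seq_len(npieces)) {
        piece <- substr(sseq, offs[i] + 1L, offs[i + 1L])
        ex[i, ] <- c(pos, pos + glens[i])
        chars <- c(chars, piece)
        pos <- pos + glens[i]
        if (i < npieces) {  # intron-like spacer between exons
          chars <- c(chars, random_dna(spacers[slot])); pos <- pos + spacers[slot]
          slot <- slot + 1L
        }
      }
      feats[[length(feats) + 1L]] <- feature(p$name, p$kind, ex, p$strand, 4L)
    }
    g <- paste(chars, collapse = "")
    stopifnot(nchar(g) == L)
    genome <- annotated_genome(seq_record(id, g, circular = TRUE), feats)
    # invariant: every CDS is a clean table-4 ORF
    for (f in genome$features)
      if (f$kind %in% c("CDS", "ORF")) translate_cds(extract_feature(genome, f), 4L)
    genome
  })
}

# per-position mutation-rate class: 2 = coding, 1 = structural RNA, 0 = other
position_classes <- function(genome) {
  L <- seq_length(genome)
  cls <- integer(L)
  for (f in genome$features) {
    v <- if (f$kind %in% c("CDS", "ORF")) 2L else 1L
    for (i in seq_len(nrow(f$exons))) {
      s <- f$exons[i, 1L]; e <- f$exons[i, 2L]
      idx <- if (e > s) (s + 1L):e else c((s + 1L):L, seq_len(e))
      cls[idx] <- pmax(cls[idx], v)
    }
  }
  cls
}

#' Derive a diverged haplotype from a base genome
#'
#' Substitutions are placed to reach the requested genome-wide divergence,
#' with ribosomal and transfer RNA genes mutating at half the coding-region
#' rate (mimicking their conservation). Mutations that would create an
#' internal stop, destroy the start codon or destroy the terminal stop of a
#' CDS are reverted. Optionally applies a structural rearrangement with
#' annotations updated. The realized p-distance to the base genome is
#' recorded in attribute `"divergence"`.
#'
#' @param base An `annotated_genome`.
#' @param divergence Target proportion of substituted sites, in \[0, 0.25\].
#' @param rearrangement `NULL`, or a list: `list(type = "inversion",
#'   from = <feature>, to = <feature>)` reverses the span from the start of
#'   `from` to the end of `to`; `list(type = "translocation",
#'   feature = <feature>, after = <feature>)` moves a single-exon feature
#'   to just after `after`.
#' @param seed Integer seed.
#' @param id Id for the derived genome.
#' @return An `annotated_genome` with attribute `"divergence"`.
#' @export
derive_haplotype <- function(base, divergence, rearrangement = NULL,
                             seed = 1L, id = paste0(base$record$id, "_hap")) {
  stopifnot(divergence >= 0, divergence <= 0.25)
  g <- with_seed(seed, {
    L <- seq_length(base)
    chars <- strsplit(base$record$seq, "")[[1L]]
    if (divergence > 0) {
      cls <- position_classes(base)
      frac_rna <- mean(cls == 1L)
      # full rate r on coding + intergenic, r/2 on structural RNA
      r <- divergence / (1 - frac_rna / 2)
      rate <- ifelse(cls == 1L, r / 2, r)
      hit <- runif(L) < rate
      idx <- which(hit)
      if (length(idx)) {
        shift <- sample(1:3, length(idx), replace = TRUE)
        bmap <- c(A = 0L, C = 1L, G = 2L, T = 3L)
        old <- bmap[chars[idx]]
        ok <- !is.na(old)  # leave N untouched
        chars[idx[ok]] <- c("A", "C", "G", "T")[((old[ok] + shift[ok]) %% 4L) + 1L]
      }
    }
    mut <- annotated_genome(seq_record(id, paste(chars, collapse = ""),
                                       base$record$circular), base$features)
    # repair CDS: revert mutations breaking the reading frame contract
    base_chars <- strsplit(base$record$seq, "")[[1L]]
    for (f in mut$features) {
      if (!f$kind %in% c("CDS", "ORF")) next
      # genomic positions of the spliced CDS in transcription order
      gpos <- unlist(lapply(seq_len(nrow(f$exons)), function(i) {
        s <- f$exons[i, 1L]; e <- f$exons[i, 2L]
        if (e > s) (s + 1L):e else c((s + 1L):L, seq_len(e))
      }))
      if (f$strand == "-") gpos <- rev(gpos)
      cds <- chars[gpos]
      if (f$strand == "-") cds <- c(T = "A", A = "T", C = "G", G = "C", N = "N")[cds]
      ncod <- length(cds) / 3L
      code4 <- Biostrings::getGeneticCode("4")
      codons <- vapply(seq_len(ncod), function(i)
        paste(cds[(3 * i - 2):(3 * i)], collapse = ""), "")
      aa <- code4[codons]
      bad <- which(is.na(aa) | (aa == "*" & seq_len(ncod) < ncod))
      if (aa[ncod] != "*" || is.na(aa[ncod])) bad <- c(bad, ncod)
      if (!codons[1L] %in% c("ATG", "GTG")) bad <- union(bad, 1L)
      for (ci in bad) {
        span <- (3L * ci - 2L):(3L * ci)
        chars[gpos[span]] <- base_chars[gpos[span]]
      }
    }
    annotated_genome(seq_record(id, paste(chars, collapse = ""),
                                base$record$circular), base$features)
  })
  if (!is.null(rearrangement)) g <- apply_rearrangement(g, rearrangement)
  d <- mean(strsplit(g$record$seq, "")[[1L]][seq_len(min(seq_length(g), seq_length(base)))] !=
            strsplit(base$record$seq, "")[[1L]][seq_len(min(seq_length(g), seq_length(base)))])
  attr(g, "divergence") <- if (is.null(rearrangement)) d else NA_real_
  g
}

# span (start, end) 0-based half-open covering a whole feature (no wrap)
feature_span <- function(f) {
  c(min(f$exons[, 1L]), max(f$exons[, 2L]))
}

apply_rearrangement <- function(genome, rearrangement) {
  type <- rearrangement$type
  feats <- genome$features
  fnames <- vapply(feats, `[[`, "", "name")
  seqc <- genome$record$seq
  L <- nchar(seqc)
  if (type == "inversion") {
    fa <- feats[[match(rearrangement$from, fnames)]]
    fb <- feats[[match(rearrangement$to, fnames)]]
    s <- min(feature_span(fa)[1L], feature_span(fb)[1L])
    e <- max(feature_span(fa)[2L], feature_span(fb)[2L])
    if (any(vapply(feats, function(f) {
      sp <- feature_span(f)
      sp[1L] < e && sp[2L] > s && (sp[1L] < s || sp[2L] > e)
    }, TRUE)))
      stop("inversion span cuts through a feature")
    newseq <- paste0(substr(seqc, 1L, s), revcomp(substr(seqc, s + 1L, e)),
                     substr(seqc, e + 1L, L))
    feats <- lapply(feats, function(f) {
      sp <- feature_span(f)
      if (sp[1L] >= s && sp[2L] <= e) {
        ex <- f$exons
        # mirror within the span; reverse rows to restore ascending order
        ex2 <- cbind(s + e - ex[, 2L], s + e - ex[, 1L])
        f <- feature(f$name, f$kind,
                     ex2[rev(seq_len(nrow(ex2))), , drop = FALSE],
                     if (f$strand == "+") "-" else "+", f$transl_table)
      }
      f
    })
  } else if (type == "translocation") {
    fi <- match(rearrangement$feature, fnames)
    f <- feats[[fi]]
    sp <- feature_span(f)
    flen <- sp[2L] - sp[1L]
    body <- substr(seqc, sp[1L] + 1L, sp[2L])
    cut <- paste0(substr(seqc, 1L, sp[1L]), substr(seqc, sp[2L] + 1L, L))
    shift_after_cut <- function(x) ifelse(x >= sp[2L], x - flen, x)
    feats2 <- feats[-fi]
    feats2 <- lapply(feats2, function(g2) {
      g2$exons[] <- shift_after_cut(g2$exons)
      g2
    })
    anchor <- feats2[[match(rearrangement$after, vapply(feats2, `[[`, "", "name"))]]
    ins <- feature_span(anchor)[2L] + 10L  # insert shortly downstream
    newseq <- paste0(substr(cut, 1L, ins), body, substr(cut, ins + 1L, nchar(cut)))
    feats2 <- lapply(feats2, function(g2) {
      g2$exons[] <- ifelse(g2$exons >= ins, g2$exons + flen, g2$exons)
      g2
    })
    rel <- f$exons - sp[1L]
    f$exons <- rel + ins
    feats <- append(feats2, list(f))
  } else stop("unknown rearrangement type: ", type)
  annotated_genome(seq_record(genome$record$id, newseq,
                              genome$record$circular,
                              genome$record$description), feats)
}

#' Simulate a host genome background
#'
#' The predator "genome" is modeled as random linear fragments totaling the
#' requested size: baiting specificity only requires non-homologous
#' background, not a realistic gastropod assembly.
#'
#' @param total_bp Total background size.
#' @param n_fragments Number of linear fragments.
#' @param seed Integer seed.
#' @return List of `seq_record` (linear).
#' @export
simulate_host <- function(total_bp = 5e6, n_fragments = 200L, seed = 1L) {
  with_seed(seed, {
    lens <- random_partition(as.integer(total_bp), n_fragments, 2000L)
    lapply(seq_len(n_fragments), function(i)
      seq_record(sprintf("host_frag%03d", i), random_dna(lens[i]), circular = FALSE))
  })
}

#' Assemble a simulation truth set
#'
#' @param prey List of `annotated_genome` (the planted prey mitogenomes).
#' @param coverages Per-prey target coverage (x).
#' @param host List of `seq_record` host fragments (or `NULL`).
#' @param host_coverage Host coverage (x).
#' @param read_length Read length in bp.
#' @param insert_range Length-2 insert interval in bp.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return An object of class `truth_set`.
#' @export
truth_set <- function(prey, coverages, host = NULL, host_coverage = 0,
                      read_length = 250L, insert_range = c(400L, 800L),
                      error_rate = 0.005, seed = 1L) {
  stopifnot(length(prey) == length(coverages), all(coverages >= 0),
            host_coverage >= 0, read_length <= insert_range[1])
  structure(list(prey = prey, coverages = coverages, host = host,
                 host_coverage = host_coverage,
                 read_length = as.integer(read_length),
                 insert_range = as.integer(insert_range),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "truth_set")
}

#' Simulate a paired-end metagenomic library
#'
#' Fragment counts per template are `round(coverage * length / (2 *
#' read_length))`; fragment starts are uniform (on the circle for circular
#' templates), inserts uniform in the stated range, and substitution errors
#' applied at the stated rate. The genome of origin and fragment placement
#' of every pair are recorded in the returned truth table.
#'
#' @param truth A [truth_set()].
#' @param outdir If non-NULL, paired gzip FASTQ, truth FASTA + feature
#'   table, the read-origin table and a JSON manifest are written there.
#' @return A list with elements `reads` (a `read_set`) and `origins`
#'   (data.frame: id, genome, start, insert, strand).
#' @export
simulate_library <- function(truth, outdir = NULL) {
  rl <- truth$read_length
  q <- min(40L, max(2L, round(-10 * log10(max(truth$error_rate, 1e-4)))))
  qchar <- rawToChar(as.raw(33L + q))
  templates <- c(lapply(truth$prey, function(g) g$record), truth$host %||% list())
  covs <- c(truth$coverages,
            rep(truth$host_coverage, length(truth$host %||% list())))
  parts <- with_seed(truth$seed, lapply(seq_along(templates), function(i) {
    tpl <- templates[[i]]
    L <- nchar(tpl$seq)
    np <- round(covs[i] * L / (2 * rl))
    if (np < 1 || L < truth$insert_range[2]) return(NULL)
    sim <- cpp_simulate_pairs(tpl$seq, tpl$circular, np, rl,
                              truth$insert_range[1], truth$insert_range[2],
                              truth$error_rate)
    list(id = sprintf("%s_p%06d", tpl$id, seq_len(np)), genome = tpl$id,
         seq1 = sim$seq1, seq2 = sim$seq2,
         start = sim$start, insert = sim$insert, strand = sim$strand)
  }))
  parts <- Filter(Negate(is.null), parts)
  cat_field <- function(f) unlist(lapply(parts, `[[`, f), use.names = FALSE)
  ids <- cat_field("id")
  reads <- read_set(ids, cat_field("seq1"), cat_field("seq2"),
                    strrep(qchar, nchar(cat_field("seq1"))),
                    strrep(qchar, nchar(cat_field("seq2"))),
                    read_length = rl, insert_range = truth$insert_range)
  origins <- data.frame(id = ids,
                        genome = rep(vapply(parts, function(p) p$genome[1], ""),
                                     vapply(parts, function(p) length(p$id), 0L)),
                        start = cat_field("start"), insert = cat_field("insert"),
                        strand = cat_field("strand"))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fastq_pairs(reads, file.path(outdir, "reads_1.fastq.gz"),
                      file.path(outdir, "reads_2.fastq.gz"))
    write_fasta(truth$prey, file.path(outdir, "truth_prey.fasta"))
    write_feature_table(truth$prey, file.path(outdir, "truth_features.tsv"))
    write.table(origins, file.path(outdir, "read_origins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = truth$seed, read_length = rl,
           insert_range = truth$insert_range, error_rate = truth$error_rate,
           coverages = setNames(as.list(truth$coverages),
                                vapply(truth$prey, function(g) g$record$id, "")),
           host_coverage = truth$host_coverage),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(reads = reads, origins = origins)
}
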