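## Comparative layer: codon-aware concatenated CDS matrices and an rDNA
## matrix, uncorrected p-distances with pairwise deletion, rank-wise
## group-mean distance tables, a diagnostic-marker scan, and
## neighbor-joining export.

#' Construct a multiple alignment object
#'
#' @param rows Named character vector of equal-length aligned rows.
#' @param alphabet `"nt"` or `"aa"`.
#' @param partitions Optional data.frame (gene, start, end), 1-based
#'   inclusive column ranges.
#' @return An object of class `gene_alignment`.
#' @export
gene_alignment <- function(rows, alphabet = c("nt", "aa"), partitions = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(rows) >= 1L, !is.null(names(rows)),
            !anyDuplicated(names(rows)))
  if (length(unique(nchar(rows))) != 1L) stop("rows must have equal length")
  structure(list(taxa = names(rows), rows = rows, alphabet = alphabet,
                 partitions = partitions),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %d taxa x %d %s columns%s\n",
              length(x$taxa), nchar(x$rows[1L]), x$alphabet,
              if (!is.null(x$partitions))
                sprintf(", %d partitions", nrow(x$partitions)) else ""))
  invisible(x)
}

# tolerant translation for matrix building: N codons and stops become X
# (missing), terminal stop stripped; trailing incomplete codon dropped
translate_tolerant <- function(dna) {
  n <- 3L * (nchar(dna) %/% 3L)
  if (n == 0L) return("")
  code4 <- Biostrings::getGeneticCode("4")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code4[codons])
  aa[is.na(aa)] <- "X"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)] else aa[aa == "*"] <- "X"
  aa[aa == "*"] <- "X"
  paste(aa, collapse = "")
}

# center-star multiple alignment on top of pairwise global alignments
# (peptides: BLOSUM62, affine 10/1; DNA: match 2 / mismatch -3, affine 5/2)
center_star_align <- function(seqs, alphabet) {
  keep <- nzchar(seqs)
  if (!any(keep)) stop("no sequences to align")
  if (length(unique(seqs[keep])) == 1L) {
    # common fast path: identical sequences need no alignment
    w <- nchar(seqs[keep][1L])
    out <- ifelse(nzchar(seqs), seqs, strrep("-", w))
    names(out) <- names(seqs)
    return(out)
  }
  center_i <- which(keep)[which.max(nchar(seqs[keep]))]
  center <- seqs[center_i]
  Lc <- nchar(center)
  others <- setdiff(which(keep), center_i)
  pair <- lapply(others, function(i) {
    if (alphabet == "aa") {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[i]), Biostrings::AAString(center),
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
        type = "global")
      list(q = as.character(Biostrings::pattern(al)),
           c = as.character(Biostrings::subject(al)))
    } else {
      mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                      baseOnly = FALSE)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[i]), Biostrings::DNAString(center),
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
        type = "global")
      list(q = as.character(Biostrings::pattern(al)),
           c = as.character(Biostrings::subject(al)))
    }
  })
  # insertion counts relative to center: ins[i + 1] = columns where the
  # center has a gap immediately before center position i+1 (i = 0..Lc)
  ins_of <- function(cal) {
    cc <- strsplit(cal, "")[[1L]]
    ins <- integer(Lc + 1L)
    ci <- 0L
    for (ch in cc) {
      if (ch == "-") ins[ci + 1L] <- ins[ci + 1L] + 1L else ci <- ci + 1L
    }
    ins
  }
  inss <- lapply(pair, function(p) ins_of(p$c))
  master <- Reduce(pmax, inss, integer(Lc + 1L))
  project <- function(qal, cal, ins) {
    qq <- strsplit(qal, "")[[1L]]
    cc <- strsplit(cal, "")[[1L]]
    out <- character(0)
    ci <- 0L
    col <- 1L
    for (slot in 0:Lc) {
      # emit insertions before center position slot+1, padded to master
      nin <- ins[slot + 1L]
      if (nin > 0L) {
        out <- c(out, qq[col:(col + nin - 1L)])
        col <- col + nin
      }
      if (master[slot + 1L] > nin)
        out <- c(out, rep("-", master[slot + 1L] - nin))
      if (slot < Lc) {  # the center base itself
        out <- c(out, qq[col])
        col <- col + 1L
      }
    }
    paste(out, collapse = "")
  }
  width <- Lc + sum(master)
  res <- setNames(rep(strrep("-", width), length(seqs)), names(seqs))
  # center row
  cch <- strsplit(center, "")[[1L]]
  crow <- character(0)
  for (slot in 0:Lc) {
    if (master[slot + 1L] > 0L) crow <- c(crow, rep("-", master[slot + 1L]))
    if (slot < Lc) crow <- c(crow, cch[slot + 1L])
  }
  res[center_i] <- paste(crow, collapse = "")
  for (t in seq_along(others))
    res[others[t]] <- project(pair[[t]]$q, pair[[t]]$c, inss[[t]])
  res
}

#' Build the three comparative data matrices
#'
#' Per gene, coding sequences are aligned codon-aware: peptides (genetic
#' code 4) are aligned and the gaps back-mapped onto the nucleotide
#' sequences, so the concatenated nucleotide matrix is exactly three times
#' the width of the amino-acid matrix. The rDNA matrix concatenates the
#' 12S alignment with an alignment of the combined 16S parts. Taxa missing
#' a gene receive an all-gap block and are flagged.
#'
#' @param genomes Named list of `annotated_genome` (names become taxa ids;
#'   unnamed lists use record ids).
#' @param genes CDS gene set (default the 12 mitochondrial genes).
#' @return List with `CDS_nt`, `CDS_aa`, `rDNA` (concatenated
#'   `gene_alignment`s with partitions) and `genes` (per-gene amino-acid
#'   alignments).
#' @export
build_matrices <- function(genomes, genes = MITO_CDS) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$record$id, "")
  taxa <- names(genomes)
  get_cds <- function(g, gene) {
    f <- Filter(function(x) x$name == gene && x$kind %in% c("CDS", "ORF"),
                g$features)
    if (!length(f)) return(NA_character_)
    extract_feature(g, f[[1L]])
  }
  missing <- NULL
  per_gene_aa <- list()
  per_gene_nt <- list()
  for (gene in genes) {
    nt <- vapply(genomes, get_cds, "", gene)
    miss <- is.na(nt)
    if (any(miss))
      missing <- rbind(missing, data.frame(taxon = taxa[miss], gene = gene))
    nt[miss] <- ""
    nt_trim <- substr(nt, 1L, 3L * (nchar(nt) %/% 3L))
    aa <- vapply(nt_trim, translate_tolerant, "", USE.NAMES = FALSE)
    names(aa) <- taxa
    aa_al <- center_star_align(aa, "aa")
    # back-map peptide gaps onto codons
    nt_al <- vapply(seq_along(aa_al), function(i) {
      chs <- strsplit(aa_al[[i]], "")[[1L]]
      codons <- character(length(chs))
      src <- nt_trim[i]
      pos <- 0L
      for (j in seq_along(chs)) {
        if (chs[j] == "-") codons[j] <- "---"
        else {
          codons[j] <- substr(src, pos * 3L + 1L, pos * 3L + 3L)
          pos <- pos + 1L
        }
      }
      paste(codons, collapse = "")
    }, "")
    names(nt_al) <- taxa
    per_gene_aa[[gene]] <- gene_alignment(aa_al, "aa")
    per_gene_nt[[gene]] <- gene_alignment(nt_al, "nt")
  }
  concat <- function(alns, alphabet) {
    widths <- vapply(alns, function(a) nchar(a$rows[1L]), 0L)
    ends <- as.integer(cumsum(widths))
    parts <- data.frame(gene = names(alns), start = ends - widths + 1L,
                        end = ends)
    rows <- vapply(taxa, function(t)
      paste(vapply(alns, function(a) unname(a$rows[t]), ""), collapse = ""), "")
    gene_alignment(rows, alphabet, parts)
  }
  cds_aa <- concat(per_gene_aa, "aa")
  cds_nt <- concat(per_gene_nt, "nt")
  # rDNA: 12S aligned alone; 16S parts combined per taxon, then aligned
  get_rna <- function(g, names_want) {
    f <- Filter(function(x) x$name %in% names_want && x$kind == "rRNA",
                g$features)
    if (!length(f)) return("")
    paste(vapply(f[order(vapply(f, `[[`, "", "name"))],
                 function(x) extract_feature(g, x), ""), collapse = "")
  }
  r12 <- vapply(genomes, get_rna, "", "12S")
  r16 <- vapply(genomes, get_rna, "", c("16S_a", "16S_b", "16S"))
  names(r12) <- names(r16) <- taxa
  rdna_parts <- list(`12S` = gene_alignment(center_star_align(r12, "nt"), "nt"),
                     `16S` = gene_alignment(center_star_align(r16, "nt"), "nt"))
  rdna <- concat(rdna_parts, "nt")
  out <- list(CDS_nt = cds_nt, CDS_aa = cds_aa, rDNA = rdna,
              genes = per_gene_aa, genes_nt = per_gene_nt)
  attr(out, "missing") <- missing
  out
}

missing_chars <- function(alphabet) {
  if (alphabet == "nt") c("-", "N", "?") else c("-", "X", "?", "*")
}

#' Uncorrected p-distance matrix with pairwise deletion
#'
#' For each taxon pair, columns where either row carries a gap or missing
#' state (N for nucleotides; X for amino acids) are excluded, and the
#' distance is the fraction of the remaining sites that differ. Pairs with
#' zero usable sites are undefined (NA).
#'
#' @param aln A `gene_alignment` (or named character vector of equal-length
#'   rows plus `alphabet`).
#' @param alphabet Used only when `aln` is a bare vector.
#' @return Object of class `distance_matrix`: list with `d` (symmetric
#'   matrix, zero diagonal), `sites` (usable-site counts) and `label`.
#' @export
pdistance_matrix <- function(aln, alphabet = "nt") {
  if (!inherits(aln, "gene_alignment")) aln <- gene_alignment(aln, alphabet)
  if (length(aln$taxa) < 2L) stop("need at least two taxa")
  m <- do.call(rbind, strsplit(unname(aln$rows), ""))
  rownames(m) <- aln$taxa
  bad <- matrix(m %in% missing_chars(aln$alphabet), nrow = nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  sites <- matrix(ncol(m), n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- !bad[i, ] & !bad[j, ]
      ns <- sum(use)
      sites[i, j] <- sites[j, i] <- ns
      d[i, j] <- d[j, i] <- if (ns == 0L) NA_real_ else
        sum(m[i, use] != m[j, use]) / ns
    }
  }
  structure(list(d = d, sites = sites, label = attr(aln, "label") %||% ""),
            class = "distance_matrix")
}

#' Percent identity between two aligned rows
#'
#' 100 x identical sites / sites where both rows are non-gap; equals
#' `100 * (1 - p)` on gap-free pairs.
#'
#' @param a,b Aligned rows (equal length) from one alignment.
#' @return Percent identity.
#' @export
percent_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  stopifnot(length(ca) == length(cb))
  use <- ca != "-" & cb != "-"
  if (!sum(use)) stop("zero comparable sites")
  100 * sum(ca[use] == cb[use]) / sum(use)
}

RANK_PAIRS <- data.frame(
  child = c("order", "family", "genus", "species", "haplotype"),
  parent = c("class", "order", "family", "genus", "clade"))

#' Validate a nested rank partition table
#'
#' @param df data.frame with columns `taxon` plus the ranks `class`,
#'   `order`, `family`, `genus`, `species`, `clade`, `haplotype`.
#' @return The validated data.frame, classed `rank_partition`.
#' @export
rank_partition <- function(df) {
  need <- c("taxon", "class", "order", "family", "genus", "species",
            "clade", "haplotype")
  if (!all(need %in% names(df)))
    stop("partition must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$taxon)) stop("duplicate taxa in partition")
  for (i in seq_len(nrow(RANK_PAIRS))) {
    ch <- df[[RANK_PAIRS$child[i]]]
    pa <- df[[RANK_PAIRS$parent[i]]]
    bad <- tapply(pa, ch, function(x) length(unique(x)) > 1L)
    if (any(bad))
      stop(sprintf("rank nesting violated: %s %s spans several %s groups",
                   RANK_PAIRS$child[i], names(bad)[bad][1L], RANK_PAIRS$parent[i]))
  }
  structure(df, class = c("rank_partition", "data.frame"))
}

#' Read a rank partition from TSV
#' @param path TSV with the columns of [rank_partition()].
#' @return A `rank_partition`.
#' @export
read_rank_partition <- function(path) {
  rank_partition(read.delim(path, stringsAsFactors = FALSE))
}

# mean distance over taxon pairs lying in different child groups within one
# parent group; NA when fewer than two child groups
between_child_mean <- function(d, taxa, child) {
  groups <- split(taxa, child)
  if (length(groups) < 2L) return(NA_real_)
  vals <- c()
  gn <- names(groups)
  for (i in seq_len(length(groups) - 1L)) {
    for (j in (i + 1L):length(groups)) {
      vals <- c(vals, as.vector(d[groups[[i]], groups[[j]]]))
    }
  }
  mean(vals)
}

#' Rank-wise group-mean distance table
#'
#' For every rank pair (orders within classes, families within orders,
#' genera within families, species within genera, haplotypes within
#' clades) and every gene: the mean distance over all between-child-group
#' taxon pairs inside each parent group, averaged over parent groups.
#' Summaries are produced over all taxa and, separately, restricted to one
#' class (by default the more diverse of the two, mirroring the within-class
#' view). Parent groups with a single child yield NA (not applicable). The
#' concatenated matrix enters as an additional "gene".
#'
#' @param per_gene Named list of `distance_matrix`, typically per-gene
#'   amino-acid matrices plus a `concat` entry.
#' @param partition A `rank_partition` covering all matrix taxa.
#' @param within_class Class name for the restricted summary; `NULL`
#'   selects the class with the most taxa.
#' @return data.frame: scope, rank, gene, mean_distance; plus per-rank
#'   grand means (gene == "GRAND_MEAN", averaged over genes).
#' @export
rank_mean_distances <- function(per_gene, partition,
                                within_class = NULL) {
  stopifnot(inherits(partition, "rank_partition"))
  if (is.null(within_class)) {
    tb <- table(partition$class)
    within_class <- names(tb)[which.max(tb)]
  }
  scopes <- list(all = partition,
                 within = partition[partition$class == within_class, ,
                                    drop = FALSE])
  names(scopes) <- c("all", paste0("within_", within_class))
  out <- NULL
  for (sc in names(scopes)) {
    part <- scopes[[sc]]
    for (ri in seq_len(nrow(RANK_PAIRS))) {
      child <- RANK_PAIRS$child[ri]
      parent <- RANK_PAIRS$parent[ri]
      for (gene in names(per_gene)) {
        dm <- per_gene[[gene]]
        taxa <- intersect(part$taxon, rownames(dm$d))
        if (length(taxa) < 2L) next
        p <- part[match(taxa, part$taxon), ]
        per_parent <- vapply(split(seq_along(taxa), p[[parent]]), function(idx) {
          between_child_mean(dm$d, taxa[idx], p[[child]][idx])
        }, 0)
        val <- if (all(is.na(per_parent))) NA_real_
               else mean(per_parent, na.rm = TRUE)
        out <- rbind(out, data.frame(scope = sc, rank = child, gene = gene,
                                     mean_distance = val))
      }
    }
  }
  grand <- do.call(rbind, lapply(split(out, list(out$scope, out$rank)),
    function(s) data.frame(scope = s$scope[1L], rank = s$rank[1L],
                           gene = "GRAND_MEAN",
                           mean_distance = mean(s$mean_distance, na.rm = TRUE))))
  rownames(grand) <- NULL
  rbind(out, grand)
}

#' Scan genes for diagnostic markers at a taxonomic rank
#'
#' A gene is diagnostic at a rank when its sequences are identical within
#' every group (maximum within-group distance 0) while all groups differ
#' from one another (minimum between-group distance > 0). Undefined pairs
#' (no usable sites) disqualify a gene.
#'
#' @param per_gene Named list of `distance_matrix` (one per gene).
#' @param partition A `rank_partition`.
#' @param rank Rank column to scan (e.g. `"genus"` or `"clade"`).
#' @return Character vector of diagnostic gene names.
#' @export
diagnostic_marker_scan <- function(per_gene, partition, rank) {
  stopifnot(inherits(partition, "rank_partition"), rank %in% names(partition))
  hits <- character(0)
  for (gene in names(per_gene)) {
    dm <- per_gene[[gene]]
    taxa <- intersect(partition$taxon, rownames(dm$d))
    if (length(taxa) < 2L) next
    grp <- partition[[rank]][match(taxa, partition$taxon)]
    d <- dm$d[taxa, taxa, drop = FALSE]
    same <- outer(grp, grp, "==")
    diag(same) <- NA
    within <- d[same & !is.na(same)]
    between <- d[!same & !is.na(same)]
    if (length(between) == 0L) next
    if (anyNA(within) || anyNA(between)) next  # undefined pairs disqualify
    if ((length(within) == 0L || max(within) == 0) && min(between) > 0)
      hits <- c(hits, gene)
  }
  hits
}

#' Neighbor-joining tree with alignment export
#'
#' Builds a neighbor-joining tree from a complete distance matrix, clamps
#' negative branch lengths to zero and roots it on the outgroup. When an
#' alignment and output prefix are given, relaxed PHYLIP and NEXUS files
#' (the latter with partition charsets) are written alongside the newick.
#'
#' @param dm A `distance_matrix` (no missing pairs).
#' @param outgroup Taxon id to root on.
#' @param alignment Optional `gene_alignment` to export.
#' @param out_prefix Optional path prefix for `.nwk`, `.phy`, `.nex`.
#' @return List with `tree` (an `ape::phylo`), `newick`, and `files`.
#' @export
nj_tree_and_export <- function(dm, outgroup, alignment = NULL,
                               out_prefix = NULL) {
  stopifnot(inherits(dm, "distance_matrix"))
  if (anyNA(dm$d)) stop("distance matrix has undefined pairs")
  if (!outgroup %in% rownames(dm$d)) stop("outgroup absent from matrix")
  tree <- ape::nj(stats::as.dist(dm$d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree <- ape::root(tree, outgroup, resolve.root = TRUE)
  newick <- ape::write.tree(tree)
  files <- character(0)
  if (!is.null(out_prefix)) {
    nwk <- paste0(out_prefix, ".nwk")
    writeLines(newick, nwk)
    files <- nwk
    if (!is.null(alignment)) {
      phy <- paste0(out_prefix, ".phy")
      nex <- paste0(out_prefix, ".nex")
      write_phylip(alignment, phy)
      write_nexus(alignment, nex)
      files <- c(files, phy, nex)
    }
  }
  list(tree = tree, newick = newick, files = files)
}

#' Write an alignment in relaxed PHYLIP format
#' @param aln A `gene_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(aln$taxa), nchar(aln$rows[1L])), con)
  writeLines(sprintf("%s  %s", aln$taxa, aln$rows), con)
  invisible(path)
}

#' Write an alignment in NEXUS format with partition charsets
#' @param aln A `gene_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(aln, path) {
  dt <- if (aln$alphabet == "nt") "DNA" else "PROTEIN"
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(aln$taxa),
                     nchar(aln$rows[1L])),
             sprintf("FORMAT DATATYPE=%s MISSING=? GAP=-;", dt), "MATRIX",
             sprintf("%s  %s", aln$taxa, aln$rows),
             ";", "END;")
  if (!is.null(aln$partitions)) {
    lines <- c(lines, "BEGIN SETS;",
               sprintf("CHARSET %s = %d-%d;", aln$partitions$gene,
                       aln$partitions$start, aln$partitions$end),
               "END;")
  }
  writeLines(lines, path)
  invisible(path)
}
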