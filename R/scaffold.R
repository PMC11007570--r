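## Reference-guided scaffolding: anchor extended contigs on an annotated
## reference mitogenome, merge them at agreeing overlaps, recruit and
## locally reassemble reads across residual gaps (reference flank +/- 300
## bp), N-fill what remains at reference-implied lengths, and back-map the
## trimmed reads for coverage and chimera QC. Reference bases are never
## copied into a scaffold.

ref_record <- function(reference) {
  if (inherits(reference, "annotated_genome")) reference$record else reference
}

# reference sequence doubled far enough to expose origin-spanning windows
ref_doubled <- function(rec, extra) {
  if (rec$circular) paste0(rec$seq, substr(rec$seq, 1L, extra)) else rec$seq
}

#' Anchor contigs on a reference mitogenome
#'
#' Each contig is placed by shared-k-mer diagonal voting followed by a
#' banded global alignment against the implied reference window, in both
#' orientations; the better-scoring orientation wins. Contigs below
#' `min_identity` (default 0.75, permissive enough to anchor across
#' inter-genus divergence) are reported as unplaced.
#'
#' @param contigs data.frame with columns `id` and `seq` (as returned by
#'   [assemble_and_extend()]), or a character vector of sequences.
#' @param reference An `annotated_genome` or `seq_record`; circular
#'   references are handled origin-aware.
#' @param min_identity Minimum alignment identity to accept a placement.
#' @param k Anchoring k-mer size.
#' @return data.frame of placements: contig id, 0-based half-open reference
#'   interval (`end` may exceed the reference length to denote origin
#'   wrap), orientation, identity, and the contig sequence oriented to the
#'   reference forward strand. Unplaced contigs appear with `NA` interval.
#' @export
anchor_contigs <- function(contigs, reference, min_identity = 0.75, k = 17L) {
  if (is.character(contigs))
    contigs <- data.frame(id = sprintf("contig%03d", seq_along(contigs)),
                          seq = contigs, stringsAsFactors = FALSE)
  rec <- ref_record(reference)
  L <- nchar(rec$seq)
  empty <- data.frame(id = character(), start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      seq = character(), stringsAsFactors = FALSE)
  if (!nrow(contigs)) return(empty)
  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    seq <- contigs$seq[i]
    best <- NULL
    dbl <- ref_doubled(rec, min(L, nchar(seq) + 400L))
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else revcomp(seq)
      hits <- cpp_diag_hits(s, dbl, k, 4L)
      if (!nrow(hits)) next
      offs <- hits[, "pos_b"] - hits[, "pos_a"]
      # restrict diagonals to one circle copy to avoid double counting
      offs <- offs[offs >= 0 & offs < max(L, 1L)]
      if (!length(offs)) next
      d <- as.integer(names(sort(table(offs), decreasing = TRUE))[1L])
      pad <- max(30L, ceiling(0.02 * nchar(s)))
      ws <- max(0L, d - pad)
      we <- min(nchar(dbl), d + nchar(s) + pad)
      win <- substr(dbl, ws + 1L, we)
      band <- 2L * pad + abs(nchar(win) - nchar(s)) + 10L
      al <- cpp_banded_global(s, win, band, 2, -3, 5, 2)
      ca <- strsplit(al$a, "")[[1L]]
      cb <- strsplit(al$b, "")[[1L]]
      core <- which(ca != "-")
      core <- min(core):max(core)  # drop terminal gap columns of the contig
      both <- ca[core] != "-" & cb[core] != "-"
      ident <- sum(ca[core] == cb[core] & both) / max(1L, sum(both))
      # reference coords covered by the contig (within the window frame)
      covered <- sum(cb[core] != "-")
      lead <- sum(cb[seq_len(core[1L] - 1L)] != "-")
      start <- ws + lead
      cand <- list(id = contigs$id[i], start = start, end = start + covered,
                   strand = strand, identity = ident, score = al$score,
                   seq = s)
      if (is.null(best) || cand$score > best$score) best <- cand
    }
    if (is.null(best) || best$identity < min_identity)
      return(data.frame(id = contigs$id[i], start = NA_integer_,
                        end = NA_integer_, strand = NA_character_,
                        identity = if (is.null(best)) NA_real_ else best$identity,
                        seq = contigs$seq[i], stringsAsFactors = FALSE))
    st <- as.integer(best$start %% L)
    data.frame(id = best$id, start = st,
               end = st + as.integer(best$end - best$start),
               strand = best$strand, identity = best$identity,
               seq = best$seq, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# uncovered reference intervals (0-based half-open, wrap-aware) given
# placements on a reference of length L
coverage_gaps <- function(placements, L, circular) {
  cov <- logical(L)
  for (i in seq_len(nrow(placements))) {
    if (is.na(placements$start[i])) next
    idx <- (placements$start[i]:(placements$end[i] - 1L)) %% L + 1L
    cov[idx] <- TRUE
  }
  if (all(cov)) return(data.frame(start = integer(), end = integer()))
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  g <- data.frame(start = starts[!r$values], end = ends[!r$values])
  # merge a wrap-around gap into one record on circular references
  if (circular && nrow(g) > 1L && g$start[1L] == 0L && g$end[nrow(g)] == L) {
    g$start[1L] <- g$start[nrow(g)] - L  # negative start denotes wrap
    g <- g[-nrow(g), , drop = FALSE]
  }
  g
}

# the reference sequence over each gap plus `flank` bases of context on
# both sides (wrap-aware); these windows recruit the gap-closing reads
gap_flanks <- function(rec, gaps, flank) {
  L <- nchar(rec$seq)
  dbl <- ref_doubled(rec, L)
  vapply(seq_len(nrow(gaps)), function(i) {
    s <- gaps$start[i] - flank
    e <- gaps$end[i] + flank
    s0 <- ((s %% L) + L) %% L
    substr(dbl, s0 + 1L, s0 + (e - s))
  }, "")
}

#' Merge anchored contigs and close gaps by local reassembly
#'
#' Placements overlapping on the reference are merged when the overlapping
#' contig sequence agrees at >= 99% identity over >= 30 bp (contig
#' sequence, never reference sequence, makes up the scaffold). Overlaps
#' that disagree are left unmerged and logged as haplotype-conflict
#' warnings. For each residual reference gap, reads are recruited against
#' the gap region plus `flank` bp on both sides, locally reassembled over
#' the k-mer ladder, re-anchored, and the merge repeated, to a fixpoint or
#' at most `max_rounds` rounds.
#'
#' @param placements Output of [anchor_contigs()].
#' @param contigs The contig data.frame (unused beyond provenance; may be
#'   `NULL`).
#' @param reference `annotated_genome` or `seq_record`.
#' @param reads A `read_set` of (trimmed) reads for gap recruitment, or
#'   `NULL` to skip gap closing.
#' @param flank Bases of reference context on each side of a gap.
#' @param k_list k-mer ladder for local reassembly.
#' @param min_merge_overlap,min_merge_identity Overlap acceptance rule.
#' @param max_rounds Maximum recruit-reassemble-merge rounds.
#' @param gap_anchor_identity Anchoring identity required of gap-closing
#'   contigs; stricter than initial anchoring because locally recruited
#'   reads may include high-coverage near-relatives of other haplotypes.
#' @return A pre-fill scaffold result: list with `placements`, `gaps`,
#'   `conflicts`, `reference_id`, `rounds`.
#' @export
merge_and_close <- function(placements, contigs, reference, reads = NULL,
                            flank = 300L, k_list = c(33L, 55L, 77L),
                            min_merge_overlap = 30L, min_merge_identity = 0.99,
                            max_rounds = 3L, gap_anchor_identity = 0.85) {
  rec <- ref_record(reference)
  L <- nchar(rec$seq)
  if (is.null(placements) || !nrow(placements))
    placements <- data.frame(id = character(), start = integer(),
                             end = integer(), strand = character(),
                             identity = numeric(), seq = character())
  pl <- placements[!is.na(placements$start), , drop = FALSE]
  conflicts <- list()
  merge_pass <- function(pl) {
    if (nrow(pl) < 2L) return(pl)
    pl <- pl[order(pl$start, -(pl$end - pl$start)), , drop = FALSE]
    i <- 1L
    while (i < nrow(pl)) {
      merged <- FALSE
      j <- i + 1L
      while (j <= nrow(pl)) {
        ov <- pl$end[i] - pl$start[j]
        if (ov < min_merge_overlap) break  # sorted: later j overlap even less
        if (pl$end[j] <= pl$end[i]) { j <- j + 1L; next }  # contained
        # compare contig suffix of i with prefix of j over the overlap
        a <- pl$seq[i]; b <- pl$seq[j]
        ov_eff <- min(ov, nchar(a), nchar(b))
        sa <- substr(a, nchar(a) - ov_eff + 1L, nchar(a))
        sb <- substr(b, 1L, ov_eff)
        ident <- mean(strsplit(sa, "")[[1L]] == strsplit(sb, "")[[1L]])
        if (ident >= min_merge_identity) {
          pl$seq[i] <- paste0(a, substr(b, ov_eff + 1L, nchar(b)))
          pl$end[i] <- pl$start[i] + nchar(pl$seq[i])
          pl$id[i] <- paste(pl$id[i], pl$id[j], sep = "+")
          pl <- pl[-j, , drop = FALSE]
          merged <- TRUE   # re-scan from the grown contig
        } else {
          conflicts[[length(conflicts) + 1L]] <<- data.frame(
            a = pl$id[i], b = pl$id[j], overlap = ov_eff, identity = ident)
          j <- j + 1L
        }
      }
      if (!merged) i <- i + 1L
    }
    pl
  }
  pl <- merge_pass(pl)
  rounds <- 0L
  if (!is.null(reads)) {
    repeat {
      rounds <- rounds + 1L
      gaps <- coverage_gaps(pl, L, rec$circular)
      if (!nrow(gaps) || rounds > max_rounds) break
      flanks <- gap_flanks(rec, gaps, flank)
      # one recruitment scan over the library for all gaps jointly; gap
      # recruitment demands 8 shared 25-mers: still near-fully sensitive
      # to reads within ~10% of the reference, while excluding reads of
      # co-occurring distant haplotypes that graze conserved windows
      pool <- bait_reads(reads, flanks, min_shared_kmers = 8L, k_bait = 25L)
      if (!n_pairs(pool)) break
      new_pl <- NULL
      for (i in seq_len(nrow(gaps))) {
        sub <- bait_reads(pool, flanks[i], min_shared_kmers = 8L, k_bait = 25L)
        if (!n_pairs(sub)) next
        if (n_pairs(sub) > 500L) {
          # keep the strongest-matching pairs: local coverage stays ample
          # (>150x over a gap window) while the reads closest to the
          # reference — the scarce own-haplotype reads in a low-coverage
          # regime — always make the cut
          ord <- order(-attr(sub, "shared"), seq_len(n_pairs(sub)))
          sub <- subset_pairs(sub, sort(ord[seq_len(500L)]))
        }
        ctg <- assemble_and_extend(sub, k_list = k_list, iterations = 2L,
                                   min_kmer_count = 1L)
        if (!nrow(ctg)) next
        anc <- anchor_contigs(ctg, reference, gap_anchor_identity)
        anc <- anc[!is.na(anc$start), , drop = FALSE]
        if (nrow(anc)) new_pl <- rbind(new_pl, anc)
      }
      if (is.null(new_pl) || !nrow(new_pl)) break
      new_pl$id <- paste0("gapfill_r", rounds, "_", new_pl$id)
      n_before <- nrow(pl)
      len_before <- sum(pl$end - pl$start)
      pl <- merge_pass(rbind(pl, new_pl))
      if (nrow(pl) == n_before && sum(pl$end - pl$start) <= len_before) break
    }
  }
  gaps <- coverage_gaps(pl, L, rec$circular)
  conflicts <- if (length(conflicts)) unique(do.call(rbind, conflicts)) else
    data.frame(a = character(), b = character(), overlap = integer(),
               identity = numeric())
  structure(list(placements = pl, gaps = gaps, conflicts = conflicts,
                 reference_id = rec$id, reference_length = L,
                 circular = rec$circular, rounds = rounds),
            class = "prefill_scaffold")
}

#' Finalize a scaffold: N-fill residual gaps and compute completeness
#'
#' The scaffold is emitted in the reference coordinate frame starting at
#' reference position 0. Each residual gap is filled with as many N as the
#' reference spans there (so gap lengths are reference-implied
#' approximations), and completeness is the percentage of the reference
#' length covered by non-N scaffold bases. Non-N bases are never altered.
#'
#' @param pre A pre-fill scaffold from [merge_and_close()].
#' @param reference The same reference used for anchoring.
#' @param id Scaffold id.
#' @return An object of class `scaffold_result`: list with `seq` (N runs at
#'   gaps), `gaps` (data.frame of reference interval and fill length),
#'   `completeness` (percent), `reference_id`, `conflicts`.
#' @export
finalize_scaffold <- function(pre, reference,
                              id = paste0(pre$reference_id, "_scaffold")) {
  rec <- ref_record(reference)
  L <- nchar(rec$seq)
  chars <- rep("N", L)
  pl <- pre$placements
  if (nrow(pl)) {
    # longer contigs take precedence at residual (unmerged) overlaps
    pl <- pl[order(-(pl$end - pl$start)), , drop = FALSE]
    for (i in seq_len(nrow(pl))) {
      cs <- strsplit(pl$seq[i], "")[[1L]]
      # clip contigs running past the circle to one wrap
      n <- min(length(cs), L)
      idx <- ((pl$start[i] + seq_len(n) - 1L) %% L) + 1L
      free <- chars[idx] == "N"
      chars[idx[free]] <- cs[seq_len(n)][free]
    }
  }
  seqs <- paste(chars, collapse = "")
  isn <- chars == "N"
  gaps <- if (any(isn)) {
    r <- rle(isn)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(start = starts[r$values], end = ends[r$values],
               fill_length = r$lengths[r$values])
  } else data.frame(start = integer(), end = integer(), fill_length = integer())
  completeness <- 100 * sum(!isn) / L
  structure(list(id = id, seq = seqs, gaps = gaps,
                 completeness = completeness, reference_id = rec$id,
                 reference_length = L, circular = rec$circular,
                 conflicts = pre$conflicts),
            class = "scaffold_result")
}

#' @export
print.scaffold_result <- function(x, ...) {
  cat(sprintf("<scaffold_result> %s vs %s: %d bp, completeness %.1f%%, %d gap(s)\n",
              x$id, x$reference_id, nchar(x$seq), x$completeness, nrow(x$gaps)))
  invisible(x)
}

#' Back-map reads to final scaffolds for coverage and chimera QC
#'
#' Every pair is assigned to its best scaffold; a pair qualifies when both
#' mates map to the same scaffold in opposite orientations with an implied
#' insert within 3x the stated library range. Mean coverage over non-N
#' positions is reported per scaffold and library, and positions where at
#' least `flag_fraction` of spanning reads (minimum depth 5) disagree with
#' the scaffold consensus are flagged as potential chimera or
#' haplotype-mixing sites.
#'
#' @param scaffolds List of `scaffold_result` (or named character vector).
#' @param read_libraries Named list of `read_set` objects (one per
#'   library, e.g. enriched / non-enriched).
#' @param min_identity Minimum mapping identity per mate.
#' @param flag_fraction Disagreement fraction that flags a site.
#' @return data.frame with one row per scaffold per library (pairs, mean
#'   coverage, flagged sites); flagged positions in attribute
#'   `"flagged"`.
#' @export
backmap_qc <- function(scaffolds, read_libraries, min_identity = 0.9,
                       flag_fraction = 0.2) {
  if (inherits(read_libraries, "read_set"))
    read_libraries <- list(library1 = read_libraries)
  if (inherits(scaffolds, "scaffold_result")) scaffolds <- list(scaffolds)
  if (is.character(scaffolds)) {
    ids <- names(scaffolds) %||% sprintf("scaffold%d", seq_along(scaffolds))
    scaffolds <- Map(function(s, id) structure(
      list(id = id, seq = s, circular = TRUE), class = "scaffold_result"),
      scaffolds, ids)
  }
  stopifnot(length(scaffolds) >= 1L)
  seqs <- vapply(scaffolds, `[[`, "", "seq")
  circ <- vapply(scaffolds, function(s) isTRUE(s$circular), TRUE)
  ids <- vapply(scaffolds, `[[`, "", "id")
  report <- NULL
  flagged <- list()
  for (lib in names(read_libraries)) {
    rd <- read_libraries[[lib]]
    irange <- rd$insert_range
    m1 <- cpp_map_reads(seqs, circ, rd$seq1, 21L, 1 - min_identity, 7L)
    m2 <- cpp_map_reads(seqs, circ, rd$seq2, 21L, 1 - min_identity, 7L)
    same <- m1[, "ref"] > 0L & m1[, "ref"] == m2[, "ref"] &
      m1[, "strand"] == -m2[, "strand"]
    if (!all(is.na(irange))) {
      Ls <- nchar(seqs)[pmax(1L, m1[, "ref"])]
      lo <- pmin(m1[, "start"], m2[, "start"])
      hi <- pmax(m1[, "start"] + nchar(rd$seq1) - 1L,
                 m2[, "start"] + nchar(rd$seq2) - 1L)
      ins <- hi - lo + 1L
      # origin-spanning pairs on circular scaffolds take the short arc
      ins_wrap <- Ls - ins + nchar(rd$seq1) + nchar(rd$seq2)
      ins_eff <- ifelse(circ[pmax(1L, m1[, "ref"])], pmin(ins, ins_wrap), ins)
      same <- same & ins_eff <= 3 * irange[2]
    }
    for (si in seq_along(seqs)) {
      sel <- which(same & m1[, "ref"] == si)
      nn <- sum(strsplit(seqs[si], "")[[1L]] != "N")
      if (length(sel)) {
        pu <- cpp_pileup(seqs[si], circ[si],
                         c(rd$seq1[sel], rd$seq2[sel]),
                         c(m1[sel, "start"], m2[sel, "start"]),
                         c(m1[sel, "strand"], m2[sel, "strand"]))
        depth <- pu[, "depth"]; dis <- pu[, "disagree"]
        mean_cov <- sum(depth) / max(1L, nn)
        fl <- which(depth >= 5L & dis / pmax(depth, 1L) >= flag_fraction)
      } else {
        mean_cov <- 0; fl <- integer()
      }
      flagged[[paste(ids[si], lib, sep = "|")]] <- fl
      report <- rbind(report, data.frame(
        scaffold = ids[si], library = lib, pairs = length(sel),
        mean_coverage = mean_cov, flagged_sites = length(fl)))
    }
  }
  attr(report, "flagged") <- flagged
  report
}
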