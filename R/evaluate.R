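## Truth-aware evaluation of recovered scaffolds/contigs against planted
## genomes.

# classify every scaffold position against one truth genome:
# "match" / "mismatch" / "n" (scaffold N) / "uncov" (not aligned to truth).
# Sequences of equal length (substitution-only simulations share the
# coordinate frame) compare ungapped; otherwise the query is anchored on
# the truth by shared k-mers (both orientations) and banded-aligned to the
# implied window.
classify_vs_truth <- function(query, truth, circular = TRUE) {
  status <- rep("uncov", nchar(query))
  qc <- strsplit(query, "")[[1L]]
  if (nchar(query) == nchar(truth)) {
    tc <- strsplit(truth, "")[[1L]]
    status <- ifelse(qc == "N", "n", ifelse(qc == tc, "match", "mismatch"))
    return(status)
  }
  dbl <- if (circular) paste0(truth, substr(truth, 1L, min(nchar(truth),
                                                           nchar(query) + 400L)))
         else truth
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") query else revcomp(query)
    hits <- cpp_diag_hits(s, dbl, 17L, 4L)
    if (nrow(hits) > (best$n %||% 0L))
      best <- list(n = nrow(hits), strand = strand, s = s,
                   off = hits[, "pos_b"] - hits[, "pos_a"])
  }
  if (is.null(best) || best$n == 0L) return(status)
  d <- as.integer(names(sort(table(best$off), decreasing = TRUE))[1L])
  pad <- max(50L, ceiling(0.02 * nchar(query)))
  ws <- max(0L, d - pad)
  we <- min(nchar(dbl), d + nchar(query) + pad)
  win <- substr(dbl, ws + 1L, we)
  band <- 2L * pad + abs(nchar(win) - nchar(query)) + 10L
  al <- cpp_banded_global(best$s, win, band, 2, -3, 5, 2)
  a <- strsplit(al$a, "")[[1L]]
  b <- strsplit(al$b, "")[[1L]]
  st <- character(0)
  for (i in seq_along(a)) {
    if (a[i] == "-") next
    st <- c(st, if (a[i] == "N") "n" else if (b[i] == "-") "uncov"
            else if (a[i] == b[i]) "match" else "mismatch")
  }
  if (best$strand == "-") st <- rev(st)
  st
}

#' Evaluate recovered scaffolds against the planted truth
#'
#' Each scaffold (or contig) is compared position-wise to every truth
#' genome; the best match provides the reported identity over non-N
#' positions and the completeness relative to the truth length. Chimeric
#' columns are positions that disagree with the best-matching truth while
#' agreeing with a different one — the signature of a haplotype switch.
#'
#' @param scaffolds List of `scaffold_result`, or a named character vector
#'   of sequences.
#' @param truths Named list of `annotated_genome` / `seq_record`, or named
#'   character vector of truth sequences.
#' @return data.frame: scaffold, truth, identity_nonN (percent),
#'   completeness_vs_truth (percent), chimeric_columns.
#' @export
evaluate_recovery <- function(scaffolds, truths) {
  if (inherits(scaffolds, "scaffold_result")) scaffolds <- list(scaffolds)
  sseqs <- if (is.character(scaffolds)) scaffolds else
    setNames(vapply(scaffolds, `[[`, "", "seq"),
             vapply(scaffolds, `[[`, "", "id"))
  if (is.null(names(sseqs))) names(sseqs) <- sprintf("scaffold%d", seq_along(sseqs))
  tseqs <- if (is.character(truths)) truths else panel_seqs(truths)
  if (is.null(names(tseqs)) && !is.character(truths))
    names(tseqs) <- vapply(truths, function(g)
      if (inherits(g, "annotated_genome")) g$record$id else g$id, "")
  rows <- lapply(seq_along(sseqs), function(i) {
    cls <- lapply(tseqs, function(t) classify_vs_truth(sseqs[[i]], t))
    ident <- vapply(cls, function(st) {
      m <- sum(st == "match"); x <- sum(st == "mismatch")
      100 * m / max(1L, m + x)
    }, 0)
    best <- which.max(ident)
    stb <- cls[[best]]
    chim <- 0L
    mism <- which(stb == "mismatch")
    for (k in seq_along(tseqs)[-best]) {
      sto <- cls[[k]]
      hits <- mism[sto[mism] == "match"]
      chim <- chim + length(hits)
      mism <- setdiff(mism, hits)
    }
    data.frame(scaffold = names(sseqs)[i],
               truth = names(tseqs)[best],
               identity_nonN = unname(ident[best]),
               completeness_vs_truth =
                 100 * sum(stb %in% c("match", "mismatch")) /
                   nchar(tseqs[[best]]),
               chimeric_columns = chim)
  })
  do.call(rbind, rows)
}
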