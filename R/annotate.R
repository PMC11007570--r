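## Annotation transfer from an annotated reference onto a new scaffold via
## global pairwise alignment, open-reading-frame validation under the
## mitochondrial genetic code 4, and gene-order rearrangement detection on
## circular genomes.

ACCEPTED_STARTS <- c("ATG", "GTG")

#' Transfer gene models from a reference onto a target sequence
#'
#' The target (a scaffold in the reference coordinate frame) is globally
#' aligned to the reference with affine gap scores (match 2, mismatch -3,
#' open -5, extend -2, banded); every reference exon is projected through
#' the alignment. Exons landing entirely in N gaps are marked missing, and
#' a projected CDS whose raw projection breaks the reading frame is
#' snapped to the nearest in-frame boundary within +/- 6 nt.
#'
#' @param target A `seq_record` (or `scaffold_result`).
#' @param reference An `annotated_genome`.
#' @param min_identity Identity below which transfer is refused (wrong
#'   reference), default 0.6.
#' @param band_margin Extra alignment band beyond the length difference.
#' @return List with `genome` (the annotated target) and `report`
#'   (data.frame: feature, status, shift).
#' @export
transfer_annotations <- function(target, reference, min_identity = 0.6,
                                 band_margin = 200L) {
  if (inherits(target, "scaffold_result"))
    target <- seq_record(target$id, target$seq, circular = isTRUE(target$circular))
  stopifnot(inherits(target, "seq_record"), inherits(reference, "annotated_genome"))
  tseq <- target$seq
  rseq <- reference$record$seq
  band <- abs(nchar(tseq) - nchar(rseq)) + band_margin
  al <- cpp_banded_global(tseq, rseq, band, 2, -3, 5, 2)
  ta <- strsplit(al$a, "")[[1L]]
  ra <- strsplit(al$b, "")[[1L]]
  cmp <- ta != "-" & ra != "-" & ta != "N" & ra != "N"
  ident <- sum(ta == ra & cmp) / max(1L, sum(cmp))
  if (ident < min_identity)
    stop(sprintf("alignment identity %.2f below %.2f: refusing transfer (wrong reference?)",
                 ident, min_identity))
  # projection: for each reference position (0-based), the 0-based target
  # position of the first target base at-or-after it
  rpos <- cumsum(ra != "-")           # reference coordinate per column
  tpos <- cumsum(ta != "-")           # target coordinate per column
  Lr <- nchar(rseq); Lt <- nchar(tseq)
  proj_start <- integer(Lr + 1L)
  # for a ref position p (1-based), the first column where rpos == p; the
  # target start is the count of target bases before that column
  first_col <- match(seq_len(Lr), rpos)
  proj_start[seq_len(Lr)] <- ifelse(ta[first_col] != "-",
                                    tpos[first_col] - 1L,  # aligned base
                                    tpos[first_col])       # ref base in gap
  proj_start[Lr + 1L] <- Lt
  proj0 <- function(p) proj_start[p + 1L]  # 0-based in, 0-based out
  tchars <- strsplit(tseq, "")[[1L]]
  feats <- list()
  report <- NULL
  for (f in reference$features) {
    ex <- f$exons
    nex <- matrix(NA_integer_, nrow(ex), 2L)
    for (i in seq_len(nrow(ex))) {
      s <- ex[i, 1L]; e <- ex[i, 2L]
      ns <- proj0(s)
      ne <- if (e > s) proj0(e) else proj0(e)  # wrap exons keep wrap shape
      nex[i, ] <- c(ns, ne)
    }
    # which exons land entirely in N gaps?
    in_gap <- vapply(seq_len(nrow(nex)), function(i) {
      s <- nex[i, 1L]; e <- nex[i, 2L]
      idx <- if (e > s) (s + 1L):e else if (s < Lt) c((s + 1L):Lt, seq_len(max(e, 0L)))
             else seq_len(max(e, 0L))
      length(idx) == 0L || all(tchars[idx] == "N")
    }, TRUE)
    if (all(in_gap)) {
      report <- rbind(report, data.frame(feature = f$name, status = "missing",
                                         shift = NA_integer_))
      next
    }
    shift <- 0L
    if (f$kind %in% c("CDS", "ORF")) {
      total <- sum(exon_lengths(nex, Lt, target$circular))
      if (total %% 3L != 0L) {
        # snap the terminal exon boundary to restore frame
        deltas <- c(1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L, 5L, -5L, 6L, -6L)
        deltas <- deltas[(total + deltas) %% 3L == 0L]
        last <- if (f$strand == "+") which.max(nex[, 2L]) else which.min(nex[, 1L])
        for (d in deltas) {
          cand <- nex
          if (f$strand == "+") cand[last, 2L] <- cand[last, 2L] + d
          else cand[last, 1L] <- cand[last, 1L] - d
          if (any(cand < 0L) || any(cand > Lt)) next
          nex <- cand; shift <- d
          break
        }
      }
    }
    ok <- tryCatch({
      feats[[length(feats) + 1L]] <-
        feature(f$name, f$kind, nex, f$strand, f$transl_table)
      TRUE
    }, error = function(e) FALSE)
    report <- rbind(report, data.frame(
      feature = f$name, status = if (ok) "transferred" else "failed",
      shift = shift))
  }
  genome <- annotated_genome(seq_record(target$id, tseq, target$circular,
                                        target$description), feats)
  list(genome = genome, report = report, identity = ident)
}

#' Validate coding sequences as table-4 open reading frames
#'
#' Each CDS/ORF is checked for length divisible by 3, an accepted start
#' codon (ATG/GTG), a terminal stop and absence of internal stops under
#' genetic code 4. A CDS whose sequence runs into an N gap is reported as
#' incomplete (gap-truncated) rather than failed.
#'
#' @param genome An `annotated_genome`.
#' @param starts Accepted start codons.
#' @return data.frame: feature, status (`ok`, `incomplete_gap`, or a
#'   failure reason), pass (logical), stop_codon (first internal-stop codon
#'   index or NA).
#' @export
validate_orfs <- function(genome, starts = ACCEPTED_STARTS) {
  code4 <- Biostrings::getGeneticCode("4")
  rows <- lapply(genome$features, function(f) {
    if (!f$kind %in% c("CDS", "ORF")) return(NULL)
    s <- extract_feature(genome, f)
    n <- nchar(s)
    row <- function(status, pass, stop_at = NA_integer_)
      data.frame(feature = f$name, status = status, pass = pass,
                 stop_codon = stop_at)
    if (n %% 3L != 0L) return(row("length_not_multiple_of_3", FALSE))
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    has_n <- grepl("N", codons, fixed = TRUE)
    aa <- unname(code4[codons])
    aa[has_n] <- "X"
    ncod <- length(codons)
    internal <- which(aa[-ncod] == "*")
    if (length(internal)) return(row("internal_stop", FALSE, internal[1L]))
    truncated <- any(has_n)
    if (!codons[1L] %in% starts && !has_n[1L]) {
      if (truncated) return(row("incomplete_gap", TRUE))
      return(row("bad_start_codon", FALSE))
    }
    if (aa[ncod] != "*") {
      if (truncated || has_n[ncod]) return(row("incomplete_gap", TRUE))
      return(row("missing_terminal_stop", FALSE))
    }
    row(if (truncated) "incomplete_gap" else "ok", TRUE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

# circular feature order as (name, strand), rotated so `anchor` comes first
# on the forward strand
gene_order <- function(genome, shared, anchor) {
  fs <- Filter(function(f) f$name %in% shared, genome$features)
  starts <- vapply(fs, function(f) min(f$exons[, 1L]), 0L)
  fs <- fs[order(starts)]
  nm <- vapply(fs, `[[`, "", "name")
  st <- vapply(fs, `[[`, "", "strand")
  i <- match(anchor, nm)
  if (is.na(i)) i <- 1L
  rot <- c(i:length(nm), if (i > 1L) 1L:(i - 1L))
  nm <- nm[rot]; st <- st[rot]
  if (st[1L] == "-") {  # flip the whole circle so the anchor reads forward
    nm <- c(nm[1L], rev(nm[-1L]))
    st <- c(st[1L], rev(st[-1L]))
    st <- ifelse(st == "+", "-", "+")
    st[1L] <- "+"
  }
  list(name = nm, strand = st)
}

#' Detect gene-order rearrangements between two annotated genomes
#'
#' Gene orders are compared as signed circular permutations over the
#' shared features, rotated to a common anchor (COX1 by default). Maximal
#' in-place reversed blocks are reported as inversions; single features
#' whose neighborhood changed are reported as translocations. Genomes with
#' identical order up to rotation yield an empty list.
#'
#' @param a,b `annotated_genome` objects sharing at least 80% of feature
#'   names.
#' @param anchor Feature used to fix the rotation.
#' @return data.frame of calls: kind (`inversion`/`translocation`),
#'   features (comma-separated), span_a, span_b. Zero rows when collinear.
#' @export
detect_rearrangements <- function(a, b, anchor = "COX1") {
  na <- vapply(a$features, `[[`, "", "name")
  nb <- vapply(b$features, `[[`, "", "name")
  shared <- intersect(na, nb)
  if (length(shared) < 0.8 * max(length(na), length(nb)))
    stop("insufficient shared features between genomes")
  if (!anchor %in% shared) anchor <- sort(shared)[1L]
  oa <- gene_order(a, shared, anchor)
  ob <- gene_order(b, shared, anchor)
  n <- length(oa$name)
  pi <- match(ob$name, oa$name)
  sgn <- ifelse(ob$strand == oa$strand[pi], 1L, -1L)
  calls <- data.frame(kind = character(), features = character(),
                      span_a = character(), span_b = character())
  # in-place inverted blocks: positions i..j holding values j..i with
  # flipped signs; the candidate block end for a block starting at i is
  # pi[i] itself
  i <- 1L
  while (i <= n) {
    j <- pi[i]
    if (j >= i && all(pi[i:j] == (i + j) - (i:j)) && all(sgn[i:j] == -1L)) {
      calls <- rbind(calls, data.frame(
        kind = "inversion",
        features = paste(ob$name[i:j], collapse = ","),
        span_a = paste(oa$name[c(j, i)], collapse = ".."),
        span_b = paste(ob$name[c(i, j)], collapse = "..")))
      pi[i:j] <- i:j
      sgn[i:j] <- 1L
      i <- j + 1L
    } else i <- i + 1L
  }
  # translocations: features whose removal leaves the remaining order
  # sorted (identity up to renumbering)
  guard <- 0L
  while (!all(pi == seq_along(pi)) && guard < n) {
    guard <- guard + 1L
    done <- FALSE
    for (x in which(pi != seq_along(pi))) {
      keep <- setdiff(seq_along(pi), x)
      rest <- pi[keep]
      if (!all(rank(rest) == seq_along(rest)) || any(sgn[keep] != 1L)) next
      nn <- length(pi)
      calls <- rbind(calls, data.frame(
        kind = "translocation", features = ob$name[x],
        span_a = sprintf("%s..%s",
                         if (pi[x] > 1L) oa$name[pi[x] - 1L] else "origin",
                         if (pi[x] < nn) oa$name[pi[x] + 1L] else "origin"),
        span_b = sprintf("%s..%s",
                         if (x > 1L) ob$name[x - 1L] else "origin",
                         if (x < nn) ob$name[x + 1L] else "origin")))
      oa$name <- oa$name[-pi[x]]
      ob$name <- ob$name[-x]
      pi <- rank(rest)
      sgn <- sgn[keep]
      done <- TRUE
      break
    }
    if (!done) break
  }
  calls
}
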