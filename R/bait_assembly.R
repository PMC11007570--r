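## Read preprocessing, shared-k-mer baiting against a mitogenome reference
## panel, multi-k de Bruijn seed assembly and iterative consensus overlap
## extension.

DEFAULT_ADAPTERS <- c(
  "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",   # TruSeq R1
  "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT")   # TruSeq R2

#' Quality-trim, adapter-clip and optionally error-correct a read library
#'
#' A sliding-window trimmer removes 3' bases whose window mean quality
#' falls below the cutoff and clips adapter suffixes at exact matches of at
#' least 10 bp. With `correct = TRUE` a k-mer-spectrum corrector repairs
#' bases supported only by solo k-mers (count 1) when a single substitution
#' lifts all covering k-mers to solid (count >= 5). Pairs in which either
#' mate falls below `min_length` are dropped whole.
#'
#' @param reads A `read_set`.
#' @param quality_cutoff Phred cutoff for the sliding window.
#' @param adapters Adapter sequences to clip.
#' @param correct Run k-mer-spectrum error correction?
#' @param k Odd correction k-mer size in \[15, 31\].
#' @param window Sliding window width.
#' @param min_length Minimum surviving mate length.
#' @param solid_min Count at which a k-mer is considered solid.
#' @return A filtered `read_set`.
#' @export
preprocess_reads <- function(reads, quality_cutoff = 15, adapters = DEFAULT_ADAPTERS,
                             correct = FALSE, k = 21L, window = 4L,
                             min_length = 50L, solid_min = 5L) {
  if (correct && (k %% 2L == 0L || k < 15L || k > 31L))
    stop("correction k must be odd and in [15, 31]")
  t1 <- cpp_trim_reads(reads$seq1, reads$qual1, quality_cutoff, window,
                       adapters, 10L)
  t2 <- cpp_trim_reads(reads$seq2, reads$qual2, quality_cutoff, window,
                       adapters, 10L)
  keep <- nchar(t1$seq) >= min_length & nchar(t2$seq) >= min_length
  s1 <- t1$seq[keep]; s2 <- t2$seq[keep]
  if (correct && length(s1)) {
    n <- length(s1)
    corr <- cpp_correct_reads(c(s1, s2), k, solid_min)
    s1 <- corr[seq_len(n)]; s2 <- corr[n + seq_len(n)]
  }
  read_set(reads$id[keep], s1, s2, t1$qual[keep], t2$qual[keep],
           reads$read_length, reads$insert_range)
}

#' Recruit candidate prey reads by shared k-mers with a reference panel
#'
#' A pair is recruited when either mate shares at least `min_shared_kmers`
#' canonical k-mers with any panel genome (paired-end rescue: the mate of a
#' recruited read is always recruited too). When a truth table of read
#' origins is supplied, recall and precision on prey pairs are attached as
#' attribute `"metrics"`.
#'
#' @param reads A `read_set`.
#' @param panel List of `annotated_genome` / `seq_record`, or a named
#'   character vector of panel sequences.
#' @param min_shared_kmers Recruitment threshold.
#' @param k_bait Bait k-mer size in \[17, 31\].
#' @param truth Optional read-origin data.frame from [simulate_library()];
#'   pairs whose genome is not a host fragment count as prey.
#' @return The recruited `read_set`.
#' @export
bait_reads <- function(reads, panel, min_shared_kmers = 2L, k_bait = 25L,
                       truth = NULL) {
  if (k_bait < 17L || k_bait > 31L) stop("k_bait must be in [17, 31]")
  seqs <- panel_seqs(panel)
  if (!length(seqs)) stop("empty panel")
  n1 <- cpp_shared_kmer_counts(reads$seq1, seqs, k_bait)
  n2 <- cpp_shared_kmer_counts(reads$seq2, seqs, k_bait)
  hit <- n1 >= min_shared_kmers | n2 >= min_shared_kmers
  out <- subset_pairs(reads, which(hit))
  attr(out, "shared") <- pmax(n1, n2)[hit]
  if (!is.null(truth)) {
    is_prey <- !grepl("^host", truth$genome[match(reads$id, truth$id)])
    tp <- sum(hit & is_prey, na.rm = TRUE)
    attr(out, "metrics") <- c(
      recall = tp / max(1L, sum(is_prey, na.rm = TRUE)),
      precision = tp / max(1L, sum(hit)))
  }
  out
}

panel_seqs <- function(panel) {
  if (is.character(panel)) return(panel)
  vapply(panel, function(g) {
    if (inherits(g, "annotated_genome")) g$record$seq
    else if (inherits(g, "seq_record")) g$seq
    else as.character(g)
  }, "")
}

#' Seed-assemble recruited reads and lengthen contigs iteratively
#'
#' Seed contigs come from a de Bruijn assembly run over a ladder of k-mer
#' sizes; the largest k whose graph yields unitigs of at least twice the
#' read length provides the seeds. Each contig end is then extended, for up
#' to `iterations` rounds, by the consensus of reads whose overlap with the
#' terminal bases reaches `min_identity`, appending bases only while one
#' base holds at least an 80% majority of the votes; extension halts at a
#' fork (a haplotype boundary) or when no read qualifies. Ties break
#' lexicographically, so identical inputs give identical contigs.
#'
#' @param baited A `read_set` of recruited reads.
#' @param k_list de Bruijn k-mer ladder (odd values).
#' @param iterations Extension rounds.
#' @param min_overlap Minimum terminal overlap for an extending read.
#' @param min_identity Minimum overlap identity.
#' @param majority Base-majority fraction required to append.
#' @param min_kmer_count Minimum k-mer multiplicity kept in the graph (3 suppresses error k-mers shared by two reads at typical coverages).
#' @return A data.frame of contigs (id, seq, length, mean k-mer coverage,
#'   iterations used), sorted by decreasing length.
#' @export
assemble_and_extend <- function(baited, k_list = c(33L, 55L, 77L),
                                iterations = 10L, min_overlap = 50L,
                                min_identity = 0.98, majority = 0.8,
                                min_kmer_count = 3L) {
  stopifnot(iterations >= 1L)
  empty <- data.frame(id = character(), seq = character(),
                      length = integer(), coverage = numeric(),
                      iterations = integer())
  if (!inherits(baited, "read_set")) stop("baited must be a read_set")
  reads <- c(baited$seq1, baited$seq2)
  reads <- reads[nchar(reads) > 0]
  if (!length(reads)) return(empty)
  rl <- max(nchar(reads))
  seeds <- NULL
  for (k in sort(as.integer(k_list), decreasing = TRUE)) {
    if (k >= rl) next
    u <- cpp_unitigs(reads, k, min_kmer_count)
    cov <- attr(u, "coverage")
    long <- nchar(u) >= 2L * rl
    if (any(long)) {
      seeds <- data.frame(seq = u[long], coverage = cov[long])
      break
    }
  }
  if (is.null(seeds)) {
    # low-coverage fallback: keep the longest unitigs at the smallest k,
    # singleton k-mers included (partial recovery is reported, not hidden)
    k <- min(as.integer(k_list))
    u <- cpp_unitigs(reads, k, 1L)
    if (!length(u)) return(empty)
    long <- nchar(u) >= max(rl + 1L, k + 10L)
    if (!any(long)) long <- seq_len(min(5L, length(u)))
    seeds <- data.frame(seq = u[long], coverage = attr(u, "coverage")[long])
  }
  ext <- cpp_extend_contigs(seeds$seq, reads, min_overlap, min_identity,
                            majority, iterations, 21L)
  lens <- nchar(ext$seq)
  if (any(lens < nchar(seeds$seq)))
    stop("internal error: contig shrank during extension")
  polished <- polish_contigs(ext$seq, reads, majority = majority)
  lens <- nchar(polished)
  ord <- order(-lens, polished)
  data.frame(id = sprintf("contig%03d", seq_along(ord)),
             seq = polished[ord], length = lens[ord],
             coverage = seeds$coverage[ord], iterations = ext$iterations[ord],
             stringsAsFactors = FALSE)
}

# consensus polish: re-map reads to each contig at low divergence and
# replace any base out-voted by a clear majority of its own pile-up (a
# unitig path can take a wrong branch across a coverage dip; the read
# pile-up exposes it because same-haplotype reads dominate once
# cross-haplotype reads are excluded by the mapping divergence cap)
polish_contigs <- function(contigs, reads, max_div = 0.02, majority = 0.8,
                           min_depth = 5L) {
  if (!length(contigs)) return(contigs)
  bases <- c("A", "C", "G", "T")
  # one inverted-index pass assigns each read to every contig it could
  # support; per-contig mapping then only touches those candidates, so
  # overlapping sibling contigs cannot siphon off the reads that expose a
  # wrong base, and the cost stays near-linear in the read count
  cand <- cpp_candidate_reads(contigs, reads, 25L, 2L)
  vapply(seq_along(contigs), function(ci) {
    rd <- reads[cand[[ci]]]
    if (!length(rd)) return(contigs[ci])
    m <- cpp_map_reads(contigs[ci], FALSE, rd, 21L, max_div, 7L)
    sel <- which(m[, "ref"] == 1L)
    if (!length(sel)) return(contigs[ci])
    votes <- cpp_base_votes(contigs[ci], rd[sel], m[sel, "start"],
                            m[sel, "strand"])
    tot <- colSums(votes)
    top <- max.col(t(votes), ties.method = "first")
    cur <- strsplit(contigs[ci], "")[[1L]]
    flip <- tot >= min_depth & votes[cbind(top, seq_along(tot))] >= majority * tot &
      bases[top] != cur
    if (any(flip)) cur[flip] <- bases[top[flip]]
    paste(cur, collapse = "")
  }, "")
}
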