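#' @useDynLib mitobait, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames rbinom runif
#' @importFrom utils read.delim write.table head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Create a sequence record
#'
#' A minimal container for a DNA sequence: an id, the sequence itself
#' (A/C/G/T/N), a circularity flag (mitochondrial chromosomes are circular)
#' and a free-text description.
#'
#' @param id Record identifier, unique within a collection.
#' @param seq DNA string over A, C, G, T, N (case-insensitive; stored
#'   upper-case).
#' @param circular Is the molecule circular?
#' @param description Free text.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, seq, circular = FALSE, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("sequence must be non-empty")
  if (grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), seq))
    stop("sequence contains characters outside A/C/G/T/N")
  structure(
    list(id = id, seq = seq, circular = isTRUE(circular),
         description = as.character(description)),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d bp%s %s\n", x$id, nchar(x$seq),
              if (x$circular) " (circular)" else "", x$description))
  invisible(x)
}

#' Sequence length of a record or annotated genome
#' @param x A `seq_record` or `annotated_genome`.
#' @return Integer length in bp.
#' @export
seq_length <- function(x) {
  if (inherits(x, "annotated_genome")) x <- x$record
  nchar(x$seq)
}

#' Reverse complement
#'
#' @param x Character vector of DNA strings (N allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Create a genome feature
#'
#' Features are strand-aware and possibly multi-exon (placozoan
#' mitochondrial cox1, nad5 and 16S are split into exons). Exons are
#' 0-based half-open intervals on the forward strand; on circular records
#' an exon whose end does not exceed its start wraps the origin.
#'
#' @param name Gene symbol (e.g. `"COX1"`, `"NAD3"`, `"16S_a"`,
#'   `"tRNA-Thr"`, `"POLB"`).
#' @param kind One of `"CDS"`, `"rRNA"`, `"tRNA"`, `"ORF"`.
#' @param exons Two-column matrix (start, end) of 0-based half-open
#'   intervals in ascending genome order (minus-strand features are
#'   reverse-complemented as a whole on extraction).
#' @param strand `"+"` or `"-"`.
#' @param transl_table Translation table for CDS validation; placozoan
#'   mitochondria use table 4 (TGA = Trp).
#' @return An object of class `feature`.
#' @export
feature <- function(name, kind = c("CDS", "rRNA", "tRNA", "ORF"),
                    exons, strand = c("+", "-"), transl_table = 4L) {
  kind <- match.arg(kind)
  strand <- match.arg(strand)
  if (is.vector(exons) && length(exons) == 2L) exons <- matrix(exons, ncol = 2L)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("feature needs at least one exon")
  if (any(exons < 0L)) stop("exon coordinates must be >= 0")
  structure(
    list(name = name, kind = kind, exons = exons, strand = strand,
         transl_table = as.integer(transl_table)),
    class = "feature"
  )
}

# exon lengths, honouring circular wrap on a record of length L
exon_lengths <- function(exons, L, circular = TRUE) {
  len <- exons[, 2L] - exons[, 1L]
  wrap <- len <= 0L
  if (any(wrap)) {
    if (!circular) stop("interval out of range on a linear record")
    len[wrap] <- len[wrap] + L
  }
  len
}

#' Total feature length
#' @param f A `feature`.
#' @param L Genome length.
#' @param circular Whether the genome is circular.
#' @return Summed exon length in bp.
#' @export
feature_length <- function(f, L, circular = TRUE) {
  sum(exon_lengths(f$exons, L, circular))
}

#' Assemble a genome with annotations
#'
#' @param record A `seq_record`.
#' @param features List of `feature` objects; names must be unique per
#'   (name, kind).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(record, features = list()) {
  stopifnot(inherits(record, "seq_record"))
  L <- nchar(record$seq)
  keys <- vapply(features, function(f) paste(f$name, f$kind), "")
  if (anyDuplicated(keys)) stop("duplicate feature (name, kind): ",
                                keys[duplicated(keys)][1L])
  for (f in features) {
    if (any(f$exons[, 1L] >= L) || any(f$exons[, 2L] > L))
      stop(sprintf("feature %s exceeds genome length %d", f$name, L))
    exon_lengths(f$exons, L, record$circular)  # errors on bad wrap
  }
  structure(list(record = record, features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  kinds <- table(vapply(x$features, `[[`, "", "kind"))
  cat(sprintf("<annotated_genome> %s: %d bp%s; %d features (%s)\n",
              x$record$id, nchar(x$record$seq),
              if (x$record$circular) ", circular" else "",
              length(x$features),
              paste(names(kinds), kinds, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Translate a coding sequence
#'
#' Translation under the standard (1) or mold/protozoan/coelenterate
#' mitochondrial (4) genetic code. A terminal stop codon is stripped;
#' internal stops raise an error that carries the failing codon position.
#' Codons containing N translate to X.
#'
#' @param dna In-frame coding sequence (length divisible by 3).
#' @param table Genetic code id, 1 or 4.
#' @return Peptide string.
#' @export
translate_cds <- function(dna, table = 4L) {
  if (!table %in% c(1L, 4L)) stop("table must be 1 or 4")
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L)
    stop(sprintf("CDS length %d is not a multiple of 3", n), call. = FALSE)
  code <- Biostrings::getGeneticCode(as.character(table))
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  stops <- which(aa == "*")
  if (length(stops)) {
    cond <- structure(
      class = c("mitobait_internal_stop", "error", "condition"),
      list(message = sprintf("internal stop codon at codon %d", stops[1L]),
           call = NULL, codon = stops[1L]))
    stop(cond)
  }
  paste(aa, collapse = "")
}

# extract the forward-strand sequence of one exon (wrap-aware)
exon_seq <- function(seq, start, end, circular) {
  L <- nchar(seq)
  if (end > start) {
    if (end > L) stop("interval out of range")
    substr(seq, start + 1L, end)
  } else {
    if (!circular) stop("interval out of range on a linear record")
    paste0(substr(seq, start + 1L, L), substr(seq, 1L, end))
  }
}

#' Extract the spliced sequence of a feature
#'
#' Exon sequences are taken from the forward strand, concatenated in the
#' stored (ascending genome) order, and reverse-complemented as a whole for
#' minus-strand features, which yields the transcript. Origin-spanning
#' exons on circular records are handled transparently.
#'
#' @param genome An `annotated_genome`.
#' @param feat A `feature` (typically one of `genome$features`) or a
#'   feature name to look up.
#' @return DNA string of the spliced feature.
#' @export
extract_feature <- function(genome, feat) {
  if (is.character(feat)) {
    hit <- Filter(function(f) f$name == feat, genome$features)
    if (!length(hit)) stop("no feature named ", feat)
    feat <- hit[[1L]]
  }
  rec <- genome$record
  parts <- vapply(seq_len(nrow(feat$exons)), function(i)
    exon_seq(rec$seq, feat$exons[i, 1L], feat$exons[i, 2L], rec$circular), "")
  s <- paste(parts, collapse = "")
  if (feat$strand == "-") s <- revcomp(s)
  s
}

## ---------------------------------------------------------------------------
## FASTA / FASTQ / feature-table / GFF3 input-output
## ---------------------------------------------------------------------------

#' Read a FASTA file
#' @param path FASTA file, optionally gzip-compressed.
#' @return Named character vector of upper-case sequences; full headers kept
#'   in attribute `"description"`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  desc <- names(x)
  ids <- sub("\\s.*$", "", desc)
  out <- setNames(toupper(as.character(x)), ids)
  attr(out, "description") <- setNames(desc, ids)
  out
}

#' Write sequences as FASTA
#' @param seqs Named character vector, or a list of `seq_record` /
#'   `annotated_genome` objects.
#' @param path Output path; `.gz` suffix triggers gzip.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (is.list(seqs)) {
    recs <- lapply(seqs, function(x) if (inherits(x, "annotated_genome")) x$record else x)
    seqs <- setNames(vapply(recs, `[[`, "", "seq"), vapply(recs, `[[`, "", "id"))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a paired read set
#'
#' @param id Fragment ids (shared by the two mates).
#' @param seq1,seq2 Mate sequences.
#' @param qual1,qual2 Phred+33 quality strings (defaults to uniform Q30).
#' @param read_length Nominal read length of the library.
#' @param insert_range Length-2 numeric, nominal insert range.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id, seq1, seq2, qual1 = NULL, qual2 = NULL,
                     read_length = NA_integer_, insert_range = c(NA, NA)) {
  n <- length(id)
  stopifnot(length(seq1) == n, length(seq2) == n)
  if (is.null(qual1)) qual1 <- strrep("?", nchar(seq1))  # "?" = Q30
  if (is.null(qual2)) qual2 <- strrep("?", nchar(seq2))
  if (any(nchar(qual1) != nchar(seq1)) || any(nchar(qual2) != nchar(seq2)))
    stop("sequence/quality length mismatch")
  structure(
    list(id = as.character(id), seq1 = seq1, seq2 = seq2,
         qual1 = qual1, qual2 = qual2,
         read_length = as.integer(read_length),
         insert_range = as.numeric(insert_range)),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d pairs, read length %s, insert %s-%s\n",
              length(x$id), x$read_length, x$insert_range[1], x$insert_range[2]))
  invisible(x)
}

#' Number of pairs in a read set
#' @param x A `read_set`.
#' @return Integer.
#' @export
n_pairs <- function(x) length(x$id)

#' Subset a read set by pair index
#' @param x A `read_set`.
#' @param i Index vector of pairs to keep.
#' @return A `read_set`.
#' @export
subset_pairs <- function(x, i) {
  read_set(x$id[i], x$seq1[i], x$seq2[i], x$qual1[i], x$qual2[i],
           x$read_length, x$insert_range)
}

parse_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), 4L)]))
  seqs <- toupper(lines[seq(2L, length(lines), 4L)])
  quals <- lines[seq(4L, length(lines), 4L)]
  if (any(nchar(seqs) != nchar(quals)))
    stop("FASTQ sequence/quality length mismatch in ", path)
  list(id = ids, seq = seqs, qual = quals)
}

#' Read paired FASTQ files
#'
#' The two files must be synchronized (record i of file 1 is the mate of
#' record i of file 2); trailing `/1`, `/2` or space-separated tags are
#' stripped before the pairing check.
#'
#' @param path1,path2 Mate FASTQ files, optionally gzip-compressed.
#' @param read_length,insert_range Library metadata to attach.
#' @return A `read_set`.
#' @export
read_fastq_pairs <- function(path1, path2, read_length = NA_integer_,
                             insert_range = c(NA, NA)) {
  a <- parse_fastq(path1)
  b <- parse_fastq(path2)
  if (length(a$id) != length(b$id))
    stop("desynchronized pair files: record counts differ")
  ida <- sub("/[12]$", "", a$id)
  idb <- sub("/[12]$", "", b$id)
  if (!all(ida == idb)) stop("desynchronized pair files: ids differ")
  read_set(ida, a$seq, b$seq, a$qual, b$qual, read_length, insert_range)
}

#' Write a read set as paired FASTQ
#' @param reads A `read_set`.
#' @param path1,path2 Output mate files; `.gz` suffix triggers gzip.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(reads, path1, path2) {
  wr <- function(path, id, seq, qual, mate) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", id, "/", mate, "\n", seq, "\n+\n", qual), con)
  }
  wr(path1, reads$id, reads$seq1, reads$qual1, 1L)
  wr(path2, reads$id, reads$seq2, reads$qual2, 2L)
  invisible(c(path1, path2))
}

#' Write feature tables for annotated genomes
#'
#' Tab-separated with columns genome_id, name, kind, strand, exons
#' (comma-separated `start-end` 0-based half-open pairs) and transl_table.
#'
#' @param genomes List of `annotated_genome`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genomes, path) {
  rows <- lapply(genomes, function(g) {
    do.call(rbind, lapply(g$features, function(f) {
      data.frame(genome_id = g$record$id, name = f$name, kind = f$kind,
                 strand = f$strand,
                 exons = paste(sprintf("%d-%d", f$exons[, 1L], f$exons[, 2L]),
                               collapse = ","),
                 transl_table = f$transl_table,
                 circular = g$record$circular)
    }))
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomes from FASTA plus feature table
#'
#' @param fasta FASTA of genome sequences.
#' @param feature_tsv Feature table as written by [write_feature_table()].
#' @return List of `annotated_genome`, named by genome id.
#' @export
read_genomes <- function(fasta, feature_tsv) {
  seqs <- read_fasta(fasta)
  tab <- read.delim(feature_tsv, stringsAsFactors = FALSE)
  out <- list()
  for (gid in unique(tab$genome_id)) {
    if (!gid %in% names(seqs)) stop("genome ", gid, " missing from FASTA")
    sub <- tab[tab$genome_id == gid, , drop = FALSE]
    feats <- lapply(seq_len(nrow(sub)), function(i) {
      ex <- do.call(rbind, lapply(strsplit(sub$exons[i], ",")[[1L]], function(p)
        as.integer(strsplit(p, "-")[[1L]])))
      feature(sub$name[i], sub$kind[i], ex, sub$strand[i], sub$transl_table[i])
    })
    circ <- if ("circular" %in% names(sub)) isTRUE(sub$circular[1L]) else TRUE
    out[[gid]] <- annotated_genome(seq_record(gid, seqs[[gid]], circ), feats)
  }
  out
}

#' Export annotations as GFF3
#'
#' One line per exon; multi-exon features share an `ID` attribute.
#' Coordinates are 1-based inclusive; origin-spanning exons are split at
#' the origin.
#'
#' @param genome An `annotated_genome`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  L <- seq_length(genome)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$record$id, L))
  for (f in genome$features) {
    type <- if (f$kind == "ORF") "CDS" else f$kind
    for (i in seq_len(nrow(f$exons))) {
      s <- f$exons[i, 1L]; e <- f$exons[i, 2L]
      ivs <- if (e > s) list(c(s + 1L, e)) else list(c(s + 1L, L), c(1L, e))
      for (iv in ivs) {
        lines <- c(lines, sprintf(
          "%s\tmitobait\t%s\t%d\t%d\t.\t%s\t.\tID=%s;gene=%s;exon=%d",
          genome$record$id, type, iv[1L], iv[2L], f$strand, f$name, f$name, i))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
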