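## End-to-end orchestration: simulate (or load) -> trim -> bait -> correct
## -> assemble/extend -> per-reference scaffold -> annotate -> distances,
## with persisted intermediates and a deterministic run report.

#' Default pipeline configuration
#'
#' Every parameter has a default mirroring the package's stage defaults;
#' the configuration round-trips through YAML.
#'
#' @param outdir Output directory.
#' @param seed Global seed; stage seeds derive from it by fixed offsets.
#' @return A nested list, classed `run_config`.
#' @export
default_config <- function(outdir = "mitobait_run", seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    reads = list(fastq1 = NULL, fastq2 = NULL,
                 read_length = 250L, insert_range = c(400L, 800L)),
    panel = list(fasta = NULL, features = NULL),
    simulate = list(enabled = TRUE,
                    prey_coverages = c(40, 70, 100),
                    low_prey_coverage = 0.5,
                    panel_divergence = 0.08,
                    prey_divergence = 0.05,
                    host_bp = 5e6, host_fragments = 200L, host_coverage = 30,
                    read_length = 250L, insert_range = c(400L, 800L),
                    error_rate = 0.005),
    preprocess = list(quality_cutoff = 15, correct = TRUE, k = 21L,
                      solid_min = 5L, min_length = 50L),
    bait = list(k_bait = 25L, min_shared_kmers = 2L),
    assemble = list(k_list = c(33L, 55L, 77L), iterations = 10L,
                    min_overlap = 50L, min_identity = 0.98),
    scaffold = list(flank = 300L, min_anchor_identity = 0.75,
                    min_assign_identity = 0.75),
    partition = NULL
  ), class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.null(upd[[nm]])) base[nm] <- list(NULL)  # keep explicit nulls
      else if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  structure(merge_in(unclass(base), cfg), class = "run_config")
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# generate panel references, planted prey haplotypes and host background
# for a simulated run; deterministic in the config seed
simulate_inputs <- function(config) {
  sim <- config$simulate
  base <- build_panel_genome(architecture_spec(),
                             seed = derive_seed(config$seed, 101L),
                             id = "base")
  n_prey <- length(sim$prey_coverages)
  n_all <- n_prey + (sim$low_prey_coverage > 0)
  panel <- lapply(seq_len(n_all), function(i)
    derive_haplotype(base, sim$panel_divergence,
                     seed = derive_seed(config$seed, 200L + i),
                     id = sprintf("ref%d", i)))
  prey <- lapply(seq_len(n_all), function(i)
    derive_haplotype(panel[[i]], sim$prey_divergence,
                     seed = derive_seed(config$seed, 300L + i),
                     id = sprintf("prey%d", i)))
  covs <- c(sim$prey_coverages,
            if (sim$low_prey_coverage > 0) sim$low_prey_coverage)
  host <- simulate_host(sim$host_bp, sim$host_fragments,
                        seed = derive_seed(config$seed, 400L))
  truth <- truth_set(prey, covs, host, sim$host_coverage,
                     sim$read_length, sim$insert_range, sim$error_rate,
                     seed = derive_seed(config$seed, 500L))
  list(panel = setNames(panel, vapply(panel, function(g) g$record$id, "")),
       truth = truth)
}

#' Run the full recovery pipeline
#'
#' Stages: input simulation (or FASTQ loading), quality trimming, k-mer
#' baiting against the panel, targeted error correction of the recruited
#' pool, multi-k assembly with iterative extension, per-reference
#' scaffolding with gap closing and N-fill, back-mapping QC with
#' trimmed-only reads, annotation transfer with ORF validation and
#' rearrangement calls, and (when a partition is configured) the rank
#' distance tables. All stages are deterministic given the seed;
#' intermediate artifacts are persisted under `outdir`.
#'
#' @param config A `run_config`.
#' @return A `run_report` list; also written as JSON/TSV under `outdir`.
#' @export
run_pipeline <- function(config = default_config()) {
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("run started; parameters:\n"), file = log_path)
  dput_to <- utils::capture.output(utils::str(unclass(config)))
  writeLines(dput_to, log_path)
  write_config(config, file.path(out, "config.yaml"))

  truth <- NULL; origins <- NULL
  if (isTRUE(config$simulate$enabled)) {
    logf("stage simulate")
    inputs <- simulate_inputs(config)
    panel <- inputs$panel
    truth <- inputs$truth
    sim <- simulate_library(truth, outdir = file.path(out, "simulate"))
    reads <- sim$reads
    origins <- sim$origins
    write_fasta(panel, file.path(out, "simulate", "panel.fasta"))
    write_feature_table(panel, file.path(out, "simulate", "panel_features.tsv"))
  } else {
    if (is.null(config$reads$fastq1) || is.null(config$panel$fasta))
      stop("stage input: need reads and panel when simulation is disabled")
    logf("stage load")
    reads <- read_fastq_pairs(config$reads$fastq1, config$reads$fastq2,
                              config$reads$read_length,
                              config$reads$insert_range)
    panel <- read_genomes(config$panel$fasta, config$panel$features)
  }

  logf("stage preprocess: %d pairs in", n_pairs(reads))
  trimmed <- preprocess_reads(reads,
                              quality_cutoff = config$preprocess$quality_cutoff,
                              correct = FALSE,
                              min_length = config$preprocess$min_length)
  logf("stage preprocess: %d pairs kept", n_pairs(trimmed))

  logf("stage bait")
  baited <- bait_reads(trimmed, panel,
                       min_shared_kmers = config$bait$min_shared_kmers,
                       k_bait = config$bait$k_bait, truth = origins)
  metrics <- attr(baited, "metrics")
  logf("stage bait: %d pairs recruited", n_pairs(baited))
  if (isTRUE(config$preprocess$correct) && n_pairs(baited) > 0) {
    logf("stage correct")
    baited <- preprocess_reads(baited, quality_cutoff = 0, correct = TRUE,
                               k = config$preprocess$k,
                               solid_min = config$preprocess$solid_min,
                               min_length = config$preprocess$min_length)
  }

  logf("stage assemble")
  contigs <- assemble_and_extend(baited,
                                 k_list = config$assemble$k_list,
                                 iterations = config$assemble$iterations,
                                 min_overlap = config$assemble$min_overlap,
                                 min_identity = config$assemble$min_identity)
  logf("stage assemble: %d contigs, longest %s", nrow(contigs),
       if (nrow(contigs)) contigs$length[1L] else 0L)
  if (nrow(contigs))
    write_fasta(setNames(contigs$seq, contigs$id),
                file.path(out, "contigs.fasta"))

  # assign each contig to its best panel reference, then scaffold per
  # reference
  scaffolds <- list()
  logf("stage scaffold")
  per_ref <- lapply(panel, function(ref)
    anchor_contigs(contigs, ref, config$scaffold$min_anchor_identity))
  assign <- if (nrow(contigs)) {
    ident_mat <- matrix(vapply(per_ref, function(a)
      ifelse(is.na(a$start), NA_real_, a$identity), numeric(nrow(contigs))),
      nrow = nrow(contigs))
    apply(ident_mat, 1L, function(r)
      if (all(is.na(r))) NA_integer_ else which.max(r))
  } else integer(0)
  for (ri in seq_along(panel)) {
    # every panel reference gets a scaffold attempt: low-coverage prey with
    # no seed contigs can still be partially recovered by gap recruitment
    sel <- which(!is.na(assign) & assign == ri)
    pl <- per_ref[[ri]][sel, , drop = FALSE]
    pre <- merge_and_close(pl, contigs[sel, , drop = FALSE], panel[[ri]],
                           reads = trimmed, flank = config$scaffold$flank,
                           k_list = config$assemble$k_list)
    sc <- finalize_scaffold(pre, panel[[ri]])
    scaffolds[[sc$id]] <- sc
    logf("scaffold %s: completeness %.1f%%", sc$id, sc$completeness)
  }
  # drop references that recruited nothing at all
  scaffolds <- Filter(function(s) s$completeness > 0, scaffolds)
  if (length(scaffolds)) {
    write_fasta(setNames(vapply(scaffolds, `[[`, "", "seq"),
                         names(scaffolds)), file.path(out, "scaffolds.fasta"))
    gaps_bed <- do.call(rbind, lapply(scaffolds, function(s)
      if (nrow(s$gaps)) data.frame(chrom = s$id, start = s$gaps$start,
                                   end = s$gaps$end) else NULL))
    if (!is.null(gaps_bed))
      write.table(gaps_bed, file.path(out, "gaps.bed"), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
  }

  logf("stage backmap")
  qc <- if (length(scaffolds))
    backmap_qc(scaffolds, list(all = trimmed)) else NULL
  if (!is.null(qc))
    write.table(qc, file.path(out, "backmap_qc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  logf("stage annotate")
  annotations <- list()
  orf_reports <- NULL
  rearrangements <- NULL
  for (id in names(scaffolds)) {
    sc <- scaffolds[[id]]
    ref <- panel[[sc$reference_id]]
    tr <- tryCatch(transfer_annotations(sc, ref), error = function(e) NULL)
    if (is.null(tr)) next
    annotations[[id]] <- tr$genome
    val <- validate_orfs(tr$genome)  # NULL when no CDS survived transfer
    if (!is.null(val) && nrow(val))
      orf_reports <- rbind(orf_reports, cbind(scaffold = id, val))
    rc <- tryCatch(detect_rearrangements(tr$genome, ref),
                   error = function(e) NULL)
    if (!is.null(rc) && nrow(rc))
      rearrangements <- rbind(rearrangements, cbind(scaffold = id, rc))
    write_gff3(tr$genome, file.path(out, paste0(id, ".gff3")))
  }

  distances <- NULL
  if (!is.null(config$partition)) {
    logf("stage distances")
    part <- if (is.character(config$partition))
      read_rank_partition(config$partition) else config$partition
    mats <- build_matrices(c(panel, annotations))
    per_gene <- lapply(mats$genes, pdistance_matrix)
    per_gene$concat <- pdistance_matrix(mats$CDS_aa)
    distances <- rank_mean_distances(per_gene, part)
    write.table(distances, file.path(out, "rank_distances.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  recovery <- NULL
  if (!is.null(truth) && length(scaffolds)) {
    recovery <- evaluate_recovery(scaffolds, truth$prey)
    write.table(recovery, file.path(out, "recovery.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  report <- list(
    parameters = unclass(config),
    n_pairs_in = n_pairs(reads),
    n_pairs_trimmed = n_pairs(trimmed),
    n_pairs_baited = n_pairs(baited),
    bait_metrics = as.list(metrics),
    n_contigs = nrow(contigs),
    scaffolds = lapply(scaffolds, function(s) list(
      id = s$id, reference = s$reference_id, length = nchar(s$seq),
      completeness = s$completeness, gaps = nrow(s$gaps),
      conflicts = nrow(s$conflicts))),
    backmap = if (!is.null(qc)) split(qc, seq_len(nrow(qc))) else NULL,
    rearrangements = rearrangements,
    recovery = recovery
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  logf("run finished")
  structure(list(report = report, scaffolds = scaffolds,
                 annotations = annotations, contigs = contigs, qc = qc,
                 recovery = recovery, rearrangements = rearrangements,
                 orf_validation = orf_reports, distances = distances,
                 truth = truth, panel = panel),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  pairs in/trimmed/baited: %d/%d/%d\n",
              x$report$n_pairs_in, x$report$n_pairs_trimmed,
              x$report$n_pairs_baited))
  for (s in x$report$scaffolds)
    cat(sprintf("  %s (ref %s): %d bp, completeness %.1f%%, %d gaps\n",
                s$id, s$reference, s$length, s$completeness, s$gaps))
  invisible(x)
}
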