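#' Run the full synthetic-scenario pipeline
#'
#' Executes every stage on a generated scenario and writes all inputs,
#' intermediates and results as plain-text tables under `outdir`:
#' scenario generation, viral identification, vOTU dereplication, TPM and
#' alpha diversity, peak typology and ordination, virus-host linkage, and
#' the gene-sharing / co-occurrence networks. A manifest (seed, per-stage
#' record counts, output file hashes) is written as `manifest.json`; the
#' same config and seed reproduce byte-identical tabular outputs.
#'
#' @param config a [scenario_config()].
#' @param outdir output directory (created if needed).
#' @param stages character vector of stages to run, a subset of
#'   `c("hosts", "networks")` may be dropped; the core chain
#'   (simulate, identify, cluster, abundance, dynamics) always runs.
#' @param n_contigs,n_hosts scenario sizes passed to the generators.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("hosts", "networks"),
                         n_contigs = 40L, n_hosts = 20L) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts_of <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # -- simulate -------------------------------------------------------------
  cs <- stage("simulate", generate_contig_set(config, n_contigs = n_contigs))
  ts <- stage("simulate", generate_tool_scores(cs$contigs,
                                               seed = config$seed + 2L))
  Biostrings::writeXStringSet(cs$contigs, file.path(outdir, "contigs.fasta"))
  write_tsv(ts$scores, file.path(outdir, "scores.tsv"))
  counts_of$simulate <- length(cs$contigs)

  # -- identify -------------------------------------------------------------
  calls <- stage("identify", classify_contigs(ts$scores))
  write_tsv(calls[, c("contig_id", "call", "criteria_fired")],
            file.path(outdir, "calls.tsv"))
  viral_ids <- calls$contig_id[calls$call == "viral"]
  counts_of$identify <- length(viral_ids)

  # -- cluster --------------------------------------------------------------
  viral <- cs$contigs[viral_ids]
  votus <- stage("cluster", cluster_votus(viral))
  write_tsv(votus, file.path(outdir, "votus.tsv"))
  reps <- votus[votus$is_representative, ]
  rep_seqs <- viral[reps$contig_id]
  names(rep_seqs) <- reps$votu_id
  Biostrings::writeXStringSet(rep_seqs, file.path(outdir, "votu_reps.fasta"))
  counts_of$cluster <- nrow(reps)

  # -- abundance ------------------------------------------------------------
  abcfg <- config
  abcfg$n_votus <- nrow(reps)
  rep_lens <- setNames(nchar(as.character(rep_seqs)), names(rep_seqs))
  ab_gen <- stage("abundance",
                  generate_abundance(abcfg, lengths = rep_lens,
                                     votu_ids = names(rep_seqs)))
  .write_matrix_tsv(ab_gen$counts, file.path(outdir, "counts.tsv"), "votu_id")
  write_tsv(ab_gen$samples, file.path(outdir, "samples.tsv"))
  ab <- stage("abundance", tpm(ab_gen$counts, ab_gen$lengths))
  .write_matrix_tsv(round(ab, 4), file.path(outdir, "tpm.tsv"), "votu_id")
  div <- stage("abundance", diversity_table(ab))
  write_tsv(div, file.path(outdir, "diversity.tsv"))
  counts_of$abundance <- ncol(ab)

  # -- dynamics -------------------------------------------------------------
  env <- stage("dynamics", generate_env_table(config))
  write_tsv(env, file.path(outdir, "env.tsv"))
  peaks <- stage("dynamics", peak_classes(ab, ab_gen$samples))
  write_tsv(peaks, file.path(outdir, "peaks.tsv"))
  comp <- stage("dynamics", class_composition(peaks))
  write_tsv(comp, file.path(outdir, "composition.tsv"))
  pca <- stage("dynamics", pca_ordination(ab))
  envmat <- env[match(colnames(ab), env$sample),
                setdiff(names(env), c("sample", "station", "julian_day"))]
  cca <- stage("dynamics", cca_ordination(ab, envmat))
  ord <- list(pca = list(eig = pca$eig, proportion = pca$proportion),
              cca = list(eig = cca$eig, proportion = cca$proportion,
                         total_inertia = cca$total_inertia))
  jsonlite::write_json(ord, file.path(outdir, "ordination.json"),
                       auto_unbox = TRUE, digits = 10)
  counts_of$dynamics <- nrow(peaks)
  truth <- list(votu_peak_class = as.list(ab_gen$truth$votu_peak_class),
                peak_days = ab_gen$truth$peak_days,
                contig_pairs = cs$pair_truth,
                viral_contigs = ts$truth)

  # -- hosts ----------------------------------------------------------------
  if ("hosts" %in% stages) {
    n_eligible <- sum(rep_lens >= 5000) # link plan scales with the scenario
    n_broad <- min(2L, max(0L, n_eligible - 3L))
    lpc <- max(1L, min(4L, (n_eligible - n_broad) %/% 3L))
    ha <- stage("hosts", generate_host_artifacts(rep_seqs, config,
                                                 n_hosts = n_hosts,
                                                 links_per_channel = lpc,
                                                 n_broad = n_broad))
    write_tsv(ha$hits, file.path(outdir, "hits.tsv"))
    write_tsv(ha$spacers, file.path(outdir, "spacers.tsv"))
    write_tsv(ha$taxonomy, file.path(outdir, "host_taxonomy.tsv"))
    ev <- stage("hosts", rbind(
      filter_homology(ha$hits, rep_lens)[, c("votu_id", "host_id", "channel")],
      match_trna(ha$viral_trnas, ha$host_trnas)[,
        c("votu_id", "host_id", "channel")],
      spacer_evidence(ha$spacers, rep_seqs)))
    li <- stage("hosts", integrate_links(ev, ha$taxonomy, ab = ab))
    write_tsv(li$links, file.path(outdir, "links.tsv"))
    if (!is.null(li$class_abundance))
      .write_matrix_tsv(round(li$class_abundance, 4),
                        file.path(outdir, "host_class_abundance.tsv"),
                        "host_class")
    counts_of$hosts <- nrow(li$links)
    truth$host_links <- ha$truth_links
  }

  # -- networks -------------------------------------------------------------
  if ("networks" %in% stages) {
    big <- names(rep_lens)[rep_lens >= 10000]
    if (length(big) >= 3L) {
      pcm <- stage("networks",
                   generate_pc_membership(big, seed = config$seed + 5L))
      gsn <- stage("networks",
                   build_gene_share_network(pcm$membership,
                                            genome_lengths = rep_lens))
      write_tsv(gsn$edges, file.path(outdir, "gene_share_edges.tsv"))
      write_tsv(gsn$vcs, file.path(outdir, "vcs.tsv"))
      vc_ab <- rowsum(ab[gsn$vcs$genome_id, , drop = FALSE], gsn$vcs$vc_id)
      host_ab <- .synthetic_host_otus(vc_ab, seed = config$seed + 6L)
      corr <- stage("networks", correlation_network(vc_ab, host_ab))
      write_tsv(corr, file.path(outdir, "corr_edges.tsv"))
      counts_of$networks <- nrow(gsn$edges)
      truth$pc_blocks <- pcm$blocks
    } else {
      counts_of$networks <- 0L
    }
  }

  jsonlite::write_json(
    lapply(truth, function(x) if (is.data.frame(x)) x else as.list(x)),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = 10)

  files <- sort(list.files(outdir, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(package = "virotide",
                   version = as.character(utils::packageVersion("virotide")),
                   seed = config$seed,
                   stages = counts_of,
                   hashes = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# host OTU series for the co-occurrence stage: a few OTUs are exact linear
# functions (one with a sign flip) of VC trajectories, the rest are noise
.synthetic_host_otus <- function(vc_ab, seed, n_noise = 5L) {
  set.seed(seed)
  k <- nrow(vc_ab)
  linked <- head(seq_len(k), 2L)
  rows <- list()
  for (i in seq_along(linked)) {
    sgn <- if (i %% 2L == 0L) -1 else 1
    rows[[paste0("hostOTU_L", i)]] <-
      sgn * 2 * vc_ab[linked[i], ] + (if (sgn < 0) 3 * max(vc_ab) else 10)
  }
  for (j in seq_len(n_noise)) {
    rows[[paste0("hostOTU_N", j)]] <-
      rlnorm(ncol(vc_ab), meanlog = 5, sdlog = 1)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- colnames(vc_ab)
  m
}
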