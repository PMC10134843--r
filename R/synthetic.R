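#' Scenario configuration for the synthetic bloom virome
#'
#' Describes the simulated study design: three coastal stations sampled on
#' six Julian days spanning the arrival and demise of a macroalgal bloom,
#' with one library missing (17 of 18), vOTU temporal trajectories planted
#' by peak class, and multiplicative lognormal noise ahead of multinomial
#' read sampling.
#'
#' The peak-class mixture excludes `flat`: under compositional closure a
#' constant-count vOTU still inherits the day-to-day variation of the
#' denominator, so a flat relative-abundance trajectory cannot be planted.
#'
#' @param n_votus number of vOTUs to simulate.
#' @param stations station labels.
#' @param julian_days the six sampled Julian days; the peak typology is
#'   defined on exactly these days.
#' @param peak_class_mixture named probability vector over planted classes
#'   (must sum to 1; names among single1..4, wide1..3, several).
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal noise applied to true compositions before read sampling.
#' @param read_depth reads drawn per sample (multinomial size).
#' @param missing_sample `list(station =, julian_day =)` identifying the
#'   library that is absent, or `NULL` for a complete design. One of the 18
#'   station-day combinations is omitted by default to mirror a 17-library
#'   time series.
#' @param bump_fold planted peak amplitude: a peak day starts at
#'   `(1 + bump_fold)` times the vOTU's baseline (individual vOTUs are
#'   boosted further if compositional closure would blur their pattern).
#' @param baseline_sdlog lognormal sd of per-vOTU baseline abundances.
#' @param seed integer seed; fully determines every generated artifact.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_votus = 300L,
                            stations = c("ZQ", "MS", "XG"),
                            julian_days = c(165L, 181L, 193L, 208L, 243L, 271L),
                            peak_class_mixture = c(
                              single1 = 0.10, single2 = 0.10, single3 = 0.22,
                              single4 = 0.05, wide1 = 0.16, wide2 = 0.15,
                              wide3 = 0.12, several = 0.10),
                            noise_cv = 0.2,
                            read_depth = 1e5,
                            missing_sample = list(station = "XG",
                                                  julian_day = 243L),
                            bump_fold = 3,
                            baseline_sdlog = 0.5,
                            seed = 1L) {
  if (n_votus < 1L) stop("n_votus must be positive")
  if (is.unsorted(julian_days, strictly = TRUE))
    stop("julian_days must be strictly increasing")
  if (!identical(as.integer(julian_days),
                 c(165L, 181L, 193L, 208L, 243L, 271L)))
    stop("the peak typology is defined on Julian days 165, 181, 193, 208, ",
         "243, 271; other designs are not supported")
  if (abs(sum(peak_class_mixture) - 1) > 1e-8)
    stop("peak_class_mixture must sum to 1")
  bad <- setdiff(names(peak_class_mixture),
                 c(paste0("single", 1:4), paste0("wide", 1:3), "several"))
  if (length(bad))
    stop("unknown or unplantable peak class(es): ", paste(bad, collapse = ", "))
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  if (read_depth <= 0) stop("read_depth must be positive")
  structure(list(n_votus = as.integer(n_votus), stations = stations,
                 julian_days = as.integer(julian_days),
                 peak_class_mixture = peak_class_mixture,
                 noise_cv = noise_cv, read_depth = read_depth,
                 missing_sample = missing_sample, bump_fold = bump_fold,
                 baseline_sdlog = baseline_sdlog, seed = as.integer(seed)),
            class = "scenario_config")
}

# menu of plantable above-mean day sets per class
.class_menus <- list(
  single1 = list(165L, 181L),
  single2 = list(193L, 208L),
  single3 = list(243L, 271L),
  single4 = list(c(165L, 271L)),
  wide1 = list(c(165L, 181L), c(181L, 193L), c(165L, 181L, 193L),
               c(181L, 193L, 208L)),
  wide2 = list(c(193L, 208L), c(208L, 243L), c(193L, 208L, 243L),
               c(208L, 243L, 271L)),
  wide3 = list(c(243L, 271L)),
  several = list(c(165L, 208L, 271L), c(165L, 193L, 243L),
                 c(181L, 208L, 271L), c(165L, 181L, 243L, 271L))
)

#' Sample table of the scenario design
#'
#' @param config a [scenario_config()].
#' @return data.frame `sample`, `station`, `julian_day` (the missing
#'   library already removed).
#' @export
scenario_samples <- function(config) {
  grid <- expand.grid(station = config$stations,
                      julian_day = config$julian_days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ms <- config$missing_sample
  if (!is.null(ms)) {
    drop <- grid$station == ms$station & grid$julian_day == ms$julian_day
    grid <- grid[!drop, , drop = FALSE]
  }
  grid <- grid[order(grid$station, grid$julian_day), ]
  data.frame(sample = paste0(grid$station, "_", grid$julian_day),
             station = grid$station, julian_day = grid$julian_day,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a vOTU count matrix with planted peak classes
#'
#' Draws, for each vOTU, a peak class from the configured mixture and a
#' matching above-mean day set; builds true relative abundances (at the
#' length-normalized, TPM scale) as a baseline plus a `bump_fold`-times
#' bump on the peak days; then renormalizes per day. Because compositional
#' closure can shift a vOTU's own mean, planted amplitudes are boosted
#' iteratively until, noise-free, every vOTU's strictly-above-mean day set
#' equals its class definition exactly. Counts are finally drawn per sample
#' by multinomial sampling of `read_depth` reads with probabilities
#' proportional to composition times vOTU length (so that TPM computed
#' from the counts estimates the true composition).
#'
#' @param config a [scenario_config()].
#' @param lengths optional named vOTU lengths (bp); drawn uniformly in
#'   3-15 kb when omitted.
#' @param votu_ids optional vOTU ids (default `"vOTU_0001"`...).
#' @return A list: `counts` (vOTU x sample integer matrix), `lengths`,
#'   `samples` (design table), `truth` (list with `votu_peak_class`,
#'   `peak_days` per vOTU, and `true_tpm`, the noise-free vOTU x day
#'   TPM matrix).
#' @export
generate_abundance <- function(config, lengths = NULL, votu_ids = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_votus
  days <- config$julian_days
  if (is.null(votu_ids)) votu_ids <- sprintf("vOTU_%04d", seq_len(n))
  stopifnot(length(votu_ids) == n)
  if (is.null(lengths)) {
    lengths <- setNames(round(runif(n, 3000, 15000)), votu_ids)
  } else {
    lengths <- lengths[votu_ids]
    if (anyNA(lengths)) stop("lengths must cover all votu_ids")
  }
  mix <- config$peak_class_mixture
  classes <- sample(names(mix), n, replace = TRUE, prob = mix)
  peak_days <- lapply(classes, function(cl) {
    menu <- .class_menus[[cl]]
    menu[[sample.int(length(menu), 1L)]]
  })
  baseline <- rlnorm(n, meanlog = 0, sdlog = config$baseline_sdlog)
  amp <- rep(config$bump_fold, n)
  in_peak <- vapply(peak_days, function(d) days %in% d, logical(length(days)))
  in_peak <- t(in_peak) # vOTU x day
  for (iter in 1:25) {
    v <- baseline * (1 + amp * in_peak)
    true_tpm <- sweep(v, 2L, colSums(v), "/") * 1e6
    ok <- vapply(seq_len(n), function(i) {
      am <- true_tpm[i, ] > mean(true_tpm[i, ])
      identical(which(am), which(in_peak[i, ]))
    }, logical(1))
    if (all(ok)) break
    amp[!ok] <- amp[!ok] * 1.5
  }
  if (!all(ok)) {
    # In very small communities compositional closure can make a few
    # intended patterns mutually unplantable. The truth must describe the
    # generated data, so relabel those vOTUs with the class their realized
    # noise-free trajectory actually has.
    for (i in which(!ok)) {
      am <- true_tpm[i, ] > mean(true_tpm[i, ])
      peak_days[[i]] <- days[am]
      classes[i] <- classify_peak(list(days = days, above_mean = am))
    }
  }
  dimnames(true_tpm) <- list(votu_ids, as.character(days))

  samples <- scenario_samples(config)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(votu_ids, samples$sample))
  for (s in seq_len(nrow(samples))) {
    comp <- true_tpm[, as.character(samples$julian_day[s])]
    if (sdlog > 0) comp <- comp * rlnorm(n, 0, sdlog)
    pr <- comp * lengths # reads scale with length at fixed molar abundance
    counts[, s] <- rmultinom(1L, size = config$read_depth, prob = pr)[, 1L]
  }
  list(counts = counts, lengths = lengths, samples = samples,
       truth = list(votu_peak_class = setNames(classes, votu_ids),
                    peak_days = setNames(peak_days, votu_ids),
                    true_tpm = true_tpm))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute a fixed number of positions with a different base
.mutate_subs <- function(seq, n_subs) {
  if (n_subs == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), n_subs)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate contigs with planted identity/coverage pair structure
#'
#' Emits random ACGT contigs (uppercase, no ambiguity codes) in the given
#' length range, including parent-child pairs planted at controlled
#' nucleotide identity (substitutions only) and controlled overlap of the
#' shorter member (the remainder of a partial child is random sequence).
#' Children are reverse-complemented with probability 1/2 so dereplication
#' must consider both strands. The truth table records, for each planted
#' pair, whether the 95% identity / 80% coverage rule should co-cluster it.
#'
#' @param config a [scenario_config()] (its seed, offset by 1, drives this
#'   generator).
#' @param n_contigs total number of contigs (planted pairs included).
#' @param length_range contig length range in bp.
#' @param pair_plan data.frame with columns `identity` and `coverage`
#'   describing the planted pairs; the default covers 90/94/96/99%
#'   identity at full overlap plus 96% and 99% identity at 50% and 85%
#'   overlap.
#' @return A list: `contigs` (named `DNAStringSet`), `pair_truth`
#'   (data.frame `id_a`, `id_b`, `identity`, `coverage`, `same_cluster`).
#' @export
generate_contig_set <- function(config, n_contigs = 40L,
                                length_range = c(3000L, 15000L),
                                pair_plan = data.frame(
                                  identity = c(0.90, 0.94, 0.96, 0.99,
                                               0.96, 0.96, 0.99, 0.99),
                                  coverage = c(1, 1, 1, 1,
                                               0.50, 0.85, 0.50, 0.85))) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 1L)
  n_pairs <- nrow(pair_plan)
  if (n_contigs < 2L * n_pairs)
    stop("n_contigs too small for the pair plan")
  seqs <- character(0)
  truth <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    id <- pair_plan$identity[p]
    cov <- pair_plan$coverage[p]
    lp <- round(runif(1, mean(length_range), length_range[2L]))
    lc <- round(runif(1, length_range[1L], lp * 0.9))
    parent <- .random_dna(lp)
    core_len <- round(cov * lc)
    start <- sample.int(lp - core_len + 1L, 1L)
    core <- substr(parent, start, start + core_len - 1L)
    core <- .mutate_subs(core, round((1 - id) * core_len))
    child <- paste0(core, .random_dna(lc - core_len))
    if (runif(1) < 0.5)
      child <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(child)))
    ia <- sprintf("contig_p%02da", p)
    ib <- sprintf("contig_p%02db", p)
    seqs[ia] <- parent
    seqs[ib] <- child
    truth[[p]] <- data.frame(id_a = ia, id_b = ib, identity = id,
                             coverage = cov,
                             same_cluster = id >= 0.95 && cov >= 0.80,
                             stringsAsFactors = FALSE)
  }
  n_single <- n_contigs - 2L * n_pairs
  for (s in seq_len(n_single)) {
    seqs[sprintf("contig_s%03d", s)] <-
      .random_dna(round(runif(1, length_range[1L], length_range[2L])))
  }
  list(contigs = Biostrings::DNAStringSet(seqs),
       pair_truth = do.call(rbind, truth))
}

#' Generate per-contig tool-score tables with planted viral calls
#'
#' Assigns each contig a VirFinder-like score and p-value, a VirSorter-like
#' category and a CAT-like taxon call so that the four-way identification
#' rule recovers the planted viral flag exactly: each planted viral contig
#' satisfies at least one criterion (drawn uniformly over i-iv), each
#' planted nonviral contig satisfies none.
#'
#' @param contigs named `DNAStringSet` (or character vector).
#' @param truth_fraction_viral probability a contig is planted viral.
#' @param seed integer seed.
#' @return A list: `scores` (data.frame ready for [classify_contigs()]),
#'   `truth` (data.frame `contig_id`, `is_viral`, `planted_criterion`).
#' @export
generate_tool_scores <- function(contigs, truth_fraction_viral = 0.7,
                                 seed = 1L) {
  if (length(contigs) == 0L) stop("contigs must be nonempty")
  set.seed(seed)
  ids <- names(contigs)
  lens <- nchar(as.character(contigs))
  n <- length(ids)
  viral <- runif(n) < truth_fraction_viral
  crit <- ifelse(viral, sample(c("i", "ii", "iii", "iv"), n, replace = TRUE),
                 "none")
  vf <- numeric(n); p <- numeric(n)
  vs <- rep(NA_integer_, n); cat_call <- rep("other", n)
  for (j in seq_len(n)) {
    switch(crit[j],
      i = { vf[j] <- runif(1, 0.90, 1); p[j] <- runif(1, 0.001, 0.049) },
      ii = { vf[j] <- runif(1, 0, 0.65); p[j] <- runif(1, 0.05, 0.9)
             vs[j] <- sample(c(1L, 2L, 4L, 5L), 1L) },
      iii = { vf[j] <- runif(1, 0.70, 0.89); p[j] <- runif(1, 0.001, 0.049)
              vs[j] <- sample(c(3L, 6L), 1L) },
      iv = { vf[j] <- runif(1, 0, 0.65); p[j] <- runif(1, 0.05, 0.9)
             cat_call[j] <- "virus" },
      none = { vf[j] <- runif(1, 0, 0.65); p[j] <- runif(1, 0.05, 0.9)
               vs[j] <- sample(c(NA, 3L, 6L), 1L) })
  }
  list(scores = data.frame(contig_id = ids, length_bp = lens, vf_score = vf,
                           vf_p = p, vs_category = vs, cat_call = cat_call,
                           stringsAsFactors = FALSE),
       truth = data.frame(contig_id = ids, is_viral = viral,
                          planted_criterion = crit,
                          stringsAsFactors = FALSE))
}

# host classes used for planted taxonomy; weights loosely follow the
# class spectrum of coastal virus-host predictions
.host_class_pool <- c(Gammaproteobacteria = 0.30, Alphaproteobacteria = 0.15,
                      Bacteroidia = 0.12, Cyanobacteriia = 0.10,
                      Planctomycetia = 0.10, Verrucomicrobiae = 0.08,
                      Bacilli = 0.08, Actinomycetia = 0.07)

#' Generate host genomes and virus-host evidence with planted links
#'
#' For each planted virus-host pair, embeds exactly one detectable signal
#' in the generated artifacts: a passing homology hit (with a matching
#' segment copied into the host genome), a shared tRNA (identical copy in
#' the viral and host tRNA sets), or a CRISPR spacer copied verbatim or
#' with one substitution from the viral contig. Decoys that must NOT link
#' are planted alongside: homology hits that each fail one threshold,
#' tRNA pairs at 85% identity, and spacers carrying two substitutions.
#'
#' @param contigs named `DNAStringSet` of viral contigs/vOTU
#'   representatives; only members >= 5 kb are eligible for links.
#' @param config a [scenario_config()] (seed offset 3).
#' @param n_hosts number of host genomes.
#' @param links_per_channel planted links per evidence channel.
#' @param n_broad vOTUs additionally linked to a second host in a
#'   different class (making their planted host range broad).
#' @return A list: `host_genomes` (`DNAStringSet`), `taxonomy`
#'   (`host_id`, `host_class`), `hits`, `spacers` (`host_id`, `spacer_id`,
#'   `sequence`, with decoys flagged), `viral_trnas`, `host_trnas`
#'   (named character vectors), `truth_links` (`votu_id`, `host_id`,
#'   `channel`, `host_class`).
#' @export
generate_host_artifacts <- function(contigs, config, n_hosts = 20L,
                                    links_per_channel = 4L, n_broad = 2L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 3L)
  seqs <- setNames(as.character(contigs), names(contigs))
  eligible <- names(seqs)[nchar(seqs) >= 5000L]
  n_links <- 3L * links_per_channel + n_broad
  if (length(eligible) < n_links)
    stop("not enough contigs >= 5 kb for the requested links")
  host_ids <- sprintf("host_%02d", seq_len(n_hosts))
  taxonomy <- data.frame(
    host_id = host_ids,
    host_class = sample(names(.host_class_pool), n_hosts, replace = TRUE,
                        prob = .host_class_pool),
    stringsAsFactors = FALSE)
  genomes <- setNames(vapply(host_ids, function(h) .random_dna(20000L),
                             character(1)), host_ids)

  link_votus <- sample(eligible, n_links)
  link_hosts <- sample(host_ids, n_links, replace = TRUE)
  channel <- c(rep(c("homology", "trna", "crispr"), each = links_per_channel),
               sample(c("trna", "crispr"), n_broad, replace = TRUE))
  # broad vOTUs: reuse the first n_broad link vOTUs with a host from a
  # different class than their first link
  if (n_broad > 0L) {
    for (b in seq_len(n_broad)) {
      i <- 3L * links_per_channel + b
      link_votus[i] <- link_votus[b]
      first_class <- taxonomy$host_class[taxonomy$host_id == link_hosts[b]]
      other <- taxonomy$host_id[taxonomy$host_class != first_class]
      link_hosts[i] <- sample(other, 1L)
    }
  }

  hits <- list(); spacers <- list()
  viral_trnas <- character(0); host_trnas <- character(0)
  for (i in seq_len(n_links)) {
    v <- link_votus[i]; h <- link_hosts[i]
    if (channel[i] == "homology") {
      seg_len <- 2000L
      vstart <- sample.int(nchar(seqs[[v]]) - seg_len + 1L, 1L)
      seg <- .mutate_subs(substr(seqs[[v]], vstart, vstart + seg_len - 1L),
                          round(0.2 * seg_len))
      hstart <- sample.int(nchar(genomes[[h]]) - seg_len + 1L, 1L)
      substr(genomes[[h]], hstart, hstart + seg_len - 1L) <- seg
      hits[[length(hits) + 1L]] <- data.frame(
        votu_id = v, host_id = h,
        query_coverage = runif(1, 76, 95), identity = runif(1, 72, 90),
        bit_score = runif(1, 100, 800), e_value = 10^-runif(1, 6, 30),
        stringsAsFactors = FALSE)
    } else if (channel[i] == "trna") {
      trna <- .random_dna(72L)
      viral_trnas[paste0(v, "|trna", i)] <- trna
      host_trnas[paste0(h, "|trna", i)] <- trna
    } else { # crispr
      sp_len <- 32L
      at <- sample.int(nchar(seqs[[v]]) - sp_len + 1L, 1L)
      sp <- substr(seqs[[v]], at, at + sp_len - 1L)
      sp <- .mutate_subs(sp, sample(0:1, 1L)) # verbatim or one substitution
      spacers[[length(spacers) + 1L]] <- data.frame(
        host_id = h, spacer_id = sprintf("spacer_%02d", i), sequence = sp,
        decoy = FALSE, stringsAsFactors = FALSE)
    }
  }

  # decoys: must not produce any link
  decoy_votus <- sample(eligible, 3L)
  decoy_hosts <- sample(host_ids, 3L, replace = TRUE)
  hits[[length(hits) + 1L]] <- data.frame( # fails the coverage clause
    votu_id = decoy_votus[1L], host_id = decoy_hosts[1L],
    query_coverage = runif(1, 30, 74.5), identity = runif(1, 80, 99),
    bit_score = runif(1, 100, 500), e_value = 10^-runif(1, 6, 30),
    stringsAsFactors = FALSE)
  hits[[length(hits) + 1L]] <- data.frame( # fails the identity clause
    votu_id = decoy_votus[2L], host_id = decoy_hosts[2L],
    query_coverage = runif(1, 80, 95), identity = runif(1, 40, 69.5),
    bit_score = runif(1, 100, 500), e_value = 10^-runif(1, 6, 30),
    stringsAsFactors = FALSE)
  dtr <- .random_dna(72L) # tRNA pair at ~85% identity: below threshold
  viral_trnas[paste0(decoy_votus[3L], "|trnaD")] <- dtr
  host_trnas[paste0(decoy_hosts[3L], "|trnaD")] <- .mutate_subs(dtr, 11L)
  for (d in 1:2) { # spacers with two substitutions
    v <- sample(eligible, 1L)
    at <- sample.int(nchar(seqs[[v]]) - 32L + 1L, 1L)
    spacers[[length(spacers) + 1L]] <- data.frame(
      host_id = sample(host_ids, 1L),
      spacer_id = sprintf("decoy_%02d", d),
      sequence = .mutate_subs(substr(seqs[[v]], at, at + 31L), 2L),
      decoy = TRUE, stringsAsFactors = FALSE)
  }
  # background tRNAs unrelated to any link
  for (b in 1:4) {
    viral_trnas[paste0(sample(eligible, 1L), "|trnaB", b)] <- .random_dna(72L)
    host_trnas[paste0(sample(host_ids, 1L), "|trnaB", b)] <- .random_dna(72L)
  }

  truth <- data.frame(votu_id = link_votus, host_id = link_hosts,
                      channel = channel, stringsAsFactors = FALSE)
  truth$host_class <-
    taxonomy$host_class[match(truth$host_id, taxonomy$host_id)]
  list(host_genomes = Biostrings::DNAStringSet(genomes),
       taxonomy = taxonomy,
       hits = do.call(rbind, hits),
       spacers = do.call(rbind, spacers),
       viral_trnas = viral_trnas, host_trnas = host_trnas,
       truth_links = truth)
}

# noise-free seasonal shapes over days 165..271: nutrients peak at day 208,
# nitrate rises after the bloom, chlorophyll a is higher post-bloom with a
# minimum on day 193
.env_base <- function() {
  rbind(temperature = c(18, 21, 23, 25, 24, 22),
        salinity = c(30.0, 30.5, 31.0, 31.5, 31.2, 30.8),
        pH = c(8.2, 8.45, 8.3, 8.15, 8.0, 7.9),
        NH4 = c(2.0, 3.0, 4.0, 8.0, 3.0, 2.2),
        NO3 = c(2.0, 2.0, 1.8, 3.0, 6.0, 9.0),
        NO2 = c(0.5, 0.8, 1.0, 2.5, 0.9, 0.6),
        SiO3 = c(4.0, 5.0, 6.0, 12.0, 5.5, 4.5),
        chl_a = c(3.0, 2.5, 1.5, 2.5, 5.0, 6.0))
}

#' Generate the environmental-variable table
#'
#' Produces temperature, salinity, pH, NH4, NO3, NO2, SiO3 and chl.a per
#' sample with bloom-shaped temporal profiles: NH4, SiO3 and NO2 maximal
#' on day 208, NO3 rising after the bloom (maximal on day 271), and chl.a
#' higher on the post-bloom days 243 and 271 than during the bloom.
#' Stations differ by a small fixed multiplicative offset; `noise_cv`
#' adds multiplicative lognormal noise (none when 0).
#'
#' @param config a [scenario_config()] (seed offset 4).
#' @return data.frame `sample`, `station`, `julian_day`, then one column
#'   per variable.
#' @export
generate_env_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 4L)
  base <- .env_base()
  colnames(base) <- as.character(config$julian_days)
  samples <- scenario_samples(config)
  offs <- setNames(seq(-0.03, 0.03,
                       length.out = length(config$stations)),
                   config$stations)
  sdlog <- if (config$noise_cv > 0)
    sqrt(log(1 + (config$noise_cv / 4)^2)) else 0
  vals <- t(vapply(seq_len(nrow(samples)), function(s) {
    x <- base[, as.character(samples$julian_day[s])] *
      exp(offs[samples$station[s]])
    if (sdlog > 0) x <- x * rlnorm(nrow(base), 0, sdlog)
    x
  }, numeric(nrow(base))))
  colnames(vals) <- rownames(base)
  cbind(samples, as.data.frame(vals))
}

#' Generate protein-cluster membership with planted block structure
#'
#' Assigns genomes to blocks; genomes in one block share that block's pool
#' of protein clusters (each genome carries a large random subset), while
#' carrying a few private singleton clusters. Gene-sharing network
#' clustering should recover the blocks as connected components.
#'
#' @param genome_ids character vector of genome ids.
#' @param n_blocks number of planted blocks.
#' @param pcs_per_block size of each block's shared PC pool.
#' @param carry_fraction fraction of the pool each member carries.
#' @param n_private private singleton PCs per genome.
#' @param seed integer seed.
#' @return A list: `membership` (named list genome -> PC ids), `blocks`
#'   (named integer vector of planted block per genome).
#' @export
generate_pc_membership <- function(genome_ids, n_blocks = 3L,
                                   pcs_per_block = 30L,
                                   carry_fraction = 0.8,
                                   n_private = 2L, seed = 1L) {
  set.seed(seed)
  if (length(genome_ids) < n_blocks)
    stop("need at least one genome per block")
  blocks <- sort(rep_len(seq_len(n_blocks), length(genome_ids)))
  names(blocks) <- genome_ids
  membership <- lapply(genome_ids, function(g) {
    b <- blocks[[g]]
    pool <- sprintf("PC_b%d_%03d", b, seq_len(pcs_per_block))
    shared <- sample(pool, round(carry_fraction * pcs_per_block))
    private <- sprintf("PC_%s_%02d", g, seq_len(n_private))
    c(shared, private)
  })
  names(membership) <- genome_ids
  list(membership = membership, blocks = blocks)
}
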