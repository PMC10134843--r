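test_that("scenario configuration validates its invariants", {
  expect_error(scenario_config(peak_class_mixture = c(single1 = 0.5)),
               "sum to 1")
  expect_error(scenario_config(julian_days = c(165, 165, 193, 208, 243, 271)),
               "strictly increasing")
  expect_error(scenario_config(read_depth = 0), "positive")
  expect_error(scenario_config(noise_cv = -1), "nonnegative")
  expect_error(scenario_config(
    peak_class_mixture = c(single1 = 0.5, flat = 0.5)), "unplantable")
  smp <- scenario_samples(scenario_config())
  expect_equal(nrow(smp), 17L) # one library missing by design
  expect_equal(nrow(scenario_samples(scenario_config(missing_sample = NULL))),
               18L)
})

test_that("planted trajectories realize their class exactly when noise-free", {
  cfg <- scenario_config(n_votus = 120, noise_cv = 0, seed = 42)
  g <- generate_abundance(cfg)
  days <- cfg$julian_days
  for (v in rownames(g$truth$true_tpm)) {
    series <- g$truth$true_tpm[v, ]
    above <- series > mean(series)
    expect_equal(sort(days[above]), sort(g$truth$peak_days[[v]]),
                 label = v)
  }
  # a single3 vOTU is above its own mean only on day 243 or 271
  s3 <- names(g$truth$votu_peak_class)[g$truth$votu_peak_class == "single3"]
  for (v in s3) expect_true(all(g$truth$peak_days[[v]] %in% c(243, 271)))
})

test_that("counts are a multinomial draw that converges on the truth", {
  cfg <- scenario_config(n_votus = 50, noise_cv = 0, read_depth = 1e6,
                         missing_sample = NULL, seed = 13)
  g <- generate_abundance(cfg)
  expect_true(all(g$counts >= 0))
  expect_true(all(colSums(g$counts) == cfg$read_depth))
  # empirical read fractions within 3 binomial SE of the true fractions
  for (s in colnames(g$counts)[c(1, 9, 18)]) {
    day <- as.character(g$samples$julian_day[g$samples$sample == s])
    pr <- g$truth$true_tpm[, day] * g$lengths
    pr <- pr / sum(pr)
    phat <- g$counts[, s] / cfg$read_depth
    se <- sqrt(pr * (1 - pr) / cfg$read_depth)
    expect_gt(mean(abs(phat - pr) <= 3 * se + 1e-12), 0.99)
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- scenario_config(n_votus = 40, seed = 77)
  g1 <- generate_abundance(cfg)
  g2 <- generate_abundance(cfg)
  expect_identical(g1$counts, g2$counts)
  expect_identical(g1$truth$votu_peak_class, g2$truth$votu_peak_class)
  expect_identical(generate_env_table(cfg), generate_env_table(cfg))
  cs1 <- generate_contig_set(cfg, n_contigs = 18)
  cs2 <- generate_contig_set(cfg, n_contigs = 18)
  expect_identical(as.character(cs1$contigs), as.character(cs2$contigs))
  ts1 <- generate_tool_scores(cs1$contigs, seed = 5)
  ts2 <- generate_tool_scores(cs2$contigs, seed = 5)
  expect_identical(ts1$scores, ts2$scores)
})

test_that("planted contig pairs encode the dereplication boundary", {
  cfg <- scenario_config(seed = 19)
  cs <- generate_contig_set(cfg, n_contigs = 16)
  tr <- cs$pair_truth
  expect_true(all(tr$same_cluster == (tr$identity >= 0.95 &
                                        tr$coverage >= 0.80)))
  expect_true(any(tr$identity == 0.96 & tr$coverage == 1 & tr$same_cluster))
  expect_true(any(tr$identity == 0.96 & tr$coverage == 0.5 &
                    !tr$same_cluster))
  expect_true(any(tr$identity == 0.90 & !tr$same_cluster))
  seqs <- as.character(cs$contigs)
  expect_true(all(nchar(seqs) >= 3000 & nchar(seqs) <= 15000))
  expect_false(any(grepl("[^ACGT]", seqs)))
})

test_that("planted tool scores are recovered exactly by the decision rule", {
  cfg <- scenario_config(seed = 29)
  cs <- generate_contig_set(cfg, n_contigs = 30)
  ts <- generate_tool_scores(cs$contigs, truth_fraction_viral = 0.6,
                             seed = 30)
  calls <- classify_contigs(ts$scores)
  expect_identical(calls$call == "viral", ts$truth$is_viral)
})

test_that("environmental series reproduce the bloom shapes when noise-free", {
  cfg <- scenario_config(noise_cv = 0, seed = 3)
  env <- generate_env_table(cfg)
  for (st in cfg$stations) {
    e <- env[env$station == st, ]
    e <- e[order(e$julian_day), ]
    expect_equal(e$julian_day[which.max(e$NH4)], 208)
    expect_equal(e$julian_day[which.max(e$SiO3)], 208)
    expect_equal(e$julian_day[which.max(e$NO2)], 208)
    expect_equal(e$julian_day[which.max(e$NO3)], 271)
    post <- e$julian_day >= 243
    expect_gt(mean(e$chl_a[post]), mean(e$chl_a[!post]))
  }
})

test_that("TPM from deep counts recovers planted compositions", {
  cfg <- scenario_config(n_votus = 100, noise_cv = 0, read_depth = 1e6,
                         missing_sample = NULL, seed = 55)
  g <- generate_abundance(cfg)
  ab <- tpm(g$counts, g$lengths)
  ok <- 0L
  tot <- 0L
  for (s in colnames(ab)) {
    day <- as.character(g$samples$julian_day[g$samples$sample == s])
    truth <- g$truth$true_tpm[, day]
    pr <- truth * g$lengths / sum(truth * g$lengths)
    se_tpm <- 3 * sqrt(pr * (1 - pr) / cfg$read_depth) / (pr / truth)
    ok <- ok + sum(abs(ab[, s] - truth) <= se_tpm + 1e-9)
    tot <- tot + nrow(ab)
  }
  expect_gt(ok / tot, 0.99)
})
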