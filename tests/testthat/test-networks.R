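test_that("hypergeometric similarity matches enumeration on the worked case", {
  h <- hypergeom_score(c("a", "b", "c"), c("a", "b", "d", "e"),
                       N = 10, n_comparisons = 1)
  expect_equal(h$k, 2L)
  expect_equal(h$p_hyper, 1 / 3, tolerance = 1e-12)
  expect_equal(h$p_hyper, hyper_tail_oracle(2, 3, 4, 10), tolerance = 1e-12)
  # disjoint sets carry no signal
  d <- hypergeom_score(c("a", "b"), c("c", "d"), N = 10, n_comparisons = 45)
  expect_equal(d$p_hyper, 1)
  expect_equal(d$score, 0)
  expect_error(hypergeom_score(letters[1:5], letters[1:3], N = 4,
                               n_comparisons = 1), "universe")
})

test_that("hypergeometric tail equals enumeration on random configurations", {
  set.seed(31)
  for (i in 1:200) {
    N <- sample(2:30, 1)
    Ka <- sample(N, 1)
    Kb <- sample(N, 1)
    kmin <- max(0L, Ka + Kb - N)
    kmax <- min(Ka, Kb)
    k <- if (kmin == kmax) kmin else sample(seq(kmin, kmax), 1)
    set_a <- seq_len(Ka)
    set_b <- c(seq_len(k), Ka + seq_len(Kb - k))
    h <- hypergeom_score(as.character(set_a), as.character(set_b), N,
                         n_comparisons = 1)
    expect_equal(h$p_hyper, hyper_tail_oracle(k, Ka, Kb, N),
                 tolerance = 1e-12)
  }
})

test_that("gene-sharing components recover planted structure", {
  mem <- list(gA = paste0("p", 1:20), gB = paste0("p", 1:20),
              gC = paste0("q", 1:10), gD = paste0("r", 1:10))
  net <- build_gene_share_network(mem)
  expect_equal(nrow(net$edges), 1L) # only the full-overlap pair scores
  vc_of <- setNames(net$vcs$vc_id, net$vcs$genome_id)
  expect_equal(vc_of[["gA"]], vc_of[["gB"]])
  expect_equal(length(unique(vc_of)), 3L) # one pair VC plus two singletons
  # an unreachable threshold isolates everything
  net_inf <- build_gene_share_network(mem, score_threshold = Inf)
  expect_equal(nrow(net_inf$edges), 0L)
  expect_equal(length(unique(net_inf$vcs$vc_id)), 4L)
  # planted three-block membership resolves into exactly its blocks
  pcm <- generate_pc_membership(sprintf("g%02d", 1:12), n_blocks = 3,
                                seed = 4)
  got <- build_gene_share_network(pcm$membership)
  tab <- table(got$vcs$vc_id, pcm$blocks[got$vcs$genome_id])
  expect_equal(length(unique(got$vcs$vc_id)), 3L)
  expect_true(all(rowSums(tab > 0) == 1L)) # no VC mixes blocks
  # the genome-size filter excludes short genomes
  lens <- setNames(c(12000, 12000, 9000, 12000), names(mem))
  flt <- build_gene_share_network(mem, genome_lengths = lens)
  expect_false("gC" %in% flt$vcs$genome_id)
})

test_that("correlation edges demand robustness, significance and carry sign", {
  set.seed(32)
  base <- rlnorm(17, 3, 1)
  vc <- rbind(vc1 = base, vc2 = rlnorm(17, 3, 1))
  colnames(vc) <- paste0("s", 1:17)
  hosts <- rbind(hLin = 3 * base + 2, # exact linear: r = 1
                 hNeg = -2 * base + 100, # exact with sign flip: r = -1
                 hNoise = rlnorm(17, 3, 1))
  colnames(hosts) <- colnames(vc)
  out <- correlation_network(vc, hosts)
  lin <- out[out$vc_id == "vc1" & out$host_otu_id == "hLin", ]
  expect_equal(lin$sign, "positive")
  expect_equal(lin$r, 1, tolerance = 1e-12)
  neg <- out[out$vc_id == "vc1" & out$host_otu_id == "hNeg", ]
  expect_equal(neg$sign, "negative")
  flat <- rbind(hFlat = rep(1, 17))
  colnames(flat) <- colnames(vc)
  expect_warning(correlation_network(vc, flat), "zero-variance")
  expect_error(correlation_network(vc[, 1:3], hosts[, 1:3]), "4 shared")
})

test_that("correlation p-values match the closed-form t tail", {
  n <- 17
  for (r in seq(-0.95, 0.95, by = 0.1)) {
    x <- 1:17
    # build a pair with exactly this correlation via rotation
    set.seed(33)
    e <- residuals(lm(rnorm(n) ~ x))
    y <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
    vc <- rbind(v = x)
    colnames(vc) <- paste0("s", 1:n)
    ho <- rbind(h = y)
    colnames(ho) <- colnames(vc)
    out <- correlation_network(vc, ho, r_threshold = 0, p_threshold = 1)
    tstat <- out$r * sqrt((n - 2) / (1 - out$r^2))
    expect_equal(out$p, 2 * pt(abs(tstat), n - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_equal(out$r, r, tolerance = 1e-10)
  }
})

test_that("edge sets are invariant to consistent sample reordering", {
  set.seed(34)
  vc <- matrix(rlnorm(5 * 12), 5, 12,
               dimnames = list(paste0("vc", 1:5), paste0("s", 1:12)))
  ho <- matrix(rlnorm(4 * 12), 4, 12,
               dimnames = list(paste0("h", 1:4), paste0("s", 1:12)))
  perm <- sample(12)
  e1 <- correlation_network(vc, ho, r_threshold = 0.3, p_threshold = 0.5)
  e2 <- correlation_network(vc[, perm], ho[, perm],
                            r_threshold = 0.3, p_threshold = 0.5)
  key <- function(e) e[order(e$vc_id, e$host_otu_id), ]
  expect_equal(key(e1)$r, key(e2)$r, tolerance = 1e-12)
})
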