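test_that("homology filtering applies all four thresholds jointly", {
  lens <- c(vA = 8000, vB = 6000, vSmall = 4000)
  hits <- data.frame(
    votu_id = c("vA", "vA", "vB", "vSmall"),
    host_id = c("h1", "h2", "h3", "h4"),
    query_coverage = c(80, 74.9, 90, 90),
    identity = c(75, 99, 71, 95),
    bit_score = c(60, 500, 55, 300),
    e_value = c(1e-8, 0, 1e-6, 1e-20))
  out <- filter_homology(hits, lens)
  # the coverage failure and the sub-5kb vOTU are both dropped
  expect_equal(out$host_id, c("h1", "h3"))
  expect_true(all(out$channel == "homology"))
  expect_equal(nrow(filter_homology(hits[0, ], lens)), 0L)
  bad <- hits
  bad$votu_id[1] <- "vUnknown"
  expect_error(filter_homology(bad, lens), "unknown")
})

test_that("tRNA matching demands identity, length and reciprocity", {
  set.seed(23)
  t1 <- rand_dna(72)
  expect_equal(nrow(match_trna(c("v1|t1" = t1), c("h1|t1" = t1))), 1L)
  # ~85% identity fails the 90% clause
  t85 <- local({
    ch <- strsplit(t1, "")[[1]]
    for (p in sample(72, 11)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  })
  expect_equal(nrow(match_trna(c("v1|t1" = t1), c("h1|t1" = t85))), 0L)
  # one-directional best hit only: v1 prefers h1, but h1 prefers v2
  t96 <- local({
    ch <- strsplit(t1, "")[[1]]
    for (p in sample(72, 3)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  })
  out <- match_trna(c("v1|t1" = t96, "v2|t1" = t1), c("h1|t1" = t1))
  expect_equal(out$votu_id, "v2")
})

test_that("spacer matching tolerates exactly one substitution", {
  set.seed(24)
  contig <- rand_dna(3000)
  sp <- substr(contig, 1001, 1032)
  hit <- match_spacer(sp, contig)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$position, 1001L)
  ch <- strsplit(sp, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "T"), ch[5])[1]
  one <- match_spacer(paste(ch, collapse = ""), contig)
  expect_equal(one$mismatches, 1L)
  ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]
  expect_null(match_spacer(paste(ch, collapse = ""), contig))
  expect_error(match_spacer("ACGTNACGTACGTACGTACGTACGT", contig), "ACGT")
  expect_error(match_spacer("ACGT", contig), "20-60")
  # reverse-strand occurrences are found
  rc_hit <- match_spacer(revcomp_chr(sp), contig)
  expect_equal(rc_hit$strand, "-")
  expect_equal(rc_hit$mismatches, 0L)
})

test_that("spacer matching agrees with the sliding-window oracle", {
  set.seed(25)
  for (i in 1:15) {
    contig <- rand_dna(800)
    sp <- if (i %% 3 == 0) rand_dna(30) else {
      at <- sample(770, 1)
      s <- substr(contig, at, at + 29)
      ch <- strsplit(s, "")[[1]]
      nmut <- sample(0:2, 1)
      for (p in sample(30, nmut))
        ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
      if (runif(1) < 0.5) revcomp_chr(paste(ch, collapse = ""))
      else paste(ch, collapse = "")
    }
    got <- match_spacer(sp, contig)
    want <- spacer_scan_oracle(sp, contig)
    if (length(want) == 0L) {
      expect_null(got)
    } else {
      expect_equal(got$mismatches,
                   min(vapply(want, `[[`, integer(1), "mismatches")))
    }
  }
})

test_that("evidence integrates into breadth-labelled links", {
  ev <- data.frame(
    votu_id = c("v1", "v1", "v2", "v2"),
    host_id = c("h1", "h2", "h3", "h4"),
    channel = c("homology", "crispr", "trna", "crispr"))
  tax <- data.frame(host_id = paste0("h", 1:4),
                    host_class = c("Gammaproteobacteria",
                                   "Gammaproteobacteria",
                                   "Alphaproteobacteria", "Bacteroidia"))
  ab <- matrix(c(10, 20, 30, 40), 2, 2,
               dimnames = list(c("v1", "v2"), c("s1", "s2")))
  out <- integrate_links(ev, tax, ab = ab)
  l1 <- out$links[out$links$votu_id == "v1", ]
  expect_equal(l1$breadth, "narrow") # two channels, one class
  expect_equal(l1$channels, "crispr;homology")
  expect_equal(out$links$breadth[out$links$votu_id == "v2"], "broad")
  # rollup counts a vOTU once per linked class
  expect_equal(out$class_abundance["Gammaproteobacteria", "s1"], 10)
  expect_equal(out$class_abundance["Alphaproteobacteria", "s2"], 40)
  expect_error(integrate_links(ev, tax[1:2, ]), "taxonomy")
})
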