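# Independent oracles used across the suite. These deliberately re-derive
# each quantity through a different route than the package implementation.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# full dynamic-programming local alignment (both strands) via Biostrings,
# with the same scoring scheme as the package aligner (match 1, mismatch -1,
# linear gap -2); returns identity over aligned columns and coverage of the
# shorter sequence
dp_align_oracle <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  best <- NULL
  best_strand <- "+"
  for (strand in c("+", "-")) {
    bb <- if (strand == "+") b else revcomp_chr(b)
    p <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(bb), type = "local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
    if (is.null(best) || Biostrings::score(p) > Biostrings::score(best)) {
      best <- p
      best_strand <- strand
    }
  }
  span <- if (nchar(a) <= nchar(b)) {
    Biostrings::width(Biostrings::pattern(best))
  } else {
    Biostrings::width(Biostrings::subject(best))
  }
  list(identity = Biostrings::nmatch(best) / Biostrings::nchar(best),
       coverage_short = span / min(nchar(a), nchar(b)),
       score = Biostrings::score(best), strand = best_strand)
}

# shared-15-mer prescreen in plain R (either strand); a pair that can pass
# 95% identity over >= 80% of a >= 2 kb sequence always shares an exact
# 15-mer, so screening cannot split a mergeable pair
kmer_sets <- function(s, k = 15L) {
  unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
}

shares_kmer_oracle <- function(a, b) {
  ka <- kmer_sets(a)
  any(ka %in% kmer_sets(b)) || any(ka %in% kmer_sets(revcomp_chr(b)))
}

# greedy longest-first dereplication computed on exact DP alignments
greedy_cluster_oracle <- function(seqs, min_id = 0.95, min_cov = 0.80) {
  ord <- order(-nchar(seqs), names(seqs))
  reps <- integer(0)
  assign <- integer(length(seqs))
  for (i in ord) {
    hit <- 0L
    for (r in seq_along(reps)) {
      if (!shares_kmer_oracle(seqs[[reps[r]]], seqs[[i]])) next
      al <- dp_align_oracle(seqs[[reps[r]]], seqs[[i]])
      if (al$identity >= min_id && al$coverage_short >= min_cov) {
        hit <- r
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      hit <- length(reps)
    }
    assign[i] <- hit
  }
  setNames(assign, names(seqs))
}

# peak-typology decision table, written independently of classify_peak:
# group by day thresholds, runs via rle
peak_label_oracle <- function(above, days = c(165L, 181L, 193L, 208L, 243L, 271L)) {
  pk <- days[above]
  if (length(pk) == 0L) return("flat")
  if (length(pk) == 2L && identical(pk, c(165L, 271L))) return("single4")
  grp <- function(d) if (d <= 181L) 1L else if (d <= 208L) 2L else 3L
  if (length(pk) == 1L) return(paste0("single", grp(pk)))
  r <- rle(above)
  n_runs <- sum(r$values)
  if (n_runs == 1L && length(pk) %in% 2:3) return(paste0("wide", grp(pk[1L])))
  "several"
}

# four identification criteria evaluated one by one, then OR-ed
or_criteria_oracle <- function(vf, p, vs, cat_call) {
  c1 <- isTRUE(vf >= 0.9) && isTRUE(p < 0.05)
  c2 <- isTRUE(vs %in% c(1, 2, 4, 5))
  c3 <- isTRUE(vf >= 0.7) && isTRUE(p < 0.05) && isTRUE(vs %in% 1:6)
  c4 <- isTRUE(cat_call == "virus")
  if (c1 || c2 || c3 || c4) "viral" else "nonviral"
}

# upper-tail hypergeometric probability by explicit enumeration over
# binomial coefficients
hyper_tail_oracle <- function(k, Ka, Kb, N) {
  j <- k:min(Ka, Kb)
  sum(choose(Ka, j) * choose(N - Ka, Kb - j)) / choose(N, Kb)
}

# sliding-window spacer scan at every offset on both strands
spacer_scan_oracle <- function(spacer, seq) {
  sp <- strsplit(spacer, "")[[1L]]
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_chr(seq)
    sc <- strsplit(s, "")[[1L]]
    L <- length(sp)
    for (off in seq_len(length(sc) - L + 1L)) {
      mm <- sum(sc[off:(off + L - 1L)] != sp)
      if (mm <= 1L)
        hits[[length(hits) + 1L]] <- list(mismatches = mm, offset = off,
                                          strand = strand)
    }
  }
  hits
}
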