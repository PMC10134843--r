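#' Pairwise nucleotide identity and coverage of the shorter sequence
#'
#' Aligns two nucleotide sequences with a seeded banded local aligner
#' (shared 15-mer anchors, densest-diagonal band, Smith-Waterman within the
#' band; linear gap penalty) and summarizes the best local alignment as the
#' two quantities dereplication needs: `identity`, the fraction of matching
#' columns over all aligned columns (gap columns included in the
#' denominator), and `coverage_short`, the aligned span on the shorter
#' sequence divided by its length. Both orientations of `seq_b` are tried;
#' the higher-scoring one is reported.
#'
#' @param seq_a,seq_b character strings or [Biostrings::DNAString] objects
#'   over the uppercase ACGT alphabet.
#' @param k anchor k-mer size. A pair sharing no `k`-mer in either
#'   orientation is reported as unaligned; at dereplication-grade identity
#'   (>= 90% over >= 2.4 kb) an exact shared 15-mer is effectively certain,
#'   so the prefilter only prunes hopeless pairs.
#' @param band_pad extra diagonals kept on each side of the anchor band.
#' @param match,mismatch,gap alignment scores (gap is linear, per column).
#'
#' @return A list with `found = TRUE`, `identity`, `coverage_short`,
#'   `strand` (`"+"` or `"-"` for the orientation of `seq_b`), `score`,
#'   `matches`, `aligned_cols`, and the 1-based alignment spans `a_start`,
#'   `a_end`, `b_start`, `b_end` (on the forward strand of each input);
#'   or `list(found = FALSE)` when no alignment seed exists.
#' @examples
#' s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
#' pairwise_identity(s, s)[c("identity", "coverage_short")]
#' @export
pairwise_identity <- function(seq_a, seq_b, k = 15L, band_pad = 48L,
                              match = 1L, mismatch = -1L, gap = -2L) {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  if (length(a) != 1L || length(b) != 1L || nchar(a) == 0L || nchar(b) == 0L)
    stop("pairwise_identity() needs two single non-empty sequences")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    stop("sequences must contain only A, C, G, T")

  fwd <- .align_band_cpp(a, b, k = k, band_pad = band_pad,
                         match = match, mismatch = mismatch, gap = gap)
  brc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  rev <- .align_band_cpp(a, brc, k = k, band_pad = band_pad,
                         match = match, mismatch = mismatch, gap = gap)
  use_rev <- isTRUE(rev$found) &&
    (!isTRUE(fwd$found) || rev$score > fwd$score)
  hit <- if (use_rev) rev else fwd
  if (!isTRUE(hit$found)) return(list(found = FALSE))

  nb <- nchar(b)
  b_start <- hit$b_start
  b_end <- hit$b_end
  if (use_rev) { # map back to forward coordinates of b
    b_start <- nb - hit$b_end + 1L
    b_end <- nb - hit$b_start + 1L
  }
  span_a <- hit$a_end - hit$a_start + 1L
  span_b <- b_end - b_start + 1L
  short_len <- min(nchar(a), nb)
  span_short <- if (nchar(a) <= nb) span_a else span_b
  list(found = TRUE,
       identity = hit$matches / hit$aligned_cols,
       coverage_short = span_short / short_len,
       strand = if (use_rev) "-" else "+",
       score = hit$score, matches = hit$matches,
       aligned_cols = hit$aligned_cols,
       a_start = hit$a_start, a_end = hit$a_end,
       b_start = b_start, b_end = b_end)
}

#' Greedy dereplication of viral contigs into vOTUs
#'
#' Clusters contigs into viral operational taxonomic units (vOTUs) with the
#' greedy incremental rule of CD-HIT-style dereplication: contigs are sorted
#' by length (longest first, ties broken lexicographically by id) and each
#' contig joins the first established representative it matches at
#' `min_identity` nucleotide identity over at least `min_coverage` of the
#' shorter sequence; otherwise it founds a new vOTU and becomes its
#' representative. Both strands are considered.
#'
#' @param contigs a named [Biostrings::DNAStringSet] (or named character
#'   vector) of viral contig sequences.
#' @param min_identity identity threshold on aligned columns (default 0.95).
#' @param min_coverage threshold on aligned fraction of the shorter
#'   sequence (default 0.80).
#' @param ... passed to [pairwise_identity()].
#'
#' @return A data.frame with one row per contig: `contig_id`, `votu_id`
#'   (`"vOTU_0001"`-style, numbered in founding order), and
#'   `is_representative`. The representative of each vOTU is its longest
#'   member.
#' @export
cluster_votus <- function(contigs, min_identity = 0.95, min_coverage = 0.80,
                          ...) {
  seqs <- setNames(as.character(contigs), names(contigs))
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == "") || anyDuplicated(ids))
    stop("contigs must carry unique non-empty names")
  lens <- nchar(seqs)
  ord <- order(-lens, ids)
  rep_idx <- integer(0) # indices (into seqs) of representatives, founding order
  assign <- integer(length(seqs)) # vOTU number per contig
  for (i in ord) {
    joined <- 0L
    for (r in seq_along(rep_idx)) {
      hit <- pairwise_identity(seqs[[rep_idx[r]]], seqs[[i]], ...)
      if (isTRUE(hit$found) && hit$identity >= min_identity &&
          hit$coverage_short >= min_coverage) {
        joined <- r
        break
      }
    }
    if (joined == 0L) {
      rep_idx <- c(rep_idx, i)
      joined <- length(rep_idx)
    }
    assign[i] <- joined
  }
  votu_id <- sprintf("vOTU_%04d", assign)
  data.frame(contig_id = ids,
             votu_id = votu_id,
             is_representative = seq_along(seqs) %in% rep_idx,
             stringsAsFactors = FALSE)
}
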