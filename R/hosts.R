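#' Filter nucleotide-homology hits into virus-host evidence
#'
#' Keeps hits between a vOTU (>= 5 kb) and a host genome that pass all four
#' thresholds simultaneously: query coverage >= 75%, identity >= 70%,
#' bit score >= 50 and E value <= 1e-5.
#'
#' @param hits data.frame with columns `votu_id`, `host_id`,
#'   `query_coverage` (percent), `identity` (percent), `bit_score`,
#'   `e_value`.
#' @param votu_lengths named vector of vOTU lengths (bp) covering every
#'   vOTU referenced in `hits`; hits from vOTUs shorter than
#'   `min_votu_length` are discarded.
#' @param min_votu_length default 5000.
#' @param min_coverage,min_identity,min_bit_score,max_e_value thresholds.
#' @return The passing rows, with a `channel = "homology"` column.
#' @export
filter_homology <- function(hits, votu_lengths, min_votu_length = 5000,
                            min_coverage = 75, min_identity = 70,
                            min_bit_score = 50, max_e_value = 1e-5) {
  need <- c("votu_id", "host_id", "query_coverage", "identity", "bit_score",
            "e_value")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hits table is missing columns: ", paste(miss, collapse = ", "))
  unknown <- setdiff(hits$votu_id, names(votu_lengths))
  if (length(unknown))
    stop("hits reference unknown vOTUs: ", paste(unknown, collapse = ", "))
  keep <- votu_lengths[hits$votu_id] >= min_votu_length &
    hits$query_coverage >= min_coverage &
    hits$identity >= min_identity &
    hits$bit_score >= min_bit_score &
    hits$e_value <= max_e_value
  out <- hits[keep, , drop = FALSE]
  if (nrow(out)) out$channel <- "homology" else out$channel <- character(0)
  rownames(out) <- NULL
  out
}

# local alignment stats for short sequences (tRNA matching)
.trna_align <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  p <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                     Biostrings::DNAString(b),
                                     type = "local",
                                     substitutionMatrix = mat,
                                     gapOpening = 0, gapExtension = 2)
  alen <- Biostrings::nchar(p) # alignment columns, gaps included
  list(score = Biostrings::score(p),
       identity = Biostrings::nmatch(p) / alen,
       cov_a = Biostrings::width(Biostrings::pattern(p)) / nchar(a),
       cov_b = Biostrings::width(Biostrings::subject(p)) / nchar(b))
}

#' Match viral and host tRNAs by reciprocal best alignment
#'
#' A viral tRNA links its vOTU to a host when the host tRNA is its best
#' match and vice versa (reciprocal best hit), and the alignment covers at
#' least `min_length_fraction` of both sequences at
#' `min_identity` identity or better.
#'
#' @param viral_trnas named character vector (or `DNAStringSet`) of viral
#'   tRNA sequences; names formatted `"<votu_id>|<trna_id>"`.
#' @param host_trnas named character vector of host tRNA sequences; names
#'   formatted `"<host_id>|<trna_id>"`.
#' @param min_length_fraction,min_identity thresholds (defaults 0.9, 0.9).
#' @return data.frame `votu_id`, `host_id`, `identity`, `length_fraction`,
#'   `channel = "trna"`, one row per linked pair.
#' @export
match_trna <- function(viral_trnas, host_trnas,
                       min_length_fraction = 0.9, min_identity = 0.9) {
  v <- setNames(toupper(as.character(viral_trnas)), names(viral_trnas))
  h <- setNames(toupper(as.character(host_trnas)), names(host_trnas))
  if (length(v) == 0L || length(h) == 0L)
    return(data.frame(votu_id = character(0), host_id = character(0),
                      identity = numeric(0), length_fraction = numeric(0),
                      channel = character(0)))
  score <- matrix(0, length(v), length(h))
  ident <- matrix(0, length(v), length(h))
  lenfr <- matrix(0, length(v), length(h))
  for (i in seq_along(v)) {
    for (j in seq_along(h)) {
      al <- .trna_align(v[[i]], h[[j]])
      score[i, j] <- al$score
      ident[i, j] <- al$identity
      lenfr[i, j] <- min(al$cov_a, al$cov_b)
    }
  }
  best_h <- apply(score, 1L, which.max) # best host tRNA per viral tRNA
  best_v <- apply(score, 2L, which.max) # best viral tRNA per host tRNA
  rows <- list()
  for (i in seq_along(v)) {
    j <- best_h[i]
    if (best_v[j] != i) next # not reciprocal
    if (ident[i, j] < min_identity || lenfr[i, j] < min_length_fraction) next
    rows[[length(rows) + 1L]] <- data.frame(
      votu_id = sub("\\|.*$", "", names(v)[i]),
      host_id = sub("\\|.*$", "", names(h)[j]),
      identity = ident[i, j], length_fraction = lenfr[i, j],
      channel = "trna", stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(votu_id = character(0), host_id = character(0),
                      identity = numeric(0), length_fraction = numeric(0),
                      channel = character(0)))
  unique(do.call(rbind, rows))
}

#' Match a CRISPR spacer against a viral contig
#'
#' Scans both strands of the contig for a full-length occurrence of the
#' spacer with at most `max_mismatch` substitutions (no indels). BLAST-style
#' E-value screening is subsumed by the mismatch bound at spacer lengths.
#'
#' @param spacer spacer sequence, 20-60 nt, ACGT only.
#' @param votu_seq contig sequence (character or `DNAString`).
#' @param max_mismatch default 1.
#' @return `NULL` when there is no qualifying occurrence; otherwise a list
#'   with `mismatches` (of the best occurrence), `position` (1-based start
#'   on the forward strand of the contig) and `strand`.
#' @export
match_spacer <- function(spacer, votu_seq, max_mismatch = 1L) {
  spacer <- toupper(as.character(spacer))
  if (grepl("[^ACGT]", spacer))
    stop("spacer contains non-ACGT characters")
  if (nchar(spacer) < 20L || nchar(spacer) > 60L)
    stop("spacer length must be 20-60 nt")
  subj <- Biostrings::DNAString(toupper(as.character(votu_seq)))
  pat <- Biostrings::DNAString(spacer)
  best <- NULL
  for (strand in c("+", "-")) {
    p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
    m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatch,
                                  with.indels = FALSE)
    if (length(m) == 0L) next
    mm <- Biostrings::neditStartingAt(p, subj,
                                      starting.at = IRanges::start(m))
    i <- which.min(mm)
    if (is.null(best) || mm[i] < best$mismatches)
      best <- list(mismatches = as.integer(mm[i]),
                   position = IRanges::start(m)[i], strand = strand)
  }
  best
}

#' Scan a spacer table against a set of viral contigs
#'
#' Runs [match_spacer()] for every (spacer, contig) combination and returns
#' one evidence row per qualifying occurrence.
#'
#' @param spacers data.frame with columns `host_id`, `spacer_id`,
#'   `sequence`.
#' @param contigs named `DNAStringSet` or character vector of contigs.
#' @return data.frame `votu_id`, `host_id`, `channel = "crispr"`, unique
#'   rows only.
#' @export
spacer_evidence <- function(spacers, contigs) {
  seqs <- setNames(as.character(contigs), names(contigs))
  rows <- list()
  for (s in seq_len(nrow(spacers))) {
    for (v in names(seqs)) {
      hit <- match_spacer(spacers$sequence[s], seqs[[v]])
      if (!is.null(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          votu_id = v, host_id = spacers$host_id[s], channel = "crispr",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(votu_id = character(0), host_id = character(0),
                      channel = character(0)))
  unique(do.call(rbind, rows))
}

#' Integrate virus-host evidence into linkages with host-range breadth
#'
#' Unions evidence records per vOTU across the three channels, labels each
#' vOTU's host range `narrow` (a single predicted host class) or `broad`
#' (two or more classes), and, when an abundance matrix is given, rolls up
#' vOTU TPM per host class per sample.
#'
#' @param evidences data.frame with at least `votu_id`, `host_id`,
#'   `channel`; typically rbind-ed output of [filter_homology()],
#'   [match_trna()] and spacer matching.
#' @param taxonomy data.frame `host_id`, `host_class`; must cover every
#'   host in `evidences`.
#' @param ab optional TPM matrix (vOTUs in rows) for the class rollup.
#' @return A list with `links` (one row per vOTU: `votu_id`,
#'   `host_classes` (`;`-joined), `channels` (`;`-joined), `n_classes`,
#'   `breadth`), `evidence` (the annotated input), and `class_abundance`
#'   (host_class x sample TPM sums; `NULL` without `ab`).
#' @export
integrate_links <- function(evidences, taxonomy, ab = NULL) {
  if (nrow(evidences) == 0L)
    return(list(links = data.frame(votu_id = character(0),
                                   host_classes = character(0),
                                   channels = character(0),
                                   n_classes = integer(0),
                                   breadth = character(0)),
                evidence = evidences, class_abundance = NULL))
  unknown <- setdiff(evidences$host_id, taxonomy$host_id)
  if (length(unknown))
    stop("hosts without taxonomy: ", paste(unknown, collapse = ", "))
  evidences$host_class <-
    taxonomy$host_class[match(evidences$host_id, taxonomy$host_id)]
  by_votu <- split(evidences, evidences$votu_id)
  links <- do.call(rbind, lapply(by_votu, function(e) {
    cls <- sort(unique(e$host_class))
    data.frame(votu_id = e$votu_id[1L],
               host_classes = paste(cls, collapse = ";"),
               channels = paste(sort(unique(e$channel)), collapse = ";"),
               n_classes = length(cls),
               breadth = if (length(cls) >= 2L) "broad" else "narrow",
               stringsAsFactors = FALSE)
  }))
  rownames(links) <- NULL
  class_ab <- NULL
  if (!is.null(ab)) {
    pairs <- unique(evidences[, c("votu_id", "host_class")])
    pairs <- pairs[pairs$votu_id %in% rownames(ab), , drop = FALSE]
    if (nrow(pairs)) {
      class_ab <- rowsum(ab[pairs$votu_id, , drop = FALSE],
                         pairs$host_class)
    }
  }
  list(links = links, evidence = evidences, class_abundance = class_ab)
}
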