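#' Hypergeometric gene-sharing similarity of two genomes
#'
#' Given the protein-cluster (PC) sets of two genomes and a universe of `N`
#' distinct PCs, computes the exact upper-tail hypergeometric probability
#' of observing at least the shared number of PCs by chance, and the
#' network score `-log10(p * n_comparisons)` floored at zero (a Bonferroni
#' style rescaling by the number of genome pairs compared).
#'
#' @param set_a,set_b character vectors of PC ids (nonempty).
#' @param N total number of distinct PCs in the universe.
#' @param n_comparisons total number of genome pairs compared.
#' @return A list with `k` (shared PCs), `p_hyper` = P(X >= k) for X
#'   hypergeometric(N, |A|, |B|), and `score`.
#' @examples
#' hypergeom_score(letters[1:3], letters[c(1, 2, 4, 5)], N = 10,
#'                 n_comparisons = 1)$p_hyper # exactly 1/3
#' @export
hypergeom_score <- function(set_a, set_b, N, n_comparisons) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("PC sets must be nonempty")
  if (N < length(set_a) || N < length(set_b))
    stop("universe N smaller than a PC set")
  if (N < length(union(set_a, set_b)))
    stop("universe N smaller than the union of the PC sets")
  k <- length(intersect(set_a, set_b))
  # exact tail: P(X >= k), X ~ hypergeom(pop N, successes |A|, draws |B|)
  p <- phyper(k - 1L, length(set_a), N - length(set_a), length(set_b),
              lower.tail = FALSE)
  list(k = k, p_hyper = p,
       score = max(0, -log10(p * n_comparisons)))
}

#' Gene-sharing network and viral clusters
#'
#' Scores every genome pair with [hypergeom_score()] (with
#' `n_comparisons` = number of pairs), keeps edges with score at or above
#' `score_threshold`, and defines viral clusters (VCs) as the connected
#' components of the thresholded graph. Intended for genomes >= 10 kb;
#' supply `genome_lengths` to enforce the size filter.
#'
#' @param membership named list mapping genome id to a character vector of
#'   PC ids, or a data.frame with columns `genome_id`, `pc_id`.
#' @param score_threshold minimum edge score (default 1).
#' @param genome_lengths optional named vector (bp); genomes shorter than
#'   `min_genome_length` are excluded before scoring.
#' @param min_genome_length default 10000.
#' @return A list with `edges` (data.frame `genome_a`, `genome_b`, `k`,
#'   `p_hyper`, `score`), `vcs` (data.frame `genome_id`, `vc_id`;
#'   singletons included), `N`, `n_comparisons`.
#' @export
build_gene_share_network <- function(membership, score_threshold = 1,
                                     genome_lengths = NULL,
                                     min_genome_length = 10000) {
  if (is.data.frame(membership))
    membership <- split(membership$pc_id, membership$genome_id)
  membership <- lapply(membership, unique)
  if (!is.null(genome_lengths)) {
    keep <- names(membership)[
      genome_lengths[names(membership)] >= min_genome_length]
    membership <- membership[keep]
  }
  genomes <- names(membership)
  if (length(genomes) < 2L)
    stop("need at least two genomes after filtering")
  N <- length(unique(unlist(membership)))
  pairs <- combn(genomes, 2L)
  n_comp <- ncol(pairs)
  res <- lapply(seq_len(n_comp), function(p) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    hs <- hypergeom_score(membership[[a]], membership[[b]], N, n_comp)
    data.frame(genome_a = a, genome_b = b, k = hs$k, p_hyper = hs$p_hyper,
               score = hs$score, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, res)
  edges <- edges[edges$score >= score_threshold, , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("genome_a", "genome_b")], directed = FALSE,
    vertices = data.frame(name = genomes))
  comp <- igraph::components(g)$membership
  vcs <- data.frame(genome_id = names(comp),
                    vc_id = sprintf("VC_%03d", unname(comp)),
                    stringsAsFactors = FALSE)
  list(edges = edges, vcs = vcs, N = N, n_comparisons = n_comp)
}

#' Thresholded Pearson co-occurrence network between VCs and host OTUs
#'
#' Pearson correlation of each (viral cluster, host OTU) abundance pair
#' over the shared samples, with a two-sided p-value from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. Only
#' robust (`|r| > r_threshold`) and significant (`p < p_threshold`) pairs
#' are retained; no multiple-testing correction is applied. Pairs in which
#' either series has zero variance are skipped with a warning.
#'
#' @param vc_ab VC x sample abundance matrix.
#' @param host_ab host-OTU x sample abundance matrix; columns are matched
#'   to `vc_ab` by name.
#' @param r_threshold,p_threshold strict thresholds (defaults 0.8, 0.05).
#' @return data.frame `vc_id`, `host_otu_id`, `r`, `p`, `sign`
#'   (`"positive"`/`"negative"`), one row per retained edge.
#' @export
correlation_network <- function(vc_ab, host_ab,
                                r_threshold = 0.8, p_threshold = 0.05) {
  shared <- intersect(colnames(vc_ab), colnames(host_ab))
  if (length(shared) < 4L) stop("need at least 4 shared samples")
  X <- t(vc_ab[, shared, drop = FALSE])
  Y <- t(host_ab[, shared, drop = FALSE])
  n <- length(shared)
  sx <- apply(X, 2L, stats::sd)
  sy <- apply(Y, 2L, stats::sd)
  if (any(sx == 0) || any(sy == 0))
    warning("zero-variance series skipped: ",
            paste(c(colnames(X)[sx == 0], colnames(Y)[sy == 0]),
                  collapse = ", "))
  R <- suppressWarnings(cor(X, Y)) # NA where sd == 0
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  keep <- which(!is.na(R) & abs(R) > r_threshold & P < p_threshold,
                arr.ind = TRUE)
  data.frame(vc_id = colnames(X)[keep[, 1L]],
             host_otu_id = colnames(Y)[keep[, 2L]],
             r = R[keep], p = P[keep],
             sign = ifelse(R[keep] > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}
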