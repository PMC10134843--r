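#' TPM normalization of a vOTU read-count matrix
#'
#' Converts per-sample mapped-read counts into transcripts-per-million
#' (TPM): within each sample, counts are first divided by vOTU length
#' (length-rate), then rescaled so the sample sums to one million. Columns
#' with no mapped reads at all are returned as all-zero with a warning.
#'
#' @param counts numeric matrix of nonnegative integers, vOTUs in rows
#'   (rownames required), samples in columns.
#' @param lengths named numeric vector of vOTU lengths in bp, covering all
#'   rows of `counts`.
#' @return A numeric matrix of the same shape; every column with any
#'   mapped reads sums to 1e6.
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' tpm(m, c(a = 1000, b = 2000))
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have vOTU rownames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!all(rownames(counts) %in% names(lengths)))
    stop("lengths missing for some vOTUs")
  L <- lengths[rownames(counts)]
  if (any(L <= 0)) stop("vOTU lengths must be positive")
  rate <- counts / L
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("sample(s) with no mapped reads returned as all-zero: ",
            paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Aggregate AMG abundance from vOTU abundances
#'
#' Each ORF inherits the TPM of the vOTU encoding it; a gene family's
#' abundance in a sample is the sum over its ORFs. Families with no ORF are
#' absent from the result rather than reported as zero.
#'
#' @param amg data.frame with columns `orf_id`, `votu_id`, `gene_family`
#'   (and optionally a `pathway` tag, carried through).
#' @param ab TPM matrix from [tpm()], vOTUs in rows.
#' @return A long-format data.frame `gene_family`, `sample`, `abundance`
#'   (plus `pathway` when supplied), suitable for bubble plots.
#' @export
amg_abundance <- function(amg, ab) {
  need <- c("orf_id", "votu_id", "gene_family")
  miss <- setdiff(need, names(amg))
  if (length(miss))
    stop("amg table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(amg$orf_id))
    stop("orf_id values must be unique")
  orphan <- setdiff(amg$votu_id, rownames(ab))
  if (length(orphan))
    stop("ORFs reference vOTUs absent from the abundance matrix: ",
         paste(unique(orphan), collapse = ", "))
  orf_ab <- ab[amg$votu_id, , drop = FALSE] # ORF inherits parent vOTU TPM
  fam <- factor(amg$gene_family)
  agg <- rowsum(orf_ab, fam) # sum over ORFs per family
  out <- data.frame(
    gene_family = rep(rownames(agg), times = ncol(agg)),
    sample = rep(colnames(agg), each = nrow(agg)),
    abundance = as.vector(agg),
    stringsAsFactors = FALSE)
  if ("pathway" %in% names(amg)) {
    pw <- tapply(amg$pathway, fam, function(x) x[[1]])
    out$pathway <- unname(pw[out$gene_family])
  }
  out
}

#' Alpha diversity of one sample
#'
#' Shannon index H (natural log), richness S (number of taxa with positive
#' abundance) and Pielou evenness J = H / ln(S). Computed through the
#' standard community-ecology routines ([vegan::diversity()],
#' [vegan::specnumber()]). J is undefined (NA) for a single-taxon sample.
#'
#' @param x numeric vector of nonnegative abundances (e.g. one TPM column),
#'   with at least one positive entry.
#' @return A list with `H`, `J`, `S`.
#' @examples
#' alpha_diversity(c(1, 1, 1, 1)) # H = ln 4, J = 1
#' @export
alpha_diversity <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0) || !any(x > 0))
    stop("abundances must be nonnegative with at least one positive entry")
  H <- unname(vegan::diversity(x, index = "shannon"))
  S <- unname(vegan::specnumber(x))
  J <- if (S > 1) H / log(S) else NA_real_
  list(H = H, J = J, S = S)
}

#' Per-sample alpha-diversity table
#'
#' @param ab TPM matrix, vOTUs in rows, samples in columns.
#' @return data.frame with columns `sample`, `H`, `J`, `S`.
#' @export
diversity_table <- function(ab) {
  res <- lapply(seq_len(ncol(ab)), function(j) alpha_diversity(ab[, j]))
  data.frame(sample = colnames(ab),
             H = vapply(res, `[[`, numeric(1), "H"),
             J = vapply(res, `[[`, numeric(1), "J"),
             S = vapply(res, `[[`, numeric(1), "S"),
             stringsAsFactors = FALSE)
}
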