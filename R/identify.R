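#' Rule-based viral contig identification from per-tool score tables
#'
#' Calls a contig viral when any one of four criteria over upstream tool
#' outputs holds:
#'
#' * i. VirFinder-style score >= 0.9 with p < 0.05;
#' * ii. VirSorter-style category in \{1, 2, 4, 5\};
#' * iii. VirFinder-style score >= 0.7 with p < 0.05 AND VirSorter-style
#'   category in \{1..6\};
#' * iv. called `virus` by a CAT-style taxonomic annotator.
#'
#' Score comparisons use `>=`, p-value comparisons strict `<`. A missing
#' field (NA) fails every clause that uses it; category 6 can only
#' contribute through criterion iii. Contigs shorter than 3 kb must have
#' been removed upstream and are rejected with an error.
#'
#' @param scores a data.frame with columns `contig_id`, `length_bp`,
#'   `vf_score`, `vf_p`, `vs_category`, `cat_call` (`"virus"`/`"other"`;
#'   NA allowed in the tool columns).
#' @param min_length_bp minimum contig length enforced upstream
#'   (default 3000).
#' @return The input with two added columns: `call` (`"viral"` /
#'   `"nonviral"`) and `criteria_fired` (comma-joined roman numerals,
#'   `""` for nonviral contigs).
#' @examples
#' s <- data.frame(contig_id = "c1", length_bp = 5000, vf_score = 0.95,
#'                 vf_p = 0.01, vs_category = NA, cat_call = "other")
#' classify_contigs(s)$call
#' @export
classify_contigs <- function(scores, min_length_bp = 3000L) {
  need <- c("contig_id", "length_bp", "vf_score", "vf_p", "vs_category",
            "cat_call")
  miss <- setdiff(need, names(scores))
  if (length(miss))
    stop("scores table is missing columns: ", paste(miss, collapse = ", "))
  if (any(scores$length_bp < min_length_bp))
    stop("contigs shorter than ", min_length_bp,
         " bp must be removed upstream: ",
         paste(scores$contig_id[scores$length_bp < min_length_bp],
               collapse = ", "))
  vf <- scores$vf_score
  p <- scores$vf_p
  vs <- scores$vs_category
  cat_call <- scores$cat_call
  ok <- function(x) !is.na(x) & x # NA fails its clause
  crit <- cbind(
    i = ok(vf >= 0.9) & ok(p < 0.05),
    ii = ok(vs %in% c(1, 2, 4, 5) & !is.na(vs)),
    iii = ok(vf >= 0.7) & ok(p < 0.05) & ok(vs %in% 1:6 & !is.na(vs)),
    iv = ok(cat_call == "virus")
  )
  fired <- apply(crit, 1L, function(z) paste(colnames(crit)[z], collapse = ","))
  scores$call <- ifelse(rowSums(crit) > 0L, "viral", "nonviral")
  scores$criteria_fired <- fired
  scores
}

#' @rdname classify_contigs
#' @param contig_scores a one-row data.frame (or list coercible to one)
#'   with the same fields as `scores`.
#' @return `classify_contig()` returns the single call, `"viral"` or
#'   `"nonviral"`.
#' @export
classify_contig <- function(contig_scores, min_length_bp = 3000L) {
  classify_contigs(as.data.frame(contig_scores, stringsAsFactors = FALSE),
                   min_length_bp = min_length_bp)$call
}
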