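#' Principal component analysis of a community matrix
#'
#' Column-centered singular value decomposition of the sample x vOTU
#' matrix, by default after a Hellinger transform (square root of sample
#' relative abundances), the standard variance-stabilizing choice for
#' compositional community data.
#'
#' @param ab abundance matrix, vOTUs in rows, samples in columns.
#' @param transform `"hellinger"` (default) or `"none"`.
#' @return A list with `scores` (sample x axis), `eig` (eigenvalues, i.e.
#'   squared singular values scaled by 1/(n-1)), `proportion` (share of
#'   total variance per axis), `transform`.
#' @export
pca_ordination <- function(ab, transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  X <- t(as.matrix(ab)) # samples in rows
  if (nrow(X) < 3L) stop("PCA needs at least 3 samples")
  if (transform == "hellinger")
    X <- vegan::decostand(X, method = "hellinger")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  list(scores = pc$x, eig = eig, proportion = eig / sum(eig),
       transform = transform)
}

#' Canonical correspondence analysis of a community against environment
#'
#' Textbook CCA: the community matrix is chi-square standardized, projected
#' onto the environmental variables by weighted least squares (row-total
#' weights), and the fitted matrix eigen-analyzed. Computed through
#' [vegan::cca()]; collinear environmental columns are dropped with a
#' warning and recorded in the result.
#'
#' @param ab abundance matrix, vOTUs in rows, samples in columns
#'   (nonnegative; converted internally to proportions by `vegan`'s
#'   chi-square standardization).
#' @param env data.frame or matrix of environmental variables, one row per
#'   sample, in the column order of `ab`. Constant columns are an error.
#' @return A list with `eig` (constrained eigenvalues), `total_inertia`,
#'   `proportion` (constrained eigenvalues over total inertia),
#'   `site_scores`, `biplot_scores` (environmental variable scores),
#'   `dropped` (aliased variable names, possibly empty).
#' @export
cca_ordination <- function(ab, env) {
  Y <- t(as.matrix(ab))
  env <- as.data.frame(env)
  if (nrow(env) != nrow(Y))
    stop("env must have one row per sample of ab")
  const <- vapply(env, function(x) length(unique(x)) == 1L, logical(1))
  if (any(const))
    stop("constant environmental column(s): ",
         paste(names(env)[const], collapse = ", "))
  m <- vegan::cca(Y ~ ., data = env)
  dropped <- tryCatch(stats::alias(m, names = TRUE),
                      error = function(e) NULL)
  dropped <- as.character(unlist(dropped))
  if (length(dropped))
    warning("dropped collinear environmental variable(s): ",
            paste(dropped, collapse = ", "))
  eig <- unname(m$CCA$eig)
  list(eig = eig,
       total_inertia = m$tot.chi,
       proportion = eig / m$tot.chi,
       # suppressWarnings: vegan's scores() sweeps over two axes even for
       # single-axis models and warns harmlessly
       site_scores = suppressWarnings(
         vegan::scores(m, display = "sites", choices = seq_along(eig))),
       biplot_scores = m$CCA$biplot,
       dropped = dropped)
}
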