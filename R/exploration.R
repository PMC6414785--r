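#' Principal component analysis of samples
#'
#' Samples are observations, genes variables; gene rows are centered (and
#' unit-scaled when \code{scale_genes = TRUE}) before the decomposition.
#' Components are ordered by explained variance with a deterministic sign
#' convention: the largest-magnitude entry of each loading vector is
#' positive.
#'
#' @param ms a [merged_study] or a gene x sample numeric matrix.
#' @param n_components number of components to keep in scores/loadings
#'   (default all, i.e. \code{min(genes, samples - 1)}).
#' @param scale_genes standardize genes to unit variance (correlation PCA)
#'   instead of covariance PCA (the default).
#' @return object of class \code{pca_result}: \code{scores} (sample x
#'   component), \code{loadings} (gene x component), \code{variance_fraction}
#'   over all components, and the centering/scaling flags.
#' @export
run_pca <- function(ms, n_components = NULL, scale_genes = FALSE) {
  v <- study_values(ms)
  if (ncol(v) < 2) stop("PCA needs at least 2 samples")
  if (all(apply(v, 1, var) == 0)) stop("constant matrix: nothing to decompose")
  if (scale_genes && any(apply(v, 1, var) == 0))
    stop("zero-variance genes cannot be unit-scaled; filter them first")
  max_comp <- min(nrow(v), ncol(v) - 1L)
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp)
    stop("n_components exceeds min(genes, samples - 1) = ", max_comp)
  pc <- prcomp(t(v), center = TRUE, scale. = scale_genes)
  eig <- pc$sdev^2
  k_all <- min(length(eig), max_comp)
  varfrac <- eig[seq_len(k_all)] / sum(eig[seq_len(k_all)])
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = varfrac,
                 centered = TRUE, scaled = scale_genes),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples x %d components kept\n",
              nrow(x$scores), ncol(x$scores)))
  vf <- x$variance_fraction
  k <- min(3L, length(vf))
  cat(sprintf("  first %d components explain %.1f%% of variance\n",
              k, 100 * sum(vf[seq_len(k)])))
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Euclidean distance on the (optionally gene-restricted) sample profiles
#' with the chosen linkage. The tree can be exported as newick via
#' [write_newick()].
#'
#' @param ms a [merged_study] or gene x sample matrix.
#' @param gene_subset optional character vector of genes to restrict to.
#' @param linkage one of \code{"average"}, \code{"complete"}, \code{"ward"}
#'   (Ward's D2 on squared distances).
#' @return object of class \code{sample_tree} wrapping the \code{hclust}
#'   merge history, leaf order, metric and linkage.
#' @export
cluster_samples <- function(ms, gene_subset = NULL,
                            linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  v <- study_values(ms)
  if (ncol(v) < 2) stop("clustering needs at least 2 samples")
  if (!is.null(gene_subset)) {
    unknown <- setdiff(gene_subset, rownames(v))
    if (length(unknown) > 0)
      stop("unknown genes in subset: ",
           paste(head(unknown, 10), collapse = ", "))
    v <- v[gene_subset, , drop = FALSE]
  }
  method <- c(average = "average", complete = "complete",
              ward = "ward.D2")[linkage]
  hc <- hclust(dist(t(v), method = "euclidean"), method = method)
  structure(list(hclust = hc, metric = "euclidean", linkage = linkage,
                 leaf_order = hc$labels[hc$order]),
            class = "sample_tree")
}

#' @export
print.sample_tree <- function(x, ...) {
  cat(sprintf("sample_tree: %d leaves, %s linkage on %s distance\n",
              length(x$leaf_order), x$linkage, x$metric))
  invisible(x)
}

#' Write a sample tree as newick
#'
#' Leaves are sample ids; branch lengths derive from merge heights.
#'
#' @param tree a [cluster_samples()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "sample_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Mean silhouette of a sample partition
#'
#' Silhouette width of each sample against a labelling (e.g. the state
#' factor), averaged; used to quantify how well a gene subset separates a
#' known partition.
#'
#' @param ms a [merged_study] or gene x sample matrix.
#' @param labels vector of group labels, one per sample.
#' @param gene_subset optional gene restriction.
#' @return mean silhouette width (numeric scalar).
#' @export
partition_silhouette <- function(ms, labels, gene_subset = NULL) {
  v <- study_values(ms)
  if (!is.null(gene_subset)) v <- v[gene_subset, , drop = FALSE]
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(v))
  d <- as.matrix(dist(t(v)))
  sil <- vapply(seq_len(ncol(v)), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

## Accept a merged_study or a bare matrix anywhere downstream of the merge.
study_values <- function(x) {
  if (inherits(x, "merged_study")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x))) stop("matrix must carry gene rownames")
    return(x)
  }
  stop("expected a merged_study or a numeric gene x sample matrix")
}
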