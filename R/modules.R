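#' Conventional module colour order
#'
#' Size-ranked module colour names as used throughout the co-expression
#' field: turquoise for the largest module, blue for the second largest,
#' then brown, yellow, green, ... Label 0 (unassigned) is grey.
#'
#' @param n how many colours to return.
#' @return character vector of length \code{n}.
#' @export
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen",
            "darkturquoise", "darkgrey", "orange", "darkorange", "white",
            "skyblue", "saddlebrown", "steelblue", "paleturquoise",
            "violet", "darkolivegreen", "darkmagenta")
  if (n > length(base))
    base <- c(base, sprintf("module%d", seq_len(n - length(base)) +
                              length(base)))
  base[seq_len(n)]
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' \eqn{1 - \omega}, cut at a fixed height (default 0.99 of the tallest
#' merge); branches smaller than \code{min_module_size} are left
#' unassigned (label 0, grey). Labels are ranked by decreasing size and
#' named by the conventional colour order, so "blue" is always the
#' second-largest module.
#'
#' @param nm a [network_model] with TOM present.
#' @param min_module_size smallest branch kept as a module.
#' @param cut_height absolute cut height; default \code{0.99 * max(height)}.
#' @return object of class \code{module_assignment}: data.frame (gene,
#'   label, color) with the dendrogram, cut height and minimum size as
#'   attributes.
#' @export
detect_modules <- function(nm, min_module_size = 30L, cut_height = NULL) {
  stopifnot(inherits(nm, "network_model"))
  if (is.null(nm$tom)) stop("TOM not computed; run tom_similarity() first")
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  diss <- 1 - nm$tom
  hc <- hclust(as.dist(diss), method = "average")
  if (is.null(cut_height)) cut_height <- 0.99 * max(hc$height)
  raw <- cutree(hc, h = cut_height)
  assignment <- relabel_by_size(raw, min_module_size, genes = nm$genes)
  if (all(assignment$label == 0))
    warning("no branch reached min_module_size; all genes unassigned")
  attr(assignment, "dendrogram") <- hc
  attr(assignment, "cut_height") <- cut_height
  attr(assignment, "min_module_size") <- min_module_size
  assignment
}

## size-rank raw cluster ids into labels 1..m (0 = unassigned), colours per
## convention; ties in size broken by the smallest member symbol.
relabel_by_size <- function(raw, min_module_size, genes) {
  tab <- table(raw)
  keep_ids <- names(tab)[tab >= min_module_size]
  sizes <- tab[keep_ids]
  first_gene <- vapply(keep_ids, function(id)
    min(genes[raw == as.integer(id)]), character(1))
  ord <- order(-as.integer(sizes), first_gene)
  ranked <- keep_ids[ord]
  label <- integer(length(raw))
  for (r in seq_along(ranked)) label[raw == as.integer(ranked[r])] <- r
  colors <- c("grey", module_colors(length(ranked)))
  structure(data.frame(gene = genes, label = label,
                       color = colors[label + 1L],
                       stringsAsFactors = FALSE),
            class = c("module_assignment", "data.frame"))
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- table(x$label[x$label > 0])
  cat(sprintf("module_assignment: %d genes, %d modules (%d unassigned)\n",
              nrow(x), length(tab), sum(x$label == 0)))
  if (length(tab) > 0) {
    info <- vapply(names(tab), function(l)
      sprintf("%s:%d", x$color[x$label == as.integer(l)][1], tab[[l]]),
      character(1))
    cat("  ", paste(info, collapse = " "), "\n")
  }
  invisible(x)
}

#' Genes of one module
#'
#' @param assignment a [module_assignment].
#' @param label module label (integer) or colour name.
#' @return character vector of gene symbols.
#' @export
module_genes <- function(assignment, label) {
  stopifnot(inherits(assignment, "module_assignment"))
  if (is.character(label)) {
    hit <- assignment$label[match(label, assignment$color)]
    if (is.na(hit)) stop("no module with colour '", label, "'")
    label <- hit
  }
  if (!label %in% assignment$label) stop("no module with label ", label)
  assignment$gene[assignment$label == label]
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized submatrix, scaled to unit norm and oriented so that
#' its mean correlation with the module's genes is non-negative.
#'
#' @param ms a [merged_study] or gene x sample matrix.
#' @param assignment a [module_assignment] over (a superset of) the
#'   matrix's genes.
#' @return object of class \code{eigengene_matrix}: module x sample matrix
#'   (rownames are module colours) with per-module variance explained as
#'   attribute \code{"variance_explained"}.
#' @export
module_eigengenes <- function(ms, assignment) {
  v <- study_values(ms)
  stopifnot(inherits(assignment, "module_assignment"))
  labels <- sort(unique(assignment$label[assignment$label > 0]))
  if (length(labels) == 0) stop("no modules to summarize")
  eig <- matrix(0, length(labels), ncol(v),
                dimnames = list(NULL, colnames(v)))
  varexp <- numeric(length(labels))
  colors <- character(length(labels))
  for (i in seq_along(labels)) {
    gs <- intersect(module_genes(assignment, labels[i]), rownames(v))
    if (length(gs) < 2) stop("module ", labels[i], " has fewer than 2 genes")
    sub <- v[gs, , drop = FALSE]
    sds <- apply(sub, 1, sd)
    if (any(sds == 0))
      stop("degenerate module ", labels[i], ": constant gene(s) ",
           paste(head(gs[sds == 0], 3), collapse = ", "))
    z <- (sub - rowMeans(sub)) / sds
    sv <- svd(z)
    e <- sv$v[, 1]
    e <- e / sqrt(sum(e^2))
    if (mean(cor(e, t(sub))) < 0) e <- -e
    eig[i, ] <- e
    varexp[i] <- sv$d[1]^2 / sum(sv$d^2)
    colors[i] <- assignment$color[assignment$label == labels[i]][1]
  }
  rownames(eig) <- colors
  structure(eig, class = c("eigengene_matrix", "matrix"),
            labels = labels, variance_explained = setNames(varexp, colors))
}

#' Merge modules with close eigengenes
#'
#' Iteratively merges the closest module pair whose eigengene
#' dissimilarity \eqn{1 - cor(E_a, E_b)} is below \code{merge_distance},
#' recomputing eigengenes after every merge, until no pair qualifies.
#' Unassigned genes (label 0) never merge. Labels are re-ranked by size
#' and recoloured afterwards.
#'
#' @param ms a [merged_study] or gene x sample matrix.
#' @param assignment a [module_assignment].
#' @param merge_distance eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. eigengene correlation above 0.75).
#' @return a re-ranked [module_assignment]; merged pairs are recorded in
#'   attribute \code{"merges"}.
#' @export
merge_close_modules <- function(ms, assignment, merge_distance = 0.25) {
  v <- study_values(ms)
  stopifnot(inherits(assignment, "module_assignment"))
  if (merge_distance <= 0 || merge_distance >= 1)
    stop("merge_distance must lie in (0, 1)")
  labels <- assignment$label
  names(labels) <- assignment$gene
  merges <- list()
  repeat {
    present <- sort(unique(labels[labels > 0]))
    if (length(present) < 2) break
    tmp <- assignment
    tmp$label <- labels
    eig <- module_eigengenes(v, tmp)
    cm <- cor(t(unclass(eig)))
    diss <- 1 - cm
    diag(diss) <- Inf
    i <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    if (diss[i[1], i[2]] >= merge_distance) break
    a <- present[i[1]]; b <- present[i[2]]
    labels[labels == b] <- a
    merges[[length(merges) + 1L]] <- c(kept = a, absorbed = b)
  }
  out <- relabel_keep_zero(labels, assignment$gene)
  attr(out, "merges") <- merges
  attr(out, "merge_distance") <- merge_distance
  out
}

## rank nonzero labels by size (ties by smallest member symbol), keep 0
relabel_keep_zero <- function(labels, genes) {
  nz <- sort(unique(labels[labels > 0]))
  sizes <- vapply(nz, function(l) sum(labels == l), integer(1))
  first_gene <- vapply(nz, function(l) min(genes[labels == l]), character(1))
  ord <- order(-sizes, first_gene)
  new <- integer(length(labels))
  for (r in seq_along(ord)) new[labels == nz[ord[r]]] <- r
  colors <- c("grey", module_colors(length(nz)))
  structure(data.frame(gene = genes, label = new,
                       color = colors[new + 1L],
                       stringsAsFactors = FALSE),
            class = c("module_assignment", "data.frame"))
}

#' Intramodular connectivity and module hubs
#'
#' \code{kTotal} is each gene's whole-network connectivity (sum of its
#' adjacencies), \code{kWithin} the connectivity restricted to its own
#' module. The hub of a module is its maximal-\code{kWithin} gene (ties
#' broken lexicographically).
#'
#' @param nm a [network_model] (adjacency used).
#' @param assignment a [module_assignment] consistent with the network's
#'   genes.
#' @return list with \code{table} (gene, label, color, kTotal, kWithin)
#'   and \code{hubs} (label, color, hub_gene, k_within).
#' @export
intramodular_connectivity <- function(nm, assignment) {
  stopifnot(inherits(nm, "network_model"),
            inherits(assignment, "module_assignment"))
  a <- nm$adjacency
  idx <- match(nm$genes, assignment$gene)
  if (any(is.na(idx)))
    stop("assignment does not cover the network's genes")
  label <- assignment$label[idx]
  color <- assignment$color[idx]
  k_total <- rowSums(a) - 1
  k_within <- vapply(seq_along(nm$genes), function(i) {
    same <- label == label[i]
    same[i] <- FALSE
    sum(a[i, same])
  }, numeric(1))
  tab <- data.frame(gene = nm$genes, label = label, color = color,
                    kTotal = k_total, kWithin = k_within,
                    stringsAsFactors = FALSE)
  mods <- sort(unique(label[label > 0]))
  hubs <- do.call(rbind, lapply(mods, function(m) {
    sub <- tab[tab$label == m, ]
    sub <- sub[order(-sub$kWithin, sub$gene), ]
    data.frame(label = m, color = sub$color[1], hub_gene = sub$gene[1],
               k_within = sub$kWithin[1], stringsAsFactors = FALSE)
  }))
  list(table = tab, hubs = hubs)
}

#' Export thresholded within-module edges
#'
#' Undirected edges (each pair once) inside one module whose TOM weight
#' strictly exceeds the threshold, sorted by descending weight; the
#' per-gene degree in the export is the graphical connectivity of a
#' thresholded module network plot.
#'
#' @param nm a [network_model] with TOM present.
#' @param assignment a [module_assignment].
#' @param module_label module label or colour.
#' @param weight_threshold strict lower bound on edge weight.
#' @return data.frame (gene_a, gene_b, weight) with per-gene exported
#'   degree as attribute \code{"degree"} (named vector over all module
#'   genes, zeros included).
#' @export
export_module_edges <- function(nm, assignment, module_label,
                                weight_threshold = 0.41) {
  stopifnot(inherits(nm, "network_model"))
  if (is.null(nm$tom)) stop("TOM not computed; run tom_similarity() first")
  gs <- module_genes(assignment, module_label)
  gs <- intersect(gs, nm$genes)
  w <- nm$tom[gs, gs, drop = FALSE]
  ut <- upper.tri(w)
  keep <- ut & w > weight_threshold
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(gene_a = gs[idx[, 1]], gene_b = gs[idx[, 2]],
                      weight = w[keep], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight, edges$gene_a, edges$gene_b), ]
  rownames(edges) <- NULL
  degree <- setNames(numeric(length(gs)), gs)
  if (nrow(edges) > 0) {
    cnt <- table(c(edges$gene_a, edges$gene_b))
    degree[names(cnt)] <- as.numeric(cnt)
  }
  attr(edges, "degree") <- degree
  attr(edges, "weight_threshold") <- weight_threshold
  edges
}

#' Overlap between two modules from different runs
#'
#' Reports the intersection size, Jaccard and per-set overlap fractions,
#' and an upper-tail hypergeometric p-value for the overlap given a shared
#' gene universe; optionally after restricting both modules (e.g. to
#' transcription-factor genes).
#'
#' @param assign_a,assign_b [module_assignment] objects (or plain
#'   character vectors of gene symbols).
#' @param universe character vector of the shared gene universe; must
#'   contain both modules.
#' @param label_a,label_b module labels/colours (ignored when character
#'   vectors are given directly).
#' @param restrict_to optional gene set applied to both modules and the
#'   universe before counting.
#' @return list: sizes, overlap count, jaccard, fraction_a/b,
#'   hypergeometric p.
#' @export
module_overlap <- function(assign_a, assign_b, universe,
                           label_a = NULL, label_b = NULL,
                           restrict_to = NULL) {
  set_of <- function(x, label) {
    if (is.character(x)) return(unique(x))
    module_genes(x, label)
  }
  a <- set_of(assign_a, label_a)
  b <- set_of(assign_b, label_b)
  if (length(universe) == 0) stop("empty gene universe")
  universe <- unique(universe)
  if (!all(a %in% universe) || !all(b %in% universe))
    stop("universe must contain both modules")
  if (!is.null(restrict_to)) {
    universe <- intersect(universe, restrict_to)
    a <- intersect(a, restrict_to)
    b <- intersect(b, restrict_to)
  }
  k <- length(intersect(a, b))
  n_u <- length(universe)
  p <- phyper(k - 1, length(a), n_u - length(a), length(b),
              lower.tail = FALSE)
  union_size <- length(union(a, b))
  list(n_a = length(a), n_b = length(b), n_universe = n_u,
       overlap = k,
       jaccard = if (union_size == 0) NA_real_ else k / union_size,
       fraction_a = if (length(a) == 0) NA_real_ else k / length(a),
       fraction_b = if (length(b) == 0) NA_real_ else k / length(b),
       p_value = p)
}
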