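#' Pavlidis template matching against a regulator gene
#'
#' Finds genes whose expression trajectory follows a template gene's
#' observed profile: Pearson correlation of every gene with the template
#' across all samples, matched when \eqn{R} strictly exceeds the threshold
#' (signed, so anti-correlated genes never match). The template itself is
#' excluded from the matched set. For plotting, the z-scored template and
#' the mean profile of the matched genes are reported with samples ordered
#' by group then timepoint when metadata is available.
#'
#' @param ms a [merged_study] (sample ordering taken from its metadata) or
#'   a gene x sample matrix.
#' @param template_gene symbol of the template; must be present and
#'   non-constant.
#' @param r_threshold strict correlation threshold (default 0.8).
#' @param gene_subset optional candidate restriction (e.g. one module's
#'   genes).
#' @return object of class \code{template_match_result}: per-gene
#'   correlations, the matched gene set, the z-scored template profile and
#'   the matched-mean profile.
#' @export
pavlidis_template_match <- function(ms, template_gene, r_threshold = 0.8,
                                    gene_subset = NULL) {
  v <- study_values(ms)
  meta <- if (inherits(ms, "merged_study")) ms$metadata else NULL
  if (!template_gene %in% rownames(v))
    stop("template gene '", template_gene, "' not in matrix")
  if (ncol(v) < 3) stop("template matching needs at least 3 samples")
  if (!is.null(gene_subset)) {
    unknown <- setdiff(gene_subset, rownames(v))
    if (length(unknown) > 0)
      stop("unknown genes in subset: ",
           paste(head(unknown, 10), collapse = ", "))
    v <- v[union(gene_subset, template_gene), , drop = FALSE]
  }
  tmpl <- v[template_gene, ]
  if (sd(tmpl) == 0) stop("template gene has zero variance")
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0),
            " zero-variance gene(s) excluded from template matching")
    v <- v[sds > 0, , drop = FALSE]
  }
  r <- as.numeric(cor(tmpl, t(v)))
  names(r) <- rownames(v)
  r <- r[names(r) != template_gene]
  matched <- names(r)[r > r_threshold]

  ord <- seq_len(ncol(v))
  if (!is.null(meta)) ord <- order(meta$group, meta$timepoint)
  profile <- data.frame(
    sample_id = colnames(v)[ord],
    template_z = as.numeric(scale(tmpl))[ord],
    matched_mean = if (length(matched) > 0)
      colMeans(v[matched, ord, drop = FALSE]) else rep(NA_real_, ncol(v)),
    stringsAsFactors = FALSE)
  structure(list(template_gene = template_gene,
                 r = r, r_threshold = r_threshold,
                 matched = matched, n_matched = length(matched),
                 profile = profile),
            class = "template_match_result")
}

#' @export
print.template_match_result <- function(x, ...) {
  cat(sprintf("template match: %d genes match %s (R > %g)\n",
              x$n_matched, x$template_gene, x$r_threshold))
  invisible(x)
}
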