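#' Probe-level expression matrix with annotation
#'
#' Container for probe-level log2 intensities plus the probe-to-gene-symbol
#' annotation of one platform. Probes with a missing (NA or empty) symbol
#' are retained but flagged as unannotated; they are dropped at collapse.
#'
#' @param values numeric matrix, probes x samples, finite, with unique
#'   rownames (probe ids).
#' @param annotation data.frame with columns \code{probe_id} and
#'   \code{symbol} covering every probe.
#' @param platform_id platform label.
#' @return object of class \code{probe_matrix}.
#' @export
probe_matrix <- function(values, annotation, platform_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("probe ids (rownames) must be present and unique")
  if (any(!is.finite(values))) stop("probe matrix contains non-finite values")
  if (!all(c("probe_id", "symbol") %in% names(annotation)))
    stop("annotation needs columns probe_id and symbol")
  if (!all(rownames(values) %in% annotation$probe_id))
    stop("annotation does not cover every probe")
  ann <- annotation[match(rownames(values), annotation$probe_id), ]
  ann$symbol[!is.na(ann$symbol) & ann$symbol == ""] <- NA_character_
  structure(list(values = values,
                 probe_ids = rownames(values),
                 annotation = ann,
                 platform_id = platform_id),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix '%s': %d probes x %d samples (%d unannotated)\n",
              x$platform_id, nrow(x$values), ncol(x$values),
              sum(is.na(x$annotation$symbol))))
  invisible(x)
}

#' Collapse probes to unique gene symbols (max-signal probe)
#'
#' For each gene symbol, keeps the single probe with the highest mean
#' intensity across all samples (the max-probe convention of GSEA-style
#' collapsing); ties are broken by the lexicographically smallest probe id.
#' Unannotated probes are dropped.
#'
#' @param pm a [probe_matrix()].
#' @return object of class \code{gene_matrix}: gene x sample values (rows
#'   ordered by symbol), \code{source} platform label and a
#'   \code{provenance} data.frame recording each symbol's winning probe.
#' @export
collapse_probes <- function(pm) {
  stopifnot(inherits(pm, "probe_matrix"))
  ann <- pm$annotation
  keep <- !is.na(ann$symbol)
  if (!any(keep))
    stop("platform annotation is unusable: no probe maps to a gene symbol")
  vals <- pm$values[keep, , drop = FALSE]
  sym <- ann$symbol[keep]
  means <- rowMeans(vals)
  ## order so the best (then lexicographically smallest) probe per symbol
  ## comes first, then keep the first occurrence of each symbol
  ord <- order(sym, -means, rownames(vals), method = "radix")
  first <- !duplicated(sym[ord])
  win <- ord[first]
  out <- vals[win, , drop = FALSE]
  rownames(out) <- sym[ord][first]
  prov <- data.frame(gene = rownames(out),
                     probe_id = rownames(vals)[win],
                     stringsAsFactors = FALSE)
  structure(list(values = out,
                 gene_symbols = rownames(out),
                 source = pm$platform_id,
                 provenance = prov,
                 n_probes_in = nrow(pm$values),
                 n_unannotated = sum(!keep)),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("gene_matrix '%s': %d genes x %d samples (collapsed from %d probes)\n",
              x$source, nrow(x$values), ncol(x$values), x$n_probes_in))
  invisible(x)
}

#' Merged cross-platform study
#'
#' Internal constructor; users normally obtain one from
#' [intersect_and_merge()].
#'
#' @param values gene x sample matrix.
#' @param metadata sample metadata data.frame (sample_id, platform, state,
#'   group, timepoint) covering every column exactly once.
#' @param report named list of provenance counts.
#' @return object of class \code{merged_study}.
#' @export
merged_study <- function(values, metadata, report = list()) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!all(colnames(values) %in% metadata$sample_id) ||
      anyDuplicated(metadata$sample_id))
    stop("metadata must cover every sample exactly once")
  metadata <- metadata[match(colnames(values), metadata$sample_id), ]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata, report = report),
            class = "merged_study")
}

#' @export
print.merged_study <- function(x, ...) {
  cat(sprintf("merged_study: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$metadata$platform)),
                            table(x$metadata$platform)), collapse = ", ")))
  invisible(x)
}

#' Intersect gene universes and merge two collapsed platforms
#'
#' Rows of the merged matrix are the sorted intersection of the two
#' platforms' symbols; columns are platform A's samples followed by
#' platform B's. Values are copied unchanged; platform-private genes are
#' discarded and counted in the report.
#'
#' @param gm_a,gm_b collapsed [gene_matrix] objects.
#' @param meta sample metadata covering all samples of both platforms.
#' @return a [merged_study].
#' @export
intersect_and_merge <- function(gm_a, gm_b, meta) {
  stopifnot(inherits(gm_a, "gene_matrix"), inherits(gm_b, "gene_matrix"))
  common <- sort(intersect(gm_a$gene_symbols, gm_b$gene_symbols))
  if (length(common) == 0)
    stop("empty gene-universe intersection between platforms")
  dup <- intersect(colnames(gm_a$values), colnames(gm_b$values))
  if (length(dup) > 0)
    stop("duplicate sample ids across platforms: ",
         paste(head(dup, 5), collapse = ", "))
  values <- cbind(gm_a$values[common, , drop = FALSE],
                  gm_b$values[common, , drop = FALSE])
  report <- list(
    n_genes_a = length(gm_a$gene_symbols),
    n_genes_b = length(gm_b$gene_symbols),
    n_intersected = length(common),
    n_discarded_a = length(gm_a$gene_symbols) - length(common),
    n_discarded_b = length(gm_b$gene_symbols) - length(common),
    source = setNames(c(rep(gm_a$source, ncol(gm_a$values)),
                        rep(gm_b$source, ncol(gm_b$values))),
                      colnames(values))
  )
  merged_study(values, meta, report)
}

#' Renormalize a merged study
#'
#' \code{scale}: per-sample centering to zero mean and unit sd.
#' \code{quantile}: classic quantile normalization (each column's sorted
#' values replaced by the cross-column mean of sorted values, ties
#' receiving the mean of their candidate values; delegated to
#' \code{limma::normalizeQuantiles}). \code{none}: identity.
#'
#' @param ms a [merged_study].
#' @param method one of \code{"none"}, \code{"scale"}, \code{"quantile"}.
#' @return a [merged_study] with the same labels.
#' @export
renormalize <- function(ms, method = c("none", "scale", "quantile")) {
  stopifnot(inherits(ms, "merged_study"))
  method <- match.arg(method)
  v <- ms$values
  if (method == "scale") {
    sds <- apply(v, 2, sd)
    if (any(sds == 0))
      stop("zero-variance sample under 'scale': ",
           paste(colnames(v)[sds == 0], collapse = ", "))
    v <- scale(v, center = TRUE, scale = TRUE)
    attr(v, "scaled:center") <- NULL
    attr(v, "scaled:scale") <- NULL
  } else if (method == "quantile") {
    dn <- dimnames(v)
    v <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(v) <- dn
  }
  ms$values <- v
  ms$report$renormalized <- method
  ms
}

#' Filter genes by interquartile range
#'
#' Keeps genes whose across-sample IQR strictly exceeds \code{threshold}.
#' Quartiles use linear interpolation (\code{stats::quantile} type 7, the
#' convention under which the quartiles of 1..4 are 1.75 and 3.25).
#'
#' @param ms a [merged_study].
#' @param threshold non-negative IQR cutoff (default 0.5, the conventional
#'   variable-gene filter for merged log2 microarray data).
#' @return a [merged_study] restricted to passing genes, original order
#'   preserved; report records kept/dropped counts.
#' @export
iqr_filter <- function(ms, threshold = 0.5) {
  stopifnot(inherits(ms, "merged_study"), threshold >= 0)
  q <- apply(ms$values, 1, quantile, probs = c(0.25, 0.75),
             names = FALSE, type = 7)
  iqr <- q[2, ] - q[1, ]
  keep <- iqr > threshold
  ms$report$iqr_threshold <- threshold
  ms$report$n_genes_kept <- sum(keep)
  ms$report$n_genes_dropped <- sum(!keep)
  ms$values <- ms$values[keep, , drop = FALSE]
  ms
}

#' Exclude listed samples from a merged study
#'
#' @param ms a [merged_study].
#' @param sample_ids ids to drop; all must be present.
#' @return a [merged_study]; report notes the exclusion list.
#' @export
exclude_samples <- function(ms, sample_ids) {
  stopifnot(inherits(ms, "merged_study"))
  if (length(sample_ids) == 0) return(ms)
  missing <- setdiff(sample_ids, colnames(ms$values))
  if (length(missing) > 0)
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  keep <- !colnames(ms$values) %in% sample_ids
  out <- ms
  out$values <- ms$values[, keep, drop = FALSE]
  out$metadata <- ms$metadata[keep, , drop = FALSE]
  rownames(out$metadata) <- NULL
  out$report$excluded_samples <- sample_ids
  if (length(unique(out$metadata$platform)) < 2)
    warning("all remaining samples come from a single platform")
  out
}
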