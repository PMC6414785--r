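#' Assign peaks to genes by TSS proximity
#'
#' Drops peaks scoring below \code{min_score}, then flags a gene when any
#' retained peak's midpoint lies strictly within \code{max_distance} base
#' pairs of the gene's TSS (absolute genomic distance on the same
#' chromosome; strand is used only insofar as the TSS coordinate encodes
#' it). The nearest retained-peak distance is reported per gene.
#'
#' @param peaks data.frame (chrom, start, end, name, score) with 0-based
#'   half-open intervals, e.g. from [generate_peak_table()] or
#'   [read_bed()].
#' @param loci data.frame (symbol, chrom, tss, strand), e.g. from
#'   [generate_gene_loci()].
#' @param max_distance strict proximity bound in bp (default 1000).
#' @param min_score minimum retained peak score (default 50).
#' @return data.frame (gene, chrom, tss, has_peak, nearest_distance);
#'   \code{nearest_distance} is NA for genes with no retained peak on
#'   their chromosome.
#' @export
annotate_peaks_to_genes <- function(peaks, loci, max_distance = 1000,
                                    min_score = 50) {
  if (max_distance <= 0) stop("max_distance must be positive")
  validate_gene_loci(loci)
  validate_peak_table(peaks)
  kept <- peaks[peaks$score >= min_score, , drop = FALSE]
  if (nrow(peaks) > 0 &&
      length(intersect(unique(peaks$chrom), unique(loci$chrom))) == 0)
    stop("no shared chromosomes between peaks and loci; ",
         "check chromosome naming")
  mid <- (kept$start + kept$end) / 2
  nearest <- vapply(seq_len(nrow(loci)), function(i) {
    on_chrom <- kept$chrom == loci$chrom[i]
    if (!any(on_chrom)) return(NA_real_)
    min(abs(mid[on_chrom] - loci$tss[i]))
  }, numeric(1))
  data.frame(gene = loci$symbol, chrom = loci$chrom, tss = loci$tss,
             has_peak = !is.na(nearest) & nearest < max_distance,
             nearest_distance = nearest,
             stringsAsFactors = FALSE)
}

validate_peak_table <- function(peaks) {
  need <- c("chrom", "start", "end", "score")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks)))
    stop("peaks must be a data.frame with columns chrom, start, end, ",
         "name, score")
  if (nrow(peaks) > 0) {
    if (any(peaks$start >= peaks$end))
      stop("malformed peak intervals: start must be < end (0-based half-open)")
    if (any(peaks$score < 0)) stop("peak scores must be non-negative")
  }
  invisible(peaks)
}

#' Fisher enrichment of peak-bearing genes: module vs comparison module
#'
#' Builds the 2x2 table (with peak / without peak) x (module / comparison
#' module) and tests it with the two-sided Fisher exact test (sum of
#' hypergeometric probabilities no larger than the observed table's). The
#' odds ratio is the unconditional sample estimate \eqn{ad/bc}, with a 0.5
#' continuity correction applied (and flagged) only when a zero cell
#' occurs.
#'
#' @param flags gene-level peak flags from [annotate_peaks_to_genes()], or
#'   a named logical vector.
#' @param module_genes,comparison_genes disjoint, non-empty gene sets
#'   covered by the flags.
#' @return object of class \code{enrichment_result}: 2x2 \code{table},
#'   \code{odds_ratio}, \code{p_value}, \code{continuity_corrected}.
#' @export
module_peak_enrichment <- function(flags, module_genes, comparison_genes) {
  if (is.data.frame(flags)) flags <- setNames(flags$has_peak, flags$gene)
  if (length(module_genes) == 0 || length(comparison_genes) == 0)
    stop("module and comparison gene sets must be non-empty")
  if (length(intersect(module_genes, comparison_genes)) > 0)
    stop("module and comparison gene sets must be disjoint")
  missing <- setdiff(c(module_genes, comparison_genes), names(flags))
  if (length(missing) > 0)
    stop("flags do not cover: ", paste(head(missing, 5), collapse = ", "))
  a <- sum(flags[module_genes])       # module, with peak
  b <- sum(!flags[module_genes])      # module, without
  c_ <- sum(flags[comparison_genes])  # comparison, with peak
  d <- sum(!flags[comparison_genes])  # comparison, without
  counts <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                   dimnames = list(c("module", "comparison"),
                                   c("with_peak", "without_peak")))
  enrichment_from_table(counts)
}

#' Fisher enrichment from a ready-made 2x2 table
#'
#' @param counts 2x2 matrix: rows module/comparison, columns
#'   with/without peak.
#' @return an \code{enrichment_result}; see [module_peak_enrichment()].
#' @export
enrichment_from_table <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == 2), all(counts >= 0))
  a <- counts[1, 1]; b <- counts[1, 2]; c_ <- counts[2, 1]; d <- counts[2, 2]
  zero <- any(counts == 0)
  if (zero) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  p <- fisher.test(counts)$p.value
  structure(list(table = counts, odds_ratio = or, p_value = p,
                 continuity_corrected = zero),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("peak enrichment (two-sided Fisher exact)\n")
  print(x$table)
  cat(sprintf("  odds ratio %.3f%s, p = %.3g\n", x$odds_ratio,
              if (x$continuity_corrected) " (continuity corrected)" else "",
              x$p_value))
  invisible(x)
}
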