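#' Write a numeric matrix as TSV
#'
#' Genes (rows) in the first column, header = sample ids. Floats are
#' serialized with 9 significant digits so identical runs produce
#' byte-identical files.
#'
#' @param x numeric matrix with dimnames.
#' @param path output file.
#' @param row_label header of the first column.
#' @return the path, invisibly.
#' @export
write_tsv_matrix <- function(x, path, row_label = "gene") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(row_label, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(r)
    paste(sprintf("%.9g", r), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a TSV matrix written by [write_tsv_matrix()]
#'
#' @param path input file.
#' @return numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a probe matrix plus annotation from TSV
#'
#' @param values_path probe x sample TSV (first column probe ids).
#' @param annotation_path two-column TSV (probe_id, symbol); empty or NA
#'   symbols mark unannotated probes.
#' @param platform_id platform label.
#' @return a [probe_matrix].
#' @export
read_probe_matrix <- function(values_path, annotation_path, platform_id) {
  values <- read_tsv_matrix(values_path)
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  probe_matrix(values, ann, platform_id)
}

#' Write a probe matrix and its annotation as TSV
#'
#' @param pm a [probe_matrix].
#' @param values_path,annotation_path output files.
#' @return invisibly, the two paths.
#' @export
write_probe_matrix <- function(pm, values_path, annotation_path) {
  stopifnot(inherits(pm, "probe_matrix"))
  write_tsv_matrix(pm$values, values_path, row_label = "probe_id")
  write.table(pm$annotation, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(values_path, annotation_path))
}

#' Read sample metadata TSV
#'
#' Expects columns sample_id, platform, state, group, timepoint.
#'
#' @param path input TSV.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "platform", "state", "group", "timepoint")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0)
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  meta
}

#' Read / write a 5-column BED peak table
#'
#' 0-based half-open intervals, columns chrom, start, end, name, score,
#' no header.
#'
#' @param path file path.
#' @return \code{read_bed}: a peak table data.frame.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5) stop("expected 5-column BED (chrom start end name score)")
  df <- df[, 1:5]
  names(df) <- c("chrom", "start", "end", "name", "score")
  validate_peak_table(df)
  structure(df, class = c("peak_table", "data.frame"))
}

#' @rdname read_bed
#' @param peaks a peak table data.frame.
#' @export
write_bed <- function(peaks, path) {
  validate_peak_table(peaks)
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    sprintf("%.9g", peaks$score))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write gene loci TSV (symbol, chrom, tss, strand)
#'
#' @param path file path.
#' @return \code{read_gene_loci}: a loci data.frame.
#' @export
read_gene_loci <- function(path) {
  loci <- read.delim(path, stringsAsFactors = FALSE)
  validate_gene_loci(loci)
  loci
}

#' @rdname read_gene_loci
#' @param loci a loci data.frame.
#' @export
write_gene_loci <- function(loci, path) {
  validate_gene_loci(loci)
  write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
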