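#' Unsigned weighted network adjacency
#'
#' \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} with Pearson correlation across
#' samples; the diagonal is 1. Raising the soft-thresholding power
#' \eqn{\beta} suppresses weak correlations, pushing the weighted network
#' toward scale-free topology.
#'
#' @param ms a [merged_study] or gene x sample matrix (genes must be
#'   variance-filtered: zero-variance genes are an error).
#' @param beta soft-thresholding power, \eqn{\ge 1}.
#' @return object of class \code{network_model} with the adjacency filled
#'   (TOM slot empty until [tom_similarity()]).
#' @export
adjacency_matrix <- function(ms, beta = 9) {
  v <- study_values(ms)
  if (beta < 1) stop("beta must be >= 1")
  if (ncol(v) < 3) stop("adjacency needs at least 3 samples")
  sds <- apply(v, 1, sd)
  if (any(sds == 0))
    stop("zero-variance genes must be filtered first: ",
         paste(head(rownames(v)[sds == 0], 10), collapse = ", "))
  a <- abs(cor(t(v)))^beta
  diag(a) <- 1
  structure(list(genes = rownames(v), beta = beta,
                 adjacency = a, tom = NULL, type = "unsigned"),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model: %d genes, unsigned, beta = %g, TOM %s\n",
              length(x$genes), x$beta,
              if (is.null(x$tom)) "not computed" else "computed"))
  invisible(x)
}

#' Topological overlap of a weighted network
#'
#' Fills the TOM slot:
#' \deqn{\omega_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is 1. Two genes overlap
#' strongly when they are directly connected and share neighbours.
#'
#' @param nm a [network_model] with adjacency present.
#' @return the model with \code{tom} filled (symmetric, entries in [0, 1]).
#' @export
tom_similarity <- function(nm) {
  stopifnot(inherits(nm, "network_model"))
  a <- nm$adjacency
  k <- rowSums(a) - 1
  ## (A^2)_ij counts u = i and u = j; remove both (diag(a) = 1)
  l <- a %*% a - 2 * a
  denom <- outer(k, k, pmin) + 1 - a
  w <- (l + a) / denom
  diag(w) <- 1
  w <- (w + t(w)) / 2
  w[w < 0] <- 0
  w[w > 1] <- 1
  nm$tom <- w
  nm
}

#' Scale-free topology fit across candidate soft-thresholding powers
#'
#' For each candidate power the connectivity distribution is summarized by
#' an equal-occupancy binning of \eqn{\log_{10} k} (10 bins); the log
#' density per bin is regressed on the bin's mean \eqn{\log_{10} k} and the
#' fit is reported as a signed R-squared (negated when the slope is
#' positive, since scale-free topology requires a decreasing density). The
#' recommended power is the smallest candidate reaching \code{target_r2},
#' or the best-fitting candidate when none does.
#'
#' @param ms a [merged_study] or gene x sample matrix.
#' @param candidate_betas powers to evaluate.
#' @param target_r2 signed R-squared considered an adequate fit.
#' @param n_bins connectivity bins.
#' @return object of class \code{soft_threshold_fit}: a data.frame (beta,
#'   signed_r2, slope, mean_k, median_k, max_k) with the recommended power
#'   as attribute \code{"recommended_beta"}.
#' @export
pick_soft_threshold <- function(ms, candidate_betas = c(1:10, 12, 14, 16, 18, 20),
                                target_r2 = 0.85, n_bins = 10L) {
  v <- study_values(ms)
  if (length(candidate_betas) < 1) stop("need at least one candidate power")
  absr <- abs(cor(t(v)))
  diag(absr) <- 0
  rows <- lapply(candidate_betas, function(b) {
    k <- rowSums(absr^b)
    fit <- scale_free_fit(k, n_bins = n_bins)
    data.frame(beta = b, signed_r2 = fit$signed_r2, slope = fit$slope,
               mean_k = mean(k), median_k = median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$signed_r2) & tab$signed_r2 >= target_r2
  recommended <- if (any(ok)) tab$beta[which(ok)[1]] else
    tab$beta[which.max(tab$signed_r2)]
  structure(tab, class = c("soft_threshold_fit", "data.frame"),
            recommended_beta = recommended, target_r2 = target_r2)
}

## Binned power-law fit of a connectivity vector. Equal-occupancy bins in
## log10(k); the bin frequency is turned into a density by dividing by the
## bin width so that the regression measures the shape of p(k), not the
## binning itself.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(list(signed_r2 = NA_real_, slope = NA_real_))
  lk <- log10(k)
  breaks <- unique(quantile(lk, probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE, type = 7))
  if (length(breaks) < 4) {
    warning("fewer than 3 usable connectivity bins; fit skipped")
    return(list(signed_r2 = NA_real_, slope = NA_real_))
  }
  bins <- cut(lk, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bins, nbins = nlevels(bins))
  widths <- diff(breaks)
  keep <- counts > 0 & widths > 0
  if (sum(keep) < 3) {
    warning("fewer than 3 usable connectivity bins; fit skipped")
    return(list(signed_r2 = NA_real_, slope = NA_real_))
  }
  dens <- (counts / length(lk)) / widths
  mean_lk <- vapply(seq_len(nlevels(bins)), function(i)
    mean(lk[as.integer(bins) == i]), numeric(1))
  fit <- lm(log10(dens[keep]) ~ mean_lk[keep])
  r2 <- summary(fit)$r.squared
  slope <- unname(coef(fit)[2])
  list(signed_r2 = if (slope > 0) -r2 else r2, slope = slope)
}

#' @export
print.soft_threshold_fit <- function(x, ...) {
  cat(sprintf("soft-threshold fit (recommended beta = %g, target R2 = %.2f)\n",
              attr(x, "recommended_beta"), attr(x, "target_r2")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot the scale-free fit against candidate powers
#'
#' @param fit a [pick_soft_threshold()] result.
#' @return a ggplot object: signed R-squared and mean connectivity vs power.
#' @export
plot_soft_threshold <- function(fit) {
  stopifnot(inherits(fit, "soft_threshold_fit"))
  df <- rbind(
    data.frame(beta = fit$beta, value = fit$signed_r2,
               panel = "signed scale-free R2"),
    data.frame(beta = fit$beta, value = fit$mean_k,
               panel = "mean connectivity"))
  beta <- value <- NULL # NSE bindings
  ggplot2::ggplot(df, ggplot2::aes(x = beta, y = value)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::geom_vline(xintercept = attr(fit, "recommended_beta"),
                        linetype = "dashed") +
    ggplot2::theme_minimal()
}
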