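#' Principal variance component analysis
#'
#' Audits the sources of variation in a merged study. The gene-standardized
#' matrix is decomposed by sample-space PCA; the leading components whose
#' cumulative variance reaches \code{variance_threshold} are each modelled
#' by a random-effects fit with one random intercept per supplied factor
#' and (optionally) per pairwise interaction; the per-component variance
#' proportions (negative estimates truncated at zero by the fitter) are
#' then averaged with eigenvalue weights into one proportion per factor
#' plus residual.
#'
#' Because genes are standardized first, the result is invariant to
#' gene-wise positive rescaling of the input.
#'
#' @param ms a [merged_study].
#' @param factors character vector of metadata columns to decompose over
#'   (default platform and state, the two design axes of a cross-platform
#'   study).
#' @param variance_threshold fraction in (0, 1]: keep the first components
#'   whose cumulative variance reaches it (default 0.6).
#' @param include_interactions add all pairwise interactions of the
#'   supplied factors (default TRUE).
#' @return object of class \code{pvca_result}: a data.frame (factor,
#'   proportion) sorted by decreasing proportion, with the retained
#'   component count, eigenvalues and threshold as attributes.
#' @export
pvca <- function(ms, factors = c("platform", "state"),
                 variance_threshold = 0.6,
                 include_interactions = TRUE) {
  stopifnot(inherits(ms, "merged_study"))
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must lie in (0, 1]")
  meta <- ms$metadata
  missing <- setdiff(factors, names(meta))
  if (length(missing) > 0)
    stop("factors not in metadata: ", paste(missing, collapse = ", "))
  fac <- lapply(setNames(factors, factors), function(f) factor(meta[[f]]))
  single <- vapply(fac, nlevels, 1L) < 2
  if (any(single)) {
    warning("excluding single-level factor(s): ",
            paste(names(fac)[single], collapse = ", "))
    fac <- fac[!single]
  }
  if (length(fac) == 0) stop("no usable factors left")

  v <- ms$values
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    v <- v[sds > 0, , drop = FALSE]
    warning(sum(sds == 0), " zero-variance gene(s) dropped before PVCA")
  }
  z <- (v - rowMeans(v)) / apply(v, 1, sd)
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  prop <- eig / sum(eig)
  n_keep <- max(1L, which(cumsum(prop) >= variance_threshold)[1])

  terms <- names(fac)
  if (include_interactions && length(fac) >= 2) {
    cmb <- utils::combn(names(fac), 2)
    for (k in seq_len(ncol(cmb))) {
      nm <- paste(cmb[1, k], cmb[2, k], sep = ":")
      fac[[nm]] <- interaction(fac[[cmb[1, k]]], fac[[cmb[2, k]]], drop = TRUE)
      terms <- c(terms, nm)
    }
  }
  df <- as.data.frame(fac, check.names = FALSE)
  form <- stats::as.formula(paste(
    "y ~", paste(sprintf("(1 | `%s`)", terms), collapse = " + ")))

  comp_props <- matrix(0, n_keep, length(terms) + 1L,
                       dimnames = list(NULL, c(terms, "residual")))
  for (k in seq_len(n_keep)) {
    df$y <- pc$x[, k]
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(form, data = df, REML = TRUE,
                   control = lme4::lmerControl(
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore",
                     calc.derivs = FALSE)))),
      error = function(e)
        stop("variance-component model is singular for component ", k,
             ": ", conditionMessage(e)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vars <- setNames(pmax(vc$vcov, 0),
                     ifelse(vc$grp == "Residual", "residual", vc$grp))
    comp_props[k, names(vars)] <- vars / sum(vars)
  }
  w <- eig[seq_len(n_keep)] / sum(eig[seq_len(n_keep)])
  overall <- colSums(comp_props * w)
  overall <- overall / sum(overall)
  res <- data.frame(factor = names(overall),
                    proportion = unname(overall),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$proportion), ]
  rownames(res) <- NULL
  structure(res,
            class = c("pvca_result", "data.frame"),
            n_components = n_keep,
            eigenvalues = eig,
            variance_threshold = variance_threshold,
            per_component = comp_props)
}

#' @export
print.pvca_result <- function(x, ...) {
  cat(sprintf("PVCA over %d principal component(s) (threshold %.2f)\n",
              attr(x, "n_components"), attr(x, "variance_threshold")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Bar plot of PVCA variance proportions
#'
#' @param pv a [pvca()] result, or a named list of them (e.g.
#'   \code{list(before = ..., after = ...)}) for side-by-side comparison.
#' @return a ggplot object.
#' @export
plot_pvca <- function(pv) {
  if (inherits(pv, "pvca_result")) pv <- list(pvca = pv)
  df <- do.call(rbind, lapply(names(pv), function(nm) {
    data.frame(run = nm, factor = pv[[nm]]$factor,
               proportion = pv[[nm]]$proportion)
  }))
  df$factor <- factor(df$factor, levels = unique(df$factor))
  proportion <- run <- NULL # NSE bindings
  ggplot2::ggplot(df, ggplot2::aes(x = factor, y = proportion, fill = run)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "weighted variance proportion") +
    ggplot2::theme_minimal()
}
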