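#' Empirical-Bayes batch correction (parametric location/scale model)
#'
#' Removes additive and multiplicative batch effects from a merged study by
#' the parametric empirical-Bayes procedure of the classic location/scale
#' batch model: gene-wise standardization against a pooled fit (grand mean,
#' optional covariates, batch means weighted by batch size), per-batch
#' gene-wise location/scale estimates, shrinkage of those estimates toward
#' method-of-moments priors (normal prior on locations, inverse-gamma on
#' scales, conditional posterior means solved iteratively to convergence),
#' then adjustment and back-transformation.
#'
#' @param ms a [merged_study].
#' @param batch_factor metadata column naming the batch (default
#'   \code{"platform"}).
#' @param covariates optional character vector of metadata columns to
#'   protect as fixed effects during standardization (e.g. \code{"state"});
#'   must not be confounded with batch.
#' @param conv convergence tolerance of the EB fixed point.
#' @param max_iter iteration cap for the fixed point.
#' @return a [merged_study] with corrected values (same shape and labels).
#'   The EB fit (raw and shrunken batch estimates, hyperparameters) is
#'   attached as attribute \code{"combat_fit"}.
#' @export
combat <- function(ms, batch_factor = "platform", covariates = NULL,
                   conv = 1e-4, max_iter = 100L) {
  stopifnot(inherits(ms, "merged_study"))
  meta <- ms$metadata
  if (!batch_factor %in% names(meta))
    stop("batch factor '", batch_factor, "' not found in metadata")
  batch <- factor(meta[[batch_factor]])
  n_batch <- nlevels(batch)
  if (n_batch < 2)
    stop("batch correction needs at least 2 batches; '", batch_factor,
         "' has ", n_batch)
  n_per <- table(batch)
  if (any(n_per < 2))
    stop("each batch needs at least 2 samples; too small: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))

  dat <- ms$values
  n_array <- ncol(dat)
  batchmod <- model.matrix(~ -1 + batch)
  design <- batchmod
  if (!is.null(covariates)) {
    missing <- setdiff(covariates, names(meta))
    if (length(missing) > 0)
      stop("covariates not in metadata: ", paste(missing, collapse = ", "))
    covdf <- as.data.frame(lapply(meta[covariates], factor))
    mod <- model.matrix(~ ., data = covdf)[, -1, drop = FALSE]
    design <- cbind(batchmod, mod)
  }
  if (qr(design)$rank < ncol(design)) {
    offender <- if (is.null(covariates)) "batch" else
      paste(covariates, collapse = "/")
    stop("design matrix is rank deficient: covariate(s) ", offender,
         " confounded with batch")
  }

  var_zero <- apply(dat, 1, var) == 0
  if (any(var_zero))
    stop("zero-variance genes cannot be standardized: ",
         paste(head(rownames(dat)[var_zero], 5), collapse = ", "))

  ## pooled model fit and gene-wise standardization
  B_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- crossprod(as.numeric(n_per) / n_array,
                          B_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- rowMeans((dat - t(design %*% B_hat))^2)
  stand_mean <- t(grand_mean) %*% t(rep(1, n_array))
  if (ncol(design) > n_batch) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  ## per-batch location/scale estimates
  batches <- lapply(levels(batch), function(b) which(batch == b))
  gamma_hat <- t(solve(crossprod(batchmod), t(batchmod) %*% t(s_data)))
  delta_hat <- vapply(batches, function(ix)
    apply(s_data[, ix, drop = FALSE], 1, var), numeric(nrow(dat)))

  ## method-of-moments EB hyperparameters
  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, var)
  aprior <- apply(delta_hat, 2, function(dh) {
    m <- mean(dh); s2 <- var(dh); (2 * s2 + m^2) / s2
  })
  bprior <- apply(delta_hat, 2, function(dh) {
    m <- mean(dh); s2 <- var(dh); (m * s2 + m^3) / s2
  })

  gamma_star <- matrix(0, nrow(dat), n_batch)
  delta_star <- matrix(0, nrow(dat), n_batch)
  for (i in seq_len(n_batch)) {
    fit <- eb_fixed_point(s_data[, batches[[i]], drop = FALSE],
                          gamma_hat[, i], delta_hat[, i],
                          gamma_bar[i], t2[i], aprior[i], bprior[i],
                          conv = conv, max_iter = max_iter)
    gamma_star[, i] <- fit$gamma
    delta_star[, i] <- fit$delta
  }
  if (any(delta_star <= 0))
    stop("shrunken batch scales are not strictly positive")

  bayes <- s_data
  for (i in seq_len(n_batch)) {
    ix <- batches[[i]]
    bayes[, ix] <- (bayes[, ix, drop = FALSE] - gamma_star[, i]) /
      sqrt(delta_star[, i])
  }
  corrected <- bayes * sqrt(var_pooled) + stand_mean

  out <- ms
  out$values <- corrected
  out$report$combat <- list(batch_factor = batch_factor,
                            covariates = covariates,
                            n_batches = n_batch)
  attr(out, "combat_fit") <- list(
    batch_levels = levels(batch),
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_bar = gamma_bar, t2 = t2,
    a_prior = aprior, b_prior = bprior,
    grand_mean = as.numeric(grand_mean),
    var_pooled = var_pooled)
  out
}

## Iterative solution of the conditional posterior means for one batch:
## normal posterior for the location given the scale, inverse-gamma
## posterior mean for the scale given the location.
eb_fixed_point <- function(sdat, g_hat, d_hat, g_bar, t2, a, b,
                           conv = 1e-4, max_iter = 100L) {
  n <- ncol(sdat)
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((sdat - g_new)^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / abs(g_old),
                  abs(d_new - d_old) / abs(d_old))
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(gamma = g_old, delta = d_old, iterations = it)
}
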