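# Shared fixtures. Prepared default-design studies are cached per seed so
# property tests that sweep seeds reuse one preparation.

.study_cache <- new.env(parent = emptyenv())

# generate -> collapse -> merge -> combat -> IQR filter for the default design
prepared_study <- function(seed = 1L, hub_mode = "single_hub") {
  key <- paste0(hub_mode, "_", seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  st <- generate_two_platform_study(synthetic_design(seed = seed,
                                                     hub_mode = hub_mode))
  ms <- intersect_and_merge(collapse_probes(st$platform_a),
                            collapse_probes(st$platform_b),
                            st$metadata)
  cc <- combat(ms)
  out <- list(study = st, truth = st$truth, merged = ms,
              corrected = cc, filtered = iqr_filter(cc, 0.5))
  .study_cache[[key]] <- out
  out
}

# a small fast design for determinism / probe-level checks
small_design <- function(seed = 1L, ...) {
  args <- list(n_genes = 60, shared_gene_fraction = 1,
               probes_per_gene = c(1L, 2L), samples_per_cell = 2L,
               module_sizes = c(12L, 10L), hub_module_index = 2L,
               n_template_followers = 5L, seed = seed)
  do.call(synthetic_design, utils::modifyList(args, list(...)))
}

# 60-sample single-module contrast dataset: both platforms pooled (no
# planted batch), restricted to the hub module's genes
contrast_module_matrix <- function(seed, mode) {
  st <- generate_two_platform_study(
    synthetic_design(n_genes = 120, shared_gene_fraction = 1,
                     probes_per_gene = c(1L, 1L), samples_per_cell = 6L,
                     module_sizes = c(20L, 60L), hub_module_index = 2L,
                     n_template_followers = 0L, batch_shift = 0,
                     batch_scale = 1, seed = seed, hub_mode = mode))
  gs <- st$truth$module_genes[[2]]
  v <- cbind(collapse_probes(st$platform_a)$values[gs, ],
             collapse_probes(st$platform_b)$values[gs, ])
  list(values = v, hub = st$truth$hub_gene)
}

# hand-built merged study from a plain matrix (two pseudo-platforms)
toy_study <- function(values, platforms = NULL, states = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", 1:n)
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%03d", 1:nrow(values))
  meta <- data.frame(
    sample_id = colnames(values),
    platform = if (is.null(platforms)) rep(c("A", "B"), length.out = n) else platforms,
    state = if (is.null(states)) rep(c("naive", "extreme"), length.out = n) else states,
    group = "grp", timepoint = 7, stringsAsFactors = FALSE)
  merged_study(values, meta)
}

# independent brute-force TOM: literal triple loop over the formula
brute_force_tom <- function(a) {
  n <- nrow(a)
  w <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  w
}

# random valid unsigned adjacency from random expression data
random_adjacency <- function(n_genes, n_samples = 8, beta = 4) {
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  rownames(x) <- sprintf("g%02d", seq_len(n_genes))
  a <- abs(cor(t(x)))^beta
  diag(a) <- 1
  a
}

# two-sided Fisher p by full hypergeometric enumeration over fixed margins
enumerate_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  obs <- dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
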