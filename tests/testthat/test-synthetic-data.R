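test_that("identical seeds give bit-identical studies", {
  a <- generate_two_platform_study(small_design(seed = 7))
  b <- generate_two_platform_study(small_design(seed = 7))
  expect_identical(a$platform_a$values, b$platform_a$values)
  expect_identical(a$platform_b$values, b$platform_b$values)
  expect_identical(a$truth$module_membership, b$truth$module_membership)
  c <- generate_two_platform_study(small_design(seed = 8))
  expect_false(identical(a$platform_a$values, c$platform_a$values))
})

test_that("emitted values are finite and truth is consistent with matrices", {
  st <- generate_two_platform_study(small_design(seed = 2))
  expect_true(all(is.finite(st$platform_a$values)))
  expect_true(all(is.finite(st$platform_b$values)))
  tr <- st$truth
  expect_equal(unname(table(tr$module_membership[tr$module_membership > 0])),
               unname(as.integer(lengths(tr$module_genes))),
               ignore_attr = TRUE)
  expect_true(tr$hub_gene %in% tr$module_genes[[tr$design$hub_module_index]])
  expect_false(tr$template_gene %in% tr$follower_genes)
  ## the flagged max-signal probe really carries the max mean, and exactly
  ## one probe per gene is flagged
  for (pm in list(st$platform_a, st$platform_b)) {
    pt <- tr$probe_map_truth[tr$probe_map_truth$platform == pm$platform_id &
                               !is.na(tr$probe_map_truth$gene), ]
    means <- rowMeans(pm$values)[pt$probe_id]
    best_by_gene <- tapply(means, pt$gene, max)
    flagged <- pt[pt$is_max_signal, ]
    expect_equal(sort(flagged$gene), sort(names(best_by_gene)))
    expect_equal(as.numeric(means[flagged$probe_id]),
                 as.numeric(best_by_gene[flagged$gene]))
  }
})

test_that("without planted batch, shared-gene platform means agree to sampling noise", {
  d <- small_design(seed = 5, batch_shift = 0, batch_scale = 1,
                    samples_per_cell = 4L)
  st <- generate_two_platform_study(d)
  gm_a <- collapse_probes(st$platform_a)
  gm_b <- collapse_probes(st$platform_b)
  common <- intersect(gm_a$gene_symbols, gm_b$gene_symbols)
  ## background genes only: module genes differ between platforms through
  ## independent factor draws, background only through iid noise
  bg <- common[st$truth$module_membership[common] == 0 &
                 !common %in% c(st$truth$follower_genes, st$truth$template_gene)]
  delta <- rowMeans(gm_a$values[bg, ]) - rowMeans(gm_b$values[bg, ])
  se <- sqrt(apply(gm_a$values[bg, ], 1, var) / ncol(gm_a$values) +
               apply(gm_b$values[bg, ], 1, var) / ncol(gm_b$values))
  expect_gt(mean(abs(delta) < 4 * se), 0.95)
})

test_that("planted hub-member correlation matches its target (Fisher z coverage)", {
  hits <- 0L
  zcrit <- qnorm(0.995)
  for (seed in 1:20) {
    st <- generate_two_platform_study(
      synthetic_design(n_genes = 80, shared_gene_fraction = 1,
                       probes_per_gene = c(1L, 1L), samples_per_cell = 6L,
                       module_sizes = c(10L, 20L), hub_module_index = 2L,
                       n_template_followers = 2L, seed = seed))
    gm <- collapse_probes(st$platform_a)
    gm_b <- collapse_probes(st$platform_b)
    v <- cbind(gm$values, gm_b$values)   # no batch removal needed for cor
    ## use platform A only so the batch model cannot distort correlations
    v <- gm$values
    hub <- st$truth$hub_gene
    member <- st$truth$module_genes[[2]][7]
    r <- cor(v[hub, ], v[member, ])
    n <- ncol(v)
    z <- atanh(r); z0 <- atanh(0.9)
    if (abs(z - z0) < zcrit / sqrt(n - 3)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("infeasible designs are rejected", {
  expect_error(synthetic_design(hub_strength = 0.999), "unattainable")
  expect_error(synthetic_design(within_module_cor = 1.2), "inside")
  expect_error(synthetic_design(module_sizes = c(1000, 900)), "exceeds")
  expect_error(synthetic_design(noise_sd = 0), "noise_sd")
  expect_error(synthetic_design(hub_module_index = 9), "out of range")
  expect_error(synthetic_design(n_genes = 1200, shared_gene_fraction = 0.1),
               "not enough shared genes")
})

test_that("peak table honours forced enrichment fractions", {
  st <- generate_two_platform_study(small_design(seed = 3))
  tr <- st$truth
  loci <- generate_gene_loci(names(tr$module_membership))
  mod <- names(tr$module_membership)[tr$module_membership ==
                                       tr$peak_enriched_module]
  ## every module gene hit, no background gene hit
  pk <- generate_peak_table(tr, loci, enrich_fraction_in = 1.0,
                            enrich_fraction_out = 1e-9, seed = 4)
  expect_equal(nrow(pk), length(mod))
  flags <- annotate_peaks_to_genes(pk, loci, max_distance = 1000,
                                   min_score = 0)
  expect_true(all(flags$has_peak[flags$gene %in% mod]))
  expect_false(any(flags$has_peak[!flags$gene %in% mod]))
  expect_true(all(pk$start < pk$end))
  expect_error(generate_peak_table(tr, loci, 0.05, 0.5, seed = 1),
               "must exceed")
  expect_error(generate_peak_table(tr, loci[-1, ], 0.5, 0.05, seed = 1),
               "cover")
})

test_that("planted peak enrichment gives the downstream Fisher test power", {
  d <- synthetic_design(n_genes = 1000, shared_gene_fraction = 1,
                        probes_per_gene = c(1L, 1L), samples_per_cell = 1L,
                        module_sizes = c(200L, 10L), hub_module_index = 2L,
                        n_template_followers = 0L, seed = 1)
  st <- generate_two_platform_study(d)
  tr <- st$truth
  tr$peak_enriched_module <- 1L       # the 200-gene module
  loci <- generate_gene_loci(names(tr$module_membership))
  mod <- names(tr$module_membership)[tr$module_membership == 1L]
  bg <- sample(setdiff(names(tr$module_membership), mod), 800)
  rejections <- 0L
  for (seed in 1:20) {
    pk <- generate_peak_table(tr, loci, enrich_fraction_in = 0.5,
                              enrich_fraction_out = 0.05, seed = seed)
    flags <- annotate_peaks_to_genes(pk, loci, max_distance = 1000,
                                     min_score = 0)
    enr <- module_peak_enrichment(flags, mod, bg)
    if (enr$p_value < 0.01) rejections <- rejections + 1L
  }
  expect_gte(rejections, 19L)
})

test_that("truth_partition exposes modules plus the follower block", {
  st <- generate_two_platform_study(small_design(seed = 1))
  part <- truth_partition(st$truth)
  tr <- st$truth
  expect_equal(sum(part == 3), length(tr$follower_genes) + 1L)
  expect_equal(part[tr$template_gene], c(TPL1 = 3L))
  expect_error(truth_partition(tr, genes = "NOPE"), "unknown genes")
})
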