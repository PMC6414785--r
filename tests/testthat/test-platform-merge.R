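make_pm <- function(values, symbols, platform = "A") {
  probe_matrix(values,
               data.frame(probe_id = rownames(values), symbol = symbols,
                          stringsAsFactors = FALSE),
               platform)
}

test_that("collapse keeps the max-mean probe, ties broken lexicographically", {
  v <- rbind(p1 = c(5.0, 5.4), p2 = c(6.0, 6.2), p3 = c(1, 2))
  colnames(v) <- c("s1", "s2")
  gm <- collapse_probes(make_pm(v, c("G", "G", "H")))
  expect_equal(gm$values["G", ], v["p2", ])            # mean 6.1 beats 5.2
  expect_equal(gm$provenance$probe_id[gm$provenance$gene == "G"], "p2")
  ## exact tie: same values -> smallest probe id wins
  v2 <- rbind(pB = c(1, 2), pA = c(1, 2))
  colnames(v2) <- c("s1", "s2")
  gm2 <- collapse_probes(make_pm(v2, c("G", "G")))
  expect_equal(gm2$provenance$probe_id, "pA")
})

test_that("collapse is the identity for one probe per gene, rows sorted by symbol", {
  v <- rbind(pz = c(1, 2), pa = c(3, 4))
  colnames(v) <- c("s1", "s2")
  gm <- collapse_probes(make_pm(v, c("ZZ", "AA")))
  expect_equal(rownames(gm$values), c("AA", "ZZ"))
  expect_equal(gm$values["ZZ", ], v["pz", ])
})

test_that("duplicated symbols collapse to one row each; unannotated dropped", {
  v <- matrix(rnorm(10 * 3), 10,
              dimnames = list(sprintf("p%02d", 1:10), c("s1", "s2", "s3")))
  sym <- c("A", "A", "B", "C", "C", "C", "D", "E", "F", "G")
  gm <- collapse_probes(make_pm(v, sym))
  expect_equal(nrow(gm$values), 7)
  gm2 <- collapse_probes(make_pm(v, c(sym[1:8], NA, NA)))
  expect_equal(nrow(gm2$values), 5)
  expect_equal(gm2$n_unannotated, 2)
  expect_error(collapse_probes(make_pm(v, rep(NA_character_, 10))),
               "unusable")
})

test_that("collapse on synthetic data recovers the truth-flagged probe for every gene", {
  st <- generate_two_platform_study(small_design(seed = 4))
  for (pm in list(st$platform_a, st$platform_b)) {
    gm <- collapse_probes(pm)
    pt <- st$truth$probe_map_truth
    flagged <- pt[pt$platform == pm$platform_id & pt$is_max_signal, ]
    expect_equal(sort(gm$provenance$probe_id), sort(flagged$probe_id))
  }
})

test_that("intersect_and_merge takes the sorted symbol intersection", {
  mk <- function(genes, samples, platform) {
    v <- matrix(seq_len(length(genes) * length(samples)),
                length(genes), dimnames = list(genes, samples))
    collapse_probes(make_pm(v, genes, platform))
  }
  gm_a <- mk(paste0("g", 1:5), paste0("a", 1:4), "A")
  gm_b <- mk(paste0("g", 3:7), paste0("b", 1:6), "B")
  meta <- data.frame(sample_id = c(paste0("a", 1:4), paste0("b", 1:6)),
                     platform = rep(c("A", "B"), c(4, 6)),
                     state = "naive", group = "g", timepoint = 0)
  ms <- intersect_and_merge(gm_a, gm_b, meta)
  expect_equal(dim(ms$values), c(3, 10))
  expect_equal(rownames(ms$values), c("g3", "g4", "g5"))
  expect_equal(ms$report$n_discarded_a, 2)
  ## identical gene sets: nothing discarded
  ms2 <- intersect_and_merge(gm_a, mk(paste0("g", 1:5), paste0("b", 1:2), "B"),
                             meta[c(1:4, 5:6), ])
  expect_equal(nrow(ms2$values), 5)
  ## disjoint: error
  expect_error(intersect_and_merge(gm_a, mk(paste0("x", 1:3), "b1", "B"), meta),
               "empty gene-universe")
  ## duplicate sample ids across platforms: error
  expect_error(intersect_and_merge(gm_a, mk(paste0("g", 1:5), "a1", "B"), meta),
               "duplicate sample ids")
})

test_that("quantile renormalization matches the hand-computed reference and is idempotent", {
  ms <- toy_study(cbind(c(1, 2, 3), c(6, 4, 5)))
  qn <- renormalize(ms, "quantile")
  expect_equal(unname(qn$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, 2]), c(4.5, 2.5, 3.5))
  ## every column has identical sorted values
  st <- prepared_study(1)
  q1 <- renormalize(st$merged, "quantile")
  sorted <- apply(q1$values, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
  q2 <- renormalize(q1, "quantile")
  expect_lt(max(abs(q2$values - q1$values)), 1e-9)
})

test_that("scale renormalization centers samples; zero-variance sample is named", {
  ms <- toy_study(matrix(rnorm(40, 5), 10))
  sc <- renormalize(ms, "scale")
  expect_lt(max(abs(colMeans(sc$values))), 1e-12)
  expect_equal(unname(apply(sc$values, 2, sd)), rep(1, 4))
  expect_identical(renormalize(ms, "none")$values, ms$values)
  bad <- toy_study(cbind(c(1, 1, 1), c(1, 2, 3)))
  expect_error(renormalize(bad, "scale"), "s01")
})

test_that("IQR filter follows the linear-interpolation quartile convention", {
  ms <- toy_study(rbind(a = c(1, 2, 3, 4), b = rep(2, 4), c = c(0, 0, 10, 10)))
  kept <- iqr_filter(ms, 0.5)
  expect_true("a" %in% rownames(kept$values))       # IQR(1:4) = 1.5
  expect_false("b" %in% rownames(kept$values))      # constant
  expect_equal(iqr_filter(ms, 0)$report$n_genes_dropped, 1)  # only constant
  ## monotone: raising the threshold never adds genes
  st <- prepared_study(1)
  g1 <- rownames(iqr_filter(st$corrected, 0.4)$values)
  g2 <- rownames(iqr_filter(st$corrected, 0.8)$values)
  expect_true(all(g2 %in% g1))
})

test_that("sample exclusion removes columns and metadata rows", {
  st <- prepared_study(1)
  ids <- colnames(st$merged$values)[1:5]
  out <- exclude_samples(st$merged, ids)
  expect_equal(ncol(out$values), 55)
  expect_false(any(ids %in% out$metadata$sample_id))
  expect_identical(exclude_samples(st$merged, character(0)), st$merged)
  expect_error(exclude_samples(st$merged, "nope"), "unknown sample ids")
  a_ids <- st$merged$metadata$sample_id[st$merged$metadata$platform == "A"]
  expect_warning(exclude_samples(st$merged, a_ids), "single platform")
})
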