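## small planted-module matrix built directly from the latent-factor form
planted_matrix <- function(sizes, within_cor = 0.7, n_samples = 60,
                           seed = 1, noise_bg = 0) {
  set.seed(seed)
  r <- sqrt(within_cor)
  rows <- list()
  for (m in seq_along(sizes)) {
    f <- rnorm(n_samples)
    rows[[m]] <- t(vapply(seq_len(sizes[m]), function(i)
      r * f + sqrt(1 - r^2) * rnorm(n_samples), numeric(n_samples)))
  }
  if (noise_bg > 0)
    rows[[length(rows) + 1]] <- matrix(rnorm(noise_bg * n_samples),
                                       noise_bg, n_samples)
  v <- do.call(rbind, rows)
  dimnames(v) <- list(sprintf("g%04d", seq_len(nrow(v))),
                      sprintf("s%03d", seq_len(n_samples)))
  v
}

test_that("planted modules are recovered with high ARI; colours follow size rank", {
  v <- planted_matrix(c(100, 60, 40), within_cor = 0.7, seed = 9)
  run <- analyze_coexpression(v, beta = 6)
  truth <- rep(seq_along(c(100, 60, 40)), c(100, 60, 40))
  ari <- mclust::adjustedRandIndex(truth, run$assignment$label)
  expect_gt(ari, 0.9)
  sizes <- table(run$assignment$label[run$assignment$label > 0])
  expect_true(all(diff(as.integer(sizes)) <= 0))
  expect_equal(run$assignment$color[run$assignment$label == 2][1], "blue")
  expect_equal(run$assignment$color[run$assignment$label == 1][1], "turquoise")
})

test_that("identical-profile genes land in one module at zero dissimilarity", {
  base <- rnorm(30)
  v <- rbind(t(vapply(1:35, function(i) base + rnorm(30, sd = 1e-6),
                      numeric(30))),
             matrix(rnorm(40 * 30), 40, 30))
  dimnames(v) <- list(sprintf("g%03d", 1:75), sprintf("s%02d", 1:30))
  nm <- tom_similarity(adjacency_matrix(v, beta = 6))
  asg <- detect_modules(nm, min_module_size = 30)
  labs <- asg$label[1:35]
  expect_equal(length(unique(labs)), 1)
  expect_gt(labs[1], 0)
})

test_that("pure-noise genes stay unassigned", {
  unassigned_ok <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    v <- matrix(rnorm(150 * 25), 150, 25,
                dimnames = list(sprintf("g%03d", 1:150), sprintf("s%02d", 1:25)))
    nm <- tom_similarity(adjacency_matrix(v, beta = 6))
    asg <- suppressWarnings(detect_modules(nm, min_module_size = 30))
    if (mean(asg$label == 0) >= 0.8) unassigned_ok <- unassigned_ok + 1L
  }
  expect_gte(unassigned_ok, 18L)
})

test_that("module detection is invariant to gene input order", {
  v <- planted_matrix(c(40, 30), seed = 4, noise_bg = 20)
  r1 <- analyze_coexpression(v, beta = 6)
  set.seed(1)
  perm <- sample(nrow(v))
  r2 <- analyze_coexpression(v[perm, ], beta = 6)
  l1 <- setNames(r1$assignment$label, r1$assignment$gene)
  l2 <- setNames(r2$assignment$label, r2$assignment$gene)[names(l1)]
  expect_equal(mclust::adjustedRandIndex(l1, l2), 1)
})

test_that("eigengene closed forms: single profile, orientation, two-gene module", {
  base <- seq(-2, 2, length.out = 20)
  v <- rbind(g1 = 3 * base + 5, g2 = -base + 1, g3 = 0.5 * base)
  colnames(v) <- sprintf("s%02d", 1:20)
  asg <- structure(data.frame(gene = rownames(v), label = 1L,
                              color = "turquoise"),
                   class = c("module_assignment", "data.frame"))
  eig <- module_eigengenes(v, asg)
  e <- unclass(eig)[1, ]
  expect_equal(sum(e^2), 1, tolerance = 1e-12)
  expect_equal(abs(cor(e, base)), 1, tolerance = 1e-12)
  expect_equal(unname(attr(eig, "variance_explained")), 1, tolerance = 1e-12)
  ## orientation: mean correlation with genes is non-negative, and flipping
  ## the genes flips the eigengene
  expect_gte(mean(cor(e, t(v))), 0)
  eig2 <- module_eigengenes(-v, asg)
  expect_equal(unclass(eig2)[1, ], -e, tolerance = 1e-10)
  ## two-gene module with cor r: variance explained = (1 + r)/2
  set.seed(8)
  f <- rnorm(500)
  g_a <- f
  g_b <- 0.8 * f + sqrt(1 - 0.64) * rnorm(500)
  v2 <- rbind(a = g_a, b = g_b)
  colnames(v2) <- sprintf("s%03d", 1:500)
  asg2 <- structure(data.frame(gene = c("a", "b"), label = 1L, color = "turquoise"),
                    class = c("module_assignment", "data.frame"))
  r_ab <- cor(g_a, g_b)
  expect_equal(unname(attr(module_eigengenes(v2, asg2), "variance_explained")),
               (1 + r_ab) / 2, tolerance = 1e-10)
  ## degenerate module errors
  vc <- rbind(a = rep(1, 10), b = rnorm(10))
  colnames(vc) <- paste0("s", 1:10)
  expect_error(module_eigengenes(vc, asg2), "degenerate")
})

test_that("eigengene-based merging respects the merge distance", {
  set.seed(5)
  n <- 80
  f <- rnorm(n)
  mk <- function(f_mod, size, r = 0.9)
    t(vapply(seq_len(size), function(i) r * f_mod + sqrt(1 - r^2) * rnorm(n),
             numeric(n)))
  ## modules 1 and 2 share a factor (eigengene cor ~0.9); module 3 independent
  shared <- f
  v <- rbind(mk(shared, 40), mk(0.97 * shared + sqrt(1 - 0.97^2) * rnorm(n), 30),
             mk(rnorm(n), 30))
  dimnames(v) <- list(sprintf("g%03d", 1:100), sprintf("s%03d", 1:n))
  asg <- structure(data.frame(gene = rownames(v),
                              label = rep(c(1L, 2L, 3L), c(40, 30, 30)),
                              color = rep(c("turquoise", "blue", "brown"),
                                          c(40, 30, 30))),
                   class = c("module_assignment", "data.frame"))
  merged <- merge_close_modules(v, asg, merge_distance = 0.25)
  labs <- merged$label
  expect_equal(length(unique(labs)), 2)                 # 1+2 merged, 3 apart
  expect_equal(length(unique(labs[1:70])), 1)
  expect_equal(unname(labs[1]), 1L)                     # merged module largest
  ## fixed point: all remaining eigengene dissimilarities >= merge distance
  eig <- module_eigengenes(v, merged)
  dd <- 1 - cor(t(unclass(eig)))
  expect_true(all(dd[upper.tri(dd)] >= 0.25))
  ## far modules (cor ~0.5) do not merge
  v2 <- rbind(mk(f, 30), mk(0.5 * f + sqrt(0.75) * rnorm(n), 30))
  dimnames(v2) <- list(sprintf("g%03d", 1:60), sprintf("s%03d", 1:n))
  asg2 <- structure(data.frame(gene = rownames(v2),
                               label = rep(c(1L, 2L), each = 30),
                               color = rep(c("turquoise", "blue"), each = 30)),
                    class = c("module_assignment", "data.frame"))
  expect_equal(length(unique(merge_close_modules(v2, asg2, 0.25)$label)), 2)
  ## three mutually close modules collapse to one
  v3 <- rbind(mk(f, 30, 0.95), mk(0.96 * f + sqrt(1 - 0.96^2) * rnorm(n), 25, 0.95),
              mk(0.97 * f + sqrt(1 - 0.97^2) * rnorm(n), 20, 0.95))
  dimnames(v3) <- list(sprintf("g%03d", 1:75), sprintf("s%03d", 1:n))
  asg3 <- structure(data.frame(gene = rownames(v3),
                               label = rep(1:3, c(30, 25, 20)),
                               color = rep(c("turquoise", "blue", "brown"),
                                           c(30, 25, 20))),
                    class = c("module_assignment", "data.frame"))
  expect_equal(length(unique(merge_close_modules(v3, asg3, 0.25)$label)), 1)
})

test_that("connectivity: star topology, ties, and the planted hub", {
  ## star: center connected at 0.9 to 10 leaves, leaves unconnected
  n <- 11
  a <- matrix(0, n, n, dimnames = list(c("center", paste0("leaf", 1:10)),
                                       c("center", paste0("leaf", 1:10))))
  a["center", -1] <- 0.9; a[-1, "center"] <- 0.9
  diag(a) <- 1
  nm <- structure(list(genes = rownames(a), beta = 1, adjacency = a,
                       tom = NULL, type = "unsigned"), class = "network_model")
  asg <- structure(data.frame(gene = rownames(a), label = 1L, color = "turquoise"),
                   class = c("module_assignment", "data.frame"))
  conn <- intramodular_connectivity(nm, asg)
  expect_equal(conn$table$kWithin[conn$table$gene == "center"], 9.0)
  expect_equal(conn$hubs$hub_gene, "center")
  ## two-gene tie: lexicographic hub
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("gB", "gA"), c("gB", "gA")))
  nm2 <- structure(list(genes = rownames(a2), beta = 1, adjacency = a2,
                        tom = NULL, type = "unsigned"), class = "network_model")
  asg2 <- structure(data.frame(gene = c("gB", "gA"), label = 1L, color = "turquoise"),
                    class = c("module_assignment", "data.frame"))
  conn2 <- intramodular_connectivity(nm2, asg2)
  expect_equal(conn2$table$kWithin, c(0.4, 0.4))
  expect_equal(conn2$hubs$hub_gene, "gA")
  ## planted hub attains max kWithin in its own module across seeds
  hits <- 0L
  for (seed in 1:20) {
    st <- prepared_study(seed)
    run <- analyze_coexpression(st$filtered$values)
    hubs <- run$connectivity$hubs
    lab <- run$assignment$label[run$assignment$gene == st$truth$hub_gene]
    if (lab > 0 && hubs$hub_gene[hubs$label == lab] == st$truth$hub_gene)
      hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("edge export: strict threshold, full export, hub degree dominance", {
  w <- matrix(c(1, 0.42, 0.41, 0.42, 1, 0.40, 0.41, 0.40, 1), 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  nm <- structure(list(genes = rownames(w), beta = 1, adjacency = w, tom = w,
                       type = "unsigned"), class = "network_model")
  asg <- structure(data.frame(gene = rownames(w), label = 1L, color = "turquoise"),
                   class = c("module_assignment", "data.frame"))
  ed <- export_module_edges(nm, asg, 1, weight_threshold = 0.41)
  expect_equal(nrow(ed), 1)                       # only 0.42 survives strict >
  expect_equal(ed$weight, 0.42)
  ed0 <- export_module_edges(nm, asg, 1, weight_threshold = 0)
  expect_equal(nrow(ed0), 3 * 2 / 2)
  ## hub-driven synthetic module: hub has the max degree at the top-decile
  ## threshold, and at least twice the median member degree
  st <- prepared_study(21)
  run <- analyze_coexpression(st$filtered$values)
  blue <- run$assignment$label[run$assignment$gene == st$truth$hub_gene]
  gs <- module_genes(run$assignment, blue)
  wsub <- run$network$tom[gs, gs]
  thr <- quantile(wsub[upper.tri(wsub)], 0.9, names = FALSE)
  edh <- export_module_edges(run$network, run$assignment, blue, thr)
  deg <- attr(edh, "degree")
  expect_equal(names(which.max(deg)), st$truth$hub_gene)
  expect_gte(deg[st$truth$hub_gene], 2 * median(deg[names(deg) != st$truth$hub_gene]))
})

test_that("hub-collapse contrast: dominant hub degree only in the hub-driven regime", {
  ## hub-driven regime: the regulator is the top-degree gene with at least
  ## twice the median member degree; two-factor regime: the same regulator
  ## loses the hub property outright (degree at or below the median, never
  ## the maximum)
  hub_ok <- 0L; flat_ok <- 0L
  for (seed in 1:20) {
    for (mode in c("single_hub", "two_factor")) {
      cm <- contrast_module_matrix(seed, mode)
      w <- tom_similarity(adjacency_matrix(cm$values, beta = 6))$tom
      thr <- quantile(w[upper.tri(w)], 0.9, names = FALSE)
      deg <- rowSums(w > thr) - 1
      if (mode == "single_hub") {
        if (names(which.max(deg)) == cm$hub &&
            deg[cm$hub] >= 2 * median(deg[names(deg) != cm$hub]))
          hub_ok <- hub_ok + 1L
      } else {
        if (deg[cm$hub] <= median(deg) && names(which.max(deg)) != cm$hub)
          flat_ok <- flat_ok + 1L
      }
    }
  }
  expect_gte(hub_ok, 18L)
  expect_gte(flat_ok, 18L)
})

test_that("module overlap counts and hypergeometric tail", {
  u <- sprintf("g%02d", 1:20)
  a <- u[1:5]
  ov <- module_overlap(a, a, u)
  expect_equal(ov$overlap, 5)
  expect_equal(ov$jaccard, 1)
  expect_equal(ov$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  ov2 <- module_overlap(u[1:5], u[6:10], u)
  expect_equal(ov2$overlap, 0)
  expect_error(module_overlap(a, a, character(0)), "empty gene universe")
  expect_error(module_overlap(c(a, "zz"), a, u), "universe must contain")
  ## restriction applies before counting
  ov3 <- module_overlap(u[1:5], u[3:8], u, restrict_to = u[4:6])
  expect_equal(ov3$n_a, 2)
  expect_equal(ov3$overlap, 2)
})
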