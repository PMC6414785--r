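#' Generate a two-platform probe-level study with planted structure
#'
#' Simulates gene-level log2 expression under a latent-factor module model,
#' injects platform batch effects (gene-wise additive offset + variance
#' inflation on platform B), expands genes to probes with a fixed offset
#' ladder (the top-rung probe is the "max signal" probe), and returns
#' probe-level matrices for both platforms together with sample metadata and
#' a ground-truth record.
#'
#' Gene model, per sample j: background genes are
#' \eqn{x = \mu_g + \sigma \epsilon}; a member of module m is
#' \eqn{x = \mu_g + c_g f_{mj} + \sigma \epsilon} with the loading chosen so
#' the population member-member correlation equals the design target given
#' the factor's total variance (unit latent variance plus the state-shift
#' pattern variance under the sample design). The hub gene is its module's
#' factor plus a small residual (r = 0.995 with the factor), and members'
#' loadings are set so the population hub-member correlation equals
#' \code{hub_strength}. In \code{two_factor} mode the same module is driven
#' by two independent latent factors (half the members each), with the
#' regulator gene loading equally on both - same within-half correlation,
#' no single hub.
#'
#' @param design a [synthetic_design()].
#' @return a list of class \code{synthetic_study} with elements
#'   \code{platform_a}, \code{platform_b} (class \code{probe_matrix}),
#'   \code{metadata} (data.frame: sample_id, platform, state, group,
#'   timepoint) and \code{truth} (class \code{synthetic_truth}).
#' @export
generate_two_platform_study <- function(design) {
  validate_synthetic_design(design)
  set.seed(design$seed)
  d <- design
  sigma <- d$noise_sd

  meta <- build_metadata(d)
  n_samp <- nrow(meta)

  ## ---- gene universe -------------------------------------------------
  n_shared <- round(d$shared_gene_fraction * d$n_genes)
  n_private <- d$n_genes - n_shared
  n_priv_a <- floor(n_private / 2)
  n_priv_b <- n_private - n_priv_a
  shared <- sprintf("G%04d", seq_len(n_shared))
  priv_a <- if (n_priv_a > 0) sprintf("PA%04d", seq_len(n_priv_a)) else character(0)
  priv_b <- if (n_priv_b > 0) sprintf("PB%04d", seq_len(n_priv_b)) else character(0)

  n_mod <- length(d$module_sizes)
  membership <- setNames(rep(0L, length(c(shared, priv_a, priv_b))),
                         c(shared, priv_a, priv_b))
  pos <- 0L
  module_genes <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    module_genes[[m]] <- shared[pos + seq_len(d$module_sizes[m])]
    membership[module_genes[[m]]] <- m
    pos <- pos + d$module_sizes[m]
  }
  followers <- shared[pos + seq_len(d$n_template_followers)]
  pos <- pos + d$n_template_followers
  template_slot <- shared[pos + 1L]
  ## rename the template slot to the requested symbol
  all_syms <- c(shared, priv_a, priv_b)
  all_syms[all_syms == template_slot] <- d$template_gene
  shared[shared == template_slot] <- d$template_gene
  names(membership) <- all_syms
  template <- d$template_gene
  hub_gene <- module_genes[[d$hub_module_index]][1L]

  ## ---- latent factors -------------------------------------------------
  state_idx <- match(meta$state, d$states)
  pattern_var <- function(shift) {
    w <- tabulate(state_idx, nbins = length(d$states)) / n_samp
    sum(w * shift^2) - sum(w * shift)^2
  }
  factors <- matrix(0, n_mod, n_samp)
  fac_var <- numeric(n_mod)
  for (m in seq_len(n_mod)) {
    shift <- d$state_shift[[m]]
    factors[m, ] <- shift[state_idx] + rnorm(n_samp)
    fac_var[m] <- 1 + pattern_var(shift)
  }
  f_template <- rnorm(n_samp)                     # state-independent program
  two_factor <- d$hub_mode == "two_factor"
  if (two_factor) {
    f_hub_a <- rnorm(n_samp)
    f_hub_b <- rnorm(n_samp)
  }

  ## loading for target pairwise r given factor variance v: the gene-factor
  ## correlation must be sqrt(rho), i.e. c = sigma * sqrt(rho / ((1-rho) v))
  loading <- function(rho, v, noise = sigma) noise * sqrt(rho / ((1 - rho) * v))
  anchor_load <- function(v, noise) {            # gene-factor r = .995
    noise * .ANCHOR_R / sqrt((1 - .ANCHOR_R^2) * v)
  }

  ## ---- gene-level expression ------------------------------------------
  genes <- all_syms
  n_gene <- length(genes)
  mu <- setNames(runif(n_gene, 6, 12), genes)
  X <- matrix(rnorm(n_gene * n_samp, sd = sigma), n_gene, n_samp,
              dimnames = list(genes, meta$sample_id))

  r_member_nonhub <- sqrt(d$within_module_cor)
  r_member_hub <- d$hub_strength / .ANCHOR_R
  hub_noise <- 0.1 * sigma

  for (m in seq_len(n_mod)) {
    gs <- module_genes[[m]]
    if (m == d$hub_module_index) {
      if (two_factor) {
        ## exhaustion-like: two independent state-free factors, no hub;
        ## the regulator loads equally on both
        u <- (f_hub_a + f_hub_b) / sqrt(2)
        X[gs[1L], ] <- anchor_load(1, hub_noise) * u +
          rnorm(n_samp, sd = hub_noise)
        rest <- gs[-1L]
        half <- seq_len(ceiling(length(rest) / 2))
        c_m <- loading(r_member_hub^2, 1)
        X[rest[half], ] <- X[rest[half], ] +
          tcrossprod(rep(c_m, length(half)), f_hub_a)
        X[rest[-half], ] <- X[rest[-half], ] +
          tcrossprod(rep(c_m, length(rest) - length(half)), f_hub_b)
      } else {
        v <- fac_var[m]
        X[gs[1L], ] <- anchor_load(v, hub_noise) * factors[m, ] +
          rnorm(n_samp, sd = hub_noise)
        c_m <- loading(r_member_hub^2, v)
        X[gs[-1L], ] <- X[gs[-1L], ] +
          tcrossprod(rep(c_m, length(gs) - 1L), factors[m, ])
      }
    } else {
      c_m <- loading(r_member_nonhub^2, fac_var[m])
      X[gs, ] <- X[gs, ] + tcrossprod(rep(c_m, length(gs)), factors[m, ])
    }
  }
  ## template system: template gene anchored to its own factor, followers
  ## load so the follower-template correlation equals follower_cor
  X[template, ] <- anchor_load(1, hub_noise) * f_template +
    rnorm(n_samp, sd = hub_noise)
  r_follow <- d$follower_cor / .ANCHOR_R
  c_f <- loading(r_follow^2, 1)
  X[followers, ] <- X[followers, ] +
    tcrossprod(rep(c_f, length(followers)), f_template)

  X <- X + mu[genes]

  ## ---- platform batch effect on B -------------------------------------
  is_b <- meta$platform == "B"
  offsets <- setNames(rnorm(n_gene, sd = d$batch_shift), genes)
  Xb <- X
  Xb[, is_b] <- mu[genes] + offsets[genes] +
    sqrt(d$batch_scale) * (X[, is_b, drop = FALSE] - mu[genes])

  ## ---- probe expansion -------------------------------------------------
  genes_a <- c(shared, priv_a)
  genes_b <- c(shared, priv_b)
  pm_a <- expand_probes(Xb[genes_a, !is_b, drop = FALSE], d, prefix = "ILA")
  pm_b <- expand_probes(Xb[genes_b, is_b, drop = FALSE], d, prefix = "AFB")
  pm_a$platform_id <- "A"
  pm_b$platform_id <- "B"

  probe_truth <- rbind(
    cbind(platform = "A", pm_a$probe_truth),
    cbind(platform = "B", pm_b$probe_truth)
  )
  pa <- probe_matrix(pm_a$values, pm_a$annotation, "A")
  pb <- probe_matrix(pm_b$values, pm_b$annotation, "B")

  truth <- structure(list(
    module_membership = membership,
    module_genes = module_genes,
    hub_gene = hub_gene,
    template_gene = template,
    follower_genes = followers,
    batch_offsets = data.frame(gene = genes, offset_b = unname(offsets)),
    peak_enriched_module = d$hub_module_index,
    probe_map_truth = probe_truth,
    hub_mode = d$hub_mode,
    design = d
  ), class = "synthetic_truth")

  structure(list(platform_a = pa, platform_b = pb,
                 metadata = meta, truth = truth),
            class = "synthetic_study")
}

build_metadata <- function(d) {
  group_label <- function(platform, state) {
    key <- c(A.naive = "naive_A", A.resolving = "M45", A.extreme = "M38",
             B.naive = "naive_B", B.resolving = "Arm", B.extreme = "Cl13")
    lbl <- key[paste(platform, state, sep = ".")]
    ifelse(is.na(lbl), paste(platform, state, sep = "_"), lbl)
  }
  rows <- list()
  for (pf in c("A", "B")) {
    for (st in d$states) {
      for (tp in d$timepoints[[st]]) {
        for (r in seq_len(d$samples_per_cell)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_%s_d%g_r%d", pf, st, tp, r),
            platform = pf, state = st,
            group = unname(group_label(pf, st)),
            timepoint = tp, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

## Expand a gene x sample matrix to probes. Probe k of a gene sits on a fixed
## offset ladder (0, -0.4, -0.8, ...) assigned to probe ids in random order,
## so exactly one probe per gene carries the maximal mean signal.
expand_probes <- function(X, design, prefix) {
  genes <- rownames(X)
  np <- sample(seq(design$probes_per_gene[1], design$probes_per_gene[2]),
               length(genes), replace = TRUE)
  total <- sum(np)
  values <- matrix(0, total, ncol(X), dimnames = list(NULL, colnames(X)))
  probe_ids <- character(total)
  symbols <- character(total)
  is_max <- logical(total)
  row <- 0L
  for (i in seq_along(genes)) {
    k <- np[i]
    ladder <- -0.4 * (seq_len(k) - 1L)
    ord <- sample.int(k)
    for (j in seq_len(k)) {
      row <- row + 1L
      probe_ids[row] <- sprintf("%s_%s_p%d", prefix, genes[i], j)
      symbols[row] <- genes[i]
      values[row, ] <- X[i, ] + ladder[ord[j]]
      is_max[row] <- ord[j] == 1L
    }
  }
  ## a handful of unannotated probes, as real annotation files have
  n_un <- 5L
  un_vals <- matrix(rnorm(n_un * ncol(X), mean = 7, sd = design$noise_sd),
                    n_un, ncol(X), dimnames = list(NULL, colnames(X)))
  values <- rbind(values, un_vals)
  probe_ids <- c(probe_ids, sprintf("%s_anon_p%d", prefix, seq_len(n_un)))
  symbols <- c(symbols, rep(NA_character_, n_un))
  is_max <- c(is_max, rep(FALSE, n_un))
  rownames(values) <- probe_ids
  list(values = values,
       annotation = data.frame(probe_id = probe_ids, symbol = symbols,
                               stringsAsFactors = FALSE),
       probe_truth = data.frame(probe_id = probe_ids, gene = symbols,
                                is_max_signal = is_max,
                                stringsAsFactors = FALSE))
}

#' Ground-truth planted partition of a synthetic study
#'
#' Returns the full planted gene partition: module indices as planted,
#' the template/follower block as one extra class, and 0 for background.
#' Useful as the reference partition when scoring module recovery.
#'
#' @param truth a \code{synthetic_truth} record.
#' @param genes optional character vector restricting (and ordering) the
#'   returned labels.
#' @return named integer vector of class labels.
#' @export
truth_partition <- function(truth, genes = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  part <- truth$module_membership
  extra <- max(part) + 1L
  part[c(truth$follower_genes, truth$template_gene)] <- extra
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(part))
    if (length(missing) > 0)
      stop("unknown genes: ", paste(head(missing, 5), collapse = ", "))
    part <- part[genes]
  }
  part
}

#' Deterministic gene loci for a set of symbols
#'
#' Lays gene TSS coordinates on a synthetic genome (19 chromosomes, 20 kb
#' gene spacing, alternating strand) so that 1-2 kb proximity windows of
#' neighbouring genes never overlap.
#'
#' @param symbols character vector of gene symbols.
#' @return data.frame with columns symbol, chrom, tss, strand.
#' @export
generate_gene_loci <- function(symbols) {
  stopifnot(!anyDuplicated(symbols))
  i <- seq_along(symbols)
  data.frame(symbol = symbols,
             chrom = paste0("chr", ((i - 1L) %% 19L) + 1L),
             tss = 50000L + ((i - 1L) %/% 19L) * 20000L,
             strand = ifelse(i %% 2L == 0L, "-", "+"),
             stringsAsFactors = FALSE)
}

#' Generate a scored peak table enriched near one planted module
#'
#' Places one peak within 1 kb of the TSS for a fraction of the
#' peak-enriched module's genes and a (smaller) fraction of all other
#' genes; peak scores are uniform in \code{score_range}. Intervals are
#' 0-based half-open BED.
#'
#' @param truth a \code{synthetic_truth} record (uses
#'   \code{peak_enriched_module} and \code{module_membership}).
#' @param loci gene loci as from [generate_gene_loci()]; must cover all
#'   genes in the truth record.
#' @param enrich_fraction_in fraction of module genes receiving a proximal
#'   peak; must exceed \code{enrich_fraction_out}.
#' @param enrich_fraction_out fraction of non-module genes receiving one.
#' @param score_range length-2 numeric, uniform score range.
#' @param seed integer seed.
#' @param peak_width width of each peak in bp.
#' @return data.frame (chrom, start, end, name, score), class
#'   \code{peak_table}.
#' @export
generate_peak_table <- function(truth, loci,
                                enrich_fraction_in = 0.5,
                                enrich_fraction_out = 0.05,
                                score_range = c(30, 100),
                                seed = 1L,
                                peak_width = 200L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  validate_gene_loci(loci)
  if (enrich_fraction_in <= enrich_fraction_out)
    stop("enrich_fraction_in must exceed enrich_fraction_out")
  genes <- names(truth$module_membership)
  if (!all(genes %in% loci$symbol))
    stop("loci must cover every gene in the truth record")
  set.seed(seed)
  mod_genes <- genes[truth$module_membership == truth$peak_enriched_module]
  bg_genes <- setdiff(genes, mod_genes)
  pick <- function(g, frac) {
    n <- round(frac * length(g))
    if (n == 0) character(0) else sample(g, n)
  }
  hit <- c(pick(mod_genes, enrich_fraction_in),
           pick(bg_genes, enrich_fraction_out))
  if (length(hit) == 0)
    return(structure(data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), name = character(0),
                                score = numeric(0)),
                     class = c("peak_table", "data.frame")))
  idx <- match(hit, loci$symbol)
  half <- as.integer(peak_width / 2)
  ## midpoint strictly within 1 kb of the TSS
  mid <- loci$tss[idx] + sample(seq(-900L, 900L), length(hit), replace = TRUE)
  start <- pmax(0L, mid - half)
  end <- start + as.integer(peak_width)
  tbl <- data.frame(chrom = loci$chrom[idx],
                    start = start, end = end,
                    name = sprintf("peak_%05d", seq_along(hit)),
                    score = runif(length(hit), score_range[1], score_range[2]),
                    stringsAsFactors = FALSE)
  tbl <- tbl[order(tbl$chrom, tbl$start), ]
  rownames(tbl) <- NULL
  structure(tbl, class = c("peak_table", "data.frame"))
}

validate_gene_loci <- function(loci) {
  if (!is.data.frame(loci) ||
      !all(c("symbol", "chrom", "tss", "strand") %in% names(loci)))
    stop("loci must be a data.frame with columns symbol, chrom, tss, strand")
  if (anyDuplicated(loci$symbol)) stop("loci symbols must be unique")
  if (!all(loci$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(!is.finite(loci$tss)) || any(loci$tss < 0))
    stop("malformed TSS coordinates")
  invisible(loci)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Planted truth record\n")
  cat(sprintf("  modules: %s (hub module %d, hub gene %s, mode %s)\n",
              paste(lengths(x$module_genes), collapse = "/"),
              x$design$hub_module_index, x$hub_gene, x$hub_mode))
  cat(sprintf("  template %s with %d followers; peak-enriched module %d\n",
              x$template_gene, length(x$follower_genes),
              x$peak_enriched_module))
  invisible(x)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic two-platform study\n")
  cat(sprintf("  platform A: %d probes x %d samples\n",
              nrow(x$platform_a$values), ncol(x$platform_a$values)))
  cat(sprintf("  platform B: %d probes x %d samples\n",
              nrow(x$platform_b$values), ncol(x$platform_b$values)))
  print(x$truth)
  invisible(x)
}
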