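#' Design of a two-platform synthetic expression study
#'
#' Describes the layout and effect sizes of a simulated two-platform
#' microarray study with planted co-expression structure. The defaults
#' emulate the shape of a merged inflation/exhaustion-style CD8+ T-cell
#' study: two platforms of 30 arrays each (5 design cells x 6 replicates),
#' a three-level sample state (naive / resolving / extreme), three planted
#' co-expression modules of which the second-largest is driven by a single
#' hub gene, gene-wise additive + multiplicative platform batch effects,
#' and a planted template-regulator system (a template gene plus follower
#' genes tracking its trajectory).
#'
#' Module correlations are planted through a latent-factor model: each
#' module has one latent factor per sample and members load on it so that
#' the population member-member correlation equals \code{within_module_cor}
#' (and, in the hub module, the hub-member correlation equals
#' \code{hub_strength}). State effects enter as per-module shifts of the
#' factor mean, so "state" separates samples in expression space the way a
#' differentiation trajectory would.
#'
#' @param n_genes total number of gene symbols across both platforms.
#' @param shared_gene_fraction fraction of symbols present on both
#'   platforms; the remainder is split into platform-private halves.
#' @param probes_per_gene integer vector \code{c(min, max)}: each gene is
#'   measured by a uniformly drawn number of probes in this range.
#' @param samples_per_cell replicates per (platform x state x timepoint)
#'   design cell.
#' @param states ordered state labels (reference, intermediate, extreme).
#' @param timepoints named list mapping each state to its day labels.
#' @param module_sizes sizes of the planted modules (genes).
#' @param hub_module_index which module is hub-driven.
#' @param hub_strength target hub-member correlation in (0, 0.99).
#' @param within_module_cor target member-member correlation in non-hub
#'   modules, in (0, 0.99).
#' @param state_shift named list (or NULL) of per-module latent-factor mean
#'   shifts, one numeric vector per module in \code{states} order, in
#'   latent-sd units. Default: module 1 is an acute-transient program
#'   (0, 4, 1: strong in the resolving response, largely switched off in
#'   the extreme phenotype), the hub module an extreme-specific program
#'   (0, -2, 9: suppressed during resolution, strongly induced in the
#'   extreme phenotype), remaining modules state-free. The two patterns
#'   are anticorrelated under the sample design, keeping the planted
#'   factors well separated while the extreme state sits several latent
#'   sds away from both other states on the hub module.
#' @param batch_shift sd (log2 units) of the gene-wise additive offset
#'   applied to platform B.
#' @param batch_scale multiplicative variance-inflation factor applied to
#'   platform B around each gene's baseline.
#' @param noise_sd residual sd (log2 units) of background genes.
#' @param template_gene symbol to assign to the planted template regulator.
#' @param n_template_followers number of background genes planted to track
#'   the template's trajectory.
#' @param follower_cor target follower-template correlation in (0, 0.99).
#' @param hub_mode \code{"single_hub"} plants one dominant hub
#'   ("inflation-like"); \code{"two_factor"} generates the same module from
#'   two independent latent factors with no single hub ("exhaustion-like"),
#'   the regulator gene loading equally on both.
#' @param seed integer seed; identical seeds give bit-identical studies.
#'
#' @return an object of class \code{synthetic_design}.
#' @seealso [generate_two_platform_study()]
#' @export
synthetic_design <- function(n_genes = 1200,
                             shared_gene_fraction = 0.8,
                             probes_per_gene = c(1L, 3L),
                             samples_per_cell = 6L,
                             states = c("naive", "resolving", "extreme"),
                             timepoints = list(naive = 0,
                                               resolving = c(7, 50),
                                               extreme = c(7, 50)),
                             module_sizes = c(100L, 60L, 40L),
                             hub_module_index = 2L,
                             hub_strength = 0.9,
                             within_module_cor = 0.7,
                             state_shift = NULL,
                             batch_shift = 1.0,
                             batch_scale = 2.0,
                             noise_sd = 0.3,
                             template_gene = "TPL1",
                             n_template_followers = 50L,
                             follower_cor = 0.95,
                             hub_mode = c("single_hub", "two_factor"),
                             seed = 1L) {
  hub_mode <- match.arg(hub_mode)
  if (is.null(state_shift)) {
    state_shift <- lapply(seq_along(module_sizes), function(m) {
      if (m == hub_module_index) c(0, -2, 9)[seq_along(states)]
      else if (m == 1L) c(0, 4, 1)[seq_along(states)]
      else rep(0, length(states))
    })
  }
  design <- structure(list(
    n_genes = as.integer(n_genes),
    shared_gene_fraction = shared_gene_fraction,
    probes_per_gene = as.integer(probes_per_gene),
    samples_per_cell = as.integer(samples_per_cell),
    states = states,
    timepoints = timepoints,
    module_sizes = as.integer(module_sizes),
    hub_module_index = as.integer(hub_module_index),
    hub_strength = hub_strength,
    within_module_cor = within_module_cor,
    state_shift = state_shift,
    batch_shift = batch_shift,
    batch_scale = batch_scale,
    noise_sd = noise_sd,
    template_gene = template_gene,
    n_template_followers = as.integer(n_template_followers),
    follower_cor = follower_cor,
    hub_mode = hub_mode,
    seed = as.integer(seed)
  ), class = "synthetic_design")
  validate_synthetic_design(design)
  design
}

# Loadings on the hub/template latent factor are anchored at r = .995 (the
# hub gene is the factor plus a small residual); planted correlations above
# that are unattainable for any noise level.
.ANCHOR_R <- 0.995

validate_synthetic_design <- function(d) {
  stopifnot(inherits(d, "synthetic_design"))
  if (d$n_genes < 1L) stop("n_genes must be positive")
  if (d$shared_gene_fraction < 0 || d$shared_gene_fraction > 1)
    stop("shared_gene_fraction must lie in [0, 1]")
  if (length(d$probes_per_gene) != 2L || any(d$probes_per_gene < 1L) ||
      d$probes_per_gene[1] > d$probes_per_gene[2])
    stop("probes_per_gene must be c(min, max) with 1 <= min <= max")
  if (d$samples_per_cell < 1L) stop("samples_per_cell must be positive")
  if (!all(names(d$timepoints) == d$states))
    stop("timepoints must be a named list matching 'states' in order")
  if (sum(d$module_sizes) > d$n_genes)
    stop("sum(module_sizes) exceeds n_genes")
  if (d$hub_module_index < 1L || d$hub_module_index > length(d$module_sizes))
    stop("hub_module_index out of range")
  if (any(d$module_sizes < 2L)) stop("each module needs at least 2 genes")
  if (d$noise_sd <= 0) stop("noise_sd must be > 0")
  for (nm in c("hub_strength", "within_module_cor", "follower_cor")) {
    v <- d[[nm]]
    if (v <= 0 || v >= 1) stop(nm, " must lie strictly inside (0, 1)")
    if (v >= .ANCHOR_R)
      stop(nm, " = ", v, " is unattainable given the residual noise model ",
           "(must be < ", .ANCHOR_R, ")")
  }
  if (length(d$state_shift) != length(d$module_sizes) ||
      !all(vapply(d$state_shift, length, 1L) == length(d$states)))
    stop("state_shift needs one numeric vector per module, one entry per state")
  n_shared <- round(d$shared_gene_fraction * d$n_genes)
  if (n_shared < sum(d$module_sizes) + d$n_template_followers + 1L)
    stop("not enough shared genes to host modules, followers and template")
  invisible(d)
}

#' @export
print.synthetic_design <- function(x, ...) {
  n_cells <- sum(lengths(x$timepoints))
  cat("Two-platform synthetic study design\n")
  cat(sprintf("  genes: %d (%.0f%% shared), probes/gene %d-%d\n",
              x$n_genes, 100 * x$shared_gene_fraction,
              x$probes_per_gene[1], x$probes_per_gene[2]))
  cat(sprintf("  samples: 2 platforms x %d cells x %d reps = %d arrays\n",
              n_cells, x$samples_per_cell, 2 * n_cells * x$samples_per_cell))
  cat(sprintf("  modules: %s (hub module %d, mode %s)\n",
              paste(x$module_sizes, collapse = "/"), x$hub_module_index,
              x$hub_mode))
  cat(sprintf("  batch: shift sd %.2g, scale %.2g; noise sd %.2g; seed %d\n",
              x$batch_shift, x$batch_scale, x$noise_sd, x$seed))
  invisible(x)
}
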