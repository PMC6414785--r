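#' Pipeline configuration with field-standard defaults
#'
#' Collects every stage parameter of the integration/network workflow in
#' one validated list. Defaults follow the conventional settings for
#' merged two-platform microarray studies: IQR filter 0.5, eigengene merge
#' distance 0.25, soft-thresholding power presets \{9, 20\}, template
#' threshold R > 0.8, edge-weight display thresholds 0.41 / 0.54, peak
#' proximity 1000 / 2000 bp, minimum peak score 50.
#'
#' @param design a [synthetic_design()] (used when no input paths are
#'   given).
#' @param inputs optional named list of file paths
#'   (\code{values_a, annotation_a, values_b, annotation_b, metadata},
#'   optionally \code{peaks, loci}) to run on user data instead of a
#'   simulation.
#' @param renormalize post-merge normalization: none, scale or quantile.
#' @param iqr_threshold variance filter cutoff.
#' @param run_combat toggle batch correction.
#' @param combat_covariates optional covariates protected during
#'   correction.
#' @param pvca_factors metadata factors audited by PVCA.
#' @param pvca_variance_threshold cumulative-variance cutoff for retained
#'   components.
#' @param beta soft-thresholding power used for the network.
#' @param beta_presets the two conventional power presets.
#' @param min_module_size,cut_height static tree-cut parameters.
#' @param merge_distance eigengene merge distance.
#' @param r_threshold template-match correlation threshold.
#' @param edge_weight_threshold,edge_weight_threshold_alt edge display
#'   thresholds.
#' @param peak_max_distance,peak_max_distance_wide TSS proximity bounds
#'   (bp).
#' @param peak_min_score minimum retained peak score.
#' @param enrich_fraction_in,enrich_fraction_out planted peak fractions
#'   for the simulated peak table.
#' @param exclude_samples sample ids dropped after merging.
#' @param seed single seed from which all randomness flows.
#' @param out_dir artifact directory (created on run).
#' @return a validated list of class \code{run_config}.
#' @export
run_config <- function(design = synthetic_design(),
                       inputs = NULL,
                       renormalize = "none",
                       iqr_threshold = 0.5,
                       run_combat = TRUE,
                       combat_covariates = NULL,
                       pvca_factors = c("platform", "state"),
                       pvca_variance_threshold = 0.6,
                       beta = 9,
                       beta_presets = c(9, 20),
                       min_module_size = 30L,
                       cut_height = NULL,
                       merge_distance = 0.25,
                       r_threshold = 0.8,
                       edge_weight_threshold = 0.41,
                       edge_weight_threshold_alt = 0.54,
                       peak_max_distance = 1000,
                       peak_max_distance_wide = 2000,
                       peak_min_score = 50,
                       enrich_fraction_in = 0.5,
                       enrich_fraction_out = 0.05,
                       exclude_samples = character(0),
                       seed = 1L,
                       out_dir = tempfile("mergenet_run_")) {
  cfg <- as.list(environment())
  if (!renormalize %in% c("none", "scale", "quantile"))
    stop("renormalize must be none, scale or quantile")
  if (is.null(inputs)) validate_synthetic_design(design)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config\n")
  cat(sprintf("  input: %s; seed %d; out_dir %s\n",
              if (is.null(x$inputs)) "synthetic design" else "files",
              x$seed, x$out_dir))
  cat(sprintf("  iqr %.3g | beta %g | merge %.3g | R %.3g | edge %.3g | peak <%g bp, score %g\n",
              x$iqr_threshold, x$beta, x$merge_distance, x$r_threshold,
              x$edge_weight_threshold, x$peak_max_distance,
              x$peak_min_score))
  invisible(x)
}

#' Run the full integration and network-comparison pipeline
#'
#' Fixed stage order: simulate-or-load, probe collapse, gene-universe
#' merge, sample exclusion, PVCA audit (before), batch correction, PVCA
#' audit (after), renormalization, IQR filter, PCA, sample clustering,
#' network construction (adjacency, TOM, soft-threshold fit table), module
#' detection with eigengene merging, connectivity/hubs, edge export for
#' the regulator's module, template matching, peak annotation and module
#' enrichment. Every stochastic step consumes the single config seed, and
#' artifacts are serialized with a fixed float format, so rerunning an
#' identical config reproduces byte-identical TSVs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the run \code{report} (class
#'   \code{run_report}) and all intermediate objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  report <- list(parameters = config_parameters(config), stages = list())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), stage))
  }

  ## --- inputs ---------------------------------------------------------
  truth <- NULL
  if (is.null(config$inputs)) {
    design <- config$design
    design$seed <- config$seed
    study <- generate_two_platform_study(design)
    pm_a <- study$platform_a; pm_b <- study$platform_b
    meta <- study$metadata; truth <- study$truth
    note("simulate", n_probes_a = nrow(pm_a$values),
         n_probes_b = nrow(pm_b$values), n_samples = nrow(meta))
  } else {
    ins <- config$inputs
    pm_a <- read_probe_matrix(ins$values_a, ins$annotation_a, "A")
    pm_b <- read_probe_matrix(ins$values_b, ins$annotation_b, "B")
    meta <- read_sample_metadata(ins$metadata)
    note("load", n_probes_a = nrow(pm_a$values),
         n_probes_b = nrow(pm_b$values))
  }

  ## --- collapse + merge ------------------------------------------------
  gm_a <- collapse_probes(pm_a)
  gm_b <- collapse_probes(pm_b)
  merged <- intersect_and_merge(gm_a, gm_b, meta)
  note("merge", genes_a = length(gm_a$gene_symbols),
       genes_b = length(gm_b$gene_symbols),
       intersected = nrow(merged$values), samples = ncol(merged$values))
  if (length(config$exclude_samples) > 0) {
    merged <- exclude_samples(merged, config$exclude_samples)
    note("exclude", removed = length(config$exclude_samples),
         remaining = ncol(merged$values))
  }

  ## --- batch audit + correction ----------------------------------------
  pvca_before <- pvca(merged, factors = config$pvca_factors,
                      variance_threshold = config$pvca_variance_threshold)
  corrected <- merged
  if (config$run_combat) {
    corrected <- combat(merged, batch_factor = "platform",
                        covariates = config$combat_covariates)
  }
  pvca_after <- pvca(corrected, factors = config$pvca_factors,
                     variance_threshold = config$pvca_variance_threshold)
  note("batch_adjust", combat = config$run_combat,
       top_factor_before = pvca_before$factor[1],
       top_factor_after = pvca_after$factor[1])

  corrected <- renormalize(corrected, config$renormalize)

  ## --- variance filter + exploration ------------------------------------
  filtered <- iqr_filter(corrected, config$iqr_threshold)
  note("iqr_filter", kept = nrow(filtered$values),
       dropped = filtered$report$n_genes_dropped)
  pca <- run_pca(corrected)
  tree <- cluster_samples(filtered)
  note("explore",
       var_first3 = sum(pca$variance_fraction[1:min(3, length(pca$variance_fraction))]))

  ## --- network ----------------------------------------------------------
  sft <- pick_soft_threshold(filtered,
                             candidate_betas = sort(unique(c(1:10, config$beta_presets))))
  nm <- tom_similarity(adjacency_matrix(filtered, beta = config$beta))
  assignment <- detect_modules(nm, min_module_size = config$min_module_size,
                               cut_height = config$cut_height)
  n_raw <- length(unique(assignment$label[assignment$label > 0]))
  if (n_raw >= 2)
    assignment <- merge_close_modules(filtered, assignment,
                                      merge_distance = config$merge_distance)
  eig <- if (any(assignment$label > 0))
    module_eigengenes(filtered, assignment) else NULL
  conn <- intramodular_connectivity(nm, assignment)
  note("network", beta = config$beta,
       recommended_beta = attr(sft, "recommended_beta"),
       modules_before_merge = n_raw,
       modules = length(unique(assignment$label[assignment$label > 0])))

  ## --- regulator-centric analyses ----------------------------------------
  regulator <- if (!is.null(truth)) truth$hub_gene else config$inputs$regulator
  edges <- NULL
  tmatch <- NULL
  reg_module <- NA_integer_
  if (!is.null(regulator) && regulator %in% assignment$gene) {
    reg_module <- assignment$label[assignment$gene == regulator]
    if (reg_module > 0) {
      edges <- export_module_edges(nm, assignment, reg_module,
                                   config$edge_weight_threshold)
    }
    tmatch <- pavlidis_template_match(filtered, regulator,
                                      r_threshold = config$r_threshold)
    note("template", regulator = regulator, module = reg_module,
         n_matched = tmatch$n_matched,
         n_edges = if (is.null(edges)) 0L else nrow(edges))
  }

  ## --- peaks --------------------------------------------------------------
  enrichment <- NULL
  flags <- NULL
  if (!is.null(truth)) {
    loci <- generate_gene_loci(names(truth$module_membership))
    peaks <- generate_peak_table(truth, loci,
                                 enrich_fraction_in = config$enrich_fraction_in,
                                 enrich_fraction_out = config$enrich_fraction_out,
                                 seed = config$seed + 1L)
  } else if (!is.null(config$inputs$peaks)) {
    loci <- read_gene_loci(config$inputs$loci)
    peaks <- read_bed(config$inputs$peaks)
  } else {
    loci <- NULL; peaks <- NULL
  }
  if (!is.null(peaks)) {
    flags <- annotate_peaks_to_genes(peaks, loci,
                                     max_distance = config$peak_max_distance,
                                     min_score = config$peak_min_score)
    labs <- sort(unique(assignment$label[assignment$label > 0]))
    if (!is.na(reg_module) && reg_module > 0 && length(labs) >= 2) {
      comparison <- setdiff(labs, reg_module)[1] # largest other module
      enrichment <- module_peak_enrichment(
        flags,
        intersect(module_genes(assignment, reg_module), flags$gene),
        intersect(module_genes(assignment, comparison), flags$gene))
      note("peaks", n_peaks = nrow(peaks),
           flagged = sum(flags$has_peak),
           p_value = enrichment$p_value)
    }
  }

  ## --- artifacts -----------------------------------------------------------
  out <- config$out_dir
  write_tsv_matrix(merged$values, file.path(out, "merged_matrix.tsv"))
  write_tsv_matrix(corrected$values, file.path(out, "corrected_matrix.tsv"))
  write_tsv_matrix(filtered$values, file.path(out, "filtered_matrix.tsv"))
  write.table(corrected$metadata, file.path(out, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(factor = pvca_before$factor,
                         before = pvca_before$proportion,
                         after = pvca_after$proportion[
                           match(pvca_before$factor, pvca_after$factor)]),
              file.path(out, "pvca.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv_matrix(t(pca$scores[, 1:min(3, ncol(pca$scores)), drop = FALSE]),
                   file.path(out, "pca_scores_first3.tsv"),
                   row_label = "component")
  write_newick(tree, file.path(out, "sample_tree.nwk"))
  write.table(assignment, file.path(out, "module_assignment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(format(sft, digits = 6), file.path(out, "soft_threshold.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(eig))
    write_tsv_matrix(unclass(eig), file.path(out, "eigengenes.tsv"),
                     row_label = "module")
  write.table(conn$table, file.path(out, "connectivity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(edges)) {
    ed <- edges
    ed$weight <- sprintf("%.9g", ed$weight)
    write.table(ed, file.path(out, "module_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_sif(edges, file.path(out, "module_edges.sif"))
  }
  if (!is.null(tmatch))
    write.table(data.frame(gene = names(tmatch$r),
                           r = sprintf("%.9g", tmatch$r),
                           matched = names(tmatch$r) %in% tmatch$matched),
                file.path(out, "template_match.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(flags)) {
    fl <- flags
    fl$nearest_distance <- sprintf("%.9g", fl$nearest_distance)
    write.table(fl, file.path(out, "peak_flags.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- report ---------------------------------------------------------------
  hubs <- conn$hubs
  report$summary <- list(
    n_genes_intersected = nrow(merged$values),
    n_samples = ncol(merged$values),
    n_genes_filtered = nrow(filtered$values),
    n_modules = length(unique(assignment$label[assignment$label > 0])),
    module_sizes = as.list(table(assignment$color[assignment$label > 0])),
    hubs = if (!is.null(hubs)) setNames(as.list(hubs$hub_gene), hubs$color)
           else list(),
    regulator = regulator,
    regulator_module = reg_module,
    n_template_matches = if (is.null(tmatch)) NA else tmatch$n_matched,
    enrichment = if (is.null(enrichment)) NULL else
      list(table = as.list(setNames(as.numeric(enrichment$table),
                                    c("module_with", "comparison_with",
                                      "module_without", "comparison_without"))),
           odds_ratio = enrichment$odds_ratio,
           p_value = enrichment$p_value),
    pvca_before = setNames(as.list(pvca_before$proportion),
                           pvca_before$factor),
    pvca_after = setNames(as.list(pvca_after$proportion), pvca_after$factor),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  report$software_version <- as.character(utils::packageVersion("mergenet"))
  report$artifact_hash <- artifact_hash(out)
  report$config_hash <- config_hash(config)
  class(report) <- "run_report"
  jsonlite::write_json(unclass_report(report),
                       file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(report = report, merged = merged, corrected = corrected,
                 filtered = filtered, pvca_before = pvca_before,
                 pvca_after = pvca_after, pca = pca, tree = tree,
                 soft_threshold = sft, network = nm,
                 assignment = assignment, eigengenes = eig,
                 connectivity = conn, edges = edges,
                 template_match = tmatch, peak_flags = flags,
                 enrichment = enrichment, truth = truth))
}

config_parameters <- function(config) {
  keep <- setdiff(names(config), c("design", "inputs", "out_dir"))
  pars <- config[keep]
  pars$cut_height <- if (is.null(pars$cut_height)) "auto" else pars$cut_height
  if (!is.null(config$design) && is.null(config$inputs))
    pars$design <- config$design[setdiff(names(config$design),
                                         c("state_shift", "timepoints"))]
  pars
}

unclass_report <- function(report) {
  rapply(unclass(report), function(x) x, how = "replace")
}

## md5 over the sorted artifact files: identical runs => identical hash
artifact_hash <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE, pattern = "\\.(tsv|nwk|sif)$"))
  sums <- tools::md5sum(files)
  paste(unname(sums), collapse = "")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  pars <- config_parameters(config)
  writeLines(paste(names(pars),
                   vapply(pars, function(p) paste(format(p), collapse = ","),
                          character(1)),
                   sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("mergenet run report\n")
  cat(sprintf("  %d genes x %d samples merged; %d after IQR filter\n",
              s$n_genes_intersected, s$n_samples, s$n_genes_filtered))
  cat(sprintf("  %d modules; regulator %s in module %s; %s template matches\n",
              s$n_modules, s$regulator %||% "<none>",
              s$regulator_module, s$n_template_matches))
  if (!is.null(s$enrichment))
    cat(sprintf("  peak enrichment p = %.3g (OR %.2f)\n",
                s$enrichment$p_value, s$enrichment$odds_ratio))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write edges in SIF format for Cytoscape
#'
#' @param edges edge data.frame (gene_a, gene_b, weight).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sif <- function(edges, path) {
  lines <- sprintf("%s tom %s", edges$gene_a, edges$gene_b)
  writeLines(lines, path)
  invisible(path)
}

#' One-call co-expression analysis of a single dataset
#'
#' Convenience wrapper producing the objects [compare_networks()]
#' consumes: adjacency + TOM at the given power, static-cut module
#' detection, eigengene merging and connectivity.
#'
#' @param ms a [merged_study] or gene x sample matrix (already variance
#'   filtered).
#' @param beta soft-thresholding power.
#' @param min_module_size,cut_height,merge_distance see
#'   [detect_modules()] / [merge_close_modules()].
#' @return list of class \code{coexpression_run}: matrix, network,
#'   assignment, eigengenes, connectivity.
#' @export
analyze_coexpression <- function(ms, beta = 9, min_module_size = 30L,
                                 cut_height = NULL, merge_distance = 0.25) {
  v <- study_values(ms)
  nm <- tom_similarity(adjacency_matrix(v, beta = beta))
  assignment <- detect_modules(nm, min_module_size = min_module_size,
                               cut_height = cut_height)
  if (length(unique(assignment$label[assignment$label > 0])) >= 2)
    assignment <- merge_close_modules(v, assignment,
                                      merge_distance = merge_distance)
  eig <- if (any(assignment$label > 0)) module_eigengenes(v, assignment)
         else NULL
  conn <- intramodular_connectivity(nm, assignment)
  structure(list(values = v, network = nm, assignment = assignment,
                 eigengenes = eig, connectivity = conn),
            class = "coexpression_run")
}

#' Compare a regulator's module between two co-expression runs
#'
#' Locates the module containing the regulator in each run and reports,
#' as one table: module overlap (counts, Jaccard, hypergeometric p on the
#' shared gene universe), each module's hub, the regulator's
#' within-module connectivity rank, its exported-edge degree at a
#' threshold, and template-match counts against the regulator in each
#' dataset.
#'
#' @param run_a,run_b [analyze_coexpression()] results.
#' @param regulator gene symbol present in both runs.
#' @param r_threshold template-match threshold.
#' @param edge_weight_quantile within-module TOM quantile used as the
#'   edge-display threshold (default 0.9, i.e. the top decile of edges).
#' @return list of class \code{network_comparison}.
#' @export
compare_networks <- function(run_a, run_b, regulator,
                             r_threshold = 0.8,
                             edge_weight_quantile = 0.9) {
  side <- function(run, name) {
    if (!regulator %in% run$assignment$gene)
      stop("regulator '", regulator, "' absent from run ", name)
    lab <- run$assignment$label[run$assignment$gene == regulator]
    genes <- if (lab > 0) module_genes(run$assignment, lab) else character(0)
    tab <- run$connectivity$table
    rank <- NA_integer_
    hub <- NA_character_
    degree <- NA_real_
    threshold <- NA_real_
    if (lab > 0) {
      sub <- tab[tab$label == lab, ]
      sub <- sub[order(-sub$kWithin, sub$gene), ]
      rank <- match(regulator, sub$gene)
      hub <- sub$gene[1]
      w <- run$network$tom[genes, genes]
      threshold <- quantile(w[upper.tri(w)], edge_weight_quantile,
                            names = FALSE)
      edges <- export_module_edges(run$network, run$assignment, lab,
                                   threshold)
      degree <- attr(edges, "degree")[regulator]
    }
    tm <- pavlidis_template_match(run$values, regulator,
                                  r_threshold = r_threshold)
    list(module = lab, genes = genes, hub = hub,
         regulator_rank = rank, regulator_degree = unname(degree),
         edge_threshold = threshold, n_template_matches = tm$n_matched)
  }
  a <- side(run_a, "A")
  b <- side(run_b, "B")
  universe <- union(rownames(run_a$values), rownames(run_b$values))
  overlap <- if (length(a$genes) > 0 && length(b$genes) > 0)
    module_overlap(a$genes, b$genes, universe) else NULL
  structure(list(regulator = regulator, a = a, b = b, overlap = overlap),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("network comparison for regulator %s\n", x$regulator))
  for (nm in c("a", "b")) {
    s <- x[[nm]]
    cat(sprintf("  run %s: module %d (%d genes), hub %s, regulator rank %s, degree %s, %d template matches\n",
                toupper(nm), s$module, length(s$genes), s$hub,
                s$regulator_rank, s$regulator_degree, s$n_template_matches))
  }
  if (!is.null(x$overlap))
    cat(sprintf("  overlap %d (Jaccard %.2f, p = %.3g)\n",
                x$overlap$overlap, x$overlap$jaccard, x$overlap$p_value))
  invisible(x)
}
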