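#' Pipeline configuration
#'
#' Collects every threshold, seed and method switch of the analysis chain in
#' one validated object. Defaults follow the study conventions: DE call at
#' adjusted p <= 0.05, Bonferroni < 0.05 for the clustering input, a 1-log2
#' dependence rule, threshold-MAP misclassification control at 5%, PLM
#' cluster enrichment at p < 0.01, GO at p < 0.05, hub cutoff 19 (strict),
#' and a >50% DE interpretability rule.
#'
#' @param out_dir Output directory (created if absent).
#' @param simulate If `TRUE` (default) all inputs are generated by the
#'   synthetic-data module; otherwise `probe_table` must point to a TSV.
#' @param probe_table Path to a probe-level TSV (ignored when simulating).
#' @param n_genes,de_fraction,effect_size Simulation scenario.
#' @param seed Master seed; stage seeds are derived from it.
#' @param de_alpha,bonferroni_alpha,dependence_logratio,map_alpha,plm_alpha,
#'   go_alpha,hub_cutoff,interpretable_fraction Thresholds (see above).
#' @param K_range Candidate component numbers (default 2:40).
#' @param null_dist `"normal"` or `"t"` null for the moderated statistic.
#' @param fdr_method `"bh"`, `"bonferroni"` or `"local_fdr"` for the DE call.
#' @param strand_mode `"both"` or `"given"` for motif scanning.
#' @param loess_span Loess span for the normalisation.
#' @param promoter_length Promoter length in bases.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = TRUE,
                            probe_table = NULL,
                            n_genes = 2000,
                            de_fraction = 0.2,
                            effect_size = 1.5,
                            seed = 1L,
                            de_alpha = 0.05,
                            bonferroni_alpha = 0.05,
                            dependence_logratio = 1,
                            map_alpha = 0.05,
                            plm_alpha = 0.01,
                            go_alpha = 0.05,
                            hub_cutoff = 19,
                            interpretable_fraction = 0.5,
                            K_range = 2:40,
                            null_dist = c("normal", "t"),
                            fdr_method = c("bh", "bonferroni", "local_fdr"),
                            strand_mode = c("both", "given"),
                            loess_span = 0.3,
                            promoter_length = 1000) {
  cfg <- list(out_dir = out_dir, simulate = isTRUE(simulate),
              probe_table = probe_table, n_genes = n_genes,
              de_fraction = de_fraction, effect_size = effect_size,
              seed = as.integer(seed), de_alpha = de_alpha,
              bonferroni_alpha = bonferroni_alpha,
              dependence_logratio = dependence_logratio,
              map_alpha = map_alpha, plm_alpha = plm_alpha,
              go_alpha = go_alpha, hub_cutoff = hub_cutoff,
              interpretable_fraction = interpretable_fraction,
              K_range = as.integer(K_range),
              null_dist = match.arg(null_dist),
              fdr_method = match.arg(fdr_method),
              strand_mode = match.arg(strand_mode),
              loess_span = loess_span,
              promoter_length = as.integer(promoter_length))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  for (f in c("de_alpha", "bonferroni_alpha", "map_alpha", "plm_alpha",
              "go_alpha", "interpretable_fraction"))
    if (!in01(cfg[[f]])) stop("config field '", f, "' must be in (0, 1)")
  if (cfg$dependence_logratio <= 0) stop("config field 'dependence_logratio' must be > 0")
  if (cfg$hub_cutoff < 1) stop("config field 'hub_cutoff' must be >= 1")
  if (length(cfg$K_range) < 1 || any(cfg$K_range < 1))
    stop("config field 'K_range' must be positive")
  if (!cfg$simulate) {
    if (is.null(cfg$probe_table))
      stop("config field 'probe_table' is required when simulate = FALSE")
    if (!file.exists(cfg$probe_table))
      stop("config field 'probe_table': file not found: ", cfg$probe_table)
  }
  invisible(TRUE)
}

#' Write / read a pipeline configuration (round-trips exactly)
#'
#' @param cfg A `pipeline_config`.
#' @param path JSON file path.
#' @return `write_config` the path invisibly; `read_config` the config.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis chain
#'
#' Stages, in order: simulate (or load) probe intensities; loess
#' normalisation; replicate averaging; moderated tests and DE calls;
#' MAPK-dependence; Bonferroni-filtered constrained-mixture clustering with
#' BIC selection and threshold-MAP assignment; PLM detection and cluster
#' enrichment; GO and kinetic-class enrichment; interaction-network hubs.
#' Every table is written as TSV under `cfg$out_dir` together with a
#' manifest (JSON) of parameters, seeds, package version and per-stage
#' counts. Outputs are a pure function of the configuration.
#'
#' @param cfg A [pipeline_config()].
#' @param design The [array_design()] to simulate/aggregate under.
#' @return Invisibly, a list with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(cfg, design = array_design()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  unlink(log_path)
  counts <- list()

  ## stage 1: inputs -------------------------------------------------------
  if (cfg$simulate) {
    logf("stage simulate: n_genes = ", cfg$n_genes)
    sim <- gen_two_colour_arrays(design, cfg$n_genes, cfg$de_fraction,
                                 cfg$effect_size, seed = cfg$seed)
    probes <- sim$probes
    truth <- sim$truth
    write_tsv(probes, file.path(cfg$out_dir, "probes.tsv"))
    write_tsv(data.frame(gene = rownames(truth$true_logratio),
                         truth$true_logratio, check.names = FALSE),
              file.path(cfg$out_dir, "truth_logratio.tsv"))
  } else {
    logf("stage load: ", cfg$probe_table)
    probes <- utils::read.delim(cfg$probe_table, stringsAsFactors = FALSE)
    truth <- NULL
  }

  ## stage 2-3: normalisation and averaging --------------------------------
  norm <- loess_normalize(probes, span = cfg$loess_span)
  lrm <- average_replicates(norm, design)
  counts$genes <- nrow(lrm$mean)

  ## stage 4: differential expression --------------------------------------
  de <- moderated_test(lrm, null = cfg$null_dist, de_alpha = cfg$de_alpha,
                       adjust = cfg$fdr_method)
  write_tsv(de, file.path(cfg$out_dir, "de_results.tsv"))
  de_counts <- do.call(rbind, lapply(design$comparisons, function(cc) {
    sub <- de[de$comparison == cc, ]
    data.frame(comparison = cc,
               genes_up = sum(sub$de_flag & sub$logratio > 0),
               genes_down = sum(sub$de_flag & sub$logratio < 0),
               stringsAsFactors = FALSE)
  }))
  write_tsv(de_counts, file.path(cfg$out_dir, "de_counts.tsv"))
  counts$de_per_comparison <- stats::setNames(
    as.list(de_counts$genes_up + de_counts$genes_down), de_counts$comparison)
  for (i in seq_len(nrow(de_counts)))
    logf("stage de: ", de_counts$comparison[i], " up ", de_counts$genes_up[i],
         " down ", de_counts$genes_down[i])

  ## stage 5: MAPK dependence ----------------------------------------------
  col_comp <- design$comparisons[1]
  mut_comps <- grep("flg22_vs_mpk", design$comparisons, value = TRUE)
  dep <- NULL
  if (length(mut_comps)) {
    col_de <- de[de$comparison == col_comp & de$de_flag, ]
    col_lr <- stats::setNames(col_de$logratio, col_de$gene)
    mut_lr <- lapply(mut_comps, function(cc) {
      sub <- de[de$comparison == cc, ]
      stats::setNames(sub$logratio, sub$gene)
    })
    names(mut_lr) <- mut_comps
    dep <- mapk_dependence(col_lr, mut_lr, cfg$dependence_logratio)
    write_tsv(dep, file.path(cfg$out_dir, "dependence.tsv"))
    counts$affected <- sum(dep$status == "affected")
    logf("stage depend: ", counts$affected, " affected gene x mutant calls")
  }

  ## stage 6: clustering ----------------------------------------------------
  bonf_de <- de$gene[de$p_bonf < cfg$bonferroni_alpha]
  keep <- rownames(lrm$mean) %in% bonf_de
  X <- lrm$mean[keep, , drop = FALSE]
  counts$clustering_input <- nrow(X)
  logf("stage cluster: ", nrow(X), " Bonferroni-selected genes")
  model <- select_K(X, K_range = cfg$K_range, seed = cfg$seed + 1L)
  assign <- threshold_map_assign(model, X, alpha = cfg$map_alpha)
  de_flag_mat <- matrix(FALSE, nrow(X), length(design$comparisons),
                        dimnames = list(rownames(X), design$comparisons))
  bonf <- de[de$p_bonf < cfg$bonferroni_alpha, ]
  de_flag_mat[cbind(match(bonf$gene, rownames(X)),
                    match(bonf$comparison, design$comparisons))[
                      !is.na(match(bonf$gene, rownames(X))), , drop = FALSE]] <- TRUE
  summ <- summarise_clusters(assign, X, de_flag_mat,
                             cfg$interpretable_fraction)
  model_json <- list(K = model$K, proportions = model$proportions,
                     means = model$means, volumes = model$volumes,
                     shape = model$shape, loglik = model$loglik,
                     bic = model$bic)
  jsonlite::write_json(model_json, file.path(cfg$out_dir, "mixture_model.json"),
                       digits = NA, auto_unbox = TRUE)
  write_tsv(attr(model, "bic_trace"), file.path(cfg$out_dir, "bic_trace.tsv"))
  write_tsv(data.frame(gene = rownames(X), cluster = assign$map,
                       max_posterior = assign$max_posterior,
                       classified = assign$classified),
            file.path(cfg$out_dir, "assignments.tsv"))
  write_tsv(summ$profiles, file.path(cfg$out_dir, "cluster_profiles.tsv"))
  write_tsv(summ$clusters, file.path(cfg$out_dir, "cluster_summary.tsv"))
  counts$K <- model$K
  counts$classified <- sum(assign$classified)
  logf("stage cluster: K = ", model$K, ", ", counts$classified,
       " classified (tau = ", format(assign$tau, digits = 4), ")")

  ## stage 7: promoters and PLMs -------------------------------------------
  clustered_genes <- rownames(X)[assign$classified]
  clusters <- split(clustered_genes, assign$map[assign$classified])
  motif <- "TTGACY"   # W-box with its 3' pyrimidine, the canonical elicitor-responsive element
  prom <- gen_promoters(counts$genes, length = cfg$promoter_length,
                        planted = list(list(motif = motif,
                                            genes = match(clustered_genes,
                                                          rownames(lrm$mean)),
                                            window = c(-300, -200),
                                            prob = 0.5)),
                        seed = cfg$seed + 2L)
  occ <- scan_motif(prom$promoters, motif, strands = cfg$strand_mode)
  plm <- detect_plm(occ, promoter_length = cfg$promoter_length)
  counts$plms <- as.integer(!is.null(plm))
  enr <- NULL
  if (!is.null(plm)) {
    enr <- do.call(rbind, lapply(names(clusters), function(k) {
      cbind(cluster = k, motif = motif,
            test_cluster_enrichment(plm, clusters[[k]], occ, cfg$plm_alpha))
    }))
    write_tsv(enr, file.path(cfg$out_dir, "plm_enrichment.tsv"))
  }
  logf("stage plm: ", counts$plms, " PLM(s) declared")

  ## stage 8: GO and kinetic classes ---------------------------------------
  ann_sim <- gen_annotations_and_edges(counts$genes, seed = cfg$seed + 3L,
                                       ppi_density = 2 / counts$genes,
                                       tf_target_count = counts$genes %/% 10,
                                       planted_hubs = list(
                                         list(gene = 1L, degree = 30L)))
  universe <- rownames(lrm$mean)
  go_res <- do.call(rbind, lapply(names(clusters), function(k) {
    r <- hypergeom_enrichment(intersect(clusters[[k]], unique(ann_sim$go$gene_id)),
                              ann_sim$go, alpha = cfg$go_alpha)
    if (nrow(r)) cbind(cluster = k, r) else NULL
  }))
  if (!is.null(go_res))
    write_tsv(go_res, file.path(cfg$out_dir, "go_enrichment.tsv"))
  counts$go_significant <- if (is.null(go_res)) 0L else sum(go_res$significant)
  logf("stage go: ", counts$go_significant, " significant term x cluster pairs")

  ## stage 9: network -------------------------------------------------------
  net <- build_network(ann_sim$ppi, ann_sim$tf_target, universe)
  hubs <- hub_report(net, cfg$hub_cutoff)
  write_tsv(hubs$nodes, file.path(cfg$out_dir, "degrees.tsv"))
  export_network(net, sif = file.path(cfg$out_dir, "network.sif"),
                 graphml = file.path(cfg$out_dir, "network.graphml"))
  counts$network_nodes <- length(net$degree)
  counts$hubs <- length(hubs$hubs)
  logf("stage network: ", counts$network_nodes, " nodes, ",
       nrow(net$edges), " relations, ", counts$hubs, " hub(s)")

  manifest <- list(package = "coexpipe",
                   version = as.character(utils::packageVersion("coexpipe")),
                   config = unclass(cfg), counts = counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(de = de, de_counts = de_counts, dependence = dep,
                 model = model, assignment = assign, summary = summ,
                 plm = plm, plm_enrichment = enr, go = go_res,
                 network = net, hubs = hubs, truth = truth,
                 manifest = manifest))
}

#' Summarise a finished pipeline run
#'
#' Builds a plain-text report from the tables `run_pipeline()` wrote: the DE
#' count table (one row per comparison, genes up / genes down), the
#' per-cluster boxplot summaries and interpretability calls, enrichment
#' hits, the network degree summary, and — when simulation truth is present
#' in the output directory — effect-recovery metrics.
#'
#' @param out_dir The pipeline output directory.
#' @param path File to write (default `report.txt` inside `out_dir`).
#' @return The report lines, invisibly; missing stage outputs are reported
#'   as gaps.
#' @export
make_report <- function(out_dir, path = file.path(out_dir, "report.txt")) {
  lines <- c("Pipeline report", "===============", "")
  grab <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  dec <- grab("de_counts.tsv")
  if (is.null(dec)) {
    lines <- c(lines, "[missing] differential-expression counts", "")
  } else {
    lines <- c(lines, "Number of differentially expressed genes",
               sprintf("%-28s %9s %10s", "Comparison", "Genes up", "Genes down"),
               sprintf("%-28s %9d %10d", dec$comparison, dec$genes_up,
                       dec$genes_down), "")
  }
  cs <- grab("cluster_summary.tsv")
  if (is.null(cs)) {
    lines <- c(lines, "[missing] cluster summary", "")
  } else if (nrow(cs) == 0) {
    lines <- c(lines, "Zero interpretable clusters", "")
  } else {
    lines <- c(lines, sprintf("Clusters: %d found, %d interpretable (>50%% DE rule)",
                              nrow(cs), sum(cs$interpretable)),
               sprintf(" cluster %2d: size %4d, max DE %5.1f%%%s", cs$cluster,
                       cs$size, cs$max_de_percent,
                       ifelse(cs$interpretable, "", "  [excluded]")), "")
  }
  for (f in c(plm = "plm_enrichment.tsv", go = "go_enrichment.tsv")) {
    t <- grab(f)
    lines <- c(lines,
               if (is.null(t)) paste0("[missing] ", f)
               else sprintf("%s: %d significant row(s) of %d", f,
                            sum(t$significant), nrow(t)))
  }
  deg <- grab("degrees.tsv")
  lines <- c(lines, "",
             if (is.null(deg)) "[missing] network degrees"
             else sprintf("Network: %d nodes; degree min %d, median %s, max %d; %d hub(s)",
                          nrow(deg), min(deg$degree),
                          format(stats::median(deg$degree)), max(deg$degree),
                          sum(deg$hub)))
  truth <- grab("truth_logratio.tsv")
  de <- grab("de_results.tsv")
  if (!is.null(truth) && !is.null(de)) {
    lr <- as.matrix(truth[, -1, drop = FALSE])
    rownames(lr) <- truth$gene
    est <- matrix(de$logratio, nrow = length(unique(de$gene)),
                  dimnames = list(unique(de$gene), unique(de$comparison)))
    common <- intersect(rownames(lr), rownames(est))
    rmse <- sqrt(mean((est[common, colnames(est)] -
                         lr[common, colnames(est)])^2))
    lines <- c(lines, "",
               sprintf("Truth recovery: log-ratio RMSE %.4f over %d genes",
                       rmse, length(common)))
  }
  writeLines(lines, path)
  invisible(lines)
}
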