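#' Pipeline run configuration
#'
#' Collects every tunable of an end-to-end run. Defaults mirror the
#' reference analysis: pseudocount 0.5, natural log, 10 PCs for embeddings,
#' correlation edge threshold 0.4, 95 percent stratified subsampling with
#' 1000 iterations, Bonferroni level 0.05 and FDR tiers at 5/10 percent.
#'
#' @param scenario Optional [cohort_scenario()]; when given, inputs are
#'   simulated instead of read from files.
#' @param counts_path,metadata_path,clinical_path,prs_path Input TSV paths
#'   (ignored when `scenario` is given).
#' @param out_dir Output directory.
#' @param pseudocount,log_base Normalisation settings (see [normalize_log()]).
#' @param min_total,max_missing_fraction QC thresholds (see [qc_filter()]).
#' @param n_pcs_residual PCs removed during residualisation; `NULL` resolves
#'   to 10 when batch structure is expected (file inputs, or a scenario with
#'   batch effects) and 0 for scenarios without planted batch structure,
#'   where PC removal would only delete biological signal.
#' @param n_pcs Embedding dimension for disease and patient clustering.
#' @param linkage_cells,linkage Linkage methods for the correlation and
#'   Euclidean resolutions.
#' @param r_threshold Correlation-network edge threshold.
#' @param subsample_fraction,n_iterations Stability settings.
#' @param alpha Bonferroni family-wise level.
#' @param clinical_disease Disease analysed in the cluster-clinical stage.
#' @param seed Integer seed used for every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, counts_path = NULL,
                       metadata_path = NULL, clinical_path = NULL,
                       prs_path = NULL, out_dir = "airdstrat_run",
                       pseudocount = 0.5, log_base = exp(1),
                       min_total = 1000, max_missing_fraction = 0.2,
                       n_pcs_residual = NULL, n_pcs = 10L,
                       linkage_cells = "average", linkage = "ward.D2",
                       r_threshold = 0.4, subsample_fraction = 0.95,
                       n_iterations = 1000L, alpha = 0.05,
                       clinical_disease = "RA", seed = 1L) {
  if (is.null(scenario) && (is.null(counts_path) || is.null(metadata_path))) {
    stop("either a scenario or counts_path + metadata_path must be given")
  }
  if (is.null(n_pcs_residual)) {
    n_pcs_residual <- if (is.null(scenario)) 10L else
      if (!is.null(scenario$confounder_effects$batch)) 10L else 0L
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML file may carry any [run_config()] argument; a `scenario` entry
#' names a scenario builder (`patient_clusters`, `disease_supergroups`,
#' `celltype_blocks`, `reference_cohort`) with optional arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scenario)) {
    builder <- switch(cfg$scenario$builder,
                      patient_clusters = scenario_patient_clusters,
                      disease_supergroups = scenario_disease_supergroups,
                      celltype_blocks = scenario_celltype_blocks,
                      reference_cohort = scenario_reference_cohort,
                      stop("unknown scenario builder: ", cfg$scenario$builder))
    args <- cfg$scenario
    args$builder <- NULL
    cfg$scenario <- do.call(builder, args)
  }
  do.call(run_config, cfg)
}

.stage_log <- function(log_path, stage, detail) {
  cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%H:%M:%S"), stage, detail),
      file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess, the three clustering resolutions, the stability
#' check, the three network layers and the association stage, writing every
#' artifact plus a deterministic manifest (config digest, seed, per-stage
#' row counts, md5 of every output file) to the output directory. Re-running
#' with the same configuration and seed reproduces the manifest byte for
#' byte; wall-clock timings go to `run.log`, which is not part of the
#' manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  stages <- list()
  written <- character(0)
  emit <- function(name) written <<- c(written, file.path(out, name))

  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      .stage_log(log_path, stage, paste("FAILED:", conditionMessage(e)))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", out, ")", call. = FALSE)
    })
    .stage_log(log_path, stage,
               sprintf("done in %.1fs", as.numeric(Sys.time() - t0, "secs")))
    res
  }

  # -- stage 1: inputs -----------------------------------------------------
  inputs <- run_stage("inputs", {
    if (!is.null(config$scenario)) {
      cohort <- generate_cohort(config$scenario)
      write_cohort(cohort, file.path(out, "cohort"))
      list(counts = cohort$counts, meta = cohort$metadata,
           clinical = cohort$clinical, prs = cohort$prs,
           truth = cohort$truth)
    } else {
      list(counts = read_cell_counts(config$counts_path),
           meta = read_sample_metadata(config$metadata_path),
           clinical = if (!is.null(config$clinical_path))
             utils::read.delim(config$clinical_path,
                               stringsAsFactors = FALSE) else NULL,
           prs = if (!is.null(config$prs_path))
             utils::read.delim(config$prs_path,
                               stringsAsFactors = FALSE) else NULL,
           truth = NULL)
    }
  })
  stages$inputs <- list(n_samples = nrow(inputs$counts),
                        n_cell_types = ncol(inputs$counts))

  # -- stage 2: preprocess -------------------------------------------------
  pre <- run_stage("preprocess", {
    qc <- qc_filter(inputs$counts, min_total = config$min_total,
                    max_missing_fraction = config$max_missing_fraction)
    utils::write.table(qc$removal_log, file.path(out, "qc_removals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("qc_removals.tsv")
    norm <- normalize_log(qc$counts, pseudocount = config$pseudocount,
                          log_base = config$log_base)
    meta <- inputs$meta[inputs$meta$sample_id %in% rownames(qc$counts), ,
                        drop = FALSE]
    resid <- residualize(norm, meta, n_pcs = config$n_pcs_residual)
    list(norm = norm, resid = resid, meta = meta)
  })
  stages$preprocess <- list(n_samples = nrow(pre$norm$values),
                            n_removed = stages$inputs$n_samples -
                              nrow(pre$norm$values),
                            covariates = pre$resid$covariates_used)

  # -- stage 3: clustering -------------------------------------------------
  clust <- run_stage("clustering", {
    cells <- cluster_cell_types(pre$norm, linkage = config$linkage_cells)
    diseases <- cluster_diseases(pre$norm, pre$meta, n_pcs = config$n_pcs,
                                 linkage = config$linkage)
    patients <- cluster_patients(pre$resid, n_pcs = config$n_pcs,
                                 linkage = config$linkage)
    write_cluster_solution(cells, file.path(out, "clusters_cell_types.json"),
                           file.path(out, "clusters_cell_types.tsv"))
    write_cluster_solution(diseases, file.path(out, "clusters_diseases.json"),
                           file.path(out, "clusters_diseases.tsv"))
    write_cluster_solution(patients, file.path(out, "clusters_patients.json"),
                           file.path(out, "clusters_patients.tsv"))
    for (f in c("clusters_cell_types", "clusters_diseases",
                "clusters_patients")) {
      emit(paste0(f, ".json")); emit(paste0(f, ".tsv"))
    }
    list(cells = cells, diseases = diseases, patients = patients)
  })
  stages$clustering <- list(k_cell_types = clust$cells$k,
                            k_diseases = clust$diseases$k,
                            k_patients = clust$patients$k)

  # -- stage 4: stability --------------------------------------------------
  stab <- run_stage("stability", {
    fn <- function(n, m) cluster_patients(n, n_pcs = config$n_pcs,
                                          linkage = config$linkage)
    rep <- stability_run(pre$resid, pre$meta, fn,
                         fraction = config$subsample_fraction,
                         n_iter = config$n_iterations, seed = config$seed,
                         reference = clust$patients)
    write_stability_report(rep, file.path(out, "stability.json"),
                           file.path(out, "stability.tsv"))
    emit("stability.json"); emit("stability.tsv")
    rep
  })
  stages$stability <- list(mean_concordance = stab$mean_concordance,
                           n_iterations = stab$n_iterations)

  # -- stage 5: networks ---------------------------------------------------
  nets <- run_stage("networks", {
    cc <- cell_correlation_network(pre$norm, r_threshold = config$r_threshold,
                                   alpha = config$alpha)
    dd <- disease_distance_network(clust$diseases$dist)
    dc <- disease_cell_network(pre$norm, pre$meta, alpha = config$alpha)
    write_network(cc, file.path(out, "network_cell_correlation.tsv"),
                  file.path(out, "network_cell_correlation.graphml"))
    write_network(dd, file.path(out, "network_disease_distance.tsv"),
                  file.path(out, "network_disease_distance.graphml"))
    write_network(dc, file.path(out, "network_disease_cell.tsv"),
                  file.path(out, "network_disease_cell.graphml"))
    for (f in c("network_cell_correlation", "network_disease_distance",
                "network_disease_cell")) {
      emit(paste0(f, ".tsv")); emit(paste0(f, ".graphml"))
    }
    list(cc = cc, dd = dd, dc = dc)
  })
  stages$networks <- list(cell_correlation_edges = nrow(nets$cc$edges),
                          disease_distance_edges = nrow(nets$dd$edges),
                          disease_cell_edges = nrow(nets$dc$edges))

  # -- stage 6: associations -----------------------------------------------
  assoc <- run_stage("associations", {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(config$seed)
    het <- cluster_heterogeneity(pre$meta, clust$patients,
                                 alpha = config$alpha)
    write_associations(het, file.path(out, "heterogeneity.tsv"))
    emit("heterogeneity.tsv")
    frac <- cluster_fractions(pre$meta, clust$patients)
    utils::write.table(as.data.frame.matrix(frac$cluster_given_disease),
                       file.path(out, "cluster_fractions.tsv"), sep = "\t",
                       quote = FALSE)
    emit("cluster_fractions.tsv")
    res <- list(het = het, frac = frac)
    if (!is.null(inputs$clinical)) {
      res$clinical <- cluster_clinical_assoc(
        inputs$clinical, clust$patients, pre$meta,
        disease = config$clinical_disease, alpha = config$alpha)
      write_associations(res$clinical, file.path(out, "clinical_assoc.tsv"))
      emit("clinical_assoc.tsv")
    }
    if (!is.null(inputs$prs)) {
      res$prs <- prs_assoc(inputs$prs, clinical = inputs$clinical,
                           norm = pre$norm)
      write_associations(res$prs, file.path(out, "prs_assoc.tsv"))
      emit("prs_assoc.tsv")
    }
    res
  })
  stages$associations <- list(
    n_heterogeneity = nrow(assoc$het),
    n_clinical = if (is.null(assoc$clinical)) 0L else nrow(assoc$clinical),
    n_prs = if (is.null(assoc$prs)) 0L else nrow(assoc$prs))

  # -- manifest ------------------------------------------------------------
  cfg_for_digest <- unclass(config)
  cfg_for_digest$scenario <- NULL
  cfg_for_digest$out_dir <- NULL  # analysis parameters only, not location
  cfg_for_digest <- cfg_for_digest[sort(names(cfg_for_digest))]
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(cfg_for_digest, cfg_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  written <- sort(unique(c(written, cfg_path,
                           list.files(file.path(out, "cohort"),
                                      full.names = TRUE))))
  digests <- tools::md5sum(written)
  names(digests) <- sub(out, "", names(digests), fixed = TRUE)
  names(digests) <- sub("^/", "", names(digests))
  manifest <- list(package = "airdstrat",
                   version = as.character(utils::packageVersion("airdstrat")),
                   seed = config$seed, stages = stages,
                   files = as.list(digests))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a cohort and validate recovery of the planted structure
#'
#' Generates a cohort, runs preprocessing and patient clustering in memory
#' and compares the result to the planted truth: adjusted Rand index and
#' selected cluster number, per-disease heterogeneity, and (when planted)
#' recovery of clinical and PRS effects at their significance tiers.
#'
#' @param scenario A [cohort_scenario()].
#' @param n_pcs Embedding dimension (default 10).
#' @param n_pcs_residual PCs removed in residualisation. The default 1
#'   removes the leading PC, which in log-fraction data captures the
#'   per-sample compositional common mode introduced by the shared
#'   denominator; builder scenarios plant no batch structure, so no further
#'   PCs are removed.
#' @param stability_iter When > 0, also run the stability check with this
#'   many iterations.
#' @param subsample_fraction Stability subsample fraction.
#' @return A list of class `validation_report` with fields `k_patients`,
#'   `ari`, `heterogeneity`, and where applicable `mean_concordance`,
#'   `clinical_recovered`, `prs_recovered`.
#' @export
simulate_and_validate <- function(scenario, n_pcs = 10L, n_pcs_residual = 1L,
                                  stability_iter = 0L,
                                  subsample_fraction = 0.95) {
  cohort <- generate_cohort(scenario)
  norm <- normalize_log(cohort$counts)
  resid <- residualize(norm, cohort$metadata, n_pcs = n_pcs_residual)
  patients <- cluster_patients(resid, n_pcs = n_pcs)
  truth <- planted_truth(cohort)
  rep <- list(k_patients = patients$k, forced = patients$forced)
  if (!is.null(truth$patient_cluster)) {
    rep$ari <- mclust::adjustedRandIndex(
      truth$patient_cluster[patients$entity_ids], patients$labels)
  }
  rep$heterogeneity <- cluster_heterogeneity(cohort$metadata, patients)
  if (stability_iter > 0L) {
    fn <- function(n, m) cluster_patients(n, n_pcs = n_pcs)
    stab <- stability_run(resid, cohort$metadata, fn,
                          fraction = subsample_fraction,
                          n_iter = stability_iter, seed = scenario$seed)
    rep$mean_concordance <- stab$mean_concordance
    rep$stability <- stab
  }
  if (!is.null(cohort$clinical) && !is.null(truth$clinical_effects)) {
    dz <- if ("RA" %in% cohort$metadata$disease) "RA" else
      cohort$metadata$disease[1]
    assoc <- cluster_clinical_assoc(cohort$clinical, patients,
                                    cohort$metadata, disease = dz)
    rep$clinical_assoc <- assoc
  }
  if (!is.null(cohort$prs) && !is.null(truth$prs_effects)) {
    rep$prs_assoc <- prs_assoc(cohort$prs, clinical = cohort$clinical,
                               norm = norm)
  }
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report\n")
  cat("  selected patient k: ", x$k_patients, "\n", sep = "")
  if (!is.null(x$ari)) cat(sprintf("  ARI vs planted truth: %.3f\n", x$ari))
  if (!is.null(x$mean_concordance)) {
    cat(sprintf("  stability mean concordance: %.3f\n", x$mean_concordance))
  }
  invisible(x)
}
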