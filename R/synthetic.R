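#' Define a synthetic cohort scenario
#'
#' A scenario fixes every parameter of the synthetic cohort generator:
#' per-group sample sizes, the cell-type panel and its baseline fractions,
#' per-group mean log-abundance shifts (archetypes), optional planted patient
#' clusters, log-scale noise (iid or block-correlated), confounder effects
#' (age, sex, batch), per-sample total PBMC draw, and optional clinical / PRS
#' layers with planted effects.
#'
#' The abundance model is multiplicative log-normal on cell fractions: for
#' sample \eqn{s} in group \eqn{g}, the latent log-abundance of cell type
#' \eqn{t} is
#' \deqn{w_{st} = \log b_t + a_{g t} + c_{k(s) t} + x_s^\top \beta_t +
#'   \epsilon_{st},}
#' where \eqn{b_t} is the baseline fraction, \eqn{a} the group archetype,
#' \eqn{c} the planted patient-cluster archetype, \eqn{x_s} the confounders
#' and \eqn{\epsilon} Gaussian log-scale noise. Counts are
#' \eqn{\mathrm{round}(T_s e^{w_{st}})} for a per-sample total \eqn{T_s}
#' drawn log-normal.
#'
#' @param n_per_group Named integer vector: samples per group label.
#' @param cell_types Character vector of cell-type names; must contain the
#'   five lineage totals (see [lineage_totals()]).
#' @param base_fractions Named numeric baseline fractions per cell type.
#' @param archetypes Numeric matrix (groups x cell types) of mean log-abundance
#'   shifts; rownames must cover every group label.
#' @param patient_clusters `NULL`, or a list with `archetypes` (clusters x cell
#'   types matrix, rownames are cluster labels) and `proportions` (numeric
#'   summing to 1, one entry per cluster). Samples are allocated to clusters
#'   within each group by exact largest-remainder allocation of the
#'   proportions, then permuted at random, so realised cluster sizes are
#'   deterministic up to +-1 per group.
#' @param noise_sd Positive log-scale noise standard deviation per cell type.
#' @param correlation_blocks `NULL`, or a list with `blocks` (named list
#'   partitioning cell types), `within_r` (within-block correlation) and
#'   optionally `factor_cor` (block-factor correlation matrix) to generate
#'   block-correlated noise from a latent factor model.
#' @param confounder_effects List with optional named numeric vectors `age`
#'   (per decade of age, centred at 50), `sex` (female = 1) and matrix `batch`
#'   (`n_batches` x cell types additive log shifts).
#' @param n_batches Integer number of assay batches.
#' @param age_range Length-2 numeric, uniform sampling range for age in years.
#' @param female_fraction Probability that a sample is female.
#' @param total_log_mean,total_log_sd Log-normal parameters of the per-sample
#'   total PBMC count (default mean 1e5).
#' @param clinical `NULL`, or a list with `model` (see
#'   [default_clinical_model()]) and `cluster_effects` (named list: patient
#'   cluster label -> named numeric shifts; names may be a feature, or
#'   `delta_<feature>` to shift the treatment-response improvement).
#' @param prs `NULL`, or a list with `scores` (character), `effects` (named
#'   list: score -> named numeric slopes on clinical features or cell types)
#'   and `n_pcs` (number of genetic PCs to simulate).
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#'
#' @return An object of class `cohort_scenario`.
#' @seealso [generate_cohort()], [scenario_patient_clusters()],
#'   [scenario_disease_supergroups()], [scenario_celltype_blocks()]
#' @export
cohort_scenario <- function(n_per_group,
                            cell_types = default_cell_panel(),
                            base_fractions = NULL,
                            archetypes = NULL,
                            patient_clusters = NULL,
                            noise_sd = 0.35,
                            correlation_blocks = NULL,
                            confounder_effects = list(),
                            n_batches = 4L,
                            age_range = c(20, 85),
                            female_fraction = 0.77,
                            total_log_mean = log(1e5),
                            total_log_sd = 0.25,
                            clinical = NULL,
                            prs = NULL,
                            seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop("n_per_group must be a named vector of group sample sizes")
  }
  n_per_group <- vapply(n_per_group, as.integer, integer(1))
  if (any(n_per_group < 1L)) stop("all group sizes must be >= 1")
  p <- length(cell_types)
  missing_lin <- setdiff(lineage_totals(), cell_types)
  if (length(missing_lin) > 0L) {
    stop("cell_types must include the lineage totals; missing: ",
         paste(missing_lin, collapse = ", "))
  }
  if (is.null(base_fractions)) {
    if (!identical(cell_types, default_cell_panel())) {
      stop("base_fractions must be supplied for a non-default panel")
    }
    base_fractions <- .panel_base_fractions()
  }
  base_fractions <- base_fractions[cell_types]
  if (anyNA(base_fractions) || any(base_fractions <= 0)) {
    stop("base_fractions must be positive and cover every cell type")
  }
  groups <- names(n_per_group)
  if (is.null(archetypes)) {
    archetypes <- matrix(0, length(groups), p,
                         dimnames = list(groups, cell_types))
  }
  if (!all(groups %in% rownames(archetypes))) {
    stop("configuration error: archetypes must cover every group label; ",
         "missing: ",
         paste(setdiff(groups, rownames(archetypes)), collapse = ", "))
  }
  if (!all(rownames(archetypes) %in% groups)) {
    stop("configuration error: unknown group label in archetypes: ",
         paste(setdiff(rownames(archetypes), groups), collapse = ", "))
  }
  archetypes <- archetypes[groups, cell_types, drop = FALSE]
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.null(patient_clusters)) {
    pa <- patient_clusters$archetypes
    pr <- patient_clusters$proportions
    if (is.null(rownames(pa)) || nrow(pa) != length(pr)) {
      stop("patient_clusters needs an archetype matrix with cluster rownames ",
           "and one proportion per cluster")
    }
    if (abs(sum(pr) - 1) > 1e-8) stop("cluster proportions must sum to 1")
    patient_clusters$archetypes <- pa[, cell_types, drop = FALSE]
  }
  if (!is.null(correlation_blocks)) {
    bl <- correlation_blocks$blocks
    if (!setequal(unlist(bl), cell_types)) {
      stop("correlation_blocks$blocks must partition the cell types")
    }
    if (is.null(correlation_blocks$factor_cor)) {
      correlation_blocks$factor_cor <- diag(length(bl))
    }
  }
  scen <- list(
    n_per_group = n_per_group, cell_types = cell_types,
    base_fractions = base_fractions, archetypes = archetypes,
    patient_clusters = patient_clusters, noise_sd = noise_sd,
    correlation_blocks = correlation_blocks,
    confounder_effects = confounder_effects, n_batches = as.integer(n_batches),
    age_range = age_range, female_fraction = female_fraction,
    total_log_mean = total_log_mean, total_log_sd = total_log_sd,
    clinical = clinical, prs = prs, seed = as.integer(seed)
  )
  class(scen) <- "cohort_scenario"
  scen
}

#' @export
print.cohort_scenario <- function(x, ...) {
  cat("Synthetic cohort scenario\n")
  cat("  groups:      ", length(x$n_per_group),
      " (n = ", sum(x$n_per_group), ")\n", sep = "")
  cat("  cell types:  ", length(x$cell_types), "\n", sep = "")
  cat("  noise_sd:    ", x$noise_sd, "\n", sep = "")
  if (!is.null(x$patient_clusters)) {
    cat("  planted patient clusters: ",
        nrow(x$patient_clusters$archetypes), "\n", sep = "")
  }
  cat("  seed:        ", x$seed, "\n", sep = "")
  invisible(x)
}

# Exact largest-remainder allocation of n items to proportions p.
.largest_remainder <- function(n, p) {
  q <- n * p
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    frac <- q - k
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    k[take] <- k[take] + 1
  }
  as.integer(k)
}

#' Generate a synthetic cohort from a scenario
#'
#' Draws metadata, latent log-abundances, counts, and (if configured)
#' clinical and PRS tables from the generative model described in
#' [cohort_scenario()]. The output is bit-identical for a fixed seed.
#'
#' @param scenario A [cohort_scenario()] object.
#' @return An object of class `synthetic_cohort`: a list with `counts`
#'   (samples x cell types integer matrix), `metadata` (data.frame with
#'   sample_id, disease, age, sex, batch), `clinical`, `prs` (data.frames or
#'   `NULL`) and `truth` (planted labels and effects; see [planted_truth()]).
#' @export
generate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  sc <- scenario
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(sc$seed)

  groups <- names(sc$n_per_group)
  n <- sum(sc$n_per_group)
  p <- length(sc$cell_types)
  disease <- rep(groups, sc$n_per_group)
  sample_id <- sprintf("S%04d", seq_len(n))

  age <- stats::runif(n, sc$age_range[1], sc$age_range[2])
  sex <- stats::rbinom(n, 1L, sc$female_fraction)
  batch <- sample.int(sc$n_batches, n, replace = TRUE)

  # planted patient clusters: exact largest-remainder allocation per group,
  # randomly permuted within the group
  cluster <- NULL
  if (!is.null(sc$patient_clusters)) {
    labs <- rownames(sc$patient_clusters$archetypes)
    cluster <- character(n)
    for (g in groups) {
      idx <- which(disease == g)
      sizes <- .largest_remainder(length(idx), sc$patient_clusters$proportions)
      cluster[idx] <- sample(rep(labs, sizes))
    }
  }

  # PRS drawn before abundances so planted PRS -> cell-type effects can act
  prs_tab <- NULL
  prs_cell_shift <- matrix(0, n, p, dimnames = list(NULL, sc$cell_types))
  if (!is.null(sc$prs)) {
    scores <- sc$prs$scores
    n_gpc <- if (is.null(sc$prs$n_pcs)) 10L else as.integer(sc$prs$n_pcs)
    prs_tab <- data.frame(sample_id = sample_id)
    for (s in scores) prs_tab[[s]] <- stats::rnorm(n)
    for (j in seq_len(n_gpc)) {
      prs_tab[[paste0("PC", j)]] <- stats::rnorm(n)
    }
    for (s in names(sc$prs$effects)) {
      eff <- sc$prs$effects[[s]]
      hit <- intersect(names(eff), sc$cell_types)
      for (t in hit) {
        prs_cell_shift[, t] <- prs_cell_shift[, t] + eff[[t]] * prs_tab[[s]]
      }
    }
  }

  # latent log-abundances
  w <- matrix(rep(log(sc$base_fractions), each = n), n, p,
              dimnames = list(sample_id, sc$cell_types))
  w <- w + sc$archetypes[disease, , drop = FALSE]
  if (!is.null(cluster)) {
    w <- w + sc$patient_clusters$archetypes[cluster, , drop = FALSE]
  }
  ce <- sc$confounder_effects
  if (!is.null(ce$age)) {
    co <- .expand_coef(ce$age, sc$cell_types)
    w <- w + outer((age - 50) / 10, co)
  }
  if (!is.null(ce$sex)) {
    co <- .expand_coef(ce$sex, sc$cell_types)
    w <- w + outer(as.numeric(sex), co)
  }
  if (!is.null(ce$batch)) {
    bm <- ce$batch
    stopifnot(nrow(bm) == sc$n_batches)
    colnames(bm) <- if (is.null(colnames(bm))) sc$cell_types else colnames(bm)
    w <- w + bm[batch, sc$cell_types, drop = FALSE]
  }
  w <- w + prs_cell_shift
  w <- w + .draw_noise(n, sc)

  totals <- exp(stats::rnorm(n, sc$total_log_mean, sc$total_log_sd))
  counts <- round(totals * exp(w))
  counts[counts < 1] <- 1
  # a subset count may never exceed the total viable PBMC denominator
  denom <- rowSums(counts[, lineage_totals(), drop = FALSE])
  non_lineage <- setdiff(sc$cell_types, lineage_totals())
  counts[, non_lineage] <- pmin(counts[, non_lineage, drop = FALSE], denom)
  storage.mode(counts) <- "integer"

  metadata <- data.frame(sample_id = sample_id, disease = disease,
                         age = age, sex = sex, batch = factor(batch),
                         stringsAsFactors = FALSE)

  clinical_tab <- NULL
  if (!is.null(sc$clinical)) {
    clinical_tab <- .generate_clinical(sc, sample_id, cluster, prs_tab)
  }

  truth <- list(
    group = stats::setNames(disease, sample_id),
    patient_cluster = if (is.null(cluster)) NULL else
      stats::setNames(cluster, sample_id),
    archetypes = sc$archetypes,
    patient_archetypes = if (is.null(sc$patient_clusters)) NULL else
      sc$patient_clusters$archetypes,
    clinical_effects = if (is.null(sc$clinical)) NULL else
      sc$clinical$cluster_effects,
    prs_effects = if (is.null(sc$prs)) NULL else sc$prs$effects
  )

  out <- list(counts = counts, metadata = metadata, clinical = clinical_tab,
              prs = prs_tab, truth = truth, scenario = sc)
  class(out) <- "synthetic_cohort"
  out
}

.expand_coef <- function(coef, cell_types) {
  co <- stats::setNames(numeric(length(cell_types)), cell_types)
  if (is.null(names(coef))) {
    stopifnot(length(coef) == length(cell_types))
    co[] <- coef
  } else {
    co[names(coef)] <- coef
  }
  co
}

# Gaussian log-scale noise, iid or block-correlated via a latent factor model
.draw_noise <- function(n, sc) {
  p <- length(sc$cell_types)
  if (is.null(sc$correlation_blocks)) {
    return(matrix(stats::rnorm(n * p, 0, sc$noise_sd), n, p))
  }
  cb <- sc$correlation_blocks
  b <- length(cb$blocks)
  load <- sqrt(cb$within_r) * sc$noise_sd
  resid_sd <- sqrt(1 - cb$within_r) * sc$noise_sd
  ch <- chol(cb$factor_cor)
  f <- matrix(stats::rnorm(n * b), n, b) %*% ch
  noise <- matrix(stats::rnorm(n * p, 0, resid_sd), n, p,
                  dimnames = list(NULL, sc$cell_types))
  for (j in seq_len(b)) {
    types <- cb$blocks[[j]]
    noise[, types] <- noise[, types, drop = FALSE] + load * f[, j]
  }
  noise
}

#' Default clinical feature model
#'
#' Feature definitions used by the synthetic clinical layer: disease-activity
#' measures observed at baseline and week 24 (the treatment-response delta is
#' baseline minus week 24, so positive delta means improvement), static
#' continuous biomarkers, and binary autoantibody status.
#'
#' @return A list with components `activity` (name -> c(mean, sd) of the
#'   baseline value; improvement is drawn with mean `imp_frac * mean` and the
#'   same sd), `imp_frac`, `static` (name -> c(mean, sd)) and `binary`
#'   (name -> positivity probability).
#' @export
default_clinical_model <- function() {
  list(
    activity = list(
      DAS28_CRP = c(mean = 4.5, sd = 1.2),
      DAS28_ESR = c(mean = 5.0, sd = 1.2),
      SDAI      = c(mean = 26,  sd = 10),
      EGA       = c(mean = 6,   sd = 2),
      morning_stiffness = c(mean = 60, sd = 40)
    ),
    imp_frac = 0.25,
    static = list(
      MTX_dose = c(mean = 8,   sd = 3),
      CRP      = c(mean = 1.5, sd = 2)
    ),
    binary = c(ACPA_positive = 0.743, RF_positive = 0.90)
  )
}

.generate_clinical <- function(sc, sample_id, cluster, prs_tab) {
  n <- length(sample_id)
  model <- if (is.null(sc$clinical$model)) default_clinical_model() else
    sc$clinical$model
  eff <- sc$clinical$cluster_effects
  shift_of <- function(feature) {
    s <- numeric(n)
    if (!is.null(eff) && !is.null(cluster)) {
      for (cl in names(eff)) {
        v <- eff[[cl]]
        if (feature %in% names(v)) s[cluster == cl] <- s[cluster == cl] + v[[feature]]
      }
    }
    if (!is.null(sc$prs) && !is.null(prs_tab)) {
      for (scn in names(sc$prs$effects)) {
        v <- sc$prs$effects[[scn]]
        if (feature %in% names(v)) s <- s + v[[feature]] * prs_tab[[scn]]
      }
    }
    s
  }
  out <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  for (f in names(model$activity)) {
    ms <- model$activity[[f]]
    base <- stats::rnorm(n, ms[["mean"]] + shift_of(f), ms[["sd"]])
    imp <- stats::rnorm(n, model$imp_frac * ms[["mean"]] +
                          shift_of(paste0("delta_", f)), ms[["sd"]])
    out[[paste0(f, "_baseline")]] <- base
    out[[paste0(f, "_week24")]] <- base - imp
    out[[paste0("delta_", f)]] <- imp
  }
  for (f in names(model$static)) {
    ms <- model$static[[f]]
    out[[f]] <- stats::rnorm(n, ms[["mean"]] + shift_of(f), ms[["sd"]])
  }
  for (f in names(model$binary)) {
    lo <- stats::qlogis(model$binary[[f]]) + shift_of(f)
    out[[f]] <- stats::rbinom(n, 1L, stats::plogis(lo))
  }
  out
}

#' Planted truth of a synthetic cohort
#'
#' Returns the planted labels and effect sets of a generated cohort, for use
#' as oracles in recovery tests: the group label per sample, the planted
#' patient-cluster label per sample (if any), the archetype matrices and the
#' planted clinical/PRS association pairs.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @return The cohort's truth record (a list).
#' @export
planted_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort$truth
}

# -- RNG state preservation so generation does not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a synthetic cohort to disk
#'
#' Writes tab-separated counts, metadata, clinical and PRS tables (first
#' column `sample_id`) plus the truth record as JSON into a directory.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  cdf <- data.frame(sample_id = rownames(cohort$counts),
                    cohort$counts, check.names = FALSE)
  utils::write.table(cdf, paths[["counts"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$clinical)) {
    paths[["clinical"]] <- file.path(dir, "clinical.tsv")
    utils::write.table(cohort$clinical, paths[["clinical"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$prs)) {
    paths[["prs"]] <- file.path(dir, "prs.tsv")
    utils::write.table(cohort$prs, paths[["prs"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  truth <- cohort$truth
  truth$archetypes <- NULL
  truth$patient_archetypes <- NULL
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
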