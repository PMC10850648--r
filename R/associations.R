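.assoc_record <- function(feature, group, effect, p, adjusted, tier, n_used) {
  data.frame(feature = feature, group = group, effect = effect, p = p,
             adjusted = adjusted, tier = tier, n_used = n_used,
             stringsAsFactors = FALSE)
}

#' Per-disease heterogeneity of patient-cluster membership
#'
#' For each disease, tests whether its patients distribute across the
#' patient clusters differently from all remaining samples, with a Pearson
#' chi-square test on the 2 x k contingency table. When any expected cell
#' falls below 5 (small disease groups violate the asymptotics) the p-value
#' is obtained by Monte-Carlo permutation instead. The Bonferroni threshold
#' is `alpha` divided by the number of disease groups tested (12 in the
#' reference design, giving 0.05/12).
#'
#' @param meta Metadata with `sample_id` and `disease`.
#' @param patients A patient `cluster_solution`.
#' @param diseases Diseases to test (default: all present, including
#'   controls).
#' @param alpha Nominal level (default 0.05).
#' @param n_families Bonferroni denominator; defaults to the number of
#'   diseases tested.
#' @param mc_B Monte-Carlo replicates when expected cells are small.
#' @return Data.frame of association records (one per disease): `feature` is
#'   the disease, `effect` is Cramer's V of the table, `adjusted` the
#'   Bonferroni-adjusted p, `tier` one of bonferroni/nominal/none.
#' @export
cluster_heterogeneity <- function(meta, patients, diseases = NULL,
                                  alpha = 0.05, n_families = NULL,
                                  mc_B = 10000L) {
  stopifnot(inherits(patients, "cluster_solution"),
            patients$entity_kind == "patient")
  labels <- stats::setNames(patients$labels, patients$entity_ids)
  meta <- meta[meta$sample_id %in% names(labels), , drop = FALSE]
  cl <- labels[meta$sample_id]
  if (length(unique(cl)) < 2L) stop("need at least 2 patient clusters")
  present <- unique(meta$disease)
  if (is.null(diseases)) diseases <- present
  absent <- setdiff(diseases, present)
  if (length(absent) > 0L) {
    warning("disease(s) absent from data skipped: ",
            paste(absent, collapse = ", "))
    diseases <- intersect(diseases, present)
  }
  if (is.null(n_families)) n_families <- length(diseases)
  out <- list()
  for (dz in diseases) {
    tab <- table(factor(meta$disease == dz, levels = c(FALSE, TRUE)),
                 factor(cl))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ht <- stats::chisq.test(tab, simulate.p.value = TRUE, B = mc_B)
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    }
    v <- sqrt(unname(ht$statistic) / sum(tab))  # Cramer's V for a 2 x k table
    p <- ht$p.value
    adj <- min(1, p * n_families)
    tier <- if (p < alpha / n_families) "bonferroni" else
      if (p < alpha) "nominal" else "none"
    out[[dz]] <- .assoc_record(dz, "all_clusters", v, p, adj, tier, sum(tab))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cluster composition fractions
#'
#' @param meta Metadata with `sample_id` and `disease`.
#' @param patients A patient `cluster_solution`.
#' @return List with `disease_given_cluster` (columns = clusters, each
#'   summing to 1) and `cluster_given_disease` (columns = diseases, each
#'   summing to 1).
#' @export
cluster_fractions <- function(meta, patients) {
  labels <- stats::setNames(patients$labels, patients$entity_ids)
  meta <- meta[meta$sample_id %in% names(labels), , drop = FALSE]
  tab <- table(disease = meta$disease, cluster = labels[meta$sample_id])
  list(
    disease_given_cluster = prop.table(tab, margin = 2),
    cluster_given_disease = t(prop.table(tab, margin = 1))
  )
}

.is_binary <- function(v) {
  u <- unique(v[!is.na(v)])
  length(u) <= 2L && all(u %in% c(0, 1, TRUE, FALSE))
}

#' Cluster-versus-clinical associations within a disease
#'
#' One-versus-rest comparison of every clinical feature against every
#' patient cluster, restricted to the patients of one disease. Continuous
#' features are tested by Wilcoxon rank-sum (robust to skewed activity
#' scores) with effect = cluster mean minus rest mean; binary features by
#' Fisher's exact test with effect = log odds ratio (Haldane-corrected).
#' P-values are BH-FDR adjusted across the whole feature-by-cluster family.
#'
#' @param clinical Clinical table with `sample_id` plus feature columns;
#'   treatment-response deltas should already be present (baseline minus
#'   week 24).
#' @param patients A patient `cluster_solution`.
#' @param meta Metadata with `sample_id` and `disease`.
#' @param disease Disease whose patients are analysed (default `"RA"`).
#' @param min_n Minimum non-missing observations per arm (default 5;
#'   feature-cluster pairs below it are skipped and listed in the
#'   `"skipped"` attribute).
#' @param alpha Level for the Bonferroni tier.
#' @return Data.frame of association records; `group` is the cluster label.
#' @export
cluster_clinical_assoc <- function(clinical, patients, meta, disease = "RA",
                                   min_n = 5L, alpha = 0.05) {
  labels <- stats::setNames(patients$labels, patients$entity_ids)
  ids <- meta$sample_id[meta$disease == disease]
  ids <- intersect(intersect(ids, names(labels)), clinical$sample_id)
  if (length(ids) == 0L) stop("no samples of disease '", disease,
                              "' with clinical data and cluster labels")
  cl <- labels[ids]
  cdat <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  features <- setdiff(colnames(cdat), "sample_id")
  clusters <- sort(unique(cl))
  rows <- list()
  skipped <- list()
  for (f in features) {
    v <- cdat[[f]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        feature = f, group = "all", reason = "constant_or_empty",
        stringsAsFactors = FALSE)
      next
    }
    binary <- .is_binary(v)
    for (k in clusters) {
      in_cl <- cl == k
      a <- v[in_cl]
      b <- v[!in_cl]
      if (sum(!is.na(a)) < min_n || sum(!is.na(b)) < min_n) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          feature = f, group = as.character(k), reason = "too_few_obs",
          stringsAsFactors = FALSE)
        next
      }
      if (binary) {
        tab <- table(factor(in_cl, levels = c(TRUE, FALSE)),
                     factor(v, levels = c(1, 0)))
        ht <- stats::fisher.test(tab)
        eff <- log((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
                     ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5)))
        p <- ht$p.value
      } else {
        ht <- stats::wilcox.test(a, b, exact = FALSE)
        eff <- mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)
        p <- ht$p.value
      }
      rows[[length(rows) + 1L]] <- .assoc_record(
        f, as.character(k), eff, p, NA_real_, NA_character_,
        sum(!is.na(a)) + sum(!is.na(b)))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(out) && nrow(out) > 0L) {
    out$adjusted <- stats::p.adjust(out$p, method = "BH")
    out$tier <- significance_tiers(out$p, alpha = alpha)
  }
  attr(out, "skipped") <- if (length(skipped) > 0L)
    do.call(rbind, c(skipped, list(make.row.names = FALSE))) else NULL
  out
}

#' PRS-versus-phenotype associations
#'
#' Regresses every target feature on each polygenic risk score, adjusted for
#' the genetic principal components: linear regression for continuous
#' targets, logistic for binary ones. Effects are the PRS coefficients; BH
#' adjustment is applied per score family and records are flagged at the
#' FDR < 0.10 and p < 0.05 tiers.
#'
#' @param prs PRS table with `sample_id`, one column per score and the
#'   genetic PC columns.
#' @param clinical Optional clinical table (feature targets).
#' @param norm Optional `normalized_matrix` (cell-type targets).
#' @param scores Score column names; default: every non-PC, non-id column.
#' @param pc_prefix Prefix of the genetic PC columns (default `"PC"`).
#' @param adjust_pcs Adjust for genetic PCs (default `TRUE`; an error if the
#'   PC columns are absent).
#' @return Data.frame of association records; `group` is the score name.
#' @export
prs_assoc <- function(prs, clinical = NULL, norm = NULL, scores = NULL,
                      pc_prefix = "PC", adjust_pcs = TRUE) {
  pc_cols <- grep(paste0("^", pc_prefix, "[0-9]+$"), colnames(prs),
                  value = TRUE)
  if (adjust_pcs && length(pc_cols) == 0L) {
    stop("PC adjustment requested but no genetic PC columns found")
  }
  if (is.null(scores)) {
    scores <- setdiff(colnames(prs), c("sample_id", pc_cols))
  }
  targets <- list()
  if (!is.null(clinical)) {
    for (f in setdiff(colnames(clinical), "sample_id")) {
      targets[[f]] <- stats::setNames(clinical[[f]], clinical$sample_id)
    }
  }
  if (!is.null(norm)) {
    stopifnot(inherits(norm, "normalized_matrix"))
    for (f in colnames(norm$values)) {
      targets[[f]] <- stats::setNames(norm$values[, f],
                                      rownames(norm$values))
    }
  }
  if (length(targets) == 0L) stop("no target features supplied")
  pcs <- if (adjust_pcs) as.matrix(prs[, pc_cols, drop = FALSE]) else NULL
  out <- list()
  for (s in scores) {
    recs <- list()
    for (f in names(targets)) {
      y <- targets[[f]][prs$sample_id]
      ok <- !is.na(y) & !is.na(prs[[s]])
      if (sum(ok) < 10L) next
      df <- data.frame(y = y[ok], score = prs[[s]][ok])
      if (!is.null(pcs)) df <- cbind(df, pcs[ok, , drop = FALSE])
      if (.is_binary(y[ok])) {
        fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                           family = stats::binomial()))
      } else {
        fit <- stats::lm(y ~ ., data = df)
      }
      sm <- summary(fit)$coefficients
      recs[[f]] <- .assoc_record(f, s, sm["score", 1],
                                 sm["score", 4], NA_real_, NA_character_,
                                 sum(ok))
    }
    fam <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
    if (!is.null(fam) && nrow(fam) > 0L) {
      fam$adjusted <- stats::p.adjust(fam$p, method = "BH")
      fam$tier <- significance_tiers(fam$p)
    }
    out[[s]] <- fam
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write association records
#'
#' @param records Data.frame of association records.
#' @param tsv_path Output TSV path.
#' @param json_path Optional JSON output path.
#' @return Invisibly, `tsv_path`.
#' @export
write_associations <- function(records, tsv_path, json_path = NULL) {
  utils::write.table(records, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(records, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(tsv_path)
}
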