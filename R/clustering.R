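#' Cluster solution container
#'
#' Holds one hierarchical clustering result at a fixed resolution: the entity
#' kind (cell types, diseases or patients), the agglomeration tree, the
#' selected number of clusters `k` and the labels obtained by cutting the
#' tree at `k`.
#'
#' @param entity_kind One of `"cell_type"`, `"disease"`, `"patient"`.
#' @param hc An [stats::hclust] tree whose labels are the entity ids.
#' @param k Integer number of clusters.
#' @param distance_kind Free-text description of the distance used.
#' @param k_report Per-k admissibility report from [select_k()].
#' @param forced Logical: `TRUE` when no cut satisfied the admissibility rule
#'   and `k` is a fallback.
#' @return An object of class `cluster_solution` with elements
#'   `entity_kind`, `entity_ids`, `labels` (named integer vector), `k`,
#'   `hclust`, `distance_kind`, `k_report`, `forced`.
#' @export
cluster_solution <- function(entity_kind, hc, k, distance_kind,
                             k_report = NULL, forced = FALSE) {
  stopifnot(inherits(hc, "hclust"),
            entity_kind %in% c("cell_type", "disease", "patient"))
  labels <- stats::cutree(hc, k = k)
  structure(
    list(entity_kind = entity_kind, entity_ids = hc$labels,
         labels = labels, k = as.integer(k), hclust = hc,
         distance_kind = distance_kind, k_report = k_report,
         forced = forced),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("Cluster solution (", x$entity_kind, "): ", length(x$entity_ids),
      " entities in k = ", x$k, " clusters",
      if (x$forced) " [forced: no admissible cut]", "\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Cut a cluster solution's tree at another k
#'
#' @param solution A `cluster_solution`.
#' @param k Number of clusters.
#' @return Named integer vector of labels.
#' @export
cut_solution <- function(solution, k) {
  stats::cutree(solution$hclust, k = k)
}

#' Select the number of clusters by admissibility rules
#'
#' The cluster number is swept over candidate cuts of the agglomeration tree
#' and chosen by the per-resolution admissibility condition:
#' \describe{
#'   \item{cell types}{the cut must distinguish the major lineage classes:
#'     no cluster may contain cell types from more than one of T, B and
#'     innate. Purity is monotone in `k`, so the smallest admissible
#'     `k >= 2` is returned.}
#'   \item{diseases}{every cluster must contain at least two disease
#'     entities. Because cuts are nested, singleton clusters persist once
#'     they appear, so admissibility is monotone decreasing in `k` and the
#'     largest admissible `k >= 2` is returned.}
#'   \item{patients}{at least two clusters must each hold fewer than 20
#'     percent of the patients; the smallest admissible `k >= 2` is
#'     returned.}
#' }
#'
#' @param hc An [stats::hclust] tree over the entities.
#' @param entity_kind One of `"cell_type"`, `"disease"`, `"patient"`.
#' @param lineage Named character vector mapping cell types to lineage class
#'   (required for `entity_kind = "cell_type"`).
#' @param small_fraction Patient-rule threshold (default 0.2).
#' @param min_diseases Disease-rule minimum entities per cluster (default 2).
#' @param max_k Largest cut examined (default: number of entities).
#' @return List with `k`, `forced` (no admissible cut found; `k` is the
#'   fallback and a warning is emitted) and `report` (data.frame with one row
#'   per examined `k`: `k`, `satisfied`, `detail`).
#' @export
select_k <- function(hc, entity_kind, lineage = NULL, small_fraction = 0.2,
                     min_diseases = 2L, max_k = NULL) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  if (is.null(max_k)) max_k <- n
  max_k <- min(max_k, n)
  rule <- switch(
    entity_kind,
    cell_type = {
      if (is.null(lineage)) stop("cell-type rule needs a lineage map")
      lin <- lineage[hc$labels]
      if (anyNA(lin)) stop("lineage map does not cover every cell type")
      function(labels) {
        mixed <- tapply(lin, labels, function(z) length(unique(z)) > 1L)
        if (any(mixed)) {
          list(ok = FALSE, detail = paste0(sum(mixed), " cluster(s) mix lineages"))
        } else list(ok = TRUE, detail = "all clusters lineage-pure")
      }
    },
    disease = function(labels) {
      sizes <- table(labels)
      if (any(sizes < min_diseases)) {
        list(ok = FALSE,
             detail = paste0(sum(sizes < min_diseases),
                             " cluster(s) with < ", min_diseases, " diseases"))
      } else list(ok = TRUE, detail = "all clusters hold multiple diseases")
    },
    patient = function(labels) {
      frac <- as.numeric(table(labels)) / length(labels)
      n_small <- sum(frac < small_fraction)
      if (n_small >= 2L) {
        list(ok = TRUE, detail = paste0(n_small, " clusters below ",
                                        small_fraction * 100, "% of patients"))
      } else {
        list(ok = FALSE, detail = paste0(n_small, " cluster(s) below ",
                                         small_fraction * 100, "%"))
      }
    },
    stop("unknown entity kind: ", entity_kind)
  )

  report <- data.frame(k = integer(0), satisfied = logical(0),
                       detail = character(0), stringsAsFactors = FALSE)
  chosen <- NA_integer_
  forced <- FALSE
  for (k in 2:max_k) {
    res <- rule(stats::cutree(hc, k = k))
    report <- rbind(report, data.frame(k = k, satisfied = res$ok,
                                       detail = res$detail,
                                       stringsAsFactors = FALSE))
    if (entity_kind == "disease") {
      # admissibility is monotone decreasing: keep raising k while it holds
      if (res$ok) chosen <- k else break
    } else if (res$ok) {
      chosen <- k
      break
    }
  }
  if (is.na(chosen)) {
    forced <- TRUE
    chosen <- if (entity_kind == "disease") 2L else max_k
    warning("no cut of 2..", max_k, " satisfies the ", entity_kind,
            " admissibility rule; returning k = ", chosen)
  }
  list(k = chosen, forced = forced, report = report)
}

# canonical entity order: lexicographic ids, so equal-height merges resolve
# identically regardless of input order
.order_entities <- function(m) {
  m[, order(colnames(m)), drop = FALSE]
}

#' Hierarchical clustering of cell types on correlation distance
#'
#' Pairwise distance between cell types is `1 - r` with `r` the Pearson
#' correlation of their normalised values across samples. The tree is built
#' by agglomerative clustering (average linkage by default, the standard
#' pairing for correlation distance) and the cluster number is chosen by the
#' lineage-separation admissibility rule.
#'
#' @param norm A `normalized_matrix`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param lineage Named lineage map; defaults to the shipped map for the
#'   panel's cell types.
#' @return A `cluster_solution` (entity kind `"cell_type"`) whose `dist`
#'   element carries the correlation-distance matrix.
#' @export
cluster_cell_types <- function(norm, linkage = "average", lineage = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  values <- norm$values
  if (nrow(values) < 3L || ncol(values) < 3L) {
    stop("need at least 3 samples and 3 cell types")
  }
  sds <- apply(values, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    warning("excluding constant cell type column(s): ",
            paste(colnames(values)[sds == 0 | is.na(sds)], collapse = ", "))
    values <- values[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  values <- .order_entities(values)
  if (is.null(lineage)) lineage <- lineage_map(colnames(values))
  r <- stats::cor(values, use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = linkage)
  sel <- select_k(hc, "cell_type", lineage = lineage)
  sol <- cluster_solution("cell_type", hc, sel$k,
                          distance_kind = "1 - Pearson r",
                          k_report = sel$report, forced = sel$forced)
  sol$dist <- as.matrix(d)
  sol$correlation <- r
  sol
}

#' Hierarchical clustering of diseases on PC-space centroid distance
#'
#' Samples are embedded in the top `n_pcs` principal components of the
#' normalised matrix; each disease is represented by its centroid in that
#' space and diseases are clustered on pairwise Euclidean centroid
#' distances (Ward linkage by default). The cluster number is the largest
#' cut in which every cluster still contains at least two diseases.
#'
#' @param norm A `normalized_matrix`.
#' @param meta Metadata with `sample_id` and `disease`.
#' @param n_pcs Number of principal components for the embedding.
#' @param linkage Agglomeration method.
#' @return A `cluster_solution` (entity kind `"disease"`) with the centroid
#'   distance matrix in `dist` and centroids in `centroids`.
#' @export
cluster_diseases <- function(norm, meta, n_pcs = 10L, linkage = "ward.D2") {
  stopifnot(inherits(norm, "normalized_matrix"))
  idx <- match(rownames(norm$values), meta$sample_id)
  if (anyNA(idx)) stop("metadata missing for some samples")
  disease <- meta$disease[idx]
  sizes <- table(disease)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("excluding disease group(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(disease %in% small)
    norm <- subset_samples(norm, rownames(norm$values)[keep])
    disease <- disease[keep]
  }
  if (length(unique(disease)) < 2L) stop("need at least 2 disease groups")
  n_pcs <- min(n_pcs, nrow(norm$values) - 1L, ncol(norm$values))
  pc <- stats::prcomp(norm$values, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  centroids <- apply(scores, 2, function(v) tapply(v, disease, mean))
  centroids <- centroids[order(rownames(centroids)), , drop = FALSE]
  d <- stats::dist(centroids)
  hc <- stats::hclust(d, method = linkage)
  sel <- select_k(hc, "disease")
  sol <- cluster_solution("disease", hc, sel$k,
                          distance_kind = "Euclidean on PC centroids",
                          k_report = sel$report, forced = sel$forced)
  sol$dist <- as.matrix(d)
  sol$centroids <- centroids
  sol
}

#' Hierarchical clustering of patients on PC embeddings
#'
#' Patients are embedded in the top `n_pcs` principal components of the
#' residualised matrix and clustered on Euclidean distances with Ward
#' linkage; the cluster number is the smallest cut in which at least two
#' clusters each hold fewer than 20 percent of the patients.
#'
#' @param norm A residualised `normalized_matrix` (see [residualize()]).
#' @param n_pcs Number of principal components (reduced with a warning when
#'   it exceeds the available dimensions).
#' @param linkage Agglomeration method.
#' @param small_fraction Patient-rule threshold (default 0.2).
#' @return A `cluster_solution` (entity kind `"patient"`).
#' @export
cluster_patients <- function(norm, n_pcs = 10L, linkage = "ward.D2",
                             small_fraction = 0.2) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (!norm$residualised) {
    stop("cluster_patients expects a residualised matrix; run residualize()")
  }
  avail <- min(nrow(norm$values) - 1L, ncol(norm$values))
  if (n_pcs > avail) {
    warning("n_pcs reduced from ", n_pcs, " to ", avail)
    n_pcs <- avail
  }
  pc <- stats::prcomp(norm$values, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(scores) <- rownames(norm$values)
  d <- stats::dist(scores)
  hc <- stats::hclust(d, method = linkage)
  sel <- select_k(hc, "patient", small_fraction = small_fraction)
  cluster_solution("patient", hc, sel$k,
                   distance_kind = "Euclidean on PC embedding",
                   k_report = sel$report, forced = sel$forced)
}

#' Serialise a cluster solution
#'
#' Writes the labels, selected `k` and merge tree as JSON, and optionally a
#' flat tab-separated label table.
#'
#' @param solution A `cluster_solution`.
#' @param json_path Output JSON path.
#' @param tsv_path Optional output TSV path (`entity_id`, `cluster`).
#' @return Invisibly, `json_path`.
#' @export
write_cluster_solution <- function(solution, json_path, tsv_path = NULL) {
  stopifnot(inherits(solution, "cluster_solution"))
  hc <- solution$hclust
  payload <- list(
    entity_kind = solution$entity_kind,
    k = solution$k,
    forced = solution$forced,
    distance_kind = solution$distance_kind,
    labels = as.list(stats::setNames(unname(solution$labels),
                                     solution$entity_ids)),
    merges = lapply(seq_len(nrow(hc$merge)), function(i) {
      list(left = hc$merge[i, 1], right = hc$merge[i, 2],
           height = hc$height[i])
    })
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    utils::write.table(
      data.frame(entity_id = solution$entity_ids,
                 cluster = unname(solution$labels)),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
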