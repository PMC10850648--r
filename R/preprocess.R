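#' Total viable PBMC count per sample
#'
#' The normalisation denominator: the per-sample sum of the five major
#' lineage totals (CD4 T cells, B cells, NK cells, dendritic cells,
#' monocytes). Samples with a non-positive total are reported by
#' [qc_filter()]; here they simply carry their (non-positive) sum.
#'
#' @param counts Numeric matrix or data.frame, samples in rows, cell types in
#'   columns; must contain the five lineage-total columns.
#' @return Named numeric vector of per-sample totals.
#' @export
total_viable_pbmc <- function(counts) {
  counts <- .as_count_matrix(counts)
  lin <- lineage_totals()
  missing <- setdiff(lin, colnames(counts))
  if (length(missing) > 0L) {
    stop("missing lineage total column(s): ", paste(missing, collapse = ", "))
  }
  rowSums(counts[, lin, drop = FALSE], na.rm = TRUE)
}

.as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    if ("sample_id" %in% colnames(counts)) {
      rn <- counts$sample_id
      counts <- as.matrix(counts[setdiff(colnames(counts), "sample_id")])
      rownames(counts) <- rn
    } else {
      counts <- as.matrix(counts)
    }
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("S%04d", seq_len(nrow(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids in counts")
  storage.mode(counts) <- "double"
  counts
}

#' Normalise counts to log fractions of total viable PBMCs
#'
#' Each count is divided by the sample's total viable PBMC count (sum of the
#' five lineage totals) and log transformed:
#' `value = log((count + pseudocount) / total)`. The transform is invariant
#' to per-sample scaling of the counts (with pseudocount 0) and monotone in
#' the count.
#'
#' @param counts Count matrix/data.frame (samples x cell types).
#' @param pseudocount Non-negative value added to each count before the
#'   fraction; default 0.5 avoids minus infinity at zero counts while
#'   preserving ranks. With `pseudocount = 0`, zero counts are set to `NA`
#'   (treated as missing) rather than producing `-Inf`.
#' @param log_base Base of the logarithm (default natural log).
#' @return An object of class `normalized_matrix`: list with `values`
#'   (log-fraction matrix), `total_pbmc`, `residualised` flag,
#'   `covariates_used`, and the normalisation settings.
#' @export
normalize_log <- function(counts, pseudocount = 0.5, log_base = exp(1)) {
  counts <- .as_count_matrix(counts)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts are not allowed")
  total <- total_viable_pbmc(counts)
  if (any(total <= 0)) {
    stop("non-positive total viable PBMC count for sample(s): ",
         paste(names(total)[total <= 0], collapse = ", "),
         " (run qc_filter first)")
  }
  raw_frac <- sweep(counts, 1, total, "/")
  if (any(raw_frac > 1 + 1e-12, na.rm = TRUE)) {
    stop("fraction above 1: a subset count exceeds its sample's total")
  }
  frac <- sweep(counts + pseudocount, 1, total, "/")
  frac <- pmin(frac, 1)  # the pseudocount may not push a fraction past 1
  if (pseudocount == 0) {
    n_zero <- sum(counts == 0, na.rm = TRUE)
    if (n_zero > 0L) {
      message(n_zero, " zero count(s) set to NA (pseudocount = 0)")
      frac[counts == 0] <- NA
    }
  }
  values <- log(frac) / log(log_base)
  structure(
    list(values = values, total_pbmc = total, residualised = FALSE,
         covariates_used = character(0), covariates = NULL,
         pseudocount = pseudocount, log_base = log_base),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("Normalised immunophenotype matrix: ", nrow(x$values), " samples x ",
      ncol(x$values), " cell types\n", sep = "")
  cat("  residualised: ", x$residualised,
      if (x$residualised) paste0(" (", paste(x$covariates_used, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Subset a normalised matrix by sample
#'
#' Keeps the residualisation state and stored covariate design consistent
#' with the retained samples.
#'
#' @param norm A `normalized_matrix`.
#' @param sample_ids Character vector of samples to keep.
#' @return A `normalized_matrix` restricted to `sample_ids`.
#' @export
subset_samples <- function(norm, sample_ids) {
  stopifnot(inherits(norm, "normalized_matrix"))
  idx <- match(sample_ids, rownames(norm$values))
  if (anyNA(idx)) stop("unknown sample id(s) in subset")
  norm$values <- norm$values[idx, , drop = FALSE]
  norm$total_pbmc <- norm$total_pbmc[idx]
  if (!is.null(norm$covariates)) {
    norm$covariates <- norm$covariates[idx, , drop = FALSE]
  }
  norm
}

#' Remove low-quality samples
#'
#' Explicit quality-control thresholds: samples are removed when their total
#' viable PBMC count falls below `min_total` or when more than
#' `max_missing_fraction` of their cell-type counts are missing (`NA`).
#'
#' @param counts Count matrix/data.frame.
#' @param min_total Minimum total viable PBMC count (default 1000).
#' @param max_missing_fraction Maximum tolerated fraction of missing counts
#'   per sample (default 0.2).
#' @return List with `counts` (retained samples) and `removal_log`
#'   (data.frame: sample_id, reason).
#' @export
qc_filter <- function(counts, min_total = 1000, max_missing_fraction = 0.2) {
  if (min_total < 0 || max_missing_fraction < 0) {
    stop("QC thresholds must be >= 0")
  }
  counts <- .as_count_matrix(counts)
  total <- total_viable_pbmc(counts)
  miss <- rowMeans(is.na(counts))
  bad_total <- total < min_total | total <= 0
  bad_miss <- miss > max_missing_fraction
  removal_log <- rbind(
    data.frame(sample_id = rownames(counts)[bad_total],
               reason = rep("low_total_pbmc", sum(bad_total)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = rownames(counts)[bad_miss & !bad_total],
               reason = rep("excess_missing", sum(bad_miss & !bad_total)),
               stringsAsFactors = FALSE)
  )
  keep <- !(bad_total | bad_miss)
  if (!any(keep)) {
    stop("QC removed every sample (", nrow(counts), " of ", nrow(counts),
         "); check thresholds and input counts")
  }
  list(counts = counts[keep, , drop = FALSE], removal_log = removal_log)
}

#' Residualise confounders from a normalised matrix
#'
#' Replaces each cell-type column by the residuals of an ordinary
#' least-squares fit on age, sex and the top `n_pcs` principal components of
#' the normalised matrix (PCs act as a surrogate for assay batch structure).
#' Residual columns are orthogonal to every covariate. The returned object
#' stores the covariate design; residualising an already-residualised matrix
#' reuses that stored design, so the operation is idempotent.
#'
#' @param norm A `normalized_matrix`.
#' @param meta Sample metadata with columns `sample_id`, `age`, `sex`.
#' @param n_pcs Number of principal components to include (>= 0). With
#'   `n_pcs = 0` only age and sex are removed, the appropriate choice when no
#'   batch structure is present.
#' @return The `normalized_matrix` with residualised `values`,
#'   `residualised = TRUE` and `covariates_used` recorded. Samples with a
#'   missing covariate are excluded (listed in attribute `"excluded"`).
#' @export
residualize <- function(norm, meta, n_pcs = 10L) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (n_pcs < 0) stop("n_pcs must be >= 0")

  if (norm$residualised && !is.null(norm$covariates)) {
    x <- norm$covariates
  } else {
    idx <- match(rownames(norm$values), meta$sample_id)
    if (anyNA(idx)) stop("metadata missing for sample(s): ",
                         paste(rownames(norm$values)[is.na(idx)], collapse = ", "))
    meta <- meta[idx, , drop = FALSE]
    complete <- !(is.na(meta$age) | is.na(meta$sex))
    if (!all(complete)) {
      excluded <- meta$sample_id[!complete]
      message("excluding ", length(excluded),
              " sample(s) with missing covariates")
      norm <- subset_samples(norm, meta$sample_id[complete])
      meta <- meta[complete, , drop = FALSE]
    } else {
      excluded <- character(0)
    }
    x <- cbind(age = meta$age - mean(meta$age), sex = as.numeric(meta$sex))
    n_pcs <- min(n_pcs, nrow(norm$values) - 1L, ncol(norm$values))
    if (n_pcs > 0) {
      pc <- stats::prcomp(norm$values, center = TRUE, scale. = FALSE)
      k <- min(n_pcs, ncol(pc$x))
      x <- cbind(x, pc$x[, seq_len(k), drop = FALSE])
    }
    keep <- apply(x, 2, function(v) stats::sd(v) > 0)
    if (!all(keep)) {
      warning("dropping zero-variance covariate(s): ",
              paste(colnames(x)[!keep], collapse = ", "))
      x <- x[, keep, drop = FALSE]
    }
    attr(x, "excluded") <- excluded
  }

  design <- cbind(intercept = 1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("rank-deficient covariate matrix (rank ", qrd$rank, " < ",
         ncol(design), " columns)")
  }
  norm$values <- qr.resid(qrd, norm$values)
  norm$residualised <- TRUE
  norm$covariates <- x
  norm$covariates_used <- colnames(x)
  attr(norm, "excluded") <- attr(x, "excluded")
  norm
}

#' Read a count matrix from a tab-separated file
#'
#' Expects a header row of cell-type names and a first column `sample_id`.
#'
#' @param path File path.
#' @return Numeric matrix with sample-id rownames.
#' @export
read_cell_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) {
    stop("counts file ", path, " lacks a 'sample_id' column")
  }
  .as_count_matrix(df)
}

#' Read a sample metadata table from a tab-separated file
#'
#' @param path File path. Must contain columns `sample_id`, `disease`,
#'   `age`, `sex`; `disease` values are checked against the 12-label
#'   vocabulary.
#' @return A data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "disease", "age", "sex")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0L) {
    stop("metadata file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(df$disease), disease_labels())
  if (length(bad) > 0L) {
    stop("unknown disease label(s): ", paste(bad, collapse = ", "))
  }
  df
}
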