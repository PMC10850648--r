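#' Stratified subsample of a cohort
#'
#' Draws `ceiling(fraction * n_g)` samples without replacement from each
#' disease group `g` and returns the union, so every group keeps (at least)
#' the requested fraction.
#'
#' @param meta Metadata with `sample_id` and `disease`.
#' @param fraction Fraction in (0, 1].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return Character vector of retained sample ids.
#' @export
stratified_subsample <- function(meta, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  out <- character(0)
  for (g in unique(meta$disease)) {
    ids <- meta$sample_id[meta$disease == g]
    if (length(ids) == 0L) {
      warning("empty disease group skipped: ", g)
      next
    }
    take <- ceiling(fraction * length(ids))
    out <- c(out, if (take >= length(ids)) ids else sample(ids, take))
  }
  out
}

# Exact maximum-agreement assignment on a contingency table via bitmask
# dynamic programming over the smaller dimension (exact for up to 20
# clusters; partitions here have far fewer).
.max_agreement <- function(tab) {
  r <- nrow(tab)
  c <- ncol(tab)
  if (r > c) return(.max_agreement(t(tab)))
  if (r > 20L) stop("assignment matching supports up to 20 clusters")
  # dp over columns, mask of matched rows; skipping a column is allowed
  n_mask <- bitwShiftL(1L, r)
  dp <- rep(-1, n_mask)
  dp[1] <- 0
  for (j in seq_len(c)) {
    new_dp <- dp
    for (mask in which(dp >= 0) - 1L) {
      for (i in seq_len(r)) {
        bit <- bitwShiftL(1L, i - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          nm <- bitwOr(mask, bit) + 1L
          cand <- dp[mask + 1L] + tab[i, j]
          if (cand > new_dp[nm]) new_dp[nm] <- cand
        }
      }
    }
    dp <- new_dp
  }
  max(dp)
}

#' Concordance between two cluster solutions
#'
#' Restricts the reference solution to the entities shared with the
#' candidate, matches candidate clusters to reference clusters by
#' maximum-agreement assignment on the contingency table (exact; computed by
#' dynamic programming), and returns the fraction of shared entities whose
#' matched labels agree. When the two solutions use different numbers of
#' clusters the assignment is computed on the rectangular table and
#' unmatched clusters contribute disagreements, so instability of the
#' selected cluster number is penalised.
#'
#' @param reference,candidate `cluster_solution` objects (or named label
#'   vectors); the candidate's entities must be a subset of the reference's.
#' @return Concordance between 0 and 1, with the adjusted Rand index attached as
#'   attribute `"ari"` for diagnostics.
#' @export
concordance <- function(reference, candidate) {
  ref <- if (inherits(reference, "cluster_solution")) {
    stats::setNames(reference$labels, reference$entity_ids)
  } else reference
  cand <- if (inherits(candidate, "cluster_solution")) {
    stats::setNames(candidate$labels, candidate$entity_ids)
  } else candidate
  shared <- intersect(names(cand), names(ref))
  if (length(shared) == 0L) stop("no shared entities between solutions")
  if (length(shared) < length(cand)) {
    stop("candidate contains entities absent from the reference")
  }
  ref <- ref[shared]
  cand <- cand[shared]
  tab <- table(ref, cand)
  agree <- .max_agreement(tab)
  out <- agree / length(shared)
  attr(out, "ari") <- mclust::adjustedRandIndex(ref, cand)
  out
}

#' Subsampling stability of a clustering
#'
#' Repeats de novo clustering (including cluster-number selection) on
#' stratified subsamples and scores each repeat by its concordance with the
#' full-data solution restricted to the subsample.
#'
#' @param norm A `normalized_matrix` (residualised when the cluster function
#'   requires it).
#' @param meta Metadata with `sample_id` and `disease`.
#' @param cluster_fn Function `(norm, meta) -> cluster_solution` re-run on
#'   every subsample.
#' @param fraction Subsample fraction per disease group (default 0.95).
#' @param n_iter Number of iterations (default 1000; use fewer for quick
#'   checks).
#' @param seed Integer seed; per-iteration seeds are derived from it.
#' @param reference Optional precomputed full-data solution (computed from
#'   `norm` when `NULL`).
#' @return An object of class `stability_report`: list with `n_iterations`,
#'   `subsample_fraction`, `concordance_per_iteration` (NA where an
#'   iteration failed), `mean_concordance`, `median_concordance`,
#'   `pooled_concordance` (total matched entities over total entities),
#'   `ari_per_iteration`, `n_failed` and `seed`.
#' @export
stability_run <- function(norm, meta, cluster_fn, fraction = 0.95,
                          n_iter = 1000L, seed = 1L, reference = NULL) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (is.null(reference)) reference <- cluster_fn(norm, meta)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)

  conc <- rep(NA_real_, n_iter)
  ari <- rep(NA_real_, n_iter)
  agree_total <- 0
  n_total <- 0
  for (i in seq_len(n_iter)) {
    ids <- stratified_subsample(meta, fraction, seed = iter_seeds[i])
    res <- tryCatch({
      sub_norm <- subset_samples(norm, ids)
      sub_meta <- meta[meta$sample_id %in% ids, , drop = FALSE]
      cand <- cluster_fn(sub_norm, sub_meta)
      concordance(reference, cand)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      conc[i] <- as.numeric(res)
      ari[i] <- attr(res, "ari")
      agree_total <- agree_total + as.numeric(res) * length(ids)
      n_total <- n_total + length(ids)
    }
  }
  structure(
    list(n_iterations = n_iter, subsample_fraction = fraction,
         concordance_per_iteration = conc,
         mean_concordance = mean(conc, na.rm = TRUE),
         median_concordance = stats::median(conc, na.rm = TRUE),
         pooled_concordance = if (n_total > 0) agree_total / n_total else NA_real_,
         ari_per_iteration = ari,
         n_failed = sum(is.na(conc)),
         seed = seed),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report: ", x$n_iterations, " iterations at fraction ",
      x$subsample_fraction, "\n", sep = "")
  cat(sprintf("  mean concordance:   %.4f\n", x$mean_concordance))
  cat(sprintf("  median concordance: %.4f\n", x$median_concordance))
  cat(sprintf("  pooled concordance: %.4f\n", x$pooled_concordance))
  if (x$n_failed > 0) cat("  failed iterations: ", x$n_failed, "\n")
  invisible(x)
}

#' Write a stability report
#'
#' JSON for the summary plus an optional per-iteration TSV.
#'
#' @param report A `stability_report`.
#' @param json_path Output JSON path.
#' @param tsv_path Optional TSV path (iteration, concordance, ari).
#' @return Invisibly, `json_path`.
#' @export
write_stability_report <- function(report, json_path, tsv_path = NULL) {
  stopifnot(inherits(report, "stability_report"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  if (!is.null(tsv_path)) {
    utils::write.table(
      data.frame(iteration = seq_len(report$n_iterations),
                 concordance = report$concordance_per_iteration,
                 ari = report$ari_per_iteration),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
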