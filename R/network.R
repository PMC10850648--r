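#' Map p-values to significance tiers
#'
#' Assigns each p-value the strongest tier it reaches within its
#' multiple-testing family: `bonferroni` (p below `alpha / family_size`),
#' `fdr5` / `fdr10` (Benjamini-Hochberg adjusted p below 0.05 / 0.10),
#' `nominal` (p below 0.05), else `none`.
#'
#' @param p Numeric vector of p-values forming one family.
#' @param alpha Family-wise level for the Bonferroni tier (default 0.05).
#' @param family_size Family size for the Bonferroni denominator; defaults
#'   to `length(p)` but may be larger (e.g. all possible pairs when only a
#'   subset was tested).
#' @return Character vector of tiers, same length as `p`.
#' @export
significance_tiers <- function(p, alpha = 0.05, family_size = length(p)) {
  adj <- stats::p.adjust(p, method = "BH")
  tier <- rep("none", length(p))
  tier[p < 0.05] <- "nominal"
  tier[adj < 0.10] <- "fdr10"
  tier[adj < 0.05] <- "fdr5"
  tier[p < alpha / family_size] <- "bonferroni"
  tier
}

.new_network <- function(nodes, edges, layer) {
  structure(list(nodes = nodes, edges = edges, layer = layer),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat("Network graph [", x$layer, "]: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Cell-type correlation network
#'
#' Builds the all-pairs Pearson correlation network of the normalised cell
#' abundances: an undirected edge is drawn for every pair with `|r|`
#' strictly above `r_threshold` (default 0.4), weighted by `|r|` and signed
#' by the sign of `r`. Each pair's correlation test p-value is mapped to a
#' significance tier with the Bonferroni denominator equal to the number of
#' cell-type pairs.
#'
#' @param norm A `normalized_matrix`.
#' @param r_threshold Absolute-correlation edge threshold (strict).
#' @param alpha Family-wise level for the Bonferroni tier.
#' @return A `network_graph` (layer `"cell_correlation"`). Constant columns
#'   are retained as isolated nodes with a warning.
#' @export
cell_correlation_network <- function(norm, r_threshold = 0.4, alpha = 0.05) {
  stopifnot(inherits(norm, "normalized_matrix"))
  values <- norm$values
  if (nrow(values) < 3L) stop("need at least 3 samples")
  sds <- apply(values, 2, stats::sd, na.rm = TRUE)
  constant <- colnames(values)[sds == 0 | is.na(sds)]
  if (length(constant) > 0L) {
    warning("constant cell type(s) left isolated: ",
            paste(constant, collapse = ", "))
  }
  types <- colnames(values)
  active <- setdiff(types, constant)
  pairs <- utils::combn(active, 2)
  n_pairs <- ncol(pairs)
  r <- numeric(n_pairs)
  p <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    ct <- stats::cor.test(values[, pairs[1, i]], values[, pairs[2, i]],
                          method = "pearson")
    r[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  tier <- significance_tiers(p, alpha = alpha, family_size = n_pairs)
  keep <- abs(r) > r_threshold
  edges <- data.frame(
    source = pairs[1, keep], target = pairs[2, keep],
    weight = abs(r[keep]),
    sign = ifelse(r[keep] > 0, "positive", "negative"),
    tier = tier[keep], r = r[keep], p = p[keep],
    stringsAsFactors = FALSE
  )
  nodes <- data.frame(id = types, kind = "cell_type",
                      stringsAsFactors = FALSE)
  .new_network(nodes, edges, "cell_correlation")
}

#' Disease inverse-distance network
#'
#' Converts pairwise disease distances to weights `w = 1/d` and retains the
#' edges whose weight strictly exceeds one third of the maximum weight.
#'
#' @param dist Symmetric positive distance matrix (or `dist` object) over
#'   diseases, e.g. the `dist` element of [cluster_diseases()].
#' @param zero_cap Weight assigned (with a warning) to zero distances.
#' @return A `network_graph` (layer `"disease_distance"`).
#' @export
disease_distance_network <- function(dist, zero_cap = 1e6) {
  d <- as.matrix(dist)
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("D", seq_len(nrow(d)))
  pairs <- utils::combn(seq_along(labs), 2)
  dv <- d[t(pairs)]
  if (any(dv < 0)) stop("distances must be non-negative")
  w <- ifelse(dv == 0, zero_cap, 1 / dv)
  if (any(dv == 0)) {
    warning(sum(dv == 0), " zero distance(s) capped at weight ", zero_cap)
  }
  keep <- w > max(w) / 3
  edges <- data.frame(
    source = labs[pairs[1, keep]], target = labs[pairs[2, keep]],
    weight = w[keep], sign = "positive", tier = "none",
    distance = dv[keep], stringsAsFactors = FALSE
  )
  nodes <- data.frame(id = labs, kind = "disease", stringsAsFactors = FALSE)
  .new_network(nodes, edges, "disease_distance")
}

# Fast backward-forward stepwise logistic selection by AIC/BIC.
# Starts from the full model; at each step evaluates every single-variable
# drop and add (forced covariates are never dropped) and applies the best
# criterion-improving move until none improves.
.stepwise_logistic <- function(y, x, forced = NULL, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  n <- length(y)
  pen <- if (criterion == "AIC") 2 else log(n)
  xf <- if (is.null(forced)) NULL else as.matrix(forced)
  eta0 <- NULL  # warm start: linear predictor of the current model
  fit_sel <- function(sel, etastart = NULL) {
    design <- cbind(1, xf, x[, sel, drop = FALSE])
    suppressWarnings(
      stats::glm.fit(design, y, family = stats::binomial(),
                     etastart = etastart))
  }
  crit_of <- function(sel) {
    fit <- fit_sel(sel, etastart = eta0)
    fit$deviance + pen * (1 + length(sel) +
                            if (is.null(xf)) 0 else ncol(xf))
  }
  vars <- colnames(x)
  sel <- vars
  cur_fit <- fit_sel(sel)
  eta0 <- cur_fit$linear.predictors
  current <- cur_fit$deviance + pen * (1 + length(sel) +
                                         if (is.null(xf)) 0 else ncol(xf))
  repeat {
    best_move <- NULL
    best_crit <- current
    for (v in sel) {
      cand <- crit_of(setdiff(sel, v))
      if (cand < best_crit - 1e-8) {
        best_crit <- cand
        best_move <- list(op = "drop", var = v)
      }
    }
    for (v in setdiff(vars, sel)) {
      cand <- crit_of(c(sel, v))
      if (cand < best_crit - 1e-8) {
        best_crit <- cand
        best_move <- list(op = "add", var = v)
      }
    }
    if (is.null(best_move)) break
    sel <- if (best_move$op == "drop") setdiff(sel, best_move$var) else
      c(sel, best_move$var)
    cur_fit <- fit_sel(sel)
    eta0 <- cur_fit$linear.predictors
    current <- best_crit
  }
  sel
}

#' Disease-versus-control stepwise association network
#'
#' For every disease with enough cases, fits a logistic regression of
#' disease-versus-control status on the normalised cell-type abundances with
#' sex (optionally age) as a forced adjustment covariate, performs
#' backward-forward stepwise selection from the full model by AIC (or BIC),
#' and draws a directed edge for every retained cell type. Edge sign follows
#' the coefficient ("increasing" or "decreasing" dosage of the cell type on
#' the disease); the Wald p-values of all retained disease-by-cell-type
#' coefficients form a single multiple-testing family across the whole
#' network for the significance tiers. Post-selection p-values are reported
#' as such in the graph metadata.
#'
#' @param norm A `normalized_matrix`.
#' @param meta Metadata with `sample_id`, `disease`, `sex` (and `age` when
#'   `adjust_age`).
#' @param control_label Label of the control group (default `"control"`).
#' @param criterion `"BIC"` (default) or `"AIC"`. With ~46 correlated
#'   predictors and a few hundred samples per disease model, AIC's constant
#'   penalty retains a large number of null cell types (the five lineage
#'   log-fractions are near-collinear by compositional closure, which
#'   inflates conditional Wald statistics); BIC's `log(n)` penalty restores
#'   type-I control while keeping power for moderate effects.
#' @param adjust_age Also force age into the model (off by default).
#' @param min_cases Minimum number of cases per disease (default 10; smaller
#'   diseases are skipped with a warning).
#' @param alpha Family-wise level for the Bonferroni tier.
#' @return A `network_graph` (layer `"disease_cell"`) with directed tiered
#'   edges.
#' @export
disease_cell_network <- function(norm, meta, control_label = "control",
                                 criterion = "BIC", adjust_age = FALSE,
                                 min_cases = 10L, alpha = 0.05) {
  stopifnot(inherits(norm, "normalized_matrix"))
  idx <- match(rownames(norm$values), meta$sample_id)
  if (anyNA(idx)) stop("metadata missing for some samples")
  meta <- meta[idx, , drop = FALSE]
  if (!control_label %in% meta$disease) {
    stop("control group '", control_label, "' absent from metadata")
  }
  diseases <- setdiff(unique(meta$disease), control_label)
  rows <- list()
  for (dz in diseases) {
    in_model <- meta$disease %in% c(dz, control_label)
    if (sum(meta$disease == dz) < min_cases) {
      warning("skipping ", dz, ": fewer than ", min_cases, " cases")
      next
    }
    y <- as.integer(meta$disease[in_model] == dz)
    x <- norm$values[in_model, , drop = FALSE]
    forced <- cbind(sex = as.numeric(meta$sex[in_model]))
    if (adjust_age) forced <- cbind(forced, age = meta$age[in_model])
    # perfect single-variable separation makes the likelihood unbounded;
    # drop such cell types up front
    sep <- vapply(colnames(x), function(v) {
      max(x[y == 0, v]) < min(x[y == 1, v]) ||
        max(x[y == 1, v]) < min(x[y == 0, v])
    }, logical(1))
    if (any(sep)) {
      warning("dropping perfectly separating cell type(s) for ", dz, ": ",
              paste(colnames(x)[sep], collapse = ", "))
      x <- x[, !sep, drop = FALSE]
    }
    sel <- .stepwise_logistic(y, x, forced = forced, criterion = criterion)
    if (length(sel) == 0L) next
    df <- data.frame(y = y, forced, x[, sel, drop = FALSE],
                     check.names = FALSE)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    sm <- summary(fit)$coefficients
    for (v in sel) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = dz, target = v, weight = sm[v, "Estimate"],
        p = sm[v, "Pr(>|z|)"], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(source = character(0), target = character(0),
               weight = numeric(0), p = numeric(0))
  if (nrow(edges) > 0L) {
    edges$sign <- ifelse(edges$weight > 0, "positive", "negative")
    edges$tier <- significance_tiers(edges$p, alpha = alpha)
    edges <- edges[, c("source", "target", "weight", "sign", "tier", "p")]
  } else {
    edges$sign <- character(0)
    edges$tier <- character(0)
  }
  nodes <- rbind(
    data.frame(id = diseases, kind = "disease", stringsAsFactors = FALSE),
    data.frame(id = colnames(norm$values), kind = "cell_type",
               stringsAsFactors = FALSE)
  )
  net <- .new_network(nodes, edges, "disease_cell")
  net$directed <- TRUE
  net$note <- "Wald p-values are post-selection (computed on the selected model)"
  net
}

#' Convert a network to an igraph object
#'
#' @param net A `network_graph`.
#' @return An [igraph::graph] with the edge attributes of the layer.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "network_graph"))
  igraph::graph_from_data_frame(net$edges, directed = isTRUE(net$directed),
                                vertices = net$nodes)
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param net A `network_graph`.
#' @param tsv_path Output TSV path (source, target, weight, sign, tier).
#' @param graphml_path Optional GraphML output path.
#' @return Invisibly, `tsv_path`.
#' @export
write_network <- function(net, tsv_path, graphml_path = NULL) {
  stopifnot(inherits(net, "network_graph"))
  utils::write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  invisible(tsv_path)
}
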