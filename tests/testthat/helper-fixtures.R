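# Fixture builders and independent brute-force oracles used across the suite.

# Wrap a plain value matrix as a normalized_matrix object (for unit tests
# that exercise downstream stages directly).
make_norm <- function(values, residualised = FALSE) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  }
  structure(
    list(values = values, total_pbmc = rep(1, nrow(values)),
         residualised = residualised,
         covariates_used = character(0), covariates = NULL,
         pseudocount = 0.5, log_base = exp(1)),
    class = "normalized_matrix"
  )
}

# Small raw count matrix containing the five lineage totals plus extras.
make_counts <- function(n = 6, seed = 1) {
  set.seed(seed)
  types <- c(lineage_totals(), "Naive_CD4_T", "Plasmablasts", "Th17")
  m <- matrix(rpois(n * length(types), lambda = 500), n, length(types),
              dimnames = list(sprintf("S%04d", seq_len(n)), types))
  m
}

# Literal Benjamini-Hochberg step-up: sort, apply p * n / rank, enforce
# monotonicity from the largest p downwards.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  stepped <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(stepped)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Exhaustive maximum-agreement matching between two labelings (feasible for
# a handful of distinct labels): tries every injective mapping of candidate
# labels onto reference labels, allowing labels to stay unmatched.
oracle_concordance <- function(ref, cand) {
  rl <- unique(ref)
  cl <- unique(cand)
  best <- 0
  recurse <- function(i, used, acc) {
    if (i > length(cl)) {
      best <<- max(best, acc)
      return(invisible())
    }
    recurse(i + 1, used, acc)  # leave cl[i] unmatched
    for (r in setdiff(rl, used)) {
      recurse(i + 1, c(used, r), acc + sum(cand == cl[i] & ref == r))
    }
  }
  recurse(1, character(0), 0)
  best / length(ref)
}

# Tiny two-group scenario for fast end-to-end runs.
tiny_scenario <- function(seed = 1, n1 = 40L, n2 = 30L, noise_sd = 0.35) {
  arch <- matrix(0, 2, 46,
                 dimnames = list(c("RA", "control"), default_cell_panel()))
  arch["RA", c("Th17", "Plasmablasts")] <- 0.8
  cohort_scenario(n_per_group = c(RA = n1, control = n2),
                  archetypes = arch, noise_sd = noise_sd, seed = seed)
}
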