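test_that("correlation distances equal the brute-force 1 - r oracle", {
  set.seed(1)
  types <- c("Th17", "Tfh", "Naive_B", "NK_cells", "Monocytes")
  values <- matrix(rnorm(20 * 5), 20, dimnames = list(NULL, types))
  sol <- cluster_cell_types(make_norm(values))
  oracle <- 1 - cor(values[, sort(types)])
  expect_equal(sol$dist, oracle[rownames(sol$dist), colnames(sol$dist)],
               tolerance = 1e-12)
})

test_that("perfectly correlated cell types are merged first", {
  set.seed(2)
  values <- matrix(rnorm(30 * 5), 30)
  colnames(values) <- c("Th17", "Tfh", "Naive_B", "NK_cells", "Monocytes")
  values <- cbind(values, Memory_B = values[, "Naive_B"])  # exact duplicate
  sol <- cluster_cell_types(make_norm(values))
  expect_equal(sol$dist["Naive_B", "Memory_B"], 0, tolerance = 1e-12)
  first <- sol$hclust$labels[-sol$hclust$merge[1, ]]
  expect_setequal(first, c("Naive_B", "Memory_B"))
})

test_that("constant cell-type columns are excluded with a warning", {
  set.seed(3)
  values <- matrix(rnorm(30 * 4), 30)
  colnames(values) <- c("Th17", "Tfh", "Naive_B", "NK_cells")
  values <- cbind(values, Monocytes = 1)
  expect_warning(sol <- cluster_cell_types(make_norm(values)), "Monocytes")
  expect_false("Monocytes" %in% sol$entity_ids)
})

test_that("planted correlation blocks are recovered as six lineage-pure clusters", {
  scen <- scenario_celltype_blocks(seed = 4)
  coh <- generate_cohort(scen)
  sol <- cluster_cell_types(normalize_log(coh$counts))
  expect_equal(sol$k, 6L)
  expect_false(sol$forced)
  bl <- scen$correlation_blocks$blocks
  truth <- setNames(rep(names(bl), lengths(bl)), unlist(bl))
  expect_gte(mclust::adjustedRandIndex(truth[sol$entity_ids], sol$labels),
             0.99)
})

test_that("cell-type rule selects the first lineage-pure cut on a hand-built tree", {
  # pairs of T, B and innate types; T and B merge before innate joins, so
  # k = 2 mixes lineages and k = 3 is the first pure cut
  labs <- c("T1", "T2", "B1", "B2", "N1", "N2")
  D <- matrix(0.9, 6, 6, dimnames = list(labs, labs))
  D[1:4, 1:4] <- 0.5
  D[1:2, 1:2] <- 0.1
  D[3:4, 3:4] <- 0.1
  D[5:6, 5:6] <- 0.1
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = "average")
  lineage <- c(T1 = "T", T2 = "T", B1 = "B", B2 = "B",
               N1 = "innate", N2 = "innate")
  sel <- select_k(hc, "cell_type", lineage = lineage)
  expect_equal(sel$k, 3L)
  expect_false(sel$forced)
  expect_false(sel$report$satisfied[sel$report$k == 2])
})

test_that("disease rule keeps the largest cut without singleton-disease clusters", {
  # five tight pairs of diseases; cutting beyond five clusters breaks a pair
  labs <- paste0("D", 1:10)
  pair <- rep(1:5, each = 2)
  D <- outer(pair, pair, function(p, q) 10 + pmax(p, q))
  D[outer(pair, pair, "==")] <- 1
  diag(D) <- 0
  dimnames(D) <- list(labs, labs)
  hc <- hclust(as.dist(D), method = "average")
  sel <- select_k(hc, "disease")
  expect_equal(sel$k, 5L)
  expect_true(all(sel$report$satisfied[sel$report$k <= 5]))
  expect_false(sel$report$satisfied[sel$report$k == 6])
})

test_that("patient rule waits for two clusters under 20 percent", {
  set.seed(5)
  x <- c(rep(0, 40), rep(10, 40), rep(20, 12), rep(30, 12)) + rnorm(104, 0, 0.01)
  hc <- hclust(dist(x), method = "ward.D2")
  hc$labels <- sprintf("P%03d", seq_along(x))
  sel <- select_k(hc, "patient")
  # k = 2 and 3 leave at most one small cluster (23% is not < 20%);
  # k = 4 isolates the two 12-patient groups (11.5% each)
  expect_equal(sel$k, 4L)
  expect_false(any(sel$report$satisfied[sel$report$k < 4]))
})

test_that("disease centroid distances match a brute-force PCA oracle", {
  set.seed(6)
  values <- matrix(rnorm(30 * 6), 30)
  colnames(values) <- c("Th17", "Tfh", "Naive_B", "NK_cells", "Monocytes",
                        "Treg")
  rownames(values) <- sprintf("S%04d", 1:30)
  meta <- data.frame(sample_id = rownames(values),
                     disease = rep(c("RA", "SLE", "control"), each = 10))
  sol <- suppressWarnings(cluster_diseases(make_norm(values), meta, n_pcs = 2))
  pc <- prcomp(values, center = TRUE, scale. = FALSE)
  cent <- apply(pc$x[, 1:2], 2, function(v) tapply(v, meta$disease, mean))
  oracle <- as.matrix(dist(cent))
  expect_equal(sol$dist, oracle[rownames(sol$dist), colnames(sol$dist)],
               tolerance = 1e-12)
})

test_that("diseases with identical archetypes collapse to near-zero distance", {
  arch <- matrix(0, 3, 46,
                 dimnames = list(c("RA", "SLE", "control"),
                                 default_cell_panel()))
  arch[c("RA", "SLE"), "Th17"] <- 0.8  # identical archetypes for RA and SLE
  arch["control", "Naive_B"] <- 0.8
  scen <- cohort_scenario(n_per_group = c(RA = 15L, SLE = 15L, control = 15L),
                          archetypes = arch, noise_sd = 1e-6,
                          total_log_sd = 1e-6, seed = 7)
  coh <- generate_cohort(scen)
  sol <- suppressWarnings(
    cluster_diseases(normalize_log(coh$counts), coh$metadata, n_pcs = 2))
  expect_lt(sol$dist["RA", "SLE"], 0.01)
  expect_gt(sol$dist["RA", "control"], 0.1)
})

test_that("planted disease super-groups are recovered at k = 4", {
  scen <- scenario_disease_supergroups(seed = 8)
  coh <- generate_cohort(scen)
  sol <- cluster_diseases(normalize_log(coh$counts), coh$metadata)
  expect_equal(sol$k, 4L)
  ari <- mclust::adjustedRandIndex(scen$disease_supergroup[sol$entity_ids],
                                   sol$labels)
  expect_equal(ari, 1)
})

test_that("tiny disease groups are excluded with a warning", {
  coh <- generate_cohort(tiny_scenario(seed = 9))
  meta <- coh$metadata
  meta$disease[1] <- "GCA"  # a single-sample group
  w <- capture_warnings(
    sol <- cluster_diseases(normalize_log(coh$counts), meta, n_pcs = 2))
  expect_true(any(grepl("GCA", w)))
  expect_false("GCA" %in% rownames(sol$dist))
})

test_that("patient clustering requires a residualised matrix and handles duplicates", {
  set.seed(10)
  base <- matrix(rnorm(20 * 6), 20)
  colnames(base) <- c("Th17", "Tfh", "Naive_B", "NK_cells", "Monocytes",
                      "Treg")
  base[1:10, "Th17"] <- base[1:10, "Th17"] + 4
  base[11, ] <- base[12, ]  # duplicated patients
  expect_error(cluster_patients(make_norm(base)), "residualise")
  sol <- suppressWarnings(cluster_patients(make_norm(base, residualised = TRUE),
                                           n_pcs = 3))
  expect_equal(unname(sol$labels[11]), unname(sol$labels[12]))
})

test_that("merge trees are deterministic and invariant to column order", {
  coh <- generate_cohort(tiny_scenario(seed = 11))
  norm <- normalize_log(coh$counts)
  a <- cluster_cell_types(norm)
  b <- cluster_cell_types(norm)
  expect_identical(a$hclust$merge, b$hclust$merge)
  norm_perm <- norm
  perm <- sample(ncol(norm$values))
  norm_perm$values <- norm$values[, perm]
  c <- cluster_cell_types(norm_perm)
  expect_identical(a$labels[a$entity_ids], c$labels[a$entity_ids])
})

test_that("cutting the tree at k always yields exactly k non-empty clusters", {
  coh <- generate_cohort(tiny_scenario(seed = 12))
  sol <- cluster_cell_types(normalize_log(coh$counts))
  for (k in c(2, 5, 11, 46)) {
    labs <- cut_solution(sol, k)
    expect_equal(length(unique(labs)), k)
  }
})

test_that("patient recovery degrades monotonically along a noise ladder", {
  ari_at <- function(noise) {
    scen <- scenario_patient_clusters(noise_sd = noise,
                                      separation = 2 * 0.35 / noise,
                                      seed = 13)
    coh <- generate_cohort(scen)
    resid <- residualize(normalize_log(coh$counts), coh$metadata, n_pcs = 1)
    sol <- suppressWarnings(cluster_patients(resid))
    mclust::adjustedRandIndex(planted_truth(coh)$patient_cluster[sol$entity_ids],
                              sol$labels)
  }
  ladder <- vapply(c(0.35, 0.7, 1.4), ari_at, numeric(1))
  expect_gte(ladder[1], ladder[2] - 0.02)
  expect_gte(ladder[2], ladder[3] - 0.02)
  expect_gt(ladder[1], 0.9)
})
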