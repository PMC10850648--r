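# Wrap desired patient labels in a cluster_solution by clustering well
# separated 1-d points grouped by label.
fake_solution <- function(labels) {
  stopifnot(!is.null(names(labels)))
  x <- as.numeric(factor(labels)) * 100 + seq_along(labels) * 1e-6
  hc <- hclust(dist(x), method = "ward.D2")
  hc$labels <- names(labels)
  cluster_solution("patient", hc, k = length(unique(labels)),
                   distance_kind = "fixture")
}

test_that("a disease concentrated in one cluster is flagged past Bonferroni", {
  meta <- data.frame(sample_id = sprintf("S%03d", 1:250),
                     disease = rep(c("MCTD", "RA"), c(50, 200)))
  labels <- setNames(c(rep("A", 50), rep(c("A", "B", "C"), length.out = 200)),
                     meta$sample_id)
  sol <- fake_solution(labels)
  set.seed(1)
  rec <- cluster_heterogeneity(meta, sol, n_families = 12)
  expect_lt(rec$p[rec$feature == "MCTD"], 0.05 / 12)
  expect_equal(rec$tier[rec$feature == "MCTD"], "bonferroni")
})

test_that("the 2x2 table statistic matches the closed form", {
  meta <- data.frame(sample_id = sprintf("S%03d", 1:20),
                     disease = rep(c("RA", "SLE"), each = 10))
  labels <- setNames(rep(c("A", "B"), each = 10), meta$sample_id)
  rec <- cluster_heterogeneity(meta, fake_solution(labels))
  # table (10,0 / 0,10): Pearson chi-square = n = 20, Cramer's V = 1
  expect_equal(rec$effect[rec$feature == "RA"], 1)
  expect_equal(rec$p[rec$feature == "RA"], pchisq(20, 1, lower.tail = FALSE))
})

test_that("heterogeneity p-values are invariant to cluster relabeling", {
  set.seed(2)
  meta <- data.frame(sample_id = sprintf("S%03d", 1:120),
                     disease = rep(c("RA", "SLE", "control"), each = 40))
  labels <- setNames(sample(c("A", "B", "C"), 120, replace = TRUE),
                     meta$sample_id)
  relabeled <- setNames(c(A = "C", B = "A", C = "B")[labels], names(labels))
  p1 <- cluster_heterogeneity(meta, fake_solution(labels))$p
  p2 <- cluster_heterogeneity(meta, fake_solution(relabeled))$p
  expect_equal(sort(p1), sort(p2), tolerance = 1e-12)
})

test_that("the heterogeneity test is roughly calibrated under the null", {
  meta <- data.frame(sample_id = sprintf("S%04d", 1:500),
                     disease = rep(c("RA", "SLE"), c(300, 200)))
  set.seed(3)
  rej <- vapply(1:300, function(i) {
    labels <- setNames(sample(paste0("c", 1:4), 500, replace = TRUE,
                              prob = c(0.3, 0.3, 0.25, 0.15)),
                       meta$sample_id)
    rec <- cluster_heterogeneity(meta, fake_solution(labels),
                                 diseases = "RA")
    rec$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("composition fractions sum to one per margin", {
  set.seed(4)
  meta <- data.frame(sample_id = sprintf("S%03d", 1:90),
                     disease = sample(c("RA", "SLE", "SSc"), 90, TRUE))
  labels <- setNames(sample(c("A", "B"), 90, TRUE), meta$sample_id)
  fr <- cluster_fractions(meta, fake_solution(labels))
  expect_equal(unname(colSums(fr$disease_given_cluster)), c(1, 1))
  expect_equal(unname(colSums(fr$cluster_given_disease)), c(1, 1, 1))

  meta$disease <- "RA"
  fr1 <- cluster_fractions(meta, fake_solution(labels))
  expect_true(all(fr1$disease_given_cluster == 1))
})

test_that("a planted treatment-response shift is detected with its sign", {
  detected <- vapply(1:5, function(s) {
    scen <- cohort_scenario(
      n_per_group = c(RA = 200L),
      patient_clusters = list(
        archetypes = matrix(0, 2, 46,
                            dimnames = list(c("c1", "c2"),
                                            default_cell_panel())),
        proportions = c(0.5, 0.5)),
      clinical = list(cluster_effects = list(c1 = c(delta_EGA = -2))),
      seed = s)
    coh <- generate_cohort(scen)
    truth <- planted_truth(coh)$patient_cluster
    sol <- fake_solution(truth)
    c1_label <- as.character(sol$labels[names(truth)[truth == "c1"][1]])
    rec <- cluster_clinical_assoc(coh$clinical, sol, coh$metadata,
                                  disease = "RA")
    hit <- rec[rec$feature == "delta_EGA" & rec$group == c1_label, ]
    nrow(hit) == 1 && hit$adjusted < 0.05 && hit$effect < 0
  }, logical(1))
  expect_gte(sum(detected), 4L)
})

test_that("a null clinical table produces almost no FDR discoveries", {
  rates <- vapply(1:5, function(s) {
    scen <- cohort_scenario(
      n_per_group = c(RA = 150L),
      patient_clusters = list(
        archetypes = matrix(0, 3, 46,
                            dimnames = list(paste0("c", 1:3),
                                            default_cell_panel())),
        proportions = c(0.4, 0.35, 0.25)),
      clinical = list(cluster_effects = NULL),
      seed = 100 + s)
    coh <- generate_cohort(scen)
    rec <- cluster_clinical_assoc(coh$clinical,
                                  fake_solution(planted_truth(coh)$patient_cluster),
                                  coh$metadata, disease = "RA")
    mean(rec$adjusted < 0.05)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("constant clinical features are skipped and logged", {
  scen <- cohort_scenario(
    n_per_group = c(RA = 60L),
    patient_clusters = list(
      archetypes = matrix(0, 2, 46,
                          dimnames = list(c("c1", "c2"),
                                          default_cell_panel())),
      proportions = c(0.5, 0.5)),
    clinical = list(cluster_effects = NULL), seed = 9)
  coh <- generate_cohort(scen)
  coh$clinical$flat_marker <- 1
  rec <- cluster_clinical_assoc(coh$clinical,
                                fake_solution(planted_truth(coh)$patient_cluster),
                                coh$metadata, disease = "RA")
  expect_false("flat_marker" %in% rec$feature)
  expect_true("flat_marker" %in% attr(rec, "skipped")$feature)
})

test_that("one-vs-rest effects of a centred feature balance across equal clusters", {
  set.seed(10)
  n <- 120
  ids <- sprintf("S%03d", 1:n)
  clinical <- data.frame(sample_id = ids, marker = rnorm(n))
  clinical$marker <- clinical$marker - mean(clinical$marker)
  meta <- data.frame(sample_id = ids, disease = "RA")
  labels <- setNames(rep(c("A", "B", "C"), each = 40), ids)
  rec <- cluster_clinical_assoc(clinical, fake_solution(labels), meta,
                                disease = "RA")
  expect_lt(abs(sum(rec$effect[rec$feature == "marker"])), 1e-8)
})

test_that("regressing the PRS on itself returns slope one", {
  set.seed(11)
  n <- 100
  prs <- data.frame(sample_id = sprintf("S%03d", 1:n), prs_ra = rnorm(n))
  for (j in 1:5) prs[[paste0("PC", j)]] <- rnorm(n)
  clinical <- data.frame(sample_id = prs$sample_id, self = prs$prs_ra)
  rec <- suppressWarnings(prs_assoc(prs, clinical = clinical))  # exact fit
  expect_equal(rec$effect[rec$feature == "self"], 1, tolerance = 1e-10)
  expect_lt(rec$p[rec$feature == "self"], 1e-12)
})

test_that("PRS adjustment demands genetic PCs when requested", {
  prs <- data.frame(sample_id = c("S1", "S2"), prs_ra = c(0.1, -0.2))
  clinical <- data.frame(sample_id = c("S1", "S2"), y = c(1.0, 2.0))
  expect_error(prs_assoc(prs, clinical = clinical), "PC")
})

test_that("a planted PRS slope on a cell type is recovered through the matrix", {
  scen <- cohort_scenario(
    n_per_group = c(RA = 200L), seed = 12, noise_sd = 0.3,
    prs = list(scores = "prs_ild", effects = list(prs_ild = c(DCs = 0.15)),
               n_pcs = 5L))
  coh <- generate_cohort(scen)
  rec <- prs_assoc(coh$prs, norm = normalize_log(coh$counts))
  hit <- rec[rec$feature == "DCs", ]
  expect_gt(hit$effect, 0)
  expect_lt(hit$p, 0.05)
})
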