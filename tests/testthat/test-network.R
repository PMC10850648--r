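# Build a column whose empirical Pearson correlation with x is exactly r.
make_cor_col <- function(x, r, noise) {
  x0 <- as.numeric(scale(x))
  z <- noise - x0 * sum(noise * x0) / sum(x0^2)
  z0 <- as.numeric(scale(z))
  r * x0 + sqrt(1 - r^2) * z0
}

test_that("correlation edges follow the strict |r| > threshold rule with signs", {
  set.seed(1)
  n <- 60
  x <- rnorm(n)
  values <- cbind(
    Th17 = x,
    Tfh = make_cor_col(x, 0.9, rnorm(n)),
    Naive_B = make_cor_col(x, 0.3, rnorm(n)),
    NK_cells = make_cor_col(x, -0.5, rnorm(n))
  )
  net <- cell_correlation_network(make_norm(values))
  e <- net$edges
  th <- e[e$source == "Th17" | e$target == "Th17", ]
  partners <- setdiff(c(th$source, th$target), "Th17")
  expect_true(all(c("Tfh", "NK_cells") %in% partners))
  expect_false("Naive_B" %in% partners)
  expect_equal(th$sign[th$target == "Tfh" | th$source == "Tfh"], "positive")
  expect_equal(th$sign[th$target == "NK_cells" | th$source == "NK_cells"],
               "negative")
})

test_that("the correlation threshold boundary is strict", {
  set.seed(2)
  n <- 80
  x <- rnorm(n)
  eps <- 1e-7
  values <- cbind(Th17 = x,
                  Tfh = make_cor_col(x, 0.4 - eps, rnorm(n)),
                  Naive_B = make_cor_col(x, 0.4 + 1e-4, rnorm(n)))
  net <- cell_correlation_network(make_norm(values))
  pairs <- paste(net$edges$source, net$edges$target)
  expect_false(any(grepl("Tfh", pairs) & grepl("Th17", pairs)))
  expect_true(any(grepl("Naive_B", pairs) & grepl("Th17", pairs)))
})

test_that("the correlation edge set equals a brute-force all-pairs scan", {
  set.seed(3)
  types <- c("Th17", "Tfh", "Naive_B", "NK_cells", "Monocytes", "Treg")
  values <- matrix(rnorm(40 * 6), 40, dimnames = list(NULL, types))
  values[, "Tfh"] <- values[, "Th17"] * 0.8 + rnorm(40, 0, 0.4)
  net <- cell_correlation_network(make_norm(values), r_threshold = 0.4)
  oracle <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    r <- cor(values[, i], values[, j])
    if (abs(r) > 0.4) {
      oracle[[length(oracle) + 1L]] <-
        paste(sort(c(types[i], types[j])), collapse = "|")
    }
  }
  got <- apply(net$edges[, c("source", "target")], 1,
               function(z) paste(sort(z), collapse = "|"))
  expect_setequal(got, unlist(oracle))
})

test_that("raising the correlation threshold never adds edges", {
  coh <- generate_cohort(scenario_celltype_blocks(n = 100, seed = 4))
  norm <- normalize_log(coh$counts)
  e1 <- cell_correlation_network(norm, r_threshold = 0.2)$edges
  e2 <- cell_correlation_network(norm, r_threshold = 0.4)$edges
  e3 <- cell_correlation_network(norm, r_threshold = 0.6)$edges
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(e2) %in% key(e1)))
  expect_true(all(key(e3) %in% key(e2)))
})

test_that("inverse-distance weights and the one-third-of-max rule are applied", {
  d <- matrix(0, 3, 3, dimnames = list(c("RA", "SLE", "SSc"),
                                       c("RA", "SLE", "SSc")))
  d["RA", "SLE"] <- d["SLE", "RA"] <- 1
  d["RA", "SSc"] <- d["SSc", "RA"] <- 2
  d["SLE", "SSc"] <- d["SSc", "SLE"] <- 10
  net <- disease_distance_network(d)
  expect_equal(sort(net$edges$weight, decreasing = TRUE), c(1, 0.5))
  expect_false(any(net$edges$weight == 0.1))

  all_equal <- matrix(3, 4, 4); diag(all_equal) <- 0
  dimnames(all_equal) <- list(paste0("D", 1:4), paste0("D", 1:4))
  expect_equal(nrow(disease_distance_network(all_equal)$edges), 6L)
})

test_that("inverse-distance retention matches a brute-force oracle", {
  set.seed(5)
  for (rep in 1:10) {
    p <- matrix(runif(25, 0.5, 5), 5)
    d <- (p + t(p)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("D", 1:5), paste0("D", 1:5))
    net <- disease_distance_network(d)
    w <- 1 / d[upper.tri(d)]
    expect_equal(nrow(net$edges), sum(w > max(w) / 3))
    expect_equal(sort(net$edges$weight), sort(w[w > max(w) / 3]))
  }
})

test_that("zero distances are capped with a warning", {
  d <- matrix(c(0, 0, 1, 0, 0, 2, 1, 2, 0), 3,
              dimnames = list(paste0("D", 1:3), paste0("D", 1:3)))
  expect_warning(net <- disease_distance_network(d, zero_cap = 100), "capped")
  expect_equal(max(net$edges$weight), 100)
})

test_that("BH adjustment matches the literal step-up procedure", {
  set.seed(6)
  for (n in c(1, 5, 37, 100, 1000)) {
    p <- runif(n)^2
    expect_equal(stats::p.adjust(p, method = "BH"), bh_bruteforce(p))
  }
})

test_that("the stepwise selector agrees with the reference implementation", {
  set.seed(7)
  for (rep in 1:4) {
    n <- 90
    x <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("V", 1:8)))
    eta <- 1.2 * x[, 1] - 0.9 * x[, 5]
    y <- rbinom(n, 1, plogis(eta))
    for (crit in c("AIC", "BIC")) {
      mine <- airdstrat:::.stepwise_logistic(y, x, criterion = crit)
      df <- data.frame(y = y, x)
      full <- glm(y ~ ., data = df, family = binomial)
      k <- if (crit == "AIC") 2 else log(n)
      ref <- step(full, direction = "both", trace = 0, k = k,
                  scope = list(lower = ~1))
      ref_vars <- setdiff(names(coef(ref)), "(Intercept)")
      expect_setequal(mine, ref_vars)
    }
  }
})

test_that("a planted cell-type effect yields a signed tiered edge", {
  noise <- 0.35
  arch <- matrix(0, 2, 46,
                 dimnames = list(c("RA", "control"), default_cell_panel()))
  arch["RA", "Plasmablasts"] <- 2 * noise^2  # logistic slope of 2
  hits <- vapply(1:5, function(s) {
    scen <- cohort_scenario(n_per_group = c(RA = 150L, control = 54L),
                            archetypes = arch, noise_sd = noise, seed = s)
    coh <- generate_cohort(scen)
    net <- suppressWarnings(
      disease_cell_network(normalize_log(coh$counts), coh$metadata))
    e <- net$edges
    any(e$target == "Plasmablasts" & e$sign == "positive" & e$tier != "none")
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("a sex-only signal does not flood the network with cell edges", {
  rates <- vapply(1:6, function(s) {
    scen <- cohort_scenario(n_per_group = c(RA = 150L, control = 54L),
                            noise_sd = 0.35, seed = 300 + s)
    coh <- generate_cohort(scen)
    meta <- coh$metadata
    # relabel disease status so that it tracks sex, not the immunophenotype
    set.seed(s)
    p_case <- ifelse(meta$sex == 1, 0.85, 0.55)
    meta$disease <- ifelse(rbinom(nrow(meta), 1, p_case) == 1, "RA", "control")
    if (sum(meta$disease == "RA") < 10 || sum(meta$disease == "control") < 10) {
      return(0)
    }
    net <- suppressWarnings(
      disease_cell_network(normalize_log(coh$counts), meta))
    sum(net$edges$tier != "none") / 46
  }, numeric(1))
  expect_lte(mean(rates), 0.10)
})

test_that("perfectly separating cell types are dropped with a warning", {
  set.seed(8)
  types <- c("Th17", "Tfh", "Naive_B", "NK_cells")
  n <- 30
  values <- matrix(rnorm(n * 4), n, dimnames = list(NULL, types))
  values[1:15, "Th17"] <- values[1:15, "Th17"] + 50  # cases fully separated
  meta <- data.frame(sample_id = sprintf("S%04d", 1:n),
                     disease = rep(c("RA", "control"), each = 15),
                     sex = rbinom(n, 1, 0.5), age = runif(n, 30, 70))
  expect_warning(
    net <- disease_cell_network(make_norm(values), meta),
    "separating")
  expect_false("Th17" %in% net$edges$target)
})

test_that("undirected layers carry each pair at most once and exports work", {
  coh <- generate_cohort(scenario_celltype_blocks(n = 80, seed = 9))
  net <- cell_correlation_network(normalize_log(coh$counts))
  key <- apply(net$edges[, c("source", "target")], 1,
               function(z) paste(sort(z), collapse = "|"))
  expect_false(any(duplicated(key)))
  expect_false(any(net$edges$source == net$edges$target))

  dir <- withr::local_tempdir()
  write_network(net, file.path(dir, "net.tsv"), file.path(dir, "net.graphml"))
  expect_true(file.exists(file.path(dir, "net.graphml")))
  g <- as_igraph(net)
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
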