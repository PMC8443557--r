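test_that("trajectory distance follows the mean-absolute formula", {
  expect_equal(trajectory_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(trajectory_distance(c(1, 0, -1), c(0, 0, 0)), 2 / 3)
  a <- c(0.3, -0.2, 0.5); b <- c(-0.1, 0.4, 0)
  expect_equal(trajectory_distance(a, -b), trajectory_distance(-a, b))
  expect_error(trajectory_distance(c(1, NA, 0), c(0, 0, 0)), "missing")
  expect_error(trajectory_distance(c(1, 2), c(1, 2, 3)), "length")
})

test_that("trajectory distance satisfies the metric axioms", {
  set.seed(71)
  for (i in 1:500) {
    a <- rnorm(3); b <- rnorm(3); cc <- rnorm(3)
    dab <- trajectory_distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, trajectory_distance(b, a), tolerance = 1e-12)
    expect_lte(dab, trajectory_distance(a, cc) + trajectory_distance(cc, b) +
                 1e-12)
  }
  expect_equal(trajectory_distance(c(1, 1, 1), c(1, 1, 1)), 0)
})

test_that("distance matrix appends the reversed cluster-3 column correctly", {
  clusters <- rbind("1" = c(-0.8, -0.2, -0.1), "2" = c(-0.1, -0.7, -0.3),
                    "3" = c(0.1, 0.7, 0.3))
  pheno <- rbind(spine_density = c(-0.8, -0.2, -0.1),
                 ltd = c(-0.1, -0.6, -0.2))
  dm <- distance_matrix(clusters, pheno)
  expect_identical(rownames(dm), c("1", "2", "3", "3r"))
  expect_equal(dm["1", "spine_density"], 0)
  # the 3r row equals cluster 3 measured against negated phenotypes
  expect_equal(unname(dm["3r", ]),
               vapply(rownames(pheno), function(p)
                 trajectory_distance(clusters["3", ], -pheno[p, ]),
                 numeric(1), USE.NAMES = FALSE), tolerance = 1e-12)
  expect_error(distance_matrix(rbind("3" = 1:3, "3r" = 1:3), pheno),
               "collision")
})

test_that("cross-species Spearman filters on padj and matches exact p", {
  tab <- data.frame(logFC_model = c(0.5, -0.3, 0.2, 0.9, -0.7),
                    padj_model = rep(0.01, 5),
                    logFC_ext = c(0.4, -0.2, 0.1, 1.0, -0.5),
                    padj_ext = rep(0.01, 5))
  res <- cross_species_spearman(tab)
  expect_equal(res$rho, 1)
  tab$logFC_ext <- -tab$logFC_ext
  expect_equal(cross_species_spearman(tab)$rho, -1)
  # p matches full permutation enumeration for small n
  set.seed(81)
  for (i in 1:5) {
    n <- sample(5:7, 1)
    tb <- data.frame(logFC_model = rnorm(n), padj_model = 0.01,
                     logFC_ext = rnorm(n), padj_ext = 0.01)
    res <- cross_species_spearman(tb)
    expect_equal(res$p.value, spearman_perm_p(tb$logFC_model, tb$logFC_ext),
                 tolerance = 1e-9)
  }
  # the padj filter applies to both datasets
  tb2 <- data.frame(logFC_model = rnorm(10), padj_model = rep(c(0.01, 0.5), 5),
                    logFC_ext = rnorm(10), padj_ext = 0.01)
  expect_identical(cross_species_spearman(tb2)$n_genes, 5L)
  expect_identical(cross_species_spearman(tb2, require = "either")$n_genes,
                   10L)
  few <- tb2[1:2, ]
  expect_true(cross_species_spearman(few)$insufficient)
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(83)
  tb <- data.frame(logFC_model = rnorm(30), padj_model = 0.01,
                   logFC_ext = rnorm(30), padj_ext = 0.01)
  r0 <- cross_species_spearman(tb)$rho
  tb$logFC_model <- exp(tb$logFC_model)
  tb$logFC_ext <- tb$logFC_ext^3
  expect_equal(cross_species_spearman(tb)$rho, r0, tolerance = 1e-12)
})

test_that("module concordance matches exact binomial enumeration", {
  mk <- function(signs_model, signs_ext, module = "m") {
    n <- length(signs_model)
    list(table = data.frame(gene = paste0("g", 1:n),
                            logFC_model = signs_model * runif(n, 0.1, 1),
                            logFC_ext = signs_ext * runif(n, 0.1, 1)),
         map = data.frame(gene = paste0("g", 1:n), module = module))
  }
  set.seed(91)
  d <- mk(rep(1, 10), c(rep(1, 9), -1))
  res <- module_concordance(d$table, d$map)
  expect_equal(res$p.value, 11 / 1024, tolerance = 1e-12)
  expect_identical(res$agree_n, 9L)
  expect_identical(res$direction, 1)
  d5 <- mk(rep(-1, 5), rep(-1, 5))
  expect_equal(module_concordance(d5$table, d5$map)$p.value, 1 / 32,
               tolerance = 1e-12)
  # half agreement sits at the null center
  d6 <- mk(rep(1, 6), rep(c(1, -1), 3))
  expect_gt(module_concordance(d6$table, d6$map)$p.value, 0.5)
  # implementation equals enumeration for all n <= 12
  for (n in 1:12) for (k in 0:n) {
    expect_equal(stats::binom.test(k, n, 0.5, "greater")$p.value,
                 binom_enum_p(k, n), tolerance = 1e-12)
  }
  # zero logFC rows are excluded with a count
  dz <- mk(c(1, 1, 0, 1), c(1, 1, 1, 1))
  rz <- module_concordance(dz$table, dz$map)
  expect_identical(rz$total_n, 3L)
  expect_identical(rz$n_zero_excluded, 1L)
})

test_that("planted module concordance separates 0.9 from 0.5", {
  hits <- vapply(1:20, function(s) {
    g <- gen_cross_species(s, module_sizes = c(hi = 200, lo = 200),
                           concordance_probs = c(0.9, 0.5))
    mc <- module_concordance(g$table, g$module_map)
    c(mc$p.value[mc$module == "hi"] < 0.01,
      mc$p.value[mc$module == "lo"] >= 0.01)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
})

test_that("symbol harmonization maps, drops and deduplicates", {
  tab <- data.frame(gene = c("Rat1", "Rat2", "Rat3"), logFC_model = 1:3)
  idmap <- data.frame(from = c("Rat1", "Rat2", "Rat3"),
                      to = c("Rat1", "Rat2", "Rat3"))
  expect_identical(harmonize_symbols(tab, idmap)$gene,
                   c("Rat1", "Rat2", "Rat3"))
  # unmapped rows dropped with a message
  part <- data.frame(from = c("Rat1", "Rat3"), to = c("HUM1", "HUM3"))
  expect_message(out <- harmonize_symbols(tab, part), "1 unmapped")
  expect_identical(out$gene, c("HUM1", "HUM3"))
  # one-to-many resolves to the lexicographically first target
  multi <- data.frame(from = c("Rat1", "Rat1", "Rat2", "Rat3"),
                      to = c("HUMB", "HUMA", "HUM2", "HUM3"))
  expect_message(out2 <- harmonize_symbols(tab, multi), "one-to-many")
  expect_true("HUMA" %in% out2$gene && !"HUMB" %in% out2$gene)
  expect_error(harmonize_symbols(tab, data.frame(x = 1)), "malformed")
})
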