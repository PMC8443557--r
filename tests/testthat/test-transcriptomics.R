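make_study <- function(seed = 1, n_genes = 300, noise_sd = 0.3) {
  gen_expression(expr_sim_config(seed = seed, n_genes = n_genes,
                                 noise_sd = noise_sd))
}

test_that("expressed-gene filter uses a strict mean-threshold rule", {
  mat <- rbind(a = rep(5.1, 4), b = rep(4.9, 4), c = rep(5, 4),
               d = c(4, 6, 4, 6))
  flags <- filter_expressed(mat)
  expect_identical(unname(flags), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("row-wise Welch test agrees with stats::t.test gene by gene", {
  set.seed(51)
  x <- matrix(rnorm(20 * 5, 8), 20)
  y <- matrix(rnorm(20 * 6, 8.5), 20)
  w <- synaptodev:::welch_rows(x, y)
  for (i in seq_len(20)) {
    tt <- stats::t.test(y[i, ], x[i, ], var.equal = FALSE)
    expect_equal(w$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(w$logFC[i], mean(y[i, ]) - mean(x[i, ]), tolerance = 1e-12)
  }
})

test_that("differential expression handles BH families and degenerate genes", {
  # hand-computed BH step-up: (0.01, 0.02, 0.03, 0.04) -> all 0.04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  g <- make_study(seed = 3, n_genes = 200)
  de <- diff_expression(g$matrix, g$metadata, "3M")
  expressed <- filter_expressed(g$matrix)
  expect_true(all(is.na(de$p_adj[!expressed])))
  fam <- expressed & !de$flagged
  expect_equal(de$p_adj[fam], stats::p.adjust(de$p_raw[fam], "BH"))
  expect_true(all(de$p_adj[fam] >= de$p_raw[fam] - 1e-15))

  # zero variance in both groups: equal means p = 1, unequal means flagged
  meta0 <- data.frame(sample_id = paste0("s", 1:12), age = "0M",
                      group = rep(c("UE", "VPA"), each = 6))
  mat <- rbind(g1 = rep(6, 12), g2 = rep(c(6, 7), each = 6))
  colnames(mat) <- meta0$sample_id
  expect_message(de0 <- diff_expression(mat, meta0, "0M"), "zero-variance")
  expect_equal(de0$p_raw[1], 1)
  expect_true(de0$flagged[2])
  expect_true(is.na(de0$p_adj[2]))
})

test_that("probe collapse keeps the lowest-padj probe with tie-breaks", {
  tab <- data.frame(probe = c("p1", "p2", "p3", "p4", "p5"),
                    padj_0M = c(0.01, 0.2, 0.01, 0.01, 0.5),
                    padj_3M = c(0.5, 0.4, 0.6, 0.9, 0.7),
                    p_0M = c(0.001, 0.05, 0.002, 0.001, 0.3))
  map <- data.frame(probe = c("p1", "p2", "p3", "p4", "p6"),
                    gene = c("A", "A", "B", "B", "C"))
  expect_message(out <- collapse_probes(tab, map), "unmapped")
  expect_identical(out$probe[out$gene == "A"], "p1")   # lower padj wins
  expect_identical(out$probe[out$gene == "B"], "p4")   # padj tie -> raw p...
  # p3 and p4 tie on padj (0.01) and p4 has p_0M 0.001 < p3 0.002
  single <- collapse_probes(tab[5, ], data.frame(probe = "p5", gene = "D"))
  expect_identical(single$probe, "p5")
})

test_that("the DEG rule is strict and matches a brute-force row scan", {
  lf <- rbind(c(0.5, 0, 0), c(0.4, 0, 0), c(0.9, 0.9, 0.9), c(0, 0.41, 0))
  pa <- rbind(c(0.01, 1, 1), c(0.001, 1, 1), c(0.06, 0.06, 0.06),
              c(1, 0.049, 1))
  expect_identical(unname(select_degs(lf, pa)), c(TRUE, FALSE, FALSE, TRUE))
  set.seed(61)
  lf_r <- matrix(runif(300, -1, 1), ncol = 3)
  pa_r <- matrix(runif(300), ncol = 3)
  brute <- vapply(seq_len(100), function(i)
    any(abs(lf_r[i, ]) > 0.4 & pa_r[i, ] < 0.05), logical(1))
  expect_identical(unname(select_degs(lf_r, pa_r)), brute)
})

test_that("trajectory clustering recovers planted structure and labels", {
  eff <- rbind(c(-0.8, -0.2, -0.1), c(-0.1, -0.7, -0.3), c(0.1, 0.7, 0.3))
  # noiseless: exact recovery, perfect ARI, labels ordered by 0M centroid
  traj <- eff[rep(1:3, each = 60), ]
  cm <- cluster_trajectories(traj, seed = 4)
  expect_identical(cm$k, 3L)
  expect_equal(adjusted_rand_index(cm$assignments, rep(1:3, each = 60)), 1)
  expect_equal(unname(cm$centroids[, 1]), sort(unname(cm$centroids[, 1])))
  expect_equal(unname(cm$centroids["1", ]), eff[1, ])  # most negative at 0M

  # one shared trajectory: a single cluster is selected
  cm1 <- cluster_trajectories(matrix(rep(eff[1, ], each = 50), ncol = 3),
                              seed = 1)
  expect_identical(cm1$k, 1L)

  # near-noiseless: AIC increases for every k beyond the planted 3
  set.seed(7)
  trajn <- traj + rnorm(length(traj), 0, 1e-6)
  cmn <- cluster_trajectories(trajn, seed = 2)
  expect_identical(cmn$k, 3L)
  aic_tail <- cmn$aic$aic[cmn$aic$k >= 3]
  expect_true(all(diff(aic_tail) > 0))

  # label order is deterministic across clustering seeds
  set.seed(9)
  trajr <- traj + rnorm(length(traj), 0, 0.05)
  a1 <- cluster_trajectories(trajr, seed = 10)$assignments
  a2 <- cluster_trajectories(trajr, seed = 99)$assignments
  expect_identical(a1, a2)
})

test_that("age-overlap Fisher test matches hypergeometric enumeration", {
  universe <- letters[1:10]
  p <- age_overlap_fisher(c("a", "b", "c"), c("b", "c", "d"), universe)
  expect_equal(p, 22 / 120, tolerance = 1e-9)
  expect_equal(p, fisher_hyper_p(2, 1, 1, 6), tolerance = 1e-9)
  # disjoint sets covering the universe: no enrichment
  p2 <- age_overlap_fisher(letters[1:5], letters[6:10], letters[1:10])
  expect_equal(p2, fisher_hyper_p(0, 5, 5, 0), tolerance = 1e-9)
  expect_gte(p2, 1 - 1e-9)
  # identical sets filling the universe: degenerate, p = 1
  expect_equal(age_overlap_fisher(letters[1:3], letters[1:3], letters[1:3]),
               1)
  expect_error(age_overlap_fisher("a", "b", character(0)), "universe")
})

test_that("gene-set enrichment reports p and the two ratios", {
  universe <- letters[1:10]
  res <- geneset_enrichment(letters[1:4], letters[1:5], universe)
  expect_equal(res$p.value, 5 / 210, tolerance = 1e-9)
  expect_equal(res$cluster_ratio, 1)
  expect_equal(res$universe_ratio, 0.5)
  # set disjoint from the cluster
  res2 <- geneset_enrichment(letters[1:4], letters[7:9], universe)
  expect_equal(res2$p.value, 1, tolerance = 1e-9)
  # cluster ratio equal to universe ratio: no enrichment signal
  res3 <- geneset_enrichment(letters[1:4], c("a", "b", "e", "f", "g"),
                             universe)
  expect_gte(res3$p.value, 0.5)
  expect_error(geneset_enrichment(character(0), "a", universe), "empty")
})
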