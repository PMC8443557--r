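#' Flag expressed genes
#'
#' A gene counts as expressed when its mean log2 value across all samples
#' exceeds the threshold (strict `>`). The mean aggregation is a stable,
#' documented choice; a per-sample rule is not used.
#'
#' @param mat Genes x samples log2 expression matrix.
#' @param threshold Log2 expression threshold (default 5).
#' @return Named logical vector per gene.
#' @export
filter_expressed <- function(mat, threshold = 5) {
  stopifnot(is.matrix(mat), nrow(mat) > 0)
  rowMeans(mat) > threshold
}

# Vectorized two-sided Welch t-test across matrix rows.
# Returns logFC (mean(y) - mean(x), i.e. exposed minus unexposed on the
# log2 scale), p, and a degenerate flag (zero variance in both groups with
# unequal means, where the Welch statistic is undefined).
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tt <- (my - mx) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero_var <- se2 == 0
  equal <- zero_var & (my == mx)
  p[equal] <- 1
  flagged <- zero_var & !equal
  p[flagged] <- NA_real_
  list(logFC = my - mx, p = p, flagged = flagged)
}

#' Per-age differential expression
#'
#' For one age, a two-sided Welch t-test per expressed gene between
#' unexposed and exposed samples; `logFC` is the difference of group means
#' on the log2 scale (exposed minus unexposed). Benjamini-Hochberg
#' adjustment is applied across all expressed, non-degenerate genes within
#' the age (the per-age family choice is documented in the vignette).
#'
#' @param mat Genes x samples log2 matrix.
#' @param metadata Data frame with `sample_id`, `age`, `group` matching the
#'   matrix columns.
#' @param age Age to test (`"0M"`, `"3M"`, `"6M"`).
#' @param expressed Optional logical vector from [filter_expressed()];
#'   computed from `mat` when missing. Non-expressed genes get `NA`
#'   statistics and are outside the BH family.
#' @return Data frame: `gene`, `logFC`, `p_raw`, `p_adj`, `flagged`; the
#'   number of degenerate genes excluded from the BH family is in the
#'   `n_flagged` attribute.
#' @export
diff_expression <- function(mat, metadata, age, expressed = NULL) {
  stopifnot(all(colnames(mat) %in% metadata$sample_id))
  meta <- metadata[match(colnames(mat), metadata$sample_id), ]
  ue <- which(meta$age == age & meta$group == "UE")
  vpa <- which(meta$age == age & meta$group == "VPA")
  if (length(ue) < 2 || length(vpa) < 2)
    stop("need at least 2 samples per group at age ", age)
  expressed <- expressed %||% filter_expressed(mat)
  w <- welch_rows(mat[, ue, drop = FALSE], mat[, vpa, drop = FALSE])
  out <- data.frame(gene = rownames(mat), logFC = w$logFC, p_raw = w$p,
                    p_adj = NA_real_, flagged = w$flagged)
  out$logFC[!expressed] <- NA_real_
  out$p_raw[!expressed] <- NA_real_
  fam <- expressed & !w$flagged
  out$p_adj[fam] <- stats::p.adjust(w$p[fam], method = "BH")
  n_flagged <- sum(expressed & w$flagged)
  if (n_flagged > 0)
    message(n_flagged, " zero-variance gene(s) with unequal means excluded ",
            "from the BH family at age ", age)
  structure(out, n_flagged = n_flagged)
}

#' Collapse probe-level statistics to gene level
#'
#' Per gene, keeps the single probe with the smallest adjusted p-value
#' (minimum across ages); ties are broken by the smallest raw p-value, then
#' by lexicographic probe ID. Probes absent from the map are dropped with a
#' message.
#'
#' @param table Probe-keyed data frame with a `probe` column and per-age
#'   `padj_*` (and optionally `p_*`) columns.
#' @param probe_map Data frame with `probe` and `gene` columns.
#' @return The input rows for the selected probes, with a `gene` column.
#' @export
collapse_probes <- function(table, probe_map) {
  stopifnot("probe" %in% names(table),
            all(c("probe", "gene") %in% names(probe_map)))
  idx <- match(table$probe, probe_map$probe)
  dropped <- sum(is.na(idx))
  if (dropped > 0) message(dropped, " unmapped probe(s) dropped")
  tab <- table[!is.na(idx), , drop = FALSE]
  tab$gene <- probe_map$gene[idx[!is.na(idx)]]
  padj_cols <- grep("^padj", names(tab), value = TRUE)
  p_cols <- grep("^p_(?!adj)", names(tab), value = TRUE, perl = TRUE)
  if (!length(padj_cols)) stop("no padj_* columns found")
  min_padj <- do.call(pmin, c(unname(tab[padj_cols]), na.rm = TRUE))
  min_p <- if (length(p_cols))
    do.call(pmin, c(unname(tab[p_cols]), na.rm = TRUE)) else min_padj
  ord <- order(tab$gene, min_padj, min_p, tab$probe)
  tab <- tab[ord, , drop = FALSE]
  out <- tab[!duplicated(tab$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG iff at some age `|logFC| > 0.4` and `p_adj < 0.05`
#' (both strict).
#'
#' @param logfc Genes x ages matrix (or data frame) of logFC values.
#' @param padj Matching matrix of BH-adjusted p-values.
#' @param logfc_cut,p_cut Thresholds (defaults 0.4 and 0.05).
#' @return Logical vector per gene.
#' @export
select_degs <- function(logfc, padj, logfc_cut = 0.4, p_cut = 0.05) {
  logfc <- as.matrix(logfc); padj <- as.matrix(padj)
  stopifnot(all(dim(logfc) == dim(padj)))
  hit <- abs(logfc) > logfc_cut & padj < p_cut
  hit[is.na(hit)] <- FALSE
  rowSums(hit) > 0
}

#' Run the full differential-expression stage
#'
#' Expressed-gene filter, per-age Welch + BH, and the DEG rule, returning a
#' per-gene table with one logFC and one adjusted p-value per age.
#'
#' @param mat Genes x samples log2 matrix.
#' @param metadata Sample metadata (`sample_id`, `age`, `group`).
#' @param ages Ages to test (default the three standard ages present).
#' @param expressed_threshold Passed to [filter_expressed()].
#' @param logfc_cut,p_cut Passed to [select_degs()].
#' @return Data frame: `gene`, `is_expressed`, per-age `logFC_*` and
#'   `padj_*` columns, `is_deg`.
#' @export
deg_analysis <- function(mat, metadata, ages = intersect(c("0M", "3M", "6M"),
                                                         unique(metadata$age)),
                         expressed_threshold = 5, logfc_cut = 0.4,
                         p_cut = 0.05) {
  expressed <- filter_expressed(mat, expressed_threshold)
  out <- data.frame(gene = rownames(mat), is_expressed = unname(expressed))
  for (a in ages) {
    de <- diff_expression(mat, metadata, a, expressed)
    out[[paste0("logFC_", a)]] <- de$logFC
    out[[paste0("padj_", a)]] <- de$p_adj
  }
  out$is_deg <- select_degs(out[paste0("logFC_", ages)],
                            out[paste0("padj_", ages)], logfc_cut, p_cut)
  out
}

# k-means++ seeding: first center uniform, then D^2-weighted draws.
# Requires k <= number of distinct rows; centers are always distinct.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    if (all(d2 == 0)) stop("fewer distinct points than centers")
    pick <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Cluster logFC trajectories by k-means with AIC model selection
#'
#' For each candidate k, runs k-means with `n_restarts` k-means++
#' initializations and keeps the solution with the lowest within-cluster
#' sum of squares (RSS). The cluster number is chosen by minimizing
#' `AIC = RSS + 2 * k * d` (d = number of ages), the standard k-means AIC
#' in which each additional centroid must buy its 2d parameter penalty in
#' residual reduction; ties go to the smaller k. Cluster labels are
#' renumbered by ascending centroid value at the first age, so the cluster
#' most strongly downregulated at birth is cluster 1.
#'
#' @param traj Numeric matrix of DEG logFC trajectories (genes x 3 ages,
#'   columns ordered 0M, 3M, 6M).
#' @param k_range Candidate cluster numbers (default 1..8); values
#'   exceeding the number of trajectories are skipped.
#' @param n_restarts k-means++ restarts per k (default 50).
#' @param seed Seed for the restarts.
#' @return List of class `cluster_model`: `k`, `centroids` (k x d, rows
#'   named by label), `assignments` (integer per gene), `aic` (data frame
#'   `k`, `rss`, `aic`).
#' @export
cluster_trajectories <- function(traj, k_range = 1:8, n_restarts = 50,
                                 seed = 1) {
  traj <- as.matrix(traj)
  stopifnot(ncol(traj) >= 2, nrow(traj) >= 1, !anyNA(traj))
  d <- ncol(traj)
  n_distinct <- nrow(unique(traj))
  k_range <- k_range[k_range <= n_distinct]  # k needs k distinct points
  if (!length(k_range)) stop("fewer trajectories than every candidate k")
  fits <- vector("list", length(k_range))
  with_seed(derive_seed(seed, "kmeans"), {
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      best <- NULL
      for (r in seq_len(n_restarts)) {
        km <- suppressWarnings(
          stats::kmeans(traj, centers = kmeanspp_centers(traj, k),
                        iter.max = 100))
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      fits[[i]] <- best
    }
  })
  rss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  aic <- rss + 2 * k_range * d
  pick <- which.min(aic)  # which.min takes the first (smallest k) on ties
  best <- fits[[pick]]
  # deterministic labels: order clusters by centroid value at the first age
  ord <- order(best$centers[, 1])
  relabel <- match(seq_along(ord), ord)
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- as.character(seq_len(nrow(centroids)))
  colnames(centroids) <- colnames(traj)
  structure(list(k = k_range[pick], centroids = centroids,
                 assignments = relabel[best$cluster],
                 aic = data.frame(k = k_range, rss = rss, aic = aic)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d selected by AIC over k in {%s}\n",
              x$k, paste(x$aic$k, collapse = ", ")))
  print(round(x$centroids, 3))
  invisible(x)
}

#' One-sided Fisher enrichment of overlap between two DEG sets
#'
#' Tests whether the overlap of two gene sets (e.g. genes upregulated at
#' two different ages) is larger than expected in the universe of expressed
#' genes.
#'
#' @param set_a,set_b Character vectors of genes.
#' @param universe Character vector of all expressed genes.
#' @return One-sided (enrichment) Fisher p-value.
#' @export
age_overlap_fisher <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe")
  set_a <- intersect(set_a, universe)
  set_b <- intersect(set_b, universe)
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  c_ <- length(set_b) - a
  d <- length(universe) - a - b - c_
  stats::fisher.test(matrix(c(a, b, c_, d), 2), alternative = "greater")$p.value
}

#' Gene-set enrichment of a cluster by one-sided Fisher test
#'
#' Tests over-representation of a gene set (e.g. an ASD-associated or
#' critical-period catalogue) within a cluster against the universe of
#' expressed genes. No multiple-testing correction is applied across
#' clusters (raw one-sided p-values are reported).
#'
#' @param cluster_genes Genes in the cluster (non-empty).
#' @param gene_set Gene set to test; only its intersection with the
#'   universe counts.
#' @param universe All expressed genes.
#' @return List: `p.value`, `cluster_ratio` (set fraction within the
#'   cluster), `universe_ratio` (set fraction in the universe; the
#'   reference baseline), `n_overlap`.
#' @export
geneset_enrichment <- function(cluster_genes, gene_set, universe) {
  cluster_genes <- intersect(cluster_genes, universe)
  if (!length(cluster_genes)) stop("empty cluster (after universe filter)")
  gene_set <- intersect(gene_set, universe)
  a <- length(intersect(cluster_genes, gene_set))
  b <- length(cluster_genes) - a
  c_ <- length(gene_set) - a
  d <- length(universe) - a - b - c_
  p <- stats::fisher.test(matrix(c(a, b, c_, d), 2),
                          alternative = "greater")$p.value
  list(p.value = p,
       cluster_ratio = a / length(cluster_genes),
       universe_ratio = length(gene_set) / length(universe),
       n_overlap = a)
}
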