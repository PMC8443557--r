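#' Distance between two logFC trajectories
#'
#' Mean absolute difference across the three ages:
#' `sum_t |a(t) - b(t)| / n_ages`. This is a metric on trajectory space
#' (non-negative, symmetric, triangle inequality).
#'
#' @param a,b Numeric length-3 trajectories (logFC at 0M, 3M, 6M), no
#'   missing components.
#' @return Non-negative distance.
#' @export
trajectory_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("trajectories differ in length")
  if (anyNA(a) || anyNA(b)) stop("trajectory has missing components")
  mean(abs(a - b))
}

#' Distance matrix between gene-cluster centroids and phenotype trajectories
#'
#' All pairwise [trajectory_distance()] values between cluster-mean logFC
#' trajectories and phenotype logFC trajectories. If a cluster labeled
#' `"3"` is present, a reversed column `"3r"` (its element-wise negation)
#' is appended, to expose phenotypes that track the cluster with inverted
#' sign.
#'
#' @param clusters Matrix (or data frame) of cluster centroids, rows named
#'   by cluster label, 3 age columns.
#' @param phenotypes Matrix of phenotype trajectories, rows named by
#'   phenotype, same age columns.
#' @return Matrix of distances, clusters (plus `"3r"`) x phenotypes.
#' @export
distance_matrix <- function(clusters, phenotypes) {
  clusters <- as.matrix(clusters); phenotypes <- as.matrix(phenotypes)
  if (is.null(rownames(clusters)))
    rownames(clusters) <- as.character(seq_len(nrow(clusters)))
  if ("3" %in% rownames(clusters)) {
    rev3 <- -clusters["3", , drop = FALSE]
    rownames(rev3) <- "3r"
    if ("3r" %in% rownames(clusters)) stop("label collision: '3r'")
    clusters <- rbind(clusters, rev3)
  }
  if (anyDuplicated(rownames(clusters)) || anyDuplicated(rownames(phenotypes)))
    stop("label collision in trajectory names")
  out <- matrix(NA_real_, nrow(clusters), nrow(phenotypes),
                dimnames = list(rownames(clusters), rownames(phenotypes)))
  for (i in seq_len(nrow(clusters)))
    for (j in seq_len(nrow(phenotypes)))
      out[i, j] <- trajectory_distance(clusters[i, ], phenotypes[j, ])
  out
}

#' Spearman correlation of model and external logFC values
#'
#' Restricted to genes modulated in both datasets (`p_adj < p_cut` in both
#' by default; set `require = "either"` to demand it in only one). Average
#' ranks are used for ties; the two-sided p-value is exact for small
#' tie-free samples and asymptotic otherwise (the `stats::cor.test`
#' convention).
#'
#' @param table Data frame with `logFC_model`, `padj_model`, `logFC_ext`,
#'   `padj_ext`.
#' @param p_cut Adjusted-p cutoff defining "modulated" (default 0.1).
#' @param require `"both"` (default) or `"either"`.
#' @return List: `rho`, `p.value`, `n_genes`; when fewer than 3 genes pass
#'   the filter, `insufficient = TRUE` and the statistics are `NA`.
#' @export
cross_species_spearman <- function(table, p_cut = 0.1,
                                   require = c("both", "either")) {
  require <- match.arg(require)
  sel <- if (require == "both")
    table$padj_model < p_cut & table$padj_ext < p_cut
  else
    table$padj_model < p_cut | table$padj_ext < p_cut
  sel[is.na(sel)] <- FALSE
  n <- sum(sel)
  if (n < 3)
    return(list(rho = NA_real_, p.value = NA_real_, n_genes = n,
                insufficient = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(table$logFC_model[sel], table$logFC_ext[sel],
                    method = "spearman"))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n_genes = n,
       insufficient = FALSE)
}

#' Per-module sign concordance of logFC modulations
#'
#' For each module, counts genes whose model and external logFC values
#' agree in sign and tests the agreement fraction against 0.5 with a
#' one-sided (greater) exact binomial test. Genes with a zero logFC in
#' either dataset are excluded (and counted); the module direction is the
#' majority sign of its model logFC values.
#'
#' @param table Data frame with `gene`, `logFC_model`, `logFC_ext`.
#' @param module_map Data frame with `gene`, `module`.
#' @return Data frame per module: `module`, `agree_n`, `total_n`,
#'   `n_zero_excluded`, `p.value`, `direction` (+1/-1/0). Modules empty
#'   after exclusions get `NA` statistics.
#' @export
module_concordance <- function(table, module_map) {
  stopifnot(all(c("gene", "logFC_model", "logFC_ext") %in% names(table)),
            all(c("gene", "module") %in% names(module_map)))
  merged <- merge(table, module_map, by = "gene")
  out <- do.call(rbind, lapply(split(merged, merged$module), function(d) {
    mod <- d$module[1]
    nonzero <- d$logFC_model != 0 & d$logFC_ext != 0
    n_zero <- sum(!nonzero)
    d <- d[nonzero, ]
    if (!nrow(d))
      return(data.frame(module = mod, agree_n = NA_integer_, total_n = 0L,
                        n_zero_excluded = n_zero, p.value = NA_real_,
                        direction = NA_real_))
    agree <- sum(sign(d$logFC_model) == sign(d$logFC_ext))
    p <- stats::binom.test(agree, nrow(d), p = 0.5,
                           alternative = "greater")$p.value
    data.frame(module = d$module[1], agree_n = agree, total_n = nrow(d),
               n_zero_excluded = n_zero, p.value = p,
               direction = sign(sum(sign(d$logFC_model))))
  }))
  rownames(out) <- NULL
  out
}

#' Harmonize external gene symbols onto the model's symbol space
#'
#' Maps the `gene` column of an external table through a two-column
#' homolog map. Unmapped rows are dropped with a message; one-to-many
#' mappings are resolved deterministically to the lexicographically first
#' target; if two external rows collapse onto the same target symbol, the
#' first (by source symbol order) is kept so symbols stay unique.
#'
#' @param table Data frame with a `gene` column of external symbols.
#' @param homolog_map Data frame whose first two columns are source and
#'   target symbols.
#' @return The table with `gene` replaced by target symbols, unique.
#' @export
harmonize_symbols <- function(table, homolog_map) {
  if (ncol(homolog_map) < 2) stop("malformed homolog map: need two columns")
  map <- data.frame(from = as.character(homolog_map[[1]]),
                    to = as.character(homolog_map[[2]]))
  if (anyNA(map$from) || anyNA(map$to)) stop("malformed homolog map: NAs")
  # one-to-many: keep the lexicographically first target per source
  map <- map[order(map$from, map$to), ]
  multi <- sum(duplicated(map$from))
  if (multi > 0)
    message(multi, " one-to-many homolog mapping(s) resolved to first target")
  map <- map[!duplicated(map$from), ]
  idx <- match(table$gene, map$from)
  dropped <- sum(is.na(idx))
  if (dropped > 0) message(dropped, " unmapped gene(s) dropped")
  out <- table[!is.na(idx), , drop = FALSE]
  out$gene <- map$to[idx[!is.na(idx)]]
  out <- out[order(out$gene), , drop = FALSE]
  collided <- sum(duplicated(out$gene))
  if (collided > 0)
    message(collided, " duplicate harmonized symbol(s) dropped")
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
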