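#' Derive a stream-specific seed from a master seed
#'
#' Every generator in the package draws its randomness from a sub-stream
#' keyed by a label, so adding a new generator never perturbs the output of
#' existing ones under the same master seed.
#'
#' @param seed Master seed (integer).
#' @param label Character label naming the sub-stream.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps the fold well mixed
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  h <- as.integer(h)
  if (h <= 0L) h + 1L else h
}

# Evaluate expr with a temporary RNG state; restores .Random.seed afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Step-down Sidak adjustment: order the m raw p-values ascending, adjust the
#' i-th as 1 - (1 - p_(i))^(m - i + 1), then enforce monotonicity by running
#' maxima, and return in the original order. NA values are left NA and do not
#' count towards the family size.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
p_adjust_holm_sidak <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep(NA_real_, length(p))
  keep <- which(!is.na(p))
  m <- length(keep)
  if (m == 0L) return(out)
  pk <- p[keep]
  if (any(pk < 0 | pk > 1)) stop("p-values must lie in [0, 1]")
  o <- order(pk)
  adj <- 1 - (1 - pk[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  res <- numeric(m)
  res[o] <- adj
  out[keep] <- res
  out
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Deterministic TSV writer: UTF-8, tab-separated, '.' decimal, no quoting.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
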