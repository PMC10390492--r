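# Independent oracles and small in-code fixtures shared across tests.
# Each oracle is a from-definition implementation kept deliberately
# separate from the package's computational path.

st_log_level("off")

# One-sided ("greater") Fisher p by explicit hypergeometric enumeration
# over all achievable co-occurrence counts, using choose() ratios.
oracle_fisher_greater <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(1)
  row1 <- a + b
  col1 <- a + c
  ks <- seq.int(a, min(row1, col1))
  if (length(ks) == 0L || a > min(row1, col1)) return(0)
  sum(exp(lchoose(row1, ks) + lchoose(n - row1, col1 - ks) -
            lchoose(n, col1)))
}

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, monotone from the largest p down.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# CSI by brute-force triple loop over the correlation matrix.
oracle_csi <- function(ras) {
  P <- cor(ras)
  n <- ncol(P)
  out <- matrix(1, n, n, dimnames = dimnames(P))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      cnt <- 0L
      for (cc in seq_len(n)) {
        if (P[a, cc] < P[a, b] && P[b, cc] < P[a, b]) cnt <- cnt + 1L
      }
      out[a, b] <- cnt / n
    }
  }
  out
}

# Exact Wilcoxon rank-sum p by enumeration of all label assignments
# (tie-free inputs only). U counts pairs with x > y.
oracle_wilcox_enum <- function(x, y, alternative = "two.sided") {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- sum(outer(x, y, ">"))
  all_u <- apply(utils::combn(nx + ny, nx), 2L, u_of)
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Recovery-curve AUC by literal step-curve integration.
oracle_auc <- function(expr_vec, tiebreak, in_set, max_rank) {
  ord <- order(-expr_vec, tiebreak)
  cum <- cumsum(in_set[ord])[seq_len(max_rank)]
  s <- sum(in_set)
  max_cum <- pmin(seq_len(max_rank), s)
  sum(cum) / sum(max_cum)
}

# Base-2 JSD straight from the definition, written independently.
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  term <- function(x) {
    i <- x > 0
    sum(x[i] * log2(x[i] / m[i]))
  }
  (term(p) + term(q)) / 2
}

# Tiny weight matrix wrapped as CellTypeWeights (uniformly rescaled when
# needed to keep row sums on the simplex; a common positive factor leaves
# every column correlation unchanged).
toy_weights <- function(cols) {
  w <- do.call(cbind, cols)
  rownames(w) <- sprintf("spot%02d", seq_len(nrow(w)))
  w <- w / max(1, max(rowSums(w)) + 1e-9)
  cell_type_weights(w)
}

# Drop the class/layer decoration of an ExpressionMatrix for raw-value
# comparisons.
as_plain <- function(m) {
  m <- unclass(m)
  attr(m, "layer") <- NULL
  m
}

# Lognorm expression matrix from a plain numeric matrix.
toy_lognorm <- function(values, genes = NULL, obs = NULL) {
  if (!is.null(genes)) rownames(values) <- genes
  if (!is.null(obs)) colnames(values) <- obs
  expression_matrix(values, layer = "lognorm")
}
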