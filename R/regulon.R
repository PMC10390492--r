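# Regulon activity scoring (area under the gene-rank recovery curve),
# Jensen-Shannon-divergence regulon specificity scores over spatial
# domains, connection specificity index matrices, regulon modules and the
# CSI co-activation network.

.validate_ras <- function(ras) {
  stopifnot(is.matrix(ras), is.numeric(ras))
  if (is.null(colnames(ras))) stop("activity matrix needs regulon names")
  if (anyNA(ras) && any(colSums(!is.na(ras)) == 0L)) {
    stop("activity matrix has an all-NA column")
  }
  rng <- range(ras, na.rm = TRUE)
  if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9) {
    stop("activity values must lie in [0, 1]")
  }
  invisible(ras)
}

#' Area-under-recovery-curve gene-set activity score
#'
#' Per observation, genes are ranked by descending expression (ties broken
#' by a fixed seeded random tiebreak so that the heavily tied zeros of
#' sparse spot data rank deterministically); the recovery curve counts set
#' genes among the top ranks up to `max_rank = ceiling(top_frac * n_genes)`
#' and the score is the area under that step curve normalized by its
#' maximum possible value. The score depends only on the gene ranking, so
#' it is invariant to monotone transforms of the expression values.
#'
#' @param m An `ExpressionMatrix` (any layer).
#' @param genes Character vector: the gene set (intersected with the
#'   matrix genes; empty intersection errors).
#' @param top_frac Fraction of the ranking integrated, in (0, 1\].
#' @param seed Integer seed for the tiebreak permutation.
#' @param set_name Name used in error messages.
#' @return Named numeric vector of per-observation scores in \[0, 1\].
#' @export
auc_recovery_score <- function(m, genes, top_frac = 0.05, seed = 0L,
                               set_name = deparse(substitute(genes))) {
  validate_expression_matrix(m)
  stopifnot(top_frac > 0, top_frac <= 1)
  in_set <- rownames(m) %in% genes
  if (!any(in_set)) {
    stop("gene set ", set_name, " has no genes in the matrix")
  }
  n_genes <- nrow(m)
  max_rank <- ceiling(top_frac * n_genes)
  s <- sum(in_set)
  max_area <- if (s >= max_rank) {
    max_rank * (max_rank + 1) / 2
  } else {
    s * (s + 1) / 2 + s * (max_rank - s)
  }
  tiebreak <- with_seed(seed, sample.int(n_genes))
  vals <- unclass(m)
  scores <- vapply(seq_len(ncol(vals)), function(j) {
    ord <- order(-vals[, j], tiebreak)
    pos <- which(in_set[ord][seq_len(max_rank)])
    sum(max_rank - pos + 1) / max_area
  }, numeric(1L))
  stats::setNames(scores, colnames(m))
}

#' Activity scores for a whole signature collection
#'
#' Applies [auc_recovery_score()] to every set; used both to compute
#' regulon activity matrices from regulon target-gene sets and to score
#' region-related (e.g. dorsal/medial/ventral) gene sets.
#'
#' @param m An `ExpressionMatrix`.
#' @param sigs A `SignatureCollection`.
#' @param top_frac,seed Passed to [auc_recovery_score()].
#' @return Observations x sets numeric matrix of scores in \[0, 1\].
#' @export
activity_scores <- function(m, sigs, top_frac = 0.05, seed = 0L) {
  sigs <- intersect_signatures(sigs, rownames(m))
  out <- vapply(names(sigs), function(nm) {
    auc_recovery_score(m, sigs[[nm]], top_frac = top_frac, seed = seed,
                       set_name = nm)
  }, numeric(ncol(m)))
  matrix(out, nrow = ncol(m), dimnames = list(colnames(m), names(sigs)))
}

#' Jensen-Shannon divergence (base-2)
#'
#' `JSD(p, q) = KL(p||m)/2 + KL(q||m)/2` with `m = (p + q)/2`, base-2
#' logarithms and the convention `0 * log(0/x) = 0`; bounded in \[0, 1\].
#'
#' @param p,q Probability vectors of equal length (nonnegative, summing
#'   to 1 within 1e-9).
#' @return The divergence, a number in \[0, 1\].
#' @export
jensen_shannon_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("probability vectors must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("probability vectors must sum to 1")
  }
  m <- (p + q) / 2
  kl <- function(x) {
    nz <- x > 0
    sum(x[nz] * (log2(x[nz]) - log2(m[nz])))
  }
  (kl(p) + kl(q)) / 2
}

#' Regulon specificity scores over spatial domains
#'
#' Each regulon's activity column is normalized to a probability
#' distribution over spots, each domain's membership indicator likewise,
#' and the specificity score is `RSS = 1 - sqrt(JSD(p_regulon, p_domain))`
#' (base-2). RSS is 1 exactly when the normalized activity equals the
#' normalized indicator and is invariant to positive scaling of the
#' activity column. Zero-sum activity columns yield NA with a logged
#' warning.
#'
#' @param ras Spots x regulons activity matrix, values in \[0, 1\].
#' @param domains Character domain labels, one per spot.
#' @return An `RSSMatrix`: regulons x domains matrix in \[0, 1\].
#' @export
regulon_specificity_scores <- function(ras, domains) {
  .validate_ras(ras)
  stopifnot(length(domains) == nrow(ras))
  if (anyNA(domains)) stop("unknown (NA) domain labels")
  doms <- unique(domains)
  csums <- colSums(ras)
  if (any(csums == 0)) {
    st_log("regulon_specificity_scores: %d regulon(s) with zero total activity -> NA",
           sum(csums == 0), level = "warning")
  }
  out <- matrix(NA_real_, ncol(ras), length(doms),
                dimnames = list(colnames(ras), doms))
  for (d in doms) {
    p_d <- as.numeric(domains == d)
    p_d <- p_d / sum(p_d)
    for (r in seq_len(ncol(ras))) {
      if (csums[r] == 0) next
      p_r <- ras[, r] / csums[r]
      out[r, d] <- 1 - sqrt(jensen_shannon_divergence(p_r, p_d))
    }
  }
  structure(out, class = c("RSSMatrix", "matrix"))
}

#' Connection specificity index of regulon pairs
#'
#' With `P` the pairwise Pearson correlation matrix of activity columns
#' and `N` the number of regulons, `CSI(A, B)` is the fraction of regulons
#' `C` whose correlation with both `A` and `B` is strictly below
#' `P(A, B) - margin`. High CSI marks pairs whose association stands out
#' against each member's other partnerships. Constant activity columns are
#' excluded with a log entry; at least 3 usable regulons are required.
#'
#' @param ras Spots x regulons activity matrix.
#' @param margin Subtracted from `P(A, B)` before counting (default 0; the
#'   cited CSI literature sometimes uses 0.05).
#' @return A `CSIMatrix`: symmetric regulons x regulons matrix in \[0, 1\]
#'   with unit diagonal.
#' @export
connection_specificity_index <- function(ras, margin = 0) {
  .validate_ras(ras)
  sds <- apply(ras, 2L, sd)
  if (any(sds == 0)) {
    st_log("connection_specificity_index: excluding %d constant column(s): %s",
           sum(sds == 0), paste(colnames(ras)[sds == 0], collapse = ", "),
           level = "warning")
    ras <- ras[, sds > 0, drop = FALSE]
  }
  n <- ncol(ras)
  if (n < 3L) stop("connection_specificity_index needs at least 3 usable regulons")
  P <- cor(ras)
  csi <- matrix(1, n, n, dimnames = dimnames(P))
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      r <- P[a, b] - margin
      csi[a, b] <- csi[b, a] <- sum(P[a, ] < r & P[b, ] < r) / n
    }
  }
  structure(csi, class = c("CSIMatrix", "matrix"))
}

#' Regulon modules by hierarchical clustering of the CSI matrix
#'
#' Agglomerative clustering on Euclidean distances between CSI rows
#' (Ward linkage by default), cut at `n_modules`.
#'
#' @param csi A `CSIMatrix`.
#' @param n_modules Number of modules, in `[2, N - 1]`.
#' @param linkage `hclust` linkage method (default `"ward.D2"`).
#' @return A `ModuleAssignment`: named integer vector regulon -> module,
#'   with the `hclust` tree as attribute `tree`.
#' @export
regulon_modules <- function(csi, n_modules = 7L, linkage = "ward.D2") {
  stopifnot(is.matrix(csi))
  n <- nrow(csi)
  if (n_modules < 2L || n_modules > n - 1L) {
    stop("n_modules must lie in [2, N - 1]")
  }
  tree <- hclust(dist(unclass(csi)), method = linkage)
  assignment <- cutree(tree, k = n_modules)
  st_log("regulon_modules: %d regulons -> %d modules (%s linkage)",
         n, n_modules, linkage)
  structure(assignment, tree = tree,
            class = c("ModuleAssignment", class(assignment)))
}

#' Per-spot mean activity of each regulon module
#'
#' @param ras Spots x regulons activity matrix.
#' @param assignment A `ModuleAssignment` (named regulon -> module).
#' @return Spots x modules matrix of arithmetic means over member columns.
#' @export
module_mean_activity <- function(ras, assignment) {
  .validate_ras(ras)
  mods <- sort(unique(as.integer(assignment)))
  out <- vapply(mods, function(k) {
    members <- names(assignment)[assignment == k]
    rowMeans(ras[, members, drop = FALSE])
  }, numeric(nrow(ras)))
  matrix(out, nrow = nrow(ras),
         dimnames = list(rownames(ras), paste0("M", mods)))
}

#' Edges of the regulon co-activation network
#'
#' Keeps regulon pairs with CSI strictly above `threshold` (default 0.85),
#' filtering weakly connected regulons; the edge list loads directly into
#' standard graph viewers.
#'
#' @param csi A `CSIMatrix`.
#' @param threshold Edge threshold, strict `>`.
#' @return Data frame `regulonA`, `regulonB`, `csi`.
#' @export
csi_network_edges <- function(csi, threshold = 0.85) {
  stopifnot(is.matrix(csi))
  idx <- which(upper.tri(csi) & unclass(csi) > threshold, arr.ind = TRUE)
  out <- data.frame(regulonA = rownames(csi)[idx[, 1L]],
                    regulonB = colnames(csi)[idx[, 2L]],
                    csi = csi[idx], stringsAsFactors = FALSE)
  st_log("csi_network_edges: %d edges at CSI > %g", nrow(out), threshold)
  out
}
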