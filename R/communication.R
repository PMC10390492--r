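# Sender -> receiver communication probability on reference single cells
# with a one-sided label-permutation test, and the final intersection
# filter combining colocalization, spatial enrichment and communication.

#' Per-type mean expression
#'
#' Arithmetic mean of log-normalized expression per cell type and gene.
#' Every label must cover at least 3 cells.
#'
#' @param m An `ExpressionMatrix` (cells as observations), layer `lognorm`.
#' @param labels Character cell-type labels, one per cell.
#' @return A types x genes numeric matrix.
#' @export
group_means <- function(m, labels) {
  validate_expression_matrix(m)
  stopifnot(length(labels) == ncol(m))
  cnt <- table(labels)
  small <- names(cnt)[cnt < 3L]
  if (length(small) > 0L) {
    stop("cell types with fewer than 3 cells: ",
         paste(small, collapse = ", "))
  }
  sums <- rowsum(t(unclass(m)), group = labels)
  sums / as.vector(cnt[rownames(sums)])
}

# Geometric mean of per-type means over subunit genes, for every type.
.subunit_score <- function(means, genes) {
  sub <- means[, genes, drop = FALSE]
  out <- exp(rowMeans(log(sub)))
  out[!is.finite(out)] <- 0
  out
}

#' Permutation-tested communication probability between cell types
#'
#' For each ordered (sender, receiver) type pair and LR pair, the ligand
#' mass `L_s` is the geometric mean over ligand subunits of the sender's
#' mean expression, the receptor mass `R_r` likewise for the receiver, and
#' the communication probability is the saturating Hill form
#' `prob = L_s * R_r / (kh + L_s * R_r)`. Significance comes from a
#' one-sided global label-permutation test:
#' `p_perm = (1 + #\{prob* >= prob\}) / (n_perm + 1)`.
#'
#' @param m An `ExpressionMatrix` of reference cells, layer `lognorm`.
#' @param labels Character cell-type labels, one per cell.
#' @param db An `LRDatabase`; pairs with missing subunits are skipped.
#' @param kh Half-saturation constant (default 0.5).
#' @param n_perm Number of permutations (default 1000; a value below 100
#'   triggers a warning, 0 disables testing with `p_perm = NA`).
#' @param seed Integer seed; required when `n_perm > 0`.
#' @param alpha Significance level on `p_perm` (strict `<`).
#' @return A `CCCTable` data frame keyed by `(sender, receiver, pair_id)`
#'   with `prob`, `p_perm` and `significant`.
#' @export
communication_probability <- function(m, labels, db, kh = 0.5,
                                      n_perm = 1000L, seed = NULL,
                                      alpha = 0.05) {
  validate_expression_matrix(m)
  validate_lr_database(db)
  stopifnot(kh > 0, n_perm >= 0L)
  if (n_perm > 0L && is.null(seed)) {
    stop("a seed is required when n_perm > 0")
  }
  if (n_perm > 0L && n_perm < 100L) {
    warning("n_perm < 100 gives a coarse permutation p-value")
  }
  genes <- rownames(m)
  usable <- vapply(seq_len(nrow(db)), function(i) {
    all(c(db$ligand_subunits[[i]], db$receptor_subunits[[i]]) %in% genes)
  }, logical(1L))
  if (!all(usable)) {
    st_log("communication_probability: skipping %d pair(s) with missing subunits",
           sum(!usable), level = "warning")
  }
  db <- db[usable, , drop = FALSE]
  if (nrow(db) == 0L) stop("no LR pair has all subunit genes in the matrix")
  # only the subunit genes enter the score; drop the rest for speed
  need <- unique(unlist(c(db$ligand_subunits, db$receptor_subunits)))
  sub <- expression_matrix(unclass(m)[need, , drop = FALSE], layer = "lognorm")

  types <- sort(unique(labels))
  grid <- expand.grid(sender = types, receiver = types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  probs_for <- function(means) {
    res <- numeric(nrow(grid) * nrow(db))
    k <- 1L
    for (i in seq_len(nrow(db))) {
      L <- .subunit_score(means, db$ligand_subunits[[i]])
      R <- .subunit_score(means, db$receptor_subunits[[i]])
      lr <- L[grid$sender] * R[grid$receiver]
      res[seq.int(k, k + nrow(grid) - 1L)] <- lr / (kh + lr)
      k <- k + nrow(grid)
    }
    res
  }
  means_obs <- group_means(sub, labels)
  prob <- probs_for(means_obs)
  out <- data.frame(sender = rep(grid$sender, times = nrow(db)),
                    receiver = rep(grid$receiver, times = nrow(db)),
                    pair_id = rep(db$pair_id, each = nrow(grid)),
                    prob = prob, stringsAsFactors = FALSE)
  if (n_perm > 0L) {
    exceed <- integer(nrow(out))
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        perm <- sample(labels)
        pm <- rowsum(t(unclass(sub)), group = perm) /
          as.vector(table(perm)[types])
        exceed <- exceed + (probs_for(pm) >= prob)
      }
    })
    out$p_perm <- (1 + exceed) / (n_perm + 1)
  } else {
    out$p_perm <- NA_real_
  }
  out$significant <- !is.na(out$p_perm) & out$p_perm < alpha
  st_log("communication_probability: %d rows (%d type pairs x %d LR pairs), %d significant",
         nrow(out), nrow(grid), nrow(db), sum(out$significant))
  class(out) <- c("CCCTable", "data.frame")
  out
}

#' Final intersection filter of the spatial communication pipeline
#'
#' A directed (sender, receiver, pair) communication row is retained iff
#' its unordered type pair is a kept colocalization edge, the (edge, pair)
#' row is spatially enriched, and the permutation test is significant.
#' Both directions of an unordered enriched pair are evaluated.
#'
#' @param enr An `EnrichmentTable`.
#' @param ccc A `CCCTable`.
#' @param net A `ColocalizationNetwork`.
#' @return An `STcommResult` data frame: the `ccc` rows joined with the
#'   matching enrichment columns and a `retained` flag.
#' @export
stcomm_filter <- function(enr, ccc, net) {
  stopifnot(inherits(enr, "EnrichmentTable"), inherits(ccc, "CCCTable"))
  ukey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "||")
  }
  edge_keys <- ukey(net$typeA[net$kept], net$typeB[net$kept])
  enr_key <- paste(ukey(enr$typeA, enr$typeB), enr$pair_id, sep = "||")
  ccc_key <- paste(ukey(ccc$sender, ccc$receiver), ccc$pair_id, sep = "||")
  idx <- match(ccc_key, enr_key)
  out <- ccc
  out$enriched <- !is.na(idx) & enr$enriched[idx]
  out$q_enrichment <- ifelse(is.na(idx), NA_real_, enr$q[idx])
  out$edge <- ukey(ccc$sender, ccc$receiver) %in% edge_keys
  out$retained <- out$edge & out$enriched & out$significant
  st_log("stcomm_filter: %d/%d directed rows retained",
         sum(out$retained), nrow(out))
  class(out) <- c("STcommResult", "data.frame")
  out
}

#' Run the full spatially constrained communication pipeline
#'
#' Convenience driver: log-normalizes the spot and reference matrices,
#' builds the colocalization network from the weights, scores per-spot LR
#' co-expression, tests spatial enrichment, computes permutation-tested
#' communication probabilities on the reference cells, and intersects the
#' three.
#'
#' @param expr Spot `ExpressionMatrix` (raw counts).
#' @param weights A `CellTypeWeights`.
#' @param ref_expr Reference-cell `ExpressionMatrix` (raw counts).
#' @param ref_labels Cell-type labels for `ref_expr`.
#' @param lr_db An `LRDatabase`.
#' @param config An `AnalysisConfig`; `config$seed` drives the
#'   permutation test.
#' @param occupancy Optional external Boolean occupancy table.
#' @return A list with `network`, `coexpression`, `enrichment`, `ccc` and
#'   `result` (the `STcommResult`).
#' @export
stcomm_run <- function(expr, weights, ref_expr, ref_labels, lr_db,
                       config = analysis_config(), occupancy = NULL) {
  validate_analysis_config(config)
  ln <- lognormalize(expr, scale_factor = config$scale_factor)
  net <- colocalization_network(pairwise_pcc(weights),
                                min_pcc = config$min_pcc,
                                alpha = config$alpha)
  co <- coexpression_scores(ln, lr_db)
  occ <- binarize_weights(weights, threshold = config$weight_threshold,
                          table = occupancy)
  enr <- spatial_lr_enrichment(occ, co, net, alpha = config$alpha)
  ref_ln <- lognormalize(ref_expr, scale_factor = config$scale_factor)
  ccc <- communication_probability(ref_ln, ref_labels, lr_db,
                                   kh = config$kh, n_perm = config$n_perm,
                                   seed = config$seed, alpha = config$alpha)
  res <- stcomm_filter(enr, ccc, net)
  list(network = net, coexpression = co, enrichment = enr, ccc = ccc,
       result = res)
}
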