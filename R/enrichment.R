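# Per-spot ligand-receptor co-expression scoring and Fisher-exact spatial
# enrichment of co-expressed pairs within colocalized cell-type pairs.

# Geometric mean over subunit rows per observation; any zero subunit gives 0.
.geo_mean_rows <- function(m, genes) {
  sub <- m[genes, , drop = FALSE]
  out <- exp(colMeans(log(sub)))
  out[!is.finite(out)] <- 0  # log(0) = -Inf propagates to a 0 score
  out
}

#' Per-spot ligand-receptor co-expression scores
#'
#' For every database pair and spot, the ligand side `L(exp)` is the
#' geometric mean of the ligand subunit values, the receptor side `R(exp)`
#' likewise, and the co-expression level is the product
#' `R_LR = L(exp) * R(exp)`. Arithmetic minimum is offered as an
#' alternative multi-subunit aggregation. Pairs with subunits missing from
#' the matrix are skipped with a logged warning.
#'
#' @param m An `ExpressionMatrix`, layer `lognorm`.
#' @param db An `LRDatabase`.
#' @param aggregate `"geometric"` (default) or `"min"` subunit aggregation.
#' @return A `CoexpressionScores` matrix, spots x pairs, nonnegative.
#' @export
coexpression_scores <- function(m, db, aggregate = c("geometric", "min")) {
  validate_expression_matrix(m)
  validate_lr_database(db)
  aggregate <- match.arg(aggregate)
  if (!identical(attr(m, "layer"), "lognorm")) {
    stop("coexpression_scores expects log-normalized expression")
  }
  agg <- if (aggregate == "geometric") {
    .geo_mean_rows
  } else {
    function(mm, genes) apply(mm[genes, , drop = FALSE], 2L, min)
  }
  genes <- rownames(m)
  usable <- vapply(seq_len(nrow(db)), function(i) {
    all(c(db$ligand_subunits[[i]], db$receptor_subunits[[i]]) %in% genes)
  }, logical(1L))
  if (!all(usable)) {
    st_log("coexpression_scores: skipping %d pair(s) with missing subunits: %s",
           sum(!usable), paste(db$pair_id[!usable], collapse = ", "),
           level = "warning")
  }
  if (!any(usable)) stop("no LR pair has all subunit genes in the matrix")
  keep <- which(usable)
  scores <- vapply(keep, function(i) {
    agg(m, db$ligand_subunits[[i]]) * agg(m, db$receptor_subunits[[i]])
  }, numeric(ncol(m)))
  scores <- matrix(scores, nrow = ncol(m),
                   dimnames = list(colnames(m), db$pair_id[keep]))
  st_log("coexpression_scores: %d spots x %d pairs (%s aggregation)",
         nrow(scores), ncol(scores), aggregate)
  structure(scores, class = c("CoexpressionScores", "matrix"))
}

#' One-sided Fisher exact test for enrichment
#'
#' Vectorized over tables. The p-value is the hypergeometric tail
#' `P(X >= a)` for the 2x2 table with fixed margins ("greater"
#' alternative); the odds ratio is the sample cross-product `ad/bc`
#' (`Inf` when `bc = 0` with `ad > 0`, `NaN` when both products are 0).
#'
#' @param a,b,c,d Nonnegative integer vectors: `a` co-occurrence,
#'   `b`/`c` single-positive, `d` double-negative counts.
#' @return A data frame with `odds_ratio` and `p`.
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  stopifnot(length(a) == length(b), length(a) == length(c),
            length(a) == length(d))
  counts <- cbind(a, b, c, d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be nonnegative integers")
  }
  p <- phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
  ad <- a * d; bc <- b * c
  odds <- ifelse(bc > 0, ad / bc, ifelse(ad > 0, Inf, NaN))
  data.frame(odds_ratio = odds, p = p)
}

#' Spatial enrichment of co-expressed LR pairs within colocalized types
#'
#' For each kept colocalization edge `(A, B)` and each LR pair:
#' `X = occ(A) AND occ(B)` (both types confidently present in the spot)
#' and `Y = (R_LR > 0)` (the pair co-expressed there). The 2x2 contingency
#' table over spots (`a = |X & Y|`, `b = |X & !Y|`, `c = |!X & Y|`,
#' `d = |!X & !Y|`) is tested with the one-sided Fisher exact test and
#' Benjamini-Hochberg correction pooled over all (edge, pair) rows.
#'
#' @param occ A `BooleanOccupancy` (spots x types).
#' @param co A `CoexpressionScores` (spots x pairs).
#' @param net A `ColocalizationNetwork`.
#' @param alpha Adjusted-p threshold, strict `<` (default 0.05).
#' @param coexpr_quantile Optional quantile in (0, 1); when given, `Y`
#'   requires `R_LR` above that quantile of its positive values instead of
#'   simply `R_LR > 0` (for deeply sequenced data; default off).
#' @return An `EnrichmentTable` data frame keyed by
#'   `(typeA, typeB, pair_id)` with counts, `odds_ratio`, `p`, `q` and
#'   `enriched` (`q < alpha`). Zero kept edges give an empty table.
#' @export
spatial_lr_enrichment <- function(occ, co, net, alpha = 0.05,
                                  coexpr_quantile = NULL) {
  stopifnot(inherits(occ, "BooleanOccupancy"),
            inherits(co, "CoexpressionScores"))
  if (!setequal(rownames(occ), rownames(co))) {
    stop("occupancy and co-expression matrices cover different spots")
  }
  co <- unclass(co)[rownames(occ), , drop = FALSE]
  kept <- net[net$kept, , drop = FALSE]
  cols <- c("typeA", "typeB", "pair_id", "a", "b", "c", "d",
            "odds_ratio", "p", "q", "enriched")
  if (nrow(kept) == 0L) {
    st_log("spatial_lr_enrichment: network has no kept edges; empty table",
           level = "warning")
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 3L), cols[1:3]))
    for (cc in cols[4:11]) out[[cc]] <- numeric(0)
    class(out) <- c("EnrichmentTable", "data.frame")
    return(out)
  }
  ybin <- if (is.null(coexpr_quantile)) {
    co > 0
  } else {
    stopifnot(coexpr_quantile > 0, coexpr_quantile < 1)
    thr <- apply(co, 2L, function(v) {
      pos <- v[v > 0]
      if (length(pos) == 0L) Inf else stats::quantile(pos, coexpr_quantile)
    })
    sweep(co, 2L, thr, ">")
  }
  rows <- lapply(seq_len(nrow(kept)), function(e) {
    x <- occ[, kept$typeA[e]] & occ[, kept$typeB[e]]
    a <- colSums(ybin & x); b <- sum(x) - a
    c_ <- colSums(ybin & !x); d <- sum(!x) - c_
    data.frame(typeA = kept$typeA[e], typeB = kept$typeB[e],
               pair_id = colnames(co), a = a, b = b, c = c_, d = d,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  ft <- fisher_exact_greater(tab$a, tab$b, tab$c, tab$d)
  tab$odds_ratio <- ft$odds_ratio
  tab$p <- ft$p
  tab$q <- bh_adjust(tab$p)
  tab$enriched <- tab$q < alpha
  st_log("spatial_lr_enrichment: %d/%d (edge, pair) rows enriched at q < %g",
         sum(tab$enriched), nrow(tab), alpha)
  class(tab) <- c("EnrichmentTable", "data.frame")
  tab
}
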