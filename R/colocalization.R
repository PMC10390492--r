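# Cell-type colocalization from deconvolution weights: within-spot
# correlation of weight columns, a filtered colocalization network, and
# weight binarization into Boolean occupancy.

#' Pairwise Pearson correlation of cell-type weights with p-values
#'
#' Computes the full symmetric PCC matrix over cell-type weight columns
#' (all spots used) and two-sided p-values from the t approximation with
#' `n - 2` degrees of freedom, `t = r * sqrt((n - 2) / (1 - r^2))`.
#' Zero-variance columns yield undefined correlations: they are flagged
#' (attribute `degenerate`) and excluded from testing (NA entries).
#'
#' @param w A `CellTypeWeights` (spots x types), at least 3 spots.
#' @return A list with `pcc` (types x types), `p` (types x types, NA on
#'   the diagonal and for degenerate columns) and `n` (number of spots).
#' @export
pairwise_pcc <- function(w) {
  validate_cell_type_weights(w)
  n <- nrow(w)
  if (n < 3L) stop("pairwise_pcc needs at least 3 spots")
  sds <- apply(w, 2L, sd)
  degenerate <- colnames(w)[sds == 0]
  if (length(degenerate) == ncol(w)) {
    stop("all cell-type weight columns have zero variance")
  }
  if (length(degenerate) > 0L) {
    st_log("pairwise_pcc: excluding zero-variance column(s): %s",
           paste(degenerate, collapse = ", "), level = "warning")
  }
  r <- suppressWarnings(cor(unclass(w)))
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  rr <- pmin(pmax(r, -1), 1)
  tstat <- rr * sqrt((n - 2) / pmax(1 - rr^2, 0))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[!is.finite(rr)] <- NA_real_
  p[is.finite(rr) & abs(rr) == 1] <- 0  # |r| = 1 exactly: t is infinite
  diag(p) <- NA_real_
  st_log("pairwise_pcc: %d spots x %d types", n, ncol(w))
  list(pcc = r, p = p, n = n,
       degenerate = degenerate)
}

#' Build the cell-type colocalization network
#'
#' Benjamini-Hochberg adjustment is applied over the family of all
#' unordered type pairs with finite PCC; an edge is kept iff
#' `pcc > min_pcc` and `q < alpha` (both strict).
#'
#' @param pcc,p Matrices from [pairwise_pcc()] (or the list itself passed
#'   as `pcc`, in which case `p` is taken from it).
#' @param min_pcc PCC threshold, strict `>` (default 0.06).
#' @param alpha Adjusted-p threshold, strict `<` (default 0.05).
#' @return A `ColocalizationNetwork`: data frame of all tested unordered
#'   pairs (`typeA`, `typeB`, `pcc`, `p`, `q`, `kept`) with the full PCC
#'   matrix as attribute `pcc_matrix`.
#' @export
colocalization_network <- function(pcc, p = NULL, min_pcc = 0.06,
                                   alpha = 0.05) {
  if (is.list(pcc) && !is.data.frame(pcc)) {
    p <- pcc$p; pcc <- pcc$pcc
  }
  stopifnot(is.matrix(pcc), is.matrix(p), identical(dim(pcc), dim(p)))
  types <- colnames(pcc)
  idx <- which(upper.tri(pcc), arr.ind = TRUE)
  edges <- data.frame(typeA = types[idx[, 1L]], typeB = types[idx[, 2L]],
                      pcc = pcc[idx], p = p[idx], stringsAsFactors = FALSE)
  edges <- edges[is.finite(edges$pcc), , drop = FALSE]
  if (nrow(edges) > 0L && anyNA(edges$p)) {
    stop("p-values missing for pairs with finite PCC")
  }
  edges$q <- bh_adjust(edges$p)
  edges$kept <- edges$pcc > min_pcc & edges$q < alpha
  rownames(edges) <- NULL
  st_log("colocalization_network: %d/%d pairs kept (pcc > %g, q < %g)",
         sum(edges$kept), nrow(edges), min_pcc, alpha)
  structure(edges, pcc_matrix = pcc,
            class = c("ColocalizationNetwork", "data.frame"))
}

#' Binarize deconvolution weights into Boolean occupancy
#'
#' Either thresholds weights (`weight >= threshold`, boundary inclusive)
#' or passes through an externally supplied Boolean table (e.g. confident
#' calls from the upstream deconvolution), aligned to the weights' spot
#' and type order.
#'
#' @param w A `CellTypeWeights`.
#' @param threshold Threshold in (0, 1); ignored when `table` is given.
#' @param table Optional logical matrix with matching spot/type ids.
#' @return A `BooleanOccupancy` logical matrix, same dimnames as `w`.
#' @export
binarize_weights <- function(w, threshold = 0.1, table = NULL) {
  validate_cell_type_weights(w)
  if (is.null(table)) {
    stopifnot(threshold > 0, threshold < 1)
    occ <- unclass(w) >= threshold
  } else {
    table <- as.matrix(table)
    if (!setequal(rownames(table), rownames(w)) ||
        !setequal(colnames(table), colnames(w))) {
      stop("external occupancy table ids do not match the weight matrix")
    }
    occ <- matrix(as.logical(table[rownames(w), colnames(w)]),
                  nrow(w), ncol(w))
    dimnames(occ) <- dimnames(unclass(w))
  }
  st_log("binarize_weights: %.1f%% of entries occupied",
         100 * mean(occ))
  structure(occ, class = c("BooleanOccupancy", "matrix"))
}
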