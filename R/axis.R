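# Axis-patterning statistics: combinatorial anterior-posterior section
# patterns and gene selection, dorsal/medial/ventral gene-set scoring and
# binarization, rank-sum differential tests, and axis-related regulon
# selection.

#' Enumerate consecutive combinatorial section patterns
#'
#' All contiguous section intervals with length between `min_len` and
#' `max_len`, ordered by (start, length). With the defaults (singleton
#' sections and the full run excluded) 9 ordered sections yield exactly 35
#' patterns; the count is `sum(n - len + 1)` over admissible lengths.
#'
#' @param n_sections Number of ordered sections (>= 3).
#' @param min_len,max_len Inclusive interval-length bounds (defaults 2 and
#'   `n_sections - 1`).
#' @return Data frame `pattern_id`, `start`, `end`, `length`.
#' @export
enumerate_section_patterns <- function(n_sections, min_len = 2L,
                                       max_len = n_sections - 1L) {
  stopifnot(n_sections >= 3L)
  if (min_len > max_len) stop("min_len must not exceed max_len")
  rows <- list()
  for (start in seq_len(n_sections)) {
    for (len in seq.int(min_len, max_len)) {
      end <- start + len - 1L
      if (end > n_sections) next
      rows[[length(rows) + 1L]] <- data.frame(
        pattern_id = sprintf("P%d_%d", start, end),
        start = start, end = end, length = len, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$length), , drop = FALSE]
}

#' Indicator matrix of section patterns
#'
#' @param patterns Output of [enumerate_section_patterns()].
#' @param n_sections Number of sections.
#' @return Sections x patterns 0/1 matrix.
#' @export
section_pattern_matrix <- function(patterns, n_sections) {
  out <- vapply(seq_len(nrow(patterns)), function(i) {
    as.numeric(seq_len(n_sections) >= patterns$start[i] &
                 seq_len(n_sections) <= patterns$end[i])
  }, numeric(n_sections))
  matrix(out, nrow = n_sections,
         dimnames = list(NULL, patterns$pattern_id))
}

#' Select anterior-posterior pattern genes by pattern correlation
#'
#' For each candidate gene and each consecutive section pattern, the
#' Pearson correlation between the gene's spot expression and the pattern
#' indicator broadcast to spots via section membership is computed; the
#' selected genes are the union of the `top_k` correlations per pattern.
#' Constant genes have undefined correlation and are skipped with a log
#' entry. Ranking ties are broken by gene name for determinism.
#'
#' @param m An `ExpressionMatrix` restricted to the target region's spots.
#' @param ann A `SpotAnnotations` covering the same spots; each section
#'   must contribute at least 3 spots.
#' @param candidate_genes Character vector of genes to rank.
#' @param top_k Genes kept per pattern (default 20; clamped to the
#'   candidate count).
#' @param min_len,max_len Passed to [enumerate_section_patterns()].
#' @param per_section Correlate section-mean expression instead of
#'   spot-level values (default `FALSE`: spot-level uses all data).
#' @return An `AxisGeneTable`: long data frame `gene`, `pattern_id`,
#'   `pcc`, `rank`, `selected`, with the union of selected genes as
#'   attribute `selected_genes`.
#' @export
ap_pattern_genes <- function(m, ann, candidate_genes, top_k = 20L,
                             min_len = 2L, max_len = NULL,
                             per_section = FALSE) {
  validate_expression_matrix(m)
  validate_spot_annotations(ann)
  stopifnot(top_k >= 1L)
  ann <- ann[match(colnames(m), ann$obs_id), , drop = FALSE]
  if (anyNA(ann$obs_id)) stop("annotations missing for some spots")
  sec <- ann$section_index - min(ann$section_index) + 1L
  n_sections <- max(sec)
  if (any(table(sec) < 3L)) stop("each section needs at least 3 spots")
  max_len <- max_len %||% (n_sections - 1L)
  pats <- enumerate_section_patterns(n_sections, min_len, max_len)
  pmat <- section_pattern_matrix(pats, n_sections)

  genes <- intersect(candidate_genes, rownames(m))
  if (length(genes) == 0L) stop("no candidate gene is present in the matrix")
  expr <- t(unclass(m)[genes, , drop = FALSE])
  if (per_section) {
    expr <- rowsum(expr, group = sec) / as.vector(table(sec))
    ind <- pmat
  } else {
    ind <- pmat[sec, , drop = FALSE]
  }
  const <- apply(expr, 2L, sd) == 0
  if (any(const)) {
    st_log("ap_pattern_genes: skipping %d constant gene(s): %s",
           sum(const), paste(genes[const], collapse = ", "),
           level = "warning")
    expr <- expr[, !const, drop = FALSE]
    genes <- genes[!const]
  }
  pcc <- cor(expr, ind)
  k <- min(top_k, length(genes))
  tabs <- lapply(colnames(pcc), function(pid) {
    v <- pcc[, pid]
    ord <- order(-v, names(v))  # ties broken by gene name
    data.frame(gene = names(v)[ord], pattern_id = pid, pcc = v[ord],
               rank = seq_along(v), selected = seq_along(v) <= k,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, tabs)
  selected <- sort(unique(out$gene[out$selected]))
  st_log("ap_pattern_genes: %d genes x %d patterns, union of top %d = %d genes",
         length(genes), nrow(pats), k, length(selected))
  structure(out, selected_genes = selected,
            class = c("AxisGeneTable", "data.frame"))
}

#' Score region-related gene sets per spot
#'
#' Activity of each region-related (e.g. dorsal / medial / ventral) gene
#' set per spot via the area-under-recovery-curve score.
#'
#' @param m An `ExpressionMatrix`.
#' @param sigs A `SignatureCollection`, one set per region label.
#' @param top_frac,seed Passed to [auc_recovery_score()].
#' @return Spots x regions score matrix.
#' @export
region_activity_scores <- function(m, sigs, top_frac = 0.05, seed = 0L) {
  activity_scores(m, sigs, top_frac = top_frac, seed = seed)
}

#' Binarize region activity scores
#'
#' Method `"zscore"` zeroes spots whose column z-score falls below
#' `z_min`; method `"bimodal"` zeroes spots below the midpoint of the
#' best two-group split of the score distribution (the split minimizing
#' within-group sum of squares over all cut points of the sorted scores).
#' A degenerate distribution (all scores equal) cannot be split: scores
#' pass through unchanged with a warning under `"bimodal"` and error
#' under `"zscore"`.
#'
#' @param scores Spots x regions score matrix.
#' @param method `"zscore"` or `"bimodal"`.
#' @param z_min Z-score floor for method `"zscore"` (default 2.5).
#' @return Matrix of the same shape with sub-threshold entries set to 0.
#' @export
binarize_scores <- function(scores, method = c("zscore", "bimodal"),
                            z_min = 2.5) {
  method <- match.arg(method)
  stopifnot(is.matrix(scores))
  out <- scores
  for (j in seq_len(ncol(scores))) {
    v <- scores[, j]
    if (method == "zscore") {
      s <- sd(v)
      if (s == 0) stop("zero-variance score column: ",
                       colnames(scores)[j] %||% j)
      z <- (v - mean(v)) / s
      out[z < z_min, j] <- 0
    } else {
      thr <- .two_group_midpoint(v)
      if (is.na(thr)) {
        warning("degenerate score distribution in column ",
                colnames(scores)[j] %||% j, "; passing scores through")
        next
      }
      out[v < thr, j] <- 0
    }
  }
  out
}

# Best two-group 1-D split by within-group sum of squares; returns the
# midpoint of the two group means, or NA when all values are equal.
.two_group_midpoint <- function(v) {
  sv <- sort(v)
  n <- length(sv)
  if (sv[1L] == sv[n]) return(NA_real_)
  cs <- cumsum(sv); cs2 <- cumsum(sv^2)
  best <- Inf; cut <- 1L
  for (k in seq_len(n - 1L)) {
    ss_left <- cs2[k] - cs[k]^2 / k
    nr <- n - k
    sr <- cs[n] - cs[k]; sr2 <- cs2[n] - cs2[k]
    ss_right <- sr2 - sr^2 / nr
    if (ss_left + ss_right < best) {
      best <- ss_left + ss_right
      cut <- k
    }
  }
  (cs[cut] / cut + (cs[n] - cs[cut]) / (n - cut)) / 2
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact p by enumeration of the rank-sum distribution when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `U` (the Mann-Whitney statistic, pairs with
#'   `x > y`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 12L
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Dorsal-ventral domain genes by one-vs-rest rank-sum tests
#'
#' For each gene and each region label, a two-sided rank-sum test of the
#' region's spots against all others; Benjamini-Hochberg correction over
#' all (gene, region) tests jointly; genes with `q < alpha` in a region
#' are that region's domain genes.
#'
#' @param m An `ExpressionMatrix` over the region's spots (lognorm
#'   recommended).
#' @param dmv_labels Character region labels (e.g. D/M/V), one per spot;
#'   each region needs at least 3 spots.
#' @param alpha Adjusted-p threshold, strict `<`.
#' @return Data frame `gene`, `region`, `U`, `p`, `q`, `selected`.
#' @export
dv_domain_genes <- function(m, dmv_labels, alpha = 0.05) {
  validate_expression_matrix(m)
  stopifnot(length(dmv_labels) == ncol(m))
  regions <- sort(unique(dmv_labels))
  if (any(table(dmv_labels) < 3L)) {
    stop("each region needs at least 3 spots")
  }
  vals <- unclass(m)
  rows <- list()
  for (reg in regions) {
    inside <- dmv_labels == reg
    for (g in rownames(vals)) {
      wt <- wilcoxon_rank_sum(vals[g, inside], vals[g, !inside])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, region = reg, U = wt$U, p = wt$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$selected <- out$q < alpha
  st_log("dv_domain_genes: %d/%d (gene, region) tests selected at q < %g",
         sum(out$selected), nrow(out), alpha)
  out
}

#' Select anterior-posterior patterned regulons
#'
#' Correlates each regulon's activity with the pseudo-space ordering and
#' keeps regulons with `|PCC| > sd_mult * SD` of all regulon correlations
#' and maximum activity strictly above `min_max_ras`.
#'
#' @param ras Spots x regulons activity matrix.
#' @param pseudo_order Numeric pseudo-space order, one value per spot.
#' @param sd_mult SD multiplier (default 1.5).
#' @param min_max_ras Maximum-activity floor (default 0.2, strict `>`).
#' @return Data frame `regulon`, `pcc`, `max_ras`, `selected`.
#' @export
ap_regulon_selection <- function(ras, pseudo_order, sd_mult = 1.5,
                                 min_max_ras = 0.2) {
  .validate_ras(ras)
  stopifnot(length(pseudo_order) == nrow(ras))
  pcc <- suppressWarnings(as.vector(cor(ras, pseudo_order)))
  cutoff <- sd_mult * sd(pcc, na.rm = TRUE)
  out <- data.frame(regulon = colnames(ras), pcc = pcc,
                    max_ras = apply(ras, 2L, max),
                    stringsAsFactors = FALSE)
  out$selected <- !is.na(out$pcc) & abs(out$pcc) > cutoff &
    out$max_ras > min_max_ras
  st_log("ap_regulon_selection: %d/%d regulons selected (|PCC| > %.3f, max > %g)",
         sum(out$selected), nrow(out), cutoff, min_max_ras)
  out
}

#' Select dorsal-ventral patterned regulons
#'
#' One-vs-rest rank-sum tests of regulon activity per region with
#' Benjamini-Hochberg correction; a regulon is selected when it is
#' differential in some region (`q < alpha`) and its maximum activity
#' exceeds `min_max_ras` (strict `>`).
#'
#' @param ras Spots x regulons activity matrix.
#' @param dmv_labels Region labels, one per spot (>= 3 spots each).
#' @param alpha Adjusted-p threshold.
#' @param min_max_ras Maximum-activity floor.
#' @return Data frame `regulon`, `region`, `p`, `q`, `max_ras`,
#'   `selected`.
#' @export
dv_regulon_selection <- function(ras, dmv_labels, alpha = 0.05,
                                 min_max_ras = 0.2) {
  .validate_ras(ras)
  stopifnot(length(dmv_labels) == nrow(ras))
  regions <- sort(unique(dmv_labels))
  if (any(table(dmv_labels) < 3L)) stop("each region needs at least 3 spots")
  rows <- list()
  for (reg in regions) {
    inside <- dmv_labels == reg
    for (r in colnames(ras)) {
      wt <- wilcoxon_rank_sum(ras[inside, r], ras[!inside, r])
      rows[[length(rows) + 1L]] <- data.frame(
        regulon = r, region = reg, p = wt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  mx <- apply(ras, 2L, max)
  out$max_ras <- mx[out$regulon]
  out$selected <- out$q < alpha & out$max_ras > min_max_ras
  st_log("dv_regulon_selection: %d/%d (regulon, region) rows selected",
         sum(out$selected), nrow(out))
  out
}
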