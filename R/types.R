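# Domain containers. All are light S3 wrappers over base structures:
# matrices carry gene/observation identifiers in dimnames, tables are plain
# data frames, and every constructor runs its validator so invalid objects
# cannot circulate.

#' Construct a gene-by-observation expression matrix
#'
#' The substrate for all scoring. Rows are genes, columns are observations
#' (spots of a spatial array, or cells of a reference dataset). Two layers
#' exist: `raw_counts` (nonnegative integers) and `lognorm`
#' (log-normalized values, see [lognormalize()]).
#'
#' @param values Numeric matrix, genes x observations, with rownames
#'   (gene ids) and colnames (observation ids).
#' @param layer `"raw_counts"` or `"lognorm"`.
#' @return An `ExpressionMatrix`: the matrix with a `layer` attribute.
#' @export
expression_matrix <- function(values, layer = c("raw_counts", "lognorm")) {
  layer <- match.arg(layer)
  x <- structure(as.matrix(values), layer = layer, class = c("ExpressionMatrix", "matrix"))
  validate_expression_matrix(x)
  x
}

#' Validate an ExpressionMatrix
#'
#' Checks identifier uniqueness, nonnegativity, integrality of raw counts
#' and finiteness of log-normalized values.
#'
#' @param x Object to validate.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_expression_matrix <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  layer <- attr(x, "layer") %||% "raw_counts"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("ExpressionMatrix needs gene ids (rownames) and observation ids (colnames)")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids in ExpressionMatrix")
  if (anyDuplicated(colnames(x))) stop("duplicate observation ids in ExpressionMatrix")
  if (anyNA(x)) stop("ExpressionMatrix contains NA values")
  if (min(x) < 0) stop("ExpressionMatrix values must be nonnegative")
  if (layer == "raw_counts" && max(abs(x - round(x))) > 1e-8) {
    stop("raw_counts layer must contain integer counts")
  }
  if (layer == "lognorm" && !all(is.finite(x))) {
    stop("lognorm layer must be finite")
  }
  invisible(x)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d observations\n",
              attr(x, "layer"), nrow(x), ncol(x)))
  invisible(x)
}

#' Construct spot annotations
#'
#' Per-spot metadata for a serially sectioned atlas: craniocaudal section
#' index, array coordinates, an optional spatial-domain label and an
#' optional externally supplied pseudo-space order (one-dimensional axis
#' rank; computed upstream, never here).
#'
#' @param obs_id Character, unique spot ids.
#' @param section_index Integer >= 1; section order along the body axis.
#' @param array_x,array_y Numeric array coordinates.
#' @param domain Optional character domain labels.
#' @param pseudo_order Optional numeric pseudo-space order.
#' @return A `SpotAnnotations` data frame.
#' @export
spot_annotations <- function(obs_id, section_index, array_x, array_y,
                             domain = NULL, pseudo_order = NULL) {
  df <- data.frame(obs_id = as.character(obs_id),
                   section_index = as.integer(section_index),
                   array_x = as.numeric(array_x),
                   array_y = as.numeric(array_y),
                   stringsAsFactors = FALSE)
  df$domain <- if (is.null(domain)) NA_character_ else as.character(domain)
  df$pseudo_order <- if (is.null(pseudo_order)) NA_real_ else as.numeric(pseudo_order)
  class(df) <- c("SpotAnnotations", "data.frame")
  validate_spot_annotations(df)
  df
}

#' Validate SpotAnnotations
#' @param ann Object to validate.
#' @param expr Optional ExpressionMatrix whose observation ids must match.
#' @return `ann`, invisibly.
#' @export
validate_spot_annotations <- function(ann, expr = NULL) {
  stopifnot(is.data.frame(ann))
  need <- c("obs_id", "section_index", "array_x", "array_y")
  if (!all(need %in% names(ann))) {
    stop("SpotAnnotations needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ann$obs_id)) stop("duplicate obs_id in SpotAnnotations")
  if (any(ann$section_index < 1L)) stop("section_index must be >= 1")
  secs <- sort(unique(ann$section_index))
  if (!identical(secs, seq(min(secs), max(secs)))) {
    stop("section_index values must form a contiguous ordered set")
  }
  if (!is.null(expr) && !setequal(ann$obs_id, colnames(expr))) {
    stop("SpotAnnotations obs_ids do not match the expression matrix")
  }
  invisible(ann)
}

#' Construct a spot-by-cell-type deconvolution weight matrix
#'
#' Nonnegative weights in `[0, 1]` per spot (rows) and cell type (columns),
#' as produced by an upstream spot deconvolution method; row sums may be at
#' most 1 (plus numerical tolerance).
#'
#' @param weights Numeric matrix, spots x cell types, with dimnames.
#' @return A `CellTypeWeights` matrix.
#' @export
cell_type_weights <- function(weights) {
  x <- structure(as.matrix(weights), class = c("CellTypeWeights", "matrix"))
  validate_cell_type_weights(x)
  x
}

#' Validate CellTypeWeights
#' @param w Object to validate.
#' @return `w`, invisibly.
#' @export
validate_cell_type_weights <- function(w) {
  stopifnot(is.matrix(w), is.numeric(w))
  if (is.null(rownames(w)) || is.null(colnames(w))) {
    stop("CellTypeWeights needs spot ids (rownames) and type names (colnames)")
  }
  if (anyDuplicated(colnames(w))) stop("duplicate cell-type names")
  if (ncol(w) < 2L) stop("CellTypeWeights needs at least 2 cell types")
  if (anyNA(w) || min(w) < 0 || max(w) > 1 + 1e-6) {
    stop("weights must lie in [0, 1]")
  }
  if (any(rowSums(w) > 1 + 1e-6)) stop("weight row sums must be <= 1")
  invisible(w)
}

#' Construct a ligand-receptor database
#'
#' One record per interacting ligand-receptor unit: possibly multi-subunit
#' ligand and receptor gene sets, the signaling pathway, and the signaling
#' mode (`secreted`, `contact` or `ecm`).
#'
#' @param pair_id Character, unique pair ids.
#' @param ligand_subunits,receptor_subunits Lists of character vectors
#'   (each non-empty) of gene ids.
#' @param pathway Character pathway labels.
#' @param mode Character, each one of `"secreted"`, `"contact"`, `"ecm"`.
#' @return An `LRDatabase` data frame with list columns for subunits.
#' @export
lr_database <- function(pair_id, ligand_subunits, receptor_subunits,
                        pathway, mode) {
  df <- data.frame(pair_id = as.character(pair_id),
                   pathway = as.character(pathway),
                   mode = as.character(mode),
                   stringsAsFactors = FALSE)
  df$ligand_subunits <- lapply(ligand_subunits, as.character)
  df$receptor_subunits <- lapply(receptor_subunits, as.character)
  df <- df[, c("pair_id", "ligand_subunits", "receptor_subunits", "pathway", "mode")]
  class(df) <- c("LRDatabase", "data.frame")
  validate_lr_database(df)
  df
}

#' Validate an LRDatabase
#' @param db Object to validate.
#' @return `db`, invisibly.
#' @export
validate_lr_database <- function(db) {
  stopifnot(is.data.frame(db))
  if (anyDuplicated(db$pair_id)) stop("duplicate pair_id in LRDatabase")
  if (!all(db$mode %in% c("secreted", "contact", "ecm"))) {
    bad <- setdiff(unique(db$mode), c("secreted", "contact", "ecm"))
    stop("unknown signaling mode: ", paste(bad, collapse = ", "))
  }
  for (i in seq_len(nrow(db))) {
    lig <- db$ligand_subunits[[i]]
    rec <- db$receptor_subunits[[i]]
    if (length(lig) < 1L || length(rec) < 1L || any(!nzchar(c(lig, rec)))) {
      stop("empty subunit list in record ", db$pair_id[i])
    }
    if (length(intersect(lig, rec)) > 0L) {
      stop("gene appears as both ligand and receptor subunit in record ",
           db$pair_id[i])
    }
  }
  invisible(db)
}

#' Construct a collection of named gene sets
#'
#' Used for regulon target sets, dorsal/medial/ventral marker sets,
#' signaling signatures and cell-cycle gene lists.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param category Optional character vector (one per set), e.g. region or
#'   pathway labels.
#' @return A `SignatureCollection` (named list with a `category` attribute).
#' @export
signature_collection <- function(sets, category = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  }
  sets <- lapply(sets, as.character)
  if (!is.null(category)) {
    stopifnot(length(category) == length(sets))
    category <- stats::setNames(as.character(category), names(sets))
  }
  structure(sets, category = category,
            class = c("SignatureCollection", "list"))
}

#' Intersect a signature collection with the genes of a matrix
#'
#' Sets that become empty after intersection are dropped with a logged
#' warning (flagged, per the collection's invariant).
#'
#' @param sigs A `SignatureCollection`.
#' @param genes Character vector of gene ids to intersect with.
#' @return The filtered collection.
#' @export
intersect_signatures <- function(sigs, genes) {
  kept <- lapply(sigs, intersect, y = genes)
  empty <- names(kept)[lengths(kept) == 0L]
  if (length(empty) > 0L) {
    st_log("dropping %d gene set(s) with no genes in the matrix: %s",
           length(empty), paste(empty, collapse = ", "), level = "warning")
    kept <- kept[lengths(kept) > 0L]
    if (length(kept) == 0L) stop("no gene set overlaps the matrix genes")
  }
  cat_attr <- attr(sigs, "category")
  signature_collection(kept, category = if (!is.null(cat_attr)) cat_attr[names(kept)])
}
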