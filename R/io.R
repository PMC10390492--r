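# Readers and writers for the standard exchange formats: MatrixMarket
# triplet directories (matrix + features + barcodes, plain or gzip), dense
# TSV matrices, GMT gene sets, and long/keyed TSV tables for weights and
# annotations. All outputs are id-keyed, never positional.

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

.find_triplet_file <- function(dir, stem) {
  for (cand in c(paste0(stem, ".gz"), stem)) {
    p <- file.path(dir, cand)
    if (file.exists(p)) return(p)
  }
  stop("triplet directory ", dir, " is missing ", stem, "[.gz]")
}

#' Read a raw count matrix
#'
#' Accepts either a 10x-style triplet directory (`matrix.mtx`,
#' `features.tsv`, `barcodes.tsv`, each optionally gzipped) or a dense TSV
#' with gene ids in the first column and observation ids in the header.
#' Duplicated feature ids are disambiguated deterministically with
#' suffixes `.1`, `.2`, ...
#'
#' @param path Directory (triplet) or file (dense TSV).
#' @return An `ExpressionMatrix` with layer `raw_counts`.
#' @export
read_count_matrix <- function(path) {
  if (dir.exists(path)) {
    mtx_path <- .find_triplet_file(path, "matrix.mtx")
    feat_path <- .find_triplet_file(path, "features.tsv")
    bc_path <- .find_triplet_file(path, "barcodes.tsv")
    mm <- Matrix::readMM(.open_maybe_gz(mtx_path))
    feats <- read.delim(.open_maybe_gz(feat_path), header = FALSE,
                        stringsAsFactors = FALSE)
    bcs <- read.delim(.open_maybe_gz(bc_path), header = FALSE,
                      stringsAsFactors = FALSE)
    if (nrow(feats) != nrow(mm)) {
      stop(sprintf("dimension mismatch: %s lists %d features but %s declares %d rows",
                   feat_path, nrow(feats), mtx_path, nrow(mm)))
    }
    if (nrow(bcs) != ncol(mm)) {
      stop(sprintf("dimension mismatch: %s lists %d barcodes but %s declares %d columns",
                   bc_path, nrow(bcs), mtx_path, ncol(mm)))
    }
    # 10x convention: column 2 holds the gene symbol when present
    ids <- trimws(if (ncol(feats) >= 2L) feats[[2L]] else feats[[1L]])
    if (anyDuplicated(ids)) {
      st_log("disambiguating %d duplicated feature id(s)",
             sum(duplicated(ids)), level = "warning")
      ids <- make.unique(ids, sep = ".")
    }
    vals <- as.matrix(mm)
    dimnames(vals) <- list(ids, trimws(bcs[[1L]]))
  } else if (file.exists(path)) {
    df <- read.delim(path, header = TRUE, row.names = 1L, check.names = FALSE)
    vals <- as.matrix(df)
    rownames(vals) <- trimws(rownames(vals))
    if (!is.numeric(vals)) stop("dense matrix ", path, " is not numeric")
  } else {
    stop("no such file or directory: ", path)
  }
  st_log("read_count_matrix: %d genes x %d observations from %s",
         nrow(vals), ncol(vals), path)
  expression_matrix(vals, layer = "raw_counts")
}

#' Write a raw count matrix as a MatrixMarket triplet directory
#'
#' Writes plain-text `matrix.mtx` (1-based coordinate format),
#' `features.tsv` and `barcodes.tsv`; the reader/writer pair round-trips
#' exactly.
#'
#' @param m An `ExpressionMatrix` (layer `raw_counts`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(m, dir) {
  validate_expression_matrix(m)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- methods::as(Matrix::Matrix(unclass(m)[, , drop = FALSE], sparse = TRUE),
                    "generalMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Log-normalize raw counts
#'
#' Per observation: `ln(1 + count / total * scale_factor)`, the standard
#' library-size normalization with a default scale factor of 10,000.
#' Observations with zero total counts are rejected.
#'
#' @param m An `ExpressionMatrix` with layer `raw_counts`.
#' @param scale_factor Positive scale factor (default 10000).
#' @return An `ExpressionMatrix` with layer `lognorm`.
#' @export
lognormalize <- function(m, scale_factor = 10000) {
  validate_expression_matrix(m)
  if (!identical(attr(m, "layer"), "raw_counts")) {
    stop("lognormalize expects the raw_counts layer")
  }
  stopifnot(scale_factor > 0)
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("observations with zero total counts: ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  }
  vals <- log1p(sweep(unclass(m), 2L, totals, "/") * scale_factor)
  st_log("lognormalize: scale_factor=%g over %d observations",
         scale_factor, ncol(m))
  expression_matrix(vals, layer = "lognorm")
}

#' Read / write a ligand-receptor database TSV
#'
#' Columns: `pair_id`, `ligand`, `receptor` (subunits separated by `_`),
#' `pathway`, `mode` (`secreted`/`contact`/`ecm`).
#'
#' @param path TSV file.
#' @return `read_lr_database`: an `LRDatabase`.
#' @export
read_lr_database <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("pair_id", "ligand", "receptor", "pathway", "mode")
  if (!all(need %in% names(df))) {
    stop("LR database TSV needs columns: ", paste(need, collapse = ", "))
  }
  split_subunits <- function(x, what) {
    parts <- strsplit(trimws(x), "_", fixed = TRUE)
    for (i in seq_along(parts)) {
      if (length(parts[[i]]) == 0L || any(!nzchar(parts[[i]]))) {
        stop("empty ", what, " subunit after split in record ", df$pair_id[i])
      }
    }
    parts
  }
  db <- lr_database(pair_id = df$pair_id,
                    ligand_subunits = split_subunits(df$ligand, "ligand"),
                    receptor_subunits = split_subunits(df$receptor, "receptor"),
                    pathway = df$pathway, mode = df$mode)
  st_log("read_lr_database: %d pairs from %s", nrow(db), path)
  db
}

#' @rdname read_lr_database
#' @param db An `LRDatabase`.
#' @export
write_lr_database <- function(db, path) {
  validate_lr_database(db)
  out <- data.frame(
    pair_id = db$pair_id,
    ligand = vapply(db$ligand_subunits, paste, "", collapse = "_"),
    receptor = vapply(db$receptor_subunits, paste, "", collapse = "_"),
    pathway = db$pathway, mode = db$mode, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param path GMT file.
#' @param category Optional per-set category labels (recycled from the GMT
#'   description field when `"description"`).
#' @return `read_gene_sets`: a `SignatureCollection`.
#' @export
read_gene_sets <- function(path, category = c("none", "description")) {
  category <- match.arg(category)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("malformed GMT line (need name, description, >=1 gene) in ", path)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  names(sets) <- nm
  sigs <- signature_collection(sets,
    category = if (category == "description") desc)
  st_log("read_gene_sets: %d sets from %s", length(sigs), path)
  sigs
}

#' @rdname read_gene_sets
#' @param sigs A `SignatureCollection`.
#' @export
write_gene_sets <- function(sigs, path) {
  cat_attr <- attr(sigs, "category")
  lines <- vapply(names(sigs), function(nm) {
    desc <- if (!is.null(cat_attr)) cat_attr[[nm]] else "na"
    paste(c(nm, desc, sigs[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write cell-type deconvolution weights as TSV
#'
#' Wide TSV keyed by `obs_id` in the first column; remaining columns are
#' cell types.
#'
#' @param path TSV file.
#' @return `read_cell_type_weights`: a `CellTypeWeights`.
#' @export
read_cell_type_weights <- function(path) {
  df <- read.delim(path, header = TRUE, row.names = 1L, check.names = FALSE)
  cell_type_weights(as.matrix(df))
}

#' @rdname read_cell_type_weights
#' @param w A `CellTypeWeights`.
#' @export
write_cell_type_weights <- function(w, path) {
  validate_cell_type_weights(w)
  out <- data.frame(obs_id = rownames(w), as.data.frame(unclass(w)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write spot annotations as TSV
#' @param path TSV file.
#' @return `read_spot_annotations`: a `SpotAnnotations`.
#' @export
read_spot_annotations <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  spot_annotations(df$obs_id, df$section_index, df$array_x, df$array_y,
                   domain = df$domain, pseudo_order = df$pseudo_order)
}

#' @rdname read_spot_annotations
#' @param ann A `SpotAnnotations`.
#' @export
write_spot_annotations <- function(ann, path) {
  validate_spot_annotations(ann)
  write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Optional spot quality-control filter
#'
#' Drops observations with fewer than `min_genes` detected genes or more
#' than `max_mito_frac` of counts on mitochondrial genes (matched by
#' `mito_pattern`). Provided as optional preprocessing; no downstream
#' stage depends on it.
#'
#' @param m An `ExpressionMatrix` (raw counts).
#' @param min_genes Minimum detected genes per observation.
#' @param max_mito_frac Maximum mitochondrial count fraction.
#' @param mito_pattern Regular expression identifying mitochondrial genes.
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_spots <- function(m, min_genes = 1000L, max_mito_frac = 0.1,
                         mito_pattern = "^mt-") {
  validate_expression_matrix(m)
  detected <- colSums(m > 0)
  mito <- grepl(mito_pattern, rownames(m), ignore.case = TRUE)
  mito_frac <- if (any(mito)) colSums(m[mito, , drop = FALSE]) / pmax(colSums(m), 1) else 0
  keep <- detected >= min_genes & mito_frac <= max_mito_frac
  st_log("filter_spots: %d of %d observations kept (min_genes=%d, max_mito_frac=%g)",
         sum(keep), ncol(m), min_genes, max_mito_frac)
  if (!any(keep)) stop("no observations survive the QC filter")
  expression_matrix(unclass(m)[, keep, drop = FALSE], layer = attr(m, "layer"))
}
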