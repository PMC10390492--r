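# Synthetic spatial atlas with planted ground truth. The generator stands
# in for a serially sectioned embryo atlas: spatial domains are bands that
# span sections, each planted colocalized cell-type pair shares elevated
# deconvolution weight inside one band, planted ligand/receptor genes are
# elevated where the sender/receiver weight is high, gradient genes ramp
# monotonically across a section interval, and domain marker genes are
# elevated inside their band. Decoy ligand-receptor pairs and filler genes
# carry no planted structure. All generators are pure functions of
# (parameters, seed).

.clip01 <- function(x) pmin(1, pmax(0, x))

#' Simulate a spatial atlas with planted colocalization and signaling
#'
#' Cell-type weights are Dirichlet-distributed per spot (respecting the
#' simplex constraint of deconvolution output); inside its hosting domain a
#' planted pair's two types receive a concentration boost proportional to
#' `effect_size`. Counts are negative-binomial around log-normal baseline
#' means (overdispersed, like real spot data); planted ligand genes are
#' elevated multiplicatively where the sender's weight is high, receptor
#' genes where the receiver's weight is high. `effect_size = 0` yields a
#' fully null atlas.
#'
#' @param n_sections Number of serial sections (craniocaudal order).
#' @param grid Integer vector `c(nx, ny)`; spots per section = `nx * ny`
#'   (at least 50).
#' @param n_types Number of cell types (>= 4).
#' @param n_genes Total genes, including planted and filler genes.
#' @param n_coloc_pairs Planted colocalized type pairs (disjoint types),
#'   each hosting one planted ligand-receptor pair.
#' @param n_lr_decoy Decoy ligand-receptor pairs with no planted signal.
#' @param n_gradient_per_interval If positive, plant this many monotone
#'   gradient genes on every admissible consecutive section interval.
#' @param n_domain_markers If positive, plant this many marker genes per
#'   spatial domain band.
#' @param effect_size Multiplicative planted effect (>= 0; 0 = null).
#' @param noise_sd SD of multiplicative log-normal noise on gene means.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list with `expr` (`ExpressionMatrix`, raw counts), `annotations`
#'   (`SpotAnnotations` with domain and pseudo_order), `weights`
#'   (`CellTypeWeights`), `lr_db` (`LRDatabase`, planted + decoys) and
#'   `truth` (`SyntheticTruth` list: `planted_coloc_pairs`, `planted_lr`,
#'   `decoy_lr`, `planted_gradient_genes`, `planted_domain_markers`,
#'   `gene_baseline`, `params`).
#' @export
simulate_spatial_atlas <- function(n_sections = 4L, grid = c(8L, 8L),
                                   n_types = 6L, n_genes = 100L,
                                   n_coloc_pairs = 2L, n_lr_decoy = 12L,
                                   n_gradient_per_interval = 0L,
                                   n_domain_markers = 0L,
                                   effect_size = 2, noise_sd = 0.3,
                                   dispersion = 2, seed = 1L) {
  stopifnot(n_sections >= 1L, length(grid) == 2L, n_types >= 4L,
            effect_size >= 0, noise_sd >= 0, dispersion > 0)
  if (prod(grid) < 50L) stop("grid must yield at least 50 spots per section")
  if (n_coloc_pairs > floor(n_types / 2)) {
    stop("infeasible planting: ", n_coloc_pairs,
         " disjoint pairs need at least ", 2L * n_coloc_pairs, " cell types")
  }
  with_seed(seed, {
    nx <- as.integer(grid[1L]); ny <- as.integer(grid[2L])
    coords <- expand.grid(array_x = seq_len(nx), array_y = seq_len(ny),
                          section_index = seq_len(n_sections))
    n_spots <- nrow(coords)
    obs_id <- sprintf("S%d_x%02d_y%02d", coords$section_index,
                      coords$array_x, coords$array_y)
    type_names <- paste0("CT", seq_len(n_types))

    # Spatial domains: horizontal bands spanning all sections; band i hosts
    # planted pair i, the last band is unstructured background.
    n_bands <- n_coloc_pairs + 1L
    band <- as.integer(cut(coords$array_y, breaks = n_bands, labels = FALSE))
    domain <- paste0("Dom", band)

    planted_pairs <- data.frame(
      typeA = type_names[2L * seq_len(n_coloc_pairs) - 1L],
      typeB = type_names[2L * seq_len(n_coloc_pairs)],
      domain = paste0("Dom", seq_len(n_coloc_pairs)),
      stringsAsFactors = FALSE)

    conc <- matrix(0.8, n_spots, n_types, dimnames = list(obs_id, type_names))
    for (i in seq_len(n_coloc_pairs)) {
      inside <- band == i
      conc[inside, c(2L * i - 1L, 2L * i)] <-
        conc[inside, c(2L * i - 1L, 2L * i)] + 6 * effect_size
    }
    g <- matrix(rgamma(n_spots * n_types, shape = conc, rate = 1),
                n_spots, n_types)
    weights <- g / rowSums(g)
    dimnames(weights) <- list(obs_id, type_names)

    # Gene catalogue --------------------------------------------------------
    lig_p <- sprintf("LigP%d", seq_len(n_coloc_pairs))
    rec_p <- sprintf("RecP%d", seq_len(n_coloc_pairs))
    planted_lr <- data.frame(sender = planted_pairs$typeA,
                             receiver = planted_pairs$typeB,
                             pair_id = paste0(lig_p, "_", rec_p),
                             stringsAsFactors = FALSE)
    lig_sub <- as.list(lig_p)
    rec_sub <- as.list(rec_p)
    decoy_ids <- character(0)
    if (n_lr_decoy > 0L) {
      for (j in seq_len(n_lr_decoy)) {
        lj <- sprintf("LigD%d", j)
        # first decoy receptor is heteromeric, to exercise multi-subunit paths
        rj <- if (j == 1L) c("RecD1a", "RecD1b") else sprintf("RecD%d", j)
        lig_sub <- c(lig_sub, list(lj))
        rec_sub <- c(rec_sub, list(rj))
        decoy_ids <- c(decoy_ids, paste(lj, paste(rj, collapse = "_"), sep = "_"))
      }
    }
    pair_ids <- c(planted_lr$pair_id, decoy_ids)
    modes <- rep_len(c("secreted", "contact", "ecm"), length(pair_ids))
    lr_db <- lr_database(pair_id = pair_ids, ligand_subunits = lig_sub,
                         receptor_subunits = rec_sub,
                         pathway = paste0("PW", rep_len(1:5, length(pair_ids))),
                         mode = modes)
    lr_genes <- unique(unlist(c(lig_sub, rec_sub)))

    grad_df <- data.frame(gene = character(0), start_section = integer(0),
                          end_section = integer(0), stringsAsFactors = FALSE)
    if (n_gradient_per_interval > 0L && n_sections >= 3L) {
      pats <- enumerate_section_patterns(n_sections)
      grad_df <- do.call(rbind, lapply(seq_len(nrow(pats)), function(i) {
        data.frame(gene = sprintf("Grad_%d_%d_g%d", pats$start[i], pats$end[i],
                                  seq_len(n_gradient_per_interval)),
                   start_section = pats$start[i], end_section = pats$end[i],
                   stringsAsFactors = FALSE)
      }))
    }

    mark_df <- data.frame(gene = character(0), domain = character(0),
                          stringsAsFactors = FALSE)
    if (n_domain_markers > 0L) {
      mark_df <- do.call(rbind, lapply(seq_len(n_bands), function(b) {
        data.frame(gene = sprintf("Mark_Dom%d_g%d", b, seq_len(n_domain_markers)),
                   domain = paste0("Dom", b), stringsAsFactors = FALSE)
      }))
    }

    n_special <- length(lr_genes) + nrow(grad_df) + nrow(mark_df)
    if (n_genes < n_special + 10L) {
      stop("n_genes too small: need at least ", n_special + 10L,
           " for the planted gene catalogue plus 10 filler genes")
    }
    filler <- sprintf("Gene%03d", seq_len(n_genes - n_special))
    gene_ids <- c(lr_genes, grad_df$gene, mark_df$gene, filler)

    baseline <- stats::setNames(numeric(length(gene_ids)), gene_ids)
    baseline[lr_genes] <- 0.15
    baseline[grad_df$gene] <- 0.6
    baseline[mark_df$gene] <- 0.5
    baseline[filler] <- exp(rnorm(length(filler), mean = 0, sd = 0.5))

    # Mean model -----------------------------------------------------------
    mu <- matrix(baseline, nrow = length(gene_ids), ncol = n_spots,
                 dimnames = list(gene_ids, obs_id))
    for (i in seq_len(n_coloc_pairs)) {
      mu[lig_p[i], ] <- baseline[lig_p[i]] *
        (1 + 10 * effect_size * weights[, planted_lr$sender[i]])
      mu[rec_p[i], ] <- baseline[rec_p[i]] *
        (1 + 10 * effect_size * weights[, planted_lr$receiver[i]])
    }
    if (nrow(grad_df) > 0L) {
      for (i in seq_len(nrow(grad_df))) {
        a <- grad_df$start_section[i]; b <- grad_df$end_section[i]
        inside <- coords$section_index >= a & coords$section_index <= b
        ramp <- numeric(n_spots)
        ramp[inside] <- 1 + (coords$section_index[inside] - a) / max(1L, b - a)
        mu[grad_df$gene[i], ] <- baseline[grad_df$gene[i]] *
          (1 + effect_size * ramp)
      }
    }
    if (nrow(mark_df) > 0L) {
      for (i in seq_len(nrow(mark_df))) {
        inside <- domain == mark_df$domain[i]
        mu[mark_df$gene[i], inside] <- baseline[mark_df$gene[i]] *
          (1 + 3 * effect_size)
      }
    }

    if (noise_sd > 0) {
      mu <- mu * exp(matrix(rnorm(length(mu), -noise_sd^2 / 2, noise_sd),
                            nrow(mu), ncol(mu)))
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = dispersion),
                     nrow(mu), ncol(mu), dimnames = dimnames(mu))
    # guard against empty spots in tiny simulations
    empty <- colSums(counts) == 0
    if (any(empty)) counts[1L, empty] <- 1L

    ord <- order(coords$section_index, coords$array_y, coords$array_x)
    pseudo <- numeric(n_spots)
    pseudo[ord] <- seq_len(n_spots)

    ann <- spot_annotations(obs_id, coords$section_index, coords$array_x,
                            coords$array_y, domain = domain,
                            pseudo_order = pseudo)
    truth <- structure(list(
      planted_coloc_pairs = planted_pairs,
      planted_lr = planted_lr,
      decoy_lr = decoy_ids,
      planted_gradient_genes = grad_df,
      planted_domain_markers = mark_df,
      gene_baseline = baseline,
      params = list(n_types = n_types, type_names = type_names,
                    effect_size = effect_size, noise_sd = noise_sd,
                    dispersion = dispersion, n_sections = n_sections)),
      class = "SyntheticTruth")

    st_log("simulate_spatial_atlas: %d spots, %d genes, %d types, %d planted pairs, effect=%g",
           n_spots, length(gene_ids), n_types, n_coloc_pairs, effect_size)
    list(expr = expression_matrix(counts, layer = "raw_counts"),
         annotations = ann,
         weights = cell_type_weights(weights),
         lr_db = lr_db, truth = truth)
  })
}

#' Simulate reference single cells consistent with an atlas truth
#'
#' Per cell type and gene, counts are negative-binomial around the atlas
#' gene baselines; planted ligand subunits are elevated in the sender type
#' and receptor subunits in the receiver type by a fold of
#' `1 + lr_fold * effect_size`.
#'
#' @param truth A `SyntheticTruth` from [simulate_spatial_atlas()].
#' @param n_cells_per_type Cells per type.
#' @param effect_size Defaults to the atlas effect size.
#' @param lr_fold Fold gain per unit effect size for planted subunits.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return A list with `expr` (`ExpressionMatrix`, raw counts, cells as
#'   observations) and `labels` (character cell-type labels per cell).
#' @export
simulate_reference_cells <- function(truth, n_cells_per_type = 40L,
                                     effect_size = NULL, lr_fold = 4,
                                     dispersion = 2, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"), n_cells_per_type >= 1L)
  effect_size <- effect_size %||% truth$params$effect_size
  with_seed(seed, {
    types <- truth$params$type_names
    genes <- names(truth$gene_baseline)
    mu_type <- matrix(truth$gene_baseline, nrow = length(genes),
                      ncol = length(types), dimnames = list(genes, types))
    if (nrow(truth$planted_lr) > 0L) {
      for (i in seq_len(nrow(truth$planted_lr))) {
        pid <- truth$planted_lr$pair_id[i]
        parts <- strsplit(pid, "_", fixed = TRUE)[[1L]]
        lig <- parts[1L]; rec <- parts[-1L]
        mu_type[lig, truth$planted_lr$sender[i]] <-
          mu_type[lig, truth$planted_lr$sender[i]] * (1 + lr_fold * effect_size)
        mu_type[rec, truth$planted_lr$receiver[i]] <-
          mu_type[rec, truth$planted_lr$receiver[i]] * (1 + lr_fold * effect_size)
      }
    }
    labels <- rep(types, each = n_cells_per_type)
    cell_id <- sprintf("cell_%s_%03d", labels,
                       rep(seq_len(n_cells_per_type), times = length(types)))
    mu <- mu_type[, labels, drop = FALSE]
    counts <- matrix(rnbinom(length(mu), mu = mu, size = dispersion),
                     nrow(mu), ncol(mu), dimnames = list(genes, cell_id))
    empty <- colSums(counts) == 0
    if (any(empty)) counts[1L, empty] <- 1L
    st_log("simulate_reference_cells: %d cells x %d genes over %d types",
           ncol(counts), nrow(counts), length(types))
    list(expr = expression_matrix(counts, layer = "raw_counts"),
         labels = labels)
  })
}

#' Simulate regulon activity with planted domain specificity
#'
#' For each unique domain label, `n_per_domain` planted regulons receive
#' activity `specificity * indicator + noise` (clipped to \[0, 1\]);
#' decoys fluctuate around a low baseline. `specificity = 1, noise_sd = 0`
#' gives the exact domain indicator; `specificity = 0` is a null.
#'
#' @param domains Character vector of domain labels, one per spot
#'   (names, if present, become spot ids).
#' @param n_per_domain Planted regulons per domain.
#' @param n_decoy Decoy regulons.
#' @param specificity Planted in-domain activity level, in \[0, 1\].
#' @param noise_sd Gaussian noise SD.
#' @param baseline Decoy baseline activity.
#' @param seed Integer seed.
#' @return A list with `ras` (spots x regulons matrix in \[0, 1\]) and
#'   `truth` (data frame `regulon`, `domain`; decoys have domain `NA`).
#' @export
simulate_regulon_activity <- function(domains, n_per_domain = 1L,
                                      n_decoy = 6L, specificity = 0.8,
                                      noise_sd = 0.05, baseline = 0.05,
                                      seed = 1L) {
  stopifnot(specificity >= 0, specificity <= 1, noise_sd >= 0)
  with_seed(seed, {
    n <- length(domains)
    spot_ids <- names(domains) %||% sprintf("spot_%04d", seq_len(n))
    doms <- unique(domains)
    cols <- list(); truth_rows <- list()
    for (d in doms) {
      ind <- as.numeric(domains == d)
      for (k in seq_len(n_per_domain)) {
        nm <- sprintf("Reg_%s_%d", d, k)
        cols[[nm]] <- .clip01(specificity * ind +
                                if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
        truth_rows[[nm]] <- data.frame(regulon = nm, domain = d,
                                       stringsAsFactors = FALSE)
      }
    }
    for (k in seq_len(n_decoy)) {
      nm <- sprintf("RegDecoy%d", k)
      cols[[nm]] <- .clip01(baseline +
                              if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
      truth_rows[[nm]] <- data.frame(regulon = nm, domain = NA_character_,
                                     stringsAsFactors = FALSE)
    }
    ras <- do.call(cbind, cols)
    rownames(ras) <- spot_ids
    list(ras = ras, truth = do.call(rbind, truth_rows))
  })
}

#' Simulate axis-patterned regulon activity
#'
#' Planted regulons ramp monotonically along a pseudo-space ordering
#' (alternating increasing/decreasing); decoys are flat at a low baseline.
#'
#' @param pseudo_order Numeric pseudo-space order, one value per spot.
#' @param n_planted,n_decoy Numbers of planted and decoy regulons.
#' @param max_ras Peak activity of planted regulons.
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return A list with `ras` (spots x regulons) and `planted` (names).
#' @export
simulate_axis_regulons <- function(pseudo_order, n_planted = 3L,
                                   n_decoy = 17L, max_ras = 0.9,
                                   noise_sd = 0.05, seed = 1L) {
  with_seed(seed, {
    n <- length(pseudo_order)
    x <- (rank(pseudo_order, ties.method = "first") - 1) / max(1L, n - 1L)
    cols <- list()
    for (j in seq_len(n_planted)) {
      xx <- if (j %% 2L == 0L) 1 - x else x
      cols[[sprintf("AxReg%d", j)]] <-
        .clip01(0.05 + (max_ras - 0.05) * xx + rnorm(n, 0, noise_sd))
    }
    for (j in seq_len(n_decoy)) {
      cols[[sprintf("AxDecoy%d", j)]] <- .clip01(0.1 + rnorm(n, 0, noise_sd))
    }
    ras <- do.call(cbind, cols)
    rownames(ras) <- names(pseudo_order) %||% sprintf("spot_%04d", seq_len(n))
    list(ras = ras, planted = sprintf("AxReg%d", seq_len(n_planted)))
  })
}

#' Simulate a complete fixture set by preset
#'
#' `"coloc-demo"` plants colocalized pairs and ligand-receptor signal at
#' the default effect size; `"null"` uses the same sizes with
#' `effect_size = 0`; `"gradient"` adds monotone gradient genes on every
#' consecutive section interval of a 6-section atlas (8 genes per interval)
#' plus domain markers.
#'
#' @param preset One of `"coloc-demo"`, `"null"`, `"gradient"`.
#' @param seed Integer seed.
#' @param n_cells_per_type Reference cells per type.
#' @return The [simulate_spatial_atlas()] list, plus `ref_expr` and
#'   `ref_labels` from [simulate_reference_cells()].
#' @export
simulate_preset <- function(preset = c("coloc-demo", "null", "gradient"),
                            seed = 1L, n_cells_per_type = 40L) {
  preset <- match.arg(preset)
  sim <- switch(preset,
    "coloc-demo" = simulate_spatial_atlas(seed = seed),
    "null" = simulate_spatial_atlas(effect_size = 0, seed = seed),
    "gradient" = simulate_spatial_atlas(n_sections = 6L, grid = c(8L, 7L),
                                        n_genes = 240L,
                                        n_gradient_per_interval = 8L,
                                        n_domain_markers = 10L, seed = seed))
  ref <- simulate_reference_cells(sim$truth,
                                  n_cells_per_type = n_cells_per_type,
                                  seed = seed + 1L)
  sim$ref_expr <- ref$expr
  sim$ref_labels <- ref$labels
  reg <- simulate_regulon_activity(
    stats::setNames(sim$annotations$domain, sim$annotations$obs_id),
    n_per_domain = 2L, n_decoy = 6L, seed = seed + 2L)
  sim$ras <- reg$ras
  sim$truth$planted_domain_regulons <- reg$truth
  sim
}

#' Write a simulated fixture set to disk in the standard formats
#'
#' Writes the spot matrix as a MatrixMarket triplet, annotations and
#' weights as TSV, the ligand-receptor database as TSV, the reference
#' cells as a triplet under `ref/` with a label TSV, and the planted truth
#' as YAML.
#'
#' @param sim Output of [simulate_preset()] (or of the individual
#'   generators, assembled into the same list shape).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$expr, dir)
  write_spot_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  write_cell_type_weights(sim$weights, file.path(dir, "weights.tsv"))
  write_lr_database(sim$lr_db, file.path(dir, "lr_database.tsv"))
  if (!is.null(sim$ref_expr)) {
    write_count_matrix(sim$ref_expr, file.path(dir, "ref"))
    write.table(data.frame(obs_id = colnames(sim$ref_expr),
                           label = sim$ref_labels),
                file.path(dir, "ref_labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$ras)) {
    write.table(data.frame(obs_id = rownames(sim$ras),
                           as.data.frame(sim$ras), check.names = FALSE),
                file.path(dir, "ras.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tr <- sim$truth
  yaml::write_yaml(list(
    planted_coloc_pairs = tr$planted_coloc_pairs,
    planted_lr = tr$planted_lr,
    decoy_lr = tr$decoy_lr,
    planted_gradient_genes = tr$planted_gradient_genes,
    planted_domain_regulons = tr$planted_domain_regulons,
    params = tr$params), file.path(dir, "truth.yaml"))
  invisible(dir)
}
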