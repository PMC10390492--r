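test_that("co-expression scores follow R_LR = L(exp) * R(exp)", {
  vals <- rbind(Lig1 = c(2, 0, 1), Rec1 = c(3, 5, 1),
                Lig2 = c(2, 2, 2), RecA = c(1, 1, 0), RecB = c(4, 4, 4))
  colnames(vals) <- c("s1", "s2", "s3")
  m <- toy_lognorm(vals)
  db <- lr_database(pair_id = c("P1", "P2", "Pmissing"),
                    ligand_subunits = list("Lig1", "Lig2", "LigAbsent"),
                    receptor_subunits = list("Rec1", c("RecA", "RecB"), "Rec1"),
                    pathway = c("W", "W", "W"),
                    mode = c("secreted", "contact", "secreted"))
  co <- coexpression_scores(m, db)
  # single-subunit pair: plain product
  expect_equal(co["s1", "P1"], 6)
  # zero ligand side -> zero score
  expect_equal(co["s2", "P1"], 0)
  # geometric mean over receptor subunits (1, 4) -> 2; times ligand 2 -> 4
  expect_equal(co["s1", "P2"], 4)
  # zero receptor subunit zeroes the geometric mean
  expect_equal(co["s3", "P2"], 0)
  # missing-subunit pair skipped
  expect_identical(colnames(co), c("P1", "P2"))
  expect_true(all(co >= 0))
  # arithmetic-min aggregation option
  co_min <- coexpression_scores(m, db, aggregate = "min")
  expect_equal(co_min["s1", "P2"], 2 * 1)
  # nothing usable -> error
  db_bad <- db[3, ]
  expect_error(coexpression_scores(m, db_bad), "no LR pair")
})

test_that("one-sided Fisher test matches enumeration on printed examples", {
  expect_equal(fisher_exact_greater(3, 1, 1, 3)$p, 17 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_greater(0, 0, 0, 0)$p, 1)
  expect_equal(fisher_exact_greater(5, 0, 0, 5)$p, 1 / 252, tolerance = 1e-12)
  # odds-ratio conventions
  res <- fisher_exact_greater(c(2, 3, 0), c(1, 0, 0), c(1, 2, 0), c(2, 5, 4))
  expect_equal(res$odds_ratio[1], 4)
  expect_identical(res$odds_ratio[2], Inf)
  expect_true(is.nan(res$odds_ratio[3]))
  expect_error(fisher_exact_greater(-1, 0, 0, 0), "nonnegative")
})

test_that("Fisher p equals the hypergeometric oracle on a dense small grid", {
  tabs <- expand.grid(a = 0:6, b = 0:6, c = 0:6, d = 0:6)
  tabs <- tabs[rowSums(tabs) <= 18, ]
  p_impl <- fisher_exact_greater(tabs$a, tabs$b, tabs$c, tabs$d)$p
  p_or <- mapply(oracle_fisher_greater, tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(p_impl, p_or, tolerance = 1e-12)
  # spot-check against the standard implementation too
  for (i in sample(nrow(tabs), 25)) {
    ft <- fisher.test(matrix(as.numeric(tabs[i, ]), 2, 2, byrow = TRUE),
                      alternative = "greater")
    expect_equal(p_impl[i], ft$p.value, tolerance = 1e-9)
  }
})

test_that("perfectly nested co-expression gives the closed-form p", {
  n_spots <- 40L
  spots <- sprintf("s%02d", 1:n_spots)
  x <- c(rep(TRUE, 10), rep(FALSE, 30))
  occ <- structure(matrix(c(x, x), n_spots, 2,
                          dimnames = list(spots, c("A", "B"))),
                   class = c("BooleanOccupancy", "matrix"))
  co <- structure(matrix(as.numeric(x), n_spots, 1,
                         dimnames = list(spots, "P1")),
                  class = c("CoexpressionScores", "matrix"))
  net <- data.frame(typeA = "A", typeB = "B", pcc = 0.5, p = 1e-5,
                    q = 1e-5, kept = TRUE)
  class(net) <- c("ColocalizationNetwork", "data.frame")
  enr <- spatial_lr_enrichment(occ, co, net)
  expect_equal(unlist(enr[1, c("a", "b", "c", "d")]),
               c(a = 10, b = 0, c = 0, d = 30))
  expect_equal(enr$p, 1 / choose(40, 10), tolerance = 1e-12)
  expect_true(enr$enriched)
  expect_equal(enr$a + enr$b + enr$c + enr$d, n_spots)
})

test_that("an edgeless network yields an empty enrichment table", {
  sim <- simulate_spatial_atlas(seed = 6)
  ln <- lognormalize(sim$expr)
  co <- coexpression_scores(ln, sim$lr_db)
  occ <- binarize_weights(sim$weights)
  net <- colocalization_network(pairwise_pcc(sim$weights))
  net$kept <- FALSE
  enr <- spatial_lr_enrichment(occ, co, net)
  expect_s3_class(enr, "EnrichmentTable")
  expect_identical(nrow(enr), 0L)
})

test_that("enrichment verdicts are invariant to spot relabeling", {
  sim <- simulate_spatial_atlas(seed = 8)
  ln <- lognormalize(sim$expr)
  co <- coexpression_scores(ln, sim$lr_db)
  occ <- binarize_weights(sim$weights)
  net <- colocalization_network(pairwise_pcc(sim$weights))
  enr <- spatial_lr_enrichment(occ, co, net)
  perm <- withr::with_seed(1, sample(nrow(occ)))
  occ_p <- structure(unclass(occ)[perm, , drop = FALSE],
                     class = class(occ))
  co_p <- structure(unclass(co)[perm, , drop = FALSE],
                    class = class(co))
  enr_p <- spatial_lr_enrichment(occ_p, co_p, net)
  key <- function(e) e[order(e$typeA, e$typeB, e$pair_id),
                       c("a", "b", "c", "d", "p", "q", "enriched")]
  expect_equal(key(enr_p), key(enr), ignore_attr = TRUE)
})

test_that("planted LR pairs are spatially enriched, null pairs are not", {
  # recovery on planted structure
  planted_hits <- 0L; planted_total <- 0L
  for (s in 1:10) {
    sim <- simulate_spatial_atlas(seed = 200 + s)
    ln <- lognormalize(sim$expr)
    net <- colocalization_network(pairwise_pcc(sim$weights))
    enr <- spatial_lr_enrichment(binarize_weights(sim$weights),
                                 coexpression_scores(ln, sim$lr_db), net)
    tr <- merge(sim$truth$planted_lr, sim$truth$planted_coloc_pairs,
                by.x = c("sender", "receiver"), by.y = c("typeA", "typeB"))
    for (i in seq_len(nrow(tr))) {
      row <- enr[(enr$typeA == tr$sender[i] & enr$typeB == tr$receiver[i] |
                    enr$typeA == tr$receiver[i] & enr$typeB == tr$sender[i]) &
                   enr$pair_id == tr$pair_id[i], ]
      planted_total <- planted_total + 1L
      if (nrow(row) > 0L && any(row$enriched)) planted_hits <- planted_hits + 1L
    }
  }
  expect_gte(planted_hits / planted_total, 0.95)

  # type-I control under the null preset: enrichment among decoy rows
  rates <- c()
  for (s in 1:15) {
    sim <- simulate_spatial_atlas(effect_size = 0, seed = 500 + s)
    ln <- lognormalize(sim$expr)
    net <- colocalization_network(pairwise_pcc(sim$weights))
    # under the null few edges exist; force the planted-design edges so
    # rows are tested at all
    net$kept <- TRUE
    enr <- spatial_lr_enrichment(binarize_weights(sim$weights),
                                 coexpression_scores(ln, sim$lr_db), net)
    if (nrow(enr) > 0L) rates <- c(rates, mean(enr$enriched))
  }
  se <- sqrt(0.05 * 0.95 / (15 * 14 * 15))  # seeds x pairs x edges
  expect_lte(mean(rates), 0.05 + 3 * se)
})
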