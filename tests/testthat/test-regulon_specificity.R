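test_that("recovery-curve score hits its extremes and the hand oracle", {
  genes <- paste0("g", 1:10)
  # fixed expression vector: descending so ranks equal gene order
  vals <- matrix(10:1, 10, 1, dimnames = list(genes, "s1"))
  m <- toy_lognorm(vals)
  # set occupying exactly the top |s| ranks -> score 1
  expect_equal(unname(auc_recovery_score(m, c("g1", "g2"), top_frac = 0.5)), 1)
  # no set gene within max_rank -> score 0
  expect_equal(unname(auc_recovery_score(m, c("g9", "g10"), top_frac = 0.5)), 0)
  # set {g1, g3}, max_rank 5: explicit cumulative-sum integration
  tiebreak <- withr::with_seed(0, sample.int(10))
  in_set <- genes %in% c("g1", "g3")
  expected <- oracle_auc(vals[, 1], tiebreak, in_set, max_rank = 5)
  expect_equal(unname(auc_recovery_score(m, c("g1", "g3"), top_frac = 0.5,
                                         seed = 0)), expected)
  # hand check of the same case: recovery curve 1,1,2,2,2 over area 1,2,2,2,2
  expect_equal(expected, (1 + 1 + 2 + 2 + 2) / (1 + 2 + 2 + 2 + 2))
  expect_error(auc_recovery_score(m, "absent"), "no genes")
})

test_that("recovery score is invariant to monotone transforms and tie rule is seeded", {
  vals <- withr::with_seed(5, matrix(rpois(600, 2), 60, 10,
    dimnames = list(paste0("g", 1:60), paste0("s", 1:10))))
  m <- expression_matrix(vals)
  set <- paste0("g", c(3, 11, 25, 40))
  base <- auc_recovery_score(m, set, top_frac = 0.1, seed = 2)
  mono <- expression_matrix(sqrt(vals) * 7, layer = "lognorm")
  expect_equal(auc_recovery_score(mono, set, top_frac = 0.1, seed = 2), base)
  # same seed, same ties -> identical; different tiebreak may differ
  expect_identical(auc_recovery_score(m, set, top_frac = 0.1, seed = 2), base)
})

test_that("Jensen-Shannon divergence matches hand-derived values", {
  expect_equal(jensen_shannon_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0, 1)), 1)
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0.5, 0.5)), 0.311278,
               tolerance = 1e-6)
  # symmetric, and equal to the independent from-definition oracle
  p <- c(0.2, 0.3, 0.5); q <- c(0.6, 0.1, 0.3)
  expect_equal(jensen_shannon_divergence(p, q),
               jensen_shannon_divergence(q, p))
  expect_equal(jensen_shannon_divergence(p, q), oracle_jsd(p, q),
               tolerance = 1e-12)
  expect_error(jensen_shannon_divergence(c(-0.1, 1.1), c(0.5, 0.5)),
               "nonnegative")
  expect_error(jensen_shannon_divergence(c(0.5, 0.4), c(0.5, 0.5)), "sum")
})

test_that("RSS is 1 on indicator activity, scale-invariant, and decreasing off-domain", {
  domains <- rep(c("D1", "D2"), each = 20)
  ind <- as.numeric(domains == "D1")
  ras <- cbind(exact = ind, uniform = rep(1, 40))
  rownames(ras) <- sprintf("s%02d", 1:40)
  rss <- regulon_specificity_scores(ras, domains)
  expect_equal(rss["exact", "D1"], 1)
  # uniform activity vs half-cohort indicator: closed form via the oracle
  expect_equal(rss["uniform", "D1"],
               1 - sqrt(oracle_jsd(rep(1 / 40, 40), ind / sum(ind))),
               tolerance = 1e-12)
  # positive scaling leaves RSS unchanged (activity bounded by 1 for c<1)
  ras_scaled <- ras; ras_scaled[, "exact"] <- 0.37 * ind
  expect_equal(regulon_specificity_scores(ras_scaled, domains)["exact", "D1"], 1)
  # activity mass moving outside the domain decreases RSS monotonically
  leak <- vapply(c(0, 0.2, 0.4, 0.6), function(t) {
    act <- (1 - t) * ind + t * (1 - ind)
    regulon_specificity_scores(cbind(r = act), domains)["r", "D1"]
  }, numeric(1))
  expect_true(all(diff(leak) < 0))
  expect_true(all(rss >= 0 & rss <= 1))
  expect_error(regulon_specificity_scores(ras, rep(NA_character_, 40)),
               "unknown")
})

test_that("CSI matches its definition and the brute-force oracle", {
  # two mutually strongest partners among N regulons -> (N - 2) / N
  n_spots <- 200
  base <- withr::with_seed(9, {
    f <- runif(n_spots)
    cbind(A = .99 * f + 0.005, B = .97 * f + 0.01,
          C = runif(n_spots), D = runif(n_spots), E = runif(n_spots))
  })
  base <- pmin(pmax(base, 0), 1)
  csi <- connection_specificity_index(base)
  expect_equal(csi["A", "B"], (5 - 2) / 5)
  expect_equal(csi, t(csi))
  expect_equal(unname(diag(csi)), rep(1, 5))
  # the pair with the row-minimum correlation has CSI 0
  P <- cor(base)
  amin <- which(P["A", ] == min(P["A", ]))
  expect_equal(unname(csi["A", amin]), 0)

  # seeded instances up to 10 regulons: exact match to the triple loop
  for (s in 1:5) {
    ras <- withr::with_seed(s, matrix(runif(50 * 8), 50, 8,
      dimnames = list(NULL, paste0("R", 1:8))))
    expect_equal(unclass(connection_specificity_index(ras)), oracle_csi(ras),
                 tolerance = 1e-12)
  }
  expect_error(connection_specificity_index(base[, 1:2]), "at least 3")
})

test_that("planted CSI blocks are recovered as modules", {
  domains <- rep(c("D1", "D2"), each = 100)
  sim <- simulate_regulon_activity(domains, n_per_domain = 5, n_decoy = 0,
                                   specificity = 0.7, seed = 21)
  csi <- connection_specificity_index(sim$ras)
  mods <- regulon_modules(csi, n_modules = 2)
  truth <- sim$truth$domain[match(names(mods), sim$truth$regulon)]
  expect_equal(mclust::adjustedRandIndex(mods, truth), 1)
  # module means: a single-member module equals that member's column
  one <- regulon_modules(csi, n_modules = 9)
  mm <- module_mean_activity(sim$ras, one)
  singles <- names(table(one))[table(one) == 1]
  for (k in singles) {
    member <- names(one)[one == as.integer(k)]
    expect_equal(unname(mm[, paste0("M", k)]), unname(sim$ras[, member]))
  }
  expect_error(regulon_modules(csi, n_modules = 1), "n_modules")
})

test_that("CSI network edges use a strict threshold", {
  csi <- matrix(0.85, 4, 4, dimnames = list(paste0("R", 1:4), paste0("R", 1:4)))
  diag(csi) <- 1
  expect_identical(nrow(csi_network_edges(csi, threshold = 0.85)), 0L)
  csi["R1", "R2"] <- csi["R2", "R1"] <- 0.86
  edges <- csi_network_edges(csi, threshold = 0.85)
  expect_identical(nrow(edges), 1L)
  expect_identical(edges$regulonA, "R1")
})

test_that("planted regulons attain their argmax RSS in the planted domain", {
  hits <- 0L; total <- 0L
  for (s in 1:25) {
    domains <- rep(paste0("D", 1:3), times = c(70, 70, 60))
    sim <- simulate_regulon_activity(domains, specificity = 0.5,
                                     n_decoy = 4, seed = 3000 + s)
    rss <- regulon_specificity_scores(sim$ras, domains)
    planted <- sim$truth[!is.na(sim$truth$domain), ]
    am <- colnames(rss)[max.col(rss[planted$regulon, , drop = FALSE])]
    hits <- hits + sum(am == planted$domain)
    total <- total + nrow(planted)
  }
  expect_gte(hits / total, 0.95)
})
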