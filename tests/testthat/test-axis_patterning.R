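test_that("section-pattern enumeration matches the combinatorial count", {
  # 9 ordered sections with default bounds: the 35 consecutive combinations
  p9 <- enumerate_section_patterns(9)
  expect_identical(nrow(p9), 35L)
  # 3 sections: exactly (1,2) and (2,3)
  p3 <- enumerate_section_patterns(3)
  expect_identical(nrow(p3), 2L)
  expect_equal(p3$start, c(1, 2))
  expect_equal(p3$end, c(2, 3))
  # 4 sections: 3 + 2 = 5
  expect_identical(nrow(enumerate_section_patterns(4)), 5L)
  # closed form sum(n - len + 1) vs brute-force enumeration, n in [3, 15]
  for (n in 3:15) {
    lens <- 2:(n - 1)
    expect_identical(nrow(enumerate_section_patterns(n)),
                     as.integer(sum(n - lens + 1)))
    brute <- sum(vapply(seq_len(n), function(a)
      sum(vapply(seq_len(n), function(b)
        b - a + 1 >= 2 && b - a + 1 <= n - 1, logical(1))), numeric(1)))
    expect_identical(nrow(enumerate_section_patterns(n)), as.integer(brute))
  }
  expect_error(enumerate_section_patterns(5, min_len = 4, max_len = 3),
               "min_len")
  # every pattern is one contiguous run with admissible length
  pm <- section_pattern_matrix(p9, 9)
  runs <- apply(pm, 2, function(v) sum(diff(c(0, v, 0)) == 1))
  expect_true(all(runs == 1))
  expect_true(all(colSums(pm) >= 2 & colSums(pm) <= 8))
})

test_that("a perfect pattern indicator gene is top-ranked and selected", {
  sim <- simulate_spatial_atlas(n_sections = 4, seed = 50)
  ln <- lognormalize(sim$expr)
  vals <- unclass(ln)
  sec <- sim$annotations$section_index
  # plant a noiseless indicator for sections 2-3 into an existing gene
  vals["Gene001", ] <- as.numeric(sec %in% 2:3)
  m2 <- expression_matrix(vals, layer = "lognorm")
  tab <- ap_pattern_genes(m2, sim$annotations,
                          candidate_genes = rownames(vals), top_k = 5)
  row <- tab[tab$gene == "Gene001" & tab$pattern_id == "P2_3", ]
  expect_identical(row$rank, 1L)
  expect_true(row$selected)
  expect_equal(row$pcc, max(tab$pcc[tab$pattern_id == "P2_3"]))
  expect_true("Gene001" %in% attr(tab, "selected_genes"))
  # top_k beyond the candidate count selects all candidates, no error
  tab2 <- ap_pattern_genes(m2, sim$annotations,
                           candidate_genes = c("Gene001", "Gene002"),
                           top_k = 50)
  expect_setequal(attr(tab2, "selected_genes"), c("Gene001", "Gene002"))
})

test_that("pattern gene selection is invariant to spot order", {
  sim <- simulate_preset("gradient", seed = 51, n_cells_per_type = 5)
  ln <- lognormalize(sim$expr)
  cand <- c(sim$truth$planted_gradient_genes$gene,
            grep("^Gene", rownames(ln), value = TRUE))
  tab <- ap_pattern_genes(ln, sim$annotations, cand)
  perm <- withr::with_seed(2, sample(ncol(ln)))
  ln_p <- expression_matrix(unclass(ln)[, perm], layer = "lognorm")
  tab_p <- ap_pattern_genes(ln_p, sim$annotations, cand)
  expect_identical(attr(tab, "selected_genes"), attr(tab_p, "selected_genes"))
  expect_equal(tab$pcc, tab_p$pcc, tolerance = 1e-12)
})

test_that("score binarization zeroes sub-threshold spots", {
  # spike at > 3 SD survives a z-floor of 2.5; background is zeroed
  v <- c(rep(0.1, 97), 0.9, 0.9, 0.9)
  scores <- cbind(region = v)
  z <- (v - mean(v)) / sd(v)
  out <- binarize_scores(scores, method = "zscore", z_min = 2.5)
  expect_true(all(out[z >= 2.5, 1] > 0))
  expect_true(all(out[z < 2.5, 1] == 0))
  expect_error(binarize_scores(cbind(x = rep(1, 5)), method = "zscore"),
               "zero-variance")
  # bimodal split separates two clear groups at their midpoint
  v2 <- c(rep(0.1, 50), rep(0.8, 50))
  out2 <- binarize_scores(cbind(x = v2), method = "bimodal")
  expect_true(all(out2[v2 == 0.1, 1] == 0))
  expect_true(all(out2[v2 == 0.8, 1] == 0.8))
  # degenerate distribution passes through with a warning
  expect_warning(out3 <- binarize_scores(cbind(x = rep(0.3, 8)),
                                         method = "bimodal"),
                 "degenerate")
  expect_equal(out3[, 1], rep(0.3, 8), ignore_attr = TRUE)
})

test_that("planted region bands are recovered by gene-set scores", {
  hits <- 0; total <- 0
  for (s in 1:8) {
    sim <- simulate_spatial_atlas(n_domain_markers = 10, n_genes = 150,
                                  seed = 1200 + s)
    ln <- lognormalize(sim$expr)
    mk <- sim$truth$planted_domain_markers
    sigs <- signature_collection(split(mk$gene, mk$domain))
    sc <- region_activity_scores(ln, sigs)
    argmax <- colnames(sc)[max.col(sc)]
    hits <- hits + sum(argmax == sim$annotations$domain)
    total <- total + nrow(sc)
  }
  expect_gte(hits / total, 0.9)
})

test_that("rank-sum test matches enumeration exactly on small tie-free inputs", {
  # printed example: x = (1,2), y = (3,4), one-sided less -> 1/6
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), "less")$p, 1 / 6,
               tolerance = 1e-12)
  # identical samples: two-sided p = 1 on the approximation path (ties)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # exhaustive tie-free grid with combined n <= 8, all alternatives
  for (n_tot in 4:8) {
    for (nx in 2:(n_tot - 2)) {
      subsets <- utils::combn(n_tot, nx)
      take <- seq(1, ncol(subsets), by = max(1, ncol(subsets) %/% 12))
      for (jj in take) {
        x <- subsets[, jj]
        y <- setdiff(seq_len(n_tot), x)
        for (alt in c("two.sided", "less", "greater")) {
          expect_equal(wilcoxon_rank_sum(x, y, alt)$p,
                       oracle_wilcox_enum(x, y, alt),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("rank-sum approximation is close to enumeration at n = 10", {
  for (s in 1:10) {
    z <- withr::with_seed(6000 + s, rnorm(10))
    x <- z[1:5]; y <- z[6:10]
    exact_p <- oracle_wilcox_enum(x, y)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_lt(abs(wt$p.value - exact_p), 0.02)
  }
})

test_that("DV domain genes recover planted markers and stay null-calibrated", {
  sim <- simulate_spatial_atlas(n_domain_markers = 8, n_genes = 130,
                                seed = 1300)
  ln <- lognormalize(sim$expr)
  labels <- sim$annotations$domain
  res <- dv_domain_genes(ln, labels)
  mk <- sim$truth$planted_domain_markers
  own <- res[paste(res$gene, res$region) %in% paste(mk$gene, mk$domain), ]
  expect_gte(mean(own$selected), 0.9)
  # null: no planted structure -> selection rate within the nominal band
  rates <- vapply(1:12, function(s) {
    simn <- simulate_spatial_atlas(effect_size = 0, seed = 1400 + s)
    lnn <- lognormalize(simn$expr)
    resn <- dv_domain_genes(lnn, simn$annotations$domain)
    mean(resn$selected)
  }, numeric(1))
  n <- 12 * 100 * 3
  expect_lte(mean(rates), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
  expect_error(dv_domain_genes(ln, rep(c("D", "V"), c(ncol(ln) - 2, 2))),
               "at least 3")
})

test_that("axis regulon selection honors both criteria", {
  n <- 200
  ord <- seq_len(n)
  # strictly monotone regulon with high ceiling: selected
  mono <- 0.9 * (ord - 1) / (n - 1)
  # monotone but capped at 0.1: excluded by the max-RAS floor
  weak <- 0.1 * (ord - 1) / (n - 1)
  flat <- withr::with_seed(7, runif(n, 0.05, 0.15))
  ras <- cbind(mono = mono, weak = weak, flat1 = flat,
               flat2 = rev(flat), flat3 = sample(flat))
  rownames(ras) <- sprintf("s%03d", ord)
  sel <- ap_regulon_selection(ras, ord)
  expect_true(sel$selected[sel$regulon == "mono"])
  expect_false(sel$selected[sel$regulon == "weak"])
  expect_equal(sel$pcc[sel$regulon == "mono"], 1, tolerance = 1e-12)

  # DV selection: regulon differential between bands with max above floor
  bands <- rep(c("D", "M", "V"), times = c(70, 70, 60))
  act <- cbind(dv = ifelse(bands == "D", 0.7, 0.1) +
                 withr::with_seed(8, rnorm(n, 0, 0.02)),
               low = ifelse(bands == "D", 0.15, 0.05) +
                 withr::with_seed(9, rnorm(n, 0, 0.01)))
  act <- pmin(pmax(act, 0), 1)
  rownames(act) <- sprintf("s%03d", ord)
  dv <- dv_regulon_selection(act, bands)
  expect_true(any(dv$selected[dv$regulon == "dv"]))
  expect_false(any(dv$selected[dv$regulon == "low"]))  # max RAS <= 0.2
})
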