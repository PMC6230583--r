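test_that("haplotype blocks follow the gap and r2 chaining rule", {
  withr::with_seed(1, {
    col <- sample(c(0L, 2L), 60, replace = TRUE)
    other <- sample(c(0L, 2L), 60, replace = TRUE)
  })
  m <- cbind(m1 = col, m2 = col, m3 = other)
  p <- fix_panel(m, markers = colnames(m))
  map <- tibble::tibble(marker_id = c("m1", "m2", "m3"), chrom = "1A",
                        pos_cM = c(1.3, 1.7, 58.4))
  loci <- build_haplotype_loci(c("m1", "m2", "m3"), p, map,
                               r2_min = 0.7, max_gap_cM = 5)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$members[[1]], c("m1", "m2"))
  expect_equal(loci$members[[2]], "m3")
  expect_equal(loci$locus_id, c("hap_1A_1", "hap_1A_2"))
  expect_equal(loci$cM_start[1], 1.3)
  expect_equal(loci$cM_end[1], 1.7)

  # single selected marker -> singleton zero-length locus
  solo <- build_haplotype_loci("m3", p, map)
  expect_equal(solo$n_markers, 1)
  expect_equal(solo$cM_start, solo$cM_end)

  # 28 consecutive perfectly correlated markers -> one locus of 28
  m28 <- matrix(rep(col, 28), ncol = 28)
  colnames(m28) <- sprintf("x%02d", 1:28)
  p28 <- fix_panel(m28, markers = colnames(m28))
  map28 <- fix_map(colnames(m28), pos = seq(0, by = 1, length.out = 28))
  loci28 <- build_haplotype_loci(colnames(m28), p28, map28)
  expect_equal(nrow(loci28), 1)
  expect_equal(loci28$n_markers, 28)

  expect_error(build_haplotype_loci("ghost", p, map), "ghost")
})

test_that("haplotype calling builds words, pools rare alleles, handles NA", {
  m <- rbind(c(0L, 0L), c(0L, 0L), c(2L, 2L))
  p <- fix_panel(m)
  map <- fix_map(marker_ids(p), pos = c(1, 2))
  loci <- call_haplotypes(build_haplotype_loci(marker_ids(p), p, map,
                                               r2_min = 0, max_gap_cM = 10), p)
  fr <- loci$allele_freq[[1]]
  expect_equal(unname(fr[["00"]]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(fr[["22"]]), 1 / 3, tolerance = 1e-12)

  # rare pooling: an allele at 1/60 < 0.05 becomes RARE
  big <- rbind(matrix(rep(c(0L, 0L), 40), ncol = 2, byrow = TRUE),
               matrix(rep(c(2L, 2L), 19), ncol = 2, byrow = TRUE),
               c(0L, 2L))
  pb <- fix_panel(big)
  lb <- call_haplotypes(build_haplotype_loci(marker_ids(pb), pb,
                                             fix_map(marker_ids(pb), pos = 1:2),
                                             r2_min = 0, max_gap_cM = 10),
                        pb, pool_freq = 0.05)
  expect_true("RARE" %in% names(lb$allele_freq[[1]]))
  expect_equal(sum(lb$allele_freq[[1]]), 1, tolerance = 1e-12)

  # NA member call -> allele "NA"
  m2 <- rbind(c(0L, NA), c(0L, 0L), c(2L, 2L))
  p2 <- fix_panel(m2)
  l2 <- call_haplotypes(build_haplotype_loci(marker_ids(p2), p2,
                                             fix_map(marker_ids(p2), pos = 1:2),
                                             r2_min = 0, max_gap_cM = 10), p2)
  expect_equal(unname(l2$calls[[1]][1]), "NA")
})

test_that("kinship matrix: duplicates, antipodal pairs, subpop structure", {
  withr::with_seed(2, {
    base <- matrix(sample(c(0L, 2L), 6 * 50, replace = TRUE), 6, 50)
  })
  m <- rbind(base, base[1, ], 2L - base[1, ])
  p <- fix_panel(m)
  K <- kinship_matrix(p)
  expect_true(isSymmetric(K, tol = 1e-12))
  # line 7 duplicates line 1: largest off-diagonal entry for that pair
  off <- K; diag(off) <- NA
  expect_equal(unname(which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ]),
               c(7, 1), ignore_attr = TRUE)
  # line 8 is the 0<->2 flip of line 1: most negative entry involves the pair
  mn <- which(off == min(off, na.rm = TRUE), arr.ind = TRUE)
  expect_true(any(apply(mn, 1, function(z) setequal(z, c(1, 8)))))

  sim <- simulate_panel(sim_config(n_subpops = 2, lines_per_subpop = 25,
                                   F_neutral = 0.2, n_markers = 500,
                                   selected_fraction = 0, seed = 3))
  Ks <- kinship_matrix(sim$panel)
  grp <- sim$truth$subpop_of_line$subpop
  same <- outer(grp, grp, "==") & upper.tri(Ks)
  diff <- outer(grp, grp, "!=") & upper.tri(Ks)
  expect_gt(mean(Ks[same]), mean(Ks[diff]))
})

test_that("pairwise r2: identity, flip invariance, independence", {
  withr::with_seed(4, {
    a <- sample(c(0L, 2L), 200, replace = TRUE)
  })
  m <- cbind(a = a, b = a, flip = 2L - a)
  p <- fix_panel(m, markers = colnames(m))
  expect_equal(pairwise_r2(p, "a", "b"), 1)
  expect_equal(pairwise_r2(p, "a", "flip"), 1)
  expect_error(pairwise_r2(p, "a", "zz"), "zz")

  withr::with_seed(5, {
    ind <- matrix(sample(c(0L, 2L), 200 * 100, replace = TRUE), 200, 100)
  })
  pi2 <- fix_panel(ind)
  r2s <- sapply(1:50, function(k) {
    pairwise_r2(pi2, marker_ids(pi2)[2 * k - 1], marker_ids(pi2)[2 * k])
  })
  expect_lt(mean(r2s), 0.05)
})

test_that("BH q-values match hand-computed and brute-force step-up", {
  q <- bh_fdr(c(0.001, 0.01, 0.02, 0.8))
  expect_equal(q, c(0.004, 0.02, 0.02666667, 0.8), tolerance = 1e-6)
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  withr::with_seed(6, {
    for (rep in 1:50) {
      p <- stats::runif(sample(1:40, 1))
      expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("allelic effect is the carrier-vs-population mean difference", {
  y <- c(12, 14, 8, 6)
  expect_equal(allelic_effect(y, c(TRUE, TRUE, FALSE, FALSE)), 3)
  expect_equal(allelic_effect(y, rep(TRUE, 4)), 0)
  y2 <- c(10, 10, 8, 12)
  expect_equal(allelic_effect(y2, c(TRUE, TRUE, FALSE, FALSE)), 0)
})

test_that("MLM with K = identity reproduces the OLS F-test", {
  withr::with_seed(7, {
    n <- 50
    m <- matrix(sample(c(0L, 2L), n * 20, replace = TRUE), n, 20)
    p <- fix_panel(m)
    y <- stats::rnorm(n) + geno_matrix(p)[, 1] / 2
  })
  map <- fix_map(marker_ids(p), pos = 1:20)
  loci <- call_haplotypes(
    build_haplotype_loci(marker_ids(p)[c(1, 5, 9)], p, map,
                         r2_min = 0, max_gap_cM = 0.5), p)
  traits <- tibble::tibble(line_id = p$line_id, y = y)
  I <- diag(n); dimnames(I) <- list(p$line_id, p$line_id)
  got <- mlm_scan(loci, traits, I)
  for (li in seq_len(nrow(loci))) {
    al <- factor(loci$calls[[li]])
    ols <- stats::anova(stats::lm(y ~ al))
    expect_equal(got$p_value[got$locus_id == loci$locus_id[li]],
                 ols$`Pr(>F)`[1], tolerance = 1e-6)
  }
})

test_that("monomorphic or singular loci are skipped, never self-tested", {
  m <- cbind(a = rep(0L, 30), b = rep(c(0L, 2L), 15))
  p <- fix_panel(m, markers = colnames(m))
  map <- fix_map(colnames(m), pos = c(1, 50))
  loci <- call_haplotypes(build_haplotype_loci(colnames(m), p, map), p)
  traits <- tibble::tibble(line_id = p$line_id, y = stats::rnorm(30))
  I <- diag(30); dimnames(I) <- list(p$line_id, p$line_id)
  res <- mlm_scan(loci, traits, I)
  skipped <- attr(res, "skipped")
  expect_true("hap_1A_1" %in% skipped$locus_id)
  expect_false("hap_1A_1" %in% res$locus_id)
  expect_true("hap_1A_2" %in% res$locus_id)
})

test_that("null traits give calibrated lambda and controlled FDR", {
  sim <- simulate_panel(sim_config(n_markers = 450, seed = 9))
  K <- kinship_matrix(sim$panel)
  map <- sim$map
  # 150 singleton loci scattered over the map
  mks <- marker_ids(sim$panel)[seq(1, 450, by = 3)]
  loci <- call_haplotypes(
    build_haplotype_loci(mks, sim$panel, map, r2_min = 1.1, max_gap_cM = 0), sim$panel)
  lambdas <- c(); fps <- c()
  for (s in 1:3) {
    tr <- simulate_traits(sim$panel, NULL, sim_config(h2 = 0.5, seed = 100 + s),
                          traits = "null_trait")
    res <- mlm_scan(loci, tr, K)
    lambdas <- c(lambdas, res$lambda_gc[1])
    fps <- c(fps, mean(res$significant))
  }
  expect_gt(mean(lambdas), 0.8)
  expect_lt(mean(lambdas), 1.2)
  expect_lte(mean(fps), 0.05)
})

test_that("a planted haplotype QTL is recovered with accurate R2", {
  hits <- c(); r2err <- c()
  for (s in 1:5) {
    sim <- simulate_panel(sim_config(n_markers = 300, seed = 200 + s))
    st <- marker_stats(sim$panel)
    mk <- st$marker_id[which.min(abs(st$maf - 0.45))]
    x <- geno_matrix(sim$panel)[, mk] / 2
    # effect sized for ~20% of phenotypic variance
    K <- kinship_matrix(sim$panel)
    cfgt <- sim_config(h2 = 0.6, seed = 300 + s)
    g_bg <- simulate_traits(sim$panel, NULL, cfgt, traits = "bg")$bg
    beta <- sqrt(0.20 * stats::var(g_bg) / (0.8 * 0.6 * stats::var(x)))
    qtl <- tibble::tibble(marker_id = mk, trait = "bg", effect = beta)
    tr <- simulate_traits(sim$panel, qtl, cfgt, traits = "bg")
    truth_r2 <- stats::var(x * beta) / stats::var(tr$bg)
    loci <- call_haplotypes(
      build_haplotype_loci(mk, sim$panel, sim$map), sim$panel)
    res <- mlm_scan(loci, tr, K)
    hits <- c(hits, res$q_value[1] < 0.05)
    r2err <- c(r2err, abs(res$r2[1] - truth_r2))
  }
  expect_gte(mean(hits), 0.8)
  expect_lt(mean(r2err), 0.08)
})
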