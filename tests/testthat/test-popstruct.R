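test_that("Weir-Cockerham theta matches the ANOVA oracle on small instances", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      n1 <- sample(2:5, 1); n2 <- sample(2:5, 1); m <- sample(1:5, 1)
      calls <- matrix(sample(c(0L, 2L), (n1 + n2) * m, replace = TRUE),
                      n1 + n2, m)
      p <- fix_panel(calls)
      asg <- tibble::tibble(line_id = p$line_id,
                            subpop = rep(c("A", "B"), c(n1, n2)))
      got <- wc_fst(p, asg)
      want <- oracle_theta(p, asg)
      if (is.finite(want$theta) && is.finite(got$theta)) {
        expect_equal(got$theta, want$theta, tolerance = 1e-10)
      }
      ok <- is.finite(got$per_locus$theta) & is.finite(want$per_locus)
      expect_equal(got$per_locus$theta[ok], unname(want$per_locus[ok]),
                   tolerance = 1e-10)
    }
  })
})

test_that("fixed opposite alleles give theta = 1; duplicated demes give ~0", {
  m <- matrix(c(rep(0L, 5 * 10), rep(2L, 5 * 10)), 10, 10, byrow = FALSE)
  m <- rbind(matrix(0L, 5, 10), matrix(2L, 5, 10))
  p <- fix_panel(m)
  asg <- tibble::tibble(line_id = p$line_id, subpop = rep(c("A", "B"), each = 5))
  expect_equal(wc_fst(p, asg)$theta, 1)
  expect_equal(pairwise_fst(p, asg)$theta, 1)

  # literally duplicated demes force MSP = 0, so theta sits at its small
  # negative floor (~ -1/nc); no positive differentiation is ever reported
  withr::with_seed(1, {
    half <- matrix(sample(c(0L, 2L), 20 * 1000, replace = TRUE), 20, 1000)
    dup <- rbind(half, half)
  })
  p2 <- fix_panel(dup)
  asg2 <- tibble::tibble(line_id = p2$line_id,
                         subpop = rep(c("A", "B"), each = 20))
  th_dup <- wc_fst(p2, asg2)$theta
  expect_lt(th_dup, 0)
  expect_lt(abs(th_dup), 0.06)
  # a random split of one panmictic sample is the unbiased-zero case
  withr::with_seed(2, {
    pool <- matrix(sample(c(0L, 2L), 40 * 1000, replace = TRUE), 40, 1000)
    lab <- sample(rep(c("A", "B"), each = 20))
  })
  p3 <- fix_panel(pool)
  asg3 <- tibble::tibble(line_id = p3$line_id, subpop = lab)
  expect_lt(abs(wc_fst(p3, asg3)$theta), 0.02)
})

test_that("pairwise theta of 4 demes at F = 0.10 sits in the expected band", {
  means <- sapply(1:5, function(s) {
    sim <- simulate_panel(sim_config(n_subpops = 4, lines_per_subpop = 30,
                                     n_markers = 800, selected_fraction = 0,
                                     seed = s))
    mean(pairwise_fst(sim$panel, sim$truth$subpop_of_line)$theta)
  })
  expect_gt(mean(means), 0.07)
  expect_lt(mean(means), 0.13)
})

test_that("theta is invariant to marker order and deme relabeling", {
  sim <- simulate_panel(sim_config(n_markers = 100, lines_per_subpop = 10, seed = 3))
  asg <- sim$truth$subpop_of_line
  base <- wc_fst(sim$panel, asg)$theta
  shuf <- as_geno_panel(sim$panel[c("line_id",
                                    sample(marker_ids(sim$panel)))])
  expect_equal(wc_fst(shuf, asg)$theta, base)
  relab <- dplyr::mutate(asg, subpop = paste0("Z", subpop))
  expect_equal(wc_fst(sim$panel, relab)$theta, base)
})

test_that("DAPC recovers two well-separated subpopulations", {
  aris <- sapply(1:3, function(s) {
    sim <- simulate_panel(sim_config(n_subpops = 2, lines_per_subpop = 50,
                                     F_neutral = 0.30, n_markers = 1000,
                                     selected_fraction = 0, seed = s))
    st <- dapc_cluster(sim$panel, K_range = 1:5, seed = s)
    expect_equal(st$K, 2)
    truth <- sim$truth$subpop_of_line$subpop
    got <- st$assignment$subpop
    # adjusted Rand index
    tab <- table(truth, got)
    a <- sum(choose(tab, 2)); b <- sum(choose(rowSums(tab), 2))
    cc <- sum(choose(colSums(tab), 2)); n <- sum(tab)
    expected <- b * cc / choose(n, 2)
    (a - expected) / ((b + cc) / 2 - expected)
  })
  expect_gte(min(aris), 0.95)
})

test_that("a panel of identical lines selects K = 1", {
  m <- matrix(rep(c(0L, 2L), each = 20), 4, 10, byrow = TRUE)
  m[] <- rep(c(0L, 2L), length.out = length(m))
  p <- fix_panel(matrix(rep(m[1, ], each = 6), 6, 10))
  st <- dapc_cluster(p, K_range = 1:3, seed = 1)
  expect_equal(st$K, 1)
})

test_that("dapc_cluster is invariant to line and marker order", {
  sim <- simulate_panel(sim_config(n_subpops = 3, lines_per_subpop = 20,
                                   F_neutral = 0.25, n_markers = 400,
                                   selected_fraction = 0, seed = 4))
  st1 <- dapc_cluster(sim$panel, K_range = 2:4, seed = 9)
  perm <- withr::with_seed(1, sample(nrow(sim$panel)))
  shuffled <- as_geno_panel(sim$panel[perm, ])
  st2 <- dapc_cluster(shuffled, K_range = 2:4, seed = 9)
  expect_equal(st2$K, st1$K)
  a1 <- st1$assignment$subpop[match(sim$panel$line_id, st1$assignment$line_id)]
  a2 <- st2$assignment$subpop[match(sim$panel$line_id, st2$assignment$line_id)]
  expect_equal(length(unique(paste(a1, a2))), st1$K)  # identical up to relabeling
  mkperm <- withr::with_seed(2, sample(marker_ids(sim$panel)))
  st3 <- dapc_cluster(as_geno_panel(sim$panel[c("line_id", mkperm)]),
                      K_range = 2:4, seed = 9)
  expect_equal(st3$K, st1$K)
  a3 <- st3$assignment$subpop[match(sim$panel$line_id, st3$assignment$line_id)]
  expect_equal(length(unique(paste(a1, a3))), st1$K)
  expect_error(dapc_cluster(sim$panel, K_range = c(2, 60), seed = 1), "K_range")
})

test_that("AMOVA: maximal structure, percent normalisation, null behaviour", {
  m <- rbind(matrix(0L, 6, 30), matrix(2L, 6, 30))
  p <- fix_panel(m)
  asg <- tibble::tibble(line_id = p$line_id, subpop = rep(c("A", "B"), each = 6))
  res <- amova(p, asg, n_perm = 200, seed = 1)
  expect_gt(res$table$percent[1], 95)
  expect_equal(sum(res$table$percent[1:2]), 100, tolerance = 0.01)
  expect_lt(res$table$p_value[1], 0.05)

  # random split of a panmictic panel: among-percent small, p usually > 0.05
  hits <- sapply(1:10, function(s) {
    withr::with_seed(s, {
      mm <- matrix(sample(c(0L, 2L), 40 * 200, replace = TRUE), 40, 200)
      pp <- fix_panel(mm)
      aa <- tibble::tibble(line_id = pp$line_id,
                           subpop = sample(rep(c("A", "B"), each = 20)))
    })
    r <- amova(pp, aa, n_perm = 199, seed = s)
    c(pct = r$table$percent[1], p = r$table$p_value[1])
  })
  expect_true(mean(hits["pct", ] < 2) >= 0.9)
  expect_true(mean(hits["p", ] > 0.05) >= 0.8)
  expect_error(amova(p, asg, n_perm = 0), "n_perm")
})

test_that("AMOVA permutation p is approximately uniform under the null", {
  ps <- sapply(1:120, function(s) {
    withr::with_seed(1000 + s, {
      mm <- matrix(sample(c(0L, 2L), 24 * 60, replace = TRUE), 24, 60)
      pp <- fix_panel(mm)
      aa <- tibble::tibble(line_id = pp$line_id,
                           subpop = rep(c("A", "B", "C"), each = 8))
    })
    suppressWarnings(amova(pp, aa, n_perm = 99, seed = s)$table$p_value[1])
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("cohort gene diversity: closed forms and planted monotone decline", {
  # identical lines -> pi = 0
  p0 <- fix_panel(matrix(2L, 8, 5))
  co0 <- make_cohorts(tibble::tibble(line_id = p0$line_id,
                                     year_of_entry = rep(c(1950L, 1960L), each = 4)))
  d0 <- diversity_by_cohort(p0, co0, min_n = 2, n_boot = 20, seed = 1)
  expect_equal(d0$pi, c(0, 0))

  # single marker, p = 0.5, n = 4 -> (4/3) * 0.5
  p1 <- fix_panel(matrix(c(0L, 0L, 2L, 2L), 4, 1))
  co1 <- make_cohorts(tibble::tibble(line_id = p1$line_id,
                                     year_of_entry = rep(1950L, 4)))
  d1 <- diversity_by_cohort(p1, co1, min_n = 2, n_boot = 20, seed = 1)
  expect_equal(d1$pi, (4 / 3) * 0.5, tolerance = 1e-12)

  # planted frequencies moving toward fixation -> pi strictly decreasing
  withr::with_seed(7, {
    freqs <- c(0.5, 0.35, 0.2, 0.05)
    calls <- do.call(rbind, lapply(freqs, function(f) {
      matrix(2L * stats::rbinom(40 * 80, 1, f), 40, 80)
    }))
  })
  p2 <- fix_panel(calls)
  co2 <- make_cohorts(tibble::tibble(
    line_id = p2$line_id,
    year_of_entry = rep(c(1950L, 1970L, 1990L, 2010L), each = 40)
  ))
  d2 <- diversity_by_cohort(p2, co2, min_n = 10, n_boot = 20, seed = 2)
  expect_true(all(diff(d2$pi) < 0))

  # cohorts below min_n are skipped with a log entry
  co3 <- co2
  co3$year_of_entry[co3$line_id == p2$line_id[1]] <- 1930L
  co3 <- make_cohorts(co3[, c("line_id", "year_of_entry")])
  d3 <- diversity_by_cohort(p2, co3, min_n = 10, n_boot = 20, seed = 2)
  expect_equal(attr(d3, "skipped"), "1930s")
  expect_equal(nrow(d3), 4)
})
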