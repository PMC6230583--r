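test_that("monomorphic markers are excluded from scans with a log entry", {
  sim <- simulate_panel(sim_config(n_markers = 100, lines_per_subpop = 20,
                                   selected_fraction = 0, seed = 1))
  m <- geno_matrix(sim$panel)
  m[, 1] <- 0L  # force monomorphic
  p <- geno_panel(m)
  fd <- fdist_scan(p, sim$truth$subpop_of_line, n_sim_loci = 2000, seed = 1)
  mono <- marker_ids(p)[1]
  expect_false(mono %in% fd$marker_id)
  expect_true(mono %in% attr(fd, "excluded"))
})

test_that("fdist null calibration keeps the flagged fraction small", {
  fps <- sapply(1:3, function(s) {
    sim <- simulate_panel(sim_config(n_markers = 1000, F_neutral = 0.10,
                                     selected_fraction = 0, seed = s))
    fd <- fdist_scan(sim$panel, sim$truth$subpop_of_line,
                     n_sim_loci = 10000, seed = s)
    mean(fd$flag_fdist)
  })
  expect_lte(mean(fps), 0.03)
})

test_that("fdist envelope calibration recovers the simulation F", {
  sim <- simulate_panel(sim_config(n_markers = 1500, F_neutral = 0.08,
                                   selected_fraction = 0, seed = 5))
  fd <- fdist_scan(sim$panel, sim$truth$subpop_of_line, n_sim_loci = 5000, seed = 2)
  expect_lt(abs(attr(fd, "F_calibrated") - 0.08), 0.03)
})

test_that("fdist flags planted strongly divergent loci", {
  sim <- simulate_panel(sim_config(n_markers = 1010, F_neutral = 0.05,
                                   F_sel = 0.6, selected_fraction = 10 / 1010,
                                   reversal_fraction = 0, seed = 2))
  fd <- fdist_scan(sim$panel, sim$truth$subpop_of_line, n_sim_loci = 10000, seed = 2)
  sel <- fd$marker_id %in% sim$truth$selected_markers
  expect_gte(mean(fd$flag_fdist[sel]), 0.8)
  expect_error(
    fdist_scan(as_geno_panel(sim$panel[, 1:31]), sim$truth$subpop_of_line,
               seed = 1),
    "50 polymorphic"
  )
})

test_that("hier_scan controls the null and reduces to fdist with one group", {
  sim <- simulate_panel(sim_config(n_markers = 1000, selected_fraction = 0,
                                   seed = 3))
  asg <- sim$truth$subpop_of_line
  hs <- hier_scan(sim$panel, asg, n_sim = 10000, seed = 3)
  expect_lte(mean(hs$flag_hier), 0.03)
  # all subpops in one group: the two-level null degenerates to one level
  g1 <- stats::setNames(rep("G1", 4), paste0("SP", 1:4))
  hs1 <- hier_scan(sim$panel, asg, grouping = g1, n_sim = 10000, seed = 3)
  fd <- fdist_scan(sim$panel, asg, n_sim_loci = 10000, seed = 3)
  agree <- mean(hs1$flag_hier == fd$flag_fdist)
  expect_gte(agree, 0.95)
  expect_error(hier_scan(sim$panel, asg,
                         grouping = stats::setNames("G1", "SP1")),
               "grouping")
})

test_that("hier_scan flags planted divergent loci on hierarchical background", {
  sim <- simulate_panel(sim_config(n_markers = 1010, F_neutral = 0.05,
                                   F_sel = 0.6, selected_fraction = 10 / 1010,
                                   reversal_fraction = 0, seed = 4))
  hs <- hier_scan(sim$panel, sim$truth$subpop_of_line, n_sim = 10000, seed = 4)
  sel <- hs$marker_id %in% sim$truth$selected_markers
  expect_gte(mean(hs$flag_hier[sel]), 0.8)
})

test_that("bayes_scan refuses a single deme", {
  sim <- simulate_panel(sim_config(n_subpops = 1, lines_per_subpop = 20,
                                   n_markers = 60, selected_fraction = 0,
                                   seed = 1))
  expect_error(
    bayes_scan(sim$panel, sim$truth$subpop_of_line, bayes_config(seed = 1)),
    "single deme|at least 2"
  )
})

test_that("bayes_scan: strong divergent locus gets high posterior support", {
  sim <- simulate_panel(sim_config(n_markers = 205, F_neutral = 0.05,
                                   F_sel = 0.7, selected_fraction = 5 / 205,
                                   reversal_fraction = 0, seed = 6))
  bc <- bayes_config(n_pilot = 8, pilot_len = 400, n_iter = 8000,
                     sample_size = 800, thinning = 10, seed = 6)
  bs <- bayes_scan(sim$panel, sim$truth$subpop_of_line, bc)
  sel <- bs$marker_id %in% sim$truth$selected_markers
  expect_true(all(bs$alpha_mean[sel] > 0))
  expect_gte(mean(bs$post_prob[sel] > 0.9), 0.8)
  # q-values monotone non-decreasing when ranked by decreasing post_prob
  ord <- order(bs$post_prob, decreasing = TRUE)
  expect_true(all(diff(bs$q_value[ord]) >= -1e-12))
})

test_that("bayes_scan config validation and determinism", {
  expect_error(bayes_config(n_iter = 100, sample_size = 50, thinning = 10),
               "sample_size")
  sim <- simulate_panel(sim_config(n_markers = 80, lines_per_subpop = 15,
                                   selected_fraction = 0, seed = 2))
  bc <- bayes_config(n_pilot = 3, pilot_len = 200, n_iter = 2000,
                     sample_size = 200, thinning = 10, seed = 11)
  b1 <- bayes_scan(sim$panel, sim$truth$subpop_of_line, bc)
  b2 <- bayes_scan(sim$panel, sim$truth$subpop_of_line, bc)
  expect_identical(b1, b2)
})

test_that("consensus_outliers implements the Venn set semantics", {
  mk <- function(ids, flagged) {
    tibble::tibble(marker_id = ids, flag_x = ids %in% flagged)
  }
  # disjoint singletons
  out <- consensus_outliers(m1 = mk(c("a", "b", "c"), "a"),
                            m2 = mk(c("a", "b", "c"), "b"),
                            m3 = mk(c("a", "b", "c"), "c"))
  expect_equal(nrow(out), 3)
  expect_true(all(out$consensus == 1))
  # identical flag sets
  out2 <- consensus_outliers(m1 = mk(c("a", "b"), c("a", "b")),
                             m2 = mk(c("a", "b"), c("a", "b")),
                             m3 = mk(c("a", "b"), c("a", "b")))
  expect_true(all(out2$consensus == 3))
  expect_equal(attr(out2, "venn")[["m1&m2&m3"]], 2L)
  # every flagged marker appears exactly once in the union
  out3 <- consensus_outliers(m1 = mk(letters[1:5], c("a", "b")),
                             m2 = mk(letters[1:5], c("b", "c")))
  expect_equal(sort(out3$marker_id), c("a", "b", "c"))
  expect_equal(anyDuplicated(out3$marker_id), 0)
})

test_that("scans are invariant to marker order", {
  sim <- simulate_panel(sim_config(n_markers = 300, seed = 8))
  asg <- sim$truth$subpop_of_line
  fd1 <- fdist_scan(sim$panel, asg, n_sim_loci = 5000, seed = 2)
  perm <- withr::with_seed(3, sample(marker_ids(sim$panel)))
  fd2 <- fdist_scan(as_geno_panel(sim$panel[c("line_id", perm)]), asg,
                    n_sim_loci = 5000, seed = 2)
  fd2 <- fd2[match(fd1$marker_id, fd2$marker_id), ]
  expect_equal(fd1$theta, fd2$theta)
  expect_equal(fd1$flag_fdist, fd2$flag_fdist)
})
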