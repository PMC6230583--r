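#' @useDynLib breedscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- shared internals ------------------------------------------------------

# Per-locus haploid WC theta components from allele counts.
# x: L x J alt counts, n: L x J sample sizes. Returns tibble(a, b, theta, he).
theta_from_counts <- function(x, n) {
  p_j <- ifelse(n > 0, x / n, NA_real_)
  r <- rowSums(n > 0)
  N <- rowSums(n)
  pbar <- rowSums(x) / N
  ssp <- rowSums(n * (p_j - pbar)^2, na.rm = TRUE)
  ssg <- rowSums(n * p_j * (1 - p_j), na.rm = TRUE)
  msp <- ssp / (r - 1)
  msg <- ssg / (N - r)
  nc <- (N - rowSums(n^2) / N) / (r - 1)
  a <- (msp - msg) / nc
  b <- msg
  tibble::tibble(
    a = a, b = b,
    theta = ifelse(a + b > 0, a / (a + b), NA_real_),
    he = 1 - pbar^2 - (1 - pbar)^2
  )
}

# Simulate neutral Balding-Nichols loci for given deme sizes and return
# theta/he per locus. `p` may be supplied to reuse ancestral draws.
sim_neutral_loci <- function(F, deme_sizes, n_loci, p = NULL) {
  J <- length(deme_sizes)
  if (is.null(p)) p <- stats::runif(n_loci, 0.05, 0.95)
  a0 <- p * (1 - F) / F
  b0 <- (1 - p) * (1 - F) / F
  q <- matrix(stats::rbeta(n_loci * J, rep(a0, J), rep(b0, J)), n_loci, J)
  n <- matrix(rep(deme_sizes, each = n_loci), n_loci, J)
  x <- matrix(stats::rbinom(n_loci * J, as.vector(n), as.vector(q)), n_loci, J)
  theta_from_counts(x, n)
}

# Multilocus theta from per-locus components, trimming the top and bottom
# `trim` fraction of loci by per-locus theta.
trimmed_multilocus_theta <- function(comp, trim = 0.05) {
  ok <- is.finite(comp$theta)
  th <- comp$theta[ok]
  qs <- stats::quantile(th, c(trim, 1 - trim), names = FALSE)
  keep <- which(ok)[th >= qs[1] & th <= qs[2]]
  sum(comp$a[keep]) / sum(comp$a[keep] + comp$b[keep])
}

# Bisection on the simulation F so the simulated multilocus theta matches
# `target` within tol. `simulate` is function(F) -> multilocus theta.
calibrate_F <- function(simulate, target, tol = 0.005, lo = 1e-4, hi = 0.9,
                        max_iter = 25) {
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    val <- simulate(mid)
    if (abs(val - target) <= tol) return(mid)
    if (val < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Allele counts per deme from an inbred panel (haploid counts).
deme_counts <- function(panel, grp) {
  m <- geno_matrix(panel) / 2
  obs <- !is.na(m)
  x0 <- m; x0[!obs] <- 0
  n <- t(rowsum(obs + 0, grp))      # loci x demes sample sizes
  x <- t(rowsum(x0, grp))           # loci x demes alt-allele sums
  list(x = x, n = n)
}

# split loci into polymorphic / monomorphic; returns indices
polymorphic_idx <- function(panel) {
  p <- alt_freq(panel)
  which(p > 0 & p < 1)
}

he_bin_stats <- function(sim, n_bins, quantile) {
  brks <- seq(0, 0.5 + 1e-9, length.out = n_bins + 1)
  bin <- cut(pmin(sim$he, 0.5), breaks = brks, include.lowest = TRUE)
  env <- tapply(sim$theta, bin, stats::quantile, probs = quantile,
                na.rm = TRUE, names = FALSE)
  env <- as.numeric(env)
  # fill empty bins from neighbours, then smooth by running median over 3
  env <- stats::approx(seq_along(env)[!is.na(env)], env[!is.na(env)],
                       xout = seq_along(env), rule = 2)$y
  env <- stats::runmed(env, 3)
  list(breaks = brks, envelope = env, bin_of = function(he) {
    pmin(pmax(findInterval(pmin(he, 0.5), brks, rightmost.closed = TRUE), 1),
         length(env))
  }, sim_bin = bin)
}

# ---- FDIST-style scan ------------------------------------------------------

#' FDIST-style neutral-envelope Fst outlier scan
#'
#' Estimates a neutral multilocus Fst target as the trimmed (5%) multilocus
#' Weir-Cockerham theta, calibrates a Balding-Nichols island-model
#' simulation to that target by bisection, simulates `n_sim_loci` neutral
#' loci matching the deme count and per-deme sample sizes, builds a
#' conditional envelope (the per-He-bin `quantile` of simulated theta,
#' smoothed by a running median over 3 bins), and flags empirical loci whose
#' theta exceeds the envelope AND is at least `fst_cutoff`.
#'
#' Monomorphic markers are excluded with a log entry (attribute
#' `"excluded"`).
#'
#' @param panel a `geno_panel`.
#' @param assignment subpopulation assignment (see [wc_fst()]).
#' @param n_sim_loci simulated neutral loci for the envelope.
#' @param quantile envelope quantile (default 0.99).
#' @param fst_cutoff minimum per-locus theta to declare an outlier.
#' @param n_bins number of He bins (>= 20).
#' @param seed integer seed.
#' @return Tibble with `marker_id`, `he`, `theta`, `envelope`, `p_fdist`
#'   (proportion of same-bin simulated loci with theta >= observed),
#'   `flag_fdist`; calibrated F in attribute `"F_calibrated"`, excluded
#'   monomorphic markers in attribute `"excluded"`.
#' @export
fdist_scan <- function(panel, assignment, n_sim_loci = 50000, quantile = 0.99,
                       fst_cutoff = 0.20, n_bins = 25, seed = 1) {
  stopifnot(n_bins >= 20)
  grp <- droplevels(align_assignment(panel, assignment))
  if (nlevels(grp) < 2) stop("need at least 2 subpopulations")
  poly <- polymorphic_idx(panel)
  excluded <- setdiff(marker_ids(panel), marker_ids(panel)[poly])
  if (length(poly) < 50) stop("fewer than 50 polymorphic markers: envelope unstable")
  sub <- select_markers(panel, marker_ids(panel)[poly])
  wc <- wc_fst(sub, grp)
  comp <- dplyr::mutate(wc$per_locus, a = .data$a, b = .data$b)
  target <- trimmed_multilocus_theta(comp)
  deme_sizes <- as.vector(table(grp))
  n_cal <- min(n_sim_loci, 10000)
  cal_seed <- derive_seed(seed, 1)
  Fhat <- calibrate_F(function(F) {
    withr::with_seed(cal_seed, {
      s <- sim_neutral_loci(F, deme_sizes, n_cal)
      sum(s$a) / sum(s$a + s$b)
    })
  }, target = target)
  sim <- withr::with_seed(derive_seed(seed, 2),
                          sim_neutral_loci(Fhat, deme_sizes, n_sim_loci))
  bins <- he_bin_stats(sim, n_bins, quantile)
  b_obs <- bins$bin_of(comp$he)
  env <- bins$envelope[b_obs]
  sim_bin_idx <- bins$bin_of(sim$he)
  p_fdist <- purrr::map2_dbl(b_obs, comp$theta, function(bi, th) {
    ths <- sim$theta[sim_bin_idx == bi]
    if (length(ths) == 0 || !is.finite(th)) return(NA_real_)
    mean(ths >= th, na.rm = TRUE)
  })
  out <- tibble::tibble(
    marker_id = comp$marker_id, he = comp$he, theta = comp$theta,
    envelope = env, p_fdist = p_fdist,
    flag_fdist = !is.na(comp$theta) & comp$theta > env & comp$theta >= fst_cutoff
  )
  attr(out, "F_calibrated") <- Fhat
  attr(out, "neutral_target") <- target
  attr(out, "excluded") <- excluded
  out
}

# ---- hierarchical island-model scan ---------------------------------------

#' Hierarchical island-model Fst outlier scan
#'
#' Uses a two-level Balding-Nichols null — group frequency ~ BN(ancestral p,
#' F_CT), deme frequency ~ BN(group frequency, F_SC) — with (F_CT, F_SC)
#' calibrated by bisection so the simulated among-group and within-group
#' multilocus theta match the trimmed empirical values. Per locus,
#' `p_hier` is the proportion of simulated loci in the same He bin with
#' total theta >= observed; a locus is flagged when
#' `p_hier <= 1 - quantile` AND `theta >= fst_cutoff`.
#'
#' @inheritParams fdist_scan
#' @param grouping named vector mapping subpopulation to group, or `NULL`
#'   to cut the UPGMA tree of pairwise subpopulation Fst into 2 groups.
#' @param n_sim simulated neutral loci.
#' @return Tibble with `marker_id`, `he`, `theta`, `p_hier`, `flag_hier`;
#'   calibrated `F_CT`/`F_SC` and the grouping in attributes.
#' @export
hier_scan <- function(panel, assignment, grouping = NULL, n_sim = 50000,
                      quantile = 0.99, fst_cutoff = 0.20, n_bins = 25, seed = 1) {
  stopifnot(n_bins >= 20)
  grp <- droplevels(align_assignment(panel, assignment))
  if (nlevels(grp) < 2) stop("need at least 2 subpopulations")
  if (is.null(grouping)) {
    if (nlevels(grp) == 2) {
      grouping <- stats::setNames(levels(grp), levels(grp))
    } else {
      pw <- pairwise_fst(panel, grp)
      d <- stats::as.dist(attr(pw, "matrix"))
      hc <- stats::hclust(d, method = "average")
      grouping <- stats::setNames(paste0("G", stats::cutree(hc, k = 2)), levels(grp))
    }
  }
  if (!all(levels(grp) %in% names(grouping))) {
    stop("grouping must cover every subpopulation")
  }
  group_of <- factor(grouping[as.character(grp)])
  if (nlevels(droplevels(group_of)) < 1) stop("grouping produced zero groups")
  poly <- polymorphic_idx(panel)
  excluded <- setdiff(marker_ids(panel), marker_ids(panel)[poly])
  if (length(poly) < 50) stop("fewer than 50 polymorphic markers: envelope unstable")
  sub <- select_markers(panel, marker_ids(panel)[poly])
  wc <- wc_fst(sub, grp)
  comp <- wc$per_locus
  # empirical calibration targets
  groups <- levels(droplevels(group_of))
  multi_group <- length(groups) >= 2
  t_CT <- if (multi_group) {
    trimmed_multilocus_theta(wc_fst(sub, droplevels(group_of))$per_locus)
  } else NA_real_
  # within-group theta: components summed over groups with >= 2 demes
  within_comp <- purrr::map(groups, function(g) {
    keep <- group_of == g
    if (nlevels(droplevels(grp[keep])) < 2) return(NULL)
    sg <- sub[keep, , drop = FALSE]
    class(sg) <- unique(c("geno_panel", class(sg)))
    wc_fst(sg, droplevels(grp[keep]))$per_locus
  })
  within_comp <- purrr::compact(within_comp)
  if (length(within_comp) == 0) stop("no group contains 2 or more subpopulations")
  t_SC <- {
    pooled <- tibble::tibble(
      a = rowSums(sapply(within_comp, function(x) x$a)),
      b = rowSums(sapply(within_comp, function(x) x$b)),
      theta = rowSums(sapply(within_comp, function(x) x$a)) /
        rowSums(sapply(within_comp, function(x) x$a + x$b))
    )
    trimmed_multilocus_theta(pooled)
  }
  deme_sizes <- as.vector(table(grp))
  deme_group <- factor(grouping[levels(grp)])
  sim_two_level <- function(F_CT, F_SC, n_loci) {
    J <- length(deme_sizes)
    p <- stats::runif(n_loci, 0.05, 0.95)
    G <- nlevels(deme_group)
    qg <- matrix(NA_real_, n_loci, G)
    for (g in seq_len(G)) {
      if (multi_group && F_CT > 0) {
        a0 <- p * (1 - F_CT) / F_CT
        b0 <- (1 - p) * (1 - F_CT) / F_CT
        qg[, g] <- stats::rbeta(n_loci, a0, b0)
      } else qg[, g] <- p
    }
    q <- matrix(NA_real_, n_loci, J)
    for (j in seq_len(J)) {
      pg <- qg[, as.integer(deme_group)[j]]
      a0 <- pg * (1 - F_SC) / F_SC
      b0 <- (1 - pg) * (1 - F_SC) / F_SC
      q[, j] <- stats::rbeta(n_loci, a0, b0)
    }
    n <- matrix(rep(deme_sizes, each = n_loci), n_loci, J)
    x <- matrix(stats::rbinom(n_loci * J, as.vector(n), as.vector(q)), n_loci, J)
    list(x = x, n = n)
  }
  n_cal <- min(n_sim, 10000)
  cal_seed <- derive_seed(seed, 3)
  # calibrate F_SC against within-group theta (does not depend on F_CT)
  F_SC <- calibrate_F(function(F) {
    withr::with_seed(cal_seed, {
      sim <- sim_two_level(0, F, n_cal)
      tot <- 0; wa <- 0
      for (g in seq_len(nlevels(deme_group))) {
        jj <- which(as.integer(deme_group) == g)
        if (length(jj) < 2) next
        cc <- theta_from_counts(sim$x[, jj, drop = FALSE], sim$n[, jj, drop = FALSE])
        wa <- wa + sum(cc$a, na.rm = TRUE)
        tot <- tot + sum(cc$a + cc$b, na.rm = TRUE)
      }
      wa / tot
    })
  }, target = t_SC)
  # calibrate F_CT against among-group theta with F_SC fixed
  F_CT <- if (multi_group) {
    calibrate_F(function(F) {
      withr::with_seed(derive_seed(seed, 4), {
        sim <- sim_two_level(F, F_SC, n_cal)
        gx <- t(rowsum(t(sim$x), deme_group))
        gn <- t(rowsum(t(sim$n), deme_group))
        cc <- theta_from_counts(gx, gn)
        sum(cc$a, na.rm = TRUE) / sum(cc$a + cc$b, na.rm = TRUE)
      })
    }, target = max(t_CT, 1e-3))
  } else 0
  sim <- withr::with_seed(derive_seed(seed, 5), {
    s <- sim_two_level(F_CT, F_SC, n_sim)
    theta_from_counts(s$x, s$n)
  })
  bins <- he_bin_stats(sim, n_bins, quantile)
  b_obs <- bins$bin_of(comp$he)
  sim_bin_idx <- bins$bin_of(sim$he)
  p_hier <- purrr::map2_dbl(b_obs, comp$theta, function(bi, th) {
    ths <- sim$theta[sim_bin_idx == bi]
    if (length(ths) == 0 || !is.finite(th)) return(NA_real_)
    mean(ths >= th, na.rm = TRUE)
  })
  out <- tibble::tibble(
    marker_id = comp$marker_id, he = comp$he, theta = comp$theta,
    p_hier = p_hier,
    flag_hier = !is.na(p_hier) & p_hier <= (1 - quantile) &
      !is.na(comp$theta) & comp$theta >= fst_cutoff
  )
  attr(out, "F_CT") <- F_CT
  attr(out, "F_SC") <- F_SC
  attr(out, "grouping") <- grouping
  attr(out, "excluded") <- excluded
  out
}

# ---- Bayesian genome scan --------------------------------------------------

#' Configuration for the Bayesian genome scan
#'
#' Defaults follow the originally published run lengths (20 pilot runs of
#' 50,000 iterations; 100,000 main iterations retaining 5,000 thinned
#' samples at interval 10) and the customary priors: prior odds 10 for the
#' neutral model, `beta ~ N(-1, 1.8^2)`, `alpha ~ N(0, 1)`. The `"ci"`
#' profile (see [pipeline_config()]) shrinks the run lengths for fast
#' integration testing.
#'
#' @param n_pilot pilot runs.
#' @param pilot_len iterations per pilot.
#' @param n_iter main-chain iterations.
#' @param sample_size retained (thinned) samples.
#' @param thinning thinning interval.
#' @param prior_odds_neutral prior odds in favour of excluding alpha.
#' @param beta_prior length-2 numeric `(mean, sd)` of the deme effect prior.
#' @param alpha_prior_sd sd of the locus effect prior.
#' @param fst_cutoff minimum per-locus Weir-Cockerham theta for flagging.
#' @param seed integer seed.
#' @return A `bayes_config` list.
#' @export
bayes_config <- function(n_pilot = 20, pilot_len = 50000, n_iter = 100000,
                         sample_size = 5000, thinning = 10,
                         prior_odds_neutral = 10, beta_prior = c(-1, 1.8),
                         alpha_prior_sd = 1, fst_cutoff = 0.15, seed = 1) {
  if (sample_size * thinning > n_iter) {
    stop("sample_size x thinning must not exceed n_iter")
  }
  if (any(c(n_pilot, pilot_len, n_iter, sample_size, thinning) < 1)) {
    stop("all counts must be positive")
  }
  out <- list(n_pilot = n_pilot, pilot_len = pilot_len, n_iter = n_iter,
              sample_size = sample_size, thinning = thinning,
              prior_odds_neutral = prior_odds_neutral, beta_prior = beta_prior,
              alpha_prior_sd = alpha_prior_sd, fst_cutoff = fst_cutoff,
              seed = seed)
  class(out) <- "bayes_config"
  out
}

#' Bayesian Fst genome scan (Dirichlet-multinomial, reversible-jump MCMC)
#'
#' Decomposes logit(Fst_ij) into a locus effect alpha_i and a deme effect
#' beta_j; a reversible jump includes or excludes each alpha_i, and the
#' posterior inclusion frequency measures the evidence for locus-specific
#' selection. q-values are the Bayesian FDR: for each locus, the mean
#' posterior error probability (1 - inclusion probability) over all loci
#' with inclusion probability at least as large. A locus is flagged when
#' `q < 0.05`, the posterior mean alpha is positive (divergent selection),
#' and its Weir-Cockerham theta is at least `fst_cutoff`.
#'
#' @param panel a `geno_panel`.
#' @param assignment subpopulation assignment (see [wc_fst()]).
#' @param config a [bayes_config()].
#' @return Tibble with `marker_id`, `he`, `theta`, `alpha_mean`,
#'   `post_prob`, `q_value`, `flag_bayes`; deme effects in attribute
#'   `"beta_mean"`, excluded monomorphic markers in `"excluded"`.
#' @export
bayes_scan <- function(panel, assignment, config = bayes_config()) {
  stopifnot(inherits(config, "bayes_config"))
  grp <- droplevels(align_assignment(panel, assignment))
  if (nlevels(grp) < 2) {
    stop("alpha and beta are unidentifiable with a single deme; ",
         "need at least 2 subpopulations")
  }
  poly <- polymorphic_idx(panel)
  excluded <- setdiff(marker_ids(panel), marker_ids(panel)[poly])
  sub <- select_markers(panel, marker_ids(panel)[poly])
  cnt <- deme_counts(sub, grp)
  wc <- wc_fst(sub, grp)
  fit <- withr::with_seed(config$seed, {
    bayescan_mcmc(
      round(cnt$x), cnt$n,
      n_pilot = config$n_pilot, pilot_len = config$pilot_len,
      n_iter = config$n_iter, sample_size = config$sample_size,
      thinning = config$thinning, prior_odds = config$prior_odds_neutral,
      beta_mu = config$beta_prior[1], beta_sd = config$beta_prior[2],
      alpha_sd = config$alpha_prior_sd
    )
  })
  pp <- fit$post_prob
  q <- bayes_fdr_q(pp)
  out <- tibble::tibble(
    marker_id = marker_ids(sub),
    he = wc$per_locus$he,
    theta = wc$per_locus$theta,
    alpha_mean = fit$alpha_mean,
    post_prob = pp,
    q_value = q,
    flag_bayes = q < 0.05 & fit$alpha_mean > 0 &
      !is.na(wc$per_locus$theta) & wc$per_locus$theta >= config$fst_cutoff
  )
  attr(out, "beta_mean") <- fit$beta_mean
  attr(out, "excluded") <- excluded
  out
}

# Bayesian FDR: q(i) = mean(1 - pp_j) over loci with pp_j >= pp_i.
bayes_fdr_q <- function(pp) {
  ord <- order(pp, decreasing = TRUE)
  pep <- 1 - pp[ord]
  qs <- cumsum(pep) / seq_along(pep)
  # ties share the q of the last tied position
  q_sorted <- rev(cummin(rev(qs)))  # enforce monotone non-decreasing in rank
  q <- numeric(length(pp))
  q[ord] <- q_sorted
  # equal post_prob must share a q-value: take the max within ties
  stats::ave(q, pp, FUN = max)
}

#' Combine outlier flags across scan methods
#'
#' @param ... named scan result tibbles, each with `marker_id` and one
#'   logical `flag_*` column (e.g. the outputs of [fdist_scan()],
#'   [hier_scan()], [bayes_scan()]).
#' @return Tibble with `marker_id`, one logical column per method,
#'   `consensus` (number of methods flagging), restricted to the union of
#'   flagged markers; the Venn partition sizes are in attribute `"venn"`.
#' @export
consensus_outliers <- function(...) {
  scans <- list(...)
  if (length(scans) == 1 && is.list(scans[[1]]) && !is.data.frame(scans[[1]])) {
    scans <- scans[[1]]
  }
  if (is.null(names(scans)) || any(names(scans) == "")) {
    names(scans) <- paste0("method", seq_along(scans))
  }
  flags <- purrr::imap(scans, function(s, nm) {
    fcol <- grep("^flag", names(s), value = TRUE)[1]
    tibble::tibble(marker_id = s$marker_id, !!nm := s[[fcol]])
  })
  merged <- purrr::reduce(flags, dplyr::full_join, by = "marker_id")
  merged <- dplyr::mutate(merged,
                          dplyr::across(-"marker_id", ~ !is.na(.x) & .x))
  merged$consensus <- rowSums(as.matrix(merged[setdiff(names(merged), "marker_id")]))
  out <- dplyr::filter(merged, .data$consensus >= 1)
  pattern <- apply(as.matrix(out[names(scans)]), 1, function(z) {
    paste(names(scans)[z], collapse = "&")
  })
  attr(out, "venn") <- as.list(table(pattern))
  out
}
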