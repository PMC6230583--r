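#' Simulation configuration for synthetic breeding panels
#'
#' Defaults emulate the study conditions of a 60-year inbred durum breeding
#' panel: 192 lines in 4 subpopulations of moderate differentiation
#' (Balding-Nichols F = 0.10, inside the 0.05-0.15 band), thousands of
#' mapped biallelic markers on 14 chromosomes, a minority of loci under
#' divergent selection (locus F = 0.6), and seven decade cohorts
#' (1950s-2010s) in which a subset of selected loci follow directional
#' logistic frequency trajectories up to majority reversal and fixation.
#'
#' @param n_subpops number of subpopulations.
#' @param lines_per_subpop lines per subpopulation (>= 2).
#' @param n_markers number of biallelic markers.
#' @param n_chromosomes number of chromosomes (markers split evenly).
#' @param map_length_cM per-chromosome genetic map length.
#' @param F_neutral background Balding-Nichols differentiation, in (0, 1).
#' @param selected_fraction fraction of markers given locus-specific
#'   differentiation `F_sel`.
#' @param F_sel elevated differentiation for selected loci, in (0, 1).
#' @param reversal_fraction fraction of selected loci that additionally
#'   follow a temporal majority-reversal trajectory.
#' @param n_cohorts number of decade cohorts (first one starts at
#'   `start_year`).
#' @param start_year first cohort's decade start.
#' @param trajectory_slope logistic rate per cohort for reversal loci.
#' @param trajectory_midpoint cohort index of the frequency switch
#'   (default: middle cohort).
#' @param qtl_spec tibble with columns `marker_id`, `trait`, `effect`
#'   (carrier-coded effect in trait units), or `NULL`.
#' @param h2 broad-sense heritability per trait in \[0, 1\] (scalar, or named
#'   by trait).
#' @param trait_pairs list of length-2 character vectors naming trait pairs
#'   whose realized correlation should approach `trait_cor_target`.
#' @param trait_cor_target intended correlation for designated trait pairs.
#' @param polygenic_var variance of the polygenic term (trait units^2); 0
#'   disables the polygenic background.
#' @param missing_rate fraction of genotype calls masked to missing.
#' @param het_rate residual-heterozygosity rate (default 0: inbred lines are
#'   pure 0/2 haploid draws).
#' @param seed integer RNG seed; the same seed reproduces bit-identical
#'   output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subpops = 4, lines_per_subpop = 48, n_markers = 2000,
                       n_chromosomes = 14, map_length_cM = 180,
                       F_neutral = 0.10, selected_fraction = 0.05, F_sel = 0.6,
                       reversal_fraction = 0.25, n_cohorts = 7,
                       start_year = 1950L, trajectory_slope = 2,
                       trajectory_midpoint = (n_cohorts + 1) / 2,
                       qtl_spec = NULL, h2 = 0.6, trait_pairs = NULL,
                       trait_cor_target = 0.8, polygenic_var = 1,
                       missing_rate = 0, het_rate = 0, seed = 1) {
  cfg <- list(
    n_subpops = as.integer(n_subpops), lines_per_subpop = as.integer(lines_per_subpop),
    n_markers = as.integer(n_markers), n_chromosomes = as.integer(n_chromosomes),
    map_length_cM = map_length_cM, F_neutral = F_neutral,
    selected_fraction = selected_fraction, F_sel = F_sel,
    reversal_fraction = reversal_fraction, n_cohorts = as.integer(n_cohorts),
    start_year = as.integer(start_year), trajectory_slope = trajectory_slope,
    trajectory_midpoint = trajectory_midpoint, qtl_spec = qtl_spec, h2 = h2,
    trait_pairs = trait_pairs, trait_cor_target = trait_cor_target,
    polygenic_var = polygenic_var, missing_rate = missing_rate,
    het_rate = het_rate, seed = as.integer(seed)
  )
  with(cfg, {
    if (F_neutral <= 0 || F_neutral >= 1) stop("F_neutral must be in (0, 1)")
    if (F_sel <= 0 || F_sel >= 1) stop("F_sel must be in (0, 1)")
    if (selected_fraction < 0 || selected_fraction > 1) {
      stop("selected_fraction must be in [0, 1]")
    }
    if (any(h2 < 0 | h2 > 1)) stop("h2 must be in [0, 1]")
    if (lines_per_subpop < 2) stop("lines_per_subpop must be >= 2 (Fst undefined below)")
    if (n_subpops < 1 || n_markers < 1 || n_chromosomes < 1 || n_cohorts < 1) {
      stop("all counts must be positive")
    }
    if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a synthetic breeding panel with known truth
#'
#' Ancestral allele frequencies are drawn Uniform(0.05, 0.95). Neutral and
#' (non-reversal) selected markers draw subpopulation frequencies from the
#' Balding-Nichols model `Beta(p (1-F)/F, (1-p)(1-F)/F)` with
#' `F = F_neutral` or `F_sel`; each inbred line then draws one allele per
#' marker (genotype 0 or 2). Reversal markers follow a per-cohort logistic
#' trajectory `p_t = plogis(s (t - t0) + delta_j)` with a subpopulation
#' switch-time offset `delta_j ~ N(0, 3.5^2)` (truncated to +/- 5),
#' mirrored for a random half, so the majority allele flips across cohorts
#' while subpopulations differ in when the switch happens (which also
#' elevates their Fst). Cohorts are cross-sectional samples orthogonal to
#' subpopulations: each subpopulation's lines are spread round-robin over
#' the decade bins.
#'
#' @param config a [sim_config()].
#' @return List with elements `panel` (a `geno_panel`), `map` (marker map
#'   tibble), `cohorts` (cohort tibble), and `truth` (list:
#'   `selected_markers`, `planted_reversals`, `subpop_of_line`,
#'   `cohort_of_line`, `qtl_map`).
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n_lines <- config$n_subpops * config$lines_per_subpop
    line_ids <- sprintf("L%03d", seq_len(n_lines))
    subpop <- rep(paste0("SP", seq_len(config$n_subpops)),
                  each = config$lines_per_subpop)
    # cohorts are cross-sectional samples orthogonal to subpopulation:
    # each subpopulation's lines spread round-robin over the decade bins
    cohort_idx <- unlist(lapply(seq_len(config$n_subpops), function(j) {
      rep_len(seq_len(config$n_cohorts), config$lines_per_subpop)
    }))
    year <- config$start_year + 10L * (cohort_idx - 1L) +
      sample(0:9, n_lines, replace = TRUE)
    cohorts <- make_cohorts(tibble::tibble(line_id = line_ids, year_of_entry = year))

    # genetic map: even chromosome split, uniform cM, sorted; column order
    # follows map order
    chrom_names <- if (config$n_chromosomes <= 14) {
      paste0(rep(1:7, 2), rep(c("A", "B"), each = 7))[seq_len(config$n_chromosomes)]
    } else {
      paste0("chr", seq_len(config$n_chromosomes))
    }
    chrom <- sort(rep_len(seq_len(config$n_chromosomes), config$n_markers))
    pos <- stats::runif(config$n_markers, 0, config$map_length_cM)
    ord <- order(chrom, pos)
    map <- tibble::tibble(
      marker_id = sprintf("M%05d", seq_len(config$n_markers)),
      chrom = chrom_names[chrom[ord]],
      pos_cM = pos[ord]
    )

    n_sel <- round(config$selected_fraction * config$n_markers)
    sel_idx <- if (n_sel > 0) sort(sample(config$n_markers, n_sel)) else integer()
    n_rev <- round(config$reversal_fraction * n_sel)
    rev_idx <- if (n_rev > 0) sort(sample(sel_idx, n_rev)) else integer()

    p_anc <- stats::runif(config$n_markers, 0.05, 0.95)
    Fvec <- rep(config$F_neutral, config$n_markers)
    Fvec[sel_idx] <- config$F_sel

    # subpop x marker frequencies (Balding-Nichols)
    J <- config$n_subpops
    q <- matrix(0, J, config$n_markers)
    for (j in seq_len(J)) {
      a <- p_anc * (1 - Fvec) / Fvec
      b <- (1 - p_anc) * (1 - Fvec) / Fvec
      q[j, ] <- stats::rbeta(config$n_markers, a, b)
    }
    # selected (non-reversal) loci model divergent selection: their deme
    # frequencies are BN draws conditioned on a divergent configuration
    # (both sides of 0.5 represented), since divergent selection pushes
    # subpopulations toward different optima rather than letting them drift
    # to a common fixation
    if (J >= 2) {
      for (mk in setdiff(sel_idx, rev_idx)) {
        a <- p_anc[mk] * (1 - Fvec[mk]) / Fvec[mk]
        b <- (1 - p_anc[mk]) * (1 - Fvec[mk]) / Fvec[mk]
        tries <- 0
        while (!(any(q[, mk] > 0.5) && any(q[, mk] < 0.5)) && tries < 50) {
          q[, mk] <- stats::rbeta(J, a, b)
          tries <- tries + 1
        }
      }
    }

    # per-line allele probability
    prob <- q[match(subpop, paste0("SP", seq_len(J))), , drop = FALSE]
    if (length(rev_idx) > 0) {
      s <- config$trajectory_slope
      t0 <- config$trajectory_midpoint
      mirrored <- stats::runif(length(rev_idx)) < 0.5
      delta <- matrix(pmin(5, pmax(-5, stats::rnorm(J * length(rev_idx), 0, 3.5))),
                      J, length(rev_idx))
      for (k in seq_along(rev_idx)) {
        mk <- rev_idx[k]
        for (j in seq_len(J)) {
          tt <- cohort_idx[subpop == paste0("SP", j)]
          pt <- stats::plogis(s * (tt - t0) + delta[j, k])
          if (mirrored[k]) pt <- 1 - pt
          prob[subpop == paste0("SP", j), mk] <- pt
        }
      }
    }
    calls <- matrix(2L * stats::rbinom(length(prob), 1, prob), nrow = n_lines)
    if (config$het_rate > 0) {
      het <- stats::runif(length(calls)) < config$het_rate
      calls[het] <- 1L
    }
    dimnames(calls) <- list(line_ids, sprintf("M%05d", seq_len(config$n_markers)))
    calls <- calls[, map$marker_id, drop = FALSE]   # map order
    panel <- geno_panel(calls)
    if (config$missing_rate > 0) {
      panel <- inject_missing(panel, config$missing_rate,
                              seed = derive_seed(config$seed, 101))
    }
    truth <- list(
      selected_markers = sprintf("M%05d", sel_idx),
      planted_reversals = sprintf("M%05d", rev_idx),
      subpop_of_line = tibble::tibble(line_id = line_ids, subpop = subpop),
      cohort_of_line = tibble::tibble(line_id = line_ids, cohort_index = cohort_idx),
      qtl_map = config$qtl_spec
    )
    list(panel = panel, map = map, cohorts = cohorts, truth = truth)
  })
}

#' Simulate quantitative traits on a panel
#'
#' `y = sum(QTL effects x carrier coding) + polygenic + noise`, where the
#' polygenic term has covariance proportional to the realized kinship matrix
#' of the panel, and noise variance is set so the realized broad-sense
#' heritability matches `h2`. Traits listed in `config$trait_pairs` share
#' their QTL (as specified in `qtl`) and have their polygenic and noise
#' components mixed so the realized pair correlation approaches
#' `config$trait_cor_target`.
#'
#' @param panel a `geno_panel`.
#' @param qtl tibble with columns `marker_id`, `trait`, `effect`; `NULL` for
#'   purely polygenic traits.
#' @param config a [sim_config()] (fields `h2`, `trait_pairs`,
#'   `trait_cor_target`, `polygenic_var`, `seed` are used).
#' @param traits trait names to simulate (default: those in `qtl`, or
#'   `"trait1"`).
#' @return Trait tibble: `line_id` plus one numeric column per trait.
#' @export
simulate_traits <- function(panel, qtl = NULL, config = sim_config(), traits = NULL) {
  if (!is.null(qtl)) {
    missing_mk <- setdiff(qtl$marker_id, marker_ids(panel))
    if (length(missing_mk) > 0) {
      stop("QTL reference unknown marker(s): ", paste(missing_mk, collapse = ", "))
    }
  }
  if (is.null(traits)) {
    traits <- if (!is.null(qtl)) unique(qtl$trait) else "trait1"
  }
  h2 <- config$h2
  if (is.null(names(h2))) h2 <- stats::setNames(rep_len(h2, length(traits)), traits)
  n <- nrow(panel)
  m <- geno_matrix(panel)
  carrier <- m / 2
  carrier[is.na(carrier)] <- 0
  withr::with_seed(derive_seed(config$seed, 202), {
    # polygenic factor from realized kinship
    L <- NULL
    if (config$polygenic_var > 0) {
      K <- kinship_matrix(panel)
      eig <- eigen(K, symmetric = TRUE)
      L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), n)
    }
    comp <- purrr::map(traits, function(tr) {
      qv <- rep(0, n)
      if (!is.null(qtl)) {
        sub <- qtl[qtl$trait == tr, , drop = FALSE]
        if (nrow(sub) > 0) {
          qv <- as.vector(carrier[, sub$marker_id, drop = FALSE] %*% sub$effect)
        }
      }
      u <- if (!is.null(L)) as.vector(L %*% stats::rnorm(n)) else rep(0, n)
      if (stats::sd(u) > 0) u <- u / stats::sd(u) * sqrt(config$polygenic_var)
      e <- stats::rnorm(n)
      list(q = qv, u = u, e = e)
    })
    names(comp) <- traits
    # mix polygenic/noise of designated pairs toward the target correlation
    if (!is.null(config$trait_pairs)) {
      for (pr in config$trait_pairs) {
        if (!all(pr %in% traits)) next
        c1 <- comp[[pr[1]]]; c2 <- comp[[pr[2]]]
        rho <- config$trait_cor_target
        vq12 <- stats::cov(c1$q, c2$q)
        # variances on the genetic+noise scale of each trait (noise scaled below,
        # so solve on standardized components assuming equal h2 handling)
        su1 <- stats::sd(c1$u); su2 <- stats::sd(c2$u)
        mix <- function(a, b, cc) cc * a / max(stats::sd(a), 1e-12) * stats::sd(b) +
          sqrt(max(0, 1 - cc^2)) * b
        # solve for mixing coefficient using current component variances
        v1 <- stats::var(c1$q + c1$u); v2 <- stats::var(c2$q + c2$u)
        sg1 <- sqrt(v1 / max(h2[pr[1]], 1e-12)); sg2 <- sqrt(v2 / max(h2[pr[2]], 1e-12))
        denom <- su1 * su2 + sqrt(max(v1, 1e-12) * (1 / max(h2[pr[1]], 1e-12) - 1)) *
          sqrt(max(v2, 1e-12) * (1 / max(h2[pr[2]], 1e-12) - 1))
        cc <- (rho * sg1 * sg2 - vq12) / max(denom, 1e-12)
        cc <- pmin(1, pmax(-1, cc))
        c2$u <- mix(c1$u, c2$u, cc)
        c2$e <- mix(c1$e, c2$e, cc)
        comp[[pr[2]]] <- c2
      }
    }
    out <- tibble::tibble(line_id = panel$line_id)
    for (tr in traits) {
      cpt <- comp[[tr]]
      g <- cpt$q + cpt$u
      vg <- stats::var(g)
      h <- h2[tr]
      y <- if (h == 0) {
        cpt$e * sqrt(max(vg, 1))
      } else {
        se <- sqrt(vg * (1 - h) / h)
        g + cpt$e / max(stats::sd(cpt$e), 1e-12) * se
      }
      out[[tr]] <- y
    }
    out
  })
}

#' Mask genotype calls to missing
#'
#' Sets exactly `round(rate * n_cells)` entries to `NA`, at positions
#' reproducible from `seed`.
#'
#' @param panel a `geno_panel`.
#' @param rate fraction of cells to mask.
#' @param seed integer seed.
#' @return A `geno_panel` with masked calls.
#' @export
inject_missing <- function(panel, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(panel)
  m <- geno_matrix(panel)
  n_mask <- round(rate * length(m))
  withr::with_seed(seed, {
    idx <- sample(length(m), n_mask)
  })
  m[idx] <- NA_integer_
  geno_panel(m)
}
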