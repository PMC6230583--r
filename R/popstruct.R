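#' Per-locus and multilocus Weir-Cockerham Fst for inbred panels
#'
#' Inbred lines are treated as haploid allele samples (one allele per line,
#' dose/2), so the estimator has no within-individual component. Per locus,
#' with `r` demes of sizes `n_j` and allele frequencies `p_j`:
#' `MSP = sum n_j (p_j - pbar)^2 / (r - 1)`,
#' `MSG = sum n_j p_j (1 - p_j) / (N - r)`,
#' `nc = (N - sum n_j^2 / N) / (r - 1)`, among-deme component
#' `a = (MSP - MSG) / nc`, within component `b = MSG`, and
#' `theta = a / (a + b)`. The multilocus estimate is the ratio of summed
#' components `sum(a) / sum(a + b)` — never a mean of per-locus ratios.
#' Negative per-locus estimates are permitted.
#'
#' @param panel a `geno_panel`.
#' @param assignment data frame with columns `line_id` and `subpop`, or a
#'   vector of subpopulation labels in panel line order.
#' @return List with `per_locus` (tibble: `marker_id`, `a`, `b`, `theta`,
#'   `he`) and `theta` (multilocus estimate).
#' @export
wc_fst <- function(panel, assignment) {
  grp <- droplevels(align_assignment(panel, assignment))
  m <- geno_matrix(panel) / 2          # haploid allele per line in [0,1]
  sizes <- table(grp)
  if (any(sizes < 2)) {
    stop("subpopulation(s) with fewer than 2 lines: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  obs <- !is.na(m)
  x <- m; x[!obs] <- 0
  n_j <- rowsum(obs + 0, grp)          # deme x locus non-missing counts
  s_j <- rowsum(x, grp)                # deme x locus allele sums
  p_j <- ifelse(n_j > 0, s_j / n_j, NA_real_)
  r <- colSums(n_j > 0)
  N <- colSums(n_j)
  pbar <- colSums(s_j) / N
  ssp <- colSums(n_j * sweep(p_j, 2, pbar, "-")^2, na.rm = TRUE)
  ssg <- colSums(n_j * p_j * (1 - p_j), na.rm = TRUE)
  msp <- ssp / (r - 1)
  msg <- ssg / (N - r)
  nc <- (N - colSums(n_j^2) / N) / (r - 1)
  a <- (msp - msg) / nc
  b <- msg
  theta <- ifelse(a + b > 0, a / (a + b), NA_real_)
  he <- 1 - pbar^2 - (1 - pbar)^2
  list(
    per_locus = tibble::tibble(
      marker_id = colnames(m), a = unname(a), b = unname(b),
      theta = unname(theta), he = unname(he)
    ),
    theta = sum(a, na.rm = TRUE) / sum(a + b, na.rm = TRUE)
  )
}

align_assignment <- function(panel, assignment) {
  if (is.data.frame(assignment)) {
    stopifnot(all(c("line_id", "subpop") %in% names(assignment)))
    idx <- match(panel$line_id, assignment$line_id)
    if (anyNA(idx)) {
      stop("no subpopulation assignment for line(s): ",
           paste(panel$line_id[is.na(idx)], collapse = ", "))
    }
    factor(assignment$subpop[idx])
  } else {
    if (length(assignment) != nrow(panel)) {
      stop("assignment length ", length(assignment), " != ", nrow(panel), " lines")
    }
    factor(assignment)
  }
}

#' Pairwise Weir-Cockerham Fst between subpopulations
#'
#' @inheritParams wc_fst
#' @return Tibble with columns `pop1`, `pop2`, `theta` (multilocus); the
#'   symmetric matrix is attached as attribute `"matrix"`.
#' @export
pairwise_fst <- function(panel, assignment) {
  grp <- align_assignment(panel, assignment)
  lev <- levels(grp)
  if (length(lev) < 2) stop("need at least 2 subpopulations")
  pairs <- utils::combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    keep <- grp %in% pairs[, k]
    sub <- panel[keep, , drop = FALSE]
    class(sub) <- unique(c("geno_panel", class(sub)))
    tibble::tibble(
      pop1 = pairs[1, k], pop2 = pairs[2, k],
      theta = wc_fst(sub, droplevels(grp[keep]))$theta
    )
  })
  mat <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  diag(mat) <- 0
  for (k in seq_len(nrow(res))) {
    mat[res$pop1[k], res$pop2[k]] <- mat[res$pop2[k], res$pop1[k]] <- res$theta[k]
  }
  attr(res, "matrix") <- mat
  res
}

#' DAPC-style clustering with BIC model choice
#'
#' Centers the genotype matrix, takes principal components, runs k-means for
#' each candidate K (multiple restarts) in the retained PC space, scores each
#' K by `BIC(K) = n log(WSS_K / n) + K log(n)`, picks the K minimising BIC
#' (ties broken toward smaller K), and computes linear discriminant axes on
#' the retained PCs for the chosen clustering.
#'
#' @param panel a complete (no missing calls) `geno_panel`.
#' @param K_range candidate cluster counts.
#' @param n_pcs number of PCs to retain, or `"auto"` (smallest count
#'   explaining >= 90% of variance, capped at `n_lines / 3`).
#' @param n_start k-means restarts per K (>= 20 recommended).
#' @param seed integer seed.
#' @return A `bs_structure` object: list with `K`, `bic_by_K` (tibble),
#'   `assignment` (tibble `line_id`, `subpop`), `coords` (tibble `line_id`,
#'   `LD1`, `LD2`), `retained_pcs`.
#' @export
dapc_cluster <- function(panel, K_range = 1:8, n_pcs = "auto", n_start = 25, seed = 1) {
  m <- geno_matrix(panel)
  if (anyNA(m)) stop("dapc_cluster requires a complete panel; run impute_missing() first")
  n <- nrow(m)
  if (n < 2 || ncol(m) < 2) stop("need at least 2 lines and 2 markers")
  if (any(K_range >= n)) stop("K_range contains K >= number of lines (", n, ")")
  x <- scale(m, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(x, center = FALSE)
  ev <- pc$sdev^2
  if (identical(n_pcs, "auto")) {
    if (sum(ev) <= 1e-12) {
      n_pcs <- 1L  # zero-variance panel: keep a single (null) axis
    } else {
      cum <- cumsum(ev) / sum(ev)
      n_pcs <- max(1L, min(which(cum >= 0.90)[1], floor(n / 3)), na.rm = TRUE)
    }
  }
  n_pcs <- max(1L, min(n_pcs, sum(ev > 1e-12), ncol(pc$x)))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  n_distinct <- nrow(unique(round(scores, 10)))
  K_range <- sort(unique(K_range))
  fits <- withr::with_seed(seed, purrr::map(K_range, function(K) {
    if (K == 1) {
      list(cluster = rep(1L, n), wss = sum(scale(scores, scale = FALSE)^2))
    } else if (K > n_distinct) {
      NULL
    } else {
      km <- stats::kmeans(scores, centers = K, nstart = n_start, iter.max = 50)
      list(cluster = km$cluster, wss = km$tot.withinss)
    }
  }))
  ok <- !purrr::map_lgl(fits, is.null)
  K_range <- K_range[ok]; fits <- fits[ok]
  bic <- purrr::map2_dbl(fits, K_range, function(f, K) {
    n * log(max(f$wss, 1e-300) / n) + K * log(n)
  })
  best <- which.min(bic)   # ties -> first = smallest K
  K <- K_range[best]
  cl <- fits[[best]]$cluster
  # stable labels: order clusters by first occurrence
  relab <- match(cl, unique(cl))
  subpop <- factor(paste0("SP", relab), levels = paste0("SP", seq_len(K)))
  coords <- if (K >= 2) {
    ld <- MASS::lda(scores, grouping = subpop)
    proj <- scores %*% ld$scaling
    cbind(proj, 0)[, 1:2, drop = FALSE]
  } else {
    matrix(0, n, 2)
  }
  out <- list(
    K = K,
    bic_by_K = tibble::tibble(K = K_range, bic = bic),
    assignment = tibble::tibble(line_id = panel$line_id, subpop = subpop),
    coords = tibble::tibble(line_id = panel$line_id,
                            LD1 = coords[, 1], LD2 = coords[, 2]),
    retained_pcs = n_pcs
  )
  class(out) <- "bs_structure"
  out
}

#' @export
print.bs_structure <- function(x, ...) {
  cat(sprintf("<bs_structure> K = %d (BIC-selected over K in {%s}), %d PCs retained\n",
              x$K, paste(x$bic_by_K$K, collapse = ","), x$retained_pcs))
  print(table(x$assignment$subpop))
  invisible(x)
}

#' Analysis of molecular variance (two-level, permutation-tested)
#'
#' Squared-Euclidean distances on genotype vectors are partitioned into
#' among-subpopulation and among-line-within-subpopulation sums of squares.
#' Variance components follow the standard AMOVA coefficients
#' (`sigma2_within = MS_within`;
#' `sigma2_among = (MS_among - MS_within) / n0` with
#' `n0 = (N - sum n_g^2 / N) / (r - 1)`). The among-component p-value is the
#' proportion of label permutations whose among component is >= observed.
#'
#' @inheritParams wc_fst
#' @param n_perm number of permutations (>= 100 recommended; < 1 is an
#'   error).
#' @param seed integer seed.
#' @return A `bs_amova` object: list with `table` (tibble: source, df, SS,
#'   variance, percent, p_value), `phi_st`, `n_perm`.
#' @export
amova <- function(panel, assignment, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 100) warning("n_perm < 100: permutation p-values will be coarse")
  grp <- align_assignment(panel, assignment)
  m <- geno_matrix(panel)
  if (anyNA(m)) stop("amova requires a complete panel; run impute_missing() first")
  comp <- amova_components(m, grp)
  perm <- withr::with_seed(seed, {
    replicate(n_perm, amova_components(m, sample(grp))$sigma_a)
  })
  p_among <- (sum(perm >= comp$sigma_a) + 1) / (n_perm + 1)
  total <- comp$sigma_a + comp$sigma_w
  tab <- tibble::tibble(
    source = c("Among subpopulations", "Among lines within subpopulations", "Total"),
    df = c(comp$df_a, comp$df_w, comp$df_a + comp$df_w),
    SS = c(comp$ss_a, comp$ss_w, comp$ss_a + comp$ss_w),
    variance = c(comp$sigma_a, comp$sigma_w, total),
    percent = 100 * c(comp$sigma_a, comp$sigma_w, total) / total,
    p_value = c(p_among, NA, NA)
  )
  out <- list(table = tab, phi_st = comp$sigma_a / total, n_perm = n_perm)
  class(out) <- "bs_amova"
  out
}

amova_components <- function(m, grp) {
  grp <- droplevels(grp)
  n <- nrow(m)
  r <- nlevels(grp)
  gm <- colMeans(m)
  ss_total <- sum(sweep(m, 2, gm, "-")^2)
  centroids <- rowsum(m, grp) / as.vector(table(grp))
  ss_w <- sum((m - centroids[as.integer(grp), , drop = FALSE])^2)
  ss_a <- ss_total - ss_w
  df_a <- r - 1
  df_w <- n - r
  sizes <- as.vector(table(droplevels(grp)))
  n0 <- (n - sum(sizes^2) / n) / df_a
  ms_a <- ss_a / df_a
  ms_w <- ss_w / df_w
  list(ss_a = ss_a, ss_w = ss_w, df_a = df_a, df_w = df_w,
       sigma_a = (ms_a - ms_w) / n0, sigma_w = ms_w)
}

#' @export
print.bs_amova <- function(x, ...) {
  cat(sprintf("<bs_amova> Phi_ST = %.4f (%d permutations)\n", x$phi_st, x$n_perm))
  print(x$table)
  invisible(x)
}

#' Gene diversity by temporal cohort
#'
#' For each cohort with at least `min_n` lines, computes the mean over
#' markers of the unbiased gene diversity `(n / (n - 1)) * (1 - p^2 - q^2)`
#' using cohort-specific allele frequencies, with a bootstrap CI over
#' markers. Cohorts below `min_n` are skipped and listed in the attached
#' `"skipped"` attribute.
#'
#' @param panel a `geno_panel`.
#' @param cohorts cohort tibble from [make_cohorts()] / [read_cohorts()].
#' @param min_n minimum cohort size.
#' @param n_boot bootstrap replicates for the CI.
#' @param seed integer seed.
#' @return Tibble (`bs_diversity`) with `cohort`, `n_lines`, `pi`,
#'   `ci_lo`, `ci_hi`, ordered by time.
#' @export
diversity_by_cohort <- function(panel, cohorts, min_n = 10, n_boot = 200, seed = 1) {
  idx <- match(panel$line_id, cohorts$line_id)
  if (anyNA(idx)) {
    stop("no cohort record for line(s): ",
         paste(panel$line_id[is.na(idx)], collapse = ", "))
  }
  coh <- cohorts$cohort[idx]
  m <- geno_matrix(panel) / 2
  levs <- levels(coh)[levels(coh) %in% as.character(coh)]
  skipped <- character()
  rows <- withr::with_seed(seed, purrr::map(levs, function(cl) {
    rowsel <- which(coh == cl)
    if (length(rowsel) < min_n) {
      skipped <<- c(skipped, cl)
      return(NULL)
    }
    sub <- m[rowsel, , drop = FALSE]
    nmk <- colSums(!is.na(sub))
    p <- colMeans(sub, na.rm = TRUE)
    ok <- nmk >= 2
    pi_mk <- (nmk[ok] / (nmk[ok] - 1)) * (1 - p[ok]^2 - (1 - p[ok])^2)
    boots <- replicate(n_boot, mean(sample(pi_mk, replace = TRUE)))
    tibble::tibble(
      cohort = cl, n_lines = length(rowsel), pi = mean(pi_mk),
      ci_lo = stats::quantile(boots, 0.025, names = FALSE),
      ci_hi = stats::quantile(boots, 0.975, names = FALSE)
    )
  }))
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  class(out) <- unique(c("bs_diversity", class(out)))
  out
}
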