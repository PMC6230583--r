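#' Build haplotype loci from selected markers
#'
#' Per chromosome, selected markers are chained greedily left-to-right in
#' map order: the current block is extended to the next selected marker iff
#' its pairwise LD r-squared to EVERY marker already in the block is at
#' least `r2_min` AND the map gap to the previous member is at most
#' `max_gap_cM`; otherwise a new block starts. Singleton blocks are allowed.
#' Locus ids are `hap_<chrom>_<index>`, numbered per chromosome in map
#' order.
#'
#' @param selected character vector of selected marker ids.
#' @param panel a `geno_panel` containing those markers.
#' @param map map tibble (`marker_id`, `chrom`, `pos_cM`).
#' @param r2_min minimum pairwise r-squared within a block.
#' @param max_gap_cM maximum map gap between consecutive members.
#' @return Tibble (`bs_haploci`): `locus_id`, `chrom`, `cM_start`, `cM_end`,
#'   `n_markers`, `members` (list column of marker ids).
#' @export
build_haplotype_loci <- function(selected, panel, map, r2_min = 0.7,
                                 max_gap_cM = 5) {
  missing_mk <- setdiff(selected, map$marker_id)
  if (length(missing_mk) > 0) {
    stop("selected marker(s) absent from map: ", paste(missing_mk, collapse = ", "))
  }
  missing_panel <- setdiff(selected, marker_ids(panel))
  if (length(missing_panel) > 0) {
    stop("selected marker(s) absent from panel: ",
         paste(missing_panel, collapse = ", "))
  }
  m <- geno_matrix(panel)
  sel_map <- dplyr::arrange(
    dplyr::filter(map, .data$marker_id %in% selected),
    .data$chrom, .data$pos_cM
  )
  rows <- list()
  for (ch in unique(sel_map$chrom)) {
    cm <- dplyr::filter(sel_map, .data$chrom == ch)
    blocks <- list()
    cur <- cm[1, , drop = FALSE]
    for (k in seq_len(nrow(cm))[-1]) {
      cand <- cm[k, ]
      gap_ok <- (cand$pos_cM - cur$pos_cM[nrow(cur)]) <= max_gap_cM
      r2_ok <- all(purrr::map_dbl(cur$marker_id, function(mm) {
        r2_vec(m[, mm], m[, cand$marker_id])
      }) >= r2_min, na.rm = FALSE)
      r2_ok <- isTRUE(r2_ok)
      if (gap_ok && r2_ok) {
        cur <- dplyr::bind_rows(cur, cand)
      } else {
        blocks <- c(blocks, list(cur))
        cur <- cand
      }
    }
    blocks <- c(blocks, list(cur))
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      rows <- c(rows, list(tibble::tibble(
        locus_id = paste0("hap_", ch, "_", bi),
        chrom = ch, cM_start = min(b$pos_cM), cM_end = max(b$pos_cM),
        n_markers = nrow(b), members = list(b$marker_id)
      )))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("bs_haploci", class(out)))
  out
}

# squared Pearson correlation of two dosage vectors over complete pairs
r2_vec <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])^2
}

#' Pairwise LD r-squared between two markers
#'
#' Squared Pearson correlation of dosage vectors over lines complete for
#' both markers (the haploid-equivalent LD r-squared for inbred lines).
#' Invariant to a global 0<->2 allele flip of either marker.
#'
#' @param panel a `geno_panel`.
#' @param marker_a,marker_b marker ids.
#' @return r-squared in \[0, 1\] (NA if either marker is constant on the
#'   complete lines).
#' @export
pairwise_r2 <- function(panel, marker_a, marker_b) {
  m <- geno_matrix(panel)
  for (mk in c(marker_a, marker_b)) {
    if (!mk %in% colnames(m)) stop("marker not in panel: ", mk)
  }
  r2_vec(m[, marker_a], m[, marker_b])
}

#' Call per-line haplotype alleles at each locus
#'
#' A line's allele is the concatenated genotype word over the locus member
#' markers (e.g. `"02"` for calls 0, 2); lines missing any member call get
#' allele `"NA"`. Alleles with frequency below `pool_freq` (computed over
#' non-"NA" lines) are pooled into `"RARE"`, and frequencies recomputed.
#'
#' @param loci a `bs_haploci` tibble from [build_haplotype_loci()].
#' @param panel a `geno_panel`.
#' @param pool_freq pooling threshold.
#' @return The loci tibble with list columns `calls` (character vector of
#'   alleles named by line id) and `allele_freq` (named numeric), plus
#'   `n_alleles` (count of distinct non-"NA" alleles after pooling).
#' @export
call_haplotypes <- function(loci, panel, pool_freq = 0.05) {
  m <- geno_matrix(panel)
  res <- purrr::map(loci$members, function(mem) {
    sub <- m[, mem, drop = FALSE]
    word <- apply(sub, 1, function(z) {
      if (anyNA(z)) "NA" else paste(z, collapse = "")
    })
    names(word) <- rownames(m)
    obs <- word[word != "NA"]
    freq <- table(obs) / length(obs)
    rare <- names(freq)[freq < pool_freq]
    word[word %in% rare] <- "RARE"
    obs <- word[word != "NA"]
    freq <- sort(table(obs) / length(obs), decreasing = TRUE)
    list(calls = word, freq = stats::setNames(as.numeric(freq), names(freq)))
  })
  loci$calls <- purrr::map(res, "calls")
  loci$allele_freq <- purrr::map(res, "freq")
  loci$n_alleles <- purrr::map_int(res, ~ length(.x$freq))
  loci
}

#' Realized kinship matrix from genotype dosages
#'
#' Centered-dosage cross-product `K = Z Z' / (2 sum p (1 - p))` with
#' `Z = calls - 2 p` per marker, computed on the full post-QC marker set;
#' missing calls contribute 0 after centering. A small ridge
#' (`1e-6 I`) keeps the matrix numerically positive semidefinite.
#'
#' @param panel a `geno_panel`.
#' @return Symmetric line x line matrix with dimnames = line ids.
#' @export
kinship_matrix <- function(panel) {
  m <- geno_matrix(panel)
  p <- colMeans(m, na.rm = TRUE) / 2
  Z <- sweep(m, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("kinship undefined: all markers monomorphic")
  K <- (Z %*% t(Z)) / denom
  K + diag(1e-6, nrow(K))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with monotonicity enforcement; input order is
#' preserved and `NA`s propagate.
#'
#' @param p numeric vector of p-values.
#' @return q-values in the same order.
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Allelic effect of a haplotype allele
#'
#' The difference between the mean trait value of carrier lines and the
#' mean of all lines with trait data.
#'
#' @param y trait values (NA allowed).
#' @param carrier logical vector marking carrier lines.
#' @return Effect in trait units.
#' @export
allelic_effect <- function(y, carrier) {
  stopifnot(length(y) == length(carrier))
  ok <- !is.na(y)
  mean(y[ok & carrier]) - mean(y[ok])
}

# ---- kinship mixed linear model -------------------------------------------

# REML profile log-likelihood for delta = sigma_g^2 / sigma_e^2 given
# rotated responses/designs (K = U D U').
reml_ll <- function(log_delta, ys, Xs, d) {
  delta <- exp(log_delta)
  v <- delta * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xs * w, Xs)
  XtWy <- crossprod(Xs * w, ys)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  res <- ys - Xs %*% beta
  rss <- sum(res^2 * w)
  n <- length(ys); p <- ncol(Xs)
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + sum(log(v)) +
            2 * sum(log(diag(ch))) + (n - p) * 0)
}

# weighted least squares at fixed delta; returns rss and df
wls_rss <- function(ys, Xs, d, delta) {
  w <- 1 / (delta * d + 1)
  XtWX <- crossprod(Xs * w, Xs)
  XtWy <- crossprod(Xs * w, ys)
  beta <- solve(XtWX, XtWy)
  res <- ys - Xs %*% beta
  list(rss = sum(res^2 * w), p = ncol(Xs), beta = beta)
}

#' Kinship mixed-model haplotype-trait association scan
#'
#' Fits, per haplotype locus and trait, the mixed linear model
#' `y = mu + locus allele indicators (+ covariates) + u + e` with
#' `cov(u) = sigma_g^2 K` and `cov(e) = sigma_e^2 I` (MLM-K; supplying
#' structure covariates gives MLM-QK). The variance ratio is profiled by
#' exact REML per locus via a single eigendecomposition of K, and the locus
#' term is tested with an F-test (numerator df = number of allele classes
#' minus 1). Reports Benjamini-Hochberg q-values at `fdr_level`, the
#' genomic-inflation factor `lambda_gc` per trait, the locus R-squared
#' (reduction in whitened residual variance relative to the no-locus
#' model), and carrier-vs-population allelic effects for common (non-RARE)
#' alleles.
#'
#' Lines with allele `"NA"` at a locus are dropped for that locus; loci
#' monomorphic after dropping (or with a singular design) are skipped with
#' a log entry (attribute `"skipped"`).
#'
#' @param loci called loci from [call_haplotypes()].
#' @param traits trait tibble (`line_id` + numeric trait columns).
#' @param K kinship matrix over (at least) the panel lines.
#' @param fdr_level FDR level for the `significant` flag.
#' @param covariates optional tibble (`line_id` + numeric columns) of fixed
#'   structure covariates (MLM-QK).
#' @return Tibble (`bs_assoc`): `locus_id`, `trait`, `n_used`, `df_locus`,
#'   `p_value`, `q_value`, `r2`, `lambda_gc`, `significant`, `effects`
#'   (list column: tibble of allele, freq, effect).
#' @export
mlm_scan <- function(loci, traits, K, fdr_level = 0.05, covariates = NULL) {
  stopifnot(is.matrix(K), !is.null(rownames(K)))
  if (!"calls" %in% names(loci)) {
    stop("loci must be called first: run call_haplotypes()")
  }
  ev_ok <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_ok) < -1e-6) stop("kinship matrix is not positive semidefinite")
  trait_names <- setdiff(names(traits), "line_id")
  skipped <- list()
  rows <- list()
  eig_cache <- new.env(parent = emptyenv())
  for (tr in trait_names) {
    pvals <- rep(NA_real_, nrow(loci))
    fit_rows <- vector("list", nrow(loci))
    for (li in seq_len(nrow(loci))) {
      calls <- loci$calls[[li]]
      ids <- names(calls)[calls != "NA"]
      ids <- intersect(ids, traits$line_id[!is.na(traits[[tr]])])
      ids <- intersect(ids, rownames(K))
      allele <- factor(calls[ids])
      if (length(ids) < 5 || nlevels(droplevels(allele)) < 2) {
        skipped <- c(skipped, list(tibble::tibble(
          locus_id = loci$locus_id[li], trait = tr,
          reason = "monomorphic or too few lines after dropping NA alleles"
        )))
        next
      }
      allele <- droplevels(allele)
      y <- traits[[tr]][match(ids, traits$line_id)]
      key <- digest_ids(ids)
      if (is.null(eig_cache[[key]])) {
        eig_cache[[key]] <- eigen(K[ids, ids], symmetric = TRUE)
      }
      eig <- eig_cache[[key]]
      U <- eig$vectors; d <- pmax(eig$values, 0)
      X0 <- matrix(1, length(ids), 1)
      if (!is.null(covariates)) {
        cv <- as.matrix(covariates[match(ids, covariates$line_id),
                                   setdiff(names(covariates), "line_id"),
                                   drop = FALSE])
        X0 <- cbind(X0, cv)
      }
      X1 <- cbind(X0, stats::model.matrix(~allele)[, -1, drop = FALSE])
      if (qr(X1)$rank < ncol(X1)) {
        skipped <- c(skipped, list(tibble::tibble(
          locus_id = loci$locus_id[li], trait = tr, reason = "singular design"
        )))
        next
      }
      ys <- crossprod(U, y)
      X0s <- crossprod(U, X0)
      X1s <- crossprod(U, X1)
      opt <- stats::optimize(function(ld) reml_ll(ld, ys, X1s, d),
                             interval = c(-12, 12), maximum = TRUE)
      delta <- exp(opt$maximum)
      f1 <- wls_rss(ys, X1s, d, delta)
      f0 <- wls_rss(ys, X0s, d, delta)
      q_df <- ncol(X1) - ncol(X0)
      df2 <- length(ids) - ncol(X1)
      Fstat <- ((f0$rss - f1$rss) / q_df) / (f1$rss / df2)
      pvals[li] <- stats::pf(Fstat, q_df, df2, lower.tail = FALSE)
      freq <- loci$allele_freq[[li]]
      common <- setdiff(names(freq), "RARE")
      eff <- purrr::map_dbl(common, function(al) allelic_effect(y, allele == al))
      effects <- tibble::tibble(
        allele = common,
        freq = as.numeric(freq[common]),
        effect = eff
      )
      fit_rows[[li]] <- tibble::tibble(
        locus_id = loci$locus_id[li], trait = tr, n_used = length(ids),
        df_locus = q_df, p_value = pvals[li],
        r2 = (f0$rss - f1$rss) / f0$rss,
        effects = list(effects)
      )
    }
    done <- dplyr::bind_rows(fit_rows)
    if (nrow(done) == 0) next
    chi <- stats::qchisq(1 - done$p_value, df = 1)
    lambda <- stats::median(chi, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
    done$q_value <- bh_fdr(done$p_value)
    done$lambda_gc <- lambda
    done$significant <- !is.na(done$q_value) & done$q_value <= fdr_level
    rows <- c(rows, list(done))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- dplyr::select(out, "locus_id", "trait", "n_used", "df_locus",
                         "p_value", "q_value", "r2", "lambda_gc",
                         "significant", "effects")
  }
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  class(out) <- unique(c("bs_assoc", class(out)))
  out
}

digest_ids <- function(ids) paste(ids, collapse = "|")

#' Flatten per-allele effects of an association scan
#'
#' @param assoc a `bs_assoc` tibble from [mlm_scan()].
#' @return Long tibble: `locus_id`, `trait`, `allele`, `freq`, `effect`.
#' @export
allelic_effects_table <- function(assoc) {
  tidyr::unnest(
    dplyr::select(assoc, "locus_id", "trait", "effects"),
    "effects"
  )
}
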