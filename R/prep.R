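#' Per-marker summary statistics
#'
#' Computes, per marker and over non-missing calls: alt-allele frequency `p`,
#' minor-allele frequency `maf = min(p, 1 - p)`, expected heterozygosity
#' (gene diversity) `he = 1 - p^2 - q^2`, polymorphism information content
#' `pic = he - 2 p^2 q^2`, and the call rate.
#'
#' For a biallelic marker PIC is bounded above by 0.375 (at p = 0.5) and He
#' by 0.5, so `pic <= he <= 0.5` always.
#'
#' @param panel a `geno_panel`.
#' @return Tibble with columns `marker_id`, `p`, `maf`, `he`, `pic`,
#'   `call_rate`.
#' @export
marker_stats <- function(panel) {
  m <- geno_matrix(panel)
  p <- colMeans(m, na.rm = TRUE) / 2
  q <- 1 - p
  he <- 1 - p^2 - q^2
  tibble::tibble(
    marker_id = colnames(m),
    p = unname(p),
    maf = unname(pmin(p, q)),
    he = unname(he),
    pic = unname(he - 2 * p^2 * q^2),
    call_rate = unname(colMeans(!is.na(m)))
  )
}

#' Remove duplicate markers
#'
#' Two markers are duplicates when their non-missing calls are identical
#' across all lines, either directly or after a global 0<->2 allele flip
#' (array strand reporting can flip alleles without changing information
#' content). Within each duplicate group only the first marker in map order
#' is retained.
#'
#' @param panel a `geno_panel`.
#' @param map optional map tibble (`marker_id`, `chrom`, `pos_cM`) defining
#'   the retention order; unmapped markers keep panel column order after
#'   mapped ones.
#' @return A `geno_panel` with duplicates dropped; the removal log is
#'   attached as attribute `"removed"` (a tibble with `kept`, `removed`).
#' @export
remove_duplicates <- function(panel, map = NULL) {
  m <- geno_matrix(panel)
  ids <- colnames(m)
  ord <- seq_along(ids)
  if (!is.null(map)) {
    map <- dplyr::arrange(map, .data$chrom, .data$pos_cM)
    pos <- match(ids, map$marker_id)
    ord <- order(is.na(pos), pos, seq_along(ids))
  }
  m <- m[, ord, drop = FALSE]
  ids <- ids[ord]
  # canonical key: marker column and its flip share one key
  key_of <- function(col) {
    flip <- 2L - col
    a <- paste(ifelse(is.na(col), "N", col), collapse = "")
    b <- paste(ifelse(is.na(flip), "N", flip), collapse = "")
    if (a <= b) a else b
  }
  keys <- apply(m, 2, key_of)
  first <- !duplicated(keys)
  log <- tibble::tibble(
    kept = ids[match(keys[!first], keys)],
    removed = ids[!first]
  )
  keep_ids <- ids[first]
  out <- select_markers(panel, intersect(marker_ids(panel), keep_ids))
  attr(out, "removed") <- log
  out
}

#' Impute missing genotype calls
#'
#' `strategy = "mode"` fills each missing call with the marker's majority
#' code (ties broken toward the lower code). `strategy = "knn"` fills from
#' the `k` nearest lines by allele-sharing distance computed over markers
#' complete for both lines, taking the majority vote of their non-missing
#' calls at the target marker (remaining gaps fall back to the marker mode).
#' Non-missing calls are never altered.
#'
#' @param panel a `geno_panel`.
#' @param strategy `"knn"` (default) or `"mode"`.
#' @param k neighbour count for knn.
#' @param seed integer seed (knn tie-breaks are deterministic given it).
#' @return A `geno_panel` with no missing calls.
#' @export
impute_missing <- function(panel, strategy = c("knn", "mode"), k = 10, seed = 1) {
  strategy <- match.arg(strategy)
  m <- geno_matrix(panel)
  all_missing <- colnames(m)[colSums(!is.na(m)) == 0]
  if (length(all_missing) > 0) {
    stop("cannot impute markers with no observed calls: ",
         paste(all_missing, collapse = ", "))
  }
  if (!anyNA(m)) return(panel)
  mode_fill <- apply(m, 2, function(col) {
    tab <- table(factor(col, levels = c(0L, 1L, 2L)))
    as.integer(names(tab)[which.max(tab)])  # which.max takes first => lower code on tie
  })
  if (strategy == "mode") {
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mode_fill[idx[, 2]]
  } else {
    withr::with_seed(seed, {
      obs <- !is.na(m)
      n <- nrow(m)
      # allele-sharing distance: mean |dose_i - dose_j|/2 over shared markers
      d <- matrix(Inf, n, n)
      for (i in seq_len(n)) {
        shared <- obs & rep(obs[i, ], each = n) # n x m logical of shared with i
        diffsum <- rowSums(abs(sweep(m, 2, m[i, ], "-")) * shared, na.rm = TRUE)
        cnt <- rowSums(shared)
        d[i, ] <- ifelse(cnt > 0, diffsum / (2 * cnt), Inf)
      }
      diag(d) <- Inf
      for (i in seq_len(n)) {
        miss_j <- which(is.na(m[i, ]))
        if (length(miss_j) == 0) next
        nb <- order(d[i, ])[seq_len(min(k, n - 1))]
        for (j in miss_j) {
          votes <- m[nb, j]
          votes <- votes[!is.na(votes)]
          if (length(votes) == 0) {
            m[i, j] <- mode_fill[j]
          } else {
            tab <- table(factor(votes, levels = c(0L, 1L, 2L)))
            m[i, j] <- as.integer(names(tab)[which.max(tab)])
          }
        }
      }
    })
  }
  geno_panel(m)
}

#' Filter markers by minor-allele frequency
#'
#' MAF is computed on non-missing calls as `min(p, 1 - p)` with
#' `p = mean(calls) / 2`; markers with `maf < threshold` are removed
#' (monomorphic markers have MAF 0 and drop out for any threshold > 0).
#'
#' @param panel a `geno_panel`.
#' @param threshold minimum MAF to keep (default 0.05).
#' @return A filtered `geno_panel`.
#' @export
maf_filter <- function(panel, threshold = 0.05) {
  st <- marker_stats(panel)
  keep <- st$marker_id[st$maf >= threshold]
  select_markers(panel, keep)
}

#' Select an informative marker subset by PIC (or He)
#'
#' Retains markers whose polymorphism information content lies in
#' `[lo, hi]`. For biallelic markers PIC cannot exceed 0.375, so the default
#' window is `[0.30, 0.375]`; set `measure = "he"` to threshold on gene
#' diversity (max 0.5) instead.
#'
#' @param panel a `geno_panel`.
#' @param lo,hi inclusive bounds.
#' @param measure `"pic"` (default) or `"he"`.
#' @return List with `panel` (filtered) and `stats` (full [marker_stats()]
#'   table).
#' @export
pic_subset <- function(panel, lo = 0.30, hi = 0.375, measure = c("pic", "he")) {
  if (lo > hi) stop("lo (", lo, ") must not exceed hi (", hi, ")")
  measure <- match.arg(measure)
  st <- marker_stats(panel)
  v <- st[[measure]]
  keep <- st$marker_id[v >= lo & v <= hi]
  list(panel = select_markers(panel, keep), stats = st)
}
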