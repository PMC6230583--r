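#' Cohort allele-frequency trajectories
#'
#' For every marker and every cohort with at least `min_n` lines, computes
#' the frequency of the reference allele, where "reference" is defined
#' data-dependently as the major allele of the earliest eligible cohort
#' (ties resolved toward the alt allele). Cohorts in which a marker has no
#' non-missing call are marked absent (`NA` frequency).
#'
#' @param panel a `geno_panel`.
#' @param cohorts cohort tibble ([make_cohorts()]).
#' @param markers marker ids to track (default: all).
#' @param min_n minimum cohort size; smaller cohorts are omitted with a log
#'   entry (attribute `"skipped_cohorts"`).
#' @return Long tibble (`bs_traj`): `marker_id`, `cohort`, `n`, `freq_ref`.
#' @export
cohort_frequencies <- function(panel, cohorts, markers = NULL, min_n = 10) {
  if (is.null(markers)) markers <- marker_ids(panel)
  missing_mk <- setdiff(markers, marker_ids(panel))
  if (length(missing_mk) > 0) {
    stop("marker(s) not in panel: ", paste(missing_mk, collapse = ", "))
  }
  idx <- match(panel$line_id, cohorts$line_id)
  if (anyNA(idx)) {
    stop("no cohort record for line(s): ",
         paste(panel$line_id[is.na(idx)], collapse = ", "))
  }
  coh <- cohorts$cohort[idx]
  m <- geno_matrix(select_markers(panel, markers)) / 2
  sizes <- table(coh)
  eligible <- names(sizes)[sizes >= min_n]
  skipped <- setdiff(names(sizes)[sizes > 0], eligible)
  eligible <- levels(coh)[levels(coh) %in% eligible]
  if (length(eligible) == 0) stop("no cohort reaches min_n = ", min_n)
  freq_alt <- sapply(eligible, function(cl) {
    colMeans(m[coh == cl, , drop = FALSE], na.rm = TRUE)
  })
  nn <- sapply(eligible, function(cl) {
    colSums(!is.na(m[coh == cl, , drop = FALSE]))
  })
  if (length(markers) == 1) {
    freq_alt <- matrix(freq_alt, nrow = 1, dimnames = list(markers, eligible))
    nn <- matrix(nn, nrow = 1, dimnames = list(markers, eligible))
  }
  freq_alt[nn == 0] <- NA_real_
  # reference allele: major allele of earliest cohort with data; ties -> alt
  first_obs <- apply(freq_alt, 1, function(z) which(!is.na(z))[1])
  ref_is_alt <- purrr::map_lgl(seq_along(markers), function(i) {
    fo <- first_obs[i]
    if (is.na(fo)) return(TRUE)
    freq_alt[i, fo] >= 0.5
  })
  freq_ref <- freq_alt
  freq_ref[!ref_is_alt, ] <- 1 - freq_alt[!ref_is_alt, , drop = FALSE]
  out <- tibble::tibble(
    marker_id = rep(markers, times = length(eligible)),
    cohort = rep(eligible, each = length(markers)),
    n = as.vector(nn),
    freq_ref = as.vector(freq_ref)
  )
  out$cohort <- factor(out$cohort, levels = eligible, ordered = TRUE)
  attr(out, "skipped_cohorts") <- skipped
  attr(out, "ref_is_alt") <- stats::setNames(ref_is_alt, markers)
  class(out) <- unique(c("bs_traj", class(out)))
  out
}

#' Detect complete reversal of allelic state and fixation
#'
#' With the reference allele defined as the earliest-cohort major allele, a
#' complete reversal is declared when the earliest frequency is at least
#' `0.5 + margin` AND the final frequency is at most `0.5 - margin`. The
#' switch cohort is the earliest cohort after which the reference frequency
#' stays below 0.5 through the final cohort (defined only for reversals).
#' Fixation is a terminal frequency within `1/(2 n_final)` of 0 or 1.
#' Markers observed in fewer than 2 cohorts have `reversal = NA`.
#'
#' @param traj a `bs_traj` tibble from [cohort_frequencies()].
#' @param margin symmetric majority margin (default 0.10).
#' @return Tibble: `marker_id`, `first_freq`, `last_freq`, `delta`,
#'   `reversal`, `switch_cohort`, `fixed`, `n_cohorts`.
#' @export
detect_reversal <- function(traj, margin = 0.10) {
  dplyr::group_by(traj, .data$marker_id) |>
    dplyr::arrange(.data$cohort, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      obs <- df[!is.na(df$freq_ref), , drop = FALSE]
      k <- nrow(obs)
      if (k < 2) {
        return(tibble::tibble(
          first_freq = if (k == 1) obs$freq_ref[1] else NA_real_,
          last_freq = NA_real_, delta = NA_real_, reversal = NA,
          switch_cohort = NA_character_, fixed = NA, n_cohorts = k
        ))
      }
      f <- obs$freq_ref
      first <- f[1]; last <- f[k]
      rev <- first >= 0.5 + margin && last <= 0.5 - margin
      sw <- NA_character_
      if (rev) {
        below <- f < 0.5
        # earliest cohort from which the reference stays minor to the end
        run <- rev(cumprod(rev(below))) == 1
        sw <- as.character(obs$cohort[which(run)[1]])
      }
      tol <- 1 / (2 * obs$n[k])
      tibble::tibble(
        first_freq = first, last_freq = last, delta = abs(first - last),
        reversal = rev, switch_cohort = sw,
        fixed = last <= tol || last >= 1 - tol, n_cohorts = k
      )
    }) |>
    dplyr::ungroup()
}

#' Per-haplotype-locus reversal summary
#'
#' @param loci a `bs_haploci` tibble.
#' @param reversal_tbl output of [detect_reversal()].
#' @return Tibble: `locus_id`, `n_markers`, `n_reversed`,
#'   `prop_reversed`.
#' @export
haplotype_reversal_summary <- function(loci, reversal_tbl) {
  purrr::map2_dfr(loci$locus_id, loci$members, function(id, mem) {
    sub <- reversal_tbl[reversal_tbl$marker_id %in% mem, , drop = FALSE]
    nr <- sum(sub$reversal, na.rm = TRUE)
    tibble::tibble(
      locus_id = id, n_markers = length(mem), n_reversed = nr,
      prop_reversed = if (nrow(sub) > 0) nr / nrow(sub) else NA_real_
    )
  })
}
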