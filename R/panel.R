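#' Genotype panel container
#'
#' A genotype panel is a tibble whose first column `line_id` holds unique line
#' identifiers and whose remaining columns are markers, coded as alt-allele
#' dosage: `0` (homozygous reference), `2` (homozygous alternate), optionally
#' `1` (residual heterozygote), with `NA` for missing calls. Inbred lines are
#' treated downstream as effectively haploid, so the canonical codes are 0/2.
#'
#' @param calls integer matrix, lines in rows (rownames = line ids), markers
#'   in columns (colnames = marker ids); values in \{0, 1, 2, NA\}.
#' @return A `geno_panel` tibble.
#' @export
geno_panel <- function(calls) {
  stopifnot(is.matrix(calls))
  if (is.null(rownames(calls))) rownames(calls) <- paste0("L", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("M", seq_len(ncol(calls)))
  out <- tibble::as_tibble(as.data.frame(calls), .name_repair = "minimal")
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  out <- dplyr::bind_cols(tibble::tibble(line_id = rownames(calls)), out)
  validate_geno_panel(out)
}

#' Coerce a data frame to a genotype panel
#'
#' @param x data frame with a `line_id` first column and integer marker columns.
#' @return A validated `geno_panel` tibble.
#' @export
as_geno_panel <- function(x) {
  stopifnot(is.data.frame(x))
  if (names(x)[1] != "line_id") {
    stop("first column of a genotype panel must be 'line_id', got '", names(x)[1], "'")
  }
  out <- tibble::as_tibble(x)
  out$line_id <- as.character(out$line_id)
  out <- dplyr::mutate(out, dplyr::across(-"line_id", as.integer))
  validate_geno_panel(out)
}

validate_geno_panel <- function(x) {
  if (anyDuplicated(x$line_id)) {
    stop("duplicated line ids: ", paste(unique(x$line_id[duplicated(x$line_id)]), collapse = ", "))
  }
  mk <- setdiff(names(x), "line_id")
  if (anyDuplicated(mk)) {
    stop("duplicated marker ids: ", paste(unique(mk[duplicated(mk)]), collapse = ", "))
  }
  m <- as.matrix(x[mk])
  bad <- which(!(is.na(m) | m %in% c(0L, 1L, 2L)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid genotype code %s at line '%s', marker '%s' (allowed: 0, 1, 2, NA)",
      m[bad[1, 1], bad[1, 2]], x$line_id[bad[1, 1]], mk[bad[1, 2]]
    ))
  }
  class(x) <- unique(c("geno_panel", class(x)))
  x
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf(
    "<geno_panel> %d lines x %d markers (%.1f%% missing)\n",
    nrow(x), ncol(x) - 1L, 100 * mean(is.na(geno_matrix(x)))
  ))
  NextMethod()
}

#' Extract the call matrix of a panel
#'
#' @param panel a `geno_panel`.
#' @return Integer matrix, lines in rows (rownames = line ids).
#' @export
geno_matrix <- function(panel) {
  m <- as.matrix(panel[setdiff(names(panel), "line_id")])
  storage.mode(m) <- "integer"
  rownames(m) <- panel$line_id
  m
}

#' Marker identifiers of a panel
#' @param panel a `geno_panel`.
#' @return Character vector of marker ids in column order.
#' @export
marker_ids <- function(panel) setdiff(names(panel), "line_id")

#' Alternate-allele frequencies per marker
#'
#' Computed over non-missing calls as `mean(calls) / 2`.
#'
#' @param panel a `geno_panel`.
#' @return Named numeric vector of alt-allele frequencies.
#' @export
alt_freq <- function(panel) {
  colMeans(geno_matrix(panel), na.rm = TRUE) / 2
}

#' Derive a substream seed from a global seed
#'
#' Deterministic mixing of a global seed with a stage offset; the result is
#' kept strictly below 2^31 so it is always a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param offset integer stream offset.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 11 * as.double(offset)) %% 2147483629)
}

# Keep marker columns of `panel` (in given order), preserving line_id.
select_markers <- function(panel, keep) {
  out <- panel[c("line_id", keep)]
  class(out) <- unique(c("geno_panel", class(out)))
  out
}
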