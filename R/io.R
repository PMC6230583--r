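#' Read a genotype panel
#'
#' Two formats are supported. `"matrix-tsv"` is the canonical interchange
#' format: a tab-separated file with a header row of marker ids, a first
#' column `line_id`, and cells in \{0, 1, 2, NA\} coding alt-allele dosage.
#' `"vcf"` reads biallelic SNP records from a VCF (v4.x, GT field only);
#' genotypes are converted to alt dosage and missing GT to `NA`.
#'
#' REF/ALT orientation is fixed at load time and never re-polarised
#' downstream; major/minor labels are computed per analysis.
#'
#' @param path file path.
#' @param format `"matrix-tsv"` or `"vcf"`.
#' @return A `geno_panel` tibble (see [geno_panel()]).
#' @export
read_genotypes <- function(path, format = c("matrix-tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix-tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(
      line_id = readr::col_character(), .default = readr::col_character()
    ), na = c("NA", ""), progress = FALSE)
    if (names(df)[1] != "line_id") {
      stop("matrix-tsv must have 'line_id' as its first column; file ", path,
           " starts with '", names(df)[1], "'")
    }
    mk <- setdiff(names(df), "line_id")
    for (j in mk) {
      v <- df[[j]]
      bad <- which(!is.na(v) & !v %in% c("0", "1", "2"))
      if (length(bad) > 0) {
        stop(sprintf("unknown genotype code '%s' at line '%s' (row %d), marker '%s' in %s",
                     v[bad[1]], df$line_id[bad[1]], bad[1], j, path))
      }
      df[[j]] <- as.integer(v)
    }
    as_geno_panel(df)
  } else {
    read_genotypes_vcf(path)
  }
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- which(grepl(",", alt) | nchar(ref) != 1 | nchar(alt) != 1)
  if (length(multi) > 0) {
    stop("non-biallelic-SNP VCF record at ", fix[multi[1], "CHROM"], ":",
         fix[multi[1], "POS"], " (ID ", fix[multi[1], "ID"], ")")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  a <- gsub("\\|", "/", gt)
  dose <- array(NA_integer_, dim = dim(gt))
  dose[a %in% c("0/0", "0")] <- 0L
  dose[a %in% c("0/1", "1/0")] <- 1L
  dose[a %in% c("1/1", "1")] <- 2L
  known <- is.na(a) | a %in% c("./.", ".", "0/0", "0", "0/1", "1/0", "1/1", "1")
  if (any(!known)) stop("unknown GT value '", a[which(!known)[1]], "' in ", path)
  # extract.gt returns variants x samples; panel is lines x markers
  calls <- t(dose)
  dimnames(calls) <- list(colnames(gt), ids)
  geno_panel(calls)
}

#' Write a genotype panel as matrix TSV
#' @param panel a `geno_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  readr::write_tsv(tibble::as_tibble(panel), path, progress = FALSE)
  invisible(path)
}

#' Read a genetic map
#'
#' TSV with columns `marker_id`, `chrom`, `pos_cM`. Chromosome labels follow
#' the tetraploid wheat A/B-genome convention (1A..7B) but any strings are
#' accepted.
#'
#' @param path file path.
#' @return Tibble with columns `marker_id`, `chrom`, `pos_cM`.
#' @export
read_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(), chrom = readr::col_character(),
    pos_cM = readr::col_double()
  ), progress = FALSE)
  validate_map(df)
}

validate_map <- function(df) {
  stopifnot(all(c("marker_id", "chrom", "pos_cM") %in% names(df)))
  if (anyDuplicated(df$marker_id)) {
    stop("marker mapped more than once: ",
         paste(unique(df$marker_id[duplicated(df$marker_id)]), collapse = ", "))
  }
  if (any(df$pos_cM < 0, na.rm = TRUE)) {
    bad <- df$marker_id[which(df$pos_cM < 0)[1]]
    stop("negative cM position at marker '", bad, "'")
  }
  tibble::as_tibble(df)
}

#' Write a genetic map TSV
#' @param map map tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}

#' Read a line trait table (BLUP scale)
#'
#' TSV with a `line_id` column and one numeric column per trait; missing
#' values allowed.
#'
#' @param path file path.
#' @return Tibble.
#' @export
read_traits <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    line_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (names(df)[1] != "line_id") stop("trait table must start with 'line_id': ", path)
  if (anyDuplicated(df$line_id)) {
    stop("duplicated line_id in trait table: ",
         paste(unique(df$line_id[duplicated(df$line_id)]), collapse = ", "))
  }
  df
}

#' Read a cohort table
#'
#' TSV with columns `line_id` and `year_of_entry` (integer year each line
#' entered the registration trial). A decade `cohort` label (e.g. `"1970s"`)
#' is derived.
#'
#' @param path file path.
#' @param year_range plausible range check for years.
#' @return Tibble with `line_id`, `year_of_entry`, `cohort`.
#' @export
read_cohorts <- function(path, year_range = c(1900L, 2100L)) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    line_id = readr::col_character(), year_of_entry = readr::col_integer()
  ), progress = FALSE)
  make_cohorts(df, year_range = year_range)
}

#' Build a cohort table from line ids and entry years
#' @param df data frame with `line_id` and `year_of_entry`.
#' @param year_range plausible range check for years.
#' @return Tibble with `line_id`, `year_of_entry`, ordered-factor `cohort`.
#' @export
make_cohorts <- function(df, year_range = c(1900L, 2100L)) {
  stopifnot(all(c("line_id", "year_of_entry") %in% names(df)))
  if (anyDuplicated(df$line_id)) {
    stop("more than one cohort record for line(s): ",
         paste(unique(df$line_id[duplicated(df$line_id)]), collapse = ", "))
  }
  bad <- which(df$year_of_entry < year_range[1] | df$year_of_entry > year_range[2])
  if (length(bad) > 0) {
    stop("implausible year_of_entry ", df$year_of_entry[bad[1]], " for line '",
         df$line_id[bad[1]], "'")
  }
  dec <- (df$year_of_entry %/% 10L) * 10L
  lab <- paste0(dec, "s")
  lev <- paste0(sort(unique(dec)), "s")
  dplyr::mutate(tibble::as_tibble(df), cohort = factor(lab, levels = lev, ordered = TRUE))
}

#' Write a result table with a JSON run summary
#'
#' Writes `path` as a plain TSV and `<path>.summary.json` with row counts,
#' the settings recorded in `settings`, and the package version, so a run can
#' be audited without re-reading the TSV.
#'
#' @param tbl a result tibble (scan, association, trajectory, ...).
#' @param path output TSV path.
#' @param settings named list echoed into the JSON summary (thresholds, seeds).
#' @return `path`, invisibly.
#' @export
write_results <- function(tbl, path, settings = list()) {
  readr::write_tsv(tibble::as_tibble(tbl), path, progress = FALSE)
  summary <- list(
    rows = nrow(tbl),
    columns = names(tbl),
    settings = settings,
    package_version = as.character(utils::packageVersion("breedscan"))
  )
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path TSV path.
#' @return Tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
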