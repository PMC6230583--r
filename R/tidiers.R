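#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data :=
NULL

#' Tidy a structure result
#'
#' @param x a `bs_structure`.
#' @param ... unused.
#' @return Tibble of per-line assignments and discriminant coordinates.
#' @export
tidy.bs_structure <- function(x, ...) {
  dplyr::left_join(x$assignment, x$coords, by = "line_id")
}

#' @rdname tidy.bs_structure
#' @export
glance.bs_structure <- function(x, ...) {
  tibble::tibble(K = x$K, retained_pcs = x$retained_pcs,
                 bic_min = min(x$bic_by_K$bic))
}

#' Tidy an AMOVA result
#'
#' @param x a `bs_amova`.
#' @param ... unused.
#' @return The variance-partition table as a tibble.
#' @export
tidy.bs_amova <- function(x, ...) x$table

#' @rdname tidy.bs_amova
#' @export
glance.bs_amova <- function(x, ...) {
  tibble::tibble(phi_st = x$phi_st,
                 p_among = x$table$p_value[1],
                 n_perm = x$n_perm)
}

#' Tidy an association scan
#'
#' @param x a `bs_assoc`.
#' @param ... unused.
#' @return The per-locus-per-trait table without the nested effects column.
#' @export
tidy.bs_assoc <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -dplyr::any_of("effects"))
}

#' @rdname tidy.bs_assoc
#' @export
glance.bs_assoc <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    lambda_gc_min = min(x$lambda_gc, na.rm = TRUE),
    lambda_gc_max = max(x$lambda_gc, na.rm = TRUE)
  )
}
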