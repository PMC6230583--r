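# Small fixture builders shared across test files.

# panel from an explicit matrix (lines x markers)
fix_panel <- function(mat, lines = NULL, markers = NULL) {
  if (is.null(lines)) lines <- sprintf("L%02d", seq_len(nrow(mat)))
  if (is.null(markers)) markers <- sprintf("M%02d", seq_len(ncol(mat)))
  dimnames(mat) <- list(lines, markers)
  storage.mode(mat) <- "integer"
  geno_panel(mat)
}

# Balding-Nichols panel with explicit deme allele frequencies q (J x m)
fix_bn_panel <- function(q, lines_per_deme, seed = 1) {
  withr::with_seed(seed, {
    J <- nrow(q); m <- ncol(q)
    calls <- do.call(rbind, lapply(seq_len(J), function(j) {
      matrix(2L * stats::rbinom(lines_per_deme * m, 1,
                                rep(q[j, ], each = lines_per_deme)),
             lines_per_deme, m)
    }))
    panel <- fix_panel(calls)
    list(panel = panel,
         assignment = tibble::tibble(
           line_id = panel$line_id,
           subpop = rep(paste0("SP", seq_len(J)), each = lines_per_deme)
         ))
  })
}

# simple map covering the given markers on one chromosome
fix_map <- function(markers, chrom = "1A", pos = seq_along(markers)) {
  tibble::tibble(marker_id = markers, chrom = chrom, pos_cM = pos)
}

# independent haploid Weir-Cockerham theta via stats::aov mean squares
oracle_theta <- function(panel, assignment) {
  m <- geno_matrix(panel) / 2
  grp <- factor(assignment$subpop[match(panel$line_id, assignment$line_id)])
  comps <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]; g <- grp[!is.na(x)]; x <- x[!is.na(x)]
    g <- droplevels(g)
    if (nlevels(g) < 2) return(c(a = NA_real_, b = NA_real_))
    fit <- stats::aov(x ~ g)
    ms <- summary(fit)[[1]]$`Mean Sq`
    nj <- as.vector(table(g)); N <- sum(nj); r <- nlevels(g)
    nc <- (N - sum(nj^2) / N) / (r - 1)
    a <- (ms[1] - ms[2]) / nc
    c(a = a, b = ms[2])
  })
  comps <- do.call(rbind, comps)
  list(per_locus = ifelse(rowSums(comps) > 0, comps[, 1] / rowSums(comps), NA),
       theta = sum(comps[, 1], na.rm = TRUE) / sum(comps, na.rm = TRUE))
}

# brute-force Benjamini-Hochberg step-up (independent of p.adjust)
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- p[ord] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}
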