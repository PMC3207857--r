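#' Per-base conservation index at one column
#'
#' For a base carried by `n` of the `s` gap-free sequences at a column the
#' index is `(n/s) (log2(1/s) - log2(n/s)) / log2(1/s)`; unrepresented bases
#' score 0 and a monomorphic column scores 1.  The position total (sum over
#' the four bases) equals `1 - H / log2(s)` with `H` the Shannon entropy of
#' the base frequencies, so a fully conserved position scores 1 and a
#' maximally mixed one approaches 0.
#'
#' @param counts named numeric vector of base counts (names among A,C,G,T).
#' @param s number of sequences with a base at the column; `sum(counts) <= s`.
#' @return list with `per_base` (named numeric, A,C,G,T) and `total`.
#' @export
conservation_index <- function(counts, s) {
  if (s < 2L) stop("undefined profile: need s >= 2")
  if (sum(counts) > s + 1e-9) stop("counts exceed s")
  per <- stats::setNames(numeric(4L), c("A", "C", "G", "T"))
  denom <- log2(1 / s)
  for (b in names(counts)) {
    n <- counts[[b]]
    if (n >= 1) per[b] <- (n / s) * (denom - log2(n / s)) / denom
  }
  list(per_base = per, total = sum(per))
}

#' Positional conservation profile of an alignment
#'
#' Computes the per-column conservation totals and an optional centred
#' sliding-window mean for plotting.  At each column, `s` is the number of
#' sequences carrying a base there (gaps and `N` excluded from both `n` and
#' `s`); columns with fewer than two bases are reported as `NA`.
#'
#' @param aln a `haplotype_alignment`.
#' @param window odd window width for smoothing (`1` = none).
#' @param count_gaps_in_s if `TRUE`, use the full alignment depth as `s`
#'   even at gapped columns (alternative reading of the index definition).
#' @return data.frame with `column` (0-based), `s`, `total`, `smoothed`.
#' @export
conservation_profile <- function(aln, window = 11L, count_gaps_in_s = FALSE) {
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd integer >= 1")
  mat <- aln$mat
  L <- ncol(mat); depth <- nrow(mat)
  s_eff <- numeric(L); total <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    s <- if (count_gaps_in_s) depth else length(col)
    s_eff[j] <- length(col)
    if (length(col) >= 2L && s >= 2L)
      total[j] <- conservation_index(table(col), s)$total
  }
  smoothed <- total
  if (window > 1L) {
    half <- (window - 1L) %/% 2L
    smoothed <- vapply(seq_len(L), function(j) {
      idx <- max(1L, j - half):min(L, j + half)
      mean(total[idx], na.rm = TRUE)
    }, 0)
    smoothed[is.nan(smoothed)] <- NA_real_
  }
  data.frame(column = seq_len(L) - 1L, s = s_eff, total = total,
             smoothed = smoothed)
}
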