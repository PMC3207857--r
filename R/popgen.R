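# Site filter shared by all statistics: complete-deletion columns of the
# in-scope sequences ('-' and, by default, 'N' drop the whole column).
species_site_matrix <- function(aln, species = NULL, drop_n = TRUE) {
  mat <- aln$mat
  if (!is.null(species)) mat <- mat[aln$species %in% species, , drop = FALSE]
  if (nrow(mat) == 0L) stop("no sequences for species scope")
  keep <- complete_deletion_sites(
    structure(list(mat = mat, species = rep("x", nrow(mat)), length = ncol(mat)),
              class = "haplotype_alignment"), drop_n = drop_n) + 1L
  mat[, keep, drop = FALSE]
}

# per-column allele counts at gap-free columns; list of named integer vectors
column_allele_counts <- function(mat) {
  lapply(seq_len(ncol(mat)), function(j) table(mat[, j]))
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences per site over all sequence pairs,
#' computed on complete-deletion columns, with the sampling standard
#' deviation of the estimate.
#'
#' @param aln a `haplotype_alignment`.
#' @param species optional species scope (default: all sequences).
#' @return list with `pi` (per site), `sd` (sampling S.D., Nei's
#'   variance for pi), `L` (sites used), `n`.
#' @export
nucleotide_diversity <- function(aln, species = NULL) {
  mat <- species_site_matrix(aln, species)
  n <- nrow(mat); L <- ncol(mat)
  if (n < 2L) stop("insufficient data: need >= 2 sequences")
  if (L == 0L) return(list(pi = NA_real_, sd = NA_real_, L = 0L, n = n))
  diffs <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    diffs <- diffs + sum(mat[i, ] != mat[j, ])
  npairs <- n * (n - 1L) / 2
  pi <- diffs / npairs / L
  # large-sample sampling variance of pi (stochastic + sampling term)
  v <- (n + 1) * pi / (3 * (n - 1) * L) + 2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  list(pi = pi, sd = sqrt(v), L = L, n = n)
}

#' Watterson's estimator of the population mutation rate per site
#'
#' `theta_W = S / (a1 * L)` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S number of segregating sites.
#' @param n number of sequences.
#' @param L number of sites analysed.
#' @return theta per site.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2L || L < 1L) stop("need n >= 2 and L >= 1")
  S / (sum(1 / seq_len(n - 1L)) * L)
}

# segregating sites S, total mutations eta, singleton mutations eta_s
segregating_summary <- function(mat) {
  S <- 0L; eta <- 0L; eta_s <- 0L
  for (j in seq_len(ncol(mat))) {
    tab <- table(mat[, j])
    if (length(tab) > 1L) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      eta_s <- eta_s + sum(tab == 1L & seq_along(tab) != which.max(tab))
    }
  }
  list(S = S, eta = eta, eta_s = eta_s)
}

# Tajima (1989) constants
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L)); a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Contrast of mean pairwise differences against the segregating-sites
#' estimate of theta, standardised by its neutral-model variance.  Undefined
#' (returned as `NA`) when there is no segregating site.
#'
#' @inheritParams nucleotide_diversity
#' @return list with `D` (`NA` if `S = 0`), `S`, `pi_total` (pairwise
#'   differences per sequence pair, not per site), `n`, `L`.
#' @export
tajimas_d <- function(aln, species = NULL) {
  mat <- species_site_matrix(aln, species)
  n <- nrow(mat)
  if (n < 2L) stop("insufficient data: need >= 2 sequences")
  seg <- segregating_summary(mat)
  S <- seg$S
  diffs <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    diffs <- diffs + sum(mat[i, ] != mat[j, ])
  pi_total <- diffs / (n * (n - 1L) / 2)
  if (S == 0L)
    return(list(D = NA_real_, S = 0L, pi_total = pi_total, n = n, L = ncol(mat)))
  k <- tajima_constants(n)
  D <- (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  list(D = D, S = S, pi_total = pi_total, n = n, L = ncol(mat))
}

# Fu & Li (1993) constants, with the Simonsen et al. (1995) correction for D*
fu_li_constants <- function(n) {
  a <- sum(1 / seq_len(n - 1L)); b <- sum(1 / seq_len(n - 1L)^2)
  cn <- if (n == 2L) 1 else 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + (a^2 / (b + a^2)) * (cn - (n + 1) / (n - 1))
  uD <- a - 1 - vD
  an1 <- a + 1 / n
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDs <- ((n / (n - 1))^2 * b + a^2 * dn - 2 * (n * a * (a + 1)) / (n - 1)^2) /
    (a^2 + b)
  uDs <- (n / (n - 1)) * (a - n / (n - 1)) - vDs
  list(a = a, b = b, vD = vD, uD = uD, vDs = vDs, uDs = uDs)
}

#' Fu and Li's D statistic
#'
#' With an outgroup sequence the statistic contrasts total mutations against
#' mutations on external branches (derived singletons, polarised by the
#' outgroup).  Without an outgroup the starred variant `D*` is computed from
#' unpolarised singletons.  The variant used is recorded in the output.
#'
#' @inheritParams nucleotide_diversity
#' @param outgroup single aligned outgroup sequence (same column frame) used
#'   to polarise variants, or `NULL` for the `D*` variant.
#' @return list with `D` (`NA` if `S = 0`), `variant` (`"with_outgroup"` or
#'   `"star"`), `eta`, `eta_singleton`, `n`.
#' @export
fu_li_d <- function(aln, species = NULL, outgroup = NULL) {
  mat <- species_site_matrix(aln, species)
  n <- nrow(mat)
  if (n < 3L) stop("insufficient data: need >= 3 sequences")
  og <- NULL
  if (!is.null(outgroup)) {
    og <- strsplit(toupper(outgroup), "")[[1L]]
    if (length(og) != aln$length)
      stop("outgroup length must match the alignment column frame")
    # restrict the outgroup to the same complete-deletion columns
    full <- aln$mat
    if (!is.null(species)) full <- full[aln$species %in% species, , drop = FALSE]
    keep <- complete_deletion_sites(structure(
      list(mat = full, species = rep("x", nrow(full)), length = ncol(full)),
      class = "haplotype_alignment")) + 1L
    og <- og[keep]
  }
  seg <- segregating_summary(mat)
  eta <- seg$eta
  if (seg$S == 0L)
    return(list(D = NA_real_, variant = if (is.null(og)) "star" else "with_outgroup",
                eta = 0L, eta_singleton = 0L, n = n))
  k <- fu_li_constants(n)
  if (is.null(og)) {
    eta_s <- seg$eta_s
    D <- ((n / (n - 1)) * eta - k$a * eta_s) /
      sqrt(k$uDs * eta + k$vDs * eta^2)
    variant <- "star"
  } else {
    # external-branch mutations: derived allele (!= outgroup base) seen once
    eta_s <- 0L
    for (j in seq_len(ncol(mat))) {
      tab <- table(mat[, j])
      if (length(tab) > 1L && og[j] %in% names(tab))
        eta_s <- eta_s + sum(tab == 1L & names(tab) != og[j])
    }
    D <- (eta - k$a * eta_s) / sqrt(k$uD * eta + k$vD * eta^2)
    variant <- "with_outgroup"
  }
  list(D = D, variant = variant, eta = eta, eta_singleton = eta_s, n = n)
}

#' Haplotype count and haplotype diversity
#'
#' `h` is the number of distinct sequences over complete-deletion columns;
#' `hd = (n/(n-1)) (1 - sum p_i^2)` is the sample-size-corrected probability
#' that two sampled sequences differ.
#'
#' @inheritParams nucleotide_diversity
#' @return list with `h`, `hd`, `n`.
#' @export
haplotype_stats <- function(aln, species = NULL) {
  mat <- species_site_matrix(aln, species)
  n <- nrow(mat)
  if (n < 2L) stop("insufficient data: need >= 2 sequences")
  seqs <- apply(mat, 1L, paste, collapse = "")
  p <- as.numeric(table(seqs)) / n
  list(h = length(p), hd = (n / (n - 1)) * (1 - sum(p^2)), n = n)
}

#' Full diversity summary for one species
#'
#' Bundles the statistics of the per-population summary tables: sample size,
#' sites analysed, segregating sites and mutations, pi, Watterson's theta,
#' haplotype statistics and the neutrality tests.
#'
#' @inheritParams fu_li_d
#' @return a one-row `data.frame`.
#' @export
diversity_summary <- function(aln, species = NULL, outgroup = NULL) {
  mat <- species_site_matrix(aln, species)
  n <- nrow(mat); L <- ncol(mat)
  seg <- segregating_summary(mat)
  pid <- nucleotide_diversity(aln, species)
  hap <- haplotype_stats(aln, species)
  taj <- tajimas_d(aln, species)
  fl <- if (n >= 3L) fu_li_d(aln, species, outgroup)
        else list(D = NA_real_, variant = NA_character_)
  data.frame(species = if (is.null(species)) "all" else paste(species, collapse = "+"),
             n = n, total_sites = aln$length, sites_nogap = L,
             S = seg$S, eta = seg$eta, eta_singleton = seg$eta_s,
             pi = pid$pi, pi_sd = pid$sd,
             theta_w = watterson_theta(max(seg$S, 0L), n, L),
             h = hap$h, hd = hap$hd,
             tajima_d = taj$D, fu_li_d = fl$D, fu_li_variant = fl$variant,
             stringsAsFactors = FALSE)
}
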