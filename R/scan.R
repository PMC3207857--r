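revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1L]]), collapse = ""))
}

#' Exact binding-site scan (strict, no mismatches)
#'
#' Reports every occurrence (all offsets, overlaps allowed) of every library
#' site of length at least `min_len` in an ungapped sequence.  This is the
#' stringent annotation route: a site must align perfectly to a catalogued
#' binding sequence of at least 5 bp.
#'
#' @param sequence ungapped DNA string.
#' @param library a `motif_library` with exact sites.
#' @param min_len minimum site length considered (default 5).
#' @param both_strands also scan the reverse complement (default `FALSE`).
#' @return an `annotation_track` (method `PATCH`) on the ungapped frame.
#' @export
patch_scan <- function(sequence, library, min_len = 5L, both_strands = FALSE) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  sites <- library$exact_sites
  sites <- sites[nchar(sites$site) >= min_len, , drop = FALSE]
  out <- list()
  if (L > 0L && nrow(sites)) {
    subj <- Biostrings::DNAString(sequence)
    for (k in seq_len(nrow(sites))) {
      for (str in c("+", if (both_strands) "-")) {
        pat <- if (str == "+") sites$site[k] else revcomp(sites$site[k])
        m <- Biostrings::matchPattern(pat, subj)
        if (length(m))
          out[[length(out) + 1L]] <- data.frame(
            start = Biostrings::start(m) - 1L, end = Biostrings::end(m),
            factor = sites$factor[k], strand = str)
      }
    }
  }
  iv <- if (length(out)) do.call(rbind, out) else NULL
  if (!is.null(iv)) iv <- iv[order(iv$start, iv$end, iv$factor), , drop = FALSE]
  annotation_track(iv, "PATCH", max(L, 1L), "ungapped")
}

# min-max normalised information-weighted similarity of a window to a PWM
# (frequencies f, information vector I); returns NA if the window has
# ambiguous characters
pwm_window_score <- function(freq, info, window_chars, positions) {
  idx <- match(window_chars[positions], c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  cur <- sum(info[positions] * freq[cbind(idx, positions)])
  mn <- sum(info[positions] * apply(freq[, positions, drop = FALSE], 2L, min))
  mx <- sum(info[positions] * apply(freq[, positions, drop = FALSE], 2L, max))
  if (mx - mn == 0) return(1)   # degenerate stretch: any base is a perfect match
  (cur - mn) / (mx - mn)
}

#' Position-weight-matrix scan with a strict core cutoff
#'
#' Scores every window of each PWM's width with the min-max normalised,
#' information-weighted matrix similarity; a hit must reach 100% similarity
#' over the 5 consecutive core positions (`core_cut`) and at least
#' `overall_cut` over the whole matrix.  Hits carry the core span so that
#' core-only tracks can be derived.
#'
#' @param sequence ungapped DNA string.
#' @param library a `motif_library` with PWMs.
#' @param core_cut minimum core similarity (default 1.0, strict).
#' @param overall_cut minimum overall similarity (default 0.7).
#' @param min_len PWMs narrower than this are skipped (default 5).
#' @param both_strands also scan the reverse complement.
#' @return an `annotation_track` (method `MATCH`) whose intervals carry
#'   `overall`, `core` scores and `core_start`/`core_end` (0-based half-open).
#' @export
match_scan <- function(sequence, library, core_cut = 1.0, overall_cut = 0.7,
                       min_len = 5L, both_strands = FALSE) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  out <- list()
  for (p in library$pwms) {
    w <- ncol(p$counts)
    if (w < min_len) next
    freq <- p$counts / rep(colSums(p$counts), each = 4L)
    info <- pwm_information(freq)
    if (all(apply(freq, 2L, max) - apply(freq, 2L, min) == 0))
      stop("matrix error: degenerate PWM for factor ", p$factor)
    core_pos <- (p$core_start + 1L):(p$core_start + 5L)
    for (str in c("+", if (both_strands) "-")) {
      seq_use <- if (str == "+") sequence else revcomp(sequence)
      chars <- strsplit(seq_use, "")[[1L]]
      if (L < w) next
      for (s0 in 0:(L - w)) {
        win <- chars[(s0 + 1L):(s0 + w)]
        core <- pwm_window_score(freq, info, win, core_pos)
        if (is.na(core) || core < core_cut - 1e-12) next
        overall <- pwm_window_score(freq, info, win, seq_len(w))
        if (is.na(overall) || overall < overall_cut - 1e-12) next
        st <- if (str == "+") s0 else L - (s0 + w)
        cs <- if (str == "+") s0 + p$core_start else L - (s0 + p$core_start + 5L)
        out[[length(out) + 1L]] <- data.frame(
          start = st, end = st + w, factor = p$factor, strand = str,
          overall = overall, core = core, core_start = cs, core_end = cs + 5L)
      }
    }
  }
  iv <- if (length(out)) do.call(rbind, out) else NULL
  if (!is.null(iv)) iv <- iv[order(iv$start, iv$end, iv$factor), , drop = FALSE]
  annotation_track(iv, "MATCH", max(L, 1L), "ungapped")
}

#' Restrict a PWM-scan track to the core positions of its hits
#'
#' @param match_track an `annotation_track` from [match_scan()] whose
#'   intervals carry `core_start` / `core_end`.
#' @return an `annotation_track` (method `MATCH_CORE`) whose intervals are
#'   the core spans only; the core mask is contained in the full-hit mask.
#' @export
core_only_track <- function(match_track) {
  iv <- match_track$intervals
  if (nrow(iv) && !all(c("core_start", "core_end") %in% names(iv)))
    stop("track has no core spans; run match_scan first")
  if (nrow(iv)) {
    iv <- data.frame(start = iv$core_start, end = iv$core_end,
                     factor = iv$factor, strand = iv$strand)
  }
  annotation_track(iv, "MATCH_CORE", match_track$frame_length,
                   match_track$frame, match_track$frame_ref)
}

#' Phylogenetic footprint partition against a distant outgroup
#'
#' Splits the columns at which the outgroup carries a base into well-aligned
#' and poorly-aligned regions: a column is well-aligned iff it lies inside at
#' least one stretch of `min_window` consecutive outgroup bases of which at
#' least `min_matches` match (equal) an ingroup base at the same column.
#' Overlapping qualifying stretches merge; all other outgroup-base columns
#' are poorly aligned.
#'
#' @param aln a `haplotype_alignment` that contains the outgroup row.
#' @param outgroup_id haplotype id of the outgroup row.
#' @param min_window stretch length in outgroup bases (default 6).
#' @param min_matches minimum matching columns per stretch (default 5).
#' @return list with `track` (an `annotation_track`, method `PHYLO`, whose
#'   intervals are maximal runs of well-aligned columns), `well_mask`
#'   (logical over all columns; `FALSE` wherever the outgroup is gapped),
#'   `outgroup_columns` (0-based columns with an outgroup base) and
#'   `fraction_well` (share of outgroup-base columns that are well-aligned).
#' @export
phylo_footprint <- function(aln, outgroup_id, min_window = 6L, min_matches = 5L) {
  og <- aln$mat[outgroup_id, ]
  in_mat <- aln$mat[setdiff(rownames(aln$mat), outgroup_id), , drop = FALSE]
  base_cols <- which(og %in% c("A", "C", "G", "T"))
  if (length(base_cols) == 0L) stop("undefined partition: outgroup has no bases")
  match_col <- vapply(base_cols, function(j) og[j] %in% in_mat[, j], TRUE)
  nb <- length(base_cols)
  well <- logical(nb)
  if (nb >= min_window) {
    for (s in 1:(nb - min_window + 1L)) {
      idx <- s:(s + min_window - 1L)
      if (sum(match_col[idx]) >= min_matches) well[idx] <- TRUE
    }
  }
  well_mask <- logical(aln$length)
  well_mask[base_cols[well]] <- TRUE
  # maximal runs of consecutive well-aligned columns as track intervals
  iv <- NULL
  r <- rle(well_mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs))
    iv <- data.frame(start = starts[runs] - 1L, end = ends[runs],
                     factor = "well_aligned", strand = ".")
  list(track = annotation_track(iv, "PHYLO", aln$length, "alignment_columns"),
       well_mask = well_mask,
       outgroup_columns = base_cols - 1L,
       fraction_well = mean(well))
}
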