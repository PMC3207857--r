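TRACK_METHODS <- c("PATCH", "MATCH", "MATCH_CORE", "DNASE", "PHYLO", "COMBINED", "TRUTH")

#' Construct an annotation track
#'
#' A method-tagged set of intervals (TFBS hits, DNase footprints, well-aligned
#' footprint regions, ...) on either alignment columns or the ungapped
#' coordinates of one haplotype.  Intervals are 0-based half-open and may
#' overlap; the TFBS/NTFBS dichotomy is always taken from the union mask.
#'
#' @param intervals data.frame with columns `start`, `end` (0-based
#'   half-open), `factor` (character) and optionally `strand` (`+`,`-`,`.`).
#'   Extra columns (e.g. PWM scores, core spans) are preserved.
#' @param method one of `PATCH, MATCH, MATCH_CORE, DNASE, PHYLO, COMBINED, TRUTH`.
#' @param frame_length number of positions in the coordinate frame.
#' @param frame `"alignment_columns"` or `"ungapped"`.
#' @param frame_ref haplotype id the frame refers to when `frame = "ungapped"`.
#' @return an object of class `annotation_track`.
#' @export
annotation_track <- function(intervals, method, frame_length,
                             frame = c("alignment_columns", "ungapped"),
                             frame_ref = NULL) {
  frame <- match.arg(frame)
  method <- match.arg(method, TRACK_METHODS)
  if (is.null(intervals) || nrow(intervals) == 0L) {
    intervals <- data.frame(start = integer(), end = integer(),
                            factor = character(), strand = character())
  }
  if (!all(c("start", "end", "factor") %in% names(intervals)))
    stop("intervals need columns start, end, factor")
  if (is.null(intervals$strand)) intervals$strand <- rep(".", nrow(intervals))
  if (nrow(intervals)) {
    if (any(intervals$end <= intervals$start))
      stop("interval error: end <= start")
    if (any(intervals$start < 0L) || any(intervals$end > frame_length))
      stop("interval error: interval outside frame [0,", frame_length, ")")
  }
  rownames(intervals) <- NULL
  structure(list(method = method, intervals = intervals,
                 frame = frame, frame_ref = frame_ref,
                 frame_length = as.integer(frame_length)),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat("annotation_track [", x$method, "]: ", nrow(x$intervals),
      " intervals on ", x$frame_length, " ", x$frame, "\n", sep = "")
  invisible(x)
}

#' Union coverage mask of a track
#'
#' @param track an `annotation_track`.
#' @return logical vector of length `frame_length`; element `i` is `TRUE` iff
#'   0-based position `i - 1` lies inside at least one interval.
#' @export
track_mask <- function(track) {
  mask <- logical(track$frame_length)
  iv <- track$intervals
  for (k in seq_len(nrow(iv))) mask[(iv$start[k] + 1L):iv$end[k]] <- TRUE
  mask
}

#' Read a BED-dialect interval file as an annotation track
#'
#' Uses columns 2,3 (0-based half-open), 4 (name, optional) and 6 (strand,
#' optional); column 1 (chrom) is ignored beyond a consistency check.
#'
#' @param path BED file (3+ columns, tab separated, `#` comments allowed).
#' @param method track method tag.
#' @param frame_length coordinate frame length.
#' @inheritParams annotation_track
#' @return an `annotation_track`.
#' @export
read_interval_track <- function(path, method, frame_length,
                                frame = "alignment_columns", frame_ref = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("format error: BED needs >= 3 columns")
  iv <- data.frame(start = as.integer(bed[[2L]]), end = as.integer(bed[[3L]]),
                   factor = if (ncol(bed) >= 4L) as.character(bed[[4L]]) else ".",
                   strand = if (ncol(bed) >= 6L) as.character(bed[[6L]]) else ".")
  annotation_track(iv, method, frame_length, frame, frame_ref)
}

#' Write an annotation track as BED
#' @param track an `annotation_track`.
#' @param path output path.
#' @param chrom name for the first BED column.
#' @return `path`, invisibly.
#' @export
write_interval_track <- function(track, path, chrom = "region") {
  iv <- track$intervals
  bed <- data.frame(chrom = rep(chrom, nrow(iv)), start = iv$start, end = iv$end,
                    name = iv$factor, score = rep(0L, nrow(iv)), strand = iv$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Lift a track between ungapped and alignment-column frames
#'
#' An interval on the ungapped sequence of a haplotype becomes the smallest
#' column interval containing the images of its positions (gap columns inside
#' a site remain covered, matching how a binding site spans an alignment
#' insertion in another sequence).  The reverse lift drops positions that
#' fall on gaps of the reference haplotype.
#'
#' @param track an `annotation_track`.
#' @param aln the `haplotype_alignment` providing the gap pattern.
#' @param haplotype_id reference haplotype.
#' @param min_len hits whose ungapped extent is below `min_len` after the
#'   reverse lift are dropped (default 1: keep all).
#' @return an `annotation_track` in the other frame.
#' @export
lift_track <- function(track, aln, haplotype_id, min_len = 1L) {
  iv <- track$intervals
  if (track$frame == "ungapped") {
    map <- ungapped_to_columns(aln, haplotype_id)  # ungapped pos -> column
    if (nrow(iv)) {
      iv$start <- map[iv$start + 1L]
      iv$end <- map[iv$end] + 1L                  # last covered pos, then half-open
    }
    annotation_track(iv, track$method, aln$length, "alignment_columns")
  } else {
    inv <- columns_to_ungapped(aln, haplotype_id) # column -> ungapped pos or NA
    n_ungap <- sum(!is.na(inv))
    keep <- logical(nrow(iv))
    for (k in seq_len(nrow(iv))) {
      pos <- inv[(iv$start[k] + 1L):iv$end[k]]
      pos <- pos[!is.na(pos)]
      if (length(pos) >= min_len) {
        keep[k] <- TRUE
        iv$start[k] <- min(pos); iv$end[k] <- max(pos) + 1L
      }
    }
    annotation_track(iv[keep, , drop = FALSE], track$method, n_ungap,
                     "ungapped", frame_ref = haplotype_id)
  }
}

#' Union of two annotation tracks
#'
#' @param track_a,track_b `annotation_track`s on the same frame.
#' @param method method tag of the result (default `COMBINED`).
#' @return an `annotation_track` whose intervals are the concatenation; the
#'   union mask is the logical OR of the input masks.
#' @export
combine_tracks <- function(track_a, track_b, method = "COMBINED") {
  if (track_a$frame != track_b$frame ||
      track_a$frame_length != track_b$frame_length)
    stop("frame error: tracks are on different frames")
  cols <- c("start", "end", "factor", "strand")
  iv <- rbind(track_a$intervals[, cols, drop = FALSE],
              track_b$intervals[, cols, drop = FALSE])
  annotation_track(iv, method, track_a$frame_length, track_a$frame,
                   track_a$frame_ref)
}
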