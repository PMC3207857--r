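#' Construct a motif library
#'
#' Holds the two motif input flavours used by the annotation scans: exact
#' binding-site sequences (for the strict no-mismatch scan) and count-based
#' position weight matrices (for the similarity-score scan).  The library is
#' a small stand-in for a curated TFBS database; the packaged toy library
#' ([toy_motif_library()]) is synthetic.
#'
#' @param exact_sites data.frame with columns `factor`, `site` (uppercase
#'   ACGT strings), or `NULL`.
#' @param pwms list of PWM entries, each a list with elements `factor`,
#'   `counts` (4 x w numeric matrix, rownames `A,C,G,T`, constant column
#'   sums) and `core_start` (0-based start of the 5-position core), or `NULL`.
#'   A missing `core_start` defaults to the maximal-information 5-window.
#' @return object of class `motif_library`.
#' @export
motif_library <- function(exact_sites = NULL, pwms = NULL) {
  if (is.null(exact_sites))
    exact_sites <- data.frame(factor = character(), site = character())
  exact_sites$site <- toupper(exact_sites$site)
  if (nrow(exact_sites) &&
      any(!grepl("^[ACGT]+$", exact_sites$site)))
    stop("exact sites must be non-empty ACGT strings")
  pwms <- lapply(pwms %||% list(), function(p) {
    m <- p$counts
    if (!is.matrix(m) || nrow(m) != 4L)
      stop("PWM counts must be a 4 x w matrix")
    rownames(m) <- c("A", "C", "G", "T")
    cs <- colSums(m)
    if (any(abs(cs - cs[1L]) > 1e-8))
      stop("PWM column sums must be constant")
    w <- ncol(m)
    core <- p$core_start
    if (is.null(core)) core <- default_core_start(m)
    if (core < 0L || core + 5L > w)
      stop("core positions must lie within the matrix width")
    list(factor = p$factor, counts = m, core_start = as.integer(core))
  })
  structure(list(exact_sites = exact_sites, pwms = pwms),
            class = "motif_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based start of the most informative 5-position window
default_core_start <- function(counts) {
  w <- ncol(counts)
  if (w < 5L) stop("PWM width below the 5-position core")
  info <- pwm_information(counts / rep(colSums(counts), each = 4L))
  win <- vapply(0:(w - 5L), function(s) sum(info[(s + 1L):(s + 5L)]), 0)
  which.max(win) - 1L
}

# per-position information vector I(i) = sum_b f(i,b) ln(4 f(i,b)); 0 ln 0 = 0
pwm_information <- function(freq) {
  apply(freq, 2L, function(f) sum(ifelse(f > 0, f * log(4 * f), 0)))
}

#' @export
print.motif_library <- function(x, ...) {
  cat("motif_library:", nrow(x$exact_sites), "exact sites,",
      length(x$pwms), "PWMs\n")
  invisible(x)
}

#' Read an exact-site library from TSV
#'
#' Expected format: two tab-separated columns `factor<TAB>sequence`, one
#' site per line, `#` comments allowed.
#'
#' @param path TSV file.
#' @return a `motif_library` with exact sites only.
#' @export
read_exact_site_library <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  motif_library(exact_sites = data.frame(factor = as.character(tab[[1L]]),
                                         site = as.character(tab[[2L]])))
}

#' Read TRANSFAC-style count matrices
#'
#' Parses flat matrix blocks: an `ID` (or `NA`) line naming the factor,
#' numbered rows of four counts (A C G T order), an optional `CC core=<s>`
#' line giving the 0-based core start, blocks terminated by `//`.
#'
#' @param path flat file of matrix blocks.
#' @return a `motif_library` with PWMs only.
#' @export
read_transfac_pwms <- function(path) {
  lines <- readLines(path)
  pwms <- list(); rows <- NULL; fac <- NULL; core <- NULL
  flush <- function() {
    if (!is.null(rows)) {
      pwms[[length(pwms) + 1L]] <<- list(factor = fac %||% "unknown",
                                         counts = t(rows), core_start = core)
    }
    rows <<- NULL; fac <<- NULL; core <<- NULL
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" ) next
    if (grepl("^//", ln)) { flush(); next }
    if (grepl("^(ID|NA)\\s", ln)) { fac <- sub("^(ID|NA)\\s+", "", ln); next }
    if (grepl("^CC\\s+core=", ln)) { core <- as.integer(sub(".*core=", "", ln)); next }
    if (grepl("^[0-9]+\\s", ln)) {
      parts <- strsplit(ln, "\\s+")[[1L]]
      rows <- rbind(rows, as.numeric(parts[2:5]))
    }
  }
  flush()
  motif_library(pwms = pwms)
}

#' Write PWMs in the TRANSFAC-style flat format read by [read_transfac_pwms()]
#' @param lib a `motif_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transfac_pwms <- function(lib, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in lib$pwms) {
    writeLines(c(paste("ID", p$factor), "P0 A C G T"), con)
    for (i in seq_len(ncol(p$counts)))
      writeLines(sprintf("%02d %s", i,
                         paste(format(p$counts[, i]), collapse = " ")), con)
    writeLines(c(paste0("CC core=", p$core_start), "//"), con)
  }
  invisible(path)
}

#' A small synthetic motif library for examples, tests and simulations
#'
#' Entirely synthetic stand-in for a curated insect TFBS collection: a few
#' exact sites of length 5-8 named after well-known segmentation factors,
#' and two toy count matrices.  It carries no information from any real
#' motif database.
#'
#' @return a `motif_library`.
#' @export
toy_motif_library <- function() {
  exact <- data.frame(
    factor = c("eve", "ftz", "cad", "ttk", "gaga", "hb", "en", "bcd"),
    site   = c("TTCGAA", "GGATTA", "TTTATG", "AGGATAA", "GAGAG",
               "CATAAAAA", "TAATTG", "GGGATTAG"))
  pwm1 <- matrix(c(
    8, 1, 0, 1,   # A C G T counts per position (columns of the 4 x w matrix)
    0, 0, 9, 1,
    9, 0, 1, 0,
    0, 1, 0, 9,
    1, 8, 1, 0,
    3, 3, 2, 2), nrow = 4L)
  pwm2 <- matrix(c(
    10, 0, 0, 0,
    0, 0, 0, 10,
    0, 0, 10, 0,
    10, 0, 0, 0,
    0, 10, 0, 0,
    5, 2, 2, 1,
    4, 3, 2, 1), nrow = 4L)
  motif_library(exact_sites = exact,
                pwms = list(list(factor = "zld", counts = pwm1, core_start = 0L),
                            list(factor = "kr", counts = pwm2, core_start = 0L)))
}
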