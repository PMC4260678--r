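#' @keywords internal
"_PACKAGE"

# Bases carried by a sync count string, in column order.
SYNC_BASES <- c("A", "T", "C", "G", "N", "del")
NUCLEOTIDES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Display rounding used for reported ratios and summary statistics:
#' ties are rounded away from zero (so 0.125 -> 0.13 at 2 digits), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Map a frequency in [0, 1] to the nearest count in 0..N, half away from zero.
freq_to_count <- function(freq, N) {
  stopifnot(all(freq >= 0 & freq <= 1), N >= 1)
  as.integer(floor(freq * N + 0.5))
}

# Largest-remainder apportionment of n among categories with the given
# frequencies; result is integer and sums exactly to n.
largest_remainder <- function(frequencies, n) {
  stopifnot(abs(sum(frequencies) - 1) < 1e-9, n >= 0)
  raw <- frequencies * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

# Informational logging to stderr; silenced by options(cytodrift.quiet = TRUE).
cd_log <- function(fmt, ...) {
  if (!isTRUE(getOption("cytodrift.quiet", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

#' Path to a packaged example file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path, or a character vector of file names.
#' @export
cytodrift_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cytodrift")))
  }
  path <- system.file("extdata", file, package = "cytodrift")
  if (path == "") stop("no packaged file named '", file, "'", call. = FALSE)
  path
}
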