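#' Pool-Seq allele counts in sync form
#'
#' Constructor for the in-memory representation of PoPoolation2 "sync"
#' data: per site and per replicate, six integer counts in the fixed order
#' A, T, C, G, N, del.
#'
#' @param sites data frame with columns `contig`, `position` (1-based),
#'   `reference` (single base).
#' @param counts integer array of dimension (sites, 6, replicates); the
#'   second dimension must be named `A,T,C,G,N,del`.
#' @return an object of class `"sync"`.
#' @export
sync <- function(sites, counts) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "position", "reference") %in% names(sites)))
  if (length(dim(counts)) != 3 || dim(counts)[2] != 6) {
    stop("counts must be a (sites x 6 x replicates) array", call. = FALSE)
  }
  if (dim(counts)[1] != nrow(sites)) {
    stop("counts and sites disagree on the number of sites", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  dimnames(counts)[[2]] <- SYNC_BASES
  if (is.null(dimnames(counts)[[3]])) {
    dimnames(counts)[[3]] <- paste0("rep", seq_len(dim(counts)[3]))
  }
  structure(list(sites = sites, counts = counts), class = "sync")
}

#' @export
print.sync <- function(x, ...) {
  cat(sprintf("sync: %d site(s), %d replicate(s) [%s]\n",
              nrow(x$sites), dim(x$counts)[3],
              paste(dimnames(x$counts)[[3]], collapse = ", ")))
  cov <- apply(x$counts, c(1, 3), sum)
  cat("mean coverage per replicate:",
      paste(round(colMeans(cov), 1), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.sync <- function(x, ...) {
  reps <- dimnames(x$counts)[[3]]
  out <- x$sites
  for (r in seq_along(reps)) {
    out[[reps[r]]] <- apply(x$counts[, , r, drop = FALSE], 1,
                            function(v) paste(v, collapse = ":"))
  }
  out
}

#' Read a PoPoolation2 sync file
#'
#' Parses a tab-separated sync file: contig, 1-based position, reference
#' base, then one `A:T:C:G:N:del` count string per replicate. Plain and
#' gzip-compressed files are accepted. Replicate column order is preserved.
#'
#' @param path file path.
#' @return a [sync()] object; an empty file yields a zero-site object with a
#'   warning.
#' @export
read_sync <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty sync file: ", path, call. = FALSE)
    return(sync(data.frame(contig = character(), position = integer(),
                           reference = character()),
                array(integer(), dim = c(0, 6, 1))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 4)) {
    stop("sync parse error at line ", which(ncols < 4)[1],
         ": fewer than 4 tab-separated columns", call. = FALSE)
  }
  if (length(unique(ncols)) != 1) {
    stop("sync parse error at line ", which(ncols != ncols[1])[1],
         ": inconsistent column count", call. = FALSE)
  }
  n_rep <- ncols[1] - 3
  n_site <- length(lines)
  counts <- array(NA_integer_, dim = c(n_site, 6, n_rep),
                  dimnames = list(NULL, SYNC_BASES,
                                  paste0("rep", seq_len(n_rep))))
  for (i in seq_len(n_site)) {
    for (r in seq_len(n_rep)) {
      parts <- strsplit(fields[[i]][3 + r], ":", fixed = TRUE)[[1]]
      vals <- suppressWarnings(as.integer(parts))
      if (length(vals) != 6 || anyNA(vals) || any(vals < 0)) {
        stop("sync parse error at line ", i, ": malformed count string '",
             fields[[i]][3 + r], "'", call. = FALSE)
      }
      counts[i, , r] <- vals
    }
  }
  sites <- data.frame(
    contig = vapply(fields, `[`, "", 1),
    position = as.integer(vapply(fields, `[`, "", 2)),
    reference = vapply(fields, `[`, "", 3),
    stringsAsFactors = FALSE
  )
  if (anyNA(sites$position)) {
    stop("sync parse error at line ", which(is.na(sites$position))[1],
         ": non-integer position", call. = FALSE)
  }
  sync(sites, counts)
}

#' Write a sync object to a file
#'
#' Emits the headerless tab-separated sync format, byte-compatible with
#' [read_sync()].
#'
#' @param x a [sync()] object.
#' @param path output file path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "sync"))
  df <- as.data.frame(x)
  lines <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Sample Pool-Seq read counts at clade-diagnostic SNPs
#'
#' Observation model for pooled sequencing of a population with known clade
#' frequencies. Per site, depth is Poisson with mean `mean_coverage`; the
#' diagnostic-allele count is binomial with success probability equal to the
#' owning clade's frequency perturbed by sequencing error
#' (`p(1 - e) + (1 - p) e/3`); all remaining reads are assigned the
#' reference allele.
#'
#' @param clade_frequencies named numeric vector of clade frequencies
#'   (summing to at most 1; the remainder is reference background), or a
#'   matrix with one row per replicate and clades in columns.
#' @param snp_table a clade-diagnostic SNP table (see
#'   [identify_diagnostic_snps()]): columns `contig`, `position`, `allele`,
#'   `clade`.
#' @param mean_coverage mean sequencing depth per site (> 0).
#' @param error_rate per-base sequencing error fraction, default `0.002`.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return a [sync()] object with one replicate per row of
#'   `clade_frequencies`.
#' @export
sample_poolseq_counts <- function(clade_frequencies, snp_table,
                                  mean_coverage, error_rate = 0.002,
                                  seed = NULL) {
  if (mean_coverage <= 0) stop("mean_coverage must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate > 1) {
    stop("error_rate must be in [0, 1]", call. = FALSE)
  }
  if (is.null(dim(clade_frequencies))) {
    clade_frequencies <- matrix(clade_frequencies, nrow = 1,
                                dimnames = list(NULL,
                                                names(clade_frequencies)))
  }
  if (any(rowSums(clade_frequencies) > 1 + 1e-9)) {
    stop("clade frequencies must sum to <= 1 per replicate", call. = FALSE)
  }
  missing_clades <- setdiff(snp_table$clade, colnames(clade_frequencies))
  if (length(missing_clades)) {
    stop("no frequency given for clade(s): ",
         paste(missing_clades, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_snp <- nrow(snp_table)
  n_rep <- nrow(clade_frequencies)
  counts <- array(0L, dim = c(n_snp, 6, n_rep),
                  dimnames = list(NULL, SYNC_BASES,
                                  paste0("rep", seq_len(n_rep))))
  # reference base: any nucleotide other than the diagnostic allele
  refs <- vapply(snp_table$allele,
                 function(a) setdiff(NUCLEOTIDES, a)[1], "")
  for (r in seq_len(n_rep)) {
    depth <- stats::rpois(n_snp, mean_coverage)
    p <- clade_frequencies[r, snp_table$clade]
    q <- p * (1 - error_rate) + (1 - p) * error_rate / 3
    diag_n <- stats::rbinom(n_snp, depth, q)
    for (i in seq_len(n_snp)) {
      counts[i, snp_table$allele[i], r] <- diag_n[i]
      counts[i, refs[i], r] <- counts[i, refs[i], r] + depth[i] - diag_n[i]
    }
  }
  sync(data.frame(contig = snp_table$contig,
                  position = snp_table$position,
                  reference = unname(refs),
                  stringsAsFactors = FALSE),
       counts)
}

#' Downsample one site's counts to a fixed coverage
#'
#' Draws `target_coverage` reads from the six-category count vector of a
#' site, by default without replacement (multivariate hypergeometric, the
#' semantics of coverage subsampling in PoPoolation2). A site whose coverage
#' is below the target cannot be downsampled and returns `NULL` with a
#' warning; a site at exactly the target is returned unchanged.
#'
#' @param counts integer vector of six counts (A, T, C, G, N, del).
#' @param target_coverage integer >= 1.
#' @param with_replacement logical; if `TRUE`, draw multinomially with
#'   replacement instead. Default `FALSE`.
#' @return integer vector of six counts summing to `target_coverage`, or
#'   `NULL` if coverage is insufficient.
#' @export
downsample_counts <- function(counts, target_coverage,
                              with_replacement = FALSE) {
  if (target_coverage < 1) stop("target_coverage must be >= 1",
                                call. = FALSE)
  stopifnot(length(counts) == 6, all(counts >= 0))
  coverage <- sum(counts)
  if (coverage < target_coverage) {
    warning(sprintf(
      "site coverage %d below target %d: site excluded", coverage,
      as.integer(target_coverage)), call. = FALSE)
    return(NULL)
  }
  if (!with_replacement && coverage == target_coverage) {
    return(stats::setNames(as.integer(counts), SYNC_BASES))
  }
  out <- if (with_replacement) {
    as.integer(stats::rmultinom(1, target_coverage, counts / coverage))
  } else {
    reads <- rep.int(seq_len(6), counts)
    tabulate(sample(reads, target_coverage), nbins = 6)
  }
  stats::setNames(as.integer(out), SYNC_BASES)
}
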