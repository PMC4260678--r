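#' Identify clade-diagnostic SNPs from a labelled haplotype panel
#'
#' Scans the columns of an alignment of haplotypes whose labels map to clade
#' groups and returns the columns where a group carries a private allele:
#' an allele shared by every haplotype of that group and absent from all
#' other groups. Columns containing any character outside A/C/G/T (N,
#' ambiguity codes, gaps) are excluded. Closely related clades can be pooled
#' into one group through the `grouping` map before scanning.
#'
#' A column can be diagnostic for more than one group (e.g. a strict
#' two-group SNP is diagnostic for both sides); each such assignment is a
#' separate row, and the diagnostic alleles of distinct groups at a shared
#' position always differ.
#'
#' @param haplotypes named character vector of aligned sequences, all the
#'   same length (see [read_haplotypes()]).
#' @param grouping named character vector mapping haplotype names to clade
#'   group labels.
#' @param contig contig label recorded for every SNP (default
#'   `"alignment"`).
#' @return a clade SNP table: data frame with columns `contig`, `position`
#'   (1-based alignment column), `allele`, `clade`.
#' @export
identify_diagnostic_snps <- function(haplotypes, grouping,
                                     contig = "alignment") {
  if (length(haplotypes) == 0) stop("empty alignment", call. = FALSE)
  if (is.null(names(haplotypes)) ||
      !all(names(haplotypes) %in% names(grouping))) {
    stop("every haplotype must have a group in 'grouping'", call. = FALSE)
  }
  haplotypes <- toupper(haplotypes)
  len <- unique(nchar(haplotypes))
  if (length(len) != 1) {
    stop("haplotypes must be aligned (equal length)", call. = FALSE)
  }
  groups <- unname(grouping[names(haplotypes)])
  if (length(unique(groups)) < 2) {
    stop("at least two clade groups are required", call. = FALSE)
  }
  mat <- matrix(unlist(strsplit(haplotypes, "", fixed = TRUE)),
                nrow = length(haplotypes), byrow = TRUE)
  clean <- apply(mat, 2, function(col) all(col %in% NUCLEOTIDES))
  rows <- list()
  for (pos in which(clean)) {
    col <- mat[, pos]
    if (length(unique(col)) == 1) next
    for (g in unique(groups)) {
      in_g <- col[groups == g]
      if (length(unique(in_g)) == 1 && !(in_g[1] %in% col[groups != g])) {
        rows[[length(rows) + 1]] <- data.frame(
          contig = contig, position = pos, allele = in_g[1], clade = g,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(), position = integer(),
                      allele = character(), clade = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  validate_clade_table(out)
}

# Schema and uniqueness checks for a clade-diagnostic SNP table.
validate_clade_table <- function(table) {
  need <- c("contig", "position", "allele", "clade")
  if (!all(need %in% names(table))) {
    stop("clade table must have columns ", paste(need, collapse = "/"),
         call. = FALSE)
  }
  if (anyDuplicated(table[c("contig", "position", "clade")])) {
    stop("duplicate (contig, position, clade) rows in clade table",
         call. = FALSE)
  }
  if (!all(table$allele %in% NUCLEOTIDES)) {
    stop("diagnostic alleles must be one of A/C/G/T", call. = FALSE)
  }
  table
}

#' Read / write a clade-diagnostic SNP table
#'
#' Tab-separated with the exact header `contig  position  allele  clade`.
#'
#' @param path file path.
#' @return `read_clade_table()`: a validated data frame.
#' @export
read_clade_table <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("contig", "position", "allele", "clade"))) {
    stop("clade table header must be contig/position/allele/clade",
         call. = FALSE)
  }
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer",
                                          "character", "character"))
  validate_clade_table(out)
}

#' @rdname read_clade_table
#' @param table a clade SNP table.
#' @export
write_clade_table <- function(table, path) {
  utils::write.table(validate_clade_table(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an aligned haplotype panel from FASTA
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return named character vector of upper-case sequences.
#' @export
read_haplotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  is_hdr <- startsWith(lines, ">")
  if (!any(is_hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  idx <- cumsum(is_hdr)
  seqs <- vapply(split(lines[!is_hdr], idx[!is_hdr]),
                 function(x) paste(x, collapse = ""), "")
  names(seqs) <- sub("^>", "", sub("\\s.*$", "", lines[is_hdr]))
  toupper(seqs)
}

#' Estimate clade frequencies as medians of diagnostic SNP frequencies
#'
#' For each replicate and clade, looks up the clade's diagnostic SNPs in the
#' pooled counts, downsamples each site to a fixed coverage (hypergeometric,
#' without replacement), computes the diagnostic-allele frequency per SNP as
#' diagnostic count / target coverage, and reports the median across SNPs.
#' The median makes the estimate robust to a minority of misbehaving SNPs.
#'
#' Sites whose coverage is below the target are excluded from the median
#' (downsampling cannot fabricate reads); N and del reads count toward
#' coverage for the downsampling draw but never toward the diagnostic
#' numerator. A clade with no usable SNP in a replicate is reported as
#' missing (`NA`), not zero.
#'
#' @param records a [sync()] object of pooled counts.
#' @param table a clade-diagnostic SNP table (`contig`, `position`,
#'   `allele`, `clade`).
#' @param target_coverage downsampling target per site (e.g. 50 for an
#'   endosymbiont genome, 100 for mtDNA).
#' @param with_replacement passed to [downsample_counts()].
#' @return a data frame of class `"clade_freq"` with columns `replicate`,
#'   `clade`, `median_frequency`, `n_snps_used`; per-SNP frequencies are
#'   attached as attribute `"per_snp"`.
#' @export
estimate_clade_frequencies <- function(records, table, target_coverage,
                                       with_replacement = FALSE) {
  stopifnot(inherits(records, "sync"))
  table <- validate_clade_table(table)
  key_rec <- paste(records$sites$contig, records$sites$position)
  key_tab <- paste(table$contig, table$position)
  hit <- match(key_tab, key_rec)
  if (anyNA(hit)) {
    warning(sum(is.na(hit)), " diagnostic SNP(s) absent from the counts: ",
            "skipped", call. = FALSE)
  }
  reps <- dimnames(records$counts)[[3]]
  clades <- unique(table$clade)
  per_snp <- list()
  rows <- list()
  for (r in seq_along(reps)) {
    for (cl in clades) {
      sel <- which(table$clade == cl & !is.na(hit))
      freqs <- numeric(0)
      detail_pos <- integer(0)
      detail_contig <- character(0)
      for (i in sel) {
        cnt <- records$counts[hit[i], , r]
        down <- withCallingHandlers(
          downsample_counts(cnt, target_coverage, with_replacement),
          warning = function(w) invokeRestart("muffleWarning"))
        if (is.null(down)) next
        freqs <- c(freqs, down[table$allele[i]] / target_coverage)
        detail_pos <- c(detail_pos, table$position[i])
        detail_contig <- c(detail_contig, table$contig[i])
      }
      rows[[length(rows) + 1]] <- data.frame(
        replicate = reps[r], clade = cl,
        median_frequency = if (length(freqs)) stats::median(freqs)
                           else NA_real_,
        n_snps_used = length(freqs), stringsAsFactors = FALSE)
      if (length(freqs)) {
        per_snp[[length(per_snp) + 1]] <- data.frame(
          replicate = reps[r], clade = cl, contig = detail_contig,
          position = detail_pos, frequency = unname(freqs),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_snp") <- if (length(per_snp)) do.call(rbind, per_snp)
                          else NULL
  class(out) <- c("clade_freq", "data.frame")
  out
}

#' @export
print.clade_freq <- function(x, ...) {
  cat("Clade frequency estimates (median of diagnostic SNP frequencies)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cumulative clade-frequency check
#'
#' Sums the per-clade median frequencies within each replicate. If the
#' diagnostic SNP panel captures all major lineages in the pool, the
#' cumulative frequency should be close to one; a shortfall signals an
#' unaccounted lineage, an excess signals non-diagnostic or misassigned
#' SNPs.
#'
#' @param estimates a `"clade_freq"` data frame from
#'   [estimate_clade_frequencies()].
#' @param tolerance length-2 numeric band within which the sum passes
#'   (default `c(0.9, 1.1)`).
#' @return data frame with columns `replicate`, `cumulative_frequency`,
#'   `pass`.
#' @export
cumulative_frequency_check <- function(estimates, tolerance = c(0.9, 1.1)) {
  stopifnot(length(tolerance) == 2, tolerance[1] <= tolerance[2])
  sums <- tapply(estimates$median_frequency, estimates$replicate, sum)
  out <- data.frame(replicate = names(sums),
                    cumulative_frequency = as.numeric(sums),
                    stringsAsFactors = FALSE)
  out$pass <- !is.na(out$cumulative_frequency) &
    out$cumulative_frequency >= tolerance[1] &
    out$cumulative_frequency <= tolerance[2]
  for (i in which(!out$pass)) {
    cd_log("cumulative frequency %.3f in replicate %s outside [%.2f, %.2f]",
           out$cumulative_frequency[i], out$replicate[i], tolerance[1],
           tolerance[2])
  }
  out
}

#' Write clade-frequency estimates as TSV
#'
#' @param estimates a `"clade_freq"` data frame.
#' @param path output path.
#' @export
write_clade_frequencies <- function(estimates, path) {
  utils::write.table(as.data.frame(estimates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
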