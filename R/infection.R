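#' Read per-sample coverage summaries
#'
#' Tab-separated with header `sample_id`, `mean_depth_nuclear`,
#' `mean_depth_wolbachia`, `mean_depth_mtdna`, `wolbachia_breadth`;
#' additional columns (e.g. clade annotations or grouping labels) are kept.
#' Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return data frame of coverage summaries.
#' @export
read_coverage_summary <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("sample_id", "mean_depth_nuclear", "mean_depth_wolbachia",
            "mean_depth_mtdna", "wolbachia_breadth")
  if (!all(need %in% header)) {
    stop("coverage summary header must contain ",
         paste(need, collapse = "/"), call. = FALSE)
  }
  out <- utils::read.delim(text = lines, stringsAsFactors = FALSE)
  bad <- with(out, mean_depth_nuclear < 0 | mean_depth_wolbachia < 0 |
                mean_depth_mtdna < 0 | wolbachia_breadth < 0 |
                wolbachia_breadth > 1)
  if (any(bad)) {
    stop("negative depth or breadth outside [0, 1] in coverage summary",
         call. = FALSE)
  }
  out
}

#' Call endosymbiont infection status from sequencing coverage
#'
#' A sample is called infected when (a) reads cover more than 95% of the
#' endosymbiont genome and (b) the ratio of mean endosymbiont depth to mean
#' nuclear depth exceeds one. Both inequalities are strict: uninfected hosts
#' typically show a small residual signal (contamination, conserved
#' regions), so a breadth of exactly 0.95 or a ratio of exactly 1 does not
#' qualify.
#'
#' @param summaries data frame of coverage summaries (see
#'   [read_coverage_summary()]).
#' @param breadth_threshold minimum breadth (strict), default 0.95.
#' @param ratio_threshold minimum depth ratio (strict), default 1.
#' @return data frame with columns `sample_id`, `infected`, `ratio`,
#'   `breadth`.
#' @export
call_infection <- function(summaries, breadth_threshold = 0.95,
                           ratio_threshold = 1) {
  if (any(summaries$mean_depth_nuclear <= 0)) {
    stop("nuclear depth of 0 leaves the coverage ratio undefined",
         call. = FALSE)
  }
  ratio <- summaries$mean_depth_wolbachia / summaries$mean_depth_nuclear
  data.frame(
    sample_id = summaries$sample_id,
    infected = summaries$wolbachia_breadth > breadth_threshold &
      ratio > ratio_threshold,
    ratio = ratio,
    breadth = summaries$wolbachia_breadth,
    stringsAsFactors = FALSE
  )
}

#' Relative endosymbiont or mtDNA titer
#'
#' Copy number of the endosymbiont (or of mtDNA) relative to the host is
#' proxied by normalising its mean sequencing depth by the mean nuclear
#' depth, which cancels library-size differences between samples.
#'
#' @inheritParams call_infection
#' @param target `"wolbachia"` or `"mtdna"`.
#' @return numeric vector of depth ratios, named by sample.
#' @examples
#' relative_titer(data.frame(sample_id = "w2", mean_depth_nuclear = 17.07,
#'                           mean_depth_wolbachia = 209.91,
#'                           mean_depth_mtdna = 0,
#'                           wolbachia_breadth = 0.99)) # 12.30
#' @export
relative_titer <- function(summaries, target = c("wolbachia", "mtdna")) {
  target <- match.arg(target)
  if (any(summaries$mean_depth_nuclear <= 0)) {
    stop("nuclear depth of 0 leaves the titer undefined", call. = FALSE)
  }
  num <- switch(target,
                wolbachia = summaries$mean_depth_wolbachia,
                mtdna = summaries$mean_depth_mtdna)
  stats::setNames(num / summaries$mean_depth_nuclear, summaries$sample_id)
}

#' Grouped coverage summary statistics
#'
#' Mean and sample (n-1) standard deviation of a genome's mean depth per
#' sample group (e.g. infected vs uninfected flies). Groups of size one
#' report the mean with a missing SD.
#'
#' @inheritParams call_infection
#' @param grouping either the name of a column of `summaries` or a named
#'   vector mapping `sample_id` to a group label.
#' @param genome `"nuclear"`, `"wolbachia"` or `"mtdna"`.
#' @return data frame with columns `group`, `n`, `mean`, `sd`.
#' @export
group_coverage_stats <- function(summaries, grouping,
                                 genome = c("nuclear", "wolbachia",
                                            "mtdna")) {
  genome <- match.arg(genome)
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% names(summaries)) {
    groups <- summaries[[grouping]]
  } else {
    if (is.null(names(grouping)) ||
        !all(summaries$sample_id %in% names(grouping))) {
      stop("grouping must be a column name or a named sample_id -> group ",
           "vector covering every sample", call. = FALSE)
    }
    groups <- unname(grouping[summaries$sample_id])
  }
  if (anyNA(groups)) stop("every sample needs a group", call. = FALSE)
  depth <- summaries[[paste0("mean_depth_", genome)]]
  out <- do.call(rbind, lapply(split(depth, groups), function(x) {
    data.frame(n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }))
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}
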