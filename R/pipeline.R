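#' Read a pipeline configuration file
#'
#' YAML (or JSON, which YAML subsumes) with keys mirroring the pipeline
#' arguments:
#'
#' * `clade_table`: path to the diagnostic SNP table (TSV)
#' * `sync_start`, `sync_end`: sync files with the same replicates at the
#'   first and last sampled generation
#' * `target_coverage`: downsampling target (default 50; use 100 for mtDNA)
#' * `focal_clade`: clade whose frequency change is tested against drift
#' * `effective_size`, `generations`: drift-null parameters
#' * `coverage_summaries`: optional per-individual coverage TSV for
#'   infection calls and titer summaries
#' * `seed`: global seed (stage seeds are derived from it)
#' * `output_dir`: where results are written
#'
#' @param path configuration file path.
#' @return a validated named list of class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  defaults <- list(target_coverage = 50L, seed = 1L,
                   output_dir = "cytodrift_results",
                   coverage_summaries = NULL)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
  }
  need <- c("clade_table", "sync_start", "sync_end", "focal_clade",
            "effective_size", "generations")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("pipeline config is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("clade_table", "sync_start", "sync_end")) {
    if (!file.exists(cfg[[k]])) {
      stop("config path '", k, "' does not exist: ", cfg[[k]],
           call. = FALSE)
    }
  }
  if (!is.null(cfg$coverage_summaries) &&
      !file.exists(cfg$coverage_summaries)) {
    stop("coverage_summaries path does not exist: ", cfg$coverage_summaries,
         call. = FALSE)
  }
  if (cfg$target_coverage < 1) {
    stop("target_coverage must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full clade-tracking pipeline
#'
#' Executes, in order: clade-frequency estimation at the start and end time
#' points (median of diagnostic SNP frequencies after downsampling), the
#' cumulative-frequency panel check, the Wright-Fisher drift test for the
#' focal clade with replicate combination, selection-coefficient estimation
#' under both formulations, and (when coverage summaries are supplied)
#' infection calls, relative titers and grouped coverage statistics. All
#' tables are written as TSV into `output_dir`, together with a
#' machine-readable `summary.json`-style file and a run log recording the
#' seed and package version. Repeated runs with the same config and seed
#' produce identical outputs.
#'
#' @param config a `"pipeline_config"` list from [read_pipeline_config()],
#'   or a path to a config file.
#' @param output_dir optional override of the config's output directory.
#' @return invisibly, a list with elements `frequencies_start`,
#'   `frequencies_end`, `cumulative_start`, `cumulative_end`, `drift`
#'   (a [drift_test()] object or `NULL`), `infection`, `group_stats`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(unclass(config))
  outdir <- if (is.null(output_dir)) config$output_dir else output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  set.seed(config$seed)
  # derived per-stage seeds keep stages reproducible independently
  stage_seed <- sample.int(.Machine$integer.max - 1, 4)

  table <- run_stage("read-clade-table", read_clade_table(config$clade_table))
  sync_start <- run_stage("read-sync", read_sync(config$sync_start))
  sync_end <- run_stage("read-sync", read_sync(config$sync_end))

  cd_log("estimating clade frequencies (target coverage %d)",
         as.integer(config$target_coverage))
  # the same stage seed for both time points keeps estimation a pure
  # function of the input counts (identical inputs -> identical estimates)
  set.seed(stage_seed[1])
  est_start <- run_stage("estimate-frequencies", suppressWarnings(
    estimate_clade_frequencies(sync_start, table, config$target_coverage)))
  set.seed(stage_seed[1])
  est_end <- run_stage("estimate-frequencies", suppressWarnings(
    estimate_clade_frequencies(sync_end, table, config$target_coverage)))
  cum_start <- cumulative_frequency_check(est_start)
  cum_end <- cumulative_frequency_check(est_end)

  fc <- config$focal_clade
  s0 <- est_start[est_start$clade == fc, ]
  s1 <- est_end[est_end$clade == fc, ]
  drift <- NULL
  if (nrow(s0) && nrow(s1)) {
    shared <- intersect(s0$replicate, s1$replicate)
    reps <- data.frame(
      replicate = shared,
      start_frequency = s0$median_frequency[match(shared, s0$replicate)],
      end_frequency = s1$median_frequency[match(shared, s1$replicate)],
      stringsAsFactors = FALSE)
    reps <- reps[stats::complete.cases(reps), , drop = FALSE]
    if (nrow(reps)) {
      drift <- run_stage("drift-test",
                         drift_test(reps, N = config$effective_size,
                                    generations = config$generations))
    }
  }
  if (is.null(drift)) {
    cd_log("focal clade '%s' has no usable replicate estimates; drift test skipped", fc)
  }

  infection <- NULL
  group_stats <- NULL
  if (!is.null(config$coverage_summaries)) {
    cov <- run_stage("read-coverage",
                     read_coverage_summary(config$coverage_summaries))
    infection <- run_stage("call-infection", call_infection(cov))
    infection$titer_wolbachia <- relative_titer(cov, "wolbachia")
    infection$titer_mtdna <- relative_titer(cov, "mtdna")
    grp <- ifelse(infection$infected, "infected", "uninfected")
    names(grp) <- infection$sample_id
    group_stats <- do.call(rbind, lapply(
      c("nuclear", "wolbachia", "mtdna"), function(g) {
        st <- run_stage("group-stats", group_coverage_stats(cov, grp, g))
        st$genome <- g
        st
      }))
  }

  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(as.data.frame(est_start), "clade_frequencies_start.tsv")
  write_tsv(as.data.frame(est_end), "clade_frequencies_end.tsv")
  write_tsv(rbind(cbind(timepoint = "start", cum_start),
                  cbind(timepoint = "end", cum_end)),
            "cumulative_check.tsv")
  if (!is.null(drift)) write_tsv(drift$replicates, "drift_test.tsv")
  if (!is.null(infection)) write_tsv(infection, "infection_calls.tsv")
  if (!is.null(group_stats)) write_tsv(group_stats, "group_coverage.tsv")

  summary_list <- list(
    focal_clade = fc,
    effective_size = config$effective_size,
    generations = config$generations,
    target_coverage = config$target_coverage,
    seed = config$seed,
    combined_p = if (!is.null(drift)) drift$combined_p else NA,
    fisher_p = if (!is.null(drift)) drift$fisher_p else NA,
    s_discrete = if (!is.null(drift)) drift$replicates$s_discrete else NA,
    s_logit = if (!is.null(drift)) drift$replicates$s_logit else NA
  )
  writeLines(to_json(summary_list), file.path(outdir, "summary.json"))
  writeLines(c(
    sprintf("cytodrift %s", as.character(utils::packageVersion("cytodrift"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed %d", as.integer(config$seed)),
    sprintf("target_coverage %d", as.integer(config$target_coverage)),
    sprintf("focal_clade %s", fc)
  ), file.path(outdir, "run_log.txt"))

  invisible(list(frequencies_start = est_start, frequencies_end = est_end,
                 cumulative_start = cum_start, cumulative_end = cum_end,
                 drift = drift, infection = infection,
                 group_stats = group_stats))
}

# Minimal JSON serialiser for the flat summary list (numbers, strings,
# vectors); avoids a hard dependency for one write.
to_json <- function(x) {
  enc <- function(v) {
    if (is.null(v) || (length(v) == 1 && is.na(v))) return("null")
    if (is.character(v)) {
      out <- paste0("\"", gsub("\"", "\\\\\"", v), "\"")
    } else {
      out <- vapply(v, function(z) format(z, digits = 15), "")
    }
    if (length(out) == 1) out else paste0("[", paste(out, collapse = ","),
                                          "]")
  }
  paste0("{", paste(sprintf("\"%s\":%s", names(x),
                            vapply(x, enc, "")), collapse = ","), "}")
}

#' Write simulated trajectories as TSV
#'
#' @param sim a `"cyto_sim"` object.
#' @param path output path; columns `replicate`, `generation`, `cytotype`,
#'   `clade`, `infected`, `count`, `frequency`.
#' @export
write_trajectories <- function(sim, path) {
  utils::write.table(as.data.frame(sim), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
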