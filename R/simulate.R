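#' Simulation parameters for cytoplasmic lineage dynamics
#'
#' Builds and validates the configuration of the forward simulator. The
#' population is a set of `n_lineages` maternally transmitting cytoplasmic
#' lineages. Each lineage carries an mtDNA clade and an infection status;
#' infected lineages additionally carry the endosymbiont strain of the same
#' clade (complete cytoplasmic linkage: the mtDNA clade is fixed at
#' generation 0 and never changes, only infection status can be lost).
#'
#' @param n_lineages integer; number of transmitting lineages per generation
#'   (the `N` of the drift model).
#' @param generations integer >= 0; number of non-overlapping generations to
#'   simulate.
#' @param clades character vector of clade labels (infected cytotypes).
#' @param initial_frequencies named numeric vector over `c(clades,
#'   "uninfected")`, summing to 1: the starting composition.
#' @param selection named numeric vector of relative fitness multipliers
#'   (`1 + s`) over the same names; all > 0. Uninfected lineages use the
#'   `"uninfected"` multiplier regardless of their mtDNA clade.
#' @param transmission_fidelity probability in \[0, 1\] that an infected
#'   mother's offspring inherits the infection; offspring that lose it join
#'   the uninfected pool but keep their mtDNA clade.
#' @param ci_intensity probability in \[0, 1\]; hatch-rate penalty of
#'   cytoplasmic incompatibility. Offspring of uninfected mothers are
#'   down-weighted by `ci_intensity` times the current infected frequency.
#'   Default 0 (off). Only unidirectional CI (infected male x uninfected
#'   female) is modelled.
#' @param n_replicates integer >= 1; number of independent replicate
#'   populations.
#' @param seed integer seed for the simulation RNG stream.
#' @return an object of class `"sim_params"`.
#' @examples
#' p <- sim_params(
#'   n_lineages = 75, generations = 15,
#'   clades = c("I_II_III", "V", "VI"),
#'   initial_frequencies = c(I_II_III = 0.106, V = 0.1325, VI = 0.2915,
#'                           uninfected = 0.47),
#'   selection = c(I_II_III = 1, V = 1.18, VI = 1, uninfected = 1)
#' )
#' @export
sim_params <- function(n_lineages,
                       generations,
                       clades,
                       initial_frequencies,
                       selection = NULL,
                       transmission_fidelity = 1,
                       ci_intensity = 0,
                       n_replicates = 1,
                       seed = 1L) {
  n_lineages <- as.integer(n_lineages)
  generations <- as.integer(generations)
  n_replicates <- as.integer(n_replicates)
  cytotypes <- c(clades, "uninfected")
  if (n_lineages < 1) stop("n_lineages must be >= 1", call. = FALSE)
  if (generations < 0) stop("generations must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (anyDuplicated(clades)) stop("clade labels must be unique", call. = FALSE)
  if ("uninfected" %in% clades) {
    stop("'uninfected' is reserved for the uninfected cytotype", call. = FALSE)
  }
  if (is.null(selection)) {
    selection <- stats::setNames(rep(1, length(cytotypes)), cytotypes)
  }
  if (is.null(names(initial_frequencies)) || is.null(names(selection))) {
    stop("initial_frequencies and selection must be named vectors",
         call. = FALSE)
  }
  if (!setequal(names(initial_frequencies), cytotypes) ||
      !setequal(names(selection), cytotypes)) {
    stop("initial_frequencies and selection must cover each clade plus ",
         "'uninfected'", call. = FALSE)
  }
  initial_frequencies <- initial_frequencies[cytotypes]
  selection <- selection[cytotypes]
  if (abs(sum(initial_frequencies) - 1) > 1e-9) {
    stop("initial_frequencies must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (any(initial_frequencies < 0)) {
    stop("initial_frequencies must be non-negative", call. = FALSE)
  }
  if (any(selection <= 0)) stop("fitness multipliers must be > 0",
                                call. = FALSE)
  if (transmission_fidelity < 0 || transmission_fidelity > 1) {
    stop("transmission_fidelity must be in [0, 1]", call. = FALSE)
  }
  if (ci_intensity < 0 || ci_intensity > 1) {
    stop("ci_intensity must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_lineages = n_lineages, generations = generations,
         clades = as.character(clades),
         initial_frequencies = initial_frequencies,
         selection = selection,
         transmission_fidelity = transmission_fidelity,
         ci_intensity = ci_intensity,
         n_replicates = n_replicates, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Cytoplasmic lineage simulation parameters\n")
  cat(sprintf("  N = %d lineages, %d generations, %d replicate(s), seed %d\n",
              x$n_lineages, x$generations, x$n_replicates, x$seed))
  cat("  clades:", paste(x$clades, collapse = ", "), "\n")
  cat("  initial frequencies:",
      paste(sprintf("%s=%.3f", names(x$initial_frequencies),
                    x$initial_frequencies), collapse = " "), "\n")
  cat("  fitness:",
      paste(sprintf("%s=%.3f", names(x$selection), x$selection),
            collapse = " "), "\n")
  cat(sprintf("  transmission fidelity = %.3f, CI intensity = %.3f\n",
              x$transmission_fidelity, x$ci_intensity))
  invisible(x)
}

# Internal state layout: one row per cytotype = (mtDNA clade, infected?).
# Infected cytotypes exist for every clade; uninfected cytotypes comprise the
# founder uninfected pool (clade NA) plus, for fidelity < 1, cured lineages
# that keep their mtDNA clade.
cytotype_table <- function(clades) {
  data.frame(
    cytotype = c(clades, paste0(clades, ":cured"), "uninfected"),
    clade = c(clades, clades, NA_character_),
    infected = c(rep(TRUE, length(clades)), rep(FALSE, length(clades) + 1)),
    stringsAsFactors = FALSE
  )
}

# Selection weights for one generation: frequency x fitness, with the CI
# hatch-rate penalty applied to uninfected mothers.
selection_weights <- function(freq, fitness, infected, ci_intensity) {
  w <- freq * fitness
  if (ci_intensity > 0) {
    p_inf <- sum(freq[infected])
    w[!infected] <- w[!infected] * (1 - ci_intensity * p_inf)
  }
  w
}

#' Forward-simulate cytoplasmic lineage trajectories
#'
#' Wright-Fisher style resampling of `n_lineages` maternal lineages per
#' generation. Each generation, every cytotype receives a weight equal to its
#' frequency times its fitness multiplier (uninfected cytotypes additionally
#' pay the CI hatch-rate penalty when `ci_intensity > 0`), the next
#' generation is drawn as a single multinomial sample of `n_lineages`
#' offspring from those weights, and offspring of infected mothers lose the
#' infection independently with probability `1 - transmission_fidelity`,
#' joining the uninfected pool while retaining their mtDNA clade.
#'
#' Generation 0 is deterministic: initial frequencies are converted to counts
#' by largest-remainder rounding so they sum exactly to `n_lineages`.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `"cyto_sim"`: a long data frame with columns
#'   `replicate`, `generation`, `cytotype`, `clade`, `infected`, `count`,
#'   `frequency`, with the parameters attached as attribute `"params"`.
#' @seealso [clade_frequencies()], [infection_rate()], [apply_selection()]
#' @export
simulate_trajectory <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  ct <- cytotype_table(params$clades)
  n_ct <- nrow(ct)
  fitness <- ifelse(ct$infected,
                    params$selection[ct$clade],
                    params$selection["uninfected"])
  init <- stats::setNames(numeric(n_ct), ct$cytotype)
  init[params$clades] <- params$initial_frequencies[params$clades]
  init["uninfected"] <- params$initial_frequencies["uninfected"]

  set.seed(params$seed)
  out <- vector("list", params$n_replicates)
  for (r in seq_len(params$n_replicates)) {
    counts <- matrix(0L, nrow = params$generations + 1, ncol = n_ct,
                     dimnames = list(NULL, ct$cytotype))
    counts[1, ] <- largest_remainder(init, params$n_lineages)
    cur <- counts[1, ]
    for (g in seq_len(params$generations)) {
      freq <- cur / params$n_lineages
      w <- selection_weights(freq, fitness, ct$infected, params$ci_intensity)
      if (sum(w) <= 0) {
        stop("degenerate input: total selection weight is zero at ",
             "generation ", g, call. = FALSE)
      }
      cur <- as.integer(stats::rmultinom(1, params$n_lineages, w))
      names(cur) <- ct$cytotype
      if (params$transmission_fidelity < 1) {
        for (cl in params$clades) {
          lost <- stats::rbinom(1, cur[cl], 1 - params$transmission_fidelity)
          cur[cl] <- cur[cl] - lost
          cured <- paste0(cl, ":cured")
          cur[cured] <- cur[cured] + lost
        }
      }
      counts[g + 1, ] <- cur
    }
    out[[r]] <- data.frame(
      replicate = r,
      generation = rep(0:params$generations, each = n_ct),
      cytotype = rep(ct$cytotype, params$generations + 1),
      clade = rep(ct$clade, params$generations + 1),
      infected = rep(ct$infected, params$generations + 1),
      count = as.integer(t(counts)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res$frequency <- res$count / params$n_lineages
  structure(res, params = params, class = c("cyto_sim", "data.frame"))
}

#' @export
print.cyto_sim <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Cytoplasmic lineage simulation: N = %d, %d generation(s), %d replicate(s)\n",
    p$n_lineages, p$generations, p$n_replicates))
  fin <- clade_frequencies(x, generation = p$generations, genome = "mtdna")
  cat("Final mtDNA clade frequencies (replicates x clades):\n")
  print(round(fin, 3))
  cat("Final infection rate:",
      paste(round(infection_rate(x, p$generations), 3), collapse = " "), "\n")
  invisible(x)
}

#' Per-replicate clade frequencies from a simulation
#'
#' For the endosymbiont genome only infected lineages carry the symbiont, so
#' a clade's frequency is the frequency of its infected cytotype; for the
#' mtDNA genome, cured lineages still carry their clade's mtDNA, so infected
#' and cured cytotypes of a clade are pooled.
#'
#' @param sim a `"cyto_sim"` object from [simulate_trajectory()].
#' @param generation generation to extract (default: the last one).
#' @param genome `"wolbachia"` (infected lineages only) or `"mtdna"`
#'   (infected plus cured lineages).
#' @return numeric matrix, replicates in rows, clades in columns.
#' @export
clade_frequencies <- function(sim, generation = NULL,
                              genome = c("wolbachia", "mtdna")) {
  stopifnot(inherits(sim, "cyto_sim"))
  genome <- match.arg(genome)
  p <- attr(sim, "params")
  if (is.null(generation)) generation <- p$generations
  sub <- sim[sim$generation == generation & !is.na(sim$clade), , drop = FALSE]
  if (genome == "wolbachia") sub <- sub[sub$infected, , drop = FALSE]
  freq <- tapply(sub$frequency, list(sub$replicate, sub$clade), sum)
  freq[, p$clades, drop = FALSE]
}

#' Per-replicate infection rate at a generation
#'
#' @inheritParams clade_frequencies
#' @return numeric vector, one infection rate per replicate.
#' @export
infection_rate <- function(sim, generation = NULL) {
  stopifnot(inherits(sim, "cyto_sim"))
  p <- attr(sim, "params")
  if (is.null(generation)) generation <- p$generations
  sub <- sim[sim$generation == generation & sim$infected, , drop = FALSE]
  as.numeric(tapply(sub$frequency, sub$replicate, sum))
}

#' @export
plot.cyto_sim <- function(x, genome = c("mtdna", "wolbachia"), ...) {
  genome <- match.arg(genome)
  p <- attr(x, "params")
  sub <- x[!is.na(x$clade), , drop = FALSE]
  if (genome == "wolbachia") sub <- sub[sub$infected, , drop = FALSE]
  freq <- tapply(sub$frequency, list(sub$generation, sub$clade, sub$replicate),
                 sum)
  graphics::matplot(as.numeric(rownames(freq)), freq[, p$clades, 1],
                    type = "l", lty = 1, ylim = c(0, 1),
                    xlab = "generation", ylab = "clade frequency", ...)
  if (dim(freq)[3] > 1) {
    for (r in 2:dim(freq)[3]) {
      graphics::matlines(as.numeric(rownames(freq)), freq[, p$clades, r],
                         lty = 2)
    }
  }
  graphics::legend("topleft", legend = p$clades, lty = 1,
                   col = seq_along(p$clades), bty = "n")
  invisible(x)
}

#' Deterministic haploid selection recursion
#'
#' One generation of selection on cytotype frequencies: each frequency is
#' multiplied by its fitness and the vector is renormalised,
#' `f_k' = f_k w_k / sum_j f_j w_j`. This is the infinite-population limit of
#' the simulator's weighted resampling and the recursion whose inversion
#' yields the selection coefficient in [estimate_selection()].
#'
#' @param frequencies numeric vector summing to 1.
#' @param fitness numeric vector of multipliers (> 0), same length.
#' @return numeric vector of post-selection frequencies, summing to 1.
#' @examples
#' apply_selection(c(0.5, 0.5), c(2, 1)) # 2/3, 1/3
#' @export
apply_selection <- function(frequencies, fitness) {
  if (length(frequencies) != length(fitness)) {
    stop("frequencies and fitness must have the same length", call. = FALSE)
  }
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("frequencies must sum to 1", call. = FALSE)
  }
  if (any(fitness <= 0)) stop("fitness multipliers must be > 0",
                              call. = FALSE)
  w <- frequencies * fitness
  w / sum(w)
}
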