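#' Wright-Fisher transition matrix
#'
#' The (N+1) x (N+1) Markov transition matrix of a neutral Wright-Fisher
#' population of N haploid (here: cytoplasmic) lineages: entry (i, j) is the
#' binomial probability of j copies in the next generation given current
#' frequency i/N, `choose(N, j) (i/N)^j (1 - i/N)^(N - j)`. States 0 and N
#' are absorbing.
#'
#' @param N integer >= 1; number of transmitting lineages.
#' @return a dense (N+1) x (N+1) row-stochastic matrix; rows and columns
#'   are labelled by copy number `0:N`.
#' @export
wf_transition_matrix <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 1) stop("N must be an integer >= 1", call. = FALSE)
  states <- 0:N
  M <- outer(states, states, function(i, j) stats::dbinom(j, N, i / N))
  dimnames(M) <- list(states, states)
  M
}

# Matrix power by repeated squaring; n = 0 gives the identity.
matrix_power <- function(M, n) {
  stopifnot(nrow(M) == ncol(M), n >= 0)
  result <- diag(nrow(M))
  base <- M
  n <- as.integer(n)
  while (n > 0) {
    if (n %% 2L == 1L) result <- result %*% base
    base <- base %*% base
    n <- n %/% 2L
  }
  dimnames(result) <- dimnames(M)
  result
}

#' Neutral end-of-experiment frequency distribution
#'
#' Distribution of the copy number after `generations` rounds of neutral
#' Wright-Fisher resampling, conditional on the starting copy number:
#' row `start_count` of the transition matrix raised to the `generations`-th
#' power. Zero generations give a point mass at the start.
#'
#' @param N number of transmitting lineages.
#' @param start_count starting copy number in `0:N`.
#' @param generations integer >= 0.
#' @return numeric probability vector over states `0:N` (named).
#' @export
end_distribution <- function(N, start_count, generations) {
  if (start_count < 0 || start_count > N) {
    stop("start_count must lie in 0..N", call. = FALSE)
  }
  if (generations < 0) stop("generations must be >= 0", call. = FALSE)
  P <- matrix_power(wf_transition_matrix(N), generations)
  P[start_count + 1, ]
}

#' Two-sided drift p-value for an observed frequency change
#'
#' Probability, under the neutral end-of-experiment distribution, of a
#' change at least as pronounced as the observed one, doubled for the
#' two-sided alternative and capped at 1. The tail is taken in the observed
#' direction of change: `2 P(X >= obs)` for an increase, `2 P(X <= obs)`
#' for a decrease; an unchanged count gives p = 1. Absorbing states
#' contribute to the tails (no conditioning on non-fixation).
#'
#' @param distribution probability vector over `0:N` (from
#'   [end_distribution()]).
#' @param observed_count observed final copy number.
#' @param start_count starting copy number (fixes the direction of change).
#' @return p-value in \[0, 1\].
#' @export
two_sided_pvalue <- function(distribution, observed_count, start_count) {
  N <- length(distribution) - 1
  if (abs(sum(distribution) - 1) > 1e-6) {
    stop("distribution must sum to 1", call. = FALSE)
  }
  if (observed_count < 0 || observed_count > N ||
      start_count < 0 || start_count > N) {
    stop("counts must lie in 0..N", call. = FALSE)
  }
  if (observed_count == start_count) return(1)
  tail_mass <- if (observed_count > start_count) {
    sum(distribution[(observed_count + 1):(N + 1)])
  } else {
    sum(distribution[1:(observed_count + 1)])
  }
  min(1, 2 * tail_mass)
}

#' Combine independent replicate p-values
#'
#' The primary combination is the plain product of the replicate p-values
#' (the probability of seeing, in every independent replicate, a change at
#' least as extreme as observed, under drift). A product of p-values is not
#' itself uniformly distributed under the null; Fisher's combined test
#' (-2 sum log p against chi-squared with 2k df) is offered as a calibrated
#' alternative.
#'
#' @param p_values numeric vector of per-replicate p-values in \[0, 1\].
#' @param method `"product"` (default) or `"fisher"`.
#' @return a single combined value.
#' @export
combine_replicates <- function(p_values, method = c("product", "fisher")) {
  method <- match.arg(method)
  if (length(p_values) == 0) stop("no p-values to combine", call. = FALSE)
  if (any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  switch(method,
         product = prod(p_values),
         fisher = stats::pchisq(-2 * sum(log(p_values)),
                                df = 2 * length(p_values),
                                lower.tail = FALSE))
}

#' Selection coefficient from a frequency change
#'
#' Inverts the deterministic haploid selection recursion
#' `p' = p (1 + s) / (1 + p s)` over `t` generations. Under that recursion
#' the odds `p/(1-p)` grow geometrically by `(1+s)` per generation, so
#'
#' * `"discrete"` (default, exact inversion):
#'   `s = (odds(p_t) / odds(p_0))^(1/t) - 1`
#' * `"logit"` (continuous-time / logistic approximation):
#'   `s = (log odds(p_t) - log odds(p_0)) / t`
#'
#' The two agree to first order in s; both are reported by [drift_test()].
#'
#' @param start_frequency,end_frequency frequencies strictly inside (0, 1).
#' @param generations number of generations elapsed (>= 1).
#' @param model `"discrete"` or `"logit"`.
#' @return the per-generation selection coefficient s (dimensionless).
#' @examples
#' estimate_selection(0.25, 0.80, 15)                  # ~0.180
#' estimate_selection(0.25, 0.80, 15, model = "logit") # ~0.166
#' @export
estimate_selection <- function(start_frequency, end_frequency, generations,
                               model = c("discrete", "logit")) {
  model <- match.arg(model)
  if (generations < 1) stop("generations must be >= 1", call. = FALSE)
  f <- c(start_frequency, end_frequency)
  if (any(f <= 0 | f >= 1)) {
    stop("frequencies of 0 or 1 have undefined odds; replace them with a ",
         "pseudo-frequency (e.g. 1/(2N)) before inverting", call. = FALSE)
  }
  odds <- function(p) p / (1 - p)
  ratio <- odds(end_frequency) / odds(start_frequency)
  switch(model,
         discrete = ratio^(1 / generations) - 1,
         logit = log(ratio) / generations)
}

#' Test observed clade-frequency changes against neutral drift
#'
#' Fits the neutral Wright-Fisher null to per-replicate start/end clade
#' frequencies: frequencies are mapped to copy numbers out of `N` (nearest
#' count, ties away from zero), the exact end-of-experiment distribution is
#' computed by transition-matrix powers, each replicate receives a
#' two-sided p-value, the replicate p-values are combined by their product
#' (with Fisher's method as an alternative), and the selection coefficient
#' implied by each replicate's change is estimated under both the discrete
#' and logit formulations.
#'
#' @param replicates data frame with columns `start_frequency` and
#'   `end_frequency` (optionally `replicate` labels), one row per
#'   independent replicate population.
#' @param N effective number of transmitting cytoplasmic lineages.
#' @param generations number of generations between the two samples.
#' @return an object of class `"drift_test"` with components
#'   `replicates` (per-replicate counts, p-values and s estimates),
#'   `combined_p` (product), `fisher_p`, `end_distributions` (one
#'   probability vector per replicate), `N`, `generations`.
#' @examples
#' drift_test(data.frame(start_frequency = rep(0.25, 3),
#'                       end_frequency = rep(0.80, 3)),
#'            N = 75, generations = 15)
#' @export
drift_test <- function(replicates, N, generations) {
  stopifnot(is.data.frame(replicates),
            all(c("start_frequency", "end_frequency") %in%
                  names(replicates)))
  if (any(replicates$start_frequency < 0 | replicates$start_frequency > 1 |
          replicates$end_frequency < 0 | replicates$end_frequency > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (generations < 0) stop("generations must be >= 0", call. = FALSE)
  labels <- if ("replicate" %in% names(replicates)) {
    as.character(replicates$replicate)
  } else {
    paste0("rep", seq_len(nrow(replicates)))
  }
  start_count <- freq_to_count(replicates$start_frequency, N)
  obs_count <- freq_to_count(replicates$end_frequency, N)
  P <- matrix_power(wf_transition_matrix(N), generations)
  dists <- lapply(start_count, function(i) P[i + 1, ])
  p <- mapply(two_sided_pvalue, dists, obs_count, start_count)
  s_pair <- function(p0, pt, model) {
    if (generations >= 1 && p0 > 0 && p0 < 1 && pt > 0 && pt < 1) {
      estimate_selection(p0, pt, generations, model)
    } else {
      NA_real_
    }
  }
  res <- data.frame(
    replicate = labels,
    start_frequency = replicates$start_frequency,
    end_frequency = replicates$end_frequency,
    start_count = start_count,
    observed_count = obs_count,
    p_value = as.numeric(p),
    s_discrete = mapply(s_pair, replicates$start_frequency,
                        replicates$end_frequency,
                        MoreArgs = list(model = "discrete")),
    s_logit = mapply(s_pair, replicates$start_frequency,
                     replicates$end_frequency,
                     MoreArgs = list(model = "logit")),
    stringsAsFactors = FALSE
  )
  structure(
    list(replicates = res,
         combined_p = combine_replicates(res$p_value, "product"),
         fisher_p = combine_replicates(res$p_value, "fisher"),
         end_distributions = stats::setNames(dists, labels),
         N = N, generations = generations),
    class = "drift_test"
  )
}

#' @export
print.drift_test <- function(x, ...) {
  cat(sprintf(
    "Wright-Fisher drift test: N = %d, %d generation(s), %d replicate(s)\n",
    x$N, x$generations, nrow(x$replicates)))
  print.data.frame(
    x$replicates[c("replicate", "start_frequency", "end_frequency",
                   "p_value", "s_discrete", "s_logit")],
    row.names = FALSE, digits = 4)
  cat(sprintf("Combined p (product of replicates): %.3g\n", x$combined_p))
  cat(sprintf("Fisher combined p (alternative):    %.3g\n", x$fisher_p))
  invisible(x)
}

#' @export
summary.drift_test <- function(object, ...) {
  s_d <- object$replicates$s_discrete
  s_l <- object$replicates$s_logit
  out <- list(
    N = object$N, generations = object$generations,
    n_replicates = nrow(object$replicates),
    combined_p = object$combined_p, fisher_p = object$fisher_p,
    s_discrete_range = range(s_d, na.rm = TRUE),
    s_logit_range = range(s_l, na.rm = TRUE),
    replicates = object$replicates
  )
  class(out) <- "summary.drift_test"
  out
}

#' @export
print.summary.drift_test <- function(x, ...) {
  cat(sprintf("Drift null: N = %d lineages, %d generations, %d replicates\n",
              x$N, x$generations, x$n_replicates))
  cat(sprintf("  combined p (product): %.3g; Fisher: %.3g\n",
              x$combined_p, x$fisher_p))
  cat(sprintf("  s (discrete inversion): %.3f .. %.3f\n",
              x$s_discrete_range[1], x$s_discrete_range[2]))
  cat(sprintf("  s (logit):              %.3f .. %.3f\n",
              x$s_logit_range[1], x$s_logit_range[2]))
  invisible(x)
}

#' @export
coef.drift_test <- function(object, model = c("discrete", "logit"), ...) {
  model <- match.arg(model)
  col <- paste0("s_", model)
  stats::setNames(object$replicates[[col]], object$replicates$replicate)
}
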