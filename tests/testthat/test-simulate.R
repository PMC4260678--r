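test_that("parameter validation rejects malformed configurations", {
  expect_error(bp_params(n_lineages = 0), "n_lineages")
  expect_error(bp_params(generations = -1), "generations")
  expect_error(bp_params(initial_frequencies =
                           c(V = 0.5, VI = 0.5, I_II_III = 0.2,
                             uninfected = 0)), "sum to 1")
  expect_error(bp_params(selection = c(V = 0, VI = 1, I_II_III = 1,
                                       uninfected = 1)), "> 0")
  expect_error(bp_params(transmission_fidelity = 1.2), "fidelity")
  expect_error(bp_params(ci_intensity = -0.1), "ci_intensity")
  expect_error(sim_params(10, 5, clades = "uninfected",
                          initial_frequencies = c(uninfected = 1)),
               "reserved")
  expect_output(print(bp_params()), "transmission fidelity")
})

test_that("generation 0 uses largest-remainder rounding and counts are conserved", {
  counts <- cytodrift:::largest_remainder(c(0.55, 0.25, 0.20), 75)
  expect_equal(sum(counts), 75L)
  expect_equal(counts, c(41L, 19L, 15L))  # 41.25, 18.75, 15.00
  sim <- simulate_trajectory(bp_params(n_replicates = 3, seed = 7))
  totals <- tapply(sim$count, list(sim$replicate, sim$generation), sum)
  expect_true(all(totals == 75L))
  expect_true(all(sim$count >= 0))
  g0 <- clade_frequencies(sim, 0, "mtdna")
  expect_equal(unname(g0[1, bp_clades]), c(19, 41, 15) / 75)
})

test_that("a single lineage is fixed from generation 0 onward", {
  p <- sim_params(1, 10, clades = "V",
                  initial_frequencies = c(V = 1, uninfected = 0),
                  seed = 3)
  sim <- simulate_trajectory(p)
  expect_true(all(clade_frequencies(sim, NULL, "mtdna")[, "V"] == 1))
  expect_true(all(sim$count[sim$cytotype == "V"] == 1L))
})

test_that("neutral clade frequency is a martingale with WF variance", {
  n_rep <- 2000
  sim <- simulate_trajectory(bp_params(n_replicates = n_rep, seed = 11))
  f <- clade_frequencies(sim, 15, "mtdna")[, "V"]
  p0 <- 19 / 75
  se <- sqrt(p0 * (1 - p0) / 75) / sqrt(n_rep)  # upper bound on SE of mean
  expect_lt(abs(mean(f) - p0), 3 * se * sqrt(15))
  v_theory <- p0 * (1 - p0) * (1 - (1 - 1 / 75)^15)
  expect_lt(abs(var(f) - v_theory) / v_theory, 0.10)
})

test_that("selected trajectories track the deterministic recursion at large N", {
  p <- sim_params(10000, 15, clades = bp_clades,
                  initial_frequencies = bp_frequencies,
                  selection = c(V = 1.2, VI = 1, I_II_III = 1,
                                uninfected = 1),
                  n_replicates = 5, seed = 5)
  sim <- simulate_trajectory(p)
  f <- c(V = 0.25, VI = 0.55, I_II_III = 0.20)
  for (i in 1:15) f <- apply_selection(f, c(V = 1.2, VI = 1, I_II_III = 1))
  expect_lt(abs(mean(clade_frequencies(sim, 15, "mtdna")[, "V"]) - f["V"]),
            0.02)
})

test_that("imperfect transmission erodes infection without touching mtDNA clades", {
  p <- bp_params(initial_frequencies = c(V = 0.15, VI = 0.30,
                                         I_II_III = 0.15, uninfected = 0.4),
                 transmission_fidelity = 0.9, n_replicates = 300,
                 seed = 19)
  sim <- simulate_trajectory(p)
  rates <- sapply(0:15, function(g) mean(infection_rate(sim, g)))
  # non-increasing in expectation (allow Monte-Carlo wiggle)
  expect_true(all(diff(rates) < 0.01))
  expect_lt(rates[16], rates[1])
  # cured lineages keep their clade: mtDNA frequencies still sum to the
  # cytoplasmic pool carried forward from generation 0
  mt <- clade_frequencies(sim, 15, "mtdna")
  wolb <- clade_frequencies(sim, 15, "wolbachia")
  expect_true(all(mt >= wolb - 1e-12))
})

test_that("CI penalises uninfected lineages in proportion to infected frequency", {
  base <- c(V = 0.25, VI = 0.25, I_II_III = 0, uninfected = 0.5)
  p_ci <- bp_params(initial_frequencies = base, ci_intensity = 0.9,
                    n_replicates = 400, seed = 23)
  p_no <- bp_params(initial_frequencies = base, ci_intensity = 0,
                    n_replicates = 400, seed = 23)
  inf_ci <- mean(infection_rate(simulate_trajectory(p_ci), 15))
  inf_no <- mean(infection_rate(simulate_trajectory(p_no), 15))
  expect_gt(inf_ci, inf_no + 0.1)
})

test_that("selection weights implement frequency x fitness with CI penalty", {
  w <- cytodrift:::selection_weights(freq = c(0.6, 0.4),
                                     fitness = c(1.2, 1),
                                     infected = c(TRUE, FALSE),
                                     ci_intensity = 0.5)
  # uninfected weight 0.4 * 1 * (1 - 0.5 * 0.6)
  expect_equal(w, c(0.72, 0.4 * 0.7))
  # an all-uninfected population with CI off simulates without error
  p <- bp_params(initial_frequencies = c(V = 0, VI = 0, I_II_III = 0,
                                         uninfected = 1))
  expect_silent(simulate_trajectory(p))
})

test_that("the same seed reproduces trajectories bit-identically", {
  p <- bp_params(n_replicates = 2, transmission_fidelity = 0.95, seed = 99)
  s1 <- simulate_trajectory(p)
  s2 <- simulate_trajectory(p)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  s3 <- simulate_trajectory(bp_params(n_replicates = 2,
                                      transmission_fidelity = 0.95,
                                      seed = 100))
  expect_false(identical(s1$count, s3$count))
})

test_that("apply_selection renormalises frequency-weighted fitness", {
  expect_equal(apply_selection(c(0.3, 0.7), c(1, 1)), c(0.3, 0.7))
  expect_equal(apply_selection(c(0.5, 0.5), c(2, 1)), c(2 / 3, 1 / 3))
  f <- c(0.25, 0.75)
  for (i in 1:15) f <- apply_selection(f, c(1.18, 1))
  expect_equal(f[1], 0.80, tolerance = 0.005)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_error(apply_selection(c(0.5, 0.6), c(1, 1)), "sum to 1")
  expect_error(apply_selection(c(0.5, 0.5), c(1, -1)), "> 0")
})
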