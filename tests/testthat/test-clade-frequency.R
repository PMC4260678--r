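test_that("diagnostic SNP scan recovers private fixed alleles", {
  haps <- c(a1 = "AAAT", a2 = "AAAT", b1 = "AAAC", b2 = "AAAC")
  grp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  tab <- identify_diagnostic_snps(haps, grp)
  expect_equal(nrow(tab), 2)  # position 4 is diagnostic for both groups
  expect_setequal(tab$clade, c("A", "B"))
  expect_equal(unique(tab$position), 4L)
  expect_equal(tab$allele[tab$clade == "A"], "T")
  expect_equal(tab$allele[tab$clade == "B"], "C")
})

test_that("shared alleles and ambiguous columns are never diagnostic", {
  haps <- c(x = "GANT", y = "GANT", z = "TANT")
  grp <- c(x = "g1", y = "g2", z = "g3")
  tab <- identify_diagnostic_snps(haps, grp)
  # column 1: G shared by g1 and g2 -> diagnostic for g3 only;
  # column 2 monomorphic, column 3 has N, column 4 monomorphic
  expect_equal(nrow(tab), 1)
  expect_equal(tab$clade, "g3")
  expect_equal(tab$position, 1L)
  expect_equal(tab$allele, "T")
  expect_error(identify_diagnostic_snps(character(0), grp), "empty")
  expect_error(identify_diagnostic_snps(haps, c(x = "g", y = "g", z = "g")),
               "two clade groups")
})

test_that("scan equals a brute-force column oracle on a random planted panel", {
  set.seed(402)
  len <- 1000
  groups <- rep(c("P", "Q", "R"), each = 3)
  names(groups) <- paste0("h", 1:9)
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  haps <- matrix(rep(base, 9), nrow = 9, byrow = TRUE)
  rownames(haps) <- names(groups)
  planted <- sort(sample(len, 30))
  owner <- sample(c("P", "Q", "R"), 30, replace = TRUE)
  for (k in seq_along(planted)) {
    alt <- setdiff(c("A", "C", "G", "T"), base[planted[k]])[1]
    haps[groups == owner[k], planted[k]] <- alt
  }
  # scatter some N columns and within-group polymorphism
  nn <- sample(setdiff(seq_len(len), planted), 20)
  haps[1, nn] <- "N"
  poly <- sample(setdiff(seq_len(len), c(planted, nn)), 15)
  for (pos in poly) haps[sample(9, 1), pos] <- "T"
  seqs <- apply(haps, 1, paste, collapse = "")

  # independent oracle: literal per-column, per-group definition
  oracle <- list()
  for (pos in seq_len(len)) {
    col <- haps[, pos]
    if (!all(col %in% c("A", "C", "G", "T"))) next
    for (g in unique(groups)) {
      ing <- unique(col[groups == g])
      if (length(ing) == 1 && !(ing %in% col[groups != g])) {
        oracle[[length(oracle) + 1]] <- c(pos, g, ing)
      }
    }
  }
  oracle <- do.call(rbind, oracle)
  tab <- identify_diagnostic_snps(seqs, groups)
  expect_equal(nrow(tab), nrow(oracle))
  expect_equal(tab$position, as.integer(oracle[, 1]))
  expect_equal(tab$clade, oracle[, 2])
  expect_equal(tab$allele, oracle[, 3])
  # every planted private variant was recovered
  expect_true(all(planted %in% tab$position))
})

test_that("downsampling has hypergeometric semantics", {
  # coverage at target: unchanged
  cnt <- c(A = 30L, T = 20L, C = 0L, G = 0L, N = 0L, del = 0L)
  expect_equal(downsample_counts(cnt, 50), cnt)
  # insufficient coverage: excluded with a warning
  expect_warning(out <- downsample_counts(c(30, 0, 0, 0, 0, 0), 50),
                 "excluded")
  expect_null(out)
  expect_error(downsample_counts(cnt, 0), "target_coverage")
  # expectation preserved over repeated draws: 100 of (100 A + 100 T)
  set.seed(77)
  draws <- replicate(4000, downsample_counts(
    c(100, 100, 0, 0, 0, 0), 100)[1])
  hyper_var <- 100 * 0.5 * 0.5 * (200 - 100) / (200 - 1)
  expect_lt(abs(mean(draws) - 50), 3 * sqrt(hyper_var / 4000))
  expect_true(all(draws <= 100))
  # never increases coverage
  set.seed(78)
  d <- downsample_counts(c(40, 30, 20, 10, 5, 5), 60)
  expect_equal(sum(d), 60)
  d2 <- downsample_counts(c(40, 30, 20, 10, 5, 5), 60,
                          with_replacement = TRUE)
  expect_equal(sum(d2), 60)
})

test_that("median clade-frequency estimation is exact on noise-free counts", {
  tab <- data.frame(contig = "wolb", position = 1:3,
                    allele = c("A", "A", "A"), clade = "V",
                    stringsAsFactors = FALSE)
  counts <- array(0L, dim = c(3, 6, 1))
  counts[, 1, 1] <- c(20L, 25L, 90L)   # A
  counts[, 4, 1] <- c(80L, 75L, 10L)   # G fills to coverage 100
  s <- sync(data.frame(contig = "wolb", position = 1:3, reference = "G"),
            counts)
  est <- estimate_clade_frequencies(s, tab, 100)
  expect_s3_class(est, "clade_freq")
  expect_equal(est$median_frequency, 0.25)  # median of 0.20, 0.25, 0.90
  expect_equal(est$n_snps_used, 3L)
  detail <- attr(est, "per_snp")
  expect_equal(sort(detail$frequency), c(0.20, 0.25, 0.90))
  # single-SNP case
  est1 <- estimate_clade_frequencies(s, tab[1, ], 100)
  expect_equal(est1$median_frequency, 0.20)
})

test_that("estimation handles missing SNPs, low coverage and absent clades", {
  tab <- data.frame(contig = "wolb", position = c(1L, 2L, 99L),
                    allele = c("A", "A", "C"),
                    clade = c("V", "V", "ghost"), stringsAsFactors = FALSE)
  counts <- array(0L, dim = c(2, 6, 1))
  counts[1, 1, 1] <- 60L; counts[1, 4, 1] <- 40L  # coverage 100
  counts[2, 1, 1] <- 10L                          # coverage 10 < target
  s <- sync(data.frame(contig = "wolb", position = 1:2, reference = "G"),
            counts)
  expect_warning(est <- estimate_clade_frequencies(s, tab, 50),
                 "absent")
  v <- est[est$clade == "V", ]
  expect_equal(v$n_snps_used, 1L)  # the low-coverage site was excluded
  expect_equal(v$median_frequency, 0.6)
  g <- est[est$clade == "ghost", ]
  expect_true(is.na(g$median_frequency))  # missing, not zero
  expect_equal(g$n_snps_used, 0L)
})

test_that("median estimator is permutation-invariant and outlier-robust", {
  set.seed(301)
  n <- 21
  tab <- data.frame(contig = "w", position = 1:n, allele = "A",
                    clade = "V", stringsAsFactors = FALSE)
  counts <- array(0L, dim = c(n, 6, 1))
  counts[, 1, 1] <- 40L; counts[, 4, 1] <- 60L
  # corrupt 9 of 21 SNPs (< 50%) to wild values
  counts[1:9, 1, 1] <- c(rep(0L, 5), rep(100L, 4))
  counts[1:9, 4, 1] <- 100L - counts[1:9, 1, 1]
  s <- sync(data.frame(contig = "w", position = 1:n, reference = "G"),
            counts)
  est <- estimate_clade_frequencies(s, tab, 100)
  expect_equal(est$median_frequency, 0.4)
  perm <- sample(n)
  est_p <- estimate_clade_frequencies(
    sync(s$sites[perm, ], s$counts[perm, , , drop = FALSE]),
    tab, 100)
  expect_equal(est_p$median_frequency, est$median_frequency)
})

test_that("N and del reads count toward coverage but never the numerator", {
  tab <- data.frame(contig = "w", position = 1L, allele = "A",
                    clade = "V", stringsAsFactors = FALSE)
  counts <- array(0L, dim = c(1, 6, 1))
  counts[1, 1, 1] <- 50L  # A
  counts[1, 5, 1] <- 25L  # N
  counts[1, 6, 1] <- 25L  # del
  s <- sync(data.frame(contig = "w", position = 1L, reference = "G"),
            counts)
  est <- estimate_clade_frequencies(s, tab, 100)
  expect_equal(est$median_frequency, 0.5)  # 50 A / 100 total coverage
})

test_that("estimates at 50x recover simulator truth within sampling error", {
  truth <- c(V = 0.25, VI = 0.55, I_II_III = 0.20)
  tab <- make_snp_panel(30)
  s <- sample_poolseq_counts(truth, tab, mean_coverage = 80,
                             error_rate = 0, seed = 5150)
  set.seed(5151)
  est <- suppressWarnings(estimate_clade_frequencies(s, tab, 50))
  for (cl in names(truth)) {
    expect_lt(abs(est$median_frequency[est$clade == cl] - truth[cl]), 0.08)
  }
})

test_that("cumulative frequency flags unaccounted lineages", {
  est <- data.frame(replicate = "rep1", clade = bp_clades,
                    median_frequency = c(0.25, 0.55, 0.20),
                    n_snps_used = 10L)
  chk <- cumulative_frequency_check(est)
  expect_equal(chk$cumulative_frequency, 1.00)
  expect_true(chk$pass)
  est$median_frequency <- c(0.10, 0.30, 0.20)
  chk2 <- cumulative_frequency_check(est)
  expect_equal(chk2$cumulative_frequency, 0.60)
  expect_false(chk2$pass)
})

test_that("clade table io round-trips and rejects bad headers", {
  tab <- make_snp_panel(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clade_table(tab, path)
  expect_equal(read_clade_table(path), tab)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tallele\tclade", "w\t1\tA\tV"), bad)
  expect_error(read_clade_table(bad), "header")
  dup <- rbind(tab, tab[1, ])
  expect_error(write_clade_table(dup, path), "duplicate")
})

test_that("FASTA haplotype reader returns an aligned named panel", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">h1 clade V", "ACGT", "ACGT", ">h2", "acgtacgt"), path)
  seqs <- read_haplotypes(path)
  expect_equal(seqs, c(h1 = "ACGTACGT", h2 = "ACGTACGT"))
})
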