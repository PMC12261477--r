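test_that("Spearman matches the exact rank formula on all permutations of n = 5", {
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  expect_equal(nrow(perms), 120L)
  truth <- c(3, 1, 4, 2, 5)
  for (k in seq_len(nrow(perms))) {
    expect_equal(spearman_rho(perms[k, ], truth),
                 spearman_exact_no_ties(perms[k, ], truth),
                 tolerance = 1e-12)
  }
})

test_that("Spearman endpoints and error cases behave", {
  expect_equal(spearman_rho(1:4, 1:4), 1)
  expect_equal(spearman_rho(4:1, 1:4), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)),
               spearman_exact_no_ties(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)))
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rho(1, 1), "at least 2")
})

test_that("weighted averaging is exact and scale-invariant", {
  expect_equal(weighted_average(c(0.4, 0.6)), 0.5)
  expect_equal(weighted_average(c(0.4, 0.6), c(1, 0)), 0.4)
  r <- c(0.2, 0.5, 0.9)
  w <- c(1, 2, 3)
  expect_equal(weighted_average(r, w), weighted_average(r, 10 * w))
  expect_equal(weighted_average(rep(0.37, 4), c(5, 1, 2, 9)), 0.37)
  expect_error(weighted_average(r, c(1, 2)), "length")
  expect_error(weighted_average(r, c(0, 0, 0)), "zero")
})

test_that("bootstrap SD is zero for perfectly concordant assays", {
  assays <- lapply(1:3, function(k) {
    x <- stats::rnorm(30)
    data.frame(pred = x, truth = x)
  })
  names(assays) <- paste0("a", 1:3)
  bs <- bootstrap_sd(assays, B = 50, seed = 3)
  expect_equal(bs$sd, 0)
  expect_equal(bs$point, 1)
})

test_that("bootstrap is deterministic under a seed and excludes degenerate assays", {
  set.seed(5)
  assays <- list(good = data.frame(pred = stats::rnorm(40),
                                   truth = stats::rnorm(40)),
                 flat = data.frame(pred = rep(1, 10),
                                   truth = stats::rnorm(10)))
  expect_warning(b1 <- bootstrap_sd(assays, B = 100, seed = 7), "excluding")
  expect_warning(b2 <- bootstrap_sd(assays, B = 100, seed = 7), "excluding")
  expect_identical(b1$sd, b2$sd)
  expect_gte(b1$sd, 0)
})

test_that("bootstrap SD shrinks with sample size at fixed noise", {
  set.seed(11)
  make_assay <- function(n) {
    x <- stats::rnorm(n)
    data.frame(pred = x + stats::rnorm(n, sd = 0.8), truth = x)
  }
  small <- bootstrap_sd(list(a = make_assay(50)), B = 200, seed = 13)$sd
  large <- bootstrap_sd(list(a = make_assay(500)), B = 200, seed = 13)$sd
  expect_lt(large, small)
})

test_that("validation split is seed-deterministic and order-stable", {
  assay <- data.frame(mutant = paste0("A1", LETTERS[2:21][1:19]),
                      DMS_score = stats::rnorm(19))
  assay <- rbind(assay, assay, assay, assay, assay)[1:100, ]
  s1 <- validation_split(assay, fraction = 0.10, seed = 5)
  s2 <- validation_split(assay, fraction = 0.10, seed = 5)
  expect_equal(nrow(s1), 10L)
  expect_identical(s1, s2)
  expect_false(is.unsorted(as.integer(rownames(s1))))
  expect_identical(validation_split(assay, fraction = 1, seed = 1), assay)
  expect_error(validation_split(assay[0, ], 0.5), "empty")
  expect_error(validation_split(assay, 0), "fraction")
})

test_that("the ratio sweep prefers the informative source", {
  # truth generated from the profile; native logits pure noise: the
  # alignment-only endpoint must beat the model-only endpoint
  prof <- make_profile(40, concentration = 0.5, seed = 31)
  wt <- profile_consensus(prof)
  fam <- sample_msa(prof, N = 400, gap_rate = 0, seed = 32)
  sim <- simulate_dms(prof, wt, n_mutants = 120, noise_sd = 0, seed = 33)
  set.seed(34)
  noise <- logit_matrix(matrix(stats::rnorm(40 * 25), 40), role = "native")
  assays <- list(sim = data.frame(truth = sim$truth_noise_free))
  score_fn <- function(a) {
    list(sim = score_batch(wt, sim$table$mutant, family = fam,
                           native = noise, alpha = a)$score)
  }
  sweep_tab <- alpha_sweep(c(0, 1), score_fn, assays)
  expect_equal(sweep_tab$alpha, c(0, 1))
  expect_gt(sweep_tab$rho[2], sweep_tab$rho[1])
  one <- alpha_sweep(0.5, score_fn, assays)
  expect_equal(nrow(one), 1L)
})

test_that("the alpha = 0 endpoint is independent of the alignment", {
  prof <- make_profile(20, seed = 41)
  wt <- profile_consensus(prof)
  sim <- simulate_dms(prof, wt, n_mutants = 50, seed = 42)
  set.seed(43)
  nat <- logit_matrix(matrix(stats::rnorm(20 * 25), 20), role = "native")
  assays <- list(a = data.frame(truth = sim$truth_noise_free))
  rho_for <- function(msa_seed) {
    fam <- sample_msa(prof, N = 100, seed = msa_seed)
    alpha_sweep(0, function(a) {
      list(a = score_batch(wt, sim$table$mutant, family = fam, native = nat,
                           alpha = a)$score)
    }, assays)$rho
  }
  expect_identical(rho_for(1), rho_for(2))
})

test_that("assay tables round-trip through the CSV dialect", {
  tab <- data.frame(mutant = c("A1C", "A1D:C2G"), DMS_score = c(0.5, -1.2),
                    DMS_score_bin = c(1L, 0L))
  path <- tempfile(fileext = ".csv")
  write_assay_csv(tab, path)
  back <- read_assay_csv(path)
  expect_equal(back, tab)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_assay_csv(bad), "mutant")
})

test_that("evaluate_assays aggregates and groups correctly", {
  assays <- list(
    a1 = data.frame(pred = c(1, 2, 3, 4), truth = c(1, 2, 3, 4)),
    a2 = data.frame(pred = c(1, 2, 3, 4), truth = c(4, 3, 2, 1)),
    b1 = data.frame(pred = c(1, 2, 3, 4), truth = c(1, 2, 4, 3)))
  rep1 <- evaluate_assays(assays)
  expect_equal(rep1$per_assay$rho[1:2], c(1, -1))
  # grouping averages within protein before across proteins
  rep2 <- evaluate_assays(assays, groups = c("p1", "p1", "p2"))
  expect_equal(rep2$aggregate, (0 + rep1$per_assay$rho[3]) / 2)
})
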