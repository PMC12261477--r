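make_logits <- function(L, seed = 1, role = "native") {
  set.seed(seed)
  logit_matrix(matrix(stats::rnorm(L * 25), L, 25), role = role)
}

test_that("blending endpoints reproduce the inputs exactly", {
  nat <- make_logits(6, seed = 1)
  evo <- make_logits(6, seed = 2, role = "evolutionary")
  expect_equal(unclass(blend_logits(nat, evo, 0))[, ], unclass(nat)[, ],
               ignore_attr = TRUE)
  expect_equal(unclass(blend_logits(nat, evo, 1))[, ], unclass(evo)[, ],
               ignore_attr = TRUE)
  mid <- blend_logits(nat, evo, 0.8)
  # alpha = 0.8 weights the evolutionary entry by 0.8
  expect_equal(unclass(mid)[1, 1],
               0.2 * unclass(nat)[1, 1] + 0.8 * unclass(evo)[1, 1])
  expect_error(blend_logits(nat, evo, 1.2), "alpha")
  expect_error(blend_logits(nat, make_logits(5, 3), 0.5), "shape")
})

test_that("the shipped default retrieval ratio is 0.8", {
  expect_equal(default_alpha(), 0.8)
  expect_equal(formals(score_batch)$alpha, quote(default_alpha()))
})

test_that("mutant notation parses and validates against the template", {
  wt <- paste(rep("ACDEY", 100), collapse = "")  # Y at positions 5, 10, ...
  spec <- parse_mutant("Y5G", wt)
  expect_equal(spec$pos, 5L)
  expect_equal(spec$wt, "Y")
  expect_equal(spec$mut, "G")
  multi <- parse_mutant("A1C : D3E", wt)
  expect_equal(multi$pos, c(1L, 3L))
  expect_equal(format_mutant(multi), "A1C:D3E")
  # alternate separators accepted on read
  expect_equal(nrow(parse_mutant("A1C;D3E", wt)), 2L)
  expect_equal(nrow(parse_mutant("A1C,D3E", wt)), 2L)
  # wild type spellings
  expect_equal(nrow(parse_mutant("WT", wt)), 0L)
  expect_equal(nrow(parse_mutant("", wt)), 0L)
})

test_that("mutant validation errors are specific", {
  expect_error(parse_mutant("Y4G", "ACDF"), "wild-type mismatch")
  expect_error(parse_mutant("A9C", "ACDF"), "outside")
  expect_error(parse_mutant("A1", "ACDF"), "malformed")
  expect_error(parse_mutant("A1A", "ACDF"), "not a substitution")
  expect_error(parse_mutant("A1X", "ACDF"), "non-standard")
  expect_error(parse_mutant("A1C:A1G", "ACDF"), "duplicate")
})

test_that("the wild type scores exactly zero under any logits and alpha", {
  for (seed in 1:3) {
    O <- make_logits(8, seed = seed)
    expect_identical(score_mutant(O, parse_mutant("WT", "ACDEFGHI")), 0)
  }
})

test_that("scores are summed logit differences and additive over sites", {
  O <- make_logits(10, seed = 4)
  wt <- "ACDEFGHIKL"
  s1 <- score_mutant(O, parse_mutant("A1C", wt))
  expect_equal(s1, unname(unclass(O)[1, "C"] - unclass(O)[1, "A"]))
  s2 <- score_mutant(O, parse_mutant("D3E", wt))
  expect_equal(score_mutant(O, parse_mutant("A1C:D3E", wt)), s1 + s2,
               tolerance = 1e-12)
  # direct arithmetic example
  O2 <- unclass(O)
  O2[2, "A"] <- -1.0; O2[2, "C"] <- -2.5
  O2 <- logit_matrix(O2, role = "blended")
  expect_equal(score_mutant(O2, parse_mutant("C2A", wt)), 1.5)
  # positions beyond the logit matrix are a coordinate error
  expect_error(score_mutant(make_logits(3),
                            parse_mutant("L10A", "ACDEFGHIKLMN")), "beyond")
})

test_that("substitutions at fully conserved columns score -1 at alpha 1", {
  fam <- aligned_family(rep("ACDE", 8))
  sc <- score_batch("ACDE", c("WT", "A1C", "C2G", "A1C:D3E"), family = fam,
                    alpha = 1)
  expect_equal(sc$score, c(0, -1, -1, -2))
})

test_that("score is an affine function of the retrieval ratio", {
  fam <- random_family(N = 20, L = 12, gap_rate = 0, seed = 6)
  wt <- paste(ifelse(fam$sequences[1, ] %in% remscore:::STANDARD_AA,
                     fam$sequences[1, ], "A"), collapse = "")
  mt <- paste0(substr(wt, 2, 2), 2, if (substr(wt, 2, 2) == "C") "G" else "C")
  nat <- make_logits(12, seed = 7)
  s <- vapply(c(0, 0.5, 1), function(a) {
    score_batch(wt, mt, family = fam, native = nat, alpha = a)$score
  }, numeric(1))
  expect_equal(s[2], (s[1] + s[3]) / 2, tolerance = 1e-10)
})

test_that("alpha = 1 scores depend only on the alignment", {
  fam <- random_family(N = 15, L = 8, gap_rate = 0.1, seed = 8)
  wt <- "ACDEFGHI"
  a <- score_batch(wt, "A1G", family = fam, native = make_logits(8, 1),
                   alpha = 1)$score
  b <- score_batch(wt, "A1G", family = fam, native = make_logits(8, 99),
                   alpha = 1)$score
  expect_identical(a, b)
})

test_that("conservation monotonicity: more conserved wild type, lower score", {
  # same column with increasing WT frequency; substitution score nonincreasing
  scores <- vapply(c(4, 6, 8), function(n_wt) {
    grid <- matrix("C", 10, 3)
    grid[seq_len(n_wt), 2] <- "A"
    fam <- aligned_family(grid, source = "synthetic")
    evo <- evolutionary_logits(count_matrix(fam))
    score_mutant(evo, parse_mutant("A2G", "CAC"))
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("batch scores are independent of mutant order", {
  fam <- random_family(N = 12, L = 6, gap_rate = 0, seed = 10)
  wt <- "ACDEFG"
  muts <- c("A1C", "C2D", "D3E", "A1C:C2D")
  fwd <- score_batch(wt, muts, family = fam, alpha = 1)
  bwd <- score_batch(wt, rev(muts), family = fam, alpha = 1)
  expect_equal(fwd$score, rev(bwd$score))
})

test_that("length mismatches between template and alignment are rejected", {
  fam <- random_family(N = 5, L = 7, seed = 11)
  expect_error(score_batch("ACDE", "A1C", family = fam, alpha = 1),
               "re-align")
  expect_error(score_batch("ACDE", "A1C", alpha = 1), "family")
  expect_error(score_batch("ACDE", "A1C", family = NULL, native = NULL,
                           alpha = 0.5), "family")
})
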