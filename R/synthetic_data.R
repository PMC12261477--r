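#' Column profile for synthetic alignments
#'
#' Each column of the alignment gets a probability distribution over the 20
#' standard amino acids drawn from a symmetric Dirichlet. Small concentration
#' values yield near-one-hot (conserved) columns; large values yield
#' near-uniform (variable) columns.
#'
#' @param L Number of columns (residue positions).
#' @param concentration Symmetric Dirichlet parameter, > 0.
#' @param seed RNG seed.
#' @return Object of class `column_profile`: list with `probabilities`
#'   (L x 20 row-stochastic matrix, columns named by amino acid),
#'   `concentration`, `seed`.
#' @export
make_profile <- function(L, concentration = 0.5, seed = 1L) {
  stopifnot(L >= 1L, concentration > 0)
  set.seed(seed)
  g <- matrix(stats::rgamma(L * 20L, shape = concentration), L, 20L)
  # guard against all-zero rows at tiny concentrations (numerical underflow)
  zero <- rowSums(g) == 0
  if (any(zero)) g[cbind(which(zero), sample.int(20L, sum(zero), TRUE))] <- 1
  p <- g / rowSums(g)
  colnames(p) <- STANDARD_AA
  structure(list(probabilities = p, concentration = concentration,
                 seed = seed), class = "column_profile")
}

#' Consensus sequence of a profile
#'
#' @param profile A [make_profile()] result.
#' @return Amino-acid string of per-column argmax residues.
#' @export
profile_consensus <- function(profile) {
  paste(STANDARD_AA[max.col(profile$probabilities, ties.method = "first")],
        collapse = "")
}

#' Sample a synthetic alignment from a profile
#'
#' Cells are drawn i.i.d. from each column's distribution, then masked to
#' `<pad>` with probability `gap_rate`.
#'
#' @param profile A [make_profile()] result.
#' @param N Number of sequences.
#' @param gap_rate Per-cell pad probability in [0, 1).
#' @param seed RNG seed.
#' @return An [aligned_family()] with `source = "synthetic"`.
#' @export
sample_msa <- function(profile, N, gap_rate = 0, seed = 1L) {
  stopifnot(N >= 1L, gap_rate >= 0, gap_rate < 1)
  p <- profile$probabilities
  L <- nrow(p)
  set.seed(seed)
  grid <- matrix("", N, L)
  for (i in seq_len(L)) {
    grid[, i] <- sample(STANDARD_AA, N, replace = TRUE, prob = p[i, ])
  }
  if (gap_rate > 0) {
    mask <- matrix(stats::runif(N * L) < gap_rate, N, L)
    grid[mask] <- PAD_TOKEN
  }
  aligned_family(grid, query_id = "synthetic_profile", source = "synthetic")
}

#' Synthetic backbone coordinates
#'
#' `ideal_helix` traces an alpha-helical Calpha path (rise 1.5 A per residue,
#' 100 degree twist, 2.3 A helical radius), giving consecutive Calpha-Calpha
#' distances of ~3.8 A. `random_walk` uses fixed 3.8 A virtual bonds with
#' seeded random directions. Backbone N and C atoms are placed at fixed
#' offsets from each Calpha.
#'
#' @param L Number of residues.
#' @param geometry `"ideal_helix"` or `"random_walk"`.
#' @param seed RNG seed (used by `random_walk`).
#' @return A [protein_structure()].
#' @export
make_chain <- function(L, geometry = c("ideal_helix", "random_walk"),
                       seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(L >= 1L)
  if (geometry == "ideal_helix") {
    i <- seq_len(L) - 1L
    theta <- i * 100 * pi / 180
    ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  } else {
    set.seed(seed)
    dirs <- matrix(stats::rnorm(L * 3L), L, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    steps <- rbind(c(0, 0, 0), 3.8 * dirs[-1L, , drop = FALSE])
    ca <- apply(steps, 2L, cumsum)
    if (L == 1L) ca <- matrix(ca, 1L, 3L)
  }
  n <- sweep(ca, 2L, c(-1.2, 0.6, 0), "+")
  cc <- sweep(ca, 2L, c(1.2, 0.6, 0), "+")
  protein_structure(ca, n, cc, chain = "A")
}

#' Simulate a DMS assay with known ground truth
#'
#' Mutants are sampled uniformly over positions and amino acids at depths in
#' `depth_range`. The ground-truth fitness of a mutant is the sum over its
#' sites of the profile probability difference `p[t, mut] - p[t, wt]`, plus
#' Gaussian noise of sd `noise_sd`. With this construction, alpha = 1 scoring
#' on a large alignment sampled from the same profile is a plug-in estimator
#' of the noise-free truth (softmax shift-invariance makes the evolutionary
#' logit difference equal the sampled frequency difference).
#'
#' @param profile A [make_profile()] result.
#' @param wt Wild-type sequence (default: the profile consensus).
#' @param n_mutants Number of mutants (>= 2).
#' @param depth_range Integer vector of allowed mutation depths (default 1).
#' @param noise_sd Gaussian noise sd added to the ground truth.
#' @param seed RNG seed.
#' @param include_wt Prepend a `"WT"` row with ground truth 0.
#' @return Object of class `simulated_assay`: list with `wt`, `table` (data
#'   frame: `mutant`, `DMS_score`), `truth_noise_free`, `profile`, `seed`.
#' @export
simulate_dms <- function(profile, wt = profile_consensus(profile),
                         n_mutants = 100L, depth_range = 1L, noise_sd = 0,
                         seed = 1L, include_wt = FALSE) {
  stopifnot(n_mutants >= 2L, all(depth_range >= 1L), noise_sd >= 0)
  p <- profile$probabilities
  L <- nrow(p)
  wt_chars <- strsplit(wt, "")[[1]]
  stopifnot(length(wt_chars) == L)
  set.seed(seed)
  mk_one <- function() {
    depth <- if (length(depth_range) == 1L) depth_range
             else sample(depth_range, 1L)
    pos <- sort(sample.int(L, depth))
    muts <- vapply(pos, function(t) {
      sample(setdiff(STANDARD_AA, wt_chars[t]), 1L)
    }, character(1))
    paste0(wt_chars[pos], pos, muts, collapse = ":")
  }
  mutants <- unique(vapply(seq_len(3L * n_mutants), function(k) mk_one(),
                           character(1)))[seq_len(n_mutants)]
  if (anyNA(mutants)) stop("could not sample enough distinct mutants")
  truth <- vapply(mutants, function(mt) {
    spec <- parse_mutant(mt, wt)
    sum(p[cbind(spec$pos, match(spec$mut, STANDARD_AA))] -
          p[cbind(spec$pos, match(spec$wt, STANDARD_AA))])
  }, numeric(1))
  if (include_wt) {
    mutants <- c("WT", mutants)
    truth <- c(0, truth)
  }
  noisy <- truth + stats::rnorm(length(truth), sd = noise_sd)
  structure(list(
    wt = wt,
    table = data.frame(mutant = mutants, DMS_score = unname(noisy),
                       stringsAsFactors = FALSE),
    truth_noise_free = unname(truth),
    profile = profile, seed = seed), class = "simulated_assay")
}
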