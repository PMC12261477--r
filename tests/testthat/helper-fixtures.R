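# Shared fixture builders; everything is generated in code at test time.

# random aligned family over amino acids + pad, uniform column content
random_family <- function(N, L, gap_rate = 0.1, seed = 1L) {
  set.seed(seed)
  grid <- matrix(sample(remscore:::STANDARD_AA, N * L, replace = TRUE), N, L)
  if (gap_rate > 0) {
    grid[matrix(stats::runif(N * L) < gap_rate, N, L)] <- "<pad>"
  }
  aligned_family(grid, source = "synthetic")
}

write_fasta_tmp <- function(records, ext = ".a2m") {
  path <- tempfile(fileext = ext)
  lines <- character(0)
  for (nm in names(records)) lines <- c(lines, paste0(">", nm), records[[nm]])
  writeLines(lines, path)
  path
}

tiny_config <- function(...) {
  model_config(d = 2L, heads = 1L, layers = 1L, max_relative_distance = 4L,
               structure_vocab = 8L, seed = 42L, ...)
}

# random rigid transform applied to a protein_structure
rigid_transform <- function(structure, seed = 1L) {
  set.seed(seed)
  a <- stats::rnorm(3); a <- a / sqrt(sum(a^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K  # Rodrigues rotation
  shift <- stats::rnorm(3, sd = 10)
  out <- structure
  out$ca <- sweep(structure$ca %*% R, 2L, shift, "+")
  if (!is.null(out$n)) out$n <- sweep(structure$n %*% R, 2L, shift, "+")
  if (!is.null(out$c)) out$c <- sweep(structure$c %*% R, 2L, shift, "+")
  out
}

# exact Spearman for tie-free vectors via the rank-difference formula
spearman_exact_no_ties <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
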