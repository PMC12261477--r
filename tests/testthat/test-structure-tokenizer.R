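test_that("local graphs use a strict 10 A threshold", {
  s <- protein_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)))
  graphs <- build_local_graphs(s)
  g1 <- graphs[[1]]
  expect_equal(g1$nodes, c(1L, 2L))  # residue 3 at exactly 10 A is excluded
  expect_equal(g1$center, 1L)
})

test_that("dense neighborhoods keep the 40 nearest residues", {
  set.seed(11)
  cloud <- matrix(stats::rnorm(60 * 3, sd = 3), 60, 3)
  cloud[1, ] <- 0
  s <- protein_structure(cloud)
  g <- build_local_graphs(s)[[1]]
  d <- sqrt(rowSums(sweep(cloud, 2, cloud[1, ])^2))
  within <- setdiff(which(d < 10), 1L)
  expect_gt(length(within), 40L)  # the fixed seed makes the cloud dense
  expect_length(g$nodes, 41L)     # center + 40
  oracle <- within[order(d[within])][1:40]
  expect_setequal(g$nodes[-1], oracle)
  # every edge respects the strict radius
  ed <- apply(g$edges, 1, function(e) {
    sqrt(sum((g$coords[e[1], ] - g$coords[e[2], ])^2))
  })
  expect_true(all(ed < 10))
})

test_that("an isolated residue yields a single-node, zero-edge graph", {
  s <- protein_structure(rbind(c(0, 0, 0), c(50, 0, 0)))
  g <- build_local_graphs(s)[[1]]
  expect_equal(g$nodes, 1L)
  expect_equal(nrow(g$edges), 0L)
})

test_that("graph encoding is invariant to rigid transforms", {
  s <- make_chain(20, "ideal_helix")
  enc <- init_structure_encoder(seed = 3)
  e1 <- encode_local_graph(build_local_graphs(s)[[8]], enc)
  s2 <- rigid_transform(s, seed = 17)
  e2 <- encode_local_graph(build_local_graphs(s2)[[8]], enc)
  expect_equal(ncol(e1), 256L)
  expect_lt(max(abs(e1 - e2)), 1e-5)
})

test_that("a single-node graph encodes to one finite row", {
  s <- protein_structure(matrix(c(0, 0, 0), 1, 3))
  enc <- init_structure_encoder(seed = 1)
  e <- encode_local_graph(build_local_graphs(s)[[1]], enc)
  expect_equal(dim(e), c(1L, 256L))
  expect_true(all(is.finite(e)))
})

test_that("mean pooling matches direct column sums", {
  set.seed(4)
  m <- matrix(stats::rnorm(20), 5, 4)
  expect_equal(pool_graph_embedding(m), colSums(m) / 5, tolerance = 1e-12)
  expect_equal(pool_graph_embedding(m[1, , drop = FALSE]), m[1, ])
  expect_equal(pool_graph_embedding(rbind(m[1, ], -m[1, ])), rep(0, 4))
  expect_error(pool_graph_embedding(m[0, , drop = FALSE]), "no nodes")
})

test_that("denoising pretraining is deterministic and beats the corruption baseline", {
  helices <- lapply(1:10, function(i) make_chain(25, "ideal_helix"))
  fit <- train_denoising_autoencoder(helices, noise_sigma = 0.3,
                                     brownian_sigma = 0.1, steps = 200L,
                                     seed = 5L)
  fit2 <- train_denoising_autoencoder(helices, noise_sigma = 0.3,
                                      brownian_sigma = 0.1, steps = 200L,
                                      seed = 5L)
  expect_identical(fit$loss_trace, fit2$loss_trace)
  expect_lt(mean(utils::tail(fit$loss_trace, 20)),
            mean(fit$baseline_trace))
  expect_error(train_denoising_autoencoder(list()), "empty")
})

test_that("zero corruption makes the denoising input identical to the target", {
  helices <- list(make_chain(10, "ideal_helix"))
  fit <- train_denoising_autoencoder(helices, noise_sigma = 0,
                                     brownian_sigma = 0, steps = 3L,
                                     seed = 2L)
  expect_equal(fit$baseline_trace, rep(0, 3))
})

test_that("codebook fitting recovers well-separated blob centers", {
  set.seed(19)
  centers <- matrix(c(0, 0, 20, 0, 0, 20), 3, 2, byrow = TRUE)
  pts <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(stats::rnorm(60 * 2, sd = 0.5), 60, 2), 2, centers[k, ], "+")
  }))
  cb <- fit_codebook(pts, k = 3, seed = 7)
  found <- cb$centroids[apply(centers, 1, function(ctr) {
    which.min(colSums((t(cb$centroids) - ctr)^2))
  }), , drop = FALSE]
  expect_lt(max(abs(found - centers)), 3 * 0.5)
})

test_that("k = 1 gives the global mean; M < k is an error", {
  set.seed(2)
  v <- matrix(stats::rnorm(40), 10, 4)
  cb <- fit_codebook(v, k = 1, seed = 1)
  expect_equal(as.vector(cb$centroids), colMeans(v), tolerance = 1e-9)
  expect_error(fit_codebook(v, k = 11), "insufficient")
})

test_that("saturated clustering (M = k) reaches zero inertia", {
  set.seed(3)
  v <- matrix(stats::rnorm(12), 4, 3)
  cb <- fit_codebook(v, k = 4, seed = 2)
  expect_equal(cb$inertia, 0, tolerance = 1e-9)
})

test_that("Lloyd iterations never increase the K-means objective", {
  set.seed(23)
  v <- matrix(stats::rnorm(200 * 4), 200, 4)
  inertia <- vapply(1:6, function(iters) {
    fit_codebook(v, k = 8, seed = 5, max_iter = iters)$inertia
  }, numeric(1))
  expect_true(all(diff(inertia) <= 1e-9))
})

test_that("token assignment equals the exhaustive nearest-centroid argmin", {
  set.seed(31)
  cb <- fit_codebook(matrix(stats::rnorm(50 * 6), 50, 6), k = 16, seed = 9)
  v <- matrix(stats::rnorm(1000 * 6), 1000, 6)
  tok <- assign_tokens(v, cb)
  oracle <- apply(v, 1, function(x) {
    which.min(colSums((t(cb$centroids) - x)^2))
  })
  expect_equal(as.integer(tok), unname(oracle))
})

test_that("assignment ties break toward the lowest centroid index", {
  cb <- structure(list(centroids = rbind(c(0, 5), c(0, 1), c(3, 0),
                                         c(9, 9), c(0, -1)),
                       k = 5L), class = "structure_codebook")
  expect_equal(as.integer(assign_tokens(rbind(c(0, 0)), cb)), 2L)
  expect_equal(as.integer(assign_tokens(cb$centroids[4, , drop = FALSE], cb)),
               4L)
  expect_error(assign_tokens(matrix(0, 1, 3), cb), "width")
})

test_that("structure tokens are one per residue and rigid-transform invariant", {
  s <- make_chain(24, "ideal_helix")
  enc <- init_structure_encoder(seed = 6)
  set.seed(41)
  cb <- fit_codebook(matrix(stats::rnorm(64 * 256, sd = 0.5), 64, 256),
                     k = 8, seed = 3)
  tok <- tokenize_structure(s, enc, cb)
  expect_length(tok, 24L)
  expect_true(all(tok >= 1L & tok <= 8L))
  for (seed in 1:5) {
    tok2 <- tokenize_structure(rigid_transform(s, seed = seed), enc, cb)
    expect_identical(as.integer(tok2), as.integer(tok))
  }
  # congruent interior neighborhoods of an ideal helix share a token
  long <- make_chain(40, "ideal_helix")
  tl <- tokenize_structure(long, enc, cb)
  expect_equal(length(unique(tl[15:25])), 1L)
})

test_that("structure tokens round-trip through the text format", {
  tok <- structure(c(3L, 1L, 7L), k = 8L, class = "structure_tokens")
  path <- tempfile(fileext = ".txt")
  write_structure_tokens(tok, path)
  back <- read_structure_tokens(path)
  expect_equal(as.integer(back), c(3L, 1L, 7L))
  expect_equal(attr(back, "k"), 8L)
})

test_that("PDB writing and reading round-trips Calpha coordinates", {
  s <- make_chain(12, "random_walk", seed = 8)
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(s, path)
  back <- read_structure_pdb(path)
  expect_equal(back$length, 12L)
  expect_equal(back$ca, s$ca, tolerance = 1e-3)  # PDB has 3 decimal places
})
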