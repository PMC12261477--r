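#' Protein backbone structure
#'
#' Per-residue backbone coordinates (N, Calpha, C) in Angstroms. Only the
#' Calpha trace is used for neighborhood geometry; N and C are carried for
#' PDB round-tripping.
#'
#' @param ca L x 3 matrix of Calpha coordinates (required).
#' @param n,c Optional L x 3 matrices of backbone N and C coordinates.
#' @param chain Chain identifier.
#' @param resno Residue numbers (default 1..L).
#' @return Object of class `protein_structure`.
#' @export
protein_structure <- function(ca, n = NULL, c = NULL, chain = "A",
                              resno = seq_len(nrow(ca))) {
  ca <- as.matrix(ca)
  stopifnot(ncol(ca) == 3L, nrow(ca) >= 1L, all(is.finite(ca)))
  structure(list(ca = ca, n = n, c = c, chain = chain, resno = resno,
                 length = nrow(ca)),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d residues, chain %s\n", x$length, x$chain))
  invisible(x)
}

#' Read a backbone structure from a PDB file
#'
#' First model only; residues lacking a Calpha atom are skipped with a
#' warning.
#'
#' @param path PDB file path.
#' @param chain Chain to extract (default: first chain in the file).
#' @return A [protein_structure()].
#' @export
read_structure_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  atoms <- pdb$atom
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain == chain & atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records for chain ", chain)
  resnos <- unique(atoms$resno)
  pick <- function(resno, elety) {
    hit <- atoms[atoms$resno == resno & atoms$elety == elety, , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    as.numeric(hit[1L, c("x", "y", "z")])
  }
  ca <- list(); nn <- list(); cc <- list(); kept <- integer(0)
  for (r in resnos) {
    ca_r <- pick(r, "CA")
    if (is.null(ca_r)) {
      warning("residue ", r, " lacks a CA atom; skipped")
      next
    }
    kept <- c(kept, r)
    ca[[length(ca) + 1L]] <- ca_r
    nn[[length(nn) + 1L]] <- pick(r, "N") %||% ca_r
    cc[[length(cc) + 1L]] <- pick(r, "C") %||% ca_r
  }
  if (length(kept) == 0L) stop("no residues with CA atoms in chain ", chain)
  protein_structure(do.call(rbind, ca), do.call(rbind, nn), do.call(rbind, cc),
                    chain = chain, resno = kept)
}

#' Write a backbone structure to a PDB file
#'
#' @param structure A [protein_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  L <- structure$length
  n <- structure$n %||% structure$ca
  cc <- structure$c %||% structure$ca
  xyz <- numeric(0)
  elety <- character(0); resno <- integer(0)
  for (i in seq_len(L)) {
    xyz <- c(xyz, n[i, ], structure$ca[i, ], cc[i, ])
    elety <- c(elety, "N", "CA", "C")
    resno <- c(resno, rep(structure$resno[i], 3L))
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, elety = elety,
                   resid = rep("ALA", length(elety)),
                   chain = rep(structure$chain, length(elety)),
                   eleno = seq_along(elety))
  invisible(path)
}

#' Local spatial neighborhood graphs
#'
#' For each residue, neighbors are the residues whose Calpha lies strictly
#' within `radius` Angstroms, truncated to the `max_neighbors` spatially
#' nearest; any two included nodes at pairwise distance `< radius` are
#' connected by an undirected edge.
#'
#' @param structure A [protein_structure()].
#' @param radius Neighborhood radius in Angstroms (default 10).
#' @param max_neighbors Cap on the neighbor count, excluding the center
#'   (default 40).
#' @return List of `local_graph` objects, one per residue, each with fields
#'   `center` (residue index), `nodes` (residue indices, center first),
#'   `coords` (n x 3), and `edges` (two-column matrix of local node indices).
#' @export
build_local_graphs <- function(structure, radius = 10, max_neighbors = 40L) {
  ca <- structure$ca
  L <- nrow(ca)
  if (L == 0L) stop("empty structure")
  D <- as.matrix(stats::dist(ca))
  lapply(seq_len(L), function(i) {
    d <- D[i, ]
    nb <- setdiff(which(d < radius), i)
    nb <- nb[order(d[nb], nb)]
    if (length(nb) > max_neighbors) nb <- nb[seq_len(max_neighbors)]
    nodes <- c(i, nb)
    sub <- D[nodes, nodes, drop = FALSE]
    pairs <- which(upper.tri(sub) & sub < radius, arr.ind = TRUE)
    # note: the function argument shadows base::structure() in this scope
    g <- list(center = i, nodes = nodes,
              coords = ca[nodes, , drop = FALSE],
              edges = unname(pairs), dists = sub)
    class(g) <- "local_graph"
    g
  })
}

rbf_expand <- function(d, centers, sigma) {
  outer(d, centers, function(x, c) exp(-(x - c)^2 / (2 * sigma^2)))
}

#' Initialize the rotation-invariant graph encoder
#'
#' The encoder operates on scalar geometric features only (RBF-expanded
#' inter-node distances and node degree), so its output is invariant to rigid
#' rotation and translation of the input coordinates by construction. Six
#' neighborhood-averaging layers map the features to a `out_dim`-dimensional
#' embedding per node (default 256).
#'
#' @param seed RNG seed for weight initialization.
#' @param n_layers Number of message-passing layers (default 6).
#' @param hidden Hidden width of intermediate layers.
#' @param out_dim Output embedding width (default 256).
#' @param rbf_k Number of radial basis functions on [0, radius].
#' @param radius Distance range covered by the RBF centers.
#' @return Parameter list of class `structure_encoder_params` (encoder
#'   weights plus an untrained displacement-decoder head used by
#'   [train_denoising_autoencoder()]).
#' @export
init_structure_encoder <- function(seed = 1L, n_layers = 6L, hidden = 64L,
                                   out_dim = 256L, rbf_k = 16L, radius = 10) {
  set.seed(seed)
  widths <- c(rbf_k + 1L, rep(hidden, n_layers - 1L), out_dim)
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  W <- lapply(seq_len(n_layers), function(l) rmat(widths[l], widths[l + 1L]))
  b <- lapply(seq_len(n_layers), function(l) rep(0, widths[l + 1L]))
  dec_in <- rbf_k + 2L * out_dim
  structure(list(
    enc = list(W = W, b = b),
    dec = list(W1 = rmat(dec_in, 16L), b1 = rep(0, 16L),
               W2 = rmat(16L, 1L) * 0),  # start as identity corruption
    rbf_centers = seq(0, radius, length.out = rbf_k), rbf_sigma = 1,
    n_layers = n_layers, out_dim = out_dim, seed = seed),
    class = "structure_encoder_params")
}

# scalar node features + row-normalized (self-included) adjacency
graph_features <- function(graph, params) {
  n <- nrow(graph$coords)
  K <- length(params$rbf_centers)
  feats <- matrix(0, n, K + 1L)
  A <- diag(n)
  if (nrow(graph$edges) > 0L) {
    for (e in seq_len(nrow(graph$edges))) {
      a <- graph$edges[e, 1L]; b <- graph$edges[e, 2L]
      d <- sqrt(sum((graph$coords[a, ] - graph$coords[b, ])^2))
      phi <- rbf_expand(d, params$rbf_centers, params$rbf_sigma)
      feats[a, seq_len(K)] <- feats[a, seq_len(K)] + phi
      feats[b, seq_len(K)] <- feats[b, seq_len(K)] + phi
      A[a, b] <- 1; A[b, a] <- 1
    }
  }
  deg <- rowSums(A) - 1
  feats[, K + 1L] <- deg / max(1, max(deg))
  list(feats = feats, A_norm = A / rowSums(A))
}

encode_graph_tape <- function(tape, enc_nodes, graph, params) {
  gf <- graph_features(graph, params)
  Ab <- ad_const(tape, gf$A_norm)
  H <- ad_const(tape, gf$feats)
  for (l in seq_along(enc_nodes$W)) {
    M <- ad_matmul(tape, Ab, H)
    H <- ad_tanh(tape, ad_add_bias(tape, ad_matmul(tape, M, enc_nodes$W[[l]]),
                                   enc_nodes$b[[l]]))
  }
  H
}

wrap_encoder <- function(tape, params) {
  list(W = lapply(params$enc$W, function(w) ad_param(tape, w)),
       b = lapply(params$enc$b, function(v) ad_param(tape, matrix(v, nrow = 1L))))
}

#' Encode a local structure graph
#'
#' @param graph A `local_graph` from [build_local_graphs()].
#' @param params Encoder parameters from [init_structure_encoder()] or
#'   [train_denoising_autoencoder()].
#' @return nodes x `out_dim` embedding matrix; invariant to rigid rotation
#'   and translation of the input coordinates.
#' @export
encode_local_graph <- function(graph, params) {
  tape <- ad_tape()
  en <- wrap_encoder(tape, params)
  encode_graph_tape(tape, en, graph, params)$value
}

# whole-chain graph used by the denoising objective
chain_graph <- function(ca, radius = 10) {
  n <- nrow(ca)
  D <- as.matrix(stats::dist(ca))
  pairs <- which(upper.tri(D) & D < radius, arr.ind = TRUE)
  structure(list(center = NA_integer_, nodes = seq_len(n), coords = ca,
                 edges = unname(pairs), dists = D),
            class = "local_graph")
}

#' Denoising pretraining of the structure encoder
#'
#' Calpha coordinates are corrupted with i.i.d. 3D Gaussian displacements
#' (sd `noise_sigma`) plus a cumulative random walk along the chain (per-step
#' sd `brownian_sigma`). A displacement decoder predicts, for each node, a
#' correction as an edge-gated sum of unit direction vectors to its spatial
#' neighbors (keeping the prediction equivariant); the loss is the mean
#' squared error between corrected and clean coordinates. Deterministic under
#' `seed`.
#'
#' @param structures List of [protein_structure()] objects.
#' @param noise_sigma,brownian_sigma Corruption magnitudes in Angstroms.
#' @param steps Optimization steps (one structure per step, cycled).
#' @param seed RNG seed.
#' @param lr Adam learning rate.
#' @param params Optional warm-start [init_structure_encoder()] parameters.
#' @param radius Neighborhood radius for the chain graph.
#' @return List with trained `params`, per-step `loss_trace`, and
#'   `baseline_trace` (mean squared corruption per step, the
#'   predict-the-corrupted-input baseline).
#' @export
train_denoising_autoencoder <- function(structures, noise_sigma = 0.3,
                                        brownian_sigma = 0.1, steps = 200L,
                                        seed = 1L, lr = 1e-3, params = NULL,
                                        radius = 10) {
  if (length(structures) == 0L) stop("empty structure corpus")
  stopifnot(noise_sigma >= 0, brownian_sigma >= 0)
  params <- params %||% init_structure_encoder(seed = seed)
  flat <- list()
  for (l in seq_along(params$enc$W)) {
    flat[[paste0("W", l)]] <- params$enc$W[[l]]
    flat[[paste0("b", l)]] <- matrix(params$enc$b[[l]], nrow = 1L)
  }
  flat$dW1 <- params$dec$W1
  flat$db1 <- matrix(params$dec$b1, nrow = 1L)
  flat$dW2 <- params$dec$W2
  opt <- adam_state(flat)
  set.seed(seed)
  trace <- numeric(steps); baseline <- numeric(steps)
  for (step in seq_len(steps)) {
    s <- structures[[(step - 1L) %% length(structures) + 1L]]
    ca <- s$ca
    L <- nrow(ca)
    gauss <- matrix(stats::rnorm(L * 3L, sd = noise_sigma), L, 3L)
    brown <- apply(matrix(stats::rnorm(L * 3L, sd = brownian_sigma), L, 3L),
                   2L, cumsum)
    if (L == 1L) brown <- matrix(brown, 1L, 3L)
    corrupted <- ca + gauss + brown
    baseline[step] <- mean((corrupted - ca)^2)
    g <- chain_graph(corrupted, radius = radius)
    tape <- ad_tape()
    en <- list(W = lapply(seq_along(params$enc$W),
                          function(l) ad_param(tape, flat[[paste0("W", l)]])),
               b = lapply(seq_along(params$enc$b),
                          function(l) ad_param(tape, flat[[paste0("b", l)]])))
    dW1 <- ad_param(tape, flat$dW1)
    db1 <- ad_param(tape, flat$db1)
    dW2 <- ad_param(tape, flat$dW2)
    H <- encode_graph_tape(tape, en, g, params)
    if (nrow(g$edges) > 0L) {
      ea <- c(g$edges[, 1L], g$edges[, 2L])
      eb <- c(g$edges[, 2L], g$edges[, 1L])
      dvec <- corrupted[eb, , drop = FALSE] - corrupted[ea, , drop = FALSE]
      dlen <- sqrt(rowSums(dvec^2))
      u <- dvec / pmax(dlen, 1e-8)
      phi <- rbf_expand(dlen, params$rbf_centers, params$rbf_sigma)
      X <- ad_cbind(tape, list(ad_const(tape, phi),
                               ad_rows(tape, H, ea),
                               ad_rows(tape, H, eb)))
      S1 <- ad_tanh(tape, ad_add_bias(tape, ad_matmul(tape, X, dW1), db1))
      sgate <- ad_matmul(tape, S1, dW2)
      contrib <- ad_scale_rows_const(tape, sgate, u)
      disp <- ad_scatter_rows(tape, contrib, ea, L)
      pred <- ad_add(tape, disp, ad_const(tape, corrupted))
    } else {
      pred <- ad_const(tape, corrupted)
    }
    loss <- ad_mse(tape, pred, ca)
    ad_backward(tape, loss)
    trace[step] <- loss$value
    grads <- list()
    for (l in seq_along(en$W)) {
      grads[[paste0("W", l)]] <- en$W[[l]]$grad
      grads[[paste0("b", l)]] <- en$b[[l]]$grad
    }
    grads$dW1 <- dW1$grad; grads$db1 <- db1$grad; grads$dW2 <- dW2$grad
    upd <- adam_step(flat, grads, opt, lr = lr)
    flat <- upd$params; opt <- upd$state
  }
  for (l in seq_along(params$enc$W)) {
    params$enc$W[[l]] <- flat[[paste0("W", l)]]
    params$enc$b[[l]] <- as.vector(flat[[paste0("b", l)]])
  }
  params$dec$W1 <- flat$dW1
  params$dec$b1 <- as.vector(flat$db1)
  params$dec$W2 <- flat$dW2
  list(params = params, loss_trace = trace, baseline_trace = baseline)
}

#' Mean-pool node embeddings to a single vector
#'
#' @param node_embeddings nodes x D matrix.
#' @return Numeric vector of length D (column means).
#' @export
pool_graph_embedding <- function(node_embeddings) {
  node_embeddings <- as.matrix(node_embeddings)
  if (nrow(node_embeddings) == 0L) stop("no nodes to pool")
  colMeans(node_embeddings)
}

#' Fit a structure codebook by K-means
#'
#' Seeded k-means++ initialization followed by Lloyd iterations
#' (`stats::kmeans`). Deterministic under `seed`.
#'
#' @param vectors M x D matrix of pooled local-structure embeddings.
#' @param k Number of centroids (default 2048).
#' @param seed RNG seed.
#' @param max_iter Maximum Lloyd iterations.
#' @return Object of class `structure_codebook` with `centroids` (k x D),
#'   `k`, `seed`, `iterations`, `inertia`.
#' @export
fit_codebook <- function(vectors, k = 2048L, seed = 1L, max_iter = 25L) {
  vectors <- as.matrix(vectors)
  M <- nrow(vectors)
  if (M < k) stop("insufficient data: ", M, " vectors for k = ", k)
  set.seed(seed)
  init <- kmeanspp_init(vectors, k)
  fit <- tryCatch(
    suppressWarnings(stats::kmeans(vectors, centers = init,
                                   iter.max = max_iter, algorithm = "Lloyd")),
    error = function(e) {
      suppressWarnings(stats::kmeans(vectors, centers = init,
                                     iter.max = max_iter,
                                     algorithm = "MacQueen"))
    })
  structure(list(centroids = unname(fit$centers), k = as.integer(k),
                 seed = as.integer(seed), iterations = fit$iter,
                 inertia = fit$tot.withinss),
            class = "structure_codebook")
}

kmeanspp_init <- function(x, k) {
  M <- nrow(x)
  x2 <- rowSums(x^2)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(M, 1L)
  centers[1L, ] <- x[idx, ]
  dmin <- x2 - 2 * as.vector(x %*% x[idx, ]) + sum(x[idx, ]^2)
  dmin <- pmax(dmin, 0)
  if (k > 1L) {
    for (j in 2L:k) {
      p <- if (sum(dmin) > 0) dmin / sum(dmin) else rep(1 / M, M)
      idx <- sample.int(M, 1L, prob = p)
      centers[j, ] <- x[idx, ]
      d2 <- x2 - 2 * as.vector(x %*% x[idx, ]) + sum(x[idx, ]^2)
      dmin <- pmin(dmin, pmax(d2, 0))
    }
  }
  # kmeans() requires distinct centers
  centers[!duplicated(round(centers, 12L)), , drop = FALSE]
}

#' Assign structure tokens by nearest centroid
#'
#' Euclidean nearest-centroid assignment with ties broken toward the lowest
#' centroid index. Token ids are 1-based (token i = centroid row i).
#'
#' @param vectors L x D matrix.
#' @param codebook A [fit_codebook()] result.
#' @return Integer vector of length L (class `structure_tokens`), values in
#'   `[1, k]`, with attribute `k`.
#' @export
assign_tokens <- function(vectors, codebook) {
  vectors <- as.matrix(vectors)
  cb <- codebook$centroids
  if (ncol(vectors) != ncol(cb)) {
    stop("embedding width ", ncol(vectors), " does not match codebook width ",
         ncol(cb))
  }
  d2 <- outer(rowSums(vectors^2), rep(1, nrow(cb))) -
    2 * tcrossprod(vectors, cb) +
    outer(rep(1, nrow(vectors)), rowSums(cb^2))
  tokens <- max.col(-d2, ties.method = "first")
  structure(as.integer(tokens), k = codebook$k, class = "structure_tokens")
}

#' Tokenize a protein structure
#'
#' Composition of the local-structure pipeline: per-residue neighborhood
#' graphs, rotation-invariant encoding, mean pooling, nearest-centroid
#' codebook assignment. Returns one token per residue.
#'
#' @param structure A [protein_structure()].
#' @param params Encoder parameters.
#' @param codebook A [fit_codebook()] result.
#' @param radius,max_neighbors Neighborhood parameters, see
#'   [build_local_graphs()].
#' @return Integer `structure_tokens` of length `structure$length`.
#' @export
tokenize_structure <- function(structure, params, codebook, radius = 10,
                               max_neighbors = 40L) {
  graphs <- build_local_graphs(structure, radius, max_neighbors)
  pooled <- t(vapply(graphs, function(g) {
    pool_graph_embedding(encode_local_graph(g, params))
  }, numeric(params$out_dim)))
  assign_tokens(pooled, codebook)
}

#' Write / read structure tokens
#'
#' Plain-text format: a `#`-prefixed header recording the codebook size, then
#' one integer token per line.
#'
#' @param tokens A `structure_tokens` vector.
#' @param path File path.
#' @return `path` invisibly; `read_structure_tokens` returns the tokens.
#' @export
write_structure_tokens <- function(tokens, path) {
  writeLines(c(sprintf("# structure tokens; k=%d", attr(tokens, "k") %||% NA),
               as.character(as.integer(tokens))), path)
  invisible(path)
}

#' @rdname write_structure_tokens
#' @export
read_structure_tokens <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  k <- if (length(header) > 0L) {
    m <- regmatches(header[1], regexpr("k=[0-9]+", header[1]))
    if (length(m) > 0L) as.integer(sub("k=", "", m)) else NA_integer_
  } else NA_integer_
  structure(as.integer(body), k = k, class = "structure_tokens")
}
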