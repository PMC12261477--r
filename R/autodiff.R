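# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Nodes are environments holding a value, an accumulated gradient, parent
# references and a backward closure. Creation order is a valid topological
# order, so backpropagation walks the tape in reverse. Only the operations
# needed by the toy attention LM and the denoising structure encoder are
# implemented. Internal; not exported.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    requires_grad = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$requires_grad <- requires_grad
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_accum <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

ad_param <- function(tape, value) ad_node(tape, value)
ad_const <- function(tape, value) ad_node(tape, value, requires_grad = FALSE)

ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (k in seq(tape$n, 1L)) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(g) {
    ad_accum(a, g %*% t(b$value))
    ad_accum(b, t(a$value) %*% g)
  })
}

# a %*% t(b)
ad_matmul_t <- function(tape, a, b) {
  ad_node(tape, tcrossprod(a$value, b$value), list(a, b), function(g) {
    ad_accum(a, g %*% b$value)
    ad_accum(b, t(g) %*% a$value)
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

# add a length-ncol bias vector to every row
ad_add_bias <- function(tape, a, bias) {
  ad_node(tape, sweep(a$value, 2L, bias$value, "+"), list(a, bias),
          function(g) {
            ad_accum(a, g)
            ad_accum(bias, matrix(colSums(g), nrow = 1L))
          })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, list(a), function(g) ad_accum(a, g * s))
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ad_node(tape, v, list(a), function(g) ad_accum(a, g * (1 - v^2)))
}

# gather rows by integer index (with repeats); embedding lookup
ad_rows <- function(tape, a, idx) {
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    agg <- rowsum(g, group = idx)
    da <- matrix(0, nrow(a$value), ncol(a$value))
    da[as.integer(rownames(agg)), ] <- agg
    ad_accum(a, da)
  })
}

# scatter-add rows of a (m x d) into n rows grouped by idx (length m)
ad_scatter_rows <- function(tape, a, idx, n) {
  v <- matrix(0, n, ncol(a$value))
  agg <- rowsum(a$value, group = idx)
  v[as.integer(rownames(agg)), ] <- agg
  ad_node(tape, v, list(a), function(g) {
    ad_accum(a, g[idx, , drop = FALSE])
  })
}

ad_row_softmax <- function(tape, a) {
  x <- a$value
  p <- exp(x - apply(x, 1L, max))
  p <- p / rowSums(p)
  ad_node(tape, p, list(a), function(g) {
    ad_accum(a, (g - rowSums(g * p)) * p)
  })
}

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, lapply(nodes, `[[`, "value")), nodes,
          function(g) {
            for (k in seq_along(nodes)) {
              ad_accum(nodes[[k]], g[, starts[k]:ends[k], drop = FALSE])
            }
          })
}

# value[i, j] = a[i, idxmat[i, j]]; idxmat is a constant integer matrix
ad_gather_cols <- function(tape, a, idxmat) {
  v <- matrix(a$value[cbind(rep(seq_len(nrow(idxmat)), ncol(idxmat)),
                            as.vector(idxmat))],
              nrow(idxmat), ncol(idxmat))
  ad_node(tape, v, list(a), function(g) {
    da <- matrix(0, nrow(a$value), ncol(a$value))
    for (k in sort(unique(as.vector(idxmat)))) {
      sel <- idxmat == k
      da[, k] <- da[, k] + rowSums(g * sel)
    }
    ad_accum(a, da)
  })
}

# value[i, j] = a[idxmat[i, j], j]
ad_gather_rows_mat <- function(tape, a, idxmat) {
  v <- matrix(a$value[cbind(as.vector(idxmat),
                            rep(seq_len(ncol(idxmat)), each = nrow(idxmat)))],
              nrow(idxmat), ncol(idxmat))
  ad_node(tape, v, list(a), function(g) {
    da <- matrix(0, nrow(a$value), ncol(a$value))
    for (k in sort(unique(as.vector(idxmat)))) {
      sel <- idxmat == k
      da[k, ] <- da[k, ] + colSums(g * sel)
    }
    ad_accum(a, da)
  })
}

# rows of constant matrix u (m x d) scaled by column-vector node s (m x 1)
ad_scale_rows_const <- function(tape, s, u) {
  ad_node(tape, u * as.vector(s$value), list(s), function(g) {
    ad_accum(s, matrix(rowSums(g * u), ncol = 1L))
  })
}

# mean squared error against a constant target matrix
ad_mse <- function(tape, a, target) {
  d <- a$value - target
  ad_node(tape, mean(d^2), list(a), function(g) {
    ad_accum(a, g * 2 * d / length(d))
  })
}

# mean cross-entropy of rows `rows` of logits against integer targets
ad_masked_ce <- function(tape, logits, rows, targets) {
  x <- logits$value[rows, , drop = FALSE]
  p <- exp(x - apply(x, 1L, max))
  p <- p / rowSums(p)
  n <- length(rows)
  loss <- -mean(log(p[cbind(seq_len(n), targets)]))
  ad_node(tape, loss, list(logits), function(g) {
    d <- p
    d[cbind(seq_len(n), targets)] <- d[cbind(seq_len(n), targets)] - 1
    da <- matrix(0, nrow(logits$value), ncol(logits$value))
    da[rows, ] <- g * d / n
    ad_accum(logits, da)
  })
}

# ---- Adam optimizer over a flat named list of parameter matrices ----

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-2, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# flatten a nested parameter list to a flat named list (and back)
flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(x[[nm]])) out <- c(out, flatten_params(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}

unflatten_params <- function(flat, skeleton) {
  assign_one <- function(x, keys, value) {
    if (length(keys) == 1L) x[[keys]] <- value
    else x[[keys[1]]] <- assign_one(x[[keys[1]]], keys[-1], value)
    x
  }
  for (key in names(flat)) {
    skeleton <- assign_one(skeleton, strsplit(key, ".", fixed = TRUE)[[1]],
                           flat[[key]])
  }
  skeleton
}
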