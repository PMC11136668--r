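## Minimal dense/graph neural-network machinery: parameter containers,
## activations, an Adam optimizer, and a stack of edge-weighted graph
## convolutions with analytic backpropagation. Everything is plain base-R
## matrix algebra; graphs are processed one at a time (they are small), so
## predictions are independent of batching by construction.

.relu <- function(x) pmax(x, 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.addb <- function(m, b) sweep(m, 2, b, "+")

.init_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
}

## zero-structured copy of a parameter list
.zeros_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

.params_add <- function(a, b) {
  for (k in seq_along(a)) {
    a[[k]] <- if (is.list(a[[k]])) .params_add(a[[k]], b[[k]])
              else a[[k]] + b[[k]]
  }
  a
}

.params_scale <- function(a, s) rapply(a, function(x) x * s, how = "replace")

.count_params <- function(p) {
  sum(unlist(rapply(p, length, how = "unlist")))
}

## ---------------------------------------------------------------- Adam

.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

.adam_step_rec <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (k in seq_along(p)) {
    if (is.list(p[[k]])) {
      r <- .adam_step_rec(p[[k]], g[[k]], m[[k]], v[[k]], lr, t, b1, b2, eps)
      p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
    } else {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * g[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * g[[k]]^2
      mh <- m[[k]] / (1 - b1^t)
      vh <- v[[k]] / (1 - b2^t)
      p[[k]] <- p[[k]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(p = p, m = m, v = v)
}

.adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  r <- .adam_step_rec(params, grads, state$m, state$v, lr, state$t)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

## ----------------------------------------------- graph preprocessing

## dense symmetric edge-weight matrix (1/d on edges, zero diagonal)
.adj_matrix <- function(graph) {
  n <- nrow(graph$node_features)
  W <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    W[graph$edges] <- graph$edge_weights
    W[graph$edges[, c(2, 1), drop = FALSE]] <- graph$edge_weights
  }
  W
}

## propagation operator: weighted adjacency plus self-loops (sum
## aggregation, so degree information survives the convolution)
.prop_matrix <- function(graph) {
  .adj_matrix(graph) + diag(nrow(graph$node_features))
}

## ------------------------------------- GCN stack (relu convolutions)

.gcn_init <- function(n_layers, f_in, hidden) {
  lapply(seq_len(n_layers), function(l) {
    list(W = .init_mat(if (l == 1) f_in else hidden, hidden),
         b = numeric(hidden))
  })
}

## forward: returns list(H = list of activations H0..HL, Q = pre-products)
.gcn_forward <- function(S, X, layers) {
  H <- vector("list", length(layers) + 1L)
  Q <- vector("list", length(layers))
  H[[1]] <- X
  for (l in seq_along(layers)) {
    Q[[l]] <- S %*% H[[l]]
    H[[l + 1L]] <- .relu(.addb(Q[[l]] %*% layers[[l]]$W, layers[[l]]$b))
  }
  list(H = H, Q = Q)
}

## backward: grads for each layer; S symmetric
.gcn_backward <- function(S, cache, layers, dH_top, grads) {
  dH <- dH_top
  for (l in rev(seq_along(layers))) {
    dZ <- dH * (cache$H[[l + 1L]] > 0)
    grads[[l]]$W <- grads[[l]]$W + crossprod(cache$Q[[l]], dZ)
    grads[[l]]$b <- grads[[l]]$b + colSums(dZ)
    if (l > 1L) dH <- S %*% (dZ %*% t(layers[[l]]$W))
  }
  grads
}

## ------------------------------------- dense head (relu hidden layers)

.head_init <- function(f_in, hidden, n_out, n_hidden_layers = 1L) {
  dims <- c(f_in, rep(hidden, n_hidden_layers), n_out)
  lapply(seq_len(length(dims) - 1L), function(l)
    list(W = .init_mat(dims[l], dims[l + 1L]), b = numeric(dims[l + 1L])))
}

.head_forward <- function(x, layers) {
  a <- vector("list", length(layers) + 1L)
  a[[1]] <- x
  for (l in seq_along(layers)) {
    z <- .addb(a[[l]] %*% layers[[l]]$W, layers[[l]]$b)
    a[[l + 1L]] <- if (l < length(layers)) .relu(z) else z   # linear output
  }
  a
}

.head_backward <- function(a, layers, dout, grads) {
  d <- dout
  for (l in rev(seq_along(layers))) {
    if (l < length(layers)) d <- d * (a[[l + 1L]] > 0)
    grads[[l]]$W <- grads[[l]]$W + crossprod(a[[l]], d)
    grads[[l]]$b <- grads[[l]]$b + colSums(d)
    d <- d %*% t(layers[[l]]$W)
  }
  list(grads = grads, dx = d)
}
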