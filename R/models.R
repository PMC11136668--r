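## The three baseline learners.
##
##  * qm_property: graph-level regression of two molecular electronic
##    descriptors (electron affinity, chemical hardness). A dense embedding
##    layer is followed by sequential message-passing blocks whose messages
##    are conditioned on the edge weight through a learned softplus gate and
##    whose node state is updated by a GRU cell (weights shared across
##    blocks), then sum pooling over nodes and a dense head with 2 outputs.
##  * node_adaptability: node-level regression with no graph pooling -
##    sequential edge-weighted graph convolutions followed by two linear
##    layers applied per node.
##  * pair_affinity: twin network for relative binding affinity - a shared
##    GCN encoder runs on both complexes of a pair; ligand and protein nodes
##    are pooled separately (mean), the concatenated embedding passes through
##    three linear layers with ReLU nonlinearities to a scalar score, and the
##    pair prediction is score(target) - score(base). Antisymmetry under
##    swapping and exact zero on identical pairs hold by construction.
##
## Training uses mean-squared-error and Adam; with a fixed seed and a single
## thread a run is reproducible.

.paper_scale <- list(
  qm_property = list(n_conv_layers = 3, batch_size = 128, epochs = 200),
  node_adaptability = list(n_conv_layers = 5, batch_size = 8, epochs = 15),
  pair_affinity = list(n_conv_layers = 5, batch_size = 50, epochs = 50)
)

#' Model configuration
#'
#' Desk-scale defaults per task (around 10^4 trainable parameters, minutes on
#' one CPU). The reference-scale settings used at full dataset size (3
#' message-passing blocks / batch 128 / 200 epochs for the quantum task, 5
#' convolutions / batch 8 / 15 epochs for the node task, 5 convolutions /
#' batch 50 / 50 epochs for the pair task) are recorded in the training log
#' for comparison but are not the defaults.
#'
#' @param task `"qm_property"`, `"node_adaptability"` or `"pair_affinity"`.
#' @param n_conv_layers message-passing / convolution blocks.
#' @param hidden_dim hidden width.
#' @param n_dense_layers hidden dense layers in the output head.
#' @param epochs,batch_size,learning_rate optimizer settings.
#' @param seed RNG seed (initialization and shuffling).
#' @param augment_amplitude random node-translation amplitude during
#'   training, Angstrom (0 disables).
#' @param device `"cpu"` (the only supported device).
#' @return list of class `model_config`.
#' @export
model_config <- function(task = c("qm_property", "node_adaptability",
                                  "pair_affinity"),
                         n_conv_layers = NULL, hidden_dim = 16,
                         n_dense_layers = 1, epochs = NULL,
                         batch_size = NULL, learning_rate = 0.01,
                         seed = 1L, augment_amplitude = 0,
                         device = "cpu") {
  task <- match.arg(task)
  defaults <- switch(task,
    qm_property = list(n_conv_layers = 3, epochs = 150, batch_size = 32),
    node_adaptability = list(n_conv_layers = 3, epochs = 150, batch_size = 16),
    pair_affinity = list(n_conv_layers = 2, epochs = 150, batch_size = 25))
  cfg <- list(task = task,
              n_conv_layers = n_conv_layers %||% defaults$n_conv_layers,
              hidden_dim = hidden_dim, n_dense_layers = n_dense_layers,
              epochs = epochs %||% defaults$epochs,
              batch_size = batch_size %||% defaults$batch_size,
              learning_rate = learning_rate, seed = as.integer(seed),
              augment_amplitude = augment_amplitude, device = device)
  stopifnot(cfg$n_conv_layers >= 1, cfg$hidden_dim >= 1, cfg$epochs >= 1,
            cfg$batch_size >= 1)
  structure(cfg, class = "model_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.schema_of <- function(graph) colnames(graph$node_features)

.check_schema <- function(model, graph) {
  sc <- .schema_of(graph)
  if (!identical(sc, model$feature_schema)) {
    missing <- setdiff(model$feature_schema, sc)
    extra <- setdiff(sc, model$feature_schema)
    stop_ligdyn("validation",
                "feature schema mismatch: missing [%s], unexpected [%s]",
                paste(missing, collapse = ", "),
                paste(extra, collapse = ", "))
  }
}

.new_model <- function(task, config, params, log, schema, extra = list()) {
  structure(c(list(task = task, config = config, params = params,
                   training_log = log, feature_schema = schema), extra),
            class = "ligdyn_model")
}

#' @export
print.ligdyn_model <- function(x, ...) {
  cat(sprintf("<ligdyn_model %s: %d parameters, %d epochs, final loss %.4g>\n",
              x$task, x$training_log$n_parameters,
              length(x$training_log$epoch_loss),
              utils::tail(x$training_log$epoch_loss, 1)))
  invisible(x)
}

## augmentation wrapper used inside the training loops (seeded off the
## global RNG stream so the whole run stays reproducible)
.maybe_augment <- function(graph, amplitude) {
  if (amplitude <= 0) return(graph)
  augment_translate(graph, amplitude,
                    seed = sample.int(.Machine$integer.max, 1))
}

## ---------------------------------------------------------- QM model

.qm_init <- function(f_in, h, n_dense) {
  list(enc = list(W = .init_mat(f_in, h), b = numeric(h)),
       msg = list(a = 1, b = 0, Wm = .init_mat(h, h)),
       gru = list(Wz = .init_mat(h, h), Uz = .init_mat(h, h), bz = numeric(h),
                  Wr = .init_mat(h, h), Ur = .init_mat(h, h), br = numeric(h),
                  Wh = .init_mat(h, h), Uh = .init_mat(h, h), bh = numeric(h)),
       head = .head_init(h, h, 2L, n_dense))
}

.qm_forward <- function(graph, params, T_passes) {
  E <- .adj_matrix(graph)
  mask <- E > 0
  G <- matrix(0, nrow(E), ncol(E))
  G[mask] <- .softplus(params$msg$a * E[mask] + params$msg$b)
  H <- vector("list", T_passes + 1L)
  M <- z <- r <- cc <- vector("list", T_passes)
  H[[1]] <- tanh(.addb(graph$node_features %*% params$enc$W, params$enc$b))
  g <- params$gru
  for (t in seq_len(T_passes)) {
    M[[t]] <- G %*% (H[[t]] %*% params$msg$Wm)
    z[[t]] <- .sigmoid(.addb(M[[t]] %*% g$Uz + H[[t]] %*% g$Wz, g$bz))
    r[[t]] <- .sigmoid(.addb(M[[t]] %*% g$Ur + H[[t]] %*% g$Wr, g$br))
    cc[[t]] <- tanh(.addb(M[[t]] %*% g$Uh + (r[[t]] * H[[t]]) %*% g$Wh, g$bh))
    H[[t + 1L]] <- (1 - z[[t]]) * H[[t]] + z[[t]] * cc[[t]]
  }
  pool <- matrix(colSums(H[[T_passes + 1L]]), 1)
  a <- .head_forward(pool, params$head)
  list(y = a[[length(a)]], E = E, mask = mask, G = G, H = H, M = M,
       z = z, r = r, cc = cc, head_a = a)
}

.qm_backward <- function(graph, params, cache, dY, grads, T_passes) {
  hb <- .head_backward(cache$head_a, params$head, dY, grads$head)
  grads$head <- hb$grads
  n <- nrow(graph$node_features)
  dH <- matrix(rep(hb$dx, each = n), n)     # d pool -> every node
  g <- params$gru
  dG <- matrix(0, n, n)
  for (t in rev(seq_len(T_passes))) {
    Hp <- cache$H[[t]]; M <- cache$M[[t]]
    zt <- cache$z[[t]]; rt <- cache$r[[t]]; ct <- cache$cc[[t]]
    dz <- dH * (ct - Hp)
    dc <- dH * zt
    dHp <- dH * (1 - zt)
    dac <- dc * (1 - ct^2)
    dM <- dac %*% t(g$Uh)
    dRH <- dac %*% t(g$Wh)
    dr <- dRH * Hp
    dHp <- dHp + dRH * rt
    grads$gru$Uh <- grads$gru$Uh + crossprod(M, dac)
    grads$gru$Wh <- grads$gru$Wh + crossprod(rt * Hp, dac)
    grads$gru$bh <- grads$gru$bh + colSums(dac)
    dar <- dr * rt * (1 - rt)
    dM <- dM + dar %*% t(g$Ur)
    dHp <- dHp + dar %*% t(g$Wr)
    grads$gru$Ur <- grads$gru$Ur + crossprod(M, dar)
    grads$gru$Wr <- grads$gru$Wr + crossprod(Hp, dar)
    grads$gru$br <- grads$gru$br + colSums(dar)
    daz <- dz * zt * (1 - zt)
    dM <- dM + daz %*% t(g$Uz)
    dHp <- dHp + daz %*% t(g$Wz)
    grads$gru$Uz <- grads$gru$Uz + crossprod(M, daz)
    grads$gru$Wz <- grads$gru$Wz + crossprod(Hp, daz)
    grads$gru$bz <- grads$gru$bz + colSums(daz)
    ## message M = G (Hp Wm)
    P <- Hp %*% params$msg$Wm
    dG <- dG + dM %*% t(P)
    dP <- crossprod(cache$G, dM)
    grads$msg$Wm <- grads$msg$Wm + crossprod(Hp, dP)
    dHp <- dHp + dP %*% t(params$msg$Wm)
    dH <- dHp
  }
  ## gate grads (softplus' = sigmoid), edge entries only
  mk <- cache$mask
  sg <- .sigmoid(params$msg$a * cache$E[mk] + params$msg$b)
  grads$msg$a <- grads$msg$a + sum(dG[mk] * sg * cache$E[mk])
  grads$msg$b <- grads$msg$b + sum(dG[mk] * sg)
  ## encoder
  H0 <- cache$H[[1]]
  da0 <- dH * (1 - H0^2)
  grads$enc$W <- grads$enc$W + crossprod(graph$node_features, da0)
  grads$enc$b <- grads$enc$b + colSums(da0)
  grads
}

#' Train the graph-level quantum-property model
#'
#' Joint regression of two molecular targets (canonically electron affinity
#' and chemical hardness, eV) from molecular graphs. Targets should already
#' be screened with [filter_target_outliers()]; they are standardized to
#' unit variance during training and de-standardized at inference.
#'
#' @param graphs list of [build_graph()] objects with a common feature
#'   schema.
#' @param targets numeric matrix/data.frame `[n_graphs x 2]`.
#' @param config a [model_config()] for task `"qm_property"`.
#' @return a `ligdyn_model`.
#' @export
train_qm_model <- function(graphs, targets,
                           config = model_config("qm_property")) {
  targets <- as.matrix(targets)
  stopifnot(length(graphs) == nrow(targets), ncol(targets) == 2L)
  schema <- .schema_of(graphs[[1]])
  for (g in graphs) .check_schema(list(feature_schema = schema), g)
  set.seed(config$seed)
  mu <- colMeans(targets); sdv <- apply(targets, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Y <- sweep(sweep(targets, 2, mu), 2, sdv, "/")
  params <- .qm_init(length(schema), config$hidden_dim, config$n_dense_layers)
  state <- .adam_init(params)
  Tp <- config$n_conv_layers
  losses <- numeric(config$epochs)
  n <- length(graphs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      grads <- .zeros_like(params)
      for (i in idx) {
        gr <- .maybe_augment(graphs[[i]], config$augment_amplitude)
        cache <- .qm_forward(gr, params, Tp)
        err <- cache$y - Y[i, , drop = FALSE]
        tot <- tot + mean(err^2)
        grads <- .qm_backward(gr, params, cache, 2 * err / (2 * length(idx)),
                              grads, Tp)
      }
      st <- .adam_step(params, grads, state, config$learning_rate)
      params <- st$params; state <- st$state
    }
    losses[ep] <- tot / n
  }
  .new_model("qm_property", config, params,
             list(epoch_loss = losses, n_parameters = .count_params(params),
                  reference_scale = .paper_scale$qm_property),
             schema,
             list(target_mean = mu, target_sd = sdv,
                  target_names = colnames(targets)))
}

## ---------------------------------------------------------- node model

.node_init <- function(f_in, h, n_conv, n_dense) {
  list(conv = .gcn_init(n_conv, f_in, h),
       head = .head_init(h, h, 1L, n_dense))
}

.node_forward <- function(graph, params) {
  S <- .prop_matrix(graph)
  fc <- .gcn_forward(S, graph$node_features, params$conv)
  a <- .head_forward(fc$H[[length(fc$H)]], params$head)
  list(y = a[[length(a)]][, 1], S = S, conv = fc, head_a = a)
}

.node_backward <- function(graph, params, cache, dY, grads) {
  hb <- .head_backward(cache$head_a, params$head, cbind(dY), grads$head)
  grads$head <- hb$grads
  grads$conv <- .gcn_backward(cache$S, cache$conv, params$conv, hb$dx,
                              grads$conv)
  grads
}

#' Train the node-level adaptability model
#'
#' Per-node regression (no pooling of node features into graph features):
#' sequential edge-weighted graph convolutions followed by two linear layers
#' emitting one value per node, trained with per-node mean-squared error.
#'
#' @param graphs list of [build_graph()] objects.
#' @param node_targets list of per-node numeric vectors (Angstrom), lengths
#'   matching each graph.
#' @param config a [model_config()] for task `"node_adaptability"`.
#' @return a `ligdyn_model`.
#' @export
train_node_model <- function(graphs, node_targets,
                             config = model_config("node_adaptability")) {
  stopifnot(length(graphs) == length(node_targets))
  for (i in seq_along(graphs))
    if (nrow(graphs[[i]]$node_features) != length(node_targets[[i]]))
      stop_ligdyn("validation", "graph %d: %d nodes but %d node targets",
                  i, nrow(graphs[[i]]$node_features),
                  length(node_targets[[i]]))
  schema <- .schema_of(graphs[[1]])
  for (g in graphs) .check_schema(list(feature_schema = schema), g)
  set.seed(config$seed)
  ally <- unlist(node_targets)
  mu <- mean(ally); sdv <- stats::sd(ally); if (sdv == 0) sdv <- 1
  Y <- lapply(node_targets, function(v) (v - mu) / sdv)
  params <- .node_init(length(schema), config$hidden_dim,
                       config$n_conv_layers, config$n_dense_layers)
  state <- .adam_init(params)
  losses <- numeric(config$epochs)
  n <- length(graphs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      grads <- .zeros_like(params)
      for (i in idx) {
        gr <- .maybe_augment(graphs[[i]], config$augment_amplitude)
        cache <- .node_forward(gr, params)
        err <- cache$y - Y[[i]]
        tot <- tot + mean(err^2)
        grads <- .node_backward(gr, params, cache,
                                2 * err / (length(err) * length(idx)), grads)
      }
      st <- .adam_step(params, grads, state, config$learning_rate)
      params <- st$params; state <- st$state
    }
    losses[ep] <- tot / n
  }
  .new_model("node_adaptability", config, params,
             list(epoch_loss = losses, n_parameters = .count_params(params),
                  reference_scale = .paper_scale$node_adaptability),
             schema, list(target_mean = mu, target_sd = sdv))
}

## ---------------------------------------------------------- pair model

.pair_init <- function(f_in, h, n_conv) {
  list(conv = .gcn_init(n_conv, f_in, h),
       head = .head_init(2 * h, h, 1L, 2L))   # three linear layers
}

.pair_score_forward <- function(graph, params) {
  S <- .prop_matrix(graph)
  fc <- .gcn_forward(S, graph$node_features, params$conv)
  H <- fc$H[[length(fc$H)]]
  lig <- which(graph$node_origin == "ligand")
  prot <- which(graph$node_origin == "protein")
  if (length(lig) == 0L || length(prot) == 0L)
    stop_ligdyn("validation", "pair model needs both ligand and protein nodes")
  pool <- matrix(c(colMeans(H[lig, , drop = FALSE]),
                   colMeans(H[prot, , drop = FALSE])), 1)
  a <- .head_forward(pool, params$head)
  list(score = a[[length(a)]][1, 1], S = S, conv = fc, head_a = a,
       lig = lig, prot = prot)
}

.pair_score_backward <- function(graph, params, cache, dscore, grads) {
  hb <- .head_backward(cache$head_a, params$head,
                       matrix(dscore, 1, 1), grads$head)
  grads$head <- hb$grads
  h <- ncol(cache$conv$H[[length(cache$conv$H)]])
  dpool <- hb$dx
  n <- nrow(graph$node_features)
  dH <- matrix(0, n, h)
  dH[cache$lig, ] <- matrix(rep(dpool[1, 1:h] / length(cache$lig),
                                each = length(cache$lig)), length(cache$lig))
  dH[cache$prot, ] <- matrix(rep(dpool[1, (h + 1):(2 * h)] / length(cache$prot),
                                 each = length(cache$prot)), length(cache$prot))
  grads$conv <- .gcn_backward(cache$S, cache$conv, params$conv, dH, grads$conv)
  grads
}

#' Train the twin relative-affinity model
#'
#' Shared-weight encoder applied to the target and base complex of each
#' pair; per-complex score from separately pooled ligand and protein
#' embeddings through three linear layers; prediction =
#' score(target) - score(base), trained by mean-squared error against the
#' decimal log affinity ratio from [make_pairs()].
#'
#' @param pairs list of `pair_sample` objects carrying graphs.
#' @param config a [model_config()] for task `"pair_affinity"`.
#' @return a `ligdyn_model`.
#' @export
train_pair_model <- function(pairs, config = model_config("pair_affinity")) {
  stopifnot(length(pairs) >= 1)
  for (p in pairs)
    if (is.null(p$target_graph) || is.null(p$base_graph))
      stop_ligdyn("validation", "pairs must carry target and base graphs")
  schema <- .schema_of(pairs[[1]]$target_graph)
  set.seed(config$seed)
  params <- .pair_init(length(schema), config$hidden_dim,
                       config$n_conv_layers)
  state <- .adam_init(params)
  losses <- numeric(config$epochs)
  n <- length(pairs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      grads <- .zeros_like(params)
      for (i in idx) {
        p <- pairs[[i]]
        gt <- .maybe_augment(p$target_graph, config$augment_amplitude)
        gb <- .maybe_augment(p$base_graph, config$augment_amplitude)
        ct <- .pair_score_forward(gt, params)
        cb <- .pair_score_forward(gb, params)
        err <- (ct$score - cb$score) - p$label
        tot <- tot + err^2
        d <- 2 * err / length(idx)
        grads <- .pair_score_backward(gt, params, ct, d, grads)
        grads <- .pair_score_backward(gb, params, cb, -d, grads)
      }
      st <- .adam_step(params, grads, state, config$learning_rate)
      params <- st$params; state <- st$state
    }
    losses[ep] <- tot / n
  }
  .new_model("pair_affinity", config, params,
             list(epoch_loss = losses, n_parameters = .count_params(params),
                  reference_scale = .paper_scale$pair_affinity),
             schema)
}

## ---------------------------------------------------------- inference

#' Predict with a trained model
#'
#' Deterministic inference (no augmentation). Input type follows the task:
#' a list of graphs for the graph- and node-level models, a list of
#' `pair_sample`s (or two-graph lists) for the pair model. The feature
#' schema of every input is checked against the model.
#'
#' @param object a `ligdyn_model`.
#' @param newdata list of graphs or pairs (empty list gives empty output).
#' @param ... unused.
#' @return task-dependent: `[n x 2]` matrix (qm), list of per-node vectors
#'   (node), numeric vector (pair).
#' @export
predict.ligdyn_model <- function(object, newdata, ...) {
  if (length(newdata) == 0L)
    return(switch(object$task,
                  qm_property = matrix(numeric(), 0, 2),
                  node_adaptability = list(),
                  numeric(0)))
  switch(object$task,
    qm_property = {
      out <- t(vapply(newdata, function(g) {
        .check_schema(object, g)
        z <- .qm_forward(g, object$params, object$config$n_conv_layers)$y[1, ]
        z * object$target_sd + object$target_mean
      }, numeric(2)))
      colnames(out) <- object$target_names
      out
    },
    node_adaptability = lapply(newdata, function(g) {
      .check_schema(object, g)
      .node_forward(g, object$params)$y * object$target_sd + object$target_mean
    }),
    pair_affinity = vapply(newdata, function(p) {
      .check_schema(object, p$target_graph)
      .check_schema(object, p$base_graph)
      .pair_score_forward(p$target_graph, object$params)$score -
        .pair_score_forward(p$base_graph, object$params)$score
    }, numeric(1)))
}

## ---------------------------------------------------------- evaluation

.top_k_idx <- function(v, k) order(-v, seq_along(v))[seq_len(min(k, length(v)))]

#' Evaluation metrics
#'
#' Pearson/Spearman correlation, mean absolute error, and the top-k overlap
#' accuracy: for per-structure vectors, the fraction of the k truly largest
#' entries recovered among the k predicted largest (ties broken by
#' descending value then ascending index), averaged over structures.
#'
#' @param predictions,targets numeric vectors, or lists of per-structure
#'   vectors when `top_k_overlap` is requested (correlations are then
#'   computed per structure and averaged).
#' @param metrics subset of `c("pearson", "spearman", "mae",
#'   "top_k_overlap")`.
#' @param k overlap depth (default 100).
#' @return named numeric vector.
#' @export
evaluate <- function(predictions, targets,
                     metrics = c("pearson", "spearman", "mae"), k = 100) {
  metrics <- match.arg(metrics,
                       c("pearson", "spearman", "mae", "top_k_overlap"),
                       several.ok = TRUE)
  listwise <- is.list(predictions)
  if (listwise && length(predictions) != length(targets))
    stop_ligdyn("validation", "prediction/target lists differ in length")
  out <- numeric(0)
  corfun <- function(p, t, method) {
    if (length(p) < 2L)
      stop_ligdyn("validation", "correlation undefined for n < 2")
    stats::cor(p, t, method = method)
  }
  for (m in metrics) {
    val <- switch(m,
      pearson = if (listwise)
          mean(mapply(corfun, predictions, targets,
                      MoreArgs = list(method = "pearson")))
        else corfun(predictions, targets, "pearson"),
      spearman = if (listwise)
          mean(mapply(corfun, predictions, targets,
                      MoreArgs = list(method = "spearman")))
        else corfun(predictions, targets, "spearman"),
      mae = if (listwise)
          mean(mapply(function(p, t) mean(abs(p - t)), predictions, targets))
        else mean(abs(predictions - targets)),
      top_k_overlap = {
        if (!listwise)
          stop_ligdyn("validation",
                      "top_k_overlap needs per-structure vectors")
        mean(mapply(function(p, t) {
          kk <- min(k, length(p))
          length(intersect(.top_k_idx(p, kk), .top_k_idx(t, kk))) / kk
        }, predictions, targets))
      })
    out[m] <- val
  }
  out
}
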