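# Recurrent graph neural network for node-focused binary classification.
#
# The model iterates a learned state-transition MLP f_w over node
# neighborhoods for a fixed number of iterations and reads each final node
# state with an output MLP g_w:
#
#   x_n^(t) = sum_{m in ne(n)} f_w(l_n, l_m, e_{n,m}, x_m^(t-1)),  x^(0) = 0
#   p_n     = sigmoid(g_w(x_n^(T), l_n))
#
# Training is plain backprop-through-time with Adam, written directly on
# BLAS matrix operations; sparse incidence matrices scatter messages to
# their target nodes and gather state gradients back to source nodes.

#' GNN hyperparameter configuration
#'
#' @param state_dim Node state dimension (grid 16/32/64).
#' @param max_iter Number of state-update iterations (grid 3/4/5).
#' @param wbal Fraction of full class re-balancing applied as the
#'   positive-class loss weight, in [0, 1]: the positive weight is
#'   `(1 - wbal) + wbal * N_neg / N_pos`, so 0 means no balancing and 1
#'   weighs the classes to parity.
#' @param net_s_hidden Hidden units of the state network f_w (0 = affine).
#' @param net_o_hidden Hidden units of the output network g_w (0 = affine).
#' @param learning_rate Adam initial learning rate.
#' @param epochs Maximum training epochs.
#' @param early_stopping_patience Epochs without validation F-score
#'   improvement before stopping.
#' @param seed Integer seed controlling initialization and data order.
#' @param threshold Classification threshold on the output probability
#'   (calls are 1 when probability >= threshold).
#' @param aggregation Neighbor aggregation, "sum" (default) or "mean".
#' @param target_fscore Optional validation F-score at which training
#'   stops early (NULL to disable).
#' @return A `gnn_config` object.
#' @export
gnn_config <- function(state_dim = 32L, max_iter = 5L, wbal = 0.5,
                       net_s_hidden = 256L, net_o_hidden = 0L,
                       learning_rate = 0.001, epochs = 500L,
                       early_stopping_patience = 25L, seed = 1L,
                       threshold = 0.5, aggregation = c("sum", "mean"),
                       target_fscore = NULL) {
  aggregation <- match.arg(aggregation)
  stopifnot(state_dim > 0, max_iter >= 1, wbal >= 0, wbal <= 1,
            net_s_hidden >= 0, net_o_hidden >= 0, learning_rate > 0,
            epochs >= 1, early_stopping_patience >= 1,
            threshold > 0, threshold < 1)
  structure(list(state_dim = as.integer(state_dim),
                 max_iter = as.integer(max_iter), wbal = wbal,
                 net_s_hidden = as.integer(net_s_hidden),
                 net_o_hidden = as.integer(net_o_hidden),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed), threshold = threshold,
                 aggregation = aggregation, target_fscore = target_fscore),
            class = "gnn_config")
}

#' @export
print.gnn_config <- function(x, ...) {
  cat(sprintf(
    "gnn_config: state %d, %d iterations, wbal %.2f, net_s h=%d, net_o h=%d\n",
    x$state_dim, x$max_iter, x$wbal, x$net_s_hidden, x$net_o_hidden))
  invisible(x)
}

.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize a GNN model
#'
#' Glorot-uniform weights, zero biases; deterministic for a fixed seed.
#' Feature standardization vectors are initialized to the identity and
#' filled in by [gnn_train()] from training-set statistics.
#'
#' @param config A [gnn_config()].
#' @param node_dim,edge_dim Feature dimensions of the graphs the model
#'   will consume.
#' @param seed Seed (defaults to `config$seed`).
#' @return A `gnn_model`.
#' @export
init_model <- function(config, node_dim, edge_dim, seed = config$seed) {
  stopifnot(node_dim > 0, edge_dim > 0)
  ds <- config$state_dim
  hs <- config$net_s_hidden
  ho <- config$net_o_hidden
  d_static <- 2L * node_dim + edge_dim
  params <- with_local_seed(seed, {
    p <- list()
    if (hs > 0) {
      p$W1s <- .glorot(d_static + ds, hs)[seq_len(d_static), , drop = FALSE]
      p$W1x <- .glorot(d_static + ds, hs)[seq_len(ds), , drop = FALSE]
      p$b1 <- numeric(hs)
      p$W2 <- .glorot(hs, ds)
      p$b2 <- numeric(ds)
    } else {
      p$W1s <- .glorot(d_static + ds, ds)[seq_len(d_static), , drop = FALSE]
      p$W1x <- .glorot(d_static + ds, ds)[seq_len(ds), , drop = FALSE]
      p$b1 <- numeric(ds)
    }
    d_out <- ds + node_dim
    if (ho > 0) {
      p$V1 <- .glorot(d_out, ho)
      p$c1 <- numeric(ho)
      p$V2 <- .glorot(ho, 1L)
      p$c2 <- numeric(1L)
    } else {
      p$V1 <- .glorot(d_out, 1L)
      p$c1 <- numeric(1L)
    }
    p
  })
  structure(list(config = config, node_dim = as.integer(node_dim),
                 edge_dim = as.integer(edge_dim), params = params,
                 node_center = numeric(node_dim),
                 node_scale = rep(1, node_dim),
                 edge_center = numeric(edge_dim),
                 edge_scale = rep(1, edge_dim)),
            class = "gnn_model")
}

#' @export
print.gnn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("gnn_model:", x$node_dim, "node /", x$edge_dim, "edge dims,",
      format(np, big.mark = ","), "parameters\n")
  print(x$config)
  invisible(x)
}

# Precomputed per-graph tensors: standardized features, the static part of
# every directed-edge message input, and sparse scatter/gather matrices.
graph_tensors <- function(graph, model) {
  if (ncol(graph$X) != model$node_dim)
    stop("node feature dimension ", ncol(graph$X),
         " does not match model (", model$node_dim, ")")
  if (ncol(graph$E) != model$edge_dim)
    stop("edge feature dimension ", ncol(graph$E),
         " does not match model (", model$edge_dim, ")")
  n <- nrow(graph$X)
  Ln <- sweep(sweep(graph$X, 2, model$node_center), 2, model$node_scale, "/")
  m <- nrow(graph$edges)
  if (m > 0) {
    src <- c(graph$edges$i, graph$edges$j)
    tgt <- c(graph$edges$j, graph$edges$i)
    Ee <- sweep(sweep(rbind(graph$E, graph$E), 2, model$edge_center),
                2, model$edge_scale, "/")
    S <- cbind(Ln[tgt, , drop = FALSE], Ln[src, , drop = FALSE], Ee)
    Agg <- Matrix::sparseMatrix(i = tgt, j = seq_along(tgt), x = 1,
                                dims = c(n, 2L * m))
    Gat <- Matrix::sparseMatrix(i = src, j = seq_along(src), x = 1,
                                dims = c(n, 2L * m))
    deg <- tabulate(tgt, n)
  } else {
    src <- tgt <- integer(0); S <- NULL; Agg <- Gat <- NULL
    deg <- integer(n)
  }
  list(n = n, Ln = Ln, src = src, tgt = tgt, S = S, Agg = Agg, Gat = Gat,
       deg = pmax(deg, 1L))
}

#' One state-update iteration
#'
#' Applies the state-transition network to every directed edge and
#' aggregates the messages on their target nodes; isolated nodes receive
#' the zero aggregate.  Exposed mainly for testing and inspection --
#' [gnn_forward()] runs the full unrolled computation.
#'
#' @param graph A `protein_graph`.
#' @param states Numeric matrix (n_nodes x state_dim).
#' @param model A `gnn_model`.
#' @return Updated state matrix of the same shape.
#' @export
state_update <- function(graph, states, model) {
  gt <- graph_tensors(graph, model)
  .state_step(gt, states, model)$X
}

.state_step <- function(gt, X, model) {
  p <- model$params
  if (length(gt$src) == 0L)
    return(list(X = matrix(0, gt$n, ncol(X)), H = NULL))
  A <- gt$S %*% p$W1s + X[gt$src, , drop = FALSE] %*% p$W1x
  A <- sweep(A, 2, p$b1, "+")
  if (!is.null(p$W2)) {
    H <- tanh(A)
    M <- sweep(H %*% p$W2, 2, p$b2, "+")
  } else {
    H <- NULL
    M <- A
  }
  Xn <- as.matrix(gt$Agg %*% M)
  if (model$config$aggregation == "mean") Xn <- Xn / gt$deg
  list(X = Xn, H = H)
}

.output_layer <- function(Z, p) {
  if (!is.null(p$V2)) {
    Ho <- tanh(sweep(Z %*% p$V1, 2, p$c1, "+"))
    list(logit = drop(sweep(Ho %*% p$V2, 2, p$c2, "+")), Ho = Ho)
  } else {
    list(logit = drop(sweep(Z %*% p$V1, 2, p$c1, "+")), Ho = NULL)
  }
}

.forward_internal <- function(model, graph, keep = FALSE) {
  gt <- graph_tensors(graph, model)
  cfg <- model$config
  ds <- cfg$state_dim
  X <- matrix(0, gt$n, ds)
  X_list <- if (keep) vector("list", cfg$max_iter + 1L) else NULL
  H_list <- if (keep) vector("list", cfg$max_iter) else NULL
  if (keep) X_list[[1L]] <- X
  for (t in seq_len(cfg$max_iter)) {
    st <- .state_step(gt, X, model)
    X <- st$X
    if (keep) {
      X_list[[t + 1L]] <- X
      H_list[[t]] <- st$H
    }
  }
  Z <- cbind(X, gt$Ln)
  out <- .output_layer(Z, model$params)
  probs <- stats::plogis(out$logit)
  list(probs = probs, logit = out$logit, Z = Z, Ho = out$Ho, gt = gt,
       X_list = X_list, H_list = H_list)
}

#' Forward pass: per-node interface probabilities
#'
#' States start at zero, are updated `max_iter` times, and each final node
#' state (concatenated with the node's own features) is read by the output
#' network through a sigmoid.
#'
#' @param graph A `protein_graph` matching the model's feature schema.
#' @param model A `gnn_model`.
#' @return Numeric vector of probabilities in (0, 1), one per node.
#' @export
gnn_forward <- function(graph, model) {
  .forward_internal(model, graph, keep = FALSE)$probs
}

#' Class-weighted binary cross-entropy
#'
#' The positive-class weight interpolates between no balancing and full
#' balancing: `w_pos = (1 - wbal) + wbal * N_neg / N_pos`, where the
#' negative/positive ratio is computed on `labels`.  The loss is the
#' weighted mean of the per-node cross-entropies.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels.
#' @param wbal Balancing fraction in [0, 1].
#' @param w_pos Positive-class weight; computed from `labels` and `wbal`
#'   when NULL (a training loop computes it once on the training set).
#' @return Scalar loss with attribute `w_pos`.
#' @export
gnn_loss <- function(probs, labels, wbal = 0, w_pos = NULL) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  if (is.null(w_pos)) w_pos <- positive_weight(labels, wbal)
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  w <- ifelse(labels == 1, w_pos, 1)
  bce <- -(labels * log(p) + (1 - labels) * log(1 - p))
  structure(sum(w * bce) / length(p), w_pos = w_pos)
}

#' Positive-class weight implied by a label set and wbal
#' @inheritParams gnn_loss
#' @param labels Binary labels of the training set.
#' @return Scalar weight `(1 - wbal) + wbal * N_neg / N_pos`.
#' @export
positive_weight <- function(labels, wbal) {
  stopifnot(wbal >= 0, wbal <= 1)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0) {
    if (wbal > 0)
      stop("no positive examples: wbal > 0 is undefined")
    return(1)
  }
  (1 - wbal) + wbal * n_neg / n_pos
}

# Gradients of the weighted BCE loss w.r.t. all parameters, by
# backprop-through-time.  `fw` is .forward_internal(..., keep = TRUE).
.backward <- function(model, fw, labels, w_pos) {
  p <- model$params
  cfg <- model$config
  gt <- fw$gt
  n <- gt$n
  ds <- cfg$state_dim
  w <- ifelse(labels == 1, w_pos, 1)
  glogit <- matrix(w * (fw$probs - labels) / n, ncol = 1L)

  g <- lapply(p, function(x) array(0, dim = dim(x) %||% length(x)))
  if (!is.null(p$V2)) {
    g$V2 <- crossprod(fw$Ho, glogit)
    g$c2 <- sum(glogit)
    gHo <- (glogit %*% t(p$V2)) * (1 - fw$Ho^2)
    g$V1 <- crossprod(fw$Z, gHo)
    g$c1 <- colSums(gHo)
    gZ <- gHo %*% t(p$V1)
  } else {
    g$V1 <- crossprod(fw$Z, glogit)
    g$c1 <- sum(glogit)
    gZ <- glogit %*% t(p$V1)
  }
  GX <- gZ[, seq_len(ds), drop = FALSE]

  if (length(gt$src) > 0L) {
    hs <- cfg$net_s_hidden
    GhSum <- NULL
    for (t in rev(seq_len(cfg$max_iter))) {
      if (model$config$aggregation == "mean") GX <- GX / gt$deg
      Gm <- as.matrix(Matrix::crossprod(gt$Agg, GX))
      if (hs > 0) {
        Ht <- fw$H_list[[t]]
        g$W2 <- g$W2 + crossprod(Ht, Gm)
        g$b2 <- g$b2 + colSums(Gm)
        Gh <- (Gm %*% t(p$W2)) * (1 - Ht^2)
      } else {
        Gh <- Gm
      }
      GhSum <- if (is.null(GhSum)) Gh else GhSum + Gh
      Xprev <- fw$X_list[[t]]
      if (t > 1L)  # X^(0) = 0 contributes nothing
        g$W1x <- g$W1x + crossprod(Xprev[gt$src, , drop = FALSE], Gh)
      GX <- as.matrix(gt$Gat %*% (Gh %*% t(p$W1x)))
    }
    g$W1s <- g$W1s + as.matrix(Matrix::crossprod(gt$S, GhSum))
    g$b1 <- g$b1 + colSums(GhSum)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(x) array(0, dim = dim(x) %||% length(x))),
       v = lapply(params, function(x) array(0, dim = dim(x) %||% length(x))))
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Column-wise center/scale over stacked sample feature matrices.
.fit_standardizer <- function(mats) {
  all <- do.call(rbind, mats)
  center <- colMeans(all)
  scale <- apply(all, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-8] <- 1
  list(center = center, scale = scale)
}

#' Train a GNN on labeled dataset samples
#'
#' Backprop-through-time with Adam, one graph per optimization step,
#' class-weighted cross-entropy (weight computed once from the training
#' labels), validation F-score monitored every epoch with early stopping
#' that restores the best checkpoint.  Fully reproducible for a fixed
#' `config$seed`.
#'
#' @param train_samples,val_samples Non-empty lists of `dataset_sample`s.
#' @param config A [gnn_config()].
#' @param verbose Print one log line per epoch.
#' @return List with `model` (a `gnn_model`) and `history` (a
#'   `training_history`: per-epoch data.frame, `best_epoch`,
#'   `stopped_early`).
#' @export
gnn_train <- function(train_samples, val_samples, config = gnn_config(),
                      verbose = FALSE) {
  stopifnot(length(train_samples) >= 1L, length(val_samples) >= 1L)
  node_dim <- ncol(train_samples[[1]]$graph$X)
  edge_dim <- ncol(train_samples[[1]]$graph$E)
  model <- init_model(config, node_dim, edge_dim, seed = config$seed)

  std_n <- .fit_standardizer(lapply(train_samples, function(s) s$graph$X))
  model$node_center <- std_n$center
  model$node_scale <- std_n$scale
  emats <- lapply(train_samples, function(s) s$graph$E)
  emats <- emats[vapply(emats, nrow, integer(1)) > 0]
  if (length(emats)) {
    std_e <- .fit_standardizer(emats)
    model$edge_center <- std_e$center
    model$edge_scale <- std_e$scale
  }

  train_labels <- unlist(lapply(train_samples, `[[`, "labels"))
  w_pos <- positive_weight(train_labels, config$wbal)

  opt <- .adam_init(model$params)
  best <- list(params = model$params, fscore = -Inf, epoch = 0L)
  hist_rows <- vector("list", config$epochs)
  stopped_early <- FALSE

  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(train_samples))
      epoch_loss <- 0
      for (k in ord) {
        s <- train_samples[[k]]
        fw <- .forward_internal(model, s$graph, keep = TRUE)
        l <- gnn_loss(fw$probs, s$labels, w_pos = w_pos)
        if (!is.finite(l))
          stop("non-finite training loss at epoch ", epoch,
               " (sample ", k, "); try a lower learning rate")
        epoch_loss <- epoch_loss + as.numeric(l)
        grads <- .backward(model, fw, s$labels, w_pos)
        upd <- .adam_step(model$params, grads, opt, config$learning_rate)
        model$params <- upd$params
        opt <- upd$state
      }
      ev <- evaluate_model(model, val_samples)
      row <- data.frame(epoch = epoch,
                        train_loss = epoch_loss / length(train_samples),
                        val_fscore = ev$fscore,
                        val_balanced_accuracy = ev$balanced_accuracy,
                        val_auc = ev$auc)
      hist_rows[[epoch]] <- row
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val F %.4f  val AUC %.4f",
                        epoch, row$train_loss, row$val_fscore, row$val_auc))
      if (ev$fscore > best$fscore) {
        best <- list(params = model$params, fscore = ev$fscore,
                     epoch = epoch)
      }
      if (!is.null(config$target_fscore) &&
          best$fscore >= config$target_fscore) {
        stopped_early <- TRUE
        break
      }
      if (epoch - best$epoch >= config$early_stopping_patience) {
        stopped_early <- TRUE
        break
      }
    }
  })
  model$params <- best$params
  history <- structure(
    list(epochs = do.call(rbind, hist_rows[!vapply(hist_rows, is.null,
                                                   logical(1))]),
         best_epoch = best$epoch, best_fscore = best$fscore,
         stopped_early = stopped_early),
    class = "training_history")
  list(model = model, history = history)
}

#' @export
print.training_history <- function(x, ...) {
  cat("training_history:", nrow(x$epochs), "epochs, best epoch",
      x$best_epoch, sprintf("(val F %.4f)", x$best_fscore),
      if (x$stopped_early) "[stopped early]" else "", "\n")
  invisible(x)
}

#' Predict interface residues
#'
#' @param model A trained `gnn_model`.
#' @param graph A `protein_graph`.
#' @param threshold Probability threshold (default from the model config);
#'   a node is called positive when probability >= threshold.
#' @return data.frame with one row per node: chain, resno, ins,
#'   probability, call.
#' @export
gnn_predict <- function(model, graph, threshold = model$config$threshold) {
  probs <- gnn_forward(graph, model)
  data.frame(chain = graph$nodes$chain, resno = graph$nodes$resno,
             ins = graph$nodes$ins, probability = probs,
             call = as.integer(probs >= threshold),
             stringsAsFactors = FALSE)
}

#' Evaluate a model on a list of samples
#'
#' Pools the per-node predictions of all samples and computes the six
#' metrics at the model's classification threshold.
#'
#' @param model A `gnn_model`.
#' @param samples List of `dataset_sample`s.
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, samples) {
  probs <- unlist(lapply(samples, function(s) gnn_forward(s$graph, model)))
  labels <- unlist(lapply(samples, `[[`, "labels"))
  calls <- as.integer(probs >= model$config$threshold)
  compute_metrics(confusion(calls, labels), probs, labels)
}

#' Hyperparameter grid search
#'
#' Trains one model per combination of the supplied grid and selects the
#' configuration with the highest validation F-score; ties are broken by
#' higher balanced accuracy, then smaller state dimension.
#'
#' @param space Named list of value vectors over any of state_dim,
#'   max_iter, wbal, net_s_hidden, net_o_hidden (a full cross product is
#'   evaluated).
#' @param train_samples,val_samples Dataset samples.
#' @param base_config A [gnn_config()] supplying all remaining settings
#'   (epochs, learning rate, seed, ...).
#' @param verbose Print one line per configuration.
#' @return List with `best_config`, `best_model` and `results` (one row
#'   per combination with its validation metrics).
#' @export
grid_search <- function(space, train_samples, val_samples,
                        base_config = gnn_config(), verbose = FALSE) {
  stopifnot(is.list(space), length(space) >= 1L,
            all(names(space) %in% c("state_dim", "max_iter", "wbal",
                                    "net_s_hidden", "net_o_hidden")))
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(grid))
  fits <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg <- base_config
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][r]
    cfg <- do.call(gnn_config, cfg[setdiff(names(cfg), character(0))])
    fit <- gnn_train(train_samples, val_samples, cfg)
    ev <- evaluate_model(fit$model, val_samples)
    results[[r]] <- cbind(grid[r, , drop = FALSE],
                          data.frame(val_fscore = ev$fscore,
                                     val_balanced_accuracy =
                                       ev$balanced_accuracy,
                                     val_auc = ev$auc))
    fits[[r]] <- list(model = fit$model, config = cfg)
    if (verbose)
      message(sprintf("grid %d/%d: F %.4f", r, nrow(grid), ev$fscore))
  }
  tab <- do.call(rbind, results)
  rownames(tab) <- NULL
  sd_col <- if ("state_dim" %in% names(tab)) tab$state_dim
            else rep(base_config$state_dim, nrow(tab))
  best <- order(-tab$val_fscore, -tab$val_balanced_accuracy, sd_col)[1]
  list(best_config = fits[[best]]$config, best_model = fits[[best]]$model,
       results = tab)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding a JSON config sidecar and the
#' parameter arrays in a flat text bundle; round-trips exactly.
#'
#' @param model A `gnn_model`.
#' @param dir Checkpoint directory.
#' @return `dir` (invisibly) for `save_model`; a `gnn_model` for
#'   `load_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  jsonlite::write_json(
    list(checkpoint_version = "1.0",
         config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
         node_dim = model$node_dim, edge_dim = model$edge_dim,
         node_center = model$node_center, node_scale = model$node_scale,
         edge_center = model$edge_center, edge_scale = model$edge_scale,
         shapes = lapply(model$params, function(x) dim(x) %||% length(x))),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "params.txt"), "w")
  on.exit(close(con))
  for (k in names(model$params)) {
    writeLines(paste0("# ", k), con)
    writeLines(format(c(model$params[[k]]), digits = 17), con)
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(gnn_config, as.list(meta$config))
  lines <- readLines(file.path(dir, "params.txt"))
  marks <- grep("^# ", lines)
  params <- list()
  for (k in seq_along(marks)) {
    nm <- sub("^# ", "", lines[marks[k]])
    to <- if (k < length(marks)) marks[k + 1] - 1L else length(lines)
    vals <- as.numeric(lines[(marks[k] + 1L):to])
    shape <- unlist(meta$shapes[[nm]])
    params[[nm]] <- if (length(shape) == 2L) matrix(vals, shape[1], shape[2])
                    else vals
  }
  structure(list(config = cfg, node_dim = meta$node_dim,
                 edge_dim = meta$edge_dim, params = params,
                 node_center = meta$node_center,
                 node_scale = meta$node_scale,
                 edge_center = meta$edge_center,
                 edge_scale = meta$edge_scale),
            class = "gnn_model")
}
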