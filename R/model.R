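#' Survival network configuration
#'
#' Defaults follow the experimental setting used throughout: a three-layer
#' network with hidden width 32, dropout 0.7, Adam with learning rate 0.001,
#' at most 500 epochs with early stopping on validation loss.
#'
#' @param layer_type `"gcn"`, `"sage"`, `"gat"`, or `"mlp"` (the baseline
#'   that ignores the graph).
#' @param out_dim Number of output intervals m (the logits width).
#' @param n_layers Number of message-passing blocks (default 3).
#' @param hidden Hidden width (default 32).
#' @param dropout Dropout rate inside each block (default 0.7).
#' @param lr Adam learning rate (default 0.001).
#' @param max_epochs Training epoch cap (default 500).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param survival_model `"logistic_hazard"` or `"pmf"`.
#' @param leaky_slope Negative slope of the GAT attention LeakyReLU.
#' @return A `model_config` list.
#' @export
model_config <- function(layer_type = c("gcn", "sage", "gat", "mlp"),
                         out_dim, n_layers = 3L, hidden = 32L,
                         dropout = 0.7, lr = 0.001, max_epochs = 500L,
                         patience = 10L,
                         survival_model = c("logistic_hazard", "pmf"),
                         leaky_slope = 0.2) {
  layer_type <- match.arg(layer_type)
  survival_model <- match.arg(survival_model)
  stopifnot(out_dim >= 1L, n_layers >= 1L, hidden >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(layer_type = layer_type, out_dim = as.integer(out_dim),
                 n_layers = as.integer(n_layers), hidden = as.integer(hidden),
                 dropout = dropout, lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 survival_model = survival_model,
                 leaky_slope = leaky_slope),
            class = "model_config")
}

# Parameter initialization. Each of the n_layers blocks is
# layer -> batch-norm -> ReLU -> dropout; the final linear head maps to
# out_dim logits with no normalization or activation (the losses apply
# sigmoid / softmax themselves).
init_model <- function(cfg, in_dim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- c(in_dim, rep(cfg$hidden, cfg$n_layers))
  blocks <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    din <- dims[l]; dout <- dims[l + 1L]
    par <- switch(cfg$layer_type,
      gcn = list(W = glorot(din, dout), b = numeric(dout)),
      sage = list(W = glorot(2L * din, dout), b = numeric(dout)),
      gat = list(W = glorot(din, dout),
                 a_src = stats::runif(dout, -sqrt(3 / dout), sqrt(3 / dout)),
                 a_dst = stats::runif(dout, -sqrt(3 / dout), sqrt(3 / dout)),
                 b = numeric(dout)),
      mlp = list(W = glorot(din, dout), b = numeric(dout))
    )
    blocks[[l]] <- list(
      par = par,
      bn = list(gamma = rep(1, dout), beta = numeric(dout)),
      bn_state = list(mean = numeric(dout), var = rep(1, dout))
    )
  }
  head <- list(W = glorot(cfg$hidden, cfg$out_dim),
               b = numeric(cfg$out_dim))
  structure(list(cfg = cfg, in_dim = in_dim, blocks = blocks, head = head),
            class = "survival_network")
}

#' @export
print.survival_network <- function(x, ...) {
  cat(sprintf("<survival_network> %s, %d blocks (hidden %d) -> %d intervals, %s loss\n",
              x$cfg$layer_type, x$cfg$n_layers, x$cfg$hidden,
              x$cfg$out_dim, x$cfg$survival_model))
  invisible(x)
}

#' Forward pass of the survival network
#'
#' @param model A network from the training routine (or `init_model`).
#' @param X Node feature matrix (patients x features).
#' @param ops Output of [graph_operators()] for the (sub)graph being scored;
#'   ignored by the MLP variant.
#' @param training Use batch statistics and dropout (TRUE) or frozen running
#'   statistics with dropout off (FALSE, deterministic).
#' @return List with `logits` (patients x m) and, internally, the caches
#'   needed for the backward pass.
#' @export
model_forward <- function(model, X, ops, training = FALSE) {
  cfg <- model$cfg
  H <- X
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    blk <- model$blocks[[l]]
    lf <- layer_forward(cfg$layer_type, H, ops, blk$par, cfg$leaky_slope)
    bf <- bn_forward(lf$out, blk$bn, blk$bn_state, training)
    model$blocks[[l]]$bn_state <- bf$state
    pre <- bf$out
    act <- pmax(pre, 0)
    if (training && cfg$dropout > 0) {
      keep <- (matrix(stats::runif(length(act)), nrow(act)) >= cfg$dropout) /
        (1 - cfg$dropout)
      H2 <- act * keep
    } else {
      keep <- NULL
      H2 <- act
    }
    caches[[l]] <- list(layer = lf$cache, bn = bf$cache, pre = pre,
                        keep = keep)
    H <- H2
  }
  logits <- sweep(H %*% model$head$W, 2L, model$head$b, "+")
  list(logits = logits, H_last = H, caches = caches, model = model)
}

# Backward pass: gradient of the mean loss w.r.t. every parameter.
model_backward <- function(model, fwd, dlogits, ops) {
  cfg <- model$cfg
  grads <- list(head = list(W = t(fwd$H_last) %*% dlogits,
                            b = colSums(dlogits)),
                blocks = vector("list", cfg$n_layers))
  dH <- dlogits %*% t(model$head$W)
  for (l in rev(seq_len(cfg$n_layers))) {
    ca <- fwd$caches[[l]]
    if (!is.null(ca$keep)) dH <- dH * ca$keep
    dH <- dH * (ca$pre > 0)
    bb <- bn_backward(dH, model$blocks[[l]]$bn, ca$bn)
    lb <- layer_backward(cfg$layer_type, bb$dX, ops,
                         model$blocks[[l]]$par, ca$layer, cfg$leaky_slope)
    grads$blocks[[l]] <- list(par = lb$grads, bn = bb$grads)
    dH <- lb$dX
  }
  grads
}

## ---- Adam -------------------------------------------------------------

# Parameters are walked as a flat list of numeric arrays; Adam state mirrors
# that structure.
.flatten_params <- function(model) {
  out <- list(head.W = model$head$W, head.b = model$head$b)
  for (l in seq_along(model$blocks)) {
    for (nm in names(model$blocks[[l]]$par)) {
      out[[sprintf("b%d.par.%s", l, nm)]] <- model$blocks[[l]]$par[[nm]]
    }
    for (nm in names(model$blocks[[l]]$bn)) {
      out[[sprintf("b%d.bn.%s", l, nm)]] <- model$blocks[[l]]$bn[[nm]]
    }
  }
  out
}

.flatten_grads <- function(grads) {
  out <- list(head.W = grads$head$W, head.b = grads$head$b)
  for (l in seq_along(grads$blocks)) {
    for (nm in names(grads$blocks[[l]]$par)) {
      out[[sprintf("b%d.par.%s", l, nm)]] <- grads$blocks[[l]]$par[[nm]]
    }
    for (nm in names(grads$blocks[[l]]$bn)) {
      out[[sprintf("b%d.bn.%s", l, nm)]] <- grads$blocks[[l]]$bn[[nm]]
    }
  }
  out
}

.unflatten_params <- function(model, flat) {
  model$head$W <- flat$head.W
  model$head$b <- flat$head.b
  for (l in seq_along(model$blocks)) {
    for (nm in names(model$blocks[[l]]$par)) {
      model$blocks[[l]]$par[[nm]] <- flat[[sprintf("b%d.par.%s", l, nm)]]
    }
    for (nm in names(model$blocks[[l]]$bn)) {
      model$blocks[[l]]$bn[[nm]] <- flat[[sprintf("b%d.bn.%s", l, nm)]]
    }
  }
  model
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

adam_step <- function(flat, gflat, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(flat)) {
    g <- gflat[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, st = st)
}

## ---- training ---------------------------------------------------------

#' Train a discrete-time survival network with early stopping
#'
#' Full-graph gradient steps on the training subgraph with Adam; after each
#' epoch the validation loss is computed in evaluation mode (dropout off,
#' batch-norm running statistics frozen). Training stops when the validation
#' loss has not improved for `patience` epochs, and the best-validation
#' weights are restored.
#'
#' @param X_train,X_val Feature matrices (plain numeric matrices) for the
#'   training and validation subgraphs.
#' @param A_train,A_val Binary adjacency matrices of the two subgraphs.
#' @param labels_train,labels_val Discrete labels from [discretize()].
#' @param cfg A [model_config()].
#' @param seed Seed for parameter initialization and dropout masks.
#' @param verbose Print a line per epoch.
#' @return A `survival_network` with training history attached
#'   (`$history`: data frame of train/validation loss, `$best_epoch`).
#' @export
train_survival_network <- function(X_train, A_train, labels_train,
                                   X_val, A_val, labels_val,
                                   cfg, seed = 1L, verbose = FALSE) {
  set.seed(seed)
  model <- init_model(cfg, ncol(X_train))
  ops_tr <- graph_operators(A_train)
  ops_va <- graph_operators(A_val)
  flat <- .flatten_params(model)
  ast <- adam_init(flat)
  best_val <- Inf
  best_flat <- flat
  best_state <- lapply(model$blocks, `[[`, "bn_state")
  best_epoch <- 0L
  wait <- 0L
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    fwd <- model_forward(model, X_train, ops_tr, training = TRUE)
    model <- fwd$model   # running batch-norm statistics updated
    tr_loss <- survival_loss(fwd$logits, labels_train, cfg$survival_model)
    if (!is.finite(tr_loss)) {
      stop("training diverged: non-finite loss at epoch ", epoch)
    }
    dlog <- survival_loss_grad(fwd$logits, labels_train, cfg$survival_model)
    grads <- model_backward(model, fwd, dlog, ops_tr)
    upd <- adam_step(.flatten_params(model), .flatten_grads(grads), ast,
                     cfg$lr)
    ast <- upd$st
    model <- .unflatten_params(model, upd$flat)

    vfwd <- model_forward(model, X_val, ops_va, training = FALSE)
    val_loss <- survival_loss(vfwd$logits, labels_val, cfg$survival_model)
    hist[[epoch]] <- c(epoch = epoch, train = tr_loss, val = val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, tr_loss,
                      val_loss))
    }
    if (is.finite(val_loss) && val_loss < best_val - 1e-9) {
      best_val <- val_loss
      best_flat <- .flatten_params(model)
      best_state <- lapply(model$blocks, `[[`, "bn_state")
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model <- .unflatten_params(model, best_flat)
  for (l in seq_along(model$blocks)) {
    model$blocks[[l]]$bn_state <- best_state[[l]]
  }
  model$history <- as.data.frame(do.call(rbind, hist))
  model$best_epoch <- best_epoch
  model$best_val_loss <- best_val
  model
}

#' Predict survival curves for a (sub)graph
#'
#' Deterministic evaluation-mode forward pass followed by the transform of
#' the configured likelihood (sigmoid hazards -> product-limit survival, or
#' softmax PMF -> tail sums).
#'
#' @param model A trained `survival_network`.
#' @param X Feature matrix of the nodes to score.
#' @param A Adjacency of their subgraph (ignored by the MLP variant).
#' @return Matrix patients x m of survival probabilities over the grid.
#' @export
predict_survival <- function(model, X, A) {
  ops <- graph_operators(A)
  fwd <- model_forward(model, X, ops, training = FALSE)
  logits_to_survival(fwd$logits, model$cfg$survival_model)
}
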