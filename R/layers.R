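## Message-passing layers with hand-written forward/backward passes.
## All operators are dense: cohorts here are a few hundred patients, so an
## n x n adjacency is small and dense linear algebra beats sparse dispatch.

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

#' Precompute per-graph message-passing operators
#'
#' The structural operators each layer type needs are fixed per graph:
#' the symmetrically normalized adjacency with self-loops
#' `D^{-1/2}(A+I)D^{-1/2}` for GCN, the row-normalized neighbour-averaging
#' matrix for GraphSAGE (zero row for isolated nodes), and the self-loop
#' neighbourhood mask for GAT attention.
#'
#' @param A Symmetric binary adjacency matrix, zero diagonal.
#' @return List of operators consumed by [model_forward()].
#' @export
graph_operators <- function(A) {
  n <- nrow(A)
  Aself <- A + diag(n)
  deg <- rowSums(Aself)
  dinv <- 1 / sqrt(deg)
  Ahat <- Aself * outer(dinv, dinv)
  rs <- rowSums(A)
  Amean <- A / ifelse(rs > 0, rs, 1)
  Amean[rs == 0, ] <- 0
  list(n = n, Ahat = Ahat, Amean = Amean, mask = Aself > 0)
}

## ---- graph layer forward/backward -------------------------------------

layer_forward <- function(type, X, ops, par, slope = 0.2) {
  switch(type,
    gcn = {
      XW <- X %*% par$W
      out <- ops$Ahat %*% XW
      list(out = sweep(out, 2L, par$b, "+"), cache = list(X = X))
    },
    sage = {
      Mn <- ops$Amean %*% X
      C <- cbind(X, Mn)
      list(out = sweep(C %*% par$W, 2L, par$b, "+"), cache = list(C = C))
    },
    gat = {
      Hp <- X %*% par$W
      s1 <- drop(Hp %*% par$a_src)
      s2 <- drop(Hp %*% par$a_dst)
      n <- ops$n
      Epre <- matrix(s1, n, n) + matrix(s2, n, n, byrow = TRUE)
      E <- leaky_relu(Epre, slope)
      E[!ops$mask] <- -Inf
      alpha <- row_softmax(E)
      alpha[!ops$mask] <- 0
      out <- alpha %*% Hp
      list(out = sweep(out, 2L, par$b, "+"),
           cache = list(X = X, Hp = Hp, Epre = Epre, alpha = alpha))
    },
    mlp = {
      list(out = sweep(X %*% par$W, 2L, par$b, "+"), cache = list(X = X))
    },
    stop("unknown layer type: ", type)
  )
}

layer_backward <- function(type, dOut, ops, par, cache, slope = 0.2) {
  db <- colSums(dOut)
  switch(type,
    gcn = {
      AdO <- ops$Ahat %*% dOut       # Ahat is symmetric
      list(dX = AdO %*% t(par$W),
           grads = list(W = t(cache$X) %*% AdO, b = db))
    },
    sage = {
      dC <- dOut %*% t(par$W)
      d <- ncol(dC) / 2L
      dX <- dC[, seq_len(d), drop = FALSE] +
        t(ops$Amean) %*% dC[, d + seq_len(d), drop = FALSE]
      list(dX = dX, grads = list(W = t(cache$C) %*% dOut, b = db))
    },
    gat = {
      alpha <- cache$alpha
      Hp <- cache$Hp
      dalpha <- dOut %*% t(Hp)
      dalpha[!ops$mask] <- 0
      dHp <- t(alpha) %*% dOut
      dE <- alpha * (dalpha - rowSums(dalpha * alpha))
      dEpre <- dE * ifelse(cache$Epre > 0, 1, slope)
      dEpre[!ops$mask] <- 0
      ds1 <- rowSums(dEpre)
      ds2 <- colSums(dEpre)
      dHp <- dHp + outer(ds1, par$a_src) + outer(ds2, par$a_dst)
      list(dX = dHp %*% t(par$W),
           grads = list(W = t(cache$X) %*% dHp,
                        a_src = drop(t(Hp) %*% ds1),
                        a_dst = drop(t(Hp) %*% ds2),
                        b = db))
    },
    mlp = {
      list(dX = dOut %*% t(par$W),
           grads = list(W = t(cache$X) %*% dOut, b = db))
    }
  )
}

## ---- batch normalization ----------------------------------------------

bn_forward <- function(X, par, state, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2L, mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  std <- sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, mu), 2L, std, "/")
  out <- sweep(sweep(xhat, 2L, par$gamma, "*"), 2L, par$beta, "+")
  list(out = out, cache = list(xhat = xhat, std = std), state = state)
}

bn_backward <- function(dY, par, cache) {
  xhat <- cache$xhat
  n <- nrow(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, par$gamma, "*")
  mean_dxhat <- colMeans(dxhat)
  mean_dxhat_xhat <- colMeans(dxhat * xhat)
  dX <- sweep(dxhat, 2L, mean_dxhat) -
    sweep(xhat, 2L, mean_dxhat_xhat, "*")
  dX <- sweep(dX, 2L, cache$std, "/")
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}
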