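# Conditional density estimator for neural posterior estimation: a mixture
# density network (MDN). A two-hidden-layer tanh MLP maps the (z-scored)
# observation x to the parameters of a mixture of full-covariance Gaussians
# over the (z-scored, unconstrained) parameter vector theta. The covariance
# of each component is parametrized by a lower-triangular precision factor A
# with positive diagonal, z = A (theta - mu) ~ N(0, I), which keeps the
# per-sample log-density and its gradients cheap and exactly normalized.
# Training minimizes the negative conditional log-likelihood with Adam,
# mini-batches, a validation split and early stopping.

mdn_layout <- function(p, d, K, hidden) {
  noff <- d * (d - 1L) / 2L
  d_out <- K + K * d + K * d + K * noff
  list(p = p, d = d, K = K, hidden = hidden, noff = noff, d_out = d_out,
       # column offsets into the output block, per component
       logits = seq_len(K),
       mu = function(k) K + (k - 1L) * d + seq_len(d),
       ld = function(k) K + K * d + (k - 1L) * d + seq_len(d),
       off = function(k) if (noff == 0L) integer(0) else
         K + 2L * K * d + (k - 1L) * noff + seq_len(noff))
}

# strict lower-triangle index pairs (p > q), column-major over q then p
lower_tri_pairs <- function(d) {
  if (d < 2L) return(matrix(integer(0), 0L, 2L))
  idx <- which(lower.tri(matrix(0, d, d)), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

mdn_init_params <- function(layout, seed = NULL) {
  with_seed(seed, {
    glorot <- function(nin, nout) {
      matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
    }
    list(W1 = glorot(layout$p, layout$hidden), b1 = numeric(layout$hidden),
         W2 = glorot(layout$hidden, layout$hidden), b2 = numeric(layout$hidden),
         W3 = 0.1 * glorot(layout$hidden, layout$d_out),
         b3 = numeric(layout$d_out))
  })
}

mdn_mlp_forward <- function(par, Xb) {
  H1 <- tanh(sweep(Xb %*% par$W1, 2L, par$b1, "+"))
  H2 <- tanh(sweep(H1 %*% par$W2, 2L, par$b2, "+"))
  O <- sweep(H2 %*% par$W3, 2L, par$b3, "+")
  list(H1 = H1, H2 = H2, O = O)
}

# Negative mean log-likelihood of the batch and (optionally) gradients.
# Xb: n x p standardized observations; Tb: n x d standardized parameters.
mdn_loss <- function(par, Xb, Tb, layout, want_grad = TRUE) {
  n <- nrow(Xb); d <- layout$d; K <- layout$K
  fw <- mdn_mlp_forward(par, Xb)
  O <- fw$O
  ltp <- lower_tri_pairs(d)

  logits <- O[, layout$logits, drop = FALSE]
  logw <- logits - logsumexp_rows(logits)

  logN <- matrix(0, n, K)
  cache <- vector("list", K)
  for (k in seq_len(K)) {
    mu <- O[, layout$mu(k), drop = FALSE]
    ld <- pmin(pmax(O[, layout$ld(k), drop = FALSE], -7), 7)
    Ad <- exp(ld)
    off <- if (layout$noff > 0L) O[, layout$off(k), drop = FALSE] else NULL
    U <- Tb - mu
    Z <- matrix(0, n, d)
    for (pp in seq_len(d)) {
      z <- Ad[, pp] * U[, pp]
      if (!is.null(off)) {
        for (m in which(ltp[, 1L] == pp)) {
          z <- z + off[, m] * U[, ltp[m, 2L]]
        }
      }
      Z[, pp] <- z
    }
    logN[, k] <- rowSums(ld) - 0.5 * rowSums(Z^2) - d / 2 * log(2 * pi)
    cache[[k]] <- list(U = U, Z = Z, Ad = Ad, ld_raw = O[, layout$ld(k), drop = FALSE])
  }
  s <- logw + logN
  loss_i <- -logsumexp_rows(s)
  loss <- mean(loss_i)
  if (!want_grad) return(list(loss = loss))

  r <- exp(s - (-loss_i))             # responsibilities, rows sum to 1
  w <- exp(logw)
  dO <- matrix(0, n, layout$d_out)
  dO[, layout$logits] <- (w - r) / n
  for (k in seq_len(K)) {
    ck <- cache[[k]]
    rk <- r[, k] / n
    # A^T z (n x d)
    AtZ <- matrix(0, n, d)
    for (qq in seq_len(d)) {
      a <- ck$Ad[, qq] * ck$Z[, qq]
      if (layout$noff > 0L) {
        off <- O[, layout$off(k), drop = FALSE]
        for (m in which(ltp[, 2L] == qq)) {
          a <- a + off[, m] * ck$Z[, ltp[m, 1L]]
        }
      }
      AtZ[, qq] <- a
    }
    dO[, layout$mu(k)] <- -rk * AtZ
    # clamp: zero gradient where the raw log-diagonal was clipped
    live <- abs(ck$ld_raw) < 7
    dld <- -rk * (1 - ck$Z * ck$U * ck$Ad)
    dO[, layout$ld(k)] <- dld * live
    if (layout$noff > 0L) {
      doff <- matrix(0, n, layout$noff)
      for (m in seq_len(layout$noff)) {
        doff[, m] <- rk * ck$Z[, ltp[m, 1L]] * ck$U[, ltp[m, 2L]]
      }
      dO[, layout$off(k)] <- doff
    }
  }

  dW3 <- crossprod(fw$H2, dO); db3 <- colSums(dO)
  dH2 <- tcrossprod(dO, par$W3) * (1 - fw$H2^2)
  dW2 <- crossprod(fw$H1, dH2); db2 <- colSums(dH2)
  dH1 <- tcrossprod(dH2, par$W2) * (1 - fw$H1^2)
  dW1 <- crossprod(Xb, dH1); db1 <- colSums(dH1)
  list(loss = loss,
       grad = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                   W3 = dW3, b3 = db3))
}

adam_state <- function(par) {
  list(m = lapply(par, function(x) x * 0), v = lapply(par, function(x) x * 0),
       t = 0L)
}

adam_step <- function(par, grad, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(par)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

zscore_fit <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
zscore_apply <- function(m, sc) sweep(sweep(m, 2L, sc$mu), 2L, sc$sd, "/")
zscore_invert <- function(m, sc) sweep(sweep(m, 2L, sc$sd, "*"), 2L, sc$mu, "+")

# Train an MDN on (theta, x) pairs. theta: n x d (unconstrained scale),
# x: n x p. Returns the fitted estimator with scalers and training history.
mdn_train <- function(theta, x, n_components = 1L, hidden = 50L,
                      batch_size = 1000L, validation_fraction = 0.1,
                      stop_after_epochs = 20L, max_epochs = 500L,
                      learning_rate = 1e-3, seed = NULL) {
  theta <- as.matrix(theta); x <- as.matrix(x)
  stopifnot(nrow(theta) == nrow(x), nrow(theta) >= 20L)
  n <- nrow(theta)
  layout <- mdn_layout(ncol(x), ncol(theta), as.integer(n_components),
                       as.integer(hidden))
  sc_t <- zscore_fit(theta); sc_x <- zscore_fit(x)
  Ts <- zscore_apply(theta, sc_t); Xs <- zscore_apply(x, sc_x)

  with_seed(seed, {
    n_val <- max(1L, round(validation_fraction * n))
    perm <- sample.int(n)
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[-seq_len(n_val)]
    par <- mdn_init_params(layout)
    st <- adam_state(par)
    bs <- min(batch_size, length(tr_idx))
    best <- list(loss = Inf, par = par, epoch = 0L)
    history <- numeric(0)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(tr_idx)
      nb <- ceiling(length(ord) / bs)
      for (b in seq_len(nb)) {
        rows <- ord[((b - 1L) * bs + 1L):min(b * bs, length(ord))]
        fg <- mdn_loss(par, Xs[rows, , drop = FALSE],
                       Ts[rows, , drop = FALSE], layout)
        if (!is.finite(fg$loss)) next
        upd <- adam_step(par, fg$grad, st, lr = learning_rate)
        par <- upd$par; st <- upd$state
      }
      vl <- mdn_loss(par, Xs[val_idx, , drop = FALSE],
                     Ts[val_idx, , drop = FALSE], layout,
                     want_grad = FALSE)$loss
      history <- c(history, vl)
      if (is.finite(vl) && vl < best$loss - 1e-5) {
        best <- list(loss = vl, par = par, epoch = epoch)
      }
      if (epoch - best$epoch >= stop_after_epochs) break
    }
  })
  structure(list(par = best$par, layout = layout, sc_theta = sc_t,
                 sc_x = sc_x, val_loss = best$loss, history = history,
                 n_train = n),
            class = "mdn")
}

# Mixture parameters (standardized-theta space) at a single observation x.
mdn_phi <- function(fit, x) {
  xs <- zscore_apply(matrix(x, nrow = 1L), fit$sc_x)
  O <- mdn_mlp_forward(fit$par, xs)$O[1L, ]
  lo <- fit$layout
  d <- lo$d
  ltp <- lower_tri_pairs(d)
  w <- exp(O[lo$logits] - max(O[lo$logits]))
  w <- w / sum(w)
  comps <- lapply(seq_len(lo$K), function(k) {
    A <- diag(exp(pmin(pmax(O[lo$ld(k)], -7), 7)), d)
    if (lo$noff > 0L) {
      off <- O[lo$off(k)]
      for (m in seq_len(lo$noff)) A[ltp[m, 1L], ltp[m, 2L]] <- off[m]
    }
    Sigma <- chol2inv(chol(crossprod(A)))
    list(mu = O[lo$mu(k)], A = A, Sigma = Sigma)
  })
  list(w = w, comps = comps)
}

# Draw n samples from q(theta | x); returns n x d on the unconstrained
# (pre-standardization) scale.
mdn_sample <- function(fit, x, n, seed = NULL) {
  phi <- mdn_phi(fit, x)
  d <- fit$layout$d
  with_seed(seed, {
    comp <- sample.int(length(phi$w), n, replace = TRUE, prob = phi$w)
    out <- matrix(0, n, d)
    for (k in unique(comp)) {
      rows <- which(comp == k)
      Zs <- matrix(stats::rnorm(length(rows) * d), length(rows), d)
      U <- t(forwardsolve(phi$comps[[k]]$A, t(Zs)))
      out[rows, ] <- sweep(U, 2L, phi$comps[[k]]$mu, "+")
    }
    zscore_invert(out, fit$sc_theta)
  })
}

# log q(theta | x) on the unconstrained scale (includes the z-score Jacobian
# so densities integrate to one over unconstrained theta).
mdn_log_prob <- function(fit, theta, x) {
  theta <- if (is.matrix(theta)) theta else matrix(theta, ncol = fit$layout$d)
  Ts <- zscore_apply(theta, fit$sc_theta)
  phi <- mdn_phi(fit, x)
  d <- fit$layout$d
  comp_ll <- sapply(seq_along(phi$w), function(k) {
    ck <- phi$comps[[k]]
    U <- sweep(Ts, 2L, ck$mu)
    Z <- U %*% t(ck$A)
    sum(log(diag(ck$A))) - 0.5 * rowSums(Z^2) - d / 2 * log(2 * pi)
  })
  comp_ll <- matrix(comp_ll, nrow = nrow(Ts))
  logsumexp_rows(sweep(comp_ll, 2L, log(phi$w), "+")) -
    sum(log(fit$sc_theta$sd))
}

# Exact conditional of the mixture given theta[fix_dim] = value (all on the
# unconstrained scale). Returns a sampler over the remaining dims.
mdn_conditional_sample <- function(fit, x, fix_dim, fix_value, n,
                                   seed = NULL) {
  phi <- mdn_phi(fit, x)
  d <- fit$layout$d
  stopifnot(d >= 2L, fix_dim >= 1L, fix_dim <= d)
  vs <- (fix_value - fit$sc_theta$mu[fix_dim]) / fit$sc_theta$sd[fix_dim]
  free <- setdiff(seq_len(d), fix_dim)
  cond <- lapply(seq_along(phi$w), function(k) {
    ck <- phi$comps[[k]]
    S <- ck$Sigma
    mu_c <- ck$mu[free] + S[free, fix_dim] / S[fix_dim, fix_dim] *
      (vs - ck$mu[fix_dim])
    S_c <- S[free, free, drop = FALSE] -
      tcrossprod(S[free, fix_dim, drop = FALSE]) / S[fix_dim, fix_dim]
    lw <- log(phi$w[k]) +
      stats::dnorm(vs, ck$mu[fix_dim], sqrt(S[fix_dim, fix_dim]), log = TRUE)
    list(mu = mu_c, Sigma = S_c, lw = lw)
  })
  lw <- vapply(cond, `[[`, numeric(1L), "lw")
  w <- exp(lw - max(lw)); w <- w / sum(w)
  with_seed(seed, {
    comp <- sample.int(length(w), n, replace = TRUE, prob = w)
    out <- matrix(0, n, length(free))
    for (k in unique(comp)) {
      rows <- which(comp == k)
      out[rows, ] <- MASS::mvrnorm(length(rows), cond[[k]]$mu,
                                   cond[[k]]$Sigma)
    }
    sc <- list(mu = fit$sc_theta$mu[free], sd = fit$sc_theta$sd[free])
    zscore_invert(out, sc)
  })
}
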