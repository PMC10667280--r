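# Minimal dense network with tanh hidden layers and a linear output layer.
# Everything is plain matrix algebra so the exact gradient of any scalar loss
# in the outputs can be backpropagated analytically; no autodiff framework is
# used anywhere in the package.

mlp_init <- function(d_in, hidden, d_out) {
  dims <- c(d_in, hidden, d_out)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    nin <- dims[l]; nout <- dims[l + 1L]
    s <- sqrt(6 / (nin + nout))    # Glorot/Xavier uniform
    layers[[l]] <- list(W = matrix(stats::runif(nin * nout, -s, s), nin, nout),
                        b = numeric(nout))
  }
  layers
}

# forward pass; keeps layer activations for the backward pass
mlp_forward <- function(layers, X) {
  L <- length(layers)
  H <- vector("list", L + 1L)
  H[[1]] <- X
  for (l in seq_len(L - 1L))
    H[[l + 1L]] <- tanh(sweep(H[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`))
  out <- sweep(H[[L]] %*% layers[[L]]$W, 2, layers[[L]]$b, `+`)
  list(out = out, H = H)
}

# gradient of the loss wrt all weights given d(loss)/d(out)
mlp_backward <- function(layers, H, dout) {
  L <- length(layers)
  grads <- vector("list", L)
  d <- dout
  grads[[L]] <- list(W = crossprod(H[[L]], d), b = colSums(d))
  dH <- d %*% t(layers[[L]]$W)
  for (l in seq(L - 1L, 1L)) {
    d <- dH * (1 - H[[l + 1L]]^2)          # tanh'
    grads[[l]] <- list(W = crossprod(H[[l]], d), b = colSums(d))
    if (l > 1L) dH <- d %*% t(layers[[l]]$W)
  }
  grads
}

# flatten / restore parameters for the generic optimizers
mlp_pack <- function(layers)
  unlist(lapply(layers, function(l) c(as.numeric(l$W), l$b)))

mlp_unpack <- function(v, template) {
  pos <- 0L
  for (l in seq_along(template)) {
    nW <- length(template[[l]]$W); nb <- length(template[[l]]$b)
    template[[l]]$W[] <- v[pos + seq_len(nW)]; pos <- pos + nW
    template[[l]]$b <- v[pos + seq_len(nb)]; pos <- pos + nb
  }
  template
}

# Adam with standard bias correction; fn_grad(v) must return list(loss, grad)
adam_optimize <- function(v, fn_grad, iters, lr = 1e-3, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8, callback = NULL) {
  m <- numeric(length(v)); w <- numeric(length(v))
  for (it in seq_len(iters)) {
    fg <- fn_grad(v)
    if (!is.finite(fg$loss)) stop(sprintf("loss diverged at Adam iteration %d", it))
    g <- fg$grad
    m <- beta1 * m + (1 - beta1) * g
    w <- beta2 * w + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^it)
    what <- w / (1 - beta2^it)
    v <- v - lr * mhat / (sqrt(what) + eps)
    if (!is.null(callback)) callback(it, fg$loss)
  }
  v
}
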