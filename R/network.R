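## Minimal MLP machinery: linear / batch-norm / ReLU layers with manual
## forward and backward passes and an Adam optimiser, in base R matrix
## ops. Layers store parameters in named lists so optimiser state can
## mirror their structure. Rows are samples throughout.

# ---- layer constructors -----------------------------------------------

# Linear layer, W: in x out, b: out. Init U(-k, k), k = 1/sqrt(in).
newLinear <- function(din, dout) {
  k <- 1 / sqrt(din)
  list(type = "linear",
       W = matrix(runif(din * dout, -k, k), din, dout),
       b = runif(dout, -k, k))
}

# Batch norm over features; gamma/beta trainable, running stats for eval.
newBatchNorm <- function(d, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, d), beta = rep(0, d),
       runMean = rep(0, d), runVar = rep(1, d),
       momentum = momentum, eps = eps)
}

newRelu <- function() list(type = "relu")

# ---- forward / backward ----------------------------------------------

layerForward <- function(layer, x, train) {
  switch(layer$type,
    linear = {
      out <- x %*% layer$W
      out <- sweep(out, 2L, layer$b, "+")
      list(out = out, cache = list(x = x), layer = layer)
    },
    bn = {
      if (train) {
        n <- nrow(x)
        mu <- colMeans(x)
        v <- colMeans(x * x) - mu^2           # biased, for normalisation
        xhat <- sweep(sweep(x, 2L, mu), 2L, sqrt(v + layer$eps), "/")
        ub <- if (n > 1L) v * n / (n - 1L) else v
        layer$runMean <- (1 - layer$momentum) * layer$runMean +
          layer$momentum * mu
        layer$runVar <- (1 - layer$momentum) * layer$runVar +
          layer$momentum * ub
        out <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
        list(out = out, cache = list(xhat = xhat, v = v), layer = layer)
      } else {
        xhat <- sweep(sweep(x, 2L, layer$runMean), 2L,
                      sqrt(layer$runVar + layer$eps), "/")
        out <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
        list(out = out, cache = NULL, layer = layer)
      }
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask), layer = layer)
    })
}

layerBackward <- function(layer, cache, dout) {
  switch(layer$type,
    linear = list(
      grads = list(W = crossprod(cache$x, dout), b = colSums(dout)),
      dx = tcrossprod(dout, layer$W)),
    bn = {
      n <- nrow(dout)
      xhat <- cache$xhat
      dgamma <- colSums(dout * xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2L, layer$gamma, "*")
      inv <- 1 / sqrt(cache$v + layer$eps)
      dx <- sweep(
        n * dxhat -
          matrix(colSums(dxhat), n, ncol(dout), byrow = TRUE) -
          xhat * matrix(colSums(dxhat * xhat), n, ncol(dout), byrow = TRUE),
        2L, inv / n, "*")
      list(grads = list(gamma = dgamma, beta = dbeta), dx = dx)
    },
    relu = list(grads = NULL, dx = dout * cache$mask))
}

# Forward through a network (list of layers). With train = TRUE returns
# per-layer caches and the updated layers (running BN statistics).
networkForward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net))
  for (j in seq_along(net)) {
    step <- layerForward(net[[j]], x, train)
    x <- step$out
    caches[[j]] <- step$cache
    net[[j]] <- step$layer
  }
  list(out = x, caches = caches, net = net)
}

# Backward pass; returns per-layer gradient lists and the input gradient.
networkBackward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (j in rev(seq_along(net))) {
    step <- layerBackward(net[[j]], caches[[j]], dout)
    grads[j] <- list(step$grads)   # keep NULL slots (ReLU has no params)
    dout <- step$dx
  }
  list(grads = grads, dx = dout)
}

# ---- Adam -------------------------------------------------------------

trainableNames <- function(layer) {
  switch(layer$type, linear = c("W", "b"), bn = c("gamma", "beta"),
         relu = character(0))
}

newAdamState <- function(net) {
  lapply(net, function(layer) {
    nm <- trainableNames(layer)
    st <- lapply(nm, function(p) list(m = layer[[p]] * 0,
                                      v = layer[[p]] * 0))
    names(st) <- nm
    st
  })
}

# One Adam step over every trainable parameter of `net`. Weight decay is
# added to the gradient (L2 style). Returns updated net and state.
adamStep <- function(net, grads, state, t, lr, weightDecay,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (j in seq_along(net)) {
    for (p in trainableNames(net[[j]])) {
      g <- grads[[j]][[p]] + weightDecay * net[[j]][[p]]
      st <- state[[j]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net[[j]][[p]] <- net[[j]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[j]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

# ---- public surface ---------------------------------------------------

# Assemble an MLP from layer widths: linear(+BN+ReLU) per hidden layer,
# plain linear output layer.
buildMlp <- function(widths, batchNorm) {
  net <- list()
  L <- length(widths) - 1L
  for (j in seq_len(L)) {
    net[[length(net) + 1L]] <- newLinear(widths[j], widths[j + 1L])
    if (j < L) {
      if (batchNorm)
        net[[length(net) + 1L]] <- newBatchNorm(widths[j + 1L])
      net[[length(net) + 1L]] <- newRelu()
    }
  }
  net
}

#' Build the encoder and projector networks
#'
#' Constructs the two multi-layer perceptrons from a [NetworkSpec-class]:
#' hidden layers are linear + (optional) batch norm + ReLU, output
#' layers are plain linear. Initial weights follow the uniform
#' \eqn{U(-1/\sqrt{d_{in}}, 1/\sqrt{d_{in}})} convention and are
#' deterministic given `seed`.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed integer seed for the weight initialisation.
#' @return `list(encoder, projector)`, each a layer list consumed by the
#'   training loop and [embedCells()].
#' @export
buildNetworks <- function(spec, seed = 1L) {
  methods::validObject(spec)
  withSeed(deriveSeed(seed, 2L), {
    list(encoder = buildMlp(spec@encoderLayers, spec@batchNorm),
         projector = buildMlp(spec@projectorLayers, spec@batchNorm))
  })
}

#' Count trainable parameters of a network
#'
#' Sums the entries of every weight matrix, bias, and batch-norm
#' gamma/beta of a layer list from [buildNetworks()].
#'
#' @param net a layer list (e.g. `buildNetworks(spec)$encoder`).
#' @return integer parameter count.
#' @export
parameterCount <- function(net) {
  sum(vapply(net, function(layer) {
    sum(vapply(trainableNames(layer),
               function(p) length(layer[[p]]), integer(1)))
  }, numeric(1)))
}
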