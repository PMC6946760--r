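# Feed-forward multilayer perceptron: two tanh hidden layers (16 neurons
# each), softmax output over the movement classes, trained by full-batch
# gradient descent with momentum and L2 weight decay.  Written in-package so
# that the 16-16 topology, the seeding and the regularisation are fully
# deterministic and self-contained.

mlpInit <- function(sizes, seed) {
  set.seed(seed)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    nin <- sizes[i]; nout <- sizes[i + 1L]
    list(W = matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)),
                    nrow = nin),
         b = rep(0, nout))
  })
}

mlpForward <- function(layers, X) {
  acts <- list(X)
  nl <- length(layers)
  for (i in seq_len(nl)) {
    Z <- acts[[i]] %*% layers[[i]]$W
    Z <- sweep(Z, 2L, layers[[i]]$b, "+")
    acts[[i + 1L]] <- if (i < nl) tanh(Z) else {
      Z <- Z - apply(Z, 1L, max)           # stabilised softmax
      E <- exp(Z)
      E / rowSums(E)
    }
  }
  acts
}

mlpTrain <- function(X, Y, hidden = c(16L, 16L), learningRate = 0.1,
                     momentum = 0.1, weightDecay = 1e-3, maxEpochs = 400L,
                     tol = 1e-6, patience = 25L, seed = 1L) {
  n <- nrow(X)
  layers <- mlpInit(c(ncol(X), hidden, ncol(Y)), seed)
  vel <- lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  bestLoss <- Inf; bestLayers <- layers; stall <- 0L
  for (epoch in seq_len(maxEpochs)) {
    acts <- mlpForward(layers, X)
    P <- acts[[length(acts)]]
    loss <- -mean(log(rowSums(P * Y) + 1e-300)) +
      weightDecay / 2 * sum(vapply(layers, function(l) sum(l$W^2), numeric(1)))
    if (!is.finite(loss)) break
    if (loss < bestLoss - tol) { bestLoss <- loss; bestLayers <- layers; stall <- 0L }
    else { stall <- stall + 1L; if (stall >= patience) break }
    delta <- (P - Y) / n                    # softmax + cross-entropy gradient
    for (i in rev(seq_along(layers))) {
      gW <- crossprod(acts[[i]], delta) + weightDecay * layers[[i]]$W
      gb <- colSums(delta)
      if (i > 1L)
        delta <- (delta %*% t(layers[[i]]$W)) * (1 - acts[[i]]^2)
      vel[[i]]$W <- momentum * vel[[i]]$W - learningRate * gW
      vel[[i]]$b <- momentum * vel[[i]]$b - learningRate * gb
      layers[[i]]$W <- layers[[i]]$W + vel[[i]]$W
      layers[[i]]$b <- layers[[i]]$b + vel[[i]]$b
    }
  }
  list(layers = bestLayers, loss = bestLoss)
}

mlpPredict <- function(model, X) {
  P <- mlpForward(model$layers, X)
  P[[length(P)]]
}
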