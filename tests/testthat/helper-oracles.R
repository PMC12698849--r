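# Independent oracles: naive loop implementations and finite differences,
# deliberately written without reusing any of the package's vectorised code
# paths.

# Direct quadruple-loop valid convolution.
naive_conv <- function(X, W, b) {
  dX <- dim(X); dW <- dim(W)
  H <- dX[1]; Wd <- dX[2]; C <- dX[3]; N <- dX[4]
  k <- dW[1]; nf <- dW[4]
  Ho <- H - k + 1L; Wo <- Wd - k + 1L
  out <- array(0, dim = c(Ho, Wo, nf, N))
  for (n in seq_len(N)) for (f in seq_len(nf))
    for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      patch <- X[i:(i + k - 1), j:(j + k - 1), , n]
      out[i, j, f, n] <- sum(patch * W[, , , f]) + b[f]
    }
  out
}

# Direct softmax cross-entropy, scalar arithmetic per sample.
naive_softmax_ce <- function(scores, labels) {
  n <- ncol(scores)
  total <- 0
  for (i in seq_len(n)) {
    e <- exp(scores[, i] - max(scores[, i]))
    p <- e / sum(e)
    total <- total - log(p[labels[i] + 1])
  }
  total / n
}

# Central finite-difference gradient of the loss w.r.t. selected flat
# parameter coordinates of a model part.
fd_gradient <- function(part, X, y, coords, h = 1e-5) {
  flat <- part_flatten(part)
  vapply(coords, function(j) {
    fp <- flat; fp[j] <- fp[j] + h
    lp <- cross_entropy_loss(monolithic_forward(part_unflatten(part, fp), X), y)
    fm <- flat; fm[j] <- fm[j] - h
    lm <- cross_entropy_loss(monolithic_forward(part_unflatten(part, fm), X), y)
    (lp - lm) / (2 * h)
  }, numeric(1))
}

# Brute-force counting of classification metrics.
naive_metrics <- function(true, pred, n_classes) {
  acc <- sum(true == pred) / length(true)
  per <- t(vapply(0:(n_classes - 1), function(c) {
    tp <- sum(true == c & pred == c)
    fp <- sum(true != c & pred == c)
    fn <- sum(true == c & pred != c)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f = f, support = tp + fn)
  }, numeric(4)))
  list(accuracy = acc, per = per)
}
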