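#' Neural network architecture specification
#'
#' Four fully connected ReLU hidden layers (256, 128, 64, 32 units) with 1%
#' inter-layer dropout; Gaussian noise (sd 0.05) is added to the (scaled)
#' input and rectified before the hidden stack. The classification head is a
#' softmax trained with categorical cross-entropy and Adam; the regression
#' head is linear, trained with log-cosh and Nadam. The learning rate starts
#' at 1e-3 and is halved after a 10-epoch validation-loss plateau; training
#' stops after 100 non-improving epochs and the best checkpoint is restored.
#' Batches of 32 rows, reshuffled every epoch.
#'
#' @param hidden Hidden layer widths.
#' @param dropout Inter-layer dropout rate.
#' @param input_noise_sd Gaussian noise sd applied to the scaled input.
#' @param learning_rate Initial learning rate.
#' @param batch_size Mini-batch size.
#' @param lr_patience Epochs without validation improvement before halving.
#' @param stop_patience Epochs without improvement before early stopping.
#' @param max_epochs Hard cap on epochs (desk-scale runs lower this).
#' @return An object of class `net_spec`.
#' @export
net_spec <- function(hidden = c(256, 128, 64, 32), dropout = 0.01,
                     input_noise_sd = 0.05, learning_rate = 0.001,
                     batch_size = 32, lr_patience = 10, stop_patience = 100,
                     max_epochs = 1000) {
  structure(list(hidden = hidden, dropout = dropout,
                 input_noise_sd = input_noise_sd,
                 learning_rate = learning_rate, batch_size = batch_size,
                 lr_patience = lr_patience, stop_patience = stop_patience,
                 max_epochs = max_epochs),
            class = "net_spec")
}

#' Reference table for network training
#'
#' @param features Numeric matrix, one cSFS row per simulation.
#' @param labels For classification a factor/character of model ids; for
#'   regression a numeric matrix of parameter values in original units.
#' @param box For regression, the `prior_box` used to scale parameters to
#'   `[0, 1]`.
#' @param frac_train Fraction of rows used for training (rest validates);
#'   the canonical splits are 40,000/10,000 for classification and
#'   10,000/10,000 for regression.
#' @param seed Optional seed for the split.
#' @return An object of class `reference_table`.
#' @export
reference_table <- function(features, labels, box = NULL, frac_train = 0.5,
                            seed = NULL) {
  features <- as.matrix(features)
  if (nrow(features) == 0) stop("empty reference table")
  if (!all(is.finite(features))) stop("non-finite features")
  kind <- if (is.numeric(labels)) "regression" else "classification"
  if (kind == "regression") {
    labels <- as.matrix(labels)
    stopifnot(nrow(labels) == nrow(features))
    if (is.null(box)) stop("regression tables need a prior_box for scaling")
  } else {
    labels <- factor(labels)
    stopifnot(length(labels) == nrow(features))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(features)
  idx <- sample.int(n)
  n_train <- max(1L, floor(frac_train * n))
  structure(list(x = features, y = labels, box = box, kind = kind,
                 train_idx = idx[seq_len(n_train)],
                 val_idx = if (n_train < n) idx[(n_train + 1L):n] else integer(0)),
            class = "reference_table")
}

#' Scale parameters into the unit box and back
#'
#' @param params Matrix (or vector) of parameters in original units.
#' @param box A `prior_box`.
#' @return Matrix in `[0, 1]` units (`scale_params`) or original units
#'   (`unscale_params`). The two are exact inverses for in-box values.
#' @export
scale_params <- function(params, box) {
  p <- rbind(params)[, names(box$lower), drop = FALSE]
  w <- box$upper - box$lower
  w[w == 0] <- 1
  sweep(sweep(p, 2, box$lower[colnames(p)]), 2, w[colnames(p)], "/")
}

#' @rdname scale_params
#' @export
unscale_params <- function(params, box) {
  p <- rbind(params)
  w <- box$upper - box$lower
  w[w == 0] <- 1
  sweep(sweep(p, 2, w[colnames(p)], "*"), 2, box$lower[colnames(p)], "+")
}

.relu <- function(z) { z[z < 0] <- 0; z }
.log_cosh <- function(r) abs(r) + log1p(exp(-2 * abs(r))) - log(2)

.init_layers <- function(d_in, hidden, d_out) {
  dims <- c(d_in, hidden, d_out)
  lapply(seq_len(length(dims) - 1L), function(l) {
    list(W = matrix(rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
                    dims[l], dims[l + 1]),
         b = numeric(dims[l + 1]))
  })
}

.forward <- function(layers, X, spec, training) {
  nl <- length(layers)
  A <- X
  if (training && spec$input_noise_sd > 0)
    A <- A + matrix(rnorm(length(A), 0, spec$input_noise_sd), nrow(A))
  A <- .relu(A)
  caches <- vector("list", nl)
  for (l in seq_len(nl - 1L)) {
    Z <- A %*% layers[[l]]$W
    Z <- sweep(Z, 2, layers[[l]]$b, "+")
    H <- .relu(Z)
    mask <- NULL
    if (training && spec$dropout > 0) {
      mask <- (matrix(runif(length(H)), nrow(H)) >= spec$dropout) / (1 - spec$dropout)
      H <- H * mask
    }
    caches[[l]] <- list(A_prev = A, Z = Z, mask = mask)
    A <- H
  }
  Z <- sweep(A %*% layers[[nl]]$W, 2, layers[[nl]]$b, "+")
  caches[[nl]] <- list(A_prev = A)
  list(out = Z, caches = caches)
}

# gradient of the loss wrt all weights, given dZ at the head
.backward <- function(layers, caches, dZ) {
  nl <- length(layers)
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    A_prev <- caches[[l]]$A_prev
    grads[[l]] <- list(W = crossprod(A_prev, dZ), b = colSums(dZ))
    if (l > 1L) {
      dA <- tcrossprod(dZ, layers[[l]]$W)
      if (!is.null(caches[[l - 1L]]$mask)) dA <- dA * caches[[l - 1L]]$mask
      dZ <- dA * (caches[[l - 1L]]$Z > 0)
    }
  }
  grads
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.loss_head <- function(out, Y, kind) {
  n <- nrow(out)
  if (kind == "classification") {
    P <- .softmax(out)
    loss <- -mean(log(pmax(rowSums(P * Y), 1e-12)))
    dZ <- (P - Y) / n
  } else {
    r <- out - Y
    loss <- mean(.log_cosh(r))
    dZ <- tanh(r) / length(r)
  }
  list(loss = loss, dZ = dZ)
}

# Adam / Nadam step on one layer's parameter (beta1=0.9, beta2=0.999)
.opt_step <- function(theta, g, st, lr, t, nadam) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g * g
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  upd <- if (nadam) (b1 * mhat + (1 - b1) * g / (1 - b1^t)) else mhat
  list(theta = theta - lr * upd / (sqrt(vhat) + eps), st = st)
}

#' Train a neural network on a reference table
#'
#' Features are scaled to `[0, 1]` by their per-feature training maxima
#' (stored in the predictor); regression labels are scaled to the unit box.
#'
#' @param table A [reference_table()].
#' @param spec A [net_spec()].
#' @param seed Integer seed controlling initialization, noise, dropout and
#'   shuffling.
#' @param verbose Print per-epoch losses.
#' @return An object of class `nn_predictor` with the training log in
#'   `$log` and the restored best epoch in `$best_epoch`.
#' @export
train_network <- function(table, spec = net_spec(), seed = 1L, verbose = FALSE) {
  stopifnot(inherits(table, "reference_table"), inherits(spec, "net_spec"))
  set.seed(seed)
  xtr <- table$x[table$train_idx, , drop = FALSE]
  xva <- table$x[table$val_idx, , drop = FALSE]
  fscale <- pmax(apply(xtr, 2, max), 1e-12)
  xtr <- sweep(xtr, 2, fscale, "/")
  xva <- sweep(xva, 2, fscale, "/")
  if (table$kind == "classification") {
    classes <- levels(table$y)
    Ytr <- outer(table$y[table$train_idx], classes, `==`) * 1
    Yva <- outer(table$y[table$val_idx], classes, `==`) * 1
    d_out <- length(classes)
  } else {
    classes <- NULL
    Ytr <- scale_params(table$y[table$train_idx, , drop = FALSE], table$box)
    Yva <- scale_params(table$y[table$val_idx, , drop = FALSE], table$box)
    d_out <- ncol(Ytr)
  }
  nadam <- table$kind == "regression"
  layers <- .init_layers(ncol(xtr), spec$hidden, d_out)
  opt <- lapply(layers, function(l)
    list(W = list(m = 0 * l$W, v = 0 * l$W), b = list(m = 0 * l$b, v = 0 * l$b)))
  lr <- spec$learning_rate
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  since_best <- 0L
  tstep <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), lr = numeric(0))
  n <- nrow(xtr)
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0; nb <- 0
    for (start in seq(1, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1L, n)]
      fw <- .forward(layers, xtr[idx, , drop = FALSE], spec, training = TRUE)
      lh <- .loss_head(fw$out, Ytr[idx, , drop = FALSE], table$kind)
      grads <- .backward(layers, fw$caches, lh$dZ)
      tstep <- tstep + 1L
      for (l in seq_along(layers)) {
        sW <- .opt_step(layers[[l]]$W, grads[[l]]$W, opt[[l]]$W, lr, tstep, nadam)
        sB <- .opt_step(layers[[l]]$b, grads[[l]]$b, opt[[l]]$b, lr, tstep, nadam)
        layers[[l]]$W <- sW$theta; opt[[l]]$W <- sW$st
        layers[[l]]$b <- sB$theta; opt[[l]]$b <- sB$st
      }
      tr_loss <- tr_loss + lh$loss; nb <- nb + 1
    }
    val_out <- .forward(layers, xva, spec, training = FALSE)$out
    val_loss <- .loss_head(val_out, Yva, table$kind)$loss
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss / nb,
                                 val_loss = val_loss, lr = lr))
    if (verbose) message(sprintf("epoch %d train %.5f val %.5f lr %.2e",
                                 epoch, tr_loss / nb, val_loss, lr))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, layers = layers, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best %% spec$lr_patience == 0L) lr <- lr / 2
      if (since_best >= spec$stop_patience) break
    }
  }
  structure(list(layers = best$layers, feature_scale = fscale, spec = spec,
                 kind = table$kind, classes = classes, box = table$box,
                 param_names = if (!is.null(table$box)) names(table$box$lower),
                 log = log, best_epoch = best$epoch, best_val_loss = best$loss),
            class = "nn_predictor")
}

#' Predict from a trained network
#'
#' @param object An `nn_predictor`.
#' @param newdata Feature matrix (rows are cSFS vectors).
#' @param ... Unused.
#' @return Classification: matrix of class probabilities (rows sum to 1).
#'   Regression: matrix of predictions in scaled `[0, 1]` units (use
#'   [unscale_params()] for original units).
#' @export
predict.nn_predictor <- function(object, newdata, ...) {
  X <- sweep(rbind(newdata), 2, object$feature_scale, "/")
  out <- .forward(object$layers, X, object$spec, training = FALSE)$out
  if (object$kind == "classification") {
    out <- .softmax(out)
    colnames(out) <- object$classes
  } else colnames(out) <- object$param_names
  out
}
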