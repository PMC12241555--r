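#' Rejection ABC for model choice on network outputs
#'
#' Classic rejection ABC in the space of classifier outputs: for each
#' observed prediction the tolerance fraction of validation rows nearest in
#' Euclidean distance is kept, and the posterior model probabilities are the
#' label frequencies among the kept rows. With several observed replicates
#' the per-replicate posteriors are averaged.
#'
#' @param val_pred Matrix of network outputs for validation rows.
#' @param val_labels Model labels (factor/character) for the same rows.
#' @param obs_pred Matrix (or vector) of observed network outputs, one row
#'   per observed cSFS replicate.
#' @param tolerance Accepted fraction in `(0, 1]` (default 0.05).
#' @return An object of class `model_posterior` with `prob` (simplex over
#'   the model labels), `n_accepted` and `tolerance`.
#' @export
abc_model_choice <- function(val_pred, val_labels, obs_pred, tolerance = 0.05) {
  stopifnot(tolerance > 0, tolerance <= 1)
  val_pred <- as.matrix(val_pred)
  val_labels <- factor(val_labels)
  obs_pred <- rbind(obs_pred)
  stopifnot(nrow(val_pred) == length(val_labels), ncol(obs_pred) == ncol(val_pred))
  n_keep <- max(1L, ceiling(tolerance * nrow(val_pred)))
  if (n_keep < 1) stop("no rows accepted")
  if (n_keep < 10) warning("fewer than 10 accepted rows; posterior is unstable")
  probs <- vapply(seq_len(nrow(obs_pred)), function(r) {
    d <- sqrt(colSums((t(val_pred) - obs_pred[r, ])^2))
    keep <- order(d)[seq_len(n_keep)]
    tabulate(val_labels[keep], nbins = nlevels(val_labels)) / n_keep
  }, numeric(nlevels(val_labels)))
  prob <- rowMeans(probs)
  names(prob) <- levels(val_labels)
  structure(list(prob = prob, n_accepted = n_keep, tolerance = tolerance,
                 per_replicate = t(probs)),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("ABC model posterior (tolerance", x$tolerance, ",", x$n_accepted,
      "accepted):\n")
  print(round(x$prob, 4))
  invisible(x)
}

#' Bayes factor between two models
#'
#' Ratio of posterior model probabilities under equal model priors.
#'
#' @param post A `model_posterior`.
#' @param m1,m2 Model labels.
#' @return Numeric Bayes factor; `Inf` (with a warning) when `P(m2) = 0`.
#' @export
bayes_factor <- function(post, m1, m2) {
  stopifnot(inherits(post, "model_posterior"),
            m1 %in% names(post$prob), m2 %in% names(post$prob))
  p1 <- post$prob[[m1]]; p2 <- post$prob[[m2]]
  if (p2 == 0) {
    warning("P(", m2, ") = 0: Bayes factor is infinite")
    return(Inf)
  }
  p1 / p2
}

# mean distance from each row of `x` to its `k` nearest rows of `ref`
.nn_stat <- function(x, ref, k) {
  x <- rbind(x)
  vapply(seq_len(nrow(x)), function(r) {
    d <- sqrt(colSums((t(ref) - x[r, ])^2))
    mean(sort(d)[seq_len(k)])
  }, numeric(1))
}

#' Goodness-of-fit p-value for the chosen model
#'
#' Nearest-neighbor distance test: the statistic is the mean distance from a
#' prediction to its nearest accepted (tolerance-fraction) neighbors among
#' model-simulated predictions. The null distribution is built from held-out
#' model-simulated rows; the p-value is the fraction of null statistics at
#' least as large as the observed one.
#'
#' @param val_pred Network outputs for rows simulated under the chosen model.
#' @param obs_pred Observed network output (one row, or several averaged).
#' @param n_null Held-out rows used for the null (>= 100).
#' @param tolerance Accepted fraction defining the neighborhood size.
#' @param seed Optional seed for the held-out split.
#' @return List with `p_value`, `observed_stat`, `null_stats`.
#' @export
goodness_of_fit <- function(val_pred, obs_pred, n_null = 100, tolerance = 0.05,
                            seed = NULL) {
  val_pred <- as.matrix(val_pred)
  if (n_null < 100) warning("n_null < 100: p-value resolution is coarse")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(val_pred)
  stopifnot(n_null < n)
  null_idx <- sample.int(n, n_null)
  pool <- val_pred[-null_idx, , drop = FALSE]
  k <- max(1L, ceiling(tolerance * nrow(pool)))
  null_stats <- .nn_stat(val_pred[null_idx, , drop = FALSE], pool, k)
  obs_stat <- mean(.nn_stat(obs_pred, pool, k))
  list(p_value = mean(null_stats >= obs_stat), observed_stat = obs_stat,
       null_stats = null_stats)
}

#' Rejection ABC for parameter estimation on network outputs
#'
#' The tolerance fraction of validation rows nearest to the observed network
#' output is kept; the accepted rows' TRUE generating parameters form the
#' posterior sample. Point estimates are posterior medians; intervals are
#' 2.5/97.5 percentiles. With several observed replicates, per-replicate
#' estimates are combined by the median and accepted draws are pooled.
#'
#' @param val_pred Regression-network outputs for validation rows (scaled
#'   units).
#' @param val_params Matrix of the same rows' true parameters in original
#'   units.
#' @param obs_pred Observed network output(s), one row per replicate.
#' @param tolerance Accepted fraction in `(0, 1]`.
#' @return An object of class `param_posterior` with `point` (median),
#'   `ci` (2 x p matrix of 95% bounds), `accepted` (pooled draws),
#'   `per_replicate` point estimates, `tolerance`.
#' @export
abc_parameters <- function(val_pred, val_params, obs_pred, tolerance = 0.05) {
  stopifnot(tolerance > 0, tolerance <= 1)
  val_pred <- as.matrix(val_pred)
  val_params <- as.matrix(val_params)
  obs_pred <- rbind(obs_pred)
  stopifnot(nrow(val_pred) == nrow(val_params))
  n_keep <- max(1L, ceiling(tolerance * nrow(val_pred)))
  if (n_keep < 10) warning("fewer than 10 accepted rows; posterior is unstable")
  acc <- vector("list", nrow(obs_pred))
  pts <- matrix(NA_real_, nrow(obs_pred), ncol(val_params),
                dimnames = list(NULL, colnames(val_params)))
  for (r in seq_len(nrow(obs_pred))) {
    d <- sqrt(colSums((t(val_pred) - obs_pred[r, ])^2))
    keep <- order(d)[seq_len(n_keep)]
    acc[[r]] <- val_params[keep, , drop = FALSE]
    pts[r, ] <- apply(acc[[r]], 2, median)
  }
  pooled <- do.call(rbind, acc)
  point <- apply(pts, 2, median)
  ci <- apply(pooled, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  rownames(ci) <- c("2.5%", "97.5%")
  structure(list(point = point, ci = ci, accepted = pooled,
                 per_replicate = pts, tolerance = tolerance,
                 n_accepted = n_keep),
            class = "param_posterior")
}

#' @export
print.param_posterior <- function(x, ...) {
  cat("ABC parameter posterior (tolerance", x$tolerance, ",",
      nrow(x$accepted), "pooled draws):\n")
  print(round(rbind(point = x$point, x$ci), 4))
  invisible(x)
}
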