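#' Sequence-length schedule for SMC
#'
#' The canonical schedule is 100 Mb, 500 Mb, 1.5 Gb, 3 Gb per sample,
#' multiplied by a global scale factor for desk-scale runs.
#'
#' @param lengths Increasing vector of sequence lengths in bases.
#' @param scale Global scale factor applied to every length.
#' @return Numeric vector of class `length_schedule`.
#' @export
length_schedule <- function(lengths = c(100e6, 500e6, 1.5e9, 3e9), scale = 1) {
  lengths <- lengths * scale
  if (any(diff(lengths) <= 0)) stop("schedule lengths must be strictly increasing")
  structure(lengths, class = "length_schedule")
}

#' SMC state
#'
#' @param box Current `prior_box`.
#' @param seq_length Current sequence length (bases).
#' @return An object of class `smc_state` tracking the cycle index, the
#'   current box and length, per-cycle shrinkage ratios and point-estimate
#'   history.
#' @export
smc_state <- function(box, seq_length) {
  stopifnot(inherits(box, "prior_box"), seq_length > 0)
  structure(list(cycle = 0L, box = box, seq_length = seq_length,
                 shrinkage = list(), estimates = list(), boxes = list(box)),
            class = "smc_state")
}

#' Draw parameter vectors from a box, rejecting invalid event orderings
#'
#' Draws are uniform in the box; rows whose event chains violate the model's
#' ordering constraints (so [build_demography()] would reject them) are
#' redrawn, i.e. the effective prior is the uniform law truncated to valid
#' orderings.
#'
#' @param box A `prior_box`.
#' @param n Number of valid draws required.
#' @param spec A [model_spec()].
#' @param constants A [sim_constants()].
#' @param max_tries Resampling cap.
#' @return Matrix of `n` valid parameter rows.
#' @export
sample_valid_params <- function(box, n, spec, constants = sim_constants(),
                                max_tries = 50L) {
  out <- matrix(numeric(0), 0, length(box$lower),
                dimnames = list(NULL, names(box$lower)))
  for (i in seq_len(max_tries)) {
    need <- n - nrow(out)
    if (need <= 0) break
    cand <- sample_prior(box, need)
    ok <- vapply(seq_len(nrow(cand)), function(r) {
      !inherits(try(build_demography(spec, cand[r, ], constants), silent = TRUE),
                "try-error")
    }, logical(1))
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  if (nrow(out) < n) stop("could not draw ", n, " valid parameter vectors")
  out[seq_len(n), , drop = FALSE]
}

#' cSFS simulator closure for SMC
#'
#' Returns a function `(params_matrix, seq_length) -> feature matrix` that
#' simulates one cSFS row per parameter vector under the given model.
#'
#' @param spec A [model_spec()].
#' @param samples A [sample_config()] (canonical: 5 diploids per modern
#'   population, 1 per archaic).
#' @param constants A [sim_constants()].
#' @param chunk_length Locus length in bases.
#' @return A simulator function.
#' @export
csfs_simulator <- function(spec, samples = canonical_sample_config(),
                           constants = sim_constants(), chunk_length = 1e5) {
  force(spec); force(samples); force(constants); force(chunk_length)
  function(params, seq_length) {
    t(vapply(seq_len(nrow(params)), function(r) {
      g <- build_demography(spec, params[r, ], constants)
      as.numeric(csfs(simulate_joint_sfs(g, samples, seq_length, chunk_length)))
    }, numeric(csfs_length(samples))))
  }
}

#' Length of the cSFS vector for a sample configuration
#'
#' @param samples A [sample_config()].
#' @return Integer vector length (999 for the canonical configuration).
#' @export
csfs_length <- function(samples) {
  d <- 2 * samples$counts[samples$counts > 0] + 1
  pr <- utils::combn(length(d), 2)
  sum(d[pr[1, ]] * d[pr[2, ]])
}

#' One SMC cycle: simulate, train, ABC, shrink the box
#'
#' Draws `n_sims` parameter vectors from the current box, simulates their
#' summaries at the current sequence length, trains a fresh regression
#' network (half train / half validation), runs rejection ABC against the
#' observed replicates, and sets the next box to the pooled posterior
#' 2.5--97.5 percentile range intersected with the current box.
#'
#' @param state An [smc_state()].
#' @param observed Matrix of observed cSFS replicates (one per row).
#' @param obs_length Callable length the observed rows were computed at
#'   (rows are rescaled to the cycle's sequence length).
#' @param n_sims Simulations this cycle (canonical 20,000; desk >= 200).
#' @param simulator Function `(params, seq_length) -> features`, e.g. from
#'   [csfs_simulator()].
#' @param spec A [model_spec()] (for draw validation; ignored when
#'   `validate = FALSE`).
#' @param net A [net_spec()].
#' @param tolerance ABC accepted fraction.
#' @param seed Integer seed for the cycle.
#' @param validate Reject draws with invalid event orderings (disable for
#'   toy simulators whose parameters are not demographic).
#' @return Updated `smc_state`; the cycle's `param_posterior` is appended to
#'   `state$estimates`.
#' @export
smc_cycle <- function(state, observed, obs_length, n_sims, simulator,
                      spec = model_spec("A"), net = net_spec(),
                      tolerance = 0.05, seed = 1L, validate = TRUE) {
  stopifnot(inherits(state, "smc_state"), n_sims >= 200)
  set.seed(seed)
  params <- if (validate) sample_valid_params(state$box, n_sims, spec)
            else sample_prior(state$box, n_sims)
  feats <- simulator(params, state$seq_length)
  tab <- reference_table(feats, params, box = state$box, frac_train = 0.5)
  fit <- train_network(tab, net, seed = seed)
  val_pred <- predict(fit, tab$x[tab$val_idx, , drop = FALSE])
  obs <- rbind(observed)
  if (!is.null(obs_length) && obs_length != state$seq_length)
    obs <- rescale_csfs(obs, obs_length, state$seq_length)
  obs_pred <- predict(fit, obs)
  post <- abc_parameters(val_pred, tab$y[tab$val_idx, , drop = FALSE],
                         obs_pred, tolerance)
  new_lo <- pmax(state$box$lower, post$ci[1, names(state$box$lower)])
  new_hi <- pmin(state$box$upper, post$ci[2, names(state$box$lower)])
  width_old <- state$box$upper - state$box$lower
  if (any(new_hi - new_lo <= 0 & width_old > 0))
    stop("degenerate posterior: a parameter's box collapsed to zero width")
  shrink <- ifelse(width_old > 0, (new_hi - new_lo) / width_old, 1)
  state$box <- prior_box(new_lo, new_hi)
  state$cycle <- state$cycle + 1L
  state$shrinkage[[state$cycle]] <- shrink
  state$estimates[[state$cycle]] <- post
  state$boxes[[state$cycle + 1L]] <- state$box
  state
}

#' Run the full SMC loop over a length schedule
#'
#' Cycles at each schedule length until converged (geometric mean of the
#' per-parameter shrinkage ratios at least `conv_threshold` for
#' `conv_consecutive` consecutive cycles; a threshold >= 1 runs exactly one
#' cycle per length), then advances to the next length.
#'
#' @inheritParams smc_cycle
#' @param box Initial `prior_box`.
#' @param schedule A [length_schedule()].
#' @param conv_threshold Shrinkage geometric-mean threshold (default 0.95).
#' @param conv_consecutive Consecutive qualifying cycles required.
#' @param max_cycles_per_length Cap per length (warning + best-so-far).
#' @return List with `posterior` (final cycle's `param_posterior`), `state`
#'   (full trace) and `point` (final point estimates).
#' @export
run_smc <- function(box, observed, obs_length, schedule, simulator,
                    spec = model_spec("A"), net = net_spec(), n_sims = 1000,
                    tolerance = 0.05, conv_threshold = 0.95,
                    conv_consecutive = 2, max_cycles_per_length = 8,
                    seed = 1L, validate = TRUE) {
  stopifnot(length(schedule) >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(2^30, length(schedule) * max_cycles_per_length)
  state <- smc_state(box, schedule[1])
  k <- 0L
  for (len in schedule) {
    state$seq_length <- len
    if (conv_threshold >= 1) {
      k <- k + 1L
      state <- smc_cycle(state, observed, obs_length, n_sims, simulator, spec,
                         net, tolerance, seed = sub_seeds[k], validate = validate)
      next
    }
    streak <- 0L
    for (cyc in seq_len(max_cycles_per_length)) {
      k <- k + 1L
      state <- smc_cycle(state, observed, obs_length, n_sims, simulator, spec,
                         net, tolerance, seed = sub_seeds[k], validate = validate)
      g <- exp(mean(log(pmax(state$shrinkage[[state$cycle]], 1e-12))))
      streak <- if (g >= conv_threshold) streak + 1L else 0L
      if (streak >= conv_consecutive) break
      if (cyc == max_cycles_per_length)
        warning("max cycles reached at length ", len, "; continuing with best so far")
    }
  }
  post <- state$estimates[[state$cycle]]
  list(posterior = post, state = state, point = post$point)
}
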