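#' Default RCCR time bins
#'
#' @param n Number of bins (default 30, log-spaced).
#' @param from,to Bin range in years ago.
#' @return Numeric vector of `n + 1` increasing bin edges (years ago).
#' @export
default_time_bins <- function(n = 30, from = 1e3, to = 2e6) {
  exp(seq(log(from), log(to), length.out = n + 1))
}

# per-node pair-coalescence counts for two sample subsets across trees
.pair_events <- function(gs, in_a, in_b) {
  n <- length(gs$hap_label)
  out <- lapply(gs$trees, function(tr) {
    par <- tr$parent + 1L  # 1-based; root has 0
    m <- length(par)
    na <- numeric(m); nb <- numeric(m)
    na[seq_len(n)] <- as.numeric(in_a)
    nb[seq_len(n)] <- as.numeric(in_b)
    # two children per internal node; nodes are in increasing-time order
    kids <- which(par > 0L)
    o <- kids[order(par[kids])]
    c1 <- o[seq(1, length(o), by = 2)]
    c2 <- o[seq(2, length(o), by = 2)]
    pj <- par[c1]
    for (i in seq_along(c1)) {  # accumulate leaf counts upward
      na[pj[i]] <- na[c1[i]] + na[c2[i]]
      nb[pj[i]] <- nb[c1[i]] + nb[c2[i]]
    }
    data.frame(t = tr$time[pj],
               w_a = na[c1] * na[c2],
               w_b = nb[c1] * nb[c2],
               w_x = na[c1] * nb[c2] + na[c2] * nb[c1])
  })
  do.call(rbind, out)
}

.hazard <- function(t, w, bins_gen) {
  nb <- length(bins_gen) - 1L
  coal <- numeric(nb); risk <- numeric(nb)
  for (k in seq_len(nb)) {
    b1 <- bins_gen[k]; b2 <- bins_gen[k + 1]
    coal[k] <- sum(w[t >= b1 & t < b2])
    risk[k] <- sum(w * pmax(0, pmin(t, b2) - b1))
  }
  lam <- ifelse(risk > 0, coal / risk, 0)
  list(lambda = lam, coal = coal, risk = risk)
}

#' Time-binned pair-coalescence rates from genealogies
#'
#' The hazard in a bin is the number of pair coalescences in the bin divided
#' by the pair-generations at risk in the bin, pooled over all genealogies
#' (a pair is at risk from the present until its own coalescence). With two
#' populations, within-population hazards `lambda0`/`lambda1` and the
#' cross-population hazard `lambda01` are returned together.
#'
#' @param gs A `genealogy_set` from [simulate_trees()].
#' @param pop_a,pop_b Population labels (`pop_b = NULL` for single-population
#'   rates).
#' @param bins_years Bin edges in years ago.
#' @param haps_a,haps_b Optional haplotype index subsets (within each
#'   population's haplotypes) for resampling.
#' @return Object of class `rate_curve`: data frame with bin edges (years),
#'   hazards per generation, and coalescence/risk counts per bin; bins with
#'   zero risk carry hazard 0 and `low_count = TRUE`.
#' @export
coalescence_rates <- function(gs, pop_a, pop_b = NULL,
                              bins_years = default_time_bins(),
                              haps_a = NULL, haps_b = NULL) {
  stopifnot(inherits(gs, "genealogy_set"))
  lab <- gs$hap_label
  pick <- function(pop, keep) {
    sel <- which(lab == pop)
    if (length(sel) < 2) stop("need at least 2 haplotypes in ", pop)
    if (!is.null(keep)) sel <- sel[keep]
    seq_along(lab) %in% sel
  }
  in_a <- pick(pop_a, haps_a)
  in_b <- if (is.null(pop_b)) rep(FALSE, length(lab)) else pick(pop_b, haps_b)
  ev <- .pair_events(gs, in_a, in_b)
  bins_gen <- bins_years / gs$generation_time
  ha <- .hazard(ev$t, ev$w_a, bins_gen)
  out <- data.frame(bin_lo = bins_years[-length(bins_years)],
                    bin_hi = bins_years[-1],
                    lambda0 = ha$lambda, coal0 = ha$coal, risk0 = ha$risk)
  if (!is.null(pop_b)) {
    hb <- .hazard(ev$t, ev$w_b, bins_gen)
    hx <- .hazard(ev$t, ev$w_x, bins_gen)
    out$lambda1 <- hb$lambda; out$coal1 <- hb$coal; out$risk1 <- hb$risk
    out$lambda01 <- hx$lambda; out$coal01 <- hx$coal; out$risk01 <- hx$risk
  }
  out$low_count <- out$risk0 == 0
  structure(out, class = c("rate_curve", "data.frame"),
            pops = c(pop_a, pop_b))
}

#' Relative cross-coalescent rate curve
#'
#' `RCCR = 2 * lambda01 / (lambda0 + lambda1)` per bin: about 1 for a single
#' exchangeable population and tending to 0 after complete isolation.
#'
#' @param within_a A `rate_curve`; if it already carries `lambda1` and
#'   `lambda01` (two-population call), the other arguments are not needed.
#' @param within_b,cross Optional single-population / cross `rate_curve`s on
#'   identical bins.
#' @return Object of class `rccr_curve`: data frame with bin edges, `rccr`,
#'   and an `undefined` flag for bins with `lambda0 + lambda1 = 0`.
#' @export
rccr_curve <- function(within_a, within_b = NULL, cross = NULL) {
  if (!is.null(within_b)) {
    same_bins <- identical(within_a$bin_lo, within_b$bin_lo) &&
      identical(within_a$bin_lo, cross$bin_lo)
    if (!same_bins) stop("bin mismatch between rate curves")
    l0 <- within_a$lambda0; l1 <- within_b$lambda0; lx <- cross$lambda0
  } else {
    if (is.null(within_a$lambda01)) stop("need cross-population rates")
    l0 <- within_a$lambda0; l1 <- within_a$lambda1; lx <- within_a$lambda01
  }
  den <- l0 + l1
  out <- data.frame(bin_lo = within_a$bin_lo, bin_hi = within_a$bin_hi,
                    rccr = ifelse(den > 0, 2 * lx / den, NA_real_),
                    undefined = den == 0)
  structure(out, class = c("rccr_curve", "data.frame"))
}

#' RCCR value at a time point
#'
#' @param curve An `rccr_curve` (or a matrix-like with `bin_lo`, `bin_hi`).
#' @param years Time in years ago; the containing bin's value is returned.
#' @param column Column to extract (default `"rccr"`).
#' @return The bin value at `years`.
#' @export
rccr_at <- function(curve, years, column = "rccr") {
  k <- which(curve$bin_lo <= years & curve$bin_hi > years)
  if (!length(k)) stop("time outside the binned range")
  curve[[column]][k[1]]
}

#' RCCR curve with a resampling confidence band
#'
#' Repeats the RCCR computation over `repetitions` random draws of
#' `n_per_pop` diploids per population (mirroring repeated random sampling
#' of individuals) and reports the mean curve with a mean +- 2 sd band.
#'
#' @param gs A `genealogy_set` whose populations contain at least
#'   `n_per_pop` diploids each.
#' @param pop_a,pop_b Population labels.
#' @param n_per_pop Diploids drawn per repetition.
#' @param repetitions Number of random draws (>= 2; default 10).
#' @param bins_years Bin edges in years ago.
#' @param seed Optional seed.
#' @return Data frame with `bin_lo`, `bin_hi`, `rccr` (mean), `lo`, `hi`
#'   (mean -+ 2 sd) and the per-repetition matrix in attribute `"reps"`.
#' @export
rccr_band <- function(gs, pop_a, pop_b, n_per_pop, repetitions = 10,
                      bins_years = default_time_bins(), seed = NULL) {
  stopifnot(repetitions >= 2)
  if (!is.null(seed)) set.seed(seed)
  lab <- gs$hap_label
  avail_a <- sum(lab == pop_a) / 2
  avail_b <- sum(lab == pop_b) / 2
  stopifnot(n_per_pop <= avail_a, n_per_pop <= avail_b)
  reps <- vapply(seq_len(repetitions), function(r) {
    da <- sample.int(avail_a, n_per_pop)
    db <- sample.int(avail_b, n_per_pop)
    ha <- as.vector(rbind(2 * da - 1, 2 * da))
    hb <- as.vector(rbind(2 * db - 1, 2 * db))
    rc <- coalescence_rates(gs, pop_a, pop_b, bins_years, ha, hb)
    rccr_curve(rc)$rccr
  }, numeric(length(bins_years) - 1))
  m <- rowMeans(reps, na.rm = TRUE)
  s <- apply(reps, 1, stats::sd, na.rm = TRUE)
  out <- data.frame(bin_lo = bins_years[-length(bins_years)],
                    bin_hi = bins_years[-1],
                    rccr = m, lo = m - 2 * s, hi = m + 2 * s)
  attr(out, "reps") <- reps
  out
}

#' RCCR curves over a grid of minimal out-of-Africa models
#'
#' Simulates genealogies for each (bottleneck, growth, African-split)
#' combination and computes the PNG-AFR RCCR curve with a resampling band.
#' Marginal trees are sampled every `tree_spacing` bases.
#'
#' @param grid List of [minimal_model_spec()] objects (or a data frame with
#'   columns `png_bottleneck_size`, `png_growth_rate`, `african_split_kya`).
#' @param n_per_pop Diploids per population per repetition (canonical 40).
#' @param n_total_dip Diploids simulated per population (>= `n_per_pop`).
#' @param seq_length Sequence length in bases.
#' @param repetitions Resampling repetitions for the band.
#' @param seed Base seed; grid point `i` uses `seed + i` (paired across
#'   grids run with the same seed).
#' @param tree_spacing Genomic spacing between sampled trees (default 100 kb).
#' @param bins_years Bin edges in years ago.
#' @param constants A [sim_constants()].
#' @return List with one element per grid point: the spec, the band data
#'   frame, and the seed used.
#' @export
minimal_model_grid <- function(grid, n_per_pop = 40, n_total_dip = 40,
                               seq_length = 100e6, repetitions = 10, seed = 1L,
                               tree_spacing = 1e5,
                               bins_years = default_time_bins(),
                               constants = sim_constants()) {
  if (is.data.frame(grid))
    grid <- lapply(seq_len(nrow(grid)), function(i)
      minimal_model_spec(grid$png_bottleneck_size[i], grid$png_growth_rate[i],
                         grid$african_split_kya[i]))
  stopifnot(length(grid) >= 1, n_per_pop <= n_total_dip)
  n_loci <- max(2L, as.integer(round(seq_length / tree_spacing)))
  lapply(seq_along(grid), function(i) {
    ms <- grid[[i]]
    g <- build_minimal_demography(ms, constants)
    sc <- sample_config(c(AFR = n_total_dip, PNG = n_total_dip))
    gs <- simulate_trees(g, sc, n_loci, seed = seed + i)
    band <- rccr_band(gs, "PNG", "AFR", n_per_pop, repetitions, bins_years,
                      seed = seed + i)
    list(spec = ms, band = band, seed = seed + i)
  })
}
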