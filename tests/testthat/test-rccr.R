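test_that("constant-size hazard matches 1/(2N) within three standard errors", {
  # pair coalescences within a tree are correlated, so the standard error is
  # taken over independent blocks of trees rather than from Poisson counts
  N <- 1e4
  gs <- simulate_trees(constant_demography(N), sample_config(c(POP = 10)),
                       600, seed = 3)
  n_blocks <- 20
  block_lambda <- vapply(seq_len(n_blocks), function(b) {
    sub <- gs
    sub$trees <- gs$trees[seq((b - 1) * 30 + 1, b * 30)]
    rc <- coalescence_rates(sub, "POP")
    mid <- rc$bin_lo >= 2e4 & rc$bin_hi <= 5e5
    sum(rc$coal0[mid]) / sum(rc$risk0[mid])  # pooled mid-bin hazard
  }, numeric(1))
  se <- stats::sd(block_lambda) / sqrt(n_blocks)
  expect_lt(abs(mean(block_lambda) - 1 / (2 * N)), 3 * se + 1e-7)
  # per-bin hazards are also close on the pooled curve
  rc <- coalescence_rates(gs, "POP")
  mid <- rc[rc$bin_lo >= 2e4 & rc$bin_hi <= 5e5, ]
  expect_true(all(abs(mid$lambda0 - 1 / (2 * N)) / (1 / (2 * N)) < 0.25))
})

test_that("exchangeable labels give RCCR of one", {
  gs <- simulate_trees(constant_demography(1e4), sample_config(c(POP = 40)),
                       600, seed = 5)
  gs$hap_label <- rep(c("X", "Y"), each = 40)  # arbitrary split of one pop
  cc <- rccr_curve(coalescence_rates(gs, "X", "Y"))
  mid <- cc$rccr[cc$bin_lo >= 1e4 & cc$bin_hi <= 1e6]
  expect_true(all(abs(mid - 1) < 0.1))
})

test_that("a clean split yields zero recent cross-coalescence and a rising curve", {
  split_ky <- 50
  g <- clean_split_demography(1e4, split_ky)
  gs <- simulate_trees(g, sample_config(c(P0 = 20, P1 = 20)), 800, seed = 7)
  rc <- coalescence_rates(gs, "P0", "P1")
  expect_true(all(rc$lambda01[rc$bin_hi <= split_ky * 1000] == 0))
  cc <- rccr_curve(rc)
  expect_true(all(cc$rccr[cc$bin_hi <= 2.5e4] == 0, na.rm = TRUE))
  old <- cc$rccr[cc$bin_lo >= 4 * split_ky * 1000 & !is.na(cc$rccr)]
  expect_true(all(abs(old - 1) < 0.15))
  # the curve crosses one half within the bin containing the split (or its
  # log-scale neighbors)
  k <- which(cc$rccr >= 0.5)[1]
  expect_true(cc$bin_hi[k] > split_ky * 1000 / 2 &&
                cc$bin_lo[k] < split_ky * 1000 * 2)
})

test_that("rccr_curve arithmetic and bin checks", {
  rc <- data.frame(bin_lo = c(0, 10), bin_hi = c(10, 20), lambda0 = c(2, 0))
  ra <- structure(rc, class = c("rate_curve", "data.frame"))
  rb <- ra; rx <- ra
  cc <- rccr_curve(ra, rb, rx)  # lambda0 = lambda1 = lambda01
  expect_equal(cc$rccr[1], 1)
  expect_true(cc$undefined[2])
  rb2 <- rb; rb2$bin_lo <- rb2$bin_lo + 1
  expect_error(rccr_curve(ra, rb2, rx), "bin mismatch")
})

test_that("rccr_at picks the containing bin", {
  cc <- data.frame(bin_lo = c(1e3, 1e4), bin_hi = c(1e4, 1e5),
                   rccr = c(0.2, 0.8))
  expect_equal(rccr_at(cc, 5e4), 0.8)
  expect_error(rccr_at(cc, 1e6), "outside")
})

test_that("bands need at least two repetitions and grids are deterministic", {
  expect_error(rccr_band(NULL, "A", "B", 2, repetitions = 1))
  grid <- list(minimal_model_spec(500, 0, 80))
  r1 <- minimal_model_grid(grid, n_per_pop = 5, n_total_dip = 5,
                           seq_length = 2e6, repetitions = 3, seed = 42)
  r2 <- minimal_model_grid(grid, n_per_pop = 5, n_total_dip = 5,
                           seq_length = 2e6, repetitions = 3, seed = 42)
  expect_equal(r1[[1]]$band, r2[[1]]$band)
  expect_true(all(c("rccr", "lo", "hi") %in% names(r1[[1]]$band)))
})

test_that("minimal model spec enforces its bounds", {
  expect_error(minimal_model_spec(100, 0, 80))
  expect_error(minimal_model_spec(500, 0.01, 80))
  expect_error(minimal_model_spec(500, 0, 120))
  ms <- minimal_model_spec(1000, 0.001, 300)
  g <- build_minimal_demography(ms)
  expect_equal(g$pop_names, c("AFR", "EUR", "PNG", "OOA"))
  # OOA merges into AFR at the San-like split time
  t_afr <- max(g$events[, 1])
  expect_equal(t_afr * g$constants$generation_time / 1000, 300, tolerance = 1e-9)
})
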