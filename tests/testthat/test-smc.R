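test_that("one identity-toy cycle halves the box and stays nested", {
  box <- toy_box(3)
  truth <- setNames(rep(5, 3), names(box$lower))
  set.seed(1)
  obs <- rbind(truth, truth, truth)
  st <- smc_state(box, 1e6)
  st <- smc_cycle(st, obs, NULL, 600, identity_simulator(0.05),
                  net = net_spec(max_epochs = 120, stop_patience = 25),
                  seed = 2, validate = FALSE)
  expect_true(all(st$box$lower >= box$lower & st$box$upper <= box$upper))
  g <- exp(mean(log(st$shrinkage[[1]])))
  expect_lte(g, 0.5)
  expect_true(all(truth >= st$box$lower & truth <= st$box$upper))
})

test_that("a convergence threshold of one runs one cycle per length", {
  box <- toy_box(2)
  set.seed(3)
  obs <- rbind(setNames(c(4, 6), names(box$lower)))
  res <- run_smc(box, obs, NULL, length_schedule(c(1e6, 2e6)),
                 identity_simulator(0.1),
                 net = net_spec(max_epochs = 20, stop_patience = 8),
                 n_sims = 400, conv_threshold = 1, seed = 4, validate = FALSE)
  expect_equal(res$state$cycle, 2L)
})

test_that("the identity toy recovers the truth within 5%", {
  box <- toy_box(3)
  truth <- setNames(c(3, 5, 7), names(box$lower))
  set.seed(5)
  obs <- rbind(truth + rnorm(3, 0, 0.05), truth + rnorm(3, 0, 0.05),
               truth + rnorm(3, 0, 0.05))
  res <- suppressWarnings(run_smc(
    box, obs, NULL, length_schedule(c(1e6, 2e6)), identity_simulator(0.05),
    net = net_spec(max_epochs = 100, stop_patience = 20), n_sims = 500,
    max_cycles_per_length = 2, seed = 6, validate = FALSE))
  expect_true(all(abs(res$point - truth) / truth < 0.05))
  # monotone refinement: per-parameter widths never increase
  widths <- vapply(res$state$boxes, function(b) b$upper - b$lower,
                   numeric(3))
  expect_true(all(apply(widths, 1, function(w) all(diff(w) <= 1e-12))))
})

test_that("the truth stays inside the box across seeds and cycles", {
  box <- toy_box(2)
  truth <- setNames(c(4, 6), names(box$lower))
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    set.seed(100 + s)
    obs <- rbind(truth + rnorm(2, 0, 0.05))
    st <- smc_state(box, 1e6)
    for (cyc in 1:2) {
      st <- smc_cycle(st, obs, NULL, 400, identity_simulator(0.05),
                      net = net_spec(max_epochs = 60, stop_patience = 15),
                      seed = 1000 * s + cyc, validate = FALSE)
      hits <- hits + all(truth >= st$box$lower & truth <= st$box$upper)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("cycle preconditions and schedules are enforced", {
  box <- toy_box(2)
  st <- smc_state(box, 1e6)
  expect_error(smc_cycle(st, rbind(c(1, 1)), NULL, 50, identity_simulator(),
                         validate = FALSE))
  expect_error(length_schedule(c(2e6, 1e6)), "strictly increasing")
  expect_error(smc_state(box, -1))
})

test_that("observed summaries are rescaled to the cycle's sequence length", {
  # simulator whose features scale with length, like raw cSFS counts
  sim <- function(params, seq_length)
    params * seq_length / 1e6 + matrix(rnorm(length(params), 0, 0.01), nrow(params))
  box <- toy_box(2)
  truth <- setNames(c(4, 6), names(box$lower))
  set.seed(7)
  obs <- rbind(truth * 4)  # generated at 4 Mb
  st <- smc_state(box, 1e6)
  st <- smc_cycle(st, obs, 4e6, 400, sim,
                  net = net_spec(max_epochs = 60, stop_patience = 15),
                  seed = 8, validate = FALSE)
  pt <- st$estimates[[1]]$point
  expect_true(all(abs(pt - truth) / truth < 0.2))
})
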