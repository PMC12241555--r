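test_that("resolve_events chains intervals into the published event times", {
  ev <- resolve_events(best_fit_params())
  expect_equal(ev[["T_AS_PA"]], 46.2, tolerance = 1e-9)
  expect_equal(ev[["T_EU_AS"]], 51.2, tolerance = 1e-9)
  # full printed events column, +-0.15 ky rounding slack
  printed <- c(T_DPM = 31.3, T_AS_PA = 46.2, T_EU_AS = 51.2, T_NOM = 52,
               T_B = 62.4, T_AF = 105.6, T_NI_NS = 252.6, T_DI_DS = 307.4,
               T_N_D = 321.6, T_H_A = 591.5)
  expect_true(all(abs(ev[names(printed)] - printed) <= 0.15))
})

test_that("degenerate and invalid interval chains are handled", {
  p <- unclass(best_fit_params())
  p[grep("^T_", names(p))] <- 0
  ev <- resolve_events(param_vector(p, spec = model_spec("A")))
  expect_true(all(ev == 0))
  p["T_B"] <- -1
  expect_error(param_vector(p, spec = model_spec("A")), "non-negative")
})

test_that("event times strictly increase along each chain", {
  set.seed(42)
  box <- default_priors(model_spec("A"))
  draws <- sample_prior(box, 50)
  for (r in seq_len(nrow(draws))) {
    ev <- resolve_events(param_vector(draws[r, ], spec = model_spec("A")))
    expect_true(all(diff(ev[c("T_DPM", "T_AS_PA", "T_EU_AS", "T_NOM",
                               "T_B", "T_AF")]) > 0))
    expect_true(ev[["T_NI_NS"]] > ev[["T_NOM"]])
    expect_true(all(diff(ev[c("T_DI_DS", "T_N_D", "T_H_A")]) > 0))
    expect_true(all(ev >= 0))
  }
})

test_that("default priors contain the best-fit values and use stated bounds", {
  for (mid in c("A", "O")) {
    box <- default_priors(model_spec(mid))
    p <- unclass(best_fit_params())
    expect_true(all(box$lower[names(p)] <= p & p <= box$upper[names(p)]),
                label = paste("containment for model", mid))
  }
  box <- default_priors(model_spec("A"))
  expect_equal(unname(box$lower[c("NEA_m_OOA", "DEN_m_PAP")]), c(0.01, 0.01))
  expect_equal(unname(box$upper[c("NEA_m_OOA", "DEN_m_PAP")]), c(0.05, 0.05))
  expect_equal(unname(c(box$lower["T_AS_PA"], box$upper["T_AS_PA"])), c(0.5, 50))
  expect_equal(unname(c(box$lower["T_DPM"], box$upper["T_DPM"])), c(10, 100))
  bx <- default_priors(model_spec("AX"))
  expect_equal(unname(c(bx$lower["ghost_m"], bx$upper["ghost_m"])), c(0.01, 0.99))
})

test_that("prior sampling is uniform, in-box and reproducible", {
  box <- default_priors(model_spec("A"))
  expect_equal(nrow(sample_prior(box, 0)), 0)
  d <- sample_prior(box, 1000, seed = 7)
  expect_true(all(d[, "NEA_m_OOA"] >= 0.01 & d[, "NEA_m_OOA"] <= 0.05))
  expect_true(all(sweep(d, 2, box$lower, `>=`) & sweep(d, 2, box$upper, `<=`)))
  expect_identical(sample_prior(box, 10, seed = 3), sample_prior(box, 10, seed = 3))
  # Kolmogorov-Smirnov distance to the uniform law, a few parameters
  d <- sample_prior(box, 5000, seed = 11)
  for (nm in c("N_PA", "T_DPM", "DEN_m_PAP")) {
    u <- (d[, nm] - box$lower[nm]) / (box$upper[nm] - box$lower[nm])
    ks <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u)))
    expect_lt(ks, 0.05)
  }
  expect_error(prior_box(c(a = 2), c(a = 1)), "empty prior box")
})

test_that("build_demography encodes the model topology", {
  gA <- build_demography(model_spec("A"), best_fit_params())
  gO <- build_demography(model_spec("O"), best_fit_params())
  splits <- function(g) g$events[g$events[, 2] == 0, , drop = FALSE]
  # model A: PNG merges at the younger modern split
  sA <- splits(gA)
  png_id <- match("PNG", gA$pop_names) - 1
  eur_id <- match("EUR", gA$pop_names) - 1
  t_png_A <- min(sA[sA[, 3] == png_id, 1])
  t_eur_A <- min(sA[sA[, 3] == eur_id, 1])
  expect_lt(t_png_A, t_eur_A)
  # model O: EUR-ASN split younger than the PNG split
  sO <- splits(gO)
  t_png_O <- min(sO[sO[, 3] == png_id, 1])
  t_eur_O <- min(sO[sO[, 3] == eur_id, 1])
  expect_lt(t_eur_O, t_png_O)
  # ghost pulse present iff ghost model
  expect_false("GHOST" %in% gA$pop_names)
  pAX <- param_vector(c(unclass(best_fit_params()), ghost_m = 0.2, ghost_tf = 0.5),
                      spec = model_spec("AX"))
  gAX <- build_demography(model_spec("AX"), pAX)
  expect_true("GHOST" %in% gAX$pop_names)
})

test_that("draws violating event ordering are rejected", {
  p <- unclass(best_fit_params())
  p["T_NI_NS"] <- 400; p["T_DI_DS"] <- 0.5; p["T_N_D"] <- 0.5
  expect_error(build_demography(model_spec("A"), param_vector(p, spec = model_spec("A"))),
               "archaic event chain")
  p <- unclass(best_fit_params())
  # keep the archaic chain ordered but make the Denisovan branch younger
  # than its 60 ky sampling age
  p["T_DI_DS"] <- 20; p["T_NI_NS"] <- 5; p["T_N_D"] <- 10
  expect_error(build_demography(model_spec("A"), param_vector(p, spec = model_spec("A"))),
               "sampling age")
})

test_that("migration variants add bounded symmetric rate parameters", {
  sp <- model_spec("A", migration_variant = "low")
  expect_equal(length(param_names(sp)), 30)
  box <- default_priors(sp)
  expect_true(all(box$upper[grep("^m_", names(box$upper))] == 5e-5))
  p <- c(unclass(best_fit_params()),
         setNames(rep(2e-5, 6), grep("^m_", param_names(sp), value = TRUE)))
  g <- build_demography(sp, param_vector(p, spec = sp))
  expect_equal(nrow(g$mig), 12)  # 6 pairs, both directions
  expect_true(all(g$mig[, 3] == 2e-5))
})

test_that("AFR-conditioned sharing separates the A and O topologies", {
  sc <- canonical_sample_config()
  jsA <- simulate_joint_sfs(build_demography(model_spec("A"), best_fit_params()),
                            sc, 2e8, 1e5, seed = 77)
  jsO <- simulate_joint_sfs(build_demography(model_spec("O"), best_fit_params()),
                            sc, 2e8, 1e5, seed = 77)
  expect_gt(ooa_sharing(jsA, "ASN", "PNG") / ooa_sharing(jsA, "EUR", "PNG"), 1)
  expect_lt(ooa_sharing(jsO, "ASN", "PNG") / ooa_sharing(jsO, "EUR", "PNG"), 1)
})

test_that("model AX with zero ghost admixture matches model A site patterns", {
  sc <- canonical_sample_config()
  pAX <- param_vector(c(unclass(best_fit_params()), ghost_m = 0, ghost_tf = 0.5),
                      spec = model_spec("AX"))
  vA <- csfs(simulate_joint_sfs(build_demography(model_spec("A"), best_fit_params()),
                                sc, 1e8, 1e5, seed = 31))
  vX <- csfs(simulate_joint_sfs(build_demography(model_spec("AX"), pAX),
                                sc, 1e8, 1e5, seed = 32))
  keep <- setdiff(seq_along(vA), attr(vA, "layout")$offset + 1)
  expect_gt(cosine(vA[keep], vX[keep]), 0.995)
  expect_lt(abs(sum(vX[keep]) / sum(vA[keep]) - 1), 0.05)
})
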