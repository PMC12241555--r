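test_that("same plan and seed reproduce identical chunks", {
  g <- constant_demography(1e4)
  sc <- sample_config(c(POP = 4))
  plan <- simulation_plan(4e5, 1e5, base_seed = 5)
  c1 <- simulate_genomes(g, sc, plan)
  c2 <- simulate_genomes(g, sc, plan)
  expect_identical(lapply(c1, `[[`, "geno"), lapply(c2, `[[`, "geno"))
  expect_identical(lapply(c1, `[[`, "pos"), lapply(c2, `[[`, "pos"))
  expect_length(c1, 4)
})

test_that("segregating sites match the Watterson expectation", {
  N <- 1e4; L <- 1e7; n_hap <- 10; locus <- 1e5
  g <- constant_demography(N)
  js <- simulate_joint_sfs(g, sample_config(c(POP = n_hap / 2)), L, locus,
                           seed = 42)
  S <- sum(js$counts) - js$counts[1]
  theta_l <- 4 * N * g$constants$mutation_rate * locus
  a <- sum(1 / seq_len(n_hap - 1)); b <- sum(1 / seq_len(n_hap - 1)^2)
  n_loci <- L / locus
  expS <- n_loci * theta_l * a
  sdS <- sqrt(n_loci * (theta_l * a + theta_l^2 * b))  # no-recombination loci
  expect_lt(abs(S - expS), 3 * sdS)
})

test_that("neutral SFS follows the 1/i law within sampling error", {
  N <- 1e4; L <- 5e7; n_hap <- 10
  g <- constant_demography(N)
  js <- simulate_joint_sfs(g, sample_config(c(POP = n_hap / 2)), L, 1e5, seed = 9)
  counts <- as.numeric(js$counts)[2:n_hap]  # derived counts 1..n-1
  theta <- 4 * N * g$constants$mutation_rate * L
  expected <- theta / seq_len(n_hap - 1)
  # loose per-class bound: non-recombining loci inflate the variance
  expect_true(all(abs(counts - expected) / expected < 0.25))
  expect_gt(cor(counts, expected), 0.99)
})

test_that("chunked and unchunked plans agree in distribution", {
  g <- constant_demography(1e4)
  sc <- sample_config(c(POP = 5))
  sfs_of <- function(chunk_len, seed)
    as.numeric(simulate_joint_sfs(g, sc, 2e6, chunk_len, seed = seed)$counts)[2:10]
  # equal tree counts per arm: 20 x (20 x 100 kb) vs 200 x (2 x 1 Mb)
  small <- rowSums(vapply(1:20, function(s) sfs_of(1e5, s), numeric(9)))
  big <- rowSums(vapply(1:200, function(s) sfs_of(1e6, 1000 + s), numeric(9)))
  p_small <- small / sum(small); p_big <- big / sum(big)
  chi <- sum((p_small - p_big)^2 / (p_small + p_big))
  expect_lt(chi, 0.01)
})

test_that("introgressed Denisovan variants are shared with PNG", {
  g <- build_demography(model_spec("A"), best_fit_params())
  js <- simulate_joint_sfs(g, canonical_sample_config(), 5e7, 1e5, seed = 13)
  d <- js$counts
  # derived in DEN and PNG, absent from AFR/EUR/ASN
  shared <- sum(d[1, 1, 1, -1, 1, -1])
  expect_gt(shared, 0)
})

test_that("VCF export round-trips through vcf_to_csfs", {
  skip_if_not_installed("VariantAnnotation")
  g <- build_demography(model_spec("A"), best_fit_params())
  sc <- canonical_sample_config(2)
  chunks <- simulate_genomes(g, sc, simulation_plan(4e5, 1e5, base_seed = 11))
  js <- joint_sfs_from_chunks(chunks)
  vcf <- file.path(tempdir(), "roundtrip.vcf")
  out <- export_vcf(chunks, vcf)
  res <- vcf_to_csfs(out$vcf, out$popmap)
  expect_equal(as.numeric(res$csfs), as.numeric(csfs(js)))
  expect_true(all(res$exclusions == 0))
})

test_that("a zero-variant chunk exports a valid header-only VCF", {
  skip_if_not_installed("VariantAnnotation")
  empty <- structure(list(geno = matrix(integer(0), 4, 0), pos = integer(0),
                          chunk_length = 1e4,
                          hap_label = rep(c("P1", "P2"), each = 2),
                          diplo_id = rep(1L, 4), n_multihit = 0L),
                     class = "genome_chunk")
  vcf <- file.path(tempdir(), "empty.vcf")
  out <- export_vcf(list(empty), vcf)
  res <- vcf_to_csfs(out$vcf, out$popmap)
  expect_equal(sum(res$joint$counts), 1e4)
  expect_equal(sum(res$joint$counts[-1]), 0)
})
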