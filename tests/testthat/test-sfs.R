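test_that("derived_counts applies the site filters", {
  pops <- c("P1", "P1", "P2", "P2", "P2")
  # all homozygous ancestral
  r <- derived_counts(rep("0|0", 5), "A", "C", "A", pops)
  expect_equal(r$status, "ok")
  expect_equal(unname(r$counts), c(0, 0))
  # hand-counted heterozygotes
  r <- derived_counts(c("0/1", "1/1", "0/0", "0/1", "0/0"), "A", "C", "A", pops)
  expect_equal(sum(r$counts), 4)
  expect_equal(unname(r$counts), c(3, 1))
  # polarity flip: ancestral equals ALT, so derived is the REF allele
  r <- derived_counts(c("0/1", "1/1", "0/0", "0/1", "0/0"), "A", "C", "C", pops)
  expect_equal(sum(r$counts), 6)
  # exclusions
  expect_equal(derived_counts(c("0|1", "./.", "0|0", "0|0", "0|0"),
                              "A", "C", "A", pops)$status, "missing")
  expect_equal(derived_counts(rep("0|0", 5), "A", "C,G", "A", pops)$status,
               "multiallelic")
  expect_equal(derived_counts(rep("0|0", 5), "A", "C", "T", pops)$status,
               "aa_unknown")
  expect_equal(derived_counts(rep("0|0", 5), "A", "C", ".", pops)$status,
               "aa_unknown")
})

test_that("joint SFS equals exhaustive per-site counting on random tables", {
  for (seed in 1:6) {
    pops <- if (seed %% 2) c(P1 = 3, P2 = 2) else c(A = 2, B = 2, C = 1)
    ch <- random_chunk(n_sites = sample(3:50, 1), pops = pops, seed = seed)
    js <- joint_sfs_from_chunks(list(ch))
    oracle <- brute_joint_sfs(ch$geno, ch$hap_label, names(pops), ch$chunk_length)
    expect_equal(unname(js$counts), unname(oracle))
    expect_equal(sum(js$counts), ch$chunk_length)  # conservation
    # every marginal preserves the total
    pr <- combn(names(pops), 2)
    for (k in seq_len(ncol(pr)))
      expect_equal(sum(marginalize(js, pr[, k])), sum(js$counts))
  }
})

test_that("zero-variant input puts all mass at the zero cell", {
  ch <- random_chunk(0, seed = 2)
  js <- joint_sfs_from_chunks(list(ch))
  expect_equal(js$counts[1], ch$chunk_length)
  expect_equal(sum(js$counts[-1]), 0)
})

test_that("canonical configuration has the documented dimensions", {
  sc <- canonical_sample_config()
  dims <- 2 * sc$counts + 1
  expect_equal(unname(dims), c(11, 11, 11, 11, 3, 3))
  expect_equal(prod(dims), 131769)
  expect_equal(csfs_length(sc), 999)
})

test_that("pairwise marginals have the documented shapes", {
  g <- build_demography(model_spec("A"), best_fit_params())
  js <- simulate_joint_sfs(g, canonical_sample_config(), 1e6, 1e5, seed = 3)
  expect_equal(dim(marginalize(js, c("AFR", "EUR"))), c(11, 11))
  expect_equal(dim(marginalize(js, c("PNG", "DEN"))), c(11, 3))
  expect_equal(dim(marginalize(js, c("NEA", "DEN"))), c(3, 3))
  expect_error(marginalize(js, c("AFR", "AFR")), "distinct")
  v <- csfs(js)
  expect_length(v, 999)
  lay <- attr(v, "layout")
  expect_equal(nrow(lay), 15)
  expect_equal(sum(lay$n_i * lay$n_j), 999)
})

test_that("any pairwise cell is recoverable from the cSFS by index arithmetic", {
  ch <- random_chunk(40, pops = c(A = 2, B = 3, C = 1), seed = 9)
  js <- joint_sfs_from_chunks(list(ch))
  v <- csfs(js)
  lay <- attr(v, "layout")
  for (r in seq_len(nrow(lay))) {
    m <- marginalize(js, c(lay$pop_i[r], lay$pop_j[r]))
    for (a in 0:(lay$n_i[r] - 1)) for (b in 0:(lay$n_j[r] - 1))
      expect_equal(csfs_cell(v, lay$pop_i[r], lay$pop_j[r], a, b),
                   m[a + 1, b + 1])
  }
})

test_that("relabelling identically-sized populations permutes the SFS axes", {
  ch <- random_chunk(30, pops = c(X = 2, Y = 2), seed = 4)
  js <- joint_sfs_from_chunks(list(ch))
  ch2 <- ch
  ch2$hap_label <- c("Y", "X")[match(ch$hap_label, c("X", "Y"))]
  js2 <- joint_sfs_from_chunks(list(ch2), pops = c("X", "Y"))
  expect_equal(unname(js2$counts), unname(aperm(js$counts, c(2, 1))))
})

test_that("cSFS rescaling is linear and tracks the callable length", {
  ch <- random_chunk(25, seed = 6)
  v <- csfs(joint_sfs_from_chunks(list(ch)))
  w <- rescale_csfs(v, attr(v, "callable_length"), 2 * attr(v, "callable_length"))
  expect_equal(as.numeric(w), 2 * as.numeric(v))
  expect_equal(attr(w, "callable_length"), 2 * attr(v, "callable_length"))
})

test_that("toy VCFs are filtered and tallied exactly", {
  skip_if_not_installed("VariantAnnotation")
  toy <- make_toy_vcf(3, 1, 1, seed = 5)
  res <- vcf_to_csfs(toy$vcf, toy$popmap)
  expect_equal(sum(res$joint$counts[-1]), 3)
  expect_equal(unname(res$exclusions), c(1L, 1L, 0L))
  expect_equal(res$joint$counts, toy$truth$counts)
  # pure-clean table equals the brute-force tally
  toy2 <- make_toy_vcf(20, 0, 0, pops = c(P1 = 2, P2 = 2), seed = 8)
  res2 <- vcf_to_csfs(toy2$vcf, toy2$popmap)
  oracle <- brute_joint_sfs(t(toy2$geno), rep(c("P1", "P2"), each = 4),
                            c("P1", "P2"), toy2$truth$callable_length)
  expect_equal(unname(res2$joint$counts), unname(oracle))
  # header-only VCF
  toy0 <- make_toy_vcf(0, 0, 0, seed = 9)
  res0 <- vcf_to_csfs(toy0$vcf, toy0$popmap)
  expect_equal(sum(res0$joint$counts[-1]), 0)
})

test_that("cSFS tables round-trip through disk with their sidecar", {
  x <- matrix(rnorm(30)^2, 3)
  path <- file.path(tempdir(), "tab.tsv")
  meta <- list(pops = c("A", "B"), n_diploid = c(A = 2, B = 2),
               callable_length = 1e5)
  write_csfs_table(x, path, meta)
  back <- read_csfs_table(path)
  expect_equal(back$x, x)
  expect_equal(back$meta$callable_length, 1e5)
})
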