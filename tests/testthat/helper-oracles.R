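# Independent brute-force oracles and tiny fixture builders used across tests.

# Exhaustive per-site joint-SFS tally: loops sites and populations with plain
# arithmetic, independent of the package's matrix-based tally path.
brute_joint_sfs <- function(geno, hap_label, pops, callable) {
  n_hap <- vapply(pops, function(p) sum(hap_label == p), integer(1))
  dims <- unname(n_hap + 1L)
  arr <- array(0, dim = dims)
  if (!is.null(geno) && ncol(geno) > 0) {
    for (s in seq_len(ncol(geno))) {
      cnt <- integer(length(pops))
      for (k in seq_along(pops))
        cnt[k] <- sum(geno[hap_label == pops[k], s])
      idx <- as.list(cnt + 1L)
      arr[matrix(unlist(idx), 1)] <- arr[matrix(unlist(idx), 1)] + 1
    }
  }
  arr[1] <- arr[1] + callable - if (is.null(geno)) 0 else ncol(geno)
  arr
}

# A random genotype "chunk" with the genome_chunk contract, not produced by
# the simulator (keeps SFS tests independent of the coalescent engine).
random_chunk <- function(n_sites, pops = c(P1 = 3, P2 = 2), chunk_length = 1e4,
                         seed = 1) {
  set.seed(seed)
  hap_label <- rep(rep(names(pops), times = pops), each = 2)
  n_hap <- length(hap_label)
  geno <- matrix(rbinom(n_hap * n_sites, 1, runif(1, 0.2, 0.6)), n_hap, n_sites)
  diplo_id <- rep(unlist(lapply(pops, seq_len)), each = 2)
  structure(list(geno = geno, pos = sort(sample.int(chunk_length, n_sites)),
                 chunk_length = chunk_length, hap_label = hap_label,
                 diplo_id = diplo_id, n_multihit = 0L),
            class = "genome_chunk")
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# AFR-ancestral derived-allele sharing between two populations
ooa_sharing <- function(js, x, y) {
  pops <- js$pops
  m <- apply(js$counts, c(match("AFR", pops), match(x, pops), match(y, pops)), sum)
  sum(m[1, -1, -1])
}

# identity-map SMC toy: features are the parameters plus Gaussian noise
identity_simulator <- function(sd = 0.05) {
  function(params, seq_length)
    params + matrix(rnorm(length(params), 0, sd), nrow(params))
}

toy_box <- function(d, lo = 0, hi = 10) {
  nm <- paste0("p", seq_len(d))
  prior_box(setNames(rep(lo, d), nm), setNames(rep(hi, d), nm))
}
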