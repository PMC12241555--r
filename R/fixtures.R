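#' Pseudo-observed cSFS replicates under a known truth
#'
#' Simulates once with 15 diploids per modern population (plus one
#' Neanderthal and one Denisovan, which are shared) and derives three cSFS
#' vectors from disjoint 5-diploid subsets, emulating observed datasets
#' built by varying the modern samples while keeping the archaics fixed.
#' The generating parameters are stored alongside for recovery scoring.
#'
#' @param spec A [model_spec()].
#' @param params Generating `param_vector` (the truth).
#' @param seq_length Sequence length in bases.
#' @param seed Integer seed.
#' @param chunk_length Locus length in bases.
#' @param constants A [sim_constants()].
#' @return An object of class `pseudo_observed`: `csfs` (3 x 999 matrix),
#'   `truth`, `model_id`, `seq_length`, `seed`.
#' @export
make_pseudo_observed <- function(spec, params, seq_length, seed = 1L,
                                 chunk_length = 1e5,
                                 constants = sim_constants()) {
  validate_params(params, spec)
  graph <- build_demography(spec, params, constants)
  samples <- sample_config(
    counts = c(AFR = 15, EUR = 15, ASN = 15, PNG = 15, NEA = 1, DEN = 1),
    ages_years = c(AFR = 0, EUR = 0, ASN = 0, PNG = 0,
                   NEA = spec$archaic_ages_ky[["NEA"]] * 1000,
                   DEN = spec$archaic_ages_ky[["DEN"]] * 1000))
  lay <- .hap_layout(graph, samples)
  # categories: 3 disjoint 5-diploid subsets per modern population + archaics
  modern <- c("AFR", "EUR", "ASN", "PNG")
  subset_of <- ceiling(lay$diplo_id / 5)  # 1..3 for moderns, 1 for archaics
  cat <- integer(length(lay$hap_label))
  for (i in seq_along(modern))
    for (r in 1:3)
      cat[lay$hap_label == modern[i] & subset_of == r] <- (i - 1L) * 3L + r - 1L
  cat[lay$hap_label == "NEA"] <- 12L
  cat[lay$hap_label == "DEN"] <- 13L
  M <- .simulate_branch_sites(graph, lay$hap_pop, lay$age_gen, cat, 14L,
                              seq_length, chunk_length, seed = seed)
  n_loci <- ceiling(seq_length / chunk_length)
  callable <- n_loci * chunk_length
  dims <- c(11L, 11L, 11L, 11L, 3L, 3L)
  strides <- cumprod(c(1, head(dims, -1)))
  nm <- M[, 15]
  rows <- lapply(1:3, function(r) {
    cols <- c((0:3) * 3 + r, 13, 14)  # 1-based columns of this replicate
    cnts <- M[, cols, drop = FALSE]
    variant <- rowSums(cnts) > 0
    idx <- as.vector(1 + cnts[variant, , drop = FALSE] %*% strides)
    arr <- array(0, dim = dims)
    tab <- rowsum(nm[variant], idx)
    arr[as.integer(rownames(tab))] <- tab
    arr[1] <- callable - sum(nm[variant])
    js <- new_joint_sfs(arr, pops = c("AFR", "EUR", "ASN", "PNG", "NEA", "DEN"),
                        n_diploid = c(AFR = 5, EUR = 5, ASN = 5, PNG = 5,
                                      NEA = 1, DEN = 1),
                        callable_length = callable)
    as.numeric(csfs(js))
  })
  structure(list(csfs = do.call(rbind, rows), truth = params,
                 model_id = spec$model_id, spec = spec,
                 seq_length = callable, seed = seed),
            class = "pseudo_observed")
}

#' Toy VCF with a known ground-truth joint SFS
#'
#' Writes a small VCF 4.2 file containing exactly the requested mix of clean
#' biallelic sites, multiallelic sites and sites with a missing genotype,
#' plus a matching population map. Roughly a third of the clean sites have a
#' flipped polarity (`AA` equal to the alternate allele) to exercise the
#' derived-allele logic. The returned ground truth counts only the clean
#' sites; the callable length is the contig length.
#'
#' @param n_clean,n_multiallelic,n_missing Site counts by class.
#' @param pops Named diploid sample counts per population.
#' @param seed Integer seed.
#' @param dir Output directory (default `tempdir()`).
#' @param contig_length Declared contig length.
#' @return List with `vcf`, `popmap`, `truth` (a `joint_sfs`) and the
#'   generating genotype matrix.
#' @export
make_toy_vcf <- function(n_clean, n_multiallelic = 0, n_missing = 0,
                         pops = c(P1 = 3, P2 = 2), seed = 1L,
                         dir = tempdir(), contig_length = 100000) {
  stopifnot(n_clean >= 0, n_multiallelic >= 0, n_missing >= 0, all(pops > 0))
  set.seed(seed)
  n_dip <- sum(pops)
  n_hap <- 2L * n_dip
  pop_lab <- rep(names(pops), times = pops)
  hap_lab <- rep(pop_lab, each = 2)
  sample_names <- paste0(pop_lab, "_", unlist(lapply(pops, seq_len)))
  n_sites <- n_clean + n_multiallelic + n_missing
  dims <- unname(2L * pops + 1L)
  arr <- array(0, dim = dims)
  strides <- cumprod(c(1, head(dims, -1)))
  lines <- character(0)
  geno_truth <- NULL
  if (n_sites > 0) {
    pos <- sort(sample.int(contig_length, n_sites))
    kind <- sample(rep(c("clean", "multi", "miss"),
                       c(n_clean, n_multiallelic, n_missing)))
    for (s in seq_len(n_sites)) {
      hap <- rbinom(n_hap, 1, runif(1, 0.15, 0.6))  # derived indicators
      gt <- paste(hap[seq(1, n_hap, 2)], hap[seq(2, n_hap, 2)], sep = "|")
      if (kind[s] == "clean") {
        flip <- runif(1) < 1 / 3
        aa <- if (flip) "C" else "A"
        der <- if (flip) 1 - hap else hap  # allele 1 is derived unless flipped
        cnt <- vapply(split(der, hap_lab), sum, numeric(1))[names(pops)]
        idx <- 1 + sum(cnt * strides)
        arr[idx] <- arr[idx] + 1
        geno_truth <- rbind(geno_truth, der)
        lines <- c(lines, paste(c("chr1", pos[s], ".", "A", "C", ".", "PASS",
                                  paste0("AA=", aa), "GT", gt), collapse = "\t"))
      } else if (kind[s] == "multi") {
        lines <- c(lines, paste(c("chr1", pos[s], ".", "A", "C,G", ".", "PASS",
                                  "AA=A", "GT", gt), collapse = "\t"))
      } else {
        gt[sample.int(n_dip, 1)] <- "./."
        lines <- c(lines, paste(c("chr1", pos[s], ".", "A", "C", ".", "PASS",
                                  "AA=A", "GT", gt), collapse = "\t"))
      }
    }
  }
  arr[1] <- arr[1] + contig_length - n_clean
  vcf <- file.path(dir, paste0("toy_", seed, ".vcf"))
  popmap <- file.path(dir, paste0("toy_", seed, ".popmap"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=demosmc-synthetic",
           paste0("##contig=<ID=chr1,length=", contig_length, ">"),
           '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral Allele">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_names), collapse = "\t"))
  writeLines(c(hdr, lines), vcf)
  writeLines(paste(sample_names, pop_lab, sep = "\t"), popmap)
  truth <- new_joint_sfs(arr, names(pops), setNames(pops, names(pops)),
                         contig_length)
  list(vcf = vcf, popmap = popmap, truth = truth, geno = geno_truth)
}

#' Pseudo-observed sweep across ghost-admixture fractions
#'
#' Builds labelled pseudo-observed datasets under the ghost models (and a
#' ghost-free baseline under Model A) across an admixture sweep, for
#' classifier-confusion experiments.
#'
#' @param ghost_fracs Ghost admixture fractions in `[0.01, 0.99]`.
#' @param base_params 24-parameter core vector (e.g. [best_fit_params()]).
#' @param seq_length Sequence length in bases.
#' @param seed Base seed; dataset `i` uses `seed + i`.
#' @param models Ghost models to sweep (subset of `"M"`, `"AX"`, `"OX"`).
#' @param ghost_tf Ghost divergence fraction (see [build_demography()]).
#' @return List of `pseudo_observed` objects; each carries its `model_id`
#'   and `ghost_m` value.
#' @export
make_confusion_suite <- function(ghost_fracs, base_params = best_fit_params(),
                                 seq_length = 50e6, seed = 1L,
                                 models = c("M", "AX", "OX"), ghost_tf = 0.5) {
  stopifnot(all(ghost_fracs >= 0.01 & ghost_fracs <= 0.99))
  out <- list()
  i <- 0L
  for (m in models) {
    sp <- model_spec(m)
    for (f in ghost_fracs) {
      i <- i + 1L
      p <- param_vector(c(unclass(base_params), ghost_m = f, ghost_tf = ghost_tf),
                        spec = sp)
      po <- make_pseudo_observed(sp, p, seq_length, seed = seed + i)
      po$ghost_m <- f
      out[[paste0(m, "_", f)]] <- po
    }
  }
  i <- i + 1L
  out[["A"]] <- make_pseudo_observed(model_spec("A"), base_params, seq_length,
                                     seed = seed + i)
  out
}

#' Score a posterior against the generating truth
#'
#' @param pseudo A `pseudo_observed` (or a named truth vector).
#' @param posterior A `param_posterior`.
#' @param events Also score the absolute event times implied by the interval
#'   parameters (posterior draws are chained through [resolve_events()]).
#' @param spec A [model_spec()] (needed for `events = TRUE`).
#' @return Data frame with columns `param`, `truth`, `estimate`,
#'   `rel_error`, `ci_lo`, `ci_hi`, `covered`.
#' @export
recovery_score <- function(pseudo, posterior, events = TRUE,
                           spec = model_spec("A")) {
  truth <- if (inherits(pseudo, "pseudo_observed")) pseudo$truth else pseudo
  truth <- unclass(truth)
  nm <- intersect(names(truth), names(posterior$point))
  out <- data.frame(param = nm, truth = truth[nm],
                    estimate = posterior$point[nm],
                    ci_lo = posterior$ci[1, nm], ci_hi = posterior$ci[2, nm],
                    row.names = NULL)
  if (events) {
    ev_truth <- resolve_events(param_vector(truth, spec = spec), spec)
    ev_draws <- t(apply(posterior$accepted, 1, function(p)
      resolve_events(param_vector(p, spec = spec), spec)))
    ev_point <- resolve_events(param_vector(
      setNames(posterior$point[names(truth)], names(truth)), spec = spec), spec)
    out <- rbind(out, data.frame(
      param = paste0("event_", names(ev_truth)), truth = ev_truth,
      estimate = ev_point,
      ci_lo = apply(ev_draws, 2, quantile, 0.025, names = FALSE),
      ci_hi = apply(ev_draws, 2, quantile, 0.975, names = FALSE),
      row.names = NULL))
  }
  out$rel_error <- abs(out$estimate - out$truth) / ifelse(out$truth == 0, 1, abs(out$truth))
  out$covered <- out$truth >= out$ci_lo & out$truth <= out$ci_hi
  out
}
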