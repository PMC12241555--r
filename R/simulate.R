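#' Simulation plan
#'
#' Total sequence length is split into independent non-recombining chunks
#' (loci). Chunk seeds are derived deterministically from the base seed as
#' `base_seed + chunk index`.
#'
#' @param total_length Total sequence length in bases.
#' @param chunk_length Chunk (locus) length in bases; default 100 kb (see the
#'   methods vignette for why this emulates recombining sequence).
#' @param base_seed Integer base seed.
#' @return An object of class `simulation_plan`.
#' @export
simulation_plan <- function(total_length, chunk_length = 1e5, base_seed = 1L) {
  stopifnot(total_length > 0, chunk_length > 0, total_length >= chunk_length)
  n_chunks <- ceiling(total_length / chunk_length)
  structure(list(total_length = n_chunks * chunk_length,
                 chunk_length = chunk_length,
                 n_chunks = as.integer(n_chunks),
                 base_seed = as.integer(base_seed)),
            class = "simulation_plan")
}

# Map a sample_config onto a demography: 0-based haplotype population ids,
# ages in generations, and haplotype labels.
.hap_layout <- function(graph, samples) {
  stopifnot(inherits(graph, "demography_graph"), inherits(samples, "sample_config"))
  cnt <- samples$counts[samples$counts > 0]
  miss <- setdiff(names(cnt), graph$pop_names)
  if (length(miss)) stop("samples for unknown populations: ", paste(miss, collapse = ", "))
  pop_idx <- match(names(cnt), graph$pop_names) - 1L
  hap_pop <- rep.int(pop_idx, 2 * cnt)
  hap_label <- rep.int(names(cnt), 2 * cnt)
  age_gen <- rep.int(samples$ages_years[names(cnt)] / graph$constants$generation_time,
                     2 * cnt)
  diplo_id <- unlist(lapply(cnt, function(k) rep(seq_len(k), each = 2)), use.names = FALSE)
  list(hap_pop = as.integer(hap_pop), hap_label = hap_label,
       age_gen = as.numeric(age_gen), counts = cnt, diplo_id = diplo_id,
       category = as.integer(match(hap_label, names(cnt)) - 1L))
}

.demog_list <- function(graph) {
  list(npop = as.integer(graph$npop), epochs = graph$epochs,
       events = graph$events, mig = graph$mig)
}

#' Simulate genotype chunks under a demography
#'
#' Each chunk is an independent genealogy with infinite-sites mutations;
#' genotypes are phased haplotypes coded 0 (ancestral) / 1 (derived).
#'
#' @param graph A `demography_graph`.
#' @param samples A [sample_config()].
#' @param plan A [simulation_plan()].
#' @return List of `genome_chunk` objects with elements `geno` (haplotypes x
#'   sites 0/1 matrix), `pos`, `chunk_length`, `hap_label`, `n_multihit`.
#' @export
simulate_genomes <- function(graph, samples, plan) {
  lay <- .hap_layout(graph, samples)
  dl <- .demog_list(graph)
  mu <- graph$constants$mutation_rate
  lapply(seq_len(plan$n_chunks), function(i) {
    set.seed(plan$base_seed + i)
    g <- cpp_sim_genotypes(dl, lay$hap_pop, lay$age_gen, plan$chunk_length, mu)
    structure(list(geno = g$geno, pos = as.integer(g$pos),
                   chunk_length = plan$chunk_length,
                   hap_label = lay$hap_label, diplo_id = lay$diplo_id,
                   n_multihit = g$n_multihit),
              class = "genome_chunk")
  })
}

#' Simulate a joint site frequency spectrum directly
#'
#' Fast path used to build cSFS reference tables: mutations are tallied into
#' the joint SFS inside the engine without materializing genotypes. The
#' zero cell receives the monomorphic base count so that the total equals
#' the callable length.
#'
#' @param graph A `demography_graph`.
#' @param samples A [sample_config()].
#' @param total_length Total sequence length in bases.
#' @param chunk_length Locus length in bases.
#' @param seed Optional integer seed.
#' @return A `joint_sfs` object.
#' @export
simulate_joint_sfs <- function(graph, samples, total_length, chunk_length = 1e5,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lay <- .hap_layout(graph, samples)
  n_loci <- ceiling(total_length / chunk_length)
  dims <- as.integer(2 * lay$counts + 1)
  res <- cpp_sim_sfs(.demog_list(graph), lay$hap_pop, lay$age_gen, lay$category,
                     dims, as.integer(n_loci), chunk_length,
                     graph$constants$mutation_rate)
  arr <- array(res$sfs, dim = dims)
  callable <- n_loci * chunk_length
  arr[1] <- callable - res$n_sites
  new_joint_sfs(arr, pops = names(lay$counts), n_diploid = lay$counts,
                callable_length = callable)
}

#' Simulate genealogies (marginal trees at independent loci)
#'
#' @inheritParams simulate_joint_sfs
#' @param n_loci Number of independent genealogies.
#' @return Object of class `genealogy_set`: list with `trees` (each a list
#'   with `parent` pointers and node `time`s in generations), `hap_label`,
#'   and the generation time.
#' @export
simulate_trees <- function(graph, samples, n_loci, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lay <- .hap_layout(graph, samples)
  tr <- cpp_sim_trees(.demog_list(graph), lay$hap_pop, lay$age_gen,
                      as.integer(n_loci))
  structure(list(trees = tr, hap_label = lay$hap_label,
                 generation_time = graph$constants$generation_time),
            class = "genealogy_set")
}

# Branch-level mutation table (descendant counts per category + mutation
# count per branch) for tallying several SFS projections from one run.
.simulate_branch_sites <- function(graph, hap_pop, age_gen, category, ncat,
                                   total_length, chunk_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_loci <- ceiling(total_length / chunk_length)
  cpp_sim_branch_sites(.demog_list(graph), hap_pop, age_gen, category,
                       as.integer(ncat), as.integer(n_loci), chunk_length,
                       graph$constants$mutation_rate)
}

#' Export simulated chunks as a VCF 4.2 file with a population map
#'
#' Writes phased diploid genotypes with the ancestral allele in the `AA`
#' INFO tag (REF is the ancestral allele, so allele 1 is always derived) and
#' one contig per chunk, plus a two-column sample-to-population map.
#'
#' @param chunks List of `genome_chunk` objects from [simulate_genomes()].
#' @param path Output VCF path.
#' @param popmap_path Output population-map path (default `path` +
#'   `".popmap"`).
#' @return Invisibly, a list with the paths and the sample names.
#' @export
export_vcf <- function(chunks, path, popmap_path = paste0(path, ".popmap")) {
  stopifnot(length(chunks) > 0)
  ch1 <- chunks[[1]]
  n_hap <- length(ch1$hap_label)
  stopifnot(n_hap %% 2 == 0)
  dip <- seq(1, n_hap, by = 2)
  sample_pop <- ch1$hap_label[dip]
  sample_names <- paste0(sample_pop, "_", ch1$diplo_id[dip])
  hdr <- c("##fileformat=VCFv4.2",
           "##source=demosmc",
           paste0("##contig=<ID=chunk", seq_along(chunks),
                  ",length=", vapply(chunks, `[[`, numeric(1), "chunk_length"), ">"),
           '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral Allele">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_names), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  for (i in seq_along(chunks)) {
    ch <- chunks[[i]]
    s <- length(ch$pos)
    if (s == 0) next
    g <- ch$geno  # haplotypes x sites
    gt <- matrix(paste(g[dip, , drop = FALSE], g[dip + 1, , drop = FALSE], sep = "|"),
                 nrow = length(dip))
    rows <- vapply(seq_len(s), function(j) {
      paste(c(paste0("chunk", i), ch$pos[j], ".", "A", "C", ".", "PASS",
              "AA=A", "GT", gt[, j]), collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  writeLines(paste(sample_names, sample_pop, sep = "\t"), popmap_path)
  invisible(list(vcf = path, popmap = popmap_path, samples = sample_names))
}

#' Single constant-size panmictic demography (testing/calibration helper)
#'
#' @param N Diploid effective size.
#' @param constants A [sim_constants()].
#' @return A `demography_graph` with one population named `"POP"`.
#' @export
constant_demography <- function(N, constants = sim_constants()) {
  structure(list(npop = 1L, pop_names = "POP",
                 epochs = matrix(c(0, 0, N, 0), nrow = 1),
                 events = matrix(numeric(0), ncol = 5),
                 mig = matrix(numeric(0), ncol = 5),
                 constants = constants, spec = NULL, params = NULL,
                 sample_ages_gen = c(POP = 0)),
            class = "demography_graph")
}

#' Two populations with a clean split (testing/calibration helper)
#'
#' Both populations have constant size `N` and merge `split_ky` thousand
#' years ago with no migration.
#'
#' @param N Diploid effective size of each population.
#' @param split_ky Split time in thousand years ago.
#' @param constants A [sim_constants()].
#' @return A `demography_graph` with populations `"P0"` and `"P1"`.
#' @export
clean_split_demography <- function(N, split_ky, constants = sim_constants()) {
  t_split <- split_ky * 1000 / constants$generation_time
  structure(list(npop = 2L, pop_names = c("P0", "P1"),
                 epochs = rbind(c(0, 0, N, 0), c(1, 0, N, 0)),
                 events = matrix(c(t_split, 0, 1, 0, 0), nrow = 1),
                 mig = matrix(numeric(0), ncol = 5),
                 constants = constants, spec = NULL, params = NULL,
                 sample_ages_gen = c(P0 = 0, P1 = 0)),
            class = "demography_graph")
}
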