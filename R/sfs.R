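#' Joint site frequency spectrum container
#'
#' A k-dimensional count array with one dimension per population of length
#' `2 * n_diploid + 1` (derived-allele counts 0..2n). The zero cell holds the
#' monomorphic base count so that the total over all cells equals the
#' callable sequence length.
#'
#' @param arr Count array.
#' @param pops Character vector of population names, one per dimension.
#' @param n_diploid Named diploid sample sizes.
#' @param callable_length Callable length in bases.
#' @return An object of class `joint_sfs`.
#' @export
new_joint_sfs <- function(arr, pops, n_diploid, callable_length) {
  stopifnot(length(dim(arr)) == length(pops),
            all(dim(arr) == 2 * n_diploid[pops] + 1),
            all(arr >= 0))
  structure(list(counts = arr, pops = pops,
                 n_diploid = setNames(as.integer(n_diploid[pops]), pops),
                 callable_length = callable_length),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("joint SFS over", paste(x$pops, collapse = ", "),
      "| dims", paste(dim(x$counts), collapse = "x"),
      "| segregating sites", sum(x$counts) - x$counts[1],
      "| callable", x$callable_length, "bp\n")
  invisible(x)
}

#' Per-population derived allele counts at one site
#'
#' Applies the site filters used for the cSFS: the site must be biallelic,
#' genotyped in every individual, and carry a known ancestral allele matching
#' one of the two alleles. Genotypes are diploid strings (`"0/1"`, `"0|1"`,
#' `"./."`).
#'
#' @param genotypes Character vector of diploid genotypes, one per sample.
#' @param ref,alt Reference and alternate allele(s); `alt` of length > 1 (or
#'   a comma-separated string) marks a multiallelic site.
#' @param aa Ancestral allele (string, possibly `NA` or `"."`).
#' @param populations Factor/character of population labels per sample.
#' @return List with `counts` (named per-population derived counts, in level
#'   order of `populations`) and `status`, one of `"ok"`, `"missing"`,
#'   `"multiallelic"`, `"aa_unknown"`.
#' @export
derived_counts <- function(genotypes, ref, alt, aa, populations) {
  populations <- if (is.factor(populations)) populations else
    factor(populations, levels = unique(populations))
  alt <- unlist(strsplit(as.character(alt), ",", fixed = TRUE))
  if (length(alt) != 1L || is.na(alt) || alt == "." || alt == "")
    return(list(counts = NULL, status = "multiallelic"))
  if (any(grepl(".", genotypes, fixed = TRUE)) || anyNA(genotypes))
    return(list(counts = NULL, status = "missing"))
  if (is.na(aa) || !nzchar(aa) || aa == "." || !(toupper(aa) %in% toupper(c(ref, alt))))
    return(list(counts = NULL, status = "aa_unknown"))
  al <- strsplit(genotypes, "[/|]")
  if (any(lengths(al) != 2L)) return(list(counts = NULL, status = "missing"))
  derived_code <- if (toupper(aa) == toupper(ref)) "1" else "0"
  nder <- vapply(al, function(a) sum(a == derived_code), integer(1))
  counts <- vapply(split(nder, populations), sum, integer(1))
  list(counts = counts, status = "ok")
}

#' Joint SFS from simulated genotype chunks
#'
#' Tallies per-site derived counts by population over all chunks. The zero
#' cell is set to the callable length minus the number of variant sites.
#'
#' @param chunks List of `genome_chunk` objects.
#' @param pops Optional population order (default: order of appearance).
#' @return A `joint_sfs`.
#' @export
joint_sfs_from_chunks <- function(chunks, pops = NULL) {
  stopifnot(length(chunks) > 0)
  lab <- chunks[[1]]$hap_label
  if (is.null(pops)) pops <- unique(lab)
  stopifnot(all(lab %in% pops))
  n_hap <- vapply(pops, function(p) sum(lab == p), integer(1))
  stopifnot(all(n_hap %% 2 == 0))
  dims <- unname(n_hap + 1L)
  memb <- outer(lab, pops, `==`) * 1  # haplotypes x pops
  arr <- array(0, dim = dims)
  n_var <- 0
  for (ch in chunks) {
    if (!identical(ch$hap_label, lab)) stop("inconsistent samples across chunks")
    if (length(ch$pos) == 0) next
    cnt <- t(ch$geno) %*% memb  # sites x pops
    idx <- as.vector(1 + cnt %*% cumprod(c(1, head(dims, -1))))
    tab <- tabulate(idx, nbins = prod(dims))
    arr <- arr + array(tab, dim = dims)
    n_var <- n_var + length(ch$pos)
  }
  callable <- sum(vapply(chunks, `[[`, numeric(1), "chunk_length"))
  arr[1] <- arr[1] + callable - n_var
  new_joint_sfs(arr, pops, setNames(n_hap / 2, pops), callable)
}

#' Marginal two-dimensional SFS for a population pair
#'
#' @param joint A `joint_sfs`.
#' @param pair Character or integer vector of two distinct populations.
#' @return Matrix of dimension `(2n_i+1) x (2n_j+1)`; total mass preserved.
#' @export
marginalize <- function(joint, pair) {
  stopifnot(inherits(joint, "joint_sfs"), length(pair) == 2)
  if (is.character(pair)) pair <- match(pair, joint$pops)
  if (anyNA(pair) || pair[1] == pair[2]) stop("pair must name two distinct populations")
  m <- apply(joint$counts, pair, sum)
  dimnames(m) <- NULL
  m
}

#' Pair layout of the cSFS vector
#'
#' Pairs are enumerated in lexicographic order of the population indices
#' (i < j in the canonical population order) and each pairwise SFS is
#' flattened row-major (the second population's index varies fastest).
#'
#' @param joint A `joint_sfs` (or anything with `pops` and `n_diploid`).
#' @return Data frame with columns `pop_i`, `pop_j`, `offset` (0-based start
#'   of the pair block), `n_i`, `n_j` (block dimensions).
#' @export
csfs_layout <- function(joint) {
  k <- length(joint$pops)
  dims <- 2 * joint$n_diploid + 1
  pr <- utils::combn(k, 2)
  off <- 0
  out <- data.frame(pop_i = character(0), pop_j = character(0),
                    offset = integer(0), n_i = integer(0), n_j = integer(0))
  for (c0 in seq_len(ncol(pr))) {
    i <- pr[1, c0]; j <- pr[2, c0]
    out <- rbind(out, data.frame(pop_i = joint$pops[i], pop_j = joint$pops[j],
                                 offset = off, n_i = dims[i], n_j = dims[j]))
    off <- off + dims[i] * dims[j]
  }
  out
}

#' Cross-population SFS vector
#'
#' Concatenation of all flattened pairwise marginal SFS, in the layout given
#' by [csfs_layout()]. For the canonical configuration (5 diploids in each of
#' 4 modern populations + 2 single-diploid archaics) the length is
#' 6x121 + 8x33 + 9 = 999.
#'
#' @param joint A `joint_sfs`.
#' @return Numeric vector with attributes `layout`, `pops`, `n_diploid`,
#'   `callable_length`.
#' @export
csfs <- function(joint) {
  lay <- csfs_layout(joint)
  v <- unlist(lapply(seq_len(nrow(lay)), function(r) {
    m <- marginalize(joint, c(lay$pop_i[r], lay$pop_j[r]))
    as.vector(t(m))  # row-major
  }), use.names = FALSE)
  structure(v, layout = lay, pops = joint$pops, n_diploid = joint$n_diploid,
            callable_length = joint$callable_length)
}

#' Recover one pairwise-SFS cell from a cSFS vector
#'
#' Index arithmetic for the documented layout: the cell `(a, b)` (derived
#' counts, 0-based) of pair `(pop_i, pop_j)` sits at
#' `offset + a * n_j + b + 1`.
#'
#' @param v A cSFS vector from [csfs()].
#' @param pop_i,pop_j Population names (order as in the layout).
#' @param a,b 0-based derived-allele counts for `pop_i` and `pop_j`.
#' @return The cell value.
#' @export
csfs_cell <- function(v, pop_i, pop_j, a, b) {
  lay <- attr(v, "layout")
  r <- which(lay$pop_i == pop_i & lay$pop_j == pop_j)
  if (!length(r)) stop("unknown pair")
  stopifnot(a >= 0, a < lay$n_i[r], b >= 0, b < lay$n_j[r])
  v[[lay$offset[r] + a * lay$n_j[r] + b + 1]]
}

#' Rescale a cSFS between callable lengths
#'
#' Linear scaling of all cells (expected counts are proportional to length),
#' used when observed data and a reference table were built at different
#' sequence lengths.
#'
#' @param v A cSFS vector (or plain numeric vector).
#' @param from_length,to_length Callable lengths in bases.
#' @return Rescaled vector (attributes preserved, `callable_length` updated).
#' @export
rescale_csfs <- function(v, from_length, to_length) {
  stopifnot(from_length > 0, to_length > 0)
  out <- v * (to_length / from_length)
  if (!is.null(attr(v, "callable_length"))) attr(out, "callable_length") <- to_length
  out
}

#' Convert a VCF file to a cSFS vector
#'
#' Applies the site filters of [derived_counts()] (biallelic, fully
#' genotyped, known ancestral allele from the `AA` INFO tag) and tallies the
#' joint SFS over the populations in the map. Genome masks are out of scope:
#' the callable length is an explicit input.
#'
#' @param vcf_path Path to a VCF 4.2 file with an `AA` INFO tag.
#' @param popmap Either a path to a two-column (sample, population) text
#'   file or a data frame with columns `sample` and `pop`.
#' @param callable_length Callable length in bases (default: sum of contig
#'   lengths in the VCF header).
#' @param samples Optional subset of sample names to use.
#' @return List with `csfs`, `joint` (the `joint_sfs`) and `exclusions`
#'   (named counts of filtered sites by reason).
#' @export
vcf_to_csfs <- function(vcf_path, popmap, callable_length = NULL, samples = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("vcf_to_csfs requires the VariantAnnotation package")
  if (is.character(popmap))
    popmap <- read.table(popmap, col.names = c("sample", "pop"),
                         colClasses = "character")
  stopifnot(all(c("sample", "pop") %in% names(popmap)))
  if (!is.null(samples)) popmap <- popmap[popmap$sample %in% samples, , drop = FALSE]
  vcf <- suppressWarnings(VariantAnnotation::readVcf(vcf_path, genome = "unknown"))
  hdr_samp <- colnames(vcf)
  missing_s <- setdiff(popmap$sample, hdr_samp)
  if (length(missing_s)) stop("samples not in VCF: ", paste(missing_s, collapse = ", "))
  if (!("AA" %in% rownames(VariantAnnotation::info(VariantAnnotation::header(vcf)))))
    stop("VCF lacks the AA (ancestral allele) INFO tag")
  if (is.null(callable_length)) {
    sl <- GenomeInfoDb::seqlengths(
      GenomeInfoDb::seqinfo(VariantAnnotation::scanVcfHeader(vcf_path)))
    if (length(sl) == 0 || anyNA(sl))
      stop("callable_length not given and contig lengths missing")
    callable_length <- sum(as.numeric(sl))
  }
  pops <- unique(popmap$pop)
  pop_of <- setNames(popmap$pop, popmap$sample)
  n_sites <- nrow(vcf)
  excl <- c(multiallelic = 0L, missing = 0L, aa_unknown = 0L)
  n_hap <- vapply(pops, function(p) 2L * sum(popmap$pop == p), integer(1))
  dims <- unname(n_hap + 1L)
  arr <- array(0, dim = dims)
  n_var <- 0L
  if (n_sites > 0) {
    gt <- VariantAnnotation::geno(vcf)$GT[, popmap$sample, drop = FALSE]
    ref <- as.character(VariantAnnotation::ref(vcf))
    altl <- VariantAnnotation::alt(vcf)
    alt <- vapply(seq_len(n_sites), function(i)
      paste(as.character(altl[[i]]), collapse = ","), character(1))
    aa <- as.character(VariantAnnotation::info(vcf)$AA)
    strides <- cumprod(c(1, head(dims, -1)))
    for (i in seq_len(n_sites)) {
      dc <- derived_counts(gt[i, ], ref[i], alt[i], aa[i],
                           factor(pop_of[popmap$sample], levels = pops))
      if (dc$status != "ok") {
        excl[dc$status] <- excl[dc$status] + 1L
        next
      }
      idx <- 1 + sum(dc$counts * strides)
      arr[idx] <- arr[idx] + 1
      n_var <- n_var + 1L
    }
  }
  arr[1] <- arr[1] + callable_length - n_var
  joint <- new_joint_sfs(arr, pops, setNames(n_hap / 2, pops), callable_length)
  list(csfs = csfs(joint), joint = joint, exclusions = excl)
}

#' Write / read cSFS tables with a JSON sidecar
#'
#' Rows are datasets (simulations or observed replicates); the sidecar
#' records population order, diploid sample sizes and the callable length so
#' that a table is self-describing.
#'
#' @param x Matrix of cSFS rows.
#' @param path Output path (tab-separated); sidecar written to `path.json`.
#' @param meta List with `pops`, `n_diploid`, `callable_length`.
#' @return `write_csfs_table()` returns `path` invisibly; `read_csfs_table()`
#'   returns a list with `x` and `meta`.
#' @export
write_csfs_table <- function(x, path, meta) {
  write.table(x, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_csfs_table
#' @export
read_csfs_table <- function(path) {
  x <- as.matrix(read.table(path, sep = "\t"))
  dimnames(x) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(x = x, meta = meta)
}
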