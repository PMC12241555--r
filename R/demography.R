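#' Simulation constants
#'
#' Per-generation mutation and recombination rates and the generation time
#' used to convert between years and generations. Defaults are the standard
#' human values used throughout the package.
#'
#' @param mutation_rate Mutations per base per generation.
#' @param recombination_rate Recombination rate per base per generation
#'   (retained for interface completeness; loci are simulated as independent
#'   non-recombining blocks, see the methods vignette).
#' @param generation_time Years per generation.
#' @return An object of class `sim_constants`.
#' @export
sim_constants <- function(mutation_rate = 1.25e-8, recombination_rate = 1e-8,
                          generation_time = 29) {
  stopifnot(mutation_rate > 0, recombination_rate > 0, generation_time > 0)
  structure(list(mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 generation_time = generation_time),
            class = "sim_constants")
}

# Canonical parameter order: 12 diploid sizes, 10 time intervals (thousand
# years), 2 archaic admixture proportions.
.param_names_core <- c("N_A", "N_AF", "N_EU", "N_AS", "N_PA", "N_NE", "N_DE",
                       "N_EU0", "N_AS0", "N_PA0", "N_B", "N_ND",
                       "T_DPM", "T_AS_PA", "T_EU_AS", "T_NOM", "T_B", "T_AF",
                       "T_NI_NS", "T_DI_DS", "T_N_D", "T_H_A",
                       "NEA_m_OOA", "DEN_m_PAP")
.param_names_ghost <- c("ghost_m", "ghost_tf")
.mig_pairs <- c("m_AFR_EUR", "m_AFR_ASN", "m_AFR_PNG",
                "m_EUR_ASN", "m_EUR_PNG", "m_ASN_PNG")

#' Names of the demographic parameters for a model
#'
#' @param spec A [model_spec()].
#' @return Character vector of parameter names in canonical order: the 24
#'   core parameters, plus `ghost_m`/`ghost_tf` for the ghost models (M, AX,
#'   OX), plus six pairwise migration rates when a migration variant is
#'   enabled.
#' @export
param_names <- function(spec) {
  nm <- .param_names_core
  if (spec$model_id %in% c("M", "AX", "OX")) nm <- c(nm, .param_names_ghost)
  if (spec$migration_variant != "none") nm <- c(nm, .mig_pairs)
  nm
}

#' Demographic model specification
#'
#' The five competing models share one parameterization and differ in the
#' branching order of the modern out-of-Africa populations and in the
#' presence of an unsampled ("ghost") admixing lineage:
#' * `A`, `AX`, `M`: Papua New Guineans (PNG) are a sister group to East
#'   Asians -- topology (EUR, (ASN, PNG));
#' * `O`, `OX`: PNG is an outgroup to Europeans and East Asians -- topology
#'   (PNG, (EUR, ASN));
#' * `M`, `AX`, `OX` add a ghost admixture pulse into PNG (from the
#'   out-of-Africa branch for M, from an early-diverged African lineage for
#'   AX/OX).
#'
#' @param model_id One of `"A"`, `"O"`, `"M"`, `"AX"`, `"OX"`.
#' @param migration_variant `"none"`, `"low"` (pairwise symmetric rates below
#'   5e-5 per generation) or `"high"` (below 5e-4), applied between the four
#'   modern human populations after their separations.
#' @param archaic_ages_ky Named sampling ages (thousand years ago) of the
#'   sequenced Neanderthal and Denisovan genomes.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model_id = c("A", "O", "M", "AX", "OX"),
                       migration_variant = c("none", "low", "high"),
                       archaic_ages_ky = c(NEA = 120, DEN = 60)) {
  model_id <- match.arg(model_id)
  migration_variant <- match.arg(migration_variant)
  stopifnot(all(c("NEA", "DEN") %in% names(archaic_ages_ky)),
            all(archaic_ages_ky >= 0))
  structure(list(model_id = model_id,
                 migration_variant = migration_variant,
                 archaic_ages_ky = archaic_ages_ky,
                 has_ghost = model_id %in% c("M", "AX", "OX")),
            class = "model_spec")
}

#' Construct and validate a demographic parameter vector
#'
#' @param ... Named parameter values (see [param_names()]); alternatively a
#'   single named vector.
#' @param spec A [model_spec()] naming the model the vector is for.
#' @return Named numeric vector of class `param_vector`.
#' @export
param_vector <- function(..., spec = model_spec("A")) {
  dots <- list(...)
  x <- if (length(dots) == 1L && is.numeric(dots[[1]]) && length(dots[[1]]) > 1L)
    dots[[1]] else unlist(dots)
  nm <- param_names(spec)
  missing <- setdiff(nm, names(x))
  if (length(missing)) stop("missing parameters: ", paste(missing, collapse = ", "))
  x <- x[nm]
  validate_params(x, spec)
  structure(x, class = c("param_vector", "numeric"))
}

#' @rdname param_vector
#' @param params Named numeric vector to check.
#' @export
validate_params <- function(params, spec) {
  nm <- param_names(spec)
  stopifnot(all(nm %in% names(params)))
  sizes <- params[grep("^N_", nm, value = TRUE)]
  if (any(sizes <= 0)) stop("population sizes must be positive")
  ints <- params[grep("^T_", nm, value = TRUE)]
  if (any(ints < 0)) stop("time intervals must be non-negative")
  fr <- params[intersect(c("NEA_m_OOA", "DEN_m_PAP", "ghost_m", "ghost_tf"), nm)]
  if (any(fr < 0 | fr > 1)) stop("admixture fractions must lie in [0, 1]")
  if (spec$migration_variant != "none") {
    m <- params[.mig_pairs]
    if (any(m < 0)) stop("migration rates must be non-negative")
  }
  invisible(TRUE)
}

#' Best-fit parameter values for the sister-group model (Model A)
#'
#' Point estimates (posterior means) for the 24 parameters of the
#' sister-group demographic model of Papua New Guinean history, used as the
#' canonical recovery fixture and for simulating realistic data. Admixture
#' proportions are stored as fractions (e.g. 0.0404 = 4.04%).
#'
#' @return A `param_vector` for Model A.
#' @export
best_fit_params <- function() {
  param_vector(
    N_A = 19308, N_AF = 43477, N_EU = 71931, N_AS = 94703, N_PA = 32085,
    N_NE = 2360, N_DE = 2535, N_EU0 = 3512, N_AS0 = 1771, N_PA0 = 674,
    N_B = 726, N_ND = 15324,
    T_DPM = 31.3, T_AS_PA = 14.9, T_EU_AS = 5, T_NOM = 0.9, T_B = 10.3,
    T_AF = 43.2, T_NI_NS = 200.6, T_DI_DS = 276, T_N_D = 14.3, T_H_A = 269.8,
    NEA_m_OOA = 0.0404, DEN_m_PAP = 0.0323,
    spec = model_spec("A"))
}

#' Resolve time intervals into absolute event times
#'
#' Time parameters are intervals (thousand years) chained most-recent-first:
#' the modern chain runs T_DPM -> T_AS_PA -> T_EU_AS -> T_NOM -> T_B -> T_AF
#' by accumulation; the introgressing-Neanderthal split is T_NI_NS after the
#' Neanderthal pulse; the introgressing-Denisovan split is T_DI_DS after the
#' Denisovan pulse; the Neanderthal-Denisovan split is T_N_D after that, and
#' the modern-archaic split T_H_A after that.
#'
#' @param params A `param_vector`.
#' @param spec A [model_spec()].
#' @return Named numeric vector of event times in thousand years ago, one
#'   entry per interval parameter.
#' @export
resolve_events <- function(params, spec = model_spec("A")) {
  validate_params(params, spec)
  p <- as.list(params)
  if (any(unlist(p[grep("^T_", names(p))]) < 0)) stop("negative interval")
  e <- c(T_DPM = p$T_DPM)
  e["T_AS_PA"] <- e["T_DPM"] + p$T_AS_PA
  e["T_EU_AS"] <- e["T_AS_PA"] + p$T_EU_AS
  e["T_NOM"] <- e["T_EU_AS"] + p$T_NOM
  e["T_B"] <- e["T_NOM"] + p$T_B
  e["T_AF"] <- e["T_B"] + p$T_AF
  e["T_NI_NS"] <- e["T_NOM"] + p$T_NI_NS
  e["T_DI_DS"] <- e["T_DPM"] + p$T_DI_DS
  e["T_N_D"] <- e["T_DI_DS"] + p$T_N_D
  e["T_H_A"] <- e["T_N_D"] + p$T_H_A
  e
}

#' Default prior box for a demographic model
#'
#' Bounds follow the stated ranges where available (modern sizes, the
#' Denisovan-pulse interval, chained modern intervals, archaic admixture
#' 1--5%, ghost admixture 1--99%); remaining bounds are documented package
#' defaults (see the methods vignette).
#'
#' @param spec A [model_spec()].
#' @return A `prior_box`: list with `lower` and `upper` named vectors.
#' @export
default_priors <- function(spec = model_spec("A")) {
  lo <- c(N_A = 5000, N_AF = 10000, N_EU = 10000, N_AS = 10000, N_PA = 10000,
          N_NE = 500, N_DE = 500, N_EU0 = 100, N_AS0 = 100, N_PA0 = 100,
          N_B = 100, N_ND = 500,
          T_DPM = 10, T_AS_PA = 0.5, T_EU_AS = 0.5, T_NOM = 0.5, T_B = 0.5,
          T_AF = 0.5, T_NI_NS = 0.5, T_DI_DS = 0.5, T_N_D = 0.5, T_H_A = 0.5,
          NEA_m_OOA = 0.01, DEN_m_PAP = 0.01)
  hi <- c(N_A = 60000, N_AF = 60000, N_EU = 150000, N_AS = 150000, N_PA = 50000,
          N_NE = 30000, N_DE = 30000, N_EU0 = 5000, N_AS0 = 5000, N_PA0 = 5000,
          N_B = 5000, N_ND = 30000,
          T_DPM = 100, T_AS_PA = 50, T_EU_AS = 50, T_NOM = 50, T_B = 50,
          T_AF = 50, T_NI_NS = 400, T_DI_DS = 400, T_N_D = 400, T_H_A = 400,
          NEA_m_OOA = 0.05, DEN_m_PAP = 0.05)
  if (spec$has_ghost) {
    lo <- c(lo, ghost_m = 0.01, ghost_tf = 0.05)
    hi <- c(hi, ghost_m = 0.99, ghost_tf = 0.95)
  }
  if (spec$migration_variant != "none") {
    mmax <- if (spec$migration_variant == "low") 5e-5 else 5e-4
    lo <- c(lo, setNames(rep(0, 6), .mig_pairs))
    hi <- c(hi, setNames(rep(mmax, 6), .mig_pairs))
  }
  prior_box(lo, hi)
}

#' Prior box constructor
#'
#' @param lower,upper Named numeric vectors of elementwise bounds.
#' @return An object of class `prior_box`.
#' @export
prior_box <- function(lower, upper) {
  stopifnot(length(lower) == length(upper),
            !is.null(names(lower)), identical(names(lower), names(upper)))
  if (any(lower > upper)) stop("empty prior box: lower > upper")
  structure(list(lower = lower, upper = upper), class = "prior_box")
}

#' Sample parameter vectors uniformly from a prior box
#'
#' Independent uniform draws per parameter (standard rejection-ABC prior).
#'
#' @param box A `prior_box`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Matrix with `n` rows, one named column per parameter.
#' @export
sample_prior <- function(box, n, seed = NULL) {
  stopifnot(inherits(box, "prior_box"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- length(box$lower)
  m <- matrix(runif(n * p, rep(box$lower, each = n), rep(box$upper, each = n)),
              nrow = n, ncol = p)
  colnames(m) <- names(box$lower)
  m
}

.pop_names_full <- c("AFR", "EUR", "ASN", "PNG", "OOA", "NEA", "DEN",
                     "NEAI", "DENI", "GHOST")

#' Compile a model and parameter vector into a simulator-ready demography
#'
#' Produces the population/epoch/event tables consumed by the coalescent
#' engine. All times inside the graph are in generations (backwards from the
#' present); the builder converts the interval parameters (thousand years)
#' using the generation time in `constants`.
#'
#' Structure (backwards in time): Denisovan pulse into PNG at event(T_DPM);
#' ghost pulse into PNG (ghost models only) midway between the Denisovan
#' pulse and the PNG split; modern splits per the model topology with
#' exponential growth of EUR/ASN/PNG from their pre-growth sizes at their own
#' split times; Neanderthal pulse into the common out-of-Africa (OOA) branch
#' at event(T_NOM); OOA merges into AFR at event(T_B); AFR changes from N_AF
#' to the ancestral size N_A at event(T_AF); introgressing archaic branches
#' merge into the sequenced ones at event(T_NI_NS)/event(T_DI_DS); archaics
#' merge at event(T_N_D) with ancestral size N_ND, and into the modern
#' lineage at event(T_H_A).
#'
#' @param spec A [model_spec()].
#' @param params A `param_vector` valid for `spec`.
#' @param constants A [sim_constants()].
#' @return An object of class `demography_graph`.
#' @export
build_demography <- function(spec, params, constants = sim_constants()) {
  validate_params(params, spec)
  p <- as.list(params)
  ev_ky <- resolve_events(params, spec)
  gen <- function(ky) ky * 1000 / constants$generation_time
  e <- lapply(as.list(ev_ky), gen)  # event times in generations
  pops <- .pop_names_full
  if (!spec$has_ghost) pops <- pops[pops != "GHOST"]
  id <- function(nm) match(nm, pops) - 1L  # 0-based for the engine

  a_topology <- spec$model_id %in% c("A", "AX", "M")
  # own split times (generations) for the growing populations
  if (a_topology) {
    s_EUR <- e$T_EU_AS; s_ASN <- e$T_AS_PA; s_PNG <- e$T_AS_PA
  } else {
    s_EUR <- e$T_AS_PA; s_ASN <- e$T_AS_PA; s_PNG <- e$T_EU_AS
  }
  growth <- function(N_now, N0, dur) if (dur <= 0) 0 else log(N_now / N0) / dur

  ep <- list()
  add_ep <- function(pop, t0, N0, alpha = 0) ep[[length(ep) + 1L]] <<- c(id(pop), t0, N0, alpha)
  add_ep("AFR", 0, p$N_AF)
  add_ep("AFR", e$T_AF, p$N_A)
  add_ep("EUR", 0, p$N_EU, growth(p$N_EU, p$N_EU0, s_EUR))
  add_ep("ASN", 0, p$N_AS, growth(p$N_AS, p$N_AS0, s_ASN))
  add_ep("ASN", s_ASN, p$N_AS0)
  add_ep("PNG", 0, p$N_PA, growth(p$N_PA, p$N_PA0, s_PNG))
  add_ep("PNG", s_PNG, p$N_PA0)
  add_ep("OOA", 0, p$N_B)
  add_ep("NEA", 0, p$N_NE)
  add_ep("NEA", e$T_N_D, p$N_ND)  # archaic ancestor continues on this branch
  add_ep("DEN", 0, p$N_DE)
  add_ep("NEAI", 0, p$N_NE)
  add_ep("DENI", 0, p$N_DE)

  evs <- list()
  add_ev <- function(t, kind, from, to, prob = 0)
    evs[[length(evs) + 1L]] <<- c(t, kind, id(from), id(to), prob)
  # archaic pulses (backwards: recipients move into the introgressing branch)
  add_ev(e$T_DPM, 1, "PNG", "DENI", p$DEN_m_PAP)
  add_ev(e$T_NOM, 1, "OOA", "NEAI", p$NEA_m_OOA)
  # modern splits
  if (a_topology) {
    add_ev(e$T_AS_PA, 0, "PNG", "ASN")
    add_ev(e$T_EU_AS, 0, "EUR", "OOA")
    add_ev(e$T_EU_AS, 0, "ASN", "OOA")
  } else {
    add_ev(e$T_AS_PA, 0, "EUR", "ASN")
    add_ev(e$T_EU_AS, 0, "ASN", "OOA")
    add_ev(e$T_EU_AS, 0, "PNG", "OOA")
  }
  add_ev(e$T_B, 0, "OOA", "AFR")
  add_ev(e$T_NI_NS, 0, "NEAI", "NEA")
  add_ev(e$T_DI_DS, 0, "DENI", "DEN")
  add_ev(e$T_N_D, 0, "DEN", "NEA")
  add_ev(e$T_H_A, 0, "NEA", "AFR")

  if (spec$has_ghost) {
    png_split <- if (a_topology) e$T_AS_PA else e$T_EU_AS
    t_gp <- (e$T_DPM + png_split) / 2  # ghost pulse into PNG
    if (spec$model_id == "M") {
      t_gd <- e$T_EU_AS + p$ghost_tf * (e$T_B - e$T_EU_AS)
      add_ep("GHOST", 0, p$N_B)
      add_ev(t_gd, 0, "GHOST", "OOA")
    } else {
      t_gd <- e$T_B + p$ghost_tf * gen(60)
      add_ep("GHOST", 0, p$N_A)
      add_ev(t_gd, 0, "GHOST", "AFR")
    }
    add_ev(t_gp, 1, "PNG", "GHOST", p$ghost_m)
  }

  mig <- matrix(numeric(0), ncol = 5)
  if (spec$migration_variant != "none") {
    # each pair migrates while both lineages exist as distinct populations;
    # ASN persists as the sister-pair ancestor until the older split
    ends <- c(AFR = Inf, EUR = s_EUR, ASN = e$T_EU_AS, PNG = s_PNG)
    pr <- utils::combn(c("AFR", "EUR", "ASN", "PNG"), 2)
    mig <- t(vapply(seq_len(ncol(pr)), function(k) {
      i <- pr[1, k]; j <- pr[2, k]
      rate <- p[[paste0("m_", i, "_", j)]]
      c(id(i), id(j), rate, 0, min(ends[i], ends[j]))
    }, numeric(5)))
    mig <- rbind(mig, mig[, c(2, 1, 3, 4, 5)])  # symmetric
    mig <- mig[mig[, 3] > 0, , drop = FALSE]
    if (!length(mig)) mig <- matrix(numeric(0), ncol = 5)
  }

  # event-ordering validity (a draw violating these is rejected)
  if (!(e$T_DPM < e$T_AS_PA && e$T_AS_PA <= e$T_EU_AS && e$T_EU_AS < e$T_NOM &&
        e$T_NOM < e$T_B && e$T_B < e$T_AF))
    stop("invalid draw: modern event chain out of order")
  if (!(e$T_NI_NS < e$T_N_D && e$T_DI_DS < e$T_N_D && e$T_N_D < e$T_H_A))
    stop("invalid draw: archaic event chain out of order")
  ages <- gen(spec$archaic_ages_ky)
  if (ages["NEA"] >= e$T_N_D || ages["DEN"] >= e$T_DI_DS)
    stop("invalid draw: archaic sampling age older than its branch")

  structure(list(
    npop = length(pops), pop_names = pops,
    epochs = do.call(rbind, ep), events = do.call(rbind, evs), mig = mig,
    constants = constants, spec = spec, params = params,
    sample_ages_gen = c(AFR = 0, EUR = 0, ASN = 0, PNG = 0,
                        NEA = unname(ages["NEA"]), DEN = unname(ages["DEN"]))),
    class = "demography_graph")
}

#' Minimal out-of-Africa model for RCCR experiments
#'
#' A three-population toy: an African population (constant size 10,000), a
#' European-like population growing at 0.2% per generation from a 10,000
#' bottleneck, and a PNG-like population with a configurable bottleneck size
#' and growth rate. EUR and PNG diverge 50 kya from a common out-of-Africa
#' branch (size 10,000) that splits from Africa at `african_split_kya`.
#'
#' @param png_bottleneck_size Diploid bottleneck size in `[500, 10000]`.
#' @param png_growth_rate Per-generation growth rate in `[0, 0.002]`.
#' @param african_split_kya 80 (canonical) or 300 (San-like early split).
#' @return An object of class `minimal_model_spec`.
#' @export
minimal_model_spec <- function(png_bottleneck_size = 500, png_growth_rate = 0,
                               african_split_kya = 80) {
  stopifnot(png_bottleneck_size >= 500, png_bottleneck_size <= 10000,
            png_growth_rate >= 0, png_growth_rate <= 0.002,
            african_split_kya %in% c(80, 300))
  structure(list(png_bottleneck_size = png_bottleneck_size,
                 png_growth_rate = png_growth_rate,
                 african_split_kya = african_split_kya,
                 ancestral_size = 10000, eur_growth_rate = 0.002,
                 eur_png_split_kya = 50),
            class = "minimal_model_spec")
}

#' @rdname minimal_model_spec
#' @param mspec A `minimal_model_spec`.
#' @param constants A [sim_constants()].
#' @return `build_minimal_demography()` returns a `demography_graph` with
#'   populations AFR, EUR, PNG and the internal OOA branch.
#' @export
build_minimal_demography <- function(mspec, constants = sim_constants()) {
  stopifnot(inherits(mspec, "minimal_model_spec"))
  gen <- function(ky) ky * 1000 / constants$generation_time
  t_split <- gen(mspec$eur_png_split_kya)
  t_afr <- gen(mspec$african_split_kya)
  N <- mspec$ancestral_size
  eur_now <- N * exp(mspec$eur_growth_rate * t_split)
  png_now <- mspec$png_bottleneck_size * exp(mspec$png_growth_rate * t_split)
  pops <- c("AFR", "EUR", "PNG", "OOA")
  id <- function(nm) match(nm, pops) - 1L
  epochs <- rbind(
    c(id("AFR"), 0, N, 0),
    c(id("EUR"), 0, eur_now, mspec$eur_growth_rate),
    c(id("PNG"), 0, png_now, mspec$png_growth_rate),
    c(id("OOA"), 0, N, 0))
  events <- rbind(
    c(t_split, 0, id("EUR"), id("OOA"), 0),
    c(t_split, 0, id("PNG"), id("OOA"), 0),
    c(t_afr, 0, id("OOA"), id("AFR"), 0))
  structure(list(npop = 4L, pop_names = pops, epochs = epochs, events = events,
                 mig = matrix(numeric(0), ncol = 5), constants = constants,
                 spec = mspec, params = NULL,
                 sample_ages_gen = c(AFR = 0, EUR = 0, PNG = 0)),
            class = "demography_graph")
}

#' Per-population sample configuration
#'
#' @param counts Named vector of diploid sample counts (names must be
#'   population names of the demography they are used with).
#' @param ages_years Named vector of sampling ages in years ago (defaults to
#'   0 for every population).
#' @return An object of class `sample_config`.
#' @export
sample_config <- function(counts, ages_years = NULL) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  if (is.null(ages_years)) ages_years <- setNames(rep(0, length(counts)), names(counts))
  stopifnot(identical(sort(names(counts)), sort(names(ages_years))))
  structure(list(counts = counts, ages_years = ages_years[names(counts)]),
            class = "sample_config")
}

#' Canonical cSFS sample configuration
#'
#' Five diploids from each modern population (AFR, EUR, ASN, PNG) sampled at
#' present plus one Neanderthal (120 kya) and one Denisovan (60 kya).
#'
#' @param n_modern Diploids per modern population (default 5).
#' @return A [sample_config()].
#' @export
canonical_sample_config <- function(n_modern = 5) {
  sample_config(
    counts = c(AFR = n_modern, EUR = n_modern, ASN = n_modern, PNG = n_modern,
               NEA = 1, DEN = 1),
    ages_years = c(AFR = 0, EUR = 0, ASN = 0, PNG = 0,
                   NEA = 120000, DEN = 60000))
}
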