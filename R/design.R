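#' Default chromosome lengths (bp)
#'
#' Five major chromosomes of roughly 26-30 Mb, the scale of the *D. virilis*
#' assembly used for backcross genotyping. The dot chromosome (6) carries too
#' few markers to map and is excluded by default throughout.
#'
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
default_chromosomes <- function() {
  c(X = 29.5e6, `2` = 28e6, `3` = 26e6, `4` = 27e6, `5` = 26e6)
}

#' Describe a backcross study design
#'
#' A `study_design` fixes everything the cohort simulator needs: the genome,
#' the mothers and their cohort-size distributions, the meiotic crossover
#' rate, the mitotic cluster parameters (alpha = per-mother per-chromosome
#' event probability, beta = transmission frequency among progeny given an
#' event), chromatid segregation mode weights, and the sequencing noise
#' model. Defaults reflect the published BC1 experiment: 66 low-fecundity
#' dysgenic, 7 high-fecundity dysgenic and 20 non-dysgenic F1 mothers, a
#' 1.46 expected crossovers per chromosome per gamete (732 cM over five
#' chromosomes), alpha = 0.12 and beta of 0.78 (dysgenic) / 0.11
#' (non-dysgenic).
#'
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param n_mothers named integer vector: mothers per group. Groups are
#'   `dysgenic_low`, `dysgenic_high` (fecundity classes of dysgenic mothers)
#'   and `nondysgenic`.
#' @param cohort_size per-group list of `list(mean, min, max)`; cohort sizes
#'   are Poisson draws clipped to `[min, max]`.
#' @param expected_co expected meiotic crossovers per chromosome per gamete.
#' @param interference_min_sep minimum distance (bp) between crossovers on
#'   one gamete, a simple crossover-interference stand-in.
#' @param alpha,beta mitotic cluster formation probability and transmission
#'   frequency, named by condition (`dysgenic`, `nondysgenic`).
#' @param mode_weights probabilities of X vs Z chromatid segregation for a
#'   mitotic event (X produces distal LOH, Z balanced reciprocal products).
#' @param n_markers markers per chromosome (uniformly spaced).
#' @param coverage mean reads per marker (Poisson lambda).
#' @param error per-read allele miscall probability, in `[0, 0.5)`.
#' @param min_progeny carriers needed for a cluster to be observable.
#' @param n_batches library batches to assign samples to, round-robin.
#' @param seed integer seed owned by the design.
#' @return An object of class `study_design` (a validated list).
#' @export
study_design <- function(chromosomes = default_chromosomes(),
                         n_mothers = c(dysgenic_low = 66, dysgenic_high = 7,
                                       nondysgenic = 20),
                         cohort_size = list(
                           dysgenic_low  = list(mean = 4.7,  min = 1,  max = 20),
                           dysgenic_high = list(mean = 34.6, min = 20, max = 40),
                           nondysgenic   = list(mean = 13.8, min = 1,  max = 20)),
                         expected_co = 1.46,
                         interference_min_sep = 5e6,
                         alpha = c(dysgenic = 0.12, nondysgenic = 0.12),
                         beta = c(dysgenic = 0.78, nondysgenic = 0.11),
                         mode_weights = c(X = 0.75, Z = 0.25),
                         n_markers = 1000L,
                         coverage = 2,
                         error = 0.001,
                         min_progeny = 4L,
                         n_batches = 8L,
                         seed = 1L) {
  design <- list(chromosomes = chromosomes, n_mothers = n_mothers,
                 cohort_size = cohort_size, expected_co = expected_co,
                 interference_min_sep = interference_min_sep,
                 alpha = alpha, beta = beta, mode_weights = mode_weights,
                 n_markers = as.integer(n_markers), coverage = coverage,
                 error = error, min_progeny = as.integer(min_progeny),
                 n_batches = as.integer(n_batches), seed = as.integer(seed))
  class(design) <- "study_design"
  validate_design(design)
  design
}

validate_design <- function(d) {
  stopifnot(inherits(d, "study_design"))
  if (length(d$chromosomes) < 1L || any(d$chromosomes <= 0))
    stop("chromosome lengths must be positive")
  if (is.null(names(d$chromosomes))) stop("chromosomes must be named")
  groups <- names(d$n_mothers)
  if (any(d$n_mothers < 0)) stop("n_mothers must be non-negative")
  if (sum(d$n_mothers) == 0) stop("empty design: no mothers")
  if (!all(groups %in% names(d$cohort_size)))
    stop("cohort_size must cover every mother group")
  for (cs in d$cohort_size[groups]) {
    if (cs$min < 0 || cs$max < cs$min) stop("invalid cohort size bounds")
  }
  if (d$expected_co < 0) stop("expected_co must be >= 0")
  for (p in c(d$alpha, d$beta)) {
    if (p < 0 || p > 1) stop("alpha and beta must lie in [0, 1]")
  }
  if (d$error < 0 || d$error >= 0.5) stop("error must lie in [0, 0.5)")
  if (d$coverage < 0) stop("coverage must be >= 0")
  if (abs(sum(d$mode_weights) - 1) > 1e-8)
    stop("mode_weights must sum to 1")
  if (!all(names(d$mode_weights) %in% c("X", "Z")))
    stop("segregation modes are 'X' and 'Z'")
  if (d$n_markers < 2L) stop("need at least 2 markers per chromosome")
  invisible(d)
}

#' Condition (dysgenic/non-dysgenic) of a mother group
#' @param group character vector of group labels.
#' @return `"dysgenic"` or `"nondysgenic"` per element.
#' @export
group_condition <- function(group) {
  ifelse(grepl("^dysgenic", group), "dysgenic", "nondysgenic")
}
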