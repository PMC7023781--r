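#' Build a uniformly spaced marker map
#'
#' Markers are parental-diagnostic biallelic SNPs (strain 160 vs strain 9)
#' placed deterministically at the midpoints of `n_markers` equal bins, so
#' mean spacing is `length / n_markers`. Positions are 0-based bp
#' internally; CSV/TSV writers convert to 1-based.
#'
#' @param chromosomes named numeric vector of chromosome lengths (bp), or a
#'   `study_design`.
#' @param n_markers markers per chromosome; ignored when `density` is given.
#' @param density markers per bp (e.g. `1/136` emulates the real SNP
#'   density); marker count is `floor(length * density)`.
#' @return `data.table` with columns `chrom`, `pos` (0-based bp, strictly
#'   increasing within chromosome).
#' @export
make_marker_map <- function(chromosomes, n_markers = 500L, density = NULL) {
  if (inherits(chromosomes, "study_design")) {
    n_markers <- chromosomes$n_markers
    chromosomes <- chromosomes$chromosomes
  }
  if (any(chromosomes <= 0)) stop("zero-length chromosome")
  maps <- lapply(names(chromosomes), function(cn) {
    len <- chromosomes[[cn]]
    m <- if (is.null(density)) as.integer(n_markers) else as.integer(floor(len * density))
    if (m < 2L) stop("need at least 2 markers on chromosome ", cn)
    data.table::data.table(chrom = cn, pos = (seq_len(m) - 0.5) * len / m)
  })
  out <- data.table::rbindlist(maps)
  data.table::setkey(out, chrom, pos)
  out[]
}

#' Sample meiotic crossover positions for gametes
#'
#' Crossover counts are Poisson with the requested mean; positions are
#' uniform on the chromosome subject to a minimum inter-crossover distance
#' (crossover interference stand-in). The spacing constraint is imposed by
#' the exact construction (uniform draws on the shrunk interval plus offsets)
#' so counts keep their Poisson distribution; counts are capped at
#' `floor(len / min_sep)`, the largest feasible number.
#'
#' @param chrom_len chromosome length (bp).
#' @param n_gametes number of gametes to draw.
#' @param expected_co mean crossovers per gamete.
#' @param min_sep minimum distance (bp) between crossovers on one gamete.
#' @return List of sorted numeric position vectors, one per gamete.
#' @export
sample_meiotic_crossovers <- function(chrom_len, n_gametes, expected_co,
                                      min_sep = 5e6) {
  stopifnot(expected_co >= 0, chrom_len > 0, min_sep >= 0)
  if (min_sep >= chrom_len && expected_co > 1)
    stop("min_sep >= chromosome length with expected_co > 1 is infeasible")
  kmax <- if (min_sep > 0) max(1L, as.integer(floor(chrom_len / min_sep))) else .Machine$integer.max
  k <- pmin(stats::rpois(n_gametes, expected_co), kmax)
  lapply(k, function(ki) {
    if (ki == 0L) return(numeric(0))
    slack <- chrom_len - (ki - 1) * min_sep
    sort(stats::runif(ki, 0, slack)) + (seq_len(ki) - 1) * min_sep
  })
}

#' Draw one mitotic cluster event for a cohort
#'
#' With probability `alpha` a mitotic exchange arises in the mother's early
#' germline on this chromosome; given the event, each progeny independently
#' inherits a recombinant chromatid with probability `beta`. Under X
#' segregation the recombinant daughter cell is homozygous distal to the
#' event (LOH), so all carriers share one distal genotype; under Z
#' segregation the two reciprocal products are transmitted in roughly equal
#' numbers.
#'
#' @param n cohort size.
#' @param alpha event probability per mother-chromosome.
#' @param beta carrier probability per progeny given the event.
#' @param mode_weights named weights for X and Z segregation.
#' @param chrom_len chromosome length (bp) for the uniform event position.
#' @return List with `event` (logical), and when `TRUE`: `pos`, `mode`,
#'   `carriers` (logical of length `n`), `loh_genotype` (X mode; 1 = het,
#'   0 = hom-9).
#' @export
sample_mitotic_cluster <- function(n, alpha, beta,
                                   mode_weights = c(X = 0.75, Z = 0.25),
                                   chrom_len = 25e6) {
  stopifnot(n >= 0, alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  if (stats::runif(1) >= alpha) return(list(event = FALSE))
  list(event = TRUE,
       pos = stats::runif(1, 0, chrom_len),
       mode = sample(names(mode_weights), 1L, prob = mode_weights),
       carriers = stats::runif(n) < beta,
       loh_genotype = stats::rbinom(1, 1, 0.5))
}

# Genotype vector (1 = het 160/9, 0 = hom 9/9) at marker positions, given a
# start state and the sorted flip points of the gamete.
genotype_from_flips <- function(marker_pos, start_state, flips) {
  n_flips <- findInterval(marker_pos, sort(flips))
  (start_state + n_flips) %% 2L
}

#' Simulate a full backcross study with known truth
#'
#' Every BC1 sample's chromosome is a mosaic of heterozygous (160/9) and
#' homozygous (9/9) blocks delimited by its true meiotic crossovers; mothers
#' may additionally carry at most one mitotic event per chromosome whose
#' recombinant chromatid is shared by several siblings. X-mode carriers are
#' uniformly one genotype distal to the event (LOH, so distal meiotic
#' crossovers are invisible and are dropped from the truth); Z-mode carriers
#' always show the shared breakpoint, with reciprocal orientations set by
#' the meiotic state proximal to the event (~1:1).
#'
#' @param design a [study_design()].
#' @param seed optional integer overriding `design$seed`.
#' @return List with `samples` (sample table: `sample`, `mother`, `group`,
#'   `condition`, `fecundity`, `batch`, `read_count` = NA until reads are
#'   emitted), `map` (marker map), `genotypes` (per-chromosome integer
#'   matrix, markers x samples, 1 = het / 0 = hom-9), and `truth` (list:
#'   `meiotic` crossover table, `mitotic` event table with carrier lists).
#' @export
synthesize_study <- function(design, seed = NULL) {
  validate_design(design)
  set.seed(if (is.null(seed)) design$seed else as.integer(seed))
  map <- make_marker_map(design$chromosomes, design$n_markers)

  groups <- names(design$n_mothers)
  mothers <- data.table::rbindlist(lapply(groups, function(g) {
    ng <- design$n_mothers[[g]]
    if (ng == 0L) return(NULL)
    cs <- design$cohort_size[[g]]
    pre <- toupper(paste0(substr(g, 1, 1),
                          substr(sub("^[^_]*_?", "", g), 1, 1), "M"))
    data.table::data.table(
      mother = sprintf("%s%03d", pre, seq_len(ng)),
      group = g,
      cohort = pmin(pmax(stats::rpois(ng, cs$mean), cs$min), cs$max))
  }))
  mothers[, mother := make.unique(mother)]
  if (nrow(mothers) == 0L || sum(mothers$cohort) == 0L)
    stop("empty design: no progeny to simulate")

  samples <- mothers[rep(seq_len(.N), cohort)]
  samples[, sample := sprintf("%s_s%02d", mother, seq_len(.N)), by = mother]
  samples[, fecundity := data.table::fcase(group == "dysgenic_low", "low",
                                           group == "dysgenic_high", "high",
                                           default = "na")]
  samples[, condition := group_condition(group)]
  samples[, batch := ((seq_len(.N) - 1L) %% max(1L, design$n_batches)) + 1L]
  samples[, read_count := NA_real_]
  data.table::setcolorder(samples,
    c("sample", "mother", "group", "condition", "fecundity", "batch",
      "read_count", "cohort"))

  chroms <- names(design$chromosomes)
  genotypes <- vector("list", length(chroms))
  names(genotypes) <- chroms
  meiotic <- list(); mitotic <- list()

  for (cn in chroms) {
    len <- design$chromosomes[[cn]]
    mpos <- map[chrom == cn, pos]
    gm <- matrix(0L, nrow = length(mpos), ncol = nrow(samples),
                 dimnames = list(NULL, samples$sample))
    for (mi in seq_len(nrow(mothers))) {
      mom <- mothers$mother[mi]
      cond <- group_condition(mothers$group[mi])
      ids <- samples[mother == mom, sample]
      n <- length(ids)
      cos <- sample_meiotic_crossovers(len, n, design$expected_co,
                                       design$interference_min_sep)
      start <- stats::rbinom(n, 1, 0.5)
      ev <- sample_mitotic_cluster(n, design$alpha[[cond]],
                                   design$beta[[cond]],
                                   design$mode_weights, len)
      carriers <- if (isTRUE(ev$event)) ev$carriers else rep(FALSE, n)
      for (j in seq_len(n)) {
        flips <- cos[[j]]
        if (carriers[j]) {
          if (ev$mode == "X") {
            flips <- flips[flips < ev$pos]
            g <- genotype_from_flips(mpos, start[j], flips)
            g[mpos >= ev$pos] <- ev$loh_genotype
          } else {
            # Z: obligate flip at the event; downstream meiotic COs still flip
            g <- genotype_from_flips(mpos, start[j], sort(c(flips, ev$pos)))
          }
        } else {
          g <- genotype_from_flips(mpos, start[j], flips)
        }
        gm[, ids[j]] <- g
        if (length(flips))
          meiotic[[length(meiotic) + 1L]] <-
            data.table::data.table(sample = ids[j], chrom = cn, pos = flips)
      }
      if (isTRUE(ev$event))
        mitotic[[length(mitotic) + 1L]] <- data.table::data.table(
          mother = mom, chrom = cn, pos = ev$pos, mode = ev$mode,
          loh_genotype = if (ev$mode == "X") ev$loh_genotype else NA_integer_,
          n_carriers = sum(carriers),
          carriers = list(ids[carriers]))
    }
    genotypes[[cn]] <- gm
  }

  list(samples = samples, map = map, genotypes = genotypes,
       truth = list(
         meiotic = if (length(meiotic)) data.table::rbindlist(meiotic)
                   else data.table::data.table(sample = character(),
                                               chrom = character(),
                                               pos = numeric()),
         mitotic = if (length(mitotic)) data.table::rbindlist(mitotic)
                   else data.table::data.table(mother = character(),
                                               chrom = character(),
                                               pos = numeric(),
                                               mode = character(),
                                               loh_genotype = integer(),
                                               n_carriers = integer(),
                                               carriers = list())))
}

#' Emit shallow-coverage allele counts from genotype truth
#'
#' Per-marker read depth is Poisson(`coverage`), independent across markers
#' and samples (no mapping bias). A heterozygous marker emits a 160-strain
#' read with probability 0.5 (the symmetric error cancels); a homozygous
#' 9/9 marker emits 160 reads only through the per-read error `error`.
#' Only markers with at least one read are returned (long sparse format).
#'
#' @param study result of [synthesize_study()].
#' @param coverage mean reads per marker; defaults to the design's value if
#'   the study carries one, else 1.
#' @param error per-read allele miscall probability in `[0, 0.5)`.
#' @param seed optional integer seed.
#' @return List: `counts` (`data.table` `sample`, `chrom`, `pos`, `n160`,
#'   `n9`), and `samples` — the study sample table with `read_count`
#'   (total reads, zeros included) filled in.
#' @export
emit_allele_counts <- function(study, coverage = 1, error = 0.001,
                               seed = NULL) {
  stopifnot(coverage >= 0, error >= 0, error < 0.5)
  if (!is.null(seed)) set.seed(as.integer(seed))
  samples <- data.table::copy(study$samples)
  totals <- stats::setNames(numeric(nrow(samples)), samples$sample)
  out <- list()
  for (cn in names(study$genotypes)) {
    gm <- study$genotypes[[cn]]
    mpos <- study$map[chrom == cn, pos]
    n <- matrix(stats::rpois(length(gm), coverage), nrow = nrow(gm))
    p <- ifelse(gm == 1L, 0.5, error)
    n160 <- matrix(stats::rbinom(length(gm), as.vector(n), as.vector(p)),
                   nrow = nrow(gm))
    totals <- totals + stats::setNames(colSums(n), colnames(gm))[names(totals)]
    nz <- which(n > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      out[[cn]] <- data.table::data.table(
        sample = colnames(gm)[nz[, 2]], chrom = cn, pos = mpos[nz[, 1]],
        n160 = n160[nz], n9 = n[nz] - n160[nz])
    }
  }
  counts <- if (length(out)) data.table::rbindlist(out)
            else data.table::data.table(sample = character(),
                                        chrom = character(), pos = numeric(),
                                        n160 = integer(), n9 = integer())
  data.table::setkey(counts, sample, chrom, pos)
  samples[, read_count := totals[sample]]
  list(counts = counts[], samples = samples)
}

#' Simulate a study and its sequencing reads in one call
#'
#' @inheritParams synthesize_study
#' @return The [synthesize_study()] list with `counts` added and
#'   `samples$read_count` filled.
#' @export
simulate_dataset <- function(design, seed = NULL) {
  study <- synthesize_study(design, seed = seed)
  emitted <- emit_allele_counts(study, coverage = design$coverage,
                                error = design$error)
  study$counts <- emitted$counts
  study$samples <- emitted$samples
  study
}
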