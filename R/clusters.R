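#' Detect sibling-shared (mitotic) recombination clusters
#'
#' A cluster is a set of crossovers in `min_progeny` or more distinct
#' progeny of one mother whose midpoints fit within a `window_bp` span on
#' one chromosome. A 100 kb window slides across the sorted midpoints of
#' each mother-chromosome (event-anchored spans); the maximal-carrier set
#' is kept and at most one cluster per mother-chromosome is reported.
#' Deterministic and invariant to sample order.
#'
#' @param records kept crossover records.
#' @param samples sample table (`sample`, `mother`, and optionally `group`,
#'   `condition`).
#' @param window_bp span (bp) the shared breakpoints must fit in.
#' @param min_progeny minimum number of distinct carrier progeny.
#' @return `data.table`: `mother`, `condition`, `chrom`, `start`, `end`
#'   (bp span of the supporting crossovers), `x` (carriers), `N` (cohort
#'   size), `carriers` (list of sample ids).
#' @export
detect_clusters <- function(records, samples, window_bp = 100e3,
                            min_progeny = 4L) {
  recs <- kept(data.table::as.data.table(records))
  sdt <- data.table::as.data.table(samples)
  recs[, mother := sdt$mother[match(sample, sdt$sample)]]
  cohort_n <- sdt[, .(N = .N), by = mother]
  cond <- if ("condition" %in% names(sdt))
    sdt[, .(condition = condition[1]), by = mother]
  else cohort_n[, .(mother, condition = NA_character_)]
  empty <- data.table::data.table(mother = character(),
                                  condition = character(),
                                  chrom = character(), start = numeric(),
                                  end = numeric(), x = integer(),
                                  N = integer(), carriers = list())
  if (nrow(recs) == 0L) return(empty)
  data.table::setkey(recs, mother, chrom, mid, sample)
  found <- recs[, {
    o <- order(mid, sample)
    m <- mid[o]; sm <- sample[o]
    best_x <- 0L; best <- integer(0)
    for (i in seq_along(m)) {
      j <- findInterval(m[i] + window_bp, m)
      idx <- i:j
      xi <- length(unique(sm[idx]))
      if (xi > best_x) { best_x <- xi; best <- idx }
    }
    if (best_x >= min_progeny)
      .(start = m[best[1]], end = m[best[length(best)]],
        x = best_x, carriers = list(sort(unique(sm[best]))))
    else NULL
  }, by = .(mother, chrom)]
  if (nrow(found) == 0L) return(empty)
  found[cohort_n, N := i.N, on = "mother"]
  found[cond, condition := i.condition, on = "mother"]
  data.table::setcolorder(found, c("mother", "condition", "chrom", "start",
                                   "end", "x", "N", "carriers"))
  data.table::setkey(found, mother, chrom)
  found[]
}

#' Transmission distortion test against 1:1 inheritance
#'
#' Chi-squared goodness of fit and exact two-sided binomial test of the
#' het vs hom-9 genotype counts in a region. When the binomial p-value
#' falls below `p_threshold` the over-transmitted genotype is labelled:
#' excess heterozygotes mean the strain-160 haplotype is over-transmitted.
#'
#' @param n_het,n_hom counts of confidently heterozygous and homozygous-9
#'   progeny in the region.
#' @param p_threshold label threshold (Bonferroni-adjust upstream).
#' @return List: `n_het`, `n_hom`, `chisq`, `chisq_p`, `binom_p`,
#'   `distortion` (`"none"`, `"strain_160"`, `"strain_9"`).
#' @export
distortion_test <- function(n_het, n_hom, p_threshold = 0.01) {
  n <- n_het + n_hom
  if (n == 0L) stop("region with no confidently genotyped progeny")
  chisq <- (n_het - n_hom)^2 / n
  bt <- stats::binom.test(n_het, n, p = 0.5)
  lab <- "none"
  if (bt$p.value < p_threshold)
    lab <- if (n_het > n_hom) "strain_160" else "strain_9"
  list(n_het = n_het, n_hom = n_hom, chisq = chisq,
       chisq_p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       binom_p = bt$p.value, distortion = lab)
}

#' Count confidently genotyped progeny in a region
#'
#' Classifies each sample by its posterior track restricted to
#' `[from, to]`: heterozygous if more markers are confidently het than
#' confidently hom-9, and vice versa; samples with no confident markers are
#' ambiguous and excluded.
#'
#' @param posteriors long posterior table (`sample`, `chrom`, `pos`,
#'   `p_het`).
#' @param chrom_name chromosome of the region.
#' @param from,to region bounds (bp).
#' @param params an [hmm_params()] (thresholds).
#' @return List: `n_het`, `n_hom`, `n_ambiguous`.
#' @export
region_genotype_counts <- function(posteriors, chrom_name, from, to,
                                   params = hmm_params()) {
  pdt <- data.table::as.data.table(posteriors)
  reg <- pdt[chrom == chrom_name & pos >= from & pos <= to]
  cls <- reg[, .(het = sum(p_het > params$hi), hom = sum(p_het < params$lo)),
             by = sample]
  list(n_het = sum(cls$het > cls$hom),
       n_hom = sum(cls$hom > cls$het),
       n_ambiguous = sum(cls$het == cls$hom))
}

#' Reciprocal product balance within a cluster
#'
#' Carriers of a shared mitotic breakpoint fall into two orientations —
#' het-to-hom or hom-to-het across the cluster window (the two reciprocal
#' crossover products). Under Z segregation these are expected 1:1; tested
#' with the exact two-sided binomial test and the chi-squared statistic.
#' Carriers with zero or multiple crossovers in the window are ambiguous
#' and excluded (reported).
#'
#' @param cluster one row of [detect_clusters()] output.
#' @param records kept crossover records (with `dir`).
#' @return List: `n_het_to_hom`, `n_hom_to_het`, `n_ambiguous`, `chisq`,
#'   `binom_p`.
#' @export
reciprocal_balance_test <- function(cluster, records) {
  recs <- kept(data.table::as.data.table(records))
  ids <- cluster$carriers[[1]]
  inwin <- recs[sample %in% ids & chrom == cluster$chrom &
                mid >= cluster$start & mid <= cluster$end]
  per <- inwin[, .(n = .N, dir = dir[1]), by = sample]
  ok <- per[n == 1L]
  n_ambig <- length(ids) - nrow(ok)
  a <- sum(ok$dir == "het_to_hom"); b <- sum(ok$dir == "hom_to_het")
  if (a + b == 0L) stop("no unambiguous carriers in cluster window")
  list(n_het_to_hom = a, n_hom_to_het = b, n_ambiguous = n_ambig,
       chisq = (a - b)^2 / (a + b),
       binom_p = stats::binom.test(a, a + b, 0.5)$p.value)
}

#' Transposon overlap enrichment of cluster windows
#'
#' Success: a cluster window overlaps at least one annotated intact TE.
#' Background probability: the fraction of `window_bp` tiling windows of
#' the genome overlapping such a TE. One-sided binomial test for
#' enrichment.
#'
#' @param clusters [detect_clusters()] output.
#' @param te_granges `GRanges` of intact TE insertions (e.g. from
#'   [read_annotation_bed()]).
#' @param chrom_lengths named chromosome lengths (bp).
#' @param window_bp width of cluster/background windows.
#' @return List: `n_clusters`, `n_overlap`, `background`, `p`,
#'   `degenerate` (background 0 with successes).
#' @export
te_overlap_enrichment <- function(clusters, te_granges, chrom_lengths,
                                  window_bp = 100e3) {
  sl <- chrom_lengths
  tiles <- GenomicRanges::tileGenome(sl, tilewidth = window_bp,
                                     cut.last.tile.in.chrom = TRUE)
  bg <- mean(IRanges::overlapsAny(tiles, te_granges))
  cl <- data.table::as.data.table(clusters)
  half_pad <- pmax(0, (window_bp - (cl$end - cl$start)) / 2)
  cw <- GenomicRanges::GRanges(cl$chrom,
          IRanges::IRanges(start = pmax(1, floor(cl$start - half_pad) + 1),
                           end = ceiling(cl$end + half_pad)))
  succ <- sum(IRanges::overlapsAny(cw, te_granges))
  k <- nrow(cl)
  if (bg == 0 && succ > 0)
    return(list(n_clusters = k, n_overlap = succ, background = 0,
                p = 0, degenerate = TRUE))
  p <- stats::pbinom(succ - 1, k, bg, lower.tail = FALSE)
  list(n_clusters = k, n_overlap = succ, background = bg, p = p,
       degenerate = FALSE)
}

#' Probability of a by-chance sibling cluster
#'
#' Probability that `min_progeny` or more distinct progeny of one mother
#' have a crossover in a common window of the `floor(L/w)` tiling grid,
#' under independent uniform crossover placement with per-gamete expected
#' count `expected_co`. `method = "analytic"` is the union (Bonferroni)
#' bound over that grid: number of windows times the binomial tail
#' `P(>= min_progeny of N progeny hit a given window)` with per-gamete
#' per-window hit probability `expected_co * w / L`. `method =
#' "montecarlo"` simulates cohorts and evaluates the same grid-window
#' event, so the bound dominates the estimate by construction. Note that
#' [detect_clusters()] slides its span across crossover positions, which
#' is more sensitive than the fixed grid (roughly an order of magnitude
#' here); see the methods vignette.
#'
#' @param cohort_size N, progeny per mother.
#' @param expected_co expected crossovers per gamete on this chromosome.
#' @param chrom_len chromosome length (bp).
#' @param window_bp span width (bp).
#' @param min_progeny carriers required.
#' @param method `"analytic"` or `"montecarlo"`.
#' @param reps Monte Carlo replicates.
#' @param seed integer seed (Monte Carlo).
#' @return Probability (scalar).
#' @export
null_cluster_probability <- function(cohort_size, expected_co,
                                     chrom_len = 25e6, window_bp = 100e3,
                                     min_progeny = 4L,
                                     method = c("analytic", "montecarlo"),
                                     reps = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(cohort_size > 0, chrom_len > 0, window_bp > 0, expected_co >= 0)
  if (expected_co == 0) return(0)
  if (method == "analytic") {
    nwin <- floor(chrom_len / window_bp)
    p_gw <- min(1, expected_co * window_bp / chrom_len)
    p_win <- stats::pbinom(min_progeny - 1, cohort_size, p_gw,
                           lower.tail = FALSE)
    return(min(1, nwin * p_win))
  }
  set.seed(as.integer(seed))
  hits <- 0L
  for (r in seq_len(reps)) {
    k <- stats::rpois(cohort_size, expected_co)
    tot <- sum(k)
    if (tot < min_progeny) next
    owner <- rep.int(seq_len(cohort_size), k)
    win <- floor(stats::runif(tot, 0, chrom_len) / window_bp)
    # distinct progeny per grid window
    dp <- rowsum(rep(1L, tot), paste(win, owner))
    wn <- sub(" .*", "", rownames(dp))
    if (max(tabulate(factor(wn))) >= min_progeny) hits <- hits + 1L
  }
  hits / reps
}
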