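#' Genetic map lengths from crossover counts
#'
#' With whole-gamete crossover counts observed, the map length of a
#' chromosome is `100 * (total kept COs) / (gametes)` centiMorgans — the
#' mean crossover count per gamete times 100. Each BC1 sample is one
#' gamete.
#'
#' @param records kept crossover records (`sample`, `chrom`, `mid`).
#' @param n_gametes number of gametes genotyped on every chromosome.
#' @param chromosomes chromosome names to report (zero-crossover
#'   chromosomes included); defaults to those present in `records`.
#' @return `data.table`: `chrom`, `n_co`, `gametes`, `cM`; total map length
#'   in attribute `"total_cM"`.
#' @export
map_lengths <- function(records, n_gametes, chromosomes = NULL) {
  if (n_gametes <= 0) stop("zero gametes")
  recs <- kept(data.table::as.data.table(records))
  if (is.null(chromosomes)) chromosomes <- sort(unique(recs$chrom))
  counts <- recs[, .(n_co = .N), by = chrom]
  out <- data.table::data.table(chrom = chromosomes)
  out <- counts[out, on = "chrom"]
  out[is.na(n_co), n_co := 0L]
  out[, `:=`(gametes = n_gametes, cM = 100 * n_co / n_gametes)]
  data.table::setattr(out, "total_cM", sum(out$cM))
  out[]
}

#' Windowed recombination rates (cM/Mb)
#'
#' Windows tile `[0, chromosome length)`; a crossover belongs to the window
#' containing its midpoint. The per-window rate is
#' `100 * (COs / gametes) / (window Mb)`; summing `100 * COs / gametes`
#' over windows recovers the chromosome map length exactly.
#'
#' @param records kept crossover records.
#' @param n_gametes gametes per chromosome.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param window_bp window width (bp).
#' @return `data.table`: `chrom`, `start`, `end`, `mid`, `n_co`, `cM`,
#'   `rate` (cM/Mb).
#' @export
window_rates <- function(records, n_gametes, chrom_lengths,
                         window_bp = 500e3) {
  stopifnot(window_bp > 0, n_gametes > 0)
  recs <- kept(data.table::as.data.table(records))
  grids <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    s <- seq(0, len - 1e-9, by = window_bp)
    data.table::data.table(chrom = cn, start = s, end = pmin(s + window_bp, len))
  })
  grid <- data.table::rbindlist(grids)
  cnt <- recs[chrom %in% names(chrom_lengths),
              .(chrom, win = floor(mid / window_bp) * window_bp)]
  cnt <- cnt[, .(n_co = .N), by = .(chrom, start = win)]
  out <- cnt[grid, on = c("chrom", "start")]
  out[is.na(n_co), n_co := 0L]
  out[, `:=`(mid = (start + end) / 2,
             cM = 100 * n_co / n_gametes)]
  out[, rate := cM / ((end - start) / 1e6)]
  data.table::setkey(out, chrom, start)
  out[]
}

#' Loess-smoothed recombination rate curves
#'
#' Locally weighted regression (tricube weights, degree 2) of the windowed
#' rate against window midpoint, fitted per chromosome and evaluated at the
#' window midpoints with standard errors.
#'
#' @param rates window table from [window_rates()].
#' @param span loess span in `(0, 1]`.
#' @return `data.table`: `chrom`, `mid`, `rate`, `fitted`, `se`.
#' @export
smooth_rates <- function(rates, span = 0.3) {
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  rdt <- data.table::as.data.table(rates)
  rdt[, {
    if (.N < 5L) stop("need at least 5 windows per chromosome to smooth")
    fit <- stats::loess(rate ~ mid, span = span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    pr <- stats::predict(fit, se = TRUE)
    .(mid = mid, rate = rate, fitted = as.numeric(pr$fit),
      se = as.numeric(pr$se.fit))
  }, by = chrom]
}

#' Distribution of crossover counts per chromosome
#'
#' Proportion of sample-chromosomes carrying 0, 1, ..., 5+ crossovers,
#' optionally by group, with bootstrap confidence intervals obtained by
#' resampling progeny (not crossovers).
#'
#' @param records kept crossover records.
#' @param samples sample table (`sample`, `group`).
#' @param chromosomes chromosomes over which counts are formed.
#' @param by_group split by `group` column when `TRUE`.
#' @param n_boot bootstrap replicates (0 disables CIs).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return `data.table`: `group`, `n_co` (factor `0`..`5+`), `prop`, `lo`,
#'   `hi`.
#' @export
co_count_distribution <- function(records, samples, chromosomes = NULL,
                                  by_group = TRUE, n_boot = 1000,
                                  conf = 0.95, seed = 1L) {
  recs <- kept(data.table::as.data.table(records))
  sdt <- data.table::as.data.table(samples)
  if (!by_group || !"group" %in% names(sdt)) sdt[, group := "all"]
  if (is.null(chromosomes)) chromosomes <- sort(unique(recs$chrom))
  universe <- data.table::CJ(sample = sdt$sample, chrom = chromosomes)
  cnt <- recs[, .(k = .N), by = .(sample, chrom)][universe, on = c("sample", "chrom")]
  cnt[is.na(k), k := 0L]
  cnt[sdt, group := i.group, on = "sample"]
  lvls <- c(as.character(0:4), "5+")
  cnt[, cat := factor(ifelse(k >= 5, "5+", as.character(k)), levels = lvls)]
  props_of <- function(d) as.numeric(prop.table(table(d$cat)))
  point <- cnt[, .(n_co = lvls, prop = props_of(.SD)), by = group]
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    al <- (1 - conf) / 2
    cis <- cnt[, {
      ids <- unique(sample)
      bm <- replicate(n_boot, {
        pick <- sample(ids, length(ids), replace = TRUE)
        idx <- data.table::data.table(sample = pick)
        props_of(.SD[idx, on = "sample", allow.cartesian = TRUE])
      })
      .(n_co = lvls,
        lo = apply(bm, 1, stats::quantile, probs = al),
        hi = apply(bm, 1, stats::quantile, probs = 1 - al))
    }, by = group]
    point <- cis[point, on = c("group", "n_co")]
  } else {
    point[, `:=`(lo = NA_real_, hi = NA_real_)]
  }
  point[, n_co := factor(n_co, levels = lvls)]
  data.table::setcolorder(point, c("group", "n_co", "prop", "lo", "hi"))
  point[]
}

#' Correlate recombination rate with genomic features
#'
#' Pearson correlations between per-window recombination rate and each
#' feature column, per chromosome and over all windows ("total"), with and
#' without zero-recombination windows depending on `exclude_zero_co`.
#'
#' @param rates window table from [window_rates()].
#' @param features `data.table` keyed like `rates` on `chrom` and `start`,
#'   with one column per feature (e.g. TE density, gene density, GC).
#' @param exclude_zero_co drop windows with zero crossovers first.
#' @return `data.table`: `chrom` (including `"total"`), `feature`, `n`,
#'   `R`, `p` (`NA` when fewer than 3 windows remain).
#' @export
feature_correlations <- function(rates, features, exclude_zero_co = FALSE) {
  rdt <- data.table::as.data.table(rates)
  fdt <- data.table::as.data.table(features)
  feat_cols <- setdiff(names(fdt), c("chrom", "start", "end", "mid"))
  dt <- fdt[rdt, on = intersect(c("chrom", "start"), names(fdt)), nomatch = NULL]
  if (exclude_zero_co) dt <- dt[n_co > 0]
  one <- function(d, cn) {
    data.table::rbindlist(lapply(feat_cols, function(fc) {
      x <- d[[fc]]; y <- d$rate
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(data.table::data.table(chrom = cn, feature = fc,
                                      n = sum(ok), R = NA_real_, p = NA_real_))
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      data.table::data.table(chrom = cn, feature = fc, n = sum(ok),
                             R = unname(ct$estimate), p = ct$p.value)
    }))
  }
  per <- data.table::rbindlist(lapply(unique(dt$chrom),
                                      function(cn) one(dt[chrom == cn], cn)))
  rbind(per, one(dt, "total"))
}

#' Inter-crossover distances and between-group comparison
#'
#' Distances between adjacent kept crossovers on each sample-chromosome
#' (multi-crossover gametes only), compared between two groups with a
#' two-sided Mann-Whitney U test (exact for small samples without ties,
#' mid-rank normal approximation otherwise).
#'
#' @param records kept crossover records.
#' @param samples sample table with `sample` and a grouping column.
#' @param group_col name of the grouping column (default `"condition"`).
#' @return List: `distances` (`data.table` `group`, `sample`, `chrom`,
#'   `dist`), and `test` (the `htest`, or `NULL` with a message when a
#'   group has no multi-crossover chromosomes).
#' @export
interference_distances <- function(records, samples,
                                   group_col = "condition") {
  recs <- kept(data.table::as.data.table(records))
  sdt <- data.table::as.data.table(samples)
  data.table::setkey(recs, sample, chrom, mid)
  d <- recs[, if (.N >= 2L) .(dist = diff(mid)), by = .(sample, chrom)]
  d[, group := sdt[[group_col]][match(sample, sdt$sample)]]
  grps <- sort(unique(stats::na.omit(d$group)))
  test <- NULL
  if (length(grps) == 2L &&
      all(vapply(grps, function(g) sum(d$group == g) > 0, logical(1)))) {
    # ties fall back to the mid-rank normal approximation (warning silenced)
    test <- suppressWarnings(
      stats::wilcox.test(d[group == grps[1], dist],
                         d[group == grps[2], dist],
                         alternative = "two.sided"))
  } else {
    message("interference_distances: need two groups with multi-CO gametes; comparison undefined")
  }
  list(distances = d[], test = test)
}

#' Poisson likelihood-ratio comparison of crossover rates
#'
#' Tests whether two groups of per-gamete crossover counts share one
#' Poisson mean: `2 * (ll_separate - ll_shared)` is compared to chi-squared
#' with 1 df. A deliberate simplification standing in for a mixed-model
#' fit; mother-level random effects are not modelled.
#'
#' @param counts_a,counts_b non-negative integer crossover counts per
#'   gamete.
#' @return List: `rate_a`, `rate_b`, `ratio`, `statistic`, `df`, `p`.
#' @export
compare_co_rates <- function(counts_a, counts_b) {
  if (!length(counts_a) || !length(counts_b)) stop("empty group")
  if (any(c(counts_a, counts_b) < 0)) stop("counts must be non-negative")
  la <- mean(counts_a); lb <- mean(counts_b)
  l0 <- mean(c(counts_a, counts_b))
  ll <- function(x, lam) sum(stats::dpois(x, lam, log = TRUE))
  pois_ll <- function(x, lam) if (lam == 0) ifelse(all(x == 0), 0, -Inf) else ll(x, lam)
  stat <- 2 * (pois_ll(counts_a, la) + pois_ll(counts_b, lb) -
               pois_ll(c(counts_a, counts_b), l0))
  stat <- max(stat, 0)
  list(rate_a = la, rate_b = lb,
       ratio = if (lb > 0) la / lb else NA_real_,
       statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
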