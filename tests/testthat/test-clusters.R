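library(data.table)

test_that("cluster detection needs min_progeny distinct progeny in one span", {
  s <- sample_table(sprintf("p%02d", 1:32), mother = "5011",
                    group = "dysgenic_high")

  three <- records_from_mids(c("p01", "p02", "p03"), "3",
                             c(9.80e6, 9.83e6, 9.86e6))
  expect_equal(nrow(detect_clusters(three, s)), 0L)

  four <- records_from_mids(c("p01", "p02", "p03", "p04"), "3",
                            c(9.80e6, 9.83e6, 9.86e6, 9.89e6))
  cl <- detect_clusters(four, s)
  expect_equal(cl$x, 4L)
  expect_equal(cl$N, 32L)
  expect_lte(cl$end - cl$start, 100e3)

  # a 5011-like cohort: 28 of 32 progeny share a chr-3 breakpoint near 9.8 Mb
  set.seed(43)
  ids <- sprintf("p%02d", 1:28)
  shared <- records_from_mids(ids, "3", 9.8e6 + runif(28, -30e3, 30e3))
  noise <- records_from_mids(sample(s$sample, 40, replace = TRUE), "3",
                             runif(40, 15e6, 26e6))
  cl2 <- detect_clusters(rbind(shared, noise), s)
  expect_equal(cl2[start < 10e6, x], 28L)
  expect_equal(cl2[start < 10e6, N], 32L)

  # order invariance and min_progeny monotonicity
  shuf <- rbind(shared, noise)[sample(.N)]
  expect_equal(detect_clusters(shuf, s), cl2)
  n_cl <- vapply(3:8, function(mp)
    nrow(detect_clusters(rbind(shared, noise), s, min_progeny = mp)),
    numeric(1))
  expect_true(all(diff(n_cl) <= 0))
})

test_that("each progeny counts once and at most one cluster per mother-chromosome", {
  s <- sample_table(sprintf("p%d", 1:10), mother = "m1")
  dup <- records_from_mids(c("p1", "p1", "p1", "p2", "p3"), "3",
                           c(9.80e6, 9.82e6, 9.84e6, 9.86e6, 9.88e6))
  expect_equal(nrow(detect_clusters(dup, s)), 0L)  # only 3 distinct progeny

  two_sets <- records_from_mids(sprintf("p%d", 1:10), "3",
                                c(rep(5e6, 4) + 1:4 * 1e3,
                                  rep(20e6, 6) + 1:6 * 1e3))
  cl <- detect_clusters(two_sets, s)
  expect_equal(nrow(cl), 1L)     # widest-support set wins
  expect_equal(cl$x, 6L)
})

test_that("transmission distortion statistics match closed forms", {
  even <- distortion_test(14, 14)
  expect_equal(even$chisq, 0)
  expect_equal(even$binom_p, 1)
  expect_equal(even$distortion, "none")

  ext <- distortion_test(32, 0)
  expect_equal(ext$chisq, 32)
  expect_equal(ext$distortion, "strain_160")

  near <- distortion_test(10, 9)
  expect_equal(near$chisq, 1 / 19)
  expect_equal(near$distortion, "none")

  expect_equal(distortion_test(0, 20)$distortion, "strain_9")
  expect_error(distortion_test(0, 0), "no confidently genotyped")
})

test_that("region genotype counts classify progeny from posterior tracks", {
  pos <- seq(0, 9) * 1e5
  mk <- function(id, p) data.table(sample = id, chrom = "X", pos = pos, p_het = p)
  post <- rbind(mk("het1", rep(0.99, 10)), mk("hom1", rep(0.01, 10)),
                mk("amb1", rep(0.5, 10)))
  rc <- region_genotype_counts(post, "X", 0, 1e6)
  expect_equal(rc$n_het, 1L)
  expect_equal(rc$n_hom, 1L)
  expect_equal(rc$n_ambiguous, 1L)
})

test_that("reciprocal balance test matches the exact binomial", {
  s <- sample_table(sprintf("p%d", 1:12), mother = "m1")
  mids <- 9.8e6 + seq(-25e3, 25e3, length.out = 10)
  recs <- records_from_mids(sprintf("p%d", 1:10), "3", mids,
                            dir = rep(c("het_to_hom", "hom_to_het"), 5))
  cl <- detect_clusters(recs, s)
  bal <- reciprocal_balance_test(cl[1], recs)
  expect_equal(bal$n_het_to_hom, 5L)
  expect_equal(bal$n_hom_to_het, 5L)
  expect_equal(bal$binom_p, 1)

  one_way <- records_from_mids(sprintf("p%d", 1:10), "3", mids,
                               dir = "het_to_hom")
  cl2 <- detect_clusters(one_way, s)
  bal2 <- reciprocal_balance_test(cl2[1], one_way)
  expect_equal(bal2$binom_p, 2 * 0.5^10)

  # Z-mode simulated clusters: balance rarely rejected
  set.seed(47)
  ok <- replicate(40, {
    n <- 16
    orient <- rbinom(n, 1, 0.5)
    recs <- records_from_mids(sprintf("q%d", 1:n), "3",
                              9.8e6 + runif(n, -30e3, 30e3),
                              dir = ifelse(orient == 1, "het_to_hom",
                                           "hom_to_het"))
    sz <- sample_table(sprintf("q%d", 1:n), mother = "mz")
    clz <- detect_clusters(recs, sz)
    reciprocal_balance_test(clz[1], recs)$binom_p > 0.05
  })
  expect_gte(mean(ok), 0.9)
})

test_that("TE overlap enrichment matches the closed-form binomial", {
  lens <- c(`3` = 1e6)  # 10 windows of 100 kb
  te <- GenomicRanges::GRanges("3", IRanges::IRanges(
    start = seq(1, 9e5 + 1, by = 2e5), width = 1e3))  # odd windows only
  s <- sample_table(sprintf("p%d", 1:50),
                    mother = rep(sprintf("m%02d", 1:13), each = 4)[1:50])
  # five clusters, all centred in TE-bearing windows
  mk_cluster <- function(centres) {
    recs <- rbindlist(lapply(seq_along(centres), function(i) {
      ids <- s$sample[(i - 1) * 4 + 1:4]
      r <- records_from_mids(ids, "3", centres[i] + c(-9e3, -3e3, 3e3, 9e3))
      r
    }))
    detect_clusters(recs, s)
  }
  hits <- mk_cluster(c(0.3e5, 2.3e5, 4.3e5, 6.3e5, 8.3e5))
  en <- te_overlap_enrichment(hits, te, lens, window_bp = 1e5)
  expect_equal(en$background, 0.5)
  expect_equal(en$n_overlap, 5L)
  expect_equal(en$p, 0.5^5)

  misses <- mk_cluster(c(1.3e5, 3.3e5, 5.3e5, 7.3e5, 9.3e5))
  en0 <- te_overlap_enrichment(misses, te, lens, window_bp = 1e5)
  expect_equal(en0$n_overlap, 0L)
  expect_equal(en0$p, 1)

  # zero background with successes is degenerate (flagged, p = 0)
  end <- suppressWarnings(
    te_overlap_enrichment(hits, te, c(`4` = 1e6), window_bp = 1e5))
  expect_true(end$degenerate)
  expect_equal(end$p, 0)
})

test_that("anchoring clusters to TEs strengthens enrichment monotonically", {
  set.seed(53)
  lens <- c(`3` = 10e6)
  te <- GenomicRanges::GRanges("3", IRanges::IRanges(
    start = seq(1, 9.9e6, by = 1e6), width = 2e4))
  p_at <- vapply(c(0.1, 0.9), function(q) {
    centres <- ifelse(runif(40) < q,
                      sample(GenomicRanges::start(te), 40, TRUE) + 1e4,
                      runif(40, 0, 10e6))
    cl <- data.table(mother = sprintf("m%d", 1:40), condition = "dysgenic",
                     chrom = "3", start = centres - 5e3, end = centres + 5e3,
                     x = 4L, N = 10L, carriers = vector("list", 40))
    te_overlap_enrichment(cl, te, lens, window_bp = 1e5)$p
  }, numeric(1))
  expect_lt(p_at[2], p_at[1])
})

test_that("by-chance cluster probability: bound properties and degenerate cases", {
  expect_equal(null_cluster_probability(10, 0), 0)

  # min_progeny = 1 degenerates to P(any crossover in the cohort)
  mc1 <- null_cluster_probability(5, 0.5, min_progeny = 1,
                                  method = "montecarlo", reps = 2e4, seed = 2)
  expect_lt(abs(mc1 - (1 - exp(-5 * 0.5))), 0.02)
  expect_lte(null_cluster_probability(5, 0.5, min_progeny = 1), 1)

  ana <- null_cluster_probability(10, 1.46)
  mc <- null_cluster_probability(10, 1.46, method = "montecarlo",
                                 reps = 2e4, seed = 3)
  expect_gte(ana, mc)
})

test_that("alpha = 0 cohorts almost never yield a spurious cluster", {
  set.seed(59)
  n_moms <- 4000L
  cohort <- 10L
  k <- rpois(n_moms * cohort, 1.46)
  recs <- data.table(
    sample = rep(sprintf("m%04d_p%02d", rep(seq_len(n_moms), each = cohort),
                         rep(seq_len(cohort), n_moms)), k),
    chrom = "3", mid = runif(sum(k), 0, 25e6), status = "kept")
  recs[, `:=`(start = mid - 1e4, end = mid + 1e4, dir = "het_to_hom",
              support = 1)]
  s <- sample_table(sprintf("m%04d_p%02d", rep(seq_len(n_moms), each = cohort),
                            rep(seq_len(cohort), n_moms)),
                    mother = rep(sprintf("m%04d", seq_len(n_moms)),
                                 each = cohort))
  cl <- detect_clusters(recs, s)
  expect_gte(1 - nrow(cl) / n_moms, 0.999)
})

test_that("clusters with realistic breakpoint scatter are recovered reliably", {
  set.seed(61)
  n_ev <- 200L
  detected <- logical(n_ev)
  eligible <- logical(n_ev)
  for (i in seq_len(n_ev)) {
    N <- sample(6:12, 1)
    x <- rbinom(1, N, 0.78)
    eligible[i] <- x >= 4
    if (!eligible[i]) next
    ids <- sprintf("e%03d_p%02d", i, 1:N)
    s <- sample_table(ids, mother = sprintf("e%03d", i))
    pos0 <- runif(1, 1e6, 24e6)
    mids <- pos0 + runif(x, -25e3, 25e3)   # HMM-scale localization error
    extra <- sample_meiotic_crossovers(25e6, N, 1.46, min_sep = 5e6)
    recs <- rbind(records_from_mids(ids[1:x], "3", mids),
                  records_from_mids(rep(ids, lengths(extra)), "3",
                                    unlist(extra)))
    cl <- detect_clusters(recs, s)
    detected[i] <- nrow(cl) > 0 && any(cl$x >= 4)
  }
  expect_gte(mean(detected[eligible]), 0.95)
})
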