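test_that("marker maps are uniform, deterministic, and density-scalable", {
  map <- make_marker_map(c(A = 25e6), n_markers = 2500L)
  expect_equal(nrow(map), 2500L)
  expect_equal(mean(diff(map$pos)), 25e6 / 2500)
  expect_true(all(diff(map$pos) > 0))
  expect_true(all(map$pos >= 0 & map$pos <= 25e6))

  dense <- make_marker_map(c(A = 25e6), density = 1 / 136)
  expect_equal(nrow(dense), floor(25e6 / 136))

  two <- make_marker_map(c(A = 10e6, B = 12e6), n_markers = 100L)
  expect_identical(two, make_marker_map(c(A = 10e6, B = 12e6), n_markers = 100L))
  expect_setequal(unique(two$chrom), c("A", "B"))

  expect_error(make_marker_map(c(A = 0)), "zero-length")
})

test_that("meiotic crossover sampler honours rate, interference and bounds", {
  set.seed(1)
  none <- sample_meiotic_crossovers(25e6, 50, expected_co = 0)
  expect_true(all(lengths(none) == 0))

  gam <- sample_meiotic_crossovers(25e6, 10000, expected_co = 1.46,
                                   min_sep = 5e6)
  counts <- lengths(gam)
  se <- sqrt(1.46 / 10000)
  expect_lt(abs(mean(counts) - 1.46), 3 * se)
  seps <- unlist(lapply(gam[counts >= 2], diff))
  expect_true(all(seps >= 5e6))
  expect_true(all(vapply(gam, function(x) !is.unsorted(x), logical(1))))
  expect_true(all(unlist(gam) >= 0 & unlist(gam) <= 25e6))

  expect_error(sample_meiotic_crossovers(25e6, 1, expected_co = 2,
                                         min_sep = 30e6), "infeasible")
})

test_that("mitotic cluster sampler matches alpha and binomial transmission", {
  set.seed(2)
  events <- replicate(10000, sample_mitotic_cluster(5, alpha = 0, beta = 0.5)$event)
  expect_false(any(events))

  all_in <- sample_mitotic_cluster(8, alpha = 1, beta = 1)
  expect_true(all_in$event)
  expect_true(all(all_in$carriers))
  expect_length(all_in$carriers, 8)

  carriers <- replicate(5000,
    sum(sample_mitotic_cluster(32, alpha = 1, beta = 0.78)$carriers))
  se <- sqrt(32 * 0.78 * 0.22 / 5000)
  expect_lt(abs(mean(carriers) - 32 * 0.78), 3 * se)

  # frequency calibration: event rate over many mothers within 3 SE of alpha
  hits <- replicate(2000, sample_mitotic_cluster(5, alpha = 0.12, beta = 0.5)$event)
  expect_lt(abs(mean(hits) - 0.12), 3 * sqrt(0.12 * 0.88 / 2000))
})

test_that("synthesized studies conserve samples, are deterministic, and carry consistent truth", {
  d <- tiny_design(seed = 5L)
  st <- synthesize_study(d)
  expect_equal(nrow(st$samples), sum(st$samples[!duplicated(mother), cohort]))
  expect_identical(st$samples, synthesize_study(tiny_design(seed = 5L))$samples)
  st2 <- synthesize_study(d)
  expect_identical(st$genotypes, st2$genotypes)
  expect_identical(st$truth$meiotic, st2$truth$meiotic)

  # every true meiotic CO sits between adjacent markers of opposite genotype
  for (cn in names(st$genotypes)) {
    gm <- st$genotypes[[cn]]
    mpos <- st$map[chrom == cn, pos]
    tr <- st$truth$meiotic[chrom == cn]
    tr <- tr[pos > min(mpos) & pos < max(mpos)]
    for (i in seq_len(nrow(tr))) {
      k <- findInterval(tr$pos[i], mpos)
      expect_false(gm[k, tr$sample[i]] == gm[k + 1L, tr$sample[i]])
    }
  }
})

test_that("X-segregation carriers show uniform distal LOH genotypes", {
  d <- forced_cluster_design(8, cohort_mean = 8, mode = "X", seed = 9L)
  st <- synthesize_study(d)
  ev <- st$truth$mitotic
  expect_gt(nrow(ev), 0)
  gm <- st$genotypes[["3"]]
  mpos <- st$map[chrom == "3", pos]
  for (i in seq_len(nrow(ev))) {
    ids <- ev$carriers[[i]]
    distal <- gm[mpos >= ev$pos[i], ids, drop = FALSE]
    expect_equal(length(unique(as.vector(distal))), 1L)
    expect_equal(unique(as.vector(distal)), ev$loh_genotype[i])
  }
})

test_that("Z-segregation transmits reciprocal products near 1:1", {
  d <- forced_cluster_design(60, cohort_mean = 30, mode = "Z", seed = 13L,
                             beta = 1, n_markers = 300L,
                             cohort_size = list(
                               dysgenic_low = list(mean = 30, min = 30, max = 30),
                               dysgenic_high = list(mean = 30, min = 20, max = 40),
                               nondysgenic = list(mean = 10, min = 1, max = 20)))
  st <- synthesize_study(d)
  ev <- st$truth$mitotic
  gm <- st$genotypes[["3"]]
  mpos <- st$map[chrom == "3", pos]
  ps <- vapply(seq_len(nrow(ev)), function(i) {
    ids <- ev$carriers[[i]]
    k <- findInterval(ev$pos[i], mpos)
    prox <- gm[k, ids]          # orientation = state proximal of the event
    stats::binom.test(sum(prox == 1), length(ids), 0.5)$p.value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("allele count emission follows the coverage and error model", {
  d <- tiny_design(seed = 21L)
  st <- synthesize_study(d)

  em0 <- emit_allele_counts(st, coverage = 0, error = 0, seed = 1)
  expect_equal(nrow(em0$counts), 0L)
  expect_true(all(em0$samples$read_count == 0))

  # error 0: hom-9/9 markers emit no 160 reads anywhere
  em <- emit_allele_counts(st, coverage = 2, error = 0, seed = 2)
  gm <- st$genotypes[["X"]]
  mpos <- st$map[chrom == "X", pos]
  cx <- em$counts[chrom == "X"]
  cx[, gt := gm[cbind(findInterval(pos, mpos), match(sample, colnames(gm)))]]
  expect_true(all(cx[gt == 0L, n160] == 0))

  # het markers: 160-read fraction within 3 SE of 0.5 at coverage 5
  em5 <- emit_allele_counts(st, coverage = 5, error = 0, seed = 3)
  c5 <- em5$counts[chrom == "X"]
  c5[, gt := gm[cbind(findInterval(pos, mpos), match(sample, colnames(gm)))]]
  tot <- c5[gt == 1L, .(n160 = sum(n160), n = sum(n160 + n9))]
  expect_lt(abs(tot$n160 / tot$n - 0.5), 3 * sqrt(0.25 / tot$n))

  # read counts recorded per sample
  expect_equal(sum(em$samples$read_count), em$counts[, sum(n160 + n9)])
})

test_that("design validation rejects invalid worlds", {
  expect_error(study_design(alpha = c(dysgenic = 1.2, nondysgenic = 0.1)),
               "alpha and beta")
  expect_error(study_design(error = 0.6), "error")
  expect_error(study_design(mode_weights = c(X = 0.5, Z = 0.2)), "sum to 1")
  expect_error(study_design(n_mothers = c(dysgenic_low = 0, dysgenic_high = 0,
                                          nondysgenic = 0)), "empty")
  expect_error(synthesize_study(
    tiny_design(cohort_size = list(dysgenic_low = list(mean = 0, min = 0, max = 0),
                                   dysgenic_high = list(mean = 0, min = 0, max = 0),
                                   nondysgenic = list(mean = 0, min = 0, max = 0)))),
    "empty design")
})
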