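library(data.table)

# small study designs used across tests -------------------------------------

tiny_design <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    chromosomes = c(X = 29.5e6, `3` = 26e6),
    n_mothers = c(dysgenic_low = 4, dysgenic_high = 1, nondysgenic = 3),
    n_markers = 400L,
    seed = seed), list(...))
  do.call(study_design, args)
}

# design with forced mitotic events, used for cluster recovery
forced_cluster_design <- function(n_mothers, cohort_mean, mode, seed = 1L,
                                  beta = 0.78, ...) {
  args <- utils::modifyList(list(
    chromosomes = c(`3` = 26e6),
    n_mothers = c(dysgenic_low = n_mothers, dysgenic_high = 0, nondysgenic = 0),
    cohort_size = list(dysgenic_low = list(mean = cohort_mean, min = 6, max = 12),
                       dysgenic_high = list(mean = 30, min = 20, max = 40),
                       nondysgenic = list(mean = 10, min = 1, max = 20)),
    alpha = c(dysgenic = 1, nondysgenic = 1),
    beta = c(dysgenic = beta, nondysgenic = beta),
    mode_weights = if (mode == "Z") c(X = 0, Z = 1) else c(X = 1, Z = 0),
    seed = seed), list(...))
  do.call(study_design, args)
}

# build a crossover record table from bare midpoints
records_from_mids <- function(sample, chrom, mid, dir = "het_to_hom",
                              support = 1) {
  data.table(sample = sample, chrom = chrom,
             start = mid - 1e4, end = mid + 1e4, mid = mid,
             dir = dir, support = support, status = "kept")
}

sample_table <- function(ids, mother = ids, group = "nondysgenic",
                         read_count = 1e5) {
  data.table(sample = ids, mother = mother, group = group,
             condition = group_condition(group),
             fecundity = "na", batch = 1L, read_count = read_count)
}

# exhaustive forward-backward oracle: enumerate all 2^m state paths ----------
hmm_posterior_oracle <- function(n160, n9, pos, params) {
  m <- length(pos)
  stopifnot(m <= 12)
  n <- n160 + n9
  e <- rbind(het = dbinom(n160, n, 0.5),
             hom = dbinom(n160, n, params$error))
  s <- if (m > 1) 1 - exp(-params$r_per_bp * diff(pos)) else numeric(0)
  paths <- as.matrix(expand.grid(rep(list(1:2), m)))
  w <- apply(paths, 1, function(st) {
    pr <- params$pi[st[1]] * prod(e[cbind(st, seq_len(m))])
    if (m > 1) {
      sw <- st[-1] != st[-m]
      pr <- pr * prod(ifelse(sw, s, 1 - s))
    }
    pr
  })
  vapply(seq_len(m), function(t) {
    sum(w[paths[, t] == 1]) / sum(w)
  }, numeric(1))
}

# brute-force interval overlap oracle
overlaps_brute <- function(qs, qe, ss, se) {
  vapply(seq_along(qs), function(i) any(qs[i] < se & ss < qe[i]), logical(1))
}
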