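#' Parameters for the two-state ancestry HMM
#'
#' The backcross design admits two genotypes only (heterozygous 160/9 or
#' homozygous 9/9), so ancestry inference is a two-state chain along each
#' chromosome. The transition probability between adjacent markers at
#' distance d is `1 - exp(-r_per_bp * d)`; the default `r_per_bp` comes from
#' the 4.6 cM/Mb euchromatic recombination rate (4.6e-8 per bp).
#'
#' @param error per-read allele miscall probability in `[0, 0.5)`.
#' @param r_per_bp prior recombination fraction per bp.
#' @param pi initial state probabilities `c(het, hom)`.
#' @param hi,lo posterior thresholds defining confident het / hom-9 calls.
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(error = 0.001, r_per_bp = 4.6e-8,
                       pi = c(het = 0.5, hom = 0.5),
                       hi = 0.95, lo = 0.05) {
  stopifnot(error >= 0, error < 0.5, r_per_bp >= 0,
            hi > lo, hi > 0, hi < 1, lo > 0, lo < 1,
            length(pi) == 2, all(pi >= 0), abs(sum(pi) - 1) < 1e-8)
  structure(list(error = error, r_per_bp = r_per_bp, pi = pi,
                 hi = hi, lo = lo), class = "hmm_params")
}

#' Posterior probability of heterozygosity along one chromosome
#'
#' Scaled forward-backward over the two ancestry states. Emissions treat
#' reads as i.i.d.: a het site emits a 160 read with probability 0.5, a
#' hom-9 site with probability `error`. Markers without reads are
#' uninformative and carry prior-propagated posteriors.
#'
#' @param n160,n9 integer vectors of 160- and 9-strain read counts per
#'   marker, aligned to `pos`.
#' @param pos marker positions (bp), strictly increasing.
#' @param params an [hmm_params()].
#' @return Numeric vector of `P(het)` per marker (a `GenotypeTrack`).
#' @export
posterior_ancestry <- function(n160, n9, pos, params = hmm_params()) {
  m <- length(pos)
  if (length(n160) != m || length(n9) != m)
    stop("counts and marker map lengths differ")
  if (m == 0L) return(numeric(0))
  if (is.unsorted(pos, strictly = TRUE)) stop("marker positions must be strictly increasing")
  n <- n160 + n9
  e_het <- stats::dbinom(n160, n, 0.5)
  e_hom <- stats::dbinom(n160, n, params$error)
  # forward with per-step normalization
  f <- matrix(0, m, 2)
  cvec <- numeric(m)
  v <- params$pi * c(e_het[1], e_hom[1])
  cvec[1] <- sum(v)
  if (cvec[1] <= 0) stop("forward pass underflow at marker 1")
  f[1, ] <- v / cvec[1]
  if (m > 1) {
    s <- 1 - exp(-params$r_per_bp * diff(pos))
    for (t in 2:m) {
      st <- s[t - 1]
      pred <- c(f[t - 1, 1] * (1 - st) + f[t - 1, 2] * st,
                f[t - 1, 1] * st + f[t - 1, 2] * (1 - st))
      v <- pred * c(e_het[t], e_hom[t])
      cvec[t] <- sum(v)
      if (cvec[t] <= 0) stop("forward pass underflow at marker ", t)
      f[t, ] <- v / cvec[t]
    }
  }
  b <- matrix(0, m, 2)
  b[m, ] <- 1
  if (m > 1) {
    for (t in (m - 1):1) {
      st <- s[t]
      nxt <- c(e_het[t + 1], e_hom[t + 1]) * b[t + 1, ]
      b[t, ] <- c((1 - st) * nxt[1] + st * nxt[2],
                  st * nxt[1] + (1 - st) * nxt[2]) / cvec[t + 1]
    }
  }
  post <- f * b
  post[, 1] / rowSums(post)
}

#' Segment a posterior track into confident genotype blocks
#'
#' Maximal runs of markers with posterior above `hi` are het blocks; runs
#' below `lo` are hom-9 blocks; intermediate markers belong to transition
#' gaps between blocks.
#'
#' @param p_het posterior `P(het)` per marker.
#' @param params an [hmm_params()] supplying the thresholds.
#' @return `data.table` with `state` ("het"/"hom"), `start`, `end` (marker
#'   indices, inclusive), ordered and non-overlapping.
#' @export
genotype_blocks <- function(p_het, params = hmm_params()) {
  cls <- ifelse(p_het > params$hi, "het",
                ifelse(p_het < params$lo, "hom", NA_character_))
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values)
  data.table::data.table(state = r$values[keep],
                         start = starts[keep], end = ends[keep])
}

#' Genotype every sample on every chromosome
#'
#' Runs [posterior_ancestry()] per sample-chromosome over a sparse allele
#' count table, filling zero counts at markers without reads.
#'
#' @param counts long `data.table` with `sample`, `chrom`, `pos`, `n160`,
#'   `n9` (sparse: markers with reads only).
#' @param map marker map from [make_marker_map()].
#' @param params an [hmm_params()].
#' @param samples optional sample table restricting/ordering samples;
#'   defaults to the samples present in `counts`.
#' @return Long `data.table`: `sample`, `chrom`, `pos`, `p_het`.
#' @export
ancestry_posteriors <- function(counts, map, params = hmm_params(),
                                samples = NULL) {
  ids <- if (is.null(samples)) sort(unique(counts$sample)) else samples$sample
  cdt <- data.table::as.data.table(counts)
  data.table::setkey(cdt, sample, chrom, pos)
  out <- vector("list", length(ids) * length(unique(map$chrom)))
  k <- 0L
  for (cn in unique(map$chrom)) {
    mpos <- map[chrom == cn, pos]
    idx <- stats::setNames(seq_along(mpos), format(mpos, digits = 15))
    sub <- cdt[chrom == cn]
    for (sid in ids) {
      rows <- sub[sample == sid]
      v160 <- integer(length(mpos)); v9 <- integer(length(mpos))
      if (nrow(rows)) {
        i <- findInterval(rows$pos, mpos)
        v160[i] <- rows$n160; v9[i] <- rows$n9
      }
      k <- k + 1L
      out[[k]] <- data.table::data.table(
        sample = sid, chrom = cn, pos = mpos,
        p_het = posterior_ancestry(v160, v9, mpos, params))
    }
  }
  data.table::rbindlist(out[seq_len(k)])
}
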