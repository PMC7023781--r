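#' Crossover filter configuration
#'
#' The exclusion ledger applied to raw crossover calls: a per-sample read
#' floor, removal of implausibly close double crossovers, telomeric and
#' centromere-proximal exclusion zones per chromosome, and a minimum
#' flanking ancestry probability. Defaults are the published values
#' (10,000 reads; 750 kb; X/4: 500 kb and 2/3/5: 700 kb telomeric;
#' X 3.5 Mb, 2 1.1 Mb, 3 1.5 Mb, 4 2.4 Mb, 5 2.3 Mb proximal; probability
#' 0.9; chromosome 6 dropped).
#'
#' @param min_reads minimum total reads for a sample to be analysed
#'   (inclusive).
#' @param min_double_sep minimum distance (bp) between adjacent crossovers
#'   on one gamete; closer pairs are removed together.
#' @param telomere_excl,proximal_excl named numeric vectors (bp) of
#'   exclusion-zone widths at the telomeric (coordinate 0) and proximal
#'   (chromosome end) edges.
#' @param min_prob minimum flanking-block ancestry probability.
#' @param exclude_chroms chromosomes dropped from analysis entirely.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_reads = 10000,
                          min_double_sep = 750e3,
                          telomere_excl = c(X = 500e3, `2` = 700e3,
                                            `3` = 700e3, `4` = 500e3,
                                            `5` = 700e3),
                          proximal_excl = c(X = 3.5e6, `2` = 1.1e6,
                                            `3` = 1.5e6, `4` = 2.4e6,
                                            `5` = 2.3e6),
                          min_prob = 0.9,
                          exclude_chroms = "6") {
  stopifnot(min_reads >= 0, min_double_sep >= 0,
            all(telomere_excl >= 0), all(proximal_excl >= 0),
            min_prob >= 0, min_prob <= 1)
  structure(list(min_reads = min_reads, min_double_sep = min_double_sep,
                 telomere_excl = telomere_excl,
                 proximal_excl = proximal_excl,
                 min_prob = min_prob, exclude_chroms = exclude_chroms),
            class = "filter_config")
}

#' Call crossovers from genotype blocks of one sample-chromosome
#'
#' Each adjacent pair of opposite-state blocks yields one crossover whose
#' interval spans the transition gap: from the last marker of the left
#' block to the first marker of the right block. The point estimate is the
#' interval midpoint. Flanking support is the smaller of the two blocks'
#' mean posterior probability of their own state.
#'
#' @param blocks block table from [genotype_blocks()].
#' @param pos marker positions (bp) for this chromosome.
#' @param p_het posterior track used to compute flanking support.
#' @return `data.table`: `start`, `end`, `mid` (bp), `dir`
#'   (`"het_to_hom"`/`"hom_to_het"`), `support`.
#' @export
call_crossovers <- function(blocks, pos, p_het) {
  empty <- data.table::data.table(start = numeric(), end = numeric(),
                                  mid = numeric(), dir = character(),
                                  support = numeric())
  nb <- nrow(blocks)
  if (nb < 2L) return(empty)
  same <- blocks$state[-1] == blocks$state[-nb]
  contiguous <- blocks$start[-1] == blocks$end[-nb] + 1L
  if (any(same & contiguous))
    stop("adjacent blocks of identical state without gap: malformed block table")
  state_prob <- function(i) {
    p <- p_het[blocks$start[i]:blocks$end[i]]
    mean(if (blocks$state[i] == "het") p else 1 - p)
  }
  sup <- vapply(seq_len(nb), state_prob, numeric(1))
  i <- which(!same)  # same-state pairs across a gap carry no crossover
  if (!length(i)) return(empty)
  s <- pos[blocks$end[i]]
  e <- pos[blocks$start[i + 1L]]
  data.table::data.table(start = s, end = e, mid = (s + e) / 2,
                         dir = paste(blocks$state[i], "to",
                                     blocks$state[i + 1L], sep = "_"),
                         support = pmin(sup[i], sup[i + 1L]))
}

#' Call crossovers for every sample and chromosome
#'
#' @param posteriors long posterior table from [ancestry_posteriors()].
#' @param params an [hmm_params()] (thresholds).
#' @return `data.table`: `sample`, `chrom`, `start`, `end`, `mid`, `dir`,
#'   `support`, `status` (all `"kept"`; filters update it).
#' @export
call_all_crossovers <- function(posteriors, params = hmm_params()) {
  pdt <- data.table::as.data.table(posteriors)
  recs <- pdt[, {
    b <- genotype_blocks(p_het, params)
    call_crossovers(b, pos, p_het)
  }, by = .(sample, chrom)]
  recs[, status := "kept"]
  data.table::setkey(recs, sample, chrom, mid)
  recs[]
}

#' Drop samples sequenced below the read floor
#'
#' @param samples sample table with `read_count`.
#' @param cfg a [filter_config()].
#' @return The retained sample table; the number removed is reported via
#'   `message()` and the `"n_removed"` attribute.
#' @export
filter_samples <- function(samples, cfg = filter_config()) {
  if (!"read_count" %in% names(samples) || anyNA(samples$read_count))
    stop("sample read counts are required before filtering")
  sdt <- data.table::as.data.table(samples)
  keep <- sdt$read_count >= cfg$min_reads
  message(sprintf("filter_samples: %d of %d samples below %s reads removed, %d kept",
                  sum(!keep), nrow(sdt), format(cfg$min_reads, big.mark = ","),
                  sum(keep)))
  out <- sdt[keep]
  data.table::setattr(out, "n_removed", sum(!keep))
  out
}

#' Apply the crossover exclusion ledger
#'
#' Rules, in fixed order: (iii) confidence — records whose flanking support
#' is below `min_prob` are removed; (i) double crossovers — within each
#' sample-chromosome, adjacent pairs closer than `min_double_sep` are
#' removed as a pair (the short intervening block is treated as HMM error
#' and the genotype re-joined), closest pair first until none remain;
#' (ii) zones — records whose midpoint falls in a telomeric or proximal
#' exclusion zone are removed. Excluded chromosomes are dropped wholesale.
#' The operation is idempotent.
#'
#' @param records crossover record table from [call_all_crossovers()].
#' @param cfg a [filter_config()].
#' @param chrom_lengths named chromosome lengths (bp), required for the
#'   proximal zones.
#' @return Records with `status` updated (`"kept"`, `"removed_support"`,
#'   `"removed_double"`, `"removed_zone"`, `"removed_chrom"`).
#' @export
filter_crossovers <- function(records, cfg = filter_config(),
                              chrom_lengths = default_chromosomes()) {
  recs <- data.table::copy(data.table::as.data.table(records))
  data.table::setkey(recs, sample, chrom, mid)
  recs[, status := "kept"]
  recs[chrom %in% cfg$exclude_chroms, status := "removed_chrom"]
  # (iii) confidence
  recs[status == "kept" & support < cfg$min_prob, status := "removed_support"]
  # (i) double-CO pairs, closest first
  if (cfg$min_double_sep > 0) {
    drop_pairs <- function(mid, status) {
      alive <- which(status == "kept")
      repeat {
        if (length(alive) < 2L) break
        gaps <- diff(mid[alive])
        if (all(gaps >= cfg$min_double_sep)) break
        j <- which.min(gaps)
        status[alive[c(j, j + 1L)]] <- "removed_double"
        alive <- alive[-c(j, j + 1L)]
      }
      status
    }
    recs[, status := drop_pairs(mid, status), by = .(sample, chrom)]
  }
  # (ii) exclusion zones
  telo <- cfg$telomere_excl; prox <- cfg$proximal_excl
  recs[status == "kept",
       status := {
         tz <- ifelse(chrom %in% names(telo), telo[chrom], 0)
         pz <- ifelse(chrom %in% names(prox), prox[chrom], 0)
         len <- chrom_lengths[chrom]
         ifelse(mid < tz | (!is.na(len) & mid > len - pz),
                "removed_zone", "kept")
       }]
  n_rm <- table(factor(recs$status,
                       c("removed_support", "removed_double",
                         "removed_zone", "removed_chrom")))
  message(sprintf(paste0("filter_crossovers: %d support, %d double-CO, ",
                         "%d zone, %d excluded-chromosome removals; %d kept"),
                  n_rm[1], n_rm[2], n_rm[3], n_rm[4],
                  sum(recs$status == "kept")))
  recs[]
}

#' Kept crossover records
#' @param records a crossover record table.
#' @return Rows with `status == "kept"`.
#' @export
kept <- function(records) {
  data.table::as.data.table(records)[status == "kept"]
}
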