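# Internal positions are 0-based bp; CSV/TSV files are 1-based (bp) to
# match the published tables. BED stays 0-based half-open as standard.

#' Write the crossover table in the supplementary-table schema
#'
#' One row per kept crossover — `sample`, `mother`, `batch`, `group`,
#' `fecundity`, `chrom`, `position` (1-based bp) — plus one `position = 0`
#' row for every sample-chromosome with no crossover, so gamete counts are
#' recoverable from the file alone.
#'
#' @param records kept crossover records.
#' @param samples sample table.
#' @param path output CSV path.
#' @param chromosomes chromosomes every sample was genotyped on.
#' @return The written `data.table`, invisibly.
#' @export
write_crossover_table <- function(records, samples, path,
                                  chromosomes = NULL) {
  recs <- kept(data.table::as.data.table(records))
  sdt <- data.table::as.data.table(samples)
  if (is.null(chromosomes)) chromosomes <- sort(unique(recs$chrom))
  universe <- data.table::CJ(sample = sdt$sample, chrom = chromosomes)
  rows <- recs[, .(sample, chrom, position = round(mid) + 1)]
  none <- universe[!rows[, .(sample, chrom)], on = c("sample", "chrom")]
  none[, position := 0]
  out <- rbind(rows, none)
  meta_cols <- intersect(c("mother", "batch", "group", "fecundity"), names(sdt))
  out <- sdt[, c("sample", meta_cols), with = FALSE][out, on = "sample"]
  data.table::setkey(out, sample, chrom, position)
  data.table::fwrite(out, path)
  invisible(out)
}

#' Read a crossover table (supplementary-table schema)
#'
#' Tolerates column reordering and case differences. Rows with
#' `position = 0` mean the sample was genotyped on that chromosome but had
#' no crossover there: they contribute a gamete but no record.
#'
#' @param path CSV path.
#' @return List: `records` (`sample`, `chrom`, `mid` 0-based bp, `status`)
#'   and `samples` (unique sample metadata found in the file).
#' @export
read_crossover_table <- function(path) {
  dt <- data.table::fread(path)
  if (nrow(dt) == 0L) stop("empty crossover table: ", path)
  names(dt) <- tolower(names(dt))
  need <- c("sample", "chrom", "position")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(dt$position)) {
    bad <- which(is.na(suppressWarnings(as.numeric(dt$position))))[1]
    stop("non-numeric position at row ", bad)
  }
  dt[, chrom := as.character(chrom)]
  dup <- duplicated(dt[position > 0, .(sample, chrom, position)])
  if (any(dup))
    stop("duplicate (sample, chrom, position) at row ",
         which(dup)[1], " of the nonzero-position rows")
  meta_cols <- intersect(c("mother", "batch", "group", "fecundity"),
                         names(dt))
  samples <- unique(dt[, c("sample", meta_cols), with = FALSE])
  if ("group" %in% names(samples))
    samples[, condition := group_condition(group)]
  records <- dt[position > 0,
                .(sample, chrom, mid = position - 1, status = "kept")]
  data.table::setkey(records, sample, chrom, mid)
  gam <- unique(dt[, .(sample, chrom)])
  list(records = records[], samples = samples[],
       gametes = gam[, .(gametes = .N), by = chrom])
}

#' Read a BED annotation track
#'
#' Standard 0-based half-open BED via `rtracklayer`; intervals are
#' validated and returned sorted.
#'
#' @param path BED path.
#' @return Sorted `GRanges`.
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1)) stop("BED interval with start >= end")
  GenomicRanges::sort(gr)
}

#' Write the marker map as a BED-like TSV
#' @param map marker map (`chrom`, `pos` 0-based).
#' @param path output path.
#' @export
write_marker_map <- function(map, path) {
  out <- data.table::as.data.table(map)[, .(chrom, start = floor(pos),
                                            end = floor(pos) + 1)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(out)
}

#' Write a mitotic fit (plus optional model-comparison table) as JSON
#' @param fit a [fit_mitotic()] result.
#' @param path output path.
#' @param comparisons optional named list of [compare_models()] results.
#' @param cis optional named list of [profile_ci()] results.
#' @export
write_fit_json <- function(fit, path, comparisons = NULL, cis = NULL) {
  obj <- list(model = list(alpha = fit$spec$alpha, beta = fit$spec$beta,
                           n_params = fit$spec$n_params,
                           min_progeny = fit$spec$min_progeny,
                           chromosomes = fit$spec$chromosomes),
              estimates = as.list(fit$estimates),
              loglik = fit$loglik,
              transmission_rate = as.list(transmission_rate(fit)),
              profile_ci = cis, comparisons = comparisons)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(obj)
}
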