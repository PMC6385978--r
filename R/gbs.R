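#' Allele dosage from a read fraction
#'
#' For sequencing-based genotyping of a ploidy-`h` organism the genotype is
#' inferred from the fraction of alternative-allele reads `f = alt/total`
#' as the nearest integer to `f * h`, clipped to `[0, h]`. Exact halves are
#' rounded away from zero by default (`ties = "away"`); `ties = "even"`
#' uses banker's rounding. Zero coverage yields a missing call (`NA`).
#'
#' @param alt,total Read counts (vectorised); `0 <= alt <= total`.
#' @param h Ploidy level.
#' @param ties `"away"` or `"even"`.
#' @return Integer dosages in `[0, h]`, `NA` where `total == 0`.
#' @export
dosage_from_read_fraction <- function(alt, total, h, ties = c("away",
                                                              "even")) {
  ties <- match.arg(ties)
  if (any(alt < 0 | total < 0 | alt > total, na.rm = TRUE)) {
    stop("require 0 <= alt <= total", call. = FALSE)
  }
  x <- alt / total * h
  d <- if (ties == "even") round(x) else floor(x + 0.5)
  d <- pmin(pmax(d, 0), h)
  d[total == 0] <- NA_integer_
  as.integer(d)
}

#' Call dosages from a read-count table
#'
#' @param records Tibble with columns `chrom`, `pos`, `sample`, `alt`,
#'   `total`.
#' @param h Ploidy level.
#' @param ties Tie rule, see [dosage_from_read_fraction()].
#' @return `records` with a `dosage` column appended.
#' @export
call_dosages <- function(records, h, ties = "away") {
  stopifnot(all(c("chrom", "pos", "sample", "alt", "total") %in%
                  names(records)))
  dplyr::mutate(tibble::as_tibble(records),
                dosage = dosage_from_read_fraction(alt, total, h,
                                                   ties = ties))
}

#' Depth and missingness variant filters
#'
#' Two-step filter used before dosage conversion: any sample-site call with
#' fewer than `min_reads` reads is set missing, then any site whose missing
#' fraction exceeds `max_missing_frac` (strictly) is removed entirely.
#'
#' @param records Read-count tibble (`chrom`, `pos`, `sample`, `alt`,
#'   `total`), optionally already carrying a `dosage` column whose values
#'   are blanked alongside.
#' @param min_reads Minimum read depth per call (default 20).
#' @param max_missing_frac Maximum tolerated fraction of missing samples
#'   per site (default 0.6); sites at exactly the threshold are kept.
#' @return Filtered tibble; calls failing the depth filter have
#'   `total = 0` (and `NA` dosage). Attribute `filter_stats` records the
#'   number of calls set missing and sites removed.
#' @export
filter_variants <- function(records, min_reads = 20,
                            max_missing_frac = 0.6) {
  records <- tibble::as_tibble(records)
  low <- records$total < min_reads & records$total > 0
  records$alt[low] <- 0L
  records$total[low] <- 0L
  if ("dosage" %in% names(records)) records$dosage[low] <- NA_integer_
  site_missing <- dplyr::summarise(
    dplyr::group_by(records, chrom, pos),
    missing_frac = mean(total == 0), .groups = "drop"
  )
  drop_sites <- dplyr::filter(site_missing,
                              missing_frac > max_missing_frac)
  out <- dplyr::anti_join(records, drop_sites[c("chrom", "pos")],
                          by = c("chrom", "pos"))
  attr(out, "filter_stats") <- list(
    calls_set_missing = sum(low),
    sites_removed = nrow(drop_sites),
    sites_kept = nrow(site_missing) - nrow(drop_sites)
  )
  out
}

#' Impute missing dosages from site genotype frequencies
#'
#' Each missing call is drawn i.i.d. from the empirical distribution of the
#' observed dosages at its own site (independence across sites and
#' samples).
#'
#' @param calls Tibble with columns `chrom`, `pos`, `sample`, `dosage`
#'   (`NA` = missing).
#' @return The tibble with every `NA` dosage replaced by a sampled value;
#'   observed calls are untouched.
#' @export
impute_missing_by_frequency <- function(calls) {
  stopifnot(all(c("chrom", "pos", "dosage") %in% names(calls)))
  calls <- tibble::as_tibble(calls)
  if (!anyNA(calls$dosage)) return(calls)
  key <- paste(calls$chrom, calls$pos)
  for (k in unique(key[is.na(calls$dosage)])) {
    rows <- which(key == k)
    obs <- calls$dosage[rows]
    seen <- obs[!is.na(obs)]
    if (!length(seen)) {
      stop("all calls missing at site ", k,
           "; cannot impute from frequencies", call. = FALSE)
    }
    nm <- is.na(obs)
    calls$dosage[rows[nm]] <- sample(seen, sum(nm), replace = TRUE)
  }
  calls
}

#' Write called dosages as a founder dosage table
#'
#' Produces the `chrom pos id1 id2 ...` layout accepted by
#' [read_dosage_table()], closing the loop from read counts to simulation
#' input.
#'
#' @param calls Complete (no `NA`) dosage tibble (`chrom`, `pos`,
#'   `sample`, `dosage`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(calls, path) {
  if (anyNA(calls$dosage)) {
    stop("dosage table cannot contain missing calls; impute first",
         call. = FALSE)
  }
  wide <- tidyr::pivot_wider(calls[c("chrom", "pos", "sample", "dosage")],
                             names_from = sample, values_from = dosage)
  wide <- dplyr::arrange(wide, chrom, pos)
  names(wide)[1:2] <- c("CHROM", "POS")
  utils::write.table(wide, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
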