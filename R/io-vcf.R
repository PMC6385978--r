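#' Read founder genotypes from a polyploid VCF
#'
#' GT fields must carry exactly `h` alleles, separated uniformly by `|`
#' (phased) or `/` (unphased) within a call; records must be biallelic and
#' complete (no `.` calls). Phased alleles are placed into haplotype slots
#' in GT order (so `0|0|0|1` and `1|0|0|0` differ); unphased alleles are
#' placed by a uniform random permutation, which preserves the dosage.
#'
#' @param path Path to a VCF file.
#' @param h Even ploidy level.
#' @return A [founder_set()] whose founder ids are the VCF sample names.
#' @export
read_polyploid_vcf <- function(path, h) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) fix <- matrix(fix, nrow = 1,
                                     dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || !ncol(gt)) stop("VCF has no genotype columns",
                                     call. = FALSE)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic record at ", fix[which(multi)[1L], "CHROM"], ":",
         fix[which(multi)[1L], "POS"],
         "; only biallelic SNPs are supported", call. = FALSE)
  }
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ids <- colnames(gt)
  n_f <- length(ids)
  m <- nrow(gt)
  hap <- matrix(0L, n_f * h, m)
  for (j in seq_len(m)) {
    for (f in seq_len(n_f)) {
      g <- gt[j, f]
      where <- function() paste0(chrom[j], ":", pos[j], " sample ", ids[f])
      if (is.na(g) || grepl(".", g, fixed = TRUE)) {
        stop("missing genotype call at ", where(),
             "; no missing values are allowed", call. = FALSE)
      }
      phased <- grepl("|", g, fixed = TRUE)
      unphased <- grepl("/", g, fixed = TRUE)
      if (phased && unphased) {
        stop("mixed phase separators in genotype at ", where(),
             call. = FALSE)
      }
      al <- suppressWarnings(
        as.integer(strsplit(g, if (phased) "|" else "/", fixed = TRUE)[[1]]))
      if (length(al) != h) {
        stop("expected ", h, " alleles, found ", length(al), " at ",
             where(), call. = FALSE)
      }
      if (anyNA(al) || any(al < 0L | al > 1L)) {
        stop("non-biallelic allele code in genotype at ", where(),
             call. = FALSE)
      }
      if (!phased && h > 1L) al <- al[sample.int(h)]
      hap[(f - 1L) * h + seq_len(h), j] <- al
    }
  }
  chroms <- unique(chrom)
  chromosomes <- lapply(chroms, function(cc) {
    cols <- which(chrom == cc)
    cols <- cols[order(pos[cols])]
    list(positions = pos[cols], alleles = hap[, cols, drop = FALSE])
  })
  names(chromosomes) <- chroms
  founder_set(h, ids, chromosomes)
}

#' Write a founder set as a phased VCF
#'
#' @param founders A [founder_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_founder_vcf <- function(founders, path) {
  h <- founders$h
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=polysim (ploidy %d, phased)", h),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", founders$founder_ids), collapse = "\t")
  ), con)
  for (chrom in names(founders$chromosomes)) {
    ch <- founders$chromosomes[[chrom]]
    for (j in seq_along(ch$positions)) {
      calls <- vapply(seq_along(founders$founder_ids), function(f) {
        paste(ch$alleles[(f - 1L) * h + seq_len(h), j], collapse = "|")
      }, "")
      writeLines(paste(c(chrom, format(ch$positions[j], scientific = FALSE),
                         ".", "A", "T", ".", "PASS", ".", "GT", calls),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
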