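#' Founder haplotype set
#'
#' The substrate of every simulation: per chromosome, a vector of strictly
#' increasing physical positions (bp) and a matrix of 0/1 alleles with one
#' row per founder haplotype. A ploidy-`h` founder contributes `h` rows
#' ("slots"); haplotype row `(f - 1) * h + s` is slot `s` of founder `f`.
#' Slots `(1,2), (3,4), ..., (h-1,h)` are the homologous pairs, in the same
#' order as the alleles of a phased VCF genotype field.
#'
#' @param h Even ploidy level (>= 2).
#' @param founder_ids Character vector of unique founder identifiers.
#' @param chromosomes Named list; each element a list with `positions`
#'   (strictly increasing integer bp) and `alleles`
#'   (`length(founder_ids) * h` x `length(positions)` matrix of 0/1).
#' @return An object of class `founder_set`.
#' @export
founder_set <- function(h, founder_ids, chromosomes) {
  h <- as.integer(h)
  if (h < 2L || h %% 2L != 0L) {
    stop("ploidy `h` must be an even integer >= 2, got ", h, call. = FALSE)
  }
  founder_ids <- as.character(founder_ids)
  if (anyDuplicated(founder_ids)) stop("duplicated founder ids", call. = FALSE)
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)) ||
      !length(chromosomes)) {
    stop("`chromosomes` must be a non-empty uniquely named list", call. = FALSE)
  }
  n_hap <- h * length(founder_ids)
  for (chrom in names(chromosomes)) {
    ch <- chromosomes[[chrom]]
    pos <- ch$positions
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("positions not strictly increasing on chromosome ", chrom,
           call. = FALSE)
    }
    al <- ch$alleles
    if (!is.matrix(al) || nrow(al) != n_hap || ncol(al) != length(pos)) {
      stop("allele matrix on chromosome ", chrom, " must be ",
           n_hap, " x ", length(pos), call. = FALSE)
    }
    if (!all(al %in% c(0L, 1L))) {
      stop("alleles must be 0/1 on chromosome ", chrom, call. = FALSE)
    }
    storage.mode(chromosomes[[chrom]]$alleles) <- "integer"
    chromosomes[[chrom]]$positions <- as.numeric(pos)
  }
  structure(
    list(h = h, founder_ids = founder_ids, chromosomes = chromosomes),
    class = "founder_set"
  )
}

#' @export
print.founder_set <- function(x, ...) {
  cat("<founder_set> ploidy", x$h, "|", length(x$founder_ids), "founders |",
      length(x$chromosomes), "chromosomes |",
      sum(vapply(x$chromosomes, function(ch) length(ch$positions), 0)),
      "loci\n")
  invisible(x)
}

#' Loci table of a founder set
#'
#' @param founders A `founder_set`.
#' @return A tibble with columns `chrom` and `pos`, in storage order.
#' @export
founder_loci <- function(founders) {
  stopifnot(inherits(founders, "founder_set"))
  purrr::map_dfr(names(founders$chromosomes), function(chrom) {
    tibble::tibble(chrom = chrom,
                   pos = founders$chromosomes[[chrom]]$positions)
  })
}

hap_slot <- function(hap_index, h) ((hap_index - 1L) %% h) + 1L
hap_founder <- function(hap_index, h) ((hap_index - 1L) %/% h) + 1L

new_mosaic <- function(start, hap) {
  list(start = as.numeric(start), hap = as.integer(hap))
}

#' Single-segment mosaics for a founder
#'
#' Founders carry no recombination history: each of their `h` chromosome
#' copies is one segment pointing at the founder's own haplotype row.
#'
#' @param founders A `founder_set`.
#' @param id Founder id.
#' @return An individual: `list(id, mosaics)` with `h` mosaics per chromosome.
#' @export
founder_individual <- function(founders, id) {
  f <- match(id, founders$founder_ids)
  if (is.na(f)) stop("unknown founder id: ", id, call. = FALSE)
  h <- founders$h
  slots <- (f - 1L) * h + seq_len(h)
  mos <- lapply(names(founders$chromosomes), function(chrom) {
    lapply(slots, function(s) new_mosaic(0, s))
  })
  names(mos) <- names(founders$chromosomes)
  list(id = id, mosaics = mos)
}

#' Allele carried by a mosaic at a position
#'
#' Binary search over the breakpoint list: the allele is read from the
#' founder haplotype whose segment covers `position` (segments are half-open
#' `[start, next_start)`).
#'
#' @param mosaic A mosaic (`list(start, hap)`).
#' @param founders The `founder_set` the mosaic points into.
#' @param chrom Chromosome name.
#' @param position Physical position; must be a known locus.
#' @return 0 or 1.
#' @export
allele_at <- function(mosaic, founders, chrom, position) {
  ch <- founders$chromosomes[[chrom]]
  if (is.null(ch)) stop("unknown chromosome: ", chrom, call. = FALSE)
  j <- match(position, ch$positions)
  if (is.na(j)) {
    stop("position ", position, " is not a locus on chromosome ", chrom,
         call. = FALSE)
  }
  seg <- findInterval(position, mosaic$start)
  ch$alleles[mosaic$hap[seg], j]
}

## vectorised allele lookup for one mosaic at pre-resolved column indices
mosaic_alleles <- function(mosaic, positions, alleles, cols) {
  seg <- findInterval(positions, mosaic$start)
  alleles[cbind(mosaic$hap[seg], cols)]
}

resolve_panel <- function(founders, panel) {
  if (is.null(panel)) panel <- founder_loci(founders)
  stopifnot(all(c("chrom", "pos") %in% names(panel)))
  split_rows <- split(seq_len(nrow(panel)), panel$chrom)
  out <- lapply(names(split_rows), function(chrom) {
    ch <- founders$chromosomes[[chrom]]
    if (is.null(ch)) stop("panel names unknown chromosome: ", chrom,
                          call. = FALSE)
    pos <- panel$pos[split_rows[[chrom]]]
    cols <- match(pos, ch$positions)
    if (anyNA(cols)) {
      bad <- pos[is.na(cols)]
      stop("panel positions absent from founder data on ", chrom, ": ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "", call. = FALSE)
    }
    list(chrom = chrom, rows = split_rows[[chrom]], pos = pos, cols = cols)
  })
  out
}

#' Allele-dosage matrix of a population
#'
#' Entry `(i, j)` is the number of copies of the alternative allele carried
#' by individual `i` at panel locus `j`, i.e. the sum of [allele_at()] over
#' the individual's `h` chromosome copies; an integer in `[0, h]`.
#'
#' @param population A `polysim_population` (from [gene_drop()] or
#'   [expand_basepop()]), or a plain named list of individuals.
#' @param panel Tibble with columns `chrom`, `pos`; default all founder loci.
#' @param founders Founder set; defaults to the population's own.
#' @return Integer matrix (individuals x markers) with `ploidy` attribute,
#'   rownames the individual ids, colnames `chrom_pos`.
#' @export
dosage_matrix <- function(population, panel = NULL, founders = NULL) {
  inds <- if (inherits(population, "polysim_population")) {
    if (is.null(founders)) founders <- population$founders
    population$individuals
  } else population
  stopifnot(inherits(founders, "founder_set"))
  if (is.null(panel)) panel <- founder_loci(founders)
  blocks <- resolve_panel(founders, panel)
  n <- length(inds)
  m <- nrow(panel)
  h <- founders$h
  M <- matrix(0L, n, m,
              dimnames = list(unname(vapply(inds, `[[`, "", "id")),
                              paste(panel$chrom, panel$pos, sep = "_")))
  for (b in blocks) {
    al <- founders$chromosomes[[b$chrom]]$alleles
    for (i in seq_len(n)) {
      mos <- inds[[i]]$mosaics[[b$chrom]]
      acc <- 0L
      for (k in seq_along(mos)) {
        acc <- acc + mosaic_alleles(mos[[k]], b$pos, al, b$cols)
      }
      M[i, b$rows] <- acc
    }
  }
  attr(M, "ploidy") <- h
  M
}
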