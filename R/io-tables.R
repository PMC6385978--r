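#' Read a pedigree file
#'
#' Three whitespace-separated columns: id, parent1, parent2, with `0` coding
#' an unknown parent. Rows must be in topological order (every named parent
#' defined on an earlier row) and no individual may be its own ancestor.
#'
#' @param path File path.
#' @return Validated tibble `(id, parent1, parent2)` with `NA` for unknown
#'   parents, in the file's (topological) order.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(d) != 3L) stop("pedigree file must have 3 columns", call. = FALSE)
  names(d) <- c("id", "parent1", "parent2")
  validate_pedigree(tibble::as_tibble(d))
}

validate_pedigree <- function(ped) {
  stopifnot(all(c("id", "parent1", "parent2") %in% names(ped)))
  ped <- tibble::as_tibble(ped)
  ped$id <- as.character(ped$id)
  for (col in c("parent1", "parent2")) {
    ped[[col]] <- as.character(ped[[col]])
    ped[[col]][ped[[col]] %in% c("0", "", "NA")] <- NA_character_
  }
  if (anyDuplicated(ped$id)) {
    stop("duplicated individual ids in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  }
  seen <- character(0)
  for (r in seq_len(nrow(ped))) {
    for (p in c(ped$parent1[r], ped$parent2[r])) {
      if (is.na(p)) next
      if (p == ped$id[r]) {
        stop("individual ", ped$id[r], " is its own parent", call. = FALSE)
      }
      if (!p %in% seen) {
        stop("parent ", p, " of ", ped$id[r],
             " is not defined on an earlier row", call. = FALSE)
      }
    }
    seen <- c(seen, ped$id[r])
  }
  ped
}

#' Read founder genotypes from a dosage table
#'
#' One row per marker: chromosome, position, then one integer dosage in
#' `[0, h]` per founder. An optional header row names the founders
#' (`CHROM POS id1 id2 ...`); otherwise founders are `F1, F2, ...`.
#' Each dosage `c` is expanded to a random phase: `c` alternative alleles
#' placed into the `h` haplotype slots by a uniform random permutation.
#'
#' @param path File path.
#' @param h Even ploidy level.
#' @return A [founder_set()].
#' @export
read_dosage_table <- function(path, h) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[2L])))
  d <- utils::read.table(path, header = has_header)
  d[[1L]] <- as.character(d[[1L]])
  ids <- if (has_header) names(d)[-(1:2)] else paste0("F", seq_len(ncol(d) - 2L))
  doses <- as.matrix(d[, -(1:2), drop = FALSE])
  if (any(doses != round(doses))) {
    stop("non-integer dosage in ", path, call. = FALSE)
  }
  if (any(doses < 0 | doses > h)) {
    stop("dosage outside [0, ", h, "] in ", path, call. = FALSE)
  }
  build_founder_set_from_dosages(d[[1L]], as.numeric(d[[2L]]),
                                 doses, ids, h)
}

build_founder_set_from_dosages <- function(chrom, pos, doses, ids, h) {
  n_f <- length(ids)
  chroms <- unique(chrom)
  chromosomes <- lapply(chroms, function(cc) {
    rows <- which(chrom == cc)
    rows <- rows[order(pos[rows])]
    p <- pos[rows]
    if (anyDuplicated(p)) stop("duplicated position on ", cc, call. = FALSE)
    al <- matrix(0L, n_f * h, length(rows))
    for (j in seq_along(rows)) {
      for (f in seq_len(n_f)) {
        c_j <- doses[rows[j], f]
        if (c_j > 0) {
          slots <- if (c_j == h) seq_len(h) else sample.int(h, c_j)
          al[(f - 1L) * h + slots, j] <- 1L
        }
      }
    }
    list(positions = p, alleles = al)
  })
  names(chromosomes) <- chroms
  founder_set(h, ids, chromosomes)
}

#' Read a QTN or SNP-panel loci list
#'
#' 2 to 5 whitespace-separated columns: chromosome, position, and optionally
#' per-copy additive effect `a`, dominance effect `d` and dominance
#' threshold `phi` (default 1). SNP panels carry positions only; several
#' panels may be supplied to a simulation, producing one genomic
#' relationship matrix each.
#'
#' @param path File path.
#' @param founders Optional `founder_set`; when given, every position must
#'   exist there and offenders are reported.
#' @return Tibble with columns `chrom`, `pos` and, if present in the file,
#'   `a`, `d`, `phi`.
#' @export
read_loci_list <- function(path, founders = NULL) {
  d <- utils::read.table(path, header = FALSE)
  d[[1L]] <- as.character(d[[1L]])
  nc <- ncol(d)
  if (nc < 2L || nc > 5L) {
    stop("loci list must have 2-5 columns, found ", nc, call. = FALSE)
  }
  names(d) <- c("chrom", "pos", "a", "d", "phi")[seq_len(nc)]
  d <- tibble::as_tibble(d)
  d$pos <- as.numeric(d$pos)
  if (nc == 4L) d$phi <- 1
  if (!is.null(founders)) {
    known <- founder_loci(founders)
    miss <- dplyr::anti_join(d[c("chrom", "pos")], known,
                             by = c("chrom", "pos"))
    if (nrow(miss)) {
      stop("loci absent from founder data: ",
           paste(utils::head(paste(miss$chrom, miss$pos), 10L),
                 collapse = ", "),
           if (nrow(miss) > 10L) " ..." else "", call. = FALSE)
    }
  }
  d
}

#' Read a recombination map file
#'
#' Three columns: chromosome, bp, cumulative cM; an optional fourth column
#' gives the sex (`M`/`F`) for sex-specific maps, in which case a named list
#' of two maps is returned.
#'
#' @param path File path.
#' @return A `genetic_map`, or a list of them keyed by sex.
#' @export
read_genetic_map <- function(path) {
  d <- utils::read.table(path, header = FALSE)
  if (ncol(d) == 4L) {
    names(d) <- c("chrom", "bp", "cm", "sex")
    return(lapply(split(d[1:3], d$sex), genetic_map))
  }
  if (ncol(d) != 3L) stop("map file must have 3 or 4 columns", call. = FALSE)
  names(d) <- c("chrom", "bp", "cm")
  genetic_map(d)
}

#' Read a keyword parameter file
#'
#' One statement per line: `PLOIDY 4`, `H2 0.5` (repeatable, one trait
#' each), `THETA 0.25` or `THETAFILE path`, `MIMIC_DIPLOID`,
#' `MIMIC_HAPLOID`, `EXPAND_BASEPOP n_new n_generations`,
#' `QTN_DISTRIBUTION gamma 0.2 5` (or `normal mu sd`, `uniform a b`,
#' `file`), `DOMINANCE_MODE literal|plateau`, `SEED n`. `#` starts a
#' comment. Unknown keywords are an error.
#'
#' @param path File path.
#' @return A named list of parameters (class `polysim_params`).
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  p <- list(h2 = numeric(0), scoring_modes = "GT",
            dominance_mode = "literal", theta = 0)
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    kw <- toupper(tok[1L])
    val <- tok[-1L]
    switch(kw,
      PLOIDY = { p$ploidy <- as.integer(val[1L]) },
      H2 = { p$h2 <- c(p$h2, as.numeric(val[1L])) },
      THETA = { p$theta <- as.numeric(val[1L]) },
      THETAFILE = {
        p$theta <- as.matrix(utils::read.table(val[1L], header = FALSE))
        dimnames(p$theta) <- NULL
      },
      MIMIC_DIPLOID = { p$scoring_modes <- union(p$scoring_modes,
                                                 "MIMIC_DIPLOID") },
      MIMIC_HAPLOID = { p$scoring_modes <- union(p$scoring_modes,
                                                 "MIMIC_HAPLOID") },
      EXPAND_BASEPOP = {
        p$expand_basepop <- list(n_new = as.integer(val[1L]),
                                 n_generations = as.integer(val[2L]))
      },
      QTN_DISTRIBUTION = {
        p$qtn_distribution <- list(dist = tolower(val[1L]),
                                   par = as.numeric(val[-1L]))
      },
      DOMINANCE_MODE = { p$dominance_mode <- tolower(val[1L]) },
      SEED = { p$seed <- as.integer(val[1L]) },
      stop("unknown parameter keyword: ", tok[1L], call. = FALSE)
    )
  }
  if (any(p$h2 < 0 | p$h2 > 1)) {
    stop("H2 entries must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(p$ploidy) && (p$ploidy < 2L || p$ploidy %% 2L != 0L)) {
    stop("PLOIDY must be an even integer >= 2", call. = FALSE)
  }
  if (!p$dominance_mode %in% c("literal", "plateau")) {
    stop("DOMINANCE_MODE must be 'literal' or 'plateau'", call. = FALSE)
  }
  structure(p, class = "polysim_params")
}
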