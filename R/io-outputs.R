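#' Write simulation outputs
#'
#' Writes the standard output bundle of a simulation run:
#' `<prefix>.outy` (id, then per trait the phenotype `y_<trait>` and true
#' genotypic value `g_<trait>`; ids only when no trait was simulated),
#' `<prefix>.outq` (per QTN: trait, chrom, pos, a, d, phi, variance
#' contribution), one `<prefix>.grm.<k>` per SNP panel (id-pair triples,
#' or dense with `dense = TRUE`), one `<prefix>.dose.<k>` marker matrix per
#' panel (header of marker names, rows id then integer dosages), and a
#' `<prefix>.hap` restart file serialising every mosaic.
#'
#' @param population A `polysim_population`.
#' @param phenotypes Result of [simulate_phenotypes()], or `NULL`.
#' @param panels Named or unnamed list of panel tibbles (`chrom`, `pos`).
#' @param out_prefix Output path prefix.
#' @param scoring_mode Scoring mode for the relationship matrices.
#' @param dense Dense GRM layout instead of triples.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(population, phenotypes = NULL, panels = list(),
                          out_prefix = "polysim", scoring_mode = "GT",
                          dense = FALSE) {
  files <- character(0)
  ped <- population$pedigree

  outy <- paste0(out_prefix, ".outy")
  if (!is.null(phenotypes) && nrow(phenotypes)) {
    wide <- tidyr::pivot_wider(
      tibble::as_tibble(phenotypes)[c("id", "trait", "y", "g")],
      names_from = trait, values_from = c(y, g), names_sep = "_"
    )
    wide <- wide[match(ped$id, wide$id), ]
    utils::write.table(wide, outy, quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(data.frame(id = ped$id), outy, quote = FALSE,
                       row.names = FALSE)
  }
  files <- c(files, outy)

  if (!is.null(phenotypes) && !is.null(attr(phenotypes, "qtn_contrib"))) {
    outq <- paste0(out_prefix, ".outq")
    utils::write.table(qtn_contributions(phenotypes), outq, quote = FALSE,
                       row.names = FALSE)
    files <- c(files, outq)
  }

  for (k in seq_along(panels)) {
    M <- dosage_matrix(population, panel = panels[[k]])
    Mk <- recode_dosage(M, scoring_mode)
    gfile <- sprintf("%s.grm.%d", out_prefix, k)
    write_grm(grm(Mk), gfile, dense = dense)
    dfile <- sprintf("%s.dose.%d", out_prefix, k)
    utils::write.table(cbind(ID = rownames(Mk), as.data.frame(Mk)), dfile,
                       quote = FALSE, row.names = FALSE)
    files <- c(files, gfile, dfile)
  }

  hfile <- paste0(out_prefix, ".hap")
  write_restart(population, hfile)
  files <- c(files, hfile)
  invisible(files)
}

#' Serialise a population's mosaics for quick restart
#'
#' Plain-text, line-oriented dump of every individual's breakpoint lists.
#' [read_restart()] rebuilds bit-identical mosaics against the same founder
#' set, so a long gene-dropping run can be resumed or re-queried with new
#' SNP panels without re-simulating.
#'
#' @param population A `polysim_population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restart <- function(population, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fs <- population$founders
  writeLines(sprintf("PLOIDY %d", fs$h), con)
  writeLines(paste(c("CHROMS", names(fs$chromosomes)), collapse = " "), con)
  for (ind in population$individuals) {
    writeLines(paste("IND", ind$id), con)
    for (chrom in names(ind$mosaics)) {
      for (s in seq_along(ind$mosaics[[chrom]])) {
        mo <- ind$mosaics[[chrom]][[s]]
        writeLines(paste("SEG", chrom, s,
                         paste(sprintf("%.17g:%d", mo$start, mo$hap),
                               collapse = " ")), con)
      }
    }
  }
  invisible(path)
}

#' @rdname write_restart
#' @param founders The `founder_set` the file was written against.
#' @param pedigree Optional pedigree to attach; defaults to all-founder
#'   rows.
#' @return For `read_restart()`, a `polysim_population`.
#' @export
read_restart <- function(path, founders, pedigree = NULL) {
  lines <- readLines(path)
  h <- as.integer(strsplit(lines[1L], " ")[[1]][2L])
  if (h != founders$h) {
    stop("restart file ploidy ", h, " does not match founder set (",
         founders$h, ")", call. = FALSE)
  }
  chroms <- strsplit(lines[2L], " ")[[1]][-1L]
  inds <- list()
  cur_id <- NULL
  cur <- NULL
  flush_ind <- function() {
    if (!is.null(cur_id)) inds[[cur_id]] <<- list(id = cur_id, mosaics = cur)
  }
  for (ln in lines[-(1:2)]) {
    tok <- strsplit(ln, " ")[[1]]
    if (tok[1L] == "IND") {
      flush_ind()
      cur_id <- tok[2L]
      cur <- stats::setNames(
        lapply(chroms, function(x) vector("list", 0L)), chroms)
    } else if (tok[1L] == "SEG") {
      chrom <- tok[2L]
      slot <- as.integer(tok[3L])
      parts <- strsplit(tok[-(1:3)], ":", fixed = TRUE)
      cur[[chrom]][[slot]] <- new_mosaic(
        vapply(parts, function(p) as.numeric(p[1L]), 0),
        vapply(parts, function(p) as.integer(p[2L]), 0L)
      )
    } else {
      stop("malformed restart line: ", ln, call. = FALSE)
    }
  }
  flush_ind()
  if (is.null(pedigree)) {
    pedigree <- tibble::tibble(id = names(inds), parent1 = NA_character_,
                               parent2 = NA_character_)
  }
  new_population(founders, inds, pedigree)
}
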