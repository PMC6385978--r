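#' Run a full simulation from input files
#'
#' Glue over the component steps, mirroring the command-line workflow:
#' read founders (VCF or dosage table), optionally expand the base
#' population, gene-drop the pedigree, simulate one trait per `H2` entry
#' from the QTN list (effects sampled per `QTN_DISTRIBUTION` when the file
#' carries none), and write the output bundle.
#'
#' @param params A `polysim_params` list (see [read_params()]) or a path
#'   to a parameter file.
#' @param founders Path to a VCF (`.vcf`) or dosage table, or a
#'   `founder_set`.
#' @param qtn_file Path to the QTN list, or a tibble.
#' @param snp_files Character vector of SNP-panel paths (or list of
#'   tibbles); one relationship matrix is written per panel.
#' @param pedigree_file Path to the pedigree, or a tibble.
#' @param out_prefix Output prefix; `NULL` suppresses writing.
#' @param map_file Optional recombination-map path.
#' @return Invisibly, a list with `population`, `phenotypes`,
#'   `architectures` and the written `files`.
#' @export
run_simulation <- function(params, founders, qtn_file, snp_files = NULL,
                           pedigree_file, out_prefix = "polysim",
                           map_file = NULL) {
  if (is.character(params)) params <- read_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  h <- params$ploidy
  if (is.null(h)) stop("PLOIDY is required", call. = FALSE)
  fs <- if (inherits(founders, "founder_set")) {
    founders
  } else if (grepl("\\.vcf(\\.gz)?$", founders)) {
    read_polyploid_vcf(founders, h)
  } else {
    read_dosage_table(founders, h)
  }
  R <- pairing_matrix(h, params$theta)
  map <- if (is.null(map_file)) uniform_genetic_map(fs)
         else read_genetic_map(map_file)
  seed_pop <- fs
  if (!is.null(params$expand_basepop)) {
    seed_pop <- expand_basepop(fs, params$expand_basepop$n_new,
                               params$expand_basepop$n_generations,
                               R = R, map = map)
  }
  ped <- if (is.data.frame(pedigree_file)) validate_pedigree(pedigree_file)
         else read_pedigree(pedigree_file)
  pop <- gene_drop(ped, seed_pop, R = R, map = map)

  qtn <- if (is.data.frame(qtn_file)) tibble::as_tibble(qtn_file)
         else read_loci_list(qtn_file, founders = fs)
  if (!"a" %in% names(qtn)) {
    qd <- params$qtn_distribution
    if (is.null(qd)) qd <- list(dist = "gamma", par = c(0.2, 5))
    qtn$a <- switch(qd$dist,
      gamma = sample_qtn_effects(nrow(qtn), "gamma", shape = qd$par[1L],
                                 scale = qd$par[2L]),
      normal = sample_qtn_effects(nrow(qtn), "normal", mean = qd$par[1L],
                                  sd = qd$par[2L]),
      uniform = sample_qtn_effects(nrow(qtn), "uniform", min = qd$par[1L],
                                   max = qd$par[2L]),
      stop("QTN effects must come from a file or a sampling distribution",
           call. = FALSE)
    )
  }
  h2s <- if (length(params$h2)) params$h2 else 0.5
  archs <- lapply(h2s, function(x) {
    trait_architecture(qtn, h2 = x, dominance_mode = params$dominance_mode)
  })
  names(archs) <- paste0("trait", seq_along(archs))
  phen <- simulate_phenotypes(pop, archs)

  panels <- list()
  if (!is.null(snp_files)) {
    panels <- lapply(snp_files, function(sf) {
      if (is.data.frame(sf)) tibble::as_tibble(sf)
      else read_loci_list(sf, founders = fs)[c("chrom", "pos")]
    })
  }
  files <- character(0)
  if (!is.null(out_prefix)) {
    mode <- setdiff(params$scoring_modes, "GT")
    files <- write_outputs(pop, phen, panels, out_prefix,
                           scoring_mode = if (length(mode)) mode[1L]
                                          else "GT")
  }
  invisible(list(population = pop, phenotypes = phen,
                 architectures = archs, files = files))
}
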