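#' Generate a synthetic founder population
#'
#' Test-scale stand-in for real genotype panels. In `"LE"` mode every
#' founder haplotype allele is an independent Bernoulli draw at its locus
#' frequency (linkage equilibrium). In `"mosaic"` mode each founder
#' haplotype is a recombinant mosaic of `K` ancestral haplotypes with
#' exponentially distributed segment lengths, which induces linkage
#' disequilibrium whose strength grows as `K` shrinks or segments lengthen.
#'
#' @param n_founders Number of founders.
#' @param h Even ploidy level.
#' @param n_chrom Number of chromosomes.
#' @param loci_per_chrom Loci per chromosome (recycled).
#' @param freq Allele-frequency law: a length-2 vector `(lo, hi)` for
#'   uniform draws, or a single fixed frequency.
#' @param ld `"LE"` or `"mosaic"`.
#' @param K Number of ancestral haplotypes (mosaic mode).
#' @param mean_segment_bp Mean ancestral-segment length (mosaic mode).
#' @param chrom_length_bp Chromosome extent; positions are a sorted uniform
#'   draw from it. The default 1e8 bp gives 1 Morgan per chromosome under
#'   the default 1 cM/Mb map.
#' @return A [founder_set()] with founders `F1..Fn` and chromosomes
#'   `chr1..chrN`.
#' @export
make_founders <- function(n_founders, h, n_chrom = 1,
                          loci_per_chrom = 100,
                          freq = c(0.05, 0.95), ld = c("LE", "mosaic"),
                          K = 4, mean_segment_bp = 5e6,
                          chrom_length_bp = 1e8) {
  ld <- match.arg(ld)
  if (ld == "mosaic" && K < 2) stop("mosaic mode needs K >= 2",
                                    call. = FALSE)
  loci_per_chrom <- rep_len(loci_per_chrom, n_chrom)
  n_hap <- n_founders * h
  chromosomes <- lapply(seq_len(n_chrom), function(cc) {
    m <- loci_per_chrom[cc]
    pos <- sort(sample.int(chrom_length_bp, m))
    p <- if (length(freq) == 2L) stats::runif(m, freq[1L], freq[2L])
         else rep(freq, m)
    if (ld == "LE") {
      al <- matrix(stats::rbinom(n_hap * m, 1L,
                                 rep(p, each = n_hap)), n_hap, m)
    } else {
      anc <- matrix(stats::rbinom(K * m, 1L, rep(p, each = K)), K, m)
      al <- matrix(0L, n_hap, m)
      for (i in seq_len(n_hap)) {
        cuts <- 0
        while (cuts[length(cuts)] < chrom_length_bp) {
          cuts <- c(cuts, cuts[length(cuts)] +
                      stats::rexp(1L, 1 / mean_segment_bp))
        }
        src <- sample.int(K, length(cuts), replace = TRUE)
        al[i, ] <- anc[cbind(src[findInterval(pos, cuts)], seq_len(m))]
      }
    }
    list(positions = pos, alleles = al)
  })
  names(chromosomes) <- paste0("chr", seq_len(n_chrom))
  founder_set(h, paste0("F", seq_len(n_founders)), chromosomes)
}

random_mating_pedigree <- function(founder_ids, gen_sizes,
                                   prefix = "g") {
  ped <- tibble::tibble(id = founder_ids, parent1 = NA_character_,
                        parent2 = NA_character_)
  prev <- founder_ids
  for (g in seq_along(gen_sizes)) {
    ids <- sprintf("%s%d_%d", prefix, g, seq_len(gen_sizes[g]))
    ped <- dplyr::bind_rows(ped, tibble::tibble(
      id = ids,
      parent1 = sample(prev, gen_sizes[g], replace = TRUE),
      parent2 = sample(prev, gen_sizes[g], replace = TRUE)
    ))
    prev <- ids
  }
  ped
}

#' Potato-style tetraploid scenario
#'
#' Desk-scale surrogate for a tetraploid SNP-array breeding study:
#' 150 tetraploid founders typed at 407 linkage-equilibrium SNPs, a base
#' population expanded by 100 individuals bred at random for
#' `expand_generations` generations (inducing LD), a four-generation
#' pedigree of 100/100/100/150 individuals on top of the 250 founders
#' (700 pedigree rows in total), and a trait with 140 QTNs whose additive
#' effects are signed gamma(0.2, 5) draws, heritability 0.5. Pairing is
#' random (autopolyploid).
#'
#' @param n_founders,n_snp,n_qtn,h2 Scenario knobs with the worked-example
#'   defaults.
#' @param n_chrom Number of chromosomes the SNPs are spread over.
#' @param expand_new,expand_generations Base-population expansion size and
#'   depth.
#' @param gen_sizes Sizes of the pedigree generations after the founders.
#' @return A scenario bundle (list): `base_founders` (the raw
#'   [founder_set()]), `founders` (expanded `polysim_population`),
#'   `pedigree`, `R`, `map`, `architecture`, `panel`, `test_ids`, `params`.
#' @export
potato_scenario <- function(n_founders = 150, n_snp = 407, n_chrom = 5,
                            n_qtn = 140, h2 = 0.5, expand_new = 100,
                            expand_generations = 2,
                            gen_sizes = c(100, 100, 100, 150)) {
  per_chrom <- diff(round(seq(0, n_snp, length.out = n_chrom + 1L)))
  base <- make_founders(n_founders, h = 4, n_chrom = n_chrom,
                        loci_per_chrom = per_chrom, ld = "LE")
  R <- pairing_matrix(4, 0)
  map <- uniform_genetic_map(base)
  expanded <- expand_basepop(base, expand_new, expand_generations,
                             R = R, map = map)
  ped <- random_mating_pedigree(expanded$pedigree$id, gen_sizes)
  loci <- founder_loci(base)
  qtn <- loci[sort(sample.int(nrow(loci), n_qtn)), ]
  qtn$a <- sample_qtn_effects(n_qtn, "gamma", shape = 0.2, scale = 5)
  qtn$d <- 0
  qtn$phi <- 1
  arch <- trait_architecture(qtn, h2 = h2)
  last_gen <- sprintf("g%d_%d", length(gen_sizes),
                      seq_len(gen_sizes[length(gen_sizes)]))
  list(
    base_founders = base, founders = expanded, pedigree = ped, R = R,
    map = map, architecture = arch, panel = loci,
    diploid_panel = NULL, test_ids = last_gen,
    params = list(ploidy = 4L, h2 = h2, theta = 0,
                  expand_basepop = list(n_new = expand_new,
                                        n_generations = expand_generations))
  )
}

#' Strawberry-style octoploid scenario
#'
#' Desk-scale surrogate for an octoploid GBS breeding study: 53 octoploid
#' founders typed at 1500 SNPs over 7 chromosomes, strict allopolyploid
#' pairing (disomic inheritance), five generations of intercrossing of 100
#' lines each and a terminal generation of crosses with masked phenotypes.
#' A fraction of loci (default 36%) is tagged as segregating in a single
#' sub-genome pair: their polymorphism is confined to one homologous slot
#' pair, so they behave as diploid markers (dosage at most 2). A further
#' random subset is tagged "pathway" to emulate candidate-gene panels.
#' Architectures: `RQG` draws QTNs genome-wide, `RQP` from pathway loci,
#' `DQP` from diploid pathway loci; gene action is `additive` (d = 0) or
#' `dominant` (complete dominance, `d = |a|`, `phi = 1`); effects are
#' signed gamma(0.2, 5), heritability 0.5.
#'
#' @param n_founders,n_loci,n_chrom,gens,gen_size,n_terminal Scheme sizes.
#' @param architecture `"RQG"`, `"RQP"` or `"DQP"`.
#' @param gene_action `"additive"` or `"dominant"`.
#' @param n_qtn,h2 Trait knobs.
#' @param diploid_frac Fraction of loci tagged single-sub-genome.
#' @param pathway_frac Fraction of loci tagged as pathway-associated.
#' @return A scenario bundle (list) as in [potato_scenario()], plus
#'   `diploid_panel` (the diploid-tagged loci).
#' @export
strawberry_scenario <- function(n_founders = 53, n_loci = 1500,
                                n_chrom = 7, gens = 5, gen_size = 100,
                                n_terminal = 1000,
                                architecture = c("RQG", "RQP", "DQP"),
                                gene_action = c("additive", "dominant"),
                                n_qtn = 100, h2 = 0.5,
                                diploid_frac = 0.36, pathway_frac = 1 / 3) {
  architecture <- match.arg(architecture)
  gene_action <- match.arg(gene_action)
  h <- 8L
  per_chrom <- diff(round(seq(0, n_loci, length.out = n_chrom + 1L)))
  base <- make_founders(n_founders, h = h, n_chrom = n_chrom,
                        loci_per_chrom = per_chrom, ld = "LE")
  loci <- founder_loci(base)
  m <- nrow(loci)
  diploid <- sort(sample.int(m, round(diploid_frac * m)))
  pathway <- sort(sample.int(m, round(pathway_frac * m)))
  # confine diploid-tagged polymorphism to one homologous slot pair
  offset <- 0L
  subgenome <- integer(m)
  subgenome[diploid] <- sample.int(h %/% 2L, length(diploid),
                                   replace = TRUE)
  for (chrom in names(base$chromosomes)) {
    mm <- length(base$chromosomes[[chrom]]$positions)
    cols <- seq_len(mm)
    global <- offset + cols
    slot <- hap_slot(seq_len(n_founders * h), h)
    for (j in cols) {
      g <- subgenome[global[j]]
      if (g > 0L) {
        keep <- slot %in% c(2L * g - 1L, 2L * g)
        base$chromosomes[[chrom]]$alleles[!keep, j] <- 0L
      }
    }
    offset <- offset + mm
  }
  # strict allopolyploid: homologues always pair
  R <- pairing_matrix(h, 1 - 1 / (h - 1))
  map <- uniform_genetic_map(base)
  sizes <- c(rep(gen_size, gens), n_terminal)
  ped <- random_mating_pedigree(base$founder_ids, sizes)
  candidates <- switch(architecture,
    RQG = seq_len(m),
    RQP = pathway,
    DQP = intersect(pathway, diploid)
  )
  if (length(candidates) < n_qtn) {
    stop("only ", length(candidates), " candidate loci for ", n_qtn,
         " QTNs under architecture ", architecture, call. = FALSE)
  }
  qtn <- loci[sort(sample(candidates, n_qtn)), ]
  qtn$a <- sample_qtn_effects(n_qtn, "gamma", shape = 0.2, scale = 5)
  qtn$d <- if (gene_action == "dominant") abs(qtn$a) else 0
  qtn$phi <- 1
  arch <- trait_architecture(qtn, h2 = h2)
  last <- sprintf("g%d_%d", gens + 1L, seq_len(n_terminal))
  list(
    base_founders = base, founders = base, pedigree = ped, R = R,
    map = map, architecture = arch, panel = loci,
    diploid_panel = loci[diploid, ], pathway_idx = pathway,
    diploid_idx = diploid, test_ids = last,
    params = list(ploidy = h, h2 = h2, theta = 1 - 1 / (h - 1))
  )
}
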