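#' Meiotic pairing matrix
#'
#' Builds the h x h matrix of pairwise pairing probabilities between the
#' chromosome copies of one homoeologous group. Off-diagonal entries are
#' `1/(h-1) + theta_ij`; the preferential pairing factor theta raises the
#' pairing probability between homologous slots `(1,2), (3,4), ...` and, for
#' a scalar theta, the compensating offset `-theta/(h-2)` is applied to all
#' non-homologous entries so that every row still sums to one. `theta = 0`
#' is the strict autopolyploid (random, polysomic pairing);
#' `theta = 1 - 1/(h-1)` is the strict allopolyploid (disomic) limit where
#' homologues always pair.
#'
#' @param h Even ploidy level.
#' @param theta Scalar preferential pairing factor, or an h x h matrix of
#'   per-pair offsets (only the upper triangle is read; it is symmetrised).
#' @return A symmetric, zero-diagonal, row-stochastic matrix of class
#'   `pairing_matrix`.
#' @examples
#' pairing_matrix(4, 0)        # all off-diagonals 1/3
#' pairing_matrix(4, 2 / 3)    # strict allotetraploid: homologues always pair
#' @export
pairing_matrix <- function(h, theta = 0) {
  h <- as.integer(h)
  if (h < 2L || h %% 2L != 0L) {
    stop("ploidy `h` must be an even integer >= 2", call. = FALSE)
  }
  base <- 1 / (h - 1)
  if (is.matrix(theta)) {
    if (!all(dim(theta) == c(h, h))) {
      stop("theta matrix must be ", h, " x ", h, call. = FALSE)
    }
    off <- theta
    off[lower.tri(off, diag = TRUE)] <- 0
    off <- off + t(off)
    R <- base + off
  } else {
    if (h == 2L) {
      if (theta != 0) stop("theta must be 0 for h = 2", call. = FALSE)
      R <- matrix(c(0, 1, 1, 0), 2L, 2L)
      return(new_pairing_matrix(R, theta))
    }
    R <- matrix(base - theta / (h - 2), h, h)
    homolog <- cbind(seq(1L, h, 2L), seq(2L, h, 2L))
    R[homolog] <- base + theta
    R[homolog[, 2:1]] <- base + theta
  }
  diag(R) <- 0
  if (any(R < -1e-12) || any(R > 1 + 1e-12)) {
    stop("pairing probabilities fall outside [0, 1]; ",
         "theta is too large in magnitude for ploidy ", h, call. = FALSE)
  }
  R[R < 0] <- 0
  R[R > 1] <- 1
  rs <- rowSums(R)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("pairing matrix rows do not sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  new_pairing_matrix(R, if (is.matrix(theta)) NA_real_ else theta)
}

new_pairing_matrix <- function(R, theta) {
  structure(R, theta = theta, class = c("pairing_matrix", "matrix", "array"))
}

#' Sample one meiotic pairing configuration
#'
#' Draws a perfect matching of the h chromosome copies into h/2 bivalents:
#' repeatedly the lowest unpaired slot picks its partner with probabilities
#' proportional to the pairing matrix restricted to the slots still free.
#'
#' @param R A [pairing_matrix()].
#' @return An (h/2) x 2 integer matrix; row k is the k-th bivalent, rows
#'   ordered by their lower slot.
#' @export
sample_pairing <- function(R) {
  h <- nrow(R)
  free <- seq_len(h)
  pairs <- matrix(0L, h %/% 2L, 2L)
  for (k in seq_len(nrow(pairs))) {
    i <- free[1L]
    cand <- free[-1L]
    p <- R[i, cand]
    tot <- sum(p)
    if (tot <= 0) {
      stop("no positive pairing probability left for slot ", i,
           "; pairing matrix is inconsistent", call. = FALSE)
    }
    j <- cand[sample.int(length(cand), 1L, prob = p)]
    pairs[k, ] <- c(i, j)
    free <- setdiff(free, c(i, j))
  }
  pairs
}

#' Genetic maps
#'
#' A genetic map is a named-per-chromosome list of breakpoints `bp` and
#' cumulative genetic positions `cm` (centiMorgan), interpolated linearly.
#' Crossover counts are Poisson with mean the map length in Morgans;
#' crossover positions are i.i.d. uniform on the genetic scale and mapped
#' back to bp by inverse interpolation (Haldane, no interference).
#'
#' @param founders A `founder_set` (used for chromosome extents).
#' @param cm_per_mb Uniform recombination rate; default 1 cM/Mb.
#' @return A `genetic_map`: named list of `list(bp, cm)` tables.
#' @export
uniform_genetic_map <- function(founders, cm_per_mb = 1) {
  maps <- lapply(founders$chromosomes, function(ch) {
    hi <- max(ch$positions) + 1
    list(bp = c(0, hi), cm = c(0, hi * cm_per_mb / 1e6))
  })
  structure(maps, class = "genetic_map")
}

#' @rdname uniform_genetic_map
#' @param table Tibble/data frame with columns `chrom`, `bp`, `cm`
#'   (cumulative), at least two rows per chromosome, `cm` non-decreasing.
#' @export
genetic_map <- function(table) {
  stopifnot(all(c("chrom", "bp", "cm") %in% names(table)))
  maps <- lapply(split(table[c("bp", "cm")], table$chrom), function(d) {
    d <- d[order(d$bp), ]
    if (is.unsorted(d$cm)) stop("cumulative cM must be non-decreasing",
                                call. = FALSE)
    list(bp = d$bp, cm = d$cm)
  })
  structure(maps, class = "genetic_map")
}

map_length_morgans <- function(map, chrom) {
  m <- map[[chrom]]
  if (is.null(m)) stop("no genetic map for chromosome ", chrom, call. = FALSE)
  (m$cm[length(m$cm)] - m$cm[1L]) / 100
}

sample_crossovers <- function(map, chrom) {
  m <- map[[chrom]]
  len_m <- (m$cm[length(m$cm)] - m$cm[1L]) / 100
  n_x <- stats::rpois(1L, len_m)
  if (n_x == 0L) return(numeric(0))
  u <- stats::runif(n_x, m$cm[1L], m$cm[length(m$cm)])
  sort(stats::approx(m$cm, m$bp, xout = u, ties = "ordered")$y)
}

#' Sample the randomness of one meiosis on one chromosome
#'
#' All random draws of a meiosis (the pairing configuration, and per
#' bivalent the crossover positions and the starting strand) are made here
#' and nowhere else, so that alternative genome representations can replay
#' an identical meiosis from the same plan.
#'
#' @param R A [pairing_matrix()].
#' @param map A `genetic_map`.
#' @param chrom Chromosome name.
#' @return `list(pairing, xovers, first)`: the bivalent matrix, a list of
#'   crossover bp vectors, and for each bivalent which mosaic (1 or 2)
#'   the recombinant product starts from.
#' @export
sample_meiosis_plan <- function(R, map, chrom) {
  pairing <- sample_pairing(R)
  nb <- nrow(pairing)
  xovers <- vector("list", nb)
  first <- integer(nb)
  for (k in seq_len(nb)) {
    xovers[[k]] <- sample_crossovers(map, chrom)
    first[k] <- if (stats::runif(1L) < 0.5) 1L else 2L
  }
  list(pairing = pairing, xovers = xovers, first = first)
}

## splice two mosaics at crossover positions, starting from `a`
splice_mosaic <- function(a, b, xpos) {
  if (!length(xpos)) return(a)
  bounds <- c(0, xpos, Inf)
  nseg <- length(bounds) - 1L
  starts <- vector("list", nseg)
  haps <- vector("list", nseg)
  for (t in seq_len(nseg)) {
    src <- if (t %% 2L == 1L) a else b
    lo <- bounds[t]
    hi <- bounds[t + 1L]
    k1 <- max(findInterval(lo, src$start), 1L)
    k2 <- max(k1, sum(src$start < hi))
    seg_starts <- src$start[k1:k2]
    seg_starts[1L] <- lo
    starts[[t]] <- seg_starts
    haps[[t]] <- src$hap[k1:k2]
  }
  st <- unlist(starts)
  hp <- unlist(haps)
  keep <- c(TRUE, hp[-1L] != hp[-length(hp)])
  new_mosaic(st[keep], hp[keep])
}

#' Recombine one bivalent
#'
#' Produces the transmitted recombinant product of two paired chromosome
#' copies: crossover count is Poisson in the map length, positions follow
#' the inverse genetic map, and the product starts from one of the two
#' mosaics with probability 1/2 (two-strand simplification with correct
#' Mendelian marginals).
#'
#' @param mosaic_a,mosaic_b The two paired mosaics.
#' @param map A `genetic_map`.
#' @param chrom Chromosome name.
#' @return A single recombinant mosaic.
#' @export
recombine_bivalent <- function(mosaic_a, mosaic_b, map, chrom) {
  xpos <- sample_crossovers(map, chrom)
  if (stats::runif(1L) >= 0.5) {
    tmp <- mosaic_a; mosaic_a <- mosaic_b; mosaic_b <- tmp
  }
  splice_mosaic(mosaic_a, mosaic_b, xpos)
}

apply_meiosis_plan <- function(mosaics, plan) {
  nb <- nrow(plan$pairing)
  out <- vector("list", nb)
  for (k in seq_len(nb)) {
    a <- mosaics[[plan$pairing[k, 1L]]]
    b <- mosaics[[plan$pairing[k, 2L]]]
    if (plan$first[k] == 2L) { tmp <- a; a <- b; b <- tmp }
    out[[k]] <- splice_mosaic(a, b, plan$xovers[[k]])
  }
  out
}

#' Form one gamete
#'
#' Per chromosome: a pairing configuration is sampled (independently per
#' chromosome and per meiosis), each bivalent is recombined, and the h/2
#' recombinant products are transmitted in bivalent order.
#'
#' @param parent An individual (`list(id, mosaics)`).
#' @param R A [pairing_matrix()].
#' @param map A `genetic_map`.
#' @return Named list per chromosome of h/2 mosaics.
#' @export
make_gamete <- function(parent, R, map) {
  mos <- parent$mosaics
  out <- vector("list", length(mos))
  names(out) <- names(mos)
  for (chrom in names(mos)) {
    plan <- sample_meiosis_plan(R, map, chrom)
    out[[chrom]] <- apply_meiosis_plan(mos[[chrom]], plan)
  }
  out
}

unite_gametes <- function(id, gam1, gam2) {
  mos <- vector("list", length(gam1))
  names(mos) <- names(gam1)
  for (chrom in names(gam1)) {
    nb <- length(gam1[[chrom]])
    slots <- vector("list", 2L * nb)
    # interleave so slot pairs (1,2),(3,4),... receive one product from each
    # parent's k-th bivalent; under strict allopolyploid pairing this keeps
    # sub-genome identity attached to the slot pairs across generations
    slots[seq(1L, 2L * nb, 2L)] <- gam1[[chrom]]
    slots[seq(2L, 2L * nb, 2L)] <- gam2[[chrom]]
    mos[[chrom]] <- slots
  }
  list(id = id, mosaics = mos)
}

#' Gene-drop a pedigree
#'
#' Forward simulation of genotypes down a validated pedigree: every
#' non-founder is the union of one gamete from each parent (selfing allowed
#' when both parents coincide; the two gametes are drawn independently).
#' Only recombination breakpoints are stored, so cost is independent of the
#' number of loci.
#'
#' @param pedigree Tibble `(id, parent1, parent2)` in topological order
#'   (see [read_pedigree()]); parent code `"0"`/`NA` marks a founder.
#' @param founders A `founder_set`, or a `polysim_population` whose
#'   individuals already carry mosaics (e.g. from [expand_basepop()]).
#' @param R A [pairing_matrix()]; default random pairing (autopolyploid).
#' @param map A `genetic_map`; default [uniform_genetic_map()] at 1 cM/Mb.
#' @return A `polysim_population`: list with `founders` (the substrate),
#'   `individuals` (named list, one per pedigree row) and `pedigree`.
#' @export
gene_drop <- function(pedigree, founders, R = NULL, map = NULL) {
  seeds <- list()
  if (inherits(founders, "polysim_population")) {
    seeds <- founders$individuals
    founders <- founders$founders
  }
  stopifnot(inherits(founders, "founder_set"))
  pedigree <- validate_pedigree(pedigree)
  if (is.null(R)) R <- pairing_matrix(founders$h, 0)
  if (is.null(map)) map <- uniform_genetic_map(founders)
  inds <- vector("list", nrow(pedigree))
  names(inds) <- pedigree$id
  for (r in seq_len(nrow(pedigree))) {
    id <- pedigree$id[r]
    p1 <- pedigree$parent1[r]
    p2 <- pedigree$parent2[r]
    if (is.na(p1) && is.na(p2)) {
      inds[[id]] <- if (!is.null(seeds[[id]])) {
        seeds[[id]]
      } else if (id %in% founders$founder_ids) {
        founder_individual(founders, id)
      } else {
        stop("pedigree founder ", id, " has no genotype", call. = FALSE)
      }
    } else {
      if (is.na(p1) || is.na(p2)) {
        stop("individual ", id, " has exactly one known parent; ",
             "both or neither are required", call. = FALSE)
      }
      gam1 <- make_gamete(inds[[p1]], R, map)
      gam2 <- make_gamete(inds[[p2]], R, map)
      inds[[id]] <- unite_gametes(id, gam1, gam2)
    }
  }
  new_population(founders, inds, pedigree)
}

new_population <- function(founders, individuals, pedigree) {
  structure(list(founders = founders, individuals = individuals,
                 pedigree = pedigree),
            class = "polysim_population")
}

#' @export
print.polysim_population <- function(x, ...) {
  n_founder <- sum(is.na(x$pedigree$parent1) & is.na(x$pedigree$parent2))
  cat("<polysim_population>", length(x$individuals), "individuals (",
      n_founder, "founders ) | ploidy", x$founders$h, "\n")
  invisible(x)
}

#' Expand the base population
#'
#' Creates additional founders by random crossing of the available ones and
#' random breeding for a given number of generations, the standard device
#' for inducing linkage disequilibrium when founder phases were generated
#' at random. Mating is monoecious with replacement; selfing can occur.
#'
#' @param founders A `founder_set`.
#' @param n_new Number of new base-population individuals to return.
#' @param n_generations Number of random-mating generations (>= 1).
#' @param R,map As in [gene_drop()].
#' @param prefix Id prefix for the generated individuals.
#' @return A `polysim_population` whose individuals are the original
#'   founders plus the final generation's `n_new` individuals, all usable
#'   as founders of a subsequent [gene_drop()].
#' @export
expand_basepop <- function(founders, n_new, n_generations, R = NULL,
                           map = NULL, prefix = "xb") {
  stopifnot(inherits(founders, "founder_set"), n_new >= 1,
            n_generations >= 1)
  prev <- founders$founder_ids
  ped <- tibble::tibble(id = prev, parent1 = NA_character_,
                        parent2 = NA_character_)
  for (g in seq_len(n_generations)) {
    ids <- sprintf("%s%d_%d", prefix, g, seq_len(n_new))
    ped <- dplyr::bind_rows(ped, tibble::tibble(
      id = ids,
      parent1 = sample(prev, n_new, replace = TRUE),
      parent2 = sample(prev, n_new, replace = TRUE)
    ))
    prev <- ids
  }
  pop <- gene_drop(ped, founders, R = R, map = map)
  keep <- c(founders$founder_ids, prev)
  out_ped <- tibble::tibble(id = keep, parent1 = NA_character_,
                            parent2 = NA_character_)
  new_population(founders, pop$individuals[keep], out_ped)
}

#' Observed pairing frequencies (diagnostic)
#'
#' Draws repeated pairing configurations from a pairing matrix and tabulates
#' how often each slot pair ends up in a bivalent, for checking the realized
#' marginal pairing rates at intermediate preferential-pairing factors.
#'
#' @param R A [pairing_matrix()].
#' @param n_meioses Number of configurations to draw.
#' @return Tibble `(slot_i, slot_j, frequency)`.
#' @export
pairing_frequencies <- function(R, n_meioses = 10000) {
  h <- nrow(R)
  counts <- matrix(0, h, h)
  for (i in seq_len(n_meioses)) {
    p <- sample_pairing(R)
    counts[p] <- counts[p] + 1
  }
  idx <- which(upper.tri(counts), arr.ind = TRUE)
  tibble::tibble(slot_i = idx[, 1L], slot_j = idx[, 2L],
                 frequency = counts[idx] / n_meioses)
}
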