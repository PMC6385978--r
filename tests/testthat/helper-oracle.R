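# Dense gene-dropping oracle: carries full allele vectors for every
# chromosome copy instead of breakpoint mosaics. It consumes exactly the
# same random draws as the breakpoint engine (all meiotic randomness is
# sampled through sample_meiosis_plan()), so a run from the same seed must
# reproduce identical genotypes.

dense_founder <- function(founders, id) {
  h <- founders$h
  f <- match(id, founders$founder_ids)
  al <- lapply(founders$chromosomes, function(ch) {
    ch$alleles[(f - 1L) * h + seq_len(h), , drop = FALSE]
  })
  list(id = id, alleles = al)
}

dense_gamete <- function(parent, R, map, founders) {
  out <- vector("list", length(parent$alleles))
  names(out) <- names(parent$alleles)
  for (chrom in names(parent$alleles)) {
    plan <- polysim::sample_meiosis_plan(R, map, chrom)
    pos <- founders$chromosomes[[chrom]]$positions
    nb <- nrow(plan$pairing)
    g <- matrix(0L, nb, length(pos))
    for (k in seq_len(nb)) {
      a <- parent$alleles[[chrom]][plan$pairing[k, 1L], ]
      b <- parent$alleles[[chrom]][plan$pairing[k, 2L], ]
      if (plan$first[k] == 2L) { tmp <- a; a <- b; b <- tmp }
      seg <- findInterval(pos, c(0, plan$xovers[[k]]))
      g[k, ] <- ifelse(seg %% 2L == 1L, a, b)
    }
    out[[chrom]] <- g
  }
  out
}

dense_gene_drop <- function(pedigree, founders, R, map) {
  inds <- vector("list", nrow(pedigree))
  names(inds) <- pedigree$id
  for (r in seq_len(nrow(pedigree))) {
    id <- pedigree$id[r]
    p1 <- pedigree$parent1[r]
    p2 <- pedigree$parent2[r]
    if (is.na(p1) && is.na(p2)) {
      inds[[id]] <- dense_founder(founders, id)
    } else {
      g1 <- dense_gamete(inds[[p1]], R, map, founders)
      g2 <- dense_gamete(inds[[p2]], R, map, founders)
      al <- vector("list", length(g1))
      names(al) <- names(g1)
      for (chrom in names(g1)) {
        nb <- nrow(g1[[chrom]])
        m <- matrix(0L, 2L * nb, ncol(g1[[chrom]]))
        m[seq(1L, 2L * nb, 2L), ] <- g1[[chrom]]
        m[seq(2L, 2L * nb, 2L), ] <- g2[[chrom]]
        al[[chrom]] <- m
      }
      inds[[id]] <- list(id = id, alleles = al)
    }
  }
  inds
}

dense_dosages <- function(dense_pop, founders, panel = NULL) {
  if (is.null(panel)) panel <- polysim::founder_loci(founders)
  M <- matrix(0L, length(dense_pop), nrow(panel),
              dimnames = list(names(dense_pop),
                              paste(panel$chrom, panel$pos, sep = "_")))
  for (i in seq_along(dense_pop)) {
    row <- integer(0)
    for (chrom in unique(panel$chrom)) {
      pos <- panel$pos[panel$chrom == chrom]
      cols <- match(pos, founders$chromosomes[[chrom]]$positions)
      row <- c(row, colSums(dense_pop[[i]]$alleles[[chrom]][, cols,
                                                            drop = FALSE]))
    }
    M[i, ] <- row
  }
  M
}

# small random pedigree on top of founder ids: `gens` generations of
# `size` individuals, parents uniform from the previous generation
toy_pedigree <- function(founder_ids, gens = 3, size = 6) {
  ped <- tibble::tibble(id = founder_ids, parent1 = NA_character_,
                        parent2 = NA_character_)
  prev <- founder_ids
  for (g in seq_len(gens)) {
    ids <- sprintf("t%d_%d", g, seq_len(size))
    ped <- rbind(ped, tibble::tibble(
      id = ids,
      parent1 = sample(prev, size, replace = TRUE),
      parent2 = sample(prev, size, replace = TRUE)
    ))
    prev <- ids
  }
  ped
}

# founder-haplotype indices referenced by an individual on one chromosome
mosaic_hap_set <- function(ind, chrom) {
  sort(unique(unlist(lapply(ind$mosaics[[chrom]], `[[`, "hap"))))
}
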