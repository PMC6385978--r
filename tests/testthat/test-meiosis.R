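test_that("pairing matrices hit the autopolyploid and allopolyploid limits", {
  R0 <- pairing_matrix(4, 0)
  expect_equal(unclass(R0)[upper.tri(R0)], rep(1 / 3, 6),
               ignore_attr = TRUE)
  expect_equal(diag(R0), rep(0, 4))

  Ra <- pairing_matrix(4, 2 / 3)   # strict allotetraploid
  expect_equal(Ra[1, 2], 1)
  expect_equal(Ra[3, 4], 1)
  expect_equal(Ra[1, 3], 0)
  expect_equal(Ra[2, 4], 0)

  expect_error(pairing_matrix(4, 5), "outside")
  expect_error(pairing_matrix(3, 0), "even")
})

test_that("built pairing matrices are symmetric, zero-diagonal, stochastic", {
  for (h in c(2, 4, 6, 8)) {
    for (theta in c(0, 0.05, if (h > 2) 1 - 1 / (h - 1))) {
      if (h == 2 && theta != 0) next
      R <- pairing_matrix(h, theta)
      expect_equal(unclass(R), t(unclass(R)), ignore_attr = TRUE)
      expect_equal(diag(R), rep(0, h))
      expect_equal(rowSums(R), rep(1, h))
    }
  }
  # explicit offset matrix used verbatim
  off <- matrix(0, 4, 4)
  off[1, 2] <- 0.2
  off[3, 4] <- 0.2
  off[1, 3] <- off[1, 4] <- off[2, 3] <- off[2, 4] <- -0.1
  R <- pairing_matrix(4, off)
  expect_equal(R[1, 2], 1 / 3 + 0.2)
  expect_equal(R[1, 4], 1 / 3 - 0.1)
  expect_equal(rowSums(R), rep(1, 4))
})

test_that("sampled pairings cover all slots and hit the deterministic limits", {
  set.seed(61)
  Ra <- pairing_matrix(4, 2 / 3)
  for (i in 1:50) {
    expect_identical(sample_pairing(Ra), rbind(c(1L, 2L), c(3L, 4L)))
  }
  expect_identical(sample_pairing(pairing_matrix(2, 0)),
                   matrix(c(1L, 2L), 1))
  p <- sample_pairing(pairing_matrix(8, 0))
  expect_identical(sort(as.vector(p)), 1:8)
})

test_that("random tetraploid pairing is uniform over the three matchings", {
  set.seed(71)
  R <- pairing_matrix(4, 0)
  n <- 10000
  partner1 <- replicate(n, sample_pairing(R)[1, 2])
  freq <- tabulate(partner1, 4)[2:4] / n
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("crossover counts follow the map length", {
  set.seed(81)
  fs <- make_founders(2, h = 2, loci_per_chrom = 10, chrom_length_bp = 1e8)
  map <- uniform_genetic_map(fs)  # 1 Morgan
  a <- founder_individual(fs, "F1")$mosaics$chr1[[1]]
  b <- founder_individual(fs, "F1")$mosaics$chr1[[2]]
  n <- 10000
  nseg <- replicate(n, {
    length(recombine_bivalent(a, b, map, "chr1")$start)
  })
  # with two distinct source haplotypes every crossover is a breakpoint,
  # so mean(nseg - 1) equals the map length in Morgans
  len_m <- (max(fs$chromosomes$chr1$positions) + 1) / 1e8
  expect_equal(mean(nseg - 1), len_m, tolerance = 0.05)

  zero <- genetic_map(tibble::tibble(chrom = "chr1", bp = c(0, 1e8),
                                     cm = c(0, 0)))
  out <- recombine_bivalent(a, b, zero, "chr1")
  expect_true(identical(out, a) || identical(out, b))
})

test_that("recombining identical mosaics returns the same mosaic", {
  set.seed(91)
  fs <- make_founders(2, h = 2, loci_per_chrom = 5)
  map <- uniform_genetic_map(fs)
  a <- founder_individual(fs, "F1")$mosaics$chr1[[1]]
  for (i in 1:20) {
    out <- recombine_bivalent(a, a, map, "chr1")
    expect_identical(out, a)
  }
})

test_that("gametes carry exactly h/2 chromosomes and unions restore h", {
  set.seed(95)
  for (h in c(2, 4, 8)) {
    fs <- make_founders(3, h = h, n_chrom = 2, loci_per_chrom = 6)
    parent <- founder_individual(fs, "F1")
    gam <- make_gamete(parent, pairing_matrix(h, 0),
                       uniform_genetic_map(fs))
    expect_equal(lengths(gam), c(chr1 = h / 2, chr2 = h / 2))
    ped <- tibble::tibble(id = c("F1", "F2", "K"),
                          parent1 = c(NA, NA, "F1"),
                          parent2 = c(NA, NA, "F2"))
    kid <- gene_drop(ped, fs)$individuals$K
    expect_equal(lengths(kid$mosaics), c(chr1 = h, chr2 = h))
  }
})

test_that("strict allopolyploid gene dropping is fully disomic", {
  set.seed(105)
  h <- 4
  fs <- make_founders(6, h = h, n_chrom = 2, loci_per_chrom = 10)
  Ra <- pairing_matrix(h, 1 - 1 / (h - 1))
  pop <- gene_drop(toy_pedigree(fs$founder_ids, gens = 3, size = 10),
                   fs, R = Ra)
  # every mosaic in slot pair g must reference only founder haplotypes
  # whose own slot lies in pair g: homologous-pair origin is preserved
  for (ind in pop$individuals) {
    for (chrom in names(ind$mosaics)) {
      for (s in seq_along(ind$mosaics[[chrom]])) {
        pair_of_slot <- (s + 1) %/% 2
        haps <- ind$mosaics[[chrom]][[s]]$hap
        hap_pairs <- ((haps - 1) %% h + 1 + 1) %/% 2
        expect_true(all(hap_pairs == pair_of_slot))
      }
    }
  }
})

test_that("selfing draws two independent gametes from one parent", {
  set.seed(115)
  fs <- make_founders(2, h = 4, loci_per_chrom = 10)
  ped <- tibble::tibble(id = c("F1", "S"), parent1 = c(NA, "F1"),
                        parent2 = c(NA, "F1"))
  pop <- gene_drop(ped, fs)
  expect_equal(length(pop$individuals$S$mosaics$chr1), 4)
  M <- dosage_matrix(pop)
  expect_true(all(M[2, ] >= 0 & M[2, ] <= 4))
})

test_that("expand_basepop appends the requested new founders", {
  set.seed(125)
  fs <- make_founders(15, h = 4, loci_per_chrom = 30)
  pop <- expand_basepop(fs, n_new = 10, n_generations = 3)
  expect_equal(length(pop$individuals), 25)
  expect_equal(sum(grepl("^xb3_", names(pop$individuals))), 10)
  # expanded individuals are usable as founders of a further gene drop
  ped2 <- toy_pedigree(names(pop$individuals), gens = 1, size = 5)
  pop2 <- gene_drop(ped2, pop)
  expect_equal(length(pop2$individuals), 30)
})

test_that("zero-length maps make expansion copy founder chromosomes", {
  set.seed(135)
  fs <- make_founders(4, h = 4, loci_per_chrom = 8)
  flat <- genetic_map(tibble::tibble(chrom = "chr1", bp = c(0, 1e8),
                                     cm = c(0, 0)))
  pop <- expand_basepop(fs, n_new = 6, n_generations = 1, map = flat)
  for (id in grep("^xb", names(pop$individuals), value = TRUE)) {
    for (mo in pop$individuals[[id]]$mosaics$chr1) {
      expect_length(mo$hap, 1)   # single unrecombined founder segment
    }
  }
})

test_that("expansion preserves allele frequencies up to drift", {
  set.seed(145)
  fs <- make_founders(30, h = 4, loci_per_chrom = 40, freq = 0.5)
  p0 <- colMeans(fs$chromosomes$chr1$alleles)
  pop <- expand_basepop(fs, n_new = 60, n_generations = 2)
  M <- dosage_matrix(pop)
  p1 <- colMeans(M[grep("^xb", rownames(M)), ]) / 4
  # drift sd per locus ~ sqrt(p(1-p)/(2N)) summed over 2 generations
  expect_lt(mean(abs(p1 - p0)), 0.08)
  expect_lt(abs(mean(p1) - mean(p0)), 0.02)
})

test_that("pairing_frequencies reports near-marginal rates", {
  set.seed(155)
  freqs <- pairing_frequencies(pairing_matrix(4, 2 / 3), n_meioses = 200)
  expect_equal(freqs$frequency[freqs$slot_i == 1 & freqs$slot_j == 2], 1)
  expect_equal(freqs$frequency[freqs$slot_i == 1 & freqs$slot_j == 3], 0)
})
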