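test_that("gamma effect draws match the shape-scale moment identity", {
  set.seed(201)
  x <- sample_qtn_effects(1e5, "gamma", shape = 0.2, scale = 5)
  expect_equal(mean(abs(x)), 0.2 * 5, tolerance = 0.03)
  # roughly half of the signs are negative
  expect_equal(mean(x < 0), 0.5, tolerance = 0.02)
  expect_error(sample_qtn_effects(5, "gamma", shape = -1), "positive")
})

test_that("degenerate uniform support gives unit effects", {
  set.seed(202)
  x <- sample_qtn_effects(50, "uniform", min = 1, max = 1)
  expect_true(all(abs(x) == 1))
})

test_that("additive polyploid values are centred at half ploidy", {
  arch <- trait_architecture(tibble::tibble(chrom = "c", pos = 1, a = 3,
                                            d = 0, phi = 1))
  # h = 8, c = 4 = h/2: centred contribution is zero
  expect_equal(genotypic_value(matrix(4), arch, 8), 0)
  # one a-unit increase per extra copy
  vals <- genotypic_value(matrix(0:8, ncol = 1), arch, 8)
  expect_equal(diff(vals), rep(3, 8))
})

test_that("plateau mode equalises genotypes at or above the threshold", {
  arch <- trait_architecture(tibble::tibble(chrom = "c", pos = 1, a = 1,
                                            d = 0, phi = 3),
                             dominance_mode = "plateau")
  vals <- genotypic_value(matrix(0:8, ncol = 1), arch, 8)
  expect_equal(vals[4:9], rep(3 - 4, 6))     # min(c, 3) - h/2 = -1
  expect_equal(vals[1:3], (0:2) - 4)
})

test_that("literal dominance threshold fires at phi copies", {
  arch <- trait_architecture(tibble::tibble(chrom = "c", pos = 1, a = 0,
                                            d = 2, phi = 3))
  vals <- genotypic_value(matrix(0:8, ncol = 1), arch, 8)
  expect_equal(vals, c(0, 0, 0, rep(2, 6)))
})

test_that("the polyploid model at h = 2 equals the diploid model exactly", {
  a <- 1.5
  d <- 0.7
  mu <- 10
  arch <- trait_architecture(tibble::tibble(chrom = "c", pos = 1, a = a,
                                            d = d, phi = 1), mu = mu)
  got <- genotypic_value(matrix(0:2, ncol = 1), arch, 2)
  # classical diploid parameterisation: mu + gamma*a + delta*d with
  # gamma in {-1, 0, 1} and delta the heterozygote indicator
  gamma <- c(-1, 0, 1)
  delta <- c(0, 1, 0)
  expect_equal(got, mu + gamma * a + delta * d)
  # and in plateau mode as well (the diploid path is shared)
  archp <- trait_architecture(tibble::tibble(chrom = "c", pos = 1, a = a,
                                             d = d, phi = 1), mu = mu,
                              dominance_mode = "plateau")
  expect_equal(genotypic_value(matrix(0:2, ncol = 1), archp, 2), got)
})

test_that("residual calibration follows the variance-ratio identity", {
  g <- c(1, 3, 5, 7)  # var = 20/3
  expect_equal(calibrate_residual_variance(g, 0.5), stats::var(g))
  expect_equal(calibrate_residual_variance(g, 1), 0)
  expect_equal(calibrate_residual_variance(g, 0.2), stats::var(g) * 4)
  expect_equal(calibrate_residual_variance(g, 0, sigma_e2 = 2), 2)
  expect_error(calibrate_residual_variance(g, 0), "sigma_e2")
})

test_that("phenotype equals genotypic value when heritability is one", {
  set.seed(211)
  fs <- make_founders(10, h = 4, loci_per_chrom = 20)
  pop <- gene_drop(toy_pedigree(fs$founder_ids, 1, 10), fs)
  qtn <- founder_loci(fs)[1:5, ]
  qtn$a <- rnorm(5)
  phen <- simulate_phenotypes(pop, trait_architecture(qtn, h2 = 1))
  expect_equal(phen$y, phen$g)
  expect_true(all(phen$e == 0))
})

test_that("per-QTN variance contributions behave under independence", {
  set.seed(221)
  # two-locus linkage-equilibrium population built directly from dosages
  n <- 20000
  h <- 4
  doses <- cbind(rbinom(n, h, 0.5), rbinom(n, h, 0.5))
  arch <- trait_architecture(tibble::tibble(chrom = "c", pos = 1:2,
                                            a = c(1, 2), d = 0, phi = 1))
  terms <- sweep(doses - h / 2, 2, c(1, 2), `*`)
  g <- rowSums(terms)
  contrib <- apply(terms, 2, var) / var(g)
  # additive variance scales as a^2 under equal frequencies: ratio 1:4
  expect_equal(contrib[2] / contrib[1], 4, tolerance = 0.1)
  expect_equal(sum(contrib), 1, tolerance = 0.05)

  # the same quantities through the population interface
  fs <- make_founders(40, h = 4, n_chrom = 1, loci_per_chrom = 10,
                      freq = 0.5)
  pop <- gene_drop(toy_pedigree(fs$founder_ids, 1, 200), fs)
  loci <- founder_loci(fs)
  qtn <- loci[c(2, 8), ]
  qtn$a <- c(1, 2)
  phen <- simulate_phenotypes(pop, trait_architecture(qtn, h2 = 0.8))
  qc <- qtn_contributions(phen)
  expect_equal(nrow(qc), 2)
  expect_equal(sum(qc$var_contrib), 1, tolerance = 0.15)
})

test_that("a monomorphic QTN contributes nothing, a lone QTN everything", {
  al <- matrix(c(rep(1L, 8), rep(c(0L, 1L), 4)), nrow = 8)
  al <- cbind(al, matrix(rbinom(8, 1, 0.5), 8))
  set.seed(231)
  fs <- founder_set(4, c("A", "B"),
                    list(chr1 = list(positions = c(10, 20, 30) * 1e6,
                                     alleles = al)))
  pop <- gene_drop(toy_pedigree(c("A", "B"), 1, 10), fs)
  qtn <- tibble::tibble(chrom = "chr1", pos = c(10e6, 20e6), a = c(1, 1))
  phen <- simulate_phenotypes(pop, trait_architecture(qtn, h2 = 0.5))
  qc <- qtn_contributions(phen)
  expect_equal(qc$var_contrib[qc$pos == 10e6], 0)  # monomorphic
  expect_equal(qc$var_contrib[qc$pos == 20e6], 1)  # the only variable QTN
})

test_that("traits with disjoint QTN sets are essentially uncorrelated", {
  set.seed(241)
  fs <- make_founders(20, h = 4, loci_per_chrom = 40)
  loci <- founder_loci(fs)
  cors <- replicate(10, {
    pop <- gene_drop(toy_pedigree(fs$founder_ids, 1, 100), fs)
    q1 <- loci[1:10, ]
    q1$a <- rnorm(10)
    q2 <- loci[31:40, ]
    q2$a <- rnorm(10)
    phen <- simulate_phenotypes(pop, list(
      t1 = trait_architecture(q1, h2 = 0.9),
      t2 = trait_architecture(q2, h2 = 0.9)
    ))
    wide <- tidyr::pivot_wider(phen[c("id", "trait", "y")],
                               names_from = trait, values_from = y)
    cor(wide$t1, wide$t2)
  })
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("realized heritability matches the calibration target", {
  set.seed(251)
  fs <- make_founders(30, h = 4, loci_per_chrom = 50)
  pop <- gene_drop(toy_pedigree(fs$founder_ids, 1, 2000), fs)
  qtn <- founder_loci(fs)[seq(1, 50, 2), ]
  qtn$a <- sample_qtn_effects(25)
  phen <- simulate_phenotypes(pop, trait_architecture(qtn, h2 = 0.3))
  expect_equal(var(phen$g) / var(phen$y), 0.3, tolerance = 0.03)
})
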