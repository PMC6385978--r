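test_that("linkage-equilibrium founders recover the target frequency", {
  set.seed(601)
  fs <- make_founders(50, h = 4, loci_per_chrom = 500, freq = 0.5)
  p_hat <- mean(fs$chromosomes$chr1$alleles)
  se <- sqrt(0.25 / (200 * 500))
  expect_lt(abs(p_hat - 0.5), 3 * se + 0.002)
})

test_that("ancestral-mosaic founders carry more LD than LE founders", {
  set.seed(602)
  adj_cor <- function(fs) {
    al <- fs$chromosomes$chr1$alleles
    m <- ncol(al)
    poly <- apply(al, 2, sd) > 0
    cols <- which(poly[-m] & poly[-1])
    mean(abs(sapply(cols, function(j) cor(al[, j], al[, j + 1]))))
  }
  diffs <- replicate(5, {
    le <- make_founders(30, h = 2, loci_per_chrom = 120)
    mos <- make_founders(30, h = 2, loci_per_chrom = 120, ld = "mosaic",
                         K = 2, mean_segment_bp = 2e7)
    adj_cor(mos) - adj_cor(le)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.5)
})

test_that("founder generation is a pure function of the seed", {
  make <- function() {
    set.seed(603)
    make_founders(10, h = 6, n_chrom = 2, loci_per_chrom = 30,
                  ld = "mosaic")
  }
  a <- make()
  b <- make()
  expect_identical(a$chromosomes, b$chromosomes)
})

test_that("the potato-style scenario reproduces the published plumbing", {
  set.seed(604)
  scen <- potato_scenario()
  expect_equal(nrow(scen$pedigree), 700)
  n_founder_rows <- sum(is.na(scen$pedigree$parent1) &
                          is.na(scen$pedigree$parent2))
  expect_equal(n_founder_rows, 250)
  expect_equal(length(scen$founders$individuals), 250)
  expect_equal(nrow(scen$architecture$qtn), 140)
  expect_equal(nrow(scen$panel), 407)
  expect_equal(scen$architecture$h2, 0.5)
  expect_equal(length(scen$test_ids), 150)
  # and the pedigree actually gene-drops to 700 genotyped individuals
  pop <- gene_drop(scen$pedigree, scen$founders, R = scen$R,
                   map = scen$map)
  expect_equal(length(pop$individuals), 700)
})

test_that("the strawberry-style scenario tags diploid loci correctly", {
  set.seed(605)
  scen <- strawberry_scenario(n_founders = 20, n_loci = 300, n_chrom = 3,
                              gens = 2, gen_size = 30, n_terminal = 50)
  expect_equal(length(scen$test_ids), 50)
  expect_equal(nrow(scen$panel), 300)
  expect_equal(nrow(scen$diploid_panel), round(0.36 * 300))
  # diploid-tagged loci have polymorphism confined to one slot pair:
  # founder dosage never exceeds 2
  ped0 <- tibble::tibble(id = scen$base_founders$founder_ids,
                         parent1 = NA_character_, parent2 = NA_character_)
  M <- dosage_matrix(gene_drop(ped0, scen$base_founders),
                     panel = scen$diploid_panel)
  expect_lte(max(M), 2)
  # and disomic inheritance keeps it that way down the pedigree
  pop <- gene_drop(scen$pedigree, scen$founders, R = scen$R,
                   map = scen$map)
  Md <- dosage_matrix(pop, panel = scen$diploid_panel)
  expect_lte(max(Md), 2)
})

test_that("DQP architectures draw QTNs from diploid pathway loci only", {
  set.seed(606)
  scen <- strawberry_scenario(n_founders = 15, n_loci = 400, n_chrom = 2,
                              gens = 1, gen_size = 10, n_terminal = 10,
                              architecture = "DQP", n_qtn = 10)
  loci <- founder_loci(scen$base_founders)
  allowed <- intersect(scen$pathway_idx, scen$diploid_idx)
  key <- paste(loci$chrom, loci$pos)[allowed]
  qtn_key <- paste(scen$architecture$qtn$chrom, scen$architecture$qtn$pos)
  expect_true(all(qtn_key %in% key))
})

test_that("dominant gene action sets complete dominance at phi = 1", {
  set.seed(607)
  scen <- strawberry_scenario(n_founders = 10, n_loci = 100, n_chrom = 1,
                              gens = 1, gen_size = 10, n_terminal = 10,
                              gene_action = "dominant", n_qtn = 10)
  expect_equal(scen$architecture$qtn$d, abs(scen$architecture$qtn$a))
  expect_true(all(scen$architecture$qtn$phi == 1))
})

test_that("scenario bundles pass the input validators end to end", {
  set.seed(608)
  scen <- strawberry_scenario(n_founders = 8, n_loci = 60, n_chrom = 2,
                              gens = 1, gen_size = 8, n_terminal = 8,
                              n_qtn = 5)
  dir <- withr::local_tempdir()
  files <- write_scenario_bundle(scen, dir)
  expect_true(all(file.exists(files)))
  fs <- read_polyploid_vcf(file.path(dir, "founders.vcf"), 8)
  expect_identical(fs$chromosomes, scen$base_founders$chromosomes)
  ped <- read_pedigree(file.path(dir, "ped.txt"))
  expect_equal(nrow(ped), nrow(scen$pedigree))
  qtn <- read_loci_list(file.path(dir, "qtn.txt"), fs)
  expect_equal(nrow(qtn), 5)
  expect_named(qtn, c("chrom", "pos", "a", "d", "phi"))
  p <- read_params(file.path(dir, "params.cfg"))
  expect_equal(p$ploidy, 8L)
})
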