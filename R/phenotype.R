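#' Trait architecture
#'
#' A trait is defined by its QTNs (positions with per-copy additive effects
#' `a`, dominance effects `d` and integer dominance thresholds `phi`), a
#' mean `mu` and a target heritability `h2`. `phi` is the minimum number of
#' copies of the alternative allele at which the dominance deviation `d` is
#' expressed; with `dominance_mode = "plateau"` the additive contribution
#' also saturates at `phi` copies, so all genotypes with `phi` or more
#' copies share one expected phenotype.
#'
#' @param qtn Tibble with columns `chrom`, `pos` and optionally `a`, `d`,
#'   `phi` (defaults 0, 0 and 1).
#' @param mu Trait mean (default 0).
#' @param h2 Target heritability in `[0, 1]`.
#' @param dominance_mode `"literal"` (additive term always `(c - h/2) a`)
#'   or `"plateau"` (additive term saturates at `phi` copies).
#' @return A `trait_architecture` object.
#' @export
trait_architecture <- function(qtn, mu = 0, h2 = 0.5,
                               dominance_mode = c("literal", "plateau")) {
  dominance_mode <- match.arg(dominance_mode)
  stopifnot(all(c("chrom", "pos") %in% names(qtn)))
  qtn <- tibble::as_tibble(qtn)
  if (!"a" %in% names(qtn)) qtn$a <- 0
  if (!"d" %in% names(qtn)) qtn$d <- 0
  if (!"phi" %in% names(qtn)) qtn$phi <- 1
  qtn$phi[is.na(qtn$phi)] <- 1
  qtn$d[is.na(qtn$d)] <- 0
  if (any(qtn$phi < 1)) stop("phi must be >= 1", call. = FALSE)
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]", call. = FALSE)
  structure(list(qtn = qtn, mu = mu, h2 = h2,
                 dominance_mode = dominance_mode),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("<trait_architecture>", nrow(x$qtn), "QTNs | mu =", x$mu,
      "| target h2 =", x$h2, "| dominance:", x$dominance_mode, "\n")
  invisible(x)
}

#' Sample QTN effects
#'
#' Draws `n` effects from a gamma, normal or uniform distribution. Gamma
#' uses the (shape, scale) parameterisation, mean `shape * scale`; since
#' gamma draws are positive while QTN effects must be bidirectional, each
#' draw is given a random sign with probability 1/2 (the usual device for
#' leptokurtic architectures; disable with `random_sign = FALSE`).
#'
#' @param n Number of effects.
#' @param dist `"gamma"`, `"normal"` or `"uniform"`.
#' @param shape,scale Gamma parameters (default the leptokurtic
#'   shape 0.2, scale 5 used in the worked examples).
#' @param mean,sd Normal parameters.
#' @param min,max Uniform parameters.
#' @param random_sign Apply a +/- sign with probability 1/2 to gamma draws.
#' @return Numeric vector of length `n`.
#' @export
sample_qtn_effects <- function(n, dist = c("gamma", "normal", "uniform"),
                               shape = 0.2, scale = 5, mean = 0, sd = 1,
                               min = -1, max = 1, random_sign = TRUE) {
  dist <- match.arg(dist)
  switch(dist,
    gamma = {
      if (shape <= 0 || scale <= 0) {
        stop("gamma shape and scale must be positive", call. = FALSE)
      }
      x <- stats::rgamma(n, shape = shape, scale = scale)
      if (random_sign) x <- x * sample(c(-1, 1), n, replace = TRUE)
      x
    },
    normal = {
      if (sd < 0) stop("sd must be non-negative", call. = FALSE)
      stats::rnorm(n, mean, sd)
    },
    uniform = {
      if (max < min) stop("uniform requires min <= max", call. = FALSE)
      x <- stats::runif(n, min, max)
      if (random_sign && min >= 0) x <- x * sample(c(-1, 1), n, replace = TRUE)
      x
    }
  )
}

## per-QTN genotypic terms; rows = individuals, cols = QTNs
gvalue_terms <- function(dosages, arch, h) {
  stopifnot(is.matrix(dosages), ncol(dosages) == nrow(arch$qtn))
  if (any(dosages < 0 | dosages > h)) {
    stop("dosages outside [0, ", h, "]", call. = FALSE)
  }
  a <- arch$qtn$a
  d <- arch$qtn$d
  phi <- arch$qtn$phi
  n <- nrow(dosages)
  add_c <- if (arch$dominance_mode == "plateau" && h > 2L) {
    pmin(dosages, matrix(phi, n, length(phi), byrow = TRUE))
  } else dosages
  terms <- sweep(add_c - h / 2, 2L, a, `*`)
  if (h == 2L) {
    # diploid model: dominance deviation is expressed by heterozygotes only
    dom <- (dosages == 1L)
  } else {
    dom <- sweep(dosages, 2L, phi, `>=`)
  }
  terms + sweep(dom, 2L, d, `*`)
}

#' Genotypic value of polyploid genotypes
#'
#' Additive/threshold-dominance model: each QTN contributes
#' `(c - h/2) * a + 1[c >= phi] * d`, where `c` is the allele dosage. With
#' `dominance_mode = "plateau"` the additive dosage saturates at `phi`. At
#' `h = 2` the dominance indicator is the classical heterozygote indicator,
#' recovering the standard diploid additive-dominance model exactly.
#'
#' @param dosages Integer matrix (individuals x QTNs) of dosages `0..h`,
#'   columns in the order of `arch$qtn`; a vector is treated as one
#'   individual.
#' @param arch A [trait_architecture()].
#' @param h Ploidy level.
#' @return Numeric vector of genotypic values (including `mu`).
#' @export
genotypic_value <- function(dosages, arch, h) {
  if (!is.matrix(dosages)) dosages <- matrix(dosages, nrow = 1L)
  arch$mu + rowSums(gvalue_terms(dosages, arch, h))
}

#' Residual variance for a target heritability
#'
#' `sigma_e^2 = Var(g) * (1 - h2) / h2`, from the genotypic values of a
#' reference population. `h2 = 1` gives 0; `h2 = 0` is only admissible with
#' a user-supplied residual variance.
#'
#' @param g Genotypic values of the reference population.
#' @param h2 Target heritability.
#' @param sigma_e2 Optional explicit residual variance overriding the
#'   calibration.
#' @return Residual variance (scalar).
#' @export
calibrate_residual_variance <- function(g, h2, sigma_e2 = NULL) {
  if (!is.null(sigma_e2)) return(sigma_e2)
  if (h2 == 0) {
    stop("h2 = 0 leaves the residual variance undefined; ",
         "supply `sigma_e2`", call. = FALSE)
  }
  if (h2 == 1) return(0)
  vg <- stats::var(g)
  if (vg == 0) {
    stop("genotypic variance is zero; cannot calibrate residual variance",
         call. = FALSE)
  }
  vg * (1 - h2) / h2
}

#' Simulate phenotypes for a population
#'
#' Computes genotypic values at the QTNs of each architecture, calibrates
#' the residual variance to the architecture's target heritability on a
#' reference population, and adds i.i.d. normal residuals. Also reports
#' each QTN's contribution to the genotypic variance (variance of its own
#' term across the population divided by `Var(g)`; contributions sum to 1
#' only under linkage equilibrium).
#'
#' @param population A `polysim_population`.
#' @param architectures A [trait_architecture()] or a named list of them.
#' @param reference `"all"` (every simulated individual; default) or
#'   `"founders"`: the population whose `Var(g)` calibrates the residual.
#' @param sigma_e2 Optional per-trait residual variances bypassing the
#'   calibration.
#' @return A tibble of class `phenotype_sim` with columns
#'   `id`, `trait`, `g`, `e`, `y`; attributes `qtn_contrib` (tibble),
#'   `sigma_e2` (named vector) and `dominance_mode`.
#' @export
simulate_phenotypes <- function(population, architectures,
                                reference = c("all", "founders"),
                                sigma_e2 = NULL) {
  reference <- match.arg(reference)
  if (inherits(architectures, "trait_architecture")) {
    architectures <- list(trait1 = architectures)
  }
  if (is.null(names(architectures))) {
    names(architectures) <- paste0("trait", seq_along(architectures))
  }
  h <- population$founders$h
  ped <- population$pedigree
  founder_rows <- is.na(ped$parent1) & is.na(ped$parent2)
  out <- vector("list", length(architectures))
  contribs <- vector("list", length(architectures))
  s2 <- numeric(0)
  for (tr in names(architectures)) {
    arch <- architectures[[tr]]
    M <- dosage_matrix(population, panel = arch$qtn[c("chrom", "pos")])
    terms <- gvalue_terms(M, arch, h)
    g <- arch$mu + rowSums(terms)
    ref_g <- if (reference == "founders") g[founder_rows] else g
    se2 <- calibrate_residual_variance(ref_g, arch$h2,
                                       sigma_e2 = sigma_e2[[tr]])
    e <- stats::rnorm(length(g), 0, sqrt(se2))
    out[[tr]] <- tibble::tibble(id = ped$id, trait = tr, g = g, e = e,
                                y = g + e)
    vg <- stats::var(g)
    contribs[[tr]] <- dplyr::mutate(
      arch$qtn,
      trait = tr,
      var_contrib = if (vg > 0) {
        unname(apply(terms, 2L, stats::var)) / vg
      } else 0
    )
    s2[tr] <- se2
  }
  res <- dplyr::bind_rows(out)
  attr(res, "qtn_contrib") <- dplyr::bind_rows(contribs)
  attr(res, "sigma_e2") <- s2
  attr(res, "dominance_mode") <-
    vapply(architectures, `[[`, "", "dominance_mode")
  class(res) <- c("phenotype_sim", class(res))
  res
}

#' @export
print.phenotype_sim <- function(x, ...) {
  NextMethod()
  s2 <- attr(x, "sigma_e2")
  cat("# residual variance:",
      paste(sprintf("%s = %.4g", names(s2), s2), collapse = ", "), "\n")
  invisible(x)
}

#' Per-QTN variance contributions of a phenotype simulation
#'
#' @param phenotypes Result of [simulate_phenotypes()].
#' @return Tibble `(trait, chrom, pos, a, d, phi, var_contrib)`.
#' @export
qtn_contributions <- function(phenotypes) {
  out <- attr(phenotypes, "qtn_contrib")
  dplyr::select(out, trait, chrom, pos, dplyr::any_of(c("a", "d", "phi")),
                var_contrib)
}
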