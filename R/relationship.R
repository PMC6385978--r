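#' Recode a dosage matrix under a genotype-scoring mode
#'
#' Models dosage-calling degradation. `GT` keeps true dosages `0..h`.
#' `MIMIC_DIPLOID` assumes only 0, 1 and "2 or more" copies can be
#' distinguished: entries are capped at 2 and the effective ploidy becomes
#' 2. `MIMIC_HAPLOID` assumes only the all-reference homozygote can be
#' distinguished from the rest: entries become presence/absence (0/1) with
#' effective ploidy 1.
#'
#' @param M Integer dosage matrix with a `ploidy` attribute (see
#'   [dosage_matrix()]).
#' @param mode `"GT"`, `"MIMIC_DIPLOID"` or `"MIMIC_HAPLOID"`.
#' @return Recoded matrix with its `ploidy` attribute updated.
#' @export
recode_dosage <- function(M, mode = c("GT", "MIMIC_DIPLOID",
                                      "MIMIC_HAPLOID")) {
  mode <- match.arg(mode)
  dn <- dimnames(M)
  out <- switch(mode,
    GT = M,
    MIMIC_DIPLOID = pmin(M, 2L),
    MIMIC_HAPLOID = (M >= 1L) * 1L
  )
  out <- matrix(as.integer(out), nrow(M), ncol(M), dimnames = dn)
  attr(out, "ploidy") <- switch(mode,
    GT = attr(M, "ploidy"),
    MIMIC_DIPLOID = min(2L, attr(M, "ploidy")),
    MIMIC_HAPLOID = 1L
  )
  out
}

#' Polyploid genomic relationship matrix
#'
#' The VanRaden-type matrix generalised to ploidy `h`:
#' `G = (M - h p)(M - h p)' / (h * sum_j p_j (1 - p_j))`, with `M` the
#' dosage matrix, `p` the allele-frequency vector and `h` the effective
#' ploidy of the scoring mode. At `h = 2` this is the standard diploid
#' formula. Monomorphic markers carry no information: they contribute
#' nothing to the numerator and are excluded from the denominator sum.
#'
#' @param M Dosage matrix with a `ploidy` attribute (possibly recoded by
#'   [recode_dosage()]).
#' @param ploidy Effective ploidy; default the matrix's `ploidy` attribute.
#' @param freq Optional externally supplied allele frequencies; default
#'   `colMeans(M) / ploidy` computed from the full genotyped set.
#' @return Symmetric n x n matrix with ids as dimnames.
#' @export
grm <- function(M, ploidy = attr(M, "ploidy"), freq = NULL) {
  stopifnot(is.matrix(M), !is.null(ploidy))
  h <- ploidy
  p <- if (is.null(freq)) colMeans(M) / h else freq
  if (length(p) != ncol(M)) stop("freq length mismatch", call. = FALSE)
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    stop("all markers are monomorphic; the relationship matrix is undefined",
         call. = FALSE)
  }
  Z <- sweep(M[, poly, drop = FALSE], 2L, h * p[poly])
  denom <- h * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' Pedigree numerator relationship matrix
#'
#' Tabular (recursive) method with diploid coefficients: founders are
#' unrelated and non-inbred; `A[i, j] = (A[s, j] + A[d, j]) / 2` for parents
#' `s`, `d` of `i`, and `A[i, i] = 1 + A[s, d] / 2`. Unknown parents
#' contribute zero. Polysomic kinship coefficients are out of scope; the
#' diploid convention is the one used in routine polyploid evaluations.
#'
#' @param pedigree Tibble `(id, parent1, parent2)` in topological order.
#' @return Symmetric n x n matrix with ids as dimnames.
#' @export
pedigree_relationship <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  s_idx <- match(ped$parent1, ped$id)
  d_idx <- match(ped$parent2, ped$id)
  for (i in seq_len(n)) {
    s <- s_idx[i]
    d <- d_idx[i]
    if (i > 1L) {
      js <- seq_len(i - 1L)
      rel <- (if (!is.na(s)) A[js, s] else 0) / 2 +
             (if (!is.na(d)) A[js, d] else 0) / 2
      A[js, i] <- rel
      A[i, js] <- rel
    }
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
  }
  A
}

#' Write a relationship matrix as id-pair triples
#'
#' The streaming/diffable layout `id_i id_j value` over the upper triangle
#' including the diagonal; `dense = TRUE` writes the square matrix with a
#' header of ids instead.
#'
#' @param G Relationship matrix with id dimnames.
#' @param path Output path.
#' @param dense Write the dense square layout instead of triples.
#' @return `path`, invisibly.
#' @export
write_grm <- function(G, path, dense = FALSE) {
  if (dense) {
    utils::write.table(cbind(id = rownames(G), as.data.frame(G)), path,
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  idx <- which(upper.tri(G, diag = TRUE), arr.ind = TRUE)
  d <- data.frame(id_i = rownames(G)[idx[, 1L]],
                  id_j = colnames(G)[idx[, 2L]],
                  value = G[idx])
  utils::write.table(d, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a relationship matrix written by [write_grm()]
#'
#' @param path Path to a triples file.
#' @return Symmetric matrix with id dimnames.
#' @export
read_grm <- function(path) {
  d <- utils::read.table(path, header = FALSE,
                         colClasses = c("character", "character", "numeric"))
  ids <- unique(c(d[[1L]], d[[2L]]))
  G <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  G[cbind(d[[1L]], d[[2L]])] <- d[[3L]]
  G[cbind(d[[2L]], d[[1L]])] <- d[[3L]]
  G
}
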