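#' Solve the GBLUP mixed-model equations
#'
#' Best linear unbiased prediction of genetic values from a relationship
#' matrix K (genomic or pedigree) and training phenotypes: the intercept is
#' the generalised-least-squares mean under `V = K_tt + lambda I`, training
#' values are `K_tt (K_tt + lambda I)^-1 (y - mu)` and test individuals are
#' predicted through their kinship with the training set. `lambda` is the
#' residual-to-genetic variance ratio `(1 - h2) / h2`, taken from the known
#' simulated heritability by default; [estimate_lambda_ml()] offers a 1-D
#' maximum-likelihood grid search when realism is wanted.
#'
#' @param K Symmetric relationship matrix with id dimnames.
#' @param y Named numeric vector of phenotypes, or a data frame with
#'   columns `id` and `y`; only training entries are used.
#' @param train Logical vector along `K`, or a vector of training ids.
#' @param h2 Heritability used to form `lambda = (1 - h2) / h2`.
#' @param lambda Variance ratio, overriding `h2`.
#' @param jitter Diagonal jitter added (with a message) if the training
#'   system is numerically singular.
#' @return A `gblup_fit`: list with `mu`, and a tibble `predictions`
#'   (`id`, `train`, `observed`, `ghat`, `yhat`); supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @export
solve_gblup <- function(K, y, train = NULL, h2 = NULL, lambda = NULL,
                        jitter = 1e-8) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  ids <- rownames(K)
  if (is.data.frame(y)) y <- stats::setNames(y$y, y$id)
  if (!is.null(names(y)) && !is.null(ids)) {
    y <- y[ids]
  }
  n <- nrow(K)
  if (is.null(train)) train <- rep(TRUE, n)
  if (!is.logical(train)) train <- ids %in% train
  if (sum(train) < 2L) stop("at least 2 training individuals are required",
                            call. = FALSE)
  if (is.null(lambda)) {
    if (is.null(h2)) stop("supply either `h2` or `lambda`", call. = FALSE)
    if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]", call. = FALSE)
    lambda <- (1 - h2) / h2
  }
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  yt <- y[train]
  if (anyNA(yt)) stop("training phenotypes contain NA", call. = FALSE)
  Ktt <- K[train, train, drop = FALSE]
  V <- Ktt + diag(lambda, sum(train))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    message("training system numerically singular; adding diagonal jitter ",
            jitter)
    ch <- chol(V + diag(jitter, nrow(V)))
  }
  Vinv_y <- backsolve(ch, forwardsolve(t(ch), yt))
  Vinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, length(yt))))
  mu <- sum(Vinv_y) / sum(Vinv_1)
  alpha <- backsolve(ch, forwardsolve(t(ch), yt - mu))
  ghat <- drop(K[, train, drop = FALSE] %*% alpha)
  pred <- tibble::tibble(
    id = if (is.null(ids)) as.character(seq_len(n)) else ids,
    train = train,
    observed = unname(y),
    ghat = unname(ghat),
    yhat = mu + unname(ghat)
  )
  structure(list(mu = mu, lambda = lambda, predictions = pred),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("<gblup_fit> n =", nrow(x$predictions), "( train",
      sum(x$predictions$train), ") | lambda =", format(x$lambda),
      "| mu =", format(x$mu), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.gblup_fit <- function(x, ...) x$predictions

#' @export
glance.gblup_fit <- function(x, ...) {
  p <- x$predictions
  test <- dplyr::filter(p, !train)
  tibble::tibble(
    n = nrow(p),
    n_train = sum(p$train),
    n_test = nrow(test),
    lambda = x$lambda,
    mu = x$mu,
    pa_test = if (nrow(test) >= 3L && stats::sd(test$observed) > 0 &&
                  stats::sd(test$yhat) > 0) {
      stats::cor(test$observed, test$yhat)
    } else NA_real_
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.gblup_fit <- function(object, ...) {
  p <- object$predictions
  p$set <- ifelse(p$train, "training", "test")
  ggplot2::ggplot(p, ggplot2::aes(x = yhat, y = observed,
                                  colour = set)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(x = "predicted phenotype", y = "observed phenotype",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Maximum-likelihood variance ratio on a grid
#'
#' Profile log-likelihood of `y_train ~ N(mu 1, sigma2 (K + lambda I))`
#' over a grid of `lambda`, with `sigma2` and `mu` profiled out.
#'
#' @inheritParams solve_gblup
#' @param grid Candidate `lambda` values.
#' @return The grid value with the highest profile likelihood.
#' @export
estimate_lambda_ml <- function(K, y, train = NULL,
                               grid = exp(seq(log(0.05), log(20),
                                              length.out = 40))) {
  ids <- rownames(K)
  if (is.data.frame(y)) y <- stats::setNames(y$y, y$id)
  if (!is.null(names(y)) && !is.null(ids)) y <- y[ids]
  if (is.null(train)) train <- rep(TRUE, nrow(K))
  if (!is.logical(train)) train <- ids %in% train
  yt <- y[train]
  Ktt <- K[train, train, drop = FALSE]
  n <- length(yt)
  ll <- vapply(grid, function(lam) {
    V <- Ktt + diag(lam, n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    Viy <- backsolve(ch, forwardsolve(t(ch), yt))
    mu <- sum(Viy) / sum(Vi1)
    r <- yt - mu
    Vir <- backsolve(ch, forwardsolve(t(ch), r))
    s2 <- sum(r * Vir) / n
    -0.5 * (n * log(s2) + 2 * sum(log(diag(ch))) + n)
  }, 0)
  grid[which.max(ll)]
}

#' Predictive ability
#'
#' Pearson correlation between observed and predicted phenotypes over the
#' test set, the standard accuracy measure of genomic-selection
#' cross-validation.
#'
#' @param observed,predicted Numeric vectors.
#' @param test Optional logical mask or index vector selecting the test
#'   set; default all.
#' @return Scalar correlation.
#' @export
predictive_ability <- function(observed, predicted, test = NULL) {
  if (!is.null(test)) {
    observed <- observed[test]
    predicted <- predicted[test]
  }
  if (length(observed) < 3L) {
    stop("at least 3 test individuals are required", call. = FALSE)
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("zero variance in observed or predicted values", call. = FALSE)
  }
  stats::cor(observed, predicted)
}

#' Replicated genomic-selection experiment
#'
#' For each replicate: simulate a breeding scheme (founders, pedigree,
#' trait), mask the phenotypes of the final generation, predict them with
#' each requested kinship, and record the predictive ability. Kinships:
#' `GT` (true-dosage GRM on the full panel), `G2` (GRM restricted to the
#' loci tagged as segregating in a single sub-genome pair, i.e. behaving
#' as diploid markers), `G2star` (diploidized scoring of the full panel),
#' `A` (pedigree numerator matrix) and `noise` (a kinship built from
#' random markers unrelated to the data; the no-information floor).
#'
#' @param scenario A scenario bundle as returned by
#'   [strawberry_scenario()] / [potato_scenario()], or a function of the
#'   replicate number returning one.
#' @param methods Character subset of
#'   `c("GT", "G2", "G2star", "A", "noise")`.
#' @param n_reps Number of replicates.
#' @return A `gs_experiment`: tibble `(replicate, method, pa, pa_g)`
#'   (`pa_g` correlates predictions with true genotypic values, a
#'   diagnostic); [tidy()] summarises mean and standard error per method.
#' @export
run_gs_experiment <- function(scenario,
                              methods = c("GT", "G2", "G2star", "A"),
                              n_reps = 20) {
  methods <- match.arg(methods, c("GT", "G2", "G2star", "A", "noise"),
                       several.ok = TRUE)
  make_bundle <- if (is.function(scenario)) scenario else function(r) scenario
  rows <- vector("list", 0L)
  for (r in seq_len(n_reps)) {
    bundle <- make_bundle(r)
    pop <- gene_drop(bundle$pedigree, bundle$founders, R = bundle$R,
                     map = bundle$map)
    arch <- bundle$architecture
    phen <- simulate_phenotypes(pop, arch)
    test <- bundle$test_ids
    train <- !phen$id %in% test
    y <- stats::setNames(phen$y, phen$id)
    M <- dosage_matrix(pop, panel = bundle$panel)
    for (meth in methods) {
      K <- switch(meth,
        GT = grm(M),
        G2 = grm(dosage_matrix(pop, panel = bundle$diploid_panel)),
        G2star = grm(recode_dosage(M, "MIMIC_DIPLOID")),
        A = pedigree_relationship(pop$pedigree),
        noise = {
          Z <- matrix(stats::rnorm(nrow(M) * 200L), nrow(M))
          rownames(Z) <- rownames(M)
          tcrossprod(Z) / 200
        }
      )
      fit <- solve_gblup(K, y, train = train, h2 = arch$h2)
      pr <- fit$predictions
      te <- !pr$train
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = r, method = meth,
        pa = predictive_ability(pr$observed[te], pr$yhat[te]),
        pa_g = stats::cor(phen$g[te], pr$yhat[te])
      )
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("gs_experiment", class(tibble::tibble())))
}

#' @export
tidy.gs_experiment <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), method),
    n_reps = dplyr::n(),
    pa_mean = mean(pa),
    pa_se = stats::sd(pa) / sqrt(dplyr::n()),
    pa_g_mean = mean(pa_g),
    .groups = "drop"
  )
}

#' @export
autoplot.gs_experiment <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = method, y = pa)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "predictive ability") +
    ggplot2::theme_minimal()
}
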