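#' Sparse precision-matrix estimation by the graphical lasso
#'
#' Fits an L1-penalized Gaussian graphical model: maximises
#' `log det(Theta) - tr(S Theta) - lam * ||Theta||_{1,off}` over positive
#' definite `Theta`, where `S` is the sample correlation matrix of the
#' (internally standardized) data. Solved by block coordinate descent with
#' an inner lasso; only off-diagonal entries are penalized.
#'
#' @param data Numeric matrix or data frame, samples in rows, metabolites
#'   in columns (named).
#' @param lam Nonnegative regularization penalty.
#' @param tol Relative convergence tolerance on the working covariance.
#' @param maxit Maximum outer sweeps.
#' @return A `precision_matrix`: list with `metabolite_ids` and the
#'   symmetric positive-definite matrix `theta`.
#' @export
glasso_fit <- function(data, lam, tol = 1e-5, maxit = 200) {
  X <- prepare_glasso_data(data)
  S <- cor(X)
  fit <- .glasso_cpp(S, lam, tol, maxit)
  if (!fit$converged) stopf("graphical lasso failed to converge at lam = %g", lam)
  new_precision_matrix(fit$theta, colnames(X))
}

new_precision_matrix <- function(theta, ids) {
  dimnames(theta) <- list(ids, ids)
  if (max(abs(theta - t(theta))) > 1e-8) stopf("precision matrix not symmetric")
  if (any(diag(theta) <= 0)) stopf("non-positive precision diagonal")
  structure(list(metabolite_ids = ids, theta = theta),
            class = "precision_matrix")
}

#' @export
print.precision_matrix <- function(x, ...) {
  cat(sprintf("<precision_matrix> %d metabolites, %d nonzero off-diagonal pairs\n",
              length(x$metabolite_ids),
              sum(abs(x$theta[upper.tri(x$theta)]) > 1e-12)))
  invisible(x)
}

prepare_glasso_data <- function(data) {
  X <- as.matrix(data)
  if (!is.numeric(X)) stopf("data must be numeric")
  if (any(!is.finite(X))) stopf("non-finite values in data")
  if (nrow(X) < 3) stopf("need at least 3 samples, got %d", nrow(X))
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%03d", seq_len(ncol(X)))
  # standardize columns; constant columns get unit variance to stay finite
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  scale(X, center = mu, scale = s)
}

#' Regularization path for the graphical lasso
#'
#' 30 log-spaced penalties from `lambda_max` (the largest absolute
#' off-diagonal sample correlation, at which the estimated graph is empty)
#' down to `lambda_min_ratio * lambda_max` (default 10%, matching the
#' customary graphical-lasso path floor; far below it the near-singular
#' fits are slow and never selected by StARS).
#'
#' @param data Samples x metabolites matrix.
#' @param n_lambda Path length. Default 30.
#' @param lambda_min_ratio Smallest penalty relative to `lambda_max`.
#'   Default 0.01.
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_path <- function(data, n_lambda = 30, lambda_min_ratio = 0.1) {
  X <- prepare_glasso_data(data)
  S <- cor(X)
  lmax <- max(abs(S[upper.tri(S)]), 1e-4)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' StARS penalty selection for the graphical lasso
#'
#' Stability Approach to Regularization Selection: fits the glasso path on
#' `n_subsamples` random subsamples of size `floor(10 * sqrt(n))`, capped
#' at 80% of `n` so that small cohorts still produce diverse subsamples,
#' measures per-edge selection instability `2 * f * (1 - f)`
#' (with `f` the selection frequency) averaged over all node pairs,
#' monotonizes the instability curve from the sparse end, and selects the
#' smallest penalty whose monotonized instability stays at or below
#' `instability_threshold`.
#'
#' @param data Samples x metabolites matrix (n >= 10).
#' @param lambdas Optional decreasing penalty path; defaults to
#'   [lambda_path()] on `data`.
#' @param n_subsamples Number of subsamples. Default 20.
#' @param instability_threshold Instability bound (0.1 is the canonical
#'   choice). Default 0.1.
#' @param seed Integer seed driving the subsampling (mandatory for
#'   reproducible provenance).
#' @param tol,maxit Passed to the glasso solver; the default tolerance is
#'   looser than [glasso_fit()]'s because only edge supports enter the
#'   instability statistic.
#' @return A `stars_selection`: lambda path, per-lambda raw and monotonized
#'   instabilities, `selected_lambda`, subsample bookkeeping, and
#'   `all_unstable` flag (TRUE when no penalty met the threshold and the
#'   largest penalty was returned).
#' @export
stars_select <- function(data, lambdas = NULL, n_subsamples = 20,
                         instability_threshold = 0.1, seed,
                         tol = 1e-4, maxit = 200) {
  X <- prepare_glasso_data(data)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 10) stopf("StARS needs at least 10 samples, got %d", n)
  if (missing(seed) || is.null(seed)) stopf("StARS requires a seed")
  if (is.null(lambdas)) lambdas <- lambda_path(X)
  lambdas <- sort(lambdas, decreasing = TRUE)
  # subsample size: 10*sqrt(n) for large n, 80% of n for small cohorts
  # (where 10*sqrt(n) would approach n and kill subsampling diversity)
  b <- min(floor(10 * sqrt(n)), floor(0.8 * n), n - 1)
  n_pairs <- choose(p, 2)

  freq <- matrix(0, length(lambdas), n_pairs)
  with_seed(seed, {
    for (s in seq_len(n_subsamples)) {
      idx <- sample.int(n, b)
      Xs <- X[idx, , drop = FALSE]
      Ss <- cor(Xs)
      path <- .glasso_path_cpp(Ss, lambdas, tol, maxit, FALSE)
      for (l in seq_along(lambdas)) {
        supp <- path$supports[[l]]
        freq[l, ] <- freq[l, ] + supp[upper.tri(supp)] / n_subsamples
      }
    }
  })
  instability <- rowSums(2 * freq * (1 - freq)) / n_pairs
  mono <- cummax(instability)
  ok <- which(mono <= instability_threshold)
  all_unstable <- length(ok) == 0
  selected <- if (all_unstable) lambdas[1] else lambdas[max(ok)]
  if (all_unstable) {
    warnf("all penalties exceed instability threshold %g; returning the largest",
          instability_threshold)
  }
  structure(list(lambda_path = lambdas,
                 instability_per_lambda = instability,
                 monotonized_instability = mono,
                 selected_lambda = selected,
                 subsample_count = n_subsamples,
                 subsample_size = b,
                 instability_threshold = instability_threshold,
                 all_unstable = all_unstable,
                 seed = as.integer(seed)),
            class = "stars_selection")
}

#' @export
print.stars_selection <- function(x, ...) {
  cat(sprintf("<stars_selection> lambda = %.4g (path of %d, %d subsamples of %d%s)\n",
              x$selected_lambda, length(x$lambda_path), x$subsample_count,
              x$subsample_size,
              if (x$all_unstable) ", all unstable" else ""))
  invisible(x)
}

#' @export
tidy.stars_selection <- function(x, ...) {
  tibble::tibble(lambda = x$lambda_path,
                 instability = x$instability_per_lambda,
                 monotonized = x$monotonized_instability,
                 selected = x$lambda_path == x$selected_lambda)
}

#' @export
glance.stars_selection <- function(x, ...) {
  tibble::tibble(selected_lambda = x$selected_lambda,
                 subsample_count = x$subsample_count,
                 subsample_size = x$subsample_size,
                 instability_threshold = x$instability_threshold,
                 all_unstable = x$all_unstable,
                 seed = x$seed)
}

#' @export
autoplot.stars_selection <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$lambda, .data$monotonized)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(y = .data$instability), alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$instability_threshold,
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = object$selected_lambda,
                        colour = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lambda", y = "edge-selection instability")
}
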