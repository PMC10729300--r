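# run code under a temporary RNG state so library calls stay pure
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded k-fold split
#'
#' Uniformly shuffles indices 1..n under the given seed and chunks the
#' shuffled order into k contiguous validation folds whose sizes differ
#' by at most one (the remainder goes to the leading folds). Identical
#' seed, identical folds.
#'
#' @param n Number of observations.
#' @param k Number of folds, \code{2 <= k <= n}.
#' @param seed Integer seed.
#' @return List of k integer vectors (validation indices) that
#'   partition \code{1:n}.
#' @examples
#' lengths(kfold_split(161, 10, seed = 1))  # one 17, nine 16
#' @export
kfold_split <- function(n, k, seed = 1) {
  stopifnot(k >= 2)
  if (k > n) stop("k = ", k, " exceeds n = ", n, call. = FALSE)
  idx <- with_seed(seed, sample.int(n))
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  purrr::map2(starts, ends, function(s, e) sort(idx[s:e]))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Returns
#' \code{NA} with a warning when either vector is constant, where the
#' coefficient is undefined.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return Spearman's rho in [-1, 1], or \code{NA}.
#' @export
spearman_rho <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant vector: Spearman's rho undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-adjusted tau-b: (concordant - discordant) /
#' sqrt((P - T_a)(P - T_b)) with P = n(n-1)/2 and T the within-vector
#' tied pair counts.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return Kendall's tau-b in [-1, 1], or \code{NA} for a constant
#'   vector.
#' @export
kendall_tau <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant vector: Kendall's tau undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "kendall")
}

#' Cross-validated rank-correlation assessment of a ranking model
#'
#' The model-selection protocol: split the dataset into k folds; for
#' each fold fit the model on the training split (target z-scoring and
#' the combined metric computed from the training split only), score
#' the held-out variants, and correlate the scores with the held-out
#' measured combined metric (z-scored using the training-fold
#' statistics) by Spearman's rho and Kendall's tau-b. The GP family is
#' scored by the UCB of the combined metric (the quantity used for
#' ranking); the random-forest baseline by its point prediction of the
#' combined metric. Per-fold correlations are averaged by default.
#'
#' @param data Variant tibble with \code{sequence} and the objective's
#'   target columns.
#' @param spec An [objective_spec()].
#' @param kernel A [kernel_spec()] (GP family only).
#' @param model \code{"gp"} or \code{"rf"}.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the split (and the RF's
#'   bootstrap).
#' @param lambda GP regularization constant.
#' @param score \code{"ucb"} (default for GP) or \code{"mean"}; the RF
#'   always uses its point prediction.
#' @param aggregate \code{"fold_mean"} (default; average of per-fold
#'   correlations) or \code{"pooled"} (one correlation over all
#'   held-out predictions pooled).
#' @param rf_trees Number of trees for the RF baseline (default 100,
#'   mirroring the baseline protocol's default settings).
#' @return An object of class \code{cv_report}: per-fold results,
#'   summary correlations and the resolved configuration. Access the
#'   fold table with [tidy()] and the summary with [glance()].
#' @export
cross_validate <- function(data, spec = objective_spec(),
                           kernel = kernel_spec(),
                           model = c("gp", "rf"), k = 10, seed = 1,
                           lambda = 1, score = c("ucb", "mean"),
                           aggregate = c("fold_mean", "pooled"),
                           rf_trees = 100) {
  model <- match.arg(model)
  score <- match.arg(score)
  aggregate <- match.arg(aggregate)
  n <- nrow(data)
  folds <- kfold_split(n, k, seed)
  emb <- if (model == "rf") onehot_embed(data$sequence) else NULL
  fold_rows <- vector("list", k)
  pooled_pred <- pooled_meas <- numeric(0)
  for (i in seq_len(k)) {
    val_idx <- folds[[i]]
    tr_idx <- setdiff(seq_len(n), val_idx)
    train <- dplyr::slice(data, tr_idx)
    val <- dplyr::slice(data, val_idx)
    st <- target_stats(train, spec)
    val_c <- combine_targets(val, spec, stats = st)$combined
    if (model == "gp") {
      m <- fit_acquisition_model(train, spec, kernel, lambda)
      pred <- stats::predict(m, val)
      pc <- dplyr::filter(pred, .data$target == "combined")
      sc <- if (score == "ucb") ucb(pc$mu, pc$sigma, spec$beta) else pc$mu
    } else {
      train_c <- combine_targets(train, spec, stats = st)
      sc <- rf_fit_predict(emb[tr_idx, , drop = FALSE],
                           train_c["combined"],
                           emb[val_idx, , drop = FALSE],
                           seed = seed + i, ntree = rf_trees)$combined
    }
    if (length(val_idx) < 2) {
      stop("fold ", i, " has fewer than 2 validation points; reduce k",
           call. = FALSE)
    }
    fold_rows[[i]] <- tibble::tibble(
      fold = i, n_train = length(tr_idx), n_val = length(val_idx),
      rho = suppressWarnings(spearman_rho(sc, val_c)),
      tau = suppressWarnings(kendall_tau(sc, val_c)))
    pooled_pred <- c(pooled_pred, sc)
    pooled_meas <- c(pooled_meas, val_c)
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  if (aggregate == "fold_mean") {
    mean_rho <- mean(folds_tbl$rho, na.rm = TRUE)
    mean_tau <- mean(folds_tbl$tau, na.rm = TRUE)
  } else {
    mean_rho <- suppressWarnings(spearman_rho(pooled_pred, pooled_meas))
    mean_tau <- suppressWarnings(kendall_tau(pooled_pred, pooled_meas))
  }
  structure(list(
    folds = folds_tbl, mean_rho = mean_rho, mean_tau = mean_tau,
    config = list(model = model, k = k, seed = seed, lambda = lambda,
                  score = if (model == "gp") score else "mean",
                  aggregate = aggregate, beta = spec$beta,
                  kernel = kernel$family,
                  targets = spec$targets, n = n,
                  scored_quantity = if (model == "gp") score else "mean")
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %s model, %d-fold CV on %d variants (seed %d)\n",
    x$config$model, x$config$k, x$config$n, x$config$seed))
  cat(sprintf("  mean Spearman rho = %.3f, mean Kendall tau = %.3f\n",
              x$mean_rho, x$mean_tau))
  invisible(x)
}

#' Per-fold results of a cross-validation run
#'
#' @param x A [cross_validate()] report.
#' @param ... Unused.
#' @return Tibble with one row per fold: \code{fold}, \code{n_train},
#'   \code{n_val}, \code{rho}, \code{tau}.
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' One-row summary of a cross-validation run
#'
#' @param x A [cross_validate()] report.
#' @param ... Unused.
#' @return Tibble with the summary correlations and configuration.
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(model = x$config$model, k = x$config$k,
                 n = x$config$n, seed = x$config$seed,
                 scored = x$config$scored_quantity,
                 mean_rho = x$mean_rho, mean_tau = x$mean_tau)
}

#' Write a cross-validation report as TSV
#'
#' One row per fold plus a summary row (\code{fold = NA}).
#'
#' @param x A [cross_validate()] report.
#' @param path Output TSV path.
#' @export
write_cv_report <- function(x, path) {
  out <- dplyr::bind_rows(
    x$folds,
    tibble::tibble(fold = NA_integer_, n_train = NA_integer_,
                   n_val = NA_integer_, rho = x$mean_rho,
                   tau = x$mean_tau))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
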