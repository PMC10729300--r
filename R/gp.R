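#' Fit exact Gaussian-process regressors on a sequence kernel
#'
#' Fits one independent GP per named target over a shared Gram matrix
#' (multitask = shared kernel, separate dual weights). Each target is
#' standardized to zero mean and unit variance on the training data
#' before solving, and the dual weights
#' \eqn{\alpha = (K + \lambda I)^{-1} z} are obtained by triangular
#' solves against a cached Cholesky factor — no hyperparameters are
#' optimized; \eqn{\lambda} is a fixed regularization constant
#' (default 1.0) added to the Gram diagonal, equivalently an
#' observation-noise variance of 1 on the standardized scale.
#'
#' @param data Variant tibble with a sequence column and one numeric
#'   column per target.
#' @param targets Character vector of target column names to fit.
#' @param kernel A [kernel_spec()].
#' @param lambda Nonnegative regularization constant added to the Gram
#'   diagonal (default 1.0).
#' @param sequence_col Name of the sequence column (default
#'   \code{"sequence"}).
#' @return An object of class \code{gp_model}: training sequences and
#'   ids, kernel spec, \code{lambda}, upper Cholesky factor of
#'   \eqn{K + \lambda I}, dual-weight matrix (one column per target)
#'   and per-target standardization statistics.
#' @examples
#' d <- tibble::tibble(sequence = c("ACDE", "ACDF", "ACGE"),
#'                     rate = c(1, 2, 3))
#' m <- gp_fit(d, targets = "rate")
#' predict(m, d)
#' @export
gp_fit <- function(data, targets, kernel = kernel_spec(), lambda = 1,
                   sequence_col = "sequence") {
  stopifnot(is.data.frame(data), lambda >= 0)
  if (nrow(data) < 2) {
    stop("GP fitting needs at least 2 variants (cannot standardize n = 1)",
         call. = FALSE)
  }
  seqs <- data[[sequence_col]]
  if (is.null(seqs)) stop("no column '", sequence_col, "' in data", call. = FALSE)
  missing_t <- setdiff(targets, names(data))
  if (length(missing_t) > 0) {
    stop("missing target column(s): ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  y <- as.matrix(data[targets])
  if (!all(is.finite(y))) stop("non-finite target values", call. = FALSE)
  mu <- colMeans(y)
  sdv <- apply(y, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("constant target(s): ",
         paste(targets[sdv == 0], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(y, 2, mu), 2, sdv, "/")
  K <- gram(seqs, kernel)
  A <- unclass(K) + diag(lambda, nrow(K))
  R <- tryCatch(chol(A), error = function(e) {
    stop("Cholesky factorization of K + lambda*I failed; Gram matrix not ",
         "positive definite at lambda = ", lambda,
         " (consider psd_repair or larger lambda)", call. = FALSE)
  })
  alpha <- backsolve(R, forwardsolve(t(R), z))
  colnames(alpha) <- targets
  structure(list(
    sequences = seqs,
    ids = data[["id"]] %||% as.character(seq_along(seqs)),
    kernel = kernel,
    lambda = lambda,
    chol_factor = R,
    dual_weights = alpha,
    target_stats = tibble::tibble(target = targets, mean = unname(mu),
                                  sd = unname(sdv)),
    n = nrow(data)
  ), class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model> %d training variants, kernel %s, lambda %g\n",
              x$n, x$kernel$family, x$lambda))
  cat("targets:", paste(x$target_stats$target, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior predictions for candidate variants
#'
#' Predictive mean \eqn{\mu(x_*) = k_*^\top \alpha} and standard
#' deviation from
#' \eqn{\sigma^2(x_*) = k(x_*, x_*) - k_*^\top (K+\lambda I)^{-1} k_*}
#' (clamped at zero before the square root). The predictive standard
#' deviation depends only on the shared kernel, so it is common to all
#' targets. Means are on the standardized-target scale unless
#' \code{destandardize = TRUE}.
#'
#' @param object A fitted [gp_fit()] model.
#' @param newdata Tibble with a sequence column, or a character vector
#'   of sequences.
#' @param destandardize Return means on the original measurement scale
#'   (default \code{FALSE}; the acquisition machinery works on the
#'   standardized scale).
#' @param sequence_col Sequence column name when \code{newdata} is a
#'   data frame.
#' @param ... Unused.
#' @return A tibble with one row per candidate x target: \code{id},
#'   \code{target}, \code{mu}, \code{sigma}.
#' @export
predict.gp_model <- function(object, newdata, destandardize = FALSE,
                             sequence_col = "sequence", ...) {
  if (is.data.frame(newdata)) {
    seqs <- newdata[[sequence_col]]
    ids <- newdata[["id"]] %||% newdata[["mutation"]] %||%
      as.character(seq_along(seqs))
  } else {
    seqs <- as.character(newdata)
    ids <- names(seqs) %||% as.character(seq_along(seqs))
  }
  if (nchar(seqs[1]) != nchar(object$sequences[1])) {
    stop("candidate length does not match training sequence length",
         call. = FALSE)
  }
  Ks <- cross_gram(object$sequences, seqs, object$kernel)  # n_train x m
  mu_std <- t(Ks) %*% object$dual_weights                  # m x T
  # sigma^2 = k** - k*' (K+lI)^-1 k* via triangular solve
  V <- forwardsolve(t(object$chol_factor), Ks)             # n x m
  kss <- kernel_self(seqs, object$kernel)
  s2 <- kss - colSums(V^2)
  neg <- s2 < 0
  if (any(neg)) s2[neg] <- 0
  sigma <- sqrt(s2)
  targets <- object$target_stats$target
  out <- tibble::tibble(
    id = rep(ids, each = length(targets)),
    target = rep(targets, times = length(ids)))
  out$mu <- as.vector(t(mu_std))      # row-major: candidate-major ordering
  out$sigma <- rep(sigma, each = length(targets))
  if (destandardize) {
    st <- object$target_stats
    out <- dplyr::left_join(out, st, by = "target")
    out <- dplyr::mutate(out, mu = .data$mu * .data$sd + .data$mean,
                         sigma = .data$sigma * .data$sd)
    out <- dplyr::select(out, -"mean", -"sd")
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the dual weights of a GP model
#'
#' @param x A [gp_fit()] model.
#' @param ... Unused.
#' @return Tibble with one row per training variant x target:
#'   \code{id}, \code{target}, \code{alpha}.
#' @export
tidy.gp_model <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(id = x$ids),
                     tibble::as_tibble(x$dual_weights)),
    -"id", names_to = "target", values_to = "alpha")
}

#' One-row model summary of a GP model
#'
#' @param x A [gp_fit()] model.
#' @param ... Unused.
#' @return Tibble with \code{n}, \code{kernel}, \code{normalized},
#'   \code{lambda}, \code{n_targets}.
#' @export
glance.gp_model <- function(x, ...) {
  tibble::tibble(n = x$n, kernel = x$kernel$family,
                 normalized = isTRUE(x$kernel$normalize),
                 lambda = x$lambda,
                 n_targets = nrow(x$target_stats))
}

#' Save / load a fitted GP model
#'
#' Serializes the complete fitted state (training sequences, kernel
#' spec, regularization, Cholesky factor, dual weights, target
#' statistics) to a single archive for reuse, e.g. by the command-line
#' workflow.
#'
#' @param model A [gp_fit()] model.
#' @param path Archive path (.rds).
#' @return \code{path} (write) or the restored \code{gp_model} (read).
#' @export
write_gp_model <- function(model, path) {
  stopifnot(inherits(model, "gp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_gp_model
#' @export
read_gp_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gp_model")) {
    stop("archive does not contain a gp_model", call. = FALSE)
  }
  model
}
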