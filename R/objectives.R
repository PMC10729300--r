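#' Specify the multi-objective combination and acquisition parameters
#'
#' The engineering goal is multi-objective: maximize the carboxylation
#' rate while minimizing the ATP-per-carboxylation ratio. Each measured
#' target is z-scored (zero mean, unit variance on the training data),
#' minimized targets are negated, and the z-scores are summed into a
#' single combined performance metric. Candidates are ranked by the
#' upper confidence bound \eqn{\mu + \beta\sigma} of this combined
#' metric.
#'
#' @param targets Named character vector mapping target column names to
#'   directions, e.g. \code{c(rate = "maximize", atp_ratio =
#'   "minimize")}.
#' @param beta Exploration weight of the UCB criterion, in [0, 1]
#'   (default 0.5). Values outside [0, 1] raise a warning, not an
#'   error.
#' @param combined_gp If \code{TRUE} (default) the combined metric is
#'   fitted as a third GP target directly on the per-variant combined
#'   values; if \code{FALSE} the per-target GP predictions are summed
#'   (signs applied) at acquisition time.
#' @return An object of class \code{objective_spec}.
#' @export
objective_spec <- function(targets = c(rate = "maximize",
                                       atp_ratio = "minimize"),
                           beta = 0.5, combined_gp = TRUE) {
  stopifnot(length(targets) >= 1, !is.null(names(targets)))
  if (!all(targets %in% c("maximize", "minimize"))) {
    stop("directions must be 'maximize' or 'minimize'", call. = FALSE)
  }
  if (beta < 0 || beta > 1) {
    warning("beta = ", beta, " lies outside the conventional [0, 1] range")
  }
  structure(list(targets = targets, beta = beta,
                 combined_gp = isTRUE(combined_gp)),
            class = "objective_spec")
}

#' Per-target standardization statistics under an objective
#'
#' Mean and standard deviation of each objective target computed on
#' (training) data, with the direction sign attached. These statistics
#' define the z-scoring used by [combine_targets()]; in cross-validation
#' they are estimated from each training fold only and applied to the
#' held-out measurements, avoiding leakage.
#'
#' @param data Variant tibble containing the target columns.
#' @param spec An [objective_spec()].
#' @return Tibble with columns \code{target}, \code{direction},
#'   \code{sign}, \code{mean}, \code{sd}.
#' @export
target_stats <- function(data, spec = objective_spec()) {
  nm <- names(spec$targets)
  missing_t <- setdiff(nm, names(data))
  if (length(missing_t) > 0) {
    stop("missing target column(s): ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(nm, function(t) {
    v <- data[[t]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("target '", t, "' is constant; cannot z-score", call. = FALSE)
    }
    tibble::tibble(target = t, direction = unname(spec$targets[[t]]),
                   sign = if (spec$targets[[t]] == "minimize") -1 else 1,
                   mean = mean(v), sd = s)
  })
}

#' Combine measured targets into the single performance metric
#'
#' Adds a \code{combined} column: the sum over targets of
#' \eqn{s_t \cdot (y_t - m_t)/sd_t}, where \eqn{s_t} is +1 for
#' maximized and -1 for minimized targets. With statistics estimated on
#' the same data the combined values have mean zero; the result is
#' invariant under positive affine rescaling of any raw target.
#'
#' @param data Variant tibble with the target columns.
#' @param spec An [objective_spec()].
#' @param stats Optional precomputed [target_stats()] (pass the
#'   training-fold statistics when transforming held-out data).
#' @return \code{data} with an added (or replaced) \code{combined}
#'   column.
#' @export
combine_targets <- function(data, spec = objective_spec(), stats = NULL) {
  if (is.null(stats)) stats <- target_stats(data, spec)
  z <- rep(0, nrow(data))
  for (i in seq_len(nrow(stats))) {
    t <- stats$target[i]
    z <- z + stats$sign[i] * (data[[t]] - stats$mean[i]) / stats$sd[i]
  }
  data$combined <- z
  data
}

#' Upper confidence bound acquisition score
#'
#' \eqn{UCB = \mu + \beta\sigma}: predicted value plus an
#' exploration bonus proportional to the predictive uncertainty.
#'
#' @param mu Predictive mean(s).
#' @param sigma Predictive standard deviation(s), nonnegative.
#' @param beta Exploration weight (default 0.5).
#' @return Numeric vector \code{mu + beta * sigma}.
#' @examples
#' ucb(1.0, 0.4, 0.5)  # 1.2
#' @export
ucb <- function(mu, sigma, beta = 0.5) {
  if (any(sigma < 0, na.rm = TRUE)) {
    stop("sigma must be nonnegative", call. = FALSE)
  }
  if (any(beta < 0) || any(beta > 1)) {
    warning("beta = ", beta, " lies outside the conventional [0, 1] range")
  }
  mu + beta * sigma
}

#' Fit the acquisition model for an objective
#'
#' Convenience wrapper: z-score-combines the measured targets on the
#' training data and fits the shared-kernel GP on the raw targets plus
#' (by default) the combined metric as a third target.
#'
#' @param data Training variant tibble.
#' @param spec An [objective_spec()].
#' @param kernel A [kernel_spec()].
#' @param lambda GP regularization constant (default 1.0).
#' @return A [gp_fit()] model whose targets include \code{combined}
#'   when \code{spec$combined_gp} is \code{TRUE}.
#' @export
fit_acquisition_model <- function(data, spec = objective_spec(),
                                  kernel = kernel_spec(), lambda = 1) {
  data <- combine_targets(data, spec)
  targets <- names(spec$targets)
  if (spec$combined_gp) targets <- c(targets, "combined")
  model <- gp_fit(data, targets = targets, kernel = kernel, lambda = lambda)
  model$objective <- spec
  model
}

#' Rank candidate variants by the combined-metric UCB
#'
#' Predicts every candidate with the fitted GP(s), forms the combined
#' metric's \eqn{\mu} and \eqn{\sigma} (either from the directly fitted
#' combined GP or by signed summation of the per-target GPs, per the
#' objective spec), and sorts by descending \eqn{\mu + \beta\sigma}.
#' Ties preserve candidate enumeration order, so results are fully
#' reproducible.
#'
#' @param model A model from [fit_acquisition_model()] (or [gp_fit()]
#'   covering the objective's targets).
#' @param candidates Candidate tibble (e.g. from
#'   [enumerate_single_mutants()]) with a \code{sequence} column.
#' @param spec An [objective_spec()]; defaults to the one stored in the
#'   model.
#' @return A tibble of class \code{ranked_candidates}: one row per
#'   candidate with \code{rank}, the candidate columns, per-target
#'   \code{mu_*}/\code{sigma_*}, \code{mu_combined},
#'   \code{sigma_combined} and \code{ucb}, ordered by nonincreasing
#'   \code{ucb}.
#' @export
rank_candidates <- function(model, candidates, spec = NULL) {
  spec <- spec %||% model$objective %||% objective_spec()
  if (nrow(candidates) == 0) stop("empty candidate list", call. = FALSE)
  pred <- stats::predict(model, candidates)
  ids <- unique(pred$id)
  wide <- tidyr::pivot_wider(pred, id_cols = "id",
                             names_from = "target",
                             values_from = c("mu", "sigma"))
  # restore candidate order (pivot preserves first-appearance order,
  # which is the enumeration order)
  tnames <- names(spec$targets)
  if (spec$combined_gp && "mu_combined" %in% names(wide)) {
    mu_c <- wide$mu_combined
    sd_c <- wide$sigma_combined
  } else {
    sgn <- ifelse(spec$targets == "minimize", -1, 1)
    mu_c <- rowSums(purrr::map_dfc(seq_along(tnames), function(i)
      sgn[i] * wide[[paste0("mu_", tnames[i])]]))
    # shared kernel: per-target sigmas are identical; the summed
    # metric's sd scales by the number of (independent-GP) terms
    sd_c <- sqrt(rowSums(purrr::map_dfc(tnames, function(t)
      wide[[paste0("sigma_", t)]]^2)))
    wide$mu_combined <- mu_c
    wide$sigma_combined <- sd_c
  }
  score <- ucb(mu_c, sd_c, spec$beta)
  ord <- order(-score)                       # stable: keeps input order on ties
  out <- dplyr::bind_cols(
    dplyr::slice(candidates, ord),
    dplyr::select(dplyr::slice(wide, ord), -"id"))
  out$ucb <- score[ord]
  out$rank <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "rank")
  class(out) <- c("ranked_candidates", class(out))
  attr(out, "beta") <- spec$beta
  out
}

#' Keep the top fraction of a ranked list
#'
#' @param ranked A [rank_candidates()] result (or any rank-ordered
#'   tibble).
#' @param f Fraction in (0, 1]; the first \code{ceiling(f * N)} rows
#'   are kept, so the selection is never empty.
#' @return The leading sublist, same class as the input.
#' @export
top_fraction <- function(ranked, f = 0.01) {
  stopifnot(f > 0, f <= 1)
  n <- nrow(ranked)
  if (n == 0) stop("empty ranked list", call. = FALSE)
  dplyr::slice_head(ranked, n = as.integer(ceiling(f * n)))
}

#' Substitution-site frequency in a candidate selection
#'
#' Counts how often each parent position appears among a set of
#' single-mutant candidates — sites hit repeatedly in the top
#' predictions are prioritized for experimental follow-up.
#'
#' @param selected Tibble of single-mutant rows with a \code{position}
#'   column (and, if present, \code{n_mutations} which must equal 1).
#' @return Tibble with \code{position} and \code{count}, sorted by
#'   descending count then ascending position. Counts sum to
#'   \code{nrow(selected)}.
#' @export
position_frequency <- function(selected) {
  if (!"position" %in% names(selected)) {
    stop("selection must carry a 'position' column (single mutants)",
         call. = FALSE)
  }
  if ("n_mutations" %in% names(selected) &&
      any(selected$n_mutations != 1)) {
    stop("position_frequency is defined for single-mutant candidates only",
         call. = FALSE)
  }
  out <- dplyr::count(selected, .data$position, name = "count")
  dplyr::arrange(out, dplyr::desc(.data$count), .data$position)
}
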