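#' Fit the Michaelis-Menten model to substrate-saturation data
#'
#' Nonlinear least-squares fit of \eqn{v = V_{max} S / (K_M + S)} with
#' the deterministic initialization \eqn{V_{max,0} = \max v},
#' \eqn{K_{M,0} = \mathrm{median}\, S} (Levenberg-Marquardt).
#'
#' @param data Data frame of measurements, or \code{NULL} to pass
#'   vectors directly.
#' @param S Substrate concentrations (mM): a column name (tidy-eval)
#'   when \code{data} is supplied, else a numeric vector.
#' @param v Reaction rates (same convention).
#' @return Object of class \code{mm_fit}: the underlying \code{nls}
#'   fit plus the data. Use [tidy()]/[glance()] for coefficients and
#'   fit statistics, [autoplot()] for the saturation curve.
#' @examples
#' S <- c(0.05, 0.1, 0.25, 0.5, 1, 2)
#' v <- 4520 * S / (0.27 + S)
#' glance(mm_fit(S = S, v = v))
#' @export
mm_fit <- function(data = NULL, S, v) {
  if (!is.null(data)) {
    S <- rlang::eval_tidy(rlang::enquo(S), data)
    v <- rlang::eval_tidy(rlang::enquo(v), data)
  }
  stopifnot(length(S) == length(v))
  if (length(unique(S)) < 3) {
    stop("need at least 3 distinct substrate concentrations", call. = FALSE)
  }
  if (any(S < 0) || any(v < 0)) {
    stop("concentrations and rates must be nonnegative", call. = FALSE)
  }
  df <- data.frame(S = S, v = v)
  fit <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df,
                           start = list(Vmax = max(v), Km = stats::median(S)),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  if (est[["Km"]] < sqrt(.Machine$double.eps)) {
    warning("Km estimate at the zero boundary: rates look saturated ",
            "over the measured range")
  }
  structure(list(fit = fit, data = tibble::as_tibble(df),
                 Vmax = est[["Vmax"]], Km = est[["Km"]]),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Vmax = %.4g, Km = %.4g (n = %d)\n",
              x$Vmax, x$Km, nrow(x$data)))
  invisible(x)
}

#' Coefficients of a Michaelis-Menten fit
#'
#' @param x An [mm_fit()] object.
#' @param ... Unused.
#' @return Tibble with \code{term}, \code{estimate}, \code{std.error}.
#' @export
tidy.mm_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                 std.error = s[, "Std. Error"])
}

#' One-row summary of a Michaelis-Menten fit
#'
#' @param x An [mm_fit()] object.
#' @param ... Unused.
#' @return Tibble with \code{Vmax}, \code{Km}, their standard errors,
#'   \code{n_points}, \code{rss}.
#' @export
glance.mm_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(Vmax = x$Vmax, Km = x$Km,
                 Vmax_se = s["Vmax", "Std. Error"],
                 Km_se = s["Km", "Std. Error"],
                 n_points = nrow(x$data),
                 rss = sum(stats::residuals(x$fit)^2))
}

#' Catalytic efficiency kcat/Km
#'
#' @param kcat Turnover number, s^-1.
#' @param km_mM Michaelis constant in mM (converted internally to M).
#' @return Catalytic efficiency in s^-1 M^-1.
#' @examples
#' catalytic_efficiency(9.8, 0.27)  # ~3.6e4
#' @export
catalytic_efficiency <- function(kcat, km_mM) {
  if (any(kcat <= 0) || any(km_mM <= 0)) {
    stop("kcat and Km must be positive", call. = FALSE)
  }
  kcat / (km_mM * 1e-3)
}

#' Turnover number from specific activity
#'
#' Converts a maximal specific activity \eqn{V_{max}} in
#' nmol min^-1 mg^-1 to a per-protomer turnover number:
#' \eqn{k_{cat} = V_{max} \cdot 10^{-9} \cdot 10^{3} \cdot M / 60}
#' (nmol to mol, per-mg to per-g, times protomer mass in g/mol, per
#' second).
#'
#' @param vmax Specific activity, nmol min^-1 mg^-1.
#' @param protomer_mass Catalytic protomer mass in g/mol. The default
#'   1.2973e5 is the value consistent with the enzyme's published
#'   (Vmax, kcat) pairs.
#' @return kcat in s^-1.
#' @examples
#' kcat_from_vmax(2590)  # ~5.6
#' @export
kcat_from_vmax <- function(vmax, protomer_mass = 1.2973e5) {
  if (any(vmax <= 0) || any(protomer_mass <= 0)) {
    stop("vmax and protomer_mass must be positive", call. = FALSE)
  }
  vmax * 1e-9 * 1e3 * protomer_mass / 60
}

#' ATP consumed per carboxylation event
#'
#' In the ATP-limited coupled assay, all supplied ATP is hydrolyzed
#' while productive carboxylation is counted by NADPH consumption, so
#' the ATP-per-carboxylation stoichiometry is the simple quotient of
#' the ATP amount in the reaction mixture and the consumed NADPH
#' amount (same concentration units). A ratio of 1 is perfectly
#' coupled; the excess measures futile carboxybiotin decarboxylation.
#'
#' @param atp_total ATP amount in the reaction mixture.
#' @param nadph_consumed Consumed NADPH amount (same units).
#' @param max_factor Sanity bound: error if
#'   \code{nadph_consumed > atp_total * max_factor} (default 10).
#' @return Dimensionless ATP-per-carboxylation ratio.
#' @examples
#' atp_per_carboxylation(0.15, 0.0375)  # 4
#' @export
atp_per_carboxylation <- function(atp_total, nadph_consumed,
                                  max_factor = 10) {
  if (any(atp_total <= 0) || any(nadph_consumed <= 0)) {
    stop("amounts must be positive", call. = FALSE)
  }
  if (any(nadph_consumed > atp_total * max_factor)) {
    stop("nadph_consumed exceeds ", max_factor,
         "x the supplied ATP; check units", call. = FALSE)
  }
  atp_total / nadph_consumed
}

#' NADPH concentration change from A340 absorbance
#'
#' Beer-Lambert conversion for the spectrophotometric coupled assay:
#' \eqn{\Delta c = \Delta A_{340} / (\epsilon \cdot l)}, returned in
#' mM.
#'
#' @param delta_a340 Absorbance change at 340 nm.
#' @param epsilon Molar extinction coefficient of NADPH at 340 nm,
#'   M^-1 cm^-1 (default 6220).
#' @param pathlength Cuvette path length in cm (default 1).
#' @return Concentration change in mM.
#' @export
a340_to_nadph <- function(delta_a340, epsilon = 6220, pathlength = 1) {
  stopifnot(epsilon > 0, pathlength > 0)
  delta_a340 / (epsilon * pathlength) * 1e3
}

#' Fold change between two rates
#'
#' @param a Numerator (e.g. variant Vmax).
#' @param b Denominator (e.g. parent Vmax), must be positive.
#' @return \code{a / b}.
#' @examples
#' fold_change(4520, 2590)  # ~1.75, reported as 1.8-fold
#' @export
fold_change <- function(a, b) {
  if (any(b <= 0)) stop("denominator must be positive", call. = FALSE)
  a / b
}

#' Percent reduction of a quantity
#'
#' @param new New value.
#' @param old Reference value, must be positive.
#' @return \code{100 * (1 - new / old)}.
#' @examples
#' percent_reduction(1.7, 4.0)  # 57.5, reported as 60% at 1 sig fig
#' @export
percent_reduction <- function(new, old) {
  if (any(old <= 0)) stop("reference value must be positive", call. = FALSE)
  100 * (1 - new / old)
}

#' Round to the reporting precision used in publication tables
#'
#' @param x Numeric value(s).
#' @param sig Significant digits (default 2).
#' @return Rounded numeric.
#' @export
report_signif <- function(x, sig = 2) signif(x, sig)
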