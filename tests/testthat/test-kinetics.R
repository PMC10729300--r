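test_that("Michaelis-Menten fits recover noise-free parameters", {
  S <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5)
  v <- 4520 * S / (0.27 + S)
  fit <- mm_fit(S = S, v = v)
  expect_equal(fit$Vmax, 4520, tolerance = 1e-4)
  expect_equal(fit$Km, 0.27, tolerance = 1e-4)
  expect_lt(max(abs(residuals(fit$fit))), 1e-6)
  g <- glance(fit)
  expect_equal(g$n_points, 7)
  expect_lt(g$rss, 1e-10)

  # recovery across random parameter pairs, 4 significant digits
  set.seed(53)
  for (i in 1:50) {
    Vm <- runif(1, 100, 5000); Km <- runif(1, 0.05, 2)
    Sg <- Km * c(0.2, 0.5, 1, 2, 5, 10)
    f <- mm_fit(S = Sg, v = Vm * Sg / (Km + Sg))
    expect_lt(abs(f$Vmax - Vm) / Vm, 1e-4)
    expect_lt(abs(f$Km - Km) / Km, 1e-4)
  }

  # saturated (constant) rates push Km to the zero boundary
  expect_warning(mm_fit(S = c(0.5, 1, 2, 4), v = rep(100, 4)), "boundary")
  expect_error(mm_fit(S = c(1, 1, 1), v = c(1, 2, 3)), "distinct")
  expect_error(mm_fit(S = c(-1, 1, 2), v = c(1, 2, 3)), "nonnegative")

  # tidy-eval interface on a data frame
  df <- tibble::tibble(conc = S, rate = v)
  f2 <- mm_fit(df, conc, rate)
  expect_equal(f2$Km, fit$Km)
})

test_that("catalytic efficiency converts mM and matches published rows", {
  expect_equal(catalytic_efficiency(1.0, 1.0), 1000)
  # published (kcat, Km) pairs reproduce printed kcat/Km within 2%
  expect_equal(catalytic_efficiency(9.8, 0.27), 3.64e4, tolerance = 0.02)
  expect_equal(catalytic_efficiency(1.7, 0.32), 5.36e3, tolerance = 0.02)
  expect_error(catalytic_efficiency(-1, 0.2), "positive")
})

test_that("all published kcat/Km cells reproduce within input-rounding bounds", {
  rows <- tibble::tibble(
    kcat = c(5.6, 9.8, 4.9, 1.7, 0.38),
    kcat_ulp = c(0.1, 0.1, 0.1, 0.1, 0.01),
    km = c(0.15, 0.27, 0.38, 0.32, 0.63),
    km_ulp = 0.01,
    eff = c(3.63e4, 3.64e4, 1.30e4, 5.36e3, 5.96e2),
    eff_ulp = c(100, 100, 100, 10, 1))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    tol <- r$kcat_ulp / (2 * r$kcat) + r$km_ulp / (2 * r$km) +
      r$eff_ulp / (2 * r$eff)
    expect_equal(catalytic_efficiency(r$kcat, r$km), r$eff,
                 tolerance = tol)
  }
})

test_that("kcat back-calculates from specific activity with the default mass", {
  expect_equal(kcat_from_vmax(2590), 5.6, tolerance = 0.005)
  expect_equal(kcat_from_vmax(4520), 9.8, tolerance = 0.005)
  expect_equal(kcat_from_vmax(200), 2 * kcat_from_vmax(100))  # linear
  expect_error(kcat_from_vmax(-5), "positive")

  # kcat/Km is invariant to a joint rescaling of Vmax and kcat
  km <- 0.27
  e1 <- catalytic_efficiency(kcat_from_vmax(4520), km)
  e2 <- catalytic_efficiency(kcat_from_vmax(2 * 4520), km) / 2
  expect_equal(e1, e2)
})

test_that("ATP stoichiometry is the assay quotient with a sanity bound", {
  expect_equal(atp_per_carboxylation(0.15, 0.0375), 4.0)
  expect_equal(atp_per_carboxylation(0.15, 0.15), 1.0)
  expect_equal(atp_per_carboxylation(0.15, 0.088), 1.70, tolerance = 0.005)
  expect_error(atp_per_carboxylation(0, 1), "positive")
  expect_error(atp_per_carboxylation(0.15, 3), "check units")

  # absorbance conversion: Beer-Lambert with the NADPH coefficient
  expect_equal(a340_to_nadph(0.622), 0.1)        # 0.622 / 6220 M = 0.1 mM
  expect_equal(a340_to_nadph(0.311, pathlength = 0.5), 0.1)
})

test_that("fold change and percent reduction match the published claims", {
  fc <- fold_change(4520, 2590)
  expect_equal(fc, 1.745, tolerance = 1e-3)
  expect_lt(abs(fc - 1.8), 0.1)          # one printed-precision unit

  pr <- percent_reduction(1.7, 4.0)
  expect_equal(pr, 57.5)
  expect_equal(report_signif(pr, 1), 60)  # one significant figure
  expect_equal(percent_reduction(3.3, 3.3), 0)
  expect_error(fold_change(1, 0), "positive")
  expect_error(percent_reduction(1, -2), "positive")
})
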