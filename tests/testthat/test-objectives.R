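test_that("combined metric z-scores, negates minimized targets, and centres", {
  d <- tibble::tibble(sequence = c("AA", "CC"),
                      rate = c(1, 3), atp_ratio = c(4, 2))
  out <- combine_targets(d)
  # both targets improve from row 1 to row 2; equal two-point z-scores sum
  expect_equal(out$combined, c(-sqrt(2), sqrt(2)))
  expect_equal(mean(out$combined), 0)

  # single maximized target reduces to its z-score
  spec1 <- objective_spec(c(rate = "maximize"))
  expect_equal(combine_targets(d, spec1)$combined,
               (d$rate - mean(d$rate)) / sd(d$rate))

  # positive affine transforms of raw targets leave the metric unchanged
  set.seed(31)
  d2 <- tibble::tibble(sequence = random_seqs(20, 6),
                       rate = rnorm(20), atp_ratio = rnorm(20))
  base <- combine_targets(d2)$combined
  d3 <- dplyr::mutate(d2, rate = 3.7 * rate + 11, atp_ratio = 0.2 * atp_ratio - 5)
  expect_equal(combine_targets(d3)$combined, base, tolerance = 1e-12)

  expect_error(combine_targets(dplyr::mutate(d2, rate = 1)), "constant")
})

test_that("ucb is mu plus beta sigma, monotone in beta, warns off-range", {
  expect_equal(ucb(1.0, 0.4, 0.5), 1.2)
  expect_equal(ucb(2, 5, 0), 2)
  expect_equal(ucb(3, 0, 1), 3)
  expect_error(ucb(1, -0.1), "nonnegative")
  expect_warning(ucb(1, 1, 1.5), "outside")
  b <- seq(0, 1, by = 0.1)
  expect_true(all(diff(ucb(0.3, 0.7, b)) > 0))
})

test_that("ranking orders by UCB, keeps every candidate, breaks ties stably", {
  d <- toy_dataset(n = 15, L = 10)
  parent <- attr(d, "parent")
  m <- fit_acquisition_model(d)
  cands <- enumerate_single_mutants(parent)
  r <- rank_candidates(m, cands)
  expect_s3_class(r, "ranked_candidates")
  expect_equal(nrow(r), nrow(cands))
  expect_equal(sort(r$mutation), sort(cands$mutation))  # permutation, no loss
  expect_equal(r$rank, seq_len(nrow(r)))
  expect_true(all(diff(r$ucb) <= 1e-12))                # nonincreasing

  # stable ties: beta = 0 on a model with equal means keeps enumeration order
  two <- cands[c(5, 9), ]
  p <- predict(m, two)
  expect_equal(rank_candidates(m, two)$ucb,
               sort(rank_candidates(m, two)$ucb, decreasing = TRUE))
})

test_that("summed-UCB acquisition mode agrees in direction with combined GP", {
  d <- toy_dataset(n = 20, L = 10, noise = 0.05)
  parent <- attr(d, "parent")
  cands <- enumerate_single_mutants(parent)
  spec_sum <- objective_spec(combined_gp = FALSE)
  m <- fit_acquisition_model(d, spec_sum)
  r <- rank_candidates(m, cands, spec_sum)
  expect_true(all(c("mu_combined", "sigma_combined", "ucb") %in% names(r)))
  # signed sum: minimized target enters negatively
  wide <- dplyr::slice(r, 1)
  expect_equal(wide$mu_combined, wide$mu_rate - wide$mu_atp_ratio)
})

test_that("noise-free in-training single mutants rank by their true effects", {
  sim <- simulate_landscape(landscape_config(noise_sd = 0, seed = 2))
  d <- sim$data[sim$data$n_mutations == 1, ]
  spec0 <- objective_spec(beta = 0)
  m <- fit_acquisition_model(d, spec0, lambda = 1e-6)
  cands <- enumerate_single_mutants(sim$parent)
  r <- rank_candidates(m, cands, spec0)
  r <- dplyr::left_join(r, sim$ground_truth[, c("mutation", "combined_effect")],
                        by = "mutation")
  rin <- r[r$mutation %in% d$mutations, ]
  expect_gt(nrow(rin), 30)
  expect_gt(spearman_rho(rin$ucb, rin$combined_effect), 0.99)
})

test_that("top_fraction takes the ceiling and position_frequency conserves counts", {
  fake <- tibble::tibble(rank = 1:7, position = c(20, 20, 100, 3, 20, 100, 5),
                         ucb = 7:1)
  expect_equal(nrow(top_fraction(fake, 0.5)), 4)   # ceil(3.5)
  expect_equal(nrow(top_fraction(fake, 1)), 7)
  big <- tibble::tibble(rank = 1:1000, position = rep(1, 1000))
  expect_equal(nrow(top_fraction(big, 0.01)), 10)
  expect_error(top_fraction(fake, 0), "f > 0")

  freq <- position_frequency(fake[1:3, ])
  expect_equal(freq$position, c(20, 100))
  expect_equal(freq$count, c(2L, 1L))
  expect_equal(sum(position_frequency(fake)$count), nrow(fake))
  expect_equal(nrow(position_frequency(fake[0, ])), 0)
  multi <- tibble::tibble(position = 1, n_mutations = 2)
  expect_error(position_frequency(multi), "single-mutant")
})
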