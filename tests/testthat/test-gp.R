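test_that("degenerate inputs are rejected", {
  d1 <- tibble::tibble(sequence = "ACDE", rate = 1)
  expect_error(gp_fit(d1, "rate"), "at least 2")
  d2 <- tibble::tibble(sequence = c("ACDE", "ACDF"), rate = c(2, 2))
  expect_error(gp_fit(d2, "rate"), "constant")
  d3 <- tibble::tibble(sequence = c("ACDE", "ACDF"), rate = c(1, NA))
  expect_error(gp_fit(d3, "rate"), "finite")
})

test_that("closed-form posteriors hold for orthogonal and identity kernels", {
  hm <- kernel_spec("hamming")
  # k12 = 0 ("AC" vs "CA" share no positions): (I + I) alpha = z
  d <- tibble::tibble(sequence = c("AC", "CA"), rate = c(1, 3))
  m <- gp_fit(d, "rate", kernel = hm, lambda = 1)
  z <- (d$rate - 2) / sd(d$rate)
  expect_equal(unname(m$dual_weights[, "rate"]), z / 2, tolerance = 1e-12)

  # candidate sharing no position with training: prior mean 0, sd 1
  p <- predict(m, "GG")
  expect_equal(p$mu, 0, tolerance = 1e-12)
  expect_equal(p$sigma, 1, tolerance = 1e-12)

  # predicting a training point with identity gram, lambda = 1:
  # mu = z/2, sigma^2 = 1 - 1/2
  p1 <- predict(m, "AC")
  expect_equal(p1$mu, z[1] / 2, tolerance = 1e-12)
  expect_equal(p1$sigma, sqrt(0.5), tolerance = 1e-12)

  # lambda = 0 with orthogonal training set interpolates exactly
  d3 <- tibble::tibble(sequence = c("AA", "CC", "GG"), rate = c(1, 2, 4))
  m0 <- gp_fit(d3, "rate", kernel = hm, lambda = 0)
  z3 <- (d3$rate - mean(d3$rate)) / sd(d3$rate)
  expect_equal(predict(m0, d3$sequence)$mu, z3, tolerance = 1e-10)
})

test_that("fit and predict agree with a dense-inversion oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    L <- sample(8:20, 1)
    spec <- if (rep %% 2 == 0) kernel_spec() else kernel_spec("hamming")
    lambda <- sample(c(0.5, 1, 2), 1)
    pool <- random_variant_set(n + 5, L)
    seqs <- pool[seq_len(n)]
    y <- rnorm(n)
    d <- tibble::tibble(sequence = seqs, y = y)
    m <- gp_fit(d, "y", kernel = spec, lambda = lambda)
    new_seqs <- pool[(n + 1):(n + 5)]
    p <- predict(m, new_seqs)
    o <- oracle_gp(seqs, y, lambda, spec, new_seqs)
    expect_lt(max(abs(unname(m$dual_weights[, "y"]) - o$alpha)), 1e-8)
    expect_lt(max(abs(p$mu - o$mu)), 1e-8)
    expect_lt(max(abs(p$sigma - o$sigma)), 1e-8)
  }
})

test_that("posterior variance is bounded by the prior and never negative", {
  set.seed(19)
  pool <- random_variant_set(70, 15)
  d <- tibble::tibble(sequence = pool[1:30], y = rnorm(30))
  m <- gp_fit(d, "y")
  p <- predict(m, pool[31:70])
  expect_true(all(p$sigma >= 0))
  expect_true(all(p$sigma <= 1 + 1e-12))   # prior sd is 1 (normalized kernel)
})

test_that("predictions are invariant to training-data order", {
  set.seed(23)
  pool <- random_variant_set(21, 12)
  d <- tibble::tibble(id = paste0("v", 1:15),
                      sequence = pool[1:15], y = rnorm(15))
  test_seqs <- pool[16:21]
  m1 <- gp_fit(d, "y")
  m2 <- gp_fit(dplyr::slice(d, sample(15)), "y")
  expect_equal(predict(m1, test_seqs)$mu, predict(m2, test_seqs)$mu,
               tolerance = 1e-10)
  expect_equal(predict(m1, test_seqs)$sigma, predict(m2, test_seqs)$sigma,
               tolerance = 1e-10)
})

test_that("predictive means shrink to the prior as lambda grows", {
  set.seed(29)
  pool <- random_variant_set(28, 12)
  d <- tibble::tibble(sequence = pool[1:20], y = rnorm(20))
  test_seqs <- pool[21:28]
  mx <- vapply(c(1, 10, 100, 1000), function(l)
    max(abs(predict(gp_fit(d, "y", lambda = l), test_seqs)$mu)), 0)
  expect_true(all(diff(mx) < 0))
  expect_lt(mx[4], 0.01)
})

test_that("multitask fits share the kernel but carry separate dual weights", {
  d <- toy_dataset(n = 10)
  m <- gp_fit(d, c("rate", "atp_ratio"))
  expect_equal(colnames(m$dual_weights), c("rate", "atp_ratio"))
  p <- predict(m, d$sequence[1:3])
  expect_equal(nrow(p), 6)  # 3 candidates x 2 targets
  # sigma identical across targets for the same candidate
  sig <- tidyr::pivot_wider(p, id_cols = "id", names_from = "target",
                            values_from = "sigma")
  expect_equal(sig$rate, sig$atp_ratio)
  # de-standardized means recover the measurement scale
  pd <- predict(m, d$sequence[1:3], destandardize = TRUE)
  st <- m$target_stats
  pr <- dplyr::filter(p, target == "rate")
  prd <- dplyr::filter(pd, target == "rate")
  expect_equal(prd$mu, pr$mu * st$sd[1] + st$mean[1])
})

test_that("a fitted model round-trips through its archive", {
  d <- toy_dataset(n = 8)
  m <- gp_fit(d, c("rate", "atp_ratio"))
  tmp <- withr::local_tempfile(fileext = ".rds")
  write_gp_model(m, tmp)
  m2 <- read_gp_model(tmp)
  s <- random_seqs(4, nchar(d$sequence[1]))
  expect_equal(predict(m2, s), predict(m, s))
  expect_equal(glance(m2), glance(m))
})
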