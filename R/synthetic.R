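#' Configuration of a synthetic additive fitness landscape
#'
#' The generator emulates the statistical shape of an error-prone-PCR
#' screening campaign: a library of equal-length mutants of a random
#' parent, each carrying a small number of substitutions, with two
#' correlated real-valued objectives measured with Gaussian noise — a
#' carboxylation-style \code{rate} (maximize) and an
#' ATP-per-carboxylation-style \code{atp_ratio} (minimize). Ground
#' truth is an additive per-substitution effect table, so the latent
#' landscape the GP is asked to recover is known exactly.
#'
#' @param parent_length Parent sequence length (default 50).
#' @param effect_sd Standard deviation of the per-(position, residue)
#'   additive effects (default 1).
#' @param task_correlation Correlation between a substitution's rate
#'   effect and its atp effect, in [-1, 1] (default -0.3: improvements
#'   in one objective tend to cost the other, mimicking a
#'   rate-versus-ATP trade-off).
#' @param noise_sd Measurement noise standard deviation per task
#'   (default 0.3).
#' @param library_size Number of variants in the screened library
#'   (default 200).
#' @param mean_mutations Rate of the truncated Poisson distribution of
#'   substitutions per variant (default 1.5).
#' @param max_mutations Cap on substitutions per variant (default 5).
#' @param baseline_rate,baseline_atp Parent (wild-type) true values
#'   (defaults 1 and 4; the z-scored objectives are invariant to
#'   them).
#' @param epistasis_sd Standard deviation of optional pairwise
#'   interaction terms (default 0: purely additive landscape).
#' @param seed Integer seed; the whole dataset is reproducible from
#'   it.
#' @return An object of class \code{landscape_config}.
#' @export
landscape_config <- function(parent_length = 50, effect_sd = 1,
                             task_correlation = -0.3, noise_sd = 0.3,
                             library_size = 200, mean_mutations = 1.5,
                             max_mutations = 5, baseline_rate = 1,
                             baseline_atp = 4, epistasis_sd = 0,
                             seed = 1) {
  stopifnot(parent_length >= 2, effect_sd >= 0, noise_sd >= 0,
            abs(task_correlation) <= 1, library_size >= 2,
            mean_mutations > 0, max_mutations >= 1, epistasis_sd >= 0)
  structure(list(parent_length = as.integer(parent_length),
                 effect_sd = effect_sd,
                 task_correlation = task_correlation,
                 noise_sd = noise_sd,
                 library_size = as.integer(library_size),
                 mean_mutations = mean_mutations,
                 max_mutations = as.integer(max_mutations),
                 baseline_rate = baseline_rate,
                 baseline_atp = baseline_atp,
                 epistasis_sd = epistasis_sd,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# truncated Poisson on [1, cap] by rejection
rtrunc_pois <- function(n, rate, cap) {
  out <- integer(0)
  while (length(out) < n) {
    x <- stats::rpois(n, rate)
    out <- c(out, x[x >= 1 & x <= cap])
  }
  out[seq_len(n)]
}

#' Simulate a variant screening dataset with known ground truth
#'
#' Draws a random parent over the canonical alphabet; draws one
#' (rate_effect, atp_effect) pair per (position, non-wild-type residue)
#' from a zero-mean bivariate normal with sd \code{effect_sd} and the
#' configured correlation; builds \code{library_size} variants carrying
#' 1..\code{max_mutations} substitutions at distinct random positions;
#' and measures true value = baseline + sum of effects, plus
#' independent Gaussian noise per task. Fully reproducible from
#' \code{config$seed}.
#'
#' @param config A [landscape_config()].
#' @return A list of class \code{landscape_sim}: \code{parent} (a
#'   [parent_sequence()]), \code{ground_truth} (tibble: position, wt,
#'   mut, rate_effect, atp_effect, combined_effect = rate_effect -
#'   atp_effect) and \code{data} (variant tibble with id, mutations,
#'   sequence, n_mutations, rate, atp_ratio, true_rate, true_atp).
#' @export
simulate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, {
    aa <- aa_alphabet()
    L <- config$parent_length
    chars <- sample(aa, L, replace = TRUE)
    parent <- parent_sequence(paste(chars, collapse = ""), id = "parent")

    # per-(position, mutant-residue) bivariate effects
    gt <- enumerate_single_mutants(parent, with_sequence = FALSE)
    ne <- nrow(gt)
    z1 <- stats::rnorm(ne)
    z2 <- stats::rnorm(ne)
    r <- config$task_correlation
    gt$rate_effect <- config$effect_sd * z1
    gt$atp_effect <- config$effect_sd * (r * z1 + sqrt(1 - r^2) * z2)
    gt$combined_effect <- gt$rate_effect - gt$atp_effect
    key <- paste0(gt$position, gt$mut)
    rate_eff <- stats::setNames(gt$rate_effect, key)
    atp_eff <- stats::setNames(gt$atp_effect, key)

    nmut <- rtrunc_pois(config$library_size, config$mean_mutations,
                        min(config$max_mutations, L))
    rows <- purrr::map(seq_len(config$library_size), function(i) {
      k <- nmut[i]
      pos <- sort(sample.int(L, k))
      mut <- vapply(pos, function(p) sample(setdiff(aa, chars[p]), 1),
                    character(1))
      kk <- paste0(pos, mut)
      list(pos = pos, mut = mut,
           mutation = paste0(chars[pos], pos, mut, collapse = ";"),
           rate = sum(rate_eff[kk]), atp = sum(atp_eff[kk]))
    })
    seqs <- vapply(rows, function(rr) {
      s <- chars; s[rr$pos] <- rr$mut; paste(s, collapse = "")
    }, character(1))
    true_rate <- config$baseline_rate + vapply(rows, `[[`, 0, "rate")
    true_atp <- config$baseline_atp + vapply(rows, `[[`, 0, "atp")
    if (config$epistasis_sd > 0) {
      # optional pairwise interactions, hashed deterministically per pair
      epi <- vapply(rows, function(rr) {
        if (length(rr$pos) < 2) return(0)
        pr <- utils::combn(paste0(rr$pos, rr$mut), 2)
        sum(vapply(seq_len(ncol(pr)), function(j) {
          h <- sum(utf8ToInt(paste(pr[, j], collapse = "|")))
          with_seed(h %% .Machine$integer.max,
                    stats::rnorm(1, 0, config$epistasis_sd))
        }, 0))
      }, 0)
      true_rate <- true_rate + epi
    }
    data <- tibble::tibble(
      id = sprintf("v%03d", seq_len(config$library_size)),
      mutations = vapply(rows, `[[`, "", "mutation"),
      sequence = seqs,
      n_mutations = nmut,
      rate = true_rate + stats::rnorm(config$library_size, 0, config$noise_sd),
      atp_ratio = true_atp + stats::rnorm(config$library_size, 0, config$noise_sd),
      true_rate = true_rate,
      true_atp = true_atp)
    structure(list(parent = parent,
                   ground_truth = gt,
                   data = data,
                   config = config),
              class = "landscape_sim")
  })
}

#' @export
print.landscape_sim <- function(x, ...) {
  cat(sprintf(
    "<landscape_sim> parent %d aa, %d variants, noise_sd %g, seed %d\n",
    x$config$parent_length, x$config$library_size, x$config$noise_sd,
    x$config$seed))
  invisible(x)
}

#' Ground-truth recovery experiment on a synthetic landscape
#'
#' The end-to-end oracle check for the ranking engine: simulate a
#' landscape, fit the acquisition GP on the noisy library, rank the
#' complete single-mutant library by the combined-metric UCB, and
#' compare against the known per-substitution ground truth. Reports
#' (i) Spearman's rho between the UCB score and the true combined
#' effect over all single mutants, and (ii) the enrichment of the
#' selected top 1%: its mean true combined effect minus the mean of a
#' random 1% selection (averaged over \code{n_random_draws} seeded
#' draws).
#'
#' @param config A [landscape_config()].
#' @param spec An [objective_spec()].
#' @param kernel A [kernel_spec()].
#' @param lambda GP regularization constant.
#' @param top_f Selection fraction (default 0.01).
#' @param n_random_draws Random-selection replicates for the enrichment
#'   baseline (default 100).
#' @return A one-row tibble: \code{rho_truth}, \code{top_mean_true},
#'   \code{random_mean_true}, \code{enrichment}, \code{n_candidates},
#'   \code{n_top}.
#' @export
recovery_experiment <- function(config = landscape_config(),
                                spec = objective_spec(),
                                kernel = kernel_spec(), lambda = 1,
                                top_f = 0.01, n_random_draws = 100) {
  sim <- simulate_landscape(config)
  model <- fit_acquisition_model(sim$data, spec, kernel, lambda)
  cands <- enumerate_single_mutants(sim$parent)
  ranked <- rank_candidates(model, cands, spec)
  truth <- dplyr::select(sim$ground_truth, "mutation", "combined_effect")
  ranked <- dplyr::left_join(ranked, truth, by = "mutation")
  rho <- spearman_rho(ranked$ucb, ranked$combined_effect)
  n_top <- as.integer(ceiling(top_f * nrow(ranked)))
  top_mean <- mean(ranked$combined_effect[seq_len(n_top)])
  rand_means <- with_seed(config$seed + 1L, vapply(
    seq_len(n_random_draws), function(i)
      mean(sample(ranked$combined_effect, n_top)), 0))
  tibble::tibble(rho_truth = rho,
                 top_mean_true = top_mean,
                 random_mean_true = mean(rand_means),
                 enrichment = top_mean - mean(rand_means),
                 n_candidates = nrow(ranked),
                 n_top = n_top)
}

#' Write the ground-truth effect table as TSV
#'
#' @param sim A [simulate_landscape()] result.
#' @param path Output TSV path.
#' @export
write_ground_truth <- function(sim, path) {
  readr::write_tsv(sim$ground_truth, path, progress = FALSE)
  invisible(path)
}
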