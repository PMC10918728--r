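# Sampler building blocks and diagnostics.

sp <- tiny_space()

test_that("latent-state Gibbs draws follow the enumeration posterior", {
  params <- default_params()
  rec <- make_record(y = 1, v = NA_integer_, x = c(0, 0), z = 0)
  p <- state_probabilities(intensity(params$eco, c(0, 0)))
  Om <- classification_matrix(params$cls, 0)
  post <- true_state_posterior(p, Om, 1)   # (0.3907, 0.6093)
  set.seed(31)
  draws <- replicate(1e5, gibbs_latent_v(rec, params$eco, params$cls,
                                         "variable", sp))
  expect_lt(abs(mean(draws == 1) - post[1]), 0.006)
  # chi-square goodness of fit against the enumeration posterior
  expect_gt(chisq.test(tabulate(draws, 2), p = post)$p.value, 0.01)
  # degenerate posterior is deterministic
  eco_sure <- eco_params(c(50, -50), matrix(0, 2, 2))
  expect_equal(unique(replicate(50, gibbs_latent_v(rec, eco_sure, params$cls,
                                                   "variable", sp))), 1L)
  # seeded reproducibility
  set.seed(8); a <- replicate(20, gibbs_latent_v(rec, params$eco, params$cls, "variable", sp))
  set.seed(8); b <- replicate(20, gibbs_latent_v(rec, params$eco, params$cls, "variable", sp))
  expect_identical(a, b)
})

test_that("spike-and-slab flip is exact Gibbs with conjugate nu update", {
  set.seed(4)
  # identical likelihoods: flip probability equals nu
  expect_equal(spike_slab_update(-12.3, -12.3, 0.5)$prob1, 0.5)
  expect_equal(spike_slab_update(-12.3, -12.3, 0.8)$prob1, 0.8)
  # overwhelming evidence pins the indicator
  expect_equal(spike_slab_update(-10, -1e4, 0.5)$prob1, 1)
  # nu posterior mean: Beta(2,1) = 2/3 after inclusion, Beta(1,2) = 1/3 after exclusion
  nus1 <- replicate(4000, spike_slab_update(0, -1e4, 0.5)$nu)
  expect_lt(abs(mean(nus1) - 2 / 3), 0.02)
  nus0 <- replicate(4000, spike_slab_update(-1e4, 0, 0.5)$nu)
  expect_lt(abs(mean(nus0) - 1 / 3), 0.02)
})

test_that("constant-scenario posterior is the closed-form Dirichlet under full verification", {
  b <- small_bundle(seed = 7, n_sites = 400)
  recs <- b$records  # every record verified
  fit <- fit_msdm(recs, "constant", sp, config = quick_cfg(n_iter = 3000, n_burnin = 500),
                  alpha_fixed = 1)
  d <- do.call(rbind, fit$draws)
  cnt <- table(factor(recs$v, 1:2), factor(recs$y, 1:3))
  expected <- (cnt + 1) / rowSums(cnt + 1)    # Dirichlet(1 + n_j.) row means
  for (j in 1:2) for (k in 1:3) {
    expect_lt(abs(mean(d[, paste0("Omega_", j, "_", k)]) - expected[j, k]), 0.01)
  }
})

test_that("a fully verified dataset leaves the latent step a no-op", {
  b <- small_bundle(seed = 13, n_sites = 150)
  fit <- fit_msdm(b$records, "variable", sp, config = quick_cfg())
  expect_length(fit$unverified_ids, 0)
  expect_equal(ncol(fit$latent[[1]]), 0)
  expect_true(is.finite(max(fit$rhat_identified, na.rm = TRUE)))
})

test_that("prior-only runs recover the priors", {
  empty <- make_record(y = 1, v = 1)[0, ]
  fit <- suppressWarnings(
    fit_msdm(empty, "variable", sp,
             config = fit_config(n_chains = 2, n_iter = 20000,
                                 n_burnin = 2000, thin = 2, seed = 3)))
  d <- do.call(rbind, fit$draws)
  expect_lt(abs(sd(d[, "beta0_1"]) / 10 - 1), 0.05)
  expect_lt(abs(sd(d[, "beta_1_2"]) / 10 - 1), 0.05)
  expect_lt(abs(sd(d[, "omega0_1_1"]) - 1), 0.05)
  expect_lt(abs(sd(d[, "omega_1_2_1"]) - 1), 0.05)
  expect_lt(abs(mean(d[, "psi_1"]) - 0.5), 0.03)
})

test_that("Gelman-Rubin statistic behaves on identical, i.i.d. and separated chains", {
  # identical copies: no between-chain variance, statistic at (or just
  # below, by the (n-1)/n factor) one
  ch <- matrix(rnorm(500), ncol = 1)
  expect_lt(abs(unname(gelman_rubin(list(ch, ch)))[1] - 1), 2e-3)
  # i.i.d. normal chains: close to 1
  set.seed(2)
  big <- lapply(1:2, function(i) matrix(rnorm(1e4), ncol = 1))
  expect_lt(gelman_rubin(big)[1], 1.01)
  # separated chains: far above the 1.1 screen
  sep <- list(matrix(rnorm(1000, 0), ncol = 1), matrix(rnorm(1000, 10), ncol = 1))
  expect_gt(gelman_rubin(sep)[1], 5)
  # constant chains: degenerate flag
  const <- list(matrix(1, 50, 1), matrix(1, 50, 1))
  r <- gelman_rubin(const)
  expect_equal(unname(r[1]), 1)
  expect_true(attr(r, "degenerate")[1])
  expect_error(gelman_rubin(list(matrix(1, 50, 1))), ">= 2 chains")
  expect_error(gelman_rubin(list(matrix(1, 5, 1), matrix(1, 5, 1))), ">= 10")
})

test_that("posterior predictions are modal states with low-index tie-breaks", {
  fake <- structure(list(
    latent = list(rbind(c(2L, 1L), c(2L, 1L)), rbind(c(2L, 2L), c(2L, 1L))),
    unverified_ids = c("a", "b"),
    space = sp
  ), class = "msdm_fit")
  colnames(fake$latent[[1]]) <- colnames(fake$latent[[2]]) <- c("a", "b")
  out <- predict_validation(fake)
  # "a": draws (2,2,2,2) -> state 2 with probability 1
  expect_equal(out$pred[out$id == "a"], 2L)
  expect_equal(out$prob_2[out$id == "a"], 1)
  # "b": draws (1,1,2,1) -> state 1 at 0.75
  expect_equal(out$pred[out$id == "b"], 1L)
  expect_equal(out$prob_1[out$id == "b"], 0.75)
  # exact tie goes to the lowest state index
  tied <- fake
  tied$latent <- list(matrix(c(1L, 2L), 2, 1, dimnames = list(NULL, "a")),
                      matrix(c(2L, 1L), 2, 1, dimnames = list(NULL, "a")))
  tied$unverified_ids <- "a"
  expect_equal(predict_validation(tied)$pred, 1L)
  expect_error(predict_validation(fake, ids = "zzz"), "no latent draws")
})

test_that("relabelling the true states yields the label-swapped posterior", {
  b <- small_bundle(seed = 17, n_sites = 400, n_withheld = 80)
  view <- train_validation_view(b)
  cfg <- quick_cfg(n_iter = 2000, n_burnin = 1000)
  fit1 <- fit_msdm(view$training, "variable", sp, config = cfg)
  swapped <- view$training
  swapped$v <- ifelse(is.na(swapped$v), NA_integer_, 3L - swapped$v)
  # reported labels 1 and 2 swap with the true labels; 3 ("other") stays
  swapped$y <- ifelse(swapped$y == 3L, 3L, 3L - swapped$y)
  fit2 <- fit_msdm(swapped, "variable", sp, config = cfg)
  s1 <- summary(fit1); s2 <- summary(fit2)
  med <- function(s, p) s$median[s$parameter == p]
  # identified ecological contrast flips sign
  c1 <- med(s1, "beta_1_1") - med(s1, "beta_1_2")
  c2 <- med(s2, "beta_1_1") - med(s2, "beta_1_2")
  expect_equal(c1, -c2, tolerance = 0.35)
  # correct-classification intercepts swap rows (and columns)
  expect_equal(med(s1, "omega0_1_1"), med(s2, "omega0_2_2"), tolerance = 0.35)
  expect_equal(med(s1, "omega0_2_2"), med(s2, "omega0_1_1"), tolerance = 0.35)
})

test_that("fit validates inputs and warns on missing verified states", {
  b <- small_bundle(seed = 19, n_sites = 60, n_withheld = 10)
  recs <- train_validation_view(b)$training
  recs$v[recs$v == 2L & !is.na(recs$v)] <- 1L  # state 2 never verified
  expect_warning(fit_msdm(recs, "variable", sp, config = quick_cfg(n_iter = 60, n_burnin = 20)),
                 "weakly identified")
  expect_error(fit_config(n_iter = 100, n_burnin = 100), "smaller")
  expect_error(prior_spec(eco_sd = -1), "positive")
})
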