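# Deterministic model mathematics.

params <- default_params()
sp <- tiny_space()

test_that("linear predictor combines intercepts, covariates and the selection gate", {
  cls <- params$cls
  # zero covariate leaves the intercepts
  expect_equal(build_linear_predictor(cls, 0)[1, ], c(2, 0.5, 0))
  # z = 1 with psi = 1 adds the slope row
  expect_equal(build_linear_predictor(cls, 1)[1, ], c(5, -0.5, 0))
  expect_equal(build_linear_predictor(cls, 1)[2, ], c(0, 2, 0))
  # indicator off: any slope is inert
  cls_off <- cls_params(cls$omega0, cls$omega, psi = 0L, nu = 0.5)
  expect_equal(build_linear_predictor(cls_off, 1),
               build_linear_predictor(cls_off, 0))
  expect_error(build_linear_predictor(cls, c(1, 2)), "dimension mismatch")
})

test_that("classification matrix is a row-wise softmax with reference state K", {
  cls <- params$cls
  Om <- classification_matrix(cls, 0)
  expect_equal(rowSums(Om), c(1, 1), tolerance = 1e-12)
  # hand softmax oracle: exp(2), exp(0.5), exp(0) normalised
  expect_equal(Om[1, ], c(0.7361, 0.1643, 0.0996), tolerance = 1e-4)
  # zeta row (5, -0.5, 0) from z = 1
  expect_equal(classification_matrix(cls, 1)[1, ],
               c(0.9893, 0.0040, 0.0067), tolerance = 1e-4)
  # symmetric intercepts give uniform rows
  uni <- cls_params(matrix(0, 2, 3))
  expect_equal(classification_matrix(uni, numeric(0))[1, ], rep(1 / 3, 3))
  # overflow guard: huge linear predictors stay finite
  big <- cls_params(rbind(c(900, 0, 0), c(0, 900, 0)))
  expect_true(all(is.finite(classification_matrix(big, numeric(0)))))
})

test_that("softmax is invariant to row translation and zero slopes to z", {
  om0 <- rbind(c(0.3, -1.2, 0), c(2, 0.1, 0))
  omega <- array(0, c(1, 2, 3))
  for (shift in c(-5, 0.7, 30)) {
    shifted <- cls_params(om0 + shift - shift, omega)  # base
    Om1 <- classification_matrix(shifted, 0.4)
    # adding a constant to a whole zeta row: emulate via intercepts on a
    # parameter set whose reference column is absorbed analytically
    zeta <- build_linear_predictor(shifted, 0.4)
    soft <- t(apply(zeta + shift, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    expect_equal(Om1, soft, tolerance = 1e-10)
  }
  # with all slopes zero the matrix cannot depend on z
  flat <- cls_params(om0, omega)
  expect_equal(classification_matrix(flat, -3), classification_matrix(flat, 8))
})

test_that("scenario masks constrain the right cells", {
  cls <- params$cls
  # intercept scenario: slopes all zeroed
  m_int <- apply_scenario_mask("intercept", cls, sp)
  expect_true(all(m_int$omega == 0))
  expect_equal(m_int$omega0, cls$omega0)
  # fixed_covariate: off-diagonal slopes zeroed
  m_fc <- apply_scenario_mask("fixed_covariate", cls, sp)
  expect_equal(m_fc$omega[1, , ], rbind(c(3, 0, 0), c(0, 1, 0)))
  # fixed_intercov: correct-classification intercepts tied at their mean
  m_fi <- apply_scenario_mask("fixed_intercov", cls, sp)
  expect_equal(m_fi$omega0[1, 1], 1.5)
  expect_equal(m_fi$omega0[2, 2], 1.5)
  expect_equal(m_fi$omega0[1, 2], 0.5)  # off-diagonal kept
  # variable: untouched
  expect_equal(apply_scenario_mask("variable", cls, sp), cls)
})

test_that("intensity follows the log-linear model and normalises to proportions", {
  eco <- params$eco
  expect_equal(intensity(eco, c(0, 0)), c(exp(-1), 1), tolerance = 1e-12)
  expect_equal(intensity(eco, c(1, 0)), c(exp(3), exp(-2)), tolerance = 1e-12)
  flat <- eco_params(c(0, 0, 0), matrix(0, 2, 3))
  expect_equal(intensity(flat, c(0.3, -2)), c(1, 1, 1))
  expect_error(intensity(eco, c(1, 2, 3)), "dimension mismatch")

  expect_equal(state_probabilities(c(0.3679, 1)), c(0.2689, 0.7311), tolerance = 1e-3)
  expect_equal(state_probabilities(c(exp(3), exp(-2))), c(0.9933, 0.0067), tolerance = 1e-4)
  expect_equal(state_probabilities(c(7, 7)), c(0.5, 0.5))
  # scale invariance
  lam <- c(0.2, 1.4, 3)
  expect_equal(state_probabilities(lam), state_probabilities(17.3 * lam))
  expect_error(state_probabilities(c(0, 0)), "zero")
  expect_error(state_probabilities(c(-1, 2)))
})

test_that("relative proportions are invariant to a common intercept shift", {
  eco <- params$eco
  x <- c(0.7, -1.1)
  for (c0 in c(-3, 2.5)) {
    shifted <- eco_params(eco$beta0 + c0, eco$beta)
    expect_equal(state_probabilities(intensity(shifted, x)),
                 state_probabilities(intensity(eco, x)), tolerance = 1e-12)
  }
})

test_that("true-state posterior is Bayes' rule and matches brute-force enumeration", {
  # uniform prior passes the confusion column through
  expect_equal(true_state_posterior(c(0.5, 0.5), rbind(c(0.8, 0.2), c(0.2, 0.8)), 1),
               c(0.8, 0.2))
  # worked case from the default parameters at z = 0
  p <- state_probabilities(intensity(params$eco, c(0, 0)))
  Om <- classification_matrix(params$cls, 0)
  expect_equal(true_state_posterior(p, Om, 1), c(0.3907, 0.6093), tolerance = 1e-4)
  # one-hot confusion column forces the posterior
  Om1 <- rbind(c(1, 0), c(0, 1))
  expect_equal(true_state_posterior(c(0.3, 0.7), Om1, 2), c(0, 1))
  expect_error(true_state_posterior(c(1, 0), rbind(c(1, 0), c(0.5, 0.5)), 2),
               "impossible")

  # brute-force enumeration oracle on random small instances
  set.seed(7)
  for (rep in 1:20) {
    J <- sample(2:5, 1); K <- sample(J:5, 1)
    p <- as.numeric(rgamma(J, 1)); p <- p / sum(p)
    Om <- matrix(rgamma(J * K, 1), J, K); Om <- Om / rowSums(Om)
    y <- sample(K, 1)
    joint <- vapply(seq_len(J), function(j) p[j] * Om[j, y], numeric(1))
    expect_equal(true_state_posterior(p, Om, y), joint / sum(joint),
                 tolerance = 1e-12)
  }
})

test_that("joint log-likelihood matches a per-record scalar oracle", {
  # single fully-certain verified record scores zero
  eco1 <- eco_params(c(10, -10), matrix(0, 1, 2))
  cls1 <- cls_params(rbind(c(40, 0, 0), c(0, 40, 0)))
  rec <- make_record(y = 1, v = 1, x = 0, z = numeric(0))
  rec$z_1 <- NULL
  ll <- joint_log_likelihood(rec, eco1, cls1, "variable", sp)
  expect_equal(ll, 0, tolerance = 1e-8)

  # hand-computed verified record under the default parameters
  rec2 <- make_record(y = 1, v = 1, x = c(0, 0), z = 0)
  ll2 <- joint_log_likelihood(rec2, params$eco, params$cls, "variable", sp)
  expect_equal(ll2, log(0.2689) + log(0.7361), tolerance = 1e-3)

  # dataset likelihood = sum of independent per-record oracle values,
  # with unverified records marginalised over the latent state
  set.seed(21)
  b <- small_bundle(seed = 3, n_sites = 40, n_withheld = 15)
  recs <- train_validation_view(b)$training
  ll_pkg <- joint_log_likelihood(recs, b$eco, b$cls, "variable", sp)
  ll_oracle <- sum(vapply(seq_len(nrow(recs)), function(i) {
    oracle_record_loglik(recs[i, ], b$eco, b$cls)
  }, numeric(1)))
  expect_equal(ll_pkg, ll_oracle, tolerance = 1e-10)
})

test_that("state space and parameter containers validate their invariants", {
  expect_error(state_space(1, 3), "J >= 2")
  expect_error(state_space(3, 2), "J <= K")
  expect_error(state_space(2, 3, diag_map = c(1, 1)), "injective")
  expect_error(cls_params(rbind(c(1, 2, 3), c(0, 0, 1))), "reference column")
  om <- array(1, c(1, 2, 3))
  expect_error(cls_params(rbind(c(1, 0, 0), c(0, 0, 0)), om), "reference column")
  expect_error(eco_params(c(0, Inf), matrix(0, 1, 2)), "finite")
})
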