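# Synthetic-data generator.

sp <- tiny_space()

test_that("default generating parameters are the study values", {
  p <- default_params()
  expect_equal(p$eco$beta0, c(-1, 0))
  expect_equal(p$eco$beta, rbind(c(4, -2), c(0, 0)))
  expect_equal(p$cls$omega0, rbind(c(2, 0.5, 0), c(1, 1, 0)))
  expect_equal(p$cls$omega[1, , ], rbind(c(3, -1, 0), c(-1, 1, 0)))
})

test_that("covariates are standard normal, with the requested cross-correlation", {
  set.seed(11)
  d <- simulation_design(n_sites = 1e5)
  cv <- gen_covariates(d)
  expect_lt(abs(mean(cv$X[, 1])), 0.02)
  expect_lt(abs(sd(cv$X[, 1]) - 1), 0.02)
  expect_lt(abs(cor(cv$X[, 1], cv$Z[, 1])), 0.02)

  dc <- simulation_design(n_sites = 1e5, generator = "correlation", rho = 0.7)
  cvc <- gen_covariates(dc)
  expect_lt(abs(cor(cvc$X[, 1], cvc$Z[, 1]) - 0.7), 0.03)
  expect_lt(abs(mean(cvc$Z[, 1])), 0.02)
  expect_lt(abs(sd(cvc$Z[, 1]) - 1), 0.02)

  # rho = 0 reduces to independent draws from the same stream
  set.seed(5); a <- gen_covariates(simulation_design(n_sites = 100, n_withheld = 20, generator = "correlation", rho = 0))
  set.seed(5); b <- gen_covariates(simulation_design(n_sites = 100, n_withheld = 20))
  expect_equal(a$Z, b$Z)
})

test_that("simulated reported states follow the per-individual confusion rows", {
  # condition on a narrow covariate window and compare empirical
  # transition frequencies with the analytic confusion matrix there
  b <- simulate_dataset(simulation_design(n_sites = 2e5, n_withheld = 10, seed = 2))
  z <- b$records$z_1
  win <- abs(z - 0.5) < 0.05
  Om <- classification_matrix(b$cls, 0.5)
  emp <- prop.table(table(factor(b$records$v[win], 1:2),
                          factor(b$records$y[win], 1:3)), 1)
  expect_lt(max(abs(emp - Om)), 0.05)

  # marginal true-state frequencies match the covariate-averaged proportions
  X <- as.matrix(b$records[, c("x_1", "x_2")])
  eta <- cbind(-1 + 4 * X[, 1], -2 * X[, 1])
  p1 <- 1 / (1 + exp(eta[, 2] - eta[, 1]))
  expect_lt(abs(mean(b$records$v == 1) - mean(p1)), 0.01)
})

test_that("the reduced generator has a z-independent classification process", {
  b <- simulate_dataset(simulation_design(n_sites = 1e5, n_withheld = 10,
                                          generator = "reduced", seed = 4))
  expect_true(all(b$cls$omega == 0))
  zq <- cut(b$records$z_1, quantile(b$records$z_1, c(0, 0.25, 0.5, 0.75, 1)),
            include.lowest = TRUE)
  for (j in 1:2) {
    sel <- b$records$v == j
    p <- suppressWarnings(chisq.test(table(b$records$y[sel], zq[sel]))$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("decreasing misclassification raises correct-classification sharply", {
  # analytic check of the +6 diagonal shift at z = 0
  b_dec <- simulate_dataset(simulation_design(n_sites = 500, misclass_level = "decrease", seed = 9))
  expect_equal(b_dec$cls$omega0[, 1:2], rbind(c(8, 0.5), c(1, 7)))
  Om <- classification_matrix(b_dec$cls, 0)
  # softmax oracle: exp(8) / (exp(8) + exp(0.5) + 1)
  expect_equal(Om[1, 1], 0.999112, tolerance = 1e-5)
  # same seed, baseline vs decrease: identical covariates and true states,
  # strictly fewer mismatches under decrease
  b_base <- simulate_dataset(simulation_design(n_sites = 500, seed = 9))
  expect_equal(b_base$records$x_1, b_dec$records$x_1)
  expect_equal(b_base$records$v, b_dec$records$v)
  expect_lt(sum(b_dec$records$y != b_dec$records$v),
            sum(b_base$records$y != b_base$records$v))
})

test_that("simulation is byte-identical under a fixed seed", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_truth_bundle(simulate_dataset(simulation_design(n_sites = 200, n_withheld = 40, seed = 12)), f1)
  write_truth_bundle(simulate_dataset(simulation_design(n_sites = 200, n_withheld = 40, seed = 12)), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(paste0(f1, ".json")), readLines(paste0(f2, ".json")))
})

test_that("the training view masks exactly the validation ids", {
  b <- small_bundle(seed = 6)
  expect_length(b$validation_ids, 60)
  view <- train_validation_view(b)
  masked <- view$training$id[is.na(view$training$v)]
  expect_setequal(masked, b$validation_ids)
  expect_setequal(view$training$id, b$records$id)
  # answer key restores the simulated truth
  expect_equal(view$answer_key$v_true,
               b$records$v[match(view$answer_key$id, b$records$id)])
  # unmasked records keep their verified state
  keep <- !view$training$id %in% b$validation_ids
  expect_equal(view$training$v[keep], b$records$v[keep])
})

test_that("default design withholds 200 of 1000 sites", {
  d <- simulation_design()
  expect_equal(d$n_sites, 1000L)
  expect_equal(d$n_withheld, 200L)
  expect_error(simulation_design(n_sites = 100, n_withheld = 200), "smaller")
})

test_that("occurrence CSV round-trips through the documented schema", {
  b <- small_bundle(seed = 8, n_sites = 50, n_withheld = 10)
  f <- tempfile(fileext = ".csv")
  write_truth_bundle(b, f)
  back <- read_occurrence_csv(f)
  expect_equal(sum(is.na(back$v)), 10)
  expect_named(back, c("id", "site_id", "y", "v", "x_1", "x_2", "z_1"))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("id,zzz", "a,1"), bad)
  expect_error(read_occurrence_csv(bad), "missing required column")
})
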