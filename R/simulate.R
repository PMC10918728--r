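# Synthetic-data generation for the simulation study: discrete sites, one
# classified individual per site, standard-normal covariates, and three
# generating regimes (full heterogeneous, reduced homogeneous, correlated
# covariates) at two misclassification levels.

#' Simulation design
#'
#' Describes one simulated dataset: the number of discrete sites (one
#' individual per site), the state space, covariate counts, the generating
#' regime and misclassification level, and how many verified identities are
#' withheld for validation.
#'
#' @param n_sites Number of sites/individuals (default 1000).
#' @param J,K True and reported state counts (defaults 2 and 3).
#' @param n_e,n Ecological and classification covariate counts (defaults 2, 1).
#' @param generator `"full"` (heterogeneous classification), `"reduced"`
#'   (homogeneous: all classification slopes zero) or `"correlation"`
#'   (heterogeneous with `z_1` correlated to `x_1`).
#' @param misclass_level `"baseline"`, or `"decrease"` which adds 6 to the
#'   correct-classification intercepts so far fewer individuals are
#'   misclassified.
#' @param rho Correlation between `x_1` and `z_1` for the correlation
#'   generator (default 0.7; `z_1` remains standard normal marginally).
#' @param n_withheld Verified identities masked for validation (default 200).
#' @param seed Integer seed for this dataset.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_sites = 1000, J = 2, K = 3, n_e = 2, n = 1,
                              generator = c("full", "reduced", "correlation"),
                              misclass_level = c("baseline", "decrease"),
                              rho = 0.7, n_withheld = 200, seed = 1) {
  generator <- match.arg(generator)
  misclass_level <- match.arg(misclass_level)
  if (n_withheld >= n_sites) stop("n_withheld must be smaller than n_sites")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  structure(list(n_sites = as.integer(n_sites), J = as.integer(J),
                 K = as.integer(K), n_e = as.integer(n_e), n = as.integer(n),
                 generator = generator, misclass_level = misclass_level,
                 rho = rho, n_withheld = as.integer(n_withheld),
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Default generating parameters of the simulation study
#'
#' The two-true-state, three-reported-state parameter set used throughout
#' the simulation study: ecological intercepts `beta0 = (-1, 0)` (state 2 is
#' the reference), slopes `beta = ((4, -2), (0, 0))` so only the first
#' ecological covariate matters, and classification parameters
#' `omega0 = ((2, 0.5, 0), (1, 1, 0))`, `omega1 = ((3, -1, 0), (-1, 1, 0))`
#' whose zero third columns encode the reference reported state. These
#' values yield a substantial number of misclassified individuals.
#'
#' @return A list with elements `eco` ([eco_params]) and `cls`
#'   ([cls_params]).
#' @examples
#' default_params()$eco$beta0
#' @export
default_params <- function() {
  eco <- eco_params(beta0 = c(-1, 0),
                    beta = rbind(c(4, -2), c(0, 0)))
  omega0 <- rbind(c(2, 0.5, 0), c(1, 1, 0))
  omega <- array(0, c(1, 2, 3))
  omega[1, , ] <- rbind(c(3, -1, 0), c(-1, 1, 0))
  list(eco = eco, cls = cls_params(omega0, omega))
}

#' Draw per-site covariates
#'
#' All covariates are i.i.d. standard normal. Under the `correlation`
#' generator, `z_1 = rho * x_1 + sqrt(1 - rho^2) * eps` so that `z_1` is
#' standard normal marginally with `cor(x_1, z_1) = rho`.
#'
#' @param design A [simulation_design]. The caller controls the RNG state
#'   (this function does not seed).
#' @return A list with matrices `X` (`n_sites x n_e`) and `Z`
#'   (`n_sites x n`).
#' @export
gen_covariates <- function(design) {
  S <- design$n_sites
  X <- matrix(rnorm(S * design$n_e), S, design$n_e)
  Z <- matrix(rnorm(S * design$n), S, design$n)
  if (design$generator == "correlation" && design$n >= 1 && design$n_e >= 1) {
    rho <- design$rho
    Z[, 1] <- rho * X[, 1] + sqrt(1 - rho^2) * Z[, 1]
  }
  colnames(X) <- paste0("x_", seq_len(design$n_e))
  colnames(Z) <- if (design$n > 0) paste0("z_", seq_len(design$n))
  list(X = X, Z = Z)
}

#' Simulate one dataset from the hierarchical model
#'
#' Draws one individual per site: covariates, then the latent true state
#' `V ~ Categorical(p_s)` from the relative-abundance model, then the
#' reported state `Y ~ Categorical(Omega[V, , s])` from the per-individual
#' confusion matrix. The `reduced` generator zeroes the classification
#' slopes before simulating; `misclass_level = "decrease"` adds 6 to the
#' correct-classification intercepts. `n_withheld` ids are sampled without
#' replacement as the validation set.
#'
#' @param design A [simulation_design].
#' @param params Generating parameters (default [default_params]); must
#'   match the design's dimensions.
#' @return An object of class `msdm_truth`: a list with the design, the
#'   generating `eco` and `cls` parameters (after generator/level
#'   adjustments), the complete `records` data frame (both `v` and `y`
#'   filled) and `validation_ids`.
#' @export
simulate_dataset <- function(design, params = default_params()) {
  stopifnot(inherits(design, "simulation_design"))
  eco <- params$eco; cls <- params$cls
  space <- state_space(design$J, design$K)
  if (length(eco$beta0) != design$J || nrow(eco$beta) != design$n_e ||
      dim(cls$omega)[1] != design$n || ncol(cls$omega0) != design$K) {
    stop("params do not match the design dimensions")
  }
  if (design$generator == "reduced") cls$omega[] <- 0
  if (design$misclass_level == "decrease") {
    dm <- space$diag_map
    cls$omega0[cbind(seq_len(design$J), dm)] <-
      cls$omega0[cbind(seq_len(design$J), dm)] + 6
  }
  set.seed(design$seed)
  cov <- gen_covariates(design)
  S <- design$n_sites; J <- design$J; K <- design$K

  # relative-abundance probabilities, vectorised over sites
  eta <- matrix(eco$beta0, S, J, byrow = TRUE) + cov$X %*% eco$beta
  P <- softmax_rows(eta)
  u <- runif(S)
  # inverse-CDF categorical draw: first index where the cumulative reaches u
  v <- max.col(-(t(apply(P, 1L, cumsum)) < u), ties.method = "first")

  # per-individual confusion row for the drawn true state
  zeta <- matrix(cls$omega0[v, ], S, K)
  for (p in seq_len(design$n)) {
    zeta <- zeta + cls$psi[p] * cov$Z[, p] * matrix(cls$omega[p, , ][v, ], S, K)
  }
  Om <- softmax_rows(zeta)
  u2 <- runif(S)
  y <- max.col(-(t(apply(Om, 1L, cumsum)) < u2), ties.method = "first")

  ids <- sprintf("s%04d", seq_len(S))
  records <- data.frame(id = ids, site_id = ids, y = y, v = v,
                        stringsAsFactors = FALSE)
  records <- cbind(records, as.data.frame(cov$X), as.data.frame(cov$Z))
  validation_ids <- sample(ids, design$n_withheld)
  structure(list(design = design, eco = eco, cls = cls, records = records,
                 validation_ids = validation_ids),
            class = "msdm_truth")
}

#' Split a simulated truth bundle into a training view and an answer key
#'
#' The training view hides the verified state of every validation id
#' (`v = NA`); the answer key records the hidden values for scoring.
#'
#' @param bundle An `msdm_truth` from [simulate_dataset].
#' @return A list with `training` (records with masked `v`) and
#'   `answer_key` (data frame `id`, `v_true`).
#' @export
train_validation_view <- function(bundle) {
  stopifnot(inherits(bundle, "msdm_truth"))
  records <- bundle$records
  mask <- records$id %in% bundle$validation_ids
  key <- data.frame(id = records$id[mask], v_true = records$v[mask],
                    stringsAsFactors = FALSE)
  records$v[mask] <- NA_integer_
  list(training = records, answer_key = key)
}

#' Write a truth bundle as an occurrence CSV plus sidecar JSON
#'
#' The CSV is the masked training view; the sidecar records the design, the
#' generating parameters and the answer key so the run is fully
#' reproducible and scoreable.
#'
#' @param bundle An `msdm_truth`.
#' @param csv_path,json_path Output paths (sidecar defaults to
#'   `<csv_path>.json`).
#' @return `csv_path`, invisibly.
#' @export
write_truth_bundle <- function(bundle, csv_path,
                               json_path = paste0(csv_path, ".json")) {
  view <- train_validation_view(bundle)
  write_occurrence_csv(view$training, csv_path)
  sidecar <- list(
    design = unclass(bundle$design),
    eco = list(beta0 = bundle$eco$beta0, beta = bundle$eco$beta),
    cls = list(omega0 = bundle$cls$omega0, omega = bundle$cls$omega),
    answer_key = view$answer_key
  )
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
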