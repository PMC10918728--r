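# Deterministic model mathematics: linear predictors, confusion matrices,
# intensities, state probabilities, likelihood and the true-state posterior.

softmax_rows <- function(m) {
  # max-subtraction guards overflow for large linear predictors
  shifted <- m - apply(m, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}

clip_log <- function(p, floor = 1e-300) {
  if (any(p < floor)) {
    warning("probabilities below 1e-300 clipped before taking logs")
    p <- pmax(p, floor)
  }
  log(p)
}

#' MMGLM linear predictor for one individual
#'
#' Computes the `J x K` matrix of multinomial-logit linear predictors
#' `zeta[j, k] = omega0[j, k] + sum_p psi[p] * z[p] * omega[p, j, k]` for an
#' individual with classification covariates `z`. Column `K` (the reference
#' reported state) is identically zero.
#'
#' @param cls A [cls_params] object.
#' @param z Numeric vector of classification covariates, length `n`.
#' @return A `J x K` numeric matrix.
#' @examples
#' cls <- default_params()$cls
#' build_linear_predictor(cls, z = 1)
#' @export
build_linear_predictor <- function(cls, z) {
  stopifnot(inherits(cls, "cls_params"))
  z <- as.numeric(z)
  n <- dim(cls$omega)[1]
  if (length(z) != n) {
    stop(sprintf("dimension mismatch: z has length %d but cls has %d covariate(s)",
                 length(z), n))
  }
  if (n > 0 && !all(is.finite(z))) stop("z must be finite")
  zeta <- cls$omega0
  for (p in seq_len(n)) {
    zeta <- zeta + cls$psi[p] * z[p] * cls$omega[p, , , drop = TRUE]
  }
  zeta
}

#' Per-individual confusion matrix
#'
#' Maps the MMGLM linear predictor to classification probabilities by a
#' row-wise softmax with reference category `K`:
#' `Omega[j, k] = exp(zeta[j, k]) / sum_k' exp(zeta[j, k'])`. Each row of the
#' result is the probability distribution of the reported state given true
#' state `j`, so rows sum to one.
#'
#' @inheritParams build_linear_predictor
#' @param scenario A [scenario_spec] (or its name); must use the MMGLM
#'   classification form.
#' @return A `J x K` matrix of probabilities with unit row sums.
#' @examples
#' cls <- default_params()$cls
#' classification_matrix(cls, z = 0)
#' @export
classification_matrix <- function(cls, z, scenario = scenario_spec("variable")) {
  scenario <- as_scenario(scenario)
  if (scenario$classification_form != "mmglm") {
    stop("classification_matrix applies to MMGLM scenarios; '", scenario$name,
         "' draws its confusion matrix from a Dirichlet prior")
  }
  zeta <- build_linear_predictor(cls, z)
  if (any(is.nan(zeta))) stop("NaN in linear predictor")
  softmax_rows(zeta)
}

#' Apply a scenario's parameter constraints
#'
#' Enforces the parameter masks that define the simplified observation-model
#' scenarios: `fixed_covariate` allows covariates to act only on the
#' correct-classification cells (`omega[p, j, k] = 0` unless
#' `k = diag_map(j)`); `fixed_intercov` additionally ties all
#' correct-classification intercepts to one shared value (initialised at
#' their mean); `intercept` zeroes all covariate slopes; `constant` and
#' `main` do not use the MMGLM parameters at all (slopes are zeroed so the
#' returned object is inert).
#'
#' @param scenario A [scenario_spec] or scenario name.
#' @param cls A [cls_params] object.
#' @param space A [state_space].
#' @return A masked [cls_params] object.
#' @examples
#' p <- default_params()
#' apply_scenario_mask("fixed_covariate", p$cls, state_space(2, 3))
#' @export
apply_scenario_mask <- function(scenario, cls, space) {
  scenario <- as_scenario(scenario)
  stopifnot(inherits(cls, "cls_params"), inherits(space, "state_space"))
  J <- space$J; K <- space$K
  if (nrow(cls$omega0) != J || ncol(cls$omega0) != K) {
    stop("cls dimensions do not match the state space")
  }
  omega0 <- cls$omega0
  omega <- cls$omega
  n <- dim(omega)[1]
  name <- scenario$name
  if (name %in% c("fixed_covariate", "fixed_intercov")) {
    dm <- space$diag_map
    if (any(dm > K)) stop("fixed_* scenarios need a valid diag_map entry per true state")
    keep <- matrix(FALSE, J, K)
    keep[cbind(seq_len(J), dm)] <- TRUE
    for (p in seq_len(n)) omega[p, , ][!keep] <- 0
    omega[, , K] <- 0  # reference column stays pinned
    if (name == "fixed_intercov") {
      free_diag <- dm < K  # a diagonal cell in the reference column is fixed at 0
      if (!any(free_diag)) stop("fixed_intercov: no free correct-classification intercept to tie")
      shared <- mean(omega0[cbind(which(free_diag), dm[free_diag])])
      omega0[cbind(which(free_diag), dm[free_diag])] <- shared
    }
  } else if (name == "intercept" || scenario$classification_form == "dirichlet") {
    omega[] <- 0
  }
  cls_params(omega0, omega, psi = cls$psi, nu = cls$nu)
}

#' True-state intensity for one individual
#'
#' Evaluates the inhomogeneous relative-abundance intensity
#' `lambda_j = exp(beta0_j + sum_q x_q beta[q, j])`, with the extra gated
#' term `psi_eco * z1 * beta_cls[j]` under the `main` scenario.
#'
#' @param eco An [eco_params] object.
#' @param x Numeric vector of ecological covariates.
#' @param z1 First classification covariate; required for the `main`
#'   scenario only.
#' @param scenario A [scenario_spec] or name (default `"variable"`).
#' @return Strictly positive numeric vector of length `J`.
#' @examples
#' intensity(default_params()$eco, x = c(1, 0))
#' @export
intensity <- function(eco, x, z1 = NULL, scenario = scenario_spec("variable")) {
  stopifnot(inherits(eco, "eco_params"))
  scenario <- as_scenario(scenario)
  x <- as.numeric(x)
  if (length(x) != nrow(eco$beta)) {
    stop(sprintf("dimension mismatch: x has length %d but eco has %d covariate(s)",
                 length(x), nrow(eco$beta)))
  }
  if (!all(is.finite(x))) stop("x must be finite")
  eta <- eco$beta0 + as.numeric(crossprod(eco$beta, x))
  if (scenario$name == "main") {
    if (is.null(z1)) stop("scenario 'main' requires the classification covariate z1")
    if (is.null(eco$beta_cls)) stop("scenario 'main' requires eco$beta_cls")
    eta <- eta + eco$psi_eco * z1 * eco$beta_cls
  }
  lam <- exp(eta)
  if (!all(is.finite(lam))) stop("non-finite intensity")
  lam
}

#' Relative true-state proportions
#'
#' Normalises intensities to the probability that an individual belongs to
#' each true state: `p_j = lambda_j / sum(lambda)`. Only these relative
#' proportions are identified by the model (multiplying all intensities by a
#' positive constant, i.e. shifting all `beta0_j` by a common amount, leaves
#' them unchanged).
#'
#' @param lam Strictly positive numeric vector of intensities.
#' @return A probability vector of the same length.
#' @examples
#' state_probabilities(c(0.3679, 1))
#' @export
state_probabilities <- function(lam) {
  lam <- as.numeric(lam)
  if (any(!is.finite(lam)) || any(lam < 0)) stop("intensities must be finite and non-negative")
  s <- sum(lam)
  if (s <= 0) stop("intensities sum to zero")
  lam / s
}

#' Posterior probability of the true state given a reported state
#'
#' Bayes' rule combining the ecological prior `p` with the individual's
#' confusion matrix: `P(V = j | Y = y) = p_j * Omega[j, y] / sum_j' p_j' *
#' Omega[j', y]`. This is the full conditional used to impute latent true
#' states during fitting and to predict withheld identities.
#'
#' @param p Probability vector over true states (length `J`).
#' @param omega_mat `J x K` confusion matrix for this individual.
#' @param y Reported state index in `1..K`.
#' @return A probability vector of length `J`.
#' @examples
#' true_state_posterior(c(0.5, 0.5), rbind(c(0.8, 0.2), c(0.2, 0.8)), y = 1)
#' @export
true_state_posterior <- function(p, omega_mat, y) {
  p <- as.numeric(p)
  omega_mat <- as.matrix(omega_mat)
  y <- as.integer(y)
  if (length(p) != nrow(omega_mat)) stop("length(p) must equal nrow(omega_mat)")
  if (y < 1L || y > ncol(omega_mat)) stop("y out of range 1..K")
  w <- p * omega_mat[, y]
  s <- sum(w)
  if (s <= 0) stop("reported state impossible under the model (all p_j * Omega[j, y] = 0)")
  w / s
}

#' Joint log-likelihood of a set of records
#'
#' Sums, over verified records, `log p[v] + log Omega[v, y]` and, over
#' unverified records, the latent-state marginal
#' `log sum_j p[j] * Omega[j, y]`. For the Dirichlet scenarios (`constant`,
#' `main`) supply the shared confusion matrix via `Omega`; for MMGLM
#' scenarios it is rebuilt per individual from `cls` and the record's `z`
#' covariates.
#'
#' @param records An occurrence data frame (see [read_occurrence_csv] for
#'   the column conventions); `v = NA` marks unverified records.
#' @param eco An [eco_params] object.
#' @param cls A [cls_params] object (MMGLM scenarios).
#' @param scenario A [scenario_spec] or name.
#' @param space A [state_space].
#' @param Omega Optional explicit `J x K` confusion matrix (Dirichlet
#'   scenarios).
#' @return A scalar log-likelihood; `-Inf` (with a warning) if an observed
#'   outcome has probability zero.
#' @export
joint_log_likelihood <- function(records, eco, cls = NULL,
                                 scenario = scenario_spec("variable"),
                                 space, Omega = NULL) {
  scenario <- as_scenario(scenario)
  stopifnot(inherits(space, "state_space"))
  cov <- occ_covariates(records, space)
  use_mmglm <- scenario$classification_form == "mmglm"
  if (use_mmglm && is.null(cls)) stop("MMGLM scenarios require cls")
  if (!use_mmglm && is.null(Omega)) stop("Dirichlet scenarios require an explicit Omega")
  ll <- 0
  for (s in seq_len(nrow(records))) {
    z1 <- if (ncol(cov$Z) > 0) cov$Z[s, 1] else NULL
    p <- state_probabilities(intensity(eco, cov$X[s, ], z1 = z1, scenario = scenario))
    Om <- if (use_mmglm) classification_matrix(cls, cov$Z[s, ], scenario) else Omega
    y <- records$y[s]; v <- records$v[s]
    contrib <- if (!is.na(v)) p[v] * Om[v, y] else sum(p * Om[, y])
    if (contrib <= 0) {
      warning("observed outcome has probability zero; log-likelihood is -Inf")
      return(-Inf)
    }
    ll <- ll + log(contrib)
  }
  ll
}
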