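# Non-parametric score-weighting alternative: model reported-state
# intensities with a multinomial-logit regression, then convert fixed
# machine-learning prediction scores into posterior true-state predictions.

#' Reported-state intensity parameters
#'
#' Multinomial-logit parameters of the reported-state intensity model
#' `log lambda_k = gamma0_k + sum_q x_q gamma[q, k]`, with reported state
#' `K` as the reference category (its column is pinned at zero, mirroring
#' the true-state convention).
#'
#' @param gamma0 Numeric vector of length `K`; last entry must be 0.
#' @param gamma Numeric `n_e x K` matrix; last column must be 0.
#' @return An object of class `reported_state_params`.
#' @export
reported_state_params <- function(gamma0, gamma = matrix(0, 0, length(gamma0))) {
  gamma0 <- as.numeric(gamma0)
  gamma <- as.matrix(gamma)
  K <- length(gamma0)
  if (ncol(gamma) != K) stop("gamma must have K columns")
  if (gamma0[K] != 0 || (nrow(gamma) > 0 && any(gamma[, K] != 0))) {
    stop("reference column K must be zero")
  }
  structure(list(gamma0 = gamma0, gamma = gamma), class = "reported_state_params")
}

#' Fit the reported-state intensity model
#'
#' Posterior sampling for the multinomial-logit model of reported states
#' `Y_s ~ Categorical(lambda_k / sum_k lambda_k)` with
#' `log lambda_k = gamma0_k + x' gamma_k`, by the same adaptive
#' random-walk Metropolis machinery as the joint model. Verified states
#' and scores are not used at this stage.
#'
#' @param records Occurrence data frame (needs `y` and `x_*` columns).
#' @param K Number of reported states.
#' @param priors A [prior_spec]; `eco_sd` is the prior sd here since this
#'   is an intensity (ecological-type) model.
#' @param config A [fit_config].
#' @return An object of class `reported_fit` with per-chain draw matrices,
#'   Gelman-Rubin statistics and posterior-median [reported_state_params].
#' @export
fit_reported_model <- function(records, K, priors = prior_spec(),
                               config = fit_config()) {
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "fit_config"))
  y <- as.integer(records$y)
  if (any(y < 1L | y > K)) stop("reported states y outside 1..K")
  absent <- setdiff(seq_len(K), unique(y))
  if (length(absent)) {
    warning("reported state(s) ", paste(absent, collapse = ", "),
            " have no occurrences; their intensities are prior-dominated")
  }
  X <- occ_covariates(records)$X
  n_e <- ncol(X)
  g0_nm <- paste0("gamma0_", seq_len(K))
  g_nm <- if (n_e > 0) {
    as.vector(outer(seq_len(n_e), seq_len(K),
                    function(q, k) paste0("gamma_", q, "_", k)))
  } else character(0)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    raw <- mcmc_multinom_cpp(y, X, K, priors$eco_sd,
                             config$n_iter, config$n_burnin, config$thin,
                             config$adapt, config$proposal_scale)
    m <- cbind(raw$gamma0, raw$gamma)
    colnames(m) <- c(g0_nm, g_nm)
    chains[[ch]] <- m
  }
  rh <- gelman_rubin(chains)
  med <- apply(do.call(rbind, chains), 2, median)
  params <- reported_state_params(
    gamma0 = c(med[g0_nm[-K]], 0),
    gamma = if (n_e > 0) {
      g <- matrix(med[g_nm], n_e, K)
      g[, K] <- 0
      g
    } else matrix(0, 0, K)
  )
  structure(list(draws = chains, rhat = rh, params = params, K = K,
                 config = config, priors = priors),
            class = "reported_fit")
}

#' @export
print.reported_fit <- function(x, ...) {
  cat("reported_fit: K =", x$K, "reported states,", length(x$draws),
      "chains, max Gelman-Rubin", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Predict true states from ML prediction scores
#'
#' Converts each record's fixed classifier scores `w[k, j]` (for its
#' reported state `k = y`) into a posterior over true states. Under the
#' default normalisation over true states,
#' `P(V = j | Y = k) = lambda_k * w[k, j] / sum_j' lambda_k * w[k, j']`,
#' the reported-state intensity cancels and the prediction is the score
#' vector normalised over `j`. The alternative reading that normalises
#' over reported states (combining all reported-state intensities via a
#' shared `K x J` score matrix) is available with
#' `normalise = "reported_states"` for sensitivity analysis; its weights
#' are renormalised over `j` so a probability vector is still returned.
#' The point prediction is the modal state, ties broken toward the lowest
#' index.
#'
#' @param rep A [reported_state_params] or `reported_fit` (used only by
#'   the `"reported_states"` reading; may be `NULL` for the default).
#' @param records Occurrence data frame with `score_1..score_J` columns,
#'   or with `score_matrix` supplied instead.
#' @param space A [state_space].
#' @param normalise `"true_states"` (default) or `"reported_states"`.
#' @param score_matrix Optional shared `K x J` score matrix for
#'   individuals with one classifier profile (required for the
#'   `"reported_states"` reading; rows index reported states).
#' @return Data frame with `id`, `pred` and `prob_1..prob_J`.
#' @export
predict_true_from_scores <- function(rep = NULL, records, space,
                                     normalise = c("true_states", "reported_states"),
                                     score_matrix = NULL) {
  normalise <- match.arg(normalise)
  stopifnot(inherits(space, "state_space"))
  J <- space$J; K <- space$K
  cov <- occ_covariates(records, space)
  if (is.null(score_matrix)) {
    if (is.null(cov$scores)) stop("records carry no score_1..score_J columns")
    W <- cov$scores
  } else {
    score_matrix <- as.matrix(score_matrix)
    if (nrow(score_matrix) != K || ncol(score_matrix) != J) {
      stop("score_matrix must be K x J")
    }
    W <- score_matrix[records$y, , drop = FALSE]
  }
  if (any(!is.finite(W)) || any(W < 0)) stop("scores must be finite and non-negative")
  if (any(rowSums(W) == 0)) stop("some records have all-zero scores")

  if (normalise == "true_states") {
    probs <- W / rowSums(W)
  } else {
    if (is.null(score_matrix)) {
      stop("the reported-state normalisation needs a shared K x J score_matrix")
    }
    if (inherits(rep, "reported_fit")) rep <- rep$params
    if (!inherits(rep, "reported_state_params")) {
      stop("the reported-state normalisation needs reported-state parameters")
    }
    eta <- matrix(rep$gamma0, nrow(records), K, byrow = TRUE)
    if (nrow(rep$gamma) > 0) eta <- eta + cov$X %*% rep$gamma
    lam <- exp(eta)                       # S x K reported-state intensities
    denom <- lam %*% score_matrix         # sum_k lambda_k w[k, j], per true state
    num <- lam[cbind(seq_len(nrow(records)), records$y)] * W
    probs <- num / denom
    probs <- probs / rowSums(probs)       # renormalised over j
  }
  pred <- apply(probs, 1, which.max)
  out <- data.frame(id = records$id, pred = as.integer(pred),
                    stringsAsFactors = FALSE)
  colnames(probs) <- paste0("prob_", seq_len(J))
  cbind(out, as.data.frame(probs, row.names = NULL))
}
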