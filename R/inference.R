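# Bayesian fitting by Metropolis-within-Gibbs with latent true-state
# imputation. The sweep is implemented in compiled code (src/mcmc.cpp);
# this file assembles chains, names parameters, and provides diagnostics
# and posterior prediction.

.scenario_code <- c(variable = 1L, fixed_covariate = 2L, fixed_intercov = 3L,
                    intercept = 4L, constant = 5L, main = 6L)

#' MCMC configuration
#'
#' @param n_chains Number of independent chains (default 3).
#' @param n_iter Iterations per chain (default 10000).
#' @param n_burnin Burn-in iterations discarded (default 5000).
#' @param thin Keep one draw in `thin` after burn-in (default 5).
#' @param seed Base seed; chain `c` uses `seed + c - 1`.
#' @param proposal_scale Initial random-walk proposal sd.
#' @param adapt Adapt proposal scales toward 0.44 acceptance during
#'   burn-in (Robbins-Monro on the log scale); frozen afterwards.
#' @param rhat_threshold Convergence screen: a fit is flagged
#'   non-converged if any parameter's potential scale reduction factor
#'   exceeds this (default 1.1).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_chains = 3, n_iter = 10000, n_burnin = 5000,
                       thin = 5, seed = 1, proposal_scale = 0.2,
                       adapt = TRUE, rhat_threshold = 1.1) {
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), proposal_scale = proposal_scale,
                 adapt = isTRUE(adapt), rhat_threshold = rhat_threshold),
            class = "fit_config")
}

#' Prior specification
#'
#' Ecological parameters get Normal(0, `eco_sd`) priors, classification
#' parameters Normal(0, `cls_sd`); the Dirichlet scenarios place
#' `Omega_j ~ Dirichlet(alpha, ..., alpha)` with
#' `alpha ~ Exponential(rate = alpha_rate)` (mean 1 by default); each
#' selection probability `nu_p` is Uniform(0, 1).
#'
#' @param eco_sd Prior sd of ecological parameters (default 10).
#' @param cls_sd Prior sd of classification parameters (default 1).
#' @param alpha_rate Exponential rate for the Dirichlet concentration.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(eco_sd = 10, cls_sd = 1, alpha_rate = 1) {
  if (eco_sd <= 0 || cls_sd <= 0 || alpha_rate <= 0) stop("priors must be positive")
  structure(list(eco_sd = eco_sd, cls_sd = cls_sd, alpha_rate = alpha_rate),
            class = "prior_spec")
}

.param_names <- function(scenario, space, n_e, n) {
  J <- space$J; K <- space$K
  nm <- list()
  nm$beta0 <- paste0("beta0_", seq_len(J))
  if (n_e > 0) {
    nm$beta <- as.vector(outer(seq_len(n_e), seq_len(J),
                               function(q, j) paste0("beta_", q, "_", j)))
  }
  grid_jk <- expand.grid(j = seq_len(J), k = seq_len(K))  # column-major
  if (scenario$name == "main") {
    nm$beta3 <- paste0("beta3_", seq_len(J))
    nm$psi_eco <- c("psi_eco", "nu_eco")
  }
  if (scenario$classification_form == "mmglm") {
    nm$omega0 <- paste0("omega0_", grid_jk$j, "_", grid_jk$k)
    if (scenario$name != "intercept") {
      grid_pjk <- expand.grid(p = seq_len(n), j = seq_len(J), k = seq_len(K))
      nm$omega <- paste0("omega_", grid_pjk$p, "_", grid_pjk$j, "_", grid_pjk$k)
    }
    if (scenario$spike_slab_on == "classification") {
      nm$psi <- paste0("psi_", seq_len(n))
      nm$nu <- paste0("nu_", seq_len(n))
    }
  } else {
    nm$Omega <- paste0("Omega_", grid_jk$j, "_", grid_jk$k)
    nm$alpha <- "alpha"
  }
  nm
}

#' Fit the joint abundance + classification model
#'
#' Runs `n_chains` independent Metropolis-within-Gibbs chains. Each sweep
#' (i) imputes the latent true state of every unverified record from its
#' full conditional `P(V = j | .) ∝ p_j * Omega[j, y]`, (ii) updates the
#' ecological parameters by adaptive scalar random-walk Metropolis,
#' (iii) updates the free MMGLM classification parameters the same way
#' (or, for the Dirichlet scenarios, updates each confusion-matrix row
#' conjugately from the latent classification counts and the
#' concentration `alpha` by Metropolis under its Exponential prior), and
#' (iv) performs exact Gibbs flips of the spike-and-slab indicators with
#' conjugate Beta updates of their inclusion probabilities.
#'
#' @param records Occurrence data frame; `v = NA` marks unverified
#'   records, which are handled by latent-state augmentation.
#' @param scenario A [scenario_spec] or scenario name.
#' @param space A [state_space].
#' @param priors A [prior_spec].
#' @param config A [fit_config].
#' @param alpha_fixed Optionally hold the Dirichlet concentration fixed at
#'   this value instead of sampling it (used for conjugacy checks).
#' @return An object of class `msdm_fit` holding per-chain draw matrices
#'   (`$draws`), latent true-state draws for the unverified records
#'   (`$latent`), per-parameter Gelman-Rubin statistics (`$rhat`),
#'   acceptance rates and the fitting metadata. Because only relative
#'   abundances are identified, the convergence flag `$converged` screens
#'   the identified contrasts `beta_.j - beta_.J` (in
#'   `$rhat_identified`) together with all classification parameters,
#'   not the softly-identified raw ecological parameters.
#' @export
fit_msdm <- function(records, scenario, space, priors = prior_spec(),
                     config = fit_config(), alpha_fixed = NULL) {
  scenario <- as_scenario(scenario)
  stopifnot(inherits(space, "state_space"), inherits(priors, "prior_spec"),
            inherits(config, "fit_config"))
  cov <- occ_covariates(records, space)
  if (scenario$name == "main" && ncol(cov$Z) < 1) {
    stop("scenario 'main' needs a classification covariate z_1")
  }
  ver <- records$v[!is.na(records$v)]
  missing_states <- setdiff(seq_len(space$J), unique(ver))
  if (length(missing_states)) {
    warning("no verified records for true state(s) ",
            paste(missing_states, collapse = ", "),
            "; classification parameters are weakly identified")
  }
  y <- as.integer(records$y)
  v <- ifelse(is.na(records$v), 0L, as.integer(records$v))
  code <- .scenario_code[[scenario$name]]
  nm <- .param_names(scenario, space, ncol(cov$X), ncol(cov$Z))
  af <- if (is.null(alpha_fixed)) -1 else as.numeric(alpha_fixed)

  chains <- vector("list", config$n_chains)
  latent <- vector("list", config$n_chains)
  acc <- vector("list", config$n_chains)
  unver_ids <- NULL
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    raw <- mcmc_msdm_cpp(y, v, cov$X, cov$Z, space$J, space$K,
                         space$diag_map, code,
                         priors$eco_sd, priors$cls_sd,
                         config$n_iter, config$n_burnin, config$thin,
                         config$adapt, config$proposal_scale, af)
    if (!all(is.finite(raw$beta0))) {
      stop("non-finite posterior draws; check covariate scaling and priors")
    }
    blocks <- list(raw$beta0, raw$beta)
    if (scenario$name == "main") blocks <- c(blocks, list(raw$beta3, raw$psi_eco))
    if (scenario$classification_form == "mmglm") {
      blocks <- c(blocks, list(raw$omega0))
      if (scenario$name != "intercept") blocks <- c(blocks, list(raw$omega))
      if (scenario$spike_slab_on == "classification") {
        blocks <- c(blocks, list(raw$psi, raw$nu))
      }
    } else {
      blocks <- c(blocks, list(raw$Omega, raw$alpha))
    }
    m <- do.call(cbind, blocks)
    colnames(m) <- unlist(nm, use.names = FALSE)
    chains[[ch]] <- m
    lat <- raw$V
    unver_ids <- records$id[raw$unverified_index + 1L]
    colnames(lat) <- unver_ids
    latent[[ch]] <- lat
    acc[[ch]] <- raw$acc_rate
  }
  rh <- gelman_rubin(chains)
  rh_id <- gelman_rubin(lapply(chains, identified_transform, space = space))
  structure(list(draws = chains, latent = latent,
                 unverified_ids = unver_ids,
                 scenario = scenario, space = space,
                 priors = priors, config = config,
                 n_records = nrow(records), n_e = ncol(cov$X), n = ncol(cov$Z),
                 acc_rate = acc, rhat = rh, rhat_identified = rh_id,
                 converged = all(rh_id <= config$rhat_threshold, na.rm = TRUE)),
            class = "msdm_fit")
}

#' @export
print.msdm_fit <- function(x, ...) {
  cat("msdm_fit: scenario '", x$scenario$name, "', ", x$n_records,
      " records (", length(x$unverified_ids), " unverified), ",
      length(x$draws), " chains x ", nrow(x$draws[[1]]), " kept draws\n", sep = "")
  cat("max Gelman-Rubin statistic (identified quantities):",
      round(max(x$rhat_identified, na.rm = TRUE), 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.msdm_fit <- function(object, prob = 0.95, ...) {
  all_draws <- do.call(rbind, object$draws)
  a <- (1 - prob) / 2
  data.frame(
    parameter = colnames(all_draws),
    median = apply(all_draws, 2, median),
    lower = apply(all_draws, 2, quantile, a),
    upper = apply(all_draws, 2, quantile, 1 - a),
    rhat = object$rhat[colnames(all_draws)],
    row.names = NULL
  )
}

# Map a chain's draw matrix to the likelihood-identified quantities used by
# the convergence screen. Only relative abundances are identified, so the
# ecological parameters enter as contrasts against the last true state
# (beta_.j - beta_.J); classification parameters, inclusion probabilities
# and the Dirichlet quantities are identified as-is. The 0/1 indicators are
# discrete and excluded.
identified_transform <- function(m, space) {
  J <- space$J
  cols <- colnames(m)
  out <- list()
  for (prefix in c("beta0_", "beta3_")) {
    ref <- paste0(prefix, J)
    if (!ref %in% cols) next
    for (j in seq_len(J - 1)) {
      out[[paste0(prefix, j, "_vs_", J)]] <- m[, paste0(prefix, j)] - m[, ref]
    }
  }
  slope_q <- unique(sub("^beta_([0-9]+)_[0-9]+$", "\\1",
                        grep("^beta_[0-9]+_[0-9]+$", cols, value = TRUE)))
  for (q in slope_q) {
    ref <- paste0("beta_", q, "_", J)
    for (j in seq_len(J - 1)) {
      out[[paste0("beta_", q, "_", j, "_vs_", J)]] <-
        m[, paste0("beta_", q, "_", j)] - m[, ref]
    }
  }
  keep <- grep("^(omega0_|omega_|nu_|nu_eco$|Omega_|alpha$)", cols, value = TRUE)
  cbind(do.call(cbind, out), m[, keep, drop = FALSE])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF per parameter across chains:
#' `sqrt(((m - 1)/m * W + B/m) / W)` with `W` the mean within-chain
#' variance and `B/m` the variance of the chain means. Parameters with
#' zero within-chain variance (e.g. structurally fixed reference cells)
#' are reported as 1 and flagged in the `"degenerate"` attribute.
#'
#' @param x An `msdm_fit`, or a list (one element per chain) of numeric
#'   vectors or matrices with matching columns.
#' @return Named numeric vector of PSRFs, with a logical `"degenerate"`
#'   attribute.
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "msdm_fit")) x <- x$draws
  if (!is.list(x) || length(x) < 2) stop("gelman_rubin needs >= 2 chains")
  x <- lapply(x, function(ch) if (is.null(dim(ch))) matrix(ch, ncol = 1) else as.matrix(ch))
  m <- length(x)
  iters <- nrow(x[[1]])
  if (iters < 10) stop("gelman_rubin needs >= 10 kept draws per chain")
  P <- ncol(x[[1]])
  rhat <- numeric(P)
  degen <- logical(P)
  for (p in seq_len(P)) {
    draws <- vapply(x, function(ch) ch[, p], numeric(iters))
    W <- mean(apply(draws, 2, var))
    B_over_n <- var(colMeans(draws))
    if (W <= .Machine$double.eps) {
      rhat[p] <- 1; degen[p] <- TRUE
    } else {
      rhat[p] <- sqrt(((iters - 1) / iters * W + B_over_n) / W)
    }
  }
  names(rhat) <- colnames(x[[1]])
  names(degen) <- colnames(x[[1]])
  attr(rhat, "degenerate") <- degen
  rhat
}

#' Draw a latent true state from its full conditional
#'
#' One Gibbs draw of an unverified record's true state: a categorical draw
#' from [true_state_posterior] given the record's ecological prior and its
#' confusion matrix.
#'
#' @param record One-row occurrence data frame with `v` missing.
#' @param eco An [eco_params].
#' @param cls A [cls_params] (MMGLM scenarios) or `NULL`.
#' @param scenario A [scenario_spec] or name.
#' @param space A [state_space].
#' @param Omega Explicit confusion matrix for Dirichlet scenarios.
#' @return Integer state in `1..J`.
#' @export
gibbs_latent_v <- function(record, eco, cls = NULL,
                           scenario = scenario_spec("variable"), space,
                           Omega = NULL) {
  scenario <- as_scenario(scenario)
  if (!is.na(record$v[1])) stop("gibbs_latent_v applies to unverified records")
  cov <- occ_covariates(record, space)
  z1 <- if (ncol(cov$Z) > 0) cov$Z[1, 1] else NULL
  p <- state_probabilities(intensity(eco, cov$X[1, ], z1 = z1, scenario = scenario))
  Om <- if (scenario$classification_form == "mmglm") {
    classification_matrix(cls, cov$Z[1, ], scenario)
  } else {
    if (is.null(Omega)) stop("Dirichlet scenarios require an explicit Omega")
    Omega
  }
  post <- true_state_posterior(p, Om, record$y[1])
  sample.int(space$J, 1L, prob = post)
}

#' Spike-and-slab indicator and inclusion-probability update
#'
#' Exact Gibbs flip of a selection indicator given the data log-likelihood
#' under inclusion and exclusion:
#' `P(psi = 1 | .) = nu * L1 / (nu * L1 + (1 - nu) * L0)`, followed by the
#' conjugate update `nu | psi ~ Beta(1 + psi, 2 - psi)` under the
#' Uniform(0, 1) prior on `nu`.
#'
#' @param loglik1,loglik0 Data log-likelihoods with the covariate selected
#'   / not selected.
#' @param nu Current inclusion probability.
#' @return List with `prob1` (the exact flip probability), the sampled
#'   `psi` and the updated `nu`.
#' @export
spike_slab_update <- function(loglik1, loglik0, nu) {
  if (nu <= 0 || nu >= 1) stop("nu must lie strictly in (0, 1)")
  m <- max(loglik1 + log(nu), loglik0 + log(1 - nu))
  w1 <- exp(loglik1 + log(nu) - m)
  w0 <- exp(loglik0 + log(1 - nu) - m)
  prob1 <- w1 / (w1 + w0)
  psi <- as.integer(runif(1) < prob1)
  list(prob1 = prob1, psi = psi, nu = rbeta(1, 1 + psi, 2 - psi))
}

#' Predict withheld true states from the latent draws
#'
#' For each unverified record the per-state posterior probability is the
#' fraction of kept draws (pooled over chains) in which its latent true
#' state equalled that state; the point prediction is the posterior modal
#' state, with ties broken toward the lowest state index.
#'
#' @param fit An `msdm_fit`.
#' @param ids Record ids to predict (default: all unverified records).
#' @return Data frame with `id`, `pred` and `prob_1..prob_J`.
#' @export
predict_validation <- function(fit, ids = NULL) {
  stopifnot(inherits(fit, "msdm_fit"))
  if (is.null(ids)) ids <- fit$unverified_ids
  missing_ids <- setdiff(ids, fit$unverified_ids)
  if (length(missing_ids)) {
    stop("no latent draws for record(s): ", paste(missing_ids, collapse = ", "))
  }
  lat <- do.call(rbind, fit$latent)[, ids, drop = FALSE]
  J <- fit$space$J
  probs <- t(apply(lat, 2, function(col) tabulate(col, J) / length(col)))
  pred <- apply(probs, 1, which.max)  # first maximum = lowest-index tie-break
  out <- data.frame(id = ids, pred = as.integer(pred), stringsAsFactors = FALSE)
  colnames(probs) <- paste0("prob_", seq_len(J))
  cbind(out, as.data.frame(probs, row.names = NULL))
}

#' Persist posterior draws as a long-format table
#'
#' Writes one row per (chain, kept iteration, parameter) to CSV. Latent
#' true-state draws of unverified records are included as parameters
#' named `V_<id>`, so predictions can be recomputed from the file alone.
#'
#' @param fit An `msdm_fit`.
#' @param path Output CSV path.
#' @param include_latent Include the latent true-state draws (default
#'   `TRUE`).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path, include_latent = TRUE) {
  stopifnot(inherits(fit, "msdm_fit"))
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    m <- fit$draws[[ch]]
    if (include_latent && length(fit$unverified_ids)) {
      lat <- fit$latent[[ch]]
      colnames(lat) <- paste0("V_", colnames(lat))
      m <- cbind(m, lat)
    }
    data.frame(chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON fit summary
#'
#' Posterior medians, 95% intervals, Gelman-Rubin statistics, acceptance
#' rates and (where applicable) spike-and-slab inclusion probabilities.
#'
#' @param fit An `msdm_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  s <- summary(fit)
  out <- list(scenario = fit$scenario$name,
              n_records = fit$n_records,
              n_chains = length(fit$draws),
              kept_per_chain = nrow(fit$draws[[1]]),
              converged = fit$converged,
              max_rhat = max(fit$rhat, na.rm = TRUE),
              parameters = s,
              acceptance_rates = lapply(fit$acc_rate, as.numeric))
  if (fit$scenario$uses_spike_slab) {
    out$selection_probability <- as.list(selection_probability(fit))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
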