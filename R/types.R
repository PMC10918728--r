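#' Define the true/reported state space
#'
#' A state space records how many verified ("true") taxon identities `J` and
#' reported identities `K` a study distinguishes, and which reported index
#' counts as a *correct* classification of each true state. Reported states
#' may outnumber true states (e.g. an extra "others" category), so the
#' correct-classification map is explicit rather than assumed to be the
#' identity.
#'
#' @param J Number of true states (>= 2).
#' @param K Number of reported states (>= 2, `K >= J`).
#' @param labels_true,labels_reported Optional character labels.
#' @param diag_map Integer vector of length `J`: `diag_map[j]` is the
#'   reported-state index that means "correctly classified as `j`".
#'   Defaults to the identity on the first `J` reported states. Must be
#'   injective.
#'
#' @return An object of class `state_space`.
#' @examples
#' state_space(2, 3)
#' @export
state_space <- function(J, K,
                        labels_true = paste0("true", seq_len(J)),
                        labels_reported = paste0("reported", seq_len(K)),
                        diag_map = seq_len(J)) {
  J <- as.integer(J); K <- as.integer(K)
  if (J < 2L || K < 2L) stop("state_space requires J >= 2 and K >= 2")
  if (J > K) stop("state_space requires J <= K (reported states may add categories, not drop them)")
  diag_map <- as.integer(diag_map)
  if (length(diag_map) != J || anyDuplicated(diag_map) ||
      any(diag_map < 1L | diag_map > K)) {
    stop("diag_map must be an injective map from 1..J into 1..K")
  }
  if (length(labels_true) != J || length(labels_reported) != K) {
    stop("label lengths must match J and K")
  }
  structure(list(J = J, K = K, labels_true = as.character(labels_true),
                 labels_reported = as.character(labels_reported),
                 diag_map = diag_map),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space: J =", x$J, "true states, K =", x$K, "reported states\n")
  cat("  correct-classification map:",
      paste0(x$labels_true, " -> ", x$labels_reported[x$diag_map],
             collapse = ", "), "\n")
  invisible(x)
}

.scenario_names <- c("variable", "fixed_covariate", "fixed_intercov",
                     "intercept", "constant", "main")

#' Observation-model scenario
#'
#' The six study scenarios vary how the classification (observation) process
#' is modelled. Three are heterogeneous multinomial-GLM (MMGLM) forms with
#' spike-and-slab selection of the classification covariates
#' (`variable`, `fixed_covariate`, `fixed_intercov`); `intercept` is the
#' homogeneous MMGLM (intercepts only); `constant` places a Dirichlet prior
#' directly on each confusion-matrix row; `main` uses the Dirichlet
#' classification form but moves the classification covariate `z1` into the
#' ecological linear predictor with its own spike-and-slab indicator.
#'
#' @param name One of `"variable"`, `"fixed_covariate"`, `"fixed_intercov"`,
#'   `"intercept"`, `"constant"`, `"main"`.
#' @return An object of class `scenario_spec` with fields `name`,
#'   `heterogeneous`, `uses_spike_slab`, `spike_slab_on` (`"classification"`,
#'   `"ecology"` or `"none"`) and `classification_form` (`"mmglm"` or
#'   `"dirichlet"`).
#' @examples
#' scenario_spec("variable")
#' @export
scenario_spec <- function(name = .scenario_names) {
  name <- match.arg(name)
  het <- name %in% c("variable", "fixed_covariate", "fixed_intercov")
  ss_on <- if (het) "classification" else if (name == "main") "ecology" else "none"
  structure(list(
    name = name,
    heterogeneous = het,
    uses_spike_slab = ss_on != "none",
    spike_slab_on = ss_on,
    classification_form = if (name %in% c("constant", "main")) "dirichlet" else "mmglm"
  ), class = "scenario_spec")
}

as_scenario <- function(x) {
  if (inherits(x, "scenario_spec")) x else scenario_spec(x)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario '", x$name, "': ",
      if (x$heterogeneous) "heterogeneous" else "homogeneous",
      " classification (", x$classification_form, ")",
      if (x$uses_spike_slab) paste0(", spike-and-slab on ", x$spike_slab_on),
      "\n", sep = "")
  invisible(x)
}

#' Ecological process parameters
#'
#' Intercepts and slopes of the log-intensity (relative abundance) model
#' `log lambda_j = beta0_j + sum_q x_q beta[q, j]`. Under the `main`
#' scenario the classification covariate `z1` additionally enters with
#' slope `beta_cls[j]` gated by the 0/1 indicator `psi_eco`.
#'
#' @param beta0 Numeric vector of length `J`.
#' @param beta Numeric matrix `n_e x J` of covariate slopes.
#' @param beta_cls Optional numeric vector of length `J` (`main` only).
#' @param psi_eco Optional 0/1 indicator gating `beta_cls`.
#' @return An object of class `eco_params`.
#' @examples
#' eco_params(c(-1, 0), rbind(c(4, -2), c(0, 0)))
#' @export
eco_params <- function(beta0, beta, beta_cls = NULL, psi_eco = NULL) {
  beta0 <- as.numeric(beta0)
  beta <- as.matrix(beta)
  if (ncol(beta) != length(beta0)) {
    stop("beta must have one column per true state (length(beta0))")
  }
  if (!all(is.finite(beta0)) || !all(is.finite(beta))) {
    stop("ecological parameters must be finite")
  }
  if (!is.null(beta_cls)) {
    beta_cls <- as.numeric(beta_cls)
    if (length(beta_cls) != length(beta0)) stop("beta_cls must have length J")
    if (is.null(psi_eco)) psi_eco <- 1L
  }
  structure(list(beta0 = beta0, beta = beta, beta_cls = beta_cls,
                 psi_eco = if (is.null(psi_eco)) NULL else as.integer(psi_eco)),
            class = "eco_params")
}

#' Classification (observation) process parameters
#'
#' Parameters of the row-wise multinomial GLM for the confusion matrix.
#' The last reported state `K` is the reference category: column `K` of the
#' intercept matrix and of every covariate slice is identically zero, so the
#' free entries are the logit contrasts against state `K`.
#'
#' @param omega0 Numeric `J x K` intercept matrix; column `K` must be zero.
#' @param omega Numeric `n x J x K` array of covariate effects (may have
#'   `n = 0`); every `[p, , K]` slice must be zero.
#' @param psi Integer 0/1 selection indicators, length `n`.
#' @param nu Selection probabilities in (0, 1), length `n`.
#' @return An object of class `cls_params`.
#' @examples
#' omega0 <- rbind(c(2, 0.5, 0), c(1, 1, 0))
#' omega <- array(c(3, -1, -1, 1, 0, 0), dim = c(1, 2, 3))
#' cls_params(omega0, omega)
#' @export
cls_params <- function(omega0, omega = array(0, c(0, nrow(omega0), ncol(omega0))),
                       psi = rep(1L, dim(omega)[1]),
                       nu = rep(0.5, dim(omega)[1])) {
  omega0 <- as.matrix(omega0)
  J <- nrow(omega0); K <- ncol(omega0)
  if (length(dim(omega)) != 3L || dim(omega)[2] != J || dim(omega)[3] != K) {
    stop("omega must be an n x J x K array matching omega0")
  }
  n <- dim(omega)[1]
  if (!all(is.finite(omega0)) || (n > 0 && !all(is.finite(omega)))) {
    stop("classification parameters must be finite")
  }
  if (any(omega0[, K] != 0)) {
    stop("reference column K of omega0 must be zero (identifiability convention)")
  }
  if (n > 0 && any(omega[, , K] != 0)) {
    stop("reference column K of every omega slice must be zero")
  }
  if (length(psi) != n || length(nu) != n) stop("psi and nu must have length n")
  if (n > 0 && (any(!psi %in% c(0L, 1L)) || any(nu < 0 | nu > 1))) {
    stop("psi must be 0/1 and nu in [0, 1]")
  }
  structure(list(omega0 = omega0, omega = omega,
                 psi = as.integer(psi), nu = as.numeric(nu)),
            class = "cls_params")
}

#' @export
print.cls_params <- function(x, ...) {
  cat("Classification parameters: J =", nrow(x$omega0), ", K =", ncol(x$omega0),
      ",", dim(x$omega)[1], "covariate(s)\n")
  cat("omega0:\n"); print(x$omega0)
  invisible(x)
}
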