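# Validation metrics and simulation-study summaries.

#' Score predicted true states against an answer key
#'
#' The three study metrics, computed on withheld verified records:
#' *accuracy* is the proportion of validation records whose predicted true
#' state matches the verified one; *precision* is that proportion among
#' the *mismatched* records (those whose reported state differs from the
#' correct classification of their true state, `y != diag_map(v_true)`);
#' *recall* is that proportion among the *matched* records
#' (`y == diag_map(v_true)`). An empty denominator yields `NA` with an
#' `"undefined"` attribute flag, never 0/0 = 0.
#'
#' @param predicted Data frame with `id` and `pred` (e.g. from
#'   [predict_validation] or [predict_true_from_scores]).
#' @param answer_key Data frame with `id` and `v_true`.
#' @param reported Data frame with `id` and `y`.
#' @param space A [state_space] (supplies `diag_map`).
#' @return An object of class `validation_metrics`: a list with
#'   `accuracy`, `precision`, `recall`, `n_validation`, `n_mismatched`,
#'   `n_matched`.
#' @examples
#' sp <- state_space(2, 3)
#' pred <- data.frame(id = c("a", "b"), pred = c(1, 2))
#' key <- data.frame(id = c("a", "b"), v_true = c(1, 2))
#' rep <- data.frame(id = c("a", "b"), y = c(1, 1))
#' compute_metrics(pred, key, rep, sp)
#' @export
compute_metrics <- function(predicted, answer_key, reported, space) {
  stopifnot(inherits(space, "state_space"))
  ids <- answer_key$id
  if (!setequal(ids, predicted$id) || !all(ids %in% reported$id)) {
    stop("id misalignment between predictions, answer key and reported states")
  }
  pred <- predicted$pred[match(ids, predicted$id)]
  y <- reported$y[match(ids, reported$id)]
  v_true <- answer_key$v_true
  correct <- pred == v_true
  mismatched <- y != space$diag_map[v_true]
  n_val <- length(ids)
  n_mis <- sum(mismatched)
  n_mat <- n_val - n_mis
  safe_prop <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(accuracy = safe_prop(sum(correct), n_val),
              precision = safe_prop(sum(correct & mismatched), n_mis),
              recall = safe_prop(sum(correct & !mismatched), n_mat),
              n_validation = n_val, n_mismatched = n_mis, n_matched = n_mat)
  attr(out, "undefined") <- c(precision = n_mis == 0, recall = n_mat == 0,
                              accuracy = n_val == 0)
  class(out) <- "validation_metrics"
  out
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %s  recall %s  (n = %d, %d mismatched)\n",
              x$accuracy,
              ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
              ifelse(is.na(x$recall), "NA", sprintf("%.3f", x$recall)),
              x$n_validation, x$n_mismatched))
  invisible(x)
}

#' Per-parameter bias, absolute error and interval coverage
#'
#' For each named true value: `bias = posterior median - truth`, the
#' absolute error, and whether the truth falls inside the equal-tailed
#' 95% credible interval.
#'
#' @param fit An `msdm_fit`, or a matrix of pooled draws with named
#'   columns.
#' @param truth Named numeric vector of generating values; names must
#'   match parameter names.
#' @return Data frame with `parameter`, `truth`, `bias`, `abs_error`,
#'   `covered`.
#' @export
parameter_bias <- function(fit, truth) {
  draws <- if (inherits(fit, "msdm_fit")) do.call(rbind, fit$draws) else as.matrix(fit)
  missing_par <- setdiff(names(truth), colnames(draws))
  if (length(missing_par)) {
    stop("no draws for parameter(s): ", paste(missing_par, collapse = ", "))
  }
  rows <- lapply(names(truth), function(pn) {
    d <- draws[, pn]
    ci <- quantile(d, c(0.025, 0.975))
    med <- median(d)
    data.frame(parameter = pn, truth = truth[[pn]], bias = med - truth[[pn]],
               abs_error = abs(med - truth[[pn]]),
               covered = truth[[pn]] >= ci[1] && truth[[pn]] <= ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior spike-and-slab inclusion probability
#'
#' Two summaries of the selection output, per covariate (or, for the
#' `main` scenario, for the single ecological indicator):
#' `type = "psi"` is the posterior mean of the 0/1 selection indicator
#' (the fraction of kept draws with the covariate selected);
#' `type = "nu"` is the posterior mean of the expected inclusion
#' probability `nu` (updated conjugately as `Beta(1 + psi, 2 - psi)`, so
#' its posterior mean is `(1 + E[psi]) / 3`: about 1/3 for a clearly
#' excluded covariate and 2/3 for a clearly included one). The `nu`
#' summary is the conventional "variable selection probability" reported
#' for this model class; the `psi` summary is sharper and is the
#' default.
#'
#' @param fit An `msdm_fit` from a spike-and-slab scenario.
#' @param type `"psi"` (default) or `"nu"`.
#' @return Named numeric vector of inclusion probabilities.
#' @export
selection_probability <- function(fit, type = c("psi", "nu")) {
  stopifnot(inherits(fit, "msdm_fit"))
  type <- match.arg(type)
  if (!fit$scenario$uses_spike_slab) {
    stop("scenario '", fit$scenario$name, "' has no spike-and-slab indicator")
  }
  draws <- do.call(rbind, fit$draws)
  cols <- if (fit$scenario$spike_slab_on == "classification") {
    grep(paste0("^", type, "_[0-9]+$"), colnames(draws), value = TRUE)
  } else paste0(type, "_eco")
  colMeans(draws[, cols, drop = FALSE])
}
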