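# Scenario-grid experiment runner: simulate, fit every requested scenario
# on the same training view, predict the withheld identities, score them,
# and aggregate across replicates with a convergence screen.

#' Experiment configuration
#'
#' @param generators Subset of `c("full", "reduced", "correlation")`.
#' @param misclass_levels Subset of `c("baseline", "decrease")`.
#' @param scenarios Observation-model scenarios to fit (any of the six
#'   [scenario_spec] names plus `"ml_weights"` for the score-weighting
#'   alternative).
#' @param n_replicates Replicate datasets per (generator, level) cell.
#' @param design Named list of [simulation_design] overrides (e.g.
#'   `list(n_sites = 400)`).
#' @param fit A [fit_config] applied to every fit.
#' @param priors A [prior_spec].
#' @param output_dir Directory for the results tree.
#' @param master_seed Master seed; dataset `r` uses stream `master_seed +
#'   r` so arms sharing a replicate index share covariates.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(generators = "full",
                              misclass_levels = "baseline",
                              scenarios = c("variable", "intercept"),
                              n_replicates = 20,
                              design = list(),
                              fit = fit_config(),
                              priors = prior_spec(),
                              output_dir = "msdm_results",
                              master_seed = 1) {
  generators <- match.arg(generators, c("full", "reduced", "correlation"),
                          several.ok = TRUE)
  misclass_levels <- match.arg(misclass_levels, c("baseline", "decrease"),
                               several.ok = TRUE)
  valid <- c(.scenario_names, "ml_weights")
  bad <- setdiff(scenarios, valid)
  if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(generators = generators, misclass_levels = misclass_levels,
                 scenarios = scenarios, n_replicates = as.integer(n_replicates),
                 design = design, fit = fit, priors = priors,
                 output_dir = output_dir, master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

# content key for resumability: FNV-1a over the serialized scientific
# configuration (everything that changes the numbers, not the output path)
config_hash <- function(cfg) {
  key <- cfg[setdiff(names(cfg), "output_dir")]
  bytes <- as.integer(serialize(key, NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Attach synthetic classifier scores to a simulated truth bundle
#'
#' Adds `score_1..score_J` columns emulating a machine-learning classifier
#' run on each individual. Two synthetic profiles are available.
#' `mode = "classifier"` (default) draws each record's score vector from
#' `Dirichlet(1 + strength * e_v)`, concentrated on the *true* state `v`:
#' like an image classifier, its skill comes from information outside the
#' parametric observation model and does not depend on how many records
#' were misreported. `mode = "likelihood"` sets the scores to the
#' generating confusion-matrix likelihoods `w[j] = Omega[j, y_s, s]`, a
#' classifier exactly as informed as the generating model itself.
#'
#' @param bundle An `msdm_truth` from [simulate_dataset].
#' @param mode `"classifier"` or `"likelihood"`.
#' @param strength Dirichlet concentration added on the true state
#'   (classifier mode; default 8, giving a mean score near 0.9 on the
#'   true state for two states).
#' @return The bundle with score columns added to its records.
#' @export
attach_generating_scores <- function(bundle,
                                     mode = c("classifier", "likelihood"),
                                     strength = 8) {
  stopifnot(inherits(bundle, "msdm_truth"))
  mode <- match.arg(mode)
  records <- bundle$records
  J <- length(bundle$eco$beta0)
  S <- nrow(records)
  W <- matrix(NA_real_, S, J)
  if (mode == "likelihood") {
    cov <- occ_covariates(records)
    for (s in seq_len(S)) {
      Om <- classification_matrix(bundle$cls, cov$Z[s, ])
      W[s, ] <- Om[, records$y[s]]
    }
  } else {
    for (s in seq_len(S)) {
      a <- rep(1, J); a[records$v[s]] <- 1 + strength
      g <- rgamma(J, shape = a)
      W[s, ] <- g / sum(g)
    }
  }
  colnames(W) <- paste0("score_", seq_len(J))
  bundle$records <- cbind(records, as.data.frame(W))
  bundle
}

run_one_cell <- function(cfg, generator, level, r, scen_name) {
  des_args <- modifyList(c(list(generator = generator, misclass_level = level,
                                seed = cfg$master_seed + r), cfg$design),
                         list())
  design <- do.call(simulation_design, des_args)
  bundle <- simulate_dataset(design)
  if (scen_name == "ml_weights") bundle <- attach_generating_scores(bundle)
  view <- train_validation_view(bundle)
  space <- state_space(design$J, design$K)
  fit_cfg <- cfg$fit
  fit_cfg$seed <- cfg$master_seed + 100000L + 100L * r +
    match(scen_name, c(.scenario_names, "ml_weights"))
  dataset_hash <- config_hash(list(bundle$records$y, bundle$records$v))

  if (scen_name == "ml_weights") {
    rep_fit <- fit_reported_model(view$training, K = design$K,
                                  priors = cfg$priors, config = fit_cfg)
    val <- view$training[view$training$id %in% bundle$validation_ids, ]
    pred <- predict_true_from_scores(rep_fit, val, space)
    max_rhat <- max(rep_fit$rhat, na.rm = TRUE)
    converged <- max_rhat <= fit_cfg$rhat_threshold
    sel <- NA_real_; sel_nu <- NA_real_
  } else {
    fit <- fit_msdm(view$training, scen_name, space,
                    priors = cfg$priors, config = fit_cfg)
    pred <- predict_validation(fit)
    max_rhat <- max(fit$rhat_identified, na.rm = TRUE)
    converged <- fit$converged
    sel <- if (fit$scenario$uses_spike_slab) {
      mean(selection_probability(fit, "psi"))
    } else NA_real_
    sel_nu <- if (fit$scenario$uses_spike_slab) {
      mean(selection_probability(fit, "nu"))
    } else NA_real_
  }
  metrics <- compute_metrics(pred, view$answer_key, view$training, space)
  list(generator = generator, misclass_level = level, replicate = r,
       scenario = scen_name, dataset_hash = dataset_hash,
       accuracy = metrics$accuracy, precision = metrics$precision,
       recall = metrics$recall, n_mismatched = metrics$n_mismatched,
       selection_probability = sel, selection_probability_nu = sel_nu,
       max_rhat = max_rhat, converged = converged)
}

#' Run a simulation-study experiment grid
#'
#' For every (generator, misclassification level, replicate): simulate one
#' dataset, fit each requested scenario on the same masked training view,
#' predict the withheld true states and score them. Replicates whose fit
#' fails the Gelman-Rubin screen (any PSRF above the configured
#' threshold) are listed in `convergence.csv` and excluded from the
#' aggregate summary. The runner is resumable: completed cells (keyed by
#' a hash of the scientific configuration) are skipped on re-run.
#'
#' @param cfg An [experiment_config].
#' @return Invisibly, a list with `metrics` (tidy long data frame: one
#'   row per replicate x scenario x metric), `summary` (per-cell medians
#'   and interquartile ranges over converged replicates) and
#'   `convergence` (per-fit screen results). Also written to
#'   `output_dir` as `metrics.csv`, `summary.csv`, `convergence.csv`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  cell_dir <- file.path(cfg$output_dir, "cells")
  dir.create(cell_dir, showWarnings = FALSE)
  h <- config_hash(unclass(cfg))

  rows <- list()
  for (generator in cfg$generators) {
    for (level in cfg$misclass_levels) {
      for (r in seq_len(cfg$n_replicates)) {
        for (scen in cfg$scenarios) {
          cell_file <- file.path(cell_dir, sprintf("%s_%s_%s_r%03d_%s.json",
                                                   h, generator, level, r, scen))
          if (file.exists(cell_file)) {
            rows[[length(rows) + 1L]] <- jsonlite::read_json(cell_file)
            next
          }
          res <- tryCatch(
            run_one_cell(cfg, generator, level, r, scen),
            error = function(e) {
              message(sprintf("cell %s/%s/r%d/%s failed: %s",
                              generator, level, r, scen, conditionMessage(e)))
              NULL
            })
          if (is.null(res)) next
          jsonlite::write_json(res, cell_file, auto_unbox = TRUE,
                               digits = NA, na = "null")
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
  }
  if (!length(rows)) stop("no experiment cell completed")
  wide <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(lapply(r, function(x) if (is.null(x)) NA else x),
                  stringsAsFactors = FALSE)
  }))
  metrics <- do.call(rbind, lapply(c("accuracy", "precision", "recall"), function(mt) {
    data.frame(dataset = paste0(wide$generator, "_", wide$misclass_level,
                                "_r", wide$replicate),
               generator = wide$generator, misclass_level = wide$misclass_level,
               replicate = wide$replicate, scenario = wide$scenario,
               metric = mt, value = wide[[mt]],
               converged = wide$converged, stringsAsFactors = FALSE)
  }))
  metrics <- metrics[order(metrics$generator, metrics$misclass_level,
                           metrics$replicate, metrics$scenario, metrics$metric), ]
  keep <- metrics[metrics$converged & !is.na(metrics$value), ]
  summary_df <- do.call(rbind, lapply(
    split(keep, list(keep$generator, keep$misclass_level, keep$scenario,
                     keep$metric), drop = TRUE),
    function(g) data.frame(generator = g$generator[1],
                           misclass_level = g$misclass_level[1],
                           scenario = g$scenario[1], metric = g$metric[1],
                           n_converged = nrow(g),
                           median = median(g$value),
                           q25 = unname(quantile(g$value, 0.25)),
                           q75 = unname(quantile(g$value, 0.75)),
                           mean = mean(g$value), stringsAsFactors = FALSE)))
  rownames(summary_df) <- NULL
  convergence <- unique(wide[, c("generator", "misclass_level", "replicate",
                                 "scenario", "dataset_hash", "max_rhat",
                                 "converged", "selection_probability",
                                 "selection_probability_nu")])
  write.csv(metrics, file.path(cfg$output_dir, "metrics.csv"), row.names = FALSE)
  write.csv(summary_df, file.path(cfg$output_dir, "summary.csv"), row.names = FALSE)
  write.csv(convergence, file.path(cfg$output_dir, "convergence.csv"),
            row.names = FALSE)
  invisible(list(metrics = metrics, summary = summary_df,
                 convergence = convergence))
}
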