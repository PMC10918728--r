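# Shared fixtures: everything is generated in code at test time.

tiny_space <- function() state_space(2, 3)

# short-chain configuration for pipeline tests where speed matters more
# than posterior precision
quick_cfg <- function(...) {
  args <- modifyList(list(n_chains = 2, n_iter = 800, n_burnin = 400,
                          thin = 2, seed = 42), list(...))
  do.call(fit_config, args)
}

small_bundle <- function(seed = 1, n_sites = 300, n_withheld = 60,
                         generator = "full", misclass_level = "baseline") {
  simulate_dataset(simulation_design(n_sites = n_sites,
                                     n_withheld = n_withheld,
                                     generator = generator,
                                     misclass_level = misclass_level,
                                     seed = seed))
}

# independent scalar-by-scalar likelihood oracle: no shared code with
# joint_log_likelihood beyond the parameter containers
oracle_record_loglik <- function(rec, eco, cls) {
  x <- as.numeric(rec[grep("^x_", names(rec))])
  z <- as.numeric(rec[grep("^z_", names(rec))])
  lam <- exp(eco$beta0 + as.numeric(t(eco$beta) %*% x))
  p <- lam / sum(lam)
  J <- nrow(cls$omega0); K <- ncol(cls$omega0)
  Om <- matrix(0, J, K)
  for (j in seq_len(J)) {
    zeta <- numeric(K)
    for (k in seq_len(K)) {
      zeta[k] <- cls$omega0[j, k] +
        sum(cls$psi * z * cls$omega[, j, k])
    }
    Om[j, ] <- exp(zeta) / sum(exp(zeta))
  }
  if (!is.na(rec$v)) log(p[rec$v]) + log(Om[rec$v, rec$y])
  else log(sum(p * Om[, rec$y]))
}

# one-row occurrence record
make_record <- function(y, v = NA_integer_, x = c(0, 0), z = 0, id = "r1") {
  rec <- data.frame(id = id, site_id = id, y = y, v = v,
                    stringsAsFactors = FALSE)
  for (q in seq_along(x)) rec[[paste0("x_", q)]] <- x[q]
  for (p in seq_along(z)) rec[[paste0("z_", p)]] <- z[p]
  rec
}
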