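# Shared fixtures: the packaged synthetic "default organism" is the ground
# truth everywhere; random feasible cases are drawn by jittering its fitted
# parameters and sampling a light level, a sub-washout dilution rate, and a
# feed recipe.

fitted_names <- c("m", "v_I_max", "A_I", "A_Pho", "A_Bio", "Q_C_Pro_Other",
                  "Q_N_Sto_max", "Q_C_Other0", "A_RNA_P", "A_Pho_PChl",
                  "Q_P_Other0")

jitter_params <- function(base = model_params(), lo = 0.6, hi = 1.6) {
  p <- base
  for (nm in fitted_names) p[[nm]] <- base[[nm]] * runif(1, lo, hi)
  do.call(model_params, p[names(formals(model_params))])
}

# init-at-truth-times-uniform(0.5, 2) start for recovery experiments
recovery_init <- function(truth, which = fitted_names) {
  p <- truth
  for (nm in which) p[[nm]] <- truth[[nm]] * runif(1, 0.5, 2)
  do.call(model_params, p[names(formals(model_params))])
}

random_cases <- function(n, seed = 42) {
  set.seed(seed)
  base <- model_params()
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    p <- tryCatch(jitter_params(base), phytoalloc_error = function(e) NULL)
    if (is.null(p)) next
    I <- runif(1, 10, 400)
    mm <- tryCatch(mu_max(I, p), phytoalloc_error = function(e) NULL)
    if (is.null(mm)) next
    mu <- runif(1, 0.02, 0.95) * mm
    # the empirical total-P cap must leave room for the functional P quota,
    # otherwise the parameter set is internally inconsistent at this mu
    if (p_to_c(mu, I, p, check = FALSE) > 0.95 * p$Q_P_max) next
    i <- i + 1L
    out[[i]] <- list(
      params = p, I = I, mu = mu, mu_max = mm,
      env = chemostat_env(I, N_in = runif(1, 0.05, 0.5),
                          P_in = runif(1, 0.005, 0.05), D = mu)
    )
  }
  out
}
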