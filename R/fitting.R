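# Staged Metropolis-Hastings calibration.
#
# The error function is a sigma-scaled sum of squared residuals per
# dataset, normalized by each dataset's observation count so that curves
# with many points do not dominate. Proposals perturb every free
# parameter of the active stage jointly by independent uniform
# multiplicative factors in [1 - s, 1 + s]; out-of-bounds proposals are
# rejected whole and counted as non-accepted steps. Acceptance follows
# the likelihood ratio exp(-(Error_new - Error_current)) compared with a
# uniform random number, so the chain is an optimizer that can still
# escape local minima. Three stages mirror the structure of the model:
# chlorophyll parameters are identified by Chl:C alone, nitrogen/carbon
# parameters by N:C, N-limited biomass and the light-dependent maximum
# growth rate, and phosphorus parameters by P-limited biomass and P:C.

#' Sigma-scaled squared error of one dataset
#'
#' `Error_k = sum_i (data_i - model_i)^2 / (2 sigma_k^2)`.
#'
#' @param data_k One dataset: a data frame in the observation schema
#'   (columns `variable`, `light`, `mu`, `value`, `limitation`, `N_in`,
#'   `P_in`, `sigma`; `sigma` constant within the dataset).
#' @param params A [model_params()] object.
#' @param ratios A [stoich_ratios()] object.
#' @param forward Model evaluator: `function(params, rows)` returning
#'   model values for the rows. Defaults to [predict_observations()].
#' @return Dimensionless error (scalar).
#' @export
dataset_error <- function(params, data_k, ratios = default_ratios(),
                          forward = NULL) {
  sigma <- unique(data_k$sigma)
  if (length(sigma) != 1L || sigma <= 0) {
    abort_domain("each dataset must carry a single sigma > 0")
  }
  model <- if (is.null(forward)) {
    predict_observations(params, data_k, ratios)
  } else {
    forward(params, data_k)
  }
  sum((data_k$value - model)^2) / (2 * sigma^2)
}

#' Combine per-dataset errors, weighting by observation counts
#'
#' `Error = sum_k Error_k / n_k`: each dataset's error is divided by its
#' number of observations so datasets of different sizes carry similar
#' weight.
#'
#' @param per_dataset_errors Numeric vector of dataset errors.
#' @param n_k Matching observation counts (>= 1).
#' @return Total dimensionless error.
#' @export
total_error <- function(per_dataset_errors, n_k) {
  if (any(n_k < 1)) abort_domain("n_k must be >= 1")
  sum(per_dataset_errors / n_k)
}

#' Forward-model predictions for observation rows
#'
#' Evaluates the steady-state model for each row of an observation table,
#' using the row's limitation label and feed concentrations: Chl:C from
#' the linear law; N:C and P:C from the closed quadratic forms, with the
#' capped storage of the non-limiting element added when the label says
#' the other element limits; biomass as feed over non-storage quota; and
#' `mu_max` rows from the carbon-closure root at the row's light level.
#'
#' @param params A [model_params()] object.
#' @param rows Observation rows (see [generate_dataset()] for the schema).
#' @param ratios A [stoich_ratios()] object.
#' @return Numeric vector of model values; `NA` where the parameter set is
#'   infeasible (no positive maximum growth rate, or washout at the row's
#'   dilution rate).
#' @export
predict_observations <- function(params, rows, ratios = default_ratios()) {
  f <- .make_objective(rows, params, active = character(),
                       ratios = ratios, return_model = TRUE)
  f(numeric(0))
}

# Compile an observation table into a fast objective closure.
# `active` names the free parameters; the closure takes their values as a
# numeric vector. With return_model = TRUE it returns the model vector
# (NA on infeasibility) instead of the error.
.make_objective <- function(rows, base_params, active,
                            ratios = default_ratios(), penalty = 1e6,
                            return_model = FALSE) {
  n <- nrow(rows)
  I <- rows$light
  mu <- rows$mu
  obs <- rows$value
  w <- if (all(c("sigma", "dataset_id") %in% names(rows))) {
    n_k <- table(rows$dataset_id)
    1 / (2 * rows$sigma^2 * as.numeric(n_k[rows$dataset_id]))
  }
  is_mm <- rows$variable == "mu_max"
  is_chl <- rows$variable == "chl_to_c"
  is_nc_N <- rows$variable == "n_to_c" & rows$limitation == "N"
  is_nc_P <- rows$variable == "n_to_c" & rows$limitation == "P"
  is_pc_P <- rows$variable == "p_to_c" & rows$limitation == "P"
  is_pc_N <- rows$variable == "p_to_c" & rows$limitation == "N"
  is_bm_N <- rows$variable == "biomass" & rows$limitation == "N"
  is_bm_P <- rows$variable == "biomass" & rows$limitation == "P"
  Nin <- rows$N_in
  Pin <- rows$P_in
  p <- unclass(base_params)
  Y <- ratios

  function(theta) {
    p[active] <- theta
    v_I <- p$v_I_max * (1 - exp(-p$A_I * I))
    A <- (1 + p$E) / v_I
    B <- p$m / v_I
    pro_slope <- p$A_Bio + p$A_Pho * A
    pro_int <- p$A_Pho * B + p$Q_C_Pro_Other
    # closed-form coefficients (same algebra as nc/pc/mu_max_coefficients,
    # inlined for speed inside the chain)
    a_N <- Y$Y_RNA_NP * p$A_RNA_P * pro_slope
    b_N <- Y$Y_Chl_NC * A + Y$Y_Pro_NC * pro_slope +
      Y$Y_RNA_NP * p$A_RNA_P * pro_int
    c_N <- Y$Y_Chl_NC * B + Y$Y_Pro_NC * pro_int +
      Y$Y_RNA_NP * p$Q_P_min_RNA + Y$Y_DNA_NC * p$Q_C_DNA
    a_P <- p$A_RNA_P * pro_slope
    b_P <- p$A_RNA_P * pro_int + p$A_Pho_PChl * A
    c_P <- p$Q_P_min_RNA + Y$Y_DNA_PC * p$Q_C_DNA + p$A_Pho_PChl * B +
      p$Q_P_Other0
    thyla <- 1 + p$A_Pho + Y$Y_Plip_CP * p$A_Pho_PChl
    a_M <- Y$Y_RNA_CP * p$A_RNA_P * (p$A_Pho * A + p$A_Bio)
    b_M <- thyla * A + p$A_Bio +
      Y$Y_RNA_CP * p$A_RNA_P * (p$A_Pho * B + p$Q_C_Pro_Other)
    c_M <- thyla * B + p$Q_C_Pro_Other + p$Q_C_DNA + p$Q_C_Other0 +
      Y$Y_RNA_CP * p$Q_P_min_RNA - 1
    # feasibility only matters where the mu_max root itself is the model:
    # the quota and biomass curves are algebraic in mu, and stage-wise
    # fitting must not punish the active parameters for the provisional
    # values of parameters fitted in a later stage
    if (!return_model && any(c_M[is_mm] >= 0)) return(penalty)
    mm <- rep(NA_real_, n)
    root_ok <- c_M < 0
    mm[root_ok] <- -2 * c_M[root_ok] /
      (b_M[root_ok] + sqrt(b_M[root_ok]^2 - 4 * a_M[root_ok] * c_M[root_ok]))
    qn <- a_N * mu^2 + b_N * mu + c_N
    qp <- a_P * mu^2 + b_P * mu + c_P
    model <- numeric(n)
    model[is_mm] <- mm[is_mm]
    model[is_chl] <- A[is_chl] * mu[is_chl] + B[is_chl]
    model[is_nc_N] <- qn[is_nc_N]
    # available carbon for cyanophycin: the zero-storage C-storage pool,
    # which is minus the carbon-closure quadratic
    csto_avail <- pmax(-(a_M * mu^2 + b_M * mu + c_M), 0)
    model[is_nc_P] <- pmax(
      pmin(Nin[is_nc_P] * qp[is_nc_P] / Pin[is_nc_P],
           qn[is_nc_P] + p$Q_N_Sto_max,
           qn[is_nc_P] + csto_avail[is_nc_P] / Y$Y_Nsto_CN),
      qn[is_nc_P])
    model[is_pc_P] <- qp[is_pc_P]
    model[is_pc_N] <- pmax(
      pmin(Pin[is_pc_N] * qn[is_pc_N] / Nin[is_pc_N], p$Q_P_max),
      qp[is_pc_N])
    model[is_bm_N] <- Nin[is_bm_N] / qn[is_bm_N]
    model[is_bm_P] <- Pin[is_bm_P] / qp[is_bm_P]
    if (return_model) {
      model[!is_mm & (!root_ok | mu > mm)] <- NA_real_
      model[is_mm & !root_ok] <- NA_real_
      return(model)
    }
    sum((obs - model)^2 * w)
  }
}

#' One Metropolis-Hastings step
#'
#' Perturbs every free parameter jointly by an independent uniform
#' multiplicative factor in `[1 - s, 1 + s]`. A proposal outside the
#' bounds is rejected outright (a non-accepted step). Otherwise it is
#' accepted with probability `min(1, exp(-(error_new - error_current)))`,
#' decided against a uniform random number.
#'
#' @param current List with `params` (named numeric vector of the free
#'   parameters) and `error` (its objective value).
#' @param objective `function(theta) -> error`.
#' @param proposal_scale Half-width `s` of the multiplicative perturbation
#'   (default 0.2).
#' @param lower,upper Bound vectors (proposals must satisfy
#'   `lower < theta <= upper`).
#' @return List with `params`, `error`, `accepted`.
#' @export
mh_step <- function(current, objective, proposal_scale = 0.2,
                    lower = 0, upper = Inf) {
  k <- length(current$params)
  fac <- stats::runif(k, 1 - proposal_scale, 1 + proposal_scale)
  prop <- current$params * fac
  if (any(prop <= lower) || any(prop > upper)) {
    return(list(params = current$params, error = current$error,
                accepted = FALSE))
  }
  err <- objective(prop)
  ratio <- exp(current$error - err)
  if (ratio > stats::runif(1)) {
    list(params = prop, error = err, accepted = TRUE)
  } else {
    list(params = current$params, error = current$error, accepted = FALSE)
  }
}

# Chain runner used by staged_fit. Returns chain matrix of current state
# per step, error trace, best state, acceptance rate.
.mh_run <- function(objective, init, steps, proposal_scale, lower, upper) {
  cur <- list(params = init, error = objective(init))
  best <- cur
  k <- length(init)
  chain <- matrix(NA_real_, nrow = steps, ncol = k,
                  dimnames = list(NULL, names(init)))
  errors <- numeric(steps)
  accepted <- logical(steps)
  for (j in seq_len(steps)) {
    cur <- mh_step(cur, objective, proposal_scale, lower, upper)
    accepted[j] <- cur$accepted
    chain[j, ] <- cur$params
    errors[j] <- cur$error
    if (cur$error < best$error) best <- cur
  }
  list(chain = chain, errors = errors, best = best,
       acceptance_rate = mean(accepted))
}

#' Fitting configuration
#'
#' @param steps Metropolis-Hastings steps per stage. The desk-scale
#'   default is 2e4; production calibrations use 1e6.
#' @param proposal_scale Multiplicative proposal half-width (default 0.2).
#' @param seed Integer seed; all chain randomness flows from it.
#' @param chl_bound_factor Upper bounds on the chlorophyll-related
#'   parameters (`m`, `v_I_max`, `A_I`) as a multiple of their initial
#'   values (default 5).
#' @param penalty Finite error assigned to infeasible parameter sets so
#'   the chain can move away from them.
#' @param stages Optional list of stage definitions; each a list with
#'   `params` (names to free) and `filter` (`function(data) -> logical`
#'   row mask). Defaults to the three-stage schedule described in
#'   [staged_fit()].
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(steps = 2e4, proposal_scale = 0.2, seed = 1L,
                       chl_bound_factor = 5, penalty = 1e6, stages = NULL) {
  structure(list(steps = steps, proposal_scale = proposal_scale,
                 seed = as.integer(seed), chl_bound_factor = chl_bound_factor,
                 penalty = penalty, stages = stages),
            class = "fit_config")
}

.default_stages <- function() {
  list(
    chlorophyll = list(
      params = c("m", "v_I_max", "A_I"),
      filter = function(d) d$variable == "chl_to_c"
    ),
    nitrogen_carbon = list(
      params = c("A_Pho", "A_Bio", "Q_C_Pro_Other", "Q_N_Sto_max",
                 "Q_C_Other0"),
      filter = function(d) {
        d$variable == "n_to_c" |
          (d$variable == "biomass" & d$limitation == "N") |
          d$variable == "mu_max"
      }
    ),
    phosphorus = list(
      params = c("A_RNA_P", "A_Pho_PChl", "Q_P_Other0"),
      filter = function(d) {
        d$variable %in% c("biomass", "p_to_c") & d$limitation == "P"
      }
    )
  )
}

#' Staged Metropolis-Hastings calibration of the 11 free parameters
#'
#' Stage 1 fits the chlorophyll parameters (`m`, `v_I_max`, `A_I`) to
#' Chl:C vs. growth rate across light levels. Stage 2, holding those
#' fixed, fits (`A_Pho`, `A_Bio`, `Q_C_Pro_Other`, `Q_N_Sto_max`,
#' `Q_C_Other0`) to N:C under both limitations, N-limited biomass, and
#' the maximum growth rate vs. light. Stage 3 fits (`A_RNA_P`,
#' `A_Pho_PChl`, `Q_P_Other0`) to P-limited biomass and P:C. Each stage's
#' best parameters are frozen into the working set before the next stage.
#'
#' @param data Observation table (schema of [generate_dataset()]).
#' @param init_params A [model_params()] object giving the starting values
#'   of all parameters (fitted and fixed).
#' @param ratios A [stoich_ratios()] object.
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: `best_params` (full
#'   `model_params`), `best_error` (final-stage best), `stages` (per-stage
#'   chains, error traces, acceptance rates), `seed`.
#' @export
staged_fit <- function(data, init_params, ratios = default_ratios(),
                       config = fit_config()) {
  stages <- config$stages %||% .default_stages()
  need_vars <- "chl_to_c"
  if (!all(need_vars %in% data$variable) ||
      length(unique(data$light[data$variable == "chl_to_c"])) < 2) {
    abort_domain("data must contain chl_to_c observations at >= 2 light levels")
  }
  set.seed(config$seed)
  working <- init_params
  stage_results <- list()
  best_error <- NA_real_
  for (stage_name in names(stages)) {
    stage <- stages[[stage_name]]
    rows <- data[stage$filter(data), , drop = FALSE]
    if (nrow(rows) == 0L) {
      abort_domain(paste0("no observations for stage '", stage_name, "'"))
    }
    active <- stage$params
    objective <- .make_objective(rows, working, active, ratios,
                                 penalty = config$penalty)
    init <- unlist(working[active])
    upper <- rep(Inf, length(active))
    chl <- active %in% c("m", "v_I_max", "A_I")
    upper[chl] <- config$chl_bound_factor * init[chl]
    run <- .mh_run(objective, init, steps = config$steps,
                   proposal_scale = config$proposal_scale,
                   lower = rep(0, length(active)), upper = upper)
    working <- do.call(update_params,
                       c(list(working), as.list(run$best$params)))
    best_error <- run$best$error
    stage_results[[stage_name]] <- list(
      params = active,
      chain = run$chain,
      errors = run$errors,
      best = run$best,
      acceptance_rate = run$acceptance_rate,
      n_obs = nrow(rows)
    )
  }
  structure(list(best_params = working, best_error = best_error,
                 stages = stage_results, seed = config$seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Staged Metropolis-Hastings fit (seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  stage %-16s %d steps, acceptance %.2f, best error %.4g\n",
                nm, length(s$errors), s$acceptance_rate, s$best$error))
  }
  cat("Best parameters:\n")
  fitted <- x$best_params[FITTED_PARAM_NAMES]
  for (nm in names(fitted)) cat(sprintf("  %-14s %.6g\n", nm, fitted[[nm]]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
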