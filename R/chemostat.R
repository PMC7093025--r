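# Culture-level steady state.
#
# At steady state in a chemostat the growth rate equals the dilution rate.
# Biomass follows from the feed concentration of the limiting element
# divided by its non-storage quota (the residual dissolved nutrient is
# negligible relative to the feed). The non-limiting element is taken up
# in excess and stored -- polyphosphate (no carbon) for P, cyanophycin for
# N -- up to an empirical cap, and whatever carbon is left after all other
# pools closes the budget as carbon storage.

#' Chemostat environment
#'
#' @param I Irradiance (umol photons m^-2 s^-1).
#' @param N_in Dissolved inorganic nitrogen in the feed (mol m^-3).
#' @param P_in Dissolved inorganic phosphorus in the feed (mol m^-3).
#' @param D Dilution rate (d^-1); equals the growth rate at steady state.
#' @return An object of class `chemostat_env`.
#' @export
chemostat_env <- function(I, N_in, P_in, D) {
  vals <- c(I = I, N_in = N_in, P_in = P_in, D = D)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort_domain("environment fields must be finite and nonnegative")
  }
  structure(list(I = I, N_in = N_in, P_in = P_in, D = D),
            class = "chemostat_env")
}

#' Steady-state biomass if a given element limits
#'
#' `[C_Cell] = feed concentration / non-storage quota` of the limiting
#' element, using uptake = growth x quota at steady state and the
#' approximation that the residual dissolved nutrient is small relative to
#' the feed.
#'
#' @param element `"N"` or `"P"`.
#' @param env A [chemostat_env()].
#' @param q_nonsto Non-storage quota of that element (mol (mol C)^-1).
#' @return Biomass carbon concentration, mol C m^-3.
#' @export
biomass_if_limited <- function(element = c("N", "P"), env, q_nonsto) {
  element <- match.arg(element)
  if (any(q_nonsto <= 0)) abort_domain("non-storage quota must be > 0")
  feed <- if (element == "N") env$N_in else env$P_in
  feed / q_nonsto
}

#' Determine the limiting element
#'
#' The culture is N-limited iff the feed N:P is below the required
#' (non-storage) N:P -- equivalently, iff N-limited biomass would be the
#' smaller of the two. A feed ratio exactly equal to the required ratio is
#' classified N-limited (fixed tie-break).
#'
#' @param env A [chemostat_env()].
#' @param q_n_nonsto,q_p_nonsto Non-storage N and P quotas (mol (mol C)^-1).
#' @return `"N"` or `"P"` (vectorized over the quotas).
#' @export
determine_limitation <- function(env, q_n_nonsto, q_p_nonsto) {
  if (any(q_n_nonsto <= 0) || any(q_p_nonsto <= 0)) {
    abort_domain("quotas must be > 0")
  }
  if (env$N_in == 0 && env$P_in == 0) {
    abort_domain("degenerate feed: N_in and P_in are both zero")
  }
  # cross-multiplied form of N_in/P_in < q_n/q_p; safe when P_in = 0
  ifelse(env$N_in * q_p_nonsto <= env$P_in * q_n_nonsto, "N", "P")
}

# Build the cell-level pools (no storage yet) for one (mu, I).
.base_pools <- function(mu, I, params, ratios) {
  Q_C_Chl <- chl_to_c(mu, I, params)
  # protein must be assembled before the RNA rule (RNA-P depends on it)
  Q_C_Pro_Pho <- params$A_Pho * Q_C_Chl
  Q_C_Pro_Bio <- params$A_Bio * mu
  Q_C_Pro <- Q_C_Pro_Pho + Q_C_Pro_Bio + params$Q_C_Pro_Other
  al <- allocation_rules(mu, Q_C_Chl, Q_C_Pro, params, ratios)
  list(
    Q_C_Chl = Q_C_Chl,
    Q_C_Pro_Pho = Q_C_Pro_Pho,
    Q_C_Pro_Bio = Q_C_Pro_Bio,
    Q_C_Pro_Other = params$Q_C_Pro_Other,
    Q_C_Pro = Q_C_Pro,
    Q_C_RNA = al$Q_C_RNA,
    Q_C_DNA = params$Q_C_DNA,
    Q_C_Plip_Thy = al$Q_C_Plip_Thy,
    Q_C_Other0 = params$Q_C_Other0,
    Q_P_RNA = al$Q_P_RNA,
    Q_P_DNA = ratios$Y_DNA_PC * params$Q_C_DNA,
    Q_P_Thy = al$Q_P_Thy,
    Q_P_Other0 = params$Q_P_Other0,
    Q_N_Chl = ratios$Y_Chl_NC * Q_C_Chl,
    Q_N_Pro = ratios$Y_Pro_NC * Q_C_Pro,
    Q_N_RNA = ratios$Y_RNA_NP * al$Q_P_RNA,
    Q_N_DNA = ratios$Y_DNA_NC * params$Q_C_DNA
  )
}

#' Build an allocation state for one growth condition
#'
#' Assembles every carbon, nitrogen, and phosphorus pool for a cell
#' growing at rate `mu` under irradiance `I`, with storage quotas supplied
#' explicitly (zero by default; [solve_culture()] fills them from the
#' feed). The carbon budget is closed so the carbon pools sum to exactly 1.
#'
#' @param mu Growth rate (d^-1).
#' @param I Irradiance (umol photons m^-2 s^-1).
#' @param params A [model_params()] object.
#' @param ratios A [stoich_ratios()] object.
#' @param Q_N_Sto,Q_P_Sto Storage quotas of N and P (mol (mol C)^-1).
#' @param limitation `"N"` or `"P"` label carried on the state.
#' @return An object of class `allocation_state`: a list with `mu`, `I`,
#'   `limitation`, named vectors `q_c`, `q_n`, `q_p`, and the scalars
#'   `n_to_c`, `p_to_c`, `n_to_p`.
#' @export
allocation_state <- function(mu, I, params, ratios = default_ratios(),
                             Q_N_Sto = 0, Q_P_Sto = 0, limitation = "N") {
  if (Q_N_Sto < 0 || Q_P_Sto < 0) abort_domain("storage quotas must be >= 0")
  pools <- .base_pools(mu, I, params, ratios)
  Q_C_Nsto <- ratios$Y_Nsto_CN * Q_N_Sto
  q_c <- c(
    Chl = pools$Q_C_Chl, Pro_Pho = pools$Q_C_Pro_Pho,
    Pro_Bio = pools$Q_C_Pro_Bio, Pro_Other = pools$Q_C_Pro_Other,
    RNA = pools$Q_C_RNA, DNA = pools$Q_C_DNA,
    Plip_Thy = pools$Q_C_Plip_Thy, Nsto = Q_C_Nsto,
    Other0 = pools$Q_C_Other0
  )
  state <- structure(list(
    mu = mu, I = I, limitation = limitation,
    q_c = c(q_c, Csto = NA_real_),
    q_n = c(Chl = pools$Q_N_Chl, Pro = pools$Q_N_Pro, RNA = pools$Q_N_RNA,
            DNA = pools$Q_N_DNA, Sto = Q_N_Sto),
    q_p = c(RNA = pools$Q_P_RNA, DNA = pools$Q_P_DNA, Thy = pools$Q_P_Thy,
            Sto = Q_P_Sto, Other0 = params$Q_P_Other0)
  ), class = "allocation_state")
  close_carbon(state)
}

#' Close the carbon budget of an allocation state
#'
#' Sets the carbon-storage pool to one minus the sum of all other carbon
#' pools, so the pools sum to exactly 1. A negative closure beyond
#' tolerance means the growth rate is infeasible (above the light-limited
#' maximum) and raises a `phytoalloc_infeasible_error`.
#'
#' @param state An `allocation_state` with all non-storage carbon pools set.
#' @param tol Negative-closure tolerance.
#' @return The state with `q_c["Csto"]` filled.
#' @export
close_carbon <- function(state, tol = 1e-9) {
  others <- state$q_c[setdiff(names(state$q_c), "Csto")]
  csto <- 1 - sum(others)
  if (csto < -tol) {
    abort_infeasible(sprintf(
      "carbon over-allocated by %.3g at mu = %.4g, I = %.4g (mu exceeds mu_max?)",
      -csto, state$mu, state$I))
  }
  state$q_c[["Csto"]] <- max(csto, 0)
  state$n_to_c <- sum(state$q_n)
  state$p_to_c <- sum(state$q_p)
  state$n_to_p <- state$n_to_c / state$p_to_c
  state
}

#' Fill luxury storage of the non-limiting element
#'
#' Under N limitation the excess phosphorus that the biomass could take up,
#' `Q_P_pot = P_in / [C_Cell]_N`, is stored up to the cap on *total* P
#' (`Q_P_max`); under P limitation the excess nitrogen is stored up to
#' `Q_N_Sto_max` *above* the non-storage quota. Nitrogen storage carries
#' carbon at the storage-polymer C:N, so it is additionally capped by the
#' carbon left over after all functional pools -- a cap that tightens to
#' zero as the growth rate approaches the light-limited maximum, keeping
#' every pool nonnegative.
#'
#' @param env A [chemostat_env()].
#' @param state An `allocation_state` with `limitation` already set and
#'   zero storage.
#' @param params,ratios Model parameters and conversion constants.
#' @return The state with storage quotas filled and carbon re-closed.
#' @export
apply_storage <- function(env, state, params, ratios = default_ratios()) {
  q_n_nonsto <- sum(state$q_n) - state$q_n[["Sto"]]
  q_p_nonsto <- sum(state$q_p) - state$q_p[["Sto"]]
  if (state$limitation == "N") {
    biomass <- biomass_if_limited("N", env, q_n_nonsto)
    q_p_pot <- env$P_in / biomass
    q_p <- min(q_p_pot, params$Q_P_max)
    q_p_sto <- q_p - q_p_nonsto
    if (q_p_sto < -1e-12) {
      abort_infeasible(sprintf(
        "feed P cannot supply even the non-storage P quota (deficit %.3g)",
        -q_p_sto))
    }
    state$q_p[["Sto"]] <- max(q_p_sto, 0)
  } else {
    biomass <- biomass_if_limited("P", env, q_p_nonsto)
    q_n_pot <- env$N_in / biomass
    q_n_max <- params$Q_N_Sto_max + q_n_nonsto
    # carbon left after the functional pools bounds the cyanophycin pool
    csto_avail <- 1 - sum(state$q_c[setdiff(names(state$q_c),
                                            c("Nsto", "Csto"))])
    q_n_max <- min(q_n_max, q_n_nonsto + max(csto_avail, 0) / ratios$Y_Nsto_CN)
    q_n <- min(q_n_pot, q_n_max)
    q_n_sto <- q_n - q_n_nonsto
    if (q_n_sto < -1e-12) {
      abort_infeasible(sprintf(
        "feed N cannot supply even the non-storage N quota (deficit %.3g)",
        -q_n_sto))
    }
    state$q_n[["Sto"]] <- max(q_n_sto, 0)
    state$q_c[["Nsto"]] <- ratios$Y_Nsto_CN * state$q_n[["Sto"]]
  }
  close_carbon(state)
}

#' Solve one chemostat culture at steady state
#'
#' Orchestrates the full pipeline for a single environment: growth rate
#' equals dilution rate, cell-level quotas from the closed forms,
#' limiting-element determination from feed vs. required N:P, luxury
#' storage of the non-limiting element, carbon closure, and biomass.
#'
#' @param env A [chemostat_env()].
#' @param params A [model_params()] object.
#' @param ratios A [stoich_ratios()] object.
#' @return A list with `state` (an `allocation_state`) and `biomass`
#'   (mol C m^-3).
#' @section Errors: `phytoalloc_washout_error` when `D > mu_max(I)` (the
#'   condition carries `mu_max`); infeasibility errors propagate.
#' @export
solve_culture <- function(env, params, ratios = default_ratios()) {
  mm <- mu_max(env$I, params, ratios)
  if (env$D > mm) abort_washout(env$D, mm)
  mu <- env$D
  q_n_nonsto <- n_to_c(mu, env$I, params, ratios, check = FALSE)
  q_p_nonsto <- p_to_c(mu, env$I, params, ratios, check = FALSE)
  lim <- determine_limitation(env, q_n_nonsto, q_p_nonsto)
  state <- allocation_state(mu, env$I, params, ratios, limitation = lim)
  state <- apply_storage(env, state, params, ratios)
  biomass <- if (lim == "N") {
    biomass_if_limited("N", env, q_n_nonsto)
  } else {
    biomass_if_limited("P", env, q_p_nonsto)
  }
  list(state = state, biomass = biomass)
}

#' @export
print.allocation_state <- function(x, ...) {
  cat(sprintf("Allocation state: mu = %.4g d^-1, I = %.4g, %s-limited\n",
              x$mu, x$I, x$limitation))
  cat(sprintf("  N:C = %.4g  P:C = %.4g  N:P = %.4g\n",
              x$n_to_c, x$p_to_c, x$n_to_p))
  cat("  C pools (sum = 1):\n")
  print(round(x$q_c, 5))
  invisible(x)
}

#' Batch-evaluate chemostat cultures over a table of environments
#'
#' Solves one culture per row. Washout rows (`D > mu_max(I)`) are flagged,
#' not dropped, mirroring how experimental dilution series report washed
#' out vessels.
#'
#' @param envs Data frame with columns `I`, `D`, `N_in`, `P_in`.
#' @param params,ratios Model parameters and conversion constants.
#' @return A tibble: the input columns plus `washout`, `limitation`,
#'   `chl_to_c`, `n_to_c`, `p_to_c`, `n_to_p`, `biomass`, `q_c_csto`,
#'   `q_n_sto`, `q_p_sto`.
#' @export
simulate_chemostat <- function(envs, params, ratios = default_ratios()) {
  need <- c("I", "D", "N_in", "P_in")
  missing_cols <- setdiff(need, names(envs))
  if (length(missing_cols)) {
    abort_domain(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(envs)
  out <- tibble::tibble(
    I = envs$I, D = envs$D, N_in = envs$N_in, P_in = envs$P_in,
    washout = FALSE, limitation = NA_character_,
    chl_to_c = NA_real_, n_to_c = NA_real_, p_to_c = NA_real_,
    n_to_p = NA_real_, biomass = NA_real_,
    q_c_csto = NA_real_, q_n_sto = NA_real_, q_p_sto = NA_real_
  )
  for (i in seq_len(n)) {
    env <- chemostat_env(envs$I[i], envs$N_in[i], envs$P_in[i], envs$D[i])
    sol <- tryCatch(solve_culture(env, params, ratios),
                    phytoalloc_washout_error = function(e) e)
    if (inherits(sol, "phytoalloc_washout_error")) {
      out$washout[i] <- TRUE
      next
    }
    st <- sol$state
    out$limitation[i] <- st$limitation
    out$chl_to_c[i] <- st$q_c[["Chl"]]
    out$n_to_c[i] <- st$n_to_c
    out$p_to_c[i] <- st$p_to_c
    out$n_to_p[i] <- st$n_to_p
    out$biomass[i] <- sol$biomass
    out$q_c_csto[i] <- st$q_c[["Csto"]]
    out$q_n_sto[i] <- st$q_n[["Sto"]]
    out$q_p_sto[i] <- st$q_p[["Sto"]]
  }
  out
}
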