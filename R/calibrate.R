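## observation variables and the simulation columns they correspond to
OBS_VARIABLES <- c(root_dm = "w_so", leaf_dm = "w_leaf", stem_dm = "w_stem",
                   uptake_N = "act_N", uptake_P = "act_P", uptake_K = "act_K")

#' Root mean square error
#'
#' @param observed,simulated numeric vectors of equal length >= 1.
#' @return `sqrt(mean((observed - simulated)^2))`, in the input units.
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(12.5)
#' @export
rmse <- function(observed, simulated) {
  if (!length(observed) || length(observed) != length(simulated))
    stop("observed and simulated must be equal-length, non-empty vectors")
  sqrt(mean((observed - simulated)^2))
}

#' Read an observation set
#'
#' CSV with columns `treatment`, `dap`, `variable`, `value` and optional
#' `sd`. Variables: `root_dm`, `leaf_dm`, `stem_dm`, `uptake_N`,
#' `uptake_P`, `uptake_K`. Values in g m^-2 (or kg ha^-1 with
#' `units = "kg_ha"`).
#'
#' @param path CSV file path.
#' @param units `"g_m2"` or `"kg_ha"`.
#' @return data.frame observation set.
#' @export
readObservations <- function(path, units = c("g_m2", "kg_ha")) {
  units <- match.arg(units)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("treatment", "dap", "variable", "value")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observations missing column(s): ", paste(miss, collapse = ", "))
  if (!"sd" %in% names(obs)) obs$sd <- NA_real_
  if (units == "kg_ha") {
    obs$value <- kgPerHaToGPerM2(obs$value)
    obs$sd <- kgPerHaToGPerM2(obs$sd)
  }
  validateObservations(obs)
  obs
}

validateObservations <- function(obs) {
  bad <- setdiff(unique(obs$variable), names(OBS_VARIABLES))
  if (length(bad))
    stop("unknown observation variable(s): ", paste(bad, collapse = ", "))
  if (any(obs$value < 0)) stop("observation values must be >= 0")
  key <- paste(obs$treatment, obs$dap, obs$variable)
  if (anyDuplicated(key))
    stop("duplicate (treatment, dap, variable) observation: ",
         key[duplicated(key)][1])
  invisible(obs)
}

#' Generate synthetic observations from the simulator
#'
#' Runs the model for each treatment scenario, samples the observation
#' variables at the given days after planting, and adds multiplicative
#' lognormal noise with the given coefficient of variation (mean-one, so
#' expectations are unbiased). A stand-in for field data in calibration
#' and recovery experiments.
#'
#' @param params a `cassava_params`.
#' @param scenarios named list of `cassava_scenario` (one per treatment).
#' @param sample_days observation days after planting (default roughly 4,
#'   8 and 14 months).
#' @param variables which observation variables to record.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = exact simulator output).
#' @param seed RNG seed; the same seed reproduces the same observations.
#' @return observation data.frame (`treatment`, `dap`, `variable`,
#'   `value`, `sd`).
#' @export
syntheticObservations <- function(params, scenarios,
                                  sample_days = c(120, 240, 420),
                                  variables = c("root_dm", "uptake_N",
                                                "uptake_P", "uptake_K"),
                                  noise_cv = 0, seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  variables <- match.arg(variables, names(OBS_VARIABLES), several.ok = TRUE)
  rows <- lapply(names(scenarios), function(tr) {
    sim <- runSimulation(params, scenarios[[tr]])
    h <- harvestRecords(sim, sample_days)
    do.call(rbind, lapply(variables, function(v)
      data.frame(treatment = tr, dap = h$day,
                 variable = v, value = h[[OBS_VARIABLES[[v]]]])))
  })
  obs <- do.call(rbind, rows)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    obs$value <- withSeed(seed, {
      obs$value * stats::rlnorm(nrow(obs), -sdlog^2 / 2, sdlog)
    })
  }
  obs$sd <- noise_cv * obs$value
  rownames(obs) <- NULL
  obs
}

#' Evaluate simulations against observations
#'
#' Matches simulated values to observations by (treatment, day, variable)
#' and reports, per variable, the root mean square error of prediction,
#' the coefficient of determination and the slope of the ordinary
#' least-squares regression of simulated on observed values (a slope near
#' 1 indicates an unbiased model). Treatments used to derive soil supply
#' inputs can be excluded from the pairing.
#'
#' @param sims named list of `cassava_sim` (one per treatment).
#' @param observations an observation data.frame.
#' @param exclude character vector of treatment names to drop (e.g. the
#'   control and single-omission treatments).
#' @return data.frame with columns `variable`, `n`, `rmsep`, `r2`,
#'   `slope`.
#' @export
evaluateSim <- function(sims, observations, exclude = character()) {
  obs <- observations[!observations$treatment %in% exclude, , drop = FALSE]
  obs <- obs[obs$treatment %in% names(sims), , drop = FALSE]
  if (!nrow(obs)) stop("no matched observation/simulation pairs")
  obs$sim <- mapply(function(tr, dap, v) {
    s <- sims[[tr]]
    i <- match(dap, s$day)
    if (is.na(i)) NA_real_ else s[[OBS_VARIABLES[[v]]]][i]
  }, obs$treatment, obs$dap, obs$variable)
  obs <- obs[is.finite(obs$sim), , drop = FALSE]
  if (!nrow(obs)) stop("no matched observation/simulation pairs")
  out <- do.call(rbind, lapply(split(obs, obs$variable), function(s) {
    if (nrow(s) < 2)
      return(data.frame(variable = s$variable[1], n = nrow(s),
                        rmsep = rmse(s$value, s$sim),
                        r2 = NA_real_, slope = NA_real_))
    fit <- stats::lm(sim ~ value, data = s)
    data.frame(variable = s$variable[1], n = nrow(s),
               rmsep = rmse(s$value, s$sim),
               r2 = stats::cor(s$value, s$sim)^2,
               slope = unname(stats::coef(fit)[2]))
  }))
  rownames(out) <- NULL
  out
}

## mean-normalized multi-variable RMSE calibration objective
calibrationObjective <- function(theta, params, scenarios, observations) {
  params$npk$K_NI <- theta[[1]]
  params$npk$KMAX <- theta[[2]]
  params$npk$TSUM_NPKI <- theta[[3]]
  sims <- tryCatch(
    lapply(scenarios, function(sc) runSimulation(params, sc)),
    error = function(e) NULL)
  if (is.null(sims)) return(Inf)
  obs <- observations
  obs$sim <- mapply(function(tr, dap, v) {
    s <- sims[[tr]]
    i <- match(dap, s$day)
    if (is.na(i)) NA_real_ else s[[OBS_VARIABLES[[v]]]][i]
  }, obs$treatment, obs$dap, obs$variable)
  obs <- obs[is.finite(obs$sim), , drop = FALSE]
  if (!nrow(obs)) return(Inf)
  sum(vapply(split(obs, obs$variable), function(s) {
    m <- mean(s$value)
    if (m <= 0) m <- 1
    rmse(s$value, s$sim) / m
  }, numeric(1)))
}

#' Calibrate the stress-index constants
#'
#' Estimates (`K_NI`, `KMAX`, `TSUM_NPKI`) by minimizing the sum over
#' observation variables of the RMSE between observed and simulated
#' values, each normalized by the variable's observed mean (making yields
#' and uptakes commensurate). The search is a coarse grid scan followed by
#' Nelder-Mead simplex refinement from the best grid point, with
#' candidates clamped to the bounds. The reported optimum is the best
#' point ever evaluated; exact ties are broken towards the
#' lexicographically smallest `(K_NI, KMAX, TSUM_NPKI)` triple. The whole
#' procedure is deterministic given its inputs.
#'
#' Note on identifiability: the combined-stress transform switches branch
#' on the sign of `K_NI - KMAX` only, so data generated in one branch
#' constrain `KMAX` solely through that inequality; within a branch the
#' objective is flat in `KMAX` and ties resolve to the lower bound.
#'
#' @param params baseline `cassava_params` (all other parameters held
#'   fixed).
#' @param scenarios named list of `cassava_scenario` per treatment.
#' @param observations observation data.frame.
#' @param lower,upper named bounds over `K_NI`, `KMAX`, `TSUM_NPKI`; must
#'   contain the defaults (6.1, 4, 272).
#' @param grid optional named list of explicit grid vectors; by default
#'   `K_NI` steps by 1, `KMAX` by 1 and `TSUM_NPKI` by 50 across the
#'   bounds.
#' @param simplex run the Nelder-Mead refinement (default `TRUE`).
#' @return list of class `cassava_fit`: `par`, `objective`,
#'   `per_variable_rmse`, `trace` (every evaluated point) and `n_eval`.
#' @export
calibrateNPKI <- function(params, scenarios, observations,
                          lower = c(K_NI = 2, KMAX = 4, TSUM_NPKI = 122),
                          upper = c(K_NI = 10, KMAX = 8, TSUM_NPKI = 472),
                          grid = NULL, simplex = TRUE) {
  nm <- c("K_NI", "KMAX", "TSUM_NPKI")
  lower <- lower[nm]; upper <- upper[nm]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper))
    stop("invalid bounds")
  defaults <- c(K_NI = 6.1, KMAX = 4, TSUM_NPKI = 272)
  if (any(defaults < lower | defaults > upper))
    stop("bounds must contain the default triple (6.1, 4, 272)")
  validateObservations(observations)
  if (is.null(grid))
    grid <- list(K_NI = seq(lower[[1]], upper[[1]], by = 1),
                 KMAX = seq(lower[[2]], upper[[2]], by = 1),
                 TSUM_NPKI = seq(lower[[3]], upper[[3]], by = 50))
  cand <- as.matrix(expand.grid(grid[nm], KEEP.OUT.ATTRS = FALSE))

  evals <- matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c(nm, "objective")))
  record <- function(theta, value)
    evals <<- rbind(evals, c(theta, value))
  obj <- function(theta) {
    theta <- pmin(pmax(theta, lower), upper)
    value <- calibrationObjective(theta, params, scenarios, observations)
    record(theta, value)
    value
  }
  for (i in seq_len(nrow(cand))) obj(cand[i, ])

  best_i <- bestEvaluated(evals)
  if (simplex) {
    start <- evals[best_i, nm]
    stats::optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-8))
    best_i <- bestEvaluated(evals)
  }
  par <- evals[best_i, nm]

  ## per-variable RMSE at the optimum
  pfit <- params
  pfit$npk$K_NI <- par[[1]]; pfit$npk$KMAX <- par[[2]]
  pfit$npk$TSUM_NPKI <- par[[3]]
  sims <- lapply(scenarios, function(sc) runSimulation(pfit, sc))
  ev <- evaluateSim(sims, observations)
  structure(list(par = par, objective = evals[best_i, "objective"],
                 per_variable_rmse = stats::setNames(ev$rmsep, ev$variable),
                 trace = as.data.frame(evals), n_eval = nrow(evals)),
            class = "cassava_fit")
}

## index of the lowest objective; exact-tie break: lexicographically
## smallest (K_NI, KMAX, TSUM_NPKI)
bestEvaluated <- function(evals) {
  o <- evals[, "objective"]
  tied <- which(o <= min(o) + 1e-12)
  tied[order(evals[tied, 1], evals[tied, 2], evals[tied, 3])[1]]
}

#' @export
print.cassava_fit <- function(x, ...) {
  cat("<cassava_fit>\n")
  cat(sprintf("  K_NI = %.3f, KMAX = %.3f, TSUM_NPKI = %.1f\n",
              x$par[[1]], x$par[[2]], x$par[[3]]))
  cat(sprintf("  objective = %.6g over %d evaluations\n",
              x$objective, x$n_eval))
  cat("  per-variable RMSE: ",
      paste(names(x$per_variable_rmse),
            signif(x$per_variable_rmse, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
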