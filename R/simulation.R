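# Simulation study of the TME/CME/SME tests under three forms of model
# (mis)specification:
#   Scenario I   — one true mediator; the analysis also includes an
#                  irrelevant cis-gene as a second mediator.
#   Scenario II  — two true mediators with effects in the same direction.
#   Scenario III — two true mediators with effects in opposite direction,
#                  so the total effect cancels at alphaX1 = 0.6 while the
#                  component effects do not.

#' Build a simulation scenario configuration
#'
#' Fills the study's default parameters: SNP MAF 0.3; cis-regulatory effects
#' `alphaX1` varying over a grid with `alphaX2` fixed at 0.6; intercepts
#' `alpha01 = alpha02 = beta0 = 0.5`; direct effect `betaX = 0.3`; mediator
#' errors bivariate normal with unit variances and exchangeable correlation
#' 0.2; outcome error standard normal; no covariates. The mediator outcome
#' effects depend on scenario and mode: under `mode = "type1"` both are zero
#' (the shared null of all three scenarios); under `mode = "power"`,
#' `betaM1 = 0.1` always, and `betaM2` is 0 (Scenario I), +0.1 (II), or
#' -0.1 (III).
#'
#' @param scenario `"I"`, `"II"`, or `"III"`.
#' @param mode `"type1"` or `"power"`.
#' @param n sample size per replicate (the study used 100 and 300).
#' @param replicates Monte-Carlo replicates per grid point (default 1000).
#' @param B bootstrap resamples per test (default 500).
#' @param seed integer master seed.
#' @param alphaX1_grid grid of `alphaX1` values (default
#'   `c(0.2, 0.4, 0.6, 0.8, 1.0)`).
#' @param alpha_level nominal test level (default 0.05).
#' @param betaM1,betaM2 optional overrides; an override inconsistent with the
#'   mode (nonzero under `type1`) is an error.
#' @param mediator_var,outcome_var error variances (default 1); setting them
#'   to 0 gives the deterministic degenerate limit used in tests.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("I", "II", "III"),
                            mode = c("type1", "power"),
                            n = 100L, replicates = 1000L, B = 500L,
                            seed = NULL,
                            alphaX1_grid = c(0.2, 0.4, 0.6, 0.8, 1.0),
                            alpha_level = 0.05,
                            betaM1 = NULL, betaM2 = NULL,
                            mediator_var = 1, outcome_var = 1) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  defaults <- if (mode == "type1") c(0, 0)
              else switch(scenario, I = c(0.1, 0), II = c(0.1, 0.1),
                          III = c(0.1, -0.1))
  if (is.null(betaM1)) betaM1 <- defaults[1L]
  if (is.null(betaM2)) betaM2 <- defaults[2L]
  if (mode == "type1" && (betaM1 != 0 || betaM2 != 0))
    stop("type1 mode requires betaM1 = betaM2 = 0")
  stopifnot(n > 4, replicates >= 1, B >= 100,
            all(alphaX1_grid >= 0), alpha_level > 0, alpha_level < 1,
            mediator_var >= 0, outcome_var >= 0)
  structure(list(
    scenario = scenario, mode = mode, n = as.integer(n),
    maf = 0.3, alphaX1_grid = alphaX1_grid, alphaX2 = 0.6,
    alpha01 = 0.5, alpha02 = 0.5, beta0 = 0.5, betaX = 0.3,
    betaM1 = betaM1, betaM2 = betaM2, rho = 0.2,
    mediator_var = mediator_var, outcome_var = outcome_var,
    replicates = as.integer(replicates), B = as.integer(B),
    alpha_level = alpha_level, seed = seed),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config: Scenario ", x$scenario, ", mode ", x$mode,
      ", n = ", x$n, "\n", sep = "")
  cat("  betaM = (", x$betaM1, ", ", x$betaM2, "), alphaX2 = ", x$alphaX2,
      ", rho = ", x$rho, "\n", sep = "")
  cat("  grid:", x$alphaX1_grid, " replicates:", x$replicates,
      " B:", x$B, "\n")
  invisible(x)
}

#' Draw one simulated dataset
#'
#' `X ~ Binomial(2, maf)` i.i.d.; mediator errors bivariate normal with
#' variances `mediator_var` and correlation `rho`;
#' `M_j = alpha0j + alphaXj X + eps_Mj`;
#' `Y = beta0 + betaX X + betaM1 M1 + betaM2 M2 + eps_Y`. Draws consume the
#' current RNG state (seed upstream). A monomorphic X draw is rejected and
#' redrawn.
#'
#' @param cfg a [scenario_config()].
#' @param alphaX1 value of the varying cis effect for this draw.
#' @return A [mediation_data()] with p = 2 mediators and no covariates.
#' @export
simulate_scenario_data <- function(cfg, alphaX1) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$n
  repeat {
    X <- stats::rbinom(n, 2L, cfg$maf)
    if (stats::var(X) > 0) break
  }
  s <- sqrt(cfg$mediator_var)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  e1 <- s * z1
  e2 <- s * (cfg$rho * z1 + sqrt(1 - cfg$rho^2) * z2)
  M1 <- cfg$alpha01 + alphaX1 * X + e1
  M2 <- cfg$alpha02 + cfg$alphaX2 * X + e2
  eY <- sqrt(cfg$outcome_var) * stats::rnorm(n)
  Y <- cfg$beta0 + cfg$betaX * X + cfg$betaM1 * M1 + cfg$betaM2 * M2 + eY
  mediation_data(Y, X, cbind(M1 = M1, M2 = M2))
}

#' Run a simulation scenario
#'
#' For each `alphaX1` on the grid and each replicate: simulate a dataset,
#' draw one set of case-resampling bootstrap indices, and compute the TME,
#' CME, and SME tests from the same resamples. In Scenario I the SME entry
#' is the single-mediator test of the one true mediator (the correctly
#' specified model); in Scenarios II and III, where both mediators are real,
#' it applies the "at least one of the two single-mediator tests
#' significant" rule. Rejections at `cfg$alpha_level` are tallied.
#' Replicates run serially from the single master seed, so results are
#' bit-identical across runs.
#'
#' @param cfg a [scenario_config()].
#' @return A `power_table` data frame: `scenario`, `mode`, `n`, `alphaX1`,
#'   `test`, `rejections`, `replicates`, `rate`, `mc_se` (binomial
#'   Monte-Carlo standard error).
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sme_cols <- if (cfg$scenario == "I") 1L else 1:2
  out <- list()
  for (aX1 in cfg$alphaX1_grid) {
    rej <- c(TME = 0L, CME = 0L, SME = 0L)
    for (r in seq_len(cfg$replicates)) {
      dat <- simulate_scenario_data(cfg, aX1)
      st <- .boot_stats(dat, cfg$B, include_sme = TRUE)
      p_tme <- .percentile_p(st$Delta)
      comp_p <- apply(st$delta, 2L, .percentile_p)
      p_cme <- min(1, dat$p * min(comp_p))
      p_sme <- min(apply(st$sme[, sme_cols, drop = FALSE], 2L, .percentile_p))
      rej <- rej + c(p_tme <= cfg$alpha_level, p_cme <= cfg$alpha_level,
                     p_sme <= cfg$alpha_level)
    }
    rate <- rej / cfg$replicates
    out[[length(out) + 1L]] <- data.frame(
      scenario = cfg$scenario, mode = cfg$mode, n = cfg$n, alphaX1 = aX1,
      test = names(rej), rejections = unname(rej),
      replicates = cfg$replicates, rate = unname(rate),
      mc_se = unname(sqrt(rate * (1 - rate) / cfg$replicates)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("power_table", class(res))
  res
}
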