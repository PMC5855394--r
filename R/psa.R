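#' Fit a sampling distribution to a base value and plausible range
#'
#' The plausible range is interpreted as a central 95% interval. Beta
#' distributions (probabilities, utilities, rates on the unit scale) are
#' fitted by moment matching: mean equal to the base value and standard
#' deviation `(hi - lo) / (2 * 1.96)`. Log-normal distributions (costs and
#' ratio parameters) are fitted with log-scale median at the base value and
#' log-scale standard deviation `(log(hi) - log(lo)) / (2 * 1.96)`. A
#' degenerate distribution is returned whenever `lo == hi`.
#'
#' @param base Base-case value (the distribution's centre).
#' @param lo,hi Lower and upper 95% limits.
#' @param family `"beta"`, `"lognormal"` or `"degenerate"`.
#' @return A `stroke_dist` list: `family`, fitted parameters, and the
#'   source `base`, `lo`, `hi`.
#' @examples
#' fit_distribution(0.76, 0.69, 0.82, "beta")
#' @export
fit_distribution <- function(base, lo, hi,
                             family = c("beta", "lognormal", "degenerate")) {
  family <- match.arg(family)
  if (!(lo <= base && base <= hi)) stop("need lo <= base <= hi", call. = FALSE)
  if (lo == hi) family <- "degenerate"
  spec <- switch(family,
    degenerate = list(family = "degenerate", value = base),
    beta = {
      if (base <= 0 || base >= 1) {
        stop("beta requires base in (0, 1)", call. = FALSE)
      }
      s <- (hi - lo) / (2 * stats::qnorm(0.975))
      k <- base * (1 - base) / s^2 - 1
      if (k <= 0) {
        stop("infeasible beta moments: sd too large for mean ", base,
             call. = FALSE)
      }
      list(family = "beta", shape1 = base * k, shape2 = (1 - base) * k)
    },
    lognormal = {
      if (base <= 0) stop("lognormal requires base > 0", call. = FALSE)
      list(family = "lognormal", meanlog = log(base),
           sdlog = (log(hi) - log(lo)) / (2 * stats::qnorm(0.975)))
    })
  structure(c(spec, list(base = base, lo = lo, hi = hi)),
            class = "stroke_dist")
}

dist_sample <- function(spec, n) {
  switch(spec$family,
    degenerate = rep(spec$value, n),
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog))
}

# PSA family by parameter type; run settings, durations and the mortality
# anchors are not sampled (the anchors and durations have no published
# range; discount rates are varied deterministically only, since the
# published cost-rate range has its base at the lower limit and admits no
# central-interval fit).
psa_family <- function(type, group, lo, hi) {
  if (lo == hi || group == "settings") return("degenerate")
  switch(type,
    cost = "lognormal",
    odds_ratio = "lognormal",
    hazard_ratio = "lognormal",
    multiplier = "lognormal",
    probability = "beta",
    utility = "beta",
    rate = "beta",
    "degenerate")
}

#' Sampling distributions for every model input
#'
#' Assigns each parameter its probabilistic-sensitivity-analysis family
#' (log-normal for costs and ratio parameters, beta for probabilities,
#' utilities and rates, degenerate for fixed inputs and run settings) and
#' fits it with [fit_distribution()].
#'
#' @param params A [stroke_params] tibble.
#' @return A named list of `stroke_dist` objects, one per parameter.
#' @examples
#' psa_distributions(default_parameters())[["c_mt_addon"]]
#' @export
psa_distributions <- function(params) {
  specs <- purrr::pmap(
    list(params$base, params$lo, params$hi, params$type, params$group),
    function(base, lo, hi, type, group) {
      fit_distribution(base, lo, hi, psa_family(type, group, lo, hi))
    })
  stats::setNames(specs, params$name)
}

#' Draw joint parameter sets for probabilistic sensitivity analysis
#'
#' Draws every parameter independently from its fitted distribution. Draws
#' violating the joint constraint on the 90-day proportions
#' (`p_mrs02_tpa + p_death_tpa <= 1`) are resampled; more than 100
#' resampling rounds abort with a diagnostic. Uses the current RNG state,
#' so seed externally (or via [run_psa()]) for reproducibility.
#'
#' @param specs Distribution list from [psa_distributions()].
#' @param n Number of joint draws.
#' @return A tibble with `n` rows and one column per parameter.
#' @examples
#' set.seed(1)
#' draw_parameters(psa_distributions(default_parameters()), 3)
#' @export
draw_parameters <- function(specs, n = 1) {
  draws <- purrr::map_dfc(specs, dist_sample, n = n)
  rounds <- 0
  repeat {
    invalid <- draws$p_mrs02_tpa + draws$p_death_tpa > 1
    if (!any(invalid)) break
    rounds <- rounds + 1
    if (rounds > 100) {
      stop("joint parameter draw failed validation after 100 resampling ",
           "rounds (", sum(invalid), " invalid draws remain)", call. = FALSE)
    }
    k <- sum(invalid)
    draws$p_mrs02_tpa[invalid] <- dist_sample(specs$p_mrs02_tpa, k)
    draws$p_death_tpa[invalid] <- dist_sample(specs$p_death_tpa, k)
  }
  draws
}

params_from_draw <- function(params, draw) {
  params$base <- as.numeric(draw[params$name])
  params$lo <- pmin(params$lo, params$base)
  params$hi <- pmax(params$hi, params$base)
  params
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` joint parameter sets from the fitted distributions and
#' runs the full two-arm model for each, recording the incremental cost
#' and QALY pair. Deterministic given `seed`.
#'
#' @param params A [stroke_params] tibble (also supplies the horizon).
#' @param n_draws Number of Monte Carlo draws (default 10 000).
#' @param seed Integer seed; required, so every run is reproducible.
#' @param horizon Horizon in whole years; defaults to the `horizon` setting.
#' @param recurrence_event_costs Passed to [accrue()].
#' @param keep_draws Keep the per-draw parameter log (default `TRUE`).
#' @return A `stroke_psa` object: list with `draws` (tibble of `draw`,
#'   `delta_qaly`, `delta_cost`), `parameters` (per-draw log or `NULL`),
#'   `n_draws`, `seed`, `horizon`, `base_ce` (the deterministic result) and
#'   `wtp`/`wtp_low` thresholds.
#' @examples
#' run_psa(default_parameters(), n_draws = 25, seed = 1, horizon = 5)
#' @export
run_psa <- function(params, n_draws = 10000, seed, horizon = NULL,
                    recurrence_event_costs = TRUE, keep_draws = TRUE) {
  stop_if_invalid(params)
  if (missing(seed)) stop("seed is required for a PSA run", call. = FALSE)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  pv <- param_values(params)
  horizon <- horizon %||% pv[["horizon"]]
  set.seed(seed)
  specs <- psa_distributions(params)
  draws <- draw_parameters(specs, n_draws)
  dm <- as.matrix(draws)
  dq <- numeric(n_draws)
  dc <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    pp <- params_from_draw(params, dm[i, ])
    ce <- run_cea(pp, horizon, recurrence_event_costs)
    dq[i] <- ce$delta_qaly
    dc[i] <- ce$delta_cost
  }
  structure(list(
    draws = tibble::tibble(draw = seq_len(n_draws), delta_qaly = dq,
                           delta_cost = dc),
    parameters = if (keep_draws) draws else NULL,
    n_draws = n_draws, seed = seed, horizon = horizon,
    base_ce = run_cea(params, horizon, recurrence_event_costs),
    wtp = pv[["wtp"]], wtp_low = pv[["wtp_low"]]
  ), class = "stroke_psa")
}

#' @export
print.stroke_psa <- function(x, ...) {
  cat("<stroke_psa> ", x$n_draws, " draws, horizon ", x$horizon,
      " years, seed ", x$seed, "\n", sep = "")
  cat(sprintf("  mean dQALY %.3f, mean dCost %.0f CNY\n",
              mean(x$draws$delta_qaly), mean(x$draws$delta_cost)))
  cat(sprintf("  P(cost-effective) at %.0f CNY/QALY: %.3f\n", x$wtp,
              probability_cost_effective(x, x$wtp)))
  invisible(x)
}

#' Probability that the intervention is cost-effective
#'
#' Fraction of PSA draws with positive incremental net benefit
#' `wtp * delta_qaly - delta_cost` at the given threshold.
#'
#' @param psa A `stroke_psa` object.
#' @param wtp Willingness-to-pay threshold(s) in CNY per QALY.
#' @return Proportion(s) in \[0, 1\], vectorised over `wtp`.
#' @examples
#' psa <- run_psa(default_parameters(), n_draws = 25, seed = 1, horizon = 5)
#' probability_cost_effective(psa, 125700)
#' @export
probability_cost_effective <- function(psa, wtp) {
  vapply(wtp, function(w) {
    mean(w * psa$draws$delta_qaly - psa$draws$delta_cost > 0)
  }, numeric(1))
}

#' Cost-effectiveness acceptability curve
#'
#' Evaluates the probability of cost-effectiveness over a grid of
#' willingness-to-pay thresholds. The default grid runs from 0 to
#' 300 000 CNY/QALY in steps of 5000 and always includes the two GDP-based
#' thresholds stored in the parameter settings.
#'
#' @param psa A `stroke_psa` object.
#' @param wtp_grid Thresholds in CNY per QALY.
#' @return A tibble with columns `wtp` and `prob_cost_effective`.
#' @examples
#' psa <- run_psa(default_parameters(), n_draws = 25, seed = 1, horizon = 5)
#' ceac(psa, wtp_grid = c(0, 125700, 300000))
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  wtp_grid <- wtp_grid %||%
    sort(unique(c(seq(0, 300000, by = 5000), psa$wtp_low, psa$wtp)))
  if (length(wtp_grid) == 0) stop("empty willingness-to-pay grid",
                                  call. = FALSE)
  tibble::tibble(wtp = wtp_grid,
                 prob_cost_effective = probability_cost_effective(psa, wtp_grid))
}
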