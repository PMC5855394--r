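#' Model parameters for the thrombectomy cost-utility model
#'
#' A `stroke_params` object is a tibble with one row per model input and
#' columns `group`, `name`, `base`, `lo`, `hi`, `type` and `label`. The
#' `base` column holds the value used in a deterministic run; `lo`/`hi`
#' hold the plausible range used by the one-way sensitivity analysis and,
#' interpreted as a central 95% interval, by the probabilistic sensitivity
#' analysis. Inputs without a published range carry `lo == hi == base`.
#'
#' All costs are in 2013 Chinese yuan renminbi (CNY); utilities are EQ-5D
#' preference weights on the 0 (dead) to 1 (full health) scale; recurrence
#' rates are events per patient-year.
#'
#' @name stroke_params
NULL

params_row <- function(group, name, base, lo, hi, type, label) {
  tibble::tibble(group = group, name = name, base = base, lo = lo, hi = hi,
                 type = type, label = label)
}

new_stroke_params <- function(tbl) {
  structure(tbl, class = c("stroke_params", class(tibble::tibble())))
}

#' Packaged base-case parameter set
#'
#' Returns the default model inputs: 90-day outcome proportions in the
#' thrombolysis arm, pooled odds ratios for the thrombectomy arm, recurrence
#' and mortality inputs, costs (2013 CNY), utilities, and run settings
#' (cohort of 100 000 patients entering at age 63, 30-year horizon, 3%
#' annual discounting, willingness-to-pay thresholds of 125 700 and
#' 41 900 CNY/QALY, i.e. 3x and 1x China's 2013 GDP per capita).
#'
#' @return A [stroke_params] tibble.
#' @examples
#' default_parameters()
#' @export
default_parameters <- function() {
  tbl <- dplyr::bind_rows(
    # 90-day outcome inputs -------------------------------------------------
    params_row("outcomes", "p_mrs02_tpa", 0.325, 0.258, 0.392, "probability",
               "Proportion mRS 0-2 at 90 days, tPA arm"),
    params_row("outcomes", "p_death_tpa", 0.168, 0.131, 0.205, "probability",
               "Proportion dead (mRS 6) at 90 days, tPA arm"),
    params_row("outcomes", "p_sich_tpa", 0.058, 0.035, 0.095, "probability",
               "Proportion with sICH, tPA arm"),
    params_row("outcomes", "or_mrs02", 2.046, 1.692, 2.474, "odds_ratio",
               "OR for mRS 0-2 at 90 days, thrombectomy vs tPA"),
    params_row("outcomes", "or_death", 0.871, 0.684, 1.109, "odds_ratio",
               "OR for death at 90 days, thrombectomy vs tPA"),
    params_row("outcomes", "or_sich", 0.965, 0.665, 1.399, "odds_ratio",
               "OR for sICH, thrombectomy vs tPA"),
    # transition inputs -----------------------------------------------------
    params_row("transitions", "p_receive_mt", 0.861, 0.839, 0.883, "probability",
               "Proportion of intervention arm receiving thrombectomy"),
    params_row("transitions", "p_arrive_45h", 0.854, 0.839, 0.869, "probability",
               "Proportion arriving within 4.5 h (receives tPA), both arms"),
    params_row("transitions", "recur_rate_indep", 0.1026, 0.0961, 0.1093, "rate",
               "Stroke recurrence rate, independent state (per patient-year)"),
    params_row("transitions", "recur_rate_dep", 0.1418, 0.1303, 0.1534, "rate",
               "Stroke recurrence rate, dependent state (per patient-year)"),
    params_row("transitions", "rr_recur_per_year", 1.03, 1.02, 1.04, "multiplier",
               "Escalation of recurrence risk per life-year"),
    params_row("transitions", "p_death_given_recur", 0.2101, 0.1887, 0.2316,
               "probability", "Case fatality of recurrent stroke"),
    params_row("transitions", "mortality_anchor_entry", 0.0089, 0.0089, 0.0089,
               "probability", "Annual non-stroke death probability at entry age"),
    params_row("transitions", "mortality_anchor_max", 0.1653, 0.1653, 0.1653,
               "probability", "Annual non-stroke death probability at age 93"),
    params_row("transitions", "hr_nonstroke_death_dep", 1.78, 1.43, 2.14,
               "hazard_ratio", "HR of non-stroke death, dependent vs independent"),
    # cost inputs (2013 CNY) ------------------------------------------------
    params_row("costs", "c_mt_addon", 60821, 52314, 70311, "cost",
               "Additional cost of mechanical thrombectomy"),
    params_row("costs", "c_tpa_addon", 11179, 10555, 11829, "cost",
               "Additional cost of intravenous tPA treatment"),
    params_row("costs", "c_sich_addon", 2374, 2249, 2504, "cost",
               "Additional cost of sICH"),
    params_row("costs", "c_hosp_indep", 10055, 9907, 10205, "cost",
               "One-time hospitalisation cost, mRS 0-2"),
    params_row("costs", "c_hosp_dep", 13729, 13428, 14035, "cost",
               "One-time hospitalisation cost, mRS 3-5"),
    params_row("costs", "c_hosp_death", 11121, 10219, 12081, "cost",
               "One-time hospitalisation cost, mRS 6"),
    params_row("costs", "c_annual_indep", 7385, 7156, 7619, "cost",
               "Annual post-hospitalisation cost, mRS 0-2 (per year)"),
    params_row("costs", "c_annual_dep", 11350, 10730, 11996, "cost",
               "Annual post-hospitalisation cost, mRS 3-5 (per year)"),
    # utility inputs ----------------------------------------------------------
    params_row("utilities", "u_indep", 0.76, 0.69, 0.82, "utility",
               "Utility, independent (mRS 0-2)"),
    params_row("utilities", "u_dep", 0.21, 0.17, 0.26, "utility",
               "Utility, dependent (mRS 3-5)"),
    params_row("utilities", "u_death", 0, 0, 0, "utility", "Utility, dead (mRS 6)"),
    params_row("utilities", "u_recur_event", 0.34, 0.32, 0.36, "utility",
               "Temporary utility during a recurrent-stroke event"),
    params_row("utilities", "u_sich_event", 0.84, 0.72, 1.0, "utility",
               "Multiplicative utility factor during an sICH event"),
    params_row("utilities", "dur_recur_days", 30, 30, 30, "days",
               "Duration of recurrent-stroke temporary state"),
    params_row("utilities", "dur_sich_days", 14, 14, 14, "days",
               "Duration of sICH temporary state"),
    # run settings ------------------------------------------------------------
    params_row("settings", "cohort_size", 1e5, 1e5, 1e5, "count",
               "Cohort size used for reporting absolute numbers"),
    params_row("settings", "entry_age", 63, 63, 63, "years", "Age at model entry"),
    params_row("settings", "mortality_max_age", 93, 93, 93, "years",
               "Age of the upper background-mortality anchor"),
    params_row("settings", "horizon", 30, 30, 30, "years", "Model time horizon"),
    params_row("settings", "discount_cost", 0.03, 0.03, 0.08, "discount",
               "Annual discount rate, costs"),
    params_row("settings", "discount_outcome", 0.03, 0.024, 0.036, "discount",
               "Annual discount rate, health outcomes"),
    params_row("settings", "wtp", 125700, 125700, 125700, "cny_per_qaly",
               "Willingness-to-pay threshold (3x GDP per capita, 2013)"),
    params_row("settings", "wtp_low", 41900, 41900, 41900, "cny_per_qaly",
               "Lower willingness-to-pay threshold (1x GDP per capita, 2013)")
  )
  new_stroke_params(tbl)
}

#' @export
print.stroke_params <- function(x, ...) {
  cat("<stroke_params> ", nrow(x), " model inputs (costs in 2013 CNY)\n", sep = "")
  NextMethod()
}

# named vector of base values, used by the engine
param_values <- function(params) {
  stats::setNames(params$base, params$name)
}

#' Look up or modify a single parameter
#'
#' `param_value()` returns the base value of one named input;
#' `set_param()` returns a modified copy of the parameter set. Setting
#' `base` outside the stored `lo`/`hi` widens the range to keep the
#' lo <= base <= hi invariant.
#'
#' @param params A [stroke_params] tibble.
#' @param name Parameter name, e.g. `"or_mrs02"`.
#' @param base,lo,hi Replacement values; omitted components are unchanged.
#' @return `param_value()` a scalar; `set_param()` a [stroke_params] tibble.
#' @examples
#' param_value(default_parameters(), "u_indep")
#' set_param(default_parameters(), "horizon", base = 6)
#' @export
param_value <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: ", name, call. = FALSE)
  params$base[i]
}

#' @rdname param_value
#' @export
set_param <- function(params, name, base = NULL, lo = NULL, hi = NULL) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: ", name, call. = FALSE)
  if (!is.null(base)) params$base[i] <- base
  if (!is.null(lo)) params$lo[i] <- lo
  if (!is.null(hi)) params$hi[i] <- hi
  params$lo[i] <- min(params$lo[i], params$base[i])
  params$hi[i] <- max(params$hi[i], params$base[i])
  params
}

#' Validate a parameter set
#'
#' Checks every invariant the model relies on: ordering of `lo`, `base`,
#' `hi`; probabilities and utilities within \[0, 1\]; non-negative costs and
#' rates; positive ratio parameters; the 90-day outcome proportions summing
#' to at most 1; the utility of death fixed at 0; and admissible run
#' settings. Violations are returned, not raised, so the caller decides
#' how to react.
#'
#' @param params A [stroke_params] tibble.
#' @return A tibble with columns `name`, `value` and `rule`, one row per
#'   violated invariant; zero rows when the set is valid.
#' @examples
#' validate_parameters(default_parameters())
#' @export
validate_parameters <- function(params) {
  v <- list()
  bad <- function(name, value, rule) {
    tibble::tibble(name = name, value = value, rule = rule)
  }
  add <- function(sel, rule) {
    if (any(sel)) {
      v[[length(v) + 1L]] <<- bad(params$name[sel], params$base[sel], rule)
    }
  }
  lo <- params$lo; base <- params$base; hi <- params$hi; type <- params$type
  add(!(lo <= base & base <= hi), "lo <= base <= hi")
  unit <- type %in% c("probability", "utility", "discount")
  add(unit & (lo < 0 | base < 0 | hi < 0 | lo > 1 | base > 1 | hi > 1),
      "value in [0, 1]")
  add(type %in% c("cost", "rate") & (lo < 0 | base < 0 | hi < 0),
      "value >= 0")
  add(type %in% c("odds_ratio", "hazard_ratio", "multiplier") &
        (lo <= 0 | base <= 0 | hi <= 0), "ratio > 0")
  add(type %in% c("days", "years", "count") & (lo <= 0 | base <= 0 | hi <= 0),
      "value > 0")
  pv <- param_values(params)
  if (pv[["p_mrs02_tpa"]] + pv[["p_death_tpa"]] > 1) {
    v[[length(v) + 1L]] <- bad("p_mrs02_tpa",
                               pv[["p_mrs02_tpa"]] + pv[["p_death_tpa"]],
                               "p_mrs02_tpa + p_death_tpa <= 1")
  }
  if (pv[["u_death"]] != 0) {
    v[[length(v) + 1L]] <- bad("u_death", pv[["u_death"]], "u_death == 0")
  }
  if (pv[["horizon"]] < 1) {
    v[[length(v) + 1L]] <- bad("horizon", pv[["horizon"]], "horizon >= 1")
  }
  if (pv[["discount_cost"]] >= 1 || pv[["discount_outcome"]] >= 1) {
    v[[length(v) + 1L]] <- bad("discount", pv[["discount_cost"]],
                               "discount rate in [0, 1)")
  }
  if (pv[["mortality_anchor_entry"]] <= 0 || pv[["mortality_anchor_entry"]] >= 1 ||
      pv[["mortality_anchor_max"]] <= 0 || pv[["mortality_anchor_max"]] >= 1) {
    v[[length(v) + 1L]] <- bad("mortality_anchor", pv[["mortality_anchor_entry"]],
                               "anchor probability in (0, 1)")
  }
  if (length(v) == 0) {
    return(tibble::tibble(name = character(), value = numeric(),
                          rule = character()))
  }
  dplyr::bind_rows(v)
}

stop_if_invalid <- function(params) {
  viol <- validate_parameters(params)
  if (nrow(viol) > 0) {
    stop("invalid parameters: ",
         paste0(viol$name, " (", viol$rule, ")", collapse = "; "),
         call. = FALSE)
  }
  invisible(params)
}

#' Read and write parameter configuration files
#'
#' The configuration is a YAML file with one section per input group
#' (`outcomes`, `transitions`, `costs`, `utilities`, `settings`). Each
#' entry is either a mapping with `base`, `lo`, `hi` keys or a bare number,
#' which sets `base` and widens the stored range if needed. Entries not
#' present in the file keep their packaged defaults, so a partial file that
#' overrides a single value is valid. The packaged default configuration is
#' shipped at `system.file("extdata", "default_inputs.yaml",
#' package = "strokecea")`.
#'
#' @param path Path to a YAML configuration file.
#' @param params A [stroke_params] tibble to serialise.
#' @return `read_parameters()` a validated [stroke_params] tibble;
#'   `write_parameters()` the input, invisibly.
#' @examples
#' cfg <- system.file("extdata", "default_inputs.yaml", package = "strokecea")
#' identical(read_parameters(cfg), default_parameters())
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  params <- default_parameters()
  for (group in names(cfg)) {
    if (!group %in% params$group) {
      stop("unknown configuration section: ", group, call. = FALSE)
    }
    entries <- cfg[[group]]
    for (name in names(entries)) {
      i <- match(name, params$name)
      if (is.na(i) || params$group[i] != group) {
        stop("unknown parameter in section '", group, "': ", name,
             call. = FALSE)
      }
      e <- entries[[name]]
      if (is.list(e)) {
        extra <- setdiff(names(e), c("base", "lo", "hi"))
        if (length(extra)) {
          stop("unknown keys for '", name, "': ",
               paste(extra, collapse = ", "), call. = FALSE)
        }
        if (is.null(e$base)) {
          stop("missing required key 'base' for parameter: ", name,
               call. = FALSE)
        }
        params <- set_param(params, name, base = e$base, lo = e$lo, hi = e$hi)
      } else if (is.numeric(e) && length(e) == 1) {
        params <- set_param(params, name, base = e)
      } else {
        stop("parameter '", name, "' must be a number or a base/lo/hi mapping",
             call. = FALSE)
      }
    }
  }
  viol <- validate_parameters(params)
  if (nrow(viol) > 0) {
    stop("configuration violates parameter bounds: ",
         paste0(viol$name, " (", viol$rule, ")", collapse = "; "),
         call. = FALSE)
  }
  params
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "stroke_params"))
  out <- list()
  for (group in unique(params$group)) {
    rows <- params[params$group == group, ]
    out[[group]] <- stats::setNames(
      purrr::pmap(list(rows$base, rows$lo, rows$hi),
                  function(b, l, h) list(base = b, lo = l, hi = h)),
      rows$name
    )
  }
  yaml::write_yaml(out, path)
  invisible(params)
}

#' Display helper: convert 2013 CNY to US dollars
#'
#' Divides by the 6.5 CNY/US$ conversion used for reporting. Display only;
#' the model computes in CNY throughout.
#'
#' @param cny Amount(s) in 2013 CNY.
#' @return Amount(s) in US$.
#' @examples
#' cny_to_usd(125700)
#' @export
cny_to_usd <- function(cny) cny / 6.5
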