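#' Annual disease treatment cost offsets
#'
#' Per calendar year, the change (intervention minus BAU) in disease costs:
#' incident cases weighted by the first-year cost, prevalent person-years
#' beyond the first year by the subsequent-year cost, and disease deaths by
#' the last-6-months-of-life cost.  Negative values are savings.
#'
#' @param run An [run_mslt()] result with both scenarios.
#' @param disease_costs Phase-cost table (`disease`, `stratum`,
#'   `cost_first_year`, `cost_subsequent_year`, `cost_last6m`).
#' @return Numeric cost stream by year (NZ$).
#' @export
disease_cost_offsets <- function(run, disease_costs) {
  if (is.null(run$int)) stop("run has no intervention scenario")
  .disease_cost_offsets(run, disease_costs, rows = NULL)
}

.disease_cost_offsets <- function(run, disease_costs, rows = NULL) {
  T <- run$horizon
  out <- numeric(T)
  for (s in run$strata) {
    b <- run$bau$strata[[s]]; i <- run$int$strata[[s]]
    for (d in names(b$disease)) {
      cr <- disease_costs[disease_costs$disease == d & disease_costs$stratum == s, ]
      if (nrow(cr) != 1)
        stop("missing phase costs for disease ", d, " in stratum ", s)
      sel <- function(m) if (is.null(rows)) colSums(m) else
        colSums(m[rows, , drop = FALSE])
      out <- out +
        (sel(i$disease[[d]]$cases)  - sel(b$disease[[d]]$cases))  * cr$cost_first_year +
        (sel(i$disease[[d]]$prevpy) - sel(b$disease[[d]]$prevpy)) * cr$cost_subsequent_year +
        (sel(i$disease[[d]]$deaths) - sel(b$disease[[d]]$deaths)) * cr$cost_last6m
    }
  }
  out
}

#' Annual unrelated health-system costs
#'
#' Incremental life years at each age, valued at the per-capita annual
#' health-system cost for that age: the extra future expenditure incurred
#' because the intervention extends life.
#'
#' @param run An [run_mslt()] result with both scenarios.
#' @param unrelated Data frame `age`, `cost` (per-capita annual NZ$).
#' @return Numeric cost stream by year.
#' @export
unrelated_costs <- function(run, unrelated) {
  if (is.null(run$int)) stop("run has no intervention scenario")
  .unrelated_costs(run, unrelated, rows = NULL)
}

.unrelated_costs <- function(run, unrelated, rows = NULL) {
  T <- run$horizon
  a0 <- 0:109
  A <- outer(a0, 0:(T - 1L), `+`)
  cw <- matrix(0, length(a0), T)
  ok <- A <= max(unrelated$age)
  cw[ok] <- unrelated$cost[match(A[ok], unrelated$age)]
  out <- numeric(T)
  for (s in run$strata) {
    dly <- (run$int$strata[[s]]$ly - run$bau$strata[[s]]$ly) *
      run$bau$strata[[s]]$N * cw
    out <- out + (if (is.null(rows)) colSums(dly) else
      colSums(dly[rows, , drop = FALSE]))
  }
  out
}

#' Incremental cost-effectiveness ratio with dominance flags
#'
#' @param net_cost Present value of net health-system cost (NZ$).
#' @param qaly_gain Present value of the QALY gain.
#' @return List with `icer` (NZ$/QALY, `NA` when undefined) and `flag`: one of
#'   `"icer"` (positive cost, positive gain), `"cost-saving"` (negative cost,
#'   positive gain), `"dominated"` (positive cost, health loss),
#'   `"less-effective-cheaper"` or `"undefined"` (zero gain).
#' @export
compute_icer <- function(net_cost, qaly_gain) {
  stopifnot(is.finite(net_cost), is.finite(qaly_gain))
  if (qaly_gain == 0) return(list(icer = NA_real_, flag = "undefined"))
  if (qaly_gain > 0)
    return(list(icer = net_cost / qaly_gain,
                flag = if (net_cost < 0) "cost-saving" else "icer"))
  if (net_cost > 0) return(list(icer = NA_real_, flag = "dominated"))
  list(icer = net_cost / qaly_gain, flag = "less-effective-cheaper")
}

#' Equity adjustment of background rates
#'
#' Replaces the indigenous strata's background all-cause mortality and
#' morbidity (pYLD) rates with the same-age, same-sex rates of the other
#' ethnic group, so that higher background mortality does not shrink modelled
#' health gains for the disadvantaged group.  Disease epidemiology, exposure
#' and intervention parameters are untouched.
#'
#' @param inputs An [synthetic_inputs()] bundle.
#' @return The adjusted inputs.
#' @export
equity_adjust <- function(inputs) {
  pop <- inputs$population
  if (!all(c("indigenous", "other") %in% pop$ethnicity))
    stop("equity adjustment needs both ethnicity groups")
  for (sex in unique(pop$sex)) {
    src <- pop[pop$sex == sex & pop$ethnicity == "other", ]
    dst <- which(pop$sex == sex & pop$ethnicity == "indigenous")
    if (length(dst) == 0 || nrow(src) == 0)
      stop("missing matched stratum for sex ", sex)
    m <- match(pop$age[dst], src$age)
    if (anyNA(m)) stop("missing matched ages for sex ", sex)
    pop$mortality[dst] <- src$mortality[m]
    pop$pyld[dst] <- src$pyld[m]
  }
  inputs$population <- pop
  attr(inputs, "equity_adjusted") <- TRUE
  inputs
}

# Age-group labels by 2011 start age, matching the reporting convention.
.age_group <- function(a0) {
  cut(a0, breaks = c(-1, 39, 59, 79, 200),
      labels = c("<40", "40-60", "60-80", "80+"))
}

#' Cost-effectiveness analysis of a model run
#'
#' Turns a BAU-vs-intervention run into present-value QALY gains, cost
#' components (intervention cost, disease cost offsets, unrelated costs), net
#' cost and ICER, plus a stratum and age-group breakdown (QALYs per 1000
#' population, group ICERs with the intervention cost spread evenly over the
#' eligible population).
#'
#' @param run An [run_mslt()] result with an intervention scenario.
#' @param inputs The input bundle used for the run.
#' @param discount_rate Annual discount rate applied to both health gains and
#'   costs (default 0.03; scenarios use 0 and 0.06).
#' @return Object of class `mslt_cea`.
#' @export
cea <- function(run, inputs, discount_rate = 0.03) {
  if (is.null(run$int)) stop("run has no intervention scenario")
  T <- run$horizon
  dq_stream <- annual_totals(run, "int") - annual_totals(run, "bau")
  offsets_stream <- disease_cost_offsets(run, inputs$costs$disease_costs)
  unrelated_stream <- unrelated_costs(run, inputs$costs$unrelated)
  ic_stream <- intervention_cost_stream(run$intervention, T)

  qaly_gain <- discount(dq_stream, discount_rate)
  pv <- list(intervention = discount(ic_stream, discount_rate),
             offsets = discount(offsets_stream, discount_rate),
             unrelated = discount(unrelated_stream, discount_rate))
  net_cost <- pv$intervention + pv$offsets + pv$unrelated
  ic <- compute_icer(net_cost, qaly_gain)

  by_group <- .cea_by_group(run, inputs, discount_rate)

  structure(list(qaly_gain = qaly_gain, net_cost = net_cost,
                 icer = ic$icer, flag = ic$flag, components = pv,
                 discount_rate = discount_rate, by_group = by_group,
                 streams = list(qaly = dq_stream, offsets = offsets_stream,
                                unrelated = unrelated_stream,
                                intervention = ic_stream)),
            class = "mslt_cea")
}

# Stratum x start-age-group breakdown.  The intervention cost is spread
# evenly across the eligible (2011 age within the target range) population.
.cea_by_group <- function(run, inputs, discount_rate) {
  spec <- run$intervention
  a0 <- 0:109
  elig0 <- a0 >= spec$eligible_ages[1] & a0 <= spec$eligible_ages[2]
  elig_total <- sum(vapply(run$strata, function(s)
    sum(run$bau$strata[[s]]$N[elig0]), numeric(1)))
  grp <- .age_group(a0)
  rows <- list()
  for (s in run$strata) {
    b <- run$bau$strata[[s]]; i <- run$int$strata[[s]]
    for (g in levels(grp)) {
      sel <- which(grp == g)
      if (length(sel) == 0) next
      pop_g <- sum(b$N[sel])
      dq <- colSums((i$qaly[sel, , drop = FALSE] - b$qaly[sel, , drop = FALSE]) *
                      b$N[sel])
      qg <- discount(dq, discount_rate)
      sub <- list(run = run, horizon = run$horizon,
                  strata = s, bau = list(strata = run$bau$strata[s]),
                  int = list(strata = run$int$strata[s]))
      off <- discount(.disease_cost_offsets(sub, inputs$costs$disease_costs,
                                            rows = sel), discount_rate)
      unr <- discount(.unrelated_costs(sub, inputs$costs$unrelated,
                                       rows = sel), discount_rate)
      icost <- spec$cost_total * sum(b$N[sel][elig0[sel]]) / elig_total
      net <- icost + off + unr
      icg <- compute_icer(net, qg)
      rows[[length(rows) + 1]] <- data.frame(
        stratum = s, age_group = g, population = pop_g,
        qaly_gain = qg, qaly_per_1000 = 1000 * qg / pop_g,
        net_cost = net, icer = icg$icer, flag = icg$flag)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mslt_cea <- function(x, ...) {
  cat(sprintf("Cost-effectiveness (discount rate %.0f%%)\n",
              100 * x$discount_rate))
  cat(sprintf("  QALY gain (PV): %.2f\n", x$qaly_gain))
  cat(sprintf("  net health-system cost (PV): NZ$%s\n",
              format(round(x$net_cost), big.mark = ",")))
  cat(sprintf("    intervention %s | disease offsets %s | unrelated %s\n",
              format(round(x$components$intervention), big.mark = ","),
              format(round(x$components$offsets), big.mark = ","),
              format(round(x$components$unrelated), big.mark = ",")))
  if (x$flag == "icer")
    cat(sprintf("  ICER: NZ$%s per QALY gained\n",
                format(round(x$icer), big.mark = ",")))
  else cat(sprintf("  ICER: %s\n", x$flag))
  invisible(x)
}
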