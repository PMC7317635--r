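#' Fit a beta distribution to a central value and 95% interval
#'
#' Intervention pathway proportions are reported as a central value with a
#' 95% uncertainty interval.  The beta is parameterised so its mean equals
#' the central value exactly, and the concentration is solved numerically so
#' the (2.5%, 97.5%) quantiles match the interval in the least-squares sense.
#'
#' @param central Central proportion in (0, 1).
#' @param lo,hi 2.5th and 97.5th percentile targets, `0 < lo < central < hi < 1`.
#' @return List with `alpha`, `beta`, the achieved `quantiles`, and the
#'   root-mean-square quantile error `rmse`.
#' @examples
#' fit_beta_from_interval(0.779, 0.70, 0.83)
#' @export
fit_beta_from_interval <- function(central, lo, hi) {
  if (!(0 < lo && lo < central && central < hi && hi < 1))
    stop("infeasible triple: need 0 < lo < central < hi < 1 (got ",
         paste(c(central, lo, hi), collapse = ", "), ")")
  obj <- function(logk) {
    k <- exp(logk)
    a <- central * k; b <- (1 - central) * k
    (stats::qbeta(0.025, a, b) - lo)^2 + (stats::qbeta(0.975, a, b) - hi)^2
  }
  opt <- stats::optimize(obj, interval = c(log(2), log(1e6)))
  k <- exp(opt$minimum)
  a <- central * k; b <- (1 - central) * k
  q <- stats::qbeta(c(0.025, 0.975), a, b)
  list(alpha = a, beta = b, quantiles = q, rmse = sqrt(opt$objective / 2))
}

# A parameter distribution: quantile function `q`, central value, family tag.
.param_dist <- function(name, family, q, central) {
  structure(list(name = name, family = family, q = q, central = central),
            class = "param_dist")
}

#' Uncertainty distributions of the intervention parameters
#'
#' The campaign's parameter uncertainty: beta distributions (fitted by
#' [fit_beta_from_interval()]) for the four pathway proportions, a normal for
#' the effect size (truncated at 0 when sampled), and a gamma for the
#' campaign cost with mean `cost_total` and SD 20% of the mean.
#'
#' @param spec An [intervention_spec()] giving the central values.
#' @return Named list of parameter distributions (`awareness`, `download`,
#'   `use`, `adherence`, `effect_met_min`, `cost_total`), each with a
#'   quantile function `q` and `central` value.
#' @export
intervention_parameter_distributions <- function(spec = intervention_spec()) {
  stopifnot(inherits(spec, "intervention_spec"))
  intervals <- list(awareness = c(0.70, 0.83), download = c(0.21, 0.41),
                    use = c(0.10, 0.36), adherence = c(0.10, 0.21))
  out <- lapply(names(intervals), function(nm) {
    fit <- fit_beta_from_interval(spec[[nm]], intervals[[nm]][1],
                                  intervals[[nm]][2])
    .param_dist(nm, "beta",
                local({a <- fit$alpha; b <- fit$beta
                       function(p) stats::qbeta(p, a, b)}),
                spec[[nm]])
  })
  names(out) <- names(intervals)
  eff_sd <- 43 * spec$effect_met_min / 285   # SD scales with the effect size
  out$effect_met_min <- .param_dist(
    "effect_met_min", "normal",
    local({m <- spec$effect_met_min; s <- eff_sd
           function(p) pmax(0, stats::qnorm(p, m, s))}),
    spec$effect_met_min)
  shape <- 1 / 0.2^2                          # CV 20%
  out$cost_total <- .param_dist(
    "cost_total", "gamma",
    local({sh <- shape; rt <- shape / spec$cost_total
           function(p) stats::qgamma(p, shape = sh, rate = rt)}),
    spec$cost_total)
  out
}

#' Sample an independent parameter draw table
#'
#' Monte Carlo draws with all parameters sampled independently from their
#' distributions.  Normal effect-size draws are truncated at zero by
#' resampling (keeping the exposure-shift precondition); the truncation count
#' is attached as an attribute.  The whole table is generated up front from
#' the master seed, so per-run results do not depend on execution order.
#'
#' @param dists From [intervention_parameter_distributions()].
#' @param n_runs Number of draws (the headline analysis uses 2000).
#' @param seed Master RNG seed.
#' @return `n_runs` x `length(dists)` data frame of draws.
#' @export
sample_parameters <- function(dists, n_runs, seed = 1L) {
  stopifnot(n_runs >= 1)
  truncated <- 0L
  draws <- .with_seed(as.integer(seed), {
    cols <- lapply(dists, function(d) {
      if (d$family == "normal") {
        x <- d$q(stats::runif(n_runs))
        # quantile already floors at 0; count and resample exact-zero draws
        bad <- which(x <= 0)
        truncated <<- truncated + length(bad)
        tries <- 0
        while (length(bad) > 0 && tries < 100) {
          x[bad] <- d$q(stats::runif(length(bad)))
          bad <- which(x <= 0)
          tries <- tries + 1
        }
        if (length(bad)) x[bad] <- d$central
        x
      } else d$q(stats::runif(n_runs))
    })
    as.data.frame(cols)
  })
  attr(draws, "truncated") <- truncated
  draws
}

# Rebuild an intervention spec from one parameter draw row.
.spec_from_draw <- function(spec, draw) {
  for (nm in intersect(names(draw), c("awareness", "download", "use",
                                      "adherence", "effect_met_min",
                                      "cost_total")))
    spec[[nm]] <- as.numeric(draw[[nm]])
  spec
}

#' Probabilistic sensitivity analysis
#'
#' Re-runs the intervention scenario (BAU is unaffected by the intervention
#' parameters, so it is computed once) for every parameter draw and
#' summarises lifetime QALY gains, net costs and ICERs as 50th (2.5th,
#' 97.5th) percentiles of runs.
#'
#' @param inputs Model inputs.
#' @param spec The central [intervention_spec()].
#' @param draws Parameter draw table from [sample_parameters()].
#' @param discount_rate Annual discount rate.
#' @param bau Optional precomputed BAU scenario (from a previous run) to
#'   avoid recomputation.
#' @param horizon Annual cycles.
#' @return Object of class `mslt_psa`: per-run results (`runs`), percentile
#'   `summary`, and the failed-run count.
#' @export
run_psa <- function(inputs, spec = intervention_spec(), draws,
                    discount_rate = 0.03, bau = NULL, horizon = 110L) {
  if (is.null(bau)) bau <- .mslt_bau(inputs, horizon)
  rows <- vector("list", nrow(draws))
  failures <- 0L
  for (r in seq_len(nrow(draws))) {
    res <- tryCatch({
      spec_r <- .spec_from_draw(spec, draws[r, , drop = FALSE])
      run <- structure(list(
        bau = bau,
        int = .mslt_intervention(inputs, spec_r, bau, horizon),
        intervention = spec_r, horizon = horizon,
        strata = names(bau$strata)), class = "mslt_run")
      x <- .cea_totals(run, inputs, discount_rate)
      data.frame(run = r, qaly_gain = x$qaly_gain, net_cost = x$net_cost,
                 icer = x$icer, flag = x$flag)
    }, error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else rows[[r]] <- res
  }
  runs <- do.call(rbind, rows)
  if (is.null(runs) || nrow(runs) == 0) stop("all PSA runs failed")
  qs <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), na.rm = TRUE,
                                    names = FALSE)
  summ <- data.frame(output = c("qaly_gain", "net_cost", "icer"),
                     p2.5  = c(qs(runs$qaly_gain)[1], qs(runs$net_cost)[1],
                               qs(runs$icer)[1]),
                     p50   = c(qs(runs$qaly_gain)[2], qs(runs$net_cost)[2],
                               qs(runs$icer)[2]),
                     p97.5 = c(qs(runs$qaly_gain)[3], qs(runs$net_cost)[3],
                               qs(runs$icer)[3]))
  structure(list(runs = runs, summary = summ, failures = failures,
                 discount_rate = discount_rate),
            class = "mslt_psa")
}

# Totals-only CEA (no by-group breakdown): the PSA inner loop.
.cea_totals <- function(run, inputs, discount_rate) {
  dq <- annual_totals(run, "int") - annual_totals(run, "bau")
  qaly_gain <- discount(dq, discount_rate)
  net_cost <-
    discount(intervention_cost_stream(run$intervention, run$horizon), discount_rate) +
    discount(disease_cost_offsets(run, inputs$costs$disease_costs), discount_rate) +
    discount(unrelated_costs(run, inputs$costs$unrelated), discount_rate)
  ic <- compute_icer(net_cost, qaly_gain)
  list(qaly_gain = qaly_gain, net_cost = net_cost, icer = ic$icer,
       flag = ic$flag)
}

#' @export
print.mslt_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d runs (%d failed)\n",
              nrow(x$runs) + x$failures, x$failures))
  s <- x$summary
  cat(sprintf("  QALY gain: %.1f (95%% UI %.1f-%.1f)\n",
              s$p50[1], s$p2.5[1], s$p97.5[1]))
  cat(sprintf("  net cost: NZ$%s (95%% UI %s-%s)\n",
              format(round(s$p50[2]), big.mark = ","),
              format(round(s$p2.5[2]), big.mark = ","),
              format(round(s$p97.5[2]), big.mark = ",")))
  cat(sprintf("  ICER: NZ$%s/QALY (95%% UI %s-%s)\n",
              format(round(s$p50[3]), big.mark = ","),
              format(round(s$p2.5[3]), big.mark = ","),
              format(round(s$p97.5[3]), big.mark = ",")))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the proportion of PSA runs that are
#' cost-effective under the net-monetary-benefit rule
#' `lambda * QALY gain - net cost >= 0` (which handles cost-saving and
#' dominated runs coherently, unlike a raw ICER comparison).
#'
#' @param psa An [run_psa()] result (or its `runs` data frame).
#' @param thresholds NZ$/QALY grid.
#' @return Data frame `threshold`, `prob_cost_effective`; the probability is
#'   non-decreasing in the threshold.
#' @export
ceac <- function(psa, thresholds = seq(0, 200000, by = 1000)) {
  runs <- if (inherits(psa, "mslt_psa")) psa$runs else psa
  if (is.null(runs) || nrow(runs) == 0) stop("no PSA runs to summarise")
  prob <- vapply(thresholds, function(l)
    mean(l * runs$qaly_gain - runs$net_cost >= 0), numeric(1))
  structure(data.frame(threshold = thresholds, prob_cost_effective = prob),
            class = c("mslt_ceac", "data.frame"))
}

#' @export
plot.mslt_ceac <- function(x, ...) {
  graphics::plot(x$threshold, x$prob_cost_effective, type = "l", ylim = c(0, 1),
                 xlab = "Cost-effectiveness threshold (NZ$/QALY)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability curve", ...)
  invisible(x)
}

#' @export
plot.mslt_psa <- function(x, thresholds = seq(0, 200000, by = 1000), ...) {
  plot(ceac(x, thresholds), ...)
}

#' One-way (tornado) sensitivity decomposition
#'
#' Each parameter in turn is set to its 2.5th then 97.5th percentile with all
#' others at their central values; the resulting spans of QALY gain, net cost
#' and ICER are recorded and sorted by ICER span width.
#'
#' @param inputs Model inputs.
#' @param spec Central [intervention_spec()].
#' @param dists From [intervention_parameter_distributions()].
#' @param discount_rate Annual discount rate.
#' @param horizon Annual cycles.
#' @return Object of class `mslt_tornado`: a data frame with one row per
#'   parameter (`qaly_lo/hi`, `cost_lo/hi`, `icer_lo/hi`, span widths),
#'   sorted by decreasing ICER span.
#' @export
tornado <- function(inputs, spec = intervention_spec(),
                    dists = intervention_parameter_distributions(spec),
                    discount_rate = 0.03, horizon = 110L) {
  bau <- .mslt_bau(inputs, horizon)
  eval_at <- function(values) {
    spec_r <- spec
    for (nm in names(values)) spec_r[[nm]] <- as.numeric(values[[nm]])
    run <- structure(list(bau = bau,
                          int = .mslt_intervention(inputs, spec_r, bau, horizon),
                          intervention = spec_r, horizon = horizon,
                          strata = names(bau$strata)), class = "mslt_run")
    .cea_totals(run, inputs, discount_rate)
  }
  central <- eval_at(list())
  rows <- lapply(names(dists), function(nm) {
    lo <- eval_at(stats::setNames(list(dists[[nm]]$q(0.025)), nm))
    hi <- eval_at(stats::setNames(list(dists[[nm]]$q(0.975)), nm))
    data.frame(parameter = nm,
               qaly_lo = lo$qaly_gain, qaly_hi = hi$qaly_gain,
               cost_lo = lo$net_cost, cost_hi = hi$net_cost,
               icer_lo = lo$icer, icer_hi = hi$icer)
  })
  out <- do.call(rbind, rows)
  out$qaly_span <- abs(out$qaly_hi - out$qaly_lo)
  out$cost_span <- abs(out$cost_hi - out$cost_lo)
  out$icer_span <- abs(out$icer_hi - out$icer_lo)
  out <- out[order(-out$icer_span), ]
  rownames(out) <- NULL
  structure(list(table = out, central = central),
            class = "mslt_tornado")
}

#' @export
print.mslt_tornado <- function(x, ...) {
  cat("One-way sensitivity (tornado) decomposition\n")
  cat(sprintf("  central: %.2f QALYs, NZ$%s net cost, ICER NZ$%s/QALY\n",
              x$central$qaly_gain,
              format(round(x$central$net_cost), big.mark = ","),
              format(round(x$central$icer), big.mark = ",")))
  t <- x$table
  for (c_ in c("qaly_lo", "qaly_hi")) t[[c_]] <- signif(t[[c_]], 3)
  for (c_ in c("cost_lo", "cost_hi", "icer_lo", "icer_hi",
               "cost_span", "icer_span")) t[[c_]] <- round(t[[c_]])
  print(t, row.names = FALSE)
  invisible(x)
}

#' @export
plot.mslt_tornado <- function(x, what = c("icer", "qaly", "cost"), ...) {
  what <- match.arg(what)
  t <- x$table[order(x$table[[paste0(what, "_span")]]), ]
  lo <- t[[paste0(what, "_lo")]]; hi <- t[[paste0(what, "_hi")]]
  cent <- switch(what, icer = x$central$icer, qaly = x$central$qaly_gain,
                 cost = x$central$net_cost)
  graphics::plot(NA, xlim = range(c(lo, hi, cent)), ylim = c(0.5, nrow(t) + 0.5),
                 yaxt = "n", xlab = switch(what,
                   icer = "ICER (NZ$/QALY)", qaly = "QALY gain",
                   cost = "Net cost (NZ$)"),
                 ylab = "", main = "Tornado plot", ...)
  graphics::axis(2, at = seq_len(nrow(t)), labels = t$parameter, las = 1)
  graphics::segments(lo, seq_len(nrow(t)), hi, seq_len(nrow(t)), lwd = 8,
                     col = "steelblue")
  graphics::abline(v = cent, lty = 2)
  invisible(x)
}
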