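#' Fit the multistate life table cost-effectiveness model
#'
#' The package's main entry point: runs the proportional multistate life table
#' under business-as-usual and the supplied intervention, then the
#' cost-effectiveness analysis, and returns a single model object with
#' `print`, `summary`, `coef`, `simulate` (probabilistic sensitivity
#' analysis) and `plot` methods.
#'
#' @param inputs An [synthetic_inputs()] bundle.
#' @param intervention An [intervention_spec()] (default: the central
#'   mass-media campaign).
#' @param discount_rate Annual discount rate (default 0.03).
#' @param equity_adjusted If `TRUE`, apply [equity_adjust()] to the inputs
#'   before running.
#' @param horizon Annual cycles (default 110).
#' @return Object of class `mslt`.
#' @examples
#' \donttest{
#' inputs <- synthetic_inputs(synthetic_scenario(seed = 1))
#' fit <- mslt(inputs)
#' fit
#' coef(fit)
#' }
#' @export
mslt <- function(inputs, intervention = intervention_spec(),
                 discount_rate = 0.03, equity_adjusted = FALSE,
                 horizon = 110L) {
  if (equity_adjusted) inputs <- equity_adjust(inputs)
  run <- run_mslt(inputs, intervention, horizon)
  res <- cea(run, inputs, discount_rate)
  structure(list(run = run, cea = res, inputs = inputs,
                 intervention = intervention, discount_rate = discount_rate,
                 equity_adjusted = equity_adjusted, horizon = horizon),
            class = "mslt")
}

#' @export
print.mslt <- function(x, ...) {
  cat("Proportional multistate life table cost-effectiveness model\n\n")
  print(x$intervention)
  cat("\n")
  print(x$cea)
  invisible(x)
}

#' @export
coef.mslt <- function(object, ...) {
  c(qaly_gain = object$cea$qaly_gain,
    net_cost = object$cea$net_cost,
    icer = object$cea$icer)
}

#' @export
summary.mslt <- function(object, ...) {
  structure(list(cea = object$cea, by_group = object$cea$by_group,
                 equity_adjusted = object$equity_adjusted),
            class = "summary.mslt")
}

#' @export
print.summary.mslt <- function(x, ...) {
  print(x$cea)
  if (isTRUE(x$equity_adjusted)) cat("  (equity-adjusted background rates)\n")
  cat("\nBy stratum and 2011 age group:\n")
  b <- x$by_group
  b$qaly_per_1000 <- signif(b$qaly_per_1000, 3)
  b$qaly_gain <- signif(b$qaly_gain, 3)
  b$net_cost <- round(b$net_cost)
  b$icer <- round(b$icer, -2)
  b$population <- round(b$population)
  print(b, row.names = FALSE)
  invisible(x)
}

#' @rdname mslt
#' @param object An `mslt` model.
#' @param nsim Number of Monte Carlo parameter draws (the headline analysis
#'   uses 2000).
#' @param seed Master RNG seed for the draws.
#' @param ... Passed to [run_psa()].
#' @export
simulate.mslt <- function(object, nsim = 2000, seed = 1L, ...) {
  dists <- intervention_parameter_distributions(object$intervention)
  draws <- sample_parameters(dists, nsim, seed)
  run_psa(object$inputs, object$intervention, draws,
          discount_rate = object$discount_rate, bau = object$run$bau, ...)
}
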