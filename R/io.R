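# Delimited-text exchange for the input bundle.  Every table carries one
# schema-version header line so consumers can detect format drift.

.SCHEMA <- "# pamslt-schema 1"

.write_table <- function(df, path) {
  # 17 significant digits so numeric round-trips are bit-exact
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- format(df[[j]], digits = 17, trim = TRUE, scientific = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.SCHEMA, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

.read_table <- function(path) {
  header <- readLines(path, n = 1)
  if (!identical(header, .SCHEMA))
    stop("unrecognised schema header in ", path, ": ", header)
  utils::read.csv(path, skip = 1)
}

#' Write an input bundle as CSV tables
#'
#' Writes `population.csv`, `disease_epi.csv`, `diseases.csv`,
#' `exposure.csv`, `costs.csv`, `unrelated_costs.csv` and `rr.csv` into a
#' directory, each with a schema-version header line.
#'
#' @param inputs An [synthetic_inputs()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_inputs <- function(inputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_table(inputs$population, file.path(dir, "population.csv"))
  .write_table(inputs$epi, file.path(dir, "disease_epi.csv"))
  .write_table(inputs$diseases, file.path(dir, "diseases.csv"))
  expo <- do.call(rbind, lapply(names(inputs$exposure), function(s) {
    d <- inputs$exposure[[s]]
    data.frame(stratum = s, bin_lo = d$lower, bin_hi = d$upper,
               midpoint = d$midpoint, proportion = d$proportion)
  }))
  .write_table(expo, file.path(dir, "exposure.csv"))
  .write_table(inputs$costs$disease_costs, file.path(dir, "costs.csv"))
  .write_table(inputs$costs$unrelated, file.path(dir, "unrelated_costs.csv"))
  rr <- do.call(rbind, lapply(inputs$costs$rr, function(r)
    data.frame(disease = r$disease, slope = r$slope, floor = r$floor,
               anchor = r$anchor)))
  .write_table(rr, file.path(dir, "rr.csv"))
  invisible(dir)
}

#' Read an input bundle from CSV tables
#'
#' Inverse of [write_inputs()].  Distributions and relative-risk functions
#' are reconstructed; re-running the model from a written bundle reproduces
#' results exactly.
#'
#' @param dir Directory holding the tables.
#' @return An `mslt_inputs` bundle.
#' @export
read_inputs <- function(dir) {
  population <- .read_table(file.path(dir, "population.csv"))
  epi <- .read_table(file.path(dir, "disease_epi.csv"))
  diseases <- .read_table(file.path(dir, "diseases.csv"))
  expo <- .read_table(file.path(dir, "exposure.csv"))
  exposure <- lapply(split(expo, expo$stratum), function(d)
    exposure_distribution(d$proportion,
                          data.frame(lower = d$bin_lo, upper = d$bin_hi,
                                     midpoint = d$midpoint)))
  rr_tab <- .read_table(file.path(dir, "rr.csv"))
  rr <- lapply(seq_len(nrow(rr_tab)), function(k)
    relative_risk_function(rr_tab$disease[k], rr_tab$slope[k],
                           rr_tab$floor[k], rr_tab$anchor[k]))
  names(rr) <- rr_tab$disease
  structure(list(population = population, epi = epi, diseases = diseases,
                 exposure = exposure,
                 costs = list(disease_costs = .read_table(file.path(dir, "costs.csv")),
                              unrelated = .read_table(file.path(dir, "unrelated_costs.csv")),
                              rr = rr),
                 spec = strata_spec(), scenario = NULL),
            class = "mslt_inputs")
}
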