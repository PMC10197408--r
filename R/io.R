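microdata_schema <- function() {
  list(
    required = c("person_id", "country_code", "household_id", "stratum_id",
                 "cluster_id", "sample_weight", "age_years", "age_band",
                 "gender", "marital", "education", "chronic", "smoke",
                 "drink", "income_pc", "adl", "iadl", "mobility"),
    vocab = list(
      age_band = age_bands(),
      gender = c("male", "female"),
      marital = c("married", "other"),
      education = c("less than upper secondary",
                    "upper secondary and vocational training", "tertiary"),
      chronic = c(0, 1), smoke = c(0, 1), drink = c(0, 1),
      adl = c(0, 1), iadl = c(0, 1), mobility = c(0, 1)))
}

#' Validate survey microdata against the package schema
#'
#' Checks required columns, value vocabularies, positive weights, the age
#' floor of 55 years, nonnegative income and the household-consistency
#' invariant (identical per-capita income within a household).  Unknown
#' extra columns raise a warning; violations raise an error naming the
#' offending column and value.
#'
#' @param data data frame to validate.
#' @return the data, invisibly, on success.
#' @export
validate_microdata <- function(data) {
  sch <- microdata_schema()
  missing_cols <- setdiff(sch$required, names(data))
  if (length(missing_cols))
    stop("validate_microdata: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(data), sch$required)
  if (length(extra))
    warning("validate_microdata: unknown column(s) ignored: ",
            paste(extra, collapse = ", "))
  for (v in names(sch$vocab)) {
    bad <- setdiff(unique(data[[v]][!is.na(data[[v]])]), sch$vocab[[v]])
    if (length(bad))
      stop("validate_microdata: invalid value(s) in '", v, "': ",
           paste(bad, collapse = ", "))
  }
  if (anyNA(data$sample_weight) || any(data$sample_weight <= 0))
    stop("validate_microdata: 'sample_weight' must be strictly positive")
  if (anyNA(data$age_years) || any(data$age_years < 55))
    stop("validate_microdata: 'age_years' must be >= 55")
  if (anyNA(data$income_pc) || any(data$income_pc < 0))
    stop("validate_microdata: 'income_pc' must be nonnegative and complete")
  rng <- tapply(data$income_pc, data$household_id,
                function(x) max(x) - min(x))
  if (any(rng > 1e-9))
    stop("validate_microdata: per-capita income differs within household(s): ",
         paste(utils::head(names(rng)[rng > 1e-9], 3L), collapse = ", "))
  invisible(data)
}

#' Read survey microdata from CSV
#'
#' Reads a UTF-8 CSV written by [write_microdata()] (or any file matching
#' the documented schema) and validates it with [validate_microdata()].
#'
#' @param path CSV path.
#' @return validated microdata data frame.
#' @export
read_microdata <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_microdata(data)
  data
}

#' Write survey microdata to CSV
#'
#' Writes the microdata with a fixed column order (schema columns first) in
#' UTF-8, full precision, so that a read-write cycle round-trips losslessly.
#'
#' @param data microdata.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(data, path) {
  sch <- microdata_schema()
  cols <- c(sch$required, setdiff(names(data), sch$required))
  utils::write.csv(data[, cols, drop = FALSE], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Format an index value to four decimals
#' @param x numeric.
#' @return character, e.g. `-0.0857`.
#' @export
format_index <- function(x) sprintf("%.4f", x)

#' Format a percentage to one decimal
#' @param x numeric percentage.
#' @return character, e.g. `16.6`.
#' @export
format_percent <- function(x) sprintf("%.1f", x)

#' Write a result table as TSV with fixed formatting
#'
#' Deterministic column order (as supplied) and fixed decimal formatting:
#' four decimals for index-scale columns (`index`, `se`, `ci_low`,
#' `ci_high`, `estimate`, `p_value` when on the index scale is kept at four
#' decimals too), one decimal for percentage columns (`prevalence`,
#' `pct_difference`).  Columns not listed are written as-is.
#'
#' @param table data frame.
#' @param path output TSV path.
#' @param index_cols,percent_cols column-name sets to format.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path,
                        index_cols = c("index", "se", "ci_low", "ci_high",
                                       "estimate", "p_value"),
                        percent_cols = c("prevalence", "pct_difference")) {
  out <- table
  pct <- intersect(percent_cols, names(out))
  # percentage tables carry their CIs on the percent scale too
  if (length(pct)) index_cols <- setdiff(index_cols, c("ci_low", "ci_high"))
  for (v in intersect(index_cols, names(out))) {
    out[[v]] <- format_index(out[[v]])
  }
  for (v in c(pct, intersect(c("ci_low", "ci_high"), if (length(pct))
                             names(out) else character(0)))) {
    out[[v]] <- format_percent(out[[v]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
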