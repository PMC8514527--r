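# CSV schemas (column order is the contract for both readers and writers)
CLIMMORT_SCHEMAS <- list(
  covariates = c("country", "hottest_month_temp", "coldest_month_temp",
                 "gdp_pc_ppp", "population", "mortality_rate"),
  responses  = c("country", "scenario", "period", "dT", "y_hot", "y_cold"),
  warming    = c("country", "scenario", "period", "dT"),
  income     = c("country", "scenario", "year", "gdp_pc_ppp"),
  projections = c("country", "scenario", "period", "adaptation", "dT",
                  "y_hot", "y_cold", "y_net", "se_net", "ci_low", "ci_high"),
  global_summary = c("scenario", "period", "adaptation", "y_hot_global",
                     "y_cold_global", "y_net_global", "se_net", "ci_low",
                     "ci_high", "weight_scheme", "n_countries"),
  curve = c("global_dT", "global_dT_preindustrial", "y_hot", "y_cold",
            "y_net", "ci_low", "ci_high")
)
CLIMMORT_SCHEMA_VERSION <- "v1"

#' Normalize country identifiers to ISO-3166 alpha-3
#'
#' Uppercases and trims identifiers and maps a small alias table of common
#' country-name variants (the 23-country estimation panel and frequent
#' spellings) onto ISO-3166 alpha-3 codes; anything already three letters
#' is passed through unchanged.
#'
#' @param x Character vector of country names or codes.
#' @return Character vector of normalized identifiers.
#' @export
normalize_country <- function(x) {
  aliases <- c(
    "CANADA" = "CAN", "USA" = "USA", "UNITED STATES" = "USA",
    "UNITED STATES OF AMERICA" = "USA", "MEXICO" = "MEX", "BRAZIL" = "BRA",
    "CHILE" = "CHL", "FINLAND" = "FIN", "IRELAND" = "IRL", "SWEDEN" = "SWE",
    "UK" = "GBR", "UNITED KINGDOM" = "GBR", "GREAT BRITAIN" = "GBR",
    "CZECH REPUBLIC" = "CZE", "CZECHIA" = "CZE", "FRANCE" = "FRA",
    "MOLDOVA" = "MDA", "REPUBLIC OF MOLDOVA" = "MDA",
    "SWITZERLAND" = "CHE", "ITALY" = "ITA", "SPAIN" = "ESP",
    "CHINA" = "CHN", "JAPAN" = "JPN", "SOUTH KOREA" = "KOR",
    "REPUBLIC OF KOREA" = "KOR", "KOREA" = "KOR",
    "PHILIPPINES" = "PHL", "TAIWAN" = "TWN", "THAILAND" = "THA",
    "VIETNAM" = "VNM", "VIET NAM" = "VNM", "AUSTRALIA" = "AUS",
    "GLOBAL" = "GLOBAL"
  )
  up <- toupper(trimws(x))
  hit <- aliases[up]
  out <- ifelse(is.na(hit), up, hit)
  unname(out)
}

# internal: first-failure row/column error, naming the file
check_rows <- function(df, file, checks) {
  for (col in names(checks)) {
    bad <- which(!checks[[col]](df[[col]]))
    if (length(bad) > 0) {
      abort_climmort("%s: invalid value in column '%s' at row %d (value: %s)",
                     file, col, bad[1], format(df[[col]][bad[1]]))
    }
  }
  invisible(df)
}

read_schema_csv <- function(path, schema) {
  if (!file.exists(path)) abort_climmort("file not found: %s", path)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  miss <- setdiff(CLIMMORT_SCHEMAS[[schema]], names(df))
  if (length(miss) > 0) {
    abort_climmort("%s: missing required column(s): %s",
                   path, paste(miss, collapse = ", "))
  }
  df
}

#' Read and validate pipeline input tables
#'
#' Each reader enforces its CSV schema (see the package README for column
#' lists), normalizes country identifiers, and rejects unit violations with
#' an error naming the file, row and column — e.g. nonpositive per-capita
#' GDP, mortality rates outside `[0, 1)`, negative population, a hottest
#' month colder than the coldest month, negative warming in a response
#' table, or duplicated `(country, scenario, period)` keys.  Lines starting
#' with `#` (schema-version headers) are skipped.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @name read_tables
#' @export
read_covariates <- function(path) {
  df <- read_schema_csv(path, "covariates")
  df$country <- normalize_country(df$country)
  check_rows(df, path, list(
    gdp_pc_ppp = function(x) is.finite(x) & x > 0,
    population = function(x) is.finite(x) & x >= 0,
    mortality_rate = function(x) is.finite(x) & x >= 0 & x < 1
  ))
  bad <- which(df$hottest_month_temp < df$coldest_month_temp)
  if (length(bad) > 0) {
    abort_climmort("%s: hottest_month_temp < coldest_month_temp at row %d (%s)",
                   path, bad[1], df$country[bad[1]])
  }
  if (anyDuplicated(df$country)) {
    abort_climmort("%s: duplicated country '%s'",
                   path, df$country[anyDuplicated(df$country)])
  }
  df$log_gdp_pc <- log(df$gdp_pc_ppp)
  tibble::as_tibble(df)
}

#' @rdname read_tables
#' @export
read_responses <- function(path) {
  df <- read_schema_csv(path, "responses")
  df$country <- normalize_country(df$country)
  check_rows(df, path, list(
    dT = function(x) is.finite(x) & x >= 0,
    y_hot = is.finite, y_cold = is.finite
  ))
  key <- paste(df$country, df$scenario, df$period)
  if (anyDuplicated(key)) {
    abort_climmort("%s: duplicated (country, scenario, period) key: %s",
                   path, key[anyDuplicated(key)])
  }
  tibble::as_tibble(df)
}

#' @rdname read_tables
#' @export
read_warming <- function(path) {
  df <- read_schema_csv(path, "warming")
  df$country <- normalize_country(df$country)
  # dT may be NA (country without projection data) but never infinite
  bad <- which(!is.na(df$dT) & !is.finite(df$dT))
  if (length(bad) > 0) {
    abort_climmort("%s: non-finite dT at row %d", path, bad[1])
  }
  tibble::as_tibble(df)
}

#' @rdname read_tables
#' @export
read_income <- function(path) {
  df <- read_schema_csv(path, "income")
  df$country <- normalize_country(df$country)
  check_rows(df, path, list(
    year = function(x) is.finite(x),
    gdp_pc_ppp = function(x) is.finite(x) & x > 0
  ))
  tibble::as_tibble(df)
}

#' Referential-integrity check across the input bundle
#'
#' Verifies that every country referenced by the response table, the
#' warming field and the income paths has a covariate record, and errors
#' (naming the countries) on responses without covariates; warming/income
#' gaps are reported, not fatal, because projection handles them as
#' explicit missing rows.
#'
#' @param covariates,responses,warming,income Input tibbles (the last three
#'   optional).
#' @return Invisibly, a report tibble `table`, `country`, `status`.
#' @export
validate_bundle <- function(covariates, responses = NULL, warming = NULL,
                            income = NULL) {
  report <- tibble::tibble(table = character(), country = character(),
                           status = character())
  if (!is.null(responses)) {
    miss <- setdiff(unique(responses$country), covariates$country)
    if (length(miss) > 0) {
      abort_climmort("response table references country without covariates: %s",
                     paste(miss, collapse = ", "))
    }
  }
  for (nm in c("warming", "income")) {
    tab <- get(nm)
    if (is.null(tab)) next
    miss <- setdiff(setdiff(unique(tab$country), GLOBAL_ID),
                    covariates$country)
    if (length(miss) > 0) {
      report <- dplyr::bind_rows(report, tibble::tibble(
        table = nm, country = miss, status = "no covariate record"))
    }
  }
  invisible(report)
}

#' Write a pipeline table with its schema header
#'
#' Writes `df` as CSV preceded by a comment line
#' `# climmort <schema> <version>` identifying the schema, with columns in
#' the documented order (extra columns are dropped; list columns such as
#' design vectors never reach the file).
#'
#' @param df Tibble to write.
#' @param path Output path.
#' @param schema One of `names(CLIMMORT_SCHEMAS)`:
#'   covariates, responses, warming, income, projections, global_summary,
#'   curve.
#' @return `path`, invisibly.
#' @export
write_climmort_csv <- function(df, path, schema) {
  if (!schema %in% names(CLIMMORT_SCHEMAS)) {
    abort_climmort("unknown schema '%s'", schema)
  }
  cols <- intersect(CLIMMORT_SCHEMAS[[schema]], names(df))
  miss <- setdiff(CLIMMORT_SCHEMAS[[schema]], names(df))
  if (length(miss) > 0) {
    abort_climmort("cannot write schema '%s': missing column(s) %s",
                   schema, paste(miss, collapse = ", "))
  }
  writeLines(sprintf("# climmort %s %s", schema, CLIMMORT_SCHEMA_VERSION),
             path)
  readr::write_csv(df[cols], path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
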