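#' Read and write contact-survey tables
#'
#' Plain-CSV serialisation of the observation schema produced by
#' [simulate_population()]. Dates are ISO-8601, missing values are empty
#' fields, categorical levels are validated on read, and a write/read
#' cycle is lossless. Latent truth columns (`true_*`) are never written.
#'
#' @param table a schema-valid observation table.
#' @param path file path.
#' @param count_cap cap used to validate `y` on read.
#' @return `read_survey_csv()` returns the validated `data.frame`;
#'   `write_survey_csv()` returns `path` invisibly.
#' @name survey_csv
NULL

survey_factor_levels <- function() {
  list(weekday = levels_weekday(), age_group = levels_age(),
       sex = levels_sex(), household_size = levels_hh(),
       occupation = levels_occupation(), vaccination_status = levels_vax(),
       pre_health = c("yes", "no"), quarantine = c("yes", "no"),
       risk_perception = levels_risk(), infection_status = levels_infection())
}

survey_columns <- function() {
  c("participant_id", "wave_index", "report_date", "contact_date",
    "weekday", "day_of_year", "district_id", "y", "age_group", "sex",
    "household_size", "occupation", "vaccination_status",
    "first_dose_date", "days_since_first_dose", "pre_health",
    "quarantine", "risk_perception", "infection_status",
    "n_waves_joined", "SI", "trend", "mortality")
}

#' @rdname survey_csv
#' @export
write_survey_csv <- function(table, path) {
  cols <- survey_columns()
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- table[cols]
  for (dc in c("report_date", "contact_date", "first_dose_date"))
    out[[dc]] <- format(out[[dc]], "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname survey_csv
#' @export
read_survey_csv <- function(path, count_cap = 100L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", colClasses = "character")
  missing_cols <- setdiff(survey_columns(), names(raw))
  if (length(missing_cols))
    stop("survey file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  parse_date <- function(col) {
    x <- raw[[col]]
    d <- as.Date(x, format = "%Y-%m-%d")
    bad <- which(!is.na(x) & is.na(d))
    if (length(bad))
      stop(sprintf("row %d, field %s: malformed date '%s'",
                   bad[1L], col, x[bad[1L]]), call. = FALSE)
    d
  }
  parse_num <- function(col) {
    x <- raw[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop(sprintf("row %d, field %s: not numeric '%s'",
                   bad[1L], col, x[bad[1L]]), call. = FALSE)
    v
  }
  parse_factor <- function(col, levs) {
    x <- raw[[col]]
    bad <- which(!is.na(x) & !(x %in% levs))
    if (length(bad))
      stop(sprintf("row %d, field %s: unknown level '%s'",
                   bad[1L], col, x[bad[1L]]), call. = FALSE)
    factor(x, levels = levs)
  }

  out <- data.frame(
    participant_id = as.integer(parse_num("participant_id")),
    wave_index = as.integer(parse_num("wave_index")),
    report_date = parse_date("report_date"),
    contact_date = parse_date("contact_date"),
    weekday = parse_factor("weekday", levels_weekday()),
    day_of_year = as.integer(parse_num("day_of_year")),
    district_id = as.integer(parse_num("district_id")),
    y = as.integer(parse_num("y")),
    age_group = parse_factor("age_group", levels_age()),
    sex = parse_factor("sex", levels_sex()),
    household_size = parse_factor("household_size", levels_hh()),
    occupation = parse_factor("occupation", levels_occupation()),
    vaccination_status = parse_factor("vaccination_status", levels_vax()),
    first_dose_date = parse_date("first_dose_date"),
    days_since_first_dose = parse_num("days_since_first_dose"),
    pre_health = parse_factor("pre_health", c("yes", "no")),
    quarantine = parse_factor("quarantine", c("yes", "no")),
    risk_perception = parse_factor("risk_perception", levels_risk()),
    infection_status = parse_factor("infection_status", levels_infection()),
    n_waves_joined = as.integer(parse_num("n_waves_joined")),
    SI = parse_num("SI"),
    trend = parse_num("trend"),
    mortality = parse_num("mortality"),
    stringsAsFactors = FALSE
  )
  validate_survey(out, count_cap = count_cap)
  out
}

#' Validate a contact-survey table against the observation schema
#'
#' Checks counts against the cap, day-of-year bounds, the rule that
#' `days_since_first_dose` is present exactly when `first_dose_date`
#' is, and weekday consistency with the contact date. Errors name the
#' first offending row and field.
#'
#' @param table observation table.
#' @param count_cap maximum admissible contact count.
#' @return The table, invisibly.
#' @export
validate_survey <- function(table, count_cap = 100L) {
  fail <- function(rows, field, msg) {
    if (length(rows))
      stop(sprintf("row %d, field %s: %s", rows[1L], field, msg),
           call. = FALSE)
  }
  fail(which(is.na(table$y) | table$y < 0L | table$y > count_cap), "y",
       sprintf("count outside [0, %d]", count_cap))
  fail(which(table$day_of_year < 1L | table$day_of_year > 366L),
       "day_of_year", "outside [1, 366]")
  fail(which(is.na(table$first_dose_date) !=
               is.na(table$days_since_first_dose)),
       "days_since_first_dose",
       "must be present exactly when first_dose_date is")
  wd <- levels_weekday()[as.integer(format(table$contact_date, "%u"))]
  fail(which(!is.na(table$weekday) & as.character(table$weekday) != wd),
       "weekday", "inconsistent with contact_date")
  fail(which(table$n_waves_joined < 1L), "n_waves_joined", "must be >= 1")
  invisible(table)
}
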