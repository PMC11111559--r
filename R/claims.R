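MEDICAL_COLS <- c("claim_id", "member_id", "service_date", "discharge_date",
                  "setting", "dx_codes", "proc_codes", "paid_amount")
PHARMACY_COLS <- c("claim_id", "member_id", "fill_date", "drug_code", "paid_amount")
ENROLLMENT_COLS <- c("member_id", "start_date", "end_date")
MEMBER_COLS <- c("member_id", "birth_year", "sex", "payer", "region")

SETTINGS <- c("inpatient", "emergency_room", "physician_office", "other_outpatient")
SEXES <- c("male", "female")
PAYERS <- c("commercial", "medicare", "medicaid", "unknown")
REGIONS <- c("northeast", "midwest", "south", "west", "unknown")

parse_date_col <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(as.character(x), format = "%Y-%m-%d", optional = TRUE)
}

check_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0(what, " table missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
}

# validate one table; returns list(valid = tibble, rejects = tibble(row, id, reason))
validate_table <- function(df, what) {
  df <- as_tibble(df)
  reasons <- rep(NA_character_, nrow(df))
  note <- function(bad, why) {
    new <- bad & is.na(reasons)
    reasons[new] <<- why
  }
  if (what == "medical") {
    check_cols(df, MEDICAL_COLS, what)
    df$service_date <- parse_date_col(df$service_date)
    df$discharge_date <- parse_date_col(df$discharge_date)
    df$paid_amount <- suppressWarnings(as.numeric(df$paid_amount))
    df$dx_codes <- ifelse(is.na(df$dx_codes), "", as.character(df$dx_codes))
    df$proc_codes <- ifelse(is.na(df$proc_codes), "", as.character(df$proc_codes))
    note(is.na(df$service_date), "unparseable or missing service_date")
    note(!df$setting %in% SETTINGS, "unknown setting")
    note(df$setting == "inpatient" & is.na(df$discharge_date),
         "inpatient claim lacking discharge_date")
    note(df$setting != "inpatient" & !is.na(df$discharge_date),
         "discharge_date on non-inpatient claim")
    note(!is.na(df$discharge_date) & !is.na(df$service_date) &
           df$discharge_date < df$service_date,
         "discharge_date before service_date")
    note(is.na(df$paid_amount) | df$paid_amount < 0, "negative or missing paid_amount")
    id <- df$claim_id
  } else if (what == "pharmacy") {
    check_cols(df, PHARMACY_COLS, what)
    df$fill_date <- parse_date_col(df$fill_date)
    df$paid_amount <- suppressWarnings(as.numeric(df$paid_amount))
    df$drug_code <- as.character(df$drug_code)
    note(is.na(df$fill_date), "unparseable or missing fill_date")
    note(is.na(df$drug_code) | !nzchar(df$drug_code), "missing drug_code")
    note(is.na(df$paid_amount) | df$paid_amount < 0, "negative or missing paid_amount")
    id <- df$claim_id
  } else if (what == "enrollment") {
    check_cols(df, ENROLLMENT_COLS, what)
    df$start_date <- parse_date_col(df$start_date)
    df$end_date <- parse_date_col(df$end_date)
    note(is.na(df$start_date) | is.na(df$end_date), "unparseable or missing span date")
    note(!is.na(df$start_date) & !is.na(df$end_date) & df$start_date > df$end_date,
         "start_date after end_date")
    id <- df$member_id
  } else { # members
    check_cols(df, MEMBER_COLS, what)
    df$birth_year <- suppressWarnings(as.integer(df$birth_year))
    note(is.na(df$birth_year), "unparseable or missing birth_year")
    note(!df$sex %in% SEXES, "unknown sex")
    note(!df$payer %in% PAYERS, "unknown payer")
    note(!df$region %in% REGIONS, "unknown region")
    note(duplicated(df$member_id), "duplicate member_id")
    id <- df$member_id
  }
  bad <- !is.na(reasons)
  rejects <- tibble(table = what, row = which(bad),
                    id = as.character(id[bad]), reason = reasons[bad])
  list(valid = df[!bad, , drop = FALSE], rejects = rejects)
}

#' Assemble and validate a claims dataset
#'
#' Bundles the four claim tables into a validated `fn_claims` dataset. Rows
#' violating a type invariant (e.g. an inpatient claim without a discharge
#' date, a negative paid amount, an unparseable date) are rejected with
#' row-level diagnostics: a warning summarises them and the full reject table
#' is attached as `attr(x, "rejections")`.
#'
#' `dx_codes` and `proc_codes` are `";"`-separated code strings (possibly
#' empty); dates are ISO-8601 calendar dates.
#'
#' @param medical,pharmacy,enrollment,members Data frames with the documented
#'   column schemas (see `MEDICAL_COLS` etc. in the package source, or the
#'   README).
#' @return An `fn_claims` object: a list of validated tibbles `medical`,
#'   `pharmacy`, `enrollment`, `members`.
#' @export
fn_claims <- function(medical, pharmacy, enrollment, members) {
  vm <- validate_table(medical, "medical")
  vp <- validate_table(pharmacy, "pharmacy")
  ve <- validate_table(enrollment, "enrollment")
  vb <- validate_table(members, "members")
  rejects <- bind_rows(vm$rejects, vp$rejects, ve$rejects, vb$rejects)
  if (nrow(rejects) > 0) {
    warn(paste0(nrow(rejects), " row(s) rejected during validation; first: ",
                rejects$table[1], " row ", rejects$row[1], " (id ", rejects$id[1],
                "): ", rejects$reason[1]))
  }
  out <- structure(list(
    medical = vm$valid, pharmacy = vp$valid,
    enrollment = ve$valid, members = vb$valid
  ), class = "fn_claims")
  attr(out, "rejections") <- rejects
  out
}

#' @export
print.fn_claims <- function(x, ...) {
  cat("<fn_claims> ", nrow(x$medical), " medical / ", nrow(x$pharmacy),
      " pharmacy claims, ", nrow(x$enrollment), " enrollment spans, ",
      nrow(x$members), " members\n", sep = "")
  invisible(x)
}

#' Load a claims dataset from CSV files
#'
#' Reads the four tables from CSV (columns as documented in [fn_claims()]),
#' parses ISO-8601 dates, and validates. A missing required column raises a
#' schema error naming the column; rows with unparseable dates or other
#' invariant violations are rejected with row-level diagnostics.
#'
#' @param medical_path,pharmacy_path,enrollment_path,members_path CSV file paths.
#' @return A validated `fn_claims` dataset.
#' @export
load_claims <- function(medical_path, pharmacy_path, enrollment_path, members_path) {
  for (p in c(medical_path, pharmacy_path, enrollment_path, members_path)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  rd <- function(p) readr::read_csv(p, col_types = readr::cols(.default = readr::col_character()),
                                    progress = FALSE)
  fn_claims(rd(medical_path), rd(pharmacy_path), rd(enrollment_path), rd(members_path))
}

#' Write a claims dataset to CSV files
#'
#' Inverse of [load_claims()]: writes `medical.csv`, `pharmacy.csv`,
#' `enrollment.csv`, `members.csv` under `dir`. Round-trips record-for-record
#' on valid input.
#'
#' @param dataset An `fn_claims` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_claims <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fn_claims"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("medical.csv", "pharmacy.csv", "enrollment.csv", "members.csv"))
  readr::write_csv(dataset$medical, paths[1], progress = FALSE)
  readr::write_csv(dataset$pharmacy, paths[2], progress = FALSE)
  readr::write_csv(dataset$enrollment, paths[3], progress = FALSE)
  readr::write_csv(dataset$members, paths[4], progress = FALSE)
  invisible(paths)
}

# merge overlapping/adjacent (gap <= 1 day) enrollment spans per member
merge_enrollment <- function(enrollment) {
  if (nrow(enrollment) == 0) {
    return(select(enrollment, "member_id", "start_date", "end_date"))
  }
  enrollment %>%
    arrange(.data$member_id, .data$start_date) %>%
    group_by(.data$member_id) %>%
    mutate(grp = cumsum(c(1, as.integer(
      .data$start_date[-1] > cummax(as.integer(.data$end_date))[-n()] + 1)))) %>%
    group_by(.data$member_id, .data$grp) %>%
    summarise(start_date = min(.data$start_date),
              end_date = max(.data$end_date), .groups = "drop") %>%
    select(-"grp")
}
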