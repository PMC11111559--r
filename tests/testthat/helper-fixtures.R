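# In-code fixture builders: small hand-made claims datasets.

`%||%` <- function(x, y) if (is.null(x)) y else x

d0 <- as.Date("2018-06-01") # reference date used by most hand fixtures

mk_medical <- function(..., claim_id = NULL) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      member_id = r$member_id,
      service_date = as.Date(r$date),
      discharge_date = as.Date(r$discharge %||% NA),
      setting = r$setting %||% "physician_office",
      dx_codes = r$dx %||% "",
      proc_codes = r$proc %||% "",
      paid_amount = r$paid %||% 100,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(df)) {
    df <- data.frame(member_id = character(), service_date = as.Date(character()),
                     discharge_date = as.Date(character()), setting = character(),
                     dx_codes = character(), proc_codes = character(),
                     paid_amount = numeric())
  }
  df$claim_id <- claim_id %||% sprintf("MC%03d", seq_len(nrow(df)))
  df
}

mk_pharmacy <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(member_id = r$member_id, fill_date = as.Date(r$date),
               drug_code = r$drug, paid_amount = r$paid %||% 50,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(member_id = character(), fill_date = as.Date(character()),
                     drug_code = character(), paid_amount = numeric())
  }
  df$claim_id <- sprintf("RX%03d", seq_len(nrow(df)))
  df
}

mk_members <- function(ids, birth_year = 1960, sex = "female",
                       payer = "commercial", region = "south") {
  data.frame(member_id = ids,
             birth_year = rep_len(birth_year, length(ids)),
             sex = rep_len(sex, length(ids)),
             payer = rep_len(payer, length(ids)),
             region = rep_len(region, length(ids)),
             stringsAsFactors = FALSE)
}

mk_enrollment <- function(ids, start = d0 - 400, end = d0 + 400) {
  data.frame(member_id = ids,
             start_date = rep_len(as.Date(start), length(ids)),
             end_date = rep_len(as.Date(end), length(ids)),
             stringsAsFactors = FALSE)
}

# a dataset with one clean qualifying episode for `member`:
# chemo at index-10, inpatient FN trigger at index, full enrollment
mk_simple_dataset <- function(member = "A", index = d0, cs = test_codesets(),
                              extra_medical = NULL, extra_pharmacy = NULL) {
  med <- mk_medical(
    list(member_id = member, date = index - 10, setting = "other_outpatient",
         proc = cs$chemo_drugs$gemcitabine[1]),
    list(member_id = member, date = index, setting = "inpatient",
         discharge = index + 5,
         dx = paste(cs$sets$neutropenia_dx[1], cs$sets$fever_dx[1], sep = ";"))
  )
  if (!is.null(extra_medical)) {
    extra_medical$claim_id <- sprintf("MX%03d", seq_len(nrow(extra_medical)))
    med <- rbind(med, extra_medical)
  }
  ph <- if (is.null(extra_pharmacy)) mk_pharmacy() else extra_pharmacy
  suppressWarnings(fn_claims(med, ph, mk_enrollment(member), mk_members(member)))
}

test_codesets <- local({
  cs <- NULL
  function() {
    if (is.null(cs)) cs <<- load_codesets()
    cs
  }
})

flat_cpi <- c(`2014` = 100, `2015` = 100, `2016` = 100, `2017` = 100,
              `2018` = 100, `2019` = 100, `2020` = 100, `2021` = 100)
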