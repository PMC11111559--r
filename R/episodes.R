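ATTRITION_LABELS <- c(
  "candidates",
  "chemo_within_lookback",
  "continuous_enrollment",
  "clean_pre_period",
  "no_bmt_sct_cart",
  "no_excluded_heme_malignancy",
  "no_covid",
  "washout"
)

#' Detect candidate index events
#'
#' Scans the claims for (member, date) pairs meeting either case definition:
#'
#' * **inpatient definition** — the union of diagnoses on the member's
#'   inpatient claims of that date contains a neutropenia code *and* a
#'   fever/bacterial-infection/fungal-infection code;
#' * **outpatient definition** — the same diagnosis combination on the
#'   member's outpatient claims (emergency room, physician office, other
#'   outpatient) of that date, *plus* same-day evidence of an
#'   NCCN-recommended antibiotic: a pharmacy fill satisfying one of the
#'   configured oral combination rules, or a medical claim carrying a
#'   parenteral-antibiotic procedure code.
#'
#' When both definitions fire on the same date the candidate is recorded as
#' `inpatient_def`.
#'
#' @param dataset An `fn_claims` dataset.
#' @param codesets An `fn_codesets` registry.
#' @return Tibble of candidates: `member_id`, `index_date`, `trigger`
#'   (`inpatient_def`/`outpatient_def`), `triggering_claim_ids`
#'   (`";"`-separated).
#' @export
detect_candidates <- function(dataset, codesets) {
  med <- dataset$medical
  if (nrow(med) == 0) {
    return(tibble(member_id = character(), index_date = as.Date(character()),
                  trigger = character(), triggering_claim_ids = character()))
  }
  neut <- codes_match_any(med$dx_codes, codesets$sets$neutropenia_dx)
  fbf <- codes_match_any(med$dx_codes, cs_infection_fever_dx(codesets))
  parenteral <- codes_match_any(med$proc_codes,
                                codesets$sets$nccn_parenteral_antibiotic_proc)
  inp <- med$setting == "inpatient"

  day <- med %>%
    mutate(neut = neut, fbf = fbf, parenteral = parenteral, inp = inp) %>%
    filter(.data$neut | .data$fbf | .data$parenteral) %>%
    group_by(.data$member_id, date = .data$service_date) %>%
    summarise(
      inp_def = any(.data$neut & .data$inp) & any(.data$fbf & .data$inp),
      outp_def = any(.data$neut & !.data$inp) & any(.data$fbf & !.data$inp),
      parenteral = any(.data$parenteral),
      claim_ids = list(.data$claim_id[(.data$neut | .data$fbf)]),
      .groups = "drop"
    )

  # same-day oral antibiotic evidence from pharmacy fills
  ph <- dataset$pharmacy
  oral_ok <- function(member, date) {
    fills <- ph$drug_code[ph$member_id == member & ph$fill_date == date]
    any(vapply(codesets$oral_antibiotic_rules, function(rule) {
      all(vapply(rule, function(g) any(fills %in% codesets$sets[[g]]), logical(1)))
    }, logical(1)))
  }
  need_oral <- day$outp_def & !day$inp_def & !day$parenteral
  day$oral <- FALSE
  if (any(need_oral)) {
    idx <- which(need_oral)
    day$oral[idx] <- mapply(oral_ok, day$member_id[idx], day$date[idx])
  }

  day %>%
    mutate(abx = .data$parenteral | .data$oral) %>%
    filter(.data$inp_def | (.data$outp_def & .data$abx)) %>%
    mutate(trigger = if_else(.data$inp_def, "inpatient_def", "outpatient_def"),
           triggering_claim_ids = vapply(.data$claim_ids, paste, character(1),
                                         collapse = ";")) %>%
    select(member_id = "member_id", index_date = "date",
           "trigger", "triggering_claim_ids") %>%
    arrange(.data$member_id, .data$index_date)
}

# internal: per-member lookup tables used by qualification/termination
member_index <- function(dataset, codesets, config) {
  med <- dataset$medical
  ph <- dataset$pharmacy
  chemo_codes <- cs_chemo_codes(codesets)
  fn_dx <- cs_fn_dx(codesets)

  med_chemo_sel <- codes_match_any(med$proc_codes, chemo_codes)
  ph_chemo_sel <- ph$drug_code %in% chemo_codes
  chemo <- tibble(member_id = c(med$member_id[med_chemo_sel], ph$member_id[ph_chemo_sel]),
                  date = c(med$service_date[med_chemo_sel], ph$fill_date[ph_chemo_sel]))

  fnsel <- codes_match_any(med$dx_codes, fn_dx)
  bmtsel <- codes_match_any(med$proc_codes, codesets$sets$bmt_sct_cart_proc)
  hemesel <- codes_match_any(med$dx_codes, codesets$sets$excluded_heme_dx)
  covidsel <- codes_match_any(med$dx_codes, codesets$sets$covid_dx)
  inpsel <- med$setting == "inpatient"
  enr <- merge_enrollment(dataset$enrollment)

  list(
    chemo_dates = split(chemo$date, chemo$member_id),
    fn_dx_dates = split(med$service_date[fnsel], med$member_id[fnsel]),
    bmt_dates = split(med$service_date[bmtsel], med$member_id[bmtsel]),
    heme_dates = split(med$service_date[hemesel], med$member_id[hemesel]),
    covid_dates = split(med$service_date[covidsel], med$member_id[covidsel]),
    inpatient = split(
      tibble(admit = med$service_date[inpsel],
             discharge = med$discharge_date[inpsel],
             fn = fnsel[inpsel]),
      med$member_id[inpsel]),
    enrollment = split(enr, enr$member_id)
  )
}

mi_get <- function(lst, member, empty) lst[[member]] %||% empty

#' Qualify a candidate index event
#'
#' Applies the inclusion/exclusion criteria to a candidate, in the fixed
#' evaluation order used for attrition logging:
#'
#' 1. `chemo_within_lookback` — at least one chemotherapy/biologic claim in the
#'    30 days before the index date (`[index-30, index-1]` by default);
#' 2. `continuous_enrollment` — enrollment (after merging adjacent spans)
#'    covers `[index-180, index]` without a gap;
#' 3. `clean_pre_period` — no neutropenia/infection/fever diagnosis in
#'    `[index-180, index-1]` (skipped when `check_clean_pre_period = FALSE`,
#'    as for a member's episodes after the first under the washout rule);
#' 4. `no_bmt_sct_cart` — no bone-marrow/stem-cell transplant or CAR-T
#'    procedure in the pre-episode period;
#' 5. `no_excluded_heme_malignancy` — no ALL/AML/CML/MDS diagnosis in the
#'    pre-episode period;
#' 6. `no_covid` — no COVID-19 diagnosis in the pre-episode period (and on the
#'    index date, when `covid_includes_index`).
#'
#' @param candidate One-row tibble or list with `member_id` and `index_date`.
#' @param dataset An `fn_claims` dataset.
#' @param codesets An `fn_codesets` registry.
#' @param config An [fn_config()].
#' @param check_clean_pre_period Apply criterion 3 (default `TRUE`).
#' @return A list: `ok` (logical) and, when rejected, `reason` — the label of
#'   the first failing criterion.
#' @export
qualify_candidate <- function(candidate, dataset, codesets, config = fn_config(),
                              check_clean_pre_period = TRUE) {
  mi <- member_index(dataset, codesets, config)
  qualify_with_index(candidate$member_id, as.Date(candidate$index_date),
                     mi, config, check_clean_pre_period)
}

qualify_with_index <- function(member, index, mi, config, check_clean_pre_period) {
  no_date <- as.Date(character())
  chemo_hi <- if (config$chemo_on_index_qualifies) index else index - 1
  chemo <- mi_get(mi$chemo_dates, member, no_date)
  if (!any(chemo >= index - config$chemo_lookback_days & chemo <= chemo_hi)) {
    return(list(ok = FALSE, reason = "chemo_within_lookback"))
  }
  spans <- mi$enrollment[[member]]
  covered <- !is.null(spans) &&
    any(spans$start_date <= index - config$pre_episode_days & spans$end_date >= index)
  if (!covered) return(list(ok = FALSE, reason = "continuous_enrollment"))
  if (check_clean_pre_period) {
    fn <- mi_get(mi$fn_dx_dates, member, no_date)
    if (any(fn >= index - config$pre_episode_days & fn <= index - 1)) {
      return(list(ok = FALSE, reason = "clean_pre_period"))
    }
  }
  bmt <- mi_get(mi$bmt_dates, member, no_date)
  if (any(bmt >= index - config$pre_episode_days & bmt <= index - 1)) {
    return(list(ok = FALSE, reason = "no_bmt_sct_cart"))
  }
  heme <- mi_get(mi$heme_dates, member, no_date)
  if (any(heme >= index - config$pre_episode_days & heme <= index - 1)) {
    return(list(ok = FALSE, reason = "no_excluded_heme_malignancy"))
  }
  covid <- mi_get(mi$covid_dates, member, no_date)
  covid_hi <- if (config$covid_includes_index) index else index - 1
  if (any(covid >= index - config$pre_episode_days & covid <= covid_hi)) {
    return(list(ok = FALSE, reason = "no_covid"))
  }
  list(ok = TRUE, reason = NA_character_)
}

#' Terminate an episode
#'
#' The provisional end is the earlier of the next incident chemotherapy
#' administration *strictly after* the index date and `index + 60` days. If an
#' FN-related inpatient stay (admission within `[index, provisional end]` with
#' a neutropenia/infection/fever diagnosis) discharges after the provisional
#' end, the episode extends to the discharge date so the entire length of stay
#' is included — this is the only way an episode can exceed the 60-day cap.
#'
#' @param episode_start Index date (`Date` or ISO-8601 string).
#' @param member_id Member identifier.
#' @param dataset An `fn_claims` dataset.
#' @param codesets An `fn_codesets` registry.
#' @param config An [fn_config()].
#' @return List with `end_date` and `has_hospitalization` (any inpatient claim
#'   admitted within `[index, end_date]`).
#' @export
terminate_episode <- function(episode_start, member_id, dataset, codesets,
                              config = fn_config()) {
  mi <- member_index(dataset, codesets, config)
  terminate_with_index(member_id, as.Date(episode_start), mi, config)
}

terminate_with_index <- function(member, index, mi, config) {
  no_date <- as.Date(character())
  chemo <- mi_get(mi$chemo_dates, member, no_date)
  nxt <- chemo[chemo > index]
  cap <- index + config$episode_cap_days
  provisional <- if (length(nxt)) min(min(nxt), cap) else cap

  inp <- mi$inpatient[[member]]
  end <- provisional
  if (!is.null(inp) && nrow(inp) > 0) {
    ext <- inp$fn & inp$admit >= index & inp$admit <= provisional &
      !is.na(inp$discharge) & inp$discharge > provisional
    if (any(ext)) end <- max(inp$discharge[ext])
  }
  has_hosp <- !is.null(inp) && nrow(inp) > 0 &&
    any(inp$admit >= index & inp$admit <= end)
  list(end_date = end, has_hospitalization = has_hosp)
}

# does [lo, hi] contain a run of `len` consecutive days with no date in `dates`?
has_clean_run <- function(dates, lo, hi, len) {
  if (hi - lo + 1 < len) return(FALSE)
  d <- sort(unique(dates[dates >= lo & dates <= hi]))
  bounds <- c(lo - 1, as.integer(d), hi + 1)
  any(diff(bounds) - 1 >= len)
}

#' Apply the inter-episode washout rule
#'
#' The first qualified episode of a member is retained. Each subsequent
#' episode is retained only if at least 30 consecutive days free of
#' neutropenia/infection/fever diagnoses exist between the previously retained
#' episode's end date and the new index date (both exclusive).
#'
#' @param episodes Tibble of one member's qualified episodes with `index_date`
#'   and `end_date`, sorted by `index_date`.
#' @param fn_dx_dates Dates of the member's neutropenia/infection/fever
#'   diagnosis claims.
#' @param config An [fn_config()].
#' @return The retained subset of `episodes`.
#' @export
apply_washout <- function(episodes, fn_dx_dates, config = fn_config()) {
  if (nrow(episodes) <= 1) return(episodes)
  keep <- logical(nrow(episodes))
  keep[1] <- TRUE
  prev_end <- episodes$end_date[1]
  for (i in seq.int(2, nrow(episodes))) {
    idx <- episodes$index_date[i]
    if (idx > prev_end &&
        has_clean_run(fn_dx_dates, prev_end + 1, idx - 1, config$washout_days)) {
      keep[i] <- TRUE
      prev_end <- episodes$end_date[i]
    }
  }
  episodes[keep, , drop = FALSE]
}

#' Build the episode cohort
#'
#' Composes candidate detection, qualification, termination and washout, and
#' records the attrition of candidates at each study criterion in a fixed
#' order. Members' candidates are processed chronologically; after a member's
#' first retained episode, the full clean-pre-period criterion is replaced by
#' the 30-day clean-gap washout rule (configurable via
#' `subsequent_episode_rule`).
#'
#' @param dataset An `fn_claims` dataset.
#' @param codesets An `fn_codesets` registry.
#' @param config An [fn_config()].
#' @return An `fn_cohort` list: `episodes` (tibble with `episode_id`,
#'   `member_id`, `index_date`, `end_date`, `episode_length_days`,
#'   `has_hospitalization`, `index_year`, `trigger`), `attrition` (tibble
#'   `criterion`, `remaining`, non-increasing), and `rejections` (per-candidate
#'   first failing criterion).
#' @export
build_cohort <- function(dataset, codesets, config = fn_config()) {
  candidates <- detect_candidates(dataset, codesets)
  mi <- member_index(dataset, codesets, config)

  n_cand <- nrow(candidates)
  rejections <- character(n_cand)
  episodes <- vector("list", n_cand)
  no_date <- as.Date(character())

  if (n_cand > 0) {
    ord <- order(candidates$member_id, candidates$index_date)
    prev_end <- list() # member -> last retained end date
    for (k in ord) {
      member <- candidates$member_id[k]
      index <- candidates$index_date[k]
      first_for_member <- is.null(prev_end[[member]])
      check_clean <- first_for_member ||
        config$subsequent_episode_rule == "full_clean_period"
      q <- qualify_with_index(member, index, mi, config, check_clean)
      if (!q$ok) {
        rejections[k] <- q$reason
        next
      }
      if (!first_for_member) {
        pe <- prev_end[[member]]
        ok <- index > pe &&
          has_clean_run(mi_get(mi$fn_dx_dates, member, no_date),
                        pe + 1, index - 1, config$washout_days)
        if (!ok) {
          rejections[k] <- "washout"
          next
        }
      }
      term <- terminate_with_index(member, index, mi, config)
      prev_end[[member]] <- term$end_date
      episodes[[k]] <- tibble(
        member_id = member,
        index_date = index,
        end_date = term$end_date,
        episode_length_days = as.integer(term$end_date - index + 1),
        has_hospitalization = term$has_hospitalization,
        index_year = as.integer(format(index, "%Y")),
        trigger = candidates$trigger[k]
      )
    }
  }

  eps <- bind_rows(episodes)
  if (nrow(eps) > 0) {
    eps <- eps %>%
      arrange(.data$member_id, .data$index_date) %>%
      mutate(episode_id = sprintf("E%05d", row_number()), .before = 1)
  } else {
    eps <- tibble(episode_id = character(), member_id = character(),
                  index_date = as.Date(character()), end_date = as.Date(character()),
                  episode_length_days = integer(), has_hospitalization = logical(),
                  index_year = integer(), trigger = character())
  }

  remaining <- n_cand
  attr_counts <- integer(length(ATTRITION_LABELS))
  attr_counts[1] <- n_cand
  for (i in seq_along(ATTRITION_LABELS)[-1]) {
    remaining <- remaining - sum(rejections == ATTRITION_LABELS[i])
    attr_counts[i] <- remaining
  }
  attrition <- tibble(criterion = ATTRITION_LABELS, remaining = attr_counts)

  rej <- candidates
  rej$reason <- ifelse(rejections == "", NA_character_, rejections)

  structure(list(episodes = eps, attrition = attrition,
                 rejections = rej[!is.na(rej$reason), , drop = FALSE]),
            class = "fn_cohort")
}

#' @export
print.fn_cohort <- function(x, ...) {
  cat("<fn_cohort> ", nrow(x$episodes), " episodes from ",
      length(unique(x$episodes$member_id)), " members (",
      x$attrition$remaining[1], " candidates)\n", sep = "")
  invisible(x)
}
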