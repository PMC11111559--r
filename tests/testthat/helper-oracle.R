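# Deliberately naive reference implementation of cohort construction.
# Scans every (member, date) pair with explicit loops and data-frame filters;
# shares no code with the package implementation.

oracle_codes <- function(x) unlist(strsplit(x[!is.na(x)], ";", fixed = TRUE))

oracle_candidates <- function(ds, cs) {
  fbf <- c(cs$sets$fever_dx, cs$sets$bacterial_infection_dx, cs$sets$fungal_infection_dx)
  out <- data.frame(member_id = character(), index_date = as.Date(character()),
                    trigger = character(), stringsAsFactors = FALSE)
  for (m in sort(unique(ds$medical$member_id))) {
    med <- ds$medical[ds$medical$member_id == m, ]
    ph <- ds$pharmacy[ds$pharmacy$member_id == m, ]
    for (di in sort(unique(as.integer(med$service_date)))) {
      d <- as.Date(di, origin = "1970-01-01")
      day <- med[med$service_date == d, ]
      inp_dx <- oracle_codes(day$dx_codes[day$setting == "inpatient"])
      out_dx <- oracle_codes(day$dx_codes[day$setting != "inpatient"])
      inp_def <- any(inp_dx %in% cs$sets$neutropenia_dx) && any(inp_dx %in% fbf)
      fills <- ph$drug_code[ph$fill_date == d]
      oral <- FALSE
      for (rule in cs$oral_antibiotic_rules) {
        hit <- TRUE
        for (g in rule) if (!any(fills %in% cs$sets[[g]])) hit <- FALSE
        if (hit) oral <- TRUE
      }
      parenteral <- any(oracle_codes(day$proc_codes) %in%
                          cs$sets$nccn_parenteral_antibiotic_proc)
      outp_def <- any(out_dx %in% cs$sets$neutropenia_dx) &&
        any(out_dx %in% fbf) && (oral || parenteral)
      if (inp_def || outp_def) {
        out <- rbind(out, data.frame(
          member_id = m, index_date = d,
          trigger = if (inp_def) "inpatient_def" else "outpatient_def",
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# dates (as Date vector) on which the member has a claim carrying any of `codes`
oracle_dates_with <- function(ds, m, codes, dx = TRUE, proc = TRUE, drug = TRUE) {
  med <- ds$medical[ds$medical$member_id == m, ]
  ph <- ds$pharmacy[ds$pharmacy$member_id == m, ]
  dates <- as.Date(character())
  for (i in seq_len(nrow(med))) {
    hit <- (dx && any(oracle_codes(med$dx_codes[i]) %in% codes)) ||
      (proc && any(oracle_codes(med$proc_codes[i]) %in% codes))
    if (hit) dates <- c(dates, med$service_date[i])
  }
  if (drug) {
    for (i in seq_len(nrow(ph))) {
      if (ph$drug_code[i] %in% codes) dates <- c(dates, ph$fill_date[i])
    }
  }
  dates
}

oracle_fn_dx_dates <- function(ds, m, cs) {
  fnset <- c(cs$sets$neutropenia_dx, cs$sets$fever_dx,
             cs$sets$bacterial_infection_dx, cs$sets$fungal_infection_dx)
  oracle_dates_with(ds, m, fnset, proc = FALSE, drug = FALSE)
}

oracle_chemo_dates <- function(ds, m, cs) {
  oracle_dates_with(ds, m, unique(unlist(cs$chemo_drugs)))
}

# naive full cohort build; mirrors the documented semantics with day loops
oracle_build_cohort <- function(ds, cs, cfg = fn_config()) {
  cands <- oracle_candidates(ds, cs)
  episodes <- NULL
  for (m in sort(unique(cands$member_id))) {
    mc <- cands[cands$member_id == m, ]
    mc <- mc[order(mc$index_date), ]
    chemo <- oracle_chemo_dates(ds, m, cs)
    fndx <- oracle_fn_dx_dates(ds, m, cs)
    bmt <- oracle_dates_with(ds, m, cs$sets$bmt_sct_cart_proc, dx = FALSE, drug = FALSE)
    heme <- oracle_dates_with(ds, m, cs$sets$excluded_heme_dx, proc = FALSE, drug = FALSE)
    covid <- oracle_dates_with(ds, m, cs$sets$covid_dx, proc = FALSE, drug = FALSE)
    enr <- ds$enrollment[ds$enrollment$member_id == m, ]
    prev_end <- NULL
    for (k in seq_len(nrow(mc))) {
      idx <- mc$index_date[k]
      # (a) chemo in lookback
      hi <- if (cfg$chemo_on_index_qualifies) idx else idx - 1
      if (!any(chemo >= idx - cfg$chemo_lookback_days & chemo <= hi)) next
      # (b) continuous enrollment: every day of [idx-180, idx] inside some span
      ok <- TRUE
      es <- as.integer(enr$start_date); ee <- as.integer(enr$end_date)
      for (day in seq(as.integer(idx - cfg$pre_episode_days), as.integer(idx))) {
        if (!any(es <= day & ee >= day)) { ok <- FALSE; break }
      }
      if (!ok) next
      # (c) clean pre-period (first episode only under the washout rule)
      if (is.null(prev_end) || cfg$subsequent_episode_rule == "full_clean_period") {
        if (any(fndx >= idx - cfg$pre_episode_days & fndx <= idx - 1)) next
      }
      # (d,e,f)
      if (any(bmt >= idx - cfg$pre_episode_days & bmt <= idx - 1)) next
      if (any(heme >= idx - cfg$pre_episode_days & heme <= idx - 1)) next
      chi <- if (cfg$covid_includes_index) idx else idx - 1
      if (any(covid >= idx - cfg$pre_episode_days & covid <= chi)) next
      # washout for subsequent episodes: scan every 30-day window start
      if (!is.null(prev_end)) {
        if (idx <= prev_end) next
        found <- FALSE
        lo <- as.integer(prev_end + 1)
        hi2 <- as.integer(idx - 1)
        fnd <- as.integer(fndx)
        if (hi2 - lo + 1 >= cfg$washout_days) {
          for (s in lo:(hi2 - cfg$washout_days + 1)) {
            win <- s:(s + cfg$washout_days - 1)
            if (!any(fnd %in% win)) { found <- TRUE; break }
          }
        }
        if (!found) next
      }
      # termination
      nxt <- chemo[chemo > idx]
      prov <- min(c(nxt, idx + cfg$episode_cap_days))
      med <- ds$medical[ds$medical$member_id == m & ds$medical$setting == "inpatient", ]
      end <- prov
      for (i in seq_len(nrow(med))) {
        fn_stay <- any(oracle_codes(med$dx_codes[i]) %in%
                         c(cs$sets$neutropenia_dx, cs$sets$fever_dx,
                           cs$sets$bacterial_infection_dx, cs$sets$fungal_infection_dx))
        if (fn_stay && med$service_date[i] >= idx && med$service_date[i] <= prov &&
            !is.na(med$discharge_date[i]) && med$discharge_date[i] > prov) {
          end <- max(end, med$discharge_date[i])
        }
      }
      has_hosp <- FALSE
      for (i in seq_len(nrow(med))) {
        if (med$service_date[i] >= idx && med$service_date[i] <= end) has_hosp <- TRUE
      }
      episodes <- rbind(episodes, data.frame(
        member_id = m, index_date = idx, end_date = as.Date(end),
        has_hospitalization = has_hosp, trigger = mc$trigger[k],
        stringsAsFactors = FALSE))
      prev_end <- as.Date(end)
    }
  }
  if (is.null(episodes)) {
    episodes <- data.frame(member_id = character(), index_date = as.Date(character()),
                           end_date = as.Date(character()),
                           has_hospitalization = logical(), trigger = character())
  }
  episodes
}

# independent exhaustive regimen matcher for chemotherapy FN-risk
oracle_chemo_risk <- function(ep, ds, cs, cfg = fn_config()) {
  idx <- as.Date(ep$index_date)
  m <- ep$member_id
  lo <- idx - cfg$chemo_lookback_days; hi <- idx - 1
  present <- character()
  for (drug in names(cs$chemo_drugs)) {
    dd <- oracle_dates_with(ds, m, cs$chemo_drugs[[drug]])
    if (any(dd >= lo & dd <= hi)) present <- c(present, drug)
  }
  rank <- c(low_undefined = 1, intermediate = 2, high = 3)
  best <- "low_undefined"
  for (i in seq_len(nrow(cs$regimens))) {
    r <- cs$regimens[i, ]
    if (!all(r$drugs[[1]] %in% present)) next
    if (!is.na(r$requires_dx)) {
      dd <- oracle_dates_with(ds, m, cs$sets[[r$requires_dx]], proc = FALSE, drug = FALSE)
      lb_hi <- if (cfg$include_index_in_lookback) idx else idx - 1
      if (!any(dd >= idx - cfg$pre_episode_days & dd <= lb_hi)) next
    }
    if (!is.na(r$min_cycles)) {
      codes <- unique(unlist(cs$chemo_drugs[r$drugs[[1]]]))
      dd <- unique(oracle_dates_with(ds, m, codes))
      dd <- dd[dd >= idx - cfg$pre_episode_days & dd <= idx - 1]
      if (length(dd) < r$min_cycles) next
    }
    if (rank[[r$risk]] > rank[[best]]) best <- r$risk
  }
  best
}
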