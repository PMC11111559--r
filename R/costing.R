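UTIL_CATEGORIES <- c("inpatient", "emergency_room", "physician_office",
                     "other_outpatient", "pharmacy")
FN_TREATMENT_CATEGORIES <- c("gcsf", "antimicrobial")

#' Inflation-adjust a nominal cost to 2021 US dollars
#'
#' `cost_2021 = cost_nominal * index[2021] / index[service_year]`, using the
#' medical-care component of the Consumer Price Index supplied as a
#' year-indexed table (see [load_cpi_table()]).
#'
#' @param cost_nominal Numeric cost(s) in dollars of the service year.
#' @param service_year Integer year(s), recycled against `cost_nominal`.
#' @param cpi_table Named numeric vector mapping year to index value; must
#'   contain 2021.
#' @return Numeric cost(s) in 2021 USD.
#' @export
#' @examples
#' cpi <- c(`2020` = 250, `2021` = 260)
#' adjust_to_2021(100, 2020, cpi)
adjust_to_2021 <- function(cost_nominal, service_year, cpi_table) {
  yr <- as.character(service_year)
  missing <- setdiff(unique(yr), names(cpi_table))
  if (length(missing)) {
    abort(paste0("CPI table missing service year(s): ", paste(missing, collapse = ", ")))
  }
  cost_nominal * cpi_table[["2021"]] / unname(cpi_table[yr])
}

# merge overlapping inpatient admission spans into distinct stays
merge_stays <- function(admit, discharge) {
  ord <- order(admit, discharge)
  admit <- admit[ord]; discharge <- discharge[ord]
  stays <- list()
  cur_a <- admit[1]; cur_d <- discharge[1]; rows <- list(ord[1])
  k <- 1
  for (i in seq_along(admit)[-1]) {
    if (admit[i] <= cur_d) { # overlapping or same-day contiguous
      cur_d <- max(cur_d, discharge[i])
      rows[[k]] <- c(rows[[k]], ord[i])
    } else {
      stays[[k]] <- list(admit = cur_a, discharge = cur_d, rows = rows[[k]])
      k <- k + 1
      cur_a <- admit[i]; cur_d <- discharge[i]; rows[[k]] <- ord[i]
    }
  }
  stays[[k]] <- list(admit = cur_a, discharge = cur_d, rows = rows[[k]])
  stays
}

stay_los <- function(admit, discharge, config) {
  if (config$los_convention == "inclusive") {
    max(1L, as.integer(discharge - admit) + 1L)
  } else {
    as.integer(discharge - admit)
  }
}

#' Attribute claims to episode utilization categories
#'
#' Buckets every claim dated within each episode window (inclusive of the
#' index date) into utilization categories — inpatient, emergency room,
#' physician office, other outpatient (by claim setting) and pharmacy — for
#' two scopes: all-cause and FN-related. A medical claim is FN-related when it
#' carries a neutropenia/infection/fever diagnosis or a GCSF/antimicrobial
#' administration code; a pharmacy claim is FN-related when its drug is a GCSF
#' or antimicrobial. GCSF and antimicrobial claims during the episode are
#' additionally tallied as FN-related treatment categories (`gcsf`,
#' `antimicrobial`).
#'
#' Inpatient utilization is counted per distinct admission: overlapping
#' admission spans are merged into stays, and LOS follows the configured
#' convention (default `discharge - admission + 1`, floor 1). Costs are
#' reported both nominal and converted to 2021 USD by claim service year.
#'
#' @param episodes Episode tibble from [build_cohort()].
#' @param dataset An `fn_claims` dataset.
#' @param codesets An `fn_codesets` registry.
#' @param cpi_table Named numeric CPI vector (see [load_cpi_table()]).
#' @param config An [fn_config()].
#' @return Tibble of utilization records: `episode_id`, `category`,
#'   `fn_related`, `visit_count`, `inpatient_los_days`, `cost_nominal`,
#'   `cost_2021` — a complete grid (zero rows included) over episodes x
#'   categories x scopes, with the `gcsf`/`antimicrobial` treatment categories
#'   present only as FN-related.
#' @export
attribute_claims <- function(episodes, dataset, codesets,
                             cpi_table = load_cpi_table(), config = fn_config()) {
  med <- dataset$medical
  ph <- dataset$pharmacy
  fn_dx <- cs_fn_dx(codesets)
  gcsf <- cs_gcsf(codesets)
  antimicrobial <- cs_antimicrobial(codesets)

  med_fn_dx <- codes_match_any(med$dx_codes, fn_dx)
  med_gcsf <- codes_match_any(med$proc_codes, gcsf)
  med_am <- codes_match_any(med$proc_codes, antimicrobial)
  med_fn <- med_fn_dx | med_gcsf | med_am
  med_2021 <- adjust_to_2021(med$paid_amount,
                             as.integer(format(med$service_date, "%Y")), cpi_table)
  ph_gcsf <- ph$drug_code %in% gcsf
  ph_am <- ph$drug_code %in% antimicrobial
  ph_fn <- ph_gcsf | ph_am
  ph_2021 <- adjust_to_2021(ph$paid_amount,
                            as.integer(format(ph$fill_date, "%Y")), cpi_table)

  med_split <- split(seq_len(nrow(med)), med$member_id)
  ph_split <- split(seq_len(nrow(ph)), ph$member_id)

  empty_rec <- function(episode_id) {
    grid <- tibble(
      episode_id = episode_id,
      category = c(rep(UTIL_CATEGORIES, each = 2), FN_TREATMENT_CATEGORIES),
      fn_related = c(rep(c(FALSE, TRUE), length(UTIL_CATEGORIES)), TRUE, TRUE),
      visit_count = 0L, inpatient_los_days = 0L,
      cost_nominal = 0, cost_2021 = 0
    )
    grid
  }

  out <- vector("list", nrow(episodes))
  for (i in seq_len(nrow(episodes))) {
    ep <- episodes[i, ]
    rec <- empty_rec(ep$episode_id)
    set_rec <- function(category, fn_related, visits, los, nom, adj) {
      sel <- rec$category == category & rec$fn_related == fn_related
      rec$visit_count[sel] <<- as.integer(visits)
      rec$inpatient_los_days[sel] <<- as.integer(los)
      rec$cost_nominal[sel] <<- nom
      rec$cost_2021[sel] <<- adj
    }

    mi <- med_split[[ep$member_id]] %||% integer()
    mi <- mi[med$service_date[mi] >= ep$index_date & med$service_date[mi] <= ep$end_date]
    pi <- ph_split[[ep$member_id]] %||% integer()
    pi <- pi[ph$fill_date[pi] >= ep$index_date & ph$fill_date[pi] <= ep$end_date]

    # inpatient: per-stay counting over merged admission spans
    ip <- mi[med$setting[mi] == "inpatient"]
    if (length(ip)) {
      stays <- merge_stays(med$service_date[ip], med$discharge_date[ip])
      los_all <- sum(vapply(stays, function(s) stay_los(s$admit, s$discharge, config),
                            integer(1)))
      set_rec("inpatient", FALSE, length(stays), los_all,
              sum(med$paid_amount[ip]), sum(med_2021[ip]))
      ip_fn <- ip[med_fn[ip]]
      if (length(ip_fn)) {
        stays_fn <- merge_stays(med$service_date[ip_fn], med$discharge_date[ip_fn])
        los_fn <- sum(vapply(stays_fn, function(s) stay_los(s$admit, s$discharge, config),
                             integer(1)))
        set_rec("inpatient", TRUE, length(stays_fn), los_fn,
                sum(med$paid_amount[ip_fn]), sum(med_2021[ip_fn]))
      }
    }

    for (cat in c("emergency_room", "physician_office", "other_outpatient")) {
      ci <- mi[med$setting[mi] == cat]
      if (length(ci)) {
        set_rec(cat, FALSE, length(ci), 0L, sum(med$paid_amount[ci]), sum(med_2021[ci]))
        cf <- ci[med_fn[ci]]
        if (length(cf)) {
          set_rec(cat, TRUE, length(cf), 0L, sum(med$paid_amount[cf]), sum(med_2021[cf]))
        }
      }
    }

    if (length(pi)) {
      set_rec("pharmacy", FALSE, length(pi), 0L, sum(ph$paid_amount[pi]), sum(ph_2021[pi]))
      pf <- pi[ph_fn[pi]]
      if (length(pf)) {
        set_rec("pharmacy", TRUE, length(pf), 0L, sum(ph$paid_amount[pf]), sum(ph_2021[pf]))
      }
    }

    # FN-treatment tallies: medical administrations + pharmacy fills
    g_med <- mi[med_gcsf[mi]]; g_ph <- pi[ph_gcsf[pi]]
    if (length(g_med) + length(g_ph) > 0) {
      set_rec("gcsf", TRUE, length(g_med) + length(g_ph), 0L,
              sum(med$paid_amount[g_med]) + sum(ph$paid_amount[g_ph]),
              sum(med_2021[g_med]) + sum(ph_2021[g_ph]))
    }
    a_med <- mi[med_am[mi]]; a_ph <- pi[ph_am[pi]]
    if (length(a_med) + length(a_ph) > 0) {
      set_rec("antimicrobial", TRUE, length(a_med) + length(a_ph), 0L,
              sum(med$paid_amount[a_med]) + sum(ph$paid_amount[a_ph]),
              sum(med_2021[a_med]) + sum(ph_2021[a_ph]))
    }
    out[[i]] <- rec
  }
  if (length(out) == 0) return(empty_rec("placeholder")[0, , drop = FALSE])
  bind_rows(out)
}

#' Summarise utilization and costs by stratum
#'
#' Per stratum x category x scope (all-cause / FN-related), computes the
#' number of episodes with any use in the category, and — among those users —
#' the mean, sample SD (n-1) and median of per-episode 2021-USD cost, the
#' mean/SD visit count, and the mean inpatient LOS (inpatient category only).
#' Episodes with zero use in a category are excluded from that category's
#' statistics. Also emits a `total` category per scope: per-episode sums
#' across the five utilization categories (visit totals exclude pharmacy
#' fills).
#'
#' @param records Utilization records from [attribute_claims()].
#' @param strata Stratum assignments from [stratify_episodes()] (tibble with
#'   `episode_id`, `stratification`, `stratum`); the special stratification
#'   `all`/`all` covers every episode.
#' @return Tibble with one row per stratum x category x scope:
#'   `stratification`, `stratum`, `category`, `fn_related`, `n_with_use`,
#'   `cost_mean`, `cost_sd`, `cost_median`, `visits_mean`, `visits_sd`,
#'   `los_mean`. Statistics over empty strata are `NA`.
#' @export
summarize_costs <- function(records, strata) {
  totals <- records %>%
    filter(.data$category %in% UTIL_CATEGORIES) %>%
    group_by(.data$episode_id, .data$fn_related) %>%
    summarise(visit_count = sum(.data$visit_count[.data$category != "pharmacy"]),
              inpatient_los_days = sum(.data$inpatient_los_days),
              cost_nominal = sum(.data$cost_nominal),
              cost_2021 = sum(.data$cost_2021), .groups = "drop") %>%
    mutate(category = "total")
  recs <- bind_rows(records, totals)

  joined <- strata %>%
    inner_join(recs, by = "episode_id", relationship = "many-to-many")

  joined %>%
    group_by(.data$stratification, .data$stratum, .data$category, .data$fn_related) %>%
    summarise(
      n_with_use = sum(.data$visit_count > 0 | .data$cost_2021 > 0),
      cost_mean = mean_or_na(.data$cost_2021[user(.data$visit_count, .data$cost_2021)]),
      cost_sd = sd_or_na(.data$cost_2021[user(.data$visit_count, .data$cost_2021)]),
      cost_median = median_or_na(.data$cost_2021[user(.data$visit_count, .data$cost_2021)]),
      visits_mean = mean_or_na(.data$visit_count[user(.data$visit_count, .data$cost_2021)]),
      visits_sd = sd_or_na(.data$visit_count[user(.data$visit_count, .data$cost_2021)]),
      los_mean = if (first(.data$category) %in% c("inpatient", "total")) {
        mean_or_na(.data$inpatient_los_days[.data$inpatient_los_days > 0])
      } else NA_real_,
      .groups = "drop"
    )
}

user <- function(visits, cost) visits > 0 | cost > 0
mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
sd_or_na <- function(x) if (length(x) > 1) sd(x) else NA_real_
median_or_na <- function(x) if (length(x)) median(x) else NA_real_
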