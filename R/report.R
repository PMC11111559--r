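PARTITION_STRATIFICATIONS <- c("episode_type", "index_year", "nci_category",
                               "age_category")

#' Percentage with the report's display convention
#'
#' `value = 100 * numerator / denominator`, displayed with one decimal,
#' rounded half-up (so 91.15 renders "91.2"). A zero denominator yields the
#' undefined marker rather than a number.
#'
#' @param numerator,denominator Non-negative counts, `numerator <= denominator`.
#' @return List with `value` (numeric, or `NA` when undefined), `display`
#'   (e.g. `"91.2%"`, or `"--"` when undefined).
#' @export
#' @examples
#' percent(6411, 7033)$display
percent <- function(numerator, denominator) {
  stopifnot(numerator >= 0, denominator >= 0, numerator <= max(denominator, numerator))
  if (denominator == 0) return(list(value = NA_real_, display = "--"))
  v <- 100 * numerator / denominator
  list(value = v, display = paste0(formatC(round_half_up(v, 1), format = "f", digits = 1), "%"))
}

#' Assign episodes to report strata
#'
#' Produces the study's six stratifications plus an `all` stratum:
#' hospitalization episode type, index year, hematologic malignancy (composite
#' and individual), solid-tumor malignancy (composite and individual), NCI
#' comorbidity category, and age category. Episode type, index year, NCI
#' category and age category partition the cohort; malignancy strata may
#' overlap and episodes without a cancer diagnosis appear in no malignancy
#' stratum.
#'
#' @param episodes Episode tibble from [build_cohort()].
#' @param classifications Classification tibble from [classify_episodes()].
#' @return Tibble with `episode_id`, `stratification`, `stratum` (one row per
#'   membership).
#' @export
stratify_episodes <- function(episodes, classifications) {
  df <- episodes %>%
    left_join(classifications, by = "episode_id")
  if (nrow(df) == 0) {
    return(tibble(episode_id = character(), stratification = character(),
                  stratum = character()))
  }
  bad <- df$episode_id[is.na(df$nci_category) | is.na(df$age_category) |
                         is.na(df$has_hospitalization) | is.na(df$index_year)]
  if (length(bad)) {
    abort(paste0("episode(s) with unassignable partition stratum: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  malig <- c(nhl = "cancer_nhl", cll = "cancer_cll",
             other_hematologic = "cancer_other_hematologic",
             hematologic_composite = "hematologic_any",
             breast = "cancer_breast", lung = "cancer_lung",
             colorectal = "cancer_colorectal", prostate = "cancer_prostate",
             other_solid = "cancer_other_solid", solid_composite = "solid_any")
  bind_rows(
    tibble(episode_id = df$episode_id, stratification = "all", stratum = "all"),
    tibble(episode_id = df$episode_id, stratification = "episode_type",
           stratum = if_else(df$has_hospitalization, "with_hospitalization",
                             "without_hospitalization")),
    tibble(episode_id = df$episode_id, stratification = "index_year",
           stratum = as.character(df$index_year)),
    bind_rows(lapply(names(malig), function(m) {
      sel <- df[[malig[[m]]]]
      tibble(episode_id = df$episode_id[sel], stratification = "malignancy",
             stratum = m)
    })),
    tibble(episode_id = df$episode_id, stratification = "nci_category",
           stratum = df$nci_category),
    tibble(episode_id = df$episode_id, stratification = "age_category",
           stratum = df$age_category)
  )
}

count_pct <- function(n, total) {
  p <- if (total > 0) 100 * n / total else NA_real_
  tibble(n = n, pct = p)
}

summarise_numeric <- function(x) {
  tibble(mean = mean_or_na(x), sd = sd_or_na(x), median = median_or_na(x),
         min = if (length(x)) min(x) else NA_real_,
         max = if (length(x)) max(x) else NA_real_)
}

#' Assemble the cohort report
#'
#' Builds the five stratified summary tables plus the attrition log:
#'
#' * `table1` — episode counts and percentages per stratum;
#' * `table2` — demographics and episode characteristics (age, sex, payer,
#'   region, episode length, NCI score) overall and by episode type;
#' * `table3` — risk-factor counts/percentages per stratum;
#' * `table4` — treatment classification counts/percentages per stratum;
#' * `table5` — the utilization/cost grid from [summarize_costs()];
#' * `patients` — patient-level counts (distinct members, members with one
#'   qualifying episode);
#' * `attrition` — the criterion-by-criterion candidate counts.
#'
#' @param cohort An `fn_cohort` from [build_cohort()].
#' @param classifications From [classify_episodes()].
#' @param dataset The `fn_claims` dataset (for member demographics).
#' @param codesets An `fn_codesets` registry.
#' @param cpi_table CPI table for cost conversion.
#' @param config An [fn_config()].
#' @return A list of class `fn_report`.
#' @export
build_report <- function(cohort, classifications, dataset, codesets,
                         cpi_table = load_cpi_table(), config = fn_config()) {
  episodes <- cohort$episodes
  strata <- stratify_episodes(episodes, classifications)
  total <- nrow(episodes)

  table1 <- strata %>%
    group_by(.data$stratification, .data$stratum) %>%
    summarise(n = n(), .groups = "drop") %>%
    mutate(pct = if (total > 0) 100 * .data$n / total else NA_real_)

  df <- episodes %>% left_join(classifications, by = "episode_id")
  demo_for <- function(sel, label) {
    d <- df[sel, , drop = FALSE]
    nn <- nrow(d)
    cat_rows <- function(var, levels) {
      bind_rows(lapply(levels, function(l) {
        tibble(stratum = label, variable = var, level = l,
               n = sum(d[[var]] == l),
               pct = if (nn > 0) 100 * sum(d[[var]] == l) / nn else NA_real_)
      }))
    }
    num_rows <- function(var, values) {
      cbind(tibble(stratum = label, variable = var, level = "summary"),
            summarise_numeric(values))
    }
    bind_rows(
      num_rows("age_years", d$age_years),
      cat_rows("sex", SEXES),
      cat_rows("payer", PAYERS),
      cat_rows("region", REGIONS),
      num_rows("episode_length_days", d$episode_length_days),
      num_rows("nci_cci_score", d$nci_cci_score)
    )
  }
  table2 <- bind_rows(
    demo_for(rep(TRUE, nrow(df)), "all"),
    demo_for(df$has_hospitalization, "with_hospitalization"),
    demo_for(!df$has_hospitalization, "without_hospitalization")
  )

  flag_table <- function(flags) {
    strata %>%
      left_join(df, by = "episode_id") %>%
      group_by(.data$stratification, .data$stratum) %>%
      summarise(denominator = n(),
                across(all_of(flags), ~ sum(.x)), .groups = "drop") %>%
      tidyr::pivot_longer(all_of(flags), names_to = "flag", values_to = "n") %>%
      mutate(pct = if_else(.data$denominator > 0,
                           100 * .data$n / .data$denominator, NA_real_))
  }
  table3 <- flag_table(RISK_FACTORS)
  use_flags <- flag_table(c("gcsf_any", "gcsf_prophylactic", "gcsf_treatment",
                            "gcsf_long_prophylactic", "gcsf_short_prophylactic",
                            "gcsf_long_treatment", "gcsf_short_treatment",
                            "antimicrobial_any", "antimicrobial_prophylactic",
                            "antimicrobial_treatment"))
  risk_counts <- strata %>%
    left_join(df, by = "episode_id") %>%
    group_by(.data$stratification, .data$stratum) %>%
    summarise(denominator = n(),
              high = sum(.data$chemo_risk == "high"),
              intermediate = sum(.data$chemo_risk == "intermediate"),
              low_undefined = sum(.data$chemo_risk == "low_undefined"),
              .groups = "drop") %>%
    tidyr::pivot_longer(c("high", "intermediate", "low_undefined"),
                        names_to = "flag", values_to = "n") %>%
    mutate(flag = paste0("chemo_risk_", .data$flag),
           pct = if_else(.data$denominator > 0,
                         100 * .data$n / .data$denominator, NA_real_))
  table4 <- bind_rows(risk_counts, use_flags)

  util <- attribute_claims(episodes, dataset, codesets, cpi_table, config)
  table5 <- summarize_costs(util, strata)

  members_with_episode <- unique(episodes$member_id)
  per_member <- table(episodes$member_id)
  patients <- tibble(
    n_patients = length(members_with_episode),
    n_single_episode = sum(per_member == 1),
    n_multi_episode = sum(per_member > 1)
  )

  structure(list(table1 = table1, table2 = table2, table3 = table3,
                 table4 = table4, table5 = table5,
                 attrition = cohort$attrition, patients = patients,
                 n_episodes = total, utilization = util, strata = strata),
            class = "fn_report")
}

#' @export
print.fn_report <- function(x, ...) {
  cat("<fn_report> ", x$n_episodes, " episodes, ",
      x$patients$n_patients, " patients\n", sep = "")
  invisible(x)
}

fmt_n <- function(n) formatC(n, big.mark = ",", format = "d")
fmt_pct1 <- function(p) {
  ifelse(is.na(p), "--", paste0(formatC(round_half_up(p, 1), format = "f", digits = 1), "%"))
}

#' Render a cohort report to files
#'
#' Writes one CSV per table (human-readable: thousands separators, half-up
#' one-decimal percentages, whole-dollar costs) plus a `report.json` bundle
#' holding the raw unrounded values.
#'
#' @param report An `fn_report` from [build_report()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "fn_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  t1 <- report$table1 %>%
    mutate(n_display = fmt_n(.data$n), pct_display = fmt_pct1(.data$pct)) %>%
    select("stratification", "stratum", "n_display", "pct_display")
  t3 <- report$table3 %>%
    mutate(n_display = fmt_n(.data$n), pct_display = fmt_pct1(.data$pct)) %>%
    select("stratification", "stratum", "flag", "n_display", "pct_display")
  t4 <- report$table4 %>%
    mutate(n_display = fmt_n(.data$n), pct_display = fmt_pct1(.data$pct)) %>%
    select("stratification", "stratum", "flag", "n_display", "pct_display")
  t5 <- report$table5 %>%
    mutate(across(c("cost_mean", "cost_sd", "cost_median"),
                  ~ ifelse(is.na(.x), "--", paste0("$", fmt_n(round_half_up(.x, 0))))))

  paths <- file.path(out_dir, c("table1_episode_counts.csv",
                                "table2_demographics.csv",
                                "table3_risk_factors.csv",
                                "table4_treatments.csv",
                                "table5_hcru_costs.csv",
                                "attrition.csv", "report.json"))
  readr::write_csv(t1, paths[1], progress = FALSE)
  readr::write_csv(report$table2, paths[2], progress = FALSE)
  readr::write_csv(t3, paths[3], progress = FALSE)
  readr::write_csv(t4, paths[4], progress = FALSE)
  readr::write_csv(t5, paths[5], progress = FALSE)
  readr::write_csv(report$attrition, paths[6], progress = FALSE)
  jsonlite::write_json(
    list(n_episodes = report$n_episodes,
         patients = report$patients,
         table1 = report$table1,
         table2 = report$table2,
         table3 = report$table3,
         table4 = report$table4,
         table5 = report$table5,
         attrition = report$attrition),
    paths[7], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
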