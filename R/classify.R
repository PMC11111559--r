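RISK_LEVELS <- c("low_undefined", "intermediate", "high")
CANCER_GROUPS <- c("nhl", "cll", "other_hematologic", "breast", "lung",
                   "colorectal", "prostate", "other_solid")
RISK_FACTORS <- c("older_age_ge65", "bone_metastasis", "surgery", "radiation",
                  "severe_liver_dysfunction", "kidney_dysfunction")

# lookback window for pre-episode diagnosis capture
lookback_window <- function(index, config) {
  hi <- if (config$include_index_in_lookback) index else index - 1
  c(index - config$pre_episode_days, hi)
}

# claims (dates + codes) for one member, medical dx / medical proc / pharmacy drug
member_claim_codes <- function(dataset, member) {
  med <- dataset$medical[dataset$medical$member_id == member, , drop = FALSE]
  ph <- dataset$pharmacy[dataset$pharmacy$member_id == member, , drop = FALSE]
  list(med = med, ph = ph)
}

# dates on which any code of `codes` appears for the member
# (medical dx, medical proc, pharmacy drug — selectable)
code_dates <- function(mc, codes, dx = TRUE, proc = TRUE, drug = TRUE) {
  out <- as.Date(character())
  if (dx && nrow(mc$med)) {
    out <- c(out, mc$med$service_date[codes_match_any(mc$med$dx_codes, codes)])
  }
  if (proc && nrow(mc$med)) {
    out <- c(out, mc$med$service_date[codes_match_any(mc$med$proc_codes, codes)])
  }
  if (drug && nrow(mc$ph)) {
    out <- c(out, mc$ph$fill_date[mc$ph$drug_code %in% codes])
  }
  out
}

in_window <- function(dates, lo, hi) dates[dates >= lo & dates <= hi]

#' Classify the pre-episode chemotherapy FN risk
#'
#' Collects the chemotherapy/biologic drugs administered or filled during the
#' chemotherapy treatment period (`[index-30, index-1]`), matches them against
#' the configured regimen dictionary, and returns the highest FN-risk label
#' among matching regimens (`high` > `intermediate` > `low_undefined`). Drugs
#' matching no configured regimen yield `low_undefined`. Context-dependent
#' regimens are supported through per-regimen conditions: `requires_dx` (a
#' cancer diagnosis codeset that must appear in the pre-episode period) and
#' `min_cycles` (minimum distinct administration dates of the regimen's drugs
#' over the 180 days before index).
#'
#' @param episode One-row tibble/list with `member_id` and `index_date`.
#' @param dataset An `fn_claims` dataset.
#' @param codesets An `fn_codesets` registry.
#' @param config An [fn_config()].
#' @return One of `"high"`, `"intermediate"`, `"low_undefined"`.
#' @export
classify_chemo_risk <- function(episode, dataset, codesets, config = fn_config()) {
  member <- episode$member_id
  index <- as.Date(episode$index_date)
  mc <- member_claim_codes(dataset, member)
  lo <- index - config$chemo_lookback_days
  hi <- index - 1

  drugs_present <- names(codesets$chemo_drugs)[vapply(
    codesets$chemo_drugs,
    function(codes) length(in_window(code_dates(mc, codes), lo, hi)) > 0,
    logical(1))]
  if (length(drugs_present) == 0) return("low_undefined")

  lb <- lookback_window(index, config)
  best <- "low_undefined"
  for (i in seq_len(nrow(codesets$regimens))) {
    reg <- codesets$regimens[i, ]
    if (!all(reg$drugs[[1]] %in% drugs_present)) next
    if (!is.na(reg$requires_dx)) {
      dxd <- code_dates(mc, codesets$sets[[reg$requires_dx]], proc = FALSE, drug = FALSE)
      if (length(in_window(dxd, lb[1], lb[2])) == 0) next
    }
    if (!is.na(reg$min_cycles)) {
      reg_codes <- unlist(codesets$chemo_drugs[reg$drugs[[1]]], use.names = FALSE)
      cyc <- unique(in_window(code_dates(mc, reg_codes),
                              index - config$pre_episode_days, index - 1))
      if (length(cyc) < reg$min_cycles) next
    }
    if (match(reg$risk, RISK_LEVELS) > match(best, RISK_LEVELS)) best <- reg$risk
  }
  best
}

# shared prophylactic/treatment windowing for GCSF and antimicrobials
classify_drug_use <- function(member, index, dataset, codesets, config, code_groups) {
  mc <- member_claim_codes(dataset, member)
  lo <- index - config$chemo_lookback_days
  hi <- index - 1
  chemo_dates <- in_window(code_dates(mc, cs_chemo_codes(codesets)), lo, hi)
  first_chemo <- if (length(chemo_dates)) min(chemo_dates) else as.Date(NA)

  out <- list()
  for (g in names(code_groups)) {
    dates <- in_window(code_dates(mc, code_groups[[g]]), lo, hi)
    if (length(dates) == 0 || is.na(first_chemo)) {
      out[[g]] <- list(any = length(dates) > 0, prophylactic = FALSE,
                       treatment = length(dates) > 0)
      if (length(dates) == 0) out[[g]]$treatment <- FALSE
      next
    }
    proph <- dates >= first_chemo &
      dates <= first_chemo + config$prophylaxis_window_days
    out[[g]] <- list(any = TRUE, prophylactic = any(proph), treatment = any(!proph))
  }
  out
}

#' Classify GCSF use in the chemotherapy treatment period
#'
#' A GCSF utilization (pharmacy fill or medical administration) during the
#' chemotherapy treatment period is *prophylactic* if it falls on the date of,
#' or within 4 days after, the first chemotherapy administration of the
#' period; any other utilization in the period counts as *treatment*. The two
#' categories are not mutually exclusive — an episode with several
#' utilizations can be both.
#'
#' @inheritParams classify_chemo_risk
#' @return Named logical list: `gcsf_any`, `gcsf_prophylactic`,
#'   `gcsf_treatment`, and the short-/long-acting splits
#'   `gcsf_long_prophylactic`, `gcsf_short_prophylactic`,
#'   `gcsf_long_treatment`, `gcsf_short_treatment`.
#' @export
classify_gcsf <- function(episode, dataset, codesets, config = fn_config()) {
  r <- classify_drug_use(episode$member_id, as.Date(episode$index_date),
                         dataset, codesets, config,
                         list(long = codesets$sets$gcsf_long,
                              short = codesets$sets$gcsf_short))
  list(
    gcsf_any = r$long$any || r$short$any,
    gcsf_prophylactic = r$long$prophylactic || r$short$prophylactic,
    gcsf_treatment = r$long$treatment || r$short$treatment,
    gcsf_long_prophylactic = r$long$prophylactic,
    gcsf_short_prophylactic = r$short$prophylactic,
    gcsf_long_treatment = r$long$treatment,
    gcsf_short_treatment = r$short$treatment
  )
}

#' Classify antimicrobial use in the chemotherapy treatment period
#'
#' Same prophylactic/treatment windowing as [classify_gcsf()], applied to the
#' union of the antibacterial, antifungal and antiviral codesets.
#'
#' @inheritParams classify_chemo_risk
#' @return Named logical list: `antimicrobial_any`,
#'   `antimicrobial_prophylactic`, `antimicrobial_treatment`.
#' @export
classify_antimicrobial <- function(episode, dataset, codesets, config = fn_config()) {
  r <- classify_drug_use(episode$member_id, as.Date(episode$index_date),
                         dataset, codesets, config,
                         list(am = cs_antimicrobial(codesets)))
  list(
    antimicrobial_any = r$am$any,
    antimicrobial_prophylactic = r$am$prophylactic,
    antimicrobial_treatment = r$am$treatment
  )
}

#' Score the NCI Charlson comorbidity index
#'
#' Each configured comorbidity condition contributes its weight at most once
#' when at least one qualifying diagnosis appears in the pre-episode lookback
#' window. The score is the sum of contributed weights, categorised as `zero`
#' (score 0), `gt0_lt2` (0 < score < 2), or `ge2` (score >= 2).
#'
#' @inheritParams classify_chemo_risk
#' @return List with `nci_cci_score` and `nci_category`.
#' @export
score_nci_cci <- function(episode, dataset, codesets, config = fn_config()) {
  mc <- member_claim_codes(dataset, episode$member_id)
  lb <- lookback_window(as.Date(episode$index_date), config)
  hit <- vapply(codesets$cci$codes, function(codes) {
    length(in_window(code_dates(mc, codes, proc = FALSE, drug = FALSE),
                     lb[1], lb[2])) > 0
  }, logical(1))
  score <- sum(codesets$cci$weight[hit])
  list(nci_cci_score = score, nci_category = nci_category(score))
}

nci_category <- function(score) {
  if_else(score == 0, "zero", if_else(score < 2, "gt0_lt2", "ge2"))
}

#' Flag NCCN risk factors for febrile neutropenia
#'
#' Flags the six guideline risk factors: older age (>= 65 years on the index
#' date, from the member's birth year), and diagnosis/procedure evidence of
#' bone metastasis, surgery, radiation, severe liver dysfunction and kidney
#' dysfunction in the pre-episode window. All factors are assessed
#' independently.
#'
#' @inheritParams classify_chemo_risk
#' @param member One-row tibble/list with `birth_year`.
#' @return Named logical list of the six flags plus `any_risk_factor`, and
#'   `age_years`.
#' @export
flag_risk_factors <- function(episode, member, dataset, codesets, config = fn_config()) {
  index <- as.Date(episode$index_date)
  age <- as.integer(format(index, "%Y")) - member$birth_year
  mc <- member_claim_codes(dataset, episode$member_id)
  lb <- lookback_window(index, config)
  seen <- function(codes, ...) {
    length(in_window(code_dates(mc, codes, ...), lb[1], lb[2])) > 0
  }
  flags <- list(
    older_age_ge65 = age >= 65,
    bone_metastasis = seen(codesets$sets$bone_met_dx, proc = FALSE, drug = FALSE),
    surgery = seen(codesets$sets$surgery_proc, dx = FALSE, drug = FALSE),
    radiation = seen(codesets$sets$radiation_codes, drug = FALSE),
    severe_liver_dysfunction = seen(codesets$sets$liver_dysfunction_dx,
                                    proc = FALSE, drug = FALSE),
    kidney_dysfunction = seen(codesets$sets$kidney_dysfunction_dx,
                              proc = FALSE, drug = FALSE)
  )
  flags$any_risk_factor <- Reduce(`||`, flags)
  flags$age_years <- age
  flags
}

age_category <- function(age) {
  dplyr::case_when(
    age < 18 ~ "lt18",
    age <= 59 ~ "a18_59",
    age <= 74 ~ "a60_74",
    TRUE ~ "ge75"
  )
}

#' Assign cancer-type subgroups
#'
#' Maps pre-episode diagnoses to the eight cancer groups (NHL, CLL, other
#' hematologic, breast, lung, colorectal, prostate, other solid). Membership
#' is a set of flags — an episode can belong to several groups, or to none.
#'
#' @inheritParams classify_chemo_risk
#' @return Named logical list `cancer_nhl`, ..., `cancer_other_solid`, plus
#'   composites `hematologic_any` and `solid_any`.
#' @export
assign_cancer_group <- function(episode, dataset, codesets, config = fn_config()) {
  mc <- member_claim_codes(dataset, episode$member_id)
  lb <- lookback_window(as.Date(episode$index_date), config)
  set_for <- c(nhl = "nhl_dx", cll = "cll_dx", other_hematologic = "other_heme_dx",
               breast = "breast_dx", lung = "lung_dx", colorectal = "colorectal_dx",
               prostate = "prostate_dx", other_solid = "other_solid_dx")
  flags <- lapply(set_for, function(s) {
    length(in_window(code_dates(mc, codesets$sets[[s]], proc = FALSE, drug = FALSE),
                     lb[1], lb[2])) > 0
  })
  names(flags) <- paste0("cancer_", names(set_for))
  flags$hematologic_any <- flags$cancer_nhl || flags$cancer_cll ||
    flags$cancer_other_hematologic
  flags$solid_any <- flags$cancer_breast || flags$cancer_lung ||
    flags$cancer_colorectal || flags$cancer_prostate || flags$cancer_other_solid
  flags
}

#' Classify all episodes of a cohort
#'
#' Runs every classifier over each episode and joins member demographics,
#' returning one row per episode: chemotherapy FN risk, GCSF and antimicrobial
#' flags, NCI CCI score and category, risk-factor flags, cancer-group flags,
#' age and age category, sex, payer and region.
#'
#' @param episodes Episode tibble from [build_cohort()] (`$episodes`).
#' @param dataset An `fn_claims` dataset.
#' @param codesets An `fn_codesets` registry.
#' @param config An [fn_config()].
#' @return Tibble with one row per episode.
#' @export
classify_episodes <- function(episodes, dataset, codesets, config = fn_config()) {
  members <- dataset$members
  # pre-split claims by member so per-episode work is member-local
  med_split <- split(dataset$medical, dataset$medical$member_id)
  ph_split <- split(dataset$pharmacy, dataset$pharmacy$member_id)
  med0 <- dataset$medical[0, , drop = FALSE]
  ph0 <- dataset$pharmacy[0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(episodes)), function(i) {
    ep <- episodes[i, ]
    mem <- members[members$member_id == ep$member_id, ][1, ]
    dsm <- list(medical = med_split[[ep$member_id]] %||% med0,
                pharmacy = ph_split[[ep$member_id]] %||% ph0)
    c(list(episode_id = ep$episode_id,
           chemo_risk = classify_chemo_risk(ep, dsm, codesets, config)),
      classify_gcsf(ep, dsm, codesets, config),
      classify_antimicrobial(ep, dsm, codesets, config),
      score_nci_cci(ep, dsm, codesets, config),
      flag_risk_factors(ep, mem, dsm, codesets, config),
      assign_cancer_group(ep, dsm, codesets, config),
      list(sex = mem$sex, payer = mem$payer, region = mem$region))
  })
  if (length(rows) == 0) return(empty_classification())
  out <- bind_rows(lapply(rows, as_tibble))
  out$age_category <- age_category(out$age_years)
  out
}

empty_classification <- function() {
  lgl <- logical()
  tibble(
    episode_id = character(), chemo_risk = character(),
    gcsf_any = lgl, gcsf_prophylactic = lgl, gcsf_treatment = lgl,
    gcsf_long_prophylactic = lgl, gcsf_short_prophylactic = lgl,
    gcsf_long_treatment = lgl, gcsf_short_treatment = lgl,
    antimicrobial_any = lgl, antimicrobial_prophylactic = lgl,
    antimicrobial_treatment = lgl,
    nci_cci_score = numeric(), nci_category = character(),
    older_age_ge65 = lgl, bone_metastasis = lgl, surgery = lgl, radiation = lgl,
    severe_liver_dysfunction = lgl, kidney_dysfunction = lgl,
    any_risk_factor = lgl, age_years = integer(),
    cancer_nhl = lgl, cancer_cll = lgl, cancer_other_hematologic = lgl,
    cancer_breast = lgl, cancer_lung = lgl, cancer_colorectal = lgl,
    cancer_prostate = lgl, cancer_other_solid = lgl,
    hematologic_any = lgl, solid_any = lgl,
    sex = character(), payer = character(), region = character(),
    age_category = character()
  )
}
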