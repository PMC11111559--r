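#' Moment-match lognormal parameters to a target mean and SD
#'
#' Returns `(meanlog, sdlog)` such that the analytic mean and SD of the
#' lognormal distribution equal the inputs:
#' `sdlog^2 = log(1 + (sd/mean)^2)`, `meanlog = log(mean) - sdlog^2 / 2`.
#'
#' @param mean Target mean, > 0.
#' @param sd Target standard deviation, > 0.
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @export
#' @examples
#' p <- lognormal_from_mean_sd(25176, 39943)
#' exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2) # reproduces the mean
lognormal_from_mean_sd <- function(mean, sd) {
  if (!is.finite(mean) || !is.finite(sd) || mean <= 0 || sd <= 0) {
    abort("lognormal_from_mean_sd requires mean > 0 and sd > 0")
  }
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

rlnorm_target <- function(n, mean, sd) {
  p <- lognormal_from_mean_sd(mean, sd)
  rlnorm(n, p[["meanlog"]], p[["sdlog"]])
}

VIOLATION_TYPES <- c(
  chemo_too_early = "chemo_within_lookback",
  enrollment_gap = "continuous_enrollment",
  dirty_pre_period = "clean_pre_period",
  bmt_sct_cart = "no_bmt_sct_cart",
  excluded_heme = "no_excluded_heme_malignancy",
  covid = "no_covid"
)

#' Synthetic-claims generator configuration
#'
#' Defaults emulate the structure the pipeline assumes, calibrated to the
#' study's central figures: 91.2% of episodes hospitalized, 2.9% of members
#' with a second qualifying episode, FN-related episode cost lognormal with
#' mean $25,176 and SD $39,943 (2021 USD), age ~ N(55.4, 15) truncated to
#' [1, 90], and the published prevalences for sex, payer, region, risk
#' factors, cancer groups and chemotherapy FN-risk mix.
#'
#' @param n_members Number of non-violation members (each plants 1--2 episodes).
#' @param seed Integer RNG seed; the generator is deterministic given the seed.
#' @param study_start,study_end Claims window (Dates).
#' @param p_hospitalized Probability a planted episode is hospitalized.
#' @param p_second_episode Probability a member plants a second episode.
#' @param fn_cost_mean,fn_cost_sd Target mean/SD of the planted FN-related
#'   episode cost, in 2021 USD (lognormal, moment-matched).
#' @param ip_los_mean Mean inpatient length of stay (days) for the FN stay.
#' @param gcsf_any_rate,gcsf_prophylactic_given_any,gcsf_treatment_given_any,
#'   gcsf_long_given_prophylactic,gcsf_long_given_treatment GCSF planting
#'   rates for the chemotherapy treatment period.
#' @param antimicrobial_any_rate,am_prophylactic_given_any,am_treatment_given_any
#'   Antimicrobial planting rates.
#' @param chemo_risk_mix Named probabilities over
#'   `c(high, intermediate, low_undefined)`, summing to 1.
#' @param rf_prevalence Named prevalences for the planted risk factors
#'   (`bone_metastasis`, `surgery`, `radiation`, `severe_liver_dysfunction`,
#'   `kidney_dysfunction`).
#' @param cancer_prevalence Named prevalences for the eight cancer groups
#'   (independent flags; overlap allowed).
#' @param comorbidity_prevalence Named prevalences per comorbidity condition
#'   in the codeset registry's condition map (conditions not named get 0).
#' @param age_mean,age_sd Age distribution at first index date.
#' @param sex_p,payer_p,region_p Named category probabilities.
#' @param er_rate Probability of an (unrelated) emergency-room visit during
#'   the episode; `office_visits_mean`, `other_outpatient_mean`,
#'   `pharmacy_fills_mean` are Poisson means for unrelated utilization.
#' @param office_cost,other_outpatient_cost,er_cost,pharmacy_cost,gcsf_cost,
#'   antimicrobial_cost Named `c(mean, sd)` lognormal targets (2021 USD) for
#'   per-claim costs.
#' @param n_violation_members Number of additional members planted with a
#'   labelled qualification violation (types cycled).
#' @param cpi_table CPI table used to deflate planted 2021-USD costs to
#'   nominal dollars of the service year.
#' @return A list of class `fn_synth_config`.
#' @export
synth_config <- function(n_members = 500,
                         seed = 1L,
                         study_start = as.Date("2014-07-01"),
                         study_end = as.Date("2021-12-31"),
                         p_hospitalized = 0.912,
                         p_second_episode = 0.029,
                         fn_cost_mean = 25176,
                         fn_cost_sd = 39943,
                         ip_los_mean = 6.9,
                         gcsf_any_rate = 0.40,
                         gcsf_prophylactic_given_any = 0.672,
                         gcsf_treatment_given_any = 0.584,
                         gcsf_long_given_prophylactic = 0.928,
                         gcsf_long_given_treatment = 0.769,
                         antimicrobial_any_rate = 0.241,
                         am_prophylactic_given_any = 0.284,
                         am_treatment_given_any = 0.793,
                         chemo_risk_mix = c(high = 0.197, intermediate = 0.494,
                                            low_undefined = 0.309),
                         rf_prevalence = c(bone_metastasis = 0.17, surgery = 0.86,
                                           radiation = 0.24,
                                           severe_liver_dysfunction = 0.033,
                                           kidney_dysfunction = 0.142),
                         cancer_prevalence = c(nhl = 0.144, cll = 0.021,
                                               other_hematologic = 0.072,
                                               breast = 0.273, lung = 0.152,
                                               colorectal = 0.111, prostate = 0.036,
                                               other_solid = 0.476),
                         comorbidity_prevalence = c(diabetes = 0.18, copd = 0.15,
                                                    chf = 0.07, renal_disease = 0.14,
                                                    mild_liver_disease = 0.08,
                                                    rheumatologic = 0.05,
                                                    acute_mi = 0.05, pvd = 0.06,
                                                    cvd = 0.07, diabetes_sequelae = 0.05,
                                                    mod_sev_liver = 0.033, ulcer = 0.03),
                         age_mean = 55.4, age_sd = 15,
                         sex_p = c(male = 0.394, female = 0.606),
                         payer_p = c(commercial = 0.875, medicare = 0.074,
                                     medicaid = 0.021, unknown = 0.030),
                         region_p = c(northeast = 0.177, midwest = 0.268,
                                      south = 0.400, west = 0.151, unknown = 0.004),
                         er_rate = 0.15,
                         office_visits_mean = 4,
                         other_outpatient_mean = 8,
                         pharmacy_fills_mean = 6,
                         office_cost = c(mean = 170, sd = 300),
                         other_outpatient_cost = c(mean = 420, sd = 900),
                         er_cost = c(mean = 1900, sd = 2900),
                         pharmacy_cost = c(mean = 600, sd = 1200),
                         gcsf_cost = c(mean = 4000, sd = 1000),
                         antimicrobial_cost = c(mean = 50, sd = 40),
                         n_violation_members = 0L,
                         cpi_table = load_cpi_table()) {
  cfg <- as.list(environment())
  probs <- c(p_hospitalized, p_second_episode, gcsf_any_rate,
             gcsf_prophylactic_given_any, gcsf_treatment_given_any,
             gcsf_long_given_prophylactic, gcsf_long_given_treatment,
             antimicrobial_any_rate, am_prophylactic_given_any,
             am_treatment_given_any, er_rate,
             chemo_risk_mix, rf_prevalence, cancer_prevalence,
             comorbidity_prevalence, sex_p, payer_p, region_p)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0, 1]")
  if (abs(sum(chemo_risk_mix) - 1) > 1e-8) abort("chemo_risk_mix must sum to 1")
  for (nm in c("fn_cost_mean", "fn_cost_sd")) {
    if (cfg[[nm]] <= 0) abort(paste0(nm, " must be > 0"))
  }
  if (n_members < 1) abort("n_members must be >= 1")
  structure(cfg, class = "fn_synth_config")
}

first_code <- function(codesets, set) codesets$sets[[set]][1]

#' Generate a seeded synthetic claims dataset with a ground-truth ledger
#'
#' Emits members, enrollment spans, medical and pharmacy claims consistent
#' with the planted episode structure, plus a ground-truth ledger recording —
#' per planted episode — the intended index and end dates, hospitalization
#' flag, planted FN-related cost (2021 USD), chemotherapy risk class, GCSF and
#' antimicrobial use flags, risk-factor/comorbidity/cancer labels, and any
#' planted qualification violation with the criterion it should fail. Tests
#' use the ledger as the oracle; they never re-derive intent from the claims.
#'
#' Costs are drawn in 2021 USD from moment-matched lognormals and deflated to
#' nominal dollars of the service year with the configured CPI table, so the
#' pipeline's inflation adjustment recovers the planted amounts.
#'
#' @param config An [synth_config()].
#' @param codesets The `fn_codesets` registry whose codes the claims use
#'   (defaults to the shipped configuration).
#' @return A list of class `fn_synth`: `dataset` (validated [fn_claims()]),
#'   `ground_truth` (tibble), and `config`.
#' @export
generate_synthetic_claims <- function(config = synth_config(),
                                      codesets = load_codesets()) {
  stopifnot(inherits(config, "fn_synth_config"))
  # deterministic given seed; restore caller RNG state afterwards
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  pre_days <- 180L
  two_ep_extra <- 151L # second index at +91..+151 days
  earliest <- config$study_start + pre_days
  latest1 <- config$study_end - 61L
  latest2 <- latest1 - two_ep_extra
  if (earliest > latest1 || (config$p_second_episode > 0 && earliest > latest2)) {
    abort("infeasible config: study window too short for episode plus lookback windows")
  }

  n <- config$n_members
  member_id <- sprintf("M%05d", seq_len(n))
  two_ep <- runif(n) < config$p_second_episode
  hi <- ifelse(two_ep, as.integer(latest2), as.integer(latest1)) - as.integer(earliest)
  index1 <- earliest + floor(runif(n) * (hi + 1))

  age <- pmin(90, pmax(1, round(rnorm(n, config$age_mean, config$age_sd))))
  birth_year <- as.integer(format(index1, "%Y")) - age
  samp_cat <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)
  members <- tibble(
    member_id = member_id, birth_year = birth_year,
    sex = samp_cat(config$sex_p, n), payer = samp_cat(config$payer_p, n),
    region = samp_cat(config$region_p, n)
  )

  # episode-level frame
  n_epi <- 1L + two_ep
  ep <- tibble(
    member_id = rep(member_id, n_epi),
    episode_seq = sequence(n_epi),
    index_date = as.Date(unlist(mapply(function(i1, k) {
      if (k == 1) i1 else c(i1, i1 + 91L + sample.int(61L, 1) - 1L)
    }, index1, n_epi, SIMPLIFY = FALSE), use.names = FALSE), origin = "1970-01-01")
  )
  ne <- nrow(ep)
  ep$hospitalized <- runif(ne) < config$p_hospitalized
  ep$chemo_risk <- samp_cat(config$chemo_risk_mix, ne)
  ep$first_chemo <- ep$index_date - sample(7:25, ne, replace = TRUE)
  ep$second_admin <- runif(ne) < 0.5
  ep$fn_cost_2021 <- rlnorm_target(ne, config$fn_cost_mean, config$fn_cost_sd)
  ep$los <- pmin(45L, 1L + rpois(ne, max(config$ip_los_mean - 1, 0.1)))
  ep$end_date <- ep$index_date + 60L

  # GCSF / antimicrobial planting
  ep$gcsf_any <- runif(ne) < config$gcsf_any_rate
  gp <- runif(ne) < config$gcsf_prophylactic_given_any
  gt <- runif(ne) < config$gcsf_treatment_given_any
  gp[ep$gcsf_any & !gp & !gt] <- TRUE
  ep$gcsf_proph <- ep$gcsf_any & gp
  ep$gcsf_treat <- ep$gcsf_any & gt
  ep$gcsf_proph_long <- ep$gcsf_proph & (runif(ne) < config$gcsf_long_given_prophylactic)
  ep$gcsf_treat_long <- ep$gcsf_treat & (runif(ne) < config$gcsf_long_given_treatment)

  ep$am_any <- runif(ne) < config$antimicrobial_any_rate
  ap <- runif(ne) < config$am_prophylactic_given_any
  at <- runif(ne) < config$am_treatment_given_any
  ap[ep$am_any & !ap & !at] <- TRUE
  ep$am_proph <- ep$am_any & ap
  ep$am_treat <- ep$am_any & at

  # risk factors / cancer groups / comorbidities (independent flags)
  for (rf in names(config$rf_prevalence)) {
    ep[[paste0("rf_", rf)]] <- runif(ne) < config$rf_prevalence[[rf]]
  }
  for (cg in names(config$cancer_prevalence)) {
    ep[[paste0("cancer_", cg)]] <- runif(ne) < config$cancer_prevalence[[cg]]
  }
  cci_conditions <- intersect(names(config$comorbidity_prevalence),
                              codesets$cci$condition)
  for (cc in cci_conditions) {
    ep[[paste0("cci_", cc)]] <- runif(ne) < config$comorbidity_prevalence[[cc]]
  }
  wts <- setNames(codesets$cci$weight, codesets$cci$condition)
  cci_mat <- as.matrix(ep[paste0("cci_", cci_conditions)])
  ep$planted_cci_score <- as.numeric(cci_mat %*% wts[cci_conditions])

  # cost deflation: planted targets are 2021 USD; claims carry nominal dollars
  deflate <- function(amount_2021, date) {
    yr <- format(date, "%Y")
    amount_2021 * unname(config$cpi_table[yr]) / config$cpi_table[["2021"]]
  }
  draw_cost <- function(k, target) rlnorm_target(k, target[["mean"]], target[["sd"]])

  med_blocks <- list()
  ph_blocks <- list()
  mk_med <- function(member_id, service_date, setting, dx, proc, amount_2021,
                     discharge_date = as.Date(NA)) {
    tibble(member_id = member_id, service_date = service_date,
           discharge_date = discharge_date, setting = setting,
           dx_codes = dx, proc_codes = proc,
           paid_amount = round(deflate(amount_2021, service_date), 2))
  }
  mk_ph <- function(member_id, fill_date, drug_code, amount_2021) {
    tibble(member_id = member_id, fill_date = fill_date, drug_code = drug_code,
           paid_amount = round(deflate(amount_2021, fill_date), 2))
  }

  fn_trigger_dx <- paste(first_code(codesets, "neutropenia_dx"),
                         first_code(codesets, "fever_dx"), sep = ";")
  benign_dx <- "I10"
  benign_drug <- "ndc-omeprazole-20"

  # trigger claims
  hosp <- ep$hospitalized
  if (any(hosp)) {
    med_blocks$trigger_ip <- mk_med(
      ep$member_id[hosp], ep$index_date[hosp], "inpatient",
      fn_trigger_dx, "", ep$fn_cost_2021[hosp],
      discharge_date = ep$index_date[hosp] + ep$los[hosp])
  }
  if (any(!hosp)) {
    abx_cost <- pmin(100, 0.02 * ep$fn_cost_2021[!hosp])
    med_blocks$trigger_op <- mk_med(
      ep$member_id[!hosp], ep$index_date[!hosp], "other_outpatient",
      fn_trigger_dx, "", ep$fn_cost_2021[!hosp] - abx_cost)
    ph_blocks$trigger_abx <- mk_ph(
      ep$member_id[!hosp], ep$index_date[!hosp],
      first_code(codesets, "abx_levofloxacin"), abx_cost)
  }

  # chemotherapy administrations (medical claims with drug procedure codes)
  risk_drugs <- list(
    high = c("docetaxel", "doxorubicin", "cyclophosphamide"),        # TAC
    intermediate = c("carboplatin", "paclitaxel"),
    low_undefined = "gemcitabine"
  )
  chemo_proc <- vapply(risk_drugs, function(d) {
    paste(vapply(codesets$chemo_drugs[d], `[`, character(1), 1), collapse = ";")
  }, character(1))
  ep_proc <- chemo_proc[ep$chemo_risk]
  med_blocks$chemo1 <- mk_med(ep$member_id, ep$first_chemo, "other_outpatient",
                              "", ep_proc, rep(800, ne))
  if (any(ep$second_admin)) {
    s <- ep$second_admin
    med_blocks$chemo2 <- mk_med(ep$member_id[s],
                                ep$first_chemo[s] + sample(3:5, sum(s), replace = TRUE),
                                "other_outpatient", "", ep_proc[s], rep(800, sum(s)))
  }

  # GCSF fills in the chemotherapy treatment period
  gcsf_code <- function(long) ifelse(long, first_code(codesets, "gcsf_long"),
                                     first_code(codesets, "gcsf_short"))
  if (any(ep$gcsf_proph)) {
    s <- ep$gcsf_proph
    ph_blocks$gcsf_p <- mk_ph(ep$member_id[s],
                              ep$first_chemo[s] + sample(0:4, sum(s), replace = TRUE),
                              gcsf_code(ep$gcsf_proph_long[s]),
                              draw_cost(sum(s), config$gcsf_cost))
  }
  if (any(ep$gcsf_treat)) {
    s <- ep$gcsf_treat
    span <- as.integer(ep$index_date[s] - 1 - (ep$first_chemo[s] + 5))
    offs <- 5L + floor(runif(sum(s)) * (span + 1))
    ph_blocks$gcsf_t <- mk_ph(ep$member_id[s], ep$first_chemo[s] + offs,
                              gcsf_code(ep$gcsf_treat_long[s]),
                              draw_cost(sum(s), config$gcsf_cost))
  }
  am_code <- first_code(codesets, "abx_ciprofloxacin")
  if (any(ep$am_proph)) {
    s <- ep$am_proph
    ph_blocks$am_p <- mk_ph(ep$member_id[s],
                            ep$first_chemo[s] + sample(0:4, sum(s), replace = TRUE),
                            am_code, draw_cost(sum(s), config$antimicrobial_cost))
  }
  if (any(ep$am_treat)) {
    s <- ep$am_treat
    span <- as.integer(ep$index_date[s] - 1 - (ep$first_chemo[s] + 5))
    offs <- 5L + floor(runif(sum(s)) * (span + 1))
    ph_blocks$am_t <- mk_ph(ep$member_id[s], ep$first_chemo[s] + offs,
                            am_code, draw_cost(sum(s), config$antimicrobial_cost))
  }

  # pre-episode diagnosis/procedure plants (benign wrt the FN case definition)
  plant_window_date <- function(k, index) index - sample(40:170, k, replace = TRUE)
  plant_dx <- function(flag_col, code, proc = FALSE) {
    s <- which(ep[[flag_col]])
    if (!length(s)) return(NULL)
    mk_med(ep$member_id[s], plant_window_date(length(s), ep$index_date[s]),
           "physician_office",
           if (proc) "" else code, if (proc) code else "",
           runif(length(s), 80, 300))
  }
  rf_specs <- list(
    rf_bone_metastasis = list(set = "bone_met_dx", proc = FALSE),
    rf_surgery = list(set = "surgery_proc", proc = TRUE),
    rf_radiation = list(set = "radiation_codes", proc = TRUE),
    rf_severe_liver_dysfunction = list(set = "liver_dysfunction_dx", proc = FALSE),
    rf_kidney_dysfunction = list(set = "kidney_dysfunction_dx", proc = FALSE)
  )
  for (nm in names(rf_specs)) {
    if (nm %in% names(ep)) {
      med_blocks[[nm]] <- plant_dx(nm, first_code(codesets, rf_specs[[nm]]$set),
                                   rf_specs[[nm]]$proc)
    }
  }
  cancer_sets <- c(nhl = "nhl_dx", cll = "cll_dx", other_hematologic = "other_heme_dx",
                   breast = "breast_dx", lung = "lung_dx", colorectal = "colorectal_dx",
                   prostate = "prostate_dx", other_solid = "other_solid_dx")
  for (cg in names(cancer_sets)) {
    col <- paste0("cancer_", cg)
    if (col %in% names(ep)) {
      med_blocks[[col]] <- plant_dx(col, first_code(codesets, cancer_sets[[cg]]))
    }
  }
  cci_code <- setNames(vapply(codesets$cci$codes, `[`, character(1), 1),
                       codesets$cci$condition)
  for (cc in cci_conditions) {
    med_blocks[[paste0("cci_", cc)]] <- plant_dx(paste0("cci_", cc), cci_code[[cc]])
  }

  # unrelated utilization during the episode window (all-cause only)
  plant_util <- function(counts, setting, target) {
    s <- which(counts > 0)
    if (!length(s)) return(NULL)
    k <- counts[s]
    mk_med(rep(ep$member_id[s], k),
           rep(ep$index_date[s], k) + sample(0:60, sum(k), replace = TRUE),
           setting, benign_dx, "", draw_cost(sum(k), target))
  }
  med_blocks$office <- plant_util(rpois(ne, config$office_visits_mean),
                                  "physician_office", config$office_cost)
  med_blocks$other <- plant_util(rpois(ne, config$other_outpatient_mean),
                                 "other_outpatient", config$other_outpatient_cost)
  med_blocks$er <- plant_util(as.integer(runif(ne) < config$er_rate),
                              "emergency_room", config$er_cost)
  n_fills <- rpois(ne, config$pharmacy_fills_mean)
  s <- which(n_fills > 0)
  if (length(s)) {
    k <- n_fills[s]
    ph_blocks$unrelated <- mk_ph(rep(ep$member_id[s], k),
                                 rep(ep$index_date[s], k) + sample(0:60, sum(k), replace = TRUE),
                                 benign_drug, draw_cost(sum(k), config$pharmacy_cost))
  }

  enrollment <- tibble(
    member_id = member_id,
    start_date = index1 - 200L,
    end_date = index1 + ifelse(two_ep, 151L, 0L) + 90L
  )

  truth <- ep %>%
    mutate(violation = NA_character_, expected_rejection = NA_character_) %>%
    select("member_id", "episode_seq", "index_date",
           expected_end_date = "end_date", "hospitalized", "chemo_risk",
           "first_chemo", "fn_cost_2021", "gcsf_any", "gcsf_proph", "gcsf_treat",
           "gcsf_proph_long", "gcsf_treat_long", "am_any", "am_proph", "am_treat",
           dplyr::starts_with("rf_"), dplyr::starts_with("cancer_"),
           dplyr::starts_with("cci_"), "planted_cci_score",
           "violation", "expected_rejection")

  # violation members: one candidate each, planted to fail a known criterion
  nv <- as.integer(config$n_violation_members)
  if (nv > 0) {
    vtypes <- rep_len(names(VIOLATION_TYPES), nv)
    vid <- sprintf("V%04d", seq_len(nv))
    vindex <- earliest + floor(runif(nv) * (as.integer(latest1 - earliest) + 1))
    vb_year <- as.integer(format(vindex, "%Y")) -
      pmin(90, pmax(1, round(rnorm(nv, config$age_mean, config$age_sd))))
    members <- bind_rows(members, tibble(
      member_id = vid, birth_year = vb_year,
      sex = samp_cat(config$sex_p, nv), payer = samp_cat(config$payer_p, nv),
      region = samp_cat(config$region_p, nv)))
    enrollment <- bind_rows(enrollment, tibble(
      member_id = vid,
      start_date = vindex - ifelse(vtypes == "enrollment_gap", 100L, 200L),
      end_date = vindex + 90L))
    med_blocks$v_trigger <- mk_med(vid, vindex, "inpatient", fn_trigger_dx, "",
                                   rlnorm_target(nv, config$fn_cost_mean,
                                                 config$fn_cost_sd),
                                   discharge_date = vindex + 5L)
    chemo_off <- ifelse(vtypes == "chemo_too_early", 31L, 10L)
    med_blocks$v_chemo <- mk_med(vid, vindex - chemo_off, "other_outpatient", "",
                                 chemo_proc[["low_undefined"]], rep(800, nv))
    vplant <- function(type, code, proc = FALSE, offset = 60L) {
      s <- which(vtypes == type)
      if (!length(s)) return(NULL)
      mk_med(vid[s], vindex[s] - offset, "physician_office",
             if (proc) "" else code, if (proc) code else "",
             runif(length(s), 80, 300))
    }
    med_blocks$v_dirty <- vplant("dirty_pre_period",
                                 first_code(codesets, "fever_dx"), offset = 90L)
    med_blocks$v_bmt <- vplant("bmt_sct_cart",
                               first_code(codesets, "bmt_sct_cart_proc"), proc = TRUE)
    med_blocks$v_heme <- vplant("excluded_heme",
                                first_code(codesets, "excluded_heme_dx"))
    med_blocks$v_covid <- vplant("covid", first_code(codesets, "covid_dx"),
                                 offset = 50L)
    truth <- bind_rows(truth, tibble(
      member_id = vid, episode_seq = 1L, index_date = vindex,
      expected_end_date = vindex + 60L, hospitalized = TRUE,
      chemo_risk = "low_undefined", first_chemo = vindex - chemo_off,
      fn_cost_2021 = NA_real_,
      violation = vtypes,
      expected_rejection = unname(VIOLATION_TYPES[vtypes])))
  }

  medical <- bind_rows(med_blocks) %>%
    arrange(.data$member_id, .data$service_date, .data$setting) %>%
    mutate(claim_id = sprintf("MC%07d", row_number()), .before = 1)
  pharmacy <- bind_rows(ph_blocks) %>%
    arrange(.data$member_id, .data$fill_date, .data$drug_code) %>%
    mutate(claim_id = sprintf("RX%07d", row_number()), .before = 1)

  dataset <- fn_claims(medical, pharmacy, enrollment, members)
  structure(list(dataset = dataset, ground_truth = truth, config = config),
            class = "fn_synth")
}

#' @export
print.fn_synth <- function(x, ...) {
  cat("<fn_synth> ", nrow(x$ground_truth), " planted episodes (",
      sum(!is.na(x$ground_truth$violation)), " violations), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}
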