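cs <- test_codesets()
NEUT <- cs$sets$neutropenia_dx[1]
FEVER <- cs$sets$fever_dx[1]
BACT <- cs$sets$bacterial_infection_dx[1]
CHEMO <- cs$chemo_drugs$gemcitabine[1]

test_that("inpatient definition fires on same-day neutropenia plus fever", {
  med <- mk_medical(
    list(member_id = "A", date = d0, setting = "inpatient", discharge = d0 + 2,
         dx = paste(NEUT, FEVER, sep = ";"))
  )
  ds <- fn_claims(med, mk_pharmacy(), mk_enrollment("A"), mk_members("A"))
  cands <- detect_candidates(ds, cs)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$index_date, d0)
  expect_equal(cands$trigger, "inpatient_def")
})

test_that("outpatient definition requires same-day antibiotic evidence", {
  med <- mk_medical(
    list(member_id = "A", date = d0, setting = "physician_office",
         dx = paste(NEUT, BACT, sep = ";"))
  )
  # no antibiotic that day -> no candidate
  ds <- fn_claims(med, mk_pharmacy(), mk_enrollment("A"), mk_members("A"))
  expect_equal(nrow(detect_candidates(ds, cs)), 0)
  # oral combination rule satisfied -> candidate
  ph <- mk_pharmacy(
    list(member_id = "A", date = d0, drug = cs$sets$abx_ciprofloxacin[1]),
    list(member_id = "A", date = d0, drug = cs$sets$abx_amoxicillin_clavulanate[1])
  )
  ds2 <- fn_claims(med, ph, mk_enrollment("A"), mk_members("A"))
  cands <- detect_candidates(ds2, cs)
  expect_equal(cands$trigger, "outpatient_def")
  # ciprofloxacin alone is not an NCCN-listed regimen -> no candidate
  ph3 <- mk_pharmacy(list(member_id = "A", date = d0, drug = cs$sets$abx_ciprofloxacin[1]))
  ds3 <- fn_claims(med, ph3, mk_enrollment("A"), mk_members("A"))
  expect_equal(nrow(detect_candidates(ds3, cs)), 0)
  # parenteral antibiotic procedure code on the same date also qualifies
  med4 <- rbind(med, mk_medical(
    list(member_id = "A", date = d0, setting = "other_outpatient",
         proc = cs$sets$nccn_parenteral_antibiotic_proc[1]),
    claim_id = "MCX1"))
  ds4 <- fn_claims(med4, mk_pharmacy(), mk_enrollment("A"), mk_members("A"))
  expect_equal(detect_candidates(ds4, cs)$trigger, "outpatient_def")
})

test_that("candidate detection matches the exhaustive oracle on a mixed fixture", {
  # 12 hand-built claims across both definitions and both failure modes
  med <- mk_medical(
    list(member_id = "A", date = d0, setting = "inpatient", discharge = d0 + 2,
         dx = paste(NEUT, FEVER, sep = ";")),                        # inpatient hit
    list(member_id = "A", date = d0 + 10, setting = "inpatient", discharge = d0 + 12,
         dx = NEUT),                                                  # neut only: miss
    list(member_id = "A", date = d0 + 20, setting = "physician_office",
         dx = paste(NEUT, BACT, sep = ";")),                          # outp + abx below
    list(member_id = "B", date = d0, setting = "physician_office",
         dx = paste(NEUT, BACT, sep = ";")),                          # no abx: miss
    list(member_id = "B", date = d0 + 5, setting = "inpatient", discharge = d0 + 6,
         dx = FEVER),                                                 # fever only: miss
    list(member_id = "B", date = d0 + 9, setting = "inpatient", discharge = d0 + 9,
         dx = NEUT),
    list(member_id = "B", date = d0 + 9, setting = "inpatient", discharge = d0 + 10,
         dx = BACT),                                                  # same-day union hit
    list(member_id = "C", date = d0 + 1, setting = "emergency_room",
         dx = paste(NEUT, FEVER, sep = ";")),                         # ER + parenteral
    list(member_id = "C", date = d0 + 1, setting = "emergency_room",
         proc = cs$sets$nccn_parenteral_antibiotic_proc[1]),
    list(member_id = "C", date = d0 + 30, setting = "other_outpatient", dx = NEUT),
    list(member_id = "C", date = d0 + 30, setting = "physician_office", dx = FEVER),
    list(member_id = "C", date = d0 + 40, setting = "physician_office", dx = "I10")
  )
  ph <- mk_pharmacy(
    list(member_id = "A", date = d0 + 20, drug = cs$sets$abx_levofloxacin[1])
  )
  ds <- fn_claims(med, ph, mk_enrollment(c("A", "B", "C")), mk_members(c("A", "B", "C")))
  got <- detect_candidates(ds, cs)
  want <- oracle_candidates(ds, cs)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$member_id, want$member_id)
  expect_equal(got$index_date, want$index_date)
  expect_equal(got$trigger, want$trigger)
  # spot-check the expected set: A d0, A d0+20, B d0+9, C d0+1 (C d0+30 lacks abx)
  expect_setequal(paste(got$member_id, got$index_date - d0),
                  c("A 0", "A 20", "B 9", "C 1"))
})

qualify_fixture <- function(chemo_offset = -10, enroll_start = d0 - 400,
                            extra = NULL) {
  med <- mk_medical(
    list(member_id = "A", date = d0 + chemo_offset, setting = "other_outpatient",
         proc = CHEMO),
    list(member_id = "A", date = d0, setting = "inpatient", discharge = d0 + 3,
         dx = paste(NEUT, FEVER, sep = ";"))
  )
  if (!is.null(extra)) {
    extra$claim_id <- sprintf("MX%03d", seq_len(nrow(extra)))
    med <- rbind(med, extra)
  }
  fn_claims(med, mk_pharmacy(), mk_enrollment("A", start = enroll_start),
            mk_members("A"))
}
cand_a <- list(member_id = "A", index_date = d0)

test_that("qualification boundaries are exact for the chemotherapy lookback", {
  expect_true(qualify_candidate(cand_a, qualify_fixture(-10), cs)$ok)
  expect_true(qualify_candidate(cand_a, qualify_fixture(-30), cs)$ok)
  q31 <- qualify_candidate(cand_a, qualify_fixture(-31), cs)
  expect_false(q31$ok)
  expect_equal(q31$reason, "chemo_within_lookback")
  # chemo on the index date does not count by default, but can be configured to
  q0 <- qualify_candidate(cand_a, qualify_fixture(0), cs)
  expect_false(q0$ok)
  expect_true(qualify_candidate(cand_a, qualify_fixture(0), cs,
                                fn_config(chemo_on_index_qualifies = TRUE))$ok)
})

test_that("enrollment must cover the full 180-day pre-episode period", {
  expect_true(qualify_candidate(cand_a, qualify_fixture(enroll_start = d0 - 180), cs)$ok)
  q <- qualify_candidate(cand_a, qualify_fixture(enroll_start = d0 - 179), cs)
  expect_false(q$ok)
  expect_equal(q$reason, "continuous_enrollment")
  # a gap inside the period also fails, and adjacent spans are merged first
  med <- mk_medical(
    list(member_id = "A", date = d0 - 10, setting = "other_outpatient", proc = CHEMO),
    list(member_id = "A", date = d0, setting = "inpatient", discharge = d0 + 3,
         dx = paste(NEUT, FEVER, sep = ";"))
  )
  enr2 <- rbind(mk_enrollment("A", start = d0 - 400, end = d0 - 100),
                mk_enrollment("A", start = d0 - 99, end = d0 + 100))
  ds2 <- fn_claims(med, mk_pharmacy(), enr2, mk_members("A"))
  expect_true(qualify_candidate(cand_a, ds2, cs)$ok)
  enr3 <- rbind(mk_enrollment("A", start = d0 - 400, end = d0 - 100),
                mk_enrollment("A", start = d0 - 97, end = d0 + 100))
  ds3 <- fn_claims(med, mk_pharmacy(), enr3, mk_members("A"))
  expect_false(qualify_candidate(cand_a, ds3, cs)$ok)
})

test_that("pre-period diagnoses disqualify at the exact boundary", {
  fever_at <- function(off) mk_medical(
    list(member_id = "A", date = d0 + off, setting = "physician_office", dx = FEVER))
  # fever at index-1 disqualifies
  q <- qualify_candidate(cand_a, qualify_fixture(extra = fever_at(-1)), cs)
  expect_false(q$ok)
  expect_equal(q$reason, "clean_pre_period")
  # fever at index-180 disqualifies; at index-181 it is outside the window
  expect_false(qualify_candidate(cand_a, qualify_fixture(extra = fever_at(-180)), cs)$ok)
  expect_true(qualify_candidate(cand_a, qualify_fixture(extra = fever_at(-181)), cs)$ok)
})

test_that("exclusion criteria reject with the first failing label in fixed order", {
  bmt <- mk_medical(list(member_id = "A", date = d0 - 60,
                         setting = "other_outpatient",
                         proc = cs$sets$bmt_sct_cart_proc[1]))
  heme <- mk_medical(list(member_id = "A", date = d0 - 60,
                          setting = "physician_office",
                          dx = cs$sets$excluded_heme_dx[1]))
  covid <- mk_medical(list(member_id = "A", date = d0 - 50,
                           setting = "physician_office",
                           dx = cs$sets$covid_dx[1]))
  expect_equal(qualify_candidate(cand_a, qualify_fixture(extra = bmt), cs)$reason,
               "no_bmt_sct_cart")
  expect_equal(qualify_candidate(cand_a, qualify_fixture(extra = heme), cs)$reason,
               "no_excluded_heme_malignancy")
  expect_equal(qualify_candidate(cand_a, qualify_fixture(extra = covid), cs)$reason,
               "no_covid")
  # planted violations of several criteria: the first in order a->f wins
  both <- rbind(bmt, heme)
  expect_equal(qualify_candidate(cand_a, qualify_fixture(extra = both), cs)$reason,
               "no_bmt_sct_cart")
  # COVID on the index date excludes by default but not when configured off
  covid_idx <- mk_medical(list(member_id = "A", date = d0,
                               setting = "physician_office",
                               dx = cs$sets$covid_dx[1]))
  expect_false(qualify_candidate(cand_a, qualify_fixture(extra = covid_idx), cs)$ok)
  expect_true(qualify_candidate(cand_a, qualify_fixture(extra = covid_idx), cs,
                                fn_config(covid_includes_index = FALSE))$ok)
})

test_that("planted generator violations are rejected with matching labels", {
  syn <- generate_synthetic_claims(
    synth_config(n_members = 25, seed = 11, n_violation_members = 18),
    cs)
  cohort <- build_cohort(syn$dataset, cs)
  viol <- syn$ground_truth[!is.na(syn$ground_truth$violation), ]
  rej <- merge(viol, cohort$rejections, by = c("member_id", "index_date"))
  expect_equal(nrow(rej), nrow(viol))
  expect_equal(rej$reason, rej$expected_rejection)
})

test_that("termination uses next chemo, the 60-day cap, and LOS extension", {
  # no further chemo, no hospitalization extension -> cap at index+60, length 61
  ds <- qualify_fixture()
  t1 <- terminate_episode(d0, "A", ds, cs)
  expect_equal(t1$end_date, d0 + 60)
  expect_true(t1$has_hospitalization)
  # next chemo at index+20 terminates there; chemo on the index date does not
  chemo_after <- mk_medical(
    list(member_id = "A", date = d0, setting = "other_outpatient", proc = CHEMO),
    list(member_id = "A", date = d0 + 20, setting = "other_outpatient", proc = CHEMO))
  ds2 <- qualify_fixture(extra = chemo_after)
  expect_equal(terminate_episode(d0, "A", ds2, cs)$end_date, d0 + 20)
  # FN stay admitted at +55 discharged +70 extends past the cap
  stay <- mk_medical(list(member_id = "A", date = d0 + 55, setting = "inpatient",
                          discharge = d0 + 70, dx = FEVER))
  ds3 <- qualify_fixture(extra = stay)
  t3 <- terminate_episode(d0, "A", ds3, cs)
  expect_equal(t3$end_date, d0 + 70)
  # a non-FN stay does not extend
  stay_benign <- mk_medical(list(member_id = "A", date = d0 + 55,
                                 setting = "inpatient", discharge = d0 + 70,
                                 dx = "I10"))
  expect_equal(terminate_episode(d0, "A", qualify_fixture(extra = stay_benign),
                                 cs)$end_date, d0 + 60)
})

test_that("washout retains episodes exactly when a 30-day clean gap exists", {
  eps <- tibble::tibble(index_date = c(d0, d0 + 100),
                        end_date = c(d0 + 60, d0 + 160))
  # single episode always retained
  expect_equal(nrow(apply_washout(eps[1, ], as.Date(character()))), 1)
  # clean gap of 39 days -> retained
  expect_equal(nrow(apply_washout(eps, as.Date(character()))), 2)
  # second index only 10 days after first end -> dropped
  eps2 <- tibble::tibble(index_date = c(d0, d0 + 70), end_date = c(d0 + 60, d0 + 130))
  expect_equal(nrow(apply_washout(eps2, as.Date(character()))), 1)
  # fever claims can destroy every 30-day window
  gap_mid <- d0 + 80 # splits the 39-day gap into runs of 19 and 19
  expect_equal(nrow(apply_washout(eps, gap_mid)), 1)
  # a fever date leaving one clean 30-day run keeps the episode
  expect_equal(nrow(apply_washout(eps, d0 + 65)), 2)
})

test_that("washout matches a brute-force scan on a scattered-fever timeline", {
  set.seed(404)
  for (rep in 1:10) {
    n_fev <- sample(0:6, 1)
    fevers <- d0 + sample(0:400, n_fev)
    idx <- sort(d0 + sample(0:300, 4))
    eps <- tibble::tibble(index_date = idx, end_date = idx + 20)
    got <- apply_washout(eps, fevers)
    # brute force: iterate, scanning every possible 30-day window
    keep <- 1
    prev_end <- eps$end_date[1]
    for (i in 2:4) {
      lo <- as.integer(prev_end + 1); hi <- as.integer(eps$index_date[i] - 1)
      found <- FALSE
      if (hi - lo + 1 >= 30) {
        for (s in lo:(hi - 29)) {
          if (!any(as.integer(fevers) %in% s:(s + 29))) { found <- TRUE; break }
        }
      }
      if (found) { keep <- c(keep, i); prev_end <- eps$end_date[i] }
    }
    expect_equal(got$index_date, eps$index_date[keep])
  }
})

test_that("build_cohort equals the naive exhaustive reference on small datasets", {
  # hand-built 5-member fixture with known outcomes
  med <- rbind(
    mk_medical(
      # A: clean episode
      list(member_id = "A", date = d0 - 12, setting = "other_outpatient", proc = CHEMO),
      list(member_id = "A", date = d0, setting = "inpatient", discharge = d0 + 4,
           dx = paste(NEUT, FEVER, sep = ";")),
      # B: chemo too early -> rejected
      list(member_id = "B", date = d0 - 31, setting = "other_outpatient", proc = CHEMO),
      list(member_id = "B", date = d0, setting = "inpatient", discharge = d0 + 2,
           dx = paste(NEUT, BACT, sep = ";")),
      # C: two episodes with a clean gap; second one qualifies via washout
      list(member_id = "C", date = d0 - 15, setting = "other_outpatient", proc = CHEMO),
      list(member_id = "C", date = d0, setting = "inpatient", discharge = d0 + 3,
           dx = paste(NEUT, FEVER, sep = ";")),
      list(member_id = "C", date = d0 + 110, setting = "other_outpatient", proc = CHEMO),
      list(member_id = "C", date = d0 + 120, setting = "inpatient", discharge = d0 + 124,
           dx = paste(NEUT, FEVER, sep = ";")),
      # D: dirty pre-period (fever at index-40)
      list(member_id = "D", date = d0 - 40, setting = "physician_office", dx = FEVER),
      list(member_id = "D", date = d0 - 10, setting = "other_outpatient", proc = CHEMO),
      list(member_id = "D", date = d0, setting = "inpatient", discharge = d0 + 1,
           dx = paste(NEUT, FEVER, sep = ";")),
      # E: outpatient definition with levofloxacin, terminated by next chemo
      list(member_id = "E", date = d0 - 5, setting = "other_outpatient", proc = CHEMO),
      list(member_id = "E", date = d0, setting = "physician_office",
           dx = paste(NEUT, BACT, sep = ";")),
      list(member_id = "E", date = d0 + 25, setting = "other_outpatient", proc = CHEMO)
    )
  )
  ph <- mk_pharmacy(list(member_id = "E", date = d0, drug = cs$sets$abx_levofloxacin[1]))
  ids <- c("A", "B", "C", "D", "E")
  ds <- fn_claims(med, ph, mk_enrollment(ids), mk_members(ids))
  got <- build_cohort(ds, cs)
  want <- oracle_build_cohort(ds, cs)
  expect_equal(nrow(got$episodes), nrow(want))
  expect_equal(got$episodes$member_id, want$member_id)
  expect_equal(got$episodes$index_date, want$index_date)
  expect_equal(got$episodes$end_date, want$end_date)
  expect_equal(got$episodes$has_hospitalization, want$has_hospitalization)
  # known outcomes: A, C (twice), E qualify; B and D are rejected
  expect_setequal(unique(got$episodes$member_id), c("A", "C", "E"))
  expect_equal(sum(got$episodes$member_id == "C"), 2)
  expect_equal(got$episodes$end_date[got$episodes$member_id == "E"], d0 + 25)
})

test_that("build_cohort equals the naive reference on random small datasets", {
  for (seed in c(21, 22, 23)) {
    syn <- generate_synthetic_claims(
      synth_config(n_members = 8, seed = seed, n_violation_members = 2,
                   p_second_episode = 0.3),
      cs)
    got <- build_cohort(syn$dataset, cs)
    want <- oracle_build_cohort(syn$dataset, cs)
    expect_equal(nrow(got$episodes), nrow(want))
    expect_equal(got$episodes$index_date, want$index_date)
    expect_equal(got$episodes$end_date, want$end_date)
    expect_equal(got$episodes$has_hospitalization, want$has_hospitalization)
  }
})

test_that("attrition log is ordered, non-increasing, and consistent", {
  syn <- generate_synthetic_claims(
    synth_config(n_members = 40, seed = 5, n_violation_members = 12), cs)
  cohort <- build_cohort(syn$dataset, cs)
  at <- cohort$attrition
  expect_equal(at$criterion[1], "candidates")
  expect_true(all(diff(at$remaining) <= 0))
  expect_equal(at$remaining[nrow(at)], nrow(cohort$episodes))
  # empty dataset -> zero everywhere
  ds0 <- fn_claims(mk_medical(), mk_pharmacy(), mk_enrollment(character()),
                   mk_members(character()))
  c0 <- build_cohort(ds0, cs)
  expect_equal(nrow(c0$episodes), 0)
  expect_true(all(c0$attrition$remaining == 0))
})

test_that("episode construction is order-independent and episodes never overlap", {
  syn <- generate_synthetic_claims(
    synth_config(n_members = 30, seed = 9, p_second_episode = 0.25), cs)
  ds <- syn$dataset
  base <- build_cohort(ds, cs)
  set.seed(1)
  shuf <- ds
  shuf$medical <- ds$medical[sample(nrow(ds$medical)), ]
  shuf$pharmacy <- ds$pharmacy[sample(nrow(ds$pharmacy)), ]
  again <- build_cohort(shuf, cs)
  expect_equal(again$episodes$index_date, base$episodes$index_date)
  expect_equal(again$episodes$end_date, base$episodes$end_date)
  # non-overlap within members
  by_m <- split(base$episodes, base$episodes$member_id)
  for (e in by_m) {
    if (nrow(e) > 1) {
      e <- e[order(e$index_date), ]
      expect_true(all(e$index_date[-1] > e$end_date[-nrow(e)]))
    }
  }
})

test_that("monotonicity: adding a pre-period fever claim only removes episodes", {
  ds <- mk_simple_dataset("A", d0, cs)
  expect_equal(nrow(build_cohort(ds, cs)$episodes), 1)
  extra <- mk_medical(list(member_id = "A", date = d0 - 90,
                           setting = "physician_office", dx = FEVER))
  ds2 <- mk_simple_dataset("A", d0, cs, extra_medical = extra)
  expect_equal(nrow(build_cohort(ds2, cs)$episodes), 0)
})
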