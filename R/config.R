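#' Pipeline configuration
#'
#' All tunable windows and rule switches for episode construction and
#' classification, in days unless noted. Defaults implement the study design:
#' a 180-day pre-episode period, a 30-day chemotherapy lookback, a 60-day
#' episode cap, a 4-day prophylaxis window after the first chemotherapy
#' administration, and a 30-day inter-episode washout.
#'
#' @param pre_episode_days Length of the pre-episode (baseline) period before
#'   the index date used for enrollment continuity, exclusions, comorbidity
#'   scoring and risk factors. Default 180.
#' @param chemo_lookback_days Length of the chemotherapy treatment period
#'   before the index date. Default 30. The window is `[index - 30, index - 1]`:
#'   chemotherapy on the index date itself does not qualify an episode (see
#'   `chemo_on_index_qualifies`).
#' @param episode_cap_days Maximum follow-up after the index date when no
#'   further chemotherapy occurs. Default 60 (episode length up to 61 days
#'   counting the index day, absent a hospitalization extension).
#' @param prophylaxis_window_days A GCSF/antimicrobial utilization on the date
#'   of, or within this many days after, the first chemotherapy administration
#'   in the treatment period counts as prophylactic. Default 4.
#' @param washout_days Minimum number of consecutive days free of
#'   neutropenia/infection/fever diagnoses required between a retained episode's
#'   end and a subsequent index date. Default 30.
#' @param chemo_on_index_qualifies If `TRUE`, a chemotherapy claim on the index
#'   date itself satisfies the chemotherapy-lookback requirement. Default
#'   `FALSE`.
#' @param subsequent_episode_rule How the clean-pre-period requirement applies
#'   to a member's episodes after the first: `"washout_gap"` (default) replaces
#'   it with the 30-day clean-gap washout rule; `"full_clean_period"` applies
#'   the full 180-day clean-period requirement verbatim (under which no member
#'   can have a second episode, since the first episode's diagnoses are in the
#'   window).
#' @param include_index_in_lookback If `TRUE`, diagnosis lookback for
#'   comorbidity scoring and risk factors includes the index date. Default
#'   `FALSE`, consistent with the clean-pre-period convention.
#' @param covid_includes_index If `TRUE` (default), the COVID-19 exclusion
#'   considers diagnoses in the pre-episode period *or on the index date*.
#' @param los_convention Inpatient length-of-stay convention: `"inclusive"`
#'   (default) counts `discharge - admission + 1` with a floor of 1 day;
#'   `"difference"` counts `discharge - admission`.
#'
#' @return A named list of class `fn_config`.
#' @export
#' @examples
#' cfg <- fn_config()
#' cfg$episode_cap_days
fn_config <- function(pre_episode_days = 180,
                      chemo_lookback_days = 30,
                      episode_cap_days = 60,
                      prophylaxis_window_days = 4,
                      washout_days = 30,
                      chemo_on_index_qualifies = FALSE,
                      subsequent_episode_rule = c("washout_gap", "full_clean_period"),
                      include_index_in_lookback = FALSE,
                      covid_includes_index = TRUE,
                      los_convention = c("inclusive", "difference")) {
  subsequent_episode_rule <- match.arg(subsequent_episode_rule)
  los_convention <- match.arg(los_convention)
  stopifnot(pre_episode_days >= 1, chemo_lookback_days >= 1,
            episode_cap_days >= 1, prophylaxis_window_days >= 0,
            washout_days >= 1)
  structure(list(
    pre_episode_days = as.integer(pre_episode_days),
    chemo_lookback_days = as.integer(chemo_lookback_days),
    episode_cap_days = as.integer(episode_cap_days),
    prophylaxis_window_days = as.integer(prophylaxis_window_days),
    washout_days = as.integer(washout_days),
    chemo_on_index_qualifies = isTRUE(chemo_on_index_qualifies),
    subsequent_episode_rule = subsequent_episode_rule,
    include_index_in_lookback = isTRUE(include_index_in_lookback),
    covid_includes_index = isTRUE(covid_includes_index),
    los_convention = los_convention
  ), class = "fn_config")
}
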