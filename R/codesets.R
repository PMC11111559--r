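REQUIRED_CODESETS <- c(
  "neutropenia_dx", "fever_dx", "bacterial_infection_dx", "fungal_infection_dx",
  "covid_dx", "excluded_heme_dx", "bmt_sct_cart_proc",
  "nccn_parenteral_antibiotic_proc", "gcsf_short", "gcsf_long",
  "antibacterial", "antifungal", "antiviral",
  "bone_met_dx", "surgery_proc", "radiation_codes",
  "liver_dysfunction_dx", "kidney_dysfunction_dx",
  "nhl_dx", "cll_dx", "other_heme_dx",
  "breast_dx", "lung_dx", "colorectal_dx", "prostate_dx", "other_solid_dx"
)

#' Load the codeset registry
#'
#' Reads a YAML (or JSON) codeset configuration into an `fn_codesets` object.
#' Every clinical rule in the pipeline consults codes only through this
#' registry, so replacing the configuration changes behaviour with no code
#' change. The package ships a placeholder default under
#' `system.file("extdata", "codesets.yaml", package = "fncohort")`.
#'
#' The configuration holds: named diagnosis/procedure codesets, the
#' chemotherapy drug dictionary, the regimen dictionary with FN-risk labels
#' (high / intermediate; unmatched drugs are low/undefined), the
#' NCCN-recommended oral antibiotic combination rules, and the comorbidity
#' condition map (condition, positive weight, codes).
#'
#' @param path Path to a YAML/JSON codeset configuration. Defaults to the
#'   shipped placeholder configuration.
#' @return An object of class `fn_codesets`: a list with elements `sets`
#'   (named list of code character vectors), `systems`, `chemo_drugs`,
#'   `regimens` (tibble), `oral_antibiotic_rules` (list of character vectors of
#'   set names), `cci` (tibble with `condition`, `weight`, `codes`), and
#'   `unknown_sets` (names present in the file but not required by any rule).
#' @export
#' @examples
#' cs <- load_codesets()
#' length(cs$sets$neutropenia_dx)
load_codesets <- function(path = default_codesets_path()) {
  if (!file.exists(path)) abort(paste0("codeset config not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$codesets)) abort("codeset config lacks a 'codesets' mapping")

  sets <- lapply(raw$codesets, function(x) {
    codes <- as.character(x$codes %||% x)
    unique(codes[nzchar(codes)])
  })
  systems <- lapply(raw$codesets, function(x) x$system %||% "unspecified")

  dup_counts <- vapply(raw$codesets, function(x) {
    codes <- as.character(x$codes %||% x)
    length(codes) - length(unique(codes))
  }, integer(1))
  if (any(dup_counts > 0)) {
    warn(paste0("deduplicated codes in codesets: ",
                paste0(names(dup_counts)[dup_counts > 0], " (",
                       dup_counts[dup_counts > 0], ")", collapse = ", ")))
  }

  missing <- setdiff(REQUIRED_CODESETS, names(sets))
  empty <- intersect(REQUIRED_CODESETS,
                     names(sets)[vapply(sets, length, integer(1)) == 0])
  if (length(missing) || length(empty)) {
    abort(paste0("required codesets absent or empty: ",
                 paste(c(missing, empty), collapse = ", ")))
  }

  chemo_drugs <- lapply(raw$chemo_drugs %||% list(), as.character)
  if (length(chemo_drugs) == 0) abort("required codesets absent or empty: chemo_drugs")

  regs <- raw$regimens %||% list()
  regimens <- tibble(
    name = vapply(regs, function(r) as.character(r$name), character(1)),
    drugs = lapply(regs, function(r) as.character(r$drugs)),
    risk = vapply(regs, function(r) as.character(r$risk), character(1)),
    requires_dx = vapply(regs, function(r) r$requires_dx %||% NA_character_, character(1)),
    min_cycles = vapply(regs, function(r) as.integer(r$min_cycles %||% NA_integer_), integer(1))
  )
  bad_risk <- setdiff(regimens$risk, c("high", "intermediate", "low_undefined"))
  if (length(bad_risk)) abort(paste0("unknown regimen risk label: ", paste(bad_risk, collapse = ", ")))
  bad_drugs <- setdiff(unlist(regimens$drugs), names(chemo_drugs))
  if (length(bad_drugs)) abort(paste0("regimen drug not in chemo_drugs: ", paste(bad_drugs, collapse = ", ")))

  rules <- lapply(raw$oral_antibiotic_rules %||% list(), as.character)
  if (length(rules) == 0) abort("required codesets absent or empty: oral_antibiotic_rules")
  bad_rule <- setdiff(unlist(rules), names(sets))
  if (length(bad_rule)) abort(paste0("oral antibiotic rule references unknown codeset: ",
                                     paste(bad_rule, collapse = ", ")))

  ccis <- raw$cci_conditions %||% list()
  if (length(ccis) == 0) abort("required codesets absent or empty: cci_conditions")
  cci <- tibble(
    condition = vapply(ccis, function(x) as.character(x$condition), character(1)),
    weight = vapply(ccis, function(x) as.numeric(x$weight), numeric(1)),
    codes = lapply(ccis, function(x) as.character(x$codes))
  )
  if (any(!is.finite(cci$weight) | cci$weight <= 0)) {
    abort("cci_conditions weights must be positive numbers")
  }

  known <- c(REQUIRED_CODESETS, unlist(rules))
  unknown_sets <- setdiff(names(sets), known)

  structure(list(
    sets = sets,
    systems = systems,
    chemo_drugs = chemo_drugs,
    regimens = regimens,
    oral_antibiotic_rules = rules,
    cci = cci,
    unknown_sets = unknown_sets,
    source = path
  ), class = "fn_codesets")
}

#' @export
print.fn_codesets <- function(x, ...) {
  cat("<fn_codesets> ", length(x$sets), " codesets, ",
      length(x$chemo_drugs), " chemo drugs, ",
      nrow(x$regimens), " regimens, ",
      nrow(x$cci), " comorbidity conditions\n", sep = "")
  invisible(x)
}

#' Path to the shipped default codeset configuration
#' @return File path of the placeholder codesets YAML.
#' @export
default_codesets_path <- function() {
  system.file("extdata", "codesets.yaml", package = "fncohort", mustWork = TRUE)
}

#' Load a medical-CPI table
#'
#' Reads a `cpi_medical:` year-to-index mapping from YAML/JSON. Used by
#' [adjust_to_2021()].
#'
#' @param path Path to the CPI config; defaults to the shipped annual
#'   medical-care CPI table (2014--2021).
#' @return Named numeric vector, names are years.
#' @export
load_cpi_table <- function(path = system.file("extdata", "cpi_medical.yaml",
                                              package = "fncohort", mustWork = TRUE)) {
  raw <- yaml::read_yaml(path)
  tab <- raw$cpi_medical %||% raw
  out <- vapply(tab, as.numeric, numeric(1))
  names(out) <- names(tab)
  if (!"2021" %in% names(out)) abort("CPI table lacks the 2021 reference year")
  out
}

# convenience unions used by several rules
cs_fn_dx <- function(cs) {
  unique(c(cs$sets$neutropenia_dx, cs$sets$fever_dx,
           cs$sets$bacterial_infection_dx, cs$sets$fungal_infection_dx))
}
cs_infection_fever_dx <- function(cs) {
  unique(c(cs$sets$fever_dx, cs$sets$bacterial_infection_dx,
           cs$sets$fungal_infection_dx))
}
cs_chemo_codes <- function(cs) unique(unlist(cs$chemo_drugs, use.names = FALSE))
cs_gcsf <- function(cs) unique(c(cs$sets$gcsf_short, cs$sets$gcsf_long))
cs_antimicrobial <- function(cs) {
  unique(c(cs$sets$antibacterial, cs$sets$antifungal, cs$sets$antiviral))
}
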