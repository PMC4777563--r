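# Fixed sector and clinical-grouping vocabularies.
#
# The sector list is exhaustive by design: attribution accounting must cover
# every dollar, so an unknown sector string in an input file is a hard error.

.SECTORS <- c(
  "inpatient_acute", "same_day_surgery", "emergency", "inpatient_mental_health",
  "inpatient_rehab", "complex_continuing_care", "long_term_care",
  "inpatient_nonacute",
  "home_care", "physician", "laboratory", "drug", "dialysis_outpatient",
  "oncology_outpatient", "assistive_device"
)

.INSTITUTIONAL <- .SECTORS[1:8]
.COMMUNITY <- .SECTORS[9:15]
.PER_DIEM <- c("long_term_care", "complex_continuing_care")
.ACUTE_START_BASE <- c("inpatient_acute", "same_day_surgery", "inpatient_mental_health")

.GROUPINGS <- c(
  "pregnancy",
  "perinatal_congenital_lbw",
  "post_admission_events",
  "trauma_injury_poisoning",
  "mental_illness_addictions",
  "acsc",
  "cancer",
  "acute_planned_surgical",
  "acute_planned_medical",
  "acute_unplanned_surgical",
  "acute_unplanned_medical",
  "other_causes"
)

.GROUPING_LABELS <- c(
  pregnancy                 = "Pregnancy",
  perinatal_congenital_lbw  = "LBW/Perinatal/Congenital",
  post_admission_events     = "Post-Admission Events",
  trauma_injury_poisoning   = "Trauma/Accidents/Injuries/Poisonings",
  mental_illness_addictions = "Mental Illness & Addictions",
  acsc                      = "Ambulatory Care Sensitive Conditions",
  cancer                    = "Cancer",
  acute_planned_surgical    = "Acute Planned Surgical",
  acute_planned_medical     = "Acute Planned Medical",
  acute_unplanned_surgical  = "Acute Unplanned Surgical",
  acute_unplanned_medical   = "Acute Unplanned Medical",
  other_causes              = "Other Causes"
)

# categories whose membership is driven by diagnosis-code prefixes
.CODE_DRIVEN <- c(
  "pregnancy", "perinatal_congenital_lbw", "trauma_injury_poisoning",
  "mental_illness_addictions", "acsc", "cancer"
)

.ADMISSION_TYPES <- c("planned", "unplanned", "not_applicable")
.SERVICE_TYPES <- c("medical", "surgical", "not_applicable")
.DX_TYPES <- c("pre_admission", "post_admission", "other")

#' Sector vocabulary
#'
#' The fixed 15-sector vocabulary used throughout the package. Institutional
#' sectors are admitted/facility-based settings whose encounters can extend a
#' person-centred episode; community sectors are point-in-time services that
#' attach to episodes by date. Per-diem sectors carry one row per stay with the
#' total stay cost and are prorated when a stay extends past an episode end.
#'
#' @param which one of `"all"`, `"institutional"`, `"community"`, `"per_diem"`.
#' @return character vector of sector names.
#' @export
#' @examples
#' pce_sectors("institutional")
pce_sectors <- function(which = c("all", "institutional", "community", "per_diem")) {
  switch(match.arg(which),
    all = .SECTORS,
    institutional = .INSTITUTIONAL,
    community = .COMMUNITY,
    per_diem = .PER_DIEM
  )
}

#' Acute-start (episode-anchoring) sectors
#'
#' Sectors whose admissions may anchor a new episode: inpatient acute care,
#' same-day surgery, designated inpatient mental health, and (configurably)
#' the emergency department.
#'
#' @param config a [study_config()] object; `config$ed_starts_episode` controls
#'   whether emergency-department visits anchor episodes (default `TRUE`).
#' @return character vector of sector names.
#' @export
acute_start_sectors <- function(config = study_config()) {
  if (isTRUE(config$ed_starts_episode)) c(.ACUTE_START_BASE, "emergency") else .ACUTE_START_BASE
}

#' Clinical grouping vocabulary
#'
#' The twelve mutually exclusive clinical groupings, in hierarchy (rank) order.
#' Rank order is the order in which classification rules are tried; the first
#' matching rule wins.
#'
#' @param labels if `TRUE`, return display labels instead of keys.
#' @return character vector of length 12, in rank order.
#' @export
#' @examples
#' pce_groupings()
#' pce_groupings(labels = TRUE)
pce_groupings <- function(labels = FALSE) {
  if (labels) unname(.GROUPING_LABELS) else .GROUPINGS
}

#' @rdname pce_groupings
#' @param key grouping key(s) to label.
#' @export
grouping_label <- function(key) {
  out <- .GROUPING_LABELS[key]
  unname(out)
}
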