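# Clinical classification of episodes.
#
# Each episode is classified once, from its anchor encounter, into one of
# twelve mutually exclusive groupings. Rules are tried in rank order and the
# first match wins:
#
#   1  Pregnancy                      MRD matches pregnancy prefixes
#   2  LBW/Perinatal/Congenital       MRD matches perinatal prefixes
#   3  Post-Admission Events          any diagnosis flagged post_admission,
#                                     irrespective of the MRD (but only after
#                                     ranks 1-2, which are identified first)
#   4  Trauma/Injuries/Poisonings     any diagnosis code (MRD or secondary,
#                                     any type) matches trauma prefixes
#   5  Mental Illness & Addictions    anchor at an inpatient mental-health
#                                     facility, or MRD matches mental prefixes
#   6  ACSC                           MRD matches ACSC prefixes
#   7  Cancer                         MRD matches cancer prefixes
#   8-11 Acute Planned/Unplanned x    admission_type x service_type
#        Surgical/Medical
#   12 Other Causes                   everything else
#
# The function is total: a missing MRD with no triggering flags falls through
# to the admission/service-type rules, then to Other Causes.

#' Prefix-match a diagnosis code
#'
#' @param code a single diagnosis code (or `NA`).
#' @param prefixes character vector of code prefixes.
#' @return `TRUE` iff `code` starts with any prefix, case-insensitively.
#'   `NA`/empty codes never match.
#' @export
#' @examples
#' match_code("TRM101", c("TRM"))  # TRUE
#' match_code("CAN5", c("CANX"))   # FALSE
match_code <- function(code, prefixes) {
  if (length(code) == 0 || is.na(code) || !nzchar(code) || length(prefixes) == 0) return(FALSE)
  any(startsWith(toupper(code), toupper(prefixes)))
}

.cm_prefixes <- function(codemap, category) codemap$categories[[category]] %||% character(0)

#' Classify one episode from its anchor encounter
#'
#' @param anchor a single-row data.frame (or list) with the anchor encounter's
#'   `sector`, `mrd_code`, `dx_codes`, `admission_type`, `service_type`.
#' @param codemap a [read_code_map()] object.
#' @return a grouping key (see [pce_groupings()]).
#' @export
#' @examples
#' cm <- read_code_map()
#' anchor <- list(sector = "inpatient_acute", mrd_code = "PRG010",
#'                dx_codes = "TRM200:other", admission_type = "unplanned",
#'                service_type = "medical")
#' classify_episode(anchor, cm) # pregnancy outranks trauma
classify_episode <- function(anchor, codemap) {
  .assert(inherits(codemap, "pce_codemap"), "codemap must come from read_code_map()/as_code_map()")
  mrd <- anchor$mrd_code
  if (is.null(mrd)) mrd <- NA_character_
  dx <- parse_dx(if (is.null(anchor$dx_codes)) NA_character_ else anchor$dx_codes)
  all_codes <- c(if (!is.na(mrd) && nzchar(mrd)) mrd, dx[, "code"])

  if (match_code(mrd, .cm_prefixes(codemap, "pregnancy"))) return("pregnancy")
  if (match_code(mrd, .cm_prefixes(codemap, "perinatal_congenital_lbw"))) return("perinatal_congenital_lbw")
  if (any(dx[, "type"] == "post_admission")) return("post_admission_events")
  trauma <- .cm_prefixes(codemap, "trauma_injury_poisoning")
  if (any(vapply(all_codes, match_code, logical(1), prefixes = trauma))) {
    return("trauma_injury_poisoning")
  }
  if (identical(anchor$sector, "inpatient_mental_health") ||
      match_code(mrd, .cm_prefixes(codemap, "mental_illness_addictions"))) {
    return("mental_illness_addictions")
  }
  if (match_code(mrd, .cm_prefixes(codemap, "acsc"))) return("acsc")
  if (match_code(mrd, .cm_prefixes(codemap, "cancer"))) return("cancer")

  adm <- anchor$admission_type
  srv <- anchor$service_type
  adm_ok <- !is.null(adm) && !is.na(adm) && adm %in% c("planned", "unplanned")
  srv_ok <- !is.null(srv) && !is.na(srv) && srv %in% c("medical", "surgical")
  if (adm_ok && srv_ok) {
    return(switch(paste(adm, srv, sep = "_"),
      planned_surgical = "acute_planned_surgical",
      planned_medical = "acute_planned_medical",
      unplanned_surgical = "acute_unplanned_surgical",
      unplanned_medical = "acute_unplanned_medical"
    ))
  }
  "other_causes"
}

#' Classify all episodes
#'
#' Adds a `grouping` column to `built$episodes` by applying
#' [classify_episode()] to each episode's anchor encounter. Episodes whose
#' anchor has a missing MRD are counted and reported via a message (they fall
#' through to the admission/service-type rules).
#'
#' @param built a `pce_built` object.
#' @param encounters the full encounter table (for anchor attributes).
#' @param codemap a [read_code_map()] object.
#' @return `built` with `episodes$grouping` set.
#' @export
classify_episodes <- function(built, encounters, codemap = read_code_map()) {
  .assert(inherits(built, "pce_built"), "built must come from build_episodes()")
  enc <- data.table::as.data.table(encounters)
  if (nrow(built$episodes) == 0) {
    built$episodes[, grouping := character(0)]
    return(built)
  }
  anchors <- merge(built$episodes[, .(episode_key, anchor_encounter_id)],
                   enc[, .(encounter_id, sector, mrd_code, dx_codes, admission_type, service_type)],
                   by.x = "anchor_encounter_id", by.y = "encounter_id", all.x = TRUE, sort = FALSE)
  .assert(!anyNA(anchors$sector), "anchor encounter(s) missing from the encounter table")
  n_missing_mrd <- sum(is.na(anchors$mrd_code) | anchors$mrd_code == "")
  if (n_missing_mrd > 0) {
    message(sprintf("%d episode anchor(s) have a missing MRD; classified by admission/service type",
                    n_missing_mrd))
  }
  groupings <- vapply(seq_len(nrow(anchors)), function(i) {
    classify_episode(as.list(anchors[i]), codemap)
  }, character(1))
  built$episodes[match(anchors$episode_key, episode_key), grouping := groupings]
  built
}

#' Grouping census
#'
#' Counts episodes per clinical grouping, with percentages of all episodes
#' (half-up, one decimal). All twelve groupings appear, in rank order, with
#' zero rows where empty.
#'
#' @param episodes a classified episode table (needs a `grouping` column).
#' @return a `data.table` with `grouping, label, n, percent`.
#' @export
grouping_census <- function(episodes) {
  eps <- data.table::as.data.table(episodes)
  .assert("grouping" %in% names(eps), "episodes must be classified first (missing grouping column)")
  counts <- eps[, .N, by = grouping]
  out <- data.table::data.table(grouping = .GROUPINGS)
  out[, label := grouping_label(grouping)]
  out[, n := 0L]
  out[counts, n := i.N, on = "grouping"]
  total <- sum(out$n)
  out[, percent := if (total > 0) share_percent(n, total) else NA_real_]
  out[]
}

#' Episode costs by grouping and sector
#'
#' Cross-tabulates attributed episode costs by clinical grouping and sector.
#' By convention, outpatient-oncology costs attached to any episode are tallied
#' under the Cancer grouping's breakdown (oncology treatment visits belong to
#' the cancer category of spending) without changing any episode's grouping.
#'
#' @param built a costed, classified `pce_built` object.
#' @param oncology_to_cancer relabel in-episode `oncology_outpatient` costs to
#'   the Cancer grouping row (default `TRUE`).
#' @return a `data.table` with `grouping, sector, cost` (dollars).
#' @export
grouping_sector_costs <- function(built, oncology_to_cancer = TRUE) {
  .assert(inherits(built, "pce_built"), "built must come from build_episodes()")
  .assert("allocated_cents" %in% names(built$membership), "run episode_costs() first")
  .assert("grouping" %in% names(built$episodes), "run classify_episodes() first")
  mem <- built$membership[!is.na(episode_key) & allocated_cents > 0]
  mem <- merge(mem, built$episodes[, .(episode_key, grouping)], by = "episode_key", sort = FALSE)
  if (oncology_to_cancer) {
    mem[sector == "oncology_outpatient", grouping := "cancer"]
  }
  out <- mem[, .(cost = cents_to_dollars(sum(allocated_cents))), by = .(grouping, sector)]
  data.table::setorder(out, grouping, sector)
  out[]
}
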