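# High-cost cohort selection and person-level characteristics.
#
# Annual person-level costs are summed across all sectors; the cohort is the
# set of persons strictly above the chosen expenditure percentile who were
# community-dwelling (not long-term-care residents) and alive at the index
# date. Characteristics reproduce the standard descriptive bins, including the
# usual-provider-of-care (UPC) continuity index over ambulatory visits.

#' Person-level annual costs
#'
#' Sums encounter costs per person, overall and by sector. Stays spanning the
#' study end contribute their full recorded cost (input rows already represent
#' within-year cost).
#'
#' @param encounters validated encounter table.
#' @param config a [study_config()].
#' @return a `data.table` with `person_id`, `total_cost`, and one
#'   `cost_<sector>` column per sector (dollars; zero where unused). Persons
#'   with no encounters do not appear.
#' @export
person_annual_costs <- function(encounters, config = study_config()) {
  enc <- data.table::as.data.table(encounters)
  if (nrow(enc) == 0) {
    return(data.table::data.table(person_id = character(), total_cost = numeric()))
  }
  cents <- enc[, .(cents = sum(as_cents(cost))), by = .(person_id, sector)]
  wide <- data.table::dcast(cents, person_id ~ sector, value.var = "cents", fill = 0)
  sec_cols <- setdiff(names(wide), "person_id")
  wide[, total_cost := cents_to_dollars(rowSums(.SD)), .SDcols = sec_cols]
  for (col in sec_cols) data.table::set(wide, j = col, value = cents_to_dollars(wide[[col]]))
  data.table::setnames(wide, sec_cols, paste0("cost_", sec_cols))
  data.table::setcolorder(wide, c("person_id", "total_cost"))
  wide[]
}

#' High-cost expenditure threshold
#'
#' The `percentile`-th quantile of person-level total annual costs, under the
#' configured quantile convention. Cohort selection downstream is strictly
#' greater-than this value.
#'
#' @param costs output of [person_annual_costs()].
#' @param percentile percentile in (0, 100); default from `config`.
#' @param config a [study_config()] (supplies `quantile_method`).
#' @return the threshold in dollars.
#' @export
#' @examples
#' costs <- data.frame(person_id = as.character(1:100), total_cost = 1:100)
#' high_cost_threshold(costs, 95, study_config(quantile_method = "lower_value"))
high_cost_threshold <- function(costs, percentile = config$percentile,
                                config = study_config()) {
  costs <- data.table::as.data.table(costs)
  .assert(nrow(costs) > 0, "cannot compute a threshold from an empty cost table")
  .assert(percentile > 0 && percentile < 100, "percentile must lie strictly between 0 and 100")
  quantile_value(costs$total_cost, percentile / 100, config$quantile_method)
}

#' Select the high-cost community-dwelling cohort
#'
#' Persons with total annual cost strictly above the threshold, not resident in
#' long-term care at the index date, and alive at the index date (no death
#' before `study_start`).
#'
#' @param persons validated person table.
#' @param costs output of [person_annual_costs()].
#' @param threshold dollar threshold from [high_cost_threshold()].
#' @param config a [study_config()].
#' @return character vector of selected `person_id`s.
#' @export
select_cohort <- function(persons, costs, threshold, config = study_config()) {
  per <- data.table::as.data.table(persons)
  costs <- data.table::as.data.table(costs)
  above <- costs[total_cost > threshold, person_id]
  eligible <- per[person_id %in% above &
                    !ltc_resident_at_index &
                    (is.na(death_date) | death_date >= config$study_start),
                  person_id]
  eligible
}

#' Usual-provider-of-care (UPC) index for one person
#'
#' The share of a person's ambulatory visits made to their most-visited
#' provider. Defined only for persons with at least three ambulatory visits;
#' a share of 0.75 or more denotes high continuity. Visits without a provider
#' id are excluded from numerator and denominator (a message reports how
#' many).
#'
#' @param providers character vector of provider ids, one element per
#'   ambulatory visit (the UPC look-back is whatever period the visits cover).
#' @return a list with `value` (in `[0, 1]`, or `NA` if undefined), `n_visits`,
#'   and `category`: one of `"no_contact"` (0 visits), `"insufficient"`
#'   (1-2 visits), `"low"` (`< 0.75`) or `"high"` (`>= 0.75`).
#' @export
#' @examples
#' upc_index(c("A", "A", "A", "B"))$value # 0.75, high continuity
#' upc_index(c("A", "A"))$category        # "insufficient"
upc_index <- function(providers) {
  n_na <- sum(is.na(providers) | providers == "")
  if (n_na > 0) {
    message(sprintf("excluding %d ambulatory visit(s) without a provider id from the UPC index", n_na))
    providers <- providers[!(is.na(providers) | providers == "")]
  }
  n <- length(providers)
  if (n == 0) return(list(value = NA_real_, n_visits = 0L, category = "no_contact"))
  if (n < 3) return(list(value = NA_real_, n_visits = n, category = "insufficient"))
  share <- max(table(providers)) / n
  list(value = share, n_visits = n,
       category = if (share >= 0.75) "high" else "low")
}

#' UPC index for every person in an encounter table
#'
#' Ambulatory visits are encounters with `ambulatory_flag == TRUE`. Persons in
#' `person_ids` with no ambulatory visit get category `"no_contact"`.
#'
#' @param encounters encounter table covering the UPC look-back period.
#' @param person_ids persons to evaluate (default: everyone in `encounters`).
#' @return a `data.table` with `person_id, upc_value, n_visits, upc_category`.
#' @export
upc_table <- function(encounters, person_ids = NULL) {
  enc <- data.table::as.data.table(encounters)
  amb <- enc[ambulatory_flag == TRUE & !is.na(provider_id) & provider_id != ""]
  n_dropped <- enc[ambulatory_flag == TRUE, .N] - nrow(amb)
  if (n_dropped > 0) {
    message(sprintf("excluding %d ambulatory visit(s) without a provider id from the UPC index", n_dropped))
  }
  if (is.null(person_ids)) person_ids <- unique(enc$person_id)
  per_person <- amb[, {
    n <- .N
    share <- max(table(provider_id)) / n
    .(upc_value = if (n >= 3) share else NA_real_, n_visits = n)
  }, by = person_id]
  out <- data.table::data.table(person_id = person_ids)
  out <- merge(out, per_person, by = "person_id", all.x = TRUE)
  out[is.na(n_visits), n_visits := 0L]
  out[, upc_category := data.table::fcase(
    n_visits == 0L, "no_contact",
    n_visits < 3L, "insufficient",
    upc_value >= 0.75, "high",
    default = "low"
  )]
  out[]
}

.bin_age <- function(age) {
  cut(age, breaks = c(-Inf, 17, 44, 64, 84, Inf),
      labels = c("0-17", "18-44", "45-64", "65-84", "85+"))
}

.bin_drugs <- function(n) {
  cut(n, breaks = c(-Inf, 0, 5, 9, 19, Inf),
      labels = c("0", "1-5", "6-9", "10-19", "20+"))
}

#' Cohort characteristics table
#'
#' Descriptive bins for a selected cohort: age group, sex, rurality
#' (rural = rurality score `>= 40`), primary-care model, UPC continuity
#' category, morbidity burden (ADG count), drug-therapy counts among
#' drug-benefit-eligible persons, palliative care, and death during the study
#' year. Counts within one characteristic sum to the cohort size (drug bins
#' sum to the number of eligible persons, their display denominator).
#'
#' For display, persons with 1-2 ambulatory visits (UPC undefined) are merged
#' into the low-continuity bin; both raw counts are retained in the
#' `upc_detail` attribute.
#'
#' @param persons validated person table (cohort members).
#' @param upc a [upc_table()] for the same persons.
#' @return a `data.table` with `characteristic, category, n, percent`
#'   (percent half-up to one decimal).
#' @export
characterize_cohort <- function(persons, upc) {
  per <- data.table::as.data.table(persons)
  upc <- data.table::as.data.table(upc)
  n_cohort <- nrow(per)
  .assert(n_cohort > 0, "cohort is empty")
  per <- merge(per, upc[, .(person_id, upc_category)], by = "person_id", all.x = TRUE)
  per[is.na(upc_category), upc_category := "no_contact"]

  pct <- function(n, denom = n_cohort) share_percent(n, denom)
  row_block <- function(characteristic, values, levels, denom = n_cohort) {
    counts <- table(factor(values, levels = levels))
    data.table::data.table(characteristic = characteristic,
                           category = names(counts),
                           n = as.integer(counts),
                           percent = pct(as.integer(counts), denom))
  }

  blocks <- list(
    row_block("age_group", as.character(.bin_age(per$age_at_index)),
              c("0-17", "18-44", "45-64", "65-84", "85+")),
    row_block("sex", per$sex, c("female", "male")),
    row_block("rurality",
              data.table::fcase(is.na(per$rurality_score), "missing",
                                per$rurality_score >= 40, "rural",
                                default = "urban"),
              c("urban", "rural", "missing")),
    row_block("primary_care_model", per$primary_care_model, .PRIMARY_CARE_MODELS),
    row_block("upc",
              data.table::fcase(per$upc_category == "no_contact", "no_contact",
                                per$upc_category == "high", "high",
                                default = "low"), # insufficient merged into low
              c("no_contact", "low", "high")),
    row_block("morbidity",
              data.table::fcase(is.na(per$morbidity_adg_count), "no_contact",
                                per$morbidity_adg_count == 0, "0_adgs",
                                per$morbidity_adg_count <= 7, "1-7_adgs",
                                default = "8plus_adgs"),
              c("no_contact", "0_adgs", "1-7_adgs", "8plus_adgs")),
    row_block("drug_benefit", data.table::fifelse(per$drug_benefit_eligible, "eligible", "not_eligible"),
              c("not_eligible", "eligible"))
  )
  eligible <- per[drug_benefit_eligible == TRUE]
  if (nrow(eligible) > 0) {
    blocks <- c(blocks, list(
      row_block("drug_count_eligible", as.character(.bin_drugs(eligible$prior_year_drug_count)),
                c("0", "1-5", "6-9", "10-19", "20+"), denom = nrow(eligible))
    ))
  }
  blocks <- c(blocks, list(
    row_block("palliative", data.table::fifelse(per$palliative_flag, "yes", "no"), c("yes", "no")),
    row_block("died", data.table::fifelse(!is.na(per$death_date), "yes", "no"), c("yes", "no"))
  ))
  out <- data.table::rbindlist(blocks)
  detail <- per[, .N, by = upc_category]
  data.table::setattr(out, "upc_detail", detail)
  out[]
}
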