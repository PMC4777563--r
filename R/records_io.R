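# Encounter / person / code-map input contracts.
#
# Encounters arrive as one row per health-system contact with a precomputed
# within-year cost (resource-intensity costing happens upstream and is out of
# scope here). Validation is total: every row is either accepted or produces a
# diagnostic naming the offending id; nothing is silently dropped.

.ENCOUNTER_COLS <- c(
  "encounter_id", "person_id", "sector", "admit_date", "discharge_date",
  "cost", "mrd_code", "dx_codes", "admission_type", "service_type",
  "provider_id", "ambulatory_flag"
)

.PERSON_COLS <- c(
  "person_id", "age_at_index", "sex", "rurality_score", "primary_care_model",
  "drug_benefit_eligible", "death_date", "ltc_resident_at_index",
  "palliative_flag", "morbidity_adg_count", "prior_year_drug_count"
)

.PRIMARY_CARE_MODELS <- c("family_health_team", "fee_for_service", "capitation", "other")

#' Read and validate an encounter file
#'
#' Reads a CSV with columns exactly
#' `encounter_id, person_id, sector, admit_date, discharge_date, cost,
#' mrd_code, dx_codes, admission_type, service_type, provider_id,
#' ambulatory_flag`. Dates are ISO-8601; `dx_codes` is a semicolon-joined list
#' of `code:dxtype` pairs; an empty `discharge_date` denotes a stay still open
#' at study end.
#'
#' @param path path to the CSV file.
#' @param config a [study_config()].
#' @return a `data.table` of validated encounters (dates parsed, one row per
#'   contact).
#' @export
read_encounters <- function(path, config = study_config()) {
  .assert(file.exists(path), sprintf("encounter file not found: %s", path))
  dt <- data.table::fread(path, colClasses = "character", na.strings = c("", "NA"))
  missing_cols <- setdiff(.ENCOUNTER_COLS, names(dt))
  if (length(missing_cols)) {
    stop(sprintf("encounter file is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dt <- dt[, .ENCOUNTER_COLS, with = FALSE]
  if (nrow(dt) == 0) {
    warning("encounter file contains a header but no rows", call. = FALSE)
  }
  dt[, admit_date := .as_date(admit_date, "admit_date")]
  dt[, discharge_date := .as_date(discharge_date, "discharge_date")]
  dt[, cost := as.numeric(cost)]
  dt[, ambulatory_flag := as.logical(ambulatory_flag)]
  validate_encounters(dt, config)
}

#' Validate an in-memory encounter table
#'
#' Applies the full encounter contract: known sectors, non-negative costs,
#' `admit <= discharge`, point-in-time community services, unique ids, and
#' well-formed `dx_codes` strings. Errors name the offending `encounter_id`s.
#'
#' @param dt a data.frame/data.table with the encounter columns.
#' @param config a [study_config()].
#' @return the validated `data.table` (invisibly the same object, keyed use is
#'   left to callers).
#' @export
validate_encounters <- function(dt, config = study_config()) {
  dt <- data.table::as.data.table(dt)
  missing_cols <- setdiff(.ENCOUNTER_COLS, names(dt))
  .assert(length(missing_cols) == 0,
          sprintf("encounter table is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (!inherits(dt$admit_date, "Date")) dt[, admit_date := .as_date(admit_date, "admit_date")]
  if (!inherits(dt$discharge_date, "Date")) dt[, discharge_date := .as_date(discharge_date, "discharge_date")]

  .name_rows <- function(ids) paste(head(ids, 10), collapse = ", ")

  dup <- dt$encounter_id[duplicated(dt$encounter_id)]
  .assert(length(dup) == 0, sprintf("duplicate encounter_id(s): %s", .name_rows(unique(dup))))
  .assert(!anyNA(dt$encounter_id) && !anyNA(dt$person_id), "encounter_id/person_id must not be missing")

  bad_sector <- unique(dt$sector[!dt$sector %in% .SECTORS])
  .assert(length(bad_sector) == 0,
          sprintf("unknown sector(s): %s (valid: %s)", .name_rows(bad_sector),
                  paste(.SECTORS, collapse = ", ")))

  .assert(!anyNA(dt$admit_date), sprintf(
    "missing admit_date for encounter(s): %s", .name_rows(dt$encounter_id[is.na(dt$admit_date)])))

  bad_order <- dt[!is.na(discharge_date) & discharge_date < admit_date, encounter_id]
  .assert(length(bad_order) == 0,
          sprintf("discharge_date before admit_date for encounter(s): %s", .name_rows(bad_order)))

  bad_cost <- dt[is.na(cost) | cost < 0, encounter_id]
  .assert(length(bad_cost) == 0,
          sprintf("missing or negative cost for encounter(s): %s", .name_rows(bad_cost)))

  # community services are point-in-time: a single service date
  comm <- dt[sector %in% .COMMUNITY]
  bad_pt <- comm[is.na(discharge_date) | discharge_date != admit_date, encounter_id]
  .assert(length(bad_pt) == 0,
          sprintf("community-sector encounters must have admit_date == discharge_date: %s",
                  .name_rows(bad_pt)))

  bad_adm <- dt[!is.na(admission_type) & !admission_type %in% .ADMISSION_TYPES, encounter_id]
  .assert(length(bad_adm) == 0, sprintf("invalid admission_type for: %s", .name_rows(bad_adm)))
  bad_srv <- dt[!is.na(service_type) & !service_type %in% .SERVICE_TYPES, encounter_id]
  .assert(length(bad_srv) == 0, sprintf("invalid service_type for: %s", .name_rows(bad_srv)))

  # dx_codes syntax: "CODE:dxtype;CODE:dxtype"
  has_dx <- !is.na(dt$dx_codes) & dt$dx_codes != ""
  if (any(has_dx)) {
    ok <- vapply(dt$dx_codes[has_dx], function(s) {
      pairs <- strsplit(s, ";", fixed = TRUE)[[1]]
      all(grepl(":", pairs, fixed = TRUE)) &&
        all(sub("^.*:", "", pairs) %in% .DX_TYPES)
    }, logical(1))
    .assert(all(ok), sprintf("malformed dx_codes for encounter(s): %s",
                             .name_rows(dt$encounter_id[has_dx][!ok])))
  }
  dt[]
}

#' Read and validate a person file
#'
#' @param path path to the persons CSV (columns: `person_id, age_at_index, sex,
#'   rurality_score, primary_care_model, drug_benefit_eligible, death_date,
#'   ltc_resident_at_index, palliative_flag, morbidity_adg_count,
#'   prior_year_drug_count`).
#' @param config a [study_config()]; used to check `death_date >= study_start`.
#' @return a `data.table` of validated persons.
#' @export
read_persons <- function(path, config = study_config()) {
  .assert(file.exists(path), sprintf("person file not found: %s", path))
  dt <- data.table::fread(path, colClasses = "character", na.strings = c("", "NA"))
  missing_cols <- setdiff(.PERSON_COLS, names(dt))
  if (length(missing_cols)) {
    stop(sprintf("person file is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dt <- dt[, .PERSON_COLS, with = FALSE]
  dt[, death_date := .as_date(death_date, "death_date")]
  for (col in c("age_at_index", "rurality_score")) {
    data.table::set(dt, j = col, value = as.numeric(dt[[col]]))
  }
  for (col in c("morbidity_adg_count", "prior_year_drug_count")) {
    data.table::set(dt, j = col, value = as.integer(dt[[col]]))
  }
  validate_persons(dt, config)
}

#' @rdname read_persons
#' @param dt an in-memory person table.
#' @export
validate_persons <- function(dt, config = study_config()) {
  dt <- data.table::as.data.table(dt)
  missing_cols <- setdiff(.PERSON_COLS, names(dt))
  .assert(length(missing_cols) == 0,
          sprintf("person table is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (!inherits(dt$death_date, "Date")) dt[, death_date := .as_date(death_date, "death_date")]
  dup <- unique(dt$person_id[duplicated(dt$person_id)])
  .assert(length(dup) == 0, sprintf("duplicate person_id(s): %s", paste(head(dup, 10), collapse = ", ")))
  .assert(all(dt$age_at_index >= 0, na.rm = TRUE), "age_at_index must be >= 0")
  bad_sex <- unique(dt$sex[!is.na(dt$sex) & !dt$sex %in% c("female", "male")])
  .assert(length(bad_sex) == 0, sprintf("invalid sex value(s): %s", paste(bad_sex, collapse = ", ")))
  bad_pc <- unique(dt$primary_care_model[!is.na(dt$primary_care_model) &
                                           !dt$primary_care_model %in% .PRIMARY_CARE_MODELS])
  .assert(length(bad_pc) == 0, sprintf("invalid primary_care_model value(s): %s", paste(bad_pc, collapse = ", ")))
  early <- dt[!is.na(death_date) & death_date < config$study_start, person_id]
  .assert(length(early) == 0,
          sprintf("death_date before study_start for person(s): %s", paste(head(early, 10), collapse = ", ")))
  for (col in c("drug_benefit_eligible", "ltc_resident_at_index", "palliative_flag")) {
    data.table::set(dt, j = col, value = as.logical(dt[[col]]))
  }
  dt[]
}

#' Read a diagnosis code map
#'
#' A code map assigns diagnosis-code *prefixes* to the code-driven clinical
#' categories (`pregnancy`, `perinatal_congenital_lbw`, `trauma_injury_poisoning`,
#' `mental_illness_addictions`, `acsc`, `cancer`). Matching is by
#' case-insensitive prefix, and a code may appear under several categories —
#' the classification hierarchy resolves the overlap. The remaining categories
#' are flag-driven (post-admission diagnosis type, mental-health facility,
#' admission/service type) and take no prefixes.
#'
#' The bundled default map uses synthetic three-letter prefixes (`PRG`, `TRM`,
#' `CAN`, ...) rather than any jurisdiction's real ICD lists; it is intended
#' for synthetic data and as a template for a real deployment map.
#'
#' @param path path to a JSON or YAML file keyed by category name, or `NULL`
#'   (default) for the bundled toy map.
#' @return an object of class `pce_codemap`: a named list of character prefix
#'   vectors.
#' @export
#' @examples
#' cm <- read_code_map()
#' cm$categories$cancer
read_code_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "toy_codemap.json", package = "pcekit", mustWork = TRUE)
  }
  .assert(file.exists(path), sprintf("code map file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  as_code_map(raw)
}

#' @rdname read_code_map
#' @param x a named list of category -> character vector of prefixes.
#' @export
as_code_map <- function(x) {
  .assert(is.list(x) && !is.null(names(x)), "code map must be a named list of prefix vectors")
  unknown <- setdiff(names(x), .GROUPINGS)
  .assert(length(unknown) == 0,
          sprintf("unknown code-map category name(s): %s\nvalid names: %s",
                  paste(unknown, collapse = ", "), paste(.GROUPINGS, collapse = ", ")))
  cats <- lapply(x, function(p) {
    p <- as.character(unlist(p))
    .assert(all(nzchar(p)), "code-map prefixes must be non-empty strings")
    toupper(p)
  })
  # keep hierarchy (rank) order regardless of file order
  cats <- cats[intersect(.GROUPINGS, names(cats))]
  structure(list(categories = cats), class = "pce_codemap")
}

#' @export
print.pce_codemap <- function(x, ...) {
  cat("<pce_codemap>\n")
  for (nm in names(x$categories)) {
    cat(sprintf("  %-26s %s\n", nm, paste(x$categories[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Write a report table
#'
#' Writes any of the package's report tables as a plain CSV with a fixed column
#' order and `\n` line endings; output is byte-stable for identical input.
#' Dates are serialized ISO-8601.
#'
#' @param table a data.frame/data.table report.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_table <- function(table, path) {
  dt <- data.table::as.data.table(table)
  for (col in names(dt)) {
    if (inherits(dt[[col]], "Date")) data.table::set(dt, j = col, value = format(dt[[col]], "%Y-%m-%d"))
  }
  data.table::fwrite(dt, path, eol = "\n", na = "")
  invisible(path)
}

#' @rdname write_report_table
#' @export
read_report_table <- function(path) {
  data.table::fread(path, na.strings = "")
}

# split a serialized dx_codes string into a two-column matrix (code, type)
parse_dx <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("code", "type"))))
  }
  pairs <- strsplit(s, ";", fixed = TRUE)[[1]]
  code <- sub(":[^:]*$", "", pairs)
  type <- sub("^.*:", "", pairs)
  cbind(code = code, type = type)
}

# serialize (code, type) vectors back to the CSV form
serialize_dx <- function(codes, types) {
  if (length(codes) == 0) return("")
  paste(paste(codes, types, sep = ":"), collapse = ";")
}
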