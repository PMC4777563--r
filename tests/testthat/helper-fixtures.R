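# in-code fixtures: encounter/person row constructors with sensible defaults

d <- function(x) as.Date(x)

mk_enc <- function(encounter_id, person_id = "P1", sector = "inpatient_acute",
                   admit = "2010-05-01", discharge = admit, cost = 100,
                   mrd = "ZZZ000", dx = "", admission_type = "unplanned",
                   service_type = "medical", provider = NA_character_,
                   ambulatory = FALSE) {
  data.frame(
    encounter_id = encounter_id, person_id = person_id, sector = sector,
    admit_date = d(admit),
    discharge_date = if (is.na(discharge[1])) as.Date(NA) else d(discharge),
    cost = cost, mrd_code = mrd, dx_codes = dx,
    admission_type = admission_type, service_type = service_type,
    provider_id = provider, ambulatory_flag = ambulatory,
    stringsAsFactors = FALSE
  )
}

mk_encs <- function(...) do.call(rbind, list(...))

mk_person <- function(person_id = "P1", age = 70, sex = "female",
                      rurality = 10, model = "fee_for_service",
                      drug_eligible = TRUE, death = NA, ltc_at_index = FALSE,
                      palliative = FALSE, adg = 5, drugs = 3) {
  data.frame(
    person_id = person_id, age_at_index = age, sex = sex,
    rurality_score = rurality, primary_care_model = model,
    drug_benefit_eligible = drug_eligible,
    death_date = if (is.na(death[1])) as.Date(NA) else d(death),
    ltc_resident_at_index = ltc_at_index, palliative_flag = palliative,
    morbidity_adg_count = adg, prior_year_drug_count = drugs,
    stringsAsFactors = FALSE
  )
}

mk_persons <- function(...) do.call(rbind, list(...))

test_config <- function(...) study_config(...)

toy_map <- function() read_code_map()

# run the full build -> attach -> cost chain on in-memory tables
full_build <- function(enc, per, config = test_config(), codemap = toy_map()) {
  built <- build_episodes(enc, per, config)
  built <- attach_community_care(built, enc, config)
  built <- episode_costs(built, enc, config)
  classify_episodes(built, enc, codemap)
}

# compare a builder membership against planted ground truth as partitions
# (keys canonicalized to the lexicographically first encounter id per class);
# returns the number of institutional encounters assigned differently
recovery_mismatches <- function(built, ground_truth) {
  mem <- merge(as.data.frame(built$membership), as.data.frame(ground_truth),
               by = "encounter_id")
  canon <- function(keys, ids) {
    lab <- ifelse(is.na(keys) | keys == "unallocated", "unallocated", keys)
    firsts <- tapply(ids, lab, min)
    out <- unname(firsts[lab])
    out[lab == "unallocated"] <- "unallocated"
    out
  }
  builder <- canon(mem$episode_key, mem$encounter_id)
  planted <- canon(mem$planted_episode_key, mem$encounter_id)
  sum(builder != planted)
}
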