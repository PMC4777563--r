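test_that("a lone acute stay opens a 30-day episode window", {
  cfg <- test_config()
  enc <- mk_enc("E1", admit = "2010-05-01", discharge = "2010-05-06")
  built <- build_episodes(enc, mk_person(), cfg)
  expect_equal(nrow(built$episodes), 1L)
  ep <- built$episodes
  expect_equal(ep$start_date, d("2010-05-01"))
  expect_equal(ep$final_discharge_date, d("2010-05-06"))
  expect_equal(ep$end_date, d("2010-06-05")) # discharge + 30 days
  expect_equal(built$membership$episode_key, ep$episode_key)
})

test_that("a 30-day gap chains and a 31-day gap splits", {
  cfg <- test_config()
  base <- mk_enc("A1", admit = "2010-05-01", discharge = "2010-05-05")
  rehab30 <- mk_enc("R1", sector = "inpatient_rehab", admit = "2010-06-04",
                    discharge = "2010-06-20") # gap exactly 30
  rehab31 <- mk_enc("R2", sector = "inpatient_rehab", admit = "2010-06-05",
                    discharge = "2010-06-20") # gap 31
  chained <- build_episodes(mk_encs(base, rehab30), mk_person(), cfg)
  expect_equal(nrow(chained$episodes), 1L)
  expect_equal(chained$episodes$n_institutional, 2L)
  expect_equal(chained$episodes$final_discharge_date, d("2010-06-20"))

  split <- build_episodes(mk_encs(base, rehab31), mk_person(), cfg)
  expect_equal(nrow(split$episodes), 1L)
  expect_equal(split$episodes$n_institutional, 1L)
  expect_equal(split$episodes$end_date, d("2010-06-04")) # May 5 + 30
  # rehab alone cannot anchor: unallocated
  expect_true(is.na(split$membership[split$membership$encounter_id == "R2", ]$episode_key))
})

test_that("institutional care with no acute anchor stays unallocated", {
  cfg <- test_config()
  enc <- mk_encs(
    mk_enc("L1", sector = "long_term_care", admit = "2010-05-01", discharge = "2010-08-01",
           cost = 30000),
    mk_enc("N1", sector = "inpatient_nonacute", admit = "2010-09-20", discharge = "2010-09-25")
  )
  built <- build_episodes(enc, mk_person(), cfg)
  expect_equal(nrow(built$episodes), 0L)
  expect_true(all(is.na(built$membership$episode_key)))
})

test_that("inpatient_nonacute neither extends nor joins an open episode", {
  cfg <- test_config()
  enc <- mk_encs(
    mk_enc("A1", admit = "2010-05-01", discharge = "2010-05-05"),
    mk_enc("N1", sector = "inpatient_nonacute", admit = "2010-05-10", discharge = "2010-07-01"),
    # within 30 days of A1's discharge, so still a member despite N1
    mk_enc("R1", sector = "inpatient_rehab", admit = "2010-06-01", discharge = "2010-06-10")
  )
  built <- build_episodes(enc, mk_person(), cfg)
  expect_equal(nrow(built$episodes), 1L)
  mem <- built$membership
  expect_true(is.na(mem$episode_key[mem$encounter_id == "N1"]))
  expect_false(is.na(mem$episode_key[mem$encounter_id == "R1"]))
})

test_that("same-day transfers and overlapping stays chain with the max-window rule", {
  cfg <- test_config()
  enc <- mk_encs(
    mk_enc("A1", admit = "2010-05-01", discharge = "2010-05-10"),
    mk_enc("T1", sector = "complex_continuing_care", admit = "2010-05-10",
           discharge = "2010-05-20"), # same-day transfer
    # overlapping stay admitted before T1's discharge, discharged later
    mk_enc("O1", sector = "inpatient_rehab", admit = "2010-05-15", discharge = "2010-07-01"),
    # chains only because O1 extended the window beyond T1's discharge + 30
    mk_enc("A2", admit = "2010-07-20", discharge = "2010-07-22")
  )
  built <- build_episodes(enc, mk_person(), cfg)
  expect_equal(nrow(built$episodes), 1L)
  expect_equal(built$episodes$n_institutional, 4L)
  expect_equal(built$episodes$final_discharge_date, d("2010-07-22"))
})

test_that("death censors the effective discharge and the episode end", {
  cfg <- test_config()
  person <- mk_person(death = "2010-05-15")
  enc <- mk_enc("A1", admit = "2010-05-01", discharge = "2010-06-10")
  built <- build_episodes(enc, person, cfg)
  expect_equal(built$episodes$final_discharge_date, d("2010-05-15"))
  expect_equal(built$episodes$end_date, d("2010-05-15"))
})

test_that("open discharges and study-end spillover are censored at study end", {
  cfg <- test_config()
  open_stay <- mk_enc("A1", admit = "2011-03-10", discharge = NA)
  b1 <- build_episodes(open_stay, mk_person(), cfg)
  expect_equal(b1$episodes$final_discharge_date, cfg$study_end)
  expect_equal(b1$episodes$end_date, cfg$study_end)
  late <- mk_enc("A2", admit = "2011-03-20", discharge = "2011-03-25")
  b2 <- build_episodes(late, mk_person(), cfg)
  expect_equal(b2$episodes$end_date, cfg$study_end) # would be Apr 24 uncensored
})

test_that("community care attaches over the closed episode span only", {
  cfg <- test_config()
  enc <- mk_encs(
    mk_enc("A1", admit = "2010-05-01", discharge = "2010-05-05"),
    mk_enc("R1", sector = "inpatient_rehab", admit = "2010-05-20", discharge = "2010-05-30"),
    # inside the gap between the two institutional stays
    mk_enc("C1", sector = "physician", admit = "2010-05-10", cost = 80,
           admission_type = "not_applicable", service_type = "not_applicable"),
    # exactly on the end date (final discharge + 30): attached, closed interval
    mk_enc("C2", sector = "drug", admit = "2010-06-29", cost = 40,
           admission_type = "not_applicable", service_type = "not_applicable"),
    # 31 days after the final discharge: outside
    mk_enc("C3", sector = "home_care", admit = "2010-06-30", cost = 60,
           admission_type = "not_applicable", service_type = "not_applicable")
  )
  built <- attach_community_care(build_episodes(enc, mk_person(), cfg), enc, cfg)
  expect_equal(built$episodes$end_date, d("2010-06-29"))
  mem <- built$membership
  key <- built$episodes$episode_key
  expect_equal(mem$episode_key[mem$encounter_id == "C1"], key)
  expect_equal(mem$episode_key[mem$encounter_id == "C2"], key)
  expect_true(is.na(mem$episode_key[mem$encounter_id == "C3"]))
  # oracle: plain interval-membership scan agrees for every community row
  span <- c(built$episodes$start_date, built$episodes$end_date)
  for (id in c("C1", "C2", "C3")) {
    dt <- enc$admit_date[enc$encounter_id == id]
    expect_equal(!is.na(mem$episode_key[mem$encounter_id == id]),
                 dt >= span[1] && dt <= span[2])
  }
  expect_equal(built$episodes$n_community, 2L)
})

test_that("per-diem stays extending past the episode end are prorated", {
  cfg <- test_config()
  person <- mk_person(death = "2010-05-19")
  enc <- mk_encs(
    mk_enc("A1", admit = "2010-04-01", discharge = "2010-04-05", cost = 1000),
    # 100-day LTC stay; death censors the episode at day 40 of the stay
    mk_enc("L1", sector = "long_term_care", admit = "2010-04-10",
           discharge = "2010-07-18", cost = 10000)
  )
  built <- episode_costs(attach_community_care(build_episodes(enc, person, cfg), enc, cfg),
                         enc, cfg)
  expect_equal(built$episodes$end_date, d("2010-05-19"))
  mem <- built$membership
  expect_equal(mem$allocated_cents[mem$encounter_id == "L1"], 400000) # 40/100 of $10,000
  expect_equal(built$episodes$total_cost, 1000 + 4000)
  led <- allocate_costs(built, enc)
  expect_equal(led$allocated[led$sector == "long_term_care"], 4000)
  expect_equal(led$remaining[led$sector == "long_term_care"], 6000)
})

test_that("episode spans partition institutional care and separate by more than the window", {
  cfg <- test_config()
  for (seed in c(3, 9, 21)) {
    sim <- simulate_scenario(scenario_config(n_persons = 120, seed = seed))
    built <- build_episodes(sim$encounters, sim$persons, cfg)
    mem <- built$membership
    inst <- mem[mem$sector %in% setdiff(pce_sectors("institutional"), "inpatient_nonacute"), ]
    # partition: every eligible institutional encounter appears exactly once
    expect_equal(sort(inst$encounter_id),
                 sort(sim$encounters$encounter_id[
                   sim$encounters$sector %in% setdiff(pce_sectors("institutional"),
                                                      "inpatient_nonacute")]))
    expect_false(any(duplicated(inst$encounter_id)))
    eps <- as.data.frame(built$episodes)
    # separation and censoring per person
    for (pid in unique(eps$person_id)) {
      pe <- eps[eps$person_id == pid, ]
      pe <- pe[order(pe$start_date), ]
      if (nrow(pe) > 1) {
        gaps <- as.integer(pe$start_date[-1]) - as.integer(pe$final_discharge_date[-nrow(pe)])
        expect_true(all(gaps > cfg$window_days))
      }
    }
    expect_true(all(eps$end_date <= cfg$study_end))
    death <- sim$persons$death_date[match(eps$person_id, sim$persons$person_id)]
    expect_true(all(is.na(death) | eps$end_date <= death))
    expect_true(all(eps$end_date >= eps$final_discharge_date))
  }
})

test_that("builder matches the brute-force closure oracle on random persons", {
  cfg <- test_config()
  for (seed in c(101, 202)) {
    sim <- simulate_scenario(scenario_config(n_persons = 100, seed = seed))
    built <- build_episodes(sim$encounters, sim$persons, cfg)
    expect_equal(oracle_disagreements(built, sim$encounters, sim$persons, cfg), 0L)
  }
})

test_that("widening the window never increases the number of episodes", {
  sim <- simulate_scenario(scenario_config(n_persons = 150, seed = 5))
  counts <- sapply(c(15L, 30L, 45L, 60L), function(w) {
    nrow(build_episodes(sim$encounters, sim$persons, test_config(window_days = w))$episodes)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("duplicate encounter ids are rejected", {
  enc <- mk_encs(mk_enc("X1"), mk_enc("X1", admit = "2010-06-01", discharge = "2010-06-02"))
  expect_error(build_episodes(enc, mk_person(), test_config()), "duplicate encounter_id")
})
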