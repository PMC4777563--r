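# Independent brute-force episode grouper: transitive closure of the
# "admission within window of an earlier discharge" relation, restricted to
# forward reachability from acute-start anchors. Deliberately different in
# formulation from the package's sequential scan (adjacency matrix + Floyd-
# Warshall closure vs. rolling window), so the two can cross-check.

oracle_build_person <- function(enc_person, death_date, config) {
  inst <- enc_person[enc_person$sector %in% pce_sectors("institutional"), , drop = FALSE]
  if (nrow(inst) == 0) {
    return(data.frame(encounter_id = character(), episode = character(),
                      stringsAsFactors = FALSE))
  }
  sec_rank <- match(inst$sector, pce_sectors("all"))
  disch <- inst$discharge_date
  disch[is.na(disch)] <- config$study_end
  eff <- pmin(disch, config$study_end)
  if (!is.na(death_date)) eff <- pmin(eff, death_date)
  eff <- pmax(eff, inst$admit_date)
  ord <- order(inst$admit_date, eff, sec_rank, inst$encounter_id)
  inst <- inst[ord, , drop = FALSE]
  eff <- eff[ord]
  n <- nrow(inst)
  eligible <- inst$sector != "inpatient_nonacute"
  admit_i <- as.integer(inst$admit_date)
  eff_i <- as.integer(eff)

  # adjacency: j reachable in one step from i (forward in time, within window)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && eligible[i] && eligible[j] &&
          admit_i[j] >= admit_i[i] &&
          admit_i[j] <= eff_i[i] + config$window_days) {
        adj[i, j] <- TRUE
      }
    }
  }
  # Floyd-Warshall transitive closure
  reach <- adj
  diag(reach) <- TRUE
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (reach[i, k]) reach[i, ] <- reach[i, ] | reach[k, ]
    }
  }
  anchors <- acute_start_sectors(config)
  assignment <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (eligible[i] && inst$sector[i] %in% anchors && is.na(assignment[i])) {
      members <- which(reach[i, ] & is.na(assignment) & eligible)
      assignment[members] <- inst$encounter_id[i]
    }
  }
  data.frame(encounter_id = inst$encounter_id, episode = assignment,
             stringsAsFactors = FALSE)
}

# oracle over a whole encounter table; returns encounter_id -> anchor id (or NA)
oracle_build <- function(encounters, persons, config) {
  enc <- as.data.frame(encounters)
  per <- as.data.frame(persons)
  res <- lapply(unique(enc$person_id), function(pid) {
    death <- per$death_date[match(pid, per$person_id)]
    if (length(death) == 0) death <- as.Date(NA)
    oracle_build_person(enc[enc$person_id == pid, , drop = FALSE], death, config)
  })
  do.call(rbind, res)
}

# count disagreements between builder membership and oracle, as partitions
oracle_disagreements <- function(built, encounters, persons, config) {
  orc <- oracle_build(encounters, persons, config)
  mem <- as.data.frame(built$membership)
  mem <- mem[mem$sector %in% pce_sectors("institutional"), ]
  m <- merge(mem, orc, by = "encounter_id")
  # canonicalize builder keys to the anchor (first member) encounter id
  canon <- function(keys, ids) {
    lab <- ifelse(is.na(keys), "unallocated", keys)
    firsts <- tapply(ids, lab, min)
    out <- unname(firsts[lab])
    out[lab == "unallocated"] <- "unallocated"
    out
  }
  builder <- canon(m$episode_key, m$encounter_id)
  oracle <- canon(m$episode, m$encounter_id)
  sum(builder != oracle)
}
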