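# Independent oracles and programmatic fixtures shared across tests.

# Exact two-sided Mann-Whitney p-value by full enumeration of all C(N, n_a)
# assignments of the pooled ranks to the first sample (valid without ties).
mw_enum_p <- function(a, b) {
  n_a <- length(a)
  N <- n_a + length(b)
  ranks <- rank(c(a, b))
  u_from_ranks <- function(idx) sum(ranks[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_from_ranks(seq_len(n_a))
  us <- utils::combn(N, n_a, u_from_ranks)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# A small fee schedule built in code (Korean-style per-procedure fees).
toy_schedule <- function() {
  fee_schedule(tibble::tibble(
    label = c("ERCP", "EUS-BD", "PTBD"),
    category = rep("primary-intervention", 3),
    amount = c(413.42, 1028.27, 762.80),
    country = "KR"
  ), currency = "KRW", conversion_factor = 1)
}

# Minimal valid patient records: two patients per arm, no re-interventions
# unless costs are supplied.
toy_records <- function(eus_hosp = c(3000, 3200), ptbd_hosp = c(3500, 3700),
                        eus_reint = 0, ptbd_reint = 0) {
  n_e <- length(eus_hosp)
  n_p <- length(ptbd_hosp)
  eus_reint <- rep_len(eus_reint, n_e)
  ptbd_reint <- rep_len(ptbd_reint, n_p)
  tibble::tibble(
    patient_id = c(sprintf("E%02d", seq_len(n_e)), sprintf("P%02d", seq_len(n_p))),
    arm = c(rep("EUS-BD", n_e), rep("PTBD", n_p)),
    hospital_other_cost = c(eus_hosp, ptbd_hosp),
    primary_bd_cost = c(rep(1029.15, n_e), rep(1177.21, n_p)),
    reintervention_cost = c(eus_reint, ptbd_reint),
    n_reinterventions = as.integer(c(eus_reint, ptbd_reint) > 0),
    n_primary_sessions = c(rep(1L, n_e), rep(2L, n_p))
  )
}

# Records reproducing the published re-intervention structure: 34 and 32
# enrolled, 32 and 31 eligible; 8 re-intervened patients with 11 events in
# the EUS-BD arm, 17 with 29 events in the PTBD arm.
korea_structure_records <- function() {
  eus_counts <- integer(34)
  eus_counts[1:8] <- c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L)       # 11 events
  ptbd_counts <- integer(32)
  ptbd_counts[1:17] <- c(rep(2L, 12), rep(1L, 5))             # 29 events
  tibble::tibble(
    patient_id = c(sprintf("E%02d", 1:34), sprintf("P%02d", 1:32)),
    arm = c(rep("EUS-BD", 34), rep("PTBD", 32)),
    hospital_other_cost = 3000,
    primary_bd_cost = c(rep(1029.15, 34), rep(1177.21, 32)),
    reintervention_cost = 300 * c(eus_counts, ptbd_counts),
    n_reinterventions = c(eus_counts, ptbd_counts),
    n_primary_sessions = 1L,
    reint_eligible = c(seq_len(34) <= 32, seq_len(32) <= 31)
  )
}

# A pair of degenerate (point-mass) arm configurations.
point_mass_configs <- function(eus_p = 0.25, ptbd_p = 0.5) {
  list(
    eus = arm_sim_config(
      "EUS-BD", n_patients = 10, reintervention_prob = eus_p,
      mean_frequency = eus_p,
      hospital_cost_dist = dist_point(3000),
      primary_cost_dist = dist_point(1000),
      reintervention_unit_cost_dist = dist_point(200)
    ),
    ptbd = arm_sim_config(
      "PTBD", n_patients = 10, reintervention_prob = ptbd_p,
      mean_frequency = ptbd_p,
      hospital_cost_dist = dist_point(3600),
      primary_cost_dist = dist_point(1200),
      reintervention_unit_cost_dist = dist_point(300)
    )
  )
}
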