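# Hand-built two-study fixture: study A is a plain two-arm trial, study B a
# three-arm trial (one MBI arm shared by two control comparisons).  All
# numbers are short decimals chosen for exact hand computation.

fixture_measure <- function(study_id, comparison_id, ctl_arm, name, category,
                            direction = "higher_better",
                            mbi = c(10, 2, 14, 2, 20),
                            ctl = c(10, 2, 11, 2, 20)) {
  data.frame(
    study_id = study_id, comparison_id = comparison_id,
    mbi_arm_id = "mbi", control_arm_id = ctl_arm,
    measure_name = name, category = category, direction = direction,
    mbi_pre_mean = mbi[1], mbi_pre_sd = mbi[2], mbi_post_mean = mbi[3],
    mbi_post_sd = mbi[4], mbi_n = mbi[5],
    ctl_pre_mean = ctl[1], ctl_pre_sd = ctl[2], ctl_post_mean = ctl[3],
    ctl_post_sd = ctl[4], ctl_n = ctl[5],
    stringsAsFactors = FALSE
  )
}

fixture_studies <- function() {
  data.frame(
    study_id = c("A", "B"),
    age_mean = c(12.5, NA),
    total_hours = c(10, 6),
    training_weeks = c(8, 12),
    mbi_name = c("MBSR-derived", "School curriculum"),
    rob_random_sequencing = c("low", "low"),
    rob_allocation = c("low", "low"),
    rob_blinding = c("low", "low"),
    rob_incomplete = c("low", "low"),
    rob_selective = c("low", "high"),
    stringsAsFactors = FALSE
  )
}

fixture_arms <- function() {
  data.frame(
    study_id = c("A", "A", "B", "B", "B"),
    arm_id = c("mbi", "ctl1", "mbi", "ctl1", "ctl2"),
    role = c("mbi", "control", "mbi", "control", "control"),
    control_subtype = c("none", "wait_list", "none", "no_contact",
                        "active_intervention"),
    n = c(20L, 20L, 10L, 10L, 12L),
    stringsAsFactors = FALSE
  )
}

fixture_measures <- function() {
  rbind(
    # d = (4 - 1) / 2 = 1.5
    fixture_measure("A", "cmp1", "ctl1", "mind_a", "mindfulness"),
    # second mindfulness instrument, d = (2 - 0) / 2 = 1.0
    fixture_measure("A", "cmp1", "ctl1", "mind_b", "mindfulness",
                    mbi = c(5, 2, 7, 2, 20), ctl = c(5, 2, 5, 2, 20)),
    # lower-is-better: raw (-5 - (-1))/4 = -1, oriented +1
    fixture_measure("A", "cmp1", "ctl1", "dep_a", "depression",
                    direction = "lower_better",
                    mbi = c(20, 4, 15, 4, 20), ctl = c(20, 4, 19, 4, 20)),
    fixture_measure("B", "cmp1", "ctl1", "anx_a", "anxiety_stress",
                    direction = "lower_better",
                    mbi = c(30, 5, 25, 5, 10), ctl = c(30, 5, 29, 5, 10)),
    fixture_measure("B", "cmp2", "ctl2", "anx_a", "anxiety_stress",
                    direction = "lower_better",
                    mbi = c(30, 5, 25, 5, 10), ctl = c(31, 5, 30, 4, 12))
  )
}

fixture_dataset <- function() {
  ppc_dataset(fixture_studies(), fixture_arms(), fixture_measures())
}

write_fixture_csvs <- function(dir = tempfile("fixture")) {
  write_dataset(fixture_dataset(), dir)
  list(studies = file.path(dir, "studies.csv"),
       arms = file.path(dir, "arms.csv"),
       measures = file.path(dir, "measures.csv"),
       dir = dir)
}

# Random comparison-level effect table (for estimator-level tests).
random_effects <- function(k, delta = 0.2, tau2 = 0.05,
                           v_range = c(0.02, 0.1)) {
  v <- runif(k, v_range[1], v_range[2])
  data.frame(d = rnorm(k, delta, sqrt(tau2 + v)), variance = v)
}
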