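test_that("duplicate surveys within 5 minutes are removed sequentially", {
  sv <- data.frame(patient_id = "P01",
                   timestamp = c(36000, 36240, 36480))  # 10:00, 10:04, 10:08
  out <- deduplicate(sv)
  expect_equal(out$timestamp, c(36000, 36480))   # 10:04 dropped, 10:08 kept

  # exactly 5 minutes apart: both kept
  sv2 <- data.frame(patient_id = "P01", timestamp = c(36000, 36300))
  expect_equal(nrow(deduplicate(sv2)), 2L)

  # idempotence
  expect_equal(deduplicate(out), out)

  # patients are independent
  sv3 <- data.frame(patient_id = c("P01", "P02"), timestamp = c(36000, 36060))
  expect_equal(nrow(deduplicate(sv3)), 2L)
})

test_that("outcome binarization follows the PAS subscore rules", {
  sv <- data.frame(pas_vocal = c(0, 0, 1, 0),
                   pas_motor = c(0, 2, 1, 0),
                   pas_aggr  = c(0, 0, 0, 3),
                   pas_resist = c(0, 0, 0, 0))
  out <- binarize_outcomes(sv)
  expect_equal(out$agitated,        c(0, 1, 1, 1))
  expect_equal(out$motor_agitated,  c(0, 1, 1, 0))
  expect_equal(out$verbal_agitated, c(0, 0, 1, 0))
})

test_that("binarization is monotone in the item scores", {
  set.seed(30)
  for (i in 1:20) {
    base <- data.frame(pas_vocal = sample(0:4, 1), pas_motor = sample(0:4, 1),
                       pas_aggr = sample(0:4, 1), pas_resist = sample(0:4, 1))
    bumped <- base + sample(0:2, 4, replace = TRUE)
    names(bumped) <- names(base)
    b0 <- binarize_outcomes(base)
    b1 <- binarize_outcomes(bumped)
    expect_gte(b1$agitated, b0$agitated)
    expect_gte(b1$motor_agitated, b0$motor_agitated)
    expect_gte(b1$verbal_agitated, b0$verbal_agitated)
  }
})

test_that("time blocks partition the clock: 8-12, 12-16, 16-20, 20-8", {
  hms <- function(h, m = 0) h * 3600 + m * 60
  expect_equal(assign_time_group(hms(11, 59)), 1L)
  expect_equal(assign_time_group(hms(12, 0)), 2L)
  expect_equal(assign_time_group(hms(20, 30)), 4L)
  expect_equal(assign_time_group(hms(3, 0)), 4L)
  expect_equal(assign_time_group(hms(8, 0)), 1L)
  # next-day wraparound uses clock time
  expect_equal(assign_time_group(86400 + hms(9)), 1L)
  # every second of the day maps to exactly one block
  tg <- assign_time_group(seq(0, 86399, by = 61))
  expect_true(all(tg %in% 1:4))
})

test_that("patients with fewer than 2 kept surveys drop per modality only", {
  tab <- data.frame(
    patient_id = c("A", "A", "A", "B", "B", "B"),
    modality  = c("eda", "eda", "hr", "eda", "hr", "hr"),
    survey_id = c("s1", "s2", "s3", "s4", "s5", "s6"))
  out <- apply_inclusion_rules(tab)
  # A has 2 eda, 1 hr; B has 1 eda, 2 hr
  expect_setequal(out$survey_id[out$modality == "eda"], c("s1", "s2"))
  expect_setequal(out$survey_id[out$modality == "hr"], c("s5", "s6"))
})

test_that("visualization subset demands 2+2 per outcome, modality-wide", {
  mk <- function(pid, n_ag, n_non) {
    # surveys agitated in all three senses, plus non-agitated ones
    rbind(
      if (n_ag > 0) expand.grid(patient_id = pid, modality = c("acc", "eda"),
                                survey_id = paste0(pid, "a", seq_len(n_ag)),
                                agitated = 1L, motor_agitated = 1L,
                                verbal_agitated = 1L, stringsAsFactors = FALSE),
      expand.grid(patient_id = pid, modality = c("acc", "eda"),
                  survey_id = paste0(pid, "n", seq_len(n_non)),
                  agitated = 0L, motor_agitated = 0L, verbal_agitated = 0L,
                  stringsAsFactors = FALSE))
  }
  tab <- rbind(mk("A", 3, 5), mk("B", 1, 5), mk("C", 2, 2))
  out <- select_visualization_subset(tab)
  expect_setequal(out, c("A", "C"))   # B has only 1 agitated survey

  expect_warning(empty <- select_visualization_subset(tab[0, ]), "no patient")
  expect_length(empty, 0)
})
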