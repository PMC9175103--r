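# Structured-table builders for cohort tests.

vax_row <- function(pid = "p1", date = "2017-03-01", arm = "left",
                    route = "IM", setting = "facility", age = 40) {
  data.frame(patient_id = pid,
             admin_datetime = paste(date, "09:00:00"),
             vaccine_name = "influenza", route = route,
             site_laterality = arm, setting = setting,
             patient_dob = format(as.Date(date) - round(age * 365.25)),
             stringsAsFactors = FALSE)
}

mem_row <- function(pid = "p1", date = "2017-03-01", before = 200,
                    after = 200) {
  data.frame(patient_id = pid,
             start_date = format(as.Date(date) - before),
             end_date = format(as.Date(date) + after),
             stringsAsFactors = FALSE)
}

dx_rows <- function(pid = "p1", index = "2017-03-01", days = c(5, 40, 90),
                    code = "M75.42", eids = NULL) {
  if (!length(days))
    return(data.frame(patient_id = character(), date = character(),
                      icd10cm_code = character(),
                      encounter_id = character(), stringsAsFactors = FALSE))
  data.frame(patient_id = pid,
             date = format(as.Date(index) + days),
             icd10cm_code = code,
             encounter_id = eids %||% paste0("e", seq_along(days)),
             stringsAsFactors = FALSE)
}

test_that("eligibility checks route, setting, laterality, age, membership", {
  v <- rbind(vax_row("p1"), vax_row("p2", arm = "unknown"),
             vax_row("p3", age = 2), vax_row("p4", route = "SC"),
             vax_row("p5"), vax_row("p6", setting = "outside"))
  m <- rbind(mem_row("p1"), mem_row("p2"), mem_row("p3"), mem_row("p4"),
             mem_row("p5", after = 90), mem_row("p6"))
  ev <- select_eligible_vaccinations(v, m)
  dec <- setNames(ev$exclusion_reason, ev$patient_id)
  expect_equal(ev$decision[ev$patient_id == "p1"], "included")
  expect_equal(dec[["p2"]], "no_laterality")
  expect_equal(dec[["p3"]], "age")
  expect_equal(dec[["p4"]], "route")
  expect_equal(dec[["p5"]], "membership")
  expect_equal(dec[["p6"]], "setting")
})

test_that("presumptive injury needs matched codes and a clean lookback", {
  v <- rbind(vax_row("p1"), vax_row("p2"), vax_row("p3"), vax_row("p4"))
  m <- do.call(rbind, lapply(paste0("p", 1:4), mem_row))
  d <- rbind(
    dx_rows("p1", days = c(10, 60)),            # clean, matched -> in
    dx_rows("p2", days = c(-30, 10, 60)),       # prior code -> out
    dx_rows("p3", days = c(5, 20)),             # nothing in 31-180 -> out
    dx_rows("p4", days = c(10, 60), code = "M75.41"))  # right codes, left arm
  ev <- select_eligible_vaccinations(v, m)
  ev <- identify_presumptive_injury(ev, d)
  dec <- setNames(ev$exclusion_reason, ev$patient_id)
  expect_equal(ev$decision[ev$patient_id == "p1"], "included")
  expect_equal(dec[["p2"]], "prior_shoulder")
  expect_equal(dec[["p3"]], "no_31_180_code")
  expect_equal(dec[["p4"]], "no_shoulder_code")
})

test_that("day-0 rules require ordered encounters and a later acute visit", {
  event <- data.frame(patient_id = "p1", index_date = as.Date("2017-03-01"),
                      admin_datetime = "2017-03-01 09:00:00",
                      arm = "left", stringsAsFactors = FALSE)
  d0 <- dx_rows("p1", days = 0, eids = "e-virtual")
  enc2 <- data.frame(
    encounter_id = c("e-office", "e-virtual"), patient_id = "p1",
    datetime = c("2017-03-01 08:30:00", "2017-03-01 14:00:00"),
    type = c("office", "virtual"), stringsAsFactors = FALSE)
  # first encounter before vaccination -> excluded
  r <- apply_day0_rules(event, enc2, d0)
  expect_equal(r$exclusion_reason, "first_day0_before_vaccination")
  # same encounters after the vaccination time -> included
  enc_ok <- enc2; enc_ok$datetime[1] <- "2017-03-01 09:10:00"
  expect_equal(apply_day0_rules(event, enc_ok, d0)$decision, "included")
  # a single day-0 encounter fails
  expect_equal(apply_day0_rules(event, enc_ok[2, ], d0)$exclusion_reason,
               "single_day0_encounter")
  # shoulder code on the first encounter fails
  d_first <- dx_rows("p1", days = 0, eids = "e-office")
  expect_equal(apply_day0_rules(event, enc_ok, d_first)$exclusion_reason,
               "first_day0_shoulder_code")
  # no later urgent/ED/virtual visit fails
  enc_all_office <- enc_ok; enc_all_office$type <- "office"
  expect_equal(apply_day0_rules(event, enc_all_office, d0)$exclusion_reason,
               "no_day0_urgent_virtual")
  # missing timestamps are not orderable
  enc_na <- enc_ok; enc_na$datetime[2] <- NA
  expect_equal(apply_day0_rules(event, enc_na, d0)$exclusion_reason,
               "unordered_day0")
})

test_that("subpopulation criteria apply in order with group-D exclusions", {
  v <- do.call(rbind, lapply(paste0("p", 1:4), vax_row))
  m <- do.call(rbind, lapply(paste0("p", 1:4), mem_row))
  d <- rbind(
    dx_rows("p1", days = c(5, 40, 90)),                       # in
    rbind(dx_rows("p2", days = c(5, 40, 90)),                 # D code -> out
          dx_rows("p2", days = -100, code = "S43.402")),
    dx_rows("p3", days = c(40, 90)),                          # no 1-30 code
    dx_rows("p4", days = c(5, 40)))                           # one 31-180 date
  ev <- select_eligible_vaccinations(v, m)
  ev <- identify_presumptive_injury(ev, d)
  expect_equal(unname(setNames(ev$exclusion_reason,
                               ev$patient_id)["p2"]), "prior_shoulder")
  # run subpopulation on the two still included plus constructed cases
  ev2 <- apply_subpopulation_criteria(ev, d)
  dec <- setNames(ev2$exclusion_reason, ev2$patient_id)
  expect_equal(ev2$decision[ev2$patient_id == "p1"], "included")
  expect_equal(dec[["p3"]], "no_1_30_code")
  expect_equal(dec[["p4"]], "single_31_180_date")
  # a group-D code inside the window, not in the lookback
  v5 <- vax_row("p5"); m5 <- mem_row("p5")
  d5 <- rbind(dx_rows("p5", days = c(5, 40, 90)),
              dx_rows("p5", days = 100, code = "S43.402"))
  e5 <- identify_presumptive_injury(
    select_eligible_vaccinations(v5, m5), d5)
  e5 <- apply_subpopulation_criteria(e5, d5)
  expect_equal(e5$exclusion_reason, "external_injury")
})

test_that("code laterality decodes from the ICD-style final digit", {
  expect_equal(decode_code_laterality(c("M75.41", "M75.42", "M25.513",
                                        "M75.40")),
               c("right", "left", "bilateral", "none"))
})

test_that("the funnel is monotone and exclusions carry exactly one reason", {
  pop <- generate_population(small_specs(3), seed = 13)
  out <- run_cohort(pop$vaccinations, pop$encounters, pop$diagnoses,
                    pop$membership)
  expect_true(all(diff(out$funnel$n) <= 0))
  exc <- out$events[out$events$decision == "excluded", ]
  expect_true(all(!is.na(exc$exclusion_reason)))
  inc <- out$events[out$events$decision == "included", ]
  expect_true(all(is.na(inc$exclusion_reason)))
})

test_that("day windows are inclusive calendar arithmetic", {
  # a code exactly on day -180 blocks; day 180 counts; day 181 does not
  v <- rbind(vax_row("p1"), vax_row("p2"), vax_row("p3"))
  m <- rbind(mem_row("p1"), mem_row("p2"), mem_row("p3"))
  d <- rbind(dx_rows("p1", days = c(-180, 10, 60)),
             dx_rows("p2", days = c(10, 180)),
             dx_rows("p3", days = c(10, 181)))
  ev <- identify_presumptive_injury(select_eligible_vaccinations(v, m), d)
  dec <- setNames(ev$exclusion_reason, ev$patient_id)
  expect_equal(dec[["p1"]], "prior_shoulder")
  expect_equal(ev$decision[ev$patient_id == "p2"], "included")
  expect_equal(dec[["p3"]], "no_31_180_code")
  # independent check of the offset arithmetic against Date sequences
  idx <- as.Date("2017-03-01")
  expect_equal(seq(idx, by = "day", length.out = 181)[181], idx + 180)
})
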