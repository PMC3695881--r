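write_claims_csv <- function(tbl, path = withr::local_tempfile(
                               fileext = ".csv", .local_envir = parent.frame())) {
  readr::write_csv(tbl, path, progress = FALSE)
  path
}

base_claims <- function(n = 10) {
  tibble::tibble(
    hospital_id = "H1",
    patient_id = sprintf("Pa%d", rep(seq_len(ceiling(n / 2)), each = 2)[1:n]),
    physician_id = sprintf("Ph%d", rep_len(1:3, n)),
    admission_id = sprintf("Pa%d_A1",
                           rep(seq_len(ceiling(n / 2)), each = 2)[1:n]),
    service_date = as.Date("2020-03-01") + seq_len(n),
    claim_category = rep_len(c("medical", "hospital"), n),
    benefit_amount = seq_len(n) * 10,
    patient_age = 65,
    procedure_code = "THR"
  )
}

test_that("a well-formed file passes through unchanged", {
  path <- write_claims_csv(base_claims(10))
  visits <- read_claims(path)
  expect_s3_class(visits, "visit_table")
  expect_equal(nrow(visits), 10)
  expect_equal(nrow(attr(visits, "rejections")), 0)
  expect_s3_class(visits$service_date, "Date")
  expect_type(visits$benefit_amount, "double")
})

test_that("a missing mapped column is a schema error naming it", {
  tbl <- base_claims(4)
  tbl$physician_id <- NULL
  path <- write_claims_csv(tbl)
  expect_error(read_claims(path), "physician_id")
})

test_that("column mappings rename file columns to the canonical schema", {
  tbl <- base_claims(6)
  names(tbl)[names(tbl) == "physician_id"] <- "provider_no"
  path <- write_claims_csv(tbl)
  visits <- read_claims(path, claims_schema(physician_id = "provider_no"))
  expect_equal(visits$physician_id, base_claims(6)$physician_id)
  expect_error(claims_schema(nonsense = "x"), "unknown claim fields")
})

test_that("invalid rows are rejected one by one with reasons", {
  tbl <- base_claims(10)
  tbl$benefit_amount[3] <- -5
  tbl$service_date <- as.character(tbl$service_date)
  tbl$service_date[7] <- "not-a-date"
  tbl$claim_category[9] <- "dental"
  path <- write_claims_csv(tbl)
  expect_warning(visits <- read_claims(path), "3 claim row")
  expect_equal(nrow(visits), 7)
  rej <- attr(visits, "rejections")
  expect_equal(rej$row, c(3, 7, 9))
  expect_match(rej$reason[1], "negative benefit_amount")
  expect_match(rej$reason[2], "service_date")
  expect_match(rej$reason[3], "claim_category")
})

test_that("an admission episode cannot span two patients", {
  tbl <- base_claims(4)
  tbl$admission_id <- "A1"
  expect_error(validate_claims(tbl), "more than one")
})

test_that("hospital filtering keeps hospitals by distinct matching patients", {
  make_hospital <- function(hid, n_pat) {
    tibble::tibble(
      hospital_id = hid,
      patient_id = sprintf("%s_Pa%d", hid, rep(seq_len(n_pat), each = 2)),
      physician_id = "Ph1",
      admission_id = sprintf("%s_Pa%d_A1", hid, rep(seq_len(n_pat), each = 2)),
      service_date = as.Date("2020-01-01"),
      claim_category = "medical",
      benefit_amount = 10,
      patient_age = 70,
      procedure_code = "THR"
    )
  }
  visits <- validate_claims(dplyr::bind_rows(
    make_hospital("HA", 6), make_hospital("HB", 5), make_hospital("HC", 4)
  ))
  kept <- filter_hospitals(visits, min_patients = 5)
  expect_setequal(unique(kept$hospital_id), c("HA", "HB"))
  all_kept <- filter_hospitals(visits, min_patients = 1)
  expect_setequal(unique(all_kept$hospital_id), c("HA", "HB", "HC"))
  expect_warning(filter_hospitals(visits, min_patients = 100),
                 "no hospital")
})

test_that("filtering matches a brute-force per-hospital count and is idempotent", {
  set.seed(41)
  visits <- random_visits(n_hospitals = 6, n_patients = 7)
  # mark a random subset of patients as non-index-procedure
  other <- sample(unique(visits$patient_id), 15)
  visits$procedure_code[visits$patient_id %in% other] <- "KNEE"
  kept <- filter_hospitals(visits, min_patients = 4, procedure_code = "THR")

  expected_hospitals <- Filter(function(h) {
    rows <- visits[visits$hospital_id == h & visits$procedure_code == "THR", ]
    length(unique(rows$patient_id)) >= 4
  }, unique(visits$hospital_id))
  expect_setequal(unique(kept$hospital_id), expected_hospitals)
  # retained records are restricted to the matching patients
  expect_true(all(kept$procedure_code == "THR"))

  again <- filter_hospitals(kept, min_patients = 4, procedure_code = "THR")
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(kept))
})

test_that("readmission rate is the percentage of multi-admission patients", {
  tbl <- dplyr::bind_rows(lapply(1:5, function(p) {
    tibble::tibble(
      hospital_id = "H1", patient_id = paste0("Pa", p),
      physician_id = "Ph1",
      admission_id = paste0("Pa", p, "_A1"),
      service_date = as.Date("2020-01-01"), claim_category = "medical",
      benefit_amount = 100, patient_age = 70, procedure_code = "THR"
    )
  }))
  second <- tbl[1, ]
  second$admission_id <- "Pa1_A2"
  visits <- validate_claims(dplyr::bind_rows(tbl, second))
  out <- compute_outcomes(visits, "H1")
  expect_equal(out$readmission_rate, 20)
  expect_equal(out$n_patients, 5)

  single <- validate_claims(tbl)
  expect_equal(compute_outcomes(single, "H1")$readmission_rate, 0)
})

test_that("outcomes equal an independent per-patient aggregation", {
  set.seed(99)
  visits <- random_visits(n_hospitals = 3, n_patients = 9, visits = 5)
  for (h in unique(visits$hospital_id)) {
    out <- compute_outcomes(visits, h)
    rows <- visits[visits$hospital_id == h, ]
    per_patient <- split(rows, rows$patient_id)
    expect_equal(out$n_patients, length(per_patient))
    expect_equal(out$mean_cost_per_patient,
                 sum(vapply(per_patient, function(r) sum(r$benefit_amount),
                            numeric(1))) / length(per_patient))
    expect_equal(out$readmission_rate,
                 100 * mean(vapply(per_patient, function(r)
                   length(unique(r$admission_id)) > 1, logical(1))))
    expect_equal(out$mean_patient_age,
                 mean(vapply(per_patient, function(r)
                   r$patient_age[order(r$service_date)][1], numeric(1))))
    expect_true(out$readmission_rate >= 0 && out$readmission_rate <= 100)
  }
  expect_error(compute_outcomes(visits, "NOPE"), "unknown hospital")
})

test_that("conflicting patient ages resolve to the earliest record", {
  tbl <- base_claims(4)
  tbl$patient_age <- c(70, 71, 60, 60)
  visits <- validate_claims(tbl)
  expect_warning(out <- compute_outcomes(visits, "H1"), "conflicting")
  expect_equal(out$mean_patient_age, mean(c(70, 60)))
})
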