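#' Configuration of the synthetic claims generator
#'
#' Describes a synthetic multi-hospital cohort whose visit process and
#' outcomes carry the statistical structure the analysis pipeline
#' assumes: per-hospital patient-physician visit multigraphs whose
#' projection spans the decentralised-to-centralised axis via
#' `attachment`, and cost/readmission outcomes causally linked to the
#' realised network indices.
#'
#' Default sizes mirror a mid-2000s multi-hospital hip-replacement claims
#' cohort: 85 hospitals, 5-47 index patients per hospital (mean about
#' 26), 10-42 physician visits per patient, patient ages centred near 69
#' years.  The cost model plants a positive density effect and a negative
#' betweenness-centralisation effect (coefficients of the order of the
#' published hospital-level regression slopes, AUD 17310 and AUD -12385
#' per unit index), so that recovering these signs end-to-end is a
#' meaningful check of the whole pipeline.  The readmission model plants
#' a negative degree-centralisation and positive density effect on the
#' logit scale around a baseline giving roughly 12% readmissions.
#'
#' @param n_hospitals Number of hospitals.
#' @param patients_per_hospital Integer range `c(min, max)`; the minimum
#'   respects the 5-patient eligibility filter.
#' @param physicians_per_hospital Integer range.
#' @param visits_per_patient Integer range of medical visits per patient.
#' @param attachment In \[0, 1\]: 0 draws each visit's physician
#'   uniformly (decentralised networks); 1 concentrates visits on a few
#'   physicians (star-like networks).  Intermediate values interpolate.
#' @param cost_model List `base`, `beta_density`, `beta_betweenness`,
#'   `noise_sd` (currency): per-patient cost is
#'   `base + beta_density * density + beta_betweenness *
#'   betweenness_centralisation + N(0, noise_sd)`, floored at 500.
#' @param readmission_model List `base_logit`,
#'   `beta_degree_centralisation`, `beta_density`: per-patient
#'   readmission probability on the logit scale from the realised
#'   indices.
#' @param age_model List `mean`, `sd` (years); ages are clamped to
#'   \[40, 95\].
#' @param procedure_code Index procedure code stamped on every record.
#' @param seed Integer seed; the cohort is a deterministic function of
#'   the full configuration.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_hospitals = 85,
                         patients_per_hospital = c(5, 47),
                         physicians_per_hospital = c(6, 30),
                         visits_per_patient = c(10, 42),
                         attachment = 0.6,
                         cost_model = list(base = 22500,
                                           beta_density = 17310,
                                           beta_betweenness = -12385,
                                           noise_sd = 12000),
                         readmission_model = list(
                           base_logit = -1.1,
                           beta_degree_centralisation = -2.5,
                           beta_density = 3.5),
                         age_model = list(mean = 69, sd = 10),
                         procedure_code = "THR",
                         seed = 1) {
  cfg <- list(n_hospitals = n_hospitals,
              patients_per_hospital = patients_per_hospital,
              physicians_per_hospital = physicians_per_hospital,
              visits_per_patient = visits_per_patient,
              attachment = attachment, cost_model = cost_model,
              readmission_model = readmission_model, age_model = age_model,
              procedure_code = procedure_code, seed = seed)
  stopifnot(
    n_hospitals >= 1,
    length(patients_per_hospital) == 2,
    patients_per_hospital[1] >= 1,
    diff(patients_per_hospital) >= 0,
    length(physicians_per_hospital) == 2,
    physicians_per_hospital[1] >= 2,
    diff(physicians_per_hospital) >= 0,
    length(visits_per_patient) == 2, visits_per_patient[1] >= 1,
    diff(visits_per_patient) >= 0,
    attachment >= 0, attachment <= 1,
    cost_model$noise_sd >= 0, age_model$sd >= 0
  )
  structure(cfg, class = "synth_config")
}

range_draw <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic claims cohort
#'
#' Each hospital has a lead physician and each patient a small care team
#' of 2-6 slots: a slot is taken by the lead with probability
#' `0.97 * attachment` and by a uniformly drawn colleague otherwise
#' (lone-lead teams gain one colleague -- no care happens single-handed).
#' The patient's visits spread over the distinct team members, one
#' medical claim per visit.  At `attachment = 0` teams are uniform random
#' subsets and the projected network is dense and egalitarian; at
#' `attachment = 1` every team is the lead plus one varying colleague and
#' the network is a star.  The realised collaboration network of the
#' hospital is then projected and its indices computed, and the planted
#' cost and readmission models are evaluated on those realised indices:
#' structure causes outcomes, so the analysis pipeline has a ground truth
#' to recover.
#'
#' Each medical visit emits one medical claim; each admission emits one
#' hospital claim; a small fraction of patients carry an ancillary claim.
#' A readmitted patient receives a second admission episode containing
#' the tail of their visits.  Per-patient claim amounts partition the
#' planted patient cost exactly.
#'
#' @param config A [synth_config()].
#' @return A list (class `synth_cohort`): `claims`, a validated
#'   `visit_table`, and `truth`, a per-hospital tibble of realised
#'   indices and planted quantities (`density`,
#'   `degree_centralisation`, `betweenness_centralisation`,
#'   `planted_mean_cost`, `planted_readmission_prob`, `n_patients`,
#'   `n_physicians`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  # each hospital has a lead physician; a visit goes to the lead with
  # probability `hub_share` and to a uniformly drawn colleague otherwise.
  # attachment = 0 gives uniform co-visiting (dense, egalitarian
  # networks); attachment = 1 concentrates nearly all visits on the lead
  # (star-like networks).  The share is capped just below 1 so that the
  # lead always retains a sprinkling of collaborators.
  hub_share <- 0.97 * config$attachment
  hosp_ids <- sprintf("H%03d", seq_len(config$n_hospitals))
  claims_list <- vector("list", config$n_hospitals)
  truth_list <- vector("list", config$n_hospitals)

  for (h in seq_len(config$n_hospitals)) {
    hid <- hosp_ids[h]
    n_phys <- range_draw(config$physicians_per_hospital, 1)
    n_pat <- range_draw(config$patients_per_hospital, 1)
    phys_ids <- sprintf("%s_D%02d", hid, seq_len(n_phys))
    pat_ids <- sprintf("%s_P%03d", hid, seq_len(n_pat))

    n_visits <- range_draw(config$visits_per_patient, n_pat)
    visit_pat <- rep(seq_len(n_pat), n_visits)
    # every patient is attended by a small care team: a handful of slots,
    # each taken by the lead with probability hub_share and by a
    # uniformly drawn colleague otherwise; the patient's visits are then
    # spread over the distinct team members.  visits_per_patient counts
    # claims, while the team bounds distinct collaborators per patient.
    visit_phys <- unlist(lapply(seq_len(n_pat), function(p) {
      slots <- sample(2:6, 1)
      draw <- ifelse(runif(slots) < hub_share, 1L,
                     sample.int(n_phys, slots, replace = TRUE))
      team <- unique(draw)
      if (length(team) == 1L) {
        # no care happens single-handed: add one uniformly drawn colleague
        other <- sample.int(n_phys - 1L, 1L)
        team <- c(team, other + (other >= team))
      }
      team[sample.int(length(team), n_visits[p], replace = TRUE)]
    }), use.names = FALSE)

    # realised network indices drive the planted outcome models
    inc <- matrix(0L, n_pat, n_phys)
    inc[cbind(visit_pat, visit_phys)] <- 1L
    seen <- which(colSums(inc) > 0)
    adj <- crossprod(inc[, seen, drop = FALSE])
    g <- binary_graph(adj >= 1, nodes = phys_ids[seen])
    # degenerate tiny networks (possible under extreme attachment) score 0
    dens <- if (length(seen) >= 2) network_density(g) else 0
    dc <- if (length(seen) >= 3) centralisation(g, "degree") else 0
    bc <- if (length(seen) >= 3) centralisation(g, "betweenness") else 0

    cm <- config$cost_model
    rm_ <- config$readmission_model
    planted_cost <- cm$base + cm$beta_density * dens +
      cm$beta_betweenness * bc
    p_readmit <- stats::plogis(rm_$base_logit +
      rm_$beta_degree_centralisation * dc + rm_$beta_density * dens)

    ages <- pmin(pmax(round(rnorm(n_pat, config$age_model$mean,
                                  config$age_model$sd)), 40), 95)
    cost <- pmax(planted_cost + rnorm(n_pat, 0, cm$noise_sd), 500)
    readmit <- rbinom(n_pat, 1, p_readmit) == 1
    has_anc <- runif(n_pat) < 0.05

    # per-patient cost split: ancillary (1%) if present, 55% hospital
    # claim(s), remainder spread over the medical visit rows
    anc_amt <- ifelse(has_anc, 0.01 * cost, 0)
    hosp_amt <- 0.55 * cost
    med_amt <- cost - anc_amt - hosp_amt

    # visits ordered per patient; readmitted patients' last quarter of
    # visits forms a second admission episode
    ord <- order(visit_pat)
    visit_pat <- visit_pat[ord]
    visit_phys <- visit_phys[ord]
    visit_no <- sequence(n_visits)
    second <- readmit[visit_pat] &
      visit_no > ceiling(0.75 * n_visits[visit_pat])
    adm_no <- ifelse(second, 2L, 1L)
    admission <- sprintf("%s_A%d", pat_ids[visit_pat], adm_no)
    base_date <- as.Date("2006-01-01") + (h - 1) %% 365
    med <- tibble::tibble(
      hospital_id = hid,
      patient_id = pat_ids[visit_pat],
      physician_id = phys_ids[visit_phys],
      admission_id = admission,
      service_date = base_date + visit_no - 1L + 30L * (adm_no - 1L),
      claim_category = "medical",
      benefit_amount = med_amt[visit_pat] / n_visits[visit_pat],
      patient_age = as.numeric(ages[visit_pat]),
      procedure_code = config$procedure_code
    )
    n_adm <- 1L + readmit
    hos <- tibble::tibble(
      hospital_id = hid,
      patient_id = rep(pat_ids, n_adm),
      physician_id = paste0(hid, "_HOSP"),
      admission_id = sprintf("%s_A%d", rep(pat_ids, n_adm),
                             sequence(n_adm)),
      service_date = base_date + 30L * (sequence(n_adm) - 1L),
      claim_category = "hospital",
      benefit_amount = rep(hosp_amt / n_adm, n_adm),
      patient_age = as.numeric(rep(ages, n_adm)),
      procedure_code = config$procedure_code
    )
    anc <- tibble::tibble(
      hospital_id = hid,
      patient_id = pat_ids[has_anc],
      physician_id = paste0(hid, "_HOSP"),
      admission_id = sprintf("%s_A1", pat_ids[has_anc]),
      service_date = base_date,
      claim_category = "ancillary",
      benefit_amount = anc_amt[has_anc],
      patient_age = as.numeric(ages[has_anc]),
      procedure_code = config$procedure_code
    )
    claims_list[[h]] <- dplyr::bind_rows(med, hos, anc)
    truth_list[[h]] <- tibble::tibble(
      hospital_id = hid, n_patients = n_pat,
      n_physicians = length(seen),
      density = dens, degree_centralisation = dc,
      betweenness_centralisation = bc,
      planted_mean_cost = planted_cost,
      planted_readmission_prob = p_readmit
    )
  }
  claims <- dplyr::bind_rows(claims_list)
  claims <- claims[order(claims$hospital_id, claims$patient_id,
                         claims$service_date, claims$claim_category,
                         claims$physician_id), ]
  structure(list(
    claims = validate_claims(claims, provenance = "synthetic cohort"),
    truth = dplyr::bind_rows(truth_list),
    config = config
  ), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("synthetic claims cohort:", nrow(x$truth), "hospitals,",
      sum(x$truth$n_patients), "patients,", nrow(x$claims), "claims\n")
  invisible(x)
}

#' Write a synthetic cohort to a claims CSV
#'
#' The file is in the canonical input schema and round-trips exactly
#' through [read_claims()].
#'
#' @param cohort A `synth_cohort`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
emit_claims <- function(cohort, path) {
  stopifnot(inherits(cohort, "synth_cohort"))
  out <- tryCatch(
    readr::write_csv(as.data.frame(cohort$claims), path, progress = FALSE),
    error = function(e) {
      stop("failed to write claims to '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  invisible(path)
}
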