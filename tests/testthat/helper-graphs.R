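# graph constructors used across the suite -----------------------------

star_graph <- function(n) {
  adj <- matrix(0L, n, n)
  adj[1, 2:n] <- 1L
  adj[2:n, 1] <- 1L
  binary_graph(adj)
}

cycle_graph <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    adj[i, j] <- adj[j, i] <- 1L
  }
  binary_graph(adj)
}

complete_graph <- function(n) {
  binary_graph(matrix(1L, n, n) - diag(n))
}

path_graph <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  binary_graph(adj)
}

random_binary_graph <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  ties <- runif(n * (n - 1) / 2) < p
  adj[upper.tri(adj)] <- as.integer(ties)
  binary_graph(adj + t(adj))
}

# the documented three-patient worked example: Pa1 is visited by Ph1,
# Ph2, Ph4; Pa2 by Ph2, Ph3, Ph4; Pa3 by Ph3, Ph4
worked_example_visits <- function() {
  validate_claims(tibble::tibble(
    hospital_id = "H1",
    patient_id = rep(c("Pa1", "Pa2", "Pa3"), c(3, 3, 2)),
    physician_id = c("Ph1", "Ph2", "Ph4", "Ph2", "Ph3", "Ph4", "Ph3", "Ph4"),
    admission_id = rep(c("A1", "A2", "A3"), c(3, 3, 2)),
    service_date = as.Date("2020-01-01"),
    claim_category = "medical",
    benefit_amount = 100,
    patient_age = 70,
    procedure_code = "THR"
  ), provenance = "worked example")
}

# random visit tables for projection / outcome oracles ------------------

random_visits <- function(n_hospitals = 2, n_patients = 8, n_physicians = 6,
                          visits = 4, readmit_prob = 0.3) {
  rows <- list()
  for (h in seq_len(n_hospitals)) {
    hid <- paste0("H", h)
    for (p in seq_len(n_patients)) {
      pid <- sprintf("%s_Pa%d", hid, p)
      n_adm <- 1L + rbinom(1, 1, readmit_prob)
      phys <- sample(n_physicians, visits, replace = TRUE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        hospital_id = hid,
        patient_id = pid,
        physician_id = sprintf("%s_Ph%d", hid, phys),
        admission_id = sprintf("%s_A%d", pid,
                               sample(n_adm, visits, replace = TRUE)),
        service_date = as.Date("2020-01-01") + seq_len(visits),
        claim_category = "medical",
        benefit_amount = round(runif(visits, 50, 500), 2),
        patient_age = sample(50:90, 1),
        procedure_code = "THR"
      )
    }
  }
  validate_claims(dplyr::bind_rows(rows), provenance = "random fixture")
}
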