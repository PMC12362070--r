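## Shared fixtures built in code.

default_confounders <- c(
  "recipient_age", "donor_age", "recipient_bmi", "recipient_sex",
  "ethnicity", "recipient_blood_group", "cmv_status", "prd",
  "imd_quintile", "transplant_year")

## Small random competing-risks instance (<= 20 subjects, ties, random
## weights) for property-style estimator tests.
random_cr_instance <- function() {
  n <- sample(3:20, 1)
  list(time = round(rexp(n, 0.4), sample(0:1, 1)) + 0.25,
       event = sample(0:2, n, replace = TRUE),
       weights = sample(c(0.5, 1, 1, 2, 3), n, replace = TRUE))
}

## Registry-flow fixture mirroring the published cohort arithmetic:
## 26 862 rows of which 14 ABO-incompatible, 177 missing outcome and 47
## from an LDKT-only centre.
cohort_flow_fixture <- function() {
  n <- 26862
  tab <- data.frame(
    subject_id = sprintf("R%05d", seq_len(n)),
    treatment = rep(c(0L, 1L), length.out = n),
    time_years = rep(2.5, n),
    event = rep(c(0L, 1L, 2L), length.out = n),
    recipient_blood_group = rep("O", n),
    donor_blood_group = rep("O", n),
    centre_type = rep("mixed", n),
    stringsAsFactors = FALSE)
  tab$donor_blood_group[1:14] <- "A"            # A donor -> O recipient
  tab$time_years[15:191] <- NA                  # 177 missing outcomes
  tab$centre_type[192:238] <- "LDKT_only"       # 47 LDKT-only centre
  tab
}
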