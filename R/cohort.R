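## Cohort data model: schema-driven CSV reading with validation,
## eligibility filtering with first-match exclusion accounting, the
## zero-day time convention, and descriptive baseline summaries.

DAYS_PER_YEAR <- 365.25

#' Declare a cohort schema
#'
#' Column roles and categorical levels for [read_cohort()] validation.
#'
#' @param id,treatment,time,event names of the mandatory columns.  `time`
#'   may name either a years column or a days column (see `time_unit`).
#' @param time_unit `"years"` or `"days"`; day-level input is converted
#'   with 365.25 days/year.
#' @param covariates named list; each element is
#'   `list(type = "continuous")` or
#'   `list(type = "categorical", levels = c(...))`.
#' @return An object of class `cohort_schema`.
#' @export
cohort_schema <- function(id = "subject_id", treatment = "treatment",
                          time = "time_years", event = "event",
                          time_unit = c("years", "days"),
                          covariates = list()) {
  structure(list(id = id, treatment = treatment, time = time, event = event,
                 time_unit = match.arg(time_unit), covariates = covariates),
            class = "cohort_schema")
}

#' Schema matching the synthetic registry generator
#' @return A [cohort_schema()] covering the generator's covariate columns.
#' @export
registry_schema <- function() {
  sp <- .default_covariate_spec()
  covs <- lapply(names(sp), function(nm) {
    cs <- sp[[nm]]
    if (cs$type == "continuous") list(type = "continuous")
    else list(type = "categorical", levels = cs$levels)
  })
  names(covs) <- names(sp)
  names(covs)[names(covs) == "blood_group"] <- "recipient_blood_group"
  cohort_schema(covariates = covs)
}

#' Validate a cohort table
#'
#' Checks the invariants of the cohort data model: unique ids, positive
#' follow-up times, event codes in \{0, 1, 2\}, binary treatment, and
#' declared categorical levels covering all observed values.
#'
#' @param table a `data.frame`.
#' @param schema a [cohort_schema()].
#' @return The table, invisibly, on success; otherwise an error naming the
#'   offending rows or values.
#' @export
validate_cohort <- function(table, schema = cohort_schema()) {
  mandatory <- c(schema$id, schema$treatment, schema$time, schema$event)
  missing_cols <- setdiff(mandatory, names(table))
  if (length(missing_cols))
    stop_iptwcr("mandatory columns absent: ",
                paste(missing_cols, collapse = ", "))
  ids <- table[[schema$id]]
  if (anyDuplicated(ids))
    stop_iptwcr("duplicate subject ids: ",
                paste(utils::head(ids[duplicated(ids)], 5), collapse = ", "))
  ev <- table[[schema$event]]
  bad <- which(!is.na(ev) & !(ev %in% 0:2))
  if (length(bad))
    stop_iptwcr("invalid event codes (must be 0/1/2) in rows: ",
                paste(utils::head(bad, 5), collapse = ", "))
  tr <- table[[schema$treatment]]
  bad <- which(!is.na(tr) & !(tr %in% 0:1))
  if (length(bad))
    stop_iptwcr("treatment must be 0/1; offending rows: ",
                paste(utils::head(bad, 5), collapse = ", "))
  tt <- table[[schema$time]]
  bad <- which(!is.na(tt) & tt <= 0)
  if (length(bad))
    stop_iptwcr("non-positive follow-up times in rows: ",
                paste(utils::head(bad, 5), collapse = ", "))
  for (nm in names(schema$covariates)) {
    cs <- schema$covariates[[nm]]
    if (!nm %in% names(table)) next
    if (cs$type == "categorical") {
      obs <- unique(stats::na.omit(as.character(table[[nm]])))
      extra <- setdiff(obs, cs$levels)
      if (length(extra))
        stop_iptwcr("undeclared levels in '", nm, "': ",
                    paste(extra, collapse = ", "))
    }
  }
  invisible(table)
}

#' Read a cohort CSV
#'
#' Reads, types and validates a registry-like cohort table.  Continuous
#' cells that fail to parse are flagged missing (`NA`) and counted; the
#' count is attached as attribute `n_unparseable` and reported via a
#' message.  Categorical columns become factors with the declared levels.
#'
#' @param path CSV file with a header row.
#' @param schema a [cohort_schema()].
#' @return A validated `data.frame`; day-level times are converted to a
#'   `time_years` column.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) stop_iptwcr("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("NA", ""),
                         stringsAsFactors = FALSE, check.names = FALSE)
  n_bad <- 0L
  num_cols <- c(schema$time, schema$event, schema$treatment,
                names(Filter(function(cs) cs$type == "continuous",
                             schema$covariates)))
  for (nm in intersect(num_cols, names(raw))) {
    was_na <- is.na(raw[[nm]])
    val <- suppressWarnings(as.numeric(raw[[nm]]))
    n_bad <- n_bad + sum(is.na(val) & !was_na)
    raw[[nm]] <- val
  }
  for (nm in names(schema$covariates)) {
    cs <- schema$covariates[[nm]]
    if (cs$type == "categorical" && nm %in% names(raw)) {
      extra <- setdiff(unique(stats::na.omit(raw[[nm]])), cs$levels)
      if (length(extra))
        stop_iptwcr("undeclared levels in '", nm, "': ",
                    paste(extra, collapse = ", "))
      raw[[nm]] <- factor(raw[[nm]], levels = cs$levels)
    }
  }
  ## undeclared columns: type numerically when every non-missing cell
  ## parses, otherwise leave as character
  declared <- c(num_cols, names(schema$covariates), schema$id)
  for (nm in setdiff(names(raw), declared)) {
    if (!is.character(raw[[nm]])) next
    val <- suppressWarnings(as.numeric(raw[[nm]]))
    if (!any(is.na(val) & !is.na(raw[[nm]]))) raw[[nm]] <- val
  }
  if (schema$time_unit == "days") {
    raw$time_years <- raw[[schema$time]] / DAYS_PER_YEAR
    schema$time <- "time_years"
    schema$time_unit <- "years"
  }
  if (n_bad > 0)
    message(n_bad, " unparseable numeric cell(s) flagged missing")
  validate_cohort(raw, schema)
  attr(raw, "n_unparseable") <- n_bad
  raw
}

#' Write a cohort CSV
#'
#' Plain-text counterpart of [read_cohort()]; missing entries are written
#' as empty cells.
#'
#' @param table cohort `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

## ABO donor -> recipient compatibility (O universal donor, AB universal
## recipient); missing either group counts as potentially incompatible.
.abo_compatible <- function(donor, recipient) {
  ok <- rep(NA, length(donor))
  d <- as.character(donor); r <- as.character(recipient)
  known <- !is.na(d) & !is.na(r)
  allowed <- list(O = c("O", "A", "B", "AB"), A = c("A", "AB"),
                  B = c("B", "AB"), AB = "AB")
  ok[known] <- mapply(function(dd, rr) rr %in% allowed[[dd]],
                      d[known], r[known])
  ok
}

#' Apply eligibility filters with exclusion accounting
#'
#' Sequential first-match exclusion: a row counts toward only the first
#' rule it violates, so the per-rule counts and the eligible count always
#' sum to the input count.  Rules, in order: (1) ABO blood-group
#' incompatibility between donor and recipient, with missing groups
#' treated as potentially incompatible; (2) absent post-transplant outcome
#' (missing follow-up time or event); (3) transplant centre performing
#' living-donor transplants exclusively.
#'
#' @param table cohort `data.frame`.
#' @param rules logical toggles `abo_incompatible`, `missing_outcome`,
#'   `ldkt_only_centre`.
#' @param schema a [cohort_schema()].
#' @return List with `table` (eligible rows) and `report` (class
#'   `exclusion_report`): per-rule counts, excluded ids and `n_eligible`.
#' @export
apply_eligibility_filters <- function(table,
                                      rules = list(abo_incompatible = TRUE,
                                                   missing_outcome = TRUE,
                                                   ldkt_only_centre = TRUE),
                                      schema = cohort_schema()) {
  n_input <- nrow(table)
  excluded_by <- rep(NA_character_, n_input)

  if (isTRUE(rules$abo_incompatible)) {
    need <- c("donor_blood_group", "recipient_blood_group")
    if (!all(need %in% names(table)))
      stop_iptwcr("ABO rule requires columns: ", paste(need, collapse = ", "))
    comp <- .abo_compatible(table$donor_blood_group,
                            table$recipient_blood_group)
    hit <- is.na(comp) | !comp
    excluded_by[hit & is.na(excluded_by)] <- "blood_incompatible"
  }
  if (isTRUE(rules$missing_outcome)) {
    hit <- is.na(table[[schema$time]]) | is.na(table[[schema$event]])
    excluded_by[hit & is.na(excluded_by)] <- "missing_outcome"
  }
  if (isTRUE(rules$ldkt_only_centre)) {
    if (!"centre_type" %in% names(table))
      stop_iptwcr("centre rule requires a 'centre_type' column")
    hit <- !is.na(table$centre_type) & table$centre_type == "LDKT_only"
    excluded_by[hit & is.na(excluded_by)] <- "ldkt_only_centre"
  }

  keep <- is.na(excluded_by)
  ids <- table[[schema$id]]
  report <- structure(list(
    n_input = n_input,
    n_blood_incompatible = sum(excluded_by == "blood_incompatible",
                               na.rm = TRUE),
    n_missing_outcome = sum(excluded_by == "missing_outcome", na.rm = TRUE),
    n_ldkt_only_centre = sum(excluded_by == "ldkt_only_centre",
                             na.rm = TRUE),
    n_eligible = sum(keep),
    excluded_ids = split(ids[!keep], excluded_by[!keep])),
    class = "exclusion_report")
  if (report$n_eligible == 0)
    warning("no rows remain after eligibility filtering", call. = FALSE)
  list(table = table[keep, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Eligibility filtering (sequential first-match accounting)\n")
  cat(sprintf("  input rows:             %d\n", x$n_input))
  cat(sprintf("  ABO incompatible:       %d\n", x$n_blood_incompatible))
  cat(sprintf("  missing outcome:        %d\n", x$n_missing_outcome))
  cat(sprintf("  LDKT-only centre:       %d\n", x$n_ldkt_only_centre))
  cat(sprintf("  eligible:               %d (%.1f%%)\n", x$n_eligible,
              100 * x$n_eligible / x$n_input))
  invisible(x)
}

#' @export
as.data.frame.exclusion_report <- function(x, ...) {
  data.frame(rule = c("input", "blood_incompatible", "missing_outcome",
                      "ldkt_only_centre", "eligible"),
             n = c(x$n_input, x$n_blood_incompatible, x$n_missing_outcome,
                   x$n_ldkt_only_centre, x$n_eligible))
}

#' Apply the zero-day event-time convention
#'
#' Event times recorded as exactly 0 days are set to 0.5 days
#' (0.5/365.25 years) so those subjects enter the risk set; all other
#' times are unchanged.  Negative times are an error.
#'
#' @param table cohort `data.frame`.
#' @param time_days optional name of a day-scale column; when supplied the
#'   rule is applied on the day scale and a `time_years` column is
#'   (re)computed.  Otherwise times of exactly 0 in `time_col` (years) are
#'   replaced.
#' @param time_col years-scale time column (default `"time_years"`).
#' @return The adjusted table.
#' @export
adjust_zero_times <- function(table, time_days = NULL,
                              time_col = "time_years") {
  if (!is.null(time_days)) {
    d <- table[[time_days]]
    if (any(d < 0, na.rm = TRUE)) stop_iptwcr("negative event times")
    d[!is.na(d) & d == 0] <- 0.5
    table[[time_days]] <- d
    table[[time_col]] <- d / DAYS_PER_YEAR
  } else {
    y <- table[[time_col]]
    if (any(y < 0, na.rm = TRUE)) stop_iptwcr("negative event times")
    y[!is.na(y) & y == 0] <- 0.5 / DAYS_PER_YEAR
    table[[time_col]] <- y
  }
  table
}

#' Descriptive baseline summary by arm
#'
#' Per-variable, per-arm descriptive statistics, optionally weighted:
#' mean (SD) and median (IQR) for continuous covariates, level counts and
#' percentages for categorical ones.  Purely descriptive -- no hypothesis
#' tests.
#'
#' @param table cohort `data.frame`.
#' @param covariates character vector of covariate columns (default: all
#'   covariates in [registry_schema()] present in the table).
#' @param weights optional positive subject weights (e.g. IPTW).
#' @param treatment_col treatment column name.
#' @return A `data.frame` with columns `variable`, `level`, `arm`,
#'   `statistic`, `value`.
#' @export
summarize_baseline <- function(table, covariates = NULL, weights = NULL,
                               treatment_col = "treatment") {
  if (is.null(covariates))
    covariates <- intersect(names(registry_schema()$covariates),
                            names(table))
  if (is.null(weights)) weights <- rep(1, nrow(table))
  if (any(weights <= 0)) stop_iptwcr("weights must be positive")
  arms <- sort(unique(table[[treatment_col]]))
  rows <- list()
  add <- function(variable, level, arm, statistic, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, arm = arm,
      statistic = statistic, value = value)
  for (nm in covariates) {
    x_all <- table[[nm]]
    for (a in arms) {
      sel <- table[[treatment_col]] == a & !is.na(x_all)
      x <- x_all[sel]; w <- weights[sel]
      if (is.numeric(x_all)) {
        add(nm, NA, a, "mean", wmean(x, w))
        add(nm, NA, a, "sd", sqrt(wvar(x, w)))
        q <- wquantile(x, w, c(0.25, 0.5, 0.75))
        add(nm, NA, a, "median", q[2])
        add(nm, NA, a, "iqr_low", q[1])
        add(nm, NA, a, "iqr_high", q[3])
      } else {
        lv <- levels(factor(x_all))
        for (l in lv) {
          add(nm, l, a, "count", sum(w * (x == l)))
          add(nm, l, a, "percent", 100 * sum(w * (x == l)) / sum(w))
        }
      }
    }
  }
  do.call(rbind, rows)
}
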