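# Cohort ingestion and change-score construction.
#
# A cohort is a data frame with one row per patient:
#   patient_id, motor_adm, cognitive_adm, motor_dis, cognitive_dis, anchor
# FIM subscores are bounded by the instrument: 13 motor items rated 1-7
# (13-91 points), 5 cognitive items (5-35), total 18-126.  The anchor is
# 1 = discharged home (improved), 0 = discharged elsewhere.

#' FIM score ranges
#'
#' Minimum and maximum attainable scores for each FIM domain: motor 13--91
#' (13 items rated 1--7), cognitive 5--35 (5 items), total 18--126.
#'
#' @format A named list of length-2 numeric vectors (`min`, `max`) for
#'   `motor`, `cognitive` and `total`.
#' @export
fim_ranges <- list(
  motor     = c(min = 13, max = 91),
  cognitive = c(min = 5,  max = 35),
  total     = c(min = 18, max = 126)
)

fim_domains <- c("motor", "cognitive", "total")

canonical_cols <- c("patient_id", "motor_adm", "cognitive_adm",
                    "motor_dis", "cognitive_dis", "anchor")

#' Validate a cohort data frame
#'
#' Checks FIM score ranges and anchor coding, drops records with missing
#' values listwise (recording how many), and returns a `fim_cohort` data
#' frame.  Scores outside the instrument's range raise a validation error
#' naming the offending rows and fields.
#'
#' @param data Data frame with columns `patient_id`, `motor_adm`,
#'   `cognitive_adm`, `motor_dis`, `cognitive_dis`, `anchor`.
#' @return A data frame of class `fim_cohort`; attribute `n_excluded` counts
#'   listwise-deleted incomplete records.
#' @export
validate_cohort <- function(data) {
  missing_cols <- setdiff(setdiff(canonical_cols, "patient_id"), names(data))
  if (length(missing_cols))
    stop_config(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  if (is.null(data$patient_id))
    data$patient_id <- as.character(seq_len(nrow(data)))
  data <- data[, canonical_cols]

  score_cols <- setdiff(canonical_cols, "patient_id")
  for (col in score_cols) {
    v <- data[[col]]
    if (!is.numeric(v))
      stop_validation(paste0("column '", col, "' is not numeric"))
    bad <- which(!is.na(v) & v != round(v))
    if (length(bad))
      stop_validation(paste0("column '", col, "' has non-integer values at row(s) ",
                             paste(utils::head(bad, 5), collapse = ", ")))
  }

  complete <- stats::complete.cases(data[score_cols])
  n_excluded <- sum(!complete)
  data <- data[complete, , drop = FALSE]
  if (!nrow(data)) stop_validation("no complete records after listwise deletion")

  check_range <- function(col, rng) {
    v <- data[[col]]
    bad <- which(v < rng["min"] | v > rng["max"])
    if (length(bad))
      stop_validation(paste0(
        "field '", col, "' out of FIM range [", rng["min"], ", ", rng["max"],
        "] at row(s) ", paste(utils::head(bad, 10), collapse = ", ")))
  }
  check_range("motor_adm", fim_ranges$motor)
  check_range("motor_dis", fim_ranges$motor)
  check_range("cognitive_adm", fim_ranges$cognitive)
  check_range("cognitive_dis", fim_ranges$cognitive)

  bad_anchor <- which(!data$anchor %in% c(0, 1))
  if (length(bad_anchor))
    stop_validation(paste0("field 'anchor' must be 0 or 1; violated at row(s) ",
                           paste(utils::head(bad_anchor, 10), collapse = ", ")))

  rownames(data) <- NULL
  structure(data, n_excluded = n_excluded,
            class = c("fim_cohort", "data.frame"))
}

#' Read a patient cohort from delimited text
#'
#' Reads one patient per row with admission/discharge FIM subscores and the
#' dichotomous discharge-destination anchor (1 = home, 0 = elsewhere), then
#' validates against the FIM score ranges via [validate_cohort()].
#'
#' Item-level input is supported through `item_columns`: a list with
#' components `motor_adm`, `cognitive_adm`, `motor_dis`, `cognitive_dis`,
#' each a character vector of item column names (13 motor, 5 cognitive)
#' that are summed into the domain score.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delimiter `","` (default) or `"\t"`.
#' @param column_map Optional named character vector mapping canonical names
#'   (`motor_adm`, ...) to the file's column names.
#' @param item_columns Optional list of item-level column names (see Details).
#' @return A validated `fim_cohort` data frame.
#' @seealso [write_cohort()], [build_change_dataset()]
#' @export
read_cohort <- function(path, delimiter = ",", column_map = NULL,
                        item_columns = NULL) {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE)

  if (!is.null(item_columns)) {
    for (dom in names(item_columns)) {
      cols <- item_columns[[dom]]
      missing <- setdiff(cols, names(raw))
      if (length(missing))
        stop_config(paste0("item column(s) absent for '", dom, "': ",
                           paste(missing, collapse = ", ")))
      raw[[dom]] <- rowSums(raw[, cols, drop = FALSE])
    }
  }

  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), canonical_cols)
    if (length(unknown))
      stop_config(paste0("column_map has unknown canonical name(s): ",
                         paste(unknown, collapse = ", ")))
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop_config(paste0("mapped column '", src, "' not found in file"))
      raw[[canon]] <- raw[[src]]
    }
  }
  validate_cohort(raw)
}

#' Write a cohort back to delimited text
#'
#' Re-emits a validated cohort in the canonical ingestion schema, for audit
#' or as input to another run.
#'
#' @param cohort A `fim_cohort` (or compatible data frame).
#' @param path Output file path.
#' @param delimiter Field separator, `","` by default.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delimiter = ",") {
  utils::write.table(as.data.frame(cohort)[, canonical_cols], path,
                     sep = delimiter, row.names = FALSE, quote = FALSE)
  invisible(path)
}

domain_score <- function(cohort, domain, when = c("adm", "dis")) {
  when <- match.arg(when)
  switch(domain,
    motor     = cohort[[paste0("motor_", when)]],
    cognitive = cohort[[paste0("cognitive_", when)]],
    total     = cohort[[paste0("motor_", when)]] + cohort[[paste0("cognitive_", when)]]
  )
}

#' Construct a change dataset
#'
#' Pairs each patient's change score (discharge minus admission) in one FIM
#' domain with the dichotomous anchor.  The total score is formed as
#' motor + cognitive at each timepoint before differencing.  This is the
#' unit all MIC estimators consume.
#'
#' @param records A `fim_cohort` data frame (see [validate_cohort()]).
#' @param domain `"motor"`, `"cognitive"` or `"total"`.
#' @return An object of class `change_data`: list with `domain`, `change`,
#'   `anchor`, `n`.
#' @examples
#' coh <- validate_cohort(data.frame(
#'   motor_adm = c(39, 50), cognitive_adm = c(20, 19),
#'   motor_dis = c(60, 70), cognitive_dis = c(25, 24), anchor = c(1, 0)))
#' build_change_dataset(coh, "motor")$change
#' @export
build_change_dataset <- function(records, domain = fim_domains) {
  domain <- match.arg(domain)
  if (!nrow(records)) stop_validation("empty cohort")
  change_data(
    change = domain_score(records, domain, "dis") -
             domain_score(records, domain, "adm"),
    anchor = records$anchor,
    domain = domain
  )
}

#' Create a change dataset from raw vectors
#'
#' Low-level constructor validating lengths, anchor coding and the domain's
#' attainable change range (motor -78..78, cognitive -30..30,
#' total -108..108).
#'
#' @param change Numeric vector of change scores (discharge - admission).
#' @param anchor Parallel 0/1 vector (1 = improved / discharged home).
#' @param domain FIM domain the changes belong to.
#' @param check_range Enforce the attainable change range (disable for
#'   continuous synthetic scores that have not been clamped).
#' @return An object of class `change_data`.
#' @export
change_data <- function(change, anchor, domain = fim_domains,
                        check_range = TRUE) {
  domain <- match.arg(domain)
  if (length(change) != length(anchor))
    stop_validation("change and anchor differ in length")
  if (!length(change)) stop_validation("empty change dataset")
  if (anyNA(change) || anyNA(anchor))
    stop_validation("change/anchor contain missing values")
  if (!all(anchor %in% c(0, 1)))
    stop_validation("anchor values must be 0 or 1")
  if (check_range) {
    rng <- fim_ranges[[domain]]
    span <- unname(rng["max"] - rng["min"])
    if (any(abs(change) > span))
      stop_validation(paste0(domain, " change outside [-", span, ", ", span, "]"))
  }
  structure(list(domain = domain, change = as.numeric(change),
                 anchor = as.integer(anchor), n = length(change)),
            class = "change_data")
}

#' @export
print.change_data <- function(x, ...) {
  cat("FIM change dataset (", x$domain, "): n = ", x$n,
      ", improved = ", sum(x$anchor), " (",
      fmt1(100 * mean(x$anchor)), "%)\n", sep = "")
  cat("  change: mean ", fmt1(mean(x$change)), " (SD ",
      fmt1(stats::sd(x$change)), "), range ",
      min(x$change), "..", max(x$change), "\n", sep = "")
  invisible(x)
}
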