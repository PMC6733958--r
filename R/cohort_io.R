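# Cohort ingest: CSV read/write, medal split, node-variable selection.

# CSV schema <-> internal column names.  `edition` and `rank` are mandatory
# identifiers; `race_time_s`, `velocity_ms` are optional outcome variables;
# `birth_year` is accepted and ignored.
COHORT_SCHEMA <- c(
  edition = "edition", rank = "rank", age = "age", weight_kg = "weight",
  height_cm = "height", bmi = "bmi", olympic_medals = "olympic_medals",
  reaction_time_s = "reaction_time", race_time_s = "race_time",
  velocity_ms = "velocity"
)
MANDATORY_COLUMNS <- c("edition", "rank", "age", "weight_kg", "height_cm",
                       "bmi", "olympic_medals", "reaction_time_s")

#' Default node variables
#'
#' The six variables used as network nodes, in canonical order: age, weight,
#' height, BMI, number of Olympic medals, reaction time.  Race time and
#' velocity are deliberately excluded — they directly determine the finish
#' order and would bias the networks.
#' @return Character vector of length 6.
#' @export
node_variables <- function() {
  c("age", "weight", "height", "bmi", "olympic_medals", "reaction_time")
}

#' Write a cohort to CSV
#'
#' @param cohort Data frame of athlete records (internal column names, as
#'   produced by [synthesize_cohorts()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(edition = cohort$edition, rank = cohort$rank)
  for (col in setdiff(names(COHORT_SCHEMA), c("edition", "rank"))) {
    internal <- COHORT_SCHEMA[[col]]
    if (internal %in% names(cohort)) out[[col]] <- cohort[[internal]]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an athlete cohort from CSV
#'
#' Header matching is case-insensitive and order-free.  Mandatory columns:
#' `edition, rank, age, weight_kg, height_cm, bmi, olympic_medals,
#' reaction_time_s`; optional: `race_time_s, velocity_ms`; `birth_year` is
#' tolerated and dropped.  Validation: ranks are integers in 1..8, unique
#' within an edition; height, weight and reaction time strictly positive;
#' when both race time and velocity are present they must agree with a 50 m
#' course (`velocity = 50 / race_time`) within 1%.
#'
#' @param path CSV file path.
#' @return Data frame of athlete records with internal column names.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  raw <- raw[, names(raw) != "birth_year", drop = FALSE]
  missing <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  known <- intersect(names(COHORT_SCHEMA), names(raw))
  out <- data.frame(edition = raw$edition, stringsAsFactors = FALSE)
  for (col in setdiff(known, "edition")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad)) {
      stop(sprintf("malformed numeric value in column '%s', row %d: '%s'",
                   col, bad[1], raw[[col]][bad[1]]))
    }
    out[[COHORT_SCHEMA[[col]]]] <- vals
  }
  if (any(out$rank != round(out$rank) | out$rank < 1 | out$rank > 8)) {
    bad <- which(out$rank != round(out$rank) | out$rank < 1 | out$rank > 8)[1]
    stop(sprintf("rank outside 1..8 in row %d (rank = %s)", bad, out$rank[bad]))
  }
  out$rank <- as.integer(out$rank)
  dup <- duplicated(out[, c("edition", "rank")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate (edition, rank) pair in row %d: (%s, %d)",
                 i, out$edition[i], out$rank[i]))
  }
  for (v in c("height", "weight", "reaction_time")) {
    if (any(out[[v]] <= 0, na.rm = TRUE)) {
      stop(sprintf("%s must be strictly positive (row %d)",
                   v, which(out[[v]] <= 0)[1]))
    }
  }
  if (all(c("race_time", "velocity") %in% names(out))) {
    both <- !is.na(out$race_time) & !is.na(out$velocity)
    rel <- abs(out$velocity[both] - 50 / out$race_time[both]) /
      (50 / out$race_time[both])
    if (any(rel > 0.01)) {
      stop(sprintf("velocity inconsistent with 50 m race time in row %d (> 1%%)",
                   which(both)[which(rel > 0.01)[1]]))
    }
  }
  out$group <- ifelse(out$rank <= 3, "medalist", "non_medalist")
  out
}

#' Split one edition's finalists into medalist and non-medalist groups
#'
#' @param records Data frame with exactly 8 records of a single edition
#'   carrying distinct finish ranks 1..8.
#' @return A named list of two `group_table` objects: `medalist` (ranks 1-3)
#'   and `non_medalist` (ranks 4-8).
#' @export
split_by_medal <- function(records) {
  stopifnot(is.data.frame(records), "rank" %in% names(records))
  edition <- unique(records$edition)
  if (length(edition) != 1L) {
    stop("split_by_medal expects records of a single edition, got: ",
         paste(edition, collapse = ", "))
  }
  if (nrow(records) != 8L) {
    stop(sprintf("edition %s has %d records; an Olympic final has exactly 8",
                 edition, nrow(records)))
  }
  if (!setequal(records$rank, 1:8) || anyDuplicated(records$rank)) {
    stop(sprintf("edition %s must carry distinct ranks 1..8 (got: %s)",
                 edition, paste(sort(records$rank), collapse = ",")))
  }
  make_group <- function(rows, label) {
    structure(
      list(edition_label = edition, group_label = label,
           records = rows[order(rows$rank), , drop = FALSE],
           variables = node_variables()),
      class = "group_table"
    )
  }
  list(
    medalist = make_group(records[records$rank <= 3, , drop = FALSE], "medalist"),
    non_medalist = make_group(records[records$rank >= 4, , drop = FALSE], "non_medalist")
  )
}

#' @export
print.group_table <- function(x, ...) {
  cat(sprintf("<group_table> %s / %s: %d athletes, %d node variables\n",
              x$edition_label, x$group_label, nrow(x$records),
              length(x$variables)))
  invisible(x)
}

#' Extract the node-variable matrix from a group
#'
#' @param group A `group_table` from [split_by_medal()], or a plain data
#'   frame of athlete records.
#' @param variables Variables to extract, in the requested column order
#'   (default [node_variables()]).
#' @param allow_outcome_variables If `FALSE` (default), requesting
#'   `race_time` or `velocity` is an error: these directly predict victory
#'   and would bias the network (they are kept as columns, not nodes).
#' @return Numeric matrix, athletes in rows, variables in columns in exactly
#'   the requested order.
#' @export
select_node_variables <- function(group, variables = node_variables(),
                                  allow_outcome_variables = FALSE) {
  records <- if (inherits(group, "group_table")) group$records else group
  stopifnot(is.data.frame(records))
  outcome <- intersect(variables, c("race_time", "velocity"))
  if (length(outcome) && !allow_outcome_variables) {
    stop("variables ", paste(outcome, collapse = ", "),
         " directly predict victory and are excluded as nodes to avoid bias; ",
         "set allow_outcome_variables = TRUE to override")
  }
  absent <- setdiff(variables, names(records))
  if (length(absent)) {
    stop("requested variable(s) absent from records: ",
         paste(absent, collapse = ", "))
  }
  m <- as.matrix(records[, variables, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}
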