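#' Construct a dietary recall survey object
#'
#' A \code{diet_survey} bundles the three tables every analysis stage
#' transforms: participants (body weight, analysis weight), consumption
#' records (participant x recall day x food x grams) and the food composition
#' table. Each included participant must have exactly two declared recall
#' days; a day with nothing consumed is legal and is represented by declaring
#' the day with zero records, which keeps "no data" distinct from "zero
#' intake". Participants with unknown body weight are retained in the object
#' but flagged \code{excluded} and barred from every analysis operation.
#'
#' @param participants data.frame with columns \code{participant_id},
#'   \code{body_weight_kg} (NA = unknown), \code{analysis_weight} (> 0 survey
#'   weight).
#' @param records data.frame with columns \code{participant_id},
#'   \code{day_index} (1 or 2), \code{food_code}, \code{grams} (>= 0).
#' @param composition a \code{\link{food_composition}}
#' @param days optional data.frame \code{participant_id}, \code{day_index}
#'   declaring which recall days exist. Defaults to days 1 and 2 for every
#'   participant.
#' @return An object of class \code{diet_survey}.
#' @export
diet_survey <- function(participants, records, composition, days = NULL) {
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(inherits(composition, "food_composition"))

  req_p <- c("participant_id", "body_weight_kg", "analysis_weight")
  if (!all(req_p %in% names(participants))) {
    stop("participants table needs columns: ", paste(req_p, collapse = ", "),
         call. = FALSE)
  }
  participants$participant_id <- as.character(participants$participant_id)
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicate participant_id: ",
         paste(unique(participants$participant_id[
           duplicated(participants$participant_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(participants$analysis_weight) |
          participants$analysis_weight <= 0)) {
    stop("analysis_weight must be positive for every participant",
         call. = FALSE)
  }
  if (any(!is.na(participants$body_weight_kg) &
          participants$body_weight_kg <= 0)) {
    stop("body_weight_kg must be positive when known", call. = FALSE)
  }
  participants$excluded <- is.na(participants$body_weight_kg)

  req_r <- c("participant_id", "day_index", "food_code", "grams")
  if (!all(req_r %in% names(records))) {
    stop("records table needs columns: ", paste(req_r, collapse = ", "),
         call. = FALSE)
  }
  records$participant_id <- as.character(records$participant_id)
  records$food_code <- as.character(records$food_code)
  if (!all(records$day_index %in% c(1L, 2L))) {
    stop("day_index must be 1 or 2", call. = FALSE)
  }
  records$day_index <- as.integer(records$day_index)
  if (any(is.na(records$grams) | records$grams < 0)) {
    stop("grams must be non-negative", call. = FALSE)
  }
  unknown_p <- setdiff(records$participant_id, participants$participant_id)
  if (length(unknown_p) > 0L) {
    stop("records reference unknown participant(s): ",
         paste(unknown_p, collapse = ", "), call. = FALSE)
  }
  unknown_f <- setdiff(records$food_code, composition$food_code)
  if (length(unknown_f) > 0L) {
    stop("records reference unknown food code(s): ",
         paste(unknown_f, collapse = ", "), call. = FALSE)
  }

  if (is.null(days)) {
    days <- data.frame(
      participant_id = rep(participants$participant_id, each = 2L),
      day_index = rep(1:2, times = nrow(participants)),
      stringsAsFactors = FALSE)
  }
  days <- as.data.frame(days, stringsAsFactors = FALSE)
  days$participant_id <- as.character(days$participant_id)
  days$day_index <- as.integer(days$day_index)
  n_days <- table(days$participant_id)
  incl <- participants$participant_id[!participants$excluded]
  bad <- incl[!(incl %in% names(n_days)) | n_days[incl] != 2L]
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0L) {
    stop("included participant(s) without exactly 2 declared recall days: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # every record's day must be declared
  key_r <- paste(records$participant_id, records$day_index)
  key_d <- paste(days$participant_id, days$day_index)
  if (!all(key_r %in% key_d)) {
    stop("consumption records on undeclared recall days", call. = FALSE)
  }

  structure(list(participants = participants, records = records,
                 composition = composition, days = days),
            class = "diet_survey")
}

#' @export
print.diet_survey <- function(x, ...) {
  n_exc <- sum(x$participants$excluded)
  cat("<diet_survey> ", nrow(x$participants), " participants (",
      n_exc, " excluded: unknown body weight), ",
      nrow(x$records), " consumption records, ",
      nrow(x$composition), " foods in ",
      length(unique(x$composition$group)), " groups\n", sep = "")
  invisible(x)
}

included_ids <- function(survey) {
  survey$participants$participant_id[!survey$participants$excluded]
}

participant_row <- function(survey, participant_id) {
  i <- match(participant_id, survey$participants$participant_id)
  if (is.na(i)) stop("unknown participant: ", participant_id, call. = FALSE)
  if (survey$participants$excluded[i]) {
    stop("participant ", participant_id,
         " is excluded (unknown body weight)", call. = FALSE)
  }
  survey$participants[i, ]
}

assert_day_declared <- function(survey, participant_id, day_index) {
  ok <- any(survey$days$participant_id == participant_id &
            survey$days$day_index == day_index)
  if (!ok) {
    stop("recall day ", day_index, " not declared for participant ",
         participant_id, call. = FALSE)
  }
}

#' Read a survey from its three CSV files
#'
#' @param composition_path composition CSV (see \code{\link{read_composition}})
#' @param participants_path CSV with \code{participant_id},
#'   \code{body_weight_kg} (empty = missing), \code{analysis_weight}
#' @param records_path CSV with \code{participant_id}, \code{day_index},
#'   \code{food_code}, \code{grams}
#' @param days_path optional CSV with \code{participant_id}, \code{day_index};
#'   when absent, days 1 and 2 are assumed declared for everyone
#' @param quiet suppress the row-count message
#' @return a validated \code{\link{diet_survey}}
#' @export
read_survey <- function(composition_path, participants_path, records_path,
                        days_path = NULL, quiet = FALSE) {
  composition <- read_composition(composition_path)
  participants <- utils::read.csv(participants_path, stringsAsFactors = FALSE,
                                  fileEncoding = "UTF-8")
  records <- utils::read.csv(records_path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  days <- if (!is.null(days_path)) {
    utils::read.csv(days_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  sv <- diet_survey(participants, records, composition, days = days)
  if (!quiet) {
    message("read survey: ", nrow(sv$participants), " participants (",
            sum(sv$participants$excluded), " excluded), ",
            nrow(sv$records), " records, ", nrow(composition), " foods")
  }
  sv
}

#' Write a survey to CSV files
#'
#' Inverse of \code{\link{read_survey}}: writes composition, participants,
#' records and declared-days CSVs into \code{dir}. Numeric fields are written
#' at full precision (15 significant digits) so a read/write round trip
#' reproduces every value.
#'
#' @param survey a \code{diet_survey}
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of file paths written
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(composition = file.path(dir, "composition.csv"),
             participants = file.path(dir, "participants.csv"),
             records = file.path(dir, "records.csv"),
             days = file.path(dir, "days.csv"))
  write_composition(survey$composition, paths["composition"])
  p <- survey$participants[, c("participant_id", "body_weight_kg",
                               "analysis_weight")]
  utils::write.csv(format_full(p), paths["participants"], row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  utils::write.csv(format_full(survey$records), paths["records"],
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  utils::write.csv(survey$days, paths["days"], row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(paths)
}

#' Protein intake per kg body weight on one recall day
#'
#' Sums, over the participant's consumption records on that day, grams
#' consumed times protein per 100 g divided by 100, then divides by body
#' weight. A declared day with no records is a true zero intake.
#'
#' @param survey a \code{diet_survey}
#' @param participant_id participant identifier (must not be excluded)
#' @param day_index 1 or 2 (must be declared)
#' @return protein intake in g/kg body weight/day
#' @export
daily_protein_per_kg <- function(survey, participant_id, day_index) {
  p <- participant_row(survey, participant_id)
  assert_day_declared(survey, participant_id, day_index)
  r <- survey$records[survey$records$participant_id == participant_id &
                      survey$records$day_index == day_index, ]
  if (nrow(r) == 0L) return(0)
  prot <- nutrient_per_100g(survey$composition, r$food_code, "protein_g")
  sum(r$grams * prot / 100) / p$body_weight_kg
}

#' Mean protein intake per kg body weight over the two recall days
#'
#' @inheritParams daily_protein_per_kg
#' @return arithmetic mean of the two daily values, g/kg BW/d
#' @export
mean_protein_per_kg <- function(survey, participant_id) {
  (daily_protein_per_kg(survey, participant_id, 1L) +
   daily_protein_per_kg(survey, participant_id, 2L)) / 2
}

#' Total intake of one nutrient on one recall day
#'
#' @inheritParams daily_protein_per_kg
#' @param nutrient nutrient name present in the composition table
#' @return total intake for that day, in the nutrient's units
#' @export
total_nutrient_per_day <- function(survey, participant_id, day_index,
                                   nutrient) {
  participant_row(survey, participant_id)
  assert_day_declared(survey, participant_id, day_index)
  r <- survey$records[survey$records$participant_id == participant_id &
                      survey$records$day_index == day_index, ]
  if (!nutrient %in% nutrients(survey$composition)) {
    stop("nutrient not present in composition table: ", nutrient,
         call. = FALSE)
  }
  if (nrow(r) == 0L) return(0)
  amt <- nutrient_per_100g(survey$composition, r$food_code, nutrient)
  sum(r$grams * amt / 100)
}

# Render numeric columns with 17 significant digits (lossless for doubles);
# NA becomes the empty field the CSV dialect uses for "missing".
format_full <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- sprintf("%.17g", df[[nm]])
      v[is.na(df[[nm]])] <- ""
      df[[nm]] <- v
    }
  }
  df
}

# Vectorised per-participant daily protein in g/day and g/kg/day; internal
# workhorse used by the engine and the pipeline (avoids per-person subsetting).
daily_intake_table <- function(survey, nutrient = "protein_g") {
  ids <- included_ids(survey)
  r <- survey$records[survey$records$participant_id %in% ids, ]
  amt <- if (nrow(r)) {
    nutrient_per_100g(survey$composition, r$food_code, nutrient)
  } else numeric(0)
  contrib <- r$grams * amt / 100
  key <- interaction(factor(r$participant_id, levels = ids),
                     factor(r$day_index, levels = 1:2), drop = FALSE)
  sums <- tapply(contrib, key, sum, default = 0)
  out <- data.frame(
    participant_id = rep(ids, times = 2L),
    day_index = rep(1:2, each = length(ids)),
    value = as.numeric(sums),
    stringsAsFactors = FALSE)
  out[order(out$participant_id, out$day_index), , drop = FALSE]
}

# Per-participant 2-day mean of a nutrient in units/day, for included
# participants, with body weight and analysis weight attached.
participant_means <- function(survey, nutrient = "protein_g") {
  tab <- daily_intake_table(survey, nutrient)
  m <- tapply(tab$value, tab$participant_id, mean)
  p <- survey$participants[!survey$participants$excluded, ]
  data.frame(participant_id = p$participant_id,
             mean_per_day = as.numeric(m[p$participant_id]),
             body_weight_kg = p$body_weight_kg,
             analysis_weight = p$analysis_weight,
             stringsAsFactors = FALSE)
}
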