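#' Define a food-replacement scenario
#'
#' A scenario names the food groups to treat and, for each group, the single
#' alternative food every below-P75 item in that group is replaced by. The
#' alternative must belong to the group it serves and its protein content must
#' strictly exceed the group's 75th-percentile protein threshold; that
#' invariant is checked against a composition table when one is supplied and
#' is always re-checked by \code{\link{apply_scenario}} on the P75 basis in
#' force there.
#'
#' @param scenario_id short text identifier
#' @param replacements data.frame with columns \code{group},
#'   \code{alternative_food_code}; order is preserved and groups must be
#'   unique within the scenario
#' @param eligibility_cutoff protein intake cut-off in g/kg body weight/day
#'   below which (strictly) a participant's foods are replaced; default 1.0
#' @param composition optional \code{food_composition} to validate against
#' @return object of class \code{scenario_definition}
#' @export
scenario_definition <- function(scenario_id, replacements,
                                eligibility_cutoff = 1.0,
                                composition = NULL) {
  replacements <- as.data.frame(replacements, stringsAsFactors = FALSE)
  if (!all(c("group", "alternative_food_code") %in% names(replacements))) {
    stop("replacements needs columns group, alternative_food_code",
         call. = FALSE)
  }
  replacements$group <- as.character(replacements$group)
  replacements$alternative_food_code <-
    as.character(replacements$alternative_food_code)
  if (anyDuplicated(replacements$group)) {
    stop("groups must be unique within a scenario", call. = FALSE)
  }
  rownames(replacements) <- NULL
  stopifnot(is.numeric(eligibility_cutoff), eligibility_cutoff > 0)
  sc <- structure(list(scenario_id = as.character(scenario_id),
                       replacements = replacements,
                       eligibility_cutoff = eligibility_cutoff),
                  class = "scenario_definition")
  if (!is.null(composition)) validate_scenario(sc, composition)
  sc
}

#' Validate a scenario against a composition table
#'
#' Checks that every scenario group exists, every alternative food exists and
#' belongs to the group it serves, and every alternative's protein content
#' strictly exceeds that group's P75 threshold on the requested basis.
#'
#' @inheritParams compute_p75
#' @param scenario a \code{scenario_definition}
#' @return invisibly, a data.frame of the per-group P75 thresholds used
#' @export
validate_scenario <- function(scenario, composition, basis = "items",
                              survey = NULL) {
  rep <- scenario$replacements
  missing_groups <- setdiff(rep$group, composition$group)
  if (length(missing_groups) > 0L) {
    stop("scenario '", scenario$scenario_id,
         "' references group(s) absent from composition: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  idx <- match(rep$alternative_food_code, composition$food_code)
  if (anyNA(idx)) {
    stop("alternative food(s) not in composition: ",
         paste(rep$alternative_food_code[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  wrong <- composition$group[idx] != rep$group
  if (any(wrong)) {
    stop("alternative food(s) not in the group they serve: ",
         paste(rep$alternative_food_code[wrong], collapse = ", "),
         call. = FALSE)
  }
  thr <- do.call(rbind, lapply(rep$group, function(g) {
    t <- compute_p75(composition, g, basis = basis, survey = survey)
    data.frame(group = g, p75_protein_per_100g = t$p75_protein_per_100g,
               n_items = t$n_items, stringsAsFactors = FALSE)
  }))
  alt_prot <- composition$protein_g[idx]
  low <- alt_prot <= thr$p75_protein_per_100g
  if (any(low)) {
    stop("alternative food(s) with protein content not strictly above the ",
         "group P75: ", paste(rep$alternative_food_code[low], collapse = ", "),
         call. = FALSE)
  }
  invisible(thr)
}

#' @export
print.scenario_definition <- function(x, ...) {
  cat("<scenario_definition> '", x$scenario_id, "': ",
      nrow(x$replacements), " group(s), eligibility cutoff ",
      x$eligibility_cutoff, " g/kg BW/d\n", sep = "")
  for (i in seq_len(nrow(x$replacements))) {
    cat("  ", x$replacements$group[i], " -> ",
        x$replacements$alternative_food_code[i], "\n", sep = "")
  }
  invisible(x)
}

#' Read / write a scenario definition (YAML or JSON)
#'
#' The file holds \code{scenario_id}, \code{eligibility_cutoff} and a list of
#' \code{\{group, alternative_food_code\}} pairs under \code{replacements}.
#' The format is chosen by file extension (\code{.yaml}/\code{.yml} vs
#' \code{.json}).
#'
#' @param path file path
#' @return \code{read_scenario}: a \code{scenario_definition}
#' @export
read_scenario <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  reps <- do.call(rbind, lapply(x$replacements, function(r) {
    data.frame(group = r$group,
               alternative_food_code = r$alternative_food_code,
               stringsAsFactors = FALSE)
  }))
  cutoff <- if (is.null(x$eligibility_cutoff)) 1.0 else x$eligibility_cutoff
  scenario_definition(x$scenario_id, reps, eligibility_cutoff = cutoff)
}

#' @rdname read_scenario
#' @param scenario a \code{scenario_definition}
#' @export
write_scenario <- function(scenario, path) {
  x <- list(scenario_id = scenario$scenario_id,
            eligibility_cutoff = scenario$eligibility_cutoff,
            replacements = lapply(seq_len(nrow(scenario$replacements)),
              function(i) list(
                group = scenario$replacements$group[i],
                alternative_food_code =
                  scenario$replacements$alternative_food_code[i])))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
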