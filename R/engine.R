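#' Participants eligible for food replacement
#'
#' Eligibility restricts replacements to participants whose 2-day mean
#' protein intake is strictly below the cut-off; participants at or above it
#' are left untouched, and excluded participants (unknown body weight) are
#' never eligible.
#'
#' @param survey a \code{diet_survey}
#' @param cutoff g protein/kg body weight/day; default 1.0
#' @return character vector of eligible participant ids
#' @export
eligible_participants <- function(survey, cutoff = 1.0) {
  pm <- participant_means(survey, "protein_g")
  perkg <- pm$mean_per_day / pm$body_weight_kg
  pm$participant_id[perkg < cutoff]
}

#' Apply a replacement scenario to a survey
#'
#' For every consumption record of an eligible participant whose food belongs
#' to a scenario group and whose protein content per 100 g is strictly below
#' that group's P75 threshold, the food code is rewritten to the group's
#' alternative food. Grams are unchanged (substitution is on the basis of
#' weight consumed), so all nutrients of the record now come from the
#' alternative's composition row. Eligibility is determined once, on the
#' original survey, and never re-evaluated during replacement; replacements
#' never cascade. Every substitution is logged with its protein delta.
#'
#' @param survey a \code{diet_survey}
#' @param scenario a \code{scenario_definition}
#' @param p75_basis \code{"items"} (all composition-table items, default) or
#'   \code{"consumption"} (distinct consumed items); see \code{\link{compute_p75}}
#' @return object of class \code{scenario_result}: list with
#'   \code{modified_survey}, \code{log} (one row per substitution:
#'   participant_id, day_index, group, from_food_code, to_food_code, grams,
#'   protein_delta_g), \code{scenario}, \code{thresholds},
#'   \code{eligible_ids}.
#' @export
apply_scenario <- function(survey, scenario, p75_basis = "items") {
  thr <- validate_scenario(scenario, survey$composition, basis = p75_basis,
                           survey = survey)
  eligible <- eligible_participants(survey, scenario$eligibility_cutoff)

  comp <- survey$composition
  rec <- survey$records
  grp <- comp$group[match(rec$food_code, comp$food_code)]
  prot <- comp$protein_g[match(rec$food_code, comp$food_code)]
  ti <- match(grp, thr$group)          # NA when group not in scenario
  p75 <- thr$p75_protein_per_100g[ti]
  # zero-gram records represent nothing consumed and are never substituted,
  # which keeps every log entry's protein delta strictly positive
  hit <- rec$participant_id %in% eligible & !is.na(ti) & prot < p75 &
    rec$grams > 0

  alt_code <- scenario$replacements$alternative_food_code[
    match(grp[hit], scenario$replacements$group)]
  alt_prot <- comp$protein_g[match(alt_code, comp$food_code)]

  log <- data.frame(
    participant_id = rec$participant_id[hit],
    day_index = rec$day_index[hit],
    group = grp[hit],
    from_food_code = rec$food_code[hit],
    to_food_code = alt_code,
    grams = rec$grams[hit],
    protein_delta_g = rec$grams[hit] * (alt_prot - prot[hit]) / 100,
    stringsAsFactors = FALSE)

  new_rec <- rec
  new_rec$food_code[hit] <- alt_code
  modified <- diet_survey(
    survey$participants[, c("participant_id", "body_weight_kg",
                            "analysis_weight")],
    new_rec, comp, days = survey$days)

  structure(list(modified_survey = modified, log = log, scenario = scenario,
                 thresholds = thr, eligible_ids = eligible),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> scenario '", x$scenario$scenario_id, "': ",
      nrow(x$log), " replacements across ",
      length(unique(x$log$group)), " group(s), ",
      length(x$eligible_ids), " eligible participants\n", sep = "")
  invisible(x)
}

#' Count replacements per food group
#'
#' @param result a \code{scenario_result}
#' @return list with \code{per_group} (named integer vector over the
#'   scenario's groups, in scenario order) and \code{total}
#' @export
count_replacements <- function(result) {
  groups <- result$scenario$replacements$group
  counts <- vapply(groups, function(g) sum(result$log$group == g), integer(1))
  list(per_group = counts, total = nrow(result$log))
}

#' Rank food groups by their contribution to the protein increase
#'
#' For each scenario group, the population mean increase in daily protein
#' intake (g/d) attributable to replacements in that group: the per-
#' participant sum of logged protein deltas for the group, divided by 2 (the
#' two recall days), averaged with analysis weights over all non-excluded
#' participants (participants without replacements contribute zero). Sorted
#' descending; ties broken by group label.
#'
#' @param result a \code{scenario_result}
#' @return data.frame \code{group}, \code{mean_protein_increase_g_d},
#'   sorted by decreasing contribution
#' @export
group_contributions <- function(result) {
  sv <- result$modified_survey
  p <- sv$participants[!sv$participants$excluded, ]
  w <- p$analysis_weight / sum(p$analysis_weight)
  groups <- result$scenario$replacements$group
  contr <- vapply(groups, function(g) {
    e <- result$log[result$log$group == g, ]
    per_person <- tapply(e$protein_delta_g, factor(e$participant_id,
                         levels = p$participant_id), sum, default = 0)
    sum(w * as.numeric(per_person)) / 2
  }, numeric(1))
  out <- data.frame(group = groups, mean_protein_increase_g_d = contr,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$mean_protein_increase_g_d, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive a combined scenario from two scenario results
#'
#' Builds a new scenario from the food groups where replacement raised
#' protein intake most: the top \code{k} groups of the second scenario's
#' contribution ranking (keeping that scenario's alternatives), then walking
#' the first scenario's ranking from the top, skipping any group already
#' selected, until \code{k} further groups are added (with the first
#' scenario's alternatives). The result has exactly \code{2k} groups.
#'
#' @param result1,result2 \code{scenario_result}s computed on the same
#'   original survey
#' @param k number of groups taken from each ranking; default 3
#' @param scenario_id id for the derived scenario
#' @return a \code{scenario_definition} with \code{2k} replacement rows
#' @export
derive_combined_scenario <- function(result1, result2, k = 3,
                                     scenario_id = "combined") {
  r1 <- group_contributions(result1)
  r2 <- group_contributions(result2)
  if (length(unique(c(r1$group, r2$group))) < 2L * k) {
    stop("fewer than ", 2L * k, " distinct groups available", call. = FALSE)
  }
  alt_of <- function(result, g) {
    rep <- result$scenario$replacements
    rep$alternative_food_code[match(g, rep$group)]
  }
  if (nrow(r2) < k) stop("second scenario has fewer than k ranked groups",
                         call. = FALSE)
  take2 <- r2$group[seq_len(k)]
  take1 <- character(0)
  for (g in r1$group) {
    if (length(take1) == k) break
    if (!(g %in% take2)) take1 <- c(take1, g)
  }
  if (length(take1) < k) {
    stop("first scenario's ranking exhausted before ", k,
         " additional groups were found", call. = FALSE)
  }
  reps <- data.frame(
    group = c(take2, take1),
    alternative_food_code = c(alt_of(result2, take2), alt_of(result1, take1)),
    stringsAsFactors = FALSE)
  scenario_definition(scenario_id, reps,
                      eligibility_cutoff =
                        result2$scenario$eligibility_cutoff)
}

#' Survey-weighted mean and sd of nutrient intakes
#'
#' Per non-excluded participant, the 2-day average daily intake of each
#' requested nutrient; then the analysis-weighted mean and weighted standard
#' deviation across participants (weights normalised to sum 1; sd uses the
#' weighted second central moment).
#'
#' @param survey a \code{diet_survey}
#' @param nutrients_wanted character vector of nutrient names; default all
#'   nutrients in the composition table
#' @return data.frame \code{nutrient}, \code{weighted_mean}, \code{weighted_sd}
#'   (per day)
#' @export
mean_nutrient_intakes <- function(survey,
                                  nutrients_wanted = nutrients(survey$composition)) {
  out <- lapply(nutrients_wanted, function(nm) {
    pm <- participant_means(survey, nm)
    w <- pm$analysis_weight / sum(pm$analysis_weight)
    m <- sum(w * pm$mean_per_day)
    s <- sqrt(sum(w * (pm$mean_per_day - m)^2))
    data.frame(nutrient = nm, weighted_mean = m, weighted_sd = s,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Weighted fraction of participants below an intake cut-off
#'
#' Observed (2-day mean) counterpart of \code{\link{fraction_below}}: the
#' analysis-weighted share of non-excluded participants whose mean protein
#' intake per kg body weight is strictly below the cut-off.
#'
#' @inheritParams eligible_participants
#' @return weighted proportion in [0, 1]
#' @export
observed_fraction_below <- function(survey, cutoff = 1.0) {
  pm <- participant_means(survey, "protein_g")
  w <- pm$analysis_weight / sum(pm$analysis_weight)
  sum(w * as.numeric(pm$mean_per_day / pm$body_weight_kg < cutoff))
}
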