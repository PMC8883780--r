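#' Generate a synthetic survey and write its files
#'
#' Wraps \code{\link{generate_survey}} and \code{\link{write_survey}}:
#' generates the survey, writes the three survey CSVs plus the declared-days
#' CSV into \code{dir}, and writes a \code{manifest.json} recording the seed,
#' row counts, the calibration scalar and an MD5 checksum per file, so two
#' runs with the same configuration can be compared file by file.
#'
#' @param config a \code{\link{generator_config}}
#' @param dir output directory
#' @return invisibly, the manifest as a list
#' @export
simulate_survey_files <- function(config, dir) {
  sv <- generate_survey(config)
  paths <- write_survey(sv, dir)
  manifest <- list(
    seed = config$seed,
    n_participants = nrow(sv$participants),
    n_excluded = sum(sv$participants$excluded),
    n_records = nrow(sv$records),
    n_foods = nrow(sv$composition),
    grams_scalar = attr(sv, "grams_scalar"),
    checksums = as.list(stats::setNames(tools::md5sum(unname(paths)),
                                        basename(unname(paths)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Habitual-intake summary of one survey: distribution on the g/d scale,
# means on both scales, fraction below/meeting the per-kg cut-off. With
# perkg_mode = "per_kg" the estimator runs directly on g/kg daily values.
summarise_habitual <- function(survey, cutoff = 1.0,
                               perkg_mode = c("g_per_day", "per_kg")) {
  perkg_mode <- match.arg(perkg_mode)
  daily <- daily_intake_table(survey, "protein_g")
  p <- survey$participants[!survey$participants$excluded, ]
  weights <- p[, c("participant_id", "analysis_weight")]
  bw <- p[, c("participant_id", "body_weight_kg")]
  w <- p$analysis_weight / sum(p$analysis_weight)

  if (perkg_mode == "per_kg") {
    daily$value <- daily$value /
      p$body_weight_kg[match(daily$participant_id, p$participant_id)]
    dist <- estimate_habitual_distribution(daily, weights = weights)
    frac_below <- fraction_below(dist, cutoff, per_kg = TRUE)
    mean_perkg <- sum(w[match(dist$person$participant_id,
                              p$participant_id)] * dist$person$habitual)
    mean_g_d <- sum(w[match(dist$person$participant_id, p$participant_id)] *
                    dist$person$habitual *
                    p$body_weight_kg[match(dist$person$participant_id,
                                           p$participant_id)])
  } else {
    dist <- estimate_habitual_distribution(daily, weights = weights,
                                           body_weight_kg = bw)
    frac_below <- fraction_below(dist, cutoff, per_kg = FALSE)
    i <- match(dist$person$participant_id, p$participant_id)
    mean_g_d <- sum(w[i] * dist$person$habitual)
    mean_perkg <- sum(w[i] * dist$person$habitual / p$body_weight_kg[i])
  }
  list(distribution = dist,
       mean_habitual_g_d = mean_g_d,
       mean_habitual_g_per_kg_d = mean_perkg,
       fraction_below_cutoff = frac_below,
       fraction_meeting_cutoff = 1 - frac_below)
}

#' Run the full replacement study on one survey
#'
#' For the original survey and each scenario: applies the scenario, counts
#' replacements per food group, ranks group contributions, summarises
#' survey-weighted nutrient intakes on the 2-day-average basis, and estimates
#' the habitual protein-intake distribution with the fraction meeting the
#' cut-off. When two or more scenarios are given, a combined scenario is
#' derived from the first two by the top-k contribution rule and run as well.
#' The run is fully deterministic: its output is a pure function of the
#' inputs. With \code{out_dir} set, writes per-scenario TSV tables
#' (replacement counts, contributions, nutrient summary), a JSON summary and
#' the replacement logs as CSV.
#'
#' @param survey a \code{diet_survey}
#' @param scenarios named list of \code{scenario_definition}s
#' @param cutoff protein cut-off in g/kg BW/d
#' @param p75_basis see \code{\link{compute_p75}}
#' @param perkg_mode how the habitual estimator sees the data:
#'   \code{"g_per_day"} (estimate g/d, divide by body weight at the cut-off)
#'   or \code{"per_kg"} (estimate directly on g/kg daily values)
#' @param derive_combined derive the combined scenario from the first two
#'   scenarios (needs >= 2 scenarios)
#' @param combined_k groups taken from each ranking for the combined scenario
#' @param out_dir optional output directory for TSV/CSV/JSON artefacts
#' @param nutrients_wanted nutrients for the intake summary table
#' @return list of class \code{replacement_study}: \code{funnel} (exclusion
#'   and eligibility counts), \code{original} (habitual + nutrient summary),
#'   \code{scenarios} (per scenario: \code{result}, \code{counts},
#'   \code{contributions}, \code{habitual}, \code{nutrients}),
#'   \code{combined_definition} when derived
#' @export
run_replacement_study <- function(survey, scenarios, cutoff = 1.0,
                                  p75_basis = "items",
                                  perkg_mode = "g_per_day",
                                  derive_combined = length(scenarios) >= 2,
                                  combined_k = 3,
                                  out_dir = NULL,
                                  nutrients_wanted =
                                    nutrients(survey$composition)) {
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "scenario_id")
  }
  eligible <- eligible_participants(survey, cutoff)
  funnel <- list(n_total = nrow(survey$participants),
                 n_excluded_missing_bw = sum(survey$participants$excluded),
                 n_analyzed = sum(!survey$participants$excluded),
                 n_eligible_below_cutoff = length(eligible))

  original <- list(
    habitual = summarise_habitual(survey, cutoff, perkg_mode),
    nutrients = mean_nutrient_intakes(survey, nutrients_wanted),
    observed_fraction_below = observed_fraction_below(survey, cutoff))

  run_one <- function(sc) {
    res <- apply_scenario(survey, sc, p75_basis = p75_basis)
    list(result = res,
         counts = count_replacements(res),
         contributions = group_contributions(res),
         habitual = summarise_habitual(res$modified_survey, cutoff,
                                       perkg_mode),
         nutrients = mean_nutrient_intakes(res$modified_survey,
                                           nutrients_wanted))
  }
  sc_out <- lapply(scenarios, run_one)

  combined_definition <- NULL
  if (isTRUE(derive_combined)) {
    if (length(sc_out) < 2L) stop("combined scenario needs two scenarios",
                                  call. = FALSE)
    # rule: top-k of the second scenario, then walk the first's ranking
    combined_definition <- derive_combined_scenario(
      sc_out[[1L]]$result, sc_out[[2L]]$result, k = combined_k)
    sc_out[[combined_definition$scenario_id]] <- run_one(combined_definition)
  }

  study <- structure(list(funnel = funnel, original = original,
                          scenarios = sc_out,
                          combined_definition = combined_definition,
                          cutoff = cutoff),
                     class = "replacement_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.replacement_study <- function(x, ...) {
  f <- x$funnel
  cat("<replacement_study> cutoff ", x$cutoff, " g/kg BW/d\n",
      "  participants: ", f$n_total, " total, ", f$n_excluded_missing_bw,
      " excluded (unknown BW), ", f$n_analyzed, " analyzed, ",
      f$n_eligible_below_cutoff, " eligible (< cutoff)\n", sep = "")
  cat(sprintf(
    "  original: habitual mean %.1f g/d (%.2f g/kg BW/d), %.1f%% meeting cutoff\n",
    x$original$habitual$mean_habitual_g_d,
    x$original$habitual$mean_habitual_g_per_kg_d,
    100 * x$original$habitual$fraction_meeting_cutoff))
  for (nm in names(x$scenarios)) {
    s <- x$scenarios[[nm]]
    cat(sprintf(
      "  %s: %d replacements, habitual mean %.1f g/d (%.2f g/kg BW/d), %.1f%% meeting cutoff\n",
      nm, s$counts$total, s$habitual$mean_habitual_g_d,
      s$habitual$mean_habitual_g_per_kg_d,
      100 * s$habitual$fraction_meeting_cutoff))
  }
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

# Write the study's tables: per scenario a replacement-count table, a
# contribution ranking, a nutrient summary and the raw replacement log; one
# JSON summary for the whole run.
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(funnel = study$funnel, cutoff = study$cutoff,
                  original = list(
                    mean_habitual_g_d =
                      study$original$habitual$mean_habitual_g_d,
                    mean_habitual_g_per_kg_d =
                      study$original$habitual$mean_habitual_g_per_kg_d,
                    fraction_meeting_cutoff =
                      study$original$habitual$fraction_meeting_cutoff))
  write_tsv(study$original$nutrients,
            file.path(out_dir, "nutrients_original.tsv"))
  for (nm in names(study$scenarios)) {
    s <- study$scenarios[[nm]]
    safe <- gsub("[^A-Za-z0-9_-]", "_", nm)
    write_tsv(data.frame(group = names(s$counts$per_group),
                         n_replacements = as.integer(s$counts$per_group)),
              file.path(out_dir, paste0("replacements_", safe, ".tsv")))
    write_tsv(s$contributions,
              file.path(out_dir, paste0("contributions_", safe, ".tsv")))
    write_tsv(s$nutrients,
              file.path(out_dir, paste0("nutrients_", safe, ".tsv")))
    utils::write.csv(s$result$log,
                     file.path(out_dir, paste0("log_", safe, ".csv")),
                     row.names = FALSE)
    summary$scenarios[[nm]] <- list(
      total_replacements = s$counts$total,
      mean_habitual_g_d = s$habitual$mean_habitual_g_d,
      mean_habitual_g_per_kg_d = s$habitual$mean_habitual_g_per_kg_d,
      fraction_meeting_cutoff = s$habitual$fraction_meeting_cutoff)
  }
  if (!is.null(study$combined_definition)) {
    write_scenario(study$combined_definition,
                   file.path(out_dir, "combined_scenario.yaml"))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
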