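#' Default food-group catalog specification
#'
#' Nine food groups typical of the diet of Dutch community-dwelling older
#' adults, each with a lognormal distribution of per-item protein content
#' (g/100 g), a daily consumption probability and a lognormal distribution of
#' portion size (grams). Values are round numbers chosen to resemble food-
#' composition-table protein contents and realistic portion sizes; the
#' generator's calibration step rescales portions globally, so only the
#' relative pattern matters.
#'
#' @return data.frame with one row per group: \code{group},
#'   \code{foods_per_group}, \code{protein_log_mean}, \code{protein_log_sd},
#'   \code{consumption_probability_per_day}, \code{grams_log_mean},
#'   \code{grams_log_sd}
#' @export
default_group_specs <- function() {
  g <- function(group, n, prot, prot_sd, p, grams, grams_sd) {
    data.frame(group = group, foods_per_group = n,
               protein_log_mean = log(prot), protein_log_sd = prot_sd,
               consumption_probability_per_day = p,
               grams_log_mean = log(grams), grams_log_sd = grams_sd,
               stringsAsFactors = FALSE)
  }
  rbind(
    g("bread",                                      8, 9.0, 0.25, 0.95, 120, 0.40),
    g("yoghurt, cream desserts and pudding",        8, 4.0, 0.30, 0.60, 150, 0.40),
    g("potatoes, vegetables and legumes",           8, 2.0, 0.40, 0.85, 200, 0.35),
    g("non-alcoholic beverages and milk",           8, 2.5, 0.50, 0.90, 400, 0.40),
    g("soups",                                      6, 2.0, 0.35, 0.30, 250, 0.30),
    g("savoury spreads, sweet spreads and cheese",  8, 10.0, 0.60, 0.80, 40, 0.40),
    g("meat and fish",                              8, 20.0, 0.25, 0.80, 100, 0.35),
    g("cereals",                                    6, 10.0, 0.30, 0.35, 50, 0.40),
    g("fruit",                                      6, 0.7, 0.40, 0.70, 150, 0.35))
}

#' Configuration for the synthetic-survey generator
#'
#' @param n_participants number of participants (>= 2); default 727
#' @param seed integer seed controlling every random draw
#' @param body_weight_mean_kg,body_weight_sd_kg body-weight distribution
#'   (normal, truncated at 35 kg)
#' @param group_specs per-group catalog specification; see
#'   \code{\link{default_group_specs}}
#' @param within_person_day_sd_multiplier log-sd of the day-level
#'   multiplicative noise on portion size (>= 0); the source of within-person
#'   variance alongside the day-level consumption indicators
#' @param person_grams_log_sd log-sd of the person-level portion-size
#'   propensity (between-person variance source)
#' @param target_fraction_below_cutoff calibrate the global portion scalar so
#'   this fraction of included participants has a 2-day mean protein intake
#'   below \code{cutoff}; NULL disables calibration. Default 0.529.
#' @param cutoff calibration cut-off, g/kg BW/d
#' @param enriched_protein_multiplier protein content of the per-group
#'   protein-enriched catalog item, as a multiple of the group's highest
#'   regular protein content
#' @param n_missing_bw number of participants whose body weight is recorded
#'   as unknown (they are flagged excluded downstream)
#' @param weight_log_sd log-sd of the analysis weights (mean-1 lognormal)
#' @return list of class \code{generator_config}
#' @export
generator_config <- function(n_participants = 727L, seed = 1L,
                             body_weight_mean_kg = 75, body_weight_sd_kg = 12,
                             group_specs = default_group_specs(),
                             within_person_day_sd_multiplier = 0.35,
                             person_grams_log_sd = 0.25,
                             target_fraction_below_cutoff = 0.529,
                             cutoff = 1.0,
                             enriched_protein_multiplier = 2.0,
                             n_missing_bw = 0L,
                             weight_log_sd = 0.15) {
  stopifnot(n_participants >= 2, body_weight_sd_kg >= 0,
            within_person_day_sd_multiplier >= 0, person_grams_log_sd >= 0,
            all(group_specs$consumption_probability_per_day >= 0),
            all(group_specs$consumption_probability_per_day <= 1),
            all(group_specs$protein_log_sd >= 0),
            all(group_specs$grams_log_sd >= 0),
            all(group_specs$foods_per_group >= 1),
            is.null(target_fraction_below_cutoff) ||
              (target_fraction_below_cutoff >= 0 &&
               target_fraction_below_cutoff <= 1),
            n_missing_bw >= 0, n_missing_bw < n_participants)
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed),
                 body_weight_mean_kg = body_weight_mean_kg,
                 body_weight_sd_kg = body_weight_sd_kg,
                 group_specs = group_specs,
                 within_person_day_sd_multiplier =
                   within_person_day_sd_multiplier,
                 person_grams_log_sd = person_grams_log_sd,
                 target_fraction_below_cutoff = target_fraction_below_cutoff,
                 cutoff = cutoff,
                 enriched_protein_multiplier = enriched_protein_multiplier,
                 n_missing_bw = as.integer(n_missing_bw),
                 weight_log_sd = weight_log_sd),
            class = "generator_config")
}

#' Read a generator configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of
#' \code{\link{generator_config}}; \code{group_specs} is a list of per-group
#' mappings with the columns of \code{\link{default_group_specs}} (omitted
#' keys fall back to the defaults).
#'
#' @param path YAML file
#' @return a \code{generator_config}
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$group_specs)) {
    x$group_specs <- do.call(rbind, lapply(x$group_specs, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  do.call(generator_config, x)
}

# Build the food catalog: per group, `foods_per_group` regular items with
# lognormal protein content plus one protein-enriched item whose content is a
# fixed multiple of the group's regular maximum (so it always clears the P75
# threshold). Energy is a crude linear function of protein so nutrient
# summaries have a second column to report.
build_catalog <- function(config) {
  specs <- config$group_specs
  rows <- lapply(seq_len(nrow(specs)), function(gi) {
    s <- specs[gi, ]
    code <- sprintf("G%02d_F%02d", gi, seq_len(s$foods_per_group))
    prot <- exp(stats::rnorm(s$foods_per_group, s$protein_log_mean,
                             s$protein_log_sd))
    enr_code <- sprintf("G%02d_ENR", gi)
    enr_prot <- max(prot) * config$enriched_protein_multiplier
    data.frame(
      food_code = c(code, enr_code),
      name = c(paste0(s$group, " item ", seq_len(s$foods_per_group)),
               paste0("protein-enriched ", s$group)),
      group = s$group,
      protein_g = c(prot, enr_prot),
      energy_kcal = 60 + 8 * c(prot, enr_prot),
      enriched = c(rep(FALSE, s$foods_per_group), TRUE),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic two-day recall survey
#'
#' Builds a food catalog (lognormal per-item protein contents per group plus
#' one protein-enriched item per group), draws participants (body weight,
#' mean-1 lognormal analysis weights), and simulates two recall days per
#' participant: for each food group and day, a Bernoulli consumption
#' indicator with a person-specific probability (Beta-distributed around the
#' group's rate), a uniformly chosen regular item, and a lognormal portion
#' with person-level and day-level multiplicative components — so protein
#' intake carries both between-person and within-person variance. When
#' \code{target_fraction_below_cutoff} is set, a single global portion scalar
#' is found by bisection (tolerance 0.005 on the fraction, at most 40
#' iterations) so that the target fraction of included participants falls
#' below the cut-off; the fraction is provably monotone in the scalar.
#' Everything is reproducible from the seed.
#'
#' @param config a \code{\link{generator_config}}
#' @return a \code{\link{diet_survey}}; the calibration scalar is attached as
#'   attribute \code{"grams_scalar"} and the enriched/regular flag travels in
#'   the composition's \code{enriched} column
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  specs <- config$group_specs
  catalog <- build_catalog(config)

  n <- config$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  bw <- pmax(35, stats::rnorm(n, config$body_weight_mean_kg,
                              config$body_weight_sd_kg))
  aw <- exp(stats::rnorm(n, 0, config$weight_log_sd) -
            config$weight_log_sd^2 / 2)
  if (config$n_missing_bw > 0L) {
    bw[sample.int(n, config$n_missing_bw)] <- NA_real_
  }

  kappa <- 10  # concentration of the person-level consumption propensity
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    person_dev <- stats::rnorm(nrow(specs), 0, config$person_grams_log_sd)
    p_base <- specs$consumption_probability_per_day
    p_i <- ifelse(p_base %in% c(0, 1), p_base,
                  stats::rbeta(nrow(specs), p_base * kappa,
                               (1 - p_base) * kappa))
    out <- list()
    for (d in 1:2) {
      eat <- stats::runif(nrow(specs)) < p_i
      if (!any(eat)) next
      gi <- which(eat)
      pick <- vapply(gi, function(g) {
        sample.int(specs$foods_per_group[g], 1L)
      }, integer(1))
      grams <- exp(specs$grams_log_mean[gi] + person_dev[gi] +
                   stats::rnorm(length(gi), 0, specs$grams_log_sd[gi]) +
                   stats::rnorm(length(gi), 0,
                                config$within_person_day_sd_multiplier))
      out[[d]] <- data.frame(
        participant_id = ids[i], day_index = d,
        food_code = sprintf("G%02d_F%02d", gi, pick),
        grams = grams, stringsAsFactors = FALSE)
    }
    recs[[i]] <- do.call(rbind, out)
  }
  records <- do.call(rbind, recs)
  if (is.null(records)) {
    records <- data.frame(participant_id = character(0),
                          day_index = integer(0),
                          food_code = character(0), grams = numeric(0),
                          stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL

  scalar <- 1
  if (!is.null(config$target_fraction_below_cutoff)) {
    prot <- catalog$protein_g[match(records$food_code, catalog$food_code)]
    contrib <- records$grams * prot / 100
    keep <- !is.na(bw[match(records$participant_id, ids)])
    f <- factor(records$participant_id, levels = ids[!is.na(bw)])
    day_tot <- tapply(contrib[keep],
                      list(f[keep], records$day_index[keep]), sum,
                      default = 0)
    base_perkg <- rowMeans(day_tot) / bw[!is.na(bw)]
    frac_at <- function(s) mean(s * base_perkg < config$cutoff)
    scalar <- calibrate_scalar(frac_at,
                               config$target_fraction_below_cutoff)
    records$grams <- records$grams * scalar
  }

  sv <- diet_survey(
    data.frame(participant_id = ids, body_weight_kg = bw,
               analysis_weight = aw, stringsAsFactors = FALSE),
    records,
    food_composition(catalog))
  attr(sv, "grams_scalar") <- scalar
  sv
}

# Bisection for the global portion scalar: frac_at(s) is non-increasing in s.
calibrate_scalar <- function(frac_at, target, tol = 0.005, max_iter = 40L) {
  lo <- 1e-3; hi <- 1e3
  if (frac_at(lo) < target || frac_at(hi) > target) {
    # target unreachable even at the bracket ends; return nearer end
    return(if (abs(frac_at(lo) - target) < abs(frac_at(hi) - target)) lo
           else hi)
  }
  s <- 1
  for (it in seq_len(max_iter)) {
    s <- sqrt(lo * hi)  # bisect on the log scale
    f <- frac_at(s)
    if (abs(f - target) <= tol) return(s)
    if (f > target) lo <- s else hi <- s
  }
  s
}

#' Generate a cohort with known habitual intakes
#'
#' Parameter-recovery harness for the habitual-intake estimator: person i has
#' a true habitual intake H_i drawn lognormal, and each observed day is H_i
#' times mean-one multiplicative lognormal noise, so the expectation of a
#' person's observed days equals H_i. With \code{within_sd = 0} every
#' observed day equals H_i exactly.
#'
#' @param n number of persons (>= 2)
#' @param habitual_log_mean,habitual_log_sd log-scale mean and sd of the true
#'   habitual intakes
#' @param within_sd log-scale sd of the day-level noise (>= 0)
#' @param n_days days observed per person (>= 2)
#' @param seed integer seed
#' @return list with \code{daily} (data.frame participant_id, day_index,
#'   value) and \code{truth} (data.frame participant_id, habitual_true)
#' @export
generate_known_habitual_cohort <- function(n, habitual_log_mean,
                                           habitual_log_sd, within_sd,
                                           n_days = 2L, seed = 1L) {
  stopifnot(n >= 2, n_days >= 2, within_sd >= 0, habitual_log_sd >= 0)
  set.seed(seed)
  ids <- sprintf("P%05d", seq_len(n))
  H <- exp(stats::rnorm(n, habitual_log_mean, habitual_log_sd))
  eps <- matrix(stats::rnorm(n * n_days, 0, within_sd), nrow = n)
  obs <- H * exp(eps - within_sd^2 / 2)  # mean-one noise multiplier
  list(daily = data.frame(
         participant_id = rep(ids, times = n_days),
         day_index = rep(seq_len(n_days), each = n),
         value = as.numeric(obs),
         stringsAsFactors = FALSE),
       truth = data.frame(participant_id = ids, habitual_true = H,
                          stringsAsFactors = FALSE))
}

#' Build an enrichment scenario from a generated catalog
#'
#' Convenience for scenario configuration on synthetic surveys: for each
#' requested group, picks either the protein-enriched catalog item
#' (\code{style = "enriched"}) or the highest-protein regular item
#' (\code{style = "rich"}) as the alternative food. Both sit strictly above
#' the group's P75 by construction of the catalog.
#'
#' @param composition a generated \code{food_composition} carrying the
#'   \code{enriched} flag column
#' @param groups food groups to include
#' @param style \code{"rich"} (highest-protein regular item) or
#'   \code{"enriched"}
#' @param scenario_id id for the scenario
#' @param eligibility_cutoff cut-off in g/kg BW/d
#' @return a validated \code{scenario_definition}
#' @export
build_enrichment_scenario <- function(composition, groups,
                                      style = c("rich", "enriched"),
                                      scenario_id = style,
                                      eligibility_cutoff = 1.0) {
  style <- match.arg(style)
  if (!"enriched" %in% names(composition)) {
    stop("composition lacks the generator's 'enriched' flag column",
         call. = FALSE)
  }
  alt <- vapply(groups, function(g) {
    rows <- composition[composition$group == g, ]
    if (style == "enriched") {
      cand <- rows[rows$enriched, ]
      if (nrow(cand) == 0L) stop("no enriched item in group ", g,
                                 call. = FALSE)
      cand$food_code[which.max(cand$protein_g)]
    } else {
      cand <- rows[!rows$enriched, ]
      cand$food_code[which.max(cand$protein_g)]
    }
  }, character(1))
  scenario_definition(scenario_id,
                      data.frame(group = groups, alternative_food_code = alt,
                                 stringsAsFactors = FALSE),
                      eligibility_cutoff = eligibility_cutoff,
                      composition = composition)
}
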