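# Fixtures and independent brute-force oracles shared across tests.

# Tiny two-group composition used by many unit tests.
tiny_composition <- function() {
  food_composition(data.frame(
    food_code = c("B1", "B2", "B3", "B4", "ALT_B",
                  "S1", "S2", "ALT_S"),
    name = c(paste("bread item", 1:4), "protein bread",
             "soup 1", "soup 2", "protein soup"),
    group = c(rep("bread", 5), rep("soups", 3)),
    protein_g = c(1, 2, 3, 4, 9, 2, 3, 8),
    energy_kcal = c(250, 240, 230, 220, 250, 40, 50, 60),
    stringsAsFactors = FALSE))
}

tiny_survey <- function(composition = tiny_composition()) {
  participants <- data.frame(
    participant_id = c("A", "B", "C"),
    body_weight_kg = c(80, 60, 70),
    analysis_weight = c(1, 1, 1), stringsAsFactors = FALSE)
  records <- data.frame(
    participant_id = c("A", "A", "A", "B", "B", "C"),
    day_index =      c(1L,  1L,  2L,  1L,  2L,  1L),
    food_code =      c("B1", "S1", "B2", "B4", "S2", "B1"),
    grams =          c(150, 250, 100, 300, 200, 50),
    stringsAsFactors = FALSE)
  diet_survey(participants, records, composition)
}

# Linear-interpolation 75th percentile, written independently of the
# implementation: sorted values, position 1 + 0.75 (n - 1), interpolate.
p75_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  h <- 1 + 0.75 * (n - 1)
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Record-by-record re-implementation of the replacement rule, looping over
# rows with scalar arithmetic only.
brute_apply_scenario <- function(survey, scenario) {
  comp <- survey$composition
  cutoff <- scenario$eligibility_cutoff
  eligible <- character(0)
  for (pid in survey$participants$participant_id) {
    i <- match(pid, survey$participants$participant_id)
    if (survey$participants$excluded[i]) next
    tot <- c(0, 0)
    for (d in 1:2) {
      r <- survey$records[survey$records$participant_id == pid &
                          survey$records$day_index == d, ]
      if (nrow(r) > 0) {
        for (j in seq_len(nrow(r))) {
          prot <- comp$protein_g[comp$food_code == r$food_code[j]]
          tot[d] <- tot[d] + r$grams[j] * prot / 100
        }
      }
    }
    if (mean(tot) / survey$participants$body_weight_kg[i] < cutoff) {
      eligible <- c(eligible, pid)
    }
  }
  p75 <- sapply(scenario$replacements$group, function(g) {
    p75_oracle(comp$protein_g[comp$group == g])
  })
  new_records <- survey$records
  log <- list()
  for (j in seq_len(nrow(new_records))) {
    if (!(new_records$participant_id[j] %in% eligible)) next
    if (new_records$grams[j] == 0) next
    code <- new_records$food_code[j]
    grp <- comp$group[comp$food_code == code]
    gi <- match(grp, scenario$replacements$group)
    if (is.na(gi)) next
    prot <- comp$protein_g[comp$food_code == code]
    if (prot >= p75[gi]) next
    alt <- scenario$replacements$alternative_food_code[gi]
    alt_prot <- comp$protein_g[comp$food_code == alt]
    log[[length(log) + 1]] <- data.frame(
      participant_id = new_records$participant_id[j],
      day_index = new_records$day_index[j],
      group = grp, from_food_code = code, to_food_code = alt,
      grams = new_records$grams[j],
      protein_delta_g = new_records$grams[j] * (alt_prot - prot) / 100,
      stringsAsFactors = FALSE)
    new_records$food_code[j] <- alt
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(participant_id = character(0), day_index = integer(0),
               group = character(0), from_food_code = character(0),
               to_food_code = character(0), grams = numeric(0),
               protein_delta_g = numeric(0), stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(records = new_records, log = log, eligible = sort(eligible))
}

# Random small survey (<= 10 participants, <= 5 regular foods per group) with
# a dedicated above-P75 alternative appended to every group; occasional
# protein-content ties and zero-gram records are deliberately included.
random_small_survey <- function(seed) {
  set.seed(seed)
  n_groups <- sample(2:4, 1)
  groups <- paste0("grp", seq_len(n_groups))
  items <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    n_foods <- sample(1:5, 1)
    prot <- round(runif(n_foods, 0.5, 12), sample(0:1, 1))  # ties likely
    alt_prot <- max(prot) + runif(1, 1, 5)
    data.frame(
      food_code = c(sprintf("g%d_f%d", g, seq_len(n_foods)),
                    sprintf("g%d_alt", g)),
      name = "x", group = groups[g],
      protein_g = c(prot, alt_prot), stringsAsFactors = FALSE)
  }))
  comp <- food_composition(items)
  n_p <- sample(2:10, 1)
  ids <- sprintf("p%02d", seq_len(n_p))
  participants <- data.frame(
    participant_id = ids,
    body_weight_kg = runif(n_p, 55, 95),
    analysis_weight = runif(n_p, 0.5, 2), stringsAsFactors = FALSE)
  regular <- comp$food_code[!grepl("_alt$", comp$food_code)]
  n_r <- sample(5:30, 1)
  records <- data.frame(
    participant_id = sample(ids, n_r, replace = TRUE),
    day_index = sample(1:2, n_r, replace = TRUE),
    food_code = sample(regular, n_r, replace = TRUE),
    grams = round(c(runif(n_r - 1, 0, 120), 0), 1),  # one zero-gram record
    stringsAsFactors = FALSE)
  sv <- diet_survey(participants, records, comp)
  scen <- scenario_definition(
    paste0("rand", seed),
    data.frame(group = groups,
               alternative_food_code = sprintf("g%d_alt", seq_len(n_groups)),
               stringsAsFactors = FALSE),
    eligibility_cutoff = runif(1, 0.4, 1.6))
  list(survey = sv, scenario = scen)
}

# Composition + one-participant survey engineered so that the scenario-1 and
# scenario-2 contribution rankings retrace the published narrative: six food
# groups, each with six low-protein items and two high-protein alternatives,
# grams chosen so scenario 2 ranks bread > yoghurt-desserts > soups and
# scenario 1 ranks yoghurt-desserts > potatoes-veg-legumes > beverages-milk >
# spreads-cheese.
narrative_fixture <- function() {
  groups <- c("bread", "yoghurt, cream desserts and pudding",
              "potatoes, vegetables and legumes",
              "non-alcoholic beverages and milk", "soups",
              "savoury spreads, sweet spreads and cheese")
  items <- do.call(rbind, lapply(seq_along(groups), function(g) {
    data.frame(
      food_code = sprintf("G%d_%s", g,
                          c("L1", "L2", "L3", "L4", "L5", "L6",
                            "RICH", "ENR")),
      name = "x", group = groups[g],
      protein_g = c(1, 1, 1, 1, 2, 2, 12, 20),
      stringsAsFactors = FALSE)
  }))
  comp <- food_composition(items)
  # grams of the consumed low-protein item (L1) per group
  grams <- c("bread" = 500,
             "yoghurt, cream desserts and pudding" = 400,
             "potatoes, vegetables and legumes" = 300,
             "non-alcoholic beverages and milk" = 200,
             "soups" = 100,
             "savoury spreads, sweet spreads and cheese" = 50)
  records <- data.frame(
    participant_id = "p1", day_index = 1L,
    food_code = sprintf("G%d_L1", seq_along(groups)),
    grams = as.numeric(grams[groups]), stringsAsFactors = FALSE)
  sv <- diet_survey(
    data.frame(participant_id = "p1", body_weight_kg = 100,
               analysis_weight = 1, stringsAsFactors = FALSE),
    records, comp)
  s1_groups <- c("yoghurt, cream desserts and pudding",
                 "potatoes, vegetables and legumes",
                 "non-alcoholic beverages and milk",
                 "savoury spreads, sweet spreads and cheese")
  s1 <- scenario_definition("protein-rich", data.frame(
    group = s1_groups,
    alternative_food_code = sprintf("G%d_RICH", match(s1_groups, groups)),
    stringsAsFactors = FALSE), composition = comp)
  s2_groups <- c("bread", "yoghurt, cream desserts and pudding", "soups")
  s2 <- scenario_definition("protein-enriched", data.frame(
    group = s2_groups,
    alternative_food_code = sprintf("G%d_ENR", match(s2_groups, groups)),
    stringsAsFactors = FALSE), composition = comp)
  list(survey = sv, s1 = s1, s2 = s2, groups = groups)
}
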