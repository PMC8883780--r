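#' Construct a food composition table
#'
#' A food composition table holds, for every food code, its name, food-group
#' label and nutrient content per 100 g edible portion. Protein (column
#' \code{protein_g}) is mandatory for every item; all other nutrients are
#' optional per item, and a missing value is an error when that nutrient is
#' requested, never silently zero.
#'
#' @param items data.frame with columns \code{food_code}, \code{name},
#'   \code{group}, \code{protein_g}, and optionally further nutrient columns
#'   (amounts per 100 g edible portion).
#' @return An object of class \code{food_composition} (a validated data.frame).
#' @examples
#' comp <- food_composition(data.frame(
#'   food_code = c("F1", "F2"), name = c("white bread", "protein bread"),
#'   group = "bread", protein_g = c(8, 15), energy_kcal = c(250, 260)))
#' nutrients(comp)
#' @export
food_composition <- function(items) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  required <- c("food_code", "name", "group", "protein_g")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0L) {
    stop("composition table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  items$food_code <- as.character(items$food_code)
  items$group <- as.character(items$group)
  if (anyDuplicated(items$food_code)) {
    dup <- unique(items$food_code[duplicated(items$food_code)])
    stop("duplicate food_code in composition table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyNA(items$protein_g)) {
    stop("protein_g missing for food(s): ",
         paste(items$food_code[is.na(items$protein_g)], collapse = ", "),
         call. = FALSE)
  }
  for (nm in nutrient_columns(items)) {
    v <- items[[nm]]
    if (any(!is.na(v) & v < 0)) {
      stop("negative ", nm, " in composition table", call. = FALSE)
    }
  }
  rownames(items) <- NULL
  class(items) <- c("food_composition", "data.frame")
  items
}

# "enriched" is generator metadata (regular vs protein-enriched item), not a
# nutrient.
nutrient_columns <- function(items) {
  setdiff(names(items), c("food_code", "name", "group", "enriched"))
}

#' List the nutrients available in a composition table
#' @param composition a \code{food_composition}
#' @return character vector of nutrient names (amounts are per 100 g)
#' @export
nutrients <- function(composition) {
  nutrient_columns(composition)
}

#' List the distinct food-group labels in a composition table
#' @param composition a \code{food_composition}
#' @return character vector of group labels
#' @export
food_groups <- function(composition) {
  sort(unique(composition$group))
}

#' Look up the per-100-g amount of one nutrient for given food codes
#'
#' @param composition a \code{food_composition}
#' @param food_code character vector of food codes
#' @param nutrient nutrient name, e.g. \code{"protein_g"}
#' @return numeric vector of amounts per 100 g
#' @export
nutrient_per_100g <- function(composition, food_code, nutrient = "protein_g") {
  if (!nutrient %in% nutrient_columns(composition)) {
    stop("nutrient not present in composition table: ", nutrient, call. = FALSE)
  }
  idx <- match(food_code, composition$food_code)
  if (anyNA(idx)) {
    stop("unknown food code(s): ",
         paste(unique(food_code[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  v <- composition[[nutrient]][idx]
  if (anyNA(v)) {
    stop("nutrient '", nutrient, "' missing for food(s): ",
         paste(unique(food_code[is.na(v)]), collapse = ", "), call. = FALSE)
  }
  v
}

#' Read / write a composition table as CSV
#'
#' The CSV dialect has columns \code{food_code}, \code{name}, \code{group},
#' then one column per nutrient named \code{<nutrient>_per_100g}
#' (\code{protein_g_per_100g} mandatory). UTF-8, header row required.
#'
#' @param path file path
#' @return \code{read_composition}: a \code{food_composition}.
#' @export
read_composition <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  nut <- grepl("_per_100g$", names(raw))
  names(raw)[nut] <- sub("_per_100g$", "", names(raw)[nut])
  food_composition(raw)
}

#' @rdname read_composition
#' @param composition a \code{food_composition}
#' @export
write_composition <- function(composition, path) {
  out <- as.data.frame(composition)
  nut <- names(out) %in% nutrient_columns(composition)
  names(out)[nut] <- paste0(names(out)[nut], "_per_100g")
  utils::write.csv(format_full(out), path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.food_composition <- function(x, ...) {
  cat("<food_composition> ", nrow(x), " items, ",
      length(unique(x$group)), " groups, nutrients: ",
      paste(nutrient_columns(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Group-level 75th percentile of protein content
#'
#' Computes the 75th percentile of per-item protein content (g/100 g) within
#' one food group. Each distinct food item counts once, unweighted by
#' consumption, using the linear-interpolation percentile definition
#' (sorted values x(1..n), position 1 + 0.75 (n - 1), interpolate; this is
#' \code{stats::quantile} type 7). With \code{basis = "consumption"} the
#' percentile is computed over only the distinct items that actually appear in
#' the supplied survey's consumption records.
#'
#' @param composition a \code{food_composition}
#' @param group food-group label
#' @param basis \code{"items"} (all items in the composition table, default)
#'   or \code{"consumption"} (distinct items consumed in \code{survey})
#' @param survey required when \code{basis = "consumption"}
#' @return list with \code{group}, \code{p75_protein_per_100g}, \code{n_items}
#' @examples
#' comp <- food_composition(data.frame(
#'   food_code = paste0("F", 1:5), name = letters[1:5], group = "soups",
#'   protein_g = c(1, 2, 3, 4, 5)))
#' compute_p75(comp, "soups")$p75_protein_per_100g  # 4
#' @export
compute_p75 <- function(composition, group, basis = c("items", "consumption"),
                        survey = NULL) {
  basis <- match.arg(basis)
  keep <- composition$group == group
  if (basis == "consumption") {
    if (is.null(survey)) {
      stop("basis = \"consumption\" requires a survey", call. = FALSE)
    }
    keep <- keep & composition$food_code %in% unique(survey$records$food_code)
  }
  vals <- composition$protein_g[keep]
  if (length(vals) == 0L) {
    stop("no food items for group '", group, "' on basis '", basis, "'",
         call. = FALSE)
  }
  list(group = group,
       p75_protein_per_100g = unname(stats::quantile(vals, 0.75, type = 7)),
       n_items = length(vals))
}
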