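# Analytical greenness: Eco-scale penalty points and an AGREE-style
# 12-principle aggregator.

# published Eco-scale bracket tables
eco_amount_mult <- c(under_10 = 1, from_10_to_100 = 2, over_100 = 3)
eco_signal_mult <- c(none = 0, warning = 1, danger = 2)
eco_instrument_pts <- c(up_to_0.1_kWh = 0, up_to_1.5_kWh = 1, over_1.5_kWh = 2)
eco_hazard_pts <- c(hermetic = 0, emission_to_air = 3)
eco_waste_pts <- c(none = 0, under_1 = 1, from_1_to_10 = 3, over_10 = 5)

#' Build an Eco-scale penalty item
#'
#' Reagent penalty points follow the published rule: number of GHS pictograms
#' times the signal-word multiplier (warning 1, danger 2) times the amount
#' bracket multiplier (<10 mL/g: 1, 10-100: 2, >100: 3). Instrument,
#' occupational-hazard and waste items score directly from their bracket
#' tables.
#'
#' @param name item label.
#' @param category one of `"reagent"`, `"instrument"`,
#'   `"occupational_hazard"`, `"waste"`.
#' @param pictogram_count number of GHS pictograms (reagents).
#' @param signal_word `"none"`, `"warning"` or `"danger"` (reagents).
#' @param amount_bracket bracket key; for reagents one of `"under_10"`,
#'   `"from_10_to_100"`, `"over_100"` (mL or g); for instruments an energy
#'   bracket (`"up_to_0.1_kWh"`, `"up_to_1.5_kWh"`, `"over_1.5_kWh"`); for
#'   hazards `"hermetic"`/`"emission_to_air"`; for waste `"none"`,
#'   `"under_1"`, `"from_1_to_10"`, `"over_10"` (mL/g).
#' @return A `penalty_item` with its computed integer `points`.
#' @export
penalty_item <- function(name, category = c("reagent", "instrument",
                                            "occupational_hazard", "waste"),
                         pictogram_count = 0, signal_word = "none",
                         amount_bracket = NULL) {
  category <- match.arg(category)
  points <- switch(category,
    reagent = {
      qs_check(pictogram_count >= 0, "pictogram_count must be non-negative")
      qs_check(signal_word %in% names(eco_signal_mult),
               "signal_word must be none, warning or danger")
      qs_check(amount_bracket %in% names(eco_amount_mult),
               "unknown reagent amount bracket")
      pictogram_count * eco_signal_mult[[signal_word]] *
        eco_amount_mult[[amount_bracket]]
    },
    instrument = {
      qs_check(amount_bracket %in% names(eco_instrument_pts),
               "unknown instrument energy bracket")
      eco_instrument_pts[[amount_bracket]]
    },
    occupational_hazard = {
      qs_check(amount_bracket %in% names(eco_hazard_pts),
               "unknown occupational hazard bracket")
      eco_hazard_pts[[amount_bracket]]
    },
    waste = {
      qs_check(amount_bracket %in% names(eco_waste_pts),
               "unknown waste bracket")
      eco_waste_pts[[amount_bracket]]
    })
  structure(list(name = name, category = category,
                 pictogram_count = pictogram_count,
                 signal_word = signal_word, amount_bracket = amount_bracket,
                 points = as.integer(points)),
            class = "penalty_item")
}

#' Analytical Eco-scale score
#'
#' Sums the penalty points of all items and subtracts from a base of 100.
#' Scores above 75 rate "excellent", above 50 "acceptable", otherwise
#' "inadequate".
#'
#' @param items list of [penalty_item()] objects (possibly empty).
#' @return An `eco_scale_report`: `items`, `total_pp`, `score`, `verdict`.
#' @export
eco_scale <- function(items = list()) {
  qs_check(all(vapply(items, inherits, TRUE, "penalty_item")),
           "items must be penalty_item objects")
  total <- sum(vapply(items, function(i) i$points, 0L))
  score <- max(0L, 100L - total)
  verdict <- if (score > 75) "excellent"
             else if (score > 50) "acceptable" else "inadequate"
  structure(list(items = items, total_pp = total, score = score,
                 verdict = verdict),
            class = "eco_scale_report")
}

#' @export
print.eco_scale_report <- function(x, ...) {
  cat("<eco_scale_report> score ", x$score, " (", x$verdict, "), ",
      x$total_pp, " penalty points over ", length(x$items), " items\n",
      sep = "")
  for (i in x$items)
    cat(sprintf("  %-24s %-20s %3d PP\n", i$name, i$category, i$points))
  invisible(x)
}

#' Read Eco-scale items from a CSV file
#'
#' Columns: `name`, `category`, `pictogram_count`, `signal_word`,
#' `amount_bracket` (NA fields allowed where a category ignores them).
#'
#' @param path CSV path; the packaged item lists for the methanol-based
#'   procedure and the water-based reported method ship in `extdata`.
#' @return List of `penalty_item`s.
#' @export
read_eco_items <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    penalty_item(df$name[i], df$category[i],
                 pictogram_count = ifelse(is.na(df$pictogram_count[i]), 0,
                                          df$pictogram_count[i]),
                 signal_word = ifelse(is.na(df$signal_word[i]), "none",
                                      df$signal_word[i]),
                 amount_bracket = df$amount_bracket[i]))
}

#' AGREE-style greenness aggregation
#'
#' Weighted arithmetic mean of 12 per-principle scores in \[0, 1\]. Equal
#' weights by default. The per-principle rubric automation of the full AGREE
#' tool is out of scope: scores are direct numeric inputs.
#'
#' @param principle_scores numeric vector of 12 scores in \[0, 1\].
#' @param weights 12 positive weights (default equal).
#' @return An `agree_report`: `principle_scores`, `weights`, `overall`.
#' @export
agree_score <- function(principle_scores, weights = rep(1, 12)) {
  qs_check(length(principle_scores) == 12, "exactly 12 principle scores")
  qs_check(all(principle_scores >= 0 & principle_scores <= 1),
           "principle scores must lie in [0, 1]")
  qs_check(length(weights) == 12 && all(weights > 0),
           "12 positive weights required")
  structure(list(principle_scores = principle_scores, weights = weights,
                 overall = sum(principle_scores * weights) / sum(weights)),
            class = "agree_report")
}

#' @export
print.agree_report <- function(x, ...) {
  cat("<agree_report> overall ", format(x$overall, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Packaged greenness fixtures
#'
#' Convenience loaders for the shipped item lists: the methanol-based
#' procedure, the water-based reported comparator, and a *synthetic
#' reconstruction* of 12 AGREE principle scores (the published assessment
#' prints only the overall value; these per-principle scores are an editorial
#' reconstruction averaging to it, not published values).
#'
#' @return `eco_items_proposed()`/`eco_items_reported()` return item lists;
#'   `agree_scores_synthetic()` a numeric vector of 12 scores.
#' @export
eco_items_proposed <- function() read_eco_items(qs_extdata("eco_items_proposed.csv"))

#' @rdname eco_items_proposed
#' @export
eco_items_reported <- function() read_eco_items(qs_extdata("eco_items_reported21.csv"))

#' @rdname eco_items_proposed
#' @export
agree_scores_synthetic <- function() {
  df <- utils::read.csv(qs_extdata("agree_scores_synthetic.csv"))
  stats::setNames(df$score, df$principle)
}
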