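# Calibration design: five-level, four-factor concentration layout.

#' Default five-point concentration grids
#'
#' One strictly increasing grid of five levels per analyte (ug/mL), spanning
#' the working ranges of the quaternary mixture: PARA 4-20, ASC 3-15,
#' CAF 2.5-12.5, CPM 1-9. Coded levels -2..+2 index these grids.
#'
#' @return Named list of four numeric vectors of length 5.
#' @export
default_level_grids <- function() {
  list(PARA = c(4, 8, 12, 16, 20),
       ASC  = c(3, 6, 9, 12, 15),
       CAF  = c(2.5, 5, 7.5, 10, 12.5),
       CPM  = c(1, 3, 5, 7, 9))
}

check_level_grids <- function(level_grids) {
  qs_check(is.list(level_grids) && length(level_grids) == 4,
           "level_grids must be a list of 4 concentration grids")
  for (g in level_grids) {
    qs_check(is.numeric(g) && length(g) == 5,
             "each level grid must have exactly 5 concentrations")
    qs_check(all(g > 0) && all(diff(g) > 0),
             "each level grid must be strictly increasing and positive")
  }
  if (is.null(names(level_grids))) names(level_grids) <- analytes()
  level_grids
}

new_design_matrix <- function(sample_ids, nominal, coded, role, level_grids) {
  dimnames(nominal) <- list(sample_ids, names(level_grids))
  dimnames(coded) <- dimnames(nominal)
  structure(list(sample_ids = sample_ids, nominal = nominal, coded = coded,
                 role = role, level_grids = level_grids),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$nominal), " samples (",
      sum(x$role == "calibration"), " calibration, ",
      sum(x$role == "validation"), " validation); analytes: ",
      paste(colnames(x$nominal), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Convert nominal concentrations to coded levels
#'
#' Looks each concentration up in its analyte grid; entries not on the grid
#' (e.g. off-design validation mixtures) code as `NA`.
#'
#' @param nominal numeric matrix, samples x 4 analytes (ug/mL).
#' @param level_grids list of four 5-point grids (see [default_level_grids()]).
#' @return Integer matrix of coded levels in \{-2,...,+2\} (or NA off-grid).
#' @export
coded_from_nominal <- function(nominal, level_grids = default_level_grids()) {
  level_grids <- check_level_grids(level_grids)
  coded <- nominal
  for (j in seq_len(4)) {
    idx <- match(round(nominal[, j], 6), round(level_grids[[j]], 6))
    coded[, j] <- idx - 3L
  }
  coded
}

#' Convert coded levels back to nominal concentrations
#'
#' @inheritParams coded_from_nominal
#' @param coded integer matrix of levels in \{-2,...,+2\}.
#' @return Numeric matrix of concentrations (ug/mL).
#' @export
nominal_from_coded <- function(coded, level_grids = default_level_grids()) {
  level_grids <- check_level_grids(level_grids)
  nominal <- coded + 0.0
  for (j in seq_len(4)) nominal[, j] <- level_grids[[j]][coded[, j] + 3L]
  nominal
}

# cyclic five-level generator: one 24-long cyclic sequence of 0-based levels
# (center placed at every sixth position) is walked with a phase shift of six
# runs per factor, so run 1 is the all-center point for every factor, run 25
# wraps back onto it (replicated center, as in the published table), every
# factor visits all five levels, and no two factor columns coincide.
cyclic_coded_block <- function(n_factors = 4) {
  L <- c(2L, 0L, 1L, 3L, 4L, 1L,
         2L, 4L, 3L, 0L, 1L, 3L,
         2L, 1L, 4L, 3L, 0L, 0L,
         2L, 3L, 0L, 4L, 1L, 4L)
  coded <- matrix(0L, 25, n_factors)
  for (j in seq_len(n_factors)) {
    idx <- (seq_len(25) - 1L + 6L * (j - 1L)) %% 24L
    coded[, j] <- L[idx + 1L] - 2L
  }
  coded
}

#' Build the calibration + validation design
#'
#' Returns the 25-sample calibration block plus the 5-sample validation
#' hold-out. By default (`source = "table1"`) the literal published
#' concentration table is loaded from the packaged fixture, which is taken as
#' ground truth (including its duplicated center point in rows 1 and 25).
#' `source = "generated"` instead builds a fresh 25-run cyclic five-level
#' design from the grids (first row all-center; subsequent rows follow a
#' rotated difference sequence over coded levels) while keeping the same
#' published validation block.
#'
#' @param level_grids four 5-point concentration grids.
#' @param source `"table1"` (packaged fixture, default) or `"generated"`.
#' @return A `design_matrix`: sample ids, nominal (ug/mL) and coded matrices,
#'   and a role tag (`calibration`/`validation`) per sample.
#' @export
generate_design <- function(level_grids = default_level_grids(),
                            source = c("table1", "generated")) {
  level_grids <- check_level_grids(level_grids)
  source <- match.arg(source)
  tab <- utils::read.csv(qs_extdata("design_table1.csv"),
                         stringsAsFactors = FALSE)
  if (source == "table1") {
    nominal <- as.matrix(tab[, analytes()])
    ids <- tab$sample_id
    role <- tab$role
  } else {
    coded_cal <- cyclic_coded_block(4)
    nominal_cal <- nominal_from_coded(coded_cal, level_grids)
    val <- tab[tab$role == "validation", ]
    nominal <- rbind(nominal_cal, as.matrix(val[, analytes()]))
    ids <- c(sprintf("gen%02d", 1:25), val$sample_id)
    role <- c(rep("calibration", 25), rep("validation", 5))
  }
  coded <- coded_from_nominal(nominal, level_grids)
  new_design_matrix(ids, nominal, coded, role, level_grids)
}

#' Subset a design by role
#'
#' @param design a `design_matrix`.
#' @param role `"calibration"`, `"validation"` or any tag present.
#' @return A `design_matrix` containing only the requested rows.
#' @export
design_subset <- function(design, role) {
  keep <- design$role == role
  qs_check(any(keep), paste("no samples with role", role))
  new_design_matrix(design$sample_ids[keep],
                    design$nominal[keep, , drop = FALSE],
                    design$coded[keep, , drop = FALSE],
                    design$role[keep], design$level_grids)
}

#' Write / read a design as CSV
#'
#' Columns: `sample_id`, the four analytes (ug/mL) and `role`.
#'
#' @param design a `design_matrix`.
#' @param path file path.
#' @return `read_design_csv` returns a `design_matrix`.
#' @export
write_design_csv <- function(design, path) {
  df <- data.frame(sample_id = design$sample_ids,
                   design$nominal, role = design$role,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param level_grids grids used to recompute coded levels.
#' @export
read_design_csv <- function(path, level_grids = default_level_grids()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nominal <- as.matrix(df[, analytes()])
  new_design_matrix(df$sample_id, nominal,
                    coded_from_nominal(nominal, level_grids),
                    df$role, check_level_grids(level_grids))
}
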