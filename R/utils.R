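# Internal helpers shared across modules.

#' Canonical analyte order
#'
#' All containers in the package carry analyte names explicitly; this constant
#' fixes the canonical column order (the order of the published calibration
#' table): paracetamol, ascorbic acid, caffeine, chlorpheniramine maleate.
#'
#' @return Character vector of the four analyte codes.
#' @export
analytes <- function() c("PARA", "ASC", "CAF", "CPM")

# path to a packaged data file
qs_extdata <- function(file) {
  path <- system.file("extdata", file, package = "quatspec")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

# all permutations of 1..n (n small); used for component matching
all_perms <- function(n) {
  stopifnot(n >= 1, n <= 7)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# stopifnot with a readable message
qs_check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
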