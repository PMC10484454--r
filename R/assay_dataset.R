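#' Per-animal assay dataset
#'
#' The common currency of all statistics in the package: a data frame of
#' per-animal (or per-nucleus) records for one assay across genotypes, with
#' an `assay` attribute naming the assay and a fixed value-column schema.
#'
#' Schemas (beyond `genotype` and `animal_id`):
#' \describe{
#'   \item{viability}{`brood` (total eggs laid, integer >= 0), `unhatched`
#'     (integer, `0 <= unhatched <= brood`), and the three daily counts
#'     `eggs_day1..eggs_day3` summing to `brood` when present.}
#'   \item{swimming}{`bbps` (body bends per second, >= 0).}
#'   \item{migration}{`mislocalized` (nuclei stranded in the dorsal cord,
#'     integer in `[0, nuclei_total]`), optional `nuclei_total`.}
#'   \item{morphology}{`blebs` (nuclear blebs on one lateral side,
#'     integer >= 0).}
#'   \item{fluorescence}{`intensity` (arbitrary units, finite real).}
#' }
#'
#' @param records A data frame with at least `genotype`, `animal_id` and the
#'   assay's value columns.
#' @param assay Assay name.
#' @param units Optional unit note stored as metadata.
#' @return The data frame with class `assay_dataset` and attributes `assay`
#'   and `units`.
#' @export
assay_dataset <- function(records,
                          assay = c("viability", "swimming", "migration",
                                    "morphology", "fluorescence"),
                          units = NULL) {
  assay <- match.arg(assay)
  stopifnot(is.data.frame(records))
  out <- as.data.frame(records, stringsAsFactors = FALSE)
  attr(out, "assay") <- assay
  attr(out, "units") <- units
  class(out) <- c("assay_dataset", "data.frame")
  validate_assay_dataset(out)
  out
}

assay_value_column <- function(assay) {
  switch(assay,
         viability = "brood", swimming = "bbps", migration = "mislocalized",
         morphology = "blebs", fluorescence = "intensity")
}

#' Validate an assay dataset against its schema
#'
#' @param x An `assay_dataset`.
#' @return `x` invisibly; validation failures name the offending column and
#'   row rather than silently coercing.
#' @export
validate_assay_dataset <- function(x) {
  if (!inherits(x, "assay_dataset"))
    stop("not an assay_dataset", call. = FALSE)
  assay <- attr(x, "assay")
  need <- c("genotype", "animal_id", assay_value_column(assay))
  if (assay == "viability") need <- c(need, "unhatched")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("assay '", assay, "': missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  check_num <- function(col, integer = FALSE, nonneg = TRUE) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) &
                     !is.na(v))
      stop("column '", col, "' is not numeric (e.g. row ",
           if (length(bad)) bad[1] else 1, ")", call. = FALSE)
    }
    if (any(!is.finite(v)))
      stop("column '", col, "' has non-finite value at row ",
           which(!is.finite(v))[1], call. = FALSE)
    if (nonneg && any(v < 0))
      stop("column '", col, "' has negative value at row ",
           which(v < 0)[1], call. = FALSE)
    if (integer && any(v != round(v)))
      stop("column '", col, "' has non-integer count at row ",
           which(v != round(v))[1], call. = FALSE)
  }
  switch(assay,
    viability = {
      check_num("brood", integer = TRUE)
      check_num("unhatched", integer = TRUE)
      bad <- which(x$unhatched > x$brood)
      if (length(bad))
        stop("column 'unhatched' exceeds 'brood' at row ", bad[1],
             call. = FALSE)
    },
    swimming = check_num("bbps"),
    migration = {
      check_num("mislocalized", integer = TRUE)
      if ("nuclei_total" %in% names(x)) {
        check_num("nuclei_total", integer = TRUE)
        bad <- which(x$mislocalized > x$nuclei_total)
        if (length(bad))
          stop("column 'mislocalized' exceeds 'nuclei_total' at row ",
               bad[1], call. = FALSE)
      }
    },
    morphology = check_num("blebs", integer = TRUE),
    fluorescence = check_num("intensity", nonneg = FALSE))
  invisible(x)
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat("<assay_dataset> assay:", attr(x, "assay"),
      "|", nrow(x), "records,", length(unique(x$genotype)), "genotypes\n")
  NextMethod()
}

# subsetting keeps the class and attributes
#' @export
`[.assay_dataset` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "assay") <- attr(x, "assay")
    attr(out, "units") <- attr(x, "units")
    class(out) <- c("assay_dataset", "data.frame")
  }
  out
}
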