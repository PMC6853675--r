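#' @include AllClasses.R
NULL

## Required columns of a raw activity export (ChEMBL-style field names).
rawColumns <- c("molecule_id", "smiles", "standard_value", "standard_units",
                "standard_relation", "target_type", "organism")

#' Read a raw molecule-activity table
#'
#' Reads a ChEMBL-style CSV export. Required columns: `molecule_id` (falls
#' back to `canonical_smiles` as identifier when absent), `smiles` (or
#' `canonical_smiles`), `standard_value`, `standard_units`,
#' `standard_relation`, `target_type`, `organism`.
#'
#' @param path CSV file with a header row.
#' @return data.frame of raw activity records with the canonical column
#'   names above.
#' @export
readActivityRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!"smiles" %in% names(df) && "canonical_smiles" %in% names(df))
    df$smiles <- df$canonical_smiles
  if (!"molecule_id" %in% names(df)) {
    if ("canonical_smiles" %in% names(df)) df$molecule_id <- df$canonical_smiles
    else stop("no 'molecule_id' (or 'canonical_smiles' fallback) column in ", path)
  }
  missing <- setdiff(rawColumns, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  df[rawColumns]
}

eqFold <- function(x, target) {
  !is.na(x) & tolower(trimws(x)) == tolower(target)
}

#' Filter raw activity records by the curation criteria
#'
#' Keeps only records with (i) activity unit 'nM', (ii) activity relation
#' '=', (iii) target type 'SINGLE PROTEIN' and (iv) organism 'Homo sapiens'.
#' Matching is case-insensitive after trimming (export casing varies), order
#' is preserved, and records with missing value or unit are dropped. The
#' counts removed per criterion are reported via `message()` and attached as
#' the `"filterLog"` attribute.
#'
#' @param records data.frame of raw records (see [readActivityRecords()]).
#' @return Filtered data.frame (possibly 0 rows, with a warning).
#' @export
filterActivityRecords <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(rawColumns, names(records))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  n0 <- nrow(records)
  crit <- list(
    value_present = !is.na(suppressWarnings(as.numeric(records$standard_value))),
    unit_nM = eqFold(records$standard_units, "nM"),
    relation_eq = eqFold(records$standard_relation, "="),
    single_protein = eqFold(records$target_type, "SINGLE PROTEIN"),
    homo_sapiens = eqFold(records$organism, "Homo sapiens"))
  keep <- Reduce(`&`, crit)
  dropped <- vapply(crit, function(ok) sum(!ok), integer(1))
  message(sprintf("curation: %d of %d records retained (dropped per criterion: %s)",
                  sum(keep), n0,
                  paste(names(dropped), dropped, sep = "=", collapse = ", ")))
  out <- records[keep, , drop = FALSE]
  if (!nrow(out)) warning("no records survive the curation filters")
  attr(out, "filterLog") <- dropped
  out
}

## Concentration units convertible to molar.
unitToMolar <- c(m = 1, mm = 1e-3, um = 1e-6, "µm" = 1e-6, nm = 1e-9,
                 pm = 1e-12)

#' Convert an IC50 concentration to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the IC50 expressed in molar,
#' so 100 nM becomes 7 and 1 nM becomes 9. Strictly decreasing in the
#' concentration: more potent compounds (lower IC50) score higher.
#'
#' @param value positive IC50 value(s).
#' @param unit concentration unit: one of "M", "mM", "uM", "nM", "pM"
#'   (case-insensitive; recycled to the length of `value`).
#' @return Numeric pIC50 value(s).
#' @examples
#' toPIC50(100, "nM")  # 7
#' @export
toPIC50 <- function(value, unit = "nM") {
  value <- as.numeric(value)
  if (any(is.na(value)) || any(value <= 0))
    stop("IC50 values must be positive numbers")
  key <- tolower(trimws(unit))
  factor <- unitToMolar[key]
  if (any(is.na(factor)))
    stop("unknown concentration unit(s): ",
         paste(unique(unit[is.na(factor)]), collapse = ", "))
  unname(-log10(value * factor))
}

#' Collapse replicate measurements into one activity per molecule
#'
#' Converts each filtered record to pIC50 and averages replicates on the
#' pIC50 (log) scale, one entry per molecule id. The first SMILES seen for a
#' molecule is retained.
#'
#' @param records filtered data.frame (see [filterActivityRecords()]).
#' @return An [ActivityDataset-class] with one row per distinct molecule id,
#'   in first-appearance order.
#' @examples
#' recs <- data.frame(molecule_id = c("a", "a"), smiles = "C",
#'                    standard_value = c(10, 1000), standard_units = "nM",
#'                    standard_relation = "=", target_type = "SINGLE PROTEIN",
#'                    organism = "Homo sapiens")
#' activities(collapseReplicates(recs))  # (8 + 6) / 2 = 7
#' @export
collapseReplicates <- function(records) {
  stopifnot(is.data.frame(records))
  if (!nrow(records))
    return(ActivityDataset(character(), numeric()))
  p <- toPIC50(records$standard_value, records$standard_units)
  ids <- as.character(records$molecule_id)
  uid <- unique(ids)
  act <- vapply(split(p, factor(ids, levels = uid)), mean, numeric(1))
  sm <- if ("smiles" %in% names(records))
    vapply(split(as.character(records$smiles), factor(ids, levels = uid)),
           `[`, character(1), 1L)
  else character()
  ActivityDataset(uid, unname(act), unname(sm))
}

#' Write / read the curated activity CSV
#'
#' The curated format is the contract between curation and the rest of the
#' pipeline: columns `molecule_id`, `pic50` and, when structures are
#' available, `smiles`.
#'
#' @param dataset an [ActivityDataset-class].
#' @param path CSV path.
#' @return `path` (write) or an [ActivityDataset-class] (read).
#' @export
writeCuratedActivities <- function(dataset, path) {
  stopifnot(is(dataset, "ActivityDataset"))
  df <- data.frame(molecule_id = moleculeIds(dataset),
                   pic50 = activities(dataset))
  if (!is.null(moleculeSmiles(dataset))) df$smiles <- moleculeSmiles(dataset)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCuratedActivities
#' @export
readCuratedActivities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("molecule_id", "pic50") %in% names(df)))
    stop("curated CSV must have columns 'molecule_id' and 'pic50': ", path)
  sm <- if ("smiles" %in% names(df)) df$smiles else character()
  ActivityDataset(df$molecule_id, df$pic50, sm)
}

#' Curate a raw activity table end to end
#'
#' Reads, filters, converts to pIC50 and collapses replicates. A two-column
#' pre-curated file (`molecule_id`, `pic50`) is detected and passed through
#' unchanged.
#'
#' @param path raw (or pre-curated) CSV path.
#' @return An [ActivityDataset-class].
#' @export
curateActivityTable <- function(path) {
  header <- tolower(names(utils::read.csv(path, nrows = 1L, check.names = FALSE)))
  if ("pic50" %in% header)
    return(readCuratedActivities(path))
  collapseReplicates(filterActivityRecords(readActivityRecords(path)))
}
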