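#' @include AllClasses.R
NULL

## The cheminformatics steps run through ChemmineR/ChemmineOB (Open Babel).
## They are optional: the statistical core only needs a FingerprintMatrix,
## which can be loaded from CSV, so the packages live in Suggests.
needChemmine <- function() {
  ok <- requireNamespace("ChemmineR", quietly = TRUE) &&
        requireNamespace("ChemmineOB", quietly = TRUE)
  if (!ok)
    stop("structure handling needs the 'ChemmineR' and 'ChemmineOB' packages; ",
         "install them or supply a precomputed fingerprint CSV", call. = FALSE)
}

#' Standardize a structure: keep the largest organic fragment
#'
#' Multi-component SMILES (salts, counterions) are reduced to their largest
#' fragment by heavy-atom count; a molecule is rejected when no fragment
#' contains carbon ("inorganic") or when the SMILES cannot be parsed.
#' Rejections are returned as `NA` so callers can drop and log them rather
#' than abort a curation run.
#'
#' @param smiles character vector of SMILES strings.
#' @return Character vector of canonical SMILES of the largest organic
#'   fragment, `NA` where the molecule was rejected.
#' @examples
#' \dontrun{standardizeStructure("CCO.[Na+].[Cl-]")  # "CCO"}
#' @export
standardizeStructure <- function(smiles) {
  needChemmine()
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    counts <- lapply(frags, function(f) {
      tryCatch({
        sdf <- suppressWarnings(ChemmineR::smiles2sdf(f))
        tab <- ChemmineR::atomcount(sdf)[[1]]
        list(heavy = sum(tab[!names(tab) %in% c("H", "h")]),
             carbon = sum(tab[names(tab) %in% c("C", "c")]))
      }, error = function(e) NULL)
    })
    ok <- !vapply(counts, is.null, logical(1))
    if (!any(ok)) return(NA_character_)
    organic <- ok & vapply(counts, function(x) !is.null(x) && x$carbon > 0, logical(1))
    if (!any(organic)) return(NA_character_)
    heavy <- vapply(counts, function(x) if (is.null(x)) -1L else as.integer(x$heavy),
                    integer(1))
    heavy[!organic] <- -1L
    best <- frags[which.max(heavy)]
    canon <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(best, "\tm\n")),
      error = function(e) NA_character_)
    if (is.na(canon)) return(NA_character_)
    sub("[\t ].*$", "", trimws(canon))
  }, character(1), USE.NAMES = FALSE)
}

## Fold a wide hashed fingerprint down to nBits by OR-ing bit blocks
## (position j maps to j mod nBits), the standard folding scheme.
foldBits <- function(bits, nBits) {
  p <- length(bits)
  if (p %% nBits != 0)
    stop("fingerprint length ", p, " is not a multiple of ", nBits)
  as.integer(colSums(matrix(bits, nrow = p %/% nBits, byrow = TRUE)) > 0)
}

#' Circular (Morgan-style) fingerprints
#'
#' Computes hashed circular fingerprints of the given radius via Open
#' Babel's ECFP implementation (diameter = 2 * radius) and folds them to
#' `nBits` bits. Deterministic: the same standardized SMILES always yields
#' the same bit vector. Bit patterns are toolkit-specific; none of the
#' statistical machinery depends on which toolkit hashed them.
#'
#' @param smiles character vector of (standardized) SMILES.
#' @param radius circular neighbourhood radius (default 2).
#' @param nBits folded fingerprint length (default 128).
#' @return A [FingerprintMatrix-class] with one row per input molecule;
#'   unparseable SMILES raise an error naming the offenders.
#' @param ids molecule identifiers for the rows (default the SMILES).
#' @export
morganFingerprint <- function(smiles, radius = 2L, nBits = 128L, ids = smiles) {
  needChemmine()
  if (!radius %in% 0:5) stop("'radius' must be in 0..5")
  smiles <- as.character(smiles)
  bad <- !nzchar(smiles) | is.na(smiles)
  if (any(bad))
    stop("unparseable/empty SMILES at position(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  fpName <- paste0("ECFP", 2L * as.integer(radius))
  input <- paste0(paste(smiles, collapse = "\n"), "\n")
  wide <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SMILES", input, identity), fpName)
  if (is.null(dim(wide))) wide <- matrix(wide, nrow = 1L)
  if (nrow(wide) != length(smiles))
    stop("Open Babel parsed ", nrow(wide), " of ", length(smiles), " SMILES")
  empty <- rowSums(wide) == 0
  if (any(empty))
    stop("no fingerprint bits for SMILES: ",
         paste(utils::head(smiles[empty], 5), collapse = ", "))
  folded <- t(apply(wide, 1L, foldBits, nBits = as.integer(nBits)))
  rownames(folded) <- ids
  FingerprintMatrix(folded)
}

#' Fingerprint the molecules of a curated dataset
#'
#' Standardizes each SMILES, drops molecules that fail standardization
#' (logged via `message()`), and fingerprints the survivors.
#'
#' @param dataset an [ActivityDataset-class] carrying SMILES.
#' @param radius,nBits see [morganFingerprint()].
#' @return List with `fingerprints` ([FingerprintMatrix-class]), `dataset`
#'   (the input restricted to fingerprinted molecules) and `dropped`
#'   (character vector of rejected molecule ids).
#' @export
fingerprintMolecules <- function(dataset, radius = 2L, nBits = 128L) {
  stopifnot(is(dataset, "ActivityDataset"))
  sm <- moleculeSmiles(dataset)
  if (is.null(sm)) stop("dataset carries no SMILES")
  std <- standardizeStructure(sm)
  ok <- !is.na(std)
  if (!all(ok))
    message(sprintf("dropped %d molecule(s) failing standardization: %s",
                    sum(!ok),
                    paste(utils::head(moleculeIds(dataset)[!ok], 5), collapse = ", ")))
  if (!any(ok)) stop("no molecule survived standardization")
  kept <- which(ok)
  fps <- morganFingerprint(std[kept], radius = radius, nBits = nBits,
                           ids = moleculeIds(dataset)[kept])
  list(fingerprints = fps, dataset = dataset[kept],
       dropped = moleculeIds(dataset)[!ok])
}

#' Load / write a fingerprint matrix CSV
#'
#' The fingerprint CSV has a `molecule_id` column followed by P binary
#' columns (`fp_0` .. `fp_<P-1>`). Loading validates that every entry is 0
#' or 1 (errors name the first offending row and column) and that rows are
#' complete; [runExperiment()] later checks the ids against the activity
#' table and names any mismatches.
#'
#' @param path CSV path.
#' @return A [FingerprintMatrix-class] (load) or `path` (write).
#' @export
loadFingerprintMatrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[1] <- tolower(names(df)[1])
  if (names(df)[1] != "molecule_id")
    stop("first column of ", path, " must be 'molecule_id'")
  ids <- as.character(df[[1]])
  bits <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(bits)) {
    col <- which(!vapply(df[-1], is.numeric, logical(1)))[1] + 1L
    stop(sprintf("non-numeric fingerprint entries in column %d ('%s') of %s",
                 col, names(df)[col], path))
  }
  offending <- which(!(bits == 0 | bits == 1), arr.ind = TRUE)
  if (nrow(offending))
    stop(sprintf("non-binary entry %s at row %d, column '%s' of %s",
                 format(bits[offending[1, 1], offending[1, 2]]),
                 offending[1, 1], colnames(bits)[offending[1, 2]], path))
  rownames(bits) <- ids
  FingerprintMatrix(bits)
}

#' @rdname loadFingerprintMatrix
#' @param fps a [FingerprintMatrix-class] to write.
#' @export
writeFingerprintMatrix <- function(fps, path) {
  stopifnot(is(fps, "FingerprintMatrix"))
  bits <- fpBits(fps)
  df <- data.frame(molecule_id = rownames(bits), bits,
                   check.names = FALSE, row.names = NULL)
  names(df)[-1] <- paste0("fp_", seq_len(ncol(bits)) - 1L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
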