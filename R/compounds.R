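#' Read a compound collection from disk
#'
#' Reads molecules from one of three plain-text formats and returns one row
#' per input entry, in input order. Entries whose SMILES cannot be parsed are
#' kept as rows with `valid = FALSE` and a `failure_reason`; parsing problems
#' never abort the read. Identifiers are made unique by deterministic
#' suffixing (`"dup"`, `"dup.2"`, ...) so downstream joins are safe.
#'
#' Supported formats:
#' \describe{
#'   \item{`smi`}{One `SMILES[whitespace]ID` per line; the ID is optional
#'     (missing IDs become `mol<line>`); lines starting with `#` and blank
#'     lines are ignored.}
#'   \item{`csv`}{UTF-8 with a header row; requires a `smiles` column
#'     (case-insensitive) and uses an `id` column when present.}
#'   \item{`sdf`}{V2000 SD file; the molecule title is used as the ID.}
#' }
#'
#' @param path Path to the input file.
#' @param format One of `"auto"`, `"smi"`, `"csv"`, `"sdf"`. `"auto"` picks by
#'   file extension.
#' @return A tibble with columns `id`, `smiles`, `valid`, `failure_reason`.
#' @examples
#' \dontrun{
#' read_compounds("actives.smi")
#' }
#' @export
read_compounds <- function(path, format = c("auto", "smi", "csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      smi = "smi", smiles = "smi",
      csv = "csv",
      sdf = "sdf", sd = "sdf", mol = "sdf",
      stop("cannot infer format from extension '.", ext,
           "'; pass format= explicitly", call. = FALSE)
    )
  }
  raw <- switch(format,
    smi = read_smi_entries(path),
    csv = read_csv_entries(path),
    sdf = read_sdf_entries(path)
  )
  compound_tbl(raw$smiles, raw$id)
}

read_smi_entries <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  smiles <- sub("\\s.*$", "", lines)
  id <- ifelse(grepl("\\s", lines), sub("^\\S+\\s+", "", lines), "")
  id <- trimws(id)
  id[id == ""] <- paste0("mol", which(id == ""))
  list(smiles = smiles, id = id)
}

read_csv_entries <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  smi_col <- which(tolower(names(tbl)) == "smiles")
  if (length(smi_col) == 0) {
    stop("CSV input must contain a 'smiles' column (case-insensitive)",
         call. = FALSE)
  }
  id_col <- which(tolower(names(tbl)) == "id")
  id <- if (length(id_col) > 0) as.character(tbl[[id_col[1]]]) else
    paste0("mol", seq_len(nrow(tbl)))
  list(smiles = as.character(tbl[[smi_col[1]]]), id = id)
}

read_sdf_entries <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  id <- vapply(ChemmineR::SDFset2list(sdf), function(x) x$header[["Molecule_Name"]], "")
  id <- trimws(id)
  id[is.na(id) | id == ""] <- paste0("mol", which(is.na(id) | id == ""))
  smiles <- rep(NA_character_, length(sdf))
  ok <- ChemmineR::validSDF(sdf)
  if (any(ok)) {
    smi <- tryCatch(ChemmineR::sdf2smiles(sdf[which(ok)]),
                    error = function(e) NULL)
    if (!is.null(smi)) smiles[which(ok)] <- as.character(smi)
  }
  smiles[is.na(smiles)] <- ""
  list(smiles = smiles, id = id)
}

#' Build a compound table from SMILES strings
#'
#' Validates each SMILES with the chemistry engine and returns the standard
#' compound tibble used throughout the package. A compound is `valid` only if
#' its SMILES parses to a molecule with at least one heavy atom.
#'
#' @param smiles Character vector of SMILES strings.
#' @param id Optional identifiers (defaults to `mol1`, `mol2`, ...);
#'   duplicates are suffixed deterministically.
#' @return A tibble with columns `id`, `smiles`, `valid`, `failure_reason`.
#' @examples
#' \dontrun{
#' compound_tbl(c("CCO", "c1ccccc1"), c("ethanol", "benzene"))
#' }
#' @export
compound_tbl <- function(smiles, id = NULL) {
  smiles <- as.character(smiles)
  n <- length(smiles)
  if (is.null(id)) id <- paste0("mol", seq_len(n))
  id <- as.character(id)
  stopifnot(length(id) == n)
  id <- make.unique(id, sep = "_dup")

  valid <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  bad_syntax <- is.na(smiles) | trimws(smiles) == ""
  reason[bad_syntax] <- "empty SMILES"
  check <- which(!bad_syntax)
  if (length(check) > 0) {
    parsed <- parse_smiles_batch(smiles[check])
    valid[check] <- parsed$ok
    reason[check][!parsed$ok] <- parsed$reason[!parsed$ok]
  }
  tibble::tibble(id = id, smiles = smiles, valid = valid,
                 failure_reason = reason)
}

# Batch SMILES validation through OpenBabel. The batch conversion aborts at
# the first unparseable entry, so anything missing from the batch result is
# retried individually before being declared invalid. The heavy-atom
# requirement is checked on the SMILES text (ChemmineR's atom blocks are not
# reliable for bondless molecules).
parse_smiles_batch <- function(smiles) {
  nm <- paste0("q", seq_along(smiles))
  names(smiles) <- nm
  sdf <- suppressWarnings(tryCatch(ChemmineR::smiles2sdf(smiles),
                                   error = function(e) NULL))
  parsed <- if (is.null(sdf)) character(0) else ChemmineR::cid(sdf)
  retry <- setdiff(nm, parsed)
  for (q in retry) {
    one <- suppressWarnings(tryCatch(
      ChemmineR::smiles2sdf(smiles[q]), error = function(e) NULL))
    if (!is.null(one) && length(one) > 0) parsed <- c(parsed, q)
  }
  ok <- nm %in% parsed &
    vapply(smiles, heavy_atoms_in_smiles, numeric(1), USE.NAMES = FALSE) >= 1
  reason <- ifelse(ok, NA_character_,
                   "SMILES failed to parse to a molecule with >= 1 heavy atom")
  list(ok = ok, reason = reason)
}

#' Deduplicate compounds by canonical SMILES
#'
#' Collapses repeated structures (e.g. the same molecule reported by several
#' studies) to their first occurrence, comparing OpenBabel canonical SMILES so
#' that different SMILES spellings of one structure count as duplicates.
#' Invalid rows are kept untouched.
#'
#' @param compounds Compound tibble from [read_compounds()] or
#'   [compound_tbl()].
#' @return The input tibble with duplicate valid structures removed.
#' @export
dedupe_compounds <- function(compounds) {
  check_compound_tbl(compounds)
  valid_idx <- which(compounds$valid)
  if (length(valid_idx) < 2) return(compounds)
  can <- canonical_smiles(compounds$smiles[valid_idx])
  drop <- valid_idx[duplicated(can)]
  if (length(drop) > 0) compounds <- compounds[-drop, , drop = FALSE]
  compounds
}

canonical_smiles <- function(smiles) {
  nm <- paste0("q", seq_along(smiles))
  names(smiles) <- nm
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  out <- rep(NA_character_, length(smiles))
  with_bonds <- ChemmineR::validSDF(sdf)
  if (any(with_bonds)) {
    sub <- sdf[which(with_bonds)]
    out[match(ChemmineR::cid(sub), nm)] <- ChemmineR::propOB(sub)$cansmi
  }
  for (q in ChemmineR::cid(sdf)[!with_bonds]) {
    p <- ChemmineOB::forEachMol("SMILES", smiles[[q]],
                                function(m) ChemmineOB::prop_OB(m))[[1]]
    out[match(q, nm)] <- p$cansmi
  }
  out
}

check_compound_tbl <- function(x) {
  need <- c("id", "smiles", "valid")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("expected a compound table with columns id, smiles, valid ",
         "(see read_compounds())", call. = FALSE)
  }
  invisible(x)
}
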