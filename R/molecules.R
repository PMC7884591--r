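#' Read molecules from a SMILES or SDF file
#'
#' Parses compound structures into a molecule table. SMILES files hold one
#' record per line (`SMILES` optionally followed by whitespace and an
#' identifier); SDF files are V2000 connection tables. Records that fail to
#' parse are skipped with a message naming their position, so a single corrupt
#' entry does not abort a library read. Parsing goes through OpenBabel (via
#' ChemmineR/ChemmineOB), which perceives aromaticity and leaves hydrogens
#' implicit, so the same molecule read from SMILES or SDF yields the same
#' canonical structure and hence identical fingerprints.
#'
#' @param path Path to the structure file.
#' @param format `"smiles"` or `"sdf"`. Defaults from the file extension
#'   (`.smi`/`.smiles` vs `.sdf`/`.mol`).
#' @return A tibble with one row per successfully parsed record: `id`
#'   (non-empty, made unique if duplicated), `molecule` (list-column of
#'   `ChemmineR::SDF` objects) and `source` (file and record index).
#' @examples
#' smi <- tempfile(fileext = ".smi")
#' writeLines(c("CCO eth", "c1ccccc1 benz"), smi)
#' read_molecules(smi)
#' @export
read_molecules <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("structure file not found: ", path), class = "dockcal_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      smi = , smiles = , ism = "smiles",
      sdf = , mol = , mdl = "sdf",
      abort(paste0("cannot infer format from extension '.", ext,
                   "'; pass format explicitly"), class = "dockcal_io_error")
    )
  }
  mols <- switch(format,
    smiles = read_molecules_smiles(path),
    sdf = read_molecules_sdf(path)
  )
  if (nrow(mols) == 0L) {
    abort(paste0("no valid molecules in ", path), class = "dockcal_data_error")
  }
  if (anyDuplicated(mols$id)) {
    warn("duplicate molecule ids; making unique with suffixes")
    mols$id <- make.unique(mols$id, sep = "_")
  }
  mols
}

read_molecules_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) {
    abort(paste0("no SMILES records in ", path), class = "dockcal_data_error")
  }
  tok <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  smiles <- vapply(tok, `[[`, character(1), 1L)
  ids <- vapply(tok, function(t) if (length(t) >= 2L) t[[2L]] else NA_character_,
                character(1))
  ids <- ifelse(is.na(ids) | !nzchar(ids), paste0("mol_", keep), ids)
  parsed <- parse_smiles(smiles, ids)
  skipped <- setdiff(seq_along(keep), parsed$ok)
  for (k in skipped) {
    inform(paste0("skipping unparseable SMILES at line ", keep[k],
                  " (", smiles[k], ")"))
  }
  tibble::tibble(
    id = ids[parsed$ok],
    molecule = parsed$mols,
    source = paste0(basename(path), ":line", keep[parsed$ok])
  )
}

# Batch conversion aborts at the first bad record, so fall back to a
# per-record loop when the batch comes back short.
parse_smiles <- function(smiles, ids) {
  batch <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, ids))),
    error = function(e) NULL
  )
  if (!is.null(batch) && length(batch) == length(smiles)) {
    return(list(ok = seq_along(smiles), mols = as.list(batch@SDF)))
  }
  ok <- integer(0)
  mols <- list()
  for (i in seq_along(smiles)) {
    one <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles[i], ids[i]))),
      error = function(e) NULL
    )
    if (!is.null(one) && length(one) == 1L) {
      ok <- c(ok, i)
      mols <- c(mols, as.list(one@SDF))
    }
  }
  list(ok = ok, mols = mols)
}

read_molecules_sdf <- function(path) {
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) abort(paste0("cannot read SDF file ", path, ": ",
                                     conditionMessage(e)),
                              class = "dockcal_io_error")
  )
  valid <- ChemmineR::validSDF(sdfset)
  for (k in which(!valid)) {
    inform(paste0("skipping invalid SDF record ", k))
  }
  sdfset <- sdfset[valid]
  if (length(sdfset) == 0L) {
    return(tibble::tibble(id = character(), molecule = list(),
                          source = character()))
  }
  ids <- unname(ChemmineR::sdfid(sdfset))
  ids[is.na(ids) | !nzchar(ids)] <- paste0("mol_", which(is.na(ids) | !nzchar(ids)))
  tibble::tibble(
    id = ids,
    molecule = as.list(sdfset@SDF),
    source = paste0(basename(path), ":record", which(valid))
  )
}

heavy_atom_counts <- function(mols) {
  vapply(mols$molecule, function(m) {
    ab <- ChemmineR::atomblock(m)
    sum(!grepl("^H(_|$)", rownames(ab)))
  }, integer(1))
}
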