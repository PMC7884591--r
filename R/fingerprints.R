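#' Compute 2D fingerprints for a molecule table
#'
#' Computes one of the four OpenBabel 2D fingerprints for every molecule:
#' `FP2`, a path-based fingerprint hashing linear fragments of up to 7 heavy
#' atoms into 1024 bits; `FP3` (55 SMARTS patterns); `FP4` (307 SMARTS
#' patterns); or `MACCS` (the 166 public structural keys). OpenBabel stores the
#' SMARTS-based fingerprints padded to word multiples; the padding bits are
#' always zero and are dropped so that `nbits` is the canonical length.
#' Fingerprinting is deterministic: the same structure always yields the same
#' bits, whether parsed from SMILES or SDF.
#'
#' @param molecules A molecule table from [read_molecules()] (columns `id`,
#'   `molecule`).
#' @param fp_type One of `"FP2"`, `"FP3"`, `"FP4"`, `"MACCS"`.
#' @return A fingerprint table: tibble with columns `id`, `fp_type`, `nbits`
#'   and `bits` (list-column of logical vectors of length `nbits`).
#' @examples
#' smi <- tempfile(fileext = ".smi")
#' writeLines("c1ccccc1 benz", smi)
#' fps <- compute_fingerprints(read_molecules(smi), "FP2")
#' sum(fps$bits[[1]])
#' @export
compute_fingerprints <- function(molecules, fp_type = c("FP2", "FP3", "FP4", "MACCS")) {
  fp_type <- match.arg(fp_type)
  stopifnot(is.data.frame(molecules), all(c("id", "molecule") %in% names(molecules)))
  if (nrow(molecules) == 0L) {
    abort("no molecules to fingerprint", class = "dockcal_data_error")
  }
  heavy <- heavy_atom_counts(molecules)
  if (any(heavy < 1L)) {
    abort(paste0("molecule(s) without heavy atoms: ",
                 paste(molecules$id[heavy < 1L], collapse = ", ")),
          class = "dockcal_data_error")
  }
  sdfset <- methods::new("SDFset", SDF = molecules$molecule,
                         ID = molecules$id)
  fpset <- ChemmineR::fingerprintOB(sdfset, fp_type)
  mat <- fpset@fpma
  nbits <- FP_NBITS[[fp_type]]
  mat <- mat[, seq_len(nbits), drop = FALSE]
  tibble::tibble(
    id = molecules$id,
    fp_type = fp_type,
    nbits = nbits,
    bits = lapply(seq_len(nrow(mat)), function(i) mat[i, ] != 0)
  )
}

#' Read precomputed fingerprints from a hex table
#'
#' Loads externally computed fingerprints (for example Open Babel
#' `babel -ofpt` output post-processed to hex) so that bit-exact similarities
#' from another toolkit can drive the calibration. The table is CSV or TSV
#' with header `id,fp_hex,nbits`; `fp_hex` is the bit vector in big-endian bit
#' order (first hex digit encodes bits 1--4, most significant bit first).
#'
#' @param path Path to the table.
#' @return A fingerprint table with `fp_type = "EXTERNAL"`.
#' @examples
#' tab <- tempfile(fileext = ".csv")
#' writeLines(c("id,fp_hex,nbits", "m1,ff00,16"), tab)
#' read_fingerprints(tab)$bits[[1]]
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("fingerprint table not found: ", path), class = "dockcal_io_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.csv(path, sep = sep, strip.white = TRUE,
                 colClasses = c("character", "character", "integer"))
  if (!all(c("id", "fp_hex", "nbits") %in% names(df))) {
    abort("fingerprint table must have columns id, fp_hex, nbits",
          class = "dockcal_data_error")
  }
  if (nrow(df) == 0L) {
    abort("fingerprint table is empty", class = "dockcal_data_error")
  }
  if (anyDuplicated(df$id)) {
    abort(paste0("duplicate fingerprint ids: ",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")),
          class = "dockcal_data_error")
  }
  bad <- nchar(df$fp_hex) != ceiling(df$nbits / 4)
  if (any(bad)) {
    abort(paste0("hex length inconsistent with declared nbits for: ",
                 paste(df$id[bad], collapse = ", ")),
          class = "dockcal_data_error")
  }
  tibble::tibble(
    id = df$id,
    fp_type = "EXTERNAL",
    nbits = df$nbits,
    bits = mapply(hex_to_bits, df$fp_hex, df$nbits, SIMPLIFY = FALSE,
                  USE.NAMES = FALSE)
  )
}

#' Write a fingerprint table to the hex format read by [read_fingerprints()]
#'
#' @param fps A fingerprint table.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  check_fp_tbl(fps)
  df <- data.frame(
    id = fps$id,
    fp_hex = vapply(seq_len(nrow(fps)),
                    function(i) bits_to_hex(fps$bits[[i]]), character(1)),
    nbits = fps$nbits
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

hex_to_bits <- function(hex, nbits) {
  digits <- strtoi(strsplit(tolower(hex), "")[[1]], base = 16L)
  if (anyNA(digits)) {
    abort(paste0("invalid hex string: ", hex), class = "dockcal_data_error")
  }
  bits <- as.vector(vapply(digits, function(d) {
    as.logical(bitwAnd(d, c(8L, 4L, 2L, 1L)))
  }, logical(4)))
  bits[seq_len(nbits)]
}

bits_to_hex <- function(bits) {
  pad <- (-length(bits)) %% 4
  bits <- c(as.integer(bits), rep(0L, pad))
  m <- matrix(bits, nrow = 4)
  paste(sprintf("%x", colSums(m * c(8L, 4L, 2L, 1L))), collapse = "")
}

check_fp_tbl <- function(fps, arg = deparse(substitute(fps))) {
  if (!is.data.frame(fps) ||
      !all(c("id", "fp_type", "nbits", "bits") %in% names(fps))) {
    abort(paste0(arg, " is not a fingerprint table ",
                 "(need columns id, fp_type, nbits, bits)"),
          class = "dockcal_data_error")
  }
  invisible(fps)
}

#' Tanimoto similarity between two fingerprints
#'
#' The Tanimoto coefficient of bit vectors X and Y is z / (x + y - z), where x
#' and y are the numbers of bits set in X and Y and z the number of bits set in
#' both. Two all-zero vectors have an undefined ratio 0/0; by convention this
#' returns 1 (two featureless molecules are maximally similar) and notes the
#' degenerate pair, which keeps downstream similarity weights finite.
#'
#' @param a,b Logical bit vectors of equal length, or single-row fingerprint
#'   tables of matching `fp_type` and `nbits`.
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE))
#' @export
tanimoto <- function(a, b) {
  a <- as_bits(a, "a")
  b <- as_bits(b, "b")
  if (length(a) != length(b)) {
    abort("fingerprint lengths differ", class = "dockcal_data_error")
  }
  x <- sum(a)
  y <- sum(b)
  z <- sum(a & b)
  if (x + y == 0L) {
    inform("Tanimoto of two all-zero fingerprints; returning 1 by convention")
    return(1)
  }
  z / (x + y - z)
}

as_bits <- function(v, arg) {
  if (is.data.frame(v)) {
    check_fp_tbl(v, arg)
    if (nrow(v) != 1L) {
      abort(paste0(arg, " must be a single fingerprint"), class = "dockcal_data_error")
    }
    return(v$bits[[1]])
  }
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  abort(paste0(arg, " is not a bit vector"), class = "dockcal_data_error")
}

#' All-pairs Tanimoto similarity between two fingerprint tables
#'
#' Computes the full query-by-reference similarity matrix in one matrix
#' product, which is what makes batch calibration cheap next to docking
#' itself. Fingerprint types and lengths must match between the two tables.
#' All-zero/all-zero pairs are set to 1 (see [tanimoto()]).
#'
#' @param x,y Fingerprint tables.
#' @return A numeric matrix of dimension `nrow(x)` by `nrow(y)` with the ids
#'   as dimnames.
#' @export
tanimoto_matrix <- function(x, y) {
  check_fp_tbl(x)
  check_fp_tbl(y)
  if (!identical(unique(x$fp_type), unique(y$fp_type)) ||
      length(unique(c(x$nbits, y$nbits))) != 1L) {
    abort("fingerprint type or length mismatch between the two tables",
          class = "dockcal_data_error")
  }
  a <- do.call(rbind, lapply(x$bits, as.numeric))
  b <- do.call(rbind, lapply(y$bits, as.numeric))
  z <- a %*% t(b)
  denom <- outer(rowSums(a), rowSums(b), `+`) - z
  s <- ifelse(denom == 0, 1, z / pmax(denom, .Machine$double.eps))
  dimnames(s) <- list(x$id, y$id)
  s
}
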