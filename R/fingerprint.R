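# Circular (Morgan-style) drug fingerprints from SMILES, via OpenBabel's
# ECFP4 implementation (radius 2).  The native 4096-bit vector is folded
# by OR onto 1024 bits, the conventional width for ECFP4 features.

#' Circular fingerprint of a drug from its SMILES
#'
#' @param smiles A single SMILES string.
#' @param nbits Folded fingerprint width (default 1024).
#' @return Integer 0/1 vector of length `nbits`; errors on an
#'   unparseable SMILES.
#' @export
drug_fingerprint <- function(smiles, nbits = 1024L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  raw <- tryCatch(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity), "ECFP4"),
    error = function(e)
      stop(sprintf("unparseable SMILES '%s': %s", smiles, conditionMessage(e)),
           call. = FALSE))
  raw <- as.numeric(raw)
  folded <- tapply(raw, (seq_along(raw) - 1L) %% nbits, max)
  as.integer(folded[order(as.integer(names(folded)))])
}

#' Fingerprint matrix for a drug table
#'
#' @param drug_table Data frame with columns `drug_id` and `smiles`.
#' @param nbits Folded width, see [drug_fingerprint()].
#' @return List with `fingerprints` (matrix, one row per parseable drug,
#'   rownames = drug ids) and `missing` (ids whose SMILES failed to
#'   parse, flagged for the missing-attribute policy).
#' @export
drug_fingerprint_matrix <- function(drug_table, nbits = 1024L) {
  stopifnot(all(c("drug_id", "smiles") %in% names(drug_table)))
  rows <- lapply(seq_len(nrow(drug_table)), function(i)
    tryCatch(drug_fingerprint(drug_table$smiles[i], nbits),
             error = function(e) NULL))
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("no drug SMILES parsed")
  fp <- do.call(rbind, rows[ok])
  rownames(fp) <- drug_table$drug_id[ok]
  list(fingerprints = fp, missing = drug_table$drug_id[!ok])
}

#' Read a drug SMILES table
#'
#' TSV with columns `drug_id<TAB>smiles`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with `drug_id` and `smiles`.
#' @export
read_drug_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (!all(c("drug_id", "smiles") %in% names(df)))
    stop("drug table must have columns drug_id, smiles")
  df
}
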