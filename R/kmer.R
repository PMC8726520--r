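# Grouped 3-mer composition of protein and ncRNA sequences.
#
# Residues are mapped onto a 4-letter alphabet before windowing: amino
# acids collapse into four physicochemical groups, ribonucleotides stay as
# A/C/G/U.  Overlapping windows of length 3 over the reduced alphabet give
# a 4^3 = 64-bin frequency vector.

.aa_groups <- list(
  g1 = c("A", "V", "L", "I", "M", "F", "W", "P"),   # hydrophobic
  g2 = c("G", "S", "T", "C", "N", "Q", "Y"),        # polar uncharged
  g3 = c("R", "K", "H"),                            # basic
  g4 = c("D", "E")                                  # acidic
)

.group_of <- local({
  m <- integer(0)
  for (i in seq_along(.aa_groups)) m[.aa_groups[[i]]] <- i
  m
})

.rna_letters <- c("A", "C", "G", "U")

kmer_cell_names <- function(alphabet_kind) {
  lab <- if (alphabet_kind == "rna") .rna_letters else names(.aa_groups)
  # cell index is 16(a-1) + 4(b-1) + c: third position varies fastest
  g <- expand.grid(c = lab, b = lab, a = lab, stringsAsFactors = FALSE)
  paste0(g$a, g$b, g$c)
}

#' Grouped 3-mer frequency vector of a sequence
#'
#' @param sequence A single protein or RNA sequence string.  DNA `T` is
#'   read as `U` for RNA; characters outside the alphabet are dropped
#'   (count reported via a message).
#' @param alphabet_kind `"protein"` (4 physicochemical groups) or `"rna"`
#'   (A/C/G/U).
#' @return Named numeric vector of length 64, entries nonnegative and
#'   summing to 1, or an error if fewer than 3 usable residues remain.
#' @export
kmer_vector <- function(sequence, alphabet_kind = c("protein", "rna")) {
  alphabet_kind <- match.arg(alphabet_kind)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (alphabet_kind == "rna") {
    chars[chars == "T"] <- "U"
    codes <- match(chars, .rna_letters)
  } else {
    codes <- unname(.group_of[chars])
  }
  dropped <- sum(is.na(codes))
  if (dropped > 0) {
    message(sprintf("dropped %d character(s) outside the %s alphabet",
                    dropped, alphabet_kind))
    codes <- codes[!is.na(codes)]
  }
  n <- length(codes)
  if (n < 3L)
    stop("sequence has fewer than 3 usable residues: no attribute")
  idx <- 16L * (codes[1:(n - 2L)] - 1L) +
          4L * (codes[2:(n - 1L)] - 1L) +
               (codes[3:n]        - 1L) + 1L
  v <- tabulate(idx, nbins = 64L) / (n - 2L)
  names(v) <- kmer_cell_names(alphabet_kind)
  v
}
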