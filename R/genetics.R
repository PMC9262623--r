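# Low-level nucleotide/protein helpers shared by every module.

# Standard genetic code, taken from Biostrings so the table itself is not
# re-typed by hand. Evaluated once at install time for fast batch translation.
.genetic_code <- Biostrings::GENETIC_CODE

#' Normalize a DNA string
#'
#' Uppercases, strips whitespace and IMGT gap characters (`.`), and checks the
#' alphabet.
#'
#' @param x Character scalar.
#' @param allow_empty Permit the empty string.
#' @return Normalized DNA character scalar.
#' @keywords internal
normalize_dna <- function(x, allow_empty = TRUE) {
  if (length(x) != 1L || is.na(x)) stop("expected a single DNA string", call. = FALSE)
  x <- toupper(gsub("[[:space:].]", "", x))
  if (!allow_empty && !nzchar(x)) stop("empty DNA sequence", call. = FALSE)
  if (nzchar(x) && grepl("[^ACGT]", x)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", x), "")[[1]])
    stop("non-ACGT character(s) in sequence: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' Translate DNA to protein
#'
#' Standard genetic code, `*` for stop codons. A trailing partial codon is
#' dropped. `frame` counts skipped bases at the 5' end (0, 1 or 2).
#'
#' @param nt DNA character scalar (A/C/G/T only).
#' @param frame Reading frame offset, 0 (default), 1 or 2.
#' @return Amino-acid character scalar (possibly empty).
#' @export
#' @examples
#' translate_dna("TGTGCCAGCAGC")        # "CASS"
#' translate_dna("AACTATGGCTACACCTTC")  # "NYGYTF"
translate_dna <- function(nt, frame = 0L) {
  nt <- normalize_dna(nt)
  stopifnot(frame %in% 0:2)
  if (frame > 0L) nt <- substr(nt, frame + 1L, nchar(nt))
  n <- nchar(nt)
  ncod <- n %/% 3L
  if (ncod == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = ncod)
  codons <- substring(nt, starts, starts + 2L)
  aa <- .genetic_code[codons]
  if (anyNA(aa)) stop("untranslatable codon in sequence", call. = FALSE)
  paste0(aa, collapse = "")
}

#' Reverse complement
#' @param nt DNA character scalar.
#' @return Reverse-complemented DNA character scalar.
#' @export
revcomp_dna <- function(nt) {
  nt <- normalize_dna(nt)
  if (!nzchar(nt)) return(nt)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# TRUE when the in-frame codon at the 3' end is a stop.
ends_with_stop <- function(nt) {
  n <- nchar(nt)
  n >= 3L && n %% 3L == 0L &&
    substr(nt, n - 2L, n) %in% c("TAA", "TAG", "TGA")
}

# Longest k such that the last k characters of a equal the first k of b.
longest_suffix_prefix <- function(a, b) {
  kmax <- min(nchar(a), nchar(b))
  if (kmax == 0L) return(0L)
  na <- nchar(a)
  for (k in kmax:1) {
    if (substr(a, na - k + 1L, na) == substr(b, 1L, k)) return(k)
  }
  0L
}
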