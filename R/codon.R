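# Species codon-usage tables: back-translation of non-templated junction
# residues picks the most common codon per residue.

#' Load a codon-usage table
#'
#' Reads a TSV of `codon`, `amino_acid`, `fraction` rows (header optional for
#' three-column files). Fractions are renormalized to sum to 1 per residue.
#'
#' @param input Path to a TSV file, or TSV text.
#' @return An object of class `codon_usage_table`.
#' @export
load_codon_table <- function(input) {
  path <- input
  if (length(input) != 1L || grepl("\n", input)) {
    path <- tempfile(fileext = ".tsv")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(input) > 1L) input else sub("\n$", "", input), path)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  wanted <- c("codon", "amino_acid", "fraction")
  if (!all(wanted %in% names(tab))) {
    if (ncol(tab) == 3L) {
      tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
      names(tab) <- wanted
    } else {
      stop("codon table must have columns codon, amino_acid, fraction", call. = FALSE)
    }
  }
  tab <- tab[wanted]
  tab$codon <- toupper(trimws(tab$codon))
  tab$amino_acid <- toupper(trimws(tab$amino_acid))
  tab$fraction <- as.numeric(tab$fraction)
  bad <- nchar(tab$codon) != 3L | grepl("[^ACGT]", tab$codon)
  if (any(bad)) {
    stop("invalid codon(s) in table: ", paste(unique(tab$codon[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(tab$fraction) | tab$fraction < 0)) {
    stop("invalid fraction values in codon table", call. = FALSE)
  }
  # renormalize per residue; modal codon = argmax, alphabetical on ties
  split_tab <- split(tab, tab$amino_acid)
  modal <- vapply(split_tab, function(d) {
    d$fraction <- d$fraction / sum(d$fraction)
    d <- d[order(-d$fraction, d$codon), ]
    d$codon[1]
  }, character(1))
  tab$fraction <- stats::ave(tab$fraction, tab$amino_acid, FUN = function(f) f / sum(f))
  structure(
    list(table = tibble::as_tibble(tab), modal = modal),
    class = "codon_usage_table"
  )
}

#' Most common codon for a residue
#'
#' @param table A `codon_usage_table`.
#' @param residue Single-letter amino-acid code.
#' @return The modal codon (ties broken alphabetically).
#' @export
modal_codon <- function(table, residue) {
  stopifnot(inherits(table, "codon_usage_table"))
  codon <- table$modal[toupper(residue)]
  if (is.na(codon)) {
    stop("residue '", residue, "' absent from codon-usage table", call. = FALSE)
  }
  unname(codon)
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("<codon_usage_table>", nrow(x$table), "codons,",
      length(x$modal), "residues\n")
  invisible(x)
}

#' Back-translate a peptide with modal codons
#'
#' Concatenates the most common codon for each residue; used for the
#' non-templated portion of amino-acid-mode junctions.
#'
#' @param aa Amino-acid character scalar (may be empty).
#' @param table A `codon_usage_table`.
#' @return DNA text of length `3 * nchar(aa)`.
#' @export
fill_non_templated <- function(aa, table) {
  if (!nzchar(aa)) return("")
  residues <- strsplit(toupper(aa), "")[[1]]
  paste0(vapply(residues, function(r) modal_codon(table, r), character(1)),
         collapse = "")
}
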