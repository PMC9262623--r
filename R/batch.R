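# High-throughput driver: read a rearrangement table, stitch every row with
# per-row error capture, optionally link paired chains bicistronically, and
# write a results table.

CHAIN_PREFIXES <- c("alpha", "beta")
CHAIN_FIELDS <- c("v_call", "j_call", "junction", "junction_aa",
                  "constant", "leader", "extra_5prime", "extra_3prime")

# Standard 2A self-cleaving peptide linkers (GSG-prefixed), as commonly
# used nucleotide sequences; all lengths divisible by 3.
LINKERS <- c(
  P2A = "GGAAGCGGAGCTACTAACTTCAGCCTGCTGAAGCAGGCTGGAGACGTGGAGGAGAACCCTGGACCT",
  T2A = "GGAAGCGGAGAGGGCAGAGGAAGTCTGCTAACATGCGGTGACGTCGAGGAGAATCCTGGCCCA",
  E2A = "GGCAGCGGCCAGTGCACCAACTACGCCCTGCTGAAGCTGGCCGGCGACGTGGAGAGCAACCCCGGCCCC",
  F2A = "GGCAGCGGCGTGAAGCAGACCCTGAACTTCGACCTGCTGAAGCTGGCCGGCGACGTGGAGAGCAACCCCGGCCCC"
)

#' Resolve a linker name or sequence
#'
#' Built-in names: P2A, T2A, E2A, F2A. Anything else is treated as a literal
#' nucleotide sequence (with a warning when it is not a known name but looks
#' like one).
#'
#' @param linker Linker name or DNA text.
#' @return DNA text.
#' @export
resolve_linker <- function(linker) {
  key <- toupper(trimws(linker))
  if (key %in% names(LINKERS)) return(unname(LINKERS[key]))
  warn_code("unknown_linker", paste0(
    "'", linker, "' is not a built-in linker name; treating it as a literal sequence"))
  normalize_dna(key, allow_empty = FALSE)
}

#' Read a batch rearrangement table
#'
#' Tab-separated, one rearrangement (one or two chains) per row. Columns
#' follow AIRR-style verbs with per-chain prefixes: `alpha_v_call`,
#' `alpha_j_call`, `alpha_junction` / `alpha_junction_aa`, and likewise for
#' `beta_`, plus optional `alpha_constant`, `alpha_leader`,
#' `alpha_extra_5prime`, `alpha_extra_3prime`, `linker`, `link_order`.
#' Unknown columns are ignored with a warning; empty cells mean "absent".
#'
#' @param path TSV file path.
#' @return A tibble of batch rows.
#' @export
read_batch <- function(path) {
  rows <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  known <- c("name", "linker", "link_order",
             as.vector(outer(CHAIN_PREFIXES, CHAIN_FIELDS, paste, sep = "_")))
  unknown <- setdiff(names(rows), known)
  if (length(unknown) > 0L) {
    warn_code("unknown_columns", paste0(
      "ignoring unknown column(s): ", paste(unknown, collapse = ", ")))
    rows <- rows[setdiff(names(rows), unknown)]
  }
  missing <- character()
  if (!"name" %in% names(rows)) missing <- "name"
  has_chain <- vapply(CHAIN_PREFIXES, function(p) {
    all(paste0(p, "_", c("v_call", "j_call")) %in% names(rows)) &&
      any(paste0(p, "_", c("junction", "junction_aa")) %in% names(rows))
  }, logical(1))
  if (!any(has_chain)) {
    missing <- c(missing,
                 "at least one chain's v_call/j_call/junction (e.g. beta_v_call, beta_j_call, beta_junction)")
  }
  if (length(missing) > 0L) {
    stop("batch file is missing mandatory column(s): ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  rows
}

.cell <- function(rows, col, i) {
  if (!col %in% names(rows)) return(NULL)
  x <- rows[[col]][i]
  if (is.na(x) || !nzchar(trimws(x))) NULL else trimws(x)
}

#' Stitch every row of a batch table
#'
#' Each row yields exactly one result; a row's failure never aborts the run
#' and its failure reason is recorded verbatim. Rows carrying both chains
#' and a `linker` are additionally joined into a single bicistronic open
#' reading frame.
#'
#' @param rows Batch tibble from [read_batch()] (or built in code).
#' @param ref A `vdj_reference`.
#' @param mode Junction input mode for all rows: `"aa"`, `"nt"`, `"sl"`.
#' @param sl_min_overlap Seamless minimum overlap (nt).
#' @return A list of `vdj_batch_result` objects, one per row, in input order.
#' @export
process_batch <- function(rows, ref, mode = "aa", sl_min_overlap = 10L) {
  stopifnot(inherits(ref, "vdj_reference"))
  mode <- tolower(mode)
  n <- nrow(rows)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    chains <- list()
    for (p in CHAIN_PREFIXES) {
      v <- .cell(rows, paste0(p, "_v_call"), i)
      j <- .cell(rows, paste0(p, "_j_call"), i)
      junc <- if (mode == "aa") {
        .cell(rows, paste0(p, "_junction_aa"), i) %||% .cell(rows, paste0(p, "_junction"), i)
      } else {
        .cell(rows, paste0(p, "_junction"), i)
      }
      if (is.null(v) && is.null(j) && is.null(junc)) next
      chains[[p]] <- if (is.null(v) || is.null(j) || is.null(junc)) {
        structure(list(message = "incomplete chain description (v_call, j_call and junction required)",
                       stage = "input"), class = "vdj_chain_error")
      } else {
        tryCatch(
          stitch_tcr(ref, v, j, junc, mode = mode,
                     constant_override = .cell(rows, paste0(p, "_constant"), i),
                     leader_override = .cell(rows, paste0(p, "_leader"), i),
                     extra_5prime = .cell(rows, paste0(p, "_extra_5prime"), i) %||% "",
                     extra_3prime = .cell(rows, paste0(p, "_extra_3prime"), i) %||% "",
                     sl_min_overlap = sl_min_overlap),
          error = function(e) structure(
            list(message = conditionMessage(e),
                 stage = if (!is.null(e$stage)) e$stage else "stitch"),
            class = "vdj_chain_error")
        )
      }
    }
    ok <- vapply(chains, function(x) inherits(x, "vdj_stitch"), logical(1))
    status <- if (length(chains) == 0L) "FAILED"
      else if (all(ok)) "OK"
      else if (any(ok)) "PARTIAL"
      else "FAILED"
    linked <- NULL
    linker <- .cell(rows, "linker", i)
    if (!is.null(linker) && status == "OK" && length(chains) == 2L) {
      ord <- tolower(.cell(rows, "link_order", i) %||% "ab")
      first <- if (ord == "ba") chains$beta else chains$alpha
      second <- if (ord == "ba") chains$alpha else chains$beta
      linked <- tryCatch(
        collect_warnings(link_chains(first, second, linker))$value,
        error = function(e) {
          status <<- "PARTIAL"
          structure(list(message = conditionMessage(e), stage = "link"),
                    class = "vdj_chain_error")
        })
    }
    out[[i]] <- structure(list(
      name = .cell(rows, "name", i) %||% paste0("row", i),
      row_index = i, chains = chains, linked = linked, status = status
    ), class = "vdj_batch_result")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Link two stitched chains into a bicistronic sequence
#'
#' Concatenates the two coding sequences around a linker (e.g. a 2A
#' self-cleaving peptide), removing the trailing stop codon of the 5' chain
#' so the open reading frame runs through.
#'
#' @param first,second `vdj_stitch` objects; `first` is placed 5'.
#' @param linker Linker name or DNA text (length divisible by 3).
#' @return DNA text of the combined open reading frame.
#' @export
link_chains <- function(first, second, linker) {
  stopifnot(inherits(first, "vdj_stitch"), inherits(second, "vdj_stitch"))
  linker_nt <- resolve_linker(linker)
  if (nchar(linker_nt) %% 3L != 0L) {
    stop("linker length (", nchar(linker_nt), " nt) breaks the reading frame",
         call. = FALSE)
  }
  five <- first$sequence
  if (ends_with_stop(five)) five <- substr(five, 1L, nchar(five) - 3L)
  paste0(five, linker_nt, second$sequence)
}

#' Summarize batch results as a table
#'
#' @param results List from [process_batch()].
#' @return Tibble with one row per input row: name, per-chain stitched
#'   sequence or error, warnings (semicolon-joined), linked sequence, status.
#' @export
batch_results_table <- function(results) {
  row_of <- function(r) {
    get_chain <- function(p, field) {
      x <- r$chains[[p]]
      if (is.null(x)) return(NA_character_)
      if (inherits(x, "vdj_chain_error")) {
        if (field == "error") x$message else NA_character_
      } else {
        switch(field,
          nt = x$sequence,
          aa = x$translation,
          warnings = if (length(x$warnings)) paste(x$warnings, collapse = "; ") else NA_character_,
          error = NA_character_)
      }
    }
    tibble::tibble(
      name = r$name,
      alpha_nt = get_chain("alpha", "nt"), alpha_aa = get_chain("alpha", "aa"),
      alpha_error = get_chain("alpha", "error"),
      beta_nt = get_chain("beta", "nt"), beta_aa = get_chain("beta", "aa"),
      beta_error = get_chain("beta", "error"),
      warnings = paste(stats::na.omit(c(get_chain("alpha", "warnings"),
                                        get_chain("beta", "warnings"))),
                       collapse = "; "),
      linked_nt = if (is.null(r$linked) || inherits(r$linked, "vdj_chain_error"))
        NA_character_ else r$linked,
      status = r$status
    )
  }
  dplyr::bind_rows(lapply(results, row_of))
}

#' Write batch results
#'
#' Writes the results TSV and, optionally, a FASTA with one record per
#' stitched chain and per linked construct.
#'
#' @param results List from [process_batch()].
#' @param path Output TSV path.
#' @param fasta Optional FASTA path.
#' @return The results tibble, invisibly.
#' @export
write_batch_results <- function(results, path, fasta = NULL) {
  tab <- batch_results_table(results)
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(fasta)) {
    lines <- character()
    for (r in results) {
      for (p in names(r$chains)) {
        x <- r$chains[[p]]
        if (inherits(x, "vdj_stitch")) {
          lines <- c(lines, stitch_fasta(x, paste0(r$name, "_", p)))
        }
      }
      if (!is.null(r$linked) && !inherits(r$linked, "vdj_chain_error")) {
        lines <- c(lines, paste0(">", r$name, "_linked"), r$linked)
      }
    }
    writeLines(lines, fasta)
  }
  invisible(tab)
}
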