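# Germline reference handling: IMGT-dialect FASTA parsing, indexing,
# gene/allele resolution, constant/leader defaulting rules.

SEGMENT_TYPES <- c("LEADER", "VARIABLE", "JOINING", "CONSTANT")

# IMGT GENE-DB region label <-> internal segment type
.region_to_type <- function(label) {
  if (label == "L-PART1+L-PART2") return("LEADER")
  if (label == "V-REGION") return("VARIABLE")
  if (label == "J-REGION") return("JOINING")
  if (label == "C-REGION" || label == "CONSTANT" || grepl("^EX[0-9]", label)) {
    return("CONSTANT")
  }
  NA_character_
}

.type_to_region <- c(
  LEADER = "L-PART1+L-PART2", VARIABLE = "V-REGION",
  JOINING = "J-REGION", CONSTANT = "C-REGION"
)

#' Parse a gene/allele call
#'
#' Splits IMGT nomenclature `"gene*allele"` (e.g. `"TRAV21*02"`) into its
#' parts. A bare gene name yields `allele = NA`. Inferred-allele suffixes
#' (e.g. `"TRAV27*01_A233G"`) stay attached to the allele component so the
#' full form round-trips.
#'
#' @param call Character scalar, `"gene"` or `"gene*allele"`.
#' @return List with elements `gene` and `allele`.
#' @export
#' @examples
#' parse_gene_id("TRAV21*02")
parse_gene_id <- function(call) {
  call <- toupper(trimws(call))
  if (!nzchar(call)) stop("empty gene call", call. = FALSE)
  parts <- strsplit(call, "*", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(list(gene = parts[1], allele = NA_character_))
  if (length(parts) != 2L || !nzchar(parts[2])) {
    stop("malformed gene call: ", call, call. = FALSE)
  }
  if (!grepl("^[0-9]{2}(_[ACGT][0-9]+[ACGT])?$", parts[2])) {
    stop("malformed allele designation in call: ", call, call. = FALSE)
  }
  list(gene = parts[1], allele = parts[2])
}

#' Format a gene/allele pair as a full call
#' @param gene,allele Character scalars.
#' @return `"gene*allele"`.
#' @export
format_gene_id <- function(gene, allele) paste0(gene, "*", allele)

# Structured warning used throughout so callers (stitch/batch) can collect
# coded messages without them leaking into output streams.
warn_code <- function(code, msg) {
  warning(warningCondition(
    paste0("[", code, "] ", msg),
    class = c("vdjweave_warning", "warning")
  ))
  invisible(NULL)
}

collect_warnings <- function(expr) {
  notes <- character()
  value <- withCallingHandlers(
    expr,
    vdjweave_warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  list(value = value, warnings = notes)
}

#' Parse IMGT-dialect germline FASTA
#'
#' Reads GENE-DB style records whose headers are pipe-delimited:
#' accession | gene*allele | species | functionality | region label | ...
#' Gaps (`.`) are stripped from sequences; region labels are mapped to
#' segment types (`L-PART1+L-PART2` -> LEADER, `V-REGION` -> VARIABLE,
#' `J-REGION` -> JOINING, constant labels -> CONSTANT). Records with
#' unmapped region labels or short headers are skipped with a warning.
#'
#' @param input Path to a FASTA file, or FASTA text (detected by a leading
#'   `>` or embedded newline).
#' @return A tibble of segment records (columns `accession`, `gene`,
#'   `allele`, `segment_type`, `functionality`, `sequence`, `partial`).
#' @export
parse_imgt_fasta <- function(input) {
  path <- input
  if (length(input) != 1L || grepl("^>", input) || grepl("\n", input)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(input) > 1L) input else sub("\n$", "", input), path)
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA input", call. = FALSE)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    fields <- strsplit(header, "|", fixed = TRUE)[[1]]
    if (length(fields) < 5L) {
      warn_code("bad_header", paste0("header has fewer than 5 fields, skipped: ", header))
      next
    }
    type <- .region_to_type(trimws(fields[5]))
    if (is.na(type)) {
      warn_code("unknown_region", paste0(
        "unmapped region label '", trimws(fields[5]), "' for ", trimws(fields[2]), ", skipped"
      ))
      next
    }
    id <- parse_gene_id(trimws(fields[2]))
    if (is.na(id$allele)) {
      warn_code("bad_header", paste0("no allele in header, skipped: ", header))
      next
    }
    func <- gsub("[][()]", "", trimws(fields[4]))
    if (!func %in% c("F", "ORF", "P")) func <- "F"
    seq <- normalize_dna(as.character(seqs[[i]]), allow_empty = FALSE)
    out[[i]] <- tibble::tibble(
      accession = trimws(fields[1]),
      gene = id$gene, allele = id$allele,
      segment_type = type, functionality = func,
      sequence = seq,
      partial = grepl("partial", header, ignore.case = TRUE)
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) stop("no usable records in FASTA input", call. = FALSE)
  dplyr::bind_rows(out)
}

#' Write segment records as IMGT-dialect FASTA
#'
#' Inverse of [parse_imgt_fasta()]: emits pipe-delimited headers with the
#' accession, full gene*allele call, species, functionality and region label.
#'
#' @param segments Segment tibble (as returned by [parse_imgt_fasta()]).
#' @param path Output file path.
#' @param species Species string written into header field 3.
#' @return `path`, invisibly.
#' @export
write_imgt_fasta <- function(segments, path, species = "human") {
  headers <- paste(
    segments$accession,
    format_gene_id(segments$gene, segments$allele),
    species, segments$functionality,
    unname(.type_to_region[segments$segment_type]),
    sep = "|"
  )
  headers <- paste0(headers, ifelse(segments$partial, "|partial", ""))
  lines <- character(2L * nrow(segments))
  lines[c(TRUE, FALSE)] <- paste0(">", headers)
  lines[c(FALSE, TRUE)] <- segments$sequence
  writeLines(lines, path)
  invisible(path)
}

# Locate the conserved anchor in each V (the CDR3-opening cysteine near the
# 3' end) and J (the [FWC]-G-x-G motif nearest the 3' end). Adds columns
# aa / anchor_res / anchor_nt / frame to the segment tibble.
annotate_anchors <- function(segments) {
  n <- nrow(segments)
  aa <- rep(NA_character_, n)
  anchor_res <- rep(NA_integer_, n)
  anchor_nt <- rep(NA_integer_, n)
  frame <- rep(0L, n)
  for (i in seq_len(n)) {
    type <- segments$segment_type[i]
    seq <- segments$sequence[i]
    if (type == "VARIABLE") {
      p <- translate_dna(seq)
      aa[i] <- p
      tail_start <- max(1L, nchar(p) - 11L)
      tail <- substr(p, tail_start, nchar(p))
      hit <- gregexpr("C", tail, fixed = TRUE)[[1]]
      if (hit[1] != -1L) {
        anchor_res[i] <- tail_start + hit[length(hit)] - 1L
        anchor_nt[i] <- 3L * (anchor_res[i] - 1L) + 1L
      }
    } else if (type == "JOINING") {
      # pick the frame whose translation carries an [FWC]GxG motif; prefer
      # the motif nearest the 3' end
      best <- NULL
      for (f in 0:2) {
        p <- translate_dna(seq, frame = f)
        hit <- gregexpr("[FWC]G.G", p)[[1]]
        if (hit[1] != -1L) {
          pos <- hit[length(hit)]
          if (is.null(best) || pos * 3L + f > best$score) {
            best <- list(frame = f, res = pos, aa = p, score = pos * 3L + f)
          }
        }
      }
      if (!is.null(best)) {
        frame[i] <- best$frame
        aa[i] <- best$aa
        anchor_res[i] <- best$res
        anchor_nt[i] <- best$frame + 3L * (best$res - 1L) + 1L
      } else {
        aa[i] <- translate_dna(seq)
      }
    } else {
      aa[i] <- translate_dna(seq)
    }
  }
  segments$aa <- aa
  segments$anchor_res <- anchor_res
  segments$anchor_nt <- anchor_nt
  segments$frame <- frame
  segments
}

#' Build a germline reference set
#'
#' Indexes segment records together with a codon-usage table. Anchors (the
#' conserved V cysteine and the J [FWC]GxG motif) are located once here and
#' reused by stitching, annotation and junction extraction.
#'
#' @param segments Segment tibble from [parse_imgt_fasta()].
#' @param codon_table A `codon_usage_table` from [load_codon_table()].
#' @param species Species name (default `"human"`).
#' @return An object of class `vdj_reference`.
#' @export
build_reference <- function(segments, codon_table, species = "human") {
  stopifnot(is.data.frame(segments), inherits(codon_table, "codon_usage_table"))
  key <- paste(segments$gene, segments$allele, segments$segment_type, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (gene, allele, segment_type) records in reference", call. = FALSE)
  }
  vg <- unique(segments$gene[segments$segment_type == "VARIABLE"])
  if (length(vg) == 0L) stop("reference contains no VARIABLE records", call. = FALSE)
  segments <- annotate_anchors(segments)
  structure(
    list(species = tolower(species), segments = segments,
         key = paste(segments$gene, segments$allele, segments$segment_type, sep = "\r"),
         codon = codon_table),
    class = "vdj_reference"
  )
}

#' @export
print.vdj_reference <- function(x, ...) {
  counts <- table(x$segments$segment_type)
  cat("<vdj_reference> species:", x$species, "\n  segments:",
      paste(names(counts), as.integer(counts), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Merge additional or modified genes into a reference
#'
#' Records matching an existing (gene, allele, segment type) triple replace
#' the stored record, with a logged notice; new triples are appended.
#'
#' @param ref A `vdj_reference`.
#' @param segments Segment tibble of additional records.
#' @return The updated `vdj_reference`.
#' @export
merge_reference <- function(ref, segments) {
  stopifnot(inherits(ref, "vdj_reference"))
  old <- ref$segments[intersect(names(ref$segments),
                                c("accession", "gene", "allele", "segment_type",
                                  "functionality", "sequence", "partial"))]
  newkey <- paste(segments$gene, segments$allele, segments$segment_type, sep = "\r")
  oldkey <- paste(old$gene, old$allele, old$segment_type, sep = "\r")
  clash <- oldkey %in% newkey
  if (any(clash)) {
    message("merge_reference: replacing ", sum(clash), " existing record(s): ",
            paste(format_gene_id(old$gene[clash], old$allele[clash]), collapse = ", "))
  }
  combined <- dplyr::bind_rows(old[!clash, ], segments)
  build_reference(combined, ref$codon, ref$species)
}

# Internal exact lookup; returns one-row list or NULL.
.lookup <- function(ref, gene, allele, type) {
  i <- match(paste(gene, allele, type, sep = "\r"), ref$key)
  if (is.na(i)) return(NULL)
  as.list(ref$segments[i, ])
}

#' Resolve a gene call to a stored segment record
#'
#' A bare gene call resolves to the prototypical allele (`*01`). For LEADER
#' requests where the requested allele has no recorded leader, the `*01`
#' leader is substituted with a warning, mirroring standard practice when
#' the database lacks a leader for a non-prototypical allele.
#'
#' @param ref A `vdj_reference`.
#' @param call `"gene"` or `"gene*allele"`.
#' @param type One of `"LEADER"`, `"VARIABLE"`, `"JOINING"`, `"CONSTANT"`.
#' @param allow_pseudogene Permit records with functionality `P` (with a
#'   warning); off by default.
#' @return A segment record as a named list.
#' @export
resolve_segment <- function(ref, call, type, allow_pseudogene = FALSE) {
  stopifnot(inherits(ref, "vdj_reference"), type %in% SEGMENT_TYPES)
  id <- parse_gene_id(call)
  allele <- if (is.na(id$allele)) "01" else id$allele
  genes_of_type <- unique(ref$segments$gene[ref$segments$segment_type == type])
  rec <- .lookup(ref, id$gene, allele, type)
  if (is.null(rec) && type == "LEADER") {
    rec <- .lookup(ref, id$gene, "01", type)
    if (!is.null(rec)) {
      warn_code("leader_fallback", paste0(
        "no leader recorded for ", format_gene_id(id$gene, allele),
        "; using the *01 leader"
      ))
    }
  }
  if (is.null(rec)) {
    if (!id$gene %in% genes_of_type) {
      near <- utils::head(sort(genes_of_type[startsWith(
        genes_of_type, substr(id$gene, 1L, 4L))]), 8L)
      if (length(near) == 0L) near <- utils::head(sort(genes_of_type), 8L)
      stop("gene '", id$gene, "' not found among ", type,
           " records; known genes include: ", paste(near, collapse = ", "),
           call. = FALSE)
    }
    stop("allele '", format_gene_id(id$gene, allele), "' not found among ",
         type, " records", call. = FALSE)
  }
  if (rec$functionality == "P") {
    if (!allow_pseudogene) {
      stop(format_gene_id(rec$gene, rec$allele),
           " is a pseudogene (functionality P); set allow_pseudogene = TRUE to use it",
           call. = FALSE)
    }
    warn_code("pseudogene", paste0("using pseudogene ", format_gene_id(rec$gene, rec$allele)))
  }
  rec
}

#' Select the constant region for a rearrangement
#'
#' An explicit override always wins. Otherwise, for beta chains the J gene's
#' cluster digit selects the constant (TRBJ1-n -> TRBC1, TRBJ2-n -> TRBC2);
#' alpha chains take TRAC, gamma TRGC1, delta TRDC. For species other than
#' human or mouse the constant region must be specified explicitly, because
#' other species may differ in their TCR locus architecture.
#'
#' @param ref A `vdj_reference`.
#' @param j_call The J gene call (used for the beta cluster rule and to infer
#'   the chain when `chain` is missing).
#' @param chain One of `"alpha"`, `"beta"`, `"gamma"`, `"delta"`, or `NULL`
#'   to infer from `j_call`.
#' @param species Species; defaults to the reference's species.
#' @param override Optional explicit constant region call.
#' @return A CONSTANT segment record (named list).
#' @export
default_constant <- function(ref, j_call, chain = NULL, species = NULL,
                             override = NULL) {
  stopifnot(inherits(ref, "vdj_reference"))
  if (!is.null(override) && nzchar(override)) {
    return(resolve_segment(ref, override, "CONSTANT"))
  }
  species <- tolower(if (is.null(species)) ref$species else species)
  if (!species %in% c("human", "mouse")) {
    stop("for species other than human or mouse the constant region to be ",
         "used must be specified explicitly", call. = FALSE)
  }
  jg <- parse_gene_id(j_call)$gene
  if (is.null(chain)) {
    chain <- switch(substr(jg, 1L, 3L),
      TRA = "alpha", TRB = "beta", TRG = "gamma", TRD = "delta",
      stop("cannot infer chain from J call '", j_call, "'", call. = FALSE)
    )
  }
  call <- switch(chain,
    beta = {
      m <- regmatches(jg, regexec("^TRBJ([0-9])", jg))[[1]]
      if (length(m) < 2L) {
        stop("cannot determine TRBJ cluster from '", j_call,
             "'; specify the constant region explicitly", call. = FALSE)
      }
      paste0("TRBC", m[2])
    },
    alpha = "TRAC",
    gamma = "TRGC1",
    delta = "TRDC",
    stop("unknown chain '", chain, "'", call. = FALSE)
  )
  resolve_segment(ref, call, "CONSTANT")
}
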