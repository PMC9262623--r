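# Tiled-tag read annotation: allele-level V/J calling from overlapping
# 20-mer tags in a multi-pattern matcher, jump values, junction extraction,
# and inference of novel single-nucleotide-variant alleles from recurrent
# two-tag match breaks.

#' Build a tiled-tag index
#'
#' Tiles `tag_length`-mer tags every `step` nt across every allele of every
#' V and J gene, adding a terminal tag anchored at the allele's 3' end when
#' the last grid tag does not reach it. Every interior position at least
#' half a tag from both ends is therefore covered by at least two tags. The
#' tags populate a Biostrings `PDict` for multi-pattern matching.
#'
#' @param ref A `vdj_reference`.
#' @param tag_length Tag length in nt (default 20).
#' @param step Tiling step in nt (default 10).
#' @return An object of class `vdj_tag_index`.
#' @export
build_tag_index <- function(ref, tag_length = 20L, step = 10L) {
  stopifnot(inherits(ref, "vdj_reference"), tag_length > 0L, step > 0L)
  segs <- ref$segments[ref$segments$segment_type %in% c("VARIABLE", "JOINING"), ]
  rows <- list()
  meta <- list()
  for (i in seq_len(nrow(segs))) {
    len <- nchar(segs$sequence[i])
    allele_id <- format_gene_id(segs$gene[i], segs$allele[i])
    if (len < tag_length) {
      warn_code("short_allele", paste0(
        allele_id, " is shorter than the tag length (", len, " nt); skipped"))
      next
    }
    grid <- seq.int(0L, len - tag_length, by = step)
    offsets <- grid
    if (max(grid) + tag_length < len) offsets <- c(grid, len - tag_length)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      tag = substring(segs$sequence[i], offsets + 1L, offsets + tag_length),
      allele = allele_id, gene = segs$gene[i],
      segment_type = segs$segment_type[i], offset = offsets
    )
    meta[[allele_id]] <- list(
      length = len, grid = grid, segment_type = segs$segment_type[i],
      gene = segs$gene[i], sequence = segs$sequence[i],
      anchor_nt = segs$anchor_nt[i], anchor_res = segs$anchor_res[i],
      frame = segs$frame[i]
    )
  }
  tags <- dplyr::bind_rows(rows)
  patterns <- unique(tags$tag)
  structure(list(
    tag_length = as.integer(tag_length), step = as.integer(step),
    tags = tags, patterns = patterns,
    pdict = Biostrings::PDict(Biostrings::DNAStringSet(patterns)),
    tag_map = split(seq_len(nrow(tags)),
                    factor(match(tags$tag, patterns),
                           levels = seq_along(patterns))),
    alleles = meta
  ), class = "vdj_tag_index")
}

#' @export
print.vdj_tag_index <- function(x, ...) {
  cat("<vdj_tag_index>", length(x$alleles), "alleles,", nrow(x$tags), "tags (",
      x$tag_length, "nt every", x$step, "nt)\n")
  invisible(x)
}

# all (tag row index, read start) hits for one read; NULL when none
.tag_hits <- function(read, index) {
  m <- Biostrings::matchPDict(index$pdict, Biostrings::DNAString(read))
  starts <- Biostrings::startIndex(m)
  hit_pat <- which(lengths(starts) > 0L)
  if (length(hit_pat) == 0L) return(NULL)
  out <- vector("list", length(hit_pat))
  for (k in seq_along(hit_pat)) {
    p <- hit_pat[k]
    rows <- index$tag_map[[p]]
    s <- starts[[p]]
    out[[k]] <- data.frame(row = rep(rows, each = length(s)),
                           start = rep(s, times = length(rows)))
  }
  do.call(rbind, out)
}

#' Annotate a single read
#'
#' Matches the tiled tags against the read (forward first; the reverse
#' complement is tried when there are no forward hits). Candidate alleles
#' are scored by the number of collinear tag matches — matches whose
#' read-to-allele shift agrees exactly — and the call set is the alleles
#' attaining the maximal count (at least two matches required). Jump values
#' report how far from the segment edges the extreme matches lie: `v_jump`
#' is 0 exactly when the read covers the V-REGION start. When both calls are
#' unambiguous, the junction is extracted from the read verbatim between
#' the projected V cysteine and J anchor codons.
#'
#' @param read DNA text.
#' @param index A `vdj_tag_index`.
#' @param read_id Optional identifier echoed in the result.
#' @return One-row tibble: calls, jump values, junction, flags.
#' @export
annotate_read <- function(read, index, read_id = NA_character_) {
  stopifnot(inherits(index, "vdj_tag_index"))
  read <- normalize_dna(read, allow_empty = FALSE)
  rc <- FALSE
  hits <- .tag_hits(read, index)
  if (is.null(hits)) {
    rcread <- revcomp_dna(read)
    hits <- .tag_hits(rcread, index)
    if (!is.null(hits)) {
      read <- rcread
      rc <- TRUE
    }
  }
  empty <- tibble::tibble(
    read_id = read_id, v_call = NA_character_, j_call = NA_character_,
    v_n_calls = 0L, j_n_calls = 0L, v_ambiguous = FALSE, j_ambiguous = FALSE,
    v_jump = NA_integer_, j_jump = NA_integer_,
    v_score = 0L, j_score = 0L, v_shift = NA_integer_,
    junction_nt = NA_character_, junction_aa = NA_character_,
    reverse_complement = rc,
    v_matched_offsets = list(integer(0))
  )
  if (is.null(hits)) return(empty)

  tags <- index$tags
  allele <- tags$allele[hits$row]
  offset <- tags$offset[hits$row]
  shift <- hits$start - 1L - offset
  seg <- tags$segment_type[hits$row]

  score_side <- function(side) {
    sel <- seg == side
    if (!any(sel)) return(NULL)
    key <- paste(allele[sel], shift[sel], sep = "\r")
    counts <- table(key)
    per_allele_best <- tapply(as.integer(counts),
                              sub("\r.*", "", names(counts)), max)
    best <- max(per_allele_best)
    if (best < 2L) return(NULL)
    calls <- sort(names(per_allele_best)[per_allele_best == best])
    # consistent hits for the first (alphabetically) called allele
    first <- calls[1]
    ckey <- names(counts)[as.integer(counts) == best &
                            startsWith(names(counts), paste0(first, "\r"))][1]
    cshift <- as.integer(sub(".*\r", "", ckey))
    consistent <- sel & allele == first & shift == cshift
    list(calls = calls, score = best, shift = cshift,
         offsets = sort(offset[consistent]))
  }
  v <- score_side("VARIABLE")
  j <- score_side("JOINING")
  if (is.null(v) && is.null(j)) return(empty)

  v_call <- if (is.null(v)) NA_character_ else paste(v$calls, collapse = ",")
  j_call <- if (is.null(j)) NA_character_ else paste(j$calls, collapse = ",")
  v_jump <- if (is.null(v)) NA_integer_ else min(v$offsets)
  j_jump <- if (is.null(j)) NA_integer_ else {
    jl <- index$alleles[[j$calls[1]]]$length
    jl - (max(j$offsets) + index$tag_length)
  }
  junction_nt <- NA_character_
  junction_aa <- NA_character_
  if (!is.null(v) && length(v$calls) == 1L &&
      !is.null(j) && length(j$calls) == 1L) {
    vm <- index$alleles[[v$calls[1]]]
    jm <- index$alleles[[j$calls[1]]]
    if (!is.na(vm$anchor_nt) && !is.na(jm$anchor_res)) {
      jstart <- v$shift + vm$anchor_nt
      jend <- j$shift + jm$frame + 3L * jm$anchor_res
      if (jstart >= 1L && jend <= nchar(read) && jstart < jend) {
        junction_nt <- substr(read, jstart, jend)
        if (nchar(junction_nt) %% 3L == 0L) {
          junction_aa <- translate_dna(junction_nt)
        }
      }
    }
  }
  tibble::tibble(
    read_id = read_id, v_call = v_call, j_call = j_call,
    v_n_calls = if (is.null(v)) 0L else length(v$calls),
    j_n_calls = if (is.null(j)) 0L else length(j$calls),
    v_ambiguous = !is.null(v) && length(v$calls) > 1L,
    j_ambiguous = !is.null(j) && length(j$calls) > 1L,
    v_jump = v_jump, j_jump = j_jump,
    v_score = if (is.null(v)) 0L else v$score,
    j_score = if (is.null(j)) 0L else j$score,
    v_shift = if (is.null(v)) NA_integer_ else v$shift,
    junction_nt = junction_nt, junction_aa = junction_aa,
    reverse_complement = rc,
    v_matched_offsets = list(if (is.null(v)) integer(0) else v$offsets)
  )
}

#' Annotate a set of reads
#'
#' @param reads Tibble with columns `read_id` and `sequence` (e.g. from
#'   [sim_reads()] or [read_fastx()]).
#' @param index A `vdj_tag_index`.
#' @return Tibble with one row per read (AIRR-style columns).
#' @export
annotate_reads <- function(reads, index) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  dplyr::bind_rows(lapply(seq_len(nrow(reads)), function(i) {
    annotate_read(reads$sequence[i], index, read_id = reads$read_id[i])
  }))
}

#' Read FASTA/FASTQ into a read tibble
#'
#' Qualities, if present, are ignored by the annotator.
#'
#' @param path FASTA or FASTQ file.
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_fastx <- function(path) {
  first <- readLines(path, n = 1L)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble::tibble(
    read_id = sub("\\s.*", "", names(seqs)),
    sequence = as.character(seqs)
  )
}

#' Locate two-tag match breaks in an annotated read
#'
#' A single-nucleotide variant relative to the recorded germline causes
#' exactly two consecutive overlapping grid tags to fail while their
#' neighbours still match. This reports those windows, the read sequence
#' spanning them, and — when the spanning sequence differs from germline by
#' exactly one base — the implied substitution in allele coordinates
#' (1-based within the V-REGION). Substitutions within half a tag of the
#' allele ends break only one tag and are not reported (a noted
#' limitation).
#'
#' @param read DNA text (forward orientation, as annotated).
#' @param annotation One-row tibble from [annotate_read()]; the V call must
#'   be unambiguous.
#' @param index A `vdj_tag_index`.
#' @return Tibble of break windows (possibly empty): `allele`,
#'   `break_offset` (first failed grid offset, 0-based), `span_seq`,
#'   `position`, `ref_base`, `alt_base` (NA when not a clean single SNV).
#' @export
find_tag_breaks <- function(read, annotation, index) {
  empty <- tibble::tibble(
    allele = character(0), break_offset = integer(0), span_seq = character(0),
    position = integer(0), ref_base = character(0), alt_base = character(0)
  )
  if (is.na(annotation$v_call) || annotation$v_ambiguous) return(empty)
  if (isTRUE(annotation$reverse_complement)) read <- revcomp_dna(read)
  allele <- annotation$v_call
  meta <- index$alleles[[allele]]
  if (is.null(meta)) return(empty)
  shift <- annotation$v_shift
  matched <- annotation$v_matched_offsets[[1]]
  grid <- meta$grid
  in_read <- grid[shift + grid >= 0L &
                    shift + grid + index$tag_length <= nchar(read)]
  failed <- setdiff(in_read, matched)
  if (length(failed) == 0L) return(empty)
  step <- index$step
  out <- list()
  for (o in failed) {
    o2 <- o + step
    if (!o2 %in% failed) next            # need two consecutive failures
    if (!(o - step) %in% matched) next   # left flank must match
    if (!(o2 + step) %in% matched) next  # right flank must match
    if ((o - step) %in% failed || (o2 + step) %in% failed) next
    span_len <- step + index$tag_length  # both failed tags
    rstart <- shift + o + 1L
    span <- substr(read, rstart, rstart + span_len - 1L)
    germ <- substr(meta$sequence, o + 1L, o + span_len)
    pos <- NA_integer_; ref <- NA_character_; alt <- NA_character_
    if (nchar(span) == nchar(germ)) {
      mm <- which(charToRaw(span) != charToRaw(germ))
      if (length(mm) == 1L) {
        pos <- o + mm
        ref <- substr(germ, mm, mm)
        alt <- substr(span, mm, mm)
      }
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      allele = allele, break_offset = o, span_seq = span,
      position = pos, ref_base = ref, alt_base = alt
    )
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out)
}

#' Find tag breaks across a read set
#'
#' @param reads Read tibble (`read_id`, `sequence`).
#' @param annotations Tibble from [annotate_reads()].
#' @param index A `vdj_tag_index`.
#' @return Tibble of break windows with a `read_id` column.
#' @export
find_tag_breaks_all <- function(reads, annotations, index) {
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    ri <- match(ann$read_id, reads$read_id)
    if (is.na(ri)) next
    b <- find_tag_breaks(reads$sequence[ri], ann, index)
    if (nrow(b) > 0L) {
      b$read_id <- ann$read_id
      out[[length(out) + 1L]] <- b
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(allele = character(0), break_offset = integer(0),
                          span_seq = character(0), position = integer(0),
                          ref_base = character(0), alt_base = character(0),
                          read_id = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Infer novel single-nucleotide-variant alleles for one donor
#'
#' Clusters identical break-spanning sequences per V gene and applies four
#' criteria to separate germline variants from PCR/sequencing noise: the
#' variant must (i) occur in a V gene with at least `min_gene_recombs`
#' distinct recombinations with unambiguous gene calls, (ii) account for at
#' least `min_gene_read_frac` of that gene's reads, (iii) be found in at
#' least `min_recombs` unique recombinations, and (iv) account for at least
#' `min_break_frac` of that gene's reads containing a two-tag break. A
#' candidate is additionally called only when it ranks in the top two most
#' abundant break sequences for its gene (the inferred genotype). Only
#' reads with `v_jump == 0` (full-length V) enter the analysis.
#'
#' @param annotations Tibble from [annotate_reads()].
#' @param breaks Tibble from [find_tag_breaks_all()].
#' @param min_gene_recombs,min_gene_read_frac,min_recombs,min_break_frac
#'   The four thresholds (defaults 10, 0.05, 3, 0.10).
#' @param max_rank Genotype rank cutoff (default 2).
#' @return Tibble of novel-allele candidates with identifiers of the form
#'   `gene*allele_RefPosAlt` (e.g. `TRAV27*01_A233G`); empty when nothing
#'   passes.
#' @export
infer_novel_alleles <- function(annotations, breaks,
                                min_gene_recombs = 10L,
                                min_gene_read_frac = 0.05,
                                min_recombs = 3L,
                                min_break_frac = 0.10,
                                max_rank = 2L) {
  empty <- tibble::tibble(
    base_allele = character(0), position = integer(0),
    ref_base = character(0), alt_base = character(0),
    supporting_reads = integer(0), supporting_recombinations = integer(0),
    fraction_of_gene_reads = numeric(0), fraction_of_break_reads = numeric(0),
    identifier = character(0)
  )
  ann <- annotations[!is.na(annotations$v_call) & !annotations$v_ambiguous &
                       !is.na(annotations$v_jump) & annotations$v_jump == 0L &
                       !is.na(annotations$junction_nt), ]
  if (nrow(ann) == 0L || nrow(breaks) == 0L) return(empty)
  ann$gene <- sub("\\*.*", "", ann$v_call)
  ann$recomb <- paste(ann$v_call, ann$j_call, ann$junction_nt, sep = "|")
  gene_reads <- table(ann$gene)
  gene_recombs <- tapply(ann$recomb, ann$gene, function(x) length(unique(x)))

  b <- dplyr::inner_join(breaks, ann[c("read_id", "gene", "recomb")],
                         by = "read_id")
  if (nrow(b) == 0L) return(empty)
  gene_break_reads <- tapply(b$read_id, b$gene, function(x) length(unique(x)))

  key <- paste(b$allele, b$break_offset, b$span_seq, sep = "\r")
  clusters <- lapply(split(seq_len(nrow(b)), key), function(ix) {
    d <- b[ix, ]
    tibble::tibble(
      base_allele = d$allele[1], gene = d$gene[1],
      break_offset = d$break_offset[1], span_seq = d$span_seq[1],
      position = d$position[1], ref_base = d$ref_base[1],
      alt_base = d$alt_base[1],
      supporting_reads = length(unique(d$read_id)),
      supporting_recombinations = length(unique(d$recomb))
    )
  })
  cl <- dplyr::bind_rows(clusters)
  # genotype rank over all break-sequence clusters of each gene
  cl <- cl[order(cl$gene, -cl$supporting_reads, cl$span_seq), ]
  cl$rank <- stats::ave(seq_len(nrow(cl)), cl$gene, FUN = seq_along)

  cl$fraction_of_gene_reads <-
    cl$supporting_reads / as.integer(gene_reads[cl$gene])
  cl$fraction_of_break_reads <-
    cl$supporting_reads / as.integer(gene_break_reads[cl$gene])
  keep <- as.integer(gene_recombs[cl$gene]) >= min_gene_recombs &
    cl$fraction_of_gene_reads >= min_gene_read_frac &
    cl$supporting_recombinations >= min_recombs &
    cl$fraction_of_break_reads >= min_break_frac &
    cl$rank <= max_rank &
    !is.na(cl$position)
  cl <- cl[keep, ]
  if (nrow(cl) == 0L) return(empty)
  cl$identifier <- paste0(cl$base_allele, "_", cl$ref_base, cl$position,
                          cl$alt_base)
  tibble::as_tibble(cl[c("base_allele", "position", "ref_base", "alt_base",
                         "supporting_reads", "supporting_recombinations",
                         "fraction_of_gene_reads", "fraction_of_break_reads",
                         "identifier")])
}

#' Augment a reference with inferred alleles
#'
#' Applies each candidate substitution to its base allele and stores the
#' result as a new VARIABLE record whose allele name carries the variant
#' suffix (e.g. `TRAV27*01_A233G`), so both stitching and annotation accept
#' the inferred call. Leaders fall back to the base gene's *01 leader.
#'
#' @param ref A `vdj_reference`.
#' @param candidates Tibble from [infer_novel_alleles()].
#' @return The augmented `vdj_reference`.
#' @export
augment_reference <- function(ref, candidates) {
  stopifnot(inherits(ref, "vdj_reference"))
  if (nrow(candidates) == 0L) return(ref)
  if (anyDuplicated(candidates$identifier)) {
    stop("duplicate candidate identifier(s): ",
         paste(unique(candidates$identifier[duplicated(candidates$identifier)]),
               collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- as.list(candidates[i, ])
    id <- parse_gene_id(cand$base_allele)
    base <- resolve_segment(ref, cand$base_allele, "VARIABLE")
    have <- substr(base$sequence, cand$position, cand$position)
    if (have != cand$ref_base) {
      stop("candidate ", cand$identifier, ": reference base at position ",
           cand$position, " is ", have, ", not ", cand$ref_base, call. = FALSE)
    }
    new_allele <- paste0(id$allele, "_", cand$ref_base, cand$position,
                         cand$alt_base)
    if (!is.na(match(paste(id$gene, new_allele, "VARIABLE", sep = "\r"), ref$key))) {
      stop("identifier collision: ", cand$identifier,
           " already present in the reference", call. = FALSE)
    }
    seq <- base$sequence
    substr(seq, cand$position, cand$position) <- cand$alt_base
    rows[[i]] <- tibble::tibble(
      accession = paste0("INFERRED", i), gene = id$gene, allele = new_allele,
      segment_type = "VARIABLE", functionality = base$functionality,
      sequence = seq, partial = FALSE
    )
  }
  merge_reference(ref, dplyr::bind_rows(rows))
}

#' Write inferred alleles as IMGT-dialect FASTA
#'
#' @param candidates Tibble from [infer_novel_alleles()].
#' @param ref The `vdj_reference` holding the base alleles.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_novel_fasta <- function(candidates, ref, path) {
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- as.list(candidates[i, ])
    id <- parse_gene_id(cand$base_allele)
    base <- resolve_segment(ref, cand$base_allele, "VARIABLE")
    seq <- base$sequence
    substr(seq, cand$position, cand$position) <- cand$alt_base
    rows[[i]] <- tibble::tibble(
      accession = paste0("INFERRED", i), gene = id$gene,
      allele = paste0(id$allele, "_", cand$ref_base, cand$position, cand$alt_base),
      segment_type = "VARIABLE", functionality = base$functionality,
      sequence = seq, partial = FALSE
    )
  }
  write_imgt_fasta(dplyr::bind_rows(rows), path, species = ref$species)
}

#' Extract the junction from an annotated read
#'
#' The junction runs from the codon of the V's conserved cysteine to the
#' codon of the J's conserved F/W inclusive, located by projecting the
#' reference anchor positions through the tag-match coordinates. The
#' sequence is taken from the read verbatim.
#'
#' @param read DNA text.
#' @param annotation One-row tibble from [annotate_read()] for that read.
#' @param index A `vdj_tag_index`.
#' @return List with `junction_nt` and `junction_aa` (NA when anchors are
#'   not locatable in the read).
#' @export
extract_junction <- function(read, annotation, index) {
  list(junction_nt = annotation$junction_nt,
       junction_aa = annotation$junction_aa)
}
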