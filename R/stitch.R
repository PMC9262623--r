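# Core assembly: junction decomposition in the three input modes and
# full-length coding sequence construction.
#
# The CDR3 junction runs inclusively from the conserved V cysteine to the
# conserved J phenylalanine (or equivalent residue). Residues the germline
# genes can wholly encode take germline nucleotides; the rest is filled from
# the codon-usage table (AA mode) or copied from the provided nucleotides
# (NT mode). Seamless (SL) mode joins a longer provided nucleotide sequence
# to the germline V/J by exact overlap and keeps it verbatim.

stitch_error <- function(msg, stage) {
  stop(errorCondition(msg, class = c("vdjweave_error", "error"), stage = stage))
}

# longest suffix-prefix bounded above by max_k
.suffix_prefix_max <- function(a, b, max_k) {
  kmax <- min(nchar(a), nchar(b), max_k)
  if (kmax <= 0L) return(0L)
  na <- nchar(a)
  for (k in kmax:1) {
    if (substr(a, na - k + 1L, na) == substr(b, 1L, k)) return(k)
  }
  0L
}

#' Count junction residues attributable to the V gene
#'
#' The maximal germline attribution on the V side. When the position of the
#' V's conserved cysteine is known (`anchor_res`), the junction's first
#' residue is anchored there and the match extended rightward maximally —
#' equivalent to incrementally deleting germline V residues until the
#' longest overlap with the junction start is found. Without an anchor the
#' longest suffix of the translated V that is a prefix of the junction is
#' used.
#'
#' @param v_aa Translated V gene.
#' @param junction_aa Amino-acid junction (C...F/W).
#' @param anchor_res Optional 1-based residue index of the conserved
#'   cysteine in `v_aa`.
#' @return Integer count (0 when no overlap exists).
#' @export
#' @examples
#' v_overlap_aa("VYFCASS", "CASSLNYGYTF")  # 4
v_overlap_aa <- function(v_aa, junction_aa, anchor_res = NULL) {
  v_aa <- toupper(v_aa); junction_aa <- toupper(junction_aa)
  if (!nzchar(junction_aa)) stop("empty junction", call. = FALSE)
  if (is.null(anchor_res) || is.na(anchor_res)) {
    return(longest_suffix_prefix(v_aa, junction_aa))
  }
  kmax <- min(nchar(junction_aa), nchar(v_aa) - anchor_res + 1L)
  k <- 0L
  while (k < kmax &&
         substr(junction_aa, k + 1L, k + 1L) ==
         substr(v_aa, anchor_res + k, anchor_res + k)) {
    k <- k + 1L
  }
  k
}

#' Count junction residues attributable to the J gene
#'
#' The junction's final residue is anchored at the J's conserved terminal
#' residue (the F/W/C of the [FWC]GxG motif); the match is then extended
#' leftward maximally.
#'
#' @param j_aa Translated J gene.
#' @param remainder Junction minus its V-attributed prefix.
#' @param anchor_res 1-based residue index of the conserved terminal residue
#'   in `j_aa`; located by motif scan when `NULL`.
#' @return Integer count of attributed residues (>= 1).
#' @export
#' @examples
#' j_overlap_aa("NYGYTFGQGT", "LNYGYTF", anchor_res = 6)  # 6
j_overlap_aa <- function(j_aa, remainder, anchor_res = NULL) {
  j_aa <- toupper(j_aa); remainder <- toupper(remainder)
  if (is.null(anchor_res)) {
    hit <- gregexpr("[FWC]G.G", j_aa)[[1]]
    if (hit[1] == -1L) {
      stitch_error("no [FWC]GxG anchor motif in J translation", "junction")
    }
    anchor_res <- hit[length(hit)]
  }
  n <- nchar(remainder)
  if (n == 0L || substr(remainder, n, n) != substr(j_aa, anchor_res, anchor_res)) {
    stitch_error(
      "junction terminal residue cannot be anchored at the J conserved residue",
      "junction"
    )
  }
  m <- 1L
  while (m < n && m < anchor_res &&
         substr(remainder, n - m, n - m) ==
         substr(j_aa, anchor_res - m, anchor_res - m)) {
    m <- m + 1L
  }
  m
}

# Residue-level decomposition shared by AA and NT modes. The junction is
# anchored at both conserved residues: its first residue at the V cysteine
# (match extended rightward maximally) and its last at the J anchor (match
# extended leftward maximally); whatever neither germline gene can encode
# is the non-templated fill.
.decompose_residues <- function(junction_aa, v_rec, j_rec) {
  L <- nchar(junction_aa)
  if (L < 2L) stitch_error("junction shorter than 2 residues", "junction")
  if (is.na(j_rec$anchor_res)) {
    stitch_error(paste0("J gene ", format_gene_id(j_rec$gene, j_rec$allele),
                        " has no [FWC]GxG anchor"), "junction")
  }
  if (is.na(v_rec$anchor_res)) {
    stitch_error(paste0("V gene ", format_gene_id(v_rec$gene, v_rec$allele),
                        " has no conserved cysteine anchor"), "junction")
  }
  # cap V attribution at L-1 so the terminal residue is always the J anchor
  k_v <- min(v_overlap_aa(v_rec$aa, junction_aa, anchor_res = v_rec$anchor_res),
             L - 1L)
  remainder <- substr(junction_aa, k_v + 1L, L)
  j_used <- j_overlap_aa(j_rec$aa, remainder, anchor_res = j_rec$anchor_res)
  list(v_used = k_v, j_used = j_used,
       fill_aa = substr(remainder, 1L, nchar(remainder) - j_used))
}

#' Decompose a CDR3 junction against germline V and J genes
#'
#' Determines the germline attribution of the junction and builds the
#' junction-spanning nucleotide sequence for the requested input mode
#' (`"aa"`, `"nt"`, or `"sl"`). See the package vignette for the three
#' mode definitions.
#'
#' @param junction Junction text: amino acids (`aa`), exact nucleotides
#'   (`nt`), or a longer nucleotide sequence with flanking context (`sl`).
#' @param mode One of `"aa"`, `"nt"`, `"sl"`.
#' @param v_rec,j_rec Resolved VARIABLE / JOINING segment records.
#' @param codon_table A `codon_usage_table` (needed for `aa` mode).
#' @param sl_min_overlap Minimum exact nucleotide overlap on each side for
#'   seamless mode (default 10).
#' @return A list describing the decomposition: residue counts attributed to
#'   V and J, the non-templated fill, the junction nucleotide sequence, the
#'   fill span within it (0-based half-open), and the germline segments to
#'   place around it.
#' @export
decompose_junction <- function(junction, mode, v_rec, j_rec,
                               codon_table = NULL, sl_min_overlap = 10L) {
  mode <- tolower(mode)
  junction <- toupper(trimws(junction))
  v_seq <- v_rec$sequence
  j_seq <- j_rec$sequence
  ncod_v <- nchar(v_rec$aa)

  if (mode == "sl") {
    S <- normalize_dna(junction, allow_empty = FALSE)
    if (nchar(S) < 2L * sl_min_overlap) {
      stitch_error("seamless junction shorter than twice the minimum overlap",
                   "junction")
    }
    v_hit <- .sl_match(v_seq, S, sl_min_overlap, side = "v")
    if (is.null(v_hit)) {
      stitch_error(paste0("seamless 5' overlap with the V gene below the ",
                          "minimum of ", sl_min_overlap, " nt"), "junction")
    }
    j_hit <- .sl_match(j_seq, S, sl_min_overlap, side = "j")
    if (is.null(j_hit)) {
      stitch_error(paste0("seamless 3' overlap with the J gene below the ",
                          "minimum of ", sl_min_overlap, " nt"), "junction")
    }
    return(list(
      mode = "sl", junction_nt = S,
      fill_span = c(0L, nchar(S)),
      v_keep_nt = v_hit$keep, j_skip_nt = j_hit$skip,
      v_used = NA_integer_, j_used = NA_integer_, fill_aa = NA_character_
    ))
  }

  if (mode == "aa") {
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", junction)) {
      stitch_error("amino-acid junction contains non-amino-acid characters",
                   "junction")
    }
    junction_aa <- junction
  } else if (mode == "nt") {
    jnt <- normalize_dna(junction, allow_empty = FALSE)
    if (nchar(jnt) %% 3L != 0L) {
      stitch_error("nucleotide junction length is not divisible by 3", "junction")
    }
    junction_aa <- translate_dna(jnt)
    if (grepl("*", junction_aa, fixed = TRUE)) {
      warn_code("junction_stop", "provided nucleotide junction contains a stop codon")
    }
  } else {
    stop("unknown junction mode '", mode, "'", call. = FALSE)
  }

  dec <- .decompose_residues(junction_aa, v_rec, j_rec)
  if (dec$v_used == 0L) {
    warn_code("no_v_overlap",
              "junction has no overlap with the V gene; entire 5' portion is non-templated")
  }
  v_anchor <- v_rec$anchor_res
  v_nt <- substr(v_seq, 3L * (v_anchor - 1L) + 1L,
                 3L * (v_anchor - 1L + dec$v_used))
  j_first_nt <- j_rec$frame + 3L * (j_rec$anchor_res - dec$j_used) + 1L
  j_anchor_end <- j_rec$frame + 3L * j_rec$anchor_res
  j_nt <- substr(j_seq, j_first_nt, j_anchor_end)
  n_fill <- nchar(dec$fill_aa)
  fill_nt <- if (mode == "aa") {
    if (is.null(codon_table)) stop("codon_table required for aa mode", call. = FALSE)
    fill_non_templated(dec$fill_aa, codon_table)
  } else {
    substr(junction, 3L * dec$v_used + 1L, 3L * (dec$v_used + n_fill))
  }
  junction_nt <- paste0(v_nt, fill_nt, j_nt)
  list(
    mode = mode, junction_nt = junction_nt,
    fill_span = c(3L * dec$v_used, 3L * dec$v_used + nchar(fill_nt)),
    v_used = dec$v_used, j_used = dec$j_used, fill_aa = dec$fill_aa,
    v_keep_nt = 3L * (v_anchor - 1L),
    j_skip_nt = j_first_nt - 1L,
    junction_aa = junction_aa
  )
}

# Exact-overlap search for seamless mode. For the V side ("v"), the 5' of
# the provided sequence is searched against the incrementally deleted 3' of
# the V gene: occurrences of the leading probe are extended rightward and
# the rightmost-ending (least-deleted) maximal match wins. For the J side,
# the trailing probe is searched against the 5' of the J and extended
# leftward, the leftmost-starting match winning.
.sl_match <- function(germ, S, min_ov, side) {
  nS <- nchar(S); nG <- nchar(germ)
  if (side == "v") {
    probe <- substr(S, 1L, min_ov)
    hits <- gregexpr(probe, germ, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NULL)
    best <- NULL
    for (p in as.integer(hits)) {
      l <- min_ov
      while (p + l <= nG && l < nS &&
             substr(germ, p + l, p + l) == substr(S, l + 1L, l + 1L)) {
        l <- l + 1L
      }
      end <- p + l - 1L
      if (is.null(best) || end > best$end ||
          (end == best$end && l > best$len)) {
        best <- list(end = end, len = l, keep = p - 1L)
      }
    }
    best
  } else {
    probe <- substr(S, nS - min_ov + 1L, nS)
    hits <- gregexpr(probe, germ, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NULL)
    best <- NULL
    for (p in as.integer(hits)) {
      # probe occupies germ[p .. p+min_ov-1]; extend leftward
      l <- min_ov
      while (p - (l - min_ov) > 1L && l < nS &&
             substr(germ, p - (l - min_ov) - 1L, p - (l - min_ov) - 1L) ==
             substr(S, nS - l, nS - l)) {
        l <- l + 1L
      }
      start <- p - (l - min_ov)
      if (is.null(best) || start < best$start ||
          (start == best$start && l > best$len)) {
        best <- list(start = start, len = l, skip = p + min_ov - 1L)
      }
    }
    best
  }
}

#' Stitch a full-length TCR coding sequence
#'
#' Assembles `extra_5prime + leader + V + junction + J + constant +
#' extra_3prime` for one rearrangement, recording segment offsets and coded
#' warnings. The leader defaults to the V gene's own (falling back to the
#' *01 leader when the requested allele lacks one) and the constant region
#' follows the locus rules of [default_constant()].
#'
#' @param ref A `vdj_reference`.
#' @param v_call,j_call Gene calls (`"gene"` or `"gene*allele"`).
#' @param junction Junction text (interpretation depends on `mode`).
#' @param mode `"aa"`, `"nt"`, or `"sl"`.
#' @param chain Chain name; inferred from `v_call` when `NULL`.
#' @param species Species; defaults to the reference's.
#' @param constant_override,leader_override Optional explicit calls.
#' @param extra_5prime,extra_3prime Arbitrary sequences added outside the
#'   coding region (e.g. Kozak sequences, stop codons, restriction sites).
#' @param sl_min_overlap Minimum seamless overlap per side (nt).
#' @param strict Upgrade warnings to errors.
#' @return An object of class `vdj_stitch` with elements `sequence`,
#'   `translation`, `offsets` (0-based half-open intervals for extra5,
#'   leader, v_germline, junction_fill, j_germline, constant, extra3 —
#'   tiling the sequence contiguously; `junction_fill` spans the whole
#'   junction-spanning segment: conserved C to conserved F/W in aa/nt
#'   modes, the verbatim provided sequence in sl mode), `warnings`,
#'   `junction_nt`, `junction_aa`, and `calls`.
#' @export
stitch_tcr <- function(ref, v_call, j_call, junction, mode = "aa",
                       chain = NULL, species = NULL,
                       constant_override = NULL, leader_override = NULL,
                       extra_5prime = "", extra_3prime = "",
                       sl_min_overlap = 10L, strict = FALSE) {
  stopifnot(inherits(ref, "vdj_reference"))
  res <- collect_warnings({
    v_call <- toupper(trimws(v_call)); j_call <- toupper(trimws(j_call))
    if (is.null(chain)) {
      chain <- switch(substr(v_call, 1L, 3L),
        TRA = "alpha", TRB = "beta", TRG = "gamma", TRD = "delta", NULL)
    }
    v_rec <- tryCatch(resolve_segment(ref, v_call, "VARIABLE"),
                      vdjweave_error = function(e) stop(e),
                      error = function(e) stitch_error(conditionMessage(e), "reference"))
    j_rec <- tryCatch(resolve_segment(ref, j_call, "JOINING"),
                      vdjweave_error = function(e) stop(e),
                      error = function(e) stitch_error(conditionMessage(e), "reference"))
    leader_call <- if (!is.null(leader_override) && nzchar(leader_override)) {
      toupper(trimws(leader_override))
    } else {
      format_gene_id(v_rec$gene, v_rec$allele)
    }
    l_rec <- tryCatch(resolve_segment(ref, leader_call, "LEADER"),
                      vdjweave_error = function(e) stop(e),
                      error = function(e) stitch_error(conditionMessage(e), "reference"))
    c_rec <- tryCatch(
      default_constant(ref, j_call, chain = chain, species = species,
                       override = constant_override),
      vdjweave_error = function(e) stop(e),
      error = function(e) stitch_error(conditionMessage(e), "reference"))

    extra_5prime <- normalize_dna(extra_5prime)
    extra_3prime <- normalize_dna(extra_3prime)

    dec <- decompose_junction(junction, mode, v_rec, j_rec,
                              codon_table = ref$codon,
                              sl_min_overlap = sl_min_overlap)

    v_part <- substr(v_rec$sequence, 1L, dec$v_keep_nt)
    j_part <- substr(j_rec$sequence, dec$j_skip_nt + nchar_span(dec) + 1L,
                     nchar(j_rec$sequence))
    parts <- c(
      extra5 = extra_5prime,
      leader = l_rec$sequence,
      v_germline = v_part,
      junction_fill = dec$junction_nt,
      j_germline = j_part,
      constant = c_rec$sequence,
      extra3 = extra_3prime
    )
    lens <- nchar(parts)
    ends <- cumsum(lens)
    starts <- ends - lens
    offsets <- mapply(function(s, e) c(s, e), starts, ends, SIMPLIFY = FALSE)
    sequence <- paste0(parts, collapse = "")

    coding <- substr(sequence, lens[["extra5"]] + 1L,
                     nchar(sequence) - lens[["extra3"]])
    if (nchar(coding) %% 3L != 0L) {
      stitch_error("assembled coding sequence length is not divisible by 3",
                   "assembly")
    }
    translation <- translate_dna(coding)

    junction_aa <- if (tolower(mode) == "sl") NA_character_ else dec$junction_aa
    check_aa <- if (is.na(junction_aa)) NULL else junction_aa
    if (!is.null(check_aa)) {
      if (substr(check_aa, 1L, 1L) != "C") {
        warn_code("junction_start", "junction does not begin with the conserved C")
      }
      last <- substr(check_aa, nchar(check_aa), nchar(check_aa))
      if (!last %in% c("F", "W", "C")) {
        warn_code("junction_end",
                  "junction does not end with a conserved F/W (or equivalent) residue")
      }
    }
    body <- substr(translation, 1L, nchar(translation) - 1L)
    if (grepl("*", body, fixed = TRUE)) {
      warn_code("internal_stop", "translation contains an internal stop codon")
    }

    structure(list(
      sequence = sequence, translation = translation, offsets = offsets,
      junction_nt = dec$junction_nt, junction_aa = junction_aa,
      decomposition = dec,
      calls = list(
        v = format_gene_id(v_rec$gene, v_rec$allele),
        j = format_gene_id(j_rec$gene, j_rec$allele),
        leader = format_gene_id(l_rec$gene, l_rec$allele),
        constant = format_gene_id(c_rec$gene, c_rec$allele),
        mode = tolower(mode), chain = chain
      )
    ), class = "vdj_stitch")
  })
  out <- res$value
  out$warnings <- res$warnings
  if (strict && length(out$warnings) > 0L) {
    stitch_error(paste0("warnings upgraded to errors in strict mode: ",
                        paste(out$warnings, collapse = "; ")), "strict")
  }
  out
}

# nt of the J already consumed inside the junction (anchor end minus skip)
nchar_span <- function(dec) {
  if (dec$mode == "sl") return(0L)
  # junction's J-attributed nucleotides
  3L * dec$j_used
}

#' @export
print.vdj_stitch <- function(x, ...) {
  cat("<vdj_stitch>", x$calls$v, "/", x$calls$j, "mode:", x$calls$mode, "\n")
  cat("  length:", nchar(x$sequence), "nt  constant:", x$calls$constant, "\n")
  if (!is.na(x$junction_aa)) cat("  junction:", x$junction_aa, "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' FASTA representation of a stitched sequence
#'
#' The definition line records the calls and segment offsets so downstream
#' tools can recover the breakdown.
#'
#' @param x A `vdj_stitch`.
#' @param name Record name.
#' @return Character vector of FASTA lines.
#' @export
stitch_fasta <- function(x, name = "stitched") {
  stopifnot(inherits(x, "vdj_stitch"))
  off <- vapply(names(x$offsets), function(r) {
    iv <- x$offsets[[r]]
    paste0(r, "=", iv[1], "-", iv[2])
  }, character(1))
  header <- paste0(">", name, " ", x$calls$v, "|", x$calls$j, "|",
                   x$calls$constant, "|mode=", x$calls$mode, " ",
                   paste(off, collapse = ";"))
  c(header, x$sequence)
}
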