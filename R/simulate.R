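# Ground-truth V(D)J recombination simulator over any reference set, plus a
# bundled synthetic fixture reference and sequence-comparison helpers.
#
# The simulator is first-class, tested code: it provides exact per-record
# annotations (chosen alleles, trims, inserted nucleotides, spans) so the
# stitching and annotation modules can be validated end to end.

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.NONSTOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
nonstop_codons <- function() .NONSTOP_CODONS

# n random non-stop codons, optionally excluding residues in `avoid_aa`
.rand_codons <- function(n, avoid_aa = NULL) {
  pool <- nonstop_codons()
  if (!is.null(avoid_aa)) {
    gc_tab <- Biostrings::GENETIC_CODE
    pool <- pool[!gc_tab[pool] %in% avoid_aa]
  }
  paste0(sample(pool, n, replace = TRUE), collapse = "")
}

.aa_to_nt <- function(aa) {
  # deterministic back-translation used only in fixture construction
  tab <- load_codon_table(system.file("extdata", "human_codon_usage.tsv",
                                      package = "vdjweave"))
  fill_non_templated(aa, tab)
}

#' Synthetic fixture reference
#'
#' Builds a small, deterministic, human-like TRA/TRB germline reference for
#' testing and examples: 7 V genes (one with a second allele), 6 J genes,
#' 3 constant regions and leaders, with realistic anchors (each V ends in a
#' conserved-cysteine context such as CASS; each J carries exactly one
#' [FWC]GxG motif). All segments are codon-aligned. The sequences are
#' synthetic — they follow the architecture of the human loci but are not
#' real germline sequences.
#'
#' @param seed RNG seed; the same seed always yields a byte-identical
#'   reference.
#' @return A `vdj_reference` (species `"human"`, since the synthetic loci
#'   follow human locus architecture and defaulting rules).
#' @export
fixture_reference <- function(seed = 42) {
  with_seed(seed, {
    v_tails <- c(
      TRAV1 = "CAVR", TRAV2 = "CAVS", TRAV3 = "CAAS",
      TRBV1 = "CASS", TRBV2 = "CASG", TRBV3 = "CAWS", TRBV4 = "CAIS"
    )
    # J design: 5 junction-side residues, anchor at residue 6, G-x-G, tail;
    # F/W/C excluded from all non-anchor residues so the motif is unique
    j_spec <- list(
      TRAJ1 = list(head = "NSGYA", anchor = "F"),
      TRAJ2 = list(head = "DYGNT", anchor = "F"),
      `TRBJ1-1` = list(head = "NTEAY", anchor = "F"),
      `TRBJ1-2` = list(head = "NYGYT", anchor = "W"),
      `TRBJ2-1` = list(head = "NEQYA", anchor = "F"),
      `TRBJ2-5` = list(head = "QETQY", anchor = "F")
    )
    segs <- list()
    acc <- 0L
    add <- function(gene, allele, type, seq, func = "F") {
      acc <<- acc + 1L
      segs[[length(segs) + 1L]] <<- tibble::tibble(
        accession = sprintf("SYN%05d", acc),
        gene = gene, allele = allele, segment_type = type,
        functionality = func, sequence = seq, partial = FALSE
      )
    }
    for (g in names(v_tails)) {
      body <- .rand_codons(86L, avoid_aa = "C")
      tail_nt <- .aa_to_nt(v_tails[[g]])
      vseq <- paste0(body, tail_nt)  # 90 codons, 270 nt
      add(g, "01", "VARIABLE", vseq)
      leader <- paste0("ATG", .rand_codons(15L))  # 16 codons, 48 nt
      add(g, "01", "LEADER", leader)
    }
    # a second allele of TRBV2, one substitution, and no leader of its own
    v2 <- segs[[which(vapply(segs, function(s)
      s$gene == "TRBV2" && s$segment_type == "VARIABLE", logical(1)))]]$sequence
    pos <- 100L
    base <- substr(v2, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), base)[1]
    v2alt <- v2
    substr(v2alt, pos, pos) <- alt
    while (grepl("*", translate_dna(v2alt), fixed = TRUE)) {
      alt <- setdiff(c("A", "C", "G", "T"), c(base, alt))[1]
      v2alt <- v2
      substr(v2alt, pos, pos) <- alt
    }
    add("TRBV2", "02", "VARIABLE", v2alt)
    for (g in names(j_spec)) {
      aa_head <- j_spec[[g]]$head
      anchor <- j_spec[[g]]$anchor
      motif_mid <- .rand_codons(1L, avoid_aa = c("F", "W", "C", "*"))
      jseq <- paste0(
        .aa_to_nt(aa_head),
        .aa_to_nt(anchor), "GGA", motif_mid, "GGT",
        .rand_codons(9L, avoid_aa = c("F", "W", "C"))
      )  # 18 codons, 54 nt
      add(g, "01", "JOINING", jseq)
    }
    for (g in c("TRAC", "TRBC1", "TRBC2")) {
      add(g, "01", "CONSTANT", paste0(.rand_codons(40L), "TAA"))  # 123 nt
    }
    codon <- load_codon_table(system.file("extdata", "human_codon_usage.tsv",
                                          package = "vdjweave"))
    build_reference(dplyr::bind_rows(segs), codon, species = "human")
  })
}

#' Simulation parameters
#'
#' @param n Number of recombinations to simulate.
#' @param max_v_trim,max_j_trim Maximum exonuclease trims (nt, uniform on
#'   `[0, max]`).
#' @param mean_insert Mean non-templated insertion length (nt; bounded
#'   geometric).
#' @param max_insert Upper bound on insertion length.
#' @param min_junction_aa Minimum junction length in residues (default 8).
#' @param seed RNG seed; fully determines the repertoire.
#' @param chains Chains to draw from.
#' @param v_genes,j_genes Optional gene-name restriction (bare gene names).
#' @return A `sim_params` list.
#' @export
sim_params <- function(n = 100L, max_v_trim = 6L, max_j_trim = 6L,
                       mean_insert = 4, max_insert = 20L,
                       min_junction_aa = 8L, seed = 1L,
                       chains = c("alpha", "beta"),
                       v_genes = NULL, j_genes = NULL) {
  stopifnot(n >= 1L, max_v_trim >= 0L, max_j_trim >= 0L, mean_insert >= 0,
            min_junction_aa >= 2L)
  structure(list(n = as.integer(n), max_v_trim = as.integer(max_v_trim),
                 max_j_trim = as.integer(max_j_trim),
                 mean_insert = mean_insert, max_insert = as.integer(max_insert),
                 min_junction_aa = as.integer(min_junction_aa),
                 seed = as.integer(seed), chains = chains,
                 v_genes = v_genes, j_genes = j_genes),
            class = "sim_params")
}

#' Simulate a repertoire of V(D)J recombinations
#'
#' Draws V and J alleles, uniform exonuclease trims that never remove the
#' conserved anchors, and bounded-geometric non-templated insertions padded
#' to preserve the reading frame. Draws whose junction contains a stop codon
#' or falls below the minimum length are rejected and redrawn, so every
#' emitted record is in-frame and potentially productive, with a junction
#' running from the conserved C to a conserved F/W/C terminal residue.
#'
#' @param ref A `vdj_reference`.
#' @param params A `sim_params` object.
#' @return Tibble of ground-truth recombinations: calls, trims, inserted
#'   nucleotides, full-length sequence (leader + recombined V-junction-J +
#'   constant) and 1-based spans for the variable domain, the junction and
#'   the non-templated insert.
#' @export
simulate_repertoire <- function(ref, params = sim_params()) {
  stopifnot(inherits(ref, "vdj_reference"), inherits(params, "sim_params"))
  segs <- ref$segments
  pick_pool <- function(type, chain, genes) {
    prefix <- switch(chain, alpha = "TRA", beta = "TRB")
    letter <- if (type == "VARIABLE") "V" else "J"
    rows <- segs[segs$segment_type == type &
                   startsWith(segs$gene, paste0(prefix, letter)), ]
    if (!is.null(genes)) rows <- rows[rows$gene %in% genes, ]
    rows
  }
  as_rowlist <- function(d) lapply(seq_len(nrow(d)), function(r) as.list(d[r, ]))
  pools <- list()
  for (chain in params$chains) {
    vp <- pick_pool("VARIABLE", chain, params$v_genes)
    jp <- pick_pool("JOINING", chain, params$j_genes)
    if (nrow(vp) > 0L && nrow(jp) > 0L) {
      pools[[chain]] <- list(v = as_rowlist(vp), j = as_rowlist(jp))
    }
  }
  if (length(pools) == 0L) stop("no eligible V/J genes for the requested chains/genes",
                                call. = FALSE)
  with_seed(params$seed, {
    n <- params$n
    col_chr <- function() character(n)
    col_int <- function() integer(n)
    out <- list(
      name = col_chr(), chain = col_chr(), v_call = col_chr(),
      j_call = col_chr(), constant = col_chr(), v_trim = col_int(),
      j_trim = col_int(), inserted_nt = col_chr(), full_nt = col_chr(),
      junction_nt = col_chr(), junction_aa = col_chr(),
      v_domain_start = col_int(), v_domain_end = col_int(),
      junction_start = col_int(), junction_end = col_int(),
      insert_start = col_int(), insert_end = col_int(),
      leader_len = col_int(), constant_len = col_int()
    )
    leader_cache <- list()
    const_cache <- list()
    consecutive_rejects <- 0L
    i <- 1L
    while (i <= params$n) {
      chain <- sample(names(pools), 1L)
      vp <- pools[[chain]]$v; jp <- pools[[chain]]$j
      vrow <- vp[[sample.int(length(vp), 1L)]]
      jrow <- jp[[sample.int(length(jp), 1L)]]
      vlen <- nchar(vrow$sequence)
      v_anchor <- vrow$anchor_nt
      j_anchor_end <- jrow$frame + 3L * jrow$anchor_res
      max_vt <- min(params$max_v_trim, vlen - (v_anchor + 2L))
      max_jt <- min(params$max_j_trim, jrow$frame + 3L * (jrow$anchor_res - 1L))
      v_trim <- sample.int(max_vt + 1L, 1L) - 1L
      j_trim <- sample.int(max_jt + 1L, 1L) - 1L
      LV <- (vlen - v_trim) - v_anchor + 1L
      LJ <- j_anchor_end - j_trim
      LI <- min(stats::rgeom(1L, 1 / (params$mean_insert + 1)), params$max_insert)
      LI <- LI + (3L - (LV + LJ + LI) %% 3L) %% 3L
      insert <- if (LI > 0L) paste0(sample(c("A", "C", "G", "T"), LI, replace = TRUE),
                                    collapse = "") else ""
      junction_nt <- paste0(
        substr(vrow$sequence, v_anchor, vlen - v_trim),
        insert,
        substr(jrow$sequence, j_trim + 1L, j_anchor_end)
      )
      junction_aa <- translate_dna(junction_nt)
      ok <- !grepl("*", junction_aa, fixed = TRUE) &&
        nchar(junction_aa) >= params$min_junction_aa
      if (!ok) {
        consecutive_rejects <- consecutive_rejects + 1L
        if (consecutive_rejects > 500L) {
          stop("simulation rejection rate too high; parameters are pathological",
               call. = FALSE)
        }
        next
      }
      consecutive_rejects <- 0L
      v_call <- format_gene_id(vrow$gene, vrow$allele)
      j_call <- format_gene_id(jrow$gene, jrow$allele)
      if (is.null(leader_cache[[v_call]])) {
        leader_cache[[v_call]] <- collect_warnings(
          resolve_segment(ref, v_call, "LEADER"))$value
      }
      leader <- leader_cache[[v_call]]
      if (is.null(const_cache[[j_call]])) {
        const_cache[[j_call]] <- default_constant(ref, j_call, chain = chain)
      }
      const <- const_cache[[j_call]]
      jlen <- nchar(jrow$sequence)
      full_nt <- paste0(leader$sequence,
                        substr(vrow$sequence, 1L, vlen - v_trim),
                        insert,
                        substr(jrow$sequence, j_trim + 1L, jlen),
                        const$sequence)
      llen <- nchar(leader$sequence)
      clen <- nchar(const$sequence)
      out$name[i] <- sprintf("sim%05d", i)
      out$chain[i] <- chain
      out$v_call[i] <- v_call
      out$j_call[i] <- j_call
      out$constant[i] <- format_gene_id(const$gene, const$allele)
      out$v_trim[i] <- v_trim
      out$j_trim[i] <- j_trim
      out$inserted_nt[i] <- insert
      out$full_nt[i] <- full_nt
      out$junction_nt[i] <- junction_nt
      out$junction_aa[i] <- junction_aa
      out$v_domain_start[i] <- llen + 1L
      out$v_domain_end[i] <- nchar(full_nt) - clen
      out$junction_start[i] <- llen + v_anchor
      out$junction_end[i] <- llen + v_anchor + nchar(junction_nt) - 1L
      out$insert_start[i] <- llen + (vlen - v_trim) + 1L
      out$insert_end[i] <- llen + (vlen - v_trim) + LI
      out$leader_len[i] <- llen
      out$constant_len[i] <- clen
      i <- i + 1L
    }
    tibble::as_tibble(out)
  })
}

#' Convert simulated recombinations to batch input rows
#'
#' Amino-acid mode rows carry `junction_aa`; nucleotide mode rows carry the
#' exact junction; seamless rows carry the junction extended by true
#' germline-context pads taken from the simulated full-length sequence.
#' Pads are truncated (with a warning) to the germline context available
#' inside the variable domain.
#'
#' @param sims Tibble from [simulate_repertoire()].
#' @param mode `"aa"`, `"nt"` or `"sl"`.
#' @param pad_5,pad_3 Seamless pad lengths (nt).
#' @return A batch-row tibble suitable for [process_batch()].
#' @export
to_stitch_inputs <- function(sims, mode = "aa", pad_5 = 0L, pad_3 = 0L) {
  mode <- tolower(mode)
  n <- nrow(sims)
  junction <- character(n)
  if (mode == "sl") {
    avail5 <- sims$junction_start - sims$v_domain_start
    avail3 <- sims$v_domain_end - sims$junction_end
    if (any(avail5 < pad_5) || any(avail3 < pad_3)) {
      warn_code("pad_truncated",
                "seamless pads exceed available germline context for some records; truncated")
    }
    p5 <- pmin(pad_5, avail5)
    p3 <- pmin(pad_3, avail3)
    junction <- substr(sims$full_nt, sims$junction_start - p5,
                       sims$junction_end + p3)
  } else if (mode == "nt") {
    junction <- sims$junction_nt
  } else {
    junction <- sims$junction_aa
  }
  juncol <- if (mode == "aa") "junction_aa" else "junction"
  rows <- tibble::tibble(name = sims$name)
  for (chain in c("alpha", "beta")) {
    sel <- sims$chain == chain
    for (field in c("v_call", "j_call", juncol)) {
      col <- paste0(chain, "_", field)
      val <- rep(NA_character_, n)
      src <- switch(field, v_call = sims$v_call, j_call = sims$j_call, junction)
      val[sel] <- src[sel]
      rows[[col]] <- val
    }
  }
  rows
}

#' Emit annotator reads from simulated recombinations
#'
#' Reads cover the variable domain (start of the V-REGION to the end of the
#' J) plus a short constant-region tail; an optional 5' truncation produces
#' reads that miss the V start, exercising jump-value filtering.
#'
#' @param sims Tibble from [simulate_repertoire()].
#' @param truncate_5prime Nucleotides removed from the 5' end of each read.
#' @param constant_tail Constant-region nucleotides appended after the J.
#' @return Tibble of reads with ground-truth labels.
#' @export
sim_reads <- function(sims, truncate_5prime = 0L, constant_tail = 20L) {
  start <- sims$v_domain_start + truncate_5prime
  end <- pmin(sims$v_domain_end + constant_tail, nchar(sims$full_nt))
  tibble::tibble(
    read_id = paste0(sims$name, "_r"),
    sequence = substr(sims$full_nt, start, end),
    sim_name = sims$name, chain = sims$chain,
    v_call = sims$v_call, j_call = sims$j_call,
    junction_nt = sims$junction_nt, junction_aa = sims$junction_aa,
    truncated = truncate_5prime > 0L
  )
}

#' Inject a single-nucleotide variant into a fraction of a gene's reads
#'
#' Emulates a donor carrying an unrecorded germline allele: the stated
#' fraction of reads whose V call uses `gene` receive the substitution at
#' the given V-REGION position. Ground-truth carrier labels are retained so
#' inference can be evaluated.
#'
#' @param sims Tibble from [simulate_repertoire()].
#' @param gene Bare V gene name (e.g. `"TRBV2"`).
#' @param position 1-based position within the gene's V-REGION.
#' @param alt_base Substituted base.
#' @param carrier_fraction Fraction of that gene's reads to mutate.
#' @param seed RNG seed for carrier selection.
#' @param ref A `vdj_reference` (used to validate the position/base).
#' @return Read tibble as from [sim_reads()] with columns `is_carrier` and
#'   `ref_base` added.
#' @export
inject_snv_reads <- function(sims, gene, position, alt_base, carrier_fraction,
                             seed = 1L, ref = NULL) {
  reads <- sim_reads(sims)
  if (!is.null(ref)) {
    vrec <- resolve_segment(ref, gene, "VARIABLE")
    if (position < 1L || position > nchar(vrec$sequence)) {
      stop("position ", position, " lies outside the V-REGION of ", gene,
           call. = FALSE)
    }
    if (substr(vrec$sequence, position, position) == alt_base) {
      stop("alt_base ", alt_base, " equals the germline base of ", gene,
           " at position ", position, call. = FALSE)
    }
  }
  gene_of <- vapply(reads$v_call, function(x) parse_gene_id(x)$gene, character(1),
                    USE.NAMES = FALSE)
  idx <- which(gene_of == gene)
  reads$is_carrier <- FALSE
  reads$ref_base <- NA_character_
  if (length(idx) == 0L || carrier_fraction <= 0) return(reads)
  n_carriers <- round(carrier_fraction * length(idx))
  carriers <- with_seed(seed, sample(idx, n_carriers))
  for (i in carriers) {
    seq <- reads$sequence[i]
    if (position > nchar(seq)) next
    reads$ref_base[i] <- substr(seq, position, position)
    substr(seq, position, position) <- alt_base
    reads$sequence[i] <- seq
    reads$is_carrier[i] <- TRUE
  }
  reads
}

#' Positional comparison of two equal-length sequences
#'
#' Used to localize differences between simulated truth and stitched output
#' over the variable domain.
#'
#' @param truth,stitched DNA text of equal length.
#' @return List with `positions` (1-based mismatch positions), `scaled`
#'   (positions scaled to `[0, 1]` for histogramming) and `length_mismatch`
#'   (TRUE when the sequences could not be compared position-wise).
#' @export
compare_sequences <- function(truth, stitched) {
  if (nchar(truth) != nchar(stitched)) {
    return(list(positions = integer(0), scaled = numeric(0),
                length_mismatch = TRUE))
  }
  pos <- which(charToRaw(truth) != charToRaw(stitched))
  list(positions = pos, scaled = if (length(pos)) pos / nchar(truth) else numeric(0),
       length_mismatch = FALSE)
}
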