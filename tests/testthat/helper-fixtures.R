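# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

fix_ref <- function() {
  if (is.null(.fixture_env$ref)) .fixture_env$ref <- fixture_reference(42)
  .fixture_env$ref
}

fix_index <- function() {
  if (is.null(.fixture_env$index)) .fixture_env$index <- build_tag_index(fix_ref())
  .fixture_env$index
}

fix_sims <- function() {
  if (is.null(.fixture_env$sims)) {
    .fixture_env$sims <- simulate_repertoire(fix_ref(), sim_params(n = 300, seed = 101))
  }
  .fixture_env$sims
}

# Tiny hand-checkable reference built around the classic CASS / NYGYTF motifs:
# V translates ...VYFCASS (conserved C at residue 24 of 27), J is
# NYGYTFGQGTRLTV (anchor F at residue 6).
toy_reference <- function() {
  if (!is.null(.fixture_env$toy)) return(.fixture_env$toy)
  v_seq <- paste0(strrep("GCT", 20), "GTGTATTTCTGTGCCAGCAGC")
  j_seq <- "AACTATGGCTACACCTTCGGGCAGGGGACCAGACTGACAGTG"
  segs <- tibble::tibble(
    accession = paste0("TOY", 1:6),
    gene = c("TRBV9", "TRBV9", "TRBJ1-2", "TRBJ2-5", "TRBC1", "TRBC2"),
    allele = "01",
    segment_type = c("VARIABLE", "LEADER", "JOINING", "JOINING",
                     "CONSTANT", "CONSTANT"),
    functionality = "F",
    sequence = c(v_seq, "ATGGGATCT", j_seq, j_seq,
                 "GGAGGCGGATCTTAA", "GGTGGAGGTTCTTAA"),
    partial = FALSE
  )
  codon <- load_codon_table(system.file("extdata", "human_codon_usage.tsv",
                                        package = "vdjweave"))
  .fixture_env$toy <- build_reference(segs, codon, species = "human")
  .fixture_env$toy
}

# variable-domain span of a stitched result (start of V to end of J)
stitched_vd <- function(res) {
  substr(res$sequence, res$offsets$v_germline[1] + 1, res$offsets$j_germline[2])
}

truth_vd <- function(sims, i) {
  substr(sims$full_nt[i], sims$v_domain_start[i], sims$v_domain_end[i])
}

# stitch result for the chain a simulated record belongs to
chain_result <- function(results, sims, i) {
  results[[i]]$chains[[sims$chain[i]]]
}

# brute-force junction split maximizing germline attribution, independent of
# the decomposition code path: enumerate every (i, j) split where the first
# i residues extend the V from its conserved C and the last j residues
# extend the J leftward from its anchor
oracle_split <- function(junction_aa, v_aa, v_anchor, j_aa, j_anchor) {
  L <- nchar(junction_aa)
  ok_v <- function(i) {
    i == 0 || (v_anchor + i - 1 <= nchar(v_aa) &&
                 substr(junction_aa, 1, i) ==
                 substr(v_aa, v_anchor, v_anchor + i - 1))
  }
  ok_j <- function(j) {
    j >= 1 && j <= j_anchor &&
      substr(junction_aa, L - j + 1, L) ==
      substr(j_aa, j_anchor - j + 1, j_anchor)
  }
  best <- -1L
  for (i in 0:(L - 1)) {
    if (!ok_v(i)) next
    for (j in 1:(L - i)) {
      if (ok_j(j) && i + j > best) best <- i + j
    }
  }
  best
}
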