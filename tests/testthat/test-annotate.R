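# Tiled-tag indexing, allele-level calling, jump values, break detection,
# and novel-allele inference thresholds.

test_that("tag tiling covers the grid plus a terminal anchor when needed", {
  seq60 <- paste0("ACGTGATCCATTGCAGCATG", "GAACTTCGGACTTAGGCATA",
                  "ACGGTCAAGGTTCACCTGAT")
  seq65 <- paste0(substr(seq60, 1, 20), "CCGATTACAGGATCGGAATC",
                  "TTCGAGGCTAAGTCCGGATT", "ACAGC")
  segs <- tibble::tibble(
    accession = c("X1", "X2"), gene = c("TRXV1", "TRXV2"), allele = "01",
    segment_type = "VARIABLE", functionality = "F",
    sequence = c(seq60, seq65), partial = FALSE
  )
  ref <- build_reference(segs, fix_ref()$codon, species = "human")
  idx <- build_tag_index(ref)
  t1 <- idx$tags[idx$tags$allele == "TRXV1*01", ]
  expect_equal(t1$offset, c(0L, 10L, 20L, 30L, 40L))       # len 60: 5 grid tags
  t2 <- idx$tags[idx$tags$allele == "TRXV2*01", ]
  expect_equal(t2$offset, c(0L, 10L, 20L, 30L, 40L, 45L))  # len 65: + terminal
  # the shared leading 20-mer maps to both alleles
  shared <- idx$tags$tag[idx$tags$allele == "TRXV1*01" & idx$tags$offset == 0]
  expect_equal(sort(idx$tags$allele[idx$tags$tag == shared]),
               c("TRXV1*01", "TRXV2*01"))
})

test_that("alleles shorter than the tag length are skipped with a warning", {
  segs <- tibble::tibble(
    accession = c("S1", "S2"), gene = c("TRYV1", "TRYV2"), allele = "01",
    segment_type = "VARIABLE", functionality = "F",
    sequence = c("ACGTGATCCAACGTG", strrep("ACGTGATCCA", 6)), partial = FALSE
  )
  ref <- build_reference(segs, fix_ref()$codon, species = "human")
  got <- vdjweave:::collect_warnings(build_tag_index(ref))
  expect_match(got$warnings, "TRYV1")
  expect_false("TRYV1*01" %in% got$value$tags$allele)
})

test_that("error-free reads get allele-exact calls, zero jumps and true junctions", {
  sims <- fix_sims()[1:40, ]
  reads <- sim_reads(sims)
  ann <- annotate_reads(reads, fix_index())
  expect_equal(ann$v_call, reads$v_call)
  expect_equal(ann$j_call, reads$j_call)
  expect_true(all(ann$v_jump == 0L))
  expect_equal(ann$junction_nt, reads$junction_nt)
  expect_equal(ann$junction_aa, reads$junction_aa)
  expect_false(any(ann$v_ambiguous | ann$j_ambiguous))
})

test_that("5'-truncated reads have positive v_jump and non-TCR reads no calls", {
  sims <- fix_sims()[1:15, ]
  trunc <- sim_reads(sims, truncate_5prime = 25L)
  ann <- annotate_reads(trunc, fix_index())
  expect_true(all(ann$v_jump > 0L))
  rnd <- vdjweave:::with_seed(99, paste0(
    sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = ""))
  got <- annotate_read(rnd, fix_index())
  expect_true(is.na(got$v_call) && is.na(got$j_call))
})

test_that("reads are matched on the reverse complement when needed", {
  sims <- fix_sims()[1:5, ]
  reads <- sim_reads(sims)
  rc <- revcomp_dna(reads$sequence[1])
  ann <- annotate_read(rc, fix_index())
  expect_true(ann$reverse_complement)
  expect_equal(ann$v_call, reads$v_call[1])
  expect_equal(ann$junction_nt, reads$junction_nt[1])
})

test_that("an interior SNV breaks exactly two consecutive grid tags", {
  ref <- fix_ref()
  idx <- fix_index()
  sims <- simulate_repertoire(ref, sim_params(n = 1, seed = 33,
                                              v_genes = "TRAV3",
                                              chains = "alpha"))
  clean <- sim_reads(sims)$sequence[1]
  v <- resolve_segment(ref, "TRAV3", "VARIABLE")
  ann0 <- annotate_read(clean, idx)
  expect_equal(nrow(find_tag_breaks(clean, ann0, idx)), 0L)
  # sweep substitution positions across the tag-interior of the allele
  for (p in seq(25L, 235L, by = 30L)) {
    mutated <- clean
    old <- substr(mutated, p, p)
    substr(mutated, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    ann <- annotate_read(mutated, idx)
    b <- find_tag_breaks(mutated, ann, idx)
    expect_equal(nrow(b), 1L, info = paste("position", p))
    expect_equal(b$position, p)
    expect_equal(b$ref_base, old)
    # brute-force check: grid tags failing on the mutated read
    grid <- idx$alleles[["TRAV3*01"]]$grid
    fails <- grid[vapply(grid, function(o) {
      tag <- substr(v$sequence, o + 1, o + 20)
      substr(mutated, o + 1, o + 20) != tag
    }, logical(1))]
    fails <- fails[fails + 20 <= nchar(clean)]
    expect_equal(length(intersect(fails, c(b$break_offset, b$break_offset + 10))),
                 2L)
  }
})

test_that("substitutions near the allele start break one tag and are not reported", {
  ref <- fix_ref()
  idx <- fix_index()
  sims <- simulate_repertoire(ref, sim_params(n = 1, seed = 34,
                                              v_genes = "TRAV3",
                                              chains = "alpha"))
  read <- sim_reads(sims)$sequence[1]
  substr(read, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(read, 5, 5))[1]
  ann <- annotate_read(read, idx)
  expect_equal(nrow(find_tag_breaks(read, ann, idx)), 0L)
})

test_that("the four inference criteria act independently", {
  # constructed donor: gene TRZV1 with configurable counts
  make_donor <- function(n_recombs, n_carriers, n_noise = 0L) {
    ann <- tibble::tibble(
      read_id = paste0("r", seq_len(n_recombs)),
      v_call = "TRZV1*01", j_call = "TRZJ1*01",
      v_ambiguous = FALSE, v_jump = 0L,
      junction_nt = sprintf("TGTGCCJUNC%03dTTC", seq_len(n_recombs))
    )
    brk <- tibble::tibble(
      allele = "TRZV1*01", break_offset = 100L,
      span_seq = "SPANSEQ_VARIANT", position = 120L,
      ref_base = "A", alt_base = "G",
      read_id = paste0("r", seq_len(n_carriers))
    )
    if (n_noise > 0L) {
      noise <- tibble::tibble(
        allele = "TRZV1*01",
        break_offset = 100L + 10L * seq_len(n_noise),
        span_seq = paste0("NOISE", seq_len(n_noise)),
        position = 130L + seq_len(n_noise),
        ref_base = "A", alt_base = "C",
        read_id = paste0("r", n_carriers + seq_len(n_noise))
      )
      brk <- rbind(brk, noise)
    }
    list(ann = ann, brk = brk)
  }
  pass <- make_donor(20L, 4L)
  cand <- infer_novel_alleles(pass$ann, pass$brk)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$identifier, "TRZV1*01_A120G")
  expect_equal(cand$supporting_reads, 4L)
  expect_equal(cand$fraction_of_gene_reads, 0.2)
  # (i) fewer than 10 distinct recombinations
  d <- make_donor(8L, 4L)
  expect_equal(nrow(infer_novel_alleles(d$ann, d$brk)), 0L)
  # (ii) below 5% of gene reads
  d <- make_donor(100L, 3L)
  expect_equal(nrow(infer_novel_alleles(d$ann, d$brk)), 0L)
  # (iii) fewer than 3 unique recombinations
  d <- make_donor(20L, 2L)
  expect_equal(nrow(infer_novel_alleles(d$ann, d$brk)), 0L)
  # (iv) below 10% of break-bearing reads
  d <- make_donor(60L, 4L, n_noise = 50L)
  expect_equal(nrow(infer_novel_alleles(d$ann, d$brk)), 0L)
})

test_that("augmenting the reference makes the inferred allele first-class", {
  ref <- fix_ref()
  cand <- tibble::tibble(
    base_allele = "TRAV3*01", position = 150L,
    ref_base = substr(resolve_segment(ref, "TRAV3", "VARIABLE")$sequence, 150, 150),
    alt_base = "N", supporting_reads = 5L, supporting_recombinations = 4L,
    fraction_of_gene_reads = 0.2, fraction_of_break_reads = 1,
    identifier = NA_character_
  )
  cand$alt_base <- setdiff(c("A", "C", "G", "T"), cand$ref_base)[1]
  cand$identifier <- paste0("TRAV3*01_", cand$ref_base, 150, cand$alt_base)
  ref2 <- augment_reference(ref, cand)
  rec <- resolve_segment(ref2, cand$identifier, "VARIABLE")
  expect_equal(substr(rec$sequence, 150, 150), cand$alt_base)
  # stitching with the inferred call carries the variant base
  sims <- simulate_repertoire(ref, sim_params(n = 1, seed = 35,
                                              v_genes = "TRAV3",
                                              chains = "alpha"))
  res <- stitch_tcr(ref2, cand$identifier, sims$j_call[1], sims$junction_aa[1],
                    mode = "aa")
  vpos <- res$offsets$leader[2] + 150L
  expect_equal(substr(res$sequence, vpos, vpos), cand$alt_base)
  # leader fell back to *01 with a warning
  expect_true(any(grepl("leader_fallback", res$warnings)))
  # identity on the empty candidate list; collision errors
  expect_identical(augment_reference(ref, cand[0, ]), ref)
  expect_error(augment_reference(ref2, cand), "collision")
})

test_that("novel-allele FASTA emission round-trips through the IMGT parser", {
  ref <- fix_ref()
  base <- resolve_segment(ref, "TRBV3", "VARIABLE")
  rb <- substr(base$sequence, 99, 99)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  cand <- tibble::tibble(
    base_allele = "TRBV3*01", position = 99L, ref_base = rb, alt_base = ab,
    supporting_reads = 4L, supporting_recombinations = 3L,
    fraction_of_gene_reads = 0.1, fraction_of_break_reads = 1,
    identifier = paste0("TRBV3*01_", rb, 99, ab)
  )
  path <- withr::local_tempfile(fileext = ".fasta")
  write_novel_fasta(cand, ref, path)
  recs <- parse_imgt_fasta(path)
  expect_equal(nrow(recs), 1L)
  expect_equal(format_gene_id(recs$gene, recs$allele), cand$identifier)
  expect_equal(substr(recs$sequence, 99, 99), ab)
})
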