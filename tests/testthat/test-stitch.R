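# Junction decomposition and full-length assembly in all three input modes.

test_that("translation follows the standard code and drops partial codons", {
  expect_equal(translate_dna("TGTGCCAGCAGC"), "CASS")
  expect_equal(translate_dna("AACTATGGCTACACCTTC"), "NYGYTF")
  expect_equal(translate_dna(""), "")
  expect_equal(translate_dna("TGTGCCAG"), "CA")        # trailing 2 nt dropped
  expect_equal(translate_dna("ATGTGA"), "M*")
  expect_equal(translate_dna("CTGTGCC", frame = 1), "CA")
  expect_error(translate_dna("ATGN"), "non-ACGT")
})

test_that("V-side overlap maximizes germline attribution", {
  expect_equal(v_overlap_aa("VYFCASS", "CASSLNYGYTF"), 4L)
  expect_equal(v_overlap_aa("VYFCASS", "GASSLNYGYTF"), 0L)
  expect_equal(v_overlap_aa("VYFCASS", "CASS"), 4L)
  # anchored form: same values when the junction runs to the V end ...
  expect_equal(v_overlap_aa("VYFCASS", "CASSLNYGYTF", anchor_res = 4L), 4L)
  # ... and correct attribution when a terminal V residue was re-encoded
  expect_equal(v_overlap_aa("VYFCASS", "CASRLNYGYTF", anchor_res = 4L), 3L)
})

test_that("J-side overlap anchors the terminal residue and extends leftward", {
  expect_equal(j_overlap_aa("NYGYTFGQGT", "LNYGYTF", anchor_res = 6L), 6L)
  expect_equal(j_overlap_aa("NYGYTFGQGT", "LQKATF", anchor_res = 6L), 2L)
  expect_error(j_overlap_aa("NYGYTFGQGT", "LNYGYTX", anchor_res = 6L),
               "cannot be anchored")
  # anchor located by motif scan when not supplied
  expect_equal(j_overlap_aa("NYGYTFGQGT", "LNYGYTF"), 6L)
})

test_that("non-templated fill concatenates modal codons", {
  tab <- fix_ref()$codon
  expect_equal(fill_non_templated("L", tab), "CTG")
  expect_equal(fill_non_templated("", tab), "")
  expect_equal(fill_non_templated("LL", tab), "CTGCTG")
  expect_error(fill_non_templated("LXL", tab), "absent")
})

test_that("amino-acid mode decomposition reproduces the hand-built junction", {
  ref <- toy_reference()
  v <- resolve_segment(ref, "TRBV9", "VARIABLE")
  j <- resolve_segment(ref, "TRBJ1-2", "JOINING")
  dec <- decompose_junction("CASSLNYGYTF", "aa", v, j, codon_table = ref$codon)
  expect_equal(dec$v_used, 4L)
  expect_equal(dec$j_used, 6L)
  expect_equal(dec$fill_aa, "L")
  expect_equal(dec$junction_nt,
               paste0("TGTGCCAGCAGC", "CTG", "AACTATGGCTACACCTTC"))
  expect_equal(dec$fill_span, c(12L, 15L))
})

test_that("nucleotide mode keeps provided fill but germline codons elsewhere", {
  ref <- toy_reference()
  v <- resolve_segment(ref, "TRBV9", "VARIABLE")
  j <- resolve_segment(ref, "TRBJ1-2", "JOINING")
  # rearrangement encoded the last CASS serine as AGT; germline has AGC
  provided <- paste0("TGTGCCAGCAGT", "CTT", "AACTATGGCTACACCTTC")
  dec <- decompose_junction(provided, "nt", v, j)
  expect_equal(substr(dec$junction_nt, 10, 12), "AGC")  # germline codon used
  expect_equal(substr(dec$junction_nt, 13, 15), "CTT")  # provided fill kept
  expect_equal(translate_dna(dec$junction_nt), translate_dna(provided))
  expect_error(decompose_junction(paste0(provided, "AC"), "nt", v, j),
               "divisible by 3")
})

test_that("seamless mode integrates the provided sequence verbatim", {
  ref <- toy_reference()
  v <- resolve_segment(ref, "TRBV9", "VARIABLE")
  j <- resolve_segment(ref, "TRBJ1-2", "JOINING")
  core <- paste0("TGTGCCAGCAGT", "CTT", "AACTATGGCTACACCTTC")
  pad5 <- substr(v$sequence, nchar(v$sequence) - 21, nchar(v$sequence) - 12)
  pad3 <- substr(j$sequence, 19, 28)
  S <- paste0(pad5, core, pad3)
  res <- stitch_tcr(ref, "TRBV9", "TRBJ1-2", S, mode = "sl")
  expect_true(grepl(S, res$sequence, fixed = TRUE))     # retained verbatim
  expect_true(grepl("AGT", res$sequence, fixed = TRUE)) # synonymous variant kept
  expect_error(
    stitch_tcr(ref, "TRBV9", "TRBJ1-2", paste0("ACGTACGTAC", core, pad3),
               mode = "sl"),
    "5' overlap")
})

test_that("stitched sequences tile contiguously and keep the reading frame", {
  ref <- toy_reference()
  res <- stitch_tcr(ref, "TRBV9", "TRBJ2-5", "CASSLNYGYTF", mode = "aa",
                    extra_5prime = "GCCACCATGG", extra_3prime = "TGATAA")
  offs <- res$offsets
  expect_equal(names(offs),
               c("extra5", "leader", "v_germline", "junction_fill",
                 "j_germline", "constant", "extra3"))
  prev_end <- 0L
  for (r in names(offs)) {
    expect_equal(offs[[r]][1], prev_end)
    prev_end <- offs[[r]][2]
  }
  expect_equal(prev_end, nchar(res$sequence))
  expect_true(startsWith(res$sequence, "GCCACCATGG"))
  coding_len <- nchar(res$sequence) - 10L - 6L
  expect_equal(coding_len %% 3L, 0L)
  expect_true(grepl("CASSLNYGYTF", res$translation, fixed = TRUE))
  expect_equal(res$calls$constant, "TRBC2*01")  # cluster-2 J selects TRBC2
  expect_length(res$warnings, 0L)
})

test_that("non-canonical junctions warn rather than error, strict upgrades", {
  ref <- toy_reference()
  res <- stitch_tcr(ref, "TRBV9", "TRBJ1-2", "GASSLNYGYTF", mode = "aa")
  expect_true(any(grepl("junction_start", res$warnings)))
  ok <- stitch_tcr(ref, "TRBV9", "TRBJ1-2", "CASSLNYGYTF", mode = "aa")
  expect_equal(nchar(res$sequence), nchar(ok$sequence))
  expect_error(
    stitch_tcr(ref, "TRBV9", "TRBJ1-2", "GASSLNYGYTF", mode = "aa",
               strict = TRUE),
    "strict")
})

test_that("stitch errors carry the failing stage", {
  ref <- toy_reference()
  err <- tryCatch(stitch_tcr(ref, "TRBV77", "TRBJ1-2", "CASSLNYGYTF"),
                  error = function(e) e)
  expect_s3_class(err, "vdjweave_error")
  expect_equal(err$stage, "reference")
  err2 <- tryCatch(stitch_tcr(ref, "TRBV9", "TRBJ1-2", "CASSLNYGYTK"),
                   error = function(e) e)
  expect_equal(err2$stage, "junction")
})

test_that("the three input modes agree on the translated product", {
  ref <- fix_ref()
  sims <- fix_sims()[1:60, ]
  translations <- list()
  for (mode in c("aa", "nt", "sl")) {
    rows <- to_stitch_inputs(sims, mode = mode, pad_5 = 20, pad_3 = 20)
    results <- process_batch(rows, ref, mode = mode)
    translations[[mode]] <- vapply(seq_len(nrow(sims)), function(i) {
      r <- chain_result(results, sims, i)
      expect_s3_class(r, "vdj_stitch")
      r$translation
    }, character(1))
  }
  expect_equal(translations$aa, translations$nt)
  expect_equal(translations$aa, translations$sl)
})

test_that("decomposition matches the brute-force germline-maximality oracle", {
  ref <- fix_ref()
  sims <- fix_sims()
  sims <- sims[nchar(sims$junction_aa) <= 20, ]
  sims <- sims[seq_len(min(nrow(sims), 100L)), ]
  for (i in seq_len(nrow(sims))) {
    v <- resolve_segment(ref, sims$v_call[i], "VARIABLE")
    j <- resolve_segment(ref, sims$j_call[i], "JOINING")
    dec <- decompose_junction(sims$junction_aa[i], "aa", v, j,
                              codon_table = ref$codon)
    best <- oracle_split(sims$junction_aa[i], v$aa, v$anchor_res,
                         j$aa, j$anchor_res)
    expect_equal(dec$v_used + dec$j_used, best,
                 info = paste("junction", sims$junction_aa[i]))
  }
})

test_that("every successful stitch keeps the coding span a codon multiple", {
  ref <- fix_ref()
  sims <- fix_sims()[1:50, ]
  results <- process_batch(to_stitch_inputs(sims, "aa"), ref, mode = "aa")
  for (i in seq_along(results)) {
    r <- chain_result(results, sims, i)
    expect_equal(nchar(r$sequence) %% 3L, 0L)
    # no internal stop for productive simulated inputs
    expect_false(grepl("*", substr(r$translation, 1, nchar(r$translation) - 1),
                       fixed = TRUE))
  }
})
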