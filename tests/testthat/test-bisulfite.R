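test_that("bisulfite_reference converts the right base per strand", {
  expect_equal(bisulfite_reference("ACGT", "top"), "ATGT")
  expect_equal(bisulfite_reference("AACG", "bottom"), "AACA")
  expect_equal(bisulfite_reference("TTTT", "top"), "TTTT")
  expect_error(bisulfite_reference("ACXT", "top"), "non-ACGT")
})

test_that("align_clone maps columns and tolerates conversion", {
  ref <- "ACCGTAGGTACCAGTT"
  aln <- align_clone(ref, ref)
  expect_equal(aln$columns$ref_pos, 0:15)
  expect_equal(aln$columns$clone_pos, 0:15)
  expect_equal(aln$identity, 1)

  # a fully converted clone still aligns gap-free with identity 1
  for (s in c("top", "bottom")) {
    aln <- align_clone(bisulfite_reference(ref, s), ref)
    expect_false(any(is.na(aln$columns$ref_pos)))
    expect_false(any(is.na(aln$columns$clone_pos)))
    expect_equal(aln$identity, 1)
  }

  # an internal 2 nt deletion shows as one 2-column gap; check the
  # mapping against exhaustive expectations on a short pair
  clone <- paste0(substr(ref, 1, 6), substr(ref, 9, 16))
  aln <- align_clone(clone, ref)
  gaps <- which(is.na(aln$columns$clone_pos))
  expect_length(gaps, 2)
  expect_equal(diff(gaps), 1)
  expect_equal(sum(!is.na(aln$columns$clone_pos)), nchar(clone))

  expect_error(align_clone("", ref), "non-empty")
})

test_that("low-identity clones are rejected with a typed error", {
  set.seed(17)
  ref <- random_dna(120)
  junk <- random_dna(120)
  expect_error(align_clone(junk, ref),
               class = "bisfoot_alignment_error")
  expect_no_error(align_clone(junk, ref, min_identity = 0))
})

test_that("assign_strand counts bisulfite-consistent mismatches", {
  # 8 C->T and 1 G->A: top with score 8/9
  ref <- paste0(paste(rep("AC", 8), collapse = ""), "AG", "TTT")
  clone <- paste0(paste(rep("AT", 8), collapse = ""), "AA", "TTT")
  sa <- assign_strand(clone, ref)
  expect_equal(sa$strand, "top")
  expect_equal(sa$score, 8 / 9, tolerance = 1e-12)
  expect_equal(c(sa$n_ct, sa$n_ga), c(8, 1))

  # clone identical to reference: nothing informative
  expect_equal(assign_strand(ref, ref)$strand, "undetermined")

  # one-sided G->A: bottom with score 1
  ref2 <- paste(rep("AG", 12), collapse = "")
  clone2 <- paste(rep("AA", 12), collapse = "")
  sb <- assign_strand(clone2, ref2)
  expect_equal(sb$strand, "bottom")
  expect_equal(sb$score, 1)

  # balanced mismatches fall below the dominance threshold
  ref3 <- paste0(paste(rep("AC", 5), collapse = ""),
                 paste(rep("AG", 5), collapse = ""))
  clone3 <- paste0(paste(rep("AT", 5), collapse = ""),
                   paste(rep("AA", 5), collapse = ""))
  expect_equal(assign_strand(clone3, ref3)$strand, "undetermined")
})

test_that("call_conversions enumerates statuses and CpG context", {
  p <- call_conversions("ATCGTT", "ACCGTC", "top")
  expect_equal(p$calls$ref_pos, c(1, 2, 5))
  expect_equal(p$calls$status, c("converted", "unconverted", "converted"))
  expect_equal(p$calls$context, c("non-CpG", "CpG", "non-CpG"))

  ref <- "ACCGTAGGTACCAGTT"
  for (s in c("top", "bottom")) {
    p <- call_conversions(bisulfite_reference(ref, s), ref, s)
    expect_true(all(p$calls$status == "converted"))
    expect_equal(p$n_mismatch_other, 0)
    p0 <- call_conversions(ref, ref, s)
    expect_true(all(p0$calls$status == "unconverted"))
  }

  # non-bisulfite-consistent base is mismatch_other (aligned with a
  # relaxed floor: the toy sequence is too short to pass QC)
  aln <- align_clone("AGCGTC", "ACCGTC", min_identity = 0)
  p <- call_conversions(aln, "ACCGTC", "top")
  expect_equal(p$calls$status[p$calls$ref_pos == 1], "mismatch_other")
  expect_equal(p$n_mismatch_other, 1)

  # bottom strand: CpG context is a G preceded by C
  p <- call_conversions("ACCGTC", "ACCGTC", "bottom")
  expect_equal(p$calls$ref_pos, 3)
  expect_equal(p$calls$context, "CpG")

  expect_error(call_conversions("ACGT", "ACGT", "undetermined"),
               "assign_strand")
})

test_that("gap columns in the clone become excluded calls", {
  ref <- "AACCGGTTAACCGGTTAACC"
  clone <- paste0(substr(ref, 1, 2), substr(ref, 5, 20))  # drop two C
  p <- call_conversions(clone, ref, "top")
  expect_equal(p$calls$status[p$calls$ref_pos %in% c(2, 3)],
               c("excluded", "excluded"))
})

test_that("apply_cpg_rule trusts CpGs only after a conversion run", {
  # k=4, four conversions then a converted CpG -> kept
  p <- profile_from_string("11111",
                           context = c(rep("non-CpG", 4), "CpG"))
  expect_equal(apply_cpg_rule(p, 4)$calls$status[5], "converted")

  # a break in the run demotes the CpG to excluded
  p2 <- profile_from_string("10111",
                            context = c(rep("non-CpG", 4), "CpG"))
  expect_equal(apply_cpg_rule(p2, 4)$calls$status[5], "excluded")

  # k=0 is the identity
  expect_identical(apply_cpg_rule(p2, 0), p2)

  # never touches non-CpG calls; idempotent
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    ctx <- sample(c("CpG", "non-CpG"), n, replace = TRUE,
                  prob = c(0.3, 0.7))
    p <- profile_from_string(random_call_string(n), context = ctx,
                             strand = sample(c("top", "bottom"), 1))
    q <- apply_cpg_rule(p, 4)
    non_cpg <- p$calls$context == "non-CpG"
    expect_identical(q$calls$status[non_cpg], p$calls$status[non_cpg])
    expect_identical(apply_cpg_rule(q, 4), q)
  }
})

test_that("the CpG rule follows the molecule's own 5'->3' direction", {
  # bottom strand reads right to left in top coordinates: the
  # preceding conversions must sit at HIGHER coordinates
  ctx <- c("CpG", rep("non-CpG", 4))
  p <- profile_from_string("11111", context = ctx, strand = "bottom")
  expect_equal(apply_cpg_rule(p, 4)$calls$status[1], "converted")
  p_top <- profile_from_string("11111", context = ctx, strand = "top")
  expect_equal(apply_cpg_rule(p_top, 4)$calls$status[1], "excluded")
})
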