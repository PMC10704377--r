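test_that("simulate_reference is deterministic and respects GC", {
  p <- sim_params(ref_length = 1000, seed = 7, footprints = NULL)
  expect_identical(simulate_reference(p)$seq, simulate_reference(p)$seq)

  p_gc1 <- sim_params(ref_length = 300, gc_fraction = 1,
                      footprints = NULL, seed = 3)
  expect_false(grepl("[AT]", simulate_reference(p_gc1)$seq))

  # planted motif lands where the scanner finds it
  motif <- "GGGAGGGTGGGAGGG"
  p_m <- sim_params(ref_length = 1000, seed = 7, footprints = NULL,
                    planted_g4 = data.frame(position = 100,
                                            motif = motif))
  ref <- simulate_reference(p_m)
  expect_equal(substr(ref$seq, 101, 115), motif)
  hits <- find_g4_conventional(ref$seq)
  expect_true(any(hits$start == 100))

  p_bad <- sim_params(ref_length = 1000, seed = 7, footprints = NULL,
                      planted_g4 = data.frame(position = c(100, 105),
                                              motif = motif))
  expect_error(simulate_reference(p_bad), "overlapping")
})

test_that("degenerate conversion probabilities behave exactly", {
  p <- sim_params(ref_length = 400, p_ss = 1, p_bg = 0, p_seq_err = 0,
                  n_clones = 10, strand_mix = 1,
                  footprints = data.frame(strand = "bottom",
                                          start = 100, end = 160),
                  seed = 5)
  ref <- simulate_reference(p)$seq
  sim <- simulate_bisulfite_clones(ref, p)
  g_in <- which(strsplit(ref, "")[[1]] == "G") - 1L
  g_in <- g_in[g_in >= 100 & g_in < 160]
  for (tc in sim$truth$clones) {
    expect_equal(tc$strand, "bottom")
    expect_setequal(tc$converted_pos, g_in)
  }

  p0 <- sim_params(ref_length = 400, p_ss = 0, p_bg = 0, p_seq_err = 0,
                   n_clones = 5, footprints = NULL, seed = 5)
  sim0 <- simulate_bisulfite_clones(ref, p0)
  expect_true(all(sim0$clones == ref))
})

test_that("truth reconstructs the clone sequences when p_seq_err = 0", {
  p <- sim_params(ref_length = 500, p_seq_err = 0, n_clones = 20,
                  seed = 9)
  ref <- simulate_reference(p)$seq
  sim <- simulate_bisulfite_clones(ref, p)
  for (k in seq_along(sim$clones)) {
    tc <- sim$truth$clones[[k]]
    chars <- strsplit(ref, "")[[1]]
    chars[tc$converted_pos + 1L] <-
      if (tc$strand == "top") "T" else "A"
    expect_identical(paste(chars, collapse = ""),
                     unname(sim$clones[k]))
  }
})

test_that("clone sets are seed-deterministic and strand asymmetry holds", {
  p <- sim_params(seed = 21)
  ref <- simulate_reference(p)$seq
  a <- simulate_bisulfite_clones(ref, p)
  b <- simulate_bisulfite_clones(ref, p)
  expect_identical(a$clones, b$clones)

  # bottom-strand footprint leaves top-strand clones at background:
  # no top-strand clone accumulates a footprint-like conversion run
  p_top <- sim_params(strand_mix = 0, n_clones = 30, seed = 22)
  sim <- simulate_bisulfite_clones(ref, p_top)
  inside <- function(tc) sum(tc$converted_pos >= 250 &
                               tc$converted_pos < 310)
  n_inside <- vapply(sim$truth$clones, inside, numeric(1))
  c_inside <- sum(strsplit(ref, "")[[1]][251:310] == "C")
  expect_lt(mean(n_inside), 0.2 * c_inside)
})

test_that("conversion counts inside footprints are binomial at p_ss", {
  p <- sim_params(p_ss = 0.95, n_clones = 50, strand_mix = 1, seed = 31)
  ref <- simulate_reference(p)$seq
  sim <- simulate_bisulfite_clones(ref, p)
  g_in <- sum(strsplit(ref, "")[[1]][251:310] == "G")
  n_in <- vapply(sim$truth$clones, function(tc)
    sum(tc$converted_pos >= 250 & tc$converted_pos < 310), numeric(1))
  se <- sqrt(g_in * 0.95 * 0.05 / 50)
  expect_lt(abs(mean(n_in) - 0.95 * g_in), 3 * se)
})

test_that("AID simulation respects degenerate rates", {
  ref <- "ATCGATCCGGAT"
  ss <- data.frame(start = 0, end = nchar(ref))
  r0 <- simulate_aid_clones(ref, ss, 0, n_clones = 3, seed = 1)
  expect_true(all(r0$clones == ref))
  expect_equal(nrow(r0$truth$mutations), 0)

  # rate 1, misrepair 0: every exposed C (and bottom-strand C = G)
  # converts in every clone
  interval <- data.frame(start = 2, end = 8)  # CGATCC -> C at 2,6,7; G at 3
  r1 <- simulate_aid_clones(ref, interval, 1, n_clones = 4, seed = 2)
  per_clone <- table(r1$truth$mutations$clone_id)
  expect_true(all(per_clone == 4))
  expect_true(all(r1$truth$mutations$alt_base %in% c("T", "A")))
})

test_that("evaluate_recovery scores matches and boundary offsets", {
  truth <- data.frame(start = 100, end = 160)
  perfect <- evaluate_recovery(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$boundary_error_nt, 0)

  none <- evaluate_recovery(truth[0, ], truth)
  expect_equal(none$recall, 0)

  off <- evaluate_recovery(data.frame(start = 95, end = 165), truth)
  expect_equal(off$n_matched, 1)
  expect_equal(off$boundary_error_nt, 5)

  # reciprocal-overlap gate: a tiny sliver is not a match
  sliver <- evaluate_recovery(data.frame(start = 155, end = 300), truth)
  expect_equal(sliver$n_matched, 0)
  expect_equal(sliver$precision, 0)
})

test_that("truth tables round-trip through TSV", {
  p <- sim_params(n_clones = 4, seed = 12)
  ref <- simulate_reference(p)$seq
  sim <- simulate_bisulfite_clones(ref, p)
  d <- withr::local_tempdir()
  write_truth(sim$truth, d)
  tab <- read.delim(file.path(d, "truth_clones.tsv"),
                    colClasses = "character")
  expect_equal(nrow(tab), 4)
  got <- as.integer(strsplit(tab$converted_pos[1], ",")[[1]])
  expect_equal(got, sim$truth$clones[[1]]$converted_pos)
  fp <- read.delim(file.path(d, "truth_footprints.tsv"))
  expect_equal(fp$start, 250)
})
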