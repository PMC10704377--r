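test_that("continuous stretches are maximal runs of converted calls", {
  p <- profile_from_string(strrep("1", 12))
  st <- find_stretches(p, stretch_config(min_run = 10),
                       mode = "continuous")
  expect_equal(nrow(st), 1)
  expect_equal(st$n_converted, 12)
  expect_equal(c(st$start_pos, st$end_pos), c(0, 11))

  expect_equal(nrow(find_stretches(profile_from_string(strrep("0", 20)),
                                   mode = "continuous")), 0)
  # excluded calls break runs
  p2 <- profile_from_string(paste0(strrep("1", 6), "E", strrep("1", 6)))
  expect_equal(nrow(find_stretches(p2, stretch_config(min_run = 10),
                                   mode = "continuous")), 0)
  expect_equal(nrow(find_stretches(p2, stretch_config(min_run = 6),
                                   mode = "continuous")), 2)

  empty <- profile_from_string("")
  expect_equal(nrow(find_stretches(empty)), 0)
})

test_that("a 12-of-15 window yields one merged windowed stretch", {
  s <- "111011101110111"  # 12 converted of 15
  st <- find_stretches(profile_from_string(s), stretch_config(),
                       mode = "windowed")
  expect_equal(nrow(st), 1)
  expect_equal(st$n_converted, 12)
  expect_equal(st$kind, "windowed")
})

test_that("continuous mode matches a brute-force run scan", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    s <- random_call_string(n)
    min_run <- sample(1:15, 1)
    p <- profile_from_string(s)
    got <- find_stretches(p, stretch_config(min_run = min_run),
                          mode = "continuous")
    want <- oracle_runs(p$calls$status, min_run)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(c(got$start_pos[k], got$end_pos[k]), want[[k]] - 1L)
      expect_equal(got$n_converted[k], diff(want[[k]]) + 1L)
    }
  }
})

test_that("windowed mode matches exhaustive window evaluation", {
  set.seed(202)
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    s <- random_call_string(n)
    w <- sample(5:15, 1)
    k <- sample(3:w, 1)
    p <- profile_from_string(s)
    got <- find_stretches(p, stretch_config(min_run = 10, window = w,
                                            min_in_window = k),
                          mode = "windowed")
    want <- oracle_windows(p$calls$status, w, k)
    kept_pos <- p$calls$ref_pos[p$calls$status != "excluded"]
    expect_equal(nrow(got), length(want))
    for (j in seq_along(want)) {
      expect_equal(c(got$start_pos[j], got$end_pos[j]),
                   kept_pos[want[[j]]])
    }
  }
})

test_that("windowed stretches survive scattered excluded calls", {
  # 12 conversions within 15 informative calls, interleaved with E
  s <- "11E10111E0111101111E"
  p <- profile_from_string(s)
  got <- find_stretches(p, stretch_config(), mode = "windowed")
  want <- oracle_windows(p$calls$status, 15, 12)
  expect_equal(nrow(got), length(want))
})

test_that("classify_clone applies category precedence", {
  cfg <- stretch_config()
  expect_equal(classify_clone(profile_from_string(strrep("1", 16)), cfg),
               "run_gt15")
  expect_equal(classify_clone(profile_from_string(strrep("1", 11)), cfg),
               "run_gt10")
  # longest run 8 but a 12-of-15 window exists
  s <- paste0("11111111", "0", "1110", "11111111")
  expect_equal(classify_clone(profile_from_string(s), cfg),
               "windowed_only")
  expect_equal(classify_clone(profile_from_string("10101010"), cfg),
               "none")
  # boundary: a run of exactly 15 is not >15
  expect_equal(classify_clone(profile_from_string(strrep("1", 15)), cfg),
               "run_gt10")
})

test_that("positionwise_frequency counts coverage and conversions", {
  p1 <- profile_from_string("1E0", positions = c(5, 9, 12))
  p2 <- profile_from_string("011", positions = c(5, 9, 12))
  tab <- positionwise_frequency(list(p1, p2))
  expect_equal(tab$ref_pos, c(5, 9, 12))
  expect_equal(tab$n_covered, c(2, 1, 2))
  expect_equal(tab$n_converted, c(1, 1, 1))
  expect_equal(tab$fraction, c(0.5, 1, 0.5))

  # all-excluded position has undefined frequency
  tab2 <- positionwise_frequency(list(profile_from_string("E"),
                                      profile_from_string("E")))
  expect_equal(tab2$n_covered, 0)
  expect_true(is.na(tab2$fraction))

  # 10 clones: 7 converted, 1 excluded, 2 unconverted -> 7/9
  profs <- lapply(strsplit(paste0(strrep("1", 7), "E00"), "")[[1]],
                  profile_from_string)
  expect_equal(positionwise_frequency(profs)$fraction, 7 / 9)

  pb <- profile_from_string("1", strand = "bottom")
  expect_error(positionwise_frequency(list(p1, pb)), "mix")
})

test_that("frequency fractions are bounded and conversions conserved", {
  set.seed(303)
  for (i in 1:20) {
    profs <- lapply(1:8, function(j)
      profile_from_string(random_call_string(30)))
    tab <- positionwise_frequency(profs)
    expect_true(all(tab$fraction[!is.na(tab$fraction)] >= 0))
    expect_true(all(tab$fraction[!is.na(tab$fraction)] <= 1))
    expect_equal(sum(tab$n_converted),
                 sum(vapply(profs, function(p)
                   sum(p$calls$status == "converted"), numeric(1))))
  }
})

test_that("call_footprints merges plateaus and honours thresholds", {
  # fraction 0.8 plateau over 60 nt of informative positions
  pos <- seq(100, 159, by = 2)
  freq <- data.frame(ref_pos = pos, n_converted = 8, n_covered = 10,
                     fraction = 0.8)
  fp <- call_footprints(freq, min_fraction = 0.5, min_span = 30,
                        max_gap = 10)
  expect_equal(nrow(fp), 1)
  expect_equal(c(fp$start, fp$end), c(100, 159))
  expect_equal(fp$mean_fraction, 0.8)

  # uniform background never calls
  freq_bg <- data.frame(ref_pos = pos, n_converted = 0, n_covered = 10,
                        fraction = 0.02)
  expect_equal(nrow(call_footprints(freq_bg)), 0)

  # two plateaus 200 nt apart, with background-level informative
  # positions in between, stay separate at max_gap 20
  between <- data.frame(ref_pos = seq(170, 350, by = 4),
                        n_converted = 0, n_covered = 10,
                        fraction = 0.02)
  freq2 <- rbind(freq, between,
                 transform(freq, ref_pos = ref_pos + 260))
  fp2 <- call_footprints(freq2, max_gap = 20)
  expect_equal(nrow(fp2), 2)
  expect_equal(fp2$start, c(100, 360))

  # a no-data span (no informative cytosines) does not split a
  # footprint
  freq3 <- rbind(freq, transform(freq, ref_pos = ref_pos + 100))
  fp3 <- call_footprints(freq3, max_gap = 10)
  expect_equal(nrow(fp3), 1)
  expect_equal(c(fp3$start, fp3$end), c(100, 259))

  # a single noisy sub-threshold position is bridged
  noisy <- rbind(freq,
                 data.frame(ref_pos = 131, n_converted = 3,
                            n_covered = 10, fraction = 0.3))
  expect_equal(nrow(call_footprints(noisy)), 1)

  expect_equal(nrow(call_footprints(freq[0, ])), 0)

  # sub-minimum span is dropped
  short <- data.frame(ref_pos = 10:19, n_converted = 9, n_covered = 10,
                      fraction = 0.9)
  expect_equal(nrow(call_footprints(short, min_span = 30)), 0)
})

test_that("supporting clones require half their covered calls converted", {
  strong <- profile_from_string(strrep("1", 10), positions = 100:109)
  weak <- profile_from_string(strrep("0", 10), positions = 100:109)
  freq <- positionwise_frequency(list(strong, strong, weak))
  fp <- call_footprints(freq, min_fraction = 0.5, min_span = 5,
                        max_gap = 2,
                        profiles = list(strong, strong, weak))
  expect_equal(fp$n_supporting_clones, 2)
})

test_that("compare_conditions tabulates cumulative run categories", {
  a <- list(profile_from_string(strrep("1", 20)),
            profile_from_string(strrep("1", 12)),
            profile_from_string("101010"))
  b <- list(profile_from_string("000000"))
  tab <- compare_conditions(a, b, labels = c("untreated", "rnaseh"))
  expect_equal(tab$n_run_gt10, c(2, 0))
  expect_equal(tab$n_run_gt15, c(1, 0))
  expect_equal(tab$n_total, c(3, 1))
  # identical sets give identical rows
  tab2 <- compare_conditions(a, a)
  expect_equal(tab2$n_run_gt10[1], tab2$n_run_gt10[2])
})

test_that("profile matrix export encodes calls as 1/0/E/M", {
  f <- withr::local_tempfile(fileext = ".tsv")
  p1 <- profile_from_string("10EM", positions = c(2, 4, 6, 8))
  mat <- write_profile_matrix(list(p1), f)
  expect_equal(unname(mat[1, ]), c("1", "0", "E", "M"))
  tab <- read.delim(f, check.names = FALSE, colClasses = "character")
  expect_equal(names(tab), c("clone_id", "2", "4", "6", "8"))
})
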