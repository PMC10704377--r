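# Independent oracles used to cross-check the scanners. These are
# deliberately naive (character-level recursion, brute-force window
# evaluation) and share no code with the package implementations.

# Build a conversion_profile directly from a call-status string
# ("1" converted, "0" unconverted, "E" excluded, "M" mismatch_other),
# informative positions at the given reference coordinates.
profile_from_string <- function(s, positions = NULL, strand = "top",
                                context = NULL) {
  st <- strsplit(s, "")[[1]]
  status <- c(`1` = "converted", `0` = "unconverted", E = "excluded",
              M = "mismatch_other")[st]
  if (is.null(positions)) positions <- seq_along(st) - 1L
  if (is.null(context)) context <- rep("non-CpG", length(st))
  structure(list(clone_id = "synthetic", strand = strand,
                 calls = data.frame(ref_pos = as.integer(positions),
                                    context = context,
                                    status = unname(status),
                                    stringsAsFactors = FALSE),
                 n_informative = length(st),
                 n_mismatch_other = sum(status == "mismatch_other"),
                 high_mismatch = FALSE),
            class = "conversion_profile")
}

# Brute-force continuous-run finder: scan every maximal run by eye.
oracle_runs <- function(status, min_run) {
  conv <- status == "converted"
  out <- list()
  i <- 1L
  while (i <= length(conv)) {
    if (!conv[i]) { i <- i + 1L; next }
    j <- i
    while (j < length(conv) && conv[j + 1L]) j <- j + 1L
    if (j - i + 1L >= min_run) out[[length(out) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  out
}

# Brute-force windowed finder over non-excluded calls: evaluate every
# length-w slice, mark covered indices, take maximal covered runs,
# trim to converted calls. Returns list of index pairs into the
# non-excluded call vector.
oracle_windows <- function(status, w, k) {
  keep <- status != "excluded"
  conv <- (status == "converted")[keep]
  n <- length(conv)
  if (n < w) return(list())
  covered <- rep(FALSE, n)
  for (i in seq_len(n - w + 1L)) {
    if (sum(conv[i:(i + w - 1L)]) >= k) covered[i:(i + w - 1L)] <- TRUE
  }
  out <- list()
  i <- 1L
  while (i <= n) {
    if (!covered[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && covered[j + 1L]) j <- j + 1L
    idx <- i:j
    cidx <- idx[conv[idx]]
    if (length(cidx) > 0L) out[[length(out) + 1L]] <- range(cidx)
    i <- j + 1L
  }
  out
}

# Naive recursive G4 decomposition test: does chars[from..to] split
# into exactly 4 tracts and 3 loops under the given rules? No
# memoisation, no G-run precomputation.
oracle_is_g4 <- function(chars, from, to, min_tract = 3, min_loop = 1,
                         max_loop_std = 7, max_long_loop = 7,
                         allow_bulge = FALSE) {
  is_tract <- function(a, b, bulge_ok) {
    seg <- chars[a:b]
    if (all(seg == "G")) return(list(ok = length(seg) >= min_tract,
                                     bulged = FALSE))
    if (!bulge_ok) return(list(ok = FALSE, bulged = FALSE))
    non_g <- which(seg != "G")
    ok <- length(non_g) == 1L && non_g > 1L && non_g < length(seg) &&
      sum(seg == "G") >= min_tract
    list(ok = ok, bulged = TRUE)
  }
  rec <- function(pos, tracts_left, ll_free, bulge_free) {
    if (tracts_left == 0L) return(pos == to + 1L)
    if (pos > to) return(FALSE)
    for (tend in pos:to) {
      tr <- is_tract(pos, tend, bulge_free)
      if (!tr$ok) next
      bf <- bulge_free && !tr$bulged
      if (tracts_left == 1L) {
        if (rec(tend + 1L, 0L, ll_free, bf)) return(TRUE)
        next
      }
      for (loop in min_loop:(if (ll_free) max_long_loop else max_loop_std)) {
        nxt <- tend + 1L + loop
        if (nxt > to + 1L) break
        if (rec(nxt, tracts_left - 1L,
                ll_free && loop <= max_loop_std, bf)) return(TRUE)
      }
    }
    FALSE
  }
  rec(from, 4L, max_long_loop > max_loop_std, allow_bulge)
}

# All decomposable spans (0-based half-open) of a string, by brute
# force over every substring.
oracle_g4_spans <- function(seq, min_tract = 3, min_loop = 1,
                            max_loop_std = 7, max_long_loop = 7,
                            allow_bulge = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  min_len <- 4L * min_tract + 3L * min_loop
  spans <- list()
  for (a in seq_len(n)) {
    if (chars[a] != "G") next
    for (b in a:n) {
      if (b - a + 1L < min_len) next
      if (chars[b] != "G" && !(allow_bulge)) next
      if (oracle_is_g4(chars, a, b, min_tract, min_loop, max_loop_std,
                       max_long_loop, allow_bulge)) {
        spans[[length(spans) + 1L]] <- c(a - 1L, b)
      }
    }
  }
  if (length(spans) == 0L) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, spans))
}

random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

random_call_string <- function(n) {
  paste(sample(c("1", "0", "E", "M"), n, replace = TRUE,
               prob = c(0.5, 0.3, 0.1, 0.1)), collapse = "")
}

spans_as_set <- function(m) {
  if (nrow(m) == 0) character(0) else paste(m[, 1], m[, 2], sep = "-")
}
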