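# Sequence-motif analyses: AID WRC hotspots, conventional and extended
# G-quadruplex motifs, GC content and GC skew.
#
# The conventional G4 motif is four tracts of >= 3 G separated by three
# loops of 1-7 nt. The extended definition additionally allows (i) one
# loop to extend up to `max_long_loop` nt (a long loop that can fold
# into a duplex hairpin) and (ii) one tract to carry a single non-G
# interruption (a bulged G+NG+ tract) provided its total G count still
# reaches `min_tract`.

#' G-quadruplex scanning configuration
#'
#' @param min_tract Minimum number of G's per tract (conventional >= 3).
#' @param min_loop,max_loop_std Standard loop length bounds in nt.
#' @param max_long_loop Upper bound for the single permitted long loop
#'   (extended scanning only; default 21 nt, the range over which a
#'   loop can plausibly fold back as a duplex hairpin).
#' @param allow_bulge Permit one bulged `G+NG+` tract (extended only).
#' @return List of class `g4_config`.
#' @export
g4_config <- function(min_tract = 3, min_loop = 1, max_loop_std = 7,
                      max_long_loop = 21, allow_bulge = TRUE) {
  stopifnot(min_tract >= 2, min_loop >= 1, max_loop_std >= min_loop,
            max_long_loop >= max_loop_std)
  structure(list(min_tract = min_tract, min_loop = min_loop,
                 max_loop_std = max_loop_std,
                 max_long_loop = max_long_loop,
                 allow_bulge = allow_bulge),
            class = "g4_config")
}

#' Find AID hotspot WRC motifs
#'
#' Scans for the AID deamination hotspot WRC (W = A/T, R = A/G,
#' then C). Minus-strand occurrences are reported as GYW matches on
#' the given sequence (G, Y = C/T, W = A/T) with `strand = "-"`.
#' Overlapping occurrences are all reported.
#'
#' @param seq DNA string (ACGT).
#' @param both_strands Also report minus-strand (GYW) hits.
#' @return `data.frame` with `motif_class`, `strand`, `start`, `end`
#'   (0-based half-open) and `matched_sequence` (plus-strand
#'   spelling).
#' @export
find_wrc <- function(seq, both_strands = TRUE) {
  .check_dna(seq)
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  empty <- data.frame(motif_class = character(), strand = character(),
                      start = integer(), end = integer(),
                      matched_sequence = character())
  if (n < 3L) return(empty)
  i <- seq_len(n - 2L)
  as_hits <- function(at, strand) {
    if (length(at) == 0L) return(empty)
    data.frame(motif_class = "WRC", strand = strand,
               start = at - 1L, end = at + 2L,
               matched_sequence = substring(seq, at, at + 2L))
  }
  plus <- i[s[i] %in% c("A", "T") & s[i + 1L] %in% c("A", "G") &
              s[i + 2L] == "C"]
  hits <- as_hits(plus, "+")
  if (both_strands) {
    minus <- i[s[i] == "G" & s[i + 1L] %in% c("C", "T") &
                 s[i + 2L] %in% c("A", "T")]
    hits <- rbind(hits, as_hits(minus, "-"))
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Memoised depth-first search over G4 decompositions. State:
# (character position, tracts still needed, long loop still
# available, bulge still available). Returns, per state, the set of
# valid end positions (exclusive, 1-based). Tracts may use any prefix
# of a G-run of length >= min_tract; a bulged tract must consume a
# full leading G-run, one non-G base, and >= 1 further G. The engine
# is built once per sequence and queried at every candidate start.
.g4_engine <- function(chars, cfg, extended) {
  n <- length(chars)
  grun <- integer(n)  # length of G-run starting at each position
  run <- 0L
  for (i in rev(seq_len(n))) {
    run <- if (chars[i] == "G") run + 1L else 0L
    grun[i] <- run
  }
  memo <- new.env(parent = emptyenv())
  max_loop_one <- if (extended) cfg$max_long_loop else cfg$max_loop_std

  ends_from <- function(pos, tracts_left, ll_free, bulge_free) {
    key <- paste0(pos, ":", tracts_left, ":", ll_free, ":", bulge_free)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- integer(0)
    if (pos <= n) {
      # candidate tracts starting exactly at pos
      tract_ends <- integer(0)       # end position (exclusive), pure
      bulge_ends <- integer(0)       # end position (exclusive), bulged
      if (grun[pos] >= cfg$min_tract) {
        tract_ends <- pos + cfg$min_tract:grun[pos]
      }
      if (extended && cfg$allow_bulge && bulge_free && grun[pos] >= 1L) {
        a <- grun[pos]
        gap <- pos + a
        if (gap <= n - 1L && chars[gap] != "G" && grun[gap + 1L] >= 1L) {
          b_needed <- max(1L, cfg$min_tract - a)
          if (grun[gap + 1L] >= b_needed) {
            bulge_ends <- gap + 1L + b_needed:grun[gap + 1L]
          }
        }
      }
      advance <- function(tract_end, used_bulge) {
        if (tracts_left == 1L) {
          res <<- c(res, tract_end)
          return(invisible())
        }
        loop_max <- if (ll_free) max_loop_one else cfg$max_loop_std
        for (loop in cfg$min_loop:loop_max) {
          nxt <- tract_end + loop
          ll2 <- ll_free && loop <= cfg$max_loop_std
          res <<- c(res, ends_from(nxt, tracts_left - 1L, ll2,
                                   bulge_free && !used_bulge))
        }
      }
      for (e in tract_ends) advance(e, FALSE)
      for (e in bulge_ends) advance(e, TRUE)
    }
    res <- sort(unique(res))
    memo[[key]] <- res
    res
  }
  function(start) ends_from(start, 4L, extended, TRUE)
}

# Recover one decomposition (tract spans, loop lengths, flags) for a
# hit [start, end); prefers decompositions without long loop or bulge.
.g4_structure <- function(chars, start, end, cfg, extended) {
  n <- length(chars)
  best <- NULL
  rec <- function(pos, tracts, loops, ll_used, bulge_idx) {
    if (!is.null(best)) return(invisible())
    if (length(tracts) == 4L) {
      if (pos == end) {
        best <<- list(tracts = tracts, loops = loops,
                      long_loop = ll_used, bulge_tract = bulge_idx)
      }
      return(invisible())
    }
    if (pos >= end) return(invisible())
    run <- 0L
    while (pos + run <= n && pos + run < end + 1L &&
           chars[pos + run] == "G") run <- run + 1L
    cand <- list()
    if (run >= cfg$min_tract) {
      for (len in cfg$min_tract:run) {
        cand[[length(cand) + 1L]] <- list(e = pos + len, bulge = FALSE)
      }
    }
    if (extended && cfg$allow_bulge && is.na(bulge_idx) && run >= 1L) {
      gap <- pos + run
      if (gap < end && chars[gap] != "G") {
        b <- 0L
        while (gap + 1L + b <= n && chars[gap + 1L + b] == "G") b <- b + 1L
        b_needed <- max(1L, cfg$min_tract - run)
        if (b >= b_needed) {
          for (len in b_needed:b) {
            cand[[length(cand) + 1L]] <- list(e = gap + 1L + len,
                                              bulge = TRUE)
          }
        }
      }
    }
    for (cnd in cand) {
      tr <- c(tracts, list(c(pos - 1L, cnd$e - 1L)))  # 0-based half-open
      bi <- if (cnd$bulge) length(tr) else bulge_idx
      if (length(tr) == 4L) {
        rec(cnd$e, tr, loops, ll_used, bi)
      } else {
        loop_max <- if (extended && !ll_used) cfg$max_long_loop
                    else cfg$max_loop_std
        for (loop in cfg$min_loop:loop_max) {
          rec(cnd$e + loop, tr, c(loops, loop),
              ll_used || loop > cfg$max_loop_std, bi)
        }
      }
      if (!is.null(best)) break
    }
  }
  rec(start, list(), integer(0), FALSE, NA_integer_)
  best
}

.g4_scan <- function(seq, cfg, extended, overlapping, class_label) {
  .check_dna(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  empty <- data.frame(motif_class = character(), strand = character(),
                      start = integer(), end = integer(),
                      matched_sequence = character())
  rows <- list()
  structures <- list()
  engine <- .g4_engine(chars, cfg, extended)
  pos <- 1L
  while (pos <= n) {
    if (chars[pos] != "G") { pos <- pos + 1L; next }
    ends <- engine(pos)
    if (length(ends) == 0L) { pos <- pos + 1L; next }
    if (overlapping) {
      for (e in ends) {
        rows[[length(rows) + 1L]] <- c(pos - 1L, e - 1L)
      }
      pos <- pos + 1L
    } else {
      e <- max(ends)  # leftmost-maximal; search resumes after the hit
      rows[[length(rows) + 1L]] <- c(pos - 1L, e - 1L)
      structures[[length(rows)]] <- .g4_structure(chars, pos, e, cfg,
                                                  extended)
      pos <- e
    }
  }
  if (length(rows) == 0L) return(empty)
  mat <- do.call(rbind, rows)
  hits <- data.frame(motif_class = class_label, strand = "+",
                     start = mat[, 1], end = mat[, 2],
                     matched_sequence = substring(seq, mat[, 1] + 1L,
                                                  mat[, 2]))
  if (!overlapping) {
    hits$structure <- I(structures)
    hits$long_loop <- vapply(structures, function(s)
      isTRUE(s$long_loop), logical(1))
    hits$bulge_tract <- vapply(structures, function(s)
      if (is.null(s)) NA_integer_ else s$bulge_tract, integer(1))
  }
  rownames(hits) <- NULL
  hits
}

#' Find conventional G-quadruplex motifs
#'
#' Plus-strand matches of four runs of at least `min_tract` G's
#' separated by three loops of `min_loop`-`max_loop_std` nt. Reporting
#' is greedy leftmost-maximal and non-overlapping: at the leftmost
#' matching start the longest valid match is emitted and the search
#' resumes after its end. `overlapping = TRUE` instead enumerates every
#' decomposable span (used to validate against exhaustive
#' enumeration).
#'
#' @param seq DNA string (ACGT).
#' @param cfg A `g4_config` (loop/tract bounds; the extended-only
#'   fields are ignored here).
#' @param overlapping Report all decomposable spans instead of greedy
#'   non-overlapping hits.
#' @return `data.frame` of hits with `motif_class`, `strand`, `start`,
#'   `end`, `matched_sequence`, and (greedy mode) a `structure` list
#'   column with 4 tract spans and 3 loop lengths plus `long_loop` and
#'   `bulge_tract` flags.
#' @export
find_g4_conventional <- function(seq, cfg = g4_config(),
                                 overlapping = FALSE) {
  .g4_scan(seq, cfg, extended = FALSE, overlapping = overlapping,
           class_label = "G4_conventional")
}

#' Find extended G-quadruplex motifs
#'
#' As [find_g4_conventional()], but additionally admitting at most one
#' loop of up to `max_long_loop` nt (hairpin-forming long loop) and,
#' when `allow_bulge` is set, at most one bulged `G+NG+` tract whose
#' total G count reaches `min_tract`. Every span matching the
#' conventional definition also matches the extended one.
#'
#' @inheritParams find_g4_conventional
#' @return `data.frame` of hits; see [find_g4_conventional()].
#' @export
find_g4_extended <- function(seq, cfg = g4_config(),
                             overlapping = FALSE) {
  .g4_scan(seq, cfg, extended = TRUE, overlapping = overlapping,
           class_label = "G4_extended")
}

#' GC content of a sequence
#'
#' @param seq Non-empty DNA string.
#' @return Percent G+C, in 0-100.
#' @export
gc_content <- function(seq) {
  if (nchar(seq) == 0L) stop("empty sequence")
  .check_dna(seq)
  s <- strsplit(seq, "")[[1]]
  100 * sum(s %in% c("G", "C")) / length(s)
}

#' Windowed GC skew
#'
#' Computes (G - C) / (G + C) in sliding windows. Skew > 0 marks
#' G-richness of the given strand, a sequence feature favouring R-loop
#' formation when the displaced strand is G-rich.
#'
#' @param seq DNA string.
#' @param window Window size in nt (must not exceed the sequence).
#' @param step Step between window starts in nt.
#' @return `data.frame` with `window_start` (0-based) and `skew` (`NA`
#'   where the window holds no G or C).
#' @export
gc_skew <- function(seq, window = 100, step = window) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  .check_dna(seq)
  n <- nchar(seq)
  if (window > n) stop("window exceeds sequence length")
  s <- strsplit(seq, "")[[1]]
  cg <- cumsum(s == "G")
  cc <- cumsum(s == "C")
  starts <- seq(1L, n - window + 1L, by = step)
  g <- cg[starts + window - 1L] - c(0L, cg)[starts]
  c_ <- cc[starts + window - 1L] - c(0L, cc)[starts]
  data.frame(window_start = starts - 1L,
             skew = ifelse(g + c_ > 0, (g - c_) / (g + c_), NA_real_))
}
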