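# Conversion stretches, per-position frequency and footprint calls.
#
# A "stretch" of converted cytosines in one molecule is the operational
# evidence of single-strandedness. Two detection modes are used:
# continuous (a maximal run of >= min_run consecutive converted
# informative calls) and windowed (some window of `window` consecutive
# informative calls contains >= min_in_window conversions, e.g. 12 of
# 15). Run lengths count converted cytosines, not nucleotide span; the
# span in nt is reported separately.

#' Stretch-detection configuration
#'
#' @param min_run Minimum number of consecutive converted informative
#'   calls for a continuous stretch.
#' @param window Number of consecutive informative calls in the
#'   windowed criterion.
#' @param min_in_window Minimum conversions within the window.
#' @param cpg_run_k Continuous conversions required before a CpG call
#'   is trusted (see [apply_cpg_rule()]).
#' @return List of class `stretch_config`.
#' @export
stretch_config <- function(min_run = 10, window = 15, min_in_window = 12,
                           cpg_run_k = 4) {
  stopifnot(min_run >= 1, min_in_window > 0, min_in_window <= window,
            cpg_run_k >= 0)
  structure(list(min_run = min_run, window = window,
                 min_in_window = min_in_window, cpg_run_k = cpg_run_k),
            class = "stretch_config")
}

.empty_stretches <- function() {
  data.frame(start_pos = integer(), end_pos = integer(),
             n_converted = integer(), n_informative = integer(),
             span_nt = integer(), kind = character())
}

#' Find conversion stretches in one clone
#'
#' Continuous mode reports maximal runs of at least `min_run`
#' consecutive informative calls with status `converted`; `excluded`
#' calls break runs (as do unconverted and mismatch_other calls, the
#' latter counting as unconverted evidence). Windowed mode drops
#' `excluded` calls (indels and ambiguity should not mimic unconverted
#' cytosines), slides a window of `window` consecutive informative
#' calls, and merges overlapping qualifying windows into one stretch
#' trimmed to its first and last converted call.
#'
#' @param profile A `conversion_profile`.
#' @param cfg A `stretch_config`.
#' @param mode `"continuous"`, `"windowed"` or `"both"`.
#' @return `data.frame` with `start_pos`, `end_pos` (0-based, inclusive
#'   of the first/last converted cytosine), `n_converted`,
#'   `n_informative`, `span_nt` and `kind`.
#' @export
find_stretches <- function(profile, cfg = stretch_config(),
                           mode = c("both", "continuous", "windowed")) {
  mode <- match.arg(mode)
  calls <- profile$calls[order(profile$calls$ref_pos), , drop = FALSE]
  out <- .empty_stretches()
  if (nrow(calls) == 0L) return(out)

  if (mode %in% c("both", "continuous")) {
    conv <- calls$status == "converted"
    r <- rle(conv)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= cfg$min_run
    if (any(keep)) {
      out <- rbind(out, data.frame(
        start_pos = calls$ref_pos[starts[keep]],
        end_pos = calls$ref_pos[ends[keep]],
        n_converted = r$lengths[keep],
        n_informative = r$lengths[keep],
        span_nt = calls$ref_pos[ends[keep]] - calls$ref_pos[starts[keep]] + 1L,
        kind = "continuous"))
    }
  }

  if (mode %in% c("both", "windowed")) {
    kept <- calls[calls$status != "excluded", , drop = FALSE]
    conv <- kept$status == "converted"
    n <- length(conv)
    w <- cfg$window
    if (n >= w) {
      counts <- as.integer(stats::filter(as.integer(conv), rep(1L, w),
                                         sides = 1))[w:n]
      qual <- which(counts >= cfg$min_in_window)  # window start indices
      if (length(qual) > 0L) {
        grp <- cumsum(c(TRUE, diff(qual) > w))  # merge overlapping windows
        for (g in unique(grp)) {
          idx_first <- qual[grp == g][1]
          idx_last <- utils::tail(qual[grp == g], 1) + w - 1L
          span_idx <- idx_first:idx_last
          conv_idx <- span_idx[conv[span_idx]]
          if (length(conv_idx) == 0L) next
          conv_idx <- min(conv_idx):max(conv_idx)
          out <- rbind(out, data.frame(
            start_pos = kept$ref_pos[min(conv_idx)],
            end_pos = kept$ref_pos[max(conv_idx)],
            n_converted = sum(conv[conv_idx]),
            n_informative = length(conv_idx),
            span_nt = kept$ref_pos[max(conv_idx)] -
              kept$ref_pos[min(conv_idx)] + 1L,
            kind = "windowed"))
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Classify a clone by its strongest conversion evidence
#'
#' The highest category attained by a clone: `run_gt15` when some
#' continuous run exceeds 15 converted cytosines, else `run_gt10` for a
#' run exceeding 10, else `windowed_only` when a windowed stretch
#' exists, else `none`.
#'
#' @param profile A `conversion_profile`.
#' @param cfg A `stretch_config` (supplies the windowed criterion).
#' @return One of `"run_gt15"`, `"run_gt10"`, `"windowed_only"`,
#'   `"none"`.
#' @export
classify_clone <- function(profile, cfg = stretch_config()) {
  runs <- find_stretches(profile, stretch_config(
    min_run = 1, window = cfg$window,
    min_in_window = cfg$min_in_window, cpg_run_k = cfg$cpg_run_k),
    mode = "continuous")
  max_run <- if (nrow(runs) > 0L) max(runs$n_converted) else 0L
  if (max_run > 15) return("run_gt15")
  if (max_run > 10) return("run_gt10")
  win <- find_stretches(profile, cfg, mode = "windowed")
  if (nrow(win) > 0L) "windowed_only" else "none"
}

#' Cumulative per-position conversion frequency
#'
#' Aggregates conversion calls over clones of one strand into the
#' cumulative conversion frequency at each informative reference
#' position. `excluded` calls reduce coverage; `mismatch_other` calls
#' count as covered but unconverted.
#'
#' @param profiles List of `conversion_profile`s sharing one strand
#'   (mixing strands is an error: the two strands interrogate
#'   different cytosines and must be summarised separately).
#' @param region Optional region (`list`/single-row `data.frame` with
#'   `start`, `end`) restricting the table.
#' @return `data.frame` with `ref_pos`, `n_converted`, `n_covered`,
#'   `fraction` (`NA` where no clone covers the position).
#' @export
positionwise_frequency <- function(profiles, region = NULL) {
  stopifnot(length(profiles) > 0)
  strands <- vapply(profiles, function(p) p$strand, character(1))
  if (length(unique(strands)) > 1L) {
    stop("profiles mix strands; summarise each strand separately")
  }
  calls <- do.call(rbind, lapply(profiles, function(p) p$calls))
  pos <- sort(unique(calls$ref_pos))
  conv <- tapply(calls$status == "converted", calls$ref_pos, sum)
  cov <- tapply(calls$status != "excluded", calls$ref_pos, sum)
  tab <- data.frame(ref_pos = pos,
                    n_converted = as.integer(conv[as.character(pos)]),
                    n_covered = as.integer(cov[as.character(pos)]))
  tab$fraction <- ifelse(tab$n_covered > 0,
                         tab$n_converted / tab$n_covered, NA_real_)
  if (!is.null(region)) {
    tab <- tab[tab$ref_pos >= region$start & tab$ref_pos < region$end, ,
               drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Call single-stranded footprints from a frequency table
#'
#' Merges informative positions whose conversion fraction reaches
#' `min_fraction` into intervals and keeps intervals spanning at least
#' `min_span` nt. Two consecutive qualifying positions are merged when
#' the contrary evidence between them is short: the covered
#' informative positions between them that fall below `min_fraction`
#' must span at most `max_gap` nt. A stretch of sequence with no
#' informative cytosine at all carries no evidence either way and
#' never splits a footprint; likewise, positions whose coverage has
#' collapsed below half the table's median (typically CpG sites
#' demoted by the conversion-run rule, leaving a biased residue of
#' clones) are treated as no-data. The defaults (0.5 / 30 nt / 10 nt) are
#' tuned so that footprints down to 30-40 nt, the shortest
#' biologically reported, remain recoverable at realistic cytosine
#' densities.
#'
#' @param freq Frequency table from [positionwise_frequency()].
#' @param min_fraction Minimum conversion fraction of a qualifying
#'   position.
#' @param min_span Minimum footprint span in nt.
#' @param max_gap Maximum nt span of sub-threshold covered positions
#'   bridged between qualifying positions.
#' @param profiles Optional list of `conversion_profile`s used to count
#'   supporting clones (clones whose covered informative calls inside
#'   the interval are at least 50% converted).
#' @param strand Strand label attached to the calls.
#' @return `data.frame` with `start`, `end` (0-based half-open),
#'   `strand`, `span_nt`, `mean_fraction` (over covered informative
#'   positions in the interval) and `n_supporting_clones` (`NA` when
#'   `profiles` is absent).
#' @export
call_footprints <- function(freq, min_fraction = 0.5, min_span = 30,
                            max_gap = 10, profiles = NULL,
                            strand = NA_character_) {
  stopifnot(min_fraction > 0, min_span > 0, max_gap >= 0)
  out <- data.frame(start = integer(), end = integer(),
                    strand = character(), span_nt = integer(),
                    mean_fraction = numeric(),
                    n_supporting_clones = integer())
  if (is.null(freq) || nrow(freq) == 0L) return(out)
  covered <- freq[!is.na(freq$fraction), , drop = FALSE]
  if ("n_covered" %in% names(covered) && nrow(covered) > 0L) {
    covered <- covered[covered$n_covered >=
                         0.5 * stats::median(covered$n_covered), ,
                       drop = FALSE]
  }
  if (nrow(covered) == 0L) return(out)
  covered <- covered[order(covered$ref_pos), , drop = FALSE]
  qual <- covered$ref_pos[covered$fraction >= min_fraction]
  if (length(qual) == 0L) return(out)
  low <- covered$ref_pos[covered$fraction < min_fraction]
  splits <- vapply(seq_len(length(qual) - 1L), function(i) {
    between <- low[low > qual[i] & low < qual[i + 1L]]
    length(between) > 0L && diff(range(between)) + 1L > max_gap
  }, logical(1))
  grp <- cumsum(c(TRUE, splits))
  for (g in unique(grp)) {
    p <- qual[grp == g]
    start <- min(p); end <- max(p) + 1L
    if (end - start < min_span) next
    inside <- freq$ref_pos >= start & freq$ref_pos < end &
      !is.na(freq$fraction)
    n_sup <- NA_integer_
    if (!is.null(profiles)) {
      sup <- vapply(profiles, function(pr) {
        cc <- pr$calls[pr$calls$ref_pos >= start & pr$calls$ref_pos < end &
                         pr$calls$status != "excluded", , drop = FALSE]
        nrow(cc) > 0L && mean(cc$status == "converted") >= 0.5
      }, logical(1))
      n_sup <- sum(sup)
    }
    out <- rbind(out, data.frame(
      start = start, end = end, strand = strand,
      span_nt = end - start,
      mean_fraction = mean(freq$fraction[inside]),
      n_supporting_clones = n_sup))
  }
  rownames(out) <- NULL
  out
}

#' Compare clone classifications between two conditions
#'
#' Tabulates, per condition (e.g. with and without RNase H), how many
#' clones carry continuous conversion runs of more than 10 and more
#' than 15 cytosines, and how many qualify only under the windowed
#' criterion. Counts of run lengths are cumulative (a clone with a
#' 17-conversion run counts in both `n_run_gt10` and `n_run_gt15`);
#' zero counts are reported as 0.
#'
#' @param profiles_a,profiles_b Non-empty lists of
#'   `conversion_profile`s for the two conditions.
#' @param cfg A `stretch_config`.
#' @param labels Length-2 character vector of condition names.
#' @return `data.frame` with `condition`, `n_total`, `n_run_gt10`,
#'   `n_run_gt15`, `n_windowed_only`.
#' @export
compare_conditions <- function(profiles_a, profiles_b,
                               cfg = stretch_config(),
                               labels = c("A", "B")) {
  stopifnot(length(profiles_a) > 0, length(profiles_b) > 0)
  one <- function(profiles, label) {
    cls <- vapply(profiles, classify_clone, character(1), cfg = cfg)
    data.frame(condition = label, n_total = length(profiles),
               n_run_gt10 = sum(cls %in% c("run_gt10", "run_gt15")),
               n_run_gt15 = sum(cls == "run_gt15"),
               n_windowed_only = sum(cls == "windowed_only"))
  }
  rbind(one(profiles_a, labels[1]), one(profiles_b, labels[2]))
}

#' Export conversion profiles as a clone-by-position matrix
#'
#' Writes a TSV with one row per clone and one column per informative
#' reference position; cells are `1` (converted), `0` (unconverted),
#' `E` (excluded) or `M` (mismatch_other).
#'
#' @param profiles List of `conversion_profile`s (one strand).
#' @param path Output TSV path.
#' @return The character matrix, invisibly.
#' @export
write_profile_matrix <- function(profiles, path) {
  pos <- sort(unique(unlist(lapply(profiles,
                                   function(p) p$calls$ref_pos))))
  code <- c(converted = "1", unconverted = "0", excluded = "E",
            mismatch_other = "M")
  mat <- matrix(".", nrow = length(profiles), ncol = length(pos),
                dimnames = list(vapply(profiles, function(p) p$clone_id,
                                       character(1)), pos))
  for (i in seq_along(profiles)) {
    calls <- profiles[[i]]$calls
    mat[i, match(calls$ref_pos, pos)] <- code[calls$status]
  }
  utils::write.table(cbind(clone_id = rownames(mat), as.data.frame(mat)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mat)
}
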