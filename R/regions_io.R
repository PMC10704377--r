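#' Read a FASTA file of DNA sequences
#'
#' Reads a (multi-)FASTA file, folds sequences to upper case and checks
#' that only the characters A, C, G, T and N remain. Used for both the
#' reference locus and sequenced clone sets.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case DNA strings, one element
#'   per record, named by the first whitespace-delimited token of each
#'   header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal characters (non-ACGTN) in FASTA record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA strings.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Build regions from an anchor and offset/length entries
#'
#' Region layouts at a locus are often given as offsets from an anchor
#' such as a transcription start site ("starts 277 nt downstream of
#' P1"). Each entry `(name, offset, length)` yields the 0-based
#' half-open interval `[anchor + offset, anchor + offset + length)`.
#'
#' @param anchor 0-based coordinate of the anchor position.
#' @param entries `data.frame` with columns `name`, `offset`, `length`
#'   (non-negative integers, nt).
#' @param ref_id Sequence identifier the regions live on.
#' @param strand Strand label for the regions (`"+"`, `"-"` or `"*"`).
#' @return `data.frame` with columns `name`, `ref_id`, `start`, `end`,
#'   `strand` (0-based half-open), carrying the attribute `span`, a list
#'   with the union span `start`, `end` and `length` over all entries.
#' @seealso [region_span()], [region_overlap()]
#' @export
make_regions <- function(anchor, entries, ref_id = "locus", strand = "*") {
  stopifnot(is.data.frame(entries),
            all(c("name", "offset", "length") %in% names(entries)))
  if (any(entries$offset < 0) || any(entries$length <= 0)) {
    stop("offsets must be non-negative and lengths positive")
  }
  start <- as.integer(anchor + entries$offset)
  end <- as.integer(start + entries$length)
  if (any(start < 0)) stop("negative resulting coordinate")
  regions <- data.frame(name = as.character(entries$name),
                        ref_id = ref_id,
                        start = start, end = end,
                        strand = strand,
                        stringsAsFactors = FALSE)
  attr(regions, "span") <- list(start = min(start), end = max(end),
                                length = max(end) - min(start))
  regions
}

#' Union span of a set of regions
#'
#' @param regions `data.frame` with `start` and `end` columns.
#' @return List with `start`, `end` and `length` of the enclosing span.
#' @export
region_span <- function(regions) {
  stopifnot(nrow(regions) > 0)
  list(start = min(regions$start), end = max(regions$end),
       length = max(regions$end) - min(regions$start))
}

#' Overlap between two intervals
#'
#' @param a,b Single-row region `data.frame`s, or lists with `start` and
#'   `end`.
#' @return List with `start`, `end`, `length` of the intersection, or
#'   `NULL` when the intervals are disjoint.
#' @export
region_overlap <- function(a, b) {
  s <- max(a$start, b$start)
  e <- min(a$end, b$end)
  if (e <= s) return(NULL)
  list(start = s, end = e, length = e - s)
}

#' Read a breakpoint position list from TSV
#'
#' Expects a header row and a column named `position` (0-based
#' coordinates). Positions are sorted on load; duplicates are kept
#' (several patients can share a breakpoint site).
#'
#' @param path TSV file path.
#' @param source_label Free-text label attached to the set.
#' @return List with sorted integer vector `positions` and
#'   `source_label`.
#' @export
read_breakpoints <- function(path, source_label = basename(path)) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE)
  if (!"position" %in% names(tab)) stop("TSV needs a 'position' column")
  list(positions = sort(as.integer(tab$position)),
       source_label = source_label)
}

#' Cluster breakpoint positions along a sequence
#'
#' Single-linkage 1-D clustering: consecutive sorted positions belong to
#' the same cluster when the gap between them does not exceed
#' `gap_threshold`. This is how dispersed patient breakpoints condense
#' into a small number of breakpoint clusters along a locus.
#'
#' @param positions Integer vector of 0-based breakpoint coordinates
#'   (need not be sorted; duplicates allowed), or the list returned by
#'   [read_breakpoints()].
#' @param gap_threshold Maximum joining gap in nt (> 0). A gap exactly
#'   equal to the threshold still joins.
#' @return `data.frame` with columns `cluster_id`, `start`, `end`
#'   (inclusive extremes of member positions) and `count`, ordered left
#'   to right. Empty input gives a zero-row frame.
#' @export
cluster_breakpoints <- function(positions, gap_threshold = 200) {
  if (is.list(positions)) positions <- positions$positions
  stopifnot(gap_threshold > 0)
  empty <- data.frame(cluster_id = integer(), start = integer(),
                      end = integer(), count = integer())
  if (length(positions) == 0L) return(empty)
  p <- sort(as.integer(positions))
  new_cluster <- c(TRUE, diff(p) > gap_threshold)
  id <- cumsum(new_cluster)
  data.frame(cluster_id = seq_len(max(id)),
             start = as.integer(tapply(p, id, min)),
             end = as.integer(tapply(p, id, max)),
             count = as.integer(tapply(p, id, length)),
             row.names = NULL)
}

#' Read a signal track (bedGraph or wiggle)
#'
#' Imports a processed signal track such as a DRIP-seq coverage file.
#' Both bedGraph and fixed/variable-step wiggle dialects are accepted
#' (dispatched on file extension by rtracklayer). Intervals that touch
#' the same base twice are rejected: overlapping records indicate a
#' malformed track and silently overwriting one value with another
#' would hide that.
#'
#' @param path bedGraph (`.bedGraph`/`.bg`) or wiggle (`.wig`) file.
#' @return List of class `signal_track` with `ref_id` and a
#'   `data.frame` `intervals` (`start`, `end` 0-based half-open,
#'   `value`), sorted by start.
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  gr <- rtracklayer::import(path)
  if (length(gr) == 0L) stop("track contains no intervals: ", path)
  ref_ids <- as.character(GenomicRanges::seqnames(gr))
  if (length(unique(ref_ids)) > 1L) {
    stop("multi-reference tracks are not supported; found: ",
         paste(unique(ref_ids), collapse = ", "))
  }
  ints <- data.frame(start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     value = as.numeric(gr$score))
  ints <- ints[order(ints$start), , drop = FALSE]
  if (any(!is.finite(ints$value))) stop("non-finite track values")
  if (nrow(ints) > 1L && any(ints$start[-1] < ints$end[-nrow(ints)])) {
    stop("overlapping track intervals (same base covered twice)")
  }
  structure(list(ref_id = ref_ids[1], intervals = ints),
            class = "signal_track")
}

#' Summarise a signal track over a region
#'
#' Base-weighted summary of track values across a region: the mean is
#' weighted by the number of covered bases each interval contributes,
#' uncovered bases contribute nothing to the mean, and
#' `covered_fraction` is covered bases over region length.
#'
#' @param track A `signal_track` from [read_track()], or a compatible
#'   list.
#' @param region Single-row region `data.frame` (or list) with `start`,
#'   `end` and optionally `ref_id`.
#' @return List with `mean`, `max` and `covered_fraction`. When no base
#'   of the region is covered, `mean` and `max` are `NA` and
#'   `covered_fraction` is 0.
#' @export
summarize_track <- function(track, region) {
  if (!is.null(region$ref_id) && !is.null(track$ref_id) &&
      region$ref_id != track$ref_id) {
    stop("region ref_id does not match track ref_id")
  }
  ints <- track$intervals
  ov_start <- pmax(ints$start, region$start)
  ov_end <- pmin(ints$end, region$end)
  w <- pmax(0L, ov_end - ov_start)
  covered <- sum(w)
  len <- region$end - region$start
  if (covered == 0L) {
    return(list(mean = NA_real_, max = NA_real_, covered_fraction = 0))
  }
  list(mean = sum(ints$value * w) / covered,
       max = max(ints$value[w > 0]),
       covered_fraction = covered / len)
}

#' Write intervals as a BED file
#'
#' Writes BED6 (or BED4 when `score`/`strand` are absent). Internal
#' coordinates are already 0-based half-open, so they are emitted as-is.
#'
#' @param x `data.frame` with columns `start`, `end`, and optionally
#'   `ref_id`, `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  n <- nrow(x)
  chrom <- if ("ref_id" %in% names(x)) x$ref_id else rep("locus", n)
  name <- if ("name" %in% names(x)) x$name else rep(".", n)
  out <- data.frame(chrom = chrom, start = x$start, end = x$end,
                    name = name)
  if ("score" %in% names(x) || "strand" %in% names(x)) {
    out$score <- if ("score" %in% names(x)) x$score else 0
    out$strand <- if ("strand" %in% names(x)) x$strand else "*"
    out$strand[!out$strand %in% c("+", "-")] <- "."
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
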