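# Core single-molecule bisulfite machinery.
#
# Coordinates are 0-based half-open throughout; `ref_pos` in all call
# tables is a 0-based reference coordinate. Bottom-strand molecules are
# always expressed in top-strand coordinates: a converted bottom-strand
# cytosine appears as G -> A against the top-strand reference.

.check_dna <- function(seq, what = "sequence") {
  if (grepl("[^ACGT]", seq)) stop(what, " contains non-ACGT characters")
  invisible(seq)
}

#' Fully bisulfite-converted reference
#'
#' The in-silico image of a completely single-stranded, completely
#' converted molecule: on the top strand every C reads as T; on the
#' bottom strand every C reads as T in bottom coordinates, which in
#' top-strand coordinates is every G reading as A.
#'
#' @param ref Reference DNA string (ACGT).
#' @param strand `"top"` or `"bottom"`.
#' @return Converted DNA string in top-strand coordinates.
#' @export
bisulfite_reference <- function(ref, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  .check_dna(ref, "reference")
  if (strand == "top") chartr("C", "T", ref) else chartr("G", "A", ref)
}

# Fold the bisulfite-ambiguous letters: C -> T and G -> A. Aligning
# folded sequences makes C/T and G/A pairs exact matches, so heavy
# conversion cannot distort the alignment (the standard
# three-letter-alphabet trick of bisulfite mappers, applied on both
# strands at once).
.bs_fold <- function(seq) chartr("CG", "TA", seq)

#' Bisulfite-aware global alignment of a clone to the reference
#'
#' Globally aligns a sequenced clone to the reference with affine gap
#' penalties, scoring C/T and G/A pairs as matches so that bisulfite
#' conversions (on either strand) do not attract spurious gaps. The
#' alignment is computed on bisulfite-folded sequences (C->T, G->A on
#' both sequences; match +1, mismatch -1, gap open 4, gap extend 1) and
#' the column mapping is reported against the original bases.
#'
#' Clone quality is gated on the fully informative columns: aligned
#' columns that are neither exact matches of a bisulfite-neutral pair
#' nor C/T / G/A substitutions. Identity is exact matches over exact
#' matches plus non-neutral mismatches; clones below `min_identity`
#' are rejected with an error of class `bisfoot_alignment_error`.
#'
#' @param clone Clone DNA string (ACGTN; N is treated as mismatching
#'   everything).
#' @param ref Reference DNA string (ACGT).
#' @param min_identity Identity floor on fully informative columns.
#' @param gap_opening,gap_extension Affine gap costs (non-negative).
#' @return Object of class `clone_alignment`: list with `columns` (a
#'   `data.frame` of `ref_pos`, `ref_base`, `clone_pos`, `clone_base`,
#'   gaps as `NA`/`"-"`), `identity`, `n_ref`, `n_clone`.
#' @export
align_clone <- function(clone, ref, min_identity = 0.9,
                        gap_opening = 4, gap_extension = 1) {
  if (nchar(clone) == 0L || nchar(ref) == 0L) {
    stop("clone and reference must be non-empty")
  }
  .check_dna(ref, "reference")
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                      mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(
    pattern = .bs_fold(clone), subject = .bs_fold(ref),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  clone_chars <- strsplit(clone, "")[[1]]
  ref_chars <- strsplit(ref, "")[[1]]

  clone_idx <- ifelse(pat == "-", NA_integer_, cumsum(pat != "-"))
  ref_idx <- ifelse(sub == "-", NA_integer_, cumsum(sub != "-"))
  columns <- data.frame(
    ref_pos = ref_idx - 1L,
    ref_base = ifelse(is.na(ref_idx), "-", ref_chars[ref_idx]),
    clone_pos = clone_idx - 1L,
    clone_base = ifelse(is.na(clone_idx), "-", clone_chars[clone_idx]),
    stringsAsFactors = FALSE)

  both <- !is.na(columns$ref_pos) & !is.na(columns$clone_pos)
  rb <- columns$ref_base[both]
  cb <- columns$clone_base[both]
  neutral <- (rb == "C" & cb == "T") | (rb == "T" & cb == "C") |
    (rb == "G" & cb == "A") | (rb == "A" & cb == "G")
  informative <- !neutral
  identity <- if (any(informative)) {
    sum(rb[informative] == cb[informative]) / sum(informative)
  } else 1
  if (identity < min_identity) {
    stop(structure(class = c("bisfoot_alignment_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "clone rejected: identity %.3f below floor %.3f",
                     identity, min_identity),
                     call = sys.call(-1))))
  }
  structure(list(columns = columns, identity = identity,
                 score = Biostrings::score(pa),
                 n_ref = nchar(ref), n_clone = nchar(clone)),
            class = "clone_alignment")
}

.as_alignment <- function(clone, ref, ...) {
  if (inherits(clone, "clone_alignment")) clone else align_clone(clone, ref, ...)
}

#' Assign the strand of origin of a bisulfite clone
#'
#' A bisulfite-treated top-strand molecule accumulates C->T reads
#' against the reference; a bottom-strand molecule accumulates G->A
#' (its own C->T, seen in top coordinates). The strand is called from
#' the dominant class of bisulfite-consistent mismatches.
#'
#' The call is `undetermined` when fewer than `min_informative`
#' bisulfite-consistent mismatches are present or when the dominant
#' class accounts for less than `min_score` of them.
#'
#' @param clone Clone DNA string, or a `clone_alignment`.
#' @param ref Reference DNA string (ignored when `clone` is already an
#'   alignment).
#' @param min_informative Minimum C->T + G->A mismatches required.
#' @param min_score Minimum fraction of the dominant class.
#' @return List with `strand` (`"top"`, `"bottom"` or
#'   `"undetermined"`), `score`, `n_ct`, `n_ga`.
#' @export
assign_strand <- function(clone, ref = NULL, min_informative = 3,
                          min_score = 0.8) {
  aln <- .as_alignment(clone, ref)
  cols <- aln$columns
  both <- !is.na(cols$ref_pos) & !is.na(cols$clone_pos)
  n_ct <- sum(cols$ref_base[both] == "C" & cols$clone_base[both] == "T")
  n_ga <- sum(cols$ref_base[both] == "G" & cols$clone_base[both] == "A")
  total <- n_ct + n_ga
  if (total < min_informative) {
    return(list(strand = "undetermined", score = NA_real_,
                n_ct = n_ct, n_ga = n_ga))
  }
  score <- max(n_ct, n_ga) / total
  strand <- if (score < min_score) "undetermined"
  else if (n_ct > n_ga) "top" else "bottom"
  list(strand = strand, score = score, n_ct = n_ct, n_ga = n_ga)
}

.cpg_context <- function(ref_chars, strand) {
  n <- length(ref_chars)
  if (strand == "top") {
    # C followed by G on the top strand
    idx <- which(ref_chars == "C")
    idx[idx < n & ref_chars[pmin(idx + 1L, n)] == "G"]
  } else {
    # bottom-strand C (top G) whose bottom-strand successor is G, i.e.
    # top-strand C immediately 5' of the G: a CG dinucleotide read on
    # the other strand
    idx <- which(ref_chars == "G")
    idx[idx > 1L & ref_chars[pmax(idx - 1L, 1L)] == "C"]
  }
}

#' Call per-cytosine conversion states for one clone
#'
#' For a top-strand molecule the informative positions are the
#' reference C's; for a bottom-strand molecule they are the reference
#' G's (the molecule's own cytosines, read in top coordinates). Each
#' informative position is called `converted` when the clone shows the
#' bisulfite-expected base (T for a top C, A for a bottom G),
#' `unconverted` when it matches the reference, `excluded` at gap or N
#' columns, and `mismatch_other` for any other substitution (not
#' bisulfite-consistent; tallied for QC). CpG context is flagged from
#' the reference: a C followed by G on the molecule's own strand.
#'
#' @param clone Clone DNA string, or a `clone_alignment`.
#' @param ref Reference DNA string.
#' @param strand `"top"` or `"bottom"`. An undetermined strand is an
#'   error; run [assign_strand()] first.
#' @param clone_id Identifier carried through to outputs.
#' @return Object of class `conversion_profile`: list with `clone_id`,
#'   `strand`, `calls` (`data.frame` of `ref_pos`, `context`
#'   (`"CpG"`/`"non-CpG"`), `status`), `n_informative`,
#'   `n_mismatch_other`, and a QC flag `high_mismatch` set when
#'   mismatch_other calls exceed 5% of informative positions.
#' @export
call_conversions <- function(clone, ref, strand, clone_id = "clone") {
  if (!strand %in% c("top", "bottom")) {
    stop("strand must be 'top' or 'bottom'; run assign_strand() first")
  }
  aln <- .as_alignment(clone, ref)
  cols <- aln$columns
  ref_chars <- character(aln$n_ref)
  ok <- !is.na(cols$ref_pos)
  ref_chars[cols$ref_pos[ok] + 1L] <- cols$ref_base[ok]

  informative_base <- if (strand == "top") "C" else "G"
  expected_base <- if (strand == "top") "T" else "A"
  inf_idx <- which(ref_chars == informative_base)  # 1-based
  if (length(inf_idx) == 0L) {
    calls <- data.frame(ref_pos = integer(), context = character(),
                        status = character())
    return(structure(list(clone_id = clone_id, strand = strand,
                          calls = calls, n_informative = 0L,
                          n_mismatch_other = 0L, high_mismatch = FALSE),
                     class = "conversion_profile"))
  }
  cpg_idx <- .cpg_context(ref_chars, strand)
  context <- ifelse(inf_idx %in% cpg_idx, "CpG", "non-CpG")

  # clone base at each informative reference position (gap columns of
  # the reference cannot carry an informative position)
  clone_base <- rep("-", length(inf_idx))
  m <- match(inf_idx - 1L, cols$ref_pos)
  clone_base[!is.na(m)] <- cols$clone_base[m[!is.na(m)]]
  status <- ifelse(clone_base %in% c("-", "N"), "excluded",
            ifelse(clone_base == expected_base, "converted",
            ifelse(clone_base == informative_base, "unconverted",
                   "mismatch_other")))
  calls <- data.frame(ref_pos = inf_idx - 1L, context = context,
                      status = status, stringsAsFactors = FALSE)
  n_mm <- sum(status == "mismatch_other")
  structure(list(clone_id = clone_id, strand = strand, calls = calls,
                 n_informative = nrow(calls), n_mismatch_other = n_mm,
                 high_mismatch = n_mm > 0.05 * nrow(calls)),
            class = "conversion_profile")
}

#' Resolve methylation-ambiguous CpG conversions
#'
#' A CpG cytosine that reads unconverted may be protected by
#' methylation rather than double-strandedness, so CpG conversion
#' calls are only trusted inside an established run of conversion: a
#' converted CpG keeps its status only when the `cpg_run_k`
#' immediately preceding non-CpG informative calls (in the molecule's
#' own 5'->3' direction: increasing coordinates for top-strand
#' molecules, decreasing for bottom-strand) are all converted.
#' Otherwise it is reclassified `excluded` (methylation-ambiguous).
#' Non-CpG calls are never touched; `cpg_run_k = 0` is the identity.
#'
#' @param profile A `conversion_profile`.
#' @param cpg_run_k Number of continuous preceding conversions
#'   required (default 4; 2 is an alternative in circulation).
#' @return The modified `conversion_profile`.
#' @export
apply_cpg_rule <- function(profile, cpg_run_k = 4) {
  stopifnot(inherits(profile, "conversion_profile"), cpg_run_k >= 0)
  if (cpg_run_k == 0 || nrow(profile$calls) == 0L) return(profile)
  calls <- profile$calls
  ord <- order(calls$ref_pos,
               decreasing = identical(profile$strand, "bottom"))
  st <- calls$status[ord]
  cx <- calls$context[ord]
  for (i in which(cx == "CpG" & st == "converted")) {
    prev <- which(cx[seq_len(i - 1L)] == "non-CpG")
    if (length(prev) < cpg_run_k ||
        !all(st[utils::tail(prev, cpg_run_k)] == "converted")) {
      st[i] <- "excluded"
    }
  }
  calls$status[ord] <- st
  profile$calls <- calls
  profile
}
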