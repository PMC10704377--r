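# AID deamination mutation calling, frequency and condition ratios.
#
# AID deaminates cytosine to uracil on single-stranded DNA; after
# replication this reads as C->T (or G->A when the deaminated C sat on
# the bottom strand), while aberrant base-excision repair of the
# uracil can leave any other substitution. Mutation frequency is the
# number of mutations per total nucleotide sequenced across clones.

#' Call point mutations in a clone against the reference
#'
#' Every aligned substitution column emits a record. Columns within
#' `gap_flank` nt of an alignment gap are excluded (and tallied):
#' indel-adjacent columns are alignment artifacts more often than
#' mutations. With `exclude_bisulfite_like`, C->T and G->A records are
#' suppressed — on bisulfite-treated material those are conversions,
#' not mutations.
#'
#' @param clone Clone DNA string, or a `clone_alignment`.
#' @param ref Reference DNA string.
#' @param exclude_bisulfite_like Drop C->T and G->A substitutions.
#' @param clone_id Identifier carried into the records.
#' @param gap_flank Exclusion distance (alignment columns) around
#'   gaps.
#' @return `data.frame` with `clone_id`, `ref_pos` (0-based),
#'   `ref_base`, `alt_base`, `substitution_class` (e.g. `"C>T"`) and
#'   `in_motif` (`NA` until [annotate_mutations()] is run). Attributes
#'   `n_indel_columns` and `n_near_gap_excluded` carry the tallies;
#'   `aligned_nt` carries the number of aligned non-gap clone
#'   nucleotides (the clone's contribution to total nt sequenced).
#' @export
call_mutations <- function(clone, ref, exclude_bisulfite_like = FALSE,
                           clone_id = "clone", gap_flank = 2) {
  aln <- .as_alignment(clone, ref)
  cols <- aln$columns
  gap <- is.na(cols$ref_pos) | is.na(cols$clone_pos)
  near_gap <- rep(FALSE, nrow(cols))
  if (any(gap) && gap_flank > 0) {
    for (i in which(gap)) {
      lo <- max(1L, i - gap_flank)
      hi <- min(nrow(cols), i + gap_flank)
      near_gap[lo:hi] <- TRUE
    }
  }
  subst <- !gap & cols$ref_base != cols$clone_base &
    cols$clone_base != "N"
  kept <- subst & !near_gap
  rec <- data.frame(clone_id = rep(clone_id, sum(kept)),
                    ref_pos = cols$ref_pos[kept],
                    ref_base = cols$ref_base[kept],
                    alt_base = cols$clone_base[kept],
                    stringsAsFactors = FALSE)
  rec$substitution_class <- if (nrow(rec) > 0L) {
    paste0(rec$ref_base, ">", rec$alt_base)
  } else character(0)
  if (exclude_bisulfite_like) {
    rec <- rec[!rec$substitution_class %in% c("C>T", "G>A"), ,
               drop = FALSE]
  }
  rec$in_motif <- rep(NA, nrow(rec))
  rownames(rec) <- NULL
  attr(rec, "n_indel_columns") <- sum(gap)
  attr(rec, "n_near_gap_excluded") <- sum(subst & near_gap)
  attr(rec, "aligned_nt") <- sum(!gap)
  rec
}

#' Total nucleotides sequenced across clone alignments
#'
#' Sums aligned, non-gap clone nucleotides over a clone set — the
#' denominator of the mutation frequency. (The amplicon-length-times-
#' clones alternative can be computed directly by the caller.)
#'
#' @param clones Named character vector of clone sequences, or list of
#'   `clone_alignment`s.
#' @param ref Reference DNA string (when `clones` are sequences).
#' @return Integer total.
#' @export
total_nt_sequenced <- function(clones, ref = NULL) {
  sum(vapply(clones, function(cl) {
    aln <- .as_alignment(cl, ref)
    cols <- aln$columns
    sum(!is.na(cols$ref_pos) & !is.na(cols$clone_pos))
  }, numeric(1)))
}

#' Summarise mutation records into a mutation frequency
#'
#' @param records Mutation record `data.frame` (possibly from several
#'   clones, rbind-ed).
#' @param total_nt Total nucleotides sequenced (> 0).
#' @return List of class `mutation_summary`: `n_mutations`,
#'   `total_nt_sequenced`, `frequency` (mutations per nt), `percent`,
#'   and `per_class` (named count vector partitioning `n_mutations`).
#' @export
mutation_frequency <- function(records, total_nt) {
  if (total_nt <= 0) stop("total_nt must be positive")
  n <- nrow(records)
  per_class <- if (n > 0) {
    tab <- table(records$substitution_class)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  structure(list(n_mutations = n, total_nt_sequenced = total_nt,
                 frequency = n / total_nt,
                 percent = 100 * n / total_nt,
                 per_class = per_class),
            class = "mutation_summary")
}

#' Percent reduction of a mutation frequency between conditions
#'
#' `100 * (freq_a - freq_b) / freq_a`: how much condition B (e.g.
#' RNase H treated) reduces the frequency relative to condition A.
#'
#' @param freq_a Baseline frequency (> 0); a `mutation_summary` is
#'   also accepted.
#' @param freq_b Comparison frequency (or `mutation_summary`).
#' @return Percent reduction (negative when B exceeds A).
#' @export
condition_reduction <- function(freq_a, freq_b) {
  if (inherits(freq_a, "mutation_summary")) freq_a <- freq_a$frequency
  if (inherits(freq_b, "mutation_summary")) freq_b <- freq_b$frequency
  if (freq_a <= 0) stop("baseline frequency must be positive")
  100 * (freq_a - freq_b) / freq_a
}

#' Flag mutations at or near motif hits
#'
#' Sets `in_motif` when a mutation lies inside a motif hit span or
#' within `flank` nt of it.
#'
#' @param records Mutation record `data.frame`.
#' @param motif_hits Hit `data.frame` with `start`, `end` (0-based
#'   half-open, same coordinates as the records).
#' @param flank Flank in nt around each hit.
#' @return `records` with `in_motif` filled in.
#' @export
annotate_mutations <- function(records, motif_hits, flank = 5) {
  if (nrow(records) == 0L) {
    records$in_motif <- logical(0)
    return(records)
  }
  records$in_motif <- vapply(records$ref_pos, function(p) {
    any(p >= motif_hits$start - flank & p < motif_hits$end + flank)
  }, logical(1))
  records
}

#' Write mutation records as a minimal VCF-like file
#'
#' One line per record: CHROM, 1-based POS, ID (`.`), REF, ALT, QUAL
#' (`.`), FILTER (`.`), INFO carrying `CLONE=` and `INMOTIF=` when
#' annotated.
#'
#' @param records Mutation record `data.frame`.
#' @param path Output path.
#' @param ref_id Reference identifier for CHROM.
#' @return `path`, invisibly.
#' @export
write_mutations_vcf <- function(records, path, ref_id = "locus") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", ref_id, ">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(records) > 0L) {
    info <- paste0("CLONE=", records$clone_id,
                   ifelse(is.na(records$in_motif), "",
                          paste0(";INMOTIF=", as.integer(records$in_motif))))
    writeLines(paste(ref_id, records$ref_pos + 1L, ".", records$ref_base,
                     records$alt_base, ".", ".", info, sep = "\t"), con)
  }
  invisible(path)
}
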