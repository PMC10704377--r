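# Seeded simulator for reference loci, bisulfite clone sets with
# planted single-stranded footprints, and AID-mutagenised clone sets,
# all with full ground truth. Footprints are strand-specific: a
# bottom-strand footprint produces no excess conversion on top-strand
# clones, encoding the strand asymmetry that distinguishes a genuine
# R-loop signal from background. All randomness flows through R's
# default generator under the seed stored in the parameters.

#' Simulation parameters
#'
#' Defaults encode the reference condition used throughout the
#' package's validation: a 600 nt locus at 50% GC carrying one 60 nt
#' bottom-strand single-stranded footprint; near-complete conversion
#' (`p_ss = 0.95`) of informative cytosines inside a footprint, sparse
#' background conversion (`p_bg = 0.02`) elsewhere, and a low
#' per-base sequencing error (`p_seq_err = 0.001`); 50 clones with
#' half drawn from each strand.
#'
#' @param ref_length Reference length in nt.
#' @param gc_fraction Background GC fraction of the simulated locus.
#' @param planted_g4 Optional `data.frame` with `position` (0-based)
#'   and `motif` (string) to overwrite into the reference.
#' @param footprints `data.frame` with `strand` (`"top"`/`"bottom"`),
#'   `start`, `end` (0-based half-open) of planted single-stranded
#'   intervals; `NULL` for none.
#' @param p_ss Conversion probability per informative cytosine inside
#'   a footprint on the clone's strand.
#' @param p_bg Background conversion probability elsewhere.
#' @param p_seq_err Per-base sequencing error probability (uniform
#'   substitution to one of the three other bases).
#' @param n_clones Number of clones.
#' @param strand_mix Fraction of bottom-strand clones.
#' @param seed Integer seed; fully determines all output.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(ref_length = 600, gc_fraction = 0.5,
                       planted_g4 = NULL,
                       footprints = data.frame(strand = "bottom",
                                               start = 250L,
                                               end = 310L),
                       p_ss = 0.95, p_bg = 0.02, p_seq_err = 0.001,
                       n_clones = 50, strand_mix = 0.5, seed = 1L) {
  probs <- c(p_ss, p_bg, p_seq_err, strand_mix, gc_fraction)
  stopifnot(all(probs >= 0 & probs <= 1), ref_length > 0, n_clones >= 0)
  if (!is.null(footprints) && nrow(footprints) > 0) {
    stopifnot(all(footprints$start >= 0),
              all(footprints$end <= ref_length),
              all(footprints$end > footprints$start),
              all(footprints$strand %in% c("top", "bottom")))
  }
  structure(list(ref_length = as.integer(ref_length),
                 gc_fraction = gc_fraction, planted_g4 = planted_g4,
                 footprints = footprints, p_ss = p_ss, p_bg = p_bg,
                 p_seq_err = p_seq_err, n_clones = as.integer(n_clones),
                 strand_mix = strand_mix, seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a reference locus
#'
#' I.i.d. background sequence at the requested GC fraction, with any
#' planted motifs overwritten at their positions (coordinates are
#' preserved in the returned truth).
#'
#' @param params A `sim_params`.
#' @return List with `seq` (DNA string) and `planted` (`data.frame` of
#'   `position`, `motif`, or `NULL`).
#' @export
simulate_reference <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  gc <- params$gc_fraction
  chars <- sample(c("A", "C", "G", "T"), params$ref_length,
                  replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  planted <- params$planted_g4
  if (!is.null(planted) && nrow(planted) > 0) {
    planted <- planted[order(planted$position), , drop = FALSE]
    last_end <- -1L
    for (i in seq_len(nrow(planted))) {
      p0 <- planted$position[i]
      m <- strsplit(planted$motif[i], "")[[1]]
      if (p0 < last_end) stop("overlapping planted motifs")
      if (p0 + length(m) > params$ref_length) {
        stop("planted motif extends beyond the reference")
      }
      chars[(p0 + 1L):(p0 + length(m))] <- m
      last_end <- p0 + length(m)
    }
  }
  list(seq = paste(chars, collapse = ""), planted = planted)
}

.substitute_errors <- function(chars, p_err) {
  hit <- which(stats::runif(length(chars)) < p_err)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  list(chars = chars, positions = hit - 1L)
}

#' Simulate a bisulfite-treated clone set with planted footprints
#'
#' Each clone draws a strand of origin (`bottom` with probability
#' `strand_mix`); each informative cytosine (reference C for top
#' clones, reference G — the bottom-strand C — for bottom clones)
#' converts with probability `p_ss` inside a footprint on the clone's
#' strand and `p_bg` elsewhere; sequencing errors are then applied
#' uniformly. Clones are emitted in top-strand coordinates. Every
#' decision is recorded in the truth.
#'
#' @param ref Reference DNA string.
#' @param params A `sim_params`.
#' @return List with `clones` (named character vector) and `truth`
#'   (list: `params`, `footprints`, and per-clone list `clones` with
#'   `strand`, `converted_pos`, `error_pos`, all 0-based).
#' @export
simulate_bisulfite_clones <- function(ref, params) {
  stopifnot(inherits(params, "sim_params"))
  .check_dna(ref, "reference")
  set.seed(params$seed + 1L)
  ref_chars <- strsplit(ref, "")[[1]]
  fp <- params$footprints
  in_fp <- function(pos0, strand) {
    if (is.null(fp) || nrow(fp) == 0L) return(rep(FALSE, length(pos0)))
    rows <- fp[fp$strand == strand, , drop = FALSE]
    vapply(pos0, function(p)
      any(p >= rows$start & p < rows$end), logical(1))
  }
  clones <- character(params$n_clones)
  truth_clones <- vector("list", params$n_clones)
  ids <- sprintf("clone_%03d", seq_len(max(params$n_clones, 1L)))
  for (k in seq_len(params$n_clones)) {
    strand <- if (stats::runif(1) < params$strand_mix) "bottom" else "top"
    inf_base <- if (strand == "top") "C" else "G"
    conv_to <- if (strand == "top") "T" else "A"
    inf_pos0 <- which(ref_chars == inf_base) - 1L
    p <- ifelse(in_fp(inf_pos0, strand), params$p_ss, params$p_bg)
    converted <- inf_pos0[stats::runif(length(inf_pos0)) < p]
    chars <- ref_chars
    chars[converted + 1L] <- conv_to
    err <- .substitute_errors(chars, params$p_seq_err)
    clones[k] <- paste(err$chars, collapse = "")
    truth_clones[[k]] <- list(clone_id = ids[k], strand = strand,
                              converted_pos = converted,
                              error_pos = err$positions)
  }
  names(clones) <- ids[seq_len(params$n_clones)]
  list(clones = clones,
       truth = list(params = params, footprints = fp,
                    clones = truth_clones))
}

#' Simulate AID-deaminated clones over known single-stranded intervals
#'
#' Within the given single-stranded intervals, each top-strand C
#' deaminates to T and each bottom-strand C (reference G) to A with
#' probability `deamination_rate`; with probability `misrepair` a
#' deamination event instead leaves a random other substitution
#' (emulating aberrant base-excision repair). Bases outside the
#' intervals never mutate.
#'
#' @param ref Reference DNA string.
#' @param ss_intervals `data.frame` with `start`, `end` (0-based
#'   half-open) single-stranded intervals exposing both strands.
#' @param deamination_rate Per-exposed-cytosine deamination
#'   probability.
#' @param n_clones Number of clones.
#' @param seed Integer seed.
#' @param misrepair Fraction of deamination events converted to a
#'   random non-transition substitution.
#' @return List with `clones` (named character vector) and `truth`
#'   (list: `ss_intervals`, `exposed_c` count of exposed cytosines per
#'   clone, `mutations` `data.frame` of `clone_id`, `ref_pos`,
#'   `ref_base`, `alt_base`).
#' @export
simulate_aid_clones <- function(ref, ss_intervals, deamination_rate,
                                n_clones, seed = 1L, misrepair = 0) {
  stopifnot(deamination_rate >= 0, deamination_rate <= 1,
            misrepair >= 0, misrepair <= 1)
  .check_dna(ref, "reference")
  set.seed(as.integer(seed) + 2L)
  ref_chars <- strsplit(ref, "")[[1]]
  pos0 <- seq_along(ref_chars) - 1L
  exposed <- rep(FALSE, length(ref_chars))
  for (i in seq_len(nrow(ss_intervals))) {
    exposed <- exposed | (pos0 >= ss_intervals$start[i] &
                            pos0 < ss_intervals$end[i])
  }
  target <- which(exposed & ref_chars %in% c("C", "G"))
  clones <- character(n_clones)
  ids <- sprintf("aid_%03d", seq_len(max(n_clones, 1L)))
  muts <- list()
  for (k in seq_len(n_clones)) {
    chars <- ref_chars
    hit <- target[stats::runif(length(target)) < deamination_rate]
    for (i in hit) {
      deaminated <- if (chars[i] == "C") "T" else "A"
      alt <- if (misrepair > 0 && stats::runif(1) < misrepair) {
        sample(setdiff(c("A", "C", "G", "T"),
                       c(chars[i], deaminated)), 1L)
      } else deaminated
      muts[[length(muts) + 1L]] <- data.frame(
        clone_id = ids[k], ref_pos = i - 1L, ref_base = chars[i],
        alt_base = alt, stringsAsFactors = FALSE)
      chars[i] <- alt
    }
    clones[k] <- paste(chars, collapse = "")
  }
  names(clones) <- ids[seq_len(n_clones)]
  mutations <- if (length(muts) > 0) do.call(rbind, muts) else
    data.frame(clone_id = character(), ref_pos = integer(),
               ref_base = character(), alt_base = character())
  list(clones = clones,
       truth = list(ss_intervals = ss_intervals,
                    exposed_c = length(target),
                    deamination_rate = deamination_rate,
                    mutations = mutations))
}

#' Score recovered footprints against the simulation truth
#'
#' A called interval matches a truth interval when their reciprocal
#' overlap is at least 0.5 (overlap covers half of each interval).
#' Precision and recall are computed over matches; `boundary_error_nt`
#' is the mean absolute start/end offset over matched pairs, and
#' `midpoint_error_nt` the mean absolute midpoint offset.
#'
#' @param called `data.frame` of called intervals (`start`, `end`).
#' @param truth `data.frame` of true intervals (`start`, `end`), or a
#'   simulation truth list carrying `footprints`.
#' @return List with `precision`, `recall`, `boundary_error_nt`,
#'   `midpoint_error_nt`, `n_called`, `n_truth`, `n_matched`.
#' @export
evaluate_recovery <- function(called, truth) {
  if (is.list(truth) && !is.data.frame(truth) &&
      !is.null(truth$footprints)) truth <- truth$footprints
  n_called <- if (is.null(called)) 0L else nrow(called)
  n_truth <- nrow(truth)
  matched_c <- logical(n_called)
  matched_t <- logical(n_truth)
  b_err <- c()
  m_err <- c()
  for (i in seq_len(n_called)) {
    for (j in seq_len(n_truth)) {
      if (matched_t[j]) next
      ov <- min(called$end[i], truth$end[j]) -
        max(called$start[i], truth$start[j])
      if (ov <= 0) next
      if (ov >= 0.5 * (called$end[i] - called$start[i]) &&
          ov >= 0.5 * (truth$end[j] - truth$start[j])) {
        matched_c[i] <- TRUE
        matched_t[j] <- TRUE
        b_err <- c(b_err, mean(c(abs(called$start[i] - truth$start[j]),
                                 abs(called$end[i] - truth$end[j]))))
        m_err <- c(m_err, abs((called$start[i] + called$end[i]) / 2 -
                                (truth$start[j] + truth$end[j]) / 2))
        break
      }
    }
  }
  list(precision = if (n_called > 0) mean(matched_c) else NA_real_,
       recall = if (n_truth > 0) mean(matched_t) else NA_real_,
       boundary_error_nt = if (length(b_err) > 0) mean(b_err) else NA_real_,
       midpoint_error_nt = if (length(m_err) > 0) mean(m_err) else NA_real_,
       n_called = n_called, n_truth = n_truth,
       n_matched = sum(matched_c))
}

#' Write a simulation truth as TSV tables
#'
#' Emits `truth_clones.tsv` (clone_id, strand, comma-separated
#' converted and error positions) and, when footprints are present,
#' `truth_footprints.tsv`.
#'
#' @param truth Truth list from [simulate_bisulfite_clones()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(truth$clones, function(tc) {
    data.frame(clone_id = tc$clone_id, strand = tc$strand,
               converted_pos = paste(tc$converted_pos, collapse = ","),
               error_pos = paste(tc$error_pos, collapse = ","))
  }))
  if (is.null(tab)) {
    tab <- data.frame(clone_id = character(), strand = character(),
                      converted_pos = character(),
                      error_pos = character())
  }
  utils::write.table(tab, file.path(dir, "truth_clones.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$footprints) && nrow(truth$footprints) > 0) {
    utils::write.table(truth$footprints,
                       file.path(dir, "truth_footprints.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
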