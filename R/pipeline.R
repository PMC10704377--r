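# High-level orchestration: each run_* function ties the module
# surfaces into one of the standard workflows and writes plain-text
# outputs (TSV with header rows, BED for intervals) into an output
# directory. A thin command-line wrapper around these functions ships
# in inst/scripts/bisfoot.R.

.ensure_dir <- function(dir, force = FALSE) {
  if (dir.exists(dir) && !force &&
      length(list.files(dir, all.files = FALSE)) > 0) {
    stop("output directory exists and is non-empty (use force = TRUE): ",
         dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  invisible(dir)
}

#' Run the bisulfite footprinting workflow
#'
#' Aligns every clone to the reference, assigns strands, calls
#' conversions with the CpG rule, detects stretches, accumulates
#' per-position frequencies per strand, and calls footprints. Writes,
#' per strand with any clones: a profile matrix
#' (`profiles_<strand>.tsv`), a frequency table (`freq_<strand>.tsv`),
#' stretch and footprint BED files, and a clone summary
#' (`clones.tsv`).
#'
#' @param ref Reference: FASTA path or DNA string.
#' @param clones Clones: FASTA path or named character vector.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param cfg A `stretch_config`.
#' @param min_fraction,min_span,max_gap Footprint thresholds; see
#'   [call_footprints()].
#' @param min_identity Alignment identity floor; clones below it are
#'   rejected. More than 50% rejections aborts the run.
#' @param force Overwrite a non-empty `out_dir`.
#' @return List with `profiles` (per strand), `freq` (per strand),
#'   `footprints` (per strand), `clone_summary`, `n_rejected`.
#' @export
run_footprint <- function(ref, clones, out_dir = NULL,
                          cfg = stretch_config(), min_fraction = 0.5,
                          min_span = 30, max_gap = 10,
                          min_identity = 0.9, force = FALSE) {
  if (length(ref) == 1L && file.exists(ref)) ref <- read_fasta(ref)[[1]]
  if (length(clones) == 1L && !is.null(clones) && file.exists(clones[1])) {
    clones <- read_fasta(clones)
  }
  if (length(clones) == 0L) stop("no clones provided")
  ids <- names(clones)
  if (is.null(ids)) ids <- sprintf("clone_%03d", seq_along(clones))

  profiles <- list(top = list(), bottom = list())
  summary_rows <- list()
  n_rejected <- 0L
  for (i in seq_along(clones)) {
    aln <- tryCatch(align_clone(clones[[i]], ref,
                                min_identity = min_identity),
                    bisfoot_alignment_error = function(e) NULL)
    if (is.null(aln)) {
      n_rejected <- n_rejected + 1L
      summary_rows[[i]] <- data.frame(clone_id = ids[i],
                                      strand = "rejected",
                                      class = NA_character_,
                                      max_run = NA_integer_)
      next
    }
    sa <- assign_strand(aln)
    if (sa$strand == "undetermined") {
      summary_rows[[i]] <- data.frame(clone_id = ids[i],
                                      strand = "undetermined",
                                      class = NA_character_,
                                      max_run = NA_integer_)
      next
    }
    prof <- call_conversions(aln, ref, sa$strand, clone_id = ids[i])
    prof <- apply_cpg_rule(prof, cfg$cpg_run_k)
    runs <- find_stretches(prof, stretch_config(
      min_run = 1, window = cfg$window,
      min_in_window = cfg$min_in_window), mode = "continuous")
    summary_rows[[i]] <- data.frame(
      clone_id = ids[i], strand = sa$strand,
      class = classify_clone(prof, cfg),
      max_run = if (nrow(runs) > 0) max(runs$n_converted) else 0L)
    profiles[[sa$strand]][[length(profiles[[sa$strand]]) + 1L]] <- prof
  }
  if (n_rejected > 0.5 * length(clones)) {
    stop("more than 50% of clones rejected at alignment (",
         n_rejected, "/", length(clones), ")")
  }
  clone_summary <- do.call(rbind, summary_rows)

  freq <- list()
  footprints <- list()
  for (strand in c("top", "bottom")) {
    if (length(profiles[[strand]]) == 0L) next
    freq[[strand]] <- positionwise_frequency(profiles[[strand]])
    footprints[[strand]] <- call_footprints(
      freq[[strand]], min_fraction = min_fraction, min_span = min_span,
      max_gap = max_gap, profiles = profiles[[strand]],
      strand = strand)
  }

  if (!is.null(out_dir)) {
    .ensure_dir(out_dir, force)
    utils::write.table(clone_summary, file.path(out_dir, "clones.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (strand in names(freq)) {
      write_profile_matrix(profiles[[strand]],
                           file.path(out_dir,
                                     paste0("profiles_", strand, ".tsv")))
      utils::write.table(freq[[strand]],
                         file.path(out_dir, paste0("freq_", strand, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fp <- footprints[[strand]]
      if (nrow(fp) > 0) {
        bed <- data.frame(start = fp$start, end = fp$end,
                          name = "footprint",
                          score = round(fp$mean_fraction * 1000),
                          strand = ifelse(fp$strand == "top", "+", "-"))
        write_bed(bed, file.path(out_dir,
                                 paste0("footprints_", strand, ".bed")))
      }
    }
  }
  list(profiles = profiles, freq = freq, footprints = footprints,
       clone_summary = clone_summary, n_rejected = n_rejected)
}

#' Run the motif-scanning workflow
#'
#' Scans the reference (optionally restricted to regions) for WRC
#' hotspots, conventional and extended G-quadruplex motifs, computes
#' per-region GC content and a GC-skew profile, and writes
#' `motifs.bed`, `skew.tsv` and `region_summary.tsv`.
#'
#' @param ref Reference: FASTA path or DNA string.
#' @param regions Optional region `data.frame` from [make_regions()];
#'   default is one region covering the whole reference.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param g4cfg A `g4_config`.
#' @param skew_window,skew_step GC-skew window and step (nt).
#' @param force Overwrite a non-empty `out_dir`.
#' @return List with `hits` (all motif classes, region-restricted),
#'   `region_summary` and `skew`.
#' @export
run_scan <- function(ref, regions = NULL, out_dir = NULL,
                     g4cfg = g4_config(), skew_window = 100,
                     skew_step = 50, force = FALSE) {
  if (length(ref) == 1L && file.exists(ref)) ref <- read_fasta(ref)[[1]]
  n <- nchar(ref)
  if (is.null(regions)) {
    regions <- data.frame(name = "locus", ref_id = "locus",
                          start = 0L, end = n, strand = "*")
  }
  if (any(regions$start < 0) || any(regions$end > n)) {
    stop("region outside reference bounds")
  }
  all_hits <- list()
  summary_rows <- list()
  for (i in seq_len(nrow(regions))) {
    sub <- substring(ref, regions$start[i] + 1L, regions$end[i])
    wrc <- find_wrc(sub)
    g4c <- find_g4_conventional(sub, g4cfg)
    g4e <- find_g4_extended(sub, g4cfg)
    keep <- c("motif_class", "strand", "start", "end",
              "matched_sequence")
    shift <- function(h) {
      h <- h[, keep, drop = FALSE]
      h$start <- h$start + regions$start[i]
      h$end <- h$end + regions$start[i]
      h$region <- rep(regions$name[i], nrow(h))
      h
    }
    all_hits[[i]] <- rbind(shift(wrc), shift(g4c), shift(g4e))
    summary_rows[[i]] <- data.frame(
      region = regions$name[i], length_nt = nchar(sub),
      n_wrc_both = nrow(wrc), n_wrc_plus = sum(wrc$strand == "+"),
      n_g4_conventional = nrow(g4c), n_g4_extended = nrow(g4e),
      gc_content_pct = gc_content(sub))
  }
  hits <- do.call(rbind, all_hits)
  region_summary <- do.call(rbind, summary_rows)
  skew <- if (skew_window <= n) gc_skew(ref, skew_window, skew_step)
          else NULL

  if (!is.null(out_dir)) {
    .ensure_dir(out_dir, force)
    if (nrow(hits) > 0) {
      g_count <- function(s) vapply(strsplit(s, ""), function(x)
        sum(x == "G"), integer(1))
      bed <- data.frame(start = hits$start, end = hits$end,
                        name = hits$motif_class,
                        score = ifelse(grepl("^G4", hits$motif_class),
                                       g_count(hits$matched_sequence) * 100,
                                       0),
                        strand = hits$strand)
      write_bed(bed, file.path(out_dir, "motifs.bed"))
    }
    if (!is.null(skew)) {
      utils::write.table(skew, file.path(out_dir, "skew.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(region_summary,
                       file.path(out_dir, "region_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(hits = hits, region_summary = region_summary, skew = skew)
}

#' Run the AID mutation-analysis workflow
#'
#' Calls mutations in every clone, optionally annotates them with
#' motif overlap, and summarises the mutation frequency. With a second
#' clone set the percent reduction of condition B relative to A is
#' also reported. Writes `mutations.tsv`, `mutations.vcf` and
#' `mutation_summary.tsv`.
#'
#' @param ref Reference: FASTA path or DNA string.
#' @param clones Clones: FASTA path or named character vector.
#' @param clones_b Optional second-condition clone set.
#' @param motif_hits Optional motif hit `data.frame` for annotation.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param exclude_bisulfite_like Suppress C>T / G>A records.
#' @param flank Motif annotation flank (nt).
#' @param force Overwrite a non-empty `out_dir`.
#' @return List with `records`, `summary`, and (two-condition mode)
#'   `records_b`, `summary_b`, `reduction_pct`.
#' @export
run_mutations <- function(ref, clones, clones_b = NULL,
                          motif_hits = NULL, out_dir = NULL,
                          exclude_bisulfite_like = FALSE, flank = 5,
                          force = FALSE) {
  if (length(ref) == 1L && file.exists(ref)) ref <- read_fasta(ref)[[1]]
  load_set <- function(x) {
    if (length(x) == 1L && file.exists(x[1])) read_fasta(x) else x
  }
  analyse <- function(set) {
    set <- load_set(set)
    ids <- names(set)
    if (is.null(ids)) ids <- sprintf("clone_%03d", seq_along(set))
    recs <- list()
    total_nt <- 0
    for (i in seq_along(set)) {
      r <- call_mutations(set[[i]], ref,
                          exclude_bisulfite_like = exclude_bisulfite_like,
                          clone_id = ids[i])
      total_nt <- total_nt + attr(r, "aligned_nt")
      recs[[i]] <- r
    }
    records <- do.call(rbind, recs)
    if (!is.null(motif_hits)) {
      records <- annotate_mutations(records, motif_hits, flank = flank)
    }
    list(records = records,
         summary = mutation_frequency(records, total_nt))
  }
  a <- analyse(clones)
  out <- list(records = a$records, summary = a$summary)
  if (!is.null(clones_b)) {
    b <- analyse(clones_b)
    out$records_b <- b$records
    out$summary_b <- b$summary
    out$reduction_pct <- condition_reduction(a$summary, b$summary)
  }

  if (!is.null(out_dir)) {
    .ensure_dir(out_dir, force)
    utils::write.table(a$records, file.path(out_dir, "mutations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_mutations_vcf(a$records, file.path(out_dir, "mutations.vcf"))
    sum_tab <- data.frame(condition = "A",
                          n_mutations = a$summary$n_mutations,
                          total_nt = a$summary$total_nt_sequenced,
                          frequency = a$summary$frequency,
                          percent = a$summary$percent)
    if (!is.null(clones_b)) {
      sum_tab <- rbind(sum_tab, data.frame(
        condition = "B", n_mutations = out$summary_b$n_mutations,
        total_nt = out$summary_b$total_nt_sequenced,
        frequency = out$summary_b$frequency,
        percent = out$summary_b$percent))
    }
    utils::write.table(sum_tab,
                       file.path(out_dir, "mutation_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate a simulated fixture directory
#'
#' Writes `reference.fa`, `clones.fa`, the truth tables and a
#' serialised copy of the parameters (`params.tsv`). Re-running with
#' the same parameters reproduces the files byte-identically.
#'
#' @param params A `sim_params`.
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty `out_dir`.
#' @return List with `ref` (the `simulate_reference()` result),
#'   `clones`, `truth` and `out_dir`.
#' @export
run_simulate <- function(params, out_dir, force = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  .ensure_dir(out_dir, force)
  ref <- simulate_reference(params)
  sim <- simulate_bisulfite_clones(ref$seq, params)
  write_fasta(c(reference = ref$seq), file.path(out_dir, "reference.fa"))
  write_fasta(sim$clones, file.path(out_dir, "clones.fa"))
  write_truth(sim$truth, out_dir)
  scalar <- vapply(unclass(params), function(x)
    is.atomic(x) && length(x) == 1L, logical(1))
  ptab <- data.frame(parameter = names(params)[scalar],
                     value = vapply(unclass(params)[scalar],
                                    as.character, character(1)))
  utils::write.table(ptab, file.path(out_dir, "params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(ref = ref, clones = sim$clones, truth = sim$truth,
       out_dir = out_dir)
}
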