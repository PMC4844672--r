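#' Pipeline configuration
#'
#' Collects the input file paths and tunable parameters of the full
#' analysis. All coverage inputs are bedGraph, regions BED, the genome
#' FASTA and the PWM the tab-separated max-0 format of [read_pwm()].
#' Chromatin inputs are optional; when absent the chromatin stage is
#' skipped.
#'
#' @param ref_rep1,ref_rep2 Reference-genotype replicate bedGraphs.
#' @param alt_rep1,alt_rep2 Mutant-genotype replicate bedGraphs.
#' @param control Control-genotype bedGraph.
#' @param regions Bound-region BED (ranked peaks).
#' @param genome Genome FASTA.
#' @param pwm PWM TSV.
#' @param open_bed Optional open-chromatin BED.
#' @param dhs_bedgraph Optional quantitative DHS bedGraph.
#' @param fragment_length Read extension length (bp); also sets the
#'   default CFR cap floor.
#' @param background_cutoff Signal cutoff of the control peak finder.
#' @param background_min_gap Merge control peaks separated by fewer
#'   sub-cutoff bases than this.
#' @param cap CFR value assigned to capped regions.
#' @param min_alt_coverage Mutant-coverage floor for capping (default:
#'   one extended read, i.e. `fragment_length`).
#' @param alpha Per-window significance level for the threshold scan.
#' @param gc_tol GC tolerance of the negative set.
#' @param max_distance Spacing-histogram upper bound (bp).
#' @param seed Integer seed (negative-set sampling).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ref_rep1, ref_rep2, alt_rep1, alt_rep2,
                            control, regions, genome, pwm,
                            open_bed = NULL, dhs_bedgraph = NULL,
                            fragment_length = 130L,
                            background_cutoff = 20,
                            background_min_gap = 30L, cap = 300,
                            min_alt_coverage = fragment_length,
                            alpha = 0.05, gc_tol = 0.05,
                            max_distance = 40L, seed = 1L) {
  cfg <- as.list(environment())
  required <- c("ref_rep1", "ref_rep2", "alt_rep1", "alt_rep2", "control",
                "regions", "genome", "pwm")
  for (nm in required) {
    if (!is.character(cfg[[nm]]) || !file.exists(cfg[[nm]])) {
      stop("pipeline input '", nm, "' missing or not a readable file")
    }
  }
  for (nm in c("open_bed", "dhs_bedgraph")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]])) {
      stop("pipeline input '", nm, "' not found: ", cfg[[nm]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Run the full occupancy / landscape / chromatin pipeline
#'
#' Stages: two-step normalization of both genotypes against the control
#' (replicate fusion via `m`, depth rescaling via `m'` fitted on control
#' background peaks); per-region CFR; PWM scan of the bound regions with
#' a GC-matched negative set and data-driven score threshold;
#' binding-site landscape (best score, density, 1-bp-gap pairs, spacing
#' by CFR decile, extreme-decile tests); and, when chromatin inputs are
#' given, openness classification, closed fraction by decile, and the
#' CFR-DHS correlation. All tables are written as TSV plus a JSON run
#' manifest; identical config and seed give byte-identical outputs.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory.
#' @param skip_chromatin Force-skip the chromatin stage even when inputs
#'   are present.
#' @return Invisibly, a list of in-memory results (`scale_factors`,
#'   `cfr`, `threshold`, `landscape`, `spacing`, `tests`,
#'   `accessibility`, `fraction_closed`, `cfr_dhs`, `outputs`).
#' @export
run_pipeline <- function(config, outdir, skip_chromatin = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_fasta(config$genome)
  lens <- nchar(genome)
  tracks <- lapply(config[c("ref_rep1", "ref_rep2", "alt_rep1",
                            "alt_rep2", "control")],
                   read_bedgraph, chrom_lengths = lens)
  regions <- read_bed(config$regions)
  mat <- read_pwm(config$pwm)
  outputs <- character(0)
  emit <- function(x, name) {
    p <- file.path(outdir, name)
    write_tsv(x, p)
    outputs <<- c(outputs, p)
  }

  # --- normalization ----------------------------------------------------
  m_ref <- fit_replicate_scale(region_coverage(tracks$ref_rep1, regions),
                               region_coverage(tracks$ref_rep2, regions))
  m_alt <- fit_replicate_scale(region_coverage(tracks$alt_rep1, regions),
                               region_coverage(tracks$alt_rep2, regions))
  fused_ref <- fuse_replicates(tracks$ref_rep1, tracks$ref_rep2, m_ref$m)
  fused_alt <- fuse_replicates(tracks$alt_rep1, tracks$alt_rep2, m_alt$m)
  bg_peaks <- rudimentary_peak_find(tracks$control,
                                    cutoff = config$background_cutoff,
                                    min_gap = config$background_min_gap)
  mp_ref <- fit_genotype_scale(fused_ref, tracks$control, bg_peaks)
  mp_alt <- fit_genotype_scale(fused_alt, tracks$control, bg_peaks)
  norm_ref <- apply_genotype_scale(fused_ref, mp_ref$m)
  norm_alt <- apply_genotype_scale(fused_alt, mp_alt$m)
  scale_factors <- data.frame(
    genotype = c("ref", "alt"), m = c(m_ref$m, m_alt$m),
    m_prime = c(mp_ref$m, mp_alt$m),
    n_peaks_m = c(m_ref$n, m_alt$n),
    n_background_peaks = nrow(bg_peaks))
  emit(scale_factors, "scale_factors.tsv")
  write_bed(bg_peaks, file.path(outdir, "background_peaks.bed"))
  outputs <- c(outputs, file.path(outdir, "background_peaks.bed"))

  # --- CFR --------------------------------------------------------------
  cfr <- compute_cfr(regions, norm_ref, norm_alt, cap = config$cap,
                     min_alt_coverage = config$min_alt_coverage)
  if (any(cfr$capped)) {
    message(sum(cfr$capped), " region(s) capped at CFR = ", config$cap)
  }
  emit(cfr, "cfr_table.tsv")

  # --- binding-site landscape ------------------------------------------
  negset <- sample_negative_set(regions, genome, gc_tol = config$gc_tol,
                                seed = config$seed)
  pos_d <- window_densities(regions, genome, mat)
  neg_d <- window_densities(negset, genome, mat)
  thr <- determine_threshold(pos_d$densities, neg_d$densities,
                             alpha = config$alpha)
  emit(thr$table, "threshold_report.tsv")
  write_bed(negset[, c("chrom", "start", "end", "id")],
            file.path(outdir, "negative_set.bed"))
  outputs <- c(outputs, file.path(outdir, "negative_set.bed"))

  landscape <- NULL
  spacing <- NULL
  tests <- list()
  if (!is.na(thr$threshold)) {
    L <- pwm_length(mat)
    site_map <- list()
    best <- numeric(nrow(regions))
    dens <- numeric(nrow(regions))
    unit <- integer(nrow(regions))
    for (i in seq_len(nrow(regions))) {
      sites <- scan_sequence(mat, interval_sequence(genome, regions[i, ]),
                             threshold = thr$threshold)
      site_map[[regions$id[i]]] <- sites$offset
      best[i] <- if (nrow(sites) > 0L) max(sites$score) else NA_real_
      dens[i] <- nrow(sites) * 1000 / (regions$end[i] - regions$start[i])
      unit[i] <- count_unit_gap_pairs(sites$offset, L)
    }
    landscape <- cbind(cfr,
                       data.frame(best_score = best, site_density = dens,
                                  unit_gap_pairs = unit))
    landscape$decile <- decile_partition(landscape, "cfr")
    emit(landscape, "landscape_table.tsv")
    spacing <- spacing_by_decile(cfr, site_map, L,
                                 max_distance = config$max_distance)
    sp_df <- data.frame(decile = seq_len(10L), spacing)
    names(sp_df) <- c("decile",
                      paste0("d", seq_len(config$max_distance) - 1L))
    emit(sp_df, "spacing_by_decile.tsv")
    ls_cc <- landscape[stats::complete.cases(landscape$best_score), ]
    tests$best_score <- extreme_decile_compare(ls_cc, "cfr", "best_score")
    tests$site_density <- extreme_decile_compare(landscape, "cfr",
                                                 "site_density")
    tests$unit_gap_pairs <- extreme_decile_compare(landscape, "cfr",
                                                   "unit_gap_pairs")
  } else {
    message("no significant score window; landscape stage skipped")
  }

  # --- chromatin accessibility -----------------------------------------
  accessibility <- NULL
  fraction_closed <- NULL
  cfr_dhs <- NULL
  if (!skip_chromatin && !is.null(config$open_bed)) {
    open_set <- read_open_set(config$open_bed)
    dhs_track <- if (!is.null(config$dhs_bedgraph))
      read_bedgraph(config$dhs_bedgraph, lens) else NULL
    accessibility <- accessibility_table(cfr, open_set, dhs_track)
    emit(accessibility, "accessibility_table.tsv")
    fraction_closed <- fraction_closed_by_decile(accessibility)
    emit(data.frame(decile = 1:10, fraction_closed = fraction_closed),
         "fraction_closed_by_decile.tsv")
    if (!is.null(dhs_track)) {
      cfr_dhs <- cfr_vs_dhs(accessibility)
      emit(data.frame(r = cfr_dhs$pearson$r,
                      r_squared = cfr_dhs$pearson$r_squared,
                      p_value = cfr_dhs$pearson$p_value,
                      extreme_decile_p = cfr_dhs$extreme_deciles$p_value),
           "cfr_vs_dhs.tsv")
    }
  }

  # --- run manifest -----------------------------------------------------
  input_files <- unlist(config[c("ref_rep1", "ref_rep2", "alt_rep1",
                                 "alt_rep2", "control", "regions",
                                 "genome", "pwm", "open_bed",
                                 "dhs_bedgraph")])
  manifest <- list(
    package = "bindscape",
    version = as.character(utils::packageVersion("bindscape")),
    seed = config$seed,
    parameters = config[c("fragment_length", "background_cutoff",
                          "background_min_gap", "cap", "min_alt_coverage",
                          "alpha", "gc_tol", "max_distance")],
    threshold = if (is.na(thr$threshold)) "none" else thr$threshold,
    input_md5 = as.list(tools::md5sum(input_files)),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(scale_factors = scale_factors, background_peaks = bg_peaks,
                 cfr = cfr, negative_set = negset, threshold = thr,
                 landscape = landscape, spacing = spacing, tests = tests,
                 accessibility = accessibility,
                 fraction_closed = fraction_closed, cfr_dhs = cfr_dhs,
                 outputs = outputs))
}
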