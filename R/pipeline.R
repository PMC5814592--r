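#' Pipeline configuration
#'
#' Collects and validates every stage parameter of the end-to-end
#' pipeline. Defaults are the declared defaults of the individual
#' stages.
#'
#' @param seed master seed; all stage streams derive from it.
#' @param n_progeny,genotyping_error_rate,missing_rate,distorted_fraction,distortion_strength
#'   simulated-cross settings (see [sim_cross_config()] and
#'   [sim_map_truth()]).
#' @param n_chromosomes,markers_per_chromosome,length_cm simulated map
#'   dimensions.
#' @param call_rate_threshold variant call-rate threshold.
#' @param data_tolerance minimum segregation-distortion p-value.
#' @param missing_limit maximum missing fraction per marker.
#' @param lod_limit,min_group_size,min_informative,n_iterations mapping
#'   parameters.
#' @param e_cutoff hit-table e-value cutoff.
#' @param ambiguity_ratio homoeology ambiguity threshold.
#' @param min_block,max_rank_gap synteny-block parameters.
#' @param noise_rate hit-table noise rate.
#' @param window_mb,step_mb introgression window track parameters (Mb).
#' @param het_z_min,missing_z_min robust calling thresholds.
#' @param markers_per_wheat_chrom wheat scaffold density for the
#'   introgression panel.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            n_progeny = 119,
                            genotyping_error_rate = 0.01,
                            missing_rate = 0.15,
                            distorted_fraction = 0.05,
                            distortion_strength = 0.6,
                            n_chromosomes = 7,
                            markers_per_chromosome = 100,
                            length_cm = 120,
                            call_rate_threshold = 0.8,
                            data_tolerance = 0.001,
                            missing_limit = 0.2,
                            lod_limit = 11,
                            min_group_size = 15,
                            min_informative = 20,
                            n_iterations = 40,
                            e_cutoff = 1e-05,
                            ambiguity_ratio = 0.5,
                            min_block = 5,
                            max_rank_gap = 3,
                            noise_rate = 0.15,
                            window_mb = 50,
                            step_mb = 1,
                            het_z_min = 5,
                            missing_z_min = 5,
                            markers_per_wheat_chrom = 300) {
  cfg <- as.list(environment())
  probs <- c("genotyping_error_rate", "missing_rate", "distorted_fraction",
             "missing_limit", "noise_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] >= 1) stop2(p, " must be in [0, 1)")
  }
  if (cfg$data_tolerance <= 0 || cfg$data_tolerance > 1) {
    stop2("data_tolerance must be in (0, 1]")
  }
  if (cfg$lod_limit <= 0) stop2("lod_limit must be positive")
  if (cfg$window_mb < cfg$step_mb) stop2("window_mb must be >= step_mb")
  if (cfg$n_progeny < 2) stop2("n_progeny must be >= 2")
  if (cfg$e_cutoff <= 0) stop2("e_cutoff must be positive")
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on simulated data
#'
#' Executes the stages in experimental order — simulate, genotype QC and
#' filtering, two-point linkage and map construction, homoeology and
#' synteny assignment, introgression-panel identification — persisting
#' every intermediate artifact as TSV/JSON under `outdir` together with
#' a run manifest (package version, seed, parameter hash). A rerun with
#' the same configuration produces byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param stages which stages to run (prerequisites are always run
#'   in-memory; this controls what is persisted/returned).
#' @return (invisibly) list with the in-memory results: `sim`, `qc`,
#'   `maps`, `hits`, `homoeology`, `synteny`, `introgression`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("cpmapr_run_"),
                         stages = c("simulate", "qc", "map", "homoeology",
                                    "introgress")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stamp <- paste0("cpmapr ", as.character(utils::packageVersion("cpmapr")),
                  " params=", hash)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  truth <- sim_map_truth(n_chromosomes = config$n_chromosomes,
                         markers_per_chromosome = config$markers_per_chromosome,
                         length_cm = config$length_cm,
                         distorted_fraction = config$distorted_fraction,
                         seed = config$seed)
  cross_cfg <- sim_cross_config(n_progeny = config$n_progeny,
                                genotyping_error_rate = config$genotyping_error_rate,
                                missing_rate = config$missing_rate,
                                distortion_strength = config$distortion_strength,
                                seed = config$seed)
  sim <- simulate_cp_cross(truth, cross_cfg)
  say("simulate: %d markers x %d progeny on %d chromosomes",
      nrow(sim$gm$geno), config$n_progeny, config$n_chromosomes)
  if ("simulate" %in% stages) {
    write_genotype_matrix(sim$gm, file.path(outdir, "genotypes.tsv"), stamp)
  }

  qc <- filter_markers(marker_qc(sim$gm,
                                 call_rate_threshold = config$call_rate_threshold),
                       distortion_p_min = config$data_tolerance,
                       missing_limit = config$missing_limit)
  att <- attr(qc, "attrition")
  say("qc: %d/%d markers kept (%s)", sum(qc$kept), nrow(qc),
      paste(sprintf("%s=%d", att$reason, att$n), collapse = ", "))
  if ("qc" %in% stages) {
    write_tsv_artifact(qc, file.path(outdir, "marker_qc.tsv"), stamp)
    write_tsv_artifact(att, file.path(outdir, "attrition.tsv"), stamp)
  }

  maps <- build_maps(sim$gm, qc, lod_limit = config$lod_limit,
                     min_group_size = config$min_group_size,
                     min_informative = config$min_informative,
                     n_iterations = config$n_iterations)
  for (m in c("male", "female", "integrated")) {
    say("map (%s): %d LGs, %.1f cM", m, length(maps[[m]]$lg),
        sum(maps[[m]]$summary$length_cm))
    if ("map" %in% stages) {
      write_map_tsv(maps[[m]], file.path(outdir, paste0("map_", m, ".tsv")), stamp)
      write_tsv_artifact(map_summary(maps[[m]]),
                         file.path(outdir, paste0("map_", m, "_summary.tsv")),
                         stamp)
    }
  }

  raw_hits <- simulate_hit_table(truth, noise_rate = config$noise_rate,
                                 seed = config$seed)
  hits <- filter_hits(raw_hits, e_cutoff = config$e_cutoff)
  hom <- assign_homoeology(maps$integrated, hits,
                           ambiguity_ratio = config$ambiguity_ratio)
  syn <- detect_synteny_blocks(maps$integrated, hits, assignment = hom,
                               min_block = config$min_block,
                               max_rank_gap = config$max_rank_gap)
  say("homoeology: %s",
      paste(sprintf("%s->%sP", hom$assignment$lg, hom$assignment$assigned_group),
            collapse = " "))
  if ("homoeology" %in% stages) {
    write_hit_table(raw_hits, file.path(outdir, "hits_raw.tsv"), stamp)
    write_tsv_artifact(hom$assignment, file.path(outdir, "homoeology.tsv"), stamp)
    write_tsv_artifact(syn$blocks, file.path(outdir, "synteny_blocks.tsv"), stamp)
    write_tsv_artifact(scale_map_for_comparison(maps$integrated),
                       file.path(outdir, "map_integrated_scaled.tsv"), stamp)
  }

  panel <- example_line_panel()
  wm <- default_wheat_marker_map(markers_per_chrom = config$markers_per_wheat_chrom,
                                 seed = config$seed)
  lines <- simulate_introgression_lines(panel, wm, seed = config$seed)
  comp <- vapply(panel, function(s) attr(s, "composition") %||% NA_character_, "")
  names(comp) <- vapply(panel, `[[`, "", "line_id")
  expected <- expected_alien_pairs(comp)
  intro <- batch_report(lines$gm, wm,
                        expected_counts = expected, compositions = comp,
                        het_z_min = config$het_z_min,
                        missing_z_min = config$missing_z_min,
                        window_bp = config$window_mb * 1e6,
                        step_bp = config$step_mb * 1e6)
  say("introgression: %d/%d lines match simulated truth",
      sum(intro$report$additions == lines$truth$additions &
            intro$report$missing == lines$truth$missing),
      nrow(intro$report))
  if ("introgress" %in% stages) {
    write_tsv_artifact(intro$report, file.path(outdir, "introgression_report.tsv"),
                       stamp)
    win <- do.call(rbind, lapply(intro$tracks, function(tr)
      cbind(line_id = tr$line_id, tr$windows)))
    write_tsv_artifact(win, file.path(outdir, "introgression_windows.tsv"), stamp)
  }

  manifest <- list(tool = "cpmapr",
                   version = as.character(utils::packageVersion("cpmapr")),
                   seed = config$seed, parameter_hash = hash,
                   parameters = unclass(config), log = log_lines)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sim = sim, qc = qc, maps = maps, hits = hits,
                 homoeology = hom, synteny = syn,
                 introgression = intro, truth = lines$truth,
                 manifest = manifest, outdir = outdir))
}

#' Expected alien pair count from a composition string
#'
#' Parses cytology metadata like `"42W + 2P"` (one added pair) or
#' `"40W + 4P"` (two pairs, of which one substitutes) into the number of
#' alien chromosome pairs.
#'
#' @param composition character vector of composition strings.
#' @return named integer vector (NA where unparsable).
#' @export
expected_alien_pairs <- function(composition) {
  m <- regmatches(composition, regexpr("[0-9]+P", composition))
  out <- rep(NA_integer_, length(composition))
  ok <- lengths(regmatches(composition, gregexpr("[0-9]+P", composition))) > 0
  out[ok] <- as.integer(sub("P", "", m)) %/% 2L
  names(out) <- names(composition)
  out
}
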