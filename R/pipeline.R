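PIPELINE_KEYS <- c(
  "sam", "reference", "diagnostic_table", "calibration_fasta", "tip_dates",
  "outdir", "seed", "min_length", "min_mapq", "error_rate",
  "terminal_window", "mask_window", "min_coverage", "min_support",
  "contamination_threshold", "n_boot", "min_overlap", "consensus_name"
)

#' Validate a pipeline configuration
#'
#' Accepts a named list or a YAML file path. Unknown keys are rejected;
#' required input paths must exist. Validation happens before any
#' computation so configuration mistakes fail fast.
#'
#' @param config Named list or YAML path.
#' @return The validated config list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "ancientmt_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "ancientmt_config_error")
  }
  for (key in c("sam", "reference", "outdir")) {
    if (is.null(config[[key]])) {
      abort(sprintf("config key `%s` is required", key),
            class = "ancientmt_config_error")
    }
  }
  for (key in c("sam", "reference", "diagnostic_table", "calibration_fasta",
                "tip_dates")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      abort(sprintf("config path `%s` does not exist: %s", key, config[[key]]),
            class = "ancientmt_config_error")
    }
  }
  defaults <- list(
    seed = 1L, min_length = 35, min_mapq = 25, error_rate = 0.001,
    terminal_window = 3, mask_window = 7, min_coverage = 5,
    min_support = 0.80, contamination_threshold = 0.05, n_boot = 200,
    min_overlap = 1000, consensus_name = "consensus"
  )
  for (key in names(defaults)) {
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]
  }
  config
}

#' Run the full ancient-mtDNA pipeline
#'
#' Executes filter -> deduplicate -> damage profile -> contamination ->
#' mode selection -> lineage assignment (if a diagnostic table is
#' configured) -> consensus -> pairwise comparison and tip dating (if
#' calibration genomes and tip dates are configured). Stage artefacts
#' are written under `outdir` and a machine-readable JSON report is
#' returned and written as `report.json`. The report's timestamp is
#' isolated in one field so the remainder is reproducible under a fixed
#' seed.
#'
#' @param config Named list or YAML path; see [pipeline_config()].
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "ancientmt_pipeline_error")
    })
  }
  report <- list(schema_version = "1.0", params = cfg[setdiff(names(cfg), "outdir")])

  ref_seqs <- stage("reference", read_fasta(cfg$reference))
  ref <- reference_genome(ref_seqs[[1]], name = names(ref_seqs)[1])

  frags <- stage("read_sam", read_sam(cfg$sam, ref))
  report$read_sam <- list(n_fragments = dplyr::n_distinct(frags$fragment_id),
                          n_skipped_unmapped = attr(frags, "n_skipped_unmapped"))

  frags <- stage("filter", filter_fragments(frags, cfg$min_length,
                                            cfg$min_mapq, quiet = TRUE))
  fc <- attr(frags, "filter_counts")
  report$filter <- as.list(setNames(fc$n, fc$criterion))

  frags <- stage("deduplicate", deduplicate(frags, quiet = TRUE))
  report$deduplicate <- as.list(attr(frags, "dedup_counts"))

  prof <- stage("damage_profile", damage_profile(frags, ref))
  write_damage_profile(prof, file.path(cfg$outdir, "damage_profile.tsv"))
  report$damage <- as.list(glance(prof))

  attr(frags, "error_rate") <- cfg$error_rate
  contam <- stage("contamination", estimate_contamination(
    frags, ref, error_rate = cfg$error_rate,
    terminal_window = cfg$terminal_window, n_boot = cfg$n_boot,
    seed = cfg$seed))
  jsonlite::write_json(glance(contam),
                       file.path(cfg$outdir, "contamination.json"),
                       auto_unbox = TRUE, digits = NA)
  report$contamination <- as.list(glance(contam))
  mode <- select_mode(contam, cfg$contamination_threshold)
  report$mode <- mode

  if (!is.null(cfg$diagnostic_table)) {
    tab <- stage("taxonomy", read_diagnostic_table(cfg$diagnostic_table))
    assign <- stage("taxonomy", assign_lineage(
      frags, tab, mask_window = cfg$mask_window))
    jsonlite::write_json(
      list(verdict = assign$verdict, lineages = assign$lineages,
           contrasts = assign$contrasts),
      file.path(cfg$outdir, "lineage_assignment.json"),
      auto_unbox = TRUE, digits = NA)
    report$taxonomy <- list(verdict = assign$verdict,
                            n_sites_covered = assign$n_sites_covered,
                            n_excluded_damage = assign$n_excluded_damage)
  }

  params <- consensus_params(
    min_coverage = cfg$min_coverage, min_support = cfg$min_support,
    mask_window = cfg$mask_window, mode = mode,
    contamination_threshold = cfg$contamination_threshold)
  genome <- stage("consensus", call_consensus(
    frags, ref, params = params, name = cfg$consensus_name))
  write_consensus(genome, file.path(cfg$outdir, "consensus.fasta"),
                  file.path(cfg$outdir, "consensus_sites.tsv"))
  report$consensus <- as.list(glance(genome))

  if (!is.null(cfg$calibration_fasta) && !is.null(cfg$tip_dates)) {
    cal <- stage("tipdating", read_fasta(cfg$calibration_fasta))
    dates_tbl <- stage("tipdating", readr::read_tsv(
      cfg$tip_dates, show_col_types = FALSE))
    outgroup <- dates_tbl$id[isTRUE_vec(dates_tbl$is_outgroup)]
    cal_dates <- setNames(dates_tbl$age_bp, dates_tbl$id)

    genomes <- c(setNames(genome$sequence, cfg$consensus_name), cal)
    dm <- stage("compare", difference_matrix(genomes))
    write_difference_matrix(dm, file.path(cfg$outdir, "n_diff.tsv"),
                            file.path(cfg$outdir, "n_compared.tsv"))
    groups <- zero_difference_groups(dm, min_overlap = cfg$min_overlap)
    jsonlite::write_json(
      list(groups = lapply(groups$members, identity),
           min_overlap = cfg$min_overlap),
      file.path(cfg$outdir, "zero_difference_groups.json"),
      auto_unbox = TRUE, digits = NA)
    report$compare <- list(n_genomes = length(genomes),
                           largest_group = max(groups$size))

    date <- stage("tipdating", estimate_tip_date(
      genomes, cal_dates, query_id = cfg$consensus_name,
      outgroup_ids = outgroup, n_boot = cfg$n_boot, seed = cfg$seed))
    jsonlite::write_json(glance(date),
                         file.path(cfg$outdir, "date_estimate.json"),
                         auto_unbox = TRUE, digits = NA)
    report$tipdating <- as.list(glance(date))
  }

  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(logical(0))
  !is.na(x) & (x == TRUE | x == "TRUE" | x == "true" | x == 1)
}
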