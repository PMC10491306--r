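# Configuration, full-protocol runs and report assembly.

#' Default run configuration
#'
#' All defaults follow the analysis protocol: 1 ns angle stride, buffer
#' 55-125 deg, 2 us equilibration discard, 1 us bins, cut-off 1 event/us,
#' 1.0 nm protein proximity, 5 ns density stride, 0.1 nm density bins,
#' hydrophobic body excluding NC3 and PO4, 0.6 nm pathway contact cutoff.
#'
#' @return nested named list of configuration blocks (`input`, `lipid`,
#'   `detector`, `rate`, `thickness`, `pathway`).
#' @export
default_config <- function() {
  list(
    input = list(topology = NULL, trajectories = NULL, dt_ns = 1),
    lipid = list(residue = "DOPC", head_bead = "NC3",
                 tail_beads = c("C4A", "C4B")),
    detector = list(stride_ns = 1, buffer_low_deg = 55,
                    buffer_high_deg = 125, angle_method = "vector_mean"),
    rate = list(equilibration_ns = 2000, bin_width_ns = 1000, cutoff = 1),
    thickness = list(cutoff_nm = 1.0, stride_ns = 5,
                     exclude_beads = c("NC3", "PO4"), bin_nm = 0.1),
    pathway = list(contact_cutoff_nm = 0.6)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Values present in the file override the protocol defaults of
#' [default_config()]; everything else keeps its default.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

load_from_config <- function(config) {
  if (is.null(config$input$topology) || is.null(config$input$trajectories))
    stopf("config must provide input$topology and input$trajectories")
  sys <- load_system(config$input$topology,
                     unlist(config$input$trajectories),
                     dt_ns = config$input$dt_ns %||% 1)
  sys$topology <- define_groups(sys$topology,
                                lipid_residues = config$lipid$residue)
  sys
}

write_manifest <- function(config, path, extra = list()) {
  inputs <- c(config$input$topology, unlist(config$input$trajectories))
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- c(list(
    package = "scramblescan",
    version = as.character(utils::packageVersion("scramblescan")),
    config = config,
    input_md5 = as.list(tools::md5sum(unlist(inputs)))), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the scrambling quantification protocol
#'
#' Loads the system, selects lipids, assigns initial leaflets on the first
#' frame of each replica, builds 1 ns orientation traces, counts buffered
#' threshold-crossing events, bins them per microsecond after the
#' equilibration discard and classifies the system. Writes `events.tsv`,
#' `bins.tsv`, `summary.json` and `manifest.json` into `output_dir`.
#'
#' @param config configuration list (see [read_config()]); paths in
#'   `config$input` are required.
#' @param output_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param system optional pre-loaded `cg_system` (bypasses `config$input`).
#' @return invisibly, list with `events`, `binned`, `summary`, `selection`,
#'   `leaflets`.
#' @export
run_scrambling <- function(config = default_config(), output_dir = NULL,
                           system = NULL) {
  sys <- if (is.null(system)) load_from_config(config) else system
  sel <- select_lipids(sys$topology, config$lipid$residue,
                       config$lipid$head_bead, config$lipid$tail_beads)
  message(sprintf("[scramble] %d lipids selected (%s)", nrow(sel),
                  config$lipid$residue))
  leaf <- lapply(sys$trajectories, function(tr)
    assign_initial_leaflets(get_frame(tr, 1L), sel,
                            angle_method = config$detector$angle_method))
  events <- detect_events_all(
    sys$trajectories, sel, leaf,
    stride_ns = config$detector$stride_ns,
    method = config$detector$angle_method,
    lower_threshold = config$detector$buffer_low_deg,
    upper_threshold = config$detector$buffer_high_deg)
  message(sprintf("[scramble] %d raw events over %d replicas",
                  nrow(events), length(sys$trajectories)))
  t_end <- vapply(sys$trajectories, function(tr) tr$times[n_frames(tr)],
                  numeric(1))
  names(t_end) <- vapply(sys$trajectories, `[[`, integer(1), "replica")
  binned <- bin_events(events, t_end,
                       equilibration_ns = config$rate$equilibration_ns,
                       bin_width_ns = config$rate$bin_width_ns)
  summ <- summarize_rates(binned, cutoff = config$rate$cutoff)
  message(sprintf("[scramble] %d data points, mean %.3g events/us -> %s",
                  summ$n_points, summ$mean, summ$classification))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_event_table(events, file.path(output_dir, "events.tsv"))
    write_rate_summary(summ, binned,
                       json_path = file.path(output_dir, "summary.json"),
                       tsv_path = file.path(output_dir, "bins.tsv"))
    if (!is.null(config$input$topology))
      write_manifest(config, file.path(output_dir, "manifest.json"),
                     extra = list(n_lipids = nrow(sel),
                                  n_events = nrow(events)))
  }
  invisible(list(events = events, binned = binned, summary = summ,
                 selection = sel, leaflets = leaf))
}

#' Run the membrane thickness / thinning analysis
#'
#' @inheritParams run_scrambling
#' @param bulk_only compute only the bulk thickness (required when the
#'   system has no protein).
#' @return invisibly, a [thinning_analysis()] result (or a list with
#'   `bulk_nm` only when `bulk_only`).
#' @export
run_thickness <- function(config = default_config(), output_dir = NULL,
                          system = NULL, bulk_only = FALSE) {
  sys <- if (is.null(system)) load_from_config(config) else system
  sel <- select_lipids(sys$topology, config$lipid$residue,
                       config$lipid$head_bead, config$lipid$tail_beads)
  tc <- config$thickness
  res_list <- lapply(sys$trajectories, function(tr) {
    if (bulk_only) {
      prof <- density_profile(tr, sys$topology, sel, mode = "bulk",
                              exclude_beads = tc$exclude_beads,
                              stride_ns = tc$stride_ns,
                              equilibration_ns = config$rate$equilibration_ns,
                              bin_nm = tc$bin_nm)
      list(bulk_nm = thickness_from_profile(prof), bulk_profile = prof)
    } else {
      thinning_analysis(tr, sys$topology, sel, cutoff_nm = tc$cutoff_nm,
                        exclude_beads = tc$exclude_beads,
                        stride_ns = tc$stride_ns,
                        equilibration_ns = config$rate$equilibration_ns,
                        bin_nm = tc$bin_nm)
    }
  })
  # average over replicas for the report
  bulk <- mean(vapply(res_list, `[[`, numeric(1), "bulk_nm"))
  report <- if (bulk_only) list(bulk_nm = bulk) else list(
    local_nm = mean(vapply(res_list, `[[`, numeric(1), "local_nm")),
    bulk_nm = bulk,
    thinning_nm = mean(vapply(res_list, `[[`, numeric(1), "thinning_nm")),
    cutoff_nm = tc$cutoff_nm)
  message(sprintf("[thickness] bulk %.3f nm%s", bulk,
                  if (!bulk_only) sprintf(", local %.3f nm, thinning %.3f nm",
                                          report$local_nm,
                                          report$thinning_nm) else ""))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(output_dir, "thickness.json"),
                         auto_unbox = TRUE, digits = NA)
    write_density_profile(res_list[[1]]$bulk_profile,
                          file.path(output_dir, "density_bulk.tsv"))
    if (!bulk_only)
      write_density_profile(res_list[[1]]$local_profile,
                            file.path(output_dir, "density_local.tsv"))
  }
  invisible(c(report, list(per_replica = res_list)))
}

#' Run the scrambling-pathway analysis
#'
#' Re-detects events with the same configuration as [run_scrambling()]
#' (identical equilibration window), extracts headgroup transit positions
#' and maps them onto protein residues. Writes `contacts.tsv` and
#' `pathway.pdb`.
#'
#' @inheritParams run_scrambling
#' @return invisibly, list with per-replica [residue_contact_map()] results
#'   and the pooled map.
#' @export
run_pathway <- function(config = default_config(), output_dir = NULL,
                        system = NULL) {
  sys <- if (is.null(system)) load_from_config(config) else system
  scr <- run_scrambling(config, output_dir = NULL, system = sys)
  maps <- lapply(sys$trajectories, function(tr) {
    ev <- scr$events[scr$events$replica == tr$replica, , drop = FALSE]
    residue_contact_map(ev, tr, sys$topology, scr$selection,
                        contact_cutoff_nm = config$pathway$contact_cutoff_nm,
                        equilibration_ns = config$rate$equilibration_ns,
                        stride_ns = config$detector$stride_ns)
  })
  pooled <- maps[[1]]
  if (length(maps) > 1L) {
    for (m in maps[-1]) {
      pooled$contact_count <- pooled$contact_count + m$contact_count
    }
    tot <- sum(vapply(maps, function(m)
      nrow(attr(m, "points")), numeric(1)))
    pooled$normalized_frequency <- pooled$contact_count / max(tot, 1)
    attr(pooled, "points") <- do.call(rbind, lapply(maps, attr, "points"))
  }
  message(sprintf("[pathway] %d transit samples, %d residues contacted",
                  nrow(attr(pooled, "points")),
                  sum(pooled$contact_count > 0)))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_contact_table(pooled, file.path(output_dir, "contacts.tsv"))
    write_pathway_pdb(pooled, file.path(output_dir, "pathway.pdb"))
  }
  invisible(list(per_replica = maps, pooled = pooled, events = scr$events))
}
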