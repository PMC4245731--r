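# Workbench: run configuration, single-structure and cohort report writers,
# synthetic-cohort generation. The exported functions are the interface; a
# thin command-line wrapper lives in inst/cli/chanatomy.

#' Run configuration
#'
#' Collects the detection parameters (surfaced under their customary names:
#' ProbeRadius, OriginRadius, InteriorThreshold, BottleneckRadius,
#' BottleneckLength, CutoffRatio, SurfaceCoverRadius, MinReportLength,
#' LayerDistance), the lining contact tolerance, pooling mode, SASA surface
#' threshold and seed.
#'
#' @param params A [channel_params()].
#' @param contact_tolerance Lining contact margin (A).
#' @param sasa_threshold Relative-accessibility surface cut.
#' @param generic Also compute generic channels.
#' @param seed Integer seed for synthetic generation.
#' @param verbose Log per-structure progress.
#' @return A `run_config` object.
#' @export
run_config <- function(params = channel_params(), contact_tolerance = 1.0,
                       sasa_threshold = 0.25, generic = FALSE, seed = 1,
                       verbose = FALSE) {
  structure(list(params = params, contact_tolerance = contact_tolerance,
                 sasa_threshold = sasa_threshold, generic = generic,
                 seed = seed, verbose = verbose),
            class = "run_config")
}

.config_keys <- c(ProbeRadius = "probe_radius", OriginRadius = "origin_radius",
                  InteriorThreshold = "interior_threshold",
                  BottleneckRadius = "bottleneck_radius",
                  BottleneckLength = "bottleneck_length",
                  CutoffRatio = "cutoff_ratio",
                  SurfaceCoverRadius = "surface_cover_radius",
                  MinReportLength = "min_report_length",
                  LayerDistance = "layer_distance")

#' Read a run configuration from a flat key = value file
#'
#' Lines of the form `Key = value`; `#` starts a comment. Unknown keys are
#' rejected. Recognized keys: the parameter names of [run_config()]
#' (ContactTolerance, SasaThreshold, Generic, Seed, Verbose) and the channel
#' parameters under their customary names (ProbeRadius, OriginRadius,
#' InteriorThreshold, BottleneckRadius, BottleneckLength, CutoffRatio,
#' SurfaceCoverRadius, MinReportLength, LayerDistance).
#'
#' @param file Path to the config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad))
    chan_error("chanatomy_schema_error",
               paste0("unparseable config line(s): ", paste(bad, collapse = "; ")))
  keys <- vapply(kv, `[[`, character(1), 2)
  vals <- vapply(kv, `[[`, character(1), 3)
  other <- c(ContactTolerance = "contact_tolerance",
             SasaThreshold = "sasa_threshold", Generic = "generic",
             Seed = "seed", Verbose = "verbose")
  unknown <- setdiff(keys, c(names(.config_keys), names(other)))
  if (length(unknown))
    chan_error("chanatomy_schema_error",
               paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  pargs <- list()
  cargs <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% names(.config_keys)) {
      pargs[[.config_keys[[k]]]] <- as.numeric(vals[i])
    } else if (k %in% c("Generic", "Verbose")) {
      cargs[[other[[k]]]] <- toupper(vals[i]) %in% c("TRUE", "1", "YES")
    } else if (k == "Seed") {
      cargs[[other[[k]]]] <- as.integer(vals[i])
    } else {
      cargs[[other[[k]]]] <- as.numeric(vals[i])
    }
  }
  cargs$params <- do.call(channel_params, pargs)
  do.call(run_config, cargs)
}

#' Write a run configuration to a flat key = value file
#'
#' @param config A `run_config`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_run_config <- function(config, file) {
  p <- config$params
  lines <- c(
    vapply(names(.config_keys), function(k)
      sprintf("%s = %g", k, p[[.config_keys[[k]]]]), character(1)),
    sprintf("ContactTolerance = %g", config$contact_tolerance),
    sprintf("SasaThreshold = %g", config$sasa_threshold),
    sprintf("Generic = %s", config$generic),
    sprintf("Seed = %d", as.integer(config$seed)),
    sprintf("Verbose = %s", config$verbose))
  writeLines(lines, file)
  invisible(file)
}

provenance_block <- function(config, inputs = character(0)) {
  cf <- tempfile()
  write_run_config(config, cf)
  on.exit(unlink(cf))
  list(package = "chanatomy",
       version = as.character(utils::packageVersion("chanatomy")),
       config_md5 = unname(tools::md5sum(cf)),
       input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])))
}

channel_report <- function(ch) {
  list(site_id = ch$site_id, generic = ch$generic,
       sub_threshold = ch$sub_threshold, length = ch$length,
       cost = ch$cost, n_points = nrow(ch$centerline),
       bottleneck_radius = ch$bottleneck$radius %||% NA,
       bottleneck_index = ch$bottleneck$index %||% NA,
       local_minima = ch$local_minima,
       centerline = unname(apply(ch$centerline, 1, as.list)),
       radii = ch$radii,
       hydropathy = ch$physchem$hydropathy %||% NA,
       polarity = ch$physchem$polarity %||% NA,
       n_positive = ch$physchem$n_positive %||% NA,
       n_negative = ch$physchem$n_negative %||% NA)
}

lining_table <- function(channels) {
  do.call(rbind, lapply(seq_along(channels), function(k) {
    lin <- channels[[k]]$lining
    if (is.null(lin) || !nrow(lin)) return(NULL)
    cbind(channel = k, site_id = channels[[k]]$site_id, lin)
  }))
}

#' Detect and report channels for one structure
#'
#' Writes `channels.json` (geometry, filters, physchem per channel, plus a
#' provenance block), `lining.csv` (per-channel lining residues with layers
#' and flags), `physchem.csv` and `centerlines.pdb` into `out_dir`.
#'
#' @param structure_path PDB file.
#' @param sites_path Site-annotation CSV.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a list with `status` (`"ok"`, `"site-unreachable"`,
#'   `"parse-error"`, `"degenerate"`, `"io-error"`) and the `record`.
#' @export
run_detect <- function(structure_path, sites_path, out_dir,
                       config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- "ok"
  rec <- NULL
  res <- tryCatch({
    s <- parse_pdb(file = structure_path)
    s <- sanitize(s)
    s <- assign_radii(s)
    sites <- load_sites(sites_path)
    rec <- analyze_structure(s, sites, config$params,
                             config$contact_tolerance,
                             generic = config$generic)
    if (rec$site_unreachable) status <- "site-unreachable"
    rec
  },
  chanatomy_io_error = function(e) { status <<- "io-error"; e },
  chanatomy_parse_error = function(e) { status <<- "parse-error"; e },
  chanatomy_degenerate_error = function(e) { status <<- "degenerate"; e })
  channels <- if (!is.null(rec)) rec$channels else list()
  prov <- provenance_block(config, c(structure_path, sites_path))
  jsonlite::write_json(
    list(structure = basename(structure_path), status = status,
         site_id = rec$site_id %||% NA,
         channels = lapply(channels, channel_report),
         provenance = prov),
    file.path(out_dir, "channels.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  lt <- lining_table(channels)
  write.csv(lt %||% data.frame(), file.path(out_dir, "lining.csv"),
            row.names = FALSE)
  pc <- do.call(rbind, lapply(seq_along(channels), function(k) {
    ph <- channels[[k]]$physchem
    if (is.null(ph)) return(NULL)
    data.frame(channel = k, length = channels[[k]]$length,
               hydropathy = ph$hydropathy, polarity = ph$polarity,
               n_positive = ph$n_positive, n_negative = ph$n_negative,
               net_charge = ph$net_charge)
  }))
  write.csv(pc %||% data.frame(), file.path(out_dir, "physchem.csv"),
            row.names = FALSE)
  write_centerline_pdb(channels, file.path(out_dir, "centerlines.pdb"))
  invisible(list(status = status, record = rec, out_dir = out_dir))
}

#' Analyze a cohort manifest and write the report tables
#'
#' Writes `table_occurrence.csv` (per-EC Na/P/M/L and threshold counts),
#' `table_physchem.csv`, `propensities.csv` (channel wall, bottleneck and
#' layers vs whole-structure background), `extremes.csv`, a `summary.json`
#' with provenance, and a per-structure `run_log.csv`. Structures that fail
#' detection stay in the denominators.
#'
#' @param manifest_path Manifest CSV (see [load_manifest()]).
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return Invisibly: list(records, summary, composition).
#' @export
run_cohort <- function(manifest_path, out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- load_manifest(manifest_path)
  if (!nrow(manifest))
    chan_error("chanatomy_value_error", "empty manifest")
  records <- analyze_cohort(manifest, config$params, config$contact_tolerance,
                            generic = config$generic, verbose = config$verbose)
  summ <- summarize_cohort(records)
  comp <- bottleneck_and_layer_composition(records)
  occ <- summ$table[c("ec_class", "n_enzymes", "Na", "P", "M", "L",
                      "n_ge5", "n_ge10", "n_ge15", "n_ge20")]
  write.csv(occ, file.path(out_dir, "table_occurrence.csv"), row.names = FALSE)
  write.csv(summ$table[c("ec_class", "hydropathy", "hydropathy_sem",
                         "polarity", "polarity_sem")],
            file.path(out_dir, "table_physchem.csv"), row.names = FALSE)
  prop <- do.call(rbind, lapply(
    intersect(c("channel", "bottleneck", "internal", "middle", "external",
                "generic", "generic_vs_active"), names(comp)),
    function(rg) if (!is.null(comp[[rg]])) cbind(region = rg, comp[[rg]])))
  write.csv(prop, file.path(out_dir, "propensities.csv"), row.names = FALSE)
  ext <- rbind(
    if (!is.null(summ$extremes$hydrophobic))
      cbind(direction = "hydrophobic", summ$extremes$hydrophobic),
    if (!is.null(summ$extremes$hydrophilic))
      cbind(direction = "hydrophilic", summ$extremes$hydrophilic))
  write.csv(ext %||% data.frame(), file.path(out_dir, "extremes.csv"),
            row.names = FALSE)
  log <- data.frame(
    structure_id = vapply(records, `[[`, character(1), "structure_id"),
    status = vapply(records, function(r) r$status %||% "ok", character(1)),
    n_channels = vapply(records, function(r) length(r$channels), numeric(1)),
    n_qualifying = vapply(records, function(r) length(qualifying(r$channels)),
                          numeric(1)))
  write.csv(log, file.path(out_dir, "run_log.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_structures = nrow(manifest),
         n_failed = sum(log$status != "ok"),
         spearman_na_channels = summ$spearman_na_channels,
         table = summ$table,
         provenance = provenance_block(config, manifest_path)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null", dataframe = "rows")
  invisible(list(records = records, summary = summ, composition = comp))
}

#' Generate a synthetic cohort on disk
#'
#' Thin wrapper over [make_cohort()]: writes the structures, site
#' annotations, manifest and ground-truth JSON into `out_dir`.
#'
#' @param n Number of structures.
#' @param out_dir Output directory.
#' @param config A [run_config()] (uses `seed`).
#' @return Invisibly, the [make_cohort()] result.
#' @export
run_synthesize <- function(n, out_dir, config = run_config()) {
  res <- make_cohort(n, seed = config$seed, out_dir = out_dir)
  invisible(res)
}
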