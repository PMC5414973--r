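#' Study-level configuration
#'
#' One declarative object gathering every tunable surfaced by the other
#' modules; its contents are echoed into the report manifest so a run can
#' be reproduced exactly.
#'
#' @param sim a [sim_config()].
#' @param scheme a [binning_scheme()].
#' @param combine_rule AOI combination, see [summarize_body_part()].
#' @param calibration_band nm band for photon calibration.
#' @param sun_reference_time reference sun exposure, s.
#' @param alpha omnibus significance level.
#' @param adjustment Dunn adjustment method.
#' @param data_source `"images"` renders and quantifies image pairs (the
#'   full pipeline); `"scores"` draws scores at the table level (used for
#'   large replicate simulations).
#' @param reflectance_noise_sd spectrometer reading noise, percent units.
#' @export
study_config <- function(sim = sim_config(),
                         scheme = binning_scheme(),
                         combine_rule = "mean_of_aois",
                         calibration_band = c(330, 350),
                         sun_reference_time = 0.1,
                         alpha = 0.05,
                         adjustment = "bonferroni",
                         data_source = c("images", "scores"),
                         reflectance_noise_sd = 1) {
  data_source <- match.arg(data_source)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  structure(list(sim = sim, scheme = scheme, combine_rule = combine_rule,
                 calibration_band = calibration_band,
                 sun_reference_time = sun_reference_time, alpha = alpha,
                 adjustment = adjustment, data_source = data_source,
                 reflectance_noise_sd = reflectance_noise_sd),
            class = "study_config")
}

config_hash <- function(config) {
  hash_string(paste(deparse(config), collapse = "\n"))
}

# Build the specimen table by rendering every image pair and quantifying it.
quantify_simulated_images <- function(config) {
  sim <- config$sim
  rec <- list()
  for (g in names(sim$groups)) {
    for (i in seq_len(sim$groups[[g]])) {
      sid <- sprintf("%s_%02d", g, i)
      for (part in parts_for_group(g, sim$body_parts)) {
        for (fc in sim$filters) {
          att_sim <- sim
          if (fc == "blocking") {
            att_sim$group_brightness <- lapply(sim$group_brightness,
                                               function(b) b * sim$blocking_attenuation)
          }
          pair <- render_image_pair(g, part, att_sim,
                                    derive_seed(sim$seed, sid, part, fc))
          s <- summarize_body_part(pair$fluor, pair$aois, config$scheme,
                                   combine_rule = config$combine_rule,
                                   specimen_id = sid, filter_config = fc)
          rec[[length(rec) + 1L]] <- data.frame(
            specimen_id = sid, group = g, body_part = part,
            filter_config = fc, mean_intensity = s$mean_intensity,
            percent_brightest = s$percent_brightest,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rec)
}

#' Run the full study pipeline on simulated data
#'
#' Simulate -> quantify -> compare groups -> calibrate -> reflectance ->
#' report. Returns a bundle mirroring the study outputs: the specimen-level
#' table, the omnibus table for both metrics (mean intensity under both
#' filter configurations; percent-in-brightest under the beam splitter
#' alone, where bright pixels are quantifiable), the post-hoc matrices,
#' per-group bar summaries, the photon-calibration result, group
#' reflectance curves, and a run manifest. Idempotent given the same
#' config.
#'
#' @param config a [study_config()].
#' @return object of class `report_bundle`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  sim <- config$sim
  if (config$data_source == "images") {
    records <- quantify_simulated_images(config)
    ground_truth <- NULL
  } else {
    gen <- generate_specimen_table(sim)
    records <- gen$records
    ground_truth <- gen$ground_truth
  }

  tables <- list(
    mean_intensity_dichroic = assemble_study_tables(
      records, "mean_intensity", "dichroic_only", config$alpha,
      config$adjustment),
    percent_brightest_dichroic = assemble_study_tables(
      records, "percent_brightest", "dichroic_only", config$alpha,
      config$adjustment))
  if ("blocking" %in% records$filter_config) {
    tables$mean_intensity_blocking <- assemble_study_tables(
      records, "mean_intensity", "blocking", config$alpha,
      config$adjustment)
  }

  spectra_pair <- generate_irradiance_spectra()
  calibration <- equivalent_exposure(spectra_pair$led, spectra_pair$sun,
                                     band = config$calibration_band,
                                     sun_reference_time = config$sun_reference_time)

  refl_set <- generate_reflectance_curves(
    noise_sd = config$reflectance_noise_sd, seed = sim$seed)
  per_spec <- average_hierarchy(refl_set)
  refl_groups <- group_mean_reflectance(
    per_spec, vapply(refl_set$specimens, `[[`, character(1), "group"))

  manifest <- list(
    package = "fluorquant",
    version = as.character(utils::packageVersion("fluorquant")),
    seed = sim$seed,
    config_hash = config_hash(config),
    data_source = config$data_source,
    n_records = nrow(records),
    n_specimens = length(unique(records$specimen_id)))

  structure(list(records = records, ground_truth = ground_truth,
                 tables = tables, calibration = calibration,
                 reflectance = refl_groups, manifest = manifest,
                 config = config),
            class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' Emits the specimen CSV, omnibus/post-hoc tables as CSV, the calibration
#' JSON, group reflectance curves as tab-delimited spectra, and the
#' manifest JSON into `out_dir`.
#'
#' @param bundle a [run_study()] result.
#' @param out_dir output directory (created if missing).
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_specimen_table(bundle$records, file.path(out_dir, "specimens.csv"))
  for (nm in names(bundle$tables)) {
    tb <- bundle$tables[[nm]]
    write.csv(tb$omnibus, file.path(out_dir, paste0("omnibus_", nm, ".csv")),
              row.names = FALSE)
    write.csv(tb$group_summary,
              file.path(out_dir, paste0("group_summary_", nm, ".csv")),
              row.names = FALSE)
    for (part in names(tb$posthoc)) {
      if (!is.null(tb$posthoc[[part]])) {
        write.csv(tb$posthoc[[part]]$pairs,
                  file.path(out_dir, paste0("posthoc_", nm, "_", part, ".csv")),
                  row.names = FALSE)
      }
    }
  }
  jsonlite::write_json(unclass(bundle$calibration),
                       file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  for (g in names(bundle$reflectance)) {
    sp <- bundle$reflectance[[g]]
    write_spectrum_tsv(sp$wavelengths, sp$values,
                       file.path(out_dir, paste0("reflectance_", g, ".tsv")),
                       value_name = "reflectance_pct")
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Bar summary of group scores for one body part
#'
#' Group means with standard-deviation whiskers, the per-body-part bar
#' chart analog of the study's intensity figures.
#'
#' @param tables an [assemble_study_tables()] result.
#' @param body_part which body part to plot.
#' @export
plot_group_summary <- function(tables, body_part = "abdomen") {
  stopifnot(inherits(tables, "study_tables"))
  gs <- tables$group_summary
  gs <- gs[gs$body_part == body_part, , drop = FALSE]
  if (nrow(gs) == 0L) stop("no groups for body part '", body_part, "'")
  mids <- barplot(gs$mean, names.arg = gs$group, las = 2,
                  ylim = c(0, max(gs$mean + ifelse(is.na(gs$sd), 0, gs$sd)) * 1.1),
                  ylab = tables$metadata$metric, main = body_part)
  ok <- !is.na(gs$sd) & gs$sd > 0
  if (any(ok)) {
    arrows(mids[ok], gs$mean[ok] - gs$sd[ok], mids[ok], gs$mean[ok] + gs$sd[ok],
           angle = 90, code = 3, length = 0.05)
  }
  invisible(mids)
}

#' Convert exported supplementary tables into pipeline formats
#'
#' Ingests CSV/TSV exports of a deposited workbook's tabs. For the
#' intensity table (`which = "S1"`) the expected layout is wide: one row
#' per specimen with columns `specimen_id`, `group`, and per-body-part
#' scores named with the deposited abbreviations `ab` (abdomen), `ct`
#' (cephalothorax), `rt1` (right leg one); one file per filter tab. For
#' spectrometer tabs (`which = "S2"`) the layout is a wavelength column
#' followed by one column per reading. Counts are reported as found -- the
#' converter never reconciles caption discrepancies in the source.
#'
#' @param path CSV/TSV export of one tab.
#' @param which `"S1"` (intensity table) or `"S2"` (spectra).
#' @param filter_config filter tab being converted (S1 only).
#' @param metric score carried by the S1 tab.
#' @return for S1: list with `records` (long specimen table rows) and
#'   `log` (rows read/emitted, per-group counts); for S2: list with
#'   `spectra` (one [spectrum_obj()] per reading column) and `log`.
#' @export
convert_supplementary <- function(path, which = c("S1", "S2"),
                                  filter_config = "dichroic_only",
                                  metric = "mean_intensity") {
  which <- match.arg(which)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop("conversion error: empty table in ", path)
  }
  if (which == "S1") {
    abbrev <- c(ab = "abdomen", ct = "cephalothorax", rt1 = "right_leg_1")
    have <- intersect(names(abbrev), names(df))
    if (!all(c("specimen_id", "group") %in% names(df)) || length(have) == 0L) {
      stop("conversion error: unrecognized layout; found columns: ",
           paste(names(df), collapse = ", "))
    }
    rows <- list()
    for (ab in have) {
      keep <- !is.na(df[[ab]])
      if (!any(keep)) next
      rows[[ab]] <- data.frame(
        specimen_id = df$specimen_id[keep], group = df$group[keep],
        body_part = abbrev[[ab]], filter_config = filter_config,
        metric = metric, value = df[[ab]][keep], stringsAsFactors = FALSE)
    }
    long <- do.call(rbind, rows)
    wide <- stats::reshape(long, direction = "wide", timevar = "metric",
                           idvar = c("specimen_id", "group", "body_part",
                                     "filter_config"))
    names(wide) <- sub("^value\\.", "", names(wide))
    for (m in setdiff(c("mean_intensity", "percent_brightest"), names(wide))) {
      wide[[m]] <- NA_real_
    }
    rownames(wide) <- NULL
    log <- list(rows_read = nrow(df), rows_emitted = nrow(wide),
                per_group = table(df$group))
    list(records = wide, log = log)
  } else {
    wl <- df[[1L]]
    if (any(diff(wl) <= 0)) {
      stop("conversion error: first column is not an increasing wavelength grid")
    }
    value_cols <- names(df)[-1L]
    # Auto-detect scale: percent reflectance vs raw counts.
    mx <- max(as.matrix(df[value_cols]), na.rm = TRUE)
    scale_guess <- if (mx <= 150) "percent" else "raw_counts"
    spectra <- lapply(value_cols, function(cn) {
      spectrum_obj(wl, df[[cn]], kind = "reflectance",
                   metadata = list(reading = cn, scale = scale_guess))
    })
    names(spectra) <- value_cols
    list(spectra = spectra,
         log = list(rows_read = nrow(df), readings = length(value_cols),
                    scale_guess = scale_guess))
  }
}
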