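#' Generate a synthetic specimen score table with known ground truth
#'
#' Draws one record per specimen x body part x filter configuration.
#' Mean intensity is a truncated normal on \[0, 4095\] around the group's
#' configured emission mean (attenuated under the blocking filter); the
#' percent-in-brightest score is a zero-inflated Beta scaled to \[0, 100\]:
#' exactly zero with the group's zero-inflation probability, otherwise a
#' positive continuous draw whose mean tracks the group's brightness.
#' Deterministic given the config seed; each specimen uses a derived
#' substream so output does not depend on generation order.
#'
#' @param config a [sim_config()].
#' @return list with `records` (the specimen table, a data.frame with
#'   columns specimen_id, group, body_part, filter_config, mean_intensity,
#'   percent_brightest) and `ground_truth` (one row per specimen x body
#'   part: true mean emission level, expected bright-area fraction, group).
#' @export
generate_specimen_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rec <- list()
  gt <- list()
  for (g in names(config$groups)) {
    br <- config$group_brightness[[g]]
    p0 <- config$zero_inflation[[g]]
    for (i in seq_len(config$groups[[g]])) {
      sid <- sprintf("%s_%02d", g, i)
      for (part in parts_for_group(g, config$body_parts)) {
        mu_frac <- clamp(br[["mean"]] / 4095, 0.02, 0.95)
        gt[[length(gt) + 1L]] <- data.frame(
          specimen_id = sid, group = g, body_part = part,
          true_mean = br[["mean"]],
          true_bright_fraction = (1 - p0) * mu_frac,
          stringsAsFactors = FALSE)
        for (fc in config$filters) {
          att <- if (fc == "blocking") config$blocking_attenuation else 1
          sub <- derive_seed(config$seed, sid, part, fc)
          draws <- withr::with_seed(sub, {
            m <- rtruncnorm(1L, br[["mean"]] * att, br[["dispersion"]] * att,
                            0, 4095)
            pb <- if (runif(1L) < p0) 0 else {
              mu <- clamp(br[["mean"]] * att / 4095, 0.02, 0.95)
              phi <- 8
              100 * rbeta(1L, mu * phi, (1 - mu) * phi)
            }
            c(m, pb)
          })
          rec[[length(rec) + 1L]] <- data.frame(
            specimen_id = sid, group = g, body_part = part,
            filter_config = fc, mean_intensity = draws[1L],
            percent_brightest = draws[2L], stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(records = do.call(rbind, rec), ground_truth = do.call(rbind, gt))
}

#' Read / write the specimen score table
#'
#' CSV with columns specimen_id, group, body_part, filter_config,
#' mean_intensity, percent_brightest (mirrors the deposited per-specimen
#' intensity table, with tabs flattened into the filter_config column).
#'
#' @param records specimen table data.frame.
#' @param path file path.
#' @export
write_specimen_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_specimen_table
#' @export
read_specimen_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "group", "body_part", "filter_config",
            "mean_intensity", "percent_brightest")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("specimen table is missing columns: ", paste(miss, collapse = ", "))
  }
  df
}
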