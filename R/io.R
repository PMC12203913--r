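# File formats: TSV tables for tracks/events/titrations with a JSON sidecar
# carrying the schema version and generating configuration.

SCHEMA_VERSION <- "1.0"

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, extra = list()) {
  meta <- c(list(schema_version = SCHEMA_VERSION), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

check_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(invisible(NULL))
  meta <- jsonlite::read_json(sp)
  ver <- meta$schema_version
  if (!is.null(ver)) {
    major <- as.integer(strsplit(as.character(ver), ".", fixed = TRUE)[[1]][1])
    if (major > as.integer(strsplit(SCHEMA_VERSION, ".", fixed = TRUE)[[1]][1]))
      smc_abort(sprintf("file %s has schema %s, newer than supported %s",
                        path, ver, SCHEMA_VERSION), "schema")
  }
  invisible(meta)
}

TRACK_COLS <- c("track_id", "frame", "time_s", "position_kbp", "sigma_kbp",
                "salt_mM", "censored_end")

#' Write trajectories to a TSV track table
#'
#' Long-format TSV with columns `track_id`, `frame`, `time_s`, `position_kbp`,
#' `sigma_kbp`, `salt_mM`, `censored_end`, plus a JSON sidecar
#' (`<path>.json`) recording the schema version and, optionally, the
#' generating configuration and seed.
#'
#' @param trajs List of [curtain_track()] (or a single track).
#' @param path Output TSV path.
#' @param config Optional [sim_config()] recorded in the sidecar.
#' @param seed Optional seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trajs, path, config = NULL, seed = NULL) {
  if (inherits(trajs, "curtain_track")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    data.frame(track_id = tr$track_id,
               frame = seq_along(tr$times_s),
               time_s = tr$times_s,
               position_kbp = tr$positions_kbp,
               sigma_kbp = tr$sigma_loc_kbp,
               salt_mM = tr$salt_mM,
               censored_end = tr$censored_end,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(TRACK_COLS))),
                    TRACK_COLS)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- if (is.null(config)) NULL else unclass(config)
  write_sidecar(path, list(config = cfg, seed = seed, kind = "tracks"))
  invisible(path)
}

#' Read a TSV track table
#'
#' Validates the schema (column set), per-track time monotonicity and uniform
#' spacing, and the sidecar schema version if present. Malformed tracks are
#' reported by id.
#'
#' @param path TSV path written by [write_tracks()].
#' @param dna_length_kbp Optional DNA length for position validation.
#' @return List of [curtain_track()]; empty (with a warning) for an empty file.
#' @export
read_tracks <- function(path, dna_length_kbp = NA_real_) {
  check_sidecar(path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRACK_COLS, names(df))
  if (length(missing_cols))
    smc_abort(paste("track table is missing columns:",
                    paste(missing_cols, collapse = ", ")), "schema")
  if (!nrow(df)) {
    warning("empty track table: ", path)
    return(list())
  }
  ids <- unique(df$track_id)
  lapply(ids, function(id) {
    sub <- df[df$track_id == id, ]
    sub <- sub[order(sub$frame), ]
    tryCatch(
      curtain_track(id, sub$time_s, sub$position_kbp,
                    sigma_loc_kbp = sub$sigma_kbp[1], salt_mM = sub$salt_mM[1],
                    censored_end = isTRUE(as.logical(sub$censored_end[1])),
                    dna_length_kbp = dna_length_kbp),
      smcurtain_validation = function(e)
        smc_abort(sprintf("track '%s' failed validation: %s", id,
                          conditionMessage(e)), "validation")
    )
  })
}

#' Write dwell events to TSV
#'
#' @param events Data frame from [classify_events()] or
#'   [simulate_search_experiment()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(path, list(kind = "events"))
  invisible(path)
}

#' Read a dwell-event TSV
#' @param path TSV path written by [write_events()].
#' @return Data frame of events.
#' @export
read_events <- function(path) {
  check_sidecar(path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("track_id", "mode", "bypass_count", "dwell_s", "censored")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    smc_abort(paste("event table is missing columns:",
                    paste(missing_cols, collapse = ", ")), "schema")
  df
}

#' Write a titration series to TSV
#'
#' Long format: `conc_nM`, `species`, `fraction`.
#' @param series A [titration_series()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  bf <- series$band_fractions
  df <- data.frame(
    conc_nM = rep(series$protein_concs_nM, times = ncol(bf)),
    species = rep(colnames(bf), each = nrow(bf)),
    fraction = as.vector(bf), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(path, list(kind = "titration",
                           dna_total_nM = series$dna_total_nM,
                           noise_sd = series$noise_sd))
  invisible(path)
}

#' Read a titration TSV
#' @param path TSV path written by [write_titration()].
#' @return A [titration_series()].
#' @export
read_titration <- function(path) {
  meta <- check_sidecar(path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("conc_nM", "species", "fraction")
  if (length(setdiff(need, names(df))))
    smc_abort("titration table needs conc_nM, species, fraction", "schema")
  concs <- sort(unique(df$conc_nM))
  species <- unique(df$species)
  bf <- sapply(species, function(s) {
    sub <- df[df$species == s, ]
    sub$fraction[match(concs, sub$conc_nM)]
  })
  titration_series(concs, meta$dna_total_nM %||% NA_real_, bf,
                   noise_sd = meta$noise_sd %||% 0)
}

#' Write a kymograph as a TIFF image plus JSON metadata
#'
#' Requires the optional `tiff` package.
#' @param img A [kymograph()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_kymograph_tiff <- function(img, path) {
  stopifnot(inherits(img, "kymograph"))
  if (!requireNamespace("tiff", quietly = TRUE))
    smc_abort("the 'tiff' package is required for TIFF output", "invalid_argument")
  m <- img$intensity
  tiff::writeTIFF(m / max(m, 1), path, bits.per.sample = 16)
  write_sidecar(path, list(kind = "kymograph",
                           pixel_size_kbp = img$pixel_size_kbp,
                           frame_interval_s = img$frame_interval_s,
                           psf_sigma_px = img$psf_sigma_px,
                           background_level = img$background_level,
                           max_intensity = max(m, 1)))
  invisible(path)
}
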