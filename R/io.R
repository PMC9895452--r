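# On-disk session bundle. The study does not prescribe formats; these are
# artifact conventions: little-endian int16 flat binary + JSON sidecar for
# traces (channel-major interleaving, microvolt scale in the sidecar), CSV
# (comma, UTF-8, header, "." decimal) for trials / eye / spike times, and a
# manifest.json naming the components present.

write_num_csv <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- format(out[[nm]], digits = 17,
                                                   trim = TRUE,
                                                   scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Save a session bundle to a directory
#'
#' @param bundle named list with any of `recording` ([recording_block()]),
#'   `trials` ([trial_table()]), `eye` ([eye_trace()]), `clusters` (list of
#'   [spike_cluster()]).
#' @param path directory (created if absent).
#' @param scale_uV microvolts per int16 count for the raw trace; default
#'   uses the full int16 range. Voltages already on the `scale_uV` grid
#'   round-trip bit-identically; others are quantized.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path, scale_uV = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format_version = 1L, components = character(0))
  if (!is.null(bundle$recording)) {
    blk <- bundle$recording
    scale <- scale_uV %||% (max(abs(blk$samples), 1e-12) / 32767)
    counts <- as.integer(round(t(blk$samples) / scale))  # channel-major
    con <- file(file.path(path, "recording.bin"), "wb")
    writeBin(counts, con, size = 2L, endian = "little")
    close(con)
    side <- list(rate = blk$rate, n_channels = nrow(blk$samples),
                 n_samples = ncol(blk$samples), dtype = "int16",
                 byte_order = "little", interleave = "channel-major",
                 scale_uV = scale, t0 = blk$t0,
                 channel_map = blk$channel_map)
    jsonlite::write_json(side, file.path(path, "recording.json"),
                         auto_unbox = TRUE, digits = I(17), dataframe = "rows")
    manifest$components <- c(manifest$components, "recording")
  }
  if (!is.null(bundle$trials)) {
    write_num_csv(as.data.frame(bundle$trials), file.path(path, "trials.csv"))
    manifest$components <- c(manifest$components, "trials")
  }
  if (!is.null(bundle$eye)) {
    ey <- bundle$eye
    write_num_csv(data.frame(t = ey$t, x = ey$x, y = ey$y,
                             blink = as.integer(ey$blink)),
                  file.path(path, "eye.csv"))
    jsonlite::write_json(list(rate = ey$rate), file.path(path, "eye.json"),
                         auto_unbox = TRUE, digits = I(17))
    manifest$components <- c(manifest$components, "eye")
  }
  if (!is.null(bundle$clusters)) {
    cdir <- file.path(path, "clusters")
    dir.create(cdir, showWarnings = FALSE)
    ids <- character(0)
    for (cl in bundle$clusters) {
      id <- as.character(cl$unit_id)
      ids <- c(ids, id)
      write_num_csv(data.frame(spike_time = cl$spike_times),
                    file.path(cdir, paste0(id, "_times.csv")))
      meta <- list(unit_id = id, peak_channel = cl$peak_channel)
      if (!is.null(cl$snippets)) {
        d <- dim(cl$snippets)
        con <- file(file.path(cdir, paste0(id, "_snippets.bin")), "wb")
        writeBin(as.numeric(cl$snippets), con, size = 8L, endian = "little")
        close(con)
        meta$snippet_dims <- d
      }
      if (!is.null(cl$mean_waveform)) {
        con <- file(file.path(cdir, paste0(id, "_meanwf.bin")), "wb")
        writeBin(as.numeric(cl$mean_waveform), con, size = 8L,
                 endian = "little")
        close(con)
        meta$meanwf_dims <- dim(cl$mean_waveform)
      }
      jsonlite::write_json(meta, file.path(cdir, paste0(id, ".json")),
                           auto_unbox = TRUE, digits = I(17))
    }
    manifest$cluster_ids <- ids
    manifest$components <- c(manifest$components, "clusters")
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

read_sidecar <- function(path, required) {
  if (!file.exists(path)) stop("missing sidecar file: ", path)
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(required, names(side))
  if (length(miss))
    stop("sidecar ", basename(path), " missing key(s): ",
         paste(miss, collapse = ", "))
  side
}

#' Load a session bundle saved by [save_bundle()]
#'
#' @param path bundle directory.
#' @return named list mirroring the saved bundle.
#' @export
load_bundle <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  out <- list()
  if ("recording" %in% man$components) {
    side <- read_sidecar(file.path(path, "recording.json"),
                         c("rate", "n_channels", "n_samples", "scale_uV",
                           "channel_map"))
    n <- side$n_channels * side$n_samples
    con <- file(file.path(path, "recording.bin"), "rb")
    counts <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                      endian = "little")
    close(con)
    if (length(counts) != n)
      stop("recording.bin length (", length(counts),
           ") inconsistent with sidecar n_channels x n_samples (", n, ")")
    samples <- t(matrix(counts, nrow = side$n_samples)) * side$scale_uV
    out$recording <- recording_block(samples, as.numeric(side$rate),
                                     as.data.frame(side$channel_map),
                                     t0 = as.numeric(side$t0 %||% 0))
  }
  if ("trials" %in% man$components) {
    out$trials <- validate_trial_table(
      utils::read.csv(file.path(path, "trials.csv"),
                      colClasses = c(condition = "character",
                                     outcome = "character")))
  }
  if ("eye" %in% man$components) {
    side <- read_sidecar(file.path(path, "eye.json"), "rate")
    df <- utils::read.csv(file.path(path, "eye.csv"))
    out$eye <- eye_trace(df$t, df$x, df$y, side$rate, as.logical(df$blink))
  }
  if ("clusters" %in% man$components) {
    cdir <- file.path(path, "clusters")
    out$clusters <- lapply(man$cluster_ids, function(id) {
      meta <- jsonlite::read_json(file.path(cdir, paste0(id, ".json")),
                                  simplifyVector = TRUE)
      times <- utils::read.csv(file.path(cdir,
                                         paste0(id, "_times.csv")))$spike_time
      if (is.null(times)) times <- numeric(0)
      snip <- NULL
      sf <- file.path(cdir, paste0(id, "_snippets.bin"))
      if (file.exists(sf) && !is.null(meta$snippet_dims)) {
        con <- file(sf, "rb")
        v <- readBin(con, "numeric", n = prod(meta$snippet_dims), size = 8L,
                     endian = "little")
        close(con)
        snip <- array(v, dim = meta$snippet_dims)
      }
      mw <- NULL
      mf <- file.path(cdir, paste0(id, "_meanwf.bin"))
      if (file.exists(mf) && !is.null(meta$meanwf_dims)) {
        con <- file(mf, "rb")
        v <- readBin(con, "numeric", n = prod(meta$meanwf_dims), size = 8L,
                     endian = "little")
        close(con)
        mw <- matrix(v, nrow = meta$meanwf_dims[1])
      }
      spike_cluster(meta$unit_id, times, snippets = snip, mean_waveform = mw,
                    peak_channel = meta$peak_channel)
    })
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
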