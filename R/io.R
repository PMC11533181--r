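#' Write an inversion-recovery dataset to a directory
#'
#' Serializes a [fid_series()] in the package's plain-text dataset dialect:
#' `meta.json` holds the acquisition metadata and the recovery-delay list,
#' `data.csv` holds one row per recovery delay with interleaved real and
#' imaginary values (`2 * n_points` numeric columns, no header).  Values are
#' written with 17 significant digits so that [read_dataset()] round-trips
#' finite doubles bit-exactly.
#'
#' @param series a [fid_series()].
#' @param path directory to write into (created if absent); existing
#'   `meta.json` / `data.csv` files are replaced.
#' @return `invisible(path)`.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(series, path) {
  if (!inherits(series, "fid_series")) stop_input("series must be a fid_series")
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop_io("cannot create directory '%s'", path)
  meta <- list(
    nucleus = series$acq$nucleus_label,
    carrier_hz = series$acq$carrier_hz,
    dwell_s = series$acq$dwell_s,
    n_points = series$acq$n_points,
    tau_s = series$tau_s
  )
  if (!is.null(series$acq$proton_tms_hz)) meta$proton_tms_hz <- series$acq$proton_tms_hz
  if (!is.null(series$acq$temperature_k)) meta$temperature_k <- series$acq$temperature_k
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # interleave Re/Im column-wise: row i is re[1], im[1], re[2], im[2], ...
  n <- series$acq$n_points
  inter <- matrix(0, nrow = nrow(series$data), ncol = 2L * n)
  inter[, seq(1L, 2L * n, by = 2L)] <- Re(series$data)
  inter[, seq(2L, 2L * n, by = 2L)] <- Im(series$data)
  lines <- apply(inter, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  con <- file(file.path(path, "data.csv"), "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read an inversion-recovery dataset from a directory
#'
#' Inverse of [write_dataset()]: reads `meta.json` and `data.csv` in the
#' documented dialect and returns a validated [fid_series()].
#'
#' @param path directory holding `meta.json` and `data.csv`.
#' @return a [fid_series()].
#' @export
read_dataset <- function(path) {
  meta_path <- file.path(path, "meta.json")
  data_path <- file.path(path, "data.csv")
  if (!file.exists(meta_path)) stop_input("missing file '%s'", meta_path)
  if (!file.exists(data_path)) stop_input("missing file '%s'", data_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  req <- c("nucleus", "carrier_hz", "dwell_s", "n_points", "tau_s")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop_format("meta.json is missing keys: %s", paste(miss, collapse = ", "))
  acq <- acq_meta(carrier_hz = meta$carrier_hz, dwell_s = meta$dwell_s,
                  n_points = meta$n_points, nucleus_label = meta$nucleus,
                  proton_tms_hz = meta$proton_tms_hz,
                  temperature_k = meta$temperature_k)
  lines <- readLines(data_path)
  n_tau <- length(meta$tau_s)
  if (length(lines) != n_tau)
    stop_format("data.csv has %d rows but meta.json lists %d recovery delays",
                length(lines), n_tau)
  vals <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, ",", fixed = TRUE)[[1L]]))
    v
  })
  ncols <- vapply(vals, length, integer(1))
  if (any(ncols != 2L * meta$n_points))
    stop_format("data.csv rows must have %d values (2 x n_points); found %s",
                2L * meta$n_points, paste(unique(ncols), collapse = "/"))
  m <- do.call(rbind, vals)
  if (any(!is.finite(m))) stop_format("data.csv contains non-finite or non-numeric values")
  cdata <- m[, seq(1L, ncol(m), by = 2L), drop = FALSE] +
    1i * m[, seq(2L, ncol(m), by = 2L), drop = FALSE]
  fid_series(cdata, meta$tau_s, acq)
}

#' Serialize a relaxation-shift map
#'
#' Writes the amplitude matrix to `map.csv` (rows = T1 grid points) and the
#' axes, per-channel regularization parameters and metadata to `map.json`.
#'
#' @param map an [adrosys_map()].
#' @param path output directory (created if absent).
#' @return `invisible(path)`.
#' @export
write_map <- function(map, path) {
  if (!inherits(map, "adrosys_map")) stop_input("map must be an adrosys_map")
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop_io("cannot create directory '%s'", path)
  utils::write.table(map$amplitude, file.path(path, "map.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(
    t1_grid_s = map$t1_grid$values_s,
    ppm_axis = map$ppm_axis,
    alpha_per_channel = map$alpha_per_channel,
    meta = map$meta
  ), file.path(path, "map.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE,
     null = "null", na = "null")
  invisible(path)
}

#' Read back a serialized relaxation-shift map
#'
#' @param path directory written by [write_map()].
#' @return an [adrosys_map()].
#' @export
read_map <- function(path) {
  j <- jsonlite::read_json(file.path(path, "map.json"), simplifyVector = TRUE)
  amp <- as.matrix(utils::read.csv(file.path(path, "map.csv"), header = FALSE))
  dimnames(amp) <- NULL
  g <- j$t1_grid_s
  grid <- relax_grid(min(g), max(g), length(g))
  adrosys_map(amp, grid, j$ppm_axis, alpha_per_channel = j$alpha_per_channel,
              meta = as.list(j$meta))
}
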