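#' Summarize peaks of a relaxation-shift map
#'
#' Reduces the 2D amplitude distribution to one record per peak:
#' amplitude-weighted centroids in ppm and log10(T1), full widths
#' (2.355 times the amplitude-weighted standard deviation, i.e. FWHM for a
#' Gaussian) along both dimensions, and the summed amplitude (mass).
#'
#' In `"auto"` mode peaks are the connected components (4-neighbourhood) of
#' the map above `threshold_mult` times the channel-noise-equivalent
#' amplitude.  Overlapping populations -- e.g. a solvent-exchange resonance
#' next to the water peak -- can instead be separated by explicit ppm
#' intervals, mirroring the practice of zeroing one ppm range while
#' integrating the other.
#'
#' @param map an [adrosys_map()].
#' @param regions `"auto"`, or a list of `c(lo, hi)` ppm intervals.
#' @param threshold_mult threshold in noise units for auto detection
#'   (default 3).
#' @param noise_sigma noise-equivalent amplitude; defaults to the value
#'   recorded in `map$meta`, falling back to 1e-3 of the map maximum.
#' @param min_mass_frac peaks carrying less than this fraction of the total
#'   map amplitude are dropped as noise specks (default 0.01; set to 0 to
#'   keep everything).
#' @return data frame with columns `shift_centroid_ppm`, `logt1_centroid`,
#'   `width_ppm`, `width_logt1`, `mass`; zero rows for an empty map.
#' @export
summarize_peaks <- function(map, regions = "auto", threshold_mult = 3,
                            noise_sigma = NULL, min_mass_frac = 0.01) {
  if (!inherits(map, "adrosys_map")) stop_input("map must be an adrosys_map")
  amp <- map$amplitude
  logt1 <- log10(map$t1_grid$values_s)
  ppm <- map$ppm_axis
  empty <- data.frame(shift_centroid_ppm = numeric(0),
                      logt1_centroid = numeric(0), width_ppm = numeric(0),
                      width_logt1 = numeric(0), mass = numeric(0))
  if (all(amp == 0)) return(empty)
  sigma <- noise_sigma %||% map$meta$noise_sigma %||% (1e-3 * max(amp))
  thr <- threshold_mult * sigma
  one <- function(cells) {
    w <- amp[cells]
    m <- sum(w)
    if (m <= 0) return(NULL)
    rows <- ((cells - 1L) %% nrow(amp)) + 1L
    cols <- ((cells - 1L) %/% nrow(amp)) + 1L
    cp <- sum(w * ppm[cols]) / m
    ct <- sum(w * logt1[rows]) / m
    data.frame(shift_centroid_ppm = cp, logt1_centroid = ct,
               width_ppm = 2.355 * sqrt(sum(w * (ppm[cols] - cp)^2) / m),
               width_logt1 = 2.355 * sqrt(sum(w * (logt1[rows] - ct)^2) / m),
               mass = m)
  }
  if (identical(regions, "auto")) {
    labels <- label_components(amp > thr)
    ids <- setdiff(unique(as.vector(labels)), 0L)
    out <- lapply(ids, function(id) one(which(labels == id)))
  } else {
    out <- lapply(regions, function(rg) {
      sel_cols <- which(ppm >= min(rg) & ppm <= max(rg))
      cells <- which(col(amp) %in% sel_cols & amp > 0)
      if (!length(cells)) {
        warning(sprintf("region [%g, %g] ppm contains no signal; skipped",
                        min(rg), max(rg)), call. = FALSE)
        return(NULL)
      }
      one(cells)
    })
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[res$mass >= min_mass_frac * sum(amp), , drop = FALSE]
  if (!nrow(res)) return(empty)
  res <- res[order(-res$mass), , drop = FALSE]
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# label connected components (4-neighbourhood) of a logical matrix
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      cell <- queue[[1L]]; queue <- queue[-1L]
      r <- ((cell - 1L) %% nr) + 1L
      cc <- ((cell - 1L) %/% nr) + 1L
      for (nb in c(if (r > 1L) cell - 1L, if (r < nr) cell + 1L,
                   if (cc > 1L) cell - nr, if (cc < nc) cell + nr)) {
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

#' Diagonality of a T1-T2 map
#'
#' Fraction of the map amplitude lying within `delta_decades` of the
#' T1 = T2 diagonal, i.e. with `|log10(T1 / T2)| < delta_decades`.  Water in
#' the extreme narrowing regime has T1 = T2, so a diagonality near 1 is the
#' signature of motional narrowing; off-diagonal mass indicates slow motion
#' (T1 > T2) or artifacts.
#'
#' @param map a [t1t2_map()].
#' @param delta_decades half-width of the diagonal band in decades (> 0).
#' @return fraction in `[0, 1]` (`NA` for an all-zero map).
#' @export
diagonality <- function(map, delta_decades = 0.3) {
  if (!inherits(map, "t1t2_map")) stop_input("map must be a t1t2_map")
  if (delta_decades <= 0) stop_domain("delta_decades must be > 0")
  total <- sum(map$amplitude)
  if (total == 0) return(NA_real_)
  lr <- outer(log10(map$t1_grid$values_s), log10(map$t2_grid$values_s), `-`)
  sum(map$amplitude[abs(lr) < delta_decades]) / total
}

#' Perceptually uniform colormap over water loadings
#'
#' Builds one color per water loading in the CIE Lab space: all colors share
#' the same lightness L*, and they sit on a constant-chroma arc in the
#' (a*, b*) plane with arc position linear in w0.  Equal steps in w0 then
#' correspond to equal perceptual distances (Lab Euclidean Delta-E), so the
#' color of a contour set encodes its water loading faithfully.
#'
#' @param w0_values strictly ascending water loadings (>= 1 value).
#' @param lightness shared L* value (default 45).
#' @param chroma radius of the (a*, b*) arc (default 55).
#' @param hue_range_deg arc start and end in degrees (default 30 to 330).
#' @return an object of class `w0_colorspec`: list with `lightness_L`, `w0`,
#'   `lab` (matrix of L, a, b rows) and `hex` (sRGB strings).
#' @export
w0_colormap <- function(w0_values, lightness = 45, chroma = 55,
                        hue_range_deg = c(30, 330)) {
  w0_values <- as.numeric(w0_values)
  if (!length(w0_values)) stop_domain("need at least one w0 value")
  if (length(w0_values) > 1 && any(diff(w0_values) <= 0))
    stop_domain("w0_values must be strictly ascending")
  pos <- if (length(w0_values) == 1L) 0 else
    (w0_values - w0_values[1]) / (w0_values[length(w0_values)] - w0_values[1])
  hue <- (hue_range_deg[1] + pos * diff(hue_range_deg)) * pi / 180
  lab <- cbind(L = rep(lightness, length(w0_values)),
               a = chroma * cos(hue), b = chroma * sin(hue))
  srgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB", clip = TRUE)
  hex <- grDevices::rgb(srgb[, 1], srgb[, 2], srgb[, 3])
  structure(list(lightness_L = lightness, w0 = w0_values, lab = lab,
                 hex = hex), class = "w0_colorspec")
}

#' Contour plot of a relaxation-shift map
#'
#' Draws logarithmically spaced contour levels of the amplitude over
#' (ppm, log10 T1), with the ppm axis reversed per NMR convention.  The map
#' object is never modified.
#'
#' @param map an [adrosys_map()].
#' @param n_levels number of contour levels (log-spaced in amplitude).
#' @param col contour color.
#' @param add overlay on an existing plot.
#' @param ... passed to [graphics::contour()].
#' @return `invisible(map)`.
#' @export
plot_adrosys_map <- function(map, n_levels = 10, col = "#204060",
                             add = FALSE, ...) {
  amp <- map$amplitude
  mx <- max(amp)
  if (mx <= 0) stop_input("cannot plot an all-zero map")
  levels <- mx * 10^seq(-2, 0, length.out = n_levels + 1)[-(n_levels + 1)]
  ord <- order(map$ppm_axis)
  x <- map$ppm_axis[ord]
  graphics::contour(x = x, y = log10(map$t1_grid$values_s),
                    z = t(amp[, ord, drop = FALSE]), levels = levels,
                    drawlabels = FALSE, col = col, add = add,
                    xlim = rev(range(x)), xlab = "chemical shift (ppm)",
                    ylab = "log10 T1 (s)", ...)
  invisible(map)
}

#' Full processing pipeline: dataset directory to map and peak table
#'
#' Runs the complete chain on a dataset in the documented dialect:
#' [read_dataset()], [process_direct()] (with ppm referencing), [ilt_1p5d()]
#' and [summarize_peaks()].  Optionally writes the map (`map.csv` +
#' `map.json`), the peak table (`peaks.tsv`), a contour plot and a run
#' record (`run.json` with the configuration and package version) to an
#' output directory.  The pipeline has no stochastic stage: rerunning on the
#' same inputs and configuration reproduces the artifacts exactly.
#'
#' @param dataset_dir directory holding `meta.json` and `data.csv`.
#' @param out_dir optional output directory.
#' @param config list of settings: `line_broaden_hz`, `zero_fill_factor`,
#'   `phase` (`"auto"` or a [phase_correction()]), `ref` (`"tms"` or
#'   `"carrier"`), `grid` (a [relax_grid()]), `opts` (a [brd_options()]),
#'   `inv_eff`, `threshold_mult`, `ppm_range`, `regions`, `plot` (logical).
#' @return list with `map` (an [adrosys_map()]), `peaks` (data frame) and
#'   `files` (paths written, if any).
#' @export
run_pipeline <- function(dataset_dir, out_dir = NULL, config = list()) {
  cfg <- utils::modifyList(list(
    line_broaden_hz = 1, zero_fill_factor = 2, phase = "auto", ref = "tms",
    grid = relax_grid(), opts = brd_options(), inv_eff = 1,
    threshold_mult = 5, ppm_range = NULL, regions = "auto", plot = TRUE
  ), config)
  stage <- function(name, expr) {
    tryCatch(expr, adrosys_error = function(e) {
      stop_with(class(e)[1],
                "pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  series <- stage("read_dataset", read_dataset(dataset_dir))
  spec <- stage("process_direct",
                process_direct(series, line_broaden_hz = cfg$line_broaden_hz,
                               zero_fill_factor = cfg$zero_fill_factor,
                               phase = cfg$phase, ref = cfg$ref))
  map <- stage("ilt_1p5d",
               ilt_1p5d(spec, grid = cfg$grid, opts = cfg$opts,
                        inv_eff = cfg$inv_eff,
                        threshold_mult = cfg$threshold_mult,
                        ppm_range = cfg$ppm_range))
  peaks <- stage("summarize_peaks", summarize_peaks(map, regions = cfg$regions))
  files <- character(0)
  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                            showWarnings = FALSE)
    if (!ok) stop_io("cannot create output directory '%s'", out_dir)
    write_map(map, out_dir)
    peaks_path <- file.path(out_dir, "peaks.tsv")
    utils::write.table(peaks, peaks_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(file.path(out_dir, c("map.csv", "map.json")), peaks_path)
    jsonlite::write_json(list(
      dataset = normalizePath(dataset_dir),
      config = list(line_broaden_hz = cfg$line_broaden_hz,
                    zero_fill_factor = cfg$zero_fill_factor, ref = cfg$ref,
                    inv_eff = cfg$inv_eff, threshold_mult = cfg$threshold_mult),
      package_version = as.character(utils::packageVersion("adrosys"))
    ), file.path(out_dir, "run.json"), auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, file.path(out_dir, "run.json"))
    if (isTRUE(cfg$plot) && max(map$amplitude) > 0) {
      plot_path <- file.path(out_dir, "map.png")
      ok <- tryCatch({
        grDevices::png(plot_path, width = 900, height = 700)
        plot_adrosys_map(map)
        grDevices::dev.off()
        TRUE
      }, error = function(e) {
        try(grDevices::dev.off(), silent = TRUE)
        warning("could not render contour plot: ", conditionMessage(e),
                call. = FALSE)
        FALSE
      })
      if (ok) files <- c(files, plot_path)
    }
  }
  list(map = map, peaks = peaks, files = files)
}
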