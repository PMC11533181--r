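#' Packaged correlation-time table for reverse-micelle samples
#'
#' Rotational correlation times (in picoseconds) determined from deuterium T1
#' measurements across reverse-micelle preparations: three AOT dispersant
#' series (isooctane, hexane, CCl4), an Igepal/cyclohexane series, a
#' CTAB/hexane series (hexanol cosurfactant), and AOT/isooctane series with
#' glucose and PEG-200 guest molecules -- seven (surfactant, dispersant,
#' guest) series, 40 rows in total.  Shipped as plain text under
#' `inst/extdata/table1_tauc.tsv` and parsed on demand; this is the single
#' source of truth used by the tests and the theory layer.
#'
#' @return a data frame with columns `surfactant`, `dispersant`, `guest`
#'   (`NA` for none), `w0` and `tau_c_ps`, one row per sample.
#' @examples
#' tbl <- table1_fixture()
#' rm_lookup(tbl, "AOT", "isooctane", w0 = 0.9)$tau_c_ps
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_tauc.tsv", package = "adrosys",
                      mustWork = TRUE)
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "numeric", "numeric"))
  tbl$guest[!nzchar(tbl$guest)] <- NA_character_
  tbl
}

#' Look up a sample in the correlation-time table
#'
#' @param tbl the data frame from [table1_fixture()].
#' @param surfactant,dispersant,guest identity of the series (`guest = NA`
#'   selects guest-free samples).
#' @param w0 water loading; matched within `tol`.
#' @param tol matching tolerance on `w0`.
#' @return the matching row(s) of `tbl` (possibly zero rows).
#' @export
rm_lookup <- function(tbl, surfactant, dispersant, guest = NA, w0 = NULL,
                      tol = 1e-6) {
  sel <- tbl$surfactant == surfactant & tbl$dispersant == dispersant
  sel <- sel & (if (is.na(guest)) is.na(tbl$guest) else !is.na(tbl$guest) & tbl$guest == guest)
  if (!is.null(w0)) sel <- sel & abs(tbl$w0 - w0) <= tol
  tbl[which(sel), , drop = FALSE]
}

#' Split the correlation-time table into its series
#'
#' @param tbl the data frame from [table1_fixture()].
#' @return a named list of data frames, one per (surfactant, dispersant,
#'   guest) combination, each ordered by increasing `w0`.
#' @export
rm_series_split <- function(tbl) {
  key <- paste(tbl$surfactant, tbl$dispersant,
               ifelse(is.na(tbl$guest), "none", tbl$guest), sep = "/")
  out <- split(tbl, key)
  lapply(out, function(d) d[order(d$w0), , drop = FALSE])
}
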