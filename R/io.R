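#' Read a TCSPC decay from multi-column ASCII
#'
#' Whitespace- or comma-separated columns: time (ns), counts, optional
#' IRF, optional linearization curve. Lines starting with `#` are
#' skipped.
#'
#' @param file path.
#' @return a [decay_curve()].
#' @export
read_decay_ascii <- function(file) {
  d <- utils::read.table(file, comment.char = "#",
                         sep = "", fill = TRUE)
  decay_curve(d[[1]], d[[2]],
              irf = if (ncol(d) >= 3) d[[3]],
              linearization = if (ncol(d) >= 4) d[[4]])
}

#' @rdname read_decay_ascii
#' @param curve a [decay_curve()].
#' @export
write_decay_ascii <- function(curve, file) {
  d <- data.frame(time = curve$time, counts = curve$counts)
  if (!is.null(curve$irf)) d$irf <- curve$irf
  if (!is.null(curve$linearization)) d$lin <- curve$linearization
  utils::write.table(d, file, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read / write a two-column DEER trace (t in us, V)
#' @param file path.
#' @export
read_deer_ascii <- function(file) {
  d <- utils::read.table(file, comment.char = "#")
  deer_trace(d[[1]], d[[2]])
}

#' @rdname read_deer_ascii
#' @param trace a [deer_trace()].
#' @export
write_deer_ascii <- function(trace, file) {
  utils::write.table(data.frame(trace$t_us, trace$v), file,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a SASBDB-style 3-column SAXS .dat file
#'
#' Header-tolerant: any leading lines that do not parse as three numbers
#' are skipped.
#'
#' @param file path.
#' @param unit q unit of the file.
#' @export
read_saxs_dat <- function(file, unit = "A-1") {
  lines <- readLines(file, warn = FALSE)
  parsed <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (length(v) >= 3 && !anyNA(v[1:3])) v[1:3] else NULL
  })
  m <- do.call(rbind, parsed)
  if (is.null(m) || nrow(m) < 3) stop("no data rows found in ", file)
  saxs_curve(m[, 1], m[, 2], m[, 3], unit = unit)
}

#' @rdname read_saxs_dat
#' @param curve a [saxs_curve()].
#' @export
write_saxs_dat <- function(curve, file) {
  sig <- curve$sigma %||% rep(0, length(curve$q))
  writeLines(c(sprintf("# q (%s)  I(q)  sigma", curve$unit),
               sprintf("%.6e %.6e %.6e", curve$q, curve$i, sig)), file)
  invisible(file)
}

#' Write a label cloud in XYZ-with-weights text format
#'
#' First line: point count; second line: comment; then `x y z w` rows.
#'
#' @param cloud a `label_cloud`.
#' @param file path.
#' @export
write_cloud_xyz <- function(cloud, file) {
  writeLines(c(as.character(nrow(cloud$points)),
               sprintf("label cloud, residue %s", format(cloud$site$resid)),
               sprintf("%.3f %.3f %.3f %.6e", cloud$points[, 1],
                       cloud$points[, 2], cloud$points[, 3],
                       cloud$weights)), file)
  invisible(file)
}

#' Write / read a distance distribution as two-column CSV
#' @param dist a [distance_distribution()].
#' @param file path.
#' @export
write_distribution_csv <- function(dist, file) {
  utils::write.csv(data.frame(r = dist$r, p = dist$p), file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname write_distribution_csv
#' @param kind,unit passed to [distance_distribution()].
#' @export
read_distribution_csv <- function(file, kind = "FRET", unit = "angstrom") {
  d <- utils::read.csv(file)
  distance_distribution(d[[1]], d[[2]], kind = kind, unit = unit)
}

#' Write / read species correlation curves as CSV
#'
#' Columns: lag_s, g, sd, kind, variant.
#'
#' @param curves list of [corr_curve()]s.
#' @param file path.
#' @export
write_corr_csv <- function(curves, file) {
  d <- do.call(rbind, lapply(curves, function(cv)
    data.frame(lag_s = cv$lag_s, g = cv$g,
               sd = cv$sd %||% NA_real_, kind = cv$kind,
               variant = cv$variant)))
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_corr_csv
#' @export
read_corr_csv <- function(file) {
  d <- utils::read.csv(file)
  out <- list()
  for (key in unique(paste(d$variant, d$kind))) {
    sub <- d[paste(d$variant, d$kind) == key, ]
    out[[key]] <- corr_curve(sub$lag_s, sub$g,
                             sd = if (all(is.na(sub$sd))) NULL else sub$sd,
                             kind = sub$kind[1], variant = sub$variant[1])
  }
  out
}

#' Export fit results as JSON
#'
#' @param results named list (parameters, intervals, chi-squares, ...).
#' @param file path.
#' @export
write_results_json <- function(results, file) {
  jsonlite::write_json(results, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(file)
}
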