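# Readers/writers for the tabular formats the pipeline exchanges:
# Sparky-style assigned peak lists and per-stage CSV/TSV tables. Every
# writer has a matching reader and round-trips finite values at the
# written precision.

assignment_label <- function(residue_name, residue_index, atom_pair) {
  atoms <- strsplit(atom_pair, "-", fixed = TRUE)[[1]]
  paste0(residue_name, residue_index, atoms[1], "-", atoms[2])
}

#' Write a Sparky-style assigned peak list
#'
#' Writes rows of the form `Assignment w1 w2 Height` (e.g.
#' `S26CA-HA  58.10000  4.52000  1.0e+06`), the plain-text peak-list
#' format exchanged with spectral analysis software.
#'
#' @param peaks Peak tibble with columns `residue_index`, `residue_name`,
#'   `atom_pair`, `w1`, `w2`, `intensity`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".list")
#' write_sparky(sim_peak_tables()$reference, f)
#' readLines(f, n = 3)
write_sparky <- function(peaks, path) {
  check_columns(peaks, c("residue_index", "residue_name", "atom_pair",
                         "w1", "w2", "intensity"), "peaks")
  lines <- c(
    sprintf("%-14s %10s %10s %14s", "Assignment", "w1", "w2", "Height"),
    purrr::pmap_chr(
      peaks[c("residue_name", "residue_index", "atom_pair", "w1", "w2",
              "intensity")],
      function(residue_name, residue_index, atom_pair, w1, w2, intensity) {
        sprintf("%-14s %10.5f %10.5f %14.6e",
                assignment_label(residue_name, residue_index, atom_pair),
                w1, w2, intensity)
      }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Sparky-style assigned peak list
#'
#' Parses `Assignment w1 w2 [Height]` rows; assignment strings such as
#' `"S26N-H"` are decomposed into residue name, 1-based residue index and
#' atom pair. Malformed rows are collected into the `"rejects"`
#' attribute (with a warning), never silently dropped; an empty file
#' yields an empty peak table with a warning.
#'
#' @param path Path to the peak list.
#' @return A peak tibble (`residue_index`, `residue_name`, `atom_pair`,
#'   `w1`, `w2`, `intensity`), with malformed lines in
#'   `attr(, "rejects")`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".list")
#' write_sparky(sim_peak_tables()$reference, f)
#' read_sparky(f) |> head(3)
read_sparky <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_header <- grepl("^\\s*Assignment\\b", lines)
  if (length(lines) > 0 && !any(is_header)) {
    abort("Unparseable peak list: no 'Assignment' header line found.")
  }
  body <- lines[!is_header]
  empty <- tibble::tibble(residue_index = integer(),
                          residue_name = character(),
                          atom_pair = character(),
                          w1 = double(), w2 = double(),
                          intensity = double())
  if (length(body) == 0) {
    warn(sprintf("Peak list %s contains no peaks.", path))
    return(structure(empty, rejects = character()))
  }
  pat <- "^([A-Z])(\\d+)([A-Za-z0-9']+)-([A-Za-z0-9']+)$"
  parsed <- purrr::map(body, function(line) {
    fields <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(fields) < 3) return(NULL)
    m <- regmatches(fields[1], regexec(pat, fields[1]))[[1]]
    vals <- suppressWarnings(as.numeric(fields[2:min(4, length(fields))]))
    if (length(m) == 0 || anyNA(vals[1:2])) return(NULL)
    tibble::tibble(
      residue_index = as.integer(m[3]),
      residue_name = m[2],
      atom_pair = paste0(m[4], "-", m[5]),
      w1 = vals[1], w2 = vals[2],
      intensity = if (length(vals) >= 3) vals[3] else NA_real_)
  })
  ok <- !purrr::map_lgl(parsed, is.null)
  rejects <- body[!ok]
  if (length(rejects) > 0) {
    warn(sprintf("%d malformed line(s) in %s (kept in attr 'rejects').",
                 length(rejects), path))
  }
  out <- if (any(ok)) dplyr::bind_rows(parsed[ok]) else empty
  structure(out, rejects = rejects)
}

#' @rdname sensorgram_io
#' @export
write_sensorgrams <- function(data, path) {
  check_columns(data, c("curve_id", "concentration_M", "t0_s", "time_s",
                        "response"), "data")
  readr::write_csv(
    dplyr::select(data, "curve_id", "concentration_M", "t0_s", "time_s",
                  "response"), path)
  invisible(path)
}

#' Read and write sensorgram CSV files
#'
#' CSV with columns `curve_id`, `concentration_M`, `t0_s`, `time_s`,
#' `response` — one row per sampled point, one `curve_id` per injection.
#'
#' @param data Sensorgram tibble (see [sim_sensorgrams()]).
#' @param path File path.
#' @return `read_sensorgrams()` returns the sensorgram tibble;
#'   `write_sensorgrams()` returns `path` invisibly.
#' @name sensorgram_io
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' sg <- sim_sensorgrams(kinetic_params(), concentrations = 1e-6,
#'                       t_grid = seq(0, 600, 50), t0 = 300)
#' write_sensorgrams(sg, f)
#' read_sensorgrams(f)
read_sensorgrams <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    curve_id = readr::col_character(),
    concentration_M = readr::col_double(),
    t0_s = readr::col_double(),
    time_s = readr::col_double(),
    response = readr::col_double()))
}

#' @rdname relaxation_io
#' @export
write_relaxation <- function(data, path) {
  check_columns(data, c("residue_index", "condition", "delay_s",
                        "intensity", "noise_sd"), "data")
  readr::write_csv(data, path)
  invisible(path)
}

#' Read and write inversion-recovery CSV files
#'
#' CSV with columns `residue_index`, `condition`, `delay_s`, `intensity`,
#' `noise_sd` — one row per sampled delay per residue series.
#'
#' @param data Relaxation tibble (see [sim_inversion_recovery()]).
#' @param path File path.
#' @return `read_relaxation()` returns the relaxation tibble;
#'   `write_relaxation()` returns `path` invisibly.
#' @name relaxation_io
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' r1s <- tibble::tibble(residue_index = 1, condition = "undoped", r1 = 0.5)
#' write_relaxation(sim_inversion_recovery(r1s), f)
#' read_relaxation(f) |> head(3)
read_relaxation <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    residue_index = readr::col_integer(),
    condition = readr::col_character(),
    delay_s = readr::col_double(),
    intensity = readr::col_double(),
    noise_sd = readr::col_double()))
}

#' @rdname diameter_io
#' @export
write_diameters <- function(data, path) {
  check_columns(data, c("condition", "diameter_nm"), "data")
  readr::write_csv(data, path)
  invisible(path)
}

#' Read and write fibril-diameter CSV files
#'
#' CSV with columns `condition` and `diameter_nm` (one measured fibril
#' per row). A single-column file of diameters is accepted on read, with
#' the condition taken from the file name.
#'
#' @param data Diameter tibble (see [sim_diameters()]).
#' @param path File path.
#' @return `read_diameters()` returns the diameter tibble;
#'   `write_diameters()` returns `path` invisibly.
#' @name diameter_io
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_diameters(sim_diameters(fibril_diameter_summaries()[1, ]), f)
#' read_diameters(f) |> head(3)
read_diameters <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0,
                               show_col_types = FALSE))
  if ("condition" %in% hdr) {
    readr::read_csv(path, col_types = readr::cols(
      condition = readr::col_character(),
      diameter_nm = readr::col_double()))
  } else {
    vals <- readr::read_csv(path, col_names = "diameter_nm",
                            col_types = "d", skip = as.integer(
                              !grepl("^[0-9.+-]", hdr[1])))
    dplyr::mutate(vals,
                  condition = sub("\\.[^.]*$", "", basename(path)),
                  .before = 1)
  }
}
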