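# Readers and writers shared by all modules: two-column spectra
# (CSV/TSV/whitespace, auto-detected), map matrices as TSV with a JSON
# metadata sidecar, assignment tables, and the structured run configuration.

detect_delimiter <- function(line) {
  if (grepl(",", line)) "," else if (grepl("\t", line)) "\t" else ""
}

#' Read a Raman spectrum from a delimited text file
#'
#' Two columns (wavenumber in cm^-1, intensity), comma-, tab- or
#' whitespace-separated (auto-detected), optional header, `#` comment lines
#' ignored.
#'
#' @param path file path.
#' @return a [raman_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no data lines in ", path)
  body <- lines[keep]
  sep <- detect_delimiter(body[1])
  first <- strsplit(body[1], if (sep == "") "\\s+" else sep)[[1]]
  header <- suppressWarnings(any(is.na(as.numeric(first))))
  tab <- utils::read.table(text = body, sep = sep, header = header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected two columns in ", path)
  shift <- as.numeric(tab[[1]]); intensity <- as.numeric(tab[[2]])
  bad <- which(!is.finite(shift) | !is.finite(intensity))
  if (length(bad) > 0) {
    stop("non-numeric spectral data at data line ", bad[1], " of ", path)
  }
  if (any(diff(shift) <= 0)) {
    stop("non-monotone wavenumber axis in ", path, " (first violation at ",
         "data line ", which(diff(shift) <= 0)[1] + 1, ")")
  }
  raman_spectrum(shift, intensity,
                 label = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a Raman spectrum as CSV
#'
#' Emits `# key: value` metadata comment lines followed by a
#' `wavenumber_cm-1,intensity` table; [read_spectrum()] round-trips it.
#'
#' @param spec a [raman_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "raman_spectrum"))
  meta <- c(
    if (!is.null(spec$label)) sprintf("# label: %s", spec$label),
    if (!is.null(spec$concentration))
      sprintf("# concentration_uM: %g", spec$concentration),
    if (!is.null(spec$seed)) sprintf("# seed: %d", spec$seed))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(meta, "wavenumber_cm-1,intensity"), con)
  writeLines(sprintf("%.10g,%.10g", spec$shift, spec$intensity), con)
  invisible(path)
}

#' Read / write surface maps as TSV plus JSON sidecar
#'
#' Maps are stored as a plain TSV matrix (one row per map row) together with
#' a JSON sidecar `<path>.json` holding `pixel_size_nm`, `unit`, `kind` and
#' any extra metadata.  `read_map()` restores the proper class from the
#' sidecar `kind`.
#'
#' @param map a [height_map()] or [current_map()].
#' @param path TSV path; the sidecar is written next to it.
#' @param extra named list merged into the sidecar (e.g. `seed`, model echo).
#' @return `read_map()`: the map object; `write_map()`: `path`, invisibly.
#' @export
write_map <- function(map, path, extra = list()) {
  stopifnot(inherits(map, "surface_map"))
  kind <- class(map)[1]
  meta <- c(list(kind = kind,
                 pixel_size_nm = attr(map, "pixel_size"),
                 unit = if (kind == "height_map") "nm" else "normalized",
                 origin = "top-left; x = column, y = row",
                 nrow = nrow(map), ncol = ncol(map)),
            extra)
  utils::write.table(unclass(map), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar for map: ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (length(unique(nfield)) != 1) {
    stop("ragged map matrix in ", path, ": row ",
         which(nfield != nfield[1])[1], " has ",
         nfield[which(nfield != nfield[1])[1]], " fields, expected ",
         nfield[1])
  }
  m <- matrix(as.numeric(unlist(parts)), nrow = length(parts), byrow = TRUE)
  if (any(!is.finite(m))) stop("non-numeric map values in ", path)
  ctor <- if (identical(meta$kind, "current_map")) current_map else height_map
  ctor(m, meta$pixel_size_nm)
}

#' Read a band-assignment table from CSV
#'
#' Expects columns `low`, `high` (cm^-1) and `assignment`; windows must be
#' sorted and non-overlapping.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_assignment_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_assignment_table(tab)
}

#' Default run configuration
#'
#' Nested list of every tunable of the toolkit with its default value:
#' optics (785 nm silver on polycarbonate), geometry (L = 400 nm, h = 80 nm,
#' d = 15 nm), spectra (quiet windows, 1589 cm^-1 band, S/N = 3 criterion),
#' correlate thresholds and simulate defaults.  A fully defaulted
#' configuration reproduces the packaged worked example.
#'
#' @return named nested list.
#' @export
default_config <- function() {
  list(
    optics = list(wavelength_nm = 785,
                  epsilon_metal = list(re = -29.8, im = 0.38),
                  eps_front = 1, eps_substrate = 2.5),
    geometry = list(L_nm = 400, h_nm = 80, d_nm = 15),
    spectra = list(quiet_windows = list(c(600, 650), c(1650, 1700)),
                   band_center = 1589, band_half_width = 15,
                   band_method = "height", lod_criterion = 3,
                   baseline_lambda = 1e8),
    correlate = list(drop_fraction = 0.9, min_bump_height = 25,
                     size_gate = c(30, 150), match_radius = 200),
    simulate = list(seed = 1,
                    concentrations = c(50, 5, 0.5, 0.05), sn_slope = 15,
                    noise_sigma = 5,
                    npix = 1024, pixel_size = 10,
                    n_exosomes = 5, n_defects = 3, n_imperfections = 3,
                    roughness_rms = 4),
    io = list(format = "csv")
  )
}

#' Read / write the run configuration (YAML)
#'
#' @param path YAML file path.
#' @param config configuration list; missing fields are filled from
#'   [default_config()].
#' @return `read_config()`: completed configuration list; `write_config()`:
#'   `path`, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
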