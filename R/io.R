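# Readers and writers for the plain-text formats the pipeline exchanges:
# two-column angle scans (CSV/TSV, '#' comments), layer-stack configurations
# (YAML or JSON), density-profile tables, and the end-to-end pipeline driver.

.read_table_checked <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "sprgamma_format_error")
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, comment.char = "#", sep = sep, strip.white = TRUE)
}

#' Read an angle scan from delimited text
#'
#' Expects a header row with columns `angle_deg` and `reflectivity`
#' (comma- or tab-separated by extension); lines starting with `#` are
#' comments. Malformed rows are reported with their line numbers.
#'
#' @param path Path to a CSV/TSV file.
#' @param sample Sample label attached to the scan (defaults to the file
#'   name).
#' @return An [angle_scan()].
#' @export
read_angle_scan <- function(path, sample = basename(path)) {
  df <- .read_table_checked(path)
  if (!all(c("angle_deg", "reflectivity") %in% names(df))) {
    abort(paste0("Missing required columns `angle_deg`, `reflectivity` in ",
                 path), class = "sprgamma_format_error")
  }
  bad <- which(!is.finite(df$angle_deg) | !is.finite(df$reflectivity))
  if (length(bad)) {
    abort(paste0("Non-numeric scan values at data row(s) ",
                 paste(head(bad, 5), collapse = ", "), " of ", path),
          class = "sprgamma_format_error")
  }
  non_mono <- which(diff(df$angle_deg) <= 0)
  if (length(non_mono)) {
    abort(paste0("Angles not strictly increasing at data row ",
                 non_mono[1] + 1, " of ", path),
          class = "sprgamma_format_error")
  }
  out_of_range <- which(df$reflectivity < -0.05 | df$reflectivity > 1.05)
  if (length(out_of_range)) {
    abort(paste0("Reflectivity outside [-0.05, 1.05] at data row ",
                 out_of_range[1], " of ", path),
          class = "sprgamma_format_error")
  }
  angle_scan(df$angle_deg, df$reflectivity, sample = sample,
             source = "measured")
}

#' Write an angle scan to delimited text
#'
#' @param scan An [angle_scan()].
#' @param path Output path (.csv or .tsv).
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_angle_scan <- function(scan, path, digits = 10) {
  stopifnot(inherits(scan, "angle_scan"))
  meta <- scan_metadata(scan)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  hdr <- c(
    paste0("# sample: ", meta$sample),
    paste0("# source: ", meta$source),
    if (!is.null(meta$seed)) paste0("# seed: ", meta$seed),
    paste0("# written_by: sprgamma ", as.character(packageVersion("sprgamma"))))
  body <- paste(format(scan$angle_deg, digits = digits, trim = TRUE),
                format(scan$reflectivity, digits = digits, trim = TRUE),
                sep = sep)
  writeLines(c(hdr, paste("angle_deg", "reflectivity", sep = sep), body),
             path)
  invisible(path)
}

#' Read a layer-stack configuration (YAML or JSON)
#'
#' The document must contain `wavelength_nm` and a `layers` list; each layer
#' has `label`, `eps_re`, optional `eps_im` (default 0), optional
#' `thickness_nm` (absent for the two terminal half-spaces) and optional
#' `interfacial` flag.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [layer_stack()].
#' @export
read_layer_stack <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "sprgamma_format_error")
  }
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$layers) || length(doc$layers) < 2) {
    abort("Stack configuration needs a `layers` list with >= 2 entries.",
          class = "sprgamma_config_error")
  }
  layers <- bind_rows(map(doc$layers, function(l) {
    tibble(label = l$label,
           eps = complex(real = l$eps_re, imaginary = l$eps_im %||% 0),
           thickness_nm = l$thickness_nm %||% NA_real_,
           interfacial = isTRUE(l$interfacial))
  }))
  layer_stack(layers, wavelength_nm = doc$wavelength_nm %||% 632.8)
}

#' Write a layer-stack configuration
#' @param stack A [layer_stack()].
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_layer_stack <- function(stack, path) {
  stopifnot(inherits(stack, "layer_stack"))
  doc <- list(
    wavelength_nm = attr(stack, "wavelength_nm"),
    layers = map(seq_len(nrow(stack)), function(i) {
      l <- list(label = stack$label[i], eps_re = Re(stack$eps[i]),
                eps_im = Im(stack$eps[i]))
      if (is.finite(stack$thickness_nm[i])) {
        l$thickness_nm <- stack$thickness_nm[i]
      }
      if (stack$interfacial[i]) l$interfacial <- TRUE
      l
    }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path, precision = 15)
  }
  invisible(path)
}

#' Read a density-profile table
#'
#' Plain-text format: `#` comment header that may carry `area_nm2`,
#' `bin_width_nm` and `frames` as `# key: value` lines, then columns `z_nm`,
#' `rho_solute`, `rho_solvent`.
#'
#' @param path Path to the profile file.
#' @return A [density_profile()].
#' @export
read_density_profile <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "sprgamma_format_error")
  }
  lines <- readLines(path)
  meta_lines <- grep("^#\\s*\\w+\\s*:", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- suppressWarnings(as.numeric(trimws(sub("^[^:]*:", "", kv))))
    meta[[key]] <- val
  }
  df <- .read_table_checked(path)
  if (!all(c("z_nm", "rho_solute", "rho_solvent") %in% names(df))) {
    abort("Profile file needs columns z_nm, rho_solute, rho_solvent.",
          class = "sprgamma_format_error")
  }
  bw <- meta$bin_width_nm %||% stats::median(diff(sort(df$z_nm)))
  density_profile(
    bind_rows(
      tibble(z_nm = df$z_nm, species = "solute",
             density_g_cm3 = df$rho_solute),
      tibble(z_nm = df$z_nm, species = "solvent",
             density_g_cm3 = df$rho_solvent)),
    bin_width_nm = bw,
    area_nm2 = meta$area_nm2 %||% NA_real_,
    frames = as.integer(meta$frames %||% 1))
}

#' Write a density-profile table
#' @param profile A [density_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_profile <- function(profile, path) {
  stopifnot(inherits(profile, "density_profile"))
  solute <- .species_profile(profile, "solute")
  solvent <- .species_profile(profile, "solvent")
  hdr <- c(paste0("# bin_width_nm: ", attr(profile, "bin_width_nm")),
           paste0("# area_nm2: ", attr(profile, "area_nm2")),
           paste0("# frames: ", attr(profile, "frames")))
  body <- paste(format(solute$z_nm, trim = TRUE),
                format(solute$density_g_cm3, digits = 10, trim = TRUE),
                format(solvent$density_g_cm3, digits = 10, trim = TRUE),
                sep = ",")
  writeLines(c(hdr, "z_nm,rho_solute,rho_solvent", body), path)
  invisible(path)
}

#' Read a LAMMPS-style chunk-averaged profile
#'
#' Parses the `fix ave/chunk` text format (three `#` header lines, then
#' per-block `timestep n_chunks` lines followed by chunk rows) and maps the
#' requested columns to the package's profile container. Column indices are
#' given explicitly because chunk files carry arbitrary compute columns.
#'
#' @param path Path to the chunk-averaged file.
#' @param col_z 1-based column index of the chunk coordinate (nm).
#' @param col_solute,col_solvent Column indices of the solute and solvent
#'   mass densities (g/cm^3).
#' @param area_nm2 Cross-sectional area in nm^2.
#' @return A [density_profile()] averaged over all blocks in the file.
#' @export
read_chunk_profile <- function(path, col_z = 2, col_solute = 4,
                               col_solvent = 5, area_nm2 = NA_real_) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "sprgamma_format_error")
  }
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  rows <- toks[lengths(toks) >= max(col_z, col_solute, col_solvent)]
  if (length(rows) == 0) {
    abort("No chunk rows found.", class = "sprgamma_format_error")
  }
  m <- do.call(rbind, lapply(rows, function(t) as.numeric(t)))
  df <- tibble(z_nm = m[, col_z], solute = m[, col_solute],
               solvent = m[, col_solvent])
  agg <- df |>
    group_by(.data$z_nm) |>
    summarise(solute = mean(.data$solute), solvent = mean(.data$solvent),
              n = dplyr::n(), .groups = "drop")
  bw <- stats::median(diff(sort(unique(agg$z_nm))))
  density_profile(
    bind_rows(tibble(z_nm = agg$z_nm, species = "solute",
                     density_g_cm3 = agg$solute),
              tibble(z_nm = agg$z_nm, species = "solvent",
                     density_g_cm3 = agg$solvent)),
    bin_width_nm = bw, area_nm2 = area_nm2,
    frames = as.integer(max(agg$n)))
}

#' Run the full SPR inversion pipeline
#'
#' Calibrate, extract features, invert, and convert to an excess interfacial
#' mass density, mirroring the index-matching measurement protocol: the
#' reference (index-matched solvent) scan fixes the effective prism
#' permittivity and the bulk permittivity; the sample scan is then inverted
#' for the interfacial permittivity at the assumed thickness, and the
#' permittivity pair is pushed through the Clausius-Mossotti/density chain.
#' If no reference scan is given, the bulk permittivity is taken from the
#' sample scan's own TIR edge and the report flags the fallback.
#'
#' @param config Named list (or path to a YAML/JSON file with the same
#'   fields): `sample_scan` (path or [angle_scan()]), optional
#'   `reference_scan`, `stack` (path or [layer_stack()]; defaults to the
#'   calibrated default chip), `eps_bulk_reference` (literature permittivity
#'   of the reference liquid, default ethanol 1.8507), `t_nm` (default 1),
#'   `tir_window`, `spr_window`, `mode` (`"feature"` or `"curve"`).
#' @return One-row tibble report with the extracted angles, permittivities,
#'   interfacial composition and Gamma; provenance (config hash, package
#'   version) is carried in attributes.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg_hash <- rlang::hash(config)
  get_scan <- function(x, what) {
    if (inherits(x, "angle_scan")) return(x)
    if (is.character(x)) return(read_angle_scan(x))
    abort(paste0("Invalid ", what, " in config."),
          class = "sprgamma_config_error")
  }
  sample_scan <- get_scan(config$sample_scan, "sample_scan")
  stack <- config$stack %||% make_chip(seed = 0L, surface = "gold")
  if (is.character(stack)) stack <- read_layer_stack(stack)
  t_nm <- config$t_nm %||% 1.0
  tir_window <- config$tir_window %||% c(48, 52)
  spr_window <- config$spr_window %||% c(60, 66)
  mode <- config$mode %||% "feature"
  eps_ref <- config$eps_bulk_reference %||% 1.8507

  if (!is.null(config$reference_scan)) {
    reference_scan <- get_scan(config$reference_scan, "reference_scan")
    eps_prism <- calibrate_prism(reference_scan, eps_ref,
                                 tir_window = tir_window)
    eps_bulk <- fit_bulk_eps(reference_scan, eps_prism,
                             tir_window = tir_window)
    bulk_source <- "index_matched_reference"
  } else {
    eps_prism <- if (!is.null(config$eps_prism)) config$eps_prism else
      chip_constants()$eps_prism
    eps_bulk <- fit_bulk_eps(sample_scan, eps_prism, tir_window = tir_window)
    bulk_source <- "sample_scan_tir"
  }
  feats <- scan_features(sample_scan, tir_window = tir_window,
                         spr_window = spr_window)
  fit <- fit_interfacial_eps(sample_scan, stack, eps_bulk, t_nm = t_nm,
                             mode = mode, spr_window = spr_window)
  if (!fit$converged) {
    abort("Interfacial fit did not converge.",
          class = "sprgamma_nonconvergence_error")
  }
  gx <- gamma_excess(fit$eps_interf, eps_bulk, t_nm = t_nm)
  report <- tibble(
    sample = scan_metadata(sample_scan)$sample,
    theta_tir = feats$theta_tir, theta_spr = feats$theta_spr,
    eps_prism = eps_prism, eps_bulk = eps_bulk,
    eps_interf = fit$eps_interf, t_nm = t_nm,
    x_interf = gx$x_interf, gamma_ng_cm2 = gx$gamma_ng_cm2,
    excess_molecules_per_nm3 = gx$excess_molecules_per_nm3,
    residual = fit$residual, bulk_source = bulk_source)
  attr(report, "provenance") <- list(
    config_hash = cfg_hash,
    package_version = as.character(packageVersion("sprgamma")))
  report
}

#' Write a pipeline report to JSON
#' @param report Report tibble from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- c(as.list(report), list(provenance = attr(report, "provenance")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
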