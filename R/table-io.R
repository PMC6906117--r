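# Delimited-text readers/writers for ITC tables, nonbonded parameter tables
# and flat key/value config files.
#
# ITC table dialect: comma-delimited; header lines "# key = value" declare
# cell_volume_ul, temperature_K, cell_conc_M, syringe_conc_M,
# pre_injection_ul; then columns injection_index, volume_ul, heat_uJ
# [, control_heat_uJ].

#' Read an ITC table
#'
#' @param path path to a comma-delimited ITC table (see Details).
#' @return a [thermogram()].
#' @details Header lines of the form `# key = value` must declare
#'   `cell_volume_ul`, `temperature_K`, `cell_conc_M`, `syringe_conc_M` and
#'   `pre_injection_ul`. The body has columns `injection_index`,
#'   `volume_ul`, `heat_uJ` and optionally `control_heat_uJ`.
#' @export
read_itc_table <- function(path) {
  if (!file.exists(path))
    stop_cavitherm(paste("no such file:", path), "cavitherm_io_error")
  lines <- readLines(path, warn = FALSE)
  if (!length(lines))
    stop_cavitherm("empty ITC table", "cavitherm_empty_input_error")
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_,
                 "")
  vals <- suppressWarnings(as.numeric(
    vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_, "")))
  header <- setNames(vals, keys)
  need <- c("cell_volume_ul", "temperature_K", "cell_conc_M",
            "syringe_conc_M", "pre_injection_ul")
  missing_keys <- setdiff(need, names(header))
  if (length(missing_keys))
    stop_cavitherm(paste("ITC table missing header keys:",
                         paste(missing_keys, collapse = ", ")),
                   "cavitherm_config_error")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
  if (!all(c("injection_index", "volume_ul", "heat_uJ") %in% names(df)))
    stop_cavitherm("ITC table needs columns injection_index, volume_ul, heat_uJ",
                   "cavitherm_format_error")
  if (any(df$volume_ul <= 0))
    stop_cavitherm("injection volumes must be positive",
                   "cavitherm_validation_error")
  df <- df[order(df$injection_index), , drop = FALSE]
  thermogram(cell_volume_ul = header[["cell_volume_ul"]],
             temperature_K = header[["temperature_K"]],
             cell_conc_M = header[["cell_conc_M"]],
             syringe_conc_M = header[["syringe_conc_M"]],
             injection_volumes_ul = df$volume_ul,
             heats_uJ = df$heat_uJ,
             control_heats_uJ = if ("control_heat_uJ" %in% names(df))
               df$control_heat_uJ else NULL,
             pre_injection_ul = header[["pre_injection_ul"]])
}

#' Write a thermogram as an ITC table
#'
#' @param tg a [thermogram()] with heats.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_itc_table <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  if (is.null(tg$heats_uJ))
    stop_cavitherm("thermogram has no heats to write",
                   "cavitherm_validation_error")
  hdr <- sprintf("# %s = %.17g",
                 c("cell_volume_ul", "temperature_K", "cell_conc_M",
                   "syringe_conc_M", "pre_injection_ul"),
                 c(tg$cell_volume_ul, tg$temperature_K, tg$cell_conc_M,
                   tg$syringe_conc_M, tg$pre_injection_ul))
  df <- data.frame(injection_index = seq_along(tg$injection_volumes_ul),
                   volume_ul = tg$injection_volumes_ul,
                   heat_uJ = tg$heats_uJ)
  if (!is.null(tg$control_heats_uJ)) df$control_heat_uJ <- tg$control_heats_uJ
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a nonbonded parameter table
#'
#' Comma-delimited with columns `residue_name`, `atom_name`, `charge_e`,
#' `sigma_A`, `epsilon_kJmol`; optional `# key = value` header lines may set
#' `coulomb_constant` and `cutoff_A`.
#'
#' @param path path to the table.
#' @param cutoff_A interaction cutoff (overridden by a header line if present).
#' @return a [nonbonded_params()].
#' @export
read_params_table <- function(path, cutoff_A = 10) {
  if (!file.exists(path))
    stop_cavitherm(paste("no such file:", path), "cavitherm_io_error")
  lines <- readLines(path, warn = FALSE)
  if (!length(lines))
    stop_cavitherm("empty params table", "cavitherm_empty_input_error")
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", hdr))
  coul <- .COULOMB_KJ_A_E2
  for (m in kv) {
    if (length(m) == 3 && m[2] == "coulomb_constant") coul <- as.numeric(m[3])
    if (length(m) == 3 && m[2] == "cutoff_A") cutoff_A <- as.numeric(m[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
  req <- c("residue_name", "atom_name", "charge_e", "sigma_A", "epsilon_kJmol")
  if (!all(req %in% names(df)))
    stop_cavitherm(paste("params table needs columns:",
                         paste(req, collapse = ", ")),
                   "cavitherm_format_error")
  nonbonded_params(data.frame(resname = df$residue_name, name = df$atom_name,
                              charge_e = df$charge_e, sigma_A = df$sigma_A,
                              epsilon_kJmol = df$epsilon_kJmol),
                   coulomb_constant = coul, cutoff_A = cutoff_A)
}

#' Write a nonbonded parameter table
#' @param params a [nonbonded_params()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params_table <- function(params, path) {
  stopifnot(inherits(params, "nonbonded_params"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coulomb_constant = %.17g", params$coulomb_constant), con)
  writeLines(sprintf("# cutoff_A = %.17g", params$cutoff_A), con)
  df <- data.frame(residue_name = params$table$resname,
                   atom_name = params$table$name,
                   charge_e = params$table$charge_e,
                   sigma_A = params$table$sigma_A,
                   epsilon_kJmol = params$table$epsilon_kJmol)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key/value config file into a pipeline configuration
#'
#' Lines `key = value`; comma-separated values become vectors; `true`/`false`
#' become logicals; numeric-looking values become numbers. Keys are those of
#' [pipeline_config()].
#'
#' @param path path to the config file.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_cavitherm(paste("no such file:", path), "cavitherm_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3) next
    val <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!anyNA(num)) num
      else if (all(tolower(val) %in% c("true", "false"))) tolower(val) == "true"
      else val
    out[[m[2]]] <- parsed
  }
  do.call(pipeline_config, out)
}
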