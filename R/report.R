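# End-to-end orchestration: run the requested stages (ITC fitting and
# comparison; hydration census, bulk reference and desolvation; contact
# chemistry) and render the summary tables. Deterministic given the config
# and its seed; every report embeds a provenance block (config hash, seed).

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages and assembles a `pipeline_report`. Stages
#' are independent: an ITC-only or hydration-only run is valid and simply
#' omits the other section.
#'
#' The ITC stage accepts per-ligand entries that are either paths to ITC
#' tables (`file`) or synthetic specifications (`truth` = list with `n`,
#' `Kd_M`, `dH_kJmol`, plus `cell_conc_M`, `syringe_conc_M`, optional
#' `noise_sd_uJ`, `dilution_heat_uJ`); each entry needs a `ligand` name.
#' The first entry is the comparison reference. The hydration stage accepts
#' state entries (`label`, plus either `system` = a pocket_system or the
#' generator arguments `n_cavity_waters`, `n_bulk_waters`, `ligand`,
#' `n_frames`); the first entry is the ligand-free reference state.
#'
#' @param config a [pipeline_config()].
#' @param itc optional list of ITC entries (see Details).
#' @param hydration optional list of hydration state entries.
#' @param contacts optional list with `model` (a [structure_model()] or PDB
#'   path) and `ligand_resname`.
#' @return object of class `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), itc = NULL,
                         hydration = NULL, contacts = NULL) {
  report <- list(provenance = list(config_hash = .config_hash(config),
                                   seed = config$seed,
                                   package_version =
                                     as.character(utils::packageVersion("cavitherm")),
                                   units = list(energy = "kJ/mol",
                                                entropy = "J/mol/K",
                                                distance = "Angstrom",
                                                heat = "uJ", Kd = "mol/l")))

  if (!is.null(itc)) {
    fits <- vector("list", length(itc))
    for (i in seq_along(itc)) {
      entry <- itc[[i]]
      tg <- if (!is.null(entry$file)) read_itc_table(entry$file) else {
        tr <- entry$truth
        proto <- default_protocol(cell_conc_M = entry$cell_conc_M,
                                  syringe_conc_M = entry$syringe_conc_M)
        generate_isotherm(binding_params(tr$n, 1 / tr$Kd_M, tr$dH_kJmol),
                          proto,
                          noise_sd_uJ = entry$noise_sd_uJ %||% 0,
                          dilution_heat_uJ = entry$dilution_heat_uJ %||% 0,
                          seed = config$seed + i)
      }
      fits[[i]] <- fit_single_site(
        tg,
        fix_n = if (isTRUE(config$fix_n)) config$fix_n_value else NULL,
        drop_first_injection = config$drop_first_injection,
        ligand = entry$ligand %||% sprintf("ligand_%d", i))
    }
    thermo <- do.call(rbind, lapply(fits, function(f) data.frame(
      ligand = f$ligand, Kd_M = f$Kd_M, n = f$n, dH_kJmol = f$dH_kJmol,
      dG_kJmol = f$dG_kJmol, dS_JmolK = f$dS_JmolK,
      dS_consistent = f$dS_consistent)))
    report$itc <- list(fits = fits, table = thermo,
                       comparison = if (length(fits) > 1L)
                         compare_ligands(fits[[1L]], fits[-1L]) else NULL)
  }

  if (!is.null(hydration)) {
    summaries <- vector("list", length(hydration))
    bulk <- NA_real_
    for (i in seq_along(hydration)) {
      entry <- hydration[[i]]
      sys <- entry$system %||% generate_pocket_system(
        n_cavity_waters = entry$n_cavity_waters,
        n_bulk_waters = entry$n_bulk_waters %||% 0,
        ligand = entry$ligand, n_frames = entry$n_frames %||% 1L,
        seed = config$seed + 100L + i)
      summaries[[i]] <- hydration_summary(sys$trajectory, sys$cavity,
                                          sys$params,
                                          state_label = entry$label %||%
                                            sprintf("state_%d", i))
      if (is.na(bulk) && length(sys$labels$bulk_resnos))
        bulk <- tryCatch(bulk_reference_energy(sys$trajectory, sys$params,
                                               config$bulk_distance_A),
                         error = function(e) NA_real_)
    }
    apo <- summaries[[1L]]
    hyd_tab <- do.call(rbind, lapply(summaries, function(s) {
      D <- desolvation_score(apo, s)
      data.frame(state = s$state, N_bar = s$N_bar,
                 E_bar_kJmol = s$E_bar_kJmol, D_kJmol = D$D_kJmol)
    }))
    report$hydration <- list(summaries = summaries, table = hyd_tab,
                             bulk_E_kJmol = bulk)
  }

  if (!is.null(contacts)) {
    model <- contacts$model
    if (is.character(model)) model <- read_pdb(model, config)[[1L]]
    crit <- hbond_criteria(distance_A = config$hbond_distance_A,
                           angle_deg = config$hbond_angle_deg)
    report$contacts <- list(
      hbonds = find_hbonds(model, contacts$ligand_resname, crit),
      vdw = find_vdw_contacts(model, contacts$ligand_resname,
                              cutoff_A = config$vdw_cutoff_A,
                              hbond_criteria = crit))
  }
  class(report) <- "pipeline_report"
  report
}

.round_sig <- function(x, digits) signif(x, digits)

#' Render a pipeline report
#'
#' JSON output is lossless (full precision); TSV and markdown round to
#' reporting precision (dissociation constants to 2 significant figures,
#' energies and entropies to 1 decimal).
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param format `"json"`, `"tsv"` or `"markdown"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, format = c("json", "tsv", "markdown"),
                          path) {
  format <- match.arg(format)
  stopifnot(inherits(report, "pipeline_report"))
  if (format == "json") {
    out <- list(provenance = report$provenance)
    if (!is.null(report$itc))
      out$itc <- list(table = report$itc$table,
                      comparison = if (!is.null(report$itc$comparison))
                        list(reference = report$itc$comparison$reference,
                             table = report$itc$comparison$table,
                             mean_ddS_JmolK =
                               report$itc$comparison$mean_ddS_JmolK))
    if (!is.null(report$hydration))
      out$hydration <- list(table = report$hydration$table,
                            bulk_E_kJmol = report$hydration$bulk_E_kJmol)
    if (!is.null(report$contacts))
      out$contacts <- list(hbonds = as.data.frame(report$contacts$hbonds),
                           vdw = as.data.frame(report$contacts$vdw))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(path))
  }
  fmt_thermo <- function(tab) data.frame(
    ligand = tab$ligand, Kd_M = .round_sig(tab$Kd_M, 2),
    n = round(tab$n, 2), dH_kJmol = round(tab$dH_kJmol, 1),
    dG_kJmol = round(tab$dG_kJmol, 1), dS_JmolK = round(tab$dS_JmolK, 1))
  fmt_hyd <- function(tab) data.frame(
    state = tab$state, N_bar = round(tab$N_bar, 1),
    E_bar_kJmol = round(tab$E_bar_kJmol, 1),
    D_kJmol = round(tab$D_kJmol, 1))
  lines <- c(sprintf("# config_hash: %s", report$provenance$config_hash),
             sprintf("# seed: %s", report$provenance$seed))
  emit <- function(df, title) {
    cells <- lapply(df, function(col)
      if (is.numeric(col)) vapply(col, function(v)
        base::format(v, trim = TRUE, scientific = NA), "")
      else as.character(col))
    rows <- if (nrow(df)) do.call(mapply, c(list(FUN = function(...)
      paste(..., sep = "\t")), cells)) else character(0)
    if (format == "tsv") {
      c(sprintf("# %s", title), paste(names(df), collapse = "\t"), rows, "")
    } else {
      hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
      sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
      c(sprintf("## %s", title), "",
        hdr, sep, gsub("\t", " | ", paste0("| ", rows, " |")), "")
    }
  }
  if (!is.null(report$itc)) {
    lines <- c(lines, emit(fmt_thermo(report$itc$table), "thermodynamics"))
    if (!is.null(report$itc$comparison)) {
      ct <- report$itc$comparison$table
      lines <- c(lines, emit(data.frame(
        ligand = ct$ligand, ddH_kJmol = round(ct$ddH_kJmol, 1),
        ddS_JmolK = round(ct$ddS_JmolK, 1)),
        sprintf("comparison vs %s (mean ddS = %.1f J/mol/K)",
                report$itc$comparison$reference,
                report$itc$comparison$mean_ddS_JmolK)))
    }
  }
  if (!is.null(report$hydration))
    lines <- c(lines, emit(fmt_hyd(report$hydration$table),
                           sprintf("hydration (bulk E = %.1f kJ/mol)",
                                   report$hydration$bulk_E_kJmol)))
  if (!is.null(report$contacts)) {
    hb <- as.data.frame(report$contacts$hbonds)
    hb$distance_A <- round(hb$distance_A, 2)
    lines <- c(lines, emit(hb, "hydrogen bonds"))
  }
  writeLines(lines, path)
  invisible(path)
}
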