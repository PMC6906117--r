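# PDB reading/writing. Parsing and fixed-column formatting are delegated to
# bio3d; this layer adds multi-model framing, altloc policy, element
# inference and record-kind classification.

# Element symbol from atom-name leading characters, for files whose element
# column (77-78) is empty. Two-letter symbols are only inferred when the
# name starts in column 13 style with an unambiguous prefix.
.ELEMENT_FROM_NAME <- c(CL = "Cl", BR = "Br", FE = "Fe", ZN = "Zn",
                        MG = "Mg", NA. = "Na", MN = "Mn", CU = "Cu",
                        SE = "Se", IOD = "I")

infer_element <- function(name, resname) {
  name <- toupper(trimws(name))
  # monoatomic ion residues first (their names equal the residue)
  two <- substr(name, 1L, 2L)
  if (name %in% c("NA", "CL", "MG", "ZN", "FE", "MN", "CU", "BR", "K") &&
      toupper(resname) == name) {
    return(paste0(substr(name, 1, 1), tolower(substr(name, 2, 2))))
  }
  stripped <- gsub("[0-9']", "", name)
  first <- substr(stripped, 1L, 1L)
  if (first %in% c("C", "N", "O", "S", "P", "H", "F", "I", "K", "B"))
    return(first)
  if (two %in% names(.ELEMENT_FROM_NAME)) return(.ELEMENT_FROM_NAME[[two]])
  if (nzchar(first)) first else "X"
}

classify_kind <- function(resname, config) {
  resname <- toupper(trimws(resname))
  protein_names <- c(.AA3, toupper(config$protein_resnames %||% character(0)))
  ifelse(resname %in% toupper(config$water_resnames), "water",
  ifelse(resname %in% toupper(config$ligand_resnames), "ligand",
  ifelse(resname %in% toupper(config$ion_resnames), "ion",
  ifelse(resname %in% protein_names, "protein", "other"))))
}

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

#' Read a PDB file into structure models
#'
#' Reads a single-model or multi-MODEL PDB file. Each MODEL block becomes
#' one [structure_model()]; a file without MODEL records yields one model.
#' Alternate locations other than blank/'A' are dropped (single-conformer
#' policy); elements missing from columns 77-78 are inferred from atom
#' names; every atom is classified as protein, ligand, water, ion or other
#' from its residue name via the configured name sets.
#'
#' @param path path to a PDB file.
#' @param config a [pipeline_config()] (water/ligand/ion residue name sets).
#' @return list of [structure_model()] objects, one per model.
#' @export
read_pdb <- function(path, config = pipeline_config()) {
  if (!file.exists(path))
    stop_cavitherm(paste("no such file:", path), "cavitherm_io_error")
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  coord_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(coord_lines))
    stop_cavitherm(paste("no ATOM/HETATM records in", path),
                   "cavitherm_empty_input_error")
  bad <- coord_lines[is.na(suppressWarnings(
    as.numeric(substr(lines[coord_lines], 31, 38))))]
  if (length(bad))
    stop_cavitherm(sprintf("unparseable coordinate field at line %d of %s",
                           bad[1L], path), "cavitherm_format_error")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nmod <- nrow(pdb$xyz)
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  elem <- at$elesy
  no_elem <- is.na(elem) | !nzchar(trimws(elem))
  if (any(no_elem))
    elem[no_elem] <- mapply(infer_element, at$elety[no_elem],
                            at$resid[no_elem])
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = trimws(elem),
    resname = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain), "", at$chain),
    x = 0, y = 0, z = 0,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    kind = classify_kind(at$resid, config),
    stringsAsFactors = FALSE)
  models <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    a <- atoms
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    models[[m]] <- structure_model(a[keep, , drop = FALSE], model_id = m)
  }
  models
}

#' Write structure models to a PDB file
#'
#' Writes standard fixed-column PDB; multiple models are wrapped in
#' MODEL/ENDMDL blocks. Coordinates are written to 3 decimals (the PDB
#' column precision). Water, ligand, ion and other atoms are emitted as
#' HETATM, protein as ATOM.
#'
#' @param models a [structure_model()], a list of them, or a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(models, path) {
  if (inherits(models, "trajectory")) models <- models$frames
  if (inherits(models, "structure_model")) models <- list(models)
  if (!length(models))
    stop_cavitherm("no models to write", "cavitherm_empty_input_error")
  fmt_one <- function(m) {
    a <- m$atoms
    if (any(abs(c(a$x, a$y, a$z)) >= 10000))
      stop_cavitherm("coordinate magnitude exceeds PDB column width",
                     "cavitherm_overflow_error")
    rectype <- ifelse(a$kind == "protein", "ATOM  ", "HETATM")
    # atom-name column convention: 1-3 char names start in column 14
    nm <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name),
                 sprintf("%-4s", a$name))
    sprintf("%s%5d %s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rectype, a$serial %% 100000L, nm,
            ifelse(nzchar(a$altloc), a$altloc, " "),
            a$resname, ifelse(nzchar(a$chain), a$chain, " "),
            a$resno %% 10000L, a$x, a$y, a$z, a$occupancy, a$b,
            substr(a$element, 1, 2))
  }
  out <- character(0)
  multi <- length(models) > 1L
  for (i in seq_along(models)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", i))
    out <- c(out, fmt_one(models[[i]]))
    if (multi) out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
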