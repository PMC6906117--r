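# Protein-ligand contact chemistry: hydrogen bonds (heavy-atom distance
# criterion by default, optional D-H...A angle when hydrogens are present)
# and van der Waals contacts.

# donor/acceptor typing for heavy atoms of standard residues; backbone N is
# a donor, backbone O (and OXT) an acceptor
.SIDECHAIN_DA <- list(
  SER = c(OG = "both"), THR = c(OG1 = "both"), TYR = c(OH = "both"),
  CYS = c(SG = "both"), ASN = c(OD1 = "acceptor", ND2 = "donor"),
  GLN = c(OE1 = "acceptor", NE2 = "donor"),
  ASP = c(OD1 = "acceptor", OD2 = "acceptor"),
  GLU = c(OE1 = "acceptor", OE2 = "acceptor"),
  LYS = c(NZ = "donor"),
  ARG = c(NE = "donor", NH1 = "donor", NH2 = "donor"),
  HIS = c(ND1 = "both", NE2 = "both"), TRP = c(NE1 = "donor"),
  MET = c(SD = "acceptor"))

# typing for one atom: "donor", "acceptor", "both" or NA
.da_type <- function(name, resname, element, kind) {
  element <- toupper(element)
  if (kind == "water") {
    if (element == "O") return("both")
    return(NA_character_)
  }
  if (kind == "protein") {
    if (name == "N") return("donor")
    if (name %in% c("O", "OXT")) return("acceptor")
    sc <- .SIDECHAIN_DA[[resname]]
    if (!is.null(sc) && name %in% names(sc)) return(sc[[name]])
    return(NA_character_)
  }
  # ligands (and other heteroatoms): sulfonate/phosphonate/carbonyl O and
  # ring O accept; amine/amide N donates; S accepts weakly
  if (element == "O") return("acceptor")
  if (element == "N") return("donor")
  if (element == "S") return("acceptor")
  NA_character_
}

#' Hydrogen-bond criteria
#'
#' @param distance_A maximum donor-acceptor heavy-atom distance (default 3.5).
#' @param angle_deg minimum D-H...A angle in degrees (default 120).
#' @param hydrogen_free if TRUE (default), use the distance-only criterion
#'   appropriate for crystal structures without hydrogens; if FALSE, the
#'   angle criterion is additionally enforced using explicit hydrogens.
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(distance_A = 3.5, angle_deg = 120,
                           hydrogen_free = TRUE) {
  if (distance_A <= 0)
    stop_cavitherm("distance must be positive", "cavitherm_validation_error")
  if (angle_deg <= 0 || angle_deg > 180)
    stop_cavitherm("angle must be in (0, 180]", "cavitherm_validation_error")
  structure(list(distance_A = distance_A, angle_deg = angle_deg,
                 hydrogen_free = hydrogen_free), class = "hbond_criteria")
}

.select_ligand <- function(model, ligand_resname) {
  sel <- model$atoms$resname %in% ligand_resname
  if (!any(sel))
    stop_cavitherm(paste("ligand selector matched no atoms:",
                         paste(ligand_resname, collapse = ",")),
                   "cavitherm_selection_error")
  sel
}

#' Find protein-ligand hydrogen bonds
#'
#' In hydrogen-free mode (the default, for crystal structures): every
#' donor/acceptor heavy-atom pair between the ligand and the protein (and,
#' optionally, waters) within the distance criterion. With explicit
#' hydrogens, a pair is additionally required to have a hydrogen on the
#' donor (within 1.25 Angstrom, same residue) making a D-H...A angle of at
#' least the angle criterion. Pairs are reported sorted by distance.
#'
#' @param model a [structure_model()].
#' @param ligand_resname residue name(s) selecting the ligand.
#' @param criteria an [hbond_criteria()].
#' @param include_water include water oxygens as partners (default FALSE).
#' @return data frame of class `contact_report`: ligand atom, partner atom,
#'   residue, distance, angle (NA in hydrogen-free mode), role of the
#'   ligand atom.
#' @export
find_hbonds <- function(model, ligand_resname, criteria = hbond_criteria(),
                        include_water = FALSE) {
  a <- model$atoms
  lig <- .select_ligand(model, ligand_resname)
  partner <- a$kind == "protein" | (include_water & a$kind == "water")
  heavy <- toupper(a$element) != "H"
  lt <- vapply(which(lig & heavy), function(i)
    .da_type(a$name[i], a$resname[i], a$element[i], a$kind[i]), "")
  pt <- vapply(which(partner & heavy), function(i)
    .da_type(a$name[i], a$resname[i], a$element[i], a$kind[i]), "")
  li <- which(lig & heavy)[!is.na(lt)]; lt <- lt[!is.na(lt)]
  pi_ <- which(partner & heavy)[!is.na(pt)]; pt <- pt[!is.na(pt)]
  out <- list()
  xyz <- coords(model)
  for (k in seq_along(li)) {
    i <- li[k]
    d <- sqrt(colSums((t(xyz[pi_, , drop = FALSE]) - xyz[i, ])^2))
    for (m in which(d <= criteria$distance_A)) {
      j <- pi_[m]
      # one side must be able to donate, the other to accept
      role <- NULL
      if (lt[k] %in% c("donor", "both") && pt[m] %in% c("acceptor", "both"))
        role <- "donor"
      if (is.null(role) &&
          lt[k] %in% c("acceptor", "both") && pt[m] %in% c("donor", "both"))
        role <- "acceptor"
      if (is.null(role)) next
      ang <- NA_real_
      if (!criteria$hydrogen_free) {
        don <- if (role == "donor") i else j
        acc <- if (role == "donor") j else i
        hyd <- which(toupper(a$element) == "H" &
                     a$resno == a$resno[don] & a$chain == a$chain[don])
        if (length(hyd)) {
          hd <- sqrt(colSums((t(xyz[hyd, , drop = FALSE]) - xyz[don, ])^2))
          hyd <- hyd[hd <= 1.25]
        }
        if (!length(hyd)) next
        angs <- vapply(hyd, function(h) {
          v1 <- xyz[don, ] - xyz[h, ]; v2 <- xyz[acc, ] - xyz[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        }, 0)
        if (max(angs) < criteria$angle_deg) next
        ang <- max(angs)
      }
      out[[length(out) + 1L]] <- data.frame(
        ligand_atom = a$name[i], ligand_role = role,
        partner_atom = a$name[j], partner_resname = a$resname[j],
        partner_resno = a$resno[j], partner_chain = a$chain[j],
        distance_A = d[m], angle_deg = ang, stringsAsFactors = FALSE)
    }
  }
  rep_df <- if (length(out)) do.call(rbind, out) else
    data.frame(ligand_atom = character(0), ligand_role = character(0),
               partner_atom = character(0), partner_resname = character(0),
               partner_resno = integer(0), partner_chain = character(0),
               distance_A = numeric(0), angle_deg = numeric(0))
  rep_df <- rep_df[order(rep_df$distance_A, rep_df$partner_resno,
                         rep_df$partner_atom), , drop = FALSE]
  rownames(rep_df) <- NULL
  class(rep_df) <- c("contact_report", "data.frame")
  attr(rep_df, "kind") <- "hbond"
  rep_df
}

#' Find protein-ligand van der Waals contacts
#'
#' Heavy-atom ligand-protein pairs within the cutoff that are not already
#' reported as hydrogen bonds (under the supplied criteria).
#'
#' @param model a [structure_model()].
#' @param ligand_resname residue name(s) selecting the ligand.
#' @param cutoff_A contact cutoff, Angstrom (default 4.0).
#' @param hbond_criteria criteria used to exclude hydrogen-bonded pairs.
#' @return data frame of class `contact_report`, sorted by distance.
#' @export
find_vdw_contacts <- function(model, ligand_resname, cutoff_A = 4.0,
                              hbond_criteria = cavitherm::hbond_criteria()) {
  a <- model$atoms
  lig <- .select_ligand(model, ligand_resname)
  heavy <- toupper(a$element) != "H"
  hb <- find_hbonds(model, ligand_resname, hbond_criteria)
  hb_key <- paste(hb$ligand_atom, hb$partner_atom, hb$partner_resno,
                  hb$partner_chain)
  li <- which(lig & heavy)
  pi_ <- which(a$kind == "protein" & heavy)
  xyz <- coords(model)
  out <- list()
  for (i in li) {
    d <- sqrt(colSums((t(xyz[pi_, , drop = FALSE]) - xyz[i, ])^2))
    for (m in which(d <= cutoff_A)) {
      j <- pi_[m]
      if (paste(a$name[i], a$name[j], a$resno[j], a$chain[j]) %in% hb_key)
        next
      out[[length(out) + 1L]] <- data.frame(
        ligand_atom = a$name[i], partner_atom = a$name[j],
        partner_resname = a$resname[j], partner_resno = a$resno[j],
        partner_chain = a$chain[j], distance_A = d[m],
        stringsAsFactors = FALSE)
    }
  }
  rep_df <- if (length(out)) do.call(rbind, out) else
    data.frame(ligand_atom = character(0), partner_atom = character(0),
               partner_resname = character(0), partner_resno = integer(0),
               partner_chain = character(0), distance_A = numeric(0))
  rep_df <- rep_df[order(rep_df$distance_A, rep_df$partner_resno,
                         rep_df$partner_atom), , drop = FALSE]
  rownames(rep_df) <- NULL
  class(rep_df) <- c("contact_report", "data.frame")
  attr(rep_df, "kind") <- "vdw"
  rep_df
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Matches atoms between two models by (chain, residue number, atom name)
#' over the selected atom names, then computes the optimal rotation (SVD of
#' the covariance matrix with reflection correction) and translation
#' minimizing the RMSD. The returned transform maps mobile coordinates onto
#' the reference: `x_ref ~ R x_mob + t`.
#'
#' @param model_ref reference [structure_model()].
#' @param model_mob mobile [structure_model()].
#' @param atom_names atom names to match (default `"CA"` for C-alpha).
#' @return object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation`, `rmsd_A`, `n_atoms_matched`, `n_unmatched`.
#' @export
superpose <- function(model_ref, model_mob, atom_names = "CA") {
  key <- function(m) {
    a <- m$atoms
    sel <- a$name %in% atom_names
    k <- paste(a$chain[sel], a$resno[sel], a$name[sel])
    list(keys = k, xyz = coords(m)[sel, , drop = FALSE])
  }
  ka <- key(model_ref); kb <- key(model_mob)
  common <- intersect(ka$keys, kb$keys)
  n_unmatched <- (length(ka$keys) - length(common)) +
    (length(kb$keys) - length(common))
  if (length(common) < 3L)
    stop_cavitherm("fewer than 3 matched atoms: superposition underdetermined",
                   "cavitherm_underdetermined_error")
  A <- ka$xyz[match(common, ka$keys), , drop = FALSE]
  B <- kb$xyz[match(common, kb$keys), , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- unname(ca - as.vector(R %*% cb))
  Bfit <- B %*% t(R) + matrix(t_vec, nrow(B), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Bfit - A)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd_A = rmsd,
                 n_atoms_matched = length(common),
                 n_unmatched = n_unmatched),
            class = "superposition")
}

#' Apply a superposition transform to a model
#'
#' @param model a [structure_model()].
#' @param sup a `superposition` from [superpose()].
#' @return the transformed [structure_model()].
#' @export
apply_superposition <- function(model, sup) {
  xyz <- coords(model) %*% t(sup$rotation) +
    matrix(sup$translation, nrow(model$atoms), 3, byrow = TRUE)
  m <- model
  m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
  m
}

#' Match conserved waters between two (aligned) models
#'
#' Greedy nearest-neighbor matching of water oxygens: candidate pairs
#' within `match_radius_A` are taken in order of increasing distance (ties
#' broken by lower residue number), each water used at most once. Models
#' are assumed already superposed (see [superpose()] and
#' [apply_superposition()]).
#'
#' @param model_a,model_b [structure_model()] objects.
#' @param match_radius_A maximum match distance, Angstrom (default 1.0).
#' @return list with `matched` (data frame: resno_a, resno_b, distance_A),
#'   `unmatched_a`, `unmatched_b` (water ids).
#' @export
conserved_waters <- function(model_a, model_b, match_radius_A = 1.0) {
  oa <- .water_oxygens(model_a); ob <- .water_oxygens(model_b)
  empty <- data.frame(resno_a = integer(0), resno_b = integer(0),
                      distance_A = numeric(0))
  if (!nrow(oa) || !nrow(ob))
    return(list(matched = empty,
                unmatched_a = paste(oa$chain, oa$resno, sep = "/"),
                unmatched_b = paste(ob$chain, ob$resno, sep = "/")))
  pa <- as.matrix(oa[, c("x", "y", "z")])
  pb <- as.matrix(ob[, c("x", "y", "z")])
  cand <- list()
  for (i in seq_len(nrow(pa))) {
    d <- sqrt(colSums((t(pb) - pa[i, ])^2))
    for (j in which(d <= match_radius_A))
      cand[[length(cand) + 1L]] <- c(i, j, d[j])
  }
  used_a <- logical(nrow(oa)); used_b <- logical(nrow(ob))
  matched <- empty
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    ord <- order(cm[, 3], oa$resno[cm[, 1]], ob$resno[cm[, 2]])
    for (r in ord) {
      i <- cm[r, 1]; j <- cm[r, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      matched <- rbind(matched, data.frame(resno_a = oa$resno[i],
                                           resno_b = ob$resno[j],
                                           distance_A = cm[r, 3]))
    }
  }
  list(matched = matched,
       unmatched_a = paste(oa$chain, oa$resno, sep = "/")[!used_a],
       unmatched_b = paste(ob$chain, ob$resno, sep = "/")[!used_b])
}
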