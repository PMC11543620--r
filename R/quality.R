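# CAPRI assessment conventions, centralized: heavy-atom contact distance for
# fnat, heavy-atom interface distance for iRMSD residue selection, backbone
# atom set, and the DockQ scale constants.
.capri <- list(contact_cutoff = 5, interface_cutoff = 10,
               backbone = c("N", "CA", "C", "O"),
               dockq_d1 = 1.5, dockq_d2 = 8.5, hit_threshold = 0.23)

.atom_xyz <- function(complex, partner) {
  a <- complex$atoms[complex$atoms$partner == partner, , drop = FALSE]
  list(xyz = cbind(a$x, a$y, a$z), res_row = a$res_row, name = a$atom_name)
}

.cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
}

# cross-partner residue contact pairs (any heavy-atom pair <= cutoff)
.contact_pairs <- function(complex, cutoff) {
  a <- .atom_xyz(complex, "a"); b <- .atom_xyz(complex, "b")
  hit <- .cross_dist2(a$xyz, b$xyz) <= cutoff^2
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(character(0))
  unique(paste(a$res_row[idx[, 1L]], b$res_row[idx[, 2L]], sep = "-"))
}

#' Fraction of native contacts preserved in a decoy
#'
#' A native contact is a cross-partner residue pair with any heavy-atom pair
#' within 5 Angstrom in the native structure. Residue correspondence between
#' decoy and native is by chain identifier, residue number and insertion
#' code.
#'
#' @param decoy,native \code{\link{protein_complex}} objects with matching
#'   residue numbering.
#' @return Fraction in [0, 1].
#' @export
fnat <- function(decoy, native) {
  .check_correspondence(decoy, native)
  nat <- .contact_pairs(native, .capri$contact_cutoff)
  if (length(nat) == 0L) stop("no native contacts: the native complex has no cross-partner heavy-atom pair within 5 A")
  dec <- .contact_pairs(decoy, .capri$contact_cutoff)
  length(intersect(nat, dec)) / length(nat)
}

.check_correspondence <- function(decoy, native) {
  for (p in c("partner_a", "partner_b")) {
    kd <- .residue_keys(decoy[[p]]); kn <- .residue_keys(native[[p]])
    if (length(kd) != length(kn) || any(kd != kn))
      stop("decoy and native residues do not correspond (", p, ")")
  }
  invisible(TRUE)
}

# matched backbone coordinate matrices over a residue-row subset of a partner
.backbone_xyz <- function(complex, partner, res_rows) {
  at <- .atom_xyz(complex, partner)
  keep <- at$res_row %in% res_rows & at$name %in% .capri$backbone
  ord <- order(at$res_row[keep], match(at$name[keep], .capri$backbone))
  list(xyz = at$xyz[keep, , drop = FALSE][ord, , drop = FALSE],
       key = paste(at$res_row[keep], at$name[keep])[ord])
}

# residue rows (per partner) of the native interface: any heavy atom within
# 10 A of the other partner
.interface_rows <- function(native) {
  a <- .atom_xyz(native, "a"); b <- .atom_xyz(native, "b")
  hit <- .cross_dist2(a$xyz, b$xyz) <= .capri$interface_cutoff^2
  list(a = sort(unique(a$res_row[apply(hit, 1L, any)])),
       b = sort(unique(b$res_row[apply(hit, 2L, any)])))
}

# rotation + translation aligning mobile onto fixed (least squares, SVD)
.kabsch_rt <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  H <- crossprod(sweep(mobile, 2L, cm), sweep(fixed, 2L, cf))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.vector(cf - R %*% cm))
}

#' Interface RMSD of a decoy against its native
#'
#' Native interface residues are those with any heavy atom within 10 Angstrom
#' of the other partner. The decoy's interface backbone (N, CA, C, O) is
#' optimally superposed onto the native's and the RMSD of those atoms after
#' superposition is returned.
#'
#' @inheritParams fnat
#' @return RMSD in Angstrom.
#' @export
interface_rmsd <- function(decoy, native) {
  .check_correspondence(decoy, native)
  iface <- .interface_rows(native)
  if (length(iface$a) + length(iface$b) < 3L)
    stop("underdetermined superposition: fewer than 3 interface residues")
  nat <- rbind(.backbone_xyz(native, "a", iface$a)$xyz,
               .backbone_xyz(native, "b", iface$b)$xyz)
  dec <- rbind(.backbone_xyz(decoy, "a", iface$a)$xyz,
               .backbone_xyz(decoy, "b", iface$b)$xyz)
  stopifnot(nrow(nat) == nrow(dec))
  rt <- .kabsch_rt(dec, nat)
  fitted <- sweep(dec %*% t(rt$R), 2L, rt$t, "+")
  sqrt(mean(rowSums((fitted - nat)^2)))
}

#' Ligand RMSD of a decoy against its native
#'
#' Superposes the decoy on the receptor (partner a) backbone and reports the
#' backbone RMSD of partner b (the ligand) without further fitting.
#'
#' @inheritParams fnat
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(decoy, native) {
  .check_correspondence(decoy, native)
  rows_a <- seq_len(nrow(native$partner_a))
  rows_b <- seq_len(nrow(native$partner_b))
  if (length(rows_a) < 3L) stop("underdetermined superposition: receptor too small")
  nat_a <- .backbone_xyz(native, "a", rows_a)$xyz
  dec_a <- .backbone_xyz(decoy, "a", rows_a)$xyz
  rt <- .kabsch_rt(dec_a, nat_a)
  nat_b <- .backbone_xyz(native, "b", rows_b)$xyz
  dec_b <- .backbone_xyz(decoy, "b", rows_b)$xyz
  fitted_b <- sweep(dec_b %*% t(rt$R), 2L, rt$t, "+")
  sqrt(mean(rowSums((fitted_b - nat_b)^2)))
}

#' CAPRI quality class from fnat, iRMSD and LRMSD
#'
#' Standard CAPRI tiers: high if fnat >= 0.5 and (LRMSD <= 1 or iRMSD <= 1);
#' else medium if fnat >= 0.3 and (LRMSD <= 5 or iRMSD <= 2); else acceptable
#' if fnat >= 0.1 and (LRMSD <= 10 or iRMSD <= 4); else incorrect.
#'
#' @param fnat Fraction of native contacts in [0, 1].
#' @param irmsd Interface RMSD in Angstrom.
#' @param lrmsd Ligand RMSD in Angstrom.
#' @return One of "high", "medium", "acceptable", "incorrect".
#' @export
capri_classify <- function(fnat, irmsd, lrmsd) {
  stopifnot(fnat >= 0, fnat <= 1, irmsd >= 0, lrmsd >= 0)
  if (fnat >= 0.5 && (lrmsd <= 1 || irmsd <= 1)) return("high")
  if (fnat >= 0.3 && (lrmsd <= 5 || irmsd <= 2)) return("medium")
  if (fnat >= 0.1 && (lrmsd <= 10 || irmsd <= 4)) return("acceptable")
  "incorrect"
}

#' DockQ score
#'
#' DockQ = (fnat + 1/(1+(iRMSD/1.5)^2) + 1/(1+(LRMSD/8.5)^2)) / 3.
#'
#' @inheritParams capri_classify
#' @return Value in [0, 1].
#' @export
dockq <- function(fnat, irmsd, lrmsd) {
  stopifnot(fnat >= 0, fnat <= 1, irmsd >= 0, lrmsd >= 0)
  (fnat + 1 / (1 + (irmsd / .capri$dockq_d1)^2) +
     1 / (1 + (lrmsd / .capri$dockq_d2)^2)) / 3
}

#' Is a model a "hit" by DockQ?
#'
#' A hit (acceptable-or-better model) has DockQ >= 0.23.
#' @param dockq_value DockQ score(s).
#' @return Logical vector.
#' @export
dockq_hit <- function(dockq_value) dockq_value >= .capri$hit_threshold

#' AlphaFold-Multimer ranking confidence
#'
#' 0.8 * ipTM + 0.2 * pTM.
#' @param iptm,ptm Predicted interface / overall TM-score confidences, each in
#'   [0, 1].
#' @return Ranking confidence in [0, 1].
#' @export
ranking_confidence <- function(iptm, ptm) {
  if (any(iptm < 0 | iptm > 1 | ptm < 0 | ptm > 1))
    stop("iptm and ptm must lie in [0, 1]")
  0.8 * iptm + 0.2 * ptm
}

#' Combined confidence-plus-DockQ regression target
#'
#' The continuous training target for the distillation-style model: ranking
#' confidence of the decoy plus its DockQ against the native; range [0, 2].
#'
#' @inheritParams ranking_confidence
#' @param dockq_value DockQ in [0, 1].
#' @return Value in [0, 2].
#' @export
afm_target <- function(iptm, ptm, dockq_value) {
  stopifnot(all(dockq_value >= 0 & dockq_value <= 1))
  ranking_confidence(iptm, ptm) + dockq_value
}

#' Full interface quality report for a decoy
#'
#' Computes fnat, iRMSD, LRMSD, DockQ, the CAPRI class and the binary label
#' (1 iff acceptable or better) of a decoy against its native reference.
#'
#' @inheritParams fnat
#' @return One-row data frame with columns \code{fnat}, \code{irmsd},
#'   \code{lrmsd}, \code{dockq}, \code{capri_class}, \code{binary_label}.
#' @export
quality_report <- function(decoy, native) {
  f <- fnat(decoy, native)
  ir <- interface_rmsd(decoy, native)
  lr <- ligand_rmsd(decoy, native)
  cls <- capri_classify(f, ir, lr)
  data.frame(fnat = f, irmsd = ir, lrmsd = lr, dockq = dockq(f, ir, lr),
             capri_class = cls, binary_label = as.integer(cls != "incorrect"),
             stringsAsFactors = FALSE)
}
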