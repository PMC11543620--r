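.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

#' Amino-acid alphabet used by the one-hot encoding
#'
#' The 20 canonical one-letter codes followed by \code{"X"} (unknown), giving
#' the 21 one-hot slots.
#' @return Character vector of length 21.
#' @export
aa_alphabet <- function() c(unname(.aa3), "X")

#' A residue-level protein complex with two binding partners
#'
#' @param partner_a,partner_b Data frames of residues, one row per residue,
#'   with columns \code{chain_id}, \code{seq_index}, \code{insertion_code},
#'   \code{aa_type} (one-letter, \code{"X"} for non-canonical).
#' @param atoms Data frame of heavy atoms with columns \code{partner}
#'   ("a"/"b"), \code{res_row} (row index into that partner's residue table),
#'   \code{atom_name}, \code{x}, \code{y}, \code{z}.
#' @param source_id Text label.
#' @return Object of class \code{protein_complex}. Each partner data frame
#'   additionally carries CA coordinates in columns \code{ca_x, ca_y, ca_z}.
#' @export
protein_complex <- function(partner_a, partner_b, atoms, source_id = "complex") {
  stopifnot(nrow(partner_a) > 0L, nrow(partner_b) > 0L)
  for (p in list(partner_a, partner_b))
    stopifnot(all(c("chain_id", "seq_index", "insertion_code", "aa_type",
                    "ca_x", "ca_y", "ca_z") %in% names(p)),
              all(is.finite(c(p$ca_x, p$ca_y, p$ca_z))))
  structure(list(partner_a = partner_a, partner_b = partner_b,
                 atoms = atoms, source_id = source_id),
            class = "protein_complex")
}

#' @export
print.protein_complex <- function(x, ...) {
  cat(sprintf("<protein_complex '%s': partner_a %d residues (%s), partner_b %d residues (%s), %d heavy atoms>\n",
              x$source_id, nrow(x$partner_a),
              paste(unique(x$partner_a$chain_id), collapse = ","),
              nrow(x$partner_b),
              paste(unique(x$partner_b$chain_id), collapse = ","),
              nrow(x$atoms)))
  invisible(x)
}

#' CA coordinate matrix of a complex
#'
#' @param complex A \code{\link{protein_complex}}.
#' @param partner "a", "b" or "both" (partner a rows first).
#' @return Numeric matrix (n, 3) in Angstrom.
#' @export
ca_coords <- function(complex, partner = c("both", "a", "b")) {
  partner <- match.arg(partner)
  a <- as.matrix(complex$partner_a[, c("ca_x", "ca_y", "ca_z")])
  b <- as.matrix(complex$partner_b[, c("ca_x", "ca_y", "ca_z")])
  dimnames(a) <- dimnames(b) <- NULL
  switch(partner, a = a, b = b, both = rbind(a, b))
}

.residue_table <- function(pdb, chains) {
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L) return(NULL)
  # first altloc wins; drop hydrogens
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elesy <- trimws(ifelse(is.na(at$elesy), "", at$elesy))
  is_h <- elesy == "H" | (elesy == "" & grepl("^[0-9]*H", trimws(at$elety)))
  at <- at[!is_h, , drop = FALSE]
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  key <- paste(at$chain, at$resno, ins, sep = "|")
  keys <- unique(key)   # file order
  res <- data.frame(chain_id = character(0))
  rows <- list(); atom_rows <- list()
  kept <- 0L
  for (k in keys) {
    sub <- at[key == k, , drop = FALSE]
    ca <- sub[trimws(sub$elety) == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) {
      warning(sprintf("dropping residue %s %s%s: no CA atom", sub$chain[1L],
                      sub$resno[1L], ifelse(is.na(sub$insert[1L]), "", sub$insert[1L])))
      next
    }
    kept <- kept + 1L
    aa <- unname(.aa3[sub$resid[1L]])
    rows[[kept]] <- data.frame(
      chain_id = sub$chain[1L], seq_index = sub$resno[1L],
      insertion_code = ifelse(is.na(sub$insert[1L]) | sub$insert[1L] == "", "", sub$insert[1L]),
      aa_type = ifelse(is.na(aa), "X", aa),
      ca_x = ca$x[1L], ca_y = ca$y[1L], ca_z = ca$z[1L],
      stringsAsFactors = FALSE)
    atom_rows[[kept]] <- data.frame(
      res_row = kept, atom_name = trimws(sub$elety),
      x = sub$x, y = sub$y, z = sub$z, stringsAsFactors = FALSE)
  }
  if (kept == 0L) return(NULL)
  list(residues = do.call(rbind, rows), atoms = do.call(rbind, atom_rows))
}

#' Read a two-partner protein complex from a PDB file
#'
#' Parses ATOM records only (HETATM, waters and hydrogens ignored), keeps the
#' first alternate location, preserves insertion codes, and drops residues
#' lacking a CA atom with a warning. Chain-to-partner assignment is explicit.
#'
#' @param path Path to a PDB file.
#' @param partner_a_chains,partner_b_chains Disjoint, non-empty character
#'   vectors of chain identifiers.
#' @param source_id Optional label; defaults to the file name.
#' @return A \code{\link{protein_complex}}.
#' @export
read_complex <- function(path, partner_a_chains, partner_b_chains,
                         source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(length(partner_a_chains) > 0L, length(partner_b_chains) > 0L,
            length(intersect(partner_a_chains, partner_b_chains)) == 0L)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file ", path, ": ", conditionMessage(e)))
  a <- .residue_table(pdb, partner_a_chains)
  b <- .residue_table(pdb, partner_b_chains)
  if (is.null(a)) stop("empty partner: no residues found for partner_a chains ",
                       paste(partner_a_chains, collapse = ","))
  if (is.null(b)) stop("empty partner: no residues found for partner_b chains ",
                       paste(partner_b_chains, collapse = ","))
  atoms <- rbind(cbind(partner = "a", a$atoms), cbind(partner = "b", b$atoms))
  protein_complex(a$residues, b$residues, atoms, source_id = source_id)
}

#' Write a protein complex to a PDB file
#'
#' Emits standard ATOM records (3-decimal coordinates), a TER line after each
#' chain, and END. Chain identifiers and insertion codes are preserved.
#'
#' @param complex A \code{\link{protein_complex}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_complex <- function(complex, path) {
  stopifnot(inherits(complex, "protein_complex"))
  inv_aa <- stats::setNames(names(.aa3), unname(.aa3))
  lines <- character(0)
  serial <- 0L
  for (p in c("a", "b")) {
    res <- if (p == "a") complex$partner_a else complex$partner_b
    atoms <- complex$atoms[complex$atoms$partner == p, , drop = FALSE]
    last_chain <- NULL
    for (i in seq_len(nrow(res))) {
      ch <- res$chain_id[i]
      if (!is.null(last_chain) && ch != last_chain)
        lines <- c(lines, sprintf("TER   %5d", serial + 1L))
      last_chain <- ch
      rn3 <- if (res$aa_type[i] %in% names(inv_aa)) inv_aa[[res$aa_type[i]]] else "UNK"
      sub <- atoms[atoms$res_row == i, , drop = FALSE]
      for (j in seq_len(nrow(sub))) {
        serial <- serial + 1L
        nm <- sub$atom_name[j]
        nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
        lines <- c(lines, sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
                                  serial, nm_fmt, rn3, ch, res$seq_index[i],
                                  ifelse(res$insertion_code[i] == "", " ", res$insertion_code[i]),
                                  sub$x[j], sub$y[j], sub$z[j], 1, 0))
      }
    }
    lines <- c(lines, sprintf("TER   %5d", serial + 1L))
  }
  lines <- c(lines, "END")
  con <- tryCatch(file(path, "w"), error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Rigid-body transform
#'
#' @param rotation 3x3 orthonormal matrix with det +1 (checked to 1e-8).
#' @param translation Length-3 numeric vector in Angstrom.
#' @return Object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0)
    stop("rotation must be orthonormal with det +1")
  stopifnot(length(translation) == 3L, all(is.finite(translation)))
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Compose two rigid transforms
#'
#' \code{compose_transforms(t2, t1)} is the transform applying t1 first, then
#' t2.
#' @param t2,t1 \code{\link{rigid_transform}} objects.
#' @return A \code{\link{rigid_transform}}.
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.vector(t2$rotation %*% t1$translation) + t2$translation)
}

#' Apply a rigid transform to one or both partners of a complex
#'
#' Every selected coordinate x (CA and heavy atoms) becomes R x + t; the
#' other partner is untouched.
#'
#' @param complex A \code{\link{protein_complex}}.
#' @param t A \code{\link{rigid_transform}}.
#' @param partner "a", "b" or "both".
#' @return The transformed \code{\link{protein_complex}}.
#' @export
apply_transform <- function(complex, t, partner = c("both", "a", "b")) {
  partner <- match.arg(partner)
  stopifnot(inherits(complex, "protein_complex"), inherits(t, "rigid_transform"))
  sel <- if (partner == "both") c("a", "b") else partner
  tx <- function(m) sweep(m %*% t(t$rotation), 2L, t$translation, "+")
  for (p in sel) {
    key <- paste0("partner_", p)
    res <- complex[[key]]
    m <- tx(as.matrix(res[, c("ca_x", "ca_y", "ca_z")]))
    res$ca_x <- m[, 1L]; res$ca_y <- m[, 2L]; res$ca_z <- m[, 3L]
    complex[[key]] <- res
    idx <- complex$atoms$partner == p
    am <- tx(as.matrix(complex$atoms[idx, c("x", "y", "z")]))
    complex$atoms$x[idx] <- am[, 1L]
    complex$atoms$y[idx] <- am[, 2L]
    complex$atoms$z[idx] <- am[, 3L]
  }
  complex
}
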