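# Shared fixtures and independent oracles. Everything here is built in
# code at test time; nothing is loaded from binary files.

# --- independent superposition oracle (Horn quaternion method) ------------
# Least-squares rigid-fit RMSD via the largest eigenvector of the 4x4
# quaternion key matrix; entirely independent of the SVD-based Kabsch
# implementation it cross-checks.
quat_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P0, Q0)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[1, 3] + M[3, 1]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  q <- eigen(S, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
                2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
                2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
}

# random proper rotation matrix (QR of a Gaussian matrix, det forced +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# --- PDB text fixtures ----------------------------------------------------
# Hand-formatted ATOM/HETATM records, written independently of the
# package's own writer so they double as a parser oracle.
write_fixture_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$record, i, a$atom, ifelse(is.null(a$altloc), " ", a$altloc),
            a$resname, a$chain, a$resno, a$x, a$y, a$z, a$occ, 0, a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

fx_atom <- function(record, chain, resno, resname, atom, element, x, y, z,
                    occ = 1, altloc = " ") {
  data.frame(record = record, chain = chain, resno = resno, resname = resname,
             atom = atom, element = element, x = x, y = y, z = z, occ = occ,
             altloc = altloc, stringsAsFactors = FALSE)
}

# C-alpha-only poly-alanine model from an n x 3 coordinate matrix.
# Built in memory (not via PDB text) so coordinates stay exact: the
# fixed-column PDB format rounds to 3 decimals, which would defeat the
# 1e-8 oracle-equality and 1e-6 rigid-invariance tolerances.
ca_model <- function(coords, chain = "A") {
  atoms <- do.call(rbind, lapply(seq_len(nrow(coords)), function(i) {
    fx_atom("ATOM", chain, i, "ALA", "CA", "C",
            coords[i, 1], coords[i, 2], coords[i, 3])
  }))
  atoms$record <- NULL
  pprkit:::.new_structure_model(atoms, source = "fixture")
}

# --- constructed dPPR-RNA recognition fixtures ----------------------------
# One 35-residue repeat (chain A, residues 1-35) facing a single
# nucleotide (chain B), with planted distances:
#   base = "U": Asn5 ND2 2.9 A from O2 (direct position-5 bond) and a
#     water bridging base N3 and Asp35 OD1 (2.8 A each); no direct 35 bond.
#   base = "G": Asp35 OD1 2.8 A from N1 and OD2 2.6 A from N2 (the two
#     direct purine bonds of guanine recognition); no water.
# Also planted: Val2 CB within 4.5 A of the base ring, Lys13 NZ 3.0 A
# from the phosphate OP1.
recognition_fixture <- function(base = c("U", "G")) {
  base <- match.arg(base)
  rows <- list(
    fx_atom("ATOM", "A", 1, "GLY", "CA", "C", -5, -5, -5),
    fx_atom("ATOM", "A", 2, "VAL", "CA", "C", 0, 1, 7),
    fx_atom("ATOM", "A", 2, "VAL", "CB", "C", 0, 1, 3.5),
    fx_atom("ATOM", "A", 5, "ASN", "CA", "C", 2, -7, 1),
    fx_atom("ATOM", "A", 5, "ASN", "OD1", "O", 5, -6, 3),
    fx_atom("ATOM", "A", 13, "LYS", "CA", "C", 9, 5, 5),
    fx_atom("ATOM", "A", 13, "LYS", "NZ", "N", 6, 5, 3),
    fx_atom("ATOM", "A", 35, "ASP", "CA", "C", 8, 8, 8)
  )
  if (base == "U") {
    rows <- c(rows, list(
      fx_atom("ATOM", "A", 5, "ASN", "ND2", "N", 1.9, -4.0, 0),
      fx_atom("ATOM", "A", 35, "ASP", "OD1", "O", 2.0, 1.1, 5.6),
      fx_atom("ATOM", "B", 101, "U", "N1", "N", 0, 0, 0),
      fx_atom("ATOM", "B", 101, "U", "C2", "C", 1.3, 0, 0),
      fx_atom("ATOM", "B", 101, "U", "O2", "O", 1.9, -1.1, 0),
      fx_atom("ATOM", "B", 101, "U", "N3", "N", 2.0, 1.1, 0),
      fx_atom("ATOM", "B", 101, "U", "C4", "C", 1.4, 2.3, 0),
      fx_atom("ATOM", "B", 101, "U", "C5", "C", 0, 2.4, 0),
      fx_atom("ATOM", "B", 101, "U", "C6", "C", -0.7, 1.2, 0),
      fx_atom("ATOM", "B", 101, "U", "OP1", "O", 6, 5, 0),
      fx_atom("ATOM", "B", 101, "U", "P", "P", 6.5, 5.5, -1),
      fx_atom("HETATM", "W", 201, "HOH", "O", "O", 2.0, 1.1, 2.8)
    ))
  } else {
    rows <- c(rows, list(
      fx_atom("ATOM", "A", 5, "THR", "OG1", "O", 1.9, 3.0, 2.2),
      fx_atom("ATOM", "A", 35, "ASP", "OD1", "O", 0, 0, 2.8),
      fx_atom("ATOM", "A", 35, "ASP", "OD2", "O", 2.6, -1.2, 2.5),
      fx_atom("ATOM", "B", 101, "G", "N1", "N", 0, 0, 0),
      fx_atom("ATOM", "B", 101, "G", "C2", "C", 1.3, 0.3, 0),
      fx_atom("ATOM", "B", 101, "G", "N2", "N", 2.0, -0.8, 0),
      fx_atom("ATOM", "B", 101, "G", "N3", "N", 1.9, 1.5, 0),
      fx_atom("ATOM", "B", 101, "G", "C4", "C", 1.2, 2.6, 0),
      fx_atom("ATOM", "B", 101, "G", "C5", "C", -0.2, 2.6, 0),
      fx_atom("ATOM", "B", 101, "G", "C6", "C", -0.9, 1.3, 0),
      fx_atom("ATOM", "B", 101, "G", "O6", "O", -2.2, 1.3, 0),
      fx_atom("ATOM", "B", 101, "G", "OP1", "O", 6, 5, 0),
      fx_atom("ATOM", "B", 101, "G", "P", "P", 6.5, 5.5, -1)
    ))
  }
  atoms <- do.call(rbind, rows)
  path <- tempfile(fileext = ".pdb")
  write_fixture_pdb(atoms, path)
  read_structure(path)
}

# apply a rigid transform to every atom of a structure model (in memory,
# exact arithmetic)
transform_model <- function(model, R, t) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  a$class <- NULL
  pprkit:::.new_structure_model(a, source = "fixture")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
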