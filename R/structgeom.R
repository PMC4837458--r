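AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
RNA3 <- c("A", "C", "G", "U")
WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD")

.residue_class <- function(resname) {
  ifelse(resname %in% names(AA3), "protein",
  ifelse(resname %in% RNA3, "rna",
  ifelse(resname %in% WATER_NAMES, "water", "other")))
}

.new_structure_model <- function(atoms, source = "memory") {
  stopifnot(all(c("chain", "resno", "resname", "atom", "element",
                  "x", "y", "z", "occ") %in% names(atoms)))
  if (!nrow(atoms)) stop("empty model: no atoms", call. = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in model", call. = FALSE)
  }
  atoms$class <- .residue_class(atoms$resname)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("<structure model>", nrow(a), "atoms;",
      length(unique(paste(a$chain, a$resno)[a$class == "protein"])), "protein,",
      length(unique(paste(a$chain, a$resno)[a$class == "rna"])), "RNA,",
      sum(a$class == "water"), "water residues\n")
  invisible(x)
}

# --- PDB parsing (fixed-column) -------------------------------------------

.parse_pdb <- function(lines, path) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records found in ", path, call. = FALSE)
  rec <- lines[sel]
  fx <- function(from, to) trimws(substr(rec, from, to))
  num <- function(from, to) suppressWarnings(as.numeric(fx(from, to)))
  atoms <- data.frame(
    chain = substr(rec, 22, 22),
    resno = suppressWarnings(as.integer(fx(23, 26))),
    resname = fx(18, 20),
    atom = fx(13, 16),
    altloc = substr(rec, 17, 17),
    element = fx(77, 78),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    occ = num(55, 60),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) || anyNA(atoms$resno)) {
    stop("malformed or truncated coordinate records in ", path, call. = FALSE)
  }
  atoms$occ[is.na(atoms$occ)] <- 1
  miss <- atoms$element == ""
  atoms$element[miss] <- substr(gsub("[0-9']", "", atoms$atom[miss]), 1, 1)
  atoms
}

# --- minimal mmCIF parsing (atom_site loop) -------------------------------

.parse_mmcif <- function(lines, path) {
  i <- 1L
  tags <- character(0)
  rows <- list()
  n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      j <- i + 1L
      tg <- character(0)
      while (j <= n && startsWith(trimws(lines[j]), "_")) {
        tg <- c(tg, trimws(lines[j])); j <- j + 1L
      }
      if (length(tg) && all(startsWith(tg, "_atom_site."))) {
        tags <- sub("^_atom_site\\.", "", tg)
        while (j <= n) {
          ln <- trimws(lines[j])
          if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
              ln == "loop_" || startsWith(ln, "data_")) break
          rows[[length(rows) + 1L]] <- scan(text = ln, what = character(),
                                            quiet = TRUE)
          j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(tags) || !length(rows)) {
    stop("no _atom_site loop found in ", path, call. = FALSE)
  }
  bad <- vapply(rows, length, integer(1)) != length(tags)
  if (any(bad)) stop("malformed _atom_site row in ", path, call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  pick <- function(...) {
    for (cand in c(...)) if (cand %in% tags) return(m[, cand])
    rep(NA_character_, nrow(m))
  }
  atoms <- data.frame(
    chain = pick("auth_asym_id", "label_asym_id"),
    resno = suppressWarnings(as.integer(pick("auth_seq_id", "label_seq_id"))),
    resname = pick("auth_comp_id", "label_comp_id"),
    atom = gsub('"', "", pick("auth_atom_id", "label_atom_id")),
    altloc = pick("label_alt_id"),
    element = pick("type_symbol"),
    x = suppressWarnings(as.numeric(pick("Cartn_x"))),
    y = suppressWarnings(as.numeric(pick("Cartn_y"))),
    z = suppressWarnings(as.numeric(pick("Cartn_z"))),
    occ = suppressWarnings(as.numeric(pick("occupancy"))),
    stringsAsFactors = FALSE
  )
  atoms$altloc[is.na(atoms$altloc) | atoms$altloc == "."] <- " "
  atoms$occ[is.na(atoms$occ)] <- 1
  if (anyNA(atoms$x) || anyNA(atoms$resno)) {
    stop("malformed coordinates in ", path, call. = FALSE)
  }
  atoms
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Format is chosen by extension (`.cif`/`.mmcif` vs anything else treated
#' as PDB) unless forced. Alternate locations are resolved to the highest
#' occupancy (ties keep the first conformer in file order); waters are
#' retained. Residues are classified as protein / RNA / water / other.
#'
#' @param path file path
#' @param format `"auto"`, `"pdb"` or `"cif"`
#' @return a `structure_model` whose `atoms` data frame has columns
#'   `chain`, `resno`, `resname`, `atom`, `element`, `x`, `y`, `z`, `occ`,
#'   `class`
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  atoms <- if (format == "cif") .parse_mmcif(lines, path) else .parse_pdb(lines, path)
  # altloc resolution: per (chain, resno, atom) keep the highest-occupancy
  # conformer, first in file order on ties
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$atom)
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$resname,
                                   atoms$atom)), , drop = FALSE]
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)), atoms$resno), ,
                 drop = FALSE]
  .new_structure_model(atoms, source = path)
}

#' Write a structure model in PDB format
#'
#' Minimal writer used for fixtures and report output; round-trips through
#' [read_structure()].
#'
#' @param model a `structure_model`
#' @param path output path
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  rec <- ifelse(a$class %in% c("protein", "rna"), "ATOM  ", "HETATM")
  lines <- sprintf("%s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)) %% 100000L,
                   ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
                   " ", a$resname, a$chain, a$resno,
                   a$x, a$y, a$z, a$occ, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# First chain of a given class, or validate a requested chain.
.pick_chain <- function(model, class, chain = NULL) {
  a <- model$atoms
  if (!is.null(chain)) {
    if (!chain %in% a$chain) stop("chain '", chain, "' not in model", call. = FALSE)
    return(chain)
  }
  ch <- unique(a$chain[a$class == class])
  if (!length(ch)) {
    stop("model contains no ", class, " chain (expected one for this analysis)",
         call. = FALSE)
  }
  ch[1]
}

#' Segment a PPR protein chain into 35-residue repeats
#'
#' Either validates explicit ranges or tiles 35-residue windows from an
#' anchor residue. The default anchor 174 matches the deposited designer
#' constructs, whose ten repeats occupy residues 174-523.
#'
#' @param model a `structure_model`
#' @param chain protein chain id (default: first protein chain)
#' @param anchor first residue of repeat 1 (auto mode)
#' @param n_repeats number of repeats to tile (auto mode; default: as many
#'   complete repeats as the chain holds from the anchor)
#' @param ranges optional explicit segmentation: data frame with columns
#'   `start_res`, `end_res` (each exactly 35 residues, contiguous,
#'   non-overlapping)
#' @return a `repeat_segmentation` data frame: `repeat_index`,
#'   `start_res`, `end_res`, `code5_resno`, `code35_resno`, with the chain
#'   id as attribute
#' @export
segment_repeats <- function(model, chain = NULL, anchor = 174L,
                            n_repeats = NULL, ranges = NULL) {
  stopifnot(inherits(model, "structure_model"))
  chain <- .pick_chain(model, "protein", chain)
  resnos <- sort(unique(model$atoms$resno[model$atoms$chain == chain &
                                          model$atoms$class == "protein"]))
  if (!is.null(ranges)) {
    stopifnot(all(c("start_res", "end_res") %in% names(ranges)))
    if (any(ranges$end_res - ranges$start_res + 1L != 35L)) {
      stop("every repeat range must span exactly 35 residues", call. = FALSE)
    }
    o <- order(ranges$start_res)
    ranges <- ranges[o, , drop = FALSE]
    if (nrow(ranges) > 1L &&
        any(ranges$start_res[-1] <= ranges$end_res[-nrow(ranges)])) {
      stop("repeat ranges overlap", call. = FALSE)
    }
    starts <- ranges$start_res
  } else {
    if (is.null(n_repeats)) {
      n_repeats <- max(0L, (max(resnos) - anchor + 1L) %/% 35L)
    }
    if (n_repeats < 1L) stop("no complete repeats fit after anchor ", anchor,
                             call. = FALSE)
    starts <- anchor + (seq_len(n_repeats) - 1L) * 35L
  }
  missing <- !(starts %in% resnos) | !((starts + 34L) %in% resnos)
  if (any(missing)) {
    stop("chain ", chain, " does not cover repeat range ",
         starts[which(missing)[1]], "-", starts[which(missing)[1]] + 34L,
         call. = FALSE)
  }
  seg <- data.frame(
    repeat_index = seq_along(starts),
    start_res = starts,
    end_res = starts + 34L,
    code5_resno = starts + 4L,
    code35_resno = starts + 34L
  )
  structure(seg, chain = chain, class = c("repeat_segmentation", "data.frame"))
}

# --- Kabsch superposition -------------------------------------------------

# Closed-form least-squares rigid fit of P onto Q (n x 3 each).
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  Pfit <- sweep(P %*% t(R), 2, t, "+")
  dists <- sqrt(rowSums((Pfit - Q)^2))
  list(R = R, t = t, rmsd = sqrt(mean(dists^2)), dists = dists)
}

.ca_table <- function(model, chain) {
  a <- model$atoms
  ca <- a[a$chain == chain & a$class == "protein" & a$atom == "CA", ,
          drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  ca$aa <- unname(AA3[ca$resname])
  ca$aa[is.na(ca$aa)] <- "X"
  ca
}

#' Superpose two structures on paired C-alpha atoms
#'
#' Residues are paired either by global sequence alignment of the selected
#' chains (match 1, mismatch 0, gap -1; the default) or by deposited
#' residue numbering. The rigid fit is the closed-form Kabsch
#' least-squares solution, refined by iterative pruning: pairs deviating
#' more than `prune_sigma` times the current RMSD are dropped and the fit
#' repeated, up to `max_cycles` cycles or convergence.
#'
#' @param model_a,model_b `structure_model` objects (a is moved onto b)
#' @param chain_a,chain_b protein chain ids (default: first protein chain)
#' @param prune_sigma pruning multiple of the current RMSD (default 2)
#' @param max_cycles maximum pruning cycles (default 5)
#' @param pair_by `"alignment"` or `"numbering"`
#' @return a `superpose_result`: `rmsd` (A), `n_retained`, `n_initial`,
#'   rotation `R` (det +1), translation `t`
#' @export
superpose <- function(model_a, model_b, chain_a = NULL, chain_b = NULL,
                      prune_sigma = 2, max_cycles = 5L,
                      pair_by = c("alignment", "numbering")) {
  pair_by <- match.arg(pair_by)
  chain_a <- .pick_chain(model_a, "protein", chain_a)
  chain_b <- .pick_chain(model_b, "protein", chain_b)
  ca_a <- .ca_table(model_a, chain_a)
  ca_b <- .ca_table(model_b, chain_b)
  if (pair_by == "numbering") {
    common <- intersect(ca_a$resno, ca_b$resno)
    ia <- match(common, ca_a$resno)
    ib <- match(common, ca_b$resno)
  } else {
    sm <- matrix(0, 24, 24,
                 dimnames = list(c(AA1, "X", "B", "Z", "*"),
                                 c(AA1, "X", "B", "Z", "*")))
    diag(sm) <- 1
    al <- Biostrings::pairwiseAlignment(
      paste(ca_a$aa, collapse = ""), paste(ca_b$aa, collapse = ""),
      type = "global", substitutionMatrix = sm,
      gapOpening = 0, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ia <- integer(0); ib <- integer(0); i <- 0L; j <- 0L
    for (k in seq_along(pa)) {
      if (pa[k] != "-") i <- i + 1L
      if (pb[k] != "-") j <- j + 1L
      if (pa[k] != "-" && pb[k] != "-") { ia <- c(ia, i); ib <- c(ib, j) }
    }
  }
  if (length(ia) < 3L) stop("fewer than 3 paired C-alpha atoms", call. = FALSE)
  P <- as.matrix(ca_a[ia, c("x", "y", "z")])
  Q <- as.matrix(ca_b[ib, c("x", "y", "z")])
  n_initial <- nrow(P)
  keep <- seq_len(n_initial)
  fit <- .kabsch(P, Q)
  for (cyc in seq_len(max_cycles)) {
    cut <- prune_sigma * fit$rmsd
    new_keep <- keep[fit$dists <= cut]
    if (length(new_keep) == length(keep)) break
    if (length(new_keep) < 3L) {
      stop("degenerate fit: fewer than 3 pairs survive pruning", call. = FALSE)
    }
    keep <- new_keep
    fit <- .kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
  }
  structure(list(rmsd = fit$rmsd, n_retained = length(keep),
                 n_initial = n_initial, R = fit$R, t = fit$t,
                 chain_a = chain_a, chain_b = chain_b),
            class = "superpose_result")
}

#' @export
print.superpose_result <- function(x, ...) {
  cat(sprintf("<superposition> RMSD %.3f A over %d of %d C-alpha pairs\n",
              x$rmsd, x$n_retained, x$n_initial))
  invisible(x)
}

# --- superhelix geometry --------------------------------------------------

.repeat_centroids <- function(model, seg, chain = NULL) {
  chain <- if (!is.null(attr(seg, "chain"))) attr(seg, "chain") else
    .pick_chain(model, "protein", chain)
  a <- model$atoms
  ca <- a[a$chain == chain & a$atom == "CA", , drop = FALSE]
  t(vapply(seq_len(nrow(seg)), function(i) {
    sel <- ca$resno >= seg$start_res[i] & ca$resno <= seg$end_res[i]
    if (!any(sel)) stop("no C-alpha atoms in repeat ", i, call. = FALSE)
    colMeans(as.matrix(ca[sel, c("x", "y", "z")]))
  }, numeric(3)))
}

#' Superhelical parameters of a repeat solenoid
#'
#' Repeat centroids (mean C-alpha per repeat) are fitted with a helical
#' axis (principal direction of the centroids, oriented from the first
#' repeat to the last, i.e. N to C and hence 5' to 3' along the bound
#' RNA). Rise is the mean spacing of consecutive centroid projections on
#' the axis; twist is the mean signed angle between consecutive radial
#' vectors; period = rise x 360 / |twist|; diameter = 2 x mean centroid
#' radius. Positive twist about the oriented axis is a right-handed
#' superhelix.
#'
#' @param model a `structure_model`
#' @param seg a `repeat_segmentation` (or any data frame with `start_res`,
#'   `end_res`), at least 4 repeats
#' @param chain protein chain (default from `seg`)
#' @return a `superhelix_params` list: `axis`, `rise`, `twist`, `period`,
#'   `diameter`, `radius`, `handedness`
#' @export
superhelix <- function(model, seg, chain = NULL) {
  cen <- .repeat_centroids(model, seg, chain)
  n <- nrow(cen)
  if (n < 4L) stop("superhelix fit needs at least 4 repeats", call. = FALSE)
  # Axis direction: on an ideal helix the axial component of the
  # step vectors c[i+1]-c[i] is constant, so the second differences lie
  # exactly in the plane perpendicular to the axis. The axis is the null
  # direction (smallest principal component) of the second-difference
  # matrix -- exact for ideal helices, least-squares for real solenoids,
  # and immune to the partial-turn bias of centroid PCA.
  steps <- diff(cen)
  S <- diff(steps)
  if (max(abs(S)) < 1e-9) {
    stop("degenerate geometry: repeat centroids are collinear with the axis",
         call. = FALSE)
  }
  ev <- eigen(crossprod(S), symmetric = TRUE)
  axis <- ev$vectors[, 3]
  if (sum((cen[n, ] - cen[1, ]) * axis) < 0) axis <- -axis
  # in-plane basis and Kasa circle fit for the axis position
  e1 <- if (abs(axis[1]) < 0.9) pracma_cross(axis, c(1, 0, 0)) else
    pracma_cross(axis, c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(axis, e1)
  u <- as.numeric(cen %*% e1)
  v <- as.numeric(cen %*% e2)
  A <- cbind(2 * u, 2 * v, 1)
  sol <- tryCatch(qr.solve(A, u^2 + v^2), error = function(e) NULL)
  if (is.null(sol)) {
    stop("degenerate geometry: repeat centroids are collinear with the axis",
         call. = FALSE)
  }
  ru <- u - sol[1]
  rv <- v - sol[2]
  radii <- sqrt(ru^2 + rv^2)
  if (max(radii) < 1e-6) {
    stop("degenerate geometry: repeat centroids are collinear with the axis",
         call. = FALSE)
  }
  proj <- as.numeric(cen %*% axis)
  rise <- mean(diff(proj))
  # signed rotation of the radial vector between consecutive repeats,
  # right-handed about the (N-to-C oriented) axis
  angs <- atan2(ru[-n] * rv[-1] - rv[-n] * ru[-1],
                ru[-n] * ru[-1] + rv[-n] * rv[-1]) * 180 / pi
  twist <- mean(angs)
  structure(list(
    axis = axis, rise = rise, twist = twist,
    period = if (abs(twist) > 1e-12) rise * 360 / abs(twist) else Inf,
    radius = mean(radii), diameter = 2 * mean(radii),
    handedness = if (twist >= 0) "right" else "left",
    n_repeats = nrow(cen)
  ), class = "superhelix_params")
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' @export
print.superhelix_params <- function(x, ...) {
  cat(sprintf("<superhelix> %s-handed; rise %.2f A, twist %.2f deg, period %.1f A, diameter %.1f A (%d repeats)\n",
              x$handedness, x$rise, x$twist, x$period, x$diameter, x$n_repeats))
  invisible(x)
}

# --- hydrogen bonds and contacts ------------------------------------------

# Watson-Crick-face atoms read by the code residues
WC_FACE <- list(A = c("N1", "N3", "N6"), G = c("N1", "N2", "N3", "O6"),
                C = c("O2", "N3"), U = c("O2", "N3"))
PURINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.dist <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

# RNA residues of a chain in 5'-to-3' order (deposited numbering order)
.rna_residues <- function(model, rna_chain = NULL) {
  chain <- .pick_chain(model, "rna", rna_chain)
  a <- model$atoms
  resnos <- sort(unique(a$resno[a$chain == chain & a$class == "rna"]))
  list(chain = chain, resnos = resnos)
}

# Map repeat i to the i-th modelled nucleotide. The deposited complexes
# bind one nucleotide per repeat with repeat 1 facing the 5'-most
# modelled base; an offset shifts the register if a deposit differs.
.repeat_base_map <- function(seg, rna, register_offset = 0L) {
  idx <- seg$repeat_index + register_offset
  ifelse(idx >= 1L & idx <= length(rna$resnos), rna$resnos[idx], NA_integer_)
}

#' Detect base-recognition hydrogen bonds of the code residues
#'
#' Hydrogens are absent from the crystal structures, so a hydrogen bond is
#' called from heavy-atom geometry alone: a polar (N/O) side-chain atom of
#' a repeat's code residue (position 5 or 35) within `d_cutoff` of a
#' Watson-Crick-face atom of the aligned base (pyrimidines O2/N3; purines
#' N1/N2/N3/O6/N6). A water bridge is reported when one water oxygen lies
#' within the cutoff of both the base N3 and a polar side-chain atom of
#' the position-35 residue - the uracil/cytosine discrimination route.
#'
#' @param model a `structure_model` containing protein and RNA chains
#' @param seg a `repeat_segmentation`
#' @param d_cutoff heavy-atom distance cutoff in Angstrom (default 3.5)
#' @param include_water_bridges detect water-mediated bonds (default TRUE)
#' @param rna_chain RNA chain id (default: first RNA chain)
#' @param register_offset shift of the repeat-to-nucleotide register
#' @return list with `hbonds` (one row per contact: `repeat_index`,
#'   `position` (5/35), `prot_resno`, `prot_resname`, `prot_atom`,
#'   `base_resno`, `base`, `base_atom`, `distance`, `water_mediated`,
#'   `water_id`) and `per_repeat` counts (`direct5`, `direct35`, `water`)
#' @export
find_hbonds <- function(model, seg, d_cutoff = 3.5,
                        include_water_bridges = TRUE, rna_chain = NULL,
                        register_offset = 0L) {
  stopifnot(inherits(model, "structure_model"))
  rna <- .rna_residues(model, rna_chain)
  a <- model$atoms
  pchain <- attr(seg, "chain")
  if (is.null(pchain)) pchain <- .pick_chain(model, "protein")
  base_map <- .repeat_base_map(seg, rna, register_offset)
  waters <- a[a$class == "water" & a$element == "O", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(seg))) {
    bres <- base_map[i]
    if (is.na(bres)) next
    batoms <- a[a$chain == rna$chain & a$resno == bres, , drop = FALSE]
    base <- batoms$resname[1]
    face <- WC_FACE[[base]]
    if (is.null(face)) next
    bface <- batoms[batoms$atom %in% face, , drop = FALSE]
    for (pos in c(5L, 35L)) {
      presno <- if (pos == 5L) seg$code5_resno[i] else seg$code35_resno[i]
      pat <- a[a$chain == pchain & a$resno == presno & a$class == "protein" &
               !(a$atom %in% BACKBONE_ATOMS) & a$element %in% c("N", "O"), ,
               drop = FALSE]
      if (!nrow(pat)) next
      for (ip in seq_len(nrow(pat))) for (ib in seq_len(nrow(bface))) {
        d <- .dist(pat[ip, ], bface[ib, ])
        if (d <= d_cutoff) {
          rows[[length(rows) + 1L]] <- data.frame(
            repeat_index = i, position = pos,
            prot_resno = presno, prot_resname = pat$resname[ip],
            prot_atom = pat$atom[ip],
            base_resno = bres, base = base, base_atom = bface$atom[ib],
            distance = d, water_mediated = FALSE, water_id = NA_character_,
            stringsAsFactors = FALSE)
        }
      }
      if (include_water_bridges && pos == 35L && nrow(waters)) {
        n3 <- batoms[batoms$atom == "N3", , drop = FALSE]
        if (nrow(n3)) {
          for (iw in seq_len(nrow(waters))) {
            dw_base <- .dist(waters[iw, ], n3[1, ])
            if (dw_base > d_cutoff) next
            for (ip in seq_len(nrow(pat))) {
              dw_prot <- .dist(waters[iw, ], pat[ip, ])
              if (dw_prot <= d_cutoff) {
                rows[[length(rows) + 1L]] <- data.frame(
                  repeat_index = i, position = 35L,
                  prot_resno = presno, prot_resname = pat$resname[ip],
                  prot_atom = pat$atom[ip],
                  base_resno = bres, base = base, base_atom = "N3",
                  distance = max(dw_base, dw_prot), water_mediated = TRUE,
                  water_id = paste0(waters$chain[iw], waters$resno[iw]),
                  stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
    }
  }
  hb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(repeat_index = integer(0), position = integer(0),
               prot_resno = integer(0), prot_resname = character(0),
               prot_atom = character(0), base_resno = integer(0),
               base = character(0), base_atom = character(0),
               distance = numeric(0), water_mediated = logical(0),
               water_id = character(0), stringsAsFactors = FALSE)
  per <- data.frame(
    repeat_index = seg$repeat_index,
    direct5 = vapply(seg$repeat_index, function(i) {
      sum(hb$repeat_index == i & hb$position == 5L & !hb$water_mediated)
    }, integer(1)),
    direct35 = vapply(seg$repeat_index, function(i) {
      sum(hb$repeat_index == i & hb$position == 35L & !hb$water_mediated)
    }, integer(1)),
    water = vapply(seg$repeat_index, function(i) {
      length(unique(hb$water_id[hb$repeat_index == i & hb$water_mediated]))
    }, integer(1))
  )
  list(hbonds = hb, per_repeat = per)
}

#' Val2 sandwich and Lys13-phosphate contact report
#'
#' Residue 2 of each repeat (the hydrophobic clamp, valine in the
#' scaffold) is checked for side-chain heavy atoms within `val2_cutoff` of
#' the ring atoms of its own aligned base and of the preceding repeat's
#' base - together with the next repeat's Val2 each base is clamped in a
#' sandwich. Residue 13 (the phosphate-binding lysine) is checked for an
#' NZ nitrogen within `salt_cutoff` of any RNA phosphate oxygen.
#'
#' @param model a `structure_model`
#' @param seg a `repeat_segmentation`
#' @param val2_cutoff van der Waals contact cutoff in Angstrom (default 4.5)
#' @param salt_cutoff salt-bridge cutoff in Angstrom (default 4.0)
#' @param rna_chain RNA chain id
#' @param register_offset repeat-to-nucleotide register shift
#' @return data frame, one row per repeat: `repeat_index`, `val2_resno`,
#'   `val2_own_base`, `val2_prev_base` (contact flags), `lys13_resno`,
#'   `salt_bridge`, `salt_partner`, `incomplete` (side chain missing)
#' @export
contact_report <- function(model, seg, val2_cutoff = 4.5, salt_cutoff = 4.0,
                           rna_chain = NULL, register_offset = 0L) {
  rna <- .rna_residues(model, rna_chain)
  a <- model$atoms
  pchain <- attr(seg, "chain")
  if (is.null(pchain)) pchain <- .pick_chain(model, "protein")
  base_map <- .repeat_base_map(seg, rna, register_offset)
  phos <- a[a$chain == rna$chain & a$class == "rna" &
            a$atom %in% c("OP1", "OP2", "OP3", "O5'", "O3'") &
            a$element == "O", , drop = FALSE]
  ring_atoms <- function(bres) {
    if (is.na(bres)) return(a[0, , drop = FALSE])
    b <- a[a$chain == rna$chain & a$resno == bres, , drop = FALSE]
    ring <- if (b$resname[1] %in% c("A", "G")) PURINE_RING else PYRIMIDINE_RING
    b[b$atom %in% ring, , drop = FALSE]
  }
  min_dist <- function(set_a, set_b) {
    if (!nrow(set_a) || !nrow(set_b)) return(Inf)
    min(vapply(seq_len(nrow(set_a)), function(i) {
      min(.dist(set_a[i, ], set_b))
    }, numeric(1)))
  }
  out <- lapply(seq_len(nrow(seg)), function(i) {
    v2_resno <- seg$start_res[i] + 1L
    k13_resno <- seg$start_res[i] + 12L
    v2 <- a[a$chain == pchain & a$resno == v2_resno &
            !(a$atom %in% BACKBONE_ATOMS) & a$element == "C", , drop = FALSE]
    nz <- a[a$chain == pchain & a$resno == k13_resno & a$atom == "NZ", ,
            drop = FALSE]
    own <- min_dist(v2, ring_atoms(base_map[i]))
    prev <- if (i > 1L) min_dist(v2, ring_atoms(base_map[i - 1L])) else Inf
    salt <- FALSE; partner <- NA_character_
    if (nrow(nz) && nrow(phos)) {
      dd <- vapply(seq_len(nrow(phos)), function(j) .dist(nz[1, ], phos[j, ]),
                   numeric(1))
      if (min(dd) <= salt_cutoff) {
        salt <- TRUE
        j <- which.min(dd)
        partner <- paste0(phos$resname[j], phos$resno[j], ":", phos$atom[j])
      }
    }
    data.frame(repeat_index = i, val2_resno = v2_resno,
               val2_own_base = is.finite(own) && own <= val2_cutoff,
               val2_prev_base = is.finite(prev) && prev <= val2_cutoff,
               lys13_resno = k13_resno, salt_bridge = salt,
               salt_partner = partner,
               incomplete = !nrow(v2) || !nrow(nz),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
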