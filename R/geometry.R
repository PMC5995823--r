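#' Ideal backbone geometry constants
#'
#' Fixed bond lengths and angles used by the internal-coordinate backbone
#' builder.  Values follow standard peptide geometry (Engh-Huber-like);
#' the peptide bond is held planar trans (omega = 180).  Trial structures
#' built with these constants are intended as starting points for external
#' geometry optimisation, not as final structures.
#'
#' @param n_ca,ca_c,c_n,c_o Bond lengths in Angstrom.
#' @param ang_n_ca_c,ang_ca_c_n,ang_c_n_ca,ang_ca_c_o Bond angles in degrees.
#' @param ang_n_ca_cb,ca_cb CB placement angle (deg) and bond length (A).
#' @param omega Peptide-bond torsion in degrees (fixed).
#' @return A list of class `backbone_geometry`.
#' @export
backbone_geometry <- function(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                              c_o = 1.231, ang_n_ca_c = 111.2,
                              ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                              ang_ca_c_o = 120.8, ang_n_ca_cb = 110.4,
                              ca_cb = 1.521, omega = 180) {
  g <- list(n_ca = n_ca, ca_c = ca_c, c_n = c_n, c_o = c_o,
            ang_n_ca_c = ang_n_ca_c, ang_ca_c_n = ang_ca_c_n,
            ang_c_n_ca = ang_c_n_ca, ang_ca_c_o = ang_ca_c_o,
            ang_n_ca_cb = ang_n_ca_cb, ca_cb = ca_cb, omega = omega)
  lens <- c(g$n_ca, g$ca_c, g$c_n, g$c_o, g$ca_cb)
  angs <- c(g$ang_n_ca_c, g$ang_ca_c_n, g$ang_c_n_ca, g$ang_ca_c_o,
            g$ang_n_ca_cb)
  if (any(lens <= 0)) stop("bond lengths must be positive")
  if (any(angs <= 0 | angs >= 180)) stop("bond angles must lie in (0, 180)")
  structure(g, class = "backbone_geometry")
}

## internal: torsion angle (degrees, IUPAC sign) of four points (rows or vecs)
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  wrap_angle(-atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

## internal: NeRF placement -- position d bonded to c with
## |cd| = bond, angle(b,c,d) = ang, torsion(a,b,c,d) = tor (degrees)
place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  nxbc <- c(n[2] * bc[3] - n[3] * bc[2],
            n[3] * bc[1] - n[1] * bc[3],
            n[1] * bc[2] - n[2] * bc[1])
  c + d2[1] * bc + d2[2] * nxbc + d2[3] * n
}

#' Build Cartesian backbone coordinates from a phi-psi unit string
#'
#' Realises a conformer as 3D coordinates by sequential internal-coordinate
#' (natural extension reference frame) construction with fixed ideal bond
#' lengths and angles and planar trans peptide bonds.  Atoms emitted per
#' residue: N, CA, C, O, plus CB for non-glycine residues; the final residue
#' additionally carries OXT.  The psi torsion of residue 1 is not part of any
#' unit and is fixed at 180 (extended); the psi of the final residue closes
#' on OXT, and O sits trans to it.  Termini are built neutral (no hydrogens,
#' no charged groups).
#'
#' @param units Matrix with columns `phi`, `psi` (one row per unit, degrees),
#'   or a numeric vector `c(phi1, psi1, phi2, ...)`.
#' @param sequence One-letter sequence; `length(units) == nchar(sequence)-1`.
#' @param geometry A [backbone_geometry()].
#' @return Data frame with columns `resno`, `resid` (three-letter code),
#'   `atom`, `x`, `y`, `z` (Angstrom).
#' @examples
#' xyz <- build_backbone(cbind(phi = -60, psi = -45), "GG")
#' @export
build_backbone <- function(units, sequence, geometry = backbone_geometry()) {
  if (is.null(dim(units))) units <- matrix(units, ncol = 2, byrow = TRUE)
  units <- as.matrix(units)
  if (ncol(units) != 2) stop("'units' must have two columns (phi, psi)")
  if (any(!is.finite(units)) || any(units <= -180) || any(units > 180))
    stop("unit angles must be finite and in (-180, 180]")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (nrow(units) != n - 1L)
    stop("need ", n - 1L, " units for a ", n, "-residue peptide")
  g <- geometry
  aa <- strsplit(sequence, "")[[1]]
  phi <- c(NA, units[, 1])          # phi of residue i (i >= 2)
  psi <- c(180, units[, 2])         # psi of residue i; residue 1 fixed

  N <- CA <- C <- vector("list", n)
  rows <- list()
  add <- function(resno, atom, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      resno = resno, resid = aa3(aa[resno]), atom = atom,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)

  # residue 1: N at the origin, CA on +x, C in the xy-plane
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  C[[1]] <- CA[[1]] + g$ca_c *
    c(-cos(g$ang_n_ca_c * pi / 180), sin(g$ang_n_ca_c * pi / 180), 0)
  for (i in seq_len(n - 1L)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], g$c_n, g$ang_ca_c_n,
                             psi[i])
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]], g$n_ca,
                              g$ang_c_n_ca, g$omega)
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], g$ca_c,
                             g$ang_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(n)) {
    add(i, "N", N[[i]])
    add(i, "CA", CA[[i]])
    if (aa[i] != "G")
      add(i, "CB", place_atom(C[[i]], N[[i]], CA[[i]], g$ca_cb,
                              g$ang_n_ca_cb, 122.6))
    add(i, "C", C[[i]])
    if (i < n) {
      add(i, "O", place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o,
                             wrap_angle(psi[i] + 180)))
    } else {
      add(i, "O", place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o,
                             wrap_angle(psi[i] + 180)))
      add(i, "OXT", place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o,
                               psi[i]))
    }
  }
  do.call(rbind, rows)
}

#' Extract phi-psi units from backbone coordinates
#'
#' Unit i (i = 1 .. n-1) carries the dihedrals of residue i + 1:
#' phi from C(i)-N(i+1)-CA(i+1)-C(i+1) and psi from
#' N(i+1)-CA(i+1)-C(i+1)-X, where X is N(i+2) for interior residues and the
#' carboxyl oxygen (OXT if present, else O) for the final residue.
#'
#' @param coords Data frame as produced by [build_backbone()] (columns
#'   `resno`, `atom`, `x`, `y`, `z`).
#' @return Matrix with columns `phi`, `psi`, one row per unit (degrees).
#' @export
extract_units <- function(coords) {
  stopifnot(is.data.frame(coords),
            all(c("resno", "atom", "x", "y", "z") %in% names(coords)))
  resnos <- sort(unique(coords$resno))
  n <- length(resnos)
  if (n < 2L) stop("need at least 2 residues to define a phi-psi unit")
  atom_xyz <- function(resno, atom) {
    r <- coords[coords$resno == resno & coords$atom == atom, , drop = FALSE]
    if (nrow(r) < 1L) stop("missing backbone atom ", atom,
                           " of residue ", resno)
    as.numeric(r[1, c("x", "y", "z")])
  }
  has_atom <- function(resno, atom)
    any(coords$resno == resno & coords$atom == atom)
  out <- matrix(NA_real_, n - 1L, 2, dimnames = list(NULL, c("phi", "psi")))
  for (i in seq_len(n - 1L)) {
    r <- resnos[i + 1L]
    ci <- atom_xyz(resnos[i], "C")
    ni <- atom_xyz(r, "N"); cai <- atom_xyz(r, "CA"); cci <- atom_xyz(r, "C")
    out[i, "phi"] <- dihedral_angle(ci, ni, cai, cci)
    xo <- if (i + 1L < n) atom_xyz(resnos[i + 2L], "N")
          else if (has_atom(r, "OXT")) atom_xyz(r, "OXT")
          else atom_xyz(r, "O")
    out[i, "psi"] <- dihedral_angle(ni, cai, cci, xo)
  }
  out
}

## internal: one-letter -> three-letter residue codes
aa3 <- function(x) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- map[x]
  if (anyNA(out)) stop("unknown residue code(s): ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

aa1 <- function(x) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  out <- map[toupper(x)]
  if (anyNA(out)) stop("unknown residue code(s): ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}
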