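#' Read a conformer ensemble from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`csv`}{One conformer per row, columns `phi1,psi1,phi2,psi2,...`
#'     in degrees, optional `energy` (kcal/mol) and `id` columns.}
#'   \item{`pdb`}{Multi-model PDB (`MODEL`/`ENDMDL` blocks; a file without
#'     `MODEL` records is read as one conformer).  Energies are taken from a
#'     per-model `REMARK ... ENERGY <value>` line when present.  Models
#'     missing any of N, CA, C for a residue (or a carboxyl oxygen on the
#'     last residue) are rejected with a message.}
#'   \item{`xyz`}{Multi-frame XYZ in the package's atom-name dialect (atom
#'     labels N/CA/CB/C/O/OXT rather than bare elements); the frame comment
#'     line may carry `ENERGY <value>`.}
#' }
#' Energies, when present, are re-based so the ensemble minimum is 0.
#'
#' @param path File path.
#' @param peptide One-letter sequence of the peptide.  Required for `csv`
#'   and `xyz`; for `pdb` it is checked against the residue records.
#' @param format `"csv"`, `"pdb"` or `"xyz"`; default guessed from the file
#'   extension.
#' @param energy_window Low-energy window in kcal/mol (default 10).
#' @return A [phipsi_ensemble()].
#' @export
read_ensemble <- function(path, peptide = NULL, format = NULL,
                          energy_window = 10) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", pdb = "pdb", xyz = "xyz",
                     stop("cannot guess format of ", path))
  format <- match.arg(format, c("csv", "pdb", "xyz"))
  switch(format,
         csv = read_ensemble_csv(path, peptide, energy_window),
         pdb = read_ensemble_pdb(path, peptide, energy_window),
         xyz = read_ensemble_xyz(path, peptide, energy_window))
}

read_ensemble_csv <- function(path, peptide, energy_window) {
  if (is.null(peptide)) stop("'peptide' is required for CSV input")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty ensemble file: ", path)
  k <- nchar(peptide) - 1L
  pcols <- paste0("phi", seq_len(k)); scols <- paste0("psi", seq_len(k))
  miss <- setdiff(c(pcols, scols), names(d))
  if (length(miss))
    stop("CSV is missing columns: ", paste(miss, collapse = ", "))
  phipsi_ensemble(peptide,
                  phi = as.matrix(d[pcols]), psi = as.matrix(d[scols]),
                  energy = if ("energy" %in% names(d)) d$energy else NULL,
                  id = if ("id" %in% names(d)) d$id else NULL,
                  energy_window = energy_window)
}

## internal: split PDB text into model blocks (whole file if no MODEL lines)
pdb_model_blocks <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records")
  Map(function(s, e) lines[s:e], starts, ends)
}

read_ensemble_pdb <- function(path, peptide, energy_window) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty ensemble file: ", path)
  blocks <- pdb_model_blocks(lines)
  units <- list(); energies <- c(); seq_seen <- NULL; kept <- 0L
  for (bi in seq_along(blocks)) {
    blk <- blocks[[bi]]
    tf <- tempfile(fileext = ".pdb")
    writeLines(c(blk[grepl("^(ATOM|HETATM|TER)", blk)], "END"), tf)
    pdb <- try(bio3d::read.pdb(tf, verbose = FALSE), silent = TRUE)
    unlink(tf)
    if (inherits(pdb, "try-error")) {
      message("model ", bi, " rejected: unparseable ATOM records")
      next
    }
    at <- pdb$atom
    coords <- data.frame(resno = at$resno, atom = at$elety,
                         x = at$x, y = at$y, z = at$z,
                         stringsAsFactors = FALSE)
    resnos <- sort(unique(coords$resno))
    need_ok <- all(vapply(resnos, function(r) {
      a <- coords$atom[coords$resno == r]
      all(c("N", "CA", "C") %in% a)
    }, TRUE)) && any(coords$atom[coords$resno == max(resnos)] %in%
                       c("O", "OXT"))
    if (!need_ok || length(resnos) < 2L) {
      message("model ", bi, " rejected: missing backbone atoms")
      next
    }
    seq1 <- paste(aa1(at$resid[match(resnos, at$resno)]), collapse = "")
    if (is.null(seq_seen)) seq_seen <- seq1
    else if (seq1 != seq_seen) {
      message("model ", bi, " rejected: sequence mismatch")
      next
    }
    e <- parse_energy_line(blk[grepl("^REMARK", blk)])
    kept <- kept + 1L
    units[[kept]] <- extract_units(coords)
    energies[kept] <- e
  }
  if (kept == 0L) stop("no usable model in ", path)
  if (!is.null(peptide) && toupper(peptide) != seq_seen)
    stop("file contains ", seq_seen, ", not ", peptide)
  phi <- do.call(rbind, lapply(units, function(u) u[, "phi"]))
  psi <- do.call(rbind, lapply(units, function(u) u[, "psi"]))
  phipsi_ensemble(seq_seen, phi, psi,
                  energy = if (all(is.na(energies))) NULL else energies,
                  energy_window = energy_window)
}

parse_energy_line <- function(lines) {
  hits <- regmatches(lines, regexpr("ENERGY[_A-Z]*\\s+(-?[0-9.eE+-]+)",
                                    lines))
  if (length(hits) == 0L) return(NA_real_)
  as.numeric(sub("^ENERGY[_A-Z]*\\s+", "", hits[1]))
}

read_ensemble_xyz <- function(path, peptide, energy_window) {
  if (is.null(peptide)) stop("'peptide' is required for XYZ input")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty ensemble file: ", path)
  units <- list(); energies <- c(); i <- 1L; kept <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ atom-count line at line ", i)
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(body), "\\s+")
    coords <- data.frame(
      atom = vapply(tok, `[`, "", 1L),
      x = as.numeric(vapply(tok, `[`, "", 2L)),
      y = as.numeric(vapply(tok, `[`, "", 3L)),
      z = as.numeric(vapply(tok, `[`, "", 4L)),
      stringsAsFactors = FALSE)
    coords$resno <- cumsum(coords$atom == "N")
    kept <- kept + 1L
    units[[kept]] <- extract_units(coords)
    energies[kept] <- parse_energy_line(comment)
    i <- i + 2L + nat
  }
  phi <- do.call(rbind, lapply(units, function(u) u[, "phi"]))
  psi <- do.call(rbind, lapply(units, function(u) u[, "psi"]))
  phipsi_ensemble(peptide, phi, psi,
                  energy = if (all(is.na(energies))) NULL else energies,
                  energy_window = energy_window)
}

#' Write a conformer ensemble to disk
#'
#' Inverse of [read_ensemble()].  PDB output is one `MODEL`/`ENDMDL` block
#' per conformer (single chain A, residues from 1, no hydrogens) with the
#' relative energy on a `REMARK   1 ENERGY` line; XYZ output uses the
#' package's atom-name dialect with the energy in the comment line; CSV
#' output has columns `id, phi1, psi1, ..., energy`.  For PDB and XYZ the
#' Cartesian coordinates are rebuilt from the dihedrals with
#' [build_backbone()].
#'
#' @param ensemble A [phipsi_ensemble()].
#' @param path Output file.
#' @param format `"csv"`, `"pdb"` or `"xyz"`; default from the extension.
#' @param geometry A [backbone_geometry()] for coordinate rebuilding.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, format = NULL,
                           geometry = backbone_geometry()) {
  stopifnot(inherits(ensemble, "phipsi_ensemble"))
  if (n_conformers(ensemble) < 1L) stop("empty ensemble")
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", pdb = "pdb", xyz = "xyz",
                     stop("cannot guess format of ", path))
  format <- match.arg(format, c("csv", "pdb", "xyz"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(ensemble), path, row.names = FALSE,
                     quote = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  for (ci in seq_len(n_conformers(ensemble))) {
    u <- cbind(phi = ensemble$phi[ci, ], psi = ensemble$psi[ci, ])
    xyz <- build_backbone(u, ensemble$peptide, geometry)
    e <- ensemble$energy[ci]
    if (format == "pdb") {
      writeLines(sprintf("MODEL     %4d", ci), con)
      if (!is.na(e)) writeLines(sprintf("REMARK   1 ENERGY %10.4f", e), con)
      for (ai in seq_len(nrow(xyz))) {
        a <- xyz[ai, ]
        writeLines(sprintf(
          "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          ai, a$atom, a$resid, a$resno, a$x, a$y, a$z,
          substr(a$atom, 1, 1)), con)
      }
      writeLines("ENDMDL", con)
    } else {
      writeLines(as.character(nrow(xyz)), con)
      writeLines(if (is.na(e)) paste("conformer", ensemble$id[ci])
                 else sprintf("ENERGY %.6f", e), con)
      writeLines(sprintf("%-4s %12.6f %12.6f %12.6f",
                         xyz$atom, xyz$x, xyz$y, xyz$z), con)
    }
  }
  if (format == "pdb") writeLines("END", con)
  invisible(path)
}

#' Load the packaged pairwise error-rate matrix of the tri/tetrapeptide
#' learning set
#'
#' Returns the published 19x19 symmetric matrix of pairwise random-forest
#' classification error rates between the phi-psi units of the learning-set
#' peptides (GVGG, GTGG, GFGG, GTG, GVG, VGG, MGG, FGG).  Values are error
#' rates in \[0, 1\] reported to one decimal; the diagonal is undefined
#' (`NA`).  High error rate means the two units' phi-psi distributions are
#' hard to tell apart, i.e. similar.
#'
#' @return An [error_rate_matrix()] over the 19 unit labels.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_error_rates.csv",
                      package = "pepgrammar", mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- d$unit
  m <- as.matrix(d[, -1])
  rownames(m) <- labs
  if (!identical(labs, colnames(m)) || nrow(m) != 19L)
    stop("packaged error-rate table is corrupt (labels)")
  if (!isTRUE(all.equal(m, t(m))))
    stop("packaged error-rate table is corrupt (asymmetric)")
  if (round(sum(m[upper.tri(m)]) * 10) != 413)
    stop("packaged error-rate table is corrupt (checksum)")
  error_rate_matrix_obj(m)
}
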