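#' Wrap an angle into the canonical interval (-180, 180]
#'
#' All dihedral angles in the package are kept in degrees in the half-open
#' interval (-180, 180]; -180 is mapped to +180 so that every angle has a
#' single canonical representative.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector congruent to `x` modulo 360, in (-180, 180].
#' @examples
#' wrap_angle(c(0, 190, -180, 540))
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("angles must be finite numeric values")
  w <- x - 360 * floor(x / 360)        # [0, 360)
  w[w > 180] <- w[w > 180] - 360       # (-180, 180]
  w[w == -180] <- 180
  w
}

#' Shortest angular distance between two angles
#'
#' @param a,b Numeric vectors of angles in degrees (recycled).
#' @return Shortest distance on the circle, in degrees, in \[0, 180\].
#' @examples
#' circular_diff(179, -179)  # 2
#' @export
circular_diff <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b) ||
      any(!is.finite(a)) || any(!is.finite(b)))
    stop("angles must be finite numeric values")
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Parse a phi-psi unit label
#'
#' Unit labels are the lower-cased peptide sequence followed by a 1-based
#' unit index, e.g. `"gfgg2"` for the 2nd phi-psi unit of GFGG.  Unit i
#' carries the (phi, psi) pair of residue i + 1, so a peptide of n residues
#' has units 1 .. n - 1.
#'
#' @param text Character vector of labels.
#' @return A data frame with columns `peptide` (upper-case sequence) and
#'   `index` (integer unit index).
#' @examples
#' parse_unit_label("gfgg2")
#' @export
parse_unit_label <- function(text) {
  if (!is.character(text) || length(text) < 1L)
    stop("'text' must be a character vector")
  m <- regmatches(text, regexec("^([a-z]+)([0-9]+)$", text))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed unit label(s): ", paste(text[bad], collapse = ", "))
  pep <- toupper(vapply(m, `[`, "", 2L))
  idx <- as.integer(vapply(m, `[`, "", 3L))
  out_of_range <- idx < 1L | idx > nchar(pep) - 1L
  if (any(out_of_range))
    stop("unit index out of range (must be 1 .. n-1) in: ",
         paste(text[out_of_range], collapse = ", "))
  data.frame(peptide = pep, index = idx, stringsAsFactors = FALSE)
}

#' Format a phi-psi unit label
#'
#' Inverse of [parse_unit_label()].
#'
#' @param peptide Character vector of sequences (any case).
#' @param index Integer vector of 1-based unit indices.
#' @return Character vector of canonical labels such as `"gfgg2"`.
#' @export
format_unit_label <- function(peptide, index) {
  index <- as.integer(index)
  if (any(index < 1L | index > nchar(peptide) - 1L))
    stop("unit index out of range (must be 1 .. n-1)")
  paste0(tolower(peptide), index)
}

## internal: seeded evaluation that restores the RNG state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## internal: feature encoding of angle columns (degrees).
## "sincos": periodicity-respecting (sin, cos) pairs; "degrees": raw wrapped
## angles; "full": both, so tree splits can be axis-aligned in angle space
## while the sin/cos pair still disambiguates the wrap.
encode_angles <- function(m, encode = c("sincos", "degrees", "full")) {
  encode <- match.arg(encode)
  m <- as.matrix(m)
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("a", seq_len(ncol(m)))
  deg <- matrix(wrap_angle(m), nrow(m), ncol(m),
                dimnames = list(NULL, paste0("deg_", cn)))
  if (encode == "degrees") return(deg)
  rad <- m * pi / 180
  sc <- cbind(sin(rad), cos(rad))
  colnames(sc) <- c(paste0("sin_", cn), paste0("cos_", cn))
  if (encode == "sincos") sc else cbind(sc, deg)
}
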