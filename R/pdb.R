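# PDB coordinate input/output (wwPDB fixed-width dialect, via bio3d).

# Infer the chemical element from a PDB atom-name field: strip digits and
# primes, take the leading character (organic/protein atoms: C, N, O, H, S, P).
elementFromAtomName <- function(name) {
  nm <- gsub("[0-9' ]", "", toupper(name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "NA", "MG", "FE", "ZN", "SE"), two,
         substr(nm, 1, 1))
}

#' Read an atomic structure from a PDB file
#'
#' Parses ATOM and HETATM records of a wwPDB fixed-width file. The element
#' is taken from the element column (77-78) when present and inferred from
#' the atom-name field otherwise. Only the first model and the first
#' alternate conformer are kept. Waters (HOH/WAT/DOD) are excluded unless
#' requested.
#'
#' @param path Path to a PDB file.
#' @param includeWaters Keep water records (default `FALSE`).
#' @return An [AtomicStructure-class] with coordinates in Angstrom.
#' @export
readPdb <- function(path, includeWaters = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e)
      stop("PDB parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("empty structure: no ATOM/HETATM records in ", path, call. = FALSE)
  # first alternate conformer only
  if (!is.null(a$alt)) a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
  if (!includeWaters)
    a <- a[!toupper(a$resid) %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (nrow(a) == 0L)
    stop("empty structure: no non-water atoms in ", path, call. = FALSE)
  elesy <- if (!is.null(a$elesy)) trimws(toupper(a$elesy)) else rep("", nrow(a))
  element <- ifelse(nzchar(elesy) & !is.na(elesy), elesy,
                    elementFromAtomName(a$elety))
  AtomicStructure(element, a$x, a$y, a$z,
                  label = sub("\\.pdb$", "", basename(path)))
}

#' Write an atomic structure to a PDB file
#'
#' Emits ATOM records in the wwPDB fixed-width dialect; inverse of
#' [readPdb()] up to the retained fields.
#'
#' @param structure An [AtomicStructure-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePdb <- function(structure, path) {
  stopifnot(is(structure, "AtomicStructure"))
  a <- structure@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = seq_len(nrow(a)),
                   resid = rep("GLY", nrow(a)),
                   eleno = seq_len(nrow(a)),
                   elety = a$element,
                   elesy = a$element)
  invisible(path)
}
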