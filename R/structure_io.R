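# Reading and writing protein/ligand structures.  PDBQT follows the AutoDock
# fixed-column layout (partial charge in columns 71-76, atom type in 78-79);
# a whitespace-separated fallback with a warning tolerates sloppy writers.

#' Construct a protein structure
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `x`,
#'   `y`, `z`, `charge`, `vdw_radius`, `atom_type`.
#' @param id identifier string.
#' @return object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, id = "protein") {
  needed <- c("serial", "name", "element", "x", "y", "z", "charge",
              "vdw_radius", "atom_type")
  stopifnot(is.data.frame(atoms), all(needed %in% names(atoms)))
  if (nrow(atoms) == 0) stop("no atoms", call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("non-finite atom coordinates", call. = FALSE)
  if (any(atoms$vdw_radius <= 0)) stop("vdw_radius must be positive", call. = FALSE)
  structure(list(atoms = atoms, id = id), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure>", x$id, "-", nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param x a `protein_structure` or `ligand_structure`.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(x) {
  as.matrix(x$atoms[c("x", "y", "z")])
}

#' Construct a ligand structure
#'
#' The site center is the unweighted geometric mean of the ligand atom
#' positions and defines the "actual site" used in evaluation.
#'
#' @param atoms data.frame as in [protein_structure()].
#' @return object of class `ligand_structure` with a `site_center` field.
#' @export
ligand_structure <- function(atoms) {
  if (nrow(atoms) == 0) stop("empty ligand", call. = FALSE)
  lig <- structure(list(atoms = atoms), class = "ligand_structure")
  lig$site_center <- site_center(lig)
  lig
}

#' Geometric center of a ligand
#'
#' @param ligand a `ligand_structure` (or any object with an `atoms`
#'   data.frame).
#' @return numeric length-3 vector, Angstrom.
#' @export
site_center <- function(ligand) {
  if (is.null(ligand$atoms) || nrow(ligand$atoms) == 0)
    stop("empty ligand", call. = FALSE)
  unname(colMeans(ligand$atoms[c("x", "y", "z")]))
}

element_from_type <- function(type) {
  map <- c(C = "C", A = "C", N = "N", "NA" = "N", OA = "O", S = "S", SA = "S",
           H = "H", HD = "H", P = "P", F = "F", Cl = "Cl", Br = "Br", I = "I",
           Zn = "Zn", Ca = "Ca", Mg = "Mg", Mn = "Mn", Fe = "Fe")
  out <- unname(map[type])
  out[is.na(out)] <- type[is.na(out)]
  out
}

type_from_element <- function(element, name) {
  el <- toupper(element)
  map <- c(C = "C", N = "N", O = "OA", S = "SA", H = "HD", P = "P",
           F = "F", CL = "Cl", BR = "Br", I = "I", ZN = "Zn", CA = "Ca",
           MG = "Mg", MN = "Mn", FE = "Fe")
  out <- unname(map[el])
  miss <- is.na(out)
  if (any(miss)) {
    # fall back on the first letter of the atom name
    first <- toupper(substr(gsub("[^A-Za-z].*", "", name[miss]), 1, 1))
    out[miss] <- unname(map[first])
  }
  out
}

read_structure_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  list(records = lines[keep], lineno = which(keep))
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

parse_records <- function(records, lineno, charged) {
  if (length(records) == 0) stop("no atoms", call. = FALSE)
  f <- function(from, to) trimws(substring(records, from, to))
  serial <- num_or_na(f(7, 11))
  name <- f(13, 16)
  altloc <- substring(records, 17, 17)
  resname <- f(18, 20)
  chain <- substring(records, 22, 22)
  resseq <- f(23, 26)
  x <- num_or_na(f(31, 38))
  y <- num_or_na(f(39, 46))
  z <- num_or_na(f(47, 54))
  charge <- if (charged) num_or_na(f(71, 76)) else rep(0, length(records))
  type <- if (charged) f(78, 79) else f(77, 78)
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z) |
    (charged & !is.finite(charge))
  if (any(bad)) {
    # fixed columns failed: try whitespace-separated tokens for those lines
    warning("fixed-column parse failed for ", sum(bad),
            " record(s); falling back to whitespace splitting", call. = FALSE)
    for (i in which(bad)) {
      tok <- strsplit(trimws(records[i]), "\\s+")[[1]]
      nums <- num_or_na(tok)
      runs <- which(is.finite(nums))
      # coordinates are the first run of >= 3 consecutive numeric tokens
      # after the serial; take the last 3 of tokens 6..8 style layouts
      cand <- runs[runs >= 6]
      if (length(cand) < 3)
        stop("malformed record at line ", lineno[i], call. = FALSE)
      x[i] <- nums[cand[1]]; y[i] <- nums[cand[2]]; z[i] <- nums[cand[3]]
      if (charged) {
        charge[i] <- nums[cand[length(cand)]]
        type[i] <- tok[length(tok)]
      }
    }
    still <- !is.finite(x) | !is.finite(y) | !is.finite(z)
    if (any(still))
      stop("malformed record at line ", lineno[which(still)[1]], call. = FALSE)
  }
  data.frame(serial = serial, name = name, altloc = altloc, resname = resname,
             chain = chain, resseq = resseq, x = x, y = y, z = z,
             charge = charge, type = type, lineno = lineno,
             stringsAsFactors = FALSE)
}

# keep the first alternate location seen for each atom; blank altloc kept
filter_altloc <- function(df) {
  key <- paste(df$chain, df$resseq, df$resname, df$name)
  first <- match(key, key)
  keep <- df$altloc == " " | df$altloc == "" | df$altloc == df$altloc[first]
  df[keep, , drop = FALSE]
}

#' Parse an AutoDock PDBQT file
#'
#' Reads ATOM/HETATM records with partial charges (columns 71-76) and
#' AutoDock atom types (columns 78-79).  Atom order is preserved; the first
#' alternate location of each atom is kept; hydrogens are retained because
#' polar hydrogens (type HD) carry the hydrogen-bond donor role.
#'
#' @param path file path.
#' @param ff force-field table used to resolve van der Waals radii.
#' @param id structure identifier; defaults to the file name.
#' @return a `protein_structure`.
#' @export
parse_pdbqt <- function(path, ff = default_forcefield(), id = NULL) {
  rl <- read_structure_lines(path)
  df <- parse_records(rl$records, rl$lineno, charged = TRUE)
  df <- filter_altloc(df)
  rows <- ff_lookup(ff, df$type)
  atoms <- data.frame(serial = df$serial, name = df$name,
                      element = element_from_type(df$type),
                      x = df$x, y = df$y, z = df$z, charge = df$charge,
                      vdw_radius = rows$radius, atom_type = df$type,
                      stringsAsFactors = FALSE)
  protein_structure(atoms, id = if (is.null(id)) basename(path) else id)
}

#' Parse a PDB file
#'
#' Charges default to 0 (the PDB format carries none); atom types are derived
#' from the element column with name-based fallback, and van der Waals radii
#' come from the force-field table.
#'
#' @inheritParams parse_pdbqt
#' @param keep_waters keep HOH/WAT residues? Default FALSE.
#' @return a `protein_structure`.
#' @export
parse_pdb <- function(path, ff = default_forcefield(), id = NULL,
                      keep_waters = FALSE) {
  rl <- read_structure_lines(path)
  df <- parse_records(rl$records, rl$lineno, charged = FALSE)
  df <- filter_altloc(df)
  if (!keep_waters) df <- df[!df$resname %in% c("HOH", "WAT"), , drop = FALSE]
  if (nrow(df) == 0) stop("no atoms", call. = FALSE)
  type <- type_from_element(df$type, df$name)
  if (anyNA(type))
    stop("cannot type atom(s) at line(s) ",
         paste(df$lineno[is.na(type)], collapse = ", "), call. = FALSE)
  rows <- ff_lookup(ff, type)
  atoms <- data.frame(serial = df$serial, name = df$name,
                      element = element_from_type(type),
                      x = df$x, y = df$y, z = df$z, charge = 0,
                      vdw_radius = rows$radius, atom_type = type,
                      stringsAsFactors = FALSE)
  protein_structure(atoms, id = if (is.null(id)) basename(path) else id)
}

#' Read a ligand from PDB or PDBQT
#'
#' @inheritParams parse_pdbqt
#' @return a `ligand_structure` with its geometric `site_center`.
#' @export
read_ligand <- function(path, ff = default_forcefield()) {
  p <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE))
    parse_pdbqt(path, ff) else parse_pdb(path, ff, keep_waters = TRUE)
  ligand_structure(p$atoms)
}

#' Write a structure as PDBQT
#'
#' Positions and charges are written to 3 decimals in the AutoDock layout, so
#' a round trip through [parse_pdbqt()] reproduces them to format precision.
#'
#' @param protein a `protein_structure` or `ligand_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdbqt <- function(protein, path) {
  a <- protein$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
    a$serial %% 100000, substr(a$name, 1, 4), "UNK", "A", 1L,
    a$x, a$y, a$z, 1, 0, a$charge, a$atom_type)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
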