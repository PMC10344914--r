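#' @keywords internal
"_PACKAGE"

# van der Waals radii (Angstrom) used by all geometric operations.
# Fixed internal table for determinism; unknown elements fall back to carbon.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
.VDW_DEFAULT <- 1.70

vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

# Atomic masses for the mass-weighted radius of gyration.
.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974)
.MASS_DEFAULT <- 12.011

atomic_mass <- function(element) {
  m <- .ATOMIC_MASS[toupper(element)]
  m[is.na(m)] <- .MASS_DEFAULT
  unname(m)
}

#' Construct a molecular Structure
#'
#' A `Structure` is the container every geometric operation in the package
#' consumes: a flat atom table (one row per atom, with author residue
#' numbering kept verbatim) plus a coordinate array holding one or more
#' models. Multi-model structures double as trajectories when all models
#' share the same topology.
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resno`, `inscode`, `element`, `occupancy`,
#'   `bfactor`, `is_het`.
#' @param xyz numeric array `n_atoms x 3 x n_models` (a matrix is promoted
#'   to a single model).
#' @param header optional character vector of free-text provenance.
#' @return An object of class `Structure`.
#' @export
Structure <- function(atoms, xyz, header = character()) {
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3L, 1L))
  stopifnot(is.data.frame(atoms), length(dim(xyz)) == 3L, dim(xyz)[2] == 3L)
  if (nrow(atoms) != dim(xyz)[1]) {
    stop("atom table and coordinate array disagree on atom count")
  }
  if (dim(xyz)[3] < 1L) stop("a Structure needs at least one model")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique within a model")
  structure(list(atoms = atoms, xyz = xyz, header = header),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, %d chain(s), %d model(s)\n",
              nrow(x$atoms), n_residues(x), length(unique(x$atoms$chain)),
              n_models(x)))
  invisible(x)
}

#' Number of models (frames) in a Structure
#' @param s a `Structure`
#' @return integer model count
#' @export
n_models <- function(s) dim(s$xyz)[3]

#' Number of distinct residues in a Structure
#' @param s a `Structure`
#' @return integer residue count
#' @export
n_residues <- function(s) length(unique(residue_keys(s)))

# Residue key per atom row: chain|resno|inscode (author numbering).
residue_keys <- function(s) {
  a <- if (is.data.frame(s)) s else s$atoms
  paste(a$chain, a$resno, a$inscode, sep = "|")
}

#' Coordinates of one model
#' @param s a `Structure`
#' @param model 1-based model index
#' @return numeric matrix `n_atoms x 3`
#' @export
model_coords <- function(s, model = 1L) {
  if (model < 1L || model > n_models(s)) stop("model index out of range")
  m <- s$xyz[, , model, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Read a PDB file into a Structure
#'
#' Parses ATOM/HETATM records with fixed PDB columns; MODEL/ENDMDL blocks
#' become models of the returned `Structure`. Author residue numbering,
#' insertion codes and chains are preserved verbatim; HETATM records are
#' flagged so they can serve as ligand residues. When alternate locations
#' are present only the highest-occupancy conformer of each atom is kept
#' (with a warning), so downstream geometry is deterministic.
#'
#' @param path path to a PDB file.
#' @param format input format; only `"pdb"` is supported.
#' @return A [Structure].
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty PDB file: ", path)
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_idx) == 0L) stop("no ATOM/HETATM records in ", path)

  model_starts <- which(rec == "MODEL ")
  model_of_line <- cumsum(rec == "MODEL ")
  if (length(model_starts) == 0L) model_of_line <- model_of_line + 1L
  model_of_line[model_of_line == 0L] <- 1L

  parse_block <- function(idx) {
    ln <- lines[idx]
    bad <- which(nchar(ln) < 54)
    if (length(bad)) {
      stop("malformed ATOM/HETATM record at line ", idx[bad[1]],
           " (record shorter than coordinate fields)")
    }
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      first <- idx[which(is.na(x) | is.na(y) | is.na(z))[1]]
      stop("malformed coordinates at line ", first)
    }
    occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    occ[is.na(occ)] <- 1
    bf <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
    bf[is.na(bf)] <- 0
    el <- trimws(substr(ln, 77, 78))
    name <- trimws(substr(ln, 13, 16))
    # fall back to the leading letter(s) of the atom name when the element
    # column is blank (common in docking / modelling outputs)
    guess <- sub("^[0-9']*", "", name)
    guess <- toupper(substr(guess, 1, 1))
    el[!nzchar(el)] <- guess[!nzchar(el)]
    data.frame(
      serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
      name = name,
      altloc = substr(ln, 17, 17),
      resname = trimws(substr(ln, 18, 20)),
      chain = ifelse(nzchar(trimws(substr(ln, 22, 22))),
                     trimws(substr(ln, 22, 22)), "A"),
      resno = suppressWarnings(as.integer(substr(ln, 23, 26))),
      inscode = trimws(substr(ln, 27, 27)),
      element = toupper(el),
      occupancy = occ, bfactor = bf,
      is_het = substr(ln, 1, 6) == "HETATM",
      x = x, y = y, z = z,
      stringsAsFactors = FALSE
    )
  }

  models <- split(atom_idx, model_of_line[atom_idx])
  first <- parse_block(models[[1]])

  # altloc resolution: keep highest-occupancy conformer per atom site
  if (any(first$altloc != " " & first$altloc != "")) {
    site <- paste(first$chain, first$resno, first$inscode, first$name)
    keep <- unlist(lapply(split(seq_len(nrow(first)), site), function(i) {
      i[which.max(first$occupancy[i])]
    }), use.names = FALSE)
    keep <- sort(keep)
    if (length(keep) < nrow(first)) {
      warning("alternate locations found; keeping highest-occupancy conformer")
    }
    altkeep <- keep
  } else {
    altkeep <- seq_len(nrow(first))
  }

  atoms <- first[altkeep, c("serial", "name", "altloc", "resname", "chain",
                            "resno", "inscode", "element", "occupancy",
                            "bfactor", "is_het")]
  rownames(atoms) <- NULL
  rk <- paste(atoms$chain, atoms$resno, atoms$inscode, atoms$name)

  nm <- length(models)
  xyz <- array(NA_real_, dim = c(nrow(atoms), 3L, nm))
  xyz[, , 1] <- as.matrix(first[altkeep, c("x", "y", "z")])
  if (nm > 1L) {
    for (k in 2:nm) {
      blk <- parse_block(models[[k]])
      if (nrow(blk) != nrow(first)) {
        stop("model ", k, " has a different atom count than model 1")
      }
      xyz[, , k] <- as.matrix(blk[altkeep, c("x", "y", "z")])
    }
  }
  Structure(atoms, xyz,
            header = lines[rec %in% c("HEADER", "TITLE ", "REMARK")])
}

#' Write a Structure to a PDB file
#'
#' Multi-model structures are written as MODEL/ENDMDL blocks, so round trips
#' through [read_structure()] preserve the model count. Coordinates are
#' written at PDB precision (3 decimals).
#'
#' @param s a [Structure].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "Structure"))
  if (n_models(s) < 1L) stop("empty model list")
  a <- s$atoms
  name_fmt <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                     sprintf("%-4s", a$name))
  rectype <- ifelse(a$is_het, "HETATM", "ATOM  ")
  multi <- n_models(s) > 1L
  out <- character(0)
  for (k in seq_len(n_models(s))) {
    m <- model_coords(s, k)
    body <- sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    rectype, a$serial %% 100000L, name_fmt,
                    ifelse(nzchar(trimws(a$altloc)), a$altloc, " "),
                    a$resname, a$chain, a$resno %% 10000L,
                    ifelse(nzchar(a$inscode), a$inscode, " "),
                    m[, 1], m[, 2], m[, 3], a$occupancy, a$bfactor, a$element)
    if (multi) {
      out <- c(out, sprintf("MODEL %8d", k), body, "ENDMDL")
    } else {
      out <- c(out, body)
    }
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# Three-letter to one-letter amino-acid code, unknowns -> X.
.AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "U", PYL = "O")

#' Extract the one-letter sequence of a chain
#'
#' @param s a [Structure]; the first model's topology is used.
#' @param chain chain identifier.
#' @return list with `sequence` (one-letter string, unknown residues as
#'   `"X"`) and `numbering` (author residue numbers, parallel to the
#'   sequence).
#' @export
extract_sequence <- function(s, chain = "A") {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms[s$atoms$chain == chain & !s$atoms$is_het, , drop = FALSE]
  if (nrow(a) == 0L) stop("chain not found: ", chain)
  key <- paste(a$resno, a$inscode, sep = "|")
  first <- !duplicated(key)
  resn <- a$resname[first]
  one <- .AA321[resn]
  one[is.na(one)] <- "X"
  list(sequence = paste(one, collapse = ""), numbering = a$resno[first])
}

#' Select residues within a distance cutoff of a set of atoms
#'
#' Heavy-atom semantics: hydrogens are ignored on the protein side, matching
#' the convention of docking and structure-prediction outputs that usually
#' lack them. A residue qualifies when at least one of its heavy atoms lies
#' within `cutoff` Angstrom of any center atom.
#'
#' @param s a [Structure] (first model used unless `model` given).
#' @param center numeric matrix `m x 3` of center coordinates, or an atom
#'   index vector into `s`.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @param model model index.
#' @return data.frame of qualifying residues (`chain`, `resno`, `inscode`,
#'   `resname`) in structure order.
#' @export
select_within <- function(s, center, cutoff, model = 1L) {
  stopifnot(inherits(s, "Structure"))
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- model_coords(s, model)
  if (!is.matrix(center)) {
    center <- xyz[center, , drop = FALSE]
  }
  if (nrow(center) == 0L) stop("empty center set")
  heavy <- s$atoms$element != "H"
  idx <- which(heavy)
  d2 <- min_dist2_to_set(xyz[idx, , drop = FALSE], center)
  hit <- idx[d2 <= cutoff^2]
  key <- residue_keys(s)
  sel <- key %in% unique(key[hit])
  a <- s$atoms[sel & !duplicated(key), c("chain", "resno", "inscode", "resname")]
  rownames(a) <- NULL
  a
}

# Squared distance from each row of `pts` to its nearest row of `ref`.
min_dist2_to_set <- function(pts, ref) {
  # ||p - r||^2 = |p|^2 + |r|^2 - 2 p.r ; vectorized over both sets
  p2 <- rowSums(pts^2)
  r2 <- rowSums(ref^2)
  cross <- pts %*% t(ref)
  d2 <- outer(p2, r2, "+") - 2 * cross
  d2[d2 < 0] <- 0
  apply(d2, 1, min)
}

#' Define a ligand pose
#'
#' A ligand is exactly one residue (multi-residue selections are rejected:
#' BHET and its relatives are single small molecules). The optional binding
#' energy is an ingested docking result, never computed here.
#'
#' @param s a [Structure] containing the ligand residue.
#' @param resname ligand residue name (e.g. `"BHT"`).
#' @param binding_energy optional docking binding energy, kcal/mol.
#' @param pose_id identifier.
#' @param model model index to take coordinates from.
#' @return An object of class `LigandPose` with fields `atoms`, `xyz`,
#'   `binding_energy`, `pose_id`.
#' @export
ligand_pose <- function(s, resname, binding_energy = NULL,
                        pose_id = resname, model = 1L) {
  stopifnot(inherits(s, "Structure"))
  sel <- s$atoms$resname == resname
  if (!any(sel)) stop("ligand residue not found: ", resname)
  keys <- unique(residue_keys(s)[sel])
  if (length(keys) > 1L) {
    stop("ligand '", resname, "' spans ", length(keys),
         " residues; a ligand must be exactly one residue")
  }
  structure(list(atoms = s$atoms[sel, , drop = FALSE],
                 xyz = model_coords(s, model)[sel, , drop = FALSE],
                 binding_energy = binding_energy, pose_id = pose_id),
            class = "LigandPose")
}

#' Define a catalytic site around a nucleophilic serine
#'
#' The serine hydroxyl oxygen (atom `OG`) anchors every site-based
#' measurement: attack distances, site occupancy, the substrate binding
#' cleft proxy.
#'
#' @param s a [Structure].
#' @param chain chain of the catalytic Ser.
#' @param resno author residue number of the catalytic Ser.
#' @param label free-text label (e.g. `"S189"`).
#' @return An object of class `CatalyticSite` with the atom index of OG.
#' @export
catalytic_site <- function(s, chain, resno, label = paste0("S", resno)) {
  stopifnot(inherits(s, "Structure"))
  i <- which(s$atoms$chain == chain & s$atoms$resno == resno &
               s$atoms$name == "OG")
  if (length(i) == 0L) {
    stop("no OG atom on residue ", chain, ":", resno,
         "; the catalytic Ser must carry its hydroxyl oxygen")
  }
  structure(list(chain = chain, resno = resno, og_index = i[1], label = label),
            class = "CatalyticSite")
}

#' Apply a rigid transform to a Structure
#'
#' @param s a [Structure].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 shift, Angstrom.
#' @return transformed [Structure].
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(s, "Structure"))
  out <- s
  for (k in seq_len(n_models(s))) {
    out$xyz[, , k] <- sweep(model_coords(s, k) %*% t(rotation), 2,
                            translation, "+")
  }
  out
}
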