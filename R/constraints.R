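#' Minimal PDB coordinate reader
#'
#' Parses `ATOM`/`HETATM` records from a PDB file using the wwPDB
#' fixed-width columns (no installed package provides this, so the few
#' needed fields are read directly). Only fields required for constraint
#' measurement are kept.
#'
#' @param path PDB file path.
#' @return `data.frame` with `record`, `atom_name`, `res_name`, `chain`,
#'   `res_seq`, `x`, `y`, `z`.
#' @export
read_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM  |HETATM)", lines)]
  assert_that(length(lines) > 0, "no ATOM/HETATM records in %s", path)
  fw <- function(l, a, b) trimws(substr(l, a, b))
  data.frame(
    record    = fw(lines, 1, 6),
    atom_name = fw(lines, 13, 16),
    res_name  = fw(lines, 18, 20),
    chain     = fw(lines, 22, 22),
    res_seq   = as.integer(fw(lines, 23, 26)),
    x = as.numeric(fw(lines, 31, 38)),
    y = as.numeric(fw(lines, 39, 46)),
    z = as.numeric(fw(lines, 47, 54)),
    stringsAsFactors = FALSE)
}

# coordinates of one referenced atom; errors name the missing atom
atom_xyz <- function(atoms, ref) {
  hit <- atoms$chain == ref$chain & atoms$res_seq == ref$res_seq &
    atoms$atom_name == ref$atom
  assert_that(sum(hit) >= 1, "atom not found: chain %s residue %s atom %s",
              ref$chain, ref$res_seq, ref$atom)
  as.numeric(atoms[which(hit)[1], c("x", "y", "z")])
}

#' Dihedral angle of four points
#'
#' Standard atan2 formulation; degrees in (-180, 180]. 0 corresponds to a
#' cis arrangement of the outer atoms (as in the cis-peptide-bond
#' restraint between the acetyl-lysine and the following residue).
#'
#' @param p1,p2,p3,p4 numeric xyz triples.
#' @return angle in degrees.
#' @export
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
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Constraint specifications for catalysis-competent binding
#'
#' A constraint references atoms of the receptor-peptide complex and, once
#' measured on a structure, carries a target value. Three classes encode
#' the geometry that must hold for catalysis: `zinc_coordination` (atoms
#' positioning the catalytic Zn2+), `acetyl_lysine_pocket` (acetyl-lysine
#' side chain in the channel) and `cis_peptide` (the dihedral between
#' peptide residues 3 and 4 enforcing a cis-peptide bond).
#'
#' @param kind `"atom_pair"` (2 atoms, Angstrom target) or `"dihedral"`
#'   (4 atoms, degree target).
#' @param atoms list of atom references, each
#'   `list(chain =, res_seq =, atom =)`.
#' @param class constraint class label.
#' @param tolerance harmonic standard deviation (Angstrom or degrees).
#' @param target measured target value; usually filled by
#'   [measure_constraints()].
#' @export
constraint_spec <- function(kind = c("atom_pair", "dihedral"), atoms,
                            class = c("zinc_coordination",
                                      "acetyl_lysine_pocket", "cis_peptide"),
                            tolerance = 0.2, target = NA_real_) {
  kind <- match.arg(kind)
  class <- match.arg(class)
  need <- if (kind == "atom_pair") 2L else 4L
  assert_that(length(atoms) == need, "%s constraint needs %d atoms", kind, need)
  assert_that(is_number(tolerance) && tolerance > 0, "tolerance must be > 0")
  structure(list(kind = kind, atoms = atoms, class = class,
                 tolerance = tolerance, target = target),
            class = "constraint_spec")
}

#' Measure constraint targets on a structure
#'
#' Fills the `target` of each constraint from the coordinates of the given
#' structure: Euclidean distance in Angstrom for atom pairs, dihedral in
#' degrees (-180, 180] for four-atom constraints. Constraints are always
#' measured on the structure the protocol will use, so templates with
#' slightly different geometry get self-consistent restraints.
#'
#' @param structure path to a PDB file, or the `data.frame` from
#'   [read_pdb_atoms()].
#' @param specs list of [constraint_spec()]s (targets may be `NA`).
#' @return the specs with `target` filled.
#' @export
measure_constraints <- function(structure, specs) {
  atoms <- if (is.character(structure)) read_pdb_atoms(structure) else structure
  lapply(specs, function(sp) {
    xyz <- lapply(sp$atoms, function(a) atom_xyz(atoms, a))
    sp$target <- if (sp$kind == "atom_pair") {
      sqrt(sum((xyz[[1]] - xyz[[2]])^2))
    } else {
      dihedral_angle(xyz[[1]], xyz[[2]], xyz[[3]], xyz[[4]])
    }
    sp
  })
}

#' Write constraints in the external engine dialect
#'
#' Emits `AtomPair a1 r1 a2 r2 HARMONIC target sd` and
#' `Dihedral a1 r1 ... a4 r4 CIRCULARHARMONIC target_rad sd_rad` lines
#' (dihedral targets are converted to radians, per the dialect).
#'
#' @param specs measured [constraint_spec()]s.
#' @param path output path.
#' @export
write_constraint_file <- function(specs, path) {
  lines <- vapply(specs, function(sp) {
    assert_that(is_number(sp$target), "constraint target not measured")
    at <- vapply(sp$atoms, function(a) sprintf("%s %d", a$atom, a$res_seq),
                 character(1))
    if (sp$kind == "atom_pair") {
      sprintf("AtomPair %s HARMONIC %.3f %.3f",
              paste(at, collapse = " "), sp$target, sp$tolerance)
    } else {
      sprintf("Dihedral %s CIRCULARHARMONIC %.4f %.4f",
              paste(at, collapse = " "),
              sp$target * pi / 180, sp$tolerance * pi / 180)
    }
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
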