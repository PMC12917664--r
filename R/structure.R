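#' Read a protein-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), splits atoms into protein and
#' ligand by residue name, and keeps per-model coordinates for multi-model
#' files (docking poses, MD snapshots).
#'
#' @param file Path to a PDB file.
#' @param ligand_resname Residue name(s) identifying the ligand (default
#'   `c("LIG", "UNL")`).
#' @return An object of class `complex_structure`: a list with `atoms`
#'   (data.frame: serial, name, element, resname, resno, chain, is_ligand),
#'   `coords` (list of n_atoms x 3 matrices, one per model), `n_models`,
#'   and `ligand_resname`.
#' @export
read_complex <- function(file, ligand_resname = c("LIG", "UNL")) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) elem <- NA
  guess <- sub("^[0-9]*", "", at$elety)
  guess <- toupper(substr(guess, 1, 1))
  elem <- ifelse(is.na(elem) | elem == "", guess, toupper(trimws(elem)))
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      element = elem, resname = trimws(at$resid),
                      resno = at$resno, chain = at$chain,
                      stringsAsFactors = FALSE)
  atoms$is_ligand <- atoms$resname %in% ligand_resname
  if (!any(atoms$is_ligand))
    stop("no ligand atoms found for residue name(s): ",
         paste(ligand_resname, collapse = ", "))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords <- lapply(seq_len(nrow(xyz)),
                   function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  structure(list(atoms = atoms, coords = coords, n_models = length(coords),
                 ligand_resname = ligand_resname),
            class = "complex_structure")
}

#' Residues in contact with the ligand
#'
#' A protein residue is a contact if any of its (heavy, by default) atoms
#' lies within `cutoff` of any ligand heavy atom. Reports the minimum
#' atom-pair distance and the number of atom pairs within the cutoff per
#' residue, sorted by minimum distance.
#'
#' @param structure A [read_complex()] result.
#' @param cutoff Contact distance cutoff in Angstrom (default 3.4).
#' @param model Model index (default 1).
#' @param include_hydrogens Include hydrogen atoms in the distance scan
#'   (default FALSE; docking and MD structures often lack them anyway).
#' @return An object of class `contact_report`: data.frame with columns
#'   `resname`, `resno`, `chain`, `min_distance`, `n_atom_pairs`; `cutoff`
#'   and `model` attributes.
#' @export
contact_residues <- function(structure, cutoff = 3.4, model = 1,
                             include_hydrogens = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  at <- structure$atoms
  xyz <- structure$coords[[model]]
  heavy <- if (include_hydrogens) rep(TRUE, nrow(at)) else at$element != "H"
  li <- which(at$is_ligand & heavy)
  pi <- which(!at$is_ligand & heavy)
  if (length(li) == 0L) stop("empty ligand selection")
  d <- .pair_dist(xyz[pi, , drop = FALSE], xyz[li, , drop = FALSE])
  mind <- apply(d, 1, min)
  npair <- rowSums(d <= cutoff)
  key <- paste(at$chain[pi], at$resno[pi], sep = "|")
  agg_min <- tapply(mind, key, min)
  agg_n <- tapply(npair, key, sum)
  first <- !duplicated(key)
  info <- data.frame(resname = at$resname[pi][first],
                     resno = at$resno[pi][first],
                     chain = at$chain[pi][first],
                     key = key[first], stringsAsFactors = FALSE)
  info$min_distance <- as.numeric(agg_min[info$key])
  info$n_atom_pairs <- as.integer(agg_n[info$key])
  rep <- info[info$min_distance <= cutoff,
              c("resname", "resno", "chain", "min_distance", "n_atom_pairs")]
  rep <- rep[order(rep$min_distance), , drop = FALSE]
  rownames(rep) <- NULL
  structure(rep, class = c("contact_report", "data.frame"),
            cutoff = cutoff, model = model)
}

.pair_dist <- function(a, b) {
  # Euclidean distances between the rows of two n x 3 matrices
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("Contact residues within %.2f A (model %d): %d residue(s)\n",
              attr(x, "cutoff"), attr(x, "model"), nrow(x)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Per-residue contact frequency across models
#'
#' Fraction of models in which each residue is a ligand contact, for
#' multi-model files (MD snapshots, docking ensembles).
#'
#' @inheritParams contact_residues
#' @return data.frame with `resno`, `chain`, `resname`, `frequency` and
#'   `n_models`.
#' @export
contact_frequency <- function(structure, cutoff = 3.4,
                              include_hydrogens = FALSE) {
  reps <- lapply(seq_len(structure$n_models), function(m)
    contact_residues(structure, cutoff = cutoff, model = m,
                     include_hydrogens = include_hydrogens))
  all_keys <- unique(do.call(rbind, lapply(reps, function(r)
    data.frame(resno = r$resno, chain = r$chain, resname = r$resname,
               stringsAsFactors = FALSE))))
  if (is.null(all_keys) || nrow(all_keys) == 0L)
    return(data.frame(resno = integer(), chain = character(),
                      resname = character(), frequency = numeric(),
                      n_models = integer()))
  all_keys$frequency <- vapply(seq_len(nrow(all_keys)), function(i) {
    mean(vapply(reps, function(r)
      any(r$resno == all_keys$resno[i] & r$chain == all_keys$chain[i]),
      logical(1)))
  }, numeric(1))
  all_keys$n_models <- structure$n_models
  all_keys[order(-all_keys$frequency), ]
}

#' Hydrogen bonds between protein and ligand oxygens
#'
#' Distance-only geometric heuristic: a protein nitrogen or oxygen
#' (potential donor or acceptor) within `d_max` of a ligand oxygen counts
#' as a hydrogen bond. No angular criterion is applied, which is the
#' appropriate default for structures lacking hydrogens.
#'
#' @param structure A [read_complex()] result.
#' @param d_max Maximum heavy-atom distance in Angstrom (default 3.5).
#' @param model Model index.
#' @return data.frame with `protein_atom`, `protein_resname`,
#'   `protein_resno`, `ligand_atom`, `distance`; zero rows when none found.
#' @export
hydrogen_bonds <- function(structure, d_max = 3.5, model = 1) {
  at <- structure$atoms
  xyz <- structure$coords[[model]]
  pol <- which(!at$is_ligand & at$element %in% c("N", "O"))
  lox <- which(at$is_ligand & at$element == "O")
  empty <- data.frame(protein_atom = character(), protein_resname = character(),
                      protein_resno = integer(), ligand_atom = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (length(pol) == 0L || length(lox) == 0L) return(empty)
  d <- .pair_dist(xyz[pol, , drop = FALSE], xyz[lox, , drop = FALSE])
  hits <- which(d <= d_max, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty)
  out <- data.frame(protein_atom = at$name[pol][hits[, 1]],
                    protein_resname = at$resname[pol][hits[, 1]],
                    protein_resno = at$resno[pol][hits[, 1]],
                    ligand_atom = at$name[lox][hits[, 2]],
                    distance = d[hits], stringsAsFactors = FALSE)
  out[order(out$distance), ]
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Least-squares rigid superposition of two equal-length coordinate sets by
#' the Kabsch algorithm (SVD of the cross-covariance with a proper-rotation
#' correction), followed by the root-mean-square deviation. Invariant under
#' any rigid transform of either input.
#'
#' @param coords_a,coords_b n x 3 numeric matrices, n >= 3.
#' @return RMSD in the coordinate units (Angstrom for PDB input).
#' @export
superpose_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets must have equal dimensions")
  if (nrow(a) < 3L) stop("need >= 3 atoms for superposition")
  ac <- scale(a, scale = FALSE)
  bc <- scale(b, scale = FALSE)
  s <- svd(t(bc) %*% ac)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- bc %*% rot
  sqrt(mean(rowSums((ac - fitted)^2)))
}

#' Radius of gyration
#'
#' `Rg = sqrt(sum m_i |r_i - r_bar|^2 / sum m_i)`, mass-weighted when
#' masses are supplied, uniform otherwise.
#'
#' @param coords n x 3 numeric matrix (n >= 1).
#' @param masses Optional atomic masses, length n.
#' @return Rg in the coordinate units.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  x <- as.matrix(coords)
  if (nrow(x) < 1L) stop("need >= 1 atom")
  if (is.null(masses)) masses <- rep(1, nrow(x))
  if (length(masses) != nrow(x)) stop("masses length must match atom count")
  ctr <- colSums(x * masses) / sum(masses)
  dev <- sweep(x, 2, ctr)
  sqrt(sum(masses * rowSums(dev^2)) / sum(masses))
}
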