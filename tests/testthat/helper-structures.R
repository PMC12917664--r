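# Build a complex_structure directly from an atom table and coordinates,
# bypassing PDB serialization (used for oracle comparisons at full
# floating-point precision).
make_complex <- function(atoms, coords) {
  structure(list(atoms = atoms, coords = list(as.matrix(coords)),
                 n_models = 1L, ligand_resname = unique(atoms$resname[atoms$is_ligand])),
            class = "complex_structure")
}

# Random protein-ligand point cloud: n_res single-atom "residues" plus a
# handful of ligand atoms, uniform in a box.
random_complex <- function(n_res = 15, n_lig = 5, box = 12) {
  n <- n_res + n_lig
  atoms <- data.frame(
    serial = seq_len(n),
    name = c(rep("CA", n_res), paste0("C", seq_len(n_lig))),
    element = "C",
    resname = c(rep("ALA", n_res), rep("LIG", n_lig)),
    resno = c(seq_len(n_res), rep(900L, n_lig)),
    chain = c(rep("A", n_res), rep("L", n_lig)),
    is_ligand = c(rep(FALSE, n_res), rep(TRUE, n_lig)),
    stringsAsFactors = FALSE)
  coords <- matrix(runif(3 * n, 0, box), ncol = 3)
  make_complex(atoms, coords)
}

# Exhaustive double-loop contact oracle: which protein residues have any
# atom within cutoff of any ligand atom, with the minimum pair distance.
contact_oracle <- function(cs, cutoff) {
  at <- cs$atoms
  xyz <- cs$coords[[1]]
  res <- list()
  for (i in which(!at$is_ligand)) {
    for (j in which(at$is_ligand)) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      key <- paste(at$chain[i], at$resno[i])
      if (is.null(res[[key]]) || d < res[[key]]) res[[key]] <- d
    }
  }
  keep <- vapply(res, function(d) d <= cutoff, logical(1))
  mins <- unlist(res[keep])
  out <- data.frame(key = names(mins), min_distance = unname(mins),
                    stringsAsFactors = FALSE)
  out[order(out$min_distance), ]
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)),
         3, 3, byrow = TRUE)
}
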