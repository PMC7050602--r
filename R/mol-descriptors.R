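# Physicochemical descriptors and circular fingerprints.
#
# The seven default reference-space descriptors are standard
# physicochemical properties: molecular weight, an additive lipophilicity
# estimate, topological polar surface area (reduced Ertl N/O contribution
# table), H-bond donor and acceptor counts, rotatable bonds and ring
# count.  The descriptor set is configurable; scores are computed in a
# z-normalized space, so only relative positions matter.

# simplified additive lipophilicity increments per heavy atom; hydrogens
# on heteroatoms subtract.  Coarse by design: it orders analogs by
# hydrophobic content, which is all the normalized reference space needs.
.CLOGP_INC <- c(C = 0.13, B = 0.05, N = -0.60, O = -0.55, S = 0.25,
                P = -0.40, F = 0.14, Cl = 0.65, Br = 0.86, I = 1.12)
.CLOGP_AROM_BONUS <- c(C = 0.16, N = 0.18, O = 0.20, S = 0.15)

mol_mw <- function(mol) {
  h <- atom_hydrogens(mol)
  sum(.ATOMIC_MASS[mol$elem], na.rm = TRUE) + sum(h) * .ATOMIC_MASS[["H"]]
}

mol_clogp <- function(mol) {
  h <- atom_hydrogens(mol)
  v <- 0
  for (i in seq_len(n_atoms(mol))) {
    e <- mol$elem[i]
    if (e %in% names(.CLOGP_INC)) v <- v + .CLOGP_INC[[e]]
    if (mol$arom[i] && e %in% names(.CLOGP_AROM_BONUS))
      v <- v + .CLOGP_AROM_BONUS[[e]]
    if (e %in% c("N", "O", "S") && h[i] > 0) v <- v - 0.30 * h[i]
  }
  v
}

# reduced Ertl TPSA: nitrogen and oxygen contributions for the common
# valence states in this package's SMILES dialect
mol_tpsa <- function(mol) {
  h <- atom_hydrogens(mol)
  deg <- atom_degree(mol)
  bos <- .bond_order_sum(mol)
  # count double bonds per atom
  ndouble <- integer(n_atoms(mol))
  for (k in seq_len(n_bonds(mol))) {
    if (!mol$bond_arom[k] && mol$bond_order[k] == 2L) {
      ndouble[mol$bond_a[k]] <- ndouble[mol$bond_a[k]] + 1L
      ndouble[mol$bond_b[k]] <- ndouble[mol$bond_b[k]] + 1L
    }
    if (!mol$bond_arom[k] && mol$bond_order[k] == 3L) {
      ndouble[mol$bond_a[k]] <- ndouble[mol$bond_a[k]] + 3L
      ndouble[mol$bond_b[k]] <- ndouble[mol$bond_b[k]] + 3L
    }
  }
  tpsa <- 0
  for (i in seq_len(n_atoms(mol))) {
    e <- mol$elem[i]; hi <- h[i]; chg <- mol$charge[i]
    if (e == "N") {
      contrib <-
        if (mol$arom[i]) {
          if (hi >= 1) 15.79 else if (deg[i] >= 3L) 4.41 else 12.89
        } else if (chg != 0L) 11.68
      else if (ndouble[i] >= 3L) 23.79            # nitrile
      else if (ndouble[i] >= 1L) { if (hi >= 1) 23.85 else 12.36 }
      else if (hi >= 2L) 26.02
      else if (hi == 1L) 12.03
      else 3.24
      tpsa <- tpsa + contrib
    } else if (e == "O") {
      contrib <-
        if (mol$arom[i]) 13.14
      else if (chg < 0L) 23.06
      else if (ndouble[i] >= 1L) 17.07
      else if (hi >= 1L) 20.23
      else 9.23
      tpsa <- tpsa + contrib
    }
  }
  tpsa
}

mol_hbd <- function(mol) {
  h <- atom_hydrogens(mol)
  sum(mol$elem %in% c("N", "O") & h > 0)
}

mol_hba <- function(mol) sum(mol$elem %in% c("N", "O"))

mol_rotatable_bonds <- function(mol) {
  if (n_bonds(mol) == 0L) return(0L)
  inring <- bonds_in_ring(mol)
  deg <- atom_degree(mol)
  n <- 0L
  for (k in seq_len(n_bonds(mol))) {
    if (mol$bond_order[k] != 1L || mol$bond_arom[k] || inring[k]) next
    a <- mol$bond_a[k]; b <- mol$bond_b[k]
    if (mol$elem[a] == "*" || mol$elem[b] == "*") next
    if (deg[a] >= 2L && deg[b] >= 2L) n <- n + 1L
  }
  n
}

.DEFAULT_DESCRIPTORS <- c("mw", "clogp", "tpsa", "hbd", "hba", "rotb", "rings")

.descriptor_fun <- function(name) {
  switch(name,
         mw = mol_mw, clogp = mol_clogp, tpsa = mol_tpsa, hbd = mol_hbd,
         hba = mol_hba, rotb = mol_rotatable_bonds, rings = ring_count,
         heavy = mol_heavy_atoms,
         stop("unknown descriptor '", name, "'"))
}

#' Compute physicochemical descriptors for a set of structures
#'
#' @param smiles character vector of SMILES
#' @param descriptors descriptor names; default the 7-dimensional set
#'   `mw, clogp, tpsa, hbd, hba, rotb, rings`
#' @return numeric matrix, one row per structure
#' @export
compute_descriptors <- function(smiles, descriptors = .DEFAULT_DESCRIPTORS) {
  funs <- lapply(descriptors, .descriptor_fun)
  out <- matrix(NA_real_, length(smiles), length(descriptors),
                dimnames = list(NULL, descriptors))
  for (i in seq_along(smiles)) {
    mol <- parse_smiles(smiles[i])
    out[i, ] <- vapply(funs, function(f) as.numeric(f(mol)), numeric(1))
  }
  out
}

# ---- folded circular fingerprint (ECFP-like, bond diameter 4) ----

.HASH_MOD <- 2147483647  # 2^31 - 1

.mix <- function(h, v) ((h * 33 + v) %% .HASH_MOD)

#' Circular substructure fingerprint folded into a fixed-length bit vector
#'
#' Extended-connectivity style: per-atom invariants are iteratively
#' hashed with sorted neighbor identifiers out to the given radius
#' (radius 2 = bond diameter 4); all identifiers are folded modulo the
#' vector length.
#'
#' @param smiles character vector of SMILES (or a single `mol`)
#' @param nbits folded length (default 1024)
#' @param radius neighborhood radius (default 2)
#' @return binary matrix with `length(smiles)` rows and `nbits` columns
#' @export
morgan_fingerprint <- function(smiles, nbits = 1024L, radius = 2L) {
  if (inherits(smiles, "mol")) smiles <- list(smiles)
  out <- matrix(0L, length(smiles), nbits)
  for (m in seq_along(smiles)) {
    mol <- if (inherits(smiles[[m]], "mol")) smiles[[m]] else parse_smiles(smiles[[m]])
    n <- n_atoms(mol)
    h <- atom_hydrogens(mol)
    deg <- atom_degree(mol)
    inring <- atoms_in_ring(mol)
    elem_code <- match(mol$elem, c("*", "H", .ORGANIC_SUBSET))
    ids <- numeric(n)
    for (i in seq_len(n)) {
      v <- 7
      v <- .mix(v, elem_code[i]); v <- .mix(v, mol$charge[i] + 10)
      v <- .mix(v, h[i]); v <- .mix(v, deg[i])
      v <- .mix(v, as.integer(mol$arom[i])); v <- .mix(v, as.integer(inring[i]))
      ids[i] <- v
    }
    all_ids <- ids
    adj <- vector("list", n)
    btag <- ifelse(mol$bond_arom, 9L, mol$bond_order)
    for (k in seq_len(n_bonds(mol))) {
      a <- mol$bond_a[k]; b <- mol$bond_b[k]
      adj[[a]] <- rbind(adj[[a]], c(b, btag[k]))
      adj[[b]] <- rbind(adj[[b]], c(a, btag[k]))
    }
    for (r in seq_len(radius)) {
      new_ids <- numeric(n)
      for (i in seq_len(n)) {
        v <- .mix(11, ids[i])
        nb <- adj[[i]]
        if (!is.null(nb)) {
          codes <- nb[, 2] * (.HASH_MOD + 1) / 8 + ids[nb[, 1]]
          for (cd in sort(codes)) v <- .mix(v, cd %% .HASH_MOD)
        }
        new_ids[i] <- v
      }
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
    out[m, (all_ids %% nbits) + 1L] <- 1L
  }
  out
}

#' Tanimoto kernel matrix between binary fingerprint matrices
#'
#' K(x, y) = |x AND y| / |x OR y|; by convention K = 1 when both vectors
#' are all-zero.
#'
#' @param x,y binary matrices (rows = compounds); `y` defaults to `x`
#' @return kernel matrix of dimension `nrow(x)` x `nrow(y)`
#' @export
tanimoto_kernel <- function(x, y = x) {
  x <- as.matrix(x); y <- as.matrix(y)
  inter <- tcrossprod(x, y)
  rx <- rowSums(x); ry <- rowSums(y)
  uni <- outer(rx, ry, "+") - inter
  k <- ifelse(uni == 0, 1, inter / pmax(uni, 1e-12))
  k
}
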