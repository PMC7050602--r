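# Fragmentation and recombination of molecules around analog-series cores.
#
# MMP fragmentation cuts single exocyclic (acyclic, non-aromatic) bonds
# whose environment is plausible under retrosynthetic rules: at least one
# end sits on a ring atom, or the bond is an ether/amine/amide/ester-type
# heteroatom attachment.  Substituent fragments respect a heavy-atom cap.

# returns indices of bonds eligible for cutting
eligible_cut_bonds <- function(mol) {
  nb <- n_bonds(mol)
  if (nb == 0L) return(integer(0))
  inring_bond <- bonds_in_ring(mol)
  inring_atom <- atoms_in_ring(mol)
  out <- integer(0)
  for (k in seq_len(nb)) {
    if (mol$bond_order[k] != 1L || mol$bond_arom[k] || inring_bond[k]) next
    a <- mol$bond_a[k]; b <- mol$bond_b[k]
    ea <- mol$elem[a]; eb <- mol$elem[b]
    if (ea == "*" || eb == "*" || ea == "H" || eb == "H") next
    ring_adjacent <- inring_atom[a] || inring_atom[b]
    hetero_link <- ea %in% c("N", "O", "S") || eb %in% c("N", "O", "S")
    if (ring_adjacent || hetero_link) out <- c(out, k)
  }
  out
}

# fragment side of bond k containing atom `from`, as atom index vector
.frag_atoms <- function(mol, k, from) {
  which(component_side(mol, k, from))
}

# SMILES of the substituent fragment: atoms `idx`, attachment at atom
# `at` (index into mol), with a wildcard atom marking the open valence
.frag_smiles <- function(mol, idx, at) {
  sub <- mol_delete_atoms(mol, setdiff(seq_len(n_atoms(mol)), idx))
  remap <- integer(n_atoms(mol)); remap[sort(idx)] <- seq_along(idx)
  sub <- mol_add_atom(sub, "*")
  sub <- mol_add_bond(sub, remap[at], n_atoms(sub))
  canonical_smiles(sub)
}

# all single-cut splits of a molecule
#
# Returns a data.frame with one row per (bond, orientation):
#   bond, context_key (canonical SMILES of the context with a wildcard),
#   coreH_key (context with the open valence hydrogen-filled),
#   frag (canonical substituent SMILES with wildcard), frag_heavy
single_cut_splits <- function(mol, max_substituent_heavy_atoms = 13L) {
  elig <- eligible_cut_bonds(mol)
  rows <- list()
  # hydrogen "splits": an implicit hydrogen at a ring atom or heteroatom
  # is an exchangeable substituent (frag "H"); the context is the whole
  # molecule with an open valence at that atom
  hcnt <- atom_hydrogens(mol)
  inring_atom <- atoms_in_ring(mol)
  for (i in seq_len(n_atoms(mol))) {
    if (hcnt[i] < 1L || mol$elem[i] == "*") next
    if (!(inring_atom[i] || mol$elem[i] %in% c("N", "O", "S"))) next
    ctx_key <- .frag_smiles(mol, seq_len(n_atoms(mol)), i)
    rows[[length(rows) + 1L]] <- data.frame(
      bond = NA_integer_, context_key = ctx_key,
      coreH_key = canonical_smiles(mol), frag = "H", frag_heavy = 0L,
      stringsAsFactors = FALSE)
  }
  for (k in elig) {
    for (from in c(mol$bond_a[k], mol$bond_b[k])) {
      frag_idx <- .frag_atoms(mol, k, from)
      fh <- sum(mol$elem[frag_idx] != "*")
      if (fh < 1L || fh > max_substituent_heavy_atoms) next
      ctx_idx <- setdiff(seq_len(n_atoms(mol)), frag_idx)
      # series cores retain ring systems: a context stripped of every
      # ring atom is not an admissible core side
      if (any(inring_atom) && !any(inring_atom[ctx_idx])) next
      at_ctx <- setdiff(c(mol$bond_a[k], mol$bond_b[k]), from)
      ctx_key <- .frag_smiles(mol, ctx_idx, at_ctx)
      coreH <- canonical_smiles(mol_delete_atoms(mol, frag_idx))
      frag <- .frag_smiles(mol, frag_idx, from)
      rows[[length(rows) + 1L]] <- data.frame(
        bond = k, context_key = ctx_key, coreH_key = coreH,
        frag = frag, frag_heavy = fh, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(bond = integer(), context_key = character(),
                      coreH_key = character(), frag = character(),
                      frag_heavy = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Enumerate multi-cut decompositions: up to `max_cuts` independent cuts
# with pairwise-disjoint substituent sides.  Returns a list of
# candidates, each with: coreH_key, cuts = data.frame(bond, ctx_atom,
# frag (canonical SMILES)), core_heavy.
multi_cut_decompositions <- function(mol, max_cuts = 6L,
                                     max_substituent_heavy_atoms = 13L,
                                     min_core_heavy = 3L) {
  elig <- eligible_cut_bonds(mol)
  if (!length(elig)) return(list())
  # precompute both orientations per eligible bond
  choices <- list()
  for (k in elig) {
    for (from in c(mol$bond_a[k], mol$bond_b[k])) {
      frag_idx <- .frag_atoms(mol, k, from)
      fh <- length(frag_idx)
      if (fh < 1L || fh > max_substituent_heavy_atoms) next
      at_ctx <- setdiff(c(mol$bond_a[k], mol$bond_b[k]), from)
      choices[[length(choices) + 1L]] <- list(
        bond = k, frag_idx = frag_idx, ctx_atom = at_ctx, frag_at = from)
    }
  }
  if (!length(choices)) return(list())
  nheavy <- mol_heavy_atoms(mol)
  bond_of <- vapply(choices, function(ch) ch$bond, integer(1))
  out <- list()
  recurse <- function(start, removed, used_bonds, cuts) {
    if (length(cuts)) {
      core_heavy <- nheavy - length(removed)
      if (core_heavy >= min_core_heavy) {
        ctx_atoms <- vapply(cuts, function(cc) cc$ctx_atom, integer(1))
        if (!anyDuplicated(ctx_atoms) && !any(ctx_atoms %in% removed)) {
          out[[length(out) + 1L]] <<- list(cuts = cuts, removed = removed)
        }
      }
    }
    if (length(cuts) >= max_cuts) return()
    for (ci in seq_along(choices)) {
      if (ci < start) next
      ch <- choices[[ci]]
      if (ch$bond %in% used_bonds) next
      if (any(ch$frag_idx %in% removed)) next
      recurse(ci + 1L, c(removed, ch$frag_idx), c(used_bonds, ch$bond),
              c(cuts, list(ch)))
    }
  }
  recurse(1L, integer(0), integer(0), list())
  # finalize: compute coreH keys and canonical substituent fragments
  lapply(out, function(cand) {
    coreH_mol <- mol_delete_atoms(mol, cand$removed)
    list(
      coreH_key = canonical_smiles(coreH_mol),
      core_heavy = mol_heavy_atoms(coreH_mol),
      cuts = cand$cuts,
      removed = cand$removed
    )
  })
}

# Decompose a molecule against a known hydrogen-filled core key.
#
# Returns NULL when the molecule does not contain the core, otherwise a
# list(sites = integer canonical-rank labels, frags = character
# substituent SMILES keyed by site rank).  Sites not present in the
# returned table carry hydrogen.
decompose_on_core <- function(mol, coreH_key, max_cuts = 6L,
                              max_substituent_heavy_atoms = 13L) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  # molecule equal to the bare core: all-H decomposition
  if (canonical_smiles(mol) == coreH_key) {
    return(list(site_ranks = integer(0), frags = character(0)))
  }
  cands <- multi_cut_decompositions(mol, max_cuts = max_cuts,
                                    max_substituent_heavy_atoms = max_substituent_heavy_atoms)
  for (cand in cands) {
    if (cand$coreH_key != coreH_key) next
    core_mol <- mol_delete_atoms(mol, cand$removed)
    keep <- sort(setdiff(seq_len(n_atoms(mol)), cand$removed))
    remap <- integer(n_atoms(mol)); remap[keep] <- seq_along(keep)
    ranks <- canonical_ranks(core_mol)
    site_ranks <- vapply(cand$cuts, function(cc) ranks[remap[cc$ctx_atom]], numeric(1))
    frags <- vapply(cand$cuts, function(cc)
      .frag_smiles(mol, cc$frag_idx, cc$frag_at), character(1))
    o <- order(site_ranks)
    return(list(site_ranks = as.integer(site_ranks[o]), frags = frags[o]))
  }
  NULL
}

#' Attach substituents to a hydrogen-filled core
#'
#' @param core `mol` (or SMILES) of the bare core
#' @param site_ranks canonical-rank positions of the substitution sites
#'   (see [canonical_smiles()]; ranks of the bare core's atoms)
#' @param subs character vector of substituent SMILES (one wildcard
#'   attachment each) or `"H"`, aligned with `site_ranks`
#' @return canonical SMILES of the assembled analog
#' @export
attach_substituents <- function(core, site_ranks, subs) {
  mol <- if (is.character(core)) parse_smiles(core) else core
  stopifnot(length(site_ranks) == length(subs))
  ranks <- canonical_ranks(mol)
  cur <- mol
  for (i in seq_along(site_ranks)) {
    if (subs[i] == "H") next
    at <- which(ranks == site_ranks[i])
    if (length(at) != 1L)
      stop("substitution site rank ", site_ranks[i],
           " does not identify a unique core atom")
    frag <- parse_smiles(subs[i])
    star <- which(frag$elem == "*")
    if (length(star) != 1L)
      stop("substituent must contain exactly one attachment wildcard: ", subs[i])
    nb <- n_bonds(frag)
    star_nbr <- NA_integer_
    for (k in seq_len(nb)) {
      if (frag$bond_a[k] == star) star_nbr <- frag$bond_b[k]
      if (frag$bond_b[k] == star) star_nbr <- frag$bond_a[k]
    }
    if (is.na(star_nbr)) stop("attachment wildcard has no neighbor: ", subs[i])
    comb <- mol_combine(cur, frag)
    m <- comb$mol
    m <- mol_add_bond(m, at, comb$offset + star_nbr)
    m <- mol_delete_atoms(m, comb$offset + star)
    cur <- m
    # ranks of the original core atoms are positional: deletion above only
    # removed atoms appended after the core block, so `ranks` still aligns
  }
  canonical_smiles(cur)
}

# heavy-atom count of a substituent SMILES ("H" counts as zero)
substituent_heavy_atoms <- function(frag) {
  vapply(frag, function(f) {
    if (identical(f, "H")) return(0L)
    mol_heavy_atoms(parse_smiles(f))
  }, integer(1), USE.NAMES = FALSE)
}
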