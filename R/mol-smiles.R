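# Lightweight molecular-graph layer on a constrained SMILES dialect.
#
# Supported: organic subset atoms (B C N O P S F Cl Br I), aromatic
# lowercase (b c n o p s), bracket atoms with isotope / chirality tag /
# H count / charge / atom map, branches, ring-bond closures (1-9, %nn),
# bond symbols - = # :, and wildcard attachment atoms '*' (one open
# valence marker per fragment in most of this package).  Not supported:
# multi-component dots, E/Z bond marks (stripped with a warning),
# aromaticity *perception* (the aromatic flags of the input are trusted;
# compare keys only between structures written in the same aromaticity
# model).

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s")

.ATOMIC_MASS <- c(
  "*" = 0, H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

# allowed standard valences used for implicit-H assignment
.DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, "*" = 0
)

new_mol <- function(elem, arom, charge, hexp, isotope, chiral, map,
                    bond_a = integer(), bond_b = integer(),
                    bond_order = integer(), bond_arom = logical()) {
  structure(list(
    elem = elem, arom = arom, charge = charge, hexp = hexp,
    isotope = isotope, chiral = chiral, map = map,
    bond_a = bond_a, bond_b = bond_b,
    bond_order = bond_order, bond_arom = bond_arom
  ), class = "mol")
}

n_atoms <- function(mol) length(mol$elem)
n_bonds <- function(mol) length(mol$bond_a)

#' @export
print.mol <- function(x, ...) {
  cat(sprintf("<mol> %d atoms, %d bonds: %s\n",
              n_atoms(x), n_bonds(x), write_smiles(x)))
  invisible(x)
}

.parse_bracket <- function(body, pos) {
  # body is the text between '[' and ']'
  m <- regmatches(body, regexec(
    "^([0-9]*)(\\*|[A-Z][a-z]?|[a-z]{1,2})(@@|@)?(H[0-9]*)?([+-][0-9]*|\\+\\+|--)?(:([0-9]+))?$",
    body))[[1]]
  if (length(m) == 0)
    stop("unparsable bracket atom '[", body, "]' at position ", pos)
  isotope <- if (nzchar(m[2])) as.integer(m[2]) else NA_integer_
  sym <- m[3]
  arom <- sym %in% .AROMATIC_ELEMS
  elem <- if (arom) toupper(sym) else sym
  if (elem != "*" && !(elem %in% c(.ORGANIC_SUBSET, "H")))
    stop("unsupported element '", sym, "' in bracket atom")
  chiral <- m[4]
  h <- m[5]
  hexp <- if (!nzchar(h)) 0L else if (h == "H") 1L else as.integer(substring(h, 2))
  chg <- m[6]
  charge <- if (!nzchar(chg)) 0L
  else if (chg == "+") 1L else if (chg == "-") -1L
  else if (chg == "++") 2L else if (chg == "--") -2L
  else as.integer(paste0(substring(chg, 1, 1), substring(chg, 2)))
  map <- if (nzchar(m[8])) as.integer(m[8]) else 0L
  list(elem = elem, arom = arom, charge = charge, hexp = hexp,
       isotope = isotope, chiral = chiral, map = map)
}

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles single SMILES string (constrained dialect, see details in
#'   the package vignette).
#' @return an object of class `mol`.
#' @export
parse_smiles <- function(smiles) {
  if (length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop("expected a single non-empty SMILES string")
  s <- gsub("[/\\\\]", "", smiles)  # drop E/Z marks, treated as plain single
  if (grepl(".", s, fixed = TRUE))
    stop("multi-component SMILES (dot) not supported: ", smiles)

  elem <- character(); arom <- logical(); charge <- integer()
  hexp <- integer(); isotope <- integer(); chiral <- character()
  map <- integer()
  ba <- integer(); bb <- integer(); bo <- integer(); bar <- logical()

  add_atom <- function(a) {
    elem[length(elem) + 1L] <<- a$elem
    arom[length(arom) + 1L] <<- a$arom
    charge[length(charge) + 1L] <<- a$charge
    hexp[length(hexp) + 1L] <<- a$hexp
    isotope[length(isotope) + 1L] <<- a$isotope
    chiral[length(chiral) + 1L] <<- a$chiral
    map[length(map) + 1L] <<- a$map
    length(elem)
  }
  add_bond <- function(i, j, sym) {
    if (i == j) stop("self-bond in SMILES")
    if (sym == "") {
      if (arom[i] && arom[j]) { o <- 1L; aro <- TRUE } else { o <- 1L; aro <- FALSE }
    } else if (sym == "-") { o <- 1L; aro <- FALSE
    } else if (sym == "=") { o <- 2L; aro <- FALSE
    } else if (sym == "#") { o <- 3L; aro <- FALSE
    } else if (sym == ":") { o <- 1L; aro <- TRUE
    } else stop("bad bond symbol '", sym, "'")
    ba[length(ba) + 1L] <<- min(i, j)
    bb[length(bb) + 1L] <<- max(i, j)
    bo[length(bo) + 1L] <<- o
    bar[length(bar) + 1L] <<- aro
  }

  prev <- NA_integer_
  stack <- integer()
  pending <- ""
  ring_open <- list()  # digit -> list(atom, bond)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substring(s, i, i)
    if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending <- ch; i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        d <- substring(s, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", d)) stop("bad %nn ring closure")
        i <- i + 3L
      } else { d <- ch; i <- i + 1L }
      if (is.na(prev)) stop("ring closure before any atom")
      if (!is.null(ring_open[[d]])) {
        op <- ring_open[[d]]
        sym <- pending
        if (sym == "" && op$bond != "") sym <- op$bond
        if (op$bond != "" && pending != "" && op$bond != pending)
          stop("conflicting ring-closure bond symbols for ", d)
        add_bond(op$atom, prev, sym)
        ring_open[[d]] <- NULL
      } else {
        ring_open[[d]] <- list(atom = prev, bond = pending)
      }
      pending <- ""
    } else if (ch == "[") {
      j <- regexpr("]", substring(s, i + 1L), fixed = TRUE)
      if (j < 0) stop("unclosed '['")
      a <- .parse_bracket(substring(s, i + 1L, i + j - 1L), i)
      idx <- add_atom(a)
      if (!is.na(prev)) add_bond(prev, idx, pending)
      pending <- ""; prev <- idx
      i <- i + j + 1L
    } else {
      two <- substring(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) { sym <- two; i <- i + 2L }
      else if (ch %in% c(.ORGANIC_SUBSET, .AROMATIC_ELEMS, "*")) { sym <- ch; i <- i + 1L }
      else stop("unexpected character '", ch, "' in SMILES: ", smiles)
      aro <- sym %in% .AROMATIC_ELEMS
      idx <- add_atom(list(elem = if (aro) toupper(sym) else sym, arom = aro,
                           charge = 0L, hexp = NA_integer_,
                           isotope = NA_integer_, chiral = "", map = 0L))
      if (!is.na(prev)) add_bond(prev, idx, pending)
      pending <- ""; prev <- idx
    }
  }
  if (length(stack) != 0L) stop("unbalanced '(' in SMILES: ", smiles)
  if (length(ring_open) != 0L) stop("unclosed ring bond in SMILES: ", smiles)
  if (length(elem) == 0L) stop("empty SMILES")
  # duplicate bond check
  if (n_distinct_pairs(ba, bb) != length(ba))
    stop("duplicate bond in SMILES: ", smiles)
  new_mol(elem, arom, charge, hexp, isotope, chiral, map, ba, bb, bo, bar)
}

n_distinct_pairs <- function(a, b) length(unique(paste(a, b)))

# per-atom total bond-order sum; aromatic bonds count 1 each and an
# aromatic atom gets +1 for its delocalized contribution
.bond_order_sum <- function(mol) {
  v <- numeric(n_atoms(mol))
  if (n_bonds(mol)) {
    ord <- ifelse(mol$bond_arom, 1L, mol$bond_order)
    for (k in seq_len(n_bonds(mol))) {
      v[mol$bond_a[k]] <- v[mol$bond_a[k]] + ord[k]
      v[mol$bond_b[k]] <- v[mol$bond_b[k]] + ord[k]
    }
  }
  v + as.numeric(mol$arom)
}

#' Total hydrogen count per atom (implicit for organic-subset atoms,
#' explicit for bracket atoms)
#' @param mol a `mol` object
#' @return integer vector, one entry per atom
#' @export
atom_hydrogens <- function(mol) {
  bos <- .bond_order_sum(mol)
  h <- integer(n_atoms(mol))
  for (i in seq_len(n_atoms(mol))) {
    if (!is.na(mol$hexp[i])) { h[i] <- mol$hexp[i]; next }
    val <- .DEFAULT_VALENCES[[mol$elem[i]]]
    if (is.null(val)) { h[i] <- 0L; next }
    v <- val[val >= bos[i]]
    h[i] <- if (length(v)) as.integer(v[1] - bos[i]) else 0L
  }
  h
}

atom_degree <- function(mol) {
  d <- integer(n_atoms(mol))
  t1 <- tabulate(mol$bond_a, nbins = n_atoms(mol))
  t2 <- tabulate(mol$bond_b, nbins = n_atoms(mol))
  d + t1 + t2
}

mol_heavy_atoms <- function(mol) sum(mol$elem != "*")

adjacency_list <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (k in seq_len(n_bonds(mol))) {
    a <- mol$bond_a[k]; b <- mol$bond_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# logical vector: is bond k part of a cycle?  A bond is in a ring iff it
# is not a bridge; bridges are found with one lowlink DFS pass.
bonds_in_ring <- function(mol) {
  nb <- n_bonds(mol)
  if (nb == 0L) return(logical(0))
  n <- n_atoms(mol)
  # adjacency with bond ids
  adj <- vector("list", n)
  for (k in seq_len(nb)) {
    a <- mol$bond_a[k]; b <- mol$bond_b[k]
    adj[[a]] <- rbind(adj[[a]], c(b, k))
    adj[[b]] <- rbind(adj[[b]], c(a, k))
  }
  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(nb)
  dfs <- function(u, parent_bond) {
    timer <<- timer + 1L
    disc[u] <<- timer; low[u] <<- timer
    nbrs <- adj[[u]]
    if (!is.null(nbrs)) for (r in seq_len(nrow(nbrs))) {
      v <- nbrs[r, 1]; k <- nbrs[r, 2]
      if (k == parent_bond) next
      if (disc[v] == 0L) {
        dfs(v, k)
        low[u] <<- min(low[u], low[v])
        if (low[v] > disc[u]) is_bridge[k] <<- TRUE
      } else {
        low[u] <<- min(low[u], disc[v])
      }
    }
  }
  for (s in seq_len(n)) if (disc[s] == 0L) dfs(s, 0L)
  !is_bridge
}

atoms_in_ring <- function(mol) {
  rb <- bonds_in_ring(mol)
  inring <- logical(n_atoms(mol))
  if (any(rb)) {
    inring[mol$bond_a[rb]] <- TRUE
    inring[mol$bond_b[rb]] <- TRUE
  }
  inring
}

mol_components <- function(mol) {
  comp <- integer(n_atoms(mol))
  adj <- adjacency_list(mol)
  cid <- 0L
  for (s in seq_len(n_atoms(mol))) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nx in adj[[cur]]) if (comp[nx] == 0L) { comp[nx] <- cid; queue <- c(queue, nx) }
    }
  }
  comp
}

ring_count <- function(mol) {
  n_bonds(mol) - n_atoms(mol) + length(unique(mol_components(mol)))
}

# --- canonical ranking (Weisfeiler-Lehman refinement + tie splitting) ---

canonical_ranks <- function(mol, use_maps = FALSE, split_ties = TRUE) {
  n <- n_atoms(mol)
  if (n == 1L) return(1L)
  h <- atom_hydrogens(mol)
  deg <- atom_degree(mol)
  inring <- atoms_in_ring(mol)
  base <- paste(mol$elem, mol$arom, mol$charge, h, deg, inring,
                ifelse(is.na(mol$isotope), 0L, mol$isotope), mol$chiral,
                if (use_maps) mol$map else 0L)
  rank <- match(base, sort(unique(base)))
  # directed edge list for vectorized refinement
  bond_tag <- ifelse(mol$bond_arom, 9L, mol$bond_order)
  efrom <- c(mol$bond_a, mol$bond_b)
  eto <- c(mol$bond_b, mol$bond_a)
  etag <- c(bond_tag, bond_tag)
  maxdeg <- if (length(efrom)) max(tabulate(efrom, n)) else 0L
  refine <- function(rank) {
    repeat {
      # per-atom sorted neighbor codes (bond tag * 2^20 + neighbor rank),
      # all-numeric so ordering is exact and monotone in the old ranks
      key <- matrix(0, n, maxdeg + 1L)
      key[, 1L] <- rank
      if (maxdeg > 0L) {
        code <- etag * 2^20 + rank[eto]
        o <- order(efrom, -code)
        f <- efrom[o]; cd <- code[o]
        pos <- stats::ave(seq_along(f), f, FUN = seq_along)
        key[cbind(f, pos + 1L)] <- cd
      }
      o2 <- do.call(order, lapply(seq_len(ncol(key)), function(j) key[, j]))
      changed <- c(TRUE, rowSums(abs(key[o2[-1], , drop = FALSE] -
                                       key[o2[-n], , drop = FALSE])) > 0)
      new_rank <- integer(n)
      new_rank[o2] <- cumsum(changed)
      if (identical(new_rank, as.integer(rank))) return(new_rank)
      rank <- new_rank
    }
  }
  rank <- refine(rank)
  if (!split_ties) return(rank)
  # split remaining ties deterministically (tied atoms are almost always
  # graph-automorphic for chemically sensible structures)
  while (max(table(rank)) > 1L) {
    tab <- table(rank)
    tied <- as.integer(names(tab)[tab > 1L])[1]
    pick <- which(rank == tied)[1]
    rank[pick] <- rank[pick] - 0.5
    rank <- match(rank, sort(unique(rank)))
    rank <- refine(rank)
  }
  rank
}

# --- SMILES writer ---

.atom_token <- function(mol, i, h, bos) {
  elem <- mol$elem[i]
  needs_bracket <- (elem == "*" && mol$map[i] != 0L) ||
    mol$charge[i] != 0L || !is.na(mol$isotope[i]) || nzchar(mol$chiral[i])
  sym <- if (mol$arom[i]) tolower(elem) else elem
  if (elem == "*") sym <- "*"
  if (!needs_bracket && elem != "*") {
    # check the bare atom would round-trip to the same H count
    val <- .DEFAULT_VALENCES[[elem]]
    v <- val[val >= bos[i]]
    himpl <- if (length(v)) as.integer(v[1] - bos[i]) else 0L
    if (himpl != h[i]) needs_bracket <- TRUE
  }
  if (!needs_bracket) return(sym)
  iso <- if (is.na(mol$isotope[i])) "" else as.character(mol$isotope[i])
  htok <- if (h[i] == 0L) "" else if (h[i] == 1L) "H" else paste0("H", h[i])
  chg <- mol$charge[i]
  ctok <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
  else sprintf("%+d", chg)
  mtok <- if (mol$map[i] != 0L) paste0(":", mol$map[i]) else ""
  paste0("[", iso, sym, mol$chiral[i], htok, ctok, mtok, "]")
}

.bond_token <- function(mol, k) {
  if (mol$bond_arom[k]) return("")
  if (mol$bond_order[k] == 2L) return("=")
  if (mol$bond_order[k] == 3L) return("#")
  # single bond between two aromatic atoms must be written explicitly
  if (mol$arom[mol$bond_a[k]] && mol$arom[mol$bond_b[k]]) return("-")
  ""
}

#' Write a molecule as SMILES
#'
#' @param mol a `mol` object
#' @param canonical order atoms by canonical rank (default TRUE); with
#'   FALSE the input atom order drives the traversal.
#' @param keep_maps keep atom-map labels on wildcard atoms (default TRUE).
#' @return SMILES string
#' @export
write_smiles <- function(mol, canonical = TRUE, keep_maps = TRUE) {
  n <- n_atoms(mol)
  if (!keep_maps && any(mol$map != 0L)) { mol$map[] <- 0L }
  rank <- if (canonical) canonical_ranks(mol) else seq_len(n)
  h <- atom_hydrogens(mol)
  bos <- .bond_order_sum(mol)
  # bond lookup
  nb <- n_bonds(mol)
  bond_id <- function(i, j) {
    w <- which((mol$bond_a == i & mol$bond_b == j) |
                 (mol$bond_a == j & mol$bond_b == i))
    w[1]
  }
  adj <- adjacency_list(mol)
  visited <- logical(n)
  ring_digit_next <- 0L
  ring_tokens <- vector("list", n)   # closure tokens per atom
  closure_seen <- new.env(parent = emptyenv())

  # first pass: DFS to classify edges and allocate ring digits
  tree_children <- vector("list", n)
  back_edges <- list()
  order_neighbors <- function(i) {
    nbrs <- adj[[i]]
    if (is.null(nbrs)) return(integer(0))
    unique(nbrs[order(rank[nbrs])])
  }
  start <- which.min(rank)
  visited[start] <- TRUE
  dfs <- function(node, parent) {
    for (nx in order_neighbors(node)) {
      if (!is.na(parent) && nx == parent) next
      if (visited[nx]) {
        key <- paste(min(node, nx), max(node, nx))
        if (is.null(closure_seen[[key]])) {
          closure_seen[[key]] <- TRUE
          ring_digit_next <<- ring_digit_next + 1L
          d <- ring_digit_next
          dt <- if (d < 10) as.character(d) else paste0("%", d)
          k <- bond_id(node, nx)
          # bond symbol on first-written side (nx was visited first)
          ring_tokens[[nx]] <<- c(ring_tokens[[nx]], paste0(.bond_token(mol, k), dt))
          ring_tokens[[node]] <<- c(ring_tokens[[node]], dt)
        }
      } else {
        visited[nx] <<- TRUE
        tree_children[[node]] <<- c(tree_children[[node]], nx)
        dfs(nx, node)
      }
    }
  }
  dfs(start, NA_integer_)
  if (!all(visited)) stop("molecule is not connected; cannot write single SMILES")

  emit <- function(node) {
    out <- .atom_token(mol, node, h, bos)
    out <- paste0(out, paste(ring_tokens[[node]], collapse = ""))
    ch <- tree_children[[node]]
    if (length(ch)) {
      for (idx in seq_along(ch)) {
        k <- bond_id(node, ch[idx])
        sub <- paste0(.bond_token(mol, k), emit(ch[idx]))
        if (idx < length(ch)) out <- paste0(out, "(", sub, ")")
        else out <- paste0(out, sub)
      }
    }
    out
  }
  emit(start)
}

.canon_cache <- new.env(parent = emptyenv())

#' Canonical SMILES key for a structure
#'
#' Atom-map labels are stripped so that keys compare structures only.
#' @param smiles SMILES string or a `mol` object
#' @return canonical SMILES string usable as a dictionary key
#' @export
canonical_smiles <- function(smiles) {
  if (is.character(smiles)) {
    hit <- .canon_cache[[smiles]]
    if (!is.null(hit)) return(hit)
    res <- write_smiles(parse_smiles(smiles), canonical = TRUE, keep_maps = FALSE)
    .canon_cache[[smiles]] <- res
    return(res)
  }
  write_smiles(smiles, canonical = TRUE, keep_maps = FALSE)
}

# ---- graph editing helpers used by fragmentation / recombination ----

mol_delete_atoms <- function(mol, idx) {
  keep <- setdiff(seq_len(n_atoms(mol)), idx)
  remap <- integer(n_atoms(mol)); remap[keep] <- seq_along(keep)
  kb <- !(mol$bond_a %in% idx) & !(mol$bond_b %in% idx)
  new_mol(mol$elem[keep], mol$arom[keep], mol$charge[keep], mol$hexp[keep],
          mol$isotope[keep], mol$chiral[keep], mol$map[keep],
          remap[mol$bond_a[kb]], remap[mol$bond_b[kb]],
          mol$bond_order[kb], mol$bond_arom[kb])
}

mol_delete_bond <- function(mol, k) {
  keep <- setdiff(seq_len(n_bonds(mol)), k)
  mol$bond_a <- mol$bond_a[keep]; mol$bond_b <- mol$bond_b[keep]
  mol$bond_order <- mol$bond_order[keep]; mol$bond_arom <- mol$bond_arom[keep]
  mol
}

mol_add_atom <- function(mol, elem, arom = FALSE, charge = 0L,
                         hexp = NA_integer_, map = 0L) {
  i <- n_atoms(mol) + 1L
  mol$elem[i] <- elem; mol$arom[i] <- arom; mol$charge[i] <- charge
  mol$hexp[i] <- hexp; mol$isotope[i] <- NA_integer_; mol$chiral[i] <- ""
  mol$map[i] <- map
  mol
}

mol_add_bond <- function(mol, i, j, order = 1L, arom = FALSE) {
  k <- n_bonds(mol) + 1L
  mol$bond_a[k] <- min(i, j); mol$bond_b[k] <- max(i, j)
  mol$bond_order[k] <- order; mol$bond_arom[k] <- arom
  mol
}

# disjoint union of two molecules; returns combined mol and the atom
# offset of the second block
mol_combine <- function(m1, m2) {
  off <- n_atoms(m1)
  list(mol = new_mol(
    c(m1$elem, m2$elem), c(m1$arom, m2$arom), c(m1$charge, m2$charge),
    c(m1$hexp, m2$hexp), c(m1$isotope, m2$isotope), c(m1$chiral, m2$chiral),
    c(m1$map, m2$map),
    c(m1$bond_a, m2$bond_a + off), c(m1$bond_b, m2$bond_b + off),
    c(m1$bond_order, m2$bond_order), c(m1$bond_arom, m2$bond_arom)
  ), offset = off)
}

# component membership after deleting bond k: TRUE for atoms on the
# `from` side
component_side <- function(mol, k, from) {
  m2 <- mol_delete_bond(mol, k)
  comp <- mol_components(m2)
  comp == comp[from]
}
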