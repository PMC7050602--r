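# Synthetic analog series and substituent pools.
#
# The generator builds chemically real series: an asymmetric ring core
# (2-methylpyridine, or quinoline beyond 4 sites) with substituents drawn
# from a fragment vocabulary, and potencies with exact Free-Wilson structure
# (base + per-site additive contributions), optional pairwise
# nonadditivity and Gaussian noise.  Ground truth for the full factorial
# lattice is returned alongside the sampled members.

# run code with a local RNG state seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.POOL_BODIES <- c(
  "C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C", "CC(C)C",
  "O", "OC", "OCC", "OC(C)C", "CO", "CCO", "COC",
  "N", "NC", "NCC", "N(C)C", "CN", "CCN",
  "F", "Cl", "Br", "I", "CF", "CCl", "C(F)(F)F", "OC(F)(F)F", "CC(F)(F)F",
  "C#N", "CC#N", "C=C", "CC=C",
  "C(=O)C", "C(=O)OC", "C(=O)N", "C(=O)NC", "C(=O)NCC",
  "OC(=O)C", "NC(=O)C", "C(=O)O", "S", "SC", "CS",
  "c1ccccc1", "c1ccncc1", "c1cccnc1", "c1ccc(F)cc1", "c1ccc(C)cc1",
  "c1ccc(O)cc1", "c1ccc(Cl)cc1", "c1ccco1", "c1cccs1",
  "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "N1CCCC1", "N1CCCCC1",
  "OCC(F)(F)F", "NCC(F)(F)F", "C(=O)NCC(F)(F)F"
)
.POOL_PREFIXES <- c("", "C", "CC", "CCC", "OC", "NC", "C(C)")

#' Generate a synthetic substituent pool
#'
#' Unique single-attachment-point fragments composed from a small
#' fragment grammar (prefix chain + terminal body).
#'
#' @param n_fragments requested pool size
#' @param max_heavy_atoms heavy-atom cap (default 13)
#' @param seed integer seed controlling sampling order
#' @return object of class `substituent_pool`: list with `fragments`
#'   (canonical SMILES, one wildcard each) and `source_tag`
#' @export
make_pool <- function(n_fragments, max_heavy_atoms = 13L, seed = 1L) {
  stopifnot(n_fragments >= 1L)
  combos <- expand.grid(prefix = .POOL_PREFIXES, body = .POOL_BODIES,
                        stringsAsFactors = FALSE)
  smiles <- paste0("*", combos$prefix, combos$body)
  keys <- vapply(smiles, function(s)
    tryCatch(canonical_smiles(s), error = function(e) NA_character_),
    character(1), USE.NAMES = FALSE)
  keys <- unique(keys[!is.na(keys)])
  heavy <- substituent_heavy_atoms(keys)
  keys <- keys[heavy >= 1L & heavy <= max_heavy_atoms]
  keys <- with_seed(seed, sample(keys))
  if (length(keys) < n_fragments) {
    warning("substituent grammar yields only ", length(keys),
            " unique fragments under the heavy-atom cap; returning all")
  } else {
    keys <- keys[seq_len(n_fragments)]
  }
  structure(list(fragments = keys, source_tag = "synthetic-grammar"),
            class = "substituent_pool")
}

#' @export
print.substituent_pool <- function(x, ...) {
  cat(sprintf("<substituent_pool> %d fragments (%s)\n",
              length(x$fragments), x$source_tag))
  invisible(x)
}

# Core scaffolds must be asymmetric: every open ring position has to be
# distinguishable by graph refinement alone, otherwise the site identity
# of substituents would depend on arbitrary symmetry breaking.
.core_for_sites <- function(n_sites, core_smiles = NULL) {
  core <- core_smiles
  if (is.null(core)) {
    core <- if (n_sites <= 4L) "Cc1ccccn1"       # 2-methylpyridine
    else if (n_sites <= 7L) "c1ccc2ncccc2c1"     # quinoline
    else stop("at most 7 substitution sites supported")
  }
  mol <- parse_smiles(core)
  ranks <- canonical_ranks(mol, split_ties = FALSE)
  h <- atom_hydrogens(mol)
  open_atoms <- which(h > 0 & atoms_in_ring(mol) & mol$elem != "*")
  if (anyDuplicated(ranks[open_atoms]))
    stop("core '", core, "' has symmetry-equivalent open positions; ",
         "choose an asymmetric scaffold")
  open <- sort(ranks[open_atoms])
  if (length(open) < n_sites)
    stop("core '", core, "' has only ", length(open),
         " open ring positions but ", n_sites, " sites were requested")
  list(coreH_key = canonical_smiles(core),
       core_heavy = mol_heavy_atoms(mol),
       site_ranks = open[seq_len(n_sites)])
}

#' Specification of a synthetic Free-Wilson potency landscape
#'
#' @param n_sites number of substitution sites (1-6)
#' @param substituents_per_site integer vector (recycled) of substituent
#'   counts per site, including hydrogen when `include_h` is TRUE
#' @param base_potency intercept in log potency units (default 6)
#' @param contribution_sd spread of the per-substituent additive
#'   contributions (default 0.75 log units)
#' @param nonadditivity optional data.frame with columns `site_a`,
#'   `sub_a`, `site_b`, `sub_b`, `delta`: pairwise interaction terms
#'   added when both substituents co-occur (indices into the per-site
#'   substituent lists)
#' @param noise_sd Gaussian noise on observed potencies (default 0.2 log
#'   units, the scale of experimental potency reproducibility)
#' @param occupancy fraction of the factorial lattice realized as
#'   existing analogs (default 1)
#' @param include_h make hydrogen the first substituent at every site
#' @param core_smiles optional core scaffold (asymmetric ring system with
#'   enough distinguishable CH positions); defaults to 2-methylpyridine
#'   for up to 4 sites and quinoline beyond
#' @param seed integer seed
#' @return object of class `landscape_spec`
#' @export
landscape_spec <- function(n_sites = 2L, substituents_per_site = 3L,
                           base_potency = 6, contribution_sd = 0.75,
                           nonadditivity = NULL, noise_sd = 0.2,
                           occupancy = 1, include_h = TRUE,
                           core_smiles = NULL, seed = 1L) {
  stopifnot(n_sites >= 1L, n_sites <= 6L)
  counts <- rep_len(as.integer(substituents_per_site), n_sites)
  if (any(counts < 1L)) stop("need at least one substituent per site")
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.null(nonadditivity)) {
    need <- c("site_a", "sub_a", "site_b", "sub_b", "delta")
    if (!all(need %in% names(nonadditivity)))
      stop("nonadditivity needs columns ", paste(need, collapse = ", "))
    if (any(nonadditivity$site_a == nonadditivity$site_b))
      stop("nonadditivity terms must couple two distinct sites")
    if (any(nonadditivity$site_a > n_sites | nonadditivity$site_b > n_sites |
              nonadditivity$sub_a > counts[nonadditivity$site_a] |
              nonadditivity$sub_b > counts[nonadditivity$site_b]))
      stop("nonadditivity term indexes a nonexistent site or substituent")
  }
  structure(list(n_sites = n_sites, counts = counts,
                 base_potency = base_potency,
                 contribution_sd = contribution_sd,
                 nonadditivity = nonadditivity, noise_sd = noise_sd,
                 occupancy = occupancy, include_h = include_h,
                 core_smiles = core_smiles, seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Build a synthetic analog series from a landscape specification
#'
#' @param spec a [landscape_spec()]
#' @return list with elements `series` (an `analog_series` whose members
#'   carry noisy observed potencies), `truth` (data.frame over the full
#'   factorial lattice with noiseless potencies and realized flags),
#'   `substituents` (per-site substituent lists),
#'   `contributions` (per-site additive terms) and `spec`
#' @export
make_series <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  core <- .core_for_sites(spec$n_sites, spec$core_smiles)
  res <- with_seed(spec$seed, {
    pool <- make_pool(sum(spec$counts) + 50L, seed = spec$seed + 1L)
    frags <- pool$fragments
    subs <- vector("list", spec$n_sites)
    used <- 0L
    for (s in seq_len(spec$n_sites)) {
      k <- spec$counts[s]
      n_frag <- if (spec$include_h) k - 1L else k
      if (used + n_frag > length(frags))
        stop("substituent grammar too small for the requested lattice")
      picks <- if (n_frag > 0L) frags[used + seq_len(n_frag)] else character(0)
      used <- used + n_frag
      subs[[s]] <- if (spec$include_h) c("H", picks) else picks
    }
    contrib <- lapply(seq_len(spec$n_sites), function(s) {
      v <- stats::rnorm(spec$counts[s], 0, spec$contribution_sd)
      v - v[1]  # reference substituent contributes zero
    })
    lattice <- expand.grid(lapply(spec$counts, seq_len))
    names(lattice) <- paste0("site", seq_len(spec$n_sites))
    truth_pot <- spec$base_potency +
      Reduce(`+`, lapply(seq_len(spec$n_sites),
                         function(s) contrib[[s]][lattice[[s]]]))
    if (!is.null(spec$nonadditivity)) {
      for (r in seq_len(nrow(spec$nonadditivity))) {
        na <- spec$nonadditivity[r, ]
        hit <- lattice[[na$site_a]] == na$sub_a & lattice[[na$site_b]] == na$sub_b
        truth_pot[hit] <- truth_pot[hit] + na$delta
      }
    }
    n_cells <- nrow(lattice)
    n_real <- max(1L, round(spec$occupancy * n_cells))
    realized <- sort(sample.int(n_cells, n_real))
    noise <- stats::rnorm(n_cells, 0, spec$noise_sd)
    list(subs = subs, contrib = contrib, lattice = lattice,
         truth_pot = truth_pot, realized = realized, noise = noise)
  })
  # assemble structures for realized cells
  lattice <- res$lattice
  labels <- paste0("R", seq_len(spec$n_sites))
  cell_smiles <- rep(NA_character_, nrow(lattice))
  is_real <- seq_len(nrow(lattice)) %in% res$realized
  members <- NULL
  rows <- list()
  for (ci in res$realized) {
    fr <- vapply(seq_len(spec$n_sites),
                 function(s) res$subs[[s]][lattice[ci, s]], character(1))
    smi <- attach_substituents(core$coreH_key, core$site_ranks, fr)
    cell_smiles[ci] <- smi
    rows[[length(rows) + 1L]] <- c(list(
      id = sprintf("EA%03d", ci), smiles = smi, key = smi,
      potency = res$truth_pot[ci] + res$noise[ci]),
      stats::setNames(as.list(fr), labels))
  }
  members <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (anyDuplicated(members$key))
    stop("substituent grammar produced duplicate analogs; widen the pool")
  rownames(members) <- NULL
  series <- structure(list(
    series_id = "SYN1",
    core = list(coreH_key = core$coreH_key, core_heavy = core$core_heavy,
                site_ranks = core$site_ranks, site_labels = labels),
    members = members,
    target_label = "synthetic"
  ), class = "analog_series")
  truth <- cbind(lattice,
                 data.frame(potency = res$truth_pot, realized = is_real,
                            smiles = cell_smiles, stringsAsFactors = FALSE))
  sub_tab <- lapply(res$subs, identity)
  list(series = series, truth = truth, substituents = sub_tab,
       contributions = res$contrib, spec = spec)
}

# substituent strings for one truth-lattice row
lattice_substituents <- function(fixture, cell) {
  vapply(seq_len(fixture$spec$n_sites),
         function(s) fixture$substituents[[s]][fixture$truth[cell, s]],
         character(1))
}

#' Write a fixture series to .smi / CSV files
#' @param fixture result of [make_series()]
#' @param dir output directory
#' @return invisibly, the file paths written
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mem <- fixture$series$members
  smi <- file.path(dir, "series.smi")
  writeLines(paste(mem$smiles, mem$id), smi)
  csv <- file.path(dir, "series.csv")
  utils::write.csv(mem[, c("id", "smiles", "potency")], csv, row.names = FALSE)
  invisible(c(smi = smi, csv = csv))
}
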