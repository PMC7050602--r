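# Analog sets, MMP fragmentation and analog-series assembly.

#' Build an analog set from ids, SMILES and potencies
#'
#' Validates and canonicalizes a compound collection. Unparsable
#' structures do not abort processing: they are collected in the
#' `errors` attribute of the result and dropped from the set.
#'
#' @param id character vector of compound identifiers
#' @param smiles character vector of SMILES
#' @param potency optional numeric vector of logarithmic potencies
#'   (pKi / pIC50); `NA` marks virtual analogs
#' @param provenance one of `"existing"`, `"virtual_diagnostic"`,
#'   `"virtual_fw"` (recycled)
#' @return data.frame of class `analog_set` with columns `id`, `smiles`,
#'   `key` (canonical SMILES), `potency`, `provenance`
#' @export
analog_set <- function(id, smiles, potency = NULL, provenance = "existing") {
  stopifnot(length(id) == length(smiles))
  if (is.null(potency)) potency <- rep(NA_real_, length(id))
  stopifnot(length(potency) == length(id))
  if (any(is.infinite(potency)))
    stop("potency values must be finite (or NA for virtual analogs)")
  provenance <- rep_len(provenance, length(id))
  key <- character(length(id))
  ok <- logical(length(id))
  errors <- list()
  for (i in seq_along(smiles)) {
    key[i] <- tryCatch(canonical_smiles(smiles[i]), error = function(e) {
      errors[[length(errors) + 1L]] <<- list(id = id[i], message = conditionMessage(e))
      NA_character_
    })
    ok[i] <- !is.na(key[i])
  }
  if (anyDuplicated(id[ok]))
    stop("duplicate compound ids: ", paste(unique(id[ok][duplicated(id[ok])]), collapse = ", "))
  dup <- duplicated(key[ok])
  if (any(dup)) {
    warning("dropping ", sum(dup), " compounds with duplicate canonical keys")
  }
  out <- data.frame(id = id[ok], smiles = smiles[ok], key = key[ok],
                    potency = as.numeric(potency[ok]),
                    provenance = provenance[ok], stringsAsFactors = FALSE)
  out <- out[!duplicated(out$key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("analog_set", "data.frame")
  attr(out, "errors") <- errors
  out
}

#' Read a .smi file (SMILES + id per line, whitespace separated)
#' @param path file path
#' @return an [analog_set()] (without potencies)
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no compounds in ", path)
  parts <- strsplit(lines, "[ \t]+")
  smiles <- vapply(parts, `[`, character(1), 1L)
  id <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][2L] else paste0("cpd", i)
  }, character(1))
  analog_set(id, smiles)
}

#' Read a compound/potency CSV with columns id, smiles, potency
#' @param path file path
#' @return an [analog_set()]
#' @export
read_potency_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "potency")
  if (!all(need %in% names(df)))
    stop("CSV must have columns id, smiles, potency")
  analog_set(as.character(df$id), df$smiles, as.numeric(df$potency))
}

#' Read an SD file (V2000), taking potencies from a named property tag
#' @param path file path
#' @param potency_tag property tag holding the logarithmic potency
#'   (default "potency"); missing tags yield NA
#' @param id_tag property tag holding the compound id; default uses the
#'   molecule title line, falling back to running numbers
#' @return an [analog_set()]
#' @export
read_sdf <- function(path, potency_tag = "potency", id_tag = NULL) {
  txt <- readLines(path, warn = FALSE)
  recs <- split(txt, cumsum(c(TRUE, utils::head(txt, -1) == "$$$$")))
  ids <- character(); smi <- character(); pot <- numeric()
  n <- 0L
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (!length(rec) || all(!nzchar(trimws(rec)))) next
    n <- n + 1L
    mol <- .parse_molblock(rec)
    props <- .parse_sdf_props(rec)
    id <- if (!is.null(id_tag) && !is.null(props[[id_tag]])) props[[id_tag]]
    else if (nzchar(trimws(rec[1]))) trimws(rec[1]) else paste0("cpd", n)
    p <- if (!is.null(props[[potency_tag]])) suppressWarnings(as.numeric(props[[potency_tag]]))
    else NA_real_
    ids <- c(ids, id); smi <- c(smi, write_smiles(mol)); pot <- c(pot, p)
  }
  if (!n) stop("no records in ", path)
  analog_set(ids, smi, pot)
}

.parse_molblock <- function(rec) {
  counts <- rec[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("bad V2000 counts line")
  elem <- character(na); charge <- integer(na)
  for (i in seq_len(na)) {
    elem[i] <- trimws(substr(rec[4 + i], 32, 34))
    chg <- suppressWarnings(as.integer(trimws(substr(rec[4 + i], 37, 39))))
    charge[i] <- switch(as.character(chg), "1" = 3L, "2" = 2L, "3" = 1L,
                        "5" = -1L, "6" = -2L, "7" = -3L, 0L)
  }
  ba <- integer(nb); bb <- integer(nb); bo <- integer(nb); bar <- logical(nb)
  for (k in seq_len(nb)) {
    ln <- rec[4 + na + k]
    ba[k] <- as.integer(substr(ln, 1, 3))
    bb[k] <- as.integer(substr(ln, 4, 6))
    typ <- as.integer(substr(ln, 7, 9))
    if (typ == 4L) { bo[k] <- 1L; bar[k] <- TRUE } else { bo[k] <- typ; bar[k] <- FALSE }
  }
  arom <- logical(na)
  if (any(bar)) { arom[ba[bar]] <- TRUE; arom[bb[bar]] <- TRUE }
  # charged atoms need explicit H counts we cannot infer reliably from a
  # molblock; use standard valence minus charge-adjusted bond sum
  hexp <- rep(NA_integer_, na)
  m <- new_mol(elem, arom, charge, hexp, rep(NA_integer_, na),
               rep("", na), rep(0L, na),
               pmin(ba, bb), pmax(ba, bb), bo, bar)
  # "M  CHG" lines override the legacy charge column
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  for (ln in chg_lines) {
    f <- as.integer(strsplit(trimws(substring(ln, 7)), "[ ]+")[[1]])
    cnt <- f[1]
    for (j in seq_len(cnt)) {
      m$charge[f[2 * j]] <- f[2 * j + 1]
    }
  }
  m
}

.parse_sdf_props <- function(rec) {
  idx <- grep("^>\\s*<", rec)
  props <- list()
  for (i in idx) {
    tag <- sub("^>\\s*<([^>]+)>.*$", "\\1", rec[i])
    val <- if (i + 1 <= length(rec)) rec[i + 1] else ""
    props[[tag]] <- trimws(val)
  }
  props
}

#' Matched molecular pair fragmentation
#'
#' Single-cut fragmentation of exocyclic single bonds under
#' retrosynthetic-style eligibility rules. Two compounds form an MMP when
#' they share a single-cut context (core plus all other substituents) and
#' differ in the exchanged substituent fragment.
#'
#' @param analogs an [analog_set()]
#' @param max_substituent_heavy_atoms heavy-atom cap for exchanged
#'   fragments (default 13)
#' @return data.frame of class `mmp_edges` with columns `analog_a`,
#'   `analog_b`, `context_key`, `substituent_a`, `substituent_b`,
#'   `context_heavy`; one row per unordered compound pair
#' @export
fragment_mmp <- function(analogs, max_substituent_heavy_atoms = 13L) {
  empty <- data.frame(analog_a = character(), analog_b = character(),
                      context_key = character(), substituent_a = character(),
                      substituent_b = character(), context_heavy = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("mmp_edges", "data.frame")
  if (nrow(analogs) == 0L) return(empty)
  splits <- vector("list", nrow(analogs))
  for (i in seq_len(nrow(analogs))) {
    sp <- single_cut_splits(parse_smiles(analogs$smiles[i]),
                            max_substituent_heavy_atoms)
    if (nrow(sp)) sp$id <- analogs$id[i]
    splits[[i]] <- sp
  }
  tab <- do.call(rbind, splits[vapply(splits, nrow, integer(1)) > 0])
  if (is.null(tab) || nrow(tab) == 0L) return(empty)
  tab$context_heavy <- substituent_heavy_atoms(tab$context_key)
  edges <- list()
  for (ctx in unique(tab$context_key)) {
    grp <- tab[tab$context_key == ctx, , drop = FALSE]
    grp <- grp[!duplicated(paste(grp$id, grp$frag)), , drop = FALSE]
    ids <- unique(grp$id)
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      fa <- grp$frag[grp$id == ids[i]]
      fb <- grp$frag[grp$id == ids[j]]
      # same context; exchanged fragments must differ
      for (x in fa) for (y in fb) {
        if (x == y) next
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        sa <- if (a == ids[i]) x else y
        sb <- if (a == ids[i]) y else x
        edges[[length(edges) + 1L]] <- data.frame(
          analog_a = a, analog_b = b, context_key = ctx,
          substituent_a = sa, substituent_b = sb,
          context_heavy = grp$context_heavy[1], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(edges)) return(empty)
  out <- do.call(rbind, edges)
  # one edge per unordered pair: keep the split with the largest context
  # (smallest exchanged fragments), ties broken by context key
  o <- order(out$analog_a, out$analog_b, -out$context_heavy, out$context_key)
  out <- out[o, , drop = FALSE]
  out <- out[!duplicated(paste(out$analog_a, out$analog_b)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mmp_edges", "data.frame")
  out
}

#' Assemble analog series from MMP relationships
#'
#' Connected components of the MMP network are resolved into series with
#' a shared hydrogen-filled core: the largest core (by heavy atoms, ties
#' by canonical key) common to every member under multi-cut fragmentation
#' is selected, and every member is decomposed into one substituent per
#' indexed site.  Compounds without MMP partners are left out as
#' singletons.
#'
#' @param analogs an [analog_set()]
#' @param mmp_edges result of [fragment_mmp()] on the same set
#' @param max_sites maximum number of substitution sites (default 6)
#' @param max_substituent_heavy_atoms heavy-atom cap (default 13)
#' @return list of `analog_series` objects
#' @export
assemble_series <- function(analogs, mmp_edges, max_sites = 6L,
                            max_substituent_heavy_atoms = 13L) {
  if (nrow(mmp_edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    mmp_edges[, c("analog_a", "analog_b")], directed = FALSE,
    vertices = data.frame(name = analogs$id))
  comp <- igraph::components(g)
  series <- list()
  for (ci in seq_len(comp$no)) {
    ids <- names(comp$membership)[comp$membership == ci]
    if (length(ids) < 2L) next
    sub <- analogs[match(ids, analogs$id), , drop = FALSE]
    core <- .find_common_core(sub, max_sites, max_substituent_heavy_atoms)
    if (is.null(core)) {
      # component links compounds without a shared core (a substituent of
      # one family matching the core of another); drop edges whose
      # context is dominated by the exchanged fragment and re-split
      parts <- .split_component(sub, mmp_edges)
      if (is.null(parts)) {
        warning("no common core for component of ", length(ids),
                " compounds (", paste(utils::head(ids, 3), collapse = ","),
                "...); skipped")
        next
      }
      for (p in parts) {
        cp <- .find_common_core(p, max_sites, max_substituent_heavy_atoms)
        if (is.null(cp)) {
          warning("no common core for sub-component of ", nrow(p),
                  " compounds; skipped")
          next
        }
        ser <- .build_series(p, cp, max_sites, max_substituent_heavy_atoms)
        if (!is.null(ser)) series[[length(series) + 1L]] <- ser
      }
      next
    }
    ser <- .build_series(sub, core, max_sites, max_substituent_heavy_atoms)
    if (!is.null(ser)) series[[length(series) + 1L]] <- ser
  }
  # deterministic ordering and ids: by decreasing size, then core key
  if (length(series)) {
    o <- order(-vapply(series, function(s) nrow(s$members), integer(1)),
               vapply(series, function(s) s$core$coreH_key, character(1)))
    series <- series[o]
    for (i in seq_along(series)) series[[i]]$series_id <- paste0("S", i)
  }
  series
}

# ring-atom and heavy-atom counts of a fragment key ("H" counts as zero)
.frag_stats <- function(key) {
  if (identical(key, "H")) return(c(rings = 0L, heavy = 0L))
  mol <- parse_smiles(key)
  c(rings = sum(atoms_in_ring(mol) & mol$elem != "*"),
    heavy = mol_heavy_atoms(mol))
}

# Keep only "strong" edges (context carries more ring atoms than the
# exchanged fragments, ties broken by heavy atoms) and return the
# resulting sub-components of the given compound subset; NULL when the
# filtering does not split anything.
.split_component <- function(sub, mmp_edges) {
  ed <- mmp_edges[mmp_edges$analog_a %in% sub$id &
                    mmp_edges$analog_b %in% sub$id, , drop = FALSE]
  if (!nrow(ed)) return(NULL)
  strong <- logical(nrow(ed))
  for (r in seq_len(nrow(ed))) {
    ctx <- .frag_stats(ed$context_key[r])
    fa <- .frag_stats(ed$substituent_a[r])
    fb <- .frag_stats(ed$substituent_b[r])
    fr <- max(fa["rings"], fb["rings"])
    fh <- max(fa["heavy"], fb["heavy"])
    strong[r] <- ctx[["rings"]] > fr ||
      (ctx[["rings"]] == fr && ctx[["heavy"]] >= fh)
  }
  ed <- ed[strong, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed[, c("analog_a", "analog_b")], directed = FALSE,
    vertices = data.frame(name = sub$id))
  comp <- igraph::components(g)
  if (comp$no <= 1L) return(NULL)
  parts <- list()
  for (ci in seq_len(comp$no)) {
    ids <- names(comp$membership)[comp$membership == ci]
    if (length(ids) < 2L) next
    parts[[length(parts) + 1L]] <- sub[match(ids, sub$id), , drop = FALSE]
  }
  if (!length(parts)) NULL else parts
}

.find_common_core <- function(sub, max_sites, max_heavy) {
  key_sets <- vector("list", nrow(sub))
  info <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(sub))) {
    mol <- parse_smiles(sub$smiles[i])
    own <- canonical_smiles(mol)
    cands <- multi_cut_decompositions(mol, max_cuts = max_sites,
                                      max_substituent_heavy_atoms = max_heavy)
    keys <- c(own, vapply(cands, function(cc) cc$coreH_key, character(1)))
    heavy <- c(mol_heavy_atoms(mol),
               vapply(cands, function(cc) cc$core_heavy, integer(1)))
    for (j in seq_along(keys)) assign(keys[j], heavy[j], envir = info)
    key_sets[[i]] <- unique(keys)
  }
  common <- Reduce(intersect, key_sets)
  if (!length(common)) return(NULL)
  heavy <- vapply(common, function(k) get(k, envir = info), numeric(1))
  o <- order(-heavy, common)
  list(coreH_key = common[o[1]], core_heavy = heavy[o[1]])
}

.build_series <- function(sub, core, max_sites, max_heavy) {
  decomp <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    d <- decompose_on_core(sub$smiles[i], core$coreH_key,
                           max_cuts = max_sites,
                           max_substituent_heavy_atoms = max_heavy)
    if (is.null(d)) return(NULL)
    decomp[[i]] <- d
  }
  site_ranks <- sort(unique(unlist(lapply(decomp, function(d) d$site_ranks))))
  if (!length(site_ranks)) return(NULL)
  if (length(site_ranks) > max_sites) {
    warning("series exceeds ", max_sites, " substitution sites; skipped")
    return(NULL)
  }
  labels <- paste0("R", seq_along(site_ranks))
  tab <- matrix("H", nrow(sub), length(site_ranks),
                dimnames = list(NULL, labels))
  for (i in seq_len(nrow(sub))) {
    d <- decomp[[i]]
    if (length(d$site_ranks))
      tab[i, match(d$site_ranks, site_ranks)] <- d$frags
  }
  members <- cbind(sub[, c("id", "smiles", "key", "potency"), drop = FALSE],
                   as.data.frame(tab, stringsAsFactors = FALSE))
  rownames(members) <- NULL
  structure(list(
    series_id = NA_character_,
    core = list(coreH_key = core$coreH_key, core_heavy = core$core_heavy,
                site_ranks = site_ranks, site_labels = labels),
    members = members,
    target_label = NULL
  ), class = "analog_series")
}

#' @export
print.analog_series <- function(x, ...) {
  cat(sprintf("<analog_series %s> core %s | %d sites | %d members\n",
              x$series_id, x$core$coreH_key,
              length(x$core$site_labels), nrow(x$members)))
  invisible(x)
}

#' Decompose one analog against a series core
#'
#' @param analog SMILES string (or `mol`)
#' @param series an `analog_series`
#' @return named character vector of substituents, one per site ("H" for
#'   unsubstituted sites); errors if the analog does not match the core.
#' @export
decompose <- function(analog, series) {
  d <- decompose_on_core(analog, series$core$coreH_key,
                         max_cuts = length(series$core$site_labels))
  if (is.null(d))
    stop("analog does not decompose on the series core ",
         series$core$coreH_key)
  extra <- setdiff(d$site_ranks, series$core$site_ranks)
  if (length(extra))
    stop("analog substitutes core positions outside the series sites")
  out <- stats::setNames(rep("H", length(series$core$site_labels)),
                         series$core$site_labels)
  if (length(d$site_ranks))
    out[match(d$site_ranks, series$core$site_ranks)] <- d$frags
  out
}

#' Reassemble an analog from a series core and per-site substituents
#'
#' @param series an `analog_series`
#' @param subs named or positional character vector of substituents
#'   (one per site, "H" allowed)
#' @return canonical SMILES of the assembled structure
#' @export
recompose <- function(series, subs) {
  if (!is.null(names(subs))) subs <- subs[series$core$site_labels]
  attach_substituents(series$core$coreH_key, series$core$site_ranks,
                      unname(subs))
}

#' Per-series MMP network with site labels
#'
#' Builds the MMP network over series members from the per-site
#' substituent table: an edge joins two members differing at exactly one
#' substitution site.
#'
#' @param series an `analog_series`
#' @return data.frame of class `mmp_network` with columns `analog_a`,
#'   `analog_b`, `site`, `substituent_a`, `substituent_b`
#' @export
series_mmp_network <- function(series) {
  mem <- series$members
  labs <- series$core$site_labels
  tab <- as.matrix(mem[, labs, drop = FALSE])
  n <- nrow(mem)
  empty <- data.frame(analog_a = character(), analog_b = character(),
                      site = character(), substituent_a = character(),
                      substituent_b = character(), stringsAsFactors = FALSE)
  class(empty) <- c("mmp_network", "data.frame")
  if (n < 2L) return(empty)
  # per-site integer codes; count differing sites for all pairs at once
  ndiff <- matrix(0L, n, n)
  last_diff_site <- matrix(0L, n, n)
  for (s in seq_along(labs)) {
    code <- match(tab[, s], unique(tab[, s]))
    ds <- outer(code, code, "!=")
    ndiff <- ndiff + ds
    last_diff_site[ds] <- s
  }
  hit <- which(ndiff == 1L & upper.tri(ndiff), arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  s <- last_diff_site[hit]
  out <- data.frame(
    analog_a = mem$id[hit[, 1]], analog_b = mem$id[hit[, 2]],
    site = labs[s],
    substituent_a = tab[cbind(hit[, 1], s)],
    substituent_b = tab[cbind(hit[, 2], s)],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mmp_network", "data.frame")
  out
}

#' Export a series member table as CSV
#' @param series an `analog_series`
#' @param path output file
#' @return invisibly, the written data.frame
#' @export
write_series_csv <- function(series, path) {
  df <- cbind(series_id = series$series_id, series$members)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
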