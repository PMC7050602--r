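# Chemical saturation and SAR progression diagnostics.
#
# A population of virtual analogs (VAs) is enumerated for a series from a
# substituent pool, projected together with the existing analogs (EAs)
# into a z-normalized physicochemical reference space, and analyzed
# through fixed-radius neighborhoods (NBHs) around each EA:
#
#   coverage    C = n_N / n_V           (VAs inside any NBH / all VAs)
#   density     d_mean = NBH_O_VA / n_N, D = 1 - 1/d_mean
#   saturation  S = 2CD / (C + D)       (harmonic mean; 0 when C+D = 0)
#   progression P = sum(w_i * dbar_i) / sum(w_i),
#     dbar_i = mean |pot_j - pot_k| over EA pairs sharing VA i,
#     w_i = 1/m_i when m_i > 1, else 0
#
# NBH_O_VA counts VA-in-NBH incidences (sum of the per-VA NBH
# multiplicities m_i over in-NBH VAs), so d_mean >= 1 and D in [0, 1).

#' Enumerate diagnostic virtual analogs for a series
#'
#' At every substitution site hydrogen is drawn with probability equal
#' to the observed hydrogen frequency among the series members at that
#' site; otherwise a pool fragment is drawn uniformly. Candidates
#' identical to an existing member (by canonical key) or already drawn
#' are rejected.
#'
#' @param series an `analog_series`
#' @param pool a `substituent_pool` (see [make_pool()]) or character
#'   vector of substituent SMILES
#' @param n_va target population size (default 2000)
#' @param seed integer seed; the draw is reproducible given the seed
#' @param max_attempts rejection-sampling budget as a multiple of `n_va`
#' @return an [analog_set()] with provenance `virtual_diagnostic`; fewer
#'   than `n_va` rows (with a warning) when the pool is too small
#' @export
enumerate_diagnostic_vas <- function(series, pool, n_va = 2000L, seed = 1L,
                                     max_attempts = 50L) {
  stopifnot(n_va >= 1L)
  frags <- if (inherits(pool, "substituent_pool")) pool$fragments else pool
  if (!length(frags)) stop("substituent pool is empty")
  labs <- series$core$site_labels
  mem <- series$members
  h_freq <- vapply(labs, function(l) mean(mem[[l]] == "H"), numeric(1))
  ea_keys <- mem$key
  n_sites <- length(labs)
  res <- with_seed(seed, {
    seen <- new.env(parent = emptyenv())
    for (k in ea_keys) assign(k, TRUE, envir = seen)
    out_smiles <- character(0)
    out_subs <- list()
    attempts <- 0L
    budget <- max_attempts * n_va
    while (length(out_smiles) < n_va && attempts < budget) {
      attempts <- attempts + 1L
      subs <- vapply(seq_len(n_sites), function(s) {
        if (stats::runif(1) < h_freq[s]) "H"
        else frags[[sample.int(length(frags), 1L)]]
      }, character(1))
      sig <- paste(subs, collapse = "\r")
      if (!is.null(seen[[sig]])) next
      seen[[sig]] <- TRUE
      key <- tryCatch(
        attach_substituents(series$core$coreH_key, series$core$site_ranks, subs),
        error = function(e) NA_character_)
      if (is.na(key) || !is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out_smiles <- c(out_smiles, key)
      out_subs[[length(out_subs) + 1L]] <- subs
    }
    list(smiles = out_smiles, subs = out_subs)
  })
  if (length(res$smiles) < n_va)
    warning("pool supports only ", length(res$smiles), " of ", n_va,
            " requested unique virtual analogs")
  if (!length(res$smiles)) stop("no virtual analogs could be enumerated")
  va <- analog_set(sprintf("VA%04d", seq_along(res$smiles)), res$smiles,
                   provenance = "virtual_diagnostic")
  sub_tab <- do.call(rbind, lapply(res$subs, function(s)
    as.data.frame(as.list(stats::setNames(s, labs)), stringsAsFactors = FALSE)))
  attr(va, "substituents") <- sub_tab
  attr(va, "seed") <- seed
  va
}

#' Build the normalized chemical reference space
#'
#' Descriptors are computed for the joint EA + VA population and
#' z-normalized (sample standard deviation) over that population.
#'
#' @param eas,vas [analog_set()]s of existing and virtual analogs
#' @param descriptors descriptor names (default 7D set, see
#'   [compute_descriptors()])
#' @return object of class `reference_space`: coordinates, normalization
#'   parameters, and the EA/VA partition
#' @export
build_reference_space <- function(eas, vas,
                                  descriptors = .DEFAULT_DESCRIPTORS) {
  ids <- c(eas$id, vas$id)
  smiles <- c(eas$key, vas$key)
  if (length(smiles) < 2L) stop("need at least two compounds")
  raw <- compute_descriptors(smiles, descriptors)
  center <- colMeans(raw)
  scale <- apply(raw, 2, stats::sd)
  zero <- !is.finite(scale) | scale < 1e-12
  if (any(zero)) {
    warning("zero-variance descriptor(s): ",
            paste(descriptors[zero], collapse = ", "), "; scale set to 1")
    scale[zero] <- 1
  }
  coords <- sweep(sweep(raw, 2, center), 2, scale, "/")
  structure(list(descriptor_names = descriptors, center = center,
                 scale = scale, coords = coords, ids = ids,
                 is_ea = c(rep(TRUE, nrow(eas)), rep(FALSE, nrow(vas)))),
            class = "reference_space")
}

#' @export
print.reference_space <- function(x, ...) {
  cat(sprintf("<reference_space> %dD, %d EAs + %d VAs\n",
              length(x$descriptor_names), sum(x$is_ea), sum(!x$is_ea)))
  invisible(x)
}

#' Neighborhood membership of virtual analogs around existing analogs
#'
#' Every EA defines a ball of the given radius (Euclidean distance in
#' the normalized space); the model records which VAs fall into which
#' EA neighborhoods.
#'
#' @param space a `reference_space`
#' @param radius NBH radius in normalized distance units (default 1)
#' @return object of class `nbh_model` with the logical membership
#'   matrix (VAs x EAs) and per-VA multiplicities `m`
#' @export
compute_nbh <- function(space, radius = 1) {
  if (radius <= 0) stop("radius must be positive")
  ea <- space$coords[space$is_ea, , drop = FALSE]
  va <- space$coords[!space$is_ea, , drop = FALSE]
  # squared Euclidean distances VA x EA
  d2 <- outer(rowSums(va^2), rowSums(ea^2), "+") - 2 * tcrossprod(va, ea)
  d2[d2 < 0] <- 0
  membership <- d2 <= radius^2
  dimnames(membership) <- list(space$ids[!space$is_ea], space$ids[space$is_ea])
  structure(list(radius = radius, membership = membership,
                 m = rowSums(membership),
                 n_va = nrow(va), n_ea = nrow(ea)),
            class = "nbh_model")
}

#' Chemical saturation scores from a neighborhood model
#'
#' @param nbh an `nbh_model`
#' @return list with `C`, `d_mean`, `D`, `S` and the underlying counts
#'   `n_V`, `n_N`, `NBH_O_VA`
#' @export
score_saturation <- function(nbh) {
  n_v <- nbh$n_va
  if (n_v < 1L) stop("no virtual analog population")
  m <- nbh$m
  in_nbh <- m >= 1L
  n_n <- sum(in_nbh)
  nbh_o_va <- sum(m[in_nbh])
  C <- n_n / n_v
  if (n_n == 0L) {
    return(list(C = 0, d_mean = NA_real_, D = 0, S = 0,
                n_V = n_v, n_N = 0L, NBH_O_VA = 0L))
  }
  d_mean <- nbh_o_va / n_n
  D <- 1 - 1 / d_mean
  S <- if (C + D == 0) 0 else 2 * C * D / (C + D)
  list(C = C, d_mean = d_mean, D = D, S = S,
       n_V = n_v, n_N = n_n, NBH_O_VA = nbh_o_va)
}

#' SAR progression score from a neighborhood model and EA potencies
#'
#' @param nbh an `nbh_model`
#' @param potencies named numeric vector of EA potencies (names matching
#'   the EA columns of the membership matrix)
#' @return list with `P` (NA when every in-NBH VA has multiplicity 1),
#'   `defined` flag, and the per-VA `dbar`/weights used
#' @export
score_progression <- function(nbh, potencies) {
  ea_ids <- colnames(nbh$membership)
  m <- nbh$m
  used <- m >= 1L
  touched <- colSums(nbh$membership[used, , drop = FALSE]) > 0
  missing_pot <- ea_ids[touched][!(ea_ids[touched] %in% names(potencies)) |
                                   is.na(potencies[ea_ids[touched]])]
  if (length(missing_pot))
    stop("missing potency for EA(s) with VA neighborhoods: ",
         paste(utils::head(missing_pot, 5), collapse = ", "))
  idx <- which(used)
  dbar <- numeric(length(idx)); w <- numeric(length(idx))
  for (r in seq_along(idx)) {
    eas <- ea_ids[nbh$membership[idx[r], ]]
    mi <- length(eas)
    if (mi > 1L) {
      pots <- potencies[eas]
      dd <- abs(outer(pots, pots, "-"))
      dbar[r] <- mean(dd[upper.tri(dd)])
      w[r] <- 1 / mi
    } else {
      dbar[r] <- NA_real_
      w[r] <- 0
    }
  }
  if (sum(w) == 0) {
    return(list(P = NA_real_, defined = FALSE, dbar = dbar, w = w))
  }
  list(P = sum(w * dbar, na.rm = TRUE) / sum(w), defined = TRUE,
       dbar = dbar, w = w)
}

#' Full diagnostic score report for one analog series
#'
#' Runs VA enumeration, reference-space construction, NBH analysis and
#' all scores (C, D, S, P, and the Free-Wilson saturation score N).
#'
#' @param series an `analog_series` with member potencies
#' @param pool substituent pool for VA enumeration
#' @param n_va VA population size (default 2000)
#' @param radius NBH radius (default 1 normalized unit)
#' @param descriptors reference-space descriptors
#' @param seed integer seed
#' @return object of class `score_report`
#' @export
score_series <- function(series, pool, n_va = 2000L, radius = 1,
                         descriptors = .DEFAULT_DESCRIPTORS, seed = 1L) {
  vas <- enumerate_diagnostic_vas(series, pool, n_va = n_va, seed = seed)
  eas <- analog_set(series$members$id, series$members$key,
                    series$members$potency)
  space <- build_reference_space(eas, vas, descriptors)
  nbh <- compute_nbh(space, radius)
  sat <- score_saturation(nbh)
  pot <- stats::setNames(series$members$potency, series$members$id)
  prog <- score_progression(nbh, pot)
  net <- series_mmp_network(series)
  nbhs <- find_fw_nbhs(series, net)
  fw_ea_ids <- unique(nbhs$target_id[nbhs$target_exists])
  n_fw_nbh <- sum(nbhs$target_exists)
  N <- score_fw_saturation(length(fw_ea_ids), n_fw_nbh)
  structure(list(
    series_id = series$series_id,
    C = sat$C, d_mean = sat$d_mean, D = sat$D, S = sat$S,
    P = prog$P, P_defined = prog$defined, N = N,
    counts = list(n_V = sat$n_V, n_N = sat$n_N, NBH_O_VA = sat$NBH_O_VA,
                  n_EA = nrow(series$members),
                  n_FW_EA = length(fw_ea_ids), n_FW_NBH = n_fw_nbh),
    parameters = list(radius = radius, dimension = length(descriptors),
                      descriptors = descriptors, n_va = n_va, seed = seed)
  ), class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf(
    "<score_report %s> C=%s D=%s S=%s P=%s N=%s (nV=%d nN=%d EAs=%d FW EAs=%d)\n",
    x$series_id, fmt(x$C), fmt(x$D), fmt(x$S), fmt(x$P), fmt(x$N),
    x$counts$n_V, x$counts$n_N, x$counts$n_EA, x$counts$n_FW_EA))
  invisible(x)
}

#' @export
as.data.frame.score_report <- function(x, ...) {
  data.frame(series_id = x$series_id, C = x$C, d_mean = x$d_mean, D = x$D,
             S = x$S, P = x$P, N = x$N, n_V = x$counts$n_V,
             n_N = x$counts$n_N, NBH_O_VA = x$counts$NBH_O_VA,
             n_EA = x$counts$n_EA, n_FW_EA = x$counts$n_FW_EA,
             n_FW_NBH = x$counts$n_FW_NBH, radius = x$parameters$radius,
             dimension = x$parameters$dimension, n_va = x$parameters$n_va,
             seed = x$parameters$seed, stringsAsFactors = FALSE)
}
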