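# Free-Wilson neighborhood detection, analog generation, potency
# prediction and the N saturation score.
#
# A Free-Wilson neighborhood (FW NBH) is a hub analog A with two MMP
# edges at distinct substitution sites, A-B at s1 and A-C at s2.  The
# double-substituted target X (hub with both new substituents applied)
# forms an MMP with B and with C but not with A, and its potency is
# predicted additively: pot(X) = pot(B) + pot(C) - pot(A).  Predictions
# for a target covered by several FW NBHs are averaged.

#' Find all Free-Wilson neighborhoods in a series MMP network
#'
#' Every hub with two or more MMP edges at distinct sites contributes one
#' FW NBH per unordered pair of such edges.
#'
#' @param series an `analog_series`
#' @param network result of [series_mmp_network()] for the series
#' @return data.frame of class `fw_nbhs`: columns `hub`, `b`, `c`,
#'   `site_1`, `site_2`, `sub_1`, `sub_2` (the newly introduced
#'   substituents at the two sites), `target_sig` (per-site substituent
#'   signature of the target), `target_id` (member id when the target
#'   exists, else NA) and `target_exists`
#' @export
find_fw_nbhs <- function(series, network) {
  mem <- series$members
  labs <- series$core$site_labels
  tab <- as.matrix(mem[, labs, drop = FALSE])
  rownames(tab) <- mem$id
  sig_of <- function(subs) paste(subs, collapse = "\r")
  member_sig <- apply(tab, 1, sig_of)
  sig_to_id <- stats::setNames(mem$id, member_sig)
  empty <- data.frame(hub = character(), b = character(), c = character(),
                      site_1 = character(), site_2 = character(),
                      sub_1 = character(), sub_2 = character(),
                      target_sig = character(), target_id = character(),
                      target_exists = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("fw_nbhs", "data.frame")
  if (nrow(network) == 0L) return(empty)
  # incident edges per hub, with the exchange direction hub -> partner
  inc <- rbind(
    data.frame(hub = network$analog_a, partner = network$analog_b,
               site = network$site, new_sub = network$substituent_b,
               stringsAsFactors = FALSE),
    data.frame(hub = network$analog_b, partner = network$analog_a,
               site = network$site, new_sub = network$substituent_a,
               stringsAsFactors = FALSE))
  site_idx <- match(inc$site, labs)
  parts <- list()
  for (h in unique(inc$hub)) {
    sel <- inc$hub == h
    ed <- inc[sel, , drop = FALSE]
    si <- site_idx[sel]
    ne <- nrow(ed)
    if (ne < 2L) next
    pr <- which(outer(si, si, "!=") & upper.tri(diag(ne)), arr.ind = TRUE)
    if (!nrow(pr)) next
    # order each pair by site label for a canonical representation
    swap <- ed$site[pr[, 1]] > ed$site[pr[, 2]]
    e1 <- ifelse(swap, pr[, 2], pr[, 1])
    e2 <- ifelse(swap, pr[, 1], pr[, 2])
    hub_subs <- tab[h, ]
    sig <- vapply(seq_along(e1), function(r) {
      subs <- hub_subs
      subs[si[e1[r]]] <- ed$new_sub[e1[r]]
      subs[si[e2[r]]] <- ed$new_sub[e2[r]]
      sig_of(subs)
    }, character(1))
    tid <- unname(sig_to_id[sig])
    parts[[length(parts) + 1L]] <- data.frame(
      hub = h, b = ed$partner[e1], c = ed$partner[e2],
      site_1 = ed$site[e1], site_2 = ed$site[e2],
      sub_1 = ed$new_sub[e1], sub_2 = ed$new_sub[e2],
      target_sig = sig, target_id = tid,
      target_exists = !is.na(tid), stringsAsFactors = FALSE)
  }
  if (!length(parts)) return(empty)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("fw_nbhs", "data.frame")
  out
}

#' Generate Free-Wilson virtual analogs from detected neighborhoods
#'
#' One target structure per neighborhood, deduplicated by canonical key.
#' Targets matching an existing member are returned as FW EAs; the rest
#' are new FW VAs differing from their hubs at exactly two sites.
#'
#' @param series an `analog_series`
#' @param nbhs result of [find_fw_nbhs()]
#' @return list with `fw_vas` (an [analog_set()], provenance
#'   `virtual_fw`, with the per-site substituent table as attribute
#'   `substituents`), `fw_eas` (subset of the member table) and `failed`
#'   (count of chemically invalid recombinations, skipped)
#' @export
generate_fw_vas <- function(series, nbhs) {
  mem <- series$members
  labs <- series$core$site_labels
  ex <- nbhs[nbhs$target_exists, , drop = FALSE]
  fw_ea_ids <- unique(ex$target_id)
  fw_eas <- mem[mem$id %in% fw_ea_ids, , drop = FALSE]
  rownames(fw_eas) <- NULL
  virt <- nbhs[!nbhs$target_exists, , drop = FALSE]
  sigs <- unique(virt$target_sig)
  smiles <- character(0); subs_rows <- list(); failed <- 0L
  for (sig in sigs) {
    subs <- strsplit(sig, "\r", fixed = TRUE)[[1]]
    key <- tryCatch(
      attach_substituents(series$core$coreH_key, series$core$site_ranks, subs),
      error = function(e) NA_character_)
    if (is.na(key)) { failed <- failed + 1L; next }
    smiles <- c(smiles, key)
    subs_rows[[length(subs_rows) + 1L]] <- subs
  }
  keep <- !duplicated(smiles)
  fw_vas <- if (length(smiles)) {
    va <- analog_set(sprintf("FWVA%04d", seq_len(sum(keep))), smiles[keep],
                     provenance = "virtual_fw")
    st <- do.call(rbind, lapply(subs_rows[keep], function(s)
      as.data.frame(as.list(stats::setNames(s, labs)), stringsAsFactors = FALSE)))
    attr(va, "substituents") <- st
    va
  } else {
    analog_set(character(0), character(0))
  }
  list(fw_vas = fw_vas, fw_eas = fw_eas, failed = failed)
}

#' Free-Wilson potency prediction for one target
#'
#' Per neighborhood: pot(B) + pot(C) - pot(A); the final prediction is
#' the unweighted mean over all neighborhoods of the target.
#'
#' @param target a `target_sig` value or an existing member id
#' @param nbhs result of [find_fw_nbhs()]
#' @param potencies named numeric vector of member potencies
#' @return object of class `fw_prediction`: `target`,
#'   `predicted_potency`, `n_nbhs`, `per_nbh_values`
#' @export
fw_predict <- function(target, nbhs, potencies) {
  hit <- nbhs$target_sig == target | (!is.na(nbhs$target_id) &
                                        nbhs$target_id == target)
  sel <- nbhs[hit, , drop = FALSE]
  if (!nrow(sel)) stop("no Free-Wilson neighborhood covers target ", target)
  need <- unique(c(sel$hub, sel$b, sel$c))
  miss <- need[!(need %in% names(potencies)) | is.na(potencies[need])]
  if (length(miss))
    stop("missing potency for compound(s): ", paste(miss, collapse = ", "))
  vals <- potencies[sel$b] + potencies[sel$c] - potencies[sel$hub]
  structure(list(target = target,
                 predicted_potency = mean(vals),
                 n_nbhs = nrow(sel),
                 per_nbh_values = unname(vals)),
            class = "fw_prediction")
}

#' @export
print.fw_prediction <- function(x, ...) {
  cat(sprintf("<fw_prediction> %s: %.3f over %d NBH(s)\n",
              x$target, x$predicted_potency, x$n_nbhs))
  invisible(x)
}

#' Virtualize every Free-Wilson existing analog and predict its potency
#'
#' Each FW EA (a member that is the target of at least one FW NBH) is
#' treated as unknown and predicted as the mean over the neighborhoods in
#' which it is the target; its own potency never enters those values.
#'
#' @param series an `analog_series`
#' @param nbhs result of [find_fw_nbhs()]
#' @return data.frame with columns `id`, `true_potency`, `predicted`,
#'   `n_nbhs`; zero rows when the series has no FW EAs
#' @export
virtualize_and_predict_eas <- function(series, nbhs) {
  pot <- stats::setNames(series$members$potency, series$members$id)
  ids <- unique(nbhs$target_id[nbhs$target_exists])
  out <- data.frame(id = character(), true_potency = numeric(),
                    predicted = numeric(), n_nbhs = integer(),
                    stringsAsFactors = FALSE)
  for (id in ids) {
    pr <- fw_predict(id, nbhs, pot)
    out <- rbind(out, data.frame(id = id, true_potency = pot[[id]],
                                 predicted = pr$predicted_potency,
                                 n_nbhs = pr$n_nbhs, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Free-Wilson neighborhood saturation score
#'
#' N = 1 - n_FW_EA / n_FW_NBH, where n_FW_NBH counts the neighborhoods
#' whose targets are existing analogs.  Undefined (NA) when there are no
#' such neighborhoods.
#'
#' @param n_fw_ea number of FW EAs
#' @param n_fw_nbh number of FW NBHs with existing targets
#' @return the N score in `[0, 1)`, or NA
#' @export
score_fw_saturation <- function(n_fw_ea, n_fw_nbh) {
  if (n_fw_nbh == 0L) return(NA_real_)
  if (n_fw_ea > n_fw_nbh)
    stop("n_fw_ea exceeds n_fw_nbh: every FW EA occupies at least one NBH")
  if (n_fw_ea < 0L) stop("counts must be nonnegative")
  1 - n_fw_ea / n_fw_nbh
}

#' Predict potencies for all Free-Wilson virtual analogs of a series
#'
#' @param series an `analog_series`
#' @param nbhs result of [find_fw_nbhs()]
#' @return data.frame: `target_sig`, `key`, `predicted`, `n_nbhs`,
#'   sorted by decreasing predicted potency
#' @export
fw_predict_vas <- function(series, nbhs) {
  gen <- generate_fw_vas(series, nbhs)
  va <- gen$fw_vas
  if (!nrow(va)) {
    return(data.frame(target_sig = character(), key = character(),
                      predicted = numeric(), n_nbhs = integer(),
                      stringsAsFactors = FALSE))
  }
  pot <- stats::setNames(series$members$potency, series$members$id)
  st <- attr(va, "substituents")
  sig <- apply(as.matrix(st), 1, paste, collapse = "\r")
  out <- data.frame(target_sig = sig, key = va$key,
                    predicted = NA_real_, n_nbhs = NA_integer_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    pr <- fw_predict(out$target_sig[r], nbhs, pot)
    out$predicted[r] <- pr$predicted_potency
    out$n_nbhs[r] <- pr$n_nbhs
  }
  out <- out[order(-out$predicted), , drop = FALSE]
  rownames(out) <- NULL
  out
}
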