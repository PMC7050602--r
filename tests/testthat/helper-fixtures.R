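# Shared fixtures and independent oracles.

# Four analogs reproducing the textbook Free-Wilson neighborhood: hub A,
# single-site partners B (R1-type change, +0.3) and C (R2-type change,
# +0.6), and the double-substituted target X.  Pyridine core, two
# distinguishable substitution sites; substituents chosen so that the
# A->B exchange is an aryl fluorination and the A->C exchange swaps a
# methyl ester for a trifluoroethyl amide.
fig1_analog_set <- function() {
  core <- "c1ccncc1"
  sites <- c(2L, 5L)
  A <- attach_substituents(core, sites, c("*Cc1ccncc1", "*C(=O)OC"))
  B <- attach_substituents(core, sites, c("*Cc1ccc(F)nc1", "*C(=O)OC"))
  C <- attach_substituents(core, sites, c("*Cc1ccncc1", "*C(=O)NCC(F)(F)F"))
  X <- attach_substituents(core, sites, c("*Cc1ccc(F)nc1", "*C(=O)NCC(F)(F)F"))
  analog_set(c("A", "B", "C", "X"), c(A, B, C, X),
             potency = c(8.4, 8.7, 9.0, 9.5))
}

# assembled series + network + neighborhoods for the four analogs
fig1_assembled <- function() {
  aset <- fig1_analog_set()
  edges <- fragment_mmp(aset)
  series <- assemble_series(aset, edges)
  stopifnot(length(series) == 1L)
  ser <- series[[1]]
  net <- series_mmp_network(ser)
  list(aset = aset, series = ser, network = net,
       nbhs = find_fw_nbhs(ser, net))
}

# random neighborhood-membership fixture (VA x EA logical matrix) wrapped
# as an nbh_model
random_nbh <- function(n_va, n_ea, p, radius = 1) {
  m <- matrix(stats::runif(n_va * n_ea) < p, n_va, n_ea)
  dimnames(m) <- list(paste0("VA", seq_len(n_va)), paste0("EA", seq_len(n_ea)))
  structure(list(radius = radius, membership = m, m = rowSums(m),
                 n_va = n_va, n_ea = n_ea), class = "nbh_model")
}

# --- independent brute-force score recomputation from a raw matrix ---

oracle_saturation <- function(membership) {
  n_v <- nrow(membership)
  mult <- apply(membership, 1, sum)
  inn <- mult >= 1
  n_n <- length(which(inn))
  C <- n_n / n_v
  if (n_n == 0) return(list(C = 0, d_mean = NA_real_, D = 0, S = 0))
  total_incidences <- 0
  for (i in which(inn)) total_incidences <- total_incidences + sum(membership[i, ])
  d_mean <- total_incidences / n_n
  D <- 1 - 1 / d_mean
  S <- if (C + D > 0) 2 * C * D / (C + D) else 0
  list(C = C, d_mean = d_mean, D = D, S = S)
}

oracle_progression <- function(membership, potencies) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(membership))) {
    eas <- which(membership[i, ])
    mi <- length(eas)
    if (mi <= 1) next
    tot <- 0; np <- 0
    for (a in seq_len(mi - 1)) for (b in (a + 1):mi) {
      tot <- tot + abs(potencies[eas[a]] - potencies[eas[b]])
      np <- np + 1
    }
    num <- num + (1 / mi) * (tot / np)
    den <- den + 1 / mi
  }
  if (den == 0) NA_real_ else unname(num / den)
}

# all-pairs MMP oracle over a per-site substituent table: pairs differing
# at exactly one site
oracle_mmp_pairs <- function(tab, ids) {
  out <- character(0)
  n <- nrow(tab)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    nd <- sum(tab[i, ] != tab[j, ])
    if (nd == 1) {
      a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
      out <- c(out, paste(a, b))
    }
  }
  sort(out)
}

# exhaustive FW-neighborhood oracle: all (hub, partner1, partner2)
# triples with single-site differences at two distinct sites; counts
# unordered partner pairs per hub
oracle_fw_nbhs <- function(tab, ids) {
  n <- nrow(tab)
  count <- 0L
  keys <- character(0)
  for (h in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || i == h || j == h) next
    di <- which(tab[h, ] != tab[i, ])
    dj <- which(tab[h, ] != tab[j, ])
    if (length(di) == 1 && length(dj) == 1 && di != dj) {
      count <- count + 1L
      keys <- c(keys, paste(ids[h], min(ids[i], ids[j]), max(ids[i], ids[j])))
    }
  }
  list(count = count, keys = sort(keys))
}

# small deterministic binary fingerprint fixture for model tests
random_fingerprints <- function(n, p = 64, density = 0.3, seed = 1) {
  with_seed(seed, matrix(as.integer(stats::runif(n * p) < density), n, p))
}

# independent epsilon-SVR dual solve via quadprog on a precomputed
# kernel.  The 2n-variable quadratic form is singular (rank n); a 1e-6
# ridge keeps solve.QP numerically stable without visibly moving the
# optimum on these problem sizes.
oracle_svr_qp <- function(K, y, C, eps) {
  n <- length(y)
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-6, 2 * n)
  d <- c(y - eps, -y - eps)
  A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  b0 <- c(0, rep(0, 2 * n), rep(-C, 2 * n))
  sol <- quadprog::solve.QP(D, d, A, b0, meq = 1)
  beta <- sol$solution[1:n] - sol$solution[(n + 1):(2 * n)]
  # bias from clearly interior support vectors only: at a kink (beta ~ 0)
  # or at the box the KKT equality does not hold
  tb <- 1e-4 * C
  free <- which(abs(beta) > tb & abs(beta) < C - tb)
  b <- if (length(free)) {
    mean(y[free] - eps * sign(beta[free]) -
           as.numeric(K[free, , drop = FALSE] %*% beta))
  } else {
    f0 <- as.numeric(K %*% beta)
    lo <- max(ifelse(beta < C - tb, y - eps - f0, -Inf))
    hi <- min(ifelse(beta > -C + tb, y + eps - f0, Inf))
    (lo + hi) / 2
  }
  list(beta = beta, b = b)
}
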