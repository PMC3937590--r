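# Fixture builders and independent oracles shared across test files.

# One plate row in the raw plate dialect. `treated` is a length-9 list of
# OD triplicates (already including background); defaults describe a clean
# plate with T0 = 100, control = 200 and background 10.
make_plate <- function(cellline = "CL1", compound = "drugX",
                       conc = 10^seq(-9, -5, length.out = 9),
                       background = 10,
                       od0 = c(210, 212, 208),
                       treated = NULL,
                       growth = NULL,
                       t0_median = 110) {
  if (is.null(treated)) {
    if (is.null(growth)) growth <- seq(80, -80, length.out = 9)
    treated <- lapply(100 + growth + background, function(v) rep(v, 3))
  }
  rec <- c(list(cellline = cellline, compound = compound,
                drug_plate_id = "DP1", T0_plate_id = "TP1",
                background_od1 = background, background_od2 = background),
           stats::setNames(as.list(od0), paste0("od0.", 1:3)),
           stats::setNames(as.list(unlist(treated)),
                           as.vector(t(outer(1:9, 1:3, function(j, r)
                             paste0("od", j, ".", r))))),
           list(T0_background_od1 = background,
                T0_background_od2 = background,
                T0_median_od = t0_median),
           stats::setNames(as.list(conc), paste0("c", 1:9)),
           list(units = "M"))
  tibble::as_tibble(rec)
}

# Small omic dataset with ids "G1|gene" ... over samples S1..Sn.
make_omic <- function(n = 10, p = 6, data_type = "expression_array",
                      seed = 1, ids = NULL) {
  withr::with_seed(seed, {
    if (is.null(ids)) ids <- sprintf("G%d|gene", seq_len(p))
    m <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sprintf("S%02d", seq_len(n)), ids))
    omic_dataset(m, data_type)
  })
}

# Small panel wrapper used by modeling tests.
quick_panel <- function(seed = 1, n_lines = 30, n_features = 200,
                        compounds = design_compound("dA"),
                        data_types = "expression_array") {
  simulate_panel(simulation_design(
    n_lines = n_lines, data_types = data_types, n_features = n_features,
    compounds = compounds, seed = seed))
}

# ---- independent oracles -------------------------------------------------

# AUC by exhaustive enumeration of all (positive, negative) pairs.
auc_enum <- function(scores, pos) {
  ip <- which(pos); ineg <- which(!pos)
  tot <- 0
  for (i in ip) for (j in ineg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(ip) * length(ineg))
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (minimum-likelihood convention).
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Weighted LS-SVM oracle: builds the saddle system entry by entry (loops,
# no shared code with the implementation) and solves it by QR.
lssvm_oracle <- function(Xs, y, gamma) {
  n <- nrow(Xs)
  w <- numeric(n)
  for (i in seq_len(n)) {
    w[i] <- n / (2 * sum(y == y[i]))
  }
  A <- matrix(0, n + 1, n + 1)
  A[1, 2:(n + 1)] <- 1
  A[2:(n + 1), 1] <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i + 1, j + 1] <- sum(Xs[i, ] * Xs[j, ]) + (i == j) / (gamma * w[i])
  }
  sol <- qr.solve(A, c(0, y))
  list(b = sol[1], alpha = sol[-1])
}

# Piecewise-log-linear crossing oracle: evaluate the interpolated growth
# curve on a dense log10-concentration grid and return the first grid point
# at or below `level`.
crossing_oracle <- function(conc, growth, level, n_grid = 1e5) {
  lc <- log10(conc)
  grid <- seq(min(lc), max(lc), length.out = n_grid)
  g <- stats::approx(lc, growth, xout = grid)$y
  hit <- which(g <= level)
  if (length(hit) == 0) return(list(value = -max(lc), clamped = "at_max"))
  if (hit[1] == 1) return(list(value = -min(lc), clamped = "at_min"))
  list(value = -grid[hit[1]], clamped = "none")
}
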