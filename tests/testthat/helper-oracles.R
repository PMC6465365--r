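# Independent oracles used by the tests. These deliberately re-derive
# results with different algorithms/data structures than the package code.

# Brute-force bounded volume growing: batch semantics written directly from
# the update rule, using plain R sets (no frontier bookkeeping).
bvgOracle <- function(z, seed, forbidden, deltaT, theta = Inf,
                      connectivity = 6L) {
  d <- dim(z)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  toIjk <- function(ind) {
    ind0 <- ind - 1L
    cbind(ind0 %% d[1L] + 1L, (ind0 %/% d[1L]) %% d[2L] + 1L,
          ind0 %/% (d[1L] * d[2L]) + 1L)
  }
  region <- seed
  repeat {
    ijk <- toIjk(region)
    nb <- unique(unlist(lapply(seq_len(nrow(offs)), function(o) {
      cand <- sweep(ijk, 2, offs[o, ], "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
        cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      cand[, 1] + d[1] * (cand[, 2] - 1L) + d[1] * d[2] * (cand[, 3] - 1L)
    })))
    nb <- setdiff(nb, region)
    nb <- nb[!forbidden[nb]]
    m <- mean(z[region])
    acc <- nb[abs(z[nb] - m) <= deltaT]
    if (length(acc) == 0L) return(list(region = sort(region), discarded = FALSE))
    region <- c(region, acc)
    if (is.finite(theta) && length(region) >= theta)
      return(list(region = sort(region), discarded = TRUE))
  }
}

# Exhaustive optimal assignment maximizing total Dice over all permutations.
assignmentOracle <- function(diceMat) {
  n <- max(dim(diceMat))
  full <- matrix(0, n, n)
  full[seq_len(nrow(diceMat)), seq_len(ncol(diceMat))] <- diceMat
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- -Inf
  bestP <- NULL
  for (p in perms(seq_len(n))) {
    s <- sum(full[cbind(seq_len(n), p)])
    if (s > best) { best <- s; bestP <- p }
  }
  list(total = best, assignment = bestP)
}

# Nested ANOVA by explicit projection matrices: P_X = X (X'X)^- X'.
nestedAnovaOracle <- function(df) {
  y <- df$value
  n <- length(y)
  proj <- function(X) {
    X %*% MASS::ginv(crossprod(X)) %*% t(X)
  }
  X0 <- matrix(1, n, 1)
  Xg <- stats::model.matrix(~ 0 + factor(df$group))
  Xa <- stats::model.matrix(~ 0 + factor(paste(df$group, df$animal)))
  P0 <- proj(X0); Pg <- proj(Xg); Pa <- proj(Xa)
  ssG <- drop(t(y) %*% (Pg - P0) %*% y)
  ssA <- drop(t(y) %*% (Pa - Pg) %*% y)
  ssE <- drop(t(y) %*% (diag(n) - Pa) %*% y)
  g <- length(unique(df$group))
  a <- length(unique(paste(df$group, df$animal)))
  msG <- ssG / (g - 1)
  msA <- ssA / (a - g)
  list(ssG = ssG, ssA = ssA, ssE = ssE, F = msG / msA,
       p = stats::pf(msG / msA, g - 1, a - g, lower.tail = FALSE))
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
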