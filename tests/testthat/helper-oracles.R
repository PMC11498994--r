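# Independent oracles, deliberately coded apart from the package internals.

# Textbook NIPALS PLS1, one component, on pre-scaled data: returns the
# regression coefficients on the scaled predictors.
nipals_pls1_coef <- function(Xs, ys) {
  u <- ys
  w <- t(Xs) %*% u / drop(crossprod(u))
  w <- w / sqrt(drop(crossprod(w)))
  t_score <- Xs %*% w
  q <- drop(crossprod(ys, t_score)) / drop(crossprod(t_score))
  drop(w) * q
}

# Closed-form ordinary least squares through the normal equations.
ols_normal_equations <- function(x, y) {
  A <- cbind(1, x)
  drop(solve(t(A) %*% A, t(A) %*% y))  # (intercept, slope)
}

# Brute-force pairwise clustering for two tiny peak tables: peaks i, j match
# when |rt_i - rt_j| <= 2 * window of their joint median (enumeration over
# all pairings; adequate for the hand-sized cases it is used on).
brute_pair_clusters <- function(rt1, rt2, window) {
  clusters <- list()
  used2 <- logical(length(rt2))
  for (i in seq_along(rt1)) {
    d <- abs(rt2 - rt1[i])
    j <- which(!used2 & d == min(d[!used2]) &
                 abs(rt2 - stats::median(c(rt1[i], rt2))) <= window)
    j <- j[abs((rt2[j] + rt1[i]) / 2 - rt1[i]) <= window &
             abs((rt2[j] + rt1[i]) / 2 - rt2[j]) <= window]
    if (length(j)) {
      used2[j[1L]] <- TRUE
      clusters[[length(clusters) + 1L]] <- c(rt1[i], rt2[j[1L]])
    } else clusters[[length(clusters) + 1L]] <- rt1[i]
  }
  for (j in which(!used2)) clusters[[length(clusters) + 1L]] <- rt2[j]
  clusters
}

# Fixture-backed toy inputs used across files.
table3_matrix <- function() fixture_matrix(load_fixture("table3"))
table5_activity <- function() load_fixture("table5")
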