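# independent brute-force oracles, kept deliberately naive

# per-voxel depth-layer density (3D voxel counting)
oracle_density_voxel <- function(mask, dz, offsets) {
  fg <- numeric(8); tot <- numeric(8)
  d <- dim(mask)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    depth <- (k - 0.5) * dz - offsets[i, j]
    if (is.na(depth) || depth < 0 || depth >= 20) next
    l <- floor(depth / 2.5) + 1
    tot[l] <- tot[l] + 1
    if (mask[i, j, k]) fg[l] <- fg[l] + 1
  }
  list(fg = fg, tot = tot, pct = ifelse(tot > 0, 100 * fg / tot, NA))
}

# per-layer 2D projection density (pixel counted once per layer)
oracle_density_projection <- function(mask, dz, offsets) {
  fg <- numeric(8); tot <- numeric(8)
  d <- dim(mask)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    seen <- rep(FALSE, 8); hit <- rep(FALSE, 8)
    for (k in seq_len(d[3])) {
      depth <- (k - 0.5) * dz - offsets[i, j]
      if (is.na(depth) || depth < 0 || depth >= 20) next
      l <- floor(depth / 2.5) + 1
      seen[l] <- TRUE
      if (mask[i, j, k]) hit[l] <- TRUE
    }
    tot <- tot + seen
    fg <- fg + hit
  }
  list(fg = fg, tot = tot, pct = ifelse(tot > 0, 100 * fg / tot, NA))
}

# quartiles by explicit sort-and-interpolate at positions (n-1)p + 1
oracle_quartiles <- function(x, probs = c(0.25, 0.5, 0.75)) {
  s <- sort(x)
  n <- length(s)
  vapply(probs, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# OLS through explicit normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = b[1], slope = b[2])
}
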