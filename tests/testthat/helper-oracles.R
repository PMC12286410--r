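# Independent brute-force oracles. These deliberately avoid the package's
# filtering code paths: circular convolutions are realized as explicit
# circulant matrices, Ra as a per-window loop, rank statistics from scratch.

# N x N circulant matrix for y[t] = sum_l f[l] x[(t - step*(l-1)) mod N]
oracle_circulant <- function(f, step, n) {
  A <- matrix(0, n, n)
  for (t in seq_len(n)) {
    for (l in seq_along(f)) {
      src <- ((t - 1 - step * (l - 1)) %% n) + 1
      A[t, src] <- A[t, src] + f[l]
    }
  }
  A
}

oracle_modwt_forward <- function(x, order, J) {
  f <- daubechies_filters(order)
  n <- length(x)
  V <- x
  W <- vector("list", J)
  for (j in seq_len(J)) {
    Ah <- oracle_circulant(f$wavelet, 2^(j - 1), n)
    Ag <- oracle_circulant(f$scaling, 2^(j - 1), n)
    W[[j]] <- drop(Ah %*% V)
    V <- drop(Ag %*% V)
  }
  list(W = W, V = V)
}

oracle_modwt_mra <- function(x, order, J) {
  f <- daubechies_filters(order)
  n <- length(x)
  fwd <- oracle_modwt_forward(x, order, J)
  inv_chain <- function(v, top_filter, j) {
    A <- oracle_circulant(top_filter, 2^(j - 1), n)
    v <- drop(t(A) %*% v)
    for (k in rev(seq_len(j - 1))) {
      Ag <- oracle_circulant(f$scaling, 2^(k - 1), n)
      v <- drop(t(Ag) %*% v)
    }
    v
  }
  details <- lapply(seq_len(J), function(j) inv_chain(fwd$W[[j]], f$wavelet, j))
  smooth <- fwd$V
  Ag <- lapply(seq_len(J), function(k) oracle_circulant(f$scaling, 2^(k - 1), n))
  for (k in rev(seq_len(J))) smooth <- drop(t(Ag[[k]]) %*% smooth)
  list(details = details, smooth = smooth)
}

oracle_ra <- function(x, w) {
  n <- length(x)
  lo <- (w - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- x[max(1, i - lo):min(n, i - lo + w - 1)]
    out[i] <- mean(abs(win - mean(win)))
  }
  out
}

# mid-ranks from scratch (sort-based), independent of base rank()
oracle_ranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

oracle_kruskal_H <- function(groups) {
  pooled <- unlist(groups)
  n <- length(pooled)
  r <- oracle_ranks(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(seq_along(groups), function(i)
      length(groups[[i]]) * (mean(r[idx == i]) - (n + 1) / 2)^2, numeric(1)))
  tt <- sum(sapply(unique(pooled), function(v) {
    t <- sum(pooled == v); t^3 - t
  }))
  h / (1 - tt / (n^3 - n))
}

# tiny ASCII-grid DEM written via plain writeLines, independent of write_raster
write_asc_by_hand <- function(values, path, cellsize = 0.008, xll = 0, yll = 0,
                              nodata = -9999) {
  hdr <- c(paste("ncols", ncol(values)), paste("nrows", nrow(values)),
           paste("xllcorner", xll), paste("yllcorner", yll),
           paste("cellsize", cellsize), paste("NODATA_value", nodata))
  rows <- apply(values, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  path
}

make_square_feature <- function(x0, y0, side, species_code) {
  list(rings = list(cbind(c(x0, x0 + side, x0 + side, x0),
                          c(y0, y0, y0 + side, y0 + side))),
       species_code = species_code)
}
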