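# Fixtures and independent oracles built in code at test time.

# 90-degree counter-clockwise rotation (no interpolation)
rot90m <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# flat image with a dark/bright horizontal line of Gaussian cross-profile
line_image <- function(nr = 41, nc = 81, row = 21, half_width = 2,
                       contrast = 80, background = 200) {
  d <- abs(outer(seq_len(nr) - row, rep(0, nc), `+`))
  round(pmin(pmax(background - contrast * exp(-d^2 / (2 * half_width^2)), 0), 255))
}

# flat image with a dark disc (Gaussian radial profile) centered in the frame
blob_image <- function(nr = 41, nc = 41, sigma = 2, contrast = 80,
                       background = 200) {
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  d2 <- outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, `+`)
  round(pmin(pmax(background - contrast * exp(-d2 / (2 * sigma^2)), 0), 255))
}

# binary fixtures (0/255)
binary_hline <- function(nr = 9, nc = 21, row = 5) {
  m <- matrix(0, nr, nc); m[row, ] <- 255; m
}
binary_rect <- function(nr = 15, nc = 30, rows = 6:10, cols = 6:25) {
  m <- matrix(0, nr, nc); m[rows, cols] <- 255; m
}
binary_ring <- function(n = 21, r_out = 7, r_in = 4) {
  c0 <- (n + 1) / 2
  d2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`)
  ifelse(d2 <= r_out^2 & d2 >= r_in^2, 255, 0)
}
binary_yjunction <- function() {
  m <- matrix(0, 25, 25)
  m[13, 3:13] <- 255
  for (i in 0:9) { m[13 - i, 13 + i] <- 255; m[13 + i, 13 + i] <- 255 }
  m
}

# number of 8-connected foreground components, by label propagation
count_components8 <- function(mask) {
  fg <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[fg] <- seq_len(sum(fg))
  shift0 <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr); cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    nb <- lab
    for (d in list(c(1,0),c(-1,0),c(0,1),c(0,-1),c(1,1),c(1,-1),c(-1,1),c(-1,-1))) {
      s <- shift0(lab, d[1], d[2])
      nb <- pmax(nb, s * fg)
    }
    nb[!fg] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  length(unique(lab[fg]))
}

# brute-force closing oracle via coordinate-set dilation/erosion on the
# (conceptually infinite) plane, foreground-preserving crop at the end
brute_close <- function(mask, se_width, se_height) {
  off <- veinviz:::ellipse_se_offsets(se_width, se_height)
  key <- function(r, c) complex(real = r, imaginary = c)
  a <- which(mask == 255, arr.ind = TRUE)
  if (nrow(a) == 0) return(mask * 0)
  dil <- unique(as.vector(outer(key(a[, 1], a[, 2]), key(off[, 1], off[, 2]), `+`)))
  ero <- dil[vapply(dil, function(p) all((p + key(off[, 1], off[, 2])) %in% dil),
                    logical(1))]
  out <- matrix(0, nrow(mask), ncol(mask))
  keep <- Re(ero) >= 1 & Re(ero) <= nrow(mask) & Im(ero) >= 1 & Im(ero) <= ncol(mask)
  out[cbind(Re(ero[keep]), Im(ero[keep]))] <- 255
  out
}

# for each foreground pixel of `a`, distance to the nearest foreground pixel
# of `b` (both binary matrices)
nearest_distances <- function(a, b) {
  pa <- which(a > 0, arr.ind = TRUE)
  pb <- which(b > 0, arr.ind = TRUE)
  stopifnot(nrow(pa) > 0, nrow(pb) > 0)
  vapply(seq_len(nrow(pa)), function(i) {
    sqrt(min((pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2))
  }, numeric(1))
}

# skeleton endpoints: foreground pixels with exactly one 8-neighbor
count_endpoints <- function(mask) {
  fg <- (mask > 0) * 1L
  pad <- matrix(0L, nrow(fg) + 2, ncol(fg) + 2)
  pad[2:(nrow(fg) + 1), 2:(ncol(fg) + 1)] <- fg
  n <- 0L
  for (i in 2:(nrow(fg) + 1)) for (j in 2:(ncol(fg) + 1)) {
    if (pad[i, j] == 1 && sum(pad[(i-1):(i+1), (j-1):(j+1)]) - 1L == 1L) n <- n + 1L
  }
  n
}
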