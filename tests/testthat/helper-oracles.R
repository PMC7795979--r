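# Independent brute-force oracles: naive double loops sharing no code with
# the package implementations.

# Per-pixel Kirsch response: explicit loops over pixels, kernels and taps,
# replicate padding.
oracle_kirsch <- function(px, kernels) {
  nr <- nrow(px); nc <- ncol(px)
  ks <- nrow(kernels[[1]])
  r <- (ks - 1) %/% 2
  out <- matrix(0, nr, nc)
  for (y in 1:nr) for (x in 1:nc) {
    best <- -Inf
    for (k in kernels) {
      acc <- 0
      for (dy in -r:r) for (dx in -r:r) {
        yy <- min(max(y + dy, 1), nr)
        xx <- min(max(x + dx, 1), nc)
        acc <- acc + k[dy + r + 1, dx + r + 1] * px[yy, xx]
      }
      if (acc > best) best <- acc
    }
    out[y, x] <- best
  }
  out
}

# Pair-counting GLCM: explicit loop over pixel pairs.
oracle_glcm <- function(px, levels, distance, angle, symmetric) {
  q <- floor(px * levels / 256)
  off <- switch(as.character(angle),
                "0"   = c(0, distance),
                "45"  = c(-distance, distance),
                "90"  = c(-distance, 0),
                "135" = c(-distance, -distance))
  counts <- matrix(0, levels, levels)
  for (y in 1:nrow(q)) for (x in 1:ncol(q)) {
    y2 <- y + off[1]; x2 <- x + off[2]
    if (y2 >= 1 && y2 <= nrow(q) && x2 >= 1 && x2 <= ncol(q)) {
      i <- q[y, x] + 1; j <- q[y2, x2] + 1
      counts[i, j] <- counts[i, j] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# Descriptor formulas evaluated by double loops over the matrix cells.
oracle_descriptors <- function(p) {
  G <- nrow(p)
  asm <- 0; ent <- 0; con <- 0; idm <- 0; eij <- 0
  px <- rowSums(p); py <- colSums(p)
  mx <- sum((0:(G - 1)) * px); my <- sum((0:(G - 1)) * py)
  sx <- sqrt(sum((0:(G - 1))^2 * px) - mx^2)
  sy <- sqrt(sum((0:(G - 1))^2 * py) - my^2)
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]
    asm <- asm + v^2
    if (v > 0) ent <- ent - v * log2(v)
    con <- con + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    eij <- eij + (i - 1) * (j - 1) * v
  }
  corr <- if (sx == 0 || sy == 0) NA_real_ else (eij - mx * my) / (sx * sy)
  c(asm = asm, entropy = ent, contrast = con, correlation = corr, idm = idm)
}

# Textbook Pearson coefficient.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Rotate a compass kernel by one 45-degree step: cells are ordered by angle
# within each square ring and cyclically shifted by one eighth of the ring.
oracle_rotate_kernel <- function(kern) {
  ks <- nrow(kern)
  r <- (ks - 1) %/% 2
  out <- matrix(0, ks, ks)
  for (rho in 1:r) {
    cells <- list()
    for (dy in -rho:rho) for (dx in -rho:rho) {
      if (max(abs(dx), abs(dy)) == rho) {
        cells[[length(cells) + 1]] <- c(dx, dy, atan2(-dy, dx) %% (2 * pi))
      }
    }
    angs <- sapply(cells, `[`, 3)
    ord <- order(angs)
    n <- length(ord)
    shift <- n / 8
    for (i in seq_len(n)) {
      src <- cells[[ord[i]]]
      dst <- cells[[ord[(i - 1 + shift) %% n + 1]]]
      out[dst[2] + r + 1, dst[1] + r + 1] <- kern[src[2] + r + 1, src[1] + r + 1]
    }
  }
  out
}

random_gray <- function(w, h, seed) {
  set.seed(seed)
  gray_image(matrix(sample(0:255, w * h, replace = TRUE), h, w))
}
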