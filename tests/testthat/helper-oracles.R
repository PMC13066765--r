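# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (brute-force flood fill, literal sum-over-pairs
# partition, closed-form solves).

# Brute-force connected-component count by iterative flood fill over a binary
# matrix (1 = habitat), rook or queen connectivity.
oracle_patch_count <- function(grid, connectivity = 8) {
  nr <- nrow(grid); nc <- ncol(grid)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    nb <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  n <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (grid[r, c] != 1 || seen[r, c]) next
      n <- n + 1L
      stack <- list(c(r, c))
      seen[r, c] <- TRUE
      while (length(stack)) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(nb))) {
          rr <- cur[1] + nb[k, 1]; cc <- cur[2] + nb[k, 2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              grid[rr, cc] == 1 && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            stack[[length(stack) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  n
}

# Multi-site abundance partition assembled purely from pairwise_bray() output
# sums (independent accumulation path).
oracle_multi_site <- function(m) {
  n <- nrow(m)
  sA <- 0; smin <- 0; smax <- 0
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      pb <- pairwise_bray(m[j, ], m[k, ])
      sA <- sA + pb$A
      smin <- smin + min(pb$B, pb$C)
      smax <- smax + max(pb$B, pb$C)
    }
  }
  total <- (smin + smax) / (2 * sA + smin + smax)
  bal <- smin / (sA + smin)
  c(total = total, balanced = bal, gradient = total - bal)
}

# Shoelace polygon area.
oracle_polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Small habitat raster straight from a matrix given in reading order
# (top row first), as one would sketch it on paper.
raster_from_rows <- function(rows, cell_size = 30, year = NA_integer_) {
  m <- do.call(rbind, rows)
  habitat_raster(m[rev(seq_len(nrow(m))), , drop = FALSE],
                 cell_size = cell_size, year = year)
}

# A small valid inventory table + matching abundance matrix.
make_inventories <- function(n = 5, effort = 0.5, dbh = 5) {
  inv <- data.frame(
    id = sprintf("inv%02d", seq_len(n)),
    x = seq_len(n), y = rep(1, n), year = 2000 + seq_len(n),
    effort_ha = rep(effort, length.out = n),
    dbh_cutoff_cm = rep(dbh, length.out = n),
    stringsAsFactors = FALSE
  )
  ab <- matrix(1L, nrow = n, ncol = 3,
               dimnames = list(inv$id, c("sp1", "sp2", "sp3")))
  list(inventories = inv, abundances = ab)
}

# Two columns with an exact sample correlation r (and exact unit sample sd).
make_exact_corr_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  z1 <- (z1 - mean(z1)) / sd(z1)
  z2 <- residuals(lm(z2 ~ z1))
  z2 <- (z2 - mean(z2)) / sd(z2)
  x2 <- r * z1 + sqrt(1 - r^2) * z2
  data.frame(a = z1, b = x2 / sd(x2))
}
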