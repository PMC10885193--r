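# Independent brute-force oracles used across the test files. These are
# deliberately naive implementations kept separate from the package code
# paths they validate.

# Recursive flood-fill connected-component labelling.
flood_fill_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 4) cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
        else cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  cur <- 0L
  fill <- function(r0, c0) {
    stack <- list(c(r0, c0))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      r <- p[1]; c <- p[2]
      if (r < 1 || r > H || c < 1 || c > W) next
      if (!mask[r, c] || lab[r, c] != 0L) next
      lab[r, c] <<- cur
      for (k in seq_len(nrow(nb)))
        stack[[length(stack) + 1]] <- c(r + nb[k, 1], c + nb[k, 2])
    }
  }
  for (c in seq_len(W)) for (r in seq_len(H)) {
    if (mask[r, c] && lab[r, c] == 0L) { cur <- cur + 1L; fill(r, c) }
  }
  lab
}

# Identical label partition up to renaming?
same_partition <- function(a, b) {
  fa <- as.vector(a); fb <- as.vector(b)
  if (!identical(fa == 0L, fb == 0L)) return(FALSE)
  fg <- fa != 0L
  length(unique(paste(fa[fg], fb[fg]))) ==
    length(unique(fa[fg])) &&
    length(unique(fa[fg])) == length(unique(fb[fg]))
}

# Exhaustive optimal one-to-one matching between point sets under a gate:
# among assignments with the maximum number of links (all links <= gate),
# pick the one minimizing total squared displacement. Returns the set of
# (i, j) pairs.
brute_force_match <- function(x1, y1, x2, y2, gate) {
  n <- length(x1); m <- length(x2)
  best <- list(links = -1, cost = Inf, pairs = NULL)
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  consider <- function(idx) { # idx: for each of 1..n, 0 or index in 1..m
    used <- idx[idx > 0]
    if (anyDuplicated(used)) return()
    ok <- all(vapply(seq_len(n), function(i)
      idx[i] == 0 || d2[i, idx[i]] <= gate^2, TRUE))
    if (!ok) return()
    links <- sum(idx > 0)
    cost <- sum(vapply(seq_len(n), function(i)
      if (idx[i] > 0) d2[i, idx[i]] else 0, 0))
    if (links > best$links ||
        (links == best$links && cost < best$cost - 1e-12)) {
      best <<- list(links = links, cost = cost,
                    pairs = cbind(which(idx > 0), idx[idx > 0]))
    }
  }
  grid <- expand.grid(rep(list(0:m), n))
  for (r in seq_len(nrow(grid))) consider(as.integer(grid[r, ]))
  best
}

# Small synthetic contrast frame: signed Gaussian spots on zero background.
spot_frame <- function(H, W, spots, sigma_px = 1.5) {
  img <- matrix(0, H, W)
  for (s in spots) {
    for (r in seq_len(H)) for (c in seq_len(W)) {
      img[r, c] <- img[r, c] +
        s$amp * exp(-((c - 0.5 - s$x)^2 + (r - 0.5 - s$y)^2) /
                      (2 * sigma_px^2))
    }
  }
  img
}

# Movie of static rendered particles for end-to-end fixtures.
static_particle_truth <- function(x_nm, y_nm, z_nm, arrival, dwell) {
  structure(list(particle_id = 1L, arrival_frame = arrival,
                 dwell_frames = dwell, dwell_frames_drawn = dwell,
                 dwell_ms_true = NA_real_,
                 x_nm = rep(x_nm, dwell), y_nm = rep(y_nm, dwell),
                 z_nm = rep(z_nm, dwell), exited_fov = FALSE),
            class = "particle_truth")
}
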