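# Shared fixtures. The full-size island stack is expensive (~10 s), so it is
# built once per test run and memoised here; small toys are built inline.

the_cache <- new.env(parent = emptyenv())

demo_island <- function() {
  if (is.null(the_cache$island)) {
    dem <- generate_dem(island_config())
    stack <- build_predictors(dem)
    the_cache$island <- list(dem = dem, stack = stack,
                             fit = scale_transfer(stack, 60)$fit)
  }
  the_cache$island
}

# small matrix-backed raster with everything land
toy_crast <- function(values, cell_m = 5) {
  crast(as.matrix(values), cell_m = cell_m)
}

# DEM with land where `land` is TRUE, elevation `elev`
toy_dem <- function(land, elev = 10, cell_m = 5) {
  v <- matrix(NA_real_, nrow(land), ncol(land))
  v[land] <- if (length(elev) == 1) elev else elev[land]
  crast(v, cell_m = cell_m)
}

# independent flood-fill component labelling (queue-based BFS), used as the
# oracle for igraph-backed connected components
bfs_label <- function(mask, connectivity = 8) {
  lab <- matrix(NA_integer_, nrow(mask), ncol(mask))
  offs <- if (connectivity == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || !is.na(lab[i, j])) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] && is.na(lab[r, c])) {
          lab[r, c] <- cur
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# brute-force epsilon-graph components by union-find, the oracle for
# consolidate_sites / loco_folds
uf_components <- function(x, y, eps) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# shoelace polygon area for one closed ring
shoelace <- function(x, y) {
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}
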