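#' @importFrom withr with_seed
NULL

# shift a matrix by (dr, dc), filling exposed cells with `fill`
mat_shift <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  if (max(1, 1 - dr) > min(nr, nr - dr) ||
      max(1, 1 - dc) > min(nc, nc - dc)) return(out)
  r_src <- max(1, 1 - dr):min(nr, nr - dr)
  c_src <- max(1, 1 - dc):min(nc, nc - dc)
  out[r_src + dr, c_src + dc] <- m[r_src, c_src]
  out
}

# offsets (dr, dc) of cells whose center lies within `radius_cells` of the
# focal cell center (Euclidean, in cell units); optionally drop the center
disc_offsets <- function(radius_cells, include_center = TRUE) {
  k <- floor(radius_cells)
  g <- expand.grid(dr = -k:k, dc = -k:k)
  g <- g[g$dr^2 + g$dc^2 <= radius_cells^2 + 1e-9, ]
  if (!include_center) g <- g[!(g$dr == 0 & g$dc == 0), ]
  g
}

# NA-aware focal statistic over a disc, by shift-accumulation.
# stat: "mean", "max", "min", "sum", "count"
focal_disc <- function(m, radius_cells, stat = "mean", include_center = TRUE) {
  off <- disc_offsets(radius_cells, include_center)
  nr <- nrow(m); nc <- ncol(m)
  if (stat %in% c("mean", "sum", "count")) {
    s <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
    for (i in seq_len(nrow(off))) {
      sh <- mat_shift(m, off$dr[i], off$dc[i], fill = NA)
      ok <- !is.na(sh)
      s[ok] <- s[ok] + sh[ok]
      cnt <- cnt + ok
    }
    switch(stat,
           mean = ifelse(cnt > 0, s / cnt, NA),
           sum = s, count = cnt)
  } else {
    acc <- matrix(if (stat == "max") -Inf else Inf, nr, nc)
    for (i in seq_len(nrow(off))) {
      sh <- mat_shift(m, off$dr[i], off$dc[i], fill = NA)
      ok <- !is.na(sh)
      acc[ok] <- if (stat == "max") pmax(acc[ok], sh[ok]) else pmin(acc[ok], sh[ok])
    }
    acc[!is.finite(acc)] <- NA
    acc
  }
}

# connected-component labels of a logical matrix; returns integer matrix
# (NA off-mask), labels 1..k in decreasing component size
cc_label <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  idx <- which(mask)
  if (length(idx) == 0) return(matrix(NA_integer_, nrow(mask), ncol(mask)))
  nr <- nrow(mask)
  id <- matrix(NA_integer_, nrow(mask), ncol(mask))
  id[idx] <- seq_along(idx)
  offs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  edges <- integer(0)
  for (o in offs) {
    a <- id
    b <- mat_shift(id, -o[1], -o[2], fill = NA)  # neighbor (r+dr, c+dc) pulled back
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) edges <- c(edges, rbind(a[ok], b[ok]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  # relabel by decreasing size
  ord <- order(comp$csize, decreasing = TRUE)
  relab <- integer(comp$no); relab[ord] <- seq_len(comp$no)
  out <- matrix(NA_integer_, nrow(mask), ncol(mask))
  out[idx] <- relab[comp$membership]
  out
}

# deterministic 32-bit stage seed derived from a global seed and a label
stage_seed <- function(global_seed, stage) {
  h <- as.numeric(global_seed) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
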