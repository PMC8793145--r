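# Marching-squares iso-contour tracing on a 2D scalar field.
#
# Returns closed sub-pixel polygons at the requested level, with vertex
# positions linearly interpolated along crossed pixel edges. Coordinates are
# 0-based: x along columns, y along rows. Saddle cells are disambiguated by
# the cell-centre average. Used by extract_contour() after the binary mask
# has been lightly smoothed, which is what makes the traced 0.5-level polygon
# sub-pixel accurate rather than a staircase.

ms_isocontours <- function(z, level) {
  nr <- nrow(z); nc <- ncol(z)
  ins <- z > level

  nh <- nr * (nc - 1)                       # horizontal edge count
  # horizontal edge (i, j): between z[i, j] and z[i, j + 1]; id (i-1)*(nc-1)+j
  # vertical   edge (i, j): between z[i, j] and z[i + 1, j]; id nh+(i-1)*nc+j
  h_id <- function(i, j) (i - 1L) * (nc - 1L) + j
  v_id <- function(i, j) nh + (i - 1L) * nc + j
  n_edges <- nh + (nr - 1L) * nc
  pos_x <- rep(NA_real_, n_edges)
  pos_y <- rep(NA_real_, n_edges)

  # crossing positions for every edge whose endpoints straddle the level
  hz1 <- z[, -nc, drop = FALSE]; hz2 <- z[, -1, drop = FALSE]
  hx <- which(xor(hz1 > level, hz2 > level), arr.ind = TRUE)
  if (nrow(hx)) {
    i <- hx[, 1]; j <- hx[, 2]
    t <- (level - hz1[hx]) / (hz2[hx] - hz1[hx])
    ids <- h_id(i, j)
    pos_x[ids] <- (j - 1) + t
    pos_y[ids] <- i - 1
  }
  vz1 <- z[-nr, , drop = FALSE]; vz2 <- z[-1, , drop = FALSE]
  vx <- which(xor(vz1 > level, vz2 > level), arr.ind = TRUE)
  if (nrow(vx)) {
    i <- vx[, 1]; j <- vx[, 2]
    t <- (level - vz1[vx]) / (vz2[vx] - vz1[vx])
    ids <- v_id(i, j)
    pos_x[ids] <- j - 1
    pos_y[ids] <- (i - 1) + t
  }

  # cell codes: tl*8 + tr*4 + br*2 + bl
  a <- ins[-nr, -nc, drop = FALSE]; b <- ins[-nr, -1, drop = FALSE]
  cc <- ins[-1, -1, drop = FALSE];  d <- ins[-1, -nc, drop = FALSE]
  code <- a * 8L + b * 4L + cc * 2L + d
  cells <- which(code > 0L & code < 15L, arr.ind = TRUE)
  if (!nrow(cells)) return(list())

  seg_a <- integer(0); seg_b <- integer(0)
  add_seg <- function(e1, e2) {
    seg_a[[length(seg_a) + 1L]] <<- e1
    seg_b[[length(seg_b) + 1L]] <<- e2
  }
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]
    cd <- code[i, j]
    top <- h_id(i, j); bottom <- h_id(i + 1L, j)
    left <- v_id(i, j); right <- v_id(i, j + 1L)
    if (cd %in% c(1L, 14L)) add_seg(left, bottom)
    else if (cd %in% c(2L, 13L)) add_seg(bottom, right)
    else if (cd %in% c(4L, 11L)) add_seg(top, right)
    else if (cd %in% c(8L, 7L)) add_seg(top, left)
    else if (cd %in% c(3L, 12L)) add_seg(left, right)
    else if (cd %in% c(6L, 9L)) add_seg(top, bottom)
    else {
      ctr <- (z[i, j] + z[i, j + 1L] + z[i + 1L, j] + z[i + 1L, j + 1L]) / 4
      if (cd == 5L) {          # tr and bl inside
        if (ctr > level) { add_seg(top, left); add_seg(bottom, right) }
        else { add_seg(top, right); add_seg(left, bottom) }
      } else {                 # cd == 10: tl and br inside
        if (ctr > level) { add_seg(top, right); add_seg(left, bottom) }
        else { add_seg(top, left); add_seg(bottom, right) }
      }
    }
  }

  nseg <- length(seg_a)
  adj1 <- integer(n_edges); adj2 <- integer(n_edges)
  for (s in seq_len(nseg)) {
    for (e in c(seg_a[s], seg_b[s])) {
      if (adj1[e] == 0L) adj1[e] <- s else adj2[e] <- s
    }
  }
  other_seg <- function(e, s) {
    if (adj1[e] == s) adj2[e] else adj1[e]
  }

  visited <- logical(nseg)
  loops <- list()
  for (s0 in seq_len(nseg)) {
    if (visited[s0]) next
    edges <- integer(0)
    s <- s0
    e <- seg_a[s0]
    start_e <- e
    repeat {
      visited[s] <- TRUE
      edges <- c(edges, e)
      e_next <- if (seg_a[s] == e) seg_b[s] else seg_a[s]
      ns <- other_seg(e_next, s)
      if (ns == 0L || visited[ns]) {
        if (e_next != start_e) edges <- c(edges, e_next)
        break
      }
      e <- e_next
      s <- ns
    }
    loops[[length(loops) + 1L]] <- cbind(x = pos_x[edges], y = pos_y[edges])
  }
  loops
}

# Separable Gaussian smoothing with zero-fill boundaries (background = 0).
gauss_blur <- function(m, sigma = 1) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  shift_rows <- function(x, s) {
    nr <- nrow(x)
    out <- matrix(0, nr, ncol(x))
    if (s == 0) return(x)
    if (s > 0) out[(1 + s):nr, ] <- x[1:(nr - s), , drop = FALSE]
    else out[1:(nr + s), ] <- x[(1 - s):nr, , drop = FALSE]
    out
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (t in -r:r) out <- out + k[t + r + 1] * shift_rows(m, t)
  m2 <- t(out)
  out <- matrix(0, nrow(m2), ncol(m2))
  for (t in -r:r) out <- out + k[t + r + 1] * shift_rows(m2, t)
  t(out)
}
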