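# Shared fixtures and independent oracles.

# place a hexagon molecule (frozen template) at a centroid with a plane
# normal, without using the package's placement code path beyond the template
hex_at <- function(at, normal = c(0, 0, 1), spin = 0, edge = 1.40) {
  tpl <- hexagon_template(edge)
  rz <- matrix(c(cos(spin), sin(spin), 0, -sin(spin), cos(spin), 0, 0, 0, 1), 3, 3)
  z <- c(0, 0, 1); n <- normal / sqrt(sum(normal^2))
  v <- c(z[2] * n[3] - z[3] * n[2], z[3] * n[1] - z[1] * n[3], z[1] * n[2] - z[2] * n[1])
  s <- sqrt(sum(v^2)); c_ <- sum(z * n)
  r <- if (s < 1e-12) {
    if (c_ > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  }
  sweep(tpl %*% t(rz) %*% t(r), 2, at, `+`)
}

# frame + topology holding hexagons at the given centroids/normals
hex_system <- function(centroids, normals = NULL, box = 50, time = 0) {
  n <- nrow(centroids)
  if (is.null(normals)) normals <- matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE)
  coords <- do.call(rbind, lapply(seq_len(n), function(i)
    hex_at(centroids[i, ], normals[i, ])))
  topo <- mol_topology(lapply(seq_len(n), function(i) {
    atoms <- (i - 1L) * 6L + 1:6
    list(id = sprintf("mol%d", i), atoms = atoms, elements = rep("C", 6),
         rings = list(atoms))
  }))
  list(frame = traj_frame(time, box, coords), topology = topo)
}

# brute-force minimum-image distance by enumerating all 27 periodic images
brute_min_image <- function(p, q, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- sqrt(sum((q + c(i, j, k) * box - p)^2))
    if (d < best) best <- d
  }
  best
}

# hand-rolled union-find partition from an edge list over n nodes
union_find_partition <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (length(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

# canonical form of a partition (for set equality)
canon_partition <- function(parts) {
  parts <- lapply(parts, function(p) sort(as.integer(p)))
  parts[order(vapply(parts, `[`, integer(1), 1))]
}

# Newell's method plane normal (independent of the SVD fit)
newell_normal <- function(xyz) {
  n <- nrow(xyz)
  v <- c(0, 0, 0)
  for (i in seq_len(n)) {
    a <- xyz[i, ]; b <- xyz[if (i == n) 1 else i + 1, ]
    v <- v + c((a[2] - b[2]) * (a[3] + b[3]),
               (a[3] - b[3]) * (a[1] + b[1]),
               (a[1] - b[1]) * (a[2] + b[2]))
  }
  v / sqrt(sum(v^2))
}

mol_id_of <- function(i) sprintf("mol%d", i)
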