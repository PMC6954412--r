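# Shared fixtures: random rigid motions, simple axis-aligned label atom
# sets, and small canonical ensembles. Everything is built in code.

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# planar label atoms in the xy-plane: ring hexagon, N-O along +x
flat_label <- function(shift = c(0, 0, 0), R = diag(3), O_out_of_plane = 0) {
  tpl <- peldor::frame_to_atoms(
    peldor::nitroxide_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    "syn")
  tpl$O <- tpl$O + c(0, 0, O_out_of_plane)
  move <- function(p) {
    p <- rbind(p)
    out <- t(R %*% t(p)) + matrix(shift, nrow(p), 3, byrow = TRUE)
    if (nrow(out) == 1L) drop(out) else out
  }
  list(ring = move(tpl$ring), N = move(tpl$N), O = move(tpl$O),
       d1 = move(tpl$d1))
}

# two axis-aligned parallel labels separated along z (u parallel to both
# z axes); r_nm in nanometres
axis_pair <- function(r_nm = 3.7) {
  frA <- peldor::nitroxide_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  frB <- peldor::nitroxide_frame(c(0, 0, 10 * r_nm), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  peldor::spin_pair(frA, frB)
}

as_ensemble <- function(...) {
  structure(list(...), class = "spin_pair_ensemble")
}

# brute-force best-fit plane: average the unit normals of all atom
# triples (sign-aligned), then project onto the span; independent of the
# SVD route used by the package
brute_force_plane_normal <- function(points) {
  n_ref <- NULL
  acc <- c(0, 0, 0)
  idx <- utils::combn(nrow(points), 3)
  for (c_i in seq_len(ncol(idx))) {
    i <- idx[, c_i]
    v <- pracma::cross(points[i[2], ] - points[i[1], ],
                       points[i[3], ] - points[i[1], ])
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) next
    v <- v / nv
    if (is.null(n_ref)) n_ref <- v
    if (sum(v * n_ref) < 0) v <- -v
    acc <- acc + v
  }
  acc / sqrt(sum(acc^2))
}
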