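# Shared fixtures, built in code at test time.

# a toy structure model from a coordinate matrix
toy_model <- function(xyz, atom = "CA", element = "C", resno = NULL,
                      resid = "ALA") {
  n <- nrow(xyz)
  structure_model(data.frame(
    atom = rep_len(atom, n), element = rep_len(element, n),
    resno = if (is.null(resno)) seq_len(n) else resno,
    resid = rep_len(resid, n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

random_rotation_fixture <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# brute-force superposition oracle: minimize RMSD over Euler angles with
# multi-start Nelder-Mead on centred coordinates (independent of Kabsch)
grid_superpose_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((Ac %*% rot(ang) - Bc)^2)))
  starts <- as.matrix(expand.grid(a = c(0, pi / 2, pi, 3 * pi / 2),
                                  b = c(-pi / 3, 0.4, pi / 3),
                                  c = c(0, 2, 4)))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# minimal peak table for io tests
small_peak_table <- function() {
  data.frame(residue_index = rep(c(5L, 6L), each = 4),
             residue = rep(c("A", "L"), each = 4),
             time_min = rep(c(10, 20, 30, 40), 2),
             height = c(exp(-0.01 * c(10, 20, 30, 40)),
                        exp(-0.05 * c(10, 20, 30, 40))),
             pD = 5.5, temperature_K = 298.15)
}
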