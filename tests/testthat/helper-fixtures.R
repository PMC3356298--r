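# shared fixtures and independent oracles, all built in code

kB_ref <- 1.987204259e-3  # kcal/mol/K, restated independently of the package

# a single hand-placed frame: S, C, N collinear on x, tetrahedral cap on N
# whose lone pair points from N toward C (perfect SN2 alignment, theta = 0)
make_aligned_frame <- function(r_cn = 3.0, r_cs = 1.8) {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  # rotate so the missing vertex (tet[1, ]) points along +x (toward C at 0)
  rot <- rotation_onto(tet[1, ], c(1, 0, 0))
  p_n <- c(-r_cn, 0, 0)
  coords <- array(NA_real_, c(6, 3, 1))
  coords[1, , 1] <- c(r_cs, 0, 0)                       # SD
  coords[2, , 1] <- c(0, 0, 0)                          # CM
  coords[3, , 1] <- p_n                                 # NZ
  for (s in 1:3) coords[3 + s, , 1] <- p_n + 1.2 * (tet[s + 1, ] %*% t(rot))[1, ]
  frame_series(coords, c("SD", "CM", "NZ", "CE", "HZ1", "HZ2"),
               role_map("SD", "CM", "NZ", c("CE", "HZ1", "HZ2")))
}

# independent rotation construction (Gram-Schmidt frames, no Rodrigues)
rotation_onto <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  basis_for <- function(v) {
    ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e2 <- ref - sum(ref * v) * v; e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(v[2] * e2[3] - v[3] * e2[2],
            v[3] * e2[1] - v[1] * e2[3],
            v[1] * e2[2] - v[2] * e2[1])
    cbind(v, e2, e3)
  }
  basis_for(b) %*% t(basis_for(a))
}

# apply a rigid rotation + translation to every frame of a series
rigid_transform <- function(fs, rot, shift) {
  coords <- fs$coords
  for (f in seq_len(dim(coords)[3])) {
    coords[, , f] <- coords[, , f] %*% t(rot) +
      matrix(shift, dim(coords)[1], 3, byrow = TRUE)
  }
  frame_series(coords, fs$atom_names, fs$role_map,
               temperature = fs$temperature, elements = fs$elements,
               resnames = fs$resnames, index = fs$index, time = fs$time)
}

# brute-force per-frame geometry by plain arithmetic loops
brute_geometry <- function(fs) {
  n <- dim(fs$coords)[3]
  out <- data.frame(r_cn = numeric(n), r_cs = numeric(n),
                    R = numeric(n), theta = numeric(n))
  dist3 <- function(a, b) sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 +
                                 (a[3] - b[3])^2)
  for (f in seq_len(n)) {
    at <- function(role) fs$coords[fs$role_index[role, f], , f]
    p_s <- at("s_delta"); p_c <- at("c_methyl"); p_n <- at("n_zeta")
    s <- c(0, 0, 0)
    for (r in c("sub1", "sub2", "sub3")) {
      bv <- at(r) - p_n
      s <- s + bv / dist3(bv, c(0, 0, 0))
    }
    u <- -s / dist3(s, c(0, 0, 0))
    v <- p_s - p_c
    cosang <- sum(u * v) / dist3(v, c(0, 0, 0))
    out$r_cn[f] <- dist3(p_c, p_n)
    out$r_cs[f] <- dist3(p_c, p_s)
    out$R[f] <- out$r_cs[f] - out$r_cn[f]
    out$theta[f] <- acos(max(-1, min(1, cosang))) * 180 / pi
  }
  out
}

# brute-force 2D binning by a double loop over edges
brute_histogram2d <- function(r, theta, r_edges, t_edges) {
  nr <- length(r_edges) - 1; nt <- length(t_edges) - 1
  counts <- matrix(0L, nr, nt)
  for (k in seq_along(r)) {
    for (i in seq_len(nr)) {
      hi_r <- if (i == nr) r[k] <= r_edges[i + 1] else r[k] < r_edges[i + 1]
      if (!(r[k] >= r_edges[i] && hi_r)) next
      for (j in seq_len(nt)) {
        hi_t <- if (j == nt) theta[k] <= t_edges[j + 1] else
          theta[k] < t_edges[j + 1]
        if (theta[k] >= t_edges[j] && hi_t) {
          counts[i, j] <- counts[i, j] + 1L
        }
      }
    }
  }
  counts
}

# a quick double-well + protocol + windows bundle for WHAM tests
make_wham_case <- function(barrier = 13.4, n_per_window = 5000, seed = 1,
                           n_windows = 20) {
  pot <- make_potential("quartic_double_well", barrier = barrier,
                        r_a = -1.4, r_b = 1.2)
  proto <- umbrella_protocol(pot, n_windows = n_windows)
  windows <- gen_umbrella_windows(pot, proto$centers,
                                  proto$force_constants,
                                  n_per_window = n_per_window, seed = seed)
  list(potential = pot, protocol = proto, windows = windows)
}
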