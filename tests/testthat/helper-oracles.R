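# Independent oracle implementations and small fixture builders. These stay
# deliberately naive (O(N^2) loops, generator exponentials, brute-force
# sweeps) so they share no code path with the package.

# --- rotation oracles -------------------------------------------------------

# Wigner matrix by composing generator exponentials: D_l(exp(theta K)) =
# expm(theta G_l), with G_l estimated from the package's sh convention at
# the identity via finite differences of axis rotations
oracle_wigner_generators <- function(l) {
  h <- 1e-6
  gen <- list()
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (a in 1:3) {
    Rp <- .oracle_axis_rot(axes[[a]], h)
    Rm <- .oracle_axis_rot(axes[[a]], -h)
    Dp <- .oracle_wigner_lstsq(l, Rp); Dm <- .oracle_wigner_lstsq(l, Rm)
    gen[[a]] <- (Dp - Dm) / (2 * h)
  }
  gen
}

.oracle_axis_rot <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

.oracle_expm <- function(A, terms = 40L) {
  out <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in seq_len(terms)) {
    term <- term %*% A / k
    out <- out + term
  }
  out
}

# D_l via generator exponential for rotation about a single axis by theta
oracle_wigner_axis <- function(l, axis, theta, gens) {
  u <- axis / sqrt(sum(axis^2))
  G <- u[1] * gens[[1]] + u[2] * gens[[2]] + u[3] * gens[[3]]
  .oracle_expm(theta * G)
}

# D_l by least squares over sampled directions: sh(Rv) = D sh(v)
.oracle_wigner_lstsq <- function(l, R, n = 25L) {
  d <- 2L * l + 1L
  A <- matrix(0, n, d); B <- matrix(0, n, d)
  for (i in seq_len(n)) {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    A[i, ] <- spherical_harmonics(v, l)[[as.character(l)]]
    B[i, ] <- spherical_harmonics(as.vector(R %*% v), l)[[as.character(l)]]
  }
  t(qr.solve(A, B))
}

oracle_wigner_lstsq <- .oracle_wigner_lstsq

# --- geometry oracles -------------------------------------------------------

oracle_dist_matrix <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    out[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  out
}

# brute-force interface flags and radius+kNN edges
oracle_graph <- function(coords, partner_id, interface_cutoff, edge_cutoff,
                         max_neighbors) {
  n <- nrow(coords)
  D <- oracle_dist_matrix(coords, coords)
  iface <- numeric(n)
  for (i in seq_len(n)) {
    other <- which(partner_id != partner_id[i])
    iface[i] <- as.numeric(any(D[i, other] <= interface_cutoff))
  }
  edges <- data.frame(from = integer(0), to = integer(0))
  for (j in seq_len(n)) {
    cand <- setdiff(which(D[, j] <= edge_cutoff), j)
    if (length(cand) > max_neighbors)
      cand <- cand[order(D[cand, j])][seq_len(max_neighbors)]
    if (length(cand))
      edges <- rbind(edges, data.frame(from = cand, to = j))
  }
  list(iface = iface, edges = edges)
}

# independent Kabsch via bio3d; returns RMSD of mobile onto fixed
oracle_fit_rmsd <- function(fixed, mobile) {
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(fixed)),
                           mobile = as.vector(t(mobile)),
                           fixed.inds = seq_len(3 * nrow(fixed)),
                           mobile.inds = seq_len(3 * nrow(mobile)))
  m <- matrix(fitted, ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums((m - fixed)^2)))
}

# brute-force cross-partner residue contacts (any heavy-atom pair <= cutoff)
oracle_contacts <- function(complex, cutoff = 5) {
  at <- complex$atoms
  a <- at[at$partner == "a", ]; b <- at[at$partner == "b", ]
  pairs <- character(0)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
    if (d <= cutoff) pairs <- c(pairs, paste(a$res_row[i], b$res_row[j], sep = "-"))
  }
  unique(pairs)
}

# --- ranking oracles --------------------------------------------------------

oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

oracle_mcc_f1_sweep <- function(scores, labels) {
  best_mcc <- -Inf; best_f1 <- -Inf
  for (t in unique(scores)) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    best_mcc <- max(best_mcc, mcc); best_f1 <- max(best_f1, f1)
  }
  c(mcc = best_mcc, f1 = best_f1)
}

# step-by-step threshold walk of the printed AP definition
oracle_ap_walk <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  r_prev <- 0; ap <- 0
  for (t in thr) {
    sel <- scores >= t
    r <- sum(labels[sel] == 1) / P
    p <- sum(labels[sel] == 1) / sum(sel)
    ap <- ap + (r - r_prev) * p
    r_prev <- r
  }
  ap
}

# --- fixtures ---------------------------------------------------------------

# hand-placed complex: two short strands with controllable separation
toy_complex <- function(gap = 5, n_a = 4L, n_b = 3L) {
  mk <- function(chain, n, zoff) {
    ca <- cbind(3.8 * seq_len(n), 0, zoff)
    res <- data.frame(chain_id = chain, seq_index = seq_len(n),
                      insertion_code = "", aa_type = rep("A", n),
                      ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                      stringsAsFactors = FALSE)
    atoms <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(res_row = i,
                 atom_name = c("N", "CA", "C", "O"),
                 x = ca[i, 1] + c(-1.2, 0, 1.2, 1.6),
                 y = ca[i, 2] + c(0, 0, 0, 1.0),
                 z = ca[i, 3], stringsAsFactors = FALSE)))
    list(res = res, atoms = atoms)
  }
  a <- mk("A", n_a, 0); b <- mk("B", n_b, gap)
  protein_complex(a$res, b$res, rbind(cbind(partner = "a", a$atoms),
                                      cbind(partner = "b", b$atoms)),
                  source_id = "toy")
}

expect_rotation <- function(R) {
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
  expect_gt(det(R), 0)
}
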