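#' Synthetic-dataset configuration
#'
#' Defines the study conditions for the synthetic decoy generator: the number
#' of native scaffolds, decoys per native, chain lengths of the two partners,
#' the rigid-body noise ladder spanning incorrect to high CAPRI quality, and
#' the group-wise split fractions.
#'
#' @param n_natives Number of native complexes.
#' @param decoys_per_native Decoys generated per native.
#' @param chain_lengths Integer pair (partner a, partner b), each >= 8.
#' @param noise_ladder List of c(rotation degrees, translation Angstrom)
#'   rungs, cycled over the decoys of each native.
#' @param split_fractions Train/validation/test fractions over natives,
#'   summing to 1.
#' @param seed Integer seed controlling every random draw.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_natives = 20L, decoys_per_native = 20L,
                       chain_lengths = c(16L, 12L),
                       noise_ladder = list(c(0, 0), c(5, 1), c(15, 4),
                                           c(60, 15), c(180, 60)),
                       split_fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(n_natives >= 1L, decoys_per_native >= 1L,
            length(chain_lengths) == 2L, all(chain_lengths >= 8L),
            abs(sum(split_fractions) - 1) < 1e-9, length(split_fractions) == 3L)
  structure(list(n_natives = as.integer(n_natives),
                 decoys_per_native = as.integer(decoys_per_native),
                 chain_lengths = as.integer(chain_lengths),
                 noise_ladder = noise_ladder,
                 split_fractions = split_fractions, seed = as.integer(seed)),
            class = "sim_config")
}

.rot_axis <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.unit <- function(v) v / sqrt(sum(v^2))

# idealized helical CA trace with small jitter; 3.8 A consecutive spacing
.helix_ca <- function(n) {
  i <- seq_len(n)
  m <- cbind(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180), 1.5 * i)
  m + matrix(stats::rnorm(3 * n, sd = 0.08), n, 3)
}

# backbone N/C/O and CB synthesized from ideal local frames along the trace
.chain_atoms <- function(ca) {
  n <- nrow(ca)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    vprev <- if (i > 1) .unit(ca[i - 1, ] - ca[i, ]) else .unit(ca[i, ] - ca[i + 1, ])
    vnext <- if (i < n) .unit(ca[i + 1, ] - ca[i, ]) else .unit(ca[i, ] - ca[i - 1, ])
    perp <- vprev - sum(vprev * vnext) * vnext
    if (sqrt(sum(perp^2)) < 1e-6) perp <- c(-vnext[2], vnext[1], 0)
    perp <- .unit(perp)
    ortho <- .unit(c(vnext[2] * perp[3] - vnext[3] * perp[2],
                     vnext[3] * perp[1] - vnext[1] * perp[3],
                     vnext[1] * perp[2] - vnext[2] * perp[1]))
    Npos <- ca[i, ] + 1.46 * vprev
    Cpos <- ca[i, ] + 1.52 * vnext
    Opos <- Cpos + 1.23 * ortho
    Bpos <- ca[i, ] + 1.53 * .unit(-0.6 * (vprev + vnext) + ortho)
    out[[i]] <- data.frame(res_row = i,
                           atom_name = c("N", "CA", "C", "O", "CB"),
                           x = c(Npos[1], ca[i, 1], Cpos[1], Opos[1], Bpos[1]),
                           y = c(Npos[2], ca[i, 2], Cpos[2], Opos[2], Bpos[2]),
                           z = c(Npos[3], ca[i, 3], Cpos[3], Opos[3], Bpos[3]),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.residue_df <- function(chain_id, n, ca) {
  data.frame(chain_id = chain_id, seq_index = seq_len(n), insertion_code = "",
             aa_type = sample(aa_alphabet()[1:20], n, replace = TRUE),
             ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
             stringsAsFactors = FALSE)
}

.count_contacts <- function(A, B, cutoff = 5) {
  hit <- .cross_dist2(as.matrix(A[, c("x", "y", "z")]),
                      as.matrix(B[, c("x", "y", "z")])) <= cutoff^2
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  length(unique(paste(A$res_row[idx[, 1]], B$res_row[idx[, 2]])))
}

#' Generate a synthetic native two-chain complex
#'
#' Builds two idealized helical mini-proteins (3.8 Angstrom CA spacing, N/C/O
#' and CB placed by ideal local frames), random sequences, and docks the
#' second against the first so that at least 5 cross-partner residue pairs
#' have heavy atoms within 5 Angstrom while no CA pair comes closer than
#' 3.5 Angstrom.
#'
#' @param length_a,length_b Chain lengths (>= 8).
#' @param seed Integer seed; the same seed reproduces the complex exactly.
#' @param source_id Label for the complex.
#' @return A \code{\link{protein_complex}} (chains "A" and "B").
#' @export
make_native <- function(length_a = 16L, length_b = 12L, seed = 1L,
                        source_id = sprintf("native%04d", seed)) {
  stopifnot(length_a >= 8L, length_b >= 8L)
  set.seed(seed)
  ca_a <- .helix_ca(length_a)
  ca_a <- sweep(ca_a, 2L, colMeans(ca_a))
  res_a <- .residue_df("A", length_a, ca_a)
  atoms_a <- .chain_atoms(ca_a)

  ca_b0 <- .helix_ca(length_b)
  ca_b0 <- sweep(ca_b0, 2L, colMeans(ca_b0))
  for (try in 1:200) {
    R <- random_rotation()
    dir <- .unit(stats::rnorm(3))
    ca_rot <- ca_b0 %*% t(R)
    atoms_b0 <- .chain_atoms(ca_rot)
    placed <- NULL
    for (dist in seq(40, 4, by = -0.5)) {
      off <- dir * dist
      ca_b <- sweep(ca_rot, 2L, off, "+")
      dmin <- sqrt(min(.cross_dist2(ca_a, ca_b)))
      if (dmin < 3.5) break
      ab <- atoms_b0
      ab$x <- ab$x + off[1]; ab$y <- ab$y + off[2]; ab$z <- ab$z + off[3]
      if (.count_contacts(atoms_a, ab, 5) >= 5L) {
        placed <- list(ca = ca_b, atoms = ab)
        break
      }
    }
    if (!is.null(placed)) {
      res_b <- .residue_df("B", length_b, placed$ca)
      atoms <- rbind(cbind(partner = "a", atoms_a), cbind(partner = "b", placed$atoms))
      return(protein_complex(res_a, res_b, atoms, source_id = source_id))
    }
  }
  stop("native generation failed: no clash-free docked placement found")
}

#' Generate graded rigid-body decoys of a native complex
#'
#' Cycles through the noise ladder: for each decoy, partner b is rotated
#' about the centroid of its native interface residues by the rung's angle
#' (random axis) and translated by the rung's distance (random direction);
#' the full quality report against the native is attached.
#'
#' @param native A \code{\link{protein_complex}} from
#'   \code{\link{make_native}}.
#' @param config A \code{\link{sim_config}}.
#' @param seed Seed for the perturbation draws (defaults to the config
#'   seed).
#' @return List of decoy records: each a list with \code{decoy},
#'   \code{decoy_id}, \code{native_id}, \code{quality} (one-row data frame)
#'   and \code{noise_level}.
#' @export
make_decoys <- function(native, config = sim_config(), seed = config$seed) {
  set.seed(seed)
  iface_b <- .interface_rows(native)$b
  if (length(iface_b) == 0L) iface_b <- seq_len(nrow(native$partner_b))
  centroid <- colMeans(ca_coords(native, "b")[iface_b, , drop = FALSE])
  ladder <- config$noise_ladder
  out <- vector("list", config$decoys_per_native)
  for (i in seq_len(config$decoys_per_native)) {
    rung <- ladder[[(i - 1L) %% length(ladder) + 1L]]
    R <- if (rung[1] > 0) .rot_axis(stats::rnorm(3), rung[1]) else diag(3)
    t_dir <- if (rung[2] > 0) .unit(stats::rnorm(3)) * rung[2] else c(0, 0, 0)
    tr <- rigid_transform(R, as.vector(centroid - R %*% centroid) + t_dir)
    decoy <- apply_transform(native, tr, partner = "b")
    decoy$source_id <- sprintf("%s_d%02d", native$source_id, i)
    out[[i]] <- list(decoy = decoy, decoy_id = decoy$source_id,
                     native_id = native$source_id,
                     quality = quality_report(decoy, native),
                     noise_level = rung)
  }
  out
}

#' Deterministic synthetic per-residue embeddings
#'
#' Stand-in for protein-language-model embeddings: each amino-acid type maps
#' to a fixed seeded vector, plus a small deterministic positional component,
#' so the same residue type at the same chain position always yields the
#' same row.
#'
#' @param complex A \code{\link{protein_complex}}.
#' @param dim Embedding width (>= 1).
#' @param seed Integer seed for the per-type base vectors.
#' @return Data frame with columns \code{chain_id}, \code{seq_index},
#'   \code{e_0 ... e_(dim-1)}; one row per residue, node order.
#' @export
synthetic_embeddings <- function(complex, dim = 32L, seed = 1L) {
  stopifnot(dim >= 1L)
  alpha <- aa_alphabet()
  set.seed(seed)
  base <- matrix(stats::rnorm(length(alpha) * dim), length(alpha), dim)
  res <- rbind(complex$partner_a[, c("chain_id", "seq_index", "aa_type")],
               complex$partner_b[, c("chain_id", "seq_index", "aa_type")])
  pos <- c(seq_len(nrow(complex$partner_a)), seq_len(nrow(complex$partner_b)))
  jitter <- 0.05 * sin(outer(pos, seq_len(dim), function(p, k) 0.37 * p * k))
  emb <- base[match(res$aa_type, alpha), , drop = FALSE] + jitter
  out <- data.frame(chain_id = res$chain_id, seq_index = res$seq_index,
                    stringsAsFactors = FALSE)
  colnames(emb) <- paste0("e_", seq_len(dim) - 1L)
  cbind(out, as.data.frame(emb))
}

#' Group-wise train/validation/test split over natives
#'
#' Natives (not decoys) are the unit of splitting: they are shuffled by the
#' config seed and partitioned by the split fractions; every decoy follows
#' its native, so no native appears in two splits.
#'
#' @param records List of decoy records (each carrying \code{native_id}).
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{natives} (named character vector native_id ->
#'   split) and \code{record_split} (character vector along \code{records}).
#' @export
split_dataset <- function(records, config = sim_config()) {
  native_ids <- unique(vapply(records, function(r) r$native_id, character(1)))
  n <- length(native_ids)
  fr <- config$split_fractions
  n_tr <- round(fr[1] * n); n_va <- round(fr[2] * n)
  n_te <- n - n_tr - n_va
  if (n < 3L || n_tr < 1L || n_va < 1L || n_te < 1L)
    stop("sizing error: too few natives to populate train/validation/test splits")
  set.seed(config$seed)
  shuffled <- sample(native_ids)
  assign <- stats::setNames(rep(c("train", "val", "test"), c(n_tr, n_va, n_te)),
                            shuffled)
  rec <- unname(assign[vapply(records, function(r) r$native_id, character(1))])
  list(natives = assign, record_split = rec)
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

#' Simulate a full labeled decoy dataset
#'
#' Generates natives, graded decoys, quality labels and group-wise splits;
#' optionally attaches synthetic AlphaFold-Multimer confidences (ipTM/pTM
#' drawn as noisy monotone functions of DockQ) and the combined
#' confidence-plus-DockQ regression target.
#'
#' @param config A \code{\link{sim_config}}.
#' @param with_afm Attach ipTM/pTM and the continuous target?
#' @return Object of class \code{decoy_dataset}: list with \code{records}
#'   (decoy records), \code{natives} (list of \code{protein_complex}),
#'   \code{labels} (data frame: decoy_id, native_id, fnat, irmsd, lrmsd,
#'   dockq, capri_class, binary_label, split, and when requested iptm, ptm,
#'   afm_target), and \code{config}.
#' @export
simulate_dataset <- function(config = sim_config(), with_afm = FALSE) {
  natives <- lapply(seq_len(config$n_natives), function(k)
    make_native(config$chain_lengths[1], config$chain_lengths[2],
                seed = config$seed * 1000L + k,
                source_id = sprintf("native%03d", k)))
  records <- list()
  for (k in seq_along(natives))
    records <- c(records, make_decoys(natives[[k]], config,
                                      seed = config$seed * 1000L + 500L + k))
  sp <- split_dataset(records, config)
  labels <- do.call(rbind, lapply(seq_along(records), function(i)
    cbind(data.frame(decoy_id = records[[i]]$decoy_id,
                     native_id = records[[i]]$native_id,
                     stringsAsFactors = FALSE),
          records[[i]]$quality)))
  labels$split <- sp$record_split
  if (with_afm) {
    set.seed(config$seed + 77L)
    labels$iptm <- .clamp01(0.12 + 0.75 * labels$dockq + stats::rnorm(nrow(labels), sd = 0.06))
    labels$ptm <- .clamp01(0.45 + 0.40 * labels$dockq + stats::rnorm(nrow(labels), sd = 0.06))
    labels$afm_target <- afm_target(labels$iptm, labels$ptm, labels$dockq)
    for (i in seq_along(records)) records[[i]]$afm_target <- labels$afm_target[i]
  }
  for (i in seq_along(records)) records[[i]]$split <- labels$split[i]
  structure(list(records = records, natives = natives, labels = labels,
                 config = config),
            class = "decoy_dataset")
}

#' @export
print.decoy_dataset <- function(x, ...) {
  cat(sprintf("<decoy_dataset: %d natives x %d decoys, %d acceptable-or-better (%.0f%%)>\n",
              x$config$n_natives, x$config$decoys_per_native,
              sum(x$labels$binary_label), 100 * mean(x$labels$binary_label)))
  invisible(x)
}
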