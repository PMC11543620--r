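#' Graph construction configuration
#'
#' @param interface_cutoff Interface flag distance in Angstrom: a residue is
#'   flagged when any residue of the other partner has its CA within this
#'   distance. Default 16.
#' @param edge_cutoff Radius for message-passing edges in Angstrom.
#' @param max_neighbors Maximum incoming edges per node (nearest kept).
#' @param embedding_dim Width of the per-residue embedding channel.
#' @return Object of class \code{graph_config}.
#' @export
graph_config <- function(interface_cutoff = 16, edge_cutoff = 12,
                         max_neighbors = 24L, embedding_dim = 32L) {
  stopifnot(interface_cutoff > 0, edge_cutoff > 0, max_neighbors >= 1L,
            embedding_dim >= 1L)
  structure(list(interface_cutoff = interface_cutoff, edge_cutoff = edge_cutoff,
                 max_neighbors = as.integer(max_neighbors),
                 embedding_dim = as.integer(embedding_dim)),
            class = "graph_config")
}

.residue_keys <- function(res) paste(res$chain_id, res$seq_index, res$insertion_code, sep = "|")

#' Interface residues of a complex
#'
#' Residues whose CA lies within \code{cutoff} Angstrom of any CA of the
#' other partner.
#'
#' @param complex A \code{\link{protein_complex}}.
#' @param cutoff Distance cutoff in Angstrom (> 0); may be \code{Inf}.
#' @return Character vector of residue identifiers
#'   (\code{chain|seq_index|insertion}).
#' @export
interface_residues <- function(complex, cutoff = 16) {
  stopifnot(cutoff > 0)
  a <- ca_coords(complex, "a"); b <- ca_coords(complex, "b")
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  hit <- d2 <= cutoff^2
  keys <- c(.residue_keys(complex$partner_a), .residue_keys(complex$partner_b))
  flags <- c(apply(hit, 1L, any), apply(hit, 2L, any))
  keys[flags]
}

# unit CA-trace direction (previous -> next CA) per node, zero at termini;
# computed within each partner so the two molecules do not leak into each other
.geom_vectors <- function(complex) {
  per_partner <- function(res) {
    m <- as.matrix(res[, c("ca_x", "ca_y", "ca_z")])
    n <- nrow(m)
    g <- matrix(0, n, 3L)
    if (n >= 3L) {
      d <- m[3:n, , drop = FALSE] - m[1:(n - 2L), , drop = FALSE]
      nr <- sqrt(rowSums(d^2))
      nr[nr < 1e-9] <- 1
      g[2:(n - 1L), ] <- d / nr
    }
    g
  }
  rbind(per_partner(complex$partner_a), per_partner(complex$partner_b))
}

#' Build the model input graph for a protein complex
#'
#' Nodes are residues (partner a first, then partner b) carrying CA
#' coordinates, a 21-way amino-acid one-hot, the binary interface flag
#' (other-partner CA within \code{interface_cutoff}), a binary partner
#' identifier, a per-residue embedding row, and a unit CA-trace direction
#' vector (zero at chain termini). Edges connect nodes within
#' \code{edge_cutoff}, capped at the \code{max_neighbors} nearest incoming
#' senders per receiver; the candidate set is symmetric, the capped set is
#' directed.
#'
#' @param complex A \code{\link{protein_complex}}.
#' @param config A \code{\link{graph_config}}.
#' @param embeddings Optional data frame with columns \code{chain_id},
#'   \code{seq_index} and \code{e_0 ... e_(d-1)}; one row per residue. When
#'   absent, rows come from \code{\link{synthetic_embeddings}}.
#' @param seed Seed for the synthetic embedding provider (ignored when
#'   \code{embeddings} is supplied).
#' @return Object of class \code{complex_graph} with fields \code{coords},
#'   \code{onehot}, \code{interface_flag}, \code{partner_id},
#'   \code{embeddings}, \code{geom_vec}, \code{edges} (data frame
#'   \code{from}, \code{to}, \code{dx}, \code{dy}, \code{dz}, \code{dist}
#'   with r = x_to - x_from) and \code{config}.
#' @export
build_graph <- function(complex, config = graph_config(), embeddings = NULL,
                        seed = 1L) {
  stopifnot(inherits(complex, "protein_complex"), inherits(config, "graph_config"))
  coords <- ca_coords(complex, "both")
  n <- nrow(coords)
  na <- nrow(complex$partner_a)
  res <- rbind(complex$partner_a[, c("chain_id", "seq_index", "insertion_code", "aa_type")],
               complex$partner_b[, c("chain_id", "seq_index", "insertion_code", "aa_type")])
  alpha <- aa_alphabet()
  onehot <- matrix(0, n, length(alpha))
  onehot[cbind(seq_len(n), match(res$aa_type, alpha))] <- 1
  partner_id <- c(rep(0, na), rep(1, n - na))

  d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") - 2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  cross <- outer(partner_id, partner_id, "!=")
  iface <- as.numeric(apply(d2 <= config$interface_cutoff^2 & cross, 1L, any))

  if (is.null(embeddings))
    embeddings <- synthetic_embeddings(complex, dim = config$embedding_dim, seed = seed)
  ecols <- grep("^e_", names(embeddings), value = TRUE)
  if (length(ecols) != config$embedding_dim)
    stop(sprintf("embedding table has %d channels, config expects %d",
                 length(ecols), config$embedding_dim))
  key_tab <- paste(embeddings$chain_id, embeddings$seq_index, sep = "|")
  key_res <- paste(res$chain_id, res$seq_index, sep = "|")
  pos <- match(key_res, key_tab)
  if (anyNA(pos)) {
    miss <- which(is.na(pos))[1L]
    stop(sprintf("embedding table misaligned: no row for chain %s residue %s",
                 res$chain_id[miss], res$seq_index[miss]))
  }
  emb <- as.matrix(embeddings[pos, ecols, drop = FALSE])
  dimnames(emb) <- NULL

  dmat <- sqrt(d2)
  from <- integer(0); to <- integer(0)
  for (j in seq_len(n)) {
    cand <- which(dmat[, j] <= config$edge_cutoff & seq_len(n) != j)
    if (length(cand) > config$max_neighbors)
      cand <- cand[order(dmat[cand, j])[seq_len(config$max_neighbors)]]
    from <- c(from, cand); to <- c(to, rep.int(j, length(cand)))
  }
  rel <- coords[to, , drop = FALSE] - coords[from, , drop = FALSE]
  edges <- data.frame(from = from, to = to, dx = rel[, 1L], dy = rel[, 2L],
                      dz = rel[, 3L], dist = dmat[cbind(from, to)])

  structure(list(coords = coords, onehot = onehot, interface_flag = iface,
                 partner_id = partner_id, embeddings = emb,
                 geom_vec = .geom_vectors(complex), edges = edges,
                 residue_keys = .residue_keys(res), n = n, config = config,
                 source_id = complex$source_id),
            class = "complex_graph")
}

#' @export
print.complex_graph <- function(x, ...) {
  cat(sprintf("<complex_graph '%s': %d nodes (%d interface-flagged), %d directed edges>\n",
              x$source_id, x$n, sum(x$interface_flag), nrow(x$edges)))
  invisible(x)
}
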