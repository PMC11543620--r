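#' Model configuration for the equivariant attention scorer
#'
#' Defaults follow the published configuration: maximum rotation order 2,
#' 16 spherical channels, three attention layers.
#'
#' @param lmax Maximum rotation order of node features.
#' @param spherical_channels Channels per order.
#' @param num_layers Number of attention blocks.
#' @param attention_heads Attention heads (must divide
#'   \code{spherical_channels}).
#' @param head_mode "binary" (sigmoid score in (0,1), cross-entropy
#'   training) or "continuous" (unbounded output, mean-squared-error
#'   training).
#' @param seed Seed for parameter initialization.
#' @param n_rbf Gaussian radial basis functions over [0, edge_cutoff].
#' @param attn_hidden Hidden width of the attention MLP on invariant scalars.
#' @param pool "mean" over all nodes or "interface" (interface-flagged nodes
#'   only, all nodes when a graph has none).
#' @return Object of class \code{model_config}.
#' @export
model_config <- function(lmax = 2L, spherical_channels = 16L, num_layers = 3L,
                         attention_heads = 4L,
                         head_mode = c("binary", "continuous"), seed = 1L,
                         n_rbf = 16L, attn_hidden = 32L,
                         pool = c("mean", "interface")) {
  head_mode <- match.arg(head_mode)
  pool <- match.arg(pool)
  stopifnot(lmax >= 0L, lmax <= 2L, spherical_channels >= 1L, num_layers >= 1L,
            spherical_channels %% attention_heads == 0L)
  structure(list(lmax = as.integer(lmax),
                 spherical_channels = as.integer(spherical_channels),
                 num_layers = as.integer(num_layers),
                 attention_heads = as.integer(attention_heads),
                 head_mode = head_mode, seed = as.integer(seed),
                 n_rbf = as.integer(n_rbf), attn_hidden = as.integer(attn_hidden),
                 pool = pool),
            class = "model_config")
}

# tensor-product paths (l_sender, l_sh, l_out) used by the message layer:
# a connected subset of the 15 triangle-valid triples, covering every output
# order from every sender order while keeping the per-edge cost bounded
.msg_paths <- list(c(0L, 0L, 0L), c(0L, 1L, 1L), c(0L, 2L, 2L),
                   c(1L, 0L, 1L), c(1L, 1L, 0L), c(1L, 1L, 1L), c(1L, 1L, 2L),
                   c(1L, 2L, 1L), c(2L, 0L, 2L), c(2L, 1L, 1L), c(2L, 2L, 0L))

.paths_for <- function(lmax) Filter(function(p) all(p <= lmax), .msg_paths)

.xavier <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc)

#' Initialize model parameters
#'
#' @param config A \code{\link{model_config}}.
#' @param in_dim Width of the scalar node-feature block (one-hot + interface
#'   flag + partner id + embedding).
#' @return Named list of parameter matrices.
#' @export
init_params <- function(config, in_dim) {
  set.seed(config$seed)
  C <- config$spherical_channels
  p <- list(W_in = .xavier(in_dim, C), W_geom = .xavier(in_dim, C))
  for (layer in seq_len(config$num_layers)) {
    key <- function(nm) sprintf("L%d_%s", layer, nm)
    p[[key("W_a1")]] <- .xavier(2L * C + config$n_rbf, config$attn_hidden)
    p[[key("b_a1")]] <- matrix(0, 1L, config$attn_hidden)
    p[[key("W_a2")]] <- .xavier(config$attn_hidden, config$attention_heads)
    for (i in seq_along(.paths_for(config$lmax)))
      p[[key(sprintf("W_r%d", i))]] <- .xavier(config$n_rbf, C)
    for (l in 0:config$lmax) {
      p[[key(sprintf("W_self%d", l))]] <- .xavier(C, C)
      p[[key(sprintf("W_msg%d", l))]] <- .xavier(C, C)
      # unnormalized-sum aggregation channel: the attention softmax averages
      # its messages, so contact counts need a parallel additive route
      p[[key(sprintf("W_sum%d", l))]] <- .xavier(C, C)
      if (l == 0L) p[[key("b_s")]] <- matrix(0, 1L, C)
      else {
        p[[key(sprintf("W_g%d", l))]] <- .xavier(C, C)
        p[[key(sprintf("b_g%d", l))]] <- matrix(0, 1L, C)
      }
    }
  }
  # readout: small MLP over the final scalars concatenated with the raw
  # input block (skip connection), so input-level statistics reach the
  # output through a single nonlinearity
  p$W_o1 <- .xavier(C + in_dim, 16L)
  p$b_o1 <- matrix(0, 1L, 16L)
  p$w_out <- .xavier(16L, 1L)
  p$b_out <- matrix(0, 1L, 1L)
  p
}

# per-graph constant features consumed by the forward pass. Besides the node
# scalars from the graph (one-hot, interface flag, partner bit, embeddings),
# the input block carries an edge-degree embedding: the unweighted sum of
# radial basis values over incoming edges, split by same-partner and
# cross-partner senders, which hands the network neighbor-density statistics
# directly.
.graph_features <- function(graph, config) {
  E <- nrow(graph$edges)
  if (E > 0L) {
    rel <- as.matrix(graph$edges[, c("dx", "dy", "dz")])
    dist <- graph$edges$dist
    degen <- dist < 1e-9
    if (any(degen)) {
      warning(sprintf("%d degenerate edge direction(s) replaced by +z", sum(degen)))
      rel[degen, ] <- matrix(rep(c(0, 0, 1), sum(degen)), ncol = 3L, byrow = TRUE)
      dist[degen] <- 1e-9
    }
    dirs <- rel / sqrt(rowSums(rel^2))
    centers <- seq(0, graph$config$edge_cutoff, length.out = config$n_rbf)
    width <- centers[2L] - centers[1L]
    rbf <- exp(-((outer(graph$edges$dist, centers, "-")) / width)^2)
    sh <- lapply(0:config$lmax, function(l) .sh_block(dirs, l))
    cross <- graph$partner_id[graph$edges$from] != graph$partner_id[graph$edges$to]
    deg_same <- .scatter_add_cpp(rbf * (1 - cross), as.integer(graph$edges$to), graph$n) / 16
    deg_cross <- .scatter_add_cpp(rbf * cross, as.integer(graph$edges$to), graph$n) / 16
  } else {
    rbf <- matrix(0, 0L, config$n_rbf)
    sh <- lapply(0:config$lmax, function(l) matrix(0, 0L, 2L * l + 1L))
    deg_same <- deg_cross <- matrix(0, graph$n, config$n_rbf)
  }
  X <- cbind(graph$onehot, graph$interface_flag, graph$partner_id,
             graph$embeddings, deg_same, deg_cross)
  list(X = X, send = graph$edges$from, recv = graph$edges$to, rbf = rbf,
       sh = sh, gvec_l1 = graph$geom_vec[, c(2L, 3L, 1L), drop = FALSE],
       iface = graph$interface_flag, n = graph$n)
}

# concatenate per-graph features into one batch with node offsets, and
# precompute the channel-stacked ("flat") index structures used by the
# forward pass: flat row (c-1)*N + n for node n, channel c
.batch_features <- function(feats, config) {
  ns <- vapply(feats, `[[`, integer(1), "n")
  off <- cumsum(c(0L, ns[-length(ns)]))
  lmax <- length(feats[[1L]]$sh) - 1L
  C <- config$spherical_channels
  n <- sum(ns)
  send <- unlist(lapply(seq_along(feats), function(i) feats[[i]]$send + off[i]))
  recv <- unlist(lapply(seq_along(feats), function(i) feats[[i]]$recv + off[i]))
  E <- length(send)
  sh <- lapply(0:lmax, function(l) do.call(rbind, lapply(feats, function(f) f$sh[[l + 1L]])))
  erep <- rep(seq_len(max(E, 1L)), C)[seq_len(E * C)]
  list(X = do.call(rbind, lapply(feats, `[[`, "X")),
       send = send, recv = recv,
       send_flat = as.vector(outer(send, (0:(C - 1L)) * n, "+")),
       recv_flat = as.vector(outer(recv, (0:(C - 1L)) * n, "+")),
       rbf = do.call(rbind, lapply(feats, `[[`, "rbf")),
       sh = sh,
       shrep = lapply(sh, function(m) m[erep, , drop = FALSE]),
       gvec_rep = do.call(rbind, lapply(feats, `[[`, "gvec_l1"))[rep(seq_len(n), C), , drop = FALSE],
       iface = unlist(lapply(feats, `[[`, "iface")),
       graph_id = rep(seq_along(feats), ns),
       n = n, n_graphs = length(feats))
}

# train-time edge subsetting (DropEdge): each optimization step sees a
# random subgraph, which regularizes message passing on small datasets
.drop_edges <- function(feats, rate) {
  lapply(feats, function(f) {
    E <- length(f$send)
    if (E == 0L || rate <= 0) return(f)
    keep <- which(stats::runif(E) >= rate)
    f$send <- f$send[keep]; f$recv <- f$recv[keep]
    f$rbf <- f$rbf[keep, , drop = FALSE]
    f$sh <- lapply(f$sh, function(m) m[keep, , drop = FALSE])
    f
  })
}

# logits for a list of per-graph feature sets, evaluated in chunks to bound
# the working set of any single tape
.logits_for <- function(params, feats, config, chunk = 8L) {
  out <- numeric(0)
  for (ix in split(seq_along(feats), ceiling(seq_along(feats) / chunk))) {
    batch <- .batch_features(feats[ix], config)
    tape <- ad_tape()
    pnodes <- lapply(params, function(v) ad_const(tape, v))
    fw <- .forward_impl(tape, function(nm) pnodes[[nm]], batch, config)
    out <- c(out, as.vector(ad_value(fw$logits)))
  }
  out
}

# head -> channel incidence (H, C), so alpha %*% M gives per-channel weights
.head_map <- function(config) {
  C <- config$spherical_channels; H <- config$attention_heads
  M <- matrix(0, H, C)
  M[cbind(rep(seq_len(H), each = C %/% H), seq_len(C))] <- 1
  M
}

# full forward pass on a batch; pn maps a parameter name to its tape node;
# returns ad nodes for logits and per-node readout. Node states live in the
# flat channel-stacked layout (N*C, 2l+1).
.forward_impl <- function(tape, pn, batch, config) {
  C <- config$spherical_channels
  n <- batch$n
  X <- ad_const(tape, batch$X)
  rbf <- ad_const(tape, batch$rbf)
  x <- list()
  x[["0"]] <- ad_flatten(tape, ad_mm(tape, X, pn("W_in")))
  if (config$lmax >= 1L)
    x[["1"]] <- ad_outer_flat(tape, ad_mm(tape, X, pn("W_geom")), batch$gvec_rep)
  if (config$lmax >= 2L)
    x[["2"]] <- ad_const(tape, matrix(0, n * C, 5L))
  Mhc <- ad_const(tape, .head_map(config))
  paths <- .paths_for(config$lmax)
  has_edges <- length(batch$send) > 0L

  for (layer in seq_len(config$num_layers)) {
    key <- function(nm) sprintf("L%d_%s", layer, nm)
    s <- ad_as_mat(tape, x[["0"]], n, C)
    if (has_edges) {
      ssend <- ad_rows(tape, s, batch$send)
      srecv <- ad_rows(tape, s, batch$recv)
      h <- ad_silu(tape, ad_addbias(tape, ad_mm(tape, ad_cbind(tape, ssend, srecv, rbf),
                                                pn(key("W_a1"))), pn(key("b_a1"))))
      alpha <- ad_segsoftmax(tape, ad_mm(tape, h, pn(key("W_a2"))), batch$recv)
      alpha_chan <- ad_mm(tape, alpha, Mhc)
      msgs <- list()
      for (i in seq_along(paths)) {
        pth <- paths[[i]]
        w <- ad_mm(tape, rbf, pn(key(sprintf("W_r%d", i))))
        xs <- ad_rows(tape, x[[as.character(pth[1L])]], batch$send_flat)
        m <- ad_tp_flat(tape, xs, batch$shrep[[pth[2L] + 1L]], w, pth[1L], pth[2L], pth[3L])
        k3 <- as.character(pth[3L])
        msgs[[k3]] <- if (is.null(msgs[[k3]])) m else ad_add(tape, msgs[[k3]], m)
      }
    }
    for (l in 0:config$lmax) {
      kl <- as.character(l)
      u <- ad_chanmix_flat(tape, x[[kl]], pn(key(sprintf("W_self%d", l))), n)
      if (has_edges && !is.null(msgs[[kl]])) {
        agg <- ad_segsum(tape, ad_gate_flat(tape, msgs[[kl]], alpha_chan),
                         batch$recv_flat, n * C)
        u <- ad_add(tape, u, ad_chanmix_flat(tape, agg, pn(key(sprintf("W_msg%d", l))), n))
        # fixed 1/16 scale keeps the additive route near unit magnitude for
        # typical neighborhood sizes
        agg_sum <- ad_scale(tape, ad_segsum(tape, msgs[[kl]], batch$recv_flat, n * C), 1 / 16)
        u <- ad_add(tape, u, ad_chanmix_flat(tape, agg_sum, pn(key(sprintf("W_sum%d", l))), n))
      }
      if (l == 0L) {
        upd <- ad_silu(tape, ad_addbias(tape, ad_as_mat(tape, u, n, C), pn(key("b_s"))))
        x[[kl]] <- ad_add(tape, x[[kl]], ad_flatten(tape, upd))
      } else {
        gate <- ad_sigmoid(tape, ad_addbias(tape, ad_mm(tape, s, pn(key(sprintf("W_g%d", l)))),
                                            pn(key(sprintf("b_g%d", l)))))
        x[[kl]] <- ad_add(tape, x[[kl]], ad_gate_flat(tape, u, gate))
      }
    }
  }
  ro_in <- ad_cbind(tape, ad_as_mat(tape, x[["0"]], n, C), X)
  hid <- ad_silu(tape, ad_addbias(tape, ad_mm(tape, ro_in, pn("W_o1")), pn("b_o1")))
  per_node <- ad_addbias(tape, ad_mm(tape, hid, pn("w_out")), pn("b_out"))
  if (config$pool == "interface") {
    keep <- .pool_rows(batch)
    logits <- ad_segmean(tape, ad_rows(tape, per_node, keep$rows), keep$gid, batch$n_graphs)
  } else {
    logits <- ad_segmean(tape, per_node, batch$graph_id, batch$n_graphs)
  }
  list(logits = logits, per_node = per_node, states = x)
}

# rows used by interface pooling: interface nodes, or all nodes of graphs
# that have none
.pool_rows <- function(batch) {
  rows <- integer(0); gid <- integer(0)
  for (g in seq_len(batch$n_graphs)) {
    idx <- which(batch$graph_id == g)
    sel <- idx[batch$iface[idx] == 1]
    if (length(sel) == 0L) sel <- idx
    rows <- c(rows, sel); gid <- c(gid, rep.int(g, length(sel)))
  }
  list(rows = rows, gid = gid)
}

# forward + reverse pass with parameter-gradient collection; embed_dropout
# masks the embedding block of the input scalars (train-time only), which
# discourages memorizing training natives through their embedding quirks
.forward_backward <- function(params, batch, config, labels, embed_dropout = 0) {
  if (embed_dropout > 0 && ncol(batch$X) > 23L + 2L * config$n_rbf) {
    # identity channels: 21 one-hot columns and the embedding block; the
    # interface flag (22), partner bit (23) and the trailing edge-degree
    # block are never masked
    ecols <- c(1L:21L, 24L:(ncol(batch$X) - 2L * config$n_rbf))
    mask <- matrix(stats::rbinom(nrow(batch$X) * length(ecols), 1L, 1 - embed_dropout),
                   nrow(batch$X), length(ecols)) / (1 - embed_dropout)
    batch$X[, ecols] <- batch$X[, ecols] * mask
  }
  tape <- ad_tape()
  pnodes <- lapply(params, function(v) ad_const(tape, v))
  pn_ids <- vapply(pnodes, `[[`, integer(1), "id")
  fw <- .forward_impl(tape, function(nm) pnodes[[nm]], batch, config)
  loss <- if (config$head_mode == "binary") ad_bce(tape, fw$logits, labels)
          else ad_mse(tape, fw$logits, labels)
  grads_all <- ad_backward(tape, loss)
  grads <- lapply(seq_along(params), function(i) {
    g <- grads_all[[pn_ids[i]]]
    if (is.null(g)) params[[i]] * 0 else g
  })
  names(grads) <- names(params)
  list(loss = as.numeric(ad_value(loss)), grads = grads,
       logits = as.vector(ad_value(fw$logits)))
}

#' Score one or many complexes with a trained model
#'
#' Runs the full network (irreps initialization, attention blocks, per-node
#' scalar readout, pooling, output nonlinearity) deterministically.
#'
#' @param x A \code{\link{protein_complex}}, a \code{\link{complex_graph}},
#'   or a list of either.
#' @param model A trained model (from \code{\link{train_scorer}}) or a list
#'   with \code{params} and \code{config}.
#' @param graph_cfg Graph configuration used when \code{x} contains raw
#'   complexes.
#' @return For a single input, a list with \code{score},
#'   \code{per_node_scalars} and \code{logit}; for a list input, a numeric
#'   vector of scores.
#' @export
score_complex <- function(x, model, graph_cfg = NULL) {
  if (is.null(graph_cfg)) graph_cfg <- model$graph_cfg %||% graph_config()
  single <- inherits(x, "protein_complex") || inherits(x, "complex_graph")
  xs <- if (single) list(x) else x
  graphs <- lapply(xs, function(g)
    if (inherits(g, "complex_graph")) g else build_graph(g, graph_cfg))
  feats <- lapply(graphs, .graph_features, config = model$config)
  if (single) {
    batch <- .batch_features(feats, model$config)
    tape <- ad_tape()
    pnodes <- lapply(model$params, function(v) ad_const(tape, v))
    fw <- .forward_impl(tape, function(nm) pnodes[[nm]], batch, model$config)
    logit <- as.vector(ad_value(fw$logits))
    if (!is.finite(logit)) stop("numeric error: non-finite output in forward pass")
    score <- if (model$config$head_mode == "binary") 1 / (1 + exp(-logit)) else logit
    return(list(score = score, per_node_scalars = as.vector(ad_value(fw$per_node)),
                logit = logit))
  }
  logits <- .logits_for(model$params, feats, model$config)
  if (any(!is.finite(logits))) stop("numeric error: non-finite output in forward pass")
  if (model$config$head_mode == "binary") 1 / (1 + exp(-logits)) else logits
}

#' Train the equivariant scorer
#'
#' Adam optimization of the full network against binary cross-entropy
#' (binary mode, labels in {0,1}) or mean-squared error (continuous mode,
#' real-valued targets), with per-epoch validation and best-validation
#' checkpoint selection. Fully reproducible for a fixed seed.
#'
#' @param dataset A \code{\link{simulate_dataset}} result, or a list of decoy
#'   records each carrying \code{decoy}, \code{quality} and (continuous
#'   mode) \code{afm_target}.
#' @param config A \code{\link{model_config}}.
#' @param split Optional character vector of "train"/"val"/"test" along the
#'   records; defaults to the dataset's own split.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Graphs per optimization step.
#' @param weight_decay Decoupled (AdamW-style) weight decay coefficient.
#' @param embed_dropout Train-time dropout rate on the identity channels of
#'   the input scalars (amino-acid one-hot and embedding block).
#' @param edge_dropout Train-time fraction of edges dropped per optimization
#'   step (DropEdge-style regularization; 0 disables).
#' @param seed Seed for batching and initialization.
#' @param graph_cfg A \code{\link{graph_config}}.
#' @param verbose Print per-epoch progress?
#' @return Object of class \code{scorer_model}: list with \code{params}
#'   (best-validation checkpoint), \code{config}, \code{graph_cfg},
#'   \code{history} (data frame epoch, train_loss, val_loss, val_auc) and
#'   \code{in_dim}.
#' @export
train_scorer <- function(dataset, config = model_config(), split = NULL,
                         epochs = 8L, learning_rate = 1e-3, batch_size = 4L,
                         weight_decay = 0, embed_dropout = 0.6, edge_dropout = 0,
                         seed = config$seed, graph_cfg = graph_config(),
                         verbose = FALSE) {
  records <- if (inherits(dataset, "decoy_dataset")) dataset$records else dataset
  if (is.null(split))
    split <- vapply(records, function(r) r$split %||% "train", character(1))
  stopifnot(length(split) == length(records))
  labels <- vapply(records, function(r) {
    if (config$head_mode == "binary") as.numeric(r$quality$binary_label)
    else r$afm_target %||% stop("continuous mode requires afm_target on every record")
  }, numeric(1))
  tr <- which(split == "train"); va <- which(split == "val")
  stopifnot(length(tr) > 0L, length(va) > 0L)
  if (config$head_mode == "binary" && length(unique(labels[tr])) < 2L)
    stop("degenerate labels: binary training requires both classes in the training set")

  feats <- lapply(records, function(r) .graph_features(build_graph(r$decoy, graph_cfg), config))
  in_dim <- ncol(feats[[1L]]$X)
  set.seed(seed)
  params <- init_params(config, in_dim)
  mom <- lapply(params, function(v) v * 0)
  vel <- lapply(params, function(v) v * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  val_feats <- feats[va]
  best <- list(val_loss = Inf, params = params)
  history <- data.frame()

  for (epoch in seq_len(epochs)) {
    ord <- sample(tr)
    losses <- numeric(0)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      batch <- .batch_features(.drop_edges(feats[b], edge_dropout), config)
      fb <- .forward_backward(params, batch, config, labels[b], embed_dropout)
      losses <- c(losses, fb$loss)
      step <- step + 1L
      # global gradient-norm clipping stabilizes the additive message route
      gnorm <- sqrt(sum(vapply(fb$grads, function(g) sum(g^2), numeric(1))))
      if (gnorm > 5) fb$grads <- lapply(fb$grads, function(g) g * (5 / gnorm))
      for (nm in names(params)) {
        g <- fb$grads[[nm]]
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - learning_rate *
          (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
      }
    }
    ev <- .evaluate(params, val_feats, config, labels[va])
    history <- rbind(history, data.frame(epoch = epoch, train_loss = mean(losses),
                                         val_loss = ev$loss, val_auc = ev$auc))
    if (ev$loss < best$val_loss) best <- list(val_loss = ev$loss, params = params)
    if (verbose)
      message(sprintf("epoch %d: train %.4f  val %.4f  val_auc %s", epoch,
                      mean(losses), ev$loss,
                      ifelse(is.na(ev$auc), "-", sprintf("%.3f", ev$auc))))
  }
  structure(list(params = best$params, config = config, graph_cfg = graph_cfg,
                 history = history, in_dim = in_dim),
            class = "scorer_model")
}

.evaluate <- function(params, feats, config, labels) {
  z <- .logits_for(params, feats, config)
  if (config$head_mode == "binary") {
    loss <- mean(pmax(z, 0) - labels * z + log1p(exp(-abs(z))))
    auc <- if (length(unique(labels)) > 1L)
      roc_auc(labeled_scores(z, labels))$auc else NA_real_
  } else {
    loss <- mean((z - labels)^2)
    auc <- NA_real_
  }
  list(loss = loss, auc = auc, logits = z)
}

#' @export
print.scorer_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<scorer_model (%s): lmax %d, %d channels, %d layers; best val loss %.4f>\n",
              x$config$head_mode, x$config$lmax, x$config$spherical_channels,
              x$config$num_layers, min(x$history$val_loss)))
  invisible(x)
}

#' Save / load a model checkpoint (JSON text)
#'
#' @param model A \code{scorer_model}.
#' @param path Output path.
#' @return \code{save_checkpoint}: the path, invisibly;
#'   \code{load_checkpoint}: the restored model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(version = 1L,
              config = unclass(model$config),
              graph_cfg = unclass(model$graph_cfg),
              in_dim = model$in_dim,
              params = lapply(model$params, function(m) list(dim = dim(m), data = as.vector(m))),
              history = model$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) matrix(p$data, p$dim[1L], p$dim[2L]))
  cfg <- obj$config
  config <- model_config(cfg$lmax, cfg$spherical_channels, cfg$num_layers,
                         cfg$attention_heads, cfg$head_mode, cfg$seed,
                         cfg$n_rbf, cfg$attn_hidden, cfg$pool)
  g <- obj$graph_cfg
  structure(list(params = params, config = config,
                 graph_cfg = graph_config(g$interface_cutoff, g$edge_cutoff,
                                          g$max_neighbors, g$embedding_dim),
                 history = as.data.frame(obj$history), in_dim = obj$in_dim),
            class = "scorer_model")
}

#' Rigid-transform invariance of the score
#'
#' Applies random rigid transforms to a complex and reports the maximum
#' absolute score change -- the end-to-end invariance check.
#'
#' @param model A \code{scorer_model} (trained or freshly initialized).
#' @param complex A \code{\link{protein_complex}}.
#' @param n_transforms Number of random rigid transforms.
#' @param seed RNG seed.
#' @return Maximum absolute score deviation.
#' @export
score_invariance <- function(model, complex, n_transforms = 20L, seed = 1L) {
  set.seed(seed)
  base <- score_complex(complex, model)$score
  dev <- 0
  for (i in seq_len(n_transforms)) {
    tr <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 20))
    s <- score_complex(apply_transform(complex, tr, "both"), model)$score
    dev <- max(dev, abs(s - base))
  }
  dev
}

`%||%` <- function(a, b) if (is.null(a)) b else a
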