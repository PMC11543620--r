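# Minimal reverse-mode automatic differentiation on numeric matrices, sized
# for the equivariant network: a flat tape of nodes, each with a backward
# closure returning gradients for its parents. Everything is double
# precision; shapes are plain R matrices.

ad_tape <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$k <- 0L
  env
}

.ad_push <- function(tape, val, parents = integer(0), back = NULL) {
  # force the promises first: argument expressions may push their own nodes,
  # and those must receive ids before this one
  force(val); force(parents); force(back)
  tape$k <- tape$k + 1L
  node <- list(id = tape$k, val = val, parents = parents, back = back)
  tape$nodes[[tape$k]] <- node
  node
}

ad_const <- function(tape, val) .ad_push(tape, val)

ad_value <- function(node) node$val

# reverse pass: returns list of gradients indexed by node id (NULL if unused)
ad_backward <- function(tape, loss) {
  grads <- vector("list", tape$k)
  grads[[loss$id]] <- 1
  for (i in seq(tape$k, 1L)) {
    g <- grads[[i]]
    node <- tape$nodes[[i]]
    if (is.null(g) || is.null(node$back)) next
    pg <- node$back(g)
    for (j in seq_along(node$parents)) {
      p <- node$parents[j]
      if (is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

ad_mm <- function(tape, a, b) {
  .ad_push(tape, a$val %*% b$val, c(a$id, b$id), local({
    av <- a$val; bv <- b$val
    function(g) list(g %*% t(bv), crossprod(av, g))
  }))
}

ad_add <- function(tape, a, b) {
  .ad_push(tape, a$val + b$val, c(a$id, b$id),
           function(g) list(g, g))
}

# matrix + row-vector bias
ad_addbias <- function(tape, a, b) {
  .ad_push(tape, sweep(a$val, 2L, as.vector(b$val), "+"), c(a$id, b$id),
           function(g) list(g, matrix(colSums(g), nrow = 1L)))
}

ad_mul <- function(tape, a, b) {
  .ad_push(tape, a$val * b$val, c(a$id, b$id), local({
    av <- a$val; bv <- b$val
    function(g) list(g * bv, g * av)
  }))
}

ad_scale <- function(tape, a, s) {
  .ad_push(tape, a$val * s, a$id, function(g) list(g * s))
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$val))
  .ad_push(tape, v, a$id, function(g) list(g * v * (1 - v)))
}

ad_silu <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  .ad_push(tape, a$val * s, a$id, local({
    av <- a$val
    function(g) list(g * (s + av * s * (1 - s)))
  }))
}

ad_cbind <- function(tape, ...) {
  args <- list(...)
  vals <- lapply(args, `[[`, "val")
  widths <- vapply(vals, ncol, integer(1))
  .ad_push(tape, do.call(cbind, vals), vapply(args, `[[`, integer(1), "id"),
           function(g) {
             out <- vector("list", length(widths)); at <- 0L
             for (i in seq_along(widths)) {
               out[[i]] <- g[, at + seq_len(widths[i]), drop = FALSE]
               at <- at + widths[i]
             }
             out
           })
}

# gather rows; backward scatter-adds
ad_rows <- function(tape, a, idx) {
  nr <- nrow(a$val)
  idx <- as.integer(idx)
  .ad_push(tape, a$val[idx, , drop = FALSE], a$id,
           function(g) list(.scatter_add_cpp(g, idx, nr)))
}

# scatter-add rows into n groups; backward gathers
ad_segsum <- function(tape, a, seg, n) {
  seg <- as.integer(seg)
  .ad_push(tape, .scatter_add_cpp(a$val, seg, n), a$id,
           function(g) list(g[seg, , drop = FALSE]))
}

# per-segment mean of each column (n groups, all groups assumed non-empty)
ad_segmean <- function(tape, a, seg, n) {
  seg <- as.integer(seg)
  cnt <- tabulate(seg, n)
  v <- .scatter_add_cpp(a$val, seg, n) / cnt
  .ad_push(tape, v, a$id, function(g) list((g / cnt)[seg, , drop = FALSE]))
}

# column-wise softmax within row segments
ad_segsoftmax <- function(tape, a, seg) {
  seg <- as.integer(seg)
  nseg <- max(seg)
  out <- .seg_softmax_cpp(a$val, seg, nseg)
  .ad_push(tape, out, a$id,
           function(g) list(.seg_softmax_bwd_cpp(g, out, seg, nseg)))
}

# channel-mixing equivariant linear: x (N, C*d) column layout (c-1)*d + m,
# out[, (c'-1)d+m] = sum_c x[, (c-1)d+m] W[c, c']
ad_chanmix <- function(tape, x, W, d) {
  C <- ncol(W$val)
  K <- kronecker(W$val, diag(d))
  .ad_push(tape, x$val %*% K, c(x$id, W$id), local({
    xv <- x$val; Wv <- W$val
    function(g) {
      gx <- g %*% kronecker(t(Wv), diag(d))
      gW <- matrix(0, nrow(Wv), C)
      for (m in seq_len(d)) {
        cols <- seq(m, ncol(xv), by = d)
        gW <- gW + crossprod(xv[, cols, drop = FALSE], g[, cols, drop = FALSE])
      }
      list(gx, gW)
    }
  }))
}

# gate broadcast: x (N, C*d) * g (N, C) expanded over the d columns of each
# channel
ad_gate <- function(tape, x, gt, d) {
  C <- ncol(gt$val)
  expand <- rep(seq_len(C), each = d)
  ge <- gt$val[, expand, drop = FALSE]
  .ad_push(tape, x$val * ge, c(x$id, gt$id), local({
    xv <- x$val
    function(g) {
      gg <- g * xv
      gsum <- matrix(0, nrow(g), C)
      for (c in seq_len(C))
        gsum[, c] <- rowSums(gg[, (c - 1L) * d + seq_len(d), drop = FALSE])
      list(g * ge, gsum)
    }
  }))
}

# order-1 outer product: out[, (c-1)*3+m] = gate[, c] * vec[, m]; vec constant
ad_outer_vec <- function(tape, gate, vec) {
  C <- ncol(gate$val)
  v <- matrix(0, nrow(vec), C * 3L)
  for (c in seq_len(C)) v[, (c - 1L) * 3L + 1:3] <- gate$val[, c] * vec
  .ad_push(tape, v, gate$id, function(g) {
    gg <- matrix(0, nrow(g), C)
    for (c in seq_len(C))
      gg[, c] <- rowSums(g[, (c - 1L) * 3L + 1:3, drop = FALSE] * vec)
    list(gg)
  })
}

# Clebsch-Gordan tensor-product path with per-channel radial weights:
# x (E, C*d1), sh (E, d2) constant, w (E, C);
# out[, (c-1)d3+m3] = sum_{m1,m2} cg[m1,m2,m3] x[, (c-1)d1+m1] sh[, m2] w[, c]
ad_tp_path <- function(tape, x, sh, w, l1, l2, l3) {
  cg <- cg_coupling(l1, l2, l3)
  d1 <- 2L * l1 + 1L; d3 <- 2L * l3 + 1L
  C <- ncol(w$val)
  nz <- which(cg != 0, arr.ind = TRUE)
  xv <- x$val; wv <- w$val
  colix1 <- lapply(seq_len(d1), function(m) (0:(C - 1L)) * d1 + m)
  colix3 <- lapply(seq_len(d3), function(m) (0:(C - 1L)) * d3 + m)
  out <- matrix(0, nrow(xv), C * d3)
  for (r in seq_len(nrow(nz))) {
    m1 <- nz[r, 1L]; m2 <- nz[r, 2L]; m3 <- nz[r, 3L]
    out[, colix3[[m3]]] <- out[, colix3[[m3]]] +
      cg[m1, m2, m3] * xv[, colix1[[m1]], drop = FALSE] * (sh[, m2] * wv)
  }
  .ad_push(tape, out, c(x$id, w$id), function(g) {
    gx <- matrix(0, nrow(g), C * d1)
    gw <- matrix(0, nrow(g), C)
    for (r in seq_len(nrow(nz))) {
      m1 <- nz[r, 1L]; m2 <- nz[r, 2L]; m3 <- nz[r, 3L]
      gm3 <- g[, colix3[[m3]], drop = FALSE]
      gx[, colix1[[m1]]] <- gx[, colix1[[m1]]] + cg[m1, m2, m3] * gm3 * (sh[, m2] * wv)
      gw <- gw + cg[m1, m2, m3] * gm3 * xv[, colix1[[m1]], drop = FALSE] * sh[, m2]
    }
    list(gx, gw)
  })
}

# ---- flat channel-stacked layout -------------------------------------------
# Higher-order states are stored as (N*C, 2l+1) matrices, row = (c-1)*N + n,
# so every Clebsch-Gordan term is a contiguous column operation.

# zero-cost reshape between (N*C, 1) and (N, C); x column-major either way
ad_as_mat <- function(tape, x, n, C) {
  .ad_push(tape, matrix(x$val, n, C), x$id,
           function(g) list(matrix(g, n * C, 1L)))
}

ad_flatten <- function(tape, x) {
  nr <- nrow(x$val); nc <- ncol(x$val)
  .ad_push(tape, matrix(x$val, nr * nc, 1L), x$id,
           function(g) list(matrix(g, nr, nc)))
}

# multiply the columns of x (A*B, d) by the flattened gate g (A, B)
ad_gate_flat <- function(tape, x, gt) {
  gv <- as.vector(gt$val)
  .ad_push(tape, x$val * gv, c(x$id, gt$id), local({
    xv <- x$val; a <- nrow(gt$val); b <- ncol(gt$val)
    function(g) {
      gs <- rowSums(g * xv)
      list(g * gv, matrix(gs, a, b))
    }
  }))
}

# order-1 initialization in flat layout: out[, m] = gate[n, c] * vrep[row, m]
ad_outer_flat <- function(tape, gate, vrep) {
  gv <- as.vector(gate$val)
  .ad_push(tape, vrep * gv, gate$id, local({
    a <- nrow(gate$val); b <- ncol(gate$val)
    function(g) list(matrix(rowSums(g * vrep), a, b))
  }))
}

# channel-mixing equivariant linear in flat layout: for each m,
# out[, m] = vec( mat(x[, m], N, C) %*% W )
ad_chanmix_flat <- function(tape, x, W, n) {
  C <- nrow(W$val)
  d <- ncol(x$val)
  v <- matrix(0, nrow(x$val), d)
  for (m in seq_len(d)) v[, m] <- matrix(x$val[, m], n, C) %*% W$val
  .ad_push(tape, v, c(x$id, W$id), local({
    xv <- x$val; Wv <- W$val
    function(g) {
      gx <- matrix(0, nrow(g), d)
      gW <- matrix(0, C, C)
      for (m in seq_len(d)) {
        gm <- matrix(g[, m], n, C)
        gx[, m] <- gm %*% t(Wv)
        gW <- gW + crossprod(matrix(xv[, m], n, C), gm)
      }
      list(gx, gW)
    }
  }))
}

# Clebsch-Gordan path in flat layout: x (E*C, d1), shrep (E*C, d2) constant,
# w (E, C) radial weights; out (E*C, d3). Contraction runs in compiled code.
.cg_nz_cache <- new.env(parent = emptyenv())

.cg_nz <- function(l1, l2, l3) {
  key <- sprintf("%d.%d.%d", l1, l2, l3)
  hit <- .cg_nz_cache[[key]]
  if (!is.null(hit)) return(hit)
  cg <- cg_coupling(l1, l2, l3)
  nz <- which(cg != 0, arr.ind = TRUE)
  storage.mode(nz) <- "integer"
  out <- list(nz = nz, coef = cg[nz])
  .cg_nz_cache[[key]] <- out
  out
}

ad_tp_flat <- function(tape, x, shrep, w, l1, l2, l3) {
  cache <- .cg_nz(l1, l2, l3)
  nz <- cache$nz
  coef <- cache$coef
  wv <- as.vector(w$val)
  xv <- x$val
  out <- .tp_forward_cpp(xv, shrep, wv, nz, coef, 2L * l3 + 1L)
  .ad_push(tape, out, c(x$id, w$id), local({
    er <- nrow(w$val); cc <- ncol(w$val)
    function(g) {
      bk <- .tp_backward_cpp(g, xv, shrep, wv, nz, coef, 2L * l1 + 1L)
      list(bk$gx, matrix(bk$gw, er, cc))
    }
  }))
}

# mean of a column vector -> 1x1
ad_mean <- function(tape, a) {
  n <- length(a$val)
  .ad_push(tape, matrix(mean(a$val), 1L, 1L), a$id,
           function(g) list(matrix(as.numeric(g) / n, nrow(a$val), ncol(a$val))))
}

# numerically stable binary cross-entropy from logits; y constant vector
ad_bce <- function(tape, logits, y) {
  z <- as.vector(logits$val)
  loss <- mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
  .ad_push(tape, matrix(loss, 1L, 1L), logits$id, function(g) {
    p <- 1 / (1 + exp(-z))
    list(matrix(as.numeric(g) * (p - y) / length(z), nrow(logits$val), ncol(logits$val)))
  })
}

# mean squared error; y constant vector
ad_mse <- function(tape, pred, y) {
  r <- as.vector(pred$val) - y
  .ad_push(tape, matrix(mean(r^2), 1L, 1L), pred$id, function(g)
    list(matrix(as.numeric(g) * 2 * r / length(r), nrow(pred$val), ncol(pred$val))))
}
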