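## Minimal define-by-run reverse-mode engine for the 3D segmentation network.
##
## Feature maps are N x C matrices (N voxels in column-major (d, h, w)
## flatten order, C channels). Convolutions are im2col gathers followed by
## one BLAS matmul; pooling/upsampling use precomputed index tables cached
## per spatial geometry. Each forward op pushes a backward closure onto a
## tape; backward() replays the tape in reverse, accumulating gradients for
## intermediate values (by node id) and parameters (by name).

new_tape <- function(params, geom) {
  t <- new.env(parent = emptyenv())
  t$ops <- list()
  t$grads <- new.env(parent = emptyenv())   # node id -> matrix
  t$pgrads <- new.env(parent = emptyenv())  # param name -> matrix
  t$params <- params
  t$geom <- geom
  t$next_id <- 1L
  t
}

ag_value <- function(tape, mat) {
  id <- tape$next_id
  tape$next_id <- id + 1L
  list(id = id, mat = mat)
}

ag_push <- function(tape, mat, bwd) {
  v <- ag_value(tape, mat)
  tape$ops[[length(tape$ops) + 1L]] <- list(id = v$id, bwd = bwd)
  v
}

ag_grad_of <- function(tape, id) {
  g <- tape$grads[[as.character(id)]]
  g
}

ag_add_grad <- function(tape, id, g) {
  key <- as.character(id)
  cur <- tape$grads[[key]]
  tape$grads[[key]] <- if (is.null(cur)) g else cur + g
}

ag_add_pgrad <- function(tape, name, g) {
  cur <- tape$pgrads[[name]]
  tape$pgrads[[name]] <- if (is.null(cur)) g else cur + g
}

## seed: named list id -> gradient matrix (typically the loss dZ per head)
ag_backward <- function(tape, seeds) {
  for (nm in names(seeds)) ag_add_grad(tape, as.integer(nm), seeds[[nm]])
  for (i in rev(seq_along(tape$ops))) {
    op <- tape$ops[[i]]
    g <- ag_grad_of(tape, op$id)
    if (!is.null(g)) op$bwd(g)
  }
  invisible(tape)
}

## ---- geometry caches -------------------------------------------------------

geom_key <- function(dims, tag) paste0(tag, "_", paste(dims, collapse = "x"))

## neighbour linear indices for a cubic kernel; out-of-bounds -> N + 1 (zero pad)
conv_indices <- function(geom, dims, k) {
  key <- geom_key(dims, paste0("conv", k))
  got <- geom[[key]]
  if (!is.null(got)) return(got)
  D <- dims[1]; H <- dims[2]; W <- dims[3]
  N <- D * H * W
  r <- (k - 1L) %/% 2L
  dmat <- rep(seq_len(D), times = H * W)
  hmat <- rep(rep(seq_len(H), each = D), times = W)
  wmat <- rep(seq_len(W), each = D * H)
  offs <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  idx <- matrix(N + 1L, N, nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nd <- dmat + offs$dz[o]; nh <- hmat + offs$dy[o]; nw <- wmat + offs$dx[o]
    ok <- nd >= 1L & nd <= D & nh >= 1L & nh <= H & nw >= 1L & nw <= W
    lin <- nd + (nh - 1L) * D + (nw - 1L) * D * H
    lin[!ok] <- N + 1L
    idx[, o] <- lin
  }
  geom[[key]] <- idx
  idx
}

## 2x2x2 pooling children: N/8 x 8 index matrix into the fine grid
pool_indices <- function(geom, dims) {
  key <- geom_key(dims, "pool")
  got <- geom[[key]]
  if (!is.null(got)) return(got)
  if (any(dims %% 2L != 0L)) stop_validation("pooling requires even spatial dims")
  do2 <- dims %/% 2L
  Dc <- do2[1]; Hc <- do2[2]; Wc <- do2[3]
  D <- dims[1]; H <- dims[2]
  dmat <- rep(seq_len(Dc), times = Hc * Wc)
  hmat <- rep(rep(seq_len(Hc), each = Dc), times = Wc)
  wmat <- rep(seq_len(Wc), each = Dc * Hc)
  offs <- expand.grid(dz = 0:1, dy = 0:1, dx = 0:1)
  idx <- matrix(0L, Dc * Hc * Wc, 8L)
  for (o in 1:8) {
    nd <- 2L * dmat - 1L + offs$dz[o]
    nh <- 2L * hmat - 1L + offs$dy[o]
    nw <- 2L * wmat - 1L + offs$dx[o]
    idx[, o] <- nd + (nh - 1L) * D + (nw - 1L) * D * H
  }
  geom[[key]] <- idx
  idx
}

## nearest-neighbour x2 upsampling: parent index for every fine voxel
upsample_indices <- function(geom, dims_coarse) {
  key <- geom_key(dims_coarse, "up")
  got <- geom[[key]]
  if (!is.null(got)) return(got)
  df <- dims_coarse * 2L
  D <- df[1]; H <- df[2]; W <- df[3]
  Dc <- dims_coarse[1]; Hc <- dims_coarse[2]
  dmat <- rep(seq_len(D), times = H * W)
  hmat <- rep(rep(seq_len(H), each = D), times = W)
  wmat <- rep(seq_len(W), each = D * H)
  pd <- (dmat + 1L) %/% 2L; ph <- (hmat + 1L) %/% 2L; pw <- (wmat + 1L) %/% 2L
  parent <- pd + (ph - 1L) * Dc + (pw - 1L) * Dc * Hc
  geom[[key]] <- parent
  parent
}

## ---- ops -------------------------------------------------------------------

ag_conv3d <- function(tape, x, wname, bname, dims, k) {
  W <- tape$params[[wname]]; b <- tape$params[[bname]]
  idx <- conv_indices(tape$geom, dims, k)
  N <- nrow(x$mat); Cin <- ncol(x$mat); K <- ncol(idx)
  Xaug <- rbind(x$mat, 0)
  cols <- matrix(0, N, K * Cin)
  for (o in seq_len(K))
    cols[, ((o - 1L) * Cin + 1L):(o * Cin)] <- Xaug[idx[, o], , drop = FALSE]
  out <- cols %*% W
  out <- sweep(out, 2, b, `+`)
  xid <- x$id
  ag_push(tape, out, function(dout) {
    ag_add_pgrad(tape, wname, crossprod(cols, dout))
    ag_add_pgrad(tape, bname, colSums(dout))
    dcols <- dout %*% t(W)
    dx <- matrix(0, N, Cin)
    for (o in seq_len(K)) {
      io <- idx[, o]
      valid <- io <= N
      blk <- dcols[valid, ((o - 1L) * Cin + 1L):(o * Cin), drop = FALSE]
      tgt <- io[valid]
      dx[tgt, ] <- dx[tgt, , drop = FALSE] + blk
    }
    ag_add_grad(tape, xid, dx)
  })
}

ag_bn <- function(tape, x, gname, bname, eps = 1e-5) {
  g <- as.numeric(tape$params[[gname]]); b <- as.numeric(tape$params[[bname]])
  n <- nrow(x$mat)
  mu <- colMeans(x$mat)
  xc <- sweep(x$mat, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  out <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
  xid <- x$id
  ag_push(tape, out, function(dout) {
    ag_add_pgrad(tape, gname, colSums(dout * xhat))
    ag_add_pgrad(tape, bname, colSums(dout))
    dxhat <- sweep(dout, 2, g, `*`)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- sweep(dxhat, 2, s1 / n) - sweep(xhat, 2, s2 / n, `*`)
    dx <- sweep(dx, 2, istd, `*`)
    ag_add_grad(tape, xid, dx)
  })
}

ag_relu <- function(tape, x) {
  mask <- x$mat > 0
  xid <- x$id
  ag_push(tape, x$mat * mask, function(dout) ag_add_grad(tape, xid, dout * mask))
}

ag_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$mat))
  xid <- x$id
  ag_push(tape, s, function(dout) ag_add_grad(tape, xid, dout * s * (1 - s)))
}

ag_add <- function(tape, a, b) {
  aid <- a$id; bid <- b$id
  ag_push(tape, a$mat + b$mat, function(dout) {
    ag_add_grad(tape, aid, dout)
    ag_add_grad(tape, bid, dout)
  })
}

ag_concat <- function(tape, a, b) {
  ca <- ncol(a$mat)
  aid <- a$id; bid <- b$id
  ag_push(tape, cbind(a$mat, b$mat), function(dout) {
    ag_add_grad(tape, aid, dout[, seq_len(ca), drop = FALSE])
    ag_add_grad(tape, bid, dout[, -seq_len(ca), drop = FALSE])
  })
}

ag_maxpool <- function(tape, x, dims) {
  idx <- pool_indices(tape$geom, dims)
  C <- ncol(x$mat)
  cur <- x$mat[idx[, 1], , drop = FALSE]
  arg <- matrix(1L, nrow(idx), C)
  for (o in 2:8) {
    cand <- x$mat[idx[, o], , drop = FALSE]
    better <- cand > cur
    cur[better] <- cand[better]
    arg[better] <- o
  }
  xid <- x$id
  nin <- nrow(x$mat)
  ag_push(tape, cur, function(dout) {
    dx <- matrix(0, nin, C)
    for (o in 1:8) {
      contrib <- dout * (arg == o)
      dx[idx[, o], ] <- dx[idx[, o], , drop = FALSE] + contrib
    }
    ag_add_grad(tape, xid, dx)
  })
}

ag_upsample <- function(tape, x, dims_coarse) {
  parent <- upsample_indices(tape$geom, dims_coarse)
  xid <- x$id
  ag_push(tape, x$mat[parent, , drop = FALSE], function(dout) {
    ag_add_grad(tape, xid, rowsum(dout, parent, reorder = TRUE))
  })
}

## global average pool to a 1 x C row
ag_gap <- function(tape, x) {
  n <- nrow(x$mat)
  xid <- x$id
  ag_push(tape, matrix(colMeans(x$mat), 1), function(dout) {
    ag_add_grad(tape, xid, matrix(rep(dout / n, each = n), n))
  })
}

ag_dense <- function(tape, x, wname, bname) {
  W <- tape$params[[wname]]; b <- tape$params[[bname]]
  out <- sweep(x$mat %*% W, 2, b, `+`)
  xid <- x$id
  xm <- x$mat
  ag_push(tape, out, function(dout) {
    ag_add_pgrad(tape, wname, crossprod(xm, dout))
    ag_add_pgrad(tape, bname, colSums(dout))
    ag_add_grad(tape, xid, dout %*% t(W))
  })
}

## multiply an N x C map by a 1 x C channel gate
ag_scale_channels <- function(tape, x, s) {
  xid <- x$id; sid <- s$id
  xm <- x$mat; sv <- as.numeric(s$mat)
  ag_push(tape, sweep(xm, 2, sv, `*`), function(dout) {
    ag_add_grad(tape, xid, sweep(dout, 2, sv, `*`))
    ag_add_grad(tape, sid, matrix(colSums(dout * xm), 1))
  })
}

## multiply an N x C map by an N x 1 spatial gate
ag_scale_spatial <- function(tape, x, s) {
  xid <- x$id; sid <- s$id
  xm <- x$mat; sv <- as.numeric(s$mat)
  ag_push(tape, xm * sv, function(dout) {
    ag_add_grad(tape, xid, dout * sv)
    ag_add_grad(tape, sid, matrix(rowSums(dout * xm), ncol = 1))
  })
}
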