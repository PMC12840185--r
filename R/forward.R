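# Full forward and backward passes. Layout reminders:
#   x        : C x T x B array of standardized epochs
#   XC       : C x (B*T) matrix, batch-major column blocks
#   features : (B*Tp) x D matrices, batch-major row blocks
#   node     : C x g x (B*Tp) arrays for the graph path

fe_forward <- function(model, x, training) {
  cfg <- model$config; p <- model$params
  C <- cfg$C; T_len <- cfg$T_in; B <- dim(x)[3]
  XC <- matrix(x, C, T_len * B)
  nb <- length(cfg$branch_specs)
  convs <- vector("list", nb)
  Ys <- vector("list", nb)
  shifts <- vector("list", nb)
  for (i in seq_len(nb)) {
    bs <- cfg$branch_specs[[i]]
    shifts[[i]] <- conv_shifts(XC, bs[1], bs[2], B, T_len)
    convs[[i]] <- conv_full_fwd(XC, p[[sprintf("fe.b%d.W", i)]],
                                p[[sprintf("fe.b%d.b", i)]],
                                bs[1], bs[2], B, T_len,
                                shifted = shifts[[i]])
    Ys[[i]] <- convs[[i]]$Y
  }
  Ycat <- pool2_fwd(do.call(rbind, Ys), B, T_len)   # stride-2 after concat
  P0 <- model$params[["fe.proj.W"]] %*% Ycat + p[["fe.proj.b"]]
  bn <- bn_fwd(P0, p[["fe.bn.g"]], p[["fe.bn.b"]],
               model$buffers[["bn.rmean"]], model$buffers[["bn.rvar"]], training)
  Gp <- gelu_fwd_c(bn$Y)
  dr <- drop_fwd(Gp$Y, cfg$dropout, training)
  Fmat <- t(dr$Y)

  node <- NULL; dwc <- NULL; dwp <- NULL; dwt <- NULL
  if ("spatial" %in% cfg$paths) {
    m <- cfg$dw_multiplier
    g0 <- nb * m
    M <- B * cfg$T_prime
    node <- array(0, c(C, g0, M))
    dwc <- vector("list", nb)
    dwp <- vector("list", nb)
    dwt <- vector("list", nb)
    for (i in seq_len(nb)) {
      bs <- cfg$branch_specs[[i]]
      dwc[[i]] <- conv_dw_fwd(XC, p[[sprintf("fe.dw%d.w", i)]],
                              p[[sprintf("fe.dw%d.b", i)]],
                              bs[1], bs[2], B, T_len,
                              shifted = shifts[[i]])
      dwp[[i]] <- array(0, c(C, M, m))
      dwt[[i]] <- array(0, c(C, M, m))
      for (q in seq_len(m)) {
        pooled <- pool2_fwd(dwc[[i]]$Y[, , q], B, T_len)
        dwp[[i]][, , q] <- pooled
        act <- gelu_fwd_c(pooled)
        dwt[[i]][, , q] <- act$t
        node[, (i - 1L) * m + q, ] <- act$Y
      }
    }
  }
  list(Fmat = Fmat, node = node, B = B,
       cache = list(XC = XC, convs = convs, Ycat = Ycat, P0 = P0, bn = bn,
                    bnY = bn$Y, bnT = Gp$t, drop = dr, dwc = dwc, dwp = dwp,
                    dwt = dwt),
       bn_state = list(rmean = bn$rmean, rvar = bn$rvar))
}

fe_backward <- function(model, cache, dFmat, dnode, B) {
  cfg <- model$config; p <- model$params
  C <- cfg$C; T_len <- cfg$T_in
  nb <- length(cfg$branch_specs)
  g <- list()
  dP <- drop_bwd(t(dFmat), cache$drop)
  dP <- gelu_bwd_c(dP, cache$bnY, cache$bnT)
  bnb <- bn_bwd(dP, cache$bn, p[["fe.bn.g"]])
  g[["fe.bn.g"]] <- bnb$dg; g[["fe.bn.b"]] <- bnb$db
  dP0 <- bnb$dX
  g[["fe.proj.W"]] <- tcrossprod(dP0, cache$Ycat)
  g[["fe.proj.b"]] <- rowSums(dP0)
  dYcat <- pool2_bwd(crossprod(p[["fe.proj.W"]], dP0))
  row0 <- 0L
  for (i in seq_len(nb)) {
    bs <- cfg$branch_specs[[i]]
    ch <- bs[3]
    dYi <- dYcat[row0 + seq_len(ch), , drop = FALSE]
    row0 <- row0 + ch
    cb <- conv_full_bwd(dYi, cache$convs[[i]], p[[sprintf("fe.b%d.W", i)]],
                        bs[1], bs[2], B, T_len)
    g[[sprintf("fe.b%d.W", i)]] <- cb$dW
    g[[sprintf("fe.b%d.b", i)]] <- cb$db
  }
  if (!is.null(dnode)) {
    m <- cfg$dw_multiplier
    for (i in seq_len(nb)) {
      bs <- cfg$branch_specs[[i]]
      dY <- array(0, c(C, B * T_len, m))
      for (q in seq_len(m)) {
        dg <- gelu_bwd_c(dnode[, (i - 1L) * m + q, , drop = FALSE][, 1, ],
                         cache$dwp[[i]][, , q], cache$dwt[[i]][, , q])
        dY[, , q] <- pool2_bwd(dg)
      }
      db <- conv_dw_bwd(dY, cache$dwc[[i]], p[[sprintf("fe.dw%d.w", i)]],
                        bs[1], bs[2], B, T_len)
      g[[sprintf("fe.dw%d.w", i)]] <- db$dw
      g[[sprintf("fe.dw%d.b", i)]] <- db$dbias
    }
  }
  g
}

tp_forward <- function(model, Fmat, B, training) {
  cfg <- model$config; p <- model$params
  Tp <- cfg$T_prime
  pe_big <- model$buffers$pe[rep(seq_len(Tp), B), , drop = FALSE]
  proj <- lin_fwd(Fmat, p[["tp.in.W"]], p[["tp.in.b"]])
  X <- proj + pe_big
  layers <- vector("list", cfg$L_t)
  for (l in seq_len(cfg$L_t)) {
    pr <- sprintf("tp.l%d", l)
    lc <- list(Xin = X)
    lc$ln1 <- ln_fwd(X, p[[paste0(pr, ".ln1.g")]], p[[paste0(pr, ".ln1.b")]])
    lc$att <- mhsa_fwd(lc$ln1$Y, p, pr, B, Tp, cfg$h)
    lc$dr1 <- drop_fwd(lc$att$Y, cfg$dropout, training)
    X1 <- X + lc$dr1$Y
    lc$X1 <- X1
    lc$lnc <- ln_fwd(X1, p[[paste0(pr, ".lnc.g")]], p[[paste0(pr, ".lnc.b")]])
    lc$dw <- feat_dw_fwd(lc$lnc$Y, p[[paste0(pr, ".dw.w")]],
                         p[[paste0(pr, ".dw.b")]], cfg$dw_kernel, B, Tp)
    lc$dwg <- gelu_fwd_c(lc$dw$Y)
    lc$dr2 <- drop_fwd(lc$dwg$Y, cfg$dropout, training)
    X2 <- X1 + lc$dr2$Y
    lc$X2 <- X2
    lc$ln2 <- ln_fwd(X2, p[[paste0(pr, ".ln2.g")]], p[[paste0(pr, ".ln2.b")]])
    lc$f1 <- lin_fwd(lc$ln2$Y, p[[paste0(pr, ".ff1.W")]], p[[paste0(pr, ".ff1.b")]])
    lc$f1g <- gelu_fwd_c(lc$f1)
    lc$f2 <- lin_fwd(lc$f1g$Y, p[[paste0(pr, ".ff2.W")]], p[[paste0(pr, ".ff2.b")]])
    lc$dr3 <- drop_fwd(lc$f2, cfg$dropout, training)
    X <- X2 + lc$dr3$Y
    layers[[l]] <- lc
  }
  lnf <- ln_fwd(X, p[["tp.lnf.g"]], p[["tp.lnf.b"]])
  list(Ht = lnf$Y, cache = list(Fmat = Fmat, layers = layers, lnf = lnf))
}

tp_backward <- function(model, cache, dHt, B) {
  cfg <- model$config; p <- model$params
  Tp <- cfg$T_prime
  g <- list()
  lb <- ln_bwd(dHt, cache$lnf, p[["tp.lnf.g"]])
  g[["tp.lnf.g"]] <- lb$dg; g[["tp.lnf.b"]] <- lb$db
  dX <- lb$dX
  for (l in rev(seq_len(cfg$L_t))) {
    pr <- sprintf("tp.l%d", l)
    lc <- cache$layers[[l]]
    # FFN sublayer
    df2 <- drop_bwd(dX, lc$dr3)
    l2 <- lin_bwd(df2, lc$f1g$Y, p[[paste0(pr, ".ff2.W")]])
    g[[paste0(pr, ".ff2.W")]] <- l2$dW; g[[paste0(pr, ".ff2.b")]] <- l2$db
    df1 <- gelu_bwd_c(l2$dX, lc$f1, lc$f1g$t)
    l1 <- lin_bwd(df1, lc$ln2$Y, p[[paste0(pr, ".ff1.W")]])
    g[[paste0(pr, ".ff1.W")]] <- l1$dW; g[[paste0(pr, ".ff1.b")]] <- l1$db
    lnb <- ln_bwd(l1$dX, lc$ln2, p[[paste0(pr, ".ln2.g")]])
    g[[paste0(pr, ".ln2.g")]] <- lnb$dg; g[[paste0(pr, ".ln2.b")]] <- lnb$db
    dX2 <- dX + lnb$dX
    # depthwise conv sublayer
    ddw <- drop_bwd(dX2, lc$dr2)
    ddw <- gelu_bwd_c(ddw, lc$dw$Y, lc$dwg$t)
    fb <- feat_dw_bwd(ddw, lc$dw, p[[paste0(pr, ".dw.w")]], cfg$dw_kernel, B, Tp)
    g[[paste0(pr, ".dw.w")]] <- fb$dw; g[[paste0(pr, ".dw.b")]] <- fb$dbias
    lnb <- ln_bwd(fb$dX, lc$lnc, p[[paste0(pr, ".lnc.g")]])
    g[[paste0(pr, ".lnc.g")]] <- lnb$dg; g[[paste0(pr, ".lnc.b")]] <- lnb$db
    dX1 <- dX2 + lnb$dX
    # attention sublayer
    datt <- drop_bwd(dX1, lc$dr1)
    ab <- mhsa_bwd(datt, lc$att, p, pr, B, Tp, cfg$h)
    g <- c(g, ab$grads)
    lnb <- ln_bwd(ab$dX, lc$ln1, p[[paste0(pr, ".ln1.g")]])
    g[[paste0(pr, ".ln1.g")]] <- lnb$dg; g[[paste0(pr, ".ln1.b")]] <- lnb$db
    dX <- dX1 + lnb$dX
  }
  li <- lin_bwd(dX, cache$Fmat, p[["tp.in.W"]])
  g[["tp.in.W"]] <- li$dW; g[["tp.in.b"]] <- li$db
  list(grads = g, dFmat = li$dX)
}

gcn_layer_fwd <- function(X, A, W, b) {
  dims <- dim(X); C <- dims[1]; gi <- dims[2]; M <- dims[3]
  AX <- array(A %*% matrix(X, C, gi * M), c(C, gi, M))
  Xf <- matrix(aperm(AX, c(2, 1, 3)), gi, C * M)
  Z <- sweep(crossprod(Xf, W), 2L, b, "+")   # (C*M) x g_out
  go <- ncol(W)
  Zarr <- aperm(array(t(Z), c(go, C, M)), c(2, 1, 3))
  act <- gelu_fwd_c(Zarr)
  list(H = act$Y, t = act$t, Zarr = Zarr, Xf = Xf, X = X)
}

gcn_layer_bwd <- function(dH, cache, A, W) {
  dims <- dim(dH); C <- dims[1]; go <- dims[2]; M <- dims[3]
  gi <- nrow(W)
  dZarr <- gelu_bwd_c(dH, cache$Zarr, cache$t)
  dZ <- t(matrix(aperm(dZarr, c(2, 1, 3)), go, C * M))
  dW <- cache$Xf %*% dZ
  db <- colSums(dZ)
  dXf <- t(tcrossprod(dZ, W))               # gi x (C*M)
  dAX <- aperm(array(dXf, c(gi, C, M)), c(2, 1, 3))
  dX <- array(A %*% matrix(dAX, C, gi * M), c(C, gi, M))  # A symmetric
  list(dW = dW, db = db, dX = dX)
}

sp_forward <- function(model, node, B, training) {
  cfg <- model$config; p <- model$params
  A <- model$buffers$A
  X <- node
  layers <- vector("list", cfg$L_g)
  for (l in seq_len(cfg$L_g)) {
    layers[[l]] <- gcn_layer_fwd(X, A, p[[sprintf("sp.gcn%d.W", l)]],
                                 p[[sprintf("sp.gcn%d.b", l)]])
    X <- layers[[l]]$H
  }
  C <- dim(X)[1]; gL <- dim(X)[2]; M <- dim(X)[3]
  Hbar <- t(matrix(colMeans(matrix(X, C, gL * M)), gL, M))  # M x gL
  Hs <- lin_fwd(Hbar, p[["sp.proj.W"]], p[["sp.proj.b"]])
  list(Hs = Hs, cache = list(layers = layers, Hbar = Hbar, C = C))
}

sp_backward <- function(model, cache, dHs) {
  cfg <- model$config; p <- model$params
  g <- list()
  lp <- lin_bwd(dHs, cache$Hbar, p[["sp.proj.W"]])
  g[["sp.proj.W"]] <- lp$dW; g[["sp.proj.b"]] <- lp$db
  C <- cache$C
  gL <- ncol(cache$Hbar); M <- nrow(cache$Hbar)
  dHbar <- t(lp$dX) / C                                    # gL x M
  dX <- array(rep(as.vector(dHbar), each = C), c(C, gL, M))
  for (l in rev(seq_len(cfg$L_g))) {
    lb <- gcn_layer_bwd(dX, cache$layers[[l]], model$buffers$A,
                        p[[sprintf("sp.gcn%d.W", l)]])
    g[[sprintf("sp.gcn%d.W", l)]] <- lb$dW
    g[[sprintf("sp.gcn%d.b", l)]] <- lb$db
    dX <- lb$dX
  }
  list(grads = g, dnode = dX)
}

fuse_forward <- function(model, Ht, Hs, training) {
  cfg <- model$config; p <- model$params
  cache <- list()
  Htp <- NULL; Hsp <- NULL
  if (!is.null(Ht)) Htp <- lin_fwd(Ht, p[["fuse.pt.W"]], p[["fuse.pt.b"]])
  if (!is.null(Hs)) Hsp <- lin_fwd(Hs, p[["fuse.ps.W"]], p[["fuse.ps.b"]])
  cache$Ht <- Ht; cache$Hs <- Hs; cache$Htp <- Htp; cache$Hsp <- Hsp
  G <- NULL
  if (is.null(Hsp)) {
    Hf <- Htp
  } else if (is.null(Htp)) {
    Hf <- Hsp
  } else if (cfg$fusion == "gate") {
    Z <- cbind(Htp, Hsp)
    A1 <- lin_fwd(Z, p[["fuse.g1.W"]], p[["fuse.g1.b"]])
    G1 <- gelu_fwd(A1)
    A2 <- lin_fwd(G1, p[["fuse.g2.W"]], p[["fuse.g2.b"]])
    G <- sigmoid(A2)
    Hf <- G * Htp + (1 - G) * Hsp
    cache$Z <- Z; cache$A1 <- A1; cache$G1 <- G1; cache$G <- G
  } else if (cfg$fusion == "concat") {
    Z <- cbind(Htp, Hsp)
    Hf <- lin_fwd(Z, p[["fuse.cat.W"]], p[["fuse.cat.b"]])
    cache$Z <- Z
  } else {  # average
    Hf <- (Htp + Hsp) / 2
  }
  list(Hf = Hf, G = G, cache = cache)
}

fuse_backward <- function(model, cache, dHf) {
  cfg <- model$config; p <- model$params
  g <- list()
  Df <- cfg$D_f
  dHtp <- NULL; dHsp <- NULL
  if (is.null(cache$Hsp)) {
    dHtp <- dHf
  } else if (is.null(cache$Htp)) {
    dHsp <- dHf
  } else if (cfg$fusion == "gate") {
    G <- cache$G
    dHtp <- dHf * G
    dHsp <- dHf * (1 - G)
    dG <- dHf * (cache$Htp - cache$Hsp)
    dA2 <- dG * G * (1 - G)
    l2 <- lin_bwd(dA2, cache$G1, p[["fuse.g2.W"]])
    g[["fuse.g2.W"]] <- l2$dW; g[["fuse.g2.b"]] <- l2$db
    dA1 <- gelu_bwd(l2$dX, cache$A1)
    l1 <- lin_bwd(dA1, cache$Z, p[["fuse.g1.W"]])
    g[["fuse.g1.W"]] <- l1$dW; g[["fuse.g1.b"]] <- l1$db
    dHtp <- dHtp + l1$dX[, seq_len(Df), drop = FALSE]
    dHsp <- dHsp + l1$dX[, Df + seq_len(Df), drop = FALSE]
  } else if (cfg$fusion == "concat") {
    lc <- lin_bwd(dHf, cache$Z, p[["fuse.cat.W"]])
    g[["fuse.cat.W"]] <- lc$dW; g[["fuse.cat.b"]] <- lc$db
    dHtp <- lc$dX[, seq_len(Df), drop = FALSE]
    dHsp <- lc$dX[, Df + seq_len(Df), drop = FALSE]
  } else {
    dHtp <- dHf / 2
    dHsp <- dHf / 2
  }
  dHt <- NULL; dHs <- NULL
  if (!is.null(dHtp) && !is.null(cache$Htp)) {
    lt <- lin_bwd(dHtp, cache$Ht, p[["fuse.pt.W"]])
    g[["fuse.pt.W"]] <- lt$dW; g[["fuse.pt.b"]] <- lt$db
    dHt <- lt$dX
  }
  if (!is.null(dHsp) && !is.null(cache$Hsp)) {
    ls <- lin_bwd(dHsp, cache$Hs, p[["fuse.ps.W"]])
    g[["fuse.ps.W"]] <- ls$dW; g[["fuse.ps.b"]] <- ls$db
    dHs <- ls$dX
  }
  list(grads = g, dHt = dHt, dHs = dHs)
}

tar_forward <- function(model, Hf, task, training) {
  cfg <- model$config; p <- model$params
  if (!cfg$use_tar) return(list(Hout = Hf, cache = list(identity = TRUE)))
  if (task < 0L || task >= cfg$n_tasks)
    stop("unknown task id ", task, "; valid ids are 0..", cfg$n_tasks - 1L)
  e <- p[["tar.emb"]][task + 1L, ]
  gam <- as.vector(e %*% p[["tar.Wg"]]) + p[["tar.bg"]]
  bet <- as.vector(e %*% p[["tar.Wb"]]) + p[["tar.bb"]]
  Hmod <- sweep(sweep(Hf, 2L, gam, "*"), 2L, bet, "+")
  Dn <- lin_fwd(Hmod, p[["tar.down.W"]], p[["tar.down.b"]])
  Dg <- gelu_fwd(Dn)
  Up <- lin_fwd(Dg, p[["tar.up.W"]], p[["tar.up.b"]])
  Hout <- Hmod + Up
  list(Hout = Hout,
       cache = list(identity = FALSE, Hf = Hf, e = e, task = task, gam = gam,
                    Hmod = Hmod, Dn = Dn, Dg = Dg))
}

tar_backward <- function(model, cache, dHout) {
  p <- model$params
  if (isTRUE(cache$identity)) return(list(grads = list(), dHf = dHout))
  g <- list()
  lu <- lin_bwd(dHout, cache$Dg, p[["tar.up.W"]])
  g[["tar.up.W"]] <- lu$dW; g[["tar.up.b"]] <- lu$db
  dDn <- gelu_bwd(lu$dX, cache$Dn)
  ld <- lin_bwd(dDn, cache$Hmod, p[["tar.down.W"]])
  g[["tar.down.W"]] <- ld$dW; g[["tar.down.b"]] <- ld$db
  dHmod <- dHout + ld$dX
  dgam <- colSums(dHmod * cache$Hf)
  dbet <- colSums(dHmod)
  g[["tar.Wg"]] <- outer(cache$e, dgam)
  g[["tar.bg"]] <- dgam
  g[["tar.Wb"]] <- outer(cache$e, dbet)
  g[["tar.bb"]] <- dbet
  demb <- matrix(0, model$config$n_tasks, model$config$D_e)
  demb[cache$task + 1L, ] <- as.vector(p[["tar.Wg"]] %*% dgam) +
    as.vector(p[["tar.Wb"]] %*% dbet)
  g[["tar.emb"]] <- demb
  dHf <- sweep(dHmod, 2L, cache$gam, "*")
  list(grads = g, dHf = dHf)
}

head_forward <- function(model, Hout, B, training) {
  cfg <- model$config; p <- model$params
  Tp <- cfg$T_prime
  if (nrow(Hout) != B * Tp) stop("feature block has wrong frame count")
  grp <- rep(seq_len(B), each = Tp)
  Hp <- rowsum(Hout, grp) / Tp
  A1 <- lin_fwd(Hp, p[["head.h.W"]], p[["head.h.b"]])
  G1 <- gelu_fwd(A1)
  pred <- as.vector(lin_fwd(G1, p[["head.o.W"]], p[["head.o.b"]]))
  list(pred = pred, cache = list(Hp = Hp, A1 = A1, G1 = G1, B = B, Tp = Tp))
}

head_backward <- function(model, cache, dpred) {
  p <- model$params
  g <- list()
  lo <- lin_bwd(matrix(dpred, ncol = 1L), cache$G1, p[["head.o.W"]])
  g[["head.o.W"]] <- lo$dW; g[["head.o.b"]] <- lo$db
  dA1 <- gelu_bwd(lo$dX, cache$A1)
  lh <- lin_bwd(dA1, cache$Hp, p[["head.h.W"]])
  g[["head.h.W"]] <- lh$dW; g[["head.h.b"]] <- lh$db
  dHout <- lh$dX[rep(seq_len(cache$B), each = cache$Tp), , drop = FALSE] / cache$Tp
  list(grads = g, dHout = dHout)
}

# Complete forward pass. Returns predictions, the stage caches needed for the
# backward pass, and updated batch-norm running statistics.
model_forward <- function(model, x, task, training = FALSE) {
  cfg <- model$config
  check_signal(x, cfg)
  B <- dim(x)[3]
  fe <- fe_forward(model, x, training)
  Ht <- NULL; tpc <- NULL
  if ("temporal" %in% cfg$paths) {
    tp <- tp_forward(model, fe$Fmat, B, training)
    Ht <- tp$Ht; tpc <- tp$cache
  }
  Hs <- NULL; spc <- NULL
  if ("spatial" %in% cfg$paths) {
    sp <- sp_forward(model, fe$node, B, training)
    Hs <- sp$Hs; spc <- sp$cache
  }
  fu <- fuse_forward(model, Ht, Hs, training)
  ta <- tar_forward(model, fu$Hf, task, training)
  hd <- head_forward(model, ta$Hout, B, training)
  list(pred = hd$pred, G = fu$G,
       cache = list(fe = fe$cache, tp = tpc, sp = spc, fu = fu$cache,
                    ta = ta$cache, hd = hd$cache, B = B),
       bn_state = fe$bn_state)
}

# Backward pass; when `backbone = FALSE` gradient computation stops after the
# adapter and head (used under the transfer freeze policy).
model_backward <- function(model, cache, dpred, backbone = TRUE) {
  cfg <- model$config
  B <- cache$B
  hb <- head_backward(model, cache$hd, dpred)
  tb <- tar_backward(model, cache$ta, hb$dHout)
  g <- c(hb$grads, tb$grads)
  if (!backbone) return(g)
  fb <- fuse_backward(model, cache$fu, tb$dHf)
  g <- c(g, fb$grads)
  dFmat <- NULL; dnode <- NULL
  if (!is.null(fb$dHt)) {
    tpb <- tp_backward(model, cache$tp, fb$dHt, B)
    g <- c(g, tpb$grads)
    dFmat <- tpb$dFmat
  }
  if (!is.null(fb$dHs)) {
    spb <- sp_backward(model, cache$sp, fb$dHs)
    g <- c(g, spb$grads)
    dnode <- spb$dnode
  }
  if (is.null(dFmat)) dFmat <- matrix(0, B * cfg$T_prime, cfg$D)
  g <- c(g, fe_backward(model, cache$fe, dFmat, dnode, B))
  g
}

#' Run the encoder on a batch of epochs
#'
#' Composes front-end, dual paths, gated fusion, task-adaptive modulation and
#' regression head in evaluation mode (dropout off, batch-norm running
#' statistics), so repeated calls on the same input are bitwise identical.
#'
#' @param model a [dstage()] model.
#' @param x `channels x frames x epochs` array.
#' @param task integer task id, `0` for the pre-training target (reaction
#'   time) and `1` for the transfer target.
#' @return Numeric vector of one prediction per epoch (standardized scale; the
#'   fitting functions handle target rescaling).
#' @export
dstage_forward <- function(model, x, task = 0L) {
  stopifnot(inherits(model, "dstage"))
  model_forward(model, x, task, training = FALSE)$pred
}
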