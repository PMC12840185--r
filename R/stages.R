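# Exported per-stage operations. These wrap the internal fast paths and
# exchange features in the reader-friendly epoch x frame x feature layout.

feat_to_array <- function(mat, B, Tp) {
  aperm(array(t(mat), c(ncol(mat), Tp, B)), c(3, 2, 1))
}

array_to_feat <- function(arr) {
  B <- dim(arr)[1]; Tp <- dim(arr)[2]; D <- dim(arr)[3]
  t(matrix(aperm(arr, c(3, 2, 1)), D, Tp * B))
}

#' Multi-scale convolution front-end
#'
#' Applies the parallel dilated temporal convolution branches, concatenates
#' and projects them to the common feature dimension, and pools frames by a
#' factor of two. Two views are produced: a channel-mixed temporal stream for
#' the transformer path and a channel-preserving stream (per-channel depthwise
#' convolutions) for the graph path.
#'
#' @param model a [dstage()] model.
#' @param x `channels x frames x epochs` array.
#' @return List with `temporal` (`epochs x T' x D` array) and `spatial`
#'   (`epochs x T' x channels x node_dim` array, or `NULL` when the spatial
#'   path is disabled).
#' @export
multiscale_frontend <- function(model, x) {
  stopifnot(inherits(model, "dstage"))
  check_signal(x, model$config)
  B <- dim(x)[3]
  fe <- fe_forward(model, x, training = FALSE)
  Tp <- model$config$T_prime
  spatial <- NULL
  if (!is.null(fe$node)) {
    # node: C x g x (B*Tp) -> B x Tp x C x g
    g0 <- dim(fe$node)[2]
    spatial <- aperm(array(fe$node, c(model$config$C, g0, Tp, B)), c(4, 3, 1, 2))
  }
  list(temporal = feat_to_array(fe$Fmat, B, Tp), spatial = spatial)
}

#' Temporal transformer path
#'
#' Adds fixed sinusoidal positional encodings, then applies pre-norm encoder
#' layers of multi-head self-attention, depthwise temporal convolution and a
#' feed-forward sublayer, each with a residual connection.
#'
#' @param model a [dstage()] model.
#' @param F_arr front-end temporal stream, `epochs x T' x D`.
#' @return `epochs x T' x D_t` array.
#' @export
temporal_path <- function(model, F_arr) {
  stopifnot(inherits(model, "dstage"))
  if (!("temporal" %in% model$config$paths)) stop("temporal path is disabled")
  B <- dim(F_arr)[1]; Tp <- dim(F_arr)[2]
  if (Tp != model$config$T_prime || dim(F_arr)[3] != model$config$D)
    stop("front-end stream must be epochs x T' x D")
  tp <- tp_forward(model, array_to_feat(F_arr), B, training = FALSE)
  feat_to_array(tp$Ht, B, Tp)
}

#' Spatial graph-convolution path
#'
#' Treats channels as graph nodes: normalized-adjacency message passing with a
#' nonlinearity, applied per frame, followed by mean pooling over nodes and a
#' projection.
#'
#' @param model a [dstage()] model.
#' @param node_arr channel-preserving stream, `epochs x T' x channels x g`.
#' @param A optional adjacency override (must be symmetric, same dimension).
#' @return `epochs x T' x D_s` array.
#' @export
spatial_path <- function(model, node_arr, A = NULL) {
  stopifnot(inherits(model, "dstage"))
  if (!("spatial" %in% model$config$paths)) stop("spatial path is disabled")
  B <- dim(node_arr)[1]; Tp <- dim(node_arr)[2]; C <- dim(node_arr)[3]
  if (C != model$config$C) stop("node axis must match the channel count")
  if (!is.null(A)) {
    check_adjacency(A, C)
    model$buffers$A <- unclass(A)
  }
  g0 <- dim(node_arr)[4]
  node <- array(aperm(node_arr, c(3, 4, 2, 1)), c(C, g0, Tp * B))
  sp <- sp_forward(model, node, B, training = FALSE)
  feat_to_array(sp$Hs, B, Tp)
}

#' Gated fusion of the temporal and spatial streams
#'
#' A sigmoid gate `G = sigmoid(MLP(concat(Ht', Hs')))` forms the elementwise
#' convex combination `Hf = G * Ht' + (1 - G) * Hs'`. Every fused element
#' therefore lies between the two stream values, and every gate value lies
#' strictly in (0, 1).
#'
#' @param model a [dstage()] model with `fusion = "gate"`.
#' @param Ht_proj,Hs_proj the two streams already projected to the common
#'   dimension `D_f`, `epochs x T' x D_f` arrays of identical shape.
#' @return List with `H_f` and `G`, both `epochs x T' x D_f`.
#' @export
st_gate_fuse <- function(model, Ht_proj, Hs_proj) {
  stopifnot(inherits(model, "dstage"))
  if (model$config$fusion != "gate") stop("model was built without a fusion gate")
  if (!identical(dim(Ht_proj), dim(Hs_proj)))
    stop("the two streams must have identical shapes")
  if (dim(Ht_proj)[3] != model$config$D_f)
    stop("streams must be projected to D_f = ", model$config$D_f)
  B <- dim(Ht_proj)[1]; Tp <- dim(Ht_proj)[2]
  p <- model$params
  Htp <- array_to_feat(Ht_proj); Hsp <- array_to_feat(Hs_proj)
  Z <- cbind(Htp, Hsp)
  G1 <- gelu_fwd(lin_fwd(Z, p[["fuse.g1.W"]], p[["fuse.g1.b"]]))
  G <- sigmoid(lin_fwd(G1, p[["fuse.g2.W"]], p[["fuse.g2.b"]]))
  Hf <- G * Htp + (1 - G) * Hsp
  list(H_f = feat_to_array(Hf, B, Tp), G = feat_to_array(G, B, Tp))
}

#' Task-adaptive residual modulation
#'
#' Looks up the task embedding, derives feature-wise scale and shift
#' (`gamma_t`, `beta_t`), modulates the fused features and applies a
#' bottleneck residual block. With scale one, shift zero and the
#' zero-initialized bottleneck output layer this is the exact identity.
#'
#' @param model a [dstage()] model with the adapter enabled.
#' @param H_f fused features, `epochs x T' x D_f`.
#' @param task integer task id in `0..n_tasks-1`.
#' @return `epochs x T' x D_f` array.
#' @export
tar_block <- function(model, H_f, task) {
  stopifnot(inherits(model, "dstage"))
  if (!model$config$use_tar) stop("model was built without the task-adaptive block")
  B <- dim(H_f)[1]; Tp <- dim(H_f)[2]
  ta <- tar_forward(model, array_to_feat(H_f), as.integer(task), training = FALSE)
  feat_to_array(ta$Hout, B, Tp)
}

#' Regression head
#'
#' Global average pooling over frames followed by a small MLP producing one
#' scalar per epoch.
#'
#' @param model a [dstage()] model.
#' @param H_out modulated features, `epochs x T' x D_f`.
#' @return Numeric vector, one value per epoch.
#' @export
regression_head <- function(model, H_out) {
  stopifnot(inherits(model, "dstage"))
  B <- dim(H_out)[1]; Tp <- dim(H_out)[2]
  if (is.na(Tp) || Tp < 1L) stop("empty frame axis")
  p <- model$params
  Hp <- matrix(0, B, dim(H_out)[3])
  for (i in seq_len(B)) Hp[i, ] <- colMeans(matrix(H_out[i, , ], Tp))
  G1 <- gelu_fwd(lin_fwd(Hp, p[["head.h.W"]], p[["head.h.b"]]))
  as.vector(lin_fwd(G1, p[["head.o.W"]], p[["head.o.b"]]))
}
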