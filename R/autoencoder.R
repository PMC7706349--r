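# Minimal convolutional autoencoder, implemented directly on matrix
# primitives. Feature maps are arrays [H, W, C, N]; convolutions run as
# im2col gathers followed by one matrix multiply, so the heavy lifting is
# BLAS. Everything is deterministic given the seed.

conv_plan <- function(H, W, k, stride, pad) {
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1; Wo <- (Wp - k) %/% stride + 1
  i0 <- (seq_len(Ho) - 1) * stride  # top-left of each patch (0-based)
  j0 <- (seq_len(Wo) - 1) * stride
  # rows ordered (h fastest, then w); cols ordered (di fastest, then dj)
  pr <- outer(rep(i0, times = Wo), rep(0:(k - 1), times = k), `+`)
  pc <- outer(rep(j0, each = Ho), rep(0:(k - 1), each = k), `+`)
  idx <- pr + pc * Hp + 1L
  list(H = H, W = W, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, k = k,
       stride = stride, pad = pad, idx = idx)
}

pad_array <- function(A, pad) {
  if (pad == 0) return(A)
  d <- dim(A)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- A
  out
}

im2col <- function(A, plan) {
  Ap <- pad_array(A, plan$pad)
  C <- dim(Ap)[3]; N <- dim(Ap)[4]
  flat <- matrix(Ap, plan$Hp * plan$Wp, C * N)
  G <- flat[as.vector(plan$idx), , drop = FALSE]   # (P*k2) x (C*N)
  P <- plan$Ho * plan$Wo; k2 <- plan$k^2
  dim(G) <- c(P, k2, C, N)
  G <- aperm(G, c(1, 4, 2, 3))                      # P, N, k2, C
  dim(G) <- c(P * N, k2 * C)
  G
}

col2im <- function(dG, plan, C, N) {
  P <- plan$Ho * plan$Wo; k2 <- plan$k^2
  dim(dG) <- c(P, N, k2, C)
  dG <- aperm(dG, c(1, 3, 4, 2))                    # P, k2, C, N
  dim(dG) <- c(P * k2, C * N)
  grp <- as.vector(plan$idx)
  acc <- rowsum(dG, group = grp)                    # sorted unique idx
  flat <- matrix(0, plan$Hp * plan$Wp, C * N)
  flat[sort(unique(grp)), ] <- acc
  Ap <- array(flat, c(plan$Hp, plan$Wp, C, N))
  if (plan$pad > 0)
    Ap <- Ap[plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W), , ,
             drop = FALSE]
  Ap
}

conv_forward <- function(A, Wt, b, plan) {
  C <- dim(A)[3]; N <- dim(A)[4]
  G <- im2col(A, plan)
  Z <- sweep(G %*% Wt, 2, b, `+`)                   # (P*N) x Cout
  Cout <- length(b)
  dim(Z) <- c(plan$Ho * plan$Wo, N, Cout)
  Z <- aperm(Z, c(1, 3, 2))
  dim(Z) <- c(plan$Ho, plan$Wo, Cout, N)
  list(out = Z, G = G)
}

conv_backward <- function(dZ, G, Wt, plan, C, N) {
  Cout <- ncol(Wt)
  dim(dZ) <- c(plan$Ho * plan$Wo, Cout, N)
  dZ <- aperm(dZ, c(1, 3, 2))
  dim(dZ) <- c(plan$Ho * plan$Wo * N, Cout)
  dW <- crossprod(G, dZ)
  db <- colSums(dZ)
  dG <- dZ %*% t(Wt)
  dA <- col2im(dG, plan, C, N)
  list(dA = dA, dW = dW, db = db)
}

upsample2 <- function(A) {
  A[rep(seq_len(dim(A)[1]), each = 2),
    rep(seq_len(dim(A)[2]), each = 2), , , drop = FALSE]
}

downsum2 <- function(dB) {
  H2 <- dim(dB)[1]; i1 <- seq(1, H2, 2); i2 <- seq(2, H2, 2)
  W2 <- dim(dB)[2]; j1 <- seq(1, W2, 2); j2 <- seq(2, W2, 2)
  dB[i1, j1, , , drop = FALSE] + dB[i1, j2, , , drop = FALSE] +
    dB[i2, j1, , , drop = FALSE] + dB[i2, j2, , , drop = FALSE]
}

ae_init <- function(side, latent_dim) {
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  ch <- c(1, 8, 16, 32)
  plans <- list(conv_plan(side, side, 3, 2, 1),
                conv_plan(side / 2, side / 2, 3, 2, 1),
                conv_plan(side / 4, side / 4, 3, 2, 1))
  s8 <- side / 8
  dplans <- list(conv_plan(side / 4, side / 4, 3, 1, 1),
                 conv_plan(side / 2, side / 2, 3, 1, 1),
                 conv_plan(side, side, 3, 1, 1))
  params <- list(
    W1 = matrix(he(9 * ch[1], 9 * ch[1] * ch[2]), 9 * ch[1], ch[2]),
    b1 = numeric(ch[2]),
    W2 = matrix(he(9 * ch[2], 9 * ch[2] * ch[3]), 9 * ch[2], ch[3]),
    b2 = numeric(ch[3]),
    W3 = matrix(he(9 * ch[3], 9 * ch[3] * ch[4]), 9 * ch[3], ch[4]),
    b3 = numeric(ch[4]),
    W4 = matrix(he(s8 * s8 * ch[4], s8 * s8 * ch[4] * latent_dim),
                s8 * s8 * ch[4], latent_dim),
    b4 = numeric(latent_dim),
    W5 = matrix(he(latent_dim, latent_dim * s8 * s8 * ch[4]),
                latent_dim, s8 * s8 * ch[4]),
    b5 = numeric(s8 * s8 * ch[4]),
    W6 = matrix(he(9 * ch[4], 9 * ch[4] * ch[3]), 9 * ch[4], ch[3]),
    b6 = numeric(ch[3]),
    W7 = matrix(he(9 * ch[3], 9 * ch[3] * ch[2]), 9 * ch[3], ch[2]),
    b7 = numeric(ch[2]),
    W8 = matrix(he(9 * ch[2], 9 * ch[2] * 1), 9 * ch[2], 1),
    b8 = numeric(1))
  list(params = params, plans = plans, dplans = dplans, ch = ch,
       side = side, s8 = s8, latent_dim = latent_dim)
}

ae_forward <- function(model, X, with_cache = TRUE) {
  p <- model$params; pl <- model$plans; dpl <- model$dplans
  N <- dim(X)[4]
  c1 <- conv_forward(X, p$W1, p$b1, pl[[1]]); a1 <- pmax(c1$out, 0)
  c2 <- conv_forward(a1, p$W2, p$b2, pl[[2]]); a2 <- pmax(c2$out, 0)
  c3 <- conv_forward(a2, p$W3, p$b3, pl[[3]]); a3 <- pmax(c3$out, 0)
  Fm <- t(matrix(a3, model$s8 * model$s8 * model$ch[4], N))
  Z <- sweep(Fm %*% p$W4, 2, p$b4, `+`)             # latent, N x 8
  D <- sweep(Z %*% p$W5, 2, p$b5, `+`); Da <- pmax(D, 0)
  A4 <- array(t(Da), c(model$s8, model$s8, model$ch[4], N))
  u1 <- upsample2(A4)
  c6 <- conv_forward(u1, p$W6, p$b6, dpl[[1]]); a6 <- pmax(c6$out, 0)
  u2 <- upsample2(a6)
  c7 <- conv_forward(u2, p$W7, p$b7, dpl[[2]]); a7 <- pmax(c7$out, 0)
  u3 <- upsample2(a7)
  c8 <- conv_forward(u3, p$W8, p$b8, dpl[[3]])
  Y <- 1 / (1 + exp(-c8$out))                       # sigmoid logits
  out <- list(Y = Y, Z = Z)
  if (with_cache)
    out$cache <- list(X = X, c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3,
                      a3 = a3, Fm = Fm, Z = Z, D = D, Da = Da, u1 = u1,
                      c6 = c6, a6 = a6, u2 = u2, c7 = c7, a7 = a7,
                      u3 = u3, logits = c8)
  out
}

ae_loss <- function(Y, X) {
  eps <- 1e-7
  -mean(X * log(Y + eps) + (1 - X) * log(1 - Y + eps))
}

#' Train a convolutional autoencoder on silhouette images
#'
#' A small encoder--decoder: three stride-2 3x3 convolution blocks
#' (8, 16, 32 filters, ReLU) down to a dense `latent_dim`-dimensional
#' bottleneck, mirrored by a dense expansion and three nearest-neighbour
#' upsample + 3x3 convolution blocks, sigmoid output, binary cross-entropy
#' loss, full-batch Adam. Training is deterministic given `seed`.
#'
#' @param images list of side x side numeric matrices in [0, 1] (all the
#'   same size, >= 16 of them), or a 3-d array (side, side, N).
#' @param latent_dim bottleneck width (default 8).
#' @param epochs training epochs (default 60).
#' @param lr Adam learning rate.
#' @param seed RNG seed for the weight initialization.
#' @return an `autoencoder`: list with `encode(images)` returning the
#'   N x latent_dim feature matrix, `params`, `history` (per-epoch loss)
#'   and `fingerprint` (architecture string, seed, epochs).
#' @export
train_autoencoder <- function(images, latent_dim = 8, epochs = 60,
                              lr = 2e-3, seed = 1) {
  X <- stack_images(images)
  side <- dim(X)[1]; N <- dim(X)[4]
  if (N < 16) stop_param("need >= 16 images")
  if (side %% 8 != 0) stop_param("image side must be divisible by 8")
  model <- with_seed(derive_seed(seed, "autoencoder_init"),
                     ae_init(side, latent_dim))
  mstate <- lapply(model$params, function(w) w * 0)
  vstate <- mstate
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fwd <- ae_forward(model, X)
    history[ep] <- ae_loss(fwd$Y, X)
    gr <- ae_gradients(model, fwd, X)
    upd <- adam_update(model$params, gr, mstate, vstate, ep, lr)
    model$params <- upd$params; mstate <- upd$m; vstate <- upd$v
  }
  structure(list(
    params = model$params, model = model, history = history,
    encode = function(imgs) {
      Xn <- stack_images(imgs)
      out <- ae_forward(model, Xn, with_cache = FALSE)
      unname(out$Z)
    },
    fingerprint = list(architecture = sprintf(
      "conv8-16-32/s2 + dense%d + mirrored decoder, side %d",
      latent_dim, side), seed = seed, epochs = epochs)),
    class = "autoencoder")
}

stack_images <- function(images) {
  if (is.array(images) && length(dim(images)) == 3) {
    X <- array(images, c(dim(images)[1], dim(images)[2], 1, dim(images)[3]))
    return(X)
  }
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1) stop_param("images must share one size")
  side <- dims[[1]]
  array(unlist(images), c(side[1], side[2], 1, length(images)))
}

ae_gradients <- function(model, fwd, X) {
  p <- model$params; pl <- model$plans; dpl <- model$dplans
  ca <- fwd$cache; N <- dim(X)[4]; M <- length(X)
  gr <- list()
  dlogit <- (fwd$Y - X) / M
  g8 <- conv_backward(dlogit, ca$logits$G, p$W8, dpl[[3]], model$ch[2], N)
  gr$W8 <- g8$dW; gr$b8 <- g8$db
  d_u3 <- g8$dA
  d_a7 <- downsum2(d_u3) * (ca$a7 > 0)
  g7 <- conv_backward(d_a7, ca$c7$G, p$W7, dpl[[2]], model$ch[3], N)
  gr$W7 <- g7$dW; gr$b7 <- g7$db
  d_a6 <- downsum2(g7$dA) * (ca$a6 > 0)
  g6 <- conv_backward(d_a6, ca$c6$G, p$W6, dpl[[1]], model$ch[4], N)
  gr$W6 <- g6$dW; gr$b6 <- g6$db
  d_A4 <- downsum2(g6$dA)
  dDa <- t(matrix(d_A4, model$s8 * model$s8 * model$ch[4], N))
  dD <- dDa * (ca$D > 0)
  gr$W5 <- crossprod(ca$Z, dD); gr$b5 <- colSums(dD)
  dZ <- dD %*% t(p$W5)
  gr$W4 <- crossprod(ca$Fm, dZ); gr$b4 <- colSums(dZ)
  dFm <- dZ %*% t(p$W4)
  d_a3 <- array(t(dFm), dim(ca$a3)) * (ca$a3 > 0)
  g3 <- conv_backward(d_a3, ca$c3$G, p$W3, pl[[3]], model$ch[3], N)
  gr$W3 <- g3$dW; gr$b3 <- g3$db
  d_a2 <- g3$dA * (ca$a2 > 0)
  g2 <- conv_backward(d_a2, ca$c2$G, p$W2, pl[[2]], model$ch[2], N)
  gr$W2 <- g2$dW; gr$b2 <- g2$db
  d_a1 <- g2$dA * (ca$a1 > 0)
  g1 <- conv_backward(d_a1, ca$c1$G, p$W1, pl[[1]], model$ch[1], N)
  gr$W1 <- g1$dW; gr$b1 <- g1$db
  gr
}

adam_update <- function(params, gr, m, v, t, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- gr[[nm]]
    m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
    v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g^2
    mhat <- m[[nm]] / (1 - beta1^t)
    vhat <- v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, m = m, v = v)
}

#' Shape-based clusters from latent features
#'
#' k-means (Euclidean, 25 restarts, deterministic given `seed`) on the
#' latent feature vectors; clusters are relabelled "A"... by decreasing
#' mean of the member genotypes' z-scored trait values when `trait_z` is
#' supplied (ties broken by cluster size), otherwise by decreasing cluster
#' size.
#'
#' @param latents N x d feature matrix (rownames = genotypes).
#' @param k number of clusters (default 8).
#' @param trait_z optional genotype x trait matrix of z-scored traits used
#'   for ordering the labels.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart restarts (default 25).
#' @return a `cluster_assignment` factor named by genotype, with attribute
#'   `kmeans` (the fit).
#' @export
shape_clusters <- function(latents, k = 8, trait_z = NULL, seed = 1,
                           nstart = 25) {
  X <- as.matrix(latents)
  if (k > nrow(X)) stop_param("k exceeds the number of observations")
  km <- with_seed(derive_seed(seed, "shape_kmeans"),
                  stats::kmeans(X, centers = k, nstart = nstart,
                                iter.max = 100))
  grp <- km$cluster
  if (!is.null(trait_z)) {
    Z <- as.matrix(trait_z)[rownames(X), , drop = FALSE]
    assign <- relabel_by_meanz(grp, Z, k, sizes_break_ties = TRUE)
  } else {
    sz <- tabulate(grp, k)
    new_lab <- character(k)
    new_lab[order(-sz)] <- LETTERS[seq_len(k)]
    assign <- factor(new_lab[grp], levels = LETTERS[seq_len(k)])
  }
  names(assign) <- rownames(X)
  structure(assign, method = "SBC", kmeans = km,
            class = c("cluster_assignment", "factor"))
}
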