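# Minimal neural-network engine: dense, 1-D convolution (optionally dilated
# and causal), max-pooling, GRU and LSTM layers with reverse-mode gradients,
# and an Adam optimizer. Activations are arrays (batch, time, channels);
# convolution is implemented as im2col + matrix multiply.
#
# Ordering conventions (used consistently by forward and backward passes):
#   - (B, T, C) arrays flatten with B fastest, so matrix(A, B*T, C) rows are
#     (b, t) pairs with b varying fastest.
#   - conv kernels W have dim (K, Cin, Cout); the im2col matrix columns are
#     ordered (cin within k-block), matching matrix(aperm(W, c(2,1,3)), ...).

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_rand <- function(dims, fan_in) {
  s <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -s, s), dims)
}

# ---- dense ----------------------------------------------------------------

dense_forward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2L, b, `+`), X = X)
}

dense_backward <- function(cache, W, dOut) {
  list(dX = dOut %*% t(W), dW = t(cache$X) %*% dOut, db = colSums(dOut))
}

# ---- conv1d ---------------------------------------------------------------

conv1d_forward <- function(A, W, b, dilation = 1L, causal = FALSE) {
  dA <- dim(A)
  B <- dA[1]; Tt <- dA[2]; Cin <- dA[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  pad <- if (causal) (K - 1L) * dilation else 0L
  Ap <- if (pad > 0L) {
    tmp <- array(0, c(B, Tt + pad, Cin))
    tmp[, (pad + 1L):(Tt + pad), ] <- A
    tmp
  } else {
    A
  }
  Tp <- dim(Ap)[2]
  Tout <- Tp - (K - 1L) * dilation
  M <- matrix(0, B * Tout, K * Cin)
  for (k in seq_len(K)) {
    off <- (k - 1L) * dilation
    sl <- Ap[, (off + 1L):(off + Tout), , drop = FALSE]
    M[, ((k - 1L) * Cin + 1L):(k * Cin)] <- matrix(sl, B * Tout, Cin)
  }
  Wm <- matrix(aperm(W, c(2L, 1L, 3L)), K * Cin, Cout)
  out <- sweep(M %*% Wm, 2L, b, `+`)
  list(out = array(out, c(B, Tout, Cout)), M = M,
       dims = list(B = B, Tt = Tt, Cin = Cin, K = K, Cout = Cout,
                   Tout = Tout, pad = pad, dilation = dilation))
}

conv1d_backward <- function(cache, W, dOut) {
  d <- cache$dims
  dOm <- matrix(dOut, d$B * d$Tout, d$Cout)
  Wm <- matrix(aperm(W, c(2L, 1L, 3L)), d$K * d$Cin, d$Cout)
  dWm <- t(cache$M) %*% dOm
  dW <- aperm(array(dWm, c(d$Cin, d$K, d$Cout)), c(2L, 1L, 3L))
  db <- colSums(dOm)
  dM <- dOm %*% t(Wm)
  dAp <- array(0, c(d$B, d$Tt + d$pad, d$Cin))
  for (k in seq_len(d$K)) {
    off <- (k - 1L) * d$dilation
    idx <- (off + 1L):(off + d$Tout)
    dAp[, idx, ] <- dAp[, idx, , drop = FALSE] +
      array(dM[, ((k - 1L) * d$Cin + 1L):(k * d$Cin)],
            c(d$B, d$Tout, d$Cin))
  }
  dA <- if (d$pad > 0L) {
    dAp[, (d$pad + 1L):(d$Tt + d$pad), , drop = FALSE]
  } else {
    dAp
  }
  list(dA = dA, dW = dW, db = db)
}

# ---- relu / maxpool / flatten --------------------------------------------

relu_forward <- function(A) list(out = pmax(A, 0), mask = A > 0)
relu_backward <- function(cache, dOut) dOut * cache$mask

maxpool2_forward <- function(A) {
  dA <- dim(A)
  T2 <- dA[2] %/% 2L
  i1 <- seq.int(1L, 2L * T2, by = 2L)
  A1 <- A[, i1, , drop = FALSE]
  A2 <- A[, i1 + 1L, , drop = FALSE]
  mask <- A1 >= A2
  list(out = pmax(A1, A2), mask = mask, Tin = dA[2])
}

maxpool2_backward <- function(cache, dOut) {
  dm <- dim(dOut)
  T2 <- dm[2]
  dA <- array(0, c(dm[1], cache$Tin, dm[3]))
  i1 <- seq.int(1L, 2L * T2, by = 2L)
  dA[, i1, ] <- dOut * cache$mask
  dA[, i1 + 1L, ] <- dOut * !cache$mask
  dA
}

flatten_forward <- function(A) {
  dA <- dim(A)
  list(out = matrix(A, dA[1], dA[2] * dA[3]), dims = dA)
}

flatten_backward <- function(cache, dOut) array(dOut, cache$dims)

# ---- recurrent cells ------------------------------------------------------

gru_init <- function(input_dim, hidden) {
  list(
    Wz = nn_rand(c(input_dim, hidden), input_dim + hidden),
    Wr = nn_rand(c(input_dim, hidden), input_dim + hidden),
    Wh = nn_rand(c(input_dim, hidden), input_dim + hidden),
    Uz = nn_rand(c(hidden, hidden), input_dim + hidden),
    Ur = nn_rand(c(hidden, hidden), input_dim + hidden),
    Uh = nn_rand(c(hidden, hidden), input_dim + hidden),
    bz = numeric(hidden), br = numeric(hidden), bh = numeric(hidden)
  )
}

# X: (B, T) single-channel input; returns last hidden state and caches
gru_forward <- function(X, p) {
  B <- nrow(X); Tt <- ncol(X); H <- length(p$bz)
  h <- matrix(0, B, H)
  steps <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    xt <- X[, t, drop = FALSE]
    z <- sigmoid(sweep(xt %*% p$Wz + h %*% p$Uz, 2L, p$bz, `+`))
    r <- sigmoid(sweep(xt %*% p$Wr + h %*% p$Ur, 2L, p$br, `+`))
    hh <- tanh(sweep(xt %*% p$Wh + (r * h) %*% p$Uh, 2L, p$bh, `+`))
    h_new <- (1 - z) * h + z * hh
    steps[[t]] <- list(xt = xt, h_prev = h, z = z, r = r, hh = hh)
    h <- h_new
  }
  list(out = h, steps = steps)
}

gru_backward <- function(cache, p, dH) {
  g <- lapply(p, function(w) array(0, dim(as.array(w))))
  g$bz <- numeric(length(p$bz)); g$br <- g$bz; g$bh <- g$bz
  dh <- dH
  for (t in rev(seq_along(cache$steps))) {
    st <- cache$steps[[t]]
    dz <- dh * (st$hh - st$h_prev)
    dhh <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    dah <- dhh * (1 - st$hh^2)
    daz <- dz * st$z * (1 - st$z)
    drh <- dah %*% t(p$Uh)
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    dar <- dr * st$r * (1 - st$r)
    g$Wh <- g$Wh + t(st$xt) %*% dah
    g$Uh <- g$Uh + t(st$r * st$h_prev) %*% dah
    g$bh <- g$bh + colSums(dah)
    g$Wz <- g$Wz + t(st$xt) %*% daz
    g$Uz <- g$Uz + t(st$h_prev) %*% daz
    g$bz <- g$bz + colSums(daz)
    g$Wr <- g$Wr + t(st$xt) %*% dar
    g$Ur <- g$Ur + t(st$h_prev) %*% dar
    g$br <- g$br + colSums(dar)
    dh <- dh_prev + daz %*% t(p$Uz) + dar %*% t(p$Ur)
  }
  g
}

lstm_init <- function(input_dim, hidden) {
  mk <- function() nn_rand(c(input_dim, hidden), input_dim + hidden)
  mku <- function() nn_rand(c(hidden, hidden), input_dim + hidden)
  list(Wi = mk(), Wf = mk(), Wo = mk(), Wg = mk(),
       Ui = mku(), Uf = mku(), Uo = mku(), Ug = mku(),
       bi = numeric(hidden), bf = rep(1, hidden), bo = numeric(hidden),
       bg = numeric(hidden))
}

lstm_forward <- function(X, p) {
  B <- nrow(X); Tt <- ncol(X); H <- length(p$bi)
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  steps <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    xt <- X[, t, drop = FALSE]
    i <- sigmoid(sweep(xt %*% p$Wi + h %*% p$Ui, 2L, p$bi, `+`))
    f <- sigmoid(sweep(xt %*% p$Wf + h %*% p$Uf, 2L, p$bf, `+`))
    o <- sigmoid(sweep(xt %*% p$Wo + h %*% p$Uo, 2L, p$bo, `+`))
    gg <- tanh(sweep(xt %*% p$Wg + h %*% p$Ug, 2L, p$bg, `+`))
    c_new <- f * cst + i * gg
    tc <- tanh(c_new)
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cst, i = i, f = f,
                       o = o, g = gg, tc = tc)
    cst <- c_new
    h <- o * tc
  }
  list(out = h, steps = steps)
}

lstm_backward <- function(cache, p, dH) {
  g <- lapply(p, function(w) array(0, dim(as.array(w))))
  for (nm in c("bi", "bf", "bo", "bg")) g[[nm]] <- numeric(length(p[[nm]]))
  dh <- dH
  dc <- matrix(0, nrow(dH), ncol(dH))
  for (t in rev(seq_along(cache$steps))) {
    st <- cache$steps[[t]]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dai <- di * st$i * (1 - st$i)
    daf <- df * st$f * (1 - st$f)
    dao <- do * st$o * (1 - st$o)
    dag <- dg * (1 - st$g^2)
    g$Wi <- g$Wi + t(st$xt) %*% dai; g$Ui <- g$Ui + t(st$h_prev) %*% dai
    g$bi <- g$bi + colSums(dai)
    g$Wf <- g$Wf + t(st$xt) %*% daf; g$Uf <- g$Uf + t(st$h_prev) %*% daf
    g$bf <- g$bf + colSums(daf)
    g$Wo <- g$Wo + t(st$xt) %*% dao; g$Uo <- g$Uo + t(st$h_prev) %*% dao
    g$bo <- g$bo + colSums(dao)
    g$Wg <- g$Wg + t(st$xt) %*% dag; g$Ug <- g$Ug + t(st$h_prev) %*% dag
    g$bg <- g$bg + colSums(dag)
    dh <- dai %*% t(p$Ui) + daf %*% t(p$Uf) + dao %*% t(p$Uo) +
      dag %*% t(p$Ug)
    dc <- dc * st$f
  }
  g
}

# ---- architectures --------------------------------------------------------

nn_arch_defaults <- function(family) {
  switch(family,
    gru = list(hidden = 64L),
    lstm = list(hidden = 64L),
    cnn1d = list(kernel = 5L, channels = c(16L, 32L, 64L)),
    tcn = list(kernel = 3L, dilations = c(1L, 2L, 4L, 8L), channels = 32L),
    stop("unknown sequence family: ", family, call. = FALSE)
  )
}

nn_init <- function(family, input_len, n_out, arch) {
  if (family %in% c("gru", "lstm")) {
    cell <- if (family == "gru") {
      gru_init(1L, arch$hidden)
    } else {
      lstm_init(1L, arch$hidden)
    }
    head_in <- arch$hidden
    list(cell = cell,
         Wout = nn_rand(c(head_in, n_out), head_in), bout = numeric(n_out))
  } else if (family == "cnn1d") {
    ch <- c(1L, arch$channels)
    convs <- list()
    Tt <- input_len
    for (i in seq_along(arch$channels)) {
      convs[[i]] <- list(
        W = nn_rand(c(arch$kernel, ch[i], ch[i + 1L]), arch$kernel * ch[i]),
        b = numeric(ch[i + 1L])
      )
      Tt <- (Tt - arch$kernel + 1L) %/% 2L
    }
    if (Tt < 1L) {
      stop("cnn1d: input window too short for the architecture",
           call. = FALSE)
    }
    head_in <- Tt * ch[length(ch)]
    list(convs = convs,
         Wout = nn_rand(c(head_in, n_out), head_in), bout = numeric(n_out))
  } else if (family == "tcn") {
    ch <- c(1L, rep(arch$channels, length(arch$dilations)))
    convs <- list()
    for (i in seq_along(arch$dilations)) {
      convs[[i]] <- list(
        W = nn_rand(c(arch$kernel, ch[i], ch[i + 1L]), arch$kernel * ch[i]),
        b = numeric(ch[i + 1L])
      )
    }
    head_in <- arch$channels
    list(convs = convs,
         Wout = nn_rand(c(head_in, n_out), head_in), bout = numeric(n_out))
  }
}

# forward to logits/outputs; returns caches when train = TRUE
nn_forward <- function(family, params, X, arch, train = FALSE) {
  B <- nrow(X)
  if (family %in% c("gru", "lstm")) {
    rec <- if (family == "gru") {
      gru_forward(X, params$cell)
    } else {
      lstm_forward(X, params$cell)
    }
    head <- dense_forward(rec$out, params$Wout, params$bout)
    list(out = head$out,
         cache = if (train) list(rec = rec, head = head) else NULL)
  } else if (family == "cnn1d") {
    A <- array(X, c(B, ncol(X), 1L))
    caches <- list()
    for (i in seq_along(params$convs)) {
      cv <- conv1d_forward(A, params$convs[[i]]$W, params$convs[[i]]$b)
      rl <- relu_forward(cv$out)
      mp <- maxpool2_forward(rl$out)
      caches[[i]] <- list(cv = cv, rl = rl, mp = mp)
      A <- mp$out
    }
    fl <- flatten_forward(A)
    head <- dense_forward(fl$out, params$Wout, params$bout)
    list(out = head$out,
         cache = if (train) list(blocks = caches, fl = fl, head = head)
                 else NULL)
  } else if (family == "tcn") {
    A <- array(X, c(B, ncol(X), 1L))
    caches <- list()
    for (i in seq_along(params$convs)) {
      cv <- conv1d_forward(A, params$convs[[i]]$W, params$convs[[i]]$b,
                           dilation = arch$dilations[i], causal = TRUE)
      rl <- relu_forward(cv$out)
      caches[[i]] <- list(cv = cv, rl = rl)
      A <- rl$out
    }
    last <- A[, dim(A)[2], , drop = FALSE]
    last <- matrix(last, B, dim(A)[3])
    head <- dense_forward(last, params$Wout, params$bout)
    list(out = head$out,
         cache = if (train) list(blocks = caches, Adim = dim(A),
                                 head = head) else NULL)
  }
}

nn_backward <- function(family, params, fw, dOut, arch) {
  hb <- dense_backward(fw$cache$head, params$Wout, dOut)
  grads <- list(Wout = hb$dW, bout = hb$db)
  if (family %in% c("gru", "lstm")) {
    grads$cell <- if (family == "gru") {
      gru_backward(fw$cache$rec, params$cell, hb$dX)
    } else {
      lstm_backward(fw$cache$rec, params$cell, hb$dX)
    }
  } else if (family == "cnn1d") {
    dA <- flatten_backward(fw$cache$fl, hb$dX)
    grads$convs <- vector("list", length(params$convs))
    for (i in rev(seq_along(params$convs))) {
      blk <- fw$cache$blocks[[i]]
      dA <- maxpool2_backward(blk$mp, dA)
      dA <- relu_backward(blk$rl, dA)
      cb <- conv1d_backward(blk$cv, params$convs[[i]]$W, dA)
      grads$convs[[i]] <- list(W = cb$dW, b = cb$db)
      dA <- cb$dA
    }
  } else if (family == "tcn") {
    Adim <- fw$cache$Adim
    dA <- array(0, Adim)
    dA[, Adim[2], ] <- hb$dX
    grads$convs <- vector("list", length(params$convs))
    for (i in rev(seq_along(params$convs))) {
      blk <- fw$cache$blocks[[i]]
      dA <- relu_backward(blk$rl, dA)
      cb <- conv1d_backward(blk$cv, params$convs[[i]]$W, dA)
      grads$convs[[i]] <- list(W = cb$dW, b = cb$db)
      dA <- cb$dA
    }
  }
  grads
}

# ---- losses ---------------------------------------------------------------

softmax_ce <- function(logits, y) {
  # y: integer 0..k-1
  m <- apply(logits, 1L, max)
  ex <- exp(logits - m)
  p <- ex / rowSums(ex)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n)
}

mse_loss <- function(pred, y) {
  n <- length(y)
  d <- as.numeric(pred) - y
  list(loss = mean(d^2), dpred = matrix(2 * d / n, ncol = 1L))
}

# ---- Adam -----------------------------------------------------------------

# params/grads are nested lists of numeric arrays with identical shapes;
# leaves are matched by name where names exist (construction order differs)
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p
      keys <- if (!is.null(names(p)) && all(nzchar(names(p)))) {
        names(p)
      } else {
        seq_along(p)
      }
      out_s <- if (is.null(s)) {
        tmp <- vector("list", length(p))
        names(tmp) <- names(p)
        tmp
      } else {
        s
      }
      for (k in keys) {
        r <- walk(p[[k]], g[[k]], out_s[[k]])
        out_p[[k]] <- r$p; out_s[[k]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      if (is.null(s)) s <- list(m = p * 0, v = p * 0)
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
    }
  }
  walk(params, grads, state)
}

# ---- training loop --------------------------------------------------------

# X: (n, input_len) matrix of windows; y: integer classes or numeric target
nn_train <- function(family, X, y, task, n_out, lr = 0.001, epochs = 75L,
                     batch_size = 32L, seed = 1L, arch = NULL) {
  arch <- utils::modifyList(nn_arch_defaults(family),
                            if (is.null(arch)) list() else arch)
  n <- nrow(X)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  params <- nn_init(family, ncol(X), n_out, arch)
  state <- NULL
  step <- 0L
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  if (epochs > 0L) {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      losses <- numeric(0)
      for (start in seq.int(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        fw <- nn_forward(family, params, Xb, arch, train = TRUE)
        if (task == "classification") {
          ls <- softmax_ce(fw$out, y[idx])
          dOut <- ls$dlogits
        } else {
          ls <- mse_loss(fw$out, y[idx])
          dOut <- ls$dpred
        }
        grads <- nn_backward(family, params, fw, dOut, arch)
        step <- step + 1L
        upd <- adam_step(params, grads, state, lr, step)
        params <- upd$p
        state <- upd$s
        losses <- c(losses, ls$loss)
      }
      log <- rbind(log, data.frame(epoch = ep, loss = mean(losses)))
    }
  }
  list(params = params, arch = arch, log = log, family = family,
       task = task, n_out = n_out, input_len = ncol(X))
}

nn_predict_raw <- function(fit, X, chunk = 512L) {
  n <- nrow(X)
  out <- NULL
  for (start in seq.int(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- nn_forward(fit$family, fit$params, X[idx, , drop = FALSE],
                     fit$arch, train = FALSE)
    out <- rbind(out, fw$out)
  }
  out
}
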