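#' LSTM decoder specification
#'
#' Architecture and training hyperparameters for a gait decoder: a stack
#' of LSTM layers over the per-window feature sequence, a fully-connected
#' layer of size equal to the number of classes, and a softmax emitting a
#' posterior per window. Training uses truncated backpropagation through
#' contiguous non-overlapping runs of `seq_len` windows (default 100
#' windows = 1 s at the 100 Hz decision rate), cross-entropy loss, and the
#' Adam optimizer with early stopping on validation loss.
#'
#' @param input_size Number of feature channels.
#' @param lstm_layers Integer vector of LSTM unit counts per layer.
#' @param classes Character vector of class names (the softmax is defined
#'   over this set, in this order).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Sequences per minibatch (default 32).
#' @param seq_len Training sequence length in windows (default 100).
#' @param max_epochs Maximum training epochs (default 30).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param class_weighting Class-imbalance compensation: `FALSE` (or 0)
#'   for none, `TRUE` (or 1) for inverse-frequency weights, or a numeric
#'   exponent `p` in (0, 1] weighting each class by
#'   `(1 / frequency)^p` (tempered weighting; `p = 0.5` raises the
#'   minority class moderately without flooding its precision).
#' @param seed Integer seed controlling initialization and batch
#'   shuffling; identical data + spec + seed give identical parameters.
#' @return A `network_spec` object.
#' @export
network_spec <- function(input_size, lstm_layers, classes,
                         learning_rate = 1e-3, batch_size = 32,
                         seq_len = 100, max_epochs = 30, patience = 10,
                         class_weighting = FALSE, seed = 1L) {
  stopifnot(input_size >= 1, all(lstm_layers >= 1), length(classes) >= 2,
            learning_rate > 0, batch_size >= 1, seq_len >= 2,
            max_epochs >= 1, patience >= 1)
  structure(list(input_size = as.integer(input_size),
                 lstm_layers = as.integer(lstm_layers),
                 classes = as.character(classes),
                 n_classes = length(classes),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seq_len = as.integer(seq_len),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 class_weighting = if (is.numeric(class_weighting)) {
                   class_weighting
                 } else as.numeric(isTRUE(class_weighting)),
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' EEG decoder architecture: two LSTM layers with 250 and 150 units,
#' classifying swing (of either leg) against double stance. Tempered
#' class weighting (exponent 0.5) is on by default: swing occupies
#' roughly 80% of walking time, and without weighting a briefly trained
#' network settles into the trivial always-swing solution, while full
#' inverse-frequency weighting over-predicts stance and drives its
#' precision below one half — at which point a stance vote carries no
#' evidence and the belief fusion can never recover the stance phase.
#'
#' @param input_size Number of EEG channels.
#' @param class_weighting Class-imbalance exponent (default 0.5).
#' @param ... Passed to [network_spec()].
#' @return A `network_spec`.
#' @export
eeg_network_spec <- function(input_size, class_weighting = 0.5, ...) {
  network_spec(input_size, lstm_layers = c(250L, 150L),
               classes = EEG_CLASSES, class_weighting = class_weighting, ...)
}

#' EMG decoder architecture: one LSTM layer with 150 units, classifying
#' right swing, left swing and double stance.
#'
#' @param input_size Number of EMG channels.
#' @param ... Passed to [network_spec()].
#' @return A `network_spec`.
#' @export
emg_network_spec <- function(input_size, ...) {
  network_spec(input_size, lstm_layers = 150L,
               classes = GAIT_CLASSES, ...)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Uniform(-k, k) init with k = 1/sqrt(hidden); forget-gate bias starts at 1
# so memory is open early in training. Gate column order: input, forget,
# candidate, output.
init_lstm_params <- function(spec) {
  layers <- list()
  fan_in <- spec$input_size
  for (h in spec$lstm_layers) {
    k <- 1 / sqrt(h)
    b <- rep(0, 4 * h)
    b[(h + 1):(2 * h)] <- 1
    layers[[length(layers) + 1L]] <- list(
      Wx = matrix(stats::runif(fan_in * 4 * h, -k, k), fan_in, 4 * h),
      Wh = matrix(stats::runif(h * 4 * h, -k, k), h, 4 * h),
      b = b)
    fan_in <- h
  }
  k <- 1 / sqrt(fan_in)
  list(layers = layers,
       Wf = matrix(stats::runif(fan_in * spec$n_classes, -k, k),
                   fan_in, spec$n_classes),
       bf = rep(0, spec$n_classes))
}

add_bias <- function(z, b) z + rep(b, each = nrow(z))

# One LSTM cell step. Returns new state plus the gate activations needed
# for backpropagation.
lstm_step <- function(lp, x, h_prev, c_prev) {
  H <- ncol(lp$Wh)
  h_units <- H / 4
  z <- add_bias(x %*% lp$Wx + h_prev %*% lp$Wh, lp$b)
  i <- sigmoid(z[, 1:h_units, drop = FALSE])
  f <- sigmoid(z[, (h_units + 1):(2 * h_units), drop = FALSE])
  g <- tanh(z[, (2 * h_units + 1):(3 * h_units), drop = FALSE])
  o <- sigmoid(z[, (3 * h_units + 1):(4 * h_units), drop = FALSE])
  c_new <- f * c_prev + i * g
  tc <- tanh(c_new)
  list(h = o * tc, c = c_new, i = i, f = f, g = g, o = o, tc = tc,
       c_prev = c_prev, h_prev = h_prev, x = x)
}

# Forward pass over a [B, T, F] batch. Returns per-timestep class
# probabilities and (optionally) the caches for backpropagation.
lstm_forward <- function(params, X, keep_cache = FALSE, state = NULL) {
  B <- dim(X)[1]; T_len <- dim(X)[2]
  n_layers <- length(params$layers)
  if (is.null(state)) {
    state <- lapply(params$layers, function(lp) {
      h_units <- ncol(lp$Wh) / 4
      list(h = matrix(0, B, h_units), c = matrix(0, B, h_units))
    })
  }
  caches <- if (keep_cache) {
    lapply(seq_len(n_layers), function(l) vector("list", T_len))
  }
  probs <- vector("list", T_len)
  logits <- vector("list", T_len)
  top_h <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    inp <- X[, t, , drop = FALSE]
    dim(inp) <- dim(X)[c(1, 3)]
    for (l in seq_len(n_layers)) {
      st <- lstm_step(params$layers[[l]], inp, state[[l]]$h, state[[l]]$c)
      state[[l]]$h <- st$h
      state[[l]]$c <- st$c
      if (keep_cache) caches[[l]][[t]] <- st
      inp <- st$h
    }
    top_h[[t]] <- inp
    zt <- add_bias(inp %*% params$Wf, params$bf)
    zt <- zt - apply(zt, 1, max)
    e <- exp(zt)
    logits[[t]] <- zt
    probs[[t]] <- e / rowSums(e)
  }
  list(probs = probs, top_h = top_h, caches = caches, state = state)
}

# Backpropagation through time given per-timestep output gradients
# d_logits (list of [B, M]). Returns gradients in the same structure as
# the parameters.
lstm_backward <- function(params, fwd, d_logits) {
  n_layers <- length(params$layers)
  T_len <- length(d_logits)
  grads <- list(layers = lapply(params$layers, function(lp) {
                  list(Wx = lp$Wx * 0, Wh = lp$Wh * 0, b = lp$b * 0)
                }),
                Wf = params$Wf * 0, bf = params$bf * 0)
  dh_ext <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    grads$Wf <- grads$Wf + crossprod(fwd$top_h[[t]], d_logits[[t]])
    grads$bf <- grads$bf + colSums(d_logits[[t]])
    dh_ext[[t]] <- tcrossprod(d_logits[[t]], params$Wf)
  }
  for (l in rev(seq_len(n_layers))) {
    lp <- params$layers[[l]]
    cache <- fwd$caches[[l]]
    B <- nrow(cache[[1]]$h)
    h_units <- ncol(lp$Wh) / 4
    dh_next <- matrix(0, B, h_units)
    dc_next <- matrix(0, B, h_units)
    dx_ext <- vector("list", T_len)
    gWx <- lp$Wx * 0; gWh <- lp$Wh * 0; gb <- lp$b * 0
    for (t in rev(seq_len(T_len))) {
      st <- cache[[t]]
      dh <- dh_ext[[t]] + dh_next
      do <- dh * st$tc
      dc <- dc_next + dh * st$o * (1 - st$tc^2)
      di <- dc * st$g
      df <- dc * st$c_prev
      dg <- dc * st$i
      dc_next <- dc * st$f
      dz <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  dg * (1 - st$g^2),
                  do * st$o * (1 - st$o))
      gWx <- gWx + crossprod(st$x, dz)
      gWh <- gWh + crossprod(st$h_prev, dz)
      gb <- gb + colSums(dz)
      dx_ext[[t]] <- tcrossprod(dz, lp$Wx)
      dh_next <- tcrossprod(dz, lp$Wh)
    }
    grads$layers[[l]]$Wx <- gWx
    grads$layers[[l]]$Wh <- gWh
    grads$layers[[l]]$b <- gb
    dh_ext <- dx_ext
  }
  grads
}

# Flatten/param-walk helpers so Adam state mirrors the parameter tree.
walk_params <- function(params, grads, fn) {
  for (l in seq_along(params$layers)) {
    for (nm in c("Wx", "Wh", "b")) {
      params$layers[[l]][[nm]] <-
        fn(params$layers[[l]][[nm]], grads$layers[[l]][[nm]],
           paste0("L", l, nm))
    }
  }
  params$Wf <- fn(params$Wf, grads$Wf, "Wf")
  params$bf <- fn(params$bf, grads$bf, "bf")
  params
}

make_adam <- function(lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- list(); v <- list(); t_step <- 0L
  step <- function(params, grads) {
    t_step <<- t_step + 1L
    walk_params(params, grads, function(p, g, key) {
      if (is.null(m[[key]])) {
        m[[key]] <<- p * 0
        v[[key]] <<- p * 0
      }
      m[[key]] <<- beta1 * m[[key]] + (1 - beta1) * g
      v[[key]] <<- beta2 * v[[key]] + (1 - beta2) * g^2
      mhat <- m[[key]] / (1 - beta1^t_step)
      vhat <- v[[key]] / (1 - beta2^t_step)
      p - lr * mhat / (sqrt(vhat) + eps)
    })
  }
  step
}

# Build [n_seq, seq_len, F] sequence tensors from one or more contiguous
# feature blocks; sequences never straddle block boundaries. Windows left
# over at a block end (fewer than seq_len) are dropped.
build_sequences <- function(feat_blocks, label_blocks, classes, seq_len) {
  xs <- list(); ys <- list()
  for (bi in seq_along(feat_blocks)) {
    f <- feat_blocks[[bi]]
    y <- match(label_blocks[[bi]], classes)
    if (anyNA(y)) stop("labels outside the decoder class set")
    n_seq <- nrow(f) %/% seq_len
    if (n_seq == 0) next
    for (s in seq_len(n_seq)) {
      idx <- ((s - 1) * seq_len + 1):(s * seq_len)
      xs[[length(xs) + 1L]] <- f[idx, , drop = FALSE]
      ys[[length(ys) + 1L]] <- y[idx]
    }
  }
  if (!length(xs)) stop("not enough windows for a single training sequence")
  X <- array(0, c(length(xs), seq_len, ncol(xs[[1]])))
  Y <- matrix(0L, length(xs), seq_len)
  for (s in seq_along(xs)) {
    X[s, , ] <- xs[[s]]
    Y[s, ] <- ys[[s]]
  }
  list(X = X, Y = Y)
}

# Mean weighted cross-entropy and the matching d_logits for a forward pass.
sequence_loss <- function(fwd, Y, class_weights) {
  T_len <- ncol(Y); B <- nrow(Y)
  loss <- 0; total_w <- 0
  d_logits <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    p <- fwd$probs[[t]]
    idx <- cbind(seq_len(B), Y[, t])
    w <- class_weights[Y[, t]]
    loss <- loss - sum(w * log(pmax(p[idx], 1e-12)))
    total_w <- total_w + sum(w)
    d <- p * w
    d[idx] <- d[idx] - w
    d_logits[[t]] <- d
  }
  list(loss = loss / total_w,
       d_logits = lapply(d_logits, function(d) d / total_w))
}

as_feature_matrix <- function(x) {
  if (inherits(x, "feature_sequence")) x$features else as.matrix(x)
}

#' Train an LSTM gait decoder
#'
#' Fits the network described by `spec` on per-window features and labels.
#' Features are standardized per channel with training-set statistics
#' (stored in the decoder and re-applied at prediction, so amplitude
#' changes in later data propagate to the decoder input). Training is
#' deterministic given the data and `spec$seed`. If validation data are
#' supplied, the epoch with the lowest validation loss is kept
#' (early stopping with `spec$patience`); otherwise training loss is used.
#'
#' `features` may be a single [feature_sequence()] (or matrix) or a list
#' of them; list elements are treated as separate contiguous blocks and
#' training sequences never straddle block boundaries.
#'
#' @param features Training features (windows x channels), or a list of
#'   feature blocks.
#' @param labels Per-window labels aligned with `features` (or a list of
#'   label vectors; defaults to the labels carried by the feature
#'   sequences).
#' @param spec A [network_spec()]; every class in `spec$classes` must be
#'   present in the training labels.
#' @param validation Optional list `list(features =, labels =)` used only
#'   for early stopping.
#' @param init Optional `gait_decoder` whose parameters seed the
#'   optimization (warm start); feature standardization is inherited
#'   from it so the input mapping stays fixed across the two fits.
#' @param verbose Print per-epoch losses.
#' @return A `gait_decoder` object.
#' @export
train_decoder <- function(features, labels = NULL, spec,
                          validation = NULL, init = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "network_spec"))
  feat_blocks <- if (is.list(features) && !inherits(features, "feature_sequence")) {
    lapply(features, as_feature_matrix)
  } else list(as_feature_matrix(features))
  if (is.null(labels)) {
    src <- if (is.list(features) && !inherits(features, "feature_sequence")) {
      features
    } else list(features)
    labels <- lapply(src, function(f) f$labels)
    if (any(vapply(labels, is.null, logical(1)))) {
      stop("labels must be supplied when feature sequences carry none")
    }
  }
  label_blocks <- if (is.list(labels) && !is.character(labels)) labels
                  else list(labels)
  stopifnot(length(feat_blocks) == length(label_blocks))
  all_labels <- unlist(label_blocks)
  missing_cls <- setdiff(spec$classes, unique(all_labels))
  if (length(missing_cls)) {
    stop("class(es) absent from training labels: ",
         paste(missing_cls, collapse = ", "))
  }
  if (ncol(feat_blocks[[1]]) != spec$input_size) {
    stop("feature dimensionality does not match spec$input_size")
  }

  set.seed(spec$seed)
  if (is.null(init)) {
    centre <- colMeans(do.call(rbind, feat_blocks))
    scale_ <- apply(do.call(rbind, feat_blocks), 2, stats::sd)
    scale_[scale_ == 0] <- 1
  } else {
    stopifnot(inherits(init, "gait_decoder"),
              identical(init$classes, spec$classes))
    centre <- init$feature_center
    scale_ <- init$feature_scale
  }
  std <- function(f) sweep(sweep(f, 2, centre), 2, scale_, "/")
  feat_blocks <- lapply(feat_blocks, std)

  seqs <- build_sequences(feat_blocks, label_blocks, spec$classes,
                          spec$seq_len)
  class_weights <- if (spec$class_weighting > 0) {
    freq <- tabulate(match(all_labels, spec$classes), spec$n_classes)
    w <- (sum(freq) / pmax(freq, 1))^spec$class_weighting
    w / mean(w)
  } else rep(1, spec$n_classes)

  val_seqs <- NULL
  if (!is.null(validation)) {
    vf <- std(as_feature_matrix(validation$features))
    vl <- if (!is.null(validation$labels)) validation$labels
          else validation$features$labels
    val_seqs <- build_sequences(list(vf), list(vl), spec$classes,
                                spec$seq_len)
  }

  params <- if (is.null(init)) init_lstm_params(spec) else init$params
  adam <- make_adam(spec$learning_rate)
  n_seq <- dim(seqs$X)[1]
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    monitor_loss = numeric())
  best_loss <- Inf; best_params <- params; wait <- 0L

  for (epoch in seq_len(spec$max_epochs)) {
    perm <- sample.int(n_seq)
    epoch_loss <- 0; n_batches <- 0L
    for (b0 in seq(1, n_seq, by = spec$batch_size)) {
      idx <- perm[b0:min(b0 + spec$batch_size - 1L, n_seq)]
      Xb <- seqs$X[idx, , , drop = FALSE]
      Yb <- seqs$Y[idx, , drop = FALSE]
      fwd <- lstm_forward(params, Xb, keep_cache = TRUE)
      sl <- sequence_loss(fwd, Yb, class_weights)
      grads <- lstm_backward(params, fwd, sl$d_logits)
      params <- adam(params, grads)
      epoch_loss <- epoch_loss + sl$loss
      n_batches <- n_batches + 1L
    }
    train_loss <- epoch_loss / n_batches
    monitor <- if (!is.null(val_seqs)) {
      vfwd <- lstm_forward(params, val_seqs$X)
      sequence_loss(vfwd, val_seqs$Y, class_weights)$loss
    } else train_loss
    log <- rbind(log, data.frame(epoch = epoch, train_loss = train_loss,
                                 monitor_loss = monitor))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f, monitor %.4f", epoch,
                      train_loss, monitor))
    }
    if (monitor < best_loss - 1e-9) {
      best_loss <- monitor
      best_params <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }

  structure(list(spec = spec, params = best_params, classes = spec$classes,
                 feature_center = centre, feature_scale = scale_,
                 training_log = log),
            class = "gait_decoder")
}

#' @export
print.gait_decoder <- function(x, ...) {
  cat(sprintf("<gait_decoder> %s-class LSTM [%s units], input %d\n",
              length(x$classes),
              paste(x$spec$lstm_layers, collapse = ", "),
              x$spec$input_size))
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("trained %d epochs (best monitored loss %.4f)\n",
              nrow(x$training_log), min(x$training_log$monitor_loss)))
  invisible(x)
}

#' Decode a feature sequence
#'
#' Runs the trained decoder over per-window features, emitting one
#' predicted class and one softmax posterior per window at the decision
#' rate. In stateful mode (the online emulation, default) the recurrent
#' state is carried across all consecutive windows; in stateless mode it
#' is reset every `spec$seq_len` windows, as during training. The two
#' modes agree on the first window of a sequence.
#'
#' @param object A `gait_decoder`.
#' @param features A [feature_sequence()] or matrix (windows x channels).
#' @param stateful Carry recurrent state across the whole run
#'   (default `TRUE`).
#' @param ... Unused.
#' @return List with `class` (character, per window) and `posterior`
#'   (windows x classes matrix, rows summing to 1).
#' @export
predict.gait_decoder <- function(object, features, stateful = TRUE, ...) {
  f <- as_feature_matrix(features)
  if (ncol(f) != object$spec$input_size) {
    stop("feature dimensionality does not match the decoder input size")
  }
  f <- sweep(sweep(f, 2, object$feature_center), 2, object$feature_scale, "/")
  n <- nrow(f)
  posterior <- matrix(NA_real_, n, length(object$classes),
                      dimnames = list(NULL, object$classes))
  chunk <- if (stateful) n else object$spec$seq_len
  state <- NULL
  for (s0 in seq(1, n, by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, n)
    # put windows on the time axis for a batch of one
    X <- aperm(array(f[idx, , drop = FALSE],
                     c(length(idx), 1, ncol(f))), c(2, 1, 3))
    fwd <- lstm_forward(object$params, X,
                        state = if (stateful) state else NULL)
    state <- fwd$state
    for (t in seq_along(idx)) posterior[idx[t], ] <- fwd$probs[[t]]
  }
  list(class = object$classes[max.col(posterior, ties.method = "first")],
       posterior = posterior)
}

#' Retrain a decoder on the concatenated training and validation splits
#'
#' After fusion calibration the decoders are refitted on all pre-test
#' data, maximizing the data available for learning; the retrained
#' decoders are then evaluated on the test split only. Window order is
#' preserved within each split and training sequences never straddle the
#' split boundary. With an empty validation split and no warm start this
#' reduces to [train_decoder()] on the training split alone.
#'
#' When the decoder that was used to calibrate the fusion is passed as
#' `init`, retraining continues from its weights instead of refitting
#' from scratch. This keeps the retrained network behaviorally close to
#' the calibrated one, so the validation-set confusion matrices remain a
#' faithful description of the decoder that actually decodes the test
#' stream — an independent refit can land in a different optimum whose
#' error structure the calibration no longer describes.
#'
#' @param spec A [network_spec()].
#' @param train_features,train_labels Training split features/labels.
#' @param val_features,val_labels Validation split features/labels
#'   (may be `NULL`).
#' @param init Optional `gait_decoder` to warm-start from.
#' @param verbose Print per-epoch losses.
#' @return A `gait_decoder`.
#' @export
retrain_on_train_plus_validation <- function(spec, train_features,
                                             train_labels = NULL,
                                             val_features = NULL,
                                             val_labels = NULL,
                                             init = NULL,
                                             verbose = FALSE) {
  if (is.null(val_features) ||
      nrow(as_feature_matrix(val_features)) == 0) {
    return(train_decoder(train_features, train_labels, spec,
                         init = init, verbose = verbose))
  }
  tf <- as_feature_matrix(train_features)
  vf <- as_feature_matrix(val_features)
  tl <- if (is.null(train_labels)) train_features$labels else train_labels
  vl <- if (is.null(val_labels)) val_features$labels else val_labels
  train_decoder(list(tf, vf), list(tl, vl), spec, init = init,
                verbose = verbose)
}
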