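#' Model configuration
#'
#' Assembles and validates the hyperparameter set of one architecture.
#' The tunable ranges mirror the swarm-search bounds: filters 32--256,
#' LSTM units 32--128, learning rate 1e-5--1e-2, batch size 16--64. The
#' vanilla LSTM has no convolutional stage and ignores `filters`.
#'
#' @param kind One of `"vanilla_lstm"`, `"cnn_lstm"`, `"cnn_lstm_attention"`.
#' @param filters Number of filters of the first convolutional layer (the
#'   second uses twice as many).
#' @param lstm_units Hidden units of the recurrent layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param kernel_size Convolution kernel width (same-padding).
#' @param max_epochs,patience Training budget and early-stopping patience.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param allow_outside Permit values outside the declared tuning ranges
#'   (for experiments).
#' @return An object of class `crown_config`.
#' @export
model_config <- function(kind = c("vanilla_lstm", "cnn_lstm",
                                  "cnn_lstm_attention"),
                         filters = 32L, lstm_units = 32L,
                         learning_rate = 1e-3, batch_size = 32L,
                         kernel_size = 3L, max_epochs = 200L, patience = 20L,
                         seed = 1L, allow_outside = FALSE) {
  kind <- match.arg(kind)
  cfg <- list(kind = kind, filters = as.integer(round(filters)),
              lstm_units = as.integer(round(lstm_units)),
              learning_rate = learning_rate,
              batch_size = as.integer(round(batch_size)),
              kernel_size = as.integer(kernel_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), seed = as.integer(seed))
  if (!allow_outside) {
    rng <- tuning_ranges()
    check <- function(v, nm) {
      if (v < rng[[nm]][1] || v > rng[[nm]][2]) {
        stop(sprintf("%s = %s outside the tuning range [%s, %s]",
                     nm, format(v), rng[[nm]][1], rng[[nm]][2]), call. = FALSE)
      }
    }
    if (kind != "vanilla_lstm") check(cfg$filters, "filters")
    check(cfg$lstm_units, "lstm_units")
    check(cfg$learning_rate, "learning_rate")
    check(cfg$batch_size, "batch_size")
  }
  structure(cfg, class = "crown_config")
}

#' Hyperparameter search bounds
#' @return Named list of `c(lower, upper)` bounds for the four tuned
#'   hyperparameters.
#' @export
tuning_ranges <- function() {
  list(filters = c(32, 256), lstm_units = c(32, 128),
       learning_rate = c(1e-5, 1e-2), batch_size = c(16, 64))
}

#' Build an untrained model
#'
#' Instantiates the architecture's parameters: for the convolutional
#' variants, two same-padded 1-D convolutions (the second with twice the
#' filters, ReLU activations) plus a linear residual projection of the
#' input added elementwise to the second convolution's output; a single
#' LSTM layer returning the full 10-step hidden sequence; for the
#' attention variant a learned softmax distribution over the time steps
#' that reweights the hidden sequence elementwise; and a per-step linear
#' output head.
#'
#' @param config A `crown_config`.
#' @param n_features Input feature dimension (13 or 14).
#' @return An object of class `crown_model` (untrained).
#' @export
build_model <- function(config, n_features) {
  stopifnot(inherits(config, "crown_config"))
  params <- nn_init(config$kind, n_features, config$filters,
                    config$lstm_units, config$kernel_size, config$seed)
  structure(list(params = params, config = config, n_features = n_features,
                 normalizer = NULL, history = NULL, trained = FALSE),
            class = "crown_model")
}

#' @export
print.crown_model <- function(x, ...) {
  cat(sprintf("<crown_model> %s (%s), %d input feature(s)\n", x$config$kind,
              if (x$trained) "trained" else "untrained", x$n_features))
  if (!is.null(x$history)) {
    best <- which.min(x$history$val_loss)
    cat(sprintf("  %d epoch(s); best val MSE %.6g at epoch %d\n",
                nrow(x$history), x$history$val_loss[best], best))
  }
  invisible(x)
}

#' Train a model
#'
#' Minimizes mean squared error on the normalized targets with Adam and
#' minibatch gradient descent, early-stopping on validation loss with the
#' configured patience and restoring the best-validation weights. All
#' randomness (initialization, batch shuffling) is governed by the config
#' seed. Aborts with diagnostics if the loss turns non-finite.
#'
#' @param model An untrained `crown_model` from [build_model()].
#' @param train,val Normalized `crown_sequences` partitions.
#' @param normalizer The `crown_normalizer` the partitions were scaled
#'   with; stored on the model so predictions can be mapped back to metres.
#' @param max_epochs Optional override of the configured epoch budget.
#' @return The trained `crown_model` with a `history` data.frame
#'   (`epoch, train_loss, val_loss`).
#' @export
train_model <- function(model, train, val, normalizer = NULL,
                        max_epochs = NULL) {
  stopifnot(inherits(model, "crown_model"))
  cfg <- model$config
  if (is.null(max_epochs)) max_epochs <- cfg$max_epochs
  Xtr <- x_to_list(train$x); ytr <- train$y
  Xva <- x_to_list(val$x); yva <- val$y
  n <- nrow(ytr)
  params <- model$params
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  wait <- 0L
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(max_epochs)) {
      idx <- sample(n)
      batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
      tr_loss <- 0
      for (bb in batches) {
        Xb <- lapply(Xtr, function(m) m[bb, , drop = FALSE])
        yb <- ytr[bb, , drop = FALSE]
        fw <- nn_forward(params, Xb, cfg$kind)
        loss <- mean((fw$yhat - yb)^2)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d (lr = %g)",
                       epoch, cfg$learning_rate))
        }
        tr_loss <- tr_loss + loss * length(bb)
        dY <- 2 * (fw$yhat - yb) / length(yb)
        grads <- nn_backward(params, fw$cache, dY, cfg$kind)
        st <- adam_step(params, grads, state, cfg$learning_rate)
        params <- st$params
        state <- st$state
      }
      val_loss <- nn_loss(params, Xva, yva, cfg$kind)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss / n,
                                     val_loss = val_loss))
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  model$params <- best$params
  model$history <- hist
  model$normalizer <- normalizer
  model$trained <- TRUE
  model
}

#' Predict crown profiles
#'
#' Runs the network on new sequences and returns the predicted radii in
#' metres (after reverse normalization) as an `[n, 10]` matrix. `newdata`
#' may be raw (un-normalized) sequences -- they are scaled with the
#' model's stored normalizer. With `lag_mode = "autoregressive"` the
#' previous-layer radius feature is replaced step by step with the model's
#' own (re-normalized) prediction instead of the observed value
#' (teacher forcing).
#'
#' @param object A trained `crown_model`.
#' @param newdata A `crown_sequences` object (raw scale).
#' @param lag_mode `"teacher"` (default) or `"autoregressive"`.
#' @param denormalize Return metres (default) or the normalized scale.
#' @param ... Unused.
#' @return Matrix `[n, 10]` of predicted crown radii.
#' @export
predict.crown_model <- function(object, newdata, lag_mode = c("teacher",
                                                              "autoregressive"),
                                denormalize = TRUE, ...) {
  lag_mode <- match.arg(lag_mode)
  if (!object$trained) stop("model is not trained")
  nrm <- object$normalizer
  if (is.null(nrm)) stop("model carries no normalizer")
  seqs <- transform_sequences(nrm, newdata)
  Xl <- x_to_list(seqs$x)
  if (lag_mode == "teacher") {
    yhat <- nn_forward(object$params, Xl, object$config$kind)$yhat
  } else {
    lag_idx <- match("CR_lag", seqs$feature_names)
    rng <- nrm$x_max[lag_idx] - nrm$x_min[lag_idx]
    Tn <- length(Xl)
    yhat <- NULL
    for (t in seq_len(Tn)) {
      yhat <- nn_forward(object$params, Xl, object$config$kind)$yhat
      if (t < Tn) {
        r_m <- inverse_transform_y(nrm, yhat[, t])
        Xl[[t + 1L]][, lag_idx] <-
          if (rng > 0) (r_m - nrm$x_min[lag_idx]) / rng else 0
      }
    }
  }
  if (denormalize) inverse_transform_y(nrm, yhat) else yhat
}

#' Canonical particle swarm optimizer
#'
#' Minimizes `fn` over a box with the standard velocity update
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, position clamping
#' to the bounds, and optional rounding of integer dimensions before each
#' evaluation. The best-so-far trace is monotone nonincreasing.
#'
#' @param fn Objective taking a numeric vector, returning a scalar.
#' @param lower,upper Bound vectors (equal length, lower < upper).
#' @param n_particles Swarm size.
#' @param iterations Iteration count.
#' @param inertia,cognitive,social PSO coefficients.
#' @param integer_dims Indices of dimensions rounded to integers.
#' @param seed Integer seed.
#' @return List with `par`, `value`, and `trace` (best objective after
#'   each iteration, including the initial evaluation at index 1).
#' @export
pso_optim <- function(fn, lower, upper, n_particles = 10L, iterations = 20L,
                      inertia = 0.7, cognitive = 1.5, social = 1.5,
                      integer_dims = integer(0), seed = 1L) {
  d <- length(lower)
  if (d == 0L || length(upper) != d) stop("empty or mismatched bounds")
  if (any(upper <= lower)) stop("upper must exceed lower")
  with_seed(seed, {
    clampround <- function(x) {
      x <- pmin(pmax(x, lower), upper)
      x[integer_dims] <- round(x[integer_dims])
      x
    }
    X <- t(replicate(n_particles, stats::runif(d, lower, upper)))
    if (d == 1L) X <- matrix(X, ncol = 1L)
    V <- t(replicate(n_particles, stats::runif(d, -(upper - lower),
                                               upper - lower))) * 0.1
    if (d == 1L) V <- matrix(V, ncol = 1L)
    pbest <- X
    pval <- apply(X, 1, function(x) fn(clampround(x)))
    gi <- which.min(pval)
    gbest <- X[gi, ]; gval <- pval[gi]
    trace <- gval
    for (it in seq_len(iterations)) {
      r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
      r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
      V <- inertia * V + cognitive * r1 * (pbest - X) +
        social * r2 * sweep(X, 2, gbest, function(x, g) g - x)
      X <- X + V
      X <- pmin(pmax(X, matrix(lower, n_particles, d, byrow = TRUE)),
                matrix(upper, n_particles, d, byrow = TRUE))
      val <- apply(X, 1, function(x) fn(clampround(x)))
      improved <- val < pval
      pbest[improved, ] <- X[improved, , drop = FALSE]
      pval[improved] <- val[improved]
      if (min(pval) < gval) {
        gi <- which.min(pval)
        gbest <- pbest[gi, ]; gval <- pval[gi]
      }
      trace <- c(trace, gval)
    }
    list(par = clampround(gbest), value = gval, trace = trace)
  })
}

#' Particle swarm hyperparameter search
#'
#' Tunes (filters,) LSTM units, learning rate and batch size of one
#' architecture by minimizing the validation MSE of a shortened training
#' run. Integer dimensions are rounded before each evaluation; the learning
#' rate is searched on a log scale.
#'
#' @param kind Architecture name.
#' @param train,val Normalized `crown_sequences` partitions.
#' @param ranges Bounds, as from [tuning_ranges()].
#' @param swarm_size,iterations Swarm parameters.
#' @param epochs Shortened training budget per evaluation.
#' @param seed Integer seed.
#' @return List with `config` (the best `crown_config`), `value`
#'   (its validation MSE) and `trace`.
#' @export
pso_tune <- function(kind, train, val, ranges = tuning_ranges(),
                     swarm_size = 10L, iterations = 20L, epochs = 50L,
                     seed = 1L) {
  has_conv <- kind != "vanilla_lstm"
  nms <- c(if (has_conv) "filters", "lstm_units", "learning_rate",
           "batch_size")
  lower <- vapply(ranges[nms], `[`, numeric(1), 1L)
  upper <- vapply(ranges[nms], `[`, numeric(1), 2L)
  lr_i <- match("learning_rate", nms)
  lower[lr_i] <- log10(lower[lr_i]); upper[lr_i] <- log10(upper[lr_i])
  int_dims <- which(nms != "learning_rate")
  n_features <- dim(train$x)[3]
  eval_cfg <- function(x) {
    vals <- stats::setNames(as.list(x), nms)
    vals$learning_rate <- 10^vals$learning_rate
    cfg <- model_config(kind = kind,
                        filters = if (has_conv) vals$filters else 32L,
                        lstm_units = vals$lstm_units,
                        learning_rate = vals$learning_rate,
                        batch_size = vals$batch_size,
                        max_epochs = epochs, patience = epochs,
                        seed = seed)
    m <- build_model(cfg, n_features)
    m <- train_model(m, train, val, max_epochs = epochs)
    min(m$history$val_loss)
  }
  res <- pso_optim(eval_cfg, lower, upper, n_particles = swarm_size,
                   iterations = iterations, integer_dims = int_dims,
                   seed = seed)
  vals <- stats::setNames(as.list(res$par), nms)
  vals$learning_rate <- 10^vals$learning_rate
  cfg <- model_config(kind = kind,
                      filters = if (has_conv) vals$filters else 32L,
                      lstm_units = vals$lstm_units,
                      learning_rate = vals$learning_rate,
                      batch_size = vals$batch_size, seed = seed)
  list(config = cfg, value = res$value, trace = res$trace)
}
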