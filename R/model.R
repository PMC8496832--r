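# User-facing model API: hyperparameters, construction, training, prediction.

#' Hyperparameters for the read classifier
#'
#' The network is: one-hot input (T x 4) -> \code{n_conv_blocks} 1-D
#' convolutional blocks (same-padded convolution of window \code{W}, batch
#' normalization, ReLU; \code{N_c} output channels, so the conv stage yields
#' a T x N_c matrix) -> bidirectional LSTM with \code{N_h/2} units per
#' direction concatenated to \code{N_h} (a T x N_h matrix of hidden states)
#' -> soft attention (an \code{N_a}-unit tanh layer scores each position;
#' scores are softmax-normalized over positions into the attention vector)
#' -> the read embedding, the attention-weighted sum of hidden states
#' -> dense softmax over the \code{N_y} classes.
#'
#' @param T Read length in bases (encoded length).
#' @param N_y Number of phenotype classes.
#' @param W Convolution window in bases; odd (default 9).
#' @param n_conv_blocks Number of convolutional blocks (default 2).
#' @param N_c Convolution output channels (default 256).
#' @param N_h Attention/embedding width; even (default 64).
#' @param N_a Hidden units of the attention scorer (default 16).
#' @param dropout Dropout rate applied after each conv block and on the
#'   embedding during training (default 0).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 10).
#' @param batch_size Minibatch size (default 512).
#' @param seed Integer seed driving weight initialization and shuffling.
#' @return A list of class \code{ampatt_hyperparams}.
#' @export
hyperparams <- function(T, N_y, W = 9L, n_conv_blocks = 2L, N_c = 256L,
                        N_h = 64L, N_a = 16L, dropout = 0,
                        learning_rate = 0.001, epochs = 10L,
                        batch_size = 512L, seed = 1L) {
  hp <- list(T = as.integer(T), N_y = as.integer(N_y), W = as.integer(W),
             n_conv_blocks = as.integer(n_conv_blocks), N_c = as.integer(N_c),
             N_h = as.integer(N_h), N_a = as.integer(N_a),
             dropout = as.numeric(dropout),
             learning_rate = as.numeric(learning_rate),
             epochs = as.integer(epochs), batch_size = as.integer(batch_size),
             seed = as.integer(seed))
  counts <- c(hp$T, hp$N_y, hp$W, hp$n_conv_blocks, hp$N_c, hp$N_h, hp$N_a,
              hp$epochs + 1L, hp$batch_size)
  if (any(is.na(counts)) || any(counts < 1L))
    stop("all hyperparameter counts must be positive integers")
  if (hp$W %% 2L == 0L) stop("`W` must be odd (same-padded convolution)")
  if (hp$N_h %% 2L != 0L)
    stop("`N_h` must be even (split across the two LSTM directions)")
  if (hp$N_y < 2L) stop("`N_y` must be at least 2")
  if (hp$T < hp$W) stop("read length `T` must be at least the window `W`")
  if (hp$dropout < 0 || hp$dropout >= 1) stop("`dropout` must be in [0, 1)")
  structure(hp, class = "ampatt_hyperparams")
}

#' Build an (untrained) read classifier
#'
#' Initializes all network weights (Glorot-uniform, forget-gate biases at 1)
#' from \code{hp$seed}. The returned model can already run a forward pass:
#' attention vectors and class scores are valid softmax outputs before any
#' training.
#'
#' @param hp A \code{\link{hyperparams}} object.
#' @param class_names Optional character vector of length \code{N_y}; if
#'   omitted it is fixed when \code{\link{train_model}} first sees labels.
#' @return An object of class \code{ampatt_model}.
#' @export
build_model <- function(hp, class_names = NULL) {
  stopifnot(inherits(hp, "ampatt_hyperparams"))
  if (!is.null(class_names) && length(class_names) != hp$N_y)
    stop("`class_names` must have length N_y")
  set.seed(hp$seed)
  structure(list(
    hyperparams = hp,
    params = .init_params(hp),
    bn_state = .init_bn_state(hp),
    class_names = class_names,
    training_log = data.frame(epoch = integer(), loss = numeric(),
                              accuracy = numeric())
  ), class = "ampatt_model")
}

#' @export
print.ampatt_model <- function(x, ...) {
  hp <- x$hyperparams
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf(paste0("Attention read classifier: T=%d, W=%d, %d conv block(s)",
                     " (N_c=%d), Bi-LSTM N_h=%d, N_a=%d, N_y=%d (%s params)\n"),
              hp$T, hp$W, hp$n_conv_blocks, hp$N_c, hp$N_h, hp$N_a, hp$N_y,
              format(n_par, big.mark = ",")))
  if (nrow(x$training_log)) {
    last <- x$training_log[nrow(x$training_log), ]
    cat(sprintf("trained %d epoch(s) [%s]; final loss %.4f, accuracy %.4f\n",
                nrow(x$training_log), attr(x$training_log, "loss_name"),
                last$loss, last$accuracy))
  } else cat("untrained\n")
  invisible(x)
}

.as_label_index <- function(labels, class_names) {
  idx <- match(as.character(labels), class_names)
  if (anyNA(idx))
    stop(sprintf("label '%s' not among the model's classes",
                 as.character(labels)[which(is.na(idx))[1]]))
  idx
}

#' Train the read classifier
#'
#' Runs minibatch Adam (learning rate from \code{hp}) for \code{hp$epochs}
#' passes over the reads, shuffling with the configured seed each epoch. The
#' loss is cross-entropy on the softmax scores: binary cross-entropy when
#' \code{N_y = 2}, categorical cross-entropy otherwise (for a 2-class
#' softmax the two coincide; the name is recorded in the training log).
#'
#' @param model An \code{ampatt_model} from \code{\link{build_model}}.
#' @param x Encoded reads: an \code{n x T x 4} array
#'   (\code{\link{encode_reads}}), or a bucket list from
#'   \code{\link{bucket_by_length}} for variable-length training (each epoch
#'   then visits buckets in increasing length order).
#' @param labels Character/factor vector of per-read phenotype labels
#'   (length n). Reads inherit the phenotype of their sample.
#' @param epochs Override of \code{hp$epochs} (e.g. 0 returns the model
#'   unchanged with an empty log).
#' @param verbose Print one line per epoch.
#' @return The trained model; \code{model$training_log} holds per-epoch loss
#'   and read-level training accuracy.
#' @export
train_model <- function(model, x, labels, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "ampatt_model"))
  hp <- model$hyperparams
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels must span at least 2 classes")
  if (is.null(model$class_names)) {
    model$class_names <- sort(unique(labels))
    if (length(model$class_names) != hp$N_y)
      stop(sprintf("found %d classes in labels but N_y = %d",
                   length(model$class_names), hp$N_y))
  }
  epochs <- if (is.null(epochs)) hp$epochs else as.integer(epochs)
  loss_name <- if (hp$N_y == 2L) "binary cross-entropy"
               else "categorical cross-entropy"
  buckets <- if (is.list(x) && !is.array(x)) x else
    list(list(length = hp$T, indices = seq_along(labels), encoded = x))
  for (bk in buckets) {
    if (dim(bk$encoded)[1] != length(bk$indices) ||
        dim(bk$encoded)[3] != 4L)
      stop("encoded reads must be an n x T x 4 array")
  }
  if (epochs < 1L) {
    attr(model$training_log, "loss_name") <- loss_name
    return(model)
  }
  y_all <- .as_label_index(labels, model$class_names)
  params <- model$params; bn_state <- model$bn_state
  adam <- .adam_init(params)
  set.seed(hp$seed)
  log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  for (ep in seq_len(epochs)) {
    tot_loss <- 0; tot_correct <- 0; tot_n <- 0
    for (bk in buckets) {
      n <- length(bk$indices)
      ord <- sample.int(n)
      y <- y_all[bk$indices]
      nb <- ceiling(n / hp$batch_size)
      for (b in seq_len(nb)) {
        take <- ord[((b - 1L) * hp$batch_size + 1L):min(b * hp$batch_size, n)]
        xb <- bk$encoded[take, , , drop = FALSE]
        yb <- y[take]
        fw <- .forward(params, bn_state, hp, xb, training = TRUE,
                       keep_cache = TRUE)
        bn_state <- fw$bn_state
        la <- .loss_accuracy(fw$scores, yb)
        tot_loss <- tot_loss + la["loss"] * length(take)
        tot_correct <- tot_correct + la["accuracy"] * length(take)
        tot_n <- tot_n + length(take)
        grads <- .backward(params, hp, fw$cache, yb)
        upd <- .adam_step(params, grads, adam, hp$learning_rate)
        params <- upd$params; adam <- upd$state
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = tot_loss / tot_n,
                                 accuracy = tot_correct / tot_n))
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.4f, accuracy %.4f",
                      ep, epochs, tot_loss / tot_n, tot_correct / tot_n))
  }
  attr(log, "loss_name") <- loss_name
  model$params <- params
  model$bn_state <- bn_state
  model$training_log <- log
  model
}

#' Run the classifier over encoded reads
#'
#' Deterministic forward pass (batch normalization in inference mode,
#' dropout off). Outputs are ordered as the inputs.
#'
#' @param model An \code{ampatt_model}.
#' @param x An \code{n x T x 4} encoded-read array, or a bucket list from
#'   \code{\link{bucket_by_length}}.
#' @param batch_size Prediction batch size (memory only; results are
#'   batching-invariant).
#' @param return_hidden Also return the \code{T x N_h} hidden-state matrix
#'   per read (memory-heavy; used to audit the attention-weighted sum).
#' @return A list of class \code{ampatt_prediction}: \code{scores}
#'   (n x N_y, rows sum to 1), \code{attention} (n x T for array input, or a
#'   list of per-read vectors for bucketed input; rows sum to 1),
#'   \code{embedding} (n x N_h), \code{class_names}, and optionally
#'   \code{hidden} (list of T x N_h matrices).
#' @export
predict_reads <- function(model, x, batch_size = 512L, return_hidden = FALSE) {
  stopifnot(inherits(model, "ampatt_model"))
  hp <- model$hyperparams
  if (is.list(x) && !is.array(x)) {
    n_tot <- sum(vapply(x, function(b) length(b$indices), 0L))
    scores <- matrix(NA_real_, n_tot, hp$N_y)
    emb <- matrix(NA_real_, n_tot, hp$N_h)
    attn <- vector("list", n_tot)
    hid <- if (return_hidden) vector("list", n_tot) else NULL
    for (bk in x) {
      pr <- .predict_array(model, bk$encoded, batch_size, return_hidden,
                           check_T = FALSE)
      scores[bk$indices, ] <- pr$scores
      emb[bk$indices, ] <- pr$embedding
      for (j in seq_along(bk$indices))
        attn[[bk$indices[j]]] <- pr$attention[j, ]
      if (return_hidden) hid[bk$indices] <- pr$hidden
    }
    colnames(scores) <- model$class_names
    out <- list(scores = scores, attention = attn, embedding = emb,
                class_names = model$class_names, hidden = hid)
    return(structure(out, class = "ampatt_prediction"))
  }
  .predict_array(model, x, batch_size, return_hidden, check_T = TRUE)
}

# Array-input forward pass. All network weights are shared across positions,
# so any encoded length >= W is computable; `check_T` enforces the model's
# nominal T for plain array input (bucketed mode passes FALSE).
.predict_array <- function(model, x, batch_size, return_hidden, check_T) {
  hp <- model$hyperparams
  if (length(dim(x)) != 3L || dim(x)[3] != 4L)
    stop("`x` must be an n x T x 4 array")
  if (check_T && dim(x)[2] != hp$T)
    stop(sprintf("read length %d does not match the model's T = %d",
                 dim(x)[2], hp$T))
  T_here <- dim(x)[2]
  n <- dim(x)[1]
  scores <- matrix(0, n, hp$N_y)
  attn <- matrix(0, n, T_here)
  emb <- matrix(0, n, hp$N_h)
  hid <- if (return_hidden) vector("list", n) else NULL
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fw <- .forward(model$params, model$bn_state, hp,
                   x[i:j, , , drop = FALSE], training = FALSE)
    scores[i:j, ] <- fw$scores
    attn[i:j, ] <- fw$attention
    emb[i:j, ] <- fw$embedding
    if (return_hidden) {
      B <- j - i + 1L
      for (b in seq_len(B)) {
        rows <- seq(b, by = B, length.out = T_here)
        hid[[i + b - 1L]] <- fw$hidden[rows, , drop = FALSE]
      }
    }
    i <- j + 1L
  }
  colnames(scores) <- model$class_names
  structure(list(scores = scores, attention = attn, embedding = emb,
                 class_names = model$class_names, hidden = hid),
            class = "ampatt_prediction")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: hyperparameters, class names, weights,
#' batch-norm statistics and the training log.
#'
#' @param model An \code{ampatt_model}.
#' @param path Checkpoint file path (RDS).
#' @return \code{load_model} returns the restored \code{ampatt_model}.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ampatt_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  need <- c("hyperparams", "params", "bn_state", "class_names", "training_log")
  if (!all(need %in% names(obj))) stop("not an ampatt model checkpoint")
  class(obj$hyperparams) <- "ampatt_hyperparams"
  structure(obj, class = "ampatt_model")
}
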