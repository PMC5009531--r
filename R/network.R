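# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Network configuration
#'
#' Hyperparameters of the single-hidden-layer feed-forward classifier:
#' sigmoidal hidden units, softmax output, cross-entropy loss minimized by
#' mini-batch gradient descent with momentum, and early stopping on
#' validation loss. The architecture (510 inputs, 250 hidden nodes, one
#' output per flexibility state) is the method's reference setting; the
#' optimizer defaults are this implementation's and are recorded on the
#' fitted object.
#'
#' @param n_in Input width (default 510 = 15 x 34).
#' @param n_hidden Hidden-layer size (default 250).
#' @param states Output states, in order (default `c("R", "I", "F")`; use
#'   `c("rigid", "flexible")` for two-state prediction).
#' @param seed Integer seed; training is fully reproducible given the seed.
#' @param learning_rate,momentum,batch_size,epochs,patience Optimizer
#'   settings: step size (0.01), momentum coefficient (0.9), mini-batch
#'   size (128), epoch cap (200), and epochs without validation improvement
#'   tolerated before stopping (10).
#' @return A list of class `flex_net_config`.
#' @export
flex_net_config <- function(n_in = 510L, n_hidden = 250L,
                            states = FLEX_STATES, seed = 1L,
                            learning_rate = 0.01, momentum = 0.9,
                            batch_size = 128L, epochs = 200L,
                            patience = 10L) {
  if (n_hidden < 1L) abort("n_hidden must be positive")
  if (!length(states) %in% c(2L, 3L)) abort("states must have 2 or 3 levels")
  structure(list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
                 n_out = length(states), states = states,
                 seed = as.integer(seed), learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience)),
            class = "flex_net_config")
}

.xent <- function(p, t) -mean(rowSums(t * log(pmax(p, 1e-12))))

#' Train the feed-forward flexibility classifier
#'
#' Fits one hidden layer of sigmoidal units with a softmax output by
#' mini-batch gradient descent with momentum on the cross-entropy loss.
#' After every epoch the validation loss is evaluated; training stops at
#' the epoch cap or once the validation loss has failed to improve for
#' `patience` consecutive epochs, and the parameters achieving the best
#' validation loss are returned. Fully reproducible given `config$seed`.
#'
#' @param x Numeric training matrix (rows = residues, `config$n_in`
#'   columns).
#' @param y Character vector of training states (values in
#'   `config$states`).
#' @param x_val,y_val Validation set in the same layout.
#' @param config A [flex_net_config()].
#' @return An object of class `flex_net` with the fitted weights, the
#'   config, and a per-epoch `history` tibble (`epoch`, `train_loss`,
#'   `val_loss`, `val_accuracy`).
#' @export
train_network <- function(x, y, x_val, y_val, config = flex_net_config()) {
  stopifnot(inherits(config, "flex_net_config"))
  if (nrow(x) == 0L) abort("empty training set")
  if (ncol(x) != config$n_in) {
    abort(sprintf("input width %d does not match configured n_in %d",
                  ncol(x), config$n_in))
  }
  if (length(y) != nrow(x)) abort("x and y sizes differ")
  si <- match(y, config$states)
  sv <- match(y_val, config$states)
  if (anyNA(si) || anyNA(sv)) abort("labels outside the configured states")
  n <- nrow(x); K <- config$n_out; H <- config$n_hidden
  T1 <- matrix(0, n, K); T1[cbind(seq_len(n), si)] <- 1
  Tv <- matrix(0, nrow(x_val), K); Tv[cbind(seq_along(sv), sv)] <- 1

  .with_seed(config$seed, {
    a1 <- 1 / sqrt(config$n_in)
    a2 <- 1 / sqrt(H)
    W1 <- matrix(runif(config$n_in * H, -a1, a1), config$n_in, H)
    b1 <- rep(0, H)
    W2 <- matrix(runif(H * K, -a2, a2), H, K)
    b2 <- rep(0, K)
    vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- b2
    lr <- config$learning_rate; mom <- config$momentum
    best <- list(loss = Inf)
    wait <- 0L
    hist <- vector("list", config$epochs)
    n_epochs <- 0L

    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      tl <- 0
      for (s0 in starts) {
        rows <- perm[s0:min(s0 + config$batch_size - 1L, n)]
        xb <- x[rows, , drop = FALSE]
        tb <- T1[rows, , drop = FALSE]
        nb <- length(rows)
        hpre <- sweep(xb %*% W1, 2, b1, "+")
        h <- .sigmoid(hpre)
        p <- .softmax_rows(sweep(h %*% W2, 2, b2, "+"))
        tl <- tl + .xent(p, tb) * nb
        d2 <- (p - tb) / nb
        gW2 <- crossprod(h, d2)
        gb2 <- colSums(d2)
        dh <- tcrossprod(d2, W2) * h * (1 - h)
        gW1 <- crossprod(xb, dh)
        gb1 <- colSums(dh)
        vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
        vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
        vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
        vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
      }
      pv <- .softmax_rows(sweep(
        .sigmoid(sweep(x_val %*% W1, 2, b1, "+")) %*% W2, 2, b2, "+"))
      vl <- .xent(pv, Tv)
      vacc <- mean(max.col(pv, ties.method = "first") == sv)
      hist[[ep]] <- tibble(epoch = ep, train_loss = tl / n,
                           val_loss = vl, val_accuracy = vacc)
      n_epochs <- ep
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                     epoch = ep, val_accuracy = vacc)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(
      W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
      config = config,
      best_epoch = best$epoch,
      best_val_loss = best$loss,
      best_val_accuracy = best$val_accuracy,
      n_epochs = n_epochs,
      history = dplyr::bind_rows(hist[seq_len(n_epochs)])
    ), class = "flex_net")
  })
}

#' @export
print.flex_net <- function(x, ...) {
  cat(sprintf(
    "<flex_net> %d-%d-%d, trained %d epochs (best %d, val loss %.4f, val acc %.3f)\n",
    x$config$n_in, x$config$n_hidden, x$config$n_out,
    x$n_epochs, x$best_epoch, x$best_val_loss, x$best_val_accuracy))
  invisible(x)
}

#' Predict flexibility states
#'
#' Applies the trained network to an input matrix (or a `flex_encoding`)
#' and returns per-residue state probabilities (summing to 1) and the
#' argmax state, ties broken toward the earlier state in the configured
#' order.
#'
#' @param object A `flex_net`.
#' @param newdata Numeric matrix with `n_in` columns, or a `flex_encoding`.
#' @param ... Unused.
#' @return Tibble with one probability column per state (`p_R`, `p_I`,
#'   `p_F` in three-state mode) and a `state` column. When `newdata` is an
#'   encoding its `chain_id`/`position` metadata is prepended.
#' @export
predict.flex_net <- function(object, newdata, ...) {
  meta <- NULL
  if (inherits(newdata, "flex_encoding")) {
    meta <- newdata$meta
    newdata <- newdata$x
  }
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$config$n_in) {
    abort(sprintf("input width %d does not match network n_in %d",
                  ncol(newdata), object$config$n_in))
  }
  p <- .softmax_rows(sweep(
    .sigmoid(sweep(newdata %*% object$W1, 2, object$b1, "+")) %*% object$W2,
    2, object$b2, "+"))
  out <- tibble::as_tibble(setNames(
    as.data.frame(p), paste0("p_", object$config$states)))
  out$state <- object$config$states[max.col(p, ties.method = "first")]
  if (!is.null(meta)) out <- dplyr::bind_cols(meta, out)
  out
}

#' @rdname flex_tidiers
#' @export
tidy.flex_net <- function(x, ...) {
  tibble(
    layer = c("hidden", "output"),
    n_parameters = c(length(x$W1) + length(x$b1),
                     length(x$W2) + length(x$b2)),
    weight_mean = c(mean(x$W1), mean(x$W2)),
    weight_sd = c(sd(as.vector(x$W1)), sd(as.vector(x$W2)))
  )
}

#' @rdname flex_tidiers
#' @export
glance.flex_net <- function(x, ...) {
  tibble(n_in = x$config$n_in, n_hidden = x$config$n_hidden,
         n_out = x$config$n_out, n_epochs = x$n_epochs,
         best_epoch = x$best_epoch, best_val_loss = x$best_val_loss,
         best_val_accuracy = x$best_val_accuracy)
}

#' @rdname flex_autoplot
#' @export
autoplot.flex_net <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save and load a model checkpoint
#'
#' The checkpoint is a single JSON document holding the configuration and
#' the parameter matrices.
#'
#' @param net A `flex_net`.
#' @param path Checkpoint path.
#' @return Invisibly, `path` (writer); a `flex_net` (reader).
#' @export
write_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "flex_net"))
  doc <- list(
    format = "flexseq_checkpoint", version = 1L,
    config = unclass(net$config),
    W1 = as.vector(net$W1), b1 = net$b1,
    W2 = as.vector(net$W2), b2 = net$b2,
    best_epoch = net$best_epoch, best_val_loss = net$best_val_loss,
    best_val_accuracy = net$best_val_accuracy, n_epochs = net$n_epochs
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "flexseq_checkpoint") {
    abort("not a flexseq model checkpoint")
  }
  cfg <- doc$config
  config <- flex_net_config(
    n_in = cfg$n_in, n_hidden = cfg$n_hidden, states = cfg$states,
    seed = cfg$seed, learning_rate = cfg$learning_rate,
    momentum = cfg$momentum, batch_size = cfg$batch_size,
    epochs = cfg$epochs, patience = cfg$patience)
  structure(list(
    W1 = matrix(doc$W1, cfg$n_in, cfg$n_hidden),
    b1 = doc$b1,
    W2 = matrix(doc$W2, cfg$n_hidden, length(cfg$states)),
    b2 = doc$b2,
    config = config,
    best_epoch = doc$best_epoch, best_val_loss = doc$best_val_loss,
    best_val_accuracy = doc$best_val_accuracy, n_epochs = doc$n_epochs,
    history = tibble()
  ), class = "flex_net")
}
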