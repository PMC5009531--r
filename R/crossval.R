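#' Chain-level fold assignment
#'
#' Assigns whole chains (never individual residues) to `n_folds` folds by
#' a seeded shuffle followed by round-robin allocation, so fold sizes
#' differ by at most one chain and the same seed always yields the same
#' plan.
#'
#' @param chain_ids Character vector of distinct chain identifiers.
#' @param n_folds Number of folds (default 7).
#' @param seed Integer seed.
#' @return Tibble with `chain_id` and `fold`.
#' @export
cv_plan <- function(chain_ids, n_folds = 7L, seed = 1L) {
  chain_ids <- unique(chain_ids)
  if (length(chain_ids) < n_folds) {
    abort(sprintf("need at least %d chains for %d folds, got %d",
                  n_folds, n_folds, length(chain_ids)))
  }
  .with_seed(seed, {
    shuffled <- sample(chain_ids)
    tibble(chain_id = shuffled,
           fold = rep_len(seq_len(n_folds), length(shuffled))) |>
      dplyr::arrange(.data$chain_id)
  })
}

#' Seven-fold cross-validation of the flexibility classifier
#'
#' Chains are partitioned into `n_folds` subsets. In rotation `j`, subset
#' `j` is the validation set (used for early stopping), subset
#' `j %% n_folds + 1` is the test set, and the remaining subsets train the
#' network. Per-fold test metrics and their unweighted mean are reported.
#' Within a fold the three roles are disjoint at chain level, so residues
#' of one chain never leak across them.
#'
#' @param encoding A labeled `flex_encoding` from [encode_corpus()].
#' @param config A [flex_net_config()]; its `seed` is combined with `seed`
#'   per fold so fold networks differ reproducibly.
#' @param n_folds Number of folds (default 7).
#' @param seed Seed for the fold assignment.
#' @param keep_predictions Keep per-residue test predictions (default
#'   FALSE).
#' @return An object of class `flex_cv`: `folds` (per-fold metric tibble),
#'   `mean` (named means over folds), `plan`, `config`, and optionally
#'   `predictions`.
#' @export
cross_validate <- function(encoding, config = flex_net_config(),
                           n_folds = 7L, seed = 1L,
                           keep_predictions = FALSE) {
  stopifnot(inherits(encoding, "flex_encoding"))
  if (anyNA(encoding$label)) abort("encoding must be fully labeled")
  plan <- cv_plan(unique(encoding$meta$chain_id), n_folds, seed)
  fold_of <- plan$fold[match(encoding$meta$chain_id, plan$chain_id)]
  states <- config$states

  fold_rows <- vector("list", n_folds)
  preds <- vector("list", n_folds)
  for (j in seq_len(n_folds)) {
    val_f <- j
    test_f <- j %% n_folds + 1L
    idx_val <- fold_of == val_f
    idx_test <- fold_of == test_f
    idx_train <- !(idx_val | idx_test)
    cfg <- config
    cfg$seed <- config$seed + j
    net <- train_network(encoding$x[idx_train, , drop = FALSE],
                         encoding$label[idx_train],
                         encoding$x[idx_val, , drop = FALSE],
                         encoding$label[idx_val],
                         cfg)
    pr <- predict(net, encoding$x[idx_test, , drop = FALSE])
    ev <- evaluate_states(encoding$label[idx_test], pr$state)
    g <- glance(ev)
    fold_rows[[j]] <- dplyr::bind_cols(
      tibble(fold = j,
             n_chains_test = sum(plan$fold == test_f),
             n_residues_test = sum(idx_test),
             best_epoch = net$best_epoch),
      g[, c(paste0("q_", states), "q3")]
    )
    if (keep_predictions) {
      preds[[j]] <- dplyr::bind_cols(
        tibble(fold = j),
        encoding$meta[idx_test, ],
        tibble(observed = encoding$label[idx_test]),
        pr)
    }
  }
  folds <- dplyr::bind_rows(fold_rows)
  metric_cols <- c(paste0("q_", states), "q3")
  mean_row <- colMeans(folds[, metric_cols], na.rm = TRUE)
  structure(list(
    folds = folds,
    mean = mean_row,
    plan = plan,
    config = config,
    n_folds = n_folds,
    predictions = if (keep_predictions) dplyr::bind_rows(preds) else NULL
  ), class = "flex_cv")
}

#' @export
print.flex_cv <- function(x, ...) {
  cat(sprintf("<flex_cv> %d folds, %d chains\n",
              x$n_folds, nrow(x$plan)))
  print(x$folds)
  cat("  mean:", paste(names(x$mean), sprintf("%.3f", x$mean),
                       sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @rdname flex_tidiers
#' @export
tidy.flex_cv <- function(x, ...) x$folds

#' @rdname flex_tidiers
#' @export
glance.flex_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_folds = x$n_folds, n_chains = nrow(x$plan)),
    tibble::as_tibble(as.list(setNames(
      x$mean, paste0(names(x$mean), "_mean"))))
  )
}

#' @rdname flex_autoplot
#' @export
autoplot.flex_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(factor(.data$fold), .data$q3)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = unname(object$mean["q3"]),
                        linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "test Q3") +
    ggplot2::theme_minimal()
}
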