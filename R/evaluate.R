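#' Accuracy / coverage / F-measure for two-state prediction
#'
#' With the flexible class positive: accuracy `A = TP / (TP + FP)`,
#' coverage `C = TP / (TP + FN)`, and the harmonic mean
#' `F = 2AC / (A + C)`; `F` is reported as 0 when `A = C = 0`.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return One-row tibble with columns `A`, `C`, `F`.
#' @examples
#' f_measure(30, 10, 20)   # A 0.75, C 0.6, F 2/3
#' @export
f_measure <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort("counts must be non-negative")
  if (tp + fp == 0 && tp + fn == 0) {
    abort("undefined metric: no predicted and no observed positives")
  }
  if (tp + fp == 0 || tp + fn == 0) {
    abort("undefined metric: a denominator (TP+FP or TP+FN) is zero")
  }
  A <- tp / (tp + fp)
  C <- tp / (tp + fn)
  Fm <- if (A == 0 && C == 0) 0 else 2 * A * C / (A + C)
  tibble(A = A, C = C, F = Fm)
}

#' Evaluate predicted flexibility states
#'
#' Builds the confusion matrix of observed vs predicted states and the
#' per-state prediction rates `Q_s` (fraction of residues observed in
#' state `s` that are predicted correctly -- recall) together with the
#' overall rate `Q3` (total correct / total). In two-state mode
#' (`rigid` / `flexible` labels) the accuracy, coverage and F-measure of
#' the flexible class are computed as well.
#'
#' @param observed,predicted Equal-length character vectors of states;
#'   either both in `{R, I, F}` or both in `{rigid, flexible}`.
#' @return An object of class `flex_eval`: `confusion` (observed in rows,
#'   predicted in columns), `q_per_state` (named; `NA` when a state has no
#'   observed residues), `q3`, `n`, and -- in two-state mode -- `two_state`
#'   (tibble `TP`, `TN`, `FP`, `FN`, `A`, `C`, `F`).
#' @examples
#' evaluate_states(c("R", "R", "I", "F"), c("R", "I", "I", "F"))
#' @export
evaluate_states <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("observed and predicted must have equal length")
  }
  vals <- unique(c(observed, predicted))
  states <- if (all(vals %in% FLEX_STATES)) {
    FLEX_STATES
  } else if (all(vals %in% c("rigid", "flexible"))) {
    c("rigid", "flexible")
  } else {
    abort("states must all be in {R, I, F} or all in {rigid, flexible}")
  }
  conf <- table(factor(observed, levels = states),
                factor(predicted, levels = states))
  conf <- unclass(conf)
  names(dimnames(conf)) <- c("observed", "predicted")
  n <- sum(conf)
  obs_tot <- rowSums(conf)
  q <- ifelse(obs_tot > 0, diag(conf) / obs_tot, NA_real_)
  names(q) <- states
  out <- list(confusion = conf, q_per_state = q,
              q3 = sum(diag(conf)) / n, n = n, states = states)
  if (length(states) == 2L) {
    tp <- conf["flexible", "flexible"]
    tn <- conf["rigid", "rigid"]
    fp <- conf["rigid", "flexible"]
    fn <- conf["flexible", "rigid"]
    acf <- f_measure(tp, fp, fn)
    out$two_state <- dplyr::bind_cols(
      tibble(TP = tp, TN = tn, FP = fp, FN = fn), acf)
  }
  structure(out, class = "flex_eval")
}

#' @export
print.flex_eval <- function(x, ...) {
  cat("<flex_eval>", x$n, "residues\n")
  print(x$confusion)
  qs <- paste(sprintf("Q_%s=%.1f%%", names(x$q_per_state),
                      100 * x$q_per_state), collapse = "  ")
  cat(" ", qs, sprintf(" Q_total=%.1f%%\n", 100 * x$q3))
  if (!is.null(x$two_state)) {
    cat(sprintf("  flexible class: A=%.1f%% C=%.1f%% F=%.1f%%\n",
                100 * x$two_state$A, 100 * x$two_state$C,
                100 * x$two_state$F))
  }
  invisible(x)
}

#' Tidiers for flexseq result objects
#'
#' Broom-style `tidy()` and `glance()` methods: `tidy()` returns one row
#' per component (metric, fold, or layer), `glance()` a one-row summary.
#'
#' @param x A fitted/evaluated flexseq object.
#' @param ... Unused.
#' @name flex_tidiers
NULL

#' @rdname flex_tidiers
#' @export
tidy.flex_eval <- function(x, ...) {
  out <- tibble(
    metric = c(paste0("q_", names(x$q_per_state)), "q3"),
    value = c(unname(x$q_per_state), x$q3)
  )
  if (!is.null(x$two_state)) {
    out <- dplyr::bind_rows(out, tibble(
      metric = c("A", "C", "F"),
      value = c(x$two_state$A, x$two_state$C, x$two_state$F)))
  }
  out
}

#' @rdname flex_tidiers
#' @export
glance.flex_eval <- function(x, ...) {
  base <- tibble::as_tibble(as.list(setNames(
    x$q_per_state, paste0("q_", names(x$q_per_state)))))
  base$q3 <- x$q3
  base$n <- x$n
  if (!is.null(x$two_state)) base <- dplyr::bind_cols(base, x$two_state)
  base
}

#' Plots for flexseq result objects
#'
#' `autoplot()` methods: confusion heatmap for `flex_eval`, training curve
#' for `flex_net`, per-fold accuracy bars for `flex_cv`.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name flex_autoplot
NULL

#' @rdname flex_autoplot
#' @export
autoplot.flex_eval <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object$confusion,
                                        responseName = "count"))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$observed,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted state", y = "observed state") +
    ggplot2::theme_minimal()
}
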