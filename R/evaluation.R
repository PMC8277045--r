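#' Three-class confusion matrix
#'
#' Rows are the true class, columns the predicted class, in the fixed
#' order fetal / laugh / respiratory.
#'
#' @param true_labels,pred_labels Equal-length vectors of labels drawn from
#'   the three classes.
#' @return A `fetmov_confusion`: 3 x 3 integer matrix with class
#'   dimnames.
#' @export
#' @examples
#' confusion_matrix3(c("fetal", "laugh"), c("fetal", "fetal"))
confusion_matrix3 <- function(true_labels, pred_labels) {
  cls <- fm_classes()
  tl <- as.character(true_labels)
  pl <- as.character(pred_labels)
  if (length(tl) != length(pl)) abort("label vectors must have equal length")
  if (length(tl) && (!all(tl %in% cls) || !all(pl %in% cls))) {
    abort("labels outside the three-class set")
  }
  cm <- table(factor(tl, levels = cls), factor(pl, levels = cls))
  m <- matrix(as.integer(cm), 3, 3, dimnames = list(true = cls, pred = cls))
  structure(m, class = c("fetmov_confusion", "matrix", "array"))
}

#' Per-class detection rates from a confusion matrix
#'
#' One-vs-rest rates per class `c`: the true positive rate is
#' `cm[c, c] / rowsum(c)` (recall), and the false positive rate is the
#' share of all *other*-class realizations predicted as `c`,
#' `(colsum(c) - cm[c, c]) / (total - rowsum(c))`. The one-vs-rest FPR is
#' the reading under which a three-class detector's false-alarm burden is
#' meaningful; classes with an empty denominator get `NA` with
#' `defined = FALSE` rather than propagating NaN.
#'
#' @param cm A `fetmov_confusion` (or any 3 x 3 count matrix).
#' @return Tibble: `class`, `support`, `tpr`, `fpr`, `defined`.
#' @export
#' @examples
#' cm <- confusion_matrix3(rep(c("fetal", "laugh", "respiratory"), 10),
#'                         rep(c("fetal", "laugh", "respiratory"), 10))
#' per_class_rates(cm)
per_class_rates <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)) || any(m < 0)) {
    abort("cm must be a 3 x 3 non-negative count matrix")
  }
  cls <- fm_classes()
  total <- sum(m)
  rows <- rowSums(m)
  cols <- colSums(m)
  tpr <- ifelse(rows > 0, diag(m) / rows, NA_real_)
  neg <- total - rows
  fpr <- ifelse(neg > 0, (cols - diag(m)) / neg, NA_real_)
  tibble(
    class = cls, support = as.integer(rows),
    tpr = as.numeric(tpr), fpr = as.numeric(fpr),
    defined = rows > 0 & neg > 0
  )
}

#' Agreement between detection methods
#'
#' During validation, three methods flag fetal movements: the abdominal
#' ultrasound (the ground truth), the device, and the mother's button
#' press. This tallies, over the ground-truth events, which combination of
#' the other two methods also caught each event. Device and mother events
#' are matched one-to-one to truth events greedily (closest first) within
#' `match_tol_s`; percentages are shares of the truth events, rounded
#' half-up to 2 decimals.
#'
#' @param truth_times Sorted numeric event times (seconds) of the
#'   ground-truth (ultrasound) events; must be non-empty.
#' @param device_times,mother_times Sorted numeric event times of the two
#'   compared methods.
#' @param match_tol_s Matching tolerance in seconds (default 5).
#' @return Tibble with `ultrasound`, `device`, `mother` 0/1 pattern flags,
#'   `n` counts, and `percent`.
#' @export
agreement_table <- function(truth_times, device_times, mother_times,
                            match_tol_s = 5) {
  if (!length(truth_times)) abort("the ground-truth event list is empty")
  assert_scalar_num(match_tol_s, "match_tol_s", lo = 1e-12)
  dev <- match_events(truth_times, device_times, match_tol_s)
  mom <- match_events(truth_times, mother_times, match_tol_s)
  pat <- tibble(
    ultrasound = 1L, device = as.integer(dev), mother = as.integer(mom)
  ) |>
    dplyr::count(.data$ultrasound, .data$device, .data$mother, name = "n") |>
    dplyr::mutate(percent = round_half_up(100 * .data$n / length(truth_times), 2)) |>
    dplyr::arrange(.data$device, .data$mother)
  pat
}

# Greedy one-to-one matching: each candidate event may claim at most one
# truth event; pairs are claimed in order of increasing time difference.
# Returns a logical over truth events (matched or not).
match_events <- function(truth_times, cand_times, tol) {
  matched <- rep(FALSE, length(truth_times))
  if (!length(cand_times)) return(matched)
  pairs <- expand.grid(ti = seq_along(truth_times),
                       ci = seq_along(cand_times))
  pairs$d <- abs(truth_times[pairs$ti] - cand_times[pairs$ci])
  pairs <- pairs[pairs$d <= tol, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  used_c <- rep(FALSE, length(cand_times))
  for (r in seq_len(nrow(pairs))) {
    ti <- pairs$ti[r]; ci <- pairs$ci[r]
    if (!matched[ti] && !used_c[ci]) {
      matched[ti] <- TRUE
      used_c[ci] <- TRUE
    }
  }
  matched
}

#' Class occurrences by gestational-age band
#'
#' Tabulates realization counts per class within the three gestational-age
#' bands used in the clinical tabulation (27-31, 32-35, 36-40+ weeks),
#' with a totals row.
#'
#' @param labels Vector of class labels, one per realization.
#' @param gestational_age Numeric vector of weeks, one per realization;
#'   all values must lie in `[26, 42]`.
#' @return Tibble: `age_band`, one column per class, rows for each band
#'   plus `"total"`.
#' @export
class_count_table <- function(labels, gestational_age) {
  if (length(labels) != length(gestational_age)) {
    abort("labels and gestational_age must have equal length")
  }
  if (length(gestational_age) &&
      (any(is.na(gestational_age)) ||
       any(gestational_age < 26 | gestational_age > 42))) {
    abort("gestational ages must lie in [26, 42] weeks")
  }
  cls <- fm_classes()
  lab <- factor(as.character(labels), levels = cls)
  if (anyNA(lab) && length(labels)) abort("labels outside the three-class set")
  band <- cut(gestational_age, breaks = c(26, 31.5, 35.5, 42),
              labels = c("27-31", "32-35", "36-40+"),
              include.lowest = TRUE, right = TRUE)
  tab <- table(band, lab)
  out <- tibble(age_band = rownames(tab))
  for (k in seq_along(cls)) out[[cls[k]]] <- as.integer(tab[, k])
  totals <- tibble(age_band = "total")
  for (k in seq_along(cls)) totals[[cls[k]]] <- sum(out[[cls[k]]])
  dplyr::bind_rows(out, totals)
}

#' Tidy and summarise evaluation reports
#'
#' `tidy()` on a `fetmov_eval` returns the per-class rate table;
#' `glance()` returns a one-row summary (accuracy plus the class-1 rates
#' the application cares most about). The same generics are provided for
#' `fetmov_nnmf` objects (objective trajectory / fit summary).
#'
#' @param x A `fetmov_eval` or `fetmov_nnmf` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.fetmov_eval
NULL

#' @rdname tidy.fetmov_eval
#' @method tidy fetmov_eval
#' @export
tidy.fetmov_eval <- function(x, ...) {
  dplyr::mutate(x$rates, algorithm = x$algorithm, .before = 1)
}

#' @rdname tidy.fetmov_eval
#' @name glance.fetmov_eval
NULL

#' @rdname tidy.fetmov_eval
#' @method glance fetmov_eval
#' @export
glance.fetmov_eval <- function(x, ...) {
  m <- unclass(x$cm)
  tibble(
    algorithm = x$algorithm,
    n_test = sum(m),
    accuracy = sum(diag(m)) / max(1, sum(m)),
    tpr_fetal = x$rates$tpr[1],
    fpr_fetal = x$rates$fpr[1]
  )
}

#' @export
print.fetmov_eval <- function(x, ...) {
  cat(sprintf("<fetmov_eval> algorithm %s (%d test realizations)\n",
              x$algorithm, sum(unclass(x$cm))))
  print(unclass(x$cm))
  print(x$rates)
  invisible(x)
}

#' Plot a confusion matrix
#'
#' @param object A `fetmov_confusion` or `fetmov_eval`.
#' @param ... Unused.
#' @return A ggplot heat map with counts annotated.
#' @method autoplot fetmov_confusion
#' @export
autoplot.fetmov_confusion <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(true = rownames(m), pred = colnames(m)) |>
    dplyr::mutate(n = as.vector(t(m)))
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$true, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' @method autoplot fetmov_eval
#' @export
autoplot.fetmov_eval <- function(object, ...) {
  autoplot(object$cm, ...) + ggplot2::ggtitle(object$algorithm)
}
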