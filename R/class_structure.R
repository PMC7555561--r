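# Partial-order (hierarchy) analysis among latent classes from a fitted
# table of correct-response probabilities, with an approximate-order
# tolerance iota.

#' Correct-response probability table of a fit
#'
#' Builds the `I x C` matrix of correct-response probabilities used by the
#' partial-order analysis. For dichotomous items (K = 1) the correct
#' response is category 1; for polytomous multiple-choice scorings the
#' correct response is the reference category 0.
#'
#' @param fit an `rlca_fit`, or a list of per-item `(K+1) x C` probability
#'   tables.
#' @param items optional item labels.
#' @param correct_category optional fixed category; by default chosen
#'   per item by the convention above.
#' @return `I x C` numeric matrix with item rownames.
#' @export
correct_response_probs <- function(fit, items = NULL, correct_category = NULL) {
  tabs <- if (inherits(fit, "rlca_fit")) fit$item_probs else fit
  if (is.null(items))
    items <- if (inherits(fit, "rlca_fit")) fit$items else paste0("item", seq_along(tabs))
  P <- t(vapply(tabs, function(tab) {
    k <- if (is.null(correct_category)) {
      if (nrow(tab) == 2L) 1L else 0L
    } else correct_category
    tab[k + 1L, ]
  }, numeric(ncol(tabs[[1]]))))
  rownames(P) <- items
  P
}

#' Partial order of latent classes
#'
#' Class `c` is smaller than class `d` when its correct-response
#' probability is no larger on every item; with tolerance `iota`, `c` is
#' approximately smaller than `d` when `p_ic <= p_id` holds for at least
#' `I - iota` items. Exact ties never count as violations in either
#' direction (so exactly tied classes are mutually comparable).
#'
#' @param prob_table `I x C` matrix of correct-response probabilities
#'   (items in rows, classes in columns).
#' @param iota integer tolerance, number of violating items allowed.
#' @return object of class `rlca_partial_order` with fields `violations`
#'   (`C x C` counts of items with `p_ic > p_id`), `relation` (`C x C`
#'   logical, `c` below `d` at tolerance `iota`), `violating_items`
#'   (nested list of item labels per ordered pair), `iota`, `I`, `labels`.
#' @export
partial_order <- function(prob_table, iota = 0L) {
  P <- as.matrix(prob_table)
  if (any(P < 0) || any(P > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (iota < 0) stop("`iota` must be >= 0", call. = FALSE)
  I <- nrow(P); C <- ncol(P)
  if (iota >= I)
    warning("iota >= number of items: the approximate order is trivial")
  labels <- colnames(P)
  if (is.null(labels)) labels <- paste0("C", seq_len(C))
  if (is.null(rownames(P))) rownames(P) <- paste0("item", seq_len(I))
  viol <- matrix(0L, C, C, dimnames = list(labels, labels))
  vit <- lapply(seq_len(C), function(c) vector("list", C))
  for (c in seq_len(C)) for (d in seq_len(C)) {
    if (c == d) next
    w <- which(P[, c] > P[, d])
    viol[c, d] <- length(w)
    vit[[c]][[d]] <- rownames(P)[w]
  }
  structure(list(violations = viol, relation = viol <= iota,
                 violating_items = vit, iota = as.integer(iota),
                 I = I, labels = labels),
            class = "rlca_partial_order")
}

#' @export
print.rlca_partial_order <- function(x, ...) {
  cat("Partial order of ", length(x$labels), " classes (iota = ", x$iota,
      ", ", x$I, " items)\n", sep = "")
  cat("violation counts (row above column):\n")
  print(x$violations)
  invisible(x)
}

#' Per-class mean correct-response probability
#'
#' Averages each class's correct-response probabilities over items,
#' `pbar_c = (sum_i p_ic) / I`, and ranks classes from weakest to
#' strongest.
#'
#' @param prob_table `I x C` matrix of correct-response probabilities.
#' @param class_probs optional class probabilities to attach.
#' @return data frame with columns `class`, `mean_prob`, `rank` (1 =
#'   lowest mean), and optionally `class_prob`.
#' @export
class_summary <- function(prob_table, class_probs = NULL) {
  P <- as.matrix(prob_table)
  m <- colMeans(P)
  labels <- colnames(P)
  if (is.null(labels)) labels <- paste0("C", seq_len(ncol(P)))
  out <- data.frame(class = labels, mean_prob = as.numeric(m),
                    rank = rank(m, ties.method = "min"))
  if (!is.null(class_probs)) out$class_prob <- as.numeric(class_probs)
  out
}

#' Edge list of the class hierarchy
#'
#' Strict comparabilities (`c` below `d` but not conversely) are reduced to
#' their transitive reduction, the Hasse-diagram edges. Each edge is
#' annotated with the items violating the ordering when the pair is only
#' approximately ordered (`0 < violations <= iota`). At `iota > 0` the
#' approximate relation need not be transitive; failures are reported via
#' a warning and the reduction is taken over the strict relation as is.
#'
#' @param result an [partial_order()] result.
#' @param class_labels optional replacement labels.
#' @return data frame with columns `from`, `to`, `n_violations`,
#'   `violating_items` (semicolon-separated).
#' @export
order_report <- function(result, class_labels = NULL) {
  if (!inherits(result, "rlca_partial_order"))
    stop("`result` must come from partial_order()", call. = FALSE)
  labels <- if (is.null(class_labels)) result$labels else class_labels
  C <- length(labels)
  rel <- result$relation
  diag(rel) <- FALSE
  strict <- rel & !t(rel)
  # transitivity check of the (approximate) relation
  trans_ok <- TRUE
  for (c in seq_len(C)) for (e in seq_len(C)) for (d in seq_len(C))
    if (rel[c, e] && rel[e, d] && c != d && !rel[c, d]) trans_ok <- FALSE
  if (!trans_ok)
    warning("approximate order is not transitive at iota = ", result$iota)
  keep <- strict
  for (c in seq_len(C)) for (d in seq_len(C)) {
    if (!strict[c, d]) next
    for (e in seq_len(C))
      if (strict[c, e] && strict[e, d]) keep[c, d] <- FALSE
  }
  idx <- which(keep, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(from = character(0), to = character(0),
                      n_violations = integer(0),
                      violating_items = character(0)))
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    from = labels[idx[, 1]],
    to = labels[idx[, 2]],
    n_violations = result$violations[idx],
    violating_items = apply(idx, 1, function(r)
      paste(result$violating_items[[r[1]]][[r[2]]], collapse = ";")),
    row.names = NULL)
}

#' Write a hierarchy edge list as CSV
#'
#' @param report an [order_report()] data frame.
#' @param path output file.
#' @export
write_order_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
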