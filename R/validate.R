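#' Label validation segments with the 1-km absence rule
#'
#' A segment is a *presence* if sign was recorded on it. It is an *absence*
#' only if no sign was recorded there **and** no sign-bearing segment lies
#' within `radius` metres. Sign-free segments near sign (failing both rules)
#' are ambiguous and dropped.
#'
#' @param segments tibble with `x`, `y` and logical `sign` (raw sign
#'   presence on the segment), e.g. from
#'   [simulate_validation_transects()].
#' @param radius exclusion radius in metres (default 1000).
#' @return the input tibble restricted to labelled segments, with a new
#'   `label` column ("presence"/"absence").
#' @export
assign_validation_labels <- function(segments, radius = 1000) {
  segments <- tibble::as_tibble(segments)
  if (!nrow(segments)) stop("no validation segments supplied.", call. = FALSE)
  stopifnot(all(c("x", "y", "sign") %in% names(segments)))
  pres <- segments[segments$sign, , drop = FALSE]
  label <- ifelse(segments$sign, "presence", NA_character_)
  if (nrow(pres)) {
    for (i in which(!segments$sign)) {
      d2 <- (pres$x - segments$x[i])^2 + (pres$y - segments$y[i])^2
      if (min(d2) > radius^2) label[i] <- "absence"
    }
  } else {
    label[!segments$sign] <- "absence"
  }
  out <- segments[!is.na(label), , drop = FALSE]
  out$label <- label[!is.na(label)]
  out
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the probability that a random presence scores above a random
#' absence, with ties counted 1/2:
#' \deqn{\mathrm{AUC} = \frac{R_1 - n_1(n_1+1)/2}{n_1 n_0}}
#' where \eqn{R_1} is the rank sum of presence scores (midranks). ROC
#' points are computed at every distinct threshold.
#'
#' @param scores numeric scores (e.g. predicted \eqn{\psi}) per point.
#' @param labels labels, coercible to logical presence: logical, 0/1, or
#'   "presence"/"absence".
#' @return a `roc_result`: list with `auc`, `n_presence`, `n_absence`, and
#'   a `curve` tibble (`threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "presence"
  }
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both presence and absence labels are required for ROC analysis.",
         call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties -> each tied pair counts 1/2
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = vapply(c(Inf, thr), function(t) mean(scores[labels] >= t), 0),
    fpr = vapply(c(Inf, thr), function(t) mean(scores[!labels] >= t), 0)
  )
  structure(list(auc = auc, n_presence = n1, n_absence = n0, curve = curve),
            class = "roc_result")
}

#' @method print roc_result
#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d presences, %d absences)\n",
              x$auc, x$n_presence, x$n_absence))
  invisible(x)
}

#' @rdname roc_auc
#' @param x a `roc_result`.
#' @param ... unused.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_presence = x$n_presence, n_absence = x$n_absence)
}

#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc))
}

#' Validate a suitability map against labelled points
#'
#' Convenience wrapper: reads \eqn{\psi} at each labelled point's cell and
#' runs [roc_auc()].
#'
#' @param psi_map [raster_grid()] of predicted occupancy probability.
#' @param points labelled points from [assign_validation_labels()].
#' @return a `roc_result`.
#' @export
validate_suitability <- function(psi_map, points) {
  cells <- cell_at(psi_map, points$x, points$y)
  scores <- psi_map$values[cbind(cells$row, cells$col)]
  keep <- !is.na(scores)
  roc_auc(scores[keep], points$label[keep])
}
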