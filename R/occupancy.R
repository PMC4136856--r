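#' Build a detection history from deployment records
#'
#' Splits each camera deployment into consecutive non-overlapping segments of
#' `segment_days` days starting at the deployment start; an occasion scores 1
#' if at least one detection falls inside it. A trailing partial segment
#' shorter than `segment_days` is dropped (equal effort per occasion).
#' Deployments too short for a single occasion are excluded with a warning.
#' Occasion covariates (lure, temperature class, camera view) are inherited
#' from the deployment.
#'
#' @param deployments tibble with `site_id`, `start` (integer day number or
#'   Date), `length` (days), `lure` (logical), `temperature`
#'   ("low"/"medium"/"high"), `camera_view` ("open"/"limited").
#' @param detections tibble with `site_id`, `day` (same scale as `start`).
#' @param segment_days occasion length in days (default 5).
#' @return a `detection_history`: list with binary matrix `y`
#'   (site x occasion, `NA` = occasion not surveyed) and occasion covariate
#'   matrices in `$occ_cov`.
#' @export
build_detection_history <- function(deployments, detections = NULL,
                                    segment_days = 5) {
  stopifnot(segment_days >= 1)
  dep <- tibble::as_tibble(deployments)
  if (inherits(dep$start, "Date")) dep$start <- as.numeric(dep$start)
  if (is.null(detections)) {
    detections <- tibble::tibble(site_id = dep$site_id[0], day = numeric(0))
  }
  det <- tibble::as_tibble(detections)
  if (inherits(det$day, "Date")) det$day <- as.numeric(det$day)
  n_occ_per <- floor(dep$length / segment_days)
  short <- n_occ_per == 0
  if (any(short)) {
    warning(sprintf("%d deployment(s) shorter than one %d-day occasion excluded: %s",
                    sum(short), segment_days,
                    paste(dep$site_id[short], collapse = ", ")))
    dep <- dep[!short, , drop = FALSE]
    n_occ_per <- n_occ_per[!short]
  }
  if (!nrow(dep)) stop("no deployment long enough for a single occasion.", call. = FALSE)
  n <- nrow(dep); T_max <- max(n_occ_per)
  y <- matrix(NA_real_, n, T_max)
  for (i in seq_len(n)) {
    Ti <- n_occ_per[i]
    y[i, seq_len(Ti)] <- 0
    dd <- det$day[det$site_id == dep$site_id[i]]
    if (length(dd)) {
      off <- dd - dep$start[i]
      if (any(off < 0 | off >= dep$length[i])) {
        stop(sprintf("detection date outside deployment window at site %s.",
                     dep$site_id[i]), call. = FALSE)
      }
      occ <- floor(off / segment_days) + 1
      occ <- occ[occ <= Ti]  # detections in the dropped partial tail are unused
      y[i, unique(occ)] <- 1
    }
  }
  rep_mat <- function(v) matrix(rep(v, T_max), n, T_max)
  structure(list(
    y = y,
    site_id = dep$site_id,
    occ_cov = list(
      lure = rep_mat(as.numeric(dep$lure)),
      temperature = rep_mat(as.character(dep$temperature)),
      camera_view = rep_mat(as.character(dep$camera_view))
    ),
    segment_days = segment_days
  ), class = "detection_history")
}

#' @method print detection_history
#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf("<detection_history> %d sites x %d occasions (%d-day), naive occupancy %.3f\n",
              nrow(x$y), ncol(x$y), x$segment_days,
              mean(rowSums(x$y == 1, na.rm = TRUE) > 0)))
  invisible(x)
}

#' Specify an occupancy model
#'
#' Occupancy terms are covariate names, optionally wrapped in `log()`
#' (fitted as `log(x + 1)`) or `quad()` (fitted as `x + x^2`). Detection
#' terms are drawn from `lure`, `temperature`, `camera_view`. Both parts
#' always include an intercept.
#'
#' @param occ_terms character vector of occupancy terms (may be empty).
#' @param det_terms character subset of `c("lure","temperature","camera_view")`.
#' @return an `occu_spec` object.
#' @export
occu_spec <- function(occ_terms = character(0), det_terms = character(0)) {
  if (anyDuplicated(occ_terms)) stop("duplicate occupancy terms.", call. = FALSE)
  bad <- setdiff(det_terms, c("lure", "temperature", "camera_view"))
  if (length(bad)) stop(sprintf("unknown detection term(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  structure(list(occ_terms = occ_terms, det_terms = det_terms),
            class = "occu_spec")
}

parse_term <- function(term) {
  if (grepl("^log\\(.+\\)$", term)) {
    list(term = term, base = sub("^log\\((.+)\\)$", "\\1", term), form = "log")
  } else if (grepl("^quad\\(.+\\)$", term)) {
    list(term = term, base = sub("^quad\\((.+)\\)$", "\\1", term), form = "quadratic")
  } else {
    list(term = term, base = term, form = "raw")
  }
}

# Build (or re-apply) the occupancy design matrix. Continuous columns are
# z-scored with stored constants so fits are stable and predictions reuse the
# training scaling; factor columns expand to treatment dummies with stored
# level sets.
build_occ_design <- function(data, occ_terms, info = NULL) {
  n <- nrow(data)
  fresh <- is.null(info)
  if (fresh) info <- list(terms = occ_terms, meta = list())
  cols <- list(`(Intercept)` = rep(1, n))
  for (term in occ_terms) {
    pt <- parse_term(term)
    if (!pt$base %in% names(data)) {
      stop(sprintf("occupancy term '%s' has no column '%s' in the data.",
                   term, pt$base), call. = FALSE)
    }
    v <- data[[pt$base]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      if (pt$form != "raw") stop(sprintf("'%s' is categorical; only raw form applies.",
                                         term), call. = FALSE)
      if (fresh) info$meta[[term]] <- list(type = "factor", levels = levels(v))
      lv <- info$meta[[term]]$levels
      v <- factor(as.character(v), levels = lv)
      for (l in lv[-1]) cols[[paste0(pt$base, l)]] <- as.numeric(v == l)
    } else {
      raw <- switch(pt$form,
                    raw = list(v), log = list(log(v + 1)),
                    quadratic = list(v, v^2))
      nms <- switch(pt$form,
                    raw = pt$base, log = sprintf("log(%s)", pt$base),
                    quadratic = c(pt$base, sprintf("I(%s^2)", pt$base)))
      if (fresh) {
        info$meta[[term]] <- list(
          type = "numeric",
          center = vapply(raw, mean, 0), scale = vapply(raw, stats::sd, 0))
        info$meta[[term]]$scale[info$meta[[term]]$scale == 0] <- 1
      }
      m <- info$meta[[term]]
      for (k in seq_along(raw)) {
        cols[[nms[k]]] <- (raw[[k]] - m$center[k]) / m$scale[k]
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, info = info)
}

# Detection design matrix, one row per (site, occasion) in column-major
# occasion order (site index varies fastest), aligned with as.vector(y).
build_det_design <- function(history, det_terms) {
  n <- nrow(history$y); T_ <- ncol(history$y)
  cols <- list(`(Intercept)` = rep(1, n * T_))
  if ("lure" %in% det_terms) cols$lure <- as.vector(history$occ_cov$lure)
  if ("temperature" %in% det_terms) {
    tmp <- as.vector(history$occ_cov$temperature)
    cols$temperaturemedium <- as.numeric(tmp == "medium")
    cols$temperaturehigh <- as.numeric(tmp == "high")
  }
  if ("camera_view" %in% det_terms) {
    cols$camera_viewlimited <- as.numeric(as.vector(history$occ_cov$camera_view) == "limited")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Negative log-likelihood of the single-season occupancy model
#'
#' The zero-inflated binomial likelihood with imperfect detection: for site
#' \eqn{i} with occupancy probability \eqn{\psi_i} and occasion detection
#' probabilities \eqn{p_{it}},
#' \deqn{L_i = \psi_i \prod_t p_{it}^{y_{it}} (1-p_{it})^{1-y_{it}}
#'       + (1-\psi_i)\,[\mathrm{all}\; y_{it}=0],}
#' with missing occasions skipped. Both \eqn{\psi} and \eqn{p} are
#' logit-linear in their design matrices.
#'
#' @param params numeric vector `c(beta, alpha)` on the logit scale.
#' @param X_occ occupancy design matrix (n x p).
#' @param X_det detection design matrix (n*T x q), site index varying fastest.
#' @param y site x occasion binary matrix with `NA` for unsurveyed occasions.
#' @return the negative log-likelihood (single non-negative number).
#' @export
occupancy_negloglik <- function(params, X_occ, X_det, y) {
  if (any(!is.finite(params))) stop("non-finite parameters.", call. = FALSE)
  p_occ <- ncol(X_occ)
  beta <- params[seq_len(p_occ)]
  alpha <- params[-seq_len(p_occ)]
  psi <- stats::plogis(drop(X_occ %*% beta))
  P <- matrix(stats::plogis(drop(X_det %*% alpha)), nrow(y), ncol(y))
  ll_occ <- y * log(P) + (1 - y) * log1p(-P)
  ll_occ[is.na(y)] <- 0
  A <- exp(rowSums(ll_occ))
  never <- rowSums(y == 1, na.rm = TRUE) == 0
  L <- psi * A + (1 - psi) * as.numeric(never)
  -sum(log(pmax(L, 1e-300)))
}

occupancy_negloglik_grad <- function(params, X_occ, X_det, y) {
  p_occ <- ncol(X_occ)
  beta <- params[seq_len(p_occ)]
  alpha <- params[-seq_len(p_occ)]
  psi <- stats::plogis(drop(X_occ %*% beta))
  pv <- stats::plogis(drop(X_det %*% alpha))
  P <- matrix(pv, nrow(y), ncol(y))
  ll_occ <- y * log(P) + (1 - y) * log1p(-P)
  ll_occ[is.na(y)] <- 0
  A <- exp(rowSums(ll_occ))
  never <- as.numeric(rowSums(y == 1, na.rm = TRUE) == 0)
  L <- pmax(psi * A + (1 - psi) * never, 1e-300)
  w_beta <- (A - never) / L * psi * (1 - psi)
  resid <- y - P
  resid[is.na(y)] <- 0
  v <- as.vector(resid * (psi * A / L))  # recycles by column: (i,t) scaled by site i
  c(-drop(crossprod(X_occ, w_beta)), -drop(crossprod(X_det, v)))
}

#' Fit a single-season occupancy model by maximum likelihood
#'
#' Minimises [occupancy_negloglik()] by quasi-Newton (BFGS) with an analytic
#' gradient from multiple starts (the zero vector plus deterministic jittered
#' starts), keeping the best. Estimates are capped at |logit| = 15 with a
#' boundary flag so degenerate data terminate cleanly.
#'
#' @param spec an [occu_spec()].
#' @param history a [detection_history()].
#' @param site_data site covariate data frame, rows aligned to `history`.
#' @param init optional start vector (defaults to zeros).
#' @param n_starts number of optimiser starts (default 5).
#' @param max_logit cap for boundary estimates.
#' @return an `occu_fit` with coefficients (standardised scale), `logLik`,
#'   `K`, `AIC`, convergence and boundary flags, and the design metadata
#'   needed for prediction.
#' @export
fit_occupancy <- function(spec, history, site_data, init = NULL, n_starts = 5,
                          max_logit = 15) {
  stopifnot(inherits(spec, "occu_spec"), inherits(history, "detection_history"))
  if (nrow(site_data) != nrow(history$y)) {
    stop("site_data rows must align with history sites.", call. = FALSE)
  }
  od <- build_occ_design(site_data, spec$occ_terms)
  X_occ <- od$X
  X_det <- build_det_design(history, spec$det_terms)
  y <- history$y
  K <- ncol(X_occ) + ncol(X_det)
  if (K >= nrow(y)) {
    warning(sprintf("model has %d parameters for %d sites; identifiability is doubtful.",
                    K, nrow(y)))
  }
  if (is.null(init)) init <- rep(0, K)
  fn <- function(par) occupancy_negloglik(par, X_occ, X_det, y)
  gr <- function(par) occupancy_negloglik_grad(par, X_occ, X_det, y)
  best <- NULL
  for (s in seq_len(max(1, n_starts))) {
    start <- if (s == 1) init else init + 0.75 * sin(s * seq_len(K) * 2.3997)
    res <- tryCatch(stats::optim(start, fn, gr, method = "BFGS",
                                 control = list(maxit = 300, reltol = 1e-10)),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(structure(list(spec = spec, converged = FALSE, boundary = FALSE,
                          logLik = NA_real_, K = K, AIC = NA_real_),
                     class = "occu_fit"))
  }
  par <- pmin(pmax(best$par, -max_logit), max_logit)
  boundary <- any(abs(best$par) >= max_logit)
  gnorm <- sqrt(sum(gr(par)^2))
  nll <- fn(par)
  p_occ <- ncol(X_occ)
  structure(list(
    spec = spec,
    beta = stats::setNames(par[seq_len(p_occ)], colnames(X_occ)),
    alpha = stats::setNames(par[-seq_len(p_occ)], colnames(X_det)),
    logLik = -nll, K = K, AIC = 2 * nll + 2 * K,
    converged = best$convergence == 0 || boundary || gnorm < 1e-3,
    boundary = boundary, grad_norm = gnorm,
    design_info = od$info, det_terms = spec$det_terms,
    n_sites = nrow(y), n_occasions = ncol(y)
  ), class = "occu_fit")
}

#' @method print occu_fit
#' @export
print.occu_fit <- function(x, ...) {
  cat(sprintf("<occu_fit> psi ~ %s | p ~ %s\n",
              if (length(x$spec$occ_terms)) paste(x$spec$occ_terms, collapse = " + ") else "1",
              if (length(x$spec$det_terms)) paste(x$spec$det_terms, collapse = " + ") else "1"))
  cat(sprintf("  K = %d, logLik = %.3f, AIC = %.3f, converged = %s%s\n",
              x$K, x$logLik, x$AIC, x$converged,
              if (isTRUE(x$boundary)) " (boundary)" else ""))
  invisible(x)
}

#' @rdname fit_occupancy
#' @param x an `occu_fit`.
#' @param ... unused.
#' @export
tidy.occu_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(component = "occupancy", term = names(x$beta), estimate = unname(x$beta)),
    tibble::tibble(component = "detection", term = names(x$alpha), estimate = unname(x$alpha))
  )
}

#' @rdname fit_occupancy
#' @export
glance.occu_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, K = x$K, AIC = x$AIC,
                 converged = x$converged, boundary = isTRUE(x$boundary),
                 n_sites = x$n_sites, n_occasions = x$n_occasions)
}

#' Select detection covariates under the full occupancy model
#'
#' Fits the general model containing every occupancy covariate once per
#' subset of the detection covariate pool (including the empty subset) and
#' returns the minimal-AIC subset. Ties go to fewer terms, then
#' lexicographic order. Non-convergent subsets are skipped with a log entry.
#'
#' @param history a [detection_history()].
#' @param site_data aligned site covariates.
#' @param occ_terms all occupancy terms (the general model).
#' @param det_pool candidate detection covariates (at most 10).
#' @param n_starts optimiser starts per fit.
#' @return list with `best` (character vector of retained detection terms)
#'   and `table` (tibble of all subsets with K, AIC, converged).
#' @export
select_detection_model <- function(history, site_data, occ_terms,
                                   det_pool = c("lure", "temperature", "camera_view"),
                                   n_starts = 5) {
  if (length(det_pool) > 10) stop("detection pool too large to enumerate.", call. = FALSE)
  subsets <- subset_list(det_pool)
  rows <- purrr::map(subsets, function(s) {
    fit <- fit_occupancy(occu_spec(occ_terms, s), history, site_data,
                         n_starts = n_starts)
    tibble::tibble(det_terms = list(s),
                   label = if (length(s)) paste(s, collapse = " + ") else "(none)",
                   n_terms = length(s), K = fit$K,
                   AIC = if (fit$converged) fit$AIC else NA_real_,
                   converged = fit$converged)
  })
  tab <- dplyr::bind_rows(rows)
  ok <- tab[tab$converged & !is.na(tab$AIC), ]
  if (!nrow(ok)) stop("no detection subset converged.", call. = FALSE)
  ok <- ok[order(ok$AIC, ok$n_terms, ok$label), ]
  list(best = ok$det_terms[[1]], table = dplyr::arrange(tab, .data$AIC))
}

subset_list <- function(pool) {
  k <- length(pool)
  if (k == 0) return(list(character(0)))
  out <- list()
  for (m in 0:(2^k - 1)) {
    out[[m + 1]] <- pool[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
  }
  out
}

#' All-subsets occupancy model selection
#'
#' Fits every combination of the occupancy covariate pool (detection terms
#' held fixed) and ranks the fits by AIC with \eqn{\Delta}AIC, Akaike
#' weights \eqn{w_i = \exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)} and
#' cumulative weight, in the style of a multimodel-inference results table.
#'
#' @param history a [detection_history()].
#' @param site_data aligned site covariates.
#' @param occ_pool character vector of candidate occupancy terms (<= 12).
#' @param det_terms fixed detection terms used in every model.
#' @param n_starts optimiser starts per fit.
#' @return an `occu_modelset`: tibble with one ranked row per converged
#'   model (`model`, `occ_terms`, `K`, `logLik`, `AIC`, `dAIC`, `weight`,
#'   `cum_weight`), carrying the fits and any skipped models as attributes.
#' @export
all_subsets_selection <- function(history, site_data, occ_pool,
                                  det_terms = character(0), n_starts = 5) {
  if (length(occ_pool) > 12) stop("occupancy pool too large to enumerate.", call. = FALSE)
  subsets <- subset_list(occ_pool)
  fits <- purrr::map(subsets, function(s) {
    fit_occupancy(occu_spec(s, det_terms), history, site_data, n_starts = n_starts)
  })
  labels <- vapply(subsets, function(s) {
    if (length(s)) paste(s, collapse = " + ") else "(intercept)"
  }, "")
  conv <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$AIC), TRUE)
  skipped <- labels[!conv]
  tab <- tibble::tibble(
    model = labels[conv],
    occ_terms = subsets[conv],
    K = vapply(fits[conv], function(f) f$K, 0L + 0),
    logLik = vapply(fits[conv], function(f) f$logLik, 0),
    AIC = vapply(fits[conv], function(f) f$AIC, 0)
  )
  tab <- dplyr::arrange(tab, .data$AIC)
  tab$dAIC <- tab$AIC - tab$AIC[1]
  w <- exp(-tab$dAIC / 2)
  tab$weight <- w / sum(w)
  tab$cum_weight <- cumsum(tab$weight)
  # fits keyed by model label, aligned with the ranked rows
  attr(tab, "fits") <- stats::setNames(fits[conv], labels[conv])[tab$model]
  attr(tab, "skipped") <- skipped
  attr(tab, "det_terms") <- det_terms
  attr(tab, "occ_pool") <- occ_pool
  attr(tab, "site_summary") <- summarise_site_data(site_data, occ_pool)
  class(tab) <- c("occu_modelset", class(tab))
  tab
}

summarise_site_data <- function(site_data, occ_pool) {
  bases <- unique(vapply(occ_pool, function(t) parse_term(t)$base, ""))
  bases <- intersect(bases, names(site_data))
  purrr::map(stats::setNames(bases, bases), function(b) {
    v <- site_data[[b]]
    if (is.numeric(v)) {
      list(type = "numeric", mean = mean(v), range = range(v))
    } else {
      v <- as.character(v)
      list(type = "factor", mode = names(sort(table(v), decreasing = TRUE))[1],
           levels = sort(unique(v)))
    }
  })
}

#' @method print occu_modelset
#' @export
print.occu_modelset <- function(x, ...) {
  cat(sprintf("<occu_modelset> %d models, detection: %s\n", nrow(x),
              if (length(attr(x, "det_terms"))) paste(attr(x, "det_terms"), collapse = " + ") else "(none)"))
  print(tibble::as_tibble(x)[, c("model", "K", "AIC", "dAIC", "weight", "cum_weight")],
        n = min(nrow(x), 15))
  invisible(x)
}

#' Model-average the top set of an all-subsets selection
#'
#' The top set is every model with \eqn{\Delta}AIC at or below the
#' threshold (default 2); its Akaike weights are renormalised. Coefficients
#' are averaged with zero substitution (a model not containing a term
#' contributes zero), and each pool covariate gets an importance weight:
#' the summed renormalised weight of the top models containing it.
#'
#' @param modelset an `occu_modelset` from [all_subsets_selection()].
#' @param delta_threshold \eqn{\Delta}AIC cut-off (default 2).
#' @return an `occu_avg` with averaged occupancy/detection coefficients (on
#'   the standardised fitting scale), importance weights and the top-set
#'   table.
#' @export
model_average <- function(modelset, delta_threshold = 2) {
  stopifnot(inherits(modelset, "occu_modelset"), nrow(modelset) >= 1)
  top <- modelset[modelset$dAIC <= delta_threshold, , drop = FALSE]
  wt <- top$weight / sum(top$weight)
  fits <- attr(modelset, "fits")[top$model]
  # union of coefficient columns over the top set, in first-appearance order
  occ_cols <- unique(unlist(lapply(fits, function(f) names(f$beta))))
  det_cols <- unique(unlist(lapply(fits, function(f) names(f$alpha))))
  avg_over <- function(cols, get) {
    out <- stats::setNames(rep(0, length(cols)), cols)
    for (k in seq_along(fits)) {
      co <- get(fits[[k]])
      out[names(co)] <- out[names(co)] + wt[k] * co
    }
    out
  }
  coef_occ <- avg_over(occ_cols, function(f) f$beta)
  coef_det <- avg_over(det_cols, function(f) f$alpha)
  pool <- attr(modelset, "occ_pool")
  importance <- tibble::tibble(
    covariate = pool,
    importance = vapply(pool, function(tm) {
      sum(wt[vapply(top$occ_terms, function(s) tm %in% s, TRUE)])
    }, 0, USE.NAMES = FALSE)
  )
  # merged design metadata: every term's scaling is identical across models
  # (computed from the same site data), so take each term's first occurrence
  meta <- list()
  for (f in fits) for (tm in names(f$design_info$meta)) {
    if (is.null(meta[[tm]])) meta[[tm]] <- f$design_info$meta[[tm]]
  }
  structure(list(
    coef_occ = coef_occ, coef_det = coef_det, importance = importance,
    top = tibble::as_tibble(top)[, c("model", "K", "AIC", "dAIC", "weight")],
    top_weights = wt, delta_threshold = delta_threshold,
    occ_terms = unique(unlist(top$occ_terms)),
    det_terms = attr(modelset, "det_terms"),
    design_meta = meta,
    site_summary = attr(modelset, "site_summary")
  ), class = "occu_avg")
}

#' @method print occu_avg
#' @export
print.occu_avg <- function(x, ...) {
  cat(sprintf("<occu_avg> %d top model(s) (dAIC <= %g)\n", nrow(x$top),
              x$delta_threshold))
  cat("occupancy coefficients (standardised scale):\n")
  print(round(x$coef_occ, 4))
  invisible(x)
}

#' @rdname model_average
#' @param x an `occu_avg`.
#' @param ... unused.
#' @export
tidy.occu_avg <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(component = "occupancy", term = names(x$coef_occ),
                   estimate = unname(x$coef_occ)),
    tibble::tibble(component = "detection", term = names(x$coef_det),
                   estimate = unname(x$coef_det))
  )
}

#' @rdname model_average
#' @export
glance.occu_avg <- function(x, ...) {
  tibble::tibble(n_top = nrow(x$top), delta_threshold = x$delta_threshold,
                 best_AIC = min(x$top$AIC))
}

# evaluate the averaged linear predictor on arbitrary rows of covariates
avg_linear_predictor <- function(avg, data) {
  od <- build_occ_design(data, names(avg$design_meta),
                         info = list(terms = names(avg$design_meta),
                                     meta = avg$design_meta))
  X <- od$X
  keep <- intersect(names(avg$coef_occ), colnames(X))
  eta <- drop(X[, keep, drop = FALSE] %*% avg$coef_occ[keep])
  extra <- setdiff(names(avg$coef_occ), c(colnames(X)))
  if (length(extra)) {
    stop(sprintf("averaged terms not resolvable from the data: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  eta
}

#' Predict a habitat-suitability map from an averaged model
#'
#' Applies the model-averaged predictive equation
#' \eqn{\psi(\mathrm{cell}) = \mathrm{logit}^{-1}(\bar\beta \cdot x)} to
#' every cell of the covariate stack, using the standardisation constants
#' stored at fitting time. Nodata cells propagate.
#'
#' @param avg an `occu_avg` (or an `occu_fit`, used as a one-model average).
#' @param stack a [covariate_stack()] whose layers include every base
#'   covariate of the averaged terms. Categorical layers are decoded via
#'   their label lists.
#' @return a [raster_grid()] of occupancy probabilities in \[0, 1\].
#' @export
predict_suitability <- function(avg, stack) {
  if (inherits(avg, "occu_fit")) {
    avg <- structure(list(coef_occ = avg$beta, coef_det = avg$alpha,
                          design_meta = avg$design_info$meta,
                          occ_terms = avg$spec$occ_terms),
                     class = "occu_avg")
  }
  ref <- stack$layers[[1]]
  bases <- unique(vapply(names(avg$design_meta), function(t) parse_term(t)$base, ""))
  miss <- setdiff(bases, names(stack$layers))
  if (length(miss)) {
    stop(sprintf("stack is missing layer(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  idx <- expand.grid(row = seq_len(ref$n_rows), col = seq_len(ref$n_cols))
  data <- stack_site_data(stack, idx$row, idx$col, layers = bases)
  complete <- stats::complete.cases(data)
  eta <- rep(NA_real_, nrow(data))
  if (any(complete)) eta[complete] <- avg_linear_predictor(avg, data[complete, , drop = FALSE])
  vals <- matrix(NA_real_, ref$n_rows, ref$n_cols)
  vals[cbind(idx$row, idx$col)] <- stats::plogis(eta)
  raster_grid(vals, ref$cell_size, ref$origin_x, ref$origin_y, ref$nodata)
}

#' Extract model-ready covariates from a stack at cells
#'
#' Continuous layers come back numeric; categorical layers are decoded to
#' their labels (factors), matching how site tables are built.
#'
#' @param stack a [covariate_stack()].
#' @param row,col cell indices.
#' @param layers layer names to extract (default all).
#' @return a tibble, one row per cell.
#' @export
stack_site_data <- function(stack, row, col, layers = names(stack$layers)) {
  out <- purrr::map(stats::setNames(layers, layers), function(nm) {
    v <- stack$layers[[nm]]$values[cbind(row, col)]
    if (stack$kind[[nm]] == "categorical") {
      labs <- stack$labels[[nm]]
      if (is.null(labs)) labs <- as.character(seq_len(max(v, na.rm = TRUE)))
      factor(labs[v], levels = labs)
    } else v
  })
  tibble::as_tibble(out)
}

#' Partial response curve of an averaged model
#'
#' Occupancy probability as one covariate sweeps its observed range while
#' all other covariates are fixed at their mean (continuous) or modal
#' (categorical) values from the fitting data.
#'
#' @param avg an `occu_avg` from [model_average()].
#' @param covariate base covariate name to vary.
#' @param n number of grid points (continuous covariates).
#' @return a tibble (class `partial_response`) with `value` and `psi`.
#' @export
partial_response <- function(avg, covariate, n = 100) {
  ss <- avg$site_summary
  if (is.null(ss) || !covariate %in% names(ss)) {
    stop(sprintf("unknown covariate '%s' for partial response.", covariate),
         call. = FALSE)
  }
  bases <- names(ss)
  base_row <- purrr::map(ss, function(s) {
    if (s$type == "numeric") s$mean else factor(s$mode, levels = s$levels)
  })
  if (ss[[covariate]]$type == "numeric") {
    grid_vals <- seq(ss[[covariate]]$range[1], ss[[covariate]]$range[2],
                     length.out = n)
  } else {
    grid_vals <- factor(ss[[covariate]]$levels, levels = ss[[covariate]]$levels)
  }
  data <- tibble::as_tibble(purrr::map(base_row, function(v) rep(v, length(grid_vals))))
  data[[covariate]] <- grid_vals
  psi <- stats::plogis(avg_linear_predictor(avg, data))
  out <- tibble::tibble(covariate = covariate, value = grid_vals, psi = psi)
  class(out) <- c("partial_response", class(out))
  out
}

#' @method autoplot partial_response
#' @export
autoplot.partial_response <- function(object, ...) {
  if (is.numeric(object$value)) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$psi)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = object$covariate[1], y = "occupancy probability") +
      ggplot2::ylim(0, 1)
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$psi)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = object$covariate[1], y = "occupancy probability") +
      ggplot2::ylim(0, 1)
  }
}

#' @method autoplot occu_modelset
#' @export
autoplot.occu_modelset <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Akaike weight", y = NULL)
}
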