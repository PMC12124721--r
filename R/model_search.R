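# Exhaustive 1- and 2-descriptor multilinear regression search:
# fit, score (R2/MAE/RMSE), rank, select, predict, correlate.

#' Regression metrics from observed and fitted responses
#'
#' @param y Observed response.
#' @param fitted Fitted values from a model on the same compounds.
#' @return List with `r2` (1 - SS_res/SS_tot), `mae` (mean absolute
#'   residual) and `rmse` (root mean squared residual). RMSE >= MAE always
#'   holds (power-mean inequality).
#' @export
regression_metrics <- function(y, fitted) {
  stopifnot(length(y) == length(fitted), length(y) >= 2L)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-300) stop("zero response variance: R2 undefined")
  res <- y - fitted
  list(r2 = 1 - sum(res^2) / ss_tot,
       mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)))
}

#' Ordinary least squares on one or two scaled descriptor columns
#'
#' Coefficients are the closed-form normal-equation solution with an
#' intercept always included; metrics are computed in-sample (training
#' R2/MAE/RMSE, no held-out split). A rank-deficient design (collinear
#' descriptor pair) yields a model flagged `degenerate` instead of an error
#' so that exhaustive searches can keep counting it.
#'
#' @param X Numeric matrix of 1-2 scaled descriptor columns (named).
#' @param y Response vector aligned with the rows of `X`.
#' @param scaling Optional data.frame `name,min,max` recording the training
#'   min-max ranges of the columns, carried along for prediction.
#' @param response_name Label for the response (metadata only).
#' @return An object of class `candidate_model`.
#' @export
fit_ols <- function(X, y, scaling = NULL, response_name = "response") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, ncol = 1L, dimnames = list(NULL, "x"))
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1L) stop("need more compounds than terms plus intercept")
  A <- cbind(`(intercept)` = 1, X)
  qr_A <- qr(A)
  degenerate <- qr_A$rank < ncol(A)
  if (degenerate) {
    coefs <- rep(NA_real_, k)
    intercept <- NA_real_
    met <- list(r2 = -Inf, mae = Inf, rmse = Inf)
  } else {
    beta <- solve(crossprod(A), crossprod(A, y))[, 1L]
    intercept <- beta[1L]
    coefs <- beta[-1L]
    met <- regression_metrics(y, as.numeric(A %*% beta))
  }
  structure(list(terms = colnames(X),
                 coefficients = stats::setNames(coefs, colnames(X)),
                 intercept = unname(intercept),
                 r2 = met$r2, mae = met$mae, rmse = met$rmse,
                 n = n, degenerate = degenerate,
                 collinear = k == 2L && !degenerate &&
                   abs(stats::cor(X[, 1L], X[, 2L])) > 0.999,
                 scaling = scaling, response_name = response_name),
            class = "candidate_model")
}

#' @export
print.candidate_model <- function(x, digits = 4, ...) {
  eq <- paste(sprintf("%+.*f*%s", digits, x$coefficients, x$terms),
              collapse = " ")
  cat(sprintf("<candidate_model> %s = %.*f %s\n", x$response_name, digits,
              x$intercept, eq))
  cat(sprintf("  n=%d  R2=%.4f  MAE=%.4f  RMSE=%.4f%s\n", x$n, x$r2, x$mae,
              x$rmse,
              if (x$degenerate) "  [degenerate]"
              else if (isTRUE(x$collinear)) "  [collinear pair]" else ""))
  invisible(x)
}

#' Fit a named descriptor subset against a response
#'
#' Convenience wrapper: pull the named columns from a scaled table and fit.
#' Used e.g. for the confirmatory pKa fit on the same two descriptors as the
#' lipophilicity model.
#'
#' @param t A scaled `descriptor_table`.
#' @param response Named response vector or vector aligned to the table rows;
#'   `NA` responses drop the compound from the fit.
#' @param terms Character vector of 1-2 descriptor names.
#' @param response_name Response label.
#' @return A `candidate_model`.
#' @export
fit_terms <- function(t, response, terms, response_name = "response") {
  stopifnot(inherits(t, "descriptor_table"))
  missing_terms <- setdiff(terms, descriptor_names(t))
  if (length(missing_terms) > 0L)
    stop("descriptor(s) not in table: ", paste(missing_terms, collapse = ", "))
  if (!is.null(names(response)))
    response <- response[compound_ids(t)]
  keep <- !is.na(response)
  X <- t$values[keep, terms, drop = FALSE]
  scaling <- if (!is.null(t$scaling))
    t$scaling[t$scaling$name %in% terms, , drop = FALSE]
  fit_ols(X, response[keep], scaling = scaling, response_name = response_name)
}

#' Exhaustive search over all 1- and 2-descriptor regressions
#'
#' Fits every single descriptor and every unordered pair exactly once
#' against the response (d + choose(d, 2) models), computes in-sample R2,
#' MAE and RMSE for each, and ranks them: primary key max R2; ties within
#' `1e-6` in R2 broken by min MAE, then min RMSE, then fewer terms, then
#' lexical term order. Collinear pairs are fitted and flagged but remain in
#' the model count; rank-deficient fits are excluded from the ranking.
#'
#' @param t A scaled `descriptor_table`.
#' @param response Response vector (named by compound id, or aligned to the
#'   table rows). `NA` entries drop those compounds from every fit.
#' @param max_terms Maximum model size; only 1 or 2 are supported.
#' @param keep_models Number of top models to retain as full
#'   `candidate_model` objects (the ranked metric table always covers all).
#' @param response_name Response label.
#' @return An object of class `search_report`: `n_models`, `ranked`
#'   (data.frame of terms/r2/mae/rmse/rank), `models` (top fits), `best`,
#'   `criteria`.
#' @export
enumerate_models <- function(t, response, max_terms = 2L, keep_models = 50L,
                             response_name = "response") {
  stopifnot(inherits(t, "descriptor_table"))
  if (max_terms > 2L) stop("max_terms > 2 is not supported")
  if (max_terms < 1L) stop("max_terms must be 1 or 2")
  if (!is.null(names(response))) response <- response[compound_ids(t)]
  stopifnot(length(response) == nrow(t$values))
  keep <- !is.na(response)
  V <- t$values[keep, , drop = FALSE]
  y <- as.numeric(response[keep])
  n <- nrow(V); d <- ncol(V)
  if (n < 4L) stop("need at least 4 compounds with responses")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-300) stop("zero response variance: R2 undefined")

  # precomputed cross-products make each candidate a 2x2/3x3 solve
  A <- cbind(1, V)
  G <- crossprod(A)
  g <- crossprod(A, y)[, 1L]

  singles <- seq_len(d)
  pairs <- if (max_terms >= 2L && d >= 2L) utils::combn(d, 2L) else
    matrix(integer(0), nrow = 2L)
  n_models <- length(singles) + ncol(pairs)

  terms_chr <- character(n_models)
  r2 <- mae <- rmse <- numeric(n_models)
  degenerate <- logical(n_models)
  nterm <- integer(n_models)
  fits <- vector("list", n_models)

  eval_subset <- function(idx) {
    sel <- c(1L, idx + 1L)
    Asub <- G[sel, sel, drop = FALSE]
    bsub <- g[sel]
    beta <- tryCatch(solve(Asub, bsub), error = function(e) NULL)
    if (is.null(beta) || any(!is.finite(beta))) return(NULL)
    fitted <- as.numeric(A[, sel, drop = FALSE] %*% beta)
    res <- y - fitted
    list(beta = beta, r2 = 1 - sum(res^2) / ss_tot,
         mae = mean(abs(res)), rmse = sqrt(mean(res^2)))
  }

  m <- 0L
  for (j in singles) {
    m <- m + 1L
    terms_chr[m] <- colnames(V)[j]
    nterm[m] <- 1L
    f <- eval_subset(j)
    if (is.null(f)) { degenerate[m] <- TRUE; r2[m] <- -Inf; mae[m] <- Inf; rmse[m] <- Inf }
    else { r2[m] <- f$r2; mae[m] <- f$mae; rmse[m] <- f$rmse; fits[[m]] <- f }
  }
  if (ncol(pairs) > 0L) {
    for (p in seq_len(ncol(pairs))) {
      m <- m + 1L
      idx <- pairs[, p]
      terms_chr[m] <- paste(sort(colnames(V)[idx]), collapse = " + ")
      nterm[m] <- 2L
      f <- eval_subset(idx)
      if (is.null(f)) { degenerate[m] <- TRUE; r2[m] <- -Inf; mae[m] <- Inf; rmse[m] <- Inf }
      else { r2[m] <- f$r2; mae[m] <- f$mae; rmse[m] <- f$rmse; fits[[m]] <- f }
    }
  }

  ord <- rank_models(r2, mae, rmse, nterm, terms_chr, degenerate)
  ranked <- data.frame(terms = terms_chr, n_terms = nterm, r2 = r2,
                       mae = mae, rmse = rmse, degenerate = degenerate,
                       stringsAsFactors = FALSE)[ord, ]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL

  build_model <- function(pos) {  # pos indexes the pre-ranking order
    idx <- if (nterm[pos] == 1L) match(terms_chr[pos], colnames(V)) else
      pairs[, pos - d]
    f <- fits[[pos]]
    cols <- colnames(V)[idx]
    scaling <- if (!is.null(t$scaling))
      t$scaling[t$scaling$name %in% cols, , drop = FALSE]
    structure(list(terms = cols,
                   coefficients = stats::setNames(f$beta[-1L], cols),
                   intercept = unname(f$beta[1L]),
                   r2 = f$r2, mae = f$mae, rmse = f$rmse, n = n,
                   degenerate = FALSE,
                   collinear = length(idx) == 2L &&
                     abs(stats::cor(V[, idx[1L]], V[, idx[2L]])) > 0.999,
                   scaling = scaling, response_name = response_name),
              class = "candidate_model")
  }
  top <- ord[!degenerate[ord]]
  top <- top[seq_len(min(keep_models, length(top)))]
  models <- lapply(top, build_model)
  names(models) <- terms_chr[top]

  structure(list(n_models = n_models, ranked = ranked, models = models,
                 best = if (length(models) > 0L) models[[1L]] else NULL,
                 criteria = list(primary = "max r2",
                                 ties = c("min mae", "min rmse",
                                          "fewer terms", "lexical"),
                                 r2_tie_tol = 1e-6),
                 response_name = response_name),
            class = "search_report")
}

# Ranking order: max r2; ties (within tol) by mae, rmse, parsimony, name.
# Implemented by quantising r2 into tie groups after sorting.
rank_models <- function(r2, mae, rmse, nterm, terms_chr, degenerate,
                        tol = 1e-6) {
  # degenerate fits (r2 = -Inf) sort last and skip the tie refinement
  bad <- !is.finite(r2)
  if (any(bad)) {
    good <- which(!bad)
    ord_good <- good[rank_models(r2[good], mae[good], rmse[good],
                                 nterm[good], terms_chr[good],
                                 degenerate[good], tol)]
    return(c(ord_good, which(bad)[order(terms_chr[bad], method = "radix")]))
  }
  ord <- order(-r2, mae, rmse, nterm, terms_chr, method = "radix")
  # refine: within runs of r2 equal up to tol, re-sort by the tie cascade
  out <- integer(0)
  i <- 1L
  while (i <= length(ord)) {
    j <- i
    while (j < length(ord) &&
           abs(r2[ord[j + 1L]] - r2[ord[i]]) < tol) j <- j + 1L
    grp <- ord[i:j]
    grp <- grp[order(mae[grp], rmse[grp], nterm[grp], terms_chr[grp],
                     method = "radix")]
    out <- c(out, grp)
    i <- j + 1L
  }
  out
}

#' @export
print.search_report <- function(x, n = 10L, ...) {
  cat(sprintf("<search_report> %d models fitted for %s\n", x$n_models,
              x$response_name))
  print(utils::head(x$ranked, n))
  invisible(x)
}

#' Select the best model from a search report
#'
#' @param report A `search_report`.
#' @return The top-ranked `candidate_model`.
#' @export
select_best <- function(report) {
  stopifnot(inherits(report, "search_report"))
  if (is.null(report$best)) stop("no non-degenerate models in report")
  report$best
}

#' Predict the response for selected compounds
#'
#' Descriptor values are taken from `t` on the raw scale (a scaled table is
#' first inverted with its own records), then scaled with the *training*
#' (min, max) stored on the model. A scaled input falling outside [0, 1]
#' means extrapolation beyond the training descriptor range and raises a
#' warning plus a per-compound flag.
#'
#' @param object A `candidate_model` carrying scaling records.
#' @param t A `descriptor_table` holding the model's terms.
#' @param ids Compound ids to predict (default: all rows of `t`).
#' @param ... Unused.
#' @return data.frame `id`, `prediction`, `extrapolated`.
#' @export
predict.candidate_model <- function(object, t, ids = NULL, ...) {
  stopifnot(inherits(t, "descriptor_table"))
  if (object$degenerate) stop("cannot predict from a degenerate model")
  if (is.null(ids)) ids <- compound_ids(t)
  ids <- as.character(ids)
  missing_ids <- setdiff(ids, compound_ids(t))
  if (length(missing_ids) > 0L)
    stop("compound(s) absent from table: ", paste(missing_ids, collapse = ", "))
  missing_terms <- setdiff(object$terms, descriptor_names(t))
  if (length(missing_terms) > 0L)
    stop("descriptor(s) absent from table: ",
         paste(missing_terms, collapse = ", "))
  raw <- if (!is.null(t$scaling)) inverse_scale(t) else t
  X <- raw$values[ids, object$terms, drop = FALSE]
  if (is.null(object$scaling) || nrow(object$scaling) < length(object$terms))
    stop("model carries no training scaling records for its terms")
  s <- object$scaling[match(object$terms, object$scaling$name), ]
  Xs <- sweep(sweep(X, 2L, s$min, "-"), 2L, s$max - s$min, "/")
  extrapolated <- apply(Xs < -1e-9 | Xs > 1 + 1e-9, 1L, any)
  if (any(extrapolated))
    warning("prediction outside the training descriptor range for: ",
            paste(ids[extrapolated], collapse = ", "))
  pred <- object$intercept +
    as.numeric(Xs %*% object$coefficients[object$terms])
  data.frame(id = ids, prediction = pred, extrapolated = extrapolated,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Back-transform coefficients to the raw descriptor scale
#'
#' On min-max scaled descriptors the fitted line y = a + sum b_i x'_i is
#' equivalent to y = a' + sum (b_i/(max_i - min_i)) x_i on the raw scale.
#'
#' @param model A `candidate_model` with scaling records.
#' @return List with `coefficients` and `intercept` on the raw scale.
#' @export
unscale_coefficients <- function(model) {
  stopifnot(inherits(model, "candidate_model"))
  if (is.null(model$scaling)) stop("model carries no scaling records")
  s <- model$scaling[match(model$terms, model$scaling$name), ]
  b_raw <- model$coefficients / (s$max - s$min)
  a_raw <- model$intercept - sum(b_raw * s$min)
  list(coefficients = stats::setNames(b_raw, model$terms),
       intercept = unname(a_raw))
}

#' Pearson correlation between two columns
#'
#' @param a,b Equal-length numeric vectors, n >= 3, both non-constant.
#' @return List with `pearson_r` and `r_squared`.
#' @export
correlate <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(a) < 1e-300 || stats::sd(b) < 1e-300)
    stop("constant input: correlation undefined")
  r <- stats::cor(a, b)
  list(pearson_r = r, r_squared = r^2)
}

#' Serialize a candidate model to JSON
#'
#' @param model A `candidate_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "candidate_model"))
  jsonlite::write_json(
    list(response = model$response_name,
         terms = model$terms,
         coefficients = as.list(model$coefficients),
         intercept = model$intercept,
         metrics = list(r2 = model$r2, mae = model$mae, rmse = model$rmse),
         n = model$n,
         scaling = model$scaling),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model back
#'
#' @param path JSON path written by [write_model_json()].
#' @return A `candidate_model` (without residual-level information).
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(terms = j$terms,
                 coefficients = stats::setNames(as.numeric(j$coefficients),
                                                j$terms),
                 intercept = j$intercept,
                 r2 = j$metrics$r2, mae = j$metrics$mae, rmse = j$metrics$rmse,
                 n = j$n, degenerate = FALSE, collinear = FALSE,
                 scaling = as.data.frame(j$scaling),
                 response_name = j$response),
            class = "candidate_model")
}
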