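# Shared helpers: tiny table builders and independent oracles.

# descriptor_table straight from a matrix of values
make_table <- function(values, ids = NULL, names = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.null(ids)) rownames(values) <- ids
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("C%02d", seq_len(nrow(values)))
  if (!is.null(names)) colnames(values) <- names
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("D%02d", seq_len(ncol(values)))
  descriptor_table(values)
}

# Independent brute-force search oracle: fits every 1-/2-descriptor model
# with lm(), computes metrics directly, and ranks with the same tie cascade
# but via an entirely separate code path.
brute_force_ranking <- function(values, y) {
  d <- ncol(values)
  sets <- c(lapply(seq_len(d), identity),
            if (d >= 2) combn(d, 2, simplify = FALSE))
  rows <- lapply(sets, function(idx) {
    df <- data.frame(y = y, values[, idx, drop = FALSE], check.names = FALSE)
    names(df) <- c("y", paste0("V", seq_along(idx)))
    fit <- lm(y ~ ., data = df)
    res <- residuals(fit)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    data.frame(terms = paste(sort(colnames(values)[idx]), collapse = " + "),
               n_terms = length(idx), r2 = r2, mae = mean(abs(res)),
               rmse = sqrt(mean(res^2)), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  # group by r2 within 1e-6, then mae, rmse, parsimony, lexical
  ord <- order(-tab$r2, tab$mae, tab$rmse, tab$n_terms, tab$terms,
               method = "radix")
  tab <- tab[ord, ]
  out <- tab[0, ]
  i <- 1
  while (i <= nrow(tab)) {
    j <- i
    while (j < nrow(tab) && abs(tab$r2[j + 1] - tab$r2[i]) < 1e-6) j <- j + 1
    grp <- tab[i:j, ]
    grp <- grp[order(grp$mae, grp$rmse, grp$n_terms, grp$terms,
                     method = "radix"), ]
    out <- rbind(out, grp)
    i <- j + 1
  }
  rownames(out) <- NULL
  out
}
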