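# Independent brute-force oracles used to check the implementation.
# These deliberately use different algorithms from the package code
# (direct normal equations, uniroot-based moment solving, triple loops).

# weighted least squares by explicit normal equations
oracle_wls <- function(y, X, w, coef = 2L) {
  W <- diag(w)
  XtWX <- t(X) %*% W %*% X
  XtWy <- t(X) %*% W %*% y
  beta <- solve(XtWX, XtWy)
  r <- y - X %*% beta
  n <- nrow(X); p <- ncol(X)
  s2 <- sum(w * r^2) / (n - p)
  covu <- solve(XtWX)
  list(beta = beta[coef], u = sqrt(covu[coef, coef]), s2 = s2)
}

# method-of-moments prior estimation solved with uniroot instead of Newton
oracle_moments <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    root <- uniroot(function(x) trigamma(x) - evar,
                    lower = 1e-6, upper = 1e8, tol = 1e-12)$root
    d0 <- 2 * root
    s0 <- exp(emean + digamma(root) - log(root))
    list(d0 = d0, s0_2 = s0, s2_post = (d0 * s0 + df * s2) / (d0 + df))
  } else {
    list(d0 = Inf, s0_2 = exp(mean(z)), s2_post = rep(exp(mean(z)), length(s2)))
  }
}

# textbook Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# topological overlap by triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# small count matrix with explicit values
make_jcm <- function(counts, ids = NULL, samples = NULL, gene = NULL) {
  counts <- as.matrix(counts)
  if (is.null(ids))
    ids <- sprintf("chr1:%d:%d:1", seq_len(nrow(counts)) * 1000L,
                   seq_len(nrow(counts)) * 1000L + 500L)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(counts)))
  dimnames(counts) <- list(ids, samples)
  m <- junction_count_matrix(counts)
  if (!is.null(gene)) m$meta$gene_id <- gene
  m
}

# minimal GTF writer: exons is a list of data frames with start, end and
# optional strand, one element per transcript; names are "gene|transcript"
write_test_gtf <- function(exons, path = tempfile(fileext = ".gtf")) {
  lines <- character()
  for (nm in names(exons)) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    ex <- exons[[nm]]
    strand <- if ("strand" %in% names(ex)) ex$strand else "+"
    lines <- c(lines, sprintf(
      "chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      ex$start, ex$end, strand, parts[1], parts[2]))
  }
  writeLines(lines, path)
  path
}

# synthetic fit/moderated pair for usage-level unit tests
make_fit <- function(beta, u, s2 = rep(1, length(beta)), df = 10) {
  structure(list(beta = beta, u = u, s2 = s2, df = rep(df, length(beta)),
                 junction_id = sprintf("j%d", seq_along(beta))),
            class = "JunctionFit")
}

make_mod <- function(fit, s2_post = rep(1, length(fit$beta)), d0 = 10) {
  structure(list(d0 = d0, s0_2 = 1, s2_post = s2_post,
                 t = rep(0, length(fit$beta)), p = rep(1, length(fit$beta)),
                 fdr = rep(1, length(fit$beta)),
                 df_total = d0 + fit$df),
            class = "ModeratedStats")
}
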