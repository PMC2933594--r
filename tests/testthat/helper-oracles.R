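# Shared fixtures and independent oracles for the test suite.
# Oracles here deliberately avoid the package's own code paths.

# a balanced 2x2x2 design built by hand (independent of the generator)
toy_design <- function(n_replicates = 3) {
  grid <- expand.grid(replicate = seq_len(n_replicates), N = 0:1, L = 0:1, G = 0:1)
  grid$sample_id <- sprintf("s%02d", seq_len(nrow(grid)))
  sample_design(grid[, c("sample_id", "N", "L", "G", "replicate")])
}

# independent per-gene 3-way ANOVA via stats::aov (treatment contrasts)
aov_oracle <- function(values, design, transform = c("log2", "identity")) {
  transform <- match.arg(transform)
  y <- if (transform == "log2") log2(values + 1) else values
  df <- data.frame(y = y, N = factor(design$N), L = factor(design$L),
                   G = factor(design$G))
  s <- summary(stats::aov(y ~ N * L * G, df))[[1]]
  rn <- trimws(rownames(s))
  map <- c(N = "N", L = "L", G = "G", "N:L" = "L:N", "L:G" = "L:G",
           "N:G" = "N:G", "N:L:G" = "N:L:G")
  out <- data.frame(term = unname(map[rn[rn != "Residuals"]]),
                    F = s[rn != "Residuals", "F value"],
                    p = s[rn != "Residuals", "Pr(>F)"])
  out[match(c("N", "L", "G", "L:N", "L:G", "N:G", "N:L:G"), out$term), ]
}

# brute-force cell-means sums-of-squares decomposition (loops, no matrix
# algebra shared with the implementation)
brute_force_anova <- function(values, design, transform = c("log2", "identity")) {
  transform <- match.arg(transform)
  y <- if (transform == "log2") log2(values + 1) else values
  cells <- split(seq_along(y), paste(design$N, design$L, design$G))
  cm <- vapply(cells, function(i) mean(y[i]), numeric(1))
  lev <- do.call(rbind, strsplit(names(cells), " "))
  storage.mode(lev) <- "integer"
  colnames(lev) <- c("N", "L", "G")
  r <- length(cells[[1]])
  terms <- list("N" = "N", "L" = "L", "G" = "G", "L:N" = c("L", "N"),
                "L:G" = c("L", "G"), "N:G" = c("N", "G"),
                "N:L:G" = c("N", "L", "G"))
  ss_res <- 0
  for (i in seq_along(cells)) ss_res <- ss_res + sum((y[cells[[i]]] - cm[i])^2)
  df_res <- length(y) - 8
  out <- data.frame(term = names(terms), F = NA_real_, p = NA_real_)
  for (k in seq_along(terms)) {
    contrast <- rep(1, 8)
    for (f in terms[[k]]) contrast <- contrast * (2 * lev[, f] - 1)
    ss <- r * sum(contrast * cm)^2 / 8
    Fv <- ss / (ss_res / df_res)
    out$F[k] <- Fv
    out$p[k] <- stats::pf(Fv, 1, df_res, lower.tail = FALSE)
  }
  out
}

# naive O(n^3) UPGMA, merging by exhaustive search over mean inter-cluster
# distances; returns the partition at k clusters
naive_upgma_cut <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  dist_between <- function(a, b) mean(d[a, b])
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- dist_between(clusters[[i]], clusters[[j]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  membership <- integer(n)
  for (i in seq_along(clusters)) membership[clusters[[i]]] <- i
  membership
}

# straightforward re-implementation of the adjusted leave-one-condition-out
# figure of merit (independent code path, same definition)
naive_fom <- function(pm, k_range) {
  z <- t(apply(pm, 1, function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0))
  n <- nrow(z)
  out <- numeric(length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    per_cond <- numeric(ncol(z))
    for (j in seq_len(ncol(z))) {
      sub <- z[, -j, drop = FALSE]
      C <- suppressWarnings(cor(t(sub)))
      C[!is.finite(C)] <- 0
      dd <- 1 - C; diag(dd) <- 0
      cl <- cutree(hclust(as.dist(dd), method = "average"), k = k)
      pred <- ave(z[, j], cl)
      per_cond[j] <- sqrt(mean((z[, j] - pred)^2))
    }
    out[ki] <- mean(per_cond) * sqrt(n / (n - k))
  }
  out
}

# exact upper-tail binomial probability by direct summation
binom_tail_sum <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
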