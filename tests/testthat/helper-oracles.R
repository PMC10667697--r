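# Independent brute-force oracles and fixture builders used across tests.

# long table for one environment from a genotype x block matrix (rows =
# genotypes); optionally several traits from a named list of matrices
toy_env_table <- function(mats, year = "2018", regime = "non-stress") {
  if (is.matrix(mats)) mats <- list(Y = mats)
  rows <- lapply(names(mats), function(tr) {
    m <- mats[[tr]]
    expand.grid(
      genotype = sprintf("G%02d", seq_len(nrow(m))),
      block = sprintf("B%d", seq_len(ncol(m))),
      stringsAsFactors = FALSE
    ) |>
      transform(year = year, regime = regime, trait = tr,
                value = as.vector(m))
  })
  phenotype_table(do.call(rbind, rows))
}

# RCBD sums of squares straight from the defining mean contrasts
brute_rcbd_ss <- function(m) {
  g <- nrow(m); r <- ncol(m)
  mu <- mean(m)
  list(
    block = g * sum((colMeans(m) - mu)^2),
    genotype = r * sum((rowMeans(m) - mu)^2),
    error = sum((m - outer(rowMeans(m), colMeans(m), `+`) + mu)^2),
    total = sum((m - mu)^2)
  )
}

# genotype / error mean cross-products for two genotype x block matrices
brute_cross_products <- function(x, y) {
  g <- nrow(x); r <- ncol(x)
  mcp_g <- r * sum((rowMeans(x) - mean(x)) * (rowMeans(y) - mean(y))) / (g - 1)
  rx <- x - outer(rowMeans(x), colMeans(x), `+`) + mean(x)
  ry <- y - outer(rowMeans(y), colMeans(y), `+`) + mean(y)
  mcp_e <- sum(rx * ry) / ((g - 1) * (r - 1))
  list(mcp_g = mcp_g, mcp_e = mcp_e,
       cov_g = (mcp_g - mcp_e) / r, cov_p = (mcp_g - mcp_e) / r + mcp_e)
}

# exhaustive ward.D2 agglomeration via the Lance-Williams recurrence on
# squared distances; returns, per merge, the sorted member labels of the
# newly formed cluster
brute_ward_d2_merges <- function(pts, distance = "manhattan") {
  d2 <- as.matrix(dist(pts, method = distance))^2
  labs <- rownames(pts)
  active <- as.list(seq_len(nrow(pts)))
  merges <- list()
  while (length(active) > 1) {
    k <- length(active)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      dij <- d2[active[[i]][1], active[[j]][1]]
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    mi <- active[[i]]; mj <- active[[j]]
    ni <- length(mi); nj <- length(mj)
    merges[[length(merges) + 1]] <- sort(labs[c(mi, mj)])
    # Lance-Williams ward.D2 update of squared inter-cluster distances,
    # stored on the first member's row/col
    for (l in seq_len(k)) {
      if (l == i || l == j) next
      ml <- active[[l]]; nl <- length(ml)
      dnew <- ((ni + nl) * d2[mi[1], ml[1]] + (nj + nl) * d2[mj[1], ml[1]] -
                 nl * d2[mi[1], mj[1]]) / (ni + nj + nl)
      d2[mi[1], ml[1]] <- d2[ml[1], mi[1]] <- dnew
    }
    active[[i]] <- c(mi, mj)
    active[[j]] <- NULL
  }
  merges
}

# merge order of an hclust tree: sorted member labels of the cluster formed
# at each merge
hclust_merges <- function(h) {
  labs <- h$labels
  members <- function(idx) {
    if (idx < 0) return(labs[-idx])
    c(members(h$merge[idx, 1]), members(h$merge[idx, 2]))
  }
  lapply(seq_len(nrow(h$merge)), function(i) sort(members(i)))
}

# best achievable R2 for every subset size, by exhaustive search
brute_best_subset_r2 <- function(y, x) {
  x <- as.data.frame(x)
  tss <- sum((y - mean(y))^2)
  vapply(seq_len(ncol(x)), function(size) {
    combos <- utils::combn(names(x), size, simplify = FALSE)
    max(vapply(combos, function(vars) {
      fit <- lm(y ~ ., data = x[vars])
      1 - sum(residuals(fit)^2) / tss
    }, numeric(1)))
  }, numeric(1))
}

# small balanced random multi-environment table
random_trial <- function(g = 4, r = 2, years = "2018", regimes = "non-stress",
                         traits = "Y", seed = 1) {
  des <- trial_design(g, r, years = years, regimes = regimes, traits = traits)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      genotype = des$genotypes, year = des$years, regime = des$regimes,
      block = des$blocks, trait = des$traits
    )
    grid$value <- rnorm(nrow(grid), 10, 2)
  })
  phenotype_table(grid, design = des)
}
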