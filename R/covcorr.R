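#' Genotypic and phenotypic (co)variance components for trait pairs
#'
#' Multivariate analogue of the expected-mean-square decomposition: mean
#' cross-products (MCP) for genotype and error are extracted from the
#' RCBD layout of one year x regime environment, and covariance components
#' follow the same moment equations as the variances,
#' `Cov_g = (MCP_g - MCP_e) / r`, `Cov_e = MCP_e`, `Cov_p = Cov_g + Cov_e`.
#' The diagonals reproduce [variance_components()] exactly (without the
#' negative-truncation policy, so matrices stay internally consistent).
#'
#' @param table A `phenotype_table`.
#' @param traits Traits to include (>= 2); default all present.
#' @param year,regime Environment selectors.
#' @return An object of class `cross_product_components`: list of matrices
#'   `mcp_g`, `mcp_e`, `cov_g`, `cov_e`, `cov_p` (traits x traits), plus
#'   `n_genotypes`, `n_blocks` and labels.
#' @export
cross_product_components <- function(table, traits = NULL, year, regime) {
  d <- as_tibble(table)
  if (is.null(traits)) traits <- unique(d$trait)
  if (length(traits) < 1) abort("need at least one trait.", class = "forageQG_design_error")
  subs <- lapply(traits, function(tr) environment_subset(table, tr, year, regime))
  wide <- Reduce(
    function(a, b) left_join(a, b, by = c("genotype", "block")),
    lapply(seq_along(traits), function(i) {
      s <- subs[[i]][c("genotype", "block", "value")]
      names(s)[3] <- traits[i]
      s
    })
  )
  if (anyNA(wide)) {
    abort("traits are not observed on identical experimental units.",
          class = "forageQG_design_error")
  }
  g <- length(unique(wide$genotype))
  r <- length(unique(wide$block))
  y <- as.matrix(wide[traits])
  full <- lm(y ~ factor(block) + factor(genotype), data = wide)
  reduced <- lm(y ~ factor(block), data = wide)
  sscp_e <- crossprod(residuals(full))
  sscp_g <- crossprod(residuals(reduced)) - sscp_e
  mcp_g <- sscp_g / (g - 1)
  mcp_e <- sscp_e / ((g - 1) * (r - 1))
  cov_g <- (mcp_g - mcp_e) / r
  cov_e <- mcp_e
  dimnames(mcp_g) <- dimnames(mcp_e) <- dimnames(cov_g) <- dimnames(cov_e) <-
    list(traits, traits)
  structure(
    list(mcp_g = mcp_g, mcp_e = mcp_e,
         cov_g = cov_g, cov_e = cov_e, cov_p = cov_g + cov_e,
         n_genotypes = g, n_blocks = r,
         traits = traits, year = as.character(year), regime = as.character(regime)),
    class = "cross_product_components"
  )
}

#' Phenotypic and genotypic correlation matrices
#'
#' `r_p(X,Y) = Cov_p(X,Y) / (sigma_p(X) * sigma_p(Y))` and analogously for
#' the genotypic correlation from the genotypic covariance components.
#' Method-of-moments genotypic correlations can exceed 1 in absolute value;
#' such entries are retained and flagged (`abs_gt1`), never silently
#' clamped.
#'
#' @param cpc A [cross_product_components()] object, or a list with `cov_p`
#'   and `cov_g` matrices.
#' @return An object of class `correlation_matrices`: list with symmetric
#'   unit-diagonal matrices `r_p` and `r_g`, a logical matrix `abs_gt1`
#'   marking out-of-range genotypic entries, and `traits`.
#' @export
correlation_matrices <- function(cpc) {
  cov_p <- cpc$cov_p
  cov_g <- cpc$cov_g
  traits <- colnames(cov_p)
  keep <- diag(cov_p) > 0 & diag(cov_g) > 0
  if (!all(keep)) {
    warn(paste0("excluding zero-variance trait(s): ",
                paste(traits[!keep], collapse = ", ")),
         class = "forageQG_zero_variance_warning")
    cov_p <- cov_p[keep, keep, drop = FALSE]
    cov_g <- cov_g[keep, keep, drop = FALSE]
    traits <- traits[keep]
  }
  if (length(traits) < 2) {
    abort("need at least two traits with positive variance.",
          class = "forageQG_design_error")
  }
  norm <- function(v) {
    s <- sqrt(diag(v))
    m <- v / tcrossprod(s)
    diag(m) <- 1
    (m + t(m)) / 2
  }
  r_p <- norm(cov_p)
  r_g <- norm(cov_g)
  structure(
    list(r_p = r_p, r_g = r_g,
         abs_gt1 = abs(r_g) > 1, traits = traits),
    class = "correlation_matrices"
  )
}

#' Trait correlations per regime, pooling years
#'
#' Convenience wrapper for the usual reporting layout of one correlation
#' matrix per irrigation regime: covariance components are estimated per
#' year within the regime, averaged across years, and converted to
#' correlations. `pool_years = FALSE` instead returns one
#' `correlation_matrices` per year.
#'
#' @inheritParams cross_product_components
#' @param regime Regime selector.
#' @param pool_years Average covariance components across years (default).
#' @return A `correlation_matrices` object, or a named list of them when
#'   `pool_years = FALSE`.
#' @export
trait_correlations <- function(table, regime, traits = NULL, pool_years = TRUE) {
  d <- as_tibble(table)
  years <- sort(unique(d$year))
  cpcs <- lapply(years, function(yr)
    cross_product_components(table, traits = traits, year = yr, regime = regime))
  if (!pool_years) {
    out <- lapply(cpcs, correlation_matrices)
    names(out) <- years
    return(out)
  }
  pooled <- cpcs[[1]]
  if (length(cpcs) > 1) {
    for (fld in c("mcp_g", "mcp_e", "cov_g", "cov_e", "cov_p")) {
      pooled[[fld]] <- Reduce(`+`, lapply(cpcs, `[[`, fld)) / length(cpcs)
    }
    pooled$year <- paste(years, collapse = "+")
  }
  correlation_matrices(pooled)
}

#' @export
print.correlation_matrices <- function(x, ...) {
  cat("<correlation_matrices> ", length(x$traits), " traits; ",
      sum(x$abs_gt1[upper.tri(x$abs_gt1)]),
      " genotypic pair(s) with |r_g| > 1\n", sep = "")
  cat("phenotypic (lower) / genotypic (upper):\n")
  m <- x$r_p
  m[upper.tri(m)] <- x$r_g[upper.tri(x$r_g)]
  print(round(m, 3))
  invisible(x)
}

#' Export paired correlation matrices as TSV
#'
#' Writes a long table with one row per trait pair and columns `r_p`,
#' `r_g`, `r_g_out_of_range`.
#'
#' @param x A [correlation_matrices()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlations <- function(x, path) {
  tr <- x$traits
  idx <- which(upper.tri(x$r_p), arr.ind = TRUE)
  out <- tibble(
    trait_x = tr[idx[, 1]], trait_y = tr[idx[, 2]],
    r_p = x$r_p[idx], r_g = x$r_g[idx],
    r_g_out_of_range = x$abs_gt1[idx]
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Paired-triangle correlation plot
#'
#' Phenotypic correlations on the lower triangle, genotypic on the upper,
#' as a tile plot. Genotypic entries beyond [-1, 1] are clamped for the
#' colour scale only and marked with an asterisk.
#'
#' @param x A [correlation_matrices()] object.
#' @return A ggplot object.
#' @export
plot_correlation_matrices <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plotting requires the ggplot2 package.")
  }
  tr <- x$traits
  k <- length(tr)
  cells <- expand_grid(i = seq_len(k), j = seq_len(k))
  cells <- filter(cells, .data$i != .data$j)
  cells <- mutate(cells,
    which = ifelse(.data$i > .data$j, "phenotypic", "genotypic"),
    r = ifelse(.data$i > .data$j,
               x$r_p[cbind(cells$i, cells$j)],
               x$r_g[cbind(cells$i, cells$j)])
  )
  cells <- mutate(cells,
    shown = pmin(pmax(.data$r, -1), 1),
    label = paste0(sprintf("%.2f", .data$r),
                   ifelse(abs(.data$r) > 1, "*", ""))
  )
  ggplot2::ggplot(cells, ggplot2::aes(x = factor(tr[.data$j], levels = tr),
                                      y = factor(tr[.data$i], levels = rev(tr)),
                                      fill = .data$shown)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "r") +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = "lower: phenotypic, upper: genotypic") +
    ggplot2::theme_minimal()
}
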