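#' Two-way clustering of accessions on their trait profiles
#'
#' Hierarchical clustering of accessions (and, for heatmap ordering, of
#' traits) on genotype-mean trait profiles: columns are z-scored so traits
#' on different measurement scales contribute comparably, distances are
#' Manhattan, and agglomeration uses the ward.D2 criterion (Ward linkage on
#' the given distances with squared updates). The accession tree is cut at
#' `n_groups`; groups are relabelled by the descending mean of their
#' standardized trait profile, so group I collects the accessions with the
#' highest overall trait values.
#'
#' @param means Genotype x trait matrix of means, or a tibble from
#'   [genotype_means()] (a `genotype` column becomes row names). No missing
#'   cells are allowed; imputation is refused.
#' @param n_groups Number of groups to extract (default 3).
#' @param scale Z-score the trait columns before distances (default TRUE).
#' @param distance Distance metric for [stats::dist()] (default
#'   `"manhattan"`).
#' @return An object of class `cluster_result`: list with `accession_tree`
#'   and `trait_tree` (hclust), `groups` (tibble: genotype, group with
#'   levels `"I"`, `"II"`, ...), `group_means` (per-group means on the
#'   original trait scale), and the scaled matrix `profile`.
#' @export
cluster_accessions <- function(means, n_groups = 3, scale = TRUE,
                               distance = "manhattan") {
  if (is.data.frame(means) && "genotype" %in% names(means)) {
    m <- as.matrix(means[setdiff(names(means), "genotype")])
    rownames(m) <- means$genotype
  } else {
    m <- as.matrix(means)
    if (is.null(rownames(m))) rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
  }
  if (anyNA(m)) {
    abort("missing cells in the trait-mean matrix; imputation is refused.",
          class = "forageQG_data_error")
  }
  if (nrow(m) < n_groups) {
    abort("need at least `n_groups` accessions.", class = "forageQG_design_error")
  }
  z <- if (scale) {
    s <- apply(m, 2, sd)
    if (any(s == 0)) {
      abort("zero-variance trait column; cannot z-score.", class = "forageQG_data_error")
    }
    base::scale(m)
  } else m

  acc_tree <- hclust(dist(z, method = distance), method = "ward.D2")
  trait_tree <- if (ncol(z) >= 2) {
    hclust(dist(t(z), method = distance), method = "ward.D2")
  } else NULL
  raw_groups <- cutree(acc_tree, k = n_groups)

  # relabel so group I has the highest mean standardized profile
  profile_score <- tapply(rowMeans(z), raw_groups, mean)
  ord <- order(profile_score, decreasing = TRUE)
  relabel <- setNames(as.roman(seq_len(n_groups)), names(profile_score)[ord])
  groups <- tibble(
    genotype = rownames(m),
    group = as.character(relabel[as.character(raw_groups)])
  )
  group_means <- as_tibble(cbind(
    tibble(group = as.character(relabel[as.character(sort(unique(raw_groups)))])),
    as.data.frame(do.call(rbind, lapply(sort(unique(raw_groups)), function(k)
      colMeans(m[raw_groups == k, , drop = FALSE]))))
  ))
  group_means <- arrange(group_means, .data$group)
  structure(
    list(accession_tree = acc_tree, trait_tree = trait_tree,
         groups = groups, group_means = group_means,
         profile = z, n_groups = n_groups,
         scaled = scale, distance = distance),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d accessions in %d group(s) (ward.D2, %s distance%s)\n",
              nrow(x$groups), x$n_groups, x$distance,
              if (x$scaled) ", z-scored traits" else ""))
  print(table(x$groups$group))
  invisible(x)
}

#' Write cluster group assignments as TSV
#'
#' @param x A [cluster_accessions()] result.
#' @param path Output path.
#' @param regime Optional regime label added as a column.
#' @return `path`, invisibly.
#' @export
write_cluster_groups <- function(x, path, regime = NULL) {
  out <- x$groups
  if (!is.null(regime)) out <- mutate(out, regime = regime, .after = "genotype")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Save a two-way cluster heatmap
#'
#' Renders the standardized genotype x trait profile as a heatmap with the
#' ward.D2/Manhattan dendrograms on both margins (via pheatmap).
#'
#' @param x A [cluster_accessions()] result.
#' @param path Output image path (extension selects the device, e.g.
#'   `.png` or `.pdf`).
#' @return `path`, invisibly.
#' @export
save_cluster_heatmap <- function(x, path) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    abort("heatmap export requires the pheatmap package.")
  }
  pheatmap::pheatmap(
    x$profile,
    cluster_rows = x$accession_tree,
    cluster_cols = if (is.null(x$trait_tree)) FALSE else x$trait_tree,
    show_rownames = nrow(x$profile) <= 60,
    filename = path, silent = TRUE
  )
  invisible(path)
}
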