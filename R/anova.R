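#' RCBD analysis of variance for one trait in one environment
#'
#' Fits the two-way (block + genotype) decomposition for a single trait in a
#' single year x irrigation-regime environment of a balanced randomized
#' complete block design. The genotype mean square carries expectation
#' `sigma_e^2 + r * sigma_g^2`, which downstream variance-component
#' estimation exploits (see [variance_components()]).
#'
#' @param table A `phenotype_table`.
#' @param trait,year,regime Labels selecting the environment subset; the
#'   subset must be a complete RCBD (every genotype once per block) with at
#'   least 2 genotypes and 2 blocks.
#' @return An object of class `rcbd_anova`: a list with `anova` (tibble of
#'   source, df, SS, MS, F, p), `n_genotypes`, `n_blocks`, `grand_mean` and
#'   the selection labels.
#' @examples
#' spec <- paper_trial_spec(n_genotypes = 10, seed = 1)
#' tab <- generate_trial(spec)
#' rcbd_anova(tab, "FY", "2018", "non-stress")
#' @export
rcbd_anova <- function(table, trait, year, regime) {
  sub <- environment_subset(table, trait, year, regime)
  g <- length(unique(sub$genotype))
  r <- length(unique(sub$block))
  if (g < 2 || r < 2) {
    abort("RCBD ANOVA needs at least 2 genotypes and 2 blocks.",
          class = "forageQG_design_error")
  }
  fit <- aov(value ~ factor(block) + factor(genotype), data = sub)
  at <- anova(fit)
  out <- tibble(
    source = c("block", "genotype", "error"),
    df = at$Df,
    ss = at$`Sum Sq`,
    ms = at$`Mean Sq`,
    f = at$`F value`,
    p = at$`Pr(>F)`
  )
  structure(
    list(
      anova = out,
      trait = trait, year = as.character(year), regime = as.character(regime),
      n_genotypes = g, n_blocks = r,
      grand_mean = mean(sub$value),
      ms_genotype = out$ms[out$source == "genotype"],
      ms_error = out$ms[out$source == "error"]
    ),
    class = "rcbd_anova"
  )
}

#' @export
print.rcbd_anova <- function(x, ...) {
  cat(sprintf("<rcbd_anova> %s | %s | %s (g = %d, r = %d, mean = %.4g)\n",
              x$trait, x$year, x$regime, x$n_genotypes, x$n_blocks, x$grand_mean))
  print(as.data.frame(x$anova), row.names = FALSE)
  invisible(x)
}

# mean of y within the named grouping columns, returned joined back per group
group_mean <- function(d, cols) {
  summarise(group_by(d, across(all_of(cols))), m = mean(.data$value), .groups = "drop")
}

#' Combined ANOVA across years and irrigation regimes
#'
#' Decomposes a balanced multi-environment RCBD trial into the sources
#' irrigation regime (Ir), replicates within regime (Error I), genotype (G),
#' Ir x G, replicate x genotype within regime (Error II), year (Y), Y x Ir,
#' Y x G, Y x G x Ir, and a pooled Residual, with blocks nested in regime.
#' F-tests follow a split-plot-in-time convention: Ir is tested against
#' Error I; G and Ir x G against Error II; the year-containing terms against
#' the Residual. The paper trail for this scheme is a convention, not an
#' identity, and is flagged as such in the output.
#'
#' @param table A `phenotype_table`, balanced over at least 2 years,
#'   2 regimes, `r` blocks and `g` genotypes.
#' @param trait Trait to analyse.
#' @return An object of class `combined_anova`: a list with `anova` (tibble
#'   of source, df, SS, MS, F, p), the design sizes and `grand_mean`.
#' @export
combined_anova <- function(table, trait) {
  d <- filter(as_tibble(table), .data$trait == !!trait)
  if (nrow(d) == 0) {
    abort(paste0("no observations for trait ", trait), class = "forageQG_design_error")
  }
  ny <- length(unique(d$year)); nm <- length(unique(d$regime))
  ng <- length(unique(d$genotype)); nr <- length(unique(d$block))
  if (ny < 2 || nm < 2) {
    abort("combined ANOVA needs at least 2 years and 2 regimes.",
          class = "forageQG_design_error")
  }
  counts <- dplyr::count(d, .data$year, .data$regime, .data$genotype, .data$block)
  if (nrow(counts) != ny * nm * ng * nr || any(counts$n != 1)) {
    abort("combined ANOVA requires a balanced table (every year x regime x genotype x block cell exactly once).",
          class = "forageQG_design_error")
  }

  mu <- mean(d$value)
  m_m   <- group_mean(d, "regime")
  m_t   <- group_mean(d, "year")
  m_g   <- group_mean(d, "genotype")
  m_mr  <- group_mean(d, c("regime", "block"))
  m_mg  <- group_mean(d, c("regime", "genotype"))
  m_tm  <- group_mean(d, c("year", "regime"))
  m_tg  <- group_mean(d, c("year", "genotype"))
  m_mrg <- group_mean(d, c("regime", "block", "genotype"))
  m_tmg <- group_mean(d, c("year", "regime", "genotype"))

  lk <- function(x, by) left_join(x, by, by = intersect(names(x), names(by)))

  ss_ir <- ny * nr * ng * sum((m_m$m - mu)^2)
  ss_e1 <- ny * ng * sum((lk(m_mr, rename(m_m, mm = "m"))$m -
                          lk(m_mr, rename(m_m, mm = "m"))$mm)^2)
  ss_g  <- ny * nm * nr * sum((m_g$m - mu)^2)
  tmp <- lk(lk(m_mg, rename(m_m, mm = "m")), rename(m_g, mg = "m"))
  ss_irg <- ny * nr * sum((tmp$m - tmp$mm - tmp$mg + mu)^2)
  tmp <- lk(lk(lk(m_mrg, rename(m_mr, mmr = "m")), rename(m_mg, mmg = "m")),
            rename(m_m, mm = "m"))
  ss_e2 <- ny * sum((tmp$m - tmp$mmr - tmp$mmg + tmp$mm)^2)
  ss_y  <- nm * nr * ng * sum((m_t$m - mu)^2)
  tmp <- lk(lk(m_tm, rename(m_t, mt = "m")), rename(m_m, mm = "m"))
  ss_yir <- nr * ng * sum((tmp$m - tmp$mt - tmp$mm + mu)^2)
  tmp <- lk(lk(m_tg, rename(m_t, mt = "m")), rename(m_g, mg = "m"))
  ss_yg <- nm * nr * sum((tmp$m - tmp$mt - tmp$mg + mu)^2)
  tmp <- lk(lk(lk(lk(lk(lk(m_tmg,
         rename(m_tm, mtm = "m")), rename(m_tg, mtg = "m")),
         rename(m_mg, mmg = "m")), rename(m_t, mt = "m")),
         rename(m_m, mm = "m")), rename(m_g, mg = "m"))
  ss_ygir <- nr * sum((tmp$m - tmp$mtm - tmp$mtg - tmp$mmg +
                       tmp$mt + tmp$mm + tmp$mg - mu)^2)
  ss_tot <- sum((d$value - mu)^2)
  ss_res <- ss_tot - (ss_ir + ss_e1 + ss_g + ss_irg + ss_e2 +
                      ss_y + ss_yir + ss_yg + ss_ygir)
  ss_res <- max(ss_res, 0)  # guards tiny negative round-off on constant data

  src <- c("Ir", "Error I", "G", "Ir x G", "Error II",
           "Y", "Y x Ir", "Y x G", "Y x G x Ir", "Residual")
  df <- c(nm - 1, nm * (nr - 1), ng - 1, (nm - 1) * (ng - 1),
          nm * (nr - 1) * (ng - 1), ny - 1, (ny - 1) * (nm - 1),
          (ny - 1) * (ng - 1), (ny - 1) * (nm - 1) * (ng - 1),
          (ny - 1) * nm * (nr - 1) * ng)
  ss <- c(ss_ir, ss_e1, ss_g, ss_irg, ss_e2, ss_y, ss_yir, ss_yg, ss_ygir, ss_res)
  ms <- ss / df
  # denominator per source: Error I for Ir; Error II for G, Ir x G;
  # Residual for the year-containing terms; none for the error strata
  den <- c("Error I", NA, "Error II", "Error II", NA,
           "Residual", "Residual", "Residual", "Residual", NA)
  fval <- pval <- rep(NA_real_, length(src))
  for (i in seq_along(src)) {
    if (!is.na(den[i])) {
      j <- match(den[i], src)
      fval[i] <- ms[i] / ms[j]
      pval[i] <- pf(fval[i], df[i], df[j], lower.tail = FALSE)
    }
  }
  structure(
    list(
      anova = tibble(source = src, df = as.integer(df), ss = ss, ms = ms,
                     f = fval, p = pval),
      trait = trait, n_years = ny, n_regimes = nm,
      n_genotypes = ng, n_blocks = nr, grand_mean = mu,
      f_test_convention = "split-plot-in-time (Ir vs Error I; G, Ir x G vs Error II; year terms vs Residual)"
    ),
    class = "combined_anova"
  )
}

#' @export
print.combined_anova <- function(x, ...) {
  cat(sprintf("<combined_anova> %s (g = %d, r = %d, %d years, %d regimes)\n",
              x$trait, x$n_genotypes, x$n_blocks, x$n_years, x$n_regimes))
  print(as.data.frame(x$anova), row.names = FALSE)
  cat("F-test denominators:", x$f_test_convention, "\n")
  invisible(x)
}

#' Export an ANOVA table to TSV or JSON
#'
#' @param x An `rcbd_anova` or `combined_anova` object.
#' @param path Output path; `.json` writes JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_anova <- function(x, path) {
  stopifnot(inherits(x, c("rcbd_anova", "combined_anova")))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x$anova, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(x$anova, path)
  }
  invisible(path)
}
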