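#' Genotype-mean trait matrix for one regime
#'
#' Builds the genotype x trait matrix of means used by the regression and
#' clustering stages: plot values are averaged per genotype within the
#' regime, pooling years by default.
#'
#' @param table A `phenotype_table`.
#' @param regime Regime selector.
#' @param traits Traits to include; default all present.
#' @param years Years to pool; default all present.
#' @return A tibble with a `genotype` column and one numeric column per
#'   trait.
#' @export
genotype_means <- function(table, regime, traits = NULL, years = NULL) {
  d <- filter(as_tibble(table), .data$regime == !!as.character(regime))
  if (nrow(d) == 0) abort(paste0("no observations for regime ", regime),
                          class = "forageQG_design_error")
  if (!is.null(traits)) d <- filter(d, .data$trait %in% traits)
  if (!is.null(years)) d <- filter(d, .data$year %in% as.character(years))
  wide <- summarise(group_by(d, .data$genotype, .data$trait),
                    value = mean(.data$value), .groups = "drop")
  pivot_wider(wide, names_from = "trait", values_from = "value")
}

partial_f <- function(rss0, rss1, df1) {
  # F for a 1-df comparison of nested least-squares fits
  f <- (rss0 - rss1) / (rss1 / df1)
  p <- pf(f, 1, df1, lower.tail = FALSE)
  list(f = f, p = p)
}

#' Stepwise multiple regression with partial R2 accounting
#'
#' Classic forward-selection-with-backward-elimination stepwise on least
#' squares, the procedure behind the familiar "variable entered / partial
#' R2 / model R2 / F" regression tables of trait-association studies. At
#' each step the candidate with the largest partial F enters if its p-value
#' is below `alpha_enter`; after each entry, already-entered variables whose
#' partial p-value (given the rest of the model) exceeds `alpha_stay` are
#' removed, worst first. Iteration stops when no entry or removal occurs.
#'
#' Candidates whose addition leaves the model numerically rank-deficient
#' (near-collinear with the entered set) are skipped with a warning.
#'
#' @param response Numeric response vector, or the name of a column in
#'   `predictors` when `predictors` is a data frame containing it.
#' @param predictors Data frame or matrix of candidate predictors.
#' @param alpha_enter,alpha_stay Entry/stay significance levels
#'   (defaults 0.15, the classic stepwise convention).
#' @param max_steps Safety bound on iterations.
#' @return An object of class `stepwise_result`: list with `steps` (tibble:
#'   step, action, variable, estimate, partial_r2, model_r2, f, p),
#'   `selected`, `model` (the final `lm`), `intercept`, `r2`.
#' @examples
#' set.seed(1)
#' d <- data.frame(gs = runif(40, 0.1, 0.3), A = runif(40, 8, 16))
#' y <- 1000 * d$gs + 30 * d$A + rnorm(40, sd = 20)
#' stepwise_regression(y, d)
#' @export
stepwise_regression <- function(response, predictors,
                                alpha_enter = 0.15, alpha_stay = 0.15,
                                max_steps = 50L) {
  x <- as.data.frame(predictors)
  if (is.character(response) && length(response) == 1) {
    stopifnot(response %in% names(x))
    y <- x[[response]]
    x <- x[setdiff(names(x), response)]
  } else {
    y <- as.numeric(response)
  }
  n <- length(y)
  if (nrow(x) != n) abort("response and predictors differ in length.",
                          class = "forageQG_design_error")
  constant <- vapply(x, function(v) var(v) == 0, logical(1))
  if (any(constant)) {
    abort(paste0("constant predictor(s): ", paste(names(x)[constant], collapse = ", ")),
          class = "forageQG_design_error")
  }
  if (n <= ncol(x) + 2) {
    abort("need more observations than candidate predictors + 2.",
          class = "forageQG_design_error")
  }

  rss <- function(vars) {
    if (length(vars) == 0) return(sum((y - mean(y))^2))
    fit <- lm(y ~ ., data = x[vars])
    sum(residuals(fit)^2)
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) abort("response is constant.", class = "forageQG_design_error")

  entered <- character(0)
  steps <- list()
  step_no <- 0L
  repeat {
    if (step_no >= max_steps) break
    changed <- FALSE
    candidates <- setdiff(names(x), entered)
    rss_cur <- rss(entered)
    if (length(candidates) > 0 && rss_cur > 0) {
      best <- NULL
      for (v in candidates) {
        vars <- c(entered, v)
        qx <- qr(cbind(1, as.matrix(x[vars])))
        if (qx$rank < length(vars) + 1) {
          warn(paste0("skipping near-collinear candidate: ", v),
               class = "forageQG_collinearity_warning")
          next
        }
        rss_new <- rss(vars)
        pf1 <- partial_f(rss_cur, rss_new, n - length(vars) - 1)
        if (is.null(best) || pf1$f > best$f) {
          best <- list(var = v, rss = rss_new, f = pf1$f, p = pf1$p)
        }
      }
      if (!is.null(best) && !is.na(best$p) && best$p < alpha_enter) {
        entered <- c(entered, best$var)
        step_no <- step_no + 1L
        model_r2 <- 1 - best$rss / tss
        prev_r2 <- 1 - rss_cur / tss
        fit <- lm(y ~ ., data = x[entered])
        steps[[length(steps) + 1]] <- tibble(
          step = step_no, action = "enter", variable = best$var,
          estimate = coef(fit)[[best$var]],
          partial_r2 = model_r2 - prev_r2, model_r2 = model_r2,
          f = best$f, p = best$p
        )
        changed <- TRUE
      }
    }
    # backward check: drop entered variables no longer significant
    repeat {
      if (length(entered) < 1) break
      rss_full <- rss(entered)
      drops <- lapply(entered, function(v) {
        rest <- setdiff(entered, v)
        partial_f(rss(rest), rss_full, n - length(entered) - 1)
      })
      ps <- vapply(drops, `[[`, numeric(1), "p")
      if (all(ps <= alpha_stay, na.rm = TRUE)) break
      worst <- which.max(ps)
      v <- entered[worst]
      prev_r2 <- 1 - rss_full / tss
      entered <- setdiff(entered, v)
      step_no <- step_no + 1L
      model_r2 <- 1 - rss(entered) / tss
      steps[[length(steps) + 1]] <- tibble(
        step = step_no, action = "remove", variable = v,
        estimate = NA_real_,
        partial_r2 = model_r2 - prev_r2, model_r2 = model_r2,
        f = drops[[worst]]$f, p = drops[[worst]]$p
      )
      changed <- TRUE
    }
    if (!changed) break
  }

  final <- if (length(entered) > 0) lm(y ~ ., data = x[entered]) else lm(y ~ 1)
  steps_tbl <- if (length(steps) > 0) bind_rows(steps) else
    tibble(step = integer(), action = character(), variable = character(),
           estimate = double(), partial_r2 = double(), model_r2 = double(),
           f = double(), p = double())
  # refresh coefficient estimates to the final model
  if (nrow(steps_tbl) > 0) {
    cf <- coef(final)
    steps_tbl$estimate <- ifelse(steps_tbl$variable %in% names(cf) &
                                   steps_tbl$action == "enter",
                                 cf[steps_tbl$variable], steps_tbl$estimate)
  }
  structure(
    list(
      steps = steps_tbl, selected = entered, model = final,
      intercept = coef(final)[["(Intercept)"]],
      r2 = 1 - sum(residuals(final)^2) / tss,
      alpha_enter = alpha_enter, alpha_stay = alpha_stay
    ),
    class = "stepwise_result"
  )
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise_result> %d variable(s) selected, model R2 = %.4f\n",
              length(x$selected), x$r2))
  if (nrow(x$steps) > 0) print(as.data.frame(x$steps), row.names = FALSE)
  cat(sprintf("intercept: %.4g\n", x$intercept))
  invisible(x)
}

#' Export a stepwise result as TSV
#'
#' Columns mirror the conventional stepwise report: variable entered,
#' parameter estimate, partial R2, model R2, F and p, with a final
#' intercept row.
#'
#' @param x A [stepwise_regression()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stepwise <- function(x, path) {
  out <- bind_rows(
    x$steps,
    tibble(step = NA_integer_, action = "intercept", variable = "(Intercept)",
           estimate = x$intercept, partial_r2 = NA_real_,
           model_r2 = x$r2, f = NA_real_, p = NA_real_)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
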