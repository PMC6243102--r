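#' Collinearity diagnostics for a fitted design
#'
#' `vif_values()` returns the variance inflation factor of each predictor
#' (1 / (1 - R^2) of that predictor regressed on the others; 1 for a single
#' predictor). `condition_index()` returns the Belsley condition index of the
#' intercept-included design matrix: columns scaled to unit length, then the
#' ratio of the largest to the smallest singular value.
#'
#' @param X Numeric matrix or data frame of predictors (no intercept column).
#' @return A named numeric vector (`vif_values`) or a single number
#'   (`condition_index`).
#' @export
vif_values <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) return(setNames(rep(1, ncol(X)), colnames(X)))
  R <- cor(X)
  setNames(diag(solve(R)), colnames(X))
}

#' @rdname vif_values
#' @export
condition_index <- function(X) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  X <- sweep(X, 2L, sqrt(colSums(X^2)), "/")
  d <- svd(X, nu = 0, nv = 0)$d
  max(d) / min(d)
}

#' Stepwise regression of chronological order with collinearity gates
#'
#' Bidirectional p-value stepwise selection regressing a musician's
#' chronological ordering (1 = earliest piece) on candidate predictors --
#' per-piece TPs of the musician's highest-probability patterns, or per-piece
#' conditional entropies. At each step the candidate with the smallest
#' coefficient p-value enters if that p-value is at most `p_enter` *and* the
#' resulting model stays free of collinearity (every VIF below `vif_max` and
#' the intercept-included condition index below `ci_max`); after each entry,
#' any retained predictor whose p-value exceeds `p_remove` is dropped. An
#' empty model ("no significant regression equation") is a valid result.
#'
#' @param data Tibble containing the response and predictor columns.
#' @param response Column name of the chronological index; its values must be
#'   a permutation of `1..n`.
#' @param predictors Character vector of candidate predictor column names.
#' @param p_enter,p_remove Entry / removal p-value thresholds (0.05, 0.10).
#' @param vif_max,ci_max Collinearity gates (VIF < 2, condition index < 20).
#' @return An object of class `tp_stepwise`: `selected` (term, B, SE,
#'   standardized beta, VIF, t, p per retained predictor), `model_stats`
#'   (adjusted R^2, F, p, condition index), and the final `fit` (or NULL).
#'   `tidy()` returns the coefficient table, `glance()` the model stats.
#' @examples
#' d <- tibble::tibble(chron = 1:7, x = (1:7) / 10 + 0.2)
#' stepwise_tp(d, "chron", "x")
#' @export
stepwise_tp <- function(data, response, predictors,
                        p_enter = 0.05, p_remove = 0.10,
                        vif_max = 2, ci_max = 20) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)))
  y <- as.numeric(data[[response]])
  n <- length(y)
  if (n < 3L) abort("Need at least 3 observations.")
  if (!isTRUE(all.equal(sort(y), as.numeric(seq_len(n))))) {
    abort("`response` must be a permutation of 1..n (a chronological ordering).")
  }
  X <- data[predictors]
  if (any(!vapply(X, function(v) all(is.finite(v)), logical(1)))) {
    abort("Predictors must be finite.")
  }
  predictors <- lex_sort(predictors)

  # fit on safe positional names so non-syntactic pattern strings (brackets,
  # commas) never meet the formula parser
  fit_on <- function(vars) {
    df <- setNames(as.data.frame(X[vars]),
                   paste0("x", match(vars, predictors)))
    df$..y <- y
    lm(..y ~ ., data = df)
  }
  coef_p <- function(fit, var) {
    cf <- suppressWarnings(summary(fit))$coefficients
    nm <- paste0("x", match(var, predictors))
    if (!nm %in% rownames(cf)) return(NA_real_)
    cf[nm, "Pr(>|t|)"]
  }

  in_model <- character(0)
  repeat {
    changed <- FALSE
    # entry scan
    candidates <- setdiff(predictors, in_model)
    candidates <- candidates[vapply(X[candidates], sd, numeric(1)) > 0]
    if (length(candidates) > 0L && length(in_model) < n - 2L) {
      scan <- purrr::map(candidates, function(cand) {
        trial <- c(in_model, cand)
        p <- coef_p(fit_on(trial), cand)
        tibble(cand = cand, p = p,
               vif = max(vif_values(X[trial])),
               ci = condition_index(X[trial]))
      }) |> purrr::list_rbind()
      ok <- scan |>
        dplyr::filter(is.finite(.data$p), .data$p <= p_enter,
                      .data$vif < vif_max, .data$ci < ci_max) |>
        dplyr::arrange(.data$p, .data$cand)
      if (nrow(ok) > 0L) {
        in_model <- c(in_model, ok$cand[1])
        changed <- TRUE
      }
    }
    # removal scan
    if (length(in_model) > 0L) {
      pv <- vapply(in_model, function(v) coef_p(fit_on(in_model), v), numeric(1))
      if (any(pv > p_remove)) {
        in_model <- in_model[-which.max(pv)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  if (length(in_model) == 0L) {
    res <- list(selected = tibble(term = character(), estimate = numeric(),
                                  std.error = numeric(), beta = numeric(),
                                  vif = numeric(), statistic = numeric(),
                                  p.value = numeric()),
                model_stats = tibble(adj_r_squared = NA_real_,
                                     statistic = NA_real_, p.value = NA_real_,
                                     condition_index = NA_real_,
                                     n_predictors = 0L, n_obs = n),
                fit = NULL, response = response)
    return(structure(res, class = "tp_stepwise"))
  }

  fit <- fit_on(in_model)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients[paste0("x", match(in_model, predictors)), , drop = FALSE]
  vifs <- vif_values(X[in_model])
  betas <- cf[, "Estimate"] *
    vapply(X[in_model], sd, numeric(1)) / sd(y)
  fstat <- sm$fstatistic
  selected <- tibble(
    term = in_model,
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]),
    beta = unname(betas),
    vif = unname(vifs),
    statistic = unname(cf[, "t value"]),
    p.value = unname(cf[, "Pr(>|t|)"])
  )
  model_stats <- tibble(
    adj_r_squared = sm$adj.r.squared,
    statistic = unname(fstat[1]),
    p.value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    condition_index = condition_index(X[in_model]),
    n_predictors = length(in_model), n_obs = n
  )
  structure(list(selected = selected, model_stats = model_stats, fit = fit,
                 response = response),
            class = "tp_stepwise")
}

#' @export
print.tp_stepwise <- function(x, ...) {
  if (nrow(x$selected) == 0L) {
    cat("<tp_stepwise> no significant regression equation\n")
  } else {
    cat(sprintf("<tp_stepwise> %d predictor(s); adj R^2 = %.2f, F = %.2f, p = %.4g\n",
                nrow(x$selected), x$model_stats$adj_r_squared,
                x$model_stats$statistic, x$model_stats$p.value))
    print(as.data.frame(x$selected), digits = 4)
  }
  invisible(x)
}

#' @rdname stepwise_tp
#' @param x,object A `tp_stepwise` object.
#' @param ... Unused.
#' @export
tidy.tp_stepwise <- function(x, ...) x$selected

#' @rdname stepwise_tp
#' @export
glance.tp_stepwise <- function(x, ...) x$model_stats
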