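#' Assemble a design matrix for outcome modeling
#'
#' Selects covariate columns by timing (`ex_ante`: knowable before the
#' intervention; `post_hoc`: measured after it) and scope (procedural,
#' community diversity, metabolic, species abundance, focal-species
#' characteristics, other species' outcomes), one-hot encodes categorical
#' covariates (each level an independent indicator), drops constant columns
#' with a warning, and appends a missingness indicator for every column with
#' missing values. Missing values themselves are left in place: they are
#' median-imputed per training fold inside [fit_lasso_cv()], and
#' standardization likewise happens on training folds only, so no information
#' leaks from validation folds. The response column is never part of the
#' design.
#'
#' @param covariates Tibble with one row per FMT (or species-by-FMT event).
#' @param tags Tibble describing the covariates: columns `column`, `timing`
#'   (`ex_ante`/`post_hoc`), `scope`. Every covariate must have exactly one
#'   tag row.
#' @param response Name of the response column in `covariates`.
#' @param timing Optional filter: keep only covariates with this timing.
#' @param scope Optional filter: keep only covariates with this scope
#'   (`"all"` or `NULL` keeps everything).
#' @return A list with `x` (numeric matrix, possibly containing `NA`), `y`
#'   (response vector) and `columns` (tibble mapping matrix columns to source
#'   covariates).
#' @export
build_design <- function(covariates, tags, response,
                         timing = NULL, scope = NULL) {
  if (!response %in% names(covariates)) abort("response column not found")
  tags <- as_tibble(tags)
  if (!all(c("column", "timing", "scope") %in% names(tags))) {
    abort("tags needs columns: column, timing, scope")
  }
  if (response %in% tags$column) {
    abort("the response must not appear among the tagged covariates")
  }
  if (anyDuplicated(tags$column) > 0) abort("each covariate needs exactly one tag")
  keep <- tags
  if (!is.null(timing)) keep <- keep |> filter(.data$timing == .env$timing)
  if (!is.null(scope) && !identical(scope, "all")) {
    keep <- keep |> filter(.data$scope == .env$scope)
  }
  miss <- setdiff(keep$column, names(covariates))
  if (length(miss) > 0) abort(paste0("tagged covariates absent from data: ",
                                     paste(miss, collapse = ", ")))
  y <- covariates[[response]]
  ok <- !is.na(y)
  dat <- covariates[ok, keep$column, drop = FALSE]
  y <- y[ok]

  cols <- list(); names_out <- character(); src <- character()
  for (cn in keep$column) {
    v <- dat[[cn]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      v <- as.factor(v)
      for (lv in levels(v)) {
        cols[[length(cols) + 1]] <- as.numeric(v == lv)
        names_out <- c(names_out, paste0(cn, "=", lv))
        src <- c(src, cn)
      }
    } else {
      cols[[length(cols) + 1]] <- as.numeric(v)
      names_out <- c(names_out, cn)
      src <- c(src, cn)
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names_out

  # missingness indicators, then drop zero-variance columns
  has_na <- which(colSums(is.na(x)) > 0)
  for (j in has_na) {
    x <- cbind(x, as.numeric(is.na(x[, j])))
    colnames(x)[ncol(x)] <- paste0(names_out[j], "_missing")
    src <- c(src, src[j])
  }
  v <- apply(x, 2, function(col) var(col[!is.na(col)]))
  const <- which(is.na(v) | v == 0)
  if (length(const) > 0) {
    warn(paste0("dropping constant columns: ",
                paste(colnames(x)[const], collapse = ", ")))
    x <- x[, -const, drop = FALSE]
    src <- src[-const]
  }
  list(
    x = x, y = y,
    columns = tibble(column = colnames(x), source = src) |>
      left_join(keep, by = c(source = "column"))
  )
}

#' Species eligible for per-species outcome models
#'
#' Per-species models are only fit for species observed in at least
#' `min_fmts` FMT time series, for sufficient statistical power.
#'
#' @param records Outcome records across a cohort.
#' @param min_fmts Minimum number of FMTs (default 50).
#' @return Character vector of eligible species.
#' @export
eligible_species <- function(records, min_fmts = 50L) {
  records |>
    distinct(.data$species_id, .data$fmt_id) |>
    count(.data$species_id) |>
    filter(.data$n >= min_fmts) |>
    pull("species_id")
}

#' Repeated cross-validated LASSO regression
#'
#' Fits `repeats` (default 10) rounds of `folds`-fold (default 5)
#' cross-validated LASSO-regularized regression. The lambda path (100 values,
#' log-spaced over four decades below the smallest lambda that zeroes all
#' coefficients) is fixed once; within each repeat, training folds are
#' median-imputed and standardized (zero mean, unit variance) using training
#' statistics only, the validation fold is transformed with those statistics,
#' and the cross-validation curve selects the largest lambda within one
#' standard error of the minimum. Coefficients are taken from each training
#' fold's fit at that per-repeat one-standard-error lambda and averaged over
#' all repeats x folds; performance is the held-out R-squared (linear) or
#' AUROC (logistic), averaged over the same folds. Identical seeds give
#' identical results.
#'
#' @param x Numeric design matrix (may contain `NA`; see [build_design()]).
#' @param y Response vector; for `family = "logistic"` a two-level (0/1 or
#'   logical) vector with both classes present.
#' @param family `"linear"` or `"logistic"`.
#' @param folds,repeats Cross-validation layout.
#' @param seed Integer seed controlling fold assignment.
#' @param nlambda,lambda_min_ratio Lambda path parameters.
#' @return A `model_result` list: `family`, `performance` (mean over held-out
#'   folds), `performance_folds`, `lambda_selected` (per repeat),
#'   `coefficients` (named fold-averaged vector including zeros and the
#'   intercept, on the standardized scale), `folds`, `repeats`, `n`, `seed`.
#' @export
fit_lasso_cv <- function(x, y, family = c("linear", "logistic"),
                         folds = 5L, repeats = 10L, seed = 1L,
                         nlambda = 100L, lambda_min_ratio = 1e-4) {
  family <- match.arg(family)
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) abort("x and y disagree on the number of rows")
  if (family == "logistic") {
    y <- as.numeric(as.logical(y))
    if (length(unique(y)) < 2) abort("logistic regression needs both classes")
  } else {
    y <- as.numeric(y)
  }
  glmnet_family <- if (family == "linear") "gaussian" else "binomial"

  # fixed lambda path from the full data (standardized once, imputed with
  # overall medians — used only to anchor the path, not for any fit score)
  x0 <- .impute_standardize(x, x)$train
  path_fit <- glmnet::glmnet(x0, y, family = glmnet_family,
                             nlambda = nlambda,
                             lambda.min.ratio = lambda_min_ratio,
                             standardize = FALSE)
  lambda_path <- path_fit$lambda

  set.seed(seed)
  coefs <- matrix(0, nrow = ncol(x) + 1, ncol = 0)
  perf <- numeric(0)
  lambda_sel <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold_id <- .make_folds(y, folds, stratify = family == "logistic")
    fits <- vector("list", folds)
    cv_err <- matrix(NA_real_, nrow = folds, ncol = length(lambda_path))
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      std <- .impute_standardize(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
      fit <- glmnet::glmnet(std$train, y[tr], family = glmnet_family,
                            lambda = lambda_path, standardize = FALSE)
      fits[[k]] <- list(fit = fit, test_x = std$test, test_y = y[!tr])
      pred <- predict(fit, std$test, s = lambda_path,
                      type = if (family == "linear") "response" else "response")
      err <- if (family == "linear") {
        colMeans((fits[[k]]$test_y - pred)^2)
      } else {
        p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
        -2 * colMeans(fits[[k]]$test_y * log(p) + (1 - fits[[k]]$test_y) * log(1 - p))
      }
      cv_err[k, seq_along(err)] <- err
    }
    cvm <- colMeans(cv_err)
    cvsd <- apply(cv_err, 2, sd) / sqrt(folds)
    i_min <- which.min(cvm)
    i_1se <- which(cvm <= cvm[i_min] + cvsd[i_min])[1]  # largest such lambda
    lam <- lambda_path[i_1se]
    lambda_sel[r] <- lam
    for (k in seq_len(folds)) {
      fk <- fits[[k]]
      cf <- as.numeric(predict(fk$fit, s = lam, type = "coefficients",
                               exact = FALSE))
      coefs <- cbind(coefs, cf)
      pr <- as.numeric(predict(fk$fit, fk$test_x, s = lam, type = "response"))
      perf <- c(perf, .fold_performance(fk$test_y, pr, family))
    }
  }
  avg <- rowMeans(coefs)
  names(avg) <- c("(Intercept)", colnames(x))
  structure(
    list(
      family = family,
      performance = mean(perf, na.rm = TRUE),
      performance_folds = perf,
      lambda_selected = lambda_sel,
      coefficients = avg,
      folds = folds, repeats = repeats, n = n, seed = seed
    ),
    class = "model_result"
  )
}

#' @export
print.model_result <- function(x, ...) {
  metric <- if (x$family == "linear") "R2" else "AUROC"
  nz <- sum(x$coefficients[-1] != 0)
  cat(sprintf(
    "<%s LASSO, %dx%d-fold CV (n = %d): mean held-out %s = %.3f, %d nonzero coefficients>\n",
    x$family, x$repeats, x$folds, x$n, metric, x$performance, nz
  ))
  invisible(x)
}

# Internal: fold assignment; stratified by class for logistic responses so
# every training fold sees both classes.
.make_folds <- function(y, folds, stratify) {
  n <- length(y)
  fold_id <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  } else {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
  }
  fold_id
}

# Internal: median-impute then center/scale using training statistics only.
.impute_standardize <- function(train, test) {
  med <- apply(train, 2, function(v) median(v, na.rm = TRUE))
  med[is.na(med)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  train <- fill(train); test <- fill(test)
  mu <- colMeans(train)
  sg <- apply(train, 2, sd)
  sg[sg == 0 | is.na(sg)] <- 1  # constant-in-fold columns pass through centered
  list(
    train = scale(train, center = mu, scale = sg),
    test = scale(test, center = mu, scale = sg)
  )
}

# Internal: held-out performance for one validation fold.
.fold_performance <- function(y_true, y_pred, family) {
  if (family == "linear") {
    sst <- sum((y_true - mean(y_true))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((y_true - y_pred)^2) / sst
  } else {
    if (length(unique(y_true)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y_true, y_pred, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }
}

#' Variable importance across per-species models
#'
#' Combines fold-averaged LASSO coefficients with overall model performance:
#' the importance of predictor j for species s is the averaged coefficient
#' weighted by the model's performance above chance, so less predictive
#' models penalize importance. For logistic models the weight is
#' `max(AUROC - 0.5, 0) / 0.5` (a model at chance contributes nothing); for
#' linear models it is `max(R2, 0)`. Predictors zeroed out in a model
#' produce no edge; the aggregated importance of a predictor is its mean
#' signed importance over all models.
#'
#' @param results Named list of `model_result` objects, one per response
#'   (e.g. per species).
#' @return A list with `edges` (tibble `response`, `predictor`, `coefficient`,
#'   `weight`, `importance`, `sign`) and `aggregate` (tibble `predictor`,
#'   `importance` averaged across models, `n_models`).
#' @export
variable_importance <- function(results) {
  if (length(results) == 0) abort("no model results supplied")
  if (is.null(names(results))) names(results) <- paste0("model_", seq_along(results))
  edges <- purrr::imap_dfr(results, function(m, nm) {
    w <- if (m$family == "logistic") {
      max(m$performance - 0.5, 0) / 0.5
    } else {
      max(m$performance, 0)
    }
    cf <- m$coefficients[-1]  # drop intercept
    nz <- cf[cf != 0]
    if (length(nz) == 0 || w == 0) {
      return(tibble(response = character(), predictor = character(),
                    coefficient = numeric(), weight = numeric(),
                    importance = numeric(), sign = integer()))
    }
    tibble(
      response = nm, predictor = names(nz), coefficient = unname(nz),
      weight = w, importance = unname(nz) * w, sign = as.integer(sign(nz))
    )
  })
  all_pred <- unique(unlist(lapply(results, function(m) names(m$coefficients)[-1])))
  agg <- purrr::map_dfr(all_pred, function(p) {
    imp <- purrr::map_dbl(results, function(m) {
      w <- if (m$family == "logistic") max(m$performance - 0.5, 0) / 0.5 else max(m$performance, 0)
      cf <- m$coefficients[p]
      if (is.na(cf)) 0 else unname(cf) * w
    })
    tibble(predictor = p, importance = mean(imp), n_models = length(imp))
  })
  list(edges = edges, aggregate = agg |> arrange(desc(abs(.data$importance))))
}
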