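# Lasso regression of uORF regulatory effects on codon-identity features.

#' Encode variant codon composition as indicator features
#'
#' Three encodings of a 3-position variant design:
#' \describe{
#'   \item{\code{codon_position}}{one indicator per (codon, position); every
#'     row sums to 3. Column order is position-major, codon-alphabetical
#'     (\code{AAA.p1, AAC.p1, ..., AAA.p2, ...}).}
#'   \item{\code{codon}}{one presence indicator per codon (1 if the codon
#'     occurs at any varied position); rows sum to the number of distinct
#'     codons in the variant (1-3).}
#'   \item{\code{aa_position}}{one indicator per (amino acid, position)
#'     under the standard genetic code.}
#' }
#' An optional numeric column (e.g. predicted 5'-leader folding energy) is
#' appended z-scored under the name \code{mfe}.
#'
#' @param x A table with \code{codon1..3} columns (an effects table or the
#'   AUG rows of a library).
#' @param encoding One of \code{"codon_position"}, \code{"codon"},
#'   \code{"aa_position"}.
#' @param mfe Optional numeric vector (one value per row of \code{x}).
#' @return Numeric matrix with an \code{"encoding"} attribute.
#' @export
encode_features <- function(x, encoding = c("codon_position", "codon",
                                            "aa_position"), mfe = NULL) {
  encoding <- match.arg(encoding)
  stopifnot(all(c("codon1", "codon2", "codon3") %in% names(x)))
  cods <- cbind(x$codon1, x$codon2, x$codon3)
  n <- nrow(cods)

  if (encoding == "codon_position") {
    alphabet <- sort(unique(as.vector(cods)))
    m <- matrix(0L, n, 3L * length(alphabet))
    colnames(m) <- paste0(rep(alphabet, times = 3L), ".p",
                          rep(1:3, each = length(alphabet)))
    for (p in 1:3)
      for (cod in alphabet)
        m[, paste0(cod, ".p", p)] <- as.integer(cods[, p] == cod)
  } else if (encoding == "codon") {
    alphabet <- sort(unique(as.vector(cods)))
    m <- matrix(0L, n, length(alphabet))
    colnames(m) <- alphabet
    for (cod in alphabet)
      m[, cod] <- as.integer(cods[, 1L] == cod | cods[, 2L] == cod |
                               cods[, 3L] == cod)
  } else {
    aas <- matrix(translate_codon(as.vector(cods)), ncol = 3L)
    alphabet <- sort(unique(as.vector(aas)))
    m <- matrix(0L, n, 3L * length(alphabet))
    colnames(m) <- paste0(rep(alphabet, times = 3L), ".p",
                          rep(1:3, each = length(alphabet)))
    for (p in 1:3)
      for (aa in alphabet)
        m[, paste0(aa, ".p", p)] <- as.integer(aas[, p] == aa)
  }

  if (!is.null(mfe)) {
    stopifnot(length(mfe) == n)
    z <- if (sd(mfe) > 0) (mfe - mean(mfe)) / sd(mfe) else mfe - mean(mfe)
    m <- cbind(m, mfe = z)
  }
  attr(m, "encoding") <- encoding
  m
}

#' Lasso regression with cross-validated penalty selection
#'
#' Fits an L1-penalized linear model of the response on the feature matrix,
#' choosing the penalty by k-fold cross-validation (CV-minimum rule) and
#' reporting the coefficients of the full-data fit at that penalty. Binary
#' indicator features are left unstandardized (they share a scale).
#' Variance explained is the in-sample R-squared of that fit; the
#' cross-validated R-squared is reported alongside. Importance is the
#' absolute coefficient, ties broken by column order.
#'
#' @param x Feature matrix from \code{\link{encode_features}}.
#' @param y Numeric response (e.g. \code{protein_effect}); rows with NA are
#'   dropped.
#' @param nfolds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment (default 1).
#' @return An object of class \code{uorf_lasso}: \code{lambda},
#'   \code{coefficients} (named, intercept excluded), \code{intercept},
#'   \code{selected} (names of nonzero coefficients),
#'   \code{variance_explained}, \code{cv_r2}, \code{importance} (data.frame),
#'   \code{encoding}, \code{nfolds}, \code{seed}, \code{n}.
#' @export
fit_lasso <- function(x, y, nfolds = 10L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  enc <- attr(x, "encoding")
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < nfolds)
    stop("need at least as many rows as folds")

  empty_fit <- function() {
    coefs <- setNames(rep(0, ncol(x)), colnames(x))
    structure(list(lambda = NA_real_, coefficients = coefs,
                   intercept = mean(y), selected = character(),
                   variance_explained = 0, cv_r2 = 0,
                   importance = data.frame(feature = character(),
                                           coefficient = numeric(),
                                           importance = numeric(),
                                           rank = integer(),
                                           stringsAsFactors = FALSE),
                   encoding = enc, nfolds = nfolds, seed = seed, n = n),
              class = "uorf_lasso")
  }
  if (var(y) == 0) return(empty_fit())

  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                          standardize = FALSE)
  beta <- coef(cv, s = "lambda.min")
  coefs <- setNames(as.numeric(beta)[-1L], rownames(beta)[-1L])
  intercept <- as.numeric(beta)[1L]
  pred <- as.numeric(predict(cv, newx = x, s = "lambda.min"))
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - pred)^2) / sst
  cv_r2 <- 1 - min(cv$cvm) / mean((y - mean(y))^2)
  nz <- which(coefs != 0)
  ord <- nz[order(-abs(coefs[nz]))]  # order() is stable: ties keep column order
  importance <- data.frame(feature = names(coefs)[ord],
                           coefficient = unname(coefs[ord]),
                           importance = abs(unname(coefs[ord])),
                           rank = seq_along(ord),
                           stringsAsFactors = FALSE)
  structure(list(lambda = cv$lambda.min, coefficients = coefs,
                 intercept = intercept, selected = names(coefs)[nz],
                 variance_explained = r2, cv_r2 = cv_r2,
                 importance = importance, encoding = enc,
                 nfolds = nfolds, seed = seed, n = n),
            class = "uorf_lasso")
}

#' @export
print.uorf_lasso <- function(x, ...) {
  cat("Lasso fit (", if (!is.null(x$encoding)) x$encoding else "custom",
      " encoding): ", length(x$selected), " of ",
      length(x$coefficients), " variables selected\n",
      "  lambda = ", signif(x$lambda, 4),
      ", in-sample R2 = ", round(x$variance_explained, 4),
      ", CV R2 = ", round(x$cv_r2, 4), "\n", sep = "")
  if (nrow(x$importance))
    print(utils::head(x$importance, 5L), row.names = FALSE)
  invisible(x)
}

#' Top-ranked predictors of a lasso fit
#'
#' Nonzero coefficients ranked by decreasing absolute value (ties broken by
#' column order).
#'
#' @param fit A \code{uorf_lasso}.
#' @param top Number of predictors to return (default 20).
#' @return data.frame \code{feature}, \code{coefficient}, \code{importance},
#'   \code{rank}.
#' @export
importance_report <- function(fit, top = 20L) {
  stopifnot(inherits(fit, "uorf_lasso"))
  utils::head(fit$importance, top)
}

#' Compare feature encodings by cross-validated lasso fits
#'
#' Fits one lasso per encoding on the same response with identical folds and
#' seed, reporting the number of features, selected variables and variance
#' explained for each.
#'
#' @param effects A \code{uorf_effects} table (response is
#'   \code{protein_effect} unless another column is named).
#' @param encodings Encodings to compare.
#' @param column Response column.
#' @param nfolds,seed Passed to \code{\link{fit_lasso}}.
#' @param mfe Optional per-variant numeric column appended to every encoding.
#' @return data.frame ordered as given: \code{encoding}, \code{n_features},
#'   \code{n_selected}, \code{variance_explained}, \code{cv_r2}.
#' @export
compare_encodings <- function(effects,
                              encodings = c("codon_position", "codon",
                                            "aa_position"),
                              column = "protein_effect",
                              nfolds = 10L, seed = 1L, mfe = NULL) {
  y <- effects[[column]]
  rows <- lapply(encodings, function(enc) {
    x <- encode_features(effects, enc, mfe = mfe)
    fit <- fit_lasso(x, y, nfolds = nfolds, seed = seed)
    data.frame(encoding = enc, n_features = ncol(x),
               n_selected = length(fit$selected),
               variance_explained = fit$variance_explained,
               cv_r2 = fit$cv_r2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
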