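# Firth bias-reduced logistic regression for a single standardized
# covariate; used as fallback under (quasi-)separation, where ordinary
# maximum likelihood diverges. X includes the intercept column.
.firthLogit <- function(X, y, maxIter = 100L, tol = 1e-8) {
    beta <- numeric(ncol(X))
    for (it in seq_len(maxIter)) {
        eta <- drop(X %*% beta)
        p <- 1 / (1 + exp(-eta))
        W <- p * (1 - p)
        XW <- X * W
        I <- crossprod(X, XW)
        Iinv <- solve(I)
        # hat diagonal of the weighted design
        H <- rowSums((X %*% Iinv) * XW)
        U <- crossprod(X, y - p + H * (0.5 - p))
        step <- drop(Iinv %*% U)
        # dampen oversized steps for stability
        if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
        beta <- beta + step
        if (max(abs(step)) < tol) break
    }
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    I <- crossprod(X, X * p * (1 - p))
    list(coef = beta, se = sqrt(diag(solve(I))), fitted = p)
}

#' Univariate logistic association of an index with a binary outcome
#'
#' Fits a maximum-likelihood logistic regression of the outcome on the
#' z-scored index, reporting the slope (log odds ratio per SD), its Wald
#' p-value, and the AUC of the fitted probabilities. Under perfect or
#' quasi-perfect separation the fit is flagged and refitted with Firth's
#' bias-reduced likelihood, which keeps the estimates finite. A constant
#' index is reported with zero slope and AUC 0.5.
#'
#' @param values numeric index, one value per subject.
#' @param outcomes binary outcome (0/1, logical, or two-level factor), e.g.
#'   AF recurrence after electrical cardioversion.
#'
#' @return A list: `beta` (slope per SD), `se`, `oddsRatio`, `pValue`, `auc`,
#'   and `flag` (`"ok"`, `"separation"` or `"constant"`).
#'
#' @examples
#' set.seed(1)
#' x <- rnorm(60)
#' y <- rbinom(60, 1, plogis(x))
#' univariateAssociation(x, y)$auc
#' @export
univariateAssociation <- function(values, outcomes) {
    y <- if (is.factor(outcomes)) as.integer(outcomes) - 1L
         else as.integer(outcomes)
    if (!all(y %in% c(0L, 1L)))
        stop("'outcomes' must be binary")
    if (length(values) != length(y))
        stop("'values' and 'outcomes' must have equal length")
    if (min(table(y)) < 2L)
        stop("at least 2 subjects per outcome class are required")
    if (sd(values) == 0)
        return(list(beta = 0, se = NA_real_, oddsRatio = 1,
                    pValue = NA_real_, auc = 0.5, flag = "constant"))
    z <- (values - mean(values)) / sd(values)
    sep <- FALSE
    fit <- withCallingHandlers(
        glm(y ~ z, family = binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)) ||
                grepl("did not converge", conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    if (!sep && abs(coef(fit)[2L]) > 15) sep <- TRUE
    if (sep) {
        ff <- .firthLogit(cbind(1, z), y)
        beta <- ff$coef[2L]
        se <- ff$se[2L]
        fitted <- ff$fitted
    } else {
        beta <- coef(fit)[2L]
        se <- summary(fit)$coefficients[2L, 2L]
        fitted <- fit$fitted.values
    }
    auc <- as.numeric(pROC::auc(pROC::roc(y, fitted, quiet = TRUE,
                                          direction = "<")))
    list(beta = unname(beta), se = unname(se),
         oddsRatio = unname(exp(beta)),
         pValue = unname(2 * pnorm(-abs(beta / se))), auc = auc,
         flag = if (sep) "separation" else "ok")
}

#' Multivariable logistic association
#'
#' Fits one logistic model with several (z-scored) indices as joint
#' predictors. No variable selection is performed; strongly correlated
#' predictor pairs (|r| > 0.8) are reported in `collinear` so that
#' coefficients can be interpreted with care.
#'
#' @param indexMatrix numeric matrix or data.frame, subjects x indices.
#' @param outcomes binary outcome vector.
#'
#' @return A list: `coefficients` (summary table), `auc`, and `collinear`
#'   (character vector of flagged predictor pairs).
#' @export
multivariableAssociation <- function(indexMatrix, outcomes) {
    X <- as.matrix(indexMatrix)
    y <- if (is.factor(outcomes)) as.integer(outcomes) - 1L
         else as.integer(outcomes)
    if (!all(y %in% c(0L, 1L)))
        stop("'outcomes' must be binary")
    Z <- scale(X)
    cm <- stats::cor(X)
    pairs <- which(abs(cm) > 0.8 & upper.tri(cm), arr.ind = TRUE)
    collinear <- if (nrow(pairs))
        paste(colnames(cm)[pairs[, 1L]], colnames(cm)[pairs[, 2L]],
              sep = " ~ ") else character()
    df <- data.frame(y = y, Z)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    auc <- as.numeric(pROC::auc(pROC::roc(y, fit$fitted.values,
                                          quiet = TRUE, direction = "<")))
    list(coefficients = summary(fit)$coefficients, auc = auc,
         collinear = collinear)
}
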