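## Soil-chemistry preprocessing: linear-model imputation of incomplete
## nutrient columns from the always-measured predictors, standardized PCA,
## and a deterministic PC1 orientation defining the calcareous-siliceous
## gradient (calcareous = high pH = negative scores).

.SOIL_PREDICTORS <- c("pH_H2O", "pH_KCl", "bioavailable_Ca")

#' Impute missing soil measurements by linear regression
#'
#' For every incomplete column, an ordinary least squares model on the
#' complete rows with the three always-measured predictors (pH H2O, pH KCl,
#' bioavailable Ca) fills the missing entries with fitted values. Observed
#' cells are never altered; imputed cells are flagged in
#' `attr(x, "imputed")`.
#'
#' @param table soil data.frame with a `population` column and numeric
#'   chemistry columns; the three predictors must be complete.
#' @return completed data.frame, with a logical flag matrix attached.
#' @export
imputeSoil <- function(table) {
    stopifnot(all(.SOIL_PREDICTORS %in% names(table)))
    if (anyNA(table[, .SOIL_PREDICTORS]))
        stop("predictor columns (pH_H2O, pH_KCl, bioavailable_Ca) must be complete",
             call. = FALSE)
    num_cols <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                        .SOIL_PREDICTORS)
    flags <- matrix(FALSE, nrow(table), length(num_cols),
                    dimnames = list(NULL, num_cols))
    X <- table[, .SOIL_PREDICTORS]
    for (col in num_cols) {
        miss <- is.na(table[[col]])
        if (!any(miss)) next
        complete <- which(!miss)
        if (length(complete) < length(.SOIL_PREDICTORS) + 1)
            stop("fewer complete rows than predictors + 1 for column '", col,
                 "'", call. = FALSE)
        fit <- stats::lm(y ~ ., data = cbind(y = table[[col]][complete],
                                             X[complete, , drop = FALSE]))
        table[[col]][miss] <- stats::predict(fit, newdata = X[miss, , drop = FALSE])
        flags[miss, col] <- TRUE
    }
    attr(table, "imputed") <- flags
    table
}

#' Standardized PCA of the soil table with a fixed PC1 orientation
#'
#' Columns are standardized; zero-variance columns are dropped with a
#' warning. PC1's sign is fixed so that the pH_H2O loading is negative, i.e.
#' calcareous (high-pH, calcium-rich) populations receive negative scores
#' and siliceous populations positive ones, regardless of numerical library
#' conventions.
#'
#' @param table completed soil data.frame (see [imputeSoil()]) with a
#'   `population` column.
#' @return list: `scores` (data.frame population, pc1, pc2), `loadings`,
#'   `var_explained` (fractions summing to 1).
#' @export
soilPCA <- function(table) {
    num <- table[, vapply(table, is.numeric, TRUE), drop = FALSE]
    if (anyNA(num)) stop("soil table must be complete; run imputeSoil() first",
                         call. = FALSE)
    vars <- vapply(num, stats::var, 0)
    if (any(vars == 0)) {
        warning("dropping zero-variance column(s): ",
                paste(names(vars)[vars == 0], collapse = ", "))
        num <- num[, vars > 0, drop = FALSE]
    }
    pc <- stats::prcomp(num, center = TRUE, scale. = TRUE)
    if (pc$rotation["pH_H2O", 1] > 0) {
        pc$rotation[, 1] <- -pc$rotation[, 1]
        pc$x[, 1] <- -pc$x[, 1]
    }
    list(scores = data.frame(population = table$population,
                             pc1 = pc$x[, 1], pc2 = pc$x[, 2]),
         loadings = pc$rotation,
         var_explained = pc$sdev^2 / sum(pc$sdev^2))
}
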