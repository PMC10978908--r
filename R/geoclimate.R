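#' Seasonal means of monthly climate variables
#'
#' Winter is November-February, summer March-June; July-October does not
#' enter either season. Input columns follow the `{var}_{01..12}` convention
#' (vars: temp, prec, srad, vapr, wind); output columns carry the `_1`
#' (winter) and `_2` (summer) suffixes.
#'
#' @param table data.frame with accession rows and monthly climate columns.
#' @param vars variable prefixes to summarize.
#' @return data.frame(accession, `{var}_1`, `{var}_2`, ...).
#' @export
seasonal_means <- function(table,
                           vars = c("temp", "prec", "srad", "vapr", "wind")) {
  winter <- c(11, 12, 1, 2)
  summer <- c(3, 4, 5, 6)
  out <- data.frame(accession = table$accession, stringsAsFactors = FALSE)
  for (v in vars) {
    cols <- sprintf("%s_%02d", v, 1:12)
    missing_cols <- setdiff(cols, names(table))
    if (length(missing_cols)) {
      bad_acc <- table$accession[1]
      stop(sprintf("missing month column %s (first accession: %s)",
                   missing_cols[1], bad_acc), call. = FALSE)
    }
    m <- as.matrix(table[, cols])
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("missing %s month %02d for accession %s",
                   v, idx[2], table$accession[idx[1]]), call. = FALSE)
    }
    out[[paste0(v, "_1")]] <- rowMeans(m[, winter, drop = FALSE])
    out[[paste0(v, "_2")]] <- rowMeans(m[, summer, drop = FALSE])
  }
  out
}

#' PCA of seasonal climate variables and elevation
#'
#' Unit-variance normalization followed by PCA (shared implementation with
#' the phenotype module). With the five climate variables in two seasons
#' plus elevation the loading matrix has 11 rows.
#'
#' @param seasonal data.frame from [seasonal_means()].
#' @param elevation numeric vector aligned with `seasonal$accession`.
#' @return a `pca_result` (see [run_pca()]).
#' @export
climate_pca <- function(seasonal, elevation = NULL) {
  m <- as.matrix(seasonal[, setdiff(names(seasonal), "accession")])
  if (!is.null(elevation)) m <- cbind(m, elev = elevation)
  rownames(m) <- seasonal$accession
  assert_that(nrow(m) >= 3, "need >= 3 accessions")
  run_pca(scale_uv(m))
}

#' Cline test: ordinary least squares plus correlation
#'
#' Fits y = a + b x by least squares on pairwise-complete observations and
#' reports the Pearson correlation with its two-sided p-value from the t
#' distribution on n - 2 degrees of freedom. Zero variance in x makes the
#' test undefined (all-NA result row rather than an error).
#'
#' @param x predictor (latitude, longitude, or a climate variable).
#' @param y response (trait value or PC score).
#' @param x_name,y_name labels for the output row.
#' @return data.frame(x, y, slope, intercept, r, p, n).
#' @export
cline_test <- function(x, y, x_name = deparse(substitute(x)),
                       y_name = deparse(substitute(y))) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, "need >= 3 paired observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    return(data.frame(x = x_name, y = y_name, slope = NA_real_,
                      intercept = NA_real_, r = NA_real_, p = NA_real_,
                      n = n, stringsAsFactors = FALSE))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  syy <- sum((y - mean(y))^2)
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  data.frame(x = x_name, y = y_name, slope = slope, intercept = intercept,
             r = r, p = p, n = n, stringsAsFactors = FALSE)
}
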