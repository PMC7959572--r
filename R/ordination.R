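#' Square-root transform of a relative-abundance matrix
#'
#' Standard variance-stabilizing transform for percentage species data before
#' ordination. Row sums are no longer ~100 after transformation. The result
#' carries an attribute guarding against accidental double application.
#'
#' @param m Numeric matrix or data frame of abundances (samples x taxa),
#'   non-negative.
#' @return The element-wise square root, as a matrix, with attribute
#'   `sqrt_transformed = TRUE`.
#' @export
sqrt_transform <- function(m) {
  if (isTRUE(attr(m, "sqrt_transformed")))
    stop("matrix is already square-root transformed", call. = FALSE)
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("abundance matrix must be numeric", call. = FALSE)
  if (any(m < 0, na.rm = TRUE))
    stop("abundances must be non-negative", call. = FALSE)
  out <- sqrt(m)
  attr(out, "sqrt_transformed") <- TRUE
  out
}

#' First principal-component axis of a community matrix
#'
#' Column-centred PCA on the covariance matrix (no scaling), the standard
#' choice for square-root transformed percentage data. Axis-1 scores serve as
#' a one-dimensional summary of compositional change; the variance fraction is
#' the leading eigenvalue share. Sign is made deterministic by orienting the
#' scores to correlate positively with time (sample ages, or row order when
#' ages are not given).
#'
#' @param m Numeric matrix (samples x taxa), typically already
#'   [sqrt_transform()]ed.
#' @param ages Optional sample ages (years CE) used for the sign convention.
#' @return List with `scores` (centred axis-1 scores),
#'   `axis1_variance_fraction`, and `loadings`.
#' @export
pca_axis1 <- function(m, ages = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 3 || ncol(m) < 2)
    stop("need at least 3 samples and 2 taxa", call. = FALSE)
  total_var <- sum(apply(m, 2, var))
  if (total_var == 0)
    stop("community matrix has zero variance (identical samples)",
         call. = FALSE)
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  scores <- p$x[, 1]
  loadings <- p$rotation[, 1]
  orient <- if (is.null(ages)) seq_along(scores) else ages
  r <- suppressWarnings(cor(scores, orient))
  if (is.finite(r) && r < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  list(scores = unname(scores),
       axis1_variance_fraction = p$sdev[1]^2 / sum(p$sdev^2),
       loadings = loadings)
}

#' Partial redundancy analysis with a single predictor and covariable
#'
#' Measures the share of community variance attributable to a predictor after
#' removing a covariable (typically time): both the column-centred community
#' matrix and the predictor are residualized on the covariable by least
#' squares, and the variance fraction is the total sum of squares of the
#' fitted values from regressing the residual matrix on the residual
#' predictor, divided by the total sum of squares of the residual matrix.
#'
#' When predictor and covariable are essentially collinear (|r| > 0.999) no
#' variance can be attributed to the predictor; the fraction is reported as 0
#' and flagged.
#'
#' @param m Community matrix (samples x taxa), typically square-root
#'   transformed.
#' @param predictor Numeric vector aligned to samples (e.g. reconstructed
#'   silicic acid supply).
#' @param covariable Numeric vector aligned to samples (e.g. sample age).
#' @return List with `rda_variance_fraction` and logical `collinear_flag`.
#' @export
partial_rda <- function(m, predictor, covariable) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (length(predictor) != n || length(covariable) != n)
    stop("predictor and covariable must match the number of samples",
         call. = FALSE)
  r_pc <- suppressWarnings(cor(predictor, covariable))
  if (is.finite(r_pc) && abs(r_pc) > 0.999) {
    warning("predictor is collinear with the covariable (|r| > 0.999); ",
            "no attributable variance")
    return(list(rda_variance_fraction = 0, collinear_flag = TRUE))
  }
  Y <- scale(m, center = TRUE, scale = FALSE)
  Z <- cbind(1, covariable)
  resid_on <- function(x) x - Z %*% qr.coef(qr(Z), x)
  Yr <- resid_on(Y)
  xr <- drop(resid_on(matrix(predictor, ncol = 1)))
  ss_x <- sum(xr^2)
  if (ss_x == 0)
    return(list(rda_variance_fraction = 0, collinear_flag = TRUE))
  bhat <- crossprod(Yr, xr) / ss_x          # taxa x 1
  fitted <- outer(xr, drop(bhat))
  list(rda_variance_fraction = sum(fitted^2) / sum(Yr^2),
       collinear_flag = FALSE)
}

#' Ratio of autumn to spring diatom taxa
#'
#' Per sample, the summed relative abundance of autumn-blooming taxa divided
#' by that of spring-blooming taxa. Samples with zero spring abundance have an
#' undefined ratio and are flagged (`NA` ratio) so they can be excluded from
#' trend fitting.
#'
#' @param m Abundance matrix (samples x taxa, %), untransformed.
#' @param seasons Named character vector mapping taxon name to
#'   `"spring"`, `"autumn"` or `"other"`; taxa absent from the map count as
#'   `"other"`.
#' @param ages Optional sample ages carried into the result.
#' @return Data frame with `age_ce`, `autumn_pct`, `spring_pct`, `ratio`,
#'   `flag` (`"ok"` or `"undefined"`).
#' @export
autumn_spring_ratio <- function(m, seasons, ages = NULL) {
  m <- as.matrix(m)
  if (length(seasons) == 0 || !any(seasons %in% c("spring", "autumn")))
    stop("no taxa labelled spring or autumn", call. = FALSE)
  spring <- names(seasons)[seasons == "spring"]
  autumn <- names(seasons)[seasons == "autumn"]
  if (length(spring) == 0)
    stop("at least one spring taxon is required", call. = FALSE)
  miss <- setdiff(c(spring, autumn), colnames(m))
  if (length(miss) > 0)
    stop("labelled taxa absent from matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  s <- rowSums(m[, spring, drop = FALSE])
  a <- if (length(autumn) > 0) rowSums(m[, autumn, drop = FALSE]) else
    rep(0, nrow(m))
  ratio <- ifelse(s > 0, a / s, NA_real_)
  data.frame(age_ce = if (is.null(ages)) rep(NA_real_, nrow(m)) else ages,
             autumn_pct = a, spring_pct = s, ratio = ratio,
             flag = ifelse(s > 0, "ok", "undefined"),
             stringsAsFactors = FALSE)
}

#' Pearson correlation between two aligned series
#'
#' @param x,y Numeric vectors of equal length (n >= 5), aligned on the same
#'   samples.
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate_series <- function(x, y) {
  if (length(x) != length(y))
    stop("series must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) stop("need at least 5 aligned pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in one of the series", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
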