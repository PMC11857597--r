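#' Welch two-sample t test
#'
#' Unequal-variance two-sided t test with Satterthwaite degrees of
#' freedom, as used for group comparisons between patient classes.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' ROC AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney U statistic divided by `n1 * n0` --- the
#' probability that a positive sample outscores a negative one, with
#' ties counted 1/2.  The confidence interval uses DeLong's
#' structural-components variance estimate.  By default the interval is
#' constructed on the logit scale and mapped back, which keeps its
#' small-sample coverage honest for AUCs near 1 where the linear-scale
#' interval collapses against the boundary; `ci_scale = "linear"` gives
#' the plain `auc +/- z * se` interval clipped to `[0, 1]`.  Perfect
#' separation (AUC exactly 0 or 1) has zero DeLong variance and yields
#' the degenerate interval `[auc, auc]` on either scale.
#'
#' @param scores numeric vector.
#' @param labels class labels, coercible to 0 (negative/HC) and 1
#'   (positive/LN).
#' @param conf_level confidence level (default 0.95).
#' @param ci_scale `"logit"` (default) or `"linear"`.
#' @return list with `auc`, `ci_low`, `ci_high`, `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95,
                    ci_scale = c("logit", "linear")) {
  ci_scale <- match.arg(ci_scale)
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (length(scores) != length(labels)) stop("length mismatch")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L)
    stop("both classes must be present to compute an AUC")
  # psi(X, Y) = 1 if X > Y, 1/2 if tied, 0 otherwise
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)   # per-positive structural components
  v01 <- colMeans(psi)   # per-negative
  # a singleton class contributes no estimable component variance
  se <- sqrt((if (m > 1) stats::var(v10) else 0) / m +
             (if (n > 1) stats::var(v01) else 0) / n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (auc <= 0 || auc >= 1 || se == 0) {
    lo <- hi <- auc
  } else if (ci_scale == "logit") {
    se_l <- se / (auc * (1 - auc))    # delta method
    lo <- stats::plogis(stats::qlogis(auc) - z * se_l)
    hi <- stats::plogis(stats::qlogis(auc) + z * se_l)
  } else {
    lo <- max(0, auc - z * se)
    hi <- min(1, auc + z * se)
  }
  list(auc = auc, ci_low = lo, ci_high = hi,
       se = se, n_pos = m, n_neg = n)
}

#' Combined panel score across analytes
#'
#' The multiplexed panel is summarized per sample either as the mean of
#' rank-standardized analyte values (default; ranks scaled to `[0, 1]`,
#' monotone-invariant) or as the in-sample linear predictor of a
#' logistic regression on the analyte values.
#'
#' @param values numeric matrix or data.frame, samples x analytes.
#' @param labels class labels (needed for `method = "logistic"`).
#' @param method `"rank_mean"` (default) or `"logistic"`.
#' @return numeric vector of per-sample combined scores.
#' @export
panel_score <- function(values, labels = NULL,
                        method = c("rank_mean", "logistic")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (ncol(values) < 1L) stop("need at least one analyte")
  n_missing <- sum(is.na(values))
  if (n_missing > 0)
    warning(sprintf("%d missing value(s) excluded pairwise", n_missing))
  if (method == "rank_mean") {
    rk <- apply(values, 2, function(v) {
      r <- rank(v, na.last = "keep")
      n <- sum(!is.na(v))
      if (n > 1) (r - 1) / (n - 1) else r * 0
    })
    return(rowMeans(rk, na.rm = TRUE))
  }
  if (is.null(labels)) stop("logistic combination requires labels")
  df <- data.frame(.y = as.integer(as.logical(as.numeric(labels))), values)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  unname(stats::predict(fit, type = "link"))
}

#' Pearson or Spearman correlation
#'
#' @param x,y numeric vectors (n >= 3, equal length).
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation coefficient; `NA` with attribute
#'   `undefined = TRUE` when either vector has zero variance.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, undefined = TRUE))
  stats::cor(x, y, method = method)
}

#' Read a GenePix results (GPR/ATF) table
#'
#' Parses the ATF 1.0 dialect: a version line, a line declaring the
#' number of optional header records and data columns, the header
#' records, then a tab-delimited table.  Returns the indexing, naming
#' and median foreground/background columns needed for cross-platform
#' net-intensity comparison, plus the remaining columns untouched.
#'
#' @param path path to a `.gpr` file.
#' @param wavelength wavelength tag of the intensity columns (default
#'   532, the Cy3 scan); set `NULL` to skip net-intensity derivation.
#' @return data.frame of the spot records, with an added `net` column
#'   (`F<w> Median - B<w> Median`) when the columns are present; ATF
#'   header records are attached as the `"atf_header"` attribute.
#' @export
read_gpr <- function(path, wavelength = 532) {
  if (!file.exists(path)) stop("GPR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !grepl("^ATF", lines[1]))
    stop("malformed ATF header at line 1: expected 'ATF <version>'")
  decl <- strsplit(trimws(lines[2]), "[ \t]+")[[1]]
  n_head <- suppressWarnings(as.integer(decl[1]))
  if (is.na(n_head))
    stop("malformed ATF header at line 2: expected '<n_headers> <n_columns>'")
  if (length(lines) < 2L + n_head + 1L)
    stop(sprintf("truncated ATF file: %d header records declared at line 2",
                 n_head))
  header <- lines[seq_len(n_head) + 2L]
  header <- gsub('^"|"$', "", header)
  tab <- utils::read.delim(text = paste(lines[-(seq_len(n_head + 2L))],
                                        collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Block", "Row", "Column", "Name")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("GPR table missing declared column(s): ",
         paste(miss, collapse = ", "))
  if (!is.null(wavelength)) {
    fcol <- sprintf("F%d Median", wavelength)
    bcol <- sprintf("B%d Median", wavelength)
    if (all(c(fcol, bcol) %in% names(tab)))
      tab$net <- tab[[fcol]] - tab[[bcol]]
  }
  structure(tab, atf_header = header)
}

#' Group comparison report for a biomarker panel
#'
#' Per-analyte Welch test and ROC/AUC (DeLong CI) between two classes,
#' plus the combined panel score's AUC.
#'
#' @param values samples x analytes matrix or data.frame of (normalized)
#'   intensities.
#' @param labels per-sample class labels (0 = control, 1 = case).
#' @param adjust `"none"` (default, raw p values) or `"BH"` for
#'   Benjamini-Hochberg adjustment.
#' @return data.frame: `analyte`, `t_statistic`, `p_value`, `auc`,
#'   `ci_low`, `ci_high` --- one row per analyte plus a `"panel"` row
#'   (combined score; no t test).
#' @export
panel_stats <- function(values, labels, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  values <- as.matrix(values)
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  rows <- lapply(colnames(values), function(a) {
    v <- values[, a]
    tt <- welch_t_test(v[labels == 1L], v[labels == 0L])
    rc <- roc_auc(v, labels)
    data.frame(analyte = a, t_statistic = tt$statistic,
               p_value = tt$p_value, auc = rc$auc,
               ci_low = rc$ci_low, ci_high = rc$ci_high)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  combined <- panel_score(values)
  rc <- roc_auc(combined, labels)
  rbind(out, data.frame(analyte = "panel", t_statistic = NA_real_,
                        p_value = NA_real_, auc = rc$auc,
                        ci_low = rc$ci_low, ci_high = rc$ci_high))
}
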