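#' Correlate perturbation signatures with functional-assay activity
#'
#' For each kept peptide-timepoint, ordinary least squares of assay
#' activity on the compounds' perturbation values, reporting slope,
#' intercept, Pearson r-squared, two-tailed slope p-value and BH-adjusted
#' p across the peptide-timepoint family of the assay. Flags follow the
#' screening conventions: \code{significant} when adjusted p < 0.05,
#' \code{predictive} when r-squared > 0.4. Cells with constant
#' perturbation or fewer than 3 complete compound pairs are excluded from
#' the family and flagged.
#'
#' @param pm an [perturbation_matrix()].
#' @param activities activity table (\code{compound}, \code{assay},
#'   \code{value}), e.g. from [simulate_activities()] or
#'   [read_activity_table()].
#' @param assay which assay to correlate.
#' @param kept optional [significance_filter()] result (or cell-label
#'   character vector) restricting the cells; default uses all cells.
#' @return data.frame of class \code{hdx_correlation}, one row per cell.
#' @export
activity_correlation <- function(pm, activities, assay, kept = NULL) {
  stopifnot(inherits(pm, "hdx_perturbation"))
  act <- as.data.frame(activities)
  act <- act[act$assay == assay, ]
  if (nrow(act) == 0L) stop("no activity values for assay '", assay, "'")
  labels <- .kept_labels(pm, kept)
  if (!length(labels)) {
    res <- data.frame(label = character(0), peptide_id = character(0),
                      timepoint_s = numeric(0), assay = character(0),
                      slope = numeric(0), intercept = numeric(0),
                      r_squared = numeric(0), slope_p = numeric(0),
                      adjusted_p = numeric(0), n = integer(0),
                      flag = character(0), significant = logical(0),
                      predictive = logical(0))
    class(res) <- c("hdx_correlation", "data.frame")
    return(res)
  }
  y_all <- act$value[match(pm$compounds, act$compound)]
  out <- lapply(labels, function(lb) {
    x <- pm$delta[, lb]
    ok <- !is.na(x) & !is.na(y_all)
    base <- data.frame(
      label = lb,
      peptide_id = pm$cells$peptide_id[match(lb, pm$cells$label)],
      timepoint_s = pm$cells$timepoint_s[match(lb, pm$cells$label)],
      assay = assay, slope = NA_real_, intercept = NA_real_,
      r_squared = NA_real_, slope_p = NA_real_, adjusted_p = NA_real_,
      n = sum(ok), flag = "")
    if (sum(ok) < 3L) { base$flag <- "n<3"; return(base) }
    if (stats::var(x[ok]) == 0) {
      base$flag <- "constant-perturbation"; return(base)
    }
    fit <- stats::lm(y_all[ok] ~ x[ok])
    sm <- summary(fit)
    base$slope <- unname(stats::coef(fit)[2])
    base$intercept <- unname(stats::coef(fit)[1])
    base$r_squared <- sm$r.squared
    base$slope_p <- sm$coefficients[2, 4]
    base
  })
  res <- do.call(rbind, out)
  fam <- res$flag == ""
  res$adjusted_p[fam] <- bh_adjust(res$slope_p[fam])
  res$significant <- !is.na(res$adjusted_p) & res$adjusted_p < 0.05
  res$predictive <- !is.na(res$r_squared) & res$r_squared > 0.4
  rownames(res) <- NULL
  class(res) <- c("hdx_correlation", "data.frame")
  res
}

#' @export
print.hdx_correlation <- function(x, ...) {
  cat(sprintf("Activity correlation (%s): %d peptide-timepoints, %d significant, %d predictive (r^2 > 0.4)\n",
              x$assay[1], nrow(x), sum(x$significant, na.rm = TRUE),
              sum(x$predictive & x$significant, na.rm = TRUE)))
  top <- x[order(-replace(x$r_squared, is.na(x$r_squared), -1)), ]
  print.data.frame(utils::head(
    top[, c("label", "slope", "r_squared", "adjusted_p", "n")], 5),
    digits = 3)
  invisible(x)
}

.kept_labels <- function(pm, kept) {
  if (is.null(kept)) return(pm$cells$label)
  if (inherits(kept, "hdx_kept")) return(kept$kept$label)
  as.character(kept)
}

#' Peptide-peptide covariation across compounds
#'
#' Pairwise Pearson r-squared of perturbation values between every pair
#' of kept peptide-timepoints, computed across compounds; p-values for a
#' non-zero slope are BH-adjusted over the upper-triangle family, and the
#' display mask keeps pairs with adjusted p < 0.01 (the correlogram
#' convention). The grid is symmetric with unit diagonal; the sign of the
#' correlation is retained in \code{records$r} but lost in r-squared.
#'
#' @param pm an [perturbation_matrix()].
#' @param kept optional [significance_filter()] result or label vector.
#' @param mask_threshold adjusted-p cutoff for the display mask.
#' @return list of class \code{hdx_covariation}: \code{records} (long,
#'   upper triangle), \code{r2} (symmetric matrix), \code{adjusted_p}
#'   (symmetric), \code{mask} (logical), \code{labels}.
#' @export
covariation <- function(pm, kept = NULL, mask_threshold = 0.01) {
  stopifnot(inherits(pm, "hdx_perturbation"))
  labels <- .kept_labels(pm, kept)
  m <- pm$delta[, labels, drop = FALSE]
  if (nrow(m) < 3L) stop("covariation needs >= 3 compounds")
  k <- length(labels)
  r2 <- diag(1, k); dimnames(r2) <- list(labels, labels)
  padj <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  pairs <- which(upper.tri(r2), arr.ind = TRUE)
  recs <- data.frame(x = labels[pairs[, 1]], y = labels[pairs[, 2]],
                     r = NA_real_, r_squared = NA_real_,
                     p_value = NA_real_, n = NA_integer_, flag = "")
  for (i in seq_len(nrow(pairs))) {
    a <- m[, pairs[i, 1]]; b <- m[, pairs[i, 2]]
    ok <- !is.na(a) & !is.na(b)
    recs$n[i] <- sum(ok)
    if (sum(ok) < 3L) { recs$flag[i] <- "n<3"; next }
    if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) {
      recs$flag[i] <- "constant-perturbation"; next
    }
    ct <- stats::cor.test(a[ok], b[ok])
    recs$r[i] <- unname(ct$estimate)
    recs$r_squared[i] <- ct$estimate^2
    recs$p_value[i] <- ct$p.value
  }
  fam <- recs$flag == ""
  recs$adjusted_p <- NA_real_
  recs$adjusted_p[fam] <- bh_adjust(recs$p_value[fam])
  for (i in seq_len(nrow(pairs))) {
    r2[pairs[i, 1], pairs[i, 2]] <- r2[pairs[i, 2], pairs[i, 1]] <-
      recs$r_squared[i]
    padj[pairs[i, 1], pairs[i, 2]] <- padj[pairs[i, 2], pairs[i, 1]] <-
      recs$adjusted_p[i]
  }
  mask <- !is.na(padj) & padj < mask_threshold
  diag(mask) <- TRUE
  structure(list(records = recs, r2 = r2, adjusted_p = padj, mask = mask,
                 labels = labels, mask_threshold = mask_threshold),
            class = "hdx_covariation")
}

#' @export
print.hdx_covariation <- function(x, ...) {
  n_pair <- nrow(x$records)
  cat(sprintf("Covariation: %d peptide-timepoints, %d pairs, %d shown at adjusted p < %g\n",
              length(x$labels), n_pair,
              sum(x$records$adjusted_p < x$mask_threshold, na.rm = TRUE),
              x$mask_threshold))
  invisible(x)
}

#' Correlogram of a covariation grid
#'
#' @param x an \code{hdx_covariation}.
#' @param ... passed to [graphics::image()].
#' @export
plot.hdx_covariation <- function(x, ...) {
  z <- x$r2; z[!x$mask] <- NA
  k <- ncol(z)
  graphics::image(seq_len(k), seq_len(k), z[, k:1], axes = FALSE,
                  xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  ...)
  graphics::axis(1, seq_len(k), x$labels, las = 2, cex.axis = 0.5)
  graphics::axis(2, seq_len(k), rev(x$labels), las = 2, cex.axis = 0.5)
  invisible(x)
}

#' Ward clustering of compound perturbation signatures
#'
#' Agglomerative hierarchical clustering of compounds on the Euclidean
#' distance between their perturbation signatures (the vector of delta
#' percent D over the kept peptide-timepoints), using Ward's
#' minimum-variance criterion (\code{hclust} method \code{ward.D2}, which
#' implements Ward's criterion for unsquared Euclidean input). Cells with
#' any missing value are dropped before clustering by default;
#' alternatively missing values are imputed with the cell mean.
#'
#' @param pm an [perturbation_matrix()].
#' @param kept optional [significance_filter()] result or label vector.
#' @param na_action \code{"drop"} (default) or \code{"impute"}.
#' @return object of class \code{hdx_clustering}: list with
#'   \code{hclust} (the stats::hclust tree), \code{merge}, \code{height},
#'   \code{order}, \code{labels}, \code{signature_cells}.
#' @export
cluster_compounds <- function(pm, kept = NULL,
                              na_action = c("drop", "impute")) {
  stopifnot(inherits(pm, "hdx_perturbation"))
  na_action <- match.arg(na_action)
  labels <- .kept_labels(pm, kept)
  m <- pm$delta[, labels, drop = FALSE]
  if (nrow(m) < 2L) stop("clustering needs >= 2 compounds")
  if (na_action == "drop") {
    keep <- colSums(is.na(m)) == 0L
    m <- m[, keep, drop = FALSE]
  } else {
    for (j in seq_len(ncol(m))) {
      bad <- is.na(m[, j])
      if (any(bad)) m[bad, j] <- mean(m[, j], na.rm = TRUE)
    }
  }
  if (ncol(m) == 0L) stop("no complete peptide-timepoints to cluster on")
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 order = hc$order, labels = hc$labels,
                 signature_cells = colnames(m)),
            class = "hdx_clustering")
}

#' @export
print.hdx_clustering <- function(x, ...) {
  cat(sprintf("Ward clustering of %d compounds on %d peptide-timepoint signatures\n",
              length(x$labels), length(x$signature_cells)))
  cat(sprintf("  merge heights in [%.2f, %.2f]\n", min(x$height),
              max(x$height)))
  invisible(x)
}

#' @export
plot.hdx_clustering <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "", sub = "",
                 main = "compound perturbation signatures", ...)
  invisible(x)
}

#' Cut a compound clustering into k groups
#'
#' @param clustering an [cluster_compounds()] result.
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cut_clusters <- function(clustering, k) {
  stats::cutree(clustering$hclust, k = k)
}

#' Flag compounds outside the regression prediction interval
#'
#' Fits activity on perturbation by ordinary least squares and flags
#' compounds whose observed activity falls outside the two-sided
#' prediction interval of the fitted line (default 95\%), the standard
#' reading of outliers from correlation plots with prediction bands.
#'
#' @param x perturbation values per compound.
#' @param y activity values per compound.
#' @param ids compound identifiers.
#' @param level prediction-interval coverage.
#' @return character vector of flagged compound ids, with the annotated
#'   per-compound table as attribute \code{"detail"}.
#' @export
flag_outliers <- function(x, y, ids = names(x), level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; ids <- ids[ok]
  if (length(x) < 4L)
    stop("outlier flagging needs >= 4 points")
  if (stats::var(x) == 0) stop("degenerate fit: constant predictor")
  d <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x, data = d)
  pi <- stats::predict(fit, newdata = d, interval = "prediction",
                       level = level)
  out <- y < pi[, "lwr"] | y > pi[, "upr"]
  detail <- data.frame(id = ids, x = x, y = y, fit = pi[, "fit"],
                       lwr = pi[, "lwr"], upr = pi[, "upr"],
                       outlier = out)
  structure(ids[out], detail = detail)
}
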