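#' Intensity-weighted centroid of a peptide isotope envelope
#'
#' @param mz m/z values of the envelope peaks (Th).
#' @param intensity peak intensities (>= 0, not all zero).
#' @return the intensity-weighted mean m/z.
#' @export
centroid_mz <- function(mz, intensity) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) < 1L) stop("empty envelope")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  s <- sum(intensity)
  if (s == 0) stop("all-zero intensity envelope")
  sum(mz * intensity) / s
}

#' Convert centroid m/z to percent deuterium incorporation
#'
#' Linear interpolation of the observed centroid between the undeuterated
#' reference and the maximally deuterated (Dmax) control:
#' \deqn{\%D = 100 (m_{obs} - m_{0}) / (m_{Dmax} - m_{0}).}
#' Using the empirically measured Dmax control as the 100\% reference is
#' what corrects for back-exchange: any handling loss affects the Dmax
#' sample identically, so it cancels. All three centroids share the charge
#' state, which therefore drops out of the formula.
#'
#' @param undeut_mz centroid of the undeuterated spectrum.
#' @param obs_mz centroid of the exchange timepoint spectrum.
#' @param dmax_mz centroid of the fully deuterated control.
#' @param tol how far (Th) outside \code{[undeut_mz, dmax_mz]} an observed
#'   centroid may fall before a warning is raised.
#' @return percent deuterium (vectorised); values slightly outside
#'   [0, 100] are possible for noisy observations and are flagged with a
#'   warning beyond \code{tol}.
#' @export
percent_deuterium <- function(undeut_mz, obs_mz, dmax_mz, tol = 0.1) {
  span <- dmax_mz - undeut_mz
  if (any(span <= 0))
    stop("degenerate Dmax control: dmax_mz must exceed undeut_mz")
  out_of_range <- obs_mz < undeut_mz - tol | obs_mz > dmax_mz + tol
  if (any(out_of_range))
    warning(sum(out_of_range),
            " observed centroid(s) far outside the undeuterated-Dmax span")
  100 * (obs_mz - undeut_mz) / span
}

#' Summarise replicate observations into uptake curves
#'
#' Collapses a long table of percent-deuterium observations into one curve
#' per peptide and condition: per timepoint the replicate mean, sample
#' standard deviation (n - 1 denominator; reported only when n >= 2) and
#' replicate count, timepoints sorted ascending.
#'
#' @param observations data.frame with columns \code{peptide_id},
#'   \code{condition}, \code{timepoint_s}, \code{replicate},
#'   \code{percent_d} (e.g. from [simulate_hdx_dataset()] or
#'   [read_uptake_table()]).
#' @param peptide_id,condition optional filters; by default curves are
#'   built for every peptide-condition pair present.
#' @return data.frame of class \code{hdx_curves} with columns
#'   \code{peptide_id}, \code{condition}, \code{timepoint_s},
#'   \code{mean_d}, \code{sd_d} (NA when n < 2), \code{n}.
#' @export
build_uptake_curves <- function(observations, peptide_id = NULL,
                                condition = NULL) {
  obs <- as.data.frame(observations)
  if (!is.null(peptide_id)) obs <- obs[obs$peptide_id %in% peptide_id, ]
  if (!is.null(condition)) obs <- obs[obs$condition %in% condition, ]
  if (nrow(obs) == 0L) stop("no observations for the requested selection")
  key <- interaction(obs$peptide_id, obs$condition, obs$timepoint_s,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(obs, key), function(d) {
    data.frame(peptide_id = d$peptide_id[1], condition = d$condition[1],
               timepoint_s = d$timepoint_s[1],
               mean_d = mean(d$percent_d),
               sd_d = if (nrow(d) >= 2L) stats::sd(d$percent_d) else NA_real_,
               n = nrow(d))
  }))
  agg <- agg[order(agg$peptide_id, agg$condition, agg$timepoint_s), ]
  rownames(agg) <- NULL
  class(agg) <- c("hdx_curves", "data.frame")
  agg
}

#' @export
print.hdx_curves <- function(x, ...) {
  cat(sprintf("Deuterium build-up curves: %d peptide(s) x %d condition(s), %d timepoints\n",
              length(unique(x$peptide_id)), length(unique(x$condition)),
              length(unique(x$timepoint_s))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Plot deuterium build-up curves
#'
#' Semi-log build-up plot (mean +/- SD over replicates) for one peptide,
#' one line per condition.
#'
#' @param x an \code{hdx_curves} object.
#' @param peptide_id which peptide to plot (default: the first present).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hdx_curves <- function(x, peptide_id = NULL, ...) {
  if (is.null(peptide_id)) peptide_id <- x$peptide_id[1]
  d <- x[x$peptide_id == peptide_id & x$timepoint_s > 0, ]
  if (nrow(d) == 0L) stop("no curve for peptide ", peptide_id)
  conds <- unique(d$condition)
  tps <- sort(unique(d$timepoint_s))
  m <- sapply(conds, function(cc)
    d$mean_d[d$condition == cc][match(tps, d$timepoint_s[d$condition == cc])])
  graphics::matplot(tps, m, type = "b", log = "x", pch = 16, lty = 1,
                    xlab = "exposure (s)", ylab = "% deuterium",
                    ylim = c(0, 100), main = peptide_id, ...)
  graphics::legend("topleft", legend = conds, col = seq_along(conds),
                   pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}
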