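#' Ligand-versus-vehicle perturbation for one peptide-timepoint
#'
#' The perturbation is the difference of replicate means,
#' \eqn{\Delta\%D = \bar{x}_{treated} - \bar{x}_{vehicle}} (percentage
#' points; protection is negative). Significance uses Welch's two-sample,
#' two-tailed t-test, avoiding an equal-variance assumption between arms.
#'
#' @param treated,vehicle replicate percent-deuterium vectors.
#' @param p_value compute a p-value (requires >= 2 replicates per arm)?
#' @return list with \code{delta}, \code{t_statistic}, \code{p_value} and
#'   \code{flag} (\code{""}, or \code{"zero-variance"} when both arms are
#'   constant: p is 1 for equal means, 0 otherwise).
#' @export
delta_percent_d <- function(treated, vehicle, p_value = TRUE) {
  if (length(treated) < 1L || length(vehicle) < 1L)
    stop("each arm needs at least one replicate")
  delta <- mean(treated) - mean(vehicle)
  if (!p_value)
    return(list(delta = delta, t_statistic = NA_real_,
                p_value = NA_real_, flag = ""))
  if (length(treated) < 2L || length(vehicle) < 2L)
    stop("a p-value needs >= 2 replicates in each arm")
  if (stats::var(treated) == 0 && stats::var(vehicle) == 0) {
    if (delta == 0)
      return(list(delta = 0, t_statistic = 0, p_value = 1,
                  flag = "zero-variance"))
    return(list(delta = delta, t_statistic = sign(delta) * Inf,
                p_value = 0, flag = "zero-variance"))
  }
  tt <- stats::t.test(treated, vehicle, var.equal = FALSE)
  list(delta = delta, t_statistic = unname(tt$statistic),
       p_value = tt$p.value, flag = "")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving wrapper around the BH false-discovery-rate step-up
#' procedure: adjusted values are >= raw values, capped at 1, and returned
#' in input order. NA p-values pass through as NA without entering the
#' family.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significance and screening-filter settings
#'
#' @param fdr_threshold adjusted-p cutoff for calling one compound's
#'   perturbation significant (default 0.05).
#' @param magnitude_threshold optional absolute delta-percent-D cutoff in
#'   percentage points applied on top of the FDR rule (default 0 = off).
#' @param min_significant_compounds a peptide-timepoint is kept when at
#'   least this many compounds are significant there (default 15, the
#'   convention for a 38-compound screen). Mutually exclusive with
#'   \code{min_significant_fraction}.
#' @param min_significant_fraction fractional variant of the rule for
#'   libraries of other sizes (e.g. 15/38); supply instead of the absolute
#'   count, never both.
#' @param bh_scope \code{"compound"} adjusts each compound's p-values
#'   across its peptide-timepoint family (default; matches a per-compound
#'   screening narrative), \code{"global"} adjusts across all records.
#' @return list of class \code{hdx_sig_config}.
#' @export
significance_config <- function(fdr_threshold = 0.05,
                                magnitude_threshold = 0,
                                min_significant_compounds = 15L,
                                min_significant_fraction = NULL,
                                bh_scope = c("compound", "global")) {
  bh_scope <- match.arg(bh_scope)
  if (fdr_threshold < 0 || magnitude_threshold < 0)
    stop("thresholds must be >= 0")
  if (!is.null(min_significant_fraction)) {
    if (min_significant_fraction < 0 || min_significant_fraction > 1)
      stop("min_significant_fraction must be in [0, 1]")
    min_significant_compounds <- NULL
  } else if (is.null(min_significant_compounds)) {
    stop("one of the compound-count rules must be set")
  }
  structure(list(fdr_threshold = fdr_threshold,
                 magnitude_threshold = magnitude_threshold,
                 min_significant_compounds = min_significant_compounds,
                 min_significant_fraction = min_significant_fraction,
                 bh_scope = bh_scope),
            class = "hdx_sig_config")
}

#' Compound x peptide-timepoint perturbation matrix
#'
#' The central object of a differential HDX-MS screen: for every compound
#' and peptide-timepoint, the perturbation versus vehicle with Welch
#' t-test p-value, BH-adjusted p (per compound family by default) and a
#' significance call. Cells lacking two replicates in either arm get a
#' delta when possible but no p-value; missing cells stay NA, never 0.
#'
#' @param observations long uptake table (see [simulate_hdx_dataset()] /
#'   [read_uptake_table()]).
#' @param vehicle condition id of the control arm.
#' @param config an [significance_config()].
#' @return object of class \code{hdx_perturbation}: list with
#'   \code{records} (long data.frame), \code{delta} (compound x cell
#'   matrix), \code{cells} (peptide-timepoint descriptors),
#'   \code{compounds}, \code{vehicle}, \code{config}, \code{peptides}.
#' @export
perturbation_matrix <- function(observations, vehicle = "vehicle",
                                config = significance_config()) {
  obs <- as.data.frame(observations)
  obs <- obs[obs$timepoint_s > 0, ]
  if (!vehicle %in% obs$condition)
    stop("vehicle condition '", vehicle, "' absent from the data")
  compounds <- setdiff(unique(obs$condition), vehicle)
  if (length(compounds) == 0L) stop("no compound conditions present")
  tps <- sort(unique(obs$timepoint_s))
  peps <- unique(obs[, intersect(
    c("peptide_id", "sequence", "start", "end", "charge"),
    names(obs)), drop = FALSE])
  peps <- peps[!duplicated(peps$peptide_id), , drop = FALSE]
  cells <- expand.grid(peptide_id = peps$peptide_id, timepoint_s = tps,
                       stringsAsFactors = FALSE)
  if (all(c("start", "end", "charge") %in% names(peps))) {
    i <- match(cells$peptide_id, peps$peptide_id)
    cells$label <- sprintf("%d-%d (%d) %s", peps$start[i], peps$end[i],
                           peps$charge[i], .fmt_tp(cells$timepoint_s))
  } else {
    cells$label <- paste(cells$peptide_id, .fmt_tp(cells$timepoint_s))
  }
  reps <- split(obs$percent_d,
                list(obs$condition, obs$peptide_id, obs$timepoint_s),
                drop = FALSE)
  getr <- function(cond, pid, tp)
    reps[[paste(cond, pid, tp, sep = ".")]]
  recs <- vector("list", length(compounds))
  for (ci in seq_along(compounds)) {
    cmp <- compounds[ci]
    delta <- t_stat <- p <- rep(NA_real_, nrow(cells))
    flag <- rep("", nrow(cells))
    for (k in seq_len(nrow(cells))) {
      tr <- getr(cmp, cells$peptide_id[k], cells$timepoint_s[k])
      ve <- getr(vehicle, cells$peptide_id[k], cells$timepoint_s[k])
      if (is.null(tr) || is.null(ve) || !length(tr) || !length(ve)) {
        flag[k] <- "missing"
        next
      }
      if (length(tr) < 2L || length(ve) < 2L) {
        delta[k] <- mean(tr) - mean(ve)
        flag[k] <- "insufficient-replication"
        next
      }
      r <- delta_percent_d(tr, ve)
      delta[k] <- r$delta; t_stat[k] <- r$t_statistic; p[k] <- r$p_value
      flag[k] <- r$flag
    }
    recs[[ci]] <- data.frame(compound = cmp,
                             peptide_id = cells$peptide_id,
                             timepoint_s = cells$timepoint_s,
                             label = cells$label, delta = delta,
                             t_statistic = t_stat, p_value = p,
                             adjusted_p = NA_real_, flag = flag)
  }
  records <- do.call(rbind, recs)
  if (config$bh_scope == "compound") {
    for (cmp in compounds) {
      i <- records$compound == cmp
      records$adjusted_p[i] <- bh_adjust(records$p_value[i])
    }
  } else {
    records$adjusted_p <- bh_adjust(records$p_value)
  }
  records$significant <- !is.na(records$adjusted_p) &
    records$adjusted_p < config$fdr_threshold &
    abs(records$delta) >= config$magnitude_threshold
  delta_m <- matrix(records$delta, nrow = length(compounds),
                    byrow = TRUE,
                    dimnames = list(compounds, cells$label))
  structure(list(records = records, delta = delta_m, cells = cells,
                 compounds = compounds, vehicle = vehicle,
                 config = config, peptides = peps),
            class = "hdx_perturbation")
}

.fmt_tp <- function(s) ifelse(s >= 3600, paste0(s / 3600, "hr"),
                              paste0(s, "s"))

#' @export
print.hdx_perturbation <- function(x, ...) {
  cat("Differential HDX perturbation matrix\n")
  cat(sprintf("  %d compounds x %d peptide-timepoints (vehicle: %s)\n",
              length(x$compounds), nrow(x$cells), x$vehicle))
  cat(sprintf("  delta %%D range [%.1f, %.1f]; %d significant records at FDR < %g\n",
              min(x$delta, na.rm = TRUE), max(x$delta, na.rm = TRUE),
              sum(x$records$significant, na.rm = TRUE),
              x$config$fdr_threshold))
  invisible(x)
}

#' @export
summary.hdx_perturbation <- function(object, ...) {
  f <- significance_filter(object)
  cat("Differential HDX screen summary\n")
  cat(sprintf("  %d compounds, %d peptides, %d timepoints\n",
              length(object$compounds),
              length(unique(object$cells$peptide_id)),
              length(unique(object$cells$timepoint_s))))
  cat(sprintf("  screening filter keeps %d of %d peptide-timepoints\n",
              nrow(f$kept), nrow(object$cells)))
  invisible(f)
}

#' Two-timepoint screening filter
#'
#' Keeps the peptide-timepoints at which enough compounds show
#' perturbations significantly different from zero (BH-adjusted p below
#' the FDR threshold, and beyond the magnitude threshold when one is set):
#' at least \code{min_significant_compounds} of them (or the fractional
#' rule). With the defaults this is the 15-of-38 / FDR < 0.05 convention.
#'
#' @param pm an [perturbation_matrix()].
#' @param config an [significance_config()]; defaults to the one stored in
#'   \code{pm}.
#' @return list of class \code{hdx_kept}: \code{kept} (cell descriptors),
#'   \code{counts} (significant-compound count per cell), \code{threshold}.
#' @export
significance_filter <- function(pm, config = NULL) {
  stopifnot(inherits(pm, "hdx_perturbation"))
  if (is.null(config)) config <- pm$config
  r <- pm$records
  if (nrow(r) == 0L) stop("empty perturbation matrix")
  sig <- !is.na(r$adjusted_p) & r$adjusted_p < config$fdr_threshold &
    abs(r$delta) >= config$magnitude_threshold
  counts <- tapply(sig, r$label, sum)
  counts <- counts[pm$cells$label]
  thr <- config$min_significant_compounds
  if (is.null(thr))
    thr <- ceiling(config$min_significant_fraction * length(pm$compounds))
  keep <- counts >= thr
  structure(list(kept = pm$cells[keep, , drop = FALSE],
                 counts = as.vector(counts), threshold = thr,
                 cells = pm$cells),
            class = "hdx_kept")
}

#' @export
print.hdx_kept <- function(x, ...) {
  cat(sprintf("Screening filter: %d of %d peptide-timepoints kept (>= %d significant compounds)\n",
              nrow(x$kept), nrow(x$cells), x$threshold))
  invisible(x)
}

#' Mean perturbation over timepoints
#'
#' Averages each compound-peptide perturbation over the available
#' timepoints (unweighted), the quantity painted onto structures in
#' differential HDX figures. Missing timepoints are simply excluded and
#' counted.
#'
#' @param pm an [perturbation_matrix()].
#' @param compound optional compound filter.
#' @return data.frame with \code{compound}, \code{peptide_id},
#'   \code{mean_delta}, \code{n_timepoints}.
#' @export
mean_perturbation <- function(pm, compound = NULL) {
  r <- pm$records
  if (!is.null(compound)) r <- r[r$compound %in% compound, ]
  sp <- split(r, list(r$compound, r$peptide_id), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    ok <- !is.na(d$delta)
    data.frame(compound = d$compound[1], peptide_id = d$peptide_id[1],
               mean_delta = if (any(ok)) mean(d$delta[ok]) else NA_real_,
               n_timepoints = sum(ok))
  }))
  rownames(out) <- NULL
  out
}
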