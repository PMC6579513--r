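#' Compound specification for the simulator
#'
#' A compound is modelled by its pharmacological class and the additive
#' shifts it applies to the log10 protection factor of residues inside
#' named structural regions, scaled by fractional occupancy. A \code{null}
#' compound has no effects (useful for type-I-error studies).
#'
#' @param id compound identifier.
#' @param pharm_class one of \code{"agonist"}, \code{"partial_agonist"},
#'   \code{"inverse_agonist"}, \code{"null"}.
#' @param region_effects named numeric vector, region name -> delta log10
#'   protection factor (>= 0 means stabilisation).
#' @param occupancy bound fraction in [0, 1]; defaults to 1 (single
#'   saturating concentration, as in a screening design).
#' @return object of class \code{hdx_compound}.
#' @export
compound_spec <- function(id, pharm_class = "null",
                          region_effects = numeric(0), occupancy = 1) {
  classes <- c("agonist", "partial_agonist", "inverse_agonist", "null")
  if (!pharm_class %in% classes)
    stop("unknown pharmacological class: ", pharm_class)
  if (occupancy < 0 || occupancy > 1) stop("occupancy must be in [0, 1]")
  region_effects <- unlist(region_effects)
  if (pharm_class == "null" && length(region_effects))
    stop("a null compound has no region effects")
  if (length(region_effects) && is.null(names(region_effects)))
    stop("region_effects must be named by region")
  structure(list(id = id, pharm_class = pharm_class,
                 region_effects = region_effects, occupancy = occupancy),
            class = "hdx_compound")
}

#' Default planted effect-size distributions per pharmacological class
#'
#' Every non-null class shares an orthosteric binding signature:
#' protection of the beta-sheet region and helices 3 and 7 with milder
#' distal H1/H2 effects. Agonists add strong stabilisation of the
#' activation helix H12 and the adjacent H4/H10; partial agonists add the
#' same elements weakly; inverse agonists add none. Effects are normal
#' (mean, sd) on the delta-log10-protection scale, truncated to
#' \code{[lower, upper]} (and always at 0). The compound-to-compound
#' spread is deliberately much wider for H12 than for the shared pocket
#' signature: modulator series show a wide range of H12 stabilisation
#' even within one pharmacological class, and it is this within-class
#' H12 variation that the functional-assay couplings ride on. The H12
#' distributions of agonists and partial agonists are truncated apart
#' (at 1.2 log10 units) because the class labels are themselves defined
#' by the degree of H12 stabilisation: a compound below that boundary
#' would have been called a partial agonist in the first place.
#'
#' @return named list (one element per class) of data.frames with columns
#'   \code{region}, \code{mean}, \code{sd}, \code{lower}, \code{upper}.
#' @export
default_effect_profiles <- function() {
  pocket <- data.frame(
    region = c("BSR", "H3", "H7", "H1", "H2"),
    mean = c(1.6, 1.3, 1.3, 0.8, 1.0),
    sd = c(0.20, 0.20, 0.20, 0.15, 0.15),
    lower = 0, upper = Inf)
  list(
    agonist = rbind(pocket, data.frame(
      region = c("H12", "H4", "H10"),
      mean = c(1.9, 1.8, 1.7), sd = c(0.75, 0.25, 0.25),
      lower = c(1.2, 0, 0), upper = Inf)),
    partial_agonist = rbind(pocket, data.frame(
      region = c("H12", "H4", "H10"),
      mean = c(0.70, 0.70, 1.20), sd = c(0.30, 0.15, 0.15),
      lower = 0, upper = c(1.1, Inf, Inf))),
    inverse_agonist = pocket,
    null = pocket[0, ])
}

# truncated-normal draw via the probability-integral transform
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Simulate a compound library with planted pharmacological classes
#'
#' Draws \code{n} compounds from the given class proportions, with
#' per-compound effect sizes drawn from the class effect-size
#' distributions (see [default_effect_profiles()]).
#'
#' @param n library size.
#' @param class_proportions named numeric vector summing to 1 over the
#'   four classes (missing classes get 0). Default mirrors a screen in
#'   which the three binder classes are roughly balanced.
#' @param effect_profiles list of per-class effect-size distributions in
#'   the format of [default_effect_profiles()].
#' @param occupancy occupancy applied to every compound.
#' @param seed integer seed.
#' @return list of \code{hdx_compound}, with a \code{classes} attribute
#'   giving the planted class labels.
#' @export
simulate_compound_library <- function(n = 38L,
                                      class_proportions = c(
                                        agonist = 13 / 38,
                                        partial_agonist = 12 / 38,
                                        inverse_agonist = 13 / 38),
                                      effect_profiles =
                                        default_effect_profiles(),
                                      occupancy = 1, seed = 1L) {
  classes <- c("agonist", "partial_agonist", "inverse_agonist", "null")
  unknown <- setdiff(names(class_proportions), classes)
  if (length(unknown)) stop("unknown class name: ",
                            paste(unknown, collapse = ", "))
  p <- setNames(numeric(4), classes)
  p[names(class_proportions)] <- class_proportions
  if (abs(sum(p) - 1) > 1e-8) stop("class proportions must sum to 1")
  set.seed(as.integer(seed))
  # largest-remainder apportionment for exact class counts
  quota <- n * p
  cnt <- floor(quota)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(quota - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1L
  }
  labels <- rep(classes, cnt)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- labels[i]
    prof <- effect_profiles[[cl]]
    eff <- if (!is.null(prof) && nrow(prof)) {
      lo <- pmax(0, prof$lower %||% 0)
      hi <- prof$upper %||% Inf
      setNames(.rtruncnorm(nrow(prof), prof$mean, prof$sd, lo, hi),
               prof$region)
    } else numeric(0)
    out[[i]] <- compound_spec(sprintf("C%02d", i), cl, eff, occupancy)
  }
  attr(out, "classes") <- labels
  out
}

#' Deuterium fraction of one residue under exchange kinetics
#'
#' Single-exponential amide exchange relative to full deuteration:
#' \deqn{f_i(t) = 1 - \exp(-(k_{int,i} / P_{i,eff}) \, t)}
#' where \eqn{\log_{10} P_{i,eff}} is the baseline log10 protection plus
#' occupancy times the sum of the compound's region effects covering the
#' residue. Fractions are Dmax-normalised, so deuterium-bath fraction and
#' back-exchange cancel and do not appear here.
#'
#' @param protein an \code{hdx_protein}.
#' @param compound an \code{hdx_compound} or \code{NULL} for the apo /
#'   vehicle state.
#' @param residues construct-numbered residue indices (vectorised).
#' @param t exposure time in seconds (scalar, >= 0).
#' @return numeric vector of fractions in [0, 1].
#' @export
residue_fraction <- function(protein, compound, residues, t) {
  if (t < 0) stop("exposure time must be >= 0")
  if (any(residues < protein$first_index) ||
      any(residues > protein$last_index))
    stop("residue index outside the construct")
  i <- residues - protein$first_index + 1L
  log10P <- protein$log10_protection[i]
  if (!is.null(compound) && length(compound$region_effects)) {
    for (rn in names(compound$region_effects)) {
      rr <- protein$regions[protein$regions$name == rn, ]
      if (nrow(rr) == 0L) stop("compound references unknown region: ", rn)
      sel <- residues >= rr$start & residues <= rr$end
      log10P[sel] <- log10P[sel] +
        compound$occupancy * compound$region_effects[[rn]]
    }
  }
  k_obs <- protein$k_int[i] / 10^log10P
  1 - exp(-k_obs * t)
}

#' Simulation settings
#'
#' @param timepoints deuterium exposure times in seconds (the full
#'   time-course default; use \code{c(10, 14400)} for the two-timepoint
#'   screening mode). Must be non-negative and strictly increasing.
#' @param n_replicates technical replicates per condition and timepoint.
#' @param noise_sd replicate noise on percent deuterium, in percentage
#'   points (typical HDX replicate precision is 1-2 points).
#' @param d2o_fraction deuterium fraction of the exchange buffer (5 uL
#'   sample into 20 uL D2O buffer gives 0.8); only affects raw centroid
#'   output, since Dmax normalisation cancels it.
#' @param back_exchange_loss fraction of incorporated deuterium lost to
#'   back-exchange during handling; also cancelled by Dmax normalisation.
#' @param seed master seed for everything the generator draws.
#' @return list of class \code{hdx_sim_config}.
#' @export
sim_config <- function(timepoints = c(0, 10, 30, 110, 380, 1270, 4270,
                                      14400),
                       n_replicates = 3L, noise_sd = 1.5,
                       d2o_fraction = 0.8, back_exchange_loss = 0.25,
                       seed = 1L) {
  if (any(timepoints < 0)) stop("timepoints must be >= 0")
  tp <- timepoints[timepoints > 0]
  if (length(tp) > 1 && any(diff(tp) <= 0))
    stop("timepoints must be strictly increasing")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (d2o_fraction <= 0 || d2o_fraction > 1)
    stop("d2o_fraction must be in (0, 1]")
  if (back_exchange_loss < 0 || back_exchange_loss >= 1)
    stop("back_exchange_loss must be in [0, 1)")
  structure(list(timepoints = timepoints,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, d2o_fraction = d2o_fraction,
                 back_exchange_loss = back_exchange_loss,
                 seed = as.integer(seed)),
            class = "hdx_sim_config")
}

# noise-free %D of one peptide: mean residue fraction over its
# exchangeable residues
.true_percent_d <- function(protein, compound, pep_row, t) {
  res <- exchangeable_residues(pep_row$start, pep_row$end,
                               pep_row$sequence)
  if (!length(res)) stop("peptide ", pep_row$id,
                         " has no exchangeable residues")
  100 * mean(residue_fraction(protein, compound, res, t))
}

# average mass difference between D and H
.D_MINUS_H <- 1.006277
.PROTON <- 1.007276
# rough average residue mass for synthetic centroid scaffolding
.MEAN_RESIDUE_MASS <- 111.1

#' Simulate replicate observations for one peptide
#'
#' Generates percent-deuterium observations for every timepoint and
#' replicate: the noise-free value is the mean residue fraction over the
#' peptide's exchangeable residues (times 100), to which Gaussian replicate
#' noise is added and the result clipped to [0, 100]. In \code{raw} mode
#' the same values are emitted as centroid m/z triples (undeuterated,
#' observed, fully deuterated Dmax control) consistent with the buffer
#' deuterium fraction and back-exchange loss, so that the centroid-to-%D
#' conversion can be exercised and round-tripped.
#'
#' @param protein an \code{hdx_protein}.
#' @param peptide one row of an \code{hdx_peptides} table.
#' @param compound an \code{hdx_compound} or \code{NULL} (vehicle).
#' @param config an [sim_config()].
#' @param raw emit centroid triples instead of percent deuterium.
#' @return data.frame with columns \code{timepoint_s}, \code{replicate}
#'   and either \code{percent_d} or \code{undeut_mz}, \code{obs_mz},
#'   \code{dmax_mz}, \code{charge}.
#' @export
simulate_peptide_observations <- function(protein, peptide, compound,
                                          config, raw = FALSE) {
  pep <- as.data.frame(peptide)
  set.seed(config$seed)
  tp <- config$timepoints[config$timepoints > 0]
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      timepoint_s = tp)[, 2:1]
  truth <- vapply(grid$timepoint_s, function(t)
    .true_percent_d(protein, compound, pep, t), numeric(1))
  pct <- pmin(100, pmax(0, truth + stats::rnorm(nrow(grid), 0,
                                                config$noise_sd)))
  if (!raw) return(cbind(grid, percent_d = pct))
  n_ex <- exchangeable_residue_count(pep$sequence)
  z <- pep$charge
  mono <- nchar(pep$sequence) * .MEAN_RESIDUE_MASS
  undeut <- (mono + z * .PROTON) / z
  span <- n_ex * .D_MINUS_H * config$d2o_fraction *
    (1 - config$back_exchange_loss) / z
  cbind(grid, undeut_mz = undeut, obs_mz = undeut + pct / 100 * span,
        dmax_mz = undeut + span, charge = z)
}

#' Simulate a full differential HDX-MS dataset
#'
#' Runs the exchange simulator for the vehicle condition and every
#' compound over all peptides, producing the long uptake table consumed by
#' the downstream modules. Deterministic given the config seed.
#'
#' @param protein an \code{hdx_protein}.
#' @param peptides an \code{hdx_peptides} table.
#' @param compounds list of \code{hdx_compound}.
#' @param config an [sim_config()].
#' @param vehicle condition id used for the untreated control arm.
#' @return data.frame (class \code{hdx_uptake}) with columns
#'   \code{peptide_id}, \code{sequence}, \code{start}, \code{end},
#'   \code{charge}, \code{condition}, \code{timepoint_s},
#'   \code{replicate}, \code{percent_d}.
#' @export
simulate_hdx_dataset <- function(protein, peptides, compounds, config,
                                 vehicle = "vehicle") {
  stopifnot(inherits(protein, "hdx_protein"))
  peptides <- hdx_peptides(peptides)
  tp <- config$timepoints[config$timepoints > 0]
  n_rep <- config$n_replicates
  conds <- c(list(NULL), compounds)
  cond_ids <- c(vehicle, vapply(compounds, `[[`, "", "id"))
  set.seed(config$seed)
  # noise-free truth per condition x peptide x timepoint, vectorised over
  # residues once per condition x timepoint
  n_pep <- nrow(peptides)
  ex_res <- lapply(seq_len(n_pep), function(j)
    exchangeable_residues(peptides$start[j], peptides$end[j],
                          peptides$sequence[j]))
  if (any(lengths(ex_res) == 0L))
    stop("peptide(s) with no exchangeable residues: ",
         paste(peptides$id[lengths(ex_res) == 0L], collapse = ", "))
  all_res <- protein$first_index:protein$last_index
  out <- vector("list", length(conds))
  for (ci in seq_along(conds)) {
    frac <- vapply(tp, function(t)
      residue_fraction(protein, conds[[ci]], all_res, t),
      numeric(length(all_res)))
    truth <- vapply(seq_along(tp), function(ti) {
      vapply(ex_res, function(r)
        100 * mean(frac[r - protein$first_index + 1L, ti]), numeric(1))
    }, numeric(n_pep))  # n_pep x n_tp
    g <- expand.grid(replicate = seq_len(n_rep), timepoint_s = tp,
                     pep = seq_len(n_pep))
    mu <- truth[cbind(g$pep, match(g$timepoint_s, tp))]
    pct <- pmin(100, pmax(0, mu + stats::rnorm(nrow(g), 0,
                                               config$noise_sd)))
    out[[ci]] <- data.frame(
      peptide_id = peptides$id[g$pep],
      sequence = peptides$sequence[g$pep],
      start = peptides$start[g$pep], end = peptides$end[g$pep],
      charge = peptides$charge[g$pep],
      condition = cond_ids[ci], timepoint_s = g$timepoint_s,
      replicate = g$replicate, percent_d = pct)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "vehicle") <- vehicle
  class(res) <- c("hdx_uptake", "data.frame")
  res
}

#' True (noise-free) regional perturbation score of compounds
#'
#' The planted regional-stabilisation score: the mean change in percent
#' deuterium (compound minus vehicle) over a region's residues at one
#' timepoint, from the closed-form kinetics. Protection gives negative
#' scores. This is the quantity the functional-assay link models couple to.
#'
#' @param protein an \code{hdx_protein}.
#' @param compounds list of \code{hdx_compound}.
#' @param region region name.
#' @param timepoint seconds.
#' @return named numeric vector of scores (percentage points), one per
#'   compound.
#' @export
regional_score <- function(protein, compounds, region, timepoint) {
  res <- region_residues(protein, region)
  apo <- mean(residue_fraction(protein, NULL, res, timepoint))
  out <- vapply(compounds, function(cmp)
    100 * (mean(residue_fraction(protein, cmp, res, timepoint)) - apo),
    numeric(1))
  names(out) <- vapply(compounds, `[[`, "", "id")
  out
}

#' Functional-assay link models
#'
#' Each assay readout is a linear function of a planted regional
#' stabilisation score plus Gaussian noise. The score for an assay is the
#' mean [regional_score()] over the listed regions at the listed
#' timepoint. Noise can be given directly (\code{noise_sd}, assay units)
#' or calibrated from a target population R-squared: with
#' \code{target_r2}, the noise SD is set to
#' \eqn{|slope| \cdot sd(score) \sqrt{(1-R^2)/R^2}} for the library at
#' hand, so the population coefficient of determination between score and
#' readout equals the target.
#'
#' Defaults mirror a nuclear-receptor modulator screen: coactivator
#' peptide recruitment (AlphaScreen, RLU) coupled to activation-helix H12
#' stabilisation at 10 s with population R2 = 0.638; thermal stability
#' (delta Tm, degrees C) coupled to the binding-site score (BSR) with
#' R2 = 0.538; cell-reporter fold change coupled to H2/H7 at 4 hr with
#' R2 = 0.51.
#'
#' @param alphascreen,thermal_shift,cell_reporter lists with elements
#'   \code{regions}, \code{timepoint}, \code{intercept}, \code{slope} and
#'   one of \code{noise_sd} / \code{target_r2}.
#' @return list of class \code{hdx_assay_link}.
#' @export
assay_link_model <- function(
    alphascreen = list(regions = "H12", timepoint = 10,
                       intercept = 1500, slope = -400,
                       target_r2 = 0.638),
    thermal_shift = list(regions = "BSR", timepoint = 14400,
                         intercept = 4.5, slope = -0.25,
                         target_r2 = 0.538),
    cell_reporter = list(regions = c("H2", "H7"), timepoint = 14400,
                         intercept = 1.2, slope = -0.18,
                         target_r2 = 0.51)) {
  links <- list(alphascreen = alphascreen, thermal_shift = thermal_shift,
                cell_reporter = cell_reporter)
  for (nm in names(links)) {
    l <- links[[nm]]
    stopifnot(all(c("regions", "timepoint", "intercept", "slope")
                  %in% names(l)))
    if (is.null(l$noise_sd) && is.null(l$target_r2))
      stop("link '", nm, "' needs noise_sd or target_r2")
    if (!is.null(l$noise_sd) && l$noise_sd < 0)
      stop("noise_sd must be >= 0")
  }
  structure(links, class = "hdx_assay_link")
}

#' Simulate functional-assay activities coupled to planted scores
#'
#' @param protein an \code{hdx_protein}.
#' @param compounds list of \code{hdx_compound}.
#' @param link an [assay_link_model()].
#' @param seed integer seed.
#' @return data.frame with columns \code{compound}, \code{assay},
#'   \code{value}; one row per compound per assay.
#' @export
simulate_activities <- function(protein, compounds,
                                link = assay_link_model(), seed = 1L) {
  stopifnot(inherits(link, "hdx_assay_link"))
  set.seed(as.integer(seed))
  n <- length(compounds)
  ids <- vapply(compounds, `[[`, "", "id")
  out <- list()
  for (assay in names(link)) {
    l <- link[[assay]]
    sc <- rowMeans(vapply(l$regions, function(r)
      regional_score(protein, compounds, r, l$timepoint),
      numeric(n)))
    sd_noise <- l$noise_sd
    if (is.null(sd_noise)) {
      pop_sd <- sqrt(mean((sc - mean(sc))^2))
      if (pop_sd == 0)
        stop("cannot calibrate target_r2: planted scores are constant")
      sd_noise <- abs(l$slope) * pop_sd *
        sqrt((1 - l$target_r2) / l$target_r2)
    }
    val <- l$intercept + l$slope * sc + stats::rnorm(n, 0, sd_noise)
    out[[assay]] <- data.frame(compound = ids, assay = assay, value = val)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
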