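#' Distance restraint table
#'
#' Experimental inter-label distances used for structural scoring: one row
#' per measurement with the technique (FRET or DEER), the conformational
#' state the distance is assigned to (M1, M2, or shared), the distance and
#' (possibly asymmetric) uncertainties in Angstrom.
#'
#' @param df data.frame with columns `pair_id`, `resid1`, `resid2`,
#'   `technique` ("FRET"/"DEER"), `state` ("M1"/"M2"/"shared"),
#'   `distance`, `sigma_minus`, `sigma_plus` (Angstrom; `sigma_plus`
#'   defaults to `sigma_minus`).
#' @return validated data.frame of class `restraint_table`.
#' @export
restraint_table <- function(df) {
  need <- c("pair_id", "resid1", "resid2", "technique", "state",
            "distance", "sigma_minus")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$sigma_plus)) df$sigma_plus <- df$sigma_minus
  if (any(df$sigma_minus <= 0) || any(df$sigma_plus <= 0))
    stop("uncertainties must be positive")
  if (!all(df$technique %in% c("FRET", "DEER")))
    stop("technique must be FRET or DEER")
  if (!all(df$state %in% c("M1", "M2", "shared")))
    stop("state must be M1, M2 or shared")
  class(df) <- c("restraint_table", "data.frame")
  df
}

#' Predict inter-label distances on a structure
#'
#' Computes AV (or ACV, when the site defines a contact fraction) clouds
#' for every residue appearing in the restraint table and returns the
#' model distance for each restraint row: the FRET-averaged apparent
#' distance for FRET rows and the mean inter-label distance for DEER
#' rows.
#'
#' @param structure a [coarse_structure()].
#' @param restraints a [restraint_table()].
#' @param fret_site,spin_site template [label_site()] /
#'   [spin_label_site()] whose parameters are applied at each residue.
#' @param grid_spacing AV grid spacing in Angstrom.
#' @param R0 Forster radius for the FRET average.
#' @return numeric vector of model distances (Angstrom), NA where a site
#'   is inaccessible.
#' @export
predict_restraints <- function(structure, restraints,
                               fret_site = label_site(1),
                               spin_site = spin_label_site(1),
                               grid_spacing = 1.5, R0 = 52) {
  clouds <- new.env(parent = emptyenv())
  get_cloud <- function(resid, technique) {
    key <- paste0(technique, resid)
    if (!is.null(clouds[[key]])) return(clouds[[key]])
    tmpl <- if (technique == "FRET") fret_site else spin_site
    site <- tmpl; site$resid <- resid
    cl <- tryCatch({
      av <- accessible_volume(structure, site, grid_spacing)
      if (site$contact_fraction > 0)
        av <- accessible_contact_volume(av, structure)
      av
    }, error = function(e) NA)
    clouds[[key]] <- cl
    cl
  }
  vapply(seq_len(nrow(restraints)), function(i) {
    row <- restraints[i, ]
    c1 <- get_cloud(row$resid1, row$technique)
    c2 <- get_cloud(row$resid2, row$technique)
    if (!inherits(c1, "label_cloud") || !inherits(c2, "label_cloud"))
      return(NA_real_)
    if (row$technique == "FRET")
      fret_observables(c1, c2, R0 = R0, max_points = 1500)$fret_distance
    else
      cloud_distance_distribution(c1, c2, kind = "spin",
                                  max_points = 1500) |>
        (\(d) attr(d, "mean"))()
  }, numeric(1))
}

# sigma for a signed residual with asymmetric uncertainties
asym_sigma <- function(resid, s_minus, s_plus)
  ifelse(resid < 0, s_minus, s_plus)

#' Label-based chi-square of a conformer pair
#'
#' Uncertainty-weighted squared deviations between experimental FRET/DEER
#' distances and AV-model distances predicted on a candidate (M1, M2)
#' structure pair: state-specific rows are evaluated on the assigned
#' member, shared rows on both members. Both label assignments
#' (M1 <-> M2 swapped) are evaluated and the smaller chi-square is
#' returned with the swap recorded.
#'
#' @param pred_m1,pred_m2 model distances per restraint row on the two
#'   candidate structures (from [predict_restraints()]).
#' @param restraints a [restraint_table()].
#' @return list with `chi2`, `swapped`, `n_residuals`, `valid` (FALSE if
#'   any needed prediction is NA, e.g. an inaccessible site).
#' @export
chi2_labels <- function(pred_m1, pred_m2, restraints) {
  score <- function(p1, p2) {
    tot <- 0; nres <- 0
    for (i in seq_len(nrow(restraints))) {
      row <- restraints[i, ]
      preds <- switch(row$state, M1 = p1[i], M2 = p2[i],
                      shared = c(p1[i], p2[i]))
      if (anyNA(preds)) return(NULL)
      for (p in preds) {
        r <- p - row$distance
        tot <- tot + (r / asym_sigma(r, row$sigma_minus, row$sigma_plus))^2
        nres <- nres + 1
      }
    }
    list(chi2 = tot, n = nres)
  }
  a <- score(pred_m1, pred_m2)
  b <- score(pred_m2, pred_m1)
  if (is.null(a) && is.null(b))
    return(list(chi2 = NA_real_, swapped = NA, n_residuals = NA_integer_,
                valid = FALSE))
  if (is.null(b) || (!is.null(a) && a$chi2 <= b$chi2))
    list(chi2 = a$chi2, swapped = FALSE, n_residuals = a$n, valid = TRUE)
  else
    list(chi2 = b$chi2, swapped = TRUE, n_residuals = b$n, valid = TRUE)
}

#' Effective number of informative restraints
#'
#' Greedy backward elimination: starting from the full restraint set,
#' repeatedly removes the restraint whose removal least changes the
#' chi-square ranking of the candidate ensemble (Spearman correlation
#' with the full-set ranking) and stops when the correlation would fall
#' below `rho_min`. The number of retained restraints estimates the
#' effective degrees of freedom of the dataset, discounting redundant
#' measurements.
#'
#' @param residual_matrix matrix (candidates x restraints) of normalized
#'   residuals (deviation / sigma) so that per-candidate chi-square is
#'   the row sum of squares.
#' @param rho_min Spearman threshold (default 0.9).
#' @return `k_eff`, the retained restraint count (integer >= 1).
#' @export
estimate_effective_dof <- function(residual_matrix, rho_min = 0.9) {
  R2 <- residual_matrix^2
  m <- ncol(R2)
  if (m == 1) return(1L)
  if (nrow(R2) < 2) stop("need an ensemble of candidates to assess redundancy")
  full_rank <- rank(rowSums(R2))
  keep <- seq_len(m)
  repeat {
    if (length(keep) == 1) break
    rho <- vapply(seq_along(keep), function(j) {
      sub <- keep[-j]
      stats::cor(full_rank, rank(rowSums(R2[, sub, drop = FALSE])),
                 method = "spearman")
    }, numeric(1))
    jbest <- which.max(rho)
    if (rho[jbest] < rho_min) break
    keep <- keep[-jbest]
  }
  length(keep)
}

#' Upper-tail chi-square p-value
#'
#' @param chi2 statistic (>= 0).
#' @param k degrees of freedom (>= 1).
#' @export
chi2_to_pvalue <- function(chi2, k) {
  if (any(k < 1)) stop("dof must be >= 1")
  stats::pchisq(chi2, df = k, lower.tail = FALSE)
}

#' Combine p-values by Fisher's method
#'
#' \eqn{X^2 = -2 \sum_i \ln p_i \sim \chi^2_{2k}} under the null; exact
#' zeros are clipped to the smallest positive double and flagged.
#'
#' @param p vector of p-values in (0, 1].
#' @return list with `X2`, `p` (combined), `clipped` flag.
#' @export
fisher_combine <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  clipped <- any(p == 0)
  p <- pmax(p, .Machine$double.xmin)
  X2 <- -2 * sum(log(p))
  list(X2 = X2, p = stats::pchisq(X2, df = 2 * length(p),
                                  lower.tail = FALSE),
       clipped = clipped)
}

#' Score candidate conformer pairs against label and SAXS data
#'
#' For every (M1, M2) pair from two candidate structure lists: computes
#' the label chi-square ([chi2_labels()]), the best two-state SAXS
#' mixture chi-square ([two_state_fit()]), converts both to p-values with
#' the supplied effective dofs, and combines them by Fisher's method.
#'
#' @param cands_m1,cands_m2 lists of [coarse_structure()] candidates.
#' @param restraints a [restraint_table()].
#' @param saxs_data experimental [saxs_curve()] (optional; label-only
#'   scoring when NULL).
#' @param k_label effective dof of the label dataset (default: estimated
#'   with [estimate_effective_dof()] over the scored pairs is up to the
#'   caller; here defaults to the residual count).
#' @param dmax Shannon-channel correction for the SAXS dof.
#' @param fret_site,spin_site,grid_spacing,R0 forwarded to
#'   [predict_restraints()].
#' @param saxs_q q grid for candidate Debye curves (1/Angstrom).
#' @return data.frame of class `scored_pairs`: one row per pair with
#'   chi2 values, p-values, Fisher statistic and combined p, SAXS
#'   fraction, swap and validity flags.
#' @export
score_pairs <- function(cands_m1, cands_m2, restraints, saxs_data = NULL,
                        k_label = NULL, dmax = NULL,
                        fret_site = label_site(1),
                        spin_site = spin_label_site(1),
                        grid_spacing = 1.5, R0 = 52,
                        saxs_q = seq(0.01, 0.25, length.out = 60)) {
  pred1 <- lapply(cands_m1, predict_restraints, restraints = restraints,
                  fret_site = fret_site, spin_site = spin_site,
                  grid_spacing = grid_spacing, R0 = R0)
  pred2 <- lapply(cands_m2, predict_restraints, restraints = restraints,
                  fret_site = fret_site, spin_site = spin_site,
                  grid_spacing = grid_spacing, R0 = R0)
  sx1 <- sx2 <- NULL
  if (!is.null(saxs_data)) {
    sx1 <- lapply(cands_m1, debye_scattering, q = saxs_q)
    sx2 <- lapply(cands_m2, debye_scattering, q = saxs_q)
  }
  rows <- list()
  for (i in seq_along(cands_m1)) for (j in seq_along(cands_m2)) {
    lab <- chi2_labels(pred1[[i]], pred2[[j]], restraints)
    kl <- k_label %||% lab$n_residuals
    p_lab <- if (lab$valid) chi2_to_pvalue(lab$chi2, kl) else NA_real_
    if (!is.null(saxs_data)) {
      ts <- two_state_fit(sx1[[i]], sx2[[j]], saxs_data, dmax = dmax)
      # rescale to the Shannon information scale: per-point reduced chi2
      # times the effective dof, so correlated q points are not overcounted
      n_pt <- length(saxs_data$q)
      stat <- ts$chi2 / max(1, n_pt - 3) * ts$dof
      p_sax <- chi2_to_pvalue(stat, ts$dof)
      x_m1 <- ts$x; chi2_sax <- ts$chi2r
    } else {
      p_sax <- NA_real_; x_m1 <- NA_real_; chi2_sax <- NA_real_
    }
    ps <- c(p_lab, if (!is.null(saxs_data)) p_sax)
    comb <- if (anyNA(ps)) list(X2 = NA_real_, p = NA_real_)
            else fisher_combine(ps)
    rows[[length(rows) + 1]] <- data.frame(
      m1 = i, m2 = j, chi2_labels = lab$chi2, chi2r_saxs = chi2_sax,
      k_label = if (lab$valid) kl else NA_integer_,
      p_labels = p_lab, p_saxs = p_sax, x_m1 = x_m1,
      fisher_X2 = comb$X2, p_combined = comb$p,
      swapped = lab$swapped, valid = lab$valid)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scored_pairs", "data.frame")
  out
}

#' Select conformer pairs at a combined confidence level
#'
#' Keeps pairs whose Fisher-combined p-value is at least the threshold
#' (invalid pairs are always rejected) and reports the rejected fraction.
#'
#' @param scored a `scored_pairs` data.frame from [score_pairs()].
#' @param confidence combined p threshold (default 0.68, at which the
#'   meta-analysis discriminates 95 percent of model pairs).
#' @return list with `accepted` (subset of rows), `rejected_fraction`.
#' @export
select_pairs <- function(scored, confidence = 0.68) {
  if (!nrow(scored)) stop("no scored pairs")
  keep <- !is.na(scored$p_combined) & scored$p_combined >= confidence
  list(accepted = scored[keep, , drop = FALSE],
       rejected_fraction = 1 - mean(keep))
}

#' Precision metrics of a selected structure ensemble
#'
#' Pairwise C-alpha distance SDs over the ensemble, the same quantity for
#' a reference ensemble generated by resampling the restraints within
#' their uncertainties around a best model and re-running the selection
#' (precision of an ideal, perfectly-consistent dataset), the normalized
#' precision (SD / SD_ref), and per-residue RMSF after iterative global
#' superposition onto the ensemble mean.
#'
#' @param ensemble list of [coarse_structure()]s (common bead topology).
#' @param reference_ensemble list of structures forming the reference
#'   (e.g. produced by [resample_reference_ensemble()]); `NULL` skips
#'   normalization.
#' @param n_iter superposition iterations for the RMSF (default 3).
#' @return object of class `ensemble_metrics`: `sd_matrix`,
#'   `sd_ref_matrix`, `normalized` (element-wise ratio, NA where the
#'   reference SD is 0), `rmsf` (per residue, Angstrom).
#' @export
ensemble_precision <- function(ensemble, reference_ensemble = NULL,
                               n_iter = 3) {
  ns <- vapply(ensemble, n_beads, integer(1))
  if (length(unique(ns)) != 1) stop("inconsistent residue sets")
  sd_mat <- pairwise_distance_sd(ensemble)
  sd_ref <- norm_mat <- NULL
  if (!is.null(reference_ensemble)) {
    sd_ref <- pairwise_distance_sd(reference_ensemble)
    norm_mat <- sd_mat / sd_ref
    norm_mat[sd_ref == 0] <- NA
    diag(norm_mat) <- 0
  }
  structure(list(sd_matrix = sd_mat, sd_ref_matrix = sd_ref,
                 normalized = norm_mat,
                 rmsf = ensemble_rmsf(ensemble, n_iter)),
            class = "ensemble_metrics")
}

pairwise_distance_sd <- function(ensemble) {
  n <- n_beads(ensemble[[1]])
  dists <- vapply(ensemble, function(s) as.vector(stats::dist(s$xyz)),
                  numeric(n * (n - 1) / 2))
  sds <- apply(dists, 1, stats::sd)
  M <- matrix(0, n, n)
  M[lower.tri(M)] <- sds
  M + t(M)
}

ensemble_rmsf <- function(ensemble, n_iter = 3) {
  coords <- lapply(ensemble, function(s) s$xyz)
  mean_c <- coords[[1]]
  for (it in seq_len(n_iter)) {
    coords <- lapply(coords, function(x) kabsch_superpose(x, mean_c)$coords)
    mean_c <- Reduce(`+`, coords) / length(coords)
  }
  dev2 <- Reduce(`+`, lapply(coords, function(x) rowSums((x - mean_c)^2)))
  sqrt(dev2 / length(coords))
}

#' Reference ensemble by restraint resampling
#'
#' Treats `best_model` (an index pair into the candidate lists) as truth:
#' replaces the experimental distances by the model predictions of that
#' pair perturbed within the stated uncertainties (seeded), re-runs
#' scoring and selection on the fixed candidate set, and returns the
#' structures of the accepted pairs. Repeating over seeds builds the
#' reference ensemble whose spread reflects the data uncertainty alone.
#'
#' @param cands_m1,cands_m2 candidate lists.
#' @param restraints a [restraint_table()].
#' @param best_model integer vector `c(i, j)` indexing the best pair.
#' @param n_resample number of resampled datasets.
#' @param confidence selection threshold.
#' @param seed RNG seed (mandatory: resampling must be reproducible).
#' @param scatter SD of the resampling noise per restraint; defaults to
#'   half the quoted sigma, matching the convention that quoted
#'   uncertainties include a systematic allowance on top of the random
#'   scatter.
#' @param ... forwarded to [score_pairs()].
#' @return list of accepted [coarse_structure()]s (possibly with
#'   duplicates across resamples; when a resample accepts no pair at the
#'   threshold, its best-scoring pair represents it).
#' @export
resample_reference_ensemble <- function(cands_m1, cands_m2, restraints,
                                        best_model, n_resample = 5,
                                        confidence = 0.68, seed,
                                        scatter = NULL, ...) {
  set.seed(seed)
  if (is.null(scatter)) scatter <- restraints$sigma_minus / 2
  base1 <- predict_restraints(cands_m1[[best_model[1]]], restraints, ...)
  base2 <- predict_restraints(cands_m2[[best_model[2]]], restraints, ...)
  truth <- ifelse(restraints$state == "M2", base2, base1)
  out <- list()
  for (rep in seq_len(n_resample)) {
    rs <- restraints
    rs$distance <- stats::rnorm(nrow(rs), truth, scatter)
    sc <- score_pairs(cands_m1, cands_m2, restraint_table(rs), ...)
    acc <- select_pairs(sc, confidence)$accepted
    if (!nrow(acc)) acc <- sc[which.max(sc$p_combined), , drop = FALSE]
    for (r in seq_len(nrow(acc))) {
      out[[length(out) + 1]] <- cands_m1[[acc$m1[r]]]
      out[[length(out) + 1]] <- cands_m2[[acc$m2[r]]]
    }
  }
  out
}
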