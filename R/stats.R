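#' Convert a dissociation constant to a binding free energy
#'
#' \eqn{\Delta G = RT \ln K_D} (for K_D in molar, i.e. against the 1 M
#' standard state): a smaller dissociation constant -- a tighter binder --
#' gives a more negative free energy, so a nanomolar ligand sits near
#' -12 kcal/mol at room temperature. The conversion is often typeset as
#' \eqn{-RT \ln K_D} with the association constant implied; the sign here
#' is fixed by the physics (tabulated binding free energies are negative).
#'
#' @param kd Equilibrium dissociation constant(s), molar (> 0).
#' @param temperature Temperature, K (default 298.15; set 310.15 for
#'   physiological conditions).
#' @param R Gas constant, kcal/(mol K).
#' @return Binding free energy, kcal/mol.
#' @examples
#' kd_to_dg(1e-9)  # about -12.3 kcal/mol at 298.15 K
#' @export
kd_to_dg <- function(kd, temperature = fe_constants$T_standard,
                     R = fe_constants$R_kcal) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop_fe("'kd' must be > 0")
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  R * temperature * log(kd)
}

#' Convert a binding free energy back to a dissociation constant
#'
#' Inverse of [kd_to_dg()]: \eqn{K_D = \exp(\Delta G / RT)}.
#'
#' @param dg Binding free energy, kcal/mol.
#' @inheritParams kd_to_dg
#' @return Dissociation constant, molar.
#' @export
dg_to_kd <- function(dg, temperature = fe_constants$T_standard,
                     R = fe_constants$R_kcal) {
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  exp(dg / (R * temperature))
}

#' An experimental affinity measurement
#'
#' One ligand-receptor binding free energy with its uncertainty. Given as a
#' dissociation constant, it is converted via [kd_to_dg()] (with the
#' uncertainty propagated through the logarithm,
#' \eqn{\sigma_{\Delta G} = RT \, \sigma_{K_D}/K_D}).
#'
#' @param ligand,receptor Identifier strings.
#' @param dg Binding free energy, kcal/mol (give either `dg` or `kd`).
#' @param err Uncertainty, same units as the value given (>= 0).
#' @param kd Dissociation constant, molar.
#' @param temperature Temperature for the K_D conversion, K.
#' @param source Optional provenance tag.
#' @return A one-row data frame of class `"affinity_measurement"` with
#'   columns `ligand, receptor, dg, err, source`.
#' @export
affinity_measurement <- function(ligand, receptor, dg = NULL, err = 0,
                                 kd = NULL,
                                 temperature = fe_constants$T_standard,
                                 source = NA_character_) {
  if (is.null(dg) == is.null(kd)) {
    stop_fe("give exactly one of 'dg' or 'kd'")
  }
  check_number(err, "err", lower = 0)
  if (!is.null(kd)) {
    dg <- kd_to_dg(kd, temperature)
    err <- fe_constants$R_kcal * temperature * err / kd
  }
  out <- data.frame(ligand = as.character(ligand),
                    receptor = as.character(receptor),
                    dg = dg, err = err, source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("affinity_measurement", "data.frame")
  out
}

#' Average replicate affinity measurements
#'
#' Unweighted mean of replicate \eqn{\Delta G} determinations for one
#' ligand/receptor, with the replicate uncertainties combined in quadrature
#' and divided by the replicate count
#' (\eqn{\sqrt{\sum \sigma_i^2}/n}, the standard error of the mean of
#' independent measurements).
#'
#' @param measurements Data frame of [affinity_measurement()] rows for a
#'   single ligand and receptor.
#' @return A one-row `"affinity_measurement"`.
#' @export
average_measurements <- function(measurements) {
  if (nrow(measurements) < 1L) stop_fe("no measurements to average")
  if (length(unique(measurements$receptor)) > 1L) {
    stop_fe("cannot average across receptors: %s",
            paste(unique(measurements$receptor), collapse = ", "))
  }
  if (length(unique(measurements$ligand)) > 1L) {
    stop_fe("cannot average across ligands: %s",
            paste(unique(measurements$ligand), collapse = ", "))
  }
  n <- nrow(measurements)
  affinity_measurement(measurements$ligand[1], measurements$receptor[1],
                       dg = mean(measurements$dg),
                       err = sqrt(sum(measurements$err^2)) / n,
                       source = "averaged")
}

#' Experimental relative binding free energy of a transformation
#'
#' For an alchemical transformation L1 to L2 at one receptor, the
#' experimental observable is
#' \eqn{\Delta\Delta G = \Delta G(L2) - \Delta G(L1)}, with the two
#' uncertainties added in quadrature. Values are rounded to `digits`
#' decimals (2 by default, the precision at which such tables are printed);
#' use `digits = Inf` for full precision.
#'
#' @param g1,g2 One-row [affinity_measurement()]s for L1 and L2 at the same
#'   receptor.
#' @param digits Decimal places for the reported values (default 2).
#' @return A one-row data frame of class `"transformation_record"`:
#'   `l1, l2, receptor, ddg, err`.
#' @export
experimental_ddg <- function(g1, g2, digits = 2) {
  if (!identical(g1$receptor, g2$receptor)) {
    stop_fe("receptor mismatch: %s vs %s", g1$receptor, g2$receptor)
  }
  ddg <- g2$dg - g1$dg
  err <- sqrt(g1$err^2 + g2$err^2)
  if (is.finite(digits)) {
    ddg <- round(ddg, digits)
    err <- round(err, digits)
  }
  out <- data.frame(l1 = g1$ligand, l2 = g2$ligand, receptor = g1$receptor,
                    ddg = ddg, err = err, stringsAsFactors = FALSE)
  class(out) <- c("transformation_record", "data.frame")
  out
}

#' Experimental relative-affinity table for a set of transformations
#'
#' Builds the full experimental \eqn{\Delta\Delta G} table for a list of
#' ligand pairs from an affinity table: for each pair and each receptor in
#' which both ligands have a measurement, [experimental_ddg()] is computed;
#' missing entries stay `NA` (never imputed).
#'
#' @param affinities Data frame with columns `ligand, receptor, dg, err`
#'   (e.g. from [read_affinity_table()]).
#' @param pairs Data frame with columns `l1, l2`.
#' @param receptors Receptors to report (default: those in `affinities`).
#' @param digits Decimal places (default 2).
#' @return Data frame with `l1, l2` and, per receptor, `ddg_<receptor>` and
#'   `err_<receptor>` columns.
#' @export
ddg_table <- function(affinities, pairs, receptors = NULL, digits = 2) {
  receptors <- receptors %||% sort(unique(affinities$receptor))
  out <- pairs[, c("l1", "l2")]
  for (rec in receptors) {
    sub <- affinities[affinities$receptor == rec & is.finite(affinities$dg), ]
    dd <- ee <- rep(NA_real_, nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i1 <- match(pairs$l1[k], sub$ligand)
      i2 <- match(pairs$l2[k], sub$ligand)
      if (!is.na(i1) && !is.na(i2)) {
        r <- experimental_ddg(
          affinity_measurement(sub$ligand[i1], rec, dg = sub$dg[i1],
                               err = sub$err[i1]),
          affinity_measurement(sub$ligand[i2], rec, dg = sub$dg[i2],
                               err = sub$err[i2]),
          digits = digits)
        dd[k] <- r$ddg; ee[k] <- r$err
      }
    }
    out[[paste0("ddg_", rec)]] <- dd
    out[[paste0("err_", rec)]] <- ee
  }
  out
}

#' Pearson correlation between predictions and experiments
#'
#' Standard product-moment correlation. Zero variance in either vector
#' leaves the statistic undefined and is an explicit error rather than a
#' silent `NA`.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_fe("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop_fe("need at least 3 points for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_fe("correlation undefined: zero variance in input")
  }
  stats::cor(x, y)
}

#' Mean absolute error
#'
#' \eqn{MAE = \mathrm{mean}(|x_i - y_i|)}, kcal/mol for free-energy vectors.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Mean absolute error.
#' @export
mean_absolute_error <- function(x, y) {
  if (length(x) != length(y)) stop_fe("'x' and 'y' must have equal length")
  if (length(x) < 1L) stop_fe("need at least one point")
  mean(abs(x - y))
}

#' Cook's-distance outlier screening
#'
#' Flags influential points in a prediction-vs-experiment comparison using
#' Cook's distance with the common \eqn{D_i > 4/n} rule. By default an
#' ordinary least-squares regression of experiment on prediction (with
#' intercept) is fitted and `stats::cooks.distance` applied. The
#' `"identity"` variant measures influence of residuals about the fixed
#' line \eqn{y = x} (the natural reference when the prediction is itself an
#' estimate of \eqn{y}) using the same leverage-weighted form; it is a
#' heuristic, since Cook's distance presupposes a fitted model, and the OLS
#' variant is the default.
#'
#' @param x Predictions (n >= 4, non-degenerate).
#' @param y Experimental values, same length.
#' @param variant `"ols"` (default) or `"identity"`.
#' @param threshold Flagging threshold (default `4/n`).
#' @return List with `distance` (per-point Cook's D), `threshold`,
#'   `outlier` (logical flags), and `variant`.
#' @export
cooks_outliers <- function(x, y, variant = c("ols", "identity"),
                           threshold = NULL) {
  variant <- match.arg(variant)
  n <- length(x)
  if (length(y) != n) stop_fe("'x' and 'y' must have equal length")
  if (n < 4L) stop_fe("need at least 4 points for the 4/n rule")
  if (stats::sd(x) == 0) stop_fe("degenerate predictions: zero variance")
  threshold <- threshold %||% (4 / n)
  if (variant == "ols") {
    fit <- stats::lm(y ~ x)
    res <- stats::residuals(fit)
    # exactly collinear data: zero influence by definition (the naive
    # formula would divide rounding noise by a ~0 residual variance)
    d <- if (sum(res^2) <= 1e-20 * max(1, sum(y^2))) {
      rep(0, n)
    } else {
      unname(stats::cooks.distance(fit))
    }
  } else {
    e <- y - x
    h <- 1 / n + (x - mean(x))^2 / sum((x - mean(x))^2)
    s2 <- sum(e^2) / (n - 2)
    d <- if (s2 == 0) rep(0, n) else e^2 * h / (2 * s2 * (1 - h)^2)
  }
  list(distance = d, threshold = threshold,
       outlier = d > threshold, variant = variant)
}

#' Prediction-vs-experiment summary
#'
#' One-call summary of a set of predictions against experiment: Pearson
#' correlation, mean absolute error, and Cook's-distance outlier flags.
#'
#' @inheritParams cooks_outliers
#' @return List with `r_pearson`, `mae`, and `outliers` (a
#'   [cooks_outliers()] result).
#' @export
prediction_summary <- function(x, y, variant = "ols") {
  list(r_pearson = pearson_r(x, y),
       mae = mean_absolute_error(x, y),
       outliers = cooks_outliers(x, y, variant = variant))
}

#' Packaged adenosine-receptor affinity data
#'
#' Experimental binding free energies (kcal/mol, with uncertainties) for 23
#' adenosine A1/A2A receptor ligands, assembled from published
#' radioligand-binding dissociation constants, and the 11 ligand-pair
#' transformations with experimentally determined relative binding free
#' energies used to validate alchemical predictions. Missing entries are
#' `NA` (a ligand measured at only one receptor).
#'
#' @return `adenosine_affinities()`: a long data frame with columns
#'   `ligand` (abbreviation), `name`, `type`, `pdb`, `receptor`
#'   (`"A1"`/`"A2A"`), `dg`, `err`. `adenosine_transformations()`: a data
#'   frame with `l1, l2, ddg_A1, err_A1, ddg_A2A, err_A2A`.
#' @export
adenosine_affinities <- function() {
  path <- system.file("extdata", "adenosine_affinities.tsv",
                      package = "ensembleFE", mustWork = TRUE)
  wide <- read_affinity_table(path)
  long <- rbind(
    data.frame(ligand = wide$abbreviation, name = wide$ligand,
               type = wide$type, pdb = wide$pdb, receptor = "A1",
               dg = wide$dg_a1, err = wide$err_a1,
               stringsAsFactors = FALSE),
    data.frame(ligand = wide$abbreviation, name = wide$ligand,
               type = wide$type, pdb = wide$pdb, receptor = "A2A",
               dg = wide$dg_a2a, err = wide$err_a2a,
               stringsAsFactors = FALSE))
  long[order(long$receptor, long$ligand), ]
}

#' @rdname adenosine_affinities
#' @export
adenosine_transformations <- function() {
  path <- system.file("extdata", "adenosine_ddg_experiment.tsv",
                      package = "ensembleFE", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}
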