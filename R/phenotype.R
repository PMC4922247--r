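#' Fineness ratio
#'
#' Body slenderness as fork length divided by maximal body depth; a
#' dimensionless shape index (hydrodynamically efficient fish fall roughly
#' between 4.5 and 8).
#'
#' @param fork_length fork length, cm.
#' @param body_depth maximal body depth, cm.
#' @return `fork_length / body_depth` (vectorized).
#' @export
fineness_ratio <- function(fork_length, body_depth) {
  if (any(!is.finite(fork_length)) || any(!is.finite(body_depth)) ||
      any(fork_length <= 0) || any(body_depth <= 0)) {
    stop("fork_length and body_depth must be positive and finite", call. = FALSE)
  }
  fork_length / body_depth
}

#' Mass-correct a metabolic trait by residual analysis
#'
#' Regresses log10(trait) on log10(body mass) across the cohort by ordinary
#' least squares and returns the per-fish residuals: positive residuals mark
#' fish with higher-than-expected metabolism for their size. Applied to SMR,
#' MMR, aerobic scope and the mass-dependent secondary traits; recovery rate
#' and metabolic variability are analysed uncorrected.
#'
#' @param trait per-fish trait values (must be positive), mg O2 kg^-1 h^-1.
#' @param mass per-fish body mass (any consistent unit; only the log-slope
#'   matters).
#' @return list with `residuals` (log10 scale), `slope`, `intercept`.
#' @export
mass_correct <- function(trait, mass) {
  if (length(trait) != length(mass)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(trait) & is.finite(mass)
  if (sum(ok) < 3) stop("need at least 3 fish with complete data", call. = FALSE)
  if (any(trait[ok] <= 0) || any(mass[ok] <= 0)) {
    stop("trait and mass must be positive for log10 transformation", call. = FALSE)
  }
  if (var(log10(mass[ok])) < .Machine$double.eps) {
    stop("zero variance in body mass: residuals undefined", call. = FALSE)
  }
  fit <- lm(log10(trait) ~ log10(mass), subset = ok)
  res <- rep(NA_real_, length(trait))
  res[ok] <- stats::residuals(fit)
  list(residuals = res,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]))
}

#' Principal component reduction of the seven secondary metabolic traits
#'
#' Centres and scales each trait to unit variance (sample SD), performs an
#' eigendecomposition of the correlation matrix, and returns the first
#' `n_axes` score vectors. Axes are ordered by descending eigenvalue; the
#' sign of each loading vector is fixed so that its largest-magnitude
#' element is positive. Fish with any missing trait are dropped listwise
#' with a warning.
#'
#' @param traits numeric matrix or data.frame, one row per fish, one column
#'   per trait (row names or a `fish_id` column identify fish).
#' @param n_axes number of axes to return as scores (default 3).
#' @return list with `scores` (n x n_axes, centred; columns `MET1`...),
#'   `loadings` (p x p orthonormal), `eigenvalues`,
#'   `cumulative_variance` (percent, length `n_axes`), and `kept` (logical,
#'   which rows entered the PCA).
#' @export
pca_traits <- function(traits, n_axes = 3) {
  if (is.data.frame(traits)) {
    id <- traits$fish_id
    traits <- as.matrix(traits[setdiff(names(traits), "fish_id")])
    if (!is.null(id)) rownames(traits) <- id
  }
  storage.mode(traits) <- "double"
  keep <- stats::complete.cases(traits)
  if (any(!keep)) {
    warning(sprintf("dropping %d fish with missing traits from the PCA",
                    sum(!keep)))
  }
  x <- traits[keep, , drop = FALSE]
  if (nrow(x) < 4) stop("need at least 4 fish with complete traits", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds < .Machine$double.eps)) {
    stop(sprintf("constant trait column(s): %s",
                 paste(colnames(x)[sds < .Machine$double.eps], collapse = ", ")),
         call. = FALSE)
  }
  z <- scale(x, center = TRUE, scale = sds)
  eig <- eigen(stats::cor(x), symmetric = TRUE)
  load <- eig$vectors
  # sign convention: largest-|loading| element of each axis is positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("MET", seq_len(ncol(load)))
  n_axes <- min(n_axes, ncol(load))
  scores <- z %*% load[, seq_len(n_axes), drop = FALSE]
  ev <- pmax(eig$values, 0)
  cumvar <- cumsum(ev) / sum(ev) * 100
  list(scores = scores,
       loadings = load,
       eigenvalues = ev,
       cumulative_variance = cumvar[seq_len(n_axes)],
       kept = keep)
}

#' Assemble the corrected per-fish phenotype table
#'
#' Joins morphometrics and metabolic traits for a cohort: computes fineness
#' ratio, mass-corrects SMR, MMR, aerobic scope and the five mass-dependent
#' secondary traits (average, routine, spontaneous min/max and spontaneous
#' scope), leaves recovery rate and metabolic variability uncorrected, and
#' reduces the seven secondary traits (corrected where applicable) to three
#' principal component scores.
#'
#' @param traits `data.frame` with one `metabolic_traits` row per fish
#'   (column `fish_id` required).
#' @param phenotypes `data.frame` with `fish_id`, `body_mass` (g),
#'   `fork_length` and `body_depth` (cm).
#' @return `data.frame` keyed by `fish_id` with `fork_length`,
#'   `fineness_ratio`, residual columns `smr_resid`, `mmr_resid`,
#'   `ams_resid`, and scores `MET1`-`MET3`; the PCA object is attached as
#'   attribute `"pca"`.
#' @export
correct_traits <- function(traits, phenotypes) {
  m <- merge(traits, phenotypes, by = "fish_id", sort = TRUE)
  if (nrow(m) < 4) stop("need at least 4 fish", call. = FALSE)
  mass <- m$body_mass
  corr <- function(v) mass_correct(v, mass)$residuals
  sec <- data.frame(
    fish_id = m$fish_id,
    recovery_rate = m$recovery_rate,
    avg_mo2 = corr(m$avg_mo2),
    metabolic_variability = m$metabolic_variability,
    routine_mo2 = corr(m$routine_mo2),
    spont_min = corr(m$spont_min),
    spont_max = corr(m$spont_max),
    spont_ams = corr(m$spont_ams)
  )
  pca <- pca_traits(sec)
  out <- data.frame(
    fish_id = m$fish_id,
    fork_length = m$fork_length,
    fineness_ratio = fineness_ratio(m$fork_length, m$body_depth),
    smr_resid = corr(m$smr),
    mmr_resid = corr(m$mmr),
    ams_resid = corr(m$ams),
    stringsAsFactors = FALSE
  )
  sc <- matrix(NA_real_, nrow(out), 3,
               dimnames = list(NULL, c("MET1", "MET2", "MET3")))
  sc[pca$kept, ] <- pca$scores[, 1:3]
  out <- cbind(out, sc)
  attr(out, "pca") <- pca
  out
}
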