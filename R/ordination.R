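## Ordination: compositional PCA, Hellinger diatom PCA, probabilistic PCA
## with missing values, and age-uncertain ensemble PCA.

#' Centred (optionally standardized) PCA by singular value decomposition
#'
#' @param x numeric matrix, samples x variables, no missing values.
#' @param standardize scale columns to unit variance (zero-variance columns
#'   are excluded with a notice).
#' @return a `pca_result`: `loadings` (variable x component, unit norm),
#'   `scores` (sample x component), `varfrac` (variance fractions), `sdev`.
#' @export
standardized_pca <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    abort("PCA needs >= 2 samples and >= 2 variables", "limnoflux_parameter_error")
  if (anyNA(x))
    abort("missing values: use ppca_missing()", "limnoflux_data_error")
  if (standardize) {
    sdv <- apply(x, 2, stats::sd)
    zero <- sdv == 0
    if (any(zero)) {
      message(sprintf("excluding %d zero-variance column(s): %s",
                      sum(zero), paste(colnames(x)[zero], collapse = ", ")))
      x <- x[, !zero, drop = FALSE]
      if (ncol(x) < 2L)
        abort("fewer than 2 variables left after dropping zero variance",
              "limnoflux_data_error")
    }
    x <- scale(x, center = TRUE, scale = TRUE)
  } else {
    x <- scale(x, center = TRUE, scale = FALSE)
  }
  sv <- svd(x)
  lam <- sv$d^2
  structure(list(loadings = structure(sv$v, dimnames = list(colnames(x), NULL)),
                 scores = sv$u %*% diag(sv$d, length(sv$d)),
                 varfrac = lam / sum(lam),
                 sdev = sv$d / sqrt(max(nrow(x) - 1, 1))),
            class = "pca_result")
}

#' Hellinger-transformed diatom PCA
#'
#' Taxa are retained when their maximum relative abundance exceeds
#' `min_abundance` and they occur in at least `min_occurrences` samples.
#' Retained counts are re-closed per sample and Hellinger transformed
#' (`sqrt` of relative abundance), then subjected to a centred,
#' non-standardized PCA.
#'
#' @param counts a `diatom_counts` table or a plain count matrix
#'   (samples x taxa).
#' @param min_abundance relative-abundance threshold (default 0.01 = 1%).
#' @param min_occurrences minimum number of samples with presence.
#' @return a `pca_result` with the retained taxa in
#'   `attr(, "taxa_retained")` and the transformed matrix in
#'   `attr(, "hellinger")`.
#' @export
hellinger_pca <- function(counts, min_abundance = 0.01, min_occurrences = 2) {
  m <- count_matrix(counts)
  tot <- rowSums(m)
  if (any(tot <= 0))
    abort("every sample must have a positive valve total", "limnoflux_data_error")
  rel <- m / tot
  keep <- apply(rel, 2, max) > min_abundance & colSums(m > 0) >= min_occurrences
  if (!any(keep))
    abort("all taxa removed by the abundance/occurrence filter",
          "limnoflux_filter_error")
  mk <- m[, keep, drop = FALSE]
  h <- sqrt(mk / rowSums(mk))
  res <- standardized_pca(h, standardize = FALSE)
  attr(res, "taxa_retained") <- colnames(mk)
  attr(res, "hellinger") <- h
  res
}

## Extract the taxon count matrix from a diatom_counts table.
count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  reserved <- c("depth", "age_ce", "cysts", "microspheres", "spike", "mass_g")
  m <- as.matrix(counts[, setdiff(names(counts), reserved), drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Probabilistic PCA with missing values (EM)
#'
#' Fits the probabilistic PCA model `x = mu + W z + eps`,
#' `eps ~ N(0, sigma^2 I)`, by expectation-maximization with missing
#' cells integrated out of the observed-data likelihood. With complete
#' data the maximum-likelihood solution coincides with classical PCA.
#'
#' @param x numeric matrix with (possibly) missing cells; every row and
#'   column needs at least one observed value.
#' @param n_components latent dimension.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param seed RNG seed (random restarts are not used; kept for interface
#'   stability).
#' @return a `pca_result` with orthonormal `loadings`, `scores`,
#'   `varfrac`, plus `sigma2` and the log-likelihood trace.
#' @export
ppca_missing <- function(x, n_components = 2, tol = 1e-9, max_iter = 2000,
                         seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x); q <- n_components
  if (q < 1 || q >= p)
    abort("n_components must be in [1, ncol - 1]", "limnoflux_parameter_error")
  obs <- is.finite(x)
  if (any(rowSums(obs) == 0L) || any(colSums(obs) == 0L))
    abort("every row and column needs at least one observed cell",
          "limnoflux_precondition_error")
  mu <- colSums(ifelse(obs, x, 0)) / colSums(obs)
  xc <- sweep(x, 2, mu)
  xc[!obs] <- 0

  ## init: eigen solution of the mean-imputed covariance (exact ML when
  ## complete; note the 1/n denominator matches the likelihood)
  S0 <- crossprod(xc) / n
  e0 <- eigen(S0, symmetric = TRUE)
  ev <- pmax(e0$values, 0)
  sigma2 <- max(mean(ev[(q + 1):p]), 1e-12)
  W <- e0$vectors[, 1:q, drop = FALSE] %*%
    diag(sqrt(pmax(ev[1:q] - sigma2, 1e-12)), q)

  ## group rows by missingness pattern once
  pat <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)

  ll_old <- -Inf; ll_trace <- numeric(0)
  Ez <- matrix(0, n, q)
  for (it in seq_len(max_iter)) {
    ## E-step
    ll <- 0
    SW <- matrix(0, p, q)        # sum_i x_i E[z_i]'  (observed rows only)
    Szz <- matrix(0, q, q)       # sum_i E[z_i z_i']
    denom <- numeric(p)          # per-dimension observed counts
    for (rows in groups) {
      o <- obs[rows[1], ]
      Wo <- W[o, , drop = FALSE]
      M <- crossprod(Wo) + diag(sigma2, q)
      Mi <- solve(M)
      Xo <- xc[rows, o, drop = FALSE]
      EzR <- Xo %*% Wo %*% Mi
      Ez[rows, ] <- EzR
      Szz <- Szz + length(rows) * sigma2 * Mi + crossprod(EzR)
      SW[o, ] <- SW[o, ] + crossprod(Xo, EzR)
      denom[o] <- denom[o] + length(rows)
      ## observed-data log-likelihood for the group
      Co <- tcrossprod(Wo) + diag(sigma2, sum(o))
      cf <- chol(Co)
      z <- forwardsolve(t(cf), t(Xo))
      ll <- ll - 0.5 * length(rows) * (sum(o) * log(2 * pi) +
                                         2 * sum(log(diag(cf)))) -
        0.5 * sum(z^2)
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll

    ## M-step
    W_new <- SW %*% solve(Szz)
    ## sigma^2 over observed cells only
    resid <- 0; n_obs <- 0
    for (rows in groups) {
      o <- obs[rows[1], ]
      Wo <- W_new[o, , drop = FALSE]
      Xo <- xc[rows, o, drop = FALSE]
      EzR <- Ez[rows, , drop = FALSE]
      M <- crossprod(W[o, , drop = FALSE]) + diag(sigma2, q)
      Mi <- solve(M)
      Vz <- sigma2 * Mi
      resid <- resid + sum((Xo - EzR %*% t(Wo))^2) +
        length(rows) * sum((Wo %*% Vz) * Wo)
      n_obs <- n_obs + length(rows) * sum(o)
    }
    sigma2 <- max(resid / n_obs, 1e-12)
    W <- W_new
    if (it == max_iter)
      abort(sprintf("PPCA did not converge in %d iterations (last rel. change %.3g)",
                    max_iter, abs(ll - ll_old) / abs(ll_old)),
            "limnoflux_convergence_error")
  }

  ## rotate to orthonormal loadings ordered by variance
  sw <- svd(W)
  loadings <- sw$u
  lam <- sw$d^2 + sigma2
  total_var <- sum(sw$d^2) + p * sigma2
  scores <- Ez %*% sw$v %*% diag(sw$d, q)
  dimnames(loadings) <- list(colnames(x), NULL)
  structure(list(loadings = loadings, scores = scores,
                 varfrac = lam / total_var, sdev = sqrt(lam),
                 sigma2 = sigma2, loglik = ll_trace, mu = mu),
            class = "pca_result")
}

#' Bundle an age-uncertain series for ensemble PCA
#'
#' @param name variable name.
#' @param ages member x sample matrix of ages, yr CE.
#' @param values either one value per sample or a member x sample matrix.
#' @export
au_series <- function(name, ages, values) {
  ages <- as.matrix(ages)
  if (is.matrix(values) && !all(dim(values) == dim(ages)))
    abort("values matrix must match the ages matrix", "limnoflux_schema_error")
  if (!is.matrix(values) && length(values) != ncol(ages))
    abort("values vector must have one entry per sample", "limnoflux_schema_error")
  structure(list(name = name, ages = ages, values = values),
            class = "au_series")
}

#' Age-uncertain series from a flux ensemble
#' @param fe a `flux_ensemble`.
#' @param what `"toc_flux"` or `"l_flux"`.
#' @param name variable name (default `what`).
#' @export
au_from_flux <- function(fe, what = c("toc_flux", "l_flux"), name = NULL) {
  what <- match.arg(what)
  au_series(if (is.null(name)) what else name, fe$age_ce, fe[[what]])
}

#' Age-uncertain ensemble PCA
#'
#' For each of `n_members_used` ensemble draws, every variable is averaged
#' onto a common time grid (bins empty for that draw become missing),
#' columns are standardized within the draw, and a probabilistic PCA
#' integrates the missing bins out. Component signs are aligned to the
#' first draw's loadings (sign of the loading dot product), making the
#' summary invariant to per-member sign flips. Scores are summarized per
#' bin by the median and the 50%/95% highest-density regions.
#'
#' @param series list of [au_series()] objects (>= 2).
#' @param bin_width bin width, yr (default 25).
#' @param t0,t1 time window, yr CE (defaults 800-2015).
#' @param n_members_used ensemble draws used.
#' @param n_components latent components (default 2).
#' @param seed RNG seed (member selection).
#' @return an `ensemble_pca`: `bin_centre`, per-draw `scores` (draw x bin x
#'   component array), `summary` data frame (component, bin, median, hdi
#'   bounds), `loadings` (draw x variable x component), `varfrac` (draw x
#'   component).
#' @export
age_uncertain_pca <- function(series, bin_width = 25, t0 = 800, t1 = 2015,
                              n_members_used = 100, n_components = 2,
                              seed = NULL) {
  if (length(series) < 1L)
    abort("age-uncertain PCA needs at least one variable", "limnoflux_parameter_error")
  breaks <- seq(t0, t1 + bin_width - 1e-9, by = bin_width)
  nb <- length(breaks) - 1L
  nv <- length(series)
  M <- min(vapply(series, function(s) nrow(s$ages), numeric(1)))
  if (M < 1) abort("empty ensembles", "limnoflux_data_error")
  draws <- with_seed(seed, {
    if (M >= n_members_used) sample.int(M, n_members_used)
    else sample.int(M, n_members_used, replace = TRUE)
  })

  bin_one <- function(s, m) {
    v <- if (is.matrix(s$values)) s$values[m, ] else s$values
    bin_means(s$ages[m, ], v, breaks)
  }

  ## global coverage check on the first draw
  occ <- vapply(series, function(s) !is.na(bin_one(s, draws[1])), logical(nb))
  if (mean(rowSums(occ) == 0) > 0.5)
    abort("more than half of the time bins are empty for every variable",
          "limnoflux_coverage_error")

  scores <- array(NA_real_, c(length(draws), nb, n_components))
  loadings <- array(NA_real_, c(length(draws), nv, n_components),
                    dimnames = list(NULL, vapply(series, `[[`, "", "name"), NULL))
  varfrac <- matrix(NA_real_, length(draws), n_components)
  ref <- NULL
  for (j in seq_along(draws)) {
    m <- draws[j]
    X <- vapply(series, bin_one, numeric(nb), m = m)
    ## standardize per variable within the draw (observed bins)
    X <- apply(X, 2, function(col) {
      mu <- mean(col, na.rm = TRUE); sd <- stats::sd(col, na.rm = TRUE)
      if (!is.finite(sd) || sd == 0) sd <- 1
      (col - mu) / sd
    })
    rows_ok <- rowSums(is.finite(X)) > 0L
    if (nv == 1L) {
      # degenerate one-variable "PCA": the component is the variable itself
      scores[j, , 1] <- X[, 1]
      loadings[j, 1, 1] <- 1
      varfrac[j, 1] <- 1
      next
    }
    q <- min(n_components, nv - 1L)
    p <- tryCatch(
      ppca_missing(X[rows_ok, , drop = FALSE], n_components = q,
                   tol = 1e-7, max_iter = 500),
      limnoflux_error = function(e) NULL)
    if (is.null(p)) next
    ld <- p$loadings
    sc <- matrix(NA_real_, nb, q)
    sc[rows_ok, ] <- p$scores
    if (is.null(ref)) ref <- ld
    for (k in seq_len(q)) {
      if (sum(ld[, k] * ref[, k]) < 0) { ld[, k] <- -ld[, k]; sc[, k] <- -sc[, k] }
    }
    scores[j, , seq_len(q)] <- sc
    loadings[j, , seq_len(q)] <- ld
    varfrac[j, seq_len(q)] <- p$varfrac[seq_len(q)]
  }

  bin_centre <- (breaks[-1] + breaks[-length(breaks)]) / 2
  summ <- do.call(rbind, lapply(seq_len(n_components), function(k) {
    do.call(rbind, lapply(seq_len(nb), function(b) {
      v <- scores[, b, k]
      h50 <- hdi_interval(v, 0.50); h95 <- hdi_interval(v, 0.95)
      data.frame(component = k, bin_centre = bin_centre[b],
                 median = if (all(is.na(v))) NA_real_ else
                   stats::median(v, na.rm = TRUE),
                 hdi50_lo = h50[1], hdi50_hi = h50[2],
                 hdi95_lo = h95[1], hdi95_hi = h95[2])
    }))
  }))
  structure(list(bin_centre = bin_centre, scores = scores,
                 loadings = loadings, varfrac = varfrac, summary = summ,
                 n_draws = length(draws)),
            class = "ensemble_pca")
}

#' Per-sample diatom summaries
#'
#' Relative abundances, planktonic fraction, chrysophyte-cyst-to-diatom
#' (C/D) ratio, and valve concentration from the microsphere spike:
#' `valves g^-1 = total * (spike / microspheres) / mass`.
#'
#' @param counts a `diatom_counts` table.
#' @param planktonic taxon names counted as planktonic (default: the
#'   attribute set by [simulate_diatoms()], if present).
#' @param concentration compute valve concentrations (requires positive
#'   microsphere counts, spike and mass).
#' @return list: `rel` (samples x taxa), `planktonic_fraction`, `cd_ratio`,
#'   `valves_per_g` (NULL unless requested).
#' @export
diatom_summaries <- function(counts, planktonic = attr(counts, "planktonic"),
                             concentration = !is.null(counts$microspheres)) {
  m <- count_matrix(counts)
  tot <- rowSums(m)
  if (any(tot <= 0))
    abort("valve totals must be > 0", "limnoflux_data_error")
  rel <- m / tot
  pf <- if (!is.null(planktonic) && length(planktonic))
    rowSums(rel[, intersect(colnames(rel), planktonic), drop = FALSE])
  else rep(NA_real_, nrow(rel))
  cd <- if (!is.null(counts$cysts)) counts$cysts / tot else rep(NA_real_, nrow(rel))
  vpg <- NULL
  if (concentration) {
    if (is.null(counts$microspheres) || any(counts$microspheres <= 0))
      abort("valve concentration requested but microsphere counts are missing or zero",
            "limnoflux_data_error")
    vpg <- tot * (counts$spike / counts$microspheres) / counts$mass_g
  }
  list(rel = rel, planktonic_fraction = pf, cd_ratio = cd, valves_per_g = vpg)
}
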