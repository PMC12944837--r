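# Source characterization by correlation-matrix PCA with varimax rotation.
#
# Concentrations are imputed (non-detects at LOD/sqrt(2)), natural-log
# transformed to tame the heavy right tails, column-standardized, and
# decomposed via the correlation matrix. Components are retained by an
# eigenvalue > 1 rule with a near-one slack used only when needed to reach
# a cumulative-variance target, then varimax-rotated in the factor-loading
# convention (eigenvectors scaled by sqrt eigenvalue).

#' Component retention rule
#'
#' Components with eigenvalues above `eigen_threshold` are always retained;
#' a component with eigenvalue within `near_one_slack` below the threshold
#' may additionally be retained when needed to reach `cumulative_target`.
#'
#' @param eigen_threshold Eigenvalue cutoff (default 1, the Kaiser rule for
#'   correlation-matrix PCA).
#' @param cumulative_target Target cumulative variance fraction
#'   (default 0.70).
#' @param near_one_slack Allowed shortfall below the eigenvalue cutoff for
#'   the extra component (default 0.05).
#' @return Object of class `retention_rule`.
#' @export
retention_rule <- function(eigen_threshold = 1.0, cumulative_target = 0.70,
                           near_one_slack = 0.05) {
  stopifnot(eigen_threshold > 0, cumulative_target > 0, near_one_slack >= 0)
  structure(list(eigen_threshold = eigen_threshold,
                 cumulative_target = cumulative_target,
                 near_one_slack = near_one_slack),
            class = "retention_rule")
}

#' Prepare the log-standardized concentration matrix for PCA
#'
#' Restricts the survey to a stratum, checks the detection-rate inclusion
#' gate for each requested metal (by default rate > 40%, the PCA gate),
#' imputes non-detects at LOD/sqrt(2), takes natural logs, and standardizes
#' each metal column to mean 0 and (sample) sd 1.
#'
#' @param ds A `survey` tibble.
#' @param metals Metal symbols to include (at least 2).
#' @param country,category,product_type Optional stratum filters.
#' @param detection_threshold Inclusion gate threshold (default 0.40).
#' @param strict Strict inequality for the gate (default `TRUE`, i.e.
#'   rate > threshold).
#' @param check_gate Set `FALSE` to bypass the gate (e.g. for fixtures).
#' @return Object of class `pca_input`: list with the standardized
#'   `matrix` (samples x metals), `metal_order`, and the unstandardized
#'   log matrix `log_matrix`.
#' @export
prepare_matrix <- function(ds, metals, country = NULL, category = NULL,
                           product_type = NULL, detection_threshold = 0.40,
                           strict = TRUE, check_gate = TRUE) {
  stopifnot(length(metals) >= 2, all(metals %in% metal_symbols()))
  sub <- filter_stratum(ds, country, category, product_type)
  if (check_gate) {
    passing <- select_metals_by_detection(sub, detection_threshold,
                                          strict = strict)
    failed <- setdiff(metals, passing)
    if (length(failed) > 0) {
      stop("metal(s) below the detection-rate gate: ",
           paste(failed, collapse = ", "), call. = FALSE)
    }
  }
  sub <- sub[sub$metal %in% metals, , drop = FALSE]
  wide <- tidyr::pivot_wider(
    tibble::tibble(sample_id = sub$sample_id, metal = sub$metal,
                   conc = impute_nondetects(sub$value, sub$detected, sub$lod)),
    names_from = "metal", values_from = "conc")
  if (!all(metals %in% names(wide)) || anyNA(wide[metals])) {
    stop("every sample must carry a determination for every requested metal",
         call. = FALSE)
  }
  m <- log(as.matrix(wide[metals]))
  if (nrow(m) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column for metal ",
         paste(metals[sds == 0], collapse = ", "), call. = FALSE)
  }
  x <- scale(m)
  structure(list(matrix = x, metal_order = metals, log_matrix = m,
                 sample_id = wide$sample_id),
            class = "pca_input")
}

#' Fit correlation-matrix PCA
#'
#' Eigendecomposition of the correlation matrix of the prepared input.
#' Components are ordered by descending eigenvalue with a deterministic
#' sign convention: the largest-magnitude loading of each component is made
#' positive. `loadings` holds the orthonormal eigenvectors;
#' `factor_loadings` holds eigenvectors scaled by sqrt(eigenvalue), whose
#' squared row sums are the communalities.
#'
#' @param x A `pca_input`.
#' @return Object of class `pca_model` with elements `eigenvalues`,
#'   `loadings`, `factor_loadings`, `scores`, `variance_fraction`,
#'   `cumulative_variance`, `metal_order`.
#' @export
fit_pca <- function(x) {
  stopifnot(inherits(x, "pca_input"))
  if (!all(is.finite(x$matrix))) stop("non-finite input", call. = FALSE)
  r <- stats::cor(x$log_matrix)
  e <- eigen(r, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- x$metal_order
  colnames(vecs) <- paste0("PC", seq_along(vals))
  fl <- vecs %*% diag(sqrt(vals), nrow = length(vals))
  dimnames(fl) <- dimnames(vecs)
  scores <- x$matrix %*% vecs
  structure(list(
    eigenvalues = vals,
    loadings = vecs,
    factor_loadings = fl,
    scores = scores,
    variance_fraction = vals / sum(vals),
    cumulative_variance = cumsum(vals) / sum(vals),
    metal_order = x$metal_order
  ), class = "pca_model")
}

#' Number of components to retain
#'
#' Applies [retention_rule()]: all components with eigenvalue above the
#' threshold are retained (at least one), and while the cumulative variance
#' falls short of the target, the next component is added provided its
#' eigenvalue is within the near-one slack of the threshold.
#'
#' @param model A `pca_model`.
#' @param rule A [retention_rule()].
#' @return Integer k >= 1.
#' @export
retain_components <- function(model, rule = retention_rule()) {
  vals <- model$eigenvalues
  cum <- cumsum(vals) / sum(vals)
  k <- max(1L, sum(vals > rule$eigen_threshold))
  while (cum[k] < rule$cumulative_target && k < length(vals) &&
         vals[k + 1] >= rule$eigen_threshold - rule$near_one_slack) {
    k <- k + 1L
  }
  k
}

#' @keywords internal
varimax_criterion <- function(L) {
  p <- nrow(L)
  sq <- L^2
  sum(colSums(sq^2) - colSums(sq)^2 / p)
}

#' Varimax rotation (Kaiser row-normalized, pairwise planar rotations)
#'
#' Orthogonal rotation of the first k factor-loading columns maximizing the
#' varimax criterion. Rows are Kaiser-normalized (divided by the square
#' root of their communality) before rotation and restored afterwards, so
#' per-metal communalities are preserved exactly up to floating point.
#' Iteration stops when a full sweep of column pairs improves the criterion
#' by less than `eps`, or after `max_sweeps` sweeps.
#'
#' @param loadings Metals x components matrix of factor loadings
#'   (eigenvectors scaled by sqrt eigenvalue).
#' @param k Number of components to rotate (default all columns).
#' @param normalize Kaiser row normalization (default `TRUE`).
#' @param eps Convergence tolerance on the criterion gain (default 1e-6).
#' @param max_sweeps Sweep limit (default 1000).
#' @return List with `loadings` (rotated metals x k matrix), `rotmat`
#'   (k x k orthogonal rotation), `sweeps`, `criterion`.
#' @export
varimax_rotate <- function(loadings, k = ncol(loadings), normalize = TRUE,
                           eps = 1e-6, max_sweeps = 1000) {
  stopifnot(k >= 1, k <= ncol(loadings))
  L <- loadings[, seq_len(k), drop = FALSE]
  rot <- diag(k)
  if (k == 1) {
    return(list(loadings = L, rotmat = rot, sweeps = 0L,
                criterion = varimax_criterion(L)))
  }
  h <- sqrt(rowSums(L^2))
  scale_rows <- if (normalize) ifelse(h > 0, h, 1) else rep(1, nrow(L))
  W <- L / scale_rows
  p <- nrow(W)
  crit <- varimax_criterion(W)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        x <- W[, i]; y <- W[, j]
        u <- x^2 - y^2
        v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- 2 * sum(u * v)
        num <- D - 2 * A * B / p
        den <- C - (A^2 - B^2) / p
        theta <- atan2(num, den) / 4
        if (abs(theta) < 1e-12) next
        cs <- cos(theta); sn <- sin(theta)
        W[, i] <- x * cs + y * sn
        W[, j] <- -x * sn + y * cs
        ri <- rot[, i]; rj <- rot[, j]
        rot[, i] <- ri * cs + rj * sn
        rot[, j] <- -ri * sn + rj * cs
      }
    }
    new_crit <- varimax_criterion(W)
    if (new_crit - crit < eps || sweeps >= max_sweeps) {
      crit <- new_crit
      break
    }
    crit <- new_crit
  }
  out <- W * scale_rows
  dimnames(out) <- list(rownames(loadings), paste0("RC", seq_len(k)))
  list(loadings = out, rotmat = rot, sweeps = sweeps, criterion = crit)
}

#' Biplot-ready scores and loading vectors
#'
#' First-two-component sample scores and metal loading vectors as plain
#' tibbles for plotting.
#'
#' @param model A `pca_model`.
#' @param input The `pca_input` the model was fitted to (for sample ids).
#' @return List of two tibbles: `scores` (`sample_id`, `PC1`, `PC2`) and
#'   `vectors` (`metal`, `PC1`, `PC2`, from the factor loadings).
#' @export
biplot_data <- function(model, input = NULL) {
  stopifnot(inherits(model, "pca_model"))
  if (length(model$eigenvalues) < 2) {
    stop("biplot requires at least 2 components", call. = FALSE)
  }
  ids <- if (!is.null(input)) input$sample_id else
    seq_len(nrow(model$scores))
  list(
    scores = tibble::tibble(sample_id = ids,
                            PC1 = model$scores[, 1], PC2 = model$scores[, 2]),
    vectors = tibble::tibble(metal = model$metal_order,
                             PC1 = model$factor_loadings[, 1],
                             PC2 = model$factor_loadings[, 2])
  )
}
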