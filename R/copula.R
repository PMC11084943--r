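#' Gaussian-copula specification for correlated behavioral variables
#'
#' A copula spec pins the joint rank-correlation structure (a target Spearman
#' matrix) and the marginal distribution of each behavioral variable. Samples
#' are drawn by mapping a latent multivariate normal through the marginal
#' quantile functions; the latent Pearson matrix is obtained from the target
#' Spearman matrix via the exact bivariate-normal conversion
#' `r_P = 2 * sin(pi * r_S / 6)`.
#'
#' Supported marginal descriptors are lists `list(dist = , ...)` with
#' `dist` one of `"norm"` (`mean`, `sd`), `"lnorm"` (`meanlog`, `sdlog`),
#' `"gamma"` (`shape`, `rate`), `"beta"` (`shape1`, `shape2`) and `"unif"`
#' (`min`, `max`).
#'
#' @param target_spearman Symmetric matrix with unit diagonal; the desired
#'   Spearman correlations.
#' @param marginals Named list of marginal descriptors, one per variable.
#'   Defaults to standard normal for every variable.
#' @param variables Variable names; taken from `target_spearman` dimnames or
#'   `marginals` names when omitted.
#' @return An object of class `copula_spec`.
#' @examples
#' s <- matrix(0.5, 2, 2); diag(s) <- 1
#' dimnames(s) <- list(c("A", "B"), c("A", "B"))
#' copula_spec(s)
#' @export
copula_spec <- function(target_spearman, marginals = NULL, variables = NULL) {
  m <- as.matrix(target_spearman)
  if (is.null(variables))
    variables <- if (!is.null(colnames(m))) colnames(m) else names(marginals)
  if (is.null(variables))
    variables <- paste0("V", seq_len(ncol(m)))
  stopifnot(nrow(m) == ncol(m), length(variables) == ncol(m))
  dimnames(m) <- list(variables, variables)
  if (max(abs(m - t(m))) > 1e-10) stop("target Spearman matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-10) stop("target Spearman matrix must have unit diagonal")
  if (any(abs(m) > 1)) stop("Spearman correlations must lie in [-1, 1]")

  if (is.null(marginals))
    marginals <- stats::setNames(
      rep(list(list(dist = "norm", mean = 0, sd = 1)), length(variables)),
      variables)
  if (!setequal(names(marginals), variables))
    stop("marginals must be named after the variables")
  marginals <- marginals[variables]
  lapply(marginals, .validate_marginal)

  latent <- spearman_to_pearson(m)
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    viol <- .worst_pair(latent)
    stop(sprintf(
      "converted Pearson matrix is not positive semi-definite (min eigenvalue %.3g); strongest off-diagonal pair: %s-%s (%.3f)",
      min(ev), viol[1], viol[2], latent[viol[1], viol[2]]))
  }
  structure(list(variables = variables, target_spearman = m,
                 latent_pearson = latent, marginals = marginals),
            class = "copula_spec")
}

#' @rdname copula_spec
#' @param rho Spearman correlation value(s).
#' @export
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

.validate_marginal <- function(d) {
  if (!is.list(d) || is.null(d$dist))
    stop("each marginal must be a list with a 'dist' element")
  if (!d$dist %in% c("norm", "lnorm", "gamma", "beta", "unif"))
    stop("unsupported marginal distribution: ", d$dist)
  invisible(d)
}

.worst_pair <- function(m) {
  a <- abs(m); diag(a) <- 0
  idx <- which(a == max(a), arr.ind = TRUE)[1L, ]
  rownames(m)[idx]
}

.marginal_quantile <- function(d, u) {
  switch(d$dist,
    norm  = stats::qnorm(u, d$mean, d$sd),
    lnorm = stats::qlnorm(u, d$meanlog, d$sdlog),
    gamma = stats::qgamma(u, shape = d$shape, rate = d$rate),
    beta  = stats::qbeta(u, d$shape1, d$shape2),
    unif  = stats::qunif(u, d$min, d$max))
}

#' Sample a behavior matrix from a copula specification
#'
#' Draws `n` subjects from the Gaussian copula of `spec`: a latent
#' multivariate normal with the converted Pearson matrix, pushed through the
#' marginal quantile functions. The sample's rank-correlation structure
#' approximates `spec$target_spearman`.
#'
#' @param spec A [copula_spec].
#' @param n Number of subjects (rows); at least 3.
#' @param seed Integer seed; if `NULL` the current RNG stream is used.
#' @param subject_ids Optional row names.
#' @return A numeric matrix, subjects in rows and the spec's variables in
#'   columns.
#' @export
sample_behavior_matrix <- function(spec, n, seed = NULL, subject_ids = NULL) {
  stopifnot(inherits(spec, "copula_spec"), n >= 3)
  if (!is.null(seed)) set.seed(as.integer(seed))
  k <- length(spec$variables)
  # tiny ridge keeps chol() stable for boundary-PSD hub structures
  ch <- chol(spec$latent_pearson + diag(k) * 1e-10)
  z <- matrix(stats::rnorm(n * k), nrow = n) %*% ch
  u <- stats::pnorm(z)
  x <- vapply(seq_len(k),
              function(j) .marginal_quantile(spec$marginals[[j]], u[, j]),
              numeric(n))
  dimnames(x) <- list(
    subject_ids %||% sprintf("S%03d", seq_len(n)), spec$variables)
  x
}

#' Default copula specifications for the study subgroups
#'
#' Three ready-made specs over the five network variables (RGT, Lat, PDT,
#' SP, STM) emulating the subgroup-specific trait structure: both non-PDM
#' groups share a strong decision-making/motivation (RGT-Lat) correlation;
#' the control group adds a social axis (SP-STM); the knockdown non-PDM
#' group instead links memory and motivation (STM-Lat); and the
#' knockdown-PDM group is an STM-centered hub in which short-term social
#' memory correlates 0.70 with every other function (with a 0.35 background
#' among the others, the closest positive semi-definite relaxation of an
#' exact STM common factor).
#'
#' @return A named list of [copula_spec] objects: `wt_nonpdm`, `kd_nonpdm`,
#'   `kd_pdm`.
#' @export
default_copulas <- function() {
  vars <- c("RGT", "Lat", "PDT", "SP", "STM")
  base <- function(bg) {
    m <- matrix(bg, 5, 5, dimnames = list(vars, vars)); diag(m) <- 1; m
  }
  wt <- base(0.10); wt["RGT", "Lat"] <- wt["Lat", "RGT"] <- 0.60
  wt["SP", "STM"] <- wt["STM", "SP"] <- 0.60
  kd <- base(0.10); kd["RGT", "Lat"] <- kd["Lat", "RGT"] <- 0.60
  kd["STM", "Lat"] <- kd["Lat", "STM"] <- 0.60
  pdm <- base(0.35); pdm["STM", ] <- pdm[, "STM"] <- 0.70; diag(pdm) <- 1

  marg <- function(rgt_mean, rgt_sd, stm_meanlog) list(
    RGT = list(dist = "norm", mean = rgt_mean, sd = rgt_sd),
    Lat = list(dist = "lnorm", meanlog = log(2), sdlog = 0.4),
    PDT = list(dist = "beta", shape1 = 6, shape2 = 2),
    SP  = list(dist = "lnorm", meanlog = log(2.5), sdlog = 0.3),
    STM = list(dist = "lnorm", meanlog = stm_meanlog, sdlog = 0.25))

  list(
    wt_nonpdm = copula_spec(wt, marg(82, 12, log(2.0))),
    kd_nonpdm = copula_spec(kd, marg(78, 14, log(2.0))),
    kd_pdm    = copula_spec(pdm, marg(18, 8, log(1.0))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
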